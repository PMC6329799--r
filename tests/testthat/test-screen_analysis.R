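tiny_library <- function(genes, is_control = genes == "scrambled",
                         ids = sprintf("hp%02d", seq_along(genes))) {
  shrna_library(data.frame(hairpin_id = ids, gene = genes,
                           guide_seq = helper_guides(length(genes)),
                           is_control = is_control, stringsAsFactors = FALSE))
}

test_that("count normalization yields within-sample frequencies", {
  m <- cbind(s1 = c(10, 30, 60))
  rownames(m) <- paste0("hp", 1:3)
  expect_equal(unname(normalize_counts(m, 0)[, 1]), c(0.1, 0.3, 0.6))
  m2 <- cbind(s1 = c(0, 0)); rownames(m2) <- c("a", "b")
  expect_equal(unname(normalize_counts(m2, 0.5)[, 1]), c(0.5, 0.5))
  expect_error(normalize_counts(m2, 0), "non-positive total")
  set.seed(1)
  m3 <- matrix(rpois(40, 20), 10, 4,
               dimnames = list(paste0("h", 1:10), paste0("s", 1:4)))
  expect_equal(unname(colSums(normalize_counts(m3, 0.5))), rep(1, 4),
               tolerance = 1e-9)
})

test_that("fold changes are control-normalized ratios of frequencies", {
  lib <- tiny_library(c("A", "scrambled"))
  freqs <- rbind(hp01 = c(inp = 0.01, out = 0.04),
                 hp02 = c(inp = 0.02, out = 0.04))  # control raw ratio 2
  fc <- fold_change(freqs, "inp", "out", lib, "median")
  expect_equal(fc$fc[fc$hairpin_id == "hp01"], 2.0)
  expect_equal(fc$log2fc[fc$hairpin_id == "hp01"], 1.0)
  # the sole control self-normalizes to fc 1
  expect_equal(fc$fc[fc$hairpin_id == "hp02"], 1.0)
  expect_equal(fc$log2fc[fc$hairpin_id == "hp02"], 0.0)
})

test_that("median control summary uses the middle control ratio", {
  lib <- tiny_library(c(rep("A", 5), rep("scrambled", 3)))
  inp <- rep(0.125, 8)
  out <- 0.125 * c(1.3, 0.7, 2, 1.1, 0.9, 0.5, 1.0, 4.0)  # ctrl raws .5,1,4
  freqs <- cbind(inp = inp, out = out)
  rownames(freqs) <- sprintf("hp%02d", 1:8)
  fc <- fold_change(freqs, "inp", "out", lib, "median")
  raw <- out / inp
  expect_equal(fc$fc, unname(raw / 1.0))
  # and with no controls, an explicit instruction is required
  lib2 <- tiny_library(rep("A", 3))
  freqs2 <- freqs[1:3, ]
  expect_error(fold_change(freqs2, "inp", "out", lib2, "median"),
               "control_summary")
  fc2 <- fold_change(freqs2, "inp", "out", lib2, "none")
  expect_equal(fc2$fc, unname(raw[1:3]))
})

test_that("log2 fold changes average across replicates", {
  r1 <- data.frame(hairpin_id = c("a", "b"), log2fc = c(1, 0))
  r2 <- data.frame(hairpin_id = c("a", "b"), log2fc = c(3, 2))
  expect_equal(unname(mean_log2fc(list(r1, r2))), c(2, 1))
  expect_equal(unname(mean_log2fc(list(r1))), c(1, 0))
  r3 <- data.frame(hairpin_id = c("b", "a"), log2fc = c(3, 2))
  expect_error(mean_log2fc(list(r1, r3)), "different hairpin sets")
})

test_that("replicate correlation is plain Pearson r", {
  expect_equal(replicate_correlation(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(replicate_correlation(c(1, 2, 3), -c(1, 2, 3)), -1.0)
  # hand computation: cov = 5, var1 = 2 (x2), var2 = 114/9 (x2) -> 5/sqrt(2*114/9)
  expect_equal(round(replicate_correlation(c(1, 2, 3), c(2, 4, 7)), 4), 0.9934)
  expect_error(replicate_correlation(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("ranks and percentiles are consistent and deterministic on ties", {
  mlfc <- stats::setNames(c(2, 0, -1), c("a", "b", "c"))
  rk <- rank_percentiles(mlfc)
  expect_equal(rk$enrich_rank, c(1, 2, 3))
  expect_equal(rk$deplete_rank, c(3, 2, 1))
  mlfc10 <- stats::setNames(10:1, sprintf("h%02d", 1:10))
  rk10 <- rank_percentiles(mlfc10)
  expect_equal(rk10$enrich_pctile[1], 0.1)
  # all tied: ranks follow hairpin_id order
  tied <- stats::setNames(rep(1, 4), c("d", "b", "a", "c"))
  rkt <- suppressMessages(rank_percentiles(tied))
  expect_equal(rkt$enrich_rank[match(c("a", "b", "c", "d"), rkt$hairpin_id)],
               1:4)
  # untied: enrich + deplete = N + 1 for every hairpin
  set.seed(8)
  v <- stats::setNames(rnorm(25), sprintf("x%02d", 1:25))
  rkv <- rank_percentiles(v)
  expect_equal(rkv$enrich_rank + rkv$deplete_rank, rep(26L, 25))
})

test_that("the hit caller matches the brute-force rule on a planted case", {
  # 10 genes x 3 hairpins + 5 controls; 2 planted enriched genes, 1 of them
  # also enriched in the counter arm -> exactly 1 ENRICHED call
  set.seed(21)
  gene_of <- c(rep(sprintf("g%02d", 1:10), each = 3), rep("scrambled", 5))
  ids <- sprintf("hp%02d", seq_along(gene_of))
  aml <- stats::setNames(rnorm(35, 0, 0.1), ids)
  ctr <- stats::setNames(rnorm(35, 0, 0.1), ids)
  aml[gene_of == "g01"] <- aml[gene_of == "g01"] + 3
  aml[gene_of == "g02"] <- aml[gene_of == "g02"] + 3
  ctr[gene_of == "g02"] <- ctr[gene_of == "g02"] + 3
  is_control <- gene_of == "scrambled"
  lib <- tiny_library(gene_of, is_control, ids)
  params <- hit_params()
  hits <- call_hits(as_fc_table(aml, gene_of, is_control),
                    as_fc_table(ctr, gene_of, is_control), lib, params)
  called <- hits[hits$called & hits$direction == "ENRICHED", ]
  expect_equal(called$gene, "g01")
  flagged <- hits[hits$direction == "ENRICHED" & hits$counter_flag, ]
  expect_true("g02" %in% flagged$gene)
  want <- oracle_hits(aml, ctr, gene_of, is_control, params)
  got <- as.data.frame(hits)[order(hits$direction, hits$gene), ]
  rownames(got) <- NULL
  expect_equal(got, want)
})

test_that("a gene supported by a single hairpin is never called", {
  gene_of <- c("g1", rep("g2", 3), rep("scrambled", 2))
  ids <- sprintf("hp%d", 1:6)
  aml <- stats::setNames(c(5, 0.1, -0.1, 0.2, 0, 0.05), ids)
  ctr <- stats::setNames(rep(0:1, 3) * 0.01, ids)
  lib <- tiny_library(gene_of, gene_of == "scrambled", ids)
  hits <- call_hits(as_fc_table(aml, gene_of, gene_of == "scrambled"),
                    as_fc_table(ctr, gene_of, gene_of == "scrambled"),
                    lib, hit_params())
  expect_false("g1" %in% hits$gene[hits$called])
})

test_that("fold changes, ranks and calls are invariant to sample rescaling", {
  ps <- planted_screen(1, n_genes = 20, n_hairpins = 54, n_controls = 4,
                       pool_size = 58, depth_per_hairpin = 100)
  params <- hit_params(pseudocount = 0)
  cm <- ps$sim$aml
  fc1 <- fold_change_table(cm, "AML", params)
  counts2 <- cm$counts
  counts2[, "AML_OUT_R1"] <- counts2[, "AML_OUT_R1"] * 7L
  cm2 <- count_matrix(counts2, cm$samples, ps$sim$library)
  fc2 <- fold_change_table(cm2, "AML", params)
  expect_equal(fc1$mean_log2fc, fc2$mean_log2fc, tolerance = 1e-12)
  expect_equal(fc1$enrich_rank, fc2$enrich_rank)
})

test_that("with an odd control count the median control has fc exactly 1", {
  ps <- planted_screen(2, n_genes = 10, n_hairpins = 30, n_controls = 5,
                       pool_size = 35)
  fc <- fold_change_table(ps$sim$aml, "AML", hit_params())
  ctrl_fc <- 2^fc$log2fc_rep1[fc$is_control]
  expect_equal(sort(ctrl_fc)[3], 1, tolerance = 1e-12)
})

test_that("loosening enrich_pct never removes candidates; raising support never adds calls", {
  # The enrichment cutoff applies to both arms, so the clean monotonicity is
  # at the AML-criterion (candidate) level; min_support monotonicity holds
  # for final calls because support counts in both arms only shrink.
  for (seed in 1:8) {
    inst <- random_hit_instance(seed + 100)
    lib <- instance_library(inst)
    aml_fc <- as_fc_table(inst$aml, inst$gene_of, inst$is_control)
    ctr_fc <- as_fc_table(inst$ctr, inst$gene_of, inst$is_control)
    hits_with <- function(p) call_hits(aml_fc, ctr_fc, lib, p)
    base <- hits_with(hit_params(enrich_pct = 0.2, min_support = 2))
    loose <- hits_with(hit_params(enrich_pct = 0.35, min_support = 2))
    strict <- hits_with(hit_params(enrich_pct = 0.2, min_support = 3,
                                   counter_min_support = 2))
    cand <- function(h) h$gene[h$direction == "ENRICHED"]
    called <- function(h) h$gene[h$called & h$direction == "ENRICHED"]
    expect_true(all(cand(base) %in% cand(loose)))
    expect_true(all(called(strict) %in% called(base)))
  }
})

test_that("competitive GFP/YFP ratios are normalized to the input mixture", {
  expect_equal(competitive_ratio(c(0.5, 0.5), c(0.5, 0.5)), c(1, 1))
  expect_equal(competitive_ratio(c(0.5, 0.6667), c(0.5, 0.3333)),
               c(1, 2), tolerance = 0.01)
  expect_equal(competitive_ratio(c(0.4, 0.4, 0.6), c(0.6, 0.6, 0.4)),
               c(1, 1, 2.25))
  expect_error(competitive_ratio(c(0.5, 0), c(0.5, 1)), "strictly between")
})
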