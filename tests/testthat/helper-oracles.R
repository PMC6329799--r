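# Independent oracles used to validate the package implementations.
# These are deliberately naive (loops, enumeration) and share no code with
# the functions they check.

# Percentile of each hairpin by explicit pairwise comparison (ties by id).
oracle_pctile <- function(v, decreasing) {
  n <- length(v)
  ids <- names(v)
  r <- integer(n)
  for (i in seq_len(n)) {
    better <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      if (decreasing) {
        if (v[j] > v[i] || (v[j] == v[i] && ids[j] < ids[i])) better <- better + 1
      } else {
        if (v[j] < v[i] || (v[j] == v[i] && ids[j] < ids[i])) better <- better + 1
      }
    }
    r[i] <- better + 1
  }
  stats::setNames(r / n, ids)
}

# Verbatim evaluation of the hit rule: a gene scores in a direction when at
# least min_support of its hairpins rank within the cutoff percentile of the
# AML arm, and is called when the same criterion fails in the counter arm.
oracle_hits <- function(aml_mlfc, ctr_mlfc, gene_of, is_control, params) {
  dirs <- list(ENRICHED = list(dec = TRUE, cut = params$enrich_pct),
               DEPLETED = list(dec = FALSE, cut = params$deplete_pct))
  out <- list()
  for (d in names(dirs)) {
    p_aml <- oracle_pctile(aml_mlfc, dirs[[d]]$dec)
    p_ctr <- oracle_pctile(ctr_mlfc, dirs[[d]]$dec)
    for (g in sort(unique(gene_of[!is_control]))) {
      hps <- names(aml_mlfc)[gene_of == g & !is_control]
      sup <- hps[p_aml[hps] <= dirs[[d]]$cut]
      ctr_sup <- hps[p_ctr[hps] <= dirs[[d]]$cut]
      if (length(sup) >= params$min_support) {
        out[[paste(g, d)]] <- data.frame(
          gene = g, direction = d, n_support = length(sup),
          support_ids = paste(sort(sup), collapse = ","),
          counter_flag = length(ctr_sup) >= params$counter_min_support,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(gene = character(), direction = character(),
                      n_support = integer(), support_ids = character(),
                      counter_flag = logical(), called = logical()))
  }
  res <- do.call(rbind, out)
  res$called <- !res$counter_flag
  res <- res[order(res$direction, res$gene), ]
  rownames(res) <- NULL
  res
}

# Exact two-sided Mann-Whitney p by full enumeration of group labelings
# (untied data only).
oracle_mann_whitney <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  u_stat <- function(x, y) sum(outer(x, y, ">"))
  u_obs <- u_stat(a, b)
  sets <- utils::combn(na + nb, na)
  us <- apply(sets, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  list(U = u_obs, p = min(p, 1))
}

# Product-limit estimate by explicit loop (events precede censorings).
oracle_km <- function(time, event) {
  ord <- order(time, -event)
  time <- time[ord]; event <- event[ord]
  s <- 1
  out_t <- numeric(0); out_s <- numeric(0)
  for (t in sort(unique(time[event == 1]))) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    out_t <- c(out_t, t); out_s <- c(out_s, s)
  }
  list(time = out_t, survival = out_s)
}

# Naive all-pairs substring/Hamming read-to-guide assignment.
oracle_count <- function(reads, guides, max_mismatch) {
  counts <- stats::setNames(integer(length(guides)), names(guides))
  unmatched <- 0L
  for (r in reads) {
    best <- Inf; best_g <- NA; tie <- FALSE
    for (gi in seq_along(guides)) {
      g <- guides[gi]; w <- nchar(g)
      dmin <- Inf
      if (nchar(r) >= w) {
        for (off in seq_len(nchar(r) - w + 1)) {
          sub <- substr(r, off, off + w - 1)
          d <- sum(strsplit(sub, "")[[1]] != strsplit(g, "")[[1]])
          dmin <- min(dmin, d)
        }
      }
      if (dmin < best) { best <- dmin; best_g <- gi; tie <- FALSE }
      else if (is.finite(dmin) && dmin == best) tie <- TRUE
    }
    if (is.finite(best) && best <= max_mismatch && !tie) {
      counts[best_g] <- counts[best_g] + 1L
    } else unmatched <- unmatched + 1L
  }
  list(counts = counts, unmatched = unmatched)
}

# Small random screen instance for hit-caller equivalence testing.
random_hit_instance <- function(seed) {
  set.seed(seed)
  n_genes <- sample(2:12, 1)
  hpg <- sample(1:4, n_genes, replace = TRUE)
  gene_of <- rep(sprintf("g%02d", seq_len(n_genes)), hpg)
  n_ctrl <- sample(0:3, 1)
  gene_of <- c(gene_of, rep("scrambled", n_ctrl))
  is_control <- c(rep(FALSE, sum(hpg)), rep(TRUE, n_ctrl))
  ids <- sprintf("hp%03d", seq_along(gene_of))
  aml <- stats::setNames(round(stats::rnorm(length(ids)), 2), ids)
  ctr <- stats::setNames(round(stats::rnorm(length(ids)), 2), ids)
  params <- hit_params(enrich_pct = sample(c(0.2, 0.3), 1),
                       deplete_pct = sample(c(0.25, 0.4), 1),
                       min_support = sample(1:3, 1))
  list(aml = aml, ctr = ctr, gene_of = gene_of, is_control = is_control,
       ids = ids, params = params)
}

# Wrap precomputed mean log2fc vectors as a minimal fc_table for call_hits.
as_fc_table <- function(mlfc, gene_of, is_control) {
  rk <- rank_percentiles(mlfc)
  out <- data.frame(hairpin_id = names(mlfc), gene = gene_of,
                    is_control = is_control, stringsAsFactors = FALSE)
  out <- cbind(out, rk[match(out$hairpin_id, rk$hairpin_id), -1])
  rownames(out) <- NULL
  class(out) <- c("fc_table", "data.frame")
  out
}

helper_hamming <- function(a, b) {
  mapply(function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]), a, b)
}

# Unique random fixed-width guide sequences (test-local).
helper_guides <- function(n, width = 22L) {
  g <- replicate(n, paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
                          collapse = ""))
  while (anyDuplicated(g)) {
    g[duplicated(g)] <- replicate(sum(duplicated(g)),
      paste(sample(c("A", "C", "G", "T"), width, replace = TRUE), collapse = ""))
  }
  g
}

# Library wrapper for synthetic hit instances.
instance_library <- function(inst) {
  shrna_library(data.frame(
    hairpin_id = inst$ids, gene = inst$gene_of,
    guide_seq = helper_guides(length(inst$ids)),
    is_control = inst$is_control, stringsAsFactors = FALSE))
}

# Default screen experiment used by acceptance-style checks: n_enriched
# AML-specific genes (+2) and n_confounded counter-confounded genes among
# neutral genes, drawn at random per seed.
planted_screen <- function(seed, n_enriched = 8, n_confounded = 2, ...) {
  dots <- list(...)
  n_genes <- if (is.null(dots$n_genes)) 230 else dots$n_genes
  genes <- sprintf("G%03d", seq_len(n_genes))
  set.seed(seed * 7919)
  planted <- sample(genes, n_enriched + n_confounded)
  eff <- data.frame(gene = planted, aml_log2_effect = 2,
                    counter_log2_effect = rep(c(0, 2),
                                              c(n_enriched, n_confounded)))
  cfg <- do.call(screen_sim_config,
                 c(list(effects = eff, seed = seed), dots))
  sim <- simulate_screen(cfg)
  list(sim = sim, aml_specific = planted[seq_len(n_enriched)],
       confounded = planted[n_enriched + seq_len(n_confounded)])
}
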