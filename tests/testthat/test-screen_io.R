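make_lib_df <- function() {
  data.frame(
    hairpin_id = c("Rbm25_sh1", "Rbm25_sh2", "CTRL_sh1"),
    gene = c("Rbm25", "Rbm25", "scrambled"),
    guide_seq = c("ACGTACGTACGTACGTACGTAC", "TTGCATGCATGCATGCATGCAT",
                  "GGGCCCAAATTTGGGCCCAAAT"),
    is_control = c(0L, 0L, 1L), stringsAsFactors = FALSE)
}

test_that("library parsing validates and reports the collection", {
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(make_lib_df(), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  lib <- suppressMessages(parse_library(path))
  expect_s3_class(lib, "shrna_library")
  expect_equal(nrow(lib$records), 3)
  expect_equal(length(unique(lib$records$gene[!lib$records$is_control])), 1)
  expect_equal(sum(lib$records$is_control), 1)
})

test_that("duplicate guides and ids are rejected naming the offenders", {
  df <- make_lib_df()
  df$guide_seq[2] <- df$guide_seq[1]
  expect_error(shrna_library(df), "Rbm25_sh1.*Rbm25_sh2")
  df <- make_lib_df()
  df$hairpin_id[2] <- df$hairpin_id[1]
  expect_error(shrna_library(df), "duplicate hairpin_id.*Rbm25_sh1")
  df <- make_lib_df()
  df$guide_seq[3] <- "ACGTACGTNNGTACGTACGTAC"
  expect_error(shrna_library(df), "invalid nucleotide.*CTRL_sh1")
})

test_that("a full-design library (613 hairpins, 230 genes) round-trips", {
  sim <- simulate_screen(screen_sim_config(seed = 42))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_library(sim$library, path)
  lib <- suppressMessages(parse_library(path))
  expect_equal(nrow(lib$records), 633)
  expect_equal(sum(!lib$records$is_control), 613)
  expect_equal(length(unique(lib$records$gene[!lib$records$is_control])), 230)
  expect_equal(lib$records, sim$library$records)
})

test_that("demultiplexing assigns by nearest barcode and respects ties", {
  bmap <- c(ACGT = "s1", TTTT = "s2")
  r <- suppressMessages(demultiplex(c(x = "ACGTAAAACCCC"), bmap, 0))
  expect_equal(unname(r$samples$s1), "AAAACCCC")
  expect_equal(r$unassigned, 0)
  # one mismatch from s1, far from s2
  r <- suppressMessages(demultiplex(c(x = "ACGAAAAACCCC"), bmap, 1))
  expect_equal(length(r$samples$s1), 1)
  # beyond tolerance
  r <- suppressMessages(demultiplex(c(x = "AGGAAAAACCCC"), bmap, 1))
  expect_equal(r$unassigned, 1)
  # too-close barcodes are a configuration error
  expect_error(demultiplex(character(0), c(ACGT = "a", ACGA = "b"), 1),
               "ambiguity is unavoidable")
})

test_that("demultiplexing recovers ground truth and conserves reads", {
  set.seed(11)
  barcodes <- make_barcodes(2, width = 6, min_dist = 3, seed = 11)
  bmap <- stats::setNames(c("s1", "s2"), barcodes)
  truth <- sample(1:2, 100, replace = TRUE)
  payload <- replicate(100, paste(sample(c("A", "C", "G", "T"), 20,
                                         replace = TRUE), collapse = ""))
  reads <- paste0(barcodes[truth], payload)
  corrupt <- sample(100, 10)
  # scramble the barcode of 10 reads beyond max_mismatch of either barcode
  for (i in corrupt) {
    repeat {
      bc <- paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE), collapse = "")
      if (min(helper_hamming(barcodes, bc)) > 1) break
    }
    reads[i] <- paste0(bc, payload[i])
  }
  names(reads) <- sprintf("r%03d", 1:100)
  r <- suppressMessages(demultiplex(reads, bmap, max_mismatch = 1))
  expect_equal(r$unassigned, 10)
  expect_equal(length(r$samples$s1) + length(r$samples$s2) + r$unassigned, 100)
  for (i in setdiff(1:100, corrupt)) {
    smp <- c("s1", "s2")[truth[i]]
    expect_true(names(reads)[i] %in% names(r$samples[[smp]]))
  }
})

test_that("hairpin counting matches a naive all-pairs Hamming search", {
  set.seed(7)
  for (mm in 0:1) {
    guides <- stats::setNames(helper_guides(20, 20), sprintf("hp%02d", 1:20))
    lib <- shrna_library(data.frame(
      hairpin_id = names(guides), gene = paste0("g", 1:20),
      guide_seq = guides, is_control = FALSE, stringsAsFactors = FALSE))
    # reads: embedded guides with 0-2 substitutions, plus junk
    reads <- character(50)
    for (i in 1:40) {
      g <- strsplit(guides[sample(20, 1)], "")[[1]]
      nmut <- sample(0:2, 1)
      if (nmut > 0) {
        pos <- sample(20, nmut)
        g[pos] <- vapply(g[pos], function(ch)
          sample(setdiff(c("A", "C", "G", "T"), ch), 1), character(1))
      }
      pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")
      reads[i] <- paste0(pad(sample(0:4, 1)), paste(g, collapse = ""), pad(3))
    }
    for (i in 41:50) reads[i] <- paste(sample(c("A", "C", "G", "T"), 27,
                                              replace = TRUE), collapse = "")
    got <- count_hairpins(reads, lib, max_mismatch = mm)
    want <- oracle_count(reads, guides, mm)
    expect_equal(got$counts, want$counts)
    expect_equal(got$unmatched, want$unmatched)
    expect_equal(sum(got$counts) + got$unmatched, 50)
  }
})

test_that("counting recovers planted per-hairpin frequencies under 1% noise", {
  sim <- simulate_screen(screen_sim_config(
    n_genes = 10, n_hairpins = 30, n_controls = 2, pool_size = 32, seed = 3))
  cm <- sim$aml
  truth_counts <- cm$counts[, "AML_IN_R1"]
  bc <- make_barcodes(1, seed = 3)
  reads <- simulate_reads(
    count_matrix(cm$counts[, "AML_IN_R1", drop = FALSE],
                 cm$samples[cm$samples$sample_id == "AML_IN_R1", ],
                 sim$library),
    stats::setNames("AML_IN_R1", bc), error_rate = 0.01, seed = 9)[[1]]
  reads <- substr(reads, nchar(bc) + 1, nchar(reads))  # drop barcode
  got <- count_hairpins(reads, sim$library, max_mismatch = 1)
  # 22-mers at 1% substitution: ~98% of reads have <= 1 error and are exactly
  # recoverable; require near-perfect per-hairpin recovery
  expect_true(sum(abs(got$counts - truth_counts)) / sum(truth_counts) < 0.05)
  expect_equal(sum(got$counts) + got$unmatched, sum(truth_counts))
})

test_that("library coverage counts detected hairpins", {
  sim <- simulate_screen(screen_sim_config(
    n_genes = 50, n_hairpins = 150, n_controls = 0, pool_size = 150, seed = 5))
  cm <- sim$aml
  expect_error(library_coverage(cm, "nope"), "unknown sample")
  counts <- cm$counts
  counts[1:15, "AML_IN_R1"] <- 0L
  counts[16:150, "AML_IN_R1"] <- pmax(counts[16:150, "AML_IN_R1"], 1L)
  cm2 <- count_matrix(counts, cm$samples, sim$library)
  expect_equal(library_coverage(cm2, "AML_IN_R1", 1), 0.9)
  counts[, "AML_IN_R2"] <- 0L
  cm3 <- count_matrix(counts, cm$samples, sim$library)
  expect_equal(library_coverage(cm3, "AML_IN_R2", 1), 0)
})

test_that("count matrices round-trip through TSV", {
  sim <- simulate_screen(screen_sim_config(
    n_genes = 3, n_hairpins = 9, n_controls = 1, pool_size = 10, seed = 2))
  cm <- sim$aml
  path <- withr::local_tempfile(fileext = ".tsv")
  spath <- withr::local_tempfile(fileext = ".tsv")
  write_counts(cm, path, spath)
  back <- read_counts(path, spath, sim$library)
  expect_identical(back$counts, cm$counts)
  expect_equal(back$samples, cm$samples)

  # negative count named by cell
  df <- utils::read.delim(path, check.names = FALSE)
  df[2, "AML_IN_R1"] <- -2
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_counts(path, spath, sim$library), "AML_IN_R1")

  # missing hairpin row restored as zeros with a warning
  df <- utils::read.delim(path, check.names = FALSE)
  df <- df[-1, ]
  df[1, "AML_IN_R1"] <- 5  # repair the negative cell
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(back <- read_counts(path, spath, sim$library),
                 "restored as zero")
  expect_equal(unname(back$counts[sim$library$records$hairpin_id[1], ]),
               rep(0L, 4))
})
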