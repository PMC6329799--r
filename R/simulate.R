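# Synthetic-data generators: a negative-binomial pooled-screen simulator with
# planted gene effects and a patient-cohort simulator whose latent RBM25
# level drives isoform scores, the MYC target score and survival hazard.
# Every generator returns a ground-truth table alongside the data.

#' Configuration of the pooled-screen simulator
#'
#' The defaults mirror the screened library design: 613 targeting hairpins
#' over 230 genes in pools of 150 with scrambled controls, duplicate
#' replicates, and deep (500x per hairpin) amplicon sequencing. Counts are
#' negative binomial around expected pool frequencies; each construct
#' carries a hairpin-level log2 fitness perturbation (knockdown-efficiency /
#' off-target variation) shared across replicates and arms, because it is a
#' property of the construct rather than of the sequencing.
#'
#' @param n_genes number of target genes (default 230).
#' @param n_hairpins total targeting hairpins (default 613); distributed as
#'   evenly as possible over genes unless \code{hairpins_per_gene} is given.
#' @param hairpins_per_gene optional integer vector (length \code{n_genes})
#'   overriding the automatic allocation.
#' @param n_controls number of scrambled control hairpins (default 20).
#' @param pool_size sub-pool size recorded in the library (default 150).
#' @param n_replicates biological replicates per arm (default 2).
#' @param depth_per_hairpin mean sequencing reads per hairpin (default 500).
#' @param dispersion negative-binomial dispersion of counts (variance
#'   mu + dispersion * mu^2; default 0.05; 0 gives Poisson). The default,
#'   together with \code{hairpin_efficiency_sd}, reproduces the moderate
#'   replicate correlation (about 0.53) observed in the in vivo screen this
#'   design mirrors.
#' @param effects data.frame with columns \code{gene},
#'   \code{aml_log2_effect}, \code{counter_log2_effect}; genes not listed
#'   are neutral.
#' @param hairpin_efficiency_sd standard deviation (log2 units) of the
#'   construct-level fitness perturbation (default 0.3).
#' @param abundance_sdlog log-normal spread of input pool abundances
#'   (default 0.5).
#' @param seed RNG seed.
#' @return List of class \code{screen_sim_config}.
#' @export
screen_sim_config <- function(n_genes = 230L, n_hairpins = 613L,
                              hairpins_per_gene = NULL, n_controls = 20L,
                              pool_size = 150L, n_replicates = 2L,
                              depth_per_hairpin = 500, dispersion = 0.05,
                              effects = NULL, hairpin_efficiency_sd = 0.3,
                              abundance_sdlog = 0.5, seed = 1L) {
  stopifnot(n_genes >= 1, n_controls >= 0, n_replicates >= 1,
            depth_per_hairpin > 0, dispersion >= 0,
            hairpin_efficiency_sd >= 0, abundance_sdlog >= 0)
  if (is.null(hairpins_per_gene)) {
    base <- n_hairpins %/% n_genes
    if (base < 1) stop("fewer hairpins than genes", call. = FALSE)
    extra <- n_hairpins - base * n_genes
    hairpins_per_gene <- rep(base, n_genes) + rep(c(1L, 0L), c(extra, n_genes - extra))
  }
  stopifnot(length(hairpins_per_gene) == n_genes, all(hairpins_per_gene >= 1))
  n_hairpins <- sum(hairpins_per_gene)
  if (pool_size > n_hairpins + n_controls) {
    stop("pool_size exceeds total number of hairpins", call. = FALSE)
  }
  if (is.null(effects)) {
    effects <- data.frame(gene = character(), aml_log2_effect = numeric(),
                          counter_log2_effect = numeric())
  }
  stopifnot(all(c("gene", "aml_log2_effect", "counter_log2_effect") %in%
                  names(effects)))
  genes <- sprintf("G%03d", seq_len(n_genes))
  unknown <- setdiff(effects$gene, genes)
  if (length(unknown) > 0) {
    stop("effects reference unknown gene(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  structure(list(n_genes = n_genes, n_hairpins = n_hairpins,
                 hairpins_per_gene = as.integer(hairpins_per_gene),
                 n_controls = as.integer(n_controls),
                 pool_size = as.integer(pool_size),
                 n_replicates = as.integer(n_replicates),
                 depth_per_hairpin = depth_per_hairpin,
                 dispersion = dispersion, effects = effects,
                 hairpin_efficiency_sd = hairpin_efficiency_sd,
                 abundance_sdlog = abundance_sdlog, seed = as.integer(seed),
                 genes = genes),
            class = "screen_sim_config")
}

# unique random guide sequences of fixed length
random_guides <- function(n, width = 22L) {
  repeat {
    g <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), width, replace = TRUE), collapse = ""),
      character(1))
    if (!anyDuplicated(g)) return(g)
  }
}

rnb <- function(n, mu, dispersion) {
  if (dispersion > 0) stats::rnbinom(n, mu = mu, size = 1 / dispersion)
  else stats::rpois(n, mu)
}

#' Simulate a pooled shRNA screen with a counter-screen arm
#'
#' Input pool abundances are log-normal; the expected output abundance of a
#' hairpin is its input abundance times \code{2^(gene effect +
#' construct-level perturbation)} for the arm; counts are negative binomial
#' around expected frequencies times sequencing depth. Control hairpins have
#' zero effect and zero perturbation in both arms. The construct
#' perturbation is drawn once per hairpin and shared across replicates and
#' arms.
#'
#' @param cfg a \code{\link{screen_sim_config}}.
#' @return List with \code{aml} and \code{counter}
#'   (\code{\link{count_matrix}} objects sharing one library), \code{truth}
#'   (per-gene planted effects and class), and \code{library}.
#' @export
simulate_screen <- function(cfg) {
  stopifnot(inherits(cfg, "screen_sim_config"))
  set.seed(cfg$seed)
  gene_of <- rep(cfg$genes, cfg$hairpins_per_gene)
  hp_index <- unlist(lapply(cfg$hairpins_per_gene, seq_len))
  ids <- c(sprintf("%s_sh%d", gene_of, hp_index),
           sprintf("CTRL_sh%d", seq_len(cfg$n_controls)))
  is_control <- c(rep(FALSE, cfg$n_hairpins), rep(TRUE, cfg$n_controls))
  gene <- c(gene_of, rep("scrambled", cfg$n_controls))
  nh <- length(ids)

  lib_df <- data.frame(hairpin_id = ids, gene = gene,
                       guide_seq = random_guides(nh), is_control = is_control,
                       stringsAsFactors = FALSE)
  n_pools <- ceiling(nh / cfg$pool_size)
  pool_id <- rep(seq_len(n_pools), each = cfg$pool_size, length.out = nh)
  pools <- split(ids, sprintf("pool%02d", pool_id))
  library <- shrna_library(lib_df, pools)

  eff_aml <- stats::setNames(rep(0, cfg$n_genes), cfg$genes)
  eff_ctr <- eff_aml
  if (nrow(cfg$effects) > 0) {
    eff_aml[cfg$effects$gene] <- cfg$effects$aml_log2_effect
    eff_ctr[cfg$effects$gene] <- cfg$effects$counter_log2_effect
  }
  hp_eff_aml <- c(eff_aml[gene_of], rep(0, cfg$n_controls))
  hp_eff_ctr <- c(eff_ctr[gene_of], rep(0, cfg$n_controls))
  perturb <- c(stats::rnorm(cfg$n_hairpins, 0, cfg$hairpin_efficiency_sd),
               rep(0, cfg$n_controls))
  abundance <- stats::rlnorm(nh, meanlog = 0, sdlog = cfg$abundance_sdlog)

  total_reads <- cfg$depth_per_hairpin * nh
  arm_counts <- function(arm_effect) {
    out_w <- abundance * 2^(arm_effect + perturb)
    cols <- list()
    for (r in seq_len(cfg$n_replicates)) {
      cols[[paste0("IN_R", r)]] <-
        rnb(nh, total_reads * abundance / sum(abundance), cfg$dispersion)
      cols[[paste0("OUT_R", r)]] <-
        rnb(nh, total_reads * out_w / sum(out_w), cfg$dispersion)
    }
    m <- do.call(cbind, cols)
    rownames(m) <- ids
    m
  }
  make_cm <- function(m, arm) {
    colnames(m) <- paste0(arm, "_", colnames(m))
    samples <- data.frame(
      sample_id = colnames(m), arm = arm,
      replicate = as.integer(sub(".*_R", "", colnames(m))),
      timepoint = ifelse(grepl("_IN_", colnames(m)), "INPUT", "OUTPUT"),
      stringsAsFactors = FALSE)
    count_matrix(m, samples, library)
  }
  aml <- make_cm(arm_counts(hp_eff_aml), "AML")
  counter <- make_cm(arm_counts(hp_eff_ctr), "COUNTER")

  truth <- data.frame(gene = cfg$genes,
                      aml_log2_effect = unname(eff_aml),
                      counter_log2_effect = unname(eff_ctr),
                      stringsAsFactors = FALSE)
  truth$class <- ifelse(truth$aml_log2_effect == 0, "NEUTRAL",
                 ifelse(truth$counter_log2_effect != 0, "CONFOUNDED",
                 ifelse(truth$aml_log2_effect > 0, "ENRICHED", "DEPLETED")))
  list(aml = aml, counter = counter, truth = truth, library = library)
}

#' Generate well-separated sample barcodes
#'
#' @param n number of barcodes.
#' @param width barcode length (default 6).
#' @param min_dist minimum pairwise Hamming distance (default 3, allowing
#'   demultiplexing at one mismatch).
#' @param seed RNG seed.
#' @return Character vector of barcodes.
#' @export
make_barcodes <- function(n, width = 6L, min_dist = 3L, seed = 1L) {
  set.seed(seed)
  out <- character(0)
  tries <- 0
  while (length(out) < n) {
    cand <- paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
                  collapse = "")
    if (length(out) == 0 || all(hamming_dist(out, cand) >= min_dist)) {
      out <- c(out, cand)
    }
    tries <- tries + 1
    if (tries > 10000 * n) stop("cannot place ", n, " barcodes at distance >= ",
                                min_dist, " with width ", width, call. = FALSE)
  }
  out
}

#' Emit synthetic amplicon reads realizing a count matrix
#'
#' Writes one read per count: the sample barcode followed by the hairpin's
#' guide sequence, with independent per-base substitution errors at
#' \code{error_rate}. With \code{error_rate = 0},
#' \code{\link{demultiplex}} followed by \code{\link{count_hairpins}}
#' recovers the count matrix exactly.
#'
#' @param cm a \code{\link{count_matrix}}.
#' @param barcode_map named character vector: barcode -> sample id, covering
#'   all samples of \code{cm}.
#' @param error_rate per-base substitution probability in [0, 0.05].
#' @param seed RNG seed.
#' @return Named list: sample id -> character vector of reads (pooled
#'   sequencing of all samples is simply \code{unlist} of the list).
#' @export
simulate_reads <- function(cm, barcode_map, error_rate = 0, seed = 1L) {
  stopifnot(inherits(cm, "count_matrix"),
            error_rate >= 0, error_rate <= 0.05)
  if (!setequal(unname(barcode_map), colnames(cm$counts))) {
    stop("barcode_map must cover exactly the samples of the count matrix",
         call. = FALSE)
  }
  set.seed(seed)
  guides <- stats::setNames(cm$library$records$guide_seq,
                            cm$library$records$hairpin_id)
  out <- stats::setNames(vector("list", ncol(cm$counts)), colnames(cm$counts))
  for (s in colnames(cm$counts)) {
    bc <- names(barcode_map)[barcode_map == s]
    cnt <- cm$counts[, s]
    reads <- if (sum(cnt) == 0) character(0) else
      paste0(bc, rep(guides[rownames(cm$counts)], cnt))
    if (error_rate > 0 && length(reads) > 0) {
      reads <- mutate_reads(reads, error_rate)
    }
    if (length(reads) > 0) names(reads) <- sprintf("%s_read%d", s, seq_along(reads))
    out[[s]] <- reads
  }
  out
}

# independent per-base substitutions to a different base
mutate_reads <- function(reads, rate) {
  widths <- nchar(reads)
  n_mut <- stats::rbinom(length(reads), widths, rate)
  idx <- which(n_mut > 0)
  for (i in idx) {
    pos <- sample.int(widths[i], n_mut[i])
    chars <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    for (p in pos) {
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
    }
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

#' Configuration of the patient-cohort simulator
#'
#' Each simulated patient has a latent standard-normal RBM25 level; coupled
#' scores (BIN1 exon-12 inclusion, the BCL2L1 L/S ratio, the MYC target
#' score) are linear in that latent with the given couplings (in standard
#' deviations per RBM25 standard deviation; the reported biology has all
#' three negative) plus independent noise, and survival is exponential with
#' log-hazard proportional to minus the RBM25 level (low RBM25, worse
#' outcome).
#'
#' @param n_patients cohort size (default 170, the scale of the TCGA AML
#'   cohort).
#' @param rbm25_coupling named numeric vector of couplings (sd units) for
#'   any of \code{"BIN1_plus12"}, \code{"BCL2L1_ratio"}, \code{"MYC_score"};
#'   defaults to -1 for all three.
#' @param hazard_log_hr_per_sd log hazard ratio per RBM25 standard deviation
#'   (default 0.7).
#' @param censor_rate fraction of patients censored (default 0.2).
#' @param noise_sd residual standard deviation of coupled scores (default 1).
#' @param median_survival_months baseline median survival (default 12
#'   months, AML-like).
#' @param n_signature_genes number of synthetic MYC target signature genes
#'   (default 20).
#' @param seed RNG seed.
#' @return List of class \code{cohort_sim_config}.
#' @export
cohort_sim_config <- function(n_patients = 170L,
                              rbm25_coupling = c(BIN1_plus12 = -1,
                                                 BCL2L1_ratio = -1,
                                                 MYC_score = -1),
                              hazard_log_hr_per_sd = 0.7,
                              censor_rate = 0.2, noise_sd = 1,
                              median_survival_months = 12,
                              n_signature_genes = 20L, seed = 1L) {
  stopifnot(n_patients >= 2, censor_rate >= 0, censor_rate < 1, noise_sd > 0,
            median_survival_months > 0, n_signature_genes >= 1)
  known <- c("BIN1_plus12", "BCL2L1_ratio", "MYC_score")
  unknown <- setdiff(names(rbm25_coupling), known)
  if (length(unknown) > 0) {
    stop("unknown coupled score(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  coupling <- stats::setNames(rep(0, length(known)), known)
  coupling[names(rbm25_coupling)] <- rbm25_coupling
  structure(list(n_patients = as.integer(n_patients),
                 rbm25_coupling = coupling,
                 hazard_log_hr_per_sd = hazard_log_hr_per_sd,
                 censor_rate = censor_rate, noise_sd = noise_sd,
                 median_survival_months = median_survival_months,
                 n_signature_genes = as.integer(n_signature_genes),
                 seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Simulate a patient expression cohort with survival
#'
#' Builds transcript-level expression such that the package's isoform
#' scores recover the latent coupled scores up to a monotone transform: the
#' five exon-12-including BIN1 transcripts share one latent total, the two
#' BCL2L1-L transcripts and the single BCL2L1-S transcript realize the
#' latent L/S ratio symmetrically around a patient baseline, and the
#' synthetic MYC signature genes (MYCT01, MYCT02, ...) are shifted from the
#' patient's MYC level by the latent MYC score. All expression is emitted on
#' a linear positive scale so downstream log2 transforms are meaningful.
#'
#' @param cfg a \code{\link{cohort_sim_config}}.
#' @return List with \code{transcripts} (\code{\link{transcript_matrix}}),
#'   \code{genes} (gene x patient matrix including RBM25, MYC and the
#'   signature genes), \code{clinical} (patient_id, time, event),
#'   \code{signature} (synthetic signature gene symbols) and \code{truth}
#'   (per-patient latents).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_patients
  patients <- sprintf("P%03d", seq_len(n))
  r <- stats::rnorm(n)  # latent RBM25 (z units)
  lat <- lapply(cfg$rbm25_coupling, function(cp)
    cp * r + stats::rnorm(n, 0, cfg$noise_sd))

  # transcript layer
  bin1_ids <- bin1_plus12_set()$transcript_ids
  bin1_w <- c(0.35, 0.25, 0.20, 0.12, 0.08)
  bin1_total <- 2^(6 + lat$BIN1_plus12)
  bcl_base <- stats::rnorm(n, 0, 0.5)
  l_ids <- bcl2l1_l_set()$transcript_ids
  l_total <- 2^(6 + bcl_base + lat$BCL2L1_ratio / 2)
  s_val <- 2^(6 + bcl_base - lat$BCL2L1_ratio / 2)
  tx <- rbind(outer(bin1_w, bin1_total),
              outer(c(0.6, 0.4), l_total),
              s_val)
  rownames(tx) <- c(bin1_ids, l_ids, bcl2l1_s_set()$transcript_ids)
  colnames(tx) <- patients
  tx2gene <- stats::setNames(c(rep("BIN1", length(bin1_ids)),
                               rep("BCL2L1", 3)), rownames(tx))
  transcripts <- transcript_matrix(tx, tx2gene)

  # gene layer
  signature <- sprintf("MYCT%02d", seq_len(cfg$n_signature_genes))
  myc_level <- stats::rnorm(n, 5, 0.5)
  gene_offset <- stats::rnorm(cfg$n_signature_genes, 0, 0.3)
  ge <- rbind(RBM25 = 2^(7 + r),
              MYC = 2^myc_level,
              2^(outer(gene_offset, myc_level + lat$MYC_score, "+")))
  rownames(ge) <- c("RBM25", "MYC", signature)
  colnames(ge) <- patients

  # survival layer
  base_rate <- log(2) / cfg$median_survival_months
  rate <- base_rate * exp(cfg$hazard_log_hr_per_sd * (-r))
  t_event <- stats::rexp(n, rate)
  censored <- stats::runif(n) < cfg$censor_rate
  time <- ifelse(censored, t_event * stats::runif(n), t_event)
  time <- pmax(time, 1e-3)
  clinical <- data.frame(patient_id = patients, time = time,
                         event = as.integer(!censored),
                         stringsAsFactors = FALSE)

  truth <- data.frame(patient_id = patients, rbm25_latent = r,
                      bin1_latent = lat$BIN1_plus12,
                      bcl2l1_ratio_latent = lat$BCL2L1_ratio,
                      myc_latent = lat$MYC_score,
                      time = time, event = as.integer(!censored),
                      stringsAsFactors = FALSE)
  list(transcripts = transcripts, genes = ge, clinical = clinical,
       signature = signature, truth = truth)
}

#' Write a simulated cohort to TSV files
#'
#' @param cohort result of \code{\link{simulate_cohort}}.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tx <- cohort$transcripts
  write_tsv(data.frame(transcript_id = rownames(tx$expr),
                       gene = unname(tx$tx2gene[rownames(tx$expr)]),
                       tx$expr, check.names = FALSE),
            file.path(dir, "transcripts.tsv"))
  write_tsv(data.frame(gene = rownames(cohort$genes), cohort$genes,
                       check.names = FALSE),
            file.path(dir, "genes.tsv"))
  write_tsv(data.frame(patient_id = cohort$clinical$patient_id,
                       time_months = cohort$clinical$time,
                       event = cohort$clinical$event),
            file.path(dir, "clinical.tsv"))
  writeLines(cohort$signature, file.path(dir, "signature.txt"))
  write_tsv(cohort$truth, file.path(dir, "truth_cohort.tsv"))
  invisible(dir)
}
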