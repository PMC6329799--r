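# Screen-level statistics: frequency normalization, control-normalized fold
# changes, percentile ranking and gene-level hit calling with a counter-screen
# filter.

#' Parameters of the gene-level hit caller
#'
#' A gene scores in a direction when at least \code{min_support} of its
#' hairpins rank within the top \code{enrich_pct} fraction of the most
#' enriched (or \code{deplete_pct} most depleted) hairpins of the AML arm;
#' genes whose hairpins satisfy the same criterion in the counter-screen arm
#' are flagged and excluded from the final calls.
#'
#' @param enrich_pct enrichment percentile cutoff as a fraction (default
#'   0.20, the 20th percentile of the most enriched hairpins).
#' @param deplete_pct depletion percentile cutoff (default 0.25).
#' @param min_support minimum number of scoring hairpins per gene; the
#'   screen's "multiple shRNAs" requirement, read minimally as 2.
#' @param pseudocount added to raw counts before frequency normalization so
#'   that hairpins absent from one timepoint keep finite fold changes.
#' @param control_summary how the control hairpins' raw ratios are summarised
#'   into the normalizer: \code{"median"} (robust, default), \code{"mean"},
#'   or \code{"none"} (no control normalization).
#' @param counter_min_support support threshold applied in the counter arm;
#'   defaults to \code{min_support} (same rule in both arms). Set to 1 for a
#'   stricter exclusion that flags genes with any counter-screen evidence.
#' @return A list of class \code{hit_params}.
#' @export
hit_params <- function(enrich_pct = 0.20, deplete_pct = 0.25,
                       min_support = 2L, pseudocount = 0.5,
                       control_summary = c("median", "mean", "none"),
                       counter_min_support = min_support) {
  control_summary <- match.arg(control_summary)
  stopifnot(enrich_pct > 0, enrich_pct < 1, deplete_pct > 0, deplete_pct < 1,
            min_support >= 1, pseudocount >= 0, counter_min_support >= 1)
  structure(list(enrich_pct = enrich_pct, deplete_pct = deplete_pct,
                 min_support = as.integer(min_support),
                 pseudocount = pseudocount,
                 control_summary = control_summary,
                 counter_min_support = as.integer(counter_min_support)),
            class = "hit_params")
}

#' Normalize counts to within-sample frequencies
#'
#' Raw sequencing counts are normalized to the total number of reads of each
#' sample: \code{freq = (count + pseudocount) / sum(count + pseudocount)},
#' so every sample column sums to one.
#'
#' @param cm a \code{\link{count_matrix}} or a plain count matrix.
#' @param pseudocount value added to every count before normalization
#'   (default 0.5).
#' @return Numeric matrix of frequencies with the same dimnames.
#' @export
normalize_counts <- function(cm, pseudocount = 0.5) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  x <- counts + pseudocount
  totals <- colSums(x)
  if (any(totals <= 0)) {
    stop("sample(s) with non-positive total after pseudocounting: ",
         paste(colnames(counts)[totals <= 0], collapse = ", "), call. = FALSE)
  }
  sweep(x, 2, totals, "/")
}

#' Control-normalized fold change for one replicate
#'
#' The fold change of a hairpin is the ratio of its normalized read
#' frequencies between the output and input timepoints, divided by the
#' summary (median by default) of the control hairpins' raw ratios.
#'
#' @param freqs frequency matrix from \code{\link{normalize_counts}}.
#' @param input_sample,output_sample column names of the replicate's input
#'   and output samples.
#' @param library the \code{\link{shrna_library}} (identifies controls).
#' @param control_summary \code{"median"}, \code{"mean"} or \code{"none"}.
#' @return data.frame with columns \code{hairpin_id}, \code{gene},
#'   \code{is_control}, \code{fc}, \code{log2fc}.
#' @export
fold_change <- function(freqs, input_sample, output_sample, library,
                        control_summary = c("median", "mean", "none")) {
  control_summary <- match.arg(control_summary)
  stopifnot(inherits(library, "shrna_library"))
  for (s in c(input_sample, output_sample)) {
    if (!s %in% colnames(freqs)) stop("unknown sample: ", s, call. = FALSE)
  }
  rec <- library$records
  freqs <- freqs[rec$hairpin_id, , drop = FALSE]
  raw <- freqs[, output_sample] / freqs[, input_sample]
  if (control_summary == "none") {
    normalizer <- 1
  } else {
    ctrl <- raw[rec$is_control]
    if (length(ctrl) == 0) {
      stop("library has no control hairpins; pass control_summary = \"none\" ",
           "to skip control normalization explicitly", call. = FALSE)
    }
    normalizer <- if (control_summary == "median") stats::median(ctrl) else mean(ctrl)
  }
  fc <- raw / normalizer
  data.frame(hairpin_id = rec$hairpin_id, gene = rec$gene,
             is_control = rec$is_control, fc = unname(fc),
             log2fc = unname(log2(fc)), stringsAsFactors = FALSE)
}

#' Average log2 fold changes across replicates
#'
#' @param replicates list of per-replicate data.frames from
#'   \code{\link{fold_change}} (identical hairpin sets, same order).
#' @return Named numeric vector of mean log2 fold changes per hairpin.
#' @export
mean_log2fc <- function(replicates) {
  stopifnot(length(replicates) >= 1)
  ids <- replicates[[1]]$hairpin_id
  for (r in replicates) {
    if (!identical(r$hairpin_id, ids)) {
      stop("replicates cover different hairpin sets", call. = FALSE)
    }
  }
  m <- vapply(replicates, function(r) r$log2fc, numeric(length(ids)))
  stats::setNames(rowMeans(matrix(m, nrow = length(ids))), ids)
}

#' Pearson correlation between replicate fold-change vectors
#'
#' Reported as a screen quality metric; the in vivo screen underlying this
#' package's design showed moderate replicate correlation (around 0.5).
#'
#' @param rep1,rep2 numeric log2 fold-change vectors of equal length >= 3.
#' @return Pearson r in [-1, 1].
#' @export
replicate_correlation <- function(rep1, rep2) {
  if (length(rep1) != length(rep2) || length(rep1) < 3) {
    stop("replicate vectors must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(rep1) == 0 || stats::sd(rep2) == 0) {
    stop("zero variance in a replicate; correlation undefined", call. = FALSE)
  }
  stats::cor(rep1, rep2)
}

#' Rank hairpins and convert ranks to percentiles
#'
#' Enrichment ranks sort mean log2 fold changes in decreasing order (rank 1 =
#' most enriched); depletion ranks in increasing order. Ties are broken
#' deterministically by hairpin id. The percentile of rank r among N hairpins
#' is r/N, so "within the 20th percentile" means \code{pctile <= 0.20}
#' (boundary inclusive).
#'
#' @param mlfc named numeric vector of mean log2 fold changes.
#' @return data.frame with \code{hairpin_id}, \code{mean_log2fc},
#'   \code{enrich_rank}, \code{deplete_rank}, \code{enrich_pctile},
#'   \code{deplete_pctile}.
#' @export
rank_percentiles <- function(mlfc) {
  n <- length(mlfc)
  stopifnot(n >= 1, !is.null(names(mlfc)))
  ids <- names(mlfc)
  if (anyDuplicated(mlfc)) {
    message("tied fold changes present; ties broken by hairpin_id")
  }
  enrich_order <- order(-mlfc, ids)
  deplete_order <- order(mlfc, ids)
  enrich_rank <- integer(n); enrich_rank[enrich_order] <- seq_len(n)
  deplete_rank <- integer(n); deplete_rank[deplete_order] <- seq_len(n)
  data.frame(hairpin_id = ids, mean_log2fc = unname(mlfc),
             enrich_rank = enrich_rank, deplete_rank = deplete_rank,
             enrich_pctile = enrich_rank / n, deplete_pctile = deplete_rank / n,
             stringsAsFactors = FALSE)
}

#' Build the full per-arm fold-change table for a screen
#'
#' Runs normalization, per-replicate control-normalized fold changes, the
#' across-replicate mean log2 fold change and percentile ranking for one arm
#' of a \code{\link{count_matrix}}.
#'
#' @param cm a \code{\link{count_matrix}}.
#' @param arm \code{"AML"} or \code{"COUNTER"}.
#' @param params a \code{\link{hit_params}} (supplies pseudocount and control
#'   summary).
#' @return data.frame of class \code{fc_table}: one row per hairpin with
#'   gene, control flag, per-replicate log2 fold changes, \code{mean_log2fc}
#'   and enrich/deplete ranks and percentiles.
#' @export
fold_change_table <- function(cm, arm = c("AML", "COUNTER"),
                              params = hit_params()) {
  arm <- match.arg(arm)
  stopifnot(inherits(cm, "count_matrix"))
  s <- cm$samples[cm$samples$arm == arm, , drop = FALSE]
  reps <- sort(unique(s$replicate))
  if (length(reps) == 0) stop("no samples for arm ", arm, call. = FALSE)
  freqs <- normalize_counts(cm, params$pseudocount)
  per_rep <- lapply(reps, function(r) {
    inp <- s$sample_id[s$replicate == r & s$timepoint == "INPUT"]
    out <- s$sample_id[s$replicate == r & s$timepoint == "OUTPUT"]
    if (length(inp) != 1 || length(out) != 1) {
      stop("arm ", arm, " replicate ", r,
           " must have exactly one INPUT and one OUTPUT sample", call. = FALSE)
    }
    fold_change(freqs, inp, out, cm$library, params$control_summary)
  })
  mlfc <- mean_log2fc(per_rep)
  rk <- rank_percentiles(mlfc)
  out <- data.frame(hairpin_id = per_rep[[1]]$hairpin_id,
                    gene = per_rep[[1]]$gene,
                    is_control = per_rep[[1]]$is_control,
                    stringsAsFactors = FALSE)
  for (i in seq_along(reps)) {
    out[[paste0("log2fc_rep", reps[i])]] <- per_rep[[i]]$log2fc
  }
  out <- cbind(out, rk[match(out$hairpin_id, rk$hairpin_id),
                       c("mean_log2fc", "enrich_rank", "deplete_rank",
                         "enrich_pctile", "deplete_pctile")])
  rownames(out) <- NULL
  class(out) <- c("fc_table", "data.frame")
  out
}

# genes whose hairpins satisfy the percentile criterion in one direction
scoring_support <- function(fc, direction, pct) {
  pcol <- if (direction == "ENRICHED") "enrich_pctile" else "deplete_pctile"
  sel <- !fc$is_control & fc[[pcol]] <= pct
  split(fc$hairpin_id[sel], fc$gene[sel])
}

#' Call gene-level screen hits with counter-screen exclusion
#'
#' A gene is called as ENRICHED when at least \code{min_support} of its
#' hairpins rank within the top \code{enrich_pct} fraction of the most
#' enriched hairpins in the AML arm, and the same criterion is not met in
#' the counter-screen arm (analogously DEPLETED with \code{deplete_pct}).
#' Control hairpins never contribute to gene-level evaluation.
#'
#' @param aml_fc \code{fc_table} of the AML arm
#'   (\code{\link{fold_change_table}}).
#' @param counter_fc \code{fc_table} of the counter-screen arm, covering the
#'   same hairpins.
#' @param library the \code{\link{shrna_library}}.
#' @param params a \code{\link{hit_params}}.
#' @return data.frame of class \code{hit_table}: one row per (gene,
#'   direction) satisfying the AML criterion, with \code{n_support},
#'   \code{support_ids} (comma-separated), \code{counter_flag} and
#'   \code{called}.
#' @export
call_hits <- function(aml_fc, counter_fc, library, params = hit_params()) {
  stopifnot(inherits(library, "shrna_library"))
  if (!setequal(aml_fc$hairpin_id, counter_fc$hairpin_id)) {
    stop("AML and counter fold-change tables cover different hairpins",
         call. = FALSE)
  }
  cuts <- c(ENRICHED = params$enrich_pct, DEPLETED = params$deplete_pct)
  rows <- list()
  for (direction in names(cuts)) {
    aml_sup <- scoring_support(aml_fc, direction, cuts[[direction]])
    ctr_sup <- scoring_support(counter_fc, direction, cuts[[direction]])
    aml_sup <- aml_sup[lengths(aml_sup) >= params$min_support]
    ctr_genes <- names(ctr_sup)[lengths(ctr_sup) >= params$counter_min_support]
    if (length(aml_sup) == 0) next
    genes <- sort(names(aml_sup))
    rows[[direction]] <- data.frame(
      gene = genes,
      direction = direction,
      n_support = lengths(aml_sup)[genes],
      support_ids = vapply(aml_sup[genes], function(x)
        paste(sort(x), collapse = ","), character(1)),
      counter_flag = genes %in% ctr_genes,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(gene = character(), direction = character(),
               n_support = integer(), support_ids = character(),
               counter_flag = logical(), stringsAsFactors = FALSE)
  out$called <- out$n_support >= params$min_support & !out$counter_flag
  rownames(out) <- NULL
  class(out) <- c("hit_table", "data.frame")
  out
}

#' @export
print.hit_table <- function(x, ...) {
  cat(sprintf("hit_table: %d candidate gene/direction rows, %d called\n",
              nrow(x), sum(x$called)))
  NextMethod()
}

#' Normalized GFP/YFP competitive ratio over time
#'
#' In competitive validation assays, cells carrying a target-specific
#' shRNA (GFP) are mixed with scrambled-shRNA competitors (YFP) and the
#' GFP/YFP ratio is followed over time, normalized to the input mixture so
#' the first timepoint is 1 by construction.
#'
#' @param gfp_frac,yfp_frac numeric fractions in (0, 1) over shared
#'   timepoints; the first element is the input mixture.
#' @return Numeric vector of normalized ratios, first element 1.
#' @export
competitive_ratio <- function(gfp_frac, yfp_frac) {
  if (length(gfp_frac) != length(yfp_frac)) {
    stop("series must share timepoints", call. = FALSE)
  }
  if (any(gfp_frac <= 0 | gfp_frac >= 1) || any(yfp_frac <= 0 | yfp_frac >= 1)) {
    stop("fractions must lie strictly between 0 and 1", call. = FALSE)
  }
  ratio <- gfp_frac / yfp_frac
  ratio / ratio[1]
}

#' Write a fold-change table to TSV
#' @param fc an \code{fc_table}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_fold_changes <- function(fc, path) write_tsv(as.data.frame(fc), path)

#' Write a hit table to TSV
#' @param hits a \code{hit_table}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_hits <- function(hits, path) write_tsv(as.data.frame(hits), path)
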