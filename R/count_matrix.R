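#' Construct a hairpin count matrix with sample metadata
#'
#' Holds non-negative integer counts of hairpin observations per sequenced
#' sample, together with the sample sheet (arm, replicate, timepoint) and the
#' library the rows refer to. Hairpins present in the library but absent from
#' \code{counts} are restored as explicit zero rows so that downstream
#' pseudocounting treats all hairpins uniformly.
#'
#' @param counts integer matrix (hairpin x sample) with hairpin ids as
#'   rownames and sample ids as colnames.
#' @param samples data.frame with columns \code{sample_id}, \code{arm}
#'   (\code{"AML"} or \code{"COUNTER"}), \code{replicate} (integer >= 1),
#'   \code{timepoint} (\code{"INPUT"} or \code{"OUTPUT"}) and optionally
#'   \code{barcode}.
#' @param library the \code{\link{shrna_library}} the rows refer to.
#' @return An object of class \code{count_matrix}.
#' @export
count_matrix <- function(counts, samples, library) {
  stopifnot(inherits(library, "shrna_library"))
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have hairpin ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  bad <- !is.finite(counts) | counts < 0 | counts != round(counts)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid count at hairpin '%s', sample '%s': %s",
                 rownames(counts)[idx[1]], colnames(counts)[idx[2]],
                 counts[idx[1], idx[2]]), call. = FALSE)
  }
  storage.mode(counts) <- "integer"

  lib_ids <- library_hairpins(library)
  unknown <- setdiff(rownames(counts), lib_ids)
  if (length(unknown) > 0) {
    stop("counts contain hairpins absent from the library: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(lib_ids, rownames(counts))
  if (length(missing) > 0) {
    warning(length(missing), " library hairpin(s) absent from counts; ",
            "restored as zero rows", call. = FALSE)
    zeros <- matrix(0L, nrow = length(missing), ncol = ncol(counts),
                    dimnames = list(missing, colnames(counts)))
    counts <- rbind(counts, zeros)
  }
  counts <- counts[lib_ids, , drop = FALSE]

  req <- c("sample_id", "arm", "replicate", "timepoint")
  missing_cols <- setdiff(req, names(samples))
  if (length(missing_cols) > 0) {
    stop("sample sheet missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  samples$sample_id <- as.character(samples$sample_id)
  samples$arm <- toupper(as.character(samples$arm))
  samples$timepoint <- toupper(as.character(samples$timepoint))
  samples$replicate <- as.integer(samples$replicate)
  if (!all(samples$arm %in% c("AML", "COUNTER"))) {
    stop("sample arm must be AML or COUNTER", call. = FALSE)
  }
  if (!all(samples$timepoint %in% c("INPUT", "OUTPUT"))) {
    stop("sample timepoint must be INPUT or OUTPUT", call. = FALSE)
  }
  if (!setequal(samples$sample_id, colnames(counts)) ||
      anyDuplicated(samples$sample_id)) {
    stop("sample sheet ids must match count columns exactly", call. = FALSE)
  }
  key <- paste(samples$arm, samples$replicate, samples$timepoint)
  if (anyDuplicated(key)) {
    stop("duplicate (arm, replicate, timepoint) combination in sample sheet",
         call. = FALSE)
  }
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL

  structure(list(counts = counts, samples = samples, library = library),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d hairpins x %d samples (total reads %.3g)\n",
              nrow(x$counts), ncol(x$counts), sum(as.numeric(x$counts))))
  print(x$samples[, c("sample_id", "arm", "replicate", "timepoint")])
  invisible(x)
}

#' Fraction of library hairpins detected in a sample
#'
#' Library coverage is the fraction of hairpins with at least
#' \code{min_count} reads in the given sample; a well-executed pooled screen
#' retains near-complete coverage of its pools.
#'
#' @param cm a \code{\link{count_matrix}}.
#' @param sample sample id.
#' @param min_count detection threshold (reads).
#' @return A fraction in [0, 1].
#' @export
library_coverage <- function(cm, sample, min_count = 1L) {
  stopifnot(inherits(cm, "count_matrix"))
  if (!sample %in% colnames(cm$counts)) {
    stop("unknown sample: ", sample, call. = FALSE)
  }
  mean(cm$counts[, sample] >= min_count)
}

#' Read a count matrix (and its sample sheet) from TSV files
#'
#' The count file has a first column \code{hairpin_id} and one column per
#' sample; the sidecar sample sheet has columns \code{sample_id}, \code{arm},
#' \code{replicate}, \code{timepoint} and optionally \code{barcode}.
#'
#' @param path count TSV path.
#' @param samples_path sample-sheet TSV path.
#' @param library the \code{\link{shrna_library}}.
#' @return A \code{\link{count_matrix}}.
#' @export
read_counts <- function(path, samples_path, library) {
  df <- read_tsv_checked(path, "hairpin_id")
  samples <- read_tsv_checked(samples_path,
                              c("sample_id", "arm", "replicate", "timepoint"))
  mat <- as.matrix(df[, setdiff(names(df), "hairpin_id"), drop = FALSE])
  rownames(mat) <- as.character(df$hairpin_id)
  bad <- !is.finite(mat) | mat < 0 | mat != round(mat)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid count in %s at row '%s', column '%s'",
                 path, rownames(mat)[idx[1]], colnames(mat)[idx[2]]),
         call. = FALSE)
  }
  count_matrix(mat, samples, library)
}

#' Write a count matrix and sample sheet to TSV files
#'
#' \code{write_counts} followed by \code{\link{read_counts}} is an identity
#' on valid count matrices.
#'
#' @param cm a \code{\link{count_matrix}}.
#' @param path count TSV path.
#' @param samples_path sample-sheet TSV path.
#' @return The count path, invisibly.
#' @export
write_counts <- function(cm, path, samples_path) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(hairpin_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
  write_tsv(cm$samples, samples_path)
  invisible(path)
}
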