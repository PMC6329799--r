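# Read-level operations: FASTQ IO, barcode demultiplexing, guide counting.
# Reads are held as named character vectors of bases; Phred qualities play no
# role in hairpin counting and are discarded on input.

#' Read a FASTQ file into a named character vector of sequences
#'
#' @param path FASTQ path (uncompressed or gzipped).
#' @return Named character vector; names are read ids.
#' @export
read_fastq <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Write sequences to a FASTQ file (constant placeholder qualities)
#'
#' @param reads named character vector of sequences.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  ids <- names(reads) %||% paste0("read", seq_along(reads))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(reads) > 0) {
    rec <- paste0("@", ids, "\n", reads, "\n+\n",
                  vapply(nchar(reads), function(n) strrep("I", n), character(1)))
    writeLines(rec, con)
  }
  invisible(path)
}

#' Assign reads to samples by their 5' barcode
#'
#' Barcodes are expected at the start of each read (the amplicon design puts
#' the sample barcode 5' of the hairpin insert). A read is assigned to the
#' sample whose barcode has the uniquely smallest Hamming distance to the
#' read prefix, provided that distance is at most \code{max_mismatch};
#' distance ties and reads beyond tolerance go to the unassigned bin.
#'
#' @param reads named character vector of read sequences.
#' @param barcode_map named character vector: names are barcodes (equal
#'   length, A/C/G/T), values are sample ids.
#' @param max_mismatch maximum Hamming distance tolerated (default 0).
#' @param trim drop the barcode prefix from assigned reads (default TRUE).
#' @return List with \code{samples} (named list sample id -> character vector
#'   of reads) and \code{unassigned} (integer count).
#' @export
demultiplex <- function(reads, barcode_map, max_mismatch = 0L, trim = TRUE) {
  barcodes <- names(barcode_map)
  if (is.null(barcodes) || any(barcodes == "")) {
    stop("barcode_map must be a named vector with barcodes as names",
         call. = FALSE)
  }
  if (length(unique(nchar(barcodes))) != 1) {
    stop("all barcodes must have equal length", call. = FALSE)
  }
  if (!all(is_valid_dna(barcodes))) {
    stop("barcodes must be A/C/G/T only", call. = FALSE)
  }
  if (max_mismatch < 0) stop("max_mismatch must be >= 0", call. = FALSE)
  if (length(barcodes) > 1) {
    pairs <- utils::combn(barcodes, 2)
    dists <- hamming_dist(pairs[1, ], pairs[2, ])
    if (any(dists <= 2 * max_mismatch)) {
      i <- which.min(dists)
      stop(sprintf(paste0("barcodes '%s' and '%s' are Hamming distance %d apart; ",
                          "ambiguity is unavoidable at max_mismatch %d"),
                   pairs[1, i], pairs[2, i], dists[i], max_mismatch),
           call. = FALSE)
    }
  }

  blen <- nchar(barcodes[1])
  prefix <- substr(reads, 1, blen)
  n <- length(reads)
  best <- rep(Inf, n)
  best_bc <- rep(NA_integer_, n)
  tie <- rep(FALSE, n)
  for (i in seq_along(barcodes)) {
    d <- if (n > 0) hamming_dist(prefix, barcodes[i]) else numeric(0)
    d[nchar(prefix) < blen] <- Inf
    tie <- (d == best & is.finite(d)) | (tie & d > best)
    upd <- d < best
    best[upd] <- d[upd]
    best_bc[upd] <- i
  }
  assigned <- is.finite(best) & best <= max_mismatch & !tie
  samples <- stats::setNames(vector("list", length(barcode_map)),
                             unname(barcode_map))
  for (i in seq_along(barcodes)) {
    sel <- assigned & best_bc == i
    r <- reads[sel]
    if (trim) {
      nm <- names(r)
      r <- substr(r, blen + 1L, nchar(r))
      names(r) <- nm
    }
    samples[[unname(barcode_map[i])]] <- r
  }
  n_assigned <- sum(assigned)
  message(sprintf("demultiplex: %d/%d reads assigned (%d unassigned)",
                  n_assigned, n, n - n_assigned))
  list(samples = samples, unassigned = n - n_assigned)
}

#' Count hairpin guide occurrences in a set of reads
#'
#' Each read is searched for the library's guide sequences (within an
#' optional window of allowed start offsets) and assigned to the hairpin
#' whose guide matches with the uniquely smallest Hamming distance, up to
#' \code{max_mismatch} substitutions. Reads matching no guide within
#' tolerance, or two guides equally well, are tallied as unmatched; a read
#' never increments more than one hairpin, so assigned + unmatched equals
#' the number of input reads.
#'
#' @param reads character vector of read sequences.
#' @param library an \code{\link{shrna_library}}.
#' @param offset_window integer vector \code{c(first, last)} of allowed
#'   1-based guide start offsets, or NULL (default) to search whole reads.
#' @param max_mismatch maximum Hamming distance per guide (default 0, i.e.
#'   exact substring match).
#' @return List with \code{counts} (named integer vector over all library
#'   hairpins) and \code{unmatched} (integer).
#' @export
count_hairpins <- function(reads, library, offset_window = NULL,
                           max_mismatch = 0L) {
  stopifnot(inherits(library, "shrna_library"))
  guides <- library$records$guide_seq
  ids <- library$records$hairpin_id
  counts <- stats::setNames(integer(length(ids)), ids)
  if (length(reads) == 0) {
    warning("empty read stream; returning zero counts", call. = FALSE)
    return(list(counts = counts, unmatched = 0L))
  }

  if (!is.null(offset_window)) {
    stopifnot(length(offset_window) == 2, offset_window[1] >= 1,
              offset_window[2] >= offset_window[1])
    last <- offset_window[2] + max(nchar(guides)) - 1L
    reads <- substr(reads, offset_window[1], last)
  }
  subject <- Biostrings::DNAStringSet(reads)
  n <- length(reads)

  if (max_mismatch == 0 && length(unique(nchar(guides))) == 1) {
    # fast path: constant-width exact dictionary matching
    pd <- Biostrings::PDict(guides)
    hits <- Biostrings::vwhichPDict(pd, subject)
    nhit <- lengths(hits)
    uniq <- nhit == 1
    hit_idx <- unlist(hits[uniq], use.names = FALSE)
    tab <- tabulate(hit_idx, nbins = length(guides))
    counts[] <- tab
    unmatched <- n - sum(uniq)
  } else {
    best <- rep(Inf, n)
    best_g <- rep(NA_integer_, n)
    tie <- rep(FALSE, n)
    for (g in seq_along(guides)) {
      d <- rep(Inf, n)
      for (k in seq(max_mismatch, 0)) {
        hit <- Biostrings::vcountPattern(guides[g], subject,
                                         max.mismatch = k) > 0
        d[hit] <- k
      }
      tie <- (d == best & is.finite(d)) | (tie & d > best)
      upd <- d < best
      best[upd] <- d[upd]
      best_g[upd] <- g
    }
    matched <- is.finite(best) & !tie
    tab <- tabulate(best_g[matched], nbins = length(guides))
    counts[] <- tab
    unmatched <- n - sum(matched)
  }
  list(counts = counts, unmatched = as.integer(unmatched))
}

#' Count hairpins for every sample of a demultiplexed run
#'
#' Convenience wrapper applying \code{\link{count_hairpins}} per sample and
#' assembling a \code{\link{count_matrix}}.
#'
#' @param sample_reads named list: sample id -> character vector of reads.
#' @param library an \code{\link{shrna_library}}.
#' @param samples sample sheet (see \code{\link{count_matrix}}).
#' @param ... passed to \code{\link{count_hairpins}}.
#' @return A \code{\link{count_matrix}}.
#' @export
count_samples <- function(sample_reads, library, samples, ...) {
  mats <- lapply(sample_reads, function(r) {
    count_hairpins(r, library, ...)$counts
  })
  counts <- do.call(cbind, mats)
  colnames(counts) <- names(sample_reads)
  count_matrix(counts, samples, library)
}
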