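#' Construct an shRNA library object
#'
#' An shRNA library is the collection of hairpin constructs used in a pooled
#' screen: each hairpin has a unique identifier, a target gene symbol, the
#' guide (sense) sequence that identifies it in sequencing reads, and a flag
#' marking scrambled/non-targeting controls. Hairpins may optionally be
#' organised into sub-pools (the screen described by this package used pools
#' of 150 hairpins).
#'
#' @param records data.frame with columns \code{hairpin_id}, \code{gene},
#'   \code{guide_seq}, \code{is_control}.
#' @param pools optional named list mapping pool id to a character vector of
#'   hairpin ids; pools must not overlap and must only reference known
#'   hairpins.
#' @return An object of class \code{shrna_library}: a list with elements
#'   \code{records} (validated data.frame) and \code{pools}.
#' @export
shrna_library <- function(records, pools = NULL) {
  required <- c("hairpin_id", "gene", "guide_seq", "is_control")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    stop("library records missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  records <- records[, required]
  records$hairpin_id <- as.character(records$hairpin_id)
  records$gene <- as.character(records$gene)
  records$guide_seq <- toupper(as.character(records$guide_seq))
  records$is_control <- as.logical(records$is_control)

  dup_id <- records$hairpin_id[duplicated(records$hairpin_id)]
  if (length(dup_id) > 0) {
    stop("duplicate hairpin_id in library: ", paste(unique(dup_id), collapse = ", "),
         call. = FALSE)
  }
  dup_guide <- unique(records$guide_seq[duplicated(records$guide_seq)])
  if (length(dup_guide) > 0) {
    offenders <- records$hairpin_id[records$guide_seq %in% dup_guide]
    stop("duplicate guide_seq shared by hairpins: ",
         paste(offenders, collapse = ", "), call. = FALSE)
  }
  bad_nt <- !is_valid_dna(records$guide_seq)
  if (any(bad_nt)) {
    stop("invalid nucleotide (only A/C/G/T allowed) in guide_seq of: ",
         paste(records$hairpin_id[bad_nt], collapse = ", "), call. = FALSE)
  }
  if (any(nchar(records$guide_seq) < 18)) {
    short <- records$hairpin_id[nchar(records$guide_seq) < 18]
    stop("guide_seq shorter than 18 nt for: ", paste(short, collapse = ", "),
         call. = FALSE)
  }
  no_gene <- !records$is_control & (is.na(records$gene) | records$gene == "")
  if (any(no_gene)) {
    stop("non-control hairpin(s) without a gene symbol: ",
         paste(records$hairpin_id[no_gene], collapse = ", "), call. = FALSE)
  }

  if (!is.null(pools)) {
    all_pooled <- unlist(pools, use.names = FALSE)
    if (anyDuplicated(all_pooled)) {
      stop("pools must partition hairpins; duplicated assignment for: ",
           paste(unique(all_pooled[duplicated(all_pooled)]), collapse = ", "),
           call. = FALSE)
    }
    unknown <- setdiff(all_pooled, records$hairpin_id)
    if (length(unknown) > 0) {
      stop("pools reference unknown hairpins: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }

  structure(list(records = records, pools = pools), class = "shrna_library")
}

#' Parse an shRNA library from a TSV file
#'
#' The file must have a header row with columns \code{hairpin_id},
#' \code{gene}, \code{guide_seq} and \code{is_control} (0/1 or TRUE/FALSE).
#' Duplicate hairpin ids, duplicate guide sequences and non-ACGT characters
#' are rejected with an error naming the offending rows.
#'
#' @param path path to a tab-separated library file.
#' @return An \code{\link{shrna_library}}.
#' @export
parse_library <- function(path) {
  df <- read_tsv_checked(path, c("hairpin_id", "gene", "guide_seq", "is_control"))
  if (is.numeric(df$is_control)) df$is_control <- df$is_control != 0
  lib <- shrna_library(df)
  message(sprintf("parsed library: %d hairpins, %d genes, %d controls",
                  nrow(lib$records),
                  length(unique(lib$records$gene[!lib$records$is_control])),
                  sum(lib$records$is_control)))
  lib
}

#' Write an shRNA library to a TSV file
#'
#' @param library an \code{\link{shrna_library}}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_library <- function(library, path) {
  stopifnot(inherits(library, "shrna_library"))
  df <- library$records
  df$is_control <- as.integer(df$is_control)
  write_tsv(df, path)
}

#' @export
print.shrna_library <- function(x, ...) {
  r <- x$records
  cat(sprintf("shRNA library: %d hairpins, %d target genes, %d controls\n",
              nrow(r), length(unique(r$gene[!r$is_control])), sum(r$is_control)))
  if (!is.null(x$pools)) {
    sizes <- vapply(x$pools, length, integer(1))
    cat(sprintf("pools: %d (sizes %s)\n", length(sizes),
                paste(unique(sizes), collapse = "/")))
  }
  invisible(x)
}

# hairpin ids in library order
library_hairpins <- function(library) library$records$hairpin_id
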