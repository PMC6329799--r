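# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

# Read a TSV with a mandatory header; stops with the missing column names.
read_tsv_checked <- function(path, required = character()) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Hamming distance between strings; vectorised over x against a single y,
# or elementwise when y has the same length as x. Length mismatches give Inf.
hamming_dist <- function(x, y) {
  if (length(y) > 1) {
    return(mapply(function(a, b) {
      if (nchar(a) != nchar(b)) return(Inf)
      sum(charToRaw(a) != charToRaw(b))
    }, x, y, USE.NAMES = FALSE))
  }
  w <- nchar(y)
  out <- rep(Inf, length(x))
  ok <- nchar(x) == w
  if (any(ok)) {
    xm <- matrix(unlist(strsplit(x[ok], "", fixed = TRUE)),
                 ncol = w, byrow = TRUE)
    yv <- strsplit(y, "", fixed = TRUE)[[1]]
    out[ok] <- rowSums(xm != matrix(yv, nrow = sum(ok), ncol = w, byrow = TRUE))
  }
  out
}

is_valid_dna <- function(x) {
  grepl("^[ACGT]+$", x)
}
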