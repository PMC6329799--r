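# Patient-cohort scoring: transcript-set isoform scores, the BCL2L1 L/S
# ratio, BIN1 exon-12 inclusion, MYC-normalized signature scores, Z-scoring,
# stratification and Mann-Whitney group comparison.

#' Construct a transcript expression matrix
#'
#' @param expr numeric matrix (transcript x patient), non-negative, with
#'   transcript ids as rownames and patient ids as colnames.
#' @param tx2gene named character vector mapping transcript id to gene
#'   symbol.
#' @return Object of class \code{transcript_matrix}.
#' @export
transcript_matrix <- function(expr, tx2gene) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expr must have transcript ids as rownames and patient ids as colnames",
         call. = FALSE)
  }
  if (any(!is.finite(expr)) || any(expr < 0)) {
    stop("expression values must be finite and non-negative", call. = FALSE)
  }
  structure(list(expr = expr, tx2gene = tx2gene), class = "transcript_matrix")
}

#' Read a transcript matrix from TSV
#'
#' Expected columns: \code{transcript_id}, \code{gene}, then one column per
#' patient.
#'
#' @param path TSV path.
#' @return A \code{\link{transcript_matrix}}.
#' @export
read_transcripts <- function(path) {
  df <- read_tsv_checked(path, c("transcript_id", "gene"))
  mat <- as.matrix(df[, setdiff(names(df), c("transcript_id", "gene")),
                      drop = FALSE])
  rownames(mat) <- df$transcript_id
  transcript_matrix(mat, stats::setNames(df$gene, df$transcript_id))
}

#' Define a transcript-set score
#'
#' A transcript-set score sums the expression of a fixed set of transcript
#' isoforms per patient, optionally on the log2 scale.
#'
#' @param name score name.
#' @param transcript_ids non-empty character vector of transcript ids.
#' @param log2_transform apply \code{log2(sum + pseudocount)} (default TRUE).
#' @param pseudocount added inside the log2 (default 1; expression matrices
#'   of normalized counts contain zeros).
#' @return Object of class \code{transcript_set}.
#' @export
transcript_set <- function(name, transcript_ids, log2_transform = TRUE,
                           pseudocount = 1) {
  stopifnot(length(transcript_ids) >= 1, pseudocount >= 0)
  structure(list(name = name, transcript_ids = transcript_ids,
                 log2_transform = log2_transform, pseudocount = pseudocount),
            class = "transcript_set")
}

#' Built-in transcript sets for the BCL2L1 and BIN1 isoform scores
#'
#' \code{bcl2l1_l_set}: the anti-apoptotic long isoform (BCL-XL), the sum of
#' Ensembl transcripts ENST00000307677 and ENST00000376062.
#' \code{bcl2l1_s_set}: the pro-apoptotic short isoform (BCL-XS), Ensembl
#' transcript ENST00000376055. \code{bin1_plus12_set}: BIN1 isoforms that
#' include exon 12 (and therefore cannot inhibit MYC): ENST00000259238,
#' ENST00000316724, ENST00000346226, ENST00000393040, ENST00000484253.
#'
#' @param pseudocount added inside the log2 transform.
#' @return A \code{\link{transcript_set}}.
#' @export
bcl2l1_l_set <- function(pseudocount = 1) {
  transcript_set("BCL2L1_L", c("ENST00000307677", "ENST00000376062"),
                 TRUE, pseudocount)
}

#' @rdname bcl2l1_l_set
#' @export
bcl2l1_s_set <- function(pseudocount = 1) {
  transcript_set("BCL2L1_S", "ENST00000376055", TRUE, pseudocount)
}

#' @rdname bcl2l1_l_set
#' @export
bin1_plus12_set <- function(pseudocount = 1) {
  transcript_set("BIN1_plus12",
                 c("ENST00000259238", "ENST00000316724", "ENST00000346226",
                   "ENST00000393040", "ENST00000484253"),
                 TRUE, pseudocount)
}

#' Evaluate a transcript-set score per patient
#'
#' Sums the expression of the set's transcripts in each patient and applies
#' the optional log2 transform. Transcripts missing from the matrix are
#' treated as zero with a warning; if all are missing, an error is raised.
#'
#' @param tm a \code{\link{transcript_matrix}}.
#' @param set a \code{\link{transcript_set}}.
#' @return Named numeric vector over patients.
#' @export
transcript_set_score <- function(tm, set) {
  stopifnot(inherits(tm, "transcript_matrix"), inherits(set, "transcript_set"))
  present <- intersect(set$transcript_ids, rownames(tm$expr))
  if (length(present) == 0) {
    stop("none of the transcripts of score '", set$name,
         "' are present in the matrix", call. = FALSE)
  }
  absent <- setdiff(set$transcript_ids, present)
  if (length(absent) > 0) {
    warning("score '", set$name, "': transcript(s) treated as zero: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  v <- colSums(tm$expr[present, , drop = FALSE])
  if (set$log2_transform) v <- log2(v + set$pseudocount)
  v
}

#' BCL2L1 long-to-short isoform ratio per patient
#'
#' The log2 ratio of the anti-apoptotic long isoform sum (BCL-XL) to the
#' pro-apoptotic short isoform (BCL-XS):
#' \code{log2((L + pc) / (S + pc))}, i.e. the difference of the log2 set
#' scores. Larger values indicate an apoptotic balance shifted towards
#' survival.
#'
#' @param tm a \code{\link{transcript_matrix}}.
#' @param pseudocount added inside each log2 (default 1).
#' @return Named numeric vector over patients.
#' @export
bcl2l1_ratio <- function(tm, pseudocount = 1) {
  l <- transcript_set_score(tm, bcl2l1_l_set(pseudocount))
  s <- transcript_set_score(tm, bcl2l1_s_set(pseudocount))
  l - s
}

#' Z-score normalization
#'
#' Centers to mean 0 and scales to sample standard deviation 1 (n - 1
#' denominator).
#'
#' @param values numeric vector, length >= 2, non-constant.
#' @return Standardized vector (names preserved).
#' @export
zscore <- function(values) {
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) stop("zero variance; Z-score undefined", call. = FALSE)
  (values - mean(values)) / s
}

#' Extreme-quantile patient groups
#'
#' Selects the \code{floor(n * fraction)} patients with the smallest and the
#' largest stratifier values (for example the 10 percent lowest vs. highest
#' RBM25 expressers). Boundary ties are resolved deterministically by
#' patient id; the groups never overlap.
#'
#' @param stratifier named numeric vector (names are patient ids).
#' @param fraction fraction per tail, in (0, 0.5].
#' @return List with character vectors \code{low} and \code{high}.
#' @export
quantile_groups <- function(stratifier, fraction = 0.10) {
  n <- length(stratifier)
  stopifnot(fraction > 0, fraction <= 0.5, !is.null(names(stratifier)))
  k <- floor(n * fraction)
  if (k < 1) stop("fraction too small: no patients selected", call. = FALSE)
  if (2 * k > n) stop("groups would overlap (n * fraction > n / 2)", call. = FALSE)
  ord <- order(stratifier, names(stratifier))
  list(low = names(stratifier)[ord[seq_len(k)]],
       high = names(stratifier)[ord[seq(n - k + 1, n)]])
}

#' Median-split patient groups
#'
#' Patients strictly below the median go to the low group and strictly above
#' to the high group; patients exactly at the median are assigned to the low
#' group (deterministic tie policy, reported via a message).
#'
#' @param values named numeric vector (names are patient ids).
#' @return List with character vectors \code{low} and \code{high}.
#' @export
median_split <- function(values) {
  stopifnot(length(values) >= 2, !is.null(names(values)))
  m <- stats::median(values)
  at <- values == m
  if (any(at)) {
    message(sum(at), " patient(s) at the median assigned to the low group")
  }
  high <- names(values)[values > m]
  low <- names(values)[values <= m]
  if (length(high) == 0) {
    warning("empty high group (constant or degenerate stratifier)",
            call. = FALSE)
  }
  list(low = low, high = high)
}

#' Mann-Whitney U test between two patient groups
#'
#' Computes the Mann-Whitney U statistic (number of (a, b) pairs with a > b,
#' ties counted half) and a two-sided p value: by exact enumeration when the
#' combined sample size is at most 12 and there are no ties, otherwise by
#' the normal approximation with tie and continuity correction.
#'
#' @param a,b numeric vectors (each length >= 1).
#' @return Object of class \code{group_comparison}: list with \code{n_low},
#'   \code{n_high}, \code{U}, \code{p_two_sided}, \code{method}.
#' @export
mann_whitney <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  has_ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 12) && !has_ties
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)
  )
  structure(list(n_low = length(a), n_high = length(b),
                 U = unname(ht$statistic),
                 p_two_sided = min(ht$p.value, 1),
                 method = if (exact) "EXACT" else "NORMAL_APPROX"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney: n = %d vs %d, U = %g, two-sided p = %.4g (%s)\n",
              x$n_low, x$n_high, x$U, x$p_two_sided, x$method))
  invisible(x)
}

#' Reference-gene-normalized signature score (MYC target score)
#'
#' For each patient, the average of the log2-transformed expression of the
#' signature genes, each normalized to the expression of the reference gene
#' (MYC by default):
#' \code{score = mean_g log2((expr[g] + pc) / (expr[ref] + pc))}.
#' The per-patient division by the reference removes confounding differences
#' in reference-gene expression, which also makes the score invariant to
#' per-patient global rescaling (library size).
#'
#' @param expr numeric gene x patient matrix with gene symbols as rownames.
#' @param signature character vector of signature gene symbols; genes absent
#'   from the matrix are dropped with a warning.
#' @param reference_gene reference gene symbol (default "MYC"); must be
#'   present and positive in every patient.
#' @param pseudocount added before each log2 (default 1).
#' @return Named numeric vector over patients.
#' @export
myc_signature_score <- function(expr, signature, reference_gene = "MYC",
                                pseudocount = 1) {
  expr <- as.matrix(expr)
  if (!reference_gene %in% rownames(expr)) {
    stop("reference gene '", reference_gene, "' absent from matrix",
         call. = FALSE)
  }
  ref <- expr[reference_gene, ]
  if (any(ref + pseudocount <= 0)) {
    stop("reference gene must have positive expression in every patient",
         call. = FALSE)
  }
  present <- intersect(signature, rownames(expr))
  if (length(present) == 0) {
    stop("no signature gene present in the matrix", call. = FALSE)
  }
  dropped <- setdiff(signature, present)
  if (length(dropped) > 0) {
    warning("signature gene(s) dropped (absent from matrix): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  lr <- sweep(log2(expr[present, , drop = FALSE] + pseudocount), 2,
              log2(ref + pseudocount), "-")
  colMeans(lr)
}

#' Read a gene signature file
#'
#' Accepts either a plain list (one gene symbol per line) or a GMT file, in
#' which case the first set is used.
#'
#' @param path signature file path.
#' @return Character vector of gene symbols.
#' @export
read_signature <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty signature file", call. = FALSE)
  if (grepl("\t", lines[1])) {  # GMT: name, description, genes...
    fields <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) stop("malformed GMT line", call. = FALSE)
    fields[-(1:2)]
  } else {
    trimws(lines)
  }
}
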