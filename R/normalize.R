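#' Median-of-ratios size factors
#'
#' Estimates one positive scale factor per sample by the median-of-ratios
#' method: genes with strictly positive counts in every sample form the
#' reference set; for each such gene the geometric mean across samples is
#' computed, and the size factor of sample j is the median over reference
#' genes of count / geometric mean. Dividing counts by the size factors
#' yields normalized expression values comparable across samples.
#'
#' When no gene is positive in all samples the default is an error; with
#' `fallback = "poscounts"` the geometric mean of each gene is taken over
#' its positive counts only and every gene with at least one positive count
#' joins the reference set (zero-count cells are skipped in the per-sample
#' median). The fallback is intended for sparse matrices and is documented
#' as a deviation from the strict estimator.
#'
#' @param counts Count matrix (see [as_count_matrix()]).
#' @param fallback `"none"` (default, strict estimator) or `"poscounts"`.
#' @return Named numeric vector of positive size factors, one per sample.
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2,
#'             dimnames = list(c("g1", "g2", "g3"), c("A", "B")))
#' estimate_size_factors(m)  # c(A = 1/sqrt(2), B = sqrt(2))
#' @export
estimate_size_factors <- function(counts, fallback = c("none", "poscounts")) {
  fallback <- match.arg(fallback)
  counts <- as_count_matrix(counts)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (any(all_pos)) {
    ref <- counts[all_pos, , drop = FALSE]
    log_geo <- rowMeans(log(ref))
    ratios <- ref / exp(log_geo)
    s <- apply(ratios, 2L, stats::median)
  } else if (fallback == "poscounts") {
    pos_any <- rowSums(counts > 0) > 0
    if (!any(pos_any)) stop("count matrix is all zero", call. = FALSE)
    ref <- counts[pos_any, , drop = FALSE]
    lg <- log(ref)
    lg[!is.finite(lg)] <- NA
    log_geo <- rowMeans(lg, na.rm = TRUE)
    ratios <- ref / exp(log_geo)
    ratios[ref == 0] <- NA
    s <- apply(ratios, 2L, stats::median, na.rm = TRUE)
  } else {
    stop("no gene has positive counts in every sample; ",
         "filter the matrix or use fallback = \"poscounts\"", call. = FALSE)
  }
  if (any(!is.finite(s)) || any(s <= 0)) {
    stop("degenerate size factors; check the count matrix", call. = FALSE)
  }
  stats::setNames(s, colnames(counts))
}

#' Normalize counts by size factors
#'
#' Divides each sample's counts by its size factor, giving the normalized
#' expression values used for all signature scoring. With `s = NULL` the
#' size factors are estimated from the matrix itself.
#'
#' @param counts Count matrix.
#' @param s Named size-factor vector, or `NULL` to estimate.
#' @param ... Passed to [estimate_size_factors()] when `s` is `NULL`.
#' @return Numeric matrix of normalized expression, same dimnames as input.
#' @export
normalize_counts <- function(counts, s = NULL, ...) {
  counts <- as_count_matrix(counts)
  if (is.null(s)) s <- estimate_size_factors(counts, ...)
  if (!all(colnames(counts) %in% names(s))) {
    stop("size factors missing for some samples", call. = FALSE)
  }
  s <- s[colnames(counts)]
  if (any(!is.finite(s)) || any(s <= 0)) {
    stop("size factors must be positive and finite", call. = FALSE)
  }
  sweep(counts, 2L, s, "/")
}

#' Decimal-log transform of normalized expression
#'
#' Returns `log10(e + pseudocount)` elementwise. All signature scores are
#' sums of these decimal logarithms. The default pseudocount of 1 maps zero
#' expression to a zero log value and preserves ordering.
#'
#' @param e Normalized expression matrix (non-negative).
#' @param pseudocount Positive offset added before taking log10.
#' @return Matrix of decimal logs, same dimnames as input.
#' @export
log10_transform <- function(e, pseudocount = 1) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
      !is.finite(pseudocount) || pseudocount <= 0) {
    stop("pseudocount must be a single positive number", call. = FALSE)
  }
  if (any(e < 0)) stop("expression values must be non-negative", call. = FALSE)
  log10(e + pseudocount)
}

#' Write size factors as two-column TSV
#'
#' @param s Named size-factor vector.
#' @param path File path.
#' @export
write_size_factors_tsv <- function(s, path) {
  utils::write.table(
    data.frame(sample_id = names(s), size_factor = unname(s)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
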