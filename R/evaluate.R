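#' Matthews Correlation Coefficient from confusion counts
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. When any
#' marginal factor of the denominator is zero the MCC is defined as 0 (a
#' classifier or cohort degenerate in one margin carries no correlation);
#' this continuity convention keeps the statistic total. Vectorized over
#' the four arguments.
#'
#' @param tp,fp,tn,fn Non-negative integer confusion counts.
#' @return MCC value(s) in `[-1, 1]`.
#' @examples
#' mcc_from_counts(5, 0, 5, 0)  # 1
#' mcc_from_counts(3, 1, 4, 2)  # 10 / sqrt(600)
#' @export
mcc_from_counts <- function(tp, fp, tn, fn) {
  cnt <- cbind(tp, fp, tn, fn)
  if (anyNA(cnt) || any(cnt < 0) || any(cnt != round(cnt))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  tp <- cnt[, 1L]; fp <- cnt[, 2L]; tn <- cnt[, 3L]; fn <- cnt[, 4L]
  if (any(tp + fp + tn + fn == 0)) {
    stop("confusion counts are all zero", call. = FALSE)
  }
  num <- tp * tn - fp * fn
  # sqrt of each marginal separately avoids overflow of the product
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  out <- ifelse(den == 0, 0, num / den)
  unname(out)
}

# Precompute the candidate-threshold structure of a score vector: sorted
# unique values, candidate thresholds (midpoints between consecutive
# distinct values plus -Inf/+Inf), and per-value total counts. Labels can
# then be swapped cheaply (permutation tests reuse the same prep).
.eer_prepare <- function(scores) {
  if (!is.numeric(scores) || length(scores) < 2L) {
    stop("need at least two scores", call. = FALSE)
  }
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  ord <- order(scores)
  sorted <- scores[ord]
  u <- sorted[!duplicated(sorted)]
  K <- length(u)
  grp <- findInterval(sorted, u)
  thresholds <- c(-Inf, if (K > 1L) (u[-K] + u[-1L]) / 2, Inf)
  list(ord = ord, grp = grp, K = K, values = u, thresholds = thresholds,
       tab_all = tabulate(grp, K))
}

# Evaluate every candidate threshold for one labelling and return the row
# minimizing |FPR - FNR|, ties broken by maximal MCC then smallest
# threshold. Prediction rule throughout: positive iff score >= threshold.
.eer_eval <- function(prep, pos) {
  P <- sum(pos)
  N <- length(pos) - P
  if (P == 0L || N == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  tab_pos <- tabulate(prep$grp[pos[prep$ord]], prep$K)
  revcum <- function(x) rev(cumsum(rev(x)))
  tp <- c(revcum(tab_pos), 0)          # positives with score >= threshold
  pp <- c(revcum(prep$tab_all), 0)     # all samples with score >= threshold
  fp <- pp - tp
  fn <- P - tp
  tn <- N - fp
  fpr <- fp / N
  fnr <- fn / P
  obj <- abs(fpr - fnr)
  mcc <- mcc_from_counts(tp, fp, tn, fn)
  cand <- which(obj == min(obj))
  cand <- cand[mcc[cand] == max(mcc[cand])]
  i <- cand[1L]
  list(threshold = unname(prep$thresholds[i]), tp = tp[i], fp = fp[i],
       tn = tn[i], fn = fn[i], mcc = mcc[i], fpr = fpr[i], fnr = fnr[i])
}

#' Equal-error-rate decision threshold
#'
#' Turns a continuous predictor into a binary call under the assumption of
#' equal type I and type II errors: among candidate thresholds (midpoints
#' between consecutive distinct sorted scores, plus -Inf and +Inf, with
#' the rule "positive iff score >= threshold") the one minimizing
#' `|FPR - FNR|` is returned; ties are broken by maximal MCC, then by the
#' smaller threshold. If all scores are identical that value is returned
#' with attribute `degenerate = TRUE`.
#'
#' @param scores Named numeric score vector.
#' @param labels Binary GD2 labels (see [check_congruence()] for accepted
#'   forms).
#' @return The threshold, with attributes `mcc`, `fpr`, `fnr` (and
#'   `degenerate` when flagged).
#' @export
equal_error_threshold <- function(scores, labels) {
  pos <- .as_binary_labels(labels, names(scores))
  prep <- .eer_prepare(scores)
  if (prep$K == 1L) {
    thr <- unname(prep$values[1L])
    attr(thr, "degenerate") <- TRUE
    return(thr)
  }
  res <- .eer_eval(prep, unname(pos))
  structure(res$threshold, mcc = res$mcc, fpr = res$fpr, fnr = res$fnr)
}

#' Evaluate one predictor at the equal-error threshold
#'
#' Chooses the equal-error-rate threshold, forms the confusion matrix and
#' MCC there, and (optionally) attaches a permutation p-value: labels are
#' shuffled `n_perm` times, threshold and MCC are recomputed afresh for
#' each shuffle, and `p_perm = (1 + #{perm MCC >= observed}) / (1 +
#' n_perm)` (the add-one estimator, which never returns exactly zero).
#' With `n_perm = 0` the p-value is 1.
#'
#' @param scores Named numeric score vector.
#' @param labels Binary GD2 labels.
#' @param n_perm Number of label permutations (>= 0).
#' @param seed Optional integer seed for the permutations.
#' @param name Predictor name carried into reports.
#' @return A `gd2_eval` object: list with `predictor`, `threshold`,
#'   confusion counts `tp`/`fp`/`tn`/`fn`, `mcc`, `p_perm`, `n_perm`,
#'   `degenerate`.
#' @export
evaluate_predictor <- function(scores, labels, n_perm = 0L, seed = NULL,
                               name = "predictor") {
  if (n_perm < 0) stop("n_perm must be >= 0", call. = FALSE)
  pos <- unname(.as_binary_labels(labels, names(scores)))
  prep <- .eer_prepare(scores)
  degenerate <- prep$K == 1L
  if (degenerate) {
    # all scores identical: threshold at that value predicts all positive
    P <- sum(pos); N <- length(pos) - P
    res <- list(threshold = unname(prep$values[1L]), tp = P, fp = N, tn = 0L,
                fn = 0L, mcc = 0)
  } else {
    res <- .eer_eval(prep, pos)
  }
  p_perm <- 1
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      pb <- sample(pos)
      mb <- if (degenerate) 0 else .eer_eval(prep, pb)$mcc
      if (mb >= res$mcc) hits <- hits + 1L
    }
    p_perm <- (1 + hits) / (1 + n_perm)
  }
  structure(
    list(predictor = name, threshold = res$threshold, tp = res$tp,
         fp = res$fp, tn = res$tn, fn = res$fn, mcc = res$mcc,
         p_perm = p_perm, n_perm = as.integer(n_perm),
         degenerate = degenerate),
    class = "gd2_eval"
  )
}

#' @export
print.gd2_eval <- function(x, ...) {
  cat(sprintf("<gd2_eval> %s: MCC %.4f at threshold %.4g (TP %d FP %d TN %d FN %d), p_perm %.4g%s\n",
              x$predictor, x$mcc, x$threshold, x$tp, x$fp, x$tn, x$fn,
              x$p_perm, if (x$degenerate) " [degenerate scores]" else ""))
  invisible(x)
}

#' @export
as.data.frame.gd2_eval <- function(x, ...) {
  data.frame(predictor = x$predictor, mcc = x$mcc, threshold = x$threshold,
             TP = x$tp, FP = x$fp, TN = x$tn, FN = x$fn,
             p_perm = x$p_perm, n_perm = x$n_perm,
             stringsAsFactors = FALSE)
}

#' Random-gene-pair null distribution
#'
#' Builds the empirical null the observed signature is compared against:
#' `n_pairs` pairs of two distinct genes are drawn from a user-supplied
#' pool (e.g. the GO "lipid metabolic process" genes), each pair is scored
#' as the plain sum of the two genes' decimal-log expression (both signs
#' +1), and its MCC at the equal-error threshold is recorded. The p-value
#' is the frequency of null MCCs strictly greater than the observed
#' signature's MCC. Pairs are drawn independently, so the same pair may
#' recur, and the observed signature's genes are not excluded from the
#' pool.
#'
#' @param logexpr Decimal-log expression matrix.
#' @param labels Binary GD2 labels.
#' @param pool Character vector of pool gene symbols.
#' @param n_pairs Number of random pairs (default 1000).
#' @param seed Optional integer seed.
#' @param observed The observed `signature_spec` (default the flagship
#'   ST8SIA1 + B4GALNT1 signature).
#' @return A `null_distribution` object: `null_mccs`, `observed_mcc`,
#'   `p_value`, `n_pairs`, `seed`, `observed_name`.
#' @export
random_pair_null <- function(logexpr, labels, pool, n_pairs = 1000L,
                             seed = NULL, observed = gd2_signature()) {
  if (n_pairs < 1) stop("n_pairs must be >= 1", call. = FALSE)
  pos <- .as_binary_labels(labels, colnames(logexpr))
  present <- pool[pool %in% rownames(logexpr)]
  dropped <- setdiff(pool, present)
  if (length(dropped)) {
    warning(length(dropped), " pool gene(s) absent from the matrix and dropped",
            call. = FALSE)
  }
  if (length(present) < 2L) {
    stop("fewer than 2 pool genes present in the matrix", call. = FALSE)
  }
  obs_scores <- score_signature(logexpr, observed)
  obs_mcc <- evaluate_predictor(obs_scores, pos, name = observed$name)$mcc
  if (!is.null(seed)) set.seed(seed)
  sub <- logexpr[present, , drop = FALSE]
  null_mccs <- vapply(seq_len(n_pairs), function(i) {
    pair <- sample.int(length(present), 2L)
    sc <- sub[pair[1L], ] + sub[pair[2L], ]
    .eer_eval(.eer_prepare(sc), unname(pos))$mcc
  }, numeric(1))
  structure(
    list(null_mccs = null_mccs, observed_mcc = obs_mcc,
         p_value = sum(null_mccs > obs_mcc) / n_pairs,
         n_pairs = as.integer(n_pairs),
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
         observed_name = observed$name),
    class = "null_distribution"
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %s: observed MCC %.4f vs %d random pairs, p = %.4g\n",
              x$observed_name, x$observed_mcc, x$n_pairs, x$p_value))
  invisible(x)
}

#' Evaluate the six panel genes and the 2-gene signature
#'
#' One evaluation per individual panel gene (its decimal-log expression as
#' the predictor) plus one for the signature: seven rows mirroring the
#' per-predictor MCC tables of the published analysis.
#'
#' @param logexpr Decimal-log expression matrix.
#' @param labels Binary GD2 labels.
#' @param panel Panel data.frame (default [gd2_panel()]).
#' @param signature `signature_spec` (default [gd2_signature()]).
#' @param n_perm Permutations per predictor.
#' @param seed Optional integer seed (one stream across all predictors).
#' @return List of `gd2_eval`, one per predictor; see [panel_table()].
#' @export
evaluate_panel <- function(logexpr, labels, panel = gd2_panel(),
                           signature = gd2_signature(), n_perm = 0L,
                           seed = NULL) {
  missing <- setdiff(panel$gene, rownames(logexpr))
  if (length(missing)) {
    stop("panel gene(s) absent from the matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pos <- .as_binary_labels(labels, colnames(logexpr))
  if (!is.null(seed)) set.seed(seed)
  evals <- lapply(panel$gene, function(g) {
    evaluate_predictor(score_signature(logexpr, signature_spec(g, 1L)),
                       pos, n_perm = n_perm, name = g)
  })
  sig_eval <- evaluate_predictor(score_signature(logexpr, signature), pos,
                                 n_perm = n_perm, name = signature$name)
  c(evals, list(sig_eval))
}

#' Flatten a list of evaluations into a report table
#'
#' @param evals List of `gd2_eval` objects (e.g. from [evaluate_panel()]).
#' @return data.frame with columns predictor, mcc, threshold, TP, FP, TN,
#'   FN, p_perm, n_perm.
#' @export
panel_table <- function(evals) {
  do.call(rbind, lapply(evals, as.data.frame))
}

#' Write evaluation and null-distribution reports
#'
#' `write_panel_tsv` writes the per-predictor table as TSV;
#' `write_null_distribution` writes the null MCCs one per line plus a JSON
#' summary (observed MCC, p-value, number of pairs, seed).
#'
#' @param evals List of `gd2_eval` or a `panel_table` data.frame.
#' @param path Output TSV path.
#' @export
write_panel_tsv <- function(evals, path) {
  df <- if (is.data.frame(evals)) evals else panel_table(evals)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_tsv
#' @param null A `null_distribution`.
#' @param mcc_path Path for the one-MCC-per-line text file.
#' @param summary_path Path for the JSON summary.
#' @export
write_null_distribution <- function(null, mcc_path, summary_path) {
  writeLines(format(null$null_mccs, digits = 15, trim = TRUE), mcc_path)
  jsonlite::write_json(
    list(observed_name = null$observed_name,
         observed_mcc = null$observed_mcc,
         p_value = null$p_value,
         n_pairs = null$n_pairs,
         seed = null$seed),
    summary_path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(summary_path)
}
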