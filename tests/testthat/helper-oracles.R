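# Independent oracles and fixture builders. Each oracle implements the
# definition literally and stays independent of the package code paths it
# checks.

# Literal median-of-ratios: enumerate the reference gene set explicitly,
# geometric means via prod()^(1/n), per-sample median of ratios.
oracle_size_factors <- function(counts) {
  ref_genes <- character(0)
  for (g in rownames(counts)) {
    if (all(counts[g, ] > 0)) ref_genes <- c(ref_genes, g)
  }
  stopifnot(length(ref_genes) > 0)
  s <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    ratios <- numeric(0)
    for (g in ref_genes) {
      geo <- prod(counts[g, ])^(1 / ncol(counts))
      ratios <- c(ratios, counts[g, j] / geo)
    }
    s[j] <- median(ratios)
  }
  names(s) <- colnames(counts)
  s
}

# Direct MCC formula, scalar, with the product under a single sqrt.
oracle_mcc <- function(tp, fp, tn, fn) {
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

# Exhaustive equal-error-rate search: every candidate threshold evaluated
# by direct comparison, same tie-breaks as the contract (min |FPR-FNR|,
# then max MCC, then smallest threshold).
oracle_eer <- function(scores, pos) {
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2, Inf)
  P <- sum(pos); N <- sum(!pos)
  best <- NULL
  for (t in cand) {
    pred <- scores >= t
    tp <- sum(pred & pos); fp <- sum(pred & !pos)
    fn <- sum(!pred & pos); tn <- sum(!pred & !pos)
    obj <- abs(fp / N - fn / P)
    mcc <- oracle_mcc(tp, fp, tn, fn)
    row <- list(threshold = t, obj = obj, mcc = mcc,
                tp = tp, fp = fp, tn = tn, fn = fn)
    if (is.null(best) || obj < best$obj ||
        (obj == best$obj && mcc > best$mcc)) {
      best <- row
    }
  }
  best
}

# Small labelled count fixture: two clearly separated groups on the panel
# genes plus a few background genes.
toy_counts <- function() {
  genes <- c(gd2sig::gd2_panel()$gene, "BG1", "BG2")
  m <- rbind(
    ST3GAL5  = c(100, 110, 90, 95),
    ST8SIA1  = c(500, 450, 10, 12),
    ST8SIA5  = c(30, 35, 40, 38),
    B3GALT4  = c(60, 55, 70, 65),
    B4GALNT1 = c(300, 280, 5, 8),
    B4GALT6  = c(120, 130, 110, 115),
    BG1      = c(50, 55, 60, 52),
    BG2      = c(200, 190, 210, 205))
  colnames(m) <- c("P1", "P2", "N1", "N2")
  m
}

toy_labels <- function() {
  c(P1 = "positive", P2 = "positive", N1 = "negative", N2 = "negative")
}

# Random small count matrix with guaranteed all-positive reference genes.
random_counts <- function(n_genes, n_samples) {
  m <- matrix(rpois(n_genes * n_samples, lambda = 50) + 1L,
              nrow = n_genes,
              dimnames = list(sprintf("G%02d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_samples))))
  # sprinkle some zeros in up to half the genes so the reference-set
  # exclusion rule is exercised
  kill <- seq_len(max(0L, n_genes %/% 2L))
  for (g in kill) {
    j <- sample(n_samples, 1L)
    m[g, j] <- 0L
  }
  m
}
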