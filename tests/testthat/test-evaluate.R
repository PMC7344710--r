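test_that("MCC matches the direct formula on crafted cases", {
  expect_equal(mcc_from_counts(5, 0, 5, 0), 1)
  expect_equal(mcc_from_counts(0, 5, 0, 5), -1)
  expect_equal(mcc_from_counts(3, 1, 4, 2), 10 / sqrt(600))
  # zero marginal -> 0 by convention
  expect_equal(mcc_from_counts(5, 5, 0, 0), 0)
  expect_equal(mcc_from_counts(0, 0, 5, 5), 0)
  expect_error(mcc_from_counts(0, 0, 0, 0), "zero")
  expect_error(mcc_from_counts(-1, 0, 1, 0), "non-negative")
})

test_that("MCC symmetry properties hold over all small confusion matrices", {
  # swapping both predicted and true classes (TP<->TN, FP<->FN) preserves
  # MCC; swapping only the prediction (TP<->FP, TN<->FN) negates it
  total <- 12
  for (tp in 0:total) for (fp in 0:(total - tp)) {
    for (tn in 0:(total - tp - fp)) {
      fn <- total - tp - fp - tn
      m <- mcc_from_counts(tp, fp, tn, fn)
      expect_equal(m, mcc_from_counts(tn, fn, tp, fp), tolerance = 1e-12)
      expect_equal(m, -mcc_from_counts(fp, tp, fn, tn), tolerance = 1e-12)
      expect_true(m >= -1 - 1e-12 && m <= 1 + 1e-12)
    }
  }
})

test_that("equal-error threshold handles the separable toy case", {
  sc <- c(p1 = 3, p2 = 4, n1 = 1, n2 = 2)
  lab <- c(p1 = "positive", p2 = "positive", n1 = "negative", n2 = "negative")
  thr <- equal_error_threshold(sc, lab)
  expect_equal(as.numeric(thr), 2.5)
  expect_equal(attr(thr, "fpr"), 0)
  expect_equal(attr(thr, "fnr"), 0)
  expect_equal(attr(thr, "mcc"), 1)
})

test_that("equal-error threshold matches the exhaustive oracle", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    pos <- rep(FALSE, n)
    pos[sample(n, sample(seq_len(n - 1), 1))] <- TRUE
    # ties in scores are common under rounding; exercise them
    sc <- round(rnorm(n), sample(0:2, 1))
    names(sc) <- paste0("s", seq_len(n))
    got <- equal_error_threshold(sc, setNames(ifelse(pos, "positive",
                                                     "negative"), names(sc)))
    want <- oracle_eer(sc, pos)
    expect_identical(as.numeric(got), want$threshold)
    expect_equal(attr(got, "mcc"), want$mcc, tolerance = 1e-12)
  }
})

test_that("anti-predictive scores still minimize |FPR - FNR|", {
  set.seed(5)
  sc <- c(rnorm(20, 2), rnorm(20, 0))
  names(sc) <- paste0("s", 1:40)
  pos <- c(rep(FALSE, 20), rep(TRUE, 20))  # labels swapped
  got <- equal_error_threshold(sc, setNames(ifelse(pos, "positive",
                                                   "negative"), names(sc)))
  want <- oracle_eer(sc, pos)
  expect_identical(as.numeric(got), want$threshold)
  expect_true(attr(got, "mcc") < 0)
})

test_that("degenerate identical scores are flagged, not fatal", {
  sc <- setNames(rep(2.5, 6), paste0("s", 1:6))
  lab <- setNames(rep(c("positive", "negative"), 3), names(sc))
  thr <- equal_error_threshold(sc, lab)
  expect_equal(as.numeric(thr), 2.5)
  expect_true(attr(thr, "degenerate"))
  ev <- evaluate_predictor(sc, lab)
  expect_true(ev$degenerate)
  expect_equal(ev$mcc, 0)
})

test_that("evaluate_predictor is deterministic and honors the add-one estimator", {
  sc <- c(p1 = 3, p2 = 4, n1 = 1, n2 = 2)
  lab <- c(p1 = "positive", p2 = "positive", n1 = "negative", n2 = "negative")
  # perfect separation, no permutations -> mcc 1, p_perm 1
  ev0 <- evaluate_predictor(sc, lab, n_perm = 0)
  expect_equal(ev0$mcc, 1)
  expect_equal(ev0$p_perm, 1)
  expect_equal(ev0$tp + ev0$fp + ev0$tn + ev0$fn, 4)

  ev1 <- evaluate_predictor(sc, lab, n_perm = 99, seed = 7)
  ev2 <- evaluate_predictor(sc, lab, n_perm = 99, seed = 7)
  expect_identical(ev1, ev2)
  # add-one estimator never returns 0 and counts perms with mcc >= observed
  expect_true(ev1$p_perm >= 1 / 100)
  # mcc recomputable from the confusion counts
  expect_equal(ev1$mcc,
               mcc_from_counts(ev1$tp, ev1$fp, ev1$tn, ev1$fn),
               tolerance = 1e-12)
})

test_that("permutation p-values under the null are approximately uniform", {
  # reduced-scale calibration (the full experiment runs in the acceptance
  # suite): n = 60, 199 perms, 60 seeds; check p-values are not
  # stochastically smaller than uniform at the 0.1 level
  set.seed(303)
  pvals <- replicate(60, {
    sc <- setNames(rnorm(60), paste0("s", 1:60))
    lab <- setNames(sample(rep(c("positive", "negative"), 30)), names(sc))
    evaluate_predictor(sc, lab, n_perm = 199)$p_perm
  })
  frac <- mean(pvals <= 0.1)
  # binomial 99% envelope around 0.1 at n = 60: [0, 0.2167]
  expect_lte(frac, qbinom(0.995, 60, 0.1) / 60)
})

test_that("random-pair null honors the strictly-greater p-value definition", {
  lx <- log10_transform(normalize_counts(toy_counts()), 1)
  lab <- toy_labels()
  # degenerate pool of exactly 2 genes: every draw is the same pair
  null <- random_pair_null(lx, lab, c("BG1", "BG2"), n_pairs = 50, seed = 1)
  expect_length(null$null_mccs, 50)
  expect_equal(length(unique(null$null_mccs)), 1)
  expect_true(null$p_value %in% c(0, 1))
  # observed signature separates the toy cohort perfectly -> MCC 1,
  # nothing can be strictly greater -> p = 0
  expect_equal(null$observed_mcc, 1)
  expect_equal(null$p_value, 0)

  # crafted ties: null MCCs equal to the observed MCC do not count
  fake <- null
  fake$null_mccs <- c(rep(null$observed_mcc, 10), rep(-1, 40))
  expect_equal(sum(fake$null_mccs > fake$observed_mcc) / 50, 0)

  # pool genes absent from the matrix are dropped with a warning
  expect_warning(
    random_pair_null(lx, lab, c("BG1", "BG2", "GHOST"), n_pairs = 5, seed = 1),
    "dropped")
  expect_error(
    suppressWarnings(random_pair_null(lx, lab, c("BG1", "GHOST"),
                                      n_pairs = 5, seed = 1)),
    "fewer than 2")
})

test_that("an anti-predictive observed signature yields p = 1 against a positive null", {
  set.seed(17)
  n <- 40
  pos <- c(rep(TRUE, 20), rep(FALSE, 20))
  # gene A predicts perfectly; X and Y are the anti-predictive observed pair
  lx <- rbind(A = ifelse(pos, 5, 1) + rnorm(n, 0, .01),
              B = ifelse(pos, 4, 2) + rnorm(n, 0, .01),
              X = ifelse(pos, 1, 5) + rnorm(n, 0, .01),
              Y = ifelse(pos, 1, 5) + rnorm(n, 0, .01))
  colnames(lx) <- paste0("s", 1:n)
  lab <- setNames(ifelse(pos, "positive", "negative"), colnames(lx))
  null <- random_pair_null(lx, lab, c("A", "B"), n_pairs = 100, seed = 2,
                           observed = signature_spec(c("X", "Y")))
  expect_equal(null$p_value, 1)
})

test_that("panel evaluation rows equal standalone predictor evaluations", {
  lx <- log10_transform(normalize_counts(toy_counts()), 1)
  lab <- toy_labels()
  evals <- evaluate_panel(lx, lab, n_perm = 0)
  expect_length(evals, 7)
  tab <- panel_table(evals)
  expect_identical(tab$predictor,
                   c(gd2_panel()$gene, "ST8SIA1+B4GALNT1"))
  for (g in gd2_panel()$gene) {
    solo <- evaluate_predictor(setNames(lx[g, ], colnames(lx)), lab, name = g)
    row <- evals[[match(g, tab$predictor)]]
    expect_identical(row[c("mcc", "threshold", "tp", "fp", "tn", "fn")],
                     solo[c("mcc", "threshold", "tp", "fp", "tn", "fn")])
  }
  sig_row <- evals[[7]]
  solo_sig <- evaluate_predictor(score_signature(lx, gd2_signature()), lab,
                                 name = "ST8SIA1+B4GALNT1")
  expect_identical(sig_row$mcc, solo_sig$mcc)
  expect_error(evaluate_panel(lx[-2, ], lab), "ST8SIA1")
})

test_that("null distribution files are written faithfully", {
  lx <- log10_transform(normalize_counts(toy_counts()), 1)
  null <- random_pair_null(lx, toy_labels(), c("BG1", "BG2"),
                           n_pairs = 10, seed = 3)
  mcc_path <- withr::local_tempfile(fileext = ".txt")
  json_path <- withr::local_tempfile(fileext = ".json")
  write_null_distribution(null, mcc_path, json_path)
  expect_equal(as.numeric(readLines(mcc_path)), null$null_mccs,
               tolerance = 1e-12)
  js <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  expect_equal(js$p_value, null$p_value)
  expect_equal(js$n_pairs, 10)
})
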