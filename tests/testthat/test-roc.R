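test_that("AUC: perfect separation, all-tied scores, brute-force pair count", {
  lab <- c(rep(TRUE, 3), rep(FALSE, 4))
  expect_equal(roc_auc(c(5, 6, 7, 1, 2, 3, 4), lab)$auc, 1)
  expect_equal(roc_auc(rep(2, 7), lab)$auc, 0.5)
  # fixed 8-point instance with ties, against full pair enumeration
  s <- c(3, 1, 4, 4, 2, 5, 1, 3)
  l <- c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE)
  expect_equal(roc_auc(s, l)$auc, brute_auc(s, l))
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both")
  expect_error(roc_auc(1:3, c(TRUE, FALSE)), "length")
})

test_that("ROC points run monotonically from (0,0) to (1,1); trapezoid = AUC", {
  set.seed(501)
  for (i in 1:25) {
    inst <- random_roc_instance()
    roc <- roc_auc(inst$scores, inst$labels)
    p <- roc$points
    expect_equal(c(p$fpr[1], p$tpr[1]), c(0, 0))
    expect_equal(c(p$fpr[nrow(p)], p$tpr[nrow(p)]), c(1, 1))
    expect_true(all(diff(p$fpr) >= 0) && all(diff(p$tpr) >= 0))
    # trapezoidal area equals the tie-corrected Mann-Whitney statistic
    trap <- sum(diff(p$fpr) * (utils::head(p$tpr, -1) + utils::tail(p$tpr, -1)) / 2)
    expect_equal(trap, roc$auc, tolerance = 1e-12)
    # AUC within its own CI
    expect_true(roc$auc >= roc$auc_ci95[1] - 1e-12 &&
                roc$auc <= roc$auc_ci95[2] + 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(502)
  for (i in 1:20) {
    inst <- random_roc_instance()
    a1 <- roc_auc(inst$scores, inst$labels)$auc
    a2 <- roc_auc(exp(inst$scores / 3), inst$labels)$auc
    a3 <- roc_auc(2 * inst$scores + 7, inst$labels)$auc
    expect_equal(a1, a2)
    expect_equal(a1, a3)
  }
})

test_that("AUC equals the mean of DeLong placement values", {
  set.seed(503)
  inst <- random_roc_instance()
  pl <- hemoscore:::delong_placements(inst$scores, inst$labels)
  expect_equal(mean(pl$v10), pl$auc)
  expect_equal(mean(pl$v01), pl$auc)
  expect_equal(roc_auc(inst$scores, inst$labels)$auc, pl$auc)
})

test_that("AUC and DeLong CI agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(504)
  co <- generate_cohort(cohort_config(n = 300, seed = 77))
  m <- score_cohort(co, c("mticcs", "tash"))
  lab <- label_mt(co)
  ours <- roc_auc(m$mticcs, lab)
  ref <- pROC::roc(lab, m$mticcs, quiet = TRUE, direction = "<")
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)))
  # same DeLong variance (pROC var.roc uses the same estimator)
  expect_equal(ours$auc_se^2, as.numeric(pROC::var(ref, method = "delong")),
               tolerance = 1e-10)
  # paired DeLong test p-value matches
  ref2 <- pROC::roc(lab, m$tash, quiet = TRUE, direction = "<")
  dl <- delong_test(m$mticcs, m$tash, lab)
  pr <- pROC::roc.test(ref, ref2, method = "delong", paired = TRUE)
  expect_equal(dl$p_value, pr$p.value, tolerance = 1e-10)
})

test_that("Youden cut-off: exhaustive search, perfect separation, tie-break", {
  # 12-point instance against exhaustive search
  s <- c(2, 2, 3, 5, 5, 6, 7, 8, 8, 9, 4, 3)
  l <- c(F, F, F, F, T, F, T, T, T, T, F, T)
  roc <- youden_cutoff(roc_auc(s, l))
  ex <- brute_youden(s, l)
  expect_equal(roc$youden_cutoff, ex$cutoff)
  expect_equal(roc$youden_j, ex$j)

  # perfect separation: J = 1 at the maximum negative score
  roc2 <- youden_cutoff(roc_auc(c(1, 2, 3, 10, 11), c(F, F, F, T, T)))
  expect_equal(roc2$youden_j, 1)
  expect_equal(roc2$youden_cutoff, 3)

  # tie on J (c = 1 and c = 4 both give J = 0.5) resolved to the smallest c
  roc3 <- youden_cutoff(roc_auc(c(1, 4, 3, 5), c(F, F, T, T)))
  expect_equal(roc3$youden_j, 0.5)
  expect_equal(roc3$youden_cutoff, 1)
})

test_that("DeLong comparison: self-test, rank invariance, degenerate input", {
  set.seed(505)
  inst <- random_roc_instance()
  self <- delong_test(inst$scores, inst$scores, inst$labels)
  expect_equal(self$auc_difference, 0)
  expect_equal(self$p_value, 1)
  mono <- delong_test(inst$scores, qlogis(plogis(inst$scores)) + 100,
                      inst$labels)
  expect_equal(mono$auc_difference, 0, tolerance = 1e-12)
  expect_equal(mono$p_value, 1)
})

test_that("confusion_at uses strict positivity and handles extreme cut-offs", {
  s <- c(1, 2, 3, 4, 5)
  l <- c(F, F, T, F, T)
  cm <- confusion_at(s, l, 3)
  expect_equal(unlist(cm[c("tp", "fp", "fn", "tn")]),
               c(tp = 1, fp = 1, fn = 1, tn = 2))
  hi <- confusion_at(s, l, 5)
  expect_equal(c(hi$tp, hi$fp), c(0, 0))
  lo <- confusion_at(s, l, 0)
  expect_equal(c(lo$fn, lo$tn), c(0, 0))
  # strict inequality: a positive scoring exactly the cut-off is test negative
  expect_equal(confusion_at(s, l, 3)$tp, 1)
  expect_equal(confusion_at(s, l, 2.999)$tp, 2)
})
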