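check_roc_input <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels must have the same length")
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels))
    stop("scores and labels must be complete (subset to complete cases first)")
  if (!all(is.finite(scores))) stop("scores must be finite")
  if (!any(labels) || all(labels))
    stop("both outcome classes must be present")
  labels
}

# DeLong placement values. For positives x and negatives y,
# V10_i = mean_j psi(x_i, y_j), V01_j = mean_i psi(x_i, y_j) with
# psi = 1 if x > y, 1/2 if tied, 0 otherwise. AUC = mean(V10) = mean(V01)
# is the tie-corrected Mann-Whitney statistic. Computed via mid-ranks in
# O(N log N): psi-sums equal combined-rank minus within-group rank.
delong_placements <- function(scores, labels) {
  x <- scores[labels]
  y <- scores[!labels]
  m <- length(x)
  n <- length(y)
  r_all <- rank(c(x, y))
  v10 <- (r_all[seq_len(m)] - rank(x)) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(y)) / m
  list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
}

#' Empirical ROC curve and AUC with DeLong confidence interval
#'
#' Builds the empirical ROC (positivity rule "score strictly greater than
#' cut-off") and estimates the AUC as the tie-corrected Mann-Whitney
#' statistic. The AUC variance is DeLong's placement-value estimator and the
#' 95% CI is computed on the logit scale (so it respects the (0,1) bounds).
#'
#' @param scores numeric vector of score values.
#' @param labels logical vector (TRUE = event, e.g. massive transfusion).
#' @param score_name optional label for reports.
#' @param conf_level CI coverage (default 0.95).
#' @return A `hemoscore_roc` object: `thresholds` (sorted unique score
#'   values), `points` (threshold, fpr, tpr including the (0,0) and (1,1)
#'   endpoints), `auc`, `auc_se`, `auc_ci95`, and `youden_cutoff`/`youden_j`
#'   once [youden_cutoff()] has been applied.
#' @export
roc_auc <- function(scores, labels, score_name = "score", conf_level = 0.95) {
  labels <- check_roc_input(scores, labels)
  pl <- delong_placements(scores, labels)
  var_auc <- if (pl$m > 1) stats::var(pl$v10) / pl$m else 0
  if (pl$n > 1) var_auc <- var_auc + stats::var(pl$v01) / pl$n
  se <- sqrt(var_auc)

  thr <- sort(unique(scores))
  grid <- c(Inf, rev(thr), -Inf)
  x <- scores[labels]; y <- scores[!labels]
  pts <- data.frame(
    threshold = grid,
    fpr = vapply(grid, function(c) mean(y > c), numeric(1)),
    tpr = vapply(grid, function(c) mean(x > c), numeric(1))
  )

  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- if (se == 0 || pl$auc %in% c(0, 1)) {
    c(pl$auc, pl$auc)
  } else {
    l <- stats::qlogis(pl$auc)
    hw <- z * se / (pl$auc * (1 - pl$auc))
    stats::plogis(c(l - hw, l + hw))
  }

  structure(list(
    score_name = score_name, scores = scores, labels = labels,
    thresholds = thr, points = pts,
    auc = pl$auc, auc_se = se, auc_ci95 = ci,
    youden_cutoff = NA_real_, youden_j = NA_real_
  ), class = "hemoscore_roc")
}

#' @export
print.hemoscore_roc <- function(x, ...) {
  cat(sprintf("<ROC: %s> AUC %.3f (95%% CI %.3f-%.3f), n+ = %d, n- = %d\n",
              x$score_name, x$auc, x$auc_ci95[1], x$auc_ci95[2],
              sum(x$labels), sum(!x$labels)))
  if (!is.na(x$youden_cutoff))
    cat(sprintf("  Youden cut-off: > %g (J = %.3f)\n",
                x$youden_cutoff, x$youden_j))
  invisible(x)
}

#' Youden-index cut-off selection
#'
#' Selects the cut-off c maximizing J(c) = TPR(c) - FPR(c) over the observed
#' score values, under the positivity rule "score > c". Ties are broken
#' towards the smallest c (the most sensitive rule, appropriate for a
#' screening test).
#'
#' @param roc a `hemoscore_roc` from [roc_auc()].
#' @return The same object with `youden_cutoff` and `youden_j` filled in.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "hemoscore_roc"))
  x <- roc$scores[roc$labels]
  y <- roc$scores[!roc$labels]
  j <- vapply(roc$thresholds,
              function(c) mean(x > c) - mean(y > c), numeric(1))
  best <- which.max(j)  # which.max returns the first (smallest c) on ties
  roc$youden_cutoff <- roc$thresholds[best]
  roc$youden_j <- j[best]
  roc
}

#' Paired DeLong comparison of two correlated AUCs
#'
#' Tests the difference between the AUCs of two scores computed on the same
#' records (paired design) using DeLong's placement-value covariance
#' estimator; the two-sided p-value comes from the normal distribution.
#'
#' @param scores_a,scores_b numeric score vectors over the same records.
#' @param labels logical outcome vector.
#' @param names optional character(2) score labels.
#' @return A `hemoscore_delong` object with `auc_a`, `auc_b`,
#'   `auc_difference`, `variance`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels,
                        names = c("score_a", "score_b")) {
  labels <- check_roc_input(scores_a, labels)
  check_roc_input(scores_b, labels)
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / pa$m +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / pa$n
  var_diff <- max(var_diff, 0)
  diff <- pa$auc - pb$auc
  if (var_diff == 0) {
    z <- if (diff == 0) 0 else sign(diff) * Inf
  } else {
    z <- diff / sqrt(var_diff)
  }
  structure(list(
    score_a = names[1], score_b = names[2],
    auc_a = pa$auc, auc_b = pb$auc,
    auc_difference = diff, variance = var_diff,
    z = z, p_value = if (is.infinite(z)) 0 else 2 * stats::pnorm(-abs(z))
  ), class = "hemoscore_delong")
}

#' @export
print.hemoscore_delong <- function(x, ...) {
  cat(sprintf("<DeLong> AUC %s = %.3f vs %s = %.3f; dAUC = %.4f, z = %.3f, p = %.4f\n",
              x$score_a, x$auc_a, x$score_b, x$auc_b,
              x$auc_difference, x$z, x$p_value))
  invisible(x)
}

#' Confusion matrix at a cut-off
#'
#' Counts under the strict positivity rule "score > cutoff".
#'
#' @inheritParams roc_auc
#' @param cutoff score value.
#' @return A `hemoscore_confusion`: list with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_at <- function(scores, labels, cutoff) {
  labels <- check_roc_input(scores, labels)
  pos <- scores > cutoff
  confusion_matrix(tp = sum(pos & labels), fp = sum(pos & !labels),
                   fn = sum(!pos & labels), tn = sum(!pos & !labels))
}

#' @rdname confusion_at
#' @param tp,fp,fn,tn non-negative integer counts.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) == 0) stop("empty confusion matrix")
  structure(as.list(as.integer(counts)) |> setNames(names(counts)),
            class = "hemoscore_confusion")
}

#' @export
print.hemoscore_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("test +", "test -"), c("event", "no event")))
  print(m)
  invisible(x)
}
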