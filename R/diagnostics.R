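#' Exact Clopper-Pearson binomial confidence interval
#'
#' Central exact interval from beta quantiles; the lower bound is 0 when
#' `x = 0` and the upper bound 1 when `x = n`.
#'
#' @param x number of successes (0 <= x <= n).
#' @param n number of trials (>= 1).
#' @param level coverage, default 0.95.
#' @return Numeric `c(lo, hi)` on the proportion scale.
#' @export
clopper_pearson <- function(x, n, level = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n, level > 0, level < 1)
  a <- (1 - level) / 2
  lo <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lo, hi)
}

# Logit-method CI for predictive values (Mercaldo et al. 2006): the variance
# of logit(PPV)/logit(NPV) is expressed through sensitivity, specificity and
# the two group sizes, which is how MedCalc-style reports compute them.
logit_pv_ci <- function(which = c("ppv", "npv"), sens, spec, n_pos, n_neg,
                        estimate, level = 0.95) {
  which <- match.arg(which)
  if (sens %in% c(0, 1) || spec %in% c(0, 1) || estimate %in% c(0, 1))
    return(c(NA_real_, NA_real_))
  v <- if (which == "ppv") {
    ((1 - sens) / sens) / n_pos + (spec / (1 - spec)) / n_neg
  } else {
    (sens / (1 - sens)) / n_pos + ((1 - spec) / spec) / n_neg
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  stats::plogis(stats::qlogis(estimate) + c(-1, 1) * z * sqrt(v))
}

#' Diagnostic test metrics with 95% confidence intervals
#'
#' Prevalence, sensitivity, specificity, PPV and NPV (as percentages) from a
#' confusion matrix. Prevalence, sensitivity and specificity carry exact
#' Clopper-Pearson intervals; PPV and NPV carry logit-method intervals
#' (Mercaldo). A metric whose denominator is zero is reported as absent with
#' a reason rather than as 0. Values are kept full precision; rounding to
#' printed precision happens only in [render_report()].
#'
#' @param cm a `hemoscore_confusion` (see [confusion_at()]).
#' @param level CI coverage, default 0.95.
#' @return A `hemoscore_diagnostic_summary`: named list of metrics, each with
#'   `estimate` (percent), `ci` (percent), `method`, `x`, `n`, and `reason`
#'   when undefined; plus the `counts`.
#' @export
diagnostic_summary <- function(cm, level = 0.95) {
  stopifnot(inherits(cm, "hemoscore_confusion"))
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  n_pos <- cm$tp + cm$fn
  n_neg <- cm$fp + cm$tn

  metric <- function(x, d, method, reason_if_empty) {
    if (d == 0)
      return(list(estimate = NA_real_, ci = c(NA_real_, NA_real_),
                  method = method, x = x, n = d, reason = reason_if_empty))
    list(estimate = 100 * x / d, ci = NULL, method = method,
         x = x, n = d, reason = NA_character_)
  }
  out <- list(
    prevalence  = metric(n_pos, n, "clopper-pearson", "empty cohort"),
    sensitivity = metric(cm$tp, n_pos, "clopper-pearson", "no positives"),
    specificity = metric(cm$tn, n_neg, "clopper-pearson", "no negatives"),
    ppv = metric(cm$tp, cm$tp + cm$fp, "logit (mercaldo)", "no test-positives"),
    npv = metric(cm$tn, cm$tn + cm$fn, "logit (mercaldo)", "no test-negatives")
  )
  for (nm in c("prevalence", "sensitivity", "specificity")) {
    m <- out[[nm]]
    if (!is.na(m$estimate))
      out[[nm]]$ci <- 100 * clopper_pearson(m$x, m$n, level)
  }
  sens <- out$sensitivity$estimate / 100
  spec <- out$specificity$estimate / 100
  for (nm in c("ppv", "npv")) {
    m <- out[[nm]]
    if (!is.na(m$estimate)) {
      if (is.na(sens) || is.na(spec)) {
        out[[nm]]$ci <- c(NA_real_, NA_real_)
      } else {
        out[[nm]]$ci <- 100 * logit_pv_ci(nm, sens, spec, n_pos, n_neg,
                                          m$estimate / 100, level)
      }
    }
  }
  structure(c(out, list(counts = cm, n = n, conf_level = level)),
            class = "hemoscore_diagnostic_summary")
}

#' @export
print.hemoscore_diagnostic_summary <- function(x, digits = 2, ...) {
  cat(sprintf("<diagnostic summary> n = %d (tp %d, fp %d, fn %d, tn %d)\n",
              x$n, x$counts$tp, x$counts$fp, x$counts$fn, x$counts$tn))
  for (nm in c("prevalence", "sensitivity", "specificity", "ppv", "npv")) {
    m <- x[[nm]]
    if (is.na(m$estimate)) {
      cat(sprintf("  %-12s absent (%s)\n", nm, m$reason))
    } else {
      cat(sprintf("  %-12s %6.2f%%  (95%% CI %.1f-%.1f, %s)\n", nm,
                  m$estimate, m$ci[1], m$ci[2], m$method))
    }
  }
  invisible(x)
}
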