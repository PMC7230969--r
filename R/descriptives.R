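#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test with mid-ranks for ties. Exact enumeration is used
#' when both groups have at most 10 observations and there are no ties;
#' otherwise the normal approximation with tie-corrected variance and
#' continuity correction is used.
#'
#' @param x,y numeric vectors (both non-empty).
#' @return List with `statistic` (Mann-Whitney U), `p_value`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  if (length(unique(c(x, y))) == 1L)  # degenerate: no rank information at all
    return(list(statistic = length(x) * length(y) / 2, p_value = 1,
                method = "degenerate (all values tied)"))
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 10 && length(y) <= 10 && !ties
  ht <- stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = if (exact) "exact" else "normal approximation (tie-corrected, continuity-corrected)")
}

#' Chi-square test for a 2x2 table
#'
#' Pearson chi-square with Yates continuity correction (1 df).
#'
#' @param a,b,c,d cell counts, rows = groups, columns = outcome:
#'   `rbind(c(a, b), c(c, d))`.
#' @return List with `statistic`, `p_value`, `df`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be non-negative")
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal total")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value, df = 1L)
}

# Default variable panel for group descriptives: continuous variables get
# median (min-max) + Wilcoxon, categorical get % (n) + chi-square.
default_descriptive_vars <- function() {
  rbind(
    data.frame(variable = c("age", "iss", "niss", "prbc_24h",
                            paste0("ais_", AIS_REGIONS)),
               type = "continuous", stringsAsFactors = FALSE),
    data.frame(variable = c("male_sex", "sbp_initial_le_90", "blunt",
                            MECHANISM_SUBTYPES, "died"),
               type = "categorical", stringsAsFactors = FALSE)
  )
}

# Derived categorical indicators used by the default panel
derived_indicator <- function(cohort, variable) {
  switch(variable,
    male_sex = cohort$sex == "male",
    sbp_initial_le_90 = cohort$sbp_initial <= 90,
    blunt = cohort$mechanism == "blunt",
    died = cohort$died,
    if (variable %in% MECHANISM_SUBTYPES) cohort$mechanism_subtype == variable
    else as.logical(cohort[[variable]])
  )
}

#' Group comparison table (massive transfusion vs no massive transfusion)
#'
#' For each requested variable, summarizes both outcome groups and tests the
#' difference: continuous variables by median (range) and the Wilcoxon
#' rank-sum test, categorical variables by percent (count) and the
#' Yates-corrected chi-square test. No multiplicity adjustment is applied.
#'
#' @param cohort a `hemoscore_cohort`.
#' @param by logical outcome vector; default [label_mt()] on the cohort.
#' @param variables data.frame with columns `variable`, `type`
#'   (`"continuous"`/`"categorical"`); defaults to a demographics/injury
#'   panel.
#' @param mt_threshold pRBC units defining massive transfusion when `by` is
#'   not supplied.
#' @return data.frame with one row per variable: group summaries, test name
#'   and p-value.
#' @export
summarize_groups <- function(cohort, by = NULL,
                             variables = default_descriptive_vars(),
                             mt_threshold = 10L) {
  if (is.null(by)) by <- label_mt(cohort, mt_threshold)
  if (!any(by) || all(by)) stop("both groups must be present")

  one <- function(variable, type) {
    if (type == "continuous") {
      v <- as.numeric(cohort[[variable]])
      x1 <- v[by & !is.na(v)]; x0 <- v[!by & !is.na(v)]
      ht <- wilcoxon_rank_sum(x1, x0)
      data.frame(
        variable = variable, type = type,
        group_mt = sprintf("%g (%g-%g)", stats::median(x1), min(x1), max(x1)),
        group_no_mt = sprintf("%g (%g-%g)", stats::median(x0), min(x0), max(x0)),
        test = "wilcoxon rank-sum", p_value = ht$p_value,
        stringsAsFactors = FALSE)
    } else {
      f <- derived_indicator(cohort, variable)
      ok <- !is.na(f)
      t11 <- sum(f & by & ok); t10 <- sum(!f & by & ok)
      t01 <- sum(f & !by & ok); t00 <- sum(!f & !by & ok)
      p <- if ((t11 + t01) == 0 || (t10 + t00) == 0) {
        1  # constant indicator: no evidence of association
      } else {
        chi_square_2x2(t11, t10, t01, t00)$p_value
      }
      data.frame(
        variable = variable, type = type,
        group_mt = sprintf("%.1f%% (%d)", 100 * t11 / (t11 + t10), t11),
        group_no_mt = sprintf("%.1f%% (%d)", 100 * t01 / (t01 + t00), t01),
        test = "chi-square (yates)", p_value = p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, Map(one, variables$variable, variables$type))
  rownames(out) <- NULL
  out
}
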