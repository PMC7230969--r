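round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Run the full diagnostic-accuracy validation
#'
#' For each requested score: scores the cohort (per-score complete-case
#' subset), builds the empirical ROC, estimates the AUC with its DeLong 95%
#' CI, selects the Youden cut-off, and computes the confusion matrix and
#' diagnostic summary at that cut-off. Each non-reference score's AUC is then
#' compared to the reference score's AUC by the paired DeLong test on the
#' intersection of their complete cases. The reference appears in no
#' self-comparison row.
#'
#' @param cohort a `hemoscore_cohort` containing both outcome classes.
#' @param scores character vector of score names (default: all six).
#' @param reference score name used for pairwise AUC comparisons
#'   (default `"mticcs"`).
#' @param mt_threshold pRBC units defining massive transfusion (default 10).
#' @param ais_severe_threshold AIS grade treated as severe for mTICCS.
#' @param definitions rubric configuration, see [load_score_definitions()].
#' @return A `hemoscore_validation_report`: `per_score` (list with `n`,
#'   `excluded`, `roc`, `confusion`, `summary` per score), `comparisons`
#'   (data.frame of DeLong tests vs the reference), `meta` (run metadata).
#' @export
run_validation <- function(cohort, scores = NULL, reference = "mticcs",
                           mt_threshold = 10L, ais_severe_threshold = 3L,
                           definitions = load_score_definitions()) {
  if (is.null(scores)) scores <- names(definitions)
  if (!reference %in% c(scores, NA))
    stop("reference score must be among the requested scores")
  labels <- label_mt(cohort, mt_threshold)
  if (!any(labels) || all(labels))
    stop("cohort has a single outcome class after labelling")

  mat <- score_cohort(cohort, scores, definitions, ais_severe_threshold)

  per_score <- list()
  for (nm in scores) {
    v <- mat[[nm]]
    ok <- !is.na(v)
    roc <- youden_cutoff(roc_auc(v[ok], labels[ok], score_name = nm))
    cm <- confusion_at(v[ok], labels[ok], roc$youden_cutoff)
    per_score[[nm]] <- list(
      n = sum(ok), excluded = sum(!ok),
      roc = roc, confusion = cm, summary = diagnostic_summary(cm)
    )
  }

  comparisons <- NULL
  if (!is.na(reference) && length(scores) > 1L) {
    rows <- lapply(setdiff(scores, reference), function(nm) {
      ok <- !is.na(mat[[nm]]) & !is.na(mat[[reference]])
      dl <- delong_test(mat[[nm]][ok], mat[[reference]][ok], labels[ok],
                        names = c(nm, reference))
      data.frame(score = nm, reference = reference, n = sum(ok),
                 auc = dl$auc_a, auc_reference = dl$auc_b,
                 auc_difference = dl$auc_difference,
                 z = dl$z, p_value = dl$p_value, stringsAsFactors = FALSE)
    })
    comparisons <- do.call(rbind, rows)
  }

  structure(list(
    per_score = per_score,
    comparisons = comparisons,
    meta = list(
      n_records = nrow(cohort),
      provenance = attr(cohort, "provenance"),
      mt_threshold = mt_threshold,
      ais_severe_threshold = ais_severe_threshold,
      exclusions = as.list(attr(mat, "exclusions")),
      positivity_rule = "score > cut-off (strict)",
      cutoff_rule = "Youden J maximum, smallest cut-off on ties",
      ci_methods = list(auc = "DeLong, logit scale",
                        sensitivity = "Clopper-Pearson exact",
                        specificity = "Clopper-Pearson exact",
                        prevalence = "Clopper-Pearson exact",
                        ppv = "logit (Mercaldo)", npv = "logit (Mercaldo)"),
      reference = reference
    )
  ), class = "hemoscore_validation_report")
}

#' @export
print.hemoscore_validation_report <- function(x, ...) {
  cat(sprintf("<validation report> %d records (%s), MT threshold %d units\n",
              x$meta$n_records, x$meta$provenance, x$meta$mt_threshold))
  for (nm in names(x$per_score)) {
    s <- x$per_score[[nm]]
    cat(sprintf("  %-7s n=%d  AUC %.3f (%.3f-%.3f)  cut-off > %g  sens %.2f%%  spec %.2f%%\n",
                nm, s$n, s$roc$auc, s$roc$auc_ci95[1], s$roc$auc_ci95[2],
                s$roc$youden_cutoff, s$summary$sensitivity$estimate,
                s$summary$specificity$estimate))
  }
  if (!is.null(x$comparisons)) {
    cat(sprintf("  pairwise DeLong vs %s:\n", x$meta$reference))
    for (i in seq_len(nrow(x$comparisons)))
      cat(sprintf("    %-7s dAUC %+.4f  p = %.4f\n",
                  x$comparisons$score[i], x$comparisons$auc_difference[i],
                  x$comparisons$p_value[i]))
  }
  invisible(x)
}

# Flat full-precision table: one row per score, all report quantities.
report_table <- function(report) {
  rows <- lapply(names(report$per_score), function(nm) {
    s <- report$per_score[[nm]]
    d <- s$summary
    data.frame(
      score = nm, n = s$n, excluded = s$excluded,
      auc = s$roc$auc, auc_lo = s$roc$auc_ci95[1], auc_hi = s$roc$auc_ci95[2],
      cutoff = s$roc$youden_cutoff, youden_j = s$roc$youden_j,
      tp = s$confusion$tp, fp = s$confusion$fp,
      fn = s$confusion$fn, tn = s$confusion$tn,
      prevalence = d$prevalence$estimate,
      prevalence_lo = d$prevalence$ci[1], prevalence_hi = d$prevalence$ci[2],
      sensitivity = d$sensitivity$estimate,
      sensitivity_lo = d$sensitivity$ci[1], sensitivity_hi = d$sensitivity$ci[2],
      specificity = d$specificity$estimate,
      specificity_lo = d$specificity$ci[1], specificity_hi = d$specificity$ci[2],
      ppv = d$ppv$estimate, ppv_lo = d$ppv$ci[1], ppv_hi = d$ppv$ci[2],
      npv = d$npv$estimate, npv_lo = d$npv$ci[1], npv_hi = d$npv$ci[2],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Serialize a validation report
#'
#' `json` and `csv` carry full-precision values (so a round-trip loses
#' nothing); `markdown` applies the report-layer rounding conventions (AUC to
#' 3 dp, sensitivity/specificity to 2 dp, PPV/NPV/prevalence and CI bounds to
#' 1-2 dp, half-up).
#'
#' @param report a `hemoscore_validation_report`.
#' @param format one of `"json"`, `"csv"`, `"markdown"`.
#' @param path optional output file; written when supplied.
#' @return The serialized object (character for json/markdown, data.frame for
#'   csv), invisibly when written to `path`.
#' @export
render_report <- function(report, format = c("json", "csv", "markdown"),
                          path = NULL) {
  format <- match.arg(format)
  out <- switch(format,
    json = jsonlite::toJSON(list(
      table = report_table(report),
      comparisons = report$comparisons,
      meta = report$meta
    ), auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE),
    csv = report_table(report),
    markdown = markdown_report(report)
  )
  if (!is.null(path)) {
    switch(format,
      json = writeLines(as.character(out), path),
      csv = utils::write.csv(out, path, row.names = FALSE),
      markdown = writeLines(out, path))
    return(invisible(out))
  }
  out
}

markdown_report <- function(report) {
  tab <- report_table(report)
  fmt_ci <- function(lo, hi, d) sprintf("%s; %s", round_half_up(lo, d), round_half_up(hi, d))
  header <- paste0("| metric | ", paste(tab$score, collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", nrow(tab) + 1L), collapse = "|"), "|")
  row <- function(name, vals) paste0("| ", name, " | ", paste(vals, collapse = " | "), " |")
  lines <- c(
    "## Diagnostic accuracy", "", header, sep,
    row("AUC", round_half_up(tab$auc, 3)),
    row("AUC 95% CI", fmt_ci(tab$auc_lo, tab$auc_hi, 3)),
    row("Cut-off", paste0("> ", tab$cutoff)),
    row("Prevalence (%)", round_half_up(tab$prevalence, 2)),
    row("Sensitivity (%)", sprintf("%.2f", round_half_up(tab$sensitivity, 2))),
    row("Sensitivity 95% CI", fmt_ci(tab$sensitivity_lo, tab$sensitivity_hi, 1)),
    row("Specificity (%)", sprintf("%.2f", round_half_up(tab$specificity, 2))),
    row("Specificity 95% CI", fmt_ci(tab$specificity_lo, tab$specificity_hi, 1)),
    row("PPV (%)", round_half_up(tab$ppv, 1)),
    row("PPV 95% CI", fmt_ci(tab$ppv_lo, tab$ppv_hi, 1)),
    row("NPV (%)", round_half_up(tab$npv, 1)),
    row("NPV 95% CI", fmt_ci(tab$npv_lo, tab$npv_hi, 1))
  )
  if (!is.null(report$comparisons)) {
    cmp <- report$comparisons
    lines <- c(lines, "",
      sprintf("## Pairwise AUC comparison (DeLong) vs %s", report$meta$reference), "",
      "| score | dAUC | p-value |", "|---|---|---|",
      sprintf("| %s | %s | %s |", cmp$score,
              round_half_up(cmp$auc_difference, 4),
              round_half_up(cmp$p_value, 4)))
  }
  paste(lines, collapse = "\n")
}

#' Export ROC points as TSV
#'
#' @param roc a `hemoscore_roc`.
#' @param path output TSV path (columns threshold, fpr, tpr).
#' @return `path`, invisibly.
#' @export
write_roc_points <- function(roc, path) {
  stopifnot(inherits(roc, "hemoscore_roc"))
  utils::write.table(roc$points, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Overlay ROC plot for a validation report
#'
#' @param report a `hemoscore_validation_report`.
#' @param path optional image file (`.png` or `.svg`); plots to the active
#'   device when `NULL`.
#' @export
plot_roc <- function(report, path = NULL) {
  stopifnot(inherits(report, "hemoscore_validation_report"))
  if (!is.null(path)) {
    if (grepl("\\.svg$", path)) grDevices::svg(path, width = 6, height = 6)
    else grDevices::png(path, width = 600, height = 600)
    on.exit(grDevices::dev.off())
  }
  cols <- grDevices::hcl.colors(length(report$per_score), "Dark 3")
  graphics::plot(0:1, 0:1, type = "l", lty = 3, col = "grey50",
                 xlab = "1 - specificity (FPR)", ylab = "sensitivity (TPR)",
                 main = "ROC curves: massive-transfusion prediction")
  i <- 0L
  for (nm in names(report$per_score)) {
    i <- i + 1L
    p <- report$per_score[[nm]]$roc$points
    graphics::lines(p$fpr, p$tpr, type = "s", col = cols[i], lwd = 2)
  }
  graphics::legend("bottomright", bty = "n", lwd = 2, col = cols,
                   legend = sprintf("%s (AUC %.3f)", names(report$per_score),
                                    vapply(report$per_score,
                                           function(s) s$roc$auc, numeric(1))))
  invisible(report)
}
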