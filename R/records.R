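#' @importFrom stats median qbeta qlogis plogis qnorm pnorm pchisq rbinom
#'   rnorm rpois rnbinom runif setNames complete.cases wilcox.test chisq.test
#' @importFrom utils read.csv write.csv
NULL

# AIS body regions carried per record (column prefix "ais_")
AIS_REGIONS <- c("head", "face", "neck", "thorax", "abdomen", "pelvis",
                 "upper_extremity", "lower_extremity", "external")

MECHANISM_SUBTYPES <- c("car", "motorbike", "bicycle", "fall_lt3m",
                        "fall_gt3m", "pedestrian", "burn", "other")

#' Cohort column dictionary
#'
#' The fixed set of columns a trauma cohort carries, with their types.
#' Unknown extra columns in a CSV are preserved as pass-through metadata.
#' Booleans are serialized as 0/1 in CSV files.
#'
#' @return A data.frame with columns `column`, `type` (`character`,
#'   `numeric`, `integer`, `logical`) and `mandatory`.
#' @export
cohort_columns <- function() {
  ais_cols <- paste0("ais_", AIS_REGIONS)
  cols <- c(
    id = "character", age = "numeric", sex = "character",
    mechanism = "character", mechanism_subtype = "character",
    admitted_from_scene = "logical",
    sbp_initial = "numeric", sbp_ever_below_90 = "logical",
    hr = "numeric", gcs = "integer", hb = "numeric",
    base_excess = "numeric", lactate = "numeric",
    fast_positive = "logical", ct_fluid_positive = "logical",
    pelvic_fracture_displaced = "logical",
    pelvic_ring_unstable = "logical",
    femur_fracture_open_or_dislocated = "logical",
    setNames(rep("integer", length(ais_cols)), ais_cols),
    iss = "integer", niss = "integer", prbc_24h = "integer",
    los_days = "numeric", icu_days = "numeric", vent_hours = "numeric",
    died = "logical"
  )
  mandatory <- c("id", "prbc_24h", "sbp_initial", "sbp_ever_below_90", ais_cols)
  data.frame(column = names(cols), type = unname(cols),
             mandatory = names(cols) %in% mandatory,
             stringsAsFactors = FALSE)
}

logical_columns <- function() {
  d <- cohort_columns()
  d$column[d$type == "logical"]
}

#' Construct a validated trauma cohort
#'
#' Wraps a data.frame of patient records (one row per patient, columns per
#' [cohort_columns()]) as a `hemoscore_cohort`, running validation.
#'
#' @param records data.frame of patient records.
#' @param provenance one of `"read"`, `"synthetic"`, `"fixture"`.
#' @param strict logical; if `TRUE`, range violations are errors instead of
#'   warnings.
#' @return A `hemoscore_cohort` (a data.frame subclass) with a `provenance`
#'   attribute.
#' @export
as_cohort <- function(records, provenance = c("read", "synthetic", "fixture"),
                      strict = FALSE) {
  provenance <- match.arg(provenance)
  stopifnot(is.data.frame(records))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (anyDuplicated(records$id)) stop("cohort ids must be unique")
  records <- validate_records(records, strict = strict)
  structure(records,
            provenance = provenance,
            class = c("hemoscore_cohort", "data.frame"))
}

#' @export
print.hemoscore_cohort <- function(x, ...) {
  cat(sprintf("<hemoscore_cohort> %d patients (provenance: %s)\n",
              nrow(x), attr(x, "provenance")))
  if (!is.null(x$prbc_24h)) {
    mt <- sum(label_mt(x), na.rm = TRUE)
    cat(sprintf("  massive transfusion (>= 10 pRBC units / 24 h): %d (%.2f%%)\n",
                mt, 100 * mt / nrow(x)))
  }
  invisible(x)
}

# Range and consistency checks; strict = TRUE turns range violations into
# errors naming the offending row and field. ISS/AIS mismatch is always a
# warning (registries grade AIS and ISS independently).
validate_records <- function(df, strict = FALSE) {
  fail <- function(rows, field, msg) {
    txt <- sprintf("field '%s' %s (rows %s)", field, msg,
                   paste(utils::head(rows, 5L), collapse = ", "))
    if (strict) stop(txt, call. = FALSE) else warning(txt, call. = FALSE)
  }
  check_range <- function(field, lo, hi) {
    if (is.null(df[[field]])) return()
    v <- df[[field]]
    bad <- which(!is.na(v) & (v < lo | v > hi))
    if (length(bad)) fail(bad, field, sprintf("outside [%s, %s]", lo, hi))
  }
  for (r in paste0("ais_", AIS_REGIONS)) check_range(r, 0, 6)
  check_range("gcs", 3, 15)
  check_range("prbc_24h", 0, Inf)
  for (f in c("sbp_initial", "hr", "hb")) check_range(f, 0, Inf)

  # sbp_ever_below_90 must be TRUE whenever the initial SBP was < 90
  if (!is.null(df$sbp_initial) && !is.null(df$sbp_ever_below_90)) {
    bad <- which(!is.na(df$sbp_initial) & df$sbp_initial < 90 &
                   !is.na(df$sbp_ever_below_90) & !df$sbp_ever_below_90)
    if (length(bad)) {
      fail(bad, "sbp_ever_below_90", "FALSE although sbp_initial < 90; coerced to TRUE")
      if (!strict) df$sbp_ever_below_90[bad] <- TRUE
    }
  }

  # ISS consistency with AIS grades: warning only
  ais <- df[paste0("ais_", AIS_REGIONS)]
  if (!is.null(df$iss) && all(vapply(ais, is.numeric, logical(1)))) {
    ok <- stats::complete.cases(ais) & !is.na(df$iss)
    if (any(ok)) {
      expect <- apply(as.matrix(ais[ok, , drop = FALSE]), 1L, iss_from_ais)
      bad <- which(ok)[expect != df$iss[ok]]
      if (length(bad))
        warning(sprintf("iss inconsistent with AIS grades for %d record(s) (rows %s)",
                        length(bad), paste(utils::head(bad, 5L), collapse = ", ")),
                call. = FALSE)
    }
  }
  df
}

#' Injury Severity Score from AIS grades
#'
#' ISS is the sum of squares of the three highest AIS grades drawn from
#' distinct ISS body regions (head/neck, face, chest, abdomen, extremities
#' including pelvic girdle, external); any AIS of 6 sets ISS to 75 by
#' convention. NISS uses the three highest grades regardless of region.
#'
#' @param ais named numeric vector of AIS grades over
#'   `c("head","face","neck","thorax","abdomen","pelvis",
#'   "upper_extremity","lower_extremity","external")` (names optional if in
#'   that order).
#' @return Integer score.
#' @export
iss_from_ais <- function(ais) {
  ais <- as.numeric(ais)
  names(ais) <- AIS_REGIONS
  if (any(ais == 6, na.rm = TRUE)) return(75L)
  region <- c(
    max(ais[c("head", "neck")]), ais[["face"]], ais[["thorax"]],
    ais[["abdomen"]],
    max(ais[c("pelvis", "upper_extremity", "lower_extremity")]),
    ais[["external"]]
  )
  top <- sort(region, decreasing = TRUE)[1:3]
  as.integer(sum(top^2))
}

#' @rdname iss_from_ais
#' @export
niss_from_ais <- function(ais) {
  ais <- as.numeric(ais)
  if (any(ais == 6, na.rm = TRUE)) return(75L)
  top <- sort(ais, decreasing = TRUE)[1:3]
  as.integer(sum(top^2))
}

#' Label records as massive transfusion
#'
#' A patient is labelled MT when they received at least `threshold` units of
#' packed red blood cells within 24 h of emergency-room arrival (default 10).
#'
#' @param x a `hemoscore_cohort`, data.frame, or numeric vector of pRBC
#'   counts.
#' @param threshold integer number of units (>= 1).
#' @return Logical vector.
#' @export
label_mt <- function(x, threshold = 10L) {
  stopifnot(threshold >= 1)
  prbc <- if (is.data.frame(x)) x$prbc_24h else x
  if (is.null(prbc)) stop("prbc_24h is required to label massive transfusion")
  if (anyNA(prbc)) stop("prbc_24h missing for ", sum(is.na(prbc)), " record(s)")
  prbc >= threshold
}

#' Read a trauma cohort from CSV
#'
#' Reads a cohort CSV using the fixed column dictionary
#' ([cohort_columns()]). Booleans are expected as 0/1; empty cells are
#' missing values. Unknown extra columns are kept as-is. A load report
#' (records read, records dropped, per-field missingness) is attached as the
#' `"load_report"` attribute.
#'
#' @param path CSV file path.
#' @param strict logical. If `TRUE`, out-of-range values and rows missing
#'   mandatory fields are errors; otherwise rows missing mandatory fields are
#'   dropped (counted in the report) and other missing fields are kept as
#'   absent.
#' @return A `hemoscore_cohort`.
#' @export
read_cohort <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(id = "character"), check.names = FALSE)
  dict <- cohort_columns()
  missing_mand <- setdiff(dict$column[dict$mandatory], names(raw))
  if (length(missing_mand))
    stop("mandatory column(s) missing: ", paste(missing_mand, collapse = ", "))

  for (i in seq_len(nrow(dict))) {
    col <- dict$column[i]
    if (!col %in% names(raw)) { raw[[col]] <- NA; }
    raw[[col]] <- switch(dict$type[i],
      character = as.character(raw[[col]]),
      numeric   = as.numeric(raw[[col]]),
      integer   = as.integer(raw[[col]]),
      logical   = {
        v <- raw[[col]]
        if (is.logical(v)) v else as.logical(as.integer(v))
      })
  }
  n_read <- nrow(raw)

  essential <- c("id", "prbc_24h")
  drop <- !stats::complete.cases(raw[essential])
  if (any(drop) && strict)
    stop("rows missing mandatory fields: ",
         paste(which(drop), collapse = ", "))
  kept <- raw[!drop, , drop = FALSE]
  rownames(kept) <- NULL

  known <- intersect(dict$column, names(kept))
  miss <- vapply(kept[known], function(v) sum(is.na(v)), integer(1))
  cohort <- as_cohort(kept, provenance = "read", strict = strict)
  attr(cohort, "load_report") <- list(
    n_read = n_read, n_kept = nrow(kept), n_dropped = sum(drop),
    missing_per_field = as.list(miss[miss > 0])
  )
  cohort
}

#' Write a trauma cohort to CSV
#'
#' Inverse of [read_cohort()]: booleans become 0/1, missing values empty
#' cells; `read_cohort(write_cohort(x))` reproduces every populated field.
#'
#' @param cohort a `hemoscore_cohort` or compatible data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort, stringsAsFactors = FALSE)
  for (col in intersect(logical_columns(), names(df)))
    df[[col]] <- as.integer(df[[col]])
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
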