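#' Clinical massive-transfusion prediction scores
#'
#' Single-record calculators for the six shipped rubrics. All are thin
#' wrappers over [apply_score()] with the configuration from
#' [load_score_definitions()]; for whole cohorts use [score_cohort()].
#'
#' * `mticcs()` — modified Trauma-Induced Coagulopathy Clinical Score:
#'   2 points general severity (constitutive for resuscitation-room cohorts),
#'   5 points if systolic blood pressure ever fell below 90 mmHg, and
#'   1/1/1/2/2/2 points for severe injury of head-and-neck, upper extremity,
#'   lower extremity, torso, abdomen, pelvis. "Severe" means AIS at or above
#'   `ais_severe_threshold` in the mapped region(s). Range 2-16.
#' * `tash()` — Trauma-Associated Severe Hemorrhage score (0-28), with the
#'   published logistic transform to an MT probability.
#' * `abc()` — Assessment of Blood Consumption score (0-4).
#' * `larson()` — Larson / Joint Theater Trauma Registry score (0-4).
#' * `pwh()` — Prince of Wales Hospital score (0-18).
#' * `ets()` — Emergency Transfusion Score (0-9.5).
#'
#' @param record a single patient record (1-row data.frame or named list)
#'   using the [cohort_columns()] field names.
#' @param ais_severe_threshold AIS grade treated as severe (default 3).
#' @param constitutive_general_severity if `FALSE`, the 2 general-severity
#'   points are only awarded when `record$resus_admission` is `TRUE`
#'   (original TICCS behaviour for cohorts that include non-resuscitation
#'   patients).
#' @param definitions definitions list, see [load_score_definitions()].
#' @return A `hemoscore_score_result` (see [apply_score()]).
#' @examples
#' rec <- list(sbp_ever_below_90 = TRUE, ais_head = 4, ais_face = 0,
#'             ais_neck = 0, ais_thorax = 3, ais_abdomen = 0, ais_pelvis = 4,
#'             ais_upper_extremity = 0, ais_lower_extremity = 2,
#'             ais_external = 0)
#' mticcs(rec)$value  # 2 + 5 + 1 + 2 + 2 = 12
#' @name clinical_scores
NULL

#' @rdname clinical_scores
#' @export
mticcs <- function(record, ais_severe_threshold = 3L,
                   constitutive_general_severity = TRUE,
                   definitions = load_score_definitions()) {
  def <- set_mticcs_threshold(definitions$mticcs, ais_severe_threshold)
  if (!constitutive_general_severity) {
    def$criteria <- lapply(def$criteria, function(cr) {
      if (identical(cr$name, "general_severity")) {
        cr$op <- "flag"; cr$field <- "resus_admission"
      }
      cr
    })
    def$min_score <- 0
  }
  apply_score(def, record)
}

#' @rdname clinical_scores
#' @export
tash <- function(record, definitions = load_score_definitions())
  apply_score(definitions$tash, record)

#' @rdname clinical_scores
#' @export
abc <- function(record, definitions = load_score_definitions())
  apply_score(definitions$abc, record)

#' @rdname clinical_scores
#' @export
larson <- function(record, definitions = load_score_definitions())
  apply_score(definitions$larson, record)

#' @rdname clinical_scores
#' @export
pwh <- function(record, definitions = load_score_definitions())
  apply_score(definitions$pwh, record)

#' @rdname clinical_scores
#' @export
ets <- function(record, definitions = load_score_definitions())
  apply_score(definitions$ets, record)
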