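#' Load score definitions
#'
#' Reads the rubric configuration shipped with the package (or a user file of
#' the same schema): one entry per score, each a list of declarative criteria
#' (field, comparator, threshold, points). Criteria sharing a `group` tag are
#' mutually exclusive bands, listed most-severe-first; only the first
#' satisfied band awards its points. The definition is validated on load:
#' `max_score` must equal the maximum attainable total, and same-field
#' same-direction criteria must carry a group tag.
#'
#' @param path JSON file; defaults to the configuration shipped in
#'   `inst/extdata/score_definitions.json`.
#' @return Named list of `hemoscore_definition` objects.
#' @export
load_score_definitions <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "score_definitions.json",
                        package = "hemoscore", mustWork = TRUE)
  cfg <- jsonlite::read_json(path)
  defs <- lapply(names(cfg$scores), function(nm) {
    d <- cfg$scores[[nm]]
    d$name <- nm
    d <- structure(d, class = "hemoscore_definition")
    validate_definition(d)
    d
  })
  names(defs) <- names(cfg$scores)
  defs
}

validate_definition <- function(def) {
  crits <- def$criteria
  pts <- vapply(crits, function(cr) as.numeric(cr$points), numeric(1))
  if (any(!is.finite(pts)))
    stop("definition '", def$name, "': non-finite points")
  grp <- vapply(crits, function(cr) cr$group %||% NA_character_, character(1))
  # max attainable: best band per group + all ungrouped positive points
  max_attain <- sum(pts[is.na(grp)][pts[is.na(grp)] > 0])
  for (g in unique(grp[!is.na(grp)]))
    max_attain <- max_attain + max(pts[!is.na(grp) & grp == g], 0)
  if (abs(max_attain - as.numeric(def$max_score)) > 1e-9)
    stop(sprintf("definition '%s': max_score %s != attainable maximum %s",
                 def$name, def$max_score, max_attain))
  # overlapping bands (same field, same directional comparator) need a group
  key <- vapply(crits, function(cr) {
    if ((cr$op %||% "") %in% c("lt", "le", "gt", "ge"))
      paste(cr$field, substr(cr$op, 1, 1)) else NA_character_
  }, character(1))
  dup <- key[!is.na(key)][duplicated(key[!is.na(key)])]
  for (k in dup) {
    gg <- grp[!is.na(key) & key == k]
    if (anyNA(gg) || length(unique(gg)) != 1)
      stop("definition '", def$name,
           "': overlapping bands on '", k, "' without a shared group tag")
  }
  invisible(def)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hemoscore_definition <- function(x, ...) {
  cat(sprintf("<%s score definition> %d criteria, range [%s, %s]\n",
              x$label %||% x$name, length(x$criteria), x$min_score, x$max_score))
  invisible(x)
}

# Evaluate one criterion over a data.frame of records.
# Returns a logical vector; NA means the inputs needed are absent.
eval_criterion <- function(crit, data) {
  n <- nrow(data)
  get <- function(f) if (is.null(data[[f]])) rep(NA, n) else data[[f]]
  switch(crit$op,
    const = rep(TRUE, n),
    flag = as.logical(get(crit$field)),
    flag_any = {
      m <- vapply(unlist(crit$fields), function(f) as.logical(get(f)),
                  logical(n))
      m <- matrix(m, nrow = n)
      any_true <- rowSums(m, na.rm = TRUE) > 0
      all_na <- rowSums(!is.na(m)) == 0
      ifelse(all_na, NA, any_true)
    },
    lt = get(crit$field) < crit$value,
    le = get(crit$field) <= crit$value,
    gt = get(crit$field) > crit$value,
    ge = get(crit$field) >= crit$value,
    eq = get(crit$field) == crit$value,
    `in` = {
      v <- get(crit$field)
      ifelse(is.na(v), NA, v %in% unlist(crit$values))
    },
    ais_ge = {
      cols <- paste0("ais_", unlist(crit$regions))
      m <- vapply(cols, function(f) as.numeric(get(f)), numeric(n))
      m <- matrix(m, nrow = n)
      hit <- rowSums(m >= crit$value, na.rm = TRUE) > 0
      undecided <- !hit & rowSums(is.na(m)) > 0
      ifelse(undecided, NA, hit)
    },
    stop("unknown criterion op: ", crit$op)
  )
}

# Vectorized scoring of a whole data.frame against one definition.
# Returns list(value, excluded, reason, fired) where fired is an n x k
# logical matrix named by criterion.
score_with_definition <- function(def, data) {
  n <- nrow(data)
  crits <- def$criteria
  k <- length(crits)
  if (k == 0L)
    return(list(value = numeric(n), excluded = rep(FALSE, n),
                reason = rep(NA_character_, n),
                fired = matrix(logical(0), nrow = n)))
  fired <- vapply(crits, eval_criterion, logical(n), data = data)
  fired <- matrix(fired, nrow = n,
                  dimnames = list(NULL, vapply(crits, `[[`, "", "name")))
  excluded <- rowSums(is.na(fired)) > 0

  reason <- rep(NA_character_, n)
  if (any(excluded)) {
    fields_of <- lapply(crits, function(cr)
      unlist(c(cr$field, cr$fields,
               if (!is.null(cr$regions)) paste0("ais_", unlist(cr$regions)))))
    reason[excluded] <- vapply(which(excluded), function(i) {
      miss <- unique(unlist(fields_of[is.na(fired[i, ])]))
      miss <- miss[vapply(miss, function(f)
        is.null(data[[f]]) || is.na(data[[f]][i]), logical(1))]
      paste("missing:", paste(miss, collapse = ", "))
    }, character(1))
  }

  pts <- vapply(crits, function(cr) as.numeric(cr$points), numeric(1))
  grp <- vapply(crits, function(cr) cr$group %||% NA_character_, character(1))
  f0 <- fired
  f0[is.na(f0)] <- FALSE
  value <- as.numeric(f0[, is.na(grp), drop = FALSE] %*% pts[is.na(grp)])
  for (g in unique(grp[!is.na(grp)])) {
    idx <- which(!is.na(grp) & grp == g)
    open <- rep(TRUE, n)               # first satisfied band wins
    for (j in idx) {
      take <- open & f0[, j]
      value[take] <- value[take] + pts[j]
      open[take] <- FALSE
      # once a more severe band has been inspected, a less severe band may
      # still fire for other records
    }
    # band resolution: suppress later bands in the fired matrix for clarity
    won <- rep(FALSE, n)
    for (j in idx) {
      fired[won & !is.na(fired[, j]), j] <- FALSE
      won <- won | (f0[, j] & !won)
    }
  }
  value[excluded] <- NA_real_
  list(value = value, excluded = excluded, reason = reason, fired = fired)
}

#' Apply a score definition to a single patient record
#'
#' The generic rubric engine: sums the points of every satisfied criterion,
#' with mutually exclusive band groups awarding at most one band. If any
#' field a criterion needs is absent the record is excluded (the result
#' carries the reason) rather than scored incorrectly.
#'
#' @param def a `hemoscore_definition` from [load_score_definitions()].
#' @param record a single patient record (1-row data.frame or named list).
#' @return A `hemoscore_score_result`: list with `score_name`, `value`,
#'   `fired_criteria`, `probability` (when the definition carries a logistic
#'   risk transform), `excluded`, `reason`.
#' @export
apply_score <- function(def, record) {
  if (!is.data.frame(record)) record <- as.data.frame(record, stringsAsFactors = FALSE)
  stopifnot(nrow(record) == 1L)
  res <- score_with_definition(def, record)
  prob <- NA_real_
  if (!is.null(def$logistic_transform) && !res$excluded[1]) {
    lt <- def$logistic_transform
    prob <- stats::plogis(as.numeric(lt$intercept) +
                            as.numeric(lt$slope) * res$value[1])
  }
  structure(list(
    score_name = def$name,
    value = res$value[1],
    fired_criteria = colnames(res$fired)[which(res$fired[1, ])],
    probability = prob,
    excluded = res$excluded[1],
    reason = res$reason[1]
  ), class = "hemoscore_score_result")
}

#' @export
print.hemoscore_score_result <- function(x, ...) {
  if (x$excluded) {
    cat(sprintf("<%s> excluded (%s)\n", x$score_name, x$reason))
  } else {
    cat(sprintf("<%s> value %g", x$score_name, x$value))
    if (!is.na(x$probability))
      cat(sprintf(" (MT probability %.3f)", x$probability))
    cat("\n  fired:", paste(x$fired_criteria, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Score every record of a cohort against several rubrics
#'
#' @param cohort a `hemoscore_cohort` or compatible data.frame (non-empty).
#' @param scores character vector of score names (default: all shipped
#'   rubrics).
#' @param definitions definitions list from [load_score_definitions()].
#' @param ais_severe_threshold AIS grade regarded as severe for the mTICCS
#'   regional criteria (default 3, the conventional "serious" boundary).
#' @return A data.frame with `id` and one numeric column per score (`NA`
#'   where the record lacks an input that score needs), with attributes
#'   `exclusions` (named count per score) and `exclusion_reasons` (list of
#'   character vectors).
#' @export
score_cohort <- function(cohort, scores = NULL,
                         definitions = load_score_definitions(),
                         ais_severe_threshold = 3L) {
  stopifnot(nrow(cohort) > 0L)
  if (is.null(scores)) scores <- names(definitions)
  unknown <- setdiff(scores, names(definitions))
  if (length(unknown)) stop("unknown score(s): ", paste(unknown, collapse = ", "))
  out <- data.frame(id = cohort$id %||% as.character(seq_len(nrow(cohort))),
                    stringsAsFactors = FALSE)
  exclusions <- integer(0)
  reasons <- list()
  for (nm in scores) {
    def <- definitions[[nm]]
    if (nm == "mticcs") def <- set_mticcs_threshold(def, ais_severe_threshold)
    res <- score_with_definition(def, cohort)
    out[[nm]] <- res$value
    exclusions[nm] <- sum(res$excluded)
    reasons[[nm]] <- res$reason[res$excluded]
  }
  attr(out, "exclusions") <- exclusions
  attr(out, "exclusion_reasons") <- reasons
  out
}

set_mticcs_threshold <- function(def, threshold) {
  def$criteria <- lapply(def$criteria, function(cr) {
    if (identical(cr$op, "ais_ge")) cr$value <- threshold
    cr
  })
  def
}
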