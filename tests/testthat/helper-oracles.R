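# Record builder with clinically unremarkable defaults; override any field.
make_record <- function(...) {
  rec <- list(
    id = "R1", age = 40, sex = "male", mechanism = "blunt",
    mechanism_subtype = "car", admitted_from_scene = TRUE,
    sbp_initial = 130, sbp_ever_below_90 = FALSE, hr = 80, gcs = 15L,
    hb = 14, base_excess = 0, lactate = 1.2, fast_positive = FALSE,
    ct_fluid_positive = FALSE, pelvic_fracture_displaced = FALSE,
    pelvic_ring_unstable = FALSE, femur_fracture_open_or_dislocated = FALSE,
    ais_head = 0L, ais_face = 0L, ais_neck = 0L, ais_thorax = 0L,
    ais_abdomen = 0L, ais_pelvis = 0L, ais_upper_extremity = 0L,
    ais_lower_extremity = 0L, ais_external = 0L,
    iss = 0L, niss = 0L, prbc_24h = 0L,
    los_days = 5, icu_days = 1, vent_hours = 0, died = FALSE
  )
  over <- list(...)
  rec[names(over)] <- over
  as.data.frame(rec, stringsAsFactors = FALSE)
}

# Small cohort of hand-set records (bypasses the generator)
make_cohort <- function(n = 6, prbc = NULL) {
  rows <- lapply(seq_len(n), function(i)
    make_record(id = sprintf("R%03d", i),
                prbc_24h = if (is.null(prbc)) (i - 1L) * 3L else prbc[i],
                ais_external = 4L, iss = 16L, niss = 16L))
  as_cohort(do.call(rbind, rows))
}

# Brute-force Mann-Whitney AUC: enumerate every positive x negative pair.
brute_auc <- function(scores, labels) {
  x <- scores[as.logical(labels)]
  y <- scores[!as.logical(labels)]
  mean(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Exhaustive Youden search over observed score values, smallest c on ties.
brute_youden <- function(scores, labels) {
  labels <- as.logical(labels)
  thr <- sort(unique(scores))
  j <- sapply(thr, function(c)
    mean(scores[labels] > c) - mean(scores[!labels] > c))
  list(cutoff = thr[which.max(j)], j = max(j))
}

# Random ROC instance with ties and both classes present
random_roc_instance <- function(max_n = 20) {
  repeat {
    n <- sample(4:max_n, 1)
    scores <- sample(0:10, n, replace = TRUE) / 2
    labels <- runif(n) < 0.4
    if (any(labels) && !all(labels)) return(list(scores = scores, labels = labels))
  }
}

# Independent per-record scorer: re-evaluates each criterion on its own and
# combines points, without going through the vectorized engine.
brute_score <- function(def, record) {
  val <- 0
  groups_done <- character(0)
  for (cr in def$criteria) {
    g <- if (is.null(cr$group)) NA_character_ else cr$group
    if (!is.na(g) && g %in% groups_done) next
    sat <- switch(cr$op,
      const = TRUE,
      flag = isTRUE(record[[cr$field]]),
      flag_any = any(vapply(unlist(cr$fields),
                            function(f) isTRUE(record[[f]]), logical(1))),
      lt = !is.na(record[[cr$field]]) && record[[cr$field]] < cr$value,
      le = !is.na(record[[cr$field]]) && record[[cr$field]] <= cr$value,
      gt = !is.na(record[[cr$field]]) && record[[cr$field]] > cr$value,
      ge = !is.na(record[[cr$field]]) && record[[cr$field]] >= cr$value,
      eq = identical(as.character(record[[cr$field]]), as.character(cr$value)),
      `in` = as.character(record[[cr$field]]) %in% unlist(cr$values),
      ais_ge = any(vapply(unlist(cr$regions), function(r)
        !is.na(record[[paste0("ais_", r)]]) &&
          record[[paste0("ais_", r)]] >= cr$value, logical(1)))
    )
    if (isTRUE(sat)) {
      val <- val + cr$points
      if (!is.na(g)) groups_done <- c(groups_done, g)
    }
  }
  val
}

# Random fully populated record for engine property tests
random_record <- function() {
  make_record(
    age = sample(16:95, 1),
    sex = sample(c("male", "female"), 1),
    mechanism = sample(c("blunt", "penetrating"), 1, prob = c(.9, .1)),
    mechanism_subtype = sample(c("car", "motorbike", "bicycle", "fall_lt3m",
                                 "fall_gt3m", "pedestrian", "burn", "other"), 1),
    admitted_from_scene = runif(1) < .9,
    sbp_initial = sample(50:180, 1),
    sbp_ever_below_90 = runif(1) < .3,
    hr = sample(40:180, 1), gcs = sample(3:15, 1),
    hb = round(runif(1, 4, 17), 1), base_excess = round(runif(1, -15, 4), 1),
    fast_positive = runif(1) < .3, ct_fluid_positive = runif(1) < .3,
    pelvic_fracture_displaced = runif(1) < .2,
    pelvic_ring_unstable = runif(1) < .15,
    femur_fracture_open_or_dislocated = runif(1) < .15,
    ais_head = sample(0:5, 1), ais_face = sample(0:3, 1),
    ais_neck = sample(0:4, 1), ais_thorax = sample(0:5, 1),
    ais_abdomen = sample(0:5, 1), ais_pelvis = sample(0:5, 1),
    ais_upper_extremity = sample(0:4, 1), ais_lower_extremity = sample(0:5, 1),
    ais_external = sample(0:2, 1)
  )
}

fix_iss <- function(rec) {
  ais <- unlist(rec[paste0("ais_", c("head", "face", "neck", "thorax",
                                     "abdomen", "pelvis", "upper_extremity",
                                     "lower_extremity", "external"))])
  rec$iss <- iss_from_ais(ais)
  rec$niss <- niss_from_ais(ais)
  rec
}
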