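defs <- load_score_definitions()

test_that("rubric engine: additivity, empty definition, band exclusivity", {
  empty <- structure(list(name = "empty", criteria = list(),
                          min_score = 0, max_score = 0),
                     class = "hemoscore_definition")
  expect_equal(apply_score(empty, make_record())$value, 0)

  two <- structure(list(name = "two", min_score = 0, max_score = 7, criteria = list(
    list(name = "a", op = "ge", field = "hr", value = 100, points = 2),
    list(name = "b", op = "flag", field = "fast_positive", points = 5)
  )), class = "hemoscore_definition")
  res <- apply_score(two, make_record(hr = 120, fast_positive = TRUE))
  expect_equal(res$value, 7)
  expect_setequal(res$fired_criteria, c("a", "b"))

  # hb bands: exactly one band of the TASH hb group fires
  r <- apply_score(defs$tash, make_record(hb = 6.5))
  expect_equal(sum(grepl("^hb_", r$fired_criteria)), 1)
  expect_true("hb_lt_7" %in% r$fired_criteria)
  r2 <- apply_score(defs$tash, make_record(hb = 10.5))
  expect_true("hb_lt_11" %in% r2$fired_criteria)
})

test_that("malformed definitions are rejected on load", {
  bad <- structure(list(name = "bad", min_score = 0, max_score = 3, criteria = list(
    list(name = "a", op = "lt", field = "hb", value = 10, points = 1),
    list(name = "b", op = "lt", field = "hb", value = 12, points = 2)
  )), class = "hemoscore_definition")
  expect_error(hemoscore:::validate_definition(bad), "overlapping bands")
  bad2 <- structure(list(name = "bad2", min_score = 0, max_score = 5,
                         criteria = list(list(name = "a", op = "flag",
                                              field = "fast_positive", points = 1))),
                    class = "hemoscore_definition")
  expect_error(hemoscore:::validate_definition(bad2), "max_score")
})

test_that("engine value matches independent per-criterion re-evaluation", {
  set.seed(401)
  for (i in 1:1000) {
    rec <- random_record()
    nm <- sample(names(defs), 1)
    res <- apply_score(defs[[nm]], rec)
    expect_false(res$excluded)
    expect_equal(res$value, brute_score(defs[[nm]], rec),
                 label = sprintf("%s on record %d", nm, i))
  }
})

test_that("scores stay within their declared ranges", {
  set.seed(402)
  for (i in 1:200) {
    rec <- random_record()
    for (nm in names(defs)) {
      v <- apply_score(defs[[nm]], rec)$value
      expect_gte(v, defs[[nm]]$min_score)
      expect_lte(v, defs[[nm]]$max_score)
    }
  }
})

test_that("raising an input past a criterion threshold never lowers a score", {
  set.seed(403)
  bump <- list(  # field, value satisfying the most severe band, per score
    tash = list(c("sbp_initial", 80), c("hb", 6), c("hr", 130),
                c("base_excess", -12)),
    abc = list(c("sbp_initial", 85), c("hr", 125)),
    larson = list(c("hr", 110), c("sbp_initial", 100), c("hb", 10),
                  c("base_excess", -7)),
    pwh = list(c("hr", 125), c("sbp_initial", 88), c("gcs", 7), c("hb", 6.8),
               c("base_excess", -6)),
    ets = list(c("sbp_initial", 85), c("age", 70))
  )
  for (nm in names(bump)) for (fv in bump[[nm]]) {
    for (i in 1:20) {
      rec <- random_record()
      before <- apply_score(defs[[nm]], rec)$value
      rec[[fv[1]]] <- as.numeric(fv[2])
      after <- apply_score(defs[[nm]], rec)$value
      expect_gte(after, before)
    }
  }
})

test_that("mTICCS: bounds, regional points, and threshold configurability", {
  # maximum: hypotension plus severe injury in all six regions
  maxrec <- make_record(sbp_ever_below_90 = TRUE, ais_head = 4L,
                        ais_thorax = 4L, ais_abdomen = 3L, ais_pelvis = 4L,
                        ais_upper_extremity = 3L, ais_lower_extremity = 3L)
  expect_equal(mticcs(maxrec)$value, 16)
  # minimum: only the constitutive general-severity points
  expect_equal(mticcs(make_record())$value, 2)
  # hypotension + severe pelvis only: 2 + 5 + 2
  expect_equal(mticcs(make_record(sbp_ever_below_90 = TRUE,
                                  ais_pelvis = 3L))$value, 9)
  # head OR neck maps to the same region criterion (no double counting)
  expect_equal(mticcs(make_record(ais_head = 3L, ais_neck = 4L))$value, 3)
  # face and external injuries never contribute
  expect_equal(mticcs(make_record(ais_face = 3L, ais_external = 5L))$value, 2)
  # severity threshold is configurable
  rec <- make_record(ais_thorax = 2L)
  expect_equal(mticcs(rec)$value, 2)
  expect_equal(mticcs(rec, ais_severe_threshold = 2L)$value, 4)
  # original 0/2 behaviour for non-resuscitation patients
  rec$resus_admission <- FALSE
  expect_equal(mticcs(rec, constitutive_general_severity = FALSE)$value, 0)
  # always within [2, 16] under defaults
  set.seed(404)
  v <- replicate(200, mticcs(random_record())$value)
  expect_true(all(v >= 2 & v <= 16))
})

test_that("ABC counts its four components; PWH empty sum is zero", {
  allpos <- make_record(mechanism = "penetrating", sbp_initial = 90,
                        hr = 120, fast_positive = TRUE)
  expect_equal(abc(allpos)$value, 4)
  expect_equal(abc(make_record())$value, 0)
  expect_equal(pwh(make_record())$value, 0)
})

test_that("Larson increases when heart rate crosses its threshold", {
  rec <- make_record(hr = 100)
  lo <- larson(rec)$value
  rec$hr <- 106
  expect_gt(larson(rec)$value, lo)
})

test_that("TASH logistic transform is increasing; value at 16 is ~0.475", {
  recs <- list(make_record(),                       # 1 point (male)
               make_record(hb = 10.5, sbp_initial = 110),  # more points
               make_record(hb = 6, sbp_initial = 80, hr = 130,
                           base_excess = -12, fast_positive = TRUE,
                           pelvic_ring_unstable = TRUE))
  probs <- vapply(recs, function(r) tash(r)$probability, numeric(1))
  vals <- vapply(recs, function(r) tash(r)$value, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_true(all(diff(probs) > 0))
  # published coefficients give p = 1/(1+exp(4.9 - 0.3*16)) just below 0.5
  expect_equal(plogis(-4.9 + 0.3 * 16), 0.47502, tolerance = 1e-4)
  expect_equal(plogis(-4.9 + 0.3 * 28), 0.9707, tolerance = 1e-3)
})

test_that("score_cohort: shape, exclusion mask, constant inputs", {
  co <- make_cohort(1)
  m <- score_cohort(co)
  expect_equal(dim(m), c(1L, 7L))  # id + six scores

  # missing hb excludes TASH/Larson/PWH but not mTICCS/ABC/ETS
  rec <- make_record(hb = NA, ais_external = 4L, iss = 16L, niss = 16L)
  m2 <- score_cohort(as_cohort(rec))
  expect_true(all(is.na(m2[c("tash", "larson", "pwh")])))
  expect_false(anyNA(m2[c("mticcs", "abc", "ets")]))
  expect_equal(unname(attr(m2, "exclusions")[c("tash", "larson", "pwh")]),
               c(1L, 1L, 1L))
  expect_match(attr(m2, "exclusion_reasons")$tash, "hb")

  # all-identical records give constant columns
  co3 <- make_cohort(4, prbc = rep(0L, 4))
  m3 <- score_cohort(co3)
  for (nm in names(defs)) expect_length(unique(m3[[nm]]), 1)
})

test_that("single-record result carries exclusion reason", {
  rec <- make_record(base_excess = NA)
  res <- tash(rec)
  expect_true(res$excluded)
  expect_match(res$reason, "base_excess")
  expect_true(is.na(res$value))
})
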