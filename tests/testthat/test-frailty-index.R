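test_that("frailty_model validates its inputs", {
  expect_error(
    frailty_model(0, 0, race = c(White = 0),
                  indicators = c(dementia = 1)),
    "missing indicator coefficient")
  expect_error(
    frailty_model(0, 0, race = c(White = 0),
                  indicators = stats::setNames(rep(0, 20),
                                               frailty_indicators()),
                  removable_screening = "not_an_indicator"),
    "subset of frailty_indicators")
})

test_that("frailty model YAML round-trip preserves coefficients", {
  m <- default_frailty_model()
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(intercept = m$intercept,
                        age_per_year = m$age_per_year,
                        race = as.list(m$race),
                        indicators = as.list(m$indicators),
                        model_id = "roundtrip"), path)
  back <- read_frailty_model(path)
  expect_equal(back$intercept, m$intercept)
  expect_equal(back$indicators, m$indicators)
  expect_equal(back$race, m$race)
})

test_that("frailty_score follows the logistic closed form", {
  # all-zero model, intercept 0: score is exactly 0.5
  s0 <- frailty_score(mk_iv(flags = c("dementia", "wheelchair")),
                      zero_model())
  expect_equal(s0$score, 0.5)

  # hand-computed linear predictor under the default model
  m <- default_frailty_model()
  iv <- mk_iv(age = 72, race = "Black", flags = c("dementia", "ambulance"))
  eta <- m$intercept + m$age_per_year * (72 - 65) + m$race[["Black"]] +
    m$indicators[["dementia"]] + m$indicators[["ambulance"]]
  expect_equal(frailty_score(iv, m)$score, plogis(eta))
  expect_equal(frailty_score(iv, m)$model_id, m$model_id)

  # scores are strictly inside (0, 1) even with every flag set
  iv_all <- mk_iv(age = 95, flags = frailty_indicators())
  s <- frailty_score(iv_all, m)$score
  expect_true(s > 0 && s < 1)
})

test_that("deficit flags raise and screening flags lower the score", {
  m <- default_frailty_model()
  base <- frailty_score(mk_iv(), m)$score
  expect_gt(frailty_score(mk_iv(flags = "dementia"), m)$score, base)
  expect_lt(frailty_score(mk_iv(flags = "cancer_screening"), m)$score, base)
  # one more year of age raises the score
  expect_gt(frailty_score(mk_iv(age = 71), m)$score,
            frailty_score(mk_iv(age = 70), m)$score)
})

test_that("unknown race is scored at the reference level with a warning", {
  m <- default_frailty_model()
  expect_warning(s <- frailty_score(mk_iv(race = "unknown"), m),
                 "reference level")
  expect_equal(s$score,
               suppressWarnings(frailty_score(mk_iv(race = "White"),
                                              m)$score))
})

test_that("extract_indicators applies binary semantics on the window", {
  a <- d("2010-06-01")
  persons <- mk_persons("A")
  claims <- mk_claims(
    rep("A", 5),
    c(a - 1, a, a - 180, a - 181, a - 10),
    c("dementia", "wheelchair", "ambulance", "vertigo", "dementia"))
  iv <- extract_indicators(claims, persons, tibble::tibble(person_id = "A",
                                                           anchor = a))
  expect_equal(iv$dementia, 1L)      # two in-window claims still flag once
  expect_equal(iv$wheelchair, 0L)    # anchor-day claim excluded
  expect_equal(iv$ambulance, 1L)     # day -180 included
  expect_equal(iv$vertigo, 0L)       # day -181 excluded
  expect_equal(iv$age_at_anchor, 2010L - 1940L)
  expect_equal(sum(dplyr::select(iv, dplyr::all_of(frailty_indicators()))),
               2L)
})

test_that("scoring is invariant to claim duplication and reordering", {
  set.seed(21)
  persons <- mk_persons(sprintf("A%02d", 1:8))
  claims <- mk_claims(
    sample(persons$person_id, 60, replace = TRUE),
    d("2010-06-01") - sample(0:220, 60, replace = TRUE),
    sample(frailty_indicators(), 60, replace = TRUE))
  anchors <- tibble::tibble(person_id = persons$person_id,
                            anchor = d("2010-06-01"))
  score <- function(cl) {
    dplyr::arrange(frailty_score(extract_indicators(cl, persons, anchors)),
                   person_id)
  }
  base <- score(claims)
  shuffled <- claims[sample(nrow(claims)), ]
  duplicated <- dplyr::bind_rows(claims, claims[sample(nrow(claims), 20), ])
  expect_equal(score(shuffled), base)
  expect_equal(score(duplicated), base)
})

test_that("score_series truncates at death and coverage end (suffix only)", {
  persons <- mk_persons(c("A", "B", "C"), death = d(c(NA, "2010-04-10", NA)))
  # A fully covered; B dies ~day 99; C's FFS coverage ends at day 70
  enrollment <- mk_enroll(c("A", "B", "C"), "2008-01-01",
                          c("2012-12-31", "2010-04-10", "2010-03-12"))
  t0 <- tibble::tibble(person_id = c("A", "B", "C"), t0 = d("2010-01-01"))
  ser <- score_series(empty_claims(), persons, enrollment, t0,
                      model = zero_model())
  expect_equal(sum(ser$person_id == "A"), 13L)
  # B observed at anchors strictly before death: days 0, 30, 60, 90
  expect_equal(ser$anchor_index[ser$person_id == "B"], 0:3)
  # C covered through day 70: anchors 0, 30, 60
  expect_equal(ser$anchor_index[ser$person_id == "C"], 0:2)
  # with no claims and a zero model every score is exactly 0.5
  expect_true(all(ser$score == 0.5))
})

test_that("apply_sensitivity zeroes screening terms and is idempotent", {
  m <- default_frailty_model()
  ms <- apply_sensitivity(m)
  expect_equal(unname(ms$indicators[c("cancer_screening",
                                      "lipid_abnormality")]), c(0, 0))
  expect_equal(apply_sensitivity(ms), ms)  # idempotent
  expect_match(ms$model_id, "-noscreen$")
  expect_error(apply_sensitivity(m, "nope"), "unknown indicator")
  # screening flags no longer move the score; deficit flags still do
  expect_equal(frailty_score(mk_iv(flags = "cancer_screening"), ms)$score,
               frailty_score(mk_iv(), ms)$score)
  expect_gt(frailty_score(mk_iv(flags = "dementia"), ms)$score,
            frailty_score(mk_iv(), ms)$score)
})

test_that("indicator_prevalence matches exact flag fractions", {
  ids <- sprintf("A%02d", 1:10)
  persons <- mk_persons(ids)
  index <- d("2010-06-01")
  # dementia claims in-window for exactly 3 persons; flu for 2 at T2 only
  claims <- dplyr::bind_rows(
    mk_claims(ids[1:3], index - 30, "dementia"),
    mk_claims(ids[4:5], index + 100, "ambulance"))
  cohort <- tibble::tibble(person_id = ids, index_date = index)
  # most indicators have no claims at all here; the coverage warning is
  # expected and not under test
  prev <- suppressWarnings(
    indicator_prevalence(cohort, c(T1 = 0L, T2 = 120L), claims, persons))
  expect_equal(prev$T1[prev$indicator == "dementia"], 0.3)
  expect_equal(prev$T2[prev$indicator == "dementia"], 0.3)
  expect_equal(prev$T1[prev$indicator == "ambulance"], 0)
  expect_equal(prev$T2[prev$indicator == "ambulance"], 0.2)
  # restricting the observed set changes the denominator
  obs <- tibble::tibble(person_id = ids[1:5],
                        anchor_name = "T1")
  prev2 <- suppressWarnings(
    indicator_prevalence(cohort, c(T1 = 0L), claims, persons,
                         observed = obs))
  expect_equal(prev2$T1[prev2$indicator == "dementia"], 0.6)
})
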