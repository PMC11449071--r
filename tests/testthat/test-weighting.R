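# Minimal cohort for propensity / SMR tests: one factor covariate.
ps_cohort <- function(n_per_cell) {
  # cells: (arm, x) with chosen counts -> known propensities per x level
  cells <- expand.grid(arm = c("chemo", "comparator"), x = c("a", "b"),
                       stringsAsFactors = FALSE)
  rows <- rep(seq_len(nrow(cells)), n_per_cell)
  tibble::tibble(person_id = sprintf("S%04d", seq_along(rows)),
                 arm = cells$arm[rows], x = factor(cells$x[rows]))
}

test_that("a saturated propensity model recovers exact cell propensities", {
  # P(chemo | x=a) = 30/(30+60) = 1/3 ; P(chemo | x=b) = 40/(40+10) = 4/5
  cohort <- ps_cohort(c(30, 60, 40, 10))
  fit <- fit_propensity(cohort, covariates = "x")
  expect_equal(unname(fit$ps[cohort$x == "a"]), rep(1 / 3, 90),
               tolerance = 1e-8)
  expect_equal(unname(fit$ps[cohort$x == "b"]), rep(4 / 5, 50),
               tolerance = 1e-8)
})

test_that("fit_propensity drops constants and rejects degenerate input", {
  cohort <- ps_cohort(c(30, 60, 40, 10))
  cohort$z <- 1
  expect_warning(fit <- fit_propensity(cohort, covariates = c("x", "z")),
                 "constant covariate")
  expect_equal(fit$covariates, "x")
  expect_error(fit_propensity(dplyr::filter(cohort, arm == "chemo"),
                              covariates = "x"),
               "both arms")
  # x perfectly separates the arms
  sep <- tibble::tibble(arm = rep(c("chemo", "comparator"), each = 20),
                        x = rep(c("a", "b"), each = 20))
  expect_error(suppressWarnings(fit_propensity(sep, covariates = "x")),
               "separation")
})

test_that("smr_weights are the propensity odds with capped truncation", {
  cohort <- ps_cohort(c(30, 60, 40, 10))
  fit <- fit_propensity(cohort, covariates = "x")
  w <- smr_weights(fit, cohort, truncate_pct = 1)
  expect_true(all(w$smr_weight[w$arm == "chemo"] == 1))
  # odds: ps .5 -> 1, ps .75 -> 3; here 1/3 -> 0.5 and 4/5 -> 4
  expect_equal(unique(round(w$smr_weight[w$arm == "comparator" &
                                           w$x == "a"], 8)), 0.5)
  expect_equal(unique(round(w$smr_weight[w$arm == "comparator" &
                                           w$x == "b"], 8)), 4)
  # truncation caps at the comparator quantile and never raises the max
  wt <- smr_weights(fit, cohort, truncate_pct = 0.8)
  cap <- quantile(w$smr_weight[w$arm == "comparator"], 0.8, names = FALSE)
  expect_equal(max(wt$smr_weight[wt$arm == "comparator"]), cap)
  tr <- attr(wt, "truncation")
  expect_lte(tr[["post_max"]], tr[["pre_max"]])
})

test_that("saturated SMR weighting balances comparator means exactly", {
  set.seed(31)
  n <- 400
  x <- factor(sample(c("a", "b", "c"), n, replace = TRUE))
  # arm drawn with x-dependent probability so the groups are imbalanced
  p <- c(a = 0.25, b = 0.65, c = 0.45)[as.character(x)]
  cohort <- tibble::tibble(
    person_id = sprintf("S%04d", 1:n), x = x,
    arm = ifelse(runif(n) < p, "chemo", "comparator"))
  fit <- fit_propensity(cohort, covariates = "x")
  w <- smr_weights(fit, cohort, truncate_pct = 1)
  X <- model.matrix(~ 0 + x, data = cohort)
  chemo <- cohort$arm == "chemo"
  for (j in seq_len(ncol(X))) {
    m_chemo <- mean(X[chemo, j])
    m_comp_w <- sum(w$smr_weight[!chemo] * X[!chemo, j]) /
      sum(w$smr_weight[!chemo])
    expect_lt(abs(m_chemo - m_comp_w), 1e-10)
  }
})

test_that("balance_table computes standardized differences as documented", {
  cohort <- tibble::tibble(
    person_id = sprintf("S%02d", 1:8),
    arm = rep(c("chemo", "comparator"), each = 4),
    age = c(70, 72, 74, 76, 66, 68, 70, 72),
    smr_weight = c(1, 1, 1, 1, 1, 1, 1, 3))
  tab <- balance_table(cohort, covariates = "age")
  s <- sqrt((var(c(70, 72, 74, 76)) + var(c(66, 68, 70, 72))) / 2)
  expect_equal(tab$smd_unweighted, (73 - 69) / s)
  m0w <- sum(c(1, 1, 1, 3) * c(66, 68, 70, 72)) / 6
  expect_equal(tab$smd_weighted, (73 - m0w) / s)
})

# --- attrition panel and IPAW ------------------------------------------------

# 20 persons, no deaths: 5 disenroll in period 1, 4 in period 2, 11 complete
attrition_bundle <- function() {
  ids <- sprintf("A%02d", 1:20)
  idx <- d("2010-01-01")
  end <- rep(idx + 400L, 20)
  end[1:5] <- idx + 60L    # coverage ends inside (T1, T2]
  end[6:9] <- idx + 200L   # coverage ends inside (T2, T3]
  bundle <- list(persons = mk_persons(ids),
                 enrollment = mk_enroll(ids, rep(d("2009-01-01"), 20), end),
                 claims = empty_claims())
  cohort <- tibble::tibble(person_id = ids, index_date = idx)
  list(bundle = bundle, cohort = cohort)
}

test_that("build_attrition_panel flags events in the right periods", {
  ab <- attrition_bundle()
  panel <- build_attrition_panel(ab$cohort, ab$bundle)
  p1 <- dplyr::filter(panel, period == 1)
  p2 <- dplyr::filter(panel, period == 2)
  expect_equal(nrow(p1), 20L)              # everyone at risk in period 1
  expect_equal(sum(p1$disenroll), 5L)
  expect_equal(nrow(p2), 15L)              # survivors of period 1
  expect_equal(sum(p2$disenroll), 4L)
  expect_equal(sum(panel$death), 0L)
  # deaths: replace one disenrollment with a death inside period 1
  b2 <- ab$bundle
  b2$persons$death_date[1] <- d("2010-01-01") + 60L
  panel2 <- build_attrition_panel(ab$cohort, b2)
  expect_equal(sum(panel2$death), 1L)
  expect_equal(sum(panel2$disenroll), 8L)
})

test_that("intercept-only attrition models reproduce empirical retention", {
  ab <- attrition_bundle()
  panel <- build_attrition_panel(ab$cohort, ab$bundle)
  expect_warning(fits <- fit_attrition_models(panel,
                                              covariates = character()),
                 "no death events")
  ret <- fits$retention
  # per-period retention equals the empirical survivor fraction
  expect_equal(unique(ret$p_death_free), 1)
  expect_equal(unique(ret$p_disenroll_free[ret$period == 1]), 15 / 20,
               tolerance = 1e-8)
  expect_equal(unique(ret$p_disenroll_free[ret$period == 2]), 11 / 15,
               tolerance = 1e-8)
})

test_that("ipaw_weights invert cumulative retention with T1 fixed at 1", {
  # closed form: retention 0.8 in both periods -> T3 weight 1 / 0.8^2
  fits <- structure(list(retention = tibble::tibble(
    person_id = rep(c("A", "B"), each = 2), period = rep(1:2, 2),
    p_death_free = 1, p_disenroll_free = 0.8)), class = "attrition_fits")
  w <- ipaw_weights(fits, truncate_pct = 1)
  expect_equal(w$ipaw_weight[w$timepoint == 1], c(1, 1))
  expect_equal(w$ipaw_weight[w$timepoint == 2], c(1.25, 1.25))
  expect_equal(w$ipaw_weight[w$timepoint == 3], c(1.5625, 1.5625))
  # zero retention cannot be inverted
  bad <- structure(list(retention = tibble::tibble(
    person_id = "A", period = 1, p_death_free = 0, p_disenroll_free = 1)),
    class = "attrition_fits")
  expect_error(ipaw_weights(bad), "cannot be inverted")
  # truncation never raises any weight
  fits2 <- structure(list(retention = tibble::tibble(
    person_id = sprintf("A%02d", rep(1:10, each = 2)), period = rep(1:2, 10),
    p_death_free = 1,
    p_disenroll_free = rep(seq(0.5, 0.95, length.out = 10), each = 2))),
    class = "attrition_fits")
  w_full <- ipaw_weights(fits2, truncate_pct = 1)
  w_trunc <- ipaw_weights(fits2, truncate_pct = 0.9)
  expect_true(all(w_trunc$ipaw_weight <= w_full$ipaw_weight + 1e-12))
  expect_lt(max(w_trunc$ipaw_weight), max(w_full$ipaw_weight))
})
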