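# A bundle of hand-built cancer cases exercising each eligibility rule.
eligibility_bundle <- function() {
  ids <- sprintf("K%d", 1:8)
  persons <- mk_persons(ids, birth_year = c(1940L, 1946L, rep(1940L, 6)))
  # diagnosis 2010-01-01 throughout; surgery/chemo gaps vary per case
  cancer <- mk_cancer(
    ids,
    dx = rep("2010-01-01", 8),
    surgery = c("2010-02-01",   # K1 eligible
                "2010-02-01",   # K2 too young (age 64 at diagnosis)
                "2010-02-01",   # K3 stage other
                "2010-04-01",   # K4 surgery on day 90 (boundary, eligible)
                "2010-04-02",   # K5 surgery on day 91 (excluded)
                "2010-02-01",   # K6 neoadjuvant
                "2010-02-01",   # K7 chemo on day 91 after surgery (excluded)
                "2010-02-01"),  # K8 enrollment too short
    chemo = c("2010-03-01", "2010-03-01", "2010-03-01", "2010-06-30",
              "2010-05-01", "2010-03-01", "2010-05-03", "2010-03-01"))
  cancer$stage[3] <- "other"
  cancer$neoadjuvant_flag[6] <- TRUE
  # K4: chemo exactly 90 days after surgery (2010-04-01 + 90 = 2010-06-30)
  enr_start <- rep(d("2008-01-01"), 8)
  enr_start[8] <- d("2010-02-15")  # starts after diagnosis: rule fails
  enrollment <- mk_enroll(ids, enr_start, rep(d("2012-12-31"), 8))
  list(persons = persons, enrollment = enrollment, claims = empty_claims(),
       cancer = cancer)
}

test_that("build_chemo_cohort applies each rule with correct boundaries", {
  built <- build_chemo_cohort(eligibility_bundle())
  expect_setequal(built$cohort$person_id, c("K1", "K4"))
  led <- built$ledger
  expect_equal(led$n_remaining[led$criterion == "cancer cases"], 8L)
  expect_equal(led$n_removed[led$criterion == "age >= 65 at diagnosis"], 1L)
  expect_equal(led$n_removed[led$criterion == "stage I-III"], 1L)
  expect_equal(
    led$n_removed[led$criterion == "surgery within 90 days of diagnosis"], 1L)
  expect_equal(led$n_removed[led$criterion == "no neoadjuvant chemotherapy"],
               1L)
  expect_equal(
    led$n_removed[led$criterion == "chemotherapy within 90 days of surgery"],
    1L)
  expect_equal(led$n_removed[led$criterion == "continuous FFS enrollment"],
               1L)
  expect_equal(dplyr::last(led$n_remaining), 2L)
  # index date is chemotherapy initiation
  expect_equal(built$cohort$index_date,
               d(c("2010-03-01", "2010-06-30")))
  expect_true(all(built$cohort$arm == "chemo"))
})

test_that("gagne_score sums weights, once per condition, cancer excluded", {
  a <- d("2010-06-01")
  anchors <- tibble::tibble(person_id = c("A", "B"), anchor = a)
  claims <- mk_claims(
    c("A", "A", "A", "A", "B"),
    c(a - 10, a - 20, a - 30, a - 40, a - 10),
    c("chf", "chf", "hypertension", "metastatic_cancer", "copd"))
  g <- gagne_score(claims, anchors)
  w <- default_gagne_weights()
  # A: chf (once despite two claims) + hypertension; metastatic excluded
  expect_equal(g$gagne_score, c(w[["chf"]] + w[["hypertension"]],
                                w[["copd"]]))
  # out-of-window claims contribute nothing
  g2 <- gagne_score(mk_claims("A", a - 200, "chf"), anchors)
  expect_equal(g2$gagne_score, c(0, 0))
})

test_that("flu_vaccine_flag respects the half-open window", {
  a <- d("2010-06-01")
  anchors <- tibble::tibble(person_id = sprintf("A%d", 1:4), anchor = a)
  claims <- mk_claims(sprintf("A%d", 1:4),
                      c(a - 180, a - 1, a, a - 181),
                      rep("flu_vaccine", 4))
  expect_equal(flu_vaccine_flag(claims, anchors)$flu_vaccine,
               c(TRUE, TRUE, FALSE, FALSE))
})

test_that("match_comparators matches exactly with replacement across groups", {
  # two cases in the same (birth year, region) stratum, one in another
  cases <- mk_persons(c("C1", "C2", "C3"),
                      birth_year = c(1940L, 1940L, 1935L),
                      region = c("West", "West", "South"))
  pool <- mk_persons(c("P1", "P2", "P3", "P4"),
                     birth_year = c(1940L, 1940L, 1935L, 1950L),
                     region = c("West", "West", "South", "West"))
  persons <- dplyr::bind_rows(cases, pool)
  enrollment <- mk_enroll(persons$person_id, "2008-01-01", "2012-12-31")
  cancer <- mk_cancer(c("C1", "C2", "C3"), "2010-01-01", "2010-02-01",
                      "2010-03-01")
  bundle <- list(persons = persons, enrollment = enrollment,
                 claims = empty_claims(), cancer = cancer)
  chemo <- build_chemo_cohort(bundle)$cohort
  res <- match_comparators(chemo, bundle, ratio = 5L, seed = 2)
  comp <- dplyr::filter(res$cohort, arm == "comparator")
  # exact match on birth year and region, inheriting the case's index date
  for (i in seq_len(nrow(comp))) {
    case <- chemo[chemo$person_id == comp$match_group[i], ]
    expect_equal(comp$birth_year[i], case$birth_year)
    expect_equal(comp$region[i], case$region)
    expect_equal(comp$index_date[i], case$index_date)
  }
  # both same-stratum cases draw from the same two pool persons (replacement
  # across groups), without duplication within a group
  for (g in c("C1", "C2")) {
    got <- sort(comp$person_id[comp$match_group == g])
    expect_equal(got, c("P1", "P2"))
  }
  expect_equal(comp$person_id[comp$match_group == "C3"], "P3")
  expect_equal(res$n_unmatched, 0L)
  # reproducible under the same seed
  res2 <- match_comparators(chemo, bundle, ratio = 5L, seed = 2)
  expect_equal(res2$cohort, res$cohort)
})

test_that("match_comparators enforces eligibility at the index date", {
  cases <- mk_persons("C1", birth_year = 1940L, region = "West")
  pool <- mk_persons(c("P1", "P2", "P3"), birth_year = 1940L,
                     region = "West",
                     death = d(c("2010-02-01", NA, NA)))  # P1 dead at index
  persons <- dplyr::bind_rows(cases, pool)
  enrollment <- dplyr::bind_rows(
    mk_enroll(c("C1", "P2"), "2008-01-01", "2012-12-31"),
    mk_enroll("P1", "2008-01-01", "2010-02-01"),
    # P3 enrolled only from 45 days before index: fails the 180-day rule
    mk_enroll("P3", "2010-01-15", "2012-12-31"))
  cancer <- mk_cancer("C1", "2010-01-01", "2010-02-01", "2010-03-01")
  bundle <- list(persons = persons, enrollment = enrollment,
                 claims = empty_claims(), cancer = cancer)
  chemo <- build_chemo_cohort(bundle)$cohort
  res <- match_comparators(chemo, bundle, ratio = 5L, seed = 1)
  comp <- dplyr::filter(res$cohort, arm == "comparator")
  expect_equal(comp$person_id, "P2")
  # ratio caps the number of comparators per case
  expect_error(match_comparators(chemo, bundle, ratio = 0L), ">= 1")
})

test_that("cases with no eligible comparator are counted, not dropped", {
  cases <- mk_persons("C1", birth_year = 1940L, region = "West")
  pool <- mk_persons("P1", birth_year = 1941L, region = "West")
  persons <- dplyr::bind_rows(cases, pool)
  enrollment <- mk_enroll(persons$person_id, "2008-01-01", "2012-12-31")
  cancer <- mk_cancer("C1", "2010-01-01", "2010-02-01", "2010-03-01")
  bundle <- list(persons = persons, enrollment = enrollment,
                 claims = empty_claims(), cancer = cancer)
  chemo <- build_chemo_cohort(bundle)$cohort
  res <- match_comparators(chemo, bundle, seed = 1)
  expect_equal(res$n_unmatched, 1L)
  expect_equal(res$cohort$person_id, "C1")  # the case row is kept
})

test_that("screened_subset keeps only preindex-screened persons", {
  cases <- mk_persons(c("C1", "C2"), birth_year = 1940L)
  pool <- mk_persons(c("P1", "P2"), birth_year = 1940L)
  persons <- dplyr::bind_rows(cases, pool)
  enrollment <- mk_enroll(persons$person_id, "2006-01-01", "2012-12-31")
  cancer <- mk_cancer(c("C1", "C2"), "2010-01-01", "2010-02-01", "2010-03-01")
  # C1 screened within 365 days before diagnosis; C2 too early.
  # P1 screened before the inherited index date; P2 never screened.
  claims <- mk_claims(c("C1", "C2", "P1"),
                      c("2009-06-01", "2008-06-01", "2009-09-01"),
                      rep("mammogram", 3))
  bundle <- list(persons = persons, enrollment = enrollment, claims = claims,
                 cancer = cancer)
  chemo <- build_chemo_cohort(bundle)$cohort
  cohort <- match_comparators(chemo, bundle, seed = 1)$cohort
  sub <- screened_subset(cohort, bundle)
  expect_setequal(sub$person_id, c("C1", "P1"))
})

test_that("baseline covariates land on the cohort with correct bins", {
  persons <- mk_persons("C1", birth_year = 1940L)
  enrollment <- mk_enroll("C1", "2008-01-01", "2012-12-31")
  cancer <- mk_cancer("C1", "2010-01-01", "2010-02-01", "2010-03-01")
  # chf (2) + hypertension (-1) = Gagne 1 in the preindex window; flu shot too
  claims <- mk_claims(rep("C1", 3),
                      c("2010-01-15", "2010-02-10", "2010-02-20"),
                      c("chf", "hypertension", "flu_vaccine"))
  bundle <- list(persons = persons, enrollment = enrollment, claims = claims,
                 cancer = cancer)
  cohort <- build_chemo_cohort(bundle)$cohort
  expect_equal(cohort$gagne_score, 1)
  expect_equal(as.character(cohort$gagne_cat), "1")
  expect_true(cohort$flu_vaccine)
  expect_equal(cohort$age, 70L)
})
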