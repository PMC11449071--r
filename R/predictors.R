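# Baseline predictors of nonresilient trajectory membership: a logistic model
# of nonresilient (vs robust-or-resilient) cluster membership on baseline
# demographics, tumor characteristics, comorbidity and the 20 baseline
# frailty-indicator flags.

#' Build the nonresilience predictor design
#'
#' Joins cluster labels to baseline covariates with the reference coding of
#' the predictor table: age centered at 65 (per year), race (ref White, with
#' API and AI/AN collapsed to `Other`), region (ref West), stage (ref I),
#' surgery type (ref BCT), grade (ref well differentiated), Gagne category
#' (ref <= 0, i.e. the `<0` and `0` bins merged), flu vaccine, and the 20
#' baseline indicator flags. The outcome is 1 for members of a
#' nonresilient-labeled cluster. Persons without a cluster label (dropped
#' from clustering for short follow-up) are excluded.
#'
#' @param cohort Chemo-arm cohort tibble with baseline covariates.
#' @param solution A `traj_clusters` fit on that cohort.
#' @param baseline_iv Baseline indicator tibble from [extract_indicators()]
#'   at the index date.
#' @param labels Optional label table from [label_clusters()] (defaults to
#'   the default labeling rules).
#' @return Tibble ready for [fit_nonresilience()]: `person_id`,
#'   `nonresilient` (0/1), `age_c65`, factor covariates, indicator flags.
#' @export
build_design <- function(cohort, solution, baseline_iv,
                         labels = label_clusters(solution)) {
  lab <- labels %>% select("cluster", "label")
  assign_tbl <- tibble(person_id = names(solution$assignment),
                       cluster = as.integer(solution$assignment)) %>%
    left_join(lab, by = "cluster")
  dat <- cohort %>%
    inner_join(assign_tbl, by = "person_id") %>%
    left_join(baseline_iv %>% select(-"anchor", -"age_at_anchor",
                                     -"race_ethnicity"),
              by = "person_id")
  check_levels <- function(x, allowed, what) {
    bad <- setdiff(unique(x[!is.na(x)]), allowed)
    if (length(bad) > 0) {
      abort(paste0("unseen ", what, " level(s): ", paste(bad, collapse = ", ")))
    }
  }
  check_levels(dat$race, race_levels(), "race")
  check_levels(dat$region, region_levels(), "region")
  check_levels(dat$stage, stage_levels(), "stage")
  check_levels(dat$grade, grade_levels(), "grade")
  race3 <- case_when(
    dat$race %in% c("API", "AI/AN") ~ "Other",
    dat$race == "missing" | is.na(dat$race) ~ "White",
    TRUE ~ dat$race)
  grade_f <- ifelse(dat$grade == "missing" | is.na(dat$grade), "well",
                    dat$grade)
  dat %>%
    mutate(
      nonresilient = as.integer(.data$label == "nonresilient"),
      age_c65 = .data$age - 65,
      race = factor(race3, levels = c("White", "Black", "Hispanic", "Other")),
      region = factor(.data$region,
                      levels = c("West", "Northeast", "Midwest", "South")),
      stage = factor(.data$stage, levels = c("I", "II", "III")),
      surgery = factor(.data$surgery_type, levels = c("BCT", "mastectomy")),
      grade = factor(grade_f,
                     levels = c("well", "moderate", "poor",
                                "undifferentiated")),
      gagne_cat3 = factor(
        ifelse(.data$gagne_score <= 0, "<=0",
               ifelse(.data$gagne_score == 1, "1",
                      ifelse(.data$gagne_score == 2, "2", ">=3"))),
        levels = c("<=0", "1", "2", ">=3")),
      flu_vaccine = as.integer(.data$flu_vaccine)) %>%
    select(all_of(c("person_id", "nonresilient", "age_c65", "race", "region",
                    "stage", "surgery", "grade", "gagne_cat3", "flu_vaccine",
                    frailty_indicators())))
}

#' Fit the nonresilience logistic model
#'
#' Maximum-likelihood logistic regression of nonresilient membership on the
#' design from [build_design()] (or any subset of its covariates), reporting
#' odds ratios with Wald 95% CIs.
#'
#' @param design Tibble from [build_design()].
#' @param covariates Columns to include; default all design covariates.
#' @return A `nonresilience_fit` with `or_table` tibble (`term`, `or`,
#'   `conf_low`, `conf_high`) and the underlying `glm`.
#' @export
fit_nonresilience <- function(design,
                              covariates = setdiff(names(design),
                                                   c("person_id",
                                                     "nonresilient"))) {
  if (length(unique(design$nonresilient)) < 2) {
    abort("both outcome classes must be present")
  }
  keep <- covariates[vapply(covariates, function(v)
    n_distinct(design[[v]]) > 1, logical(1))]
  form <- stats::as.formula(
    paste("nonresilient ~", if (length(keep) > 0)
      paste(keep, collapse = " + ") else "1"))
  fit <- glm(form, data = design, family = binomial())
  probs <- fit$fitted.values
  if (!fit$converged || any(probs < 1e-10) || any(probs > 1 - 1e-10)) {
    abort(paste0("logistic model shows (near-)separation; consider a ",
                 "penalized refit or coarser covariates"))
  }
  s <- summary(fit)$coefficients
  or_table <- tibble(term = rownames(s),
                     or = exp(s[, 1]),
                     conf_low = exp(s[, 1] - qnorm(0.975) * s[, 2]),
                     conf_high = exp(s[, 1] + qnorm(0.975) * s[, 2]))
  structure(list(or_table = or_table, model = fit),
            class = "nonresilience_fit")
}

#' @export
tidy.nonresilience_fit <- function(x, ...) x$or_table

#' @export
glance.nonresilience_fit <- function(x, ...) {
  tibble(n = length(x$model$y), n_events = sum(x$model$y),
         null_deviance = x$model$null.deviance, deviance = x$model$deviance)
}

#' @export
print.nonresilience_fit <- function(x, ...) {
  cat("Nonresilient-trajectory logistic model (",
      sum(x$model$y), "events /", length(x$model$y), "persons )\n")
  print(as.data.frame(x$or_table), digits = 3)
  invisible(x)
}
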