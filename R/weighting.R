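# SMR weighting (standardize comparators to the chemo cohort) and inverse
# probability of attrition weighting from pooled logistic retention models,
# plus covariate balance diagnostics.

#' Fit the arm-membership (propensity) model
#'
#' Logistic regression of chemo-arm membership on baseline covariates,
#' the ingredient of SMR weighting. Covariates constant across the sample are
#' dropped with a warning; (near-)perfect separation is a hard error.
#'
#' @param cohort Combined cohort tibble (column `arm` in
#'   `{"chemo", "comparator"}`).
#' @param covariates Character vector of covariate column names; factors and
#'   logicals are expanded by the usual treatment coding.
#' @return A `propensity_fit` list: `model` (glm), `ps` (per-row fitted
#'   probability), `covariates`.
#' @export
fit_propensity <- function(cohort, covariates = c("age", "race", "region",
                                                  "gagne_cat",
                                                  "flu_vaccine")) {
  stopifnot(all(covariates %in% names(cohort)))
  if (length(unique(cohort$arm)) < 2) abort("both arms must be present")
  dat <- cohort %>%
    mutate(.y = as.integer(.data$arm == "chemo")) %>%
    select(".y", all_of(covariates))
  keep <- covariates[vapply(covariates, function(v) {
    n_distinct(dat[[v]]) > 1
  }, logical(1))]
  dropped <- setdiff(covariates, keep)
  if (length(dropped) > 0) {
    warn(paste0("constant covariate(s) dropped from propensity model: ",
                paste(dropped, collapse = ", ")))
  }
  if (length(keep) == 0) abort("no non-constant covariates")
  form <- stats::as.formula(paste(".y ~", paste(keep, collapse = " + ")))
  fit <- glm(form, data = dat, family = binomial())
  ps <- as.numeric(fit$fitted.values)
  eps <- 1e-10
  if (!fit$converged || any(ps < eps) || any(ps > 1 - eps)) {
    abort(paste0("propensity model shows (near-)separation; coarsen ",
                 "covariates or drop sparse levels"))
  }
  structure(list(model = fit, ps = ps, covariates = keep),
            class = "propensity_fit")
}

#' @export
tidy.propensity_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std_error = s[, 2],
         conf_low = s[, 1] - qnorm(0.975) * s[, 2],
         conf_high = s[, 1] + qnorm(0.975) * s[, 2])
}

#' Standardized mortality ratio weights
#'
#' Weight 1 for every chemo-arm row; the propensity odds `ps / (1 - ps)` for
#' comparator rows, standardizing the comparator covariate distribution to the
#' chemo cohort. Comparator weights above the truncation percentile are capped
#' (truncation never raises the maximum weight).
#'
#' @param fit A `propensity_fit` from [fit_propensity()] (row-aligned with
#'   `cohort`).
#' @param cohort The cohort tibble the fit was computed on.
#' @param truncate_pct Truncation percentile of comparator weights in (0, 1\];
#'   default 0.99. Use 1 for no truncation.
#' @return `cohort` with an `smr_weight` column; attribute `truncation`
#'   records pre/post maxima.
#' @export
smr_weights <- function(fit, cohort, truncate_pct = 0.99) {
  stopifnot(inherits(fit, "propensity_fit"), length(fit$ps) == nrow(cohort))
  w <- ifelse(cohort$arm == "chemo", 1, fit$ps / (1 - fit$ps))
  pre_max <- max(w[cohort$arm == "comparator"], 0)
  if (truncate_pct < 1 && any(cohort$arm == "comparator")) {
    cap <- quantile(w[cohort$arm == "comparator"], truncate_pct, names = FALSE)
    w[cohort$arm == "comparator"] <- pmin(w[cohort$arm == "comparator"], cap)
  }
  out <- cohort
  out$smr_weight <- w
  attr(out, "truncation") <- c(pre_max = pre_max,
                               post_max = max(w[cohort$arm == "comparator"], 0))
  out
}

#' Build the person-period attrition panel
#'
#' One row per person per follow-up period `(T1, T2]` and `(T2, T3]`, for
#' persons under observation at the period start. Events: `death` when the
#' death date falls in the period; `disenroll` when FFS coverage (from the
#' index date) ends in the period before death. A competing event removes all
#' later periods.
#'
#' @param cohort Combined cohort tibble with `index_date`.
#' @param bundle Table bundle (for death dates and enrollment).
#' @param scores Optional tibble (`person_id`, `anchor`, `score`) supplying
#'   the lagged frailty score at each period start.
#' @param timepoint_days Anchors of T1/T2/T3 relative to index
#'   (default `c(0, 120, 300)`).
#' @param gagne_weights,cmap For time-varying comorbidity at period starts.
#' @return Tibble: person, period (1 or 2), covariates, `death`, `disenroll`.
#' @export
build_attrition_panel <- function(cohort, bundle, scores = NULL,
                                  timepoint_days = c(0L, 120L, 300L),
                                  gagne_weights = default_gagne_weights(),
                                  cmap = default_codemap()) {
  # one attrition unit per (person, index date): a comparator matched into
  # several groups at different index dates is followed from each index
  cohort <- cohort %>% distinct(.data$person_id, .data$index_date,
                                .keep_all = TRUE)
  merged <- merge_ffs_spells(bundle$enrollment)
  dd <- bundle$persons$death_date[match(cohort$person_id,
                                        bundle$persons$person_id)]
  # end of continuous FFS coverage containing the index date
  cov_end <- as.Date(rep(NA, nrow(cohort)))
  bl <- split(merged, merged$person_id)
  for (i in seq_len(nrow(cohort))) {
    b <- bl[[cohort$person_id[i]]]
    if (is.null(b)) next
    j <- which(b$start_date <= cohort$index_date[i] &
                 b$end_date >= cohort$index_date[i])
    if (length(j) == 1) cov_end[i] <- b$end_date[j]
  }
  rows <- vector("list", 2)
  for (p in 1:2) {
    start <- cohort$index_date + timepoint_days[p]
    end <- cohort$index_date + timepoint_days[p + 1]
    alive_at_start <- is.na(dd) | dd > start
    enrolled_at_start <- !is.na(cov_end) & cov_end >= start
    at_risk <- alive_at_start & enrolled_at_start
    death <- at_risk & !is.na(dd) & dd > start & dd <= end
    disenroll <- at_risk & !death & cov_end < end &
      (is.na(dd) | cov_end < dd)
    rows[[p]] <- cohort[at_risk, , drop = FALSE] %>%
      mutate(period = p, period_start = start[at_risk],
             death = death[at_risk], disenroll = disenroll[at_risk])
  }
  panel <- bind_rows(rows)
  # time-varying covariates at period start
  g <- gagne_score(bundle$claims,
                   panel %>% select("person_id", anchor = "period_start"),
                   gagne_weights, cmap = cmap)
  panel$gagne_tv <- g$gagne_score
  if (!is.null(scores)) {
    panel <- panel %>%
      left_join(scores %>% select("person_id", period_start = "anchor",
                                  frailty_lag = "score"),
                by = c("person_id", "period_start"))
  }
  panel
}

#' Pooled logistic attrition models
#'
#' Fits one discrete-time (pooled logistic) hazard model per attrition cause
#' over the person-period panel, with period-specific intercepts plus the
#' supplied covariates, and returns per-row predicted cause-specific retention
#' probabilities. A cause with zero events gets retention 1 with a warning.
#'
#' @param panel Panel from [build_attrition_panel()].
#' @param covariates Covariate columns (default: baseline demographics plus
#'   time-varying comorbidity and, when present, lagged frailty).
#' @return An `attrition_fits` list: per-cause glance-able `glm`s (or `NULL`)
#'   and a `retention` tibble (`person_id`, `period`, `p_death_free`,
#'   `p_disenroll_free`).
#' @export
fit_attrition_models <- function(panel,
                                 covariates = intersect(
                                   c("age", "race", "region", "flu_vaccine",
                                     "gagne_tv", "frailty_lag"),
                                   names(panel))) {
  fits <- list()
  ret <- panel %>%
    select(all_of(c("person_id",
                    intersect("index_date", names(panel)), "period")))
  for (cause in c("death", "disenroll")) {
    y <- panel[[cause]]
    nm <- paste0("p_", cause, "_free")
    if (sum(y) == 0) {
      warn(paste0("no ", cause, " events; retention set to 1"))
      fits[[cause]] <- NULL
      ret[[nm]] <- 1
      next
    }
    keep <- covariates[vapply(covariates, function(v)
      n_distinct(panel[[v]]) > 1, logical(1))]
    rhs <- c("factor(period)", keep)
    form <- stats::as.formula(paste("y ~", paste(rhs, collapse = " + ")))
    dat <- panel %>% select(all_of(c("period", keep)))
    dat$y <- y
    fit <- glm(form, data = dat, family = binomial())
    fits[[cause]] <- fit
    ret[[nm]] <- 1 - as.numeric(fit$fitted.values)
  }
  structure(list(fits = fits, retention = ret), class = "attrition_fits")
}

#' Inverse probability of attrition weights
#'
#' For a person observed at timepoint `k`, the weight is the inverse of the
#' cumulative product of cause-specific retention probabilities over all
#' periods up to `k`:
#' `w_k = prod_{j <= k} (p_death_free(j) * p_disenroll_free(j))^-1`.
#' T1 weights are 1 by construction.
#'
#' @param fits An `attrition_fits` from [fit_attrition_models()].
#' @param truncate_pct Truncation percentile in (0, 1\] (default 0.99).
#' @return Tibble: `person_id`, `timepoint` (1..3), `ipaw_weight` — one row
#'   per person-period *survived* (a person at risk in period 1 gets a T2
#'   weight, etc.), plus T1 rows with weight 1.
#' @export
ipaw_weights <- function(fits, truncate_pct = 0.99) {
  ret <- fits$retention
  p_ret <- ret$p_death_free * ret$p_disenroll_free
  if (any(p_ret <= 0)) {
    abort("retention probability of 0 cannot be inverted; see truncation")
  }
  keys <- intersect(c("person_id", "index_date"), names(ret))
  cum <- ret %>%
    mutate(p_ret = p_ret) %>%
    arrange(across(all_of(c(keys, "period")))) %>%
    group_by(across(all_of(keys))) %>%
    mutate(ipaw_weight = 1 / cumprod(.data$p_ret),
           timepoint = .data$period + 1L) %>%
    ungroup() %>%
    select(all_of(c(keys, "timepoint", "ipaw_weight")))
  t1 <- ret %>% distinct(across(all_of(keys))) %>%
    mutate(timepoint = 1L, ipaw_weight = 1)
  out <- bind_rows(t1, cum)
  if (truncate_pct < 1) {
    cap <- quantile(out$ipaw_weight, truncate_pct, names = FALSE)
    out$ipaw_weight <- pmin(out$ipaw_weight, cap)
  }
  out
}

#' Standardized mean differences before and after weighting
#'
#' For each covariate (factor levels expanded to indicators), the difference
#' between the chemo mean and the (optionally weighted) comparator mean,
#' divided by the pooled unweighted SD.
#'
#' @param cohort Cohort tibble with `smr_weight` (see [smr_weights()]).
#' @param covariates Covariate columns.
#' @return Tibble: `covariate`, `smd_unweighted`, `smd_weighted`.
#' @export
balance_table <- function(cohort, covariates = c("age", "race", "region",
                                                 "gagne_cat",
                                                 "flu_vaccine")) {
  stopifnot("smr_weight" %in% names(cohort))
  dat <- as.data.frame(lapply(cohort[covariates], function(x) {
    if (is.character(x)) factor(x) else x
  }))
  X <- model.matrix(
    stats::as.formula(paste("~ 0 +", paste(covariates, collapse = " + "))),
    data = dat)
  chemo <- cohort$arm == "chemo"
  w <- cohort$smr_weight
  res <- purrr::map_dfr(colnames(X), function(cn) {
    x <- X[, cn]
    m1 <- mean(x[chemo])
    m0 <- mean(x[!chemo])
    m0w <- sum(w[!chemo] * x[!chemo]) / sum(w[!chemo])
    s <- sqrt((var(x[chemo]) + var(x[!chemo])) / 2)
    tibble(covariate = cn,
           smd_unweighted = if (s > 0) (m1 - m0) / s else 0,
           smd_weighted = if (s > 0) (m1 - m0w) / s else 0)
  })
  res
}
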