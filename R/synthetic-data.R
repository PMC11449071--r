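# Synthetic Medicare-like claims generator. Emits a person roster, enrollment
# spells, coded claims, cancer records and a latent-truth table whose hidden
# structure matches the analysis assumptions: six latent frailty-trajectory
# classes in the chemotherapy cohort, a mild secular drift in comparators,
# indicator claims positively (deficits) or negatively (screening) loaded on
# latent frailty, and frailty-dependent death and disenrollment.

default_latent_curves <- function() {
  # Per-class latent frailty at months 0..12, piecewise linear through knots
  # at months 0, 2, 6, 12. The acute-toxicity excursion peaks at month 2 and
  # resolves by month 6 in the resilient classes: because the claims window is
  # a trailing 180-day lookback, the *scored* series is roughly a 6-month
  # moving average of the latent series, so an early latent peak is what makes
  # the mean score peak near 4 months and ease back by 10 months.
  knots <- c(0, 2, 6, 12)
  k <- rbind(
    robust            = c(0.030, 0.048, 0.030, 0.030),
    resilient_low_med = c(0.045, 0.240, 0.046, 0.045),
    resilient_med_high= c(0.150, 0.330, 0.170, 0.165),
    nonres_low_med    = c(0.040, 0.075, 0.105, 0.125),
    nonres_low_high   = c(0.050, 0.120, 0.180, 0.200),
    nonres_high       = c(0.250, 0.300, 0.300, 0.300))
  t(apply(k, 1, function(v) stats::approx(knots, v, xout = 0:12)$y))
}

default_indicator_loadings <- function() {
  # P(indicator claim in a 180-day window) = plogis(a + b * latent frailty);
  # b > 0 for deficits, b < 0 for the two screening-service indicators.
  # Values chosen so rare equipment/neurologic services stay rare while common
  # office-based indicators saturate with rising frailty, keeping the mean
  # frailty score approximately linear in the latent level over [0.03, 0.35].
  tibble::tribble(
    ~indicator,            ~a,    ~b,
    "parkinsons",         -3.95,  4.7,
    "home_hospital_bed",  -4.29,  6.3,
    "wheelchair",         -4.06,  6.1,
    "home_oxygen",        -3.25,  4.8,
    "paralysis",          -4.64,  4.7,
    "podiatric_care",     -0.33,  6.5,
    "psychiatric_disease",-0.59,  6.5,
    "dementia",           -3.58,  5.3,
    "skin_ulcer",         -3.25,  4.8,
    "stroke_brain_injury",-2.80,  4.3,
    "ambulance",          -2.10,  8.8,
    "bladder_dysfunction",-1.75,  7.3,
    "arthritis",           0.32,  6.5,
    "vertigo",            -1.27,  7.1,
    "heart_failure",      -1.59,  8.0,
    "weakness",           -1.65,  8.7,
    "lipid_abnormality",   1.99, -4.9,
    "rehabilitation",     -1.32,  7.8,
    "cancer_screening",    1.82, -5.6,
    "hypotension_shock",  -4.06,  6.1)
}

default_gagne_loadings <- function() {
  # comorbidity-condition claims (Gagne components), same link as indicators;
  # dementia claims are shared with the frailty indicator of the same name
  tibble::tribble(
    ~indicator,             ~a,    ~b,
    "chf",                 -2.70,  20,
    "renal_failure",       -3.70,  20,
    "copd",                -2.10,  10,
    "complicated_diabetes",-2.55,   8,
    "anemia",              -1.85,  10,
    "electrolyte_disorder",-3.05,  15,
    "weight_loss",         -4.90,  25,
    "hypertension",        -0.28,   2,
    "metastatic_cancer",   -6.40,   5)
}

#' Simulation configuration
#'
#' Collects every tunable of [simulate_population()]. Defaults encode the
#' study conditions: a 6-class trajectory mixture (78/15/1/4/1/1 percent), a
#' chemo-cohort mean frailty-score pattern that rises from chemotherapy
#' initiation to 4 months and eases back by 10 months, a comparator mean that
#' drifts gently upward over the follow-up year, and death fractions near
#' 3 percent (chemo) versus 1 percent (comparators) over 10 months.
#'
#' @param n_chemo Number of chemotherapy cases to emit.
#' @param comparator_pool_multiplier Pool size as a multiple of `n_chemo`.
#' @param cluster_mixture Probability vector over the 6 latent classes
#'   (must sum to 1).
#' @param latent_curves 6 x 13 matrix of per-class latent frailty at months
#'   0..12, values in \[0, 1\].
#' @param comparator_drift Length-2 vector: comparator mean latent frailty at
#'   the start and end of a 12-month follow-up window.
#' @param comparator_base_sd SD of the comparator person-level latent level.
#' @param indicator_loadings,gagne_loadings Tibbles (`indicator`, `a`, `b`)
#'   giving the logistic link from latent frailty to the per-180-day-window
#'   claim probability.
#' @param attrition Named list with `death` and `disenroll`, each
#'   `c(intercept, slope, chemo_shift)`: per-30-day logistic hazards on latent
#'   frailty, with an additive chemo-arm shift on the logit scale.
#' @param contamination Fraction of emitted chemo cases deliberately violating
#'   one eligibility rule (exercises the exclusion ledger).
#' @param flu_annual,mammogram_annual Named vectors (`chemo`, `comparator`):
#'   probability of being an annual flu-shot / screening-mammogram receiver.
#' @param index_years Range of chemotherapy initiation years.
#' @param seed Integer seed; same seed, same output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_chemo = 2000,
                       comparator_pool_multiplier = 5,
                       cluster_mixture = c(0.78, 0.15, 0.01, 0.04, 0.01, 0.01),
                       latent_curves = default_latent_curves(),
                       comparator_drift = c(0.065, 0.072),
                       comparator_base_sd = 0.025,
                       indicator_loadings = default_indicator_loadings(),
                       gagne_loadings = default_gagne_loadings(),
                       attrition = list(
                         death = c(intercept = -7.3, slope = 8,
                                   chemo_shift = 1.1),
                         disenroll = c(intercept = -6.3, slope = 5,
                                       chemo_shift = 0)),
                       contamination = 0.05,
                       flu_annual = c(chemo = 0.60, comparator = 0.48),
                       mammogram_annual = c(chemo = 0.75, comparator = 0.55),
                       index_years = c(2004L, 2017L),
                       seed = 1L) {
  if (abs(sum(cluster_mixture) - 1) > 1e-8) {
    abort("`cluster_mixture` must sum to 1")
  }
  stopifnot(nrow(latent_curves) == length(cluster_mixture),
            ncol(latent_curves) == 13,
            all(latent_curves >= 0 & latent_curves <= 1),
            contamination >= 0, contamination < 1)
  structure(list(
    n_chemo = n_chemo,
    comparator_pool_multiplier = comparator_pool_multiplier,
    cluster_mixture = cluster_mixture, latent_curves = latent_curves,
    comparator_drift = comparator_drift,
    comparator_base_sd = comparator_base_sd,
    indicator_loadings = indicator_loadings,
    gagne_loadings = gagne_loadings, attrition = attrition,
    contamination = contamination, flu_annual = flu_annual,
    mammogram_annual = mammogram_annual, index_years = as.integer(index_years),
    seed = as.integer(seed)), class = "sim_config")
}

# window probability -> per-30-day-block probability (6 blocks per window)
block_prob <- function(p_window) 1 - (1 - p_window)^(1 / 6)

# Draw indicator claims for persons over 30-day blocks.
# latent: n x n_blocks matrix; anchors: Date vector (block 0 starts there);
# block_offsets: integer vector of block indices (block b covers days
# [30b, 30b+29]). Returns claims tibble.
draw_block_claims <- function(person_id, anchors, latent, block_offsets,
                              loadings) {
  n <- length(person_id)
  nb <- length(block_offsets)
  out <- vector("list", nrow(loadings))
  for (j in seq_len(nrow(loadings))) {
    p <- plogis(loadings$a[j] + loadings$b[j] * latent)
    q <- block_prob(p)
    hit <- which(matrix(runif(n * nb), n, nb) < q, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    day <- 30L * block_offsets[hit[, 2]] + sample(0:29, nrow(hit),
                                                  replace = TRUE)
    out[[j]] <- tibble(
      person_id = person_id[hit[, 1]],
      service_date = anchors[hit[, 1]] + day,
      code = loadings$indicator[j], code_system = "SYN")
  }
  bind_rows(out)
}

# first event month from per-month logistic hazards; returns Inf if none
first_event_month <- function(hazard) {
  # hazard: n x m matrix of per-block event probabilities
  u <- matrix(runif(length(hazard)), nrow(hazard), ncol(hazard))
  ev <- u < hazard
  first <- apply(ev, 1, function(z) if (any(z)) which(z)[1] else Inf)
  as.numeric(first)
}

sample_levels <- function(n, levels, probs) {
  levels[sample.int(length(levels), n, replace = TRUE, prob = probs)]
}

#' Generate a synthetic claims population
#'
#' Emits a full table bundle (persons, enrollment, claims, cancer records)
#' plus a `truth` table carrying each person's latent class, latent monthly
#' frailty and attrition months. The truth table is simulation output only;
#' no analysis stage reads it.
#'
#' @param config A [sim_config()].
#' @return Named list: `persons`, `enrollment`, `claims`, `cancer`, `truth`
#'   (all tibbles), passing [validate_bundle()].
#' @export
simulate_population <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  loadings <- bind_rows(config$indicator_loadings, config$gagne_loadings) %>%
    distinct(.data$indicator, .keep_all = TRUE)

  ## ---- chemotherapy cases -------------------------------------------------
  n <- config$n_chemo
  yr0 <- config$index_years[1]; yr1 <- config$index_years[2]
  index_date <- as.Date(paste0(sample(yr0:yr1, n, TRUE), "-01-01")) +
    sample(0:364, n, TRUE)
  age_at_index <- pmin(66L + stats::rpois(n, 1) + round(rgamma(n, 2, 0.5)), 95L)
  birth_year <- as.integer(format(index_date, "%Y")) - age_at_index
  race <- sample_levels(n, c("White", "Black", "Hispanic", "API", "AI/AN"),
                        c(0.816, 0.089, 0.055, 0.037, 0.003))
  region <- sample_levels(n, region_levels(), c(0.194, 0.416, 0.191, 0.199))
  true_class <- sample.int(length(config$cluster_mixture), n, TRUE,
                           prob = config$cluster_mixture)
  lat13 <- config$latent_curves[true_class, , drop = FALSE]  # months 0..12

  chemo_delay <- pmin(pmax(round(rnorm(n, 47, 12)), 14L), 90L)
  surgery_delay <- sample(7:60, n, TRUE)
  surgery_date <- index_date - chemo_delay
  diagnosis_date <- surgery_date - surgery_delay
  stage <- sample_levels(n, c("I", "II", "III"), c(0.223, 0.537, 0.240))
  grade <- sample_levels(n, grade_levels(),
                         c(0.084, 0.382, 0.504, 0.007, 0.023))
  surgery_type <- sample_levels(n, c("mastectomy", "BCT"), c(0.401, 0.599))
  neoadjuvant <- rep(FALSE, n)
  enroll_start <- index_date - 800L

  # contamination: cases violating one eligibility rule apiece
  n_bad <- round(config$contamination * n)
  if (n_bad > 0) {
    bad <- sample.int(n, n_bad)
    kind <- sample(1:4, n_bad, TRUE)
    neoadjuvant[bad[kind == 1]] <- TRUE
    late_surg <- bad[kind == 2]
    diagnosis_date[late_surg] <- surgery_date[late_surg] -
      sample(91:150, length(late_surg), TRUE)
    late_chemo <- bad[kind == 3]
    surgery_date[late_chemo] <- index_date[late_chemo] -
      sample(91:150, length(late_chemo), TRUE)
    diagnosis_date[late_chemo] <- surgery_date[late_chemo] -
      sample(7:60, length(late_chemo), TRUE)
    short_enroll <- bad[kind == 4]
    enroll_start[short_enroll] <- index_date[short_enroll] - 100L
  }

  # attrition over months 1..12 post-index (hazards at that month's latent)
  att <- config$attrition
  lat_fu <- lat13[, 2:13, drop = FALSE]
  death_m <- first_event_month(plogis(att$death[["intercept"]] +
                                        att$death[["chemo_shift"]] +
                                        att$death[["slope"]] * lat_fu))
  dis_m <- first_event_month(plogis(att$disenroll[["intercept"]] +
                                      att$disenroll[["chemo_shift"]] +
                                      att$disenroll[["slope"]] * lat_fu))
  dis_m[dis_m >= death_m] <- Inf
  death_m[death_m > dis_m] <- Inf
  death_date <- as.Date(ifelse(is.finite(death_m),
                               index_date + 30 * (death_m - 1) +
                                 sample(1:30, n, TRUE), NA),
                        origin = "1970-01-01")
  end_obs <- index_date + 720L
  end_obs[is.finite(death_m)] <- death_date[is.finite(death_m)]
  dis_date <- index_date + 30L * (dis_m - 1L) + sample(1:30, n, TRUE)
  end_obs[is.finite(dis_m)] <- as.Date(
    dis_date[is.finite(dis_m)], origin = "1970-01-01")

  chemo_id <- sprintf("C%05d", seq_len(n))
  persons_chemo <- tibble(
    person_id = chemo_id, birth_year = birth_year, sex = "F",
    race_ethnicity = race, region = region, death_date = death_date)
  cancer <- tibble(
    person_id = chemo_id, diagnosis_date = diagnosis_date, stage = stage,
    grade = grade, surgery_date = surgery_date, surgery_type = surgery_type,
    chemo_start_date = index_date, neoadjuvant_flag = neoadjuvant)
  enroll_chemo <- tibble(
    person_id = chemo_id, start_date = enroll_start, end_date = end_obs,
    coverage = "FFS")

  # indicator + comorbidity claims over blocks -7..12 relative to index
  blocks_c <- -7:12
  lat_blocks_c <- lat13[, pmin(pmax(blocks_c, 0), 12) + 1, drop = FALSE]
  claims_chemo <- draw_block_claims(chemo_id, index_date, lat_blocks_c,
                                    blocks_c, loadings)

  ## ---- comparator pool ----------------------------------------------------
  m <- round(n * config$comparator_pool_multiplier)
  donor <- sample.int(n, m, TRUE)  # copy stratum + calendar anchor of a case
  anchor_p <- index_date[donor]
  persons_pool_birth <- birth_year[donor]
  region_p <- region[donor]
  race_p <- sample_levels(m, c("White", "Black", "Hispanic", "API", "AI/AN"),
                          c(0.759, 0.093, 0.083, 0.061, 0.004))
  drift <- config$comparator_drift
  slope_yr <- (drift[2] - drift[1]) * 12 / 10  # follow-up drift per 360 days
  # person-level base such that the mean latent AT the anchor equals drift[1]
  base_p <- pmin(pmax(rnorm(m, drift[1] - slope_yr * 800 / 360,
                            config$comparator_base_sd), 0.005), 0.6)

  blocks_p <- -27:36
  enroll_start_p <- anchor_p - 800L
  # latent on calendar time: nondecreasing from enrollment start
  lat_blocks_p <- pmin(pmax(
    outer(base_p, rep(1, length(blocks_p))) +
      slope_yr * outer(rep(1, m), (blocks_p * 30 + 800) / 360), 0.001), 0.95)

  lat_fu_p <- lat_blocks_p[, match(1:24, blocks_p), drop = FALSE]
  death_mp <- first_event_month(plogis(att$death[["intercept"]] +
                                         att$death[["slope"]] * lat_fu_p))
  dis_mp <- first_event_month(plogis(att$disenroll[["intercept"]] +
                                       att$disenroll[["slope"]] * lat_fu_p))
  dis_mp[dis_mp >= death_mp] <- Inf
  death_mp[death_mp > dis_mp] <- Inf
  death_date_p <- as.Date(ifelse(is.finite(death_mp),
                                 anchor_p + 30 * (death_mp - 1) +
                                   sample(1:30, m, TRUE), NA),
                          origin = "1970-01-01")
  end_obs_p <- anchor_p + 1110L
  end_obs_p[is.finite(death_mp)] <- death_date_p[is.finite(death_mp)]
  dis_date_p <- anchor_p + 30L * (dis_mp - 1L) + sample(1:30, m, TRUE)
  end_obs_p[is.finite(dis_mp)] <- as.Date(
    dis_date_p[is.finite(dis_mp)], origin = "1970-01-01")

  pool_id <- sprintf("P%06d", seq_len(m))
  persons_pool <- tibble(
    person_id = pool_id, birth_year = persons_pool_birth, sex = "F",
    race_ethnicity = race_p, region = region_p, death_date = death_date_p)
  enroll_pool <- tibble(
    person_id = pool_id, start_date = enroll_start_p, end_date = end_obs_p,
    coverage = "FFS")
  claims_pool <- draw_block_claims(pool_id, anchor_p, lat_blocks_p,
                                   blocks_p, loadings)

  ## ---- service claims (flu shots, mammograms) -----------------------------
  service_claims <- function(ids, anchors, p_annual, code, years = -3:3) {
    receiver <- runif(length(ids)) < p_annual
    out <- vector("list", length(years))
    for (k in seq_along(years)) {
      idx <- which(receiver)
      out[[k]] <- tibble(
        person_id = ids[idx],
        service_date = anchors[idx] + 365L * years[k] +
          sample(0:364, length(idx), TRUE),
        code = code, code_system = "SYN")
    }
    bind_rows(out)
  }
  flu <- bind_rows(
    service_claims(chemo_id, index_date, config$flu_annual[["chemo"]],
                   "flu_vaccine"),
    service_claims(pool_id, anchor_p, config$flu_annual[["comparator"]],
                   "flu_vaccine"))
  mam <- bind_rows(
    service_claims(chemo_id, diagnosis_date,
                   config$mammogram_annual[["chemo"]], "mammogram"),
    service_claims(pool_id, anchor_p,
                   config$mammogram_annual[["comparator"]], "mammogram"))

  persons <- bind_rows(persons_chemo, persons_pool)
  enrollment <- bind_rows(enroll_chemo, enroll_pool)
  claims <- bind_rows(claims_chemo, claims_pool, flu, mam)
  # keep claims inside life and enrollment
  span <- enrollment %>% group_by(.data$person_id) %>%
    summarise(s = min(.data$start_date), e = max(.data$end_date),
              .groups = "drop")
  claims <- claims %>%
    left_join(span, by = "person_id") %>%
    filter(.data$service_date >= .data$s, .data$service_date <= .data$e) %>%
    select(-"s", -"e") %>%
    arrange(.data$person_id, .data$service_date, .data$code)

  truth <- bind_rows(
    tibble(person_id = chemo_id, arm = "chemo", true_class = true_class,
           anchor = index_date, death_month = death_m,
           disenroll_month = dis_m) %>%
      dplyr::bind_cols(as_tibble(set_names(
        as.data.frame(lat13), paste0("latent_m", 0:12)))),
    tibble(person_id = pool_id, arm = "comparator", true_class = NA_integer_,
           anchor = anchor_p, death_month = death_mp,
           disenroll_month = dis_mp) %>%
      dplyr::bind_cols(as_tibble(set_names(
        as.data.frame(lat_blocks_p[, match(0:12, blocks_p), drop = FALSE]),
        paste0("latent_m", 0:12)))))

  bundle <- list(persons = persons, enrollment = enrollment, claims = claims,
                 cancer = cancer, truth = truth)
  suppressWarnings(validate_bundle(bundle[c("persons", "enrollment",
                                            "claims", "cancer")]))
  bundle
}

#' Simulate a three-timepoint gamma panel for GEE estimator checks
#'
#' Generates `person x {T1, T2, T3}` outcomes with gamma marginals whose means
#' follow the benchmark mean model
#' `mu = b0 + b1*arm + b2*T2 + b3*T3 + b4*arm*T2 + b5*arm*T3`,
#' within-person dependence induced by a Gaussian copula with AR(1)
#' correlation `ar_rho`, and equal arm sizes. Simulates the estimand directly,
#' so GEE recovery tests are independent of the claims machinery.
#'
#' @param betas Numeric length-6: `(b0, b1, b2, b3, b4, b5)`. All six cell
#'   means must be positive (gamma support).
#' @param dispersion Gamma dispersion `phi` (variance `phi * mu^2`).
#' @param ar_rho Copula AR(1) correlation in \[0, 1).
#' @param n Number of persons (half per arm, rounding down for chemo).
#' @param seed Integer seed.
#' @return Tibble: `person_id`, `arm` (0/1), `timepoint` (1..3), `y`,
#'   `weight` (all 1).
#' @export
simulate_gee_scenario <- function(betas, dispersion = 0.3, ar_rho = 0.5,
                                  n = 1000, seed = 1L) {
  stopifnot(length(betas) == 6)
  arm1 <- rep(c(0, 1), length.out = n)
  mu <- cbind(betas[1] + betas[2] * arm1,
              betas[1] + betas[2] * arm1 + betas[3] + betas[5] * arm1,
              betas[1] + betas[2] * arm1 + betas[4] + betas[6] * arm1)
  if (any(mu <= 0)) abort("mean model implies a nonpositive cell mean")
  set.seed(seed)
  z1 <- rnorm(n); e2 <- rnorm(n); e3 <- rnorm(n)
  z2 <- ar_rho * z1 + sqrt(1 - ar_rho^2) * e2
  z3 <- ar_rho * z2 + sqrt(1 - ar_rho^2) * e3
  u <- pnorm(cbind(z1, z2, z3))
  shape <- 1 / dispersion
  y <- qgamma(u, shape = shape, scale = mu * dispersion)
  tibble(person_id = rep(sprintf("G%06d", seq_len(n)), each = 3),
         arm = rep(arm1, each = 3),
         timepoint = rep(1:3, n),
         y = as.numeric(t(y)), weight = 1)
}

#' Simulate frailty trajectories directly
#'
#' Draws per-person monthly trajectories around the latent class curves with
#' Gaussian within-person noise and (optionally) informative monotone dropout
#' whose monthly hazard rises with the current latent level. Used for
#' clustering recovery checks where the claims layer would only add noise.
#'
#' @param n Number of persons.
#' @param mixture Class probabilities (defaults to the 6-class study mixture).
#' @param curves Class-by-month latent matrix (defaults to the study curves).
#' @param noise_sd Within-person, within-month noise SD.
#' @param dropout_intercept,dropout_slope Per-month logistic dropout hazard
#'   `plogis(intercept + slope * latent)`; the defaults give roughly 30%
#'   dropout by month 12 at the default curves. Set `dropout_intercept = -Inf`
#'   for complete follow-up.
#' @param seed Integer seed.
#' @return List: `trajectories` (n x 13 matrix with NA suffixes, rownames are
#'   person ids) and `truth` tibble (`person_id`, `true_class`,
#'   `dropout_month`).
#' @export
simulate_trajectories <- function(n, mixture = c(0.78, 0.15, 0.01, 0.04,
                                                 0.01, 0.01),
                                  curves = default_latent_curves(),
                                  noise_sd = 0.01,
                                  dropout_intercept = -3.9,
                                  dropout_slope = 8,
                                  seed = 1L) {
  set.seed(seed)
  cls <- sample.int(nrow(curves), n, TRUE, prob = mixture)
  traj <- curves[cls, , drop = FALSE] +
    matrix(rnorm(n * 13, 0, noise_sd), n, 13)
  dropout <- rep(Inf, n)
  if (is.finite(dropout_intercept)) {
    haz <- plogis(dropout_intercept +
                    dropout_slope * curves[cls, 2:13, drop = FALSE])
    dropout <- first_event_month(haz)
    for (i in which(is.finite(dropout))) {
      traj[i, (dropout[i] + 1):13] <- NA_real_
    }
  }
  rownames(traj) <- sprintf("T%06d", seq_len(n))
  list(trajectories = traj,
       truth = tibble(person_id = rownames(traj), true_class = cls,
                      dropout_month = dropout))
}
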