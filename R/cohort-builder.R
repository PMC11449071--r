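# Cohort construction: eligibility chain for the adjuvant-chemotherapy cohort
# (with an auditable exclusion ledger), exact matching of noncancer
# comparators with replacement, and baseline covariates (Gagne comorbidity
# score, preindex flu vaccination).

#' Default Gagne comorbidity weights
#'
#' A configurable default condition-to-weight map for the combined
#' (Charlson + Elixhauser) comorbidity score, following the published weights
#' of the combined score. `metastatic_cancer` and `any_tumor` carry an
#' `excluded` attribute: cancer conditions do not contribute when scoring a
#' cancer cohort.
#' @return Named numeric vector with attribute `excluded`.
#' @export
default_gagne_weights <- function() {
  w <- c(metastatic_cancer = 5, chf = 2, dementia = 2, renal_failure = 2,
         weight_loss = 2, hemiplegia = 1, alcohol_abuse = 1, any_tumor = 1,
         cardiac_arrhythmia = 1, copd = 1, coagulopathy = 1,
         complicated_diabetes = 1, anemia = 1, electrolyte_disorder = 1,
         liver_disease = 1, pvd = 1, psychosis = 1, pulmonary_circulation = 1,
         hiv_aids = -1, hypertension = -1)
  attr(w, "excluded") <- c("metastatic_cancer", "any_tumor")
  w
}

# enrollment rule shared by cases and comparators: continuous FFS coverage
# over [min(diagnosis, index - 180), index]; comparators have no diagnosis
enrollment_rule_start <- function(index_date, diagnosis_date = NULL) {
  lb <- index_date - 180L
  if (is.null(diagnosis_date)) return(lb)
  out <- pmin(diagnosis_date, lb)
  out[is.na(diagnosis_date)] <- lb[is.na(diagnosis_date)]
  out
}

#' Build the adjuvant chemotherapy cohort
#'
#' Applies the eligibility chain, in order: age >= 65 at diagnosis; stage I-III;
#' primary surgery within 90 days of diagnosis (closed interval); no
#' neoadjuvant chemotherapy; adjuvant chemotherapy within 90 days after
#' surgery; continuous FFS enrollment from diagnosis to the index date or for
#' the 180 days before index, whichever window is longer. The index date is
#' the chemotherapy initiation date. Every step is recorded in an exclusion
#' ledger.
#'
#' @param bundle Validated table bundle (see [validate_bundle()]); must
#'   include `cancer`.
#' @param cmap Code map for covariate claims.
#' @param gagne_weights Condition weight map, see [default_gagne_weights()].
#' @param gap_tolerance Enrollment gap tolerance in days.
#' @return List: `cohort` (tibble of eligible cases with `index_date` and
#'   baseline covariates) and `ledger` (tibble `criterion`, `n_removed`,
#'   `n_remaining`).
#' @export
build_chemo_cohort <- function(bundle, cmap = default_codemap(),
                               gagne_weights = default_gagne_weights(),
                               gap_tolerance = 0L) {
  cancer <- bundle$cancer
  persons <- bundle$persons
  ledger <- tibble(criterion = "cancer cases",
                   n_removed = 0L, n_remaining = nrow(cancer))
  step <- function(tab, keep, name) {
    kept <- tab[keep, , drop = FALSE]
    ledger <<- bind_rows(ledger, tibble(
      criterion = name, n_removed = nrow(tab) - nrow(kept),
      n_remaining = nrow(kept)))
    kept
  }
  tab <- cancer %>%
    left_join(persons %>% select("person_id", "birth_year", "race_ethnicity",
                                 "region"),
              by = "person_id") %>%
    mutate(age_dx = as.integer(format(.data$diagnosis_date, "%Y")) -
             .data$birth_year)
  tab <- step(tab, tab$age_dx >= 65L, "age >= 65 at diagnosis")
  tab <- step(tab, tab$stage %in% c("I", "II", "III"), "stage I-III")
  surg_gap <- as.integer(tab$surgery_date - tab$diagnosis_date)
  tab <- step(tab, !is.na(surg_gap) & surg_gap >= 0L & surg_gap <= 90L,
              "surgery within 90 days of diagnosis")
  tab <- step(tab, !tab$neoadjuvant_flag, "no neoadjuvant chemotherapy")
  chemo_gap <- as.integer(tab$chemo_start_date - tab$surgery_date)
  tab <- step(tab, !is.na(chemo_gap) & chemo_gap >= 0L & chemo_gap <= 90L,
              "chemotherapy within 90 days of surgery")
  tab$index_date <- tab$chemo_start_date
  win_start <- enrollment_rule_start(tab$index_date, tab$diagnosis_date)
  enr_ok <- enrollment_covers(
    bundle$enrollment,
    tibble(person_id = tab$person_id, start = win_start, end = tab$index_date),
    gap_tolerance = gap_tolerance)
  tab <- step(tab, enr_ok, "continuous FFS enrollment")

  cohort <- tab %>%
    mutate(arm = "chemo",
           age = as.integer(format(.data$index_date, "%Y")) -
             .data$birth_year) %>%
    select("person_id", "arm", "index_date", "birth_year", "age",
           race = "race_ethnicity", "region", "stage", "grade",
           "surgery_type", "diagnosis_date")
  cohort <- add_baseline_covariates(cohort, bundle, cmap, gagne_weights)
  list(cohort = cohort, ledger = ledger)
}

# gagne score + flu flag at index for a cohort tibble (any arm)
add_baseline_covariates <- function(cohort, bundle, cmap, gagne_weights) {
  g <- gagne_score(bundle$claims, cohort %>%
                     select("person_id", anchor = "index_date"),
                   gagne_weights, cmap = cmap)
  cohort$gagne_score <- g$gagne_score
  cohort$gagne_cat <- cut(cohort$gagne_score, c(-Inf, -1, 0, 1, 2, Inf),
                          labels = c("<0", "0", "1", "2", ">=3"))
  cohort$flu_vaccine <- flu_vaccine_flag(bundle$claims, cohort %>%
                                           select("person_id",
                                                  anchor = "index_date"),
                                         cmap = cmap)$flu_vaccine
  cohort
}

#' Gagne combined comorbidity score over a 180-day lookback
#'
#' Sums condition weights over conditions with at least one mapped claim in
#' the half-open 180-day window before each anchor, excluding cancer
#' conditions (the `excluded` attribute of the weight map).
#'
#' @param claims Claims tibble.
#' @param anchors Tibble (`person_id`, `anchor`).
#' @param weights Named condition weights; see [default_gagne_weights()].
#' @param lookback_days Window length.
#' @param cmap Code map.
#' @return `anchors` with a `gagne_score` column.
#' @export
gagne_score <- function(claims, anchors, weights = default_gagne_weights(),
                        lookback_days = 180L, cmap = default_codemap()) {
  anchors <- as_tibble(anchors)
  excluded <- attr(weights, "excluded") %||% character()
  use <- setdiff(names(weights), excluded)
  mapped <- suppressWarnings(map_claims(claims, cmap))
  mapped <- mapped[mapped$indicator %in% use, , drop = FALSE]
  score <- numeric(nrow(anchors))
  if (nrow(mapped) > 0 && nrow(anchors) > 0) {
    hit <- mapped %>%
      select("person_id", "service_date", "indicator") %>%
      inner_join(anchors %>% mutate(.row = row_number()) %>%
                   select("person_id", "anchor", ".row"),
                 by = "person_id", relationship = "many-to-many") %>%
      filter(in_window(.data$service_date, .data$anchor, lookback_days)) %>%
      distinct(.data$.row, .data$indicator)
    if (nrow(hit) > 0) {
      w <- weights[hit$indicator]
      if (anyNA(w)) abort("mapped condition without a Gagne weight")
      agg <- tapply(as.numeric(w), hit$.row, sum)
      score[as.integer(names(agg))] <- agg
    }
  }
  anchors$gagne_score <- score
  anchors
}

#' Preindex flu vaccination flag
#'
#' TRUE when a flu-vaccine claim falls in the half-open 180-day window before
#' the anchor (the anchor day itself excluded).
#'
#' @inheritParams gagne_score
#' @return `anchors` with a logical `flu_vaccine` column.
#' @export
flu_vaccine_flag <- function(claims, anchors, lookback_days = 180L,
                             cmap = default_codemap()) {
  anchors <- as_tibble(anchors)
  mapped <- suppressWarnings(map_claims(claims, cmap))
  mapped <- mapped[mapped$indicator == "flu_vaccine", , drop = FALSE]
  flag <- logical(nrow(anchors))
  if (nrow(mapped) > 0 && nrow(anchors) > 0) {
    hit <- mapped %>%
      select("person_id", "service_date") %>%
      inner_join(anchors %>% mutate(.row = row_number()) %>%
                   select("person_id", "anchor", ".row"),
                 by = "person_id", relationship = "many-to-many") %>%
      filter(in_window(.data$service_date, .data$anchor, lookback_days))
    flag[unique(hit$.row)] <- TRUE
  }
  anchors$flu_vaccine <- flag
  anchors
}

#' Match noncancer comparators to chemotherapy cases
#'
#' Exact matching on year of birth and region, up to `ratio` comparators per
#' case, sampled uniformly at random *with replacement across match groups*
#' but without duplication within a group. Comparators inherit the case's
#' index date and must satisfy the same continuous-enrollment rule at that
#' date (and be alive on it). Cases with no eligible comparator keep their
#' row with an empty match group and are counted.
#'
#' @param chemo_cohort Cohort tibble from [build_chemo_cohort()].
#' @param bundle Table bundle; pool = persons without a cancer record.
#' @param ratio Maximum comparators per case (default 5).
#' @param seed Integer seed for reproducible sampling.
#' @param cmap,gagne_weights For comparator baseline covariates.
#' @param gap_tolerance Enrollment gap tolerance.
#' @return List: `cohort` (chemo + comparator rows with `match_group`) and
#'   `n_unmatched` (cases with zero eligible comparators).
#' @export
match_comparators <- function(chemo_cohort, bundle, ratio = 5L, seed = 1L,
                              cmap = default_codemap(),
                              gagne_weights = default_gagne_weights(),
                              gap_tolerance = 0L) {
  if (ratio < 1) abort("`ratio` must be >= 1")
  set.seed(seed)
  persons <- bundle$persons
  pool <- persons %>%
    anti_join(bundle$cancer, by = "person_id")
  merged <- merge_ffs_spells(bundle$enrollment, gap_tolerance)
  pool_strata <- split(seq_len(nrow(pool)),
                       paste(pool$birth_year, pool$region, sep = "\r"))
  blocks <- split(merged, merged$person_id)

  rows <- vector("list", nrow(chemo_cohort))
  n_unmatched <- 0L
  for (i in seq_len(nrow(chemo_cohort))) {
    case <- chemo_cohort[i, ]
    key <- paste(case$birth_year, case$region, sep = "\r")
    cand_idx <- pool_strata[[key]]
    if (is.null(cand_idx)) { n_unmatched <- n_unmatched + 1L; next }
    idx <- case$index_date
    cand <- pool[cand_idx, ]
    alive <- is.na(cand$death_date) | cand$death_date > idx
    covers <- vapply(cand$person_id, function(pid) {
      b <- blocks[[pid]]
      !is.null(b) && any(b$start_date <= idx - 180L & b$end_date >= idx)
    }, logical(1))
    elig <- cand$person_id[alive & covers]
    if (length(elig) == 0) { n_unmatched <- n_unmatched + 1L; next }
    take <- sample(elig, min(ratio, length(elig)))
    rows[[i]] <- tibble(person_id = take, match_group = case$person_id,
                        index_date = idx)
  }
  comp <- bind_rows(rows)
  if (nrow(comp) > 0) {
    comp <- comp %>%
      left_join(persons %>% select("person_id", "birth_year",
                                   race = "race_ethnicity", "region"),
                by = "person_id") %>%
      mutate(arm = "comparator",
             age = as.integer(format(.data$index_date, "%Y")) -
               .data$birth_year,
             stage = NA_character_, grade = NA_character_,
             surgery_type = NA_character_,
             diagnosis_date = as.Date(NA))
    comp <- add_baseline_covariates(comp, bundle, cmap, gagne_weights)
  }
  chemo <- chemo_cohort %>% mutate(match_group = .data$person_id)
  cohort <- bind_rows(chemo, comp) %>%
    select(all_of(c("person_id", "arm", "match_group", "index_date",
                    "birth_year", "age", "race", "region", "stage", "grade",
                    "surgery_type", "diagnosis_date", "gagne_score",
                    "gagne_cat", "flu_vaccine")))
  list(cohort = cohort, n_unmatched = n_unmatched)
}

#' Restrict to the preindex-screened subset
#'
#' Sensitivity subpopulation: chemo cases with a screening mammogram in the
#' 365 days before diagnosis; comparators with a mammogram in the 365 days
#' before their (inherited) index date and no cancer record at all.
#'
#' @param cohort Combined cohort tibble from [match_comparators()].
#' @param bundle Table bundle.
#' @param cmap Code map (must map `mammogram`).
#' @return Filtered cohort tibble.
#' @export
screened_subset <- function(cohort, bundle, cmap = default_codemap()) {
  anchor <- dplyr::if_else(cohort$arm == "chemo", cohort$diagnosis_date,
                           cohort$index_date)
  mapped <- suppressWarnings(map_claims(bundle$claims, cmap))
  mapped <- mapped[mapped$indicator == "mammogram", , drop = FALSE]
  anchors <- tibble(person_id = cohort$person_id, anchor = anchor)
  flag <- logical(nrow(anchors))
  if (nrow(mapped) > 0) {
    hit <- mapped %>%
      select("person_id", "service_date") %>%
      inner_join(anchors %>% mutate(.row = row_number()),
                 by = "person_id", relationship = "many-to-many") %>%
      filter(in_window(.data$service_date, .data$anchor, 365L))
    flag[unique(hit$.row)] <- TRUE
  }
  has_cancer <- cohort$person_id %in% bundle$cancer$person_id
  keep <- flag & (cohort$arm == "chemo" | !has_cancer)
  cohort[keep, , drop = FALSE]
}
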