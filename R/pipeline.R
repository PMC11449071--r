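# End-to-end convenience wrappers chaining the pipeline stages, used by the
# command-line interface and by reproducibility scripts.

#' Run the benchmark analysis end to end
#'
#' Chains cohort construction, comparator matching, frailty scoring at the
#' three timepoints, SMR + attrition weighting, panel assembly and the
#' weighted GEE fit on a table bundle.
#'
#' @param bundle Validated table bundle.
#' @param match_ratio Comparators per case.
#' @param seed Seed for comparator sampling.
#' @param model Frailty model.
#' @param cmap Code map.
#' @param screened_only Restrict to the preindex-mammogram subset.
#' @param timepoint_days T1/T2/T3 day offsets.
#' @param smr_truncate,ipaw_truncate Weight truncation percentiles.
#' @return List: `cohort`, `ledger`, `balance`, `panel`, `fit`
#'   (`frailty_gee`), `means` (marginal means), `scores`.
#' @export
run_benchmark_pipeline <- function(bundle, match_ratio = 5L, seed = 1L,
                                   model = default_frailty_model(),
                                   cmap = default_codemap(),
                                   screened_only = FALSE,
                                   timepoint_days = c(0L, 120L, 300L),
                                   smr_truncate = 0.99,
                                   ipaw_truncate = 0.99) {
  built <- build_chemo_cohort(bundle, cmap = cmap)
  matched <- match_comparators(built$cohort, bundle, ratio = match_ratio,
                               seed = seed, cmap = cmap)
  cohort <- matched$cohort
  if (screened_only) cohort <- screened_subset(cohort, bundle, cmap)
  ps <- fit_propensity(cohort)
  cohort <- smr_weights(ps, cohort, truncate_pct = smr_truncate)
  balance <- balance_table(cohort)

  # frailty scores at the three anchors for everyone still under observation
  anchors <- tidyr::crossing(
    cohort %>% distinct(.data$person_id, .data$index_date),
    offset = timepoint_days) %>%
    mutate(anchor = .data$index_date + .data$offset)
  iv <- extract_indicators(bundle$claims, bundle$persons,
                           anchors %>% select("person_id", "anchor"),
                           cmap = cmap)
  scores <- frailty_score(iv, model) %>% distinct()

  panel_attr <- build_attrition_panel(cohort, bundle, scores = scores,
                                      timepoint_days = timepoint_days,
                                      cmap = cmap)
  att <- fit_attrition_models(panel_attr)
  ipaw <- ipaw_weights(att, truncate_pct = ipaw_truncate)

  # observation status per person-timepoint: alive and FFS-covered at anchor
  dd <- bundle$persons$death_date[match(anchors$person_id,
                                        bundle$persons$person_id)]
  alive <- is.na(dd) | anchors$anchor < dd
  covered <- enrollment_covers(
    bundle$enrollment,
    tibble(person_id = anchors$person_id, start = anchors$index_date,
           end = anchors$anchor))
  observed <- anchors %>%
    mutate(timepoint = match(.data$offset, timepoint_days)) %>%
    filter(alive & covered) %>%
    distinct(.data$person_id, .data$timepoint)

  panel <- build_panel(cohort, scores, ipaw = ipaw, observed = observed,
                       timepoint_days = timepoint_days)
  fit <- fit_gee(panel)
  list(cohort = cohort, ledger = built$ledger,
       n_unmatched = matched$n_unmatched, balance = balance, panel = panel,
       fit = fit, means = marginal_means(fit), scores = scores,
       attrition = att)
}

#' Run the trajectory analysis end to end
#'
#' Monthly frailty score series for the chemo arm, trajectory matrix,
#' cluster-count selection, labels and the nonresilience predictor model.
#'
#' @param bundle Validated table bundle.
#' @param cohort Chemo-arm cohort tibble (e.g. from [build_chemo_cohort()]).
#' @param k_range Candidate cluster counts.
#' @param n_starts,seed Clustering controls.
#' @param model,cmap Scoring configuration.
#' @param min_observed Minimum observed anchors per person.
#' @return List: `series`, `traj`, `solution`, `labels`, `design`,
#'   `predictor_fit` (NULL when the outcome is degenerate).
#' @export
run_trajectory_pipeline <- function(bundle, cohort, k_range = 2:8,
                                    n_starts = 20L, seed = 1L,
                                    model = default_frailty_model(),
                                    cmap = default_codemap(),
                                    min_observed = 3L) {
  chemo <- cohort %>% filter(.data$arm == "chemo")
  series <- score_series(bundle$claims, bundle$persons, bundle$enrollment,
                         chemo %>% select("person_id", t0 = "index_date"),
                         model = model, cmap = cmap)
  traj <- build_trajectories(series, min_observed = min_observed)
  solution <- select_k(traj, k_range = k_range, n_starts = n_starts,
                       seed = seed)
  labels <- label_clusters(solution)
  iv <- extract_indicators(bundle$claims, bundle$persons,
                           chemo %>% select("person_id",
                                            anchor = "index_date"),
                           cmap = cmap)
  design <- build_design(chemo, solution, iv, labels)
  pfit <- NULL
  if (length(unique(design$nonresilient)) == 2) {
    pfit <- tryCatch(fit_nonresilience(design), error = function(e) {
      warn(paste0("predictor model not fit: ", conditionMessage(e)))
      NULL
    })
  }
  list(series = series, traj = traj, solution = solution, labels = labels,
       design = design, predictor_fit = pfit)
}
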