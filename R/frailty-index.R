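# Frailty scoring: indicator extraction over rolling 180-day windows,
# logistic scoring, monthly score series, and indicator prevalence reports.

#' Extract binary frailty indicators at anchor dates
#'
#' For each `(person_id, anchor)` pair, flags each of the 20 frailty
#' indicators as 1 if at least one mapped claim falls in the half-open
#' `[anchor - lookback_days, anchor)` window (binary semantics: repeat claims
#' do not accumulate). Age at the anchor is `year(anchor) - birth_year`.
#'
#' @param claims Claims tibble (`person_id`, `service_date`, `code`,
#'   `code_system`).
#' @param persons Persons tibble.
#' @param anchors Tibble with columns `person_id`, `anchor` (Date). A single
#'   Date may also be given, applied to every person in `persons`.
#' @param lookback_days Window length, default 180.
#' @param cmap A [codemap()]; defaults to the synthetic identity map.
#' @return Tibble: `person_id`, `anchor`, `age_at_anchor`, `race_ethnicity`,
#'   and one 0/1 column per indicator.
#' @export
extract_indicators <- function(claims, persons, anchors, lookback_days = 180L,
                               cmap = default_codemap()) {
  if (inherits(anchors, "Date")) {
    anchors <- tibble(person_id = persons$person_id, anchor = anchors)
  }
  anchors <- as_tibble(anchors)
  stopifnot(all(c("person_id", "anchor") %in% names(anchors)))
  inds <- frailty_indicators()
  mapped <- suppressWarnings(map_claims(claims, cmap))
  mapped <- mapped[mapped$indicator %in% inds, , drop = FALSE]
  base <- anchors %>%
    left_join(persons %>% select("person_id", "birth_year", "race_ethnicity"),
              by = "person_id") %>%
    mutate(age_at_anchor = as.integer(format(.data$anchor, "%Y")) -
             .data$birth_year)
  flag_mat <- matrix(0L, nrow(base), length(inds),
                     dimnames = list(NULL, inds))
  if (nrow(mapped) > 0 && nrow(base) > 0) {
    # join claims to anchor rows per person, then apply the window test
    hit <- mapped %>%
      select("person_id", "service_date", "indicator") %>%
      inner_join(base %>% mutate(.row = row_number()) %>%
                   select("person_id", "anchor", ".row"),
                 by = "person_id", relationship = "many-to-many") %>%
      filter(in_window(.data$service_date, .data$anchor, lookback_days)) %>%
      distinct(.data$.row, .data$indicator)
    if (nrow(hit) > 0) {
      flag_mat[cbind(hit$.row, match(hit$indicator, inds))] <- 1L
    }
  }
  dplyr::bind_cols(
    base %>% select("person_id", "anchor", "age_at_anchor", "race_ethnicity"),
    as_tibble(flag_mat))
}

# linear predictor of the frailty model on an indicator tibble
frailty_linpred <- function(model, iv) {
  race <- iv$race_ethnicity
  unknown_race <- !(race %in% names(model$race))
  if (any(unknown_race | is.na(race))) {
    warn("unknown/missing race categories scored at the reference level")
  }
  race_eff <- model$race[race]
  race_eff[is.na(race_eff)] <- 0
  eta <- model$intercept +
    model$age_per_year * (iv$age_at_anchor - 65) +
    as.numeric(race_eff)
  for (ind in frailty_indicators()) {
    if (!ind %in% names(iv)) {
      abort(paste0("indicator column missing from input: ", ind))
    }
    eta <- eta + model$indicators[[ind]] * iv[[ind]]
  }
  eta
}

#' Score frailty from extracted indicators
#'
#' Computes the claims-based frailty score
#' `plogis(intercept + demographic terms + sum(coef_j * flag_j))`, a predicted
#' probability of frailty strictly inside (0, 1).
#'
#' @param iv Indicator tibble from [extract_indicators()].
#' @param model A [frailty_model()]; defaults to the synthetic default.
#' @return Tibble: `person_id`, `anchor`, `score`, `model_id`.
#' @export
frailty_score <- function(iv, model = default_frailty_model()) {
  tibble(person_id = iv$person_id, anchor = iv$anchor,
         score = plogis(frailty_linpred(model, iv)),
         model_id = model$model_id)
}

#' Monthly frailty score series
#'
#' Scores each person at anchors `t0 + 0, 30, ..., horizon_days` (13 anchors
#' by default), each with its own 180-day lookback window. Anchors on or after
#' death, or after the end of continuous FFS coverage from `t0`, are omitted,
#' so missingness is always a suffix of the series.
#'
#' @param claims,persons,cmap As in [extract_indicators()].
#' @param enrollment Enrollment spells tibble.
#' @param t0 Tibble (`person_id`, `t0`) of series origins (typically index
#'   dates), or a single Date for all persons.
#' @param interval_days,horizon_days Series spacing and length (defaults 30
#'   and 360: thirteen 30-day anchors including day 0).
#' @param lookback_days Ascertainment window, default 180.
#' @param model Frailty model.
#' @return Tibble: `person_id`, `anchor_index` (0-based month), `anchor`,
#'   `score`, `model_id`, one row per *observed* person-anchor.
#' @export
score_series <- function(claims, persons, enrollment, t0,
                         interval_days = 30L, horizon_days = 360L,
                         lookback_days = 180L,
                         model = default_frailty_model(),
                         cmap = default_codemap()) {
  if (inherits(t0, "Date")) {
    t0 <- tibble(person_id = persons$person_id, t0 = t0)
  }
  offsets <- seq(0L, horizon_days, by = interval_days)
  grid <- tidyr::crossing(t0, anchor_index = seq_along(offsets) - 1L) %>%
    mutate(anchor = .data$t0 + offsets[.data$anchor_index + 1L])
  # observation rule: alive (anchor strictly before death) and continuous FFS
  # coverage from t0 through the anchor
  dd <- persons$death_date[match(grid$person_id, persons$person_id)]
  alive <- is.na(dd) | grid$anchor < dd
  covered <- enrollment_covers(
    enrollment, tibble(person_id = grid$person_id, start = grid$t0,
                       end = grid$anchor))
  grid <- grid[alive & covered, , drop = FALSE]
  iv <- extract_indicators(claims, persons,
                           grid %>% select("person_id", "anchor"),
                           lookback_days = lookback_days, cmap = cmap)
  scores <- frailty_score(iv, model)
  grid %>%
    select("person_id", "anchor_index", "anchor") %>%
    dplyr::bind_cols(scores %>% select("score", "model_id")) %>%
    arrange(.data$person_id, .data$anchor_index)
}

#' Indicator prevalence by anchor
#'
#' Fraction of persons with each indicator flagged, per named anchor offset,
#' among persons under observation at that anchor — the shape of the
#' indicator-prevalence sensitivity report (e.g. cancer screening falling
#' sharply between the index date and 4 months post-index).
#'
#' @param cohort Tibble with `person_id` and `index_date`.
#' @param anchor_offsets Named integer vector of day offsets from
#'   `index_date`, e.g. `c(T1 = 0, T2 = 120, T3 = 300)`.
#' @param claims,persons,cmap As in [extract_indicators()].
#' @param observed Optional tibble (`person_id`, `anchor_name`) restricting
#'   which persons count as observed at each anchor; default everyone.
#' @param lookback_days Window length.
#' @return Tibble: `indicator`, one column per anchor name with prevalences.
#' @export
indicator_prevalence <- function(cohort, anchor_offsets, claims, persons,
                                 observed = NULL, lookback_days = 180L,
                                 cmap = default_codemap()) {
  stopifnot(nrow(cohort) > 0, !is.null(names(anchor_offsets)))
  mapped_any <- suppressWarnings(map_claims(claims, cmap))
  absent <- setdiff(frailty_indicators(), unique(mapped_any$indicator))
  if (length(absent) > 0) {
    warn(paste0("indicator(s) with no mapped claims anywhere: ",
                paste(absent, collapse = ", ")))
  }
  res <- purrr::imap(anchor_offsets, function(off, nm) {
    sub <- cohort
    if (!is.null(observed)) {
      keep <- observed$person_id[observed$anchor_name == nm]
      sub <- sub[sub$person_id %in% keep, , drop = FALSE]
    }
    iv <- extract_indicators(
      claims, persons,
      tibble(person_id = sub$person_id, anchor = sub$index_date + off),
      lookback_days = lookback_days, cmap = cmap)
    colMeans(iv[, frailty_indicators(), drop = FALSE])
  })
  out <- tibble(indicator = frailty_indicators())
  for (nm in names(res)) out[[nm]] <- as.numeric(res[[nm]])
  out
}
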