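# Small hand-built fixtures shared across test files. Everything is
# constructed in code (no fixture files): dates, spells and claims are chosen
# so the expected answers can be worked out on paper.

d <- function(x) as.Date(x)

mk_persons <- function(ids, birth_year = 1940L, region = "West",
                       race = "White", death = as.Date(NA)) {
  tibble::tibble(person_id = ids, birth_year = as.integer(birth_year),
                 sex = "F", race_ethnicity = race, region = region,
                 death_date = rep_len(death, length(ids)))
}

mk_enroll <- function(ids, start, end, coverage = "FFS") {
  tibble::tibble(person_id = ids, start_date = d(start), end_date = d(end),
                 coverage = coverage)
}

mk_claims <- function(ids, dates, codes) {
  tibble::tibble(person_id = ids, service_date = d(dates), code = codes,
                 code_system = "SYN")
}

empty_claims <- function() mk_claims(character(), character(), character())

mk_cancer <- function(ids, dx, surgery, chemo, stage = "II",
                      grade = "moderate", surgery_type = "BCT", neo = FALSE) {
  tibble::tibble(person_id = ids, diagnosis_date = d(dx), stage = stage,
                 grade = grade, surgery_date = d(surgery),
                 surgery_type = surgery_type, chemo_start_date = d(chemo),
                 neoadjuvant_flag = neo)
}

# indicator tibble with every flag 0 except those named in `flags`
mk_iv <- function(person_id = "A", anchor = d("2010-06-01"), age = 70,
                  race = "White", flags = character()) {
  iv <- tibble::tibble(person_id = person_id, anchor = anchor,
                       age_at_anchor = age, race_ethnicity = race)
  for (ind in frailty_indicators()) {
    iv[[ind]] <- as.integer(ind %in% flags)
  }
  iv
}

# frailty model with all coefficients zero (score = plogis(intercept))
zero_model <- function(intercept = 0) {
  frailty_model(
    intercept = intercept, age_per_year = 0,
    race = c(White = 0, Black = 0, Hispanic = 0, API = 0, `AI/AN` = 0,
             missing = 0),
    indicators = stats::setNames(rep(0, 20), frailty_indicators()),
    model_id = "zero")
}

# --- independent re-implementations used as oracles ------------------------
# (deliberately written from the documented formulas, not via package
# internals)

# rescaled missing-aware squared distance between two rows
oracle_d2 <- function(a, b) {
  sh <- !is.na(a) & !is.na(b)
  length(a) / sum(sh) * sum((a[sh] - b[sh])^2)
}

# anchor-wise centers weighted by each person's T / T_obs
oracle_center <- function(X, fallback) {
  Tn <- ncol(X)
  w <- Tn / rowSums(!is.na(X))
  sapply(seq_len(Tn), function(t) {
    obs <- !is.na(X[, t])
    if (!any(obs)) return(fallback[t])
    sum(w[obs] * X[obs, t]) / sum(w[obs])
  })
}

# total within-cluster sum for a 2-cluster membership vector
oracle_within <- function(X, member, fallback) {
  tot <- 0
  for (c in 1:2) {
    rows <- which(member == c)
    ctr <- oracle_center(X[rows, , drop = FALSE], fallback)
    tot <- tot + sum(vapply(rows, function(i) oracle_d2(X[i, ], ctr),
                            numeric(1)))
  }
  tot
}

# exhaustive minimum within-cluster sum over all 2-partitions
oracle_best_2partition <- function(X, fallback) {
  n <- nrow(X)
  best <- Inf
  for (bits in 1:(2^(n - 1) - 1)) {
    member <- c(1L, 1L + as.integer(intToBits(bits))[1:(n - 1)])
    best <- min(best, oracle_within(X, member, fallback))
  }
  best
}
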