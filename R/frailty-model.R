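# The claims-based frailty proxy model: a logistic model mapping demographics
# plus 20 binary claims indicators to a predicted probability of frailty.
# The originally published coefficient values are not reproduced here; the
# package ships a documented synthetic default (screening indicators
# protective, deficit indicators deleterious) and accepts YAML overrides.

#' The 20 frailty-index indicators
#'
#' Names of the binary claims indicators entering the frailty score:
#' 18 deficit indicators (e.g. wheelchairs, home hospital beds, dementia) and
#' 2 screening-service indicators (`cancer_screening`, `lipid_abnormality`)
#' that signal routine preventive care and lower the score.
#' @return Character vector of length 20.
#' @export
frailty_indicators <- function() {
  c("parkinsons", "home_hospital_bed", "wheelchair", "home_oxygen",
    "paralysis", "podiatric_care", "psychiatric_disease", "dementia",
    "skin_ulcer", "stroke_brain_injury", "ambulance", "bladder_dysfunction",
    "arthritis", "vertigo", "heart_failure", "weakness", "lipid_abnormality",
    "rehabilitation", "cancer_screening", "hypotension_shock")
}

#' Construct a frailty model
#'
#' @param intercept Real intercept of the logistic score model.
#' @param age_per_year Coefficient per year of age above 65.
#' @param race Named numeric vector of race/ethnicity effects (reference:
#'   `White`; missing race falls back to the reference with a warning).
#' @param indicators Named numeric vector with one coefficient for every
#'   indicator in [frailty_indicators()].
#' @param removable_screening Indicators whose coefficients the screening
#'   sensitivity analysis zeroes out.
#' @param model_id Identifier stored on every score.
#' @return A `frailty_model` object.
#' @export
frailty_model <- function(intercept, age_per_year, race, indicators,
                          removable_screening = c("cancer_screening",
                                                  "lipid_abnormality"),
                          model_id = "custom") {
  missing_ind <- setdiff(frailty_indicators(), names(indicators))
  if (length(missing_ind) > 0) {
    abort(paste0("missing indicator coefficient(s): ",
                 paste(missing_ind, collapse = ", ")))
  }
  if (!all(removable_screening %in% frailty_indicators())) {
    abort("`removable_screening` must be a subset of frailty_indicators()")
  }
  structure(list(intercept = intercept, age_per_year = age_per_year,
                 race = race, indicators = indicators[frailty_indicators()],
                 removable_screening = removable_screening,
                 model_id = model_id),
            class = "frailty_model")
}

#' Default synthetic frailty model
#'
#' A documented synthetic coefficient set: deficit indicators carry positive
#' weights (scaled so durable medical equipment and neurologic deficits move
#' the score most), the two screening indicators carry negative weights, and
#' age adds a small per-year increment above 65. The intercept is calibrated
#' so that scoring the default synthetic population with this model returns a
#' cohort mean near 0.04 at chemotherapy initiation. These values are a
#' stand-in for the originally published (unprinted here) coefficients;
#' override via [read_frailty_model()].
#' @return A `frailty_model`.
#' @export
default_frailty_model <- function() {
  frailty_model(
    intercept = -4.40,
    age_per_year = 0.03,
    race = c(White = 0, Black = 0.15, Hispanic = 0.05, API = -0.05,
             `AI/AN` = 0.10, missing = 0),
    indicators = c(
      parkinsons = 1.0, home_hospital_bed = 1.3, wheelchair = 1.2,
      home_oxygen = 0.9, paralysis = 1.1, podiatric_care = 0.3,
      psychiatric_disease = 0.4, dementia = 1.1, skin_ulcer = 0.9,
      stroke_brain_injury = 0.7, ambulance = 0.8, bladder_dysfunction = 0.5,
      arthritis = 0.2, vertigo = 0.3, heart_failure = 0.5, weakness = 0.6,
      lipid_abnormality = -0.3, rehabilitation = 0.4, cancer_screening = -0.5,
      hypotension_shock = 0.6),
    model_id = "synthetic-default")
}

#' Read a frailty model from YAML
#'
#' YAML keys: `intercept`, `age_per_year`, `race` (map), `indicators` (map of
#' all 20 coefficients), optional `removable_screening` (list), `model_id`.
#' @param path YAML file path.
#' @return A `frailty_model`.
#' @export
read_frailty_model <- function(path) {
  y <- yaml::read_yaml(path)
  frailty_model(
    intercept = y$intercept,
    age_per_year = y$age_per_year,
    race = unlist(y$race),
    indicators = unlist(y$indicators),
    removable_screening = unlist(y$removable_screening) %||%
      c("cancer_screening", "lipid_abnormality"),
    model_id = y$model_id %||% "yaml")
}

#' Screening sensitivity variant of a frailty model
#'
#' Returns a model in which the coefficients of `removed` indicators are
#' forced to zero (their flags are still extracted, so prevalence reports are
#' unchanged). Idempotent. Used for the sensitivity analysis that drops the
#' cancer- and lipid-screening indicators so score changes cannot be driven
#' by deferred routine care.
#'
#' @param model A `frailty_model`.
#' @param removed Character vector of indicator names; defaults to the model's
#'   removable screening set.
#' @return A `frailty_model` with suffixed `model_id`.
#' @export
apply_sensitivity <- function(model, removed = model$removable_screening) {
  unknown <- setdiff(removed, frailty_indicators())
  if (length(unknown) > 0) {
    abort(paste0("unknown indicator(s): ", paste(unknown, collapse = ", ")))
  }
  if (length(removed) == 0) return(model)
  model$indicators[removed] <- 0
  if (!grepl("-noscreen$", model$model_id)) {
    model$model_id <- paste0(model$model_id, "-noscreen")
  }
  model
}

#' @export
print.frailty_model <- function(x, ...) {
  cat("<frailty_model>", x$model_id, "\n")
  cat("  intercept:", x$intercept, " age/yr:", x$age_per_year, "\n")
  cat("  indicators:", length(x$indicators), "(",
      sum(x$indicators > 0), "deleterious /", sum(x$indicators < 0),
      "protective /", sum(x$indicators == 0), "zeroed )\n")
  invisible(x)
}
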