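# Core claims-data conventions: ascertainment windows, continuous enrollment,
# table-bundle validation and IO. Every other stage calls in_window() and
# continuous_enrollment() rather than re-deriving date logic.

#' Is a service date inside a lookback window?
#'
#' Windows are half-open: `[anchor - lookback_days, anchor)`. The anchor day
#' itself is *excluded*, so claims generated by same-day treatment never leak
#' into the window anchored on the treatment date. All lookback logic in the
#' package goes through this function.
#'
#' @param service_date,anchor `Date` vectors (recycled against each other).
#' @param lookback_days Positive integer, length of the window in days
#'   (default 180, the 6-month ascertainment window).
#' @return Logical vector.
#' @examples
#' a <- as.Date("2010-06-01")
#' in_window(a - 1, a)            # TRUE
#' in_window(a, a)                # FALSE: anchor day excluded
#' in_window(a - 180, a)          # TRUE: inclusive lower boundary
#' in_window(a - 181, a)          # FALSE
#' @export
in_window <- function(service_date, anchor, lookback_days = 180L) {
  if (any(lookback_days <= 0)) {
    abort("`lookback_days` must be positive.")
  }
  service_date >= (anchor - lookback_days) & service_date < anchor
}

#' Continuous fee-for-service enrollment over an interval
#'
#' Checks that the union of a person's FFS enrollment spells covers
#' `[start, end]` with at most `gap_tolerance` uncovered days between spells.
#' Abutting spells (one ends the day before the next starts, or they share a
#' boundary day) count as continuous.
#'
#' @param spells Data frame with columns `start_date`, `end_date`, `coverage`.
#'   Rows with `coverage != "FFS"` are ignored.
#' @param start,end `Date` scalars, `start <= end`.
#' @param gap_tolerance Allowed gap in days between consecutive spells
#'   (default 0; administrative data sometimes carry 1-day artifacts).
#' @return Logical scalar.
#' @export
continuous_enrollment <- function(spells, start, end, gap_tolerance = 0L) {
  stopifnot(start <= end)
  ffs <- spells[spells$coverage == "FFS", , drop = FALSE]
  if (nrow(ffs) == 0) return(FALSE)
  ffs <- ffs[order(ffs$start_date), , drop = FALSE]
  cover_start <- ffs$start_date[1]
  cover_end <- ffs$end_date[1]
  if (nrow(ffs) > 1) {
    for (i in seq(2, nrow(ffs))) {
      gap <- as.integer(ffs$start_date[i] - cover_end) - 1L
      if (gap <= gap_tolerance) {
        cover_end <- max(cover_end, ffs$end_date[i])
      } else {
        if (cover_start <= start && cover_end >= end) return(TRUE)
        # a real gap before `end` but after `start` breaks continuity unless a
        # later merged block covers the whole interval on its own
        cover_start <- ffs$start_date[i]
        cover_end <- ffs$end_date[i]
      }
    }
  }
  cover_start <= start && cover_end >= end
}

# Vectorized enrollment check for many (person, interval) pairs.
# intervals: tibble(person_id, start, end). Returns logical per row.
enrollment_covers <- function(spells, intervals, gap_tolerance = 0L) {
  merged <- merge_ffs_spells(spells, gap_tolerance)
  out <- logical(nrow(intervals))
  idx <- split(seq_len(nrow(intervals)), intervals$person_id)
  blocks <- split(merged, merged$person_id)
  for (pid in names(idx)) {
    b <- blocks[[pid]]
    rows <- idx[[pid]]
    if (is.null(b)) next
    for (r in rows) {
      out[r] <- any(b$start_date <= intervals$start[r] &
                      b$end_date >= intervals$end[r])
    }
  }
  out
}

# Merge a person's FFS spells into maximal continuous blocks.
merge_ffs_spells <- function(spells, gap_tolerance = 0L) {
  ffs <- spells[spells$coverage == "FFS", , drop = FALSE]
  ffs <- ffs[order(ffs$person_id, ffs$start_date), , drop = FALSE]
  if (nrow(ffs) == 0) {
    return(tibble(person_id = character(), start_date = as.Date(character()),
                  end_date = as.Date(character())))
  }
  new_person <- c(TRUE, ffs$person_id[-1] != ffs$person_id[-nrow(ffs)])
  # running block id: new block when person changes or gap exceeds tolerance
  block <- integer(nrow(ffs))
  cur <- 0L
  cur_end <- as.Date(NA)
  for (i in seq_len(nrow(ffs))) {
    if (new_person[i] ||
        (as.integer(ffs$start_date[i] - cur_end) - 1L) > gap_tolerance) {
      cur <- cur + 1L
      cur_end <- ffs$end_date[i]
    } else {
      cur_end <- max(cur_end, ffs$end_date[i])
    }
    block[i] <- cur
  }
  ffs$block <- block
  ffs %>%
    group_by(.data$person_id, .data$block) %>%
    summarise(start_date = min(.data$start_date),
              end_date = max(.data$end_date), .groups = "drop") %>%
    select("person_id", "start_date", "end_date")
}

race_levels <- function() c("White", "Black", "Hispanic", "API", "AI/AN", "missing")
region_levels <- function() c("Northeast", "West", "Midwest", "South")
stage_levels <- function() c("I", "II", "III", "other")
grade_levels <- function() c("well", "moderate", "poor", "undifferentiated", "missing")

bundle_schemas <- function() {
  list(
    persons = c(person_id = "character", birth_year = "integer",
                sex = "character", race_ethnicity = "character",
                region = "character", death_date = "Date"),
    enrollment = c(person_id = "character", start_date = "Date",
                   end_date = "Date", coverage = "character"),
    claims = c(person_id = "character", service_date = "Date",
               code = "character", code_system = "character"),
    cancer = c(person_id = "character", diagnosis_date = "Date",
               stage = "character", grade = "character",
               surgery_date = "Date", surgery_type = "character",
               chemo_start_date = "Date", neoadjuvant_flag = "logical")
  )
}

#' Validate a claims table bundle
#'
#' Checks schemas and cross-table invariants on a bundle of `persons`,
#' `enrollment`, `claims` and (optionally) `cancer` tables. Date-logic
#' violations (claims strictly after death, reversed spell dates, overlapping
#' same-coverage spells, cancer treatment dates out of order) are hard errors;
#' claims outside any enrollment spell only raise a warning, since orphan
#' claims are common in administrative extracts.
#'
#' @param bundle Named list of tibbles: `persons`, `enrollment`, `claims`,
#'   optionally `cancer`.
#' @return The bundle, invisibly, with a `validation` attribute holding a
#'   tibble of warnings.
#' @export
validate_bundle <- function(bundle) {
  schemas <- bundle_schemas()
  for (nm in c("persons", "enrollment", "claims")) {
    if (is.null(bundle[[nm]])) abort(paste0("bundle is missing table `", nm, "`"))
  }
  for (nm in intersect(names(schemas), names(bundle))) {
    tab <- bundle[[nm]]
    sch <- schemas[[nm]]
    missing_cols <- setdiff(names(sch), names(tab))
    if (length(missing_cols) > 0) {
      abort(paste0("table `", nm, "` is missing column(s): ",
                   paste(missing_cols, collapse = ", ")))
    }
    for (col in names(sch)) {
      want <- sch[[col]]
      x <- tab[[col]]
      ok <- switch(want,
        character = is.character(x),
        integer = is.numeric(x),
        logical = is.logical(x),
        Date = inherits(x, "Date"))
      if (!ok) {
        abort(paste0("table `", nm, "`, column `", col, "`: expected ", want))
      }
    }
  }
  persons <- bundle$persons
  if (anyDuplicated(persons$person_id)) {
    abort("`persons$person_id` must be unique")
  }
  enr <- bundle$enrollment
  if (nrow(enr) > 0 && any(enr$start_date > enr$end_date)) {
    abort("enrollment spells with start_date > end_date")
  }
  # overlap within person x coverage
  if (nrow(enr) > 1) {
    ov <- enr %>%
      arrange(.data$person_id, .data$coverage, .data$start_date) %>%
      group_by(.data$person_id, .data$coverage) %>%
      mutate(prev_end = dplyr::lag(.data$end_date)) %>%
      ungroup() %>%
      filter(!is.na(.data$prev_end) & .data$start_date <= .data$prev_end)
    if (nrow(ov) > 0) {
      abort(paste0("overlapping enrollment spells within coverage for person(s): ",
                   paste(unique(ov$person_id), collapse = ", ")))
    }
  }
  # claims after death are a hard error
  cl <- bundle$claims
  if (nrow(cl) > 0) {
    dd <- persons$death_date[match(cl$person_id, persons$person_id)]
    bad <- !is.na(dd) & cl$service_date > dd
    if (any(bad)) {
      abort(paste0("claims dated after death for person(s): ",
                   paste(unique(cl$person_id[bad]), collapse = ", ")))
    }
  }
  warnings <- tibble(check = character(), n = integer())
  # orphan claims: outside every enrollment spell (warning only)
  if (nrow(cl) > 0) {
    iv <- tibble(person_id = cl$person_id, start = cl$service_date,
                 end = cl$service_date)
    covered <- enrollment_covers_any(bundle$enrollment, iv)
    n_orphan <- sum(!covered)
    if (n_orphan > 0) {
      warn(paste0(n_orphan, " claim(s) fall outside every enrollment spell"))
      warnings <- bind_rows(warnings, tibble(check = "orphan_claims",
                                             n = as.integer(n_orphan)))
    }
  }
  if (!is.null(bundle$cancer) && nrow(bundle$cancer) > 0) {
    cr <- bundle$cancer
    bad <- (!is.na(cr$surgery_date) & cr$surgery_date < cr$diagnosis_date) |
      (!is.na(cr$surgery_date) & !is.na(cr$chemo_start_date) &
         cr$chemo_start_date < cr$surgery_date)
    if (any(bad)) {
      abort(paste0("cancer records with out-of-order dates for person(s): ",
                   paste(cr$person_id[bad], collapse = ", ")))
    }
  }
  attr(bundle, "validation") <- warnings
  invisible(bundle)
}

# any-coverage containment (claims may sit in HMO spells too)
enrollment_covers_any <- function(spells, intervals) {
  sp <- spells
  sp$coverage <- "FFS"  # treat all coverages alike for orphan detection
  enrollment_covers(sp, intervals)
}

#' Read a claims table bundle from disk
#'
#' Reads `persons`, `enrollment`, `claims` and optionally `cancer` tables from
#' CSV (RFC-4180, ISO-8601 dates) or Parquet (via the arrow package), then
#' runs [validate_bundle()].
#'
#' @param paths Named character vector or list of file paths; names among
#'   `persons`, `enrollment`, `claims`, `cancer`.
#' @return Validated bundle (named list of tibbles).
#' @export
read_bundle <- function(paths) {
  schemas <- bundle_schemas()
  bundle <- lapply(set_names(names(paths)), function(nm) {
    path <- paths[[nm]]
    if (!file.exists(path)) abort(paste0("file not found: ", path))
    sch <- schemas[[nm]]
    if (grepl("\\.parquet$", path)) {
      if (!requireNamespace("arrow", quietly = TRUE)) {
        abort("reading parquet requires the arrow package")
      }
      tab <- as_tibble(arrow::read_parquet(path))
    } else {
      cts <- lapply(sch, function(t) switch(t,
        character = readr::col_character(),
        integer = readr::col_integer(),
        logical = readr::col_logical(),
        Date = readr::col_date()))
      tab <- readr::read_csv(path, col_types = do.call(readr::cols, cts),
                             progress = FALSE)
      probs <- readr::problems(tab)
      if (nrow(probs) > 0) {
        abort(paste0("parse failure in ", path, " (", nrow(probs),
                     " problem rows; first column affected: ",
                     probs$col[1], ")"))
      }
    }
    tab
  })
  validate_bundle(bundle)
  bundle
}

#' Write a claims table bundle to disk
#'
#' @param bundle Named list of tibbles (see [validate_bundle()]).
#' @param dir Output directory (created if needed).
#' @param format `"csv"` (default) or `"parquet"`.
#' @return Named vector of file paths, invisibly.
#' @export
write_bundle <- function(bundle, dir, format = c("csv", "parquet")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- intersect(c("persons", "enrollment", "claims", "cancer", "truth"),
                    names(bundle))
  paths <- set_names(file.path(dir, paste0(tabs, ".", format)), tabs)
  for (nm in tabs) {
    if (format == "csv") {
      readr::write_csv(bundle[[nm]], paths[[nm]], progress = FALSE)
    } else {
      if (!requireNamespace("arrow", quietly = TRUE)) {
        abort("writing parquet requires the arrow package")
      }
      arrow::write_parquet(bundle[[nm]], paths[[nm]])
    }
  }
  invisible(paths)
}

#' Code-to-indicator map
#'
#' Maps `(code_system, code)` pairs to named indicators: the 20 frailty-index
#' indicators, comorbidity conditions, and service codes (`surgery`,
#' `chemotherapy`, `mammogram`, `flu_vaccine`). In synthetic mode
#' (`code_system == "SYN"`) codes are the indicator names themselves.
#'
#' @param mapping Tibble with columns `code_system`, `code`, `indicator`.
#' @return A `codemap` object.
#' @export
codemap <- function(mapping) {
  mapping <- as_tibble(mapping)
  stopifnot(all(c("code_system", "code", "indicator") %in% names(mapping)))
  dup <- mapping %>% count(.data$code_system, .data$code) %>% filter(n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("code(s) mapped to more than one indicator: ",
                 paste(dup$code, collapse = ", ")))
  }
  structure(list(mapping = mapping), class = "codemap")
}

#' Default synthetic code map
#'
#' Identity map for abstract synthetic codes: every frailty indicator,
#' comorbidity condition and service name maps to itself under code system
#' `SYN`.
#' @return A `codemap`.
#' @export
default_codemap <- function() {
  nms <- c(frailty_indicators(), names(default_gagne_weights()),
           "surgery", "chemotherapy", "mammogram", "flu_vaccine")
  nms <- unique(nms)
  codemap(tibble(code_system = "SYN", code = nms, indicator = nms))
}

#' Read a code map from YAML
#'
#' Expected layout: `indicators: {wheelchair: {system: HCPCS, codes: [E1234]}}`.
#' @param path YAML file path.
#' @return A `codemap`.
#' @export
read_codemap <- function(path) {
  y <- yaml::read_yaml(path)
  rows <- purrr::imap(y$indicators, function(entry, ind) {
    tibble(code_system = entry$system %||% "SYN",
           code = as.character(entry$codes), indicator = ind)
  })
  codemap(bind_rows(rows))
}

# Map claims to indicators; unmapped codes are dropped with a counted warning.
map_claims <- function(claims, cmap) {
  m <- cmap$mapping
  key <- paste(claims$code_system, claims$code, sep = "\r")
  mkey <- paste(m$code_system, m$code, sep = "\r")
  ind <- m$indicator[match(key, mkey)]
  n_unmapped <- sum(is.na(ind) & nrow(claims) > 0)
  if (n_unmapped > 0) {
    warn(paste0(n_unmapped, " claim(s) had unmapped codes and were ignored"))
  }
  claims$indicator <- ind
  claims[!is.na(ind), , drop = FALSE]
}
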