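# ESMO-MCBS v1.1, non-curative forms: form selection by primary endpoint
# (2a OS, 2b PFS, 2c other/non-inferiority), preliminary grade from the lower
# 95% confidence bound of the hazard ratio and the absolute survival gain via
# a threshold table banded on the control-arm median, then at most one level
# of adjustment upgrade (early stopping/crossover, toxicity, QoL, plateau).

ESMO_ADJUSTMENT_FLAGS <- c(
  early_stop_crossover = "early_stop_or_crossover",
  toxicity = "toxicity_improved",
  qol = "qol_improved",
  plateau = "plateau_of_curve"
)

#' ESMO-MCBS threshold table
#'
#' The grading rules for forms 2a (OS-primary) and 2b (PFS-primary): one row
#' per (form, band, grade) giving the maximum lower-CI hazard ratio and the
#' minimum survival gain in months that the grade requires. Bands partition
#' trials by the control arm's median: form 2a at 12 and 24 months of OS,
#' form 2b at 6 months of PFS. The `source` column separates rows verified
#' against published gradings from framework-derived defaults; the table can
#' be edited and re-supplied to [esmo_score()].
#'
#' @param path Optional path to an alternative CSV with columns
#'   `form, band, grade, hr_lower_max, gain_min, source`.
#' @return A tibble ordered by form, band and descending grade.
#' @examples
#' esmo_thresholds()
#' @export
esmo_thresholds <- function(path = NULL) {
  path <- path %||% system.file("extdata", "esmo_thresholds.csv",
    package = "oncovalue", mustWork = TRUE
  )
  tab <- readr::read_csv(
    path,
    col_types = readr::cols(
      form = readr::col_character(),
      band = readr::col_character(),
      grade = readr::col_integer(),
      hr_lower_max = readr::col_double(),
      gain_min = readr::col_double(),
      source = readr::col_character()
    )
  )
  check_threshold_table(tab)
  arrange(tab, .data$form, .data$band, desc(.data$grade))
}

check_threshold_table <- function(tab) {
  needed <- c("form", "band", "grade", "hr_lower_max", "gain_min")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0) {
    stop_oncovalue(sprintf(
      "Threshold table is missing column(s) %s.",
      paste0("`", missing, "`", collapse = ", ")
    ))
  }
  if (any(tab$grade < 2 | tab$grade > 4)) {
    stop_oncovalue("Threshold rows must carry grades 2-4 (grade 1 is the floor).")
  }
  if (any(tab$form == "2b" & tab$grade > 3)) {
    stop_oncovalue("Form 2b caps the preliminary grade at 3.")
  }
  # monotone within band: a higher grade must not be laxer on either axis
  split_rows <- split(tab, paste(tab$form, tab$band))
  for (rows in split_rows) {
    rows <- rows[order(-rows$grade), ]
    if (nrow(rows) > 1) {
      if (any(diff(rows$hr_lower_max) < 0) || any(diff(rows$gain_min) > 0)) {
        stop_oncovalue(sprintf(
          "Threshold rows for form %s band %s are not monotone in grade.",
          rows$form[1], rows$band[1]
        ))
      }
    }
  }
  invisible(tab)
}

os_band <- function(median_control) {
  if (median_control <= 12) "<=12mo" else if (median_control <= 24) "12-24mo" else ">24mo"
}

pfs_band <- function(median_control) {
  if (median_control <= 6) "<=6mo" else ">6mo"
}

#' Choose the ESMO-MCBS form and band for a trial
#'
#' Non-inferiority designs and trials whose primary endpoints include
#' neither OS nor PFS route to form 2c (no band). An OS primary endpoint
#' routes to form 2a, banded by the control arm's median OS (cut at 12 and
#' 24 months); when the control median OS is not reached the trial cannot be
#' banded on the OS axis and falls back to form 2b on its PFS endpoint (the
#' situation of PFS/OS co-primary trials graded before OS maturity). A PFS
#' primary routes to form 2b, banded at 6 months of control median PFS.
#'
#' @param record A one-row trial tibble.
#' @param population Analysis-population label; defaults to the record's
#'   `assessed_population`.
#' @param band_override Optional band label used when the banding median is
#'   not reached (e.g. `">24mo"`).
#' @return A list with elements `form` (`"2a"`, `"2b"` or `"2c"`), `band`
#'   (label or `NA`) and `endpoint` (the one-row endpoint tibble graded, or
#'   `NULL` for form 2c).
#' @export
select_form <- function(record, population = NULL, band_override = NULL) {
  stopifnot(nrow(record) == 1)
  primaries <- record$primary_endpoints[[1]]
  if (identical(record$design, "non_inferiority") ||
    !any(c("OS", "PFS") %in% primaries)) {
    return(list(form = "2c", band = NA_character_, endpoint = NULL))
  }
  sel <- select_population(record, population)
  if ("OS" %in% primaries) {
    os <- sel[sel$kind == "OS", ]
    if (nrow(os) == 1) {
      if (is_reached(os$median_control_months)) {
        return(list(
          form = "2a", band = os_band(os$median_control_months),
          endpoint = os
        ))
      }
      if (!is.null(band_override)) {
        return(list(form = "2a", band = band_override, endpoint = os))
      }
      # OS cannot be banded; fall through to the PFS axis if there is one
    }
  }
  if ("PFS" %in% primaries || any(sel$kind == "PFS")) {
    pfs <- sel[sel$kind == "PFS", ]
    if (nrow(pfs) == 1) {
      if (is_reached(pfs$median_control_months)) {
        return(list(
          form = "2b", band = pfs_band(pfs$median_control_months),
          endpoint = pfs
        ))
      }
      if (!is.null(band_override)) {
        return(list(form = "2b", band = band_override, endpoint = pfs))
      }
    }
  }
  stop_oncovalue(sprintf(
    paste0(
      "Trial %s: control median needed for banding is not reached and no ",
      "`band_override` was supplied."
    ),
    record$trial_id
  ))
}

#' Hazard-ratio basis for ESMO-MCBS grading
#'
#' The scale grades on the lower bound of the 95% confidence interval of
#' the hazard ratio, not its point estimate.
#'
#' @param endpoint A one-row endpoint tibble.
#' @return The lower confidence bound.
#' @export
hr_basis <- function(endpoint) {
  stopifnot(nrow(endpoint) == 1)
  if (is.na(endpoint$hr_ci_lower)) {
    stop_oncovalue(paste0(
      "Endpoint lacks `hr_ci_lower`; supply the 95% CI ",
      "or an explicit basis override."
    ))
  }
  endpoint$hr_ci_lower
}

#' Preliminary ESMO-MCBS grade from the threshold table
#'
#' The highest grade whose row is satisfied, i.e. `hr_lower <= hr_lower_max`
#' and `gain >= gain_min`; grade 1 is the floor when no row is satisfied.
#'
#' @param form `"2a"` or `"2b"`.
#' @param band Band label within the form.
#' @param hr_lower Lower 95% confidence bound of the hazard ratio.
#' @param gain Survival gain in months (see [derive_gain()]).
#' @param thresholds A threshold table from [esmo_thresholds()].
#' @return Integer grade in 1-4.
#' @examples
#' preliminary_grade("2a", ">24mo", hr_lower = 0.44, gain = 15.2) # 4
#' @export
preliminary_grade <- function(form, band, hr_lower, gain,
                              thresholds = esmo_thresholds()) {
  idx <- which(thresholds$form == form & thresholds$band == band)
  if (length(idx) == 0) {
    stop_oncovalue(sprintf(
      "No threshold rows for form %s band %s (available bands: %s).",
      form, band,
      paste(unique(thresholds$band[thresholds$form == form]), collapse = ", ")
    ))
  }
  if (is.na(hr_lower) || is.na(gain)) {
    return(1L)
  }
  grades <- thresholds$grade[idx]
  hr_max <- thresholds$hr_lower_max[idx]
  gain_min <- thresholds$gain_min[idx]
  # rows evaluated top-down by grade; first satisfied row wins
  for (j in order(-grades)) {
    if (hr_lower <= hr_max[j] && gain >= gain_min[j]) {
      return(as.integer(grades[j]))
    }
  }
  1L
}

#' Default form 2c rule rows
#'
#' Form 2c grades trials whose primary endpoint is neither OS nor PFS,
#' including non-inferiority designs: demonstrated non-inferiority with
#' improved QoL or reduced toxicity earns grade 4; non-inferiority without
#' such an improvement earns grade 2 (a framework-derived default); a trial
#' that failed to demonstrate non-inferiority takes the floor grade 1.
#'
#' @return A list of rule rows consumed by [grade_2c()].
#' @export
esmo_2c_rules <- function() {
  list(
    list(
      grade = 4L,
      when = function(r) {
        identical(r$noninferiority_met, "yes") &&
          (identical(r$toxicity_improved, "yes") ||
            identical(r$qol_improved, "yes"))
      }
    ),
    list(
      grade = 2L,
      when = function(r) identical(r$noninferiority_met, "yes")
    )
  )
}

#' Grade a form 2c trial
#'
#' @param record A one-row trial tibble routed to form 2c.
#' @param rules Rule rows as produced by [esmo_2c_rules()]; evaluated in
#'   order, first match wins, floor grade 1.
#' @return Integer grade in 1-4.
#' @export
grade_2c <- function(record, rules = esmo_2c_rules()) {
  stopifnot(nrow(record) == 1)
  if (identical(record$design, "non_inferiority") &&
    identical(record$noninferiority_met, "unknown")) {
    stop_oncovalue(sprintf(
      "Trial %s: form 2c requires the non-inferiority outcome (`noninferiority_met`).",
      record$trial_id
    ))
  }
  for (rule in rules) {
    if (isTRUE(rule$when(record))) {
      return(as.integer(rule$grade))
    }
  }
  1L
}

#' Apply ESMO-MCBS adjustment upgrades
#'
#' At most one level of upgrade on top of the preliminary grade, capped at
#' 5. Candidate flags in precedence order: early stopping/crossover (not
#' applicable to form 2a, where it is part of the form itself), toxicity
#' improvement, QoL improvement, and — when `include_plateau` is set —
#' plateau of the survival curve. The first satisfied applicable flag is
#' credited with the upgrade and recorded; `"unknown"` flags never upgrade.
#' Form 2c takes no post-hoc upgrades (its core rule already consumes the
#' QoL/toxicity flags).
#'
#' @param preliminary Preliminary grade (1-4).
#' @param form `"2a"`, `"2b"` or `"2c"`.
#' @param record A one-row trial tibble carrying the tristate flags.
#' @param include_plateau Whether the plateau flag may earn the upgrade
#'   (default `FALSE`: accepted but inert).
#' @return A list with `final_grade` and `adjustments_applied` (character,
#'   length 0 or 1).
#' @export
apply_adjustments <- function(preliminary, form, record,
                              include_plateau = FALSE) {
  stopifnot(preliminary %in% 1:4)
  candidates <- names(ESMO_ADJUSTMENT_FLAGS)
  if (identical(form, "2a")) {
    candidates <- setdiff(candidates, "early_stop_crossover")
  }
  if (!include_plateau) candidates <- setdiff(candidates, "plateau")
  if (identical(form, "2c")) candidates <- character()
  credited <- character()
  for (cand in candidates) {
    if (identical(record[[ESMO_ADJUSTMENT_FLAGS[[cand]]]], "yes")) {
      credited <- cand
      break
    }
  }
  final <- min(preliminary + length(credited), 5L)
  list(final_grade = as.integer(final), adjustments_applied = credited)
}

#' ESMO-MCBS grade for one trial
#'
#' Composes form selection, the hazard-ratio basis and survival gain (or the
#' form 2c rule), the preliminary threshold grade, and the adjustment
#' upgrade.
#'
#' @param record A one-row trial tibble.
#' @param population Analysis-population label; defaults to the record's
#'   `assessed_population`.
#' @param thresholds A threshold table from [esmo_thresholds()].
#' @param rules_2c Form 2c rule rows ([esmo_2c_rules()]).
#' @param band_override Optional band label when the banding median is not
#'   reached.
#' @param include_plateau Passed to [apply_adjustments()].
#' @return A one-row tibble: identifiers, `form`, `band`, `endpoint_used`,
#'   `hr_lower_used`, `gain_months`, `preliminary_grade`,
#'   `adjustments_applied` (list-column), `final_grade`, `notes`.
#' @examples
#' grade_trial(rcc_trials()[2, ]) # nivolumab + ipilimumab: final grade 5
#' @export
grade_trial <- function(record, population = NULL,
                        thresholds = esmo_thresholds(),
                        rules_2c = esmo_2c_rules(),
                        band_override = NULL,
                        include_plateau = FALSE) {
  stopifnot(nrow(record) == 1)
  notes <- character()
  fb <- select_form(record, population, band_override)
  if (identical(fb$form, "2c")) {
    prelim <- grade_2c(record, rules_2c)
    hr_lower <- NA_real_
    gain <- NA_real_
    ep_kind <- NA_character_
    notes <- c(notes, "form 2c: HR and survival gain not used")
  } else {
    hr_lower <- hr_basis(fb$endpoint)
    gain <- derive_gain(fb$endpoint)
    if (!is.na(fb$endpoint$gain_override_months) &&
      !is_reached(fb$endpoint$median_treatment_months)) {
      notes <- c(notes, sprintf(
        "gain %.1f months taken from reported follow-up (median not reached)",
        gain
      ))
    }
    prelim <- preliminary_grade(fb$form, fb$band, hr_lower, gain, thresholds)
    ep_kind <- fb$endpoint$kind
  }
  adj <- apply_adjustments(prelim, fb$form, record, include_plateau)
  tibble(
    trial_id = record$trial_id,
    treatment_label = record$treatment_label,
    population = population %||% record$assessed_population,
    form = fb$form,
    band = fb$band,
    endpoint_used = ep_kind,
    hr_lower_used = hr_lower,
    gain_months = gain,
    preliminary_grade = as.integer(prelim),
    adjustments_applied = list(adj$adjustments_applied),
    final_grade = adj$final_grade,
    notes = list(notes)
  )
}

#' Score a trial set with ESMO-MCBS
#'
#' Applies [grade_trial()] to every row of a trial tibble.
#'
#' @inheritParams grade_trial
#' @param trials A trial tibble.
#' @return A tibble of class `esmo_scores`, one row per trial.
#' @examples
#' esmo_score(rcc_trials())
#' @export
esmo_score <- function(trials, population = NULL,
                       thresholds = esmo_thresholds(),
                       rules_2c = esmo_2c_rules(),
                       include_plateau = FALSE) {
  if (nrow(trials) == 0) {
    out <- tibble(
      trial_id = character(), treatment_label = character(),
      population = character(), form = character(), band = character(),
      endpoint_used = character(), hr_lower_used = double(),
      gain_months = double(), preliminary_grade = integer(),
      adjustments_applied = list(), final_grade = integer(), notes = list()
    )
    class(out) <- c("esmo_scores", class(out))
    return(out)
  }
  out <- list_rbind(lapply(
    seq_len(nrow(trials)),
    function(i) {
      grade_trial(trials[i, ], population,
        thresholds = thresholds,
        rules_2c = rules_2c, include_plateau = include_plateau
      )
    }
  ))
  class(out) <- c("esmo_scores", class(out))
  out
}

#' @rdname esmo_score
#' @param x An `esmo_scores` tibble.
#' @param ... Unused.
#' @export
tidy.esmo_scores <- function(x, ...) {
  x |>
    mutate(
      adjustment = map_chr(
        .data$adjustments_applied,
        function(a) if (length(a) == 0) NA_character_ else a
      ),
      upgraded = .data$final_grade > .data$preliminary_grade
    ) |>
    select(!c("adjustments_applied", "notes"))
}

#' @rdname esmo_score
#' @export
glance.esmo_scores <- function(x, ...) {
  tibble(
    n_trials = nrow(x),
    n_upgraded = sum(x$final_grade > x$preliminary_grade),
    median_final_grade = stats::median(x$final_grade),
    n_grade_4_or_5 = sum(x$final_grade >= 4)
  )
}
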