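# Report tables shaped like the published framework summaries, export to
# CSV/JSON, and the functions behind the command-line interface.

#' Score a trial set with one or both frameworks
#'
#' @param trials A trial tibble.
#' @param framework `"both"`, `"asco"` or `"esmo"`.
#' @param population Analysis-population label, or `NULL` for each record's
#'   `assessed_population`.
#' @param asco_cfg An [asco_config()].
#' @param thresholds An ESMO threshold table ([esmo_thresholds()]).
#' @return A named list with elements `asco` ([asco_score()] tibble) and/or
#'   `esmo` ([esmo_score()] tibble).
#' @examples
#' scores <- score_trials(rcc_trials())
#' scores$asco$nhb
#' scores$esmo$final_grade
#' @export
score_trials <- function(trials, framework = c("both", "asco", "esmo"),
                         population = NULL, asco_cfg = asco_config(),
                         thresholds = esmo_thresholds()) {
  framework <- match.arg(framework)
  out <- list()
  if (framework %in% c("both", "asco")) {
    out$asco <- asco_score(trials, population, asco_cfg)
  }
  if (framework %in% c("both", "esmo")) {
    out$esmo <- esmo_score(trials, population, thresholds)
  }
  out
}

flag_mark <- function(flag, credited) {
  dplyr::case_when(
    credited ~ "+",
    flag == "unknown" ~ NA_character_,
    TRUE ~ "-"
  )
}

#' ASCO report table
#'
#' One row per trial in the column order of the published framework
#' summaries: clinical benefit, toxicity, the four bonus categories, net
#' health benefit. Bonus cells whose underlying flag is unknown are `NA`
#' (distinct from an earned or unearned 0).
#'
#' @param scores An `asco_scores` tibble.
#' @param trials The trial tibble the scores came from (supplies the
#'   tristate flags that decide `NA` rendering).
#' @return A tibble.
#' @export
asco_table <- function(scores, trials) {
  flags <- trials[c("trial_id", "palliation_improved", "qol_improved")]
  scores |>
    left_join(flags, by = "trial_id") |>
    mutate(
      bonus_palliation = ifelse(.data$palliation_improved == "unknown",
        NA_real_, .data$bonus_palliation
      ),
      bonus_qol = ifelse(.data$qol_improved == "unknown",
        NA_real_, .data$bonus_qol
      )
    ) |>
    mutate(nhb = round_half_up(.data$nhb, 1)) |>
    select(
      treatment = "treatment_label",
      clinical_benefit = "clinical_benefit",
      toxicity = "toxicity",
      tail_of_curve = "bonus_tail",
      palliation = "bonus_palliation",
      quality_of_life = "bonus_qol",
      treatment_free_interval = "bonus_tfi",
      net_health_benefit = "nhb"
    )
}

#' ESMO-MCBS report table
#'
#' One row per trial in the column order of the published framework
#' summaries. The hazard-ratio column prints the graded lower confidence
#' bound with the endpoint it came from (e.g. `"0.44 (OS)"`). Adjustment
#' columns mark the flag credited with the upgrade `"+"`, an unused or
#' unmet flag `"-"`, and an unknown flag `NA`; columns outside the selected
#' form (early stopping under 2a, all three under 2c's core rule) are `NA`
#' except that form 2c marks the QoL/toxicity flags its rule consumed.
#'
#' @param scores An `esmo_scores` tibble.
#' @param trials The trial tibble the scores came from.
#' @return A tibble.
#' @export
esmo_table <- function(scores, trials) {
  flags <- trials[c(
    "trial_id", "early_stop_or_crossover", "toxicity_improved", "qol_improved"
  )]
  scores |>
    left_join(flags, by = "trial_id") |>
    mutate(
      credited = map_chr(
        .data$adjustments_applied,
        function(a) if (length(a) == 0) "" else a
      ),
      form_band = ifelse(is.na(.data$band), .data$form,
        sprintf("%s (%s)", .data$form, .data$band)
      ),
      hazard_ratio = ifelse(is.na(.data$hr_lower_used), NA_character_,
        sprintf("%.2f (%s)", .data$hr_lower_used, .data$endpoint_used)
      ),
      early_stop_or_crossover_mark = ifelse(
        .data$form %in% c("2a", "2c"), NA_character_,
        flag_mark(
          .data$early_stop_or_crossover,
          .data$credited == "early_stop_crossover"
        )
      ),
      toxicity_mark = ifelse(
        .data$form == "2c",
        ifelse(.data$toxicity_improved == "yes", "+",
          ifelse(.data$toxicity_improved == "no", "-", NA_character_)
        ),
        flag_mark(.data$toxicity_improved, .data$credited == "toxicity")
      ),
      qol_mark = ifelse(
        .data$form == "2c",
        ifelse(.data$qol_improved == "yes", "+",
          ifelse(.data$qol_improved == "no", "-", NA_character_)
        ),
        flag_mark(.data$qol_improved, .data$credited == "qol")
      )
    ) |>
    mutate(gain_months = round_half_up(.data$gain_months, 1)) |>
    select(
      treatment = "treatment_label",
      form = "form_band",
      hazard_ratio = "hazard_ratio",
      survival_gain_months = "gain_months",
      preliminary_grade = "preliminary_grade",
      early_stopping_or_crossover = "early_stop_or_crossover_mark",
      toxicity_improvement = "toxicity_mark",
      qol_improvement = "qol_mark",
      final_grade = "final_grade"
    )
}

#' Write a report table to CSV or JSON
#'
#' CSV renders `NA` cells as empty fields; JSON renders them as explicit
#' nulls. Values shared between the two formats are identical.
#'
#' @param table A report tibble ([asco_table()], [esmo_table()],
#'   [cost_report()] without its list-column, or any plain tibble).
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(table, path, format = c("csv", "json")) {
  format <- match.arg(format)
  table <- as_tibble(table)
  table <- table[, !vapply(table, is.list, logical(1))]
  if (format == "csv") {
    readr::write_csv(table, path, na = "")
  } else {
    jsonlite::write_json(table, path,
      auto_unbox = TRUE, digits = NA,
      pretty = TRUE, na = "null"
    )
  }
  invisible(path)
}

#' Read synthetic-trial scenarios from a JSON file
#'
#' The document holds `{"scenarios": [...]}` where each element carries the
#' scalar arguments of [trial_scenario()] and optionally an `ae_profile`
#' array of rows. Scenarios without a `seed` take consecutive seeds derived
#' from `seed`.
#'
#' @param path Path to the scenario JSON document.
#' @param seed Base seed for scenarios that do not set their own.
#' @return A list of [trial_scenario()] objects.
#' @export
read_scenarios <- function(path, seed = 1L) {
  doc <- jsonlite::read_json(path)
  reject_unknown(doc, "scenarios", "scenario document")
  scen <- doc$scenarios %||% list()
  imap(scen, function(s, i) {
    where <- sprintf("scenarios[%d]", i)
    allowed <- names(formals(trial_scenario))
    reject_unknown(s, allowed, where)
    if (!is.null(s$ae_profile)) {
      s$ae_profile <- list_rbind(map(s$ae_profile, as_tibble))
    }
    s$seed <- s$seed %||% (as.integer(seed) + i - 1L)
    do.call(trial_scenario, s)
  })
}

#' Score trials from disk (CLI backend)
#'
#' Reads a trial-evidence JSON document, validates it, scores it with the
#' requested framework(s) and writes one report file per framework
#' (`<out stem>_asco.<ext>` / `<out stem>_esmo.<ext>`, or `<out>` verbatim
#' for a single framework).
#'
#' @param input Path to a trial-evidence JSON document.
#' @param out Output path (or stem when both frameworks are requested).
#' @param framework `"both"`, `"asco"` or `"esmo"`.
#' @param population Analysis-population label or `NULL`.
#' @param format `"csv"` or `"json"`.
#' @param asco_config_path,thresholds_path Optional configuration overrides.
#' @return Invisibly, the list of written paths.
#' @export
run_score <- function(input, out, framework = c("both", "asco", "esmo"),
                      population = NULL, format = c("csv", "json"),
                      asco_config_path = NULL, thresholds_path = NULL) {
  framework <- match.arg(framework)
  format <- match.arg(format)
  trials <- read_trials(input)
  problems <- validate_trials(trials)
  if (nrow(problems) > 0) {
    stop_oncovalue(paste0(
      "Input failed validation:\n",
      paste(sprintf(
        "  %s / %s: %s", problems$trial_id, problems$field,
        problems$rule
      ), collapse = "\n")
    ))
  }
  asco_cfg <- if (is.null(asco_config_path)) {
    asco_config()
  } else {
    read_asco_config(asco_config_path)
  }
  thresholds <- esmo_thresholds(thresholds_path)
  scores <- score_trials(trials, framework, population, asco_cfg, thresholds)
  ext <- format
  paths <- character()
  emit <- function(tbl, suffix) {
    p <- if (framework == "both") {
      sub(sprintf("\\.%s$", ext), "", out) |>
        paste0("_", suffix, ".", ext)
    } else {
      out
    }
    write_report(tbl, p, format)
    p
  }
  if (!is.null(scores$asco)) {
    paths <- c(paths, emit(asco_table(scores$asco, trials), "asco"))
  }
  if (!is.null(scores$esmo)) {
    paths <- c(paths, emit(esmo_table(scores$esmo, trials), "esmo"))
  }
  invisible(paths)
}

#' Generate synthetic trials from a scenario file (CLI backend)
#'
#' @param scenario_path Path to a scenario JSON document
#'   (see [read_scenarios()]).
#' @param out Output path for the generated trial-evidence JSON.
#' @param seed Base seed for scenarios without one.
#' @return Invisibly, the generated trial tibble.
#' @export
run_synthesize <- function(scenario_path, out, seed = 1L) {
  scenarios <- read_scenarios(scenario_path, seed)
  if (length(scenarios) == 0) {
    stop_oncovalue("Scenario document contains no scenarios.")
  }
  trials <- generate_trials(scenarios)
  problems <- validate_trials(trials)
  if (nrow(problems) > 0) {
    stop_oncovalue("Generated records failed validation (internal error).")
  }
  write_trials(trials, out)
  invisible(trials)
}
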