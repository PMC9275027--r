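# ASCO Value Framework v2.0, advanced-disease track: clinical benefit from
# the hazard ratio (or relative ORR improvement), a two-arm weighted toxicity
# score scaled to +/- 20 points, four bonus categories, and their sum as the
# net health benefit (NHB).

#' ASCO Value Framework scoring configuration
#'
#' Tunable constants of the advanced-disease score. The defaults are the
#' framework's published values: clinical benefit is `(1 - HR) * 100` for
#' OS, down-weighted by 0.8 for PFS and 0.7 for the relative ORR
#' improvement; toxicity weights 0.5 (grade 1-2) and 2.0 (grade 3-4) feed a
#' relative two-arm difference scaled to +/- `tox_scale` points; QoL and
#' palliation improvements earn flat bonuses. Tail-of-curve and
#' treatment-free-interval bonuses are rule hooks (functions of the trial
#' record returning points); both default to 0 points.
#'
#' @param pfs_weight Multiplier applied to a PFS-based clinical benefit.
#' @param orr_weight Multiplier applied to an ORR-based clinical benefit.
#' @param tox_weight_g1_2,tox_weight_g3_4 Per-incidence weights by grade band.
#' @param tox_scale Scale (and clamp) of the toxicity points.
#' @param bonus_qol_points,bonus_palliation_points Flat bonuses awarded when
#'   the corresponding flag is `"yes"`.
#' @param tail_bonus_rule,tfi_bonus_rule `NULL` (always 0) or a function of
#'   a one-row trial record returning bonus points.
#' @param rounding Decimal places reported (half-up rounding).
#' @param cb_cap Upper cap on clinical benefit points (`Inf`: no cap).
#' @return An object of class `asco_config`.
#' @examples
#' asco_config()
#' asco_config(pfs_weight = 1) # score PFS like OS
#' @export
asco_config <- function(pfs_weight = 0.8,
                        orr_weight = 0.7,
                        tox_weight_g1_2 = 0.5,
                        tox_weight_g3_4 = 2.0,
                        tox_scale = 20,
                        bonus_qol_points = 10,
                        bonus_palliation_points = 10,
                        tail_bonus_rule = NULL,
                        tfi_bonus_rule = NULL,
                        rounding = 1,
                        cb_cap = Inf) {
  num <- list(
    pfs_weight = pfs_weight, orr_weight = orr_weight,
    tox_weight_g1_2 = tox_weight_g1_2, tox_weight_g3_4 = tox_weight_g3_4,
    tox_scale = tox_scale
  )
  for (nm in names(num)) {
    if (!is.numeric(num[[nm]]) || num[[nm]] <= 0) {
      stop_oncovalue(sprintf("`%s` must be a positive number.", nm))
    }
  }
  for (rule in c("tail_bonus_rule", "tfi_bonus_rule")) {
    r <- get(rule)
    if (!is.null(r) && !is.function(r)) {
      stop_oncovalue(sprintf("`%s` must be NULL or a function.", rule))
    }
  }
  structure(
    list(
      pfs_weight = pfs_weight, orr_weight = orr_weight,
      tox_weight_g1_2 = tox_weight_g1_2, tox_weight_g3_4 = tox_weight_g3_4,
      tox_scale = tox_scale, bonus_qol_points = bonus_qol_points,
      bonus_palliation_points = bonus_palliation_points,
      tail_bonus_rule = tail_bonus_rule, tfi_bonus_rule = tfi_bonus_rule,
      rounding = rounding, cb_cap = cb_cap
    ),
    class = "asco_config"
  )
}

#' Read an ASCO configuration from a JSON file
#'
#' The file holds a JSON object whose keys are the scalar arguments of
#' [asco_config()]; omitted keys keep their defaults. The rule hooks are not
#' serializable and must be set in code.
#'
#' @param path Path to a JSON configuration file.
#' @return An `asco_config` object.
#' @export
read_asco_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- setdiff(names(formals(asco_config)), c("tail_bonus_rule", "tfi_bonus_rule"))
  reject_unknown(raw, allowed, "asco config")
  do.call(asco_config, raw)
}

select_population <- function(record, population) {
  population <- population %||% record$assessed_population
  eps <- record$endpoints[[1]]
  sel <- eps[eps$population == population, ]
  if (nrow(sel) == 0) {
    stop_oncovalue(sprintf(
      "Trial %s has no endpoints for population \"%s\" (available: %s).",
      record$trial_id, population,
      paste(unique(eps$population), collapse = ", ")
    ))
  }
  sel
}

#' Choose the endpoint that carries the ASCO clinical benefit
#'
#' The framework prioritizes overall survival: a statistically significant
#' OS result is used when available, then a significant PFS result, then
#' ORR. A non-inferiority design earns no clinical-benefit score at all
#' (returns `NULL`).
#'
#' @param record A one-row trial tibble.
#' @param population Analysis-population label; defaults to the record's
#'   `assessed_population`.
#' @param config An [asco_config()].
#' @return A one-row endpoint tibble, or `NULL` when no endpoint qualifies.
#' @export
select_benefit_endpoint <- function(record, population = NULL,
                                    config = asco_config()) {
  stopifnot(nrow(record) == 1)
  if (identical(record$design, "non_inferiority")) {
    return(NULL)
  }
  sel <- select_population(record, population)
  for (k in c("OS", "PFS")) {
    hit <- sel[sel$kind == k & sel$statistically_significant == "yes", ]
    if (nrow(hit) > 0) {
      return(hit[1, ])
    }
  }
  orr <- sel[sel$kind == "ORR", ]
  if (nrow(orr) > 0) {
    return(orr[1, ])
  }
  NULL
}

#' ASCO clinical benefit score
#'
#' `(1 - HR) * 100` for OS, multiplied by `pfs_weight` for PFS; for ORR the
#' relative improvement `(rr_t - rr_c) / rr_c * 100 * orr_weight`. A `NULL`
#' endpoint (non-inferiority, or nothing qualified) scores 0.
#'
#' @param endpoint A one-row endpoint tibble or `NULL`.
#' @param config An [asco_config()].
#' @return Clinical benefit in points, rounded per the configuration.
#' @examples
#' ep <- endpoint_result("PFS", hr_point = 0.69, statistically_significant = "yes")
#' clinical_benefit_score(ep) # (1 - 0.69) * 100 * 0.8 = 24.8
#' @export
clinical_benefit_score <- function(endpoint, config = asco_config()) {
  if (is.null(endpoint)) {
    return(0)
  }
  stopifnot(nrow(endpoint) == 1)
  raw <- switch(endpoint$kind,
    OS = ,
    PFS = {
      if (is.na(endpoint$hr_point)) {
        stop_oncovalue(sprintf(
          "%s endpoint lacks `hr_point`, required for the clinical benefit score.",
          endpoint$kind
        ))
      }
      w <- if (endpoint$kind == "PFS") config$pfs_weight else 1
      (1 - endpoint$hr_point) * 100 * w
    },
    ORR = {
      if (is.na(endpoint$rr_treatment) || is.na(endpoint$rr_control)) {
        stop_oncovalue("ORR endpoint lacks `rr_treatment`/`rr_control`.")
      }
      if (endpoint$rr_control <= 0) {
        stop_oncovalue("ORR endpoint has `rr_control` 0; relative improvement undefined.")
      }
      (endpoint$rr_treatment - endpoint$rr_control) / endpoint$rr_control *
        100 * config$orr_weight
    },
    stop_oncovalue(sprintf("Unknown endpoint kind `%s`.", endpoint$kind))
  )
  round_half_up(min(raw, config$cb_cap), config$rounding)
}

#' Weighted toxicity burden of one arm
#'
#' Sum over non-laboratory adverse-event rows of grade-band weight times the
#' arm's incidence. Laboratory-only rows contribute nothing.
#'
#' @param ae_table An adverse-event tibble.
#' @param arm `"treatment"` or `"control"`.
#' @param config An [asco_config()].
#' @return Non-negative weighted incidence sum.
#' @export
toxicity_arm_score <- function(ae_table, arm = c("treatment", "control"),
                               config = asco_config()) {
  arm <- match.arg(arm)
  if (nrow(ae_table) == 0) {
    return(0)
  }
  keep <- ae_table[!ae_table$laboratory_only, ]
  if (nrow(keep) == 0) {
    return(0)
  }
  w <- ifelse(keep$grade_band == "g3_4", config$tox_weight_g3_4,
    config$tox_weight_g1_2
  )
  inc <- if (arm == "treatment") keep$incidence_treatment else keep$incidence_control
  sum(w * inc)
}

#' ASCO toxicity points
#'
#' The relative difference of the two arms' weighted toxicity burdens,
#' scaled to `tox_scale` points and clamped to `[-tox_scale, +tox_scale]`:
#' `tox_scale * (control - treatment) / control`. Positive points mean the
#' treatment arm is less toxic than control. When both arms have zero
#' burden the points are 0; a zero control burden against a non-zero
#' treatment burden returns the clamp floor `-tox_scale` with an
#' explanatory note attached as the `"note"` attribute.
#'
#' @param ae_table An adverse-event tibble covering both arms.
#' @param config An [asco_config()].
#' @return Unrounded points in `[-tox_scale, +tox_scale]`.
#' @examples
#' tox <- ae_row("any grade 3-4 event", "g3_4", 45, 63)
#' toxicity_points(tox) # positive: treatment less toxic
#' @export
toxicity_points <- function(ae_table, config = asco_config()) {
  s_t <- toxicity_arm_score(ae_table, "treatment", config)
  s_c <- toxicity_arm_score(ae_table, "control", config)
  if (s_c == 0 && s_t == 0) {
    return(0)
  }
  if (s_c == 0) {
    out <- -config$tox_scale
    attr(out, "note") <-
      "control arm has zero toxicity burden; points set to the clamp floor"
    return(out)
  }
  raw <- config$tox_scale * (s_c - s_t) / s_c
  max(min(raw, config$tox_scale), -config$tox_scale)
}

#' ASCO bonus points
#'
#' Four flat-bonus categories: tail of the survival curve, symptom
#' palliation, quality of life, and treatment-free interval. QoL and
#' palliation bonuses are awarded when the corresponding tristate flag is
#' `"yes"`; `"unknown"` earns nothing (with a note). Tail and TFI bonuses
#' come from the configurable rule hooks and default to 0.
#'
#' @param record A one-row trial tibble.
#' @param config An [asco_config()].
#' @return A one-row tibble with columns `bonus_tail`, `bonus_palliation`,
#'   `bonus_qol`, `bonus_tfi` and a `notes` list-column.
#' @export
bonus_points <- function(record, config = asco_config()) {
  stopifnot(nrow(record) == 1)
  notes <- character()
  flat <- function(flag, points, what) {
    if (identical(flag, "yes")) {
      return(points)
    }
    if (identical(flag, "unknown")) {
      notes <<- c(notes, sprintf("%s flag unknown; no bonus awarded", what))
    }
    0
  }
  hook <- function(rule) if (is.null(rule)) 0 else as.numeric(rule(record))
  tibble(
    bonus_tail = hook(config$tail_bonus_rule),
    bonus_palliation = flat(
      record$palliation_improved, config$bonus_palliation_points, "palliation"
    ),
    bonus_qol = flat(record$qol_improved, config$bonus_qol_points, "QoL"),
    bonus_tfi = hook(config$tfi_bonus_rule),
    notes = list(notes)
  )
}

#' ASCO net health benefit for one trial
#'
#' Composes endpoint selection, clinical benefit, toxicity points and
#' bonuses. Every component is rounded to the configured number of decimals
#' (half-up) and the NHB is their exact sum, so the reported decomposition
#' is always additive.
#'
#' @param record A one-row trial tibble.
#' @param population Analysis-population label; defaults to the record's
#'   `assessed_population`.
#' @param config An [asco_config()].
#' @return A one-row tibble: identifiers, `endpoint_used`, the component
#'   scores, `nhb`, and a `notes` list-column.
#' @examples
#' net_health_benefit(rcc_trials()[2, ]) # nivolumab + ipilimumab: NHB 41.9
#' @export
net_health_benefit <- function(record, population = NULL,
                               config = asco_config()) {
  stopifnot(nrow(record) == 1)
  population <- population %||% record$assessed_population
  notes <- character()
  ep <- select_benefit_endpoint(record, population, config)
  if (is.null(ep) && identical(record$design, "non_inferiority")) {
    notes <- c(notes, "non-inferiority design: clinical benefit score omitted")
  }
  cb <- clinical_benefit_score(ep, config)
  tox <- toxicity_points(record$ae_table[[1]], config)
  if (!is.null(attr(tox, "note"))) notes <- c(notes, attr(tox, "note"))
  tox <- round_half_up(as.numeric(tox), config$rounding)
  bon <- bonus_points(record, config)
  notes <- c(notes, bon$notes[[1]])
  comps <- c(
    clinical_benefit = cb, toxicity = tox,
    bonus_tail = round_half_up(bon$bonus_tail, config$rounding),
    bonus_palliation = round_half_up(bon$bonus_palliation, config$rounding),
    bonus_qol = round_half_up(bon$bonus_qol, config$rounding),
    bonus_tfi = round_half_up(bon$bonus_tfi, config$rounding)
  )
  tibble(
    trial_id = record$trial_id,
    treatment_label = record$treatment_label,
    population = population,
    endpoint_used = if (is.null(ep)) NA_character_ else ep$kind,
    clinical_benefit = comps[["clinical_benefit"]],
    toxicity = comps[["toxicity"]],
    bonus_tail = comps[["bonus_tail"]],
    bonus_palliation = comps[["bonus_palliation"]],
    bonus_qol = comps[["bonus_qol"]],
    bonus_tfi = comps[["bonus_tfi"]],
    # plain chained sum of the rounded components, so the reported
    # decomposition is additive to the last bit
    nhb = comps[["clinical_benefit"]] + comps[["toxicity"]] +
      comps[["bonus_tail"]] + comps[["bonus_palliation"]] +
      comps[["bonus_qol"]] + comps[["bonus_tfi"]],
    notes = list(notes)
  )
}

#' Score a trial set with the ASCO Value Framework
#'
#' Applies [net_health_benefit()] to every row of a trial tibble.
#'
#' @param trials A trial tibble.
#' @param population Analysis-population label applied to every trial, or
#'   `NULL` to use each record's `assessed_population`.
#' @param config An [asco_config()].
#' @return A tibble of class `asco_scores`, one row per trial, in trial
#'   order.
#' @examples
#' asco_score(rcc_trials())
#' @export
asco_score <- function(trials, population = NULL, config = asco_config()) {
  if (nrow(trials) == 0) {
    out <- tibble(
      trial_id = character(), treatment_label = character(),
      population = character(), endpoint_used = character(),
      clinical_benefit = double(), toxicity = double(),
      bonus_tail = double(), bonus_palliation = double(),
      bonus_qol = double(), bonus_tfi = double(), nhb = double(),
      notes = list()
    )
    class(out) <- c("asco_scores", class(out))
    return(out)
  }
  out <- list_rbind(lapply(
    seq_len(nrow(trials)),
    function(i) net_health_benefit(trials[i, ], population, config)
  ))
  class(out) <- c("asco_scores", class(out))
  out
}

#' @rdname asco_score
#' @param x An `asco_scores` tibble.
#' @param ... Unused.
#' @export
tidy.asco_scores <- function(x, ...) {
  x |>
    select(!"notes") |>
    tidyr::pivot_longer(
      c(
        "clinical_benefit", "toxicity", "bonus_tail", "bonus_palliation",
        "bonus_qol", "bonus_tfi", "nhb"
      ),
      names_to = "component", values_to = "points"
    )
}

#' @rdname asco_score
#' @export
glance.asco_scores <- function(x, ...) {
  tibble(
    n_trials = nrow(x),
    mean_nhb = mean(x$nhb),
    min_nhb = min(x$nhb),
    max_nhb = max(x$nhb),
    n_with_bonus = sum(x$bonus_tail + x$bonus_palliation +
      x$bonus_qol + x$bonus_tfi > 0)
  )
}
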