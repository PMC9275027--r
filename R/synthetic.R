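# Synthetic trial evidence: a summary-level generator that draws a log
# hazard ratio around the truth with the standard two-arm standard error,
# and a patient-level exponential survival simulator with a log-rank
# one-step hazard-ratio estimator, for parameter-recovery checks.

default_ae_profile <- function() {
  tibble(
    event_name = c("fatigue", "hypertension", "anemia"),
    grade_band = c("g1_2", "g3_4", "g3_4"),
    p_treatment = c(0.30, 0.20, 0.10),
    p_control = c(0.35, 0.25, 0.10),
    laboratory_only = c(FALSE, FALSE, TRUE)
  )
}

#' Define a synthetic trial scenario
#'
#' The truth parameters of one simulated two-arm comparison: exponential
#' event times in the control arm with median `control_median_months`, a
#' proportional-hazards treatment effect `true_hr`, independent exponential
#' censoring with per-month hazard `censoring_rate`, and per-event true
#' adverse-event incidences. All randomness downstream is governed by
#' `seed`.
#'
#' @param true_hr True hazard ratio, treatment vs control (> 0).
#' @param control_median_months Control-arm median in months (> 0).
#' @param n_per_arm Patients per arm (>= 2).
#' @param endpoint_kind `"OS"` or `"PFS"`.
#' @param design `"superiority"` or `"non_inferiority"`.
#' @param ae_profile Tibble of true incidences: `event_name`, `grade_band`,
#'   `p_treatment`, `p_control` (proportions in `[0, 1]`),
#'   `laboratory_only`.
#' @param qol_improved,toxicity_improved,early_stop Tristate flags copied
#'   into generated records.
#' @param censoring_rate Per-month censoring hazard (>= 0; 0 = none).
#' @param ni_margin Non-inferiority margin on the hazard ratio used to call
#'   the outcome of `non_inferiority` designs (default 1.25).
#' @param seed Integer seed.
#' @return An object of class `trial_scenario`.
#' @examples
#' trial_scenario(true_hr = 0.6, control_median_months = 8, n_per_arm = 300)
#' @export
trial_scenario <- function(true_hr,
                           control_median_months,
                           n_per_arm,
                           endpoint_kind = "PFS",
                           design = "superiority",
                           ae_profile = default_ae_profile(),
                           qol_improved = "unknown",
                           toxicity_improved = "unknown",
                           early_stop = "unknown",
                           censoring_rate = 0.02,
                           ni_margin = 1.25,
                           seed = 1L) {
  if (!is.numeric(true_hr) || true_hr <= 0) {
    stop_oncovalue("`true_hr` must be > 0.")
  }
  if (!is.numeric(control_median_months) || control_median_months <= 0) {
    stop_oncovalue("`control_median_months` must be > 0.")
  }
  if (!is.numeric(n_per_arm) || n_per_arm < 2) {
    stop_oncovalue("`n_per_arm` must be >= 2.")
  }
  if (!is.numeric(censoring_rate) || censoring_rate < 0) {
    stop_oncovalue("`censoring_rate` must be >= 0.")
  }
  endpoint_kind <- match.arg(endpoint_kind, c("OS", "PFS"))
  design <- match.arg(design, DESIGNS)
  for (fl in c("qol_improved", "toxicity_improved", "early_stop")) {
    if (!is_tristate(get(fl))) {
      stop_oncovalue(sprintf("`%s` must be one of yes/no/unknown.", fl))
    }
  }
  ae_profile <- as_tibble(ae_profile)
  p <- c(ae_profile$p_treatment, ae_profile$p_control)
  if (any(p < 0 | p > 1)) {
    stop_oncovalue("AE profile incidences must be proportions in [0, 1].")
  }
  structure(
    list(
      true_hr = true_hr, control_median_months = control_median_months,
      n_per_arm = as.integer(n_per_arm), endpoint_kind = endpoint_kind,
      design = design, ae_profile = ae_profile,
      qol_improved = qol_improved, toxicity_improved = toxicity_improved,
      early_stop = early_stop, censoring_rate = censoring_rate,
      ni_margin = ni_margin, seed = as.integer(seed)
    ),
    class = "trial_scenario"
  )
}

scenario_hazards <- function(scenario) {
  lambda_c <- log(2) / scenario$control_median_months
  list(control = lambda_c, treatment = scenario$true_hr * lambda_c)
}

# expected events per arm under exponential event and censoring hazards:
# P(event before censoring) = lambda / (lambda + c)
expected_events <- function(scenario) {
  hz <- scenario_hazards(scenario)
  cens <- scenario$censoring_rate
  p_t <- hz$treatment / (hz$treatment + cens)
  p_c <- hz$control / (hz$control + cens)
  scenario$n_per_arm * (p_t + p_c)
}

simulate_summary_impl <- function(scenario) {
  se <- 2 / sqrt(expected_events(scenario))
  log_hr <- rnorm(1, mean = log(scenario$true_hr), sd = se)
  hr <- exp(log_hr)
  z <- qnorm(0.975)
  lower <- exp(log_hr - z * se)
  upper <- exp(log_hr + z * se)
  endpoint_result(
    kind = scenario$endpoint_kind,
    population = "ITT",
    hr_point = hr,
    hr_ci_lower = lower,
    hr_ci_upper = upper,
    median_treatment_months = scenario$control_median_months / hr,
    median_control_months = scenario$control_median_months,
    statistically_significant = if (upper < 1) "yes" else "no"
  )
}

#' Simulate a summary-level endpoint result
#'
#' Draws an estimated log hazard ratio from a normal law centred at the
#' true log HR with standard error `2 / sqrt(expected events)` (the standard
#' two-arm approximation), builds the 95% confidence interval, and derives
#' medians from the exponential model (`median = ln 2 / hazard`, so the
#' estimated treatment median is `control_median / HR_est`). Deterministic
#' given the scenario seed.
#'
#' @param scenario A [trial_scenario()].
#' @return A one-row endpoint tibble.
#' @examples
#' simulate_summary(trial_scenario(0.6, 8, 300, seed = 42))
#' @export
simulate_summary <- function(scenario) {
  stopifnot(inherits(scenario, "trial_scenario"))
  withr::with_seed(scenario$seed, simulate_summary_impl(scenario))
}

simulate_patient_level_impl <- function(scenario) {
  hz <- scenario_hazards(scenario)
  n <- scenario$n_per_arm
  sim_arm <- function(arm, lambda) {
    events <- rexp(n, rate = lambda)
    if (scenario$censoring_rate > 0) {
      cens <- rexp(n, rate = scenario$censoring_rate)
    } else {
      cens <- rep(Inf, n)
    }
    tibble(
      arm = arm,
      time = pmin(events, cens),
      status = as.integer(events <= cens)
    )
  }
  bind_rows(
    sim_arm("treatment", hz$treatment),
    sim_arm("control", hz$control)
  )
}

#' Simulate patient-level two-arm survival data
#'
#' Exponential event times (control hazard `ln 2 / control_median`,
#' treatment hazard scaled by `true_hr`) with independent exponential
#' censoring. Deterministic given the scenario seed.
#'
#' @param scenario A [trial_scenario()].
#' @return A tibble with columns `arm` (`"treatment"`/`"control"`), `time`
#'   (months) and `status` (1 = event, 0 = censored).
#' @examples
#' simulate_patient_level(trial_scenario(0.6, 8, 100, seed = 42))
#' @export
simulate_patient_level <- function(scenario) {
  stopifnot(inherits(scenario, "trial_scenario"))
  withr::with_seed(scenario$seed, simulate_patient_level_impl(scenario))
}

#' One-step log-rank hazard-ratio estimate
#'
#' The log-rank observed/expected decomposition over the pooled distinct
#' event times gives the score `O - E` (observed minus expected events in
#' the treatment arm) and its hypergeometric variance `V`; the one-step
#' estimator is `HR = exp((O - E) / V)` with confidence bounds
#' `exp((O - E)/V +/- z / sqrt(V))`. Ties are handled with the standard
#' hypergeometric correction.
#'
#' @param data A tibble as returned by [simulate_patient_level()]: columns
#'   `arm`, `time`, `status`.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: `hr`, `ci_lower`, `ci_upper`, `o_minus_e`,
#'   `var`, `n_events`.
#' @examples
#' dat <- simulate_patient_level(trial_scenario(0.5, 10, 500, seed = 7))
#' estimate_hr_logrank(dat)
#' @export
estimate_hr_logrank <- function(data, conf_level = 0.95) {
  stopifnot(all(c("arm", "time", "status") %in% names(data)))
  events_per_arm <- tapply(data$status, data$arm, sum)
  if (length(events_per_arm) != 2 || any(events_per_arm == 0)) {
    stop_oncovalue("Log-rank estimate requires at least one event per arm.")
  }
  times <- sort(unique(data$time[data$status == 1]))
  o <- 0
  e <- 0
  v <- 0
  is_trt <- data$arm == "treatment"
  for (t in times) {
    at_risk <- data$time >= t
    n_all <- sum(at_risk)
    n1 <- sum(at_risk & is_trt)
    d_all <- sum(data$time == t & data$status == 1)
    d1 <- sum(data$time == t & data$status == 1 & is_trt)
    o <- o + d1
    e <- e + d_all * n1 / n_all
    if (n_all > 1) {
      v <- v + d_all * (n1 / n_all) * (1 - n1 / n_all) * (n_all - d_all) / (n_all - 1)
    }
  }
  if (v <= 0) stop_oncovalue("Log-rank variance is zero; cannot estimate.")
  beta <- (o - e) / v
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble(
    hr = exp(beta),
    ci_lower = exp(beta - z / sqrt(v)),
    ci_upper = exp(beta + z / sqrt(v)),
    o_minus_e = o - e,
    var = v,
    n_events = as.integer(sum(data$status))
  )
}

#' Generate a full synthetic trial record
#'
#' Assembles a validated [trial_record()]: the endpoint from the
#' summary-level simulator, the adverse-event table from per-event binomial
#' draws around the profile's true incidences, and the scenario's flags.
#' For non-inferiority designs the outcome flag is called from the simulated
#' confidence interval against the scenario's margin. Every generated record
#' passes [validate_trials()].
#'
#' @param scenario A [trial_scenario()].
#' @param trial_id Identifier for the generated record.
#' @return A one-row trial tibble.
#' @examples
#' generate_trial(trial_scenario(0.6, 8, 300, seed = 42))
#' @export
generate_trial <- function(scenario, trial_id = "synthetic-1") {
  stopifnot(inherits(scenario, "trial_scenario"))
  withr::with_seed(scenario$seed, {
    ep <- simulate_summary_impl(scenario)
    prof <- scenario$ae_profile
    n <- scenario$n_per_arm
    ae <- if (nrow(prof) == 0) {
      ae_prototype()
    } else {
      tibble(
        event_name = prof$event_name,
        grade_band = prof$grade_band,
        incidence_treatment = rbinom(nrow(prof), n, prof$p_treatment) / n * 100,
        incidence_control = rbinom(nrow(prof), n, prof$p_control) / n * 100,
        laboratory_only = prof$laboratory_only
      )
    }
    ni <- if (identical(scenario$design, "non_inferiority")) {
      if (ep$hr_ci_upper < scenario$ni_margin) "yes" else "no"
    } else {
      "unknown"
    }
    trial_record(
      trial_id = trial_id,
      treatment_label = "synthetic treatment",
      control_label = "synthetic control",
      n_treatment = n,
      n_control = n,
      design = scenario$design,
      primary_endpoints = scenario$endpoint_kind,
      endpoints = ep,
      ae_table = ae,
      assessed_population = "ITT",
      qol_improved = scenario$qol_improved,
      toxicity_improved = scenario$toxicity_improved,
      early_stop_or_crossover = scenario$early_stop,
      noninferiority_met = ni
    )
  })
}

#' Generate several synthetic trials
#'
#' @param scenarios A list of [trial_scenario()] objects.
#' @param ids Optional trial identifiers (default `synthetic-1 ...`).
#' @return A trial tibble, one row per scenario.
#' @export
generate_trials <- function(scenarios, ids = NULL) {
  ids <- ids %||% sprintf("synthetic-%d", seq_along(scenarios))
  out <- list_rbind(map2(scenarios, ids, generate_trial))
  class(out) <- c("trial_tbl", class(out))
  out
}
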