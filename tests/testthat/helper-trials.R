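# Shared builders and independent oracles for the test suite.

`%||%` <- function(x, y) if (is.null(x)) y else x

make_endpoint <- function(kind = "PFS", hr = 0.6, lower = hr - 0.1,
                          upper = hr + 0.1, mt = 12, mc = 8,
                          sig = "yes", population = "ITT", ...) {
  endpoint_result(kind, population,
    hr_point = hr, hr_ci_lower = lower, hr_ci_upper = upper,
    median_treatment_months = mt, median_control_months = mc,
    statistically_significant = sig, ...
  )
}

make_trial <- function(trial_id = "T1", endpoints = make_endpoint(),
                       ae_table = ae_prototype_(), design = "superiority",
                       primary_endpoints = "PFS", ...) {
  trial_record(
    trial_id = trial_id, treatment_label = "treatment",
    control_label = "control", n_treatment = 100, n_control = 100,
    design = design, primary_endpoints = primary_endpoints,
    endpoints = endpoints, ae_table = ae_table, ...
  )
}

ae_prototype_ <- function() {
  ae_row("x", "g1_2", 0, 0)[0, ]
}

# random AE table with n rows, mixed grade bands and lab-only flags
random_ae_table <- function(n_rows) {
  dplyr::bind_rows(lapply(seq_len(n_rows), function(i) {
    ae_row(
      event_name = paste0("event-", i),
      grade_band = sample(c("g1_2", "g3_4"), 1),
      incidence_treatment = round(stats::runif(1, 0, 100), 1),
      incidence_control = round(stats::runif(1, 0, 100), 1),
      laboratory_only = stats::runif(1) < 0.25
    )
  }))
}

# Independent spreadsheet-style oracle for ASCO toxicity points: explicit
# row-by-row accumulation with if-branches, no shared code with the package.
oracle_toxicity_points <- function(ae, w12 = 0.5, w34 = 2.0, scale = 20) {
  s_t <- 0
  s_c <- 0
  for (i in seq_len(nrow(ae))) {
    if (ae$laboratory_only[i]) next
    w <- if (ae$grade_band[i] == "g3_4") w34 else w12
    s_t <- s_t + w * ae$incidence_treatment[i]
    s_c <- s_c + w * ae$incidence_control[i]
  }
  if (s_c == 0 && s_t == 0) return(0)
  if (s_c == 0) return(-scale)
  raw <- scale * (s_c - s_t) / s_c
  if (raw > scale) scale else if (raw < -scale) -scale else raw
}

# Independent oracle for the preliminary ESMO grade: collect every satisfied
# row's grade and take the maximum (floor 1), rather than the engine's
# ordered first-hit scan.
oracle_preliminary_grade <- function(form, band, hr_lower, gain, tab) {
  rows <- tab[tab$form == form & tab$band == band, ]
  sat <- rows$grade[hr_lower <= rows$hr_lower_max & gain >= rows$gain_min]
  if (length(sat) == 0) 1L else max(sat)
}
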