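test_that("scenario validation rejects impossible parameters", {
  expect_error(trial_scenario(0, 8, 100), "true_hr")
  expect_error(trial_scenario(0.5, -1, 100), "control_median")
  expect_error(trial_scenario(0.5, 8, 1), "n_per_arm")
  expect_error(trial_scenario(0.5, 8, 100, censoring_rate = -0.1), "censoring")
  expect_error(trial_scenario(0.5, 8, 100, qol_improved = "maybe"), "yes/no/unknown")
})

test_that("simulation is seed-deterministic and seed-sensitive", {
  sc <- trial_scenario(0.6, 8, 500, seed = 77)
  expect_identical(simulate_summary(sc), simulate_summary(sc))
  expect_identical(simulate_patient_level(sc), simulate_patient_level(sc))
  expect_identical(generate_trial(sc), generate_trial(sc))
  sc2 <- trial_scenario(0.6, 8, 500, seed = 78)
  expect_false(identical(simulate_summary(sc)$hr_point, simulate_summary(sc2)$hr_point))
})

test_that("summary simulator is centred on the truth with ~95% CI coverage", {
  n_rep <- 4000
  hrs <- covered <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    sc <- trial_scenario(1.0, 10, 1000, seed = 100000L + r)
    ep <- simulate_summary(sc)
    hrs[r] <- ep$hr_point
    covered[r] <- ep$hr_ci_lower <= 1 && 1 <= ep$hr_ci_upper
  }
  expect_lt(abs(mean(hrs) - 1), 0.01)
  expect_lt(abs(mean(covered) - 0.95), 0.02)
})

test_that("summary medians follow the exponential relation", {
  sc <- trial_scenario(0.5, 12, 800, seed = 3)
  ep <- simulate_summary(sc)
  expect_equal(ep$median_control_months, 12)
  expect_equal(ep$median_treatment_months, 12 / ep$hr_point)
})

test_that("patient-level simulator matches the exponential model", {
  # no censoring: every observation is an event
  sc0 <- trial_scenario(0.7, 9, 400, censoring_rate = 0, seed = 5)
  d0 <- simulate_patient_level(sc0)
  expect_true(all(d0$status == 1))
  expect_equal(nrow(d0), 800)

  # large-sample arm medians approach ln2 / hazard within 5%
  sc <- trial_scenario(0.5, 10, 20000, censoring_rate = 0, seed = 9)
  d <- simulate_patient_level(sc)
  med_c <- stats::median(d$time[d$arm == "control"])
  med_t <- stats::median(d$time[d$arm == "treatment"])
  expect_lt(abs(med_c / 10 - 1), 0.05)
  expect_lt(abs(med_t / 20 - 1), 0.05)
})

test_that("log-rank one-step estimator recovers moderate effects", {
  # identical arms: HR near 1 (averaged over a few replicates so the check
  # sits well inside sampling error at n = 2000/arm)
  hr1 <- vapply(21:25, function(seed) {
    estimate_hr_logrank(
      simulate_patient_level(trial_scenario(1.0, 10, 2000, seed = seed))
    )$hr
  }, numeric(1))
  expect_lt(abs(mean(hr1) - 1), 0.05)

  # true effect 0.5 at n = 2000/arm
  sc2 <- trial_scenario(0.5, 10, 2000, seed = 22)
  est2 <- estimate_hr_logrank(simulate_patient_level(sc2))
  expect_gt(est2$hr, 0.45)
  expect_lt(est2$hr, 0.55)
  expect_lt(est2$ci_lower, est2$hr)
  expect_gt(est2$ci_upper, est2$hr)

  # swapping arm labels inverts the estimate
  d <- simulate_patient_level(trial_scenario(0.6, 8, 500, seed = 23))
  swapped <- d
  swapped$arm <- ifelse(d$arm == "treatment", "control", "treatment")
  expect_equal(
    estimate_hr_logrank(swapped)$hr,
    1 / estimate_hr_logrank(d)$hr,
    tolerance = 1e-9
  )

  no_events <- tibble::tibble(
    arm = c("treatment", "control"), time = c(1, 2), status = c(0L, 0L)
  )
  expect_error(estimate_hr_logrank(no_events), "at least one event")
})

test_that("log-rank estimate agrees with the Cox partial likelihood", {
  skip_if_not_installed("survival")
  for (seed in c(41, 42)) {
    d <- simulate_patient_level(trial_scenario(0.7, 10, 1500, seed = seed))
    ours <- estimate_hr_logrank(d)
    fit <- survival::coxph(
      survival::Surv(time, status) ~ arm == "treatment",
      data = d
    )
    expect_equal(ours$hr, exp(unname(stats::coef(fit))), tolerance = 0.02)
    # and the score decomposition matches survdiff's O-E
    sd <- survival::survdiff(survival::Surv(time, status) ~ arm, data = d)
    expect_equal(
      ours$o_minus_e,
      unname(sd$obs[2] - sd$exp[2]),
      tolerance = 1e-6
    )
  }
})

test_that("generated records validate and close the scoring pipeline", {
  designs <- c("superiority", "non_inferiority")
  for (i in 1:8) {
    sc <- trial_scenario(
      true_hr = c(0.4, 0.6, 0.8, 1.0)[(i - 1) %% 4 + 1],
      control_median_months = 8,
      n_per_arm = 300,
      design = designs[(i - 1) %/% 4 + 1],
      qol_improved = "yes",
      seed = 500L + i
    )
    rec <- generate_trial(sc, sprintf("closure-%d", i))
    expect_equal(nrow(validate_trials(rec)), 0)
    a <- asco_score(rec)
    expect_true(is.finite(a$nhb))
    e <- esmo_score(rec)
    expect_true(e$final_grade %in% 1:5)
  }
})

test_that("an all-laboratory AE profile yields zero toxicity points", {
  prof <- tibble::tibble(
    event_name = c("alt", "anemia"),
    grade_band = c("g3_4", "g3_4"),
    p_treatment = c(0.3, 0.2),
    p_control = c(0.2, 0.25),
    laboratory_only = TRUE
  )
  rec <- generate_trial(trial_scenario(0.6, 8, 200, ae_profile = prof, seed = 8))
  expect_equal(as.numeric(toxicity_points(rec$ae_table[[1]])), 0)
})

test_that("non-inferiority scenarios call the outcome from the simulated CI", {
  sc <- trial_scenario(1.0, 9, 3000,
    design = "non_inferiority",
    toxicity_improved = "yes", seed = 60
  )
  rec <- generate_trial(sc)
  ep <- rec$endpoints[[1]]
  expected <- if (ep$hr_ci_upper < 1.25) "yes" else "no"
  expect_equal(rec$noninferiority_met, expected)
  # a hugely harmful truth cannot be non-inferior
  bad <- generate_trial(trial_scenario(2.0, 9, 3000,
    design = "non_inferiority", seed = 61
  ))
  expect_equal(bad$noninferiority_met, "no")
})

test_that("scenario mimicking the cabozantinib+nivolumab trial concentrates on grade 4", {
  # PFS-primary, control median 8.3 months, strong effect, early stopping:
  # the modal ESMO final grade across replicates should be the fixture's 4
  grades <- integer(120)
  for (r in seq_along(grades)) {
    sc <- trial_scenario(
      true_hr = 0.51, control_median_months = 8.3, n_per_arm = 320,
      early_stop = "yes", censoring_rate = 0.02, seed = 7000L + r
    )
    grades[r] <- esmo_score(generate_trial(sc))$final_grade
  }
  tab <- table(grades)
  expect_equal(names(tab)[which.max(tab)], "4")
  expect_gt(mean(grades == 4), 0.5)
})
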