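test_that("form selection routes by design and primary endpoint", {
  trials <- rcc_trials()
  cm214 <- select_form(trials[trials$trial_id == "CheckMate 214", ])
  expect_equal(cm214$form, "2a")
  expect_equal(cm214$band, ">24mo")

  clear <- select_form(trials[trials$trial_id == "CLEAR", ])
  expect_equal(clear$form, "2b")
  expect_equal(clear$band, ">6mo")

  comparz <- select_form(trials[trials$trial_id == "COMPARZ", ])
  expect_equal(comparz$form, "2c")
  expect_true(is.na(comparz$band))
  expect_null(comparz$endpoint)

  # OS co-primary with unreached medians falls back to the PFS axis
  keynote <- select_form(trials[trials$trial_id == "Keynote 426", ])
  expect_equal(keynote$form, "2b")
  expect_equal(keynote$endpoint$kind, "PFS")

  # ORR-primary superiority trial is a form 2c case
  orr_primary <- make_trial(
    primary_endpoints = "ORR",
    endpoints = endpoint_result("ORR", rr_treatment = 40, rr_control = 20)
  )
  expect_equal(select_form(orr_primary)$form, "2c")

  # nothing gradeable and no override: error
  os_only <- make_trial(
    primary_endpoints = "OS",
    endpoints = make_endpoint("OS", mt = Inf, mc = Inf)
  )
  expect_error(select_form(os_only), "band_override")
  forced <- select_form(os_only, band_override = ">24mo")
  expect_equal(forced$form, "2a")
  expect_equal(forced$band, ">24mo")
})

test_that("control-median bands cut at 12/24 months (OS) and 6 months (PFS)", {
  os_trial <- function(mc) {
    make_trial(
      primary_endpoints = "OS",
      endpoints = make_endpoint("OS", mt = mc + 3, mc = mc)
    )
  }
  expect_equal(select_form(os_trial(10))$band, "<=12mo")
  expect_equal(select_form(os_trial(12))$band, "<=12mo")
  expect_equal(select_form(os_trial(18))$band, "12-24mo")
  expect_equal(select_form(os_trial(24.1))$band, ">24mo")
  pfs_trial <- function(mc) {
    make_trial(endpoints = make_endpoint("PFS", mt = mc + 2, mc = mc))
  }
  expect_equal(select_form(pfs_trial(5))$band, "<=6mo")
  expect_equal(select_form(pfs_trial(9.2))$band, ">6mo")
})

test_that("the grading basis is the lower confidence bound", {
  expect_equal(hr_basis(make_endpoint("OS", hr = 0.63, lower = 0.44, upper = 0.89)), 0.44)
  expect_equal(hr_basis(make_endpoint("PFS", hr = 0.69, lower = 0.57, upper = 0.84)), 0.57)
  degenerate <- make_endpoint("PFS", hr = 0.5, lower = 0.5, upper = 0.6)
  expect_equal(hr_basis(degenerate), 0.5)
  expect_error(hr_basis(endpoint_result("OS", hr_point = 0.6)), "hr_ci_lower")
})

test_that("preliminary grades come from the highest satisfied threshold row", {
  expect_equal(preliminary_grade("2a", ">24mo", 0.44, 15.2), 4L)
  expect_equal(preliminary_grade("2a", ">24mo", 0.70, 9), 4L)
  expect_equal(preliminary_grade("2a", ">24mo", 0.70, 8), 3L)
  expect_equal(preliminary_grade("2a", ">24mo", 0.71, 20), 2L)
  expect_equal(preliminary_grade("2b", ">6mo", 0.57, 4), 3L)
  expect_equal(preliminary_grade("2b", ">6mo", 0.90, 0.5), 1L)
  expect_equal(preliminary_grade("2b", ">6mo", 0.70, 2), 2L)
  expect_error(preliminary_grade("2b", "no-band", 0.5, 5), "band")
  # an unknown gain or basis cannot satisfy any row
  expect_equal(preliminary_grade("2b", ">6mo", NA, 5), 1L)
})

test_that("the threshold engine agrees with brute-force row evaluation", {
  tab <- esmo_thresholds()
  combos <- unique(tab[c("form", "band")])
  withr::with_seed(5, {
    for (k in seq_len(nrow(combos))) {
      for (i in 1:60) {
        hr <- stats::runif(1, 0.2, 1.1)
        gain <- stats::runif(1, 0, 20)
        expect_identical(
          preliminary_grade(combos$form[k], combos$band[k], hr, gain, tab),
          as.integer(oracle_preliminary_grade(
            combos$form[k], combos$band[k], hr, gain, tab
          ))
        )
      }
    }
  })
})

test_that("grade never decreases as the hazard ratio falls or the gain rises", {
  tab <- esmo_thresholds()
  hrs <- seq(1.1, 0.2, by = -0.05)
  gains <- seq(0, 16, by = 1)
  combos <- unique(tab[c("form", "band")])
  for (k in seq_len(nrow(combos))) {
    for (g in gains) {
      grades <- vapply(
        hrs,
        function(h) preliminary_grade(combos$form[k], combos$band[k], h, g, tab),
        integer(1)
      )
      expect_true(all(diff(grades) >= 0))
    }
    for (h in hrs) {
      grades <- vapply(
        gains,
        function(g) preliminary_grade(combos$form[k], combos$band[k], h, g, tab),
        integer(1)
      )
      expect_true(all(diff(grades) >= 0))
    }
  }
})

test_that("a malformed threshold table is rejected", {
  tab <- esmo_thresholds()
  bad <- tab
  # make grade 4 laxer than grade 3 in one band
  bad$hr_lower_max[bad$form == "2a" & bad$band == ">24mo" & bad$grade == 4] <- 0.95
  expect_error(oncovalue:::check_threshold_table(bad), "monotone")
  bad2 <- tab
  bad2$grade[1] <- 5L
  expect_error(oncovalue:::check_threshold_table(bad2), "2-4")
})

test_that("form 2c grades from non-inferiority plus improvement flags", {
  comparz <- rcc_trials()[1, ]
  expect_equal(grade_2c(comparz), 4L)
  plain <- make_trial(design = "non_inferiority", noninferiority_met = "yes")
  expect_equal(grade_2c(plain), 2L)
  inferior <- make_trial(design = "non_inferiority", noninferiority_met = "no")
  expect_equal(grade_2c(inferior), 1L)
  missing <- make_trial(design = "non_inferiority")
  expect_error(grade_2c(missing), "noninferiority_met")
})

test_that("adjustments upgrade by at most one level, capped at five", {
  tox_yes <- make_trial(toxicity_improved = "yes")
  out <- apply_adjustments(4L, "2a", tox_yes)
  expect_equal(out$final_grade, 5L)
  expect_equal(out$adjustments_applied, "toxicity")

  early <- make_trial(early_stop_or_crossover = "yes")
  out <- apply_adjustments(3L, "2b", early)
  expect_equal(out$final_grade, 4L)
  expect_equal(out$adjustments_applied, "early_stop_crossover")

  none <- make_trial()
  out <- apply_adjustments(3L, "2b", none)
  expect_equal(out$final_grade, 3L)
  expect_length(out$adjustments_applied, 0)

  # early stopping is excluded for form 2a
  out <- apply_adjustments(3L, "2a", early)
  expect_equal(out$final_grade, 3L)

  # several satisfied flags still yield a single upgrade
  both <- make_trial(early_stop_or_crossover = "yes", qol_improved = "yes")
  out <- apply_adjustments(3L, "2b", both)
  expect_equal(out$final_grade, 4L)
  expect_equal(out$adjustments_applied, "early_stop_crossover")

  # plateau is inert unless enabled
  plateau <- make_trial(plateau_of_curve = "yes")
  expect_equal(apply_adjustments(3L, "2b", plateau)$final_grade, 3L)
  expect_equal(
    apply_adjustments(3L, "2b", plateau, include_plateau = TRUE)$final_grade, 4L
  )

  # cap at 5
  expect_equal(apply_adjustments(4L, "2b", early)$final_grade, 5L)
})

test_that("upgrade bound holds across random records", {
  withr::with_seed(31, {
    for (i in 1:40) {
      rec <- make_trial(
        qol_improved = sample(c("yes", "no", "unknown"), 1),
        toxicity_improved = sample(c("yes", "no", "unknown"), 1),
        early_stop_or_crossover = sample(c("yes", "no", "unknown"), 1)
      )
      prelim <- sample(1:4, 1)
      form <- sample(c("2a", "2b"), 1)
      out <- apply_adjustments(prelim, form, rec)
      expect_true((out$final_grade - prelim) %in% c(0L, 1L))
      expect_lte(out$final_grade, 5L)
    }
  })
})

test_that("grade_trial composes the pipeline for the fixtures", {
  trials <- rcc_trials()
  g9er <- grade_trial(trials[trials$trial_id == "CheckMate 9ER", ])
  expect_equal(g9er$final_grade, 4L)
  expect_equal(g9er$preliminary_grade, 3L)
  expect_equal(g9er$adjustments_applied[[1]], "early_stop_crossover")

  javelin <- grade_trial(trials[trials$trial_id == "JAVELIN renal 101", ])
  expect_equal(javelin$final_grade, 3L)
  expect_equal(javelin$hr_lower_used, 0.56)

  weak <- make_trial(endpoints = make_endpoint("PFS",
    hr = 0.995, lower = 0.99,
    upper = 1.0, mt = 8.1, mc = 8.1
  ))
  expect_equal(grade_trial(weak)$final_grade, 1L)
})

test_that("esmo tidy and glance summarise the grade table", {
  scores <- esmo_score(rcc_trials())
  tl <- tidy(scores)
  expect_equal(sum(tl$upgraded), 3)
  g <- glance(scores)
  expect_equal(g$n_trials, 6)
  expect_equal(g$n_upgraded, 3)
  expect_equal(g$n_grade_4_or_5, 4)
})
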