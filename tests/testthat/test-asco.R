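test_that("benefit endpoint selection prefers significant OS, then PFS, then ORR", {
  trials <- rcc_trials()
  keynote <- trials[trials$trial_id == "Keynote 426", ]
  expect_equal(select_benefit_endpoint(keynote)$kind, "OS")

  javelin <- trials[trials$trial_id == "JAVELIN renal 101", ]
  expect_equal(select_benefit_endpoint(javelin)$kind, "PFS")
  expect_equal(select_benefit_endpoint(javelin, "PD-L1-positive")$kind, "PFS")

  comparz <- trials[trials$trial_id == "COMPARZ", ]
  expect_null(select_benefit_endpoint(comparz))

  orr_only <- make_trial(endpoints = endpoint_result("ORR",
    rr_treatment = 40, rr_control = 25
  ))
  expect_equal(select_benefit_endpoint(orr_only)$kind, "ORR")

  expect_error(
    select_benefit_endpoint(keynote, "no-such-group"),
    "available.*ITT"
  )
})

test_that("clinical benefit scores follow the endpoint weighting", {
  os <- function(hr) make_endpoint("OS", hr = hr, lower = hr - 0.05, upper = hr + 0.05)
  pfs <- function(hr) make_endpoint("PFS", hr = hr, lower = hr - 0.05, upper = hr + 0.05)
  expect_equal(clinical_benefit_score(os(0.53)), 47)
  expect_equal(clinical_benefit_score(pfs(0.69)), 24.8)
  expect_equal(clinical_benefit_score(os(1.0)), 0)
  expect_equal(clinical_benefit_score(NULL), 0)
  # boundary values of the score
  expect_equal(clinical_benefit_score(os(1e-12)), 100)
  expect_equal(clinical_benefit_score(pfs(1e-12)), 80)
  # relative ORR improvement with the 0.7 weighting
  orr <- endpoint_result("ORR", rr_treatment = 40, rr_control = 25)
  expect_equal(clinical_benefit_score(orr), round_half_up(15 / 25 * 100 * 0.7, 1))
  # missing required fields are named
  expect_error(
    clinical_benefit_score(endpoint_result("OS")),
    "hr_point"
  )
  expect_error(
    clinical_benefit_score(endpoint_result("ORR", rr_treatment = 10)),
    "rr_"
  )
})

test_that("clinical benefit is strictly decreasing in the hazard ratio", {
  hrs <- seq(0.05, 1.2, by = 0.05)
  for (kind in c("OS", "PFS")) {
    cb <- vapply(
      hrs,
      function(h) {
        clinical_benefit_score(
          make_endpoint(kind, hr = h, lower = h, upper = h),
          asco_config(rounding = 8)
        )
      },
      numeric(1)
    )
    expect_true(all(diff(cb) < 0))
  }
})

test_that("arm toxicity burden weights grade bands and skips laboratory rows", {
  expect_equal(toxicity_arm_score(ae_prototype_(), "treatment"), 0)
  one <- ae_row("e", "g3_4", 10, 0)
  expect_equal(toxicity_arm_score(one, "treatment"), 20)
  expect_equal(toxicity_arm_score(one, "control"), 0)
  # hand-computed three-row table (values frozen from the helper oracle):
  # 0.5*30 + 2*10 = 35 (treatment), 0.5*35 + 2*15 = 47.5 (control);
  # the laboratory-only row contributes nothing
  three <- dplyr::bind_rows(
    ae_row("a", "g1_2", 30, 35),
    ae_row("b", "g3_4", 10, 15),
    ae_row("lab", "g3_4", 20, 5, laboratory_only = TRUE)
  )
  expect_equal(toxicity_arm_score(three, "treatment"), 35)
  expect_equal(toxicity_arm_score(three, "control"), 47.5)
})

test_that("toxicity points scale the relative arm difference and clamp", {
  same <- dplyr::bind_rows(
    ae_row("a", "g1_2", 30, 30),
    ae_row("b", "g3_4", 12, 12)
  )
  expect_equal(toxicity_points(same), 0)
  expect_equal(toxicity_points(ae_prototype_()), 0)
  # control has events, treatment none: clamp at +20
  expect_equal(toxicity_points(ae_row("a", "g3_4", 0, 30)), 20)
  # hand value for a crafted 4-row table:
  # s_t = 0.5*20 + 2*12 + 2*5 = 44, s_c = 0.5*30 + 2*10 + 2*8 = 51
  # points = 20 * (51 - 44) / 51
  four <- dplyr::bind_rows(
    ae_row("a", "g1_2", 20, 30),
    ae_row("b", "g3_4", 12, 10),
    ae_row("c", "g3_4", 5, 8),
    ae_row("lab", "g1_2", 40, 10, laboratory_only = TRUE)
  )
  expect_equal(as.numeric(toxicity_points(four)), 20 * 7 / 51)
  # zero control burden against a non-zero treatment burden: floor with note
  floor_case <- toxicity_points(ae_row("a", "g3_4", 10, 0))
  expect_equal(as.numeric(floor_case), -20)
  expect_match(attr(floor_case, "note"), "zero toxicity burden")
})

test_that("toxicity points are antisymmetric under arm swap when unclamped", {
  withr::with_seed(7, {
    for (i in 1:25) {
      ae <- random_ae_table(sample(2:8, 1))
      swapped <- ae
      swapped$incidence_treatment <- ae$incidence_control
      swapped$incidence_control <- ae$incidence_treatment
      s_t <- toxicity_arm_score(ae, "treatment")
      s_c <- toxicity_arm_score(ae, "control")
      if (s_t > 0 && s_c > 0) {
        p1 <- 20 * (s_c - s_t) / s_c
        p2 <- 20 * (s_t - s_c) / s_t
        if (abs(p1) < 20 && abs(p2) < 20) {
          expect_equal(
            as.numeric(toxicity_points(ae)) * s_c,
            -as.numeric(toxicity_points(swapped)) * s_t,
            tolerance = 1e-12
          )
        }
      }
    }
  })
})

test_that("removing a laboratory-only row never changes any score", {
  withr::with_seed(11, {
    for (i in 1:20) {
      ae <- random_ae_table(6)
      stripped <- ae[!ae$laboratory_only, ]
      expect_identical(
        as.numeric(toxicity_points(ae)),
        as.numeric(toxicity_points(stripped))
      )
      for (arm in c("treatment", "control")) {
        expect_identical(
          toxicity_arm_score(ae, arm),
          toxicity_arm_score(stripped, arm)
        )
      }
    }
  })
})

test_that("toxicity points match the spreadsheet oracle on random tables", {
  withr::with_seed(23, {
    for (i in 1:200) {
      ae <- random_ae_table(sample(1:10, 1))
      expect_equal(
        as.numeric(toxicity_points(ae)),
        oracle_toxicity_points(ae),
        tolerance = 1e-9
      )
    }
  })
})

test_that("bonus points follow the tristate flags and the rule hooks", {
  paz <- rcc_trials()[1, ]
  b <- bonus_points(paz)
  expect_equal(b$bonus_qol, 10)
  expect_equal(b$bonus_palliation, 0)
  expect_equal(b$bonus_tail, 0)
  expect_equal(b$bonus_tfi, 0)

  none <- make_trial(qol_improved = "no", palliation_improved = "unknown")
  b0 <- bonus_points(none)
  expect_equal(
    unlist(b0[c("bonus_tail", "bonus_palliation", "bonus_qol", "bonus_tfi")]),
    c(bonus_tail = 0, bonus_palliation = 0, bonus_qol = 0, bonus_tfi = 0)
  )
  expect_match(b0$notes[[1]], "palliation flag unknown", all = FALSE)

  cfg <- asco_config(
    tail_bonus_rule = function(r) 16,
    tfi_bonus_rule = function(r) if (r$design == "superiority") 4 else 0
  )
  bh <- bonus_points(none, cfg)
  expect_equal(bh$bonus_tail, 16)
  expect_equal(bh$bonus_tfi, 4)
})

test_that("net health benefit is the exact sum of its reported components", {
  scores <- asco_score(rcc_trials())
  expect_equal(
    scores$nhb,
    scores$clinical_benefit + scores$toxicity + scores$bonus_tail +
      scores$bonus_palliation + scores$bonus_qol + scores$bonus_tfi
  )
  # a non-inferiority record notes the omitted clinical benefit
  expect_match(scores$notes[[1]], "non-inferiority", all = FALSE)
})

test_that("asco tidy and glance summarise the score table", {
  scores <- asco_score(rcc_trials())
  long <- tidy(scores)
  expect_setequal(
    unique(long$component),
    c(
      "clinical_benefit", "toxicity", "bonus_tail", "bonus_palliation",
      "bonus_qol", "bonus_tfi", "nhb"
    )
  )
  g <- glance(scores)
  expect_equal(g$n_trials, 6)
  expect_equal(g$max_nhb, max(scores$nhb))
})

test_that("asco config validates its constants and reads overrides from JSON", {
  expect_error(asco_config(pfs_weight = -1), "positive")
  expect_error(asco_config(tox_scale = 0), "positive")
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"pfs_weight": 1.0, "rounding": 2}', path)
  cfg <- read_asco_config(path)
  expect_equal(cfg$pfs_weight, 1.0)
  expect_equal(cfg$rounding, 2)
  writeLines('{"no_such_knob": 1}', path)
  expect_error(read_asco_config(path), "no_such_knob")
})
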