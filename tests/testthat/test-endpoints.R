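# Endpoint-derivation rules: onset dating, weight-loss onset, wire hang,
# euthanasia criteria, censoring classification, innervation and dosing
# arithmetic.

test_that("best-of-three hang takes the session maximum and flags missing", {
  expect_equal(best_of_three_hang(c(60, 23, 41)), 60)
  expect_equal(best_of_three_hang(c(0, 0, 0)), 0)
  expect_equal(best_of_three_hang(12), 12)
  expect_true(is.na(best_of_three_hang(c(NA, NA, NA))))
  expect_error(best_of_three_hang(c(10, 20, 30, 40)), "at most 3")
  expect_error(best_of_three_hang(65), "\\[0, 60\\]")
})

test_that("two-consecutive onset rule: worked examples and dating options", {
  tl <- mouse_timeline(make_timeline(c(63, 66, 68),
                                     tremor = c(FALSE, TRUE, TRUE)))
  r <- early_symptom_onset(tl)
  expect_true(r$observed)
  expect_equal(r$age_days, 66)                       # first of the pair
  expect_equal(early_symptom_onset(tl, date = "second")$age_days, 68)

  # alternating positives never satisfy consecutiveness
  tl2 <- mouse_timeline(make_timeline(c(60, 62, 65, 67, 70),
                                      tremor = c(TRUE, FALSE, TRUE, FALSE, TRUE)))
  r2 <- early_symptom_onset(tl2)
  expect_false(r2$observed)
  expect_equal(r2$age_days, 70)

  # extension loss alone also makes a session positive
  tl3 <- mouse_timeline(make_timeline(c(60, 62, 65),
                                      tremor = c(FALSE, TRUE, FALSE),
                                      extension = c(FALSE, FALSE, TRUE)))
  r3 <- early_symptom_onset(tl3)
  expect_true(r3$observed)
  expect_equal(r3$age_days, 62)
})

test_that("onset rule matches the brute-force oracle on all 64 sequences", {
  ages <- c(50, 53, 56, 59, 62, 65)
  for (code in 0:63) {
    flags <- as.logical(bitwAnd(bitwShiftR(code, 0:5), 1L))
    tl <- mouse_timeline(make_timeline(ages, tremor = flags))
    for (dating in c("first", "second")) {
      got <- early_symptom_onset(tl, date = dating)
      want <- oracle_onset(flags, ages, date = dating)
      expect_identical(got$observed, want$observed)
      expect_equal(got$age_days, want$age)
    }
  }
})

test_that("weight-loss onset: sustained-drop rule and dip handling", {
  # worked example: peak 22, first sustained drop below 0.95*22 = 20.9
  tl <- mouse_timeline(make_timeline(c(90, 95, 100, 105, 110),
                                     weights = c(20, 22, 22, 20.5, 19.8)))
  r <- weight_loss_onset(tl, drop_fraction = 0.05)
  expect_true(r$observed)
  expect_equal(r$age_days, 105)     # age of the 20.5 g observation

  # monotone increasing weights never trigger
  tl2 <- mouse_timeline(make_timeline(c(90, 95, 100), weights = c(20, 21, 22)))
  r2 <- weight_loss_onset(tl2)
  expect_false(r2$observed)
  expect_equal(r2$age_days, 100)

  # a dip below threshold followed by a new peak is ignored; onset is
  # found after the later peak
  tl3 <- mouse_timeline(make_timeline(
    c(90, 95, 100, 105, 110, 115),
    weights = c(20, 18.5, 21, 22, 20.5, 19)))
  r3 <- weight_loss_onset(tl3)
  expect_true(r3$observed)
  expect_equal(r3$age_days, 110)    # first sustained drop after peak 22

  # running peak is non-decreasing
  expect_true(all(diff(tl3$records$peak_weight_g) >= 0))
})

test_that("last full hang: scan, censoring at study end, degenerate flag", {
  mk_hang <- function(bests) {
    # three trials whose max is the requested session best
    cbind(bests, pmax(0, bests - 5), pmax(0, bests - 10))
  }
  ages <- c(90, 93, 97, 100, 104, 107)
  tl <- mouse_timeline(make_timeline(ages,
                                     hang = mk_hang(c(60, 60, 55, 60, 42, 30))))
  r <- last_full_hang_age(tl)
  expect_true(r$observed)
  expect_equal(r$age_days, 100)

  tl2 <- mouse_timeline(make_timeline(ages, hang = mk_hang(rep(60, 6))))
  r2 <- last_full_hang_age(tl2)
  expect_false(r2$observed)
  expect_equal(r2$age_days, 107)

  tl3 <- mouse_timeline(make_timeline(ages, hang = mk_hang(rep(45, 6))))
  r3 <- last_full_hang_age(tl3)
  expect_true(r3$observed)
  expect_equal(r3$age_days, 90)
  expect_identical(r3$flag, "never_full_hang")
})

test_that("euthanasia criteria boundaries", {
  # 20% weight loss boundary included
  expect_equal(euthanasia_due(16.0, 20.0), list(due = TRUE, reason = "weight_loss"))
  # righting strictly greater than 15 s
  expect_equal(euthanasia_due(19, 20, righting_s = 16),
               list(due = TRUE, reason = "righting_failure"))
  expect_equal(euthanasia_due(19, 20, righting_s = 15),
               list(due = FALSE, reason = "none"))
  expect_equal(euthanasia_due(16, 20, righting_s = 16)$reason, "both")
  # absent righting passes that criterion
  expect_false(euthanasia_due(19, 20)$due)
})

test_that("death-mode censoring classification matches the study taxonomy", {
  modes <- c("righting_failure", "weight_loss", "both",
             "found_dead_not_near_criteria", "found_dead_near_criteria",
             "injury_euthanasia", "weight_only_no_other_signs")
  want <- c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE)
  expect_identical(classify_death(modes), want)
  expect_error(classify_death("drowned"), "unknown death mode")
})

test_that("innervation percentage averages sides, not pooled counts", {
  left <- rep(c(TRUE, FALSE), c(900, 1100))    # 45.0%
  right <- rep(c(TRUE, FALSE), c(940, 1060))   # 47.0%
  r <- innervation_percent(left, right)
  expect_equal(r$percent, 46.0)
  expect_false(r$asymmetric)
  expect_equal(innervation_percent(rep(TRUE, 10), rep(TRUE, 5))$percent, 100)
  expect_warning(r2 <- innervation_percent(rep(c(TRUE, FALSE), c(45, 55)),
                                           logical(0)),
                 "one side")
  expect_equal(r2$percent, 45.0)
  expect_true(r2$asymmetric)
})

test_that("dose bracketing to 20 ul with ties rounding up", {
  d1 <- dose_volume_bracketed(24, 75)
  expect_equal(d1$exact_volume_ul, 180)
  expect_equal(d1$bracket_volume_ul, 180)
  expect_equal(d1$actual_dose_mg_per_kg, 75)
  d2 <- dose_volume_bracketed(22, 75)
  expect_equal(d2$exact_volume_ul, 165)
  expect_equal(d2$bracket_volume_ul, 160)
  expect_equal(d2$actual_dose_mg_per_kg, 1600 / 22, tolerance = 1e-12)
  d3 <- dose_volume_bracketed(20, 75)   # exact 150: tie, rounds up
  expect_equal(d3$bracket_volume_ul, 160)
  expect_equal(d3$actual_dose_mg_per_kg, 80)
})

test_that("formulation powder weight follows the salt-corrected formula", {
  expect_equal(formulation_powder_weight(0.915), 10)
  expect_equal(round(formulation_powder_weight(50), 2), 546.45)
  expect_equal(round(formulation_powder_weight(100), 2), 1092.90)
})

test_that("derive_endpoints produces three endpoints per animal", {
  cfg <- cohort_config(n_per_arm = 6, seed = 12)
  co <- simulate_cohort(cfg)
  ev <- derive_endpoints(co$timelines)
  expect_identical(nrow(ev), 3L * 12L)
  expect_setequal(unique(ev$endpoint),
                  c("early_symptom_onset", "weight_loss_onset",
                    "last_full_hang"))
  expect_true(all(ev$age_days >= min(co$timelines$age_days)))
  expect_true(all(ev$age_days <= max(co$timelines$age_days)))
})
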