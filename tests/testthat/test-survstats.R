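# Risk table, rank statistics, combined permutation test, Kaplan-Meier
# and Weibull comparison.

test_that("risk table matches the hand-built example and edge conventions", {
  s <- surv_sample(1:6, rep(TRUE, 6), rep(c("A", "B"), each = 3))
  rt <- build_risk_table(s)
  expect_equal(rt$t, 1:6)
  expect_equal(rt$n, 6:1)
  expect_equal(rt$n1, c(3, 2, 1, 0, 0, 0))
  expect_equal(rt$e1, c(0.5, 0.4, 0.25, 0, 0, 0))
  expect_equal(rt$v[1:3], c(0.25, 0.24, 0.1875))

  one <- surv_sample(5, TRUE, factor("A", levels = c("A", "B")))
  rt1 <- build_risk_table(one)
  expect_identical(nrow(rt1), 1L)
  expect_equal(rt1$n, 1)
  expect_equal(rt1$v, 0)          # variance convention at n = 1
  tie <- surv_sample(c(2, 2), c(TRUE, FALSE), c("A", "B"))
  rt_tie <- build_risk_table(tie)
  expect_equal(rt_tie$n, 2)        # censored at t still at risk at t
  allcens <- surv_sample(1:4, rep(FALSE, 4), rep(c("A", "B"), 2))
  expect_identical(nrow(build_risk_table(allcens)), 0L)
})

test_that("log-rank and Gehan Z reproduce the worked example", {
  s <- surv_sample(1:6, rep(TRUE, 6), rep(c("A", "B"), each = 3))
  rt <- build_risk_table(s)
  expect_equal(sum(rt$d1 - rt$e1), 1.85)
  expect_equal(sum(rt$v), 0.6775)
  expect_equal(logrank_z(rt), 1.85 / sqrt(0.6775), tolerance = 1e-12)
  expect_equal(gehan_wilcoxon_z(rt), 9 / sqrt(18), tolerance = 1e-12)
  # unit weights degrade the Wilcoxon statistic to the log-rank one
  expect_equal(gehan_wilcoxon_z(rt, weights = rep(1, nrow(rt))),
               logrank_z(rt), tolerance = 1e-12)
})

test_that("Z statistics negate under group-label swap", {
  set.seed(11)
  tt <- rexp(12) + 0.5; ev <- runif(12) < 0.7
  g <- rep(c("x", "y"), 6)
  z1 <- logrank_z(build_risk_table(surv_sample(tt, ev, g)))
  g2 <- factor(g, levels = c("y", "x"))
  z2 <- logrank_z(build_risk_table(surv_sample(tt, ev, g2)))
  expect_equal(z1, -z2, tolerance = 1e-12)
})

test_that("fuzzed small samples match the brute-force risk-set oracle", {
  set.seed(42)
  checked <- 0
  for (i in 1:150) {
    f <- fuzz_surv_sample()
    s <- surv_sample(f$time, f$event, f$group)
    rt <- build_risk_table(s)
    zo <- oracle_rank_zs(f$time, f$event, f$group == "a")
    if (nrow(rt) == 0 || sum(rt$v) == 0 || is.na(zo["z_lr"])) next
    expect_equal(logrank_z(rt), unname(zo["z_lr"]), tolerance = 1e-10)
    expect_equal(gehan_wilcoxon_z(rt), unname(zo["z_w"]), tolerance = 1e-10)
    checked <- checked + 1
  }
  expect_gt(checked, 80)
})

test_that("Gehan weighting emphasizes early separation", {
  # separation confined to early event times should favor the Gehan
  # statistic over the log-rank, and vice versa for late separation;
  # checked as averages over seeded replicates (the statistics are
  # rank-based, so a single symmetric example cannot distinguish them)
  set.seed(31)
  diff_early <- replicate(200, {
    a <- c(runif(10, 0, 5), runif(10, 20, 30))
    b <- c(runif(10, 5, 10), runif(10, 20, 30))
    rt <- build_risk_table(surv_sample(c(a, b), rep(TRUE, 40),
                                       rep(c("a", "b"), each = 20)))
    abs(gehan_wilcoxon_z(rt)) - abs(logrank_z(rt))
  })
  diff_late <- replicate(200, {
    a <- c(runif(10, 0, 10), runif(10, 20, 25))
    b <- c(runif(10, 0, 10), runif(10, 25, 30))
    rt <- build_risk_table(surv_sample(c(a, b), rep(TRUE, 40),
                                       rep(c("a", "b"), each = 20)))
    abs(gehan_wilcoxon_z(rt)) - abs(logrank_z(rt))
  })
  expect_gt(mean(diff_early), 0)
  expect_lt(mean(diff_late), 0)
})

test_that("combined permutation test is exhaustive and exact on the worked example", {
  s <- surv_sample(1:6, rep(TRUE, 6), rep(c("A", "B"), each = 3))
  r1 <- combined_permutation_test(s, seed = 1)
  expect_true(r1$exhaustive)
  expect_identical(r1$n_permutations, 20L)
  expect_equal(r1$m_observed, max(abs(r1$z_logrank), abs(r1$z_wilcoxon)))
  expect_equal(r1$m_observed, 1.85 / sqrt(0.6775), tolerance = 1e-12)
  expect_equal(r1$p_permutation, 2 / 20)
  # bit-for-bit reproducible regardless of the Monte-Carlo seed argument
  r2 <- combined_permutation_test(s, seed = 999)
  expect_identical(r1$p_permutation, r2$p_permutation)
})

test_that("Monte-Carlo permutation p uses the add-one estimator and its floor", {
  set.seed(3)
  tt <- c(rweibull(15, 8, 120), rweibull(15, 8, 200))
  s <- surv_sample(tt, rep(TRUE, 30), rep(c("a", "b"), each = 15))
  r <- combined_permutation_test(s, B = 99, seed = 7, exhaustive_limit = 10)
  expect_false(r$exhaustive)
  expect_gte(r$p_permutation, 1 / 100)
  expect_lte(r$p_permutation, 1)
  r2 <- combined_permutation_test(s, B = 99, seed = 7, exhaustive_limit = 10)
  expect_identical(r$p_permutation, r2$p_permutation)
})

test_that("Kaplan-Meier product-limit estimate, median and restricted mean", {
  k <- km_estimate(c(1, 2, 3, 4), rep(TRUE, 4))
  expect_equal(k$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(k$median, 2)
  expect_equal(k$restricted_mean, 2.5)
  allc <- km_estimate(c(3, 5, 9), rep(FALSE, 3))
  expect_true(is.na(allc$median))
  expect_equal(allc$restricted_mean, 9)   # S = 1 throughout
  # censoring-aware cross-check against the survival package
  set.seed(21)
  tt <- rweibull(40, 3, 100); ev <- runif(40) < 0.7
  k2 <- km_estimate(tt, ev)
  sf <- survival::survfit(survival::Surv(tt, ev) ~ 1)
  expect_equal(k2$surv, summary(sf, times = k2$time)$surv, tolerance = 1e-10)
})

test_that("Weibull LRT: scale equivariance and hand-computed likelihood", {
  set.seed(5)
  tt <- c(rweibull(40, 8, 150), rweibull(40, 8, 170))
  ev <- rep(TRUE, 80); gr <- rep(c("v", "t"), each = 40)
  f1 <- weibull_lrt(surv_sample(tt, ev, gr))
  f2 <- weibull_lrt(surv_sample(3 * tt, ev, gr))
  expect_equal(f2$shape, f1$shape, tolerance = 1e-4)
  expect_equal(unname(f2$scale_by_group), unname(3 * f1$scale_by_group),
               tolerance = 1e-4)
  expect_equal(f1$median_by_group,
               f1$scale_by_group * log(2)^(1 / f1$shape))
  # hand-written censored Weibull log-likelihood at the fitted optimum
  set.seed(6)
  tt <- rweibull(60, 5, 100); ev <- runif(60) < 0.8
  gr <- rep(c("v", "t"), each = 30)
  fit <- weibull_lrt(surv_sample(tt, ev, gr))
  k <- fit$shape
  lam <- ifelse(gr == "v", fit$scale_by_group[1], fit$scale_by_group[2])
  ll <- sum(ifelse(ev,
                   log(k / lam) + (k - 1) * log(tt / lam) - (tt / lam)^k,
                   -(tt / lam)^k))
  expect_equal(fit$loglik_full, ll, tolerance = 1e-6)
  expect_gte(fit$lrt_stat, 0)
})

test_that("qPCR delta-delta-Ct fold changes", {
  # ddCt = 0 -> fold 1; one-cycle shift doubles
  mk <- function(shift) {
    data.frame(sample_id = sprintf("s%d", 1:8),
               group = rep(c("wt", "tg"), each = 4),
               ct_target = c(rep(20, 4), rep(20 + shift, 4)),
               ct_reference = rep(15, 8))
  }
  expect_equal(qpcr_fold_change(mk(0), control = "wt")$fold_change, 1)
  expect_equal(qpcr_fold_change(mk(-1), control = "wt")$fold_change, 2)
  r <- qpcr_fold_change(mk(0.8365), control = "wt")
  expect_equal(round(r$fold_change, 2), 0.56)
  # missing reference Ct excludes the sample with a warning
  d <- mk(1); d$ct_reference[1] <- NA
  expect_warning(qpcr_fold_change(d, control = "wt"), "excluded")
})

test_that("endpoint summary table has per-arm KM columns and Holm column", {
  set.seed(9)
  ev <- data.frame(
    mouse_id = rep(sprintf("m%02d", 1:30), 2),
    arm = rep(rep(c("vehicle", "treated"), each = 15), 2),
    endpoint = rep(c("onset", "hang"), each = 30),
    age_days = c(rweibull(30, 6, 80), rweibull(30, 6, 110)),
    observed = runif(60) < 0.9)
  tab <- summarize_endpoints(ev, B = 200, seed = 4)
  expect_identical(nrow(tab), 2L)
  expect_true(all(c("median_vehicle", "median_treated",
                    "p_combined_holm") %in% names(tab)))
  expect_true(all(tab$p_combined >= 0 & tab$p_combined <= 1))
})
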