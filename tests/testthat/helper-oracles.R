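# Independent brute-force oracles and small fixture builders shared by
# the unit and acceptance tests. These deliberately use naive explicit
# loops, not the package's vectorized path.

# Brute-force risk-set computation of the log-rank and Gehan-Wilcoxon
# Z statistics: for every distinct event time walk the full sample.
oracle_rank_zs <- function(time, event, is_group1) {
  et <- sort(unique(time[event]))
  U_lr <- 0; V_lr <- 0; U_w <- 0; V_w <- 0
  for (t in et) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & is_group1)
    d <- sum(event & time == t)
    d1 <- sum(event & time == t & is_group1)
    e1 <- d * n1 / n
    v <- if (n > 1) n1 * (n - n1) * d * (n - d) / (n^2 * (n - 1)) else 0
    U_lr <- U_lr + (d1 - e1); V_lr <- V_lr + v
    U_w <- U_w + n * (d1 - e1); V_w <- V_w + n^2 * v
  }
  c(z_lr = if (V_lr > 0) U_lr / sqrt(V_lr) else NA_real_,
    z_w = if (V_w > 0) U_w / sqrt(V_w) else NA_real_)
}

# Brute-force two-consecutive-positives onset scan: test every adjacent
# pair explicitly.
oracle_onset <- function(flags, ages, date = "first") {
  for (i in seq_len(length(flags) - 1)) {
    if (flags[i] && flags[i + 1]) {
      return(list(age = if (date == "first") ages[i] else ages[i + 1],
                  observed = TRUE))
    }
  }
  list(age = ages[length(ages)], observed = FALSE)
}

# Seeded fuzzer: small censored two-group samples (ties and heavy
# censoring included on purpose).
fuzz_surv_sample <- function(n_max = 8) {
  n <- sample(3:n_max, 1)
  n1 <- sample(1:(n - 1), 1)
  time <- sample(1:5, n, replace = TRUE)        # ties likely
  event <- runif(n) < 0.7
  group <- c(rep("a", n1), rep("b", n - n1))
  list(time = time, event = event, group = group)
}

# minimal timeline data.frame for endpoint tests
make_timeline <- function(ages, weights = NULL, tremor = NULL,
                          extension = NULL, hang = NULL, id = "m1") {
  k <- length(ages)
  df <- data.frame(
    mouse_id = id, age_days = ages,
    weight_g = if (is.null(weights)) rep(20, k) else weights,
    tremor = if (is.null(tremor)) rep(FALSE, k) else tremor,
    extension_loss = if (is.null(extension)) rep(FALSE, k) else extension)
  if (!is.null(hang)) {
    df$hang1 <- hang[, 1]; df$hang2 <- hang[, 2]; df$hang3 <- hang[, 3]
  }
  df
}

# small shared scene for image tests (kept modest so the suite is quick)
small_scene <- function(...) {
  scene_config(canvas_px = c(320, 320), tissue_shape = "ellipse",
               cell_diameter_um = c(15, 32), ...)
}
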