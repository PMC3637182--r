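# Two-arm SOD1-like cohort simulator: latent onset ages, Weibull death
# times (treatment acting on the scale), logistic-then-declining weight
# trajectories, symptom flags ramping after latent onset, wire-hang
# decline, non-disease (injection-related) competing deaths, and the
# balance-beam trial generator.

#' Default observation schedule
#'
#' Two sessions per week from 42 to 63 days of age, three per week
#' thereafter (evenly spaced within weeks), up to `max_age`.
#'
#' @param start first observation age (default 42).
#' @param max_age last possible observation age (default 210).
#' @return integer vector of strictly increasing ages in days.
#' @export
observation_schedule <- function(start = 42, max_age = 210) {
  early <- round(seq(start, 63, by = 3.5))
  late <- round(seq(63 + 7 / 3, max_age, by = 7 / 3))
  unique(c(early, late))
}

#' Cohort simulation configuration
#'
#' Defaults describe a SOD1-G93A-like high-copy cohort: tight Weibull
#' survival around 150-160 days, latent early-symptom onset near 70 days,
#' weight peaking near 105 days then declining proportionally, wire-hang
#' failure beginning in the mid-90s, and a constant daily hazard of
#' injection-related (non-disease) death after 110 days calibrated to a
#' roughly 20-25% censoring incidence.
#'
#' @param n_per_arm animals per arm.
#' @param schedule observation ages; see [observation_schedule()].
#' @param weibull_shape,weibull_scale_control Weibull death-time model
#'   for the control arm (days).
#' @param treatment_time_ratio multiplier on the Weibull scale for the
#'   treated arm (1 = no survival effect).
#' @param onset_mean,onset_sd,onset_shift_treated latent symptom-onset
#'   age distribution (normal, days); the treated mean is shifted by
#'   `onset_shift_treated`.
#' @param weight_asymptote_g,weight_asymptote_sd_g,weight_growth_rate,weight_midpoint_age
#'   pre-peak logistic weight growth.
#' @param weight_peak_age_mean,weight_peak_age_sd latent age of peak
#'   weight; decline afterwards is linear-proportional at
#'   `weight_decline_rate` per day.
#' @param weight_decline_rate,weight_noise_sd decline slope and
#'   observation noise (grams).
#' @param symptom_baseline,symptom_prob_ramp per-session probability of
#'   a positive tremor/extension flag: `baseline` before latent onset,
#'   ramping by `symptom_prob_ramp` per day after it (clamped to 1).
#' @param hang_decline_age_mean,hang_decline_age_sd,hang_decline_rate,hang_noise_sd
#'   wire-hang latent decline: 60 s until the per-animal
#'   decline age, then dropping `hang_decline_rate` s/day; per-trial
#'   Gaussian noise, clamped to `[0, 60]`.
#' @param injection_death_rate daily hazard of non-disease death after
#'   `injection_min_age` (0 disables the competing risk).
#' @param injection_min_age youngest possible non-disease death age.
#' @param beam_params list of fixed effects and random-effect SDs for
#'   the beam generator (see [simulate_beam()]).
#' @param seed integer seed; identical configs reproduce bit-identical
#'   cohorts.
#' @return `cohort_config` list.
#' @export
cohort_config <- function(n_per_arm = 48,
                          schedule = observation_schedule(),
                          weibull_shape = 8,
                          weibull_scale_control = 160,
                          treatment_time_ratio = 1.0,
                          onset_mean = 70, onset_sd = 8,
                          onset_shift_treated = 0,
                          weight_asymptote_g = 24,
                          weight_asymptote_sd_g = 1.5,
                          weight_growth_rate = 0.08,
                          weight_midpoint_age = 30,
                          weight_peak_age_mean = 105,
                          weight_peak_age_sd = 8,
                          weight_decline_rate = 0.004,
                          weight_noise_sd = 0.3,
                          symptom_baseline = 0,
                          symptom_prob_ramp = 0.15,
                          hang_decline_age_mean = 95,
                          hang_decline_age_sd = 10,
                          hang_decline_rate = 1.5,
                          hang_noise_sd = 3,
                          injection_death_rate = 0.0055,
                          injection_min_age = 110,
                          beam_params = list(
                            latency_intercept = 80, latency_size_slope = -3,
                            latency_treatment = -10, latency_sd_intercept = 5,
                            latency_sd_slope = 0.4, latency_sd_resid = 5,
                            slips_intercept = 3.2, slips_size_slope = -0.12,
                            slips_treatment = -0.5, slips_sd_intercept = 0.3,
                            slips_sd_slope = 0.02),
                          seed = 1) {
  cfg <- as.list(environment())
  if (cfg$n_per_arm < 1) stopf("n_per_arm must be >= 1")
  if (any(diff(cfg$schedule) <= 0)) stopf("schedule must be increasing")
  if (cfg$treatment_time_ratio <= 0) stopf("treatment_time_ratio must be > 0")
  rates <- c(cfg$onset_sd, cfg$weight_noise_sd, cfg$symptom_prob_ramp,
             cfg$hang_noise_sd, cfg$injection_death_rate)
  if (any(rates < 0)) stopf("rates and SDs must be >= 0")
  structure(cfg, class = "cohort_config")
}

# latent (noise-free) weight at ages t for one animal
latent_weight <- function(t, W, growth, midpoint, peak_age, decline) {
  w_at <- function(a) W / (1 + exp(-growth * (a - midpoint)))
  w <- w_at(t)
  post <- t > peak_age
  w[post] <- w_at(peak_age) * pmax(0.05, 1 - decline * (t[post] - peak_age))
  w
}

#' Simulate a two-arm longitudinal cohort
#'
#' Draws per-animal latent parameters (onset age, Weibull disease death
#' age with the treated scale multiplied by `treatment_time_ratio`,
#' optional injection-related death age), then fills the observation
#' schedule with weights, symptom flags, wire-hang trials and a righting
#' latency, truncating each timeline at the first death.
#'
#' @param config a [cohort_config()].
#' @return `sim_cohort` list: `mice` (per-animal latent truth:
#'   `mouse_id`, `arm`, `latent_onset_age`, `latent_death_age`,
#'   `nondisease_death_age`, `death_age`, `true_cause`), `timelines`
#'   (long observation table), `survival` (`mouse_id`, `arm`, `age_days`,
#'   `event`, `cause`), and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n <- 2L * cfg$n_per_arm
  arm <- factor(rep(c("vehicle", "treated"), each = cfg$n_per_arm),
                levels = c("vehicle", "treated"))
  treated <- arm == "treated"
  id <- sprintf("m%03d", seq_len(n))

  onset <- rnorm(n, cfg$onset_mean + cfg$onset_shift_treated * treated,
                 cfg$onset_sd)
  scale <- cfg$weibull_scale_control *
    ifelse(treated, cfg$treatment_time_ratio, 1)
  death_dis <- rweibull(n, shape = cfg$weibull_shape, scale = scale)
  death_dis <- pmax(death_dis, cfg$schedule[1] + 1)
  death_inj <- if (cfg$injection_death_rate > 0)
    cfg$injection_min_age + rexp(n, cfg$injection_death_rate)
  else rep(Inf, n)
  death <- pmin(death_dis, death_inj)
  cause <- ifelse(death_inj < death_dis, "injection", "disease")

  W <- rnorm(n, cfg$weight_asymptote_g, cfg$weight_asymptote_sd_g)
  peak_age <- rnorm(n, cfg$weight_peak_age_mean, cfg$weight_peak_age_sd)
  hang_age <- rnorm(n, cfg$hang_decline_age_mean, cfg$hang_decline_age_sd)

  tls <- vector("list", n)
  for (i in seq_len(n)) {
    ages <- cfg$schedule[cfg$schedule < death[i]]
    if (length(ages) == 0) ages <- cfg$schedule[1]
    m <- length(ages)
    w <- latent_weight(ages, W[i], cfg$weight_growth_rate,
                       cfg$weight_midpoint_age, peak_age[i],
                       cfg$weight_decline_rate) +
      rnorm(m, 0, cfg$weight_noise_sd)
    w <- pmax(w, 1)
    p <- pmin(1, cfg$symptom_baseline +
                cfg$symptom_prob_ramp * pmax(0, ages - onset[i]))
    tremor <- rbinom(m, 1, p) == 1
    extension <- rbinom(m, 1, p) == 1
    hang_latent <- ifelse(ages < hang_age[i], 60,
                          pmax(0, 60 - cfg$hang_decline_rate *
                                 (ages - hang_age[i])))
    hg <- matrix(pmin(60, pmax(0, hang_latent +
                                 rnorm(3 * m, 0, cfg$hang_noise_sd))),
                 nrow = m, ncol = 3)
    righting <- ifelse(ages >= death_dis[i] - 2, 20, 2)
    tls[[i]] <- data.frame(
      mouse_id = id[i], arm = as.character(arm[i]), age_days = ages,
      weight_g = round(w, 2), tremor = tremor, extension_loss = extension,
      hang1 = round(hg[, 1], 1), hang2 = round(hg[, 2], 1),
      hang3 = round(hg[, 3], 1), righting_s = righting)
  }
  timelines <- do.call(rbind, tls)
  rownames(timelines) <- NULL

  mice <- data.frame(mouse_id = id, arm = arm,
                     latent_onset_age = onset,
                     latent_death_age = death_dis,
                     nondisease_death_age = ifelse(is.finite(death_inj),
                                                   death_inj, NA_real_),
                     death_age = death, true_cause = cause)
  survival <- data.frame(mouse_id = id, arm = arm,
                         age_days = round(death, 1),
                         event = cause == "disease", cause = cause)
  structure(list(mice = mice, timelines = timelines, survival = survival,
                 config = cfg), class = "sim_cohort")
}

#' Simulate balance-beam trials for a cohort
#'
#' Three trials on each of the 24, 19 and 11 mm beams per animal at a
#' single session. Latency follows a linear mixed model (fixed:
#' intercept, beam-size slope, treatment; random: per-animal intercept
#' and size slope; Gaussian residual); foot slips are Poisson with a
#' log-mean of the same structure. Ground-truth effects live in
#' `config$beam_params`.
#'
#' @param config a [cohort_config()].
#' @param mice per-animal table from [simulate_cohort()] (only
#'   `mouse_id` and `arm` are used); defaults to a fresh balanced roster.
#' @return data.frame `mouse_id`, `arm`, `beam_mm`, `trial`,
#'   `latency_s`, `slips` (9 rows per animal).
#' @export
simulate_beam <- function(config, mice = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(mice)) {
    n <- 2L * config$n_per_arm
    mice <- data.frame(
      mouse_id = sprintf("m%03d", seq_len(n)),
      arm = factor(rep(c("vehicle", "treated"), each = config$n_per_arm),
                   levels = c("vehicle", "treated")))
  }
  bp <- config$beam_params
  beams <- c(24, 19, 11)
  withr::with_seed(config$seed + 1L, {
    n <- nrow(mice)
    treated <- as.character(mice$arm) == "treated"
    u0l <- rnorm(n, 0, bp$latency_sd_intercept)
    u1l <- rnorm(n, 0, bp$latency_sd_slope)
    u0s <- rnorm(n, 0, bp$slips_sd_intercept)
    u1s <- rnorm(n, 0, bp$slips_sd_slope)
    rows <- expand.grid(trial = 1:3, beam_mm = beams, i = seq_len(n))
    i <- rows$i; b <- rows$beam_mm
    mu_lat <- bp$latency_intercept + bp$latency_size_slope * b +
      bp$latency_treatment * treated[i] + u0l[i] + u1l[i] * b
    lat <- pmax(0.5, mu_lat + rnorm(nrow(rows), 0, bp$latency_sd_resid))
    log_mu <- bp$slips_intercept + bp$slips_size_slope * b +
      bp$slips_treatment * treated[i] + u0s[i] + u1s[i] * b
    slips <- rpois(nrow(rows), exp(log_mu))
    data.frame(mouse_id = mice$mouse_id[i], arm = as.character(mice$arm)[i],
               beam_mm = b, trial = rows$trial,
               latency_s = round(lat, 1), slips = slips)
  })
}

#' Write cohort tables to CSV
#'
#' Emits `timelines.csv`, `survival.csv`, `beam.csv` and a `truth.json`
#' with the generating parameters.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param beam optional beam table from [simulate_beam()].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir, beam = NULL) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(timelines = file.path(dir, "timelines.csv"),
             survival = file.path(dir, "survival.csv"),
             truth = file.path(dir, "truth.json"))
  write.csv(cohort$timelines, paths["timelines"], row.names = FALSE)
  write.csv(cohort$survival, paths["survival"], row.names = FALSE)
  cfg <- cohort$config
  cfg$schedule <- as.numeric(cfg$schedule)
  jsonlite::write_json(unclass(cfg), paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(beam)) {
    paths <- c(paths, beam = file.path(dir, "beam.csv"))
    write.csv(beam, paths["beam"], row.names = FALSE)
  }
  invisible(paths)
}
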