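# Balance-beam mixed models: latency (linear) and foot slips (Poisson),
# with per-animal random intercept and beam-size slope, and a likelihood
# ratio test for the treatment effect. Estimation delegates to lme4; the
# model structure and the LRT are the contract here.

beam_check <- function(trials) {
  need <- c("mouse_id", "arm", "beam_mm", "trial", "latency_s", "slips")
  if (!all(need %in% names(trials)))
    stopf("trials must have columns: %s", paste(need, collapse = ", "))
  trials$arm <- if (is.factor(trials$arm)) droplevels(trials$arm) else
    factor(trials$arm, levels = unique(trials$arm))
  if (nlevels(trials$arm) != 2) stopf("two arms required")
  if (length(unique(trials$beam_mm)) < 2) stopf("need >= 2 beam sizes")
  trials
}

beam_result <- function(fit_full, fit_null) {
  fe <- lme4::fixef(fit_full)
  se <- sqrt(diag(as.matrix(stats::vcov(fit_full))))
  vc <- lme4::VarCorr(fit_full)$mouse_id
  ll1 <- as.numeric(logLik(fit_full)); ll0 <- as.numeric(logLik(fit_null))
  lrt <- max(0, 2 * (ll1 - ll0))
  structure(list(
    fixed_effects = fe, fixed_se = se,
    var_intercept = unname(vc[1, 1]), var_slope = unname(vc[2, 2]),
    singular = lme4::isSingular(fit_full),
    loglik = ll1, lrt_stat = lrt,
    p_value = pchisq(lrt, df = 1, lower.tail = FALSE),
    fit = fit_full
  ), class = "mixed_model_result")
}

#' Linear mixed model for beam-traversal latency
#'
#' `latency_s ~ beam_mm + arm + (1 + beam_mm | mouse_id)`, maximum
#' likelihood (not REML, so the treatment LRT against the model without
#' `arm` is valid). A singular random-effect fit is flagged, not an error.
#'
#' @param trials beam trial table (`mouse_id`, `arm`, `beam_mm`, `trial`,
#'   `latency_s`, `slips`).
#' @return `mixed_model_result`: fixed effects and SEs, random-effect
#'   variances, `singular` flag, treatment LRT statistic and p-value.
#' @export
fit_beam_latency <- function(trials) {
  trials <- beam_check(trials)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
  f1 <- suppressWarnings(suppressMessages(
    lme4::lmer(latency_s ~ beam_mm + arm + (1 + beam_mm | mouse_id),
               data = trials, REML = FALSE, control = ctrl)))
  f0 <- suppressWarnings(suppressMessages(
    lme4::lmer(latency_s ~ beam_mm + (1 + beam_mm | mouse_id),
               data = trials, REML = FALSE, control = ctrl)))
  beam_result(f1, f0)
}

#' Poisson mixed model for beam foot slips
#'
#' `slips ~ beam_mm + arm + (1 + beam_mm | mouse_id)`, log link, Poisson
#' error, with the treatment LRT as in [fit_beam_latency()]. A fit on
#' all-zero counts is returned with `degenerate = TRUE`.
#'
#' @inheritParams fit_beam_latency
#' @return `mixed_model_result` (with `degenerate` flag).
#' @export
fit_beam_slips <- function(trials) {
  trials <- beam_check(trials)
  if (any(trials$slips < 0) || any(trials$slips != round(trials$slips)))
    stopf("slips must be non-negative integers")
  if (all(trials$slips == 0)) {
    out <- structure(list(
      fixed_effects = NULL, fixed_se = NULL, var_intercept = NA_real_,
      var_slope = NA_real_, singular = TRUE, loglik = NA_real_,
      lrt_stat = 0, p_value = 1, degenerate = TRUE
    ), class = "mixed_model_result")
    return(out)
  }
  ctrl <- lme4::glmerControl(optimizer = "bobyqa",
                             check.conv.singular = "ignore")
  f1 <- suppressWarnings(suppressMessages(
    lme4::glmer(slips ~ beam_mm + arm + (1 + beam_mm | mouse_id),
                data = trials, family = stats::poisson, control = ctrl)))
  f0 <- suppressWarnings(suppressMessages(
    lme4::glmer(slips ~ beam_mm + (1 + beam_mm | mouse_id),
                data = trials, family = stats::poisson, control = ctrl)))
  out <- beam_result(f1, f0)
  out$degenerate <- FALSE
  out
}
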