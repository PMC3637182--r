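# Censored two-sample machinery: risk table, log-rank and Gehan-Wilcoxon
# Z statistics, the combined max-statistic permutation test, Kaplan-Meier
# summaries and the Weibull likelihood-ratio comparison.

#' Assemble a two-group right-censored survival sample
#'
#' @param times positive event/censoring ages (days).
#' @param events logical (or 0/1); `TRUE` = event observed, `FALSE` =
#'   right-censored.
#' @param groups two-level factor or character; the first level is the
#'   reference arm used for the "group 1" quantities of the risk table.
#' @return A `surv_sample` object (list with `time`, `event`, `group`).
#' @export
surv_sample <- function(times, events, groups) {
  if (length(times) != length(events) || length(times) != length(groups))
    stopf("times, events, groups must have equal length")
  if (any(!is.finite(times)) || any(times <= 0))
    stopf("times must be finite and > 0")
  events <- as.logical(events)
  if (any(is.na(events))) stopf("events must be logical with no NA")
  # a supplied factor keeps its level set (a group may be empty for
  # one-sample risk-table use; the two-sample tests enforce non-emptiness)
  group <- if (is.factor(groups)) groups else
    factor(groups, levels = unique(groups))
  if (nlevels(group) != 2)
    stopf("exactly two group levels required, got %d", nlevels(group))
  structure(list(time = as.numeric(times), event = events, group = group),
            class = "surv_sample")
}

# Pooled risk-set structure shared by all permutations of a sample:
# data sorted by time; one slot per distinct *event* time with the
# group-independent quantities (n_j, d_j) and index bookkeeping so that
# group-1 quantities (n1j, d1j) can be recomputed cheaply per relabelling.
surv_prep <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  n <- length(time)
  et <- unique(time[event])                      # distinct event times (sorted)
  J <- length(et)
  if (J == 0) {
    return(list(ord = ord, n = n, J = 0L))
  }
  first_idx <- match(et, time)                   # first subject with time >= t_j
  n_j <- n - first_idx + 1L                      # at risk (censored at t stay in)
  ev_idx <- which(event)
  g_e <- match(time[ev_idx], et)                 # event-time slot of each event
  d_j <- tabulate(g_e, nbins = J)
  list(ord = ord, n = n, J = J, t = et, first_idx = first_idx,
       n_j = n_j, d_j = d_j, ev_idx = ev_idx, g_e = g_e)
}

# Numerators/variances for both weightings, given group-1 membership
# `z` in time-sorted order. Returns c(U_lr, V_lr, U_w, V_w).
# `w` is the per-event-time weight of the Wilcoxon-type statistic.
surv_uv <- function(prep, z, w) {
  sz <- rev(cumsum(rev(z)))                      # suffix sums
  n1 <- sz[prep$first_idx]
  d1 <- tabulate(prep$g_e[z[prep$ev_idx]], nbins = prep$J)
  n_j <- prep$n_j; d_j <- prep$d_j
  e1 <- d_j * n1 / n_j
  v <- ifelse(n_j > 1,
              n1 * (n_j - n1) * d_j * (n_j - d_j) / (n_j^2 * (n_j - 1)),
              0)
  resid <- d1 - e1
  c(U_lr = sum(resid), V_lr = sum(v),
    U_w = sum(w * resid), V_w = sum(w^2 * v))
}

# Per-event-time weights for the Wilcoxon-type statistic.
# gehan: w_j = n_j (Gehan-Breslow). peto: left-continuous pooled
# Peto-Peto/Prentice survival estimate w_j = prod_{l<=j} (1 - d_l/(n_l + 1)).
wilcoxon_weights <- function(prep, variant = c("gehan", "peto")) {
  variant <- match.arg(variant)
  if (prep$J == 0) return(numeric(0))
  if (variant == "gehan") prep$n_j
  else cumprod(1 - prep$d_j / (prep$n_j + 1))
}

#' Build the two-sample risk table
#'
#' One row per distinct event time; censored times contribute to the
#' at-risk counts only (a subject censored at t is still at risk at t).
#'
#' @param sample a [surv_sample()].
#' @return data.frame with columns `t` (event time), `n` (at risk), `n1`
#'   (group-1 at risk), `d` (events), `d1` (group-1 events), `e1`
#'   (expected group-1 events `d * n1 / n`), `v` (hypergeometric variance,
#'   0 when `n = 1`). Empty (0-row) when no events occurred.
#' @export
build_risk_table <- function(sample) {
  stopifnot(inherits(sample, "surv_sample"))
  prep <- surv_prep(sample$time, sample$event)
  empty <- data.frame(t = numeric(0), n = integer(0), n1 = integer(0),
                      d = integer(0), d1 = integer(0), e1 = numeric(0),
                      v = numeric(0))
  if (prep$J == 0) return(empty)
  z <- (sample$group == levels(sample$group)[1])[prep$ord]
  sz <- rev(cumsum(rev(z)))
  n1 <- sz[prep$first_idx]
  d1 <- tabulate(prep$g_e[z[prep$ev_idx]], nbins = prep$J)
  e1 <- prep$d_j * n1 / prep$n_j
  v <- ifelse(prep$n_j > 1,
              n1 * (prep$n_j - n1) * prep$d_j * (prep$n_j - prep$d_j) /
                (prep$n_j^2 * (prep$n_j - 1)),
              0)
  data.frame(t = prep$t, n = prep$n_j, n1 = n1, d = prep$d_j, d1 = d1,
             e1 = e1, v = v)
}

#' Log-rank Z statistic from a risk table
#'
#' Weights every event time equally: `Z = sum(d1 - e1) / sqrt(sum(v))`.
#' Positive Z means more group-1 events than expected (earlier failures in
#' group 1).
#'
#' @param table risk table from [build_risk_table()].
#' @return numeric Z.
#' @export
logrank_z <- function(table) {
  if (nrow(table) == 0) stopf("risk table is empty (no events)")
  V <- sum(table$v)
  if (V <= 0) stopf("zero total variance; log-rank Z undefined")
  sum(table$d1 - table$e1) / sqrt(V)
}

#' Gehan-Breslow Wilcoxon Z statistic from a risk table
#'
#' The censored-data Wilcoxon generalization with weights `w_j = n_j`,
#' emphasizing early event times:
#' `Z = sum(n * (d1 - e1)) / sqrt(sum(n^2 * v))`.
#'
#' @inheritParams logrank_z
#' @param weights optional per-row weights overriding the Gehan `n_j`
#'   (e.g. the Peto-Prentice pooled-survival weights).
#' @return numeric Z.
#' @export
gehan_wilcoxon_z <- function(table, weights = NULL) {
  if (nrow(table) == 0) stopf("risk table is empty (no events)")
  w <- if (is.null(weights)) table$n else weights
  if (length(w) != nrow(table)) stopf("weights length must match table rows")
  V <- sum(w^2 * table$v)
  if (V <= 0) stopf("zero weighted variance; Wilcoxon Z undefined")
  sum(w * (table$d1 - table$e1)) / sqrt(V)
}

#' Combined max(log-rank, Wilcoxon) permutation test
#'
#' Computes both standardized statistics, takes
#' `M = max(|Z_logrank|, |Z_wilcoxon|)`, and assesses significance by
#' permuting group labels with fixed group sizes. When the number of
#' distinct label arrangements is at most `exhaustive_limit` the full
#' enumeration is used (p = proportion of arrangements with `M >= M_obs`,
#' which includes the observed one); otherwise `B` Monte-Carlo draws with
#' the add-one estimator `p = (1 + #{M_b >= M_obs}) / (B + 1)`.
#' Arrangements with zero variance in a statistic contribute `M_b = 0`
#' and are counted, with a warning.
#'
#' @param sample a [surv_sample()].
#' @param B number of Monte-Carlo permutations (ignored when exhaustive).
#' @param seed integer seed for the Monte-Carlo draw.
#' @param wilcoxon weighting variant, `"gehan"` (default) or `"peto"`.
#' @param exhaustive_limit enumerate exhaustively when
#'   `choose(n, n1) <= exhaustive_limit`.
#' @return `two_sample_test` object: `z_logrank`, `z_wilcoxon`,
#'   `m_observed`, `p_permutation`, `exhaustive`, `n_permutations`,
#'   `p_logrank_asymp`, `p_wilcoxon_asymp`, `seed`.
#' @export
combined_permutation_test <- function(sample, B = 2000, seed = 1,
                                      wilcoxon = c("gehan", "peto"),
                                      exhaustive_limit = 20000) {
  stopifnot(inherits(sample, "surv_sample"))
  wilcoxon <- match.arg(wilcoxon)
  if (B < 1) stopf("B must be >= 1")
  n1 <- sum(sample$group == levels(sample$group)[1])
  n <- length(sample$time)
  if (n1 == 0 || n1 == n) stopf("both groups must be non-empty")
  prep <- surv_prep(sample$time, sample$event)
  if (prep$J == 0) stopf("no events; test undefined")
  w <- wilcoxon_weights(prep, wilcoxon)
  z_obs <- (sample$group == levels(sample$group)[1])[prep$ord]

  m_of <- function(uv) {
    z1 <- if (uv["V_lr"] > 0) uv["U_lr"] / sqrt(uv["V_lr"]) else NA_real_
    z2 <- if (uv["V_w"] > 0) uv["U_w"] / sqrt(uv["V_w"]) else NA_real_
    c(z1, z2)
  }
  uv0 <- surv_uv(prep, z_obs, w)
  zz <- unname(m_of(uv0))
  if (any(is.na(zz)))
    stopf("zero variance in the observed sample; test undefined")
  m_obs <- max(abs(zz))
  eps <- 1e-12
  n_degenerate <- 0L

  perm_m <- function(z) {
    uv <- surv_uv(prep, z, w)
    m <- m_of(uv)
    if (any(is.na(m))) {
      n_degenerate <<- n_degenerate + 1L
      return(0)
    }
    max(abs(m))
  }

  n_arr <- choose(n, n1)
  exhaustive <- is.finite(n_arr) && n_arr <= exhaustive_limit
  if (exhaustive) {
    combos <- utils::combn(n, n1)
    ms <- apply(combos, 2, function(ii) {
      z <- logical(n); z[ii] <- TRUE
      perm_m(z)
    })
    p <- sum(ms >= m_obs - eps) / ncol(combos)
    n_perm <- ncol(combos)
  } else {
    ms <- withr::with_seed(seed, {
      vapply(seq_len(B), function(b) perm_m(sample(z_obs)), numeric(1))
    })
    p <- (1 + sum(ms >= m_obs - eps)) / (B + 1)
    n_perm <- B
  }
  if (n_degenerate > 0)
    warnf("%d degenerate permutations (zero variance) scored as M = 0",
          n_degenerate)
  structure(list(
    z_logrank = zz[1], z_wilcoxon = zz[2], m_observed = m_obs,
    p_permutation = p, exhaustive = exhaustive, n_permutations = n_perm,
    p_logrank_asymp = 2 * stats::pnorm(-abs(zz[1])),
    p_wilcoxon_asymp = 2 * stats::pnorm(-abs(zz[2])),
    wilcoxon_variant = wilcoxon, seed = seed
  ), class = "two_sample_test")
}

#' @export
print.two_sample_test <- function(x, ...) {
  cat("Combined max(log-rank, Wilcoxon) permutation test\n")
  cat(sprintf("  Z log-rank : %8.4f  (asymptotic p = %.4g)\n",
              x$z_logrank, x$p_logrank_asymp))
  cat(sprintf("  Z Wilcoxon : %8.4f  (asymptotic p = %.4g, %s weights)\n",
              x$z_wilcoxon, x$p_wilcoxon_asymp, x$wilcoxon_variant))
  cat(sprintf("  M observed : %8.4f\n", x$m_observed))
  cat(sprintf("  permutation p = %.4g (%s, %d arrangements)\n",
              x$p_permutation,
              if (x$exhaustive) "exhaustive" else "Monte-Carlo",
              x$n_permutations))
  invisible(x)
}

#' Kaplan-Meier product-limit estimate for one group
#'
#' @param times event/censoring ages.
#' @param events logical event indicators.
#' @return `km_estimate` list: `time` (distinct event times), `surv`
#'   (S(t) just after each event time), `median` (first event time with
#'   `S <= 0.5`, `NA` if never reached), `restricted_mean` (integral of
#'   the step function up to the largest observed time), `n`, `tmax`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) < 1) stopf("at least one subject required")
  events <- as.logical(events)
  ord <- order(times)
  time <- times[ord]; event <- events[ord]
  n <- length(time)
  et <- unique(time[event])
  tmax <- max(time)
  if (length(et) == 0) {
    return(structure(list(time = numeric(0), surv = numeric(0),
                          median = NA_real_, restricted_mean = tmax,
                          n = n, tmax = tmax), class = "km_estimate"))
  }
  first_idx <- match(et, time)
  n_j <- n - first_idx + 1L
  d_j <- tabulate(match(time[event], et), nbins = length(et))
  surv <- cumprod(1 - d_j / n_j)
  med <- if (any(surv <= 0.5 + 1e-12)) et[which(surv <= 0.5 + 1e-12)[1]]
         else NA_real_
  # step integral of S over [0, tmax]; S left-continuous with S(0) = 1
  knots <- c(0, et, tmax)
  sval <- c(1, surv)
  widths <- diff(knots)
  rmean <- sum(sval[seq_along(widths)] * widths)
  structure(list(time = et, surv = surv, median = med,
                 restricted_mean = rmean, n = n, tmax = tmax),
            class = "km_estimate")
}

#' Weibull likelihood-ratio comparison of two survival curves
#'
#' Fits censored Weibull AFT models with a common shape and a
#' group-specific log-scale (full) versus a single scale (reduced), and
#' tests the treatment coefficient by likelihood ratio against chi-square
#' with 1 df. Maximum likelihood fitting is delegated to
#' [survival::survreg()]; the comparison and reporting are constructed
#' here.
#'
#' @param sample a [surv_sample()].
#' @return `weibull_fit` list: `shape`, `log_scale_intercept`,
#'   `treatment_coef`, `scale_by_group`, `median_by_group`
#'   (`scale * log(2)^(1/shape)`), `loglik_full`, `loglik_reduced`,
#'   `lrt_stat`, `p_value`.
#' @export
weibull_lrt <- function(sample) {
  stopifnot(inherits(sample, "surv_sample"))
  d <- data.frame(time = sample$time, event = as.integer(sample$event),
                  group = sample$group)
  if (any(tapply(d$event, d$group, sum) < 1))
    stopf("each group needs at least one event for the Weibull fit")
  fit1 <- tryCatch(
    survival::survreg(survival::Surv(time, event) ~ group, data = d,
                      dist = "weibull"),
    error = function(e) stopf("weibull fit failed: %s", conditionMessage(e)))
  fit0 <- survival::survreg(survival::Surv(time, event) ~ 1, data = d,
                            dist = "weibull")
  k <- 1 / fit1$scale
  mu <- unname(coef(fit1)[1])
  beta <- unname(coef(fit1)[2])
  scales <- c(exp(mu), exp(mu + beta))
  names(scales) <- levels(d$group)
  ll1 <- as.numeric(logLik(fit1)); ll0 <- as.numeric(logLik(fit0))
  lrt <- max(0, 2 * (ll1 - ll0))
  structure(list(
    shape = k, log_scale_intercept = mu, treatment_coef = beta,
    scale_by_group = scales,
    median_by_group = scales * log(2)^(1 / k),
    loglik_full = ll1, loglik_reduced = ll0,
    lrt_stat = lrt, p_value = pchisq(lrt, df = 1, lower.tail = FALSE)
  ), class = "weibull_fit")
}

#' Summarize time-to-event endpoints for two arms
#'
#' Produces one row per endpoint with per-arm Kaplan-Meier medians and
#' restricted means, the asymptotic log-rank and Wilcoxon p-values, the
#' combined permutation p, and a Holm-adjusted column for the combined p
#' (reported alongside, the unadjusted values are the primary output).
#'
#' @param events data.frame with columns `mouse_id`, `arm`, `endpoint`,
#'   `age_days`, `observed`.
#' @param B,seed,wilcoxon passed to [combined_permutation_test()].
#' @return data.frame, one row per endpoint.
#' @export
summarize_endpoints <- function(events, B = 2000, seed = 1,
                                wilcoxon = "gehan") {
  need <- c("mouse_id", "arm", "endpoint", "age_days", "observed")
  if (!all(need %in% names(events)))
    stopf("events must have columns: %s", paste(need, collapse = ", "))
  arms <- if (is.factor(events$arm)) levels(droplevels(events$arm)) else
    unique(events$arm)
  rows <- lapply(split(events, events$endpoint), function(e) {
    s <- surv_sample(e$age_days, e$observed, factor(e$arm, levels = arms))
    km <- lapply(arms, function(a) {
      km_estimate(e$age_days[e$arm == a], e$observed[e$arm == a])
    })
    tst <- combined_permutation_test(s, B = B, seed = seed,
                                     wilcoxon = wilcoxon)
    data.frame(endpoint = e$endpoint[1],
               median_1 = km[[1]]$median, median_2 = km[[2]]$median,
               rmean_1 = km[[1]]$restricted_mean,
               rmean_2 = km[[2]]$restricted_mean,
               p_logrank = tst$p_logrank_asymp,
               p_wilcoxon = tst$p_wilcoxon_asymp,
               p_combined = tst$p_permutation)
  })
  out <- do.call(rbind, rows)
  names(out)[2:5] <- c(paste0("median_", arms), paste0("rmean_", arms))
  out$p_combined_holm <- stats::p.adjust(out$p_combined, method = "holm")
  rownames(out) <- NULL
  out
}

#' qPCR relative expression by the delta-delta-Ct method
#'
#' Per-sample `dCt = Ct_target - Ct_reference`; `ddCt` = mean dCt of the
#' condition group minus mean dCt of the control group; fold change
#' `2^(-ddCt)`. A two-sided Welch t test on the per-sample dCt values is
#' reported.
#'
#' @param ct data.frame with columns `sample_id`, `group`, `ct_target`,
#'   `ct_reference` (duplicate wells averaged upstream).
#' @param control the group label treated as baseline.
#' @return `qpcr_result` list: `dct` (per-sample table), `mean_neg_dct`
#'   (per-group mean of -dCt), `ddct`, `fold_change`, `p_value`.
#' @export
qpcr_fold_change <- function(ct, control) {
  need <- c("sample_id", "group", "ct_target", "ct_reference")
  if (!all(need %in% names(ct)))
    stopf("ct must have columns: %s", paste(need, collapse = ", "))
  drop <- !is.finite(ct$ct_reference)
  if (any(drop)) {
    warnf("%d sample(s) excluded: missing reference Ct", sum(drop))
    ct <- ct[!drop, , drop = FALSE]
  }
  if (!control %in% ct$group) stopf("control group '%s' not present", control)
  grps <- unique(ct$group)
  if (length(grps) != 2) stopf("exactly two groups required")
  cond <- setdiff(grps, control)
  ct$dct <- ct$ct_target - ct$ct_reference
  m <- tapply(ct$dct, ct$group, mean)
  ddct <- unname(m[cond] - m[control])
  # Welch t test is undefined for essentially constant dCt values
  pval <- tryCatch(
    t.test(ct$dct[ct$group == cond], ct$dct[ct$group == control])$p.value,
    error = function(e) NA_real_)
  structure(list(dct = ct[, c("sample_id", "group", "dct")],
                 mean_neg_dct = -m, ddct = ddct,
                 fold_change = 2^(-ddct), p_value = pval),
            class = "qpcr_result")
}
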