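# Rule-based derivation of longitudinal disease endpoints: early symptom
# onset (two consecutive positive observations), sustained weight-loss
# onset, last full wire hang, humane euthanasia criteria, the censoring
# classification of death modes, NMJ innervation aggregation, and the
# dosing/formulation arithmetic.

#' Build a per-mouse timeline from observation records
#'
#' @param records data.frame for one animal with columns `age_days`,
#'   `weight_g`, `tremor`, `extension_loss`, and optionally
#'   `hang1`, `hang2`, `hang3` (seconds, capped at 60; `NA` = trial not
#'   run) and `righting_s`.
#' @param mouse_id identifier (defaults to a `mouse_id` column if present).
#' @return `mouse_timeline`: records sorted by age (ages must be strictly
#'   increasing) with `peak_weight_g`, the running maximum of weight.
#' @export
mouse_timeline <- function(records, mouse_id = NULL) {
  need <- c("age_days", "weight_g", "tremor", "extension_loss")
  if (!all(need %in% names(records)))
    stopf("records must have columns: %s", paste(need, collapse = ", "))
  if (is.null(mouse_id))
    mouse_id <- if ("mouse_id" %in% names(records)) records$mouse_id[1] else NA
  records <- records[order(records$age_days), , drop = FALSE]
  if (any(diff(records$age_days) <= 0))
    stopf("ages must be strictly increasing within a timeline")
  if (any(records$weight_g <= 0)) stopf("weights must be > 0")
  hang_cols <- intersect(c("hang1", "hang2", "hang3"), names(records))
  if (length(hang_cols) > 0) {
    h <- as.matrix(records[, hang_cols, drop = FALSE])
    if (any(h < 0 | h > 60, na.rm = TRUE))
      stopf("hang latencies must lie in [0, 60] seconds")
  }
  records$peak_weight_g <- cummax(records$weight_g)
  structure(list(mouse_id = mouse_id, records = records),
            class = "mouse_timeline")
}

event_result <- function(endpoint, age, observed, flag = NULL) {
  out <- list(endpoint = endpoint, age_days = age, observed = observed)
  if (!is.null(flag)) out$flag <- flag
  out
}

#' Best-of-three wire-hang score for one session
#'
#' The recorded session score is the maximum of up to three trial
#' latencies (each capped at 60 s).
#'
#' @param latencies numeric vector of 1-3 trial latencies in `[0, 60]`;
#'   `NA` trials are dropped.
#' @return the session score, or `NA` (missing session) when no trial
#'   was run.
#' @export
best_of_three_hang <- function(latencies) {
  latencies <- latencies[!is.na(latencies)]
  if (length(latencies) == 0) return(NA_real_)
  if (length(latencies) > 3) stopf("at most 3 trials per session")
  if (any(latencies < 0 | latencies > 60))
    stopf("latencies must lie in [0, 60]")
  max(latencies)
}

#' Early symptom onset: two consecutive positive observations
#'
#' A session is positive when hindlimb tremor OR loss of the hindlimb
#' extension reflex is recorded. Onset is the earliest pair of
#' consecutive positive sessions; with `date = "first"` (default) the
#' event is dated to the first session of that pair (the appearance,
#' confirmed by the second), with `date = "second"` to the confirming
#' session. With no such pair the animal is right-censored at its last
#' observation age.
#'
#' @param timeline a [mouse_timeline()].
#' @param date which session of the pair carries the event date.
#' @return list `endpoint`, `age_days`, `observed`.
#' @export
early_symptom_onset <- function(timeline, date = c("first", "second")) {
  stopifnot(inherits(timeline, "mouse_timeline"))
  date <- match.arg(date)
  r <- timeline$records
  last_age <- r$age_days[nrow(r)]
  if (nrow(r) < 2)
    return(event_result("early_symptom_onset", last_age, FALSE))
  pos <- r$tremor | r$extension_loss
  pair <- which(pos[-length(pos)] & pos[-1])
  if (length(pair) == 0)
    return(event_result("early_symptom_onset", last_age, FALSE))
  i <- pair[1]
  age <- if (date == "first") r$age_days[i] else r$age_days[i + 1]
  event_result("early_symptom_onset", age, TRUE)
}

#' Weight-loss onset: first sustained drop below the running peak
#'
#' The event is the first observation whose weight is at or below
#' `(1 - drop_fraction)` of the running peak weight and after which the
#' running peak is never re-attained (a dip followed by a new peak is
#' ignored and the search continues after the later peak). Otherwise the
#' animal is right-censored at its last observation age.
#'
#' @param timeline a [mouse_timeline()].
#' @param drop_fraction proportional drop defining onset (default 0.05).
#' @return list `endpoint`, `age_days`, `observed`.
#' @export
weight_loss_onset <- function(timeline, drop_fraction = 0.05) {
  stopifnot(inherits(timeline, "mouse_timeline"))
  if (drop_fraction <= 0 || drop_fraction >= 1)
    stopf("drop_fraction must lie in (0, 1)")
  r <- timeline$records
  last_age <- r$age_days[nrow(r)]
  if (nrow(r) < 2)
    return(event_result("weight_loss_onset", last_age, FALSE))
  w <- r$weight_g
  peak <- r$peak_weight_g
  n <- length(w)
  for (i in seq_len(n)) {
    if (w[i] <= (1 - drop_fraction) * peak[i]) {
      later <- if (i < n) w[(i + 1):n] else numeric(0)
      if (all(later < peak[i]))   # peak never re-attained: sustained
        return(event_result("weight_loss_onset", r$age_days[i], TRUE))
    }
  }
  event_result("weight_loss_onset", last_age, FALSE)
}

#' Age at the last full (60 s) wire hang
#'
#' Sessions are scored best-of-three. The event is the greatest age whose
#' session score is 60 s; an animal still scoring 60 at its final hang
#' session is right-censored at that age. An animal that never reached
#' 60 s is returned as a degenerate event at its first hang session age,
#' with `flag = "never_full_hang"`.
#'
#' @param timeline a [mouse_timeline()] whose records carry `hang1..3`.
#' @return list `endpoint`, `age_days`, `observed` (and possibly `flag`).
#' @export
last_full_hang_age <- function(timeline) {
  stopifnot(inherits(timeline, "mouse_timeline"))
  r <- timeline$records
  hang_cols <- intersect(c("hang1", "hang2", "hang3"), names(r))
  if (length(hang_cols) == 0) stopf("timeline has no hang data")
  h <- as.matrix(r[, hang_cols, drop = FALSE])
  best <- apply(h, 1, function(x) best_of_three_hang(x))
  keep <- !is.na(best)
  if (!any(keep)) stopf("timeline has no hang data")
  ages <- r$age_days[keep]; best <- best[keep]
  full <- best >= 60
  if (!any(full))
    return(event_result("last_full_hang", ages[1], TRUE,
                        flag = "never_full_hang"))
  if (full[length(full)])  # still able at the final session
    return(event_result("last_full_hang", ages[length(ages)], FALSE))
  event_result("last_full_hang", max(ages[full]), TRUE)
}

#' Humane-endpoint check for a single observation
#'
#' Euthanasia is due when the animal cannot right itself within 15
#' seconds (strictly more than 15 s) or its weight has dropped 20% or
#' more from the running peak (at or below `0.80 * peak`). An absent
#' righting measurement passes that criterion.
#'
#' @param weight_g observed weight.
#' @param peak_weight_g running peak weight for the animal.
#' @param righting_s righting latency in seconds, or `NA` if not measured.
#' @return list `due` (logical) and `reason` (`"righting_failure"`,
#'   `"weight_loss"`, `"both"`, or `"none"`).
#' @export
euthanasia_due <- function(weight_g, peak_weight_g, righting_s = NA) {
  righting <- !is.na(righting_s) && righting_s > 15
  weight <- weight_g <= 0.80 * peak_weight_g
  reason <- if (righting && weight) "both"
    else if (righting) "righting_failure"
    else if (weight) "weight_loss"
    else "none"
  list(due = righting || weight, reason = reason)
}

#' Death-mode censoring classification
#'
#' Maps each recorded death/euthanasia mode to the censoring status used
#' in the survival analysis: deaths at (or found close to) the humane
#' criteria are events; deaths unrelated to disease progression --
#' found dead not near criteria (probable bad injection), euthanasia for
#' injury, and weight loss with no other critical signs -- are censored.
#'
#' @param mode character vector of modes among `righting_failure`,
#'   `weight_loss`, `both`, `found_dead_near_criteria`,
#'   `found_dead_not_near_criteria`, `injury_euthanasia`,
#'   `weight_only_no_other_signs`.
#' @return logical vector, `TRUE` = censored.
#' @export
classify_death <- function(mode) {
  map <- c(righting_failure = FALSE,
           weight_loss = FALSE,
           both = FALSE,
           found_dead_near_criteria = FALSE,
           found_dead_not_near_criteria = TRUE,
           injury_euthanasia = TRUE,
           weight_only_no_other_signs = TRUE)
  bad <- setdiff(unique(mode), names(map))
  if (length(bad) > 0)
    stopf("unknown death mode(s): %s", paste(bad, collapse = ", "))
  unname(map[mode])
}

#' Per-animal NMJ innervation percentage
#'
#' Each synapse is scored innervated/denervated per side; the per-side
#' percentage is `100 * innervated / total`, and the animal value is the
#' mean of the two side percentages (not pooled counts). With one side
#' unscored the other side's value is used and an asymmetry flag raised.
#'
#' @param scores_left,scores_right logical vectors (TRUE = innervated).
#' @return list `percent`, `percent_left`, `percent_right`,
#'   `asymmetric` (TRUE when only one side contributed).
#' @export
innervation_percent <- function(scores_left, scores_right) {
  pl <- if (length(scores_left) > 0) 100 * mean(scores_left) else NA_real_
  pr <- if (length(scores_right) > 0) 100 * mean(scores_right) else NA_real_
  if (is.na(pl) && is.na(pr)) stopf("at least one side must be scored")
  asym <- is.na(pl) || is.na(pr)
  if (asym) warnf("only one side scored; using it alone")
  list(percent = mean(c(pl, pr), na.rm = TRUE),
       percent_left = pl, percent_right = pr, asymmetric = asym)
}

#' Bracketed dosing volume and realized dose
#'
#' The exact volume for a nominal dose is rounded to the nearest 20 ul
#' (ties round up), and the realized dose is recomputed from the
#' bracketed volume.
#'
#' @param weight_g body weight in grams.
#' @param nominal_mg_per_kg nominal dose (the study used 60 or 75).
#' @param conc_mg_per_ml formulation concentration (default 10).
#' @return list `weight_g`, `nominal_mg_per_kg`, `exact_volume_ul`,
#'   `bracket_volume_ul` (multiple of 20), `actual_dose_mg_per_kg`.
#' @export
dose_volume_bracketed <- function(weight_g, nominal_mg_per_kg,
                                  conc_mg_per_ml = 10) {
  if (weight_g <= 0) stopf("weight must be > 0")
  exact_ul <- weight_g * nominal_mg_per_kg / conc_mg_per_ml
  bracket <- floor(exact_ul / 20 + 0.5) * 20   # ties (x.5 brackets) go up
  actual <- bracket * conc_mg_per_ml / weight_g
  list(weight_g = weight_g, nominal_mg_per_kg = nominal_mg_per_kg,
       exact_volume_ul = exact_ul, bracket_volume_ul = bracket,
       actual_dose_mg_per_kg = actual)
}

#' Drug powder weight for a formulation volume
#'
#' `W (mg) = 10 (mg/ml) / 0.915 * V (ml)`: the 10 mg/ml free-base target
#' concentration with the 0.915 salt-correction factor.
#'
#' @param volume_ml formulation volume in ml.
#' @return powder weight in mg.
#' @export
formulation_powder_weight <- function(volume_ml) {
  if (any(volume_ml <= 0)) stopf("volume must be > 0")
  10 / 0.915 * volume_ml
}

#' Derive all time-to-event endpoints for a cohort of timelines
#'
#' Applies [early_symptom_onset()], [weight_loss_onset()] and
#' [last_full_hang_age()] to every animal in a long timelines table.
#'
#' @param timelines data.frame with columns `mouse_id`, `arm`,
#'   `age_days`, `weight_g`, `tremor`, `extension_loss`,
#'   `hang1`, `hang2`, `hang3` (and optionally `righting_s`).
#' @param drop_fraction passed to [weight_loss_onset()].
#' @param onset_date passed to [early_symptom_onset()].
#' @return data.frame `mouse_id`, `arm`, `endpoint`, `age_days`,
#'   `observed`, `flag`.
#' @export
derive_endpoints <- function(timelines, drop_fraction = 0.05,
                             onset_date = "first") {
  rows <- lapply(split(timelines, timelines$mouse_id), function(tl) {
    tm <- mouse_timeline(tl)
    res <- list(early_symptom_onset(tm, date = onset_date),
                weight_loss_onset(tm, drop_fraction = drop_fraction),
                last_full_hang_age(tm))
    do.call(rbind, lapply(res, function(e) {
      data.frame(mouse_id = tl$mouse_id[1], arm = tl$arm[1],
                 endpoint = e$endpoint, age_days = e$age_days,
                 observed = e$observed,
                 flag = if (is.null(e$flag)) "" else e$flag)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
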