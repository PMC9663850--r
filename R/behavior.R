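# Scoring and filtering of the four behavioral assays: novel object
# recognition (NOR), Y maze, accelerating rotarod and balance beam.
# Trial tables come from tracking software; this module applies the
# published exclusion rules and preference formulas.

#' Filter behavioral trials by the published exclusion rules
#'
#' NOR trials are excluded when the summed day-2 exploration
#' (`time3 + time4`) is below `nor_min_s` (10 s). Y-maze trials are
#' excluded when the time in the new or the familiar arm is below
#' `ymaze_min_s` (15 s), when the total number of arm visits is below
#' `min_visits` (7), or when the camera lost the subject for more than
#' `max_tracking_loss` (10%) of the trial. Values are never modified;
#' every exclusion is logged with the rule(s) that fired.
#'
#' @param trials Data frame of trials (see [simulate_behavior()] for the
#'   expected columns).
#' @param assay `"nor"` or `"ymaze"`.
#' @param nor_min_s,ymaze_min_s,min_visits,max_tracking_loss Rule
#'   thresholds.
#' @return List with `included` (trial rows), `excluded` (trial rows
#'   plus an `exclusion_reason` column).
#' @export
filter_trials <- function(trials, assay = c("nor", "ymaze"),
                          nor_min_s = 10, ymaze_min_s = 15,
                          min_visits = 7, max_tracking_loss = 0.10) {
  assay <- match.arg(assay)
  n <- nrow(trials)
  reasons <- vector("list", n)
  add <- function(reasons, hit, why) {
    for (i in which(hit)) reasons[[i]] <- c(reasons[[i]], why)
    reasons
  }
  if (assay == "nor") {
    reasons <- add(reasons, trials$time3 + trials$time4 < nor_min_s,
                   sprintf("day2_exploration_lt_%gs", nor_min_s))
  } else {
    reasons <- add(reasons, trials$time_new < ymaze_min_s,
                   sprintf("new_arm_lt_%gs", ymaze_min_s))
    reasons <- add(reasons, trials$time_familiar < ymaze_min_s,
                   sprintf("familiar_arm_lt_%gs", ymaze_min_s))
    reasons <- add(reasons, trials$visits_total < min_visits,
                   sprintf("visits_lt_%d", min_visits))
    reasons <- add(reasons, trials$tracking_loss_frac > max_tracking_loss,
                   sprintf("tracking_loss_gt_%g", max_tracking_loss))
  }
  out <- lengths(reasons) > 0
  excluded <- trials[out, , drop = FALSE]
  if (nrow(excluded))
    excluded$exclusion_reason <-
      vapply(reasons[out], paste, character(1), collapse = ";")
  else excluded$exclusion_reason <- character(0)
  list(included = trials[!out, , drop = FALSE], excluded = excluded)
}

#' Novel-object-recognition preference
#'
#' Day-2 novelty preference corrected for any unequal object preference
#' on day 1: `(time3/time4) / (time1/time2)`, where times 1 and 2 are
#' the two identical objects on day 1 and times 3 and 4 are the novel
#' and the familiar object on day 2. A value of 1 means the apparent
#' novelty preference is fully explained by the day-1 bias.
#'
#' @param t Data frame with columns `time1`, `time2`, `time3`, `time4`
#'   (seconds); `time1`, `time2` and `time4` must be positive.
#' @return Numeric preference score(s).
#' @export
nor_preference <- function(t) {
  if (any(t$time1 <= 0 | t$time2 <= 0 | t$time4 <= 0))
    stop("nor_preference: time1, time2 and time4 must be positive")
  (t$time3 / t$time4) / (t$time1 / t$time2)
}

#' Y-maze new-arm preference
#'
#' Time in the new arm divided by time in the familiar arm.
#'
#' @param t Data frame with columns `time_new`, `time_familiar`
#'   (seconds); `time_familiar` must be positive.
#' @return Numeric preference ratio(s).
#' @export
ymaze_preference <- function(t) {
  if (any(t$time_familiar <= 0))
    stop("ymaze_preference: time_familiar must be positive")
  t$time_new / t$time_familiar
}

#' Aggregate motor trials (rotarod run times, beam velocities)
#'
#' Per subject and day, the mean and SEM across trials (SEM reported as
#' 0 for a single trial); then per day, the group mean and SEM across
#' subject-day means. If per-subject baselines are supplied, values are
#' first divided by the subject's baseline mean (rotarod run times are
#' conventionally reported raw, so no baseline is applied by default).
#'
#' @param trials Data frame with `subject_id`, `day_index`, `value`.
#' @param baseline Optional named numeric vector of per-subject baseline
#'   means used with [normalize_to_baseline()] semantics.
#' @return List with `per_subject_day` and `per_day` data frames
#'   (`mean`, `sem`, `n`).
#' @export
aggregate_motor <- function(trials, baseline = NULL) {
  if (!nrow(trials)) stop("aggregate_motor: no trials")
  v <- trials$value
  if (!is.null(baseline)) {
    b <- baseline[trials$subject_id]
    if (anyNA(b) || any(b == 0))
      stop("aggregate_motor: missing or zero baseline for some subject")
    v <- v / b
  }
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  key <- interaction(trials$subject_id, trials$day_index, drop = TRUE)
  psd <- data.frame(
    subject_id = tapply(trials$subject_id, key, `[`, 1),
    day_index = as.integer(tapply(trials$day_index, key, `[`, 1)),
    mean = as.numeric(tapply(v, key, mean)),
    sem = as.numeric(tapply(v, key, sem)),
    n = as.integer(tapply(v, key, length)))
  rownames(psd) <- NULL
  pd <- do.call(rbind, lapply(split(psd, psd$day_index), function(d)
    data.frame(day_index = d$day_index[1], mean = mean(d$mean),
               sem = sem(d$mean), n = nrow(d))))
  rownames(pd) <- NULL
  list(per_subject_day = psd[order(psd$subject_id, psd$day_index), ],
       per_day = pd[order(pd$day_index), ])
}
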