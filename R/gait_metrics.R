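# Per-step and per-bout gait variables: cadence, step time, step width,
# their coefficients of variation, and the estimated lateral margin of
# stability (eMOS) from the extrapolated centre of mass.

STEP_VARIABLES <- c("cadence", "step_time", "step_width",
                    "cv_step_time", "cv_step_width", "emos")

#' Compute per-step records from an interleaved event list
#'
#' For each pair of consecutive strikes with alternating feet:
#' * step time = time between the two strikes;
#' * step width = absolute medio-lateral distance between the two ankles at
#'   the frame of the later strike, divided by the hip width at that frame
#'   for video sources (reference streams stay in metres).
#'
#' Steps flagged by [interleave_steps()] (same-foot gaps) are omitted.
#'
#' @param bout A `walking_bout` whose trajectory the events refer to.
#' @param events Interleaved event data frame (see [interleave_steps()]).
#' @return Data frame with columns `step_index`, `leading_foot`,
#'   `step_time_s`, `step_width`, `strike_time_s`, `strike_frame`, `emos`
#'   (NA until [emos_per_step()] fills it), ordered by strike time.
#' @export
compute_step_records <- function(bout, events) {
  stopifnot(inherits(bout, "walking_bout"))
  traj <- bout$trajectory
  video <- is_video_source(traj)
  hw <- if (video) hip_width_series(traj) else NULL
  out <- list()
  k <- 0L
  n <- nrow(events)
  if (n >= 2) {
    for (i in 2:n) {
      if (events$foot[i] == events$foot[i - 1]) next  # flagged gap
      if (isTRUE(events$gap_before[i])) next
      lead <- events$foot[i]
      trail <- events$foot[i - 1]
      fi <- match(events$frame[i], traj$frame)
      if (is.na(fi)) next
      w <- abs(traj$x[fi, paste0(lead, "_ankle")] -
                 traj$x[fi, paste0(trail, "_ankle")])
      if (video) w <- w / hw[fi]
      k <- k + 1L
      out[[k]] <- data.frame(
        step_index = k,
        leading_foot = lead,
        step_time_s = events$time_s[i] - events$time_s[i - 1],
        step_width = w,
        strike_time_s = events$time_s[i],
        strike_frame = events$frame[i],
        emos = NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!k) {
    return(data.frame(step_index = integer(0), leading_foot = character(0),
                      step_time_s = numeric(0), step_width = numeric(0),
                      strike_time_s = numeric(0), strike_frame = integer(0),
                      emos = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Cadence from a strike sequence
#'
#' Cadence in steps/min: `60 * (n_events - 1) / (t_last - t_first)`.
#'
#' @param events Event data frame with a `time_s` column (2 or more rows).
#' @return Cadence in steps per minute.
#' @export
compute_cadence <- function(events) {
  n <- nrow(events)
  if (is.null(n) || n < 2) stop("cadence undefined for fewer than 2 strikes")
  span <- events$time_s[n] - events$time_s[1]
  60 * (n - 1) / span
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#'
#' @param values Numeric vector, length 2 or more, with nonzero mean.
#' @return The CV (dimensionless).
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2) stop("CV needs at least 2 values")
  m <- mean(values)
  if (m == 0) stop("CV undefined for zero mean")
  stats::sd(values) / m
}

#' Estimated margin of stability from the extrapolated centre of mass
#'
#' The extrapolated centre of mass is `XCOM = COM + V_COM / omega` with
#' `omega = sqrt(g / l)` the inverted-pendulum natural frequency of a leg of
#' length `l`. The estimated margin of stability is `eMOS = XCOM - BOS`,
#' where BOS is the lateral boundary of the base of support (the stance
#' foot's lateral position). All positions must share one lateral axis and
#' one unit system; `omega` is a temporal quantity (1/s) and is always
#' computed from the leg length in metres, so it applies equally to
#' metre-valued and hip-width-normalized velocities.
#'
#' @param com Lateral centre-of-mass position (sacrum or mid-hip proxy).
#' @param v_com Lateral centre-of-mass velocity, units of `com` per second.
#' @param bos Lateral base-of-support boundary (stance foot position).
#' @param leg_length Leg length in metres (> 0).
#' @param g Gravitational acceleration (default 9.81 m/s^2).
#' @return `eMOS = (com + v_com / sqrt(g / leg_length)) - bos`; vectorized.
#' @export
compute_emos <- function(com, v_com, bos, leg_length, g = 9.81) {
  if (!is.numeric(leg_length) || any(leg_length <= 0))
    stop("leg_length must be positive")
  omega <- sqrt(g / leg_length)
  (com + v_com / omega) - bos
}

# Central finite differences (one-sided at the edges), times fs.
finite_diff <- function(x, fs) {
  n <- length(x)
  if (n < 2) return(rep(NA_real_, n))
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) * fs
  d[n] <- (x[n] - x[n - 1]) * fs
  if (n > 2) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  d
}

#' Fill per-step eMOS values into step records
#'
#' For each step, eMOS is evaluated at the strike frame of the new stance
#' foot: BOS is that foot's ankle lateral position, COM is the mid-hip
#' lateral position (the closest frontal-view proxy for the sacrum), and
#' V_COM is its central-finite-difference velocity, all read at the same
#' frame in raw trajectory units. The lateral axis is oriented per step so
#' that the stance side is positive (eMOS is positive when XCOM lies beyond
#' the stance foot laterally). For video sources the result is normalized by
#' the hip width at the strike frame.
#'
#' @param bout A preprocessed `walking_bout` (smoothing precedes
#'   differentiation).
#' @param records Step records from [compute_step_records()].
#' @param leg_length Leg length in metres; defaults to the bout's
#'   `leg_length_m`, then to `0.53 * height_m`.
#' @param g Gravitational acceleration (default 9.81).
#' @return `records` with the `emos` column filled (hip-width units for
#'   video, metres for reference streams).
#' @export
emos_per_step <- function(bout, records, leg_length = NULL, g = 9.81) {
  stopifnot(inherits(bout, "walking_bout"))
  if (is.null(leg_length)) {
    leg_length <- bout$leg_length_m
    if (is.null(leg_length) || is.na(leg_length)) {
      if (is.null(bout$height_m) || is.na(bout$height_m))
        stop("leg length required: supply leg_length or bout height metadata")
      leg_length <- 0.53 * bout$height_m
    }
  }
  traj <- bout$trajectory
  video <- is_video_source(traj)
  mh <- mid_hip(traj)
  v_com <- finite_diff(mh$x, traj$frame_rate)
  hw <- if (video) hip_width_series(traj) else NULL
  for (i in seq_len(nrow(records))) {
    fi <- match(records$strike_frame[i], traj$frame)
    if (is.na(fi)) next
    foot <- records$leading_foot[i]
    bos <- traj$x[fi, paste0(foot, "_ankle")]
    com <- mh$x[fi]
    s <- sign(bos - com)
    if (s == 0) s <- 1
    # orient the lateral axis so the stance side is positive, then Eq. above
    e <- compute_emos(s * com, s * v_com[fi], s * bos, leg_length, g)
    if (video) e <- e / hw[fi]
    records$emos[i] <- e
  }
  records
}

#' Summarize a bout's steps into per-bout gait variables
#'
#' `method = "mean"` returns one row with the six per-bout gait variables:
#' cadence (from the full strike sequence), mean and CV of step time, mean
#' and CV of step width, and mean eMOS, plus the usable step count.
#' `method = "individual"` returns the per-step table itself (cadence and
#' CVs exist only at bout level).
#'
#' @param records Step records (with eMOS filled where available).
#' @param events The interleaved event list the records came from.
#' @param method `"mean"` or `"individual"`.
#' @return A one-row data frame (`mean`) or the per-step table
#'   (`individual`); empty with a warning when no usable steps exist.
#' @export
summarize_bout <- function(records, events, method = c("mean", "individual")) {
  method <- match.arg(method)
  if (!nrow(records)) {
    warning("no usable steps in bout")
    if (method == "individual") return(records)
    return(data.frame(cadence = NA_real_, mean_step_time = NA_real_,
                      cv_step_time = NA_real_, mean_step_width = NA_real_,
                      cv_step_width = NA_real_, mean_emos = NA_real_,
                      n_steps = 0L))
  }
  if (method == "individual") return(records)
  safe_cv <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2 || mean(v) == 0) return(NA_real_)
    coefficient_of_variation(v)
  }
  data.frame(
    cadence = compute_cadence(events),
    mean_step_time = mean(records$step_time_s),
    cv_step_time = safe_cv(records$step_time_s),
    mean_step_width = mean(records$step_width),
    cv_step_width = safe_cv(records$step_width),
    mean_emos = mean(records$emos, na.rm = TRUE),
    n_steps = nrow(records)
  )
}
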