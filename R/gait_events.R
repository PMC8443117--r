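# Foot-strike detection from the vertical ankle trajectory, and alignment of
# step sequences between two measurement systems.

# Local minima of a numeric series with prominence filtering and minimum
# spacing (candidates closer than min_dist keep the lower one). Returns
# interior indices only.
local_minima <- function(v, min_dist, prominence_floor) {
  n <- length(v)
  if (n < 3) return(integer(0))
  cand <- which(v[2:(n - 1)] < v[1:(n - 2)] & v[2:(n - 1)] <= v[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  # prominence of a minimum: on each side, height of the lowest barrier that
  # must be climbed before reaching a lower point (or the series end)
  prom <- vapply(cand, function(i) {
    left <- if (i > 1) v[1:(i - 1)] else numeric(0)
    right <- if (i < n) v[(i + 1):n] else numeric(0)
    side_prom <- function(side) {
      if (!length(side)) return(Inf)
      lower <- which(side < v[i])
      if (!length(lower)) return(max(side) - v[i])
      max(side[seq_len(min(lower) - 1)], v[i]) - v[i]
    }
    min(side_prom(rev(left)), side_prom(right))
  }, numeric(1))
  cand <- cand[prom >= prominence_floor]
  if (!length(cand)) return(integer(0))
  # greedy merge: keep lower minima first, drop any within min_dist of a keep
  ord <- cand[order(v[cand])]
  keep <- integer(0)
  for (i in ord) {
    if (!length(keep) || all(abs(keep - i) >= min_dist)) keep <- c(keep, i)
  }
  sort(keep)
}

empty_events <- function() {
  data.frame(foot = character(0), frame = integer(0), time_s = numeric(0),
             lateral = numeric(0), vertical = numeric(0),
             stringsAsFactors = FALSE)
}

#' Detect foot strikes from the vertical ankle trajectory
#'
#' The ankle's vertical pixel series is flipped to up-positive, linearly
#' detrended over the bout (the dominant trend is the monotone perspective
#' scaling as the subject approaches or recedes), and local minima of the
#' detrended series are reported as foot strikes: ankle height is lowest
#' while the foot is flat on the ground. Candidate minima closer than
#' `min_stride_interval` are merged keeping the lower one, and minima whose
#' prominence falls below `prominence_frac` times the interquartile range of
#' the detrended series are discarded. Strike times are refined to sub-frame
#' resolution by a parabolic fit through the three samples around each
#' minimum.
#'
#' @param bout A `walking_bout` from [extract_bouts()] (preprocessed:
#'   interpolated, swap-corrected, smoothed).
#' @param foot `"left"` or `"right"`.
#' @param min_stride_interval Minimum interval between two strikes of the
#'   same foot, seconds (default 0.6; a cadence of 130 steps/min still gives
#'   strides of about 0.92 s).
#' @param prominence_frac Prominence floor as a fraction of the detrended
#'   series' interquartile range (default 0.10).
#' @param refine Logical; refine strike times by parabolic interpolation
#'   (default `TRUE`). Frame indices always point at the sampled minimum.
#' @return Data frame with columns `foot`, `frame`, `time_s`, `lateral`
#'   (hip-width units for video sources, native units otherwise), `vertical`
#'   (up-positive detrended value at the strike). Empty, with a warning, when
#'   the bout is shorter than one expected stride.
#' @export
detect_foot_strikes <- function(bout, foot = c("left", "right"),
                                min_stride_interval = 0.6,
                                prominence_frac = 0.10,
                                refine = TRUE) {
  stopifnot(inherits(bout, "walking_bout"))
  foot <- match.arg(foot)
  traj <- bout$trajectory
  fs <- traj$frame_rate
  n <- n_frames(traj)
  if (n < ceiling(min_stride_interval * fs) + 2L) {
    warning("bout shorter than one expected stride; no strikes detected")
    return(empty_events())
  }
  joint <- paste0(foot, "_ankle")
  up <- -traj$y[, joint]           # image y is down-positive
  tt <- traj$time
  fit <- stats::lm.fit(cbind(1, tt), up)
  v <- fit$residuals
  iqr <- stats::IQR(v)
  # a flat (or numerically flat) series has no meaningful extrema
  floor_ <- max(prominence_frac * iqr, .Machine$double.eps^0.5)
  idx <- local_minima(v, min_dist = min_stride_interval * fs,
                      prominence_floor = floor_)
  if (!length(idx)) return(empty_events())
  time_s <- tt[idx]
  if (refine) {
    dt <- 1 / fs
    for (k in seq_along(idx)) {
      i <- idx[k]
      if (i > 1 && i < n) {
        denom <- v[i - 1] - 2 * v[i] + v[i + 1]
        if (denom > 0) {
          off <- 0.5 * (v[i - 1] - v[i + 1]) / denom
          time_s[k] <- tt[i] + max(-0.5, min(0.5, off)) * dt
        }
      }
    }
  }
  lateral <- traj$x[idx, joint]
  if (is_video_source(traj)) {
    hw <- hip_width_series(traj)[idx]
    lateral <- lateral / hw
  }
  data.frame(foot = foot, frame = traj$frame[idx], time_s = time_s,
             lateral = lateral, vertical = v[idx], stringsAsFactors = FALSE)
}

#' Interleave left- and right-foot strike events
#'
#' Merges per-foot strike lists into one time-ordered sequence. Two
#' consecutive strikes of the same foot indicate a missed contralateral
#' strike; the enclosed step is flagged (`gap_before`) and excluded from
#' step-level variables downstream.
#'
#' @param left,right Event data frames from [detect_foot_strikes()].
#' @return Time-ordered event data frame with an extra logical column
#'   `gap_before` (`TRUE` when the previous event has the same foot).
#' @export
interleave_steps <- function(left, right) {
  ev <- rbind(left, right)
  ev <- ev[order(ev$time_s), , drop = FALSE]
  rownames(ev) <- NULL
  n <- nrow(ev)
  ev$gap_before <- if (n) c(FALSE, ev$foot[-1] == ev$foot[-n]) else logical(0)
  ev
}

#' Align step sequences between video and reference systems
#'
#' Trims both sequences so they start and end on the same physical strike:
#' events are matched greedily by nearest time within `window` seconds
#' (after removing a known clock `offset`), preserving foot-label order.
#' Unmatched events on either side are trimmed and counted.
#'
#' @param video,reference Time-ordered event data frames (from
#'   [interleave_steps()] or equivalent) with columns `foot` and `time_s`.
#' @param offset Clock offset in seconds added to reference times (0 for
#'   synthetic data, which shares the video clock).
#' @param window Matching window in seconds (default 0.25, below half the
#'   shortest plausible step time).
#' @return List with elements `video` and `reference` (equal-length matched
#'   event data frames with identical foot order, plus a shared `pair`
#'   index), and `trimmed` (counts of unmatched events per side).
#' @export
align_step_sequences <- function(video, reference, offset = 0, window = 0.25) {
  nv <- nrow(video); nr <- nrow(reference)
  ref_t <- reference$time_s + offset
  iv <- 1L; ir <- 1L
  mv <- integer(0); mr <- integer(0)
  while (iv <= nv && ir <= nr) {
    dt <- video$time_s[iv] - ref_t[ir]
    if (video$foot[iv] == reference$foot[ir] && abs(dt) <= window) {
      mv <- c(mv, iv); mr <- c(mr, ir)
      iv <- iv + 1L; ir <- ir + 1L
    } else if (dt < 0) {
      iv <- iv + 1L
    } else {
      ir <- ir + 1L
    }
  }
  if (length(mv) < 2)
    stop("fewer than 2 matchable strikes between video and reference")
  out_v <- video[mv, , drop = FALSE]
  out_r <- reference[mr, , drop = FALSE]
  out_v$pair <- seq_along(mv)
  out_r$pair <- seq_along(mr)
  rownames(out_v) <- rownames(out_r) <- NULL
  list(video = out_v, reference = out_r,
       trimmed = c(video = nv - length(mv), reference = nr - length(mr)))
}
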