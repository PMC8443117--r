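# Confidence-based masking and interpolation, left/right swap correction,
# zero-phase smoothing, and cropping to straight-walking bouts.
#
# The pipeline order is fixed: mask/interpolate -> swap-correct -> smooth ->
# crop to bouts. Smoothing always precedes event detection.

#' Default confidence threshold per tracker
#'
#' Confidence scores are not calibrated across pose-estimation libraries, so
#' each tracker carries its own low-confidence threshold: 0.3 for OpenPose,
#' 0.5 for AlphaPose and 0.15 for Detectron.
#'
#' @param tracker One of `"openpose"`, `"alphapose"`, `"detectron"`.
#' @return A confidence scalar in \[0, 1\].
#' @export
default_threshold <- function(tracker) {
  thr <- c(openpose = 0.3, alphapose = 0.5, detectron = 0.15)
  if (length(tracker) != 1 || !tracker %in% names(thr))
    stop("no default confidence threshold for tracker '", tracker,
         "'; applies only to openpose, alphapose, detectron")
  unname(thr[[tracker]])
}

new_quality_report <- function(missing_fraction, interpolated_frame_count,
                               swap_correction_count, threshold_used) {
  structure(
    list(missing_fraction = missing_fraction,
         interpolated_frame_count = as.integer(interpolated_frame_count),
         swap_correction_count = as.integer(swap_correction_count),
         threshold_used = threshold_used),
    class = "quality_report"
  )
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> threshold=%s interpolated=%d swaps=%d\n",
              format(x$threshold_used), x$interpolated_frame_count,
              x$swap_correction_count))
  worst <- sort(x$missing_fraction, decreasing = TRUE)[1:3]
  cat("  worst missing fractions:",
      paste(sprintf("%s=%.3f", names(worst), worst), collapse = ", "), "\n")
  invisible(x)
}

#' Mask low-confidence keypoints and interpolate across the gaps
#'
#' Observations with confidence below `threshold` (or missing entirely) are
#' replaced by linear interpolation between the nearest flanking confident
#' observations of the same joint; leading/trailing gaps are filled by
#' holding the first/last confident value (linear extrapolation would amplify
#' tracker noise at bout edges). Confident observations are preserved
#' exactly. The quality report records the per-joint missing fraction
#' computed before interpolation, for the "<10% missing" screening rule.
#'
#' @param traj A [pose_trajectory()].
#' @param threshold Confidence scalar in \[0, 1\]; see [default_threshold()].
#' @return List with elements `trajectory` (interpolated) and `report`
#'   (a `quality_report`).
#' @export
mask_and_interpolate <- function(traj, threshold) {
  stopifnot(inherits(traj, "pose_trajectory"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > 1)
    stop("threshold must be a single value in [0, 1]")
  n <- n_frames(traj)
  missing_fraction <- stats::setNames(numeric(17), COCO_JOINTS)
  n_interp <- 0L
  for (j in COCO_JOINTS) {
    bad <- is.na(traj$conf[, j]) | traj$conf[, j] < threshold |
      !is.finite(traj$x[, j]) | !is.finite(traj$y[, j])
    missing_fraction[j] <- mean(bad)
    if (!any(bad)) next
    if (all(bad))
      stop("joint '", j, "' has no confident observations in the trajectory")
    good <- which(!bad)
    t_all <- traj$time
    traj$x[bad, j] <- stats::approx(t_all[good], traj$x[good, j],
                                    xout = t_all[bad], rule = 2)$y
    traj$y[bad, j] <- stats::approx(t_all[good], traj$y[good, j],
                                    xout = t_all[bad], rule = 2)$y
    n_interp <- n_interp + sum(bad)
  }
  list(trajectory = traj,
       report = new_quality_report(missing_fraction, n_interp, 0L, threshold))
}

#' Apply the 10%-missing screening rule
#'
#' A joint fails when its pre-interpolation missing fraction is greater than
#' or equal to `limit` (the boundary counts as failing: only recordings with
#' *less than* 10% missing survive screening). Failing joints are flagged,
#' never silently dropped.
#'
#' @param report A `quality_report` from [mask_and_interpolate()].
#' @param limit Missing-fraction limit (default 0.10).
#' @return Named logical vector, `TRUE` where the joint passes.
#' @export
check_missing_rule <- function(report, limit = 0.10) {
  stopifnot(inherits(report, "quality_report"))
  report$missing_fraction < limit
}

#' Correct left/right label swaps
#'
#' Pose estimators occasionally label a joint on the left side of the body
#' as the corresponding right-side joint. For each frame and each left/right
#' pair (hips, knees, ankles), the pair is exchanged when doing so reduces
#' the summed Euclidean displacement from the previous frame's (already
#' corrected) positions by more than the swap margin,
#' `margin_frac * hip width` at that frame. The margin prevents exchanges
#' during genuine smooth crossings of the two tracks. The operation is
#' idempotent on its own output. An optional manual-override table of
#' (frame, joint-pair) exchanges is applied after the automatic pass.
#'
#' @param traj A [pose_trajectory()] with gaps already interpolated.
#' @param margin_frac Swap margin as a fraction of the frame-local hip width
#'   (default 0.25).
#' @param overrides Optional data frame with columns `frame` (frame index
#'   values) and `joint_pair` (one of `"hip"`, `"knee"`, `"ankle"`); those
#'   pairs are exchanged unconditionally after the automatic pass.
#' @return List with elements `trajectory` and `report` (a `quality_report`
#'   whose `swap_correction_count` counts automatic exchanges).
#' @export
correct_lr_swaps <- function(traj, margin_frac = 0.25, overrides = NULL) {
  stopifnot(inherits(traj, "pose_trajectory"))
  n <- n_frames(traj)
  hw <- hip_width_series(traj)  # invariant under hip exchange
  count <- 0L
  swapped_at <- integer(0)
  if (n >= 2) {
    for (pair in LR_PAIRS) {
      l <- pair[1]; r <- pair[2]
      # distances between frame t and t-1 under both labelings, relative to
      # the *uncorrected* previous frame; if the previous frame ends up
      # exchanged, keep/swap costs simply trade places
      dist2 <- function(ca, cb) {
        sqrt((traj$x[2:n, ca] - traj$x[1:(n - 1), cb])^2 +
               (traj$y[2:n, ca] - traj$y[1:(n - 1), cb])^2)
      }
      d_keep <- dist2(l, l) + dist2(r, r)
      d_swap <- dist2(r, l) + dist2(l, r)
      margin <- margin_frac * hw[2:n]
      ok <- is.finite(d_keep) & is.finite(d_swap) & is.finite(margin)
      prev_sw <- FALSE
      sw <- logical(n)
      for (t in 2:n) {
        i <- t - 1L
        if (!ok[i]) { prev_sw <- FALSE; next }
        gain <- if (prev_sw) d_swap[i] - d_keep[i] else d_keep[i] - d_swap[i]
        sw[t] <- gain > margin[i]
        prev_sw <- sw[t]
      }
      if (any(sw)) {
        for (m in c("x", "y", "conf")) {
          tmp <- traj[[m]][sw, l]
          traj[[m]][sw, l] <- traj[[m]][sw, r]
          traj[[m]][sw, r] <- tmp
        }
        count <- count + sum(sw)
        swapped_at <- c(swapped_at, traj$frame[sw])
      }
    }
    swapped_at <- sort(swapped_at)
  }
  if (!is.null(overrides) && nrow(overrides)) {
    if (!all(c("frame", "joint_pair") %in% names(overrides)))
      stop("overrides must have columns 'frame' and 'joint_pair'")
    for (k in seq_len(nrow(overrides))) {
      t <- match(overrides$frame[k], traj$frame)
      pair <- LR_PAIRS[[overrides$joint_pair[k]]]
      if (is.na(t) || is.null(pair))
        stop("invalid override row ", k, ": frame ", overrides$frame[k],
             " / pair '", overrides$joint_pair[k], "'")
      for (m in c("x", "y", "conf")) {
        tmp <- traj[[m]][t, pair[1]]
        traj[[m]][t, pair[1]] <- traj[[m]][t, pair[2]]
        traj[[m]][t, pair[2]] <- tmp
      }
    }
  }
  rep <- new_quality_report(stats::setNames(numeric(17), COCO_JOINTS),
                            0L, count, NA_real_)
  attr(rep, "swapped_frames") <- swapped_at
  list(trajectory = traj, report = rep)
}

#' Zero-phase low-pass Butterworth filter of a numeric series
#'
#' Designs a low-pass Butterworth filter ([signal::butter()]) and applies it
#' forward and backward, giving zero net phase and an effectively doubled
#' order. Edges are handled by odd-reflective padding of `3 * (order + 1)`
#' samples and steady-state initial conditions (past inputs and outputs held
#' at the first sample; the low-pass has unit DC gain), so constants pass
#' through unchanged and startup transients are negligible.
#'
#' @param x Numeric series (finite values; interpolate gaps first).
#' @param fs Sampling rate (Hz).
#' @param cutoff Cut-off frequency (Hz), must be below `fs / 2`.
#' @param order Filter order of each pass (default 2).
#' @return Filtered series, same length as `x`.
#' @export
zero_phase_filter <- function(x, fs, cutoff = 8, order = 2) {
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency ", fs / 2)
  if (anyNA(x) || !all(is.finite(x))) stop("series contains non-finite values")
  n <- length(x)
  npad <- 3L * (order + 1L)
  if (n <= npad + 1L)
    stop("series too short for zero-phase filtering: need > ", npad + 1L,
         " samples, got ", n)
  bf <- signal::butter(order, cutoff / (fs / 2), "low")
  b <- bf$b
  a <- bf$a
  one_pass <- function(s) {
    nb <- length(b)
    # MA part with past inputs held at s[1]
    xp <- c(rep(s[1], nb - 1), s)
    v <- as.numeric(stats::filter(xp, b, method = "convolution", sides = 1))
    v <- v[(nb - 1) + seq_along(s)]
    # AR part with past outputs at steady state s[1] (DC gain is 1)
    as.numeric(stats::filter(v, -a[-1], method = "recursive",
                             init = rep(s[1], length(a) - 1)))
  }
  xp <- c(2 * x[1] - x[(npad + 1):2], x, 2 * x[n] - x[(n - 1):(n - npad)])
  y <- one_pass(xp)
  y <- rev(one_pass(rev(y)))
  y[(npad + 1):(npad + n)]
}

#' Smooth a trajectory with a zero-phase Butterworth filter
#'
#' Each joint coordinate series is filtered forward and backward with a
#' low-pass Butterworth filter ([zero_phase_filter()]); confidences pass
#' through unchanged. Defaults: second order, 8 Hz cut-off.
#'
#' @param traj A [pose_trajectory()] with gaps already interpolated.
#' @param cutoff Cut-off frequency in Hz (default 8; must be < Nyquist).
#' @param order Filter order (default 2; zero-phase doubles it effectively).
#' @return The smoothed [pose_trajectory()].
#' @export
smooth_trajectory <- function(traj, cutoff = 8, order = 2) {
  stopifnot(inherits(traj, "pose_trajectory"))
  for (j in COCO_JOINTS) {
    traj$x[, j] <- zero_phase_filter(traj$x[, j], traj$frame_rate, cutoff, order)
    traj$y[, j] <- zero_phase_filter(traj$y[, j], traj$frame_rate, cutoff, order)
  }
  traj
}

#' Crop a trajectory to annotated straight-walking bouts
#'
#' Sections where the participant was turning are excluded by construction:
#' only the annotated straight-walking segments (front or back view) are
#' returned. Annotations are inclusive on both ends and must be
#' non-overlapping and within the trajectory's frame range.
#'
#' @param traj A preprocessed [pose_trajectory()].
#' @param annotations Data frame with columns `subject_id`, `camera`, `view`,
#'   `start_frame`, `end_frame` (frame index values, inclusive).
#' @param height_m,leg_length_m Optional subject metadata attached to each
#'   bout. A missing leg length defaults downstream to `0.53 * height_m`.
#' @return List of `walking_bout` objects, in temporal order.
#' @export
extract_bouts <- function(traj, annotations, height_m = NA_real_,
                          leg_length_m = NA_real_) {
  stopifnot(inherits(traj, "pose_trajectory"))
  if (!nrow(annotations)) return(list())
  req <- c("start_frame", "end_frame", "view")
  if (!all(req %in% names(annotations)))
    stop("annotations need columns: ", paste(req, collapse = ", "))
  ann <- annotations[order(annotations$start_frame), , drop = FALSE]
  if (any(ann$start_frame >= ann$end_frame))
    stop("annotation with start_frame >= end_frame")
  lo <- min(traj$frame); hi <- max(traj$frame)
  if (any(ann$start_frame < lo) || any(ann$end_frame > hi))
    stop("annotation outside trajectory frame range [", lo, ", ", hi, "]")
  if (nrow(ann) > 1 && any(ann$start_frame[-1] <= ann$end_frame[-nrow(ann)]))
    stop("overlapping bout annotations")
  lapply(seq_len(nrow(ann)), function(i) {
    sl <- slice_trajectory(traj, ann$start_frame[i], ann$end_frame[i])
    sl$view <- as.character(ann$view[i])
    if ("camera" %in% names(ann)) sl$camera <- as.character(ann$camera[i])
    structure(
      list(trajectory = sl, annotation = ann[i, , drop = FALSE],
           height_m = height_m, leg_length_m = leg_length_m),
      class = "walking_bout"
    )
  })
}

#' @export
print.walking_bout <- function(x, ...) {
  cat(sprintf("<walking_bout> frames %d-%d | view=%s camera=%s subject=%s\n",
              min(x$trajectory$frame), max(x$trajectory$frame),
              x$trajectory$view, x$trajectory$camera, x$trajectory$subject_id))
  invisible(x)
}
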