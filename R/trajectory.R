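#' The canonical COCO-17 joint set
#'
#' All trajectories in this package key joints by the 17 COCO keypoints.
#' Tracker dialects exposing more landmarks (mid-hip, neck, feet) are reduced
#' to this set on input; the mid-hip point is always re-derived from the two
#' hip keypoints (see [mid_hip()]), never read from a file.
#'
#' @format Character vector of length 17, in COCO order.
#' @export
COCO_JOINTS <- c(
  "nose", "left_eye", "right_eye", "left_ear", "right_ear",
  "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
  "left_wrist", "right_wrist", "left_hip", "right_hip",
  "left_knee", "right_knee", "left_ankle", "right_ankle"
)

#' Left/right joint pairs used for label-swap correction
#' @format Named list of character(2) vectors (left joint, right joint).
#' @export
LR_PAIRS <- list(
  hip   = c("left_hip", "right_hip"),
  knee  = c("left_knee", "right_knee"),
  ankle = c("left_ankle", "right_ankle")
)

VALID_TRACKERS <- c("alphapose", "openpose", "detectron", "reference", "synthetic")
VALID_CAMERAS  <- c("eye_level", "top")
VALID_VIEWS    <- c("front", "back", "mixed")

#' Construct a pose trajectory
#'
#' The central container of the package: time-ordered per-frame 2D keypoints
#' with confidences for one recording. Coordinates follow the image
#' convention (origin top-left, y down-positive) exactly as read from tracker
#' output; the single flip to up-positive happens inside
#' [detect_foot_strikes()].
#'
#' @param x,y,conf Numeric matrices, one row per frame, one column per COCO
#'   joint (columns named as in [COCO_JOINTS]). Missing observations are `NA`
#'   in all three matrices at once.
#' @param frame_rate Sampling rate in Hz (> 0); 30 for phone video, 100 for
#'   reference-role streams.
#' @param frame Integer frame indices, strictly increasing. Defaults to
#'   `0:(n-1)`.
#' @param tracker One of `"alphapose"`, `"openpose"`, `"detectron"`,
#'   `"reference"`, `"synthetic"`.
#' @param camera `"eye_level"` or `"top"`.
#' @param view `"front"`, `"back"` or `"mixed"`.
#' @param subject_id Subject label.
#' @return An object of class `pose_trajectory`: a list with elements
#'   `frame`, `time`, `x`, `y`, `conf`, `frame_rate`, `tracker`, `camera`,
#'   `view`, `subject_id`. `time` is `frame / frame_rate` seconds.
#' @export
pose_trajectory <- function(x, y, conf, frame_rate,
                            frame = NULL,
                            tracker = "synthetic",
                            camera = "eye_level",
                            view = "front",
                            subject_id = "S01") {
  x <- as.matrix(x); y <- as.matrix(y); conf <- as.matrix(conf)
  n <- nrow(x)
  if (!all(dim(y) == dim(x)) || !all(dim(conf) == dim(x)))
    stop("x, y and conf must have identical dimensions")
  if (ncol(x) != length(COCO_JOINTS))
    stop("expected ", length(COCO_JOINTS), " joint columns, got ", ncol(x))
  colnames(x) <- colnames(y) <- colnames(conf) <- COCO_JOINTS
  if (is.null(frame)) frame <- seq_len(n) - 1L
  frame <- as.integer(frame)
  if (length(frame) != n) stop("frame index length does not match frame count")
  if (n > 1 && any(diff(frame) <= 0)) stop("frame indices must be strictly increasing")
  if (!is.numeric(frame_rate) || length(frame_rate) != 1 || frame_rate <= 0)
    stop("frame_rate must be a single positive number")
  tracker <- match.arg(tracker, VALID_TRACKERS)
  camera <- match.arg(camera, VALID_CAMERAS)
  view <- match.arg(view, VALID_VIEWS)
  bad_conf <- conf[!is.na(conf)]
  if (length(bad_conf) && (any(bad_conf < 0) || any(bad_conf > 1)))
    stop("confidences must lie in [0, 1]")
  # x/y finite exactly where confidence is present
  structure(
    list(
      frame = frame,
      time = frame / frame_rate,
      x = x, y = y, conf = conf,
      frame_rate = frame_rate,
      tracker = tracker, camera = camera, view = view,
      subject_id = subject_id
    ),
    class = "pose_trajectory"
  )
}

#' @export
print.pose_trajectory <- function(x, ...) {
  cat(sprintf(
    "<pose_trajectory> %d frames @ %g Hz | tracker=%s camera=%s view=%s subject=%s\n",
    n_frames(x), x$frame_rate, x$tracker, x$camera, x$view, x$subject_id
  ))
  miss <- mean(is.na(x$conf))
  cat(sprintf("  missing joint-frames: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `pose_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$frame)

is_video_source <- function(traj) !identical(traj$tracker, "reference")

#' Derived mid-hip point
#'
#' The mid-hip (sacrum proxy) is always derived as the mean of the left and
#' right hip keypoints; its confidence is the minimum of the two hip
#' confidences (conservative propagation).
#'
#' @param traj A `pose_trajectory`.
#' @return List with numeric vectors `x`, `y`, `conf` (one value per frame).
#' @export
mid_hip <- function(traj) {
  lx <- traj$x[, "left_hip"]; rx <- traj$x[, "right_hip"]
  ly <- traj$y[, "left_hip"]; ry <- traj$y[, "right_hip"]
  list(
    x = (lx + rx) / 2,
    y = (ly + ry) / 2,
    conf = pmin(traj$conf[, "left_hip"], traj$conf[, "right_hip"])
  )
}

#' Per-frame hip width
#'
#' Euclidean distance between the left and right hip keypoints, the
#' frame-local scale used to normalize spatial gait variables from video
#' ("hip-width units") and so cancel perspective.
#'
#' @param traj A `pose_trajectory`.
#' @return Numeric vector, one value per frame.
#' @export
hip_width_series <- function(traj) {
  sqrt((traj$x[, "left_hip"] - traj$x[, "right_hip"])^2 +
         (traj$y[, "left_hip"] - traj$y[, "right_hip"])^2)
}

#' Slice a trajectory by frame index
#'
#' @param traj A `pose_trajectory`.
#' @param from,to Frame index values (as stored in `traj$frame`), inclusive
#'   on both ends.
#' @return A `pose_trajectory` covering the requested frames.
#' @export
slice_trajectory <- function(traj, from, to) {
  keep <- which(traj$frame >= from & traj$frame <= to)
  if (!length(keep)) stop("slice [", from, ", ", to, "] contains no frames")
  out <- traj
  out$frame <- traj$frame[keep]
  out$time <- traj$time[keep]
  out$x <- traj$x[keep, , drop = FALSE]
  out$y <- traj$y[keep, , drop = FALSE]
  out$conf <- traj$conf[keep, , drop = FALSE]
  out
}
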