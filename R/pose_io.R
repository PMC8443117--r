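# Reading tracker-specific keypoint output into the canonical trajectory
# model, and the canonical long-form CSV interchange format.

# BODY-25 index (0-based) for each COCO-17 joint, for OpenPose runs exported
# with the BODY_25 model. Extra BODY-25 landmarks (neck, mid-hip, feet) are
# dropped; mid-hip is always re-derived.
BODY25_TO_COCO <- c(
  nose = 0L, left_eye = 16L, right_eye = 15L, left_ear = 18L, right_ear = 17L,
  left_shoulder = 5L, right_shoulder = 2L, left_elbow = 6L, right_elbow = 3L,
  left_wrist = 7L, right_wrist = 4L, left_hip = 12L, right_hip = 9L,
  left_knee = 13L, right_knee = 10L, left_ankle = 14L, right_ankle = 11L
)

#' Read a pose-tracking run into a canonical trajectory
#'
#' Parses tracker-specific keypoint output into a [pose_trajectory()] with
#' canonical COCO-17 joint naming and image pixel coordinates (origin
#' top-left, y down-positive, preserved exactly as stored).
#'
#' Supported dialects:
#' \describe{
#'   \item{`openpose`}{A directory with one JSON file per frame (processed in
#'     lexicographic filename order), persons under a `people` list, each with
#'     a flat `pose_keypoints_2d` array `[x1, y1, c1, x2, y2, c2, ...]` in
#'     COCO or BODY-25 order (`keypoint_order`).}
#'   \item{`alphapose`}{A single JSON array of detections with fields
#'     `image_id`, `keypoints` (flat COCO triplets) and `score`; frames are
#'     the distinct `image_id` values in lexicographic order.}
#'   \item{`detectron`}{A single JSON array of per-frame records with fields
#'     `frame` and `instances`, each instance holding `keypoints` (17 `[x, y,
#'     c]` triplets) and a `score`.}
#'   \item{`canonical`}{The long-form CSV written by [write_canonical()].}
#' }
#'
#' Frames with no detected person yield all-missing observations (trajectory
#' length is unchanged). When a frame contains several detected persons, the
#' participant is selected deterministically by largest keypoint bounding-box
#' area, with a continuity tie-break (nearest mid-hip to the previously
#' selected person) when areas are within 5% of each other; the per-frame
#' choice is recorded in the `person_selection` attribute.
#'
#' @param path File (or, for `openpose`, directory) to read.
#' @param dialect One of `"canonical"`, `"openpose"`, `"alphapose"`,
#'   `"detectron"`.
#' @param frame_rate Sampling rate in Hz (video sources default to 30).
#' @param keypoint_order For the OpenPose dialect: `"coco"` or `"body25"`.
#' @param tracker,camera,view,subject_id Metadata labels attached to the
#'   result (ignored for `canonical`, whose sidecar carries them).
#' @return A [pose_trajectory()].
#' @export
read_pose_run <- function(path, dialect = c("canonical", "openpose", "alphapose", "detectron"),
                          frame_rate = 30,
                          keypoint_order = c("coco", "body25"),
                          tracker = NULL, camera = "eye_level",
                          view = "front", subject_id = "S01") {
  if (!file.exists(path)) stop("path does not exist: ", path)
  dialect <- tryCatch(match.arg(dialect),
                      error = function(e) stop("unknown dialect: ", dialect[1]))
  keypoint_order <- match.arg(keypoint_order)
  if (is.null(tracker)) {
    tracker <- switch(dialect, openpose = "openpose", alphapose = "alphapose",
                      detectron = "detectron", "synthetic")
  }
  switch(dialect,
    canonical = read_canonical(path),
    openpose = read_openpose_dir(path, frame_rate, keypoint_order,
                                 tracker, camera, view, subject_id),
    alphapose = read_alphapose_file(path, frame_rate, tracker, camera, view, subject_id),
    detectron = read_detectron_file(path, frame_rate, tracker, camera, view, subject_id)
  )
}

# ---- person selection ------------------------------------------------------

# candidates: list of 17x3 matrices (x, y, conf). Returns index of the
# selected person: largest keypoint bounding-box area; if the runner-up is
# within 5% of the winner, the candidate whose mid-hip is nearest the
# previously selected mid-hip wins.
select_person <- function(candidates, prev_midhip = NULL) {
  if (!length(candidates)) return(NA_integer_)
  area <- vapply(candidates, function(kp) {
    ok <- !is.na(kp[, 3]) & kp[, 3] > 0 & is.finite(kp[, 1]) & is.finite(kp[, 2])
    if (sum(ok) < 2) return(0)
    diff(range(kp[ok, 1])) * diff(range(kp[ok, 2]))
  }, numeric(1))
  best <- which.max(area)
  if (!is.null(prev_midhip) && all(is.finite(prev_midhip))) {
    near <- which(area >= 0.95 * area[best])
    if (length(near) > 1) {
      d <- vapply(near, function(i) {
        kp <- candidates[[i]]
        mh <- c(mean(kp[c(12, 13), 1]), mean(kp[c(12, 13), 2]))
        if (any(!is.finite(mh))) return(Inf)
        sqrt(sum((mh - prev_midhip)^2))
      }, numeric(1))
      best <- near[which.min(d)]
    }
  }
  best
}

# Turn a flat [x,y,c,...] vector in COCO or BODY-25 order into a 17x3 matrix.
triplets_to_matrix <- function(v, order = "coco", where = "keypoints") {
  v <- as.numeric(v)
  if (length(v) %% 3 != 0)
    stop("keypoint array length not a multiple of 3 in ", where)
  m <- matrix(v, ncol = 3, byrow = TRUE)
  if (order == "body25") {
    if (nrow(m) < 25) stop("BODY-25 keypoint array too short in ", where)
    m <- m[BODY25_TO_COCO + 1L, , drop = FALSE]
  } else {
    if (nrow(m) < 17) stop("COCO keypoint array too short in ", where)
    m <- m[1:17, , drop = FALSE]
  }
  # zero-confidence detections are conventionally "not detected"
  miss <- is.na(m[, 3]) | m[, 3] <= 0
  m[miss, ] <- NA_real_
  m
}

assemble_trajectory <- function(per_frame, frame_rate, tracker, camera, view,
                                subject_id, frame = NULL) {
  n <- length(per_frame)
  x <- matrix(NA_real_, n, 17)
  y <- matrix(NA_real_, n, 17)
  conf <- matrix(NA_real_, n, 17)
  sel <- integer(n)
  prev_mh <- NULL
  for (i in seq_len(n)) {
    cands <- per_frame[[i]]
    j <- select_person(cands, prev_mh)
    sel[i] <- if (is.na(j)) NA_integer_ else j
    if (!is.na(j)) {
      kp <- cands[[j]]
      x[i, ] <- kp[, 1]; y[i, ] <- kp[, 2]; conf[i, ] <- kp[, 3]
      mh <- c(mean(kp[c(12, 13), 1]), mean(kp[c(12, 13), 2]))
      if (all(is.finite(mh))) prev_mh <- mh
    }
  }
  traj <- pose_trajectory(x, y, conf, frame_rate, frame = frame,
                          tracker = tracker, camera = camera, view = view,
                          subject_id = subject_id)
  attr(traj, "person_selection") <- sel
  traj
}

# ---- dialect readers -------------------------------------------------------

read_openpose_dir <- function(path, frame_rate, keypoint_order,
                              tracker, camera, view, subject_id) {
  if (!dir.exists(path)) stop("openpose dialect expects a directory: ", path)
  files <- sort(list.files(path, pattern = "\\.json$", full.names = TRUE))
  if (!length(files)) stop("no per-frame JSON files in ", path)
  per_frame <- lapply(seq_along(files), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(files[i], simplifyVector = FALSE),
                    error = function(e) stop("unparseable file at frame ", i - 1,
                                             " (", basename(files[i]), "): ",
                                             conditionMessage(e)))
    people <- rec$people
    if (is.null(people) || !length(people)) return(list())
    lapply(people, function(p)
      triplets_to_matrix(p$pose_keypoints_2d, keypoint_order,
                         where = basename(files[i])))
  })
  assemble_trajectory(per_frame, frame_rate, tracker, camera, view, subject_id)
}

read_alphapose_file <- function(path, frame_rate, tracker, camera, view, subject_id) {
  dets <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                   error = function(e) stop("unparseable AlphaPose file: ",
                                            conditionMessage(e)))
  if (!length(dets)) stop("empty AlphaPose results file: ", path)
  ids <- vapply(dets, function(d) as.character(d$image_id), character(1))
  frames <- sort(unique(ids))
  per_frame <- lapply(frames, function(f) {
    lapply(dets[ids == f], function(d)
      triplets_to_matrix(d$keypoints, "coco", where = paste0("image ", f)))
  })
  assemble_trajectory(per_frame, frame_rate, tracker, camera, view, subject_id)
}

read_detectron_file <- function(path, frame_rate, tracker, camera, view, subject_id) {
  recs <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                   error = function(e) stop("unparseable Detectron file: ",
                                            conditionMessage(e)))
  if (!length(recs)) stop("empty Detectron results file: ", path)
  ord <- order(vapply(recs, function(r) as.numeric(r$frame), numeric(1)))
  recs <- recs[ord]
  per_frame <- lapply(recs, function(r) {
    if (is.null(r$instances) || !length(r$instances)) return(list())
    lapply(r$instances, function(inst) {
      kp <- inst$keypoints
      flat <- unlist(kp, use.names = FALSE)
      triplets_to_matrix(flat, "coco", where = paste0("frame ", r$frame))
    })
  })
  frame <- vapply(recs, function(r) as.integer(r$frame), integer(1))
  assemble_trajectory(per_frame, frame_rate, tracker, camera, view, subject_id,
                      frame = frame)
}

# ---- canonical interchange format ------------------------------------------

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".meta.yml")

#' Write a trajectory to the canonical interchange format
#'
#' Long-form CSV with columns `frame, time_s, joint, x, y, confidence`
#' (UTF-8, "." decimal separator; missing observations as empty cells), plus
#' a YAML sidecar `<stem>.meta.yml` carrying `frame_rate`, `tracker`,
#' `camera`, `view` and `subject_id`. Finite values are written with 17
#' significant digits so that [read_pose_run()] on the result reproduces the
#' trajectory bit-exactly and preserves missingness.
#'
#' @param traj A [pose_trajectory()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_canonical <- function(traj, path) {
  stopifnot(inherits(traj, "pose_trajectory"))
  n <- n_frames(traj)
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  df <- data.frame(
    frame = rep(traj$frame, each = 17),
    time_s = fmt(rep(traj$time, each = 17)),
    joint = rep(COCO_JOINTS, times = n),
    x = fmt(as.vector(t(traj$x))),
    y = fmt(as.vector(t(traj$y))),
    confidence = fmt(as.vector(t(traj$conf))),
    stringsAsFactors = FALSE
  )
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write canonical trajectory to ", path)
  meta <- list(frame_rate = traj$frame_rate, tracker = traj$tracker,
               camera = traj$camera, view = traj$view,
               subject_id = traj$subject_id)
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

read_canonical <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop("missing sidecar header: ", sp)
  meta <- yaml::read_yaml(sp)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(frame = "integer", time_s = "numeric",
                                       joint = "character", x = "numeric",
                                       y = "numeric", confidence = "numeric"))
  frames <- unique(df$frame)
  n <- length(frames)
  idx_f <- match(df$frame, frames)
  idx_j <- match(df$joint, COCO_JOINTS)
  if (anyNA(idx_j)) {
    bad <- df[which(is.na(idx_j))[1], ]
    stop("unknown joint '", bad$joint, "' at frame ", bad$frame)
  }
  x <- matrix(NA_real_, n, 17); y <- matrix(NA_real_, n, 17)
  conf <- matrix(NA_real_, n, 17)
  x[cbind(idx_f, idx_j)] <- df$x
  y[cbind(idx_f, idx_j)] <- df$y
  conf[cbind(idx_f, idx_j)] <- df$confidence
  pose_trajectory(x, y, conf, meta$frame_rate, frame = frames,
                  tracker = meta$tracker, camera = meta$camera,
                  view = meta$view, subject_id = meta$subject_id)
}
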