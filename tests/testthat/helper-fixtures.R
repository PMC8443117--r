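# Fixture builders shared across the suite. Everything is generated in code;
# no binary fixtures.

# A trajectory where every joint is constant except those overridden with a
# per-frame series. Overrides: named list joint -> list(x=, y=, conf=).
make_traj <- function(n = 60, frame_rate = 30, overrides = list(),
                      tracker = "synthetic", base_conf = 0.9) {
  x <- matrix(rep(seq(100, 260, length.out = 17), each = n), n, 17)
  y <- matrix(rep(seq(100, 420, length.out = 17), each = n), n, 17)
  conf <- matrix(base_conf, n, 17)
  colnames(x) <- colnames(y) <- colnames(conf) <- COCO_JOINTS
  # keep the hips apart so hip width is well-defined
  x[, "left_hip"] <- 260
  x[, "right_hip"] <- 140
  y[, "left_hip"] <- y[, "right_hip"] <- 300
  for (j in names(overrides)) {
    o <- overrides[[j]]
    if (!is.null(o$x)) x[, j] <- o$x
    if (!is.null(o$y)) y[, j] <- o$y
    if (!is.null(o$conf)) conf[, j] <- o$conf
  }
  pose_trajectory(x, y, conf, frame_rate, tracker = tracker)
}

# Wrap a trajectory in a walking_bout without cropping.
as_bout <- function(traj, height_m = 1.64, leg_length_m = 0.87) {
  ann <- data.frame(subject_id = traj$subject_id, camera = traj$camera,
                    view = traj$view, start_frame = min(traj$frame),
                    end_frame = max(traj$frame), stringsAsFactors = FALSE)
  extract_bouts(traj, ann, height_m = height_m, leg_length_m = leg_length_m)[[1]]
}

# Small, fast simulator configuration used where the full study scale is not
# the point of the test.
small_cfg <- function(seed = 1, ...) {
  gait_sim_config(n_subjects = 2, bouts_front = 1, bouts_back = 1,
                  seed = seed, ...)
}

# Event table helper.
events_df <- function(foot, time_s, lateral = 0) {
  foot <- rep(foot, length.out = length(time_s))
  lateral <- rep(lateral, length.out = length(time_s))
  data.frame(foot = foot, frame = as.integer(round(time_s * 30)),
             time_s = time_s, lateral = lateral,
             vertical = rep(0, length(time_s)),
             stringsAsFactors = FALSE)
}
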