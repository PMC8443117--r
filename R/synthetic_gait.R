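# Seeded kinematic gait simulator: paired ground-truth gait (reference role,
# 100 Hz, metres) and clean or corrupted 2D keypoint trajectories (video
# role, 30 fps, pixels) with the statistical structure the analysis assumes.
#
# The walker is kinematic, not dynamic: strike times are drawn as
# alternating-foot intervals, foot placements as jittered lateral targets,
# the sacrum swings between stance feet on a natural spline, and the ankle
# rises on a |sin| bump between its own strikes (so ankle height has a
# unique minimum exactly at each strike). A fronto-parallel skeleton is
# projected through a pinhole camera whose depth advances at walking speed,
# which makes hip-width normalization non-trivial.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

derive_seed <- function(seed, k) as.integer((as.numeric(seed) + 7919 * k) %% 2147483647)

#' Configuration for the gait simulator
#'
#' Defaults emulate the walking of community-dwelling older adults recorded
#' by phone cameras against a 100 Hz reference system: cadence 106.44
#' steps/min (between-subject SD 8.5), step-time CV 0.06 within a bout, step
#' width 0.09 m (between-subject SD of the mean 0.04 m, per-foot placement
#' jitter 0.027 m), two camera heights (1.11 m eye-level, 2.05 m top),
#' front/back views, 30 fps video against a 100 Hz reference.
#'
#' @param n_subjects Number of simulated participants.
#' @param cadence_mean,cadence_sd Cadence in steps/min: population mean and
#'   between-subject SD.
#' @param step_time_cv Within-bout coefficient of variation of step time.
#' @param step_width_mean,step_width_sd Mean step width (m) and its
#'   between-subject SD.
#' @param foot_jitter_sd Per-step lateral placement jitter of each foot (m).
#' @param com_amplitude,com_amplitude_sd Lateral sacrum sway amplitude (m)
#'   and its between-subject SD.
#' @param hip_width Frontal projected distance between hip keypoints (m).
#' @param subject_height,subject_height_sd Stature (m) and between-subject SD.
#' @param leg_length Leg length (m); `NA` derives 0.53 * height.
#' @param step_length Anterior step length (m), sets walking speed.
#' @param n_steps_bout Steps per walking bout (scalar or range to sample).
#' @param bouts_front,bouts_back Bouts per subject and view.
#' @param video_frame_rate,reference_rate Sampling rates (Hz).
#' @param focal_px Pinhole focal length in pixels.
#' @param image_width,image_height Image size in pixels.
#' @param camera_standoff Camera distance from the near end of the walkway (m).
#' @param camera_heights Named camera-height presets in metres.
#' @param camera,view Default condition for single-walk simulation.
#' @param ankle_lift Peak ankle rise during a stride (m).
#' @param pixel_noise_sd Frame-to-frame tracker jitter SD in pixels at the
#'   camera standoff distance (scaled with the person's image size).
#' @param joint_bias_sd SD (px, at standoff scale) of the systematic
#'   per-recording localization bias drawn once per joint and stream,
#'   emulating subject/viewpoint-dependent tracker offsets that do not
#'   average out over steps.
#' @param noise_axes Axes the pixel noise and bias apply to (`"x"`, `"y"`
#'   or both).
#' @param dropout_prob Per joint-frame probability of a low-confidence
#'   dropout.
#' @param dropout_conf_max Upper bound of the confidence assigned to
#'   dropouts (must stay below every tracker threshold).
#' @param dropout_jump_sd Position error SD (px) added to dropped-out
#'   keypoints.
#' @param swap_prob Per-frame probability that one left/right lower-limb
#'   pair has its labels exchanged.
#' @param tracker Tracker label attached to degraded streams.
#' @param seed Mandatory integer seed.
#' @return List of class `gait_sim_config`.
#' @export
gait_sim_config <- function(n_subjects = 11,
                            cadence_mean = 106.44, cadence_sd = 8.5,
                            step_time_cv = 0.06,
                            step_width_mean = 0.09, step_width_sd = 0.03,
                            foot_jitter_sd = 0.027,
                            com_amplitude = 0.05, com_amplitude_sd = 0.012,
                            hip_width = 0.16,
                            subject_height = 1.636, subject_height_sd = 0.097,
                            leg_length = NA_real_,
                            step_length = 0.60,
                            n_steps_bout = c(12L, 14L),
                            bouts_front = 2L, bouts_back = 2L,
                            video_frame_rate = 30, reference_rate = 100,
                            focal_px = 1400,
                            image_width = 1920, image_height = 1080,
                            camera_standoff = 8,
                            camera_heights = c(eye_level = 1.11, top = 2.05),
                            camera = "eye_level", view = "front",
                            ankle_lift = 0.12,
                            pixel_noise_sd = 5,
                            joint_bias_sd = 2,
                            noise_axes = c("x", "y"),
                            dropout_prob = 0.02, dropout_conf_max = 0.10,
                            dropout_jump_sd = 15,
                            swap_prob = 0.01,
                            tracker = "synthetic",
                            seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(seed) || is.na(seed)) stop("a seed is mandatory")
  stopifnot(
    n_subjects >= 1, cadence_mean > 0, cadence_sd >= 0,
    step_time_cv >= 0, step_width_mean > 0, hip_width > 0,
    subject_height > 0, step_length > 0,
    video_frame_rate > 0, reference_rate > 0, focal_px > 0,
    camera_standoff > 0, ankle_lift > 0,
    dropout_prob >= 0, dropout_prob <= 1,
    swap_prob >= 0, swap_prob <= 1,
    pixel_noise_sd >= 0, joint_bias_sd >= 0,
    all(noise_axes %in% c("x", "y"))
  )
  if (60 / cadence_mean <= 2 / video_frame_rate)
    stop("implausible config: mean step time must exceed 2 video frame intervals")
  if (dropout_conf_max >= 0.15)
    stop("dropout_conf_max must stay below the lowest tracker threshold (0.15)")
  class(cfg) <- "gait_sim_config"
  cfg
}

# ---- world model -----------------------------------------------------------

# Draw strike times, foot placements and the sacrum spline for one bout.
# All RNG must already be seeded by the caller.
sim_world <- function(cfg, cadence = cfg$cadence_mean,
                      step_width = cfg$step_width_mean,
                      com_amplitude = cfg$com_amplitude,
                      height = cfg$subject_height,
                      n_steps = NULL) {
  tau <- 60 / cadence
  if (is.null(n_steps)) {
    rng <- range(cfg$n_steps_bout)
    n_steps <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1)
  }
  n_strikes <- n_steps + 1L
  lead_in <- 0.45
  intervals <- stats::rnorm(n_steps, tau, cfg$step_time_cv * tau)
  intervals <- pmax(intervals, max(0.30, 2.5 / cfg$video_frame_rate))
  t_strike <- lead_in + c(0, cumsum(intervals))
  first <- if (stats::runif(1) < 0.5) c("left", "right") else c("right", "left")
  feet <- rep(first, length.out = n_strikes)
  side <- ifelse(feet == "left", 1, -1)
  x_strike <- side * step_width / 2 + stats::rnorm(n_strikes, 0, cfg$foot_jitter_sd)
  t_end <- t_strike[n_strikes] + lead_in

  # per-foot continuous lateral position (stance hold, cosine-ease swing over
  # the last 40% of the stride) and vertical |sin| bump between own strikes
  foot_fun <- function(foot) {
    idx <- which(feet == foot)
    st <- t_strike[idx]; sx <- x_strike[idx]
    xf <- function(t) {
      out <- numeric(length(t))
      out[t <= st[1]] <- sx[1]
      out[t >= st[length(st)]] <- sx[length(sx)]
      if (length(st) > 1) for (i in seq_len(length(st) - 1)) {
        inb <- t > st[i] & t < st[i + 1]
        if (!any(inb)) next
        ph <- (t[inb] - st[i]) / (st[i + 1] - st[i])
        ease <- ifelse(ph < 0.6, 0,
                       (1 - cos(pi * (ph - 0.6) / 0.4)) / 2)
        out[inb] <- sx[i] + ease * (sx[i + 1] - sx[i])
      }
      out
    }
    # the bout is cut from ongoing walking: virtual strides before the first
    # and after the last own strike keep ankle height rising on both sides
    # of every real strike
    stride <- if (length(st) > 1) mean(diff(st)) else 1.1
    stz <- c(st[1] - stride, st, st[length(st)] + stride)
    zf <- function(t) {
      out <- numeric(length(t))
      for (i in seq_len(length(stz) - 1)) {
        inb <- t > stz[i] & t < stz[i + 1]
        if (!any(inb)) next
        ph <- (t[inb] - stz[i]) / (stz[i + 1] - stz[i])
        out[inb] <- cfg$ankle_lift * sin(pi * ph)
      }
      out
    }
    list(x = xf, z = zf)
  }
  lf <- foot_fun("left"); rf <- foot_fun("right")

  # sacrum: zero at strikes, +/- amplitude toward the stance foot mid-step
  mids <- (t_strike[-n_strikes] + t_strike[-1]) / 2
  mid_val <- side[-n_strikes] * com_amplitude
  kt <- c(0, t_strike, mids, t_end)
  kv <- c(0, rep(0, n_strikes), mid_val, 0)
  ord <- order(kt)
  com_fun <- stats::splinefun(kt[ord], kv[ord], method = "natural")

  list(t_strike = t_strike, feet = feet, x_strike = x_strike,
       t_end = t_end, left = lf, right = rf, com = com_fun,
       cadence = cadence, step_width = step_width, height = height,
       leg_length = if (is.na(cfg$leg_length)) 0.53 * height else cfg$leg_length)
}

# Ground-truth gait for a simulated world: strikes, per-step records (m),
# per-bout summary, and 100 Hz sacrum/foot series.
world_truth <- function(world, cfg) {
  n <- length(world$t_strike)
  strikes <- data.frame(
    foot = world$feet,
    frame = as.integer(round(world$t_strike * cfg$reference_rate)),
    time_s = world$t_strike,
    lateral = world$x_strike,
    vertical = 0,
    stringsAsFactors = FALSE
  )
  omega <- sqrt(9.81 / world$leg_length)
  recs <- vector("list", n - 1)
  for (k in 2:n) {
    tk <- world$t_strike[k]
    lead <- world$feet[k]
    bos <- world$x_strike[k]
    trail_x <- if (lead == "left") world$right$x(tk) else world$left$x(tk)
    com <- world$com(tk)
    v_com <- world$com(tk, deriv = 1)
    s <- sign(bos - com); if (s == 0) s <- 1
    recs[[k - 1]] <- data.frame(
      step_index = k - 1L,
      leading_foot = lead,
      step_time_s = tk - world$t_strike[k - 1],
      step_width = abs(bos - trail_x),
      strike_time_s = tk,
      strike_frame = as.integer(round(tk * cfg$reference_rate)),
      emos = (s * com + s * v_com / omega) - s * bos,
      stringsAsFactors = FALSE
    )
  }
  records <- do.call(rbind, recs)
  summary <- summarize_bout(records, strikes, method = "mean")
  tt <- seq(0, world$t_end, by = 1 / cfg$reference_rate)
  series <- data.frame(
    time_s = tt,
    sacrum_x = world$com(tt),
    left_foot_x = world$left$x(tt), right_foot_x = world$right$x(tt),
    left_foot_z = world$left$z(tt), right_foot_z = world$right$z(tt)
  )
  list(strikes = strikes, records = records, summary = summary,
       series = series, leg_length = world$leg_length)
}

# Project the fronto-parallel skeleton through a pinhole camera. The body
# plane sits at depth Z(t) = standoff + path - v t (front view, approaching)
# or standoff + v t (back view, receding); the top preset adds a constant
# vertical foreshortening for the downward camera tilt.
project_world <- function(world, cfg, camera, view, subject_id = "S01") {
  fs <- cfg$video_frame_rate
  nf <- floor(world$t_end * fs) + 1L
  t <- (seq_len(nf) - 1L) / fs
  v_walk <- cfg$step_length * world$cadence / 60
  path <- v_walk * world$t_end
  z_t <- if (view == "front") cfg$camera_standoff + path - v_walk * t
         else cfg$camera_standoff + v_walk * t
  s_t <- cfg$focal_px / z_t
  h_cam <- cfg$camera_heights[[camera]]
  hip_y <- 0.53 * world$height
  c_v <- if (camera == "top")
    cos(atan2(h_cam - hip_y, cfg$camera_standoff + path / 2)) else 1
  cx <- cfg$image_width / 2; cy <- cfg$image_height / 2

  com <- world$com(t)
  lx <- world$left$x(t); rx <- world$right$x(t)
  lz <- 0.08 + world$left$z(t); rz <- 0.08 + world$right$z(t)
  H <- world$height
  hw2 <- cfg$hip_width / 2
  # world lateral (X, +left) and vertical (Y, up) per joint
  WX <- cbind(
    nose = com, left_eye = com + 0.033, right_eye = com - 0.033,
    left_ear = com + 0.07, right_ear = com - 0.07,
    left_shoulder = com + 0.11 * H, right_shoulder = com - 0.11 * H,
    left_elbow = com + 0.13 * H, right_elbow = com - 0.13 * H,
    left_wrist = com + 0.14 * H, right_wrist = com - 0.14 * H,
    left_hip = com + hw2, right_hip = com - hw2,
    left_knee = (com + hw2 + lx) / 2, right_knee = (com - hw2 + rx) / 2,
    left_ankle = lx, right_ankle = rx
  )
  WY <- cbind(
    nose = rep(0.93 * H, nf), left_eye = rep(0.94 * H, nf),
    right_eye = rep(0.94 * H, nf), left_ear = rep(0.93 * H, nf),
    right_ear = rep(0.93 * H, nf),
    left_shoulder = rep(0.82 * H, nf), right_shoulder = rep(0.82 * H, nf),
    left_elbow = rep(0.63 * H, nf), right_elbow = rep(0.63 * H, nf),
    left_wrist = rep(0.45 * H, nf), right_wrist = rep(0.45 * H, nf),
    left_hip = rep(hip_y, nf), right_hip = rep(hip_y, nf),
    left_knee = rep(0.285 * H, nf), right_knee = rep(0.285 * H, nf),
    left_ankle = lz, right_ankle = rz
  )
  # back view: the camera sees the body mirrored left-right
  mirror <- if (view == "back") -1 else 1
  x <- cx + s_t * (mirror * WX)
  y <- cy + s_t * (h_cam - WY) * c_v
  x <- x[, COCO_JOINTS]; y <- y[, COCO_JOINTS]
  conf <- matrix(0.95, nf, 17)
  traj <- pose_trajectory(x, y, conf, fs, tracker = "synthetic",
                          camera = camera, view = view, subject_id = subject_id)
  # per-frame pixels-per-metre, used to make simulated tracker jitter
  # proportional to the person's image size
  attr(traj, "scale_px_per_m") <- s_t
  traj
}

#' Simulate one subject's walking bout
#'
#' Runs the kinematic walker and projects it through the configured camera:
#' returns the 100 Hz ground truth (strike times and feet, per-step records
#' in metres, per-bout summary, continuous sacrum/foot series) together with
#' a clean 30 fps keypoint trajectory in pixels. Deterministic under `seed`.
#'
#' @param config A [gait_sim_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return List with elements `truth`, `video` (a [pose_trajectory()]) and
#'   `annotation` (a one-row bout annotation frame).
#' @export
simulate_subject_walk <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "gait_sim_config"))
  with_seed(seed, {
    world <- sim_world(config)
    truth <- world_truth(world, config)
    video <- project_world(world, config, config$camera, config$view)
    nf <- n_frames(video)
    ann <- data.frame(subject_id = video$subject_id, camera = config$camera,
                      view = config$view, start_frame = 2L,
                      end_frame = nf - 3L, stringsAsFactors = FALSE)
    list(truth = truth, video = video, annotation = ann)
  })
}

#' Corrupt a clean keypoint trajectory with tracker-like failure modes
#'
#' Adds i.i.d. Gaussian pixel noise to the configured axes of every joint;
#' with probability `dropout_prob` per joint-frame replaces the confidence
#' with a draw below every tracker threshold (and perturbs the position, as
#' low-confidence predictions are typically also wrong); with probability
#' `swap_prob` per frame exchanges the left/right labels of one randomly
#' chosen lower-limb pair. Deterministic under `seed`; the applied swaps and
#' dropouts are recorded in the `swap_log` and `dropout_count` attributes.
#'
#' @param traj A clean [pose_trajectory()].
#' @param config A [gait_sim_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return The corrupted [pose_trajectory()], tracker label taken from
#'   `config$tracker`.
#' @export
degrade_trajectory <- function(traj, config, seed = config$seed) {
  stopifnot(inherits(traj, "pose_trajectory"), inherits(config, "gait_sim_config"))
  with_seed(seed, {
    n <- n_frames(traj)
    # keypoint localization error scales with the person's image size:
    # pixel_noise_sd and joint_bias_sd are SDs at the camera standoff
    # distance, scaled down as the subject recedes
    sc <- attr(traj, "scale_px_per_m")
    rel <- if (is.null(sc)) rep(1, n) else sc / (config$focal_px / config$camera_standoff)
    if (config$joint_bias_sd > 0) {
      bias_x <- stats::rnorm(17, 0, config$joint_bias_sd)
      bias_y <- stats::rnorm(17, 0, config$joint_bias_sd)
      if ("x" %in% config$noise_axes)
        traj$x <- traj$x + rel %o% bias_x
      if ("y" %in% config$noise_axes)
        traj$y <- traj$y + rel %o% bias_y
    }
    if (config$pixel_noise_sd > 0) {
      sd_t <- config$pixel_noise_sd * rel
      if ("x" %in% config$noise_axes)
        traj$x <- traj$x + matrix(stats::rnorm(n * 17, 0, sd_t), n, 17)
      if ("y" %in% config$noise_axes)
        traj$y <- traj$y + matrix(stats::rnorm(n * 17, 0, sd_t), n, 17)
    }
    dropout_count <- 0L
    if (config$dropout_prob > 0) {
      drop <- matrix(stats::runif(n * 17) < config$dropout_prob, n, 17)
      dropout_count <- sum(drop)
      if (dropout_count) {
        traj$conf[drop] <- stats::runif(dropout_count, 0, config$dropout_conf_max)
        traj$x[drop] <- traj$x[drop] + stats::rnorm(dropout_count, 0, config$dropout_jump_sd)
        traj$y[drop] <- traj$y[drop] + stats::rnorm(dropout_count, 0, config$dropout_jump_sd)
      }
    }
    swap_frames <- integer(0); swap_pairs <- character(0)
    if (config$swap_prob > 0) {
      hit <- which(stats::runif(n) < config$swap_prob)
      for (t in hit) {
        pn <- sample(names(LR_PAIRS), 1)
        pair <- LR_PAIRS[[pn]]
        for (m in c("x", "y", "conf")) {
          tmp <- traj[[m]][t, pair[1]]
          traj[[m]][t, pair[1]] <- traj[[m]][t, pair[2]]
          traj[[m]][t, pair[2]] <- tmp
        }
        swap_frames <- c(swap_frames, traj$frame[t])
        swap_pairs <- c(swap_pairs, pn)
      }
    }
    colnames(traj$x) <- colnames(traj$y) <- colnames(traj$conf) <- COCO_JOINTS
    if (config$tracker %in% VALID_TRACKERS) traj$tracker <- config$tracker
    attr(traj, "swap_log") <- data.frame(frame = swap_frames, joint_pair = swap_pairs,
                                         stringsAsFactors = FALSE)
    attr(traj, "dropout_count") <- dropout_count
    traj
  })
}

#' Simulate a full study cohort
#'
#' Draws per-subject gait parameters from the configured between-subject
#' distributions and, for every subject, view and bout, simulates one world
#' and observes it through both camera heights and every requested tracker
#' (each with its own corruption draw). Emits everything the downstream
#' pipeline needs: clean and degraded video trajectories, reference-role
#' ground truth, bout annotations and subject metadata.
#'
#' @param config A [gait_sim_config()].
#' @param n_subjects Number of subjects (defaults to `config$n_subjects`).
#' @param seed Integer seed (defaults to `config$seed`).
#' @param trackers Tracker labels to emit degraded streams for.
#' @param degrade Logical; `FALSE` keeps the clean projections (the tracker
#'   streams are then identical, useful for parameter-recovery checks).
#' @return List of class `gait_cohort`: `subjects` (nested per-subject
#'   bundles), `metadata` (subject data frame), `annotations` (bout
#'   annotation frame) and `config`.
#' @export
simulate_cohort <- function(config, n_subjects = config$n_subjects,
                            seed = config$seed,
                            trackers = c("alphapose", "openpose", "detectron"),
                            degrade = TRUE) {
  stopifnot(inherits(config, "gait_sim_config"))
  if (n_subjects < 1) stop("n_subjects must be at least 1")
  subjects <- list()
  meta_rows <- list()
  ann_rows <- list()
  sub_k <- 0
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", i)
    pars <- with_seed(derive_seed(seed, sub_k <- sub_k + 1), list(
      cadence = max(70, stats::rnorm(1, config$cadence_mean, config$cadence_sd)),
      step_width = max(0.05, stats::rnorm(1, config$step_width_mean, config$step_width_sd)),
      com_amplitude = max(0.015, stats::rnorm(1, config$com_amplitude, config$com_amplitude_sd)),
      height = max(1.3, stats::rnorm(1, config$subject_height, config$subject_height_sd))
    ))
    leg <- if (is.na(config$leg_length)) 0.53 * pars$height else config$leg_length
    meta_rows[[i]] <- data.frame(subject_id = sid, height_m = pars$height,
                                 leg_length_m = leg, cadence_true = pars$cadence,
                                 stringsAsFactors = FALSE)
    bouts <- list()
    for (view in c("front", "back")) {
      nb <- if (view == "front") config$bouts_front else config$bouts_back
      for (b in seq_len(nb)) {
        wseed <- derive_seed(seed, sub_k <- sub_k + 1)
        world <- with_seed(wseed, sim_world(
          config, cadence = pars$cadence, step_width = pars$step_width,
          com_amplitude = pars$com_amplitude, height = pars$height))
        truth <- world_truth(world, config)
        clean <- list()
        video <- list()
        for (cam in names(config$camera_heights)) {
          cl <- project_world(world, config, cam, view, subject_id = sid)
          clean[[cam]] <- cl
          for (tr in trackers) {
            dseed <- derive_seed(seed, sub_k <- sub_k + 1)
            cfg_tr <- config; cfg_tr$tracker <- tr
            video[[tr]][[cam]] <- if (degrade)
              degrade_trajectory(cl, cfg_tr, dseed)
            else { cl$tracker <- tr; cl }
          }
        }
        nf <- n_frames(clean[[1]])
        ann <- data.frame(subject_id = sid, view = view, bout_index = b,
                          start_frame = 2L, end_frame = nf - 3L,
                          stringsAsFactors = FALSE)
        ann_rows[[length(ann_rows) + 1L]] <- ann
        bouts[[length(bouts) + 1L]] <- list(
          view = view, bout_index = b, truth = truth, clean = clean,
          video = video, annotation = ann)
      }
    }
    subjects[[sid]] <- list(metadata = meta_rows[[i]], bouts = bouts)
  }
  structure(
    list(subjects = subjects, metadata = do.call(rbind, meta_rows),
         annotations = do.call(rbind, ann_rows), config = config,
         trackers = trackers),
    class = "gait_cohort"
  )
}

#' @export
print.gait_cohort <- function(x, ...) {
  nb <- sum(vapply(x$subjects, function(s) length(s$bouts), integer(1)))
  cat(sprintf("<gait_cohort> %d subjects, %d bouts, trackers: %s\n",
              length(x$subjects), nb, paste(x$trackers, collapse = ", ")))
  invisible(x)
}
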