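# Dialect readers, person selection, and the canonical interchange format.

# 17 keypoints laid out like a standing person, as an (x, y, conf) matrix.
person_kp <- function(cx = 500, scale = 1, conf = 0.9) {
  x <- cx + scale * c(0, 3, -3, 7, -7, 30, -30, 40, -40, 45, -45,
                      15, -15, 18, -18, 20, -20)
  y <- 200 + scale * c(0, -2, -2, 0, 0, 40, 40, 90, 90, 140, 140,
                       160, 160, 240, 240, 320, 320)
  cbind(x, y, rep(conf, 17))
}

flat_triplets <- function(kp) as.vector(t(kp))

write_openpose_dir <- function(dir, frames) {
  dir.create(dir, showWarnings = FALSE)
  for (i in seq_along(frames)) {
    people <- lapply(frames[[i]], function(kp)
      list(pose_keypoints_2d = flat_triplets(kp)))
    jsonlite::write_json(list(people = people),
                         file.path(dir, sprintf("frame_%04d.json", i - 1)),
                         auto_unbox = TRUE, digits = NA)
  }
  dir
}

test_that("openpose per-frame files map to one frame each with confidences copied", {
  kp <- person_kp()
  d <- write_openpose_dir(file.path(tempdir(), "op1"),
                          list(list(kp), list(kp), list(kp)))
  traj <- read_pose_run(d, "openpose")
  expect_s3_class(traj, "pose_trajectory")
  expect_equal(n_frames(traj), 3)
  expect_equal(unname(traj$x[2, ]), kp[, 1])
  expect_equal(unname(traj$y[2, ]), kp[, 2])
  expect_equal(unname(traj$conf[2, ]), kp[, 3])
  unlink(d, recursive = TRUE)
})

test_that("a frame with zero persons yields all-missing joints, length unchanged", {
  kp <- person_kp()
  d <- write_openpose_dir(file.path(tempdir(), "op2"),
                          list(list(kp), list(), list(kp)))
  traj <- read_pose_run(d, "openpose")
  expect_equal(n_frames(traj), 3)
  expect_true(all(is.na(traj$x[2, ])))
  expect_true(all(is.na(traj$conf[2, ])))
  expect_false(anyNA(traj$x[c(1, 3), ]))
  unlink(d, recursive = TRUE)
})

test_that("the taller of two detected persons is selected, deterministically", {
  big <- person_kp(cx = 700, scale = 2)
  small <- person_kp(cx = 300, scale = 1)
  d <- write_openpose_dir(file.path(tempdir(), "op3"),
                          list(list(small, big), list(big, small)))
  t1 <- read_pose_run(d, "openpose")
  t2 <- read_pose_run(d, "openpose")
  # both frames pick the 2x person regardless of listing order
  expect_equal(unname(t1$x[1, "nose"]), 700)
  expect_equal(unname(t1$x[2, "nose"]), 700)
  expect_identical(t1$x, t2$x)
  expect_equal(attr(t1, "person_selection"), c(2L, 1L))
  unlink(d, recursive = TRUE)
})

test_that("the three dialects encode the same keypoints to identical content", {
  kp1 <- person_kp(cx = 480); kp2 <- person_kp(cx = 492)
  d <- write_openpose_dir(file.path(tempdir(), "op4"), list(list(kp1), list(kp2)))
  op <- read_pose_run(d, "openpose")

  ap_file <- file.path(tempdir(), "ap.json")
  jsonlite::write_json(list(
    list(image_id = "0000.jpg", keypoints = flat_triplets(kp1), score = 2.5),
    list(image_id = "0001.jpg", keypoints = flat_triplets(kp2), score = 2.4)
  ), ap_file, auto_unbox = TRUE, digits = NA)
  ap <- read_pose_run(ap_file, "alphapose")

  dt_file <- file.path(tempdir(), "dt.json")
  jsonlite::write_json(list(
    list(frame = 0, instances = list(list(keypoints = apply(kp1, 1, as.list),
                                          score = 0.98))),
    list(frame = 1, instances = list(list(keypoints = apply(kp2, 1, as.list),
                                          score = 0.99)))
  ), dt_file, auto_unbox = TRUE, digits = NA)
  dt <- read_pose_run(dt_file, "detectron")

  for (m in c("x", "y", "conf")) {
    expect_identical(op[[m]], ap[[m]])
    expect_identical(op[[m]], dt[[m]])
  }
  unlink(c(ap_file, dt_file)); unlink(d, recursive = TRUE)
})

test_that("BODY-25 keypoint order is remapped onto the COCO-17 set", {
  kp <- person_kp()
  # build a BODY-25 array holding the same joints plus extras
  b25 <- matrix(0, 25, 3)
  b25_idx <- c(nose = 0, left_eye = 16, right_eye = 15, left_ear = 18,
               right_ear = 17, left_shoulder = 5, right_shoulder = 2,
               left_elbow = 6, right_elbow = 3, left_wrist = 7,
               right_wrist = 4, left_hip = 12, right_hip = 9,
               left_knee = 13, right_knee = 10, left_ankle = 14,
               right_ankle = 11)
  for (j in seq_along(COCO_JOINTS)) b25[b25_idx[[COCO_JOINTS[j]]] + 1, ] <- kp[j, ]
  b25[2, ] <- c(999, 999, 0.9)   # neck: must be dropped
  d <- file.path(tempdir(), "op25"); dir.create(d, showWarnings = FALSE)
  jsonlite::write_json(list(people = list(list(pose_keypoints_2d = as.vector(t(b25))))),
                       file.path(d, "f0.json"), auto_unbox = TRUE, digits = NA)
  traj <- read_pose_run(d, "openpose", keypoint_order = "body25")
  expect_equal(unname(traj$x[1, ]), kp[, 1])
  expect_equal(unname(traj$y[1, ]), kp[, 2])
  unlink(d, recursive = TRUE)
})

test_that("canonical round-trip is exact and preserves missingness and metadata", {
  set.seed(11)
  n <- 10
  x <- matrix(stats::runif(n * 17, 0, 1920), n, 17)
  y <- matrix(stats::runif(n * 17, 0, 1080), n, 17)
  conf <- matrix(stats::runif(n * 17), n, 17)
  x[3, 5] <- y[3, 5] <- conf[3, 5] <- NA
  traj <- pose_trajectory(x, y, conf, 30, tracker = "alphapose",
                          camera = "top", view = "back", subject_id = "S07")
  p <- file.path(tempdir(), "canon.csv")
  write_canonical(traj, p)
  back <- read_pose_run(p, "canonical")
  expect_identical(back$x, traj$x)
  expect_identical(back$y, traj$y)
  expect_identical(back$conf, traj$conf)
  expect_identical(back$frame, traj$frame)
  expect_equal(back$frame_rate, 30)
  expect_equal(back$tracker, "alphapose")
  expect_equal(back$camera, "top")
  expect_equal(back$view, "back")
  expect_equal(back$subject_id, "S07")
  unlink(c(p, gaitpose:::sidecar_path(p)))
})

test_that("unknown dialect and missing path raise configuration errors", {
  expect_error(read_pose_run(tempdir(), "kinect"), "unknown dialect")
  expect_error(read_pose_run(file.path(tempdir(), "nope.json"), "alphapose"),
               "does not exist")
})
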