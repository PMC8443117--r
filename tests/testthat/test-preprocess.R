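# Masking/interpolation, the 10% rule, swap correction, zero-phase
# smoothing, and bout extraction.

test_that("tracker-specific confidence thresholds match the published values", {
  expect_equal(default_threshold("openpose"), 0.3)
  expect_equal(default_threshold("alphapose"), 0.5)
  expect_equal(default_threshold("detectron"), 0.15)
  expect_error(default_threshold("reference"), "no default confidence threshold")
})

test_that("low-confidence observations are linearly interpolated, edges held", {
  tr <- make_traj(n = 4, overrides = list(
    left_ankle = list(x = c(1, 99, 3, 4), conf = c(0.9, 0.1, 0.9, 0.9)),
    right_ankle = list(x = c(99, 5, 5, 99), conf = c(0.1, 0.9, 0.9, 0.1))
  ))
  out <- mask_and_interpolate(tr, 0.5)
  expect_equal(unname(out$trajectory$x[, "left_ankle"]), c(1, 2, 3, 4))
  expect_equal(unname(out$trajectory$x[, "right_ankle"]), c(5, 5, 5, 5))
  # confident observations unchanged anywhere
  keep <- tr$conf >= 0.5
  expect_identical(out$trajectory$x[keep], tr$x[keep])
  expect_equal(unname(out$report$missing_fraction[["left_ankle"]]), 0.25)
  expect_equal(out$report$interpolated_frame_count, 3L)
})

test_that("missing fractions feed the strict <10% screening rule", {
  conf <- rep(0.9, 100); conf[sample.int(100, 7)] <- 0.05
  tr <- make_traj(n = 100, overrides = list(left_ankle = list(conf = conf)))
  rep1 <- mask_and_interpolate(tr, 0.3)$report
  expect_equal(unname(rep1$missing_fraction[["left_ankle"]]), 0.07)
  pass <- check_missing_rule(rep1)
  expect_true(pass[["left_ankle"]])
  # exactly 10% fails: the boundary counts as failing
  conf2 <- rep(0.9, 100); conf2[1:10] <- 0.05
  tr2 <- make_traj(n = 100, overrides = list(left_ankle = list(conf = conf2)))
  pass2 <- check_missing_rule(mask_and_interpolate(tr2, 0.3)$report)
  expect_false(pass2[["left_ankle"]])
  expect_true(all(pass2[setdiff(COCO_JOINTS, "left_ankle")]))
})

test_that("a joint with no confident observation is an unrecoverable error", {
  tr <- make_traj(n = 20, overrides = list(nose = list(conf = rep(0.01, 20))))
  expect_error(mask_and_interpolate(tr, 0.3), "nose")
})

test_that("an exchanged interior frame is restored; clean tracks untouched", {
  n <- 40
  lx <- rep(260, n); rx <- rep(200, n)
  tr <- make_traj(n = n, overrides = list(
    left_ankle = list(x = lx, y = rep(400, n)),
    right_ankle = list(x = rx, y = rep(400, n))
  ))
  swapped <- tr
  for (m in c("x", "y")) {
    tmp <- swapped[[m]][20, "left_ankle"]
    swapped[[m]][20, "left_ankle"] <- swapped[[m]][20, "right_ankle"]
    swapped[[m]][20, "right_ankle"] <- tmp
  }
  fixed <- correct_lr_swaps(swapped)
  expect_equal(fixed$report$swap_correction_count, 1L)
  expect_identical(fixed$trajectory$x, tr$x)
  # no swaps: identity with count zero
  clean <- correct_lr_swaps(tr)
  expect_equal(clean$report$swap_correction_count, 0L)
  expect_identical(clean$trajectory$x, tr$x)
  # idempotent on its own output
  again <- correct_lr_swaps(fixed$trajectory)
  expect_equal(again$report$swap_correction_count, 0L)
})

test_that("a genuine smooth crossing of the ankle tracks is not exchanged", {
  n <- 60
  lx <- seq(260, 140, length.out = n)   # left ankle sweeps across right
  rx <- seq(140, 260, length.out = n)
  tr <- make_traj(n = n, overrides = list(
    left_ankle = list(x = lx, y = rep(400, n)),
    right_ankle = list(x = rx, y = rep(400, n))
  ))
  out <- correct_lr_swaps(tr)
  expect_equal(out$report$swap_correction_count, 0L)
  expect_identical(out$trajectory$x, tr$x)
})

test_that("manual overrides exchange the requested pairs after the auto pass", {
  tr <- make_traj(n = 10)
  ov <- data.frame(frame = 4L, joint_pair = "ankle", stringsAsFactors = FALSE)
  out <- correct_lr_swaps(tr, overrides = ov)
  expect_equal(unname(out$trajectory$x[5, "left_ankle"]),
               unname(tr$x[5, "right_ankle"]))
  expect_equal(unname(out$trajectory$x[5, "right_ankle"]),
               unname(tr$x[5, "left_ankle"]))
})

test_that("zero-phase smoothing passes constants and low frequencies unchanged", {
  t <- (0:599) / 30
  expect_equal(zero_phase_filter(rep(3.7, 60), 30, 8, 2), rep(3.7, 60),
               tolerance = 1e-10)
  x <- sin(2 * pi * 1 * t)
  y <- zero_phase_filter(x, 30, 8, 2)
  cc <- stats::ccf(y, x, lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  interior <- 31:570
  expect_lt(abs(max(abs(y[interior])) / max(abs(x[interior])) - 1), 0.01)
})

test_that("frequencies well above cutoff are strongly attenuated", {
  t <- (0:599) / 30
  x <- sin(2 * pi * 14 * t)
  y <- zero_phase_filter(x, 30, 8, 2)
  expect_lt(max(abs(y[31:570])), 0.10)
})

test_that("smoothing guards its preconditions", {
  expect_error(zero_phase_filter(rnorm(100), 30, cutoff = 15), "Nyquist")
  expect_error(zero_phase_filter(rnorm(8), 30, 8, 2), "too short")
  tr <- make_traj(n = 5)
  expect_error(smooth_trajectory(tr), "too short")
})

test_that("smoothing a trajectory leaves confidences untouched", {
  tr <- make_traj(n = 60, overrides = list(
    left_ankle = list(y = 400 + sin((0:59) / 3))
  ))
  sm <- smooth_trajectory(tr)
  expect_identical(sm$conf, tr$conf)
  expect_equal(n_frames(sm), 60)
})

test_that("bout extraction slices inclusively and validates annotations", {
  tr <- make_traj(n = 1800)
  ann <- data.frame(subject_id = "S01", camera = "eye_level",
                    view = c("front", "back"),
                    start_frame = c(100L, 700L), end_frame = c(500L, 1100L),
                    stringsAsFactors = FALSE)
  bouts <- extract_bouts(tr, ann)
  expect_length(bouts, 2)
  expect_equal(n_frames(bouts[[1]]$trajectory), 401)
  expect_equal(n_frames(bouts[[2]]$trajectory), 401)
  expect_equal(bouts[[2]]$trajectory$view, "back")
  expect_length(extract_bouts(tr, ann[0, ]), 0)
  bad <- ann; bad$end_frame[2] <- 2000L
  expect_error(extract_bouts(tr, bad), "outside")
  ovl <- ann; ovl$start_frame[2] <- 400L
  expect_error(extract_bouts(tr, ovl), "overlap")
})
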