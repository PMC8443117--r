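# Cadence, step time, step width, CV and eMOS arithmetic.

test_that("cadence follows 60*(n-1)/span", {
  ev <- events_df(rep(c("left", "right"), length.out = 11), seq(0, 6, length.out = 11))
  expect_equal(compute_cadence(ev), 100)
  ev2 <- events_df(c("left", "right"), c(1, 1.57))
  expect_equal(compute_cadence(ev2), 60 / 0.57)
  expect_error(compute_cadence(events_df("left", 1)), "fewer than 2")
})

test_that("CV is sample SD over mean, with guards", {
  expect_equal(coefficient_of_variation(c(2, 2, 2)), 0)
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 0.5)
  expect_error(coefficient_of_variation(c(1, -1)), "zero mean")
  expect_error(coefficient_of_variation(3), "at least 2")
})

test_that("eMOS equals the closed form and degenerates correctly", {
  expect_equal(compute_emos(com = 0.3, v_com = 0, bos = 0.3, leg_length = 1), 0)
  expect_equal(compute_emos(0.10, 0.20, 0, 1.0), 0.10 + 0.20 / sqrt(9.81))
  for (l in c(0.4, 0.87, 1.3)) {
    expect_equal(compute_emos(0.25, 0, 0.1, l), 0.15)
  }
  expect_error(compute_emos(0, 0, 0, -1), "positive")
})

test_that("step records compute times and hip-width-normalized widths", {
  n <- 70
  tr <- make_traj(n = n, overrides = list(
    left_ankle = list(x = rep(300, n)),
    right_ankle = list(x = rep(360, n))
  ))   # hips at 260/140: hip width 120 px
  bout <- as_bout(tr)
  ev <- interleave_steps(events_df("left", c(0.9, 2.1)), events_df("right", 1.5))
  rec <- compute_step_records(bout, ev)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$step_time_s, c(0.6, 0.6))
  expect_equal(rec$step_width, c(0.5, 0.5))
  expect_equal(rec$leading_foot, c("right", "left"))
})

test_that("reference-source step widths stay in metres", {
  n <- 70
  tr <- make_traj(n = n, tracker = "reference", overrides = list(
    left_ankle = list(x = rep(0.02, n)),
    right_ankle = list(x = rep(0.12, n))
  ))
  rec <- compute_step_records(as_bout(tr),
                              interleave_steps(events_df("left", c(0.9, 2.1)),
                                               events_df("right", 1.5)))
  expect_equal(rec$step_width, c(0.10, 0.10))
})

test_that("flagged same-foot gaps are omitted from step records", {
  bout <- as_bout(make_traj(n = 120))
  ev <- interleave_steps(events_df("left", c(0.9, 2.1, 3.3)),
                         events_df("right", 1.5))
  rec <- compute_step_records(bout, ev)
  expect_equal(nrow(rec), 2)   # the left->left gap step is dropped
})

test_that("per-step eMOS matches an independent evaluation on the series", {
  n <- 90
  t <- (0:(n - 1)) / 30
  com_px <- 200 + 30 * sin(2 * pi * t / 1.14)
  tr <- make_traj(n = n, overrides = list(
    left_hip = list(x = com_px + 60, y = rep(300, n)),
    right_hip = list(x = com_px - 60, y = rep(300, n)),
    left_ankle = list(x = rep(280, n)),
    right_ankle = list(x = rep(120, n))
  ))
  bout <- as_bout(tr, leg_length_m = 0.9)
  ev <- interleave_steps(events_df("left", c(0.9, 2.04)), events_df("right", 1.47))
  rec <- emos_per_step(bout, compute_step_records(bout, ev))
  # independent route: central differences and the closed form, by hand
  omega <- sqrt(9.81 / 0.9)
  v <- c(diff(com_px)[1], (com_px[3:n] - com_px[1:(n - 2)]) / 2, rev(diff(com_px))[1]) * 30
  hw <- 120
  for (i in seq_len(nrow(rec))) {
    fi <- rec$strike_frame[i] + 1L
    bos <- if (rec$leading_foot[i] == "left") 280 else 120
    s <- sign(bos - com_px[fi])
    manual <- (s * com_px[fi] + s * v[fi] / omega - s * bos) / hw
    expect_equal(rec$emos[i], manual, tolerance = 1e-12)
  }
})

test_that("uniform pixel scaling leaves normalized width and eMOS unchanged", {
  cfg <- gait_sim_config(seed = 21)
  sw <- simulate_subject_walk(cfg)
  bout <- as_bout(smooth_trajectory(sw$video), height_m = 1.636)
  ev <- interleave_steps(detect_foot_strikes(bout, "left"),
                         detect_foot_strikes(bout, "right"))
  rec1 <- emos_per_step(bout, compute_step_records(bout, ev))
  for (k in c(0.5, 3.7)) {
    tr2 <- bout$trajectory
    tr2$x <- tr2$x * k; tr2$y <- tr2$y * k
    bout2 <- bout; bout2$trajectory <- tr2
    rec2 <- emos_per_step(bout2, compute_step_records(bout2, ev))
    expect_equal(rec2$step_width, rec1$step_width, tolerance = 1e-10)
    expect_equal(rec2$emos, rec1$emos, tolerance = 1e-10)
  }
})

test_that("bout summaries aggregate records and stay self-consistent", {
  rec <- data.frame(step_index = 1:10, leading_foot = rep(c("l", "r"), 5),
                    step_time_s = rep(0.57, 10), step_width = rep(0.6, 10),
                    strike_time_s = cumsum(rep(0.57, 10)),
                    strike_frame = 1:10, emos = rep(0.2, 10))
  ev <- events_df(rep(c("left", "right"), length.out = 11),
                  seq(0, by = 0.57, length.out = 11))
  s <- summarize_bout(rec, ev, "mean")
  expect_equal(s$mean_step_time, 0.57)
  expect_equal(s$cv_step_time, 0)
  expect_equal(s$n_steps, 10L)
  expect_lt(abs(s$cadence - 60 / s$mean_step_time) / s$cadence, 0.05)

  rec3 <- rec[1:3, ]; rec3$step_time_s <- c(0.5, 0.6, 0.7)
  s3 <- summarize_bout(rec3, ev[1:4, ], "mean")
  expect_equal(s3$mean_step_time, 0.6)
  expect_equal(s3$cv_step_time, 0.1 / 0.6)

  ind <- summarize_bout(rec, ev, "individual")
  expect_equal(nrow(ind), 10)
  expect_warning(summarize_bout(rec[0, ], ev, "mean"), "no usable steps")
})
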