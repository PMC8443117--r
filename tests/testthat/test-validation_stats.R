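# Pearson correlations, Bland-Altman agreement, precision table, condition
# grid, and the study bookkeeping arithmetic.

# Independent brute-force oracle for Pearson's r and its two-sided p.
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- 0; dx2 <- 0; dy2 <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mean(x)) * (y[i] - mean(y))
    dx2 <- dx2 + (x[i] - mean(x))^2
    dy2 <- dy2 + (y[i] - mean(y))^2
  }
  r <- num / sqrt(dx2 * dy2)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), df = n - 2))
}

test_that("pearson_correlation matches the direct formula on random inputs", {
  set.seed(42)
  for (k in 1:200) {
    n <- sample(3:40, 1)
    x <- stats::rnorm(n); y <- 0.5 * x + stats::rnorm(n)
    got <- pearson_correlation(x, y)
    want <- pearson_oracle(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
    expect_equal(got$n, n)
  }
})

test_that("perfect linear relations give |r| = 1 with tiny p", {
  x <- c(1, 2, 4, 7, 11)
  up <- pearson_correlation(x, 2 * x + 1)
  expect_equal(up$r, 1, tolerance = 1e-12)
  expect_lt(up$p, 0.001)
  down <- pearson_correlation(x, -x)
  expect_equal(down$r, -1, tolerance = 1e-12)
  fixed <- pearson_correlation(c(1, 2, 3, 4), c(2, 4, 5, 9))
  want <- pearson_oracle(c(1, 2, 3, 4), c(2, 4, 5, 9))
  expect_equal(fixed$r, want$r, tolerance = 1e-12)
})

test_that("degenerate correlation inputs raise errors", {
  expect_error(pearson_correlation(1:5, 1:4), "paired")
  expect_error(pearson_correlation(c(1, 2), c(3, 4)), "at least 3")
  expect_error(pearson_correlation(rep(1, 5), 1:5), "zero variance")
})

test_that("Bland-Altman limits follow mean +/- 1.96 sample SD", {
  same <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$mean_difference, 0)
  expect_equal(c(same$loa_low, same$loa_high), c(0, 0))
  ba <- bland_altman(c(1, 2, 3), c(2, 2, 2))
  expect_equal(ba$mean_difference, 0)
  expect_equal(ba$sd_difference, 1)
  expect_equal(ba$loa_low, -1.96)
  expect_equal(ba$loa_high, 1.96)
  expect_equal(ba$data$mean, c(1.5, 2, 2.5))
  expect_error(bland_altman(1:3, 1:4), "paired")
})

test_that("precision table reports per-subject CV of per-bout values", {
  summaries <- data.frame(
    subject_id = "S01", tracker = "alphapose", camera = "top", view = "front",
    bout_index = 1:3, cadence = c(100, 100, 100),
    mean_step_time = c(0.6, 0.6, 0.6),
    mean_step_width = c(0.25, 0.30, 0.35), mean_emos = c(0.2, 0.2, 0.2),
    stringsAsFactors = FALSE
  )
  pt <- precision_table(summaries)
  w <- pt[pt$variable == "mean_step_width", ]
  expect_equal(w$cv_mean, 0.05 / 0.30, tolerance = 1e-12)
  expect_equal(pt$cv_mean[pt$variable == "cadence"], 0)
  # a single bout per subject -> unavailable
  pt1 <- precision_table(summaries[1, ])
  expect_true(all(pt1$n_subjects == 0))
  expect_true(all(is.na(pt1$cv_mean)))
})

# Build video tables as exact copies of the reference across all conditions.
self_paired_tables <- function(n_sub = 4, n_bout = 2, steps_per_bout = 6) {
  set.seed(9)
  rs <- expand.grid(subject_id = sprintf("S%02d", 1:n_sub),
                    view = c("front", "back"), bout_index = 1:n_bout,
                    step_index = 1:steps_per_bout, stringsAsFactors = FALSE)
  rs$step_time_s <- 0.5 + 0.02 * as.integer(factor(rs$subject_id)) +
    stats::runif(nrow(rs), 0, 0.02)
  rs$step_width <- 0.1 + 0.01 * as.integer(factor(rs$subject_id)) +
    stats::runif(nrow(rs), 0, 0.01)
  rs$emos <- 0.04 + stats::runif(nrow(rs), 0, 0.01)
  rb <- expand.grid(subject_id = sprintf("S%02d", 1:n_sub),
                    view = c("front", "back"), bout_index = 1:n_bout,
                    stringsAsFactors = FALSE)
  rb$cadence <- 100 + 2 * as.integer(factor(rb$subject_id)) + stats::runif(nrow(rb))
  rb$mean_step_time <- 60 / rb$cadence
  rb$cv_step_time <- stats::runif(nrow(rb), 0.02, 0.1)
  rb$mean_step_width <- 0.1 + 0.01 * as.integer(factor(rb$subject_id))
  rb$cv_step_width <- stats::runif(nrow(rb), 0.2, 0.5)
  rb$mean_emos <- stats::runif(nrow(rb), 0.02, 0.06)
  conds <- expand.grid(tracker = c("alphapose", "openpose", "detectron"),
                       camera = c("eye_level", "top"), stringsAsFactors = FALSE)
  vs <- do.call(rbind, lapply(seq_len(nrow(conds)), function(i)
    cbind(conds[i, ], rs, row.names = NULL)))
  vb <- do.call(rbind, lapply(seq_len(nrow(conds)), function(i)
    cbind(conds[i, ], rb, row.names = NULL)))
  list(video_steps = vs, video_summaries = vb, ref_steps = rs, ref_summaries = rb)
}

test_that("the fully populated grid has exactly 24 cells, r = 1 on self-pairs", {
  tb <- self_paired_tables()
  grid <- build_condition_grid(tb$video_steps, tb$video_summaries,
                               tb$ref_steps, tb$ref_summaries)
  expect_equal(grid$n_cells, 24L)
  expect_equal(nrow(grid$table), 24 * 6)
  expect_true(all(abs(grid$table$r - 1) < 1e-10))
})

test_that("missing conditions yield unavailable cells, not errors", {
  tb <- self_paired_tables()
  vs <- tb$video_steps[tb$video_steps$camera == "eye_level", ]
  vb <- tb$video_summaries[tb$video_summaries$camera == "eye_level", ]
  grid <- build_condition_grid(vs, vb, tb$ref_steps, tb$ref_summaries)
  expect_equal(grid$n_cells, 12L)
})

test_that("tracker-pair Bland-Altman covers spatial variables by default", {
  tb <- self_paired_tables()
  ba <- bland_altman_pairs(tb$video_steps)
  expect_setequal(unique(ba$variable), c("step_width", "emos"))
  # identical trackers: zero differences everywhere
  expect_true(all(abs(ba$mean_difference) < 1e-12))
  expect_equal(nrow(ba), 3 * 2 * 2 * 2)   # pairs x cameras x views x variables
})

test_that("step bookkeeping reproduces the per-participant arithmetic", {
  front <- study_step_bookkeeping(354, 11, 2.3)
  expect_identical(front$steps_per_participant, 32.2)
  expect_identical(front$steps_per_bout, 14)
  back <- study_step_bookkeeping(244, 11, 1.8)
  expect_identical(back$steps_per_participant, 22.2)
  expect_identical(back$steps_per_bout, 12.3)
})
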