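# Orchestration: preprocessing -> events -> metrics for every bout of a
# cohort, then the validation statistics; plus file-based command wrappers
# (simulate / extract / validate) used by the command-line script.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pipeline configuration
#'
#' Processing parameters for the extraction and validation stages. The
#' effective configuration of a run is written next to its outputs by the
#' `cmd_*` wrappers, so every run is reproducible from its output directory.
#'
#' @param thresholds Named list of per-tracker confidence thresholds;
#'   trackers not listed fall back to [default_threshold()] (clean
#'   `synthetic`/`reference` streams use 0).
#' @param cutoff_hz,filter_order Butterworth smoothing parameters.
#' @param missing_limit Missing-fraction limit of the screening rule.
#' @param swap_margin_fraction Swap margin for [correct_lr_swaps()].
#' @param min_stride_interval,prominence_frac Foot-strike detection
#'   parameters (see [detect_foot_strikes()]).
#' @param align_window Matching window (s) for [align_step_sequences()].
#' @param swap_flag_frac Flag a stream as unreliable when the automatic
#'   left/right correction fires on more than this fraction of frames:
#'   pervasive exchanges signal a label flip the displacement rule cannot
#'   resolve (e.g. laterally coincident feet), so the stream needs manual
#'   review instead of silent correction.
#' @param max_step_loss Flag a stream when it yields at least this many
#'   fewer usable steps than the reference sequence: the step sequences of
#'   the two systems are compared bout by bout, and a stream that cannot
#'   reproduce the reference sequence needs review.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(thresholds = list(),
                            cutoff_hz = 8, filter_order = 2,
                            missing_limit = 0.10,
                            swap_margin_fraction = 0.25,
                            min_stride_interval = 0.6,
                            prominence_frac = 0.10,
                            align_window = 0.25,
                            swap_flag_frac = 0.04,
                            max_step_loss = 3L) {
  cfg <- as.list(environment())
  stopifnot(cutoff_hz > 0, filter_order >= 1, missing_limit > 0,
            missing_limit <= 1, swap_margin_fraction >= 0,
            min_stride_interval > 0, align_window > 0,
            swap_flag_frac > 0, max_step_loss >= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

tracker_threshold <- function(config, tracker) {
  thr <- config$thresholds[[tracker]]
  if (!is.null(thr)) return(thr)
  if (tracker %in% c("openpose", "alphapose", "detectron"))
    default_threshold(tracker)
  else 0
}

# Lower-limb joints the gait variables actually rely on; the screening rule
# flags a bout when any of these exceeds the missing limit.
GAIT_JOINTS <- c("left_hip", "right_hip", "left_knee", "right_knee",
                 "left_ankle", "right_ankle")

# Preprocess one degraded trajectory and measure one bout against its truth.
process_bout_stream <- function(traj, annotation, truth, meta, config) {
  thr <- tracker_threshold(config, traj$tracker)
  mi <- mask_and_interpolate(traj, thr)
  sw <- correct_lr_swaps(mi$trajectory, config$swap_margin_fraction)
  sm <- smooth_trajectory(sw$trajectory, config$cutoff_hz, config$filter_order)
  wb <- extract_bouts(sm, annotation, height_m = meta$height_m,
                      leg_length_m = meta$leg_length_m)[[1]]
  ev_l <- detect_foot_strikes(wb, "left", config$min_stride_interval,
                              config$prominence_frac)
  ev_r <- detect_foot_strikes(wb, "right", config$min_stride_interval,
                              config$prominence_frac)
  ev <- interleave_steps(ev_l, ev_r)
  ref_ev <- truth$strikes
  ref_ev$strike_idx <- seq_len(nrow(ref_ev))
  al <- align_step_sequences(ev, ref_ev, offset = 0, window = config$align_window)
  ev_v <- al$video
  nv <- nrow(ev_v)
  # a step is unusable when a contralateral strike was missed on either side
  ev_v$gap_before <- c(FALSE, ev_v$foot[-1] == ev_v$foot[-nv]) |
    c(FALSE, diff(al$reference$strike_idx) != 1L)
  records <- compute_step_records(wb, ev_v)
  records <- emos_per_step(wb, records)
  # share the truth's step indexing so all trackers pair on the same steps
  pos <- match(records$strike_time_s, ev_v$time_s)
  records$step_index <- al$reference$strike_idx[pos] - 1L
  summary <- summarize_bout(records, ev_v, method = "mean")
  pass <- check_missing_rule(mi$report, config$missing_limit)
  n_fr <- n_frames(traj)
  swap_rate <- sw$report$swap_correction_count / n_fr
  step_loss <- (nrow(truth$strikes) - 1L) - nrow(records)
  list(records = records, summary = summary,
       flagged = !all(pass[GAIT_JOINTS]) ||
         swap_rate > config$swap_flag_frac ||
         step_loss >= config$max_step_loss,
       quality = mi$report, swaps = sw$report$swap_correction_count)
}

#' Run the extraction stage over a simulated cohort
#'
#' For every subject, bout, camera and tracker: masks and interpolates
#' low-confidence keypoints, corrects left/right swaps, smooths, crops to
#' the annotated bout, detects foot strikes, aligns the step sequence with
#' the reference stream, and computes per-step records and per-bout
#' summaries. Reference per-step and per-bout tables come from the cohort's
#' ground truth (the reference system provides its own step detection).
#'
#' @param cohort A `gait_cohort` from [simulate_cohort()].
#' @param config A [pipeline_config()].
#' @param include_flagged Keep bouts failing the missing-data screening rule
#'   in the summary tables (default `FALSE`: flagged bouts are excluded but
#'   reported).
#' @return List with `video_steps`, `video_summaries`, `ref_steps`,
#'   `ref_summaries` (data frames) and `quality` (per-stream screening
#'   results).
#' @export
run_extraction <- function(cohort, config = pipeline_config(),
                           include_flagged = FALSE) {
  stopifnot(inherits(cohort, "gait_cohort"))
  vs <- list(); vb <- list(); rs <- list(); rb <- list(); ql <- list()
  for (sid in names(cohort$subjects)) {
    sub <- cohort$subjects[[sid]]
    for (bout in sub$bouts) {
      key <- data.frame(subject_id = sid, view = bout$view,
                        bout_index = bout$bout_index, stringsAsFactors = FALSE)
      rs[[length(rs) + 1L]] <- cbind(key, bout$truth$records)
      rb[[length(rb) + 1L]] <- cbind(key, bout$truth$summary)
      for (tr in names(bout$video)) for (cam in names(bout$video[[tr]])) {
        res <- tryCatch(
          process_bout_stream(bout$video[[tr]][[cam]], bout$annotation,
                              bout$truth, sub$metadata, config),
          error = function(e) e
        )
        kk <- cbind(key, data.frame(tracker = tr, camera = cam,
                                    stringsAsFactors = FALSE))
        if (inherits(res, "error")) {
          ql[[length(ql) + 1L]] <- cbind(kk, data.frame(
            flagged = TRUE, n_steps = 0L, swaps = NA_integer_,
            error = conditionMessage(res), stringsAsFactors = FALSE))
          next
        }
        ql[[length(ql) + 1L]] <- cbind(kk, data.frame(
          flagged = res$flagged, n_steps = nrow(res$records),
          swaps = res$swaps, error = NA_character_, stringsAsFactors = FALSE))
        if (res$flagged && !include_flagged) next
        if (nrow(res$records))
          vs[[length(vs) + 1L]] <- cbind(kk, res$records)
        vb[[length(vb) + 1L]] <- cbind(kk, res$summary)
      }
    }
  }
  list(video_steps = do.call(rbind, vs),
       video_summaries = do.call(rbind, vb),
       ref_steps = do.call(rbind, rs),
       ref_summaries = do.call(rbind, rb),
       quality = do.call(rbind, ql))
}

#' Run the validation stage
#'
#' Builds the full tracker x camera x view x method correlation grid, the
#' precision (CV) table, and the pairwise Bland-Altman agreement between
#' trackers on spatial variables.
#'
#' @param extraction Output of [run_extraction()].
#' @return List with `grid` (a `condition_grid`), `precision` and
#'   `bland_altman` data frames.
#' @export
run_validation <- function(extraction) {
  grid <- build_condition_grid(extraction$video_steps,
                               extraction$video_summaries,
                               extraction$ref_steps,
                               extraction$ref_summaries)
  list(grid = grid,
       precision = precision_table(extraction$video_summaries),
       bland_altman = bland_altman_pairs(extraction$video_steps))
}

#' Simulate, extract and validate in one call
#'
#' Convenience wrapper: [simulate_cohort()] then [run_extraction()] then
#' [run_validation()], fully deterministic under `seed`.
#'
#' @param sim_config A [gait_sim_config()].
#' @param pipe_config A [pipeline_config()].
#' @param seed Integer seed (defaults to `sim_config$seed`).
#' @param ... Passed to [simulate_cohort()].
#' @return List with `cohort`, `extraction`, `validation`.
#' @export
run_study <- function(sim_config = gait_sim_config(),
                      pipe_config = pipeline_config(),
                      seed = sim_config$seed, ...) {
  cohort <- simulate_cohort(sim_config, seed = seed, ...)
  extraction <- run_extraction(cohort, pipe_config)
  list(cohort = cohort, extraction = extraction,
       validation = run_validation(extraction))
}

# ---- file-based command wrappers -------------------------------------------

write_df <- function(df, dir, name) {
  utils::write.csv(df, file.path(dir, name), row.names = FALSE)
}

#' Write a synthetic study bundle to disk
#'
#' Simulates a cohort and writes it as plain-text files: canonical
#' trajectory CSVs for every stream, a `manifest.csv` naming them, bout
#' annotations, subject metadata, ground-truth strike and step logs, and the
#' effective simulation config (`sim_config.yml`). Reruns with the same
#' config and seed are byte-identical.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [gait_sim_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @param ... Passed to [simulate_cohort()].
#' @return Invisibly, the simulated cohort.
#' @export
cmd_simulate <- function(out_dir, config = gait_sim_config(),
                         seed = config$seed, ...) {
  cohort <- simulate_cohort(config, seed = seed, ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  traj_dir <- file.path(out_dir, "trajectories")
  dir.create(traj_dir, showWarnings = FALSE)
  manifest <- list(); strikes <- list(); steps <- list()
  for (sid in names(cohort$subjects)) {
    for (bout in cohort$subjects[[sid]]$bouts) {
      key <- data.frame(subject_id = sid, view = bout$view,
                        bout_index = bout$bout_index, stringsAsFactors = FALSE)
      strikes[[length(strikes) + 1L]] <- cbind(key, bout$truth$strikes)
      steps[[length(steps) + 1L]] <- cbind(key, bout$truth$records)
      for (tr in names(bout$video)) for (cam in names(bout$video[[tr]])) {
        fn <- sprintf("%s_%s_b%d_%s_%s.csv", sid, bout$view, bout$bout_index,
                      cam, tr)
        write_canonical(bout$video[[tr]][[cam]], file.path(traj_dir, fn))
        manifest[[length(manifest) + 1L]] <- cbind(key, data.frame(
          camera = cam, tracker = tr, file = file.path("trajectories", fn),
          stringsAsFactors = FALSE))
      }
    }
  }
  write_df(do.call(rbind, manifest), out_dir, "manifest.csv")
  write_df(cohort$annotations, out_dir, "annotations.csv")
  write_df(cohort$metadata, out_dir, "metadata.csv")
  write_df(do.call(rbind, strikes), out_dir, "truth_strikes.csv")
  write_df(do.call(rbind, steps), out_dir, "truth_steps.csv")
  cfg <- unclass(config); cfg$seed <- seed
  yaml::write_yaml(cfg, file.path(out_dir, "sim_config.yml"))
  message("wrote bundle: ", length(manifest), " trajectories, ",
          nrow(cohort$annotations), " bouts")
  print(utils::head(do.call(rbind, lapply(cohort$subjects, function(s)
    do.call(rbind, lapply(s$bouts, function(b) b$truth$summary))))))
  invisible(cohort)
}

# Rebuild an in-memory cohort from a bundle directory written by cmd_simulate.
read_bundle <- function(in_dir) {
  manifest <- utils::read.csv(file.path(in_dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  ann <- utils::read.csv(file.path(in_dir, "annotations.csv"),
                         stringsAsFactors = FALSE)
  meta <- utils::read.csv(file.path(in_dir, "metadata.csv"),
                          stringsAsFactors = FALSE)
  strikes <- utils::read.csv(file.path(in_dir, "truth_strikes.csv"),
                             stringsAsFactors = FALSE)
  steps <- utils::read.csv(file.path(in_dir, "truth_steps.csv"),
                           stringsAsFactors = FALSE)
  subjects <- list()
  for (sid in unique(manifest$subject_id)) {
    mrow <- meta[meta$subject_id == sid, , drop = FALSE]
    bouts <- list()
    mk <- manifest[manifest$subject_id == sid, , drop = FALSE]
    for (vw in unique(mk$view)) for (b in unique(mk$bout_index[mk$view == vw])) {
      sel <- mk$view == vw & mk$bout_index == b
      video <- list()
      for (i in which(sel)) {
        tr <- mk$tracker[i]; cam <- mk$camera[i]
        video[[tr]][[cam]] <- read_pose_run(file.path(in_dir, mk$file[i]),
                                            dialect = "canonical")
      }
      tk <- strikes$subject_id == sid & strikes$view == vw & strikes$bout_index == b
      pk <- steps$subject_id == sid & steps$view == vw & steps$bout_index == b
      rec <- steps[pk, setdiff(names(steps), c("subject_id", "view", "bout_index")),
                   drop = FALSE]
      stk <- strikes[tk, setdiff(names(strikes), c("subject_id", "view", "bout_index")),
                     drop = FALSE]
      rownames(rec) <- rownames(stk) <- NULL
      truth <- list(strikes = stk, records = rec,
                    summary = summarize_bout(rec, stk, method = "mean"))
      ann_row <- ann[ann$subject_id == sid & ann$view == vw &
                       ann$bout_index == b, , drop = FALSE]
      bouts[[length(bouts) + 1L]] <- list(view = vw, bout_index = b,
                                          truth = truth, video = video,
                                          annotation = ann_row)
    }
    subjects[[sid]] <- list(metadata = mrow, bouts = bouts)
  }
  structure(list(subjects = subjects, metadata = meta, annotations = ann,
                 trackers = unique(manifest$tracker), config = NULL),
            class = "gait_cohort")
}

#' Extract gait variables from a study bundle on disk
#'
#' Reads a bundle written by [cmd_simulate()] (or assembled externally in
#' the same layout), runs [run_extraction()], and writes per-step tables,
#' per-bout summaries, the quality report and the effective pipeline config
#' to `out_dir`.
#'
#' @param in_dir Bundle directory.
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @return Invisibly, the extraction result.
#' @export
cmd_extract <- function(in_dir, out_dir, config = pipeline_config()) {
  cohort <- read_bundle(in_dir)
  ex <- run_extraction(cohort, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_df(ex$video_steps, out_dir, "video_steps.csv")
  write_df(ex$video_summaries, out_dir, "video_summaries.csv")
  write_df(ex$ref_steps, out_dir, "ref_steps.csv")
  write_df(ex$ref_summaries, out_dir, "ref_summaries.csv")
  write_df(ex$quality, out_dir, "quality.csv")
  yaml::write_yaml(unclass(config), file.path(out_dir, "pipeline_config.yml"))
  n_flag <- sum(ex$quality$flagged)
  if (n_flag) message(n_flag, " stream(s) flagged by the missing-data rule")
  invisible(ex)
}

#' Validate extracted gait variables against the reference stream
#'
#' Reads the tables written by [cmd_extract()], runs [run_validation()], and
#' writes the condition grid, precision table and Bland-Altman table as CSV.
#'
#' @param in_dir Directory holding the extraction tables.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the validation result.
#' @export
cmd_validate <- function(in_dir, out_dir) {
  ex <- list(
    video_steps = utils::read.csv(file.path(in_dir, "video_steps.csv"),
                                  stringsAsFactors = FALSE),
    video_summaries = utils::read.csv(file.path(in_dir, "video_summaries.csv"),
                                      stringsAsFactors = FALSE),
    ref_steps = utils::read.csv(file.path(in_dir, "ref_steps.csv"),
                                stringsAsFactors = FALSE),
    ref_summaries = utils::read.csv(file.path(in_dir, "ref_summaries.csv"),
                                    stringsAsFactors = FALSE)
  )
  va <- run_validation(ex)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_df(va$grid$table, out_dir, "condition_grid.csv")
  write_df(va$precision, out_dir, "precision.csv")
  if (!is.null(va$bland_altman))
    write_df(va$bland_altman, out_dir, "bland_altman.csv")
  message("condition grid: ", va$grid$n_cells, " populated cells")
  invisible(va)
}
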