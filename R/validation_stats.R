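# Concurrent-validity statistics: Pearson correlation grid over the
# tracker x camera x view x method conditions, precision (CV) tables, and
# pairwise Bland-Altman agreement between trackers.

#' Pearson correlation with a two-sided p-value
#'
#' Thin, guarded wrapper around [stats::cor.test()]: Pearson's r with the
#' two-sided p-value from the t-transform on n - 2 degrees of freedom. The
#' 0.05 significance level is applied only at reporting time, never here.
#'
#' @param x,y Paired numeric vectors of equal length (n >= 3), finite, each
#'   with nonzero variance.
#' @return List of class `correlation_result` with elements `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  if (length(x) < 3) stop("need at least 3 pairs for a correlation")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("correlation undefined: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.3f, p = %.3g, n = %d\n", x$r, x$p, x$n))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = a - b` and pair means `(a + b) / 2`; limits of agreement
#' are `mean(d) +/- 1.96 * sd(d)` (sample SD), the band expected to contain
#' 95% of the differences.
#'
#' @param a,b Paired numeric vectors of equal length (n >= 2).
#' @return List of class `bland_altman` with `mean_difference`,
#'   `sd_difference`, `loa_low`, `loa_high`, `n`, and a `data` frame of
#'   per-pair means and differences for plotting.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must be paired (equal length)")
  if (length(a) < 2) stop("need at least 2 pairs")
  d <- a - b
  m <- (a + b) / 2
  md <- mean(d)
  sdd <- stats::sd(d)
  structure(
    list(mean_difference = md, sd_difference = sdd,
         loa_low = md - 1.96 * sdd, loa_high = md + 1.96 * sdd,
         n = length(d), data = data.frame(mean = m, difference = d)),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean diff %.4g, LoA [%.4g, %.4g], n = %d\n",
              x$mean_difference, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Plot a Bland-Altman analysis
#'
#' Scatter of differences against pair means with the zero line and the
#' mean-difference and limits-of-agreement lines dashed.
#'
#' @param x A `bland_altman` object.
#' @param ... Passed to [plot()].
#' @export
plot.bland_altman <- function(x, ...) {
  plot(x$data$mean, x$data$difference, xlab = "Mean of pair",
       ylab = "Difference", ...)
  graphics::abline(h = 0, col = "grey60")
  graphics::abline(h = c(x$mean_difference, x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}

#' Precision table: dispersion of per-bout values
#'
#' For each tracker/camera/view group and each per-bout gait variable, the
#' coefficient of variation of that variable across each participant's bouts
#' is computed, and reported as mean (SD) across participants. Groups (or
#' participants) with fewer than 2 bouts are marked unavailable (`NA`).
#'
#' @param summaries Per-bout summary table: columns `subject_id`, `tracker`,
#'   `camera`, `view`, `bout_index` plus per-bout variables.
#' @param variables Variables to tabulate (defaults to the four mean-level
#'   gait variables).
#' @return Long data frame: `variable`, `tracker`, `camera`, `view`,
#'   `cv_mean`, `cv_sd`, `n_subjects`.
#' @export
precision_table <- function(summaries,
                            variables = c("cadence", "mean_step_time",
                                          "mean_step_width", "mean_emos")) {
  groups <- unique(summaries[, c("tracker", "camera", "view")])
  rows <- list()
  for (gi in seq_len(nrow(groups))) {
    g <- groups[gi, ]
    sub <- summaries[summaries$tracker == g$tracker &
                       summaries$camera == g$camera &
                       summaries$view == g$view, , drop = FALSE]
    for (v in variables) {
      cvs <- vapply(split(sub[[v]], sub$subject_id), function(vals) {
        vals <- vals[is.finite(vals)]
        if (length(vals) < 2 || mean(vals) == 0) return(NA_real_)
        abs(coefficient_of_variation(vals))
      }, numeric(1))
      cvs <- cvs[is.finite(cvs)]
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, tracker = g$tracker, camera = g$camera, view = g$view,
        cv_mean = if (length(cvs)) mean(cvs) else NA_real_,
        cv_sd = if (length(cvs) > 1) stats::sd(cvs) else NA_real_,
        n_subjects = length(cvs),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

safe_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3 || stats::var(x) == 0 || stats::var(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x)))
  pearson_correlation(x, y)
}

#' Build the tracker x camera x view x method validation grid
#'
#' Correlates video-derived gait variables with the reference stream in
#' every condition: each tracker, each camera height, each walking view, and
#' both calculation methods. With three trackers this enumerates
#' 3 x 2 x 2 x 2 = 24 cells. Within a cell, each of the six gait variables
#' yields one correlation:
#' * `method = "individual"`: step-level variables (step time, step width,
#'   eMOS) are paired per matched step pooled over participants; bout-level
#'   variables (cadence, the CVs) are paired per bout.
#' * `method = "mean"`: every variable is first averaged per participant
#'   over all bouts of that view, then paired across participants.
#'
#' Cells with missing inputs are marked unavailable (`NA` correlations); the
#' grid is returned regardless.
#'
#' @param video_steps Per-step table for video sources: columns
#'   `subject_id`, `tracker`, `camera`, `view`, `bout_index`, `step_index`,
#'   `step_time_s`, `step_width`, `emos`.
#' @param video_summaries Per-bout summary table for video sources (see
#'   [summarize_bout()]), with the same key columns.
#' @param ref_steps,ref_summaries The reference-system equivalents (no
#'   `tracker`/`camera` columns needed; the reference is shared).
#' @return Object of class `condition_grid`: list with `table` (long data
#'   frame: `tracker`, `camera`, `view`, `method`, `variable`, `r`, `p`,
#'   `n`) and `n_cells` (number of populated condition cells).
#' @export
build_condition_grid <- function(video_steps, video_summaries,
                                 ref_steps, ref_summaries) {
  trackers <- sort(unique(video_steps$tracker))
  cameras <- sort(unique(video_steps$camera))
  views <- sort(unique(video_steps$view))
  methods <- c("individual", "mean")
  step_key <- c("subject_id", "view", "bout_index", "step_index")
  bout_key <- c("subject_id", "view", "bout_index")
  rows <- list()
  n_cells <- 0L
  for (tr in trackers) for (cam in cameras) for (vw in views) for (me in methods) {
    vs <- video_steps[video_steps$tracker == tr & video_steps$camera == cam &
                        video_steps$view == vw, , drop = FALSE]
    vb <- video_summaries[video_summaries$tracker == tr &
                            video_summaries$camera == cam &
                            video_summaries$view == vw, , drop = FALSE]
    rs <- ref_steps[ref_steps$view == vw, , drop = FALSE]
    rb <- ref_summaries[ref_summaries$view == vw, , drop = FALSE]
    cell_ok <- nrow(vs) > 0 && nrow(vb) > 0 && nrow(rs) > 0 && nrow(rb) > 0
    if (cell_ok) n_cells <- n_cells + 1L
    for (v in STEP_VARIABLES) {
      res <- list(r = NA_real_, p = NA_real_, n = 0L)
      if (cell_ok) {
        if (me == "individual") {
          if (v %in% c("step_time", "step_width", "emos")) {
            col <- if (v == "step_time") "step_time_s" else v
            mrg <- merge(vs[, c(step_key, col)], rs[, c(step_key, col)],
                         by = step_key, suffixes = c(".v", ".r"))
            res <- safe_cor(mrg[[paste0(col, ".v")]], mrg[[paste0(col, ".r")]])
          } else {
            col <- c(cadence = "cadence", cv_step_time = "cv_step_time",
                     cv_step_width = "cv_step_width")[[v]]
            mrg <- merge(vb[, c(bout_key, col)], rb[, c(bout_key, col)],
                         by = bout_key, suffixes = c(".v", ".r"))
            res <- safe_cor(mrg[[paste0(col, ".v")]], mrg[[paste0(col, ".r")]])
          }
        } else {
          col <- c(cadence = "cadence", step_time = "mean_step_time",
                   step_width = "mean_step_width", cv_step_time = "cv_step_time",
                   cv_step_width = "cv_step_width", emos = "mean_emos")[[v]]
          agg_v <- stats::aggregate(vb[[col]], by = vb[, "subject_id", drop = FALSE],
                                    FUN = mean, na.rm = TRUE)
          agg_r <- stats::aggregate(rb[[col]], by = rb[, "subject_id", drop = FALSE],
                                    FUN = mean, na.rm = TRUE)
          mrg <- merge(agg_v, agg_r, by = "subject_id", suffixes = c(".v", ".r"))
          res <- safe_cor(mrg$x.v, mrg$x.r)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        tracker = tr, camera = cam, view = vw, method = me, variable = v,
        r = res$r, p = res$p, n = res$n, stringsAsFactors = FALSE
      )
    }
  }
  structure(list(table = do.call(rbind, rows), n_cells = n_cells),
            class = "condition_grid")
}

#' @export
print.condition_grid <- function(x, ...) {
  cat(sprintf("<condition_grid> %d populated cells, %d correlations\n",
              x$n_cells, sum(is.finite(x$table$r))))
  invisible(x)
}

#' Pairwise Bland-Altman agreement between trackers
#'
#' Computes Bland-Altman statistics for each pair of trackers on per-step
#' values, split by camera and view. By default only the spatial variables
#' (step width, eMOS) are analysed: the gait events detected by the trackers
#' are near-identical, so temporal variables agree trivially; set
#' `variables` to include them anyway.
#'
#' @param video_steps Per-step table as in [build_condition_grid()].
#' @param variables Variables to compare (default `step_width`, `emos`).
#' @return Long data frame: `tracker_a`, `tracker_b`, `camera`, `view`,
#'   `variable`, `mean_difference`, `loa_low`, `loa_high`, `n`.
#' @export
bland_altman_pairs <- function(video_steps,
                               variables = c("step_width", "emos")) {
  trackers <- sort(unique(video_steps$tracker))
  key <- c("subject_id", "view", "bout_index", "step_index")
  rows <- list()
  if (length(trackers) < 2) return(NULL)
  combs <- utils::combn(trackers, 2)
  for (cam in sort(unique(video_steps$camera)))
    for (vw in sort(unique(video_steps$view)))
      for (ci in seq_len(ncol(combs))) {
        ta <- combs[1, ci]; tb <- combs[2, ci]
        sa <- video_steps[video_steps$tracker == ta &
                            video_steps$camera == cam &
                            video_steps$view == vw, , drop = FALSE]
        sb <- video_steps[video_steps$tracker == tb &
                            video_steps$camera == cam &
                            video_steps$view == vw, , drop = FALSE]
        for (v in variables) {
          mrg <- merge(sa[, c(key, v)], sb[, c(key, v)], by = key,
                       suffixes = c(".a", ".b"))
          ok <- is.finite(mrg[[paste0(v, ".a")]]) & is.finite(mrg[[paste0(v, ".b")]])
          mrg <- mrg[ok, , drop = FALSE]
          if (nrow(mrg) < 2) next
          ba <- bland_altman(mrg[[paste0(v, ".a")]], mrg[[paste0(v, ".b")]])
          rows[[length(rows) + 1L]] <- data.frame(
            tracker_a = ta, tracker_b = tb, camera = cam, view = vw,
            variable = v, mean_difference = ba$mean_difference,
            loa_low = ba$loa_low, loa_high = ba$loa_high, n = ba$n,
            stringsAsFactors = FALSE
          )
        }
      }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Per-participant step bookkeeping
#'
#' Averages total step counts down to steps per participant and steps per
#' walking bout, rounding to one decimal the way study summaries report
#' them.
#'
#' @param total_steps Total steps counted across all participants in a view.
#' @param n_participants Number of participants.
#' @param bouts_per_participant Mean walking bouts per participant.
#' @return List with `steps_per_participant` and `steps_per_bout`.
#' @export
study_step_bookkeeping <- function(total_steps, n_participants,
                                   bouts_per_participant) {
  spp <- round(total_steps / n_participants, 1)
  list(steps_per_participant = spp,
       steps_per_bout = round(spp / bouts_per_participant, 1))
}
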