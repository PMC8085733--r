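#' Task configuration for the Squares Task
#'
#' Bundles the stimulus parameters of the Squares judgement-of-agency task:
#' eight squares on a 1920x1080 screen are driven for 15 s (900 frames at
#' 60 Hz) by the mouse input vector. Angular jitter is added to every
#' square's motion; its two-sided 95% confidence half-width alternates
#' between a narrow and a wide state. In the low-variability condition the
#' half-width switches between 10 and 30 degrees, in high variability
#' between 90 and 110 degrees. Volatility sets how often the switch
#' happens within a trial: 3 times (low) or 10 times (high), with at least
#' 50 frames (833 ms) between changes. Each distractor square additionally
#' carries an angular offset that is redrawn (and smoothly transitioned)
#' five times per trial.
#'
#' Coordinates are in pixels with the origin at the top-left corner, x
#' rightward and y downward; angles are measured from +x, clockwise
#' positive (consistent with y-down). The screen is toroidal: squares wrap
#' at the edges.
#'
#' @param variability `"low"` or `"high"`: jitter CI half-width pair
#'   (10, 30) or (90, 110) degrees.
#' @param volatility `"low"` or `"high"`: 3 or 10 within-trial changes of
#'   the jitter state.
#' @param frames_per_trial Trial length in frames (default 900 = 15 s).
#' @param fps Stimulus frame rate in Hz (default 60).
#' @param n_squares Number of squares (default 8).
#' @param square_size_px Square side length in pixels (default 100).
#' @param screen_w,screen_h Screen size in pixels (default 1920 x 1080).
#' @param min_change_gap_frames Minimum frames between volatility changes
#'   (default 50).
#' @param distractor_redraws Number of times each distractor's angular
#'   offset is redrawn per trial (default 5).
#' @param offset_transition_frames Length of the linear shortest-arc
#'   transition after an offset redraw, in frames (default 30 = 500 ms).
#' @param start_margin_frames No volatility change happens within this many
#'   frames of trial start (default 50).
#' @param n_volatility_changes Override for the number of changes; by
#'   default derived from `volatility` (3 or 10). Useful for degenerate
#'   schedules in diagnostics.
#' @param ci_pair_deg Override for the (narrow, wide) CI half-width pair in
#'   degrees; by default derived from `variability`.
#' @return An object of class `task_config` (a validated named list).
#' @examples
#' cfg <- task_config("low", "high")
#' cfg$n_volatility_changes # 10
#' @export
task_config <- function(variability = c("low", "high"),
                        volatility = c("low", "high"),
                        frames_per_trial = 900L,
                        fps = 60L,
                        n_squares = 8L,
                        square_size_px = 100,
                        screen_w = 1920,
                        screen_h = 1080,
                        min_change_gap_frames = 50L,
                        distractor_redraws = 5L,
                        offset_transition_frames = 30L,
                        start_margin_frames = 50L,
                        n_volatility_changes = NULL,
                        ci_pair_deg = NULL) {
  variability <- match.arg(variability)
  volatility <- match.arg(volatility)
  ci_pair_deg <- ci_pair_deg %||%
    if (variability == "low") c(10, 30) else c(90, 110)
  n_volatility_changes <- as.integer(n_volatility_changes %||%
    if (volatility == "low") 3L else 10L)

  cfg <- structure(list(
    variability_level = variability,
    volatility_level = volatility,
    frames_per_trial = as.integer(frames_per_trial),
    fps = as.integer(fps),
    n_squares = as.integer(n_squares),
    square_size_px = square_size_px,
    screen_w = screen_w,
    screen_h = screen_h,
    ci_pair_deg = ci_pair_deg,
    n_volatility_changes = n_volatility_changes,
    min_change_gap_frames = as.integer(min_change_gap_frames),
    distractor_redraws = as.integer(distractor_redraws),
    offset_transition_frames = as.integer(offset_transition_frames),
    start_margin_frames = as.integer(start_margin_frames)
  ), class = "task_config")
  validate_task_config(cfg)
  cfg
}

validate_task_config <- function(cfg) {
  stopifnot(
    cfg$frames_per_trial == 15L * cfg$fps,
    cfg$n_squares >= 1L,
    all(cfg$ci_pair_deg > 0),
    cfg$ci_pair_deg[1] < cfg$ci_pair_deg[2],
    cfg$n_volatility_changes >= 0L,
    cfg$min_change_gap_frames >= 1L,
    cfg$distractor_redraws >= 0L,
    cfg$offset_transition_frames >= 0L
  )
  if (cfg$n_volatility_changes * cfg$min_change_gap_frames >=
      cfg$frames_per_trial) {
    stop("volatility schedule infeasible: ", cfg$n_volatility_changes,
         " changes with minimum gap ", cfg$min_change_gap_frames,
         " do not fit in ", cfg$frames_per_trial, " frames", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.task_config <- function(x, ...) {
  cat("<task_config> ", x$variability_level, " variability / ",
      x$volatility_level, " volatility\n", sep = "")
  cat("  ", x$frames_per_trial, " frames @ ", x$fps, " Hz, ",
      x$n_squares, " squares, screen ", x$screen_w, "x", x$screen_h, "\n",
      sep = "")
  cat("  jitter CI half-widths: ", paste(x$ci_pair_deg, collapse = "/"),
      " deg; ", x$n_volatility_changes, " changes (gap >= ",
      x$min_change_gap_frames, " frames)\n", sep = "")
  invisible(x)
}

# All four cells of the 2x2 design.
#' Configurations for the four uncertainty conditions
#'
#' @param ... Passed on to [task_config()].
#' @return Named list of four `task_config` objects
#'   (`low_low`, `low_high`, `high_low`, `high_high`;
#'   variability first, volatility second).
#' @export
condition_configs <- function(...) {
  out <- list()
  for (va in c("low", "high")) {
    for (vo in c("low", "high")) {
      out[[paste(va, vo, sep = "_")]] <- task_config(va, vo, ...)
    }
  }
  out
}
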