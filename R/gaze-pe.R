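# Gaze analysis: biased-nearest-object assignment of the looked-at
# square, hypothesis-switch detection, the per-frame prediction-error
# proxy, its trial averages and slopes, and event-related prediction
# error (ERPE).

#' Assign the looked-at square (biased nearest object)
#'
#' Per frame, the looked-at square is the one whose centroid is closest
#' (wrap-aware) to gaze, with the incumbent square's distance multiplied
#' by `beta <= 1` so momentary excursions do not flip the assignment.
#' Invalid gaze frames carry the previous assignment forward; frames
#' before the first valid sample are `NA`. With `beta = 1` this reduces
#' to plain nearest-object assignment.
#'
#' @param gaze frames x 2 matrix (or `frame_gaze` table) of gaze
#'   positions; `NA` rows are invalid.
#' @param trial A `trial_log` (supplies square positions and screen size).
#' @param beta Incumbent bias in (0, 1] (default 0.8).
#' @return Integer vector of per-frame square indices (`NA` before first
#'   valid frame).
#' @export
assign_looked_square <- function(gaze, trial, beta = 0.8) {
  stopifnot(beta > 0, beta <= 1)
  if (is.data.frame(gaze)) gaze <- cbind(gaze$gaze_x, gaze$gaze_y)
  nf <- nrow(gaze)
  w <- trial$cfg$screen_w
  h <- trial$cfg$screen_h
  out <- rep(NA_integer_, nf)
  cur <- NA_integer_
  for (t in seq_len(nf)) {
    gx <- gaze[t, 1]; gy <- gaze[t, 2]
    if (is.na(gx) || is.na(gy)) {
      out[t] <- cur
      next
    }
    d <- torus_dist(gx, gy, trial$squares_x[t, ], trial$squares_y[t, ],
                    w, h)
    if (!is.na(cur)) d[cur] <- d[cur] * beta
    cur <- which.min(d)
    out[t] <- cur
  }
  out
}

#' Detect hypothesis switches in a looked-at-square sequence
#'
#' A hypothesis switch is any change in the looked-at square that lasts
#' longer than one frame; single-frame flickers are merged back into the
#' surrounding assignment first.
#'
#' @param looked Integer vector of per-frame square indices (`NA`
#'   allowed at the start).
#' @return List with `switch_frames` (onset frames), `n_switches` and
#'   `cleaned` (the flicker-merged sequence).
#' @export
detect_hypothesis_switches <- function(looked) {
  n <- length(looked)
  lead_na <- which(!is.na(looked))
  if (length(lead_na) == 0L) {
    return(list(switch_frames = integer(0), n_switches = 0L,
                cleaned = looked))
  }
  first <- lead_na[1L]
  x <- looked[first:n]
  r <- rle(x)
  # merge 1-frame flickers into the preceding run
  while (any(r$lengths == 1L) && length(r$lengths) > 1L) {
    i <- which(r$lengths == 1L)
    i <- i[i > 1L]
    if (length(i) == 0L) break
    r$values[i[1L]] <- r$values[i[1L] - 1L]
    r <- rle(inverse.rle(r))
  }
  cleaned <- c(rep(NA_integer_, first - 1L), inverse.rle(r))
  if (length(r$lengths) < 2L) {
    return(list(switch_frames = integer(0), n_switches = 0L,
                cleaned = cleaned))
  }
  onsets <- cumsum(r$lengths)[-length(r$lengths)] + 1L
  keep <- r$values[-1L] != r$values[-length(r$values)]
  sw <- onsets[keep] + first - 1L
  list(switch_frames = as.integer(sw), n_switches = length(sw),
       cleaned = cleaned)
}

#' Per-frame prediction-error proxy
#'
#' One-step-ahead formulation: the expected location at frame t is the
#' hypothesised square's own actual position at t-1 plus the mouse
#' displacement at t; the prediction error is the wrap-aware Euclidean
#' distance between that expectation and the square's actual position.
#' At a switch the newly hypothesised square's own previous position
#' seeds the expectation, so switches do not inject spurious error.
#' Stationary-mouse frames give zero error (all squares stop with the
#' mouse). Frames without a hypothesis are `NA`. A cumulative-divergence
#' alternative (expectation integrated from the first hypothesis frame,
#' never re-anchored) is available via `formulation = "cumulative"`.
#'
#' @param trial A `trial_log`.
#' @param looked Per-frame hypothesised square indices (e.g. cleaned
#'   output of [detect_hypothesis_switches()]).
#' @param formulation `"one_step"` (default) or `"cumulative"`.
#' @return `data.frame`: frame, looked, pe_px. Attribute `mean_pe` is the
#'   trial average.
#' @export
prediction_error_series <- function(trial, looked,
                                    formulation = c("one_step",
                                                    "cumulative")) {
  formulation <- match.arg(formulation)
  nf <- nrow(trial$mouse)
  stopifnot(length(looked) == nf)
  if (all(is.na(looked))) {
    stop("no hypothesis assigned on any frame", call. = FALSE)
  }
  w <- trial$cfg$screen_w
  h <- trial$cfg$screen_h
  pe <- rep(NA_real_, nf)
  if (formulation == "one_step") {
    prev_x <- rbind(trial$init_xy[, 1],
                    trial$squares_x[-nf, , drop = FALSE])
    prev_y <- rbind(trial$init_xy[, 2],
                    trial$squares_y[-nf, , drop = FALSE])
    ok <- which(!is.na(looked))
    idx <- cbind(ok, looked[ok])
    ex <- prev_x[idx] + trial$mouse[ok, 1]
    ey <- prev_y[idx] + trial$mouse[ok, 2]
    pe[ok] <- torus_dist(ex, ey, trial$squares_x[idx],
                         trial$squares_y[idx], w, h)
  } else {
    ex <- NA_real_; ey <- NA_real_
    for (t in seq_len(nf)) {
      s <- looked[t]
      if (is.na(s)) next
      if (is.na(ex)) {
        ex <- if (t == 1L) trial$init_xy[s, 1] else trial$squares_x[t - 1L, s]
        ey <- if (t == 1L) trial$init_xy[s, 2] else trial$squares_y[t - 1L, s]
      }
      ex <- ex + trial$mouse[t, 1]
      ey <- ey + trial$mouse[t, 2]
      pe[t] <- torus_dist(ex, ey, trial$squares_x[t, s],
                          trial$squares_y[t, s], w, h)
    }
  }
  out <- data.frame(frame = seq_len(nf), looked = looked, pe_px = pe)
  attr(out, "mean_pe") <- mean(pe, na.rm = TRUE)
  class(out) <- c("pe_series", class(out))
  out
}

#' Slope of prediction error over time
#'
#' Within each grouping cell, prediction error is first averaged across
#' the cell's trials at each frame, then an ordinary least-squares line is
#' fitted to the per-frame means against time in seconds. Negative slopes
#' indicate prediction-error minimisation.
#'
#' @param pe_long `data.frame` with columns `frame`, `pe_px` and any
#'   grouping columns; one row per trial-frame.
#' @param by Character vector of grouping column names (e.g.
#'   `c("participant", "variability", "volatility")` for condition-wise
#'   slopes or `c("participant", "accuracy", "judged_agency")` for
#'   agency-wise slopes).
#' @param fps Frame rate used to convert frames to seconds.
#' @return `data.frame` with the grouping columns plus `slope`,
#'   `intercept` and `n_frames` (`NA` slope when < 2 time points).
#' @export
pe_slope <- function(pe_long, by, fps = 60) {
  stopifnot(all(c(by, "frame", "pe_px") %in% names(pe_long)))
  dt <- data.table::as.data.table(pe_long)
  mean_pe <- dt[!is.na(pe_px),
                .(mpe = mean(pe_px)), by = c(by, "frame")]
  fit <- mean_pe[, {
    tt <- (frame - 1) / fps
    if (length(tt) < 2L) {
      list(slope = NA_real_, intercept = NA_real_,
           n_frames = length(tt))
    } else {
      b <- stats::cov(tt, mpe) / stats::var(tt)
      list(slope = b, intercept = mean(mpe) - b * mean(tt),
           n_frames = length(tt))
    }
  }, by = by]
  as.data.frame(fit)
}

#' Event-related prediction error (ERPE)
#'
#' Extracts a one-second (60-frame) epoch of prediction error around each
#' event, frames `[event - 30, event + 29]`, and reduces it to five
#' 200 ms (12-frame) bin means with bin 3 centred on event onset
#' (`[event - 6, event + 5]`). Events within 30 frames of the trial edges
#' are dropped; overlapping epochs are allowed; missing prediction-error
#' frames are excluded from bin means.
#'
#' @param pe Numeric per-frame prediction-error vector (or `pe_series`).
#' @param events Integer event-onset frames (hypothesis switches or
#'   volatility changes).
#' @param event_type Label stored with the epochs.
#' @return List with `epochs` (n_events x 60 matrix), `bin_means`
#'   (n_events x 5 matrix), `events` (surviving onsets) and `event_type`.
#' @export
erpe_epochs <- function(pe, events, event_type = "hypothesis_switch") {
  if (inherits(pe, "pe_series")) pe <- pe$pe_px
  nf <- length(pe)
  events <- as.integer(events)
  keep <- events - 30L >= 1L & events + 29L <= nf
  events <- events[keep]
  if (length(events) == 0L) {
    return(list(epochs = matrix(numeric(0), 0L, 60L),
                bin_means = matrix(numeric(0), 0L, 5L),
                events = integer(0), event_type = event_type))
  }
  rel <- -30L:29L
  epochs <- t(vapply(events, function(e) pe[e + rel], numeric(60L)))
  bins <- rep(1:5, each = 12L)
  bin_means <- t(apply(epochs, 1L, function(row) {
    tapply(row, bins, mean, na.rm = TRUE)
  }))
  dimnames(bin_means) <- list(NULL, paste0("bin", 1:5))
  list(epochs = epochs, bin_means = bin_means, events = events,
       event_type = event_type)
}
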