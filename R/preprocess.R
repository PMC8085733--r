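# Binocular eye-trace cleaning: blink detection from pupil size, removal
# of out-of-bounds samples, linear interpolation, Hanning smoothing,
# binocular merging, downsampling to stimulus frames, and poor-signal
# trial exclusion.

#' Detect blinks from pupil size
#'
#' Flags samples whose pupil size falls strictly below `mu - 1.5 sd` or
#' strictly above `mu + 2 sd` of the participant's average pupil size
#' (computed per eye over all non-missing samples unless supplied), and
#' merges contiguous flagged samples into spans. Missing pupil samples are
#' treated as blink samples.
#'
#' @param trace `data.frame` with columns `t, x_l, y_l, p_l, x_r, y_r,
#'   p_r` (raw binocular samples).
#' @param pupil_stats Optional list `list(left = c(mu, sd), right = ...)`
#'   of session-level pupil statistics; when the criterion should use the
#'   whole session rather than a single trial, compute these once and pass
#'   them in.
#' @param min_valid_s Minimum seconds of valid pupil data required to
#'   estimate the statistics (default 2).
#' @return List with per-eye span tables (`left`, `right`:
#'   `data.frame(start, end)` sample indices) and the statistics used.
#' @export
detect_blinks <- function(trace, pupil_stats = NULL, min_valid_s = 2) {
  dt <- stats::median(diff(trace$t))
  one_eye <- function(p, stats_in) {
    valid <- !is.na(p)
    if (!any(valid)) stop("pupil channel entirely invalid", call. = FALSE)
    if (is.null(stats_in)) {
      if (sum(valid) * dt < min_valid_s) {
        stop("need at least ", min_valid_s,
             " s of valid pupil data to estimate blink statistics",
             call. = FALSE)
      }
      stats_in <- c(mean(p[valid]), stats::sd(p[valid]))
    }
    mu <- stats_in[1]; sg <- stats_in[2]
    flagged <- !valid | (valid & (p < mu - 1.5 * sg | p > mu + 2 * sg))
    flagged[is.na(flagged)] <- TRUE
    r <- rle(flagged)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    list(spans = data.frame(start = starts[r$values],
                            end = ends[r$values]),
         stats = c(mu = mu, sd = sg))
  }
  l <- one_eye(trace$p_l, pupil_stats$left)
  r <- one_eye(trace$p_r, pupil_stats$right)
  list(left = l$spans, right = r$spans,
       stats = list(left = l$stats, right = r$stats))
}

spans_to_logical <- function(spans, n) {
  out <- rep(FALSE, n)
  for (i in seq_len(nrow(spans))) out[spans$start[i]:spans$end[i]] <- TRUE
  out
}

#' Session-level pupil statistics
#'
#' Mean and SD of the pupil per eye over all non-missing samples of a set
#' of raw traces, for use as `pupil_stats` in [detect_blinks()].
#'
#' @param traces List of raw eye `data.frame`s.
#' @return List `list(left = c(mu, sd), right = c(mu, sd))`.
#' @export
session_pupil_stats <- function(traces) {
  pl <- unlist(lapply(traces, `[[`, "p_l"))
  pr <- unlist(lapply(traces, `[[`, "p_r"))
  list(left = c(mean(pl, na.rm = TRUE), stats::sd(pl, na.rm = TRUE)),
       right = c(mean(pr, na.rm = TRUE), stats::sd(pr, na.rm = TRUE)))
}

#' Clean and smooth a raw binocular trace
#'
#' Per eye: invalidates out-of-screen samples, linearly interpolates blink
#' spans and missing samples, then smooths x and y with a unit-normalised
#' 15-sample Hanning window at stride 1 (14/15 ~ 93% overlap), edges
#' handled by reflection. Interpolated-sample flags are preserved in
#' columns `interp_l` / `interp_r`.
#'
#' @param trace Raw eye `data.frame` (see [detect_blinks()]).
#' @param blinks Result of [detect_blinks()] on this trace.
#' @param cfg A [task_config()] (screen bounds).
#' @param hanning_n Smoothing window length in samples (default 15).
#' @return The cleaned trace with gaze replaced and flags added.
#' @export
clean_and_smooth <- function(trace, blinks, cfg, hanning_n = 15L) {
  n <- nrow(trace)
  out <- trace
  for (eye in c("l", "r")) {
    xc <- paste0("x_", eye); yc <- paste0("y_", eye)
    x <- trace[[xc]]; y <- trace[[yc]]
    oob <- !is.na(x) & !is.na(y) &
      (x < 0 | x >= cfg$screen_w | y < 0 | y >= cfg$screen_h)
    bl <- spans_to_logical(if (eye == "l") blinks$left else blinks$right, n)
    bad <- oob | bl | is.na(x) | is.na(y)
    if (all(bad)) {
      stop("eye '", eye, "' has no recoverable samples in this trial",
           call. = FALSE)
    }
    x[bad] <- NA; y[bad] <- NA
    x <- stats::approx(trace$t, x, xout = trace$t, rule = 2)$y
    y <- stats::approx(trace$t, y, xout = trace$t, rule = 2)$y
    out[[xc]] <- smooth_hanning(x, hanning_n)
    out[[yc]] <- smooth_hanning(y, hanning_n)
    out[[paste0("interp_", eye)]] <- bad
  }
  out
}

#' Merge eyes and downsample to stimulus frames
#'
#' Per sample, gaze is the mean of the two eyes; samples interpolated in
#' one eye use the other eye alone. If one eye's interpolated fraction
#' exceeds `noisy_frac` while the other's is below `good_frac`, the noisy
#' eye is discarded for the whole trial ("excessively noisy" single-eye
#' substitution). Samples are then binned to stimulus frames by
#' within-frame averaging.
#'
#' @param trace A cleaned trace from [clean_and_smooth()].
#' @param cfg A [task_config()].
#' @param noisy_frac,good_frac Whole-trial substitution thresholds
#'   (defaults 0.35 and 0.15).
#' @return `frame_gaze` `data.frame`: frame, gaze_x, gaze_y, valid,
#'   frac_interp_l, frac_interp_r (per-frame interpolated fractions).
#'   Attributes `interp_frac_l` / `interp_frac_r` give trial totals and
#'   `substituted_eye` names a discarded eye (or `NA`).
#' @export
merge_and_downsample <- function(trace, cfg, noisy_frac = 0.35,
                                 good_frac = 0.15) {
  n <- nrow(trace)
  fl <- mean(trace$interp_l)
  fr <- mean(trace$interp_r)
  use_l <- rep(TRUE, n); use_r <- rep(TRUE, n)
  substituted <- NA_character_
  if (fl > noisy_frac && fr < good_frac) {
    use_l <- rep(FALSE, n); substituted <- "left"
  } else if (fr > noisy_frac && fl < good_frac) {
    use_r <- rep(FALSE, n); substituted <- "right"
  } else {
    use_l <- !trace$interp_l | trace$interp_r
    use_r <- !trace$interp_r | trace$interp_l
  }
  wl <- as.numeric(use_l); wr <- as.numeric(use_r)
  gx <- (wl * trace$x_l + wr * trace$x_r) / (wl + wr)
  gy <- (wl * trace$y_l + wr * trace$y_r) / (wl + wr)

  frame <- pmin(floor(trace$t * cfg$fps) + 1L, cfg$frames_per_trial)
  nf <- cfg$frames_per_trial
  agg <- function(v) {
    s <- tapply(v, factor(frame, levels = seq_len(nf)), mean)
    as.numeric(s)
  }
  out <- data.frame(
    frame = seq_len(nf),
    gaze_x = agg(gx),
    gaze_y = agg(gy),
    frac_interp_l = agg(as.numeric(trace$interp_l)),
    frac_interp_r = agg(as.numeric(trace$interp_r))
  )
  out$frac_interp_l[is.na(out$frac_interp_l)] <- 1
  out$frac_interp_r[is.na(out$frac_interp_r)] <- 1
  out$valid <- !is.na(out$gaze_x) & !is.na(out$gaze_y)
  attr(out, "interp_frac_l") <- fl
  attr(out, "interp_frac_r") <- fr
  attr(out, "substituted_eye") <- substituted
  class(out) <- c("frame_gaze", class(out))
  out
}

#' Flag poor-signal trials
#'
#' A trial is excluded when more than `interp_threshold` of its samples
#' were interpolated in both eyes, or when its recorded length lies
#' outside the participant's mean +/- 2 SD of trial lengths. The length
#' criterion needs at least 3 trials per participant and is skipped (with
#' a warning) otherwise; a zero length-SD excludes nothing.
#'
#' @param trial_meta `data.frame` with one row per trial and columns
#'   `participant`, `trial`, `interp_frac_l`, `interp_frac_r`,
#'   `recorded_len_s`.
#' @param interp_threshold Both-eye interpolated-fraction threshold
#'   (default 0.30; strictly-greater comparison).
#' @param length_sd Number of SDs for the trial-length criterion.
#' @return The input with logical columns `flag_interp`, `flag_length`,
#'   `excluded` and a character `reason`.
#' @export
flag_poor_trials <- function(trial_meta, interp_threshold = 0.30,
                             length_sd = 2) {
  stopifnot(all(c("participant", "interp_frac_l", "interp_frac_r",
                  "recorded_len_s") %in% names(trial_meta)))
  out <- trial_meta
  out$flag_interp <- out$interp_frac_l > interp_threshold &
    out$interp_frac_r > interp_threshold
  out$flag_length <- FALSE
  for (p in unique(out$participant)) {
    idx <- which(out$participant == p)
    if (length(idx) < 3L) {
      warning("participant ", p, ": fewer than 3 trials, ",
              "length criterion skipped", call. = FALSE)
      next
    }
    len <- out$recorded_len_s[idx]
    mu <- mean(len); sg <- stats::sd(len)
    if (sg > 0) {
      out$flag_length[idx] <- len > mu + length_sd * sg |
        len < mu - length_sd * sg
    }
  }
  out$excluded <- out$flag_interp | out$flag_length
  out$reason <- ifelse(out$flag_interp & out$flag_length, "interp+length",
                       ifelse(out$flag_interp, "interp",
                              ifelse(out$flag_length, "length", "")))
  out
}

#' Full per-trial eye preprocessing
#'
#' Convenience wrapper: blink detection, cleaning and smoothing, binocular
#' merge, downsampling to frames.
#'
#' @param trace Raw binocular trace.
#' @param cfg A [task_config()].
#' @param pupil_stats Optional session-level pupil statistics.
#' @param ... Passed to [merge_and_downsample()].
#' @return A `frame_gaze` table (see [merge_and_downsample()]).
#' @export
preprocess_trace <- function(trace, cfg, pupil_stats = NULL, ...) {
  blinks <- detect_blinks(trace, pupil_stats = pupil_stats)
  cleaned <- clean_and_smooth(trace, blinks, cfg)
  merge_and_downsample(cleaned, cfg, ...)
}
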