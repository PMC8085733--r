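# Synthetic participants: policy-driven mouse traces, a threshold-switching
# gaze agent, eye-tracker artifact injection and agency judgements. These
# are sign-level stand-ins for human behaviour (directions of effects, not
# magnitudes), so every pipeline stage is testable without human data.

POLICY_LEVELS <- c("Horizontal", "Vertical", "PerpendicularCardinal",
                   "NonCardinal", "HesitantStraight", "Circle")

# 8 movement directions, 45 deg apart, clockwise from +x (y down):
# R, DR, D, DL, L, UL, U, UR.
DIRECTION_LEVELS <- c("R", "DR", "D", "DL", "L", "UL", "U", "UR")
DIRECTION_ANGLES <- seq(0, 315, by = 45)

#' Synthetic agent profile
#'
#' Parameters of a synthetic participant. Defaults describe a competent
#' adult mouse user: base cursor speed 10 px/frame (~600 px/s at 60 Hz),
#' occasional pauses, a leaky prediction-error accumulator that abandons
#' the current agency hypothesis when it crosses `switch_threshold_px`,
#' and a fixed-pixel cutoff for reporting "no control". Policy weights
#' order the six turn types roughly as observed in adults (non-cardinal
#' and hesitant-straight most common).
#'
#' @param policy_weights Named non-negative weights over the six policies.
#' @param base_speed_px_per_frame Cursor speed while moving, px/frame.
#' @param pause_prob Probability of inserting a pause before a turn event.
#' @param switch_threshold_px Accumulated-PE threshold (px) at which the
#'   gaze agent switches hypothesis.
#' @param accumulator_decay Leak of the PE accumulator per frame (0.9).
#' @param refractory_frames Minimum frames between switches (12 ~ 200 ms).
#' @param stickiness_beta Incumbent bias of the biased-nearest-object
#'   gaze assignment, in (0, 1].
#' @param judgement_window_s Evidence window for the end-of-trial agency
#'   judgement, seconds.
#' @param no_agency_cutoff_px If no square's mean one-step PE in the
#'   window is below this, the agent answers "0" (no control). 9 px sits
#'   between the target's expected error (~1 px low variability, ~7 px
#'   high) and a typical distractor's (~13 px) at the default speed.
#' @param aq_score Autism Quotient covariate, integer in 0..50.
#' @param blink_rate_hz Blink rate for artifact injection.
#' @param gaze_noise_sd_px Gaussian gaze noise SD for artifact injection.
#' @return An `agent_profile` list.
#' @export
agent_profile <- function(policy_weights = c(Horizontal = 0.15,
                                             Vertical = 0.10,
                                             PerpendicularCardinal = 0.25,
                                             NonCardinal = 0.30,
                                             HesitantStraight = 0.15,
                                             Circle = 0.05),
                          base_speed_px_per_frame = 10,
                          pause_prob = 0.1,
                          switch_threshold_px = 80,
                          accumulator_decay = 0.9,
                          refractory_frames = 12L,
                          stickiness_beta = 0.8,
                          judgement_window_s = 3,
                          no_agency_cutoff_px = 9,
                          aq_score = NA_integer_,
                          blink_rate_hz = 0.25,
                          gaze_noise_sd_px = 15) {
  w <- rep(0, length(POLICY_LEVELS))
  names(w) <- POLICY_LEVELS
  stopifnot(all(names(policy_weights) %in% POLICY_LEVELS),
            all(policy_weights >= 0), sum(policy_weights) > 0,
            switch_threshold_px > 0,
            stickiness_beta > 0, stickiness_beta <= 1,
            is.na(aq_score) || (aq_score >= 0 && aq_score <= 50))
  w[names(policy_weights)] <- policy_weights
  structure(list(
    policy_weights = w / sum(w),
    base_speed_px_per_frame = base_speed_px_per_frame,
    pause_prob = pause_prob,
    switch_threshold_px = switch_threshold_px,
    accumulator_decay = accumulator_decay,
    refractory_frames = as.integer(refractory_frames),
    stickiness_beta = stickiness_beta,
    judgement_window_s = judgement_window_s,
    no_agency_cutoff_px = no_agency_cutoff_px,
    aq_score = aq_score,
    blink_rate_hz = blink_rate_hz,
    gaze_noise_sd_px = gaze_noise_sd_px
  ), class = "agent_profile")
}

#' Draw AQ scores for synthetic participants
#'
#' Normal(21.43, 5.89) truncated to `[0, 50]` and rounded, matching the
#' sample moments of the human cohort the task was designed around. No
#' behavioural coupling to AQ is asserted; the covariate exists so
#' AQ-interaction code paths are exercisable.
#'
#' @param n Number of scores.
#' @param mean,sd Moments of the underlying normal.
#' @param seed Optional seed.
#' @return Integer vector of length `n`.
#' @export
sample_aq_scores <- function(n, mean = 21.43, sd = 5.89, seed = NULL) {
  with_seed(seed, {
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- x < 0 | x > 50)) {
      x[bad] <- stats::rnorm(sum(bad), mean, sd)
    }
    as.integer(round(x))
  })
}

# Which policies can start from the current direction (index 1..8)?
applicable_policies <- function(dir_idx) {
  cardinal <- dir_idx %in% c(1L, 3L, 5L, 7L) # R, D, L, U
  ok <- c(
    Horizontal = dir_idx %in% c(1L, 5L),
    Vertical = dir_idx %in% c(3L, 7L),
    PerpendicularCardinal = cardinal,
    NonCardinal = TRUE,
    HesitantStraight = TRUE,
    Circle = cardinal # 45-deg circle steps; even count keeps ends cardinal
  )
  names(ok) <- POLICY_LEVELS
  ok
}

#' Generate a policy-driven synthetic mouse trace
#'
#' Builds a piecewise-constant-direction cursor trace from runs of at
#' least 3 frames (so every intended turn satisfies the 3-frames-before /
#' 3-frames-after turn definition), with turn events drawn from the
#' profile's policy weights (restricted to policies applicable from the
#' current direction) and optional pauses. Ground-truth annotations are
#' returned so the turn detector and policy classifier can be
#' cross-validated against the generator.
#'
#' @param profile An [agent_profile()].
#' @param cfg A [task_config()] (supplies frame count and rate).
#' @param seed Optional seed.
#' @return List with `trace` (frames x 2 displacement matrix),
#'   `annotations` (`data.frame` frame, policy: one row per intended turn
#'   event, frame = onset of the post-turn direction) and `dirs`
#'   (per-frame direction index, `NA` while paused).
#' @export
generate_mouse_trace <- function(profile, cfg, seed = NULL) {
  with_seed(seed, {
    nf <- cfg$frames_per_trial
    w <- profile$policy_weights
    runs_dir <- integer(0) # direction index per run, NA = pause
    runs_len <- integer(0)
    ann_policy <- character(0)
    ann_run <- integer(0) # index of the run whose onset is the event

    startable <- vapply(seq_len(8L), function(d) {
      any(w[applicable_policies(d)] > 0)
    }, logical(1))
    cand <- which(startable & seq_len(8L) %in% c(1L, 3L, 5L, 7L))
    if (length(cand) == 0L) cand <- which(startable)
    if (length(cand) == 0L) cand <- c(1L, 3L, 5L, 7L)
    cur <- if (length(cand) == 1L) cand else sample(cand, 1L)
    push <- function(dir, len) {
      runs_dir[[length(runs_dir) + 1L]] <<- dir
      runs_len[[length(runs_len) + 1L]] <<- len
    }
    push(cur, sample(6:20, 1L))
    total <- runs_len[1L]

    rot45 <- function(d, k) ((d - 1L + k) %% 8L) + 1L
    while (total < nf) {
      ok <- applicable_policies(cur) & w > 0
      probs <- w[ok]
      pol <- if (length(probs) == 0L) "NonCardinal" else
        sample(names(probs), 1L, prob = probs)

      if (pol != "HesitantStraight" && stats::runif(1) < profile$pause_prob) {
        push(NA_integer_, sample(4:30, 1L))
      }
      if (pol == "Horizontal" || pol == "Vertical") {
        cur <- rot45(cur, 4L)
        push(cur, sample(4:20, 1L))
        ann_policy <- c(ann_policy, pol)
        ann_run <- c(ann_run, length(runs_dir))
      } else if (pol == "PerpendicularCardinal") {
        cur <- rot45(cur, sample(c(-2L, 2L), 1L))
        push(cur, sample(4:20, 1L))
        ann_policy <- c(ann_policy, pol)
        ann_run <- c(ann_run, length(runs_dir))
      } else if (pol == "NonCardinal") {
        cardinal <- cur %in% c(1L, 3L, 5L, 7L)
        step <- if (cardinal) sample(c(-3L, -1L, 1L, 3L), 1L) else
          sample(c(-3L, -2L, -1L, 1L, 2L, 3L), 1L)
        cur <- rot45(cur, step)
        # dwell on diagonals longer than the classifier's corner window so
        # an intended pair of non-cardinal turns is not collapsed into a
        # rounded corner
        push(cur, if (cur %in% c(1L, 3L, 5L, 7L)) sample(4:20, 1L) else
          sample(16:24, 1L))
        ann_policy <- c(ann_policy, pol)
        ann_run <- c(ann_run, length(runs_dir))
      } else if (pol == "HesitantStraight") {
        push(NA_integer_, sample(3:12, 1L))
        push(cur, sample(4:20, 1L))
        ann_policy <- c(ann_policy, pol)
        ann_run <- c(ann_run, length(runs_dir))
      } else { # Circle: even number of same-rotation 45-deg turns
        k <- sample(c(4L, 6L), 1L)
        rot <- sample(c(-1L, 1L), 1L)
        first_turn_run <- length(runs_dir) + 1L
        for (i in seq_len(k)) {
          cur <- rot45(cur, rot)
          # long exit dwell keeps later turns outside the circle-collapse
          # window
          push(cur, if (i < k) sample(3:4, 1L) else sample(24:30, 1L))
        }
        ann_policy <- c(ann_policy, "Circle")
        ann_run <- c(ann_run, first_turn_run)
      }
      total <- sum(runs_len)
    }

    run_start <- cumsum(c(1L, runs_len[-length(runs_len)]))
    dirs <- rep(runs_dir, runs_len)[seq_len(nf)]
    ann_frame <- run_start[ann_run]
    keep <- ann_frame <= nf - 3L
    annotations <- data.frame(frame = ann_frame[keep],
                              policy = ann_policy[keep])

    speed <- rep(profile$base_speed_px_per_frame *
                   exp(stats::rnorm(length(runs_len), 0, 0.15)),
                 runs_len)[seq_len(nf)]
    speed[is.na(dirs)] <- 0
    ang <- deg2rad(DIRECTION_ANGLES[ifelse(is.na(dirs), 1L, dirs)])
    trace <- cbind(dx = speed * cos(ang), dy = speed * sin(ang))
    list(trace = trace, annotations = annotations, dirs = dirs)
  })
}

# Per-frame one-step prediction error for every square: distance between
# each square's actual position and where it would be had it followed the
# mouse from its own previous position (wrap-aware).
one_step_pe_matrix <- function(trial) {
  nf <- nrow(trial$mouse)
  ns <- ncol(trial$squares_x)
  prev_x <- rbind(trial$init_xy[, 1], trial$squares_x[-nf, , drop = FALSE])
  prev_y <- rbind(trial$init_xy[, 2], trial$squares_y[-nf, , drop = FALSE])
  exp_x <- prev_x + trial$mouse[, 1]
  exp_y <- prev_y + trial$mouse[, 2]
  torus_dist(exp_x, exp_y, trial$squares_x, trial$squares_y,
             trial$cfg$screen_w, trial$cfg$screen_h)
}

#' Simulate the gaze of a threshold-switching agent
#'
#' The agent fixates the centroid of one hypothesised square. The one-step
#' prediction error of that square feeds a leaky accumulator
#' (`acc <- decay * acc + pe`); when the accumulator exceeds
#' `switch_threshold_px` (and the refractory period has elapsed) the
#' current agential hypothesis is abandoned for the square with the lowest
#' recent one-step error, operationalising switch-at-threshold hypothesis
#' testing.
#'
#' @param trial A `trial_log`.
#' @param profile An [agent_profile()].
#' @param seed Optional seed (initial hypothesis is random).
#' @return List with `gaze` (frames x 2), `hypothesis` (per-frame square
#'   index), `switch_frames` (ground-truth switch onsets) and `pe_matrix`
#'   (frames x n_squares one-step PE, the agent's evidence).
#' @export
simulate_gaze_agent <- function(trial, profile, seed = NULL) {
  with_seed(seed, {
    pe <- one_step_pe_matrix(trial)
    nf <- nrow(pe)
    ns <- ncol(pe)
    hyp <- integer(nf)
    cur <- sample.int(ns, 1L)
    acc <- 0
    last_switch <- -Inf
    switches <- integer(0)
    decay <- profile$accumulator_decay
    thr <- profile$switch_threshold_px
    refr <- profile$refractory_frames
    for (t in seq_len(nf)) {
      acc <- decay * acc + pe[t, cur]
      if (acc > thr && (t - last_switch) > refr) {
        recent <- colMeans(pe[max(1L, t - 11L):t, , drop = FALSE])
        best <- which.min(recent)
        if (best != cur) {
          cur <- best
          switches <- c(switches, t)
          last_switch <- t
        }
        acc <- 0
      }
      hyp[t] <- cur
    }
    idx <- cbind(seq_len(nf), hyp)
    gaze <- cbind(trial$squares_x[idx], trial$squares_y[idx])
    list(gaze = gaze, hypothesis = hyp, switch_frames = switches,
         pe_matrix = pe)
  })
}

#' Inject eye-tracker artifacts into a clean gaze trace
#'
#' Upsamples the frame-rate gaze to the tracker's native rate and adds the
#' artifacts the preprocessing stage must remove: correlated binocular
#' Gaussian noise with a small fixed disparity, Poisson blink events
#' (pupil collapse plus gaze dropout, 100-300 ms, binocular) and
#' occasional off-screen excursions.
#'
#' @param gaze frames x 2 matrix of clean gaze positions.
#' @param profile An [agent_profile()] (noise SD, blink rate).
#' @param cfg A [task_config()].
#' @param native_rate Tracker sampling rate, Hz (default 1000).
#' @param offscreen_prob Probability of one short off-screen excursion.
#' @param seed Optional seed.
#' @return `data.frame` with columns t, x_l, y_l, p_l, x_r, y_r, p_r; gaze
#'   is `NA` during blinks. Attribute `blink_spans` records the injected
#'   ground truth (sample index ranges).
#' @export
inject_eye_noise <- function(gaze, profile, cfg, native_rate = 1000,
                             offscreen_prob = 0.3, seed = NULL) {
  with_seed(seed, {
    nf <- nrow(gaze)
    dur <- nf / cfg$fps
    n <- round(dur * native_rate)
    t <- (seq_len(n) - 0.5) / native_rate
    tf <- (seq_len(nf) - 0.5) / cfg$fps
    gx <- stats::approx(tf, gaze[, 1], xout = t, rule = 2)$y
    gy <- stats::approx(tf, gaze[, 2], xout = t, rule = 2)$y

    sdn <- profile$gaze_noise_sd_px
    shared_x <- stats::rnorm(n, 0, sdn * 0.7)
    shared_y <- stats::rnorm(n, 0, sdn * 0.7)
    x_l <- gx + shared_x + stats::rnorm(n, 0, sdn * 0.5) - 3
    x_r <- gx + shared_x + stats::rnorm(n, 0, sdn * 0.5) + 3
    y_l <- gy + shared_y + stats::rnorm(n, 0, sdn * 0.5)
    y_r <- gy + shared_y + stats::rnorm(n, 0, sdn * 0.5)
    p_l <- 1000 + stats::rnorm(n, 0, 15)
    p_r <- 1000 + stats::rnorm(n, 0, 15)

    n_blinks <- stats::rpois(1, profile$blink_rate_hz * dur)
    spans <- NULL
    if (n_blinks > 0L) {
      min_gap <- round(0.5 * native_rate)
      max_len <- round(0.3 * native_rate)
      n_place <- n_blinks
      onsets <- NULL
      repeat {
        onsets <- try(sample_spaced_frames(n_place, 1L, n - max_len,
                                           min_gap), silent = TRUE)
        if (!inherits(onsets, "try-error")) break
        n_place <- n_place - 1L
        if (n_place == 0L) break
      }
      if (!is.null(onsets) && length(onsets) > 0L) {
        lens <- round(stats::runif(length(onsets), 0.1, 0.3) * native_rate)
        spans <- cbind(start = onsets, end = pmin(onsets + lens - 1L, n))
        for (i in seq_len(nrow(spans))) {
          s <- spans[i, 1]:spans[i, 2]
          x_l[s] <- NA; y_l[s] <- NA; x_r[s] <- NA; y_r[s] <- NA
          p_l[s] <- 150 + stats::rnorm(length(s), 0, 10)
          p_r[s] <- 150 + stats::rnorm(length(s), 0, 10)
        }
      }
    }

    if (stats::runif(1) < offscreen_prob) {
      len <- round(stats::runif(1, 0.05, 0.1) * native_rate)
      at <- sample.int(n - len, 1L)
      s <- at:(at + len - 1L)
      x_l[s] <- cfg$screen_w + 50
      x_r[s] <- cfg$screen_w + 50
    }

    out <- data.frame(t = t, x_l = x_l, y_l = y_l, p_l = p_l,
                      x_r = x_r, y_r = y_r, p_r = p_r)
    attr(out, "blink_spans") <- spans
    out
  })
}

#' End-of-trial judgement of agency
#'
#' The agent reports the square with the smallest mean one-step prediction
#' error over the judgement window, or `0` ("I controlled none of them")
#' if even that minimum exceeds `no_agency_cutoff_px`.
#'
#' @param pe_by_square frames x n_squares matrix of one-step PE over the
#'   judgement window (rows with missing values are ignored per column).
#' @param profile An [agent_profile()].
#' @return Integer: a square index, or `0L` for "no control".
#' @export
judge_agency <- function(pe_by_square, profile) {
  pe_by_square <- as.matrix(pe_by_square)
  if (nrow(pe_by_square) < 1L || all(is.na(pe_by_square))) {
    stop("judge_agency needs at least one frame of PE evidence",
         call. = FALSE)
  }
  m <- colMeans(pe_by_square, na.rm = TRUE)
  if (min(m, na.rm = TRUE) < profile$no_agency_cutoff_px) {
    which.min(m)
  } else {
    0L
  }
}
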