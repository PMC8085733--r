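# Independent oracles and fixture builders shared across test files.
# Oracles implement the definitions directly (window scans, brute-force
# geometry) and never reuse the package's code paths.

# Window-scanning turn oracle: a turn at position i needs three equal
# frames before and three (including i) after, and a direction change.
oracle_turn_frames <- function(d) {
  n <- length(d)
  out <- integer(0)
  if (n < 6L) return(out)
  for (i in 4:(n - 2)) {
    if (d[i] != d[i - 1] &&
        d[i - 3] == d[i - 1] && d[i - 2] == d[i - 1] &&
        d[i + 1] == d[i] && d[i + 2] == d[i]) {
      out <- c(out, i)
    }
  }
  out
}

# Definitional hypothesis-switch oracle: scan for changes relative to the
# current accepted square that persist for at least two frames.
oracle_switch_frames <- function(x) {
  n <- length(x)
  first <- which(!is.na(x))[1]
  if (is.na(first)) return(integer(0))
  cur <- x[first]
  out <- integer(0)
  t <- first + 1L
  while (t <= n) {
    if (!is.na(x[t]) && x[t] != cur) {
      runlen <- 1L
      while (t + runlen <= n && !is.na(x[t + runlen]) &&
             x[t + runlen] == x[t]) runlen <- runlen + 1L
      if (runlen >= 2L) {
        out <- c(out, t)
        cur <- x[t]
      }
      t <- t + runlen
    } else {
      t <- t + 1L
    }
  }
  out
}

# Independent minimum-image signed difference (oracle reimplementation).
torus_delta_test <- function(a, b, period) {
  d <- (a - b) %% period
  ifelse(d > period / 2, d - period, d)
}

# Brute-force wrap-aware nearest square.
oracle_nearest <- function(gx, gy, sx, sy, w, h) {
  dx <- abs(gx - sx); dx <- pmin(dx, w - dx)
  dy <- abs(gy - sy); dy <- pmin(dy, h - dy)
  which.min(sqrt(dx^2 + dy^2))
}

# Hand-built trial log on a quiet screen: squares follow prescribed
# per-frame displacements (no jitter bookkeeping needed for PE tests).
manual_trial <- function(init_xy, disp_x, disp_y, mouse, cfg = NULL,
                         target = 1L) {
  cfg <- cfg %||% task_config("low", "low")
  nf <- nrow(mouse)
  ns <- nrow(init_xy)
  sx <- (matrix(init_xy[, 1], nf, ns, byrow = TRUE) +
           apply(disp_x, 2, cumsum)) %% cfg$screen_w
  sy <- (matrix(init_xy[, 2], nf, ns, byrow = TRUE) +
           apply(disp_y, 2, cumsum)) %% cfg$screen_h
  structure(list(trial_id = 1L, participant = 1L, block = 1L,
                 condition = c(variability = cfg$variability_level,
                               volatility = cfg$volatility_level),
                 is_no_control = FALSE, target_index = target,
                 mouse = mouse, init_xy = init_xy,
                 squares_x = sx, squares_y = sy,
                 jitter_state = rep("narrow", nf),
                 jitter_deg = matrix(0, nf, ns),
                 offsets_deg = matrix(0, nf, ns),
                 schedule = NULL, seed = NULL, cfg = cfg),
            class = "trial_log")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Raw binocular eye trace with no artifacts: constant or supplied gaze.
clean_raw_trace <- function(n = 3000, rate = 1000, x = 960, y = 540,
                            pupil = 1000) {
  t <- (seq_len(n) - 0.5) / rate
  data.frame(t = t,
             x_l = rep_len(x, n), y_l = rep_len(y, n),
             p_l = rep_len(pupil, n),
             x_r = rep_len(x, n), y_r = rep_len(y, n),
             p_r = rep_len(pupil, n))
}

# Trial-grain table with a known planted variability effect and
# by-participant intercepts; used for power / type-I calibration.
make_synthetic_table <- function(n_part = 30, trials_per_cell = 4,
                                 effect = 0, seed = 1,
                                 part_sd = 1, resid_sd = 2) {
  set.seed(seed)
  grid <- expand.grid(participant = seq_len(n_part),
                      variability = c("low", "high"),
                      volatility = c("low", "high"),
                      rep = seq_len(trials_per_cell),
                      stringsAsFactors = FALSE)
  aq <- sample_aq_scores(n_part)
  b <- rnorm(n_part, 0, part_sd)
  grid$aq_score <- aq[grid$participant]
  grid$dv <- 10 + effect * (grid$variability == "high") +
    b[grid$participant] + rnorm(nrow(grid), 0, resid_sd)
  grid
}

# One scaled-down synthetic cohort reused by the acceptance criteria:
# 40 agents, 1 block per condition, 8 agentive + 2 no-control trials per
# block, 500 Hz eye tracker (documented scale-down of the full design).
acceptance_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- run_pipeline(n_participants = 40L, seed = 2024L,
                             blocks_per_condition = 1L,
                             agentive_per_block = 8L,
                             nocontrol_per_block = 2L,
                             native_rate = 500)
    }
    cache
  }
})
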