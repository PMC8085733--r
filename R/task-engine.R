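# Stimulus engine: volatility schedules, angular jitter, distractor
# offsets, square kinematics, full trial simulation.

#' Generate a within-trial volatility schedule
#'
#' Places the configured number of jitter-state changes pseudo-randomly in
#' the trial, at least `min_change_gap_frames` apart and at least
#' `start_margin_frames` from trial start. The jitter state starts in a
#' randomly chosen element of the (narrow, wide) pair and alternates at
#' every change.
#'
#' @param cfg A [task_config()].
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return A `volatility_schedule`: list with `change_frames` (ordered
#'   1-based frame indices), `state_per_frame` (character vector, one of
#'   `"narrow"`/`"wide"` per frame) and `start_state`.
#' @examples
#' sch <- make_volatility_schedule(task_config("low", "high"), seed = 1)
#' length(sch$change_frames) # 10
#' @export
make_volatility_schedule <- function(cfg, seed = NULL) {
  validate_task_config(cfg)
  with_seed(seed, {
    n <- cfg$n_volatility_changes
    change_frames <- if (n > 0L) {
      sample_spaced_frames(n,
                           first = cfg$start_margin_frames + 1L,
                           last = cfg$frames_per_trial,
                           gap = cfg$min_change_gap_frames)
    } else {
      integer(0)
    }
    start_state <- sample(c("narrow", "wide"), 1L)
    state <- rep(start_state, cfg$frames_per_trial)
    if (n > 0L) {
      states <- c("narrow", "wide")
      cur <- start_state
      bounds <- c(change_frames, cfg$frames_per_trial + 1L)
      for (i in seq_len(n)) {
        cur <- setdiff(states, cur)
        state[bounds[i]:(bounds[i + 1L] - 1L)] <- cur
      }
    }
    structure(list(change_frames = change_frames,
                   state_per_frame = state,
                   start_state = start_state),
              class = "volatility_schedule")
  })
}

#' Sample angular jitter for a given 95% CI half-width
#'
#' Jitter is zero-mean Gaussian on the angle with standard deviation
#' `ci_halfwidth_deg / qnorm(0.975)`, so the two-sided 95% interval of the
#' draws has the configured half-width.
#'
#' @param ci_halfwidth_deg Positive half-width of the 95% CI, in degrees.
#' @param n Number of draws.
#' @param seed Optional seed.
#' @return Numeric vector of angular offsets in degrees.
#' @export
sample_jitter_angle <- function(ci_halfwidth_deg, n = 1L, seed = NULL) {
  if (!is.numeric(ci_halfwidth_deg) || length(ci_halfwidth_deg) != 1L ||
      ci_halfwidth_deg <= 0) {
    stop("ci_halfwidth_deg must be a single positive number", call. = FALSE)
  }
  with_seed(seed, stats::rnorm(n, mean = 0,
                               sd = ci_halfwidth_deg / stats::qnorm(0.975)))
}

#' Per-frame angular offsets for distractor squares
#'
#' Each distractor starts at an offset uniform on `[0, 360)` degrees. The
#' offset is redrawn `distractor_redraws` times at pseudo-random frames
#' (spaced so transitions cannot overlap) and moves to each new value by
#' linear shortest-arc interpolation over `offset_transition_frames`
#' frames; with a zero-length transition the change is a step.
#'
#' @param cfg A [task_config()].
#' @param n_distractors Number of distractor squares.
#' @param seed Optional seed.
#' @return List with `offsets` (frames x n_distractors matrix, degrees in
#'   `[0, 360)`) and `redraw_frames` (n_redraws x n_distractors matrix of
#'   redraw onset frames).
#' @export
make_distractor_offsets <- function(cfg, n_distractors, seed = NULL) {
  validate_task_config(cfg)
  nf <- cfg$frames_per_trial
  nr <- cfg$distractor_redraws
  with_seed(seed, {
    offsets <- matrix(0, nrow = nf, ncol = n_distractors)
    redraws <- matrix(integer(0), nrow = nr, ncol = n_distractors)
    gap <- max(cfg$offset_transition_frames + 2L, 60L)
    for (d in seq_len(n_distractors)) {
      value <- stats::runif(1, 0, 360)
      trace <- rep(value, nf)
      if (nr > 0L) {
        at <- sample_spaced_frames(nr, first = 60L,
                                   last = nf - cfg$offset_transition_frames,
                                   gap = gap)
        redraws[, d] <- at
        for (f in at) {
          new <- stats::runif(1, 0, 360)
          delta <- shortest_arc_delta(value, new)
          tw <- cfg$offset_transition_frames
          if (tw > 0L) {
            ramp <- value + delta * seq_len(tw) / tw
            trace[f:(f + tw - 1L)] <- ramp %% 360
            if (f + tw <= nf) trace[(f + tw):nf] <- new %% 360
          } else {
            trace[f:nf] <- new %% 360
          }
          value <- new
        }
      }
      offsets[, d] <- trace %% 360
    }
    list(offsets = offsets, redraw_frames = redraws)
  })
}

#' Advance all squares by one frame
#'
#' Every square moves by the magnitude of the mouse displacement, in the
#' direction of the mouse angle plus its angular offset (zero for the
#' target) plus its jitter draw. A zero mouse displacement leaves all
#' squares exactly where they are. Positions wrap toroidally.
#'
#' @param pos n_squares x 2 matrix of current (x, y) positions in pixels.
#' @param mouse_dx,mouse_dy Mouse displacement for this frame, pixels.
#' @param jitter_deg Per-square jitter draws, degrees.
#' @param offset_deg Per-square angular offsets, degrees (0 for target).
#' @param screen_w,screen_h Screen size for wrapping.
#' @return n_squares x 2 matrix of next positions.
#' @export
step_squares <- function(pos, mouse_dx, mouse_dy, jitter_deg, offset_deg,
                         screen_w, screen_h) {
  mag <- sqrt(mouse_dx^2 + mouse_dy^2)
  if (mag == 0) return(pos)
  ang <- atan2(mouse_dy, mouse_dx) + deg2rad(offset_deg + jitter_deg)
  nxt <- pos + mag * cbind(cos(ang), sin(ang))
  nxt[, 1] <- nxt[, 1] %% screen_w
  nxt[, 2] <- nxt[, 2] %% screen_h
  nxt
}

# Uniform non-overlapping initial placement (>= min_sep between centres).
place_squares <- function(cfg, min_sep = 120) {
  n <- cfg$n_squares
  pos <- matrix(NA_real_, n, 2)
  half <- cfg$square_size_px / 2
  for (i in seq_len(n)) {
    repeat {
      cand <- c(stats::runif(1, half, cfg$screen_w - half),
                stats::runif(1, half, cfg$screen_h - half))
      if (i == 1L) break
      d <- sqrt((pos[seq_len(i - 1L), 1] - cand[1])^2 +
                (pos[seq_len(i - 1L), 2] - cand[2])^2)
      if (all(d >= min_sep)) break
    }
    pos[i, ] <- cand
  }
  pos
}

#' Simulate one trial of the Squares Task
#'
#' Runs the closed-loop stimulus for a supplied mouse trace: draws the
#' volatility schedule, target identity (agentive trials only), distractor
#' offsets and per-frame jitter, and integrates all square positions with
#' toroidal wrapping. In no-control trials all squares carry distractor
#' offsets and there is no target. Stationary mouse frames consume no
#' jitter and move nothing.
#'
#' @param cfg A [task_config()].
#' @param mouse_trace frames x 2 matrix of per-frame (dx, dy) mouse
#'   displacements in pixels.
#' @param is_no_control Logical; if `TRUE`, all squares are distractors.
#' @param seed Optional seed; the same cfg + trace + seed reproduce the
#'   trial bit-for-bit.
#' @param offset_init Optional fixed initial offset (degrees) applied to
#'   every distractor instead of a uniform draw; used with
#'   `cfg$distractor_redraws = 0` for structural diagnostics.
#' @return A `trial_log` object: per-frame square positions
#'   (`squares_x`/`squares_y`, frames x n_squares), initial positions
#'   (`init_xy`), mouse trace, per-frame `jitter_state` and jitter draws,
#'   per-frame offset matrix, target index, schedule, condition and seed.
#' @export
simulate_trial <- function(cfg, mouse_trace, is_no_control = FALSE,
                           seed = NULL, offset_init = NULL) {
  validate_task_config(cfg)
  mouse_trace <- as.matrix(mouse_trace)
  if (nrow(mouse_trace) != cfg$frames_per_trial || ncol(mouse_trace) != 2L) {
    stop("mouse_trace must be a ", cfg$frames_per_trial,
         " x 2 matrix of per-frame displacements", call. = FALSE)
  }
  with_seed(seed, {
    nf <- cfg$frames_per_trial
    ns <- cfg$n_squares
    schedule <- make_volatility_schedule(cfg)
    target_index <- if (is_no_control) NA_integer_ else sample.int(ns, 1L)

    distractors <- if (is_no_control) seq_len(ns) else setdiff(seq_len(ns), target_index)
    offs <- matrix(0, nf, ns)
    if (length(distractors) > 0L) {
      if (is.null(offset_init)) {
        dd <- make_distractor_offsets(cfg, length(distractors))
        offs[, distractors] <- dd$offsets
      } else {
        offs[, distractors] <- offset_init %% 360
      }
    }

    mag <- sqrt(mouse_trace[, 1]^2 + mouse_trace[, 2]^2)
    moving <- mag > 0
    ci <- ifelse(schedule$state_per_frame == "narrow",
                 cfg$ci_pair_deg[1], cfg$ci_pair_deg[2])
    jitter <- matrix(0, nf, ns)
    if (any(moving)) {
      sd_frame <- ci[moving] / stats::qnorm(0.975)
      jitter[moving, ] <- stats::rnorm(sum(moving) * ns, 0,
                                       rep(sd_frame, times = ns))
    }

    base_ang <- atan2(mouse_trace[, 2], mouse_trace[, 1])
    ang <- base_ang + deg2rad(offs + jitter) # recycled per column
    dx <- mag * cos(ang)
    dy <- mag * sin(ang)
    dx[!moving, ] <- 0
    dy[!moving, ] <- 0

    init_xy <- place_squares(cfg)
    squares_x <- (matrix(init_xy[, 1], nf, ns, byrow = TRUE) +
                    apply(dx, 2, cumsum)) %% cfg$screen_w
    squares_y <- (matrix(init_xy[, 2], nf, ns, byrow = TRUE) +
                    apply(dy, 2, cumsum)) %% cfg$screen_h

    structure(list(
      trial_id = NA_integer_,
      participant = NA_integer_,
      block = NA_integer_,
      condition = c(variability = cfg$variability_level,
                    volatility = cfg$volatility_level),
      is_no_control = is_no_control,
      target_index = target_index,
      mouse = mouse_trace,
      init_xy = init_xy,
      squares_x = squares_x,
      squares_y = squares_y,
      jitter_state = schedule$state_per_frame,
      jitter_deg = jitter,
      offsets_deg = offs,
      schedule = schedule,
      seed = seed,
      cfg = cfg
    ), class = "trial_log")
  })
}

#' @export
print.trial_log <- function(x, ...) {
  cat("<trial_log> ", nrow(x$mouse), " frames, ", ncol(x$squares_x),
      " squares, ", paste(x$condition, collapse = "/"),
      if (x$is_no_control) ", no-control" else
        paste0(", target ", x$target_index), "\n", sep = "")
  invisible(x)
}

#' Tidy per-frame view of a trial log
#'
#' One row per frame per square, matching the interchange schema used by
#' [write_trial_logs()].
#'
#' @param x A `trial_log`.
#' @param ... Unused.
#' @return A `data.frame` with columns participant, block, trial, frame,
#'   square, x, y, mouse_dx, mouse_dy, jitter_state, offset_deg,
#'   is_target, is_no_control.
#' @export
as.data.frame.trial_log <- function(x, ...) {
  nf <- nrow(x$mouse)
  ns <- ncol(x$squares_x)
  data.frame(
    participant = rep(x$participant, nf * ns),
    block = rep(x$block, nf * ns),
    trial = rep(x$trial_id, nf * ns),
    frame = rep(seq_len(nf), times = ns),
    square = rep(seq_len(ns), each = nf),
    x = as.vector(x$squares_x),
    y = as.vector(x$squares_y),
    mouse_dx = rep(x$mouse[, 1], times = ns),
    mouse_dy = rep(x$mouse[, 2], times = ns),
    jitter_state = rep(x$jitter_state, times = ns),
    offset_deg = as.vector(x$offsets_deg),
    is_target = rep(seq_len(ns), each = nf) ==
      (if (is.na(x$target_index)) -1L else x$target_index),
    is_no_control = rep(x$is_no_control, nf * ns)
  )
}

#' Block and trial plan for one participant
#'
#' Two blocks of each of the four variability x volatility conditions, 18
#' trials per block (16 agentive + 2 no-control, positions shuffled),
#' block order randomised per participant.
#'
#' @param seed Optional seed.
#' @param blocks_per_condition,agentive_per_block,nocontrol_per_block
#'   Design counts; defaults are the full design (2, 16, 2).
#' @return `data.frame` with one row per trial: block, variability,
#'   volatility, trial (within block), is_no_control.
#' @export
build_experiment_schedule <- function(seed = NULL,
                                      blocks_per_condition = 2L,
                                      agentive_per_block = 16L,
                                      nocontrol_per_block = 2L) {
  with_seed(seed, {
    cells <- expand.grid(variability = c("low", "high"),
                         volatility = c("low", "high"),
                         rep = seq_len(blocks_per_condition),
                         stringsAsFactors = FALSE)
    cells <- cells[sample.int(nrow(cells)), , drop = FALSE]
    npb <- agentive_per_block + nocontrol_per_block
    out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(b) {
      nc <- sample(c(rep(FALSE, agentive_per_block),
                     rep(TRUE, nocontrol_per_block)))
      data.frame(block = b,
                 variability = cells$variability[b],
                 volatility = cells$volatility[b],
                 trial = seq_len(npb),
                 is_no_control = nc)
    }))
    rownames(out) <- NULL
    out
  })
}
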