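# Cursor behaviour: kinematics, time moving, 8-direction discretisation,
# turn detection, six-way policy classification, dominant-policy stats and
# the motor-control index.

#' Per-frame cursor kinematics
#'
#' Speed is the displacement magnitude per frame, acceleration its first
#' difference and jerk the first difference of acceleration. Means are
#' taken over moving frames only (speed > `eps`); differences are aligned
#' to the later frame.
#'
#' @param mouse_trace frames x 2 matrix of (dx, dy) per frame, pixels.
#' @param eps Moving threshold in px/frame (default 0.1).
#' @return List with per-frame `speed`, `accel`, `jerk` and scalar
#'   `mean_speed`, `mean_accel`, `mean_jerk` (`NA` when undefined).
#' @export
compute_kinematics <- function(mouse_trace, eps = 0.1) {
  mouse_trace <- as.matrix(mouse_trace)
  if (nrow(mouse_trace) < 4L) stop("trace too short (< 4 frames)",
                                   call. = FALSE)
  speed <- sqrt(mouse_trace[, 1]^2 + mouse_trace[, 2]^2)
  accel <- diff(speed)
  jerk <- diff(accel)
  moving <- speed > eps
  if (!any(moving)) {
    return(list(speed = speed, accel = accel, jerk = jerk,
                mean_speed = 0, mean_accel = NA_real_,
                mean_jerk = NA_real_))
  }
  list(speed = speed, accel = accel, jerk = jerk,
       mean_speed = mean(speed[moving]),
       mean_accel = mean(accel[moving[-1L]]),
       mean_jerk = mean(jerk[moving[-c(1L, 2L)]]))
}

#' Time spent moving and movement onset
#'
#' @param mouse_trace frames x 2 displacement matrix.
#' @param fps Frame rate (default 60).
#' @param eps Moving threshold, px/frame.
#' @return List with `time_moving_s` (moving-frame count / fps) and
#'   `onset_s` (first moving frame / fps, `NA` if never moving).
#' @export
time_spent_moving <- function(mouse_trace, fps = 60, eps = 0.1) {
  speed <- sqrt(mouse_trace[, 1]^2 + mouse_trace[, 2]^2)
  moving <- speed > eps
  list(time_moving_s = sum(moving) / fps,
       onset_s = if (any(moving)) (which(moving)[1L] - 1L) / fps
                 else NA_real_)
}

#' Discretise movement angles into eight directions
#'
#' Assigns each moving frame's angle to the nearest of eight directions at
#' 45-degree spacing (R, DR, D, DL, L, UL, U, UR; y-down, clockwise).
#' Sector half-width is 22.5 degrees; an angle exactly on a boundary goes
#' to the clockwise-next sector. Stationary frames get `NA`.
#'
#' @param mouse_trace frames x 2 displacement matrix.
#' @param eps Moving threshold, px/frame.
#' @return Integer vector of direction indices 1..8 (`NA` when
#'   stationary), with the level names in attribute `levels`.
#' @export
discretise_directions <- function(mouse_trace, eps = 0.1) {
  speed <- sqrt(mouse_trace[, 1]^2 + mouse_trace[, 2]^2)
  ang <- (atan2(mouse_trace[, 2], mouse_trace[, 1]) * 180 / pi) %% 360
  idx <- (floor((ang + 22.5) / 45) %% 8) + 1L
  idx[speed <= eps] <- NA_integer_
  idx <- as.integer(idx)
  attr(idx, "levels") <- DIRECTION_LEVELS
  idx
}

#' Detect turns in a direction sequence
#'
#' A turn is a change in direction preceded by at least three frames of
#' one direction and sustained for at least three frames. The sequence is
#' taken over moving frames only (`NA`s, i.e. stationary frames, are
#' removed first and do not end a direction run). Overlapping
#' qualifications are resolved left to right by run-length encoding.
#'
#' @param dirs Integer direction sequence (1..8, `NA` = stationary), as
#'   from [discretise_directions()].
#' @param frames Optional original frame indices of `dirs` (defaults to
#'   `seq_along(dirs)`); reported turn frames refer to these.
#' @return `data.frame` with one row per turn: `frame` (onset frame of the
#'   new direction), `dir_from`, `dir_to`.
#' @export
detect_turns <- function(dirs, frames = seq_along(dirs)) {
  keep <- !is.na(dirs)
  d <- dirs[keep]
  f <- frames[keep]
  empty <- data.frame(frame = integer(0), dir_from = integer(0),
                      dir_to = integer(0))
  if (length(d) < 6L) return(empty)
  r <- rle(d)
  if (length(r$lengths) < 2L) return(empty)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- seq_len(length(r$lengths) - 1L)
  ok <- r$lengths[i] >= 3L & r$lengths[i + 1L] >= 3L
  data.frame(frame = f[starts[i + 1L][ok]],
             dir_from = r$values[i][ok],
             dir_to = r$values[i + 1L][ok])
}

#' Detect hesitant-straight events
#'
#' A full stop of at least `min_stop` stationary frames followed by
#' resumption of the same direction (with at least three moving frames on
#' each side) counts as a Hesitant-straight turn: the participant
#' interrupts and then re-commits to the same policy.
#'
#' @param dirs Direction sequence with `NA` for stationary frames (full
#'   per-frame vector, not stationary-stripped).
#' @param min_stop Minimum stationary run length (default 3).
#' @return `data.frame` with `frame` (resumption frame), `dir_from`,
#'   `dir_to` (equal).
#' @export
detect_hesitations <- function(dirs, min_stop = 3L) {
  n <- length(dirs)
  r <- rle(is.na(dirs))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- data.frame(frame = integer(0), dir_from = integer(0),
                    dir_to = integer(0))
  for (k in which(r$values & r$lengths >= min_stop)) {
    if (k == 1L || k == length(r$lengths)) next
    before <- dirs[seq_len(starts[k] - 1L)]
    before <- before[!is.na(before)]
    after_idx <- (ends[k] + 1L):n
    after <- dirs[after_idx]
    after <- after[!is.na(after)]
    if (length(before) < 3L || length(after) < 3L) next
    b <- utils::tail(before, 3L)
    a <- utils::head(after, 3L)
    if (length(unique(b)) == 1L && length(unique(a)) == 1L &&
        b[1L] == a[1L]) {
      out <- rbind(out, data.frame(frame = ends[k] + 1L,
                                   dir_from = b[1L], dir_to = a[1L]))
    }
  }
  out
}

# Signed rotation of a turn in 45-degree steps, in (-4, 4]; +4 (reversal)
# is ambiguous and returned as NA for rotation-sense purposes.
turn_rotation <- function(dir_from, dir_to) {
  d <- ((dir_to - dir_from + 4L) %% 8L) - 4L
  d[d == -4L] <- 4L
  ifelse(abs(d) == 4L, NA_integer_, d)
}

is_cardinal <- function(idx) idx %in% c(1L, 3L, 5L, 7L)

#' Classify turns into the six movement policies
#'
#' Operational definitions (pure functions of the direction sequence):
#' Horizontal / Vertical = 180-degree reversal on that axis;
#' Perpendicular-Cardinal = 90-degree turn between cardinal directions,
#' including "rounded corners" (cardinal-diagonal-cardinal two-step
#' 90-degree sequences, collapsed to one turn); Non-Cardinal = any turn
#' whose endpoints include a diagonal; Hesitant-straight = full stop of at
#' least three frames followed by the same direction; Circle = a run of
#' three or more same-rotation turns within `circle_window` frames,
#' collapsed to one turn. Collapsing runs circles first, then corners;
#' anything unclassifiable falls back to Non-Cardinal.
#'
#' @param turns Turn table from [detect_turns()].
#' @param hesitations Optional table from [detect_hesitations()].
#' @param circle_window Maximum frame span of a collapsed circle (30).
#' @param corner_window Maximum frame gap of a rounded corner's two
#'   sub-turns (15 frames).
#' @return `data.frame` with one row per (collapsed) turn: `frame`,
#'   `dir_from`, `dir_to`, `policy` (factor over the six types),
#'   `span_start`, `span_end` (collapsed range).
#' @export
classify_turn_policy <- function(turns, hesitations = NULL,
                                 circle_window = 30L, corner_window = 15L) {
  n <- nrow(turns)
  events <- if (n > 0L) {
    data.frame(frame = turns$frame, dir_from = turns$dir_from,
               dir_to = turns$dir_to, policy = NA_character_,
               span_start = turns$frame, span_end = turns$frame)
  } else {
    data.frame(frame = integer(0), dir_from = integer(0),
               dir_to = integer(0), policy = character(0),
               span_start = integer(0), span_end = integer(0))
  }

  if (nrow(events) > 0L) {
    rot <- turn_rotation(events$dir_from, events$dir_to)
    consumed <- rep(FALSE, nrow(events))
    collapsed <- list()

    # 1. circles: maximal runs of >= 3 same-rotation turns within window
    i <- 1L
    while (i <= nrow(events)) {
      if (is.na(rot[i]) || consumed[i]) { i <- i + 1L; next }
      j <- i
      while (j + 1L <= nrow(events) && !consumed[j + 1L] &&
             !is.na(rot[j + 1L]) && sign(rot[j + 1L]) == sign(rot[i]) &&
             events$frame[j + 1L] - events$frame[i] <= circle_window) {
        j <- j + 1L
      }
      if (j - i + 1L >= 3L) {
        collapsed[[length(collapsed) + 1L]] <- data.frame(
          frame = events$frame[i], dir_from = events$dir_from[i],
          dir_to = events$dir_to[j], policy = "Circle",
          span_start = events$frame[i], span_end = events$frame[j])
        consumed[i:j] <- TRUE
      }
      i <- j + 1L
    }

    # 2. rounded corners: two same-rotation 45-degree sub-turns,
    #    cardinal -> diagonal -> cardinal, close in time
    idx <- which(!consumed)
    for (k in seq_along(idx)[-length(idx)]) {
      a <- idx[k]; b <- idx[k + 1L]
      if (consumed[a] || consumed[b]) next
      if (!is.na(rot[a]) && !is.na(rot[b]) &&
          abs(rot[a]) == 1L && rot[b] == rot[a] &&
          is_cardinal(events$dir_from[a]) &&
          !is_cardinal(events$dir_to[a]) &&
          events$dir_from[b] == events$dir_to[a] &&
          is_cardinal(events$dir_to[b]) &&
          events$frame[b] - events$frame[a] <= corner_window) {
        collapsed[[length(collapsed) + 1L]] <- data.frame(
          frame = events$frame[a], dir_from = events$dir_from[a],
          dir_to = events$dir_to[b], policy = "PerpendicularCardinal",
          span_start = events$frame[a], span_end = events$frame[b])
        consumed[c(a, b)] <- TRUE
      }
    }

    # 3. remaining single turns
    singles <- events[!consumed, , drop = FALSE]
    if (nrow(singles) > 0L) {
      delta <- abs(((singles$dir_to - singles$dir_from + 4L) %% 8L) - 4L)
      delta[delta == 0L] <- 4L # wrapped reversal
      reversal <- ((singles$dir_to - singles$dir_from) %% 8L) == 4L
      pol <- rep("NonCardinal", nrow(singles))
      pol[reversal & singles$dir_from %in% c(1L, 5L)] <- "Horizontal"
      pol[reversal & singles$dir_from %in% c(3L, 7L)] <- "Vertical"
      pol[!reversal & delta == 2L & is_cardinal(singles$dir_from) &
            is_cardinal(singles$dir_to)] <- "PerpendicularCardinal"
      diag_pair <- !is_cardinal(singles$dir_from) |
        !is_cardinal(singles$dir_to)
      pol[diag_pair] <- "NonCardinal"
      singles$policy <- pol
    }
    events <- rbind(singles,
                    if (length(collapsed)) do.call(rbind, collapsed))
  }

  if (!is.null(hesitations) && nrow(hesitations) > 0L) {
    hes <- data.frame(frame = hesitations$frame,
                      dir_from = hesitations$dir_from,
                      dir_to = hesitations$dir_to,
                      policy = "HesitantStraight",
                      span_start = hesitations$frame,
                      span_end = hesitations$frame)
    events <- rbind(events, hes)
  }
  events <- events[order(events$frame), , drop = FALSE]
  rownames(events) <- NULL
  events$policy <- factor(events$policy, levels = POLICY_LEVELS)
  events
}

#' Full turn/policy analysis of one mouse trace
#'
#' @param mouse_trace frames x 2 displacement matrix.
#' @param eps Moving threshold.
#' @return Classified turn table (see [classify_turn_policy()]).
#' @export
analyse_turns <- function(mouse_trace, eps = 0.1) {
  dirs <- discretise_directions(mouse_trace, eps)
  turns <- detect_turns(dirs)
  hes <- detect_hesitations(dirs)
  classify_turn_policy(turns, hes)
}

#' Dominant policy across a session
#'
#' The dominant policy is the one with the highest percentage of turns
#' across the whole experiment (ties broken by earliest occurrence). Also
#' returns, per trial, the number of turns of the dominant policy and the
#' total turn count (the model covariate).
#'
#' @param turn_tables Named/indexed list of per-trial classified turn
#'   tables (from [analyse_turns()]).
#' @return List with `dominant` (character), `policy_counts` (named
#'   total counts), `per_trial` (`data.frame` trial, n_turns,
#'   n_dominant).
#' @export
dominant_policy_stats <- function(turn_tables) {
  all_pol <- unlist(lapply(turn_tables, function(tt) as.character(tt$policy)))
  if (length(all_pol) == 0L) {
    warning("no turns in session; dominant policy undefined",
            call. = FALSE)
    return(list(dominant = NA_character_,
                policy_counts = stats::setNames(rep(0L, 6L), POLICY_LEVELS),
                per_trial = data.frame(trial = seq_along(turn_tables),
                                       n_turns = 0L, n_dominant = 0L)))
  }
  counts <- table(factor(all_pol, levels = POLICY_LEVELS))
  top <- names(counts)[counts == max(counts)]
  if (length(top) > 1L) { # tie: earliest-occurring wins
    first_seen <- vapply(top, function(p) which(all_pol == p)[1L],
                         numeric(1))
    top <- top[which.min(first_seen)]
  }
  per_trial <- data.frame(
    trial = seq_along(turn_tables),
    n_turns = vapply(turn_tables, nrow, integer(1)),
    n_dominant = vapply(turn_tables, function(tt) {
      sum(as.character(tt$policy) == top)
    }, integer(1))
  )
  list(dominant = top, policy_counts = as.integer(counts) |>
         stats::setNames(names(counts)), per_trial = per_trial)
}

#' Motor-control task index
#'
#' Mean area traversed outside the path multiplied by mean reaction time;
#' lower is better (speed-accuracy trade-off in one number).
#'
#' @param areas_outside Per-path-trial area outside the path.
#' @param reaction_times_s Per-path-trial reaction times, seconds.
#' @return Scalar index.
#' @export
motor_control_index <- function(areas_outside, reaction_times_s) {
  stopifnot(length(areas_outside) >= 1L,
            length(reaction_times_s) >= 1L)
  mean(areas_outside) * mean(reaction_times_s)
}

#' Per-trial behaviour summary
#'
#' @param mouse_trace frames x 2 displacement matrix.
#' @param fps Frame rate.
#' @param eps Moving threshold.
#' @return One-row `data.frame`: time_moving_s, onset_s, mean_speed,
#'   mean_accel, mean_jerk, n_turns and per-policy counts.
#' @export
trial_behaviour <- function(mouse_trace, fps = 60, eps = 0.1) {
  kin <- compute_kinematics(mouse_trace, eps)
  tm <- time_spent_moving(mouse_trace, fps, eps)
  turns <- analyse_turns(mouse_trace, eps)
  counts <- table(turns$policy)
  out <- data.frame(time_moving_s = tm$time_moving_s,
                    onset_s = tm$onset_s,
                    mean_speed = kin$mean_speed,
                    mean_accel = kin$mean_accel,
                    mean_jerk = kin$mean_jerk,
                    n_turns = nrow(turns))
  for (p in POLICY_LEVELS) out[[paste0("n_", p)]] <- as.integer(counts[p])
  attr(out, "turns") <- turns
  out
}
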