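# Interchange formats, the end-to-end pipeline and its manifest/cache.

FRAME_SCHEMA <- c("participant", "block", "trial", "frame", "square",
                  "x", "y", "mouse_dx", "mouse_dy", "jitter_state",
                  "jitter_deg", "offset_deg", "is_target", "is_no_control")

trial_key <- function(meta) {
  paste(meta$participant, meta$block, meta$trial, sep = "_")
}

#' Write trial logs to disk
#'
#' Tidy tabular interchange: `frames.csv` (one row per frame per square,
#' including the jitter draws so the log is lossless), `trials.csv`
#' (per-trial metadata and task-configuration fields) and
#' `squares.csv` (initial positions). `dialect = "rds"` writes the same
#' content as a single binary columnar file with an exact round trip;
#' the CSV dialect is written at full precision and round-trips to within
#' 1e-12 after canonicalisation.
#'
#' @param trials List of `trial_log` objects (with participant/block/
#'   trial ids filled in).
#' @param path Output directory (created if needed).
#' @param dialect `"csv"` or `"rds"`.
#' @return `path`, invisibly.
#' @export
write_trial_logs <- function(trials, path, dialect = c("csv", "rds")) {
  dialect <- match.arg(dialect)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  frames <- data.table::rbindlist(lapply(trials, function(tr) {
    df <- as.data.frame(tr)
    df$jitter_deg <- as.vector(tr$jitter_deg)
    df
  }))
  meta <- data.table::rbindlist(lapply(trials, function(tr) {
    cfg <- tr$cfg
    data.frame(participant = tr$participant, block = tr$block,
               trial = tr$trial_id,
               variability = cfg$variability_level,
               volatility = cfg$volatility_level,
               is_no_control = tr$is_no_control,
               target_index = tr$target_index,
               seed = tr$seed %||% NA_integer_,
               frames_per_trial = cfg$frames_per_trial, fps = cfg$fps,
               n_squares = cfg$n_squares,
               square_size_px = cfg$square_size_px,
               screen_w = cfg$screen_w, screen_h = cfg$screen_h,
               ci_narrow = cfg$ci_pair_deg[1], ci_wide = cfg$ci_pair_deg[2],
               n_volatility_changes = cfg$n_volatility_changes,
               min_change_gap_frames = cfg$min_change_gap_frames,
               distractor_redraws = cfg$distractor_redraws,
               offset_transition_frames = cfg$offset_transition_frames,
               start_margin_frames = cfg$start_margin_frames)
  }))
  squares <- data.table::rbindlist(lapply(trials, function(tr) {
    data.frame(participant = tr$participant, block = tr$block,
               trial = tr$trial_id,
               square = seq_len(nrow(tr$init_xy)),
               init_x = tr$init_xy[, 1], init_y = tr$init_xy[, 2])
  }))
  if (dialect == "csv") {
    data.table::fwrite(frames, file.path(path, "frames.csv"))
    data.table::fwrite(meta, file.path(path, "trials.csv"))
    data.table::fwrite(squares, file.path(path, "squares.csv"))
  } else {
    saveRDS(list(frames = frames, trials = meta, squares = squares),
            file.path(path, "trial_logs.rds"))
  }
  invisible(path)
}

#' Read trial logs written by [write_trial_logs()]
#'
#' @param path Directory containing the interchange files.
#' @param dialect `"csv"` or `"rds"`.
#' @return List of `trial_log` objects (order: participant, block,
#'   trial).
#' @export
read_trial_logs <- function(path, dialect = c("csv", "rds")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    frames <- data.table::fread(file.path(path, "frames.csv"))
    meta <- data.table::fread(file.path(path, "trials.csv"))
    squares <- data.table::fread(file.path(path, "squares.csv"))
  } else {
    obj <- readRDS(file.path(path, "trial_logs.rds"))
    frames <- data.table::as.data.table(obj$frames)
    meta <- data.table::as.data.table(obj$trials)
    squares <- data.table::as.data.table(obj$squares)
  }
  missing_cols <- setdiff(FRAME_SCHEMA, names(frames))
  if (length(missing_cols) > 0L) {
    stop("frames table does not match schema; missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  meta <- meta[order(meta$participant, meta$block, meta$trial), ]
  lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    sel <- frames$participant == m$participant &
      frames$block == m$block & frames$trial == m$trial
    fr <- frames[sel, ]
    ssel <- squares$participant == m$participant &
      squares$block == m$block & squares$trial == m$trial
    sq <- squares[ssel, ]
    nf <- m$frames_per_trial
    ns <- m$n_squares
    fr <- fr[order(fr$square, fr$frame), ]
    cfg <- task_config(m$variability, m$volatility,
                       frames_per_trial = nf, fps = m$fps,
                       n_squares = ns, square_size_px = m$square_size_px,
                       screen_w = m$screen_w, screen_h = m$screen_h,
                       min_change_gap_frames = m$min_change_gap_frames,
                       distractor_redraws = m$distractor_redraws,
                       offset_transition_frames =
                         m$offset_transition_frames,
                       start_margin_frames = m$start_margin_frames,
                       n_volatility_changes = m$n_volatility_changes,
                       ci_pair_deg = c(m$ci_narrow, m$ci_wide))
    first_sq <- fr[fr$square == fr$square[1L], ]
    state <- first_sq$jitter_state
    change_frames <- which(state[-1L] != state[-nf]) + 1L
    structure(list(
      trial_id = m$trial, participant = m$participant, block = m$block,
      condition = c(variability = m$variability,
                    volatility = m$volatility),
      is_no_control = m$is_no_control,
      target_index = if (is.na(m$target_index)) NA_integer_ else
        as.integer(m$target_index),
      mouse = cbind(first_sq$mouse_dx, first_sq$mouse_dy),
      init_xy = cbind(sq$init_x, sq$init_y),
      squares_x = matrix(fr$x, nf, ns),
      squares_y = matrix(fr$y, nf, ns),
      jitter_state = state,
      jitter_deg = matrix(fr$jitter_deg, nf, ns),
      offsets_deg = matrix(fr$offset_deg, nf, ns),
      schedule = structure(list(change_frames = as.integer(change_frames),
                                state_per_frame = state,
                                start_state = state[1L]),
                           class = "volatility_schedule"),
      seed = if (is.na(m$seed)) NULL else as.integer(m$seed),
      cfg = cfg
    ), class = "trial_log")
  })
}

# Simulate and analyse one trial end to end; returns summaries.
run_one_trial <- function(cfg, profile, is_no_control, trial_seed,
                          native_rate, use_eye_noise, beta, eps, fps) {
  mouse <- generate_mouse_trace(profile, cfg,
                                seed = derive_seed(trial_seed, 1L))
  trial <- simulate_trial(cfg, mouse$trace, is_no_control,
                          seed = derive_seed(trial_seed, 2L))
  agent <- simulate_gaze_agent(trial, profile,
                               seed = derive_seed(trial_seed, 3L))
  if (use_eye_noise) {
    raw <- inject_eye_noise(agent$gaze, profile, cfg,
                            native_rate = native_rate,
                            seed = derive_seed(trial_seed, 4L))
    fg <- preprocess_trace(raw, cfg)
    interp_l <- attr(fg, "interp_frac_l")
    interp_r <- attr(fg, "interp_frac_r")
  } else {
    fg <- data.frame(frame = seq_len(nrow(agent$gaze)),
                     gaze_x = agent$gaze[, 1], gaze_y = agent$gaze[, 2])
    interp_l <- 0; interp_r <- 0
  }
  looked <- assign_looked_square(fg, trial, beta = beta)
  hs <- detect_hypothesis_switches(looked)
  pes <- prediction_error_series(trial, hs$cleaned)
  beh <- trial_behaviour(mouse$trace, fps = fps, eps = eps)

  win <- round(profile$judgement_window_s * fps)
  nf <- nrow(trial$mouse)
  wframes <- max(1L, nf - win + 1L):nf
  speed <- sqrt(trial$mouse[, 1]^2 + trial$mouse[, 2]^2)
  wmoving <- wframes[speed[wframes] > eps]
  if (length(wmoving) == 0L) wmoving <- wframes
  response <- judge_agency(agent$pe_matrix[wmoving, , drop = FALSE],
                           profile)
  accuracy <- if (is_no_control) response == 0L else
    identical(response, as.integer(trial$target_index)) ||
    (!is.na(trial$target_index) && response == trial$target_index)

  erpe <- erpe_epochs(pes$pe_px, hs$switch_frames)
  list(trial = trial, behaviour = beh,
       turns = attr(beh, "turns"),
       pe = pes$pe_px,
       mean_pe = attr(pes, "mean_pe"),
       n_switches = hs$n_switches,
       response = response, accuracy = accuracy,
       interp_frac_l = interp_l, interp_frac_r = interp_r,
       erpe_bins = erpe$bin_means)
}

#' Run the full synthetic experiment pipeline
#'
#' Simulate -> gaze agent -> (eye-noise -> preprocess) -> behaviour ->
#' gaze PE -> analysis tables, for a cohort of synthetic participants.
#' Every random draw is derived from `seed` and the (participant, block,
#' trial) coordinates, so any trial is independently reproducible. With
#' `out_dir` set, per-participant results are cached on disk next to a
#' manifest recording the seed and parameters; re-running with the same
#' arguments reloads cached participants and recomputes only missing
#' ones.
#'
#' @param n_participants Number of synthetic participants.
#' @param seed Master seed.
#' @param profile An [agent_profile()] shared by the cohort (AQ is drawn
#'   per participant).
#' @param blocks_per_condition,agentive_per_block,nocontrol_per_block
#'   Design counts (defaults: full design 2 / 16 / 2).
#' @param native_rate Eye-tracker native rate (Hz) for artifact
#'   injection.
#' @param use_eye_noise If `FALSE`, skip artifact injection and
#'   preprocessing and feed the agent's clean gaze straight to analysis.
#' @param beta Stickiness of gaze-square assignment.
#' @param eps Moving threshold, px/frame.
#' @param out_dir Optional cache/output directory.
#' @param verbose Print per-participant progress.
#' @return A `squares_session` list: `participants` (id, aq_score),
#'   `trial_table` (one row per trial with all DVs and exclusion flags),
#'   `pe_long` (per-frame PE, retained trials), `erpe_table` (bin means
#'   per participant x condition), `dominant` (per participant),
#'   `manifest`.
#' @export
run_pipeline <- function(n_participants = 2L, seed = 1L,
                         profile = agent_profile(),
                         blocks_per_condition = 2L,
                         agentive_per_block = 16L,
                         nocontrol_per_block = 2L,
                         native_rate = 1000, use_eye_noise = TRUE,
                         beta = 0.8, eps = 0.1,
                         out_dir = NULL, verbose = FALSE) {
  params <- list(n_participants = n_participants, seed = seed,
                 blocks_per_condition = blocks_per_condition,
                 agentive_per_block = agentive_per_block,
                 nocontrol_per_block = nocontrol_per_block,
                 native_rate = native_rate,
                 use_eye_noise = use_eye_noise, beta = beta, eps = eps,
                 profile = unclass(profile))
  param_hash <- paste0("h", sum(utf8ToInt(paste(
    deparse(params), collapse = ""))))
  cache_file <- function(p) {
    file.path(out_dir, sprintf("participant_%03d.rds", p))
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)

  aq <- sample_aq_scores(n_participants, seed = derive_seed(seed, 777L))
  recomputed <- logical(n_participants)
  per_part <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    if (!is.null(out_dir) && file.exists(cache_file(p))) {
      cached <- readRDS(cache_file(p))
      if (identical(cached$param_hash, param_hash)) {
        per_part[[p]] <- cached$result
        next
      }
    }
    recomputed[p] <- TRUE
    if (verbose) message("participant ", p, "/", n_participants)
    sched <- build_experiment_schedule(
      seed = derive_seed(seed, p, 0L),
      blocks_per_condition = blocks_per_condition,
      agentive_per_block = agentive_per_block,
      nocontrol_per_block = nocontrol_per_block)
    rows <- vector("list", nrow(sched))
    turns_list <- vector("list", nrow(sched))
    pe_list <- vector("list", nrow(sched))
    erpe_list <- vector("list", nrow(sched))
    for (i in seq_len(nrow(sched))) {
      cfg <- task_config(sched$variability[i], sched$volatility[i])
      res <- run_one_trial(cfg, profile, sched$is_no_control[i],
                           trial_seed = derive_seed(seed, p,
                                                    sched$block[i],
                                                    sched$trial[i]),
                           native_rate = native_rate,
                           use_eye_noise = use_eye_noise,
                           beta = beta, eps = eps, fps = cfg$fps)
      rows[[i]] <- cbind(
        data.frame(participant = p, block = sched$block[i],
                   trial_in_block = sched$trial[i], trial = i,
                   variability = sched$variability[i],
                   volatility = sched$volatility[i],
                   is_no_control = sched$is_no_control[i],
                   response = res$response,
                   accuracy = as.numeric(res$accuracy),
                   judged_agency = res$response != 0L,
                   mean_pe = res$mean_pe,
                   n_switches = res$n_switches,
                   interp_frac_l = res$interp_frac_l,
                   interp_frac_r = res$interp_frac_r,
                   recorded_len_s = cfg$frames_per_trial / cfg$fps),
        res$behaviour)
      turns_list[[i]] <- res$turns
      pe_list[[i]] <- data.table::data.table(
        participant = p, trial = i,
        variability = sched$variability[i],
        volatility = sched$volatility[i],
        accuracy = as.numeric(res$accuracy),
        judged_agency = res$response != 0L,
        frame = seq_along(res$pe), pe_px = res$pe)
      if (nrow(res$erpe_bins) > 0L) {
        erpe_list[[i]] <- data.table::data.table(
          participant = p, trial = i,
          variability = sched$variability[i],
          volatility = sched$volatility[i],
          event = seq_len(nrow(res$erpe_bins)),
          bin1 = res$erpe_bins[, 1], bin2 = res$erpe_bins[, 2],
          bin3 = res$erpe_bins[, 3], bin4 = res$erpe_bins[, 4],
          bin5 = res$erpe_bins[, 5])
      }
    }
    result <- list(trials = do.call(rbind, rows),
                   turns = turns_list,
                   pe = data.table::rbindlist(pe_list),
                   erpe = data.table::rbindlist(erpe_list))
    per_part[[p]] <- result
    if (!is.null(out_dir)) {
      saveRDS(list(param_hash = param_hash, result = result),
              cache_file(p))
    }
  }

  trial_table <- do.call(rbind, lapply(per_part, `[[`, "trials"))
  trial_table <- flag_poor_trials(trial_table)
  trial_table$aq_score <- aq[trial_table$participant]

  retained <- trial_table[!trial_table$excluded, ]
  dominant <- lapply(seq_len(n_participants), function(p) {
    keep <- retained$trial[retained$participant == p]
    d <- suppressWarnings(dominant_policy_stats(per_part[[p]]$turns[keep]))
    d$per_trial$trial <- keep
    d
  })
  trial_table$n_dominant <- NA_integer_
  trial_table$dominant_policy <- NA_character_
  for (p in seq_len(n_participants)) {
    d <- dominant[[p]]
    keep <- which(trial_table$participant == p &
                    !trial_table$excluded)
    map <- match(trial_table$trial[keep], d$per_trial$trial)
    trial_table$n_dominant[keep] <- d$per_trial$n_dominant[map]
    trial_table$dominant_policy[keep] <- d$dominant
  }

  keep_key <- paste(retained$participant, retained$trial)
  pe_long <- data.table::rbindlist(lapply(per_part, `[[`, "pe"))
  pe_long <- pe_long[paste(pe_long$participant, pe_long$trial) %in%
                       keep_key, ]
  erpe_raw <- data.table::rbindlist(lapply(per_part, `[[`, "erpe"))
  if (nrow(erpe_raw) > 0L) {
    erpe_raw <- erpe_raw[paste(erpe_raw$participant, erpe_raw$trial) %in%
                           keep_key, ]
  }

  manifest <- list(package_version =
                     as.character(utils::packageVersion("squarestask")),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   params = params[names(params) != "profile"],
                   param_hash = param_hash,
                   recomputed = recomputed,
                   n_trials = nrow(trial_table),
                   n_excluded = sum(trial_table$excluded))
  if (!is.null(out_dir)) {
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    }
    data.table::fwrite(trial_table, file.path(out_dir, "trial_table.csv"))
  }

  structure(list(participants = data.frame(participant =
                                             seq_len(n_participants),
                                           aq_score = aq),
                 trial_table = trial_table,
                 pe_long = pe_long,
                 erpe_table = erpe_raw,
                 dominant = dominant,
                 manifest = manifest),
            class = "squares_session")
}

#' @export
print.squares_session <- function(x, ...) {
  cat("<squares_session> ", nrow(x$participants), " participants, ",
      nrow(x$trial_table), " trials (", sum(x$trial_table$excluded),
      " excluded)\n", sep = "")
  invisible(x)
}

#' Assemble analysis tables from a session
#'
#' Builds the tidy tables the mixed models consume: the trial-wise table
#' (retained trials only), the condition-wise PE-slope table (4 rows per
#' participant), the agency-wise slope table (up to 4 accuracy x
#' judgement cells per participant) and the ERPE bin table (5 rows per
#' participant x condition).
#'
#' @param session A `squares_session` from [run_pipeline()].
#' @return List of data frames: `trialwise`, `condition_slopes`,
#'   `agency_slopes`, `erpe`.
#' @export
build_tables <- function(session) {
  stopifnot(inherits(session, "squares_session"))
  tw <- session$trial_table[!session$trial_table$excluded, ]
  aq <- session$participants

  cs <- pe_slope(session$pe_long,
                 by = c("participant", "variability", "volatility"))
  cs$aq_score <- aq$aq_score[match(cs$participant, aq$participant)]

  as_ <- pe_slope(session$pe_long,
                  by = c("participant", "accuracy", "judged_agency"))
  as_$aq_score <- aq$aq_score[match(as_$participant, aq$participant)]

  erpe <- NULL
  if (nrow(session$erpe_table) > 0L) {
    et <- data.table::as.data.table(session$erpe_table)
    cond <- et[, lapply(.SD, mean), by = .(participant, variability,
                                           volatility),
               .SDcols = paste0("bin", 1:5)]
    erpe <- data.table::melt(cond,
                             id.vars = c("participant", "variability",
                                         "volatility"),
                             variable.name = "time_bin",
                             value.name = "pe_bin")
    twdt <- data.table::as.data.table(tw)
    covs <- twdt[, .(cond_mean_pe = mean(mean_pe, na.rm = TRUE),
                     cond_mean_switches = mean(n_switches)),
                 by = .(participant, variability, volatility)]
    erpe <- merge(erpe, covs,
                  by = c("participant", "variability", "volatility"))
    erpe$aq_score <- aq$aq_score[match(erpe$participant,
                                       aq$participant)]
    erpe <- as.data.frame(erpe)
  }
  list(trialwise = as.data.frame(tw),
       condition_slopes = cs,
       agency_slopes = as_,
       erpe = erpe)
}
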