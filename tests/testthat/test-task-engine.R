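# Stimulus engine: schedules, jitter, offsets, square kinematics,
# trial simulation, experiment plan.

test_that("volatility schedules have the configured change counts and gaps", {
  low <- task_config("low", "low")
  high <- task_config("low", "high")
  s_low <- make_volatility_schedule(low, seed = 1)
  s_high <- make_volatility_schedule(high, seed = 1)
  expect_length(s_low$change_frames, 3L)
  expect_length(s_high$change_frames, 10L)
  expect_true(all(diff(s_high$change_frames) >= 50L))

  # alternation and state bookkeeping
  st <- s_high$state_per_frame
  expect_identical(st[1], s_high$start_state)
  expect_identical(which(st[-1] != st[-length(st)]) + 1L,
                   s_high$change_frames)

  # property: min-gap never violated, count always exact
  gaps <- vapply(1:2000, function(s) {
    ch <- make_volatility_schedule(high, seed = s)$change_frames
    c(length(ch), min(diff(ch)))
  }, numeric(2))
  expect_true(all(gaps[1, ] == 10))
  expect_true(all(gaps[2, ] >= 50))
})

test_that("degenerate and infeasible schedules are handled", {
  cfg0 <- task_config("low", "low", n_volatility_changes = 0L)
  s <- make_volatility_schedule(cfg0, seed = 4)
  expect_length(s$change_frames, 0L)
  expect_length(unique(s$state_per_frame), 1L)

  expect_error(task_config("low", "low", n_volatility_changes = 20L),
               "infeasible")
})

test_that("jitter draws recover the configured 95% CI half-width", {
  for (ci in c(10, 30, 90, 110)) {
    x <- sample_jitter_angle(ci, 1e5, seed = 42)
    hw <- diff(stats::quantile(x, c(0.025, 0.975))) / 2
    expect_lt(abs(hw - ci), 0.03 * ci)
    expect_lt(abs(mean(x)), 0.02 * ci)
  }
  # 90 deg CI -> SD 90 / 1.96 = 45.92 (Monte-Carlo oracle)
  x <- sample_jitter_angle(90, 1e5, seed = 7)
  expect_lt(abs(stats::sd(x) - 45.92), 0.5)
  # no-noise limit and error branch
  expect_lt(max(abs(sample_jitter_angle(1e-9, 100, seed = 1))), 1e-8)
  expect_error(sample_jitter_angle(0), "positive")
  expect_error(sample_jitter_angle(-5), "positive")
})

test_that("distractor offsets redraw five times with shortest-arc ramps", {
  cfg <- task_config("low", "low")
  d <- make_distractor_offsets(cfg, 3L, seed = 9)
  expect_identical(dim(d$redraw_frames), c(5L, 3L))
  for (j in 1:3) {
    # each redraw onset starts a change; count discontinuity onsets
    tr <- d$offsets[, j]
    moving <- which(abs(shortest_arc_delta(tr[-length(tr)], tr[-1])) > 1e-9)
    onsets <- moving[c(TRUE, diff(moving) > 1)] + 1L
    expect_identical(as.integer(onsets), as.integer(d$redraw_frames[, j]))
  }

  # step-change limit
  cfg0 <- task_config("low", "low", offset_transition_frames = 0L)
  d0 <- make_distractor_offsets(cfg0, 1L, seed = 9)
  tr0 <- d0$offsets[, 1]
  expect_identical(sum(tr0[-1] != tr0[-length(tr0)]), 5L)

  # shortest arc: interpolation between angles crossing 0 never takes the
  # long way round (angular-difference oracle: every step's magnitude is
  # |total delta| / transition length)
  d2 <- make_distractor_offsets(cfg, 4L, seed = 11)
  for (j in 1:4) {
    tr <- d2$offsets[, j]
    steps <- shortest_arc_delta(tr[-length(tr)], tr[-1])
    expect_true(all(abs(steps) <= 180 / cfg$offset_transition_frames + 1e-9))
  }
})

test_that("step_squares moves by mouse magnitude along rotated directions", {
  pos <- matrix(c(100, 100), 1, 2)
  # noise-free identity for the target
  nxt <- step_squares(pos, 10, 0, 0, 0, 1920, 1080)
  expect_equal(nxt, matrix(c(110, 100), 1, 2))
  # 90 deg offset in y-down screen coordinates: (10, 0) -> (0, 10)
  nxt <- step_squares(pos, 10, 0, 0, 90, 1920, 1080)
  expect_equal(nxt, matrix(c(100, 110), 1, 2), tolerance = 1e-12)
  # rotation oracle on random cases: displacement magnitude preserved
  set.seed(5)
  for (i in 1:50) {
    p <- matrix(runif(16, 0, 1000), 8, 2)
    dx <- runif(1, -20, 20); dy <- runif(1, -20, 20)
    jit <- rnorm(8, 0, 30); off <- runif(8, 0, 360)
    nxt <- step_squares(p, dx, dy, jit, off, 1920, 1080)
    d <- sqrt(torus_delta_test(nxt[, 1], p[, 1], 1920)^2 +
                torus_delta_test(nxt[, 2], p[, 2], 1080)^2)
    expect_equal(d, rep(sqrt(dx^2 + dy^2), 8), tolerance = 1e-9)
  }
  # stationary mouse: nothing moves
  expect_identical(step_squares(pos, 0, 0, 5, 90, 1920, 1080), pos)
})

test_that("simulate_trial obeys its structural contracts", {
  cfg <- task_config("high", "high")
  set.seed(1)
  mouse <- cbind(rnorm(900, 0, 6), rnorm(900, 0, 6))
  mouse[301:360, ] <- 0 # a pause
  tr <- simulate_trial(cfg, mouse, is_no_control = FALSE, seed = 77)

  # determinism: bit-identical rerun
  tr2 <- simulate_trial(cfg, mouse, is_no_control = FALSE, seed = 77)
  expect_identical(tr, tr2)

  # bounds and wrap-aware conservation of displacement magnitude
  expect_true(all(tr$squares_x >= 0 & tr$squares_x < cfg$screen_w))
  expect_true(all(tr$squares_y >= 0 & tr$squares_y < cfg$screen_h))
  mag <- sqrt(mouse[, 1]^2 + mouse[, 2]^2)
  prev_x <- rbind(tr$init_xy[, 1], tr$squares_x[-900, ])
  prev_y <- rbind(tr$init_xy[, 2], tr$squares_y[-900, ])
  d <- sqrt(torus_delta_test(tr$squares_x, prev_x, cfg$screen_w)^2 +
              torus_delta_test(tr$squares_y, prev_y, cfg$screen_h)^2)
  expect_equal(unname(d), matrix(mag, 900, 8), tolerance = 1e-9)

  # stationary frames freeze all squares
  expect_true(all(d[301:360, ] == 0))

  # exactly one square with no angular offset in an agentive trial
  zero_off <- which(colSums(abs(tr$offsets_deg)) == 0)
  expect_identical(zero_off, tr$target_index)

  # no-control: all 8 offset-bearing, no target
  nc <- simulate_trial(cfg, mouse, is_no_control = TRUE, seed = 78)
  expect_true(all(colSums(abs(nc$offsets_deg)) > 0))
  expect_true(is.na(nc$target_index))

  # trace-length contract
  expect_error(simulate_trial(cfg, mouse[1:100, ]), "900")
})

test_that("with jitter off and offsets frozen all squares trace the mouse", {
  cfg <- task_config("low", "low", n_volatility_changes = 0L,
                     ci_pair_deg = c(1e-9, 2e-9), distractor_redraws = 0L)
  set.seed(2)
  mouse <- cbind(rnorm(900, 0, 5), rnorm(900, 0, 5))
  tr <- simulate_trial(cfg, mouse, seed = 3, offset_init = 0)
  mag <- sqrt(mouse[, 1]^2 + mouse[, 2]^2)
  for (s in 1:8) {
    dx <- torus_delta_test(tr$squares_x[, s],
                           c(tr$init_xy[s, 1], tr$squares_x[-900, s]),
                           cfg$screen_w)
    dy <- torus_delta_test(tr$squares_y[, s],
                           c(tr$init_xy[s, 2], tr$squares_y[-900, s]),
                           cfg$screen_h)
    expect_equal(dx, mouse[, 1], tolerance = 1e-5)
    expect_equal(dy, mouse[, 2], tolerance = 1e-5)
  }
})

test_that("experiment schedule conserves the block/trial design", {
  sch <- build_experiment_schedule(seed = 10)
  expect_identical(nrow(sch), 144L)
  expect_identical(sum(!sch$is_no_control), 128L)
  expect_identical(sum(sch$is_no_control), 16L)
  expect_true(all(table(sch$block) == 18L))
  counts <- table(sch$variability, sch$volatility)
  expect_true(all(counts == 36L))
  # different seeds can shuffle blocks; per-condition counts conserved
  sch2 <- build_experiment_schedule(seed = 11)
  counts2 <- table(sch2$variability, sch2$volatility)
  expect_identical(counts2, counts)
})
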