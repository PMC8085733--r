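# Gaze analysis: biased-nearest-object assignment, hypothesis switches,
# the prediction-error proxy, slopes and ERPE.

simple_trial <- function(nf = 50, ns = 3, seed = 1) {
  set.seed(seed)
  cfg <- task_config("low", "low")
  init <- cbind(runif(ns, 200, 1700), runif(ns, 200, 900))
  mouse <- cbind(rnorm(nf, 0, 5), rnorm(nf, 0, 5))
  disp_x <- matrix(mouse[, 1], nf, ns)
  disp_y <- matrix(mouse[, 2], nf, ns)
  manual_trial(init, disp_x, disp_y, mouse, cfg)
}

test_that("biased-nearest-object assignment follows the bias rule", {
  tr <- simple_trial()
  # gaze exactly on a square's centroid: that square, any beta
  for (beta in c(0.5, 0.8, 1)) {
    g <- cbind(tr$squares_x[, 2], tr$squares_y[, 2])
    expect_true(all(assign_looked_square(g, tr, beta) == 2L))
  }

  # equidistant between incumbent A and B with beta < 1: A retained
  cfg <- task_config("low", "low")
  init <- rbind(c(500, 500), c(700, 500))
  nf <- 10
  mouse <- matrix(0, nf, 2)
  tr2 <- manual_trial(init, matrix(0, nf, 2), matrix(0, nf, 2), mouse, cfg)
  g <- matrix(c(500, 500), nf, 2, byrow = TRUE) # acquire A first
  g[5:10, 1] <- 600                             # midpoint afterwards
  lk <- assign_looked_square(g, tr2, beta = 0.8)
  expect_true(all(lk == 1L))
  # with beta = 1 ties go to the first index as documented by which.min
  lk1 <- assign_looked_square(g, tr2, beta = 1)
  expect_true(all(lk1 == 1L))

  # beta = 1 equals the plain nearest-object oracle
  tr3 <- simple_trial(nf = 200, ns = 8, seed = 4)
  set.seed(5)
  g3 <- cbind(runif(200, 0, 1920), runif(200, 0, 1080))
  got <- assign_looked_square(g3, tr3, beta = 1)
  want <- vapply(1:200, function(t) {
    oracle_nearest(g3[t, 1], g3[t, 2], tr3$squares_x[t, ],
                   tr3$squares_y[t, ], 1920, 1080)
  }, integer(1))
  expect_identical(got, want)

  # invalid gaze carries the assignment forward; leading invalid is NA
  g4 <- cbind(tr$squares_x[, 1], tr$squares_y[, 1])
  g4[1:3, ] <- NA
  g4[10, ] <- NA
  lk4 <- assign_looked_square(g4, tr, beta = 1)
  expect_true(all(is.na(lk4[1:3])))
  expect_identical(lk4[10], lk4[9])
})

test_that("hypothesis switches require persistence beyond one frame", {
  hs <- detect_hypothesis_switches(c(1L, 1L, 2L, 2L, 2L))
  expect_identical(hs$switch_frames, 3L)
  expect_identical(hs$n_switches, 1L)
  # flicker: merged away
  hs0 <- detect_hypothesis_switches(c(1L, 1L, 2L, 1L, 1L))
  expect_identical(hs0$n_switches, 0L)
  expect_identical(hs0$cleaned, rep(1L, 5))
  # random sequences vs the definitional oracle
  set.seed(8)
  for (i in 1:300) {
    x <- sample(1:4, sample(2:40, 1), replace = TRUE)
    expect_identical(detect_hypothesis_switches(x)$switch_frames,
                     oracle_switch_frames(x))
  }
  # with beta = 1 and no flickers, switch count equals nearest-square
  # identity changes
  x <- rep(c(3L, 1L, 4L, 2L), each = 5)
  hs2 <- detect_hypothesis_switches(x)
  expect_identical(hs2$n_switches, 3L)
})

test_that("prediction error is zero for a perfectly followed square", {
  nf <- 60
  cfg <- task_config("low", "low")
  init <- rbind(c(300, 300), c(1000, 600))
  mouse <- cbind(rep(10, nf), rep(0, nf))
  # square 1 follows the mouse exactly; square 2 rotated 90 degrees
  dx <- cbind(rep(10, nf), rep(0, nf))
  dy <- cbind(rep(0, nf), rep(10, nf))
  tr <- manual_trial(init, dx, dy, mouse, cfg)
  pe1 <- prediction_error_series(tr, rep(1L, nf))
  expect_equal(pe1$pe_px, rep(0, nf), tolerance = 1e-9)

  # hypothesised 90-degree distractor at mouse step 10: pe = 10 * sqrt(2)
  pe2 <- prediction_error_series(tr, rep(2L, nf))
  expect_equal(pe2$pe_px, rep(10 * sqrt(2), nf), tolerance = 1e-9)
  # brute-force chord oracle: 2 * step * sin(offset / 2)
  expect_equal(attr(pe2, "mean_pe"), 2 * 10 * sin(pi / 4),
               tolerance = 1e-9)

  # stationary mouse frames give zero PE
  mouse0 <- rbind(mouse[1:30, ], matrix(0, 30, 2))
  dx0 <- rbind(dx[1:30, ], matrix(0, 30, 2))
  dy0 <- rbind(dy[1:30, ], matrix(0, 30, 2))
  tr0 <- manual_trial(init, dx0, dy0, mouse0, cfg)
  pe0 <- prediction_error_series(tr0, rep(2L, nf))
  expect_equal(pe0$pe_px[31:60], rep(0, 30))

  # PE non-negative, missing exactly where no hypothesis
  hyp <- c(rep(NA_integer_, 5), rep(1L, nf - 5))
  pe3 <- prediction_error_series(tr, hyp)
  expect_identical(is.na(pe3$pe_px), is.na(hyp))
  expect_true(all(pe3$pe_px >= 0, na.rm = TRUE))
  expect_error(prediction_error_series(tr, rep(NA_integer_, nf)),
               "hypothesis")
})

test_that("PE distances respect the screen torus", {
  cfg <- task_config("low", "low")
  nf <- 4
  # square rides across the right edge while hypothesis says it follows
  init <- rbind(c(1915, 500))
  mouse <- cbind(rep(10, nf), rep(0, nf))
  dx <- matrix(10, nf, 1); dy <- matrix(0, nf, 1)
  tr <- manual_trial(init, dx, dy, mouse, cfg, target = 1L)
  pe <- prediction_error_series(tr, rep(1L, nf))
  expect_equal(pe$pe_px, rep(0, nf), tolerance = 1e-9) # wrap-aware zero
})

test_that("PE slopes are exact on noiseless lines", {
  # constant PE -> slope 0; pe = 2 t + 1 -> slope 2 (t in seconds)
  frames <- 1:600
  tsec <- (frames - 1) / 60
  long <- rbind(
    data.frame(participant = 1, cell = "flat", frame = frames,
               pe_px = 5),
    data.frame(participant = 1, cell = "line", frame = frames,
               pe_px = 2 * tsec + 1)
  )
  sl <- pe_slope(long, by = c("participant", "cell"))
  expect_equal(sl$slope[sl$cell == "flat"], 0, tolerance = 1e-12)
  expect_equal(sl$slope[sl$cell == "line"], 2, tolerance = 1e-9)
  expect_equal(sl$intercept[sl$cell == "line"], 1, tolerance = 1e-9)
  # averaging across trials happens before fitting
  long2 <- rbind(
    data.frame(participant = 1, cell = "c", frame = frames, pe_px = 0),
    data.frame(participant = 1, cell = "c", frame = frames,
               pe_px = 4 * tsec)
  )
  sl2 <- pe_slope(long2, by = c("participant", "cell"))
  expect_equal(sl2$slope, 2, tolerance = 1e-9)
  # single time point: missing slope
  one <- data.frame(participant = 1, cell = "x", frame = 1, pe_px = 3)
  expect_true(is.na(pe_slope(one, by = c("participant", "cell"))$slope))
})

test_that("ERPE epochs bin a one-second window with bin 3 on the event", {
  # flat PE: all five bins equal
  pe <- rep(4, 900)
  ep <- erpe_epochs(pe, events = c(100, 500))
  expect_identical(dim(ep$bin_means), c(2L, 5L))
  expect_true(all(ep$bin_means == 4))
  # bins tile the epoch: 5 x 12 frames
  expect_identical(ncol(ep$epochs), 60L)

  # events too close to the edges are dropped
  ep2 <- erpe_epochs(pe, events = c(10, 30, 100, 871, 895))
  expect_identical(ep2$events, c(100L, 871L))

  # ramp into the event then reset: bin 3 dominates bins 1, 4, 5
  pe3 <- rep(1, 900)
  ev <- 300
  pe3[(ev - 20):(ev - 1)] <- 1 + (1:20)    # rising error
  pe3[ev:(ev + 5)] <- 22                   # peak at switch
  ep3 <- erpe_epochs(pe3, events = ev)
  bm <- ep3$bin_means[1, ]
  expect_gt(bm[3], bm[1]); expect_gt(bm[3], bm[4]); expect_gt(bm[3], bm[5])
  # bin 3 covers [event - 6, event + 5]
  expect_equal(unname(bm[3]), mean(pe3[(ev - 6):(ev + 5)]))

  # missing PE frames are excluded from bin means
  pe4 <- rep(2, 900); pe4[95:100] <- NA
  ep4 <- erpe_epochs(pe4, events = 120)
  expect_true(all(is.finite(ep4$bin_means)))
  expect_equal(unname(ep4$bin_means[1, 1]), 2)

  # no surviving events: empty result
  ep0 <- erpe_epochs(pe, events = 5)
  expect_identical(nrow(ep0$bin_means), 0L)
})
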