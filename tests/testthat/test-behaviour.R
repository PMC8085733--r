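# Cursor behaviour: kinematics, moving time, direction discretisation,
# turn detection, policy classification, dominant policy, motor index.

test_that("kinematics match trivial cases and the finite-difference oracle", {
  # constant (3,4): speed 5, accel 0, jerk 0
  tr <- matrix(c(3, 4), 100, 2, byrow = TRUE)
  k <- compute_kinematics(tr)
  expect_equal(k$mean_speed, 5)
  expect_equal(k$mean_accel, 0)
  expect_equal(k$mean_jerk, 0)

  # speeds 0,1,2,3 -> accel 1,1,1; jerk 0,0
  tr2 <- cbind(c(0, 1, 2, 3), 0)
  k2 <- compute_kinematics(tr2)
  expect_equal(k2$accel, c(1, 1, 1))
  expect_equal(k2$jerk, c(0, 0))

  # random trace vs independent recomputation
  set.seed(3)
  tr3 <- cbind(rnorm(200), rnorm(200))
  k3 <- compute_kinematics(tr3)
  sp <- numeric(200)
  for (i in 1:200) sp[i] <- sqrt(tr3[i, 1]^2 + tr3[i, 2]^2)
  ac <- sp[-1] - sp[-200]
  jk <- ac[-1] - ac[-199]
  expect_equal(k3$speed, sp)
  expect_equal(k3$accel, ac)
  expect_equal(k3$jerk, jk)

  # kinematic chain: accel telescopes back to speed
  expect_equal(sp[1] + cumsum(ac), sp[-1])

  # all-stationary: speed 0, accel/jerk missing
  k0 <- compute_kinematics(matrix(0, 10, 2))
  expect_equal(k0$mean_speed, 0)
  expect_true(is.na(k0$mean_accel) && is.na(k0$mean_jerk))
})

test_that("time spent moving counts frames above threshold", {
  expect_equal(time_spent_moving(matrix(0, 900, 2))$time_moving_s, 0)
  expect_equal(time_spent_moving(matrix(1, 900, 2))$time_moving_s, 15)
  tr <- matrix(0, 900, 2); tr[101:550, 1] <- 5
  tm <- time_spent_moving(tr)
  expect_equal(tm$time_moving_s, 7.5)
  expect_equal(tm$onset_s, 100 / 60)
})

test_that("direction discretisation matches the nearest-angle oracle", {
  expect_identical(discretise_directions(matrix(c(10, 0), 1))[1], 1L) # R
  # exact boundary 22.5 deg -> clockwise-next sector (DR)
  ang <- 22.5 * pi / 180
  expect_identical(
    discretise_directions(matrix(c(10 * cos(ang), 10 * sin(ang)), 1))[1],
    2L)
  # random angles vs brute-force nearest direction
  set.seed(9)
  theta <- runif(1e4, 0, 2 * pi)
  tr <- cbind(5 * cos(theta), 5 * sin(theta))
  got <- discretise_directions(tr)
  centres <- seq(0, 315, by = 45) * pi / 180
  want <- vapply(theta, function(a) {
    d <- abs(atan2(sin(a - centres), cos(a - centres)))
    which.min(d)
  }, integer(1))
  expect_equal(as.integer(got), want)
  # stationary frames omitted
  tr0 <- rbind(c(0, 0), c(5, 0))
  expect_true(is.na(discretise_directions(tr0)[1]))
})

test_that("turn detection matches definitions and the window-scan oracle", {
  # minimal qualifying turn
  t1 <- detect_turns(c(1, 1, 1, 7, 7, 7))
  expect_identical(nrow(t1), 1L)
  expect_identical(t1$frame, 4L)
  expect_identical(t1$dir_from, 1); expect_identical(t1$dir_to, 7)
  # one-frame flicker: no turn
  expect_identical(nrow(detect_turns(c(1, 1, 7, 1, 1))), 0L)
  # random sequences vs oracle
  set.seed(12)
  for (i in 1:200) {
    d <- sample(1:4, sample(6:40, 1), replace = TRUE)
    expect_identical(detect_turns(d)$frame, oracle_turn_frames(d))
  }
  # stationary frames do not break a run
  d <- c(1, 1, 1, NA, NA, 3, 3, 3)
  tt <- detect_turns(d)
  expect_identical(tt$frame, 6L)
})

test_that("policies are classified by their operational definitions", {
  # L -> R reversal: Horizontal; U -> D: Vertical
  h <- classify_turn_policy(data.frame(frame = 10, dir_from = 5, dir_to = 1))
  expect_identical(as.character(h$policy), "Horizontal")
  v <- classify_turn_policy(data.frame(frame = 10, dir_from = 7, dir_to = 3))
  expect_identical(as.character(v$policy), "Vertical")
  # R -> U direct 90 degrees: Perpendicular-Cardinal
  p <- classify_turn_policy(data.frame(frame = 10, dir_from = 1, dir_to = 7))
  expect_identical(as.character(p$policy), "PerpendicularCardinal")
  # any diagonal endpoint: Non-Cardinal
  nc <- classify_turn_policy(data.frame(frame = 10, dir_from = 1, dir_to = 2))
  expect_identical(as.character(nc$policy), "NonCardinal")

  # rounded corner R -> DR -> D collapses to one Perpendicular-Cardinal
  dirs <- rep(c(1L, 2L, 3L), each = 5)
  turns <- detect_turns(dirs)
  expect_identical(nrow(turns), 2L)
  cc <- classify_turn_policy(turns)
  expect_identical(nrow(cc), 1L)
  expect_identical(as.character(cc$policy), "PerpendicularCardinal")

  # four same-rotation 45-degree turns within 30 frames: one Circle
  dirs2 <- rep(c(1L, 2L, 3L, 4L, 5L), times = c(5, 4, 4, 4, 8))
  turns2 <- detect_turns(dirs2)
  expect_identical(nrow(turns2), 4L)
  cl <- classify_turn_policy(turns2)
  expect_identical(nrow(cl), 1L)
  expect_identical(as.character(cl$policy), "Circle")
  expect_identical(cl$span_start, turns2$frame[1])
  expect_identical(cl$span_end, turns2$frame[4])

  # stop >= 3 frames then same direction: Hesitant-straight
  dirs3 <- c(1, 1, 1, 1, NA, NA, NA, 1, 1, 1, 1)
  hes <- detect_hesitations(dirs3)
  expect_identical(nrow(hes), 1L)
  expect_identical(hes$frame, 8L)
  chs <- classify_turn_policy(detect_turns(dirs3), hes)
  expect_identical(as.character(chs$policy), "HesitantStraight")

  # policy counts partition the collapsed turn set
  set.seed(21)
  pr <- agent_profile()
  cfg <- task_config("low", "low")
  mt <- generate_mouse_trace(pr, cfg, seed = 31)
  cls <- analyse_turns(mt$trace)
  expect_identical(sum(table(cls$policy)), nrow(cls))
  expect_false(any(is.na(cls$policy)))
})

test_that("dominant policy statistics take the experiment-wide argmax", {
  mk <- function(policies) {
    n <- length(policies)
    data.frame(frame = seq_len(n), dir_from = rep(1, n),
               dir_to = rep(7, n),
               policy = factor(policies, levels = POLICY_LEVELS))
  }
  # all Horizontal: per-trial dominant count equals n_turns
  d <- dominant_policy_stats(list(mk(rep("Horizontal", 4)),
                                  mk(rep("Horizontal", 2))))
  expect_identical(d$dominant, "Horizontal")
  expect_identical(d$per_trial$n_dominant, d$per_trial$n_turns)
  # 40/35/25 split: argmax wins
  pols <- c(rep("NonCardinal", 40), rep("Vertical", 35),
            rep("Circle", 25))
  d2 <- dominant_policy_stats(list(mk(pols)))
  expect_identical(d2$dominant, "NonCardinal")
  # tie: earliest-occurring wins
  d3 <- dominant_policy_stats(list(mk(c("Vertical", "Horizontal",
                                        "Horizontal", "Vertical"))))
  expect_identical(d3$dominant, "Vertical")
  # zero turns: flagged undefined
  expect_warning(d0 <- dominant_policy_stats(list(mk(character(0)))),
                 "undefined")
  expect_true(is.na(d0$dominant))
})

test_that("motor-control index is mean area times mean reaction time", {
  expect_equal(motor_control_index(c(10, 20), c(2, 4)), 45)
  expect_equal(motor_control_index(0, 100), 0)
  expect_equal(motor_control_index(c(2, 4), c(1, 3)),
               motor_control_index(c(1, 2), c(1, 3)) * 2)
})
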