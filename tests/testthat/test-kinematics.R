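test_that("boundary-condition mode satisfies the end conditions exactly", {
  p <- fitSaccade()
  s0 <- evalSaccade(p, 0)
  expect_equal(s0$theta, 0); expect_equal(s0$omega, 0)
  expect_equal(s0$alpha, 2 * p@coefficients[3])
  sT <- evalSaccade(p, p@duration)
  expect_equal(sT$theta, 50, tolerance = 1e-9)
  expect_equal(sT$omega, 0, tolerance = 1e-6)
  expect_equal(sT$alpha, 0, tolerance = 1e-4)
  # clamped hold after the saccade
  s2T <- evalSaccade(p, 2 * p@duration)
  expect_equal(unlist(s2T[c("theta", "omega", "alpha")]),
               c(theta = 50, omega = 0, alpha = 0))
  # zero amplitude degenerates to rest
  expect_equal(max(abs(evalSaccade(fitSaccade(amplitude = 0),
                                   seq(0, 0.274, by = 1e-3))$theta)), 0,
               tolerance = 1e-9)
  expect_error(fitSaccade(duration = 0))
  expect_error(evalSaccade(p, -0.01))
  expect_error(evalSaccade(p, 0.3))
})

test_that("verbatim coefficient set evaluates by direct arithmetic", {
  p <- fitSaccade(mode = "table2_verbatim")
  # independent hand evaluation at t = 0.05 s
  t <- 0.05
  expected <- 2.01e4 * t^2 - 3.29e5 * t^3 + 2.30e6 * t^4
  expect_equal(evalSaccade(p, t)$theta, expected, tolerance = 1e-12)
  expect_equal(expected, 23.5, tolerance = 1e-12)
  # no clamping in verbatim mode
  expect_false(evalSaccade(p, 0.2)$theta == p@amplitude)
})

test_that("saccade is monotone with a physiologic peak velocity", {
  traj <- saccadeTrajectory(fitSaccade(), dt = 5e-4)
  during <- traj$t <= 0.137 + 1e-12
  expect_true(all(traj$omega[during] >= -1e-6))
  expect_gte(max(traj$omega), 400)
  expect_true(all(traj$omega[!during] == 0))
})

test_that("finite-difference derivative of theta matches analytic omega", {
  traj <- saccadeTrajectory(fitSaccade(), dt = 1e-4)
  inside <- which(traj$t > 0.01 & traj$t < 0.127)
  fd <- (traj$theta[inside + 1] - traj$theta[inside - 1]) / 2e-4
  expect_equal(fd, traj$omega[inside], tolerance = 5e-3)
})
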