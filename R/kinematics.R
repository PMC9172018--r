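# Saccadic kinematics: quintic angular-displacement law for a horizontal
# saccade about the +y axis, with an observation window of twice the saccade
# duration to cover the post-saccadic fluid deceleration.

#' Fit the saccade polynomial
#'
#' `boundary_condition` mode (default) keeps the published initial
#' acceleration (c2 = 2.01e4 deg/s^2, so c0 = c1 = 0) and solves the linear
#' 3x3 system for c3, c4, c5 from the end conditions theta(T) = amplitude,
#' theta'(T) = 0, theta''(T) = 0, giving an amplitude-exact smooth saccade.
#' `table2_verbatim` mode carries the published coefficient set c0..c4
#' unchanged with c5 = 0; it is retained as a diagnostic because evaluated
#' at T it does not reproduce the stated amplitude.
#'
#' @param amplitude saccade amplitude (deg).
#' @param duration saccade duration T (s).
#' @param mode "boundary_condition" or "table2_verbatim".
#' @param c2 initial half-acceleration coefficient (deg/s^2); defaults to
#'   the published 2.01e4 scaled linearly with amplitude (so a zero-amplitude
#'   saccade is identically at rest).
#' @return a [SaccadeParams-class].
#' @examples
#' p <- fitSaccade()
#' evalSaccade(p, p@duration)   # exactly (50, 0, 0)
#' @export
fitSaccade <- function(amplitude = 50, duration = 0.137,
                       mode = c("boundary_condition", "table2_verbatim"),
                       c2 = 2.01e4 * amplitude / 50) {
  mode <- match.arg(mode)
  if (amplitude < 0 || duration <= 0)
    stop("amplitude must be >= 0 and duration > 0")
  if (mode == "table2_verbatim") {
    co <- c(0, 0, 2.01e4, -3.29e5, 2.30e6, 0)
    return(new("SaccadeParams", amplitude = amplitude, duration = duration,
               coefficients = co, mode = mode))
  }
  T <- duration
  M <- rbind(c(T^3, T^4, T^5),
             c(3 * T^2, 4 * T^3, 5 * T^4),
             c(6 * T, 12 * T^2, 20 * T^3))
  rhs <- c(amplitude - c2 * T^2, -2 * c2 * T, -2 * c2)
  c345 <- tryCatch(solve(M, rhs),
                   error = function(e) stop("singular end-condition system: ",
                                            conditionMessage(e)))
  new("SaccadeParams", amplitude = amplitude, duration = duration,
      coefficients = c(0, 0, c2, c345), mode = mode)
}

#' Evaluate the saccade law
#'
#' Polynomial theta and analytic first/second derivatives for `t <= T`. In
#' `boundary_condition` mode the state is clamped at (amplitude, 0, 0) for
#' `t > T` (the eye holds its final position); `table2_verbatim` evaluates
#' the polynomial throughout.
#'
#' @param params a [SaccadeParams-class].
#' @param t time(s) in seconds, each within [0, 2T].
#' @return data.frame with columns t, theta (deg), omega (deg/s),
#'   alpha (deg/s^2).
#' @export
evalSaccade <- function(params, t) {
  T <- params@duration
  if (any(t < -1e-12 | t > 2 * T + 1e-12))
    stop("t outside [0, 2T]")
  co <- params@coefficients
  pw <- outer(t, 0:5, `^`)
  theta <- pw %*% co
  omega <- pw[, 1:5, drop = FALSE] %*% (co[2:6] * (1:5))
  acc <- pw[, 1:4, drop = FALSE] %*% (co[3:6] * (2:5) * (1:4))
  out <- data.frame(t = t, theta = as.numeric(theta),
                    omega = as.numeric(omega), alpha = as.numeric(acc))
  if (params@mode == "boundary_condition") {
    post <- t > T
    out$theta[post] <- params@amplitude
    out$omega[post] <- 0
    out$alpha[post] <- 0
  }
  out
}

#' Sample a saccade trajectory
#'
#' Dense sampling of [evalSaccade()] over the full observation window
#' [0, 2T].
#'
#' @param params a [SaccadeParams-class].
#' @param dt sampling step in seconds (must be <= 1 ms).
#' @return data.frame as in [evalSaccade()].
#' @export
saccadeTrajectory <- function(params = fitSaccade(), dt = 1e-3) {
  if (dt > 1e-3 + 1e-12) stop("sampling step must be <= 1 ms")
  t <- seq(0, 2 * params@duration, by = dt)
  evalSaccade(params, t)
}
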