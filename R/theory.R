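#' Closed-form theory of inward colony growth
#'
#' Parameter container for the analytic radial velocity profile and the
#' flow-alignment orientation dynamics. During inward growth, area added at
#' rate `Lambda` by exponential growth must be accommodated by boundary
#' motion; assuming a constant critical radius `R_c` where the radial
#' velocity vanishes gives `v_r(r) = Lambda (r^2 - R_c^2) / (2 r)` on both
#' sides of `R_c`. `xi` is the flow-alignment parameter coupling the
#' director to the strain rate, and `S` the (fixed) scalar nematic order
#' entering the orientation equation.
#'
#' @param Lambda Exponential growth rate (1/time), > 0.
#' @param R_c Critical radius (um), >= 0 (0 recovers the uniformly
#'   expanding colony).
#' @param xi Flow alignment parameter (dimensionless).
#' @param S Scalar nematic order in (0, 1].
#' @return A list of class `theory_params`.
#' @export
theory_params <- function(Lambda = 0.005, R_c = 100, xi = 0.7, S = 1) {
  stopifnot(Lambda > 0, R_c >= 0, S > 0)
  structure(list(Lambda = Lambda, R_c = R_c, xi = xi, S = S),
            class = "theory_params")
}

#' Closed-form radial velocity profile
#'
#' `v_r(r) = Lambda (r^2 - R_c^2) / (2 r)`: negative (inward) below the
#' critical radius, positive (outward) above it. With `R_c = 0` this reduces
#' to the Hubble-like linear profile `Lambda r / 2` of a uniformly expanding
#' colony.
#'
#' @param r Radius (um), > 0 (vectorised).
#' @param p A [theory_params()] object.
#' @return Radial velocity (um/time).
#' @export
vr_closed_form <- function(r, p) {
  if (any(r <= 0)) stop("r must be positive")
  p$Lambda * (r^2 - p$R_c^2) / (2 * r)
}

#' Local growth rate and its radial derivative
#'
#' `g(r) = v_r / r = Lambda (r^2 - R_c^2) / (2 r^2)` and
#' `g'(r) = Lambda R_c^2 / r^3`, which is strictly positive whenever
#' `R_c > 0` - the origin of the radial-alignment instability. With
#' `R_c = 0` the growth rate is the constant `Lambda / 2` and `g' = 0`
#' (no orientational preference).
#'
#' @inheritParams vr_closed_form
#' @return A list with vectors `g` and `gprime`.
#' @export
local_growth_rate <- function(r, p) {
  if (any(r <= 0)) stop("r must be positive")
  list(g = p$Lambda * (r^2 - p$R_c^2) / (2 * r^2),
       gprime = p$Lambda * p$R_c^2 / r^3)
}

#' Orientation dynamics of a rod in the growth flow
#'
#' The flow-alignment approximation (uniform S, no molecular field or
#' spatial Q variation) gives
#' `dtheta/dt = xi g'(r) r sin(2 (phi - theta)) / (2 S)` for a rod at
#' angular position `phi` with orientation `theta`: the traceless strain
#' rate of the radial flow `v = g(r) r rhat` has magnitude `g'(r) r / 2`.
#' `theta = phi` (radial, aster) and `theta = phi + pi/2` (tangential) are
#' the fixed points.
#'
#' @param theta Orientation angle (rad).
#' @param phi Angular position of the rod (rad).
#' @param r Radius (um), > 0.
#' @param p A [theory_params()] object.
#' @return dtheta/dt (rad/time).
#' @export
orientation_rhs <- function(theta, phi, r, p) {
  if (p$S <= 0) stop("S must be positive (undefined director)")
  gp <- local_growth_rate(r, p)$gprime
  p$xi * gp * r * sin(2 * (phi - theta)) / (2 * p$S)
}

#' Fixed points of the orientation dynamics and their stability
#'
#' Linearising `dtheta/dt` about `theta = phi` gives decay rate
#' `xi g'(r) r / S`; about `theta = phi +- pi/2` the same magnitude with the
#' opposite sign. For `xi g' > 0` the radial (aster) state is stable and the
#' tangential state unstable; the labels swap when `xi g' < 0`, and all
#' orientations are neutrally stable when `xi g' = 0`.
#'
#' @inheritParams vr_closed_form
#' @return A data frame with `offset` (fixed point as theta - phi), `label`,
#'   `stability` and `rate` (linearised d(delta)/dt coefficient; negative
#'   means decay).
#' @export
classify_equilibria <- function(p, r) {
  if (any(r <= 0)) stop("r must be positive")
  gp <- local_growth_rate(r, p)$gprime
  k <- p$xi * gp * r / p$S
  stab <- function(rate) {
    if (rate < 0) "stable" else if (rate > 0) "unstable" else "neutral"
  }
  data.frame(offset = c(0, pi / 2),
             label = c("aster (radial)", "tangential"),
             stability = c(stab(-k), stab(k)),
             rate = c(-k, k))
}

#' Integrate the orientation equation
#'
#' Fixed-step classical 4th-order Runge-Kutta integration of
#' [orientation_rhs()] at fixed radius. For `xi g' > 0` and any start off
#' the tangential manifold, the wrapped nematic difference `|theta - phi|`
#' decreases monotonically to zero (convergence to the aster).
#'
#' @param theta0 Initial orientation (rad).
#' @param phi Angular position (rad).
#' @param r Radius (um).
#' @param p A [theory_params()] object.
#' @param t_end Final time.
#' @param dt Step size.
#' @return A data frame with `t` and `theta`.
#' @export
integrate_orientation <- function(theta0, phi, r, p, t_end, dt = t_end / 1000) {
  stopifnot(t_end >= 0, dt > 0)
  n <- ceiling(t_end / dt)
  th <- numeric(n + 1)
  th[1] <- theta0
  f <- function(x) orientation_rhs(x, phi, r, p)
  for (i in seq_len(n)) {
    x <- th[i]
    k1 <- f(x)
    k2 <- f(x + dt / 2 * k1)
    k3 <- f(x + dt / 2 * k2)
    k4 <- f(x + dt * k3)
    th[i + 1] <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  data.frame(t = seq(0, by = dt, length.out = n + 1), theta = th)
}

#' Hole-boundary trajectory under the closed-form velocity
#'
#' Integrates `dr/dt = v_r(r)` for a marker on the shrinking hole boundary
#' (RK4). Conservation of grown area implies
#' `pi (R_c^2 - r(t)^2) = pi (R_c^2 - r_0^2) exp(Lambda t)`, which this
#' integration reproduces; it serves as the independent oracle for the
#' closed-form profile.
#'
#' @param r0 Initial boundary radius (um), 0 < r0 < R_c for a hole.
#' @param p A [theory_params()] object.
#' @param t_end Final time.
#' @param dt Step size.
#' @return A data frame with `t` and `r`.
#' @export
integrate_hole_boundary <- function(r0, p, t_end, dt = t_end / 2000) {
  stopifnot(r0 > 0, t_end >= 0, dt > 0)
  n <- ceiling(t_end / dt)
  r <- numeric(n + 1)
  r[1] <- r0
  for (i in seq_len(n)) {
    x <- r[i]
    k1 <- vr_closed_form(x, p)
    k2 <- vr_closed_form(x + dt / 2 * k1, p)
    k3 <- vr_closed_form(x + dt / 2 * k2, p)
    k4 <- vr_closed_form(x + dt * k3, p)
    r[i + 1] <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (r[i + 1] <= 0) {
      r <- r[seq_len(i + 1)]
      r[i + 1] <- max(r[i + 1], 0)
      break
    }
  }
  data.frame(t = seq(0, by = dt, length.out = length(r)), r = r)
}
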