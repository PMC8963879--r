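# Finite-difference solver for the growing active-nematic continuum model:
#
#   D rho / Dt   = Lambda rho + D_rho lap(rho)
#   D(rho v)/Dt  = div(sigma) - gamma rho v
#   D Q / Dt     = xi u + Q.w - w.Q + H / Gamma
#
# with material derivative D/Dt = d/dt + v.grad + (div v) applied to all
# three fields, stress
#
#   sigma = -p I - a(rho) Q - xi H + Q.H - H.Q,
#
# molecular field H = K lap(Q) - alpha(rho) Q - beta(rho) tr(Q^2) Q from the
# Landau-de Gennes free energy, a(rho) = a0 rho, alpha(rho) = alpha0
# (rho_c - rho), beta(rho) = 2 alpha0 rho, and p = G max(rho/rho0 - 1, 0).
#
# Q is stored as its two independent components (Qxx, Qxy), so tracelessness
# and symmetry are exact by representation. Discretization: uniform grid,
# second-order central differences for gradients/Laplacians, first-order
# upwinding for all advection terms (preserves positivity of rho), explicit
# first-order time stepping, zero-normal-derivative (no-flux) boundaries by
# edge replication.

# edge-replicated neighbour shifts (matrix rows = x, cols = y)
sh_xp <- function(A) A[c(2:nrow(A), nrow(A)), , drop = FALSE]
sh_xm <- function(A) A[c(1, 1:(nrow(A) - 1)), , drop = FALSE]
sh_yp <- function(A) A[, c(2:ncol(A), ncol(A)), drop = FALSE]
sh_ym <- function(A) A[, c(1, 1:(ncol(A) - 1)), drop = FALSE]

ddx <- function(A, h) (sh_xp(A) - sh_xm(A)) / (2 * h)
ddy <- function(A, h) (sh_yp(A) - sh_ym(A)) / (2 * h)
lap <- function(A, h) {
  (sh_xp(A) + sh_xm(A) + sh_yp(A) + sh_ym(A) - 4 * A) / h^2
}

# first-order upwind advection term  v . grad A
upwind <- function(A, vx, vy, h) {
  dxm <- (A - sh_xm(A)) / h
  dxp <- (sh_xp(A) - A) / h
  dym <- (A - sh_ym(A)) / h
  dyp <- (sh_yp(A) - A) / h
  vx * ifelse(vx > 0, dxm, dxp) + vy * ifelse(vy > 0, dym, dyp)
}

#' Parameters of the continuum active-nematic model
#'
#' Defaults are the reference parameter set used throughout:
#' `Lambda = 0.005`, `gamma = 0.2`, `xi = 0.7`, `Gamma = 1`, `a0 = 0.002`,
#' `alpha0 = 0.01`, `rho_c = 0.5`, `G = 2`, `D_rho = 0.04`, `K = 0.01`,
#' `rho0 = 1` (dimensionless model units; one division time is
#' `log(2)/Lambda` time units). Explicit-scheme stability bounds (density
#' and Q diffusion, pressure-wave CFL, drag) are checked at construction.
#'
#' @param Lambda Growth rate.
#' @param D_rho Density diffusion.
#' @param gamma Frictional drag per unit density.
#' @param xi Flow alignment parameter.
#' @param Gamma Rotational diffusion constant (H enters as H / Gamma).
#' @param K Elastic constant of the Landau-de Gennes free energy.
#' @param a0 Activity scale; the active stress is `-a0 rho Q`
#'   (extensile for `a0 > 0`: outward flow along the director).
#' @param alpha0 Landau scale; `alpha(rho) = alpha0 (rho_c - rho)`.
#' @param rho_c Critical density above which the isotropic state is
#'   unstable.
#' @param rho0 Initial/reference density; pressure onset.
#' @param G Pressure stiffness: `p = G max(rho/rho0 - 1, 0)`.
#' @param nu_m Momentum viscosity (numerical regularization; a colocated
#'   grid with central pressure gradients supports a checkerboard mode that
#'   this small diffusive term damps).
#' @param h Grid spacing.
#' @param dt Time step (default: set from the stability bounds).
#' @param beta_form `"2a0rho"` (default; `beta = 2 alpha0 rho`, bounded at
#'   low density) or `"a0over2rho"` (`beta = alpha0 / (2 rho)`).
#' @param activity_sign +1 for extensile (default), -1 contractile.
#' @return A list of class `continuum_params`.
#' @export
continuum_params <- function(Lambda = 0.005, D_rho = 0.04, gamma = 0.2,
                             xi = 0.7, Gamma = 1, K = 0.01, a0 = 0.002,
                             alpha0 = 0.01, rho_c = 0.5, rho0 = 1, G = 2,
                             nu_m = 0.5, h = 1, dt = NULL,
                             beta_form = c("2a0rho", "a0over2rho"),
                             activity_sign = 1) {
  beta_form <- match.arg(beta_form)
  stopifnot(Lambda > 0, D_rho >= 0, gamma > 0, Gamma > 0, K >= 0, rho0 > 0,
            G >= 0, nu_m >= 0, h > 0)
  cwave <- sqrt(G / rho0) + 1e-12
  dt_max <- min(0.2 * h^2 / max(D_rho, 1e-12),
                0.2 * h^2 * Gamma / max(K, 1e-12),
                0.2 * h^2 / max(nu_m, 1e-12),
                0.4 * h / cwave,
                0.5 / gamma)
  if (is.null(dt)) {
    dt <- signif(dt_max, 2)
    if (dt > dt_max) dt <- signif(0.9 * dt_max, 2)
  }
  if (dt > dt_max) {
    stop(sprintf("dt = %g violates the stability bounds (max %g)", dt, dt_max))
  }
  structure(list(Lambda = Lambda, D_rho = D_rho, gamma = gamma, xi = xi,
                 Gamma = Gamma, K = K, a0 = a0, alpha0 = alpha0,
                 rho_c = rho_c, rho0 = rho0, G = G, nu_m = nu_m, h = h,
                 dt = dt,
                 beta_form = beta_form, activity_sign = activity_sign),
            class = "continuum_params")
}

#' Initialise a continuum field state
#'
#' Density `rho0` inside a disk or annulus (tanh-smoothed edge of width
#' `2 h`), zero outside; velocities zero; independent Gaussian noise of
#' standard deviation `q_noise_sd` on `Qxx`, `Qxy` inside the colony.
#'
#' @param kind `"disk"` or `"annulus"`.
#' @param nx,ny Grid size (nodes); the domain is centered on the origin.
#' @param params A [continuum_params()] object.
#' @param radius Disk radius (for `kind = "disk"`).
#' @param R_in,R_out Annulus radii (for `kind = "annulus"`).
#' @param q_noise_sd Initial Q noise standard deviation.
#' @param seed RNG seed for the noise.
#' @return A list of class `field_state` with matrices `rho`, `Qxx`, `Qxy`,
#'   `vx`, `vy`, the node coordinate vectors `xs`, `ys`, and time `t`.
#' @export
field_state_init <- function(kind = c("annulus", "disk"), nx = 128, ny = nx,
                             params = continuum_params(), radius = 30,
                             R_in = 20, R_out = 40, q_noise_sd = 0.01,
                             seed = 1L) {
  kind <- match.arg(kind)
  h <- params$h
  xs <- (seq_len(nx) - (nx + 1) / 2) * h
  ys <- (seq_len(ny) - (ny + 1) / 2) * h
  rr <- sqrt(outer(xs^2, ys^2, `+`))
  w <- 2 * h
  prof <- if (kind == "disk") {
    0.5 * (1 - tanh((rr - radius) / w))
  } else {
    0.5 * (tanh((rr - R_in) / w) - tanh((rr - R_out) / w))
  }
  rho <- params$rho0 * prof
  set.seed(seed)
  inside <- prof > 0.5
  Qxx <- matrix(0, nx, ny); Qxy <- matrix(0, nx, ny)
  Qxx[inside] <- rnorm(sum(inside), 0, q_noise_sd)
  Qxy[inside] <- rnorm(sum(inside), 0, q_noise_sd)
  structure(list(rho = rho, Qxx = Qxx, Qxy = Qxy,
                 vx = matrix(0, nx, ny), vy = matrix(0, nx, ny),
                 xs = xs, ys = ys, t = 0, clipped_mass = 0),
            class = "field_state")
}

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf("<field_state> %d x %d grid, t = %.4g, total mass %.4g\n",
              nrow(x$rho), ncol(x$rho), x$t, sum(x$rho)))
  invisible(x)
}

beta_rho <- function(rho, p) {
  if (p$beta_form == "2a0rho") 2 * p$alpha0 * rho
  else p$alpha0 / (2 * pmax(rho, 1e-6))
}

#' Molecular field of the Landau-de Gennes free energy
#'
#' `H = K lap(Q) - alpha(rho) Q - beta(rho) tr(Q^2) Q` with
#' `alpha(rho) = alpha0 (rho_c - rho)` and `tr(Q^2) = 2 (Qxx^2 + Qxy^2)`.
#' Output is symmetric traceless by representation.
#'
#' @param state A `field_state`.
#' @param params A [continuum_params()] object.
#' @return A list with matrices `Hxx`, `Hxy`.
#' @export
molecular_field <- function(state, params) {
  h <- params$h
  trQ2 <- 2 * (state$Qxx^2 + state$Qxy^2)
  al <- params$alpha0 * (params$rho_c - state$rho)
  be <- beta_rho(state$rho, params)
  list(Hxx = params$K * lap(state$Qxx, h) - al * state$Qxx - be * trQ2 * state$Qxx,
       Hxy = params$K * lap(state$Qxy, h) - al * state$Qxy - be * trQ2 * state$Qxy)
}

#' Discrete Landau-de Gennes free energy
#'
#' The free energy whose (negated, halved) discrete variational derivative
#' is the molecular field: gradient terms are summed over grid edges so that
#' the edge-replicated Laplacian in [molecular_field()] is its exact
#' gradient. Used for the gradient-flow (free-energy descent) diagnostics.
#'
#' @inheritParams molecular_field
#' @return Scalar free energy.
#' @export
ldg_free_energy <- function(state, params) {
  h <- params$h
  trQ2 <- 2 * (state$Qxx^2 + state$Qxy^2)
  al <- params$alpha0 * (params$rho_c - state$rho)
  be <- beta_rho(state$rho, params)
  local <- sum(al / 2 * trQ2 + be / 4 * trQ2^2) * h^2
  edge_en <- function(A) {
    dx <- A[-1, , drop = FALSE] - A[-nrow(A), , drop = FALSE]
    dy <- A[, -1, drop = FALSE] - A[, -ncol(A), drop = FALSE]
    sum(dx^2) + sum(dy^2)
  }
  grad <- params$K / 2 * 2 * (edge_en(state$Qxx) + edge_en(state$Qxy))
  local + grad
}

#' Continuum stress tensor
#'
#' `sigma = -p I - a(rho) Q - xi H + Q.H - H.Q` with `a(rho) = a0 rho` and
#' `p = G max(rho/rho0 - 1, 0)`. The commutator `Q.H - H.Q` is antisymmetric
#' with zero diagonal; the full (asymmetric) tensor is returned.
#'
#' @inheritParams molecular_field
#' @param H Optional precomputed molecular field.
#' @return A list with matrices `sxx`, `sxy`, `syx`, `syy` and the pressure
#'   `p`.
#' @export
continuum_stress <- function(state, params, H = molecular_field(state, params)) {
  a <- params$activity_sign * params$a0 * state$rho
  p <- params$G * pmax(state$rho / params$rho0 - 1, 0)
  comm <- state$Qxx * H$Hxy - state$Qxy * H$Hxx  # (Q.H - H.Q)_xy / 2
  list(sxx = -p - a * state$Qxx - params$xi * H$Hxx,
       syy = -p + a * state$Qxx + params$xi * H$Hxx,
       sxy = -a * state$Qxy - params$xi * H$Hxy + 2 * comm,
       syx = -a * state$Qxy - params$xi * H$Hxy - 2 * comm,
       p = p)
}

#' Advance the continuum fields by one explicit step
#'
#' First-order explicit update of density (growth, diffusion, upwind
#' advection, dilution), momentum (stress divergence minus frictional drag)
#' and Q (flow alignment, corotation, relaxation `H / Gamma`, advection and
#' dilution). Density is clipped at zero with the clipped mass accumulated
#' in `state$clipped_mass`. Aborts with step diagnostics if any field
#' becomes non-finite.
#'
#' @inheritParams molecular_field
#' @return The advanced `field_state`.
#' @export
continuum_step <- function(state, params) {
  h <- params$h; dt <- params$dt
  rho <- state$rho; Qxx <- state$Qxx; Qxy <- state$Qxy
  vx <- state$vx; vy <- state$vy

  dxvx <- ddx(vx, h); dyvx <- ddy(vx, h)
  dxvy <- ddx(vy, h); dyvy <- ddy(vy, h)
  divv <- dxvx + dyvy
  uxx <- 0.5 * (dxvx - dyvy)          # traceless symmetric strain rate
  uxy <- 0.5 * (dxvy + dyvx)
  w <- 0.5 * (dxvy - dyvx)            # vorticity (xy component)

  H <- molecular_field(state, params)
  sig <- continuum_stress(state, params, H)
  fx <- ddx(sig$sxx, h) + ddy(sig$syx, h)
  fy <- ddx(sig$sxy, h) + ddy(sig$syy, h)

  mx <- rho * vx; my <- rho * vy
  mx_new <- mx + dt * (-upwind(mx, vx, vy, h) - divv * mx + fx -
                         params$gamma * rho * vx +
                         params$nu_m * lap(mx, h))
  my_new <- my + dt * (-upwind(my, vx, vy, h) - divv * my + fy -
                         params$gamma * rho * vy +
                         params$nu_m * lap(my, h))

  rho_new <- rho + dt * (-upwind(rho, vx, vy, h) - divv * rho +
                           params$Lambda * rho + params$D_rho * lap(rho, h))
  clip <- sum(pmin(rho_new, 0))
  rho_new[rho_new < 0] <- 0

  corot_xx <- -2 * w * Qxy
  corot_xy <- 2 * w * Qxx
  Qxx_new <- Qxx + dt * (-upwind(Qxx, vx, vy, h) - divv * Qxx +
                           params$xi * uxx + corot_xx + H$Hxx / params$Gamma)
  Qxy_new <- Qxy + dt * (-upwind(Qxy, vx, vy, h) - divv * Qxy +
                           params$xi * uxy + corot_xy + H$Hxy / params$Gamma)

  # momentum is meaningful only where there is material: below a small
  # density cutoff the velocity (and momentum) are zeroed, preventing the
  # unbounded accelerations m / rho would give in the near-vacuum outside
  # the colony edge
  rho_floor <- 0.02 * params$rho0
  vx_new <- ifelse(rho_new > rho_floor, mx_new / pmax(rho_new, rho_floor), 0)
  vy_new <- ifelse(rho_new > rho_floor, my_new / pmax(rho_new, rho_floor), 0)

  if (!all(is.finite(rho_new)) || !all(is.finite(Qxx_new)) ||
      !all(is.finite(vx_new))) {
    stop(sprintf(paste0("continuum solver diverged at t = %.4g ",
                        "(non-finite field values; max |v| = %.3g, ",
                        "max rho = %.3g)"),
                 state$t, max(abs(c(vx, vy))), max(rho)))
  }

  state$rho <- rho_new; state$Qxx <- Qxx_new; state$Qxy <- Qxy_new
  state$vx <- vx_new; state$vy <- vy_new
  state$t <- state$t + dt
  state$clipped_mass <- state$clipped_mass - clip * h^2
  state
}

#' Run the continuum model and collect snapshots
#'
#' Steps the solver to `t_end`, snapshotting every `snapshot_every` time
#' units. Stops cleanly when the colony (density above 5% of `rho0`)
#' reaches within `boundary_margin` nodes of the domain edge.
#'
#' @inheritParams molecular_field
#' @param t_end Final time.
#' @param snapshot_every Snapshot cadence.
#' @param boundary_margin Stop margin in nodes.
#' @return A list of `field_state` snapshots (class `field_trajectory`);
#'   attribute `stopped` indicates an early boundary stop.
#' @export
continuum_run <- function(state, params, t_end, snapshot_every = t_end / 10,
                          boundary_margin = 4L) {
  snaps <- list(state)
  n_chunks <- max(1L, ceiling(t_end / snapshot_every))
  steps_per <- max(1L, round(snapshot_every / params$dt))
  stopped <- FALSE
  for (ch in seq_len(n_chunks)) {
    for (s in seq_len(steps_per)) {
      state <- continuum_step(state, params)
      if (state$t >= t_end) break
    }
    snaps[[length(snaps) + 1L]] <- state
    m <- boundary_margin
    edge <- max(state$rho[c(seq_len(m), nrow(state$rho) - seq_len(m) + 1L), ],
                state$rho[, c(seq_len(m), ncol(state$rho) - seq_len(m) + 1L)])
    if (edge > 0.05 * params$rho0) { stopped <- TRUE; break }
    if (state$t >= t_end) break
  }
  structure(snaps, class = "field_trajectory", stopped = stopped)
}

#' Quasi-static velocity field
#'
#' Solves the friction-dominated momentum balance `gamma rho v = div(sigma)`
#' pointwise for the velocity, the late-time limit of the damped momentum
#' equation. Provided as a cross-check on the dynamic solution.
#'
#' @inheritParams molecular_field
#' @return A list with matrices `vx`, `vy`.
#' @export
quasi_static_velocity <- function(state, params) {
  H <- molecular_field(state, params)
  sig <- continuum_stress(state, params, H)
  h <- params$h
  fx <- ddx(sig$sxx, h) + ddy(sig$syx, h)
  fy <- ddx(sig$sxy, h) + ddy(sig$syy, h)
  denom <- params$gamma * pmax(state$rho, 1e-4 * params$rho0)
  mask <- state$rho > 0.05 * params$rho0
  list(vx = ifelse(mask, fx / denom, 0), vy = ifelse(mask, fy / denom, 0))
}

#' Scalar order parameter field `S = 2 sqrt(Qxx^2 + Qxy^2)`
#' @inheritParams molecular_field
#' @return Matrix of S values.
#' @export
scalar_order <- function(state) 2 * sqrt(state$Qxx^2 + state$Qxy^2)

#' Director angle field, `0.5 atan2(Qxy, Qxx)` in (-pi/2, pi/2]
#' @inheritParams molecular_field
#' @return Matrix of director angles (rad).
#' @export
director_angle <- function(state) 0.5 * atan2(state$Qxy, state$Qxx)
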