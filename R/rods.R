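#' Strain specification for growing rods
#'
#' A strain is characterised by its exponential elongation rate and the
#' cylinder length at which a rod divides. Division splits a rod at a point
#' drawn from a zero-mean normal with standard deviation
#' `division_noise_sd_frac * L`, redrawn until it lies within
#' `division_noise_cap_frac * L` of the rod center.
#'
#' Times are measured in division times of the reference strain, so the
#' default growth rate is `log(2)` (lengths double per unit time); lengths
#' are in micrometres.
#'
#' @param strain_id Positive integer label (1-based, consecutive across the
#'   strain table of a colony).
#' @param growth_rate Exponential elongation rate Lambda (1/time).
#' @param division_length Cylinder length threshold for division (um).
#' @param division_noise_sd_frac Standard deviation of the split-point offset
#'   as a fraction of the rod length.
#' @param division_noise_cap_frac Hard cap on the offset as a fraction of the
#'   rod length.
#' @param diameter Rod diameter (um), constant over a rod's lifetime.
#' @return A one-row `data.frame` with class `strain_spec` columns.
#' @export
strain_spec <- function(strain_id = 1L, growth_rate = log(2),
                        division_length = 5, division_noise_sd_frac = 0.1,
                        division_noise_cap_frac = 0.2, diameter = 1) {
  stopifnot(growth_rate > 0, division_length > diameter, diameter > 0,
            division_noise_sd_frac >= 0, division_noise_cap_frac >= 0)
  data.frame(strain_id = as.integer(strain_id), growth_rate = growth_rate,
             division_length = division_length,
             division_noise_sd_frac = division_noise_sd_frac,
             division_noise_cap_frac = division_noise_cap_frac,
             diameter = diameter)
}

#' Simulation parameters for the overdamped rod engine
#'
#' The dynamics are overdamped: velocities are proportional to forces, with
#' translational drag scaling as the rod extent (L + d) and rotational drag
#' as (L + d)^3 (slender-body-like), so torque response is strongly
#' length-dependent. Contact repulsion is `repulsion_stiffness *
#' overlap^contact_exponent` (Hertzian-like 3/2 by default).
#'
#' @param dt Time step (division times). The explicit scheme requires
#'   `dt * repulsion_stiffness / zeta_t` below `stability_threshold`.
#' @param repulsion_stiffness Contact stiffness k.
#' @param contact_exponent 1.5 (Hertzian-like) or 1 (linear).
#' @param zeta_t Translational drag per unit extent.
#' @param zeta_r Rotational drag coefficient (per extent cubed). The default
#'   `zeta_t / 12` is the slender-body value: uniform drag per unit length
#'   `lambda` gives total translational drag `lambda L` and rotational drag
#'   `lambda L^3 / 12` about the center.
#' @param drag_ratio Ratio of axial to transverse translational drag
#'   (anisotropic substrate drag; slender bodies slide more easily along
#'   their axis, classically about 1/2).
#' @param friction_gamma Tangential contact friction: viscous coefficient
#'   resisting relative sliding at each contact (0 disables). Rigid-body
#'   colony engines transmit tangential stress at contacts; without it,
#'   frictionless soft rods slide past each other and the colony flow
#'   gradient cannot exert its full aligning torque.
#' @param friction_mu Coulomb cap: tangential force magnitude is limited to
#'   `friction_mu` times the normal force at the same contact.
#' @param wall Optional fixed circular wall: `list(center = c(x, y),
#'   radius, stiffness)`.
#' @param max_rod_count Simulation stops cleanly above this count.
#' @param rng_seed Root seed; seeding and division noise use derived child
#'   seeds so stages are independently reproducible.
#' @param stability_threshold Upper bound enforced on `dt * k / zeta_t`.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(dt = 1.25e-4, repulsion_stiffness = 30000,
                       contact_exponent = 1.5, zeta_t = 1,
                       zeta_r = zeta_t / 12, drag_ratio = 0.5,
                       friction_gamma = 0, friction_mu = 1,
                       wall = NULL, max_rod_count = 50000L, rng_seed = 1L,
                       stability_threshold = 10) {
  stopifnot(dt > 0, repulsion_stiffness > 0, zeta_t > 0, zeta_r > 0,
            friction_gamma >= 0, friction_mu >= 0)
  if (dt * repulsion_stiffness / zeta_t >= stability_threshold) {
    stop("unstable configuration: dt * k / zeta_t = ",
         dt * repulsion_stiffness / zeta_t, " >= ", stability_threshold)
  }
  if (!is.null(wall)) {
    stopifnot(is.list(wall), length(wall$center) == 2, wall$radius > 0,
              wall$stiffness > 0)
  }
  structure(list(dt = dt, repulsion_stiffness = repulsion_stiffness,
                 contact_exponent = contact_exponent, zeta_t = zeta_t,
                 zeta_r = zeta_r, drag_ratio = drag_ratio,
                 friction_gamma = friction_gamma,
                 friction_mu = friction_mu, wall = wall,
                 max_rod_count = as.integer(max_rod_count),
                 rng_seed = as.integer(rng_seed),
                 stability_threshold = stability_threshold),
            class = "sim_params")
}

new_colony <- function(rods, strains, params, time = 0,
                       next_id = max(c(0L, rods$id)) + 1L) {
  stopifnot(!anyDuplicated(rods$id))
  structure(list(time = time, rods = rods, strains = strains,
                 params = params, next_id = as.integer(next_id)),
            class = "colony")
}

#' @export
print.colony <- function(x, ...) {
  cat(sprintf("<colony> %d rods, %d strain(s), t = %.4g\n",
              nrow(x$rods), nrow(x$strains), x$time))
  invisible(x)
}

empty_rods <- function() {
  data.frame(id = integer(), strain_id = integer(), x = numeric(),
             y = numeric(), theta = numeric(), length = numeric(),
             diameter = numeric(), parent_id = integer())
}

# ---- seeding geometries ----------------------------------------------------

#' Seeding geometries
#'
#' Constructors describing the initial spatial arrangement of rods:
#' a single cell at the origin, a uniformly filled disk, an annulus, a ring
#' of small founder colonies, or an annulus whose azimuthal sectors are
#' pre-assigned to strains (segregated seeding for competition runs).
#'
#' @param R,R_in,R_out Radii (um).
#' @param n Total number of rods.
#' @param n_sites,n_per_site Founder sites on the ring and rods per site.
#' @param site_radius Radius of each founder patch (um).
#' @param n_sectors Number of azimuthal sectors.
#' @param strain_assignment Integer vector of length `n_sectors` mapping each
#'   sector to a strain id (default alternates the colony's strains).
#' @return A geometry description list.
#' @export
geom_single_cell <- function() list(type = "single_cell", n = 1L)

#' @rdname geom_single_cell
#' @export
geom_random_disk <- function(R, n) {
  stopifnot(R > 0, n >= 1)
  list(type = "random_disk", R = R, n = as.integer(n))
}

#' @rdname geom_single_cell
#' @export
geom_annulus <- function(R_in, R_out, n) {
  stopifnot(R_in > 0, R_out > R_in, n >= 1)
  list(type = "annulus", R_in = R_in, R_out = R_out, n = as.integer(n))
}

#' @rdname geom_single_cell
#' @export
geom_ring_of_colonies <- function(R, n_sites, n_per_site,
                                  site_radius = R * pi / (2 * n_sites)) {
  stopifnot(R > 0, n_sites >= 1, n_per_site >= 1, site_radius > 0)
  list(type = "ring_of_colonies", R = R, n_sites = as.integer(n_sites),
       n_per_site = as.integer(n_per_site), site_radius = site_radius,
       n = as.integer(n_sites * n_per_site))
}

#' @rdname geom_single_cell
#' @export
geom_sector_annulus <- function(R_in, R_out, n, n_sectors,
                                strain_assignment = NULL) {
  stopifnot(R_in > 0, R_out > R_in, n >= 1, n_sectors >= 1)
  list(type = "sector_annulus", R_in = R_in, R_out = R_out,
       n = as.integer(n), n_sectors = as.integer(n_sectors),
       strain_assignment = strain_assignment)
}

sample_positions <- function(geometry, n) {
  switch(geometry$type,
    single_cell = data.frame(x = 0, y = 0),
    random_disk = {
      r <- geometry$R * sqrt(runif(n))
      a <- runif(n, -pi, pi)
      data.frame(x = r * cos(a), y = r * sin(a))
    },
    annulus = ,
    sector_annulus = {
      r <- sqrt(runif(n, geometry$R_in^2, geometry$R_out^2))
      a <- runif(n, -pi, pi)
      data.frame(x = r * cos(a), y = r * sin(a))
    },
    ring_of_colonies = {
      site <- rep(seq_len(geometry$n_sites), length.out = n)
      phi0 <- 2 * pi * (site - 1) / geometry$n_sites
      r <- geometry$site_radius * sqrt(runif(n))
      a <- runif(n, -pi, pi)
      data.frame(x = geometry$R * cos(phi0) + r * cos(a),
                 y = geometry$R * sin(phi0) + r * sin(a))
    },
    stop("unknown geometry type: ", geometry$type))
}

#' Seed a colony
#'
#' Places `n` rods in the requested geometry with i.i.d. uniform nematic
#' orientations and initial cylinder lengths uniform between 40% and 80% of
#' the division length. Placement is by rejection: overlapping rods (pair
#' overlap beyond 10% of the diameter) are redrawn, up to `max_retries`
#' passes, after which an infeasible-packing error reports the requested
#' density.
#'
#' @param geometry A geometry from [geom_single_cell()] and friends.
#' @param strains A `data.frame` of [strain_spec()] rows (rbind for several).
#' @param params A [sim_params()] object.
#' @param seed Seed for the placement stream (default: derived from
#'   `params$rng_seed`).
#' @param max_retries Redraw passes before giving up.
#' @return A `colony` object at time 0.
#' @export
seed_colony <- function(geometry, strains = strain_spec(),
                        params = sim_params(),
                        seed = child_seed(params$rng_seed, 1L),
                        max_retries = 200L) {
  stopifnot(inherits(params, "sim_params"), nrow(strains) >= 1)
  set.seed(seed)
  n <- geometry$n
  sid <- assign_strains(geometry, strains, n)
  diam <- strains$diameter[match(sid, strains$strain_id)]
  ldiv <- strains$division_length[match(sid, strains$strain_id)]
  pos <- sample_positions(geometry, n)
  theta <- runif(n, -pi, pi)
  len <- runif(n, 0.4, 0.8) * ldiv
  if (geometry$type == "single_cell") {
    pos$x <- 0; pos$y <- 0
  }
  tol <- 0.1 * mean(diam)
  if (n > 1) {
    for (pass in seq_len(max_retries)) {
      cf <- cpp_contact_forces(pos$x, pos$y, theta, len, diam, seq_len(n),
                               1, 1)
      bad <- unique(cf$pair_j[cf$overlap > tol])
      # resample the azimuthal/positional draw for later-placed offenders,
      # but re-assign strain-dependent attributes consistently
      if (length(bad) == 0) break
      if (pass == max_retries) {
        area <- sum(len * diam + pi * diam^2 / 4)
        stop(sprintf(paste0("infeasible packing: could not place %d rods ",
                            "without overlap (requested rod area %.1f um^2 ",
                            "in the stated region)"), n, area))
      }
      sub <- geometry
      sub$n <- length(bad)
      newpos <- sample_positions(sub, length(bad))
      pos$x[bad] <- newpos$x
      pos$y[bad] <- newpos$y
      theta[bad] <- runif(length(bad), -pi, pi)
    }
  }
  rods <- data.frame(id = seq_len(n), strain_id = sid, x = pos$x, y = pos$y,
                     theta = theta, length = len, diameter = diam,
                     parent_id = NA_integer_)
  if (geometry$type == "sector_annulus") {
    # strain labels depend on final angular position; refresh after redraws
    # and rescale initial lengths to each rod's own division length so all
    # strains start at the same cell-cycle phase distribution
    rods$strain_id <- sector_strain(rods$x, rods$y, geometry, strains)
    idx <- match(rods$strain_id, strains$strain_id)
    rods$diameter <- strains$diameter[idx]
    rods$length <- rods$length / ldiv * strains$division_length[idx]
  }
  new_colony(rods, strains, params)
}

assign_strains <- function(geometry, strains, n) {
  if (geometry$type == "sector_annulus") {
    rep(strains$strain_id[1], n)  # placeholder, set after placement
  } else if (nrow(strains) == 1) {
    rep(strains$strain_id, n)
  } else {
    # balanced counts across strains, in random spatial order
    sample(rep(strains$strain_id, length.out = n))
  }
}

sector_strain <- function(x, y, geometry, strains) {
  assign <- geometry$strain_assignment
  if (is.null(assign)) {
    assign <- rep(strains$strain_id, length.out = geometry$n_sectors)
  }
  phi <- atan2(y, x)
  sec <- pmin(geometry$n_sectors,
              1L + floor((phi + pi) / (2 * pi) * geometry$n_sectors))
  as.integer(assign[sec])
}

# ---- elementary operations -------------------------------------------------

#' Grow all rods exponentially
#'
#' Multiplies each cylinder length by `exp(Lambda_strain * dt)`; positions,
#' orientations and everything else are unchanged.
#'
#' @param colony A `colony`.
#' @param dt Time increment (>= 0).
#' @return The grown colony with `time` advanced by `dt`.
#' @export
grow <- function(colony, dt) {
  stopifnot(dt >= 0)
  lam <- colony$strains$growth_rate[match(colony$rods$strain_id,
                                          colony$strains$strain_id)]
  colony$rods$length <- colony$rods$length * exp(lam * dt)
  colony$time <- colony$time + dt
  colony
}

#' Divide over-threshold rods
#'
#' Every rod whose cylinder length exceeds its strain's division length is
#' replaced by two collinear children. The split point is drawn from
#' N(0, (L * sd_frac)^2), redrawn until within `cap_frac * L` of the center.
#' The children tile the parent's full spherocylinder extent (caps touching),
#' so their cylinder lengths sum to the parent's minus one diameter: no
#' spherocylinder area is created or destroyed by division. Children inherit
#' the strain, receive fresh ids, and record the parent id.
#'
#' Division noise consumes the R random number stream; seed it (or rely on
#' [run_colony()], which seeds a dedicated stream) for reproducibility.
#'
#' @param colony A `colony`.
#' @return The colony with divisions applied.
#' @export
divide <- function(colony) {
  r <- colony$rods
  s <- colony$strains
  idx <- match(sort(s$strain_id), s$strain_id)
  res <- cpp_divide(r$x, r$y, r$theta, r$length, r$diameter, r$strain_id,
                    r$id, ifelse(is.na(r$parent_id), -1L, r$parent_id),
                    s$division_length[idx], s$division_noise_sd_frac[idx],
                    s$division_noise_cap_frac[idx], colony$next_id)
  colony$rods <- data.frame(id = res$id, strain_id = res$strain_id,
                            x = res$x, y = res$y, theta = res$theta,
                            length = res$length, diameter = res$diameter,
                            parent_id = ifelse(res$parent_id < 0, NA_integer_,
                                               res$parent_id))
  colony$next_id <- res$next_id
  colony
}

#' Pairwise contact forces and torques
#'
#' Computes the repulsive force between every rod pair whose minimal
#' segment-segment distance is below the mean diameter:
#' `k * overlap^exponent` along the minimal-distance direction, applied at
#' the midpoint of the closest points. Internal interactions are
#' equal-and-opposite, so total force and total torque about any fixed point
#' vanish to machine precision.
#'
#' @param colony A `colony`.
#' @return A list with per-rod `fx`, `fy`, `torque`, a `pairs` data frame
#'   (`i`, `j` row indices, contact point, force on `i`, overlap), and the
#'   maximum overlap seen.
#' @export
contact_forces <- function(colony) {
  r <- colony$rods
  p <- colony$params
  cf <- cpp_contact_forces(r$x, r$y, r$theta, r$length, r$diameter, r$id,
                           p$repulsion_stiffness, p$contact_exponent)
  list(fx = cf$fx, fy = cf$fy, torque = cf$torque,
       pairs = data.frame(i = cf$pair_i, j = cf$pair_j, x = cf$contact_x,
                          y = cf$contact_y, fx = cf$force_x, fy = cf$force_y,
                          overlap = cf$overlap),
       max_overlap = cf$max_overlap)
}

#' Confining-wall forces
#'
#' Inward normal repulsion on any end cap protruding past the configured
#' circular wall, with the same force law as rod-rod contacts.
#'
#' @param colony A `colony` whose params configure a `wall`.
#' @return A list with per-rod `fx`, `fy`, `torque`.
#' @export
wall_forces <- function(colony) {
  p <- colony$params
  if (is.null(p$wall)) stop("no wall configured in sim_params")
  r <- colony$rods
  cpp_wall_forces(r$x, r$y, r$theta, r$length, r$diameter,
                  p$wall$center[1], p$wall$center[2], p$wall$radius,
                  p$wall$stiffness, p$contact_exponent)
}

#' Advance a colony by one or more time steps
#'
#' Each step applies grow, then division, then contact (and wall) forces,
#' then the overdamped update `dx = F dt / (zeta_t (L + d))`,
#' `dtheta = T dt / (zeta_r (L + d)^3)`. Stops cleanly (attribute `stopped`)
#' when the rod count exceeds `max_rod_count`.
#'
#' @param colony A `colony`.
#' @param dt Step size (default `params$dt`).
#' @param n_steps Number of steps.
#' @return The advanced colony; attributes `stopped` and `max_overlap`
#'   carry engine diagnostics.
#' @export
step_colony <- function(colony, dt = colony$params$dt, n_steps = 1L) {
  p <- colony$params
  s <- colony$strains
  r <- colony$rods
  idx <- match(sort(s$strain_id), s$strain_id)
  has_wall <- !is.null(p$wall)
  res <- cpp_advance(r$x, r$y, r$theta, r$length, r$diameter, r$strain_id,
                     r$id, ifelse(is.na(r$parent_id), -1L, r$parent_id),
                     s$growth_rate[idx], s$division_length[idx],
                     s$division_noise_sd_frac[idx],
                     s$division_noise_cap_frac[idx],
                     dt, p$repulsion_stiffness, p$contact_exponent,
                     p$zeta_t, p$zeta_r,
                     if (is.null(p$drag_ratio)) 1 else p$drag_ratio,
                     if (is.null(p$friction_gamma)) 0 else p$friction_gamma,
                     if (is.null(p$friction_mu)) 1 else p$friction_mu,
                     has_wall,
                     if (has_wall) p$wall$center[1] else 0,
                     if (has_wall) p$wall$center[2] else 0,
                     if (has_wall) p$wall$radius else 0,
                     if (has_wall) p$wall$stiffness else 0,
                     p$max_rod_count, as.integer(n_steps), colony$time,
                     colony$next_id)
  colony$rods <- data.frame(id = res$id, strain_id = res$strain_id,
                            x = res$x, y = res$y, theta = res$theta,
                            length = res$length, diameter = res$diameter,
                            parent_id = ifelse(res$parent_id < 0, NA_integer_,
                                               res$parent_id))
  colony$time <- res$time
  colony$next_id <- res$next_id
  attr(colony, "stopped") <- res$stopped
  attr(colony, "max_overlap") <- res$max_overlap
  colony
}

#' Run a colony simulation and collect snapshots
#'
#' Seeds a dedicated division-noise stream from the colony's root seed, then
#' advances in chunks of `snapshot_every`, recording a snapshot after each
#' chunk. Identical `(seed, params)` give bit-identical trajectories. When
#' `out_dir` is given, each snapshot is written as a CSV (see
#' [write_snapshot()]) together with a JSON run manifest.
#'
#' @param colony Initial `colony` (time 0 or later).
#' @param t_end Final time.
#' @param snapshot_every Snapshot cadence (defaults to `t_end / 10`).
#' @param out_dir Optional output directory for snapshot files + manifest.
#' @return A list of `colony` snapshots (class `colony_trajectory`); the
#'   first element is the initial state. Attribute `stopped` reports an
#'   early stop on `max_rod_count`.
#' @export
run_colony <- function(colony, t_end, snapshot_every = t_end / 10,
                       out_dir = NULL) {
  stopifnot(t_end >= 0)
  set.seed(child_seed(colony$params$rng_seed, 2L))
  snaps <- list(colony)
  t0 <- colony$time
  stopped <- FALSE
  if (t_end > 0) {
    n_chunks <- max(1L, ceiling((t_end - 1e-12) / snapshot_every))
    for (ch in seq_len(n_chunks)) {
      t_target <- min(t0 + ch * snapshot_every, t0 + t_end)
      n_steps <- round((t_target - colony$time) / colony$params$dt)
      if (n_steps <= 0) next
      colony <- step_colony(colony, n_steps = n_steps)
      snaps[[length(snaps) + 1L]] <- colony
      if (isTRUE(attr(colony, "stopped"))) { stopped <- TRUE; break }
    }
  }
  traj <- structure(snaps, class = "colony_trajectory", stopped = stopped)
  if (!is.null(out_dir)) write_trajectory(traj, out_dir)
  traj
}

#' Interior void (hole) area of a colony
#'
#' Rasterizes the rod footprints on a grid (cell size half a diameter by
#' default) and flood-fills the empty region containing `center`, returning
#' its area. Used for inward-growth tracking and closure detection.
#'
#' @param colony A `colony`.
#' @param center Point inside the hole (default: origin).
#' @param cell Raster cell size (um).
#' @return Hole area in um^2 (0 when the center is covered by a rod).
#' @export
hole_area <- function(colony, center = c(0, 0),
                      cell = mean(colony$rods$diameter) / 2) {
  r <- colony$rods
  ext <- (r$length + r$diameter) / 2
  xmin <- min(r$x - ext); xmax <- max(r$x + ext)
  ymin <- min(r$y - ext); ymax <- max(r$y + ext)
  # confine the raster to the region bounded by the rods; a hole is interior
  nx <- max(4L, ceiling((xmax - xmin) / cell))
  ny <- max(4L, ceiling((ymax - ymin) / cell))
  occ <- cpp_rasterize(r$x, r$y, r$theta, r$length, r$diameter,
                       xmin, ymin, cell, nx, ny)
  sx <- 1L + floor((center[1] - xmin) / cell)
  sy <- 1L + floor((center[2] - ymin) / cell)
  if (sx < 1 || sx > nx || sy < 1 || sy > ny) return(0)
  cpp_flood_area(occ, sx, sy) * cell^2
}

#' Effective hole radius, `sqrt(hole_area / pi)`
#' @inheritParams hole_area
#' @return Radius in um.
#' @export
hole_radius <- function(colony, center = c(0, 0),
                        cell = mean(colony$rods$diameter) / 2) {
  sqrt(hole_area(colony, center, cell) / pi)
}
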