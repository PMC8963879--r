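# Protocols and metrics for mixed- and segregated-strain inward-growth
# races between strains that differ only in division length. The working
# hypothesis being tested: torque response scales with rod length, so
# longer rods align radially faster and ride the inward flow to the defect
# core (and the leading outer edge) more effectively.

#' Competition configuration
#'
#' Two strains share growth rate, diameter and mechanics; only the division
#' length differs by the ratio `rho_L >= 1` (this isolates the length
#' effect). Seeding is either a mixed random disk or a sector-segregated
#' annulus.
#'
#' @param rho_L Division-length ratio of strain 2 to strain 1.
#' @param L_div Division length of the (shorter) strain 1 (um).
#' @param geometry `"sector_annulus"` or `"mixed_disk"`.
#' @param R_in,R_out Annulus radii (um; `R_out` is the disk radius for
#'   mixed seeding, with `R_in` the initial hole radius left unseeded).
#' @param n Initial rod count (split equally between strains).
#' @param n_sectors Number of azimuthal sectors (segregated seeding).
#' @param core_radius Radius of the defect-core disc for occupancy (um).
#' @param closure_area Hole-area threshold for closure (um^2; default four
#'   rod footprints of strain 1).
#' @param t_max Bailout time (division times).
#' @param growth_rate Shared exponential growth rate.
#' @param params A [sim_params()] object (its seed is overridden per run).
#' @return A list of class `competition_config`.
#' @export
competition_config <- function(rho_L = 2, L_div = 5,
                               geometry = c("sector_annulus", "mixed_disk"),
                               R_in = 15, R_out = 30, n = 150L,
                               n_sectors = 8L, core_radius = L_div,
                               closure_area = NULL, t_max = 6,
                               growth_rate = log(2),
                               params = sim_params()) {
  geometry <- match.arg(geometry)
  stopifnot(rho_L >= 1, n >= 2, core_radius > 0)
  strains <- rbind(strain_spec(1L, growth_rate, L_div),
                   strain_spec(2L, growth_rate, rho_L * L_div))
  if (is.null(closure_area)) {
    closure_area <- 4 * (L_div * strains$diameter[1] +
                           pi * strains$diameter[1]^2 / 4)
  }
  structure(list(rho_L = rho_L, strains = strains, geometry = geometry,
                 R_in = R_in, R_out = R_out, n = as.integer(n),
                 n_sectors = as.integer(n_sectors),
                 core_radius = core_radius, closure_area = closure_area,
                 t_max = t_max, params = params),
            class = "competition_config")
}

seed_competition <- function(config, seed) {
  params <- config$params
  params$rng_seed <- as.integer(seed)
  geom <- if (config$geometry == "sector_annulus") {
    geom_sector_annulus(config$R_in, config$R_out, config$n,
                        config$n_sectors)
  } else {
    geom_annulus(config$R_in, config$R_out, config$n)
  }
  seed_colony(geom, config$strains, params)
}

#' Rod-area occupancy of the defect core by strain
#'
#' Fraction of total rod footprint area inside the core disc contributed by
#' each strain, computed from the exact polygon-circle intersection of each
#' capsule footprint with the disc. An empty core is flagged (all NA).
#'
#' @param colony A `colony`.
#' @param center Core center (um).
#' @param core_radius Core radius (um).
#' @return Named numeric vector of per-strain fractions (summing to 1), or
#'   NA when no rod area lies inside the core.
#' @export
core_occupancy <- function(colony, center = c(0, 0), core_radius = 5) {
  stopifnot(core_radius > 0)
  r <- colony$rods
  rad <- sqrt((r$x - center[1])^2 + (r$y - center[2])^2)
  near <- which(rad <= core_radius + (r$length + r$diameter) / 2)
  sids <- sort(unique(colony$strains$strain_id))
  areas <- setNames(numeric(length(sids)), sids)
  for (i in near) {
    poly <- capsule_polygon(r$x[i] - center[1], r$y[i] - center[2],
                            r$theta[i], r$length[i], r$diameter[i])
    a <- poly_circle_area(poly[, 1], poly[, 2], core_radius)
    if (a > 0) {
      key <- as.character(r$strain_id[i])
      areas[key] <- areas[key] + a
    }
  }
  tot <- sum(areas)
  if (tot <= 0) return(setNames(rep(NA_real_, length(sids)), sids))
  areas / tot
}

#' Outer-edge perimeter occupancy by strain
#'
#' Divides the plane around `center` into azimuthal sectors, finds the
#' outermost rod (largest center radius) in each non-empty sector, and
#' reports the fraction of sectors owned by each strain.
#'
#' @param colony A `colony`.
#' @param center Length-2 center (um).
#' @param n_sectors Number of azimuthal sectors.
#' @return Named numeric vector of per-strain perimeter fractions (over
#'   non-empty sectors).
#' @export
edge_occupancy <- function(colony, center = c(0, 0), n_sectors = 36L) {
  stopifnot(n_sectors >= 1)
  r <- colony$rods
  dx <- r$x - center[1]; dy <- r$y - center[2]
  rad <- sqrt(dx^2 + dy^2)
  phi <- atan2(dy, dx)
  sec <- pmin(n_sectors, 1L + floor((phi + pi) / (2 * pi) * n_sectors))
  owner <- tapply(seq_len(nrow(r)), sec, function(ix) {
    r$strain_id[ix[which.max(rad[ix])]]
  })
  sids <- sort(unique(colony$strains$strain_id))
  frac <- setNames(numeric(length(sids)), sids)
  tab <- table(factor(unlist(owner), levels = sids))
  frac[] <- as.numeric(tab) / sum(tab)
  frac
}

per_strain_metrics <- function(colony, center) {
  r <- colony$rods
  dx <- r$x - center[1]; dy <- r$y - center[2]
  rad <- sqrt(dx^2 + dy^2)
  phi <- atan2(dy, dx)
  sr <- cos(2 * (r$theta - phi))
  sids <- sort(unique(colony$strains$strain_id))
  do.call(rbind, lapply(sids, function(s) {
    sel <- r$strain_id == s & rad > 1e-12
    data.frame(time = colony$time, strain_id = s,
               n = sum(r$strain_id == s),
               mean_SR = if (any(sel)) mean(sr[sel]) else NA_real_,
               mean_dist = if (any(sel)) mean(rad[sel]) else NA_real_)
  }))
}

#' Run an inward-growth competition
#'
#' Seeds the configured geometry, advances the rod simulator, tracks
#' per-strain radial order, distance-to-center and counts on the snapshot
#' cadence, and detects hole closure (flood-filled interior void area below
#' the configured threshold). At closure (or bailout) the core and
#' outer-edge occupancies are measured.
#'
#' @param config A [competition_config()].
#' @param seed Root RNG seed for this replicate.
#' @param snapshot_every Metric cadence (division times).
#' @return A list of class `competition_result`: `closed`, `closure_time`,
#'   `core` (per-strain core fractions), `edge` (perimeter fractions),
#'   `series` (per-strain time series), and the final `colony`.
#' @export
run_competition <- function(config, seed = 1L, snapshot_every = 0.25) {
  colony <- seed_competition(config, seed)
  set.seed(child_seed(seed, 2L))
  center <- c(0, 0)
  series <- per_strain_metrics(colony, center)
  closed <- FALSE
  closure_time <- NA_real_
  steps_per <- max(1L, round(snapshot_every / colony$params$dt))
  n_chunks <- ceiling(config$t_max / snapshot_every)
  for (ch in seq_len(n_chunks)) {
    colony <- step_colony(colony, n_steps = steps_per)
    series <- rbind(series, per_strain_metrics(colony, center))
    if (isTRUE(attr(colony, "stopped"))) break
    ha <- hole_area(colony, center)
    if (ha < config$closure_area) {
      closed <- TRUE
      closure_time <- colony$time
      break
    }
  }
  core <- core_occupancy(colony, center, config$core_radius)
  edge <- edge_occupancy(colony, center)
  structure(list(closed = closed, closure_time = closure_time, core = core,
                 edge = edge, series = series, seed = seed,
                 colony = colony),
            class = "competition_result")
}

#' Replicated competition with summary statistics
#'
#' Runs [run_competition()] over a vector of seeds and summarises wins:
#' a seed is a core win for the longer strain when its core occupancy
#' exceeds 0.5 at closure.
#'
#' @param config A [competition_config()].
#' @param seeds Integer vector of replicate seeds.
#' @param snapshot_every Metric cadence.
#' @return A list with `results` (per-seed `competition_result`s) and
#'   `summary` data frame (seed, closed, core fraction of strain 2, edge
#'   fraction, late-time mean radial order per strain).
#' @export
run_competition_set <- function(config, seeds = 1:10,
                                snapshot_every = 0.25) {
  results <- lapply(seeds, function(s) run_competition(config, s,
                                                       snapshot_every))
  summ <- do.call(rbind, lapply(results, function(res) {
    late <- res$series[res$series$time == max(res$series$time), ]
    data.frame(seed = res$seed, closed = res$closed,
               closure_time = res$closure_time,
               core_long = unname(res$core["2"]),
               edge_long = unname(res$edge["2"]),
               SR_short = late$mean_SR[late$strain_id == 1],
               SR_long = late$mean_SR[late$strain_id == 2])
  }))
  list(results = results, summary = summ)
}

#' Mean tortuosity of single-strain radial lanes
#'
#' Diagnostic for post-closure buckling: rods are grouped into azimuthal
#' sectors, and each sector's tortuosity is the ratio of the summed
#' nematic misalignment of rods with the local radial direction (1 -
#' mean cos(2 (theta - phi)) mapped to [0, 1]). Increasing values mean the
#' radial lanes are losing straightness.
#'
#' @param colony A `colony`.
#' @param center Length-2 center (um).
#' @return Scalar in [0, 1]; 0 for perfectly radial lanes.
#' @export
lane_tortuosity <- function(colony, center = c(0, 0)) {
  r <- colony$rods
  dx <- r$x - center[1]; dy <- r$y - center[2]
  rad <- sqrt(dx^2 + dy^2)
  phi <- atan2(dy, dx)
  keep <- rad > 1e-12
  (1 - mean(cos(2 * (r$theta[keep] - phi[keep])))) / 2
}
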