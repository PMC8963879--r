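# File formats and configuration: rod snapshots as fixed-dialect CSV,
# run manifests as JSON, model configuration as schema-validated YAML, and
# continuum field snapshots as plain-text CSV containers. All floats are
# written with 17 significant digits so write -> read round trips are
# lossless.

snapshot_header <- c("id", "strain_id", "x_um", "y_um", "theta_rad",
                     "length_um", "diameter_um", "parent_id")

#' Write a colony snapshot to CSV
#'
#' Fixed dialect: header exactly
#' `id,strain_id,x_um,y_um,theta_rad,length_um,diameter_um,parent_id`,
#' UTF-8, '.' decimal, no thousands separators, floats at 17 significant
#' digits (lossless round trip).
#'
#' @param colony A `colony`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(colony, path) {
  r <- colony$rods
  num <- function(v) sprintf("%.17g", v)
  lines <- c(paste(snapshot_header, collapse = ","),
             if (nrow(r) > 0) {
               paste(r$id, r$strain_id, num(r$x), num(r$y), num(r$theta),
                     num(r$length), num(r$diameter),
                     ifelse(is.na(r$parent_id), "", r$parent_id), sep = ",")
             })
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a colony snapshot from CSV
#'
#' Validates the header and id uniqueness; missing columns or duplicate ids
#' are named errors.
#'
#' @param path Snapshot CSV path.
#' @param strains,params Strain table and simulation parameters to attach
#'   (snapshots store only the rod state).
#' @param time Time to stamp on the snapshot.
#' @return A `colony`.
#' @export
read_snapshot <- function(path, strains = strain_spec(),
                          params = sim_params(), time = 0) {
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  missing <- setdiff(snapshot_header, header)
  if (length(missing) > 0) {
    stop("snapshot is missing required columns: ",
         paste(missing, collapse = ", "))
  }
  df <- read.csv(path, colClasses = c(id = "integer", strain_id = "integer",
                                      x_um = "numeric", y_um = "numeric",
                                      theta_rad = "numeric",
                                      length_um = "numeric",
                                      diameter_um = "numeric",
                                      parent_id = "integer"))
  if (anyDuplicated(df$id)) {
    stop("snapshot contains duplicate rod ids: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  rods <- data.frame(id = df$id, strain_id = df$strain_id, x = df$x_um,
                     y = df$y_um, theta = df$theta_rad,
                     length = df$length_um, diameter = df$diameter_um,
                     parent_id = df$parent_id)
  new_colony(rods, strains, params, time = time)
}

#' Write a trajectory as snapshot CSVs plus a JSON manifest
#'
#' One CSV per snapshot (`snapshot_0000.csv`, zero-padded time index) and a
#' `manifest.json` echoing params, strains, seed, snapshot times, the file
#' inventory with MD5 checksums, and the package version. The manifest is
#' sufficient to re-run the deterministic simulation bit-identically.
#'
#' @param traj A `colony_trajectory`.
#' @param out_dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_trajectory <- function(traj, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(traj))
  for (i in seq_along(traj)) {
    files[i] <- sprintf("snapshot_%04d.csv", i - 1)
    write_snapshot(traj[[i]], file.path(out_dir, files[i]))
  }
  first <- traj[[1]]
  manifest <- list(
    tool = "colonyorder",
    version = as.character(utils::packageVersion("colonyorder")),
    command = "run_colony",
    params = first$params[setdiff(names(first$params), "wall")],
    wall = first$params$wall,
    strains = first$strains,
    seed = first$params$rng_seed,
    snapshot_times = vapply(traj, function(s) s$time, numeric(1)),
    files = files,
    checksums = unname(tools::md5sum(file.path(out_dir, files))),
    written_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Write / read a radial profile as CSV
#'
#' Dialect `r_um,value,count,sd` with 17-significant-digit floats.
#'
#' @param profile A `radial_profile`.
#' @param path File path.
#' @return `path` (write) or a `radial_profile` (read).
#' @export
write_profile <- function(profile, path) {
  num <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  lines <- c("r_um,value,count,sd",
             paste(num(profile$r), num(profile$value), profile$count,
                   num(profile$sd), sep = ","))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  df <- read.csv(path)
  new_radial_profile(df$r_um, df$value, df$count, df$sd)
}

# ---- configuration ---------------------------------------------------------

config_schema <- list(
  geometry = c("type", "R", "R_in", "R_out", "n_rods", "n_sites",
               "n_per_site", "site_radius", "n_sectors",
               "strain_assignment"),
  strains = c("strain_id", "growth_rate", "division_length",
              "division_noise_sd_frac", "division_noise_cap_frac",
              "diameter"),
  params = c("dt", "repulsion_stiffness", "contact_exponent", "zeta_t",
             "zeta_r", "drag_ratio", "friction_gamma", "friction_mu",
             "wall", "max_rod_count", "rng_seed", "stability_threshold"),
  run = c("t_end", "snapshot_every")
)

#' Read and validate a simulation configuration (YAML)
#'
#' The file mirrors the [sim_params()] / [strain_spec()] / geometry fields
#' under top-level keys `geometry`, `strains`, `params`, `run`. Unknown
#' keys are rejected with field-level messages; missing fields take the
#' package defaults, which are materialised into the returned object (and
#' thus into any manifest echo).
#'
#' @param path YAML file path.
#' @return A list with `geometry`, `strains` (data frame), `params`
#'   (`sim_params`) and `run`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # YAML 1.1 parses a bare `n` key as a boolean; accept it as n_rods
  if (!is.null(raw$geometry)) {
    nm <- names(raw$geometry)
    nm[nm %in% c("n", "FALSE")] <- "n_rods"
    names(raw$geometry) <- nm
  }
  unknown_top <- setdiff(names(raw), names(config_schema))
  if (length(unknown_top) > 0) {
    stop("unknown configuration section(s): ",
         paste(unknown_top, collapse = ", "))
  }
  for (sec in intersect(names(raw), names(config_schema))) {
    entries <- raw[[sec]]
    if (sec == "strains" && !is.null(entries) && is.null(names(entries))) {
      for (e in entries) check_keys(sec, e)
    } else if (!is.null(entries)) {
      check_keys(sec, entries)
    }
  }
  geometry <- build_geometry(raw$geometry)
  strains <- build_strains(raw$strains)
  params <- do.call(sim_params, validate_params_types(raw$params))
  run <- raw$run
  if (is.null(run$t_end)) run$t_end <- 1
  if (is.null(run$snapshot_every)) run$snapshot_every <- run$t_end / 10
  list(geometry = geometry, strains = strains, params = params, run = run)
}

check_keys <- function(section, entries) {
  unknown <- setdiff(names(entries), config_schema[[section]])
  if (length(unknown) > 0) {
    stop(sprintf("unknown key(s) in '%s': %s", section,
                 paste(unknown, collapse = ", ")))
  }
}

validate_params_types <- function(p) {
  if (is.null(p)) return(list())
  for (f in setdiff(names(p), "wall")) {
    if (!is.numeric(p[[f]])) {
      stop(sprintf("configuration field 'params.%s' must be numeric, got %s",
                   f, class(p[[f]])[1]))
    }
  }
  p
}

build_geometry <- function(g) {
  if (is.null(g)) return(geom_single_cell())
  type <- g$type
  if (is.null(type)) stop("configuration field 'geometry.type' is required")
  switch(type,
         single_cell = geom_single_cell(),
         random_disk = geom_random_disk(g$R, g$n_rods),
         annulus = geom_annulus(g$R_in, g$R_out, g$n_rods),
         ring_of_colonies = if (is.null(g$site_radius)) {
           geom_ring_of_colonies(g$R, g$n_sites, g$n_per_site)
         } else {
           geom_ring_of_colonies(g$R, g$n_sites, g$n_per_site, g$site_radius)
         },
         sector_annulus = geom_sector_annulus(g$R_in, g$R_out, g$n_rods,
                                              g$n_sectors,
                                              g$strain_assignment),
         stop("unknown geometry.type: ", type))
}

build_strains <- function(s) {
  if (is.null(s)) return(strain_spec())
  if (!is.null(names(s))) s <- list(s)
  do.call(rbind, lapply(s, function(e) do.call(strain_spec, e)))
}

#' Write a configuration back to YAML
#'
#' Inverse of [read_config()]: the write -> read round trip is the
#' identity on materialised configurations.
#'
#' @param config A configuration list as returned by [read_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  params <- config$params[setdiff(names(config$params),
                                  c("wall"))]
  if (!is.null(config$params$wall)) params$wall <- config$params$wall
  geom <- config$geometry[!vapply(config$geometry, is.null, logical(1))]
  names(geom)[names(geom) == "n"] <- "n_rods"
  out <- list(
    geometry = geom,
    strains = lapply(seq_len(nrow(config$strains)), function(i) {
      as.list(config$strains[i, ])
    }),
    params = params,
    run = config$run
  )
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Write continuum field snapshots as a plain-text container
#'
#' One CSV per field (`rho.csv`, `Qxx.csv`, `Qxy.csv`, `vx.csv`, `vy.csv`,
#' matrices written row-per-x-index) plus a JSON manifest with time, grid
#' spacing and the parameter echo.
#'
#' @param state A `field_state`.
#' @param params A [continuum_params()] object.
#' @param out_dir Output directory.
#' @return The manifest path, invisibly.
#' @export
write_field_snapshot <- function(state, params, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fields <- c("rho", "Qxx", "Qxy", "vx", "vy")
  for (f in fields) {
    write.table(format(state[[f]], digits = 17, scientific = TRUE,
                       trim = TRUE),
                file.path(out_dir, paste0(f, ".csv")), sep = ",",
                row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  manifest <- list(tool = "colonyorder",
                   version = as.character(utils::packageVersion("colonyorder")),
                   t = state$t, h = params$h,
                   nx = nrow(state$rho), ny = ncol(state$rho),
                   params = unclass(params),
                   clipped_mass = state$clipped_mass,
                   files = paste0(fields, ".csv"))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a continuum field snapshot written by [write_field_snapshot()]
#'
#' @param dir Snapshot directory.
#' @return A list with the `field_state` (`state`) and `params`.
#' @export
read_field_snapshot <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  rd <- function(f) {
    as.matrix(read.csv(file.path(dir, paste0(f, ".csv")), header = FALSE))
  }
  p <- man$params
  params <- continuum_params(Lambda = p$Lambda, D_rho = p$D_rho,
                             gamma = p$gamma, xi = p$xi, Gamma = p$Gamma,
                             K = p$K, a0 = p$a0, alpha0 = p$alpha0,
                             rho_c = p$rho_c, rho0 = p$rho0, G = p$G,
                             h = p$h, dt = p$dt, beta_form = p$beta_form,
                             activity_sign = p$activity_sign)
  h <- man$h
  nx <- man$nx; ny <- man$ny
  xs <- (seq_len(nx) - (nx + 1) / 2) * h
  ys <- (seq_len(ny) - (ny + 1) / 2) * h
  state <- structure(list(rho = unname(rd("rho")), Qxx = unname(rd("Qxx")),
                          Qxy = unname(rd("Qxy")), vx = unname(rd("vx")),
                          vy = unname(rd("vy")), xs = xs, ys = ys,
                          t = man$t, clipped_mass = man$clipped_mass),
                     class = "field_state")
  list(state = state, params = params)
}
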