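# Synthetic fixtures emulating the statistical structure of the measured
# inputs: rod configurations with prescribed radial/tangential/random order,
# advected snapshot pairs following the closed-form velocity profile, and
# rendered grayscale rod images emulating fluorescence micrographs.

#' Synthetic rod configuration with prescribed order
#'
#' Places `n` rods uniformly in a disc or annulus and assigns orientations:
#' `theta_i = phi_i` (aster), `phi_i + pi/2` (tangential), a fixed
#' `stripe_angle` (stripes), or i.i.d. uniform (random); wrapped angular
#' noise with von-Mises concentration `kappa` is added on the nematic angle
#' (period pi), so the expected radial order of a noisy aster is the
#' circular moment `E[cos 2 eps] = I1(kappa) / I0(kappa)`. `kappa = Inf`
#' means no noise. Deterministic under `seed`.
#'
#' @param kind `"aster"`, `"tangential"`, `"random"` or `"stripes"`.
#' @param n Number of rods.
#' @param region `list(type = "disc", R = )` or
#'   `list(type = "annulus", R_in = , R_out = )`.
#' @param kappa Angular noise concentration (von Mises on the doubled
#'   angle); `Inf` for none.
#' @param length_range Cylinder length range (um), sampled uniformly.
#' @param diameter Rod diameter (um).
#' @param stripe_angle Orientation for `kind = "stripes"` (rad).
#' @param seed RNG seed.
#' @return A `colony` snapshot (time 0) with a ground-truth attribute
#'   `truth` recording the generating spec.
#' @export
make_rod_config <- function(kind = c("aster", "tangential", "random",
                                     "stripes"),
                            n = 500, region = list(type = "annulus",
                                                   R_in = 10, R_out = 30),
                            kappa = Inf, length_range = c(2, 4),
                            diameter = 1, stripe_angle = 0, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(n >= 1, kappa >= 0)
  set.seed(seed)
  r <- if (region$type == "disc") {
    region$R * sqrt(runif(n))
  } else {
    sqrt(runif(n, region$R_in^2, region$R_out^2))
  }
  a <- runif(n, -pi, pi)
  x <- r * cos(a); y <- r * sin(a)
  phi <- atan2(y, x)
  theta <- switch(kind,
                  aster = phi,
                  tangential = phi + pi / 2,
                  random = runif(n, -pi, pi),
                  stripes = rep(stripe_angle, n))
  if (is.finite(kappa)) theta <- theta + rvonmises_half(n, kappa)
  rods <- data.frame(id = seq_len(n), strain_id = 1L, x = x, y = y,
                     theta = wrap_angle(theta),
                     length = runif(n, length_range[1], length_range[2]),
                     diameter = diameter, parent_id = NA_integer_)
  col <- new_colony(rods, strain_spec(), sim_params())
  attr(col, "truth") <- list(kind = kind, n = n, region = region,
                             kappa = kappa, seed = seed,
                             stripe_angle = stripe_angle)
  col
}

# Nematic angular noise: half of a von Mises(0, kappa) draw, so the doubled
# angle 2*eps is von Mises distributed and E[cos 2 eps] = I1(k)/I0(k).
# Rejection sampling against a uniform proposal (adequate for moderate
# kappa; draws are vectorised in batches).
rvonmises_half <- function(n, kappa) {
  if (kappa == 0) return(runif(n, -pi / 2, pi / 2))
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(64L, 2L * (n - length(out)))
    x <- runif(m, -pi, pi)
    acc <- runif(m) < exp(kappa * (cos(x) - 1))
    out <- c(out, x[acc])
  }
  out[seq_len(n)] / 2
}

#' Advected snapshot pair under the closed-form velocity
#'
#' Returns the input snapshot together with a copy advected for `dt` by
#' `vr_closed_form` along the radial direction, plus optional isotropic
#' Gaussian displacement noise; ids are preserved, so the pair is a ground
#' truth for tracking-based velocity estimation.
#'
#' @param colony A `colony` snapshot (e.g. from [make_rod_config()]).
#' @param p A [theory_params()] object.
#' @param dt Time separation.
#' @param noise_sd Isotropic displacement noise sd (um).
#' @param seed RNG seed for the noise.
#' @return A list of two `colony` snapshots.
#' @export
make_advected_pair <- function(colony, p = theory_params(), dt = 1,
                               noise_sd = 0, seed = 1L) {
  stopifnot(dt >= 0)
  set.seed(seed)
  r <- colony$rods
  rad <- sqrt(r$x^2 + r$y^2)
  vr <- ifelse(rad > 0, vr_closed_form(pmax(rad, 1e-12), p), 0)
  n <- nrow(r)
  snap2 <- colony
  snap2$rods$x <- r$x + vr * dt * ifelse(rad > 0, r$x / rad, 0) +
    rnorm(n, 0, noise_sd)
  snap2$rods$y <- r$y + vr * dt * ifelse(rad > 0, r$y / rad, 0) +
    rnorm(n, 0, noise_sd)
  snap2$time <- colony$time + dt
  list(colony, snap2)
}

#' Render a grayscale image of a rod colony
#'
#' Rasterizes rods as capsules of uniform intensity on a pixel grid,
#' applies Gaussian blur and additive Gaussian noise, and clips to [0, 1].
#' Emulates a fluorescence micrograph of a monolayer colony; the input
#' snapshot is the ground truth for image-based orientation analysis.
#'
#' @param colony A `colony` snapshot.
#' @param px_size Pixel size (um/px).
#' @param blur_sd Gaussian blur sd (px).
#' @param noise_sd Additive noise sd (intensity units).
#' @param pad Padding around the colony bounding box (um).
#' @param seed RNG seed for the noise.
#' @return A numeric matrix in [0, 1] (rows = x, columns = y), with
#'   attributes `px_size` and `origin` (um coordinates of pixel (1, 1)
#'   center).
#' @export
render_image <- function(colony, px_size = 0.2, blur_sd = 1, noise_sd = 0.02,
                         pad = 2, seed = 1L) {
  stopifnot(px_size > 0)
  set.seed(seed)
  r <- colony$rods
  origin <- c(0, 0)
  if (nrow(r) == 0) {
    img <- matrix(0, 64, 64)
  } else {
    ext <- (r$length + r$diameter) / 2
    xmin <- min(r$x - ext) - pad; xmax <- max(r$x + ext) + pad
    ymin <- min(r$y - ext) - pad; ymax <- max(r$y + ext) + pad
    nx <- ceiling((xmax - xmin) / px_size)
    ny <- ceiling((ymax - ymin) / px_size)
    img <- cpp_rasterize(r$x, r$y, r$theta, r$length, r$diameter,
                         xmin, ymin, px_size, nx, ny) * 1.0
    origin <- c(xmin + px_size / 2, ymin + px_size / 2)
  }
  if (blur_sd > 0) img <- gaussian_smooth(img, blur_sd)
  if (noise_sd > 0) img <- img + matrix(rnorm(length(img), 0, noise_sd),
                                        nrow(img), ncol(img))
  img <- pmin(pmax(img, 0), 1)
  attr(img, "px_size") <- px_size
  attr(img, "origin") <- origin
  img
}
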