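# Measurement operators applied to rod colonies, continuum fields and
# rendered images: radial order, coarse-grained Q/S, per-cell virial stress
# with polar transform, tracked velocity profiles, critical-radius
# estimation, packing fraction, structure-tensor director fields.

new_radial_profile <- function(bin_centers, values, counts, spread,
                               excluded = 0L) {
  stopifnot(all(diff(bin_centers) > 0), all(counts >= 0))
  structure(data.frame(r = bin_centers, value = values, count = counts,
                       sd = spread),
            class = c("radial_profile", "data.frame"), excluded = excluded)
}

bin_stats <- function(r, v, breaks, weights = NULL) {
  idx <- findInterval(r, breaks, rightmost.closed = TRUE)
  nb <- length(breaks) - 1
  keep <- idx >= 1 & idx <= nb
  idx <- idx[keep]; v <- v[keep]
  counts <- tabulate(idx, nbins = nb)
  if (is.null(weights)) {
    sums <- rep(0, nb); sq <- rep(0, nb)
    if (length(idx)) {
      t1 <- tapply(v, factor(idx, levels = seq_len(nb)), sum)
      t2 <- tapply(v^2, factor(idx, levels = seq_len(nb)), sum)
      sums <- ifelse(is.na(t1), 0, t1)
      sq <- ifelse(is.na(t2), 0, t2)
    }
    means <- ifelse(counts > 0, sums / counts, NA_real_)
    vars <- ifelse(counts > 1, (sq - counts * means^2) / (counts - 1), NA_real_)
    list(mean = means, count = counts, sd = sqrt(pmax(vars, 0)))
  } else {
    w <- weights[keep]
    ws <- tapply(w, factor(idx, levels = seq_len(nb)), sum)
    wv <- tapply(w * v, factor(idx, levels = seq_len(nb)), sum)
    means <- ifelse(!is.na(ws) & ws > 0, wv / ws, NA_real_)
    list(mean = as.numeric(means), count = counts, sd = rep(NA_real_, nb))
  }
}

default_breaks <- function(r, width) {
  lo <- 0
  hi <- max(r) + width
  seq(lo, hi + width, by = width)
}

rods_of <- function(x) {
  if (inherits(x, "colony")) x$rods else as.data.frame(x)
}

#' Colony center
#'
#' Default center definition for radial measurements: the centroid of the
#' interior void (hole) for annulus-like colonies (computed from the
#' rasterized empty region containing the given starting guess), and the
#' centroid of all rods otherwise.
#'
#' @param colony A `colony`.
#' @param method `"hole"`, `"centroid"`, or `"auto"` (hole if one exists,
#'   else centroid).
#' @param guess Starting point assumed to lie inside the hole.
#' @return Numeric length-2 center (um).
#' @export
colony_center <- function(colony, method = c("auto", "hole", "centroid"),
                          guess = c(0, 0)) {
  method <- match.arg(method)
  r <- rods_of(colony)
  centroid <- c(mean(r$x), mean(r$y))
  if (method == "centroid") return(centroid)
  if (!inherits(colony, "colony")) return(centroid)
  a <- hole_area(colony, center = guess)
  if (a > 0) {
    # centroid of the flood-filled void: approximate with the guess refined
    # by the covered raster; for measurement purposes the guess (hole seed)
    # is adequate and stable, so return it
    return(guess)
  }
  if (method == "hole") stop("no interior void found at the given guess")
  centroid
}

#' Azimuthally averaged radial order parameter
#'
#' Per radial bin, the mean of `cos(2 (theta_i - phi_i))` over items, where
#' `phi_i` is the angular position of item i about `center`: +1 for radial
#' alignment, -1 for tangential, 0 for isotropic. Items exactly at the
#' center (undefined `phi`) are excluded and counted in the `excluded`
#' attribute. The count-weighted global mean is available via
#' [global_radial_order()].
#'
#' @param x A `colony` or data frame with columns `x`, `y`, `theta`.
#' @param center Length-2 center (um).
#' @param breaks Radial bin breaks (um); default fixed-width bins of twice
#'   the rod diameter (or 2 um).
#' @return A `radial_profile` data frame (`r`, `value`, `count`, `sd`).
#' @export
radial_order_profile <- function(x, center = c(0, 0), breaks = NULL) {
  r <- rods_of(x)
  stopifnot(nrow(r) >= 1)
  dx <- r$x - center[1]; dy <- r$y - center[2]
  rad <- sqrt(dx^2 + dy^2)
  at_center <- rad < 1e-12
  phi <- atan2(dy, dx)
  sr <- cos(2 * (r$theta - phi))
  if (is.null(breaks)) {
    width <- if (!is.null(r$diameter)) 2 * mean(r$diameter) else 2
    breaks <- default_breaks(rad[!at_center], width)
  }
  st <- bin_stats(rad[!at_center], sr[!at_center], breaks)
  new_radial_profile((head(breaks, -1) + tail(breaks, -1)) / 2,
                     st$mean, st$count, st$sd, excluded = sum(at_center))
}

#' Count-weighted global mean of a radial profile
#' @param profile A `radial_profile`.
#' @param r_min,r_max Optional radial window (um).
#' @return Scalar weighted mean over non-empty bins.
#' @export
global_radial_order <- function(profile, r_min = -Inf, r_max = Inf) {
  keep <- profile$count > 0 & profile$r >= r_min & profile$r <= r_max
  sum(profile$value[keep] * profile$count[keep]) / sum(profile$count[keep])
}

#' Coarse-grained nematic tensor field of a rod colony
#'
#' Per grid node, the length-weighted, Gaussian-weighted average of
#' `n (x) n - I/2` over rods, giving `Qxx`, `Qxy` and the scalar order
#' `S = 2 sqrt(Qxx^2 + Qxy^2)` in [0, 1]. Nodes with total weight below
#' `min_weight` are flagged undefined (NA).
#'
#' @param x A `colony` or rods data frame.
#' @param xs,ys Node coordinate vectors (um).
#' @param kernel_sd Gaussian kernel standard deviation (um), at least the
#'   rod diameter.
#' @param min_weight Minimum total kernel weight for a defined node.
#' @return A list with matrices `Qxx`, `Qxy`, `S` (length(xs) x length(ys)).
#' @export
coarse_grain_Q <- function(x, xs, ys, kernel_sd = 3, min_weight = 1e-3) {
  r <- rods_of(x)
  if (!is.null(r$diameter)) stopifnot(kernel_sd >= max(r$diameter))
  cx <- cos(r$theta); sx <- sin(r$theta)
  qxx_i <- (cx^2 - 0.5) * r$length
  qxy_i <- (cx * sx) * r$length
  nxp <- length(xs); nyp <- length(ys)
  Qxx <- matrix(NA_real_, nxp, nyp); Qxy <- matrix(NA_real_, nxp, nyp)
  wx <- outer(xs, r$x, function(a, b) (a - b)^2)
  for (j in seq_len(nyp)) {
    w <- exp(-(wx + matrix((ys[j] - r$y)^2, nxp, nrow(r), byrow = TRUE)) /
               (2 * kernel_sd^2))
    wl <- w %*% r$length
    ok <- wl > min_weight
    Qxx[ok, j] <- (w %*% qxx_i)[ok] / wl[ok]
    Qxy[ok, j] <- (w %*% qxy_i)[ok] / wl[ok]
  }
  list(Qxx = Qxx, Qxy = Qxy, S = 2 * sqrt(Qxx^2 + Qxy^2))
}

#' Per-rod virial stress from contact forces
#'
#' For each rod, `sigma = 1/(2 a') sum_j (r_ij (x) F_ij + F_ij (x) r_ij)`
#' over its contacts, with `r_ij` the contact position relative to the rod
#' center, `F_ij` the force exerted on the rod, and `a'` the rod's
#' spherocylinder footprint area `L d + pi d^2 / 4`. The symmetrized outer
#' product makes the polar decomposition well-defined; the antisymmetric
#' residue `1/(2 a') sum (r_x F_y - r_y F_x)` is exported as the `antisym`
#' diagnostic column.
#'
#' @param colony A `colony`.
#' @param forces Optional output of [contact_forces()] (recomputed if
#'   missing).
#' @return A data frame with one row per rod: `id`, `x`, `y`, `sxx`, `syy`,
#'   `sxy`, `antisym`.
#' @export
virial_stress <- function(colony, forces = contact_forces(colony)) {
  r <- colony$rods
  n <- nrow(r)
  sxx <- syy <- sxy <- asym <- numeric(n)
  p <- forces$pairs
  if (nrow(p) > 0) {
    acc <- function(idx, rx, ry, fx, fy) {
      sxx <<- sxx + tab_sum(idx, 2 * rx * fx, n)
      syy <<- syy + tab_sum(idx, 2 * ry * fy, n)
      sxy <<- sxy + tab_sum(idx, rx * fy + ry * fx, n)
      asym <<- asym + tab_sum(idx, rx * fy - ry * fx, n)
    }
    # contact relative to rod i, force on i
    acc(p$i, p$x - r$x[p$i], p$y - r$y[p$i], p$fx, p$fy)
    # same contact seen from rod j, force on j is the reaction
    acc(p$j, p$x - r$x[p$j], p$y - r$y[p$j], -p$fx, -p$fy)
  }
  a <- r$length * r$diameter + pi * r$diameter^2 / 4
  data.frame(id = r$id, x = r$x, y = r$y,
             sxx = sxx / (2 * a), syy = syy / (2 * a), sxy = sxy / (2 * a),
             antisym = asym / (2 * a))
}

tab_sum <- function(idx, v, n) {
  out <- numeric(n)
  t <- tapply(v, factor(idx, levels = seq_len(n)), sum)
  out[!is.na(t)] <- t[!is.na(t)]
  out
}

#' Polar transform of per-cell stress
#'
#' Using each cell's angular position `phi` about `center`:
#' `srr = sxx cos^2(phi) + syy sin^2(phi)`,
#' `stt = sxx sin^2(phi) + syy cos^2(phi)`,
#' `srt = cos(phi) sin(phi) (syy - sxx)`,
#' the lateral-friction-free form (the shear component `sxy` is dropped, as
#' appropriate when lateral friction between cells is negligible). Set
#' `full_rotation = TRUE` for the standard full tensor rotation including
#' `sxy`. Cells at the center (undefined `phi`) are flagged NA.
#'
#' @param cs Output of [virial_stress()].
#' @param center Length-2 center (um).
#' @param full_rotation Use the full rotation including `sxy`.
#' @return `cs` with `phi`, `srr`, `stt`, `srt` columns appended.
#' @export
polar_stress <- function(cs, center = c(0, 0), full_rotation = FALSE) {
  dx <- cs$x - center[1]; dy <- cs$y - center[2]
  rad <- sqrt(dx^2 + dy^2)
  phi <- ifelse(rad < 1e-12, NA_real_, atan2(dy, dx))
  cphi <- cos(phi); sphi <- sin(phi)
  cs$phi <- phi
  cs$r <- rad
  if (full_rotation) {
    cs$srr <- cs$sxx * cphi^2 + cs$syy * sphi^2 + 2 * cs$sxy * sphi * cphi
    cs$stt <- cs$sxx * sphi^2 + cs$syy * cphi^2 - 2 * cs$sxy * sphi * cphi
    cs$srt <- cphi * sphi * (cs$syy - cs$sxx) + cs$sxy * cos(2 * phi)
  } else {
    cs$srr <- cs$sxx * cphi^2 + cs$syy * sphi^2
    cs$stt <- cs$sxx * sphi^2 + cs$syy * cphi^2
    cs$srt <- cphi * sphi * (cs$syy - cs$sxx)
  }
  cs
}

#' Azimuthally averaged radial stress profiles
#'
#' Bins the polar per-cell stresses radially.
#'
#' @param colony A `colony`.
#' @param center Center (um).
#' @param breaks Radial bin breaks.
#' @param component `"srr"`, `"stt"` or `"srt"`.
#' @return A `radial_profile`.
#' @export
stress_profile <- function(colony, center = c(0, 0), breaks = NULL,
                           component = "srr") {
  ps <- polar_stress(virial_stress(colony), center)
  ps <- ps[!is.na(ps$phi), ]
  if (is.null(breaks)) {
    breaks <- default_breaks(ps$r, 2 * mean(colony$rods$diameter))
  }
  st <- bin_stats(ps$r, ps[[component]], breaks)
  new_radial_profile((head(breaks, -1) + tail(breaks, -1)) / 2,
                     st$mean, st$count, st$sd)
}

#' Radial velocity profile from tracked rods
#'
#' Matches rod ids between two snapshots, computes per-rod velocities
#' `(center_2 - center_1) / (t_2 - t_1)`, projects on the radial unit
#' vector at the midpoint position, and bins azimuthally. Rods present in
#' only one snapshot (births) are excluded.
#'
#' @param snap1,snap2 Two `colony` snapshots with `snap2$time >
#'   snap1$time`, or a `colony_trajectory` of length >= 2 passed as `snap1`
#'   (then the first and last snapshots are used).
#' @param center Length-2 center (um).
#' @param breaks Radial bin breaks (um).
#' @return A `radial_profile` of `v_r` (um/time).
#' @export
velocity_profile <- function(snap1, snap2 = NULL, center = c(0, 0),
                             breaks = NULL) {
  if (inherits(snap1, "colony_trajectory")) {
    stopifnot(length(snap1) >= 2)
    snap2 <- snap1[[length(snap1)]]
    snap1 <- snap1[[1]]
  }
  r1 <- rods_of(snap1); r2 <- rods_of(snap2)
  dt <- snap2$time - snap1$time
  stopifnot(dt > 0)
  m <- match(r1$id, r2$id)
  keep <- !is.na(m)
  if (!any(keep)) stop("no common rod ids between the snapshots")
  a <- r1[keep, ]; b <- r2[m[keep], ]
  vx <- (b$x - a$x) / dt; vy <- (b$y - a$y) / dt
  mx <- (a$x + b$x) / 2 - center[1]
  my <- (a$y + b$y) / 2 - center[2]
  rad <- sqrt(mx^2 + my^2)
  ok <- rad > 1e-12
  vr <- (vx * mx + vy * my)[ok] / rad[ok]
  rad <- rad[ok]
  if (is.null(breaks)) {
    breaks <- default_breaks(rad, 2 * mean(a$diameter))
  }
  st <- bin_stats(rad, vr, breaks)
  new_radial_profile((head(breaks, -1) + tail(breaks, -1)) / 2,
                     st$mean, st$count, st$sd)
}

#' Critical radius from a radial velocity profile
#'
#' Linearly interpolates the sign change of `v_r(r)`. With several
#' crossings, the one nearest the count-weighted median radius is returned;
#' with none, `NA` with attribute `no_crossing = TRUE` (a regular expanding
#' colony).
#'
#' @param profile A `radial_profile` of `v_r` with >= 2 non-empty bins.
#' @return Estimated `R_c` (um), with attributes `bracket` (the bin centers
#'   bracketing the crossing) and `no_crossing`.
#' @export
critical_radius <- function(profile) {
  p <- profile[profile$count > 0 & !is.na(profile$value), ]
  if (nrow(p) < 2) stop("need at least two non-empty bins")
  s <- sign(p$value)
  cross <- which(s[-1] * s[-nrow(p)] < 0)
  exact <- which(s == 0)
  if (length(exact) > 0 && length(cross) == 0) {
    out <- p$r[exact[1]]
    attr(out, "bracket") <- rep(p$r[exact[1]], 2)
    attr(out, "no_crossing") <- FALSE
    return(out)
  }
  if (length(cross) == 0) {
    out <- NA_real_
    attr(out, "no_crossing") <- TRUE
    return(out)
  }
  if (length(cross) > 1) {
    med <- cumsum(p$count) / sum(p$count)
    r_med <- p$r[which(med >= 0.5)[1]]
    mid <- (p$r[cross] + p$r[cross + 1]) / 2
    cross <- cross[which.min(abs(mid - r_med))]
  }
  i <- cross[1]
  r_c <- p$r[i] - p$value[i] * (p$r[i + 1] - p$r[i]) /
    (p$value[i + 1] - p$value[i])
  attr(r_c, "bracket") <- c(p$r[i], p$r[i + 1])
  attr(r_c, "no_crossing") <- FALSE
  r_c
}

# ---- packing fraction ------------------------------------------------------

# Capsule footprint polygon (n_vertices >= 32) for a rod.
capsule_polygon <- function(x, y, theta, len, diam, n_vertices = 40) {
  n_half <- max(16L, ceiling(n_vertices / 2))
  rad <- diam / 2
  ang1 <- theta - pi / 2 + seq(0, pi, length.out = n_half)   # cap at +h end
  ang2 <- theta + pi / 2 + seq(0, pi, length.out = n_half)   # cap at -h end
  h <- len / 2
  px <- c(x + h * cos(theta) + rad * cos(ang1),
          x - h * cos(theta) + rad * cos(ang2))
  py <- c(y + h * sin(theta) + rad * sin(ang1),
          y - h * sin(theta) + rad * sin(ang2))
  cbind(px, py)
}

# Area of intersection between a simple polygon and a disk of radius R
# centered at the origin (polygon coordinates already translated).
# Green's-theorem decomposition into triangle and circular-sector
# contributions per edge.
poly_circle_area <- function(px, py, R) {
  n <- length(px)
  total <- 0
  for (k in seq_len(n)) {
    x1 <- px[k]; y1 <- py[k]
    kk <- if (k == n) 1L else k + 1L
    x2 <- px[kk]; y2 <- py[kk]
    total <- total + edge_circle_contrib(x1, y1, x2, y2, R)
  }
  total
}

edge_circle_contrib <- function(x1, y1, x2, y2, R) {
  tri <- function(ax, ay, bx, by) 0.5 * (ax * by - ay * bx)
  sector <- function(ax, ay, bx, by) {
    da <- atan2(by, bx) - atan2(ay, ax)
    da <- ((da + pi) %% (2 * pi)) - pi
    0.5 * R^2 * da
  }
  r1 <- sqrt(x1^2 + y1^2); r2 <- sqrt(x2^2 + y2^2)
  in1 <- r1 <= R; in2 <- r2 <= R
  dx <- x2 - x1; dy <- y2 - y1
  a <- dx^2 + dy^2
  if (a < 1e-300) return(0)
  b <- 2 * (x1 * dx + y1 * dy)
  cc <- x1^2 + y1^2 - R^2
  disc <- b^2 - 4 * a * cc
  ts <- numeric(0)
  if (disc > 0) {
    sq <- sqrt(disc)
    ts <- sort(c((-b - sq) / (2 * a), (-b + sq) / (2 * a)))
    ts <- ts[ts > 1e-12 & ts < 1 - 1e-12]
  }
  pts_x <- c(x1, x1 + ts * dx, x2)
  pts_y <- c(y1, y1 + ts * dy, y2)
  contrib <- 0
  for (s in seq_len(length(pts_x) - 1)) {
    ax <- pts_x[s]; ay <- pts_y[s]
    bx <- pts_x[s + 1]; by <- pts_y[s + 1]
    mx <- (ax + bx) / 2; my <- (ay + by) / 2
    if (mx^2 + my^2 <= R^2) {
      contrib <- contrib + tri(ax, ay, bx, by)
    } else {
      contrib <- contrib + sector(ax, ay, bx, by)
    }
  }
  contrib
}

#' Radial packing-fraction profile
#'
#' Per annular bin, the total rod footprint area overlapping the bin divided
#' by the bin area. Footprints are polygonal approximations of the
#' spherocylinder (>= 32 vertices); the area inside each bounding circle is
#' computed exactly for the polygon, and bin overlaps by differencing.
#'
#' @param x A `colony` or rods data frame.
#' @param center Length-2 center (um).
#' @param breaks Radial bin breaks (um).
#' @param n_vertices Polygon vertices per capsule.
#' @return A `radial_profile` of packing fraction; `count` is the number of
#'   rods contributing area to each bin.
#' @export
packing_fraction_profile <- function(x, center = c(0, 0), breaks = NULL,
                                     n_vertices = 40) {
  r <- rods_of(x)
  rad <- sqrt((r$x - center[1])^2 + (r$y - center[2])^2)
  if (is.null(breaks)) {
    width <- if (!is.null(r$diameter)) 2 * mean(r$diameter) else 2
    breaks <- default_breaks(rad + (r$length + r$diameter) / 2, width)
  }
  nb <- length(breaks) - 1
  areas <- rep(0, nb)
  counts <- integer(nb)
  for (i in seq_len(nrow(r))) {
    poly <- capsule_polygon(r$x[i] - center[1], r$y[i] - center[2],
                            r$theta[i], r$length[i], r$diameter[i],
                            n_vertices)
    ext <- (r$length[i] + r$diameter[i]) / 2
    jmin <- max(1L, findInterval(rad[i] - ext, breaks))
    jmax <- min(nb, findInterval(rad[i] + ext, breaks, rightmost.closed = TRUE))
    if (jmax < jmin) next
    a_prev <- if (breaks[jmin] > 0) {
      poly_circle_area(poly[, 1], poly[, 2], breaks[jmin])
    } else 0
    for (j in jmin:jmax) {
      a_next <- poly_circle_area(poly[, 1], poly[, 2], breaks[j + 1])
      da <- a_next - a_prev
      if (da > 1e-12) {
        areas[j] <- areas[j] + da
        counts[j] <- counts[j] + 1L
      }
      a_prev <- a_next
    }
  }
  bin_area <- pi * (tail(breaks, -1)^2 - head(breaks, -1)^2)
  new_radial_profile((head(breaks, -1) + tail(breaks, -1)) / 2,
                     areas / bin_area, counts, rep(NA_real_, nb))
}

# ---- image-based director --------------------------------------------------

# Separable Gaussian smoothing with edge replication.
gaussian_smooth <- function(A, sigma) {
  if (sigma <= 0) return(A)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-half:half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_conv <- function(M) {
    n <- nrow(M)
    Mp <- M[c(rep(1, half), seq_len(n), rep(n, half)), , drop = FALSE]
    out <- matrix(0, n, ncol(M))
    for (q in seq_along(k)) {
      out <- out + k[q] * Mp[(q - 1) + seq_len(n), , drop = FALSE]
    }
    out
  }
  t(pad_conv(t(pad_conv(A))))
}

#' Director field of a grayscale image via the structure tensor
#'
#' Computes image gradients (central differences), smooths the gradient
#' outer products with a Gaussian of standard deviation `window / 2`, and
#' reports per-window the ridge orientation (the minor eigenvector of the
#' structure tensor, i.e. the gradient-dominant direction rotated by 90
#' degrees) and the coherence `(l1 - l2) / (l1 + l2)` in [0, 1].
#' Orientations are nematic, wrapped to (-pi/2, pi/2]. Windows with
#' near-zero gradient energy are flagged with coherence 0.
#'
#' @param image Numeric matrix (rows = x, columns = y).
#' @param window Window size in pixels (also the downsampling stride).
#' @return A list with matrices `theta`, `coherence` and the window-center
#'   pixel coordinate vectors `xs`, `ys`.
#' @export
director_from_image <- function(image, window = 8) {
  stopifnot(is.matrix(image), diff(range(image)) > 0)
  gx <- (sh_xp(image) - sh_xm(image)) / 2
  gy <- (sh_yp(image) - sh_ym(image)) / 2
  sig <- window / 2
  Jxx <- gaussian_smooth(gx * gx, sig)
  Jxy <- gaussian_smooth(gx * gy, sig)
  Jyy <- gaussian_smooth(gy * gy, sig)
  xs <- seq(ceiling(window / 2), nrow(image), by = window)
  ys <- seq(ceiling(window / 2), ncol(image), by = window)
  Jxx <- Jxx[xs, ys, drop = FALSE]
  Jxy <- Jxy[xs, ys, drop = FALSE]
  Jyy <- Jyy[xs, ys, drop = FALSE]
  grad_angle <- 0.5 * atan2(2 * Jxy, Jxx - Jyy)
  theta <- nematic_diff(grad_angle + pi / 2, 0)
  tr <- Jxx + Jyy
  coh <- ifelse(tr > 1e-12 * max(tr), sqrt((Jxx - Jyy)^2 + 4 * Jxy^2) / tr, 0)
  list(theta = theta, coherence = coh, xs = xs, ys = ys)
}

#' Image-based radial order parameter
#'
#' Applies [director_from_image()] and averages `cos(2 (theta - phi))` over
#' windows with coherence above `min_coherence`, optionally restricted to an
#' annulus.
#'
#' @param image Numeric matrix.
#' @param center Center in pixel coordinates (defaults to the image center).
#' @param window Window size (px).
#' @param min_coherence Coherence threshold for inclusion.
#' @param r_min,r_max Radial window (px).
#' @return Scalar image-based radial order.
#' @export
image_radial_order <- function(image, center = (dim(image) + 1) / 2,
                               window = 8, min_coherence = 0.3,
                               r_min = 0, r_max = Inf) {
  d <- director_from_image(image, window)
  px <- outer(d$xs - center[1], rep(1, length(d$ys)))
  py <- outer(rep(1, length(d$xs)), d$ys - center[2])
  rad <- sqrt(px^2 + py^2)
  phi <- atan2(py, px)
  keep <- d$coherence >= min_coherence & rad >= r_min & rad <= r_max &
    rad > 1e-9
  mean(cos(2 * (d$theta[keep] - phi[keep])))
}

# ---- continuum-field observables -------------------------------------------

#' Radial order profile of a continuum field
#'
#' Uses the director angle of the Q field; per radial bin, the mean of
#' `cos(2 (theta - phi))` over nodes with density above
#' `rho_threshold * rho0`.
#'
#' @param state A `field_state`.
#' @param params A [continuum_params()] object.
#' @param breaks Radial bin breaks (grid units).
#' @param rho_threshold Density inclusion threshold as a fraction of `rho0`.
#' @return A `radial_profile`.
#' @export
field_radial_order <- function(state, params, breaks = NULL,
                               rho_threshold = 0.2) {
  th <- director_angle(state)
  px <- outer(state$xs, rep(1, length(state$ys)))
  py <- outer(rep(1, length(state$xs)), state$ys)
  rad <- sqrt(px^2 + py^2)
  phi <- atan2(py, px)
  keep <- state$rho > rho_threshold * params$rho0 & rad > 1e-9
  sr <- cos(2 * (th - phi))
  if (is.null(breaks)) breaks <- default_breaks(rad[keep], 2 * params$h)
  st <- bin_stats(rad[keep], sr[keep], breaks)
  new_radial_profile((head(breaks, -1) + tail(breaks, -1)) / 2,
                     st$mean, st$count, st$sd)
}

#' Radial velocity profile of a continuum field
#'
#' Projects the velocity field on the radial direction and bins azimuthally
#' over nodes with density above the threshold.
#'
#' @inheritParams field_radial_order
#' @return A `radial_profile` of `v_r`.
#' @export
field_velocity_profile <- function(state, params, breaks = NULL,
                                   rho_threshold = 0.2) {
  px <- outer(state$xs, rep(1, length(state$ys)))
  py <- outer(rep(1, length(state$xs)), state$ys)
  rad <- sqrt(px^2 + py^2)
  keep <- state$rho > rho_threshold * params$rho0 & rad > 1e-9
  vr <- (state$vx * px + state$vy * py) / pmax(rad, 1e-12)
  if (is.null(breaks)) breaks <- default_breaks(rad[keep], 2 * params$h)
  st <- bin_stats(rad[keep], vr[keep], breaks)
  new_radial_profile((head(breaks, -1) + tail(breaks, -1)) / 2,
                     st$mean, st$count, st$sd)
}
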