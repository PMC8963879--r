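test_that("radial order parameter hits its defining values", {
  aster <- make_rod_config("aster", n = 400, seed = 1)
  pr <- radial_order_profile(aster)
  expect_true(all(abs(pr$value[pr$count > 0] - 1) < 1e-12))
  expect_equal(global_radial_order(pr), 1, tolerance = 1e-12)

  tang <- make_rod_config("tangential", n = 400, seed = 1)
  prt <- radial_order_profile(tang)
  expect_true(all(abs(prt$value[prt$count > 0] + 1) < 1e-12))

  # four rods at phi = 0, 90, 180, 270 degrees, all horizontal:
  # cos terms 1, -1, 1, -1 -> mean 0
  rods <- data.frame(id = 1:4, strain_id = 1L,
                     x = c(5, 0, -5, 0), y = c(0, 5, 0, -5),
                     theta = 0, length = 3, diameter = 1,
                     parent_id = NA_integer_)
  pr4 <- radial_order_profile(rods, breaks = c(0, 10))
  expect_equal(pr4$value, 0, tolerance = 1e-15)
  expect_equal(pr4$count, 4L)
})

test_that("radial order is nematic and frame-rotation invariant", {
  col <- make_rod_config("random", n = 300, kappa = 2, seed = 7)
  base <- radial_order_profile(col)

  flip <- col
  flip$rods$theta <- colonyorder:::wrap_angle(flip$rods$theta + pi)
  expect_equal(radial_order_profile(flip)$value, base$value,
               tolerance = 1e-12)

  a <- 0.73
  rot <- col
  rot$rods$x <- cos(a) * col$rods$x - sin(a) * col$rods$y
  rot$rods$y <- sin(a) * col$rods$x + cos(a) * col$rods$y
  rot$rods$theta <- colonyorder:::wrap_angle(col$rods$theta + a)
  expect_equal(radial_order_profile(rot)$value, base$value,
               tolerance = 1e-10)

  # an item exactly at the center is excluded and counted
  rods <- rbind(col$rods, data.frame(id = 9999L, strain_id = 1L, x = 0,
                                     y = 0, theta = 0, length = 3,
                                     diameter = 1, parent_id = NA_integer_))
  pr <- radial_order_profile(rods)
  expect_equal(attr(pr, "excluded"), 1L)
})

test_that("coarse-grained Q recovers order and the S round trip", {
  # round-trip identity of the (S0, theta0) parameterization
  S0 <- 0.62; th0 <- 0.9
  st <- list(Qxx = matrix(S0 * (cos(th0)^2 - 0.5)),
             Qxy = matrix(S0 * cos(th0) * sin(th0)))
  expect_equal(scalar_order(st)[1, 1], S0, tolerance = 1e-12)
  expect_equal(colonyorder:::nematic_diff(director_angle(st)[1, 1], th0), 0,
               tolerance = 1e-12)

  # all rods parallel -> S = 1 at interior nodes
  rods <- expand.grid(x = seq(-10, 10, 2), y = seq(-10, 10, 2))
  rods$id <- seq_len(nrow(rods)); rods$strain_id <- 1L
  rods$theta <- 0.4; rods$length <- 3; rods$diameter <- 1
  rods$parent_id <- NA_integer_
  cg <- coarse_grain_Q(rods, xs = c(-2, 0, 2), ys = c(-2, 0, 2),
                       kernel_sd = 3)
  expect_true(all(abs(cg$S - 1) < 1e-12))

  # isotropic null: uniform angles, large N per kernel -> S < 0.1
  set.seed(12)
  n <- 10000
  rr <- data.frame(id = seq_len(n), strain_id = 1L,
                   x = runif(n, -10, 10), y = runif(n, -10, 10),
                   theta = runif(n, -pi, pi), length = 3, diameter = 1,
                   parent_id = NA_integer_)
  cg0 <- coarse_grain_Q(rr, xs = 0, ys = 0, kernel_sd = 8)
  expect_lt(cg0$S[1, 1], 0.1)

  # empty neighbourhood flagged
  cg_na <- coarse_grain_Q(rods, xs = 500, ys = 500, kernel_sd = 3)
  expect_true(is.na(cg_na$S[1, 1]))

  # perfect aster: director field of the coarse-grained Q is radial
  aster <- make_rod_config("aster", n = 4000,
                           region = list(type = "annulus", R_in = 5,
                                         R_out = 25), seed = 3)
  xs <- seq(-18, 18, 4)
  cga <- coarse_grain_Q(aster, xs = xs, ys = xs, kernel_sd = 2)
  ang <- director_angle(list(Qxx = cga$Qxx, Qxy = cga$Qxy))
  px <- outer(xs, rep(1, length(xs)))
  py <- t(px)
  phi <- atan2(py, px)
  rad <- sqrt(px^2 + py^2)
  sel <- rad > 7 & rad < 22 & !is.na(ang)
  sr <- cos(2 * (ang[sel] - phi[sel]))
  expect_gt(min(sr), 0.97)
})

test_that("virial stress matches hand-computed outer products", {
  p <- sim_params(repulsion_stiffness = 1, contact_exponent = 1, dt = 1e-4)

  one <- one_rod_colony(params = p)
  vs1 <- virial_stress(one)
  expect_equal(unlist(vs1[c("sxx", "syy", "sxy")]), c(sxx = 0, syy = 0,
                                                      sxy = 0))

  # head-on rods along x, overlapping caps: compressive sxx on both
  col <- two_rod_colony(x = c(-1.9, 1.9), y = c(0, 0), theta = c(0, 0),
                        len = c(3, 3), params = p)
  cf <- contact_forces(col)
  expect_equal(nrow(cf$pairs), 1)
  vs <- virial_stress(col, cf)
  # independent arithmetic: segment gap 0.8 -> overlap 0.2; contact at the
  # origin, r_1 = (1.9, 0), F on rod 1 = (-k*overlap, 0) = (-0.2, 0);
  # a' = L d + pi d^2/4
  aprime <- 3 * 1 + pi / 4
  expected_sxx <- 2 * 1.9 * (-0.2) / (2 * aprime)
  expect_equal(vs$sxx, rep(expected_sxx, 2), tolerance = 1e-12)
  expect_equal(vs$syy, c(0, 0))
  expect_equal(vs$sxy, c(0, 0))
  expect_lt(vs$sxx[1], 0)
  expect_equal(vs$antisym, c(0, 0), tolerance = 1e-12)
})

test_that("colony-summed virial pressure rises during confined growth", {
  p <- sim_params(rng_seed = 51L,
                  wall = list(center = c(0, 0), radius = 14,
                              stiffness = 30000))
  col <- seed_colony(geom_random_disk(12, 40), strain_spec(), p)
  set.seed(1)
  pressures <- numeric(3)
  for (i in 1:3) {
    col <- step_colony(col, n_steps = round(0.6 / p$dt))
    vs <- virial_stress(col)
    pressures[i] <- mean(-(vs$sxx + vs$syy) / 2)
  }
  expect_true(all(diff(pressures) > 0))
})

test_that("polar stress transform preserves the trace and known cases", {
  cs <- data.frame(id = 1L, x = 3, y = 0, sxx = -2, syy = 0.5, sxy = 0.3,
                   antisym = 0)
  ps <- polar_stress(cs)
  expect_equal(ps$srr, -2)
  expect_equal(ps$stt, 0.5)
  expect_equal(ps$srt, 0)

  # phi = pi/4, sxx = -1, syy = 0
  cs2 <- data.frame(id = 1L, x = 1, y = 1, sxx = -1, syy = 0, sxy = 0,
                    antisym = 0)
  ps2 <- polar_stress(cs2)
  expect_equal(ps2$srr, -0.5)
  expect_equal(ps2$stt, -0.5)
  expect_equal(ps2$srt, 0.5)
  # cross-check against the full rotation when sxy = 0
  ps2f <- polar_stress(cs2, full_rotation = TRUE)
  expect_equal(ps2[c("srr", "stt", "srt")], ps2f[c("srr", "stt", "srt")])

  # trace identity for random angles
  set.seed(8)
  csr <- data.frame(id = 1:50, x = rnorm(50), y = rnorm(50),
                    sxx = rnorm(50), syy = rnorm(50), sxy = rnorm(50),
                    antisym = 0)
  psr <- polar_stress(csr)
  expect_equal(psr$srr + psr$stt, csr$sxx + csr$syy, tolerance = 1e-12)

  # a cell at the center is flagged
  cs0 <- data.frame(id = 1L, x = 0, y = 0, sxx = 1, syy = 1, sxy = 0,
                    antisym = 0)
  expect_true(is.na(polar_stress(cs0)$srr))
})

test_that("tracked velocity profiles recover the closed-form flow", {
  p <- theory_params(Lambda = 0.05, R_c = 20)
  col <- make_rod_config("random", n = 3000,
                         region = list(type = "annulus", R_in = 6,
                                       R_out = 36), seed = 9)

  # static trajectory
  static <- make_advected_pair(col, p, dt = 0)
  static[[2]]$time <- col$time + 1
  vp0 <- velocity_profile(static[[1]], static[[2]])
  expect_true(all(abs(vp0$value[vp0$count > 0]) < 1e-12))

  # noiseless advection: recovered profile matches theory within 2% of peak
  pair <- make_advected_pair(col, p, dt = 0.05)
  vp <- velocity_profile(pair[[1]], pair[[2]], breaks = seq(4, 38, 2))
  keep <- vp$count > 3
  pred <- vr_closed_form(vp$r[keep], p)
  peak <- max(abs(pred))
  expect_lt(max(abs(vp$value[keep] - pred)), 0.02 * peak)

  # rigid rotation is invisible to v_r
  rot <- col
  a <- 0.02
  rot$rods$x <- cos(a) * col$rods$x - sin(a) * col$rods$y
  rot$rods$y <- sin(a) * col$rods$x + cos(a) * col$rods$y
  rot$time <- col$time + 1
  vpr <- velocity_profile(col, rot)
  expect_lt(max(abs(vpr$value[vpr$count > 0])), 1e-10)

  # disjoint ids error
  col2 <- col
  col2$rods$id <- col2$rods$id + 10000L
  col2$time <- col$time + 1
  expect_error(velocity_profile(col, col2), "no common rod ids")
})

test_that("critical radius inverts sampled profiles", {
  p <- theory_params(Lambda = 0.01, R_c = 60)
  breaks <- seq(10, 110, 5)
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  prof <- colonyorder:::new_radial_profile(mids, vr_closed_form(mids, p),
                                           rep(50L, length(mids)),
                                           rep(0.01, length(mids)))
  rc <- critical_radius(prof)
  expect_lt(abs(rc - 60), 2.5)  # half a bin
  expect_false(attr(rc, "no_crossing"))

  # strictly positive profile: no crossing
  p0 <- theory_params(Lambda = 0.01, R_c = 0)
  prof0 <- colonyorder:::new_radial_profile(mids, vr_closed_form(mids, p0),
                                            rep(50L, length(mids)),
                                            rep(0, length(mids)))
  rc0 <- critical_radius(prof0)
  expect_true(is.na(rc0))
  expect_true(attr(rc0, "no_crossing"))

  # noisy profiles: estimator spread below two bins over 10 seeds
  peak <- max(abs(vr_closed_form(mids, p)))
  ests <- vapply(1:10, function(s) {
    set.seed(s)
    noisy <- colonyorder:::new_radial_profile(
      mids, vr_closed_form(mids, p) + rnorm(length(mids), 0, 0.1 * peak),
      rep(50L, length(mids)), rep(0.1 * peak, length(mids)))
    as.numeric(critical_radius(noisy))
  }, numeric(1))
  expect_lt(sd(ests), 10)  # two bins

  expect_error(critical_radius(colonyorder:::new_radial_profile(
    c(1, 2), c(NA_real_, NA_real_), c(0L, 0L), c(NA_real_, NA_real_))),
    "non-empty")
})

test_that("packing fraction uses exact polygon-in-annulus areas", {
  # one rod fully inside a huge bin
  one <- one_rod_colony(x = 10, y = 0, theta = 0.5, len = 3, diam = 1)
  pf <- packing_fraction_profile(one, breaks = c(0, 40))
  cap_area <- 3 * 1 + pi * 0.25
  expect_equal(pf$value, cap_area / (pi * 40^2), tolerance = 5e-3)
  expect_equal(pf$count, 1L)

  # empty annulus bin
  pf2 <- packing_fraction_profile(one, breaks = c(0, 4, 16, 40))
  expect_equal(pf2$value[1], 0)

  # hexagonal lattice of discs (L = 0 rods) ~ 0.9069
  a <- 1.0  # lattice constant = diameter -> touching discs
  pts <- expand.grid(i = -30:30, j = -30:30)
  x <- a * (pts$i + 0.5 * pts$j)
  y <- a * (sqrt(3) / 2) * pts$j
  keep <- sqrt(x^2 + y^2) < 25
  rods <- data.frame(id = seq_len(sum(keep)), strain_id = 1L,
                     x = x[keep], y = y[keep], theta = 0,
                     length = 0, diameter = 1, parent_id = NA_integer_)
  pf3 <- packing_fraction_profile(rods, breaks = c(0, 20), n_vertices = 64)
  expect_equal(pf3$value, pi / (2 * sqrt(3)), tolerance = 0.01)
})

test_that("structure-tensor director recovers stripe orientation", {
  # sinusoidal stripes at 30 degrees
  n <- 128
  ang <- pi / 6
  xs <- seq_len(n); ys <- seq_len(n)
  gx <- outer(xs, rep(1, n)); gy <- outer(rep(1, n), ys)
  img <- sin(2 * pi * (cos(ang + pi / 2) * gx + sin(ang + pi / 2) * gy) / 8)
  d <- director_from_image(img, window = 8)
  interior <- matrix(FALSE, length(d$xs), length(d$ys))
  interior[2:(length(d$xs) - 1), 2:(length(d$ys) - 1)] <- TRUE
  sel <- d$coherence > 0.5 & interior
  expect_gt(mean(sel), 0.4)
  devs <- abs(colonyorder:::nematic_diff(d$theta[sel], ang))
  expect_lt(max(devs), 2 * pi / 180)

  # rotating the image by 90 degrees rotates orientations (mod pi)
  img90 <- t(img)[, rev(seq_len(n))]  # counter-clockwise rotation
  d90 <- director_from_image(img90, window = 8)
  int90 <- matrix(FALSE, length(d90$xs), length(d90$ys))
  int90[2:(length(d90$xs) - 1), 2:(length(d90$ys) - 1)] <- TRUE
  sel90 <- d90$coherence > 0.5 & int90
  devs90 <- abs(colonyorder:::nematic_diff(d90$theta[sel90], ang + pi / 2))
  expect_lt(max(devs90), 2 * pi / 180)

  expect_error(director_from_image(matrix(1, 16, 16)))
})

test_that("rendered aster images yield high image-based radial order", {
  aster <- make_rod_config("aster", n = 900,
                           region = list(type = "annulus", R_in = 8,
                                         R_out = 28),
                           length_range = c(3, 4), seed = 10)
  img <- render_image(aster, px_size = 0.5, blur_sd = 1, noise_sd = 0.02,
                      seed = 2)
  # center of the colony in pixel coordinates
  org <- attr(img, "origin")
  center_px <- (c(0, 0) - org) / attr(img, "px_size") + 1
  sr <- image_radial_order(img, center = center_px, window = 8,
                           min_coherence = 0.4,
                           r_min = 8 / 0.5, r_max = 28 / 0.5)
  expect_gt(sr, 0.9)
})
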