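test_that("seeding respects containment, determinism and overlap tolerance", {
  p <- sim_params(rng_seed = 3L)

  disk <- seed_colony(geom_random_disk(30, 200), strain_spec(), p)
  expect_true(all(sqrt(disk$rods$x^2 + disk$rods$y^2) <= 30))
  expect_true(all(disk$rods$theta > -pi & disk$rods$theta <= pi))

  ann1 <- seed_colony(geom_annulus(40, 80, 300), strain_spec(), p, seed = 1L)
  ann2 <- seed_colony(geom_annulus(40, 80, 300), strain_spec(), p, seed = 1L)
  expect_identical(ann1$rods, ann2$rods)
  rad <- sqrt(ann1$rods$x^2 + ann1$rods$y^2)
  expect_true(all(rad >= 40 & rad <= 80))
  cf <- contact_forces(ann1)
  expect_lte(cf$max_overlap, 0.1 * mean(ann1$rods$diameter) + 1e-12)

  single <- seed_colony(geom_single_cell(), strain_spec(), p)
  expect_equal(nrow(single$rods), 1)
  expect_equal(c(single$rods$x, single$rods$y), c(0, 0))

  ring <- seed_colony(geom_ring_of_colonies(30, 6, 10), strain_spec(), p)
  expect_equal(nrow(ring$rods), 60)

  expect_error(seed_colony(geom_random_disk(5, 400), strain_spec(), p,
                           max_retries = 5L),
               "infeasible packing")
})

test_that("sector-segregated seeding assigns strains by azimuthal sector", {
  strains <- rbind(strain_spec(1L), strain_spec(2L, division_length = 10))
  col <- seed_colony(geom_sector_annulus(20, 40, 200, 8), strains,
                     sim_params(), seed = 5L)
  phi <- atan2(col$rods$y, col$rods$x)
  sec <- pmin(8, 1 + floor((phi + pi) / (2 * pi) * 8))
  expected <- rep(1:2, length.out = 8)[sec]
  expect_equal(col$rods$strain_id, as.integer(expected))
  expect_gt(min(table(col$rods$strain_id)), 0)
})

test_that("growth multiplies lengths by exp(Lambda dt) and nothing else", {
  col <- one_rod_colony(len = 2,
                        strains = strain_spec(growth_rate = log(2)))
  grown <- grow(col, 1)
  expect_equal(grown$rods$length, 4)
  expect_equal(grown$rods[c("x", "y", "theta", "diameter")],
               col$rods[c("x", "y", "theta", "diameter")])

  expect_equal(grow(col, 0)$rods, col$rods)

  strains <- rbind(strain_spec(1L, growth_rate = 0.01, division_length = 50),
                   strain_spec(2L, growth_rate = 0.02, division_length = 50))
  col2 <- two_rod_colony(x = c(0, 10), y = c(0, 0), theta = c(0, 0),
                         len = c(3, 3), strains = strains)
  col2$rods$strain_id <- 1:2
  g <- grow(col2, 10)
  expect_equal(g$rods$length[2] / g$rods$length[1], exp(0.1))
})

test_that("division splits over-threshold rods with the stated geometry", {
  # no rod over threshold -> no-op
  col <- one_rod_colony(len = 4.5)
  set.seed(1)
  expect_equal(divide(col)$rods, col$rods)

  # deterministic split: L = 6, L_div = 5, d = 1, zero noise
  strains0 <- strain_spec(division_noise_sd_frac = 0,
                          division_noise_cap_frac = 0)
  col <- one_rod_colony(x = 2, y = -1, theta = pi / 6, len = 6,
                        strains = strains0)
  set.seed(1)
  div <- divide(col)
  r <- div$rods
  expect_equal(nrow(r), 2)
  expect_equal(r$length, c(2.5, 2.5))
  expect_equal(r$theta, rep(pi / 6, 2))
  expect_equal(r$parent_id, c(1L, 1L))
  expect_true(all(r$id > 1))
  # children tile the parent extent: cap-to-cap endpoints touch at the
  # split point, here the parent center
  u <- c(cos(pi / 6), sin(pi / 6))
  endA <- c(r$x[1], r$y[1]) + (r$length[1] / 2 + 0.5) * u
  endB <- c(r$x[2], r$y[2]) - (r$length[2] / 2 + 0.5) * u
  expect_equal(endA, c(2, -1), tolerance = 1e-12)
  expect_equal(endB, c(2, -1), tolerance = 1e-12)
  # total extent conserved
  expect_equal(sum(r$length + r$diameter), 6 + 1)
})

test_that("division offset follows the truncated normal (sd L/10, cap L/5)", {
  n <- 10000
  L <- 5.2
  rods <- data.frame(id = seq_len(n), strain_id = 1L, x = 0, y = 0,
                     theta = 0, length = L, diameter = 1,
                     parent_id = NA_integer_)
  col <- colonyorder:::new_colony(rods, strain_spec(), sim_params())
  set.seed(99)
  div <- divide(col)
  expect_equal(nrow(div$rods), 2 * n)
  # recover each offset: child center projections onto the axis sum to it
  byp <- split(div$rods$x, div$rods$parent_id)
  offs <- vapply(byp, sum, numeric(1))
  expect_lt(max(abs(offs)) / L, 0.2 + 1e-12)
  expect_gt(sd(offs / L), 0.08)
  expect_lt(sd(offs / L), 0.10)
})

test_that("contact forces satisfy the stated force law and conservation", {
  # parallel rods with a gap: no force
  p <- sim_params()
  col <- two_rod_colony(x = c(0, 0), y = c(0, 1.6), theta = c(0, 0),
                        len = c(3, 3), params = p)
  cf <- contact_forces(col)
  expect_equal(cf$fx, c(0, 0))
  expect_equal(cf$fy, c(0, 0))
  expect_equal(nrow(cf$pairs), 0)

  # Newton's third law on a random dense configuration
  col <- seed_colony(geom_random_disk(14, 60), strain_spec(),
                     sim_params(rng_seed = 11L))
  col$rods$length <- col$rods$length * 1.3  # force overlaps
  cf <- contact_forces(col)
  expect_gt(nrow(cf$pairs), 0)
  expect_lt(abs(sum(cf$fx)), 1e-9)
  expect_lt(abs(sum(cf$fy)), 1e-9)
  torque_origin <- sum(cf$torque + col$rods$x * cf$fy - col$rods$y * cf$fx)
  expect_lt(abs(torque_origin), 1e-9)

  # perpendicular-rod oracle: overlap 0.2 at 1 um from rod A's center,
  # linear law with k = 1 gives |F| = 0.2 and |torque on A| = 0.2
  p1 <- sim_params(dt = 1e-4, repulsion_stiffness = 1, contact_exponent = 1)
  colp <- two_rod_colony(x = c(0, 1), y = c(0, 1.8), theta = c(0, pi / 2),
                         len = c(4, 2), params = p1)
  cfp <- contact_forces(colp)
  expect_equal(nrow(cfp$pairs), 1)
  expect_equal(cfp$pairs$overlap, 0.2, tolerance = 1e-12)
  expect_equal(abs(cfp$fy[1]), 0.2, tolerance = 1e-12)
  expect_equal(cfp$fx[1], 0, tolerance = 1e-12)
  expect_equal(abs(cfp$torque[1]), 0.2, tolerance = 1e-12)
})

test_that("wall forces repel protruding caps and restore tangential tilt", {
  wall <- list(center = c(0, 0), radius = 20, stiffness = 100)
  p <- sim_params(wall = wall)

  inside <- one_rod_colony(x = 5, y = 0, theta = 0.3, len = 3, params = p)
  wf <- wall_forces(inside)
  expect_equal(c(wf$fx, wf$fy, wf$torque), rep(0, 3))

  # radial rod centered on the wall circle: pure inward force, no torque
  radial <- one_rod_colony(x = 20, y = 0, theta = 0, len = 4, params = p)
  wf <- wall_forces(radial)
  expect_lt(wf$fx, 0)
  expect_equal(wf$fy, 0, tolerance = 1e-12)
  expect_equal(wf$torque, 0, tolerance = 1e-12)

  # nearly tangential rod with one cap protruding: torque turns it toward
  # the tangent (reduces the wrapped difference from pi/2)
  tilt <- 0.25
  near <- one_rod_colony(x = 19.4, y = 0, theta = pi / 2 - tilt, len = 4,
                         params = p)
  wf <- wall_forces(near)
  # at theta slightly below pi/2 the restoring torque must increase theta
  expect_gt(wf$torque, 0)
})

test_that("step applies grow-divide-forces-update in the stated order", {
  # isolated rod: no forces, only growth
  col <- one_rod_colony(x = 3, y = 4, theta = 1, len = 3)
  set.seed(1)
  out <- step_colony(col)
  expect_equal(out$rods[c("x", "y", "theta")], col$rods[c("x", "y", "theta")])
  expect_equal(out$rods$length, 3 * exp(log(2) * col$params$dt))
  expect_equal(out$time, col$params$dt)

  # two overlapping parallel rods separate symmetrically along the normal
  col2 <- two_rod_colony(x = c(0, 0), y = c(-0.4, 0.4), theta = c(0, 0),
                         len = c(3, 3))
  set.seed(1)
  out2 <- step_colony(col2)
  expect_lt(out2$rods$y[1], -0.4)
  expect_gt(out2$rods$y[2], 0.4)
  expect_equal(out2$rods$y[1], -out2$rods$y[2], tolerance = 1e-12)
  expect_equal(out2$rods$x, c(0, 0), tolerance = 1e-12)
})

test_that("run produces reproducible snapshots and a bounded-overlap colony", {
  p <- sim_params(rng_seed = 21L)
  col <- seed_colony(geom_annulus(12, 24, 80), strain_spec(), p)

  expect_identical(run_colony(col, 0)[[1]], col)

  tr1 <- run_colony(col, 0.5, snapshot_every = 0.25)
  tr2 <- run_colony(col, 0.5, snapshot_every = 0.25)
  expect_identical(tr1[[length(tr1)]]$rods, tr2[[length(tr2)]]$rods)
  expect_equal(length(tr1), 3)
  expect_equal(tr1[[3]]$time, 0.5, tolerance = 1e-9)

  # steady-state pair overlaps stay well below the diameter
  final <- tr1[[length(tr1)]]
  cf <- contact_forces(final)
  expect_lt(cf$max_overlap, 0.2 * mean(final$rods$diameter))

  # max_rod_count stop is clean
  psmall <- sim_params(rng_seed = 21L, max_rod_count = 90L)
  cols <- seed_colony(geom_annulus(12, 24, 80), strain_spec(), psmall)
  trs <- run_colony(cols, 3, snapshot_every = 0.5)
  expect_true(attr(trs, "stopped"))
})

test_that("unconfined colony mass grows log-linearly over five divisions", {
  # sparse disk: rods never touch, so growth + division run undisturbed
  p <- sim_params(rng_seed = 31L)
  col <- seed_colony(geom_random_disk(200, 60), strain_spec(), p)
  set.seed(child_seed <- 77)
  ts <- seq(0, 5, by = 0.25)
  mass <- numeric(length(ts))
  mass[1] <- sum(col$rods$length + col$rods$diameter)
  for (i in 2:length(ts)) {
    col <- step_colony(col, n_steps = round(0.25 / p$dt))
    mass[i] <- sum(col$rods$length + col$rods$diameter)
  }
  fit <- lm(log(mass) ~ ts)
  expect_gt(coef(fit)[2], 0.4)         # effective exponential rate
  expect_lt(max(abs(residuals(fit))), 0.02)  # log-linear within 2%
})

test_that("hole area tracks the interior void and closure", {
  p <- sim_params(rng_seed = 41L)
  col <- seed_colony(geom_annulus(12, 24, 150), strain_spec(), p)
  a0 <- hole_area(col)
  expect_gt(a0, 0)
  col2 <- step_colony(col, n_steps = round(2.5 / p$dt))
  expect_lt(hole_area(col2), a0)
  # center covered by a rod -> zero hole
  one <- one_rod_colony()
  expect_equal(hole_area(one), 0)
})

test_that("growth confined by a fixed circular wall develops radial order", {
  # a stationary wall plays the role of a constant critical radius: all
  # growth flux is directed inward and the colony aligns radially
  p <- sim_params(rng_seed = 3L,
                  wall = list(center = c(0, 0), radius = 40,
                              stiffness = 30000))
  col <- seed_colony(geom_annulus(20, 36, 220), strain_spec(), p)
  set.seed(77)
  repeat {
    col <- step_colony(col, n_steps = round(0.25 / p$dt))
    hr <- hole_radius(col)
    if (hr < 6 || col$time > 6) break
  }
  # one further division time in the fully confined state
  col <- step_colony(col, n_steps = round(1 / p$dt))
  pr <- radial_order_profile(col, breaks = seq(0, 44, 4))
  # bulk: away from the wall-anchoring layer (two rod lengths)
  expect_gt(global_radial_order(pr, 2, 30), 0.5)
  expect_gt(global_radial_order(pr, 2, 20), 0.6)
})
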