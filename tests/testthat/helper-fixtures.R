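# Shared fixtures for the test suite. Everything is generated in code;
# geometry sizes are kept small so the whole suite stays fast.

# Colony with two rods placed explicitly (no RNG).
two_rod_colony <- function(x, y, theta, len, diam = c(1, 1),
                           params = sim_params(), strains = strain_spec()) {
  rods <- data.frame(id = 1:2, strain_id = 1L, x = x, y = y, theta = theta,
                     length = len, diameter = diam,
                     parent_id = NA_integer_)
  colonyorder:::new_colony(rods, strains, params)
}

one_rod_colony <- function(x = 0, y = 0, theta = 0, len = 3, diam = 1,
                           params = sim_params(), strains = strain_spec()) {
  rods <- data.frame(id = 1L, strain_id = 1L, x = x, y = y, theta = theta,
                     length = len, diameter = diam, parent_id = NA_integer_)
  colonyorder:::new_colony(rods, strains, params)
}

# Monte-Carlo area of a capsule footprint clipped to a disk, used as the
# independent oracle for polygon-clipping based area computations.
mc_capsule_disk_area <- function(x, y, theta, len, diam, R, n = 2e5,
                                 seed = 42) {
  set.seed(seed)
  ext <- (len + diam) / 2
  px <- runif(n, x - ext, x + ext)
  py <- runif(n, y - ext, y + ext)
  ux <- cos(theta); uy <- sin(theta)
  s <- pmin(pmax((px - x) * ux + (py - y) * uy, -len / 2), len / 2)
  dx <- px - (x + s * ux); dy <- py - (y + s * uy)
  inside <- (dx^2 + dy^2 <= (diam / 2)^2) & (px^2 + py^2 <= R^2)
  mean(inside) * (2 * ext)^2
}
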