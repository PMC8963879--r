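---
title: "Models and methods: radial order in inward-growing colonies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: radial order in inward-growing colonies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

When rod-shaped bacteria surround a closed area and grow into it, the
colony's radial velocity profile reverses sign at a critical radius, and the
resulting flow gradient rotates cells into the radial direction. The colony
converges on a stable aster — a +1 topological defect — instead of the
microdomain mosaic of a regular expanding colony. `colonyorder` implements
this physics three ways and cross-checks them: a closed-form theory, an
agent-based hard-rod simulator, and an active-nematic continuum solver,
together with the measurement operators that connect all three to data.

This document records the models, their assumptions, the numerical choices,
and what the package's tests do and do not establish.

## Closed-form theory

Exponential growth at rate $\Lambda$ must be accommodated by boundary
motion. Assuming a constant critical radius $R_c$ where the radial velocity
vanishes, area bookkeeping on either side of $R_c$ gives

$$v_r(r) = \frac{\Lambda (r^2 - R_c^2)}{2r},$$

negative (inward) below $R_c$ and positive above; $R_c = 0$ recovers the
Hubble-like linear profile $v_r = \Lambda r / 2$ of uniform expansion. The
local growth rate $g(r) = v_r/r$ then has
$g'(r) = \Lambda R_c^2 / r^3 > 0$ whenever $R_c > 0$.

For the orientation $\theta$ of a rod at angular position $\phi$ and radius
$r$, the flow-alignment approximation (fixed scalar order $S$, no molecular
field, no spatial coupling) reduces the Q-tensor dynamics to

$$\frac{d\theta}{dt} = \frac{\xi\, g'(r)\, r}{2S} \sin\!\big(2(\phi - \theta)\big),$$

where $\xi$ is the flow-alignment parameter. The factor $r$ enters because
the traceless strain rate of the radial flow $v = g(r)\,r\,\hat r$ has
magnitude $g'(r)\,r/2$ (by differentiating $v_\alpha = g(r) x_\alpha$; the
$r$ is required dimensionally and by the chain rule). $\theta = \phi$
(radial; the aster) and $\theta = \phi \pm \pi/2$ (tangential) are fixed
points; for $\xi g' > 0$ the aster is stable with linear decay rate
$\xi g' r / S$ and the tangential state is unstable with the same-magnitude
growth rate. All angle arithmetic in the package is nematic: comparisons
use the difference wrapped into $(-\pi/2, \pi/2]$.

Both closed forms carry independent oracles in the test suite: the
hole-boundary ODE $\dot r = v_r(r)$ is integrated (RK4) and checked against
the exponential area law $\pi(R_c^2 - r^2) \propto e^{\Lambda t}$ to
$10^{-8}$ relative, and the linearised decay rate is checked against the
slope of $\log|\theta - \phi|$ from the integrated dynamics to 1%.

## Hard-rod colony simulator

Rods are 2D spherocylinders: a cylinder of length $L$ (pole-to-pole minus
the caps) and diameter $d$, position $(x, y)$, nematic orientation
$\theta$. Defaults are $d = 1\,\mu m$ and division threshold
$L_{div} = 5\,\mu m$; time is measured in division times of the reference
strain, so the default elongation rate is $\Lambda = \log 2$ per unit time.

Each step applies, in order:

1. **Growth** — every cylinder length is multiplied by
   $e^{\Lambda_{strain}\, dt}$.
2. **Division** — a rod with $L > L_{div}$ splits at an axial offset drawn
   from $N(0, (L/10)^2)$, redrawn until $|s| \le L/5$. The two collinear
   children tile the parent's full spherocylinder extent (caps touching at
   the split point), so their cylinder lengths sum to $L - d$ and no
   footprint area is created or destroyed.
3. **Contact forces** — pairs whose minimal segment–segment distance is
   below the mean diameter repel with magnitude $k\,\delta^{3/2}$
   (Hertzian-like; $\delta$ the overlap), along the minimal-distance
   direction, applied at the closest points. For axes within 45° the
   contact is a two-point manifold: the gap is evaluated at both ends of
   the overlapping axial interval with half stiffness each. A single
   midpoint force on a near-parallel contact line cannot transmit the
   differential squeeze along the line, and it is exactly that differential
   that torques rods in a velocity gradient; without the manifold the
   emergent radial order is several times weaker. Exactly collinear
   degenerate pairs are resolved by a deterministic perpendicular chosen by
   the lower rod id. An optional fixed circular wall repels protruding end
   caps with the same law, and an optional tangential contact friction
   (`friction_gamma`) is available but off by default — with the explicit
   lagged-velocity coupling it degraded both stability and order.
4. **Overdamped update** — $\Delta x = F\,dt/(\zeta_t (L+d))$ and
   $\Delta\theta = T\,dt/(\zeta_r (L+d)^3)$. The cubic length dependence of
   the rotational drag is the slender-body scaling, and the default
   $\zeta_r = \zeta_t / 12$ is the slender-body ratio (uniform drag per
   unit length gives $\lambda L$ translational and $\lambda L^3/12$
   rotational drag). The axial force component sees half the transverse
   drag (`drag_ratio = 0.5`), again the classical slender-body value.
   Displacements are capped at $0.05\,d$ per step (rotations at the
   matching angle): a contact-chain overshoot may never carry a rod across
   a neighbour in one step. Without the cap, rare deep-overlap events
   nucleate rod crossings that scramble the emergent order.

The engine parameters are not printed in any reference and were calibrated
once, against the emergent observables (bounded overlaps, stable stress
chains, reproducible radial ordering), and then frozen:
$dt = 1.25\times10^{-4}$ division times, $k = 3\times10^4$,
$\zeta_t = 1$. The explicit scheme requires $dt\,k/\zeta_t$ below the
configured stability threshold. Seeding uses rejection sampling with an
overlap tolerance of 10% of the diameter and bounded retries; orientations
are i.i.d. uniform; initial cylinder lengths are uniform between 40% and
80% of the division length (a desynchronised age structure). One root seed
feeds derived child streams for placement and division noise, so identical
`(seed, params)` give bit-identical trajectories.

Two bookkeeping consequences are worth stating explicitly. Because division
conserves total spherocylinder extent $M = \sum (L_i + d_i)$ while growth
acts on the cylinder lengths only, $dM/dt = \Lambda (M - N d)$: the colony's
effective area growth rate is about $0.75\,\Lambda$ ($\approx 0.52$ per
division time at the defaults), not $\Lambda$ itself. Mass growth is still
log-linear to better than 2% once the age structure is desynchronised, and
the test suite checks exactly that. It also means an annulus reaches hole
half-radius with roughly $7$–$8\times10^3$ rods rather than the
$2$–$4\times10^3$ a $\Lambda$-rate extrapolation would suggest.

### What the simulator does and does not reproduce

At the reference geometry (annulus $R_{in} = 40\,\mu m$,
$R_{out} = 80\,\mu m$, 500 seeded rods, run to hole half-radius), the
simulator reproduces, across seeds:

- a nonlinear azimuthal radial-velocity profile with an interior zero whose
  closed-form fit has $R^2 > 0.9$ and whose crossing (the critical radius,
  $R_c \approx 55$–$60\,\mu m$) drifts little once the hole is a
  well-defined interior void;
- compressive radial stress peaking near $R_c$;
- strong radial order in the inner colony ($S_R \approx 0.6$–$0.85$ for
  $r \lesssim 40\,\mu m$ by closure), moderate order beyond $R_c$
  ($S_R \approx 0.3$–$0.5$), and tangential anchoring at the free edges —
  the aster phenomenology, including order on both sides of the critical
  radius;
- the expanding-colony contrast: a single-cell colony grown to a few
  thousand rods shows no comparable radial order and a near-linear velocity
  profile.

Two quantitative caveats, visible in the acceptance suite and reported
honestly there: the effective flow-alignment coupling of this soft-contact
overdamped engine is weaker than that of rigid-body engines
($\xi_{eff} \approx 0.2$–$0.4$), so the azimuthal band around $R_c$ — where
material is youngest — averages $S_R \approx 0.25$ at hole half-radius
rather than exceeding 0.5; and at colony radii beyond $\sim 50\,\mu m$ the
accumulated load compresses the packing by several percent, which bends the
expanding-colony velocity profile away from linear ($R^2 \approx 0.9$) and
seeds mild spurious radial order ($S_R \approx 0.3$ at $3\times10^3$ rods).
Stiffer contacts would reduce both effects but require a proportionally
smaller time step; the frozen parameters are the best stability–fidelity
compromise at practical run times, and the package reports the measured
values rather than adjusting the measurement to mask them.

## Continuum model

The continuum solver evolves a density $\rho$, a velocity $v$, and a
traceless symmetric nematic tensor $Q$ (stored as $Q_{xx}, Q_{xy}$, so
symmetry and tracelessness are exact) on a uniform grid:

$$\frac{D\rho}{Dt} = \Lambda\rho + D_\rho \nabla^2 \rho, \qquad
\frac{D(\rho v)}{Dt} = \nabla\cdot\sigma - \gamma\rho v, \qquad
\frac{DQ}{Dt} = \xi u + Q\omega - \omega Q + \Gamma^{-1} H,$$

with the material derivative $D/Dt = \partial_t + v\cdot\nabla +
(\nabla\cdot v)$ applied to all three fields, $u$ the traceless symmetric
strain rate, $\omega$ the vorticity, and

$$\sigma = -p\,I - a(\rho)\,Q - \xi H + QH - HQ, \qquad
H = K\nabla^2 Q - \alpha(\rho) Q - \beta(\rho)\,\mathrm{tr}(Q^2)\, Q,$$

where $a(\rho) = a_0\rho$, $\alpha(\rho) = \alpha_0(\rho_c - \rho)$,
$p = G\max(\rho/\rho_0 - 1, 0)$, and by default
$\beta(\rho) = 2\alpha_0\rho$. The printed form of the $\beta$ closure is
typographically ambiguous ($\alpha_0\cdot 2\rho$ versus
$\alpha_0/(2\rho)$); the default is the low-density-bounded first reading
and the alternative is available via `beta_form = "a0over2rho"`. The
activity sign is chosen extensile — a uniform $Q$ stripe drives outward
flow along its director — and verified empirically by a test; the opposite
sign is available via `activity_sign`.

Reference parameters (dimensionless model units): $\Lambda = 0.005$,
$\gamma = 0.2$, $\xi = 0.7$, $\Gamma = 1$, $a_0 = 0.002$,
$\alpha_0 = 0.01$, $\rho_c = 0.5$, $G = 2$, $D_\rho = 0.04$, $K = 0.01$,
$\rho_0 = 1$. One division time is $\log 2/\Lambda \approx 139$ time units.

Numerics: second-order central differences for gradients and Laplacians,
first-order upwinding for all advection terms (which keeps $\rho \ge 0$ up
to clipping, whose removed mass is logged), first-order explicit time
stepping with construction-time stability bounds (diffusive, pressure-wave
CFL, drag), and no-flux boundaries by edge replication. A colocated grid
with central pressure gradients supports a checkerboard mode; a small
momentum viscosity ($\nu_m = 0.5$ grid units) damps it and is included in
the stability bound. Velocity is zeroed below 2% of $\rho_0$: momentum is
meaningless in the near-vacuum outside the colony and dividing by a
vanishing density there is the dominant failure mode of the naive scheme.
The discrete Landau–de Gennes free energy is written so that the
edge-replicated Laplacian is its exact gradient; the molecular field is
verified against central finite differences of that discrete functional,
and pure $Q$-relaxation descends it monotonically.

At the reference parameters, an annulus initial condition ($\rho_0$ inside
$R_{in} = 20$–$R_{out} = 40$ grid units, tanh edges, seeded $Q$ noise of
s.d. 0.01) develops $S_R \approx 1$ through the bulk by $t \approx 112$
while the hole is still open, with an interior velocity zero and tangential
anchoring bands about three grid units wide at both diffuse edges; "bulk"
therefore excludes three bins at each end of the occupied radial range. A
disk initial condition (radius 24) shows a transient radial pulse from the
pressure onset that decays below $|S_R| = 0.2$ by $t \approx 336$; the disk
is measured then, after the transient. The quasi-static mode
($\gamma\rho v = \nabla\cdot\sigma$) matches the damped dynamics'
azimuthally averaged radial velocity to within 5% RMS of peak in the bulk
at late times.

## Measurement operators

The radial order parameter of a set of orientations is
$S_R = \langle \cos 2(\theta_i - \phi_i) \rangle$: $+1$ radial, $-1$
tangential, $0$ isotropic. It is invariant under $\theta \to \theta + \pi$
and global frame rotation; items exactly at the center are excluded and
counted. Radial profiles use fixed-width bins (default twice the rod
diameter) with empty bins flagged rather than interpolated. The colony
center defaults to the seeded hole center for annulus colonies and the rod
centroid otherwise.

Per-rod virial stress is
$\sigma_i = \frac{1}{2a'_i}\sum_j (r_{ij}\otimes F_{ij} + F_{ij}\otimes
r_{ij})$ over the rod's contacts, with $r_{ij}$ the contact position
relative to the rod center and $a'$ the spherocylinder footprint area
$Ld + \pi d^2/4$ (the "effective area" is not otherwise defined; the
footprint is the natural 2D choice). The symmetrized outer product makes
the polar decomposition well-defined; the antisymmetric residue is exported
as a diagnostic. The polar transform drops the shear component (negligible
lateral friction): $\sigma_{rr} = \sigma_{xx}\cos^2\phi +
\sigma_{yy}\sin^2\phi$, and cyclically; the full rotation (including
$\sigma_{xy}$, with the factor-2 cross terms of the standard tensor
rotation) is available behind a flag.

Velocities come from tracked rod ids between snapshot pairs (births are
excluded); the critical radius is the linearly interpolated sign change of
the binned $v_r$, taking the crossing nearest the count-weighted median
radius when there are several. Packing fractions use exact
polygon-with-disk intersection areas of $\ge 32$-vertex capsule polygons
(validated against the hexagonal disc-packing density). Image directors
use the structure tensor: Gaussian-smoothed gradient outer products,
ridge orientation as the minor eigenvector, coherence
$(\lambda_1-\lambda_2)/(\lambda_1+\lambda_2)$.

## Synthetic data

Generators produce rod configurations with prescribed order (aster,
tangential, random, stripes) in discs or annuli, with wrapped angular noise
applied on the nematic angle: half of a von Mises draw with concentration
$\kappa$, so the expected radial order of a noisy aster is the circular
moment $I_1(\kappa)/I_0(\kappa)$, computable by quadrature. Snapshot pairs
advected by the closed-form velocity (ids preserved) are the ground truth
for tracking estimators, and rasterized capsule images with Gaussian blur
and additive noise emulate fluorescence micrographs of monolayer colonies.
What these fixtures deliberately do not emulate: optical point-spread
functions, shot noise, uneven illumination, cell-to-cell intensity
variation, and out-of-plane (multi-layer) structure — so a passing
image-analysis test shows the estimator inverts its own forward model, not
that it is robust to real microscopy artifacts.

## Competition protocol

Two strains share growth rate, diameter and mechanics and differ only in
division length (ratio $\rho_L$), isolating the torque–length mechanism:
longer rods feel a larger aligning torque, align radially sooner, and ride
the inward flow into the defect core. Seeding is either a mixed balanced
random annulus or a sector-segregated annulus; closure is detected when the
flood-filled interior void (raster cell half a diameter) falls below four
rod footprints; core occupancy is the exact per-strain rod footprint area
inside the core disc, and edge occupancy the fraction of azimuthal sectors
whose outermost rod belongs to each strain. Statistics over replicate seeds
use sign tests, with no distributional assumptions. The identical-strain
control ($\rho_L = 1$) must be statistically symmetric; post-closure lane
buckling is recorded qualitatively via a tortuosity diagnostic, not as a
numeric claim.

## Problem sizes used by the tests and the acceptance script

Chosen to give stable statistics at practical run times; all stated in the
code that uses them:

- Rod-colony acceptance runs: annulus $R_{in} = 40$, $R_{out} = 80\,\mu m$,
  500 rods, 5 seeds, run to hole half-radius ($\approx 7$–$8\times10^3$
  rods each); expanding control to $3\times10^3$ rods (the midpoint of the
  $2$–$4\times10^3$ band the annulus estimate suggested).
- Unit-test colonies are smaller (tens to hundreds of rods; reduced annuli
  of $R_{in} = 10$–$24\,\mu m$).
- Continuum: $128^2$ grid for the acceptance contrast, $96^2$–$128^2$ in
  unit tests; the grid-refinement check compares $96^2$ against $128^2$ at
  matched physical time.
- Competition: annulus $R_{in} = 10$, $R_{out} = 20\,\mu m$, 70 rods,
  core radius $5\,\mu m$; 10 seeds for the $\rho_L = 2$ race and 20 for the
  control.

## Known limitations

- The overdamped soft-contact engine is a stand-in for an unpublished
  rigid-body engine; its weaker effective flow-alignment coupling and
  large-colony compressibility are quantified above and flagged where they
  keep an acceptance threshold out of reach.
- The continuum solver is first-order in time and first-order upwind in
  advection; refinement tests bound, but do not eliminate, numerical
  diffusion.
- No three-dimensional mechanics: no verticalization, multi-layering or
  extrusion; motility, adhesion and nutrient fields are out of scope.
- Defect tracking beyond the aster (locating or classifying half-integer
  defects) is not implemented.
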