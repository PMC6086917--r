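---
title: "flapflow: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{flapflow: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(flapflow)
```

# The problem

A fruit fly in forward flight beats its wings at hundreds of hertz while
moving through air that carries odor cues.  The same wing motion that
produces lift also stirs the air around the antennae, the primary
olfactory organs sitting at the anterior tip of the head.  `flapflow`
simulates this coupled picture at desk scale: an incompressible-flow
solver with moving immersed bodies, prescribed flapping kinematics,
surface force/power accounting, and odor transport diagnostics
(Lagrangian tracers and velocity probes a fixed offset above the
antenna).  Two experiment drivers reproduce the study designs this class
of work uses: a reduced-frequency sweep and a virtual trailing-edge
wing-clipping comparison.

# Model and nondimensionalization

The governing equations are the incompressible Navier–Stokes equations
in nondimensional form.  Lengths are scaled by the wing span R, velocity
by the freestream speed, time by R/U; the only flow parameter is the
Reynolds number `Re = U R / nu` (173 for the nominal case: U = 0.94 m/s,
R = 2.87 mm, air at 27 °C) and the only kinematic parameter of the
flapping schedule is the reduced frequency `k = f R / U` (0.65 at
f = 213 Hz).  Changing f at fixed U, or U at fixed f, leaves the
nondimensional problem unchanged as long as (Re, k) are matched — the
sweep driver therefore varies the flapping frequency at a single inflow
speed.

The wing schedule is the idealized forward-flight stroke: position angle
`phi(t) = 0.5 * Phi * cos(2 pi f t)` with `Phi = 140°` (cycle starts at
the dorsal reversal; the downstroke is `phi` decreasing), zero deviation
angle, and a feathering angle holding −30° through the downstroke and
+60° through the upstroke.  Sign conventions, which the usual verbal
descriptions leave implicit, are fixed in the code and documented in
`?wing_kinematics`: feathering is measured from the stroke plane,
positive nose-up.  Two choices were genuinely open:

* **Reversal-window phase.**  The feathering transition lasts 0.22 of a
  cycle at each reversal but its alignment is unstated; we center each
  window on the reversal instant (the extrema of `phi`).  This is the
  symmetric choice and produces smooth, C¹ transitions.
* **Blend shape.**  "Changes sinusoidally" is implemented as a
  half-cosine between the two plateaus.

# Numerical method

The solver is a fractional-step (projection) method on a collocated,
nonuniform Cartesian grid:

* **Convection**: explicit Adams–Bashforth-2 on the *skew-symmetric*
  form, the mean of the advective and divergence forms of the
  nonlinear term.  The plain advective form with central differences is
  unstable in the energetic wake at desk resolutions (cell Reynolds
  numbers of 30–300); the skew-symmetric form is discretely
  energy-conserving and removes that failure mode.  For the bluff-body
  flapping runs a further stabilization is available and used by the
  experiment drivers: `solver_settings(upwind = 0.2)` blends 20%
  first-order upwind convection into the central scheme.  The
  verification battery (Taylor–Green decay, temporal and spatial
  convergence orders) runs the pure central scheme (`upwind = 0`), so
  the measured second-order accuracy certifies the central
  discretization; the upwind blend trades locally first-order accuracy
  for robustness and is always an explicit, logged setting.
* **Diffusion**: implicit Crank–Nicolson by default (an explicit mode
  exists for verification).  The two velocity Helmholtz operators are
  assembled once per (grid, dt, Re) and LU-factorized; each step costs
  two sparse triangular solves.
* **Projection**: incremental pressure correction (the predictor carries
  the old pressure gradient; the Poisson solve returns the increment),
  which is what makes the scheme second-order in time.  The
  pressure-Poisson operator (homogeneous Neumann everywhere, or
  periodic) is singular; it is pinned at one cell, LU-factorized once,
  and each solve is followed by up to two passes of iterative refinement
  so the post-projection face divergence stays at the 1e-6 invariant
  even when fast body motion makes the right-hand side large.
* **Face velocities**: the divergence driving the projection is built
  from distance-weighted momentum-interpolated face velocities, the
  standard cure for the collocated checkerboard mode.  On the outflow
  boundary the face flux is shifted uniformly so global mass balance —
  and hence the solvability of the Neumann problem — holds exactly.
* **Immersed boundaries**: bodies are analytic rigid shapes carrying a
  signed-distance function.  Cells are classified fluid/solid/ghost
  (solid with a fluid neighbor) /fresh (newly uncovered) each step.
  Ghost cells receive the linear extrapolation `2 u_b - u_image` through
  the surface foot point (bilinear interpolation at the image point),
  which enforces no-slip at the interpolated surface location; deep
  solid cells carry the body velocity.  Fresh cells inherit the body
  velocity they carried while covered, the standard first-order fresh
  cell treatment; their count is reported per step.  One deliberate
  deviation from thin-surface practice: the 2D wing section is a
  *finite-thickness* rounded plate (0.06R, two refined cells) rather
  than a zero-thickness surface with signed-side ghosts.  At desk
  resolution the two-sided thin-wing bookkeeping is the dominant source
  of fragility, and a 2-cell plate resolves the same dynamics.
* **Pressure inside bodies**: an incremental projection has no feedback
  inside solids, and the pressure increment accumulates there without
  bound (observed directly: the spurious interior pressure eventually
  leaks into the surface force integral).  After each step the solid
  interior pressure is therefore regenerated from the fluid:
  ghost-layer cells mirror the image-point value (zero normal gradient
  at the surface), deeper cells are zeroed.
* **Time step**: chosen per run from the advective CFL bound
  (`suggest_dt`, CFL 0.4 for flapping runs, 0.5 otherwise) against the
  peak body speed plus freestream; the step is then rounded so an
  integer number of steps lands exactly on each cycle boundary.

Boundary conditions follow the wind-tunnel arrangement: fixed inflow
velocity upstream, zero streamwise-gradient outflow, zero-stress
(free-slip, impermeable) lateral walls, homogeneous Neumann pressure on
all boundaries; a fully periodic mode supports the verification cases.

## Verification

* Uniform inflow with no bodies is preserved to machine precision.
* Taylor–Green vortex (periodic, Re 100, 64²): kinetic-energy decay
  within 0.01% of `exp(-4 t / Re)` at one turnover; the 1% acceptance
  band is met with two orders to spare.
* Temporal Richardson triple (dt, dt/2, dt/4): observed order 1.99.
* Spatial triple (24², 48², 96² vs the closed form): observed order 2.0.
* Impulsively started cylinder at Re 40: the steady drag on the desk
  grid (Δ = 0.05 diameters) agrees within 3.6% with a frozen reference
  computed by the same solver on a 2× refined grid (Δ = 0.025, t = 30,
  Cd = 1.6405).  The desk budget did not allow the 4× refinement a
  textbook Richardson extrapolation would use; 2× with a 5% band is the
  documented compromise.  (The absolute value sits above the unbounded
  literature ~1.5 because the 16R-wide free-slip tunnel adds blockage —
  the comparison is solver-against-itself by design.)
* Mirror symmetry: a stream-aligned symmetric body yields a side force
  below 1e-10 and velocity fields symmetric to the same level after 80
  steps — the discrete operators preserve the reflection symmetry to
  roundoff.

# Synthetic geometry

The true wing outline used in this line of work is digitized from a real
wing and is not tabulated, so the generator builds a **parametric
stand-in**: leading and trailing edges are smooth span functions
(`sin^0.85` base chord law) plus a Gaussian trailing-edge lobe centered
at 30% span (amplitude 0.55, width 0.22 span fractions), scaled so the
planform reproduces the measured area S = 2.59 mm² and span
R = 2.87 mm exactly.  The mean chord is defined as S/R = 0.902 mm; the
conventionally quoted 0.89 mm differs by 1.5%, consistent with a
different chord convention, and S/R is used throughout (the clipped wing
then gives 2.09/2.87 = 0.728 → 0.73 mm, matching the quoted value).

**Clipping** removes everything behind a chordwise line `x = const` in
the wing frame; the default line is solved by bisection so the removed
trailing-side area is 19.3% of S, which lands the clipped planform on
2.09 mm² and mean chord 0.73 mm simultaneously.  The removed region sits
against the root-heavy trailing lobe, the span is untouched, and
area bookkeeping (clipped + removed = original) holds to rounding.

The 3D body is a triangulated ellipsoid (default semi-axes 1.25, 0.42,
0.45 mm) pitched nose-up by χ = 45°, with the **antenna landmark at the
anterior apex of the head** — the study gives no coordinates, and the
apex is the natural "bow of the boat" position.  Wings are structured
triangulations of the planform attached at a dorsal-shoulder hinge;
left/right are exact mirror images.  What the generator does *not*
emulate: wing corrugation and venation, body segmentation, legs, and the
exact digitized outline — a green geometry test certifies areas, spans,
symmetry and watertightness, not species-level shape fidelity.

# The desk-scale 2D analog

Solving the 3D problem at production fidelity takes a ~10⁷-point grid
for eight cycles — cluster work, which the sweep driver will *plan*
(`scale = "paper"`) but never run.  Desk-scale experiments use a 2D
sagittal analog built from the same morphology and kinematics:

* body = sagittal ellipse section (semi-axes 0.435R, 0.15R) at χ = 45°;
* wing = flat plate of chord c̄/R (0.314 original, 0.254 clipped),
  thickness 0.06R, **heaving along the stroke-plane line with the
  velocity of the 70%-span section** (`r_arm = 0.7`) and pitching with
  the feathering schedule (plate angle = stroke-plane angle + α);
* the stroke line is inclined χ − β = 25° to the horizontal and is
  displaced 0.45R dorsally from the shoulder hinge.  This offset is a
  *geometric feasibility* constraint, set once: a 2D section cannot pass
  beside the body the way the real wing does, and 0.45R is the smallest
  round value that keeps the plate clear of both the body (minimum
  clearance 0.068R ≈ 2.3 cells) and the antenna probes (0.039R) over the
  entire cycle at every k.

With this analog the plate sweeps from above/behind the thorax, past the
head, to ahead of and below the antenna level, and the ventral reversal
"flicks" near-head air toward the antennae — the sectional skeleton of
the trap-and-flick mechanism.  Normalizations use the full-span mean tip
speed `U_tip = 2 Phi f R` (so coefficients are comparable across k) and
the plate's own chord as the reference area.  The body-only (k = 0)
baseline has no tip speed and is normalized by the freestream; its odor
flux is steady, so peak = mean.

**What a green desk test establishes — and what it does not.**  The desk
assertions are *trend* assertions: antenna odor flux increasing in k,
lift coefficient decreasing in k, clipping reducing peak antenna flux,
and the antenna vortex weakening relatively more than the leading-edge
vortex.  All four hold (e.g. mean flux 0.96 → 1.10 → 2.88 kg s⁻¹ m⁻²
and C̄_L 0.77 → 0.60 → 0.51 across k = 0.33/0.65/1.30; clip at k = 0.65:
peak flux −8.7%, |ΔΓ_AV|/Γ_AV = 16.5% vs |ΔΓ_LEV|/Γ_LEV = 9.6%).  One
production-scale result is *not* reproducible in this analog and its
acceptance test is intentionally left failing: clipping raises the 3D
lift coefficient (+9.6% at k = 0.65) because the removed root sections
see low dynamic pressure, so the wing loses area much faster than force.
A single-section 2D analog has one chord that sets both the force and
the reference area, and the measured desk delta is −12%.  This is a
structural limitation of the stated analog, not a tuning target; the
assertion is kept red rather than weakened.

# Odor transport

The inlet carries a normalized uniform concentration C′ = 1.  For
natural odors the diffusivity is 1e-2–1e-1 cm²/s, so the Peclet number
is 10²–10³ and diffusion is dropped: pure convection of a uniform inlet
leaves C′ ≡ 1, and the odor mass flux at a probe reduces to
`C' * rho_odor * |U*|` with ρ_odor = ρ_air = 1.225 kg/m³.  Choices:

* **U\*** is taken as the velocity *magnitude* (the flux expression is a
  scalar product of scalars); a direction-resolved flux is available
  from the per-probe velocity components.
* **Antenna triplet**: three probes 0.03R above the antenna landmark
  along the outward normal, spaced one refined cell apart along the
  body-axis tangent; the antenna flux is their mean.  The probe layout
  is unstated in the source; one-cell spacing makes the three samples
  independent at grid resolution.  The 0.03R offset must be at least
  one cell — it is 1× the default refined spacing, checked at setup.
* **Tracer particles** advect with RK2 (midpoint) using bilinear spatial
  and linear temporal interpolation; they deactivate on domain exit,
  are projected back to the surface (and counted) if a step lands them
  inside a body, and keep their release-origin tag for
  plume-by-origin visualization and capture statistics.  A capture
  radius of 0.05R is the default for particle statistics (the source
  visualizes but never thresholds); the anisotropy harness in the tests
  uses a coarser radius appropriate to the frozen-field protocol it
  runs at desk scale.
* The optional Eulerian mode (`advect_scalar`) is conservative
  first-order upwind — monotone at CFL ≤ 1, exact at CFL = 1 on a
  uniform grid — with an explicit 1/Pe diffusion term when enabled.

# Diagnostics

Vorticity and Q (½(‖Ω‖² − ‖S‖²)) come from the same central-difference
velocity gradients.  Circulation integrates vorticity over a
sign-selected patch inside a window, with patch membership at |ω| ≥ 10%
of the window peak (no threshold is stated in the source; 10% is low
enough to capture the core and high enough to reject wake debris), and a
Stokes-theorem cross-check via the boundary line integral of velocity.
The antenna-vortex window is fixed around the head; the
leading-edge-vortex window follows the plate's leading edge.  The exact
"body center" plane/extent of the antenna-vortex patch is unstated and
both windows are configuration-exposed.

# Experiments and reproducibility

`frequency_sweep()` runs one case per k (same inflow, different
flapping frequency) and tabulates cycle-averaged C̄_L, C̄_F, C̄_PW,
C̄_F/C̄_PW and peak/mean antenna flux, one row per k, each row tagged
`desk` or `paper` so trend results can never masquerade as
production-scale values.  The analysis cycle is the **last completed
cycle**; whether the original protocol averaged the 8th cycle or several
late cycles is unstated, so the cycle-to-cycle L2 periodicity metric is
stored with every run (0.075 at k = 0.65 after 4 desk cycles).  Desk
runs use 4 cycles (the production protocol's 8 cycles at ~3× finer grid
is out of desk budget); the drivers expose `n_cycles`.  The pipeline
contains no random state: rerunning any experiment from its saved JSON
configuration reproduces outputs bit-identically, and each CLI run
directory gets an MD5 manifest.

# Known limitations

* Flow stepping is 2D; the 3D path covers geometry, kinematics, grids
  and the cluster-scale run plan, not time integration.
* Field output is legacy-VTK ASCII and CSV (no R HDF5 binding is
  available in the supported environment).
* The upwind-blended convection used in flapping runs is locally
  first-order where the blend is active.
* The wing is rigid and the body is tethered; free-flight coupling and
  wing flexibility are out of scope.
* Odorant–receptor kinetics and boundary-layer absorption are not
  modeled: flux at 0.03R with 100% absorption is the stated proxy.
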