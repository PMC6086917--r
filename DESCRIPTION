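Package: flapflow
Title: Immersed-Boundary Flow Simulation of Flapping Insect Flight and
    Odor Transport
Version: 0.1.0
Authors@R:
    person("flapflow", "developers", email = "flapflow@example.org",
           role = c("aut", "cre"))
Description: A "numerical wind tunnel" for insect flight olfaction studies:
    a fractional-step incompressible Navier-Stokes solver with ghost-cell
    immersed boundaries for moving rigid bodies, prescribed flapping-wing
    kinematics (position, deviation and feathering Euler angles), surface
    force and aerodynamic power quantification, and convection-dominated
    odor transport via Lagrangian particle tracing and odor-mass-flux
    probes near the antennae.  Includes a parametric fruit-fly geometry
    generator (body ellipsoid plus clippable wing planform), nonuniform
    Cartesian grid construction with a uniformly refined inner box,
    vortex diagnostics (Q-criterion, vorticity, circulation) and
    reproducible experiment drivers for reduced-frequency sweeps and
    trailing-edge wing-clipping comparisons at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
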