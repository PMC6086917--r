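#' Run one desk-scale 2D flapping (or body-only) case
#'
#' Builds the sagittal analog, grid and solver for one reduced frequency,
#' runs `n_cycles` flapping cycles with force, power, odor-probe and
#' vortex-circulation observers, and reduces the final (analysis) cycle
#' to the summary quantities of the frequency-sweep table.
#'
#' Normalizations follow the flapping-flight conventions: forces on the
#' wing by `0.5 rho U_tip^2 c`, power by `0.5 rho U_tip^3 c` (with
#' `U_tip` the cycle-mean tip speed and `c` the plate chord); the
#' body-only case (`k = 0`) has no tip speed and is normalized by the
#' freestream instead.  Odor flux is reported in kg s^-1 m^-2 using the
#' dimensional scales `U_ref` (m/s) and `rho_odor`.
#'
#' @param k reduced frequency (0 for body-only).
#' @param planform wing planform (clipped or not).
#' @param n_cycles flapping cycles (body-only: `n_cycles` time units).
#' @param delta refined-box cell size, units of R.
#' @param Re Reynolds number.
#' @param U_ref dimensional freestream speed, m/s (odor-flux scale).
#' @param odor an [odor_config()].
#' @param domain outer domain extents, units of R.
#' @param cfl advective CFL used to pick the time step.
#' @param observe_every observer stride in steps.
#' @param particles optional [particle_set()] advected alongside.
#' @param verbose print per-cycle progress.
#' @return list with `summary` (one-row data frame), `series` (observer
#'   time series), `state`, `analog`, `grid`, `periodicity`.
#' @export
run_flapping_case <- function(k, planform = wing_planform(), n_cycles = 4,
                              delta = 0.03, Re = 173, U_ref = 0.94,
                              odor = odor_config(),
                              domain = list(c(-5, 9), c(-4.5, 5)),
                              cfl = 0.4, observe_every = 2L,
                              particles = NULL, verbose = FALSE) {
  an <- fly_analog_2d(k, planform = planform)
  box <- list(c(min(an$sweep_x[1], -0.9), max(an$sweep_x[2], 0.9)),
              c(min(an$sweep_y[1], -0.75), max(an$sweep_y[2], 0.75)))
  grid <- build_grid(domain, box, delta)
  vmax <- if (k > 0) an$r_arm * 0.5 * an$kin$Phi * pi / 180 * 2 * pi * k + 1 else 1.5
  dt <- suggest_dt(grid, vmax, cfl)
  T_cycle <- if (k > 0) an$T_cycle else 1
  steps <- max(1L, round(T_cycle / dt))
  dt <- T_cycle / steps                      # land cycle boundaries exactly
  settings <- solver_settings(Re = Re, dt = dt, cfl = cfl, upwind = 0.2)
  solver <- build_solver(grid, settings)
  probes <- odor_probes(an$antenna, an$antenna_normal, grid,
                        bodies = list(an$body))
  U_tip <- if (k > 0) an$U_tip else 1        # body-only: freestream normalization
  Sref <- if (k > 0) an$chord else 2 * an$body_semiaxes[1]
  # vortex windows: AV fixed near the head; LEV follows the plate's leading edge
  av_win <- c(an$antenna[1] - 0.35, an$antenna[1] + 0.45,
              an$antenna[2] - 0.25, an$antenna[2] + 0.55)
  observers <- list(
    aero = function(state, bodies, solver) {
      if (length(bodies) >= 2) {
        f <- surface_forces(state, bodies[[2]], solver)
        P <- aero_power(state, bodies[[2]], solver)
      } else {
        f <- surface_forces(state, bodies[[1]], solver)
        P <- 0
      }
      c(C_L = f$F_L / (0.5 * U_tip^2 * Sref),
        C_T = f$F_T / (0.5 * U_tip^2 * Sref),
        C_PW = P / (0.5 * U_tip^3 * Sref))
    },
    odor = function(state, bodies, solver) {
      fl <- odor_flux(state, probes, grid, odor, U_scale = U_ref)
      c(flux = fl$antenna)
    },
    vortex = function(state, bodies, solver) {
      g_av <- circulation(state, grid, av_win)
      g_lev <- 0
      if (length(bodies) >= 2) {
        w <- bodies[[2]]
        ch <- c(cos(w$angle), sin(w$angle))
        le <- w$center - w$hx * ch * sign(sum(an$s_hat * ch))
        lev_win <- c(le[1] - 0.22, le[1] + 0.22, le[2] - 0.22, le[2] + 0.22)
        g_lev <- circulation(state, grid, lev_win)
      }
      c(G_AV = as.numeric(g_av), G_LEV = as.numeric(g_lev))
    }
  )
  state <- flow_state(grid, u = 1)
  part_trace <- NULL
  if (!is.null(particles)) {
    penv <- new.env()
    penv$p <- particles
    observers$particles <- function(state, bodies, solver) {
      penv$p <- advect_particles(penv$p, state, grid,
                                 dt * observe_every, bodies)
      c(n_active = sum(penv$p$active))
    }
  }
  res <- run_cycles(solver, state, an$pose_bodies, T_cycle, n_cycles,
                    observers = observers, observe_every = observe_every)
  if (!is.null(particles)) res$particles <- get("p", envir = penv)
  ser <- res$series
  last <- ser[ser$cycle == n_cycles, , drop = FALSE]
  summary <- data.frame(
    k = k,
    C_L_bar = mean(last$aero.C_L),
    C_T_bar = mean(last$aero.C_T),
    C_F_bar = mean(sqrt(last$aero.C_L^2 + last$aero.C_T^2)),
    C_PW_bar = mean(last$aero.C_PW),
    CF_over_CPW = NA_real_,
    peak_flux = max(last$odor.flux),
    mean_flux = mean(last$odor.flux),
    G_AV = mean(abs(last$vortex.G_AV)),
    G_LEV = mean(abs(last$vortex.G_LEV)),
    peak_flux_phase = (last$t[which.max(last$odor.flux)] %% T_cycle) / T_cycle,
    periodicity = res$periodicity,
    n_cycles = n_cycles,
    nx = grid$axes[[1]]$n, ny = grid$axes[[2]]$n,
    scale = "desk",
    stringsAsFactors = FALSE
  )
  summary$CF_over_CPW <- if (summary$C_PW_bar > 0) {
    summary$C_F_bar / summary$C_PW_bar
  } else NA_real_
  list(summary = summary, series = ser, state = res$state, analog = an,
       grid = grid, periodicity = res$periodicity)
}

#' Reduced-frequency sweep
#'
#' Runs one case per reduced frequency (same inflow, different flapping
#' frequency) and collects the cycle-averaged aerodynamic coefficients
#' and antenna odor-mass-flux statistics into a sweep table, one row per
#' k, sorted by k.  Per-run failures are collected and reported without
#' aborting the sweep.
#'
#' At `scale = "paper"` the driver does not step the flow: it assembles
#' and returns the full-scale 3D run plan (production grid, 3D geometry
#' and kinematics) tagged `cluster_scale`, because those runs need of
#' order 1e7 grid points times thousands of steps.
#'
#' @param ks reduced frequencies; include 0 for the body-only baseline.
#' @param planform wing planform.
#' @param scale `"desk"` (2D analog, runs here) or `"paper"` (3D plan).
#' @param ... passed to [run_flapping_case()].
#' @return list with `table` (data frame), `runs` (per-k results),
#'   `failures` (named list of error messages).
#' @export
frequency_sweep <- function(ks = c(0.33, 0.65, 1.30),
                            planform = wing_planform(),
                            scale = c("desk", "paper"), ...) {
  scale <- match.arg(scale)
  stopifnot(all(ks >= 0))
  ks <- sort(ks)
  if (scale == "paper") {
    return(paper_scale_plan(ks, planform))
  }
  runs <- list(); failures <- list()
  for (k in ks) {
    res <- tryCatch(run_flapping_case(k, planform = planform, ...),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[[as.character(k)]] <- conditionMessage(res)
    } else {
      runs[[as.character(k)]] <- res
    }
  }
  tab <- do.call(rbind, lapply(runs, `[[`, "summary"))
  rownames(tab) <- NULL
  list(table = tab, runs = runs, failures = failures)
}

paper_scale_plan <- function(ks, planform) {
  grid <- paper_scale_grid()
  fly <- make_fly_geometry(planform)
  kins <- lapply(ks[ks > 0], function(k) {
    wing_kinematics(f = k * 0.94 / 2.87e-3)   # f from k at U=0.94 m/s, R=2.87 mm
  })
  structure(list(scale = "paper", cluster_scale = TRUE, grid = grid,
                 geometry = fly, ks = ks, kinematics = kins,
                 n_cycles = 8,
                 note = paste("full-scale 3D preset: ~1e7-point grid, 8 cycles;",
                              "solve this on a cluster, not at desk scale")),
            class = "paper_scale_plan")
}

#' @export
print.paper_scale_plan <- function(x, ...) {
  cat("<paper_scale_plan> cluster-scale 3D sweep preset\n")
  print(x$grid)
  cat("k values:", paste(x$ks, collapse = ", "), "; cycles:", x$n_cycles, "\n")
  invisible(x)
}

#' Hovering flat-plate validation case
#'
#' A 2D analog of the classic dynamically-scaled hovering experiment:
#' the plate sweeps along a horizontal stroke plane with a 180-degree
#' stroke amplitude, holds a 50-degree angle of attack at midstroke on
#' both half-strokes, and runs at Re = 136 in quiescent fluid.  Desk
#' scale checks the qualitative signature (positive cycle-mean lift,
#' bounded periodic coefficient traces).
#'
#' @param n_cycles flapping cycles.
#' @param delta refined cell size, units of span.
#' @param chord plate chord, units of span.
#' @param r_arm span station driving the plate (0.7).
#' @return list with `series` (t, cycle, C_L, C_D), `state`, `grid`.
#' @export
sane_dickinson_case <- function(n_cycles = 2, delta = 0.05, chord = 0.3,
                                r_arm = 0.7) {
  kin <- wing_kinematics(Phi = 180, f = 1, alpha_up = -130, alpha_down = -50,
                         reversal_fraction = 0.22, beta = 0, chi = 0)
  smax <- r_arm * pi / 2
  box <- list(c(-smax - chord, smax + chord), c(-0.5, 0.5))
  grid <- build_grid(list(c(-4.5, 4.5), c(-2.5, 2.5)), box, delta)
  vmax <- r_arm * 0.5 * pi * 2 * pi
  dt <- suggest_dt(grid, vmax, 0.4)
  steps <- round(1 / dt); dt <- 1 / steps
  solver <- build_solver(grid, solver_settings(Re = 136, dt = dt, U_inf = 0, upwind = 0.2))
  U_tip <- mean_tip_speed(kin, 1)
  pose <- function(t) {
    ang <- wing_angles(t, kin)
    phi_r <- ang$phi * pi / 180
    dphidt <- -0.5 * pi * 2 * pi * sin(2 * pi * t)
    eps <- 1e-4
    da <- (wing_angles(t + eps, kin)$alpha -
             wing_angles(max(t - eps, 0), kin)$alpha) * pi / 180
    omega <- da / (eps + min(eps, t))
    list(plate_shape(chord, 0.06,
                     center = c(r_arm * phi_r, 0),
                     angle = ang$alpha * pi / 180,
                     vel = c(r_arm * dphidt, 0), omega = omega))
  }
  obs <- list(aero = function(state, bodies, solver) {
    f <- surface_forces(state, bodies[[1]], solver)
    c(C_L = f$F_L / (0.5 * U_tip^2 * chord),
      C_D = f$F[1] / (0.5 * U_tip^2 * chord))
  })
  res <- run_cycles(solver, flow_state(grid, u = 0), pose, 1, n_cycles,
                    observers = obs, observe_every = 2L)
  ser <- res$series
  names(ser) <- sub("^aero\\.", "", names(ser))
  list(series = ser, state = res$state, grid = grid,
       periodicity = res$periodicity)
}

#' Trailing-edge clipping comparison
#'
#' Runs paired cases (original vs trailing-edge-clipped wing) at each
#' reduced frequency, holding every other setting fixed, and reports the
#' percent change of the cycle-averaged lift coefficient, force-to-power
#' ratio, peak antenna odor flux and the antenna/leading-edge vortex
#' circulations.
#'
#' @param ks reduced frequencies (> 0).
#' @param planform original planform.
#' @param remove_fraction trailing-edge area fraction to clip (~0.2).
#' @param ... passed to [run_flapping_case()].
#' @return list with `original`, `modified` (sweep results) and `deltas`
#'   (one row per k, percent changes).
#' @export
wing_clip_comparison <- function(ks = 0.65, planform = wing_planform(),
                                 remove_fraction = 0.193, ...) {
  stopifnot(all(ks > 0))
  clipped <- clip_trailing_edge(planform, default_clip_line(planform, remove_fraction))
  orig <- frequency_sweep(ks, planform = planform, ...)
  mod <- frequency_sweep(ks, planform = clipped, ...)
  fails <- c(orig$failures, mod$failures)
  if (length(fails)) {
    stop("clip comparison aborted; failed runs: ",
         paste(sprintf("k=%s (%s)", names(fails), unlist(fails)), collapse = "; "))
  }
  pct <- function(a, b) 100 * (b - a) / abs(a)
  to <- orig$table; tm <- mod$table
  stopifnot(nrow(to) == nrow(tm))
  deltas <- data.frame(
    k = to$k,
    dC_L_pct = pct(to$C_L_bar, tm$C_L_bar),
    dCF_over_CPW_pct = pct(to$CF_over_CPW, tm$CF_over_CPW),
    dpeak_flux_pct = pct(to$peak_flux, tm$peak_flux),
    dG_AV_pct = pct(to$G_AV, tm$G_AV),
    dG_LEV_pct = pct(to$G_LEV, tm$G_LEV)
  )
  list(original = orig, modified = mod, deltas = deltas,
       planform_original = planform, planform_modified = clipped)
}
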