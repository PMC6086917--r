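#' Odor-transport configuration
#'
#' Convection-dominated odor transport: a normalized uniform odorant of
#' concentration `C' = 1` enters at the upstream inlet and molecular
#' diffusion is neglected (Peclet number of order 1e2-1e3 for natural
#' odors), so the concentration field stays at its inlet value and odor
#' motion is carried entirely by the air.  Plumes are visualized with
#' Lagrangian tracer particles and sensed with velocity probes placed a
#' fixed offset of 0.03R above surface landmarks.
#'
#' @param C_in normalized inlet concentration (1 by default).
#' @param rho_odor odor density, kg/m^3 (equal to air, 1.225, since the
#'   particle/air density ratio is 1).
#' @param diffusion logical; when TRUE the Eulerian scalar mode adds an
#'   explicit diffusion term with coefficient 1/Pe.
#' @param D diffusivity, cm^2/s (only used when `diffusion` is TRUE).
#' @export
odor_config <- function(C_in = 1, rho_odor = 1.225, diffusion = FALSE,
                        D = 0.1) {
  stopifnot(C_in > 0, rho_odor > 0, D > 0)
  list(C_in = C_in, rho_odor = rho_odor, diffusion = diffusion, D = D)
}

#' Lagrangian tracer particle set
#'
#' @param positions n x 2 matrix of particle positions (units of R).
#' @param origin integer or character tag per particle identifying the
#'   release location (used to color plumes by origin).
#' @param release_time release time per particle.
#' @return object of class `particle_set`; `active` flags particles still
#'   inside the domain.
#' @export
particle_set <- function(positions, origin = 1L,
                         release_time = 0) {
  positions <- matrix(positions, ncol = 2)
  n <- nrow(positions)
  structure(list(positions = positions,
                 origin = rep_len(origin, n),
                 release_time = rep_len(release_time, n),
                 active = rep(TRUE, n)),
            class = "particle_set")
}

#' Seed particles on upstream release lines
#'
#' Emulates the plume-visualization releases: horizontal lines upstream
#' of the body at a set of vertical offsets, one origin tag per offset
#' band, so vertical versus lateral sampling can be compared.
#' @param x_release upstream x station (units of R).
#' @param y_offsets vertical offsets of the release lines.
#' @param n_per_line particles per line.
#' @param spread half-width of each line along y.
#' @export
release_lines <- function(x_release = -3, y_offsets = c(0.3, 0, -0.3, -0.6, -0.9),
                          n_per_line = 40, spread = 0.05) {
  pos <- list(); org <- list()
  for (i in seq_along(y_offsets)) {
    y <- y_offsets[i] + seq(-spread, spread, length.out = n_per_line)
    pos[[i]] <- cbind(x_release, y)
    org[[i]] <- rep(i, n_per_line)
  }
  particle_set(do.call(rbind, pos), origin = unlist(org))
}

#' Advect tracer particles through a flow field
#'
#' Second-order midpoint (RK2) integration with bilinear interpolation of
#' the velocity in space; when two flow snapshots bracketing the step are
#' given the velocity is also interpolated linearly in time.  Particles
#' that leave the domain are deactivated; particles that land inside a
#' body are projected back to its surface and counted.
#'
#' @param particles a [particle_set()].
#' @param flow either a `flow_state` (frozen-field advection over the
#'   step) or a list of two states `list(a, b)` with `a$t <= t < b$t`.
#' @param grid the flow grid.
#' @param dt tracer time step (nondimensional).
#' @param bodies optional list of [shape2d] objects for collision
#'   projection.
#' @return the advanced `particle_set`; attribute `"n_projected"` counts
#'   surface projections this step.
#' @export
advect_particles <- function(particles, flow, grid, dt, bodies = list()) {
  act <- particles$active
  if (!any(act)) return(particles)
  p <- particles$positions[act, , drop = FALSE]
  vel_at <- function(x, y, tq) {
    if (inherits(flow, "flow_state")) {
      f <- interp_field(list(u = flow$u, v = flow$v), grid, x, y)
      cbind(f$u, f$v)
    } else {
      a <- flow[[1]]; b <- flow[[2]]
      w <- if (b$t > a$t) (tq - a$t) / (b$t - a$t) else 0
      w <- min(max(w, 0), 1)
      fa <- interp_field(list(u = a$u, v = a$v), grid, x, y)
      fb <- interp_field(list(u = b$u, v = b$v), grid, x, y)
      cbind((1 - w) * fa$u + w * fb$u, (1 - w) * fa$v + w * fb$v)
    }
  }
  t0 <- if (inherits(flow, "flow_state")) flow$t else flow[[1]]$t
  v1 <- vel_at(p[, 1], p[, 2], t0)
  mid <- p + 0.5 * dt * v1
  v2 <- vel_at(mid[, 1], mid[, 2], t0 + 0.5 * dt)
  pnew <- p + dt * v2
  n_proj <- 0L
  for (b in bodies) {
    d <- shape_sdf(b, pnew[, 1], pnew[, 2])
    inside <- d < 0
    if (any(inside)) {
      n_proj <- n_proj + sum(inside)
      nrm <- shape_normal(b, pnew[inside, 1], pnew[inside, 2])
      pnew[inside, ] <- pnew[inside, , drop = FALSE] -
        (d[inside] - 1e-6) * nrm
    }
  }
  xr <- grid$domain[[1]]; yr <- grid$domain[[2]]
  out <- pnew[, 1] < xr[1] | pnew[, 1] > xr[2] |
    pnew[, 2] < yr[1] | pnew[, 2] > yr[2]
  particles$positions[act, ] <- pnew
  keep <- particles$active
  keep[which(act)[out]] <- FALSE
  particles$active <- keep
  attr(particles, "n_projected") <- n_proj
  particles
}

#' Odor probes at fixed offsets above surface landmarks
#'
#' Builds the antenna probe triplet -- three points `offset` above the
#' antenna landmark along its outward normal, spaced one refined cell
#' apart along the body-axis tangent -- plus optional extra body-site
#' probes.
#'
#' @param landmark antenna landmark point (length 2).
#' @param normal outward surface normal at the landmark.
#' @param grid the flow grid (supplies the refined cell size).
#' @param offset probe offset above the surface, units of R (0.03R).
#' @param body_sites optional matrix of extra probe points (already
#'   offset), one row per site.
#' @param bodies optional shapes; probes inside a body are a
#'   configuration error.
#' @return object of class `odor_probes`.
#' @export
odor_probes <- function(landmark, normal, grid, offset = 0.03,
                        body_sites = NULL, bodies = list()) {
  normal <- normal / sqrt(sum(normal^2))
  tang <- c(-normal[2], normal[1])
  base <- landmark + offset * normal
  ant <- rbind(base - grid$delta * tang, base, base + grid$delta * tang)
  pts <- rbind(ant, body_sites)
  for (b in bodies) {
    if (any(shape_sdf(b, pts[, 1], pts[, 2]) < 0)) {
      stop("configuration error: odor probe lies inside a body")
    }
  }
  structure(list(antenna = ant, body_sites = body_sites, offset = offset),
            class = "odor_probes")
}

#' Sample the odor mass flux at the probes
#'
#' Flux per probe is `C' * rho_odor * |U*|` with `U*` the local air
#' velocity; with pure convection of a uniform inlet odor the
#' concentration is identically `C' = C_in`.  The antenna value is the
#' mean of its three probes.  Output units are kg s^-1 m^-2 when the
#' dimensional scales are supplied.
#'
#' @param state a [flow_state()].
#' @param probes an [odor_probes()] object.
#' @param grid the flow grid.
#' @param odor an [odor_config()].
#' @param U_scale dimensional velocity scale (m/s) multiplying the
#'   nondimensional `|U*|`; use 1 to stay nondimensional.
#' @param C_field optional Eulerian concentration field (matrix) to use
#'   instead of the uniform `C_in`.
#' @return named list: `antenna` (3-probe average flux), `antenna_each`,
#'   `body` (vector over body sites or NULL), `U_star` magnitudes.
#' @export
odor_flux <- function(state, probes, grid, odor = odor_config(),
                      U_scale = 1, C_field = NULL) {
  pts <- rbind(probes$antenna, probes$body_sites)
  f <- interp_field(list(u = state$u, v = state$v), grid, pts[, 1], pts[, 2])
  Umag <- sqrt(f$u^2 + f$v^2)
  Cp <- if (is.null(C_field)) rep(odor$C_in, nrow(pts)) else {
    interp_field(C_field, grid, pts[, 1], pts[, 2])
  }
  flux <- Cp * odor$rho_odor * Umag * U_scale
  n_ant <- nrow(probes$antenna)
  list(antenna = mean(flux[seq_len(n_ant)]),
       antenna_each = flux[seq_len(n_ant)],
       body = if (is.null(probes$body_sites)) NULL else flux[-seq_len(n_ant)],
       U_star = Umag)
}

#' Eulerian advection of the concentration field (optional mode)
#'
#' First-order conservative upwind advection of `C'` on the solver grid,
#' with the inlet held at `C_in` and zero-gradient elsewhere; an explicit
#' diffusion term with coefficient `1/Pe` is added when diffusion is
#' enabled.  The scheme is monotone at advective CFL <= 1 (no new
#' extrema) and translates a profile exactly one cell per step at
#' CFL = 1 on a uniform grid.
#'
#' @param C matrix `nx x ny`, current concentration.
#' @param state a [flow_state()] supplying the velocity.
#' @param grid the flow grid.
#' @param dt time step; rejected (error) if the advective CFL exceeds 1.
#' @param odor an [odor_config()]; Pe is formed from the solver Re times
#'   Sc when diffusion is on.
#' @param Pe Peclet number for the diffusive term.
#' @export
advect_scalar <- function(C, state, grid, dt, odor = odor_config(), Pe = 270) {
  ax <- grid$axes[[1]]; ay <- grid$axes[[2]]
  nx <- ax$n; ny <- ay$n
  u <- state$u; v <- state$v
  cfl <- max(abs(u) / min(ax$dx), abs(v) / min(ay$dx)) * dt
  if (cfl > 1 + 1e-12) {
    stop(sprintf("CFL violation in scalar advection (CFL=%.3f): step rejected", cfl))
  }
  # upwind face fluxes in x
  uf <- matrix(0, nx + 1L, ny)
  uf[2:nx, ] <- 0.5 * (u[-nx, , drop = FALSE] + u[-1, , drop = FALSE])
  uf[1, ] <- u[1, ]; uf[nx + 1L, ] <- u[nx, ]
  Cx <- rbind(rep(odor$C_in, ny), C, C[nx, ])        # inlet ghost holds C_in
  Fx <- ifelse(uf >= 0, Cx[1:(nx + 1L), , drop = FALSE],
               Cx[2:(nx + 2L), , drop = FALSE]) * uf
  vf <- matrix(0, nx, ny + 1L)
  vf[, 2:ny] <- 0.5 * (v[, -ny, drop = FALSE] + v[, -1, drop = FALSE])
  vf[, 1] <- v[, 1]; vf[, ny + 1L] <- v[, ny]
  Cy <- cbind(C[, 1], C, C[, ny])
  Fy <- ifelse(vf >= 0, Cy[, 1:(ny + 1L), drop = FALSE],
               Cy[, 2:(ny + 2L), drop = FALSE]) * vf
  adv <- (Fx[-1, , drop = FALSE] - Fx[-(nx + 1L), , drop = FALSE]) / ax$dx +
    t((t(Fy[, -1, drop = FALSE]) - t(Fy[, -(ny + 1L), drop = FALSE])) / ay$dx)
  # compensate for flow divergence (discretely small): advective form
  divu <- (uf[-1, , drop = FALSE] - uf[-(nx + 1L), , drop = FALSE]) / ax$dx +
    t((t(vf[, -1, drop = FALSE]) - t(vf[, -(ny + 1L), drop = FALSE])) / ay$dx)
  Cn <- C - dt * (adv - C * divu)
  if (odor$diffusion) {
    Cp <- matrix(0, nx + 2L, ny + 2L)
    Cp[2:(nx + 1L), 2:(ny + 1L)] <- C
    Cp[1, 2:(ny + 1L)] <- 2 * odor$C_in - C[1, ]
    Cp[nx + 2L, 2:(ny + 1L)] <- C[nx, ]
    Cp[, 1] <- Cp[, 2]; Cp[, ny + 2L] <- Cp[, ny + 1L]
    d2 <- (Cp[1:nx, 2:(ny + 1L)] - 2 * C + Cp[3:(nx + 2L), 2:(ny + 1L)]) /
      mean(ax$dx)^2 +
      (Cp[2:(nx + 1L), 1:ny] - 2 * C + Cp[2:(nx + 1L), 3:(ny + 2L)]) /
      mean(ay$dx)^2
    Cn <- Cn + dt * d2 / Pe
  }
  Cn
}
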