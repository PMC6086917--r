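#' Surface-integrated aerodynamic force on an immersed body
#'
#' Integrates pressure and viscous shear traction over the sampled body
#' boundary.  Pressure is interpolated a short distance off the surface
#' along the outward normal (inside the body the fields are fictitious);
#' the wall shear is obtained from a second-order one-sided normal
#' derivative of the tangential velocity built from the no-slip surface
#' value and two off-surface samples.
#'
#' Conventions: the freestream blows along +x, the insect faces upstream,
#' so lift is `F_y` and thrust (the force pushing the flier upstream) is
#' `-F_x`.  Forces are nondimensional per unit span (2D).
#'
#' @param state a [flow_state()].
#' @param body a [shape2d] posed at the state's time level.
#' @param solver the [build_solver()] object (supplies grid and Re).
#' @param n_boundary number of boundary samples.
#' @param eps_factor off-surface sampling distance in refined-cell units.
#' @return list with `F` (`c(Fx, Fy)`), `F_L` (lift), `F_T` (thrust),
#'   and `per_face`: a data frame of per-element positions, areas and
#'   force contributions whose columns sum to the totals exactly.
#' @export
surface_forces <- function(state, body, solver, n_boundary = 240,
                           eps_factor = 1.5) {
  g <- solver$grid
  if (!body_in_box(body, g)) {
    warning("body extends outside the refined grid box; force accuracy degraded")
  }
  bnd <- shape_boundary(body, n_boundary)
  tr <- surface_traction(state, bnd, solver, eps_factor)
  dFx <- tr[, 1] * bnd$ds
  dFy <- tr[, 2] * bnd$ds
  Fx <- sum(dFx); Fy <- sum(dFy)
  list(F = c(Fx, Fy), F_L = Fy, F_T = -Fx,
       per_face = data.frame(x = bnd$points[, 1], y = bnd$points[, 2],
                             ds = bnd$ds, dFx = dFx, dFy = dFy,
                             lift = dFy))
}

# traction exerted by the fluid on the body at the boundary samples
surface_traction <- function(state, bnd, solver, eps_factor = 1.5) {
  g <- solver$grid
  eps <- eps_factor * g$delta
  pts <- bnd$points; nrm <- bnd$normals
  x1 <- pts[, 1] + eps * nrm[, 1]; y1 <- pts[, 2] + eps * nrm[, 2]
  x2 <- pts[, 1] + 2 * eps * nrm[, 1]; y2 <- pts[, 2] + 2 * eps * nrm[, 2]
  f1 <- interp_field(list(u = state$u, v = state$v, p = state$p), g, x1, y1)
  f2 <- interp_field(list(u = state$u, v = state$v), g, x2, y2)
  tx <- -nrm[, 2]; ty <- nrm[, 1]                 # unit tangent
  utb <- bnd$velocity[, 1] * tx + bnd$velocity[, 2] * ty
  ut1 <- f1$u * tx + f1$v * ty
  ut2 <- f2$u * tx + f2$v * ty
  dutdn <- (-3 * utb + 4 * ut1 - ut2) / (2 * eps)
  tau <- dutdn / solver$settings$Re
  cbind(-f1$p * nrm[, 1] + tau * tx,
        -f1$p * nrm[, 2] + tau * ty)
}

body_in_box <- function(body, grid) {
  b <- shape_boundary(body, 32)
  bx <- grid$box[[1]]; by <- grid$box[[2]]
  all(b$points[, 1] >= bx[1], b$points[, 1] <= bx[2],
      b$points[, 2] >= by[1], b$points[, 2] <= by[2])
}

#' Aerodynamic power of a moving body
#'
#' Rate of work the body does on the fluid,
#' `P = -sum(traction . u_surface) ds` with `traction` the fluid-on-body
#' traction: positive when the wing flaps against air resistance, zero
#' for a stationary body.
#' @inheritParams surface_forces
#' @export
aero_power <- function(state, body, solver, n_boundary = 240,
                       eps_factor = 1.5) {
  bnd <- shape_boundary(body, n_boundary)
  tr <- surface_traction(state, bnd, solver, eps_factor)
  -sum((tr[, 1] * bnd$velocity[, 1] + tr[, 2] * bnd$velocity[, 2]) * bnd$ds)
}

#' Force and power coefficients
#'
#' The standard flapping-flight normalization: forces by
#' `0.5 rho U_tip^2 S` and power by `0.5 rho U_tip^3 S`, with `U_tip` the
#' cycle-mean wing-tip speed and `S` the wing area.  The total-force
#' coefficient uses `U_total`, which defaults to `U_tip` so that `C_F` is
#' normalized consistently with `C_L` and `C_T`.
#'
#' @param F_L,F_T lift and thrust (same units as the normalization).
#' @param P_aero aerodynamic power.
#' @param U_tip mean wing-tip speed.
#' @param S wing reference area (per unit span chord in 2D).
#' @param rho fluid density (1 in nondimensional form).
#' @param U_total speed used in the `C_F` denominator.
#' @return list `C_L`, `C_T`, `C_F`, `C_PW`, `C_F_over_C_PW`.
#' @export
coefficients <- function(F_L, F_T, P_aero, U_tip, S, rho = 1,
                         U_total = U_tip) {
  if (U_tip <= 0 || S <= 0 || rho <= 0 || U_total <= 0) {
    stop("argument error: coefficient denominators must be positive")
  }
  q <- 0.5 * rho * U_tip^2 * S
  C_L <- F_L / q
  C_T <- F_T / q
  C_F <- sqrt(F_L^2 + F_T^2) / (0.5 * rho * U_total^2 * S)
  C_PW <- P_aero / (0.5 * rho * U_tip^3 * S)
  list(C_L = C_L, C_T = C_T, C_F = C_F, C_PW = C_PW,
       C_F_over_C_PW = if (C_PW != 0) C_F / C_PW else NA_real_)
}
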