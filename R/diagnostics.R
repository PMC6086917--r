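#' Vorticity of a 2D flow state
#'
#' `omega_z = dv/dx - du/dy` by second-order central differences on the
#' (possibly nonuniform) cell centers.
#' @param state a [flow_state()].
#' @param grid the flow grid.
#' @return matrix `nx x ny`.
#' @export
vorticity_field <- function(state, grid) {
  grid_deriv(state$v, grid, 1L) - grid_deriv(state$u, grid, 2L)
}

#' Q-criterion vortex-identification field
#'
#' `Q = (||Omega||^2 - ||S||^2) / 2` from the velocity-gradient
#' decomposition into rotation-rate and strain-rate tensors: positive
#' where rotation dominates strain (vortex cores), negative in
#' shear-dominated regions, zero in uniform flow.
#' @param state a [flow_state()].
#' @param grid the flow grid.
#' @return matrix `nx x ny`.
#' @export
q_criterion <- function(state, grid) {
  ux <- grid_deriv(state$u, grid, 1L); uy <- grid_deriv(state$u, grid, 2L)
  vx <- grid_deriv(state$v, grid, 1L); vy <- grid_deriv(state$v, grid, 2L)
  S2 <- ux^2 + vy^2 + 0.5 * (uy + vx)^2
  O2 <- 0.5 * (uy - vx)^2
  0.5 * (O2 - S2)
}

#' Circulation of a vortex patch
#'
#' Integrates the normal vorticity over a sign-selected patch inside a
#' rectangular window: cells whose vorticity has the requested sign and
#' magnitude at least `threshold` times the window maximum belong to the
#' patch.  This is the working definition used for the antenna vortex
#' (window near the head) and the leading-edge vortex (window over the
#' wing's leading edge).
#'
#' @param state a [flow_state()].
#' @param grid the flow grid.
#' @param window list or vector `c(x0, x1, y0, y1)` bounding the patch
#'   search region.
#' @param sign_select `+1`, `-1`, or `0` to take the dominant sign in the
#'   window.
#' @param threshold patch-membership threshold as a fraction of the
#'   window's peak |vorticity|.
#' @return circulation `Gamma` (signed, nondimensional); attribute
#'   `"n_cells"` gives the patch size.  An empty patch returns 0 with a
#'   warning.
#' @export
circulation <- function(state, grid, window, sign_select = 0,
                        threshold = 0.10) {
  w <- unlist(window)
  om <- vorticity_field(state, grid)
  xc <- grid$axes[[1]]$xc; yc <- grid$axes[[2]]$xc
  ix <- which(xc >= w[1] & xc <= w[2])
  iy <- which(yc >= w[3] & yc <= w[4])
  if (!length(ix) || !length(iy)) {
    warning("circulation window does not intersect the grid; Gamma = 0")
    return(structure(0, n_cells = 0L))
  }
  sub <- om[ix, iy, drop = FALSE]
  peak <- max(abs(sub))
  if (peak == 0) {
    warning("empty vortex patch (zero vorticity); Gamma = 0")
    return(structure(0, n_cells = 0L))
  }
  if (sign_select == 0) {
    sign_select <- sign(sub[which.max(abs(sub))])
  }
  sel <- (sign_select * sub > 0) & (abs(sub) >= threshold * peak)
  if (!any(sel)) {
    warning("empty vortex patch after thresholding; Gamma = 0")
    return(structure(0, n_cells = 0L))
  }
  area <- outer(grid$axes[[1]]$dx[ix], grid$axes[[2]]$dx[iy])
  structure(sum(sub[sel] * area[sel]), n_cells = sum(sel))
}

#' Circulation by boundary line integral (Stokes-theorem check)
#'
#' Counter-clockwise line integral of the velocity around the rectangle
#' `window`, which by Stokes' theorem equals the total vorticity flux
#' through it.  Used as an independent cross-check of [circulation()]
#' when the window captures the whole vortex.
#' @inheritParams circulation
#' @param n_samples samples per rectangle side.
#' @export
circulation_line_integral <- function(state, grid, window, n_samples = 200) {
  w <- unlist(window)
  seg <- function(x0, y0, x1, y1) {
    s <- seq(0, 1, length.out = n_samples)
    xs <- x0 + s * (x1 - x0); ys <- y0 + s * (y1 - y0)
    f <- interp_field(list(u = state$u, v = state$v), grid, xs, ys)
    dl <- c(x1 - x0, y1 - y0) / (n_samples - 1)
    # trapezoid weights
    wt <- rep(1, n_samples); wt[c(1, n_samples)] <- 0.5
    sum((f$u * dl[1] + f$v * dl[2]) * wt)
  }
  seg(w[1], w[3], w[2], w[3]) + seg(w[2], w[3], w[2], w[4]) +
    seg(w[2], w[4], w[1], w[4]) + seg(w[1], w[4], w[1], w[3])
}

#' Closed-form Lamb-Oseen vortex velocity field
#'
#' Reference field for circulation oracles: azimuthal speed
#' `Gamma0 / (2 pi r) * (1 - exp(-r^2 / rc^2))` about `center`.
#' @param grid the flow grid.
#' @param Gamma0 total circulation.
#' @param rc core radius.
#' @param center vortex center.
#' @return a [flow_state()] holding the analytic field.
#' @export
lamb_oseen_state <- function(grid, Gamma0 = 1, rc = 0.1, center = c(0, 0)) {
  nx <- grid$axes[[1]]$n; ny <- grid$axes[[2]]$n
  X <- matrix(grid$axes[[1]]$xc, nx, ny) - center[1]
  Y <- matrix(grid$axes[[2]]$xc, nx, ny, byrow = TRUE) - center[2]
  r2 <- X^2 + Y^2
  fac <- Gamma0 / (2 * pi) * (1 - exp(-r2 / rc^2)) / pmax(r2, 1e-300)
  flow_state(grid, u = -fac * Y, v = fac * X, p = 0)
}
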