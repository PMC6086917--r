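#' Solver settings
#'
#' Numerical controls of the fractional-step scheme: explicit second-order
#' Adams-Bashforth convection, implicit Crank-Nicolson diffusion (an
#' explicit-diffusion mode is available for verification), a direct sparse
#' pressure-Poisson solve, and a ghost-cell immersed boundary for rigid
#' moving bodies.  All quantities are nondimensional: lengths by the wing
#' span R, velocities by the freestream speed, time by R/freestream.
#'
#' @param Re Reynolds number.
#' @param dt time step (nondimensional); choose with [suggest_dt()].
#' @param U_inf nondimensional inflow speed (1 for the standard scaling;
#'   0 for a quiescent box).
#' @param bc `"windtunnel"` (inflow left, zero-gradient outflow right,
#'   zero-stress lateral walls, homogeneous-Neumann pressure everywhere)
#'   or `"periodic"`.
#' @param diffusion `"cn"` (Crank-Nicolson) or `"explicit"`.
#' @param cfl advective CFL bound used by [suggest_dt()].
#' @param poisson_tol acceptance residual for the projection (the direct
#'   solve normally lands far below it; exceeding it raises an error).
#' @param upwind fraction (0..1) of first-order upwind convection blended
#'   into the skew-symmetric central scheme.  Zero (the default) keeps the
#'   pure second-order central discretization used for verification;
#'   bluff-body flapping runs at desk resolution use a small positive
#'   value (0.2) to keep the high cell-Reynolds wake stable.
#' @export
solver_settings <- function(Re, dt, U_inf = 1, bc = c("windtunnel", "periodic"),
                            diffusion = c("cn", "explicit"), cfl = 0.5,
                            poisson_tol = 1e-8, upwind = 0) {
  bc <- match.arg(bc)
  diffusion <- match.arg(diffusion)
  stopifnot(Re > 0, dt > 0, poisson_tol > 0, upwind >= 0, upwind <= 1)
  list(Re = Re, dt = dt, U_inf = U_inf, bc = bc, diffusion = diffusion,
       cfl = cfl, poisson_tol = poisson_tol, upwind = upwind)
}

#' Advective-CFL time step
#' @param grid a 2D [build_grid()] grid.
#' @param max_speed estimated peak speed (body + freestream).
#' @param cfl CFL number (default 0.5 per the advective bound).
#' @export
suggest_dt <- function(grid, max_speed, cfl = 0.5) {
  cfl * grid$delta / max_speed
}

#' Flow state on a 2D grid
#'
#' Collocated cell-center velocity and pressure at one time level.
#' @param grid a 2D [build_grid()] grid.
#' @param u,v,p initial fields: scalars or `nx x ny` matrices.
#' @param t initial time.
#' @export
flow_state <- function(grid, u = 1, v = 0, p = 0, t = 0) {
  stopifnot(grid$dim == 2L)
  nx <- grid$axes[[1]]$n; ny <- grid$axes[[2]]$n
  mk <- function(f) if (is.matrix(f)) f else matrix(f, nx, ny)
  structure(list(u = mk(u), v = mk(v), p = mk(p), t = t,
                 conv_u = NULL, conv_v = NULL,
                 classification = matrix("fluid", nx, ny),
                 divergence = 0, fresh_cells = 0L),
            class = "flow_state")
}

#' @export
print.flow_state <- function(x, ...) {
  cat(sprintf("<flow_state> %dx%d cells, t=%.4g, max|u|=%.3g, div=%.2e\n",
              nrow(x$u), ncol(x$u), x$t, max(abs(x$u), abs(x$v)), x$divergence))
  invisible(x)
}

# --- sparse operator assembly ------------------------------------------------

# finite-volume Laplacian rows for a 2D tensor grid with per-side BCs.
# bc sides: list(left=, right=, bottom=, top=) each "dirichlet" (with value),
# "neumann" (zero-gradient) or "periodic".  Returns volume-scaled operator
# M (d2/dx2 + d2/dy2 approximation) and the constant vector from Dirichlet
# ghost elimination, so  L(f) = M f + const.
assemble_laplacian <- function(grid, bc) {
  ax <- grid$axes[[1]]; ay <- grid$axes[[2]]
  nx <- ax$n; ny <- ay$n
  N <- nx * ny
  idx <- function(i, j) i + (j - 1L) * nx
  ii <- jj <- vv <- list(); cc <- numeric(N)
  add <- function(r, c, v) { ii[[length(ii) + 1L]] <<- r; jj[[length(jj) + 1L]] <<- c; vv[[length(vv) + 1L]] <<- v }
  # x-direction coupling for all cells, vectorized per column offset
  i <- rep(seq_len(nx), ny); j <- rep(seq_len(ny), each = nx)
  # center distances incl. boundary-face distance (mirror ghost => dx)
  hxm <- c(ax$dx[1], ax$xc[-1] - ax$xc[-nx])[i]   # to left neighbor
  hxp <- c(ax$xc[-1] - ax$xc[-nx], ax$dx[nx])[i]  # to right neighbor
  hym <- c(ay$dx[1], ay$xc[-1] - ay$xc[-ny])[j]
  hyp <- c(ay$xc[-1] - ay$xc[-ny], ay$dx[ny])[j]
  if (bc$left$type == "periodic") {
    hxm[i == 1L] <- (ax$dx[1] + ax$dx[nx]) / 2
    hxp[i == nx] <- (ax$dx[1] + ax$dx[nx]) / 2
  }
  if (bc$bottom$type == "periodic") {
    hym[j == 1L] <- (ay$dx[1] + ay$dx[ny]) / 2
    hyp[j == ny] <- (ay$dx[1] + ay$dx[ny]) / 2
  }
  aW <- 1 / (hxm * ax$dx[i]); aE <- 1 / (hxp * ax$dx[i])
  aS <- 1 / (hym * ay$dx[j]); aN <- 1 / (hyp * ay$dx[j])
  diag_v <- -(aW + aE + aS + aN)
  m <- idx(i, j)
  # interior couplings
  w_ok <- i > 1L; add(m[w_ok], m[w_ok] - 1L, aW[w_ok])
  e_ok <- i < nx; add(m[e_ok], m[e_ok] + 1L, aE[e_ok])
  s_ok <- j > 1L; add(m[s_ok], m[s_ok] - nx, aS[s_ok])
  n_ok <- j < ny; add(m[n_ok], m[n_ok] + nx, aN[n_ok])
  # boundaries
  bdry <- function(mask, a, nb_idx, side) {
    mm <- m[mask]
    if (side$type == "periodic") {
      add(mm, nb_idx, a[mask])
    } else if (side$type == "neumann") {
      diag_v[mask] <<- diag_v[mask] + a[mask]
    } else {                                   # dirichlet at the face
      diag_v[mask] <<- diag_v[mask] - a[mask]
      cc[mm] <<- cc[mm] + 2 * a[mask] * side$value
    }
  }
  bdry(i == 1L, aW, idx(nx, seq_len(ny)), bc$left)
  bdry(i == nx, aE, idx(1L, seq_len(ny)), bc$right)
  bdry(j == 1L, aS, idx(seq_len(nx), ny), bc$bottom)
  bdry(j == ny, aN, idx(seq_len(nx), 1L), bc$top)
  add(m, m, diag_v)
  M <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                            dims = c(N, N))
  list(M = M, const = cc)
}

velocity_bc_sides <- function(settings, comp) {
  if (settings$bc == "periodic") {
    s <- list(type = "periodic")
    return(list(left = s, right = s, bottom = s, top = s))
  }
  if (comp == "u") {
    list(left = list(type = "dirichlet", value = settings$U_inf),
         right = list(type = "neumann"),
         bottom = list(type = "neumann"),     # zero shear stress
         top = list(type = "neumann"))
  } else {
    list(left = list(type = "dirichlet", value = 0),
         right = list(type = "neumann"),
         bottom = list(type = "dirichlet", value = 0),  # impermeable lateral
         top = list(type = "dirichlet", value = 0))
  }
}

pressure_bc_sides <- function(settings) {
  if (settings$bc == "periodic") {
    s <- list(type = "periodic")
    list(left = s, right = s, bottom = s, top = s)
  } else {
    s <- list(type = "neumann")
    list(left = s, right = s, bottom = s, top = s)
  }
}

#' Build a flow solver (cached operators) for a grid
#'
#' Assembles and factorizes the pressure-Poisson operator and, for
#' Crank-Nicolson diffusion, the two velocity Helmholtz operators.  The
#' factorizations are reused every step, which is what makes the desk
#' runs affordable.
#' @param grid a 2D [build_grid()] grid.
#' @param settings a [solver_settings()].
#' @return a solver object used by [step_flow()] and [run_cycles()].
#' @export
build_solver <- function(grid, settings) {
  stopifnot(grid$dim == 2L)
  ax <- grid$axes[[1]]; ay <- grid$axes[[2]]
  lp <- assemble_laplacian(grid, pressure_bc_sides(settings))
  Mp <- lp$M
  # all-Neumann (or periodic) Poisson operator is singular: pin cell 1
  Mp[1, ] <- 0; Mp[1, 1] <- 1
  Mp <- Matrix::drop0(Mp)
  poisson_lu <- Matrix::lu(Mp)
  lap_u <- assemble_laplacian(grid, velocity_bc_sides(settings, "u"))
  lap_v <- assemble_laplacian(grid, velocity_bc_sides(settings, "v"))
  helm_u <- helm_v <- NULL
  if (settings$diffusion == "cn") {
    N <- ax$n * ay$n
    I <- Matrix::Diagonal(N)
    th <- settings$dt / (2 * settings$Re)
    helm_u <- Matrix::lu(I - th * lap_u$M)
    helm_v <- Matrix::lu(I - th * lap_v$M)
  }
  structure(list(grid = grid, settings = settings,
                 poisson = poisson_lu, poisson_mat = Mp,
                 lap_u = lap_u, lap_v = lap_v,
                 helm_u = helm_u, helm_v = helm_v),
            class = "flow_solver")
}

#' @export
print.flow_solver <- function(x, ...) {
  cat(sprintf("<flow_solver> %dx%d cells, Re=%g, dt=%g, bc=%s, diffusion=%s\n",
              x$grid$axes[[1]]$n, x$grid$axes[[2]]$n, x$settings$Re,
              x$settings$dt, x$settings$bc, x$settings$diffusion))
  invisible(x)
}

# --- padded-array derivative helpers ----------------------------------------

# ghost-extended field honoring the side BCs (windtunnel or periodic)
pad_field <- function(f, settings, comp) {
  nx <- nrow(f); ny <- ncol(f)
  g <- matrix(0, nx + 2L, ny + 2L)
  g[2:(nx + 1L), 2:(ny + 1L)] <- f
  if (settings$bc == "periodic") {
    g[1, 2:(ny + 1L)] <- f[nx, ]; g[nx + 2L, 2:(ny + 1L)] <- f[1, ]
    g[2:(nx + 1L), 1] <- f[, ny]; g[2:(nx + 1L), ny + 2L] <- f[, 1]
  } else {
    if (comp == "u") {
      g[1, 2:(ny + 1L)] <- 2 * settings$U_inf - f[1, ]
      g[nx + 2L, 2:(ny + 1L)] <- f[nx, ]
      g[2:(nx + 1L), 1] <- f[, 1]
      g[2:(nx + 1L), ny + 2L] <- f[, ny]
    } else if (comp == "v") {
      g[1, 2:(ny + 1L)] <- -f[1, ]
      g[nx + 2L, 2:(ny + 1L)] <- f[nx, ]
      g[2:(nx + 1L), 1] <- -f[, 1]
      g[2:(nx + 1L), ny + 2L] <- -f[, ny]
    } else {                                   # scalar: zero-gradient
      g[1, 2:(ny + 1L)] <- f[1, ]
      g[nx + 2L, 2:(ny + 1L)] <- f[nx, ]
      g[2:(nx + 1L), 1] <- f[, 1]
      g[2:(nx + 1L), ny + 2L] <- f[, ny]
    }
  }
  g
}

# extended center coordinates (mirror ghosts; periodic uses wrapped spacing)
ext_coords <- function(axis, periodic) {
  xc <- axis$xc; n <- axis$n
  if (periodic) {
    c(xc[1] - (axis$dx[1] + axis$dx[n]) / 2, xc,
      xc[n] + (axis$dx[n] + axis$dx[1]) / 2)
  } else {
    c(2 * axis$xf[1] - xc[1], xc, 2 * axis$xf[n + 1L] - xc[n])
  }
}

# first derivative of padded field along axis using nonuniform central weights
pad_deriv <- function(gpad, grid, settings, axis) {
  a <- grid$axes[[axis]]
  n <- a$n
  xe <- ext_coords(a, settings$bc == "periodic")
  h1 <- xe[2:(n + 1L)] - xe[1:n]
  h2 <- xe[3:(n + 2L)] - xe[2:(n + 1L)]
  wm <- -h2 / (h1 * (h1 + h2)); w0 <- (h2 - h1) / (h1 * h2)
  wp <- h1 / (h2 * (h1 + h2))
  if (axis == 1L) {
    wm * gpad[1:n, 2:(ncol(gpad) - 1L), drop = FALSE] +
      w0 * gpad[2:(n + 1L), 2:(ncol(gpad) - 1L), drop = FALSE] +
      wp * gpad[3:(n + 2L), 2:(ncol(gpad) - 1L), drop = FALSE]
  } else {
    inner <- 2:(nrow(gpad) - 1L)
    t(wm * t(gpad[inner, 1:n, drop = FALSE]) +
        w0 * t(gpad[inner, 2:(n + 1L), drop = FALSE]) +
        wp * t(gpad[inner, 3:(n + 2L), drop = FALSE]))
  }
}

# first-order upwind derivative of a padded field, direction chosen per
# cell by the sign of the advecting velocity component
pad_upwind <- function(gpad, grid, settings, axis, adv) {
  a <- grid$axes[[axis]]
  n <- a$n
  xe <- ext_coords(a, settings$bc == "periodic")
  h1 <- xe[2:(n + 1L)] - xe[1:n]
  h2 <- xe[3:(n + 2L)] - xe[2:(n + 1L)]
  if (axis == 1L) {
    jj <- 2:(ncol(gpad) - 1L)
    fm <- gpad[1:n, jj, drop = FALSE]
    f0 <- gpad[2:(n + 1L), jj, drop = FALSE]
    fp <- gpad[3:(n + 2L), jj, drop = FALSE]
    bwd <- (f0 - fm) / h1
    fwd <- (fp - f0) / h2
  } else {
    ii <- 2:(nrow(gpad) - 1L)
    bwd <- t(t(gpad[ii, 2:(n + 1L), drop = FALSE] - gpad[ii, 1:n, drop = FALSE]) / h1)
    fwd <- t(t(gpad[ii, 3:(n + 2L), drop = FALSE] - gpad[ii, 2:(n + 1L), drop = FALSE]) / h2)
  }
  ifelse(adv >= 0, bwd, fwd)
}

# --- immersed boundary -------------------------------------------------------

#' Classify grid cells against immersed bodies
#'
#' @param grid a 2D grid.
#' @param bodies list of [shape2d] objects (possibly empty).
#' @param prev_solid optional previous-step solid mask, to tag fresh cells.
#' @return list with logical masks `solid`, `ghost` (solid cells with a
#'   fluid neighbor), `fresh`, integer `owner`, and body-velocity fields
#'   `ub`, `vb` on solid cells.
#' @export
classify_cells <- function(grid, bodies, prev_solid = NULL) {
  nx <- grid$axes[[1]]$n; ny <- grid$axes[[2]]$n
  if (!length(bodies)) {
    return(list(solid = matrix(FALSE, nx, ny), ghost = matrix(FALSE, nx, ny),
                fresh = matrix(FALSE, nx, ny), owner = NULL,
                sdf = NULL, ub = NULL, vb = NULL))
  }
  X <- matrix(grid$axes[[1]]$xc, nx, ny)
  Y <- matrix(grid$axes[[2]]$xc, nx, ny, byrow = TRUE)
  sdf <- matrix(Inf, nx, ny); owner <- matrix(1L, nx, ny)
  for (b in seq_along(bodies)) {
    d <- matrix(shape_sdf(bodies[[b]], as.vector(X), as.vector(Y)), nx, ny)
    upd <- d < sdf
    sdf[upd] <- d[upd]; owner[upd] <- b
  }
  solid <- sdf < 0
  nb_fluid <- matrix(FALSE, nx, ny)
  f <- !solid
  nb_fluid[-1, ] <- nb_fluid[-1, ] | f[-nx, ]
  nb_fluid[-nx, ] <- nb_fluid[-nx, ] | f[-1, ]
  nb_fluid[, -1] <- nb_fluid[, -1] | f[, -ny]
  nb_fluid[, -ny] <- nb_fluid[, -ny] | f[, -1]
  ghost <- solid & nb_fluid
  fresh <- if (is.null(prev_solid)) matrix(FALSE, nx, ny) else (!solid & prev_solid)
  ub <- vb <- matrix(0, nx, ny)
  sol_idx <- which(solid)
  if (length(sol_idx)) {
    for (b in seq_along(bodies)) {
      sel <- sol_idx[owner[sol_idx] == b]
      if (!length(sel)) next
      V <- shape_velocity(bodies[[b]], X[sel], Y[sel])
      ub[sel] <- V[, 1]; vb[sel] <- V[, 2]
    }
  }
  list(solid = solid, ghost = ghost, fresh = fresh, owner = owner,
       sdf = sdf, X = X, Y = Y, ub = ub, vb = vb)
}

#' Bilinear interpolation of cell-center fields at scattered points
#' @param field matrix `nx x ny` (or list of such matrices).
#' @param grid a 2D grid.
#' @param px,py query coordinates.
#' @return numeric vector (or list of vectors) of interpolated values;
#'   queries outside the center hull are clamped to the boundary.
#' @export
interp_field <- function(field, grid, px, py) {
  xc <- grid$axes[[1]]$xc; yc <- grid$axes[[2]]$xc
  nx <- length(xc); ny <- length(yc)
  ix <- pmin(pmax(findInterval(px, xc), 1L), nx - 1L)
  iy <- pmin(pmax(findInterval(py, yc), 1L), ny - 1L)
  wx <- pmin(pmax((px - xc[ix]) / (xc[ix + 1L] - xc[ix]), 0), 1)
  wy <- pmin(pmax((py - yc[iy]) / (yc[iy + 1L] - yc[iy]), 0), 1)
  one <- function(f) {
    f[cbind(ix, iy)] * (1 - wx) * (1 - wy) +
      f[cbind(ix + 1L, iy)] * wx * (1 - wy) +
      f[cbind(ix, iy + 1L)] * (1 - wx) * wy +
      f[cbind(ix + 1L, iy + 1L)] * wx * wy
  }
  if (is.list(field)) lapply(field, one) else one(field)
}

# ghost-cell no-slip enforcement: solid interior takes the body velocity,
# boundary-adjacent solid cells take the linearly extrapolated value that
# places the interpolated body velocity on the surface along the normal
enforce_ib <- function(u, v, cls, grid, bodies) {
  if (is.null(cls$sdf)) return(list(u = u, v = v))
  u[cls$solid] <- cls$ub[cls$solid]
  v[cls$solid] <- cls$vb[cls$solid]
  gidx <- which(cls$ghost)
  if (length(gidx)) {
    gx <- cls$X[gidx]; gy <- cls$Y[gidx]; d <- cls$sdf[gidx]
    nrm <- matrix(0, length(gidx), 2)
    for (b in seq_along(bodies)) {
      sel <- cls$owner[gidx] == b
      if (!any(sel)) next
      nrm[sel, ] <- shape_normal(bodies[[b]], gx[sel], gy[sel])
    }
    bx <- gx - d * nrm[, 1]; by <- gy - d * nrm[, 2]   # surface foot point
    ixp <- gx - 2 * d * nrm[, 1]; iyp <- gy - 2 * d * nrm[, 2]  # image point
    ui <- interp_field(u, grid, ixp, iyp)
    vi <- interp_field(v, grid, ixp, iyp)
    ubv <- vbv <- numeric(length(gidx))
    for (b in seq_along(bodies)) {
      sel <- cls$owner[gidx] == b
      if (!any(sel)) next
      V <- shape_velocity(bodies[[b]], bx[sel], by[sel])
      ubv[sel] <- V[, 1]; vbv[sel] <- V[, 2]
    }
    u[gidx] <- 2 * ubv - ui
    v[gidx] <- 2 * vbv - vi
  }
  list(u = u, v = v)
}

# --- the fractional step -----------------------------------------------------

#' Advance the flow one time step
#'
#' One fractional step: AB2 convection (Euler on the first step), CN or
#' explicit diffusion, ghost-cell immersed-boundary enforcement on the
#' predictor, then a pressure projection built on momentum-interpolated
#' face velocities (which suppresses the collocated-grid checkerboard
#' mode).  Outer boundaries follow the solver settings.
#'
#' @param solver a [build_solver()] object.
#' @param state a [flow_state()].
#' @param bodies list of [shape2d] objects posed at the NEW time level
#'   (surface velocity included in their pose).
#' @return the advanced `flow_state`; `$divergence` holds the max
#'   post-projection divergence over fluid cells and `$fresh_cells` the
#'   number of cells uncovered by body motion this step.
#' @export
step_flow <- function(solver, state, bodies = list()) {
  g <- solver$grid; s <- solver$settings
  ax <- g$axes[[1]]; ay <- g$axes[[2]]
  nx <- ax$n; ny <- ay$n
  dt <- s$dt; nu <- 1 / s$Re
  u <- state$u; v <- state$v; p <- state$p
  if (any(!is.finite(u)) || any(!is.finite(v))) {
    stop(sprintf("divergence error: non-finite velocity entering step at t=%.5g", state$t))
  }
  prev_solid <- if (!is.null(attr(state, "solid"))) attr(state, "solid") else NULL
  cls <- classify_cells(g, bodies, prev_solid)

  up <- pad_field(u, s, "u"); vp <- pad_field(v, s, "v")
  ux <- pad_deriv(up, g, s, 1L); uy <- pad_deriv(up, g, s, 2L)
  vx <- pad_deriv(vp, g, s, 1L); vy <- pad_deriv(vp, g, s, 2L)
  # skew-symmetric convection (mean of advective and divergence forms):
  # discretely energy-conserving for central differences, which keeps the
  # high cell-Reynolds wake regions stable where the plain advective form
  # blows up
  conv_u <- 0.5 * (u * ux + v * uy +
                     pad_deriv(up * up, g, s, 1L) + pad_deriv(up * vp, g, s, 2L))
  conv_v <- 0.5 * (u * vx + v * vy +
                     pad_deriv(up * vp, g, s, 1L) + pad_deriv(vp * vp, g, s, 2L))
  if (s$upwind > 0) {
    cu1 <- u * pad_upwind(up, g, s, 1L, u) + v * pad_upwind(up, g, s, 2L, v)
    cv1 <- u * pad_upwind(vp, g, s, 1L, u) + v * pad_upwind(vp, g, s, 2L, v)
    conv_u <- (1 - s$upwind) * conv_u + s$upwind * cu1
    conv_v <- (1 - s$upwind) * conv_v + s$upwind * cv1
  }
  if (is.null(state$conv_u)) {
    cu <- conv_u; cv <- conv_v
  } else {
    cu <- 1.5 * conv_u - 0.5 * state$conv_u
    cv <- 1.5 * conv_v - 0.5 * state$conv_v
  }
  pp <- pad_field(p, s, "p")
  px <- pad_deriv(pp, g, s, 1L); py <- pad_deriv(pp, g, s, 2L)

  uv <- as.vector(u); vv <- as.vector(v)
  Lu <- as.vector(solver$lap_u$M %*% uv) + solver$lap_u$const
  Lv <- as.vector(solver$lap_v$M %*% vv) + solver$lap_v$const
  # incremental projection (second order in time); the pressure inside
  # immersed bodies is regenerated from the fluid each step further down,
  # otherwise the increments accumulate there without bound
  if (s$diffusion == "cn") {
    rhs_u <- uv + dt * (-as.vector(cu) - as.vector(px) + 0.5 * nu * Lu) +
      0.5 * dt * nu * solver$lap_u$const
    rhs_v <- vv + dt * (-as.vector(cv) - as.vector(py) + 0.5 * nu * Lv) +
      0.5 * dt * nu * solver$lap_v$const
    ustar <- matrix(as.vector(Matrix::solve(solver$helm_u, rhs_u)), nx, ny)
    vstar <- matrix(as.vector(Matrix::solve(solver$helm_v, rhs_v)), nx, ny)
  } else {
    ustar <- matrix(uv + dt * (-as.vector(cu) - as.vector(px) + nu * Lu), nx, ny)
    vstar <- matrix(vv + dt * (-as.vector(cv) - as.vector(py) + nu * Lv), nx, ny)
  }

  ib <- enforce_ib(ustar, vstar, cls, g, bodies)
  ustar <- ib$u; vstar <- ib$v

  # momentum-interpolated face velocities
  fv <- face_velocities(ustar, vstar, g, s)
  div <- ((fv$uf[-1, , drop = FALSE] - fv$uf[-(nx + 1L), , drop = FALSE]) / ax$dx) +
    t((t(fv$vf[, -1, drop = FALSE]) - t(fv$vf[, -(ny + 1L), drop = FALSE])) / ay$dx)
  rhs <- as.vector(div) / dt
  rhs[1] <- 0                                   # pinned cell of the singular system
  phiv <- as.vector(Matrix::solve(solver$poisson, rhs))
  # one or two passes of iterative refinement: the direct solve alone can
  # leave O(1e-5) divergence when body motion makes the RHS large
  for (pass in 1:2) {
    resid <- rhs - as.vector(solver$poisson_mat %*% phiv)
    if (max(abs(resid)) < 1e-10 * max(1, max(abs(rhs)))) break
    phiv <- phiv + as.vector(Matrix::solve(solver$poisson, resid))
  }
  phi <- matrix(phiv, nx, ny)

  # correct faces and centers
  hx <- ax$xc[-1] - ax$xc[-nx]
  fv$uf[2:nx, ] <- fv$uf[2:nx, , drop = FALSE] -
    dt * (phi[-1, , drop = FALSE] - phi[-nx, , drop = FALSE]) / hx
  hy <- ay$xc[-1] - ay$xc[-ny]
  fv$vf[, 2:ny] <- fv$vf[, 2:ny, drop = FALSE] -
    dt * t((t(phi[, -1, drop = FALSE]) - t(phi[, -ny, drop = FALSE])) / hy)
  if (s$bc == "periodic") {
    hxp <- (ax$dx[1] + ax$dx[nx]) / 2
    dphix <- (phi[1, ] - phi[nx, ]) / hxp
    fv$uf[1, ] <- fv$uf[1, ] - dt * dphix
    fv$uf[nx + 1L, ] <- fv$uf[nx + 1L, ] - dt * dphix
    hyp <- (ay$dx[1] + ay$dx[ny]) / 2
    dphiy <- (phi[, 1] - phi[, ny]) / hyp
    fv$vf[, 1] <- fv$vf[, 1] - dt * dphiy
    fv$vf[, ny + 1L] <- fv$vf[, ny + 1L] - dt * dphiy
  }
  php <- pad_field(phi, s, "p")
  u_new <- ustar - dt * pad_deriv(php, g, s, 1L)
  v_new <- vstar - dt * pad_deriv(php, g, s, 2L)
  p_new <- p + phi
  if (!is.null(cls$sdf) && any(cls$solid)) {
    # zero-normal-gradient pressure inside bodies: ghost layer mirrors the
    # image-point value, deeper cells are zeroed (they influence nothing)
    p_new[cls$solid & !cls$ghost] <- 0
    gidx <- which(cls$ghost)
    if (length(gidx)) {
      d <- cls$sdf[gidx]
      nrm <- matrix(0, length(gidx), 2)
      for (b in seq_along(bodies)) {
        selb <- cls$owner[gidx] == b
        if (any(selb)) nrm[selb, ] <- shape_normal(bodies[[b]], cls$X[gidx][selb], cls$Y[gidx][selb])
      }
      p_new[gidx] <- interp_field(p_new, g,
                                  cls$X[gidx] - 2 * d * nrm[, 1],
                                  cls$Y[gidx] - 2 * d * nrm[, 2])
    }
  }

  div_post <- ((fv$uf[-1, , drop = FALSE] - fv$uf[-(nx + 1L), , drop = FALSE]) / ax$dx) +
    t((t(fv$vf[, -1, drop = FALSE]) - t(fv$vf[, -(ny + 1L), drop = FALSE])) / ay$dx)
  fluid <- !cls$solid
  max_div <- max(abs(div_post[fluid]))
  if (!is.finite(max_div)) {
    stop(sprintf("divergence error: projection produced non-finite values at t=%.5g", state$t))
  }
  if (max_div > max(s$poisson_tol, 1e-6)) {
    stop(sprintf("solver error: post-projection divergence %.3e exceeds tolerance at t=%.5g",
                 max_div, state$t))
  }

  out <- state
  out$u <- u_new; out$v <- v_new; out$p <- p_new
  out$t <- state$t + dt
  out$conv_u <- conv_u; out$conv_v <- conv_v
  out$divergence <- max_div
  out$fresh_cells <- sum(cls$fresh)
  cl <- matrix("fluid", nx, ny)
  cl[cls$solid] <- "solid"; cl[cls$ghost] <- "ghost"; cl[cls$fresh] <- "fresh"
  out$classification <- cl
  attr(out, "solid") <- cls$solid
  attr(out, "faces") <- fv
  out
}

# distance-weighted interpolation of cell-center velocity to faces, with
# boundary faces set from the BCs and (windtunnel) a global mass balance
# correction applied to the outflow so the Neumann Poisson problem is
# solvable
face_velocities <- function(u, v, grid, settings) {
  ax <- grid$axes[[1]]; ay <- grid$axes[[2]]
  nx <- ax$n; ny <- ay$n
  uf <- matrix(0, nx + 1L, ny); vf <- matrix(0, nx, ny + 1L)
  wxa <- ax$dx[-1] / (ax$dx[-1] + ax$dx[-nx])
  uf[2:nx, ] <- wxa * u[-nx, , drop = FALSE] + (1 - wxa) * u[-1, , drop = FALSE]
  wya <- ay$dx[-1] / (ay$dx[-1] + ay$dx[-ny])
  vf[, 2:ny] <- t(wya * t(v[, -ny, drop = FALSE]) + (1 - wya) * t(v[, -1, drop = FALSE]))
  if (settings$bc == "periodic") {
    w <- ax$dx[1] / (ax$dx[1] + ax$dx[nx])
    uf[1, ] <- w * u[nx, ] + (1 - w) * u[1, ]
    uf[nx + 1L, ] <- uf[1, ]
    w <- ay$dx[1] / (ay$dx[1] + ay$dx[ny])
    vf[, 1] <- w * v[, ny] + (1 - w) * v[, 1]
    vf[, ny + 1L] <- vf[, 1]
  } else {
    uf[1, ] <- settings$U_inf
    uf[nx + 1L, ] <- u[nx, ]                  # zero-gradient outflow
    vf[, 1] <- 0; vf[, ny + 1L] <- 0          # impermeable lateral walls
    q_in <- sum(uf[1, ] * ay$dx)
    q_out <- sum(uf[nx + 1L, ] * ay$dx)
    uf[nx + 1L, ] <- uf[nx + 1L, ] + (q_in - q_out) / sum(ay$dx)
  }
  list(uf = uf, vf = vf)
}

#' Run whole flapping cycles with observers
#'
#' Poses the bodies from a caller-supplied schedule each step, advances
#' the flow, and invokes observer callbacks.  The final cycle is the
#' analysis cycle; a cycle-to-cycle periodicity measure (relative L2
#' difference of the last two cycles of the first numeric observer
#' column) is reported when at least two cycles are run.
#'
#' @param solver a [build_solver()] object.
#' @param state initial [flow_state()].
#' @param pose_bodies function of time returning the posed body list
#'   (may return an empty list).
#' @param T_cycle cycle period (nondimensional time).
#' @param n_cycles number of cycles to run (0 returns the input state).
#' @param observers named list of functions `f(state, bodies, solver)`
#'   returning a named numeric vector; sampled every `observe_every`
#'   steps.
#' @param observe_every sampling stride, steps.
#' @return list with `state`, `series` (data frame: `t`, `cycle`, then
#'   observer outputs), and `periodicity`.
#' @export
run_cycles <- function(solver, state, pose_bodies, T_cycle, n_cycles,
                       observers = list(), observe_every = 1L) {
  if (n_cycles == 0) {
    return(list(state = state, series = data.frame(), periodicity = NA_real_))
  }
  dt <- solver$settings$dt
  steps_per_cycle <- max(1L, round(T_cycle / dt))
  total <- steps_per_cycle * n_cycles
  rows <- list()
  for (istep in seq_len(total)) {
    t_new <- state$t + dt
    bodies <- pose_bodies(t_new)
    state <- step_flow(solver, state, bodies)
    if (istep %% observe_every == 0L && length(observers)) {
      obs <- unlist(lapply(observers, function(f) f(state, bodies, solver)))
      rows[[length(rows) + 1L]] <-
        c(t = state$t, cycle = ceiling(istep / steps_per_cycle), obs)
    }
  }
  series <- if (length(rows)) as.data.frame(do.call(rbind, rows)) else data.frame()
  periodicity <- NA_real_
  if (n_cycles >= 2 && nrow(series) > 0 && ncol(series) > 2) {
    colv <- series[[3]]
    last <- series$cycle == n_cycles
    prev <- series$cycle == n_cycles - 1
    m <- min(sum(last), sum(prev))
    if (m > 1) {
      a <- colv[last][seq_len(m)]; b <- colv[prev][seq_len(m)]
      periodicity <- sqrt(sum((a - b)^2)) / max(sqrt(sum(b^2)), 1e-12)
    }
  }
  list(state = state, series = series, periodicity = periodicity)
}
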