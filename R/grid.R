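#' Nonuniform Cartesian grid with a uniformly refined box
#'
#' Builds the tensor-product grid used by the flow solver: a uniform cell
#' size `delta` inside a refinement box (which must contain the body and
#' the swept wing region) and geometrically stretched cells from the box
#' edges out to the domain boundaries, with the cell-to-cell growth ratio
#' capped.  All lengths are in units of the wing span R.
#'
#' The default growth ratio (1.12) is calibrated so that the full-scale
#' 3D preset -- a 15R x 15R x 15R domain with a 2R x 1R x 2.5R refined box
#' at `delta = 0.0125R` -- comes out near the production-scale ten-million
#' point grid (289 x 137 x 249); desk-scale grids use the same law.
#'
#' @param domain list (or matrix) of per-axis extents `c(lo, hi)`, units R.
#' @param box per-axis extents of the refined box, units R; must lie
#'   inside the domain.
#' @param delta uniform spacing inside the box, units R.
#' @param stretch_ratio geometric growth ratio outside the box
#'   (1 < ratio <= 1.2).
#' @param max_outer_cells cap on stretched cells per side per axis; if the
#'   boundary cannot be reached within this many cells at the given ratio
#'   the construction fails with advice.
#' @return object of class `cartesian_grid`: per-axis face coordinates
#'   `xf`, centers `xc`, widths `dx`, in-box masks, and `npoints`
#'   (total face-node count, the figure usually quoted for grid size).
#' @export
build_grid <- function(domain, box, delta, stretch_ratio = 1.12,
                       max_outer_cells = 512L) {
  if (is.matrix(domain)) domain <- asplit(domain, 1)
  if (is.matrix(box)) box <- asplit(box, 1)
  dim <- length(domain)
  stopifnot(dim %in% c(2L, 3L), length(box) == dim, delta > 0)
  if (!(stretch_ratio > 1 && stretch_ratio <= 1.2)) {
    stop("grid error: stretch_ratio must be in (1, 1.2]")
  }
  axes <- vector("list", dim)
  for (d in seq_len(dim)) {
    lo <- domain[[d]][1]; hi <- domain[[d]][2]
    b0 <- box[[d]][1]; b1 <- box[[d]][2]
    if (!(lo <= b0 && b1 <= hi && b0 < b1)) {
      stop("grid error: refined box must lie inside the domain")
    }
    n_in <- max(1L, round((b1 - b0) / delta))
    d_in <- (b1 - b0) / n_in                 # snap so the box closes exactly
    faces_in <- seq(b0, b1, length.out = n_in + 1L)
    left <- stretch_segment(b0 - lo, d_in, stretch_ratio, max_outer_cells)
    right <- stretch_segment(hi - b1, d_in, stretch_ratio, max_outer_cells)
    xf <- c(b0 - rev(cumsum(left)), faces_in, b1 + cumsum(right))
    xf[1] <- lo; xf[length(xf)] <- hi        # absorb roundoff at the ends
    axes[[d]] <- axis_metrics(xf, b0, b1)
  }
  structure(list(dim = dim, axes = axes, domain = domain, box = box,
                 delta = delta, stretch_ratio = stretch_ratio,
                 npoints = prod(vapply(axes, function(a) length(a$xf), 1L))),
            class = "cartesian_grid")
}

# cell widths of one stretched side: geometric growth from d0, ratio solved
# in (1, cap] so the total equals L exactly
stretch_segment <- function(L, d0, cap, max_cells) {
  if (L <= 1e-12) return(numeric(0))
  if (L <= d0) return(L)
  total <- function(r, n) if (abs(r - 1) < 1e-12) n * d0 else d0 * r * (r^n - 1) / (r - 1)
  n <- 1L
  while (total(cap, n) < L) {
    n <- n + 1L
    if (n > max_cells) {
      stop("grid error: cannot reach the domain boundary within the stretch-ratio cap; use a larger delta or a smaller domain")
    }
  }
  if (n == 1L) return(L)
  r <- stats::uniroot(function(r) total(r, n) - L, lower = 1 + 1e-9,
                      upper = cap, tol = 1e-13)$root
  d0 * r^seq_len(n)
}

axis_metrics <- function(xf, b0, b1) {
  if (any(diff(xf) <= 0)) stop("grid error: coordinates must be strictly increasing")
  xc <- (xf[-1] + xf[-length(xf)]) / 2
  dx <- diff(xf)
  n <- length(xc)
  # second-order first-derivative weights on nonuniform centers
  h1 <- xc[2:(n - 1)] - xc[1:(n - 2)]
  h2 <- xc[3:n] - xc[2:(n - 1)]
  list(xf = xf, xc = xc, dx = dx, n = n,
       in_box = xc >= b0 - 1e-12 & xc <= b1 + 1e-12,
       wm = -h2 / (h1 * (h1 + h2)),
       w0 = (h2 - h1) / (h1 * h2),
       wp = h1 / (h2 * (h1 + h2)))
}

#' @export
print.cartesian_grid <- function(x, ...) {
  sizes <- vapply(x$axes, function(a) length(a$xf), 1L)
  cat(sprintf("<cartesian_grid> %dD, %s points (%s cells), delta=%.4gR, ratio=%.3g\n",
              x$dim, paste(sizes, collapse = "x"),
              paste(sizes - 1L, collapse = "x"),
              x$delta, x$stretch_ratio))
  invisible(x)
}

#' First derivative of a 2D field along one axis
#'
#' Second-order central differences on the (possibly nonuniform) cell
#' centers; one-sided second-order at the boundary cells.
#' @param field matrix `nx x ny` of cell-center values.
#' @param grid a 2D [build_grid()] grid.
#' @param axis 1 (x) or 2 (y).
#' @return matrix of the same shape.
#' @export
grid_deriv <- function(field, grid, axis) {
  stopifnot(grid$dim == 2L, axis %in% c(1L, 2L))
  a <- grid$axes[[axis]]
  n <- a$n
  if (axis == 2L) field <- t(field)
  out <- field
  out[2:(n - 1), ] <- a$wm * field[1:(n - 2), , drop = FALSE] +
    a$w0 * field[2:(n - 1), , drop = FALSE] +
    a$wp * field[3:n, , drop = FALSE]
  # one-sided at the ends (second order)
  h1 <- a$xc[2] - a$xc[1]; h2 <- a$xc[3] - a$xc[2]
  out[1, ] <- (-(2 * h1 + h2) / (h1 * (h1 + h2))) * field[1, ] +
    ((h1 + h2) / (h1 * h2)) * field[2, ] - (h1 / (h2 * (h1 + h2))) * field[3, ]
  g1 <- a$xc[n] - a$xc[n - 1]; g2 <- a$xc[n - 1] - a$xc[n - 2]
  out[n, ] <- ((2 * g1 + g2) / (g1 * (g1 + g2))) * field[n, ] -
    ((g1 + g2) / (g1 * g2)) * field[n - 1, ] + (g1 / (g2 * (g1 + g2))) * field[n - 2, ]
  if (axis == 2L) t(out) else out
}

#' Full-scale 3D grid preset
#'
#' The production-scale grid: 15R cubic domain, 2R x 1R x 2.5R refined
#' box, `delta = 0.0125R`.  Constructible on any machine (only axis
#' vectors are stored) but solving flow on it is cluster-scale work; the
#' desk-scale drivers never step it.
#' @export
paper_scale_grid <- function() {
  build_grid(domain = list(c(-7.5, 7.5), c(-7.5, 7.5), c(-7.5, 7.5)),
             box = list(c(-1, 1), c(-0.5, 0.5), c(-1.25, 1.25)),
             delta = 0.0125)
}
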