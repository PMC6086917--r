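#' Rigid 2D shapes for the immersed-boundary solver
#'
#' The desk-scale solver represents bodies analytically: each shape
#' carries a signed-distance function (negative inside), a sampled
#' boundary polyline with outward normals, and a rigid-body velocity
#' (translation + rotation), which is all the ghost-cell procedure and
#' the surface force integration need.  Two primitives cover the fly
#' analog: an ellipse (body section on the sagittal plane) and a
#' rounded-rectangle plate (flat-plate wing section of chord `c_bar`).
#'
#' @param a,b ellipse semi-axes (units of R).
#' @param center,angle,vel,omega pose: center (length 2), rotation
#'   (radians, CCW), translational velocity, angular velocity (rad/time).
#' @return object of class `shape2d`.
#' @name shape2d
NULL

#' @rdname shape2d
#' @export
ellipse_shape <- function(a, b, center = c(0, 0), angle = 0,
                          vel = c(0, 0), omega = 0) {
  stopifnot(a > 0, b > 0)
  structure(list(type = "ellipse", a = a, b = b, center = center,
                 angle = angle, vel = vel, omega = omega),
            class = "shape2d")
}

#' @rdname shape2d
#' @param chord,thickness plate chord and thickness (units of R); corners
#'   are rounded with radius `thickness / 2`.
#' @export
plate_shape <- function(chord, thickness, center = c(0, 0), angle = 0,
                        vel = c(0, 0), omega = 0) {
  stopifnot(chord > 0, thickness > 0, chord > thickness)
  structure(list(type = "plate", hx = chord / 2, hy = thickness / 2,
                 r = thickness / 2, center = center, angle = angle,
                 vel = vel, omega = omega),
            class = "shape2d")
}

#' Re-pose a shape
#' @param shape a [shape2d] object.
#' @inheritParams ellipse_shape
#' @export
pose_shape <- function(shape, center = shape$center, angle = shape$angle,
                       vel = shape$vel, omega = shape$omega) {
  shape$center <- center; shape$angle <- angle
  shape$vel <- vel; shape$omega <- omega
  shape
}

to_local <- function(shape, x, y) {
  ca <- cos(shape$angle); sa <- sin(shape$angle)
  dx <- x - shape$center[1]; dy <- y - shape$center[2]
  list(x = ca * dx + sa * dy, y = -sa * dx + ca * dy)
}

to_lab <- function(shape, x, y) {
  ca <- cos(shape$angle); sa <- sin(shape$angle)
  list(x = shape$center[1] + ca * x - sa * y,
       y = shape$center[2] + sa * x + ca * y)
}

#' Signed distance to a shape (negative inside)
#' @param shape a [shape2d] object.
#' @param x,y lab-frame coordinates (vectors of equal length).
#' @export
shape_sdf <- function(shape, x, y) {
  p <- to_local(shape, x, y)
  if (shape$type == "ellipse") {
    # first-order normalization of the implicit function: exact enough
    # within a cell of the boundary, which is where the solver uses it
    fx <- p$x / shape$a; fy <- p$y / shape$b
    f <- sqrt(fx^2 + fy^2)
    g <- sqrt((fx / shape$a)^2 + (fy / shape$b)^2)
    d <- (f - 1) * ifelse(g > 0, f / g, min(shape$a, shape$b))
    d[f == 0] <- -min(shape$a, shape$b)
    d
  } else {
    bx <- shape$hx - shape$r; by <- shape$hy - shape$r
    qx <- abs(p$x) - bx; qy <- abs(p$y) - by
    sqrt(pmax(qx, 0)^2 + pmax(qy, 0)^2) + pmin(pmax(qx, qy), 0) - shape$r
  }
}

#' Outward unit normal of the shape boundary near given points
#'
#' Numerical gradient of the signed distance; valid anywhere, used at
#' ghost cells adjacent to the boundary.
#' @inheritParams shape_sdf
#' @param eps differencing step.
#' @return two-column matrix of unit normals.
#' @export
shape_normal <- function(shape, x, y, eps = 1e-6) {
  gx <- (shape_sdf(shape, x + eps, y) - shape_sdf(shape, x - eps, y)) / (2 * eps)
  gy <- (shape_sdf(shape, x, y + eps) - shape_sdf(shape, x, y - eps)) / (2 * eps)
  nn <- pmax(sqrt(gx^2 + gy^2), 1e-12)
  cbind(gx / nn, gy / nn)
}

#' Rigid-body velocity of the shape at lab points
#' @inheritParams shape_sdf
#' @return two-column matrix (u, v).
#' @export
shape_velocity <- function(shape, x, y) {
  rx <- x - shape$center[1]; ry <- y - shape$center[2]
  cbind(shape$vel[1] - shape$omega * ry,
        shape$vel[2] + shape$omega * rx)
}

#' Sampled boundary polyline with normals and arc weights
#'
#' @param shape a [shape2d] object.
#' @param n number of boundary sample points.
#' @return list with `points` (n x 2, lab frame), `normals` (outward,
#'   n x 2), `ds` (arc-length weight per point), `velocity` (n x 2).
#' @export
shape_boundary <- function(shape, n = 200) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  if (shape$type == "ellipse") {
    lx <- shape$a * cos(th); ly <- shape$b * sin(th)
  } else {
    # rounded rectangle traced by arc length: sides + quarter-circle corners
    bx <- shape$hx - shape$r; by <- shape$hy - shape$r; r <- shape$r
    per <- 4 * bx + 4 * by + 2 * pi * r
    s <- seq(0, per, length.out = n + 1L)[-(n + 1L)]
    seg_len <- c(2 * bx, pi * r / 2, 2 * by, pi * r / 2,
                 2 * bx, pi * r / 2, 2 * by, pi * r / 2)
    seg_end <- cumsum(seg_len)
    lx <- numeric(n); ly <- numeric(n)
    for (i in seq_len(n)) {                     # CCW walk from the bottom side
      k <- which(s[i] < seg_end + 1e-12)[1]
      u <- s[i] - c(0, seg_end)[-9][k]
      pt <- switch(k,
        c(-bx + u, -(by + r)),
        {a <- -pi / 2 + u / r; c(bx + r * cos(a), -by + r * sin(a))},
        c(bx + r, -by + u),
        {a <- u / r; c(bx + r * cos(a), by + r * sin(a))},
        c(bx - u, by + r),
        {a <- pi / 2 + u / r; c(-bx + r * cos(a), by + r * sin(a))},
        c(-(bx + r), by - u),
        {a <- pi + u / r; c(-bx + r * cos(a), -by + r * sin(a))}
      )
      lx[i] <- pt[1]; ly[i] <- pt[2]
    }
  }
  pl <- to_lab(shape, lx, ly)
  pts <- cbind(pl$x, pl$y)
  nrm <- shape_normal(shape, pts[, 1], pts[, 2])
  # project samples exactly onto the zero level set
  d0 <- shape_sdf(shape, pts[, 1], pts[, 2])
  pts <- pts - nrm * d0
  nrm <- shape_normal(shape, pts[, 1], pts[, 2])
  nxt <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE])
  prv <- rbind(pts[n, , drop = FALSE], pts[-n, , drop = FALSE])
  ds <- (sqrt(rowSums((nxt - pts)^2)) + sqrt(rowSums((pts - prv)^2))) / 2
  list(points = pts, normals = nrm, ds = ds,
       velocity = shape_velocity(shape, pts[, 1], pts[, 2]))
}
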