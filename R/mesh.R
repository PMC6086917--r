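#' Triangulated surface meshes
#'
#' Light-weight container for body and wing surfaces: a vertex matrix, a
#' face index matrix (triangles in 3D, segments for 2D polylines), a role
#' tag and named landmark points.  Units are mm in the geometry frame.
#'
#' @param vertices numeric matrix, one vertex per row (3 columns in 3D,
#'   2 in 2D).
#' @param faces integer matrix of 1-based vertex indices; 3 columns for
#'   triangles, 2 for polyline segments.
#' @param role one of `"body"`, `"wing_left"`, `"wing_right"`.
#' @param landmarks named list of points (same dimension as vertices).
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, role = "body", landmarks = list()) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), nrow = nrow(as.matrix(faces)))
  stopifnot(ncol(vertices) %in% c(2L, 3L),
            ncol(faces) %in% c(2L, 3L),
            max(faces) <= nrow(vertices), min(faces) >= 1L)
  role <- match.arg(role, c("body", "wing_left", "wing_right"))
  m <- structure(list(vertices = vertices, faces = faces, role = role,
                      landmarks = landmarks),
                 class = "surface_mesh")
  a <- face_measures(m)
  if (any(a <= .Machine$double.eps * 100)) {
    stop("mesh error: degenerate faces (zero area/length)")
  }
  m
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> role=%s: %d vertices, %d faces, area %.4g\n",
              x$role, nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}

#' Per-face area (3D triangles) or length (2D segments)
#' @param mesh a [surface_mesh()].
#' @return numeric vector, one entry per face.
#' @export
face_measures <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (ncol(f) == 3L) {
    e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
    cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
    cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
    sqrt(cx^2 + cy^2 + cz^2) / 2
  } else {
    d <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    sqrt(rowSums(d^2))
  }
}

#' Total surface area (or polyline length in 2D)
#' @param mesh a [surface_mesh()].
#' @export
mesh_area <- function(mesh) sum(face_measures(mesh))

#' Check that a triangle mesh is closed (watertight)
#'
#' Every edge must be shared by exactly two triangles.
#' @param mesh a [surface_mesh()] with triangular faces.
#' @export
mesh_is_closed <- function(mesh) {
  f <- mesh$faces
  if (ncol(f) != 3L) return(FALSE)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Mirror a mesh about the sagittal (y = 0) plane
#' @param mesh a [surface_mesh()].
#' @param role role tag of the mirrored mesh.
#' @return mirrored `surface_mesh` with consistent face orientation.
#' @export
mirror_mesh <- function(mesh, role = mesh$role) {
  v <- mesh$vertices
  v[, 2] <- -v[, 2]
  f <- mesh$faces
  if (ncol(f) == 3L) f <- f[, c(1, 3, 2)]        # restore orientation
  lm <- lapply(mesh$landmarks, function(p) { p[2] <- -p[2]; p })
  surface_mesh(v, f, role = role, landmarks = lm)
}

# --- primitive meshes --------------------------------------------------------

#' Triangulated ellipsoid
#'
#' UV (latitude/longitude) triangulation of an ellipsoid with semi-axes
#' `a, b, c` along x, y, z, centered at the origin.
#' @param axes numeric length-3, semi-axes (mm).
#' @param n_theta,n_phi latitude / longitude resolution.
#' @return a `surface_mesh` (closed).
#' @export
ellipsoid_mesh <- function(axes, n_theta = 40, n_phi = 60) {
  stopifnot(length(axes) == 3, all(axes > 0), n_theta >= 4, n_phi >= 6)
  th <- seq(0, pi, length.out = n_theta + 1L)     # polar angle from +x pole
  ph <- seq(0, 2 * pi, length.out = n_phi + 1L)[-(n_phi + 1L)]
  # interior rings
  verts <- list(c(axes[1], 0, 0))
  idx_ring <- vector("list", n_theta - 1L)
  for (i in seq_len(n_theta - 1L)) {
    t <- th[i + 1L]
    ring <- cbind(axes[1] * cos(t),
                  axes[2] * sin(t) * cos(ph),
                  axes[3] * sin(t) * sin(ph))
    idx_ring[[i]] <- length(verts) + seq_len(n_phi)
    verts <- c(verts, split(ring, row(ring)[, 1]))
  }
  ipole2 <- length(verts) + 1L
  verts <- c(verts, list(c(-axes[1], 0, 0)))
  V <- do.call(rbind, verts)
  F <- list()
  r1 <- idx_ring[[1]]
  F[[length(F) + 1L]] <- cbind(1L, r1, c(r1[-1], r1[1]))
  for (i in seq_len(n_theta - 2L)) {
    a <- idx_ring[[i]]; b <- idx_ring[[i + 1L]]
    an <- c(a[-1], a[1]); bn <- c(b[-1], b[1])
    F[[length(F) + 1L]] <- cbind(a, b, bn)
    F[[length(F) + 1L]] <- cbind(a, bn, an)
  }
  rl <- idx_ring[[n_theta - 1L]]
  F[[length(F) + 1L]] <- cbind(ipole2, c(rl[-1], rl[1]), rl)
  surface_mesh(V, do.call(rbind, F), role = "body")
}

#' Analytic ellipsoid surface area (Thomsen's approximation)
#'
#' `4*pi*((a^p b^p + a^p c^p + b^p c^p)/3)^(1/p)` with `p = 1.6075`;
#' accurate to about 1 part in 10^3 for moderate aspect ratios.
#' @param axes semi-axes, length 3.
#' @export
ellipsoid_area_thomsen <- function(axes) {
  p <- 1.6075
  a <- axes[1]^p; b <- axes[2]^p; c <- axes[3]^p
  4 * pi * ((a * b + a * c + b * c) / 3)^(1 / p)
}

# structured triangulation of a planform (thin open surface, z = 0 wing frame)
wing_mesh_from_planform <- function(planform, n_chord = 12) {
  if (n_chord < 8) {
    stop("geometry error: resolution too coarse to resolve the wing outline (need >= 8 elements per chord)")
  }
  n_span <- max(16L, round(n_chord * planform$R / planform$c_bar))
  s <- seq(0, 1, length.out = n_span + 1L)
  le <- stats::approx(planform$s, planform$x_le, xout = s, rule = 2)$y
  te <- stats::approx(planform$s, planform$x_te, xout = s, rule = 2)$y
  u <- seq(0, 1, length.out = n_chord + 1L)
  X <- outer(le, 1 - u) + outer(te, u)        # (n_span+1) x (n_chord+1)
  Y <- matrix(s * planform$R, n_span + 1L, n_chord + 1L)
  V <- cbind(as.vector(X), as.vector(Y), 0)
  id <- matrix(seq_len((n_span + 1L) * (n_chord + 1L)), n_span + 1L, n_chord + 1L)
  F <- list()
  for (j in seq_len(n_chord)) {
    i <- seq_len(n_span)
    F[[length(F) + 1L]] <- cbind(id[i, j], id[i + 1L, j], id[i + 1L, j + 1L])
    F[[length(F) + 1L]] <- cbind(id[i, j], id[i + 1L, j + 1L], id[i, j + 1L])
  }
  F <- do.call(rbind, F)
  # drop degenerate triangles at the closed tip/root (zero local chord)
  keep <- face_measures(structure(list(vertices = V, faces = F),
                                  class = "surface_mesh")) > 1e-12
  # compact vertex list
  F <- F[keep, , drop = FALSE]
  used <- sort(unique(as.vector(F)))
  remap <- integer(nrow(V)); remap[used] <- seq_along(used)
  surface_mesh(V[used, , drop = FALSE],
               matrix(remap[F], ncol = 3), role = "wing_right")
}

# --- fly geometry ------------------------------------------------------------

#' Synthetic fruit-fly geometry
#'
#' Generates the model insect used throughout the package: an ellipsoidal
#' body inclined nose-up by `chi` degrees with an antenna landmark at the
#' anterior tip of the head, plus left and right wings built from a
#' [wing_planform()] and attached at a dorsal-shoulder hinge.  Left-right
#' symmetry is assumed: the left wing is the exact mirror image of the
#' right wing about the sagittal plane.
#'
#' Frames: x is the freestream (flight) direction with the head pointing
#' upstream (-x), y is lateral, z is vertical.  The body center sits at
#' the origin.  Wings are returned in their reference pose (feathering,
#' deviation and position angles all zero, span along +/- y); posing over
#' a stroke cycle is done by [wing_transform()].
#'
#' @param planform a [wing_planform()]; default is the standard planform.
#' @param body_axes ellipsoid semi-axes (mm) along the body's own
#'   longitudinal/lateral/vertical axes.  The default approximates a
#'   2.5 mm long fruit-fly body.
#' @param chi body inclination with respect to horizontal, degrees
#'   (default 45).
#' @param resolution wing chordwise element count (>= 8); body resolution
#'   scales with it.
#' @param hinge_body hinge (wing-root) location in the body frame before
#'   inclination, as a fraction of the semi-axes `c(x, y, z)`; default is
#'   the dorsal shoulder.
#' @return a list with `surface_mesh` entries `body`, `wing_left`,
#'   `wing_right`, plus `hinge_left`, `hinge_right` (lab-frame points) and
#'   `planform`.
#' @export
make_fly_geometry <- function(planform = wing_planform(),
                              body_axes = c(1.25, 0.42, 0.45),
                              chi = 45,
                              resolution = 12,
                              hinge_body = c(-0.15, 0.85, 0.75)) {
  stopifnot(inherits(planform, "wing_planform"), length(body_axes) == 3)
  nb <- max(24L, 2L * as.integer(resolution))
  body <- ellipsoid_mesh(body_axes, n_theta = nb, n_phi = round(1.5 * nb))
  Rchi <- rot_y(chi)     # nose-up pitch: the -x (anterior) end tilts toward +z
  # body frame: anterior along -x before rotation (head upstream)
  body$vertices <- body$vertices %*% t(Rchi)
  head_pt <- as.vector(Rchi %*% c(-body_axes[1], 0, 0))
  tail_pt <- as.vector(Rchi %*% c(body_axes[1], 0, 0))
  body$landmarks <- list(antenna = head_pt, head = head_pt, tail = tail_pt)
  hinge_r <- as.vector(Rchi %*% (hinge_body * body_axes * c(1, 1, 1)))
  hinge_l <- hinge_r * c(1, -1, 1)

  wr <- wing_mesh_from_planform(planform, n_chord = resolution)
  # wing frame -> lab reference pose: span +y (outboard right), chord +x,
  # translated to the right hinge
  wr$vertices <- sweep(wr$vertices, 2, hinge_r, "+")
  wr$landmarks <- list(root = hinge_r,
                       tip = hinge_r + c(0, planform$R, 0))
  wl <- mirror_mesh(wr, role = "wing_left")
  list(body = body, wing_right = wr, wing_left = wl,
       hinge_right = hinge_r, hinge_left = hinge_l,
       planform = planform, chi = chi, body_axes = body_axes)
}

rot_y <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), 0, sin(t),
           0, 1, 0,
           -sin(t), 0, cos(t)), 3, 3, byrow = TRUE)
}
rot_x <- function(deg) {
  t <- deg * pi / 180
  matrix(c(1, 0, 0,
           0, cos(t), -sin(t),
           0, sin(t), cos(t)), 3, 3, byrow = TRUE)
}
rot_z <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), -sin(t), 0,
           sin(t), cos(t), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}
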