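#' Prescribed flapping-wing kinematics
#'
#' Container for the Euler-angle schedules of an idealized forward-flight
#' flapping cycle.  The wing position angle follows
#' `phi(t) = 0.5 * Phi * cos(2 pi f t)` (so the cycle starts at the dorsal
#' reversal and the first half-cycle is the downstroke), the deviation
#' angle is constant (zero by default), and the feathering angle holds a
#' constant plateau on each half-stroke (`alpha_up` on the upstroke,
#' `alpha_down` on the downstroke) with a C1 half-cosine blend across a
#' reversal window of width `reversal_fraction * T` centered on each
#' stroke reversal.
#'
#' Sign conventions (documented here because they are often left
#' implicit): the downstroke is `phi` decreasing; `alpha` is measured from
#' the stroke plane and is positive nose-up.  The stroke plane is inclined
#' `beta` degrees against the longitudinal body axis and the whole body is
#' pitched nose-up by `chi` degrees, so in the lab frame the stroke plane
#' makes an angle `chi - beta` with the horizontal.
#'
#' @param Phi peak-to-peak stroke amplitude, degrees (0 < Phi <= 180).
#' @param f flapping frequency, Hz.
#' @param theta0 constant deviation angle, degrees.
#' @param alpha_up,alpha_down feathering plateaus, degrees.
#' @param reversal_fraction width of each feathering reversal window as a
#'   fraction of the period (0 < x < 0.5).
#' @param beta stroke-plane inclination against the body axis, degrees.
#' @param chi body inclination against horizontal, degrees.
#' @return object of class `wing_kinematics`.
#' @export
wing_kinematics <- function(Phi = 140, f = 213, theta0 = 0,
                            alpha_up = 60, alpha_down = -30,
                            reversal_fraction = 0.22,
                            beta = 20, chi = 45) {
  if (!(Phi > 0 && Phi <= 180)) stop("argument error: need 0 < Phi <= 180 deg")
  if (!(f > 0)) stop("argument error: need f > 0")
  if (!(reversal_fraction > 0 && reversal_fraction < 0.5)) {
    stop("argument error: need 0 < reversal_fraction < 0.5")
  }
  structure(list(Phi = Phi, f = f, theta0 = theta0,
                 alpha_up = alpha_up, alpha_down = alpha_down,
                 reversal_fraction = reversal_fraction,
                 beta = beta, chi = chi, T = 1 / f),
            class = "wing_kinematics")
}

#' @export
print.wing_kinematics <- function(x, ...) {
  cat(sprintf(
    "<wing_kinematics> Phi=%g deg, f=%g Hz, alpha up/down=%g/%g deg, beta=%g, chi=%g\n",
    x$Phi, x$f, x$alpha_up, x$alpha_down, x$beta, x$chi))
  invisible(x)
}

#' Wing Euler angles at time t
#'
#' @param t time in seconds (vectorized), t >= 0.
#' @param kin a [wing_kinematics()].
#' @return data frame with columns `t`, `phi`, `theta`, `alpha` (degrees).
#' @export
wing_angles <- function(t, kin) {
  stopifnot(inherits(kin, "wing_kinematics"), all(t >= 0))
  tau <- (t * kin$f) %% 1                     # cycle phase in [0, 1)
  phi <- 0.5 * kin$Phi * cos(2 * pi * tau)
  w <- kin$reversal_fraction
  h <- w / 2
  blend <- function(xi) (1 - cos(pi * xi)) / 2  # C1 half-cosine, 0 -> 1
  alpha <- numeric(length(tau))
  down <- tau >= h & tau <= 0.5 - h            # downstroke plateau
  up <- tau >= 0.5 + h & tau <= 1 - h          # upstroke plateau
  alpha[down] <- kin$alpha_down
  alpha[up] <- kin$alpha_up
  vent <- tau > 0.5 - h & tau < 0.5 + h        # ventral reversal: down -> up
  xi <- (tau[vent] - (0.5 - h)) / w
  alpha[vent] <- kin$alpha_down + (kin$alpha_up - kin$alpha_down) * blend(xi)
  dors <- tau < h | tau > 1 - h                # dorsal reversal: up -> down
  xi <- ((tau[dors] + h) %% 1) / w
  alpha[dors] <- kin$alpha_up + (kin$alpha_down - kin$alpha_up) * blend(xi)
  data.frame(t = t, phi = phi, theta = rep(kin$theta0, length(t)),
             alpha = alpha)
}

#' Rigid wing transform at time t
#'
#' Composes body incline, stroke-plane tilt and the instantaneous
#' position/deviation/feathering rotations about the wing hinge.  A
#' wing-frame point `x_w` (chord along +x, span along +y outboard of the
#' right wing) maps to the lab frame as `hinge + Rot %*% x_w`.  The left
#' transform is the exact mirror image (`y -> -y`) of the right one.
#'
#' @param t time, seconds (scalar).
#' @param kin a [wing_kinematics()].
#' @param side `"left"` or `"right"`.
#' @param hinge lab-frame hinge point (length 3).
#' @return list with `Rot` (3x3), `hinge`, and `apply(x)`, a function
#'   mapping wing-frame points (rows) to lab-frame points.
#' @export
wing_transform <- function(t, kin, side = c("right", "left"),
                           hinge = c(0, 0, 0)) {
  side <- match.arg(side)
  ang <- wing_angles(t, kin)
  Rot <- rot_y(kin$chi) %*% rot_y(-kin$beta) %*%
    rot_z(-ang$phi) %*% rot_x(-ang$theta) %*% rot_y(ang$alpha)
  if (side == "left") {
    S <- diag(c(1, -1, 1))
    Rot <- S %*% Rot %*% S
    hinge <- hinge * c(1, -1, 1)
  }
  list(Rot = Rot, hinge = hinge,
       apply = function(x) {
         x <- matrix(x, ncol = 3)
         sweep(x %*% t(Rot), 2, hinge, "+")
       })
}

#' Wing surface velocity by differentiating the transform
#'
#' Central finite difference of [wing_transform()] in time.
#' @param t time, seconds.
#' @param kin a [wing_kinematics()].
#' @param points wing-frame points, rows.
#' @param side `"left"` or `"right"`.
#' @param hinge lab-frame hinge point.
#' @param dt differencing step, seconds; default 1e-5 of the period.
#' @return matrix of lab-frame velocities (m/s if points are in m).
#' @export
wing_surface_velocity <- function(t, kin, points, side = "right",
                                  hinge = c(0, 0, 0), dt = kin$T * 1e-5) {
  f1 <- wing_transform(t + dt, kin, side, hinge)$apply(points)
  f0 <- wing_transform(max(t - dt, 0), kin, side, hinge)$apply(points)
  (f1 - f0) / (dt + min(dt, t))
}

#' Mean wing-tip speed over a cycle
#'
#' Closed form for the default schedules: with `theta = 0` the tip (on the
#' span axis at radius R) moves only through the position angle, so the
#' cycle-mean tip speed is `(1/T) int |R dphi/dt| dt = 2 Phi f R` with
#' `Phi` in radians.
#' @param kin a [wing_kinematics()].
#' @param R wing span (tip radius), meters.
#' @export
mean_tip_speed <- function(kin, R) 2 * (kin$Phi * pi / 180) * kin$f * R

#' Dimensionless groups of the flapping-flight problem
#'
#' Reynolds number `Re = U R / nu`, reduced frequency `k = f R / U`,
#' Schmidt number `Sc = nu / D` and Peclet number `Pe = Re * Sc`.
#'
#' @param U_inf forward flight speed, m/s.
#' @param R wing span, m.
#' @param nu kinematic viscosity, m^2/s.
#' @param f flapping frequency, Hz.
#' @param D odorant diffusivity, cm^2/s (typical natural odors:
#'   1e-2 to 1e-1 cm^2/s).
#' @return list with `Re`, `k`, `Sc`, `Pe`, plus the inputs.
#' @export
dimensionless <- function(U_inf = 0.94, R = 2.87e-3, nu = 1.56e-5,
                          f = 213, D = 0.1) {
  vals <- c(U_inf = U_inf, R = R, nu = nu, f = f, D = D)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("argument error: all inputs to dimensionless() must be positive")
  }
  D_si <- D * 1e-4                    # cm^2/s -> m^2/s
  Re <- U_inf * R / nu
  k <- f * R / U_inf
  Sc <- nu / D_si
  list(Re = Re, k = k, Sc = Sc, Pe = Re * Sc,
       U_inf = U_inf, R = R, nu = nu, f = f, D = D)
}

#' Tabulated Euler-angle schedule
#'
#' Samples one flapping cycle for export or plotting.
#' @param kin a [wing_kinematics()].
#' @param n samples per cycle.
#' @param file optional path; when given the table is written as CSV.
#' @return data frame `(t, phi, theta, alpha)` (invisibly when writing).
#' @export
kinematics_schedule <- function(kin, n = 401, file = NULL) {
  t <- seq(0, kin$T, length.out = n)
  tab <- wing_angles(t, kin)
  if (!is.null(file)) {
    utils::write.csv(tab, file, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
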