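#' Desk-scale 2D sagittal analog of the flying insect
#'
#' The full 3D flapping fly is cluster-scale work; desk-scale testing
#' uses a two-dimensional analog on the sagittal plane, built from the
#' same morphology and kinematics: the body is the sagittal ellipse
#' section (inclined nose-up by `chi`), and the wing is a flat-plate
#' section of chord `c_bar` that heaves along the inclined stroke-plane
#' line with the velocity of the 70\%-span wing section and pitches with
#' the feathering schedule.  The stroke line is displaced dorsally so the
#' plate clears the body, sweeping from above/behind the thorax down to
#' ahead of and below the head -- reproducing, in section, the
#' trap-and-flick interaction between wing, body and head region.
#'
#' All lengths are in units of the span R and velocities in units of the
#' freestream speed; with that scaling the nondimensional flapping
#' frequency equals the reduced frequency k.
#'
#' @param k reduced frequency (f R / U_inf); 0 gives a body-only analog.
#' @param planform a [wing_planform()]; its S/R^2 sets the nondimensional
#'   plate chord, so a clipped planform automatically yields the clipped
#'   analog.
#' @param body_semiaxes sagittal body ellipse semi-axes, units of R.
#' @param chi,beta body inclination and stroke-plane angles, degrees.
#' @param Phi,alpha_up,alpha_down,reversal_fraction flapping schedule,
#'   degrees / cycle fraction (defaults are the standard kinematics).
#' @param r_arm span station whose velocity the plate follows (0.7).
#' @param thickness plate thickness, units of R.
#' @param stroke_offset dorsal offset of the stroke line from the
#'   shoulder hinge, units of R.
#' @return list with the static `body` shape, `pose_bodies(t)` (posed
#'   shape list at nondimensional time t), `kin` (nondimensional
#'   [wing_kinematics()]), `T_cycle`, `antenna` landmark and normal,
#'   `chord`, `U_tip` (cycle-mean tip speed, nondimensional), and
#'   helper fields for windows and probes.
#' @export
fly_analog_2d <- function(k, planform = wing_planform(),
                          body_semiaxes = c(0.435, 0.15),
                          chi = 45, beta = 20,
                          Phi = 140, alpha_up = 60, alpha_down = -30,
                          reversal_fraction = 0.22,
                          r_arm = 0.7, thickness = 0.06,
                          stroke_offset = 0.45) {
  stopifnot(k >= 0)
  a_b <- body_semiaxes[1]; b_b <- body_semiaxes[2]
  body <- ellipse_shape(a_b, b_b, center = c(0, 0), angle = -chi * pi / 180)
  # anterior apex of the inclined body: head up-front, freestream along +x
  head_dir <- c(-cos(chi * pi / 180), sin(chi * pi / 180))
  antenna <- a_b * head_dir
  chord <- planform$S / planform$R^2          # c_bar / R, nondimensional
  gamma <- (chi - beta) * pi / 180            # stroke line angle to horizontal
  s_hat <- c(cos(gamma), sin(gamma))          # +phi direction: dorsal/posterior
  m_hat <- c(-sin(gamma), cos(gamma))         # dorsal normal of the stroke line
  # dorsal-shoulder anchor of the stroke line, in the inclined body frame
  hinge <- as.vector(rot2(-chi * pi / 180) %*% c(-0.15 * a_b, 2.25 * b_b))
  stroke_center <- hinge + stroke_offset * m_hat

  if (k == 0) {
    kin <- NULL
    pose_bodies <- function(t) list(body)
    T_cycle <- 1
    U_tip <- 0
  } else {
    kin <- wing_kinematics(Phi = Phi, f = k, alpha_up = alpha_up,
                           alpha_down = alpha_down,
                           reversal_fraction = reversal_fraction,
                           beta = beta, chi = chi)
    T_cycle <- 1 / k
    U_tip <- mean_tip_speed(kin, 1)
    pose_bodies <- function(t) {
      ang <- wing_angles(t, kin)
      phi_r <- ang$phi * pi / 180
      alpha_r <- ang$alpha * pi / 180
      dphidt <- -0.5 * (Phi * pi / 180) * 2 * pi * k * sin(2 * pi * k * t)
      eps <- 1e-4 * T_cycle
      alpha2 <- wing_angles(t + eps, kin)$alpha * pi / 180
      alpha1 <- wing_angles(max(t - eps, 0), kin)$alpha * pi / 180
      omega <- (alpha2 - alpha1) / (eps + min(eps, t))
      ctr <- stroke_center + r_arm * phi_r * s_hat
      vel <- r_arm * dphidt * s_hat
      wing <- plate_shape(chord, thickness, center = ctr,
                          angle = gamma + alpha_r, vel = vel, omega = omega)
      list(body, wing)
    }
  }
  # sweep extents for grid-box sizing
  smax <- if (k == 0) 0 else r_arm * 0.5 * Phi * pi / 180
  ends <- rbind(stroke_center + smax * s_hat, stroke_center - smax * s_hat)
  margin <- chord / 2 + 0.15
  list(body = body, pose_bodies = pose_bodies, kin = kin,
       T_cycle = T_cycle, U_tip = U_tip, chord = chord,
       antenna = antenna, antenna_normal = head_dir,
       stroke_center = stroke_center, s_hat = s_hat, r_arm = r_arm,
       sweep_x = range(ends[, 1]) + c(-margin, margin),
       sweep_y = range(ends[, 2]) + c(-margin, margin),
       body_semiaxes = body_semiaxes, chi = chi, beta = beta)
}

rot2 <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)

#' Minimum wing-body clearance of the 2D analog over a cycle
#'
#' Samples the plate boundary at many cycle phases and returns the
#' minimum signed distance to the body: positive means the bodies never
#' touch.
#' @param analog a [fly_analog_2d()] result (with a wing).
#' @param n_phase phases sampled over one cycle.
#' @export
analog_clearance <- function(analog, n_phase = 72) {
  stopifnot(!is.null(analog$kin))
  ts <- seq(0, analog$T_cycle, length.out = n_phase + 1L)[-1]
  mind <- Inf
  for (t in ts) {
    w <- analog$pose_bodies(t)[[2]]
    b <- shape_boundary(w, 80)
    mind <- min(mind, min(shape_sdf(analog$body, b$points[, 1], b$points[, 2])))
  }
  mind
}
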