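test_that("wing angle schedules match the prescribed kinematics", {
  kin <- wing_kinematics()
  a <- wing_angles(c(0, kin$T / 2, 0.25 * kin$T, 0.75 * kin$T), kin)
  expect_equal(a$phi[1], 70)            # cos(0) = 1, Phi = 140
  expect_equal(a$phi[2], -70)           # cos(pi) = -1
  expect_equal(a$alpha[3], -30)         # mid-downstroke plateau
  expect_equal(a$alpha[4], 60)          # mid-upstroke plateau
  expect_equal(a$theta, rep(0, 4))
})

test_that("position angle has zero mean and full peak-to-peak range; alpha is continuous and periodic", {
  kin <- wing_kinematics()
  t <- seq(0, kin$T, length.out = 8001)[-8001]
  ang <- wing_angles(t, kin)
  expect_equal(mean(ang$phi), 0, tolerance = 1e-10)
  expect_equal(diff(range(ang$phi)), kin$Phi)
  # continuity: largest step bounded by the blend slope times dt
  expect_lt(max(abs(diff(ang$alpha))), 0.1)
  # T-periodicity
  ang2 <- wing_angles(t + 3 * kin$T, kin)
  expect_equal(ang2$alpha, ang$alpha, tolerance = 1e-9)
  # plateaus held exactly outside the reversal windows
  tau <- (t * kin$f) %% 1
  plat <- tau > 0.12 & tau < 0.38
  expect_true(all(ang$alpha[plat] == -30))
})

test_that("wing transform composes correctly and mirrors left/right", {
  kin0 <- wing_kinematics(Phi = 140, f = 1, beta = 0, chi = 0,
                          alpha_up = 0, alpha_down = 0)
  tr <- wing_transform(0.25, kin0, "right")   # phi = 0 at quarter cycle
  expect_equal(tr$Rot, diag(3), tolerance = 1e-12)
  kin <- wing_kinematics()
  p <- matrix(c(0.3, 1.2, 0.1), 1)
  h <- c(0.1, 0.2, 0.3)
  lhs <- wing_transform(0.0013, kin, "left", h)$apply(p %*% diag(c(1, -1, 1)))
  rhs <- wing_transform(0.0013, kin, "right", h)$apply(p) %*% diag(c(1, -1, 1))
  expect_equal(lhs, rhs, tolerance = 1e-12)
  expect_error(wing_transform(0, kin, "up"), "arg")
})

test_that("numerically integrated tip speed matches the closed form", {
  kin <- wing_kinematics()
  R <- 2.87e-3
  tt <- seq(0, kin$T, length.out = 2001)[-1]
  sp <- vapply(tt, function(ti) {
    sqrt(sum(wing_surface_velocity(ti, kin, c(0, R, 0))^2))
  }, 1)
  expect_equal(mean(sp), mean_tip_speed(kin, R), tolerance = 5e-3)
})

test_that("dimensionless groups reproduce the printed definitions", {
  d <- dimensionless(U_inf = 0.94, R = 2.87e-3, nu = 1.56e-5, f = 213, D = 0.1)
  expect_equal(round(d$Re), 173)
  expect_equal(round(d$k, 2), 0.65)
  expect_equal(d$Pe, d$Re * d$Sc)
  # Sc = 1 gives Pe = Re
  d2 <- dimensionless(U_inf = 0.94, R = 2.87e-3, nu = 1.56e-5, f = 213,
                      D = 1.56e-5 * 1e4)
  expect_equal(d2$Sc, 1)
  expect_equal(d2$Pe, d2$Re)
  expect_error(dimensionless(U_inf = -1), "positive")
})

test_that("nondimensional kinematics depend only on k (dynamic similarity)", {
  # same k and Re from different f, U pairs: identical nondimensional angles
  k <- 0.65
  f1 <- 213; U1 <- 2.87e-3 * f1 / k
  f2 <- 426; U2 <- 2.87e-3 * f2 / k
  kin1 <- wing_kinematics(f = f1); kin2 <- wing_kinematics(f = f2)
  tau <- seq(0, 1, length.out = 101)
  a1 <- wing_angles(tau / f1, kin1)
  a2 <- wing_angles(tau / f2, kin2)
  expect_equal(a1$phi, a2$phi, tolerance = 1e-12)
  expect_equal(a1$alpha, a2$alpha, tolerance = 1e-12)
})

test_that("kinematics schedule export writes a readable CSV", {
  f <- tempfile(fileext = ".csv")
  kinematics_schedule(wing_kinematics(), n = 101, file = f)
  tab <- utils::read.csv(f)
  expect_named(tab, c("t", "phi", "theta", "alpha"))
  expect_equal(nrow(tab), 101)
})
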