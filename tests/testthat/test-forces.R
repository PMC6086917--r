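test_that("uniform pressure over a closed body gives zero net force", {
  g <- build_grid(list(c(-2, 2), c(-2, 2)), list(c(-1, 1), c(-1, 1)), 0.05)
  sol <- build_solver(g, solver_settings(Re = 100, dt = 0.01, U_inf = 0))
  st <- flow_state(g, u = 0, v = 0, p = 2.5)
  body <- ellipse_shape(0.5, 0.3, angle = 0.4)
  f <- surface_forces(st, body, sol)
  expect_lt(max(abs(f$F)), 1e-3 * 2.5)     # closed-surface identity, discrete
  # per-face decomposition sums to the totals exactly
  expect_equal(sum(f$per_face$dFy), f$F_L)
  expect_equal(-sum(f$per_face$dFx), f$F_T)
})

test_that("flat plate normal to a stream feels a force along the stream", {
  g <- build_grid(list(c(-3, 5), c(-2, 2)), list(c(-1, 1.5), c(-1, 1)), 0.04)
  sol <- build_solver(g, solver_settings(Re = 100, dt = 0.008))
  plate <- plate_shape(0.5, 0.08, angle = pi / 2)    # broadside to the flow
  st <- flow_state(g, u = 1)
  for (i in 1:150) st <- step_flow(sol, st, list(plate))
  f <- surface_forces(st, plate, sol)
  # force within 2 degrees of the plate normal (the x axis)
  ang <- atan2(abs(f$F[2]), abs(f$F[1])) * 180 / pi
  expect_lt(ang, 2)
  expect_gt(f$F[1], 0)
})

test_that("coefficients apply the printed normalizations", {
  S <- 0.3; U <- 3.2
  co <- coefficients(F_L = 0.5 * U^2 * S, F_T = 0, P_aero = 0.5 * U^3 * S,
                     U_tip = U, S = S)
  expect_equal(co$C_L, 1)
  expect_equal(co$C_PW, 1)
  expect_equal(co$C_F, 1)
  expect_equal(co$C_F_over_C_PW, 1)
  # doubling S at fixed force halves C_L
  co2 <- coefficients(F_L = 0.5 * U^2 * S, F_T = 0, P_aero = 1,
                      U_tip = U, S = 2 * S)
  expect_equal(co2$C_L, 0.5)
  expect_error(coefficients(1, 0, 1, U_tip = 0, S = 1), "argument error")
})

test_that("aerodynamic power identities hold", {
  g <- build_grid(list(c(-3, 5), c(-2, 2)), list(c(-1, 1.5), c(-1, 1)), 0.05)
  sol <- build_solver(g, solver_settings(Re = 100, dt = 0.01))
  body <- ellipse_shape(0.4, 0.25)
  st <- flow_state(g, u = 1)
  for (i in 1:100) st <- step_flow(sol, st, list(body))
  # stationary body: zero power
  expect_equal(aero_power(st, body, sol), 0)
  # rigid translation against the net force: P = -F . V
  V <- c(-0.6, 0.25)
  moving <- pose_shape(body, vel = V)
  f <- surface_forces(st, moving, sol)
  P <- aero_power(st, moving, sol)
  expect_equal(P, -sum(f$F * V), tolerance = 1e-10)
})

test_that("hovering validation case produces positive mean lift with bounded coefficients", {
  # horizontal-stroke hovering with 180-degree stroke amplitude and
  # 50-degree midstroke angle of attack at Re = 136
  res <- sane_dickinson_case(n_cycles = 2, delta = 0.05)
  last <- res$series[res$series$cycle == 2, ]
  expect_gt(mean(last$C_L), 0)
  expect_lt(max(abs(last$C_L)), 5)
  expect_true(all(is.finite(last$C_L)))
})
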