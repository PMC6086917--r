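test_that("particle advection matches analytic fields", {
  g <- build_grid(list(c(-2, 2), c(-2, 2)), list(c(-1.5, 1.5), c(-1.5, 1.5)), 0.05)
  # uniform flow: displacement exactly U * t
  stU <- flow_state(g, u = 0.7, v = -0.2)
  p <- particle_set(rbind(c(0, 0), c(-1, 0.5)))
  nst <- 20; dt <- 0.01
  for (i in 1:nst) p <- advect_particles(p, stU, g, dt)
  expect_equal(p$positions,
               rbind(c(0, 0), c(-1, 0.5)) +
                 matrix(rep(c(0.7, -0.2) * nst * dt, each = 2), 2),
               tolerance = 1e-12)
  # zero field: no motion
  st0 <- flow_state(g, u = 0, v = 0)
  q <- particle_set(c(0.3, 0.4))
  q2 <- advect_particles(q, st0, g, 0.5)
  expect_identical(q2$positions, q$positions)
  # solid-body rotation: radius conserved to 1e-3 per revolution
  X <- matrix(g$axes[[1]]$xc, g$axes[[1]]$n, g$axes[[2]]$n)
  Y <- matrix(g$axes[[2]]$xc, g$axes[[1]]$n, g$axes[[2]]$n, byrow = TRUE)
  om <- 2 * pi                              # one revolution per time unit
  strot <- flow_state(g, u = -om * Y, v = om * X)
  r0 <- 0.8
  pr <- particle_set(c(r0, 0))
  dtr <- 1 / 2000
  for (i in 1:2000) pr <- advect_particles(pr, strot, g, dtr)
  expect_equal(sqrt(sum(pr$positions^2)), r0, tolerance = 1e-3)
})

test_that("particles deactivate on domain exit and origin tags persist", {
  g <- build_grid(list(c(0, 1), c(0, 1)), list(c(0, 1), c(0, 1)), 0.05)
  st <- flow_state(g, u = 1, v = 0)
  p <- release_lines(x_release = 0.9, y_offsets = c(0.4, 0.6),
                     n_per_line = 5, spread = 0.02)
  for (i in 1:30) p <- advect_particles(p, st, g, 0.02)
  expect_false(any(p$active))
  expect_equal(unique(p$origin), c(1, 2))
  expect_length(p$active, 10)
})

test_that("particles landing inside a body are projected to its surface", {
  g <- build_grid(list(c(-2, 2), c(-2, 2)), list(c(-1, 1), c(-1, 1)), 0.05)
  st <- flow_state(g, u = 1, v = 0)
  body <- ellipse_shape(0.5, 0.5)
  p <- particle_set(c(-0.6, 0.0))
  p <- advect_particles(p, st, g, 0.3, bodies = list(body))
  expect_gte(shape_sdf(body, p$positions[1], p$positions[2]), 0)
  expect_equal(attr(p, "n_projected"), 1L)
})

test_that("odor flux follows the probe definitions", {
  g <- build_grid(list(c(-2, 2), c(-2, 2)), list(c(-1, 1), c(-1, 1)), 0.03)
  probes <- odor_probes(c(0, 0), c(0, 1), g)
  expect_equal(nrow(probes$antenna), 3)
  expect_equal(probes$antenna[2, ], c(0, 0.03))
  # zero velocity: zero flux
  st0 <- flow_state(g, u = 0, v = 0)
  expect_equal(odor_flux(st0, probes, g)$antenna, 0)
  # printed constants: C'=1, rho=1.225, |U*| = 0.94 m/s -> 1.15 kg/s/m^2
  stU <- flow_state(g, u = 1, v = 0)
  fl <- odor_flux(stU, probes, g, U_scale = 0.94)
  expect_equal(fl$antenna, 1.225 * 0.94, tolerance = 1e-12)
  expect_equal(round(fl$antenna, 2), 1.15)
  # three-probe averaging identity and nonnegativity
  set.seed(7)
  str <- flow_state(g, u = matrix(rnorm(g$axes[[1]]$n * g$axes[[2]]$n),
                                  g$axes[[1]]$n),
                    v = matrix(rnorm(g$axes[[1]]$n * g$axes[[2]]$n),
                               g$axes[[1]]$n))
  fr <- odor_flux(str, probes, g)
  expect_equal(fr$antenna, mean(fr$antenna_each))
  expect_true(all(fr$antenna_each >= 0))
  # probe inside a body: configuration error
  expect_error(odor_probes(c(0, 0), c(0, 1), g,
                           bodies = list(ellipse_shape(0.5, 0.5))),
               "configuration error")
})

test_that("Eulerian scalar advection is monotone and exact at CFL one", {
  # 1D top-hat advected one cell per step at CFL = 1: exact translation
  n <- 40
  g <- build_grid(list(c(0, 1), c(0, 0.1)), list(c(0, 1), c(0, 0.1)), 1 / n)
  st <- flow_state(g, u = 1, v = 0)
  dt <- (1 / n) / 1
  C <- matrix(1, n, 4)
  C[11:20, ] <- 2
  C1 <- advect_scalar(C, st, g, dt)
  expect_equal(C1[12:21, ], C[11:20, ], tolerance = 1e-12)
  # monotone: no new extrema beyond boundary values over many steps
  C2 <- C
  for (i in 1:25) C2 <- advect_scalar(C2, st, g, 0.5 * dt)
  expect_gte(min(C2), 1 - 1e-12)
  expect_lte(max(C2), 2 + 1e-12)
  # uniform C' = 1 stays 1 under any flow (inlet feeds 1)
  Cu <- matrix(1, n, 4)
  expect_equal(advect_scalar(Cu, st, g, dt), Cu)
  # CFL violation rejected
  expect_error(advect_scalar(C, st, g, 10 * dt), "CFL")
})
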