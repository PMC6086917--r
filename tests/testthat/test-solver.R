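test_that("uniform inflow with no bodies is an exact steady solution", {
  g <- build_grid(list(c(0, 4), c(0, 2)), list(c(1, 3), c(0.5, 1.5)), 0.1)
  sol <- build_solver(g, solver_settings(Re = 100, dt = 0.02))
  st <- flow_state(g, u = 1)
  for (i in 1:25) st <- step_flow(sol, st)
  expect_lt(max(abs(st$u - 1)), 1e-12)
  expect_lt(max(abs(st$v)), 1e-12)
  expect_lt(st$divergence, 1e-12)
})

test_that("Taylor-Green kinetic energy decays at the viscous rate", {
  Re <- 100
  st <- tg_decay_case()
  g <- tg_grid(64)
  u0 <- -outer(cos(g$axes[[1]]$xc), sin(g$axes[[2]]$xc))
  v0 <- outer(sin(g$axes[[1]]$xc), cos(g$axes[[2]]$xc))
  decay <- sum(st$u^2 + st$v^2) / sum(u0^2 + v0^2)
  expect_equal(decay, exp(-4 * 1 / Re), tolerance = 0.01)
  expect_lt(st$divergence, 1e-6)
})

test_that("temporal self-convergence order is about two", {
  tg <- tg_temporal_cases()
  e1 <- sqrt(sum((tg[[1]]$u - tg[[2]]$u)^2))
  e2 <- sqrt(sum((tg[[2]]$u - tg[[3]]$u)^2))
  expect_gte(log2(e1 / e2), 1.9)
})

test_that("spatial convergence order is about two on the refinement triple", {
  errs <- tg_spatial_errors()
  orders <- log2(errs[-3] / errs[-1])
  expect_true(all(orders >= 1.9))
})

test_that("post-projection divergence stays below 1e-6 with a moving body", {
  mv <- moving_body_divergence()
  expect_lt(max(mv$divs), 1e-6)
  expect_true(all(table(mv$state$classification) > 0))
})

test_that("mirror symmetry: symmetric body gives side force at roundoff level", {
  mc <- mirror_case()
  st <- mc$state
  f <- surface_forces(st, mc$body, mc$solver)
  expect_lt(abs(f$F[2]), 1e-10)
  # velocity field symmetric/antisymmetric about y = 0
  ny <- mc$grid$axes[[2]]$n
  expect_lt(max(abs(st$u - st$u[, ny:1])), 1e-10)
  expect_lt(max(abs(st$v + st$v[, ny:1])), 1e-10)
})

test_that("cylinder drag at Re=40 agrees with the refined-grid reference", {
  # reference: same solver, identical domain/protocol, delta = 0.025
  # (refinement by 2 in each direction), run to t = 30: Cd_ref = 1.6405.
  cd_ref <- 1.6405
  g <- build_grid(list(c(-8, 16), c(-8, 8)), list(c(-1.5, 3), c(-1.5, 1.5)), 0.05)
  dt <- suggest_dt(g, 1.6, 0.5)
  sol <- build_solver(g, solver_settings(Re = 40, dt = dt))
  cyl <- ellipse_shape(0.5, 0.5)
  st <- flow_state(g, u = 1)
  for (i in seq_len(round(30 / dt))) st <- step_flow(sol, st, list(cyl))
  cd <- 2 * surface_forces(st, cyl, sol)$F[1]
  expect_equal(cd, cd_ref, tolerance = 0.05)
})

test_that("run_cycles handles the degenerate and steady cases", {
  g <- build_grid(list(c(-2, 4), c(-1.5, 1.5)), list(c(-1, 1), c(-1, 1)), 0.08)
  sol <- build_solver(g, solver_settings(Re = 100, dt = 0.02))
  st <- flow_state(g, u = 1)
  # n_cycles = 0: input state back, empty series
  r0 <- run_cycles(sol, st, function(t) list(), 1, 0)
  expect_identical(r0$state, st)
  expect_equal(nrow(r0$series), 0)
  # steady body-only problem: force trace converges to a constant
  body <- ellipse_shape(0.4, 0.25)
  obs <- list(f = function(state, bodies, solver) {
    c(Fx = surface_forces(state, bodies[[1]], solver)$F[1])
  })
  r <- run_cycles(sol, st, function(t) list(body), 1, 8, observers = obs,
                  observe_every = 5L)
  last2 <- r$series[r$series$cycle >= 7, "f.Fx"]
  expect_lt(stats::sd(last2) / abs(mean(last2)), 0.01)
  expect_lt(r$periodicity, 0.01)
})

test_that("non-finite states are caught with a divergence error", {
  g <- build_grid(list(c(0, 2), c(0, 1)), list(c(0, 2), c(0, 1)), 0.1)
  sol <- build_solver(g, solver_settings(Re = 100, dt = 0.01))
  st <- flow_state(g, u = 1)
  st$u[5, 5] <- NaN
  expect_error(step_flow(sol, st), "divergence error")
})
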