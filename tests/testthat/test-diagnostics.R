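test_that("Q-criterion closed forms: uniform, rotation, shear", {
  g <- build_grid(list(c(-1, 1), c(-1, 1)), list(c(-1, 1), c(-1, 1)), 0.05)
  nx <- g$axes[[1]]$n; ny <- g$axes[[2]]$n
  X <- matrix(g$axes[[1]]$xc, nx, ny)
  Y <- matrix(g$axes[[2]]$xc, nx, ny, byrow = TRUE)
  expect_lt(max(abs(q_criterion(flow_state(g, u = 1, v = 0), g))), 1e-12)
  om <- 1.7
  Qrot <- q_criterion(flow_state(g, u = -om * Y, v = om * X), g)
  expect_equal(max(abs(Qrot - om^2)), 0, tolerance = 1e-9)
  gam <- 2.3                                 # plane Couette u = gam * y
  Qshear <- q_criterion(flow_state(g, u = gam * Y, v = 0), g)
  expect_true(all(Qshear <= 1e-12))
})

test_that("circulation recovers the Lamb-Oseen closed form within 1 percent", {
  g <- build_grid(list(c(-2, 2), c(-2, 2)), list(c(-1.5, 1.5), c(-1.5, 1.5)), 0.02)
  G0 <- 1.8
  st <- lamb_oseen_state(g, Gamma0 = G0, rc = 0.1)
  win <- c(-1.2, 1.2, -1.2, 1.2)             # patch radius >> core radius
  G <- circulation(st, g, win, threshold = 0)
  expect_equal(as.numeric(G), G0, tolerance = 0.01)
  # Stokes-theorem self-check: boundary line integral agrees
  Gline <- circulation_line_integral(st, g, win, n_samples = 400)
  expect_equal(Gline, as.numeric(G), tolerance = 0.02)
  # mirrored flow flips the sign exactly
  stm <- st
  stm$u <- st$u[, rev(seq_len(ncol(st$u)))]
  stm$v <- -st$v[, rev(seq_len(ncol(st$v)))]
  Gm <- circulation(stm, g, win, threshold = 0)
  expect_equal(as.numeric(Gm), -as.numeric(G), tolerance = 1e-10)
})

test_that("degenerate circulation inputs warn and return zero", {
  g <- build_grid(list(c(-1, 1), c(-1, 1)), list(c(-1, 1), c(-1, 1)), 0.05)
  st0 <- flow_state(g, u = 0, v = 0)
  expect_warning(G <- circulation(st0, g, c(-0.5, 0.5, -0.5, 0.5)), "empty|zero")
  expect_equal(as.numeric(G), 0)
  expect_warning(circulation(st0, g, c(5, 6, 5, 6)), "window")
})
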