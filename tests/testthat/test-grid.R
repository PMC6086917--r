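test_that("paper-scale grid preset lands near the production point count", {
  g <- paper_scale_grid()
  target <- 289 * 137 * 249
  expect_lt(abs(g$npoints - target) / target, 0.15)
  expect_equal(g$delta, 0.0125)
  # spacing uniform inside the box, stretching capped outside
  ax <- g$axes[[1]]
  expect_lt(diff(range(ax$dx[ax$in_box])), 1e-12)
  ratios <- ax$dx[-1] / ax$dx[-length(ax$dx)]
  expect_lte(max(ratios), 1.2 + 1e-9)
  expect_true(all(diff(ax$xf) > 0))
})

test_that("degenerate grid cases behave as specified", {
  # box == domain: exactly uniform with N+1 faces
  g <- build_grid(list(c(0, 1), c(0, 2)), list(c(0, 1), c(0, 2)), 1 / 32)
  expect_length(g$axes[[1]]$xf, 33)
  expect_lt(diff(range(g$axes[[1]]$dx)), 1e-14)
  # halving delta doubles the in-box cell count per axis
  g1 <- build_grid(list(c(-2, 2), c(-2, 2)), list(c(-1, 1), c(-1, 1)), 0.1)
  g2 <- build_grid(list(c(-2, 2), c(-2, 2)), list(c(-1, 1), c(-1, 1)), 0.05)
  expect_equal(sum(g2$axes[[1]]$in_box), 2 * sum(g1$axes[[1]]$in_box))
  # invalid inputs
  expect_error(build_grid(list(c(0, 1), c(0, 1)), list(c(-1, 2), c(0, 1)), 0.1),
               "inside the domain")
  expect_error(build_grid(list(c(0, 1), c(0, 1)), list(c(0, 1), c(0, 1)), 0.1,
                          stretch_ratio = 1.5), "stretch_ratio")
  expect_error(build_grid(list(c(0, 100), c(0, 1)), list(c(0, 0.5), c(0, 1)),
                          0.01, stretch_ratio = 1.01, max_outer_cells = 10),
               "cannot reach")
})

test_that("derivatives annihilate constants and are second order in the refined box", {
  g <- build_grid(list(c(-2, 2), c(-2, 2)), list(c(-1, 1), c(-1, 1)), 0.05)
  const <- matrix(3.3, g$axes[[1]]$n, g$axes[[2]]$n)
  expect_lt(max(abs(grid_deriv(const, g, 1))), 1e-12)
  expect_lt(max(abs(grid_deriv(const, g, 2))), 1e-12)
  errs <- sapply(c(0.04, 0.02, 0.01), function(d) {
    gg <- build_grid(list(c(-2, 2), c(-2, 2)), list(c(-1, 1), c(-1, 1)), d)
    x <- gg$axes[[1]]$xc; y <- gg$axes[[2]]$xc
    f <- outer(sin(2 * x), cos(2 * y))
    ex <- outer(2 * cos(2 * x), cos(2 * y))
    m <- gg$axes[[1]]$in_box
    max(abs(grid_deriv(f, gg, 1) - ex)[m, gg$axes[[2]]$in_box])
  })
  orders <- log2(errs[-3] / errs[-1])
  expect_true(all(orders >= 1.9))
})
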