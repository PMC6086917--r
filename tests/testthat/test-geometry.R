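test_that("default planform reproduces the standard morphometrics", {
  pf <- wing_planform()
  expect_equal(pf$S, 2.59, tolerance = 1e-9)
  expect_equal(pf$R, 2.87)
  expect_equal(pf$c_bar, 2.59 / 2.87, tolerance = 1e-9)
  expect_equal(diff(range(pf$outline[, 2])), pf$R)
  # root leading edge at the origin
  expect_equal(unname(pf$outline[1, ]), c(0, 0))
})

test_that("trailing-edge clip yields the modified wing morphometrics", {
  pf <- wing_planform()
  xc <- default_clip_line(pf)
  pc <- clip_trailing_edge(pf, xc)
  expect_equal(pc$S, 2.09, tolerance = 0.01)
  expect_equal(round(pc$c_bar, 2), 0.73)
  # removed area ~20% of the original, span unchanged
  expect_equal((pf$S - pc$S) / pf$S, 0.193, tolerance = 1e-6)
  expect_equal(diff(range(pc$outline[, 2])), pf$R)
  # area bookkeeping: clipped + removed = original
  expect_equal(pc$S + (pf$S - pc$S), pf$S)
  expect_lte(pc$S, pf$S)
})

test_that("degenerate and invalid clips are handled", {
  pf <- wing_planform()
  # curve at/behind the trailing edge: identity
  expect_identical(clip_trailing_edge(pf, max(pf$x_te) + 0.5), pf)
  # curve crossing the leading edge: error
  expect_error(clip_trailing_edge(pf, min(pf$x_le) - 0.1), "clipping error")
  # a polyline that dips in and out of the trailing edge more than twice
  y <- pf$s * pf$R
  wavy <- cbind(y, 0.35 + 0.35 * cos(6 * pi * pf$s))
  expect_error(clip_trailing_edge(pf, wavy), "exactly twice")
})

test_that("fly geometry meshes have the right areas and symmetry", {
  fly <- make_fly_geometry()
  pf <- fly$planform
  expect_equal(mesh_area(fly$wing_right), pf$S, tolerance = 0.01)
  expect_true(mesh_is_closed(fly$body))
  # left wing is the vertex-for-vertex mirror image of the right wing
  expect_equal(fly$wing_left$vertices,
               sweep(fly$wing_right$vertices, 2, c(1, -1, 1), "*"))
  # antenna at the anterior head tip on the sagittal plane, above center
  ant <- fly$body$landmarks$antenna
  expect_equal(ant[2], 0)
  expect_lt(ant[1], 0)
  expect_gt(ant[3], 0)
  # landmark lies on the ellipsoid surface
  a <- fly$body_axes
  local <- rot_y(-fly$chi) %*% ant
  expect_equal(sum((local / a)^2), 1, tolerance = 1e-8)
})

test_that("ellipsoid mesh area matches the analytic value and wing area converges", {
  axes <- c(1.25, 0.42, 0.45)
  m <- ellipsoid_mesh(axes, 48, 72)
  expect_equal(mesh_area(m), ellipsoid_area_thomsen(axes), tolerance = 0.02)
  # monotone error decrease with refinement
  errs <- sapply(c(8, 16, 32), function(res) {
    abs(mesh_area(make_fly_geometry(resolution = res)$wing_right) - 2.59)
  })
  expect_true(all(diff(errs) < 0))
  # too-coarse resolution refused
  expect_error(make_fly_geometry(resolution = 4), "too coarse")
})

test_that("STL and OBJ round-trips preserve the mesh", {
  fly <- make_fly_geometry(resolution = 8)
  f <- tempfile(fileext = ".stl")
  write_stl(fly$body, f)
  back <- read_stl(f)
  expect_equal(mesh_area(back), mesh_area(fly$body), tolerance = 1e-6)
  expect_true(mesh_is_closed(back))
  fo <- tempfile(fileext = ".obj")
  write_obj(fly$wing_right, fo)
  expect_true(any(grepl("^f ", readLines(fo))))
  fp <- tempfile(fileext = ".csv")
  write_polyline_csv(fly$planform$outline, fp)
  poly <- as.matrix(utils::read.csv(fp))
  expect_equal(polygon_area(poly), fly$planform$S, tolerance = 1e-9)
})
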