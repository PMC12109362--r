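test_that("geometry invariants are enforced with informative errors", {
  expect_error(make_geometry(30, 40, 200, 100, 90), "D2 < D1")
  expect_error(make_geometry(30, 8, 100, 100, 90), "L1 >= 5\\*D1")
  expect_error(make_geometry(30, 8, 200, 30, 90), "L2 >= 5\\*D2")
  expect_error(make_geometry(30, 8, 200, 100, 0), "theta")
  expect_error(make_geometry(30, 8, 200, 100, 190), "theta")
  expect_error(make_geometry(30, 8, 200, 100, 90, entry_depth = 35,
                             stent_present = TRUE), "entry_depth")
  expect_error(make_geometry(30, 8, 200, 100, 90, entry_depth = 5,
                             stent_present = TRUE, wall_thickness = 0),
               "wall_thickness")
  expect_error(make_geometry(30, 8, 200, 100, 90, bevel = TRUE),
               "bevel requires stent")
  g <- make_geometry(30, 8, 200, 100, 90, 10, stent_present = TRUE)
  expect_s3_class(g, "stent_geometry")
  expect_identical(default_scene(90, 0, FALSE)$stent_present, FALSE)
})

test_that("bevel_cut needs a protruding tip and is idempotent", {
  expect_error(bevel_cut(default_scene(90, 10, stent_present = FALSE)),
               "no protruding stent")
  expect_error(bevel_cut(default_scene(90, 0, stent_present = TRUE)),
               "nothing to cut")
  g <- default_scene(90, 15, stent_present = TRUE)
  b1 <- bevel_cut(g)
  b2 <- bevel_cut(b1)
  expect_true(b1$bevel)
  grid <- make_grid(g, 1)
  expect_identical(rasterize(b1, grid)$label, rasterize(b2, grid)$label)
  # the bevel removes upstream-side wall material only
  m0 <- rasterize(g, grid)
  m1 <- rasterize(b1, grid)
  expect_lt(protrusion_cell_count(m1), protrusion_cell_count(m0))
})

test_that("rasterized straight channel has only channel labels", {
  g <- make_geometry(30, 8, 200, 100, 90, branch_present = FALSE)
  m <- rasterize(g, make_grid(g, 1))
  cnt <- mask_label_counts(m)
  expect_identical(unname(cnt[c("wall", "solid", "branch_outlet")]),
                   c(0L, 0L, 0L))
  expect_gt(cnt[["fluid"]], 0)
})

test_that("default scene at h = 1 mm has D1/h = 30 inlet cells", {
  m <- rasterize(default_scene(), make_grid(default_scene(), 1))
  expect_identical(unname(mask_label_counts(m)[["inlet"]]), 30L)
  expect_error(make_grid(default_scene(), 1.5), "too coarse")
})

test_that("protruding tip at theta = 105, L = 5 puts solid cells in the lumen", {
  g <- default_scene(theta = 105, entry_depth = 5, stent_present = TRUE)
  m <- rasterize(g, make_grid(g, 1))
  expect_gt(protrusion_cell_count(m), 0)
  # independent point predicate on every solid cell centre
  sol <- which(m$label == 2L, arr.ind = TRUE)
  xc <- (sol[, 1] - 0.5) * m$h
  yc <- (sol[, 2] - 0.5) * m$h
  th <- 105 * pi / 180
  s <- (xc - 100) * (-cos(th)) + (yc - 30) * sin(th)
  tt <- (xc - 100) * sin(th) + (yc - 30) * cos(th)
  expect_true(all(yc < 30))            # strictly inside the aortic lumen
  expect_true(all(s >= -5 - 1e-9))     # no deeper than the entry depth
  expect_true(all(abs(tt) > 4))        # outside the lumen band
})

test_that("mirror symmetry: theta and 180 - theta masks are congruent", {
  for (th in c(45, 75)) {
    g1 <- default_scene(theta = th, entry_depth = 10, stent_present = TRUE)
    g2 <- default_scene(theta = 180 - th, entry_depth = 10,
                        stent_present = TRUE)
    c1 <- mask_label_counts(rasterize(g1, make_grid(g1, 1)))
    c2 <- mask_label_counts(rasterize(g2, make_grid(g2, 1)))
    expect_identical(c1, c2)
  }
})

test_that("protruding solid cell count is non-decreasing in entry depth", {
  counts <- vapply(c(0, 5, 10, 15), function(L) {
    g <- default_scene(theta = 90, entry_depth = L,
                       stent_present = L > 0)
    protrusion_cell_count(rasterize(g, make_grid(g, 1)))
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("fluid area converges with grid refinement", {
  g <- default_scene(theta = 105, entry_depth = 10, stent_present = TRUE)
  area <- vapply(c(2 / 3, 0.5, 0.25), function(h) {
    m <- rasterize(g, make_grid(g, h), check = FALSE)
    sum(m$label == 1L | m$label >= 3L) * h^2
  }, numeric(1))
  err <- abs(area[1:2] - area[3])
  expect_true(all(diff(err) < 0))
})

test_that("fluid connectivity validation passes for all scene variants", {
  for (g in list(default_scene(45, 10, TRUE), default_scene(135, 15, TRUE),
                 bevel_cut(default_scene(90, 15, TRUE)),
                 default_scene(90, 0, FALSE))) {
    expect_true(validate_mask(rasterize(g, make_grid(g, 1))))
  }
})

test_that("geometry config files round-trip", {
  g <- default_scene(theta = 105, entry_depth = 5, stent_present = TRUE)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_geometry_config(g, path)
  g2 <- read_geometry_config(path)
  for (f in c("D1", "D2", "L1", "L2", "theta", "entry_depth",
              "wall_thickness")) {
    expect_equal(g2[[f]], g[[f]])
  }
  expect_identical(g2$stent_present, TRUE)
  expect_identical(g2$bevel, FALSE)
})

test_that("mask exporters write parseable files", {
  g <- make_geometry(30, 8, 200, 100, 90, branch_present = FALSE)
  m <- rasterize(g, make_grid(g, 2))
  csv <- withr::local_tempfile(fileext = ".csv")
  vtk <- withr::local_tempfile(fileext = ".vtk")
  write_mask_csv(m, csv)
  df <- read.csv(csv)
  expect_identical(nrow(df), m$nx * m$ny)
  expect_setequal(unique(df$label), c("fluid", "inlet", "aortic_outlet"))
  write_vtk_mask(m, vtk)
  expect_identical(readLines(vtk, n = 1), "# vtk DataFile Version 3.0")
})
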