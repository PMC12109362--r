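# Branch-flow observables: boundary fluxes, classification, WSS,
# recirculation metrics.

zero_field <- function(mask) {
  structure(list(u = matrix(0, mask$nx + 1, mask$ny),
                 v = matrix(0, mask$nx, mask$ny + 1),
                 p = matrix(0, mask$nx, mask$ny),
                 converged = TRUE, mask = mask,
                 fluid = fluid_properties(), bcs = boundary_conditions()),
            class = "flow_field")
}

test_that("boundary fluxes: zero field gives zero, plug inlet closed form", {
  g <- default_scene()
  m <- rasterize(g, make_grid(g, 1))
  z <- zero_field(m)
  expect_identical(boundary_flux(z, m, "branch_outlet"), 0)
  expect_identical(boundary_flux(z, m, "aortic_outlet"), 0)
  cc <- channel_case()
  qin <- boundary_flux(cc$field, cc$mask, "inlet")
  expect_equal(qin, 1055 * 0.8 * 30 / 1000)  # rho U D1, per unit depth
})

test_that("classification applies the stagnation dead band", {
  expect_identical(classify_branch_flow(0.1, 1, 1e-3), "outflow")
  expect_identical(classify_branch_flow(-0.1, 1, 1e-3), "reflux")
  expect_identical(classify_branch_flow(1e-5, 1, 1e-3), "stagnant")
  expect_error(classify_branch_flow(0.1, -1), "inlet_flux")
})

test_that("branch flux splits the inlet flux (additivity, bounded split)", {
  bf <- branch_field_case()
  f <- bf$field
  qin <- boundary_flux(f, boundary_id = "inlet")
  qa <- boundary_flux(f, boundary_id = "aortic_outlet")
  qb <- boundary_flux(f, boundary_id = "branch_outlet")
  expect_lt(abs(qin - qa - qb) / qin, 1e-6)
  res <- branch_flow_result(f)
  expect_lte(abs(res$normalized_flux), 1 + 1e-6)
  expect_identical(res$classification, "outflow")
})

test_that("WSS is zero on a rigid-body-zero field and scales linearly", {
  g <- default_scene()
  m <- rasterize(g, make_grid(g, 1))
  z <- zero_field(m)
  w0 <- wall_shear_stress(z, m, "branch")
  expect_true(all(w0$tau_w == 0))
  bf <- branch_field_case()
  f <- bf$field
  w1 <- wall_shear_stress(f, f$mask, "branch")
  f3 <- f
  f3$u <- 3 * f$u
  f3$v <- 3 * f$v
  w3 <- wall_shear_stress(f3, f$mask, "branch")
  expect_equal(w3$tau_w, 3 * w1$tau_w)
  expect_error(wall_shear_stress(f, f$mask, "nonexistent"), "unknown wall")
})

test_that("matched reflux case has lower branch-wall WSS than outflow case", {
  ad <- angle_depth_sweep_cached()
  r45 <- ad[ad$theta == 45 & ad$entry_depth == 10, ]
  r135 <- ad[ad$theta == 135 & ad$entry_depth == 10, ]
  expect_identical(r45$classification, "reflux")
  expect_identical(r135$classification, "outflow")
  expect_lt(r45$wss_mean, r135$wss_mean)
})

test_that("recirculation metrics: plug flow has none, empty window errors", {
  g <- default_scene(theta = 90, entry_depth = 0, stent_present = FALSE)
  m <- rasterize(g, make_grid(g, 1))
  plug <- zero_field(m)
  plug$u[] <- 0.8
  rc <- recirculation_metrics(plug, m)
  expect_identical(rc$vortex_area, 0)
  expect_identical(rc$area_fraction, 0)
  expect_error(recirculation_metrics(plug, m,
                                     window = list(xmin = -60, xmax = -50,
                                                   s_max = 0)),
               "no fluid cells")
})

test_that("field, residual and run-log exporters write parseable files", {
  f <- branch_field_case()$field
  vtk <- withr::local_tempfile(fileext = ".vtk")
  write_vtk_field(f, vtk)
  lines <- readLines(vtk)
  expect_identical(lines[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("SCALARS speed", lines)))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_field_csv(f, csv)
  df <- read.csv(csv)
  expect_identical(nrow(df), f$mask$nx * f$mask$ny)
  expect_true(all(c("u", "v", "p", "label") %in% names(df)))
  res <- withr::local_tempfile(fileext = ".csv")
  write_residuals_csv(f, res)
  expect_identical(nrow(read.csv(res)), f$iterations)
  log <- withr::local_tempfile(fileext = ".txt")
  write_run_log(f, log)
  kv <- readLines(log)
  expect_true(any(grepl("^Re_effective = 200$", kv)))
  expect_true(any(grepl("^Re_nominal_blood", kv)))
  expect_true(any(grepl("^converged = true$", kv)))
})

test_that("classification is stable under grid refinement", {
  # representative reflux and outflow configurations at h and h/2
  for (cfg in list(list(theta = 90, L = 15, cls = "reflux"),
                   list(theta = 135, L = 15, cls = "outflow"))) {
    g <- make_geometry(D1 = 30, D2 = 12, L1 = 200, L2 = 60,
                       theta = cfg$theta, entry_depth = cfg$L,
                       stent_present = TRUE)
    bcs <- boundary_conditions(0.8, 0)
    fl <- scale_reynolds(fluid_properties(), bcs, g, 200)
    for (h in c(1.5, 0.75)) {
      m <- rasterize(g, make_grid(g, h))
      f <- solve_steady(m, fl, bcs)
      q <- boundary_flux(f, m, "branch_outlet")
      qin <- boundary_flux(f, m, "inlet")
      expect_identical(classify_branch_flow(q, qin), cfg$cls,
                       info = sprintf("theta=%g h=%g", cfg$theta, h))
    }
  }
})
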