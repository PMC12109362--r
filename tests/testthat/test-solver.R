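# SIMPLE solver validation: Poiseuille oracle, conservation, gauge
# invariance, determinism, Reynolds scaling, Stokes limit, grid checks.

test_that("developed channel flow reproduces plane Poiseuille", {
  cc <- channel_case()
  f <- cc$field
  expect_true(f$converged)
  u <- f$u[191, ]                 # station 190 mm downstream, developed
  yc <- (1:30) - 0.5
  analytic <- 6 * 0.8 * yc * (30 - yc) / 900
  expect_equal(max(u) / mean(u), 1.5, tolerance = 0.02)
  l2 <- sqrt(sum((u - analytic)^2) / sum(analytic^2))
  expect_lt(l2, 0.02)
})

test_that("developed wall shear stress matches 6 mu U / w within 5%", {
  cc <- channel_case()
  wss <- wall_shear_stress(cc$field, cc$mask, "aorta_bottom")
  tau <- wss$tau_w[wss$pos_mm > 170 & wss$pos_mm < 198]
  expect_equal(mean(tau), 6 * cc$fluid$mu * 0.8 / 0.03, tolerance = 0.05)
  top <- wall_shear_stress(cc$field, cc$mask, "aorta_top")
  expect_equal(attr(top, "mean"), attr(wss, "mean"), tolerance = 0.02)
})

test_that("converged runs conserve mass globally to 1e-6 relative", {
  cc <- channel_case()
  qin <- boundary_flux(cc$field, cc$mask, "inlet")
  qout <- boundary_flux(cc$field, cc$mask, "aortic_outlet")
  expect_equal(qin, 1055 * 0.8 * 30 / 1000, tolerance = 1e-12)
  expect_lt(abs(qin - qout) / qin, 1e-6)
  bf <- branch_field_case()
  f <- bf$field
  qin <- boundary_flux(f, boundary_id = "inlet")
  qa <- boundary_flux(f, boundary_id = "aortic_outlet")
  qb <- boundary_flux(f, boundary_id = "branch_outlet")
  expect_lt(abs(qin - qa - qb) / qin, 1e-6)
})

test_that("solution is invariant to the outlet gauge pressure", {
  gp <- gauge_pair_cached()
  expect_lt(max(abs(gp$f1$u - gp$f0$u)), 1e-10)
  expect_lt(max(abs(gp$f1$v - gp$f0$v)), 1e-10)
  expect_equal(max(abs(gp$f1$p - gp$f0$p - 13300)), 0, tolerance = 1e-8)
})

test_that("the solve is deterministic: bit-identical residual histories", {
  g <- make_geometry(30, 8, 200, 100, 90, branch_present = FALSE)
  m <- rasterize(g, make_grid(g, 2))
  fl <- scale_reynolds(fluid_properties(), boundary_conditions(0.8), g, 50)
  f1 <- solve_steady(m, fl, boundary_conditions(0.8, 0))
  f2 <- solve_steady(m, fl, boundary_conditions(0.8, 0))
  expect_identical(f1$residual_history, f2$residual_history)
  expect_identical(f1$u, f2$u)
})

test_that("Reynolds rescaling follows rho v D / Re", {
  g <- default_scene()
  bcs <- boundary_conditions(0.8)
  fl0 <- fluid_properties()
  f1 <- scale_reynolds(fl0, bcs, g, 7234)
  expect_equal(f1$mu, 0.0035, tolerance = 1e-4)
  f2 <- scale_reynolds(fl0, bcs, g, 200)
  expect_equal(f2$mu, 1055 * 0.8 * 0.03 / 200)
  nominal <- reynolds_number(fl0, bcs, g)
  f3 <- scale_reynolds(fl0, bcs, g, nominal)
  expect_equal(f3$mu, fl0$mu)
  expect_equal(attr(f1, "nominal_Re"), nominal)
})

test_that("low-Reynolds solution matches a direct Stokes solve", {
  sp <- stokes_pair_cached()
  qs <- boundary_flux(sp$direct, sp$mask, "branch_outlet")
  qd <- boundary_flux(sp$simple, sp$mask, "branch_outlet")
  expect_gt(qs, 0)
  expect_equal(qd, qs, tolerance = 0.01)
})

test_that("grid-convergence report: imposed channel flux is grid-independent", {
  g <- make_geometry(30, 8, 200, 100, 90, branch_present = FALSE)
  fl <- scale_reynolds(fluid_properties(), boundary_conditions(0.8), g, 50)
  rep <- check_grid_convergence(g, fl, boundary_conditions(0.8, 0),
                                solver_settings(), h_list = c(3, 2, 1.5))
  expect_identical(nrow(rep), 3L)
  expect_lt(max(abs(rep$branch_flux - rep$branch_flux[1])) /
              rep$branch_flux[1], 1e-6)
  expect_error(check_grid_convergence(g, fl, boundary_conditions(0.8, 0),
                                      solver_settings(), h_list = c(1, 2, 3)),
               "decreasing")
})

test_that("branch-flux sign is stable under grid refinement (no stent)", {
  g <- make_geometry(30, 12, 200, 60, theta = 135)
  fl <- scale_reynolds(fluid_properties(), boundary_conditions(0.8), g, 200)
  rep <- check_grid_convergence(g, fl, boundary_conditions(0.8, 0),
                                solver_settings(), h_list = c(1.5, 1.2, 1))
  expect_true(all(sign(rep$branch_flux) == sign(rep$branch_flux[1])))
  expect_true(all(rep$classification == rep$classification[1]))
})
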