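# Sweep experiments at the fast grid, scaled Re = 200. The shared cached
# sweeps (helper-cache.R) are reused by the acceptance suite.

test_that("no-stent branch flow is outflow everywhere and grows with tilt", {
  ns <- no_stent_sweep()
  expect_identical(nrow(ns), 7L)
  expect_true(all(ns$classification == "outflow"))
  expect_true(all(ns$mass_flux > 0))
  # increasing over the swept angles beyond 90 degrees
  beyond <- ns$mass_flux[ns$theta > 90][order(ns$theta[ns$theta > 90])]
  expect_true(all(diff(beyond) > 0))
  expect_gt(ns$mass_flux[ns$theta == 135], ns$mass_flux[ns$theta == 90])
  # near-constant below 90 degrees: spread within 15%
  small <- ns$mass_flux[ns$theta <= 90]
  expect_lte(max(small) / min(small), 1.15)
})

test_that("stented branch refluxes when tilted against or across the flow", {
  ad <- angle_depth_sweep_cached()
  expect_identical(nrow(ad), 21L)
  low <- ad[ad$theta <= 90, ]
  expect_true(all(low$classification == "reflux"))
  # reflux deepens with entry depth (example column and the 5 -> 10 step)
  f90 <- low[low$theta == 90, ]
  expect_gte(abs(f90$mass_flux[f90$entry_depth == 15]),
             abs(f90$mass_flux[f90$entry_depth == 5]))
  f75 <- low[low$theta == 75, ]
  expect_true(all(diff(abs(f75$mass_flux[order(f75$entry_depth)])) > 0))
  for (th in c(45, 60)) {
    fc <- low[low$theta == th, ]
    expect_gt(abs(fc$mass_flux[fc$entry_depth == 10]),
              abs(fc$mass_flux[fc$entry_depth == 5]))
  }
})

test_that("stented branch flows outward when tilted well with the flow", {
  ad <- angle_depth_sweep_cached()
  high <- ad[ad$theta >= 120, ]
  expect_true(all(high$classification == "outflow"))
  expect_identical(ad$classification[ad$theta == 105 & ad$entry_depth == 5],
                   "outflow")
  f135 <- ad[ad$theta == 135, ]
  expect_true(all(diff(f135$mass_flux[order(f135$entry_depth)]) > 0))
})

test_that("wider branch stents reflux harder with larger ostium vortices", {
  di <- diameter_sweep_cached()
  expect_identical(nrow(di), 4L)
  expect_true(all(di$classification == "reflux"))
  ord <- order(di$D2)
  expect_true(all(diff(abs(di$mass_flux[ord])) > 0))
  expect_true(all(diff(di$vortex_area[ord]) > 0))
})

test_that("beveling the tip flips the canonical reflux case to outflow", {
  bv <- bevel_pair_cached()
  expect_identical(bv$classification, c("reflux", "outflow"))
  expect_gt(bv$mass_flux[2], bv$mass_flux[1])
  expect_false(bv$bevel[1])
  expect_true(bv$bevel[2])
})

test_that("beveling an already-outflow case warns and does not hurt the flux", {
  expect_warning(bv <- compare_bevel(theta = 135, depth = 10, D2 = 8),
                 "not in reflux")
  expect_true(all(bv$classification == "outflow"))
  expect_gte(bv$mass_flux[2], 0.95 * bv$mass_flux[1])
})

test_that("transition angle from bisection agrees with the sweep bracket", {
  ad <- angle_depth_sweep_cached()
  col10 <- ad[ad$entry_depth == 10, ]
  col10 <- col10[order(col10$theta), ]
  last_reflux <- max(col10$theta[col10$classification != "outflow"])
  first_out <- min(col10$theta[col10$theta > last_reflux &
                                 col10$classification == "outflow"])
  tr <- find_transition_angle(depth = 10, resolution = 5)
  expect_true(tr$found)
  expect_gt(tr$theta_star, last_reflux - 1e-9)
  expect_lte(tr$theta_star, first_out + 1e-9)
  expect_lte(tr$bracket[2] - tr$bracket[1], 5)
})

test_that("a bracket with identical end classifications reports no transition", {
  tr <- find_transition_angle(depth = 10, theta_lo = 120, theta_hi = 135,
                              resolution = 10)
  expect_false(tr$found)
  expect_true(is.na(tr$theta_star))
})

test_that("key classifications are robust at the alternative Reynolds number", {
  s <- solver_settings()
  r1 <- suppressWarnings(run_sweep_case(
    default_scene(theta = 90, entry_depth = 5, stent_present = TRUE),
    target_Re = 400, settings = s))
  expect_identical(r1$classification, "reflux")
  r2 <- suppressWarnings(run_sweep_case(
    default_scene(theta = 120, entry_depth = 10, stent_present = TRUE),
    target_Re = 400, settings = s))
  expect_identical(r2$classification, "outflow")
  r3 <- suppressWarnings(run_sweep_case(
    default_scene(theta = 135, entry_depth = 0, stent_present = FALSE),
    target_Re = 400, settings = s))
  expect_identical(r3$classification, "outflow")
})

test_that("sweep tables carry provenance and reject duplicate configurations", {
  ns <- no_stent_sweep()
  expect_match(attr(ns, "provenance"), "^[0-9a-f]+$")
  expect_error(run_no_stent_angle_sweep(theta_list = c(90, 90)), "Duplicated|duplicated|anyDuplicated")
  expect_error(run_angle_depth_sweep(depth_list = c(5, 5)), "Duplicated|duplicated|anyDuplicated")
  path <- withr::local_tempfile(fileext = ".csv")
  write_sweep_csv(ns, path)
  expect_identical(nrow(read.csv(path)), 7L)
})
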