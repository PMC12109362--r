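# Parameter-sweep drivers: the four theoretical experiments.

sweep_row_names <- c("theta", "entry_depth", "D2", "bevel", "stent_present",
                     "v_inlet", "h_mm", "target_Re", "mass_flux",
                     "normalized_flux", "classification", "wss_mean",
                     "wss_max", "vortex_area", "area_fraction", "converged",
                     "iterations")

provenance_hash <- function(x) {
  v <- utf8ToInt(x)
  acc <- 0
  for (b in v) acc <- (acc * 131 + b) %% 2147483647
  sprintf("%08x", acc)
}

#' Grid profile for sweep runs
#'
#' The sweep grid resolves the branch lumen with a fixed number of cells:
#' 8 across `D2` for the fast profile (`h = D2/8`, the coarsest the mask
#' accepts), 12 for the finer profile.
#'
#' @param geometry a `stent_geometry`.
#' @param fast logical.
#' @return Cell size `h` in mm.
#' @export
sweep_cell_size <- function(geometry, fast = TRUE) {
  geometry$D2 / if (fast) 8 else 12
}

#' Run a single sweep configuration
#'
#' Builds the geometry, rasterizes, solves at the requested scaled
#' Reynolds number and post-processes branch flux, branch-wall WSS and
#' recirculation area.
#'
#' @param geometry a `stent_geometry`.
#' @param v_inlet inlet speed, m/s.
#' @param target_Re scaled channel Reynolds number for the run.
#' @param fast logical; grid profile (see [sweep_cell_size()]).
#' @param settings a `solver_settings`. The sweep default caps the outer
#'   iterations at 6000: configurations with an unsteady tendency at the
#'   scaled Reynolds number do not converge to the steady tolerance at any
#'   budget and are returned flagged, so the cap only bounds their cost.
#' @param keep_field logical; attach the solved `flow_field` as attribute
#'   `"field"`.
#' @return One-row data frame (see [run_no_stent_angle_sweep()]).
#' @export
run_sweep_case <- function(geometry, v_inlet = 0.8, target_Re = 200,
                           fast = TRUE,
                           settings = solver_settings(max_iter = 6000),
                           keep_field = FALSE) {
  h <- sweep_cell_size(geometry, fast)
  mask <- rasterize(geometry, make_grid(geometry, h))
  bcs <- boundary_conditions(v_inlet = v_inlet)
  fl <- scale_reynolds(fluid_properties(), bcs, geometry, target_Re)
  field <- tryCatch(solve_steady(mask, fl, bcs, settings),
                    error = function(e) {
                      stop(sprintf("theta=%g depth=%g D2=%g bevel=%s: %s",
                                   geometry$theta, geometry$entry_depth,
                                   geometry$D2, geometry$bevel,
                                   conditionMessage(e)), call. = FALSE)
                    })
  bf <- branch_flow_result(field, mask)
  wss <- wall_shear_stress(field, mask, "branch")
  rc <- recirculation_metrics(field, mask)
  row <- data.frame(
    theta = geometry$theta, entry_depth = geometry$entry_depth,
    D2 = geometry$D2, bevel = geometry$bevel,
    stent_present = geometry$stent_present, v_inlet = v_inlet,
    h_mm = h, target_Re = target_Re, mass_flux = bf$mass_flux,
    normalized_flux = bf$normalized_flux,
    classification = bf$classification,
    wss_mean = attr(wss, "mean"), wss_max = attr(wss, "max"),
    vortex_area = rc$vortex_area, area_fraction = rc$area_fraction,
    converged = field$converged, iterations = field$iterations)
  if (keep_field) attr(row, "field") <- field
  row
}

finish_sweep <- function(rows, what) {
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  key <- paste(what, paste(apply(tab[, 1:8], 1, paste, collapse = ","),
                           collapse = ";"))
  attr(tab, "provenance") <- provenance_hash(key)
  class(tab) <- c("sweep_result", "data.frame")
  tab
}

#' No-stent tilt-angle sweep
#'
#' Branch flow through a plain fenestration (no protruding stent) as a
#' function of the branch tilt angle, at the default scene
#' (`D1 = 30`, `D2 = 8` mm, inlet 0.8 m/s).
#'
#' @param theta_list tilt angles, degrees.
#' @param v_inlet inlet speed, m/s.
#' @param target_Re scaled Reynolds number.
#' @param fast logical; grid profile.
#' @param settings a `solver_settings`.
#' @return A `sweep_result` data frame with one row per configuration.
#' @export
run_no_stent_angle_sweep <- function(theta_list = c(45, 60, 75, 90, 105,
                                                    120, 135),
                                     v_inlet = 0.8, target_Re = 200,
                                     fast = TRUE,
                                     settings = solver_settings(max_iter = 6000)) {
  stopifnot(all(theta_list > 0 & theta_list < 180),
            !anyDuplicated(theta_list))
  rows <- lapply(theta_list, function(th) {
    run_sweep_case(default_scene(theta = th, entry_depth = 0,
                                 stent_present = FALSE),
                   v_inlet, target_Re, fast, settings)
  })
  finish_sweep(rows, "no_stent_angle")
}

#' Tilt-angle by entry-depth sweep
#'
#' Branch flow with a protruding stent over a grid of tilt angles and
#' entry depths (default depths 5, 10, 15 mm).
#'
#' @inheritParams run_no_stent_angle_sweep
#' @param depth_list entry depths, mm.
#' @return A `sweep_result` with one row per (theta, depth).
#' @export
run_angle_depth_sweep <- function(theta_list = c(45, 60, 75, 90, 105, 120,
                                                 135),
                                  depth_list = c(5, 10, 15),
                                  v_inlet = 0.8, target_Re = 200,
                                  fast = TRUE,
                                  settings = solver_settings(max_iter = 6000)) {
  stopifnot(all(depth_list > 0), !anyDuplicated(depth_list),
            !anyDuplicated(theta_list))
  rows <- list()
  for (th in theta_list) for (L in depth_list) {
    rows[[length(rows) + 1L]] <-
      run_sweep_case(default_scene(theta = th, entry_depth = L,
                                   stent_present = TRUE),
                     v_inlet, target_Re, fast, settings)
  }
  finish_sweep(rows, "angle_depth")
}

#' Branch-diameter sweep
#'
#' Branch flow versus branch stent width at fixed tilt 90 degrees and
#' 15 mm entry depth, inlet 0.4 m/s (the deep-entry reflux scene).
#'
#' @param D2_list branch widths, mm.
#' @param theta,depth fixed tilt angle (degrees) and entry depth (mm).
#' @inheritParams run_no_stent_angle_sweep
#' @return A `sweep_result` with one row per width.
#' @export
run_diameter_sweep <- function(D2_list = c(6, 8, 10, 12), theta = 90,
                               depth = 15, v_inlet = 0.4, target_Re = 200,
                               fast = TRUE, settings = solver_settings(max_iter = 6000)) {
  stopifnot(all(D2_list > 0), !anyDuplicated(D2_list))
  rows <- lapply(D2_list, function(d2) {
    run_sweep_case(default_scene(theta = theta, entry_depth = depth,
                                 stent_present = TRUE, D2 = d2),
                   v_inlet, target_Re, fast, settings)
  })
  finish_sweep(rows, "diameter")
}

#' Compare the original and beveled stent tip
#'
#' Runs one configuration twice: with the square-cut protruding tip and
#' with the beveled tip ([bevel_cut()]). The canonical use is a reflux
#' configuration, where the bevel is expected to restore outflow; if the
#' original configuration is not in reflux a warning is raised and the
#' comparison is returned anyway.
#'
#' @param theta tilt angle, degrees.
#' @param depth entry depth, mm.
#' @param D2 branch width, mm.
#' @inheritParams run_no_stent_angle_sweep
#' @return A two-row `sweep_result` (original first, beveled second).
#' @export
compare_bevel <- function(theta = 90, depth = 15, D2 = 8, v_inlet = 0.8,
                          target_Re = 200, fast = TRUE,
                          settings = solver_settings(max_iter = 6000)) {
  g0 <- default_scene(theta = theta, entry_depth = depth,
                      stent_present = TRUE, D2 = D2)
  r0 <- run_sweep_case(g0, v_inlet, target_Re, fast, settings)
  if (r0$classification != "reflux") {
    warning("original configuration is not in reflux; bevel comparison ",
            "returned anyway", call. = FALSE)
  }
  r1 <- run_sweep_case(bevel_cut(g0), v_inlet, target_Re, fast, settings)
  finish_sweep(list(r0, r1), "bevel_pair")
}

#' Locate the reflux-to-outflow transition angle
#'
#' Bisection on the tilt angle using the branch-flow classification as the
#' predicate, at fixed entry depth. Requires different classifications at
#' the two ends; otherwise a no-transition report is returned.
#'
#' @param depth entry depth, mm.
#' @param theta_lo,theta_hi bracketing angles, degrees.
#' @param resolution target bracket width, degrees.
#' @inheritParams run_no_stent_angle_sweep
#' @return A `transition_report`: list with `theta_star` (smallest tested
#'   angle classified outflow; `NA` if absent), `bracket`, `found` and the
#'   visited `evaluations` data frame.
#' @export
find_transition_angle <- function(depth, theta_lo = 45, theta_hi = 135,
                                  resolution = 2.5, v_inlet = 0.8,
                                  target_Re = 200, fast = TRUE,
                                  settings = solver_settings(max_iter = 6000)) {
  classify_at <- function(th) {
    run_sweep_case(default_scene(theta = th, entry_depth = depth,
                                 stent_present = TRUE),
                   v_inlet, target_Re, fast, settings)
  }
  evals <- list()
  note <- function(row) { evals[[length(evals) + 1L]] <<- row; row }
  lo <- note(classify_at(theta_lo))
  hi <- note(classify_at(theta_hi))
  is_out <- function(row) row$classification == "outflow"
  if (is_out(lo) == is_out(hi)) {
    return(structure(list(theta_star = NA_real_,
                          bracket = c(theta_lo, theta_hi), found = FALSE,
                          evaluations = do.call(rbind, evals)),
                     class = "transition_report"))
  }
  if (is_out(lo)) stop("lower end already outflow; swap the bracket",
                       call. = FALSE)
  a <- theta_lo; b <- theta_hi
  while (b - a > resolution) {
    mid <- (a + b) / 2
    r <- note(classify_at(mid))
    if (is_out(r)) b <- mid else a <- mid
  }
  structure(list(theta_star = b, bracket = c(a, b), found = TRUE,
                 evaluations = do.call(rbind, evals)),
            class = "transition_report")
}

#' @export
print.transition_report <- function(x, ...) {
  if (x$found) {
    cat(sprintf("reflux-to-outflow transition: theta* = %.2f deg (bracket %.2f..%.2f)\n",
                x$theta_star, x$bracket[1], x$bracket[2]))
  } else {
    cat(sprintf("no transition in [%g, %g] deg\n", x$bracket[1], x$bracket[2]))
  }
  invisible(x)
}

#' Write a sweep result as tidy CSV
#' @param sweep a `sweep_result`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  utils::write.csv(as.data.frame(sweep), path, row.names = FALSE)
  invisible(path)
}
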