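#' Fluid properties
#'
#' Blood is modelled as an incompressible Newtonian fluid. Defaults are the
#' standard haemodynamic values: density 1055 kg/m^3, dynamic viscosity
#' 0.0035 kg/(m s).
#'
#' @param rho density, kg/m^3.
#' @param mu dynamic viscosity, kg/(m s).
#' @return A `fluid_properties` object.
#' @export
fluid_properties <- function(rho = 1055, mu = 0.0035) {
  stopifnot(rho > 0, mu > 0)
  structure(list(rho = rho, mu = mu), class = "fluid_properties")
}

#' Boundary conditions
#'
#' A plug (uniform) inlet velocity directed along the aortic axis and one
#' shared gauge pressure at both outlets. Only pressure differences matter
#' in incompressible flow, so the solver works at gauge 0 internally and
#' adds `p_outlet` back when reporting fields.
#'
#' @param v_inlet inlet speed, m/s (default 0.8).
#' @param p_outlet gauge pressure at both outlets, Pa (default 13300).
#' @return A `boundary_conditions` object.
#' @export
boundary_conditions <- function(v_inlet = 0.8, p_outlet = 13300) {
  stopifnot(v_inlet > 0)
  structure(list(v_inlet = v_inlet, p_outlet = p_outlet),
            class = "boundary_conditions")
}

#' Solver settings
#'
#' Numerical settings for the SIMPLE loop. The `reynolds_scale` field is
#' informational (see [scale_reynolds()] for the viscosity rescaling used
#' to run desk-scale laminar cases).
#'
#' @param relax_momentum momentum under-relaxation factor in (0,1).
#' @param relax_pressure pressure under-relaxation factor in (0,1).
#' @param tol normalized residual target (mass and momentum).
#' @param max_iter outer iteration cap.
#' @param convection_scheme `"hybrid"` (central/upwind blend) or `"upwind"`.
#' @param mom_sweeps inner Gauss-Seidel sweeps per momentum solve.
#' @param p_sweeps inner SOR sweeps per pressure-correction solve.
#' @param omega_p SOR relaxation for the pressure-correction sweeps.
#' @param min_iter minimum outer iterations before convergence is declared.
#' @return A `solver_settings` object.
#' @export
solver_settings <- function(relax_momentum = 0.7, relax_pressure = 0.3,
                            tol = 1e-5, max_iter = 20000,
                            convection_scheme = c("hybrid", "upwind"),
                            mom_sweeps = 2, p_sweeps = 60, omega_p = 1.7,
                            min_iter = 20) {
  convection_scheme <- match.arg(convection_scheme)
  stopifnot(relax_momentum > 0, relax_momentum < 1,
            relax_pressure > 0, relax_pressure < 1, tol > 0, max_iter >= 1)
  structure(list(relax_momentum = relax_momentum,
                 relax_pressure = relax_pressure, tol = tol,
                 max_iter = as.integer(max_iter),
                 convection_scheme = convection_scheme,
                 mom_sweeps = as.integer(mom_sweeps),
                 p_sweeps = as.integer(p_sweeps), omega_p = omega_p,
                 min_iter = as.integer(min_iter)),
            class = "solver_settings")
}

#' Rescale viscosity to a target Reynolds number
#'
#' Returns fluid properties with `mu' = rho * v_inlet * D1 / target_Re`, so
#' the aortic channel Reynolds number equals `target_Re`. Nominal blood at
#' `D1 = 30` mm and 0.8 m/s has Re of about 7234, which is transitional;
#' the desk-scale runs use a reduced laminar Reynolds number (default 200
#' elsewhere in the package) and report trends, not absolute magnitudes.
#'
#' @param fluid a `fluid_properties`.
#' @param bcs a `boundary_conditions`.
#' @param geometry a `stent_geometry` (uses `D1`, mm).
#' @param target_Re desired channel Reynolds number (> 0).
#' @return `fluid_properties` with rescaled viscosity; the nominal Reynolds
#'   number is attached as attribute `"nominal_Re"`.
#' @export
scale_reynolds <- function(fluid, bcs, geometry, target_Re) {
  stopifnot(target_Re > 0)
  D_m <- geometry$D1 / 1000
  nominal <- fluid$rho * bcs$v_inlet * D_m / fluid$mu
  out <- fluid_properties(rho = fluid$rho,
                          mu = fluid$rho * bcs$v_inlet * D_m / target_Re)
  attr(out, "nominal_Re") <- nominal
  out
}

#' Channel Reynolds number of a configuration
#' @inheritParams scale_reynolds
#' @return Numeric Reynolds number `rho v D1 / mu`.
#' @export
reynolds_number <- function(fluid, bcs, geometry) {
  fluid$rho * bcs$v_inlet * (geometry$D1 / 1000) / fluid$mu
}

#' Solve steady incompressible flow on a masked grid
#'
#' Finite-volume discretization on a staggered grid with SIMPLE
#' pressure-velocity coupling: plug inlet velocity, fixed (shared) pressure
#' at both outlets, rigid no-slip walls, immersed stent solid cells with
#' first-order no-slip. Initial condition is zero velocity and zero gauge
#' pressure. The iteration order is fixed and the solve is fully
#' deterministic. After the outer loop a final exact pressure projection
#' enforces discrete continuity, so converged fields conserve mass
#' globally to well below 1e-6 relative.
#'
#' @param mask a `domain_mask` from [rasterize()].
#' @param fluid a `fluid_properties`.
#' @param bcs a `boundary_conditions`.
#' @param settings a `solver_settings`.
#' @return A `flow_field`: staggered `u` ((nx+1) x ny) and `v`
#'   (nx x (ny+1)) in m/s, cell-centred `p` in Pa (gauge `p_outlet`
#'   included), `residual_history` data frame, `converged` flag,
#'   iteration count, plus the generating mask/fluid/bcs/settings.
#'   A non-converged run is returned with a warning; a diverging run
#'   (mass residual growing beyond 1e3 of its initial value) is an error
#'   naming the iteration.
#' @export
solve_steady <- function(mask, fluid = fluid_properties(),
                         bcs = boundary_conditions(),
                         settings = solver_settings()) {
  stopifnot(inherits(mask, "domain_mask"), inherits(fluid, "fluid_properties"),
            inherits(bcs, "boundary_conditions"),
            inherits(settings, "solver_settings"))
  h_m <- mask$h / 1000
  out <- .simple_solve_cpp(mask$label, h_m, fluid$rho, fluid$mu,
                           bcs$v_inlet, settings$relax_momentum,
                           settings$relax_pressure, settings$tol,
                           settings$max_iter,
                           settings$convection_scheme == "hybrid",
                           settings$mom_sweeps, settings$p_sweeps,
                           settings$omega_p, 1.93, 1e-9,
                           settings$min_iter)
  if (isTRUE(out$diverged)) {
    stop(sprintf("solver diverged at iteration %d (mass residual grew > 1e3)",
                 out$div_iter), call. = FALSE)
  }
  if (!isTRUE(out$converged)) {
    warning(sprintf("solver not converged after %d iterations (tol %g)",
                    out$iterations, settings$tol), call. = FALSE)
  }
  res <- out$residuals
  field <- structure(list(
    u = out$u, v = out$v, p = out$p + bcs$p_outlet,
    residual_history = data.frame(iteration = seq_len(nrow(res)),
                                  mass = res[, 1], u_momentum = res[, 2],
                                  v_momentum = res[, 3]),
    converged = isTRUE(out$converged), iterations = out$iterations,
    mask = mask, fluid = fluid, bcs = bcs, settings = settings),
    class = "flow_field")
  field
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("flow_field: %d x %d cells, %s after %d iterations\n",
              x$mask$nx, x$mask$ny,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  r <- x$residual_history[nrow(x$residual_history), ]
  cat(sprintf("  final residuals  mass %.2e  u %.2e  v %.2e\n",
              r$mass, r$u_momentum, r$v_momentum))
  cat(sprintf("  speed range      %.4g .. %.4g m/s\n",
              0, max(abs(x$u), abs(x$v))))
  invisible(x)
}

#' Grid-convergence check
#'
#' Re-solves one configuration on a strictly decreasing sequence of cell
#' sizes and reports the branch mass flux at each, the observed
#' flux differences between successive grids, and whether the
#' reflux/outflow classification is stable.
#'
#' @param geometry a `stent_geometry`.
#' @param fluid,bcs,settings solver inputs (see [solve_steady()]).
#' @param h_list strictly decreasing cell sizes, mm (at least 3).
#' @return Data frame with one row per `h`: `h_mm`, `branch_flux`,
#'   `classification`, `delta_to_next`; attribute `"monotone"` flags
#'   whether successive flux differences shrink monotonically.
#' @export
check_grid_convergence <- function(geometry, fluid, bcs, settings, h_list) {
  if (length(h_list) < 3 || any(diff(h_list) >= 0)) {
    stop("h_list must be strictly decreasing with at least 3 entries",
         call. = FALSE)
  }
  rows <- lapply(h_list, function(h) {
    mask <- rasterize(geometry, make_grid(geometry, h))
    fld <- tryCatch(solve_steady(mask, fluid, bcs, settings),
                    error = function(e) {
                      stop(sprintf("h = %g mm: %s", h, conditionMessage(e)),
                           call. = FALSE)
                    })
    bid <- if (geometry$branch_present) "branch_outlet" else "aortic_outlet"
    q <- boundary_flux(fld, mask, bid)
    qin <- boundary_flux(fld, mask, "inlet")
    data.frame(h_mm = h, branch_flux = q,
               classification = classify_branch_flow(q, qin))
  })
  rep <- do.call(rbind, rows)
  d <- abs(diff(rep$branch_flux))
  rep$delta_to_next <- c(d, NA)
  attr(rep, "monotone") <- all(diff(d) <= 0) || length(d) < 2
  rep
}
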