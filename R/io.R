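# Flat key-value config files, VTK structured-grid export, run logs.

read_keyvals <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, integer(1)) != 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1], call. = FALSE)
  stats::setNames(vapply(kv, `[`, character(1), 2),
                  vapply(kv, `[`, character(1), 1))
}

as_flag <- function(x) tolower(x) %in% c("true", "1", "yes")

#' Read a geometry config file
#'
#' Flat `key = value` text with keys `D1_mm`, `D2_mm`, `L1_mm`, `L2_mm`,
#' `theta_deg`, `entry_depth_mm`, `wall_thickness_mm`, `stent_present`,
#' `bevel`.
#'
#' @param path file path.
#' @return A `stent_geometry`.
#' @export
read_geometry_config <- function(path) {
  kv <- read_keyvals(path)
  need <- c("D1_mm", "D2_mm", "L1_mm", "L2_mm", "theta_deg",
            "entry_depth_mm", "wall_thickness_mm", "stent_present", "bevel")
  miss <- setdiff(need, names(kv))
  if (length(miss)) stop("missing config keys: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  make_geometry(D1 = as.numeric(kv[["D1_mm"]]), D2 = as.numeric(kv[["D2_mm"]]),
                L1 = as.numeric(kv[["L1_mm"]]), L2 = as.numeric(kv[["L2_mm"]]),
                theta = as.numeric(kv[["theta_deg"]]),
                entry_depth = as.numeric(kv[["entry_depth_mm"]]),
                wall_thickness = as.numeric(kv[["wall_thickness_mm"]]),
                stent_present = as_flag(kv[["stent_present"]]),
                bevel = as_flag(kv[["bevel"]]))
}

#' Write a geometry config file
#' @param geometry a `stent_geometry`.
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_geometry_config <- function(geometry, path) {
  g <- geometry
  lines <- c(
    sprintf("D1_mm = %g", g$D1), sprintf("D2_mm = %g", g$D2),
    sprintf("L1_mm = %g", g$L1), sprintf("L2_mm = %g", g$L2),
    sprintf("theta_deg = %g", g$theta),
    sprintf("entry_depth_mm = %g", g$entry_depth),
    sprintf("wall_thickness_mm = %g", g$wall_thickness),
    sprintf("stent_present = %s", tolower(g$stent_present)),
    sprintf("bevel = %s", tolower(g$bevel)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a solver config file
#'
#' Keys: `relax_momentum`, `relax_pressure`, `tol`, `max_iter`,
#' `convection_scheme`, `target_Re`.
#' @param path file path.
#' @return List with `settings` (a `solver_settings`) and `target_Re`.
#' @export
read_solver_config <- function(path) {
  kv <- read_keyvals(path)
  s <- solver_settings(
    relax_momentum = as.numeric(kv[["relax_momentum"]]),
    relax_pressure = as.numeric(kv[["relax_pressure"]]),
    tol = as.numeric(kv[["tol"]]),
    max_iter = as.integer(kv[["max_iter"]]),
    convection_scheme = kv[["convection_scheme"]])
  list(settings = s, target_Re = as.numeric(kv[["target_Re"]]))
}

vtk_header <- function(con, mask, what) {
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("branchflow %s", what), "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", mask$nx + 1, mask$ny + 1),
               "ORIGIN 0 0 0",
               sprintf("SPACING %g %g 1", mask$h, mask$h),
               sprintf("CELL_DATA %d", mask$nx * mask$ny)), con)
}

#' Export a mask to a legacy-ASCII VTK structured grid
#' @param mask a `domain_mask`.
#' @param path output `.vtk` path.
#' @return The path, invisibly.
#' @export
write_vtk_mask <- function(mask, path) {
  con <- file(path, "w")
  on.exit(close(con))
  vtk_header(con, mask, "domain mask")
  writeLines(c("SCALARS label int 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(as.vector(mask$label), collapse = " "), con)
  invisible(path)
}

#' Export a flow field to a legacy-ASCII VTK structured grid
#'
#' Writes cell-centred `u`, `v`, `speed` (m/s) and `p` (Pa).
#' @param field a `flow_field`.
#' @param path output `.vtk` path.
#' @return The path, invisibly.
#' @export
write_vtk_field <- function(field, path) {
  mask <- field$mask
  nx <- mask$nx; ny <- mask$ny
  uc <- 0.5 * (field$u[seq_len(nx), ] + field$u[seq_len(nx) + 1, ])
  vc <- 0.5 * (field$v[, seq_len(ny)] + field$v[, seq_len(ny) + 1])
  con <- file(path, "w")
  on.exit(close(con))
  vtk_header(con, mask, "flow field")
  wr <- function(name, m) {
    writeLines(c(sprintf("SCALARS %s float 1", name),
                 "LOOKUP_TABLE default"), con)
    writeLines(paste(format(as.vector(m), digits = 7), collapse = " "), con)
  }
  wr("u", uc); wr("v", vc); wr("speed", sqrt(uc^2 + vc^2)); wr("p", field$p)
  invisible(path)
}

#' Export a flow field's cell-centred values as CSV
#' @param field a `flow_field`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_field_csv <- function(field, path) {
  mask <- field$mask
  nx <- mask$nx; ny <- mask$ny
  uc <- 0.5 * (field$u[seq_len(nx), ] + field$u[seq_len(nx) + 1, ])
  vc <- 0.5 * (field$v[, seq_len(ny)] + field$v[, seq_len(ny) + 1])
  df <- data.frame(
    x_mm = rep((seq_len(nx) - 0.5) * mask$h, times = ny),
    y_mm = rep((seq_len(ny) - 0.5) * mask$h, each = nx),
    u = as.vector(uc), v = as.vector(vc), p = as.vector(field$p),
    label = as.vector(mask$label))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write the residual history of a run as CSV
#' @param field a `flow_field`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_residuals_csv <- function(field, path) {
  utils::write.csv(field$residual_history, path, row.names = FALSE)
  invisible(path)
}

#' Structured run log
#'
#' Writes every effective parameter of a run (geometry, grid, fluid,
#' boundary conditions, solver settings, nominal and scaled Reynolds
#' numbers) as flat `key = value` text.
#' @param field a `flow_field`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_run_log <- function(field, path) {
  g <- field$mask$geometry
  Re <- reynolds_number(field$fluid, field$bcs, g)
  nominal <- fluid_properties()$rho * field$bcs$v_inlet * (g$D1 / 1000) /
    fluid_properties()$mu
  s <- field$settings
  lines <- c(
    sprintf("D1_mm = %g", g$D1), sprintf("D2_mm = %g", g$D2),
    sprintf("L1_mm = %g", g$L1), sprintf("L2_mm = %g", g$L2),
    sprintf("theta_deg = %g", g$theta),
    sprintf("entry_depth_mm = %g", g$entry_depth),
    sprintf("stent_present = %s", tolower(g$stent_present)),
    sprintf("bevel = %s", tolower(g$bevel)),
    sprintf("h_mm = %g", field$mask$h),
    sprintf("rho = %g", field$fluid$rho), sprintf("mu = %g", field$fluid$mu),
    sprintf("v_inlet = %g", field$bcs$v_inlet),
    sprintf("p_outlet = %g", field$bcs$p_outlet),
    sprintf("Re_effective = %g", Re),
    sprintf("Re_nominal_blood = %g", nominal),
    sprintf("relax_momentum = %g", s$relax_momentum),
    sprintf("relax_pressure = %g", s$relax_pressure),
    sprintf("tol = %g", s$tol), sprintf("max_iter = %d", s$max_iter),
    sprintf("convection_scheme = %s", s$convection_scheme),
    sprintf("converged = %s", tolower(field$converged)),
    sprintf("iterations = %d", field$iterations))
  writeLines(lines, path)
  invisible(path)
}
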