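#' Parametric branch-stent geometry
#'
#' Builds the planar (2D) model of an aortic conduit with a branch conduit
#' leaving the far wall, optionally with a covered branch stent protruding
#' into the aortic lumen. The plane modelled is the one containing both
#' vessel axes, so channel widths play the role of diameters.
#'
#' Coordinate and angle conventions:
#' * The aorta occupies `x in [0, L1]`, `y in [0, D1]` (mm); inlet flow is
#'   directed along `+x`.
#' * The branch axis crosses the far (top) aortic wall at `x = L1/2`.
#' * `theta` is measured from the upstream (proximal) aortic axis direction
#'   to the outward branch axis: `theta < 90` points the stent against the
#'   aortic flow, `theta > 90` with it. The outward branch direction is
#'   `(-cos(theta), sin(theta))`.
#' * `entry_depth` is measured along the branch axis from the inner surface
#'   of the near aortic wall to the stent tip plane.
#'
#' @param D1 aortic lumen width, mm.
#' @param D2 branch stent lumen width, mm.
#' @param L1 aortic conduit length, mm (at least `5 * D1`).
#' @param L2 branch conduit length along the branch axis, mm (at least
#'   `5 * D2`).
#' @param theta branch tilt angle, degrees, strictly between 0 and 180.
#' @param entry_depth protrusion depth of the stent tip into the aortic
#'   lumen, mm; must satisfy `0 <= entry_depth < D1`.
#' @param stent_present logical; whether the branch tube protrudes into the
#'   aorta. `FALSE` gives the plain fenestration (no-stent) limit.
#' @param bevel logical; whether the protruding tip is cut parallel to the
#'   aortic wall so the lumen opens toward the oncoming flow (see
#'   [bevel_cut()]).
#' @param wall_thickness stent wall thickness, mm (default 0.5, typical for
#'   a covered stent graft). Rendered at least one grid cell thick.
#' @param branch_present logical; `FALSE` drops the branch conduit entirely
#'   and yields a straight channel (used for solver validation).
#' @return An object of class `stent_geometry`.
#' @examples
#' g <- make_geometry(30, 8, 200, 100, theta = 90, entry_depth = 10,
#'                    stent_present = TRUE)
#' g
#' @export
make_geometry <- function(D1, D2, L1, L2, theta, entry_depth = 0,
                          stent_present = FALSE, bevel = FALSE,
                          wall_thickness = 0.5, branch_present = TRUE) {
  stopifnot(is.numeric(D1), is.numeric(theta))
  if (!(D1 > 0)) stop("invalid geometry: D1 > 0 violated", call. = FALSE)
  if (!(L1 >= 5 * D1)) {
    stop("invalid geometry: L1 >= 5*D1 violated (undeveloped in/outflow)",
         call. = FALSE)
  }
  if (branch_present) {
    if (!(D2 > 0 && D2 < D1)) {
      stop("invalid geometry: 0 < D2 < D1 violated", call. = FALSE)
    }
    if (!(theta > 0 && theta < 180)) {
      stop("invalid geometry: 0 < theta < 180 violated", call. = FALSE)
    }
    if (!(L2 >= 5 * D2)) {
      stop("invalid geometry: L2 >= 5*D2 violated (undeveloped outflow)",
           call. = FALSE)
    }
    if (!(entry_depth >= 0 && entry_depth < D1)) {
      stop("invalid geometry: 0 <= entry_depth < D1 violated", call. = FALSE)
    }
    if (stent_present && !(wall_thickness > 0)) {
      stop("invalid geometry: wall_thickness > 0 violated when stent_present",
           call. = FALSE)
    }
    if (bevel && !stent_present) {
      stop("invalid geometry: bevel requires stent_present", call. = FALSE)
    }
  } else {
    stent_present <- FALSE
    bevel <- FALSE
    entry_depth <- 0
  }
  g <- list(D1 = D1, D2 = D2, L1 = L1, L2 = L2, theta = theta,
            entry_depth = entry_depth, stent_present = stent_present,
            bevel = bevel, wall_thickness = wall_thickness,
            branch_present = branch_present)
  class(g) <- "stent_geometry"
  g
}

#' @export
print.stent_geometry <- function(x, ...) {
  cat("stent_geometry:\n")
  cat(sprintf("  aorta    D1 = %g mm, L1 = %g mm\n", x$D1, x$L1))
  if (x$branch_present) {
    cat(sprintf("  branch   D2 = %g mm, L2 = %g mm, theta = %g deg\n",
                x$D2, x$L2, x$theta))
    cat(sprintf("  stent    %s, entry depth = %g mm, wall = %g mm, bevel = %s\n",
                if (x$stent_present) "present" else "absent",
                x$entry_depth, x$wall_thickness,
                if (x$bevel) "yes" else "no"))
  } else {
    cat("  branch   absent (straight channel)\n")
  }
  invisible(x)
}

#' Study default scene
#'
#' Convenience constructor for the default theoretical scene
#' (`D1 = 30`, `D2 = 8`, `L1 = 200`, `L2 = 100` mm).
#' @param theta tilt angle, degrees.
#' @param entry_depth protrusion depth, mm.
#' @param stent_present logical.
#' @param D2 branch width, mm.
#' @param bevel logical.
#' @return A `stent_geometry`.
#' @export
default_scene <- function(theta = 90, entry_depth = 10, stent_present = TRUE,
                          D2 = 8, bevel = FALSE) {
  make_geometry(D1 = 30, D2 = D2, L1 = 200, L2 = 100, theta = theta,
                entry_depth = entry_depth, stent_present = stent_present,
                bevel = bevel)
}

#' Bevel the protruding stent tip
#'
#' Returns the geometry with `bevel = TRUE`: the stent wall material facing
#' the upstream flow is excised, truncated at the plane of the aortic wall
#' (a cut parallel to the aortic axis), while the downstream wall keeps its
#' full entry depth. The lumen cross-section at the tip then opens toward
#' the oncoming flow. Applying the cut twice is a no-op.
#'
#' @param geometry a `stent_geometry` with a protruding stent
#'   (`stent_present = TRUE`, `entry_depth > 0`).
#' @return The beveled `stent_geometry`.
#' @export
bevel_cut <- function(geometry) {
  stopifnot(inherits(geometry, "stent_geometry"))
  if (!geometry$stent_present) {
    stop("bevel_cut: no protruding stent to cut (stent_present is FALSE)",
         call. = FALSE)
  }
  if (geometry$entry_depth <= 0) {
    stop("bevel_cut: entry_depth is 0, nothing to cut", call. = FALSE)
  }
  geometry$bevel <- TRUE
  geometry
}

#' Grid specification
#'
#' A uniform Cartesian grid covering the bounding box of the flow domain.
#' The vertical extent is `D1` plus the branch rise `L2 * sin(theta)`.
#'
#' @param geometry a `stent_geometry`.
#' @param h uniform cell size, mm; must satisfy `h <= D2/8` when the branch
#'   is present (at least 8 cells across the branch lumen).
#' @return An object of class `grid_spec` with fields `h`, `nx`, `ny`,
#'   `Lx`, `Ly`.
#' @export
make_grid <- function(geometry, h) {
  stopifnot(inherits(geometry, "stent_geometry"), h > 0)
  if (geometry$branch_present && h > geometry$D2 / 8 + 1e-12) {
    stop(sprintf("grid too coarse: h = %g mm > D2/8 = %g mm", h,
                 geometry$D2 / 8), call. = FALSE)
  }
  th <- geometry$theta * pi / 180
  Ly <- geometry$D1 +
    if (geometry$branch_present) geometry$L2 * sin(th) else 0
  Lx <- geometry$L1
  nx <- as.integer(round(Lx / h))
  ny <- as.integer(ceiling(Ly / h - 1e-9))
  structure(list(h = h, nx = nx, ny = ny, Lx = Lx, Ly = ny * h),
            class = "grid_spec")
}

# Integer label codes used throughout the package.
MASK_WALL          <- 0L  # exterior solid (conduit wall)
MASK_FLUID         <- 1L
MASK_SOLID         <- 2L  # stent wall material inside the aortic lumen
MASK_INLET         <- 3L
MASK_AORTIC_OUTLET <- 4L
MASK_BRANCH_OUTLET <- 5L

#' @rdname rasterize
#' @export
mask_labels <- function() {
  c(wall = MASK_WALL, fluid = MASK_FLUID, solid = MASK_SOLID,
    inlet = MASK_INLET, aortic_outlet = MASK_AORTIC_OUTLET,
    branch_outlet = MASK_BRANCH_OUTLET)
}

#' Rasterize a geometry onto a uniform grid
#'
#' Classifies every grid cell by evaluating point-in-region predicates at
#' the cell center (no sub-cell fractions; first-order geometry). Labels
#' are `wall` (exterior solid), `fluid`, `solid` (protruding stent wall),
#' `inlet` (proximal aortic end), `aortic_outlet` (distal end) and
#' `branch_outlet` (far end of the branch conduit). The inlet and outlet
#' labels mark fluid cells whose domain-edge face carries the boundary
#' condition.
#'
#' The rasterized stent wall is thickened to at least one cell
#' (`max(wall_thickness, 1.05 h)`) so slanted walls stay watertight on the
#' Cartesian grid.
#'
#' @param geometry a `stent_geometry`.
#' @param grid a `grid_spec` from [make_grid()].
#' @param check logical; validate mask invariants (inlet contiguity, outlet
#'   presence, fluid connectivity). Default `TRUE`.
#' @return An object of class `domain_mask`: list with the integer `label`
#'   matrix (`nx` by `ny`, x index first), cell size `h` (mm), `origin`,
#'   and the generating `geometry`.
#' @export
rasterize <- function(geometry, grid, check = TRUE) {
  stopifnot(inherits(geometry, "stent_geometry"), inherits(grid, "grid_spec"))
  h <- grid$h
  nx <- grid$nx
  ny <- grid$ny
  # cell-center coordinates
  xc <- (seq_len(nx) - 0.5) * h
  yc <- (seq_len(ny) - 0.5) * h
  X <- matrix(xc, nx, ny)
  Y <- matrix(yc, nx, ny, byrow = TRUE)

  D1 <- geometry$D1
  label <- matrix(MASK_WALL, nx, ny)
  in_aorta <- Y < D1
  label[in_aorta] <- MASK_FLUID

  if (geometry$branch_present) {
    th <- geometry$theta * pi / 180
    a <- c(geometry$L1 / 2, D1)          # axis crossing of near wall
    dvec <- c(-cos(th), sin(th))         # outward branch axis
    nvec <- c(sin(th), cos(th))          # transverse; t < 0 is upstream side
    S <- (X - a[1]) * dvec[1] + (Y - a[2]) * dvec[2]
    Tt <- (X - a[1]) * nvec[1] + (Y - a[2]) * nvec[2]

    in_branch <- !in_aorta & abs(Tt) < geometry$D2 / 2
    label[in_branch] <- MASK_FLUID
    if (any(in_branch[1, ]) || any(in_branch[nx, ])) {
      stop("branch conduit reaches a lateral domain end; reduce L2 or theta tilt",
           call. = FALSE)
    }
    if (geometry$stent_present && geometry$entry_depth > 0) {
      weff <- max(geometry$wall_thickness, 1.05 * h)
      annulus <- abs(Tt) > geometry$D2 / 2 & abs(Tt) <= geometry$D2 / 2 + weff
      protr <- in_aorta & annulus & S >= -geometry$entry_depth
      if (geometry$bevel) protr <- protr & Tt > 0
      label[protr] <- MASK_SOLID
    }
  }

  # boundary labels on fluid cells at the domain edges
  aorta_rows <- yc < D1
  inlet_j <- which(label[1, ] == MASK_FLUID & aorta_rows)
  label[1, inlet_j] <- MASK_INLET
  out_j <- which(label[nx, ] == MASK_FLUID & aorta_rows)
  label[nx, out_j] <- MASK_AORTIC_OUTLET
  if (geometry$branch_present) {
    top_i <- which(label[, ny] == MASK_FLUID)
    label[top_i, ny] <- MASK_BRANCH_OUTLET
  }

  mask <- structure(list(label = label, h = h, origin = c(0, 0),
                         nx = nx, ny = ny, geometry = geometry),
                    class = "domain_mask")
  if (check) validate_mask(mask)
  mask
}

#' @export
print.domain_mask <- function(x, ...) {
  cat(sprintf("domain_mask: %d x %d cells, h = %g mm\n", x$nx, x$ny, x$h))
  cnt <- mask_label_counts(x)
  for (nm in names(cnt)) cat(sprintf("  %-14s %d\n", nm, cnt[[nm]]))
  invisible(x)
}

#' Cell counts per label
#' @param mask a `domain_mask`.
#' @return Named integer vector of cell counts.
#' @export
mask_label_counts <- function(mask) {
  labs <- mask_labels()
  vapply(labs, function(code) sum(mask$label == code), integer(1))
}

#' Validate mask invariants
#'
#' Checks: the inlet is one contiguous segment of about `D1/h` cells; both
#' outlet boundaries exist (one for a straight channel); every fluid cell
#' is reachable from the inlet through face adjacency; stent solid cells
#' appear only when the stent is present.
#'
#' @param mask a `domain_mask`.
#' @return `TRUE` invisibly; errors on violation.
#' @export
validate_mask <- function(mask) {
  label <- mask$label
  g <- mask$geometry
  inlet_j <- which(label[1, ] == MASK_INLET)
  if (length(inlet_j) == 0) stop("mask invalid: no inlet cells", call. = FALSE)
  if (any(diff(inlet_j) != 1)) {
    stop("mask invalid: inlet cells not contiguous", call. = FALSE)
  }
  n_expect <- g$D1 / mask$h
  if (abs(length(inlet_j) - n_expect) > 1 + 1e-9) {
    stop(sprintf("mask invalid: %d inlet cells, expected about %g",
                 length(inlet_j), n_expect), call. = FALSE)
  }
  if (!any(label == MASK_AORTIC_OUTLET)) {
    stop("mask invalid: no aortic outlet", call. = FALSE)
  }
  if (g$branch_present && !any(label == MASK_BRANCH_OUTLET)) {
    stop("mask invalid: no branch outlet", call. = FALSE)
  }
  if (!g$stent_present && any(label == MASK_SOLID)) {
    stop("mask invalid: stent solid cells without a stent", call. = FALSE)
  }
  # connectivity by vectorized flood fill from the inlet
  fluid <- label == MASK_FLUID | label >= MASK_INLET
  reach <- matrix(FALSE, mask$nx, mask$ny)
  reach[1, inlet_j] <- TRUE
  repeat {
    grown <- reach
    grown[-1, ] <- grown[-1, ] | reach[-mask$nx, ]
    grown[-mask$nx, ] <- grown[-mask$nx, ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -mask$ny]
    grown[, -mask$ny] <- grown[, -mask$ny] | reach[, -1]
    grown <- grown & fluid
    if (identical(grown, reach)) break
    reach <- grown
  }
  if (any(fluid & !reach)) {
    stop(sprintf("mask invalid: %d fluid cells unreachable from the inlet",
                 sum(fluid & !reach)), call. = FALSE)
  }
  invisible(TRUE)
}

#' Count stent solid cells strictly inside the aortic lumen
#' @param mask a `domain_mask`.
#' @return Integer count of protruding solid cells.
#' @export
protrusion_cell_count <- function(mask) {
  sum(mask$label == MASK_SOLID)
}

#' Export a mask as tidy CSV
#'
#' One row per cell: `x_index`, `y_index` (1-based), `label` (name).
#' @param mask a `domain_mask`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_mask_csv <- function(mask, path) {
  labs <- mask_labels()
  nm <- names(labs)[match(as.vector(mask$label), labs)]
  df <- data.frame(
    x_index = rep(seq_len(mask$nx), times = mask$ny),
    y_index = rep(seq_len(mask$ny), each = mask$nx),
    label = nm
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
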