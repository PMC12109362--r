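#' Signed boundary mass flux
#'
#' Integrates `rho * (velocity . n) * h` over the faces of a named
#' boundary. Fluxes are per unit depth (2D), kg/(m s). Outlet fluxes are
#' signed with the outward normal (positive = flow leaving the domain);
#' the inlet flux is reported inflow-positive so it can serve directly as
#' the reference flux for normalization.
#'
#' @param field a `flow_field`.
#' @param mask a `domain_mask` (defaults to the one stored in `field`).
#' @param boundary_id one of `"inlet"`, `"aortic_outlet"`,
#'   `"branch_outlet"`.
#' @return Signed mass flux, kg/(m s).
#' @export
boundary_flux <- function(field, mask = field$mask,
                          boundary_id = c("branch_outlet", "inlet",
                                          "aortic_outlet")) {
  boundary_id <- match.arg(boundary_id)
  label <- mask$label
  h <- mask$h / 1000
  rho <- if (!is.null(field$fluid)) field$fluid$rho else 1055
  nx <- mask$nx
  ny <- mask$ny
  switch(boundary_id,
    inlet = {
      j <- which(label[1, ] == MASK_INLET)
      if (length(j) == 0) stop("unknown boundary: no inlet cells", call. = FALSE)
      rho * h * sum(field$u[1, j])
    },
    aortic_outlet = {
      j <- which(label[nx, ] == MASK_AORTIC_OUTLET)
      if (length(j) == 0) stop("unknown boundary: no aortic outlet", call. = FALSE)
      rho * h * sum(field$u[nx + 1, j])
    },
    branch_outlet = {
      i <- which(label[, ny] == MASK_BRANCH_OUTLET)
      if (length(i) == 0) stop("unknown boundary: no branch outlet", call. = FALSE)
      rho * h * sum(field$v[i, ny + 1])
    })
}

#' Classify branch flow as outflow, reflux or stagnant
#'
#' Positive branch mass flux means blood leaves through the branch outlet
#' (outflow); negative means reflux. Discrete solutions need a dead band:
#' fluxes within `stagnation_frac` of the inlet flux are classified
#' stagnant.
#'
#' @param mass_flux signed branch mass flux, kg/(m s).
#' @param inlet_flux positive inlet reference flux, kg/(m s).
#' @param stagnation_frac dead-band fraction (default 1e-3).
#' @return `"outflow"`, `"reflux"` or `"stagnant"`.
#' @export
classify_branch_flow <- function(mass_flux, inlet_flux,
                                 stagnation_frac = 1e-3) {
  stopifnot(inlet_flux > 0, stagnation_frac >= 0)
  band <- stagnation_frac * inlet_flux
  if (mass_flux > band) "outflow"
  else if (mass_flux < -band) "reflux"
  else "stagnant"
}

#' Branch flow result
#'
#' Convenience wrapper: branch flux, normalization by the inlet flux and
#' the reflux/outflow classification in one object.
#'
#' @inheritParams boundary_flux
#' @param stagnation_frac dead band passed to [classify_branch_flow()].
#' @return List with `mass_flux`, `normalized_flux`, `classification`.
#' @export
branch_flow_result <- function(field, mask = field$mask,
                               stagnation_frac = 1e-3) {
  q <- boundary_flux(field, mask, "branch_outlet")
  qin <- boundary_flux(field, mask, "inlet")
  structure(list(mass_flux = q, normalized_flux = q / qin,
                 classification = classify_branch_flow(q, qin,
                                                       stagnation_frac)),
            class = "branch_flow_result")
}

# wall faces of a mask: data frame of fluid cell (i, j), face direction,
# and arc position, for the named wall
wall_faces <- function(mask, wall_id) {
  label <- mask$label
  g <- mask$geometry
  nx <- mask$nx
  ny <- mask$ny
  h <- mask$h
  xc <- (seq_len(nx) - 0.5) * h
  yc <- (seq_len(ny) - 0.5) * h
  isf <- label == MASK_FLUID | label >= MASK_INLET
  out <- list()
  push <- function(i, j, dir, pos) {
    out[[length(out) + 1L]] <<- c(i = i, j = j, dir = dir, pos = pos)
  }
  if (wall_id == "aorta_bottom") {
    for (i in seq_len(nx)) if (isf[i, 1]) push(i, 1L, 3L, xc[i]) # wall below
  } else if (wall_id == "aorta_top") {
    jj <- max(which(yc < g$D1))
    for (i in seq_len(nx)) {
      if (isf[i, jj] && (jj == ny || !isf[i, jj + 1])) push(i, jj, 4L, xc[i])
    }
  } else if (wall_id == "branch") {
    th <- g$theta * pi / 180
    a <- c(g$L1 / 2, g$D1)
    dvec <- c(-cos(th), sin(th))
    # solid neighbours that bound the branch lumen: protruding stent cells,
    # or exterior wall cells above the aortic lumen
    is_branch_wall_cell <- function(i, j) {
      if (i < 1 || i > nx || j < 1 || j > ny) return(FALSE)
      if (label[i, j] == MASK_SOLID) return(TRUE)
      label[i, j] == MASK_WALL && yc[j] > g$D1
    }
    for (i in seq_len(nx)) for (j in seq_len(ny)) {
      if (!isf[i, j]) next
      s <- (xc[i] - a[1]) * dvec[1] + (yc[j] - a[2]) * dvec[2]
      if (is_branch_wall_cell(i - 1, j)) push(i, j, 1L, s)  # wall to the west
      if (is_branch_wall_cell(i + 1, j)) push(i, j, 2L, s)  # east
      if (is_branch_wall_cell(i, j - 1)) push(i, j, 3L, s)  # south
      if (is_branch_wall_cell(i, j + 1)) push(i, j, 4L, s)  # north
    }
  } else {
    stop(sprintf("unknown wall_id '%s'", wall_id), call. = FALSE)
  }
  if (length(out) == 0) {
    stop(sprintf("wall '%s' has no adjacent fluid cells", wall_id),
         call. = FALSE)
  }
  df <- as.data.frame(do.call(rbind, out))
  df[order(df$pos), ]
}

#' Wall shear stress profile
#'
#' First-order one-sided estimate at each wall face:
#' `tau_w = mu * |u_t| / (h/2)`, with `u_t` the velocity component
#' tangential to the wall at the adjacent fluid cell centre, ordered by
#' arc-length position along the wall (axial `s` coordinate for the branch
#' wall, `x` for the aortic walls).
#'
#' @param field a `flow_field`.
#' @param mask a `domain_mask`.
#' @param wall_id `"branch"` (walls bounding the branch lumen, including
#'   the protruding stent), `"aorta_bottom"` or `"aorta_top"`.
#' @return A `wss_profile`: data frame (`pos_mm`, `tau_w`) with attributes
#'   `mean` and `max` over the wall.
#' @export
wall_shear_stress <- function(field, mask = field$mask,
                              wall_id = "branch") {
  wf <- wall_faces(mask, wall_id)
  h <- mask$h / 1000
  mu <- if (!is.null(field$fluid)) field$fluid$mu else 0.0035
  tau <- numeric(nrow(wf))
  for (r in seq_len(nrow(wf))) {
    i <- wf$i[r]; j <- wf$j[r]
    if (wf$dir[r] <= 2L) {
      ut <- 0.5 * (field$v[i, j] + field$v[i, j + 1])  # vertical wall
    } else {
      ut <- 0.5 * (field$u[i, j] + field$u[i + 1, j])  # horizontal wall
    }
    tau[r] <- mu * abs(ut) / (h / 2)
  }
  prof <- data.frame(pos_mm = wf$pos, tau_w = tau)
  structure(prof, class = c("wss_profile", "data.frame"),
            mean = mean(tau), max = max(tau))
}

#' Recirculation metrics near the branch ostium
#'
#' Counts fluid cells inside a window around the branch/aorta intersection
#' whose axial velocity opposes the local bulk direction: `u < 0` in the
#' aortic lumen (bulk is `+x`), negative branch-axis velocity component in
#' the branch lumen. The default window spans `±2 D2` axially around the
#' branch axis intersection over the full aortic width, plus the first
#' `2 D2` of the branch lumen.
#'
#' @param field a `flow_field`.
#' @param mask a `domain_mask`.
#' @param window optional list with `xmin`, `xmax` (mm, aortic axial
#'   range), `s_max` (mm along the branch axis; 0 drops the branch part).
#' @return List with `vortex_area` (mm^2), `area_fraction` (relative to
#'   the window's fluid area) and `n_cells`.
#' @export
recirculation_metrics <- function(field, mask = field$mask, window = NULL) {
  g <- mask$geometry
  if (!g$branch_present) stop("no branch in this geometry", call. = FALSE)
  if (is.null(window)) {
    window <- list(xmin = g$L1 / 2 - 2 * g$D2, xmax = g$L1 / 2 + 2 * g$D2,
                   s_max = 2 * g$D2)
  }
  label <- mask$label
  nx <- mask$nx; ny <- mask$ny; h <- mask$h
  xc <- (seq_len(nx) - 0.5) * h
  yc <- (seq_len(ny) - 0.5) * h
  X <- matrix(xc, nx, ny); Y <- matrix(yc, nx, ny, byrow = TRUE)
  th <- g$theta * pi / 180
  a <- c(g$L1 / 2, g$D1)
  dvec <- c(-cos(th), sin(th)); nvec <- c(sin(th), cos(th))
  S <- (X - a[1]) * dvec[1] + (Y - a[2]) * dvec[2]
  Tt <- (X - a[1]) * nvec[1] + (Y - a[2]) * nvec[2]
  isf <- label == MASK_FLUID | label >= MASK_INLET
  in_branch <- abs(Tt) < g$D2 / 2 &
    (Y > g$D1 | (g$stent_present & S >= -g$entry_depth))
  in_aorta_win <- Y < g$D1 & X >= window$xmin & X <= window$xmax & !in_branch
  in_branch_win <- in_branch & S <= window$s_max
  win <- isf & (in_aorta_win | in_branch_win)
  if (!any(win)) stop("recirculation window contains no fluid cells",
                      call. = FALSE)
  uc <- 0.5 * (field$u[seq_len(nx), ] + field$u[seq_len(nx) + 1, ])
  vc <- 0.5 * (field$v[, seq_len(ny)] + field$v[, seq_len(ny) + 1])
  ax <- matrix(0, nx, ny)
  ax[in_aorta_win] <- uc[in_aorta_win]
  ax[in_branch_win] <- uc[in_branch_win] * dvec[1] + vc[in_branch_win] * dvec[2]
  # relative dead band so exactly-transverse flow does not register
  vref <- if (!is.null(field$bcs)) field$bcs$v_inlet else max(abs(ax), 1e-12)
  neg <- win & ax < -1e-9 * vref
  list(vortex_area = sum(neg) * h^2,
       area_fraction = sum(neg) / sum(win),
       n_cells = sum(neg))
}
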