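# Synthetic cohort generation and the reduced-order flow surrogate.

#' Default monotone geometry-to-flow response
#'
#' Smooth response used by the synthetic cohort: strictly increasing in
#' tilt angle, changing sign near the reflux/outflow transition band
#' (97.5 degrees), with the flow magnitude growing with entry depth on
#' both sides of the transition and scaling with the branch width. Units
#' are kg/s at the case scale (median outflow around 0.005 kg/s).
#'
#' @param angle tilt angle, degrees.
#' @param depth entry depth, mm.
#' @param diameter branch width, mm.
#' @return Flow, kg/s.
#' @export
default_flow_response <- function(angle, depth, diameter) {
  0.008 * tanh((angle - 97.5) / 20) * (1 + 0.03 * (depth - 7)) *
    (diameter / 5)
}

#' Synthetic cohort specification
#'
#' Two groups of arteries whose tilt angles differ by a large standardized
#' effect (default centers 90 and 125 degrees, common SD 12, anchored to
#' the case series) while entry depth and branch diameter are drawn from
#' one common distribution. Flow is the monotone response plus Gaussian
#' noise; an artery is occluded when its flow is negative.
#'
#' @param n_arteries even cohort size (default 12).
#' @param angle_low_mean,angle_high_mean group tilt-angle centers, degrees.
#' @param angle_sd common tilt-angle SD, degrees.
#' @param depth_mean,depth_sd entry-depth distribution, mm.
#' @param diam_mean,diam_sd branch-width distribution, mm.
#' @param flow_response function(angle, depth, diameter) -> flow, strictly
#'   increasing in angle.
#' @param noise_sd flow noise SD, kg/s.
#' @param seed RNG seed.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_arteries = 12, angle_low_mean = 90,
                        angle_high_mean = 125, angle_sd = 12,
                        depth_mean = 7, depth_sd = 2, diam_mean = 5,
                        diam_sd = 0.7, flow_response = default_flow_response,
                        noise_sd = 0.001, seed = 1) {
  stopifnot(n_arteries %% 2 == 0, angle_sd > 0, depth_sd > 0, diam_sd > 0,
            noise_sd >= 0, is.function(flow_response))
  structure(list(n_arteries = as.integer(n_arteries),
                 angle_low_mean = angle_low_mean,
                 angle_high_mean = angle_high_mean, angle_sd = angle_sd,
                 depth_mean = depth_mean, depth_sd = depth_sd,
                 diam_mean = diam_mean, diam_sd = diam_sd,
                 flow_response = flow_response, noise_sd = noise_sd,
                 seed = seed), class = "cohort_spec")
}

#' Generate a synthetic artery cohort
#'
#' Reproducible under the spec's seed. Angles are drawn per group (half
#' the cohort around each center, truncated to the valid (0, 180) range),
#' depths and diameters from their common distributions (truncated
#' positive), flow from the response plus noise, patency from the sign of
#' the flow.
#'
#' @param spec a `cohort_spec`.
#' @return Data frame in the case-record schema (same columns as
#'   [load_patient_cases()], `flow` filled).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  rs <- .Random.seed_save()
  on.exit(.Random.seed_restore(rs))
  set.seed(spec$seed)
  n <- spec$n_arteries
  nh <- n %/% 2
  rtrunc <- function(n, mean, sd, lo, hi) {
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- x <= lo | x >= hi)) {
      x[bad] <- stats::rnorm(sum(bad), mean, sd)
    }
    x
  }
  angle <- c(rtrunc(nh, spec$angle_low_mean, spec$angle_sd, 1, 179),
             rtrunc(n - nh, spec$angle_high_mean, spec$angle_sd, 1, 179))
  depth <- rtrunc(n, spec$depth_mean, spec$depth_sd, 0.5, Inf)
  diam <- rtrunc(n, spec$diam_mean, spec$diam_sd, 0.5, Inf)
  flow <- spec$flow_response(angle, depth, diam) +
    stats::rnorm(n, 0, spec$noise_sd)
  data.frame(
    patient_id = sprintf("S%02d", rep(seq_len(ceiling(n / 2)), each = 2)[seq_len(n)]),
    side = rep(c("left", "right"), length.out = n),
    tilt_angle = angle, entry_depth = depth, branch_diameter = diam,
    aortic_diameter = rep(30, n),
    patency = ifelse(flow < 0, "occluded", "patent"),
    flow = flow, stringsAsFactors = FALSE)
}

lin_interp_extrap <- function(xs, ys, x) {
  # piecewise-linear with linear extrapolation from the edge segments
  k <- findInterval(x, xs, all.inside = TRUE)
  x0 <- xs[k]; x1 <- xs[k + 1]
  ys[k] + (ys[k + 1] - ys[k]) * (x - x0) / (x1 - x0)
}

#' Fit the reduced-order flow surrogate from a sweep table
#'
#' Bilinear interpolation of the solver's branch mass flux over the swept
#' (tilt angle, entry depth) grid, with linear extrapolation from the edge
#' segments. The surrogate reproduces the solver flux exactly at every
#' calibration configuration, so its sign agrees with the solver
#' classification there by construction (verified at fit time). The branch
#' width is not part of the response: the sweep calibrates only angle and
#' depth at one width, and an optional width rescaling
#' (`width_scaling = TRUE`, linear in `D2`) is provided for exploration
#' only.
#'
#' @param sweep a `sweep_result` from [run_angle_depth_sweep()] (needs at
#'   least two angles and two depths).
#' @param width_scaling logical; enable the linear width factor.
#' @return A `flow_surrogate` object.
#' @export
fit_surrogate <- function(sweep, width_scaling = FALSE) {
  stopifnot(is.data.frame(sweep),
            all(c("theta", "entry_depth", "mass_flux") %in% names(sweep)))
  thetas <- sort(unique(sweep$theta))
  depths <- sort(unique(sweep$entry_depth))
  stopifnot(length(thetas) >= 2, length(depths) >= 2)
  flux <- matrix(NA_real_, length(thetas), length(depths))
  for (r in seq_len(nrow(sweep))) {
    flux[match(sweep$theta[r], thetas),
         match(sweep$entry_depth[r], depths)] <- sweep$mass_flux[r]
  }
  if (anyNA(flux)) stop("sweep table is not a full (theta, depth) grid",
                        call. = FALSE)
  obj <- structure(list(thetas = thetas, depths = depths, flux = flux,
                        D2_ref = sweep$D2[1], width_scaling = width_scaling),
                   class = "flow_surrogate")
  # sign agreement with the solver classification on the calibration rows
  for (r in seq_len(nrow(sweep))) {
    if (sweep$classification[r] == "stagnant") next
    pred <- surrogate_flow(sweep$theta[r], sweep$entry_depth[r],
                           coeffs = obj)
    want <- if (sweep$classification[r] == "outflow") 1 else -1
    if (sign(pred) != want) {
      stop("surrogate sign disagrees with solver classification at a calibration row",
           call. = FALSE)
    }
  }
  obj
}

#' Predict branch flow from the surrogate
#'
#' @param angle tilt angle(s), degrees.
#' @param depth entry depth(s), mm.
#' @param diameter branch width(s), mm; used only when the surrogate was
#'   fitted with `width_scaling = TRUE`.
#' @param coeffs a `flow_surrogate` from [fit_surrogate()].
#' @return Predicted branch mass flux (same per-unit-depth units as the
#'   calibration sweep). Warns when extrapolating beyond the calibrated
#'   angle or depth range.
#' @export
surrogate_flow <- function(angle, depth, diameter = NULL, coeffs) {
  stopifnot(inherits(coeffs, "flow_surrogate"))
  n <- max(length(angle), length(depth))
  angle <- rep_len(angle, n); depth <- rep_len(depth, n)
  if (any(angle < min(coeffs$thetas) | angle > max(coeffs$thetas) |
            depth < min(coeffs$depths) | depth > max(coeffs$depths))) {
    warning("surrogate_flow: extrapolating beyond the calibrated range",
            call. = FALSE)
  }
  out <- vapply(seq_len(n), function(k) {
    by_depth <- vapply(seq_along(coeffs$depths), function(jd) {
      lin_interp_extrap(coeffs$thetas, coeffs$flux[, jd], angle[k])
    }, numeric(1))
    lin_interp_extrap(coeffs$depths, by_depth, depth[k])
  }, numeric(1))
  if (coeffs$width_scaling && !is.null(diameter)) {
    out <- out * rep_len(diameter, n) / coeffs$D2_ref
  }
  out
}

#' Fill case-record flows from the surrogate
#'
#' Replaces the `flow` column by the surrogate prediction at each record's
#' tilt angle and entry depth. This is the computational reconstruction of
#' the flow grouping used in the case analysis: occluded (reflux) arteries
#' receive negative flows, patent arteries positive ones, and the ranking
#' among patent arteries follows the calibrated angle/depth response.
#'
#' @param records case records (see [load_patient_cases()]).
#' @param coeffs a `flow_surrogate`.
#' @return The records with `flow` filled (per-unit-depth flux units).
#' @export
reconstruct_case_flows <- function(records, coeffs) {
  records$flow <- suppressWarnings(
    surrogate_flow(records$tilt_angle, records$entry_depth,
                   records$branch_diameter, coeffs))
  records
}
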