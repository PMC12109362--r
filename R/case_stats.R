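# Clinical statistics stage: median flow split, exact Mann-Whitney U,
# Lilliefors-style Kolmogorov-Smirnov normality gate, Cohen's d, and the
# per-variable two-group comparison report.

#' Statistics settings
#'
#' @param alpha significance level (default 0.05).
#' @param quantile_type quartile interpolation convention for
#'   [group_summary()] (default 6, SPSS-style).
#' @param ks_replicates Monte-Carlo replicates for the normality test.
#' @param ks_seed fixed seed for the normality Monte Carlo.
#' @param force_test `"auto"` gates on normality; `"mann_whitney_exact"` or
#'   `"student_t"` forces one test for all variables.
#' @return A `stat_settings` object.
#' @export
stat_settings <- function(alpha = 0.05, quantile_type = 6,
                          ks_replicates = 2000, ks_seed = 20250482,
                          force_test = c("auto", "mann_whitney_exact",
                                         "student_t")) {
  stopifnot(alpha > 0, alpha < 1)
  force_test <- match.arg(force_test)
  structure(list(alpha = alpha, quantile_type = quantile_type,
                 ks_replicates = as.integer(ks_replicates),
                 ks_seed = as.integer(ks_seed), force_test = force_test),
            class = "stat_settings")
}

#' Split records into low/high flow groups at the median
#'
#' Records with flow below the median form the low-flow group, those above
#' the high-flow group. Requires an even record count and no tie at the
#' median, so the groups are equal halves.
#'
#' @param records data frame with a numeric `flow` column (see
#'   [load_patient_cases()] for the schema).
#' @return List with `low` and `high` data frames and `median_flow`.
#' @export
median_split <- function(records) {
  stopifnot(is.data.frame(records), "flow" %in% names(records))
  flow <- records$flow
  if (anyNA(flow)) stop("median_split: records carry missing flows",
                        call. = FALSE)
  n <- length(flow)
  if (n %% 2 != 0) {
    stop(sprintf("median_split: odd record count (%d); an even count is required for equal halves", n),
         call. = FALSE)
  }
  m <- stats::median(flow)
  if (any(flow == m)) {
    stop("median_split: tied flows straddle the median", call. = FALSE)
  }
  list(low = records[flow < m, , drop = FALSE],
       high = records[flow > m, , drop = FALSE], median_flow = m)
}

# null distribution of U = #{(x_i, y_j): x_i > y_j} by the standard
# counting recursion; returns counts of arrangements for U = 0..n1*n2
mw_null_counts <- function(n1, n2) {
  # f[n1][u]: number of arrangements; recursion over sample sizes
  prev <- matrix(0, n1 + 1, n1 * n2 + 1)
  prev[1, 1] <- 1  # n2 = 0: only U = 0, any n1
  for (m in 0:n1) prev[m + 1, 1] <- 1
  cur <- prev
  for (nn in seq_len(n2)) {
    cur <- matrix(0, n1 + 1, n1 * n2 + 1)
    cur[1, 1] <- 1
    for (m in seq_len(n1)) {
      for (u in 0:(m * nn)) {
        # last element is from y (no U contribution) or from x (adds nn)
        a <- prev[m + 1, u + 1]
        b <- if (u - nn >= 0) cur[m, u - nn + 1] else 0
        cur[m + 1, u + 1] <- a + b
      }
    }
    prev <- cur
  }
  cur[n1 + 1, ]
}

#' Exact Mann-Whitney U test
#'
#' `U` counts the pairs `(x_i, y_j)` with `x_i > y_j`. For
#' `n1 + n2 <= 25` the two-sided p-value is exact,
#' `p = min(1, 2 P(U <= min(U, n1 n2 - U)))` under the full null
#' distribution obtained by the counting recursion; for larger samples a
#' normal approximation with continuity correction is used with a
#' warning. Ties across samples are an error unless `ties = "midrank"`,
#' which switches to the tie-corrected normal approximation.
#'
#' @param x,y numeric samples (first sample defines `U`).
#' @param ties `"error"` (default) or `"midrank"`.
#' @return List with `U`, `p`, `method`, `n1`, `n2`.
#' @export
exact_mann_whitney <- function(x, y, ties = c("error", "midrank")) {
  ties <- match.arg(ties)
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x); n2 <- length(y)
  has_ties <- anyDuplicated(c(x, y)) > 0
  if (has_ties && ties == "error") {
    stop("tied observations across samples; rerun with ties = \"midrank\" for the tie-corrected normal approximation",
         call. = FALSE)
  }
  if (!has_ties) {
    U <- sum(outer(x, y, ">"))
  } else {
    U <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  if (!has_ties && n1 + n2 <= 25) {
    counts <- mw_null_counts(n1, n2)
    total <- sum(counts)
    ule <- min(U, n1 * n2 - U)
    p <- min(1, 2 * sum(counts[seq_len(ule + 1)]) / total)
    method <- "exact"
  } else {
    if (!has_ties) {
      warning("n1 + n2 > 25: normal approximation with continuity correction",
              call. = FALSE)
    }
    muU <- n1 * n2 / 2
    nt <- n1 + n2
    tie_tab <- table(c(x, y))
    tie_term <- sum(tie_tab^3 - tie_tab) / (nt * (nt - 1))
    sdU <- sqrt(n1 * n2 / 12 * (nt + 1 - tie_term))
    z <- (U - muU - sign(U - muU) * 0.5) / sdU
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- if (has_ties) "normal_approx_midrank" else "normal_approx"
  }
  list(U = U, p = p, method = method, n1 = n1, n2 = n2)
}

#' Pooled-variance two-sample Student t test
#'
#' @param x,y numeric samples of length at least 2.
#' @return List with `t`, `p` (two-sided), `df`.
#' @export
students_t <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  if (sp2 <= 0) stop("students_t: zero pooled variance", call. = FALSE)
  ht <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

# Monte-Carlo null table for the Lilliefors statistic, cached per
# (n, replicates, seed); the null distribution is distribution-free in n.
.bf_cache <- new.env(parent = emptyenv())

lilliefors_D <- function(x) {
  n <- length(x)
  z <- stats::pnorm(sort(x), mean(x), stats::sd(x))
  i <- seq_len(n)
  max(i / n - z, z - (i - 1) / n)
}

ks_null_table <- function(n, replicates, seed) {
  key <- sprintf("n%d_B%d_s%d", n, replicates, seed)
  if (!is.null(.bf_cache[[key]])) return(.bf_cache[[key]])
  rs <- .Random.seed_save()
  on.exit(.Random.seed_restore(rs))
  set.seed(seed)
  sims <- matrix(stats::rnorm(n * replicates), replicates, n)
  tab <- apply(sims, 1, lilliefors_D)
  .bf_cache[[key]] <- sort(tab)
  .bf_cache[[key]]
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(rs) {
  if (is.null(rs)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", rs, envir = globalenv())
}

#' Kolmogorov-Smirnov normality test (Lilliefors variant)
#'
#' One-sample KS statistic against a normal with the sample's mean and SD.
#' Because the parameters are estimated, the p-value comes from a
#' fixed-seed Monte-Carlo null table (distribution-free given `n`), cached
#' per sample size.
#'
#' @param sample numeric vector, length at least 3 and not constant.
#' @param replicates Monte-Carlo replicates (default 2000).
#' @param seed fixed seed for the null table.
#' @return List with `D`, `p`, `replicates`.
#' @export
ks_normality <- function(sample, replicates = 2000, seed = 20250482) {
  stopifnot(length(sample) >= 3)
  if (stats::sd(sample) == 0) {
    stop("ks_normality: constant sample", call. = FALSE)
  }
  D <- lilliefors_D(sample)
  tab <- ks_null_table(length(sample), replicates, seed)
  p <- (1 + sum(tab >= D)) / (replicates + 1)
  list(D = D, p = p, replicates = replicates)
}

#' Cohen's d with bootstrap confidence interval
#'
#' `d = (mean(x) - mean(y)) / s_pooled` with (n-1)-denominator pooled SD,
#' sign preserved. A percentile bootstrap 95% CI (fixed seed) is attached.
#'
#' @param x,y numeric samples of length at least 2.
#' @param boot_reps bootstrap replicates (default 10000).
#' @param seed fixed bootstrap seed.
#' @param ci logical; compute the CI (default TRUE).
#' @return List with `d`, `ci` (length-2 or NULL), `boot_reps`.
#' @export
cohens_d <- function(x, y, boot_reps = 10000, seed = 20250482, ci = TRUE) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  pooled <- function(a, b) {
    sqrt(((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
           (length(a) + length(b) - 2))
  }
  sp <- pooled(x, y)
  if (sp == 0) stop("cohens_d: zero pooled SD", call. = FALSE)
  d <- (mean(x) - mean(y)) / sp
  civ <- NULL
  if (ci) {
    rs <- .Random.seed_save()
    on.exit(.Random.seed_restore(rs))
    set.seed(seed)
    ds <- replicate(boot_reps, {
      xb <- sample(x, replace = TRUE)
      yb <- sample(y, replace = TRUE)
      spb <- pooled(xb, yb)
      if (spb == 0) NA_real_ else (mean(xb) - mean(yb)) / spb
    })
    civ <- unname(stats::quantile(ds, c(0.025, 0.975), na.rm = TRUE))
  }
  list(d = d, ci = civ, boot_reps = if (ci) boot_reps else 0L)
}

#' Median and quartiles of one group
#'
#' Quartiles use the interpolation convention in `settings`
#' (default type 6).
#'
#' @param sample numeric vector, length at least 3.
#' @param settings a `stat_settings`.
#' @return Named vector `median`, `q1`, `q3`.
#' @export
group_summary <- function(sample, settings = stat_settings()) {
  stopifnot(length(sample) >= 3)
  q <- stats::quantile(sample, c(0.25, 0.75), type = settings$quantile_type,
                       names = FALSE)
  c(median = stats::median(sample), q1 = q[1], q3 = q[2])
}

#' Two-group differential analysis of the case variables
#'
#' Splits the records into low/high flow groups at the median flow and,
#' for each requested variable, gates on normality (both groups must pass
#' the KS test at `alpha`) to choose between the pooled Student t test and
#' the exact Mann-Whitney U test; attaches Cohen's d and per-group
#' median/quartile summaries. Tied observations fall back to the
#' tie-corrected Mann-Whitney normal approximation (flagged in `method`).
#'
#' @param records data frame with a `flow` column and the variables.
#' @param variables character vector of column names to compare.
#' @param settings a `stat_settings`.
#' @param effect_ci logical; compute the bootstrap CI for Cohen's d
#'   (disable in large simulations).
#' @return A `group_comparison` data frame, one row per variable:
#'   group summaries, test used, statistic, two-sided p, Cohen's d and CI.
#' @export
compare_groups <- function(records,
                           variables = c("tilt_angle", "entry_depth",
                                         "branch_diameter"),
                           settings = stat_settings(), effect_ci = TRUE) {
  sp <- median_split(records)
  rows <- lapply(variables, function(v) {
    hi <- sp$high[[v]]
    lo <- sp$low[[v]]
    use_t <- switch(settings$force_test,
      auto = {
        pn <- function(s) tryCatch(
          ks_normality(s, settings$ks_replicates, settings$ks_seed)$p,
          error = function(e) 0)  # constant sample: treat as non-normal
        pn(hi) > settings$alpha && pn(lo) > settings$alpha
      },
      student_t = TRUE,
      mann_whitney_exact = FALSE)
    identical_groups <- isTRUE(all.equal(sort(hi), sort(lo)))
    if (use_t && !identical_groups && stats::var(hi) + stats::var(lo) > 0) {
      ht <- students_t(hi, lo)
      test <- "student_t"; statistic <- ht$t; p <- ht$p
    } else if (use_t && identical_groups) {
      test <- "student_t"; statistic <- 0; p <- 1
    } else {
      mw <- tryCatch(exact_mann_whitney(hi, lo),
                     error = function(e) exact_mann_whitney(hi, lo,
                                                            ties = "midrank"))
      test <- if (mw$method == "exact") "mann_whitney_exact"
              else "mann_whitney_midrank"
      statistic <- mw$U; p <- mw$p
    }
    d <- tryCatch(cohens_d(hi, lo, boot_reps = 2000,
                           seed = settings$ks_seed, ci = effect_ci),
                  error = function(e) list(d = NA_real_, ci = NULL))
    sh <- group_summary(hi, settings)
    sl <- group_summary(lo, settings)
    data.frame(variable = v,
               high_median = sh["median"], high_q1 = sh["q1"],
               high_q3 = sh["q3"],
               low_median = sl["median"], low_q1 = sl["q1"],
               low_q3 = sl["q3"],
               test = test, statistic = statistic, p = p,
               cohens_d = d$d,
               d_ci_lo = if (is.null(d$ci)) NA_real_ else d$ci[1],
               d_ci_hi = if (is.null(d$ci)) NA_real_ else d$ci[2],
               n_high = length(hi), n_low = length(lo))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Formatted two-group report
#'
#' Aligned-text rendering of a [compare_groups()] result in the
#' `median (Q1, Q3)` style.
#'
#' @param comparison a `group_comparison`.
#' @return Character vector of report lines (also printed).
#' @export
format_group_report <- function(comparison) {
  fmt <- function(m, q1, q3) sprintf("%.1f (%.1f, %.1f)", m, q1, q3)
  lines <- sprintf(
    "%-16s high %-22s low %-22s %-22s d=%5.2f  p=%.3f",
    comparison$variable,
    fmt(comparison$high_median, comparison$high_q1, comparison$high_q3),
    fmt(comparison$low_median, comparison$low_q1, comparison$low_q3),
    comparison$test, comparison$cohens_d, comparison$p)
  cat(lines, sep = "\n")
  invisible(lines)
}
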