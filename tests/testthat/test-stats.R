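# Statistics stage: exact Mann-Whitney, Student t, KS normality gate,
# Cohen's d, quartile summaries and the grouped comparison report.

paper_low_angles <- c(77.5, 80.5, 81.1, 91.9, 103.5, 106.7)
paper_high_angles <- c(105.6, 118.8, 126.7, 127.1, 131.8, 139.8)

test_that("exact Mann-Whitney matches hand-enumerable cases", {
  r <- exact_mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)  # no x beats any y
  expect_equal(r$p, 2 / 20)
  # role symmetry
  r2 <- exact_mann_whitney(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r2$p, r$p)
  expect_equal(r2$U, 9)
})

test_that("exact Mann-Whitney equals full enumeration for n1+n2 <= 12", {
  set.seed(42)
  for (sizes in list(c(2, 3), c(4, 4), c(3, 6), c(6, 6), c(5, 7))) {
    x <- round(rnorm(sizes[1]), 6)
    y <- round(rnorm(sizes[2], 0.5), 6)
    r <- exact_mann_whitney(x, y)
    expect_equal(r$p, mw_enumeration_p(x, y), info = paste(sizes, collapse = "/"))
    # independent cross-check against the stats package
    expect_equal(r$p, wilcox.test(x, y, exact = TRUE)$p.value)
  }
})

test_that("tilt-angle groups give U = 1 and exact p rounding to 0.004", {
  r <- exact_mann_whitney(paper_low_angles, paper_high_angles)
  expect_equal(r$U, 1)
  expect_equal(r$p, 2 * 2 / 924)
  expect_equal(round(r$p, 3), 0.004)
})

test_that("ties are rejected unless the midrank fallback is requested", {
  expect_error(exact_mann_whitney(c(1, 2), c(2, 3)), "midrank")
  r <- exact_mann_whitney(c(1, 2), c(2, 3), ties = "midrank")
  expect_true(r$p >= 0 && r$p <= 1)
  expect_match(r$method, "midrank")
})

test_that("pooled t test matches hand computation and is shift-invariant", {
  r <- students_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(round(r$t, 3), -1.225)
  expect_equal(r$df, 4)
  expect_equal(students_t(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(students_t(c(1, 2, 3), c(1, 2, 3))$p, 1)
  r_shift <- students_t(c(1, 2, 3) + 100, c(2, 3, 4) + 100)
  expect_equal(r_shift$t, r$t)
  expect_error(students_t(c(1, 1), c(1, 1)), "pooled variance")
})

test_that("KS normality statistic is affine invariant and reproducible", {
  x <- c(1, 1.1, 1.25, 1.4, 1.62, 1.81)
  r1 <- ks_normality(x)
  r2 <- ks_normality(3 * x - 7)
  expect_equal(r1$D, r2$D)
  expect_equal(r1$p, r2$p)  # same cached null table, same D
  # direct empirical-CDF maximization oracle
  z <- pnorm(sort(x), mean(x), sd(x))
  D_oracle <- max(seq_along(x) / length(x) - z,
                  z - (seq_along(x) - 1) / length(x))
  expect_equal(r1$D, D_oracle)
  # independent cross-check of the statistic
  expect_equal(r1$D, unname(nortest::lillie.test(x)$statistic))
  expect_error(ks_normality(rep(2, 5)), "constant")
})

test_that("KS normality accepts a large normal sample", {
  set.seed(7)
  x <- rnorm(500)
  expect_gt(ks_normality(x)$p, 0.05)
})

test_that("Cohen's d matches closed forms and flags degenerate input", {
  expect_equal(cohens_d(c(1, 2, 3), c(3, 4, 5), ci = FALSE)$d, -2)
  expect_equal(cohens_d(c(5, 6), c(5, 6), ci = FALSE)$d, 0)
  expect_error(cohens_d(c(0, 0), c(1, 1)), "zero pooled SD")
  r <- cohens_d(c(1, 2, 3), c(3, 4, 5), boot_reps = 500)
  expect_length(r$ci, 2)
  expect_lte(r$ci[1], r$ci[2])
})

test_that("group_summary reproduces the printed medians", {
  expect_equal(group_summary(paper_low_angles)[["median"]], 86.5)
  expect_equal(group_summary(paper_high_angles)[["median"]], 126.9)
  expect_equal(group_summary(c(1, 2, 3, 4))[["median"]], 2.5)
  # type-6 low-group lower quartile matches the printed 79.8 at 1 dp
  expect_equal(round(group_summary(paper_low_angles)[["q1"]], 1), 79.8)
})

test_that("median_split yields equal halves and is order-invariant", {
  rec <- data.frame(flow = (1:12) / 1000, id = letters[1:12])
  sp <- median_split(rec)
  expect_identical(nrow(sp$low), 6L)
  expect_identical(nrow(sp$high), 6L)
  expect_setequal(sp$low$id, letters[1:6])
  set.seed(1)
  sp2 <- median_split(rec[sample(12), ])
  expect_setequal(sp2$low$id, sp$low$id)
  expect_error(median_split(data.frame(flow = (1:11) / 1000)), "odd")
  expect_error(median_split(data.frame(flow = c(1, 2, 2, 3))), "tied")
})

test_that("identical groups give p = 1 rows in the comparison", {
  rec <- data.frame(flow = (1:12) / 1000,
                    a = rep(c(1, 2, 3, 4, 5, 6), 2),
                    b = rep(2, 12))
  # variable a: identical across groups after the split
  cmp <- compare_groups(rec, variables = "a", effect_ci = FALSE)
  expect_equal(cmp$p, 1)
})

test_that("type-I error of the pipeline is near alpha on null cohorts", {
  null_spec <- function(seed) {
    cohort_spec(angle_low_mean = 107.5, angle_high_mean = 107.5,
                flow_response = function(a, d, di) 0.005 + 0 * a,
                noise_sd = 0.001, seed = seed)
  }
  n_rej <- 0L
  n_sim <- 500L
  for (k in seq_len(n_sim)) {
    rec <- generate_cohort(null_spec(k))
    cmp <- compare_groups(rec, variables = "tilt_angle", effect_ci = FALSE)
    if (cmp$p < 0.05) n_rej <- n_rej + 1L
  }
  rate <- n_rej / n_sim
  expect_gte(rate, 0.025)
  expect_lte(rate, 0.08)
})
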