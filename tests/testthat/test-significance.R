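# Residuals, bootstrap nulls, empirical/local/global p-values, Fisher
# combination, control correction, p-value summaries.

kern <- discretize_kernel(3, 40, 10)

test_that("residuals are the profile minus the fitted component", {
  n <- 500
  v <- kernel_signal(kern, 101, 20, n)        # mode bin 101 + mode - 1
  prof <- make_profile(v, bin_size = 10)
  pos <- peakdeconv:::site_bp(101 + kern$mode_bin - 1, 1, 10)
  calls <- data.frame(chrom = "chrT", pos = pos, coef = 20,
                      stringsAsFactors = FALSE)
  res <- compute_residuals(prof, calls, kern)
  expect_lt(max(abs(res$counts$chrT)), 1e-9)

  res0 <- compute_residuals(prof, calls[0, ], kern)
  expect_equal(res0$counts$chrT, v)

  fit <- reconstruct_fit(prof, calls, kern)
  expect_equal(fit$chrT + res$counts$chrT, v)
})

test_that("bootstrap nulls are deterministic and respect degenerate input", {
  m <- length(kern$values)
  seg <- numeric(3 * m)
  nd <- bootstrap_null(seg, kern, n_boot = 25, seed = 11)
  expect_equal(nd$maxima, rep(0, 25))

  set.seed(1)
  seg2 <- rnorm(3 * m, 0, 1)
  nd1 <- bootstrap_null(seg2, kern, n_boot = 25, seed = 11)
  nd2 <- bootstrap_null(seg2, kern, n_boot = 25, seed = 11)
  expect_identical(nd1$maxima, nd2$maxima)

  const <- rep(2, 3 * m)
  ndc <- bootstrap_null(const, kern, n_boot = 10, seed = 3)
  expect_true(all(ndc$maxima > 0))            # kernel part-fits flat signal

  expect_error(bootstrap_null(numeric(m), kern, seed = 1), "shorter")
})

test_that("empirical p-values follow the add-one estimator", {
  null99 <- structure(list(maxima = sort(runif(99, 0, 5)), n_boot = 99,
                           seed = 1), class = "null_distribution")
  expect_equal(empirical_p(10, null99), 1 / 100)
  expect_equal(empirical_p(0, null99), 1)
  expect_equal(empirical_p(max(null99$maxima), null99), 2 / 100)
})

test_that("empirical p-values are calibrated under the null", {
  # heights drawn from the same distribution as the null maxima must give
  # uniform p-values: the fraction below 0.1 stays near 0.1
  set.seed(21)
  ps <- replicate(500, {
    null <- structure(list(maxima = sort(rexp(99)), n_boot = 99, seed = 1),
                      class = "null_distribution")
    empirical_p(rexp(1), null)
  })
  expect_gt(mean(ps < 0.1), 0.05)
  expect_lt(mean(ps < 0.1), 0.15)
})

test_that("local p-values hit the floor on clean nulls and 1 when clipped", {
  m <- length(kern$values)
  n <- 4000
  res <- make_profile(numeric(n), bin_size = 10)
  ps <- local_pvalues(res, "chrT", 20000, 50, kern, n_boot = 50, seed = 2)
  expect_equal(unname(ps), rep(1 / 51, 3))    # minimum attainable p

  # tiny chromosome: every local window clips below twice the kernel
  res2 <- make_profile(numeric(80), bin_size = 10)    # 800 bp chromosome
  ps2 <- local_pvalues(res2, "chrT", 400, 50, kern,
                       window_sizes = c(5000, 10000, 15000),
                       n_boot = 50, seed = 2)
  expect_equal(unname(ps2), rep(1, 3))
})

test_that("the global null samples residuals reproducibly", {
  set.seed(5)
  res <- make_profile(abs(rnorm(30000, 0, 1)), bin_size = 10)  # 300 kb
  g1 <- global_null(res, kern, sample_len = 50000, n_boot = 30, seed = 9)
  g2 <- global_null(res, kern, sample_len = 50000, n_boot = 30, seed = 9)
  expect_identical(g1$maxima, g2$maxima)
  expect_equal(empirical_p(1e6, g1), 1 / 31)
  expect_equal(empirical_p(0, g1), 1)

  # shorter than the requested sample: falls back to all residual
  small <- make_profile(abs(rnorm(3000)), bin_size = 10)
  expect_silent(g3 <- global_null(small, kern, sample_len = 2e6,
                                  n_boot = 10, seed = 1))
  expect_equal(g3$n_boot, 10)
})

test_that("Fisher combination matches its closed forms", {
  expect_equal(fisher_combine(c(1, 1, 1, 1)), 1.0)
  for (p in c(0.5, 0.04, 1e-4)) {
    expect_equal(fisher_combine(p), p, tolerance = 1e-12)   # k=1 identity
  }
  x2 <- -2 * sum(log(rep(0.05, 4)))
  expect_equal(x2, 23.9658, tolerance = 1e-4)
  expect_equal(fisher_combine(rep(0.05, 4)),
               pchisq(x2, df = 8, lower.tail = FALSE), tolerance = 1e-12)
  expect_lt(abs(fisher_combine(rep(0.05, 4)) - 0.00233), 1e-5)
  expect_error(fisher_combine(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("Fisher of uniform p-values is uniform", {
  set.seed(31)
  draws <- replicate(10000, fisher_combine(runif(4)))
  ks <- suppressWarnings(ks.test(draws, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("p-values respond monotonically to heights", {
  null <- structure(list(maxima = sort(rexp(99, 0.5)), n_boot = 99,
                         seed = 1), class = "null_distribution")
  heights <- seq(0, 10, by = 0.5)
  ps <- vapply(heights, empirical_p, 0, null = null)
  expect_true(all(diff(ps) <= 0))
})

test_that("control correction vetoes matched control signal", {
  m <- length(kern$values)
  n <- 3000
  # control with a kernel-shaped artifact as tall as the IP site
  site_start <- 1400
  pos <- peakdeconv:::site_bp(site_start + kern$mode_bin - 1, 1, 10)
  ctrl_strong <- make_profile(kernel_signal(kern, site_start, 60, n),
                              bin_size = 10)
  expect_equal(control_correct("chrT", pos, 50, 0.001, ctrl_strong, kern,
                               n_boot = 30, seed = 4), 1.0)

  # empty control window: p passes through unchanged
  ctrl_zero <- make_profile(numeric(n), bin_size = 10)
  expect_equal(control_correct("chrT", pos, 50, 0.02, ctrl_zero, kern,
                               n_boot = 30, seed = 4), 0.02)

  # weak noisy control: correction can only sharpen confidence, and the
  # veto threshold is monotone in the control height
  set.seed(6)
  ctrl_noise <- make_profile(abs(rnorm(n, 0.2, 0.2)), bin_size = 10)
  p_corr <- control_correct("chrT", pos, 50, 0.02, ctrl_noise, kern,
                            n_boot = 30, seed = 4)
  expect_lte(p_corr, 0.02)
  expect_gt(p_corr, 0)
})

test_that("p-value summaries report quantiles without any threshold", {
  calls <- data.frame(p_combined = 0.1 * (1:10))
  s <- pvalue_summary(calls)
  expect_equal(s$quantiles$p_combined[s$quantiles$quantile == 0.5], 0.55)
  expect_equal(nrow(s$quantiles), 9)

  single <- data.frame(p_combined = 0.37)
  s1 <- pvalue_summary(single)
  expect_true(all(s1$quantiles$p_combined == 0.37))
  expect_error(pvalue_summary(calls[0, , drop = FALSE]), "at least one")
})
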