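# Window tiling, sparse non-negative pursuit and cross-window merging.

kern <- discretize_kernel(3, 40, 10)

test_that("windows tile with overlap and exactly partitioned cores", {
  w <- tile_windows(50000, 20000, 1500)
  expect_equal(w$start, c(0, 18500, 37000))
  expect_equal(w$end, c(20000, 38500, 50000))
  expect_equal(w$core_start[1], 0)
  expect_equal(w$core_end[nrow(w)], 50000)
  expect_equal(w$core_start[-1], w$core_end[-nrow(w)])   # no gaps/overlaps

  single <- tile_windows(10000, 20000, 1500)
  expect_equal(nrow(single), 1)
  expect_equal(c(single$start, single$end), c(0, 10000))

  expect_error(tile_windows(50000, 2000, 1500), "larger window")

  # enlarged overlap keeps the tiling contract
  w2 <- tile_windows(100000, 20000, 1500, overlap = 3000)
  expect_equal(w2$core_start[-1], w2$core_end[-nrow(w2)])
  expect_equal(w2$core_start[1], 0)
  expect_equal(w2$core_end[nrow(w2)], 100000)
  expect_true(all(w2$start[-1] == w2$start[-nrow(w2)] + 17000))
})

test_that("an exact kernel multiple is recovered exactly", {
  n <- 300
  sig <- kernel_signal(kern, 61, 2.5, n)     # offset 600 bp
  out <- deconvolve_window(sig, kern, min_coef = 0.5)
  expect_equal(nrow(out), 1)
  expect_equal(out$start_bin, 61)
  expect_equal(out$mode_bin, 61 + kern$mode_bin - 1)
  expect_equal(out$coef, 2.5, tolerance = 1e-9)

  expect_equal(nrow(deconvolve_window(numeric(300), kern)), 0)
})

test_that("well-separated and half-support-separated pairs resolve", {
  m <- length(kern$values)
  n <- 500
  # separation = support + 100 bp = m + 10 bins
  s1 <- 50; s2 <- 50 + m + 10
  sig <- kernel_signal(kern, c(s1, s2), c(2, 4), n)
  out <- deconvolve_window(sig, kern, min_coef = 0.5)
  expect_equal(out$start_bin, c(s1, s2))
  expect_equal(out$coef, c(2, 4), tolerance = 1e-6)

  # separation = support / 2
  s2b <- 50 + m %/% 2
  sig2 <- kernel_signal(kern, c(s1, s2b), c(3, 5), n)
  out2 <- deconvolve_window(sig2, kern, min_coef = 0.5)
  expect_equal(nrow(out2), 2)
  expect_true(all(abs(out2$start_bin - c(s1, s2b)) <= 1))
  expect_true(all(abs(out2$coef - c(3, 5)) / c(3, 5) < 0.05))
})

test_that("pursuit matches the exhaustive least-squares oracle", {
  skip_if_not_installed("pracma")
  ok <- discretize_kernel(2, 15, 10)          # small support for enumeration
  m <- length(ok$values)                      # 15 bins
  n <- 60
  cases <- list(list(shifts = 15, coefs = 4),
                list(shifts = c(10, 10 + m), coefs = c(3, 6)),
                list(shifts = c(5, 5 + m %/% 2 + 2, 5 + 2 * m),
                     coefs = c(5, 2.5, 4)))
  stopifnot(max(unlist(lapply(cases, `[[`, "shifts"))) + m - 1 <= n)
  for (cs in cases) {
    sig <- kernel_signal(ok, cs$shifts, cs$coefs, n)
    mine <- deconvolve_window(sig, ok, min_coef = 0.1)
    oracle <- brute_force_fit(sig, ok, max_sites = 3)
    expect_equal(mine$start_bin, oracle$shifts)
    expect_equal(mine$coef, oracle$coefs, tolerance = 1e-6)
  }
})

test_that("fit + residual reconstructs the signal bin-exactly", {
  set.seed(8)
  n <- 400
  sig <- kernel_signal(kern, c(50, 200), c(8, 12), n) +
    abs(rnorm(n, 0, 0.3))
  out <- deconvolve_window(sig, kern, min_coef = 1)
  fit <- kernel_signal(kern, out$start_bin, out$coef, n)
  resid <- sig - fit
  expect_equal(fit + resid, sig)
  expect_lt(sum(resid^2), sum(sig^2))
})

test_that("calls shift with the signal (translation equivariance)", {
  set.seed(9)
  n <- 400
  base <- kernel_signal(kern, c(60, 220), c(5, 9), n)
  out1 <- deconvolve_window(base, kern, min_coef = 1)
  shifted <- c(numeric(7), base[1:(n - 7)])
  out2 <- deconvolve_window(shifted, kern, min_coef = 1)
  expect_equal(out2$start_bin, out1$start_bin + 7)
  expect_equal(out2$coef, out1$coef, tolerance = 1e-9)
})

test_that("merging keeps core-owned candidates and dedupes within a bin", {
  cand <- data.frame(chrom = "chrT",
                     pos = c(5005, 5005, 9995, 10045),
                     coef = c(10, 9, 4, 5),
                     core_start = c(0, 5004, 0, 0),
                     core_end = c(5004, 20000, 20000, 20000),
                     stringsAsFactors = FALSE)
  # same site from two windows: position 5005 (0-based 5004) belongs to the
  # second window's core [5004, 20000)
  merged <- merge_window_calls(cand, 10)
  expect_equal(nrow(merged), 3)
  expect_equal(merged$pos, c(5005, 9995, 10045))   # 5 bins apart: both kept
  expect_equal(merged$coef[merged$pos == 5005], 9)

  near <- data.frame(chrom = "chrT", pos = c(1000, 1008), coef = c(3, 7),
                     core_start = 0, core_end = 20000,
                     stringsAsFactors = FALSE)
  m2 <- merge_window_calls(near, 10)
  expect_equal(nrow(m2), 1)                   # within one bin: larger kept
  expect_equal(m2$coef, 7)
})

test_that("windowed genome deconvolution equals a single-window fit", {
  true_k <- discretize_kernel(3, 40, 10)
  n <- 6000                                    # 60 kb at 10-bp bins
  starts <- c(400, 1500, 2600, 3900, 5200)
  coefs <- c(10, 25, 18, 30, 12)
  v <- kernel_signal(true_k, starts, coefs, n)
  prof <- make_profile(v, bin_size = 10)
  cfg <- run_config(window_len = 20000, min_coef = 2)
  cand <- peakdeconv:::deconvolve_genome(prof, true_k, cfg)
  tiled <- merge_window_calls(cand, 10)
  whole <- deconvolve_window(v, true_k, min_coef = 2)
  whole_pos <- peakdeconv:::site_bp(whole$mode_bin, 1, 10)
  expect_equal(tiled$pos, whole_pos)
  expect_equal(tiled$coef, whole$coef, tolerance = 1e-9)
})
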