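# Shared fixture builders. Everything is generated in code; no data files.

options(peakdeconv.verbose = FALSE)

# A coverage_profile built directly from a counts vector (unit tests often
# need exact bin values rather than simulated reads).
make_profile <- function(counts, bin_size = 10, chrom = "chrT",
                         elongation = 150) {
  if (!is.list(counts)) counts <- stats::setNames(list(counts), chrom)
  sizes <- stats::setNames(vapply(counts, length, 0L) * bin_size,
                           names(counts))
  structure(list(bin_size = bin_size, elongation = elongation,
                 strand_filter = "both", sizes = sizes, counts = counts),
            class = "coverage_profile")
}

# Sum of scaled kernel copies: coefs[i] placed with the kernel's first value
# at start bin starts[i] (1-based), in a vector of n bins.
kernel_signal <- function(kernel, starts, coefs, n) {
  g <- kernel$values
  v <- numeric(n)
  for (i in seq_along(starts)) {
    idx <- starts[i]:(starts[i] + length(g) - 1L)
    v[idx] <- v[idx] + coefs[i] * g
  }
  v
}

# A profile of well-separated kernel-shaped peaks (one chromosome), with
# optional Poisson background noise; returns the profile plus the training
# regions centered on the true peaks.
peaks_profile <- function(kernel, n_regions = 50, height_range = c(20, 60),
                          noise_mean = 0, region_bins = 300, seed = 1) {
  m <- length(kernel$values)
  bs <- kernel$bin_size
  stopifnot(region_bins > 2 * m)
  n <- n_regions * region_bins
  starts <- (seq_len(n_regions) - 1L) * region_bins + region_bins %/% 2
  coefs <- peakdeconv:::with_seed(seed,
                                  stats::runif(n_regions, height_range[1],
                                               height_range[2]))
  v <- kernel_signal(kernel, starts, coefs, n)
  if (noise_mean > 0) {
    v <- v + peakdeconv:::with_seed(seed + 1, stats::rpois(n, noise_mean))
  }
  centers <- (starts + kernel$mode_bin - 1.5) * bs
  profile <- make_profile(v, bin_size = bs)
  regions <- data.frame(chrom = "chrT", center = centers,
                        half_width = (region_bins %/% 2) * bs,
                        intensity = coefs)
  list(profile = profile, regions = regions, starts = starts, coefs = coefs)
}

# Standard small simulated experiment for pipeline-level tests.
small_sim <- function(n_sites = 20, chrom_len = 1e5, n_fragments = 60,
                      background_rate = 0.5, seed = 7, ...) {
  pos <- round(seq(chrom_len * 0.05, chrom_len * 0.95,
                   length.out = n_sites))
  spec <- simulation_spec(chrom_len = chrom_len,
                          sites = data.frame(position = pos,
                                             n_fragments = n_fragments),
                          background_rate = background_rate, seed = seed,
                          ...)
  c(simulate_reads(spec), list(positions = pos))
}

# Peak-call table with only its data (drop config/kernel attributes), for
# equality comparisons across runs.
strip_calls <- function(x) {
  df <- as.data.frame(x)
  attributes(df) <- attributes(df)[c("names", "class", "row.names")]
  df
}

# Exhaustive least-squares oracle: best non-negative fit over all subsets of
# candidate shifts with at most `max_sites` members, solved independently
# with pracma::lsqnonneg on the full design matrix.
brute_force_fit <- function(signal, kernel, max_sites = 3) {
  g <- kernel$values
  m <- length(g)
  n <- length(signal)
  shifts <- seq_len(n - m + 1L)
  col_of <- function(s) { v <- numeric(n); v[s:(s + m - 1L)] <- g; v }
  best <- list(rss = sum(signal^2), shifts = integer(0), coefs = numeric(0))
  for (k in seq_len(max_sites)) {
    subsets <- utils::combn(shifts, k)
    for (j in seq_len(ncol(subsets))) {
      sub <- subsets[, j]
      X <- vapply(sub, col_of, numeric(n))
      fit <- tryCatch(pracma::lsqnonneg(X, signal),
                      error = function(e) NULL)
      if (is.null(fit)) next                  # singular subset: never optimal
      rss <- fit$resid.norm
      if (rss < best$rss - 1e-12) {
        keep <- fit$x > 0
        best <- list(rss = rss, shifts = sub[keep], coefs = fit$x[keep])
      }
    }
  }
  ord <- order(best$shifts)
  list(rss = best$rss, shifts = best$shifts[ord], coefs = best$coefs[ord])
}
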