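# Genome-wide deconvolution: overlapping windows tiled across each
# chromosome, each fitted by sparse non-negative regression of shifted
# kernel copies (greedy matching pursuit with a joint NNLS refit).

#' Tile a chromosome into overlapping deconvolution windows
#'
#' Consecutive windows overlap by the kernel support so that no peak can
#' straddle a window boundary unseen. Each window owns a half-open "core"
#' interval; the cores tile the chromosome exactly, and only sites falling in
#' a window's core are kept when window results are merged.
#'
#' @param chrom_len chromosome length in bp.
#' @param window_len window length in bp (default 20000).
#' @param kernel_support kernel support length in bp.
#' @param overlap window overlap in bp; at least one kernel support
#'   (the default). The pipeline uses two supports so that every core
#'   position keeps a full support of signal on both sides within its own
#'   window, which protects fits near core boundaries from edge clipping.
#' @return data.frame(start, end, core_start, core_end), 0-based half-open.
#' @export
tile_windows <- function(chrom_len, window_len = 20000, kernel_support,
                         overlap = kernel_support) {
  if (window_len <= 2 * kernel_support) {
    stopf("window_len (%d) must exceed twice the kernel support (%d); use a larger window",
          window_len, kernel_support)
  }
  if (overlap < kernel_support || window_len <= 2 * overlap) {
    stopf("overlap must lie in [kernel support, window_len / 2)")
  }
  if (chrom_len <= window_len) {
    return(data.frame(start = 0, end = chrom_len,
                      core_start = 0, core_end = chrom_len))
  }
  step <- window_len - overlap
  starts <- seq(0, chrom_len - 1, by = step)
  # drop trailing windows fully covered by the previous one
  starts <- starts[starts < chrom_len - overlap | starts == 0]
  ends <- pmin(starts + window_len, chrom_len)
  n <- length(starts)
  core_start <- starts + overlap / 2
  core_end <- core_start + step
  core_start[1] <- 0
  core_end[n] <- chrom_len
  core_end <- pmin(core_end, chrom_len)
  data.frame(start = starts, end = ends,
             core_start = core_start, core_end = core_end)
}

# Cross-correlation of residual r with kernel g at every admissible shift:
# cc[s] = sum_i r[s + i - 1] * g[i], s = 1 .. n - m + 1. FFT-based with
# power-of-two padding; the kernel spectrum is cached per padded length in
# `cache` (an environment) since deconvolution reuses one kernel across many
# same-sized windows and bootstrap iterations.
xcorr <- function(r, g, cache = NULL) {
  n <- length(r); m <- length(g)
  N <- stats::nextn(n + m - 1L, 2)
  key <- as.character(N)
  fg <- if (!is.null(cache)) cache[[key]] else NULL
  if (is.null(fg)) {
    fg <- Conj(stats::fft(c(g, numeric(N - m))))
    if (!is.null(cache)) cache[[key]] <- fg
  }
  fr <- stats::fft(c(r, numeric(N - n)))
  cc <- Re(stats::fft(fr * fg, inverse = TRUE)) / N
  cc[seq_len(n - m + 1L)]
}

# Non-negative least squares in the Gram domain: Lawson-Hanson active-set
# iteration on the normal equations min_x>=0 x'Gx/2 - b'x, equivalent to
# NNLS on the full n x k design because the Gram matrix and projections are
# exact. Hand-rolled because this sits in the bootstrap hot loop where a
# general dense solver's per-call overhead dominates; tests cross-check it
# against an independent NNLS implementation.
nnls_gram <- function(G, b, tol = 1e-10) {
  k <- length(b)
  x <- numeric(k)
  P <- logical(k)
  scale <- max(diag(G))
  for (outer_it in seq_len(10L * k + 10L)) {
    w <- b - as.vector(G %*% x)                 # negative gradient
    cand <- which(!P & w > tol * scale)
    if (!length(cand)) break
    j <- cand[which.max(w[cand])]
    P[j] <- TRUE
    for (inner_it in seq_len(10L * k + 10L)) {
      sP <- tryCatch(solve(G[P, P, drop = FALSE], b[P]),
                     error = function(e)
                       solve(G[P, P, drop = FALSE] +
                               diag(1e-9 * scale, sum(P)), b[P]))
      if (all(sP > 0)) {
        x <- numeric(k)
        x[P] <- sP
        break
      }
      s <- numeric(k)
      s[P] <- sP
      q <- which(P & s <= 0)
      den <- x[q] - s[q]
      alpha <- min(ifelse(den > 0, x[q] / den, 0))
      x <- x + alpha * (s - x)
      x[q][x[q] < tol * scale] <- 0
      P <- P & x > 0
      if (!any(P)) { x <- numeric(k); break }
    }
  }
  x
}

#' Deconvolve one window of signal against the kernel
#'
#' Greedy non-negative matching pursuit: repeatedly add the kernel shift
#' maximizing the inner product with the current residual, refit all selected
#' coefficients jointly by non-negative least squares, and drop any that hit
#' zero. Stops when the relative RSS improvement falls below `tol`, the best
#' new coefficient falls below `min_coef`, or `max_sites` is reached.
#'
#' Because shifted kernel copies are never clipped at window edges, all
#' inner products live in the Gram domain: the Gram matrix is the kernel
#' autocorrelation at shift differences and the residual cross-correlation
#' is updated incrementally, so each greedy round costs O(n + k m + k^3)
#' rather than a fresh n x k regression.
#'
#' @param signal numeric vector of binned intensities for the window.
#' @param kernel a `peak_kernel`.
#' @param min_coef smallest admissible peak height; `NULL` uses
#'   max(2, 3 * median nonzero bin intensity), which suppresses fits to flat
#'   background.
#' @param tol relative RSS improvement threshold (default 1e-4).
#' @param max_sites maximum number of fitted sites (default 200).
#' @param min_sep minimum separation between fitted sites, in bins; `NULL`
#'   uses just under half the kernel support, the method's intrinsic
#'   resolution: two events at least half a support apart are still
#'   resolved, while anything closer is indistinguishable from stochastic
#'   wobble in a single observed peak (which would otherwise be fitted as
#'   spurious sub-peak copies). Set to 0 to disable.
#' @return data.frame(start_bin, mode_bin, coef): kernel start shift, the bin
#'   of the kernel mode within `signal` (both 1-based), and the fitted height.
#' @export
deconvolve_window <- function(signal, kernel, min_coef = NULL, tol = 1e-4,
                              max_sites = 200, min_sep = NULL) {
  core <- deconvolve_core(signal, kernel, min_coef, tol, max_sites, min_sep)
  if (length(core$active) == 0) {
    return(data.frame(start_bin = integer(), mode_bin = integer(),
                      coef = numeric()))
  }
  ord <- order(core$active)
  data.frame(start_bin = core$active[ord],
             mode_bin = core$active[ord] + kernel$mode_bin - 1L,
             coef = core$coefs[ord])
}

# The pursuit itself, data.frame-free for hot loops (bootstrap iterations
# call this thousands of times). Returns list(active, coefs).
deconvolve_core <- function(signal, kernel, min_coef = NULL, tol = 1e-4,
                            max_sites = 200, min_sep = NULL) {
  g <- kernel$values
  m <- length(g)
  n <- length(signal)
  empty <- list(active = integer(0), coefs = numeric(0))
  if (n < m) stopf("signal (%d bins) shorter than kernel (%d bins)", n, m)
  if (all(signal <= 0)) return(empty)
  if (is.null(min_coef)) {
    nz <- signal[signal > 0]
    min_coef <- max(2, 3 * stats::median(nz))
  }
  if (is.null(min_sep)) min_sep <- max(1L, floor(m / 2) - 1L)
  nshift <- n - m + 1L
  gg <- sum(g^2)
  # autocorrelation of the kernel at lags -(m-1) .. (m-1), index lag + m;
  # zero beyond the support (shifts that far apart do not overlap)
  A <- kernel$autocorr %||% stats::convolve(g, g, conj = TRUE, type = "open")
  gram <- function(shifts) {
    lag <- outer(shifts, shifts, "-")
    G <- matrix(0, length(shifts), length(shifts))
    ok <- abs(lag) < m
    G[ok] <- A[lag[ok] + m]
    G
  }
  cc0 <- xcorr(signal, g, kernel$fft_cache) # <signal, g_s> for every shift
  cc <- cc0                                 # running <residual, g_s>
  yy <- sum(signal^2)
  rss <- yy
  active <- integer(0)
  coefs <- numeric(0)
  repeat {
    cand <- cc
    for (a in active) {                     # enforce minimum site separation
      cand[max(1L, a - min_sep):min(nshift, a + min_sep)] <- -Inf
    }
    s_best <- which.max(cand)
    if (length(s_best) == 0 || !is.finite(cand[s_best]) ||
        cand[s_best] / gg < min_coef || cand[s_best] <= 0) break
    trial <- c(active, s_best)
    refit <- nnls_refit(trial, cc0, gram, A, m, nshift)
    if (length(refit$active) == 0) break
    # coordinate-descent reposition: with several copies active, the greedy
    # shift of an earlier copy may no longer be the least-squares optimum;
    # move each copy to the best admissible shift given the others, then
    # refit, until stable (restores matched-filter placement accuracy)
    for (pass in 1:3) {
      moved <- reposition_sites(refit, cc0, A, m, nshift, min_sep)
      if (!moved$changed) break
      refit <- nnls_refit(moved$active, cc0, gram, A, m, nshift)
      if (length(refit$active) == 0) break
    }
    if (length(refit$active) == 0) break
    active <- refit$active
    coefs <- refit$coefs
    cc <- refit$cc
    new_rss <- yy - refit$fit_ss
    improved <- (rss - new_rss) / max(rss, .Machine$double.eps)
    rss <- new_rss
    if (improved < tol || length(active) >= max_sites) break
  }
  list(active = active, coefs = coefs)
}

# Joint NNLS refit of a shift set in the Gram domain; returns the surviving
# shifts, coefficients, the residual cross-correlation with the kernel at
# every shift, and the explained sum of squares (2 b'c - c'Gc).
nnls_refit <- function(shifts, cc0, gram, A, m, nshift) {
  G <- gram(shifts)
  b <- cc0[shifts]
  x <- nnls_gram(G, b)
  keep <- x > 0
  active <- shifts[keep]
  coefs <- x[keep]
  cc <- cc0
  for (j in seq_along(active)) {
    lo <- max(1L, active[j] - m + 1L)
    hi <- min(nshift, active[j] + m - 1L)
    idx <- lo:hi
    cc[idx] <- cc[idx] - coefs[j] * A[idx - active[j] + m]
  }
  fit_ss <- if (length(active)) {
    Gk <- gram(active)
    2 * sum(cc0[active] * coefs) - drop(crossprod(coefs, Gk %*% coefs))
  } else 0
  list(active = active, coefs = coefs, cc = cc, fit_ss = fit_ss)
}

# One pass of single-site relocation: for each fitted copy, find the shift
# maximizing the correlation of (residual + that copy) with the kernel,
# within the copy's overlap neighborhood and outside other copies'
# exclusion zones.
reposition_sites <- function(refit, cc0, A, m, nshift, min_sep) {
  active <- refit$active
  coefs <- refit$coefs
  cc <- refit$cc
  changed <- FALSE
  for (j in seq_along(active)) {
    sj <- active[j]
    lo <- max(1L, sj - m + 1L)
    hi <- min(nshift, sj + m - 1L)
    idx <- lo:hi
    local_cc <- cc[idx] + coefs[j] * A[idx - sj + m]
    ok <- rep(TRUE, length(idx))
    for (a in active[-j]) ok[abs(idx - a) <= min_sep] <- FALSE
    if (!any(ok)) next
    best <- idx[ok][which.max(local_cc[ok])]
    if (best != sj &&
        local_cc[best - lo + 1L] > local_cc[sj - lo + 1L] + 1e-9) {
      active[j] <- best
      changed <- TRUE
    }
  }
  list(active = active, changed = changed)
}

#' Merge candidate sites from overlapping windows
#'
#' Keeps only candidates whose position lies in their source window's core
#' (half-open), then collapses any remaining sites within one bin of each
#' other, keeping the larger coefficient.
#'
#' @param candidates data.frame with chrom, pos (1-based bp of the kernel
#'   mode), coef, core_start, core_end.
#' @param bin_size bin width in bp.
#' @return data.frame(chrom, pos, coef) sorted by chrom, pos.
#' @export
merge_window_calls <- function(candidates, bin_size) {
  if (nrow(candidates) == 0) {
    return(data.frame(chrom = character(), pos = numeric(), coef = numeric(),
                      stringsAsFactors = FALSE))
  }
  keep <- (candidates$pos - 1) >= candidates$core_start &
    (candidates$pos - 1) < candidates$core_end
  x <- candidates[keep, c("chrom", "pos", "coef"), drop = FALSE]
  x <- x[order(x$chrom, x$pos, -x$coef), , drop = FALSE]
  out <- list()
  for (chrom in unique(x$chrom)) {
    xc <- x[x$chrom == chrom, , drop = FALSE]
    acc <- xc[1, , drop = FALSE]
    if (nrow(xc) > 1) {
      for (i in 2:nrow(xc)) {
        last <- nrow(acc)
        if (xc$pos[i] - acc$pos[last] <= bin_size) {
          if (xc$coef[i] > acc$coef[last]) acc[last, ] <- xc[i, ]
        } else {
          acc <- rbind(acc, xc[i, ])
        }
      }
    }
    out[[chrom]] <- acc
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# bp position (1-based, center of the kernel-mode bin) of a fitted site whose
# signal vector starts at chromosome bin `offset_bin` (1-based).
site_bp <- function(mode_bin, offset_bin, bin_size) {
  (offset_bin - 1 + mode_bin - 1) * bin_size + ceiling(bin_size / 2)
}
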