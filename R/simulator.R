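# Synthetic ChIP-seq read simulator with ground truth.
#
# Point binding sites emit immunoprecipitated fragments; each fragment has a
# stochastic length and contains its site at a uniformly random internal
# offset (the standard chromatin-fragmentation model, which yields the
# flat-top/triangular site density whose Gamma fit exercises the kernel
# learner realistically). Sequencing reports the 5' read-length prefix of
# the fragment on a random strand. Uniform Poisson background reads are
# added; the control sample contains background only.

#' Describe a simulated ChIP-seq experiment
#'
#' @param chrom_len chromosome length in bp.
#' @param sites data.frame(position, n_fragments): 1-based site positions
#'   and per-site fragment counts.
#' @param fragment_len_mean,fragment_len_sd fragment length distribution
#'   (Normal, truncated below at read_len + 1), bp.
#' @param read_len sequenced read length, bp.
#' @param background_rate IP background reads per kb (Poisson).
#' @param control_rate control reads per kb (Poisson).
#' @param seed integer seed; all draws are reproducible.
#' @param chrom chromosome name.
#' @return a validated `simulation_spec`.
#' @export
simulation_spec <- function(chrom_len, sites, fragment_len_mean = 200,
                            fragment_len_sd = 20, read_len = 36,
                            background_rate = 0.5, control_rate = 0.5,
                            seed = 1, chrom = "chrSim") {
  if (fragment_len_mean <= read_len) {
    stopf("fragment_len_mean (%g) must exceed read_len (%d)",
          fragment_len_mean, read_len)
  }
  if (background_rate < 0 || control_rate < 0) stopf("rates must be >= 0")
  margin <- fragment_len_mean + 5 * fragment_len_sd
  bad <- which(sites$position <= margin | sites$position > chrom_len - margin)
  if (length(bad)) {
    stopf("site %d at %d is too close to a chromosome edge for its fragments",
          bad[1], sites$position[bad[1]])
  }
  structure(list(chrom = chrom, chrom_len = chrom_len, sites = sites,
                 fragment_len_mean = fragment_len_mean,
                 fragment_len_sd = fragment_len_sd, read_len = read_len,
                 background_rate = background_rate,
                 control_rate = control_rate, seed = seed),
            class = "simulation_spec")
}

# Normal fragment lengths truncated to [read_len + 1, Inf), rounded.
draw_fragment_lengths <- function(n, mean, sd, read_len) {
  lens <- round(stats::rnorm(n, mean, sd))
  bad <- which(lens < read_len + 1)
  while (length(bad)) {
    lens[bad] <- round(stats::rnorm(length(bad), mean, sd))
    bad <- bad[lens[bad] < read_len + 1]
  }
  lens
}

background_reads <- function(chrom, chrom_len, rate_per_kb, read_len) {
  n <- stats::rpois(1, rate_per_kb * chrom_len / 1000)
  if (n == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  start <- floor(stats::runif(n, 0, chrom_len - read_len))
  strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
  data.frame(chrom = chrom, start = start, end = start + read_len,
             strand = strand, stringsAsFactors = FALSE)
}

#' Simulate IP and control read sets with ground truth
#'
#' @param spec a `simulation_spec`.
#' @return list(ip, control, truth, sizes): reads as data.frames
#'   (chrom, start, end, strand; 0-based half-open), `truth` carrying the
#'   site table and total read counts, `sizes` a named chromosome-length
#'   vector ready for [build_coverage()].
#' @export
simulate_reads <- function(spec) {
  with_seed(spec$seed, {
    rl <- spec$read_len
    site_reads <- lapply(seq_len(nrow(spec$sites)), function(i) {
      pos0 <- spec$sites$position[i] - 1          # 0-based site coordinate
      nf <- spec$sites$n_fragments[i]
      if (nf == 0) return(NULL)
      lens <- draw_fragment_lengths(nf, spec$fragment_len_mean,
                                    spec$fragment_len_sd, rl)
      offset <- floor(stats::runif(nf) * lens)    # site uniform in fragment
      fstart <- pos0 - offset
      fend <- fstart + lens
      plus <- stats::runif(nf) < 0.5
      start <- ifelse(plus, fstart, fend - rl)
      data.frame(chrom = spec$chrom, start = start, end = start + rl,
                 strand = ifelse(plus, "+", "-"), stringsAsFactors = FALSE)
    })
    ip <- do.call(rbind, c(site_reads,
                           list(background_reads(spec$chrom, spec$chrom_len,
                                                 spec$background_rate, rl))))
    ip$start <- pmax(ip$start, 0)
    ip$end <- pmin(ip$end, spec$chrom_len)
    control <- background_reads(spec$chrom, spec$chrom_len,
                                spec$control_rate, rl)
    truth <- list(sites = spec$sites, total_ip = nrow(ip),
                  total_control = nrow(control))
    sizes <- stats::setNames(spec$chrom_len, spec$chrom)
    list(ip = ip, control = control, truth = truth, sizes = sizes)
  })
}

#' Write simulated reads as BED6
#'
#' @param reads data.frame of reads.
#' @param path output BED file.
#' @export
write_bed <- function(reads, path) {
  if (nrow(reads) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  lines <- sprintf("%s\t%d\t%d\tread_%d\t0\t%s", reads$chrom, reads$start,
                   reads$end, seq_len(nrow(reads)), reads$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Write a chromosome sizes table
#'
#' @param sizes named vector of chromosome lengths.
#' @param path output TSV.
#' @export
write_chrom_sizes <- function(sizes, path) {
  writeLines(sprintf("%s\t%d", names(sizes), sizes), path)
  invisible(path)
}
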