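# Mapped-read input, read elongation, binned coverage profiles and track I/O.
#
# Coordinates are BED-style internally: 0-based, half-open [start, end).
# Wiggle output is written 1-based per the fixedStep format specification.

#' Read a two-column chromosome sizes table
#'
#' @param path TSV with columns chromosome name and length in bp.
#' @return named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stopf("chrom sizes file not found: %s", path)
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "length"))
  if (anyDuplicated(tab$chrom)) stopf("duplicate chromosome names in %s", path)
  len <- as.numeric(tab$length)
  if (any(!is.finite(len)) || any(len <= 0)) {
    stopf("chromosome lengths must be positive integers in %s", path)
  }
  stats::setNames(len, tab$chrom)
}

#' Read mapped reads from a BED6 file
#'
#' Expects at least six whitespace-separated columns
#' (chrom, start, end, name, score, strand). Reads on chromosomes absent from
#' the sizes table are dropped with a logged count; malformed lines are hard
#' errors naming the offending line number.
#'
#' @param path BED file.
#' @param sizes named vector of chromosome lengths (see [read_chrom_sizes()]).
#' @return data.frame with columns chrom, start, end, strand
#'   (0-based half-open intervals).
#' @export
read_bed <- function(path, sizes) {
  if (!file.exists(path)) stopf("BED file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "[ \t]+")
  ncol <- vapply(fields, length, 0L)
  bad <- which(ncol < 6)
  if (length(bad)) stopf("BED line %d has %d fields; need >= 6", bad[1], ncol[bad[1]])
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  strand <- vapply(fields, `[[`, "", 6)
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stopf("BED line %d: non-numeric start/end", bad[1])
  bad <- which(start < 0 | start >= end)
  if (length(bad)) stopf("BED line %d: need 0 <= start < end", bad[1])
  bad <- which(!(strand %in% c("+", "-")))
  if (length(bad)) stopf("BED line %d: strand must be '+' or '-', got '%s'",
                         bad[1], strand[bad[1]])
  keep <- chrom %in% names(sizes)
  if (any(!keep)) {
    pd_log("read_bed: dropped %d reads on chromosomes absent from sizes table",
           sum(!keep))
  }
  reads <- data.frame(chrom = chrom[keep], start = start[keep],
                      end = end[keep], strand = strand[keep],
                      stringsAsFactors = FALSE)
  over <- reads$end > sizes[reads$chrom]
  if (any(over)) stopf("%d reads extend past their chromosome end", sum(over))
  reads
}

#' Elongate reads to a fixed fragment length
#'
#' Each sequenced read marks the 5' end of an immunoprecipitated chromatin
#' fragment; before coverage counting every read is extended 3'-wards to the
#' presumed fragment length `L`: plus-strand reads to [start, start + L),
#' minus-strand reads to [end - L, end), clipped to the chromosome.
#'
#' @param reads data.frame as returned by [read_bed()].
#' @param L target length in bp; must be >= every read length.
#' @param sizes named vector of chromosome lengths.
#' @return data.frame with columns chrom, start, end of elongated intervals.
#' @export
elongate_reads <- function(reads, L, sizes) {
  rl <- reads$end - reads$start
  if (any(L < rl)) {
    stopf("elongation L=%d is shorter than a read of length %d; reads cannot shrink",
          L, max(rl))
  }
  start <- ifelse(reads$strand == "+", reads$start, reads$end - L)
  end <- ifelse(reads$strand == "+", reads$start + L, reads$end)
  start <- pmax(start, 0)
  end <- pmin(end, sizes[reads$chrom])
  data.frame(chrom = reads$chrom, start = as.numeric(start),
             end = as.numeric(end), stringsAsFactors = FALSE)
}

#' Build a binned read-count intensity profile
#'
#' Elongates reads (see [elongate_reads()]) and counts, per bin of
#' `bin_size` bp, how many elongated reads overlap the bin by at least 1 bp.
#' Bin i covers genomic interval [i * bin_size, (i+1) * bin_size).
#'
#' @param reads data.frame of reads (chrom, start, end, strand).
#' @param sizes named vector of chromosome lengths.
#' @param elongation fragment length L in bp (default 150).
#' @param bin_size bin width in bp (default 10).
#' @param strand_filter one of "both", "+", "-".
#' @param dedup drop exact duplicate reads first.
#' @return a `coverage_profile`: list with bin_size, elongation,
#'   strand_filter, sizes and `counts`, a named list of per-chromosome
#'   numeric vectors of length ceiling(length / bin_size).
#' @export
build_coverage <- function(reads, sizes, elongation = 150, bin_size = 10,
                           strand_filter = c("both", "+", "-"),
                           dedup = FALSE) {
  strand_filter <- match.arg(strand_filter)
  if (bin_size < 1) stopf("bin_size must be >= 1")
  if (dedup) {
    reads <- unique(reads[, c("chrom", "start", "end", "strand")])
  }
  if (strand_filter != "both") {
    reads <- reads[reads$strand == strand_filter, , drop = FALSE]
  }
  if (nrow(reads) == 0) {
    stopf("no reads left after strand filtering (filter = '%s')", strand_filter)
  }
  ext <- elongate_reads(reads, elongation, sizes)
  counts <- lapply(names(sizes), function(chrom) {
    nbins <- ceiling(sizes[[chrom]] / bin_size)
    sel <- ext$chrom == chrom
    v <- numeric(nbins)
    if (any(sel)) {
      b0 <- floor(ext$start[sel] / bin_size) + 1          # first overlapped bin
      b1 <- floor((ext$end[sel] - 1) / bin_size) + 1      # last overlapped bin
      b1 <- pmin(b1, nbins)
      add <- tabulate(b0, nbins + 1)
      sub <- tabulate(b1 + 1, nbins + 1)
      v <- cumsum(add - sub)[seq_len(nbins)]
    }
    v
  })
  names(counts) <- names(sizes)
  structure(list(bin_size = bin_size, elongation = elongation,
                 strand_filter = strand_filter, sizes = sizes,
                 counts = counts),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("coverage_profile: %d chromosome(s), bin %d bp, elongation %d bp, strand %s\n",
              length(x$counts), x$bin_size, x$elongation, x$strand_filter))
  for (chrom in names(x$counts)) {
    v <- x$counts[[chrom]]
    cat(sprintf("  %s: %d bins, max %.1f, mean %.3f\n",
                chrom, length(v), max(v), mean(v)))
  }
  invisible(x)
}

#' Write a coverage profile as a wiggle or bedGraph track
#'
#' Wiggle is written fixedStep (1-based start, step = span = bin_size).
#' bedGraph is 0-based half-open with runs of equal value merged and zero
#' runs omitted. Both formats round-trip through [read_track()] to an
#' identical profile.
#'
#' @param profile a `coverage_profile`.
#' @param path output file.
#' @param format "wiggle" or "bedGraph".
#' @param header optional character vector of comment lines (prefixed '#')
#'   recorded at the top of the file.
#' @export
write_track <- function(profile, path, format = c("wiggle", "bedGraph"),
                        header = NULL) {
  format <- match.arg(format)
  bs <- profile$bin_size
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  for (chrom in names(profile$counts)) {
    v <- profile$counts[[chrom]]
    if (format == "wiggle") {
      writeLines(sprintf("fixedStep chrom=%s start=1 step=%d span=%d",
                         chrom, bs, bs), con)
      writeLines(format(v, trim = TRUE, scientific = FALSE), con)
    } else {
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      keep <- r$values != 0
      if (any(keep)) {
        writeLines(sprintf("%s\t%d\t%d\t%s", chrom,
                           starts[keep] * bs,
                           pmin(ends[keep] * bs, profile$sizes[[chrom]]),
                           format(r$values[keep], trim = TRUE,
                                  scientific = FALSE)), con)
      }
    }
  }
  invisible(path)
}

#' Read a wiggle or bedGraph track back into a coverage profile
#'
#' @param path track file written by [write_track()].
#' @param sizes named vector of chromosome lengths.
#' @param bin_size bin width; required for bedGraph, inferred from the
#'   fixedStep header for wiggle.
#' @param format "wiggle" or "bedGraph"; inferred from content if omitted.
#' @return a `coverage_profile` (elongation and strand filter unknown: NA).
#' @export
read_track <- function(path, sizes, bin_size = NULL, format = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (is.null(format)) {
    format <- if (any(startsWith(lines, "fixedStep"))) "wiggle" else "bedGraph"
  }
  counts <- list()
  if (format == "wiggle") {
    hdr <- which(startsWith(lines, "fixedStep"))
    bounds <- c(hdr, length(lines) + 1L)
    for (i in seq_along(hdr)) {
      h <- lines[hdr[i]]
      chrom <- sub(".*chrom=([^ ]+).*", "\\1", h)
      step <- as.integer(sub(".*step=([0-9]+).*", "\\1", h))
      if (is.null(bin_size)) bin_size <- step
      vals <- as.numeric(lines[(hdr[i] + 1L):(bounds[i + 1L] - 1L)])
      nbins <- ceiling(sizes[[chrom]] / bin_size)
      v <- numeric(nbins)
      v[seq_along(vals)] <- vals
      counts[[chrom]] <- v
    }
  } else {
    if (is.null(bin_size)) stopf("bin_size required to read bedGraph")
    fields <- strsplit(lines, "\t")
    chrom <- vapply(fields, `[[`, "", 1)
    s <- as.numeric(vapply(fields, `[[`, "", 2))
    e <- as.numeric(vapply(fields, `[[`, "", 3))
    val <- as.numeric(vapply(fields, `[[`, "", 4))
    for (ch in names(sizes)) {
      nbins <- ceiling(sizes[[ch]] / bin_size)
      v <- numeric(nbins)
      sel <- which(chrom == ch)
      for (j in sel) {
        b0 <- s[j] / bin_size + 1
        b1 <- ceiling(e[j] / bin_size)
        v[b0:b1] <- val[j]
      }
      counts[[ch]] <- v
    }
  }
  for (ch in names(sizes)) {
    if (is.null(counts[[ch]])) counts[[ch]] <- numeric(ceiling(sizes[[ch]] / bin_size))
  }
  structure(list(bin_size = bin_size, elongation = NA_integer_,
                 strand_filter = NA_character_, sizes = sizes,
                 counts = counts[names(sizes)]),
            class = "coverage_profile")
}
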