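# Read parsing, elongation, binned coverage and track round-trips.

sizes1 <- c(chr1 = 100000)

write_bed_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".bed",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("read_bed maps BED6 fields and enforces the contract", {
  path <- write_bed_lines(c("chr1\t100\t136\tr1\t0\t+",
                            "chr1\t500\t536\tr2\t0\t-",
                            "chrUn\t10\t46\tr3\t0\t+"))
  withr::local_options(peakdeconv.verbose = TRUE)
  expect_message(reads <- read_bed(path, sizes1), "dropped 1 reads")
  expect_equal(nrow(reads), 2)
  expect_equal(reads$start[1], 100)
  expect_equal(reads$end[1], 136)
  expect_equal(reads$strand, c("+", "-"))

  empty <- write_bed_lines(character())
  expect_equal(nrow(read_bed(empty, sizes1)), 0)

  star <- write_bed_lines("chr1\t100\t136\tr1\t0\t*")
  expect_error(read_bed(star, sizes1), "line 1.*strand")
  swapped <- write_bed_lines("chr1\t136\t100\tr1\t0\t+")
  expect_error(read_bed(swapped, sizes1), "start < end")
  short <- write_bed_lines("chr1\t100\t136")
  expect_error(read_bed(short, sizes1), "need >= 6")
})

test_that("elongation extends 3'-wards per strand and clips at edges", {
  reads <- data.frame(chrom = "chr1",
                      start = c(100, 1000, 40),
                      end = c(136, 1036, 76),
                      strand = c("+", "-", "-"),
                      stringsAsFactors = FALSE)
  ext <- elongate_reads(reads, 150, sizes1)
  expect_equal(ext$start, c(100, 886, 0))
  expect_equal(ext$end, c(250, 1036, 76))
  expect_error(elongate_reads(reads, 20, sizes1), "cannot shrink")
})

test_that("coverage counts elongated-read overlaps per bin", {
  reads <- data.frame(chrom = "chr1", start = 100, end = 136, strand = "+",
                      stringsAsFactors = FALSE)
  prof <- build_coverage(reads, sizes1, elongation = 150, bin_size = 10)
  v <- prof$counts$chr1
  expect_equal(which(v > 0), 11:25)          # [100, 250) covers bins 11..25
  expect_true(all(v[11:25] == 1))

  two <- rbind(reads, reads)
  prof2 <- build_coverage(two, sizes1, elongation = 150, bin_size = 10)
  expect_equal(prof2$counts$chr1, 2 * v)

  expect_error(build_coverage(reads, sizes1, strand_filter = "-"),
               "no reads")
})

test_that("coverage is conserved exactly at bin_size = 1", {
  set.seed(3)
  n <- 50
  start <- sample(500:5000, n)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  reads <- data.frame(chrom = "chr1", start = start, end = start + 36,
                      strand = strand, stringsAsFactors = FALSE)
  prof <- build_coverage(reads, sizes1, elongation = 150, bin_size = 1)
  expect_equal(sum(prof$counts$chr1), n * 150)
})

test_that("profiles shift with the reads and ignore read order", {
  set.seed(4)
  start <- sample(1000:5000, 30)
  reads <- data.frame(chrom = "chr1", start = start, end = start + 36,
                      strand = sample(c("+", "-"), 30, replace = TRUE),
                      stringsAsFactors = FALSE)
  prof <- build_coverage(reads, sizes1, elongation = 150, bin_size = 10)
  shifted <- reads
  shifted$start <- reads$start + 30          # 3 bins
  shifted$end <- reads$end + 30
  prof_s <- build_coverage(shifted, sizes1, elongation = 150, bin_size = 10)
  n <- length(prof$counts$chr1)
  expect_equal(prof_s$counts$chr1[4:n], prof$counts$chr1[1:(n - 3)])

  perm <- reads[sample(nrow(reads)), ]
  prof_p <- build_coverage(perm, sizes1, elongation = 150, bin_size = 10)
  expect_identical(prof_p$counts, prof$counts)
})

test_that("wiggle and bedGraph tracks round-trip bit-exactly", {
  prof <- make_profile(c(0, 0, 3, 3, 1.5, 0, 7), bin_size = 10,
                       chrom = "chr1")
  for (fmt in c("wiggle", "bedGraph")) {
    path <- withr::local_tempfile(fileext = ".txt")
    write_track(prof, path, format = fmt)
    back <- read_track(path, prof$sizes, bin_size = 10)
    expect_equal(back$counts, prof$counts, info = fmt)
    expect_equal(back$bin_size, prof$bin_size)
  }
})

test_that("track formats follow their coordinate conventions", {
  prof <- make_profile(c(0, 0, 3), bin_size = 10, chrom = "chr1")
  bg <- withr::local_tempfile()
  write_track(prof, bg, format = "bedGraph")
  expect_equal(readLines(bg), "chr1\t20\t30\t3")

  wig <- withr::local_tempfile()
  write_track(prof, wig, format = "wiggle")
  expect_equal(readLines(wig)[1],
               "fixedStep chrom=chr1 start=1 step=10 span=10")
})

test_that("chromosome sizes tables parse and validate", {
  path <- withr::local_tempfile()
  writeLines(c("chr1\t1000", "chr2\t500"), path)
  sizes <- read_chrom_sizes(path)
  expect_equal(sizes, c(chr1 = 1000, chr2 = 500))
  writeLines(c("chr1\t1000", "chr1\t500"), path)
  expect_error(read_chrom_sizes(path), "duplicate")
})
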