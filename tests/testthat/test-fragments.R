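test_that("genome binning tiles chromosomes with ceil(len/w) bins", {
  b <- genome_binning(c(chr1 = 1050, chr2 = 300), bin_width = 100)
  expect_equal(b$n_bins, 11 + 3)
  expect_equal(unname(b$bins_per_chrom), c(11, 3))
  # every position maps to exactly one bin, and bins partition the genome
  idx1 <- bin_index(b, rep("chr1", 1050), 0:1049)
  expect_equal(as.integer(table(idx1)), c(rep(100L, 10), 50L))
  expect_equal(range(idx1), c(1, 11))
  idx2 <- bin_index(b, rep("chr2", 300), 0:299)
  expect_equal(range(idx2), c(12, 14))
  # round trip through bin_coords
  co <- bin_coords(b, c(1, 11, 12, 14))
  expect_equal(co$chrom, c("chr1", "chr1", "chr2", "chr2"))
  expect_equal(co$start, c(0, 1000, 0, 200))
  expect_equal(co$end, c(100, 1050, 100, 300))  # last chr1 bin truncated
})

test_that("length classification uses the 140/280 boundaries", {
  cls <- classify_length(c(1, 140, 141, 280, 281, 1000))
  expect_equal(as.character(cls),
               c("subnucleosomal", "subnucleosomal", "nucleosomal",
                 "nucleosomal", "polynucleosomal", "polynucleosomal"))
  # partition property: three contiguous runs over 1..1000
  runs <- rle(as.character(classify_length(1:1000)))
  expect_equal(runs$values,
               c("subnucleosomal", "nucleosomal", "polynucleosomal"))
  expect_equal(runs$lengths, c(140, 140, 720))
  expect_error(classify_length(0), "length")
})

test_that("extremity counting places both fragment termini", {
  b <- genome_binning(c(chr1 = 1000), 100)
  # fragment [105,245): extremities at 105 and 244 -> bins 2 and 3
  v <- count_extremities(data.frame(chrom = "chr1", start = 105, end = 245),
                         b, class_filter = NULL)
  expect_equal(which(v > 0), c(2L, 3L))
  expect_equal(sum(v), 2L)
  # fragment [100,150): both extremities (100, 149) land in bin 2
  v <- count_extremities(data.frame(chrom = "chr1", start = 100, end = 150),
                         b, class_filter = NULL)
  expect_equal(v[2], 2L)
  expect_equal(sum(v), 2L)
  # empty input -> all-zero column
  expect_equal(sum(count_extremities(
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0)),
    b, class_filter = NULL)), 0L)
})

test_that("extremity counts conserve 2x fragment number and respect the class filter", {
  set.seed(11)
  b <- genome_binning(c(chrA = 5e4, chrB = 3e4), 100)
  for (rep in 1:5) {
    n <- sample(50:400, 1)
    chrom <- sample(c("chrA", "chrB"), n, replace = TRUE)
    start <- floor(runif(n) * (c(chrA = 5e4, chrB = 3e4)[chrom] - 700))
    len <- sample(30:600, n, replace = TRUE)
    fr <- data.frame(chrom = chrom, start = start, end = start + len)
    expect_equal(sum(count_extremities(fr, b, class_filter = NULL)), 2L * n)
    n_sub <- sum(len <= 140)
    expect_equal(sum(count_extremities(fr, b, "subnucleosomal")), 2L * n_sub)
  }
})

test_that("binning is translation-consistent by one bin width", {
  b <- genome_binning(c(chr1 = 1e5), 100)
  set.seed(5)
  start <- sample(1000:5e4, 200)
  fr <- data.frame(chrom = "chr1", start = start, end = start + 90)
  fr2 <- transform(fr, start = start + 100, end = end + 100)
  v1 <- count_extremities(fr, b, class_filter = NULL)
  v2 <- count_extremities(fr2, b, class_filter = NULL)
  expect_equal(which(v2 > 0), which(v1 > 0) + 1L)
  expect_equal(v2[v2 > 0], v1[v1 > 0])
})

test_that("BED fragments round-trip and invalid records are handled", {
  b <- genome_binning(c(chr1 = 1e4, chr2 = 5e3), 100)
  fr <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                   start = c(105, 0, 4000), end = c(245, 140, 4600))
  bed <- tempfile(fileext = ".bed")
  write_fragments(fr, bed)
  rd <- read_fragments(bed, b)
  expect_equal(rd$fragments[, c("chrom", "start", "end")], fr)
  expect_equal(rd$fragments$length, c(140, 140, 600))
  expect_equal(rd$report$n_kept, 3)

  # zero-length record rejected, unknown chromosome dropped and reported
  writeLines(c("chr1\t105\t245", "chr1\t10\t10", "chrUn\t5\t50"), bed)
  rd <- suppressMessages(read_fragments(bed, b))
  expect_equal(rd$report$n_rejected, 1)
  expect_equal(rd$report$n_dropped_chrom, 1)
  expect_equal(nrow(rd$fragments), 1)

  # malformed line errors with its line number
  writeLines(c("chr1\t105\t245", "chr1\tx\t50"), bed)
  expect_error(read_fragments(bed, b), "line 2")
})

test_that("BAM and BED representations of the same fragments count identically", {
  skip_if_not_installed("Rsamtools")
  b <- genome_binning(c(chr1 = 1e4), 100)
  frags <- data.frame(chrom = "chr1",
                      start = c(105, 0, 250, 1111, 9000),
                      end = c(245, 140, 1000, 1200, 9999))
  # write the pair-level SAM equivalent (POS is 1-based; TLEN = span)
  sam <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:chr1\tLN:10000")
  pos <- integer(0); recs <- character(0)
  for (i in seq_len(nrow(frags))) {
    s <- frags$start[i]; e <- frags$end[i]
    qn <- sprintf("frag%d", i)
    recs <- c(recs,
      sprintf("%s\t99\tchr1\t%d\t60\t20M\t=\t%d\t%d\t*\t*", qn, s + 1, e - 19, e - s),
      sprintf("%s\t147\tchr1\t%d\t60\t20M\t=\t%d\t%d\t*\t*", qn, e - 19, s + 1, -(e - s)))
    pos <- c(pos, s + 1, e - 19)
  }
  writeLines(c(hdr, recs[order(pos)]), sam)
  bam <- suppressMessages(Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                                           indexDestination = FALSE))
  from_bam <- read_fragments(bam, b)$fragments
  from_bam <- from_bam[order(from_bam$start), ]
  bed <- tempfile(fileext = ".bed")
  write_fragments(frags, bed)
  from_bed <- read_fragments(bed, b)$fragments
  from_bed <- from_bed[order(from_bed$start), ]
  expect_equal(from_bam$start, from_bed$start)
  expect_equal(from_bam$end, from_bed$end)
  expect_equal(count_extremities(from_bam, b, NULL),
               count_extremities(from_bed, b, NULL))
})
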