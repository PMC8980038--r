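gr0 <- function(df) intervals_to_granges(df)

test_that("flanks are 20 kb on both sides, clipped and trimmed of gene bodies", {
  sizes <- c(chr1 = 1e6)
  genes <- gr0(data.frame(chrom = "chr1", start = 50000, end = 60000))
  fl <- make_flanks(genes, flank = 20000, chrom_sizes = sizes,
                    trim_genic = FALSE)
  df <- data.frame(chrom = "chr1",
                   start = GenomicRanges::start(fl) - 1,
                   end = GenomicRanges::end(fl))
  expect_equal(df$start, c(30000, 60000))
  expect_equal(df$end, c(50000, 80000))

  # gene starting at 5 kb: upstream flank clipped to [0, 5000)
  genes2 <- gr0(data.frame(chrom = "chr1", start = 5000, end = 9000))
  fl2 <- make_flanks(genes2, 20000, sizes, trim_genic = FALSE)
  expect_equal(min(GenomicRanges::start(fl2)) - 1, 0)
  expect_equal(GenomicRanges::end(fl2)[1], 5000)

  # two genes 10 kb apart: the inter-genic flank is trimmed to the gap
  genes3 <- gr0(data.frame(chrom = "chr1", start = c(100000, 130000),
                           end = c(120000, 150000)))
  fl3 <- make_flanks(genes3, 20000, sizes, trim_genic = TRUE)
  gap <- fl3[GenomicRanges::start(fl3) - 1 >= 120000 &
               GenomicRanges::end(fl3) <= 130000]
  expect_equal(GenomicRanges::start(gap) - 1, 120000)
  expect_equal(GenomicRanges::end(gap), 130000)
})

test_that("overlap uses half-open semantics: touching intervals do not overlap", {
  sizes <- c(chr1 = 1e5)
  genes <- gr0(data.frame(chrom = "chr1", start = 200, end = 5000))
  q_in <- data.frame(chrom = "chr1", start = 150, end = 250)   # 50-bp overlap
  q_out <- data.frame(chrom = "chr1", start = 150, end = 200)  # touching
  s_in <- overlap_summary(q_in, genes, chrom_sizes = sizes)
  s_out <- overlap_summary(q_out, genes, chrom_sizes = sizes)
  expect_equal(s_in$per_feature$genes$n_query_overlapping, 1)
  expect_equal(s_out$per_feature$genes$n_query_overlapping, 0)
})

test_that("constructed fixture recovers known gene/flank/intergenic fractions", {
  sizes <- c(chr1 = 1e6)
  genes <- gr0(data.frame(chrom = "chr1",
                          start = c(100000, 500000), end = c(200000, 600000)))
  flanks <- make_flanks(genes, 20000, sizes)
  # 100 query intervals: 40 inside genes, 20 in flanks, 40 elsewhere
  q <- data.frame(
    chrom = "chr1",
    start = c(seq(110000, 190000, length.out = 40),        # genic
              seq(80500, 99000, length.out = 10),          # upstream flank
              seq(200500, 219000, length.out = 10),        # downstream flank
              seq(700000, 990000, length.out = 40)))       # intergenic
  q$start <- round(q$start); q$end <- q$start + 100
  s <- overlap_summary(q, genes, flanks = flanks, chrom_sizes = sizes)
  expect_equal(unname(s$exclusive_fractions), c(0.40, 0.20, 0.40))
  expect_equal(sum(s$exclusive_fractions), 1)
})

test_that("query- and feature-side counts match the all-pairs oracle on random fixtures", {
  set.seed(31)
  sizes <- c(chrA = 2e5, chrB = 1e5)
  rand_iv <- function(n) {
    chrom <- sample(names(sizes), n, replace = TRUE)
    start <- floor(runif(n) * (sizes[chrom] - 2000))
    data.frame(chrom = chrom, start = unname(start),
               end = unname(start + sample(50:2000, n, replace = TRUE)))
  }
  for (rep in 1:4) {
    q <- rand_iv(300); f <- rand_iv(150)
    s <- overlap_summary(gr0(q), gr0(f), flanks = GenomicRanges::GRanges(),
                         chrom_sizes = sizes)
    expect_equal(s$per_feature$genes$n_query_overlapping,
                 sum(oracle_overlaps(q, f)))
    expect_equal(s$per_feature$genes$n_features_hit,
                 sum(oracle_overlaps(f, q)))
    # exclusive partition always sums to the number of query intervals
    expect_equal(sum(s$exclusive_counts), nrow(q))
  }
})

test_that("gene precedence over flank in the exclusive partition, cCREs counted independently", {
  sizes <- c(chr1 = 1e6)
  # geneA with a flank that overlaps geneB; query inside geneB only
  genes <- gr0(data.frame(chrom = "chr1", start = c(100000, 125000),
                          end = c(120000, 140000)))
  q <- data.frame(chrom = "chr1", start = 126000, end = 126100)
  s_incl <- overlap_summary(q, genes,
                            flanks = make_flanks(genes, 20000, sizes,
                                                 trim_genic = FALSE),
                            chrom_sizes = sizes)
  expect_equal(unname(s_incl$exclusive_counts["gene"]), 1)
  expect_equal(unname(s_incl$exclusive_counts["flank"]), 0)
  # an interval can count in several non-exclusive categories
  ccre <- gr0(data.frame(chrom = "chr1", start = 126050, end = 126250))
  s2 <- overlap_summary(q, genes, ccres = ccre, chrom_sizes = sizes)
  expect_equal(s2$per_feature$ccres$n_query_overlapping, 1)
  expect_equal(s2$per_feature$genes$n_query_overlapping, 1)
  # genome fraction covered
  expect_equal(unname(s2$genome_fraction["genes"]), 35000 / 1e6)
  # chromosome namespace mismatch errors
  bad <- gr0(data.frame(chrom = "scaffold_1", start = 0, end = 100))
  expect_error(overlap_summary(q, bad, chrom_sizes = sizes), "chromosome")
})
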