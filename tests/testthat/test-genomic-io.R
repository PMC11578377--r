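layout <- genome_layout(c("chr1", "chr2"), c(20000, 15000))

test_that("genome_layout enforces its invariants", {
  expect_error(genome_layout(c("a", "a"), c(10, 10)), "unique")
  expect_error(genome_layout("a", 0), "positive")
  expect_error(genome_layout(c("a", "b"), 10), "equal length")
})

test_that("read_bed parses BED3/BED6, validates and sorts", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t300\t400", "chr1\t100\t200"), f)
  gr <- read_bed(f, layout)
  expect_equal(start(gr) - 1, c(100, 300))  # 0-based starts, sorted
  expect_equal(end(gr), c(200, 400))
  expect_equal(as.character(strand(gr)), c("*", "*"))

  writeLines(character(0), f)
  expect_length(read_bed(f, layout), 0)

  writeLines("chr1\t200\t100", f)
  expect_error(read_bed(f, layout), "line 1.*start < end")

  writeLines("chr1\t100", f)
  expect_error(read_bed(f, layout), "line 1")

  writeLines("chr1\t100\t99999", f)
  expect_error(read_bed(f, layout), "out of chromosome bounds")

  writeLines("chrX\t1\t2", f)
  expect_error(read_bed(f, layout), "unknown chromosome")
})

test_that("write_bed / read_bed round-trips sorted input", {
  gr <- GenomicRanges::GRanges(c("chr1", "chr1", "chr2"),
                               IRanges::IRanges(c(101, 501, 11),
                                                c(200, 900, 40)))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(gr, f)
  back <- read_bed(f, layout)
  expect_equal(start(back), start(gr))
  expect_equal(end(back), end(gr))
  expect_equal(as.character(seqnames(back)), as.character(seqnames(gr)))
})

test_that("read_bedgraph fills gaps with zero and rejects overlaps", {
  small <- genome_layout("chr1", 20)
  f <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines("chr1\t0\t10\t2.0", f)
  tr <- read_bedgraph(f, small)
  expect_equal(as.numeric(tr$cov$chr1), c(rep(2, 10), rep(0, 10)))
  expect_equal(tr$total_mapped, 20)  # round(2 * 10)

  writeLines(c("chr1\t0\t10\t2.0", "chr1\t10\t20\t3.0"), f)
  tr <- read_bedgraph(f, small)
  expect_equal(as.numeric(tr$cov$chr1), c(rep(2, 10), rep(3, 10)))

  writeLines(c("chr1\t0\t10\t2.0", "chr1\t5\t15\t1.0"), f)
  expect_error(read_bedgraph(f, small), "overlapping")
})

test_that("bedGraph writing round-trips a track", {
  small <- genome_layout("chr1", 30)
  tr <- make_track(list(c(rep(0, 5), rep(2.5, 10), rep(0, 15))), small,
                   total_mapped = 1000)
  f <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, f)
  back <- read_bedgraph(f, small, total_mapped = 1000)
  expect_equal(as.numeric(back$cov$chr1), as.numeric(tr$cov$chr1))
})

test_that("read_genes computes strand-aware TSS and rejects bad input", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t500\tgeneA\t0\t+",
               "chr1\t1000\t1500\tgeneB\t0\t-"), f)
  genes <- read_genes(f, layout)
  t0 <- start(tss_positions(genes)) - 1  # 0-based TSS
  expect_equal(t0[genes$gene_id == "geneA"], 100)
  expect_equal(t0[genes$gene_id == "geneB"], 1499)  # end - 1, half-open

  writeLines(c("chr1\t100\t500\tgeneA\t0\t+",
               "chr1\t1000\t1500\tgeneA\t0\t-"), f)
  expect_error(read_genes(f, layout), "duplicate")

  writeLines("chr1\t100\t500\tgeneA\t0\t.", f)
  expect_error(read_genes(f, layout), "strand")
})

test_that("read_genes accepts GTF gene records with coordinate conversion", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(paste("chr1", "src", "gene", "101", "500", ".", "+", ".",
                   'gene_id "geneA";', sep = "\t"), f)
  genes <- read_genes(f, layout)
  expect_equal(genes$gene_id, "geneA")
  expect_equal(start(genes), 101)  # GTF 1-based inclusive == internal
  expect_equal(end(genes), 500)
})

test_that("rpkm follows the formula and its homogeneity properties", {
  expect_equal(rpkm(10, 2000, 2e6), 2.5)
  expect_equal(rpkm(0, 1234, 5e6), 0)
  # degree 1 in count, degree -1 in length and total
  expect_equal(rpkm(3 * 7, 500, 1e6), 3 * rpkm(7, 500, 1e6))
  expect_equal(rpkm(7, 2 * 500, 1e6), rpkm(7, 500, 1e6) / 2)
  expect_equal(rpkm(7, 500, 2 * 1e6), rpkm(7, 500, 1e6) / 2)
  expect_error(rpkm(1, 0, 1e6), "length")
  expect_error(rpkm(1, 100, 0), "total_mapped")
})

test_that("quantify sums per-base values and is additive over partitions", {
  small <- genome_layout("chr1", 1000)
  tr <- make_track(list(rep(1, 1000)), small, total_mapped = 1e6)
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
  expect_equal(quantify(tr, gr)$count, 100)

  tr2 <- make_track(list(c(rep(5, 100), rep(0, 900))), small)
  zero <- GenomicRanges::GRanges("chr1", IRanges::IRanges(501, 600))
  expect_equal(quantify(tr2, zero)$count, 0)

  set.seed(11)
  vals <- stats::rpois(1000, 3)
  tr3 <- make_track(list(vals), small, total_mapped = 1e6)
  for (i in 1:20) {
    s <- sort(sample(999, 2))
    whole <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
    cuts <- c(0, s, 1000)
    parts <- GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(start = cuts[-4] + 1, end = cuts[-1]))
    expect_equal(sum(quantify(tr3, parts)$count),
                 quantify(tr3, whole)$count)
  }

  outside <- GenomicRanges::GRanges("chr1", IRanges::IRanges(900, 1100))
  expect_error(quantify(tr3, outside), "out of chromosome bounds")
})
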