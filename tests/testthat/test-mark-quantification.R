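layout <- genome_layout("chr1", 100000)

mk_genes <- function(start0, end0, strand, ids = NULL, lay = layout) {
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(start0 + 1, end0),
                               strand = strand)
  suppressWarnings(GenomeInfoDb::seqinfo(gr) <- markshift:::as_seqinfo(lay))
  gr$gene_id <- if (is.null(ids)) sprintf("g%02d", seq_along(gr)) else ids
  gr
}

gr0 <- function(x) {
  data.frame(start0 = BiocGenerics::start(x) - 1, end0 = BiocGenerics::end(x))
}

test_that("gene_regions computes strand-aware promoter/body/whole-gene sets", {
  g <- mk_genes(10000, 20000, "+", "gA")
  r <- gene_regions(g, promoter_flank = 3000)
  expect_equal(gr0(r$Pro[["gA"]]), data.frame(start0 = 7000, end0 = 13000))
  expect_equal(gr0(r$GB[["gA"]]), data.frame(start0 = 13000, end0 = 20000))
  expect_equal(gr0(r$All[["gA"]]), data.frame(start0 = 7000, end0 = 20000))

  # minus strand: promoter centred on tss0 = end - 1 = 19999
  gm <- mk_genes(10000, 20000, "-", "gB")
  rm_ <- gene_regions(gm, promoter_flank = 3000)
  expect_equal(gr0(rm_$Pro[["gB"]]), data.frame(start0 = 16999, end0 = 22999))
  expect_equal(gr0(rm_$GB[["gB"]]), data.frame(start0 = 10000, end0 = 16999))

  # promoter clipped at the chromosome end
  ge <- mk_genes(95000, 99000, "-", "gC")
  re <- gene_regions(ge, promoter_flank = 3000)
  expect_equal(gr0(re$Pro[["gC"]]), data.frame(start0 = 95999, end0 = 100000))

  # gene shorter than the flank has an empty gene body
  gs <- mk_genes(50000, 52000, "+", "gD")
  rs <- gene_regions(gs, promoter_flank = 3000)
  expect_length(rs$GB[["gD"]], 0)

  # Pro and GB partition: disjoint, and contained in All
  set.seed(21)
  starts <- seq(5000, 85000, by = 10000)
  gg <- mk_genes(starts, starts + sample(2000:8000, length(starts)),
                 sample(c("+", "-"), length(starts), TRUE))
  rr <- gene_regions(gg, promoter_flank = 3000)
  for (id in gg$gene_id) {
    pro <- rr$Pro[[id]]
    gb <- rr$GB[[id]]
    if (length(gb) > 0) {
      expect_length(GenomicRanges::intersect(pro, gb, ignore.strand = TRUE), 0)
    }
    inside <- GenomicRanges::setdiff(c(GenomicRanges::granges(pro),
                                       GenomicRanges::granges(gb)),
                                     rr$All[[id]], ignore.strand = TRUE)
    expect_length(inside, 0)
  }
})

test_that("super-enhancer knee separates a dominant region and rejects flat curves", {
  lay <- genome_layout("chr1", 1000000)
  # five isolated regions with per-bp value 1,1,1,1,100 over 1 kb each
  starts0 <- seq(100000, 500000, by = 100000)
  vals <- c(1, 1, 1, 1, 100)
  v <- rep(0, 1e6)
  for (i in seq_along(starts0)) v[(starts0[i] + 1):(starts0[i] + 1000)] <- vals[i]
  track <- make_track(list(v), lay, total_mapped = 1e6)
  peaks <- df_to_gr(data.frame(chrom = "chr1", start0 = starts0,
                               end0 = starts0 + 1000), lay)
  no_prom <- GenomicRanges::GRanges()
  genes <- mk_genes(10000, 12000, "+", "g1", lay)  # far from all regions
  ses <- call_super_enhancers(peaks, track, no_prom, genes)
  expect_length(ses$se, 1)
  expect_equal(ses$cutoff_index, 4)
  expect_equal(unname(start(ses$se)) - 1, 500000)

  # equal signals: no region rises above the diagonal
  v[] <- 0
  for (s in starts0) v[(s + 1):(s + 1000)] <- 7
  flat <- make_track(list(v), lay, total_mapped = 1e6)
  expect_length(call_super_enhancers(peaks, flat, no_prom, genes)$se, 0)

  # fewer than 3 stitched regions: warning, empty set
  expect_warning(
    empty <- call_super_enhancers(peaks[1:2], track, no_prom, genes),
    "fewer than 3")
  expect_length(empty$se, 0)
})

test_that("stitching merges peaks within the gap and respects promoters", {
  lay <- genome_layout("chr1", 1000000)
  track <- make_track(list(rep(1, 1e6)), lay, total_mapped = 1e6)
  # two peaks 10 kb apart stitch at gap 12.5 kb; a third far away does not
  peaks <- df_to_gr(data.frame(chrom = "chr1",
                               start0 = c(10000, 22000, 500000),
                               end0 = c(12000, 24000, 502000)), lay)
  genes <- mk_genes(900000, 905000, "+", "g1", lay)
  suppressWarnings(
    ses <- call_super_enhancers(peaks, track, GenomicRanges::GRanges(), genes,
                                stitch_gap = 12500))
  expect_length(ses$stitched, 2)
  expect_equal(end(ses$stitched)[rank(start(ses$stitched))[1]], 24000)

  # a promoter overlapping the first peak removes it before stitching
  prom <- df_to_gr(data.frame(chrom = "chr1", start0 = 9000, end0 = 10500),
                   lay)
  suppressWarnings(
    ses2 <- call_super_enhancers(peaks, track, prom, genes,
                                 stitch_gap = 12500))
  expect_equal(min(start(ses2$stitched)) - 1, 22000)
})

test_that("SE calling is invariant under uniform signal scaling", {
  lay <- genome_layout("chr1", 1000000)
  set.seed(31)
  starts0 <- seq(50000, 950000, by = 50000)
  vals <- c(stats::runif(length(starts0) - 2, 1, 3), 40, 55)
  v <- rep(0, 1e6)
  for (i in seq_along(starts0)) v[(starts0[i] + 1):(starts0[i] + 1500)] <- vals[i]
  peaks <- df_to_gr(data.frame(chrom = "chr1", start0 = starts0,
                               end0 = starts0 + 1500), lay)
  genes <- mk_genes(10000, 12000, "+", "g1", lay)
  s1 <- call_super_enhancers(peaks, make_track(list(v), lay, 1e6),
                             GenomicRanges::GRanges(), genes)
  s2 <- call_super_enhancers(peaks, make_track(list(v * 17), lay, 1e6),
                             GenomicRanges::GRanges(), genes)
  expect_equal(start(s1$se), start(s2$se))
  expect_equal(s1$cutoff_index, s2$cutoff_index)
  expect_length(s1$se, 2)
})

test_that("region_gain applies the inclusive fold-change boundary", {
  lay <- genome_layout("chr1", 40000)
  g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10001, 20000),
                              strand = "+")
  suppressWarnings(GenomeInfoDb::seqinfo(g) <- markshift:::as_seqinfo(lay))
  g$gene_id <- "gA"
  regions <- gene_regions(g, promoter_flank = 3000)
  # constant tracks with equal library size: fc is the value ratio
  mk <- function(val) make_track(list(rep(val, 40000)), lay,
                                 total_mapped = 4e6)
  tab <- region_gain(mk(1.0), mk(1.3), regions, threshold = 1.3,
                     pseudocount = 0)
  expect_true(all(tab$fc == 1.3))
  expect_true(all(tab$gained))

  tab <- region_gain(mk(2.0), mk(1.0), regions, threshold = 1.3,
                     pseudocount = 0)
  expect_true(all(tab$fc == 0.5))
  expect_true(all(tab$lost))
  expect_false(any(tab$gained))

  tab <- region_gain(mk(1.0), mk(1.2), regions, threshold = 1.3,
                     pseudocount = 0)
  expect_false(any(tab$gained))
  expect_false(any(tab$lost))
})

test_that("raising the threshold never adds genes to a gain set", {
  lay <- genome_layout("chr1", 200000)
  set.seed(41)
  starts <- seq(5000, 180000, by = 20000)
  g <- GenomicRanges::GRanges("chr1",
                              IRanges::IRanges(starts + 1, starts + 8000),
                              strand = "+")
  suppressWarnings(GenomeInfoDb::seqinfo(g) <- markshift:::as_seqinfo(lay))
  g$gene_id <- sprintf("g%02d", seq_along(g))
  regions <- gene_regions(g, promoter_flank = 3000)
  va <- stats::rpois(200000, 2) + 1
  vb <- va * rep(stats::runif(200, 0.5, 2.5), each = 1000)
  ta <- make_track(list(va), lay)
  tb <- make_track(list(vb), lay)
  sets_lo <- gain_gene_sets(region_gain(ta, tb, regions, threshold = 1.3))
  sets_hi <- gain_gene_sets(region_gain(ta, tb, regions, threshold = 1.6))
  for (cls in names(sets_lo)) {
    expect_true(all(sets_hi[[cls]] %in% sets_lo[[cls]]))
  }
})

test_that("gain sets are separated by region class", {
  tab <- structure(
    data.frame(gene_id = c("g1", "g1"), class = c("Pro", "SE"),
               ctrl_rpkm = c(1, 1), ko_rpkm = c(2, 1),
               fc = c(2, 1), gained = c(TRUE, FALSE),
               lost = c(FALSE, FALSE), stringsAsFactors = FALSE),
    class = c("RegionGainTable", "data.frame"))
  sets <- gain_gene_sets(tab)
  expect_equal(sets$Pro, "g1")
  expect_length(sets$SE, 0)
  empty <- tab[0, ]
  class(empty) <- c("RegionGainTable", "data.frame")
  expect_true(all(lengths(gain_gene_sets(empty)) == 0))
})
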