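layout1 <- genome_layout("chr1", 30000)

peak_gr <- function(chrom, start0, end0, layout) {
  df_to_gr(data.frame(chrom = chrom, start0 = start0, end0 = end0), layout)
}

test_that("tile_windows covers every basepair with the stated grid", {
  g <- tile_windows(genome_layout("chr1", 30000), 6000, 6000)
  expect_length(g$windows, 5)

  g <- tile_windows(genome_layout("chr1", 31000), 6000, 6000)
  expect_length(g$windows, 6)
  expect_equal(start(g$windows[6]) - 1, 30000)
  expect_equal(end(g$windows[6]), 31000)

  # step 3000, size 6000, length 12000: starts 0,3000,6000,9000
  g <- tile_windows(genome_layout("chr1", 12000), 6000, 3000)
  expect_length(g$windows, 4)
  expect_equal(end(g$windows[4]), 12000)

  expect_error(tile_windows(layout1, 6000, 0), "step")
  expect_error(tile_windows(layout1, 6000, 9000), "step")
})

test_that("call_lost_domains qualifies and merges windows as specified", {
  grid <- tile_windows(layout1, 6000, 6000)
  ctrl <- peak_gr("chr1", 1000, 1500, layout1)
  none <- peak_gr(character(0), numeric(0), numeric(0), layout1)

  dom <- call_lost_domains(ctrl, none, grid)
  expect_length(dom$domains, 1)
  expect_equal(start(dom$domains) - 1, 0)
  expect_equal(end(dom$domains), 6000)

  # KO peak straddling windows 0 and 1 disqualifies window 0
  ko <- peak_gr("chr1", 5900, 6100, layout1)
  expect_length(call_lost_domains(ctrl, ko, grid)$domains, 0)

  # no control peaks: empty regardless of KO peaks
  expect_length(call_lost_domains(none, ko, grid)$domains, 0)

  # adjacent qualifying windows merge, provenance keeps window identity
  ctrl2 <- peak_gr("chr1", c(1000, 7000), c(1500, 7500), layout1)
  dom2 <- call_lost_domains(ctrl2, none, grid)
  expect_length(dom2$domains, 1)
  expect_equal(end(dom2$domains), 12000)
  expect_equal(dom2$provenance[[1]], c(1L, 2L))

  # mixed factors rejected
  a <- ctrl
  a$factor <- "SIN3B"
  b <- ko
  b$factor <- "HDAC1"
  expect_error(call_lost_domains(a, b, grid), "factor")
})

test_that("call_lost_domains matches the brute-force window scan", {
  set.seed(101)
  for (i in 1:30) {
    lay <- genome_layout(c("chrA", "chrB"),
                         c(sample(5e5:1e6, 1), sample(2e5:6e5, 1)))
    ctrl_df <- random_peaks_df(lay)
    ko_df <- random_peaks_df(lay)
    got <- call_lost_domains(df_to_gr(ctrl_df, lay), df_to_gr(ko_df, lay),
                             tile_windows(lay, 6000, 6000))$domains
    want <- brute_lost_domains(ctrl_df, ko_df, lay$chrom, lay$length)
    expect_equal(length(got), nrow(want))
    if (nrow(want)) {
      expect_equal(start(got) - 1, want$start0)
      expect_equal(end(got), want$end0)
      expect_equal(as.character(seqnames(got)), want$chrom)
    }
  }
})

test_that("domain calling is monotone in the peak sets", {
  set.seed(77)
  lay <- genome_layout("chr1", 5e5)
  grid <- tile_windows(lay, 6000, 6000)
  total_bp <- function(d) sum(width(d$domains))
  for (i in 1:10) {
    ctrl <- df_to_gr(random_peaks_df(lay), lay)
    ko <- df_to_gr(random_peaks_df(lay, n_mean = 10), lay)
    base <- total_bp(call_lost_domains(ctrl, ko, grid))
    extra_ko <- c(ko, df_to_gr(random_peaks_df(lay, n_mean = 5), lay))
    expect_lte(total_bp(call_lost_domains(ctrl, extra_ko, grid)), base)
    extra_ctrl <- c(ctrl, df_to_gr(random_peaks_df(lay, n_mean = 5), lay))
    expect_gte(total_bp(call_lost_domains(extra_ctrl, ko, grid)), base)
  }
})

test_that("select_peaks_in_domains applies the half-open overlap rule", {
  dom <- peak_gr("chr1", 6000, 12000, layout1)
  peaks <- peak_gr("chr1", c(12000, 7000, 0, 11900, 20000),
                   c(12500, 8000, 6000, 12100, 21000), layout1)
  sel <- select_peaks_in_domains(peaks, dom)
  # abutting peaks ([,6000) and [12000,)) share no basepair -> excluded
  expect_equal(sort(start(sel) - 1), c(7000, 11900))
})

test_that("domain_correlation recovers perfect and inverted relationships", {
  lay <- genome_layout("chr1", 60000)
  set.seed(5)
  v <- rep(stats::rpois(10, 8) + 1, each = 6000)  # constant per domain
  tr <- make_track(list(v), lay, total_mapped = 1e6)
  dom <- peak_gr("chr1", seq(0, 54000, by = 6000), seq(6000, 60000, by = 6000),
                 lay)
  expect_equal(domain_correlation(tr, tr, dom)$r, 1.0)

  # reciprocal per-domain values make log signals exactly anti-linear
  tr2 <- make_track(list(100 / v), lay, total_mapped = 1e6)
  expect_equal(domain_correlation(tr, tr2, dom, pseudocount = 0)$r, -1.0)

  flat <- make_track(list(rep(2, 60000)), lay, total_mapped = 1e6)
  rep_flat <- domain_correlation(flat, tr, dom)
  expect_true(rep_flat$undefined)
  expect_true(is.na(rep_flat$r))

  expect_error(domain_correlation(tr, tr, dom[1:2]), ">= 3 domains")
})

test_that("correlation is invariant to library-size rescaling at pc = 0", {
  lay <- genome_layout("chr1", 60000)
  set.seed(9)
  va <- rep(stats::rpois(60, 6) + 1, each = 1000)
  vb <- rep(stats::rpois(60, 6) + 1, each = 1000)
  dom <- peak_gr("chr1", seq(0, 54000, by = 6000),
                 seq(6000, 60000, by = 6000), lay)
  r1 <- domain_correlation(make_track(list(va), lay, 1e6),
                           make_track(list(vb), lay, 1e6), dom,
                           pseudocount = 0)$r
  r2 <- domain_correlation(make_track(list(va), lay, 7e6),
                           make_track(list(vb), lay, 3e6), dom,
                           pseudocount = 0)$r
  expect_equal(r1, r2)
})

test_that("signal_matrix bins, clips and reverses minus-strand anchors", {
  lay <- genome_layout("chr1", 20000)
  flat <- make_track(list(rep(3, 20000)), lay, total_mapped = 1e6)
  anchor <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10001, 10001),
                                   strand = "+")
  m <- signal_matrix(flat, anchor, flank = 3000, n_bins = 10)
  expect_true(all(m == 3))

  # single spike at the anchor: central bin maximal
  v <- rep(0, 20000)
  v[10001] <- 100
  spike <- make_track(list(v), lay, total_mapped = 1e6)
  m <- signal_matrix(spike, anchor, flank = 3000, n_bins = 10)
  expect_equal(which.max(m[1, ]), 6)  # bin containing [anchor, anchor+600)

  # minus-strand row equals the reversed plus-strand row
  set.seed(3)
  v <- stats::rpois(20000, 2) + rep(0:1, each = 10000) * 5
  tr <- make_track(list(v), lay, total_mapped = 1e6)
  plus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(9000, 9000),
                                 strand = "+")
  minus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(9000, 9000),
                                  strand = "-")
  mp <- signal_matrix(tr, plus, flank = 2000, n_bins = 8)
  mm <- signal_matrix(tr, minus, flank = 2000, n_bins = 8)
  expect_equal(mm[1, ], rev(mp[1, ]))

  # anchor near the chromosome start: off-chromosome bins are NA
  edge <- GenomicRanges::GRanges("chr1", IRanges::IRanges(501, 501),
                                 strand = "+")
  me <- signal_matrix(tr, edge, flank = 3000, n_bins = 10)
  expect_true(anyNA(me))
  expect_false(anyNA(me[1, 6:10]))
})
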