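#' Tile a genome with fixed-size windows
#'
#' Windows start every `step` basepairs from position 0 of each chromosome;
#' the last window of a chromosome is truncated at its end, so every
#' basepair is covered.
#'
#' @param layout A [genome_layout()].
#' @param window_size Window width in basepairs (default 6000, the domain
#'   width used throughout the package).
#' @param step Distance between window starts; `0 < step <= window_size`.
#'   Defaults to `window_size` (non-overlapping tiling).
#' @return An object of class `WindowGrid`: list with the `GRanges` of
#'   `windows` plus `window_size` and `step`.
#' @export
tile_windows <- function(layout, window_size = 6000, step = window_size) {
  stopifnot(inherits(layout, "GenomeLayout"))
  if (!is.finite(step) || step <= 0) stop("step must be > 0")
  if (step > window_size) stop("step must be <= window_size")
  parts <- lapply(seq_len(nrow(layout)), function(i) {
    len <- layout$length[i]
    starts0 <- seq(0, len - 1, by = step)  # 0-based window starts
    list(chrom = rep(layout$chrom[i], length(starts0)),
         ranges = IRanges::IRanges(start = starts0 + 1,
                                   end = pmin(starts0 + window_size, len)))
  })
  windows <- bind_to_layout(
    GenomicRanges::GRanges(unlist(lapply(parts, `[[`, "chrom")),
                           do.call(c, lapply(parts, `[[`, "ranges"))),
    layout)
  structure(list(windows = windows, window_size = window_size, step = step),
            class = "WindowGrid")
}

#' @export
print.WindowGrid <- function(x, ...) {
  cat("WindowGrid:", length(x$windows), "windows of", x$window_size,
      "bp, step", x$step, "bp\n")
  invisible(x)
}

#' Call condition-lost binding domains on a window grid
#'
#' A window qualifies when at least one control peak overlaps it by >= 1 bp
#' and no knockout peak overlaps it; overlapping or book-ended qualifying
#' windows are merged into domains. This is the binding-domain definition
#' used for a factor whose peaks disappear in the knockout.
#'
#' @param control_peaks,ko_peaks `GRanges` peak sets for the same factor in
#'   the two conditions. If both carry a `factor` metadata column the
#'   factors must agree.
#' @param grid A [tile_windows()] grid.
#' @return An object of class `BindingDomainSet`: list with `domains` (a
#'   `GRanges` with `name` = domain id and `n_windows` = contributing
#'   window count), `provenance` (per-domain integer vector of window
#'   indices into `grid$windows`), and the `grid`.
#' @export
call_lost_domains <- function(control_peaks, ko_peaks, grid) {
  stopifnot(inherits(grid, "WindowGrid"))
  fa <- unique(as.character(control_peaks$factor))
  fb <- unique(as.character(ko_peaks$factor))
  if (length(fa) > 1L || length(fb) > 1L ||
      (length(fa) == 1L && length(fb) == 1L && fa != fb)) {
    stop("control and knockout peak sets must be a single, identical factor")
  }
  w <- grid$windows
  qualifies <- IRanges::overlapsAny(w, control_peaks) &
    !IRanges::overlapsAny(w, ko_peaks)
  qw <- w[qualifies]
  if (length(qw) == 0L) {
    domains <- GenomicRanges::GRanges(seqinfo = GenomeInfoDb::seqinfo(w))
    prov <- list()
  } else {
    domains <- GenomicRanges::reduce(qw)  # merges overlapping + book-ended
    hits <- GenomicRanges::findOverlaps(domains, qw)
    prov <- split(which(qualifies)[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits))
    prov <- lapply(unname(prov), as.integer)
  }
  domains$name <- sprintf("domain_%04d", seq_along(domains))
  domains$n_windows <- lengths(prov)
  structure(list(domains = domains, provenance = prov, grid = grid),
            class = "BindingDomainSet")
}

#' @export
print.BindingDomainSet <- function(x, ...) {
  cat("BindingDomainSet:", length(x$domains), "domain(s) from",
      sum(lengths(x$provenance)), "qualifying window(s) of",
      x$grid$window_size, "bp\n")
  invisible(x)
}

#' Write a BindingDomainSet as BED6
#'
#' Name = domain id, score = number of contributing windows.
#'
#' @param x A [call_lost_domains()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domains <- function(x, path) {
  stopifnot(inherits(x, "BindingDomainSet"))
  gr <- x$domains
  gr$score <- gr$n_windows
  gr$n_windows <- NULL
  write_bed(gr, path)
}

#' Select peaks overlapping binding domains
#'
#' Keeps peaks overlapping any domain by >= 1 bp, in their input order.
#'
#' @param peaks A `GRanges` of peaks.
#' @param domains A `BindingDomainSet` or plain `GRanges`.
#' @return The overlapping subset of `peaks`.
#' @export
select_peaks_in_domains <- function(peaks, domains) {
  dom <- if (inherits(domains, "BindingDomainSet")) domains$domains
         else domains
  IRanges::subsetByOverlaps(peaks, dom, ignore.strand = TRUE)
}

#' Co-occupancy correlation of two tracks over domains
#'
#' For each domain, `x = log10(rpkm_a + pseudocount)` and
#' `y = log10(rpkm_b + pseudocount)`; reports the Pearson correlation with
#' a two-sided p-value (t transform, n - 2 df, via [stats::cor.test()]).
#'
#' @param track_a,track_b [coverage_track()]s on the same layout.
#' @param domains A `BindingDomainSet` or `GRanges` (>= 3 domains).
#' @param pseudocount RPKM pseudocount added before log10 (default 0.01),
#'   guarding against zero-signal domains.
#' @return An object of class `CorrelationReport`: `n_domains`, per-domain
#'   `x`/`y`, `r`, `p`, and `undefined` (TRUE when either side has zero
#'   variance, in which case `r` and `p` are `NA`).
#' @export
domain_correlation <- function(track_a, track_b, domains, pseudocount = 0.01) {
  dom <- if (inherits(domains, "BindingDomainSet")) domains$domains
         else domains
  if (length(dom) < 3L) stop("need >= 3 domains for a correlation")
  x <- log10(quantify(track_a, dom)$rpkm + pseudocount)
  y <- log10(quantify(track_b, dom)$rpkm + pseudocount)
  undefined <- stats::sd(x) == 0 || stats::sd(y) == 0
  if (undefined) {
    r <- NA_real_
    p <- NA_real_
  } else {
    ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
    r <- unname(ct$estimate)
    p <- ct$p.value
  }
  structure(list(n_domains = length(dom), x = x, y = y, r = r, p = p,
                 pseudocount = pseudocount, undefined = undefined),
            class = "CorrelationReport")
}

#' @export
print.CorrelationReport <- function(x, ...) {
  if (x$undefined) {
    cat("CorrelationReport:", x$n_domains,
        "domains; r undefined (zero variance)\n")
  } else {
    cat(sprintf("CorrelationReport: %d domains; Pearson r = %.3f, p = %.3g\n",
                x$n_domains, x$r, x$p))
  }
  invisible(x)
}

#' @method plot CorrelationReport
#' @export
plot.CorrelationReport <- function(x, ...,
                                   xlab = "log10 signal A",
                                   ylab = "log10 signal B") {
  graphics::plot(x$x, x$y, pch = 16, cex = 0.5, xlab = xlab, ylab = ylab,
                 main = if (x$undefined) "r undefined"
                        else sprintf("r = %.2f", x$r), ...)
  if (!x$undefined) graphics::abline(stats::lm(x$y ~ x$x), col = "red")
  invisible(x)
}

#' Write a CorrelationReport as a scatter data table
#'
#' @param x A [domain_correlation()] result.
#' @param path Output TSV path; the header comment line carries n, r, p.
#' @return `path`, invisibly.
#' @export
write_correlation <- function(x, path) {
  stopifnot(inherits(x, "CorrelationReport"))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("# n_domains=%d\tr=%s\tp=%s", x$n_domains,
                     format(x$r, digits = 15), format(x$p, digits = 15)), con)
  writeLines("log10_a\tlog10_b", con)
  writeLines(paste(format(x$x, digits = 15, trim = TRUE),
                   format(x$y, digits = 15, trim = TRUE), sep = "\t"), con)
  invisible(path)
}

#' Signal matrix around anchor positions
#'
#' Row i, bin j is the mean track value in the j-th equal subinterval of
#' `[anchor - flank, anchor + flank)`; bins of minus-strand anchors are
#' reversed so column order always reads 5' to 3'. Used for TSS-centred
#' heatmap input (e.g. TSS +/- 3000 bp).
#'
#' @param track A [coverage_track()].
#' @param anchors Width-1 `GRanges` (e.g. [tss_positions()]); strand `-`
#'   reverses bin order, `+`/`*` keep it.
#' @param flank Flank in basepairs on each side (default 3000).
#' @param n_bins Number of equal bins across the 2*flank span.
#' @return A numeric matrix (anchors x bins) with bin-centre offsets as an
#'   attribute `offsets`; bins clipped entirely off-chromosome are `NA`.
#' @export
signal_matrix <- function(track, anchors, flank = 3000, n_bins = 100) {
  stopifnot(inherits(track, "CoverageTrack"))
  if (flank <= 0 || n_bins <= 0) stop("flank and n_bins must be > 0")
  if (any(BiocGenerics::width(anchors) != 1L)) {
    stop("anchors must be width-1 positions")
  }
  a0 <- BiocGenerics::start(anchors) - 1L  # 0-based anchor position
  bounds <- round(seq(-flank, flank, length.out = n_bins + 1))
  mat <- matrix(NA_real_, nrow = length(anchors), ncol = n_bins)
  chroms <- as.character(GenomeInfoDb::seqnames(anchors))
  lens <- track$layout$length[match(chroms, track$layout$chrom)]
  for (chrom in unique(chroms)) {
    idx <- which(chroms == chrom)
    # bin j of anchor i: 0-based [a0 + bounds[j], a0 + bounds[j+1])
    st0 <- outer(a0[idx], bounds[-length(bounds)], `+`)
    en0 <- outer(a0[idx], bounds[-1L], `+`)
    st0 <- pmax(st0, 0)
    en0 <- pmin(en0, lens[idx[1L]])
    ok <- en0 > st0
    v <- IRanges::Views(track$cov[[chrom]],
                        start = as.integer(st0[ok]) + 1L,
                        end = as.integer(en0[ok]))
    vals <- matrix(NA_real_, nrow = length(idx), ncol = n_bins)
    vals[ok] <- IRanges::viewMeans(v)
    mat[idx, ] <- vals
  }
  minus <- as.logical(BiocGenerics::strand(anchors) == "-")
  if (any(minus)) mat[minus, ] <- mat[minus, n_bins:1, drop = FALSE]
  rownames(mat) <- if (!is.null(anchors$gene_id)) anchors$gene_id
                   else if (!is.null(anchors$name)) anchors$name else NULL
  attr(mat, "offsets") <- (bounds[-1L] + bounds[-length(bounds)]) / 2
  mat
}

#' Write a signal matrix as TSV with a bin-offset header row
#'
#' @param mat A [signal_matrix()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_matrix <- function(mat, path) {
  df <- as.data.frame(mat)
  names(df) <- paste0("offset_", attr(mat, "offsets"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = !is.null(rownames(mat)), col.names = TRUE)
  invisible(path)
}

#' Match called domains against a reference set
#'
#' A called domain and a reference domain match when their interval Jaccard
#' index (intersection / union, in basepairs) is at least `min_jaccard`.
#' Recall is the fraction of reference domains matched; precision the
#' fraction of called domains matched.
#'
#' @param called,reference `GRanges` or `BindingDomainSet`s.
#' @param min_jaccard Jaccard threshold for a match (default 0.5).
#' @return List: `recall`, `precision`, `n_called`, `n_reference`,
#'   `n_matched_reference`.
#' @export
domain_recovery <- function(called, reference, min_jaccard = 0.5) {
  cd <- if (inherits(called, "BindingDomainSet")) called$domains else called
  rf <- if (inherits(reference, "BindingDomainSet")) reference$domains
        else reference
  hits <- GenomicRanges::findOverlaps(cd, rf, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  inter <- BiocGenerics::width(IRanges::pintersect(cd[qi], rf[si]))
  uni <- BiocGenerics::width(cd[qi]) + BiocGenerics::width(rf[si]) - inter
  good <- (inter / uni) >= min_jaccard
  list(recall = if (length(rf)) length(unique(si[good])) / length(rf) else NA,
       precision = if (length(cd)) length(unique(qi[good])) / length(cd)
                   else NA,
       n_called = length(cd),
       n_reference = length(rf),
       n_matched_reference = length(unique(si[good])))
}
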