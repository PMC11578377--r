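#' Strand-aware gene region classes
#'
#' For each gene, the promoter (`Pro`) is `[tss - flank, tss + flank)`
#' around the strand-aware TSS (0-based convention), clipped to the
#' chromosome; the gene body (`GB`) is the gene interval minus the
#' promoter; `All` is the union of gene interval and promoter; `SE` holds
#' the super-enhancer intervals assigned to the gene (possibly none).
#'
#' @param genes `GRanges` of gene models with `gene_id` and strand.
#' @param promoter_flank Promoter half-width in basepairs (default 3000,
#'   i.e. the TSS +/- 3 kb window).
#' @param ses Optional super-enhancer intervals per gene: a
#'   [call_super_enhancers()] result, or a `GRanges` with a `gene_id`
#'   column (as re-read from a written SE BED).
#' @return An object of class `GeneRegions`: list of `GRangesList`s
#'   (`Pro`, `GB`, `All`, `SE`), each named by gene_id, plus `gene_ids`.
#' @export
gene_regions <- function(genes, promoter_flank = 3000, ses = NULL) {
  if (is.null(genes$gene_id)) stop("genes must carry gene_id")
  ids <- genes$gene_id
  tss <- tss_positions(genes)
  tss0 <- BiocGenerics::start(tss) - 1L  # 0-based TSS
  lens <- GenomeInfoDb::seqlengths(genes)[
    as.character(GenomeInfoDb::seqnames(genes))]
  pro <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(genes),
    IRanges::IRanges(start = pmax(tss0 - promoter_flank, 0) + 1L,
                     end = pmin(tss0 + promoter_flank, lens)),
    seqinfo = GenomeInfoDb::seqinfo(genes))
  body <- GenomicRanges::granges(genes)
  BiocGenerics::strand(body) <- "*"
  gb <- GenomicRanges::psetdiff(body, pro)
  all_ <- GenomicRanges::punion(body, pro, fill.gap = TRUE)
  lev <- factor(ids, levels = ids)
  pro_l <- S4Vectors::split(pro, lev)
  gb_keep <- BiocGenerics::width(gb) > 0
  gb_l <- S4Vectors::split(gb[gb_keep], lev[gb_keep])
  all_l <- S4Vectors::split(all_, lev)
  se_gr <- GenomicRanges::GRanges(seqinfo = GenomeInfoDb::seqinfo(genes))
  se_gr$gene_id <- character(0)
  if (!is.null(ses)) {
    if (inherits(ses, "SuperEnhancerSet")) {
      assigned <- !is.na(ses$gene_assignment)
      se_gr <- ses$se[assigned]
      S4Vectors::mcols(se_gr) <- S4Vectors::DataFrame(
        gene_id = ses$gene_assignment[assigned])
    } else if (methods::is(ses, "GRanges") && !is.null(ses$gene_id)) {
      se_gr <- ses[!is.na(ses$gene_id) & ses$gene_id != "."]
      S4Vectors::mcols(se_gr) <- S4Vectors::DataFrame(gene_id = se_gr$gene_id)
    } else {
      stop("ses must be a SuperEnhancerSet or a GRanges with gene_id")
    }
  }
  se_l <- S4Vectors::split(se_gr, factor(se_gr$gene_id, levels = ids))
  structure(list(Pro = pro_l, GB = gb_l, All = all_l, SE = se_l,
                 gene_ids = ids),
            class = "GeneRegions")
}

#' @export
print.GeneRegions <- function(x, ...) {
  cat("GeneRegions:", length(x$gene_ids), "genes;",
      sum(lengths(x$SE) > 0), "with assigned super-enhancers\n")
  invisible(x)
}

#' ROSE-style super-enhancer calling
#'
#' Peaks overlapping promoters are removed; the rest are stitched when
#' separated by at most `stitch_gap`; stitched regions are ranked by total
#' track signal. With rank and signal both scaled to `[0, 1]`, the cutoff
#' is the point of the rank-signal curve farthest below the unit-slope
#' diagonal -- the discrete analogue of the tangent-slope-1 knee: for a
#' convex curve it is exactly the last rank before the tangent slope
#' exceeds 1. Regions above the cutoff are super-enhancers; a flat curve
#' (no point below the diagonal, or zero signal range) yields none. Each
#' SE is assigned to the gene with the nearest TSS within
#' `assignment_radius`.
#'
#' @param peaks `GRanges` of H3K27Ac peaks.
#' @param track The matching [coverage_track()] used for ranking.
#' @param promoters `GRanges` of promoter intervals to exclude.
#' @param genes `GRanges` gene models (for TSS assignment).
#' @param stitch_gap Maximum gap merged when stitching (default 12500 bp).
#' @param assignment_radius Maximum SE-to-TSS distance for gene assignment
#'   (default 50000 bp).
#' @return An object of class `SuperEnhancerSet`: `stitched` (`GRanges`
#'   with `signal` and ascending `rank`), `cutoff_index` (number of
#'   typical enhancers; SEs are ranks above it), `se` (`GRanges`), and
#'   `gene_assignment` (gene_id or `NA` per SE).
#' @export
call_super_enhancers <- function(peaks, track, promoters, genes,
                                 stitch_gap = 12500,
                                 assignment_radius = 50000) {
  keep <- !IRanges::overlapsAny(peaks, promoters, ignore.strand = TRUE)
  stitched <- GenomicRanges::reduce(GenomicRanges::granges(peaks[keep]),
                                    min.gapwidth = stitch_gap + 1,
                                    ignore.strand = TRUE)
  empty_set <- function(stitched) {
    se <- stitched[integer(0)]
    structure(list(stitched = stitched, cutoff_index = length(stitched),
                   se = se, gene_assignment = character(0)),
              class = "SuperEnhancerSet")
  }
  if (length(stitched) < 3L) {
    warning("fewer than 3 stitched regions; no super-enhancers called")
    if (length(stitched)) {
      stitched$signal <- quantify(track, stitched)$count
      stitched$rank <- rank(stitched$signal, ties.method = "first")
    }
    return(empty_set(stitched))
  }
  stitched$signal <- quantify(track, stitched)$count
  ord <- order(stitched$signal)
  stitched <- stitched[ord]
  stitched$rank <- seq_along(stitched)
  n <- length(stitched)
  x <- (stitched$rank - 1) / (n - 1)
  rng <- max(stitched$signal) - min(stitched$signal)
  if (rng == 0) return(empty_set(stitched))
  y <- (stitched$signal - min(stitched$signal)) / rng
  gap <- x - y
  if (max(gap) <= 0) return(empty_set(stitched))
  cutoff_index <- which.max(gap)
  se <- stitched[seq_len(n) > cutoff_index]
  assignment <- rep(NA_character_, length(se))
  if (length(se) && length(genes)) {
    tss <- tss_positions(genes)
    hits <- GenomicRanges::distanceToNearest(se, tss, ignore.strand = TRUE)
    ok <- S4Vectors::mcols(hits)$distance <= assignment_radius
    assignment[S4Vectors::queryHits(hits)[ok]] <-
      genes$gene_id[S4Vectors::subjectHits(hits)[ok]]
  }
  structure(list(stitched = stitched, cutoff_index = cutoff_index,
                 se = se, gene_assignment = assignment),
            class = "SuperEnhancerSet")
}

#' @export
print.SuperEnhancerSet <- function(x, ...) {
  cat("SuperEnhancerSet:", length(x$se), "super-enhancer(s) out of",
      length(x$stitched), "stitched region(s);",
      sum(!is.na(x$gene_assignment)), "assigned to genes\n")
  invisible(x)
}

#' @method plot SuperEnhancerSet
#' @export
plot.SuperEnhancerSet <- function(x, ...) {
  n <- length(x$stitched)
  graphics::plot(seq_len(n), x$stitched$signal, type = "l",
                 xlab = "rank", ylab = "total signal", ...)
  if (length(x$se)) graphics::abline(v = x$cutoff_index + 0.5, col = "red",
                                     lty = 2)
  invisible(x)
}

#' Write super-enhancers as BED6 (rank in score)
#'
#' @param x A [call_super_enhancers()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_super_enhancers <- function(x, path) {
  stopifnot(inherits(x, "SuperEnhancerSet"))
  se <- x$se
  se$name <- ifelse(is.na(x$gene_assignment), ".", x$gene_assignment)
  se$score <- se$rank
  se$signal <- NULL
  se$rank <- NULL
  write_bed(se, path)
}

#' Per-gene, per-region mark fold changes and gain/loss flags
#'
#' For each gene and region class, signal is summed over the class's
#' intervals in both tracks, converted to RPKM, and
#' `fc = (ko_rpkm + pseudocount) / (ctrl_rpkm + pseudocount)`. A region is
#' `gained` when `fc >= threshold` (inclusive) and `lost` when
#' `fc <= 1/threshold`. Genes with an empty region in a class are omitted
#' from that class (with a notice).
#'
#' @param ctrl_track,ko_track [coverage_track()]s for the two conditions.
#' @param regions A [gene_regions()] object.
#' @param threshold Fold-change threshold (default 1.3).
#' @param pseudocount RPKM pseudocount on numerator and denominator
#'   (default 0.1), bounding fold changes on near-zero regions.
#' @return An object of class `RegionGainTable` (a data.frame): `gene_id`,
#'   `class`, `ctrl_rpkm`, `ko_rpkm`, `fc`, `gained`, `lost`.
#' @export
region_gain <- function(ctrl_track, ko_track, regions, threshold = 1.3,
                        pseudocount = 0.1) {
  stopifnot(inherits(regions, "GeneRegions"))
  if (threshold <= 1) stop("threshold must be > 1")
  rows <- list()
  for (cls in c("Pro", "SE", "GB", "All")) {
    grl <- regions[[cls]]
    widths <- sum(BiocGenerics::width(grl))
    nonempty <- widths > 0
    if (any(!nonempty)) {
      message(sum(!nonempty), " gene(s) with empty ", cls,
              " region omitted from that class")
    }
    if (!any(nonempty)) next
    flat <- unlist(grl[nonempty], use.names = FALSE)
    gene_of <- rep(names(grl)[nonempty], lengths(grl[nonempty]))
    cc <- quantify(ctrl_track, flat)$count
    kc <- quantify(ko_track, flat)$count
    ctrl_count <- vapply(split(cc, gene_of), sum, numeric(1))
    ko_count <- vapply(split(kc, gene_of), sum, numeric(1))
    gid <- names(ctrl_count)
    len <- widths[nonempty][match(gid, names(grl)[nonempty])]
    ctrl_rpkm <- rpkm(ctrl_count, len, ctrl_track$total_mapped)
    ko_rpkm <- rpkm(ko_count, len, ko_track$total_mapped)
    fc <- (ko_rpkm + pseudocount) / (ctrl_rpkm + pseudocount)
    rows[[cls]] <- data.frame(
      gene_id = gid, class = cls,
      ctrl_rpkm = unname(ctrl_rpkm), ko_rpkm = unname(ko_rpkm),
      fc = unname(fc),
      gained = unname(fc >= threshold),
      lost = unname(fc <= 1 / threshold),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(match(out$class, c("Pro", "SE", "GB", "All")),
                   out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("RegionGainTable", "data.frame"),
            threshold = threshold, pseudocount = pseudocount)
}

#' Write a RegionGainTable as TSV
#'
#' @param x A [region_gain()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_gain <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a RegionGainTable written by [write_region_gain()]
#'
#' @param path TSV path.
#' @return A `RegionGainTable`.
#' @export
read_region_gain <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  structure(df, class = c("RegionGainTable", "data.frame"))
}

#' Gained gene sets per region class
#'
#' @param table A [region_gain()] table.
#' @return Named list (`Pro`, `SE`, `GB`, `All`) of sorted gene_id vectors
#'   with `gained = TRUE` in that class.
#' @export
gain_gene_sets <- function(table) {
  stopifnot(inherits(table, "RegionGainTable"))
  out <- lapply(c(Pro = "Pro", SE = "SE", GB = "GB", All = "All"),
                function(cls) {
    sort(table$gene_id[table$class == cls & table$gained])
  })
  out
}

#' Lost gene sets per region class
#'
#' Counterpart of [gain_gene_sets()] for `lost = TRUE` rows.
#'
#' @param table A [region_gain()] table.
#' @return Named list of sorted gene_id vectors per class.
#' @export
loss_gene_sets <- function(table) {
  stopifnot(inherits(table, "RegionGainTable"))
  lapply(c(Pro = "Pro", SE = "SE", GB = "GB", All = "All"), function(cls) {
    sort(table$gene_id[table$class == cls & table$lost])
  })
}
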