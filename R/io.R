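#' Read a BED3/BED6 file of intervals
#'
#' Coordinates follow the BED convention (0-based, half-open) on disk and
#' are returned as a `GRanges` (1-based, closed) bound to `layout`. Strand
#' is `*` when the file has no strand column.
#'
#' @param path Path to a tab-separated BED3 or BED6 file (no header).
#' @param layout A [genome_layout()]; all records must fall inside it.
#' @return A sorted `GRanges`.
#' @export
read_bed <- function(path, layout) {
  validate_bed_lines(path, min_fields = 3L)
  gr <- rtracklayer::import(path, format = "BED")
  bind_to_layout(gr, layout, what = paste0("BED record in ", basename(path)),
                 sort = TRUE)
}

# Light pre-scan so malformed lines are reported with their line number;
# rtracklayer does the actual parsing.
validate_bed_lines <- function(path, min_fields = 3L) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < min_fields) {
      stop("parse error at line ", i, " of ", basename(path),
           ": expected >= ", min_fields, " tab-separated fields")
    }
    s <- suppressWarnings(as.numeric(f[2]))
    e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e)) {
      stop("parse error at line ", i, " of ", basename(path),
           ": non-numeric coordinates")
    }
    if (!(s < e) || s < 0) {
      stop("parse error at line ", i, " of ", basename(path),
           ": require 0 <= start < end")
    }
  }
  invisible(TRUE)
}

#' Write intervals as a sorted BED file
#'
#' Emits BED6 when `x` carries `name`/`score`/strand information, BED3-style
#' defaults (`.`, 0) otherwise.
#'
#' @param x A `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  rtracklayer::export(BiocGenerics::sort(x, ignore.strand = TRUE), path,
                      format = "BED")
  invisible(path)
}

#' Build a coverage track from per-base values
#'
#' A `CoverageTrack` holds run-length-encoded non-negative per-basepair
#' signal for every chromosome of a layout, plus the library size used as
#' the RPKM denominator.
#'
#' @param cov A named `RleList` (one `Rle` per chromosome, tiling it
#'   exactly), or a `GRanges` with a `score` column to be expanded.
#' @param layout A [genome_layout()].
#' @param total_mapped Library size in reads. When `NULL` it is inferred as
#'   `round(sum(value * length))` over the whole track.
#' @return An object of class `CoverageTrack`.
#' @export
coverage_track <- function(cov, layout, total_mapped = NULL) {
  si <- as_seqinfo(layout)
  if (methods::is(cov, "GRanges")) {
    cov <- bind_to_layout(cov, layout, what = "coverage record")
    cov <- IRanges::coverage(cov, weight = "score")
  }
  if (!methods::is(cov, "RleList")) stop("cov must be an RleList or GRanges")
  if (!setequal(names(cov), layout$chrom)) {
    stop("coverage chromosomes do not match layout")
  }
  cov <- cov[layout$chrom]
  lens <- vapply(cov, length, numeric(1))
  if (!all(lens == layout$length)) {
    stop("coverage runs must tile each chromosome exactly")
  }
  if (any(vapply(cov, function(r) any(S4Vectors::runValue(r) < 0),
                 logical(1)))) {
    stop("coverage values must be non-negative")
  }
  if (is.null(total_mapped)) {
    total_mapped <- round(sum(vapply(cov, function(r) sum(as.numeric(
      S4Vectors::runValue(r)) * S4Vectors::runLength(r)), numeric(1))))
  }
  if (!is.finite(total_mapped) || total_mapped <= 0) {
    stop("total_mapped must be positive")
  }
  structure(list(cov = cov, total_mapped = as.numeric(total_mapped),
                 layout = layout),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat("CoverageTrack:", length(x$cov), "chromosome(s), total_mapped =",
      format(x$total_mapped, big.mark = ","), "\n")
  invisible(x)
}

#' Read a 4-column bedGraph file into a CoverageTrack
#'
#' Records must be non-overlapping; uncovered basepairs are filled with 0.
#'
#' @inheritParams read_bed
#' @param total_mapped Optional library size (reads). Defaults to the
#'   rounded total signal mass `sum(value * length)` of the track.
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, layout, total_mapped = NULL) {
  validate_bed_lines(path, min_fields = 4L)
  gr <- rtracklayer::import(path, format = "bedGraph")
  gr <- bind_to_layout(gr, layout,
                       what = paste0("bedGraph record in ", basename(path)))
  if (!IRanges::isDisjoint(gr)) {
    stop("overlapping bedGraph records in ", basename(path))
  }
  if (any(gr$score < 0)) stop("negative bedGraph values in ", basename(path))
  coverage_track(gr, layout, total_mapped = total_mapped)
}

#' Write a CoverageTrack as a sorted bedGraph file
#'
#' Zero-valued runs are written too, so the file tiles the genome and
#' round-trips exactly through [read_bedgraph()].
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @param drop_zero Omit zero-valued runs (smaller files; zeros are
#'   restored on read). Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, drop_zero = TRUE) {
  stopifnot(inherits(track, "CoverageTrack"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (chrom in names(track$cov)) {
    r <- track$cov[[chrom]]
    len <- S4Vectors::runLength(r)
    val <- S4Vectors::runValue(r)
    end <- cumsum(as.numeric(len))
    start <- end - len
    keep <- if (drop_zero) val != 0 else rep(TRUE, length(val))
    if (!any(keep)) next
    writeLines(paste(chrom,
                     format(start[keep], scientific = FALSE, trim = TRUE),
                     format(end[keep], scientific = FALSE, trim = TRUE),
                     format(val[keep], scientific = FALSE, trim = TRUE),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read gene models (BED6 or GTF gene records)
#'
#' BED6 input: name = gene id, strand required. GTF input: records with
#' feature type `gene` and a `gene_id` attribute; 1-based inclusive GTF
#' coordinates are converted to the internal convention on read.
#'
#' @inheritParams read_bed
#' @param format `"auto"` (by file extension), `"bed"` or `"gtf"`.
#' @return A sorted `GRanges` with a `gene_id` column and strand `+`/`-`.
#'   The transcription start site of each gene is its strand-aware 5' end
#'   (see [tss_positions()]).
#' @export
read_genes <- function(path, layout, format = c("auto", "bed", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff2?)$", path, ignore.case = TRUE))
      "gtf" else "bed"
  }
  if (format == "bed") {
    validate_bed_lines(path, min_fields = 6L)
    gr <- rtracklayer::import(path, format = "BED")
    if (is.null(gr$name) || anyNA(gr$name)) {
      stop("gene BED input requires a name (gene_id) column")
    }
    gr$gene_id <- gr$name
    gr$name <- NULL
    gr$score <- NULL
  } else {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[gr$type == "gene"]
    if (length(gr) == 0L) stop("no 'gene' records in ", basename(path))
    if (is.null(gr$gene_id)) stop("GTF gene records lack gene_id")
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(gene_id = gr$gene_id)
  }
  if (any(BiocGenerics::strand(gr) == "*")) {
    stop("gene records must carry strand (+ or -)")
  }
  if (anyDuplicated(gr$gene_id)) {
    stop("duplicate gene_id(s): ",
         paste(unique(gr$gene_id[duplicated(gr$gene_id)]), collapse = ", "))
  }
  bind_to_layout(gr, layout, what = paste0("gene record in ", basename(path)),
                 sort = TRUE)
}

#' Strand-aware TSS positions of gene models
#'
#' Returns width-1 `GRanges` at each gene's 5' end (BED-style 0-based
#' position `start` for `+` genes and `end - 1` for `-` genes).
#'
#' @param genes `GRanges` of gene models with strand.
#' @return Width-1 `GRanges`, same order and metadata as `genes`.
#' @export
tss_positions <- function(genes) {
  minus <- as.logical(BiocGenerics::strand(genes) == "-")
  pos <- ifelse(minus, BiocGenerics::end(genes), BiocGenerics::start(genes))
  out <- genes
  IRanges::ranges(out) <- IRanges::IRanges(start = pos, width = 1L)
  out
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm = count / ((length/1000) * (total_mapped/1e6))`. Vectorised over
#' `count` and `length`.
#'
#' @param count Read count(s) in the region.
#' @param length Region length(s) in basepairs (> 0).
#' @param total_mapped Library size in reads (> 0).
#' @return Numeric RPKM value(s).
#' @examples
#' rpkm(10, 2000, 2e6) # 2.5
#' @export
rpkm <- function(count, length, total_mapped) {
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("length must be positive")
  }
  if (length(total_mapped) != 1L || !is.finite(total_mapped) ||
      total_mapped <= 0) {
    stop("total_mapped must be a single positive number")
  }
  count / ((length / 1000) * (total_mapped / 1e6))
}

#' Quantify a coverage track over intervals
#'
#' The count of an interval is the sum of per-base track values over it;
#' RPKM uses the track's library size.
#'
#' @param track A [coverage_track()].
#' @param intervals A `GRanges` within the track's layout.
#' @return A data.frame with one row per interval: `count`, `rpkm`.
#' @export
quantify <- function(track, intervals) {
  stopifnot(inherits(track, "CoverageTrack"))
  intervals <- bind_to_layout(intervals, track$layout, what = "interval")
  counts <- numeric(length(intervals))
  chroms <- as.character(GenomeInfoDb::seqnames(intervals))
  for (chrom in unique(chroms)) {
    idx <- which(chroms == chrom)
    v <- IRanges::Views(track$cov[[chrom]],
                        start = BiocGenerics::start(intervals)[idx],
                        end = BiocGenerics::end(intervals)[idx])
    counts[idx] <- IRanges::viewSums(v)
  }
  data.frame(count = counts,
             rpkm = rpkm(counts, BiocGenerics::width(intervals),
                         track$total_mapped))
}
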