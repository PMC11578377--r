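#' Define a genome layout
#'
#' A `GenomeLayout` is the coordinate universe for an analysis: an ordered
#' set of chromosome names with their lengths. Every interval read or
#' generated by the package is validated against it.
#'
#' @param chroms Character vector of unique chromosome names.
#' @param lengths Integer-like vector of chromosome lengths in basepairs,
#'   parallel to `chroms`, all positive.
#'
#' @return An object of class `GenomeLayout`: a data.frame with columns
#'   `chrom` and `length`, in the given order.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(1e7, 1e7))
#' @export
genome_layout <- function(chroms, lengths) {
  chroms <- as.character(chroms)
  lengths <- as.numeric(lengths)
  if (length(chroms) != length(lengths)) {
    stop("chroms and lengths must have equal length")
  }
  if (length(chroms) == 0L) stop("layout must contain at least one chromosome")
  if (anyDuplicated(chroms)) stop("chromosome names must be unique")
  if (any(!is.finite(lengths)) || any(lengths <= 0) ||
      any(lengths != floor(lengths))) {
    stop("chromosome lengths must be positive integers")
  }
  structure(data.frame(chrom = chroms, length = lengths,
                       stringsAsFactors = FALSE),
            class = c("GenomeLayout", "data.frame"))
}

#' Read a chrom.sizes file into a GenomeLayout
#'
#' Two tab-separated columns: chromosome name, length.
#'
#' @param path Path to a chrom.sizes file.
#' @return A [genome_layout()] object.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "length"))
  genome_layout(tab$chrom, tab$length)
}

#' Write a GenomeLayout as a chrom.sizes file
#'
#' @param layout A [genome_layout()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(layout, path) {
  stopifnot(inherits(layout, "GenomeLayout"))
  utils::write.table(
    data.frame(layout$chrom, format(layout$length, scientific = FALSE,
                                    trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.GenomeLayout <- function(x, ...) {
  cat("GenomeLayout:", nrow(x), "chromosome(s),",
      format(sum(x$length), big.mark = ","), "bp total\n")
  print.data.frame(x, ...)
  invisible(x)
}

# Seqinfo for constructing GRanges bound to this layout.
as_seqinfo <- function(layout) {
  stopifnot(inherits(layout, "GenomeLayout"))
  GenomeInfoDb::Seqinfo(seqnames = layout$chrom,
                        seqlengths = as.integer(layout$length))
}

# Validate that a GRanges lies within the layout; returns the GRanges with
# the layout's seqinfo attached, sorted if sort = TRUE.
bind_to_layout <- function(gr, layout, what = "interval", sort = FALSE) {
  si <- as_seqinfo(layout)
  bad_chrom <- setdiff(as.character(GenomeInfoDb::seqnames(gr)), layout$chrom)
  if (length(bad_chrom)) {
    stop(what, " on unknown chromosome(s): ",
         paste(unique(bad_chrom), collapse = ", "))
  }
  GenomeInfoDb::seqlevels(gr) <- layout$chrom
  lens <- layout$length[match(as.character(GenomeInfoDb::seqnames(gr)),
                              layout$chrom)]
  if (any(BiocGenerics::start(gr) < 1L) || any(BiocGenerics::end(gr) > lens)) {
    stop(what, " coordinates out of chromosome bounds")
  }
  suppressWarnings(GenomeInfoDb::seqinfo(gr) <- si)
  if (sort) gr <- BiocGenerics::sort(gr, ignore.strand = TRUE)
  gr
}
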