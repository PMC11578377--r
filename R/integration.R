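#' Overlap of two gene sets with hypergeometric enrichment
#'
#' Counts the Venn partition of `set_a` and `set_b` within `universe` and
#' reports the one-sided (over-representation) hypergeometric p-value
#' `P(X >= |a intersect b|)` for drawing `|b|` genes from a universe of
#' `|universe|` containing `|a|` successes.
#'
#' @param set_a,set_b Character vectors of gene ids, subsets of `universe`.
#' @param universe Character vector of all gene ids considered.
#' @return List: `n_a`, `n_b`, `n_a_only`, `n_b_only`, `n_intersect`,
#'   `n_universe`, `frac_of_a`, `frac_of_b`, `p_hyper`.
#' @export
gene_set_overlap <- function(set_a, set_b, universe) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  universe <- unique(as.character(universe))
  if (length(setdiff(set_a, universe)) || length(setdiff(set_b, universe))) {
    stop("sets must be subsets of the universe")
  }
  k <- length(intersect(set_a, set_b))
  p <- stats::phyper(k - 1, m = length(set_a),
                     n = length(universe) - length(set_a),
                     k = length(set_b), lower.tail = FALSE)
  list(n_a = length(set_a), n_b = length(set_b),
       n_a_only = length(set_a) - k, n_b_only = length(set_b) - k,
       n_intersect = k, n_universe = length(universe),
       frac_of_a = if (length(set_a)) k / length(set_a) else NA_real_,
       frac_of_b = if (length(set_b)) k / length(set_b) else NA_real_,
       p_hyper = p)
}

#' Fraction of mark-gained genes that also lost the second mark
#'
#' `|gain intersect loss| / |gain|`; 0 (with a warning) when the gain set
#' is empty.
#'
#' @param gain_genes,loss_genes Character vectors of gene ids on a common
#'   universe.
#' @return A single numeric fraction, with attributes `n_gain` and
#'   `n_intersect`.
#' @export
gain_loss_fraction <- function(gain_genes, loss_genes) {
  gain_genes <- unique(as.character(gain_genes))
  loss_genes <- unique(as.character(loss_genes))
  k <- length(intersect(gain_genes, loss_genes))
  if (length(gain_genes) == 0L) {
    warning("empty gain set; fraction reported as 0")
    out <- 0
  } else {
    out <- k / length(gain_genes)
  }
  structure(out, n_gain = length(gain_genes), n_intersect = k)
}

#' Per-region-class gain counts among upregulated DEGs
#'
#' @param up_degs Character vector of upregulated gene ids.
#' @param table A [region_gain()] table.
#' @return Named integer vector (`Pro`, `SE`, `GB`, `All`) of up-DEGs with
#'   `gained = TRUE` in each class, with attribute `n_up`.
#' @export
region_gain_counts <- function(up_degs, table) {
  stopifnot(inherits(table, "RegionGainTable"))
  sets <- gain_gene_sets(table)
  out <- vapply(sets, function(s) length(intersect(up_degs, s)), integer(1))
  attr(out, "n_up") <- length(unique(up_degs))
  out
}

#' Assemble the integration report
#'
#' Combines the DE result with the H3K27Ac gain table and the HDAC1 loss
#' table into the headline statistics: per-class overlap of up-DEGs with
#' mark-gain gene sets (Venn counts, both overlap fractions, hypergeometric
#' enrichment p), the fraction of mark-gained genes that also lost the
#' second mark, per-class gain counts among up-DEGs, and an optional
#' domain co-occupancy correlation summary.
#'
#' @param de A [de_test()] result.
#' @param gain_table [region_gain()] table for the gained mark (H3K27Ac).
#' @param loss_table [region_gain()] table for the lost mark (HDAC1).
#' @param universe Gene universe (default: all genes in `de`).
#' @param mark_class Region class used for the gain-vs-loss fraction
#'   (default `"Pro"`).
#' @param correlation Optional [domain_correlation()] report to embed.
#' @param domains Optional [call_lost_domains()] result to embed counts of.
#' @return An object of class `IntegrationReport`.
#' @export
integration_report <- function(de, gain_table, loss_table,
                               universe = NULL, mark_class = "Pro",
                               correlation = NULL, domains = NULL) {
  stopifnot(inherits(de, "DEResult"))
  if (is.null(universe)) universe <- sort(unique(de$gene_id))
  up <- up_gene_set(de)
  gains <- gain_gene_sets(gain_table)
  losses <- loss_gene_sets(loss_table)
  per_class <- lapply(gains, function(g) {
    gene_set_overlap(intersect(up, universe), intersect(g, universe),
                     universe)
  })
  frac <- gain_loss_fraction(gains[[mark_class]], losses[[mark_class]])
  mark <- list(class = mark_class,
               n_gain = attr(frac, "n_gain"),
               n_loss = length(losses[[mark_class]]),
               n_intersect = attr(frac, "n_intersect"),
               frac_gain_with_loss = as.numeric(frac))
  structure(list(n_up_degs = length(up),
                 up_degs = up,
                 universe_size = length(universe),
                 per_class_overlap = per_class,
                 up_gain_counts = region_gain_counts(up, gain_table),
                 mark = mark,
                 correlation = if (is.null(correlation)) NULL else
                   list(n_domains = correlation$n_domains,
                        r = correlation$r, p = correlation$p),
                 n_domains = if (is.null(domains)) NULL else
                   length(domains$domains)),
            class = "IntegrationReport")
}

#' @export
print.IntegrationReport <- function(x, ...) {
  cat("IntegrationReport\n")
  if (!is.null(x$n_domains)) cat("  binding domains called:", x$n_domains, "\n")
  if (!is.null(x$correlation)) {
    cat(sprintf("  domain co-occupancy: r = %.3f (p = %.3g, n = %d)\n",
                x$correlation$r, x$correlation$p, x$correlation$n_domains))
  }
  cat("  up-regulated DEGs:", x$n_up_degs, "of", x$universe_size, "genes\n")
  for (cls in names(x$per_class_overlap)) {
    o <- x$per_class_overlap[[cls]]
    cat(sprintf("  up-DEGs vs %s-gain: |gain| = %d, overlap = %d, p = %.3g\n",
                cls, o$n_b, o$n_intersect, o$p_hyper))
  }
  m <- x$mark
  cat(sprintf(
    "  %s H3K27Ac-gain vs HDAC1-loss: %d/%d gained genes also lost (%.2f%%)\n",
    m$class, m$n_intersect, m$n_gain, 100 * m$frac_gain_with_loss))
  invisible(x)
}

#' Write an IntegrationReport as TSV and JSON
#'
#' The TSV is a flat key/value table of every reported count and fraction;
#' the JSON mirrors the full nested structure.
#'
#' @param x An [integration_report()].
#' @param tsv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisible list of written paths.
#' @export
write_report <- function(x, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(x, "IntegrationReport"))
  if (!is.null(tsv_path)) {
    kv <- c(n_up_degs = x$n_up_degs, universe_size = x$universe_size)
    if (!is.null(x$n_domains)) kv <- c(kv, n_domains = x$n_domains)
    if (!is.null(x$correlation)) {
      kv <- c(kv, cooccupancy_r = x$correlation$r,
              cooccupancy_p = x$correlation$p)
    }
    for (cls in names(x$per_class_overlap)) {
      o <- x$per_class_overlap[[cls]]
      kv <- c(kv,
              stats::setNames(c(o$n_b, o$n_intersect, o$frac_of_a,
                                o$frac_of_b, o$p_hyper),
                              paste0(cls, c("_gain_genes", "_overlap_up",
                                            "_frac_of_up", "_frac_of_gain",
                                            "_p_hyper"))))
    }
    kv <- c(kv, stats::setNames(as.numeric(x$up_gain_counts),
                                paste0("up_gain_count_",
                                       names(x$up_gain_counts))),
            mark_n_gain = x$mark$n_gain, mark_n_loss = x$mark$n_loss,
            mark_n_intersect = x$mark$n_intersect,
            frac_gain_with_loss = x$mark$frac_gain_with_loss)
    utils::write.table(
      data.frame(key = names(kv),
                 value = format(unname(kv), digits = 15, trim = TRUE,
                                scientific = FALSE)),
      tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    out <- unclass(x)
    out$up_gain_counts <- as.list(x$up_gain_counts)
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }
  invisible(list(tsv = tsv_path, json = json_path))
}
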