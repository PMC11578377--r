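#' Construct a gene-level expression matrix
#'
#' @param counts Integer matrix, genes x samples, with gene ids as
#'   rownames and sample names as colnames.
#' @param gene_lengths Positive basepair lengths, one per gene (named or in
#'   row order).
#' @param condition Character/factor of `"control"`/`"KO"` per sample; each
#'   condition needs at least two replicates.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(counts, gene_lengths, condition) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene_id rownames")
  if (any(counts < 0) || anyNA(counts)) stop("counts must be non-negative")
  if (length(gene_lengths) != nrow(counts)) {
    stop("gene_lengths must match the number of genes")
  }
  if (!is.null(names(gene_lengths))) {
    gene_lengths <- gene_lengths[rownames(counts)]
  }
  if (any(!is.finite(gene_lengths)) || any(gene_lengths <= 0)) {
    stop("gene lengths must be positive")
  }
  condition <- as.character(condition)
  if (length(condition) != ncol(counts)) {
    stop("condition must have one entry per sample")
  }
  bad <- setdiff(condition, c("control", "KO"))
  if (length(bad)) stop("unknown condition(s): ", paste(bad, collapse = ", "))
  if (sum(condition == "control") < 2 || sum(condition == "KO") < 2) {
    stop("need >= 2 replicates per condition")
  }
  structure(list(counts = counts, gene_lengths = unname(gene_lengths),
                 condition = condition),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples (", sum(x$condition == "control"), "control /",
      sum(x$condition == "KO"), "KO )\n")
  invisible(x)
}

#' Read a counts TSV (gene_id, length, then sample columns)
#'
#' @param path TSV path with a header line.
#' @param condition Condition per sample column; when `NULL`, inferred from
#'   column-name prefixes `ctrl`/`control` vs `ko`.
#' @return An [expression_matrix()].
#' @export
read_counts <- function(path, condition = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 4 || names(df)[1] != "gene_id" || names(df)[2] != "length") {
    stop("counts file must have columns gene_id, length, then samples")
  }
  counts <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(counts) <- df$gene_id
  if (is.null(condition)) {
    nm <- tolower(colnames(counts))
    condition <- ifelse(grepl("^(ctrl|control)", nm), "control",
                        ifelse(grepl("^ko", nm), "KO", NA))
    if (anyNA(condition)) {
      stop("cannot infer condition from sample names; pass `condition`")
    }
  }
  expression_matrix(counts, df$length, condition)
}

#' Write an ExpressionMatrix as a counts TSV
#'
#' @param x An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  df <- data.frame(gene_id = rownames(x$counts), length = x$gene_lengths,
                   x$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Transcripts per million
#'
#' `tpm_gi = 1e6 * (c_gi / L_g) / sum_g(c_gi / L_g)`; every sample column
#' sums to 1e6.
#'
#' @param x An [expression_matrix()].
#' @return Numeric matrix of TPM values, same dimnames as the counts.
#' @export
tpm <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  rate <- x$counts / x$gene_lengths
  denom <- colSums(rate)
  if (any(denom == 0)) {
    stop("all-zero sample(s): ",
         paste(colnames(x$counts)[denom == 0], collapse = ", "))
  }
  sweep(rate, 2, denom, "/") * 1e6
}

#' Differential expression by fold-change and t-test thresholds
#'
#' Per gene, the fold change is computed on condition-mean TPM with a
#' pseudocount, `fc = (mean KO TPM + pc) / (mean control TPM + pc)`, and
#' the p-value from a two-sample t-test on `log2(TPM + 1)`. The default is
#' the pooled-variance (Student) test, which is calibrated at nominal alpha
#' for the small, equal-size replicate groups this design targets; Welch's
#' unequal-variance test is available via `var_equal = FALSE`. A gene is
#' `up` when `fc >= fc_cutoff` and `p < alpha`, `down` symmetrically with
#' `1/fc_cutoff`, otherwise `ns`. Genes whose values are constant within
#' both groups get `p = 1` and `ns`.
#'
#' @param x An [expression_matrix()].
#' @param fc_cutoff Fold-change cutoff, typically 1.3 or 1.5 (default 1.3).
#' @param alpha P-value cutoff (default 0.05), applied to raw p-values.
#' @param pseudocount TPM pseudocount for the fold change (default 1).
#' @param var_equal Pooled-variance t-test when `TRUE` (default), Welch
#'   otherwise.
#' @param adjust Apply Benjamini-Hochberg correction before thresholding
#'   (default `FALSE`: raw p-values, matching a plain `P < alpha` rule).
#' @return An object of class `DEResult` (a data.frame): `gene_id`,
#'   `mean_tpm_control`, `mean_tpm_ko`, `fc`, `log2fc`, `p`, `flag`.
#' @export
de_test <- function(x, fc_cutoff = 1.3, alpha = 0.05, pseudocount = 1,
                    var_equal = TRUE, adjust = FALSE) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (fc_cutoff <= 1) stop("fc_cutoff must be > 1")
  tp <- tpm(x)
  lg <- log2(tp + 1)
  ctrl <- x$condition == "control"
  ko <- x$condition == "KO"
  n1 <- sum(ctrl); n2 <- sum(ko)
  m1 <- rowMeans(lg[, ctrl, drop = FALSE])
  m2 <- rowMeans(lg[, ko, drop = FALSE])
  v1 <- apply(lg[, ctrl, drop = FALSE], 1, stats::var)
  v2 <- apply(lg[, ko, drop = FALSE], 1, stats::var)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(se2))
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m2 - m1) / sqrt(se2)
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  degenerate <- v1 == 0 & v2 == 0
  p[degenerate] <- 1
  if (adjust) p <- stats::p.adjust(p, method = "BH")
  mt1 <- rowMeans(tp[, ctrl, drop = FALSE])
  mt2 <- rowMeans(tp[, ko, drop = FALSE])
  fc <- (mt2 + pseudocount) / (mt1 + pseudocount)
  flag <- rep("ns", nrow(tp))
  flag[fc >= fc_cutoff & p < alpha] <- "up"
  flag[fc <= 1 / fc_cutoff & p < alpha] <- "down"
  flag[degenerate] <- "ns"
  structure(data.frame(gene_id = rownames(x$counts),
                       mean_tpm_control = unname(mt1),
                       mean_tpm_ko = unname(mt2),
                       fc = unname(fc), log2fc = unname(log2(fc)),
                       p = unname(p), flag = flag,
                       stringsAsFactors = FALSE),
            class = c("DEResult", "data.frame"),
            fc_cutoff = fc_cutoff, alpha = alpha)
}

#' @export
print.DEResult <- function(x, ...) {
  cat("DEResult:", nrow(x), "genes;", sum(x$flag == "up"), "up,",
      sum(x$flag == "down"), "down (FC >=", attr(x, "fc_cutoff"),
      ", p <", attr(x, "alpha"), ")\n")
  invisible(x)
}

#' Write a DEResult as TSV
#'
#' @param x A [de_test()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a DEResult written by [write_de()]
#'
#' @param path TSV path.
#' @return A `DEResult`.
#' @export
read_de <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  structure(df, class = c("DEResult", "data.frame"))
}

#' Upregulated gene set from a DE result
#'
#' @param result A [de_test()] result.
#' @return Sorted character vector of gene ids flagged `up`.
#' @export
up_gene_set <- function(result) {
  stopifnot(inherits(result, "DEResult"))
  sort(result$gene_id[result$flag == "up"])
}
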