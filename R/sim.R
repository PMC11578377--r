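#' Configuration for the synthetic epigenome generator
#'
#' Defines a two-condition (control vs knockout), three-signal (SIN3B,
#' HDAC1, H3K27Ac) genome with planted ground truth: SIN3B peaks lost in
#' the knockout at `n_domains` planted domains, HDAC1 log10 signal on
#' those domains correlated with SIN3B at `cooccupancy_r`, H3K27Ac gain
#' concentrated at promoters and super-enhancers of planted gene subsets,
#' a planted fraction of gain genes that also lose HDAC1, and
#' negative-binomial RNA-seq counts with upregulation linked to the gain
#' genes.
#'
#' @param seed Integer seed; the whole simulation is a deterministic
#'   function of the config.
#' @param layout [genome_layout()] (default 2 chromosomes x 10 Mb).
#' @param n_genes Number of genes (default 500).
#' @param n_domains Planted knockout-lost SIN3B domains (default 50).
#' @param domain_length Domain width in basepairs (default 6000).
#' @param cooccupancy_r Target Pearson correlation of log10 SIN3B vs HDAC1
#'   signal over domains (default 0.87).
#' @param frac_gain_with_hdac1_loss Fraction of promoter H3K27Ac-gain genes
#'   that are also HDAC1-lost (default 0.494).
#' @param n_up_genes Planted upregulated genes (default 60).
#' @param up_log2fc Planted expression effect size in log2 units (default 1).
#' @param nb_dispersion Negative-binomial dispersion of counts (default
#'   0.02, a typical cell-line value).
#' @param n_reps RNA-seq replicates per condition (default 3).
#' @param reads_per_track Optional target library size per coverage track;
#'   `NULL` (default) keeps the natural signal-rate scale.
#' @param n_gain_pro,n_se_genes,n_gain_se Sizes of the planted promoter-gain
#'   set, the super-enhancer-bearing gene set, and its gained subset.
#' @param n_hdac1_loss_extra HDAC1-lost genes outside the gain set.
#' @param frac_up_from_gain Fraction of up genes drawn from the H3K27Ac
#'   gain sets (default 0.75).
#' @param promoter_flank Promoter half-width used for planting (default
#'   3000 bp, matching the TSS +/- 3 kb analysis window).
#' @param gain_fc Planted H3K27Ac rate ratio at gained regions (default 2).
#' @param hdac1_loss_fc Planted HDAC1 promoter rate ratio at lost genes
#'   (default 0.4).
#' @param domain_ko_fc HDAC1 domain rate ratio in the knockout (default 0.3).
#' @param bin_size Coverage sampling bin in basepairs (default 100).
#' @param n_shared_peaks SIN3B peaks present in both conditions (default
#'   100); they exercise the requirement that a window with any knockout
#'   peak is not called lost.
#' @param rates Named list of per-basepair signal rates:
#'   `sin3b_bg`, `hdac1_bg`, `h3k27ac_bg` (backgrounds),
#'   `sin3b_mu`, `sin3b_sd`, `hdac1_mu` (log10 domain signal),
#'   `shared_peak`, `hdac1_pro`, `h3k27ac_pro`, `enh`, `se`.
#' @return An object of class `SimConfig`.
#' @export
sim_config <- function(seed = 42,
                       layout = genome_layout(c("chr1", "chr2"),
                                              c(1e7, 1e7)),
                       n_genes = 500, n_domains = 50, domain_length = 6000,
                       cooccupancy_r = 0.87,
                       frac_gain_with_hdac1_loss = 0.494,
                       n_up_genes = 60, up_log2fc = 1, nb_dispersion = 0.02,
                       n_reps = 3, reads_per_track = NULL,
                       n_gain_pro = 80, n_se_genes = 40, n_gain_se = 30,
                       n_hdac1_loss_extra = 40, frac_up_from_gain = 0.75,
                       promoter_flank = 3000, gain_fc = 2,
                       hdac1_loss_fc = 0.4, domain_ko_fc = 0.3,
                       bin_size = 100, n_shared_peaks = 100,
                       rates = list()) {
  stopifnot(inherits(layout, "GenomeLayout"))
  if (!(cooccupancy_r > 0 && cooccupancy_r < 1)) {
    stop("cooccupancy_r must be in (0, 1)")
  }
  if (frac_gain_with_hdac1_loss < 0 || frac_gain_with_hdac1_loss > 1) {
    stop("frac_gain_with_hdac1_loss must be in [0, 1]")
  }
  genome_size <- sum(layout$length)
  if (n_domains * domain_length >= genome_size / 10) {
    stop("planted domains exceed a tenth of the genome; enlarge the layout")
  }
  if (n_se_genes > n_genes || n_gain_se > n_se_genes ||
      n_gain_pro > n_genes || n_up_genes > n_genes) {
    stop("planted gene set sizes exceed n_genes")
  }
  default_rates <- list(sin3b_bg = 0.1, hdac1_bg = 0.2, h3k27ac_bg = 1.0,
                        sin3b_mu = log10(20), sin3b_sd = 0.25,
                        hdac1_mu = log10(4), shared_peak = 8,
                        hdac1_pro = 4, h3k27ac_pro = 3, enh = 3, se = 8)
  unknown <- setdiff(names(rates), names(default_rates))
  if (length(unknown)) {
    stop("unknown rate key(s): ", paste(unknown, collapse = ", "))
  }
  default_rates[names(rates)] <- rates
  structure(list(seed = as.integer(seed), layout = layout,
                 n_genes = n_genes, n_domains = n_domains,
                 domain_length = domain_length,
                 cooccupancy_r = cooccupancy_r,
                 frac_gain_with_hdac1_loss = frac_gain_with_hdac1_loss,
                 n_up_genes = n_up_genes, up_log2fc = up_log2fc,
                 nb_dispersion = nb_dispersion, n_reps = n_reps,
                 reads_per_track = reads_per_track,
                 n_gain_pro = n_gain_pro, n_se_genes = n_se_genes,
                 n_gain_se = n_gain_se,
                 n_hdac1_loss_extra = n_hdac1_loss_extra,
                 frac_up_from_gain = frac_up_from_gain,
                 promoter_flank = promoter_flank, gain_fc = gain_fc,
                 hdac1_loss_fc = hdac1_loss_fc, domain_ko_fc = domain_ko_fc,
                 bin_size = bin_size, n_shared_peaks = n_shared_peaks,
                 rates = default_rates),
            class = "SimConfig")
}

#' @export
print.SimConfig <- function(x, ...) {
  cat("SimConfig: seed", x$seed, "|", nrow(x$layout), "chrom(s),",
      format(sum(x$layout$length), big.mark = ","), "bp |",
      x$n_genes, "genes,", x$n_domains, "domains of", x$domain_length,
      "bp | r =", x$cooccupancy_r, "\n")
  invisible(x)
}

# Slot-based placement. The genome is divided into equal slots, one per
# planted entity (gene, domain, shared peak), shuffled across chromosomes.
# Margins keep entities far enough apart that domain calling, enhancer
# stitching and SE-to-gene assignment cannot bleed across entities.
place_entities <- function(config) {
  layout <- config$layout
  flank <- config$promoter_flank
  margin <- flank + 500          # slot edge to gene start
  enh_offset <- flank + 500      # gene end to enhancer zone (clears the
                                 # minus-strand promoter)
  se_span <- 3 * 1500 + 2 * 2000 # 3 constituents of 1500 bp, 2 kb gaps
  trailing_min <- 6000           # keeps cross-slot enhancer gaps > 12.5 kb
  gene_min <- 2000
  n_entities <- config$n_genes + config$n_domains + config$n_shared_peaks
  # slots per chromosome, proportional to length
  share <- layout$length / sum(layout$length)
  k <- floor(share * n_entities)
  rem <- n_entities - sum(k)
  if (rem > 0) k[seq_len(rem)] <- k[seq_len(rem)] + 1
  slot_len <- floor(layout$length / pmax(k, 1))
  req <- max(3 * config$domain_length,
             margin + gene_min + enh_offset + se_span + trailing_min)
  if (any(k > 0 & slot_len < req)) {
    stop("infeasible placement: planted entities do not fit the layout ",
         "(slot ", min(slot_len[k > 0]), " bp < required ", req, " bp)")
  }
  gene_max <- min(7000,
                  min(slot_len[k > 0]) -
                    (margin + enh_offset + se_span + trailing_min),
                  floor((min(slot_len[k > 0]) -
                           (margin + enh_offset + se_span)) / 2) - 100)
  gene_max <- max(gene_max, gene_min)
  slots <- do.call(rbind, lapply(seq_len(nrow(layout)), function(i) {
    if (k[i] == 0) return(NULL)
    data.frame(chrom = layout$chrom[i],
               start0 = (seq_len(k[i]) - 1) * slot_len[i],
               len = slot_len[i], stringsAsFactors = FALSE)
  }))
  types <- sample(c(rep("gene", config$n_genes),
                    rep("domain", config$n_domains),
                    rep("shared", config$n_shared_peaks)))
  slots$type <- types
  list(slots = slots, margin = margin, enh_offset = enh_offset,
       se_span = se_span, gene_min = gene_min, gene_max = gene_max)
}

#' Simulate negative-binomial RNA-seq counts
#'
#' Base means are log-normal; planted up genes have their knockout mean
#' multiplied by `2^up_log2fc`; replicates are i.i.d. negative binomial
#' with the given dispersion. Randomness comes from the caller's RNG state
#' (use `set.seed()` for reproducibility).
#'
#' @param gene_ids Character vector of gene ids.
#' @param gene_lengths Basepair lengths per gene (default 1000).
#' @param up_genes Gene ids upregulated in the knockout.
#' @param up_log2fc Planted log2 fold change (default 1).
#' @param nb_dispersion NB dispersion; 0 gives Poisson counts.
#' @param n_reps Replicates per condition (default 3).
#' @param base_meanlog,base_sdlog Log-normal parameters of baseline means.
#' @return An [expression_matrix()] with samples `ctrl_1..n, ko_1..n`.
#' @export
simulate_counts <- function(gene_ids,
                            gene_lengths = rep(1000L, length(gene_ids)),
                            up_genes = character(0), up_log2fc = 1,
                            nb_dispersion = 0.02, n_reps = 3,
                            base_meanlog = log(200), base_sdlog = 1) {
  n <- length(gene_ids)
  mu <- stats::rlnorm(n, base_meanlog, base_sdlog)
  mu_ko <- mu * ifelse(gene_ids %in% up_genes, 2^up_log2fc, 1)
  draw <- function(m) {
    if (nb_dispersion > 0) {
      stats::rnbinom(n * n_reps, mu = rep(m, n_reps),
                     size = 1 / nb_dispersion)
    } else {
      stats::rpois(n * n_reps, rep(m, n_reps))
    }
  }
  counts <- cbind(matrix(draw(mu), nrow = n),
                  matrix(draw(mu_ko), nrow = n))
  rownames(counts) <- gene_ids
  colnames(counts) <- c(paste0("ctrl_", seq_len(n_reps)),
                        paste0("ko_", seq_len(n_reps)))
  expression_matrix(counts, gene_lengths,
                    rep(c("control", "KO"), each = n_reps))
}

# Sample a coverage track: per-basepair Poisson rates (an Rle per
# chromosome) are averaged over fixed bins, reads per bin are Poisson, and
# the per-base value is reads / bin width.
sample_track <- function(rate_rles, layout, bin_size) {
  cov <- S4Vectors::SimpleList(lapply(layout$chrom, function(chrom) {
    r <- rate_rles[[chrom]]
    len <- length(r)
    n_bins <- ceiling(len / bin_size)
    starts <- (seq_len(n_bins) - 1) * bin_size + 1
    ends <- pmin(starts + bin_size - 1, len)
    widths <- ends - starts + 1
    lam <- IRanges::viewMeans(IRanges::Views(r, start = starts, end = ends)) *
      widths
    vals <- stats::rpois(n_bins, lam) / widths
    S4Vectors::Rle(vals, widths)
  }))
  names(cov) <- layout$chrom
  cov <- methods::as(cov, "RleList")
  coverage_track(cov, layout)
}

# Per-bp rate RleList = background + sum of feature rates (GRanges with a
# `rate` metadata column).
rate_rles <- function(features, bg, layout) {
  si <- as_seqinfo(layout)
  if (length(features) == 0L) {
    cv <- IRanges::coverage(GenomicRanges::GRanges(seqinfo = si))
  } else {
    suppressWarnings(GenomeInfoDb::seqinfo(features) <- si)
    cv <- IRanges::coverage(features, weight = "rate")
  }
  out <- lapply(layout$chrom, function(ch) cv[[ch]] + bg)
  names(out) <- layout$chrom
  out
}

#' Simulate a two-condition, three-signal epigenome with planted truth
#'
#' Deterministic given the config (the global RNG is seeded from
#' `config$seed`). See [sim_config()] for the planted structure.
#'
#' @param config A [sim_config()].
#' @return An object of class `EpigenomeSim`: `config`, `layout`, `genes`
#'   (`GRanges` with gene_id), `peaks` (nested list
#'   `factor -> condition -> GRanges`), `tracks` (nested list of
#'   [coverage_track()]s), `counts` (an [expression_matrix()]), and
#'   `truth` (class `GroundTruth`: `planted_domains`, `gain_genes` per
#'   class, `hdac1_loss_genes`, `up_genes`, `se_genes`, `latent`
#'   per-domain log10 signals).
#' @export
simulate_epigenome <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  layout <- config$layout
  si <- as_seqinfo(layout)
  rt <- config$rates
  pl <- place_entities(config)
  slots <- pl$slots

  # --- genes, enhancer zones ------------------------------------------------
  gs <- slots[slots$type == "gene", ]
  gene_len <- floor(stats::runif(nrow(gs), pl$gene_min, pl$gene_max + 1))
  gene_strand <- sample(c("+", "-"), nrow(gs), replace = TRUE)
  gene_start0 <- gs$start0 + pl$margin
  genes <- GenomicRanges::GRanges(
    gs$chrom,
    IRanges::IRanges(start = gene_start0 + 1,
                     end = gene_start0 + gene_len),
    strand = gene_strand, seqinfo = si)
  genes <- BiocGenerics::sort(genes, ignore.strand = TRUE)
  genes$gene_id <- sprintf("g%04d", seq_along(genes))
  ids <- genes$gene_id
  zone0 <- BiocGenerics::end(genes) + pl$enh_offset  # 0-based zone start

  # --- planted gene sets ----------------------------------------------------
  se_genes <- sort(sample(ids, config$n_se_genes))
  gain_se <- sort(sample(se_genes, config$n_gain_se))
  gain_pro <- sort(sample(ids, config$n_gain_pro))
  k_in <- round(config$frac_gain_with_hdac1_loss * length(gain_pro))
  hdac1_loss <- sort(c(sample(gain_pro, k_in),
                       sample(setdiff(ids, gain_pro),
                              config$n_hdac1_loss_extra)))
  gain_pool <- union(gain_pro, gain_se)
  n_from_gain <- min(round(config$frac_up_from_gain * config$n_up_genes),
                     length(gain_pool))
  up_genes <- sort(c(sample(gain_pool, n_from_gain),
                     sample(setdiff(ids, gain_pool),
                            config$n_up_genes - n_from_gain)))

  # --- planted domains and shared peaks ------------------------------------
  ds <- slots[slots$type == "domain", ]
  dlen <- config$domain_length
  dom_start0 <- ds$start0 + dlen +
    floor(stats::runif(nrow(ds)) * (ds$len - 3 * dlen + 1))
  domains <- BiocGenerics::sort(GenomicRanges::GRanges(
    ds$chrom, IRanges::IRanges(start = dom_start0 + 1, width = dlen),
    seqinfo = si), ignore.strand = TRUE)
  domains$name <- sprintf("planted_%04d", seq_along(domains))
  ss <- slots[slots$type == "shared", ]
  sh_w <- 1500
  sh_start0 <- ss$start0 + 6000 +
    floor(stats::runif(nrow(ss)) * (ss$len - 12000 - sh_w + 1))
  shared <- BiocGenerics::sort(GenomicRanges::GRanges(
    ss$chrom, IRanges::IRanges(start = sh_start0 + 1, width = sh_w),
    seqinfo = si), ignore.strand = TRUE)

  # --- latent domain signals (log10 per-bp rates) ---------------------------
  r <- config$cooccupancy_r
  s_lat <- stats::rnorm(length(domains), rt$sin3b_mu, rt$sin3b_sd)
  noise_sd <- rt$sin3b_sd * sqrt(1 / r^2 - 1)
  h_lat <- rt$hdac1_mu + (s_lat - rt$sin3b_mu) +
    stats::rnorm(length(domains), 0, noise_sd)

  # --- region geometry for planting -----------------------------------------
  flank <- config$promoter_flank
  tss0 <- BiocGenerics::start(tss_positions(genes)) - 1L
  lens <- layout$length[match(as.character(GenomeInfoDb::seqnames(genes)),
                              layout$chrom)]
  promoters <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(genes),
    IRanges::IRanges(start = pmax(tss0 - flank, 0) + 1L,
                     end = pmin(tss0 + flank, lens)), seqinfo = si)
  is_se <- ids %in% se_genes
  se_peaks <- GenomicRanges::GRanges(
    rep(as.character(GenomeInfoDb::seqnames(genes))[is_se], each = 3),
    IRanges::IRanges(
      start = rep(zone0[is_se], each = 3) +
        rep(c(0, 3500, 7000), sum(is_se)) + 1L,
      width = 1500), seqinfo = si)
  se_peaks$gene_id <- rep(ids[is_se], each = 3)
  enh_peaks <- GenomicRanges::GRanges(
    as.character(GenomeInfoDb::seqnames(genes))[!is_se],
    IRanges::IRanges(start = zone0[!is_se] + 1L, width = 1500),
    seqinfo = si)
  enh_peaks$gene_id <- ids[!is_se]

  with_rate <- function(gr, rate) {
    out <- GenomicRanges::granges(gr)
    out$rate <- rate
    out
  }
  gain_pro_mask <- ids %in% gain_pro
  loss_mask <- ids %in% hdac1_loss
  se_gain_mask <- se_peaks$gene_id %in% gain_se

  # KO H3K27Ac background dips so that planted gains do not shift the
  # library size: total signal mass matches control in expectation
  # (acetylation redistributes rather than accumulates).
  extra_mass <- (config$gain_fc - 1) *
    (rt$h3k27ac_pro * sum(BiocGenerics::width(promoters)[gain_pro_mask]) +
       rt$se * 1500 * sum(se_gain_mask))
  comp <- 1 - extra_mass / (rt$h3k27ac_bg * sum(layout$length))
  if (comp <= 0.1) {
    stop("infeasible placement: planted H3K27Ac gains exceed the ",
         "background mass available for redistribution")
  }

  feats <- list(
    sin3b = list(
      control = c(with_rate(domains, 10^s_lat),
                  with_rate(shared, rt$shared_peak)),
      KO = with_rate(shared, rt$shared_peak)),
    hdac1 = list(
      control = c(with_rate(domains, 10^h_lat),
                  with_rate(promoters, rt$hdac1_pro)),
      KO = c(with_rate(domains, 10^h_lat * config$domain_ko_fc),
             with_rate(promoters,
                       rt$hdac1_pro *
                         ifelse(loss_mask, config$hdac1_loss_fc, 1)))),
    h3k27ac = list(
      control = c(with_rate(promoters, rt$h3k27ac_pro),
                  with_rate(enh_peaks, rt$enh),
                  with_rate(se_peaks, rt$se)),
      KO = c(with_rate(promoters,
                       rt$h3k27ac_pro *
                         ifelse(gain_pro_mask, config$gain_fc, 1)),
             with_rate(enh_peaks, rt$enh),
             with_rate(se_peaks,
                       rt$se * ifelse(se_gain_mask, config$gain_fc, 1)))))
  bgs <- list(sin3b = c(control = rt$sin3b_bg, KO = rt$sin3b_bg),
              hdac1 = c(control = rt$hdac1_bg, KO = rt$hdac1_bg),
              h3k27ac = c(control = rt$h3k27ac_bg,
                          KO = rt$h3k27ac_bg * comp))

  tracks <- list()
  for (fac in names(feats)) {
    tracks[[fac]] <- list()
    for (cond in c("control", "KO")) {
      rr <- rate_rles(feats[[fac]][[cond]], bgs[[fac]][[cond]], layout)
      if (!is.null(config$reads_per_track)) {
        mass <- sum(vapply(rr, function(x) sum(as.numeric(
          S4Vectors::runValue(x)) * S4Vectors::runLength(x)), numeric(1)))
        rr <- lapply(rr, function(x) x * (config$reads_per_track / mass))
      }
      tracks[[fac]][[cond]] <- sample_track(rr, layout, config$bin_size)
    }
  }

  mk_peaks <- function(gr, fac, cond) {
    gr <- GenomicRanges::granges(gr)
    gr <- BiocGenerics::sort(gr, ignore.strand = TRUE)
    gr$name <- sprintf("%s_%s_%05d", fac, cond, seq_along(gr))
    gr$factor <- fac
    gr$condition <- cond
    gr
  }
  ac_peaks <- c(GenomicRanges::granges(promoters),
                GenomicRanges::granges(enh_peaks),
                GenomicRanges::granges(se_peaks))
  peaks <- list(
    sin3b = list(
      control = mk_peaks(c(GenomicRanges::granges(domains),
                           GenomicRanges::granges(shared)),
                         "SIN3B", "control"),
      KO = mk_peaks(shared, "SIN3B", "KO")),
    hdac1 = list(
      control = mk_peaks(c(GenomicRanges::granges(domains),
                           GenomicRanges::granges(promoters)),
                         "HDAC1", "control"),
      KO = mk_peaks(promoters, "HDAC1", "KO")),
    h3k27ac = list(
      control = mk_peaks(ac_peaks, "H3K27Ac", "control"),
      KO = mk_peaks(ac_peaks, "H3K27Ac", "KO")))

  counts <- simulate_counts(ids, BiocGenerics::width(genes),
                            up_genes = up_genes,
                            up_log2fc = config$up_log2fc,
                            nb_dispersion = config$nb_dispersion,
                            n_reps = config$n_reps)

  truth <- structure(list(
    planted_domains = domains,
    gain_genes = list(Pro = gain_pro, SE = gain_se),
    hdac1_loss_genes = hdac1_loss,
    up_genes = up_genes,
    se_genes = se_genes,
    frac_gain_with_hdac1_loss = length(intersect(gain_pro, hdac1_loss)) /
      length(gain_pro),
    latent = data.frame(name = domains$name, log10_sin3b = s_lat,
                        log10_hdac1 = h_lat)),
    class = "GroundTruth")

  structure(list(config = config, layout = layout, genes = genes,
                 peaks = peaks, tracks = tracks, counts = counts,
                 truth = truth),
            class = "EpigenomeSim")
}

#' @export
print.EpigenomeSim <- function(x, ...) {
  cat("EpigenomeSim: seed", x$config$seed, "|", length(x$genes), "genes,",
      length(x$truth$planted_domains), "planted domains |",
      "tracks:", paste(names(x$tracks), collapse = ", "), "\n")
  invisible(x)
}

#' Write a simulated epigenome to disk as a pipeline fixture
#'
#' Inputs (peak BEDs, bedGraph tracks, gene BED6, counts TSV, chrom.sizes)
#' go under `outdir/inputs/`; the ground truth is serialised separately
#' under `outdir/truth/`. A manifest TSV lists every file with its role
#' and md5 checksum.
#'
#' @param sim A [simulate_epigenome()] result.
#' @param outdir Output directory (created if needed).
#' @return The manifest data.frame (`file`, `role`, `md5`), invisibly;
#'   also written to `outdir/manifest.tsv`.
#' @export
write_fixture <- function(sim, outdir) {
  stopifnot(inherits(sim, "EpigenomeSim"))
  ind <- file.path(outdir, "inputs")
  trd <- file.path(outdir, "truth")
  for (d in c(ind, trd)) {
    if (!dir.create(d, recursive = TRUE, showWarnings = FALSE) &&
        !dir.exists(d)) {
      stop("cannot create output directory: ", d)
    }
  }
  rel_files <- character(0)
  roles <- character(0)
  put <- function(path, role) {
    rel_files <<- c(rel_files,
                    sub(paste0(outdir, .Platform$file.sep), "", path,
                        fixed = TRUE))
    roles <<- c(roles, role)
  }
  write_chrom_sizes(sim$layout, file.path(ind, "chrom.sizes"))
  put(file.path(ind, "chrom.sizes"), "input")
  g <- sim$genes
  g$name <- g$gene_id
  g$score <- 0L
  g$gene_id <- NULL
  write_bed(g, file.path(ind, "genes.bed"))
  put(file.path(ind, "genes.bed"), "input")
  for (fac in names(sim$peaks)) {
    for (cond in names(sim$peaks[[fac]])) {
      pk <- sim$peaks[[fac]][[cond]]
      pk$factor <- NULL
      pk$condition <- NULL
      pk$score <- 0L
      f <- file.path(ind, sprintf("peaks_%s_%s.bed", fac, tolower(cond)))
      write_bed(pk, f)
      put(f, "input")
      f <- file.path(ind, sprintf("track_%s_%s.bedGraph", fac,
                                  tolower(cond)))
      write_bedgraph(sim$tracks[[fac]][[cond]], f)
      put(f, "input")
    }
  }
  write_counts(sim$counts, file.path(ind, "counts.tsv"))
  put(file.path(ind, "counts.tsv"), "input")

  td <- sim$truth$planted_domains
  td$score <- 0L
  write_bed(td, file.path(trd, "planted_domains.bed"))
  put(file.path(trd, "planted_domains.bed"), "truth")
  sets <- list(gain_pro = sim$truth$gain_genes$Pro,
               gain_se = sim$truth$gain_genes$SE,
               hdac1_loss = sim$truth$hdac1_loss_genes,
               up_genes = sim$truth$up_genes,
               se_genes = sim$truth$se_genes)
  for (nm in names(sets)) {
    f <- file.path(trd, paste0(nm, ".txt"))
    writeLines(sets[[nm]], f)
    put(f, "truth")
  }
  utils::write.table(sim$truth$latent, file.path(trd, "latent.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  put(file.path(trd, "latent.tsv"), "truth")
  cfgf <- file.path(outdir, "sim_config.txt")
  writeLines(format_sim_config(sim$config), cfgf)
  put(cfgf, "config")
  manifest <- data.frame(
    file = rel_files,
    role = roles,
    md5 = unname(tools::md5sum(file.path(outdir, rel_files))),
    stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(outdir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

# Flat key = value serialisation of a SimConfig.
format_sim_config <- function(config) {
  c(paste0("seed = ", config$seed),
    paste0("chroms = ", paste(config$layout$chrom, collapse = ",")),
    paste0("chrom_lengths = ",
           paste(format(config$layout$length, scientific = FALSE,
                        trim = TRUE), collapse = ",")),
    vapply(setdiff(names(config), c("seed", "layout", "rates")),
           function(k) paste0(k, " = ",
                              if (is.null(config[[k]])) "NULL"
                              else format(config[[k]], scientific = FALSE,
                                          trim = TRUE)),
           character(1)),
    vapply(names(config$rates),
           function(k) paste0("rate_", k, " = ",
                              format(config$rates[[k]], trim = TRUE)),
           character(1)))
}
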