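#' Default pipeline configuration
#'
#' A flat named list of every tunable constant and input path used by
#' [run_pipeline()]. Path entries left `NULL` fall back to the standard
#' fixture layout under `<outdir>/fixture/inputs/` written by the
#' `simulate` stage.
#'
#' @return Named list of configuration keys.
#' @export
default_config <- function() {
  list(
    # input paths (NULL = <outdir>/fixture/inputs/<standard name>)
    chrom_sizes = NULL, genes = NULL, counts = NULL,
    peaks_sin3b_control = NULL, peaks_sin3b_ko = NULL,
    peaks_h3k27ac_ko = NULL,
    track_sin3b_control = NULL, track_hdac1_control = NULL,
    track_hdac1_ko = NULL, track_h3k27ac_control = NULL,
    track_h3k27ac_ko = NULL,
    # stage parameters
    window_size = 6000, step = 6000,
    promoter_flank = 3000, stitch_gap = 12500, se_assignment_radius = 50000,
    fc_threshold = 1.3, fc_pseudocount = 0.1,
    fc_cutoff = 1.3, alpha = 0.05, de_pseudocount = 1,
    corr_pseudocount = 0.01,
    seed = 42,
    outdir = "markshift_out")
}

#' Read a flat key = value configuration file
#'
#' Lines are `key = value`; blank lines and `#` comments are ignored.
#' Unknown keys are an error (all of them are listed). Values are coerced
#' to the type of the corresponding [default_config()] entry; the literal
#' `NULL` clears a key.
#'
#' @param path Config file path.
#' @param base Config list to fill in (default [default_config()]).
#' @return A full config list.
#' @export
read_config <- function(path, base = default_config()) {
  if (!file.exists(path)) stop("no such config file: ", path)
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  template <- default_config()
  unknown <- character(0)
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    if (!key %in% names(template)) {
      unknown <- c(unknown, key)
      next
    }
    if (identical(val, "NULL")) {
      base[key] <- list(NULL)
    } else if (is.numeric(template[[key]])) {
      base[[key]] <- as.numeric(val)
    } else {
      base[[key]] <- val
    }
  }
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  validate_config(base)
}

validate_config <- function(config) {
  template <- default_config()
  unknown <- setdiff(names(config), names(template))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  config <- utils::modifyList(template, config, keep.null = TRUE)
  for (k in c("window_size", "step", "promoter_flank", "stitch_gap",
              "se_assignment_radius", "fc_threshold", "fc_pseudocount",
              "fc_cutoff", "alpha", "de_pseudocount")) {
    if (!is.numeric(config[[k]]) || config[[k]] <= 0) {
      stop("config key ", k, " must be > 0")
    }
  }
  config
}

# Resolve an input path: explicit config entry, else the fixture default.
input_path <- function(config, key, default_name, stage) {
  p <- config[[key]]
  if (is.null(p)) {
    p <- file.path(config$outdir, "fixture", "inputs", default_name)
  }
  if (!file.exists(p)) {
    stop("stage '", stage, "': missing input '", key, "' (", p, ")")
  }
  p
}

# A stage output that a later stage depends on.
stage_output <- function(config, name, needed_by, produced_by) {
  p <- file.path(config$outdir, name)
  if (!file.exists(p)) {
    stop("stage '", needed_by, "': missing ", name,
         "; run stage '", produced_by, "' first")
  }
  p
}

load_layout <- function(config, stage) {
  read_chrom_sizes(input_path(config, "chrom_sizes", "chrom.sizes", stage))
}

log_stage <- function(stage, what) {
  message("[markshift] ", stage, ": ", what)
}

#' Run pipeline stages
#'
#' Stages: `simulate` (write a synthetic fixture under
#' `<outdir>/fixture/`), `call-domains` (knockout-lost SIN3B domains on the
#' window grid plus the SIN3B/HDAC1 domain correlation), `call-se`
#' (ROSE-style super-enhancers from knockout H3K27Ac), `quantify-marks`
#' (per-gene, per-region fold-change tables for H3K27Ac and HDAC1, plus
#' TSS signal matrices), `de` (differential expression from the count
#' matrix), `integrate` (overlap statistics and the final report), and
#' `all` (everything, in dependency order). A `config_used.txt` snapshot
#' and its md5 are written to the output directory for auditability.
#'
#' @param subcommand One of `simulate`, `call-domains`, `call-se`,
#'   `quantify-marks`, `de`, `integrate`, `all`.
#' @param config A config list (see [default_config()]) or the path to a
#'   flat key = value config file.
#' @param ... Individual config overrides (e.g. `outdir = "run1"`), applied
#'   after the file; an unknown name is an error.
#' @return Invisibly, a named list of paths written by the stage(s).
#' @export
run_pipeline <- function(subcommand = c("all", "simulate", "call-domains",
                                        "call-se", "quantify-marks", "de",
                                        "integrate"),
                         config = default_config(), ...) {
  subcommand <- match.arg(subcommand)
  if (is.character(config)) config <- read_config(config)
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides)))) {
      stop("config overrides must be named")
    }
    config[names(overrides)] <- overrides
  }
  config <- validate_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(config$outdir, "config_used.txt")
  writeLines(vapply(names(config), function(k) {
    paste0(k, " = ", if (is.null(config[[k]])) "NULL"
           else format(config[[k]], scientific = FALSE, trim = TRUE))
  }, character(1)), cfg_path)
  log_stage(subcommand, paste0("config md5 ",
                               unname(tools::md5sum(cfg_path)),
                               ", seed ", config$seed))
  stages <- if (subcommand == "all") {
    c("simulate", "call-domains", "call-se", "quantify-marks", "de",
      "integrate")
  } else subcommand
  out <- list()
  for (stage in stages) {
    out <- c(out, switch(stage,
      "simulate" = stage_simulate(config),
      "call-domains" = stage_call_domains(config),
      "call-se" = stage_call_se(config),
      "quantify-marks" = stage_quantify_marks(config),
      "de" = stage_de(config),
      "integrate" = stage_integrate(config)))
  }
  invisible(out)
}

stage_simulate <- function(config) {
  fixdir <- file.path(config$outdir, "fixture")
  sim <- simulate_epigenome(sim_config(seed = config$seed))
  manifest <- write_fixture(sim, fixdir)
  log_stage("simulate", paste0(nrow(manifest), " files under ", fixdir))
  list(fixture = fixdir)
}

stage_call_domains <- function(config) {
  stage <- "call-domains"
  layout <- load_layout(config, stage)
  ctrl <- read_bed(input_path(config, "peaks_sin3b_control",
                              "peaks_sin3b_control.bed", stage), layout)
  ko <- read_bed(input_path(config, "peaks_sin3b_ko",
                            "peaks_sin3b_ko.bed", stage), layout)
  grid <- tile_windows(layout, config$window_size, config$step)
  dom <- call_lost_domains(ctrl, ko, grid)
  dom_path <- file.path(config$outdir, "domains.bed")
  write_domains(dom, dom_path)
  log_stage(stage, paste0(length(dom$domains), " domains -> ", dom_path))
  out <- list(domains = dom_path)
  if (length(dom$domains) >= 3) {
    ta <- read_bedgraph(input_path(config, "track_sin3b_control",
                                   "track_sin3b_control.bedGraph", stage),
                        layout)
    tb <- read_bedgraph(input_path(config, "track_hdac1_control",
                                   "track_hdac1_control.bedGraph", stage),
                        layout)
    cr <- domain_correlation(ta, tb, dom,
                             pseudocount = config$corr_pseudocount)
    cor_path <- file.path(config$outdir, "correlation.tsv")
    write_correlation(cr, cor_path)
    log_stage(stage, sprintf("co-occupancy r = %.3f (p = %.3g)", cr$r, cr$p))
    out$correlation <- cor_path
  } else {
    log_stage(stage, "fewer than 3 domains; correlation skipped")
  }
  out
}

stage_call_se <- function(config) {
  stage <- "call-se"
  layout <- load_layout(config, stage)
  genes <- read_genes(input_path(config, "genes", "genes.bed", stage),
                      layout)
  peaks <- read_bed(input_path(config, "peaks_h3k27ac_ko",
                               "peaks_h3k27ac_ko.bed", stage), layout)
  track <- read_bedgraph(input_path(config, "track_h3k27ac_ko",
                                    "track_h3k27ac_ko.bedGraph", stage),
                         layout)
  regions <- gene_regions(genes, promoter_flank = config$promoter_flank)
  promoters <- unlist(regions$Pro, use.names = FALSE)
  ses <- call_super_enhancers(peaks, track, promoters, genes,
                              stitch_gap = config$stitch_gap,
                              assignment_radius = config$se_assignment_radius)
  se_path <- file.path(config$outdir, "se.bed")
  write_super_enhancers(ses, se_path)
  tab_path <- file.path(config$outdir, "se_table.tsv")
  st <- ses$stitched
  utils::write.table(
    data.frame(chrom = as.character(GenomeInfoDb::seqnames(st)),
               start = BiocGenerics::start(st) - 1L,
               end = BiocGenerics::end(st),
               signal = st$signal, rank = st$rank,
               is_se = st$rank > ses$cutoff_index),
    tab_path, sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage(stage, paste0(length(ses$se), " super-enhancers of ",
                          length(ses$stitched), " stitched regions"))
  list(se = se_path, se_table = tab_path)
}

stage_quantify_marks <- function(config) {
  stage <- "quantify-marks"
  layout <- load_layout(config, stage)
  genes <- read_genes(input_path(config, "genes", "genes.bed", stage),
                      layout)
  se_path <- stage_output(config, "se.bed", stage, "call-se")
  se_gr <- read_bed(se_path, layout)
  se_gr$gene_id <- if (length(se_gr)) se_gr$name else character(0)
  regions <- gene_regions(genes, promoter_flank = config$promoter_flank,
                          ses = se_gr)
  tracks <- list(
    h3k27ac = list(
      ctrl = read_bedgraph(input_path(config, "track_h3k27ac_control",
                                      "track_h3k27ac_control.bedGraph",
                                      stage), layout),
      ko = read_bedgraph(input_path(config, "track_h3k27ac_ko",
                                    "track_h3k27ac_ko.bedGraph", stage),
                         layout)),
    hdac1 = list(
      ctrl = read_bedgraph(input_path(config, "track_hdac1_control",
                                      "track_hdac1_control.bedGraph",
                                      stage), layout),
      ko = read_bedgraph(input_path(config, "track_hdac1_ko",
                                    "track_hdac1_ko.bedGraph", stage),
                         layout)))
  out <- list()
  for (mark in names(tracks)) {
    tab <- region_gain(tracks[[mark]]$ctrl, tracks[[mark]]$ko, regions,
                       threshold = config$fc_threshold,
                       pseudocount = config$fc_pseudocount)
    p <- file.path(config$outdir, paste0("region_gain_", mark, ".tsv"))
    write_region_gain(tab, p)
    log_stage(stage, paste0(mark, ": ", sum(tab$gained), " gained / ",
                            sum(tab$lost), " lost rows -> ", p))
    out[[paste0("region_gain_", mark)]] <- p
  }
  anchors <- tss_positions(genes)
  for (cond in c("ctrl", "ko")) {
    m <- signal_matrix(tracks$h3k27ac[[cond]], anchors,
                       flank = config$promoter_flank, n_bins = 100)
    p <- file.path(config$outdir,
                   paste0("tss_matrix_h3k27ac_", cond, ".tsv"))
    write_signal_matrix(m, p)
    out[[paste0("tss_matrix_", cond)]] <- p
  }
  out
}

stage_de <- function(config) {
  stage <- "de"
  counts <- read_counts(input_path(config, "counts", "counts.tsv", stage))
  res <- de_test(counts, fc_cutoff = config$fc_cutoff,
                 alpha = config$alpha, pseudocount = config$de_pseudocount)
  p <- file.path(config$outdir, "de.tsv")
  write_de(res, p)
  log_stage(stage, paste0(sum(res$flag == "up"), " up / ",
                          sum(res$flag == "down"), " down of ",
                          nrow(res), " genes -> ", p))
  list(de = p)
}

stage_integrate <- function(config) {
  stage <- "integrate"
  de <- read_de(stage_output(config, "de.tsv", stage, "de"))
  gain_tab <- read_region_gain(stage_output(config, "region_gain_h3k27ac.tsv",
                                            stage, "quantify-marks"))
  loss_tab <- read_region_gain(stage_output(config, "region_gain_hdac1.tsv",
                                            stage, "quantify-marks"))
  layout <- load_layout(config, stage)
  dom_path <- stage_output(config, "domains.bed", stage, "call-domains")
  dom_gr <- read_bed(dom_path, layout)
  correlation <- NULL
  cor_path <- file.path(config$outdir, "correlation.tsv")
  if (file.exists(cor_path)) {
    hdr <- readLines(cor_path, n = 1)
    f <- strsplit(sub("^# ", "", hdr), "\t")[[1]]
    kv <- do.call(rbind, strsplit(f, "=", fixed = TRUE))
    vals <- stats::setNames(kv[, 2], kv[, 1])
    correlation <- list(n_domains = as.integer(vals[["n_domains"]]),
                        r = as.numeric(vals[["r"]]),
                        p = as.numeric(vals[["p"]]))
  }
  report <- integration_report(de, gain_tab, loss_tab,
                               correlation = correlation,
                               domains = list(domains = dom_gr))
  # the domains argument above only needs $domains; keep the count honest
  report$n_domains <- length(dom_gr)
  tsv <- file.path(config$outdir, "report.tsv")
  json <- file.path(config$outdir, "report.json")
  write_report(report, tsv_path = tsv, json_path = json)
  log_stage(stage, paste0("report -> ", tsv, ", ", json))
  invisible(list(report_tsv = tsv, report_json = json, report = report))
}
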