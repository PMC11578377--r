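# Independent oracles and small builders shared across tests. Everything
# here deliberately avoids the package's own interval machinery: the
# brute-force implementations use plain R vectors and loops.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

# CoverageTrack from plain numeric vectors (one per chromosome).
make_track <- function(values, layout, total_mapped = NULL) {
  rl <- S4Vectors::SimpleList(lapply(values, S4Vectors::Rle))
  names(rl) <- layout$chrom
  coverage_track(methods::as(rl, "RleList"), layout,
                 total_mapped = total_mapped)
}

# 0-based half-open interval data.frame -> GRanges on a layout.
df_to_gr <- function(df, layout) {
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(start = df$start0 + 1,
                                                end = df$end0))
  suppressWarnings(GenomeInfoDb::seqlevels(gr) <- layout$chrom)
  gr
}

# Brute-force lost-domain oracle: per-window scan with explicit loops over
# peaks, then manual merging of adjacent/overlapping qualifying windows.
# All coordinates 0-based half-open; returns data.frame(chrom, start0, end0).
brute_lost_domains <- function(ctrl, ko, chroms, lengths,
                               window_size = 6000, step = 6000) {
  overlaps <- function(ws, we, ps, pe) ps < we & pe > ws
  out <- list()
  for (ci in seq_along(chroms)) {
    chrom <- chroms[ci]
    len <- lengths[ci]
    cc <- ctrl[ctrl$chrom == chrom, , drop = FALSE]
    kk <- ko[ko$chrom == chrom, , drop = FALSE]
    starts <- seq(0, len - 1, by = step)
    qual <- logical(length(starts))
    for (i in seq_along(starts)) {
      ws <- starts[i]
      we <- min(ws + window_size, len)
      has_ctrl <- FALSE
      for (j in seq_len(nrow(cc))) {
        if (overlaps(ws, we, cc$start0[j], cc$end0[j])) {
          has_ctrl <- TRUE
          break
        }
      }
      has_ko <- FALSE
      for (j in seq_len(nrow(kk))) {
        if (overlaps(ws, we, kk$start0[j], kk$end0[j])) {
          has_ko <- TRUE
          break
        }
      }
      qual[i] <- has_ctrl && !has_ko
    }
    i <- 1
    while (i <= length(starts)) {
      if (qual[i]) {
        ds <- starts[i]
        de <- min(starts[i] + window_size, len)
        while (i + 1 <= length(starts) && qual[i + 1] &&
               starts[i + 1] <= de) {
          i <- i + 1
          de <- max(de, min(starts[i] + window_size, len))
        }
        out[[length(out) + 1]] <- data.frame(chrom = chrom, start0 = ds,
                                             end0 = de)
      }
      i <- i + 1
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(0), start0 = numeric(0),
                      end0 = numeric(0)))
  }
  do.call(rbind, out)
}

# Random peak set on a layout, as a 0-based data.frame.
random_peaks_df <- function(layout, n_mean = 25, w_min = 200, w_max = 5000) {
  n <- stats::rpois(1, n_mean)
  if (n == 0) {
    return(data.frame(chrom = character(0), start0 = numeric(0),
                      end0 = numeric(0)))
  }
  chrom <- sample(layout$chrom, n, replace = TRUE)
  len <- layout$length[match(chrom, layout$chrom)]
  w <- floor(stats::runif(n, w_min, w_max))
  s <- floor(stats::runif(n) * (len - w))
  df <- data.frame(chrom = chrom, start0 = s, end0 = s + w)
  df[order(df$chrom, df$start0), , drop = FALSE]
}

# Exact hypergeometric upper-tail oracle by enumeration of all subsets of
# size n_b drawn from the universe: P(|draw ∩ A| >= k).
enum_hyper_p <- function(n_universe, n_a, n_b, k) {
  draws <- utils::combn(n_universe, n_b)
  a <- seq_len(n_a)
  hits <- apply(draws, 2, function(d) sum(d %in% a))
  mean(hits >= k)
}

# One shared default fixture per test session (written lazily).
default_fixture_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      d <- file.path(tempdir(), "markshift_fixture")
      sim <- simulate_epigenome(sim_config(seed = 42))
      write_fixture(sim, d)
      dir <<- d
    }
    dir
  }
})

fixture_inputs <- function(key = NULL) {
  ind <- file.path(default_fixture_dir(), "inputs")
  if (is.null(key)) ind else file.path(ind, key)
}

read_truth_set <- function(name) {
  readLines(file.path(default_fixture_dir(), "truth", paste0(name, ".txt")))
}
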