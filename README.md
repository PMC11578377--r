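# markshift

Integrative analysis of two-condition chromatin profiling (CUT&Tag /
ChIP-seq style coverage and peaks) together with RNA-seq, for studies that
ask how losing a chromatin factor redistributes a histone mark and
reshapes transcription. The motivating use case is a scaffold subunit of a
corepressor complex (such as SIN3B, which tethers HDAC1): knocking it out
removes its binding peaks, depletes the deacetylase from the same domains,
and lets H3K27Ac accumulate at promoters and super-enhancers of inducible
genes whose transcripts then rise.

`markshift` turns that analysis into a tested, reusable pipeline:

* **Knockout-lost binding domains.** The genome is tiled with fixed
  windows (default 6 kb). A window is *lost* when ≥ 1 bp of a control
  peak overlaps it and no knockout peak does; touching lost windows merge
  into binding domains.
* **Co-occupancy over domains.** For two tracks the per-domain
  `log10(RPKM + ε)` signals are correlated (two-sided Pearson test),
  quantifying, e.g., how faithfully HDAC1 follows SIN3B:
  `RPKM = count / ((length/10³)·(total_mapped/10⁶))`.
* **Region-level mark shifts.** Each gene gets strand-aware region
  classes — promoter `Pro = [TSS − 3 kb, TSS + 3 kb)`, gene body `GB`,
  whole gene `All`, and `SE` from ROSE-style super-enhancer calling
  (promoter-filtered peaks stitched within 12.5 kb, ranked by signal,
  knee at the tangent-slope-1 point of the scaled rank curve). A region is
  *gained* when `FC = (RPKM_KO + ε)/(RPKM_ctrl + ε) ≥ 1.3` (inclusive) and
  *lost* when `FC ≤ 1/1.3`.
* **Differential expression.** `TPM_gi = 10⁶ (c_gi/L_g) / Σ_g (c_gi/L_g)`;
  a gene is *up* when its condition-mean TPM fold change is ≥ the cutoff
  (1.3 or 1.5) **and** a two-sample t-test on `log2(TPM + 1)` gives
  p < 0.05.
* **Integration.** Venn overlaps of up-regulated DEGs with per-class
  mark-gain gene sets (one-sided hypergeometric enrichment), the fraction
  of mark-gained genes that also lost the second mark, and per-class gain
  counts among up-DEGs, all assembled into one machine-readable report.
* **Synthetic epigenome generator.** A deterministic simulator plants all
  of the above — lost domains, a target co-occupancy correlation, promoter
  and SE acetylation gains, an exact gain∩loss fraction, and
  negative-binomial counts with known up-regulated genes — so every stage
  is testable end to end without external data.

## Worked example

Everything below is synthetic, generated on the fly with planted truth
(2 × 10 Mb genome, 500 genes, 50 planted 6-kb lost domains, target
co-occupancy r = 0.87, planted gain∩loss fraction 0.494):

```r
library(markshift)

sim     <- simulate_epigenome(sim_config(seed = 42))
grid    <- tile_windows(sim$layout, window_size = 6000)
domains <- call_lost_domains(sim$peaks$sin3b$control, sim$peaks$sin3b$KO, grid)
corr    <- domain_correlation(sim$tracks$sin3b$control,
                              sim$tracks$hdac1$control, domains)
pre     <- gene_regions(sim$genes, promoter_flank = 3000)
ses     <- call_super_enhancers(sim$peaks$h3k27ac$KO, sim$tracks$h3k27ac$KO,
                                unlist(pre$Pro, use.names = FALSE), sim$genes)
regions <- gene_regions(sim$genes, promoter_flank = 3000, ses = ses)
gain    <- region_gain(sim$tracks$h3k27ac$control, sim$tracks$h3k27ac$KO, regions)
loss    <- region_gain(sim$tracks$hdac1$control, sim$tracks$hdac1$KO, regions)
de      <- de_test(sim$counts, fc_cutoff = 1.3, alpha = 0.05)

integration_report(de, gain, loss, correlation = corr, domains = domains)
#> IntegrationReport
#>   binding domains called: 50
#>   domain co-occupancy: r = 0.911 (p = 4.31e-20, n = 50)
#>   up-regulated DEGs: 54 of 500 genes
#>   up-DEGs vs Pro-gain: |gain| = 80, overlap = 31, p = 5.76e-14
#>   up-DEGs vs SE-gain: |gain| = 30, overlap = 12, p = 1.47e-05
#>   up-DEGs vs GB-gain: |gain| = 0, overlap = 0, p = 1
#>   up-DEGs vs All-gain: |gain| = 80, overlap = 31, p = 5.76e-14
#>   Pro H3K27Ac-gain vs HDAC1-loss: 40/80 gained genes also lost (50.00%)
```

Reading the output: all 50 planted domains are recovered; the SIN3B–HDAC1
correlation over only 50 domains is 0.911 (it converges to the planted
0.87 as the domain count grows); 54 of the 60 planted up-genes pass the
FC ≥ 1.3, p < 0.05 screen; promoter and super-enhancer acetylation gains
are strongly enriched among the up-DEGs while gene-body gains are absent;
and half of the acetylation-gained genes also lost HDAC1 — the planted
fraction was 0.494.

The same pipeline runs over files (BED peaks, bedGraph coverage, BED6
genes, a counts TSV) via `run_pipeline()` or the command-line wrapper:

```sh
Rscript inst/cli/markshift.R all --outdir run1 --seed 42
```

which writes `domains.bed`, `correlation.tsv`, `se.bed`, per-mark
`region_gain_*.tsv`, `de.tsv` and `report.{tsv,json}`.

## Scope

Peak calling, read alignment, motif discovery and functional (GO/GSEA)
enrichment are out of scope: peaks and coverage come in as BED/bedGraph,
and the report's gene sets are the hand-off point to enrichment tools.
See the methods vignette (`vignettes/markshift-methods.Rmd`) for the
model, parameter and calibration details.
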