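---
title: "markshift: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{markshift: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`markshift` analyses how knocking out a chromatin factor redistributes a
histone mark and reshapes transcription. This vignette records the model
behind each stage, the tunable parameters and why their defaults are what
they are, what the synthetic-data generator does and does not emulate, and
the design decisions that were genuinely open.

## Coordinate conventions

All I/O uses BED conventions (0-based, half-open, tab-separated); in
memory, intervals live in `GRanges` (1-based, closed) bound to a
`GenomeLayout` so out-of-bounds coordinates fail at read time. GTF gene
records (1-based, inclusive) are converted on read. Strand is optional
(`*`/`.`) for peaks and domains and mandatory for genes, whose
transcription start site (TSS) is the strand-aware 5' end: the 0-based
`start` for `+` genes, `end − 1` for `−` genes.

## Knockout-lost binding domains

The genome is tiled with windows of `window_size` (default 6000 bp, the
domain scale of interest) every `step` basepairs. The default `step`
equals the window size: non-overlapping tiling gives non-redundant
domains and an unambiguous merge; a half-window step is available via the
`step` config key for users who want a denser scan. A window is *lost*
when at least one control peak overlaps it by ≥ 1 bp and no knockout peak
overlaps it — a binary presence/absence criterion, matching the notion of
peaks unique to the control condition; it is deliberately not a
signal-fold-change rule, which would entangle domain calling with
normalization. Overlapping or book-ended lost windows merge into domains;
the provenance of every domain (its contributing window indices) is kept.

Requiring only partial overlap (≥ 1 bp) rather than full containment of
the control peak is a judgement call: it makes the call monotone in the
peak sets and symmetric between control and knockout evidence, at the cost
of domains extending one window beyond a boundary-straddling peak.

## Co-occupancy correlation

Per domain, both tracks are quantified as
`RPKM = count / ((length/10³) · (total_mapped/10⁶))` where `count` is the
sum of per-base coverage and `total_mapped` the track's library size
(taken from the bedGraph's total signal mass when not supplied). The
correlation is Pearson's r between `log10(RPKM + ε)` values with a
two-sided p from the t transform with n − 2 df (`stats::cor.test`). The
pseudocount ε defaults to 0.01 RPKM — small enough to be invisible on
occupied domains, large enough to keep zero-signal domains finite. With
ε = 0 the statistic is exactly invariant to rescaling either library
size (the log shift cancels in Pearson r); with the default ε that holds
to numerical noise on occupied domains. Fewer than 3 domains is an error;
a zero-variance side is reported as an explicit `undefined` flag rather
than a propagated `NaN`.

## Gene regions and super-enhancers

For each gene: `Pro = [TSS − f, TSS + f)` with `f = promoter_flank`
(default 3000 bp, matching the TSS ± 3 kb window used for signal
heatmaps); `GB` is the gene interval minus `Pro`; `All` is their union
(whether a "whole gene" should include the promoter flank is ambiguous;
including it keeps `Pro ⊆ All` and makes `All` the maximal per-gene
region); `SE` holds assigned super-enhancer intervals.

Super-enhancers are called ROSE-style, since the field has no single
definition: peaks overlapping promoters are removed; survivors are
stitched when separated by ≤ `stitch_gap` (12.5 kb, the community
default); stitched regions are ranked by total signal; with rank and
signal scaled to [0, 1], the cutoff is the point of the curve farthest
below the unit-slope diagonal, i.e. where `x − y` is maximal. For a
convex rank curve this is exactly the classic tangent-slope-1 knee, but
the max-gap form is robust to local jitter from counting noise (a strict
slope scan can terminate early when two adjacent high-rank regions happen
to have near-equal signal). A flat or concave curve (no point below the
diagonal, or zero signal range) yields zero super-enhancers; fewer than 3
stitched regions yields zero with a warning. Each SE is assigned to the
gene with the nearest TSS within `se_assignment_radius` (50 kb default;
there is no principled universal value, so it is a config key). The
calling is rank-based and therefore invariant under uniform scaling of
the signal. The knockout condition's peaks and track are used for
ranking, since the gained SEs are the objects of interest.

## Mark gain and loss

Per gene and region class, signal is summed across the class's intervals
in both conditions and converted to RPKM with each track's own library
size; then `FC = (RPKM_KO + ε)/(RPKM_ctrl + ε)` with ε = 0.1 RPKM
(bounds the FC of near-empty regions). *Gained* means `FC ≥ threshold`
with the boundary included — the threshold is 1.3 by convention of this
analysis style — and *lost* means `FC ≤ 1/threshold`; the two are
mutually exclusive by construction. Genes with an empty region in a class
(e.g. a gene shorter than the promoter flank has no gene body) are
omitted from that class with a notice.

## Differential expression

`TPM_gi = 10⁶ (c_gi/L_g) / Σ_g (c_gi/L_g)`, so every sample sums to 10⁶.
The fold change is computed on condition-mean TPM with a 1-TPM
pseudocount; the p-value comes from a two-sample t-test on
`log2(TPM + 1)`. The default is the **pooled-variance (Student) test**,
not Welch's: with the tiny, equal-size replicate groups this design
targets (3 vs 3), Welch's reduced degrees of freedom make it measurably
conservative — in a 10,000-gene null simulation it rejects ~3.5% at
α = 0.05 versus ~5.0% for the pooled test — and with equal group sizes
and similar variances the pooled test is the calibrated choice. Welch
remains available (`var_equal = FALSE`). No multiple-testing correction
is applied by default, matching the plain `p < 0.05` screen this
analysis style uses; Benjamini–Hochberg is available behind the `adjust`
flag. A gene is *up* when `FC ≥ fc_cutoff` (1.3 default; 1.5 is the other
conventional choice) **and** `p < alpha` (0.05), *down* symmetrically.
Genes constant within both groups get `p = 1` and `ns`. This stage is
deliberately a thresholding screen, not a negative-binomial GLM with
dispersion shrinkage; the package's contribution is the integration, and
the screen's operating characteristics are validated by simulation.

## Integration

Gene-set overlaps are reported with both directional fractions
(`|∩|/|A|` and `|∩|/|B|`) to remove denominator ambiguity, plus a
one-sided hypergeometric enrichment p, `P(X ≥ |∩|)`, for
over-representation. The universe defaults to all genes in the
annotation — not only expressed genes — because the mark-gain sets are
defined on the full annotation; an expressed-only universe can be passed
explicitly. The headline "fraction of mark-gained genes that also lost
the second mark" uses the gain set as denominator and the promoter class
by default.

## The synthetic epigenome

`simulate_epigenome()` is a first-class, deterministic generator: one
seed, one output (byte-identical files via `write_fixture()`). Its
defaults define the reference conditions used throughout the tests:
2 chromosomes × 10 Mb, 500 genes, 50 planted 6-kb lost domains, target
co-occupancy r = 0.87, planted gain∩loss fraction 0.494, 60 up-genes at
log2FC = 1, negative-binomial dispersion 0.02 (a typical clonal cell-line
value; smaller than patient-cohort dispersions), 3 replicates per
condition.

Placement is slot-based: the genome is divided into equal slots, one per
planted entity (gene, domain, shared peak), shuffled and jittered. Margins
guarantee that planted domains sit ≥ 2 domain-lengths apart (so called
domains never merge across plants), that enhancer zones of neighbouring
slots stay > 12.5 kb apart (so stitching cannot bleed across genes), and
that each super-enhancer's own TSS is nearer than any neighbour's (so
assignment is unambiguous). This is an idealisation: real genomes have
clustered genes, nested regulatory elements and domains overlapping
promoters, and the generator makes no attempt to emulate that — passing
tests demonstrate the pipeline's correctness on well-separated structure,
not robustness to every pathological overlap.

Coverage is sampled as reads per 100-bp bin, Poisson around piecewise-
constant per-base rate profiles (background plus feature enrichments),
stored run-length encoded; library sizes are the realised read totals.
Latent domain signals are log-normal: SIN3B `S ~ N(log10 20, 0.25)` per
bp, and HDAC1 `H = μ_H + (S − μ_S) + ε` with
`Var(ε) = Var(S)·(1 − r²)/r²`, which makes the population correlation of
the latent log signals exactly the configured `cooccupancy_r`; counting
noise over a 6-kb domain is negligible beside the latent spread, so the
measured per-domain correlation converges to the target (checked at 5000
domains within ± 0.03). The knockout H3K27Ac background is scaled down by
exactly the planted gain mass so the two libraries match in expectation —
the mark redistributes rather than accumulates — keeping the RPKM fold
change of unperturbed genes centred at 1. HDAC1 compensation is
deliberately omitted (the knockout genuinely loses occupancy); the
resulting ~12% library shrinkage inflates unperturbed HDAC1 fold changes
to ~1.13, comfortably below the 1.3 gain threshold, and is itself a
useful realism check. The gain∩loss overlap is exact by construction:
`round(frac · |gain|)` gain genes are drawn into the HDAC1-loss set.

## Problem sizes and numerical checks in the test suite

The suite validates: domain calling against an independent brute-force
window scan on 100 random 1-Mb genomes plus 30 two-chromosome genomes;
domain recovery on the default fixture (recall and precision at per-domain
Jaccard ≥ 0.5, both 1.0 in practice); co-occupancy recovery on a
2 × 160 Mb genome with 5000 domains (± 0.03); the end-to-end gain∩loss
fraction (± 0.05); DE calibration on 10,000 null genes (rejection rate in
[0.04, 0.06]) and power on 5,000 genes with 400 planted (recall ≥ 0.8);
TPM column sums (relative 10⁻⁶); quantification additivity over random
interval partitions; hypergeometric p against exhaustive subset
enumeration on universes up to 20; super-enhancer knee behaviour on
constructed curves; and byte-identical regeneration of fixtures and
reports from the same seed. These sizes were chosen to make the checked
statistics' sampling noise small relative to the stated tolerances.

## Known limitations

* Coverage tracks are taken as given; fragment-length handling, GC bias
  and mappability are upstream concerns.
* The binary lost-window criterion ignores peak strength; a
  fold-change-based variant would need matched normalization.
* The DE screen uses raw p-values and a t-test on log TPM; for real
  cohort data with few replicates and outliers, a shrinkage-based NB
  model is the better tool, and the package's gene sets can be swapped
  for its output.
* Super-enhancer calling inherits ROSE's arbitrariness (stitch gap,
  promoter exclusion, knee rule); all constants are exposed, and the SE
  gene sets should be read with that in mind.
* The hypergeometric enrichment assumes exchangeable genes; it ignores
  gene length, expression level and chromatin-domain autocorrelation,
  all of which can inflate enrichment on real data.
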