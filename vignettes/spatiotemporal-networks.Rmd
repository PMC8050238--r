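---
title: "Spatiotemporal co-expression PPI networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal co-expression PPI networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis

stnet asks when and where, during brain development, the protein products of
a query gene set (typically a CNV locus such as 7q11.23) act together. The
reasoning is that a physical protein–protein interaction can only be
functional where both partners are expressed, so an interaction corroborated
by strong co-expression within a developmental window is evidence that the
interaction is active there.

The pipeline:

1. **Ingest.** A linear-scale (RPKM-like) genes × samples expression matrix
   is filtered to brain-expressed genes; a physical interactome is cleaned
   (self-interactions, duplicate and orientation-swapped rows removed) and
   restricted to brain-expressed genes, giving the brain-expressed
   interactome (HI~BE~). The query list is reduced to its brain-expressed
   members, with every removal recorded.
2. **Partition.** Samples map into developmental-period × brain-region
   intervals (default 8 × 4 = 32 keys). Intervals with fewer than
   `min_samples` samples are excluded with a reason, which operationalizes
   "insufficient data" exclusions as a rule rather than a special case.
3. **Interval networks.** Within each retained interval, an interactome edge
   is kept when the Spearman correlation of its two genes across the
   interval's samples exceeds `rho_threshold` (strictly, by default).
4. **Enrichment scan.** Per interval, the fraction of co-expressed pairs in
   the query universe (HI~BE~ edges touching a query gene) is tested against
   three control pair universes with a one-sided Fisher's exact test:
   (i) HI~BE~ edges touching a control set of common-CNV genes,
   (ii) all query × brain-expressed gene pairs (no interaction required),
   (iii) all HI~BE~ edges. p-values are Benjamini–Hochberg corrected across
   intervals within each control comparison; an interval is *significant*
   when q < α against all three controls, and intervals clearing exactly two
   are reported separately (they are biologically interesting but weaker
   calls).
5. **Topology.** Significant networks are compared by query-node and
   partner-node overlap, and by a one-way ANOVA on per-gene partner ratios
   (unique-to-A, unique-to-B, shared, each over the partner union so they
   sum to 1). Driver genes are ranked by diameter-normalized radiality,
   `Rad(v) = (D + 1 - mean(d(v, u))) / D` per connected component.
6. **Gene sets.** Network proteins are tested for over-representation in
   user-supplied GMT collections with the cumulative hypergeometric
   distribution, plus the flat-term filter p < 0.01, count ≥ 3, enrichment
   factor > 1.5 (strict inequalities).

## Parameters that matter

| parameter | default | units / scale | rationale |
|---|---|---|---|
| `log2_intensity_min` | 0.4 | log2(RPKM + 1) | floor below which a gene is called unexpressed |
| `cv_min` | 0.07 | sd/mean, linear | removes near-constant genes that cannot carry rank signal |
| `rho_threshold` | 0.5 | Spearman ρ | edge-retention cutoff; strict `>` |
| `min_samples` | 6 | samples/interval | a rank correlation cutoff of 0.5 is close to noise below ~6 observations |
| `alpha` | 0.05 | q-value | significance on BH-corrected p |
| `background_n` | 20240 | genes | gene-set background; a measured-universe size, kept as explicit configuration rather than derived from the expression matrix |

Two readings of the expression filter are possible (drop a gene failing
*either* criterion or only one failing *both*); the package defaults to the
"either" reading — both filters target uninformative genes — and exposes
`filter_logic = "and"` for the conservative reading. The pseudo-count in
`log2(x + 1)` is the standard RPKM convention and configurable.

## Numerical choices

- **Spearman with midranks.** All pair correlations go through one kernel:
  rows are average-rank transformed, centred and scaled to unit sum of
  squares, so a pair's correlation is a dot product. This makes scanning
  thousands of pairs per interval cheap and gives one well-defined tie
  policy. A vector with fewer than two distinct values has no rank signal;
  its pairs are "not co-expressed" (never an error) and stay in fraction
  denominators — they are real candidate pairs that failed to show
  co-expression.
- **Fisher's exact test** comes from `stats::fisher.test`; the reported odds
  ratio is the sample cross-product ratio (`Inf` when the control cell is
  empty), not the conditional MLE.
- **BH** is `stats::p.adjust(method = "BH")`; the FDR family is the 31
  intervals within one control comparison (the per-control curves are the
  natural unit of reading), with a `joint` switch for the 93-test family.
- **Radiality** is computed per connected component; singleton components
  get 0 by convention. Cytoscape-style plugins use this diameter-normalized
  form; whatever tool produced any particular published table, the formula
  here is documented and unit-locked, so results are self-consistent.
  Driver ties break by degree, then symbol, deterministically.
- **ANOVA** on partner ratios uses three groups (unique-to-A, unique-to-B,
  shared; one observation per query gene). The two-group reading
  (unique vs shared) is available via `grouping = "two_group"`.

## What the simulator emulates — and what it does not

`sim_config()` defaults define the study conditions: a 8 × 4 interval grid
with 6 samples per interval, one interval deliberately underfilled (1
sample) to exercise the sparse-exclusion rule, 21 query genes with 3 planted
partners each, and a planted hub (the first query gene interacts with every
partner). Log2 expression is `baseline_g + beta * f_s * m_g + noise`, with a
single per-sample latent factor `f_s ~ N(0,1)` active only in the planted
intervals (default `P1R1`, `P1R3`) and `m_g` indicating module membership.
One shared factor per interval — rather than per-pair factors — produces
exactly the block co-expression structure the fraction statistic is designed
to detect, with one interpretable strength knob (`beta`, default 3;
`noise_sd` default 0.3).

The simulator emulates the statistical structure the analysis assumes, not
biology: marginals are log-normal, noise is homoscedastic and independent
across genes, the interactome is Erdős–Rényi plus planted edges, and there
is no confounding between region and period. Passing recovery tests
therefore shows the pipeline detects the signal it defines — not that real
developmental transcriptomes satisfy these assumptions.

Null gene sets are drawn uniformly from the simulated gene universe so the
hypergeometric null holds exactly, and their sizes vary (25–75) because
pooled exact p-values from a single table configuration are too discrete for
a Kolmogorov–Smirnov uniformity check to be meaningful. Even with varying
sizes, residual discreteness leaves the pooled KS p-value mildly
anti-conservative, so occasional small KS p-values at particular seeds
reflect granularity of the exact test, not miscalibration of the
enrichment code.

## Calibration behaviour of the scan

The test suite runs the full scan on 50 null simulations (`beta = 0`). No
interval is ever called significant against all three controls, which is the
operating characteristic that matters for downstream claims. The raw
proportion of interval × control tests with p < 0.05 sits near 0.02–0.03,
i.e. *below* a naive binomial band around 0.05, for two structural reasons:
Fisher's exact test is conservative on discrete 2 × 2 tables at these
universe sizes, and the control universes overlap the query universe (every
query edge is also an `all_ppi` edge and a query × brain pair), so a chance
excursion in the test count drags the control count with it. Both effects
are intrinsic to the design — the controls are deliberately supersets or
near-supersets — and the suite asserts the naive band anyway so the
conservatism is measured, not hidden.

## Problem sizes

Simulation batteries use 240 genes, 21 query genes, 63 partners, a 0.02
background edge density and 50 replicate seeds per battery; these sizes give
stable proportions (binomial se ≈ 0.04 at 50 seeds) while keeping a full
suite run in minutes on one core. Real-data runs scale the same code to
~15,000 genes and ~240,000 interactions; the pair-correlation kernel is
vectorized per interval, and `query_all_brain` universes are computed
exactly (a `max_pairs`-style subsample is deliberately not implemented
silently anywhere — fractions are always over the full universe).

## Known limitations

- The authoritative stage→period and structure→region maps for published
  analyses live in supplementary materials of the respective studies; the
  shipped `default_scheme()` is a clearly-labelled surrogate (standard
  sixteen structure acronyms, uniform period boundaries) and real-data runs
  should supply their own scheme file.
- Published real-data p-values depend on specific BrainSpan/BioGRID releases
  and the exact interval scheme; they are not desk-scale reproduction
  targets, and the package does not attempt to match them numerically.
- Term clustering by membership similarity (as done by some web enrichment
  tools) is out of scope; results are flat filtered term lists.
- Whether the fraction denominator should be per-interval-measurable or
  global is ambiguous in the field; the package uses the global universe
  with unmeasurable pairs logged, and this is the documented default rather
  than a switch hidden in code.
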