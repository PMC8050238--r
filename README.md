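# stnet — spatiotemporal co-expression PPI network analysis

Physical protein–protein interactions are static catalogue entries, but the
proteins they connect are made at particular times in particular tissues. For
a gene set of interest — typically a CNV locus such as 7q11.23, whose
deletion and duplication are associated with neurodevelopmental disorders —
stnet asks *when and where during brain development the set's interactions
are plausibly active*, by corroborating each physical interaction with
co-expression inside developmental-period × brain-region intervals.

For interval *t* with sample set *S(t)*, an interactome edge *(g, h)* is
retained when the Spearman correlation ρ of the two genes' expression over
*S(t)* exceeds 0.5. The headline statistic per interval is the co-expressed
fraction of the query pair universe,

    f_Q(t) = #{pairs in Q with ρ > 0.5 in t} / |Q|,

tested one-sidedly against the same fraction in three control universes
(common-CNV PPI pairs; all query × brain-expressed pairs; all brain-expressed
PPI pairs) with Fisher's exact test and Benjamini–Hochberg correction across
intervals. Intervals significant against **all three** controls feed the
downstream analyses: node overlap across networks, a one-way ANOVA on
per-gene partner ratios (unique/shared, denominated by the partner union),
driver-gene ranking by diameter-normalized radiality
Rad(v) = (D + 1 − mean d(v,·)) / D, and hypergeometric gene-set
over-representation against a configurable background (default 20,240
genes) with the p < 0.01 / count ≥ 3 / factor > 1.5 term filter.

A fully deterministic synthetic-data generator plants a latent-factor
co-expression module (query genes + partners, with a designated hub) into
chosen intervals of an 8 × 4 grid, so every pipeline stage — including its
calibration under the null — is testable without downloads.

## Worked example

Simulate a study with signal planted in P1R1 and P1R3, then run the full
pipeline from its config file:

```r
library(stnet)
dir <- tempfile()
write_fixture_bundle(sim_config(seed = 42), dir)
run <- stn_run(file.path(dir, "config.yaml"))
print(run)
#> stn_run
#>   brain-expressed genes: 240 (removed 0)
#>   interactome: 238 nodes, 670 edges
#>   query genes: 21
#>   intervals: 31 retained, 1 excluded
#>   significant intervals: P1R1, P1R3
#>   driver in P1R1: G0001 (radiality 0.936)
#>   driver in P1R3: G0001 (radiality 0.943)
```

The two planted intervals — and only those — survive the three-control
Fisher/BH screen, and the planted hub G0001 tops radiality in both
recovered networks. The scan table shows why:

```r
summary(run$scan)
#> Top interval x control tests by q:
#>  interval         control fraction_test fraction_ctrl odds_ratio        p        q
#>      P1R1  common_cnv_ppi         0.712         0.108      20.47 7.46e-24 2.31e-22
#>      P1R3  common_cnv_ppi         0.731         0.129      18.32 2.04e-23 3.15e-22
#>      P1R3         all_ppi         0.731         0.355       4.93 9.46e-22 2.93e-20
#>      ...
```

In the planted intervals ~71–73% of query pairs are co-expressed against a
~11–42% control baseline; elsewhere the fractions are statistically
indistinguishable. `stn_run(config, out = "results/")` additionally writes
`enrichment.tsv`, per-interval edge lists, `topology.tsv`, `overlap.tsv`,
`anova.tsv`, `genesets.tsv` and a reproducible run report.

Real data drop into the same entry points: an expression TSV plus sample
metadata (stage, structure), a BioGRID tab2 interaction file, plain-text
gene lists, GMT collections, and a period/region scheme YAML
(`default_scheme()` is a labelled surrogate — supply the authoritative
scheme for real runs).

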