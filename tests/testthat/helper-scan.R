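## Shared end-to-end driver for calibration/recovery suites: simulate one
## study, clean it, and run the enrichment scan.
scan_simulated <- function(seed, beta = 3, min_samples = 6L) {
  cfg <- sim_config(seed = seed, beta = beta)
  sim <- simulate_study(cfg)
  hi <- build_brain_interactome(sim$interactions,
                                rownames(sim$expression$values))
  part <- exclude_sparse_intervals(
    assign_samples(sim$expression$samples, sim$truth$scheme), min_samples)
  scan <- run_enrichment_scan(sim$expression, part, hi,
                              query_gene_set(sim$truth$query_genes),
                              sim$truth$common_cnv_genes)
  list(config = cfg, sim = sim, interactome = hi, partition = part,
       scan = scan, truth = sim$truth)
}
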