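#' Simulation configuration
#'
#' Parameters of the synthetic study generator. The generator plants a
#' co-expression module — the query genes plus their interaction partners —
#' whose log2 expression shares a per-sample latent factor inside the
#' planted intervals only, on top of independent Gaussian noise. The first
#' query gene is the planted hub: it interacts with every partner gene, so
#' it should dominate radiality in recovered networks.
#'
#' @param n_genes total genes; default 240.
#' @param n_query query (CNV-locus) genes; default 21.
#' @param n_partners_per_query planted partners per query gene; default 3.
#' @param periods,regions grid dimensions; default 8 x 4. With the default
#'   dimensions the metadata uses the standard stage/structure codes of
#'   [default_scheme()]; otherwise a generic one-stage-per-period scheme is
#'   generated.
#' @param samples_per_interval samples per interval; default 6.
#' @param sparse_interval interval deliberately left with `sparse_n` samples
#'   to exercise sparse-interval exclusion; default `"P3R4"`.
#' @param sparse_n samples in the sparse interval; default 1.
#' @param planted_intervals intervals carrying the latent factor; default
#'   `c("P1R1", "P1R3")`.
#' @param beta latent-factor strength on the log2 scale; default 3. `beta =
#'   0` gives a null simulation.
#' @param noise_sd log2-scale noise standard deviation; default 0.3.
#' @param baseline_log2_mean,baseline_log2_sd per-gene baseline log2
#'   expression distribution; defaults 3 and 1.
#' @param background_edge_prob background interactome edge probability;
#'   default 0.02.
#' @param common_cnv_size size of the control CNV gene list; default 20.
#' @param n_dirty_duplicates,n_dirty_swapped,n_dirty_selfloops,n_dirty_nonphysical
#'   dirt rows injected into the interaction table to exercise cleaning.
#' @param enriched_fraction fraction of partner genes seeded into the
#'   "enriched" gene set; default 0.5.
#' @param enriched_set_size size of the enriched set; default 60.
#' @param n_null_sets number of null gene sets; default 5.
#' @param null_set_sizes inclusive size range for null sets; default
#'   `c(25, 75)` (varying sizes keep the pooled null p-value distribution
#'   close to continuous).
#' @param seed integer seed; the generator is fully deterministic given
#'   (config, seed).
#' @return list of class `stn_sim_config`.
#' @export
sim_config <- function(n_genes = 240L, n_query = 21L, n_partners_per_query = 3L,
                       periods = 8L, regions = 4L, samples_per_interval = 6L,
                       sparse_interval = "P3R4", sparse_n = 1L,
                       planted_intervals = c("P1R1", "P1R3"),
                       beta = 3, noise_sd = 0.3,
                       baseline_log2_mean = 3, baseline_log2_sd = 1,
                       background_edge_prob = 0.02, common_cnv_size = 20L,
                       n_dirty_duplicates = 4L, n_dirty_swapped = 3L,
                       n_dirty_selfloops = 3L, n_dirty_nonphysical = 5L,
                       enriched_fraction = 0.5, enriched_set_size = 60L,
                       n_null_sets = 5L, null_set_sizes = c(25L, 75L),
                       seed = 1L) {
  cfg <- as.list(environment())
  n_partners <- n_query * n_partners_per_query
  if (n_query + n_partners > n_genes)
    stopf("n_query + planted partners (%d) exceeds n_genes (%d)",
          n_query + n_partners, n_genes)
  stopifnot(beta >= 0, noise_sd > 0,
            background_edge_prob >= 0, background_edge_prob <= 1)
  if (common_cnv_size > n_genes - n_query - n_partners)
    stopf("common_cnv_size (%d) exceeds the %d non-module genes",
          common_cnv_size, n_genes - n_query - n_partners)
  grid <- as.vector(outer(paste0("P", seq_len(periods)),
                          paste0("R", seq_len(regions)), paste0))
  bad <- setdiff(c(planted_intervals, sparse_interval), grid)
  if (length(bad))
    stopf("interval label(s) outside the %dx%d grid: %s", periods, regions,
          paste(bad, collapse = ", "))
  structure(cfg, class = "stn_sim_config")
}

sim_scheme <- function(config) {
  if (config$periods == 8L && config$regions == 4L) return(default_scheme())
  list(periods = stats::setNames(as.list(seq_len(config$periods)),
                                 paste0("P", seq_len(config$periods))),
       regions = stats::setNames(as.list(paste0("S", seq_len(config$regions))),
                                 paste0("R", seq_len(config$regions))))
}

sim_gene_names <- function(config) sprintf("G%04d", seq_len(config$n_genes))

#' Generate synthetic developmental expression data
#'
#' Log2 expression of gene g in sample s is
#' `baseline_g + beta * f_s * m_g + eps`, where `f_s ~ N(0, 1)` is drawn per
#' sample in planted intervals only (0 elsewhere), `m_g` is 1 for module
#' genes (query + partners) and 0 otherwise, and `eps ~ N(0, noise_sd)`.
#' Values are exported on the linear scale (`2^x`).
#'
#' @param config an [sim_config()].
#' @return list with `expression` (`stn_expression`) and `truth` (class
#'   `stn_truth`: planted intervals and pairs, query/partner/hub genes,
#'   common-CNV control genes, module genes, the scheme, seed).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "stn_sim_config"))
  scheme <- sim_scheme(config)
  genes <- sim_gene_names(config)
  n_partners <- config$n_query * config$n_partners_per_query
  query <- genes[seq_len(config$n_query)]
  partners <- genes[config$n_query + seq_len(n_partners)]
  module <- c(query, partners)

  ## sample sheet: cycle through the period's stages / region's structures
  rows <- list()
  for (p in names(scheme$periods)) for (r in names(scheme$regions)) {
    key <- paste0(p, r)
    n <- if (key == config$sparse_interval) config$sparse_n
         else config$samples_per_interval
    if (n == 0L) next
    stages <- scheme$periods[[p]]
    structs <- scheme$regions[[r]]
    rows[[key]] <- data.frame(
      interval = key,
      stage = stages[((seq_len(n) - 1L) %% length(stages)) + 1L],
      structure = structs[((seq_len(n) - 1L) %% length(structs)) + 1L])
  }
  samples <- do.call(rbind, rows)
  samples$sample_id <- sprintf("S%04d", seq_len(nrow(samples)))
  rownames(samples) <- NULL

  withr::with_seed(config$seed, {
    baseline <- stats::rnorm(config$n_genes, config$baseline_log2_mean,
                             config$baseline_log2_sd)
    f <- ifelse(samples$interval %in% config$planted_intervals,
                stats::rnorm(nrow(samples)), 0)
    m <- as.numeric(genes %in% module)
    eps <- matrix(stats::rnorm(config$n_genes * nrow(samples),
                               sd = config$noise_sd),
                  nrow = config$n_genes)
    log2x <- baseline + config$beta * outer(m, f) + eps
    common_cnv <- sample(setdiff(genes, module), config$common_cnv_size)
  })
  values <- 2^log2x
  rownames(values) <- genes
  colnames(values) <- samples$sample_id

  partner_of <- split(partners, rep(seq_len(config$n_query),
                                    each = config$n_partners_per_query))
  planted <- rbind(
    do.call(rbind, lapply(seq_len(config$n_query), function(i)
      canonical_pairs(rep(query[i], config$n_partners_per_query),
                      partner_of[[i]]))),
    canonical_pairs(rep(query[1L], n_partners), partners))
  planted <- planted[!duplicated(pair_key(planted$a, planted$b)), , drop = FALSE]
  rownames(planted) <- NULL

  meta <- samples[, c("sample_id", "stage", "structure")]
  truth <- structure(
    list(planted_intervals = config$planted_intervals,
         planted_pairs = planted, query_genes = query,
         partner_genes = partners, hub_gene = query[1L],
         common_cnv_genes = common_cnv, module_genes = module,
         scheme = scheme, sparse_interval = config$sparse_interval,
         seed = config$seed),
    class = "stn_truth")
  list(expression = new_stn_expression(values, meta), truth = truth)
}

#' Generate a synthetic interaction table
#'
#' Background edges appear independently with `background_edge_prob`; every
#' planted query-partner pair (including hub edges) is guaranteed present.
#' Configurable dirt — duplicate rows, orientation-swapped duplicates,
#' self-loops and non-"physical" rows — is appended so reader/cleaner code
#' paths get exercised; the dirt counts are recorded in the `dirt`
#' attribute.
#'
#' @param config an [sim_config()].
#' @param truth the `stn_truth` from [generate_expression()].
#' @return data.frame with columns `gene_a`, `gene_b`, `system_type`, ready
#'   for [build_brain_interactome()] (or for writing in the tab2 dialect).
#' @export
generate_interactome <- function(config, truth) {
  stopifnot(inherits(config, "stn_sim_config"), inherits(truth, "stn_truth"))
  genes <- sim_gene_names(config)
  all_pairs <- t(utils::combn(genes, 2L))
  withr::with_seed(config$seed + 1L, {
    on <- stats::runif(nrow(all_pairs)) < config$background_edge_prob
    bg <- all_pairs[on, , drop = FALSE]
    edges <- rbind(data.frame(a = bg[, 1L], b = bg[, 2L]),
                   truth$planted_pairs)
    edges <- edges[!duplicated(pair_key(edges$a, edges$b)), , drop = FALSE]
    tab <- data.frame(gene_a = edges$a, gene_b = edges$b,
                      system_type = "physical", stringsAsFactors = FALSE)
    pick <- function(n) tab[sample.int(nrow(tab), n, replace = TRUE), , drop = FALSE]
    dup <- pick(config$n_dirty_duplicates)
    sw <- pick(config$n_dirty_swapped)
    sw <- data.frame(gene_a = sw$gene_b, gene_b = sw$gene_a,
                     system_type = "physical")
    self <- data.frame(gene_a = sample(genes, config$n_dirty_selfloops),
                       gene_b = NA, system_type = "physical")
    self$gene_b <- self$gene_a
    nonphys <- pick(config$n_dirty_nonphysical)
    nonphys$system_type <- "genetic"
    out <- rbind(tab, dup, sw, self, nonphys)
    out <- out[sample.int(nrow(out)), , drop = FALSE]
  })
  rownames(out) <- NULL
  attr(out, "dirt") <- c(duplicates = config$n_dirty_duplicates,
                         swapped = config$n_dirty_swapped,
                         selfloops = config$n_dirty_selfloops,
                         nonphysical = config$n_dirty_nonphysical)
  attr(out, "n_clean_edges") <- nrow(tab)
  out
}

#' Generate synthetic gene-set collections
#'
#' One "enriched" set holding a configurable fraction of the planted partner
#' genes (plus random fillers) and several null sets drawn uniformly from
#' the gene universe, with varying sizes.
#'
#' @param config an [sim_config()].
#' @param truth the `stn_truth`.
#' @return an `stn_geneset_collection`.
#' @export
generate_gene_sets <- function(config, truth) {
  stopifnot(inherits(config, "stn_sim_config"), inherits(truth, "stn_truth"))
  genes <- sim_gene_names(config)
  withr::with_seed(config$seed + 2L, {
    n_seeded <- floor(config$enriched_fraction * length(truth$partner_genes))
    seeded <- sample(truth$partner_genes, n_seeded)
    fillers <- sample(setdiff(genes, truth$module_genes),
                      max(0L, config$enriched_set_size - n_seeded))
    sets <- list(enriched = c(seeded, fillers))
    for (i in seq_len(config$n_null_sets)) {
      sz <- sample(seq(config$null_set_sizes[1L], config$null_set_sizes[2L]), 1L)
      sets[[sprintf("null_%02d", i)]] <- sample(genes, sz)
    }
  })
  geneset_collection(sets, name = "simulated",
                     descriptions = stats::setNames(
                       c("planted partner-enriched set",
                         rep("uniform null set", config$n_null_sets)),
                       names(sets)))
}

#' Run the full generator in memory
#'
#' Convenience wrapper producing everything a pipeline run needs without
#' touching disk.
#'
#' @param config an [sim_config()].
#' @return list with `expression`, `truth`, `interactions` (raw table) and
#'   `gene_sets`.
#' @export
simulate_study <- function(config = sim_config()) {
  ge <- generate_expression(config)
  list(expression = ge$expression, truth = ge$truth,
       interactions = generate_interactome(config, ge$truth),
       gene_sets = generate_gene_sets(config, ge$truth))
}

#' Write a complete fixture bundle
#'
#' Generates a synthetic study and writes every input the pipeline needs:
#' expression and metadata TSVs, a tab2-dialect interaction TSV, query and
#' common-CNV gene lists, a GMT collection, the scheme YAML, a flat
#' key=value ground-truth manifest and a ready-to-run pipeline config.
#'
#' @param config an [sim_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a named list of written paths plus the `truth`.
#' @export
write_fixture_bundle <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_study(config)
  p <- function(f) file.path(outdir, f)

  write_expression(sim$expression, p("expression.tsv"), p("samples.tsv"))
  tab2 <- data.frame(sim$interactions$gene_a, sim$interactions$gene_b,
                     sim$interactions$system_type, check.names = FALSE)
  names(tab2) <- .tab2_cols
  utils::write.table(tab2, p("interactions.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(c("# simulated query (CNV locus) gene list",
               sim$truth$query_genes), p("query_genes.txt"))
  writeLines(c("# simulated common-CNV control gene list",
               sim$truth$common_cnv_genes), p("common_cnv_genes.txt"))
  write_gmt(sim$gene_sets, p("gene_sets.gmt"))
  write_scheme(sim$truth$scheme, p("scheme.yaml"))

  manifest <- c(
    sprintf("seed=%d", config$seed),
    sprintf("planted_intervals=%s",
            paste(sim$truth$planted_intervals, collapse = ",")),
    sprintf("hub_gene=%s", sim$truth$hub_gene),
    sprintf("query_genes=%s", paste(sim$truth$query_genes, collapse = ",")),
    sprintf("partner_genes=%s", paste(sim$truth$partner_genes, collapse = ",")),
    sprintf("common_cnv_genes=%s",
            paste(sim$truth$common_cnv_genes, collapse = ",")),
    sprintf("sparse_interval=%s", sim$truth$sparse_interval),
    sprintf("n_planted_pairs=%d", nrow(sim$truth$planted_pairs)))
  writeLines(manifest, p("truth.txt"))

  run_cfg <- list(
    expression = "expression.tsv", samples = "samples.tsv",
    interactions = "interactions.tsv", query_genes = "query_genes.txt",
    common_cnv_genes = "common_cnv_genes.txt", gene_sets = "gene_sets.gmt",
    scheme = "scheme.yaml",
    log2_intensity_min = 0.4, cv_min = 0.07, log2_offset = 1,
    filter_logic = "or", rho_threshold = 0.5, strict = TRUE,
    min_samples = 6L, alpha = 0.05, fdr_family = "per_control",
    background_n = config$n_genes, seed = config$seed)
  yaml::write_yaml(run_cfg, p("config.yaml"))

  paths <- list(expression = p("expression.tsv"), samples = p("samples.tsv"),
                interactions = p("interactions.tsv"),
                query_genes = p("query_genes.txt"),
                common_cnv_genes = p("common_cnv_genes.txt"),
                gene_sets = p("gene_sets.gmt"), scheme = p("scheme.yaml"),
                truth = p("truth.txt"), config = p("config.yaml"))
  stn_log("simulate", "fixture bundle written to %s", outdir)
  invisible(c(paths, list(ground_truth = sim$truth)))
}

#' Read a flat key=value manifest
#' @param path manifest path.
#' @return named character vector.
#' @export
read_manifest <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  stats::setNames(vapply(kv, function(x) paste(x[-1L], collapse = "="),
                         character(1L)),
                  vapply(kv, `[[`, character(1L), 1L))
}
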