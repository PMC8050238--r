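default_run_config <- function() {
  list(log2_intensity_min = 0.4, cv_min = 0.07, log2_offset = 1,
       filter_logic = "or", rho_threshold = 0.5, strict = TRUE,
       min_samples = 6L, alpha = 0.05, fdr_family = "per_control",
       alternative = "greater", background_n = 20240L, seed = 1L,
       exclusions = list())
}

#' Load a pipeline run configuration
#'
#' Reads a YAML key-value config (or accepts a list), fills defaults and
#' resolves relative input paths against the config file's directory.
#'
#' @param config path to a YAML file, or a named list.
#' @param base_dir directory for resolving relative paths (defaults to the
#'   config file's directory, or the working directory for list input).
#' @return a complete config list of class `stn_run_config`.
#' @export
load_run_config <- function(config, base_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    base_dir <- base_dir %||% dirname(config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  base_dir <- base_dir %||% "."
  cfg <- utils::modifyList(default_run_config(), config)
  path_keys <- c("expression", "samples", "interactions", "query_genes",
                 "common_cnv_genes", "gene_sets", "scheme")
  for (k in path_keys) {
    if (!is.null(cfg[[k]]) && !grepl("^(/|[A-Za-z]:)", cfg[[k]]))
      cfg[[k]] <- file.path(base_dir, cfg[[k]])
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stopf("alpha must lie in (0, 1)")
  structure(cfg, class = "stn_run_config")
}

#' Validate a pipeline configuration
#'
#' Dry-run checks: input files exist and parse, the scheme is disjoint, the
#' query list overlaps the expression matrix, and interval occupancy after
#' filtering. All problems are aggregated and reported together.
#'
#' @param config config path or list (see [load_run_config()]).
#' @return list of class `stn_validation`: `ok` (logical), `issues`
#'   (character) and `counts` (named list of stage counts).
#' @export
stn_validate <- function(config) {
  cfg <- load_run_config(config)
  issues <- character()
  counts <- list()
  note <- function(msg, ...) issues <<- c(issues, sprintf(msg, ...))

  for (k in c("expression", "samples", "interactions", "query_genes",
              "common_cnv_genes")) {
    if (is.null(cfg[[k]])) note("config: missing required input '%s'", k)
    else if (!file.exists(cfg[[k]])) note("%s file not found: %s", k, cfg[[k]])
  }
  if (length(issues))
    return(structure(list(ok = FALSE, issues = issues, counts = counts),
                     class = "stn_validation"))

  expr <- tryCatch(suppressMessages(read_expression(cfg$expression, cfg$samples)),
                   error = function(e) { note("expression: %s", conditionMessage(e)); NULL })
  scheme <- tryCatch(
    if (is.null(cfg$scheme)) default_scheme() else read_scheme(cfg$scheme),
    error = function(e) { note("scheme: %s", conditionMessage(e)); NULL })
  if (!is.null(scheme)) {
    tryCatch({ check_disjoint(scheme$periods, "period")
               check_disjoint(scheme$regions, "region") },
             error = function(e) note("scheme: %s", conditionMessage(e)))
  }
  if (!is.null(expr)) {
    counts$genes <- nrow(expr$values)
    counts$samples <- ncol(expr$values)
    filt <- suppressMessages(filter_brain_expressed(expr, run_filter_params(cfg)))
    counts$brain_genes <- nrow(filt$expression$values)
    query <- tryCatch(read_gene_list(cfg$query_genes),
                      error = function(e) { note("query list: %s", conditionMessage(e)); NULL })
    if (!is.null(query)) {
      counts$query_listed <- length(unique(query))
      kept <- intersect(unique(query), rownames(filt$expression$values))
      counts$query_expressed <- length(kept)
      if (!length(kept))
        note("query gene list has no overlap with the filtered expression matrix")
    }
    if (!is.null(scheme)) {
      part <- tryCatch(suppressMessages(
        exclude_sparse_intervals(assign_samples(filt$expression$samples, scheme),
                                 cfg$min_samples)),
        error = function(e) { note("partition: %s", conditionMessage(e)); NULL })
      if (!is.null(part)) {
        counts$intervals_retained <- length(part$intervals)
        counts$intervals_excluded <- length(part$excluded)
        counts$samples_unassigned <- length(part$unassigned)
      }
    }
  }
  tab <- tryCatch(suppressMessages(read_interactions(cfg$interactions)),
                  error = function(e) { note("interactions: %s", conditionMessage(e)); NULL })
  if (!is.null(tab)) counts$physical_interactions <- nrow(tab)
  structure(list(ok = !length(issues), issues = issues, counts = counts),
            class = "stn_validation")
}

#' @export
print.stn_validation <- function(x, ...) {
  if (x$ok) cat("OK\n") else {
    cat(sprintf("FAILED: %d issue(s)\n", length(x$issues)))
    for (i in x$issues) cat(sprintf("  - %s\n", i))
  }
  for (k in names(x$counts)) cat(sprintf("  %s: %s\n", k, x$counts[[k]]))
  invisible(x)
}

run_filter_params <- function(cfg) {
  expression_filter_params(cfg$log2_intensity_min, cfg$cv_min,
                           cfg$log2_offset, cfg$filter_logic)
}

run_coexpr_params <- function(cfg) {
  coexpression_params(cfg$rho_threshold, cfg$strict)
}

#' Run the full spatiotemporal network pipeline
#'
#' Orchestrates ingest, partitioning, the per-interval enrichment scan and
#' — for intervals significant against all three controls — network
#' construction, overlap, partner-ratio ANOVA, radiality-based driver
#' identification and gene-set enrichment. With `out` set, writes the
#' standard TSV outputs and a run report.
#'
#' @param config config path or list (see [load_run_config()]).
#' @param out optional output directory.
#' @return object of class `stn_run` containing the inputs after cleaning
#'   (`expression`, `interactome`, `query`, `partition`), the `scan`, the
#'   significant-interval `networks` and `subnetworks`, `overlap`, `anova`,
#'   `topology` (per-network centrality), `drivers`, `geneset_enrichment`
#'   and the resolved `config`.
#' @export
stn_run <- function(config, out = NULL) {
  cfg <- load_run_config(config)
  val <- stn_validate(cfg)
  if (!val$ok)
    stopf("configuration invalid:\n%s", paste("  -", val$issues, collapse = "\n"))

  stn_log("run", "ingest")
  expr_raw <- read_expression(cfg$expression, cfg$samples)
  filt <- filter_brain_expressed(expr_raw, run_filter_params(cfg))
  expr <- filt$expression
  brain_genes <- rownames(expr$values)
  tab <- read_interactions(cfg$interactions)
  interactome <- build_brain_interactome(tab, brain_genes)
  exclusions <- unlist(cfg$exclusions) %||% character()
  query <- load_query_genes(cfg$query_genes, exclusions, brain_genes)
  control_cnv <- read_gene_list(cfg$common_cnv_genes)

  stn_log("run", "partition")
  scheme <- if (is.null(cfg$scheme)) default_scheme() else read_scheme(cfg$scheme)
  partition <- exclude_sparse_intervals(assign_samples(expr$samples, scheme),
                                        cfg$min_samples)

  stn_log("run", "enrichment scan over %d intervals", length(partition$intervals))
  params <- run_coexpr_params(cfg)
  scan <- run_enrichment_scan(expr, partition, interactome, query, control_cnv,
                              params = params, alpha = cfg$alpha,
                              fdr_family = cfg$fdr_family,
                              alternative = cfg$alternative)

  networks <- list(); subnets <- list(); topology <- list(); drivers <- list()
  overlap <- NULL; anova <- NULL; genesets <- NULL
  if (length(scan$significant)) {
    stn_log("run", "topology on %d significant interval(s)",
            length(scan$significant))
    for (k in scan$significant) {
      networks[[k]] <- build_interval_network(interactome, expr,
                                              partition$intervals[[k]],
                                              params, key = k)
      subnets[[k]] <- extract_query_subnetwork(networks[[k]], query,
                                               include_partner_partner = TRUE)
      if (nrow(subnets[[k]]$edges)) {
        topology[[k]] <- radiality(subnets[[k]])
        drv <- tryCatch(identify_driver(topology[[k]], query$genes),
                        error = function(e) NULL)
        if (!is.null(drv)) drivers[[k]] <- drv
      }
    }
    if (length(subnets) >= 2L) {
      overlap <- network_overlap(subnets,
                                 catalog_query = length(query$genes) +
                                   nrow(query$excluded))
      keys <- names(subnets)
      anova <- list()
      for (i in seq_len(length(keys) - 1L)) for (j in seq(i + 1L, length(keys))) {
        cmp <- tryCatch(
          compare_networks_anova(subnets[[keys[i]]], subnets[[keys[j]]], query),
          error = function(e) NULL)
        if (!is.null(cmp)) anova[[cmp$comparison]] <- cmp
      }
    }
    network_proteins <- sort(unique(unlist(lapply(subnets, function(s)
      c(s$query_nodes, s$partner_nodes)))))
    if (!is.null(cfg$gene_sets) && length(network_proteins)) {
      collection <- read_gmt(cfg$gene_sets)
      genesets <- set_enrichment(network_proteins, collection,
                                 background_n = cfg$background_n)
    }
  }

  run <- structure(
    list(config = cfg, expression = expr, removed_genes = filt$removed,
         interactome = interactome, query = query,
         control_cnv_genes = control_cnv, partition = partition, scan = scan,
         networks = networks, subnetworks = subnets, overlap = overlap,
         anova = anova, topology = topology, drivers = drivers,
         geneset_enrichment = genesets),
    class = "stn_run")
  if (!is.null(out)) write_run_outputs(run, out)
  run
}

#' @export
print.stn_run <- function(x, ...) {
  cat("stn_run\n")
  cat(sprintf("  brain-expressed genes: %d (removed %d)\n",
              nrow(x$expression$values), nrow(x$removed_genes)))
  cat(sprintf("  interactome: %d nodes, %d edges\n",
              length(x$interactome$nodes), nrow(x$interactome$edges)))
  cat(sprintf("  query genes: %d\n", length(x$query$genes)))
  cat(sprintf("  intervals: %d retained, %d excluded\n",
              length(x$partition$intervals), length(x$partition$excluded)))
  cat(sprintf("  significant intervals: %s\n",
              if (length(x$scan$significant))
                paste(x$scan$significant, collapse = ", ") else "none"))
  if (length(x$drivers)) {
    for (k in names(x$drivers))
      cat(sprintf("  driver in %s: %s (radiality %.3f)\n",
                  k, x$drivers[[k]]$gene, x$drivers[[k]]$radiality))
  }
  invisible(x)
}

write_run_outputs <- function(run, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out, f)
  write_enrichment(run$scan, p("enrichment.tsv"))
  utils::write.table(run$scan$fractions, p("fractions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (length(run$networks)) {
    dir.create(p("networks"), showWarnings = FALSE)
    for (k in names(run$networks))
      write_network(run$networks[[k]], p(file.path("networks",
                                                   paste0(k, ".tsv"))))
  }
  if (length(run$topology)) {
    topo <- do.call(rbind, lapply(names(run$topology), function(k)
      cbind(run$topology[[k]], interval = k)))
    utils::write.table(topo, p("topology.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(run$anova) && length(run$anova)) {
    av <- do.call(rbind, lapply(run$anova, function(a)
      data.frame(comparison = a$comparison, F = a$anova$F,
                 df_between = a$anova$df_between,
                 df_within = a$anova$df_within, p = a$anova$p)))
    utils::write.table(av, p("anova.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(run$overlap)) {
    ov <- data.frame(
      category = c("query", "partner"),
      shared_all = c(run$overlap$query$shared_all, run$overlap$partner$shared_all),
      union_size = c(run$overlap$query$union_size, run$overlap$partner$union_size),
      frac_shared_union = c(run$overlap$query$frac_shared_union,
                            run$overlap$partner$frac_shared_union))
    utils::write.table(ov, p("overlap.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(run$geneset_enrichment))
    utils::write.table(run$geneset_enrichment, p("genesets.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  writeLines(run_report_lines(run), p("report.txt"))
  invisible(out)
}

run_report_lines <- function(run) {
  cfg <- run$config
  c("stnet run report",
    sprintf("seed=%s", cfg$seed),
    sprintf("rho_threshold=%g strict=%s", cfg$rho_threshold, cfg$strict),
    sprintf("filter: log2_intensity_min=%g cv_min=%g logic=%s",
            cfg$log2_intensity_min, cfg$cv_min, cfg$filter_logic),
    sprintf("min_samples=%d alpha=%g fdr_family=%s background_n=%d",
            cfg$min_samples, cfg$alpha, cfg$fdr_family, cfg$background_n),
    sprintf("genes_total=%d", nrow(run$expression$values) + nrow(run$removed_genes)),
    sprintf("brain_genes=%d", nrow(run$expression$values)),
    sprintf("interactome_nodes=%d", length(run$interactome$nodes)),
    sprintf("interactome_edges=%d", nrow(run$interactome$edges)),
    sprintf("query_genes=%d", length(run$query$genes)),
    sprintf("query_excluded=%d", nrow(run$query$excluded)),
    sprintf("intervals_retained=%d", length(run$partition$intervals)),
    sprintf("intervals_excluded=%d", length(run$partition$excluded)),
    sprintf("significant_intervals=%s",
            paste(run$scan$significant, collapse = ",")),
    sprintf("two_of_three_intervals=%s",
            paste(run$scan$two_of_three, collapse = ",")),
    if (length(run$drivers))
      sprintf("driver_%s=%s", names(run$drivers),
              vapply(run$drivers, `[[`, character(1L), "gene")))
}
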