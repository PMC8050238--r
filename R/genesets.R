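#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, members.
#'
#' @param path GMT file path.
#' @param name collection label (defaults to the file name).
#' @return object of class `stn_geneset_collection`: list with `name`,
#'   `sets` (named list of normalized member vectors) and `descriptions`.
#' @export
read_gmt <- function(path, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) stopf("GMT file %s: line %d has fewer than 3 fields",
                         path, bad[1L])
  sets <- lapply(fields, function(f) unique(normalize_gene_id(f[-(1:2)])))
  names(sets) <- vapply(fields, `[[`, character(1L), 1L)
  desc <- stats::setNames(vapply(fields, `[[`, character(1L), 2L), names(sets))
  if (any(lengths(sets) == 0L))
    stopf("GMT file %s: empty gene set '%s'", path,
          names(sets)[lengths(sets) == 0L][1L])
  geneset_collection(sets, name = name, descriptions = desc)
}

#' Construct a gene-set collection
#' @param sets named list of character vectors.
#' @param name collection label.
#' @param descriptions optional named character vector.
#' @return an `stn_geneset_collection`.
#' @export
geneset_collection <- function(sets, name = "collection", descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  sets <- lapply(sets, function(s) unique(normalize_gene_id(s)))
  if (any(lengths(sets) == 0L)) stopf("gene-set collection: empty set")
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  structure(list(name = name, sets = sets, descriptions = descriptions),
            class = "stn_geneset_collection")
}

#' @export
print.stn_geneset_collection <- function(x, ...) {
  cat(sprintf("stn_geneset_collection '%s': %d sets, sizes %d-%d\n",
              x$name, length(x$sets), min(lengths(x$sets)),
              max(lengths(x$sets))))
  invisible(x)
}

#' Write a collection to GMT
#' @param collection an `stn_geneset_collection`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "stn_geneset_collection"))
  lines <- vapply(names(collection$sets), function(n) {
    paste(c(n, collection$descriptions[[n]] %||% "", collection$sets[[n]]),
          collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Gene-set over-representation with Fisher's exact test
#'
#' For each set, builds the 2x2 table of network membership versus set
#' membership over a background of `background_n` genes and computes a
#' one-sided (greater) Fisher p, with Benjamini-Hochberg q across the
#' collection.
#'
#' @param network_genes character vector of network proteins.
#' @param collection an `stn_geneset_collection`.
#' @param background_n background universe size; default 20240.
#' @param universe optional character vector of annotated genes; when given,
#'   query genes outside it are dropped from `n` (logged).
#' @return data.frame with columns `set`, `k` (overlap), `n` (network
#'   genes), `K` (set size), `N` (background), `odds_ratio`, `factor`
#'   (observed/expected overlap), `p`, `q`.
#' @export
set_enrichment <- function(network_genes, collection, background_n = 20240L,
                           universe = NULL) {
  stopifnot(inherits(collection, "stn_geneset_collection"))
  genes <- unique(normalize_gene_id(network_genes))
  if (!length(genes)) stopf("set_enrichment: empty network gene set")
  if (!is.null(universe)) {
    universe <- normalize_gene_id(universe)
    dropped <- sum(!(genes %in% universe))
    if (dropped)
      stn_log("genesets", "dropped %d network gene(s) outside the annotation universe",
              dropped)
    genes <- intersect(genes, universe)
    if (!length(genes)) stopf("set_enrichment: no network gene in the universe")
  }
  n <- length(genes)
  N <- as.integer(background_n)
  rows <- lapply(names(collection$sets), function(nm) {
    set <- collection$sets[[nm]]
    K <- length(set)
    if (N < length(union(genes, set)))
      stopf("background_n = %d smaller than observed union for set '%s'", N, nm)
    k <- length(intersect(genes, set))
    tab <- matrix(c(k, n - k, K - k, N - n - K + k), nrow = 2L, byrow = TRUE)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    or <- if (tab[1, 2] * tab[2, 1] == 0) {
      if (tab[1, 1] * tab[2, 2] == 0) NaN else Inf
    } else tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1])
    data.frame(set = nm, k = k, n = n, K = K, N = N, odds_ratio = or,
               factor = (k / n) / (K / N), p = unname(p))
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out[order(out$p), , drop = FALSE]
}

#' Term enrichment parameters
#' @param p_max maximum hypergeometric p; default 0.01.
#' @param min_count minimum overlap count; default 3.
#' @param min_factor minimum enrichment factor (strictly greater);
#'   default 1.5.
#' @return list of class `stn_term_params`.
#' @export
term_enrichment_params <- function(p_max = 0.01, min_count = 3L,
                                   min_factor = 1.5) {
  stopifnot(p_max > 0, p_max < 1, min_count >= 1L)
  structure(list(p_max = p_max, min_count = min_count, min_factor = min_factor),
            class = "stn_term_params")
}

#' Term over-representation with the cumulative hypergeometric distribution
#'
#' For each term, `p = P(overlap >= k)` under the hypergeometric null and
#' `factor = (k/n) / (K/N)` (observed over expected). Terms are kept when
#' `p < p_max`, `k >= min_count` and `factor > min_factor` (all strict as
#' stated); q-values are BH-corrected across the full collection before
#' filtering.
#'
#' @param query_genes character vector of genes to annotate.
#' @param collection an `stn_geneset_collection`.
#' @param params [term_enrichment_params()].
#' @param background_n background universe size; default 20240.
#' @param universe optional annotated-gene universe, as in
#'   [set_enrichment()].
#' @return list with `kept` (filtered data.frame) and `all` (every term,
#'   columns as in [set_enrichment()] plus `pass`).
#' @export
term_enrichment <- function(query_genes, collection,
                            params = term_enrichment_params(),
                            background_n = 20240L, universe = NULL) {
  stopifnot(inherits(params, "stn_term_params"))
  genes <- unique(normalize_gene_id(query_genes))
  if (!is.null(universe)) {
    universe <- normalize_gene_id(universe)
    dropped <- sum(!(genes %in% universe))
    if (dropped)
      stn_log("genesets", "dropped %d query gene(s) outside the annotation universe",
              dropped)
    genes <- intersect(genes, universe)
  }
  if (!length(genes)) stopf("term_enrichment: empty query gene set")
  n <- length(genes)
  N <- as.integer(background_n)
  rows <- lapply(names(collection$sets), function(nm) {
    set <- collection$sets[[nm]]
    K <- length(set)
    if (N < length(union(genes, set)))
      stopf("background_n = %d smaller than observed union for term '%s'", N, nm)
    k <- length(intersect(genes, set))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, n = n, K = K, N = N,
               factor = (k / n) / (K / N), p = p)
  })
  all <- do.call(rbind, rows)
  all$q <- bh_fdr(all$p)
  all$pass <- all$p < params$p_max & all$k >= params$min_count &
    all$factor > params$min_factor
  rownames(all) <- NULL
  all <- all[order(all$p), , drop = FALSE]
  list(kept = all[all$pass, setdiff(names(all), "pass"), drop = FALSE],
       all = all)
}
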