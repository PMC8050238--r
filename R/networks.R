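#' Coexpression parameters
#'
#' @param rho_threshold Spearman correlation threshold; an interacting pair
#'   counts as co-expressed within an interval when its correlation exceeds
#'   this value. Default 0.5.
#' @param strict if `TRUE` (default) retain strictly `rho > threshold`;
#'   `FALSE` uses `>=` (sensitivity checks).
#' @return list of class `stn_coexpr_params`.
#' @export
coexpression_params <- function(rho_threshold = 0.5, strict = TRUE) {
  stopifnot(is.finite(rho_threshold))
  structure(list(rho_threshold = rho_threshold, strict = strict),
            class = "stn_coexpr_params")
}

#' Spearman rank correlation
#'
#' Rank correlation with midranks for ties: the Pearson correlation of the
#' average-rank-transformed vectors. Vectors with fewer than two distinct
#' values yield `NA` (the pair is treated as not co-expressed downstream).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in `[-1, 1]`, or `NA`.
#' @examples
#' spearman_rho(1:4, c(10, 20, 30, 40))  # 1
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stopf("spearman_rho: length mismatch (%d vs %d)",
                                    length(x), length(y))
  if (length(x) < 3L) stopf("spearman_rho: need at least 3 observations")
  z <- rank_standardize(rbind(x, y))
  if (anyNA(z[, 1L])) return(NA_real_)
  unname(min(1, max(-1, sum(z[1L, ] * z[2L, ]))))
}

## Core kernel shared by every co-expression computation.
## X: numeric matrix (genes x samples). Returns a matrix Z of the same shape
## with each row rank-transformed (midranks), centred and scaled to unit sum
## of squares, so that rowSums(Z[i,] * Z[j,]) is the Spearman correlation of
## rows i and j. Rows with < 2 distinct values become all-NA.
rank_standardize <- function(X) {
  R <- t(apply(X, 1L, rank))          # average ranks for ties
  R <- R - rowMeans(R)
  ss <- sqrt(rowSums(R^2))
  const <- ss == 0
  Z <- R / ss
  if (any(const)) Z[const, ] <- NA_real_
  Z
}

## Spearman correlations for an explicit list of row pairs.
## Z: output of rank_standardize; ia, ib: integer row indices.
pair_rho <- function(Z, ia, ib) {
  r <- rowSums(Z[ia, , drop = FALSE] * Z[ib, , drop = FALSE])
  pmin(1, pmax(-1, r))
}

coexpressed <- function(rho, params) {
  ok <- if (params$strict) rho > params$rho_threshold
        else rho >= params$rho_threshold
  ok & !is.na(rho)
}

#' Build one interval's co-expression-filtered PPI network
#'
#' For every interactome edge whose two genes are present in the expression
#' matrix, computes the Spearman correlation over the interval's samples and
#' retains the edge when the correlation exceeds the threshold. Edges with a
#' gene absent from the matrix are skipped and counted; nodes that lose all
#' edges are dropped.
#'
#' @param interactome an `stn_interactome`.
#' @param expression an `stn_expression`.
#' @param sample_ids sample ids of the interval (subset of the expression
#'   columns, length >= 3).
#' @param params [coexpression_params()].
#' @param key interval label for reporting.
#' @return object of class `stn_network`: list with `key`, `edges`
#'   (data.frame `a`, `b`, `rho`) and `nodes`.
#' @export
build_interval_network <- function(interactome, expression, sample_ids,
                                   params = coexpression_params(),
                                   key = "interval") {
  stopifnot(inherits(interactome, "stn_interactome"),
            inherits(expression, "stn_expression"))
  cols <- match(sample_ids, expression$samples$sample_id)
  if (anyNA(cols))
    stopf("interval %s: sample(s) not in expression matrix: %s", key,
          paste(sample_ids[is.na(cols)], collapse = ", "))
  if (length(cols) < 3L)
    stopf("interval %s: %d sample(s), need at least 3 for rank correlation",
          key, length(cols))
  e <- interactome$edges
  genes <- rownames(expression$values)
  ia <- match(e$a, genes); ib <- match(e$b, genes)
  measurable <- !is.na(ia) & !is.na(ib)
  if (any(!measurable))
    stn_log("networks",
            "interval %s: skipped %d edge(s) with genes absent from expression",
            key, sum(!measurable))
  e <- e[measurable, , drop = FALSE]
  Z <- rank_standardize(expression$values[, cols, drop = FALSE])
  rho <- pair_rho(Z, ia[measurable], ib[measurable])
  keep <- coexpressed(rho, params)
  edges <- data.frame(a = e$a[keep], b = e$b[keep], rho = rho[keep],
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(key = key, edges = edges,
                 nodes = sort(unique(c(edges$a, edges$b)))),
            class = "stn_network")
}

#' @export
print.stn_network <- function(x, ...) {
  cat(sprintf("stn_network %s: %d nodes, %d edges\n",
              x$key, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Extract the query-centred subnetwork
#'
#' Keeps query-query and query-partner edges; partner-partner edges are
#' included only when `include_partner_partner = TRUE` (functional-module
#' views). Partners are the non-query nodes adjacent to at least one query
#' gene.
#'
#' @param network an `stn_network`.
#' @param query an `stn_query` (or character vector of genes).
#' @param include_partner_partner include edges between partners.
#' @return object of class `stn_subnetwork`: list with `key`, `query_nodes`,
#'   `partner_nodes`, `edges` (data.frame `a`, `b`, `rho`, `kind`).
#' @export
extract_query_subnetwork <- function(network, query,
                                     include_partner_partner = FALSE) {
  stopifnot(inherits(network, "stn_network"))
  q <- if (inherits(query, "stn_query")) query$genes else normalize_gene_id(query)
  e <- network$edges
  a_q <- e$a %in% q; b_q <- e$b %in% q
  partners <- sort(setdiff(unique(c(e$b[a_q & !b_q], e$a[b_q & !a_q])), q))
  kind <- ifelse(a_q & b_q, "query-query",
          ifelse(a_q | b_q, "query-partner",
          ifelse(e$a %in% partners & e$b %in% partners, "partner-partner", "other")))
  keep <- kind %in% c("query-query", "query-partner") |
    (include_partner_partner & kind == "partner-partner")
  edges <- cbind(e[keep, , drop = FALSE], kind = kind[keep])
  rownames(edges) <- NULL
  structure(list(key = network$key,
                 query_nodes = sort(intersect(q, network$nodes)),
                 partner_nodes = partners, edges = edges),
            class = "stn_subnetwork")
}

#' @export
print.stn_subnetwork <- function(x, ...) {
  cat(sprintf("stn_subnetwork %s: %d query nodes, %d partners, %d edges\n",
              x$key, length(x$query_nodes), length(x$partner_nodes),
              nrow(x$edges)))
  invisible(x)
}

#' Write a network as an edge-list TSV
#'
#' Columns `gene_a`, `gene_b`, `rho`, `interval`; set `sif = TRUE` for a
#' Cytoscape-style SIF file (`gene_a pp gene_b`) instead.
#'
#' @param network an `stn_network` or `stn_subnetwork`.
#' @param path output path.
#' @param sif write SIF instead of TSV.
#' @return invisibly, `path`.
#' @export
write_network <- function(network, path, sif = FALSE) {
  e <- network$edges
  if (sif) {
    writeLines(sprintf("%s\tpp\t%s", e$a, e$b), path)
  } else {
    out <- data.frame(gene_a = e$a, gene_b = e$b, rho = e$rho,
                      interval = network$key)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
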