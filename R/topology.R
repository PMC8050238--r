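#' Node overlap across query subnetworks
#'
#' Set algebra on query nodes and partner nodes separately across two or
#' more networks: counts of genes present in exactly k networks, the
#' fraction shared by all (union denominator), and, when a catalogue size is
#' supplied (e.g. the full locus list), the shared-over-catalogue fraction.
#'
#' @param subnetworks list of `stn_subnetwork` objects (length >= 2).
#' @param catalog_query optional total number of catalogued query genes for
#'   the shared-over-catalogue fraction often reported alongside.
#' @return object of class `stn_overlap`: for each of `query` and `partner`,
#'   a list with `sets`, `exactly_k` (named integer vector), `shared_all`,
#'   `union_size`, `frac_shared_union` and (query only, when available)
#'   `frac_shared_catalog`.
#' @export
network_overlap <- function(subnetworks, catalog_query = NULL) {
  stopifnot(length(subnetworks) >= 2L,
            all(vapply(subnetworks, inherits, logical(1L), "stn_subnetwork")))
  keys <- vapply(subnetworks, `[[`, character(1L), "key")
  tally <- function(sets) {
    u <- sort(unique(unlist(sets)))
    membership <- matrix(vapply(sets, function(s) u %in% s,
                                logical(length(u))),
                         nrow = length(u))
    counts <- rowSums(membership)
    k <- seq_along(sets)
    exactly <- vapply(k, function(i) sum(counts == i), integer(1L))
    names(exactly) <- paste0("k", k)
    shared <- sum(counts == length(sets))
    list(sets = stats::setNames(sets, keys), exactly_k = exactly,
         shared_all = shared, union_size = length(u),
         shared_genes = u[counts == length(sets)],
         frac_shared_union = if (length(u)) shared / length(u) else NA_real_)
  }
  query <- tally(lapply(subnetworks, `[[`, "query_nodes"))
  if (!is.null(catalog_query))
    query$frac_shared_catalog <- query$shared_all / catalog_query
  partner <- tally(lapply(subnetworks, `[[`, "partner_nodes"))
  structure(list(networks = keys, query = query, partner = partner),
            class = "stn_overlap")
}

#' @export
print.stn_overlap <- function(x, ...) {
  cat(sprintf("stn_overlap across %s\n", paste(x$networks, collapse = ", ")))
  cat(sprintf("  query genes: %d/%d shared by all (%.1f%% of union)\n",
              x$query$shared_all, x$query$union_size,
              100 * x$query$frac_shared_union))
  if (!is.null(x$query$frac_shared_catalog))
    cat(sprintf("    %.1f%% of catalogued query genes\n",
                100 * x$query$frac_shared_catalog))
  cat(sprintf("  partners: %d/%d shared by all (%.1f%% of union)\n",
              x$partner$shared_all, x$partner$union_size,
              100 * x$partner$frac_shared_union))
  invisible(x)
}

#' Per-gene partner ratios between two networks
#'
#' For each query gene with a non-empty partner union across networks `a`
#' and `b`, the fractions of its partners unique to `a`, unique to `b`, and
#' shared, with the partner union as denominator so the three ratios sum
#' to 1. Genes with an empty union are skipped and logged.
#'
#' @param a,b `stn_subnetwork` objects from different intervals.
#' @param query `stn_query` or character vector.
#' @param denominator `"union"` (default) or `"per_network"` (each unique
#'   ratio over that network's own partner count; ratios then need not sum
#'   to 1).
#' @return data.frame with columns `gene`, `n_a`, `n_b`, `n_shared`,
#'   `r_unique_a`, `r_unique_b`, `r_shared`.
#' @export
partner_ratios <- function(a, b, query, denominator = c("union", "per_network")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(a, "stn_subnetwork"), inherits(b, "stn_subnetwork"))
  q <- if (inherits(query, "stn_query")) query$genes else normalize_gene_id(query)
  partners_of <- function(net, g) {
    e <- net$edges
    sort(setdiff(unique(c(e$b[e$a == g], e$a[e$b == g])), g))
  }
  rows <- list()
  skipped <- character()
  for (g in q) {
    pa <- partners_of(a, g); pb <- partners_of(b, g)
    u <- union(pa, pb)
    if (!length(u)) { skipped <- c(skipped, g); next }
    sh <- length(intersect(pa, pb))
    ua <- length(setdiff(pa, pb)); ub <- length(setdiff(pb, pa))
    if (denominator == "union") {
      den_a <- den_b <- den_s <- length(u)
    } else {
      den_a <- max(1L, length(pa)); den_b <- max(1L, length(pb))
      den_s <- length(u)
    }
    rows[[g]] <- data.frame(gene = g, n_a = length(pa), n_b = length(pb),
                            n_shared = sh, r_unique_a = ua / den_a,
                            r_unique_b = ub / den_b, r_shared = sh / den_s)
  }
  if (length(skipped))
    stn_log("topology", "partner_ratios: skipped %d gene(s) with no partners: %s",
            length(skipped), paste(utils::head(skipped, 5L), collapse = ", "))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), n_a = integer(), n_b = integer(),
               n_shared = integer(), r_unique_a = numeric(),
               r_unique_b = numeric(), r_shared = numeric())
  rownames(out) <- NULL
  out
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA (equal-variance F test) on a list
#' of groups.
#'
#' @param groups list of numeric vectors, each of length >= 2.
#' @return list of class `stn_anova`: `F`, `df_between`, `df_within`, `p`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups))
  if (length(groups) < 2L) stopf("one_way_anova: need at least 2 groups")
  if (any(lengths(groups) < 2L))
    stopf("one_way_anova: every group needs at least 2 values")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(values) <= length(groups)) stopf("one_way_anova: degenerate df")
  ow <- stats::oneway.test(values ~ g, var.equal = TRUE)
  f <- unname(ow$statistic)
  p <- unname(ow$p.value)
  if (is.nan(f)) { f <- 0; p <- 1 }   # zero within- and between-variance
  structure(list(F = f, df_between = unname(ow$parameter[1L]),
                 df_within = unname(ow$parameter[2L]), p = p),
            class = "stn_anova")
}

#' @export
print.stn_anova <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%g, %g) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Compare two networks by partner-ratio ANOVA
#'
#' Computes per-gene partner ratios between two networks and tests whether
#' the unique-to-a, unique-to-b and shared ratios differ, the network-change
#' statistic used to contrast intervals from the same period or region. The
#' `two_group` reading pools the two unique ratios against the shared ones.
#'
#' @param a,b `stn_subnetwork` objects.
#' @param query `stn_query` or character vector.
#' @param grouping `"three_group"` (default) or `"two_group"`.
#' @return list with the `stn_anova` result, the ratio data.frame and the
#'   comparison label.
#' @export
compare_networks_anova <- function(a, b, query,
                                   grouping = c("three_group", "two_group")) {
  grouping <- match.arg(grouping)
  pr <- partner_ratios(a, b, query)
  if (nrow(pr) < 2L)
    stopf("compare_networks_anova: fewer than 2 genes with partners")
  groups <- if (grouping == "three_group")
    list(unique_a = pr$r_unique_a, unique_b = pr$r_unique_b,
         shared = pr$r_shared)
  else
    list(unique = c(pr$r_unique_a, pr$r_unique_b), shared = pr$r_shared)
  list(comparison = sprintf("%s vs %s", a$key, b$key),
       anova = one_way_anova(groups), ratios = pr, grouping = grouping)
}

as_igraph <- function(net) {
  e <- net$edges
  nodes <- if (inherits(net, "stn_subnetwork"))
    unique(c(net$query_nodes, net$partner_nodes, e$a, e$b))
  else net$nodes
  igraph::graph_from_data_frame(e[, c("a", "b"), drop = FALSE],
                                directed = FALSE, vertices = nodes)
}

#' Radiality centrality
#'
#' Diameter-normalized radiality, computed per connected component: for a
#' node v in a component with unweighted diameter D,
#' `Rad(v) = (D + 1 - mean of d(v, u) over u != v) / D`. Values lie in
#' `[0, 1]`; singleton components get 0 by convention.
#'
#' @param network an `stn_network` or `stn_subnetwork`.
#' @return data.frame with columns `gene`, `radiality`, `degree`,
#'   `component`.
#' @export
radiality <- function(network) {
  g <- as_igraph(network)
  if (igraph::vcount(g) == 0L) stopf("radiality: empty network")
  comp <- igraph::components(g)
  deg <- igraph::degree(g)
  out <- data.frame(gene = igraph::V(g)$name,
                    radiality = 0, degree = as.integer(deg),
                    component = as.integer(comp$membership))
  for (ci in seq_len(comp$no)) {
    members <- which(comp$membership == ci)
    n <- length(members)
    if (n < 2L) next
    d <- igraph::distances(g, v = members, to = members)
    D <- max(d)
    rad <- (D + 1 - rowSums(d) / (n - 1)) / D
    out$radiality[members] <- unname(rad)
  }
  rownames(out) <- NULL
  out
}

#' Identify the driver gene
#'
#' The candidate with maximal radiality; ties broken by higher degree, then
#' lexicographically by symbol.
#'
#' @param centrality data.frame from [radiality()].
#' @param candidates character vector of candidate genes (e.g. the query set).
#' @return list with `gene`, `radiality`, `degree`.
#' @export
identify_driver <- function(centrality, candidates) {
  candidates <- normalize_gene_id(candidates)
  t <- centrality[centrality$gene %in% candidates, , drop = FALSE]
  if (!nrow(t)) stopf("identify_driver: no candidate present in the network")
  t <- t[order(-t$radiality, -t$degree, t$gene), , drop = FALSE]
  if (nrow(t) > 1L && t$radiality[1L] == t$radiality[2L])
    stn_log("topology", "driver tie on radiality broken by degree/symbol: %s",
            t$gene[1L])
  list(gene = t$gene[1L], radiality = t$radiality[1L], degree = t$degree[1L])
}
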