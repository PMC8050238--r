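#' Build a pair universe
#'
#' Constructs the query pair universe or one of the three control universes
#' against which per-interval co-expressed-pair fractions are compared:
#'
#' * `query_ppi` — interactome edges with at least one endpoint in the query
#'   set (the test universe);
#' * `common_cnv_ppi` — interactome edges with at least one endpoint in a
#'   control CNV gene list (control i);
#' * `query_all_brain` — all unordered pairs between query genes and
#'   brain-expressed genes, physical interaction not required (control ii);
#' * `all_ppi` — every interactome edge (control iii).
#'
#' @param kind one of the four universe names above.
#' @param query an `stn_query` or character vector.
#' @param interactome an `stn_interactome`.
#' @param brain_genes character vector (needed for `query_all_brain`).
#' @param control_cnv_genes character vector (needed for `common_cnv_ppi`).
#' @return object of class `stn_pair_universe`: list with `name`, `pairs`
#'   (data.frame `a`, `b`, canonical, unique, no self-pairs), `requires_ppi`.
#' @export
build_pair_universe <- function(kind, query = NULL, interactome = NULL,
                                brain_genes = NULL, control_cnv_genes = NULL) {
  q <- if (inherits(query, "stn_query")) query$genes
       else normalize_gene_id(query %||% character())
  pairs <- switch(kind,
    query_ppi = {
      if (!length(q)) stopf("query_ppi universe: empty query set")
      e <- interactome$edges
      e[e$a %in% q | e$b %in% q, c("a", "b"), drop = FALSE]
    },
    common_cnv_ppi = {
      cg <- normalize_gene_id(control_cnv_genes %||% character())
      if (!length(cg)) stopf("common_cnv_ppi universe: empty control CNV gene list")
      e <- interactome$edges
      e[e$a %in% cg | e$b %in% cg, c("a", "b"), drop = FALSE]
    },
    query_all_brain = {
      bg <- normalize_gene_id(brain_genes %||% character())
      if (!length(q) || !length(bg))
        stopf("query_all_brain universe: need query and brain gene sets")
      p <- canonical_pairs(rep(q, each = length(bg)), rep(bg, length(q)))
      p <- p[p$a != p$b, , drop = FALSE]
      p[!duplicated(pair_key(p$a, p$b)), , drop = FALSE]
    },
    all_ppi = interactome$edges[, c("a", "b"), drop = FALSE],
    stopf("unknown pair universe kind: '%s'", kind))
  rownames(pairs) <- NULL
  structure(list(name = kind, pairs = pairs,
                 requires_ppi = kind != "query_all_brain"),
            class = "stn_pair_universe")
}

#' Co-expressed fraction of a pair universe
#'
#' Counts, over one interval's samples, the pairs whose Spearman correlation
#' exceeds the threshold. Pairs with a missing expression row or constant
#' expression stay in the denominator but never count as co-expressed.
#'
#' @param universe an `stn_pair_universe`.
#' @param expression an `stn_expression`.
#' @param sample_ids interval sample ids.
#' @param params [coexpression_params()].
#' @param interval interval label.
#' @return list of class `stn_fraction`: `interval`, `universe`,
#'   `n_coexpressed`, `n_total`, `fraction`, `n_unmeasurable`.
#' @export
coexpressed_fraction <- function(universe, expression, sample_ids,
                                 params = coexpression_params(),
                                 interval = "interval") {
  stopifnot(inherits(universe, "stn_pair_universe"))
  if (!nrow(universe$pairs))
    stopf("pair universe '%s' is empty", universe$name)
  cols <- match(sample_ids, expression$samples$sample_id)
  if (anyNA(cols)) stopf("interval %s: unknown sample id(s)", interval)
  Z <- rank_standardize(expression$values[, cols, drop = FALSE])
  rho <- universe_rho(universe$pairs, rownames(expression$values), Z)
  n_total <- nrow(universe$pairs)
  n_co <- sum(coexpressed(rho, params))
  n_unm <- sum(is.na(rho))
  if (n_unm)
    stn_log("enrichment",
            "interval %s, universe %s: %d pair(s) unmeasurable (kept in denominator)",
            interval, universe$name, n_unm)
  structure(list(interval = interval, universe = universe$name,
                 n_coexpressed = n_co, n_total = n_total,
                 fraction = n_co / n_total, n_unmeasurable = n_unm),
            class = "stn_fraction")
}

## rho for each row of a pair data.frame given standardized ranks Z whose
## rows are named by `genes`; pairs with a missing gene get NA.
universe_rho <- function(pairs, genes, Z) {
  ia <- match(pairs$a, genes); ib <- match(pairs$b, genes)
  rho <- rep(NA_real_, nrow(pairs))
  ok <- !is.na(ia) & !is.na(ib)
  if (any(ok)) rho[ok] <- pair_rho(Z, ia[ok], ib[ok])
  rho
}

#' Fisher's exact enrichment test on two co-expressed fractions
#'
#' Tests whether the test universe has more co-expressed pairs than the
#' control universe using Fisher's exact test on the 2x2 table
#' `[[test_co, test_not], [ctrl_co, ctrl_not]]`. The default alternative is
#' one-sided `greater`.
#'
#' @param test,control `stn_fraction` objects from the same interval.
#' @param alternative `"greater"` (default) or `"two_sided"`.
#' @return list of class `stn_enrichment`: `interval`, `control`, `table`,
#'   `odds_ratio` (sample cross-product ratio, `Inf` allowed), `p`, and `q`
#'   (`NA` until FDR correction across a family).
#' @export
fisher_enrichment <- function(test, control,
                              alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(test, "stn_fraction"), inherits(control, "stn_fraction"))
  if (!identical(test$interval, control$interval))
    stopf("interval mismatch: test '%s' vs control '%s'",
          test$interval, control$interval)
  tab <- matrix(c(test$n_coexpressed, test$n_total - test$n_coexpressed,
                  control$n_coexpressed, control$n_total - control$n_coexpressed),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("test", "control"), c("coexpressed", "not")))
  ft <- stats::fisher.test(tab, alternative = sub("_", ".", alternative))
  or <- tab[1, 1] * tab[2, 2]
  denom <- tab[1, 2] * tab[2, 1]
  odds_ratio <- if (denom == 0) {
    if (or == 0) NaN else Inf
  } else or / denom
  structure(list(interval = test$interval, control = control$universe,
                 table = tab, odds_ratio = odds_ratio,
                 p = unname(ft$p.value), q = NA_real_),
            class = "stn_enrichment")
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment, returned in input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric())
  if (anyNA(p) || any(p < 0 | p > 1))
    stopf("bh_fdr: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Run the spatiotemporal enrichment scan
#'
#' The central analysis: for every retained interval, computes the
#' co-expressed-pair fraction of the query universe and of the three control
#' universes, tests the query fraction against each control with Fisher's
#' exact test (one-sided `greater`), and corrects p-values with
#' Benjamini-Hochberg. An interval is called significant when `q < alpha`
#' against all three controls; intervals clearing exactly two controls are
#' reported separately.
#'
#' @param expression brain-expressed `stn_expression`.
#' @param partition `stn_partition` after sparse-interval exclusion.
#' @param interactome brain-expressed `stn_interactome`.
#' @param query `stn_query`.
#' @param control_cnv_genes character vector for the common-CNV control.
#' @param params [coexpression_params()].
#' @param alpha significance level on q; default 0.05.
#' @param fdr_family `"per_control"` (default: correct across intervals
#'   within each control comparison) or `"joint"` (one family over all
#'   interval x control tests).
#' @param alternative passed to [fisher_enrichment()].
#' @return object of class `stn_scan`: list with `results` (data.frame, one
#'   row per interval x control), `significant` (interval keys significant
#'   vs all three controls), `two_of_three`, `alpha`, `fdr_family`,
#'   `fractions` (data.frame of per-interval per-universe fractions).
#' @export
run_enrichment_scan <- function(expression, partition, interactome, query,
                                control_cnv_genes,
                                params = coexpression_params(),
                                alpha = 0.05,
                                fdr_family = c("per_control", "joint"),
                                alternative = "greater") {
  fdr_family <- match.arg(fdr_family)
  stopifnot(inherits(partition, "stn_partition"))
  brain_genes <- rownames(expression$values)
  universes <- list(
    query_ppi = build_pair_universe("query_ppi", query, interactome),
    common_cnv_ppi = build_pair_universe("common_cnv_ppi", query, interactome,
                                         control_cnv_genes = control_cnv_genes),
    query_all_brain = build_pair_universe("query_all_brain", query,
                                          brain_genes = brain_genes),
    all_ppi = build_pair_universe("all_ppi", interactome = interactome))
  for (u in universes)
    if (!nrow(u$pairs)) stopf("pair universe '%s' is empty", u$name)
  controls <- c("common_cnv_ppi", "query_all_brain", "all_ppi")

  keys <- names(partition$intervals)
  rows <- list()
  fracs <- list()
  for (k in keys) {
    fr <- lapply(universes, coexpressed_fraction, expression = expression,
                 sample_ids = partition$intervals[[k]], params = params,
                 interval = k)
    fracs[[k]] <- data.frame(
      interval = k, universe = names(fr),
      n_coexpressed = vapply(fr, `[[`, numeric(1L), "n_coexpressed"),
      n_total = vapply(fr, `[[`, numeric(1L), "n_total"),
      fraction = vapply(fr, `[[`, numeric(1L), "fraction"),
      row.names = NULL)
    for (ctl in controls) {
      en <- fisher_enrichment(fr$query_ppi, fr[[ctl]], alternative = alternative)
      rows[[length(rows) + 1L]] <- data.frame(
        interval = k, control = ctl,
        n_test_coexp = en$table[1, 1], n_test_total = sum(en$table[1, ]),
        n_ctrl_coexp = en$table[2, 1], n_ctrl_total = sum(en$table[2, ]),
        fraction_test = fr$query_ppi$fraction, fraction_ctrl = fr[[ctl]]$fraction,
        odds_ratio = en$odds_ratio, p = en$p)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (fdr_family == "per_control") {
    res$q <- NA_real_
    for (ctl in controls) {
      i <- res$control == ctl
      res$q[i] <- bh_fdr(res$p[i])
    }
  } else {
    res$q <- bh_fdr(res$p)
  }
  res$significant <- res$q < alpha
  n_sig <- tapply(res$significant, res$interval, sum)
  significant <- names(n_sig)[n_sig == length(controls)]
  two_of_three <- names(n_sig)[n_sig == length(controls) - 1L]
  stn_log("enrichment", "%d/%d interval(s) significant vs all controls%s",
          length(significant), length(keys),
          if (length(two_of_three))
            sprintf(" (+%d vs two of three)", length(two_of_three)) else "")
  structure(list(results = res,
                 fractions = do.call(rbind, c(fracs, make.row.names = FALSE)),
                 significant = sort(significant),
                 two_of_three = sort(two_of_three),
                 alpha = alpha, fdr_family = fdr_family, params = params),
            class = "stn_scan")
}

#' @export
print.stn_scan <- function(x, ...) {
  cat(sprintf("stn_scan: %d intervals x %d controls (FDR family: %s, alpha = %g)\n",
              length(unique(x$results$interval)),
              length(unique(x$results$control)), x$fdr_family, x$alpha))
  cat(sprintf("  significant vs all controls: %s\n",
              if (length(x$significant)) paste(x$significant, collapse = ", ")
              else "none"))
  if (length(x$two_of_three))
    cat(sprintf("  significant vs two of three: %s\n",
                paste(x$two_of_three, collapse = ", ")))
  invisible(x)
}

#' @export
summary.stn_scan <- function(object, ...) {
  res <- object$results
  best <- res[order(res$q, res$p), ]
  cat("Spatiotemporal enrichment scan\n")
  print(object)
  cat("\nTop interval x control tests by q:\n")
  print(utils::head(best[, c("interval", "control", "fraction_test",
                             "fraction_ctrl", "odds_ratio", "p", "q")], 9L),
        row.names = FALSE, digits = 3L)
  invisible(object)
}

#' Write the enrichment table
#' @param scan an `stn_scan`.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_enrichment <- function(scan, path) {
  utils::write.table(scan$results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
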