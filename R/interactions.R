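## BioGRID tab2 column names we rely on; a minimal 3-column dialect is also
## accepted so fixtures stay small.
.tab2_cols <- c(a = "Official Symbol Interactor A",
                b = "Official Symbol Interactor B",
                type = "Experimental System Type")
.mini_cols <- c(a = "gene_a", b = "gene_b", type = "system_type")

#' Read a protein-interaction table
#'
#' Parses a BioGRID tab2-compatible TSV (columns `Official Symbol Interactor
#' A`/`B` and `Experimental System Type`) or a minimal dialect with columns
#' `gene_a`, `gene_b`, `system_type`. Column matching is header-driven, so
#' column order is irrelevant.
#'
#' @param path path to the TSV.
#' @param physical_only if `TRUE` (default) keep only rows whose experimental
#'   system type is `"physical"`.
#' @return data.frame with columns `gene_a`, `gene_b`, `system_type`
#'   (symbols normalized). May have zero rows.
#' @export
read_interactions <- function(path, physical_only = TRUE) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  cols <- if (all(.tab2_cols %in% names(tab))) .tab2_cols
          else if (all(.mini_cols %in% names(tab))) .mini_cols
          else stopf(paste0(
            "interaction file %s: expected columns [%s] (tab2) or [%s] ",
            "(minimal dialect)"), path,
            paste(.tab2_cols, collapse = ", "),
            paste(.mini_cols, collapse = ", "))
  out <- data.frame(gene_a = normalize_gene_id(tab[[cols[["a"]]]]),
                    gene_b = normalize_gene_id(tab[[cols[["b"]]]]),
                    system_type = tolower(trimws(tab[[cols[["type"]]]])),
                    stringsAsFactors = FALSE)
  out <- out[nzchar(out$gene_a) & nzchar(out$gene_b), , drop = FALSE]
  if (physical_only) {
    n0 <- nrow(out)
    out <- out[out$system_type == "physical", , drop = FALSE]
    stn_log("ingest", "kept %d of %d interaction rows with physical system type",
            nrow(out), n0)
  }
  rownames(out) <- NULL
  out
}

#' Build the brain-expressed interactome
#'
#' Restricts an interaction table to pairs whose endpoints are both
#' brain-expressed, removes self-interactions and collapses duplicate and
#' orientation-swapped rows, yielding a simple undirected graph (the
#' brain-expressed human interactome when fed real data).
#'
#' @param table data.frame from [read_interactions()].
#' @param brain_genes character vector of brain-expressed gene symbols.
#' @return object of class `stn_interactome`: list with `edges` (data.frame
#'   `a`, `b`, canonically ordered, unique) and `nodes` (character).
#' @export
build_brain_interactome <- function(table, brain_genes) {
  stopifnot(is.data.frame(table), all(c("gene_a", "gene_b") %in% names(table)))
  brain_genes <- normalize_gene_id(brain_genes)
  p <- canonical_pairs(table$gene_a, table$gene_b)
  p <- p[p$a != p$b, , drop = FALSE]                       # self-loops
  p <- p[p$a %in% brain_genes & p$b %in% brain_genes, , drop = FALSE]
  p <- p[!duplicated(pair_key(p$a, p$b)), , drop = FALSE]  # incl. swapped dups
  rownames(p) <- NULL
  nodes <- sort(unique(c(p$a, p$b)))
  stn_log("ingest", "interactome: %d nodes, %d edges after cleaning",
          length(nodes), nrow(p))
  structure(list(edges = p, nodes = nodes), class = "stn_interactome")
}

#' @export
print.stn_interactome <- function(x, ...) {
  cat(sprintf("stn_interactome: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Construct a query gene set in memory
#'
#' Programmatic counterpart of [load_query_genes()].
#'
#' @param genes character vector of gene symbols.
#' @param name set label.
#' @param excluded optional data.frame with `gene` and `reason`.
#' @return an `stn_query`.
#' @export
query_gene_set <- function(genes, name = "query", excluded = NULL) {
  genes <- unique(normalize_gene_id(genes))
  if (!length(genes)) stopf("empty query gene set")
  if (is.null(excluded))
    excluded <- data.frame(gene = character(), reason = character(),
                           stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "reason") %in% names(excluded)))
  excluded$gene <- normalize_gene_id(excluded$gene)
  if (length(intersect(genes, excluded$gene)))
    stopf("gene(s) both kept and excluded: %s",
          paste(intersect(genes, excluded$gene), collapse = ", "))
  structure(list(name = name, genes = genes, excluded = excluded),
            class = "stn_query")
}

#' Read a plain gene list
#'
#' One symbol per line; `#` starts a comment; blank lines ignored.
#'
#' @param path file path.
#' @return normalized character vector (duplicates retained).
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  normalize_gene_id(lines[nzchar(lines)])
}

#' Load the query (CNV) gene set
#'
#' Reads a locus gene list, applies explicit exclusions (for example, genes
#' known not to be expressed in the tissue) and drops genes absent from the
#' brain-expressed universe, recording every removal with a reason.
#'
#' @param path path to a plain-text gene list.
#' @param exclusions named character vector: names are gene symbols, values
#'   the reason for exclusion. May be empty.
#' @param brain_genes character vector of brain-expressed symbols.
#' @param name label for the set.
#' @return object of class `stn_query`: list with `name`, `genes` (character,
#'   unique) and `excluded` (data.frame `gene`, `reason`).
#' @export
load_query_genes <- function(path, exclusions = character(), brain_genes,
                             name = "query") {
  listed <- unique(read_gene_list(path))
  if (!length(listed)) stopf("query gene list %s is empty", path)
  excl_genes <- normalize_gene_id(names(exclusions) %||% character())
  reasons <- as.character(exclusions)
  missing_excl <- setdiff(excl_genes, listed)
  if (length(missing_excl)) {
    warning(sprintf("exclusion(s) not present in the gene list: %s",
                    paste(missing_excl, collapse = ", ")), call. = FALSE)
  }
  brain_genes <- normalize_gene_id(brain_genes)
  excluded <- data.frame(gene = character(), reason = character(),
                         stringsAsFactors = FALSE)
  keep <- character()
  for (g in listed) {
    i <- match(g, excl_genes)
    if (!is.na(i)) {
      excluded <- rbind(excluded, data.frame(gene = g, reason = reasons[i]))
    } else if (!(g %in% brain_genes)) {
      excluded <- rbind(excluded, data.frame(gene = g, reason = "not brain-expressed"))
    } else {
      keep <- c(keep, g)
    }
  }
  if (!length(keep))
    stopf("query gene set '%s' is empty after exclusions and expression filtering",
          name)
  stn_log("ingest", "query set '%s': %d genes kept, %d excluded",
          name, length(keep), nrow(excluded))
  structure(list(name = name, genes = keep, excluded = excluded),
            class = "stn_query")
}

#' @export
print.stn_query <- function(x, ...) {
  cat(sprintf("stn_query '%s': %d genes (%d excluded)\n",
              x$name, length(x$genes), nrow(x$excluded)))
  if (nrow(x$excluded)) {
    for (i in seq_len(nrow(x$excluded)))
      cat(sprintf("  - %s: %s\n", x$excluded$gene[i], x$excluded$reason[i]))
  }
  invisible(x)
}
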