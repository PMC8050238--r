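#' Read an expression matrix with sample metadata
#'
#' Reads a genes-by-samples TSV of linear-scale (RPKM-like) expression values
#' together with a sample metadata TSV mapping every sample column to a
#' developmental stage and an anatomical structure.
#'
#' The values file must have a first column named `gene`; every remaining
#' column is a sample. The metadata file must have columns `sample_id`,
#' `stage` and `structure`. Duplicate gene rows are collapsed by keeping the
#' row with the highest mean expression (logged).
#'
#' @param values_path path to the expression TSV.
#' @param metadata_path path to the sample metadata TSV.
#' @return An object of class `stn_expression`: a list with `values`
#'   (numeric matrix, genes x samples) and `samples` (data.frame with
#'   `sample_id`, `stage`, `structure` in column order of `values`).
#' @export
read_expression <- function(values_path, metadata_path) {
  raw <- utils::read.delim(values_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L || names(raw)[1L] != "gene")
    stopf("expression file %s: first column must be named 'gene'", values_path)
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "stage", "structure")
  if (!all(need %in% names(meta)))
    stopf("metadata file %s: missing column(s) %s", metadata_path,
          paste(setdiff(need, names(meta)), collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stopf("metadata file %s: duplicate sample_id(s): %s", metadata_path,
          paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))

  sample_ids <- names(raw)[-1L]
  missing <- setdiff(sample_ids, meta$sample_id)
  if (length(missing))
    stopf("sample column(s) absent from metadata: %s",
          paste(missing, collapse = ", "))

  genes <- normalize_gene_id(raw$gene)
  if (any(!nzchar(genes))) stopf("empty gene symbol at row %d", which(!nzchar(genes))[1L])
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(raw[-1L], is.numeric, logical(1L)))[1L]
    col <- names(raw)[-1L][bad]
    cells <- raw[[bad + 1L]]
    row <- which(suppressWarnings(is.na(as.numeric(cells))) & !is.na(cells))[1L]
    stopf("non-numeric expression value at gene '%s', sample column '%s'",
          if (is.na(row)) "?" else genes[row], col)
  }
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stopf("missing/non-numeric expression value at gene '%s', sample '%s'",
          genes[idx[1L]], sample_ids[idx[2L]])
  }
  if (any(vals < 0) || any(!is.finite(vals)))
    stopf("expression values must be finite and non-negative")
  rownames(vals) <- genes

  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    stn_log("ingest", "collapsing %d duplicate gene row(s) by highest mean: %s",
            length(dup), paste(utils::head(dup, 5L), collapse = ", "))
    means <- rowMeans(vals)
    keep <- !logical(nrow(vals))
    for (g in dup) {
      rows <- which(genes == g)
      keep[rows] <- FALSE
      keep[rows[which.max(means[rows])]] <- TRUE
    }
    vals <- vals[keep, , drop = FALSE]
    genes <- genes[keep]
  }

  meta <- meta[match(sample_ids, meta$sample_id), need, drop = FALSE]
  rownames(meta) <- NULL
  meta$stage <- as.integer(meta$stage)
  meta$structure <- as.character(meta$structure)
  new_stn_expression(vals, meta)
}

new_stn_expression <- function(values, samples) {
  stopifnot(is.matrix(values), ncol(values) == nrow(samples))
  structure(list(values = values, samples = samples), class = "stn_expression")
}

#' Construct an expression object in memory
#'
#' Programmatic counterpart of [read_expression()] with the same validation.
#'
#' @param values numeric genes x samples matrix with gene symbols as row
#'   names, linear scale, finite and non-negative.
#' @param samples data.frame with `sample_id`, `stage`, `structure` matching
#'   the matrix columns (by `sample_id` when column names are present).
#' @return an `stn_expression`.
#' @export
stn_expression <- function(values, samples) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values))) stopf("values must have gene row names")
  rownames(values) <- normalize_gene_id(rownames(values))
  if (anyDuplicated(rownames(values))) stopf("duplicate gene row names")
  if (anyNA(values) || any(values < 0) || any(!is.finite(values)))
    stopf("expression values must be finite and non-negative")
  need <- c("sample_id", "stage", "structure")
  stopifnot(all(need %in% names(samples)))
  if (anyDuplicated(samples$sample_id)) stopf("duplicate sample ids")
  if (!is.null(colnames(values))) {
    idx <- match(colnames(values), samples$sample_id)
    if (anyNA(idx)) stopf("matrix column(s) missing from samples")
    samples <- samples[idx, , drop = FALSE]
  } else {
    colnames(values) <- samples$sample_id
  }
  samples <- samples[, need, drop = FALSE]
  rownames(samples) <- NULL
  samples$stage <- as.integer(samples$stage)
  samples$structure <- as.character(samples$structure)
  new_stn_expression(values, samples)
}

#' @export
print.stn_expression <- function(x, ...) {
  cat(sprintf("stn_expression: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  stages: %s\n", paste(sort(unique(x$samples$stage)), collapse = " ")))
  cat(sprintf("  structures: %d distinct\n", length(unique(x$samples$structure))))
  invisible(x)
}

#' Write an expression matrix and metadata to TSV
#'
#' Fixture writer: the inverse of [read_expression()]. Round-tripping a valid
#' object through `write_expression()` / `read_expression()` is lossless.
#'
#' @param x an `stn_expression`.
#' @param values_path,metadata_path output paths.
#' @return invisibly, the two paths.
#' @export
write_expression <- function(x, values_path, metadata_path) {
  stopifnot(inherits(x, "stn_expression"))
  df <- data.frame(gene = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, values_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$samples, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(values_path, metadata_path))
}

#' Expression filter parameters
#'
#' Thresholds for the brain-expression filter. A gene is dropped when its
#' log2 intensity, `log2(x + log2_offset)`, stays below `log2_intensity_min`
#' in every sample, or (default `logic = "or"`) when the coefficient of
#' variation of its linear values falls below `cv_min`.
#'
#' @param log2_intensity_min minimum log2 intensity; default 0.4.
#' @param cv_min minimum coefficient of variation (population sd / mean) on
#'   the linear scale; default 0.07.
#' @param log2_offset pseudo-count added before the log2 transform; default 1.
#' @param logic `"or"` (drop on either criterion, default) or `"and"`.
#' @return a list of class `stn_filter_params`.
#' @export
expression_filter_params <- function(log2_intensity_min = 0.4, cv_min = 0.07,
                                     log2_offset = 1, logic = c("or", "and")) {
  logic <- match.arg(logic)
  stopifnot(is.finite(log2_intensity_min), is.finite(cv_min), log2_offset > 0)
  structure(list(log2_intensity_min = log2_intensity_min, cv_min = cv_min,
                 log2_offset = log2_offset, logic = logic),
            class = "stn_filter_params")
}

#' Filter to brain-expressed genes
#'
#' Removes low-intensity and low-variability genes. Intensity is assessed on
#' `log2(x + offset)`; the coefficient of variation (population standard
#' deviation over mean) on the linear values, with the CV of an all-zero gene
#' defined as 0. Retained genes keep their original order.
#'
#' @param x an `stn_expression`.
#' @param params an [expression_filter_params()] object.
#' @return list with `expression` (filtered `stn_expression`) and `removed`
#'   (data.frame `gene`, `reason`).
#' @export
filter_brain_expressed <- function(x, params = expression_filter_params()) {
  stopifnot(inherits(x, "stn_expression"), inherits(params, "stn_filter_params"))
  if (nrow(x$values) == 0L) stopf("empty expression matrix")
  v <- x$values
  low_int <- apply(log2(v + params$log2_offset) < params$log2_intensity_min,
                   1L, all)
  mu <- rowMeans(v)
  sdev <- sqrt(rowMeans(v^2) - mu^2)
  sdev[sdev < 0] <- 0       # numerical guard
  cv <- ifelse(mu == 0, 0, sdev / mu)
  low_cv <- cv < params$cv_min
  drop <- if (params$logic == "or") low_int | low_cv else low_int & low_cv
  reason <- character(sum(drop))
  di <- low_int[drop]; dc <- low_cv[drop]
  reason[di & dc] <- "low intensity; low CV"
  reason[di & !dc] <- "low intensity"
  reason[!di & dc] <- "low CV"
  removed <- data.frame(gene = rownames(v)[drop], reason = reason,
                        stringsAsFactors = FALSE)
  if (nrow(removed))
    stn_log("ingest", "expression filter removed %d of %d genes",
            nrow(removed), nrow(v))
  list(expression = new_stn_expression(v[!drop, , drop = FALSE], x$samples),
       removed = removed)
}
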