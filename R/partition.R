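#' Default spatiotemporal scheme
#'
#' A surrogate eight-period / four-region scheme over developmental stage
#' codes 1-13 and the sixteen standard developmental-transcriptome structure
#' acronyms. Regions follow the usual anatomical grouping: R1 parietal,
#' temporal and occipital cortex; R2 frontal cortex; R3 amygdala,
#' hippocampus and striatum; R4 mediodorsal thalamus and cerebellar cortex.
#' Period boundaries are a uniform surrogate; supply the authoritative scheme
#' (e.g. via [read_scheme()]) for real-data runs.
#'
#' @return list with `periods` and `regions`, each a named list mapping a
#'   label to its stage / structure codes.
#' @export
default_scheme <- function() {
  list(
    periods = list(
      P1 = c(1L, 2L), P2 = 3L, P3 = 4L, P4 = 5L,
      P5 = c(6L, 7L), P6 = c(8L, 9L), P7 = c(10L, 11L), P8 = c(12L, 13L)),
    regions = list(
      R1 = c("IPC", "A1C", "STC", "ITC", "V1C"),
      R2 = c("OFC", "DFC", "VFC", "MFC", "M1C", "S1C"),
      R3 = c("AMY", "HIP", "STR"),
      R4 = c("MD", "CBC")))
}

#' Read a period/region scheme file
#'
#' YAML with two top-level blocks, `periods:` and `regions:`, each mapping a
#' label to a list of stage codes / structure codes.
#'
#' @param path YAML file path.
#' @return scheme list as in [default_scheme()].
#' @export
read_scheme <- function(path) {
  s <- yaml::read_yaml(path)
  if (!all(c("periods", "regions") %in% names(s)))
    stopf("scheme file %s: need 'periods:' and 'regions:' blocks", path)
  s$periods <- lapply(s$periods, as.integer)
  s$regions <- lapply(s$regions, as.character)
  s[c("periods", "regions")]
}

#' Write a scheme file
#' @param scheme list as from [default_scheme()].
#' @param path output YAML path.
#' @return invisibly, `path`.
#' @export
write_scheme <- function(scheme, path) {
  yaml::write_yaml(scheme, path)
  invisible(path)
}

check_disjoint <- function(defs, what) {
  all_codes <- unlist(defs, use.names = FALSE)
  dup <- unique(all_codes[duplicated(all_codes)])
  if (length(dup)) {
    owners <- vapply(dup, function(d) {
      paste(names(defs)[vapply(defs, function(s) d %in% s, logical(1L))],
            collapse = "+")
    }, character(1L))
    stopf("overlapping %s definitions: %s", what,
          paste(sprintf("%s in %s", dup, owners), collapse = "; "))
  }
  if (any(lengths(defs) == 0L)) stopf("empty %s definition", what)
}

#' Assign samples to spatiotemporal intervals
#'
#' Maps each sample to the interval `<period><region>` containing its
#' (stage, structure). Samples whose stage or structure falls outside the
#' scheme are recorded as unassigned (this is how dropping of terminal
#' stages happens here). Every period x region combination appears as a key,
#' possibly with zero samples.
#'
#' @param samples data.frame with `sample_id`, `stage`, `structure` (e.g. the
#'   `samples` element of an `stn_expression`).
#' @param scheme list with `periods` and `regions` ([default_scheme()]).
#' @return object of class `stn_partition`: list with `intervals` (named list
#'   of sample-id vectors, one per interval key), `excluded` (named character
#'   of reasons, initially empty), `unassigned` (character sample ids) and
#'   the `scheme`.
#' @export
assign_samples <- function(samples, scheme = default_scheme()) {
  stopifnot(all(c("sample_id", "stage", "structure") %in% names(samples)))
  check_disjoint(scheme$periods, "period")
  check_disjoint(scheme$regions, "region")

  stage2p <- stats::setNames(rep(names(scheme$periods), lengths(scheme$periods)),
                             unlist(scheme$periods))
  struct2r <- stats::setNames(rep(names(scheme$regions), lengths(scheme$regions)),
                              unlist(scheme$regions))
  p <- stage2p[as.character(samples$stage)]
  r <- struct2r[as.character(samples$structure)]
  key <- ifelse(is.na(p) | is.na(r), NA_character_, paste0(p, r))

  keys <- as.vector(outer(names(scheme$periods), names(scheme$regions), paste0))
  intervals <- stats::setNames(
    lapply(keys, function(k) samples$sample_id[!is.na(key) & key == k]), keys)
  unassigned <- samples$sample_id[is.na(key)]
  if (length(unassigned))
    stn_log("partition", "%d sample(s) outside the scheme left unassigned",
            length(unassigned))
  structure(list(intervals = intervals,
                 excluded = stats::setNames(character(), character()),
                 unassigned = unassigned, scheme = scheme),
            class = "stn_partition")
}

#' Exclude data-poor intervals
#'
#' Moves intervals with fewer than `min_samples` samples into the excluded
#' set, operationalizing the removal of intervals lacking sequencing data.
#' Idempotent.
#'
#' @param partition an `stn_partition`.
#' @param min_samples minimum sample count (>= 2); default 6, below which a
#'   rank correlation threshold of 0.5 is not meaningful.
#' @return the modified `stn_partition`.
#' @export
exclude_sparse_intervals <- function(partition, min_samples = 6L) {
  stopifnot(inherits(partition, "stn_partition"), min_samples >= 2L)
  sizes <- lengths(partition$intervals)
  drop <- names(sizes)[sizes < min_samples]
  for (k in drop) {
    partition$excluded[[k]] <-
      sprintf("insufficient samples (n=%d < %d)", sizes[[k]], min_samples)
  }
  partition$intervals[drop] <- NULL
  if (length(drop))
    stn_log("partition", "excluded %d sparse interval(s): %s",
            length(drop), paste(drop, collapse = ", "))
  partition
}

#' @export
print.stn_partition <- function(x, ...) {
  cat(sprintf("stn_partition: %d intervals (%d excluded, %d unassigned samples)\n",
              length(x$intervals), length(x$excluded), length(x$unassigned)))
  sizes <- lengths(x$intervals)
  cat(sprintf("  samples/interval: min %s, median %s, max %s\n",
              if (length(sizes)) min(sizes) else NA,
              if (length(sizes)) stats::median(sizes) else NA,
              if (length(sizes)) max(sizes) else NA))
  if (length(x$excluded))
    cat(sprintf("  excluded: %s\n",
                paste(sprintf("%s (%s)", names(x$excluded), x$excluded),
                      collapse = "; ")))
  invisible(x)
}
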