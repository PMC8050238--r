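#' @keywords internal
"_PACKAGE"

## Stage-tagged logging. All pipeline chatter goes through message() so callers
## can suppressMessages(); tags make the emitting stage greppable in run logs.
stn_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Normalize gene symbols
#'
#' Gene identifiers are compared as uppercased, whitespace-stripped strings
#' throughout the package; expression sources and interaction databases
#' disagree on symbol case.
#'
#' @param x character vector of gene symbols.
#' @return normalized character vector.
#' @examples
#' normalize_gene_id(c(" gtf2i ", "Rfc2"))
#' @export
normalize_gene_id <- function(x) {
  if (!is.character(x)) x <- as.character(x)
  toupper(trimws(x))
}

## Canonical unordered pair representation: a <= b lexicographically.
## Returns a data.frame with columns a, b (character), self-pairs NOT removed.
canonical_pairs <- function(a, b) {
  a <- normalize_gene_id(a)
  b <- normalize_gene_id(b)
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  data.frame(a = a, b = b, stringsAsFactors = FALSE)
}

pair_key <- function(a, b) paste(a, b, sep = "\r")

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## Population standard deviation (divides by n, not n-1).
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
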