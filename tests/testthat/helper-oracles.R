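## Independent oracles used across the suite. Deliberately naive: each one
## recomputes its quantity from first principles, sharing no code with the
## package internals it checks.

## Fisher's exact test by exhaustive enumeration over all tables with the
## observed margins. tab: 2x2 matrix (rows: test/control; cols: yes/no).
oracle_fisher <- function(tab, alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  r1 <- sum(tab[1L, ]); r2 <- sum(tab[2L, ]); c1 <- sum(tab[, 1L])
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  support <- lo:hi
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) -
    lchoose(r1 + r2, c1)
  prob <- exp(logp)
  a <- tab[1L, 1L]
  if (alternative == "greater") {
    sum(prob[support >= a])
  } else {
    sum(prob[prob <= prob[support == a] * (1 + 1e-07)])
  }
}

## Spearman correlation from first principles: midranks computed by
## counting, then the Pearson product-moment formula.
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1L))
  }
  rx <- midrank(x); ry <- midrank(y)
  sx <- sqrt(sum((rx - mean(rx))^2)); sy <- sqrt(sum((ry - mean(ry))^2))
  if (sx == 0 || sy == 0) return(NA_real_)
  sum((rx - mean(rx)) * (ry - mean(ry))) / (sx * sy)
}

## All-pairs shortest paths by plain BFS on an adjacency list, then the
## diameter-normalized radiality formula per connected component.
oracle_radiality <- function(edges, nodes) {
  adj <- lapply(stats::setNames(nm = nodes), function(n) {
    unique(c(edges$b[edges$a == n], edges$a[edges$b == n]))
  })
  bfs <- function(src) {
    d <- stats::setNames(rep(Inf, length(nodes)), nodes)
    d[src] <- 0
    frontier <- src
    while (length(frontier)) {
      nxt <- character()
      for (v in frontier) for (w in adj[[v]]) if (!is.finite(d[w])) {
        d[w] <- d[v] + 1
        nxt <- c(nxt, w)
      }
      frontier <- unique(nxt)
    }
    d
  }
  D <- do.call(rbind, lapply(nodes, bfs))
  rownames(D) <- nodes
  rad <- stats::setNames(rep(0, length(nodes)), nodes)
  seen <- character()
  for (n in nodes) {
    if (n %in% seen) next
    comp <- nodes[is.finite(D[n, ])]
    seen <- c(seen, comp)
    if (length(comp) < 2L) next
    sub <- D[comp, comp, drop = FALSE]
    diam <- max(sub)
    for (v in comp) rad[v] <- (diam + 1 - mean(sub[v, colnames(sub) != v])) / diam
  }
  rad
}

## Benjamini-Hochberg from the step-up definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    pi <- p[ord[i]]
    js <- which(p[ord] >= pi - 1e-15)
    q[ord[i]] <- min(1, min(m * p[ord[js]] / js))
  }
  q
}

## Upper-tail hypergeometric P(X >= k) by direct summation.
oracle_hyper_tail <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

## Small random simple graph as a canonical edge data.frame.
random_edges <- function(n_nodes, n_edges, prefix = "N") {
  nodes <- sprintf("%s%02d", prefix, seq_len(n_nodes))
  pairs <- t(utils::combn(nodes, 2L))
  pick <- sample.int(nrow(pairs), min(n_edges, nrow(pairs)))
  data.frame(a = pairs[pick, 1L], b = pairs[pick, 2L],
             stringsAsFactors = FALSE)
}

## Tiny in-memory expression fixture: matrix of linear values with simple
## metadata, one structure per sample unless given.
tiny_expression <- function(values, stages = NULL, structures = NULL) {
  n <- ncol(values)
  samples <- data.frame(
    sample_id = colnames(values) %||% sprintf("s%d", seq_len(n)),
    stage = stages %||% rep(1L, n),
    structure = structures %||% rep("AMY", n))
  if (is.null(colnames(values))) colnames(values) <- samples$sample_id
  stn_expression(values, samples)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
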