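# Independent oracles, deliberately built from scratch (plain adjacency
# lists, recursive enumeration, O(n^2) pair counting) so they share no code
# path with the package implementation.

# Adjacency list from a raw edge data frame (node_a/node_b columns),
# normalized and deduplicated the same way the loader documents.
oracle_adjacency <- function(edges) {
  a <- tolower(trimws(edges$node_a))
  b <- tolower(trimws(edges$node_b))
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  key <- ifelse(a < b, paste(a, b), paste(b, a))
  first <- !duplicated(key)
  a <- a[first]; b <- b[first]
  nodes <- sort(unique(c(a, b)))
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_along(a)) {
    adj[[a[i]]] <- c(adj[[a[i]]], b[i])
    adj[[b[i]]] <- c(adj[[b[i]]], a[i])
  }
  lapply(adj, function(x) sort(unique(x)))
}

# Exhaustive recursive enumeration of simple paths with 1..max_hops edges.
oracle_enumerate <- function(adj, d, t, max_hops = 4) {
  d <- tolower(trimws(d)); t <- tolower(trimws(t))
  out <- list()
  if (!d %in% names(adj) || !t %in% names(adj) || d == t) return(out)
  walk <- function(path) {
    tail <- path[length(path)]
    if (tail == t && length(path) >= 2) {
      out[[length(out) + 1]] <<- path
      return()
    }
    if (length(path) - 1 >= max_hops) return()
    for (nb in adj[[tail]]) {
      if (!nb %in% path) walk(c(path, nb))
    }
  }
  walk(d)
  out
}

# Path weight recomputed from an explicit degree table.
oracle_path_weight <- function(adj, path) {
  deg <- lengths(adj)
  n_v <- length(adj)
  hops <- length(path) - 1
  tot <- 0
  for (i in seq_len(hops)) tot <- tot + (deg[[path[i]]] + deg[[path[i + 1]]]) / (2 * n_v)
  tot / hops
}

oracle_combined <- function(w, hops) {
  if (hops == 1) 1 else min(1, max(0, w / log(1 + hops)))
}

# End-to-end brute-force pair score.
oracle_kg_score <- function(edges, d, t, max_hops = 4) {
  adj <- oracle_adjacency(edges)
  paths <- oracle_enumerate(adj, d, t, max_hops)
  if (length(paths) == 0) return(0)
  max(vapply(paths, function(p)
    oracle_combined(oracle_path_weight(adj, p), length(p) - 1), 0))
}

# Random drug-gene edge table; guarantees at least one edge.
random_edge_table <- function(seed, n_drugs = 5, n_genes = 7, p = 0.25) {
  set.seed(seed)
  drugs <- sprintf("d%02d", seq_len(n_drugs))
  genes <- sprintf("g%02d", seq_len(n_genes))
  grid <- expand.grid(node_a = drugs, node_b = genes,
                      stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(grid)) < p
  if (!any(keep)) keep[sample.int(length(keep), 1)] <- TRUE
  data.frame(node_a = grid$node_a[keep], kind_a = "drug",
             node_b = grid$node_b[keep], kind_b = "gene",
             stringsAsFactors = FALSE)
}

# Concordant-pair AUROC: all pos x neg comparisons, half credit for ties.
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

expect_format_error <- function(expr) {
  expect_error(expr, class = "dtifuse_format_error")
}
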