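#' Knowledge-graph evidence channel
#'
#' The knowledge-graph (KG) channel scores a drug--target pair by enumerating
#' simple paths between the two nodes in an undirected drug--gene interaction
#' graph and weighting each path by the connectivity of the nodes it
#' traverses. For a path p with hops n1-n2-...-n(|p|+1),
#'
#'   w(p) = (1/|p|) * sum_i (deg(n_i) + deg(n_{i+1})) / (2|V|)
#'
#' i.e. the mean over the path's edges of the normalized endpoint degrees.
#' The pair score is
#'
#'   score(d, t) = 0                          if d or t absent, or no path
#'               = 1                          if a direct edge d-t exists
#'               = max_p w(p) / ln(1 + |p|)   otherwise, clamped to [0, 1]
#'
#' so evidence decays with path length and grows with the prominence of the
#' intermediate nodes. Paths are capped at `max_hops` edges (default 4).
#'
#' @name kg_engine
NULL

kg_kinds <- c("drug", "gene")

#' Build a knowledge graph from an edge table
#'
#' Accepts a data frame with columns `node_a, kind_a, node_b, kind_b` and an
#' optional `source` column tagging the originating database. Identifiers are
#' normalized with [normalize_id()]; duplicate edges collapse to one with
#' their source tags merged; self-loops are rejected.
#'
#' @param edges data frame of edges as above.
#' @param on_self_loop `"warn"` (drop the row with a warning) or `"error"`.
#' @return an object of class `dti_kg` wrapping an [igraph::graph] with
#'   vertex attributes `name` (normalized id), `label` (display form) and
#'   `kind`, and edge attribute `sources`.
#' @export
kg_graph <- function(edges, on_self_loop = c("warn", "error")) {
  on_self_loop <- match.arg(on_self_loop)
  need <- c("node_a", "kind_a", "node_b", "kind_b")
  if (!all(need %in% names(edges)))
    dg_parse_error(paste0("edge table must have columns ",
                          paste(need, collapse = ", ")))
  if (nrow(edges) == 0) {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    return(structure(list(graph = g), class = "dti_kg"))
  }

  bad_kind <- !(edges$kind_a %in% kg_kinds) | !(edges$kind_b %in% kg_kinds)
  if (any(bad_kind))
    dg_parse_error(paste0("node kind must be one of {drug, gene}; offending row(s): ",
                          paste(which(bad_kind), collapse = ", ")))

  a <- normalize_id(edges$node_a)
  b <- normalize_id(edges$node_b)
  if (any(a == "" | b == ""))
    dg_parse_error("empty node identifier after trimming")

  loops <- a == b
  if (any(loops)) {
    if (on_self_loop == "error")
      dg_parse_error(paste0("self-loop at row(s): ", paste(which(loops), collapse = ", ")))
    warning(sprintf("dropping %d self-loop row(s)", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
    a <- a[!loops]; b <- b[!loops]
  }
  if (length(a) == 0) {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    return(structure(list(graph = g), class = "dti_kg"))
  }

  ids    <- c(a, b)
  labels <- trimws(c(edges$node_a, edges$node_b))
  kinds  <- c(edges$kind_a, edges$kind_b)
  first  <- !duplicated(ids)
  vdf <- data.frame(name = ids[first], label = labels[first],
                    kind = kinds[first], stringsAsFactors = FALSE)
  conflict <- tapply(kinds, ids, function(k) length(unique(k)) > 1)
  if (any(conflict))
    dg_parse_error(paste0("conflicting node kind for: ",
                          paste(names(conflict)[conflict], collapse = ", ")))

  src <- if ("source" %in% names(edges)) as.character(edges$source) else rep(NA_character_, length(a))
  # canonical unordered key so duplicates collapse regardless of orientation
  key <- ifelse(a < b, paste(a, b, sep = "\u0001"), paste(b, a, sep = "\u0001"))
  merged <- tapply(src, key, function(s) {
    s <- sort(unique(s[!is.na(s) & s != ""]))
    if (length(s) == 0) NA_character_ else paste(s, collapse = ";")
  })
  ukey <- names(merged)
  parts <- strsplit(ukey, "\u0001", fixed = TRUE)
  edf <- data.frame(from = vapply(parts, `[`, "", 1),
                    to   = vapply(parts, `[`, "", 2),
                    sources = as.character(merged), stringsAsFactors = FALSE)

  g <- igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
  structure(list(graph = g), class = "dti_kg")
}

#' Load a knowledge graph from a delimited edge-list file
#'
#' The file must be UTF-8 with a header `node_a,kind_a,node_b,kind_b[,source]`;
#' tab- and comma-separated files are both accepted (the delimiter is sniffed
#' from the header line).
#'
#' @param path path to the edge-list file.
#' @param on_self_loop passed to [kg_graph()].
#' @param quiet suppress the node/edge count message.
#' @return a `dti_kg` object.
#' @export
load_graph <- function(path, on_self_loop = "warn", quiet = FALSE) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    g <- kg_graph(data.frame(node_a = character(), kind_a = character(),
                             node_b = character(), kind_b = character()))
    if (!quiet) message("loaded graph: 0 nodes, 0 edges")
    return(g)
  }
  sep <- if (grepl(",", lines[[1]], fixed = TRUE)) "," else "\t"
  fields <- strsplit(lines, sep, fixed = TRUE)
  hdr <- trimws(fields[[1]])
  if (!all(c("node_a", "kind_a", "node_b", "kind_b") %in% hdr))
    dg_parse_error("header must contain node_a, kind_a, node_b, kind_b")
  rows <- fields[-1]
  if (length(rows) == 0) {
    g <- kg_graph(data.frame(node_a = character(), kind_a = character(),
                             node_b = character(), kind_b = character()))
    if (!quiet) message("loaded graph: 0 nodes, 0 edges")
    return(g)
  }
  nf <- lengths(rows)
  bad <- which(nf != length(hdr))
  if (length(bad) > 0)
    dg_parse_error(sprintf("malformed row at line %d: expected %d fields, got %d",
                           bad[1] + 1L, length(hdr), nf[bad[1]]))
  m <- do.call(rbind, rows)
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- hdr
  df[] <- lapply(df, trimws)
  g <- kg_graph(df, on_self_loop = on_self_loop)
  if (!quiet)
    message(sprintf("loaded graph: %d nodes, %d edges", kg_vcount(g), kg_ecount(g)))
  g
}

#' @export
print.dti_kg <- function(x, ...) {
  cat(sprintf("<dti_kg> %d nodes (%d drugs, %d genes), %d edges\n",
              kg_vcount(x),
              sum(igraph::V(x$graph)$kind == "drug"),
              sum(igraph::V(x$graph)$kind == "gene"),
              kg_ecount(x)))
  invisible(x)
}

#' Node and edge counts, degrees
#' @param g a `dti_kg`.
#' @return integer count.
#' @export
kg_vcount <- function(g) igraph::vcount(g$graph)

#' @rdname kg_vcount
#' @export
kg_ecount <- function(g) igraph::ecount(g$graph)

#' @rdname kg_vcount
#' @param node node identifier (normalized before lookup).
#' @export
kg_degree <- function(g, node) {
  id <- normalize_id(node)
  if (!kg_has_node(g, id)) dg_input_error(sprintf("node '%s' not in graph", node))
  unname(igraph::degree(g$graph, id))
}

kg_has_node <- function(g, id) normalize_id(id) %in% igraph::V(g$graph)$name

kg_label <- function(g, id) {
  igraph::V(g$graph)$label[match(id, igraph::V(g$graph)$name)]
}

#' Enumerate simple paths between two nodes
#'
#' Returns every simple (node-repetition-free) path between `d` and `t` with
#' between 1 and `max_hops` edges, in a deterministic order: ascending hop
#' count, ties broken by lexicographic node sequence. Nodes absent from the
#' graph yield an empty list.
#'
#' @param g a `dti_kg`.
#' @param d,t node identifiers.
#' @param max_hops maximum number of edges per path (default 4).
#' @return list of character vectors of normalized node identifiers.
#' @export
enumerate_paths <- function(g, d, t, max_hops = 4) {
  if (max_hops < 1) dg_config_error("max_hops must be >= 1")
  d <- normalize_id(d); t <- normalize_id(t)
  if (!kg_has_node(g, d) || !kg_has_node(g, t) || d == t) return(list())
  ps <- igraph::all_simple_paths(g$graph, from = d, to = t,
                                 cutoff = max_hops, mode = "all")
  paths <- lapply(ps, function(p) igraph::V(g$graph)$name[as.integer(p)])
  if (length(paths) == 0) return(paths)
  keys <- vapply(paths, paste, "", collapse = "\u0001")
  paths[dg_order(lengths(paths), keys)]
}

#' Degree-weighted path weight
#'
#' Computes the mean over the path's edges of
#' `(deg(n_i) + deg(n_{i+1})) / (2 |V|)`: paths through well-connected nodes
#' weigh more, normalized by graph size.
#'
#' @param g a `dti_kg`.
#' @param p character vector of node identifiers forming a path in `g`.
#' @return numeric weight in (0, 1) for valid paths.
#' @export
path_weight <- function(g, p) {
  p <- normalize_id(p)
  if (length(p) < 2) dg_contract_error("a path needs at least 2 nodes")
  if (anyDuplicated(p)) dg_contract_error("path repeats a node")
  if (!all(p %in% igraph::V(g$graph)$name))
    dg_contract_error("path contains a node not in the graph")
  n_v <- kg_vcount(g)
  if (n_v < 2) dg_contract_error("graph must have at least 2 nodes")
  adj <- igraph::get_edge_ids(g$graph, rbind(p[-length(p)], p[-1]))
  if (any(adj == 0)) dg_contract_error("consecutive path nodes are not connected")
  deg <- igraph::degree(g$graph, p)
  hops <- length(p) - 1
  sum((deg[-length(deg)] + deg[-1]) / (2 * n_v)) / hops
}

# Path score combining weight and length: direct edges pin to 1, longer paths
# are damped by ln(1 + hops), and the result is clamped into [0, 1].
kg_combined_score <- function(weight, hops) {
  if (hops == 1) return(1)
  min(1, max(0, weight / log1p(hops)))
}

#' Score a drug--target pair from the knowledge graph
#'
#' Implements the path-based DTI score: 0 when either node is absent or no
#' path of at most `max_hops` edges exists, 1 for a direct interaction, and
#' otherwise the maximum over simple paths of `w(p) / ln(1 + |p|)` clamped to
#' `[0, 1]`. The returned evidence carries every scored path (descending
#' score; ties to the shorter, then lexicographically smaller path) and a
#' human-readable reason naming the best path.
#'
#' @param g a `dti_kg`.
#' @param d,t drug and target identifiers.
#' @param max_hops maximum path length in edges (default 4).
#' @param path_cap cap on the number of paths retained in the evidence record
#'   (default 10000); hitting it flags the record as truncated.
#' @return object of class `kg_evidence`: fields `drug`, `target`, `score`,
#'   `best_path`, `all_paths`, `truncated`, `reason`.
#' @export
dti_kg_score <- function(g, d, t, max_hops = 4, path_cap = 10000) {
  if (max_hops < 1) dg_config_error("max_hops must be >= 1")
  dn <- normalize_id(d); tn <- normalize_id(t)
  ev <- structure(list(drug = as.character(d), target = as.character(t),
                       score = 0, best_path = NULL, all_paths = list(),
                       truncated = FALSE, reason = ""),
                  class = "kg_evidence")
  if (!kg_has_node(g, dn) || !kg_has_node(g, tn)) {
    missing <- c(d, t)[!c(kg_has_node(g, dn), kg_has_node(g, tn))]
    ev$reason <- sprintf("No knowledge-graph evidence: %s not in graph.",
                         paste(missing, collapse = " and "))
    return(ev)
  }
  paths <- enumerate_paths(g, dn, tn, max_hops = max_hops)
  if (length(paths) == 0) {
    ev$reason <- sprintf("No path between %s and %s within %d hops.",
                         d, t, max_hops)
    return(ev)
  }
  scored <- lapply(paths, function(p) {
    w <- path_weight(g, p)
    hops <- length(p) - 1
    list(path = p, display = kg_label(g, p), hops = hops, weight = w,
         combined_score = kg_combined_score(w, hops))
  })
  sc   <- vapply(scored, `[[`, 0, "combined_score")
  hops <- vapply(scored, `[[`, 0, "hops")
  keys <- vapply(scored, function(s) paste(s$path, collapse = "\u0001"), "")
  ord <- dg_order(-sc, hops, keys)
  scored <- scored[ord]
  if (length(scored) > path_cap) {
    warning(sprintf("path cap (%d) hit for %s-%s; evidence truncated, score is a lower bound",
                    path_cap, d, t))
    scored <- scored[seq_len(path_cap)]
    ev$truncated <- TRUE
  }
  ev$all_paths <- scored
  ev$best_path <- scored[[1]]
  ev$score <- scored[[1]]$combined_score
  show <- scored[seq_len(min(5L, length(scored)))]
  lines <- vapply(seq_along(show), function(k) {
    s <- show[[k]]
    sprintf("Path %d: %s (score: %.3f)", k,
            paste(kg_label(g, s$path), collapse = " → "),
            s$combined_score)
  }, "")
  ev$reason <- paste(
    c(sprintf("Found %d path%s between %s and %s. Best score: %.3f",
              length(scored), if (length(scored) == 1) "" else "s",
              d, t, ev$score),
      lines,
      if (ev$truncated) "(path list truncated at cap; score is a lower bound)"),
    collapse = "\n")
  ev
}

#' @export
print.kg_evidence <- function(x, ...) {
  cat(sprintf("<kg_evidence> %s - %s: score %.6g\n", x$drug, x$target, x$score))
  cat(x$reason, "\n")
  invisible(x)
}
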