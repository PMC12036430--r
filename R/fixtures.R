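#' Seeded fixture generators
#'
#' Generators for synthetic knowledge graphs with planted relations, search
#' result sets with planted indicator-count profiles, predictor lookup
#' tables, and labeled pair files. Every generator is a pure function of its
#' spec (seed included): identical specs yield byte-identical artifacts, and
#' the planted ground truth is recovered exactly by the corresponding engine
#' (a planted direct edge scores 1.0; a planted k-hop chain has best-path
#' hop count k; a planted indicator profile realizes a known D).
#'
#' @name fixtures
NULL

#' Fixture specification
#'
#' @param seed integer RNG seed.
#' @param n_drugs,n_genes counts of background drug and gene nodes.
#' @param edge_density probability in (0,1] of each background drug-gene
#'   edge.
#' @param planted_pairs list of `list(drug=, target=, relation=)` with
#'   relation one of `"direct"`, `"k_hop:<k>"`, `"none"`.
#' @param search_profile list of `c(pair_hits, positive_hits, strong_hits)`
#'   per planted pair (counts among `n` results).
#' @param n number of search results per pair fixture (default 10).
#' @param label_rule named vector mapping relation class to 0/1 label
#'   (default: direct and k_hop are 1, none is 0).
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1, n_drugs = 6, n_genes = 8,
                         edge_density = 0.15, planted_pairs = list(),
                         search_profile = list(), n = 10,
                         label_rule = c(direct = 1, k_hop = 1, none = 0)) {
  if (n_drugs < 1 || n_genes < 1) dg_spec_error("need at least one drug and one gene")
  if (edge_density <= 0 || edge_density > 1)
    dg_spec_error("edge_density must be in (0,1]")
  for (pp in planted_pairs) {
    if (!pp$relation %in% c("direct", "none") &&
        !grepl("^k_hop:[0-9]+$", pp$relation))
      dg_spec_error(sprintf("unknown planted relation '%s'", pp$relation))
  }
  for (prof in search_profile) {
    if (length(prof) != 3 || any(prof < 0) || any(prof > n))
      dg_spec_error("search profile counts must be in [0, n]")
  }
  structure(list(seed = seed, n_drugs = n_drugs, n_genes = n_genes,
                 edge_density = edge_density, planted_pairs = planted_pairs,
                 search_profile = search_profile, n = n,
                 label_rule = label_rule),
            class = "fixture_spec")
}

relation_hops <- function(relation) {
  if (relation == "direct") return(1L)
  if (relation == "none") return(NA_integer_)
  as.integer(sub("^k_hop:", "", relation))
}

#' Generate a knowledge graph with planted relations
#'
#' Planted `direct` pairs get an edge; planted `k_hop:k` pairs get a
#' node-disjoint chain of exactly k edges through fresh intermediate nodes
#' (alternating gene/drug kinds), making k the shortest path length by
#' construction; planted `none` pairs stay disconnected. Background
#' drug-gene edges are sampled at `edge_density` strictly among
#' non-planted nodes so they can never create shortcuts through a planted
#' chain.
#'
#' @param spec a [fixture_spec()].
#' @return list with `graph` (a `dti_kg`), `edges` (the edge data frame) and
#'   `truth` (data frame: drug, target, relation, expected_hops).
#' @export
make_graph <- function(spec) {
  drugs <- sprintf("BD%02d", seq_len(spec$n_drugs))
  genes <- sprintf("BG%02d", seq_len(spec$n_genes))
  edges <- data.frame(node_a = character(), kind_a = character(),
                      node_b = character(), kind_b = character(),
                      source = character(), stringsAsFactors = FALSE)
  add_edge <- function(a, ka, b, kb, src = "planted") {
    rbind(edges, data.frame(node_a = a, kind_a = ka, node_b = b, kind_b = kb,
                            source = src, stringsAsFactors = FALSE))
  }
  truth <- data.frame(drug = character(), target = character(),
                      relation = character(), expected_hops = integer(),
                      stringsAsFactors = FALSE)
  chain_counter <- 0L
  for (pp in spec$planted_pairs) {
    hops <- relation_hops(pp$relation)
    truth <- rbind(truth, data.frame(drug = pp$drug, target = pp$target,
                                     relation = pp$relation,
                                     expected_hops = hops,
                                     stringsAsFactors = FALSE))
    if (pp$relation == "none") next
    if (hops > spec$n_drugs + spec$n_genes)
      dg_spec_error("planted chain longer than the node budget")
    if (hops == 1L) {
      edges <- add_edge(pp$drug, "drug", pp$target, "gene")
      next
    }
    # fresh intermediates, alternating kinds starting from a gene
    chain_counter <- chain_counter + 1L
    mids <- sprintf("CH%02dN%02d", chain_counter, seq_len(hops - 1L))
    kinds <- rep(c("gene", "drug"), length.out = hops - 1L)
    nodes <- c(pp$drug, mids, pp$target)
    nkinds <- c("drug", kinds, "gene")
    for (i in seq_len(hops)) {
      edges <- add_edge(nodes[i], nkinds[i], nodes[i + 1], nkinds[i + 1])
    }
  }
  planted_nodes <- normalize_id(unique(c(
    vapply(spec$planted_pairs, `[[`, "", "drug"),
    vapply(spec$planted_pairs, `[[`, "", "target"),
    edges$node_a, edges$node_b)))
  bg_drugs <- drugs[!normalize_id(drugs) %in% planted_nodes]
  bg_genes <- genes[!normalize_id(genes) %in% planted_nodes]
  edges <- with_local_seed(spec$seed, {
    for (d in bg_drugs) {
      for (g in bg_genes) {
        if (stats::runif(1) < spec$edge_density)
          edges <- add_edge(d, "drug", g, "gene", src = "background")
      }
    }
    edges
  })
  list(graph = kg_graph(edges), edges = edges, truth = truth)
}

# Filler sentences free of the default keyword vocabulary and of planted
# names, so indicator counts depend only on the controlled insertions.
filler_sentence <- function(i) {
  sprintf("Entry %d from a kinase pharmacology report; assay context and methods described elsewhere.", i)
}

#' Generate a search fixture with planted indicator counts
#'
#' For a pair and a profile `c(pair_hits, positive_hits, strong_hits)` over
#' `n` results, emits results in which exactly `pair_hits` contain both
#' names, exactly `positive_hits` contain one positive keyword and exactly
#' `strong_hits` one strong keyword (keywords cycled deterministically from
#' the seeded spec). The resulting totals are known in advance:
#' T = sum(profile), M = 3n, D = round(T/M, 2).
#'
#' @param spec a [fixture_spec()] whose `planted_pairs` and `search_profile`
#'   align index-by-index.
#' @param path optional path: write the fixture mapping as JSON.
#' @return named list mapping query string -> list of result records; the
#'   fixture format consumed by [fixture_search_backend()].
#' @export
make_search_fixture <- function(spec, path = NULL) {
  if (length(spec$search_profile) != length(spec$planted_pairs))
    dg_spec_error("need one search profile per planted pair")
  mapping <- list()
  for (j in seq_along(spec$planted_pairs)) {
    pp <- spec$planted_pairs[[j]]
    prof <- spec$search_profile[[j]]
    results <- with_local_seed(spec$seed + j, lapply(seq_len(spec$n), function(i) {
      content <- filler_sentence(i)
      if (i <= prof[1])
        content <- paste(content, sprintf("The compound %s was assayed against %s.",
                                          pp$drug, pp$target))
      if (i <= prof[2]) {
        kw <- default_positive_keywords[(i - 1) %% length(default_positive_keywords) + 1]
        content <- paste(content, sprintf("The compound %s the protein.", kw))
      }
      if (i <= prof[3]) {
        kw <- default_strong_keywords[(i - 1) %% length(default_strong_keywords) + 1]
        content <- paste(content, sprintf("The observed effect was %s.", kw))
      }
      list(title = sprintf("Result %d", i),
           link = sprintf("https://example.org/%d", i),
           content = content)
    }))
    mapping[[build_query(pp$drug, pp$target)]] <- results
  }
  if (!is.null(path))
    jsonlite::write_json(mapping, path, auto_unbox = TRUE, pretty = TRUE)
  mapping
}

#' Generate a predictor lookup table for the planted pairs
#'
#' Scores follow the planted relation: interacting relations draw from the
#' upper score range, `none` from the lower, seeded.
#'
#' @param spec a [fixture_spec()].
#' @return data frame `drug,target,score`.
#' @export
make_lookup_table <- function(spec) {
  with_local_seed(spec$seed, {
    rows <- lapply(spec$planted_pairs, function(pp) {
      hi <- pp$relation != "none"
      data.frame(drug = pp$drug, target = pp$target,
                 score = if (hi) stats::runif(1, 0.6, 0.95)
                         else stats::runif(1, 0.02, 0.3),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Generate labels for the planted pairs
#'
#' @param spec a [fixture_spec()].
#' @return data frame `drug,target,label` per the spec's `label_rule`.
#' @export
make_labels <- function(spec) {
  rows <- lapply(spec$planted_pairs, function(pp) {
    cls <- if (grepl("^k_hop:", pp$relation)) "k_hop" else pp$relation
    data.frame(drug = pp$drug, target = pp$target,
               label = unname(spec$label_rule[[cls]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Reconstruct the canonical worked example
#'
#' Builds the fixture set reproducing the documented Vandetanib-MARK2 run:
#' the ML channel pinned to 7.260064194269944e-06 via a lookup table, the
#' search channel realizing D = 0.3 through a planted indicator profile
#' (9, 0, 0) over 10 results (T = 9, M = 30), and the KG channel pinned to
#' 0.7213475204444817 through the explicit simulation-only override hook
#' (that score came from a production-scale interaction graph that is not
#' shipped, so it cannot arise from a small synthetic graph honestly).
#' Running [run_pair()] with the returned config yields the final score
#' 0.34045.
#'
#' @param dir optional directory: write `lookup.csv` and `search.json` there.
#' @return list with `config` (ready for [run_pair()]), `pair`, `lookup`,
#'   `search_fixture`, and `expected` (the three channel scores and final).
#' @export
make_worked_example <- function(dir = NULL) {
  pair <- query_pair("Vandetanib", "MARK2")
  lookup <- data.frame(drug = "Vandetanib", target = "MARK2",
                       score = 7.260064194269944e-06,
                       stringsAsFactors = FALSE)
  spec <- fixture_spec(seed = 42,
                       planted_pairs = list(list(drug = "Vandetanib",
                                                 target = "MARK2",
                                                 relation = "k_hop:3")),
                       search_profile = list(c(9, 0, 0)), n = 10)
  search_fixture <- make_search_fixture(spec)
  if (!is.null(dir)) {
    # full-precision score rendering so the CSV round-trips exactly
    out <- lookup
    out$score <- sprintf("%.17g", out$score)
    utils::write.csv(out, file.path(dir, "lookup.csv"), row.names = FALSE,
                     quote = FALSE)
    jsonlite::write_json(search_fixture, file.path(dir, "search.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  config <- dti_config(
    search_backend = fixture_search_backend(search_fixture),
    ai_backend = lookup_predictor(lookup),
    allow_overrides = TRUE,
    kg_overrides = list("vandetanib|mark2" = 0.7213475204444817))
  list(config = config, pair = pair, lookup = lookup,
       search_fixture = search_fixture,
       expected = list(ai = 7.260064194269944e-06,
                       kg = 0.7213475204444817,
                       search = 0.3, final = 0.34045))
}

#' Write the full fixture bundle for a spec to a directory
#'
#' Emits `edges.tsv`, `search.json`, `lookup.csv` and `labels.csv` -- the
#' file formats the pipeline consumes.
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
simulate_fixtures <- function(spec, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  gr <- make_graph(spec)
  edge_path <- file.path(out_dir, "edges.tsv")
  utils::write.table(gr$edges, edge_path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  search_path <- file.path(out_dir, "search.json")
  make_search_fixture(spec, path = search_path)
  lookup_path <- file.path(out_dir, "lookup.csv")
  utils::write.csv(make_lookup_table(spec), lookup_path, row.names = FALSE)
  labels_path <- file.path(out_dir, "labels.csv")
  utils::write.csv(make_labels(spec), labels_path, row.names = FALSE)
  invisible(c(edges = edge_path, search = search_path, lookup = lookup_path,
              labels = labels_path))
}
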