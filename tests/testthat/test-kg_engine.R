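test_that("edge-list loading builds a deduplicated undirected graph", {
  # empty input
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("node_a\tkind_a\tnode_b\tkind_b", f)
  g <- load_graph(f, quiet = TRUE)
  expect_equal(kg_vcount(g), 0)
  expect_equal(kg_ecount(g), 0)

  # duplicate rows collapse to one edge
  g2 <- kg_graph(data.frame(node_a = c("D1", "D1"), kind_a = "drug",
                            node_b = c("G1", "G1"), kind_b = "gene"))
  expect_equal(kg_vcount(g2), 2)
  expect_equal(kg_ecount(g2), 1)
  expect_equal(kg_degree(g2, "D1"), 1)
  expect_equal(kg_degree(g2, "G1"), 1)

  # shipped 6-drug x 8-gene fixture: 14 edges, hand-counted degree sum 28
  g3 <- load_graph(system.file("extdata", "kg_edges_6x8.tsv",
                               package = "dtifuse"), quiet = TRUE)
  expect_equal(kg_vcount(g3), 14)
  expect_equal(kg_ecount(g3), 14)
  expect_equal(sum(igraph::degree(g3$graph)), 28)
  expect_equal(kg_degree(g3, "D1"), 3)
  expect_equal(kg_degree(g3, "G2"), 1)
})

test_that("loader rejects malformed input with located errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("node_a,kind_a,node_b,kind_b", "D1,drug,G1", "D2,drug,G2,gene"), f)
  expect_error(load_graph(f, quiet = TRUE), "line 2",
               class = "dtifuse_parse_error")

  expect_error(kg_graph(data.frame(node_a = "D1", kind_a = "protein",
                                   node_b = "G1", kind_b = "gene")),
               class = "dtifuse_parse_error")
  loop <- data.frame(node_a = "D1", kind_a = "drug",
                     node_b = "d1 ", kind_b = "drug")
  expect_warning(gl <- kg_graph(loop), "self-loop")
  expect_equal(kg_ecount(gl), 0)
  expect_error(kg_graph(loop, on_self_loop = "error"),
               class = "dtifuse_parse_error")
})

test_that("duplicate edges merge their source-database tags", {
  g <- kg_graph(data.frame(node_a = c("D1", "G1"), kind_a = c("drug", "gene"),
                           node_b = c("G1", "D1"), kind_b = c("gene", "drug"),
                           source = c("dbB", "dbA")))
  expect_equal(kg_ecount(g), 1)
  expect_equal(igraph::E(g$graph)$sources, "dbA;dbB")
})

test_that("identifier matching is trimmed and case-insensitive", {
  g <- kg_graph(data.frame(node_a = "Nilotinib", kind_a = "drug",
                           node_b = "GRK5", kind_b = "gene"))
  expect_equal(dti_kg_score(g, " NILOTINIB ", "grk5")$score, 1.0)
})

test_that("path enumeration equals the recursive brute-force oracle", {
  edges <- random_edge_table(7, n_drugs = 5, n_genes = 7, p = 0.35)
  g <- kg_graph(edges)
  adj <- oracle_adjacency(edges)
  for (pair in list(c("d01", "g03"), c("d02", "g01"), c("d05", "g07"))) {
    got <- enumerate_paths(g, pair[1], pair[2], max_hops = 4)
    want <- oracle_enumerate(adj, pair[1], pair[2], max_hops = 4)
    key <- function(ps) sort(vapply(ps, paste, "", collapse = ">"))
    expect_equal(key(got), key(want))
  }
  # deterministic order: ascending hops, lexicographic within
  got <- enumerate_paths(g, "d01", "g03")
  hops <- lengths(got) - 1
  expect_true(all(diff(hops) >= 0))
  # absent node
  expect_equal(enumerate_paths(g, "X", "g01"), list())
  expect_error(enumerate_paths(g, "d01", "g01", max_hops = 0),
               class = "dtifuse_config_error")
})

test_that("path weight matches the degree formula", {
  # two-node graph: single edge, both degrees 1, |V| = 2
  g2 <- kg_graph(data.frame(node_a = "d", kind_a = "drug",
                            node_b = "t", kind_b = "gene"))
  expect_equal(path_weight(g2, c("d", "t")), 0.5)

  # three-node chain d-g-t: ((1+2)/6 + (2+1)/6) / 2 = 0.5
  g3 <- kg_graph(data.frame(node_a = c("d", "x"), kind_a = c("drug", "drug"),
                            node_b = c("g", "g"), kind_b = c("gene", "gene")))
  expect_equal(path_weight(g3, c("d", "g", "x")), 0.5)

  # sweep: every enumerated path in 20 random graphs agrees with the
  # independent degree-table recomputation
  for (seed in 1:20) {
    edges <- random_edge_table(seed, p = 0.3)
    g <- kg_graph(edges)
    adj <- oracle_adjacency(edges)
    paths <- enumerate_paths(g, "d01", "g01", max_hops = 4)
    for (p in paths) {
      expect_equal(path_weight(g, p), oracle_path_weight(adj, p))
    }
  }
  expect_error(path_weight(g2, c("d", "nope")),
               class = "dtifuse_contract_error")
  expect_error(path_weight(g2, c("d", "t", "d")),
               class = "dtifuse_contract_error")
})

test_that("pair scoring matches the end-to-end brute-force oracle", {
  for (seed in 1:30) {
    edges <- random_edge_table(seed, n_drugs = 4 + seed %% 4,
                               n_genes = 5 + seed %% 5, p = 0.3)
    g <- kg_graph(edges)
    for (pair in list(c("d01", "g01"), c("d02", "g03"))) {
      got <- dti_kg_score(g, pair[1], pair[2])
      expect_equal(got$score, oracle_kg_score(edges, pair[1], pair[2]))
    }
  }
})

test_that("score pins the documented boundary cases", {
  edges <- random_edge_table(3, p = 0.3)
  g <- kg_graph(edges)
  # absent node scores zero with no best path
  out <- dti_kg_score(g, "absent_drug", "g01")
  expect_equal(out$score, 0)
  expect_null(out$best_path)
  # a direct edge always scores exactly 1.0
  direct <- edges[1, ]
  expect_equal(dti_kg_score(g, direct$node_a, direct$node_b)$score, 1.0)
  expect_error(dti_kg_score(g, "d01", "g01", max_hops = 0),
               class = "dtifuse_config_error")
})

test_that("scores are symmetric, bounded, and positive iff a path exists", {
  for (seed in 31:45) {
    edges <- random_edge_table(seed, p = 0.25)
    g <- kg_graph(edges)
    adj <- oracle_adjacency(edges)
    for (pair in list(c("d01", "g02"), c("d03", "g04"))) {
      a <- dti_kg_score(g, pair[1], pair[2])$score
      b <- dti_kg_score(g, pair[2], pair[1])$score
      expect_identical(a, b)
      expect_gte(a, 0); expect_lte(a, 1)
      has_path <- length(oracle_enumerate(adj, pair[1], pair[2])) > 0
      expect_identical(a > 0, has_path)
    }
  }
})

test_that("path ranking never prefers a longer path at equal weight", {
  for (seed in c(2, 5, 11)) {
    edges <- random_edge_table(seed, p = 0.4)
    g <- kg_graph(edges)
    ev <- dti_kg_score(g, "d01", "g01")
    if (length(ev$all_paths) < 2) next
    sc <- vapply(ev$all_paths, `[[`, 0, "combined_score")
    expect_true(all(diff(sc) <= 1e-12))
    for (k in seq_len(length(ev$all_paths) - 1)) {
      a <- ev$all_paths[[k]]; b <- ev$all_paths[[k + 1]]
      if (isTRUE(all.equal(a$weight, b$weight)) &&
          a$combined_score == b$combined_score)
        expect_lte(a$hops, b$hops)
    }
  }
})

test_that("evidence reason text names the best path", {
  edges <- random_edge_table(7, p = 0.35)
  g <- kg_graph(edges)
  ev <- dti_kg_score(g, "d01", "g03")
  if (ev$score > 0 && ev$best_path$hops > 0) {
    expect_match(ev$reason, "Found \\d+ path")
    expect_match(ev$reason, "Best score:")
    expect_match(ev$reason, paste(ev$best_path$path, collapse = " → "),
                 fixed = TRUE)
  }
  none <- dti_kg_score(kg_graph(data.frame(
    node_a = c("a", "b"), kind_a = "drug",
    node_b = c("x", "y"), kind_b = "gene")), "a", "y")
  expect_equal(none$score, 0)
  expect_match(none$reason, "No path")
})

test_that("the path cap truncates evidence and flags the record", {
  edges <- random_edge_table(8, n_drugs = 6, n_genes = 6, p = 0.8)
  g <- kg_graph(edges)
  full <- dti_kg_score(g, "d01", "g01")
  expect_gt(length(full$all_paths), 2)
  expect_warning(capped <- dti_kg_score(g, "d01", "g01", path_cap = 2),
                 "cap")
  expect_true(capped$truncated)
  expect_length(capped$all_paths, 2)
  # the retained best path still leads, so the score is unchanged here
  expect_equal(capped$score, full$score)
})
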