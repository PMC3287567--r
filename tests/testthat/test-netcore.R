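test_that("interactome construction removes self-loops and duplicates", {
  g <- build_interactome(tibble::tibble(gene_a = c("A", "B", "A"),
                                        gene_b = c("B", "A", "A")),
                         quiet = TRUE)
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)

  g0 <- build_interactome(tibble::tibble(gene_a = character(),
                                         gene_b = character()), quiet = TRUE)
  expect_equal(igraph::vcount(g0), 0)
})

test_that("edge count equals distinct unordered non-self pairs (set oracle)", {
  withr::local_seed(11)
  a <- sample(LETTERS[1:12], 1000, replace = TRUE)
  b <- sample(LETTERS[1:12], 1000, replace = TRUE)
  g <- build_interactome(tibble::tibble(gene_a = a, gene_b = b), quiet = TRUE)
  keys <- unique(paste(pmin(a, b), pmax(a, b))[a != b])
  expect_equal(igraph::ecount(g), length(keys))
  # handshake lemma
  expect_equal(sum(igraph::degree(g)), 2 * igraph::ecount(g))
  # idempotence: rebuilding from the clean edge set changes nothing
  el <- igraph::as_data_frame(g)
  g2 <- build_interactome(tibble::tibble(gene_a = el$from, gene_b = el$to),
                          quiet = TRUE)
  expect_true(igraph::identical_graphs(
    igraph::permute(g2, match(igraph::V(g2)$name, igraph::V(g)$name)), g) ||
    setequal(paste(el$from, el$to),
             paste(igraph::as_data_frame(g2)$from,
                   igraph::as_data_frame(g2)$to)))
})

test_that("degree matches simple cases and the adjacency row-sum oracle", {
  tri <- make_graph(c("A", "B", "C"), c("B", "C", "A"))
  expect_equal(unname(node_degree(tri, "A")), 2)
  star <- make_graph(c("h", "h", "h"), c("l1", "l2", "l3"))
  expect_equal(unname(node_degree(star, "h")), 3)
  expect_error(node_degree(star, "absent"), "not in the interactome")

  withr::local_seed(3)
  g <- random_connected_graph(9)
  adjm <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  for (v in igraph::V(g)$name)
    expect_equal(unname(node_degree(g, v)), sum(adjm[v, ]))
})

test_that("betweenness uses fractional counting over unordered pairs", {
  path <- make_graph(c("A", "B"), c("B", "C"))
  expect_equal(unname(node_betweenness(path, "B")), 1)
  star <- make_graph(c("h", "h", "h"), c("l1", "l2", "l3"))
  expect_equal(unname(node_betweenness(star, "h")), 3)  # C(3,2) pairs
  expect_equal(unname(node_betweenness(star, "l1")), 0) # leaves score 0
  cyc <- make_graph(c("A", "B", "C", "D"), c("B", "C", "D", "A"))
  expect_equal(unname(node_betweenness(cyc, "B")), 0.5) # two tied A-C paths
})

test_that("betweenness agrees with exhaustive geodesic enumeration", {
  withr::local_seed(7)
  for (rep in 1:5) {
    n <- sample(6:10, 1)
    g <- random_connected_graph(n)
    el <- igraph::as_data_frame(g)
    expected <- oracle_betweenness(el$from, el$to)
    got <- node_betweenness(g, names(expected))
    expect_equal(got[names(expected)], expected, tolerance = 1e-10)
    # sum identity: total betweenness = sum over pairs of (path length - 1)
    adj <- oracle_adj(el$from, el$to)
    nodes <- names(adj)
    interior_total <- 0
    for (i in seq_along(nodes)) {
      d <- oracle_bfs_dist(adj, nodes[i])
      for (j in seq_along(nodes)) {
        if (i < j && is.finite(d[nodes[j]]) && d[nodes[j]] >= 1)
          interior_total <- interior_total + unname(d[nodes[j]]) - 1
      }
    }
    expect_equal(sum(got), interior_total, tolerance = 1e-10)
  }
})

test_that("shortest path lengths match a BFS oracle and handle corner cases", {
  path <- make_graph(c("A", "B"), c("B", "C"))
  expect_equal(shortest_path_length(path, "A", "C"), 2)
  expect_equal(shortest_path_length(path, "A", "A"), 0)
  two <- make_graph(c("A", "C"), c("B", "D"))
  expect_equal(shortest_path_length(two, "A", "C"), Inf)
  expect_error(shortest_path_length(path, "A", "zzz"), "not in the interactome")

  withr::local_seed(13)
  g <- random_connected_graph(10)
  el <- igraph::as_data_frame(g)
  adj <- oracle_adj(el$from, el$to)
  src <- names(adj)[1]
  d <- oracle_bfs_dist(adj, src)
  for (v in names(adj))
    expect_equal(shortest_path_length(g, src, v), unname(d[v]))
})

test_that("rank-sum test matches enumeration and is symmetric", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4)), 1 / 3)
  expect_equal(wilcoxon_rank_sum(1:4, 1:4), 1)   # same multiset
  x <- c(0.3, 1.2, 5); y <- c(0.7, 2.5, 3.3, 9)
  expect_equal(wilcoxon_rank_sum(x, y), wilcoxon_rank_sum(y, x))
  expect_error(wilcoxon_rank_sum(numeric(), 1:3), "non-empty")
})

test_that("group topology summarises mapped genes only and bins degrees", {
  g <- make_graph(c("A", "A", "B", "C", "C"), c("B", "C", "C", "D", "E"))
  # degrees: A=2, B=2, C=4
  top <- group_topology(g, c("A", "B", "C", "NOTINGRAPH"),
                        bins = c(0, 3, 5), label = "demo")
  expect_equal(top$summary$n_input, 4)
  expect_equal(top$summary$n_mapped, 3)
  expect_equal(top$unmapped, "NOTINGRAPH")
  expect_equal(top$summary$mean_degree, 8 / 3)
  expect_equal(top$summary$median_degree, 2)
  expect_equal(top$bin_table$proportion, c(2 / 3, 1 / 3, 0))
  expect_equal(sum(top$bin_table$proportion), 1)
  expect_error(group_topology(g, "nope"), "no gene")
  expect_error(group_topology(g, "A", bins = c(5, 2)), "strictly increasing")
})
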