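test_that("a forced unique connector is recruited by both solvers", {
  g <- make_graph(c("t1", "x"), c("x", "t2"))
  for (fn in list(klein_ravi_steiner, brute_force_steiner)) {
    s <- fn(g, c("t1", "t2"))
    expect_setequal(s$nodes$gene, c("t1", "t2", "x"))
    expect_equal(s$nodes$role[s$nodes$gene == "x"], "linker")
    cc <- classify_subnetwork(s)
    expect_equal(cc$terminal_count, 2)
    expect_equal(cc$linker_count, 1)
  }
})

test_that("connected terminals need no linkers", {
  g <- make_graph(c("a", "b", "c"), c("b", "c", "a"))
  s <- klein_ravi_steiner(g, c("a", "b", "c"))
  expect_equal(classify_subnetwork(s)$linker_count, 0)
  expect_setequal(s$nodes$gene, c("a", "b", "c"))
  # the output spans the terminals
  expect_equal(nrow(s$edges), 2)
})

test_that("the cheaper of two alternative routes is preferred", {
  # a - y1 - b (one linker) vs a - z1 - z2 - b (two linkers)
  g <- make_graph(c("a", "y1", "a", "z1", "z2"),
                  c("y1", "b", "z1", "z2", "b"))
  expect_setequal(brute_force_steiner(g, c("a", "b"))$nodes$gene,
                  c("a", "b", "y1"))
  expect_setequal(klein_ravi_steiner(g, c("a", "b"))$nodes$gene,
                  c("a", "b", "y1"))
})

test_that("node weights steer the route choice", {
  g <- make_graph(c("a", "y1", "a", "z1", "z2"),
                  c("y1", "b", "z1", "z2", "b"))
  w <- c(y1 = 10, z1 = 1, z2 = 1)
  expect_setequal(brute_force_steiner(g, c("a", "b"), node_weight = w)$nodes$gene,
                  c("a", "b", "z1", "z2"))
  expect_setequal(klein_ravi_steiner(g, c("a", "b"), node_weight = w)$nodes$gene,
                  c("a", "b", "z1", "z2"))
})

test_that("terminals split across components are handled per component", {
  g <- make_graph(c("a", "c", "e"), c("b", "d", "f"))  # three 2-node comps
  expect_message(s <- klein_ravi_steiner(g, c("a", "b", "c", "e")),
                 "unconnected")
  expect_setequal(s$nodes$gene, c("a", "b"))
  expect_setequal(s$unconnected_terminals, c("c", "e"))
  expect_message(s2 <- klein_ravi_steiner(g, c("a", "b", "ghost")),
                 "not in the graph")
  expect_equal(s2$terminals_mapped, c("a", "b"))
  expect_error(klein_ravi_steiner(g, "ghost"), "no terminal")
})

test_that("brute force refuses oversized instances", {
  withr::local_seed(2)
  g <- simulate_interactome(40, 2, seed = 2)
  terms <- igraph::V(g)$name[1:3]
  expect_error(brute_force_steiner(g, terms), "infeasible")
})

test_that("approximation never beats the exact optimum and stays within bound", {
  withr::local_seed(17)
  n_eq <- 0
  for (i in 1:60) {
    n <- sample(6:12, 1)
    g <- random_connected_graph(n, p = 0.3)
    k <- sample(3:5, 1)
    terms <- sample(igraph::V(g)$name, k)
    bf <- brute_force_steiner(g, terms)
    kr <- klein_ravi_steiner(g, terms)
    expect_true(bf$total_linker_weight <= kr$total_linker_weight + 1e-9)
    expect_true(kr$total_linker_weight <=
                  2 * log(k) * max(bf$total_linker_weight, 1) + 1e-9)
    if (kr$total_linker_weight == bf$total_linker_weight) n_eq <- n_eq + 1
  }
  expect_true(n_eq >= 30)  # the approximation is usually exact at this size
})

test_that("removing any linker disconnects some terminal pair", {
  withr::local_seed(23)
  for (i in 1:10) {
    g <- random_connected_graph(sample(8:12, 1), p = 0.25)
    terms <- sample(igraph::V(g)$name, 4)
    kr <- klein_ravi_steiner(g, terms)
    linkers <- kr$nodes$gene[kr$nodes$role == "linker"]
    sub <- igraph::graph_from_data_frame(kr$edges[, c("from", "to")],
                                         directed = FALSE,
                                         vertices = kr$nodes$gene)
    in_sub_terms <- intersect(terms, kr$nodes$gene)
    for (l in linkers) {
      cut <- igraph::delete_vertices(sub, l)
      comp <- igraph::components(cut)$membership
      expect_true(length(unique(comp[in_sub_terms])) > 1,
                  label = sprintf("linker %s is required", l))
    }
  }
})

test_that("the solution is invariant to edge-list permutation", {
  withr::local_seed(29)
  g <- random_connected_graph(10, p = 0.3)
  el <- igraph::as_data_frame(g)
  terms <- sort(sample(igraph::V(g)$name, 4))
  s1 <- klein_ravi_steiner(g, terms)
  perm <- sample(nrow(el))
  g2 <- make_graph(el$from[perm], el$to[perm])
  s2 <- klein_ravi_steiner(g2, terms)
  expect_equal(s1$nodes, s2$nodes)
  expect_equal(s1$total_linker_weight, s2$total_linker_weight)
})

test_that("unit weights minimise the count of recruited genes", {
  withr::local_seed(37)
  for (i in 1:20) {
    g <- random_connected_graph(sample(7:11, 1), p = 0.3)
    terms <- sample(igraph::V(g)$name, 3)
    bf <- brute_force_steiner(g, terms)
    expect_equal(bf$total_linker_weight,
                 classify_subnetwork(bf)$linker_count)
  }
})

test_that("induced-edge output is a supergraph of the tree output", {
  g <- make_graph(c("t1", "x", "t2", "t1"), c("x", "t2", "t1", "x"))
  tree <- klein_ravi_steiner(g, c("t1", "t2"))
  ind <- klein_ravi_steiner(g, c("t1", "t2"), induce_edges = TRUE)
  expect_true(nrow(ind$edges) >= nrow(tree$edges))
  expect_setequal(ind$nodes$gene, tree$nodes$gene)
})

test_that("glance and export surfaces work for subnetworks", {
  g <- make_graph(c("t1", "x"), c("x", "t2"))
  s <- klein_ravi_steiner(g, c("t1", "t2"))
  gl <- glance(s)
  expect_equal(gl$linker_count, 1)
  expect_equal(tidy(s), s$nodes)
  f <- withr::local_tempfile(fileext = ".graphml")
  write_subnetwork(s, f)
  back <- read_graph_file(f)
  expect_setequal(back$nodes$name, s$nodes$gene)
  expect_setequal(back$nodes$role[back$nodes$name == "x"], "linker")
})
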