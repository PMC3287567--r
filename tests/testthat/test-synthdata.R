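test_that("preferential attachment yields the closed-form edge count", {
  g <- simulate_interactome(10, 1, seed = 4)
  expect_equal(igraph::ecount(g), 9)          # m = 1 grows a tree
  expect_equal(igraph::components(g)$no, 1)

  g2 <- simulate_interactome(1000, 5, seed = 4)
  expect_equal(igraph::ecount(g2), sum(pmin(5, 0:999)))  # 4985
  expect_true(igraph::is_simple(g2))
  expect_equal(igraph::components(g2)$no, 1)

  # determinism: identical edge sets for the same seed
  g3 <- simulate_interactome(1000, 5, seed = 4)
  expect_identical(igraph::as_data_frame(g2), igraph::as_data_frame(g3))
  g4 <- simulate_interactome(200, 3, seed = 5)
  g5 <- simulate_interactome(200, 3, seed = 6)
  expect_false(identical(igraph::as_data_frame(g4),
                         igraph::as_data_frame(g5)))
  expect_error(simulate_interactome(3, 5), "n_nodes")
})

test_that("the degree distribution is heavy tailed", {
  g <- simulate_interactome(2000, 3, seed = 9)
  deg <- igraph::degree(g)
  expect_gt(max(deg), 10 * median(deg))
  expect_gt(mean(deg), median(deg))  # right skew
})

test_that("planted modules are recoverable Steiner instances", {
  g <- simulate_interactome(300, 3, seed = 8)
  tr <- plant_disease_module(g, 6, 3, seed = 8)
  expect_equal(length(tr$terminals), 6)
  expect_equal(length(tr$linkers), 3)
  expect_true(all(c(tr$terminals, tr$linkers) %in% igraph::V(g)$name))
  # within the planted tree every linker is a cut vertex between terminals
  sub <- igraph::graph_from_data_frame(tr$module_edges, directed = FALSE)
  for (l in tr$linkers) {
    cut <- igraph::delete_vertices(sub, l)
    comp <- igraph::components(cut)$membership
    terms_in <- intersect(tr$terminals, names(comp))
    expect_gt(length(unique(comp[terms_in])), 1)
  }
  # determinism
  tr2 <- plant_disease_module(g, 6, 3, seed = 8)
  expect_identical(tr$terminals, tr2$terminals)
  expect_identical(tr$linkers, tr2$linkers)
})

test_that("a zero-linker module needs no recruitment", {
  g <- simulate_interactome(200, 3, seed = 10)
  tr <- plant_disease_module(g, 5, 0, seed = 10)
  s <- klein_ravi_steiner(g, tr$terminals)
  expect_equal(classify_subnetwork(s)$linker_count, 0)
})

test_that("planted pathway enrichment and overlap blocks are constructed", {
  withr::local_seed(50)
  universe <- sprintf("U%05d", 1:5000)
  candidates <- sample(universe, 150)
  out <- simulate_pathways(universe, candidates, n_sets = 20,
                           size_range = c(30, 50), n_enriched = 6,
                           overlap_blocks = list(list(n_sets = 3,
                                                      core_size = 5)),
                           seed = 12)
  coll <- out$collection; truth <- out$truth
  expect_equal(length(coll$sets), 20)
  expect_equal(length(truth$enriched_sets), 6)
  # block members pairwise share at least the core
  block <- truth$block_members[[1]]
  core <- truth$block_cores[[1]]
  expect_equal(length(core), 5)
  for (a in block) for (b in block) if (a < b) {
    expect_true(all(core %in% coll$sets[[a]]))
    expect_gte(length(intersect(coll$sets[[a]], coll$sets[[b]])), 5)
  }
  # enriched sets contain many candidates, null sets few
  k_enr <- purrr::map_int(coll$sets[truth$enriched_sets],
                          ~ length(intersect(.x, candidates)))
  k_null <- purrr::map_int(coll$sets[setdiff(names(coll$sets),
                                             truth$enriched_sets)],
                           ~ length(intersect(.x, candidates)))
  expect_gt(min(k_enr), max(k_null))
  # determinism
  out2 <- simulate_pathways(universe, candidates, n_sets = 20,
                            size_range = c(30, 50), n_enriched = 6,
                            overlap_blocks = list(list(n_sets = 3,
                                                       core_size = 5)),
                            seed = 12)
  expect_identical(out$collection$sets, out2$collection$sets)
  expect_error(
    simulate_pathways(universe, candidates, n_sets = 5, n_enriched = 2,
                      overlap_blocks = list(list(n_sets = 3, core_size = 5))),
    "more sets than are enriched")
})

test_that("simulated SNP p-values respect the Beta alternative", {
  genes <- simulate_gene_table(sprintf("G%04d", 1:800))
  assoc_genes <- genes$gene_id[1:400]
  out <- simulate_gwas(genes, associated = assoc_genes,
                       snps_per_gene = c(3, 3), beta_shape = 0.2, seed = 14)
  expect_equal(nrow(out$assoc), 2400)
  expect_true(all(out$assoc$p >= 0 & out$assoc$p <= 1))
  gp <- assign_gene_p(out$assoc, genes)
  # closed form: P(p_min < q) = 1 - (1 - q^a)^s
  q <- 0.05; a <- 0.2; s <- 3
  p_assoc <- 1 - (1 - q^a)^s
  p_null <- 1 - (1 - q)^s
  obs_assoc <- mean(gp$p_min[gp$gene %in% assoc_genes] < q)
  obs_null <- mean(gp$p_min[!gp$gene %in% assoc_genes] < q)
  se <- function(p, n) sqrt(p * (1 - p) / n)
  expect_lt(abs(obs_assoc - p_assoc), 3 * se(p_assoc, 400))
  expect_lt(abs(obs_null - p_null), 3 * se(p_null, 400))
  # determinism and the degenerate beta_shape = 1 case
  out2 <- simulate_gwas(genes, associated = assoc_genes,
                        snps_per_gene = c(3, 3), beta_shape = 0.2, seed = 14)
  expect_identical(out$assoc, out2$assoc)
  expect_error(simulate_gwas(genes, beta_shape = 0), "beta_shape")
})

test_that("truth sidecars serialise to readable TSV", {
  g <- simulate_interactome(100, 2, seed = 3)
  tr <- plant_disease_module(g, 4, 2, seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_truth(tr, f)
  tab <- readr::read_tsv(f, show_col_types = FALSE)
  expect_true("terminals" %in% tab$item)
  expect_true(any(grepl("^param\\.", tab$item)))
})
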