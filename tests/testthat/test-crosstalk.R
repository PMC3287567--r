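test_that("overlap coefficients follow their definitions", {
  A <- paste0("g", 1:23)
  B <- paste0("g", 1:31)
  expect_equal(jaccard_coefficient(A, A), 1)
  expect_equal(jaccard_coefficient(A, paste0("z", 1:5)), 0)
  expect_equal(jaccard_coefficient(A, B), 23 / 31)
  expect_equal(overlap_coefficient(A, B), 1)      # subset saturates
  expect_equal(overlap_coefficient(paste0("g", 1:4), paste0("z", 1:9)), 0)
  expect_equal(crosstalk_score(A, B), (23 / 31 + 1) / 2)
  expect_error(jaccard_coefficient(character(), A), "non-empty")
  expect_error(overlap_coefficient(A, character()), "non-empty")
})

test_that("coefficients are symmetric and ordered JC <= score <= OC", {
  withr::local_seed(31)
  pool <- paste0("g", 1:40)
  for (i in 1:20) {
    A <- sample(pool, sample(3:20, 1))
    B <- sample(pool, sample(3:20, 1))
    jc <- jaccard_coefficient(A, B); oc <- overlap_coefficient(A, B)
    sc <- crosstalk_score(A, B)
    expect_equal(jc, jaccard_coefficient(B, A))
    expect_equal(oc, overlap_coefficient(B, A))
    expect_true(jc <= oc + 1e-12)
    expect_true(jc - 1e-12 <= sc && sc <= oc + 1e-12)
    expect_true(jc >= 0 && oc <= 1)
  }
})

test_that("top-fraction retention keeps floor(f*n) with deterministic ties", {
  edges <- tibble::tibble(
    pathway_a = sprintf("A%02d", 1:20), pathway_b = sprintf("B%02d", 1:20),
    n_shared = rep(c(5L, 3L), 10), score = rep(0.5, 20))
  kept <- retain_top_edges(edges, 0.25)
  expect_equal(nrow(kept), 5)             # floor(0.25 * 20)
  # all scores tie: ordering falls back to n_shared desc, then names
  expect_true(all(kept$n_shared == 5))
  expect_equal(kept$pathway_a, sprintf("A%02d", c(1, 3, 5, 7, 9)))
  expect_equal(nrow(retain_top_edges(edges, 1)), 20)
})

fake_results <- function(sets, query) {
  # enrichment-shaped table with every set "significant"; observed = overlap
  tibble::tibble(
    term = names(sets),
    k = purrr::map_int(sets, ~ length(intersect(.x, query))),
    K = lengths(sets), n = length(query), N = 1000,
    p = 1e-6, p_bh = 1e-5,
    observed_genes = purrr::map(sets, ~ sort(intersect(.x, query)))
  )
}

test_that("crosstalk network applies the three filter rules conjunctively", {
  query <- paste0("g", 1:30)
  sets <- list(
    BIG1 = paste0("g", 1:10),       # k=10
    BIG2 = paste0("g", 1:10),       # identical to BIG1
    SMALL = paste0("g", 1:4),       # k=4 < 5, filtered by rule (1)
    SHARE2 = c(paste0("g", 9:10), paste0("g", 25:29))  # shares only 2 with BIG*
  )
  res <- fake_results(sets, query)
  res$p_bh[res$term == "SHARE2"] <- 0.5   # also violates rule (2)
  net <- suppressMessages(suppressWarnings(
    build_crosstalk_network(res, crosstalk_config(top_fraction = 1))))
  expect_s3_class(net, "crosstalk_network")
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$pathway_a, "BIG1")
  expect_equal(net$edges$pathway_b, "BIG2")
  expect_equal(net$edges$score, 1)        # identical observed sets
  expect_equal(net$n_candidate_edges, 1)

  # pair sharing only 2 genes never becomes a candidate edge
  res2 <- fake_results(sets[c("BIG1", "SHARE2")], query)
  expect_warning(net2 <- suppressMessages(
    build_crosstalk_network(res2, crosstalk_config(top_fraction = 1))),
    "no crosstalk")
  expect_equal(nrow(net2$edges), 0)
})

test_that("adjusted-p filtering is strict and boundary cases are reported", {
  query <- paste0("g", 1:30)
  sets <- list(P1 = paste0("g", 1:8), P2 = paste0("g", 1:9))
  res <- fake_results(sets, query)
  res$p_bh <- c(0.01, 0.01)   # exactly at the default threshold
  expect_message(expect_warning(
    build_crosstalk_network(res), "no crosstalk"),
    "at the adjusted-p threshold")
})

test_that("every retained edge satisfies the filters post hoc", {
  withr::local_seed(41)
  pool <- paste0("g", 1:60)
  query <- sample(pool, 40)
  sets <- purrr::map(1:12, ~ sample(pool, sample(8:25, 1)))
  names(sets) <- sprintf("PW%02d", 1:12)
  res <- fake_results(sets, query)
  res$p_bh <- runif(12, 0, 0.02)
  cfg <- crosstalk_config(top_fraction = 0.5)
  net <- suppressMessages(suppressWarnings(build_crosstalk_network(res, cfg)))
  if (nrow(net$edges) > 0) {
    for (i in seq_len(nrow(net$edges))) {
      e <- net$edges[i, ]
      ra <- res[res$term == e$pathway_a, ]; rb <- res[res$term == e$pathway_b, ]
      expect_true(ra$k >= cfg$min_genes && rb$k >= cfg$min_genes)
      expect_true(ra$p_bh < cfg$max_padj && rb$p_bh < cfg$max_padj)
      expect_true(e$n_shared >= cfg$min_shared)
      expect_equal(e$score, (e$jc + e$oc) / 2)
      expect_true(e$pathway_a < e$pathway_b)  # canonical pair order
    }
    expect_equal(nrow(net$edges),
                 floor(cfg$top_fraction * net$n_candidate_edges))
  }
})

test_that("tidy, glance and export surfaces work", {
  query <- paste0("g", 1:30)
  sets <- list(P1 = paste0("g", 1:10), P2 = paste0("g", 1:12))
  res <- fake_results(sets, query)
  net <- suppressMessages(
    build_crosstalk_network(res, crosstalk_config(top_fraction = 1)))
  td <- tidy(net)
  expect_true(is.character(td$shared_genes))
  gl <- glance(net)
  expect_equal(gl$n_retained_edges, 1)
  f <- withr::local_tempfile(fileext = ".graphml")
  write_crosstalk(net, f, "graphml")
  back <- read_graph_file(f)
  expect_setequal(back$nodes$name, c("P1", "P2"))
})
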