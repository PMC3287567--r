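# Independent oracles used to verify the package's statistics and graph
# algorithms. Everything here is deliberately brute force and shares no
# code path with the implementation it checks.

# quick graph builder from paired endpoint vectors
make_graph <- function(a, b) {
  build_interactome(tibble::tibble(gene_a = a, gene_b = b), quiet = TRUE)
}

# name -> sorted neighbour names, from the raw edge lists
oracle_adj <- function(a, b) {
  nodes <- sort(unique(c(a, b)))
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_along(a)) {
    if (a[i] == b[i]) next
    adj[[a[i]]] <- union(adj[[a[i]]], b[i])
    adj[[b[i]]] <- union(adj[[b[i]]], a[i])
  }
  lapply(adj, sort)
}

# BFS hop distances from a source, own implementation
oracle_bfs_dist <- function(adj, src) {
  d <- setNames(rep(Inf, length(adj)), names(adj))
  d[src] <- 0
  queue <- src
  while (length(queue) > 0) {
    u <- queue[1]; queue <- queue[-1]
    for (v in adj[[u]]) if (!is.finite(d[v])) {
      d[v] <- d[u] + 1
      queue <- c(queue, v)
    }
  }
  d
}

# all geodesics between two nodes by DFS over the BFS layering
oracle_all_geodesics <- function(adj, s, t) {
  d <- oracle_bfs_dist(adj, s)
  if (!is.finite(d[t])) return(list())
  paths <- list()
  walk <- function(node, acc) {
    if (node == s) {
      paths[[length(paths) + 1]] <<- rev(acc)
      return(invisible())
    }
    for (u in adj[[node]]) if (d[u] == d[node] - 1) walk(u, c(acc, u))
  }
  walk(t, t)
  paths
}

# unnormalised fractional betweenness over unordered pairs (endpoints
# excluded), by exhaustive geodesic enumeration
oracle_betweenness <- function(a, b) {
  adj <- oracle_adj(a, b)
  nodes <- names(adj)
  btw <- setNames(rep(0, length(nodes)), nodes)
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i >= j) next
    paths <- oracle_all_geodesics(adj, nodes[i], nodes[j])
    if (length(paths) == 0) next
    for (p in paths) {
      interior <- setdiff(p, c(nodes[i], nodes[j]))
      btw[interior] <- btw[interior] + 1 / length(paths)
    }
  }
  btw
}

# exact two-sided rank-sum p by full enumeration of rank assignments
# (tie-free inputs only): doubled smaller tail of the U statistic, capped
oracle_wilcoxon_exact <- function(x, y) {
  m <- length(x); n <- length(y)
  ranks <- rank(c(x, y))
  u_obs <- sum(ranks[seq_len(m)]) - m * (m + 1) / 2
  all_u <- apply(utils::combn(m + n, m), 2, function(idx)
    sum(seq_len(m + n)[idx]) - m * (m + 1) / 2)
  min(1, 2 * min(mean(all_u <= u_obs), mean(all_u >= u_obs)))
}

# one-sided (enrichment) Fisher p by direct summation over the 2x2 support
oracle_fisher_enum <- function(a, b, c, d) {
  row1 <- a + b; col1 <- a + c; N <- a + b + c + d
  xs <- max(0, row1 + col1 - N):min(row1, col1)
  pmf <- choose(col1, xs) * choose(N - col1, row1 - xs) / choose(N, row1)
  sum(pmf[xs >= a])
}

# per-gene min SNP p by triple loop over genes x SNPs
oracle_min_p <- function(assoc, genes, flank = 0) {
  out <- list()
  for (i in seq_len(nrow(genes))) {
    ps <- c(); n <- 0
    for (j in seq_len(nrow(assoc))) {
      if (assoc$chrom[j] == genes$chrom[i] &&
          assoc$pos[j] >= genes$start[i] - flank &&
          assoc$pos[j] <= genes$end[i] + flank) {
        ps <- c(ps, assoc$p[j]); n <- n + 1
      }
    }
    if (n > 0)
      out[[genes$gene_id[i]]] <- list(p_min = min(ps), n_snps = n)
  }
  out
}

# random connected graph on n nodes: spanning tree + extra edges at rate p
random_connected_graph <- function(n, p = 0.35) {
  nodes <- sprintf("n%02d", seq_len(n))
  a <- character(); b <- character()
  for (i in 2:n) {
    j <- sample(i - 1, 1)
    a <- c(a, nodes[j]); b <- c(b, nodes[i])
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p) { a <- c(a, nodes[i]); b <- c(b, nodes[j]) }
  }
  make_graph(a, b)
}

# tiny gene table used across io / gwas tests
tiny_gene_table <- function() {
  tibble::tibble(
    gene_id = c("1001", "1002", "1003"),
    symbol = c("TP53", "BRCA1", "EGFR"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(100, 500, 100),
    end = c(200, 700, 300),
    aliases = list(c("P53", "SHARED"), c("SHARED"), c("ERBB1"))
  )
}
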