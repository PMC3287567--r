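#' Build a clean interactome from raw interaction records
#'
#' Collapses a raw edge table to a simple undirected graph: self
#' interactions are removed, and (A,B)/(B,A) duplicates are merged. The
#' counts of removed records are reported so the cleanup is auditable
#' against the raw download.
#'
#' @param records Tibble with columns `gene_a`, `gene_b` (see
#'   [read_edge_list()]), or any data frame whose first two columns are the
#'   endpoints.
#' @param quiet Suppress the cleanup message.
#' @return An undirected simple [igraph][igraph::graph] whose vertex names
#'   are gene identifiers.
#' @examples
#' build_interactome(tibble::tibble(gene_a = c("A", "B", "A"),
#'                                  gene_b = c("B", "A", "A")))
#' @export
build_interactome <- function(records, quiet = FALSE) {
  if (!all(c("gene_a", "gene_b") %in% names(records))) {
    names(records)[1:2] <- c("gene_a", "gene_b")
  }
  a <- as.character(records$gene_a)
  b <- as.character(records$gene_b)
  n_raw <- length(a)
  self <- a == b
  lo <- pmin(a[!self], b[!self])
  hi <- pmax(a[!self], b[!self])
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  if (!quiet && n_raw > 0) {
    inform(sprintf(
      "build_interactome: %d raw records; removed %d self-interaction(s) and %d duplicate(s); %d edges retained",
      n_raw, sum(self), sum(dup), sum(!dup)))
  }
  igraph::graph_from_data_frame(
    data.frame(from = lo[!dup], to = hi[!dup]),
    directed = FALSE,
    vertices = data.frame(name = sort(unique(c(a, b))))
  )
}

check_vertices <- function(g, genes) {
  missing <- setdiff(genes, igraph::V(g)$name)
  if (length(missing) > 0L)
    abort(sprintf("gene(s) not in the interactome: %s",
                  paste(head(missing, 5), collapse = ", ")))
}

#' Node degree
#'
#' The number of edges adjacent to a gene in the interactome. Asking for a
#' gene absent from the graph is an error (distinct from degree 0).
#'
#' @param g Interactome graph.
#' @param gene Character vector of gene identifiers.
#' @return Named integer vector of degrees.
#' @export
node_degree <- function(g, gene) {
  check_vertices(g, gene)
  igraph::degree(g, v = gene)
}

#' Node betweenness centrality
#'
#' The accumulated fraction of shortest paths between other node pairs that
#' pass through a gene (Brandes accumulation over unordered pairs,
#' endpoints excluded, fractional credit when several geodesics tie,
#' unnormalised). Disconnected pairs contribute nothing.
#'
#' @inheritParams node_degree
#' @return Named numeric vector of betweenness values.
#' @export
node_betweenness <- function(g, gene) {
  check_vertices(g, gene)
  igraph::betweenness(g, v = gene, directed = FALSE, normalized = FALSE)
}

#' Shortest path length between two genes
#'
#' Unweighted hop count; `Inf` when the genes lie in different components;
#' 0 when `a == b`.
#'
#' @param g Interactome graph.
#' @param a,b Gene identifiers.
#' @return A single number (possibly `Inf`).
#' @export
shortest_path_length <- function(g, a, b) {
  check_vertices(g, c(a, b))
  as.numeric(igraph::distances(g, v = a, to = b))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Compares two groups of topology values (e.g. degrees of two disease gene
#' lists). Uses exact enumeration when the pooled sample is small
#' (`length(x) + length(y) <= 12`) and tie-free, otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @return Two-sided p-value in (0, 1].
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) abort("both samples must be non-empty")
  no_ties <- !anyDuplicated(c(x, y))
  exact <- (length(x) + length(y)) <= 12 && no_ties
  res <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE)
  )
  min(res$p.value, 1)
}

#' Topology summary for a gene group
#'
#' Computes degree and betweenness summaries for a candidate gene list
#' mapped onto the interactome, plus the binned degree distribution used to
#' compare groups. Genes absent from the interactome are excluded from the
#' statistics and counted, mirroring the usual situation where only part of
#' a candidate list has interaction annotations.
#'
#' @param g Interactome graph.
#' @param genes Character vector of candidate gene identifiers.
#' @param bins Strictly increasing numeric vector of degree bin edges.
#'   Bins are left-closed right-open, `[lo, hi)`; degrees at or above the
#'   last edge fall in an overflow bin.
#' @param label Group label carried into the output.
#' @return A list of class `group_topology` with elements `summary` (one-row
#'   tibble: label, n_input, n_mapped, mean/median degree and betweenness),
#'   `per_gene` (tibble gene/degree/betweenness), `bin_table` (tibble bin,
#'   count, proportion) and `unmapped` (character).
#' @export
group_topology <- function(g, genes, bins = c(0, 2, 4, 8, 16, 32, 64),
                           label = "group") {
  if (is.unsorted(bins, strictly = TRUE)) abort("bins must be strictly increasing")
  genes <- unique(as.character(genes))
  mapped <- intersect(genes, igraph::V(g)$name)
  if (length(mapped) == 0L) abort("no gene in the group maps into the interactome")
  unmapped <- setdiff(genes, mapped)
  deg <- igraph::degree(g, v = mapped)
  btw <- igraph::betweenness(g, v = mapped, directed = FALSE)
  edges <- c(bins, Inf)
  labels <- c(sprintf("[%g,%g)", bins[-length(bins)], bins[-1]),
              sprintf(">=%g", bins[length(bins)]))
  idx <- findInterval(deg, edges, left.open = FALSE)
  idx[deg < bins[1]] <- NA  # below-range degrees are not binned
  counts <- tabulate(idx, nbins = length(labels))
  bin_table <- tibble(
    group = label, bin = labels, count = counts,
    proportion = counts / length(mapped)
  )
  structure(list(
    summary = tibble(
      group = label,
      n_input = length(genes),
      n_mapped = length(mapped),
      mean_degree = mean(deg),
      median_degree = median(deg),
      mean_betweenness = mean(btw),
      median_betweenness = median(btw)
    ),
    per_gene = tibble(gene = mapped, degree = as.integer(deg),
                      betweenness = unname(btw)),
    bin_table = bin_table,
    unmapped = unmapped
  ), class = "group_topology")
}

#' @export
print.group_topology <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<group_topology> %s: %d/%d genes mapped\n",
              s$group, s$n_mapped, s$n_input))
  cat(sprintf("  degree  mean %.2f  median %g\n", s$mean_degree, s$median_degree))
  cat(sprintf("  betweenness  mean %.4g  median %.4g\n",
              s$mean_betweenness, s$median_betweenness))
  invisible(x)
}

#' Plot binned degree distributions of one or more gene groups
#'
#' @param ... `group_topology` objects.
#' @return A ggplot bar chart of per-bin proportions by group.
#' @export
plot_degree_bins <- function(...) {
  groups <- list(...)
  stopifnot(all(purrr::map_lgl(groups, inherits, "group_topology")))
  tab <- purrr::map_dfr(groups, "bin_table")
  tab$bin <- factor(tab$bin, levels = unique(tab$bin))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$bin, y = .data$proportion,
                                    fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "degree bin", y = "proportion of mapped genes",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
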