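#' Jaccard coefficient of two gene sets
#'
#' `|A ∩ B| / |A ∪ B|`. Both sets must be non-empty.
#'
#' @param A,B Character vectors of gene identifiers.
#' @return A number in \[0, 1\].
#' @export
jaccard_coefficient <- function(A, B) {
  A <- unique(A); B <- unique(B)
  if (length(A) == 0L || length(B) == 0L) abort("gene sets must be non-empty")
  length(intersect(A, B)) / length(union(A, B))
}

#' Overlap coefficient of two gene sets
#'
#' `|A ∩ B| / min(|A|, |B|)`; saturates at 1 when one set contains the
#' other.
#'
#' @inheritParams jaccard_coefficient
#' @return A number in \[0, 1\].
#' @export
overlap_coefficient <- function(A, B) {
  A <- unique(A); B <- unique(B)
  if (length(A) == 0L || length(B) == 0L) abort("gene sets must be non-empty")
  length(intersect(A, B)) / min(length(A), length(B))
}

#' Crosstalk score of two gene sets
#'
#' The arithmetic mean of the Jaccard and overlap coefficients, the score
#' by which candidate crosstalk edges are ranked. Always lies between the
#' two coefficients.
#'
#' @inheritParams jaccard_coefficient
#' @return A number in \[0, 1\].
#' @examples
#' # two pathways observing 23 and 31 candidate genes, 23 shared:
#' A <- paste0("g", 1:23)
#' B <- paste0("g", 1:31)
#' crosstalk_score(A, B)  # (23/31 + 1) / 2 = 0.87 (2 d.p.)
#' @export
crosstalk_score <- function(A, B) {
  (jaccard_coefficient(A, B) + overlap_coefficient(A, B)) / 2
}

#' Crosstalk construction parameters
#'
#' Defaults follow the rule set used for candidate-gene pathway crosstalk:
#' pathways need at least `min_genes` observed candidate genes and
#' BH-adjusted p below `max_padj`; a candidate edge needs at least
#' `min_shared` shared candidate genes; and only the `top_fraction` of
#' candidate edges by score are retained.
#'
#' @param min_genes Minimum observed candidate genes per pathway (default 5).
#' @param max_padj Strict upper bound on BH-adjusted p (default 0.01).
#' @param min_shared Minimum shared candidate genes per edge (default 3).
#' @param top_fraction Fraction of candidate edges retained (default 0.10).
#' @param keep_isolated Keep filtered pathways with no retained edge as
#'   isolated nodes (default `FALSE`: the crosstalk graph shows only
#'   connected pathways).
#' @return A list of class `crosstalk_config`.
#' @export
crosstalk_config <- function(min_genes = 5, max_padj = 0.01,
                             min_shared = 3, top_fraction = 0.10,
                             keep_isolated = FALSE) {
  stopifnot(top_fraction > 0, top_fraction <= 1, min_shared >= 1,
            min_genes >= 1, max_padj > 0)
  structure(list(min_genes = min_genes, max_padj = max_padj,
                 min_shared = min_shared, top_fraction = top_fraction,
                 keep_isolated = keep_isolated),
            class = "crosstalk_config")
}

#' Retain the top-scoring fraction of candidate edges
#'
#' Keeps `floor(top_fraction * n)` edges of highest score. Ties at the
#' cutoff are broken deterministically by descending shared-gene count,
#' then lexicographic pathway pair.
#'
#' @param edges Tibble with columns `pathway_a`, `pathway_b`, `score` and
#'   `n_shared`.
#' @param top_fraction Fraction in (0, 1\].
#' @return The retained rows, ranked.
#' @export
retain_top_edges <- function(edges, top_fraction = 0.10) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  n_keep <- floor(top_fraction * nrow(edges))
  ranked <- dplyr::arrange(edges, dplyr::desc(.data$score),
                           dplyr::desc(.data$n_shared),
                           .data$pathway_a, .data$pathway_b)
  head(ranked, n_keep)
}

#' Build a pathway-crosstalk network
#'
#' Starting from an enrichment result table, applies the three filtering
#' rules — (1) at least `min_genes` observed candidate genes, (2)
#' BH-adjusted p strictly below `max_padj`, (3) edge partners share at
#' least `min_shared` observed candidate genes — scores every surviving
#' pathway pair by the mean of Jaccard and overlap coefficients computed on
#' the pathways' OBSERVED candidate genes, and retains the top fraction of
#' the score distribution.
#'
#' @param results Enrichment tibble from [run_enrichment()] (needs `term`,
#'   `k`, `p_bh`, `observed_genes`).
#' @param config A [crosstalk_config()].
#' @return An object of class `crosstalk_network`: list with `nodes`
#'   (tibble pathway/k/p_bh), `edges` (tibble pathway_a/pathway_b/
#'   n_shared/shared_genes/jc/oc/score), `n_candidate_edges`, `graph`
#'   (igraph) and `config`.
#' @export
build_crosstalk_network <- function(results, config = crosstalk_config()) {
  stopifnot(all(c("term", "k", "p_bh", "observed_genes") %in% names(results)))
  at_boundary <- sum(results$p_bh == config$max_padj)
  if (at_boundary > 0)
    inform(sprintf("build_crosstalk_network: %d pathway(s) exactly at the adjusted-p threshold excluded (strict inequality)",
                   at_boundary))
  kept <- dplyr::filter(results, .data$k >= config$min_genes,
                        .data$p_bh < config$max_padj)
  inform(sprintf("build_crosstalk_network: %d of %d pathway(s) pass filters (k >= %g, p_bh < %g)",
                 nrow(kept), nrow(results), config$min_genes, config$max_padj))
  empty <- function() {
    warn("no crosstalk network: no pathway pair survives the filters")
    edges <- tibble(pathway_a = character(), pathway_b = character(),
                    n_shared = integer(), shared_genes = list(),
                    jc = numeric(), oc = numeric(), score = numeric())
    structure(list(nodes = tibble(pathway = character(), k = integer(),
                                  p_bh = numeric()),
                   edges = edges, n_candidate_edges = 0L,
                   graph = igraph::make_empty_graph(directed = FALSE),
                   config = config),
              class = "crosstalk_network")
  }
  if (nrow(kept) < 2) return(empty())
  kept <- dplyr::arrange(kept, .data$term)
  sets <- setNames(kept$observed_genes, kept$term)
  pairs <- combn(kept$term, 2)
  cand <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    shared <- sort(intersect(sets[[a]], sets[[b]]))
    if (length(shared) < config$min_shared) return(NULL)
    tibble(pathway_a = a, pathway_b = b,
           n_shared = length(shared), shared_genes = list(shared),
           jc = jaccard_coefficient(sets[[a]], sets[[b]]),
           oc = overlap_coefficient(sets[[a]], sets[[b]]),
           score = crosstalk_score(sets[[a]], sets[[b]]))
  })
  if (is.null(cand) || nrow(cand) == 0) return(empty())
  sharing_pathways <- unique(c(cand$pathway_a, cand$pathway_b))
  inform(sprintf("build_crosstalk_network: %d pathway(s) share >= %g candidate genes with another; %d candidate edge(s)",
                 length(sharing_pathways), config$min_shared, nrow(cand)))
  edges <- retain_top_edges(cand, config$top_fraction)
  inform(sprintf("build_crosstalk_network: retained top %d edge(s) (%.0f%% of %d)",
                 nrow(edges), 100 * config$top_fraction, nrow(cand)))
  node_names <- if (config$keep_isolated) kept$term else
    unique(c(edges$pathway_a, edges$pathway_b))
  nodes <- dplyr::filter(kept, .data$term %in% node_names)
  nodes <- tibble(pathway = nodes$term, k = nodes$k, p_bh = nodes$p_bh)
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$pathway_a, to = edges$pathway_b,
               n_shared = edges$n_shared, jc = edges$jc, oc = edges$oc,
               score = edges$score),
    directed = FALSE,
    vertices = data.frame(name = nodes$pathway, k = nodes$k,
                          p_bh = nodes$p_bh))
  structure(list(nodes = nodes, edges = edges,
                 n_candidate_edges = nrow(cand), graph = g, config = config),
            class = "crosstalk_network")
}

#' @export
print.crosstalk_network <- function(x, ...) {
  cat(sprintf("<crosstalk_network> %d pathways, %d edges retained of %d candidates (top %.0f%%)\n",
              nrow(x$nodes), nrow(x$edges), x$n_candidate_edges,
              100 * x$config$top_fraction))
  invisible(x)
}

#' @rdname build_crosstalk_network
#' @param x A `crosstalk_network`.
#' @param ... Unused.
#' @method tidy crosstalk_network
#' @export
tidy.crosstalk_network <- function(x, ...) {
  out <- x$edges
  out$shared_genes <- purrr::map_chr(out$shared_genes, paste, collapse = ",")
  out
}

#' @rdname build_crosstalk_network
#' @method glance crosstalk_network
#' @export
glance.crosstalk_network <- function(x, ...) {
  tibble(n_pathways = nrow(x$nodes),
         n_candidate_edges = x$n_candidate_edges,
         n_retained_edges = nrow(x$edges),
         top_fraction = x$config$top_fraction,
         min_genes = x$config$min_genes,
         max_padj = x$config$max_padj,
         min_shared = x$config$min_shared)
}

#' @rdname build_crosstalk_network
#' @param object A `crosstalk_network`.
#' @method autoplot crosstalk_network
#' @export
autoplot.crosstalk_network <- function(object, ...) {
  if (nrow(object$edges) == 0) abort("empty crosstalk network")
  lay <- igraph::layout_with_fr(object$graph)
  nodes <- object$nodes
  nodes$x <- lay[, 1]; nodes$y <- lay[, 2]
  seg <- dplyr::left_join(object$edges,
                          dplyr::select(nodes, "pathway", "x", "y"),
                          by = c(pathway_a = "pathway"))
  seg <- dplyr::left_join(seg, dplyr::select(nodes, "pathway", "x", "y"),
                          by = c(pathway_b = "pathway"),
                          suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$score),
      colour = "grey60") +
    ggplot2::geom_point(data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$k,
                   colour = -log10(.data$p_bh))) +
    ggplot2::geom_text(data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$pathway),
      vjust = -1, size = 3) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5)) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "-log10 adj. p", size = "candidate genes")
}

#' Export a crosstalk network to disk
#'
#' @param net A `crosstalk_network`.
#' @param path Output path.
#' @param format `"graphml"`, `"sif"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_crosstalk <- function(net, path, format = c("graphml", "sif", "tsv")) {
  format <- match.arg(format)
  nodes <- dplyr::rename(net$nodes, name = "pathway")
  edges <- tidy(net)
  edges <- dplyr::rename(edges, from = "pathway_a", to = "pathway_b")
  write_graph_file(nodes, edges, path, format = format, relation = "crosstalk")
}
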