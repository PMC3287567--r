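#' Upper-tail hypergeometric p-value
#'
#' P(X >= k) where X ~ Hypergeometric(N, K, n): the probability of drawing
#' at least `k` annotated genes when `n` query genes are drawn from a
#' universe of `N` genes of which `K` carry the annotation. Computed on the
#' log scale via [stats::phyper] for numerical stability.
#'
#' @param k Observed overlap count.
#' @param n Query size.
#' @param K Set size in the universe.
#' @param N Universe size.
#' @return Upper-tail p-value in (0, 1].
#' @export
hypergeometric_p <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || k > min(n, K) || n > N || K > N)
    abort("inconsistent counts: need 0 <= k <= min(n, K) and n, K <= N")
  if (k == 0) return(1)
  exp(phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' One-sided Fisher's exact test for a 2x2 table
#'
#' Tests enrichment (tables as or more extreme toward a large top-left
#' cell) for the table `rbind(c(a, b), c(c, d))` via the hypergeometric
#' tail, as used for canonical-pathway over-representation.
#'
#' @param a,b,c,d Non-negative cell counts; `a` is the overlap cell.
#' @return One-sided p-value.
#' @export
fisher_exact_one_sided <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) abort("cell counts must be non-negative")
  if (a + b + c + d == 0) abort("all-zero table")
  fisher.test(matrix(c(a, c, b, d), nrow = 2),
              alternative = "greater")$p.value
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control: after sorting ascending,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1; returned in input
#' order. Thin validated wrapper over [stats::p.adjust].
#'
#' @param ps Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(ps) {
  if (any(is.na(ps)) || any(ps < 0 | ps > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(ps, method = "BH")
}

#' Configuration for enrichment testing
#'
#' @param test `"hypergeometric"` (upper tail) or `"fisher-one-sided"`.
#'   The two are numerically identical on the same margins; both are kept
#'   because the field's tools report them under both names.
#' @param universe_mode How the background universe is chosen:
#'   `"collection-union"` (default; union of all set members),
#'   `"explicit"` (use `universe`), or `"interactome"` (pass the
#'   interactome's gene names via `universe`).
#' @param universe Character vector used when `universe_mode` is not
#'   `"collection-union"`.
#' @return A list of class `enrichment_config`.
#' @export
enrichment_config <- function(test = c("hypergeometric", "fisher-one-sided"),
                              universe_mode = c("collection-union",
                                                "explicit", "interactome"),
                              universe = NULL) {
  test <- match.arg(test)
  universe_mode <- match.arg(universe_mode)
  if (universe_mode != "collection-union" && is.null(universe))
    abort(sprintf("universe_mode '%s' requires a universe", universe_mode))
  structure(list(test = test, universe_mode = universe_mode,
                 universe = universe),
            class = "enrichment_config")
}

#' Gene-set over-representation analysis
#'
#' Tests every set in the collection for over-representation of the query
#' genes, corrects across sets with Benjamini-Hochberg, and returns the
#' result table (one row per set, sorted by raw p, ties broken by term
#' name). Query genes outside the universe are excluded and counted.
#'
#' @param query Character vector of candidate gene identifiers.
#' @param collection A [gene_set_collection()].
#' @param config An [enrichment_config()].
#' @return A tibble with columns `term`, `k` (observed query genes in the
#'   set), `K` (set size), `n` (effective query size), `N` (universe
#'   size), `p`, `p_bh`, `observed_genes` (list-column).
#' @export
run_enrichment <- function(query, collection,
                           config = enrichment_config()) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- switch(config$universe_mode,
    "collection-union" = collection$universe,
    unique(as.character(config$universe))
  )
  query <- unique(as.character(query))
  eff <- intersect(query, universe)
  if (length(eff) == 0L) abort("query is empty after intersecting with the universe")
  if (length(eff) < length(query))
    inform(sprintf("run_enrichment: %d query gene(s) outside the universe excluded",
                   length(query) - length(eff)))
  N <- length(universe)
  n <- length(eff)
  rows <- purrr::imap_dfr(collection$sets, function(members, nm) {
    members <- intersect(members, universe)
    obs <- intersect(eff, members)
    k <- length(obs); K <- length(members)
    p <- if (config$test == "hypergeometric") {
      hypergeometric_p(k, n, K, N)
    } else {
      fisher_exact_one_sided(k, n - k, K - k, N - K - n + k)
    }
    tibble(term = nm, k = k, K = K, n = n, N = N, p = p,
           observed_genes = list(sort(obs)))
  })
  rows$p_bh <- bh_adjust(rows$p)
  dplyr::arrange(rows, .data$p, .data$term)[
    , c("term", "k", "K", "n", "N", "p", "p_bh", "observed_genes")]
}

#' Transform enrichment p-values to scores
#'
#' The `-log10(p)` convenience transform under which pathway-analysis
#' tools report network scores.
#'
#' @param p Numeric p-values.
#' @return `-log10(p)`.
#' @export
neglog10 <- function(p) -log10(p)

#' Write an enrichment result table as TSV
#'
#' @param results Tibble from [run_enrichment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(results, path) {
  out <- results
  out$observed_genes <- purrr::map_chr(results$observed_genes, paste,
                                       collapse = ",")
  readr::write_tsv(out, path)
  invisible(path)
}
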