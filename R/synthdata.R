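# Synthetic data with planted ground truth.
#
# Every generator is a pure function of its parameters and seed, so the
# whole pipeline can be exercised end to end with known answers: a
# scale-free interactome with a planted connected disease module, pathway
# collections with planted enrichment and controlled overlap blocks, and
# SNP p-values that are uniform under the null and stochastically small
# for associated genes.

gene_ids <- function(n) sprintf("G%05d", seq_len(n))

# sample() treats a scalar first argument as 1:x; guard degenerate ranges
sample_range <- function(lo, hi, n) {
  vals <- lo:hi
  if (length(vals) == 1L) rep(vals, n) else sample(vals, n, replace = TRUE)
}

#' Simulate a scale-free interactome
#'
#' Preferential-attachment growth: node `i` (arriving in order) attaches
#' `min(m, i - 1)` edges to distinct existing nodes, chosen with
#' probability proportional to current degree + 1. The result is a
#' connected simple graph with exactly `sum(min(m, i - 1))` edges and a
#' heavy-tailed degree distribution, emulating a genome-scale
#' protein-interaction network.
#'
#' @param n_nodes Number of genes (>= `edges_per_node + 1`).
#' @param edges_per_node Attachment parameter `m`.
#' @param seed Integer seed; the generator is deterministic given it.
#' @return An igraph with vertex names `G00001`, `G00002`, ...
#' @export
simulate_interactome <- function(n_nodes, edges_per_node = 3, seed = 1) {
  stopifnot(n_nodes >= edges_per_node + 1, edges_per_node >= 1)
  withr::with_seed(seed, {
    deg <- integer(n_nodes)
    n_edges <- sum(pmin(edges_per_node, seq_len(n_nodes) - 1L))
    from <- integer(n_edges); to <- integer(n_edges)
    pos <- 0L
    for (i in 2:n_nodes) {
      k <- min(edges_per_node, i - 1L)
      existing <- seq_len(i - 1L)
      targets <- if (length(existing) == 1L) existing else
        sample(existing, k, prob = deg[existing] + 1)
      from[pos + seq_len(k)] <- i
      to[pos + seq_len(k)] <- targets
      pos <- pos + k
      deg[targets] <- deg[targets] + 1L
      deg[i] <- deg[i] + k
    }
    ids <- gene_ids(n_nodes)
    igraph::graph_from_data_frame(
      data.frame(from = ids[pmin(from, to)], to = ids[pmax(from, to)]),
      directed = FALSE, vertices = data.frame(name = ids))
  })
}

#' Plant a recoverable disease module in an interactome
#'
#' Grows a random connected subtree of `n_terminals + n_linkers` nodes
#' (path-biased growth, so the tree has few leaves), then labels nodes so
#' that every tree leaf is a terminal; remaining terminals are drawn from
#' the internal nodes and the rest become linkers. Because all leaves are
#' terminals, every linker is an internal tree node lying on a path
#' between two terminals — within the planted subtree each linker is
#' required to keep the terminals connected, giving Steiner extraction an
#' unambiguous ground truth (the host graph may still offer cheaper
#' detours, so the planted linker weight upper-bounds the optimum).
#'
#' @param g Interactome (igraph).
#' @param n_terminals Number of terminal (candidate) genes, >= 2.
#' @param n_linkers Number of planted linker genes.
#' @param seed Integer seed.
#' @return A list of class `synthetic_truth` with `terminals`, `linkers`,
#'   `module_edges` (tibble from/to of the planted tree) and `params`.
#' @export
plant_disease_module <- function(g, n_terminals, n_linkers, seed = 1) {
  stopifnot(n_terminals >= 2, n_linkers >= 0)
  size <- n_terminals + n_linkers
  vnames <- igraph::V(g)$name
  if (size > length(vnames)) abort("graph too small for the requested module")
  adj <- adj_int_list(g)
  withr::with_seed(seed, {
    for (attempt in 1:50) {
      start <- sample(length(vnames), 1)
      in_tree <- rep(FALSE, length(vnames))
      in_tree[start] <- TRUE
      nodes <- start
      edges <- matrix(integer(), ncol = 2)
      last <- start
      while (length(nodes) < size) {
        # path-biased growth keeps the leaf count low
        grow_from <- NULL
        if (runif(1) < 0.8) {
          nb <- adj[[last]][!in_tree[adj[[last]]]]
          if (length(nb) > 0) grow_from <- last
        }
        if (is.null(grow_from)) {
          open <- nodes[purrr::map_lgl(nodes,
                                       ~ any(!in_tree[adj[[.x]]]))]
          if (length(open) == 0) break
          grow_from <- open[sample(length(open), 1)]
        }
        nb <- adj[[grow_from]][!in_tree[adj[[grow_from]]]]
        nxt <- nb[sample(length(nb), 1)]
        in_tree[nxt] <- TRUE
        nodes <- c(nodes, nxt)
        edges <- rbind(edges, c(grow_from, nxt))
        last <- nxt
      }
      if (length(nodes) < size) next
      deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = length(vnames))
      leaves <- nodes[deg[nodes] == 1]
      internal <- setdiff(nodes, leaves)
      if (length(leaves) > n_terminals) next
      extra <- n_terminals - length(leaves)
      extra_terminals <- if (extra > 0)
        internal[sample(length(internal), extra)] else integer(0)
      terminals <- c(leaves, extra_terminals)
      linkers <- setdiff(nodes, terminals)
      return(structure(list(
        terminals = sort(vnames[terminals]),
        linkers = sort(vnames[linkers]),
        module_edges = tibble(from = vnames[edges[, 1]],
                              to = vnames[edges[, 2]]),
        params = list(n_terminals = n_terminals, n_linkers = n_linkers,
                      seed = seed)
      ), class = "synthetic_truth"))
    }
    abort("could not plant a module with the requested shape; graph too sparse")
  })
}

#' Simulate a pathway collection with planted enrichment and overlap
#'
#' Null sets draw members uniformly from the universe; enriched sets draw
#' a fraction of their members from the candidate list, so they are truly
#' over-represented. Overlap blocks force groups of enriched sets to share
#' a common core of candidate genes, planting ground-truth crosstalk
#' edges.
#'
#' @param universe Character vector of background genes.
#' @param n_sets Total number of sets.
#' @param size_range Length-2 integer vector: set sizes are drawn
#'   uniformly from this range.
#' @param candidates Character vector of candidate genes (subset of
#'   universe).
#' @param n_enriched Number of sets planted as enriched.
#' @param enriched_fraction Fraction of an enriched set's members drawn
#'   from the candidates (default 0.5).
#' @param overlap_blocks List of blocks, each `list(n_sets =, core_size =)`;
#'   blocks claim disjoint groups of enriched sets and disjoint cores.
#' @param seed Integer seed.
#' @return List with `collection` (a [gene_set_collection()]) and `truth`
#'   (`synthetic_truth`: `enriched_sets`, `block_members`, `block_cores`,
#'   `params`).
#' @export
simulate_pathways <- function(universe, candidates, n_sets = 50,
                              size_range = c(20, 60), n_enriched = 10,
                              enriched_fraction = 0.5,
                              overlap_blocks = list(), seed = 1) {
  stopifnot(n_enriched <= n_sets, length(size_range) == 2,
            size_range[1] <= size_range[2],
            all(candidates %in% universe))
  n_block_sets <- sum(purrr::map_dbl(overlap_blocks, "n_sets"))
  if (n_block_sets > n_enriched)
    abort("overlap blocks claim more sets than are enriched")
  core_total <- sum(purrr::map_dbl(overlap_blocks, "core_size"))
  if (core_total > length(candidates))
    abort("overlap cores require more candidate genes than available")
  withr::with_seed(seed, {
    set_names <- sprintf("PW%03d", seq_len(n_sets))
    enriched <- set_names[seq_len(n_enriched)]
    sizes <- sample_range(size_range[1], size_range[2], n_sets)
    non_candidates <- setdiff(universe, candidates)
    # disjoint candidate cores per block
    pool <- sample(candidates)
    cores <- list(); block_members <- list()
    next_set <- 1L
    for (bi in seq_along(overlap_blocks)) {
      b <- overlap_blocks[[bi]]
      cores[[bi]] <- pool[seq_len(b$core_size)]
      pool <- pool[-seq_len(b$core_size)]
      block_members[[bi]] <- set_names[next_set:(next_set + b$n_sets - 1L)]
      next_set <- next_set + b$n_sets
    }
    sets <- purrr::map(seq_len(n_sets), function(i) {
      nm <- set_names[i]
      size <- sizes[i]
      core <- character(0)
      for (bi in seq_along(block_members))
        if (nm %in% block_members[[bi]]) core <- cores[[bi]]
      if (nm %in% enriched) {
        # the candidate pool caps how many candidate members a set can hold
        n_cand <- max(round(enriched_fraction * size), length(core))
        n_cand <- min(n_cand, length(candidates), size)
        avail <- setdiff(candidates, core)
        extra_cand <- sample(avail, min(n_cand - length(core), length(avail)))
        members <- c(core, extra_cand,
                     sample(non_candidates, size - length(core) -
                              length(extra_cand)))
      } else {
        members <- sample(universe, size)
      }
      unique(members)
    })
    names(sets) <- set_names
    truth <- structure(list(
      enriched_sets = enriched,
      block_members = block_members,
      block_cores = cores,
      params = list(n_sets = n_sets, n_enriched = n_enriched,
                    enriched_fraction = enriched_fraction,
                    size_range = size_range, seed = seed)
    ), class = "synthetic_truth")
    list(collection = gene_set_collection(sets, universe = universe),
         truth = truth)
  })
}

#' Simulate a gene coordinate table
#'
#' Lays genes end to end along synthetic chromosomes with fixed gene
#' length and spacing, giving every gene usable 1-based coordinates for
#' SNP mapping.
#'
#' @param ids Character vector of gene identifiers.
#' @param genes_per_chrom Number of genes per synthetic chromosome.
#' @param gene_length Gene length in bp.
#' @param spacing Gap between consecutive genes in bp.
#' @return A gene table tibble (`gene_id`, `symbol`, `chrom`, `start`,
#'   `end`, `aliases` list-column).
#' @export
simulate_gene_table <- function(ids, genes_per_chrom = 500,
                                gene_length = 20000, spacing = 5000) {
  n <- length(ids)
  idx <- seq_len(n) - 1L
  chrom <- paste0("chr", idx %/% genes_per_chrom + 1L)
  offset <- (idx %% genes_per_chrom) * (gene_length + spacing)
  tibble(
    gene_id = ids,
    symbol = sub("^G", "SYM", ids),
    chrom = chrom,
    start = offset + 1,
    end = offset + gene_length,
    aliases = purrr::map(ids, ~ character())
  )
}

#' Simulate SNP association summary statistics
#'
#' Each gene receives a uniform number of SNPs placed uniformly inside its
#' region. SNP p-values are Uniform(0, 1) for null genes and
#' Beta(`beta_shape`, 1) — stochastically small for `beta_shape < 1` — for
#' associated genes. The Beta(a, 1) alternative gives the closed form
#' P(p_min < q) = 1 - (1 - q^a)^s for a gene with s SNPs, used by the
#' recovery checks.
#'
#' @param genes Gene table with coordinates.
#' @param associated Character vector of gene_ids carrying signal.
#' @param snps_per_gene Length-2 integer range of SNP counts per gene.
#' @param beta_shape Beta shape a in (0, 1]; 1 means no signal.
#' @param seed Integer seed.
#' @return List with `assoc` (tibble snp_id/chrom/pos/p) and `truth`
#'   (`synthetic_truth` with `associated` and `params`).
#' @export
simulate_gwas <- function(genes, associated = character(),
                          snps_per_gene = c(1, 5), beta_shape = 0.2,
                          seed = 1) {
  stopifnot(beta_shape > 0, beta_shape <= 1,
            length(snps_per_gene) == 2, snps_per_gene[1] >= 1)
  withr::with_seed(seed, {
    n_snps <- sample_range(snps_per_gene[1], snps_per_gene[2], nrow(genes))
    idx <- rep(seq_len(nrow(genes)), n_snps)
    snp_no <- sequence(n_snps)
    pos <- floor(runif(length(idx), genes$start[idx], genes$end[idx] + 1))
    is_assoc <- genes$gene_id[idx] %in% associated
    p <- numeric(length(idx))
    p[!is_assoc] <- runif(sum(!is_assoc))
    p[is_assoc] <- rbeta(sum(is_assoc), beta_shape, 1)
    rows <- tibble(
      snp_id = sprintf("rs_%s_%d", genes$gene_id[idx], snp_no),
      chrom = genes$chrom[idx], pos = pos, p = p)
    truth <- structure(list(
      associated = sort(intersect(associated, genes$gene_id)),
      params = list(snps_per_gene = snps_per_gene,
                    beta_shape = beta_shape, seed = seed)
    ), class = "synthetic_truth")
    list(assoc = rows, truth = truth)
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth>\n")
  for (nm in setdiff(names(x), "params")) {
    v <- x[[nm]]
    if (is.character(v)) cat(sprintf("  %s: %d item(s)\n", nm, length(v)))
    else if (is.data.frame(v)) cat(sprintf("  %s: %d row(s)\n", nm, nrow(v)))
    else cat(sprintf("  %s: %d element(s)\n", nm, length(v)))
  }
  invisible(x)
}

#' Write a synthetic truth record as a TSV sidecar
#'
#' Serialises the planted ground truth (one `item`/`value` pair per row,
#' parameters included) next to the generated data files.
#'
#' @param truth A `synthetic_truth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  rows <- purrr::imap_dfr(truth[setdiff(names(truth), "params")],
                          function(v, nm) {
    if (is.data.frame(v))
      return(tibble(item = nm,
                    value = paste(v[[1]], v[[2]], sep = "|")))
    if (is.list(v))
      return(purrr::imap_dfr(v, function(x, i)
        tibble(item = paste0(nm, ".", i),
               value = paste(x, collapse = ","))))
    tibble(item = nm, value = as.character(v))
  })
  pars <- purrr::imap_dfr(truth$params, function(v, nm)
    tibble(item = paste0("param.", nm),
           value = paste(v, collapse = ",")))
  readr::write_tsv(dplyr::bind_rows(rows, pars), path)
  invisible(path)
}
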