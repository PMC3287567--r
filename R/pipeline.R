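#' Pipeline configuration
#'
#' Collects the file paths and parameters consumed by [run_stage()]. All
#' intermediate artifacts are plain TSV/GMT/GraphML files, so any stage
#' can equally be driven by externally produced files with the same
#' schemas (a real interactome download, a real candidate list, real GWAS
#' summary statistics).
#'
#' @param out_dir Output directory (created if missing).
#' @param network Path to an edge-list file.
#' @param genes Path to a candidate gene list (one gene per line).
#' @param gmt Path to a GMT pathway collection.
#' @param assoc Path to a PLINK-style association table.
#' @param gene_table Path to a gene coordinate table.
#' @param crosstalk A [crosstalk_config()].
#' @param enrichment An [enrichment_config()].
#' @param flank_kb Flank for SNP-to-gene mapping (kb).
#' @param alpha Nominal significance threshold for the GWAS evaluation.
#' @param steiner_induce_edges Re-induce parent-graph edges in the
#'   subnetwork output.
#' @param degree_bins Degree bin edges for the topology stage.
#' @param seed Integer seed used by the simulate stage.
#' @param sim Named list of overrides for the simulate stage (`n_nodes`,
#'   `edges_per_node`, `n_terminals`, `n_linkers`, `n_candidates`,
#'   `n_sets`, `n_enriched`,
#'   `size_range`, `enriched_fraction`, `overlap_blocks`, `snps_per_gene`,
#'   `beta_shape`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "dignet-out",
                            network = NULL, genes = NULL, gmt = NULL,
                            assoc = NULL, gene_table = NULL,
                            crosstalk = crosstalk_config(),
                            enrichment = enrichment_config(),
                            flank_kb = 0, alpha = 0.05,
                            steiner_induce_edges = FALSE,
                            degree_bins = c(0, 2, 4, 8, 16, 32, 64),
                            seed = 1, sim = list()) {
  sim_defaults <- list(n_nodes = 2000, edges_per_node = 3,
                       n_terminals = 20, n_linkers = 8,
                       n_candidates = 150,
                       n_sets = 50, n_enriched = 10,
                       size_range = c(20, 60), enriched_fraction = 0.5,
                       overlap_blocks = list(list(n_sets = 3, core_size = 5),
                                             list(n_sets = 3, core_size = 5)),
                       snps_per_gene = c(1, 5), beta_shape = 0.2)
  unknown <- setdiff(names(sim), names(sim_defaults))
  if (length(unknown) > 0)
    abort(sprintf("unknown sim parameter(s): %s", paste(unknown, collapse = ", ")))
  sim_defaults[names(sim)] <- sim
  sim <- sim_defaults
  structure(list(out_dir = out_dir, network = network, genes = genes,
                 gmt = gmt, assoc = assoc, gene_table = gene_table,
                 crosstalk = crosstalk, enrichment = enrichment,
                 flank_kb = flank_kb, alpha = alpha,
                 steiner_induce_edges = steiner_induce_edges,
                 degree_bins = degree_bins, seed = seed, sim = sim),
            class = "pipeline_config")
}

default_paths <- function(config) {
  d <- config$out_dir
  list(network = config$network %||% file.path(d, "network.tsv"),
       genes = config$genes %||% file.path(d, "candidates.txt"),
       gmt = config$gmt %||% file.path(d, "pathways.gmt"),
       assoc = config$assoc %||% file.path(d, "assoc.tsv"),
       gene_table = config$gene_table %||% file.path(d, "gene_table.tsv"))
}

require_input <- function(path, what, stage) {
  if (is.null(path) || !file.exists(path))
    abort(sprintf("stage '%s' needs %s at '%s'; run the producing stage first or point the config at an existing file",
                  stage, what, path %||% "<unset>"))
  path
}

write_manifest <- function(config, stage, artifacts) {
  existing <- artifacts[file.exists(artifacts)]
  manifest <- list(
    stage = stage,
    seed = config$seed,
    parameters = list(flank_kb = config$flank_kb, alpha = config$alpha,
                      crosstalk = unclass(config$crosstalk),
                      sim = config$sim[!purrr::map_lgl(config$sim, is.list)]),
    artifacts = purrr::map(existing, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)),
           bytes = unname(file.size(f))))
  )
  path <- file.path(config$out_dir, paste0("manifest-", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run one pipeline stage (or all of them)
#'
#' Stages: `simulate` writes a synthetic network, candidate list, pathway
#' collection, gene table, association table and truth sidecars;
#' `topology` writes per-gene and binned topology tables for the candidate
#' list; `enrich` writes the enrichment table; `crosstalk` the crosstalk
#' network (TSV + GraphML); `subnet` the Steiner subnetwork (TSV +
#' GraphML); `gwas-eval` the gene-wise p table, bin table and partition
#' tests; `all` chains every stage. Each stage writes a JSON manifest with
#' parameters, seed and artifact checksums, and never mutates its inputs;
#' rerunning with an identical config reproduces identical tables.
#'
#' @param stage One of `"simulate"`, `"topology"`, `"enrich"`,
#'   `"crosstalk"`, `"subnet"`, `"gwas-eval"`, `"all"`.
#' @param config A [pipeline_config()].
#' @return Invisibly, a character vector of written artifact paths.
#' @export
run_stage <- function(stage = c("all", "simulate", "topology", "enrich",
                                "crosstalk", "subnet", "gwas-eval"),
                      config = pipeline_config()) {
  stage <- match.arg(stage)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (stage == "all") {
    out <- c(run_stage("simulate", config), run_stage("topology", config),
             run_stage("enrich", config), run_stage("crosstalk", config),
             run_stage("subnet", config), run_stage("gwas-eval", config))
    return(invisible(out))
  }
  paths <- default_paths(config)
  d <- config$out_dir
  artifacts <- switch(stage,
    "simulate" = stage_simulate(config, paths),
    "topology" = stage_topology(config, paths),
    "enrich" = stage_enrich(config, paths),
    "crosstalk" = stage_crosstalk(config, paths),
    "subnet" = stage_subnet(config, paths),
    "gwas-eval" = stage_gwas(config, paths)
  )
  write_manifest(config, stage, artifacts)
  invisible(artifacts)
}

stage_simulate <- function(config, paths) {
  s <- config$sim
  d <- config$out_dir
  g <- simulate_interactome(s$n_nodes, s$edges_per_node, seed = config$seed)
  module <- plant_disease_module(g, s$n_terminals, s$n_linkers,
                                 seed = config$seed + 1)
  universe <- igraph::V(g)$name
  # the candidate list is wider than the planted module, as a prioritised
  # disease gene list is wider than its connected interactome core
  candidates <- withr::with_seed(config$seed + 4, {
    extra <- max(0, s$n_candidates - length(module$terminals))
    sort(c(module$terminals,
           sample(setdiff(universe, c(module$terminals, module$linkers)),
                  extra)))
  })
  pw <- simulate_pathways(universe, candidates, n_sets = s$n_sets,
                          size_range = s$size_range,
                          n_enriched = s$n_enriched,
                          enriched_fraction = s$enriched_fraction,
                          overlap_blocks = s$overlap_blocks,
                          seed = config$seed + 2)
  genes <- simulate_gene_table(universe)
  gw <- simulate_gwas(genes, associated = c(candidates, module$linkers),
                      snps_per_gene = s$snps_per_gene,
                      beta_shape = s$beta_shape, seed = config$seed + 3)
  el <- igraph::as_data_frame(g, what = "edges")
  readr::write_tsv(tibble(gene_a = el$from, gene_b = el$to), paths$network,
                   col_names = FALSE)
  readr::write_lines(candidates, paths$genes)
  write_gmt(pw$collection, paths$gmt)
  write_gene_table(genes, paths$gene_table)
  readr::write_tsv(dplyr::rename(gw$assoc, CHR = "chrom", SNP = "snp_id",
                                 BP = "pos", P = "p"), paths$assoc)
  write_truth(module, file.path(d, "truth-module.tsv"))
  write_truth(pw$truth, file.path(d, "truth-pathways.tsv"))
  write_truth(gw$truth, file.path(d, "truth-gwas.tsv"))
  c(unlist(paths, use.names = FALSE),
    file.path(d, c("truth-module.tsv", "truth-pathways.tsv",
                   "truth-gwas.tsv")))
}

read_inputs_graph <- function(config, paths, stage) {
  records <- read_edge_list(require_input(paths$network, "an edge list", stage))
  build_interactome(records, quiet = TRUE)
}

stage_topology <- function(config, paths) {
  g <- read_inputs_graph(config, paths, "topology")
  candidates <- readr::read_lines(
    require_input(paths$genes, "a candidate gene list", "topology"))
  top <- group_topology(g, candidates, bins = config$degree_bins,
                        label = "candidates")
  d <- config$out_dir
  readr::write_tsv(top$per_gene, file.path(d, "topology-genes.tsv"))
  readr::write_tsv(top$summary, file.path(d, "topology-summary.tsv"))
  readr::write_tsv(top$bin_table, file.path(d, "topology-bins.tsv"))
  file.path(d, c("topology-genes.tsv", "topology-summary.tsv",
                 "topology-bins.tsv"))
}

stage_enrich <- function(config, paths) {
  collection <- read_gmt(require_input(paths$gmt, "a GMT file", "enrich"))
  candidates <- readr::read_lines(
    require_input(paths$genes, "a candidate gene list", "enrich"))
  res <- run_enrichment(candidates, collection, config$enrichment)
  out <- file.path(config$out_dir, "enrichment.tsv")
  write_enrichment(res, out)
  out
}

read_enrichment_table <- function(path, stage) {
  require_input(path, "an enrichment table", stage)
  res <- readr::read_tsv(path, show_col_types = FALSE)
  res$observed_genes <- strsplit(res$observed_genes, ",", fixed = TRUE)
  res
}

stage_crosstalk <- function(config, paths) {
  res <- read_enrichment_table(file.path(config$out_dir, "enrichment.tsv"),
                               "crosstalk")
  net <- build_crosstalk_network(res, config$crosstalk)
  d <- config$out_dir
  readr::write_tsv(tidy(net), file.path(d, "crosstalk-edges.tsv"))
  readr::write_tsv(net$nodes, file.path(d, "crosstalk-nodes.tsv"))
  if (nrow(net$edges) > 0)
    write_crosstalk(net, file.path(d, "crosstalk.graphml"), "graphml")
  out <- file.path(d, c("crosstalk-edges.tsv", "crosstalk-nodes.tsv",
                        "crosstalk.graphml"))
  out[file.exists(out)]
}

stage_subnet <- function(config, paths) {
  g <- read_inputs_graph(config, paths, "subnet")
  candidates <- readr::read_lines(
    require_input(paths$genes, "a candidate gene list", "subnet"))
  sub <- klein_ravi_steiner(g, candidates,
                            induce_edges = config$steiner_induce_edges)
  d <- config$out_dir
  readr::write_tsv(sub$nodes, file.path(d, "subnetwork-nodes.tsv"))
  readr::write_tsv(sub$edges, file.path(d, "subnetwork-edges.tsv"))
  if (nrow(sub$edges) > 0)
    write_subnetwork(sub, file.path(d, "subnetwork.graphml"), "graphml")
  out <- file.path(d, c("subnetwork-nodes.tsv", "subnetwork-edges.tsv",
                        "subnetwork.graphml"))
  out[file.exists(out)]
}

stage_gwas <- function(config, paths) {
  assoc <- read_assoc(require_input(paths$assoc, "an association table",
                                    "gwas-eval"))
  genes <- read_gene_table(require_input(paths$gene_table,
                                         "a gene coordinate table",
                                         "gwas-eval"))
  candidates <- readr::read_lines(
    require_input(paths$genes, "a candidate gene list", "gwas-eval"))
  d <- config$out_dir
  sub_path <- require_input(file.path(d, "subnetwork-nodes.tsv"),
                            "a subnetwork node table", "gwas-eval")
  sub_nodes <- readr::read_tsv(sub_path, show_col_types = FALSE)
  gene_p <- assign_gene_p(assoc, genes, flank_kb = config$flank_kb)
  parts <- partition_genes(sub_nodes$gene, gene_p$gene, candidates)
  named <- setNames(gene_p$p_min, gene_p$gene)
  groups <- purrr::compact(purrr::map(parts, ~ named[.x]))
  bins <- bin_gene_p(groups[lengths(groups) > 0])
  tests <- dplyr::bind_rows(
    nominal_enrichment_test(parts$candidate_in_subnetwork, parts$rest,
                            named, alpha = config$alpha,
                            labels = c("candidate_in_subnetwork", "rest")),
    nominal_enrichment_test(parts$recruited, parts$rest, named,
                            alpha = config$alpha,
                            labels = c("recruited", "rest")),
    nominal_enrichment_test(c(parts$candidate_in_subnetwork,
                              parts$recruited), parts$rest, named,
                            alpha = config$alpha,
                            labels = c("subnetwork", "rest"))
  )
  readr::write_tsv(gene_p, file.path(d, "gene-wise-p.tsv"))
  readr::write_tsv(bins, file.path(d, "gene-p-bins.tsv"))
  readr::write_tsv(tests, file.path(d, "partition-tests.tsv"))
  file.path(d, c("gene-wise-p.tsv", "gene-p-bins.tsv",
                 "partition-tests.tsv"))
}
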