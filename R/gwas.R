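#' Gene-wise minimum SNP p-values
#'
#' Assigns each gene the smallest association p-value among the SNPs
#' mapping to its region: a SNP maps to a gene iff it lies on the same
#' chromosome and within `start - flank` to `end + flank` (closed
#' interval, 1-based). A SNP may map to several overlapping genes. Genes
#' with no mapped SNP are omitted (they have no gene-wise p, rather than
#' p = 1).
#'
#' Note the min-p statistic is biased: under the global null, genes with
#' more SNPs have stochastically smaller gene-wise p. No correction is
#' applied here; group comparisons should keep this in mind.
#'
#' @param assoc Tibble of SNP records (see [read_assoc()]).
#' @param genes Gene table with coordinates (see [read_gene_table()]).
#' @param flank_kb Flanking window in kilobases added to both gene ends
#'   (default 0: the gene region read literally).
#' @return Tibble with columns `gene`, `p_min`, `n_snps`, sorted by gene.
#' @export
assign_gene_p <- function(assoc, genes, flank_kb = 0) {
  stopifnot(flank_kb >= 0)
  genes <- dplyr::filter(genes, !is.na(.data$start), !is.na(.data$end))
  if (nrow(genes) == 0L) abort("no gene has coordinates")
  flank <- flank_kb * 1000
  hits <- dplyr::inner_join(
    dplyr::select(genes, gene = "gene_id", "chrom", "start", "end"),
    dplyr::select(assoc, "chrom", "pos", "p"),
    by = "chrom", relationship = "many-to-many"
  )
  hits <- dplyr::filter(hits, .data$pos >= .data$start - flank,
                        .data$pos <= .data$end + flank)
  if (nrow(hits) == 0L)
    return(tibble(gene = character(), p_min = numeric(), n_snps = integer()))
  out <- dplyr::summarise(dplyr::group_by(hits, .data$gene),
                          p_min = min(.data$p), n_snps = dplyr::n(),
                          .groups = "drop")
  dplyr::arrange(out, .data$gene)
}

#' Bin gene-wise p-values into the four reporting bins
#'
#' Bins are `<0.001`, `[0.001, 0.01)`, `[0.01, 0.05)` and `>=0.05`; the
#' last bin is closed on the left and runs to 1.
#'
#' @param groups Named list of tibbles from [assign_gene_p()] (or of bare
#'   numeric p-value vectors), one element per gene group.
#' @return A tibble of class `gene_p_bins` with columns `group`, `bin`,
#'   `count`, `proportion`.
#' @export
bin_gene_p <- function(groups) {
  stopifnot(is.list(groups), length(groups) > 0, !is.null(names(groups)))
  edges <- c(0, 0.001, 0.01, 0.05, 1 + 1e-9)
  labels <- c("<0.001", "0.001-0.01", "0.01-0.05", ">=0.05")
  out <- purrr::imap_dfr(groups, function(gr, nm) {
    p <- if (is.data.frame(gr)) gr$p_min else gr
    if (length(p) == 0L) abort(sprintf("group '%s' is empty", nm))
    idx <- findInterval(p, edges, left.open = FALSE, rightmost.closed = TRUE)
    counts <- tabulate(idx, nbins = 4L)
    tibble(group = nm, bin = labels, count = counts,
           proportion = counts / length(p))
  })
  class(out) <- c("gene_p_bins", class(out))
  out
}

#' @rdname bin_gene_p
#' @param object A `gene_p_bins` table.
#' @param ... Unused.
#' @method autoplot gene_p_bins
#' @export
autoplot.gene_p_bins <- function(object, ...) {
  object$bin <- factor(object$bin,
                       levels = c("<0.001", "0.001-0.01", "0.01-0.05",
                                  ">=0.05"))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin, y = .data$proportion,
                                       fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "gene-wise p-value bin", y = "proportion of genes",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Partition GWAS genes by subnetwork membership
#'
#' Splits the genes measured in a GWAS into three disjoint, exhaustive
#' groups: candidates inside the subnetwork, recruited (subnetwork
#' non-candidates), and all remaining genes.
#'
#' @param sub A `steiner_subnetwork` (or a character vector of subnetwork
#'   genes).
#' @param gwas_genes Character vector of genes with gene-wise p-values.
#' @param candidates Character vector of candidate genes.
#' @return Named list of character vectors: `candidate_in_subnetwork`,
#'   `recruited`, `rest`.
#' @export
partition_genes <- function(sub, gwas_genes, candidates) {
  sub_genes <- if (inherits(sub, "steiner_subnetwork")) sub$nodes$gene else
    as.character(sub)
  gwas_genes <- unique(as.character(gwas_genes))
  in_sub <- intersect(gwas_genes, sub_genes)
  cand_in <- intersect(in_sub, candidates)
  recruited <- setdiff(in_sub, candidates)
  rest <- setdiff(gwas_genes, in_sub)
  list(candidate_in_subnetwork = cand_in, recruited = recruited, rest = rest)
}

#' Test a gene group for excess nominal GWAS significance
#'
#' Compares the proportion of nominally significant genes (gene-wise
#' p below `alpha`) in a group against a disjoint reference group with a
#' one-sided Fisher's exact test (enrichment of significance in the
#' group).
#'
#' @param group,reference Disjoint character vectors of gene identifiers.
#' @param gene_p Named numeric vector of gene-wise p-values (or a tibble
#'   from [assign_gene_p()]).
#' @param alpha Nominal significance threshold (default 0.05, strict).
#' @param labels Length-2 character: labels for group and reference.
#' @return One-row tibble of class `partition_test`: labels, the 2x2
#'   counts (`a_sig`, `a_nonsig`, `b_sig`, `b_nonsig`), the two
#'   proportions and the one-sided Fisher `p`.
#' @export
nominal_enrichment_test <- function(group, reference, gene_p, alpha = 0.05,
                                    labels = c("group", "reference")) {
  if (is.data.frame(gene_p)) gene_p <- setNames(gene_p$p_min, gene_p$gene)
  if (length(intersect(group, reference)) > 0)
    abort("group and reference must be disjoint")
  miss_g <- setdiff(group, names(gene_p))
  miss_r <- setdiff(reference, names(gene_p))
  if (length(miss_g) + length(miss_r) > 0)
    warn(sprintf("nominal_enrichment_test: %d gene(s) without a gene-wise p excluded",
                 length(miss_g) + length(miss_r)))
  group <- intersect(group, names(gene_p))
  reference <- intersect(reference, names(gene_p))
  if (length(group) == 0L) abort("group is empty after exclusions")
  if (length(reference) == 0L) abort("reference is empty after exclusions")
  a_sig <- sum(gene_p[group] < alpha)
  a_nonsig <- length(group) - a_sig
  b_sig <- sum(gene_p[reference] < alpha)
  b_nonsig <- length(reference) - b_sig
  out <- tibble(
    group = labels[1], reference = labels[2],
    a_sig = a_sig, a_nonsig = a_nonsig,
    b_sig = b_sig, b_nonsig = b_nonsig,
    prop_group = a_sig / (a_sig + a_nonsig),
    prop_reference = b_sig / (b_sig + b_nonsig),
    p = fisher_exact_one_sided(a_sig, a_nonsig, b_sig, b_nonsig)
  )
  class(out) <- c("partition_test", class(out))
  out
}
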