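#' Read an interaction edge list
#'
#' Parses a tab-delimited two-column edge list or a SIF (simple interaction
#' format) file into a tibble of raw interaction records. No cleanup (self
#' loops, duplicates) is performed here; that is the job of
#' [build_interactome()], so that the raw record count stays auditable.
#'
#' @param path Path to the file.
#' @param dialect `"two-column-tab"` (default) or `"sif"`. SIF lines have the
#'   form `source<TAB>relation<TAB>target1<TAB>target2...`; one record is
#'   emitted per source-target pair.
#' @return A tibble with columns `gene_a`, `gene_b`, `source` (provenance
#'   tag: the relation type for SIF, the file name otherwise).
#' @examples
#' f <- tempfile()
#' writeLines(c("A\tB", "B\tC"), f)
#' read_edge_list(f)
#' @export
read_edge_list <- function(path, dialect = c("two-column-tab", "sif")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  lines <- readr::read_lines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    warn(paste0("empty edge list: ", path))
    return(tibble(gene_a = character(), gene_b = character(),
                  source = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # SIF files in the wild are sometimes space-delimited
  if (dialect == "sif") {
    one <- lengths(fields) == 1L
    fields[one] <- strsplit(lines[one], "\\s+")
  }
  bad <- which(lengths(fields) < if (dialect == "sif") 3L else 2L)
  if (length(bad) > 0L) {
    abort(sprintf("malformed line %d in %s: %s",
                  lineno[bad[1L]], path, lines[bad[1L]]))
  }
  if (dialect == "two-column-tab") {
    tibble(
      gene_a = purrr::map_chr(fields, 1L),
      gene_b = purrr::map_chr(fields, 2L),
      source = basename(path)
    )
  } else {
    purrr::map_dfr(fields, function(f) {
      tibble(gene_a = f[1L], gene_b = f[-(1:2)], source = f[2L])
    })
  }
}

#' Read a GMT gene-set file
#'
#' GMT is the tab-delimited gene-set format: one set per line, fields are
#' set name, description, then one member gene per field.
#'
#' @param path Path to a GMT file.
#' @param universe Optional explicit gene universe; defaults to the union of
#'   all set members.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  stopifnot(file.exists(path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    abort(sprintf("GMT line %d has fewer than 3 fields (name, description, members): %s",
                  bad[1L], lines[bad[1L]]))
  }
  names_ <- purrr::map_chr(fields, 1L)
  descriptions <- purrr::map_chr(fields, 2L)
  members <- purrr::map(fields, function(f) {
    m <- f[-(1:2)]
    unique(m[nzchar(trimws(m))])
  })
  empty <- lengths(members) == 0L
  if (any(empty)) {
    warn(sprintf("dropping %d empty gene set(s): %s", sum(empty),
                 paste(names_[empty], collapse = ", ")))
    names_ <- names_[!empty]; descriptions <- descriptions[!empty]
    members <- members[!empty]
  }
  gene_set_collection(setNames(members, names_), universe = universe,
                      descriptions = setNames(descriptions, names_))
}

#' Write a gene-set collection as GMT
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  desc <- attr(collection, "descriptions") %||%
    setNames(rep("na", length(collection$sets)), names(collection$sets))
  lines <- purrr::imap_chr(collection$sets, function(members, nm) {
    paste(c(nm, desc[[nm]] %||% "na", members), collapse = "\t")
  })
  readr::write_lines(lines, path)
  invisible(path)
}

#' Construct a gene-set collection
#'
#' A named list of gene sets together with an explicit gene universe, the
#' substrate for enrichment testing and pathway crosstalk.
#'
#' @param sets Named list of character vectors (set name -> member genes).
#'   Duplicate members are removed; empty sets are not allowed.
#' @param universe Character vector of background genes. Defaults to the
#'   union of all members. Every set must be a subset of the universe.
#' @param descriptions Optional named character vector of set descriptions.
#' @return An object of class `gene_set_collection` with elements `sets`
#'   and `universe`.
#' @export
gene_set_collection <- function(sets, universe = NULL, descriptions = NULL) {
  stopifnot(is.list(sets))
  if (length(sets) > 0 && (is.null(names(sets)) || anyDuplicated(names(sets))))
    abort("gene set names must be present and unique")
  sets <- purrr::map(sets, ~ unique(as.character(.x)))
  if (any(lengths(sets) == 0L)) abort("empty gene sets are not allowed")
  if (is.null(universe)) {
    universe <- sort(unique(unlist(sets, use.names = FALSE)))
  } else {
    universe <- unique(as.character(universe))
    outside <- setdiff(unlist(sets, use.names = FALSE), universe)
    if (length(outside) > 0L)
      abort(sprintf("%d set member(s) outside the universe (e.g. %s)",
                    length(outside), outside[1L]))
  }
  structure(list(sets = sets, universe = universe),
            descriptions = descriptions,
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, universe of %d genes\n",
              length(x$sets), length(x$universe)))
  if (length(x$sets) > 0) {
    sizes <- lengths(x$sets)
    cat(sprintf("  set sizes: min %d, median %s, max %d\n",
                min(sizes), format(median(sizes)), max(sizes)))
  }
  invisible(x)
}

#' Read a PLINK-style SNP association table
#'
#' Expects a whitespace-delimited table whose header contains (case
#' insensitively) the columns CHR, SNP, BP and P. Rows with missing or
#' out-of-range p-values are dropped and counted.
#'
#' @param path Path to the association file.
#' @return A tibble with columns `snp_id`, `chrom`, `pos`, `p`.
#' @export
read_assoc <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           colClasses = "character",
                           check.names = FALSE)
  want <- c(chrom = "chr", snp_id = "snp", pos = "bp", p = "p")
  idx <- setNames(match(want, tolower(names(tab))), names(want))
  if (anyNA(idx)) {
    abort(sprintf("missing required column(s) %s; found: %s",
                  paste(toupper(want[is.na(idx)]), collapse = ", "),
                  paste(names(tab), collapse = ", ")))
  }
  out <- tibble(
    snp_id = tab[[idx[["snp_id"]]]],
    chrom  = tab[[idx[["chrom"]]]],
    pos    = suppressWarnings(as.numeric(tab[[idx[["pos"]]]])),
    p      = suppressWarnings(as.numeric(tab[[idx[["p"]]]]))
  )
  ok <- !is.na(out$p) & out$p >= 0 & out$p <= 1 & !is.na(out$pos) & out$pos >= 1
  if (any(!ok)) inform(sprintf("read_assoc: dropped %d row(s) with invalid p or position",
                               sum(!ok)))
  out[ok, ]
}

#' Read a gene coordinate table
#'
#' Tab-delimited table with columns `gene_id`, `symbol`, `chrom`, `start`,
#' `end`, `aliases` ('|'-separated). Coordinates are 1-based inclusive.
#'
#' @param path Path to the table.
#' @return A tibble of gene records; `aliases` is a list-column of
#'   character vectors.
#' @export
read_gene_table <- function(path) {
  stopifnot(file.exists(path))
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           gene_id = readr::col_character(),
                           symbol = readr::col_character(),
                           chrom = readr::col_character(),
                           start = readr::col_double(),
                           end = readr::col_double(),
                           aliases = readr::col_character()
                         ))
  need <- c("gene_id", "symbol", "chrom", "start", "end", "aliases")
  if (!all(need %in% names(tab)))
    abort(sprintf("gene table must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(tab$gene_id)) abort("gene_id values must be unique")
  if (any(tab$start > tab$end, na.rm = TRUE)) abort("gene start must be <= end")
  tab$aliases <- purrr::map(tab$aliases, function(a) {
    if (is.na(a) || !nzchar(a)) character() else strsplit(a, "|", fixed = TRUE)[[1]]
  })
  tab
}

#' Write a gene coordinate table
#'
#' @param genes Tibble as returned by [read_gene_table()] or
#'   [simulate_gene_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  out <- genes
  out$aliases <- purrr::map_chr(genes$aliases, paste, collapse = "|")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Map gene names to stable identifiers
#'
#' Matches input names against a gene table with the priority: exact
#' `gene_id` (case sensitive), exact `symbol`, then unique alias (symbol
#' and alias matching are case insensitive, since symbol casing is
#' inconsistent across sources). Names hitting the aliases of more than one
#' gene are treated as unmappable and dropped, mirroring the usual discard
#' rule for genes that cannot be mapped appropriately — but audited: the
#' dropped names are returned and counted in a message.
#'
#' @param symbols Character vector of gene names to map.
#' @param table Gene table (see [read_gene_table()]).
#' @return A list with `mapped` (gene_ids, input order, deduplicated) and
#'   `dropped` (unmappable or ambiguous inputs).
#' @export
map_to_genes <- function(symbols, table) {
  stopifnot(nrow(table) > 0)
  symbols <- as.character(symbols)
  sym_lc <- tolower(table$symbol)
  alias_tab <- tibble(
    gene_id = rep(table$gene_id, lengths(table$aliases)),
    alias = tolower(unlist(table$aliases, use.names = FALSE))
  )
  # aliases pointing at >1 gene are unusable
  ambiguous <- unique(alias_tab$alias[duplicated(alias_tab$alias)])
  resolve_one <- function(s) {
    hit <- which(table$gene_id == s)
    if (length(hit) == 1L) return(table$gene_id[hit])
    hit <- which(sym_lc == tolower(s))
    if (length(hit) >= 1L) return(table$gene_id[hit[1L]])
    s_lc <- tolower(s)
    if (s_lc %in% ambiguous) return(NA_character_)
    hit <- which(alias_tab$alias == s_lc)
    if (length(hit) == 1L) return(alias_tab$gene_id[hit])
    NA_character_
  }
  ids <- purrr::map_chr(symbols, resolve_one)
  dropped <- symbols[is.na(ids)]
  mapped <- unique(ids[!is.na(ids)])
  if (length(dropped) > 0L)
    inform(sprintf("map_to_genes: %d of %d input name(s) could not be mapped and were discarded",
                   length(dropped), length(symbols)))
  list(mapped = mapped, dropped = dropped)
}

#' Write a graph with node and edge attributes
#'
#' Writes GraphML (round-trip safe, via igraph), SIF, or a pair of TSV
#' tables (`<path>` gets the edge table; a sibling `*.nodes.tsv` gets the
#' node table).
#'
#' @param nodes Tibble with a `name` column plus attribute columns.
#' @param edges Tibble with `from`, `to` columns plus attribute columns.
#' @param path Output path.
#' @param format One of `"graphml"`, `"sif"`, `"tsv"`.
#' @param relation Interaction type written in SIF output.
#' @return `path`, invisibly.
#' @export
write_graph_file <- function(nodes, edges, path,
                             format = c("graphml", "sif", "tsv"),
                             relation = "pp") {
  format <- match.arg(format)
  stopifnot(all(c("from", "to") %in% names(edges)), "name" %in% names(nodes))
  if (!all(c(edges$from, edges$to) %in% nodes$name))
    abort("every edge endpoint must appear in the node table")
  if (format == "graphml") {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = as.data.frame(nodes))
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "sif") {
    a <- pmin(edges$from, edges$to)
    b <- pmax(edges$from, edges$to)
    lines <- unique(paste(a, relation, b, sep = "\t"))
    isolated <- setdiff(nodes$name, c(edges$from, edges$to))
    readr::write_lines(c(lines, isolated), path)
  } else {
    readr::write_tsv(edges, path)
    readr::write_tsv(nodes, sub("(\\.[^.]+)?$", ".nodes.tsv", path))
  }
  invisible(path)
}

#' Read a GraphML file back into node and edge tables
#'
#' @param path Path to a GraphML file written by [write_graph_file()].
#' @return List with tibbles `nodes` and `edges`.
#' @export
read_graph_file <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- as_tibble(igraph::as_data_frame(g, what = "vertices"))
  if (!"name" %in% names(nodes) && "id" %in% names(nodes))
    nodes <- dplyr::rename(nodes, name = "id")
  edges <- as_tibble(igraph::as_data_frame(g, what = "edges"))
  list(nodes = nodes, edges = edges)
}
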