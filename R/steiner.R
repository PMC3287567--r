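# Node-weighted Steiner tree extraction.
#
# The disease-specific subnetwork is obtained by connecting a candidate-gene
# list (the terminals) through a host interactome while recruiting as little
# extra node weight as possible. With the default unit weights this
# minimises the COUNT of recruited linker genes. The approximation is the
# Klein-Ravi spider-merging scheme: keep a forest whose trees start as the
# individual terminals and repeatedly pick the centre node and group of
# trees with the smallest (centre weight + path costs) / (trees merged)
# ratio, giving a 2 ln(k) guarantee on the recruited weight for k terminals.

# integer adjacency lists, neighbours sorted for deterministic tie-breaks
adj_int_list <- function(g) {
  al <- igraph::as_adj_list(g, mode = "all")
  lapply(al, function(vs) sort(as.integer(vs)))
}

# Node-weighted shortest paths are delegated to igraph's (C) Dijkstra by
# splitting each node weight onto its incident edges: edge (u,v) gets
# weight (w[u] + w[v]) / 2, so a path a..b costs
# w(interior) + w[a]/2 + w[b]/2. Forest nodes carry effective weight 0, so
# the interior cost from a tree to node v is dist - w_eff[v]/2.
node_split_edge_weights <- function(edge_ends, w_eff) {
  (w_eff[edge_ends[, 1]] + w_eff[edge_ends[, 2]]) / 2
}

# BFS spanning tree of the subgraph induced by `keep` (logical), rooted at
# the smallest kept index; returns edge matrix
bfs_spanning_edges <- function(adj, keep) {
  idx <- which(keep)
  if (length(idx) <= 1) return(matrix(integer(), ncol = 2))
  root <- idx[1]
  seen <- rep(FALSE, length(adj))
  seen[root] <- TRUE
  queue <- root
  edges <- matrix(integer(), ncol = 2)
  while (length(queue) > 0) {
    u <- queue[1]; queue <- queue[-1]
    for (v in adj[[u]]) {
      if (keep[v] && !seen[v]) {
        seen[v] <- TRUE
        edges <- rbind(edges, c(u, v))
        queue <- c(queue, v)
      }
    }
  }
  edges
}

# iteratively strip non-terminal leaves so every remaining linker is
# required: afterwards all tree leaves are terminals
prune_leaf_linkers <- function(edges, nodes, is_terminal) {
  repeat {
    if (nrow(edges) == 0) break
    deg <- table(factor(c(edges[, 1], edges[, 2]), levels = nodes))
    leaves <- nodes[deg == 1 & !is_terminal[nodes]]
    if (length(leaves) == 0) break
    drop <- edges[, 1] %in% leaves | edges[, 2] %in% leaves
    edges <- edges[!drop, , drop = FALSE]
    nodes <- setdiff(nodes, leaves)
  }
  list(edges = edges, nodes = nodes)
}

new_steiner_subnetwork <- function(nodes, edges, terminals_requested,
                                   terminals_mapped, unconnected, weight,
                                   method) {
  structure(list(nodes = nodes, edges = edges,
                 terminals_requested = terminals_requested,
                 terminals_mapped = terminals_mapped,
                 unconnected_terminals = unconnected,
                 total_linker_weight = weight,
                 method = method),
            class = "steiner_subnetwork")
}

prepare_instance <- function(g, terminals, node_weight) {
  vnames <- igraph::V(g)$name
  terminals <- unique(as.character(terminals))
  mapped <- intersect(terminals, vnames)
  if (length(mapped) == 0L) abort("no terminal maps into the graph")
  if (length(mapped) < length(terminals))
    inform(sprintf("steiner: %d terminal(s) not in the graph dropped",
                   length(terminals) - length(mapped)))
  w <- rep(1, length(vnames))
  names(w) <- vnames
  if (!is.null(node_weight)) {
    if (is.null(names(node_weight))) abort("node_weight must be named by gene")
    if (any(node_weight < 0)) abort("node weights must be non-negative")
    w[names(node_weight)] <- node_weight
  }
  w[mapped] <- 0
  list(vnames = vnames, terminals = terminals, mapped = mapped, w = w)
}

#' Klein-Ravi node-weighted Steiner subnetwork
#'
#' Connects a set of terminal (candidate) genes through the interactome
#' while minimising the total weight of recruited linker genes, using the
#' Klein-Ravi spider-merging approximation (recruited weight is at most
#' `2 ln(k)` times optimal for `k` terminals). With the default weights
#' (0 on terminals, 1 elsewhere) this minimises the number of recruited
#' genes. Terminals in different graph components are connected within
#' each component holding at least two terminals; terminals alone in their
#' component are reported as unconnected. Everything is deterministic:
#' ties are broken by lexicographic node identifier.
#'
#' @param g Interactome graph (igraph, named vertices).
#' @param terminals Character vector of candidate gene identifiers;
#'   terminals absent from the graph are dropped with a message.
#' @param node_weight Optional named non-negative weights for non-terminal
#'   genes (e.g. 1 - score); default 1 for every non-terminal.
#' @param induce_edges If `TRUE`, the output additionally contains every
#'   parent-graph edge between chosen nodes (a subnetwork for display); by
#'   default only the tree edges are returned.
#' @return A `steiner_subnetwork`: list with `nodes` (tibble gene/role/
#'   component), `edges` (tibble from/to/component), `unconnected_terminals`,
#'   `total_linker_weight`, `method`.
#' @examples
#' g <- build_interactome(tibble::tibble(gene_a = c("t1", "x"),
#'                                       gene_b = c("x", "t2")), quiet = TRUE)
#' klein_ravi_steiner(g, c("t1", "t2"))
#' @export
klein_ravi_steiner <- function(g, terminals, node_weight = NULL,
                               induce_edges = FALSE) {
  inst <- prepare_instance(g, terminals, node_weight)
  vnames <- inst$vnames; mapped <- inst$mapped; w <- inst$w
  adj <- adj_int_list(g)
  edge_ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  comp <- igraph::components(g)$membership
  term_idx <- match(mapped, vnames)
  by_comp <- split(term_idx, comp[term_idx])

  nodes_out <- NULL; edges_out <- NULL
  unconnected <- character()
  total_weight <- 0
  comp_id <- 0L

  for (tset in by_comp) {
    if (length(tset) == 1L) {
      unconnected <- c(unconnected, vnames[tset])
      next
    }
    comp_id <- comp_id + 1L
    sol <- kr_component(adj, w, sort(tset), vnames, g, edge_ends)
    edges <- sol$edges
    is_term_int <- rep(FALSE, length(vnames)); is_term_int[term_idx] <- TRUE
    pr <- prune_leaf_linkers(edges, sol$nodes, is_term_int)
    keep <- pr$nodes
    edges <- pr$edges
    if (induce_edges) {
      keepl <- rep(FALSE, length(vnames)); keepl[keep] <- TRUE
      ind <- NULL
      for (u in keep) for (v in adj[[u]]) if (v > u && keepl[v])
        ind <- rbind(ind, c(u, v))
      edges <- unique(rbind(edges, ind))
      # canonical orientation
      edges <- cbind(pmin(edges[, 1], edges[, 2]),
                     pmax(edges[, 1], edges[, 2]))
      edges <- unique(edges)
    }
    role <- ifelse(keep %in% term_idx, "terminal", "linker")
    nodes_out <- rbind(nodes_out,
                       data.frame(gene = vnames[keep], role = role,
                                  component = comp_id))
    if (nrow(edges) > 0)
      edges_out <- rbind(edges_out,
                         data.frame(from = vnames[edges[, 1]],
                                    to = vnames[edges[, 2]],
                                    component = comp_id))
    total_weight <- total_weight + sum(w[vnames[keep[role == "linker"]]])
  }
  if (length(unconnected) > 0)
    inform(sprintf("steiner: %d terminal(s) alone in their component left unconnected",
                   length(unconnected)))
  nodes <- if (is.null(nodes_out)) {
    tibble(gene = character(), role = character(), component = integer())
  } else as_tibble(nodes_out)
  edges <- if (is.null(edges_out)) {
    tibble(from = character(), to = character(), component = integer())
  } else as_tibble(edges_out)
  new_steiner_subnetwork(dplyr::arrange(nodes, .data$component, .data$gene),
                         edges, inst$terminals, mapped, unconnected,
                         total_weight, "klein-ravi")
}

# spider-merging loop on one connected component
kr_component <- function(adj, w, tset, vnames, g, edge_ends) {
  n <- length(adj)
  tree_id <- rep(NA_integer_, n)
  tree_id[tset] <- seq_along(tset)
  trees <- lapply(tset, function(t) list(nodes = t,
                                         edges = matrix(integer(), ncol = 2)))
  active <- seq_along(tset)

  while (length(active) > 1) {
    w_eff <- w
    in_forest <- !is.na(tree_id)
    w_eff[in_forest] <- 0
    ew <- node_split_edge_weights(edge_ends, w_eff)
    sources <- unlist(lapply(trees[active], function(t) t$nodes))
    src_tree <- rep(seq_along(active),
                    vapply(trees[active], function(t) length(t$nodes), 0L))
    M <- igraph::distances(g, v = sources, weights = ew)  # sources x n
    # interior cost from tree j to node v: min over the tree's source rows
    # minus v's boundary half-weight
    D <- do.call(rbind, lapply(seq_along(active), function(j) {
      rows <- M[src_tree == j, , drop = FALSE]
      if (nrow(rows) == 1L) rows[1L, ] else do.call(pmin, asplit(rows, 1))
    }))
    D <- sweep(D, 2, w_eff / 2)                            # n_active x n
    # best (centre, r) by ratio; centres scanned in index order so ties in
    # ratio resolve to the lexicographically smallest node
    best <- list(ratio = Inf, v = NA_integer_, sel = NULL)
    reachable <- which(colSums(is.finite(D)) >= 2)
    for (v in reachable) {
      dv <- D[, v]
      ord <- order(dv, active)  # deterministic among equal distances
      dvs <- dv[ord]
      rmax <- sum(is.finite(dvs))
      if (rmax < 2) next
      csum <- cumsum(dvs[seq_len(rmax)])
      ratios <- (w_eff[v] + csum[2:rmax]) / (2:rmax)
      rbest <- which.min(ratios) + 1L
      ratio <- ratios[rbest - 1L]
      if (ratio < best$ratio - 1e-12) {
        best <- list(ratio = ratio, v = v, sel = ord[seq_len(rbest)])
      }
    }
    if (!is.finite(best$ratio))
      abort("internal error: no merge possible within a component")
    v <- best$v
    sel_ids <- active[best$sel]
    # gather nodes/edges: selected trees, centre, and the connecting paths
    new_nodes <- v
    new_edges <- NULL
    for (j in seq_along(best$sel)) {
      id <- sel_ids[j]
      src_nodes <- trees[[id]]$nodes
      if (v %in% src_nodes) next
      rows <- which(src_tree == best$sel[j])
      dv <- M[rows, v]
      t_star <- sources[rows[which.min(dv)]]  # smallest index among ties
      vp <- igraph::shortest_paths(g, from = t_star, to = v, weights = ew,
                                   output = "vpath")$vpath[[1]]
      pth <- as.integer(vp)
      if (length(pth) >= 2) {
        new_edges <- rbind(new_edges, cbind(pth[-length(pth)], pth[-1]))
        interior <- pth[-c(1, length(pth))]
        new_nodes <- c(new_nodes, interior)
      }
    }
    # paths may run through nodes of unselected trees (free to traverse);
    # fold every tree touched by the new node set into the merge
    touched <- unique(stats::na.omit(tree_id[new_nodes]))
    merge_ids <- sort(unique(c(sel_ids, touched)))
    merged_nodes <- sort(unique(c(new_nodes,
                                  unlist(lapply(trees[merge_ids],
                                                function(t) t$nodes)))))
    merged_edges <- do.call(rbind, c(list(new_edges),
                                     lapply(trees[merge_ids],
                                            function(t) t$edges)))
    if (is.null(merged_edges)) merged_edges <- matrix(integer(), ncol = 2)
    keep_id <- merge_ids[1]
    trees[[keep_id]] <- list(nodes = merged_nodes, edges = merged_edges)
    tree_id[merged_nodes] <- keep_id
    active <- setdiff(active, setdiff(merge_ids, keep_id))
  }
  tr <- trees[[active[1]]]
  # the union of merged paths can contain cycles; reduce to a spanning tree
  keep <- rep(FALSE, n); keep[tr$nodes] <- TRUE
  edges <- bfs_spanning_edges(restrict_adj(adj, tr$edges), keep)
  list(nodes = sort(tr$nodes), edges = edges)
}

# adjacency list containing only the accumulated tree edges
restrict_adj <- function(adj, edges) {
  out <- vector("list", length(adj))
  for (i in seq_along(out)) out[[i]] <- integer()
  if (!is.null(edges) && nrow(edges) > 0) {
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1]; b <- edges[i, 2]
      out[[a]] <- c(out[[a]], b)
      out[[b]] <- c(out[[b]], a)
    }
    out <- lapply(out, function(x) sort(unique(x)))
  }
  out
}

#' Exact node-weighted Steiner subnetwork by exhaustive search
#'
#' Enumerates subsets of non-terminal nodes to find the globally minimum
#' total linker weight connecting all terminals reachable from one
#' another; among optima the smallest, then lexicographically smallest,
#' node set is returned. Only feasible for small instances (at most 20
#' non-terminal nodes); intended as the exact reference for
#' [klein_ravi_steiner()].
#'
#' @inheritParams klein_ravi_steiner
#' @return A `steiner_subnetwork` (method `"brute-force"`).
#' @export
brute_force_steiner <- function(g, terminals, node_weight = NULL) {
  inst <- prepare_instance(g, terminals, node_weight)
  vnames <- inst$vnames; mapped <- inst$mapped; w <- inst$w
  adj <- adj_int_list(g)
  comp <- igraph::components(g)$membership
  term_idx <- match(mapped, vnames)
  by_comp <- split(term_idx, comp[term_idx])

  nodes_out <- NULL; edges_out <- NULL
  unconnected <- character(); total_weight <- 0; comp_id <- 0L
  for (tset in by_comp) {
    if (length(tset) == 1L) {
      unconnected <- c(unconnected, vnames[tset])
      next
    }
    comp_id <- comp_id + 1L
    cands <- setdiff(which(comp == comp[tset[1]]), tset)
    if (length(cands) > 20)
      abort(sprintf("brute force infeasible: %d non-terminal nodes (max 20); use klein_ravi_steiner()",
                    length(cands)))
    sol <- bf_component(adj, w, sort(tset), sort(cands), vnames)
    keep <- sol$nodes
    role <- ifelse(keep %in% term_idx, "terminal", "linker")
    nodes_out <- rbind(nodes_out,
                       data.frame(gene = vnames[keep], role = role,
                                  component = comp_id))
    if (nrow(sol$edges) > 0)
      edges_out <- rbind(edges_out,
                         data.frame(from = vnames[sol$edges[, 1]],
                                    to = vnames[sol$edges[, 2]],
                                    component = comp_id))
    total_weight <- total_weight + sum(w[vnames[keep[role == "linker"]]])
  }
  nodes <- if (is.null(nodes_out)) {
    tibble(gene = character(), role = character(), component = integer())
  } else as_tibble(nodes_out)
  edges <- if (is.null(edges_out)) {
    tibble(from = character(), to = character(), component = integer())
  } else as_tibble(edges_out)
  new_steiner_subnetwork(dplyr::arrange(nodes, .data$component, .data$gene),
                         edges, inst$terminals, mapped, unconnected,
                         total_weight, "brute-force")
}

bf_component <- function(adj, w, tset, cands, vnames) {
  n_c <- length(cands)
  check <- function(subset) {
    allowed <- rep(FALSE, length(adj))
    allowed[tset] <- TRUE; allowed[subset] <- TRUE
    seen <- rep(FALSE, length(adj))
    seen[tset[1]] <- TRUE
    queue <- tset[1]
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      for (v in adj[[u]]) if (allowed[v] && !seen[v]) {
        seen[v] <- TRUE; queue <- c(queue, v)
      }
    }
    all(seen[tset])
  }
  best <- NULL; best_w <- Inf
  for (mask in 0:(2^n_c - 1)) {
    subset <- cands[bitwAnd(bitwShiftR(mask, seq_len(n_c) - 1L), 1L) == 1L]
    wt <- sum(w[vnames[subset]])
    if (wt > best_w) next
    if (wt == best_w && !is.null(best)) {
      # prefer fewer nodes, then lexicographically smaller name set
      if (length(subset) > length(best)) next
      if (length(subset) == length(best)) {
        cmp <- compare_name_sets(vnames[subset], vnames[best])
        if (cmp >= 0) next
      }
    }
    if (check(subset)) {
      best <- subset; best_w <- wt
    }
  }
  if (is.null(best)) abort("terminals are not connectable within their component")
  keep <- sort(c(tset, best))
  keepl <- rep(FALSE, length(adj)); keepl[keep] <- TRUE
  edges <- bfs_spanning_edges(adj, keepl)
  list(nodes = keep, edges = edges, weight = best_w)
}

# -1 if a < b, 0 if equal, 1 if a > b (element-wise on sorted names)
compare_name_sets <- function(a, b) {
  a <- sort(a); b <- sort(b)
  k <- min(length(a), length(b))
  for (i in seq_len(k)) {
    if (a[i] < b[i]) return(-1L)
    if (a[i] > b[i]) return(1L)
  }
  sign(length(a) - length(b))
}

#' Count terminals and linkers in a subnetwork
#'
#' @param sub A `steiner_subnetwork`.
#' @param terminals Optional character vector to re-check roles against; by
#'   default the roles stored in the subnetwork are used.
#' @return A tibble with `terminal_count` and `linker_count`.
#' @export
classify_subnetwork <- function(sub, terminals = NULL) {
  stopifnot(inherits(sub, "steiner_subnetwork"))
  roles <- sub$nodes$role
  if (!is.null(terminals)) {
    roles <- ifelse(sub$nodes$gene %in% terminals, "terminal", "linker")
    if (!identical(roles, sub$nodes$role))
      warn("stored roles disagree with the supplied terminal set")
  }
  tibble(terminal_count = sum(roles == "terminal"),
         linker_count = sum(roles == "linker"))
}

#' @export
print.steiner_subnetwork <- function(x, ...) {
  cc <- classify_subnetwork(x)
  cat(sprintf("<steiner_subnetwork> (%s) %d terminals + %d linkers, %d edges, %d component(s)\n",
              x$method, cc$terminal_count, cc$linker_count, nrow(x$edges),
              if (nrow(x$nodes)) max(x$nodes$component) else 0L))
  if (length(x$unconnected_terminals) > 0)
    cat(sprintf("  %d terminal(s) unconnected (singleton components)\n",
                length(x$unconnected_terminals)))
  invisible(x)
}

#' @rdname klein_ravi_steiner
#' @param x,object A `steiner_subnetwork`.
#' @param ... Unused.
#' @method tidy steiner_subnetwork
#' @export
tidy.steiner_subnetwork <- function(x, ...) x$nodes

#' @rdname klein_ravi_steiner
#' @method glance steiner_subnetwork
#' @export
glance.steiner_subnetwork <- function(x, ...) {
  cc <- classify_subnetwork(x)
  tibble(method = x$method,
         terminal_count = cc$terminal_count,
         linker_count = cc$linker_count,
         n_edges = nrow(x$edges),
         n_unconnected = length(x$unconnected_terminals),
         total_linker_weight = x$total_linker_weight)
}

#' @rdname klein_ravi_steiner
#' @method autoplot steiner_subnetwork
#' @export
autoplot.steiner_subnetwork <- function(object, ...) {
  if (nrow(object$edges) == 0) abort("empty subnetwork")
  g <- igraph::graph_from_data_frame(
    object$edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = object$nodes$gene,
                          role = object$nodes$role))
  lay <- igraph::layout_with_fr(g)
  nodes <- object$nodes
  nodes$x <- lay[, 1]; nodes$y <- lay[, 2]
  pos <- setNames(seq_len(nrow(nodes)), nodes$gene)
  seg <- tibble(x = nodes$x[pos[object$edges$from]],
                y = nodes$y[pos[object$edges$from]],
                xend = nodes$x[pos[object$edges$to]],
                yend = nodes$y[pos[object$edges$to]])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      colour = "grey70") +
    ggplot2::geom_point(data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$role,
                   shape = .data$role), size = 3) +
    ggplot2::scale_shape_manual(values = c(terminal = 16, linker = 17)) +
    ggplot2::theme_void()
}

#' Export a Steiner subnetwork to disk
#'
#' @param sub A `steiner_subnetwork`.
#' @param path Output path.
#' @param format `"graphml"`, `"sif"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_subnetwork <- function(sub, path, format = c("graphml", "sif", "tsv")) {
  format <- match.arg(format)
  nodes <- dplyr::rename(sub$nodes, name = "gene")
  edges <- sub$edges
  write_graph_file(nodes, edges, path, format = format)
}
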