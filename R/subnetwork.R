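#' A node-scored graph
#'
#' Binds a network to one finite real score per node, the input of the
#' maximal-scoring subgraph search.
#'
#' @param graph an igraph with vertex names.
#' @param scores numeric vector; named by gene, or a `score_table` from
#'   [score_pvalues()].
#' @return list with `graph` and `score` (named, in vertex order), class
#'   `scored_graph`.
#' @export
scored_graph <- function(graph, scores) {
  if (inherits(scores, "score_table"))
    scores <- stats::setNames(scores$score, scores$gene)
  nodes <- igraph::V(graph)$name
  if (is.null(names(scores))) {
    if (length(scores) != length(nodes))
      stop_data("unnamed score vector must match vertex count")
    names(scores) <- nodes
  }
  missing <- setdiff(nodes, names(scores))
  if (length(missing) > 0L)
    stop_data("%d network nodes have no score (e.g. %s)",
              length(missing), missing[1L])
  scores <- scores[nodes]
  if (any(!is.finite(scores))) stop_data("node scores must be finite")
  structure(list(graph = graph, score = scores), class = "scored_graph")
}

new_subnetwork <- function(graph, nodes, score) {
  nodes <- sort(nodes)
  sub <- if (length(nodes) > 0L) igraph::induced_subgraph(graph, nodes)
         else igraph::make_empty_graph(directed = FALSE)
  structure(list(nodes = nodes, graph = sub,
                 total_score = if (length(nodes)) sum(score[nodes]) else 0,
                 node_score = if (length(nodes)) score[nodes] else numeric(0)),
            class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("subnetwork: %d nodes, %d edges, total score %.4f\n",
              length(x$nodes), igraph::ecount(x$graph), x$total_score))
  invisible(x)
}

#' Exact maximal-scoring connected subgraph by exhaustive enumeration
#'
#' Enumerates every connected induced subgraph (bitmask enumeration over
#' node subsets) and returns the one with the largest node-score sum. Serves
#' as the ground-truth oracle for [heuristic_mss()] on small instances.
#' When no subset scores positively the empty subnetwork (score 0) is
#' returned. Ties break toward the lexicographically smallest node set.
#'
#' @param sg a [scored_graph()].
#' @param max_nodes refuse graphs larger than this (default 15; the search
#'   is exponential).
#' @return a `subnetwork`.
#' @export
exact_mss <- function(sg, max_nodes = 15L) {
  g <- sg$graph
  n <- igraph::vcount(g)
  if (n > max_nodes)
    stop_config("graph has %d nodes > max_nodes = %d; use heuristic_mss()",
                n, max_nodes)
  if (n == 0L) return(new_subnetwork(g, character(0), sg$score))
  ord <- order(igraph::V(g)$name)
  names <- igraph::V(g)$name[ord]
  sc <- unname(sg$score[names])
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)[ord, ord, drop = FALSE]
  bits <- bitwShiftL(1L, 0:(n - 1L))
  adjm <- as.integer(adj %*% bits) # neighbor bitmask per vertex
  M <- bitwShiftL(1L, n)
  # DP tables over all subsets: score sum and neighborhood-union masks
  bit_idx <- integer(M)
  bit_idx[bits + 1L] <- seq_len(n)
  ssum <- numeric(M); nbr <- integer(M)
  for (m in 1:(M - 1L)) {
    li <- bit_idx[bitwAnd(m, -m) + 1L]
    rest <- bitwAnd(m, m - 1L)
    ssum[m + 1L] <- ssum[rest + 1L] + sc[li]
    nbr[m + 1L] <- bitwOr(nbr[rest + 1L], adjm[li])
  }
  best_score <- 0; best_mask <- 0L; have <- FALSE
  eps <- 1e-12
  for (m in 1:(M - 1L)) {
    s <- ssum[m + 1L]
    if (s <= eps) next
    if (have && s < best_score - eps) next
    # connectivity: expand reach set from lowest bit via neighborhood table
    reach <- bitwAnd(m, -m)
    repeat {
      nxt <- bitwAnd(bitwOr(reach, nbr[reach + 1L]), m)
      if (nxt == reach) break
      reach <- nxt
    }
    if (reach != m) next
    if (!have || s > best_score + eps) {
      best_score <- s; best_mask <- m; have <- TRUE
    } else if (abs(s - best_score) <= eps) {
      cand <- names[bitwAnd(m, bits) != 0L]
      cur <- names[bitwAnd(best_mask, bits) != 0L]
      if (lex_less(cand, cur)) best_mask <- m
    }
  }
  nodes <- if (have) names[bitwAnd(best_mask, bits) != 0L] else character(0)
  new_subnetwork(g, nodes, sg$score)
}

# edge weight transferring node penalties to edges: traversing a
# negative node costs its |score|, positive nodes are free
entity_edge_weight <- function(escore, from, to) {
  -pmin(escore[from], 0) - pmin(escore[to], 0)
}

#' Heuristic maximal-scoring connected subgraph (MST-based)
#'
#' Approximates the maximal-scoring subgraph in five stages: (1) contract
#' each connected component of positive-score nodes into a meta-node
#' carrying the component's score sum; (2) weight each edge by the penalty
#' of its negative endpoints, `w(u,v) = -min(s(u),0) - min(s(v),0)`; (3)
#' build a minimum spanning tree; (4) collect the negative nodes lying on
#' MST paths between positive meta-nodes; (5) on the subgraph induced by
#' the meta-nodes plus those connectors, build a second MST and return its
#' highest-scoring path, meta-nodes expanded back to their genes. The
#' result is post-pruned by iteratively removing negative-score leaves.
#'
#' @param sg a [scored_graph()]; the graph must be connected.
#' @param force_single if `TRUE` and no node scores positively, return the
#'   best single node instead of the empty subnetwork.
#' @return a `subnetwork`.
#' @export
heuristic_mss <- function(sg, force_single = FALSE) {
  g <- sg$graph
  score <- sg$score
  if (igraph::vcount(g) == 0L) return(new_subnetwork(g, character(0), score))
  if (!igraph::is_connected(g))
    stop_data("heuristic_mss requires a connected graph; pass one component")
  pos <- names(score)[score > 0]
  if (length(pos) == 0L) {
    if (!force_single) return(new_subnetwork(g, character(0), score))
    best <- names(score)[order(-score, names(score))][1L]
    return(new_subnetwork(g, best, score))
  }
  # stage 1: positive connected components -> meta-nodes
  posg <- igraph::induced_subgraph(g, pos)
  comp <- igraph::components(posg)
  meta_of <- stats::setNames(paste0(".meta", comp$membership), igraph::V(posg)$name)
  entity <- stats::setNames(igraph::V(g)$name, igraph::V(g)$name)
  entity[names(meta_of)] <- meta_of
  meta_ids <- sort(unique(meta_of))
  members <- split(names(meta_of), meta_of)
  escore <- score[names(score)[!(names(score) %in% pos)]]
  escore <- c(escore, vapply(members, function(v) sum(score[v]), numeric(1L)))
  # entity-level simple graph
  el <- igraph::as_edgelist(g)
  eu <- entity[el[, 1L]]; ev <- entity[el[, 2L]]
  keep <- eu != ev
  epairs <- unique(t(apply(cbind(eu[keep], ev[keep]), 1L, sort)))
  if (length(epairs) == 0L) {
    # single entity: the whole graph is one positive component
    return(prune_negative_leaves(g, members[[meta_ids[1L]]], score))
  }
  # contracting components of a connected graph keeps it connected, so no
  # entity can be isolated here
  ge <- igraph::graph_from_edgelist(epairs, directed = FALSE)
  w <- entity_edge_weight(escore, epairs[, 1L], epairs[, 2L])
  # stages 2-3: MST on penalty weights
  mst1 <- igraph::mst(ge, weights = w)
  metas_in <- intersect(meta_ids, igraph::V(mst1)$name)
  # stage 4: negative connectors on MST paths between meta-nodes
  connectors <- character(0)
  if (length(metas_in) > 1L) {
    for (i in seq_len(length(metas_in) - 1L)) {
      sp <- igraph::shortest_paths(mst1, from = metas_in[i],
                                   to = metas_in[(i + 1L):length(metas_in)],
                                   weights = NA, output = "vpath")
      for (pth in sp$vpath)
        connectors <- union(connectors, setdiff(names(pth), meta_ids))
    }
  }
  # stage 5: second MST on meta-nodes + connectors, best path on it
  keep2 <- c(metas_in, connectors)
  ge2 <- igraph::induced_subgraph(ge, keep2)
  el2 <- igraph::as_edgelist(ge2)
  w2 <- if (nrow(el2) > 0L) entity_edge_weight(escore, el2[, 1L], el2[, 2L]) else numeric(0)
  mst2 <- igraph::mst(ge2, weights = w2)
  best_nodes <- NULL; best_score <- -Inf
  consider <- function(entities) {
    genes <- unlist(lapply(entities, function(e)
      if (e %in% meta_ids) members[[e]] else e), use.names = FALSE)
    s <- sum(score[genes])
    if (s > best_score + 1e-12 ||
        (abs(s - best_score) <= 1e-12 && lex_less(sort(genes), sort(best_nodes)))) {
      best_nodes <<- genes; best_score <<- s
    }
  }
  for (i in seq_along(metas_in)) {
    consider(metas_in[i])
    if (i < length(metas_in)) {
      # paths in a tree are unique; weights are irrelevant here
      sp <- igraph::shortest_paths(mst2, from = metas_in[i],
                                   to = metas_in[(i + 1L):length(metas_in)],
                                   weights = NA, output = "vpath")
      for (pth in sp$vpath) if (length(pth) > 0L) consider(names(pth))
    }
  }
  prune_negative_leaves(g, best_nodes, score)
}

# iteratively drop negative-score nodes of degree <= 1 in the induced
# subgraph; leaf removal preserves connectivity
prune_negative_leaves <- function(g, nodes, score) {
  repeat {
    sub <- igraph::induced_subgraph(g, nodes)
    deg <- igraph::degree(sub)
    drop <- names(deg)[deg <= 1L & score[names(deg)] < 0]
    if (length(drop) == 0L || length(nodes) <= 1L) break
    nodes <- setdiff(nodes, drop)
  }
  new_subnetwork(g, nodes, score)
}

#' Full perturbed-subnetwork search on one condition
#'
#' Chains the pipeline stages for a single case/control dataset: clean the
#' network against the measured genes, compute moderated-t p-values, fit
#' the beta-uniform mixture, pick the FDR whose positive fraction is
#' closest to `target_fraction`, score the nodes and search the
#' maximal-scoring subgraph ([exact_mss()] for graphs up to `exact_max`
#' nodes, [heuristic_mss()] otherwise).
#'
#' @param m an [expression_matrix()] with a case/control design.
#' @param g interactome as an igraph with vertex names.
#' @param target_fraction desired positively scored node fraction
#'   (default 0.10).
#' @param fdr_grid candidate FDRs (default [default_fdr_grid()]).
#' @param exact_max graph size up to which the exact search is used.
#' @return list with `subnetwork`, `fit` (`bum_fit`), `scores`
#'   (`score_table`), `fdr`, `de` (moderated-t table) and `network` (the
#'   cleaned graph).
#' @export
perturbed_subnetwork <- function(m, g, target_fraction = 0.10,
                                 fdr_grid = default_fdr_grid(),
                                 exact_max = 15L) {
  common <- intersect(rownames(m$values), igraph::V(g)$name)
  if (length(common) < 100L)
    stop_data("expression matrix and network share only %d genes (need >= 100)",
              length(common))
  gc <- clean_network(g, rownames(m$values))
  keep <- igraph::V(gc)$name
  m2 <- replace_values(m, m$values[keep, , drop = FALSE])
  de <- moderated_t(m2)
  pv <- stats::setNames(de$p, de$gene)
  fit <- fit_bum(pv)
  fdr <- choose_fdr_for_fraction(fit, pv, target_fraction, fdr_grid)
  st <- score_pvalues(fit, as.numeric(fdr), pv)
  sg <- scored_graph(gc, st)
  sub <- if (igraph::vcount(gc) <= exact_max) exact_mss(sg, exact_max)
         else heuristic_mss(sg)
  list(subnetwork = sub, fit = fit, scores = st, fdr = as.numeric(fdr),
       positive_fraction = attr(fdr, "positive_fraction"), de = de,
       network = gc)
}

#' Write a subnetwork as node and edge TSV files
#'
#' The node table lists every network gene with its score and an `in_module`
#' flag; the edge table lists the subnetwork's induced edges.
#'
#' @param sub a `subnetwork`.
#' @param sg the `scored_graph` it was found in.
#' @param node_path,edge_path output paths.
#' @return invisibly, the two paths.
#' @export
write_subnetwork <- function(sub, sg, node_path, edge_path) {
  genes <- sort(igraph::V(sg$graph)$name)
  nodes <- data.frame(gene = genes, score = sg$score[genes],
                      in_module = genes %in% sub$nodes,
                      row.names = NULL)
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_edge_list(sub$graph, edge_path)
  invisible(c(node_path, edge_path))
}
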