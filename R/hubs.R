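#' Extract hub genes from a perturbed subnetwork
#'
#' A gene is a hub when its within-subnetwork degree is at or above the
#' empirical `q` quantile (linear interpolation) of the subnetwork's degree
#' distribution; the default `q = 0.9` keeps roughly the top decile of
#' connectivity.
#'
#' @param sub a `subnetwork` (or any igraph with vertex names).
#' @param q quantile in (0, 1), default 0.9.
#' @param condition optional condition label carried in the result.
#' @return list with `condition`, `hubs`, `quantile_value`, `degree`
#'   (class `hub_set`).
#' @export
find_hubs <- function(sub, q = 0.9, condition = NA_character_) {
  g <- if (inherits(sub, "subnetwork")) sub$graph else sub
  if (igraph::vcount(g) == 0L) stop_data("cannot find hubs in an empty subnetwork")
  if (q <= 0 || q >= 1) stop_config("hub quantile must be in (0, 1)")
  deg <- igraph::degree(g)
  qv <- unname(stats::quantile(deg, probs = q, type = 7L))
  hubs <- sort(names(deg)[deg >= qv])
  structure(list(condition = condition, hubs = hubs, quantile_value = qv,
                 degree = deg),
            class = "hub_set")
}

#' @export
print.hub_set <- function(x, ...) {
  cat(sprintf("hub set%s: %d hubs at degree >= %.2f (quantile value)\n",
              if (is.na(x$condition)) "" else paste0(" [", x$condition, "]"),
              length(x$hubs), x$quantile_value))
  invisible(x)
}

#' Assemble the cross-condition hub network
#'
#' Takes each condition's hub set and perturbed subnetwork and connects two
#' hub genes (of any condition) whenever their interaction is present in at
#' least one condition's subnetwork. Each edge records the conditions that
#' contributed it; connected components are reported sorted by size.
#'
#' @param hubsets list of `hub_set`s.
#' @param subs list of `subnetwork`s, aligned with `hubsets`.
#' @return list with `graph` (igraph; edge attribute `provenance` is a
#'   comma-separated condition list), `nodes`, `components` (list of node
#'   vectors, largest first), `n_hub_conditions` (per-node count of
#'   conditions calling it a hub); class `hub_network`.
#' @export
build_hub_network <- function(hubsets, subs) {
  if (length(hubsets) != length(subs))
    stop_data("hub sets (%d) and subnetworks (%d) are not aligned",
              length(hubsets), length(subs))
  conds <- vapply(seq_along(hubsets), function(i) {
    cl <- hubsets[[i]]$condition
    if (is.na(cl)) paste0("condition", i) else cl
  }, character(1L))
  all_hubs <- sort(unique(unlist(lapply(hubsets, `[[`, "hubs"))))
  edge_prov <- list()
  for (i in seq_along(subs)) {
    el <- igraph::as_edgelist(subs[[i]]$graph)
    if (nrow(el) == 0L) next
    el <- t(apply(el, 1L, sort))
    keep <- el[, 1L] %in% all_hubs & el[, 2L] %in% all_hubs
    for (j in which(keep)) {
      key <- paste(el[j, 1L], el[j, 2L], sep = "\t")
      edge_prov[[key]] <- union(edge_prov[[key]], conds[i])
    }
  }
  keys <- sort(names(edge_prov))
  if (length(keys) > 0L) {
    ep <- do.call(rbind, strsplit(keys, "\t", fixed = TRUE))
    g <- igraph::graph_from_edgelist(ep, directed = FALSE)
    g <- igraph::set_edge_attr(g, "provenance",
                               value = vapply(keys, function(k)
                                 paste(sort(edge_prov[[k]]), collapse = ","),
                                 character(1L)))
  } else {
    g <- igraph::make_empty_graph(directed = FALSE)
  }
  iso <- setdiff(all_hubs, igraph::V(g)$name)
  if (length(iso) > 0L) g <- igraph::add_vertices(g, length(iso), name = iso)
  hub_count <- table(unlist(lapply(hubsets, `[[`, "hubs")))
  comp <- igraph::components(g)
  comp_list <- split(igraph::V(g)$name, comp$membership)
  comp_list <- lapply(comp_list, sort)
  comp_list <- comp_list[order(-vapply(comp_list, length, integer(1L)),
                               vapply(comp_list, `[`, character(1L), 1L))]
  structure(list(graph = g, nodes = all_hubs, components = unname(comp_list),
                 n_hub_conditions = stats::setNames(as.integer(hub_count),
                                                    names(hub_count))),
            class = "hub_network")
}

#' @export
print.hub_network <- function(x, ...) {
  cat(sprintf("hub network: %d genes, %d interactions, %d component(s); largest %d\n",
              length(x$nodes), igraph::ecount(x$graph), length(x$components),
              if (length(x$components)) length(x$components[[1L]]) else 0L))
  invisible(x)
}

#' Permutation test for hub-network perturbation in a dataset
#'
#' The perturbation statistic is the mean absolute moderated t-statistic
#' over the hub genes measured in the dataset. Its significance is assessed
#' against `n_perm` random gene sets of the same size drawn without
#' replacement from all measured genes, with
#' `p = (1 + #(null >= observed)) / (1 + n_perm)`.
#'
#' @param hub character vector of hub genes (or a `hub_network`).
#' @param de moderated-t table from [moderated_t()].
#' @param n_perm number of permutations (default 1000, minimum 100).
#' @param seed RNG seed.
#' @return list with `statistic`, `n_used`, `n_dropped`, `p`,
#'   `null_mean`, `null_sd`; class `perturbation_result`.
#' @export
perturbation_test <- function(hub, de, n_perm = 1000L, seed = 1L) {
  if (inherits(hub, "hub_network")) hub <- hub$nodes
  if (n_perm < 100L) stop_config("n_perm must be >= 100")
  tvec <- stats::setNames(abs(de$t_mod), de$gene)
  used <- intersect(hub, de$gene)
  n_dropped <- length(setdiff(hub, de$gene))
  if (n_dropped > 0L)
    message(sprintf("perturbation_test: %d hub genes not measured, dropped",
                    n_dropped))
  if (length(used) < 10L)
    stop_data("only %d hub genes measured in dataset (need >= 10)", length(used))
  observed <- mean(tvec[used])
  k <- length(used)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    mean(tvec[sample.int(length(tvec), k)]), numeric(1L)))
  structure(list(statistic = observed, n_used = k, n_dropped = n_dropped,
                 p = (1 + sum(null >= observed)) / (1 + n_perm),
                 null_mean = mean(null), null_sd = stats::sd(null)),
            class = "perturbation_result")
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat(sprintf("hub-network perturbation: mean |t| = %.3f over %d genes, p = %.4g\n",
              x$statistic, x$n_used, x$p))
  cat(sprintf("  permutation null: %.3f +/- %.3f\n", x$null_mean, x$null_sd))
  invisible(x)
}

#' One-sided Fisher test for the overlap of two gene sets
#'
#' Over-representation p-value for the observed intersection of two gene
#' sets drawn from a common universe (for instance, two conditions'
#' perturbed subnetworks on the same interactome), from the 2 x 2
#' membership table.
#'
#' @param a,b character vectors of gene identifiers.
#' @param universe universe size (integer), or a character vector of genes.
#' @return list with `overlap` and `p`.
#' @export
subnetwork_overlap_test <- function(a, b, universe) {
  if (is.character(universe)) universe <- length(universe)
  a <- unique(a); b <- unique(b)
  if (universe < length(union(a, b)))
    stop_data("universe (%d) smaller than the union of the two sets (%d)",
              universe, length(union(a, b)))
  k <- length(intersect(a, b))
  # one-sided Fisher p == hypergeometric upper tail
  p <- stats::phyper(k - 1L, length(a), universe - length(a), length(b),
                     lower.tail = FALSE)
  list(overlap = k, p = p)
}

#' Write a hub network as node and edge TSV files
#'
#' @param hn a `hub_network`.
#' @param node_path,edge_path output paths.
#' @return invisibly, the two paths.
#' @export
write_hub_network <- function(hn, node_path, edge_path) {
  genes <- sort(hn$nodes)
  nodes <- data.frame(gene = genes,
                      n_conditions_hub = hn$n_hub_conditions[genes],
                      row.names = NULL)
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  el <- igraph::as_edgelist(hn$graph)
  prov <- igraph::edge_attr(hn$graph, "provenance")
  if (is.null(prov)) prov <- rep("", nrow(el))
  if (nrow(el) > 0L) {
    el <- t(apply(el, 1L, sort))
    ord <- order(el[, 1L], el[, 2L])
    edges <- data.frame(u = el[ord, 1L], v = el[ord, 2L],
                        provenance = prov[ord], row.names = NULL)
  } else {
    edges <- data.frame(u = character(0), v = character(0),
                        provenance = character(0))
  }
  utils::write.table(edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(node_path, edge_path))
}
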