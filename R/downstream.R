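#' Hypergeometric over-representation of gene sets in a query
#'
#' For each set in the collection, computes the hypergeometric upper-tail
#' probability of observing at least the realized overlap between the query
#' and the set, given the universe size. A set is flagged significant when
#' strictly more than `min_overlap` query genes are present and
#' `p < alpha` (defaults 5 and 0.01).
#'
#' @param query character vector of gene identifiers.
#' @param coll gene-set collection (named list, e.g. from [read_gmt()]).
#' @param universe universe size (integer) or character vector of genes; in
#'   the pipeline this is the cleaned network's node count.
#' @param min_overlap strict lower bound on the overlap for significance.
#' @param alpha raw p-value threshold for significance.
#' @return data.frame with columns `set`, `k` (overlap), `K` (set size),
#'   `n` (query size), `N` (universe), `p`, `significant`, sorted by `p`.
#' @export
enrich <- function(query, coll, universe, min_overlap = 5L, alpha = 0.01) {
  if (length(coll) == 0L) stop_data("empty gene-set collection")
  restrict <- NULL
  if (is.character(universe)) {
    restrict <- unique(universe)
    universe <- length(restrict)
  }
  query <- unique(query)
  if (!is.null(restrict)) query <- intersect(query, restrict)
  n <- length(query)
  if (universe < n) stop_data("universe (%d) smaller than query (%d)", universe, n)
  rows <- lapply(names(coll), function(nm) {
    set <- unique(coll[[nm]])
    if (!is.null(restrict)) set <- intersect(set, restrict)
    K <- length(set)
    k <- length(intersect(query, set))
    p <- if (k == 0L) 1 else
      stats::phyper(k - 1L, K, universe - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = universe, p = min(p, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$k > min_overlap & out$p < alpha
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build an enrichment map from significant gene sets
#'
#' Nodes are the significant sets; two sets are connected when the overlap
#' coefficient `|S' intersect T'| / min(|S'|, |T'|)` is at least `cutoff`,
#' where by default `S'` and `T'` are the sets restricted to the query
#' genes (the genes actually present in the perturbed subnetwork). Edge
#' weights carry the coefficient.
#'
#' @param rows enrichment table from [enrich()] (only rows with
#'   `significant == TRUE` are used).
#' @param coll the gene-set collection.
#' @param query the query gene set.
#' @param cutoff overlap-coefficient threshold in (0, 1], default 0.5.
#' @param restrict_to_query compute the coefficient on query-restricted
#'   sets (default) or on the full sets.
#' @return igraph with vertex names = set names and edge attribute `weight`.
#' @export
enrichment_map <- function(rows, coll, query, cutoff = 0.5,
                           restrict_to_query = TRUE) {
  if (cutoff <= 0 || cutoff > 1) stop_config("cutoff must be in (0, 1]")
  sig <- rows$set[rows$significant]
  g <- igraph::make_empty_graph(directed = FALSE)
  if (length(sig) > 0L) g <- igraph::add_vertices(g, length(sig), name = sig)
  if (length(sig) < 2L) return(g)
  eff <- lapply(coll[sig], function(s)
    if (restrict_to_query) intersect(unique(s), query) else unique(s))
  from <- character(0); to <- character(0); wt <- numeric(0)
  for (i in seq_len(length(sig) - 1L)) for (j in (i + 1L):length(sig)) {
    lo <- min(length(eff[[i]]), length(eff[[j]]))
    if (lo == 0L) next
    cc <- length(intersect(eff[[i]], eff[[j]])) / lo
    if (cc >= cutoff) {
      from <- c(from, sig[i]); to <- c(to, sig[j]); wt <- c(wt, cc)
    }
  }
  if (length(from) > 0L) {
    g <- igraph::add_edges(g, rbind(from, to))
    g <- igraph::set_edge_attr(g, "weight", value = wt)
  }
  g
}

#' Screen genes for correlation with severity scores
#'
#' Pearson correlation of each gene's expression against two severity
#' measures — a cognitive score that decreases with severity (MMSE-like)
#' and a pathology burden that increases with it (NFT-like) — with
#' two-sided t-based p-values. Genes are classified by which correlations
#' reach `p <= alpha`.
#'
#' @param m an [expression_matrix()] whose `severity` holds the two score
#'   vectors, or pass them via `scores`.
#' @param scores named list of exactly two numeric vectors (first treated
#'   as the MMSE-like score, second as the NFT-like score); defaults to
#'   `m$severity`.
#' @param alpha significance threshold on the correlation p-value
#'   (default 0.05, inclusive).
#' @return data.frame with `gene`, `r_mmse`, `p_mmse`, `r_nft`, `p_nft`,
#'   `class` (one of `mmse_only`, `nft_only`, `both`, `neither`).
#' @export
severity_correlation <- function(m, scores = NULL, alpha = 0.05) {
  if (is.null(scores)) scores <- m$severity
  if (is.null(scores) || length(scores) != 2L)
    stop_data("severity_correlation needs exactly two score vectors")
  s1 <- scores[[1L]]; s2 <- scores[[2L]]
  if (!is.null(names(s1))) s1 <- s1[colnames(m$values)]
  if (!is.null(names(s2))) s2 <- s2[colnames(m$values)]
  ok <- is.finite(s1) & is.finite(s2)
  if (sum(ok) < 3L) stop_data("need >= 3 samples with severity scores")
  v <- m$values[, ok, drop = FALSE]
  s1 <- s1[ok]; s2 <- s2[ok]
  one <- function(x, s) {
    if (stats::sd(x) == 0 || stats::sd(s) == 0) return(c(NA_real_, NA_real_))
    ct <- stats::cor.test(x, s, method = "pearson", alternative = "two.sided")
    c(unname(ct$estimate), ct$p.value)
  }
  res1 <- t(apply(v, 1L, one, s = s1))
  res2 <- t(apply(v, 1L, one, s = s2))
  n_const <- sum(is.na(res1[, 1L]) | is.na(res2[, 1L]))
  if (n_const > 0L)
    warning(sprintf("%d genes with undefined correlation classified 'neither'",
                    n_const))
  sig1 <- !is.na(res1[, 2L]) & res1[, 2L] <= alpha
  sig2 <- !is.na(res2[, 2L]) & res2[, 2L] <= alpha
  cls <- ifelse(sig1 & sig2, "both",
                ifelse(sig1, "mmse_only", ifelse(sig2, "nft_only", "neither")))
  data.frame(gene = rownames(v),
             r_mmse = res1[, 1L], p_mmse = res1[, 2L],
             r_nft = res2[, 1L], p_nft = res2[, 2L],
             class = cls, row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify samples into severity groups from an MMSE-like score
#'
#' Applies the conventional staging: Control (score > 25), Incipient
#' (20-25), Moderate (14-19), Severe (< 14). Non-integer scores falling in
#' the open gaps join the closest lower stage boundary (>= 20 Incipient,
#' >= 14 Moderate).
#'
#' @param mmse named numeric vector of scores.
#' @return named character vector of group labels, same order as input.
#' @export
severity_groups <- function(mmse) {
  if (!is.numeric(mmse)) stop_data("MMSE scores must be numeric")
  out <- ifelse(mmse > 25, "Control",
                ifelse(mmse >= 20, "Incipient",
                       ifelse(mmse >= 14, "Moderate", "Severe")))
  stats::setNames(out, names(mmse))
}
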