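# Shared in-code fixtures: tiny graphs, matrices and files built at test time.

path_graph <- function(scores) {
  # path A - B - C with the given named scores
  g <- igraph::make_graph(~ A - B, B - C)
  scored_graph(g, scores)
}

toy_matrix <- function(values, genes = NULL, group = NULL) {
  values <- as.matrix(values)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(values)))
  rownames(values) <- genes
  colnames(values) <- paste0("s", seq_len(ncol(values)))
  expression_matrix(values, group = group)
}

# two-group Gaussian matrix under the global null
null_matrix <- function(n_genes, n_per_group, seed) {
  set.seed(seed)
  v <- matrix(stats::rnorm(n_genes * 2 * n_per_group), nrow = n_genes,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(2 * n_per_group))))
  expression_matrix(v, group = rep(c("case", "control"), each = n_per_group))
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# random connected scored instance for oracle comparisons
random_scored_instance <- function(seed, n = 12L, p_edge = 0.3,
                                   n_planted = 3L) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p_edge)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  comp <- igraph::components(g)
  g <- igraph::induced_subgraph(
    g, igraph::V(g)$name[comp$membership == which.max(comp$csize)])
  sc <- stats::rnorm(igraph::vcount(g), -1, 1)
  idx <- sample(igraph::vcount(g), min(n_planted, igraph::vcount(g)))
  sc[idx] <- 3
  names(sc) <- igraph::V(g)$name
  scored_graph(g, sc)
}

f1_score <- function(found, truth) {
  tp <- length(intersect(found, truth))
  if (tp == 0L) return(0)
  prec <- tp / length(found)
  rec <- tp / length(truth)
  2 * prec * rec / (prec + rec)
}
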