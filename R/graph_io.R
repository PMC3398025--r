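#' Read an undirected gene network from an edge-list file
#'
#' Supports two dialects: plain two-column TSV (one edge per line) and SIF
#' (`source relation target1 [target2 ...]`, whitespace-separated, fanning
#' out to one edge per target). Duplicate edges are collapsed; blank lines
#' are skipped and counted.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"sif"`.
#' @return an undirected simple [igraph::igraph] with vertex names; attributes
#'   `edges_parsed` (edge records read, before de-duplication) and
#'   `lines_skipped` (blank lines) record parsing provenance.
#' @export
read_edge_list <- function(path, dialect = c("tsv", "sif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_data("edge list not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  blank <- grepl("^\\s*$", lines)
  n_skipped <- sum(blank)
  content <- which(!blank)
  if (length(content) == 0L) stop_data("empty edge list: %s", path)
  from <- character(0); to <- character(0)
  n_parsed <- 0L
  for (i in content) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    if (dialect == "tsv") {
      if (length(tok) != 2L)
        stop_data("malformed TSV edge at line %d: expected 2 fields, got %d",
                  i, length(tok))
      from <- c(from, tok[1L]); to <- c(to, tok[2L])
      n_parsed <- n_parsed + 1L
    } else {
      if (length(tok) < 3L)
        stop_data("malformed SIF record at line %d: expected source, relation and >=1 target",
                  i)
      targets <- tok[-(1:2)]
      from <- c(from, rep(tok[1L], length(targets))); to <- c(to, targets)
      n_parsed <- n_parsed + length(targets)
    }
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = FALSE)
  g <- igraph::set_graph_attr(g, "edges_parsed", n_parsed)
  igraph::set_graph_attr(g, "lines_skipped", n_skipped)
}

#' Write a network as a two-column TSV edge list
#'
#' @param g an igraph with vertex names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  el <- igraph::as_edgelist(g)
  # canonical order for byte-reproducibility
  el <- t(apply(el, 1L, sort))
  el <- el[order(el[, 1L], el[, 2L]), , drop = FALSE]
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Restrict a network to measured genes and keep its largest component
#'
#' Removes self-loops and multi-edges, drops nodes without expression
#' measurements, and returns the largest remaining connected component (the
#' standard interactome-cleaning step before module search). Size ties
#' between components are broken by the lexicographically smallest node set.
#'
#' @param g an igraph with vertex names.
#' @param measured character vector of measured gene identifiers.
#' @return cleaned igraph. A result that would be a single isolated node is
#'   an error: a one-node network cannot be searched for modules.
#' @export
clean_network <- function(g, measured) {
  if (length(measured) == 0L) stop_data("measured gene set is empty")
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  keep <- intersect(igraph::V(g)$name, measured)
  if (length(keep) == 0L) stop_data("no measured genes in network")
  g <- igraph::induced_subgraph(g, keep)
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # tie: lexicographically smallest sorted node set
    sets <- lapply(best, function(k) sort(igraph::V(g)$name[comp$membership == k]))
    ord <- 1L
    for (j in seq_along(sets)[-1L]) if (lex_less(sets[[j]], sets[[ord]])) ord <- j
    best <- best[ord]
  }
  nodes <- igraph::V(g)$name[comp$membership == best]
  if (length(nodes) < 2L)
    stop_data("no measured genes in network: largest component has a single node")
  igraph::induced_subgraph(g, nodes)
}

#' Drop rows not reliably detected across samples
#'
#' Rows called present in fewer than `min_fraction` of samples are removed
#' (strictly fewer: a row present in exactly 10% of arrays survives the
#' default filter).
#'
#' @param m an `expr_matrix`.
#' @param calls present/absent matrix of the same shape: logical, or
#'   character with `"P"` meaning present (MAS5-call convention; `"A"`/`"M"`
#'   count as absent).
#' @param min_fraction minimum present fraction, default 0.10.
#' @return filtered `expr_matrix`.
#' @export
filter_detection <- function(m, calls, min_fraction = 0.10) {
  if (min_fraction < 0 || min_fraction > 1)
    stop_config("min_fraction must be in [0, 1]")
  if (!all(dim(calls) == dim(m$values)))
    stop_data("detection-call matrix shape %s does not match expression %s",
              paste(dim(calls), collapse = "x"),
              paste(dim(m$values), collapse = "x"))
  if (is.character(calls)) calls <- calls == "P"
  frac <- rowMeans(calls)
  replace_values(m, m$values[frac >= min_fraction, , drop = FALSE])
}

#' Collapse probe-level rows to one row per gene
#'
#' With `strategy = "max_variance"` the probe with the largest sample
#' variance represents the gene; with `"best_correlation"` the probe with
#' the smallest Pearson-correlation p-value against a severity vector is
#' used (the convention for progression analyses). Ties break by probe id
#' order; probes absent from the map are dropped with a message.
#'
#' @param m an `expr_matrix` whose rows are probes.
#' @param probe_map named character vector `probe -> gene`.
#' @param strategy `"max_variance"` or `"best_correlation"`.
#' @param scores numeric severity vector (required for `best_correlation`),
#'   named by sample or in column order.
#' @return `expr_matrix` with one row per gene, rows renamed to gene ids.
#' @export
collapse_probes <- function(m, probe_map,
                            strategy = c("max_variance", "best_correlation"),
                            scores = NULL) {
  strategy <- match.arg(strategy)
  if (strategy == "best_correlation" && is.null(scores))
    stop_config("best_correlation collapse requires a scores vector")
  probes <- rownames(m$values)
  mapped <- probes[probes %in% names(probe_map)]
  n_dropped <- length(probes) - length(mapped)
  if (n_dropped > 0L)
    message(sprintf("collapse_probes: dropped %d unmapped probe rows", n_dropped))
  if (length(mapped) == 0L) stop_data("no probes map to genes")
  if (!is.null(scores)) {
    if (!is.null(names(scores))) scores <- scores[colnames(m$values)]
    if (length(scores) != ncol(m$values))
      stop_data("scores vector does not cover all samples")
  }
  crit <- if (strategy == "max_variance") {
    apply(m$values[mapped, , drop = FALSE], 1L, stats::var, na.rm = TRUE)
  } else {
    vapply(mapped, function(pr) {
      x <- m$values[pr, ]
      ok <- is.finite(x) & is.finite(scores)
      if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(scores[ok]) == 0)
        return(Inf) # undefined correlation loses to any defined one
      stats::cor.test(x[ok], scores[ok], method = "pearson")$p.value
    }, numeric(1L))
  }
  # max_variance keeps largest criterion, best_correlation smallest
  if (strategy == "max_variance") crit <- -crit
  genes <- probe_map[mapped]
  # stable pick per gene: sort by (gene, criterion, probe id) and keep first
  o <- order(genes, crit, mapped)
  first <- !duplicated(genes[o])
  pick <- mapped[o][first]
  out <- m$values[pick, , drop = FALSE]
  rownames(out) <- genes[pick]
  replace_values(m, out)
}

#' Impute missing entries with row-wise k-nearest neighbours
#'
#' Rows missing in more than `max_missing_fraction` of samples are removed
#' first. Remaining missing entries are replaced by the mean of the `k`
#' nearest complete rows, where distance is Euclidean over co-observed
#' columns rescaled by the fraction observed (the usual kNN-impute
#' convention).
#'
#' @param m an `expr_matrix`.
#' @param k number of neighbours (default 10).
#' @param max_missing_fraction rows with more missingness are dropped
#'   (default 0.10, strictly more).
#' @return imputed `expr_matrix`; observed entries are untouched.
#' @export
knn_impute <- function(m, k = 10L, max_missing_fraction = 0.10) {
  if (k < 1L) stop_config("k must be >= 1")
  v <- m$values
  miss_frac <- rowMeans(is.na(v))
  v <- v[miss_frac <= max_missing_fraction, , drop = FALSE]
  if (!anyNA(v)) return(replace_values(m, v))
  complete <- which(rowSums(is.na(v)) == 0L)
  if (length(complete) < k)
    stop_data("k = %d exceeds the %d complete rows available", k, length(complete))
  ref <- v[complete, , drop = FALSE]
  todo <- which(rowSums(is.na(v)) > 0L)
  p <- ncol(v)
  for (i in todo) {
    x <- v[i, ]
    obs <- !is.na(x)
    # squared distance over co-observed columns, rescaled to full length
    d2 <- colSums((t(ref[, obs, drop = FALSE]) - x[obs])^2) * (p / sum(obs))
    nn <- complete[order(d2, complete)[seq_len(k)]]
    fill <- colMeans(v[nn, !obs, drop = FALSE])
    v[i, !obs] <- fill
  }
  replace_values(m, v)
}

#' Read a gene-set collection in GMT format
#'
#' Each line is `name <TAB> description <TAB> member1 <TAB> member2 ...`.
#' Duplicate members within a set are collapsed; duplicate set names are an
#' error.
#'
#' @param path GMT file path.
#' @return named list of character vectors (class `gene_set_collection`).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_data("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0L) stop_data("empty GMT file: %s", path)
  sets <- list()
  for (i in seq_along(lines)) {
    tok <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(tok) < 3L)
      stop_data("GMT line %d has no members (need name, description, >=1 gene)", i)
    nm <- tok[1L]
    if (nm %in% names(sets)) stop_data("duplicate gene-set name at line %d: %s", i, nm)
    members <- unique(tok[-(1:2)])
    members <- members[members != ""]
    if (length(members) == 0L) stop_data("GMT line %d has no members", i)
    sets[[nm]] <- members
  }
  structure(sets, class = c("gene_set_collection", "list"))
}

#' Write a gene-set collection in GMT format
#'
#' @param coll named list of character vectors.
#' @param path output path.
#' @param description description field (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(coll, path, description = "na") {
  lines <- vapply(seq_along(coll), function(i) {
    paste(c(names(coll)[i], description, coll[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
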