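#' Simulate a sparse scale-free interactome
#'
#' Preferential-attachment growth: the graph starts from `m_per_node`
#' seed nodes, and every subsequent node attaches to `m_per_node` distinct
#' existing nodes chosen with probability proportional to degree (the first
#' added node links to all seed nodes, so the graph is connected). The
#' result has `m_per_node * (n - m_per_node)` edges and a heavy-tailed
#' degree distribution — the two properties of curated interactomes the
#' hub analysis relies on.
#'
#' @param n number of genes (>= 10).
#' @param m_per_node edges added per new node (default 2).
#' @param seed RNG seed.
#' @return connected simple igraph with vertex names `g0001`, `g0002`, ...
#' @export
simulate_network <- function(n, m_per_node = 2L, seed = 1L) {
  if (n < 10L) stop_config("n must be >= 10")
  if (m_per_node < 1L || m_per_node >= n)
    stop_config("m_per_node must be in [1, n)")
  m <- as.integer(m_per_node)
  names <- sprintf("g%0*d", max(4L, nchar(n)), seq_len(n))
  edges <- matrix(integer(0), ncol = 2L)
  with_seed(seed, {
    # repeated-node list: each node appears once per incident edge
    repeated <- integer(0)
    targets <- seq_len(m) # first new node links to all seed nodes
    for (v in (m + 1L):n) {
      edges <- rbind(edges, cbind(v, targets))
      repeated <- c(repeated, targets, rep.int(v, m))
      # sample m distinct targets preferentially for the next node
      if (v < n) {
        targets <- integer(0)
        while (length(targets) < m) {
          cand <- repeated[sample.int(length(repeated), 1L)]
          if (!(cand %in% targets)) targets <- c(targets, cand)
        }
      }
    }
  })
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  igraph::set_vertex_attr(g, "name", value = names)
}

#' Plant a connected module in a network
#'
#' Grows a connected node set by seeded random neighbour expansion from a
#' random start node; the induced subgraph of the result is connected by
#' construction.
#'
#' @param g igraph with vertex names.
#' @param size module size.
#' @param seed RNG seed.
#' @return character vector of module gene ids (sorted).
#' @export
plant_module <- function(g, size, seed = 1L) {
  n <- igraph::vcount(g)
  if (size < 1L || size > n) stop_config("module size must be in [1, %d]", n)
  adj <- igraph::as_adj_list(g)
  names <- igraph::V(g)$name
  with_seed(seed, {
    current <- sample.int(n, 1L)
    members <- current
    frontier <- setdiff(as.integer(adj[[current]]), members)
    while (length(members) < size) {
      if (length(frontier) == 0L)
        stop_data("module of size %d unreachable from start node", size)
      nxt <- frontier[sample.int(length(frontier), 1L)]
      members <- c(members, nxt)
      frontier <- setdiff(union(frontier, as.integer(adj[[nxt]])), members)
    }
  })
  sort(names[members])
}

#' Simulate two-group expression data with a planted perturbed module
#'
#' Every gene is baseline `Normal(0, sigma^2)` in every sample; module
#' genes are shifted by `effect * sigma` in case samples (optionally with a
#' random per-gene sign, mimicking mixed up/down dys-regulation). Optional
#' probe duplication (1-3 probes per gene with extra probe-level noise) and
#' missing-at-random entries exercise the probe-collapse and imputation
#' steps.
#'
#' @param g interactome (igraph with vertex names).
#' @param module character vector of planted module genes.
#' @param n_case,n_control group sizes.
#' @param effect shift in SD units (>= 0), default 2.
#' @param sigma baseline standard deviation, default 1.
#' @param random_sign randomize the direction of each module gene's shift.
#' @param probe_dup duplicate genes into 1-3 probes (rows named
#'   `gene.p1`, ...) with probe noise SD `0.2 * sigma`.
#' @param missing_rate fraction of entries set missing at random.
#' @param seed RNG seed.
#' @return list with `matrix` (an [expression_matrix()]), `truth` (list:
#'   `planted_module`, `effect_size`, `seed`, and `probe_map` when
#'   `probe_dup`).
#' @export
simulate_expression <- function(g, module, n_case = 10L, n_control = 10L,
                                effect = 2, sigma = 1, random_sign = FALSE,
                                probe_dup = FALSE, missing_rate = 0,
                                seed = 1L) {
  if (effect < 0) stop_config("effect must be >= 0")
  if (sigma <= 0) stop_config("sigma must be > 0")
  genes <- igraph::V(g)$name
  if (!all(module %in% genes)) stop_data("module genes missing from network")
  ns <- n_case + n_control
  samples <- c(sprintf("case%02d", seq_len(n_case)),
               sprintf("ctrl%02d", seq_len(n_control)))
  group <- stats::setNames(rep(c("case", "control"), c(n_case, n_control)),
                           samples)
  out <- with_seed(seed, {
    v <- matrix(stats::rnorm(length(genes) * ns, 0, sigma),
                nrow = length(genes), dimnames = list(genes, samples))
    sgn <- if (random_sign) sample(c(-1, 1), length(module), replace = TRUE)
           else rep(1, length(module))
    v[module, seq_len(n_case)] <- v[module, seq_len(n_case)] +
      sgn * effect * sigma
    probe_map <- NULL
    if (probe_dup) {
      n_probes <- sample(1:3, length(genes), replace = TRUE)
      probe_gene <- rep(genes, n_probes)
      probe_ids <- unlist(lapply(seq_along(genes), function(i)
        paste0(genes[i], ".p", seq_len(n_probes[i]))))
      v <- v[probe_gene, , drop = FALSE] +
        matrix(stats::rnorm(length(probe_gene) * ns, 0, 0.2 * sigma),
               nrow = length(probe_gene))
      rownames(v) <- probe_ids
      probe_map <- stats::setNames(probe_gene, probe_ids)
    }
    if (missing_rate > 0) {
      holes <- stats::runif(length(v)) < missing_rate
      v[holes] <- NA_real_
    }
    list(v = v, probe_map = probe_map)
  })
  truth <- list(planted_module = sort(module), effect_size = effect,
                seed = seed, probe_map = out$probe_map)
  list(matrix = expression_matrix(out$v, group = group), truth = truth)
}

#' Draw p-values from a beta-uniform mixture
#'
#' Each draw is `Uniform(0, 1)` with probability `lam`, otherwise
#' `Beta(a, 1)` — the generative counterpart of [fit_bum()].
#'
#' @param lam uniform (noise) weight in `[0, 1]`.
#' @param a beta shape in (0, 1).
#' @param n number of draws.
#' @param seed RNG seed.
#' @return numeric vector, with attribute `is_noise` (logical component
#'   labels, the ground truth for FDR calibration).
#' @export
simulate_pvalues <- function(lam, a, n, seed = 1L) {
  if (lam < 0 || lam > 1) stop_config("lam must be in [0, 1]")
  if (a <= 0 || a >= 1) stop_config("a must be in (0, 1)")
  if (n < 1L) stop_config("n must be >= 1")
  with_seed(seed, {
    noise <- stats::runif(n) < lam
    p <- numeric(n)
    p[noise] <- stats::runif(sum(noise))
    p[!noise] <- stats::rbeta(sum(!noise), a, 1)
    attr(p, "is_noise") <- noise
    p
  })
}

#' Simulate anti-correlated severity scores coupled to chosen genes
#'
#' The first score (MMSE-like, decreasing with severity) is
#' `-slope * mean(coupled gene expression) + noise`; the second (NFT-like,
#' increasing) uses `+slope`. With `slope = 0` both scores are pure noise.
#'
#' @param m an [expression_matrix()].
#' @param coupled character vector of coupled genes (subset of the rows).
#' @param slope coupling strength, default 1.
#' @param noise_sd additive Gaussian noise SD, default 0.5.
#' @param seed RNG seed.
#' @return named list with `mmse` and `nft` vectors (named by sample).
#' @export
simulate_severity <- function(m, coupled, slope = 1, noise_sd = 0.5,
                              seed = 1L) {
  if (!all(coupled %in% rownames(m$values)))
    stop_data("coupled genes missing from expression matrix")
  base <- if (length(coupled) > 0L)
    colMeans(m$values[coupled, , drop = FALSE]) else
    stats::setNames(numeric(ncol(m$values)), colnames(m$values))
  ns <- ncol(m$values)
  with_seed(seed, {
    mmse <- -slope * base + stats::rnorm(ns, 0, noise_sd)
    nft <- slope * base + stats::rnorm(ns, 0, noise_sd)
    list(mmse = stats::setNames(mmse, colnames(m$values)),
         nft = stats::setNames(nft, colnames(m$values)))
  })
}
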