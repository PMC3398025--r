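#' Default pipeline configuration
#'
#' Every default traces to the method's conventions: positive-node target
#' fraction 0.10, hub degree quantile 0.9, enrichment thresholds
#' (overlap > 5, p < 0.01), detection filter 0.10, permutation count 1000.
#'
#' @param ... overrides merged over the defaults.
#' @return named list (a run configuration).
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    outdir = "pertnet_out",
    target_fraction = 0.10,
    fdr_grid = default_fdr_grid(),
    hub_quantile = 0.9,
    min_overlap = 5L,
    enrich_alpha = 0.01,
    overlap_cutoff = 0.5,
    n_perm = 1000L,
    exact_max = 15L,
    network = list(simulate = list(n = 500L, m_per_node = 2L)),
    conditions = list(
      cond1 = list(simulate = list(module_size = 20L, n_case = 10L,
                                   n_control = 10L, effect = 2, sigma = 1))
    ),
    gmt = NULL,
    severity = NULL
  )
  utils::modifyList(cfg, list(...))
}

read_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(default_config, cfg)
}

load_network <- function(cfg) {
  nw <- cfg$network
  if (!is.null(nw$simulate)) {
    sim <- nw$simulate
    do.call(simulate_network,
            c(sim[setdiff(names(sim), "seed")],
              list(seed = sim$seed %||% cfg$seed)))
  } else if (!is.null(nw$path)) {
    if (!file.exists(nw$path)) stop_data("network file not found: %s", nw$path)
    read_edge_list(nw$path, dialect = nw$dialect %||% "tsv")
  } else stop_config("network must give either $simulate parameters or $path")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_condition <- function(cond, g, cfg, idx) {
  if (!is.null(cond$simulate)) {
    sim <- cond$simulate
    seed <- sim$seed %||% (cfg$seed + 1000L * idx)
    module <- plant_module(g, sim$module_size %||% 20L, seed = seed)
    se <- simulate_expression(g, module,
                              n_case = sim$n_case %||% 10L,
                              n_control = sim$n_control %||% 10L,
                              effect = sim$effect %||% 2,
                              sigma = sim$sigma %||% 1,
                              seed = seed + 1L)
    list(matrix = se$matrix, truth = se$truth)
  } else if (!is.null(cond$expression)) {
    if (!file.exists(cond$expression))
      stop_data("expression file not found: %s", cond$expression)
    m <- read_expression(cond$expression, group = cond$design,
                         severity = cond$severity)
    list(matrix = m, truth = NULL)
  } else stop_config("condition must give either $simulate or $expression")
}

#' Run the full perturbed-subnetwork pipeline
#'
#' Executes, per condition: network cleaning, moderated-t differential
#' expression, beta-uniform-mixture scoring at the FDR whose positive
#' fraction is closest to the target, maximal-scoring subnetwork search and
#' hub extraction; then assembles the cross-condition hub network, tests
#' its perturbation in every condition, tests pairwise subnetwork overlaps,
#' and (when a GMT collection is configured) runs over-representation of
#' the hub network. All artifacts are written as TSV under `cfg$outdir`
#' together with a JSON report; identical configuration and seed reproduce
#' the outputs byte for byte.
#'
#' @param cfg a configuration list (see [default_config()]) or the path of
#'   a JSON configuration file.
#' @return the run report (named list), invisibly; also written as
#'   `report.json`.
#' @export
run_pipeline <- function(cfg = default_config()) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  t0 <- proc.time()[["elapsed"]]
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- "network"
  report <- list(parameters = cfg[c("seed", "target_fraction", "hub_quantile",
                                    "min_overlap", "enrich_alpha", "n_perm")],
                 stages = list())
  on.exit({
    if (stage != "done") report$failed_stage <- stage
    jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  g <- load_network(cfg)
  write_edge_list(g, file.path(cfg$outdir, "network.tsv"))
  report$stages$network <- list(nodes = igraph::vcount(g),
                                edges = igraph::ecount(g))
  conds <- names(cfg$conditions)
  if (is.null(conds)) conds <- paste0("condition", seq_along(cfg$conditions))
  subs <- list(); hubsets <- list(); des <- list(); truths <- list()
  for (i in seq_along(cfg$conditions)) {
    cname <- conds[i]
    stage <- paste0("condition:", cname)
    cd <- load_condition(cfg$conditions[[i]], g, cfg, i)
    ps <- perturbed_subnetwork(cd$matrix, g,
                               target_fraction = cfg$target_fraction,
                               fdr_grid = cfg$fdr_grid,
                               exact_max = cfg$exact_max)
    subs[[cname]] <- ps$subnetwork
    des[[cname]] <- ps$de
    truths[[cname]] <- cd$truth
    hubsets[[cname]] <- find_hubs(ps$subnetwork, q = cfg$hub_quantile,
                                  condition = cname)
    prefix <- file.path(cfg$outdir, cname)
    write_de_table(ps$de, paste0(prefix, "_de.tsv"))
    write_score_table(ps$scores, paste0(prefix, "_scores.tsv"))
    write_subnetwork(ps$subnetwork, scored_graph(ps$network, ps$scores),
                     paste0(prefix, "_subnetwork_nodes.tsv"),
                     paste0(prefix, "_subnetwork_edges.tsv"))
    report$stages[[cname]] <- list(
      network_nodes = igraph::vcount(ps$network),
      bum = list(lam = ps$fit$lam, a = ps$fit$a),
      fdr = ps$fdr, tau = attr(ps$scores, "tau"),
      positive_fraction = ps$positive_fraction,
      subnetwork_size = length(ps$subnetwork$nodes),
      subnetwork_score = ps$subnetwork$total_score,
      hub_count = length(hubsets[[cname]]$hubs))
  }
  stage <- "hub_network"
  hn <- build_hub_network(hubsets, subs)
  write_hub_network(hn, file.path(cfg$outdir, "hub_network_nodes.tsv"),
                    file.path(cfg$outdir, "hub_network_edges.tsv"))
  report$stages$hub_network <- list(
    nodes = length(hn$nodes), edges = igraph::ecount(hn$graph),
    components = length(hn$components),
    largest_component = if (length(hn$components))
      length(hn$components[[1L]]) else 0L)
  stage <- "perturbation"
  if (length(hn$nodes) >= 10L) {
    report$stages$perturbation <- lapply(seq_along(des), function(i) {
      pt <- tryCatch(perturbation_test(hn$nodes, des[[i]],
                                       n_perm = cfg$n_perm,
                                       seed = cfg$seed + 7L + i),
                     pertnet_data_error = function(e) NULL)
      if (is.null(pt)) NULL else
        list(condition = conds[i], statistic = pt$statistic, p = pt$p,
             n_used = pt$n_used)
    })
  }
  stage <- "overlap"
  if (length(subs) > 1L) {
    ov <- list()
    uni <- igraph::vcount(g)
    for (i in seq_len(length(subs) - 1L)) for (j in (i + 1L):length(subs)) {
      r <- subnetwork_overlap_test(subs[[i]]$nodes, subs[[j]]$nodes, uni)
      ov[[paste(conds[i], conds[j], sep = "|")]] <-
        list(overlap = r$overlap, p = r$p)
    }
    report$stages$overlap <- ov
  }
  stage <- "enrichment"
  if (!is.null(cfg$gmt)) {
    coll <- if (is.character(cfg$gmt)) read_gmt(cfg$gmt) else cfg$gmt
    er <- enrich(hn$nodes, coll, universe = igraph::vcount(g),
                 min_overlap = cfg$min_overlap, alpha = cfg$enrich_alpha)
    utils::write.table(er, file.path(cfg$outdir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$enrichment <- list(sets = nrow(er),
                                     significant = sum(er$significant))
  }
  stage <- "done"
  if (!is.null(truths[[1L]]) && length(truths) > 0L) {
    report$truth <- lapply(truths, function(tr)
      if (is.null(tr)) NULL else list(module_size = length(tr$planted_module),
                                      effect = tr$effect_size))
  }
  report$wall_time_s <- proc.time()[["elapsed"]] - t0
  invisible(report)
}
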