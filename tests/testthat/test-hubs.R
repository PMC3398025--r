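test_that("find_hubs uses the linear-interpolation degree quantile", {
  star <- igraph::make_star(10, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("X", paste0("l", 1:9))
  hs <- find_hubs(star, q = 0.9)
  # degrees (9, 1 x 9): 0.9 quantile interpolates to 1.8
  expect_equal(hs$quantile_value, 1.8)
  expect_equal(hs$hubs, "X")
  # oracle: direct formula at h = (n-1)q + 1
  d <- sort(igraph::degree(star))
  h <- (10 - 1) * 0.9 + 1
  expect_equal(hs$quantile_value, unname(d[9] + (h - 9) * (d[10] - d[9])))

  # degenerate distribution: everyone is a hub
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- paste0("v", 1:4)
  expect_length(find_hubs(k4, 0.9)$hubs, 4L)
  # q -> 0 limit keeps everyone
  expect_length(find_hubs(star, 1e-9)$hubs, 10L)
  expect_error(find_hubs(igraph::make_empty_graph(directed = FALSE)), "empty")
  expect_error(find_hubs(star, q = 1.2), "quantile")
})

test_that("find_hubs always returns at least one node", {
  for (s in 1:10) {
    set.seed(s)
    g <- igraph::sample_gnp(15, 0.3)
    igraph::V(g)$name <- paste0("v", 1:15)
    expect_gte(length(find_hubs(g, 0.9)$hubs), 1L)
  }
})

test_that("build_hub_network unions hubs and records edge provenance", {
  gAB <- igraph::make_graph(~ A - B)
  gBC <- igraph::make_graph(~ B - C)
  mk_sub <- function(g) structure(
    list(nodes = igraph::V(g)$name, graph = g,
         total_score = 0, node_score = numeric(0)), class = "subnetwork")
  hs1 <- structure(list(condition = "C1", hubs = c("A", "B"),
                        quantile_value = 1, degree = c(A = 1, B = 1)),
                   class = "hub_set")
  hs2 <- structure(list(condition = "C2", hubs = c("B", "C"),
                        quantile_value = 1, degree = c(B = 1, C = 1)),
                   class = "hub_set")
  hn <- build_hub_network(list(hs1, hs2), list(mk_sub(gAB), mk_sub(gBC)))
  expect_setequal(hn$nodes, c("A", "B", "C"))
  expect_length(hn$components, 1L)
  expect_setequal(hn$components[[1]], c("A", "B", "C"))

  # hub with no qualifying edge becomes its own component
  hs3 <- structure(list(condition = "C3", hubs = "D", quantile_value = 0,
                        degree = c(D = 0)), class = "hub_set")
  gD <- igraph::make_empty_graph(directed = FALSE) |>
    igraph::add_vertices(1, name = "D")
  hn3 <- build_hub_network(list(hs1, hs3), list(mk_sub(gAB), mk_sub(gD)))
  expect_true(any(vapply(hn3$components, function(cmp) identical(cmp, "D"),
                         logical(1))))
  # invariant to condition order
  hn4 <- build_hub_network(list(hs2, hs1), list(mk_sub(gBC), mk_sub(gAB)))
  expect_setequal(hn4$nodes, hn$nodes)
  expect_equal(igraph::ecount(hn4$graph), igraph::ecount(hn$graph))
})

test_that("build_hub_network provenance distinguishes duplicate conditions", {
  # fix the degenerate label case above: distinct labels stay distinct
  gAB <- igraph::make_graph(~ A - B)
  sub <- structure(list(nodes = c("A", "B"), graph = gAB, total_score = 0,
                        node_score = numeric(0)), class = "subnetwork")
  mk_hs <- function(cond) structure(
    list(condition = cond, hubs = c("A", "B"), quantile_value = 1,
         degree = c(A = 1, B = 1)), class = "hub_set")
  hn <- build_hub_network(list(mk_hs("r1"), mk_hs("r2")), list(sub, sub))
  expect_equal(igraph::edge_attr(hn$graph, "provenance"), "r1,r2")
})

test_that("perturbation_test computes the mean |t| statistic and exact p behaviour", {
  de <- data.frame(gene = paste0("g", 1:100),
                   t_mod = c(2, -2, 4, rnorm(97)))
  pt <- perturbation_test(c(paste0("g", 1:3), paste0("g", 50:60)), de,
                          n_perm = 200, seed = 3)
  hub <- c(paste0("g", 1:3), paste0("g", 50:60))
  expect_equal(pt$statistic, mean(abs(de$t_mod[de$gene %in% hub])))
  expect_equal(pt$n_used, 14L)
  # direct mean-of-absolutes example
  de3 <- data.frame(gene = c(paste0("h", 1:10), paste0("g", 1:90)),
                    t_mod = c(2, -2, 4, rep(0.1, 7), rnorm(90, 0, 0.01)))
  pt3 <- perturbation_test(paste0("h", 1:10), de3, n_perm = 100, seed = 1)
  expect_equal(pt3$statistic, mean(abs(c(2, -2, 4, rep(0.1, 7)))))

  # hub set = top-|t| genes attains the minimum p
  set.seed(4)
  de2 <- data.frame(gene = paste0("g", 1:200), t_mod = rnorm(200))
  top <- de2$gene[order(-abs(de2$t_mod))][1:15]
  ptop <- perturbation_test(top, de2, n_perm = 100, seed = 5)
  expect_equal(ptop$p, 1 / 101)

  expect_error(perturbation_test(paste0("g", 1:5), de, n_perm = 100),
               ">= 10")
  expect_error(perturbation_test(paste0("g", 1:20), de, n_perm = 10),
               "n_perm")
  # bit-reproducible given the seed, invariant to hub ordering
  pt_b <- perturbation_test(rev(hub), de, n_perm = 200, seed = 3)
  expect_identical(pt$p, pt_b$p)
  expect_identical(pt$statistic, pt_b$statistic)
})

test_that("subnetwork_overlap_test matches Fisher's exact test", {
  a <- paste0("a", 1:30); b <- c(paste0("a", 1:10), paste0("b", 1:25))
  r <- subnetwork_overlap_test(a, b, 1000)
  expect_equal(r$overlap, 10L)
  ft <- stats::fisher.test(matrix(c(10, 20, 25, 945), 2), alternative = "greater")
  expect_equal(r$p, ft$p.value, tolerance = 1e-9)
  # symmetry
  expect_equal(subnetwork_overlap_test(b, a, 1000)$p, r$p, tolerance = 1e-12)
  # disjoint sets -> p = 1; identical sets -> vanishing p
  expect_equal(subnetwork_overlap_test(paste0("x", 1:5), paste0("y", 1:5),
                                       10000)$p, 1)
  expect_lt(subnetwork_overlap_test(paste0("x", 1:20), paste0("x", 1:20),
                                    10000)$p, 1e-20)
  expect_error(subnetwork_overlap_test(paste0("x", 1:20), paste0("y", 1:20),
                                       30), "universe")
})

test_that("permutation p-values are calibrated under a global null", {
  # fast version of the calibration suite (full version in acceptance tests)
  hits <- 0L
  n_rep <- 50L
  for (r in seq_len(n_rep)) {
    set.seed(3000 + r)
    de <- data.frame(gene = sprintf("g%03d", 1:300), t_mod = rnorm(300))
    hub <- sample(de$gene, 20)
    pt <- perturbation_test(hub, de, n_perm = 100, seed = 4000 + r)
    if (pt$p < 0.05) hits <- hits + 1L
  }
  expect_lte(hits / n_rep, 0.14)
})

test_that("hub networks write node and edge tables", {
  gAB <- igraph::make_graph(~ A - B)
  sub <- structure(list(nodes = c("A", "B"), graph = gAB, total_score = 0,
                        node_score = numeric(0)), class = "subnetwork")
  hs <- structure(list(condition = "C1", hubs = c("A", "B"),
                       quantile_value = 1, degree = c(A = 1, B = 1)),
                  class = "hub_set")
  hn <- build_hub_network(list(hs), list(sub))
  nf <- tempfile(); ef <- tempfile()
  write_hub_network(hn, nf, ef)
  expect_equal(utils::read.delim(nf)$gene, c("A", "B"))
  expect_equal(utils::read.delim(ef)$provenance, "C1")
})
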