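test_that("enrich matches the exhaustive hypergeometric oracle", {
  coll <- list(S = paste0("g", 1:4))
  query <- paste0("g", c(1:3, 10, 11))
  rows <- enrich(query, coll, universe = 20, min_overlap = 1, alpha = 0.05)
  # oracle by direct summation: P(X >= 3) = (C(4,3)C(16,2) + C(4,4)C(16,1)) / C(20,5)
  oracle <- (choose(4, 3) * choose(16, 2) + choose(4, 4) * choose(16, 1)) /
    choose(20, 5)
  expect_equal(rows$p, oracle, tolerance = 1e-12)
  expect_equal(oracle, 496 / 15504)
  expect_equal(rows$k, 3L)

  # zero overlap -> p = 1; saturated query -> p = 1
  expect_equal(enrich(paste0("x", 1:5), coll, 100, 1, 0.05)$p, 1)
  full <- enrich(paste0("g", 1:10), list(S = paste0("g", 1:10)), 10, 1, 0.05)
  expect_equal(full$p, 1)
  expect_error(enrich(query, list(), 20), "empty")
})

test_that("enrich significance needs more than min_overlap genes and p < alpha", {
  coll <- list(big = paste0("g", 1:20), small = paste0("g", 1:3))
  query <- paste0("g", 1:10)
  rows <- enrich(query, coll, universe = 1000, min_overlap = 5, alpha = 0.01)
  big <- rows[rows$set == "big", ]
  small <- rows[rows$set == "small", ]
  expect_true(big$significant)      # k = 10 > 5 and tiny p
  expect_false(small$significant)   # k = 3 <= 5 despite small p
  # k exactly at the bound is not enough
  coll6 <- list(S = paste0("g", 1:5))
  r6 <- enrich(query, coll6, 1000, min_overlap = 5, alpha = 0.01)
  expect_equal(r6$k, 5L)
  expect_false(r6$significant)
})

test_that("enrichment p is monotone decreasing in the overlap", {
  ps <- vapply(1:8, function(k) {
    stats::phyper(k - 1, 10, 990, 10, lower.tail = FALSE)
  }, numeric(1))
  rows <- lapply(1:8, function(k) {
    enrich(c(paste0("g", 1:k), paste0("x", 1:(10 - k))),
           list(S = paste0("g", 1:10)), 1000, 1, 0.05)$p
  })
  expect_equal(unlist(rows), ps, tolerance = 1e-12)
  expect_true(all(diff(unlist(rows)) < 0))
})

test_that("null enrichment keeps the false-positive count near alpha", {
  set.seed(21)
  genes <- sprintf("g%04d", 1:2000)
  coll <- lapply(1:50, function(i) sample(genes, 40))
  names(coll) <- paste0("S", 1:50)
  n_sig <- vapply(1:100, function(r) {
    set.seed(100 + r)
    q <- sample(genes, 100)
    sum(enrich(q, coll, universe = 2000, min_overlap = 0, alpha = 0.01)$significant)
  }, numeric(1))
  expect_lte(mean(n_sig), 0.01 * 50 + 2)
})

test_that("enrichment_map connects sets by query-restricted overlap coefficient", {
  coll <- list(S = paste0("g", 1:6), T = paste0("g", c(1:3, 10:12)),
               U = paste0("x", 1:5))
  query <- c(paste0("g", 1:6), paste0("g", 10:12), paste0("x", 1:5))
  rows <- data.frame(set = c("S", "T", "U"), significant = TRUE)
  g <- enrichment_map(rows, coll, query, cutoff = 0.5)
  # S' = g1..g6, T' = g1..g3,g10..g12: overlap 3 / min(6,6) = 0.5 -> edge
  expect_true(igraph::are_adjacent(g, "S", "T"))
  expect_false(igraph::are_adjacent(g, "S", "U"))
  expect_equal(igraph::edge_attr(g, "weight"), 0.5)
  # containment gives coefficient 1
  coll2 <- list(A = paste0("g", 1:3), B = paste0("g", 1:6))
  g2 <- enrichment_map(data.frame(set = c("A", "B"), significant = TRUE),
                       coll2, paste0("g", 1:6), cutoff = 0.5)
  expect_equal(igraph::edge_attr(g2, "weight"), 1)
  # symmetric, self-loop-free
  expect_false(any(igraph::which_loop(g)))
  expect_error(enrichment_map(rows, coll, query, cutoff = 0), "cutoff")
})

test_that("severity_correlation classifies coupled genes", {
  set.seed(22)
  n <- 31
  v <- matrix(rnorm(100 * n), 100, n,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%02d", 1:n)))
  mmse <- rnorm(n)
  v[1:20, ] <- v[1:20, ] * 0.5 + matrix(rep(mmse, each = 20), 20)
  nft <- rnorm(n)
  m <- expression_matrix(v)
  sc <- severity_correlation(m, scores = list(mmse = mmse, nft = nft))
  coupled <- sc[1:20, ]
  expect_gte(sum(coupled$class %in% c("mmse_only", "both")), 18)

  # exact-construction cases
  v2 <- rbind(g1 = mmse, g2 = rep(1, n))
  colnames(v2) <- sprintf("s%02d", 1:n)
  expect_warning(
    sc2 <- severity_correlation(expression_matrix(v2),
                                scores = list(mmse = mmse, nft = nft)),
    "undefined")
  expect_equal(sc2$r_mmse[1], 1)
  expect_true(sc2$class[1] %in% c("mmse_only", "both"))
  expect_equal(sc2$class[2], "neither")
})

test_that("severity classes are invariant to affine score transforms", {
  set.seed(23)
  v <- matrix(rnorm(50 * 20), 50, 20,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:20)))
  m <- expression_matrix(v)
  s1 <- rnorm(20); s2 <- rnorm(20)
  a <- severity_correlation(m, scores = list(mmse = s1, nft = s2))
  b <- severity_correlation(m, scores = list(mmse = 3 * s1 - 7, nft = 0.1 * s2 + 2))
  expect_equal(a$class, b$class)
  expect_equal(abs(a$r_mmse), abs(b$r_mmse), tolerance = 1e-12)
})

test_that("severity_groups applies the printed MMSE stage boundaries", {
  scores <- c(a = 30, b = 26, c = 25, d = 20, e = 19, f = 14, g = 13, h = 5)
  grp <- severity_groups(scores)
  expect_equal(unname(grp), c("Control", "Control", "Incipient", "Incipient",
                              "Moderate", "Moderate", "Severe", "Severe"))
  expect_named(grp, names(scores))
  expect_error(severity_groups("high"), "numeric")
})
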