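test_that("read_edge_list parses TSV, collapses duplicates, rejects malformed lines", {
  f <- write_lines_tmp(c("A\tB", "B\tC", "A\tB"))
  g <- read_edge_list(f, dialect = "tsv")
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))
  expect_equal(igraph::ecount(g), 2L)
  expect_equal(igraph::graph_attr(g, "edges_parsed"), 3L)

  bad <- write_lines_tmp(c("A"))
  expect_error(read_edge_list(bad, "tsv"), "line 1")
  expect_error(read_edge_list(write_lines_tmp(character(0)), "tsv"), "empty")
})

test_that("read_edge_list fans out SIF targets and counts skipped blanks", {
  f <- write_lines_tmp(c("A pp B C", "", "B pp C"))
  g <- read_edge_list(f, dialect = "sif")
  expect_equal(igraph::ecount(g), 3L) # A-B, A-C, B-C
  expect_equal(igraph::graph_attr(g, "lines_skipped"), 1L)
  expect_error(read_edge_list(write_lines_tmp("A pp"), "sif"), "line 1")
})

test_that("clean_network removes self-loops, unmeasured nodes, keeps largest component", {
  g <- igraph::make_graph(~ A - B, B - C, A - C, D - E, A - A)
  out <- clean_network(g, c("A", "B", "C", "D", "E"))
  expect_setequal(igraph::V(out)$name, c("A", "B", "C"))
  expect_equal(igraph::ecount(out), 3L)

  g2 <- igraph::make_graph(~ A - A, A - B)
  out2 <- clean_network(g2, c("A", "B"))
  expect_setequal(igraph::V(out2)$name, c("A", "B"))
  expect_equal(igraph::ecount(out2), 1L)

  # single surviving node is an error
  tri <- igraph::make_graph(~ A - B, B - C, A - C)
  expect_error(clean_network(tri, "A"), "no measured genes")
  # size ties break to the lexicographically smallest component
  tie <- igraph::make_graph(~ X - Y, A - B)
  expect_setequal(igraph::V(clean_network(tie, c("X", "Y", "A", "B")))$name,
                  c("A", "B"))
})

test_that("clean_network is idempotent", {
  set.seed(1)
  g <- igraph::sample_gnp(30, 0.1)
  igraph::V(g)$name <- paste0("v", 1:30)
  measured <- paste0("v", 1:25)
  once <- clean_network(g, measured)
  twice <- clean_network(once, measured)
  expect_setequal(igraph::V(twice)$name, igraph::V(once)$name)
  expect_equal(igraph::ecount(twice), igraph::ecount(once))
})

test_that("filter_detection applies the strict 'fewer than' rule", {
  v <- matrix(1, nrow = 3, ncol = 10)
  m <- toy_matrix(v)
  calls <- rbind(rep(FALSE, 10),            # present in 0 -> dropped
                 c(TRUE, rep(FALSE, 9)),    # present in 1 = 10% -> kept
                 rep(TRUE, 10))             # present in all -> kept
  out <- filter_detection(m, calls, 0.10)
  expect_equal(rownames(out$values), c("g2", "g3"))
  # min_fraction 0 keeps everything
  expect_equal(nrow(filter_detection(m, calls, 0)$values), 3L)
  expect_error(filter_detection(m, calls[, 1:5]), "shape")
})

test_that("collapse_probes keeps max-variance or best-correlated probe", {
  v <- rbind(p1 = c(1, 2, 1, 2), p2 = c(0, 4, 0, 4), q1 = c(5, 5, 5, 6))
  colnames(v) <- paste0("s", 1:4)
  m <- expression_matrix(v)
  pm <- c(p1 = "G", p2 = "G", q1 = "H")
  out <- collapse_probes(m, pm, "max_variance")
  expect_setequal(rownames(out$values), c("G", "H"))
  expect_equal(unname(out$values["G", ]), c(0, 4, 0, 4)) # p2 wins on variance

  sc <- c(1, 2, 1, 2)
  v2 <- rbind(p1 = c(1, 2, 1, 2), p2 = c(3, 3, 3, 3))
  colnames(v2) <- paste0("s", 1:4)
  m2 <- expression_matrix(v2)
  out2 <- collapse_probes(m2, c(p1 = "G", p2 = "G"), "best_correlation",
                          scores = sc)
  expect_equal(unname(out2$values["G", ]), c(1, 2, 1, 2)) # r = 1 beats constant

  # single probe passes through unchanged; unmapped probes dropped with message
  expect_message(
    out3 <- collapse_probes(m, c(p1 = "G"), "max_variance"),
    "2 unmapped")
  expect_equal(unname(out3$values["G", ]), c(1, 2, 1, 2))
  expect_error(collapse_probes(m2, c(p1 = "G", p2 = "G"), "best_correlation"),
               "requires a scores")
})

test_that("collapse_probes output gene ids are unique", {
  set.seed(3)
  v <- matrix(rnorm(40), 10, 4,
              dimnames = list(paste0("p", 1:10), paste0("s", 1:4)))
  pm <- setNames(paste0("G", rep(1:4, length.out = 10)), paste0("p", 1:10))
  out <- collapse_probes(expression_matrix(v), pm, "max_variance")
  expect_false(anyDuplicated(rownames(out$values)) > 0)
  expect_lte(nrow(out$values), length(unique(pm)))
})

test_that("knn_impute drops over-missing rows and averages nearest neighbours", {
  v <- rbind(a = c(1, 1, NA, 1),
             b = c(1, 1, 1, 1),
             c = c(1, 1, 1, 1),
             d = c(9, 9, 9, 9))
  colnames(v) <- paste0("s", 1:4)
  out <- knn_impute(expression_matrix(v), k = 2, max_missing_fraction = 0.3)
  expect_equal(unname(out$values["a", 3]), 1)

  # > 10% missing (2 of 10) removes the row under the default
  v2 <- matrix(1, 12, 10, dimnames = list(paste0("g", 1:12), paste0("s", 1:10)))
  v2[1, 1:2] <- NA
  out2 <- knn_impute(expression_matrix(v2), k = 3)
  expect_false("g1" %in% rownames(out2$values))

  # no missing values: identity
  m3 <- toy_matrix(matrix(rnorm(20), 4, 5))
  expect_identical(knn_impute(m3, k = 2)$values, m3$values)
  # observed entries are untouched (20% missing in the row, so relax the
  # row-drop threshold to keep it)
  v4 <- matrix(rnorm(60), 12, 5,
               dimnames = list(paste0("g", 1:12), paste0("s", 1:5)))
  v4[2, 3] <- NA
  out4 <- knn_impute(expression_matrix(v4), k = 3, max_missing_fraction = 0.3)
  expect_identical(out4$values[-2, ], v4[-2, ])
  expect_identical(out4$values[2, -3], v4[2, -3])
  expect_error(knn_impute(expression_matrix(v4), k = 50,
                          max_missing_fraction = 0.3), "complete rows")
})

test_that("read_gmt parses, de-duplicates members and rejects bad input", {
  f <- write_lines_tmp(c("S1\tdesc\tA\tB\tA", "S2\tdesc\tC"))
  coll <- read_gmt(f)
  expect_named(coll, c("S1", "S2"))
  expect_setequal(coll$S1, c("A", "B"))
  expect_error(read_gmt(write_lines_tmp("S1\tdesc")), "no members")
  expect_error(read_gmt(write_lines_tmp(c("S1\td\tA", "S1\td\tB"))),
               "duplicate")
})

test_that("expression round-trips through TSV with design and severity", {
  set.seed(4)
  v <- matrix(rnorm(12), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  m <- expression_matrix(v, group = rep(c("case", "control"), 2),
                         severity = list(mmse = 1:4))
  f <- tempfile(fileext = ".tsv")
  write_expression(m, f)
  back <- read_expression(f)
  expect_equal(back$values, v)
})
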