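test_that("Pajek reader transcribes vertices and edges, symmetrizes arcs, drops loops", {
  f <- write_pajek_lines(c("*Vertices 3", '1 "a"', '2 "b"', '3 "c"',
                           "*Edges", "1 2", "2 3"))
  g <- read_pajek(f)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::gsize(g), 2)
  expect_equal(igraph::V(g)$name, c("1", "2", "3"))

  f2 <- write_pajek_lines(c("*Vertices 2", '1 "a"', '2 "b"',
                            "*Arcs", "1 2", "2 1"))
  g2 <- suppressMessages(read_pajek(f2))
  expect_false(igraph::is_directed(g2))
  expect_equal(igraph::gsize(g2), 1)

  f3 <- write_pajek_lines(c("*Vertices 3", '1 "a"', '2 "b"', '3 "c"',
                            "*Edges", "1 1", "1 2", "2 3"))
  expect_message(g3 <- read_pajek(f3), "self-loop")
  expect_equal(igraph::gsize(g3), 2)
  expect_equal(sum(igraph::which_loop(g3)), 0)
})

test_that("Pajek reader rejects malformed headers and warns on disconnection", {
  f <- write_pajek_lines(c("vertices 2", "1", "2"))
  expect_error(read_pajek(f), "line 1")
  f2 <- write_pajek_lines(c("*Vertices 4", '1 "a"', '2 "b"', '3 "c"', '4 "d"',
                            "*Edges", "1 2"))
  expect_warning(read_pajek(f2), "disconnected")
})

test_that("Pajek writer round-trips a network", {
  g <- study_net()
  f <- tempfile(fileext = ".net")
  write_pajek(g, f)
  g2 <- read_pajek(f)
  expect_equal(igraph::vcount(g2), igraph::vcount(g))
  norm_edges <- function(x) {
    e <- as.data.frame(as_edge_tibble(x))
    e <- data.frame(a = pmin(e$source, e$target), b = pmax(e$source, e$target))
    e[order(e$a, e$b), ]
  }
  expect_equal(norm_edges(g2), norm_edges(g), ignore_attr = TRUE)
})

test_that("the study modification swaps exactly one edge and keeps the constraints", {
  g <- study_net()
  mod <- apply_study_modification(g)
  expect_equal(igraph::gsize(mod), igraph::gsize(g))
  expect_false(igraph::are_adjacent(mod, "10", "30"))
  expect_true(igraph::are_adjacent(mod, "2", "17"))
  dm <- distance_matrix(mod)
  expect_true(all(rowSums(dm == 1) >= 2))
  expect_true(all(rowSums(dm == 4) >= 2))
  # not idempotent: the edge {10,30} is already gone
  expect_error(apply_study_modification(mod), "\\{10,30\\}")
})

test_that("the study modification validates its preconditions", {
  g <- igraph::make_ring(5)
  igraph::V(g)$name <- as.character(1:5)
  expect_error(apply_study_modification(g), "required node")
})

test_that("constrained generator satisfies circle-size constraints deterministically", {
  g <- generate_constrained_network(31, seed = 1)
  dm <- distance_matrix(g)
  expect_true(all(rowSums(dm == 1) >= 2))
  expect_true(all(rowSums(dm == 4) >= 2))
  expect_gte(attr(dm, "diameter"), 4)
  g2 <- generate_constrained_network(31, seed = 1)
  expect_identical(igraph::as_edgelist(g), igraph::as_edgelist(g2))
  g3 <- generate_constrained_network(31, seed = 2)
  expect_false(identical(igraph::as_edgelist(g), igraph::as_edgelist(g3)))
  expect_error(generate_constrained_network(5, seed = 1), "at least 10")
})

test_that("distance matrix matches hand examples and a Floyd-Warshall oracle", {
  path <- igraph::make_graph(~ A - B - C)
  dm <- distance_matrix(path)
  expect_equal(dm["A", "C"], 2)
  expect_equal(attr(dm, "diameter"), 2)

  k4 <- igraph::make_full_graph(4)
  dm4 <- distance_matrix(k4)
  expect_true(all(dm4[upper.tri(dm4)] == 1))
  expect_equal(attr(dm4, "diameter"), 1)

  expect_error(distance_matrix(igraph::make_empty_graph(3, directed = FALSE)), "disconnected")

  floyd_warshall <- function(adj) {
    n <- nrow(adj)
    d <- matrix(Inf, n, n)
    d[adj == 1] <- 1
    diag(d) <- 0
    for (k in 1:n) for (i in 1:n) for (j in 1:n) {
      if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
    }
    d
  }
  set.seed(11)
  for (rep in 1:5) {
    g <- random_connected_graph(sample(5:12, 1))
    adj <- as.matrix(igraph::as_adjacency_matrix(g))
    expect_equal(unname(distance_matrix(g)) + 0, floyd_warshall(adj),
                 ignore_attr = TRUE)
  }
})

test_that("path Laplacians follow the definition on forced examples", {
  path <- igraph::make_graph(~ A - B - C)
  dm <- distance_matrix(path)
  L2 <- path_laplacian(dm, 2)
  expect_equal(unname(L2), rbind(c(1, 0, -1), c(0, 0, 0), c(-1, 0, 1)))
  L1 <- path_laplacian(dm, 1)
  expect_equal(unname(L1), rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1)))

  k3 <- igraph::make_full_graph(3)
  dm3 <- distance_matrix(k3)
  expect_error(path_laplacian(dm3, 2), "\\[1, 1\\]")
})

test_that("Laplacian family identities hold on random connected graphs", {
  set.seed(21)
  for (rep in 1:10) {
    g <- random_connected_graph(sample(8:20, 1))
    laps <- path_laplacians(g)
    n <- laps$n
    S <- Reduce(`+`, laps$laplacians)
    expect_lt(max(abs(S - (n * diag(n) - matrix(1, n, n)))), 1e-12)
    for (L in laps$laplacians) {
      expect_lt(max(abs(rowSums(L))), 1e-12)
      expect_equal(L, t(L))
      expect_gte(min(eigen(L, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
    }
  }
})

test_that("study-like fixture has the experiment's geometry", {
  g <- study_net()
  expect_equal(igraph::vcount(g), 31)
  dm <- distance_matrix(g)
  expect_equal(attr(dm, "diameter"), 5)
  for (d in 1:4) expect_true(all(rowSums(dm == d) >= 2))
  expect_true(igraph::are_adjacent(g, "10", "30"))
  expect_false(igraph::are_adjacent(g, "2", "17"))
})
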