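#' Read a social network from a Pajek .net file
#'
#' Reads the `*Vertices` and `*Edges`/`*Arcs` sections of a Pajek file into an
#' undirected simple graph. Arcs are symmetrized (an arc in each direction
#' collapses to one edge), self-loops and duplicate edges are dropped with a
#' message, and nodes are labelled `1..n` in the order the file declares them,
#' matching the 1-based vertex numbering Pajek uses.
#'
#' @param path Path to a Pajek `.net` file.
#' @return An [igraph::igraph] object with character vertex names `"1".."n"`.
#'   A warning is issued (not an error) if the graph is disconnected;
#'   connectivity is enforced by the diffusion functions, not the reader.
#' @export
#' @examples
#' f <- tempfile(fileext = ".net")
#' writeLines(c("*Vertices 3", "1 \"a\"", "2 \"b\"", "3 \"c\"",
#'              "*Edges", "1 2", "2 3"), f)
#' g <- read_pajek(f)
#' igraph::gsize(g)
read_pajek <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Pajek file not found: ", path))
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!grepl("^\\s*\\*vertices", first, ignore.case = TRUE)) {
    abort(paste0(
      "Malformed Pajek header at line 1 (expected '*Vertices <n>'): ",
      sQuote(trimws(first))
    ))
  }
  g <- tryCatch(
    igraph::read_graph(path, format = "pajek"),
    error = function(e) abort(paste0("Failed to parse Pajek file: ", conditionMessage(e)))
  )
  n_loops <- sum(igraph::which_loop(g))
  multi <- igraph::any_multiple(igraph::as_undirected(g, mode = "each"))
  g <- igraph::as_undirected(g, mode = "collapse")
  g <- igraph::simplify(g, remove.loops = TRUE, remove.multiple = TRUE)
  if (n_loops > 0) inform(paste0("Dropped ", n_loops, " self-loop(s) from Pajek file."))
  if (multi) inform("Collapsed duplicate/reciprocal edges to simple undirected edges.")
  igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  if (!igraph::is_connected(g)) {
    warn("Graph read from Pajek file is disconnected; diffusion computations will refuse it.")
  }
  g
}

#' Write a social network to a Pajek .net file
#'
#' @param net An igraph object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pajek <- function(net, path) {
  stopifnot(igraph::is_igraph(net))
  n <- igraph::vcount(net)
  el <- igraph::as_edgelist(net, names = FALSE)
  lines <- c(
    paste0("*Vertices ", n),
    paste0(seq_len(n), " \"", node_labels(net), "\""),
    "*Edges",
    paste(el[, 1], el[, 2])
  )
  writeLines(lines, path)
  invisible(path)
}

node_labels <- function(net) {
  nm <- igraph::V(net)$name
  if (is.null(nm)) as.character(seq_len(igraph::vcount(net))) else nm
}

node_index <- function(net, label) {
  match(as.character(label), node_labels(net))
}

#' Edge list of a social network as a tibble
#'
#' @param net An igraph object.
#' @return A tibble with columns `source` and `target` (integer node labels).
#' @export
as_edge_tibble <- function(net) {
  el <- igraph::as_edgelist(net, names = TRUE)
  tibble(source = as.integer(el[, 1]), target = as.integer(el[, 2]))
}

#' Apply the study's one-edge network modification
#'
#' The friendship network used in the consensus experiment was adjusted so
#' that every node had at least two nodes at distance one and two at distance
#' four: the edge between nodes 10 and 30 was removed and an edge between
#' nodes 2 and 17 was added. This applies exactly that modification, keeping
#' the edge count unchanged.
#'
#' @param net An igraph object containing nodes labelled 2, 10, 17 and 30,
#'   with edge \{10,30\} present and edge \{2,17\} absent.
#' @return A modified copy of `net`.
#' @export
apply_study_modification <- function(net) {
  stopifnot(igraph::is_igraph(net))
  labs <- node_labels(net)
  need <- c("2", "10", "17", "30")
  missing_nodes <- setdiff(need, labs)
  if (length(missing_nodes) > 0) {
    abort(paste0("Network lacks required node(s): ", paste(missing_nodes, collapse = ", ")))
  }
  if (!igraph::are_adjacent(net, "10", "30")) {
    abort("Edge {10,30} is absent; the study modification removes it and cannot be applied.")
  }
  if (igraph::are_adjacent(net, "2", "17")) {
    abort("Edge {2,17} is already present; the study modification adds it and cannot be applied.")
  }
  out <- igraph::delete_edges(net, igraph::get_edge_ids(net, c("10", "30")))
  igraph::add_edges(out, c(node_index(net, 2), node_index(net, 17)))
}

# Count, for every node, how many nodes sit at each exact shortest-path
# distance named in `req` (a named vector like c(`1` = 2, `4` = 2)); TRUE if
# all constraints hold.
distance_constraints_hold <- function(dist, req) {
  ds <- as.integer(names(req))
  for (i in seq_along(ds)) {
    cnt <- rowSums(dist == ds[i])
    if (any(cnt < req[i])) return(FALSE)
  }
  TRUE
}

#' Generate a random network with prescribed influence-circle sizes
#'
#' Builds a connected simple graph in which every node has at least
#' `min_at_distance[d]` nodes at shortest-path distance `d` (by default, two
#' at distance one and two at distance four, the property the experimental
#' network was adjusted to satisfy) and diameter at least `min_diameter`.
#' The graph is grown from a random circular backbone (which guarantees
#' connectivity) plus randomly rewired chord edges; chord sets are resampled
#' until the distance constraints hold, up to `max_tries` attempts.
#'
#' @param n Number of nodes (at least 10).
#' @param seed Integer seed; identical `(n, seed)` give identical edge sets.
#' @param n_chords Number of random chord edges added to the backbone.
#' @param min_at_distance Named integer vector: minimum number of nodes
#'   required at each exact distance, e.g. `c("1" = 2, "4" = 2)`.
#' @param min_diameter Minimum network diameter.
#' @param max_tries Bound on constraint-resampling attempts.
#' @return An igraph object with nodes labelled `"1".."n"`.
#' @export
#' @examples
#' g <- generate_constrained_network(31, seed = 1)
#' igraph::vcount(g)
generate_constrained_network <- function(n, seed,
                                         n_chords = max(2L, round(n / 4)),
                                         min_at_distance = c("1" = 2, "4" = 2),
                                         min_diameter = 4,
                                         max_tries = 200L) {
  if (n < 10) {
    abort("n must be at least 10: the distance-4 circle constraint is unreachable on smaller graphs.")
  }
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      g <- random_backbone_graph(n, n_chords)
      dm <- igraph::distances(g)
      if (max(dm) >= min_diameter && distance_constraints_hold(dm, min_at_distance)) {
        return(g)
      }
    }
    abort(paste0(
      "Could not satisfy distance constraints in ", max_tries,
      " attempts (n = ", n, "); relax min_at_distance or increase max_tries."
    ))
  })
}

# One raw draw: a random cycle backbone (guaranteeing connectivity) plus
# `n_chords` random chord edges. Uses the current RNG state.
random_backbone_graph <- function(n, n_chords) {
  perm <- sample.int(n)
  backbone <- cbind(perm, c(perm[-1], perm[1]))
  avail <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  on_cycle <- (abs(match(avail[, 1], perm) - match(avail[, 2], perm)) %in% c(1L, n - 1L))
  avail <- avail[!on_cycle, , drop = FALSE]
  k <- min(n_chords, nrow(avail))
  chords <- avail[sample.int(nrow(avail), k), , drop = FALSE]
  g <- igraph::simplify(
    igraph::graph_from_edgelist(rbind(backbone, unname(chords)), directed = FALSE)
  )
  igraph::V(g)$name <- as.character(seq_len(n))
  g
}

#' Generate a study-like fixture network
#'
#' A 31-node constrained network (see [generate_constrained_network()]) with
#' the geometry of the experimental friendship network: diameter exactly
#' `diameter` (the study network has D = 5) and at least two nodes in every
#' circle of influence up to distance 4 for every node (so each of the four
#' informational settings can display two peers at its distance). The network
#' additionally satisfies the preconditions of [apply_study_modification()]
#' (edge \{10,30\} present, edge \{2,17\} absent) and keeps all of these
#' properties after that modification. This is a synthetic stand-in for the
#' experiment's friendship network, which is not bundled with the package.
#'
#' @param seed Integer seed.
#' @param n Number of nodes; defaults to the study's 31.
#' @param diameter Required network diameter (before and after the
#'   modification).
#' @param max_tries Bound on candidate networks examined.
#' @return An igraph object.
#' @export
study_like_network <- function(seed, n = 31, diameter = 5, max_tries = 20000L) {
  req <- c("1" = 2, "2" = 2, "3" = 2, "4" = 2)
  chord_choices <- 14:18
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      g <- random_backbone_graph(n, chord_choices[1L + (try %% length(chord_choices))])
      if (igraph::are_adjacent(g, "2", "17")) {
        g <- igraph::delete_edges(g, igraph::get_edge_ids(g, c("2", "17")))
      }
      if (!igraph::are_adjacent(g, "10", "30")) {
        g <- igraph::add_edges(g, c(node_index(g, 10), node_index(g, 30)))
      }
      if (!igraph::is_connected(g)) next
      dm <- igraph::distances(g)
      if (max(dm) != diameter || !distance_constraints_hold(dm, req)) next
      mod <- tryCatch(apply_study_modification(g), error = function(e) NULL)
      if (is.null(mod) || !igraph::is_connected(mod)) next
      dmm <- igraph::distances(mod)
      if (max(dmm) == diameter && distance_constraints_hold(dmm, req)) {
        return(g)
      }
    }
    abort("Could not build a study-like network within the attempt budget.")
  })
}

#' Shortest-path distance matrix
#'
#' All-pairs shortest-path (BFS) distances of a connected graph. The network
#' diameter `D` is the maximum entry and is attached as attribute
#' `"diameter"`.
#'
#' @param net A connected igraph object.
#' @return An integer matrix with dimnames equal to the node labels and
#'   attribute `diameter`.
#' @export
distance_matrix <- function(net) {
  stopifnot(igraph::is_igraph(net))
  if (!igraph::is_connected(net)) {
    abort("Network is disconnected: shortest-path distances are infinite.")
  }
  dm <- igraph::distances(net)
  storage.mode(dm) <- "integer"
  dimnames(dm) <- list(node_labels(net), node_labels(net))
  attr(dm, "diameter") <- max(dm)
  dm
}

#' d-path Laplacian matrix
#'
#' The Laplacian of the graph whose edges join node pairs at shortest-path
#' distance exactly `d` in the original network: off-diagonal entries are -1
#' where `dist(i,j) == d` and 0 otherwise; the diagonal holds the number of
#' nodes in node i's d-th circle of influence. `path_laplacian(dist, 1)` is
#' the ordinary graph Laplacian.
#'
#' @param dist A distance matrix from [distance_matrix()].
#' @param d Circle index, between 1 and the network diameter.
#' @return A symmetric positive semidefinite numeric matrix with zero row sums.
#' @export
path_laplacian <- function(dist, d) {
  D <- attr(dist, "diameter") %||% max(dist)
  if (length(d) != 1 || d < 1 || d > D) {
    abort(paste0("d must lie in [1, ", D, "] (network diameter), got ", d, "."))
  }
  A <- (dist == d) * 1
  diag(A) <- 0
  L <- -A
  diag(L) <- rowSums(A)
  L
}

#' The full family of d-path Laplacians of a network
#'
#' @param net A connected igraph object.
#' @return An object of class `path_laplacian_set`: a list with `laplacians`
#'   (list of matrices `L_1 .. L_D`), the `distance` matrix, node count `n`
#'   and `diameter`.
#' @export
#' @examples
#' laps <- path_laplacians(igraph::make_ring(10))
#' laps$diameter
path_laplacians <- function(net) {
  dist <- distance_matrix(net)
  D <- attr(dist, "diameter")
  laps <- lapply(seq_len(D), function(d) path_laplacian(dist, d))
  structure(
    list(
      laplacians = laps,
      distance = dist,
      n = nrow(dist),
      diameter = D
    ),
    class = "path_laplacian_set"
  )
}

#' @export
print.path_laplacian_set <- function(x, ...) {
  cat("<path_laplacian_set> n =", x$n, ", diameter D =", x$diameter, "\n")
  invisible(x)
}
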