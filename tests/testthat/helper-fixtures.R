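# Shared fixtures, built once per test run.

`%||%` <- function(x, y) if (is.null(x)) y else x

fixture_env <- new.env(parent = emptyenv())

# The 31-node synthetic stand-in for the experimental friendship network
# (diameter 5, two peers in every circle up to distance 4), cached because
# its construction searches many candidate graphs.
study_net <- function() {
  if (is.null(fixture_env$net)) fixture_env$net <- study_like_network(42)
  fixture_env$net
}

study_laps <- function() {
  if (is.null(fixture_env$laps)) fixture_env$laps <- path_laplacians(study_net())
  fixture_env$laps
}

# A small Pajek file written on the fly.
write_pajek_lines <- function(lines) {
  f <- tempfile(fileext = ".net")
  writeLines(lines, f)
  f
}

# Random connected graph via the package-independent route: Erdos-Renyi
# draws, retried until connected.
random_connected_graph <- function(n, p = 0.3) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) {
      igraph::V(g)$name <- as.character(seq_len(n))
      return(g)
    }
  }
}

# Minimal hand-built round records (one setting) for payoff/stubborn tests:
# `colors` is a rounds x nodes logical matrix of innovation choices.
manual_records <- function(colors, roles = NULL, active = NULL,
                           consensus_round = NA_integer_, setting = "I") {
  r <- nrow(colors)
  n <- ncol(colors)
  roles <- roles %||% rep("human", n)
  active <- active %||% matrix(TRUE, r, n)
  rec <- dplyr::bind_rows(lapply(seq_len(r), function(i) {
    tibble::tibble(
      session_id = 1L, setting = setting, display_distance = NA_integer_,
      round = i, node = seq_len(n), role = roles, active = active[i, ],
      chose_innovation = colors[i, ],
      color = ifelse(colors[i, ], "blue", "yellow"),
      f_direct = NA_real_, f_distant = NA_real_,
      d1 = NA_integer_, d2 = NA_integer_, k1 = NA_integer_, k2 = NA_integer_,
      d1_innov = NA, d2_innov = NA, k1_innov = NA, k2_innov = NA
    )
  }))
  structure(rec, consensus_round = consensus_round, max_rounds = r, n = n)
}

# Synthetic decision table with a planted logistic signal on the features.
planted_decision_table <- function(n_rows, weights, seed, setting = "II") {
  set.seed(seed)
  f_initial <- as.numeric(runif(n_rows) < 0.15)
  f_direct <- sample(c(0, 0.5, 1), n_rows, replace = TRUE)
  f_distant <- if (setting == "I") rep(0, n_rows) else sample(c(0, 0.5, 1), n_rows, replace = TRUE)
  shown_innov <- 2 * f_direct + ifelse(setting == "I", 0, 2 * f_distant)
  n_shown <- ifelse(setting == "I", 2, 4)
  eta <- weights[1] * f_initial + weights[2] * (shown_innov > n_shown / 2) +
    weights[3] * f_direct + weights[4] * f_distant + weights[5]
  label <- runif(n_rows) < stats::plogis(eta)
  tibble::tibble(
    session_id = 1L, setting = setting, node = seq_len(n_rows), round = 2L,
    chose_innovation = label,
    f_initial = f_initial,
    f_majority = as.numeric(shown_innov > n_shown / 2),
    f_direct = f_direct, f_distant = f_distant
  )
}
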