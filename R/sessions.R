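#' Informational setting specification
#'
#' The experiment's four informational treatments: in every setting each
#' participant is shown the colours of two of their direct neighbours; in
#' settings II-IV they additionally see two participants at exact graph
#' distance 2, 3 or 4 (their k-th circle of influence). Each setting uses its
#' own colour pair (minority first) and lasts at most 13-15 rounds.
#'
#' @param index Setting index: `"I"`, `"II"`, `"III"` or `"IV"`.
#' @param max_rounds Maximum number of rounds, between 13 and 15.
#' @return A list with fields `index`, `display_distance` (NA for setting I),
#'   `colors` (minority, majority) and `max_rounds`.
#' @export
setting_spec <- function(index = c("I", "II", "III", "IV"), max_rounds = 15L) {
  index <- arg_match(index)
  if (max_rounds < 13 || max_rounds > 15) abort("max_rounds must lie in [13, 15].")
  colors <- switch(index,
    I   = c("blue", "yellow"),
    II  = c("magenta", "green"),
    III = c("orange", "red"),
    IV  = c("purple", "lilac")
  )
  list(
    index = index,
    display_distance = switch(index, I = NA_integer_, II = 2L, III = 3L, IV = 4L),
    colors = colors,
    max_rounds = as.integer(max_rounds)
  )
}

#' Behavioural parameters of the simulated human choice rule
#'
#' A simulated participant who has not yet adopted the innovation adopts it in
#' a round with probability `plogis(alpha * f_direct + beta * f_distant +
#' gamma * adopted - theta)`, where `f_direct` and `f_distant` are the
#' fractions of displayed direct and distance-k peers showing the innovation
#' colour. `theta` sets the spontaneous switching rate, `alpha` the
#' responsiveness to direct peers and `beta` to indirect (distance-k) peers.
#'
#' @param alpha Weight on the displayed direct-neighbour innovation fraction.
#' @param beta Weight on the displayed distance-k innovation fraction.
#' @param gamma Weight on the participant's own adopter status (only relevant
#'   when `cumulative = FALSE`).
#' @param theta Adoption resistance (logistic intercept).
#' @param cumulative Once a participant adopts, they never revert (default).
#' @param dropout Per-round probability that a human seat is inactive and is
#'   replaced by a bot for that round.
#' @return A list of class `behavior_spec`.
#' @export
behavior_spec <- function(alpha = 2.5, beta = 1.5, gamma = 2, theta = 1.8,
                          cumulative = TRUE, dropout = 0) {
  if (dropout < 0 || dropout > 1) abort("dropout must be a probability.")
  structure(
    list(alpha = alpha, beta = beta, gamma = gamma, theta = theta,
         cumulative = cumulative, dropout = dropout),
    class = "behavior_spec"
  )
}

#' Initial colour assignment of a session
#'
#' Assigns the innovation (minority) colour to `n_minority` nodes chosen
#' uniformly at random, mirroring the experiment's initialisation of 4 early
#' adopters among 31 participants (13%).
#'
#' @param net The session network (igraph).
#' @param n_minority Number of initial adopters (default 4).
#' @param seed Integer seed; the assignment is deterministic per seed.
#' @return Named integer vector (1 = innovation, 0 = tradition) in node order.
#' @export
initialize_session <- function(net, n_minority = 4, seed = NULL) {
  n <- igraph::vcount(net)
  if (n_minority < 1) abort("n_minority must be at least 1: there is no innovation to diffuse.")
  if (n_minority >= n) abort("n_minority must be smaller than the number of nodes.")
  with_seed(seed, {
    u0 <- integer(n)
    u0[sample.int(n, n_minority)] <- 1L
    setNames(u0, node_labels(net))
  })
}

#' Assign displayed peers for a setting
#'
#' For every node, samples without replacement the two direct neighbours and
#' (settings II-IV) the two distance-k nodes whose colours the participant
#' will be shown. The sample is drawn once per setting and held fixed across
#' rounds; the colours displayed are refreshed every round.
#'
#' @param net The session network.
#' @param dist Distance matrix from [distance_matrix()].
#' @param setting A [setting_spec()] (or its index string).
#' @param seed Integer seed.
#' @return A tibble with columns `node`, `d1`, `d2` (direct peers) and `k1`,
#'   `k2` (distance-k peers, NA in setting I), all integer node labels.
#' @export
assign_displays <- function(net, dist, setting, seed = NULL) {
  if (is.character(setting)) setting <- setting_spec(setting)
  labs <- as.integer(node_labels(net))
  k <- setting$display_distance
  with_seed(seed, {
    pick <- function(i, d) {
      cand <- labs[dist[i, ] == d]
      if (length(cand) < 2) {
        abort(paste0("Node ", labs[i], " has fewer than 2 nodes at distance ", d, "."))
      }
      sample(cand, 2)
    }
    direct <- t(vapply(seq_along(labs), pick, integer(2), d = 1L))
    if (is.na(k)) {
      distant <- matrix(NA_integer_, nrow = length(labs), ncol = 2)
    } else {
      distant <- t(vapply(seq_along(labs), pick, integer(2), d = k))
    }
    tibble(
      node = labs,
      d1 = as.integer(direct[, 1]), d2 = as.integer(direct[, 2]),
      k1 = as.integer(distant[, 1]), k2 = as.integer(distant[, 2])
    )
  })
}

#' Bot colour choice
#'
#' An inactive participant's seat is played by a bot which, with probability
#' 1/2, picks a colour uniformly at random and otherwise follows the majority
#' of the colours it is shown (ties broken uniformly at random). Draws from
#' the current RNG state.
#'
#' @param displayed_innovation Logical vector: displayed colours,
#'   TRUE = innovation.
#' @return Logical scalar: TRUE if the bot chooses the innovation colour.
#' @export
bot_decision <- function(displayed_innovation) {
  if (length(displayed_innovation) == 0) abort("A bot must be shown at least one colour.")
  if (runif(1) < 0.5) {
    runif(1) < 0.5
  } else {
    n_innov <- sum(displayed_innovation)
    n_trad <- sum(!displayed_innovation)
    if (n_innov == n_trad) runif(1) < 0.5 else n_innov > n_trad
  }
}

#' Simulate one experimental setting
#'
#' Runs a round-based colour-consensus game on the network: every round each
#' seat observes the previous-round colours of its displayed peers and makes
#' a simultaneous choice (humans via the logistic rule in [behavior_spec()],
#' stubborn agents keep their colour, bots follow the 50/50 policy). The
#' setting ends at global consensus or after `max_rounds` rounds.
#'
#' @param net The session network.
#' @param setting A [setting_spec()] or its index string.
#' @param init Initial colours from [initialize_session()].
#' @param seed Integer seed governing all choices in the setting.
#' @param behavior A [behavior_spec()].
#' @param stubborn_nodes Integer labels of agents that never change colour.
#' @param bot_nodes Integer labels of seats played by a bot in every round.
#' @param dist Optional precomputed [distance_matrix()].
#' @param displays Optional precomputed [assign_displays()] table.
#' @param resample_displays Redraw the displayed peers every round instead of
#'   holding them fixed.
#' @param session_id Identifier recorded on every row.
#' @return A tibble of round records (one row per seat per round) with
#'   attributes `consensus_round` (NA if consensus was never declared),
#'   `max_rounds` and `n`. Columns include the seat's role and activity flag,
#'   its colour choice (`chose_innovation` plus the cosmetic colour label) and
#'   the displayed peers and the innovation fractions `f_direct`/`f_distant`
#'   it saw when deciding (NA in round 1, which records the assignment).
#' @export
simulate_setting <- function(net, setting, init, seed = NULL,
                             behavior = behavior_spec(),
                             stubborn_nodes = NULL, bot_nodes = NULL,
                             dist = NULL, displays = NULL,
                             resample_displays = FALSE,
                             session_id = 1L) {
  spec <- if (is.character(setting)) setting_spec(setting) else setting
  if (is.null(dist)) dist <- distance_matrix(net)
  labs <- as.integer(node_labels(net))
  n <- length(labs)
  if (length(init) != n || !all(init %in% c(0, 1))) {
    abort("init must be a binary vector with one entry per node.")
  }
  stubborn_nodes <- as.integer(stubborn_nodes)
  bot_nodes <- as.integer(bot_nodes)
  if (length(intersect(stubborn_nodes, bot_nodes)) > 0) {
    abort("A seat cannot be both stubborn and a bot.")
  }
  role <- rep("human", n)
  role[match(stubborn_nodes, labs)] <- "stubborn"
  role[match(bot_nodes, labs)] <- "bot"

  seeds <- derive_seeds(seed %||% sample.int(.Machine$integer.max - 1L, 1), 2L)
  if (is.null(displays)) displays <- assign_displays(net, dist, spec, seed = seeds[1])

  with_seed(seeds[2], {
    state <- as.logical(init)            # TRUE = innovation colour
    adopted <- state                     # cumulative adopter flag
    rows <- vector("list", spec$max_rounds)
    rows[[1]] <- tibble(
      session_id = session_id, setting = spec$index,
      display_distance = spec$display_distance, round = 1L,
      node = labs, role = role, active = role != "bot",
      chose_innovation = state,
      color = ifelse(state, spec$colors[1], spec$colors[2]),
      f_direct = NA_real_, f_distant = NA_real_,
      d1 = displays$d1, d2 = displays$d2, k1 = displays$k1, k2 = displays$k2,
      d1_innov = NA, d2_innov = NA, k1_innov = NA, k2_innov = NA
    )
    consensus_round <- if (all(state) || all(!state)) 1L else NA_integer_
    r <- 1L
    while (is.na(consensus_round) && r < spec$max_rounds) {
      r <- r + 1L
      if (resample_displays) {
        displays <- assign_displays(net, dist, spec,
                                    seed = seeds[1] + r - 1L)
      }
      prev <- state
      idx <- function(v) match(v, labs)
      shown_d <- cbind(prev[idx(displays$d1)], prev[idx(displays$d2)])
      has_k <- !is.na(spec$display_distance)
      shown_k <- if (has_k) cbind(prev[idx(displays$k1)], prev[idx(displays$k2)]) else
        matrix(NA, n, 2)
      f_direct <- rowMeans(shown_d)
      f_distant <- if (has_k) rowMeans(shown_k) else rep(0, n)
      active <- role != "bot" & runif(n) >= behavior$dropout
      new_state <- logical(n)
      for (i in seq_len(n)) {
        if (!active[i]) {
          shown <- c(shown_d[i, ], if (has_k) shown_k[i, ])
          new_state[i] <- bot_decision(shown)
        } else if (role[i] == "stubborn") {
          new_state[i] <- prev[i]
        } else if (behavior$cumulative && adopted[i]) {
          new_state[i] <- TRUE
        } else {
          p <- stats::plogis(behavior$alpha * f_direct[i] +
                             behavior$beta * f_distant[i] +
                             behavior$gamma * adopted[i] - behavior$theta)
          new_state[i] <- runif(1) < p
        }
      }
      state <- new_state
      adopted <- adopted | state
      rows[[r]] <- tibble(
        session_id = session_id, setting = spec$index,
        display_distance = spec$display_distance, round = r,
        node = labs, role = role, active = active,
        chose_innovation = state,
        color = ifelse(state, spec$colors[1], spec$colors[2]),
        f_direct = f_direct,
        f_distant = ifelse(rep(has_k, n), f_distant, NA_real_),
        d1 = displays$d1, d2 = displays$d2, k1 = displays$k1, k2 = displays$k2,
        d1_innov = shown_d[, 1], d2_innov = shown_d[, 2],
        k1_innov = shown_k[, 1], k2_innov = shown_k[, 2]
      )
      if (all(state) || all(!state)) consensus_round <- r
    }
    records <- dplyr::bind_rows(rows[!vapply(rows, is.null, logical(1))])
    structure(records,
      consensus_round = consensus_round,
      max_rounds = spec$max_rounds,
      n = n
    )
  })
}

#' Simulate a full experimental session (settings I-IV)
#'
#' Each setting is initialised afresh (the experiment used a different colour
#' pair per setting) with `n_minority` adopters, a per-setting round cap drawn
#' uniformly from 13-15, and its own derived seed.
#'
#' @param net The session network.
#' @param seed Master seed for the session.
#' @param settings Character vector of setting indices to run.
#' @param n_minority Initial adopters per setting.
#' @param behavior A [behavior_spec()].
#' @param n_stubborn Number of stubborn agents per setting (drawn among
#'   initially-traditional seats); a vector is recycled over `settings`.
#' @param bot_nodes Seats played by bots throughout.
#' @param session_id Identifier recorded on every row.
#' @return A tibble of round records for all settings, with attribute
#'   `consensus_rounds` (named by setting).
#' @export
simulate_session <- function(net, seed, settings = c("I", "II", "III", "IV"),
                             n_minority = 4, behavior = behavior_spec(),
                             n_stubborn = 0, bot_nodes = NULL,
                             session_id = 1L) {
  dist <- distance_matrix(net)
  seeds <- derive_seeds(seed, 3L * length(settings))
  n_stubborn <- rep_len(n_stubborn, length(settings))
  out <- vector("list", length(settings))
  consensus <- setNames(rep(NA_integer_, length(settings)), settings)
  for (j in seq_along(settings)) {
    s3 <- seeds[(3 * j - 2):(3 * j)]
    max_rounds <- with_seed(s3[1], sample(13:15, 1))
    init <- initialize_session(net, n_minority, seed = s3[2])
    stubborn <- integer(0)
    if (n_stubborn[j] > 0) {
      trad <- as.integer(names(init))[init == 0]
      stubborn <- with_seed(s3[2] + 1L, sample(trad, n_stubborn[j]))
    }
    rec <- simulate_setting(
      net, setting_spec(settings[j], max_rounds = max_rounds), init,
      seed = s3[3], behavior = behavior, stubborn_nodes = stubborn,
      bot_nodes = bot_nodes, dist = dist, session_id = session_id
    )
    consensus[j] <- attr(rec, "consensus_round")
    out[[j]] <- rec
  }
  structure(dplyr::bind_rows(out), consensus_rounds = consensus)
}

#' Cumulative adopter curve of observed session records
#'
#' A seat counts as an adopter at round k if it displayed the innovation
#' colour in any round up to k. All seats (humans, bots, stubborn) are
#' included, matching how the experimental curves were computed.
#'
#' @param records Round records from [simulate_setting()] or read from file.
#' @param pad_to Optionally pad each curve to this length, repeating the final
#'   proportion (sessions that reached consensus early hold their flat tail).
#' @return A tibble with columns `session_id`, `setting`, `round`,
#'   `proportion`.
#' @export
observed_curve <- function(records, pad_to = NULL) {
  curve <- records |>
    dplyr::group_by(.data$session_id, .data$setting, .data$node) |>
    dplyr::arrange(.data$round, .by_group = TRUE) |>
    dplyr::mutate(adopted = cummax(.data$chose_innovation)) |>
    dplyr::group_by(.data$session_id, .data$setting, .data$round) |>
    dplyr::summarise(proportion = mean(.data$adopted), .groups = "drop")
  if (!is.null(pad_to)) {
    curve <- curve |>
      dplyr::group_by(.data$session_id, .data$setting) |>
      dplyr::group_modify(function(df, key) {
        r <- nrow(df)
        if (r < pad_to) {
          df <- dplyr::bind_rows(df, tibble(
            round = seq(r + 1L, pad_to),
            proportion = df$proportion[r]
          ))
        }
        df
      }) |>
      dplyr::ungroup()
  }
  curve
}

#' Session payoffs
#'
#' Each participant earns 1 point per round in which they were active, plus,
#' if the setting reached consensus and they were active in at least one of
#' the last two played rounds, a bonus of 5 points per round left until round
#' 15.
#'
#' @param records Round records for one setting.
#' @return A tibble with columns `node`, `role`, `points`.
#' @export
compute_payoffs <- function(records) {
  consensus_round <- attr(records, "consensus_round")
  last_round <- max(records$round)
  if (is.null(consensus_round)) {
    final <- records[records$round == last_round, ]
    consensus_round <- if (all(final$chose_innovation) || all(!final$chose_innovation)) {
      last_round
    } else {
      NA_integer_
    }
  }
  records |>
    dplyr::group_by(.data$node, .data$role) |>
    dplyr::summarise(
      active_rounds = sum(.data$active),
      recent = any(.data$active[.data$round >= last_round - 1L]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      points = .data$active_rounds +
        ifelse(!is.na(consensus_round) & .data$recent,
               5L * (15L - consensus_round), 0L)
    ) |>
    dplyr::select("node", "role", "points")
}
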