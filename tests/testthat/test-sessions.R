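test_that("session initialisation seeds the minority deterministically", {
  net <- study_net()
  u0 <- initialize_session(net, 4, seed = 7)
  expect_equal(sum(u0), 4)
  expect_length(u0, 31)
  expect_identical(u0, initialize_session(net, 4, seed = 7))
  expect_false(identical(u0, initialize_session(net, 4, seed = 8)))
  expect_error(initialize_session(net, 0, seed = 1), "at least 1")
  expect_error(initialize_session(net, 31, seed = 1), "smaller")
})

test_that("display assignment respects the setting's distances and is reproducible", {
  net <- study_net()
  dist <- distance_matrix(net)
  d1 <- assign_displays(net, dist, "I", seed = 3)
  expect_true(all(is.na(d1$k1)) && all(is.na(d1$k2)))
  d3 <- assign_displays(net, dist, "III", seed = 3)
  for (i in seq_len(nrow(d3))) {
    expect_equal(dist[as.character(d3$node[i]), as.character(d3$d1[i])], 1)
    expect_equal(dist[as.character(d3$node[i]), as.character(d3$d2[i])], 1)
    expect_equal(dist[as.character(d3$node[i]), as.character(d3$k1[i])], 3)
    expect_equal(dist[as.character(d3$node[i]), as.character(d3$k2[i])], 3)
    expect_false(d3$d1[i] == d3$d2[i])
    expect_false(d3$k1[i] == d3$k2[i])
  }
  expect_identical(d3, assign_displays(net, dist, "III", seed = 3))

  # 4-cycle: every node has two direct neighbours but only one node at distance 2
  ring <- igraph::make_ring(4)
  igraph::V(ring)$name <- as.character(1:4)
  expect_error(
    assign_displays(ring, distance_matrix(ring), "II", seed = 1),
    "distance 2"
  )
})

test_that("bot policy mixes random choice with majority following", {
  set.seed(99)
  # all-innovation display: P(innovation) = 0.5 * 0.5 + 0.5 * 1 = 0.75
  draws <- replicate(10000, bot_decision(c(TRUE, TRUE, TRUE)))
  expect_equal(mean(draws), 0.75, tolerance = 0.02)
  # majority tradition display: P = 0.5 * 0.5 + 0.5 * 0 = 0.25
  draws2 <- replicate(10000, bot_decision(c(FALSE, FALSE, TRUE)))
  expect_equal(mean(draws2), 0.25, tolerance = 0.02)
  # tie: uniform
  draws3 <- replicate(10000, bot_decision(c(TRUE, FALSE)))
  expect_equal(mean(draws3), 0.5, tolerance = 0.02)
  expect_error(bot_decision(logical(0)), "at least one")
})

test_that("simulated settings are deterministic and respect display invariants", {
  net <- study_net()
  dist <- distance_matrix(net)
  init <- initialize_session(net, 4, seed = 5)
  rec <- simulate_setting(net, "III", init, seed = 11)
  rec2 <- simulate_setting(net, "III", init, seed = 11)
  expect_identical(as.data.frame(rec), as.data.frame(rec2))

  expect_true(all(rec$round[rec$round == 1] == 1))
  for (i in which(rec$round == 1)) {
    expect_equal(dist[as.character(rec$node[i]), as.character(rec$d1[i])], 1)
    expect_equal(dist[as.character(rec$node[i]), as.character(rec$k1[i])], 3)
  }
  # displayed colours are the peers' previous-round choices
  r2 <- rec[rec$round == 2, ]
  r1 <- rec[rec$round == 1, ]
  prev <- setNames(r1$chose_innovation, r1$node)
  expect_equal(r2$d1_innov, unname(prev[as.character(r2$d1)]))
  expect_equal(r2$k2_innov, unname(prev[as.character(r2$k2)]))
  expect_equal(r2$f_direct, (r2$d1_innov + r2$d2_innov) / 2)
})

test_that("adoption curves from sessions start at the minority share and never decrease", {
  net <- study_net()
  for (s in 1:5) {
    rec <- simulate_setting(net, "II", initialize_session(net, 4, seed = s), seed = s)
    curve <- observed_curve(rec)
    expect_equal(curve$proportion[1], 4 / 31)
    expect_true(all(diff(curve$proportion) >= 0))
  }
  rec <- simulate_setting(net, "II", initialize_session(net, 4, seed = 1), seed = 1)
  padded <- observed_curve(rec, pad_to = 15)
  expect_equal(nrow(padded), 15)
  expect_equal(padded$proportion[15], max(observed_curve(rec)$proportion))
})

test_that("a stubborn agent blocks consensus at 30/31 adopters", {
  net <- study_net()
  init <- initialize_session(net, 4, seed = 13)
  stub <- as.integer(names(init))[init == 0][1]
  rec <- simulate_setting(net, "II", init, seed = 13, stubborn_nodes = stub,
                          behavior = behavior_spec(theta = -3))
  expect_true(is.na(attr(rec, "consensus_round")))
  final <- rec[rec$round == max(rec$round), ]
  expect_equal(sum(final$chose_innovation), 30)
  expect_false(final$chose_innovation[final$node == stub])
})

test_that("a very low adoption resistance forces consensus by round 2", {
  net <- study_net()
  init <- initialize_session(net, 4, seed = 2)
  rec <- simulate_setting(net, "I", init, seed = 2,
                          behavior = behavior_spec(theta = -20))
  expect_equal(attr(rec, "consensus_round"), 2L)
})

test_that("most default sessions reach consensus within 15 rounds", {
  net <- study_net()
  reached <- vapply(1:30, function(s) {
    rec <- simulate_setting(net, "II", initialize_session(net, 4, seed = s),
                            seed = s + 300)
    !is.na(attr(rec, "consensus_round"))
  }, logical(1))
  expect_gte(mean(reached), 0.9)
})

test_that("payoffs reward active rounds plus the early-consensus bonus", {
  # consensus at round 9, active all rounds: 9 + 5 * (15 - 9) = 39
  colors <- matrix(c(rep(FALSE, 8), TRUE), nrow = 9, ncol = 4)
  colors[, 1] <- TRUE
  colors[9, ] <- TRUE
  rec <- manual_records(colors, consensus_round = 9L)
  pay <- compute_payoffs(rec)
  expect_true(all(pay$points == 39))

  # no consensus, active 13 of 13 rounds: 13 points
  colors2 <- matrix(FALSE, nrow = 13, ncol = 4)
  colors2[, 1] <- TRUE
  rec2 <- manual_records(colors2, consensus_round = NA_integer_)
  expect_true(all(compute_payoffs(rec2)$points == 13))

  # consensus at round 15: no bonus
  colors3 <- matrix(TRUE, nrow = 15, ncol = 4)
  colors3[1:14, 2] <- FALSE
  rec3 <- manual_records(colors3, consensus_round = 15L)
  expect_true(all(compute_payoffs(rec3)$points == 15))

  # inactive rounds earn nothing; bonus needs activity near the end
  active <- matrix(TRUE, 9, 4)
  active[, 2] <- FALSE
  rec4 <- manual_records(colors, active = active, consensus_round = 9L)
  pay4 <- compute_payoffs(rec4)
  expect_equal(pay4$points[pay4$node == 2], 0)
  expect_equal(pay4$points[pay4$node == 1], 39)
})

test_that("full sessions are reproducible byte-for-byte", {
  net <- study_net()
  rec <- simulate_session(net, seed = 77, settings = c("I", "II"))
  rec2 <- simulate_session(net, seed = 77, settings = c("I", "II"))
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_session_csv(rec, f1)
  write_session_csv(rec2, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_session_csv(f1)
  expect_equal(nrow(back), nrow(rec))
  expect_equal(back$chose_innovation, rec$chose_innovation)
})
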