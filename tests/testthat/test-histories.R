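test_that("histories satisfy their structural invariants", {
  set.seed(14)
  tr <- simulate_tree(6, "coalescent")
  g <- random_geo_data(tr, 3)
  Q <- build_rate_matrix(random_dense_params(3, mu = 1.5), 3)
  for (rep in 1:20) {
    h <- sample_conditional_history(tr, g, Q)
    # tip states equal the observations
    expect_equal(h$node_state[seq_len(6)],
                 unname(g$index[tr$tip.label]))
    ev <- h$events
    if (nrow(ev)) {
      expect_true(all(ev$from != ev$to))
      for (e in unique(ev$edge)) {
        br <- ev[ev$edge == e, ]
        br <- br[order(br$time), ]
        # chain consistency along the branch
        if (nrow(br) > 1)
          expect_equal(br$from[-1], br$to[-nrow(br)])
        # endpoint states match the adjacent node states
        expect_equal(br$from[1], h$node_state[br$parent[1]])
        expect_equal(br$to[nrow(br)], h$node_state[br$child[1]])
      }
    }
    # a history realizing d distinct tip areas needs >= d - 1 events
    expect_gte(n_events(h), length(unique(g$index)) - 1)
  }
})

test_that("zero-length branches with equal endpoints carry no events", {
  tr <- read_newick_tree("(A:0,B:0);")
  g <- geo_data(c(A = "x", B = "x"), areas = c("x", "y"))
  Q <- build_rate_matrix(geo_params(TRUE, 1, 1, 1), 2)
  h <- sample_conditional_history(tr, g, Q)
  expect_equal(n_events(h), 0)
})

test_that("two-state bridges have odd event parity when endpoints differ", {
  set.seed(15)
  tr <- read_newick_tree("(A:1.3,B:0.9);")
  g <- geo_data(c(A = "x", B = "y"), areas = c("x", "y"))
  Q <- build_rate_matrix(geo_params(TRUE, 1, 1, 1), 2)
  for (i in 1:25) {
    h <- sample_conditional_history(tr, g, Q)
    root <- h$node_state[3]
    for (tip in 1:2) {
      ne <- sum(h$events$child == tip)
      parity_needed <- (root != h$node_state[tip])
      expect_equal(ne %% 2 == 1, parity_needed)
    }
  }
})

test_that("uniformization agrees with the rejection-sampling oracle", {
  Q <- build_rate_matrix(geo_params(TRUE, 1, 1, 1), 2)
  t <- 1
  P <- transition_probabilities(Q, t)
  set.seed(16)
  nu <- replicate(4000, nrow(geodisp:::sample_branch_bridge(Q, t, 1, 2,
                                                            P[1, 2])))
  nr <- replicate(4000, nrow(geodisp:::sample_branch_rejection(Q, t, 1, 2)))
  se <- sqrt(var(nu) / length(nu) + var(nr) / length(nr))
  expect_lt(abs(mean(nu) - mean(nr)), 3.5 * se)
  expect_true(all(nu %% 2 == 1))
  # same-endpoint bridge: even parity
  ne <- replicate(2000, nrow(geodisp:::sample_branch_bridge(Q, t, 1, 1,
                                                            P[1, 1])))
  expect_true(all(ne %% 2 == 0))
})

test_that("sampled node states match exact conditional marginals", {
  set.seed(17)
  tr <- simulate_tree(4, "coalescent")
  g <- random_geo_data(tr, 2)
  Q <- build_rate_matrix(geo_params(TRUE, 1, 1, 0.8), 2)
  n_hist <- 3000
  hs <- sample_conditional_histories(tr, g, Q, n = n_hist)
  anc <- ancestral_area_probabilities(hs)
  # exact conditional marginal per internal node by enumeration
  n <- 4; M <- n + tr$Nnode
  internals <- seq.int(n + 1L, M)
  joint_ll <- function(states_internal) {
    st <- integer(M)
    st[1:n] <- g$index[tr$tip.label]
    st[internals] <- states_internal
    p <- 0.5
    for (e in seq_len(nrow(tr$edge))) {
      P <- transition_probabilities(Q, tr$edge.length[e])
      p <- p * P[st[tr$edge[e, 1]], st[tr$edge[e, 2]]]
    }
    p
  }
  grid <- as.matrix(expand.grid(rep(list(1:2), length(internals))))
  w <- apply(grid, 1, joint_ll)
  w <- w / sum(w)
  for (j in seq_along(internals)) {
    exact <- sum(w[grid[, j] == 1])
    est <- anc$probs[as.character(internals[j]), 1]
    se <- sqrt(exact * (1 - exact) / n_hist)
    expect_lt(abs(est - exact), 4 * max(se, 1e-3))
  }
  expect_equal(unname(rowSums(anc$probs)), rep(1, length(internals)))
})

test_that("near-zero branch durations pin the root to the tip area", {
  tr <- read_newick_tree("(A:1e-8,B:1e-8);")
  g <- geo_data(c(A = "x", B = "x"), areas = c("x", "y"))
  Q <- build_rate_matrix(geo_params(TRUE, 1, 1, 1), 2)
  set.seed(18)
  hs <- sample_conditional_histories(tr, g, Q, n = 200)
  anc <- ancestral_area_probabilities(hs)
  expect_equal(anc$map$map_area, "x")
  expect_gt(anc$map$prob, 0.999)
})

test_that("event-count summaries close over sources and flag empties", {
  set.seed(19)
  tr <- simulate_tree(8, "coalescent")
  g <- random_geo_data(tr, 3)
  Q <- build_rate_matrix(random_dense_params(3, mu = 2), 3)
  hs <- sample_conditional_histories(tr, g, Q, n = 60)
  ec <- count_dispersal_events(hs)
  expect_equal(dim(ec$mean_counts), c(3, 3))
  expect_true(all(diag(ec$mean_counts) == 0))
  # per-source percentages sum to 100 within each history, hence in mean
  expect_equal(sum(ec$source_pct$mean_pct), 100, tolerance = 1e-9)
  expect_true(all(ec$lower <= ec$mean_counts + 1e-12))
  expect_true(all(ec$upper >= ec$mean_counts - 1e-12))
  # all-zero history sets give a zero matrix
  h0 <- list(structure(list(node_state = c(1L, 1L, 1L),
                            events = data.frame(edge = integer(0),
                                                parent = integer(0),
                                                child = integer(0),
                                                time = numeric(0),
                                                from = integer(0),
                                                to = integer(0)),
                            areas = c("x", "y"), n_tips = 2L),
                       class = "dispersal_history"))
  ec0 <- count_dispersal_events(h0)
  expect_equal(max(abs(ec0$mean_counts)), 0)
  expect_equal(ec0$n_with_events, 0)
})

test_that("MAP-area comparison reports shared-node fractions", {
  set.seed(20)
  tr <- simulate_tree(6, "coalescent")
  g <- random_geo_data(tr, 3)
  Q <- build_rate_matrix(random_dense_params(3, mu = 1), 3)
  a <- ancestral_area_probabilities(sample_conditional_histories(tr, g, Q, n = 40))
  b <- ancestral_area_probabilities(sample_conditional_histories(tr, g, Q, n = 40))
  cmp <- compare_ancestral_maps(a, b)
  expect_equal(cmp$p, 1)     # same fixed tree: all nodes shared
  expect_gte(cmp$f, 0); expect_lte(cmp$f, 1)
})

test_that("posterior histories marginalize over sampled rate matrices", {
  set.seed(22)
  sc <- simulation_scenario("hx", n_tips = 10, k = 3,
                            route_density = "dense", events_target = 8,
                            seed = 9)
  sim <- simulate_scenario(sc)
  cfg <- resolve_prior_config(3, sim$T, TRUE)
  fit <- run_mcmc(sim$tree, sim$data, cfg,
                  mcmc_settings(n_iter = 1500, burnin = 0.3, thin = 3,
                                seed = 2))
  hs <- posterior_histories(sim$tree, sim$data, fit, max_histories = 50)
  expect_length(hs, 50)
  ec <- count_dispersal_events(hs)
  expect_gt(ec$total_mean, 0)
})
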