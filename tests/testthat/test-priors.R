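test_that("prior configurations resolve to the documented hyperparameters", {
  # default symmetric: lambda = ln 2, offset k - 1
  for (k in c(3, 5, 9)) {
    cfg <- resolve_prior_config(k, 10, TRUE, "default")
    expect_equal(cfg$lambda, log(2))
    expect_equal(cfg$offset, k - 1)
  }
  # default asymmetric: Poisson mean k - 1, no offset
  cfg <- resolve_prior_config(7, 10, FALSE, "default")
  expect_equal(cfg$lambda, 6)
  expect_equal(cfg$offset, 0)
  # alternative asymmetric: half of all K = k(k-1) routes
  cfg <- resolve_prior_config(5, 10, FALSE, "alternative")
  expect_equal(cfg$lambda, 10)
  # alternative symmetric: K/2 - (k-1), floored at ln 2 for tiny k
  cfg <- resolve_prior_config(6, 10, TRUE, "alternative")
  expect_equal(cfg$lambda, 15 / 2 - 5)
  cfg <- resolve_prior_config(3, 10, TRUE, "alternative")
  expect_equal(cfg$lambda, log(2))
  expect_error(resolve_prior_config(1, 10), "k must be")
  expect_error(resolve_prior_config(3, 0), "T must be")
})

test_that("the route-number prior normalizes over all configurations", {
  for (style in c("per-delta-count", "per-configuration")) {
    for (k in 3:4) {
      cfg <- resolve_prior_config(k, 10, TRUE, delta_prior_style = style)
      all_d <- enumerate_delta(cfg$K)
      tot <- sum(exp(apply(all_d, 1, log_prior_delta, config = cfg)))
      expect_equal(tot, 1, tolerance = 1e-12,
                   info = sprintf("sym k=%d %s", k, style))
    }
    cfg <- resolve_prior_config(3, 10, FALSE, delta_prior_style = style)
    all_d <- enumerate_delta(cfg$K)
    tot <- sum(exp(apply(all_d, 1, log_prior_delta, config = cfg)))
    expect_equal(tot, 1, tolerance = 1e-12, info = paste("asym", style))
  }
})

test_that("configurations below k - 1 routes or reducible have zero prior", {
  cfg <- resolve_prior_config(3, 10, TRUE)
  expect_identical(log_prior_delta(c(1L, 0L, 0L), cfg), -Inf)
  expect_identical(log_prior_delta(c(0L, 0L, 0L), cfg), -Inf)
  cfg4 <- resolve_prior_config(4, 10, TRUE)
  # 3 routes forming a triangle on areas {1,2,3}: area 4 unreachable
  rp <- route_pairs(4, TRUE)
  tri <- as.integer(rp[, 1] <= 3 & rp[, 2] <= 3)
  expect_equal(sum(tri), 3)
  expect_identical(log_prior_delta(tri, cfg4), -Inf)
  # asymmetric prior enforces no minimum
  cfga <- resolve_prior_config(3, 10, FALSE)
  expect_true(is.finite(log_prior_delta(rep(0L, 6), cfga)))
})

test_that("equal-Delta configurations are equiprobable and match the pmf", {
  for (style in c("per-delta-count", "per-configuration")) {
    cfg <- resolve_prior_config(4, 10, TRUE, delta_prior_style = style)
    all_d <- enumerate_delta(cfg$K)
    lp <- apply(all_d, 1, log_prior_delta, config = cfg)
    D <- rowSums(all_d)
    marg <- vapply(cfg$delta_support, function(d) sum(exp(lp[D == d])),
                   numeric(1))
    expect_equal(marg, cfg$delta_pmf, tolerance = 1e-12)
    for (d in cfg$delta_support) {
      vals <- lp[D == d & is.finite(lp)]
      if (length(vals) > 1) expect_lt(diff(range(vals)), 1e-12)
    }
  }
})

test_that("renormalized truncated Poisson is the Delta marginal by default", {
  cfg <- resolve_prior_config(3, 10, TRUE, "default")
  w <- dpois(cfg$delta_support - 2, log(2))
  expect_equal(cfg$delta_pmf, w / sum(w), tolerance = 1e-14)
})

test_that("route-inclusion probability matches enumeration and trends", {
  for (style in c("per-delta-count", "per-configuration")) {
    cfg <- resolve_prior_config(4, 10, TRUE, delta_prior_style = style)
    all_d <- enumerate_delta(cfg$K)
    lp <- apply(all_d, 1, log_prior_delta, config = cfg)
    incl <- sum(exp(lp) * all_d[, 1])
    expect_equal(prior_route_inclusion_probability(cfg), incl,
                 tolerance = 1e-12)
  }
  # default symmetric inclusion probability drops as k grows
  p <- vapply(3:20, function(k)
    prior_route_inclusion_probability(resolve_prior_config(k, 10, TRUE)),
    numeric(1))
  expect_true(all(diff(p) < 0))
  # alternative prior stays roughly flat at ~1/2
  pa <- vapply(5:20, function(k)
    prior_route_inclusion_probability(
      resolve_prior_config(k, 10, TRUE, "alternative")), numeric(1))
  expect_true(all(abs(pa - 0.5) < 0.1))
  # asymmetric alternative: ~1/2 up to Poisson truncation at K
  cfg <- resolve_prior_config(5, 10, FALSE, "alternative")
  expect_equal(prior_route_inclusion_probability(cfg), 0.5, tolerance = 0.02)
})

test_that("rate priors have the documented densities and moments", {
  T <- 10
  cfg <- resolve_prior_config(3, T, rate_prior = "default")
  mu <- 0.07
  expect_equal(log_prior_mu(mu, config = cfg),
               dgamma(mu, 0.5, rate = T, log = TRUE))
  # prior mean of mu is 0.5 / T
  expect_equal(0.5 / cfg$mu_rate, 0.5 / T)
  set.seed(2)
  draws <- sample_prior_mu(cfg, 20000)$mu
  expect_lt(abs(mean(draws) - 0.5 / T), 4 * sd(draws) / sqrt(length(draws)))

  cfga <- resolve_prior_config(3, T, rate_prior = "alternative")
  expect_equal(log_prior_mu(0.3, m = 2, config = cfga),
               dexp(0.3, 1 / 2, log = TRUE) + dgamma(2, 0.5, 0.5, log = TRUE))
  expect_error(log_prior_mu(0.3, config = cfga), "hyper-mean")
  # law of total expectation: E[mu] = E[m] = 1
  set.seed(3)
  d <- sample_prior_mu(cfga, 200000)
  se <- sd(d$mu) / sqrt(length(d$mu))
  expect_lt(abs(mean(d$mu) - 1), 4 * se)
  expect_error(log_prior_mu(-1, config = cfg), "mu must be")
})

test_that("the default prior on event counts is T-free with mean 0.5", {
  means <- q975 <- p0 <- numeric(0)
  for (T in c(1, 10, 100)) {
    cfg <- resolve_prior_config(4, T, rate_prior = "default")
    pmf <- prior_event_count_distribution(cfg, T, n_max = 300)
    expect_equal(sum(pmf), 1, tolerance = 1e-10)
    means <- c(means, event_count_mean(pmf))
    q975 <- c(q975, event_count_quantile(pmf, 0.975))
    p0 <- c(p0, pmf[[1]])
  }
  expect_equal(means, rep(0.5, 3), tolerance = 1e-9)
  expect_equal(q975, rep(3, 3))               # the documented [0, 3] interval
  expect_equal(p0, rep(2^(-1 / 2), 3), tolerance = 1e-12)
})

test_that("the alternative event-count prior scales with tree length", {
  cfg <- resolve_prior_config(4, 1, rate_prior = "alternative")
  m1 <- event_count_mean(prior_event_count_distribution(cfg, 1, n_max = 500))
  m5 <- event_count_mean(prior_event_count_distribution(cfg, 5, n_max = 2500))
  # E[N] = E[mu] T = T for this hyperprior
  expect_equal(m1, 1, tolerance = 0.02)
  expect_equal(m5, 5, tolerance = 0.15)
  expect_gt(m5, m1)
})

test_that("relative-rate prior is iid Exponential(1) by default", {
  cfg <- resolve_prior_config(3, 10)
  expect_equal(log_prior_relative_rates(c(1, 1, 1), cfg), -3)
  expect_equal(log_prior_relative_rates(0.5, cfg), -0.5)
  expect_error(log_prior_relative_rates(c(1, -1, 1), cfg), "> 0")
  # sampler and density agree in their first two moments
  set.seed(4)
  d <- as.vector(sample_prior_relative_rates(cfg, 20000))
  expect_equal(mean(d), 1, tolerance = 0.03)
  expect_equal(var(d), 1, tolerance = 0.1)
})

test_that("prior samplers hit the configuration prior", {
  set.seed(5)
  cfg <- resolve_prior_config(4, 10, TRUE)
  draws <- replicate(4000, sum(sample_prior_delta(cfg)))
  emp <- table(factor(draws, levels = cfg$delta_support)) / length(draws)
  expect_lt(0.5 * sum(abs(as.numeric(emp) - cfg$delta_pmf)), 0.05)
  p <- sample_prior_params(cfg)
  expect_s3_class(p, "geo_params")
  expect_true(is.finite(log_prior(p, cfg)))
})

test_that("prior audit emits the documented tables", {
  aud <- prior_audit(4, 10, k_range = 3:6, T_values = c(1, 10), n_max = 20)
  expect_named(aud, c("delta_pmf", "route_inclusion", "event_counts"))
  expect_setequal(unique(aud$delta_pmf$prior), c("default", "alternative"))
  for (pr in c("default", "alternative"))
    expect_equal(sum(aud$delta_pmf$prob[aud$delta_pmf$prior == pr]), 1,
                 tolerance = 1e-9)
  expect_true(all(aud$route_inclusion$inclusion_prob > 0 &
                    aud$route_inclusion$inclusion_prob < 1))
})
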