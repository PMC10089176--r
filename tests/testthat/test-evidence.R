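test_that("the power-posterior schedule spans [0, 1] with stones near 0", {
  b <- power_posterior_schedule(16)
  expect_equal(b[1], 0)
  expect_equal(b[16], 1)
  expect_true(all(diff(b) > 0))
  expect_gt(sum(b < 0.1), sum(b > 0.9))   # Beta(0.3, 1) front-loading
  expect_error(power_posterior_schedule(3), ">= 4")
})

test_that("stepping stone reduces correctly in degenerate cases", {
  # beta-invariant likelihood: the estimate is that constant
  fake <- structure(list(beta = c(0, 0.25, 0.5, 1),
                         loglik = rep(list(rep(-3.2, 400)), 4),
                         mean = rep(-3.2, 4), se = rep(0, 4),
                         ess = rep(400, 4)), class = "power_posterior")
  ss <- stepping_stone_log_marginal(fake)
  expect_equal(ss$log_ml, -3.2, tolerance = 1e-12)
  # likelihood identically 1 (log 0): evidence of nothing is 1
  fake$loglik <- rep(list(rep(0, 400)), 4)
  expect_equal(stepping_stone_log_marginal(fake)$log_ml, 0)
})

test_that("stepping stone matches a conjugate closed form", {
  # one-parameter toy: y | rate ~ Poisson(rate * t), rate ~ Gamma(a, b);
  # cast as a mu-only geographic model is exercised elsewhere — here the
  # estimator itself is checked on iid prior draws per stone, where
  # E_beta[L^(d)] can be computed exactly from the gamma-Poisson marginal.
  a <- 0.5; b <- 2; yobs <- 3; t <- 1.5
  loglik_fun <- function(rate) dpois(yobs, rate * t, log = TRUE)
  exact <- dnbinom(yobs, size = a, prob = b / (b + t), log = TRUE)
  betas <- power_posterior_schedule(12)
  set.seed(6)
  ll <- lapply(betas, function(bb) {
    # iid draws from the power posterior via rejection-free conjugacy:
    # rate | beta ~ Gamma(a + beta*y, b + beta*t)
    rs <- rgamma(4000, a + bb * yobs, b + bb * t)
    loglik_fun(rs)
  })
  stones <- structure(list(beta = betas, loglik = ll,
                           mean = vapply(ll, mean, 0),
                           se = vapply(ll, function(x) sd(x) / sqrt(length(x)), 0),
                           ess = rep(4000, 12)), class = "power_posterior")
  ss <- stepping_stone_log_marginal(stones)
  expect_lt(abs(ss$log_ml - exact), 3 * max(ss$se, 1e-3))
})

test_that("model Bayes factors are twice the log-ML difference", {
  bf <- model_bayes_factor(-147.32, -187.65)
  expect_equal(bf$two_ln_bf, 80.66, tolerance = 1e-10)
  expect_equal(bf$preferred, "a")
  expect_equal(bf$category, "decisive")
  expect_equal(model_bayes_factor(-5, -5)$two_ln_bf, 0)
  expect_equal(model_bayes_factor(-10, -12)$two_ln_bf,
               -model_bayes_factor(-12, -10)$two_ln_bf)
})

test_that("Kass-Raftery categories switch at 2, 6, 10", {
  expect_equal(kass_raftery_category(c(1.9, 2, 2.1, 6, 6.1, 10, 10.1)),
               c("none", "none", "positive", "positive", "strong",
                 "strong", "decisive"))
})

test_that("route Bayes factors are posterior odds over prior odds", {
  # synthetic trace with known inclusion frequencies
  cfg <- resolve_prior_config(3, 5, TRUE)
  q <- prior_route_inclusion_probability(cfg)
  N <- 1000
  mk <- function(p) c(rep(1, round(p * N)), rep(0, N - round(p * N)))
  tr <- data.frame(mu = rep(0.1, N), delta_1 = mk(0.9), delta_2 = mk(0.5),
                   delta_3 = mk(1))
  tr[paste0("r_", 1:3)] <- 1
  attr(tr, "prior") <- cfg
  class(tr) <- c("geo_trace", "data.frame")
  rb <- route_bayes_factors(tr, cfg)
  r1 <- rb[rb$from == 1 & rb$to == 2, ]
  expect_equal(r1$bf, (0.9 / 0.1) / (q / (1 - q)), tolerance = 1e-10)
  expect_equal(r1$two_ln_bf, 2 * log(r1$bf))
  # p = 1 is reported at the MCMC resolution bound and flagged
  r3 <- rb[rb$from == 2 & rb$to == 3, ]
  expect_true(r3$bounded)
  expect_equal(r3$bf, ((N / (N + 1)) / (1 / (N + 1))) / (q / (1 - q)),
               tolerance = 1e-10)
  expect_true(all(diff(rb$two_ln_bf) <= 0))   # sorted descending
})

test_that("odds-ratio arithmetic matches the worked example", {
  p <- 0.9; q <- 0.25
  bf <- (p / (1 - p)) / (q / (1 - q))
  expect_equal(bf, 27)
  expect_equal(kass_raftery_category(2 * log(bf)), "strong")
})

test_that("a smaller prior inclusion probability inflates the BF", {
  # the mechanism behind default-prior BF inflation: at matched posterior
  # inclusion, BF is monotone decreasing in the prior inclusion q
  phat <- c(0.3, 0.6, 0.9)
  for (p in phat) {
    qs <- seq(0.05, 0.95, by = 0.05)
    bfs <- (p / (1 - p)) / (qs / (1 - qs))
    expect_true(all(diff(bfs) < 0))
  }
  # and concretely: default vs alternative prior for a moderate k
  qd <- prior_route_inclusion_probability(resolve_prior_config(8, 10, TRUE))
  qa <- prior_route_inclusion_probability(
    resolve_prior_config(8, 10, TRUE, "alternative"))
  expect_lt(qd, qa)
})

test_that("MCMC route inclusion matches exact model averaging on a toy", {
  # k = 3 symmetric, r fixed at 1, mu free: all 4 irreducible
  # configurations enumerable; exact posterior inclusion from per-model
  # marginal likelihoods by quadrature over mu
  set.seed(33)
  tr <- simulate_tree(5, "coalescent")
  g <- random_geo_data(tr, 3)
  Tlen <- tree_length(tr)
  cfg <- resolve_prior_config(3, Tlen, TRUE)
  all_d <- enumerate_delta(3)
  lp <- apply(all_d, 1, log_prior_delta, config = cfg)
  keep <- is.finite(lp)
  ml <- vapply(which(keep), function(i) {
    integrate(function(mus) vapply(mus, function(mu)
      exp(pruning_log_likelihood(tr, g, build_rate_matrix(
        geo_params(TRUE, rep(1, 3), all_d[i, ], mu), 3))), numeric(1)) *
        dgamma(mus, 0.5, rate = Tlen), 0, Inf, rel.tol = 1e-9)$value
  }, numeric(1))
  post <- exp(lp[keep]) * ml
  post <- post / sum(post)
  exact_incl <- colSums(all_d[keep, , drop = FALSE] * post)
  s <- mcmc_settings(n_iter = 20000, burnin = 0.25, thin = 1, seed = 4,
                     move_weights = c(rate = 0), init = list(r = rep(1, 3)))
  fit <- run_mcmc(tr, g, cfg, s)
  mc_incl <- colMeans(fit[paste0("delta_", 1:3)])
  expect_equal(unname(mc_incl), unname(exact_incl), tolerance = 0.04)
})

test_that("the published model-comparison table is internally consistent", {
  tab <- published_logml_comparisons()
  expect_equal(nrow(tab), 14)
  recomputed <- vapply(seq_len(nrow(tab)), function(i)
    model_bayes_factor(tab$logml_alternative[i],
                       tab$logml_default[i])$two_ln_bf, numeric(1))
  dev <- abs(recomputed - tab$two_ln_bf)
  # 13 of the 14 published rows reproduce to input-rounding precision;
  # dataset 10's printed 2lnBF disagrees with its own printed log-MLs by
  # 0.29 (2 x (305.88 - 258.13) = 95.50, printed 95.79) — an internal
  # inconsistency of the published table, not of the arithmetic
  expect_true(all(dev[tab$dataset != 10] <= 0.02 + 1e-9))
  expect_equal(dev[tab$dataset == 10], 0.29, tolerance = 1e-9)
  # alternative-prior models preferred throughout, decisively
  expect_true(all(tab$two_ln_bf > 10))
})
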