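# Prior models for the discrete-geographic CTMC: route-number priors
# (default and alternative), average-dispersal-rate priors (default
# Gamma(0.5, T); alternative hierarchical exponential / K-distribution),
# and the relative-rate prior.

#' Resolve a prior configuration
#'
#' Assembles every prior choice into a single object used by the density
#' functions, the samplers and the MCMC engine.
#'
#' Route-number priors (on Delta = number of dispersal routes):
#' \describe{
#'   \item{default, symmetric}{offset Poisson: Delta - (k-1) ~ Poisson(ln 2),
#'     i.e. strong preference for the minimal irreducible model.}
#'   \item{alternative, symmetric}{offset Poisson with lambda chosen so the
#'     expected Delta is about half the maximum K = k(k-1)/2, i.e.
#'     lambda = K/2 - (k-1), floored at ln 2 for tiny k.}
#'   \item{default, asymmetric}{Poisson(lambda = k-1), no offset and no
#'     irreducibility constraint.}
#'   \item{alternative, asymmetric}{Poisson(lambda = K/2) with K = k(k-1).}
#' }
#' In every case the Poisson is truncated/renormalized to the attainable
#' range of Delta, and all (irreducible, for symmetric models)
#' configurations with a given Delta are equiprobable.
#'
#' Average-rate priors: default mu ~ Gamma(shape 0.5, rate T) (prior mean
#' 0.5/T, so 0.5 expected events over the tree); alternative
#' mu | m ~ Exponential(mean m), m ~ Gamma(0.5, 0.5) — marginally the
#' K-distribution — treated hierarchically with m an explicit latent
#' parameter.
#'
#' @param k number of areas (>= 2).
#' @param T total tree length (> 0).
#' @param symmetric logical; symmetric or asymmetric Q.
#' @param routes_prior `"default"` or `"alternative"`.
#' @param rate_prior `"default"` or `"alternative"`.
#' @param delta_prior_style `"per-delta-count"` places the (renormalized)
#'   Poisson mass on each value of Delta and divides it equally among the
#'   configurations with that Delta; `"per-configuration"` gives every
#'   configuration an unnormalized Poisson weight (the style used by some
#'   legacy implementations) and normalizes over configurations.
#' @param lambda optional override of the Poisson rate.
#' @param rel_rate_shape,rel_rate_rate gamma prior on each relative rate
#'   r_ij; the default shape = rate = 1 is the i.i.d. Exponential(1) prior.
#' @return an object of class `prior_config`.
#' @export
resolve_prior_config <- function(k, T, symmetric = TRUE,
                                 routes_prior = c("default", "alternative"),
                                 rate_prior = c("default", "alternative"),
                                 delta_prior_style = c("per-delta-count",
                                                       "per-configuration"),
                                 lambda = NULL,
                                 rel_rate_shape = 1, rel_rate_rate = 1) {
  routes_prior <- match.arg(routes_prior)
  rate_prior <- match.arg(rate_prior)
  delta_prior_style <- match.arg(delta_prior_style)
  if (k < 2) stop("k must be >= 2")
  if (T <= 0) stop("T must be > 0")
  K <- n_routes(k, symmetric)
  offset <- if (symmetric) k - 1L else 0L
  if (is.null(lambda)) {
    lambda <- if (symmetric) {
      if (routes_prior == "default") log(2)
      else max(K / 2 - (k - 1), log(2))
    } else {
      if (routes_prior == "default") k - 1 else K / 2
    }
  }
  if (lambda <= 0) stop("lambda must be > 0")
  support <- if (symmetric) seq.int(k - 1L, K) else seq.int(0L, K)
  counts <- vapply(support, function(d)
    count_configurations(k, d, symmetric, require_irreducible = symmetric),
    numeric(1))
  w <- dpois(support - offset, lambda)
  p_delta <- switch(delta_prior_style,
    "per-delta-count" = w / sum(w),
    "per-configuration" = counts * w / sum(counts * w))
  cfg <- structure(list(
    k = as.integer(k), T = T, symmetric = isTRUE(symmetric), K = K,
    routes_prior = routes_prior, rate_prior = rate_prior,
    delta_prior_style = delta_prior_style,
    lambda = lambda, offset = offset,
    delta_support = support, delta_counts = counts, delta_pmf = p_delta,
    log_config_prob = log(p_delta) - log(counts),
    mu_shape = 0.5, mu_rate = T,          # default rate prior
    hyper_shape = 0.5, hyper_rate = 0.5,  # alternative rate hyperprior
    rel_rate_shape = rel_rate_shape, rel_rate_rate = rel_rate_rate),
    class = "prior_config")
  cfg
}

#' @export
print.prior_config <- function(x, ...) {
  cat(sprintf(
    "prior_config: k = %d, T = %g, %s\n  routes: %s (lambda = %.4f, offset = %d, style = %s)\n  rate: %s\n",
    x$k, x$T, if (x$symmetric) "symmetric" else "asymmetric",
    x$routes_prior, x$lambda, x$offset, x$delta_prior_style, x$rate_prior))
  invisible(x)
}

#' Prior distribution on the number of dispersal routes
#'
#' @param config a `prior_config`.
#' @return data.frame with columns `Delta` and `prob` (the marginal prior
#'   pmf of Delta implied by the configuration prior).
#' @export
delta_prior_pmf <- function(config) {
  data.frame(Delta = config$delta_support, prob = config$delta_pmf)
}

#' Log prior probability of a route configuration
#'
#' Symmetric models assign probability zero (log prior `-Inf`) to any
#' configuration with fewer than k - 1 routes or whose route graph is not
#' connected; configurations with the same number of routes are
#' equiprobable. Asymmetric models impose no irreducibility constraint.
#'
#' @param delta 0/1 vector of length K.
#' @param config a `prior_config`.
#' @return log prior probability (scalar, possibly `-Inf`).
#' @export
log_prior_delta <- function(delta, config) {
  if (length(delta) != config$K)
    stop("delta length ", length(delta), " != K = ", config$K)
  D <- sum(delta)
  if (config$symmetric) {
    if (D < config$k - 1L) return(-Inf)
    if (!is_irreducible_delta(delta, config$k, TRUE)) return(-Inf)
  }
  i <- match(D, config$delta_support)
  if (is.na(i)) return(-Inf)
  config$log_config_prob[i]
}

#' Prior probability that a given dispersal route exists
#'
#' P(delta_ij = 1) for an arbitrary route. By exchangeability of routes
#' under the equiprobable-given-Delta construction this is
#' sum_Delta p(Delta) * Delta / K.
#'
#' @param config a `prior_config`.
#' @return probability in (0, 1).
#' @export
prior_route_inclusion_probability <- function(config) {
  sum(config$delta_pmf * config$delta_support) / config$K
}

#' Log prior density of the average dispersal rate
#'
#' Default: Gamma(0.5, rate = T) density at mu. Alternative: joint density
#' of (mu, m) — Exponential(mean m) at mu times Gamma(0.5, 0.5) at m; the
#' marginal of mu is the K-distribution.
#'
#' @param mu average dispersal rate (> 0).
#' @param m hyper-mean; required iff the alternative rate prior is used.
#' @param config a `prior_config`.
#' @return log density.
#' @export
log_prior_mu <- function(mu, m = NULL, config) {
  if (mu <= 0) stop("mu must be > 0")
  if (config$rate_prior == "default") {
    dgamma(mu, shape = config$mu_shape, rate = config$mu_rate, log = TRUE)
  } else {
    if (is.null(m)) stop("alternative rate prior requires the hyper-mean m")
    if (m <= 0) stop("m must be > 0")
    dexp(mu, rate = 1 / m, log = TRUE) +
      dgamma(m, shape = config$hyper_shape, rate = config$hyper_rate, log = TRUE)
  }
}

#' Log prior density of the relative rates
#'
#' i.i.d. Gamma(shape, rate) over all K relative rates; the default
#' shape = rate = 1 is the standard i.i.d. Exponential(1) prior.
#'
#' @param r vector of relative rates (> 0).
#' @param config a `prior_config`.
#' @return log density.
#' @export
log_prior_relative_rates <- function(r, config) {
  if (any(r <= 0)) stop("relative rates must be > 0")
  sum(dgamma(r, shape = config$rel_rate_shape, rate = config$rel_rate_rate,
             log = TRUE))
}

#' Joint log prior of a parameter set
#'
#' @param params a `geo_params` object.
#' @param config a `prior_config`.
#' @return log prior density (possibly `-Inf`).
#' @export
log_prior <- function(params, config) {
  lp <- log_prior_delta(params$delta, config)
  if (!is.finite(lp)) return(-Inf)
  lp + log_prior_mu(params$mu, params$m, config) +
    log_prior_relative_rates(params$r, config)
}

#' Implied prior on the total number of dispersal events
#'
#' With N | mu ~ Poisson(mu * T): under the default rate prior the marginal
#' of N is negative binomial with size 0.5 and success probability
#' T/(T + T) = 1/2 — independent of T, with mean 0.5 and 95% interval
#' [0, 3]. Under the alternative prior the pmf is obtained by numerical
#' integration over the hyper-mean m (N | m is geometric with success
#' probability 1/(1 + mT)); its mean grows with T.
#'
#' @param config a `prior_config`.
#' @param T tree length; defaults to the one in `config`.
#' @param n_max largest event count evaluated.
#' @return numeric vector of probabilities for N = 0..n_max (named).
#' @export
prior_event_count_distribution <- function(config, T = config$T, n_max = 50) {
  n <- 0:n_max
  if (config$rate_prior == "default") {
    p <- dnbinom(n, size = config$mu_shape,
                 prob = config$mu_rate / (config$mu_rate + T))
  } else {
    a <- config$hyper_shape; b <- config$hyper_rate
    p <- vapply(n, function(nn) {
      integrate(function(m) {
        q <- 1 / (1 + m * T)
        dgamma(m, shape = a, rate = b) * q * (1 - q)^nn
      }, 0, Inf, rel.tol = 1e-9, abs.tol = 0)$value
    }, numeric(1))
  }
  setNames(p, n)
}

#' Mean and quantile helpers for an event-count pmf
#'
#' @param pmf output of [prior_event_count_distribution()].
#' @param prob quantile level.
#' @return `event_count_mean`: the (truncated-support) mean;
#'   `event_count_quantile`: smallest n with CDF >= `prob`.
#' @export
event_count_mean <- function(pmf) {
  n <- as.numeric(names(pmf))
  sum(n * pmf)
}

#' @rdname event_count_mean
#' @export
event_count_quantile <- function(pmf, prob = 0.975) {
  n <- as.numeric(names(pmf))
  cdf <- cumsum(pmf)
  if (cdf[length(cdf)] < prob)
    stop("n_max too small to reach the requested quantile")
  n[which(cdf >= prob)[1L]]
}

# ---- prior samplers -------------------------------------------------------

#' Draw from the prior on (mu, m)
#' @param config a `prior_config`.
#' @param n number of draws.
#' @return list with vectors `mu` and (alternative prior only) `m`.
#' @export
sample_prior_mu <- function(config, n = 1) {
  if (config$rate_prior == "default") {
    list(mu = rgamma(n, shape = config$mu_shape, rate = config$mu_rate),
         m = NULL)
  } else {
    m <- rgamma(n, shape = config$hyper_shape, rate = config$hyper_rate)
    list(mu = rexp(n, rate = 1 / m), m = m)
  }
}

#' Draw relative rates from their prior
#' @param config a `prior_config`.
#' @param n number of route-vectors to draw.
#' @return n x K matrix.
#' @export
sample_prior_relative_rates <- function(config, n = 1) {
  matrix(rgamma(n * config$K, shape = config$rel_rate_shape,
                rate = config$rel_rate_rate), n, config$K)
}

#' Draw a route configuration from its prior
#'
#' Samples Delta from its marginal pmf, then a uniform configuration with
#' that many routes (rejecting reducible ones for symmetric models).
#'
#' @param config a `prior_config`.
#' @return 0/1 vector of length K.
#' @export
sample_prior_delta <- function(config) {
  D <- sample(config$delta_support, 1L, prob = config$delta_pmf)
  # under per-configuration style the marginal of Delta differs from the
  # stored pmf only through the counts factor, which is already folded in
  repeat {
    delta <- integer(config$K)
    delta[sample.int(config$K, D)] <- 1L
    if (!config$symmetric || is_irreducible_delta(delta, config$k, TRUE))
      return(delta)
  }
}

#' Draw a full parameter set from the prior
#' @param config a `prior_config`.
#' @return a `geo_params` object.
#' @export
sample_prior_params <- function(config) {
  mm <- sample_prior_mu(config, 1)
  geo_params(config$symmetric,
             r = as.vector(sample_prior_relative_rates(config, 1)),
             delta = sample_prior_delta(config),
             mu = mm$mu, m = mm$m)
}

#' Machine-readable prior audit tables
#'
#' Emits the analogues of the prior figures as data frames: the pmf of the
#' number of routes Delta, the prior route-inclusion probability as a
#' function of k, and the implied event-count pmf for several tree lengths,
#' under both the default and the alternative prior models.
#'
#' @param k number of areas.
#' @param T tree length.
#' @param symmetric logical.
#' @param k_range values of k for the inclusion-probability curve.
#' @param T_values tree lengths for the event-count pmfs.
#' @param n_max largest event count tabulated.
#' @return list of data.frames `delta_pmf`, `route_inclusion`, `event_counts`.
#' @export
prior_audit <- function(k, T, symmetric = TRUE, k_range = 3:10,
                        T_values = c(1, 10, 100), n_max = 30) {
  modes <- c("default", "alternative")
  cfg <- function(kk, mode_r, mode_m = "default")
    resolve_prior_config(kk, T, symmetric, routes_prior = mode_r,
                         rate_prior = mode_m)
  dp <- do.call(rbind, lapply(modes, function(m) {
    d <- delta_prior_pmf(cfg(k, m)); d$prior <- m; d
  }))
  ri <- do.call(rbind, lapply(modes, function(m)
    data.frame(k = k_range, prior = m,
               inclusion_prob = vapply(k_range, function(kk)
                 prior_route_inclusion_probability(cfg(kk, m)), numeric(1)))))
  ec <- do.call(rbind, lapply(modes, function(m)
    do.call(rbind, lapply(T_values, function(tt) {
      cc <- resolve_prior_config(k, tt, symmetric, rate_prior = m)
      pmf <- prior_event_count_distribution(cc, tt, n_max)
      data.frame(T = tt, prior = m, n = as.numeric(names(pmf)), prob = pmf,
                 row.names = NULL)
    }))))
  list(delta_pmf = dp, route_inclusion = ri, event_counts = ec)
}
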