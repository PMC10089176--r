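# Metropolis-Hastings sampler for (mu, r, delta [, m]) targeting
# prior x likelihood^beta. beta = 1 is the posterior, beta = 0 the prior,
# intermediate values the power posteriors used for stepping-stone
# marginal-likelihood estimation.

#' MCMC settings
#'
#' @param n_iter total number of proposal iterations.
#' @param burnin fraction of iterations discarded (and used for proposal
#'   tuning) at the start of the chain.
#' @param thin keep every `thin`-th post-burn-in sample.
#' @param seed RNG seed; recorded in the trace.
#' @param beta power applied to the likelihood (in \[0, 1\]).
#' @param move_weights named numeric weights for the move types
#'   `mu`, `rate`, `flip`, `swap`, `m`; a zero weight disables a move
#'   (e.g. to hold delta fixed). `m` is used only under the alternative
#'   rate prior.
#' @param init optional named list of initial values (`mu`, `r`, `delta`, `m`).
#' @param tune adapt multiplier-move windows during burn-in (frozen after).
#' @return an object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_iter = 10000, burnin = 0.25, thin = 5, seed = 1,
                          beta = 1,
                          move_weights = c(mu = 2, rate = 2, flip = 2,
                                           swap = 1, m = 2),
                          init = NULL, tune = TRUE) {
  if (beta < 0 || beta > 1) stop("beta must be in [0, 1]")
  if (burnin < 0 || burnin >= 1) stop("burnin must be in [0, 1)")
  if (n_iter <= 1 / (1 - burnin)) stop("chain too short")
  defaults <- c(mu = 2, rate = 2, flip = 2, swap = 1, m = 2)
  w <- defaults
  if (!is.null(move_weights)) w[names(move_weights)] <- move_weights
  structure(list(n_iter = as.integer(n_iter), burnin = burnin,
                 thin = as.integer(thin), seed = as.integer(seed),
                 beta = beta, move_weights = w, init = init,
                 tune = isTRUE(tune)),
            class = "mcmc_settings")
}

#' Run the Metropolis-Hastings sampler
#'
#' Moves: log-scale multiplier on mu; multiplier on a single relative rate;
#' single-indicator flip on delta (proposals that violate irreducibility
#' are auto-rejected through their `-Inf` prior); a paired flip that turns
#' one route on and another off (preserving Delta, which helps mixing
#' across equal-Delta models); and a multiplier on the hyper-mean m under
#' the alternative rate prior. Multiplier windows are adapted towards a
#' ~35% acceptance rate during burn-in and frozen afterwards.
#'
#' With `beta = 0` (prior sampling) `tree` and `data` may be `NULL`; if
#' they are supplied the log-likelihood is still evaluated at recorded
#' samples so that power-posterior stone at beta = 0 can feed the
#' stepping-stone estimator.
#'
#' @param tree rooted `phylo` (may be `NULL` when `beta = 0`).
#' @param data `geo_data` (may be `NULL` when `beta = 0`).
#' @param prior a `prior_config`.
#' @param settings an `mcmc_settings`.
#' @param root_freqs root area frequencies (uniform by default).
#' @return a `geo_trace`: data.frame of retained samples with columns
#'   `iter`, `mu`, (`m`,) `r_*`, `delta_*`, `Delta`, `log_prior`,
#'   `log_lik`, `log_post`; attributes `settings`, `prior`, `acceptance`.
#' @export
run_mcmc <- function(tree, data, prior, settings, root_freqs = NULL) {
  stopifnot(inherits(prior, "prior_config"), inherits(settings, "mcmc_settings"))
  set.seed(settings$seed)
  beta <- settings$beta
  have_data <- !is.null(tree) && !is.null(data)
  if (beta > 0 && !have_data) stop("beta > 0 requires tree and data")
  if (have_data) {
    validate_tree_for_inference(tree)
    llf <- loglik_factory(tree, data, root_freqs)
  } else llf <- NULL
  K <- prior$K
  use_m <- prior$rate_prior == "alternative"

  # initial state: all routes on (always irreducible), unit rates,
  # mu from its prior — guaranteed finite starting density
  st <- list(mu = sample_prior_mu(prior, 1)$mu,
             m = if (use_m) 1 else NULL,
             r = rep(1, K), delta = rep(1L, K))
  if (!is.null(settings$init))
    for (nm in names(settings$init)) st[[nm]] <- settings$init[[nm]]
  st$delta <- as.integer(st$delta)

  lp_delta <- log_prior_delta(st$delta, prior)
  lp_mu <- log_prior_mu(st$mu, st$m, prior)
  lp_r <- log_prior_relative_rates(st$r, prior)
  Qcur <- build_rate_matrix(geo_params(prior$symmetric, st$r, st$delta,
                                       st$mu, st$m), prior$k)
  ll <- if (beta > 0) llf(Qcur) else NA_real_
  if (!is.finite(lp_delta + lp_mu + lp_r) || (beta > 0 && !is.finite(ll)))
    stop("initial state has non-finite target density")

  w <- settings$move_weights
  if (!use_m) w["m"] <- 0
  if (K == 1L) w["swap"] <- 0
  moves <- names(w)[w > 0]
  pw <- w[moves] / sum(w[moves])

  win <- c(mu = 1, rate = 1, m = 1)        # multiplier windows
  acc <- prop <- setNames(numeric(length(moves)), moves)
  n_burn <- floor(settings$n_iter * settings$burnin)
  keep_at <- seq.int(n_burn + settings$thin, settings$n_iter,
                     by = settings$thin)
  n_keep <- length(keep_at)
  cols_r <- paste0("r_", seq_len(K)); cols_d <- paste0("delta_", seq_len(K))
  out <- matrix(NA_real_, n_keep,
                4L + use_m + 2L * K + 2L)
  rec_i <- 0L
  tune_acc <- tune_prop <- c(mu = 0, rate = 0, m = 0)

  newQ <- function() build_rate_matrix(
    geo_params(prior$symmetric, st$r, st$delta, st$mu, st$m), prior$k)

  for (it in seq_len(settings$n_iter)) {
    mv <- sample(moves, 1L, prob = pw)
    prop[mv] <- prop[mv] + 1
    accepted <- FALSE
    if (mv == "mu") {
      u <- runif(1, -win["mu"], win["mu"])
      mu2 <- st$mu * exp(u)
      lp_mu2 <- log_prior_mu(mu2, st$m, prior)
      st2 <- st; st2$mu <- mu2
      Q2 <- build_rate_matrix(geo_params(prior$symmetric, st$r, st$delta,
                                         mu2, st$m), prior$k)
      ll2 <- if (beta > 0) llf(Q2) else 0
      lr <- (lp_mu2 - lp_mu) + beta * (if (beta > 0) ll2 - ll else 0) + u
      if (is.finite(lr) && log(runif(1)) < lr) {
        st$mu <- mu2; lp_mu <- lp_mu2; Qcur <- Q2
        if (beta > 0) ll <- ll2
        accepted <- TRUE
      }
      if (settings$tune && it <= n_burn) {
        tune_prop["mu"] <- tune_prop["mu"] + 1
        tune_acc["mu"] <- tune_acc["mu"] + accepted
      }
    } else if (mv == "m") {
      u <- runif(1, -win["m"], win["m"])
      m2 <- st$m * exp(u)
      lp_mu2 <- log_prior_mu(st$mu, m2, prior)
      lr <- (lp_mu2 - lp_mu) + u   # likelihood unchanged: m enters prior only
      if (is.finite(lr) && log(runif(1)) < lr) {
        st$m <- m2; lp_mu <- lp_mu2; accepted <- TRUE
      }
      if (settings$tune && it <= n_burn) {
        tune_prop["m"] <- tune_prop["m"] + 1
        tune_acc["m"] <- tune_acc["m"] + accepted
      }
    } else if (mv == "rate") {
      i <- sample.int(K, 1L)
      u <- runif(1, -win["rate"], win["rate"])
      r2 <- st$r; r2[i] <- r2[i] * exp(u)
      lp_r2 <- log_prior_relative_rates(r2, prior)
      rold <- st$r
      st$r <- r2
      lik_changes <- st$delta[i] == 1L && beta > 0
      Q2 <- if (st$delta[i] == 1L) newQ() else Qcur
      ll2 <- if (lik_changes) llf(Q2) else ll
      lr <- (lp_r2 - lp_r) + beta * (if (lik_changes) ll2 - ll else 0) + u
      if (is.finite(lr) && log(runif(1)) < lr) {
        lp_r <- lp_r2; Qcur <- Q2
        if (lik_changes) ll <- ll2
        accepted <- TRUE
      } else st$r <- rold
      if (settings$tune && it <= n_burn) {
        tune_prop["rate"] <- tune_prop["rate"] + 1
        tune_acc["rate"] <- tune_acc["rate"] + accepted
      }
    } else if (mv == "flip") {
      i <- sample.int(K, 1L)
      d2 <- st$delta; d2[i] <- 1L - d2[i]
      lp_d2 <- log_prior_delta(d2, prior)
      if (is.finite(lp_d2)) {
        dold <- st$delta; st$delta <- d2
        Q2 <- newQ()
        ll2 <- if (beta > 0) llf(Q2) else 0
        lr <- (lp_d2 - lp_delta) + beta * (if (beta > 0) ll2 - ll else 0)
        if (is.finite(lr) && log(runif(1)) < lr) {
          lp_delta <- lp_d2; Qcur <- Q2
          if (beta > 0) ll <- ll2
          accepted <- TRUE
        } else st$delta <- dold
      }
    } else if (mv == "swap") {
      on <- which(st$delta == 1L); off <- which(st$delta == 0L)
      if (length(on) && length(off)) {
        d2 <- st$delta
        d2[on[sample.int(length(on), 1L)]] <- 0L
        d2[off[sample.int(length(off), 1L)]] <- 1L
        lp_d2 <- log_prior_delta(d2, prior)
        if (is.finite(lp_d2)) {
          dold <- st$delta; st$delta <- d2
          Q2 <- newQ()
          ll2 <- if (beta > 0) llf(Q2) else 0
          lr <- (lp_d2 - lp_delta) + beta * (if (beta > 0) ll2 - ll else 0)
          if (is.finite(lr) && log(runif(1)) < lr) {
            lp_delta <- lp_d2; Qcur <- Q2
            if (beta > 0) ll <- ll2
            accepted <- TRUE
          } else st$delta <- dold
        }
      }
    }
    if (accepted) acc[mv] <- acc[mv] + 1

    # adapt multiplier windows every 50 burn-in iterations, target ~0.35
    if (settings$tune && it <= n_burn && it %% 50L == 0L) {
      for (nm in c("mu", "rate", "m")) {
        if (tune_prop[nm] >= 10) {
          rate_hat <- tune_acc[nm] / tune_prop[nm]
          win[nm] <- min(20, max(1e-3, win[nm] * exp(rate_hat - 0.35)))
          tune_acc[nm] <- tune_prop[nm] <- 0
        }
      }
    }

    if (rec_i < n_keep && it == keep_at[rec_i + 1L]) {
      rec_i <- rec_i + 1L
      ll_rec <- if (beta > 0) ll else if (have_data) llf(Qcur) else NA_real_
      lp <- lp_delta + lp_mu + lp_r
      out[rec_i, ] <- c(it, st$mu, if (use_m) st$m, st$r, st$delta,
                        sum(st$delta), lp,
                        ll_rec, lp + beta * (if (is.na(ll_rec)) 0 else ll_rec))
    }
  }

  df <- as.data.frame(out)
  names(df) <- c("iter", "mu", if (use_m) "m", cols_r, cols_d,
                 "Delta", "log_prior", "log_lik", "log_post")
  attr(df, "settings") <- settings
  attr(df, "prior") <- prior
  attr(df, "acceptance") <- ifelse(prop > 0, acc / prop, NA)
  attr(df, "route_pairs") <- route_pairs(prior$k, prior$symmetric)
  class(df) <- c("geo_trace", "data.frame")
  df
}

#' Extract a parameter set from a trace row
#'
#' @param trace a `geo_trace`.
#' @param i row index.
#' @return a `geo_params` object.
#' @export
trace_params <- function(trace, i) {
  prior <- attr(trace, "prior")
  K <- prior$K
  geo_params(prior$symmetric,
             r = as.numeric(trace[i, paste0("r_", seq_len(K))]),
             delta = as.integer(trace[i, paste0("delta_", seq_len(K))]),
             mu = trace$mu[i],
             m = if ("m" %in% names(trace)) trace$m[i] else NULL)
}

#' Write a trace as a tab-separated log
#'
#' BEAST-log-like format: `#` header lines echoing the settings, then a
#' tab-separated table readable by standard trace explorers.
#'
#' @param trace a `geo_trace`.
#' @param file output path.
#' @export
write_trace <- function(trace, file) {
  s <- attr(trace, "settings")
  hdr <- sprintf("# geodisp trace: n_iter=%d burnin=%g thin=%d seed=%d beta=%g",
                 s$n_iter, s$burnin, s$thin, s$seed, s$beta)
  con <- file(file, "w"); on.exit(close(con))
  writeLines(hdr, con)
  suppressWarnings(write.table(trace, con, sep = "\t", row.names = FALSE,
                               quote = FALSE))
}

#' Read a trace log written by [write_trace()]
#' @param file path.
#' @return data.frame (without the run attributes).
#' @export
read_trace <- function(file) {
  read.csv(file, sep = "\t", comment.char = "#")
}

#' Effective sample size of a trace column
#'
#' Autocorrelation-time ESS using Geyer's initial positive-sequence
#' truncation of the empirical autocorrelation function. A constant column
#' has no autocorrelation time; its ESS is defined as the sample size,
#' with a warning.
#'
#' @param x numeric vector (>= 100 values recommended).
#' @return estimated effective sample size.
#' @export
effective_sample_size <- function(x) {
  x <- as.numeric(x)
  N <- length(x)
  if (N < 2) stop("need at least 2 samples")
  if (var(x) == 0) {
    warning("constant column; ESS defined as the sample count")
    return(N)
  }
  lag_max <- min(N - 1L, max(100L, floor(10 * sqrt(N))))
  rho <- as.vector(acf(x, lag.max = lag_max, plot = FALSE)$acf)
  tau <- 1
  m <- 1L
  while (m + 1L <= lag_max) {
    g <- rho[m + 1L] + if (m + 2L <= lag_max + 1L) rho[m + 2L] else 0
    if (g <= 0) break
    tau <- tau + 2 * g
    m <- m + 2L
  }
  min(N, N / tau)
}
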