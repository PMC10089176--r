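# Posterior-predictive simulation and model-adequacy statistics.

#' Simulate a predictive tip-area dataset
#'
#' Draws a root area from `root_freqs`, simulates the dispersal CTMC
#' forward down every branch, and collects the areas realized at the tips.
#'
#' @param tree rooted `phylo`.
#' @param params a `geo_params` draw (e.g. from [trace_params()]).
#' @param root_freqs root frequencies (uniform default).
#' @param areas area labels (defaults to `area_1..area_k` sized by params).
#' @param k number of areas; required if `areas` is `NULL` and cannot be
#'   inferred.
#' @return a `geo_data` object.
#' @export
simulate_predictive_dataset <- function(tree, params, root_freqs = NULL,
                                        areas = NULL, k = NULL) {
  if (is.null(k)) {
    if (!is.null(areas)) k <- length(areas)
    else k <- infer_k(length(params$delta), params$symmetric)
  }
  if (is.null(areas)) areas <- paste0("area_", seq_len(k))
  Q <- build_rate_matrix(params, k)
  sim <- simulate_history_and_tips(tree, Q, root_freqs = root_freqs,
                                   areas = areas)
  sim$data
}

# Internal: recover k from the route-vector length.
infer_k <- function(K, symmetric) {
  k <- if (symmetric) (1 + sqrt(1 + 8 * K)) / 2 else (1 + sqrt(1 + 4 * K)) / 2
  if (abs(k - round(k)) > 1e-9) stop("route vector length matches no k")
  as.integer(round(k))
}

#' Fitch parsimony score of the tip areas
#'
#' Minimum number of dispersal events needed to explain the observed tip
#' areas on the tree (Fitch's algorithm; binary trees only).
#'
#' @param tree rooted binary `phylo`.
#' @param data a `geo_data` object.
#' @return non-negative integer.
#' @export
parsimony_statistic <- function(tree, data) {
  if (!ape::is.binary(tree)) stop("Fitch parsimony implemented for binary trees")
  k <- n_areas(data)
  po <- ape::reorder.phylo(tree, "postorder")
  n <- length(tree$tip.label)
  M <- n + tree$Nnode
  sets <- matrix(FALSE, M, k)
  sets[cbind(seq_len(n), data$index[tree$tip.label])] <- TRUE
  score <- 0L
  seen <- logical(M)
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    if (!seen[par]) { sets[par, ] <- sets[ch, ]; seen[par] <- TRUE }
    else {
      inter <- sets[par, ] & sets[ch, ]
      if (any(inter)) sets[par, ] <- inter
      else { sets[par, ] <- sets[par, ] | sets[ch, ]; score <- score + 1L }
    }
  }
  score
}

#' Tip-wise multinomial adequacy statistic
#'
#' sum_a n_a log(n_a / n) over the observed area counts (0 log 0 := 0);
#' the maximized multinomial log-likelihood of the tip-area frequencies.
#' Zero when all tips share one area, increasingly negative for even
#' spreads; permutation-invariant over tips.
#'
#' @param data a `geo_data` object.
#' @return numeric (<= 0).
#' @export
tipwise_multinomial_statistic <- function(data) {
  cnt <- tabulate(data$index, nbins = n_areas(data))
  n <- sum(cnt)
  cnt <- cnt[cnt > 0]
  sum(cnt * log(cnt / n))
}

#' Posterior-predictive p-value for an adequacy statistic
#'
#' Lower tail = fraction of predictive values <= observed; upper tail =
#' fraction >= observed; two-sided p = 2 min(tails), capped at 1. Flagged
#' inadequate when p falls below `alpha`.
#'
#' @param observed observed statistic value.
#' @param predictive vector of predictive statistic values (>= 100).
#' @param alpha inadequacy threshold.
#' @param statistic name carried in the report.
#' @return object of class `adequacy_report`: list with `statistic`,
#'   `observed`, `predictive`, `lower_tail`, `upper_tail`, `p_value`,
#'   `inadequate`.
#' @export
posterior_predictive_pvalue <- function(observed, predictive, alpha = 0.05,
                                        statistic = "statistic") {
  if (length(predictive) < 100)
    stop("need at least 100 predictive values")
  lo <- mean(predictive <= observed)
  hi <- mean(predictive >= observed)
  p <- min(1, 2 * min(lo, hi))
  structure(list(statistic = statistic, observed = observed,
                 predictive = predictive, lower_tail = lo, upper_tail = hi,
                 p_value = p, inadequate = p < alpha, alpha = alpha),
            class = "adequacy_report")
}

#' @export
print.adequacy_report <- function(x, ...) {
  cat(sprintf("%s: observed %.4g, tails (%.3f, %.3f), p = %.3f%s\n",
              x$statistic, x$observed, x$lower_tail, x$upper_tail, x$p_value,
              if (x$inadequate) "  [INADEQUATE]" else ""))
  invisible(x)
}

#' Posterior-predictive adequacy check of a fitted model
#'
#' For each of `n_sim` (evenly subsampled) retained posterior draws,
#' simulates a replicate tip-area dataset forward over the tree and
#' evaluates the adequacy statistics on it; compares each statistic's
#' predictive distribution against its observed value.
#'
#' @param tree,data,root_freqs as elsewhere.
#' @param trace a `geo_trace`.
#' @param n_sim number of predictive datasets (>= 100).
#' @param statistics named list of functions `f(tree, data)`.
#' @param alpha inadequacy threshold.
#' @return named list of `adequacy_report` objects.
#' @export
posterior_predictive_check <- function(tree, data, trace, n_sim = 200,
                                       statistics = default_adequacy_statistics(),
                                       root_freqs = NULL, alpha = 0.05) {
  prior <- attr(trace, "prior")
  idx <- round(seq(1, nrow(trace), length.out = min(n_sim, nrow(trace))))
  if (length(idx) < n_sim) idx <- rep_len(idx, n_sim)
  sims <- lapply(idx, function(i)
    simulate_predictive_dataset(tree, trace_params(trace, i),
                                root_freqs = root_freqs, areas = data$areas))
  out <- lapply(names(statistics), function(nm) {
    f <- statistics[[nm]]
    obs <- f(tree, data)
    pred <- vapply(sims, function(s) f(tree, s), numeric(1))
    posterior_predictive_pvalue(obs, pred, alpha = alpha, statistic = nm)
  })
  setNames(out, names(statistics))
}

#' Default adequacy statistics
#'
#' The Fitch parsimony score and the tip-wise multinomial statistic — a
#' standard pair for discrete-character model adequacy. The statistic set
#' is pluggable: any named list of `f(tree, data)` functions works.
#'
#' @return named list of statistic functions.
#' @export
default_adequacy_statistics <- function() {
  list(parsimony = function(tree, data) parsimony_statistic(tree, data),
       multinomial = function(tree, data) tipwise_multinomial_statistic(data))
}
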