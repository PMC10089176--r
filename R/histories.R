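# Endpoint-conditioned dispersal histories (stochastic mapping) and their
# summaries: ancestral-area probabilities and dispersal-event counts.

# Internal: endpoint-conditioned path on one branch by uniformization.
# Returns data.frame(time, from, to) of real (non-virtual) events, times
# measured from the parent end of the branch.
sample_branch_bridge <- function(Q, t, a, b, Pab, tol = 1e-10) {
  k <- nrow(Q)
  Omega <- max(-diag(Q))
  if (Omega <= 0 || t == 0) {
    if (a != b) stop("impossible endpoint pair on a zero-rate branch")
    return(data.frame(time = numeric(0), from = integer(0), to = integer(0)))
  }
  R <- diag(k) + Q / Omega
  # sample the number of uniformized jumps n | endpoints:
  # P(n) = dpois(n, Omega t) R^n[a,b] / Pab
  u <- runif(1) * Pab
  Rn <- diag(k)          # R^0
  Rpows <- list(Rn)
  n <- 0L
  cum <- dpois(0L, Omega * t) * Rn[a, b]
  nmax <- max(20L, ceiling(Omega * t + 12 * sqrt(Omega * t) + 20))
  while (cum < u && n < nmax) {
    n <- n + 1L
    Rn <- Rn %*% R
    Rpows[[n + 1L]] <- Rn
    cum <- cum + dpois(n, Omega * t) * Rn[a, b]
  }
  if (n == 0L)
    return(data.frame(time = numeric(0), from = integer(0), to = integer(0)))
  # sample the uniformized state path bridging a -> b
  states <- integer(n + 1L); states[1L] <- a; states[n + 1L] <- b
  if (n > 1L) for (j in 2L:n) {
    prev <- states[j - 1L]
    wgt <- R[prev, ] * Rpows[[n - j + 2L]][, b]   # R^(n-j+1)[s, b]
    states[j] <- sample.int(k, 1L, prob = wgt)
  } else {
    # n == 1: the single jump must be a -> b (if a == b it is virtual)
  }
  times <- sort(runif(n)) * t
  keep <- states[-1L] != states[-(n + 1L)]
  data.frame(time = times[keep],
             from = states[-(n + 1L)][keep],
             to = states[-1L][keep])
}

# Internal oracle: endpoint-conditioned path by rejection (forward
# simulation until the endpoint matches). Exact but potentially slow;
# retained as an independent check on the uniformization sampler.
sample_branch_rejection <- function(Q, t, a, b, max_tries = 1e6) {
  for (i in seq_len(max_tries)) {
    ev <- simulate_branch_forward(Q, t, a)
    end <- if (nrow(ev)) ev$to[nrow(ev)] else a
    if (end == b) return(ev)
  }
  stop("rejection sampler failed after ", max_tries, " tries")
}

# Internal: forward (Gillespie) simulation of the CTMC on one branch.
simulate_branch_forward <- function(Q, t, a) {
  s <- a; tau <- 0
  time <- numeric(0); from <- integer(0); to <- integer(0)
  repeat {
    rate <- -Q[s, s]
    if (rate <= 0) break
    tau <- tau + rexp(1, rate)
    if (tau >= t) break
    nxt <- sample.int(nrow(Q), 1L, prob = pmax(Q[s, ], 0) *
                        (seq_len(nrow(Q)) != s))
    time <- c(time, tau); from <- c(from, s); to <- c(to, nxt)
    s <- nxt
  }
  data.frame(time = time, from = from, to = to)
}

#' Sample an endpoint-conditioned dispersal history
#'
#' Draws one realized geographic history consistent with the observed tip
#' areas: node states are sampled from their joint conditional distribution
#' (pruning down-pass followed by a stochastic root-to-tips pass), and
#' branch interiors are filled in by endpoint-conditioned CTMC sampling via
#' uniformization — exact in distribution.
#'
#' @param tree rooted `phylo`.
#' @param data `geo_data` covering every tip.
#' @param Q rate matrix (P(G | Q, tree) must be > 0).
#' @param root_freqs root frequencies (uniform default).
#' @return object of class `dispersal_history`: list with `node_state`
#'   (integer area index per node, tips first), `events` (data.frame with
#'   columns `edge`, `parent`, `child`, `time` — measured from the parent
#'   end of the branch —, `from`, `to`), `areas`, and `n_tips`.
#' @export
sample_conditional_history <- function(tree, data, Q, root_freqs = NULL) {
  k <- nrow(Q)
  if (is.null(root_freqs)) root_freqs <- rep(1 / k, k)
  prep <- prune_prep(tree, data, k)
  tpf <- make_tp_factory(Q)
  res <- prune_pass(prep, tpf, k)
  if (is.null(res$L)) stop("observed tip areas have zero likelihood under Q")
  root_w <- root_freqs * res$L[prep$root, ]
  if (sum(root_w) <= 0) stop("observed tip areas have zero likelihood under Q")
  M <- prep$M
  state <- integer(M)
  state[prep$root] <- sample.int(k, 1L, prob = root_w)
  ne <- nrow(prep$edge)
  # reverse postorder = valid preorder (parents before children)
  events <- vector("list", ne)
  for (e in rev(seq_len(ne))) {
    par <- prep$edge[e, 1L]; ch <- prep$edge[e, 2L]
    P <- res$tps[[e]]
    Lch <- res$L[ch, ]
    wgt <- P[state[par], ] * Lch
    state[ch] <- sample.int(k, 1L, prob = wgt)
    br <- sample_branch_bridge(Q, prep$len[e], state[par], state[ch],
                               Pab = P[state[par], state[ch]])
    if (nrow(br))
      events[[e]] <- data.frame(edge = e, parent = par, child = ch, br)
  }
  events <- events[!vapply(events, is.null, TRUE)]
  events <- if (length(events)) do.call(rbind, events)
  else data.frame(edge = integer(0), parent = integer(0), child = integer(0),
                  time = numeric(0), from = integer(0), to = integer(0))
  structure(list(node_state = state, events = events, areas = data$areas,
                 n_tips = prep$n),
            class = "dispersal_history")
}

#' @export
print.dispersal_history <- function(x, ...) {
  cat(sprintf("dispersal history: %d events over %d nodes (%d areas)\n",
              nrow(x$events), length(x$node_state), length(x$areas)))
  invisible(x)
}

#' Number of dispersal events in a history
#' @param history a `dispersal_history`.
#' @return integer.
#' @export
n_events <- function(history) nrow(history$events)

#' Sample several conditional histories
#' @inheritParams sample_conditional_history
#' @param n number of histories.
#' @return list of `dispersal_history` objects.
#' @export
sample_conditional_histories <- function(tree, data, Q, root_freqs = NULL,
                                         n = 100) {
  lapply(seq_len(n), function(i)
    sample_conditional_history(tree, data, Q, root_freqs))
}

#' Draw one conditional history per retained posterior sample
#'
#' Marginalizes the conditional distribution of histories over the
#' posterior of Q by drawing a single history for each (optionally
#' subsampled) retained MCMC sample — the standard practice for
#' posterior summaries of ancestral areas and event counts.
#'
#' @param tree,data,root_freqs as in [sample_conditional_history()].
#' @param trace a `geo_trace` from [run_mcmc()].
#' @param max_histories cap on the number of histories (evenly subsampled).
#' @return list of `dispersal_history` objects.
#' @export
posterior_histories <- function(tree, data, trace, root_freqs = NULL,
                                max_histories = 500) {
  prior <- attr(trace, "prior")
  idx <- seq_len(nrow(trace))
  if (length(idx) > max_histories)
    idx <- round(seq(1, nrow(trace), length.out = max_histories))
  lapply(idx, function(i) {
    Q <- build_rate_matrix(trace_params(trace, i), prior$k)
    sample_conditional_history(tree, data, Q, root_freqs)
  })
}

#' Ancestral-area probabilities from a set of histories
#'
#' The probability that an internal node was in a given area is the
#' proportion of conditional histories in which the node is in that area.
#'
#' @param histories list of `dispersal_history` objects on the same tree.
#' @return object of class `ancestral_areas`: list with `node` (internal
#'   node ids), `probs` (nodes x areas frequency matrix, rows sum to 1),
#'   and `map` (data.frame with the MAP area and its probability per node).
#' @export
ancestral_area_probabilities <- function(histories) {
  if (!length(histories)) stop("need at least one history")
  M <- length(histories[[1L]]$node_state)
  n <- histories[[1L]]$n_tips
  areas <- histories[[1L]]$areas
  k <- length(areas)
  if (!all(vapply(histories, function(h)
    length(h$node_state) == M && h$n_tips == n, TRUE)))
    stop("histories come from mismatched trees")
  nodes <- seq.int(n + 1L, M)
  counts <- matrix(0, length(nodes), k, dimnames = list(nodes, areas))
  for (h in histories) {
    s <- h$node_state[nodes]
    counts[cbind(seq_along(nodes), s)] <- counts[cbind(seq_along(nodes), s)] + 1
  }
  probs <- counts / length(histories)
  map_i <- apply(probs, 1L, which.max)
  structure(list(node = nodes, probs = probs,
                 map = data.frame(node = nodes, map_area = areas[map_i],
                                  prob = probs[cbind(seq_along(nodes), map_i)])),
            class = "ancestral_areas")
}

#' Compare MAP ancestral areas between two analyses
#'
#' Computes the fraction `p` of internal nodes shared between the two
#' summaries (identical when both were computed on the same fixed input
#' tree) and the fraction `f` of shared nodes whose MAP ancestral area
#' differs.
#'
#' @param a,b `ancestral_areas` objects.
#' @return list with `p`, `f`, and the data.frame of disagreeing nodes.
#' @export
compare_ancestral_maps <- function(a, b) {
  shared <- intersect(a$node, b$node)
  p <- length(shared) / length(union(a$node, b$node))
  ia <- match(shared, a$node); ib <- match(shared, b$node)
  differ <- a$map$map_area[ia] != b$map$map_area[ib]
  list(p = p, f = mean(differ),
       disagreements = data.frame(node = shared[differ],
                                  map_a = a$map$map_area[ia][differ],
                                  map_b = b$map$map_area[ib][differ]))
}

#' Dispersal-event counts from a set of histories
#'
#' Per ordered area pair, the mean and 2.5/97.5 percentile number of
#' dispersal events across histories; plus the percentage of all events
#' originating from each source area (mean and 95% credible interval over
#' histories — computed over histories containing at least one event).
#'
#' @param histories list of `dispersal_history` objects on the same tree.
#' @return list with `mean_counts` (k x k), `lower`, `upper` (2.5/97.5
#'   percentiles), `total_mean`, `source_pct` (data.frame `area`,
#'   `mean_pct`, `lower`, `upper`), `n_histories`, `n_with_events`.
#' @export
count_dispersal_events <- function(histories) {
  if (!length(histories)) stop("need at least one history")
  areas <- histories[[1L]]$areas
  k <- length(areas)
  H <- length(histories)
  arr <- array(0, c(k, k, H))
  for (h in seq_len(H)) {
    ev <- histories[[h]]$events
    if (nrow(ev))
      for (r in seq_len(nrow(ev)))
        arr[ev$from[r], ev$to[r], h] <- arr[ev$from[r], ev$to[r], h] + 1
  }
  mean_counts <- apply(arr, c(1, 2), mean)
  lower <- apply(arr, c(1, 2), quantile, probs = 0.025)
  upper <- apply(arr, c(1, 2), quantile, probs = 0.975)
  dimnames(mean_counts) <- dimnames(lower) <- dimnames(upper) <-
    list(areas, areas)
  tot <- apply(arr, 3, sum)
  with_ev <- which(tot > 0)
  if (length(with_ev)) {
    pct <- sapply(with_ev, function(h) 100 * rowSums(arr[, , h, drop = FALSE][, , 1]) / tot[h])
    pct <- matrix(pct, nrow = k)
    src <- data.frame(area = areas,
                      mean_pct = rowMeans(pct),
                      lower = apply(pct, 1, quantile, probs = 0.025),
                      upper = apply(pct, 1, quantile, probs = 0.975))
  } else {
    src <- data.frame(area = areas, mean_pct = NA_real_,
                      lower = NA_real_, upper = NA_real_)
  }
  rownames(src) <- NULL
  list(mean_counts = mean_counts, lower = lower, upper = upper,
       total_mean = mean(tot), source_pct = src,
       n_histories = H, n_with_events = length(with_ev))
}
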