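# Felsenstein pruning for tip areas on a fixed time tree.

# Internal: shared postorder bookkeeping. Returns edge matrix in postorder,
# branch lengths, and tip partial-likelihood matrix.
prune_prep <- function(tree, data, k) {
  if (n_areas(data) != k)
    stop("rate matrix dimension ", k, " does not match k = ", n_areas(data))
  miss <- setdiff(tree$tip.label, names(data$index))
  if (length(miss)) stop("tips without area data: ", paste(miss, collapse = ", "))
  po <- ape::reorder.phylo(tree, "postorder")
  n <- length(tree$tip.label)
  M <- n + tree$Nnode
  tipL <- matrix(0, M, k)
  tipL[cbind(seq_len(n), data$index[tree$tip.label])] <- 1
  list(edge = po$edge, len = po$edge.length, tipL = tipL, n = n, M = M,
       root = n + 1L)
}

# Internal: pruning pass returning per-node partials (each internal node
# scaled to max 1) and the accumulated log scaling factor.
prune_pass <- function(prep, tpf, k) {
  L <- prep$tipL
  logscale <- 0
  tps <- vector("list", nrow(prep$edge))
  for (e in seq_len(nrow(prep$edge))) {
    par <- prep$edge[e, 1L]; ch <- prep$edge[e, 2L]
    P <- tpf(prep$len[e])
    tps[[e]] <- P
    contrib <- as.vector(P %*% L[ch, ])
    if (all(contrib == 0)) return(list(loglik = -Inf))
    row <- if (any(L[par, ] != 0) || par <= prep$n) L[par, ] else rep(1, k)
    row <- row * contrib
    m <- max(row)
    if (m == 0) return(list(loglik = -Inf))
    L[par, ] <- row / m
    logscale <- logscale + log(m)
  }
  list(L = L, logscale = logscale, tps = tps)
}

#' Phylogenetic likelihood of tip areas by pruning
#'
#' Computes log P(G | Q, tree) with Felsenstein's pruning algorithm,
#' using underflow-safe per-node rescaling. A tip pattern with probability
#' exactly zero (e.g. an area unreachable under a reducible Q) returns
#' `-Inf` rather than raising, so Metropolis-Hastings rejection can handle
#' such proposals.
#'
#' @param tree a rooted `phylo` with branch lengths in time units.
#' @param data a `geo_data` object covering every tip.
#' @param Q k x k rate matrix (see [build_rate_matrix()]).
#' @param root_freqs probability vector over areas at the root; uniform by
#'   default (the standard discrete-phylogeography choice).
#' @return log-likelihood (scalar; possibly `-Inf`).
#' @export
pruning_log_likelihood <- function(tree, data, Q, root_freqs = NULL) {
  k <- nrow(Q)
  if (is.null(root_freqs)) root_freqs <- rep(1 / k, k)
  if (length(root_freqs) != k || abs(sum(root_freqs) - 1) > 1e-8)
    stop("root_freqs must be a length-k probability vector")
  prep <- prune_prep(tree, data, k)
  res <- prune_pass(prep, make_tp_factory(Q), k)
  if (is.null(res$L)) return(-Inf)
  tot <- sum(root_freqs * res$L[prep$root, ])
  if (tot <= 0) return(-Inf)
  log(tot) + res$logscale
}

# Internal: returns function(Q) -> loglik with tree/data prep hoisted out,
# used by the MCMC engine where the likelihood is evaluated thousands of
# times on the same tree.
loglik_factory <- function(tree, data, root_freqs = NULL) {
  k <- n_areas(data)
  if (is.null(root_freqs)) root_freqs <- rep(1 / k, k)
  prep <- prune_prep(tree, data, k)
  function(Q) {
    if (isTRUE(attr(Q, "degenerate"))) {
      # zero rate matrix: tips must all share one area
      tips <- data$index[tree$tip.label]
      if (length(unique(tips)) > 1L) return(-Inf)
      return(log(root_freqs[tips[1L]]))
    }
    res <- prune_pass(prep, make_tp_factory(Q), k)
    if (is.null(res$L)) return(-Inf)
    tot <- sum(root_freqs * res$L[prep$root, ])
    if (tot <= 0) return(-Inf)
    log(tot) + res$logscale
  }
}
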