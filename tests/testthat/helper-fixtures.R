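# Shared fixtures and independent oracles used across the suite.

# Exhaustive state-assignment likelihood oracle: sums over every joint
# assignment of internal-node states, using exp(Qt) per branch. Feasible
# for <= 5 tips and small k; independent of the pruning code path.
brute_force_loglik <- function(tree, data, Q, root_freqs = NULL) {
  k <- nrow(Q)
  if (is.null(root_freqs)) root_freqs <- rep(1 / k, k)
  n <- length(tree$tip.label)
  M <- n + tree$Nnode
  Qm <- matrix(as.numeric(Q), k, k)
  tp <- lapply(seq_len(nrow(tree$edge)), function(e)
    as.matrix(Matrix::expm(Qm * tree$edge.length[e])))
  tip_state <- data$index[tree$tip.label]
  internals <- seq.int(n + 1L, M)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internals))))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    st <- integer(M)
    st[seq_len(n)] <- tip_state
    st[internals] <- grid[g, ]
    p <- root_freqs[st[n + 1L]]
    for (e in seq_len(nrow(tree$edge))) {
      p <- p * tp[[e]][st[tree$edge[e, 1L]], st[tree$edge[e, 2L]]]
      if (p == 0) break
    }
    total <- total + p
  }
  if (total <= 0) -Inf else log(total)
}

# All 2^K indicator vectors for small K.
enumerate_delta <- function(K) {
  as.matrix(expand.grid(rep(list(0:1), K)))
}

# Connectivity of a symmetric route set by direct search (oracle for the
# counting recurrence).
connected_by_enumeration <- function(delta, k) {
  rp <- route_pairs(k, TRUE)
  on <- which(delta == 1)
  if (!length(on)) return(FALSE)
  seen <- c(1L)
  repeat {
    grew <- FALSE
    for (i in on) {
      a <- rp[i, 1]; b <- rp[i, 2]
      if (a %in% seen && !(b %in% seen)) { seen <- c(seen, b); grew <- TRUE }
      if (b %in% seen && !(a %in% seen)) { seen <- c(seen, a); grew <- TRUE }
    }
    if (!grew) break
  }
  length(seen) == k
}

# Random tip-area data over a tree.
random_geo_data <- function(tree, k) {
  areas <- paste0("a", seq_len(k))
  geo_data(setNames(sample(areas, length(tree$tip.label), replace = TRUE),
                    tree$tip.label), areas = areas)
}

# Random symmetric geo model with all routes open.
random_dense_params <- function(k, mu = NULL) {
  K <- n_routes(k, TRUE)
  geo_params(TRUE, r = rgamma(K, 2, 2), delta = rep(1L, K),
             mu = if (is.null(mu)) rgamma(1, 2, 2) else mu)
}

# Marginal area probabilities at each tip by propagating exp(Qt) from the
# root along the unique root-to-tip path (oracle for forward simulators).
tip_marginals_by_propagation <- function(tree, Q, root_freqs = NULL) {
  k <- nrow(Q)
  if (is.null(root_freqs)) root_freqs <- rep(1 / k, k)
  n <- length(tree$tip.label)
  parent <- integer(n + tree$Nnode)
  elen <- numeric(n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  tpf <- function(t) transition_probabilities(Q, t)
  out <- matrix(0, n, k)
  for (tip in seq_len(n)) {
    path <- integer(0)
    v <- tip
    while (v != n + 1L) { path <- c(v, path); v <- parent[v] }
    p <- root_freqs
    for (v in path) p <- as.vector(p %*% tpf(elen[v]))
    out[tip, ] <- p
  }
  out
}
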