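#' Number of candidate dispersal routes
#'
#' K = k(k-1)/2 for a symmetric model (unordered pairs of areas),
#' K = k(k-1) for an asymmetric model (ordered pairs).
#'
#' @param k number of areas.
#' @param symmetric logical.
#' @return integer K.
#' @export
n_routes <- function(k, symmetric = TRUE) {
  k <- as.integer(k)
  if (k < 2) stop("k must be >= 2")
  if (symmetric) (k * (k - 1L)) %/% 2L else k * (k - 1L)
}

#' Route index table
#'
#' Deterministic ordering of the candidate dispersal routes used everywhere
#' in the package (prior vectors r and delta, trace columns, Bayes-factor
#' tables). Symmetric models enumerate unordered pairs (1,2),(1,3),...;
#' asymmetric models enumerate ordered pairs row-major, skipping i = j.
#'
#' @param k number of areas.
#' @param symmetric logical.
#' @return integer matrix with columns `from`, `to` and K rows.
#' @export
route_pairs <- function(k, symmetric = TRUE) {
  if (symmetric) {
    cb <- combn(k, 2L)
    cbind(from = cb[1L, ], to = cb[2L, ])
  } else {
    fr <- rep(seq_len(k), each = k); to <- rep(seq_len(k), k)
    keep <- fr != to
    cbind(from = fr[keep], to = to[keep])
  }
}

#' Geographic model parameters
#'
#' Bundles the parameters that determine the dispersal rate matrix Q:
#' relative rates r (> 0), route indicators delta (0/1), the average
#' dispersal rate mu (> 0, expected dispersal events per unit time), and —
#' under the hierarchical alternative rate prior — the latent hyper-mean m
#' of the exponential prior on mu.
#'
#' @param symmetric logical; symmetric Q has q_ij = q_ji.
#' @param r numeric vector of relative rates, length K (see [n_routes()]).
#' @param delta integer/logical vector of route indicators, length K.
#' @param mu average dispersal rate (> 0).
#' @param m optional hyper-mean (> 0), alternative rate prior only.
#' @return an object of class `geo_params`.
#' @export
geo_params <- function(symmetric, r, delta, mu, m = NULL) {
  delta <- as.integer(delta)
  if (length(r) != length(delta)) stop("r and delta must have equal length")
  if (any(r <= 0)) stop("relative rates must be > 0")
  if (!all(delta %in% c(0L, 1L))) stop("delta entries must be 0 or 1")
  if (mu < 0) stop("mu must be >= 0")
  if (!is.null(m) && m <= 0) stop("m must be > 0")
  structure(list(symmetric = isTRUE(symmetric), r = as.numeric(r),
                 delta = delta, mu = as.numeric(mu), m = m),
            class = "geo_params")
}

#' @export
print.geo_params <- function(x, ...) {
  cat(sprintf("geo_params: %s, K = %d routes, Delta = %d, mu = %g%s\n",
              if (x$symmetric) "symmetric" else "asymmetric",
              length(x$delta), sum(x$delta), x$mu,
              if (is.null(x$m)) "" else sprintf(", m = %g", x$m)))
  invisible(x)
}

#' Build the instantaneous-rate matrix Q
#'
#' Off-diagonal entries are first set to r_ij * delta_ij (mirrored for a
#' symmetric model), then the whole matrix is rescaled so that the mean
#' off-diagonal flow under uniform area weights equals mu:
#' (1/k) * sum_{i != j} q_ij = mu. Uniform weights (rather than the
#' stationary distribution) keep the convention well defined for reducible
#' configurations. Diagonals are the negative row sums.
#'
#' If all indicators are zero (Delta = 0), or mu = 0, the matrix is
#' identically zero and is flagged degenerate via `attr(Q, "degenerate")`.
#'
#' @param params a `geo_params` object.
#' @param k number of areas.
#' @return k x k numeric matrix with attributes `mu` and `degenerate`.
#' @examples
#' p <- geo_params(TRUE, r = 1, delta = 1, mu = 1)
#' build_rate_matrix(p, 2) # [[-1, 1], [1, -1]]
#' @export
build_rate_matrix <- function(params, k) {
  stopifnot(inherits(params, "geo_params"))
  K <- n_routes(k, params$symmetric)
  if (length(params$r) != K)
    stop("parameter length ", length(params$r), " does not match K = ", K,
         " for k = ", k)
  rp <- route_pairs(k, params$symmetric)
  Q <- matrix(0, k, k)
  w <- params$r * params$delta
  Q[rp] <- w
  if (params$symmetric) Q[rp[, c(2L, 1L), drop = FALSE]] <- w
  tot <- sum(Q)
  if (sum(params$delta) == 0L || tot == 0 || params$mu == 0) {
    Q[] <- 0
    attr(Q, "mu") <- params$mu
    attr(Q, "degenerate") <- TRUE
    return(Q)
  }
  Q <- Q * (params$mu * k / tot)
  diag(Q) <- -rowSums(Q)
  attr(Q, "mu") <- params$mu
  attr(Q, "degenerate") <- FALSE
  Q
}

# Internal: factory of transition-probability matrices P(t) = exp(Qt).
# Symmetric Q uses a symmetric eigendecomposition; a general Q tries a
# (possibly complex) eigendecomposition and falls back to Pade
# scaling-and-squaring (Matrix::expm) when the eigenbasis is ill
# conditioned. Rows are clamped to [0, 1] and renormalized to absorb
# rounding at the 1e-12 level.
make_tp_factory <- function(Q, tol = 1e-12) {
  k <- nrow(Q)
  Qm <- Q; attributes(Qm) <- list(dim = dim(Q))
  clean <- function(P) {
    P[P < 0] <- 0
    rs <- rowSums(P)
    if (any(rs <= 0)) stop("invalid transition matrix")
    P / rs
  }
  if (isSymmetric.matrix(Qm, tol = 1e-10)) {
    e <- eigen(Qm, symmetric = TRUE)
    V <- e$vectors; val <- e$values
    return(function(t) {
      if (t == 0) return(diag(k))
      clean(V %*% (exp(val * t) * t(V)))
    })
  }
  e <- tryCatch(eigen(Qm), error = function(e) NULL)
  ok <- FALSE
  if (!is.null(e)) {
    Vi <- tryCatch(solve(e$vectors), error = function(e) NULL)
    if (!is.null(Vi)) {
      # accept the eigenbasis only if it reproduces Q accurately
      chk <- Re(e$vectors %*% (e$values * Vi))
      ok <- max(abs(chk - Qm)) < 1e-8 * max(1, max(abs(Qm)))
    }
  }
  if (ok) {
    V <- e$vectors; val <- e$values
    function(t) {
      if (t == 0) return(diag(k))
      clean(Re(V %*% (exp(val * t) * Vi)))
    }
  } else {
    function(t) {
      if (t == 0) return(diag(k))
      clean(as.matrix(Matrix::expm(Qm * t)))
    }
  }
}

#' Transition probabilities over a branch
#'
#' Computes P(t) = exp(Qt). Rows sum to one; all entries are non-negative.
#'
#' @param Q a k x k rate matrix (rows summing to zero).
#' @param t branch duration (>= 0).
#' @return k x k stochastic matrix.
#' @export
transition_probabilities <- function(Q, t) {
  if (t < 0) stop("t must be >= 0")
  make_tp_factory(Q)(t)
}
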