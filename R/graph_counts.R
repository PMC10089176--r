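# Counting and checking dispersal-route configurations.

#' Is a route configuration irreducible?
#'
#' A geographic model is irreducible when every area can be reached from
#' every other area, directly or indirectly. For a symmetric model this is
#' connectivity of the undirected graph whose edges are the routes with
#' delta = 1; for an asymmetric model it is strong connectivity of the
#' corresponding digraph.
#'
#' @param delta 0/1 vector over the routes of [route_pairs()].
#' @param k number of areas.
#' @param symmetric logical.
#' @return logical.
#' @export
is_irreducible_delta <- function(delta, k, symmetric = TRUE) {
  rp <- route_pairs(k, symmetric)
  on <- which(delta == 1L)
  if (!length(on)) return(FALSE)
  adj <- vector("list", k)
  for (i in on) {
    a <- rp[i, 1L]; b <- rp[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    if (symmetric) adj[[b]] <- c(adj[[b]], a)
  }
  reach <- function(adj) {
    seen <- logical(k); seen[1L] <- TRUE; stack <- 1L
    while (length(stack)) {
      v <- stack[1L]; stack <- stack[-1L]
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; stack <- c(stack, w) }
    }
    all(seen)
  }
  if (symmetric) return(reach(adj))
  radj <- vector("list", k)
  for (i in on) {
    a <- rp[i, 1L]; b <- rp[i, 2L]
    radj[[b]] <- c(radj[[b]], a)
  }
  reach(adj) && reach(radj)
}

# memo cache for connected-graph counts
.conn_cache <- new.env(parent = emptyenv())

# Number of connected labelled graphs on n vertices with m edges, by the
# standard recurrence over the component containing vertex 1:
#   C(n, m) = T(n, m) - sum_{s=1}^{n-1} choose(n-1, s-1)
#                         sum_j C(s, j) T(n-s, m-j)
# with T(n, m) = choose(n(n-1)/2, m).
connected_graph_count <- function(n, m) {
  if (n == 1L) return(as.numeric(m == 0L))
  if (m < n - 1L || m > n * (n - 1L) / 2) return(0)
  key <- paste(n, m)
  hit <- .conn_cache[[key]]
  if (!is.null(hit)) return(hit)
  tot <- function(nn, mm) {
    if (mm < 0) return(0)
    choose(nn * (nn - 1L) / 2, mm)
  }
  val <- tot(n, m)
  for (s in seq_len(n - 1L)) {
    mx <- s * (s - 1L) / 2
    for (j in max(0L, s - 1L):mx) {
      t2 <- tot(n - s, m - j)
      if (t2 > 0) val <- val - choose(n - 1L, s - 1L) *
          connected_graph_count(s, j) * t2
    }
  }
  .conn_cache[[key]] <- val
  val
}

#' Count route configurations with a given number of routes
#'
#' Number of indicator vectors delta with sum(delta) = `Delta` that are,
#' if required, irreducible. For the symmetric model with the
#' irreducibility requirement this is the number of connected labelled
#' graphs on k vertices with `Delta` edges (computed by an exact counting
#' recurrence); otherwise it is simply choose(K, Delta).
#'
#' @param k number of areas.
#' @param Delta number of routes (0 <= Delta <= K).
#' @param symmetric logical.
#' @param require_irreducible logical; only meaningful for symmetric models
#'   (the asymmetric prior does not enforce irreducibility).
#' @return a non-negative count (numeric; exact for the sizes in scope).
#' @examples
#' count_configurations(3, 2) # 3 (the three two-route models on 3 areas)
#' count_configurations(4, 3) # 16 (spanning trees of K4)
#' @export
count_configurations <- function(k, Delta, symmetric = TRUE,
                                 require_irreducible = symmetric) {
  K <- n_routes(k, symmetric)
  if (Delta < 0 || Delta > K) stop("Delta out of range [0, ", K, "]")
  if (!symmetric || !require_irreducible) return(choose(K, Delta))
  connected_graph_count(k, Delta)
}
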