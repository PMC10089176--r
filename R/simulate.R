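# Synthetic data: random time trees, forward-simulated dispersal
# histories with known ground truth, and benchmark fixture suites.

#' Simulate a random time-calibrated tree
#'
#' Yule trees are grown forward from two lineages at the root: while j
#' lineages are alive the next split occurs after an Exponential(j * rate)
#' waiting time; after the n-th lineage appears the tree is extended by a
#' final Exponential(n * rate) waiting time, so every pendant branch has
#' positive length. (For n = 2 this gives E\[T\] = 1/rate.) Coalescent
#' trees come from [ape::rcoal()] with branch lengths scaled by the
#' population size, so for n = 2 the expected total length is
#' 2 * pop_size.
#'
#' @param n_tips number of tips (>= 2).
#' @param model `"yule"` or `"coalescent"`.
#' @param rate Yule branching rate (per lineage per time unit).
#' @param pop_size coalescent population size (time scaling).
#' @param seed optional RNG seed for reproducibility.
#' @return a rooted, binary, time-calibrated `phylo`.
#' @export
simulate_tree <- function(n_tips, model = c("yule", "coalescent"),
                          rate = 1, pop_size = 1, seed = NULL) {
  model <- match.arg(model)
  if (n_tips < 2) stop("n_tips must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  if (model == "coalescent") {
    tr <- ape::rcoal(n_tips)
    tr$edge.length <- tr$edge.length * pop_size
    return(tr)
  }
  n <- as.integer(n_tips)
  # pending lineages: origin node and start time
  next_internal <- n + 2L
  origin <- c(n + 1L, n + 1L); start <- c(0, 0)
  edges <- matrix(0L, 0L, 2L); elen <- numeric(0)
  now <- 0
  while (length(origin) < n) {
    j <- length(origin)
    now <- now + rexp(1, j * rate)
    i <- sample.int(j, 1L)
    node <- next_internal; next_internal <- next_internal + 1L
    edges <- rbind(edges, c(origin[i], node))
    elen <- c(elen, now - start[i])
    origin <- c(origin[-i], node, node)
    start <- c(start[-i], now, now)
  }
  now <- now + rexp(1, n * rate)
  tip_order <- sample.int(n)   # random tip labelling
  for (i in seq_along(origin)) {
    edges <- rbind(edges, c(origin[i], tip_order[i]))
    elen <- c(elen, now - start[i])
  }
  tr <- list(edge = edges, edge.length = elen,
             tip.label = paste0("t", seq_len(n)), Nnode = n - 1L)
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  validate_tree(tr)
  tr
}

#' Forward-simulate a dispersal history and the induced tip areas
#'
#' Exact Gillespie simulation of the dispersal CTMC from the root down
#' every branch: in state i the waiting time to the next event is
#' Exponential(-q_ii) and the destination is chosen proportional to q_ij.
#' Returns both the full timed event history (ground truth for validating
#' stochastic mapping) and the induced tip-area data.
#'
#' @param tree rooted `phylo`.
#' @param Q k x k rate matrix.
#' @param root_area optional fixed root area (index or label).
#' @param root_freqs root frequencies used when `root_area` is `NULL`
#'   (uniform default).
#' @param areas area labels (default `area_1..area_k`).
#' @return list with `history` (a `dispersal_history`) and `data`
#'   (a `geo_data`).
#' @export
simulate_history_and_tips <- function(tree, Q, root_area = NULL,
                                      root_freqs = NULL, areas = NULL) {
  k <- nrow(Q)
  if (is.null(areas)) areas <- paste0("area_", seq_len(k))
  if (length(areas) != k) stop("areas must have length k")
  n <- length(tree$tip.label)
  M <- n + tree$Nnode
  root <- n + 1L
  if (is.null(root_area)) {
    if (is.null(root_freqs)) root_freqs <- rep(1 / k, k)
    root_state <- sample.int(k, 1L, prob = root_freqs)
  } else {
    root_state <- if (is.character(root_area)) match(root_area, areas)
    else as.integer(root_area)
    if (is.na(root_state) || root_state < 1L || root_state > k)
      stop("invalid root_area")
  }
  po <- ape::reorder.phylo(tree, "postorder")
  state <- integer(M); state[root] <- root_state
  ne <- nrow(po$edge)
  events <- vector("list", ne)
  for (e in rev(seq_len(ne))) {   # preorder
    par <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    ev <- simulate_branch_forward(Q, po$edge.length[e], state[par])
    state[ch] <- if (nrow(ev)) ev$to[nrow(ev)] else state[par]
    if (nrow(ev))
      events[[e]] <- data.frame(edge = e, parent = par, child = ch, ev)
  }
  events <- events[!vapply(events, is.null, TRUE)]
  events <- if (length(events)) do.call(rbind, events)
  else data.frame(edge = integer(0), parent = integer(0), child = integer(0),
                  time = numeric(0), from = integer(0), to = integer(0))
  history <- structure(list(node_state = state, events = events,
                            areas = areas, n_tips = n),
                       class = "dispersal_history")
  data <- geo_data(setNames(areas[state[seq_len(n)]], tree$tip.label),
                   areas = areas)
  list(history = history, data = data)
}

#' Define a simulation scenario
#'
#' @param name scenario label.
#' @param n_tips,k tree and area sizes.
#' @param tree_model `"yule"` or `"coalescent"`.
#' @param tree_rate Yule rate or coalescent population size.
#' @param route_density `"sparse"` (a random spanning tree of areas,
#'   Delta = k - 1) or `"dense"` (all routes on, Delta = K).
#' @param events_target expected total number of dispersal events over the
#'   tree; mu is set to `events_target / T` after the tree is simulated.
#' @param seed scenario RNG seed.
#' @return list of class `simulation_scenario`.
#' @export
simulation_scenario <- function(name, n_tips = 20, k = 3,
                                tree_model = "yule", tree_rate = 1,
                                route_density = c("sparse", "dense"),
                                events_target = 2 * k, seed = 1) {
  route_density <- match.arg(route_density)
  structure(list(name = name, n_tips = n_tips, k = k,
                 tree_model = tree_model, tree_rate = tree_rate,
                 route_density = route_density,
                 events_target = events_target, seed = as.integer(seed)),
            class = "simulation_scenario")
}

# Internal: a random spanning tree over k areas as a delta vector
# (symmetric route indexing).
random_spanning_tree_delta <- function(k) {
  rp <- route_pairs(k, TRUE)
  key <- function(a, b) which(rp[, 1L] == min(a, b) & rp[, 2L] == max(a, b))
  delta <- integer(nrow(rp))
  inside <- sample.int(k, 1L)
  outside <- setdiff(seq_len(k), inside)
  while (length(outside)) {
    a <- inside[sample.int(length(inside), 1L)]
    b <- outside[sample.int(length(outside), 1L)]
    delta[key(a, b)] <- 1L
    inside <- c(inside, b); outside <- setdiff(outside, b)
  }
  delta
}

#' Realize a scenario: tree, true process, tip data
#'
#' @param scenario a `simulation_scenario`.
#' @return list with `tree`, `params` (true `geo_params`), `Q`, `history`,
#'   `data`, `T`, and the scenario.
#' @export
simulate_scenario <- function(scenario) {
  set.seed(scenario$seed)
  tree <- simulate_tree(scenario$n_tips, scenario$tree_model,
                        rate = scenario$tree_rate,
                        pop_size = scenario$tree_rate)
  Tlen <- tree_length(tree)
  k <- scenario$k
  K <- n_routes(k, TRUE)
  delta <- if (scenario$route_density == "dense") rep(1L, K)
  else random_spanning_tree_delta(k)
  r <- rgamma(K, shape = 2, rate = 2)   # mild spread around 1
  mu <- scenario$events_target / Tlen
  params <- geo_params(TRUE, r = r, delta = delta, mu = mu)
  Q <- build_rate_matrix(params, k)
  sim <- simulate_history_and_tips(tree, Q)
  list(scenario = scenario, tree = tree, params = params, Q = Q,
       history = sim$history, data = sim$data, T = Tlen)
}

#' Write a benchmark fixture suite
#'
#' Generates a small set of scenarios spanning the empirically common
#' ranges (k in 3/5/8, 20-50 tips, sparse vs dense true route sets, low vs
#' high dispersal rate) and writes, per scenario, `tree.nwk`, `tips.csv`,
#' `truth.json` (true parameters and event counts) and a `manifest.json`
#' with all seeds. Byte-identical given the same master seed. Sparse
#' scenarios have true Delta below, dense scenarios above, the default
#' prior mean k - 1 + ln 2, so prior-contrast experiments on these
#' fixtures are informative.
#'
#' @param dir output directory (created if needed).
#' @param master_seed integer master seed.
#' @return invisibly, the manifest as a list.
#' @export
make_benchmark_suite <- function(dir, master_seed = 20230310) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  specs <- list(
    list(name = "k3_sparse_low", n_tips = 20, k = 3, density = "sparse", mult = 1),
    list(name = "k3_dense_high", n_tips = 20, k = 3, density = "dense", mult = 4),
    list(name = "k5_sparse_low", n_tips = 50, k = 5, density = "sparse", mult = 1),
    list(name = "k5_dense_high", n_tips = 50, k = 5, density = "dense", mult = 4),
    list(name = "k8_sparse_low", n_tips = 50, k = 8, density = "sparse", mult = 1),
    list(name = "k8_dense_high", n_tips = 50, k = 8, density = "dense", mult = 4))
  manifest <- list(master_seed = master_seed, scenarios = list())
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    seed <- (master_seed + i * 1009L) %% .Machine$integer.max
    sc <- simulation_scenario(sp$name, n_tips = sp$n_tips, k = sp$k,
                              route_density = sp$density,
                              events_target = sp$mult * sp$k, seed = seed)
    sim <- simulate_scenario(sc)
    sdir <- file.path(dir, paste0("scenario_", sp$name))
    dir.create(sdir, showWarnings = FALSE)
    write_newick(sim$tree, file.path(sdir, "tree.nwk"))
    write_tip_areas(sim$data, file.path(sdir, "tips.csv"))
    truth <- list(k = sp$k, symmetric = TRUE, r = sim$params$r,
                  delta = sim$params$delta, mu = sim$params$mu,
                  T = sim$T, Delta = sum(sim$params$delta),
                  root_area = sim$data$areas[sim$history$node_state[sp$n_tips + 1L]],
                  n_events = n_events(sim$history))
    jsonlite::write_json(truth, file.path(sdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$scenarios[[sp$name]] <-
      list(seed = seed, n_tips = sp$n_tips, k = sp$k,
           route_density = sp$density, events_target = sp$mult * sp$k)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
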