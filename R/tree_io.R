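#' Read a rooted time tree from newick text or file
#'
#' Parses a newick string (or file) into an [ape::phylo] object and
#' validates it for discrete-geographic analysis: the tree must be rooted,
#' every branch must carry a non-negative length (interpreted as time in
#' the tree's own units), and tip labels must be unique.
#'
#' A tree whose total length is zero is accepted by this reader (the
#' degenerate case is occasionally useful in tests) but is rejected by the
#' inference functions; see [validate_tree_for_inference()].
#'
#' @param text newick string; exactly one of `text`/`file` must be given.
#' @param file path to a newick file.
#' @return an object of class `phylo`.
#' @examples
#' tr <- read_newick_tree("((A:1,B:1):1,C:2);")
#' tree_length(tr) # 5
#' @export
read_newick_tree <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  tree <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(file)
  if (is.null(tree)) stop("failed to parse newick input")
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  validate_tree(tree)
  tree
}

#' Read the first tree from a NEXUS TREES block
#'
#' @param file path to a NEXUS file.
#' @return an object of class `phylo`.
#' @export
read_nexus_tree <- function(file) {
  tree <- ape::read.nexus(file)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  validate_tree(tree)
  tree
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("every branch must have a branch length")
  if (any(tree$edge.length < 0)) stop("negative branch lengths are not allowed")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  invisible(tree)
}

#' Total tree length
#'
#' Sum of the durations of all branches, `T`. Under the rescaled CTMC the
#' expected number of dispersal events over the whole tree is `mu * T`.
#'
#' @param tree a `phylo` object.
#' @return numeric scalar.
#' @export
tree_length <- function(tree) sum(tree$edge.length)

#' Check that a tree is usable for inference
#'
#' Inference requires strictly positive total tree length; a tree whose
#' branches are all of length zero carries no information about dispersal.
#'
#' @param tree a `phylo` object.
#' @return the tree, invisibly; errors otherwise.
#' @export
validate_tree_for_inference <- function(tree) {
  validate_tree(tree)
  if (tree_length(tree) <= 0) stop("total tree length must be > 0 for inference")
  invisible(tree)
}

#' Write a tree as newick
#'
#' @param tree a `phylo` object.
#' @param file optional path; if `NULL` the newick string is returned.
#' @return the newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, file = NULL) {
  if (is.null(file)) ape::write.tree(tree, digits = 15)
  else {
    ape::write.tree(tree, file = file, digits = 15)
    invisible(ape::write.tree(tree, digits = 15))
  }
}

#' Write a tree annotated with ancestral-area probabilities
#'
#' Emits newick with BEAST-style bracketed node comments of the form
#' `[&area_probs={p1,...,pk},MAP_area=x]` attached to internal nodes, as
#' produced by [ancestral_area_probabilities()].
#'
#' @param tree a `phylo` object.
#' @param anc an `ancestral_areas` object for this tree.
#' @param file optional output path.
#' @param digits digits used for probabilities.
#' @return the annotated newick string (invisibly if written to file).
#' @export
write_annotated_newick <- function(tree, anc, file = NULL, digits = 4) {
  stopifnot(inherits(anc, "ancestral_areas"))
  n <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  elen <- numeric(n + tree$Nnode)
  elen[tree$edge[, 2L]] <- tree$edge.length
  probs <- anc$probs
  node_comment <- function(node) {
    i <- match(node, anc$node)
    if (is.na(i)) return("")
    p <- probs[i, ]
    sprintf("[&area_probs={%s},MAP_area=%s]",
            paste(formatC(p, digits = digits, format = "g"), collapse = ","),
            colnames(probs)[which.max(p)])
  }
  build <- function(node, root) {
    if (node <= n) {
      lab <- tree$tip.label[node]
      if (root) lab else sprintf("%s:%s", lab, format(elen[node], digits = 15))
    } else {
      inner <- paste(vapply(kids[[as.character(node)]],
                            build, "", root = FALSE), collapse = ",")
      s <- sprintf("(%s)%s", inner, node_comment(node))
      if (root) s else sprintf("%s:%s", s, format(elen[node], digits = 15))
    }
  }
  out <- paste0(build(n + 1L, TRUE), ";")
  if (!is.null(file)) { writeLines(out, file); return(invisible(out)) }
  out
}

#' Read a run configuration from YAML or JSON
#'
#' @param path path ending in `.yaml`/`.yml` or `.json`.
#' @return a named list.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("unsupported config format: ", ext)
}
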