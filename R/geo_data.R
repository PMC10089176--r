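#' Tip-to-area assignments
#'
#' Container for the observed geographic data G: an ordered vector of area
#' labels (k >= 2) and a map from tip label to area index. The ordering of
#' `areas` fixes the row/column indexing of the rate matrix Q, so it must
#' be deterministic; by default areas are ordered lexicographically.
#'
#' @param assignments named character vector: names are tip labels, values
#'   area labels.
#' @param areas optional explicit ordered vector of area labels. Supplying
#'   it is the only way to declare areas that were not sampled: k sets the
#'   prior on route numbers, so it is never inflated silently.
#' @return an object of class `geo_data` with fields `areas` (character)
#'   and `index` (named integer, 1-based area index per tip).
#' @examples
#' g <- geo_data(c(A = "x", B = "x", C = "y"))
#' n_areas(g) # 2
#' @export
geo_data <- function(assignments, areas = NULL) {
  if (is.null(names(assignments)) || anyDuplicated(names(assignments)))
    stop("assignments must be uniquely named by tip label")
  assignments <- vapply(assignments, as.character, "")
  if (is.null(areas)) areas <- sort(unique(unname(assignments)))
  areas <- as.character(areas)
  if (anyDuplicated(areas)) stop("area labels must be unique")
  if (length(areas) < 2) stop("at least two areas are required (k >= 2)")
  idx <- match(assignments, areas)
  if (anyNA(idx))
    stop("areas not in the declared area list: ",
         paste(unique(assignments[is.na(idx)]), collapse = ", "))
  structure(list(areas = areas, index = setNames(as.integer(idx), names(assignments))),
            class = "geo_data")
}

#' Number of areas k
#' @param data a `geo_data` object.
#' @return integer.
#' @export
n_areas <- function(data) length(data$areas)

#' @export
print.geo_data <- function(x, ...) {
  cat("Geographic data:", length(x$index), "tips,", length(x$areas), "areas\n")
  cat("areas:", paste(x$areas, collapse = ", "), "\n")
  tab <- table(factor(x$areas[x$index], levels = x$areas))
  print(tab)
  invisible(x)
}

#' Read a tip-to-area table
#'
#' Reads a two-column delimited table (`taxon`, `area`; the delimiter is
#' sniffed: tab if present in the header line, else comma) and matches it
#' against the tips of a tree. Every tree tip must be assigned exactly one
#' area. Rows naming taxa absent from the tree are an error by default, a
#' warning-and-drop with `unmatched = "warn"`.
#'
#' The result is independent of row order in the table.
#'
#' @param x a file path or a data.frame with columns `taxon` and `area`
#'   (first two columns are used if unnamed).
#' @param tree the companion `phylo` object.
#' @param areas optional explicit ordered area list (permits unsampled areas).
#' @param unmatched behaviour for table taxa not in the tree.
#' @return a `geo_data` object.
#' @export
read_tip_areas <- function(x, tree, areas = NULL,
                           unmatched = c("error", "warn")) {
  unmatched <- match.arg(unmatched)
  if (is.character(x) && length(x) == 1L) {
    header <- readLines(x, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
    x <- read.csv(x, sep = sep, stringsAsFactors = FALSE)
  }
  x <- as.data.frame(x)
  cn <- tolower(names(x))
  ti <- if ("taxon" %in% cn) which(cn == "taxon")[1L] else 1L
  ai <- if ("area" %in% cn) which(cn == "area")[1L] else 2L
  taxa <- as.character(x[[ti]]); area <- as.character(x[[ai]])
  if (anyDuplicated(taxa)) stop("duplicate taxa in tip-area table")
  extra <- setdiff(taxa, tree$tip.label)
  if (length(extra)) {
    msg <- paste("taxa absent from tree:", paste(extra, collapse = ", "))
    if (unmatched == "error") stop(msg)
    warning(msg, "; dropped")
    keep <- !(taxa %in% extra); taxa <- taxa[keep]; area <- area[keep]
  }
  missing <- setdiff(tree$tip.label, taxa)
  if (length(missing))
    stop("tree tips missing from table: ", paste(missing, collapse = ", "))
  geo_data(setNames(area, taxa)[tree$tip.label], areas = areas)
}

#' Write a tip-to-area table as CSV
#' @param data a `geo_data` object.
#' @param file output path.
#' @export
write_tip_areas <- function(data, file) {
  write.csv(data.frame(taxon = names(data$index),
                       area = data$areas[data$index]),
            file, row.names = FALSE, quote = FALSE)
}
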