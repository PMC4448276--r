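#' Tubule tree objects
#'
#' A `tubule_tree` is the package's container for one branched tubule: a table
#' of lattice elements (integer cells) with tip/stalk identities and parent
#' links. Coordinates are 0-based cells, x rightward, y upward, origin at the
#' bottom-left of the domain. Exactly one element is the root (parent `NA`);
#' every other element lies within Chebyshev distance 1 of its parent
#' (8-connectivity). `generation` counts bifurcations from the root: trunk
#' elements are generation 0, the daughters of the first branch point are
#' generation 1, and so on.
#'
#' @param elements A data.frame with columns `x`, `y` (integer cells), `kind`
#'   (`"tip"` or `"stalk"`), `parent` (row index of the parent element, `NA`
#'   for the root), `generation` and `birth_step` (integers).
#' @param tree_id Integer identity of the tree within its domain.
#' @return An object of class `tubule_tree`.
#' @examples
#' tr <- tubule_tree(data.frame(
#'   x = c(5L, 5L, 5L), y = c(0L, 1L, 2L),
#'   kind = c("stalk", "stalk", "tip"),
#'   parent = c(NA, 1L, 2L), generation = 0L, birth_step = 0L))
#' n_elements(tr)
#' @export
tubule_tree <- function(elements, tree_id = 1L) {
  stopifnot(is.data.frame(elements))
  need <- c("x", "y", "kind", "parent", "generation", "birth_step")
  miss <- setdiff(need, names(elements))
  if (length(miss))
    stop("elements is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  elements <- elements[, need]
  elements$x <- as.integer(elements$x)
  elements$y <- as.integer(elements$y)
  elements$parent <- as.integer(elements$parent)
  elements$generation <- as.integer(elements$generation)
  elements$birth_step <- as.integer(elements$birth_step)
  rownames(elements) <- NULL
  tr <- structure(list(tree_id = as.integer(tree_id), elements = elements),
                  class = "tubule_tree")
  validate_tree(tr)
  tr
}

validate_tree <- function(tree) {
  el <- tree$elements
  root <- which(is.na(el$parent))
  if (length(root) != 1L)
    stop("a tubule_tree must have exactly one root element", call. = FALSE)
  if (nrow(el) > 1L) {
    ch <- el[-root, , drop = FALSE]
    pp <- el[ch$parent, , drop = FALSE]
    d <- pmax(abs(ch$x - pp$x), abs(ch$y - pp$y))
    if (any(d > 1L))
      stop("every element must lie within Chebyshev distance 1 of its parent",
           call. = FALSE)
  }
  if (anyDuplicated(el[, c("x", "y")]))
    stop("a cell may be occupied by at most one element", call. = FALSE)
  if (!all(el$kind %in% c("tip", "stalk")))
    stop("element kind must be 'tip' or 'stalk'", call. = FALSE)
  invisible(tree)
}

#' @rdname tubule_tree
#' @param tree A `tubule_tree`.
#' @export
n_elements <- function(tree) nrow(tree$elements)

#' @export
print.tubule_tree <- function(x, ...) {
  el <- x$elements
  cat(sprintf("Tubule tree #%d: %d elements (%d tips), %d branch points, max generation %d\n",
              x$tree_id, nrow(el), sum(el$kind == "tip"),
              length(branch_points(x)), max(el$generation)))
  invisible(x)
}

#' Branch points of a tubule tree
#'
#' A branch point is an element with two or more child elements; in trees
#' grown by the simulator every branch point has exactly two.
#'
#' @param tree A `tubule_tree`.
#' @return Integer vector of element row indices.
#' @export
branch_points <- function(tree) {
  par <- tree$elements$parent
  tab <- tabulate(par[!is.na(par)], nbins = nrow(tree$elements))
  which(tab >= 2L)
}

children_of <- function(tree, i) which(tree$elements$parent %in% i)

# Occupied cells of one tree or a list of trees, as an n x 2 matrix
tree_cells <- function(trees) {
  if (inherits(trees, "tubule_tree")) trees <- list(trees)
  do.call(rbind, lapply(trees, function(tr)
    cbind(tr$elements$x, tr$elements$y)))
}

# Euclidean arc length of the parent path between element i and the root,
# expressed as cumulative distances; used by the self-loop detector.
path_to_root <- function(tree, i) {
  el <- tree$elements
  path <- i
  while (!is.na(el$parent[i])) {
    i <- el$parent[i]
    path <- c(path, i)
  }
  path
}

# Arc-length distance through the tree between elements i and j (via their
# lowest common ancestor).
tree_path_distance <- function(tree, i, j) {
  el <- tree$elements
  pi <- path_to_root(tree, i)
  pj <- path_to_root(tree, j)
  anc <- intersect(pi, pj)[1]           # first shared ancestor on i's path
  seg_len <- function(path, stop_at) {
    tot <- 0
    for (k in seq_len(length(path) - 1L)) {
      if (path[k] == stop_at) break
      tot <- tot + sqrt((el$x[path[k]] - el$x[path[k + 1L]])^2 +
                        (el$y[path[k]] - el$y[path[k + 1L]])^2)
    }
    tot
  }
  seg_len(pi, anc) + seg_len(pj, anc)
}
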