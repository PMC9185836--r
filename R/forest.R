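#' Rooted phylogenetic forests
#'
#' A forest is a set of rooted leaf-labelled trees whose leaf label sets
#' partition `1:n`.  Component trees are stored as nested lists: a leaf is
#' its integer label, an internal vertex (including the root) is the list of
#' its child subtrees.  Every internal vertex must have out-degree at least
#' 2; a *trivial* tree is a single labelled leaf-root.  Binary trees have
#' out-degree exactly 2 everywhere.
#'
#' @param components list of component trees (nested lists / bare integers).
#' @return An object of class `phylo_forest`.
#' @examples
#' parse_newick("(1,((4,6),(5,(2,3))));")
#' parse_newick("5;\n(1,(3,4,6));")
#' @export
forest <- function(components) {
  if (!is.list(components) || length(components) == 0L)
    stop("a forest needs at least one component tree", call. = FALSE)
  components <- lapply(components, validate_tree_node)
  labs <- sort(unlist(lapply(components, tree_leaves), use.names = FALSE))
  if (anyDuplicated(labs))
    stop("duplicate leaf label ", labs[duplicated(labs)][[1L]],
         " across components", call. = FALSE)
  n <- length(labs)
  if (!identical(labs, seq_len(n)))
    stop("leaf labels must be exactly 1..n; got {",
         paste(labs, collapse = ","), "}", call. = FALSE)
  components <- components[order(vapply(components, min_leaf, integer(1L)))]
  structure(list(components = components), class = "phylo_forest")
}

is_leaf_node <- function(nd) !is.list(nd)

validate_tree_node <- function(nd) {
  if (is_leaf_node(nd)) {
    lab <- as.integer(nd)
    if (length(lab) != 1L || is.na(lab) || lab < 1L)
      stop("leaf label must be a single positive integer", call. = FALSE)
    return(lab)
  }
  if (length(nd) < 2L)
    stop(errorCondition(
      "internal vertex of out-degree < 2 is not allowed",
      class = c("brauerphylo_validation_error", "error", "condition")))
  lapply(nd, validate_tree_node)
}

#' Leaf labels of a tree or forest
#'
#' @param x a component tree (nested list) or a `phylo_forest`.
#' @return Sorted integer vector of leaf labels.
#' @export
tree_leaves <- function(x) {
  if (inherits(x, "phylo_forest"))
    return(sort(unlist(lapply(x$components, tree_leaves), use.names = FALSE)))
  if (is_leaf_node(x)) return(as.integer(x))
  sort(unlist(lapply(x, tree_leaves), use.names = FALSE))
}

min_leaf <- function(nd) min(tree_leaves(nd))

#' Number of leaves of a forest
#'
#' @param f a `phylo_forest`.
#' @return Integer.
#' @export
n_leaves <- function(f) length(tree_leaves(f))

#' Number of component trees
#'
#' @param f a `phylo_forest`.
#' @return Integer (the component count, usually written \eqn{\tau}).
#' @export
n_components <- function(f) length(f$components)

#' Is the forest a single tree / trivial?
#'
#' @param f a `phylo_forest`.
#' @return `TRUE` or `FALSE`.
#' @export
is_single_tree <- function(f) length(f$components) == 1L

#' @rdname is_single_tree
#' @export
is_trivial_forest <- function(f) all(vapply(f$components, is_leaf_node,
                                            logical(1L)))

#' @export
print.phylo_forest <- function(x, ...) {
  cat("<phylo_forest> ", n_leaves(x), " leaves, ", n_components(x),
      " component(s)\n", write_newick(x), "\n", sep = "")
  invisible(x)
}

#' @export
Ops.phylo_forest <- function(e1, e2) {
  if (!.Generic %in% c("==", "!="))
    stop("operation `", .Generic, "` not defined for phylo_forest objects",
         call. = FALSE)
  eq <- identical(write_newick(e1), write_newick(e2))
  if (.Generic == "==") eq else !eq
}

# ---- Newick I/O -------------------------------------------------------------

#' Parse Newick text into a forest
#'
#' One semicolon-terminated statement per component tree; several statements
#' make a forest.  Leaf labels must be positive integers.  Branch lengths
#' and internal vertex labels are tolerated on input and dropped with a
#' warning (the objects of interest are topologies only).  Parenthesized
#' statements are parsed with [ape::read.tree()]; a bare label (`"5;"`) is a
#' trivial single-leaf tree, which ape cannot represent.
#'
#' @param text Newick string (possibly multi-statement).
#' @return A `phylo_forest`.
#' @examples
#' parse_newick("(1,((4,6),(5,(2,3))));")
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text))
  text <- paste(text, collapse = "\n")
  if (grepl(":", text, fixed = TRUE))
    warning("branch lengths in Newick input are ignored", call. = FALSE)
  stmts <- trimws(strsplit(text, ";", fixed = TRUE)[[1L]])
  stmts <- stmts[nzchar(stmts)]
  if (length(stmts) == 0L)
    stop(errorCondition("no Newick statement found",
         class = c("brauerphylo_parse_error", "error", "condition")))
  comps <- lapply(seq_along(stmts), function(i) {
    s <- stmts[[i]]
    if (!grepl("(", s, fixed = TRUE)) {
      lab <- suppressWarnings(as.integer(s))
      if (is.na(lab))
        stop(errorCondition(
          paste0("statement ", i, ": expected an integer leaf label, got `",
                 s, "`"),
          class = c("brauerphylo_parse_error", "error", "condition")))
      return(lab)
    }
    ph <- tryCatch(ape::read.tree(text = paste0(s, ";")),
                   error = function(e) NULL)
    if (is.null(ph))
      stop(errorCondition(
        paste0("statement ", i, ": malformed Newick `", s, "`"),
        class = c("brauerphylo_parse_error", "error", "condition")))
    ape_to_node(ph, statement = i)
  })
  forest(comps)
}

# convert an ape "phylo" to the nested-list representation (internal)
ape_to_node <- function(ph, statement = 1L) {
  ntip <- length(ph$tip.label)
  labs <- suppressWarnings(as.integer(ph$tip.label))
  if (anyNA(labs))
    stop(errorCondition(
      paste0("statement ", statement, ": leaf labels must be integers (got `",
             ph$tip.label[which(is.na(labs))[1L]], "`)"),
      class = c("brauerphylo_parse_error", "error", "condition")))
  kids <- split(ph$edge[, 2L], ph$edge[, 1L])
  build <- function(v) {
    if (v <= ntip) return(labs[[v]])
    ch <- kids[[as.character(v)]]
    if (length(ch) < 2L)
      stop(errorCondition(
        paste0("statement ", statement,
               ": vertex of out-degree 1 is not a valid phylogenetic tree"),
        class = c("brauerphylo_validation_error", "error", "condition")))
    lapply(ch, build)
  }
  build(ntip + 1L)
}

#' Write a forest as canonical Newick
#'
#' Children are ordered by smallest descendant leaf label and components by
#' smallest leaf label, one statement per component, so output is
#' byte-stable and `parse_newick(write_newick(f)) == f`.
#'
#' @param f a `phylo_forest`.
#' @return A single Newick string (statements separated by newlines).
#' @export
write_newick <- function(f) {
  stopifnot(inherits(f, "phylo_forest"))
  ser <- function(nd) {
    if (is_leaf_node(nd)) return(as.character(nd))
    nd <- nd[order(vapply(nd, min_leaf, integer(1L)))]
    paste0("(", paste(vapply(nd, ser, character(1L)), collapse = ","), ")")
  }
  paste0(paste(vapply(f$components, ser, character(1L)), collapse = ";\n"), ";")
}

# ---- structural queries -----------------------------------------------------

#' Cherries, leaf/vertex counts and binarity of a tree
#'
#' A *cherry* is the sibling set of a vertex all of whose children are
#' leaves (a pair for binary trees).  For a binary tree on `n` leaves the
#' Brauer rank of its diagram is `n - 2 * (number of cherries)`.
#'
#' @param x a single-component `phylo_forest` or a component tree.
#' @return A list with `cherries` (list of sorted integer vectors),
#'   `n_leaves`, `n_internal` (internal vertices excluding the root) and
#'   `is_binary`.
#' @examples
#' structure_stats(parse_newick("(1,((4,6),(5,(2,3))));"))$cherries
#' @export
structure_stats <- function(x) {
  if (inherits(x, "phylo_forest")) {
    if (length(x$components) != 1L)
      stop("structure_stats() expects a single tree; got a forest with ",
           length(x$components), " components", call. = FALSE)
    x <- x$components[[1L]]
  }
  cherries <- list()
  n_nonleaf <- 0L
  binary <- TRUE
  walk <- function(nd) {
    if (is_leaf_node(nd)) return(invisible(NULL))
    n_nonleaf <<- n_nonleaf + 1L
    if (length(nd) != 2L) binary <<- FALSE
    if (all(vapply(nd, is_leaf_node, logical(1L))))
      cherries[[length(cherries) + 1L]] <<- sort(vapply(nd, as.integer,
                                                        integer(1L)))
    for (ch in nd) walk(ch)
  }
  walk(x)
  list(cherries = cherries,
       n_leaves = length(tree_leaves(x)),
       n_internal = max(n_nonleaf - 1L, 0L),  # root is not internal
       is_binary = binary && !is_leaf_node(x))
}
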