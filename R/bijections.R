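#' Forest to set partition (sibling-set correspondence)
#'
#' Numbers the non-leaf vertices of the forest `n+1, n+2, ...` by repeatedly
#' choosing, among vertices all of whose children are already numbered, the
#' one with the numerically lowest-numbered child.  Exactly one root (the
#' last vertex due a number) stays unnumbered.  The partition blocks are the
#' sibling sets (the numbered children of each non-leaf vertex); every
#' *numbered* root contributes its own label as a singleton block.  A binary
#' tree yields a perfect matching of \[2n-2\]; the trivial forest yields the
#' all-singleton partition of \[n\].
#'
#' @param f a `phylo_forest` (or Newick string).
#' @return A `set_partition`.
#' @examples
#' phylo_to_partition(parse_newick("(1,((4,6),(5,(2,3))));"))
#' # -> 1,10|2,3|4,6|5,7|8,9
#' @export
phylo_to_partition <- function(f) {
  f <- as_forest(f)
  n <- n_leaves(f)
  # flatten to vertex arrays
  children <- list()   # vertex id -> integer vector of child vertex ids
  leaf_lab <- list()   # vertex id -> leaf label or NA
  roots <- integer(0)
  add_node <- function(nd) {
    id <- length(children) + 1L
    children[[id]] <<- integer(0)
    leaf_lab[[id]] <<- NA_integer_
    if (is_leaf_node(nd)) {
      leaf_lab[[id]] <<- as.integer(nd)
    } else {
      children[[id]] <<- vapply(nd, add_node, integer(1L))
    }
    id
  }
  for (comp in f$components) roots <- c(roots, add_node(comp))
  nv <- length(children)
  lab <- unlist(leaf_lab)                      # assigned numbers
  internal <- which(vapply(children, length, integer(1L)) > 0L)
  n_int <- length(internal)
  next_label <- n + 1L
  order_assigned <- integer(0)
  for (step in seq_len(n_int)) {
    cand <- internal[vapply(internal, function(v) {
      is.na(lab[[v]]) && !anyNA(lab[children[[v]]])
    }, logical(1L))]
    stopifnot(length(cand) >= 1L)
    pick <- cand[[which.min(vapply(cand, function(v) min(lab[children[[v]]]),
                                   integer(1L)))]]
    if (step < n_int) {
      lab[[pick]] <- next_label
      next_label <- next_label + 1L
    }
    order_assigned <- c(order_assigned, pick)
    internal <- setdiff(internal, pick)
  }
  blocks <- lapply(order_assigned, function(v) lab[children[[v]]])
  # numbered roots (labelled internal roots and isolated leaves) -> singletons
  root_labs <- lab[roots]
  blocks <- c(blocks, as.list(root_labs[!is.na(root_labs)]))
  set_partition(blocks)
}

#' Set partition to forest
#'
#' Inverts [phylo_to_partition()].  With `n = |pi| - l_ge2(pi) + 1` leaves
#' laid out first, the non-trivial blocks are processed one at a time: among
#' the unprocessed blocks whose elements all label existing vertices, the
#' one containing the least integer is attached under a new parent vertex,
#' which receives the next number `n+1, n+2, ...` -- except the last parent,
#' which is the unnumbered root.  Singleton blocks with label at most `n`
#' are isolated-leaf (trivial) trees; singleton labels above `n` mark
#' numbered roots.  The all-singleton partition of \[t\] maps to the trivial
#' forest on `t` leaves.
#'
#' @param pi a `set_partition` (any set partition works).
#' @return A `phylo_forest`.
#' @examples
#' pi <- text_to_partition("1,10|2,12|3,4,6|5|7,8|9,13|11")
#' partition_to_forest(pi)
#' @export
partition_to_forest <- function(pi) {
  stopifnot(inherits(pi, "set_partition"))
  sizes <- block_sizes(pi)
  if (all(sizes == 1L))
    return(forest(as.list(seq_len(pi$ground_size))))
  n <- pi$ground_size - sum(sizes >= 2L) + 1L
  vert <- vector("list", pi$ground_size)
  for (l in seq_len(n)) vert[[l]] <- l
  has_parent <- logical(pi$ground_size)
  remaining <- pi$blocks[sizes >= 2L]
  next_label <- n + 1L
  unlabelled_root <- NULL
  while (length(remaining) > 0L) {
    ok <- vapply(remaining, function(b) !any(vapply(vert[b], is.null,
                                                    logical(1L))), logical(1L))
    if (!any(ok))
      stop(errorCondition(
        "malformed partition: no block is fully contained in the current labels",
        class = c("brauerphylo_validation_error", "error", "condition")))
    pick <- which(ok)[which.min(vapply(remaining[ok], min, integer(1L)))]
    b <- remaining[[pick]]
    node <- vert[b]
    has_parent[b] <- TRUE
    remaining <- remaining[-pick]
    if (length(remaining) > 0L) {
      vert[[next_label]] <- node
      next_label <- next_label + 1L
    } else {
      unlabelled_root <- node
    }
  }
  labelled_roots <- which(!has_parent & !vapply(vert, is.null, logical(1L)))
  forest(c(list(unlabelled_root), vert[labelled_roots]))
}

#' Leaf count, bottom-row size and component count implied by a partition
#'
#' For a non-trivial partition, `n = |pi| - l_ge2(pi) + 1`,
#' `m = l_ge2(pi) - 1` and `tau = (number of singletons) + 1`.  The
#' all-singleton partition of \[t\] is the trivial forest: `n = t`, `m = 0`,
#' `tau = t`.
#'
#' @param pi a `set_partition`.
#' @return A list with integer fields `n`, `m`, `tau`.
#' @export
dims_from_partition <- function(pi) {
  l2 <- n_nontrivial_blocks(pi)
  if (l2 == 0L)
    return(list(n = pi$ground_size, m = 0L, tau = pi$ground_size))
  list(n = pi$ground_size - l2 + 1L, m = l2 - 1L, tau = n_singletons(pi) + 1L)
}

#' Forest to partition diagram
#'
#' Lays [phylo_to_partition()] out as a diagram with the `n` leaves on top
#' and the `m = l_ge2(pi) - 1` numbered internal vertices on the bottom.  A
#' binary tree gives a Brauer diagram in shape `(n, n-2)`.
#'
#' @param f a `phylo_forest` (or Newick string).
#' @return A `partition_diagram`.
#' @examples
#' phylo_to_diagram(parse_newick("(1,((4,6),(5,(2,3))));"))
#' @export
phylo_to_diagram <- function(f) {
  f <- as_forest(f)
  pi <- phylo_to_partition(f)
  n <- n_leaves(f)
  partition_diagram(n, pi$ground_size - n, pi)
}

#' Partition diagram to forest
#'
#' Inverse of [phylo_to_diagram()]: validates the diagram's shape against
#' the counting conditions (see [classify_diagram()]) and rebuilds the
#' forest with [partition_to_forest()].
#'
#' @param d a `partition_diagram`.
#' @return A `phylo_forest`.
#' @export
diagram_to_phylo <- function(d) {
  cls <- classify_diagram(d)
  if (cls$verdict == "invalid")
    stop(errorCondition(
      paste0("diagram does not correspond to a tree or forest: m = ", d$m,
             " but the partition requires m = ",
             if (cls$l_ge2 == 0L) 0L else cls$l_pi - cls$tau,
             " (= l(pi) - tau)"),
      class = c("brauerphylo_not_a_forest", "error", "condition"),
      classification = cls))
  partition_to_forest(d$partition)
}

#' Classify a partition diagram as a tree, forest, or neither
#'
#' A diagram in shape `(n, m)` with partition `pi` corresponds to a tree iff
#' `pi` has no singleton blocks and `m = l(pi) - 1`; it corresponds to a
#' forest with `tau` components iff it has `tau - 1` singleton blocks and
#' `m = l(pi) - tau` (equivalently `m = l_ge2(pi) - 1`).  The all-singleton
#' partition with `m = 0` is the trivial forest (`tau = n`).  `binary_tree`
#' additionally requires all blocks of size 2.
#'
#' @param d a `partition_diagram`.
#' @return An object of class `diagram_classification`: a list with
#'   `verdict` (one of `"binary_tree"`, `"tree"`, `"forest"`, `"invalid"`),
#'   `n`, `m`, `l_pi`, `l_ge2`, `n_singletons`, `tau`.
#' @examples
#' classify_diagram(partition_diagram(4, 2, list(c(1, 2, 6), c(3, 4, 5))))$verdict
#' classify_diagram(partition_diagram(5, 1, list(c(1, 2, 6), c(3, 4, 5))))$verdict
#' @export
classify_diagram <- function(d) {
  pi <- d$partition
  l_pi <- n_blocks(pi)
  l2 <- n_nontrivial_blocks(pi)
  singles <- n_singletons(pi)
  if (l2 == 0L) {
    verdict <- if (d$m == 0L) "forest" else "invalid"
    tau <- d$n
  } else {
    tau <- singles + 1L
    if (d$m != l2 - 1L) {
      verdict <- "invalid"
    } else if (singles == 0L) {
      verdict <- if (is_perfect_matching(pi)) "binary_tree" else "tree"
    } else {
      verdict <- "forest"
    }
  }
  structure(list(verdict = verdict, n = d$n, m = d$m, l_pi = l_pi,
                 l_ge2 = l2, n_singletons = singles, tau = tau),
            class = "diagram_classification")
}

#' @export
print.diagram_classification <- function(x, ...) {
  cat("<diagram_classification> ", x$verdict, "  (n=", x$n, ", m=", x$m,
      ", l(pi)=", x$l_pi, ", l_ge2=", x$l_ge2, ", singletons=",
      x$n_singletons, ", tau=", x$tau, ")\n", sep = "")
  invisible(x)
}

#' Balanced and unbalanced transcriptions of a binary-tree matching
#'
#' A binary tree on `n` leaves corresponds to a perfect matching of
#' \[2n-2\], which can be laid out either as an unbalanced Brauer diagram in
#' shape `(n, n-2)` (leaves on top) or as a balanced one in shape
#' `(n-1, n-1)`.  Both use the same clockwise numbering, so the conversion
#' keeps the blocks and only re-splits the rows.
#'
#' @param d a Brauer `partition_diagram` of shape `(n, n-2)`
#'   (`to_balanced`) or `(n-1, n-1)` (`from_balanced`).
#' @return The re-laid-out `partition_diagram`.
#' @export
to_balanced <- function(d) {
  if (!is_brauer(d))
    stop("`to_balanced()` requires a Brauer (perfect-matching) diagram",
         call. = FALSE)
  if (d$m != d$n - 2L)
    stop("expected an unbalanced diagram of shape (n, n-2); got (", d$n, ",",
         d$m, ")", call. = FALSE)
  partition_diagram(d$n - 1L, d$n - 1L, d$partition)
}

#' @rdname to_balanced
#' @export
from_balanced <- function(d) {
  if (!is_brauer(d))
    stop("`from_balanced()` requires a Brauer (perfect-matching) diagram",
         call. = FALSE)
  if (d$m != d$n)
    stop("expected a balanced diagram of shape (n, n); got (", d$n, ",",
         d$m, ")", call. = FALSE)
  partition_diagram(d$n + 1L, d$n - 1L, d$partition)
}

#' Matching as a fixed-point-free involution
#'
#' Reads a perfect matching as a product of disjoint transpositions, i.e.
#' the permutation exchanging the two elements of every pair (an involution
#' of the symmetric group on the ground set, without fixed points).
#'
#' @param matching a `set_partition` with all blocks of size 2 (or a Brauer
#'   `partition_diagram`).
#' @return An integer vector `perm` with `perm[i] = j` for every pair
#'   `{i, j}`.
#' @export
to_transpositions <- function(matching) {
  if (inherits(matching, "partition_diagram")) matching <- matching$partition
  if (!is_perfect_matching(matching))
    stop("`to_transpositions()` requires a perfect matching", call. = FALSE)
  perm <- integer(matching$ground_size)
  for (b in matching$blocks) {
    perm[b[[1L]]] <- b[[2L]]
    perm[b[[2L]]] <- b[[1L]]
  }
  perm
}

# coerce Newick strings for convenience (internal)
as_forest <- function(f) {
  if (inherits(f, "phylo_forest")) return(f)
  if (is.character(f)) return(parse_newick(f))
  stop("expected a phylo_forest or a Newick string", call. = FALSE)
}
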