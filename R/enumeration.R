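# fast internal constructor: blocks already disjoint and covering 1..t
new_set_partition <- function(blocks, t) {
  blocks <- lapply(blocks, function(b) sort(as.integer(b)))
  blocks <- blocks[order(vapply(blocks, min, integer(1L)))]
  structure(list(ground_size = as.integer(t), blocks = blocks),
            class = "set_partition")
}

guard_size <- function(n, force, what = "enumeration") {
  if (n > 10L && !force)
    stop(what, " over n = ", n, " is combinatorially explosive ",
         "((2n-3)!! growth); pass force = TRUE to override", call. = FALSE)
  invisible(NULL)
}

#' Enumerate set partitions with restricted block sizes
#'
#' All set partitions of `1:t` whose block sizes satisfy the given
#' restriction, each exactly once, in deterministic (canonical ascending)
#' order.  Enumeration is by recursive assignment of the smallest unplaced
#' element, pruning branches that can no longer satisfy the minimum size.
#'
#' @param t ground-set size.
#' @param min_size,max_size block-size bounds.
#' @param sizes optional explicit set of allowed block sizes (overrides the
#'   bounds for the final filter; bounds are still derived from it).
#' @return A list of `set_partition` objects.
#' @examples
#' length(all_set_partitions(5, min_size = 2))  # 11
#' @export
all_set_partitions <- function(t, min_size = 1L, max_size = Inf, sizes = NULL) {
  t <- as.integer(t)
  stopifnot(t >= 1L)
  if (!is.null(sizes)) {
    sizes <- sort(unique(as.integer(sizes)))
    min_size <- min(sizes); max_size <- max(sizes)
  }
  out <- list()
  blocks <- list()
  recurse <- function(nxt) {
    if (nxt > t) {
      sz <- vapply(blocks, length, integer(1L))
      ok <- all(sz >= min_size) &&
        (is.null(sizes) || all(sz %in% sizes))
      if (ok) out[[length(out) + 1L]] <<- new_set_partition(blocks, t)
      return(invisible(NULL))
    }
    remaining <- t - nxt + 1L
    # prune: every under-filled block still needs top-up elements
    deficit <- sum(pmax(min_size - vapply(blocks, length, integer(1L)), 0L))
    if (deficit > remaining) return(invisible(NULL))
    for (i in seq_along(blocks)) {
      if (length(blocks[[i]]) < max_size) {
        blocks[[i]] <<- c(blocks[[i]], nxt)
        recurse(nxt + 1L)
        blocks[[i]] <<- blocks[[i]][-length(blocks[[i]])]
      }
    }
    blocks[[length(blocks) + 1L]] <<- nxt
    recurse(nxt + 1L)
    blocks[[length(blocks)]] <<- NULL
  }
  recurse(1L)
  out
}

#' Count set partitions with restricted block sizes
#'
#' Closed-form count via the partial-Bell-polynomial recursion on the block
#' containing the smallest element:
#' `f(t) = sum over allowed s of choose(t-1, s-1) * f(t-s)`, `f(0) = 1`.
#' Equals `length(all_set_partitions(t, ...))`.
#'
#' @inheritParams all_set_partitions
#' @return A numeric count.
#' @examples
#' vapply(2:7, count_restricted_partitions, numeric(1), min_size = 2)
#' # 1 1 4 11 41 162
#' @export
count_restricted_partitions <- function(t, min_size = 1L, max_size = Inf,
                                        sizes = NULL) {
  t <- as.integer(t)
  allowed <- function(s) {
    if (!is.null(sizes)) s %in% sizes else s >= min_size && s <= max_size
  }
  f <- numeric(t + 1L)  # f[u + 1] = count for ground size u
  f[[1L]] <- 1
  for (u in seq_len(t)) {
    acc <- 0
    for (s in seq_len(u)) if (allowed(s)) acc <- acc + choose(u - 1L, s - 1L) * f[[u - s + 1L]]
    f[[u + 1L]] <- acc
  }
  f[[t + 1L]]
}

# raw perfect matchings of a given element set (internal; list of pair lists)
all_matchings_of <- function(elems) {
  if (length(elems) == 0L) return(list(list()))
  first <- elems[[1L]]
  rest <- elems[-1L]
  out <- list()
  for (i in seq_along(rest)) {
    sub <- all_matchings_of(rest[-i])
    pair <- c(first, rest[[i]])
    out <- c(out, lapply(sub, function(mt) c(list(pair), mt)))
  }
  out
}

#' All Brauer diagrams of shape (n, n-2)
#'
#' Enumerates the `(2n-3)!!` perfect matchings of `1:(2n-2)` and lays each
#' out with `n` top and `n-2` bottom nodes; these are exactly the diagrams
#' of binary trees on `n` leaves.
#'
#' @param n number of top nodes (leaves); guarded at `n <= 10`.
#' @param force allow larger `n`.
#' @return A list of Brauer `partition_diagram`s.
#' @export
all_brauer_diagrams <- function(n, force = FALSE) {
  n <- as.integer(n)
  stopifnot(n >= 2L)
  guard_size(n, force)
  lapply(all_matchings_of(seq_len(2L * n - 2L)), function(mt) {
    partition_diagram(n, n - 2L, new_set_partition(mt, 2L * n - 2L))
  })
}

#' Exhaustive generation of trees and forests
#'
#' * `mode = "binary_trees"`: all `(2n-3)!!` binary trees on `n` leaves,
#'   from the perfect matchings of `1:(2n-2)`.
#' * `mode = "trees"`: all rooted (possibly non-binary) trees, from the
#'   partitions into blocks of size >= 2 with `|pi| - l(pi) + 1 = n`.
#' * `mode = "forests"`: all forests on `n` leaves, from the partitions with
#'   `|pi| - l_ge2(pi) + 1 = n`, plus the trivial forest.
#'
#' @param n leaf count (`n >= 2` for tree modes, `n >= 1` for forests).
#' @param mode one of `"binary_trees"`, `"trees"`, `"forests"`.
#' @param force allow `n > 10`.
#' @return A list of `phylo_forest` objects, in deterministic order.
#' @export
all_phylo <- function(n, mode = c("binary_trees", "trees", "forests"),
                      force = FALSE) {
  mode <- match.arg(mode)
  n <- as.integer(n)
  guard_size(n, force)
  if (mode == "binary_trees") {
    stopifnot(n >= 2L)
    return(lapply(all_brauer_diagrams(n, force = force), diagram_to_phylo))
  }
  if (mode == "trees") {
    stopifnot(n >= 2L)
    out <- list()
    for (m in 0:(n - 2L)) {
      parts <- all_set_partitions(n + m, min_size = 2L)
      parts <- parts[vapply(parts, n_blocks, integer(1L)) == m + 1L]
      out <- c(out, lapply(parts, partition_to_forest))
    }
    return(out)
  }
  # forests: tau >= 2 or single trees; trivial forest handled separately
  stopifnot(n >= 1L)
  out <- list(forest(as.list(seq_len(n))))
  if (n >= 2L) {
    for (s in seq_len(n - 1L)) {        # s = number of non-trivial blocks
      t <- n + s - 1L
      parts <- all_set_partitions(t)
      parts <- parts[vapply(parts, n_nontrivial_blocks, integer(1L)) == s]
      out <- c(out, lapply(parts, partition_to_forest))
    }
  }
  out
}

#' Rank census of binary-tree diagrams
#'
#' Counts the Brauer diagrams of shape `(n, n-2)` (equivalently the binary
#' trees on `n` leaves) by rank, i.e. by number of transversal pairs.
#'
#' @param n leaf count; guarded at `n <= 10`.
#' @param force allow larger `n`.
#' @return A named numeric vector, names = ranks, values = counts.
#' @examples
#' count_by_rank(6)  # 45, 540, 360 at ranks 0, 2, 4
#' @export
count_by_rank <- function(n, force = FALSE) {
  n <- as.integer(n)
  guard_size(n, force)
  mts <- all_matchings_of(seq_len(2L * n - 2L))
  ranks <- vapply(mts, function(mt) {
    sum(vapply(mt, function(p) p[[1L]] <= n && p[[2L]] > n, logical(1L)))
  }, integer(1L))
  tab <- table(ranks)
  out <- as.numeric(tab)
  names(out) <- names(tab)
  out
}

# memoized counts A[t, l] = partitions of [t] into l blocks all of size >= 2
restricted_block_counts <- function(t_max, l_max) {
  A <- matrix(0, nrow = t_max + 1L, ncol = l_max + 1L)
  A[1L, 1L] <- 1  # A[t=0, l=0]
  for (t in seq_len(t_max)) for (l in seq_len(l_max)) {
    acc <- 0
    if (t >= 2L) for (s in 2:t) {
      acc <- acc + choose(t - 1L, s - 1L) * A[t - s + 1L, l]
    }
    A[t + 1L, l + 1L] <- acc
  }
  A
}

# uniform partition of `elems` into l blocks of size >= 2 (internal)
sample_restricted_partition <- function(elems, l, A) {
  t <- length(elems)
  if (l == 0L) return(list())
  sizes <- 2:(t - 2L * (l - 1L))
  w <- vapply(sizes, function(s) choose(t - 1L, s - 1L) * A[t - s + 1L, l],
              numeric(1L))
  s <- sizes[sample.int(length(sizes), 1L, prob = w)]
  companions <- if (t - 1L == s - 1L) elems[-1L] else
    sort(sample(elems[-1L], s - 1L))
  block <- c(elems[[1L]], companions)
  c(list(block),
    sample_restricted_partition(setdiff(elems, block), l - 1L, A))
}

#' Random trees
#'
#' * `mode = "binary"`: uniform over the `(2n-3)!!` binary topologies, by
#'   sequential growth: starting from the cherry on leaves 1 and 2, leaf
#'   `k+1` is attached to one of the `2k-1` positions (any edge, or above
#'   the root) chosen uniformly.  Each topology on `k+1` leaves arises from
#'   exactly one predecessor in exactly one way, so the result is uniform.
#' * `mode = "general"`: uniform over all rooted (possibly non-binary) trees
#'   on `n` leaves, by exact sampling of a partition from the
#'   blocks-of-size->=2 slice using the partial-Bell counting recursion.
#'
#' Reproducible under `set.seed()`.
#'
#' @param n leaf count, `n >= 2`.
#' @param mode `"binary"` or `"general"`.
#' @return A single-tree `phylo_forest`.
#' @export
random_phylo <- function(n, mode = c("binary", "general")) {
  mode <- match.arg(mode)
  n <- as.integer(n)
  stopifnot(n >= 2L)
  if (mode == "binary") return(random_binary_tree(n))
  # choose the number of internal vertices proportionally to slice size
  A <- restricted_block_counts(2L * n - 2L, n - 1L)
  ms <- 0:(n - 2L)
  w <- vapply(ms, function(m) A[n + m + 1L, m + 2L], numeric(1L))
  m <- ms[sample.int(length(ms), 1L, prob = w)]
  blocks <- sample_restricted_partition(seq_len(n + m), m + 1L, A)
  partition_to_forest(new_set_partition(blocks, n + m))
}

random_binary_tree <- function(n) {
  # vertex ids: leaves 1..n, internals n+1.., root tracked separately
  par <- integer(2L * n - 1L)   # 0 = root
  par[1L] <- par[2L] <- n + 1L  # initial cherry under root n+1
  root <- n + 1L
  next_id <- n + 2L
  for (k in seq_len(n - 2L) + 1L) {   # k = current leaf count, 2 .. n-1
    verts <- c(seq_len(k), if (next_id > n + 1L) (n + 1L):(next_id - 1L))
    non_root <- setdiff(verts, root)
    choice <- sample.int(2L * k - 1L, 1L)
    v <- next_id; next_id <- next_id + 1L
    leaf <- k + 1L
    if (choice > length(non_root)) {     # attach above the root
      par[root] <- v
      par[leaf] <- v
      root <- v
    } else {
      u <- non_root[[choice]]
      par[v] <- par[u]
      par[u] <- v
      par[leaf] <- v
    }
  }
  kids <- split(seq_along(par)[par != 0L], par[par != 0L])
  build <- function(v) {
    if (v <= n) return(v)
    lapply(kids[[as.character(v)]], build)
  }
  forest(list(build(root)))
}
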