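#' Partition and Brauer diagrams
#'
#' A partition diagram lays a set partition of \{1..n+m\} out on two rows:
#' labels `1..n` are the top nodes, read left to right, and labels
#' `n+1..n+m` are the bottom nodes, read **right to left**, continuing the
#' numbering clockwise around the frame.  Under this layout the bottom node
#' at left-to-right position `p` carries label `n + m + 1 - p`.  A Brauer
#' diagram is the special case in which every block has size exactly 2
#' (a perfect matching).
#'
#' Equality is by `(n, m, canonical block set)`; see [Ops.partition_diagram].
#'
#' @param n number of top nodes (>= 1).
#' @param m number of bottom nodes (>= 0).
#' @param blocks the blocks, as a list of integer vectors or a
#'   `set_partition` of `1:(n + m)`.
#' @return An object of class `partition_diagram` with fields `n`, `m`,
#'   `partition`.
#' @examples
#' # the B_{6,4} diagram of a six-leaf caterpillar-free tree
#' partition_diagram(6, 4, list(c(1, 10), c(2, 3), c(4, 6), c(5, 7), c(8, 9)))
#' @export
partition_diagram <- function(n, m, blocks) {
  n <- as.integer(n); m <- as.integer(m)
  if (is.na(n) || n < 1L) stop("`n` must be a positive integer", call. = FALSE)
  if (is.na(m) || m < 0L) stop("`m` must be a non-negative integer", call. = FALSE)
  pi <- if (inherits(blocks, "set_partition")) blocks else set_partition(blocks)
  if (pi$ground_size != n + m)
    stop("blocks partition [", pi$ground_size, "] but n + m = ", n + m,
         call. = FALSE)
  structure(list(n = n, m = m, partition = pi), class = "partition_diagram")
}

#' @export
print.partition_diagram <- function(x, ...) {
  cat("<partition_diagram B[", x$n, ",", x$m, "]> ",
      partition_to_text(x$partition),
      if (is_brauer(x)) "  (Brauer)" else "", "\n", sep = "")
  invisible(x)
}

#' @export
Ops.partition_diagram <- function(e1, e2) {
  if (!.Generic %in% c("==", "!="))
    stop("operation `", .Generic, "` not defined for partition_diagram objects",
         call. = FALSE)
  eq <- identical(unclass(e1)[c("n", "m")], unclass(e2)[c("n", "m")]) &&
    identical(unclass(e1$partition), unclass(e2$partition))
  if (.Generic == "==") eq else !eq
}

#' Is the diagram a Brauer diagram?
#'
#' @param d a `partition_diagram`.
#' @return `TRUE` iff every block has size exactly 2.
#' @export
is_brauer <- function(d) is_perfect_matching(d$partition)

# ---- positional layout helpers (internal) ----------------------------------
# top label i sits at position i; bottom label j sits at position n + m + 1 - j
# (clockwise numbering).  Positions are counted left to right within a row.

bottom_label_to_pos <- function(d, label) d$n + d$m + 1L - label
bottom_pos_to_label <- bottom_label_to_pos

#' Compose two diagrams
#'
#' Diagram concatenation: the bottom row of `upper` is glued to the top row
#' of `lower` *by left-to-right position*, blocks are merged by connected
#' components over the identified middle nodes, and any component consisting
#' only of middle nodes is removed as a closed loop.  The loop parameter is
#' fixed at 1, so loops contribute nothing to the result, but their number is
#' returned for completeness.
#'
#' Composition is the partial product of the diagram category: it is defined
#' only when `upper$m == lower$n`.
#'
#' @param upper a `partition_diagram` with shape `(n, m)`.
#' @param lower a `partition_diagram` with shape `(m, k)`.
#' @return A list with elements `diagram` (the composite in shape `(n, k)`)
#'   and `loops` (integer count of removed closed loops).
#' @examples
#' e1 <- brauer_generator("e", 1, 2)
#' compose(e1, e1)   # e1 again, with one loop removed
#' @export
compose <- function(upper, lower) {
  stopifnot(inherits(upper, "partition_diagram"),
            inherits(lower, "partition_diagram"))
  if (upper$m != lower$n) {
    stop(errorCondition(
      paste0("cannot compose: upper diagram has ", upper$m,
             " bottom nodes but lower diagram has ", lower$n, " top nodes"),
      class = c("brauerphylo_dimension_error", "error", "condition")))
  }
  n <- upper$n; m <- upper$m; k <- lower$m
  n_up <- n + m; n_lo <- m + k
  total <- n_up + n_lo
  parent <- seq_len(total)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
    invisible(NULL)
  }
  for (b in upper$partition$blocks)
    if (length(b) > 1L) for (x in b[-1L]) union_(b[[1L]], x)
  for (b in lower$partition$blocks)
    if (length(b) > 1L) for (x in b[-1L]) union_(n_up + b[[1L]], n_up + x)
  # glue: upper bottom position p  <->  lower top position p
  if (m > 0L) for (p in seq_len(m)) {
    union_(n + m + 1L - p,    # upper node at bottom position p
           n_up + p)          # lower top node at position p
  }
  roots <- vapply(seq_len(total), find, integer(1L))
  # retained nodes: upper top labels 1..n keep their labels; lower bottom
  # label x (at position m + k + 1 - x) becomes result label x - m + n,
  # which preserves its left-to-right position under clockwise renumbering.
  keep_idx <- c(seq_len(n), if (k > 0L) n_up + m + seq_len(k) else integer(0))
  keep_lab <- c(seq_len(n), if (k > 0L) n + seq_len(k) else integer(0))
  comp <- roots[keep_idx]
  blocks <- unname(split(keep_lab, comp))
  middle_idx <- c(if (m > 0L) n + seq_len(m) else integer(0),
                  if (m > 0L) n_up + seq_len(m) else integer(0))
  loops <- length(setdiff(unique(roots[middle_idx]), unique(comp)))
  list(diagram = partition_diagram(n, k, blocks), loops = loops)
}

#' Reflect a diagram about the horizontal axis
#'
#' The flip (the `*`-involution on diagrams) exchanges the rows positionally:
#' the node at top position `i` moves to bottom position `i` and vice versa.
#' Under the clockwise numbering this is the label relabelling
#' `x -> n + m + 1 - x` together with swapping `n` and `m`, so
#' `flip(flip(d)) == d` and `flip` is an anti-homomorphism for composition.
#'
#' @param d a `partition_diagram` of shape `(n, m)`.
#' @return The flipped `partition_diagram` of shape `(m, n)`.
#' @export
flip <- function(d) {
  t <- d$n + d$m
  blocks <- lapply(d$partition$blocks, function(b) t + 1L - b)
  partition_diagram(d$m, d$n, blocks)
}

#' Domain, codomain, kernel, cokernel and rank of a diagram
#'
#' A *transversal* block meets both rows.  `dom` collects the top labels and
#' `codom` the bottom labels lying on transversal blocks; `ker` (resp.
#' `coker`) is the symmetric relation holding between distinct top (resp.
#' bottom) labels sharing a block, stored as a two-column matrix containing
#' both `(i, j)` and `(j, i)`.  The rank is the number of transversal blocks
#' (for Brauer diagrams this equals `|dom|`).  `u_ker` / `u_coker` are the
#' underlying sets of the two relations.
#'
#' For a Brauer diagram in shape `(n, n-2)` these satisfy
#' `dom ∪ u_ker = 1..n` (disjointly), `codom ∪ u_coker = n+1..2n-2`
#' (disjointly), `|dom| == |codom|` and `|u_ker| == |u_coker| + 2`.
#'
#' @param d a `partition_diagram`.
#' @return An object of class `diagram_stats`: a list with fields `dom`,
#'   `codom`, `ker`, `coker`, `rank`, `u_ker`, `u_coker`.
#' @examples
#' fig <- partition_diagram(6, 4, list(c(1, 10), c(2, 3), c(4, 6), c(5, 7), c(8, 9)))
#' analyze(fig)$dom    # 1, 5
#' analyze(fig)$rank   # 2
#' @export
analyze <- function(d) {
  n <- d$n
  tops <- lapply(d$partition$blocks, function(b) b[b <= n])
  bots <- lapply(d$partition$blocks, function(b) b[b > n])
  trans <- vapply(tops, length, integer(1L)) > 0L &
    vapply(bots, length, integer(1L)) > 0L
  sym_pairs <- function(groups) {
    groups <- groups[vapply(groups, length, integer(1L)) >= 2L]
    if (length(groups) == 0L)
      return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j"))))
    out <- do.call(rbind, lapply(groups, function(g) {
      cmb <- t(utils::combn(g, 2L))
      rbind(cmb, cmb[, 2:1, drop = FALSE])
    }))
    colnames(out) <- c("i", "j")
    out[order(out[, 1L], out[, 2L]), , drop = FALSE]
  }
  structure(list(
    dom    = sort(unlist(tops[trans], use.names = FALSE)),
    codom  = sort(unlist(bots[trans], use.names = FALSE)),
    ker    = sym_pairs(tops),
    coker  = sym_pairs(bots),
    rank   = sum(trans),
    u_ker  = sort(unlist(tops[vapply(tops, length, integer(1L)) >= 2L],
                         use.names = FALSE)),
    u_coker = sort(unlist(bots[vapply(bots, length, integer(1L)) >= 2L],
                          use.names = FALSE))
  ), class = "diagram_stats")
}

#' @export
print.diagram_stats <- function(x, ...) {
  fmt_rel <- function(r) {
    if (nrow(r) == 0L) return("{}")
    up <- r[r[, 1L] < r[, 2L], , drop = FALSE]
    paste0("{", paste(sprintf("(%d,%d)", up[, 1L], up[, 2L]), collapse = ","),
           "}")
  }
  cat("rank:  ", x$rank, "\n",
      "dom:   {", paste(x$dom, collapse = ","), "}\n",
      "codom: {", paste(x$codom, collapse = ","), "}\n",
      "ker:   ", fmt_rel(x$ker), " (+ symmetric pairs)\n",
      "coker: ", fmt_rel(x$coker), " (+ symmetric pairs)\n", sep = "")
  invisible(x)
}

#' Diagram rank
#'
#' @param d a `partition_diagram`.
#' @return Number of transversal blocks.
#' @export
diagram_rank <- function(d) {
  n <- d$n
  sum(vapply(d$partition$blocks,
             function(b) any(b <= n) && any(b > n), logical(1L)))
}

#' Row of a diagram as a positional equivalence relation
#'
#' Restricts the blocks to one row and re-expresses them in left-to-right
#' *positions* within that row (`1..n` on top, `1..m` on the bottom), with
#' unrelated positions as singleton classes.  This is the normalization used
#' whenever relations from different diagrams are compared or joined: e.g.
#' the cokernel of a flipped tree equals the kernel of the tree positionally.
#'
#' @param d a `partition_diagram`.
#' @param row `"top"` or `"bottom"`.
#' @return A `set_partition` on the row positions (an equivalence relation).
#' @export
row_classes <- function(d, row = c("top", "bottom")) {
  row <- match.arg(row)
  n <- d$n; m <- d$m
  if (row == "top") {
    parts <- lapply(d$partition$blocks, function(b) b[b <= n])
    size <- n
  } else {
    if (m == 0L) stop("diagram has no bottom row", call. = FALSE)
    parts <- lapply(d$partition$blocks,
                    function(b) n + m + 1L - b[b > n])  # label -> position
    size <- m
  }
  parts <- parts[vapply(parts, length, integer(1L)) > 0L]
  covered <- unlist(parts, use.names = FALSE)
  singles <- as.list(setdiff(seq_len(size), covered))
  set_partition(c(parts, singles), ground_size = size)
}

#' Join of two equivalence relations
#'
#' The smallest equivalence relation containing the union of `r1` and `r2`
#' (their join in the lattice of equivalences), computed by transitive
#' closure of the merged classes.  Both relations are represented as
#' `set_partition`s of the same ground set.
#'
#' @param r1,r2 `set_partition` objects on the same ground set.
#' @return A `set_partition`: the join.
#' @export
join_equivalences <- function(r1, r2) {
  if (r1$ground_size != r2$ground_size)
    stop("equivalences are on different ground sets (", r1$ground_size,
         " vs ", r2$ground_size, ")", call. = FALSE)
  t <- r1$ground_size
  parent <- seq_len(t)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (b in c(r1$blocks, r2$blocks))
    if (length(b) > 1L) for (x in b[-1L]) {
      ri <- find(b[[1L]]); rj <- find(x)
      if (ri != rj) parent[rj] <- ri
    }
  membership_to_partition(vapply(seq_len(t), find, integer(1L)))
}

#' Does an equivalence separate a target set?
#'
#' An equivalence relation separates a set `targets` when every equivalence
#' class contains at most one element of `targets`.
#'
#' @param eq a `set_partition` (equivalence relation).
#' @param targets integer vector, a subset of the ground set.
#' @return `TRUE` or `FALSE`.
#' @export
separates <- function(eq, targets) {
  targets <- as.integer(targets)
  if (length(targets) > 0L &&
      (min(targets) < 1L || max(targets) > eq$ground_size))
    stop("`targets` must be a subset of the ground set 1..", eq$ground_size,
         call. = FALSE)
  all(vapply(eq$blocks, function(b) sum(b %in% targets) <= 1L, logical(1L)))
}

# ---- generators -------------------------------------------------------------

#' Diagrams of the standard generators
#'
#' `brauer_generator("s", i, n)` is the simple transposition \eqn{s_i}
#' (crossing of strands `i` and `i+1`); `brauer_generator("e", i, n)` is the
#' Temperley--Lieb cup/cap generator \eqn{e_i}; `permutation_diagram(sigma)`
#' is the diagram of an arbitrary permutation, connecting top `j` to bottom
#' position `sigma[j]`.  All are balanced diagrams in `B[n, n]`.
#'
#' @param kind `"s"` or `"e"`.
#' @param i generator index, `1 <= i <= n - 1`.
#' @param n ambient size.
#' @param sigma an integer permutation of `1:n`.
#' @return A `partition_diagram` in shape `(n, n)`.
#' @export
brauer_generator <- function(kind = c("s", "e"), i, n) {
  kind <- match.arg(kind)
  i <- as.integer(i); n <- as.integer(n)
  if (i < 1L || i > n - 1L)
    stop("generator index must satisfy 1 <= i <= n - 1", call. = FALSE)
  bot <- function(p) 2L * n + 1L - p   # bottom position p -> label
  other <- setdiff(seq_len(n), c(i, i + 1L))
  id_part <- lapply(other, function(j) c(j, bot(j)))
  blocks <- if (kind == "s") {
    c(list(c(i, bot(i + 1L)), c(i + 1L, bot(i))), id_part)
  } else {
    c(list(c(i, i + 1L), c(bot(i), bot(i + 1L))), id_part)
  }
  partition_diagram(n, n, blocks)
}

#' @rdname brauer_generator
#' @export
permutation_diagram <- function(sigma) {
  sigma <- as.integer(sigma)
  n <- length(sigma)
  if (!setequal(sigma, seq_len(n)))
    stop("`sigma` must be a permutation of 1..n", call. = FALSE)
  blocks <- lapply(seq_len(n), function(j) c(j, 2L * n + 1L - sigma[j]))
  partition_diagram(n, n, blocks)
}

#' Identity diagram in B\[n, n\]
#'
#' @param n size.
#' @return The identity `partition_diagram`.
#' @export
identity_diagram <- function(n) permutation_diagram(seq_len(n))

# ---- text / JSON dialect ----------------------------------------------------

#' Text and JSON dialects for diagrams
#'
#' Diagrams serialize as `n=6;m=4;blocks=1,10|2,3|4,6|5,7|8,9` (canonical
#' block order) or as the JSON twin
#' `{"n":6,"m":4,"blocks":[[1,10],[2,3],...]}`.  Both round-trip exactly.
#'
#' @param d a `partition_diagram`.
#' @param text,json serialized forms.
#' @return The serialized string, or the parsed `partition_diagram`.
#' @export
diagram_to_text <- function(d) {
  paste0("n=", d$n, ";m=", d$m, ";blocks=", partition_to_text(d$partition))
}

#' @rdname diagram_to_text
#' @export
text_to_diagram <- function(text) {
  text <- trimws(text)
  m <- regmatches(text,
                  regexec("^n=([0-9]+);m=([0-9]+);blocks=(.+)$", text))[[1L]]
  if (length(m) != 4L)
    stop("malformed diagram text; expected `n=..;m=..;blocks=..`", call. = FALSE)
  partition_diagram(as.integer(m[[2L]]), as.integer(m[[3L]]),
                    text_to_partition(m[[4L]]))
}

#' @rdname diagram_to_text
#' @export
diagram_to_json <- function(d) {
  jsonlite::toJSON(list(n = d$n, m = d$m, blocks = d$partition$blocks),
                   auto_unbox = TRUE)
}

#' @rdname diagram_to_text
#' @export
json_to_diagram <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  partition_diagram(x$n, x$m, lapply(x$blocks, function(b) unlist(b)))
}
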