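#' Double factorial
#'
#' `double_factorial(k)` is `k * (k - 2) * ...` down to 1 or 2, with the
#' conventions `(-1)!! = 0!! = 1` (the `(-1)!!` case is needed by the
#' regular-subsemigroup counting formula at `j = k`).
#'
#' @param k integer `>= -1`.
#' @return A numeric (exact for the desk-scale sizes used here).
#' @export
double_factorial <- function(k) {
  k <- as.integer(k)
  if (k < -1L) stop("double factorial undefined for k < -1", call. = FALSE)
  if (k <= 0L) return(1)
  prod(seq(k, 1L, by = -2L))
}

#' Act on a diagram from the top or the bottom
#'
#' `act_top(g, d)` composes the balanced diagram `g` (an element of
#' `B[n, n]`, e.g. a generator from [brauer_generator()] or a permutation
#' diagram) above `d`; `act_bottom(d, g)` composes `g` below.  Permutation
#' actions permute one row of `d` and realize the restricted Green's
#' relations; Temperley--Lieb actions can create singleton blocks and hence
#' leave tree space.  Loops removed by the composition are discarded.
#'
#' @param g a balanced `partition_diagram`.
#' @param d a `partition_diagram` with matching row size.
#' @return The resulting `partition_diagram`.
#' @export
act_top <- function(g, d) compose(g, d)$diagram

#' @rdname act_top
#' @export
act_bottom <- function(d, g) compose(d, g)$diagram

#' Keys for the restricted Green's relations
#'
#' Two diagrams of `B[n, n-2]` are L-related (left action by the symmetric
#' group on the top row) iff they have the same bottom half; R-related
#' (right action on the bottom row) iff they have the same top half;
#' H-related iff both; D-related iff they have the same rank.  The key is a
#' canonical string of the relevant half: the row's positional equivalence
#' classes plus the positions of its transversal endpoints.
#'
#' @param d a `partition_diagram`.
#' @param relation one of `"L"`, `"R"`, `"H"`, `"D"`.
#' @return A character key; equal keys characterize related diagrams.
#' @export
green_class_key <- function(d, relation = c("L", "R", "H", "D")) {
  relation <- match.arg(relation)
  st <- analyze(d)
  top_key <- paste0(partition_to_text(row_classes(d, "top")), "/dom:",
                    paste(st$dom, collapse = ","))
  bottom_key <- if (d$m == 0L) "-" else
    paste0(partition_to_text(row_classes(d, "bottom")), "/codom:",
           paste(sort(d$n + d$m + 1L - st$codom), collapse = ","))
  switch(relation,
         L = bottom_key,
         R = top_key,
         H = paste(top_key, bottom_key, sep = " || "),
         D = as.character(st$rank))
}

#' Eggbox census of a D-class of binary-tree diagrams
#'
#' Enumerates all Brauer diagrams of shape `(n, n-2)` (equivalently all
#' binary trees on `n` leaves) of the given rank and tabulates the eggbox of
#' the restricted Green's relations: L-classes are the rows (distinct bottom
#' halves), R-classes the columns (distinct top halves), and each H-class
#' (row-column intersection) holds `k!` diagrams.
#'
#' @param n number of leaves (guarded at `n <= 10`).
#' @param k rank; must satisfy `0 <= k <= n - 2` and `k = n (mod 2)`.
#' @return An object of class `eggbox`: a list with `n`, `rank`, `n_L`
#'   (rows), `n_R` (columns), `n_H`, `h_size`, `total`.
#' @examples
#' eggbox(6, 2)  # 6 rows x 45 columns, H-classes of size 2, 540 trees
#' @export
eggbox <- function(n, k) {
  n <- as.integer(n); k <- as.integer(k)
  if (k < 0L || k > n - 2L || ((n - k) %% 2L) != 0L)
    stop("rank k must satisfy 0 <= k <= n - 2 and k = n (mod 2)",
         call. = FALSE)
  diags <- all_brauer_diagrams(n)
  diags <- diags[vapply(diags, diagram_rank, integer(1L)) == k]
  l_keys <- vapply(diags, green_class_key, character(1L), relation = "L")
  r_keys <- vapply(diags, green_class_key, character(1L), relation = "R")
  h_keys <- paste(r_keys, l_keys, sep = " || ")
  n_L <- length(unique(l_keys))
  n_R <- length(unique(r_keys))
  n_H <- length(unique(h_keys))
  h_size <- factorial(k)
  total <- length(diags)
  stopifnot(total == n_L * n_R * h_size, n_H == n_L * n_R,
            all(table(h_keys) == h_size))
  structure(list(n = n, rank = k, n_L = n_L, n_R = n_R, n_H = n_H,
                 h_size = h_size, total = total), class = "eggbox")
}

#' @export
print.eggbox <- function(x, ...) {
  cat("<eggbox> B[", x$n, ",", x$n - 2L, "], rank ", x$rank, ": ",
      x$n_L, " L-classes (rows) x ", x$n_R, " R-classes (columns), ",
      x$n_H, " H-classes of size ", x$h_size, ", total ", x$total,
      " diagrams\n", sep = "")
  invisible(x)
}

#' Fixed-tree context for the sandwich product
#'
#' Fixes the middle diagram `T` of the sandwich product, caching its flip
#' `Tbar` and rank.  `T` may be given as a diagram, a forest, or Newick
#' text.  The classification of `T` is recorded: the product is defined for
#' any diagram of compatible shape, but only binary-tree contexts keep the
#' product inside Brauer tree space.
#'
#' @param T a `partition_diagram`, `phylo_forest` or Newick string.
#' @return An object of class `sandwich_context` with fields `T`, `Tbar`,
#'   `rank`, `classification`.
#' @export
sandwich_context <- function(T) {
  if (!inherits(T, "partition_diagram")) T <- phylo_to_diagram(as_forest(T))
  structure(list(T = T, Tbar = flip(T), rank = diagram_rank(T),
                 classification = classify_diagram(T)),
            class = "sandwich_context")
}

#' @export
print.sandwich_context <- function(x, ...) {
  cat("<sandwich_context> T in B[", x$T$n, ",", x$T$m, "], rank ", x$rank,
      ", ", x$classification$verdict, "\n", sep = "")
  invisible(x)
}

#' Sandwich product of two diagrams relative to a fixed tree
#'
#' The product `a *_T b = a . Tbar . b`, composing through the flipped fixed
#' diagram.  It turns the unbalanced diagrams of shape `(n, n-2)` into a
#' semigroup.  The result's rank is at most `min(rank a, rank T, rank b)`;
#' when non-binary diagrams are involved the product may leave tree space,
#' so the classification of the result is attached.
#'
#' @param a,b `partition_diagram`s of the same shape as `ctx$T`.
#' @param ctx a [sandwich_context()].
#' @return A list with `diagram`, `loops` (total removed), and
#'   `classification` of the product.
#' @export
sandwich_product <- function(a, b, ctx) {
  stopifnot(inherits(ctx, "sandwich_context"))
  step1 <- compose(a, ctx$Tbar)
  step2 <- compose(step1$diagram, b)
  list(diagram = step2$diagram, loops = step1$loops + step2$loops,
       classification = classify_diagram(step2$diagram))
}

#' Regularity of a diagram in the sandwich semigroup
#'
#' An element `x` of a semigroup is regular when `x a x = x` for some `a`.
#' In the sandwich semigroup relative to `T` this is equivalent to either
#' characterization implemented here:
#' * `method = "rank"`: `Tbar . alpha . Tbar` has the same rank as `alpha`;
#' * `method = "separation"`: `coker(alpha) v ker(Tbar)` separates
#'   `codom(alpha)` and `ker(alpha) v coker(Tbar)` separates `dom(alpha)`,
#'   with all relations normalized to left-to-right positions within their
#'   row before joining.
#'
#' @param alpha a `partition_diagram` of the shape of `ctx$T`.
#' @param ctx a [sandwich_context()].
#' @param method `"rank"` or `"separation"`.
#' @return `TRUE` or `FALSE`.
#' @export
is_regular <- function(alpha, ctx, method = c("rank", "separation")) {
  method <- match.arg(method)
  stopifnot(inherits(ctx, "sandwich_context"))
  if (method == "rank") {
    mid <- compose(compose(ctx$Tbar, alpha)$diagram, ctx$Tbar)$diagram
    return(diagram_rank(mid) == diagram_rank(alpha))
  }
  st <- analyze(alpha)
  n <- alpha$n; m <- alpha$m
  codom_pos <- n + m + 1L - st$codom
  cond1 <- separates(join_equivalences(row_classes(alpha, "bottom"),
                                       row_classes(ctx$Tbar, "top")),
                     codom_pos)
  cond2 <- separates(join_equivalences(row_classes(alpha, "top"),
                                       row_classes(ctx$Tbar, "bottom")),
                     st$dom)
  cond1 && cond2
}

#' Size of the regular subsemigroup, in closed form
#'
#' The number of regular elements of the sandwich semigroup on
#' `B[n, n-2]` relative to any diagram of rank `k`:
#' \deqn{\sum_{0 \le j \le k,\; j \equiv k (2)}
#'   \binom{k}{j}^2 \frac{((k-j-1)!!)^2\,(n+j-1)!!\,(n+j-3)!!\, j!}
#'        {((k+j-1)!!)^2},}
#' with the convention `(-1)!! = 1` for the `j = k` term.
#'
#' @param n number of leaves.
#' @param k rank of the fixed diagram; `0 <= k <= n - 2`, `k = n (mod 2)`.
#' @return The exact count (numeric).
#' @examples
#' regular_count_formula(6, 4)  # 45 + 504 + 216 = 765
#' @export
regular_count_formula <- function(n, k) {
  n <- as.integer(n); k <- as.integer(k)
  if (k < 0L || k > n - 2L || ((n - k) %% 2L) != 0L)
    stop("rank k must satisfy 0 <= k <= n - 2 and k = n (mod 2)",
         call. = FALSE)
  js <- seq.int(k %% 2L, k, by = 2L)
  sum(vapply(js, function(j) {
    choose(k, j)^2 * double_factorial(k - j - 1L)^2 *
      double_factorial(n + j - 1L) * double_factorial(n + j - 3L) *
      factorial(j) / double_factorial(k + j - 1L)^2
  }, numeric(1L)))
}

#' Enumerate the regular elements / idempotents of a sandwich semigroup
#'
#' Brute-force enumeration over all `(2n-3)!!` Brauer diagrams of shape
#' `(n, n-2)`: `regular_elements()` keeps those passing [is_regular()];
#' `idempotents()` keeps those with `x *_T x == x`.  Idempotents are always
#' regular.  Guarded at `n <= 10` unless `force = TRUE`.
#'
#' @param ctx a [sandwich_context()].
#' @param method regularity test passed to [is_regular()].
#' @param force allow `n > 10`.
#' @return A list of `partition_diagram`s.
#' @export
regular_elements <- function(ctx, method = "rank", force = FALSE) {
  n <- ctx$T$n
  diags <- all_brauer_diagrams(n, force = force)
  diags[vapply(diags, is_regular, logical(1L), ctx = ctx, method = method)]
}

#' @rdname regular_elements
#' @export
idempotents <- function(ctx, force = FALSE) {
  n <- ctx$T$n
  diags <- all_brauer_diagrams(n, force = force)
  diags[vapply(diags, function(x) {
    sandwich_product(x, x, ctx)$diagram == x
  }, logical(1L))]
}

#' Product and involution of binary trees via balanced Brauer diagrams
#'
#' `tree_product_balanced(t1, t2)` multiplies two binary trees on the same
#' leaf set through their balanced diagrams in `B[n-1]`
#' (compose, then invert the bijection); `tree_involution(t)` applies the
#' `*`-involution (flip of the balanced diagram).  Since the balanced-diagram
#' correspondence is onto the whole Brauer monoid `B[n-1]`, both operations
#' are total on binary trees; a typed `brauerphylo_not_a_tree` error is
#' raised should a result ever fail to classify as a tree.
#'
#' @param t1,t2,t binary trees (`phylo_forest` with one component, or Newick).
#' @return A single-tree `phylo_forest`.
#' @examples
#' t <- "(1,((4,6),(5,(2,3))));"
#' tree_involution(t) == parse_newick(t)  # this tree is self-adjoint
#' @export
tree_product_balanced <- function(t1, t2) {
  d1 <- balanced_tree_diagram(as_forest(t1))
  d2 <- balanced_tree_diagram(as_forest(t2))
  if (d1$n != d2$n)
    stop(errorCondition("trees have different leaf counts",
         class = c("brauerphylo_dimension_error", "error", "condition")))
  balanced_to_tree(compose(d1, d2)$diagram)
}

#' @rdname tree_product_balanced
#' @export
tree_involution <- function(t) {
  balanced_to_tree(flip(balanced_tree_diagram(as_forest(t))))
}

balanced_tree_diagram <- function(f) {
  if (!is_single_tree(f) || !structure_stats(f)$is_binary)
    stop(errorCondition("expected a single binary tree",
         class = c("brauerphylo_not_a_tree", "error", "condition")))
  to_balanced(phylo_to_diagram(f))
}

balanced_to_tree <- function(d) {
  ub <- from_balanced(d)
  cls <- classify_diagram(ub)
  if (cls$verdict != "binary_tree")
    stop(errorCondition("product diagram does not correspond to a tree",
         class = c("brauerphylo_not_a_tree", "error", "condition"),
         diagram = ub))
  diagram_to_phylo(ub)
}
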