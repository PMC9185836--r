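---
title: "Trees, forests and diagram algebra: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trees, forests and diagram algebra: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brauerphylo)
```

## The model

A rooted binary phylogenetic tree on `n` labelled leaves can be encoded as a
perfect matching of the set `{1, ..., 2n-2}`: the leaves take the labels
`1..n`, the internal vertices are numbered `n+1, n+2, ...` by a
deterministic rule (below), and each block of the matching is a sibling
pair.  Perfect matchings of `2n-2` points are exactly the diagrams of the
Brauer monoid, so the encoding transports the rich algebra of diagram
monoids — composition, involution, Green's relations, sandwich semigroups —
onto tree space.  This package implements that correspondence and its
extension to arbitrary (multifurcating) trees and forests, where matchings
are replaced by general set partitions and Brauer diagrams by partition
diagrams.

The objects and their invariants:

* **Set partition** `pi` of `[t]`: `n_blocks(pi)` is the block count
  `l(pi)`, `n_nontrivial_blocks(pi)` counts blocks of size at least 2
  (`l_ge2(pi)`).
* **Partition diagram** in shape `(n, m)`: the partition laid out with `n`
  top nodes labelled `1..n` left to right and `m` bottom nodes labelled
  `n+1..n+m` **right to left** — the numbering continues clockwise around
  the frame.  This is the only layout under which the package's worked
  examples and the self-adjointness of symmetric trees hold simultaneously.
* **Forest** on `[n]`: components are rooted trees, internal out-degrees
  at least 2, leaf sets partitioning `[n]`; trivial single-leaf trees are
  allowed.

## The numbering rule and its inverse

`phylo_to_partition()` numbers non-leaf vertices `n+1, n+2, ...` by
repeatedly choosing, among the vertices all of whose children are already
numbered, the one whose lowest-numbered child is smallest.  Ties cannot
occur: candidate vertices are compared by the minimum of their children's
numbers, and these minima are distinct because each number belongs to one
vertex.  Exactly one root is left unnumbered.  Blocks are the sibling sets;
every *numbered* root contributes a singleton block.

`partition_to_forest()` inverts this.  Given `pi`, the leaf count is
`n = |pi| - l_ge2(pi) + 1`.  Starting from `n` isolated leaves, the
non-trivial blocks are consumed one at a time: among the blocks whose
elements all label existing vertices, the one containing the least integer
is attached under a new parent, numbered `n+1, n+2, ...`; the final parent
is the unnumbered root.  A counting argument guarantees an eligible block
always exists, so the construction succeeds for *every* set partition of
`[t]` — the error branch for an ineligible state is an assertion, not a
recoverable path.

**Trivial-forest convention.**  The dimension formula
`n = |pi| - l_ge2(pi) + 1` accounts for the one unnumbered root and is
therefore stated for non-trivial partitions.  The all-singleton partition
of `[t]` has no unnumbered root; we pair it with the trivial forest on `t`
leaves and set `n = t`, `m = 0`, `tau = t` in `dims_from_partition()`.
With this convention the forest/partition correspondence is a bijection
with no gaps at the boundary.

## Diagram composition and the loop weight

`compose()` glues the bottom row of the upper diagram to the top row of the
lower diagram **by left-to-right position**, not by label: under the
clockwise convention the bottom labels read backwards, so positional gluing
is what makes the categorical product associative.  Components of the glue
are computed by union–find; components consisting only of middle nodes are
closed loops.  The loop weight is fixed at 1, so loops simply vanish from
the product, but their count is returned so that a later generalization to
an arbitrary loop parameter needs no interface change.  No downstream
computation in the package consumes the loop count.

The `flip()` involution reflects a diagram about the horizontal axis.
Positionally this is `top position i <-> bottom position i`; on clockwise
labels it is simply `x -> n + m + 1 - x` with the row sizes swapped, which
is why it is exact and cheap.  It is an anti-homomorphism:
`flip(a . b) = flip(b) . flip(a)`.

Whenever relations from different diagrams are compared or joined —
notably in the separation form of the regularity test — both relations are
first normalized to *positional* indices within their row
(`row_classes()`).  Comparing raw labels across diagrams of different
shapes would be meaningless because the clockwise numbering shifts with
the shape.

## Green's relations on tree space

The package uses the restricted relations: left action by the symmetric
group on the top row (L), right action on the bottom row (R), their
intersection (H).  Because the top action reaches every arrangement of a
top half, an L-class is exactly "all diagrams with a given bottom half",
and dually for R; `green_class_key()` therefore keys classes by canonical
strings of the halves, and the test suite verifies the keys against an
explicit orbit computation.  For the D-relation we take the equivalence
*generated* by L and R, which here coincides with "equal rank".  A literal
reading of the defining union `[T]_D = [T]_L ∪ [T]_R` would not be an
equivalence relation (it is not transitive class-wise); the generated
equivalence is what the eggbox picture and the rank decomposition use, so
that is what `green_class_key(d, "D")` implements.

`eggbox(n, k)` recomputes the census by enumeration and cross-checks the
identity `total = rows x columns x k!` as an internal assertion.

## The sandwich product and regularity

For a fixed diagram `T` of shape `(n, n-2)`, the product
`a *_T b = a . flip(T) . b` makes the unbalanced diagrams a semigroup.
`is_regular()` implements two independent characterizations:

* **rank**: `flip(T) . a . flip(T)` has the same rank as `a`;
* **separation**: `coker(a) v ker(flip(T))` separates `codom(a)`, and
  `ker(a) v coker(flip(T))` separates `dom(a)`, all relations positional.

The two are proved equivalent in the semigroup literature; the suite
checks their agreement exhaustively over all 945 six-leaf diagrams for
contexts of ranks 0, 2 and 4.  `regular_count_formula()` evaluates the
closed-form sum for the size of the regular subsemigroup, using the
convention `(-1)!! = 1` for its top term, and is cross-checked against the
brute-force census.

`tree_product_balanced()` multiplies two binary trees through their
balanced diagrams.  Because the balanced correspondence is onto the whole
Brauer monoid, this product is total on binary trees; the typed
not-a-tree error is retained defensively and is exercised only by
non-binary inputs, where sandwich products can genuinely leave tree space
(an isolated node appears, or the count condition `m = l(pi) - tau`
fails).  `classify_diagram()` reports which of these cases occurred.

## Generators and enumeration

`all_set_partitions()` enumerates by assigning the smallest unplaced
element to an existing or a new block, pruning branches whose under-filled
blocks can no longer be completed; the order is canonical and
duplicate-free, which the fixtures rely on.  Counts come independently
from the partial-Bell recursion
`f(t) = sum_s C(t-1, s-1) f(t-s)` over allowed block sizes `s`.
Enumerative entry points guard at `n <= 10` (the `(2n-3)!!` growth makes
larger `n` pointless to enumerate) with a `force` override.

`random_phylo(n, mode = "binary")` grows a tree by sequential attachment:
leaf `k+1` is attached uniformly to one of the `2k-1` positions (any
non-root vertex's parent edge, or above the root).  Every topology on
`k+1` leaves arises from exactly one topology on `k` leaves in exactly one
way, which yields the uniform distribution over all `(2n-3)!!` labelled
topologies; the suite backs this argument with a chi-squared test against
the exhaustive census.  `mode = "general"` samples uniformly over all
rooted (possibly non-binary) trees on `n` leaves by exact two-stage
sampling: the number of internal vertices is drawn proportionally to its
slice count, then a partition of the slice is drawn by the standard
recursive unranking of the restricted-block counting recursion.  No
rejection or approximation is involved.

What the generators emulate — and what they do not: they produce uniform
*topologies* with integer leaf labels.  They have no branch lengths, no
clock, and no biological non-uniformity (real tree posteriors are far from
uniform), so passing distributional tests here validates the combinatorial
machinery, not any evolutionary model fit.

## Problem sizes used by the test suite

All headline claims are desk-scale integer combinatorics, so the suite
verifies them exactly: exhaustive enumeration of the 945 six-leaf binary
trees (census, eggboxes, both regularity tests, idempotents), exhaustive
tree round trips at `n = 6` and forest round trips at `n <= 6` (5504
forests on six leaves), 500-case random checks for the algebra laws, and
28,350 random draws (30 expected per topology) for the chi-squared
uniformity check at significance 0.01.

## Limitations

* Enumeration-backed operations are for small `n` by design; the package
  does not attempt asymptotic or unlabelled-shape counting.
* The loop parameter is fixed at 1; the Brauer *algebra* over a general
  loop weight (formal linear combinations of diagrams) is out of scope.
* Green's relations are the restricted (symmetric-group) versions; the
  full-monoid versions coarsen them and are not implemented.
* Newick input keeps only topology: branch lengths and internal labels are
  dropped with a warning.
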