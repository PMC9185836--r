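# brauerphylo

Rooted phylogenetic trees and forests as elements of Brauer and partition
diagram monoids.

Every rooted binary tree on `n` labelled leaves corresponds to a perfect
matching of `{1, ..., 2n-2}`: leaves carry `1..n`, internal vertices are
numbered deterministically, and blocks are sibling pairs.  Laid out with the
`n` leaves on top and the `n-2` internal numbers on the bottom (numbered
clockwise), the matching is an unbalanced Brauer diagram in `B[n, n-2]`, and
tree space inherits the algebra of diagram monoids:

* **Composition** of diagrams (concatenation, positional gluing, closed
  loops removed at loop weight 1) and the **flip** involution
  `x -> n + m + 1 - x`.
* **Restricted Green's relations**: L/R/H-classes from symmetric-group
  actions on the rows, displayed as eggbox censuses — e.g. the 945 six-leaf
  binary trees split by rank into 45 + 540 + 360, and the rank-2 class is a
  6 x 45 eggbox of 270 H-classes of size 2.
* **Sandwich product** `a *_T b = a · flip(T) · b` relative to a fixed tree
  `T`, its regular subsemigroup (two independent regularity tests: rank
  preservation under `flip(T) · a · flip(T)`, and the join/separation
  conditions on kernels and cokernels), the closed-form count

  `|Reg| = Σ_{j ≡ k (2), 0 ≤ j ≤ k} C(k,j)² ((k-j-1)!!)² (n+j-1)!! (n+j-3)!! j! / ((k+j-1)!!)²`,

  and idempotent enumeration.
* **Non-binary trees and forests** via general set partitions: a partition
  `pi` of `[t]` encodes a tree iff it has no singletons and `m = l(pi) - 1`,
  and a forest with `tau` components iff it has `tau - 1` singletons and
  `m = l(pi) - tau`; `partition_to_forest()` realizes every set partition as
  a forest and `phylo_to_partition()` inverts it.
* **Enumeration and random generation** of binary trees (`(2n-3)!!`),
  general trees, forests, and set partitions with restricted block sizes
  (partial-Bell counting), plus uniform random topologies.

The package is aimed at researchers in algebraic phylogenetics and
combinatorics who want executable access to these correspondences: all the
desk-scale censuses are recomputed exactly rather than hard-coded.

## Worked example

```r
library(brauerphylo)

tr <- parse_newick("(1,((4,6),(5,(2,3))));")   # six-leaf binary tree
d  <- phylo_to_diagram(tr)
d
#> <partition_diagram B[6,4]> 1,10|2,3|4,6|5,7|8,9  (Brauer)
analyze(d)
#> rank:  2
#> dom:   {1,5}
#> codom: {7,10}
#> ker:   {(2,3),(4,6)} (+ symmetric pairs)
#> coker: {(8,9)} (+ symmetric pairs)
```

The tree's two cherries `{2,3}` and `{4,6}` become the kernel pairs, and the
rank 2 equals `n - 2·(number of cherries)`.  The diagram round-trips:

```r
write_newick(diagram_to_phylo(d))
#> [1] "(1,(((2,3),5),(4,6)));"       # same topology, canonical child order
```

Fixing the rank-4 tree `T` with matching `{{1,10},{2,9},{3,4},{5,8},{6,7}}`
as sandwich context, brute force over all 945 diagrams and the closed-form
formula agree:

```r
ctx <- sandwich_context(partition_diagram(6, 4,
         list(c(1,10), c(2,9), c(3,4), c(5,8), c(6,7))))
length(regular_elements(ctx))
#> [1] 765
regular_count_formula(6, 4)
#> [1] 765
table(sapply(regular_elements(ctx), diagram_rank))
#>   0   2   4
#>  45 504 216
```

Forests work through general partitions, including singleton blocks
(numbered roots and isolated leaves):

```r
f <- partition_to_forest(text_to_partition("1,10|2,12|3,4,6|5|7,8|9,13|11"))
write_newick(f)
#> [1] "(1,(3,4,6));\n((2,(7,8)),9);\n5;"
```

A command-line wrapper is installed at `exec/brauerphylo`, e.g.
`brauerphylo count --n 6 --by rank` prints `{"0":45,"2":540,"4":360}`.

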