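# Shared worked-example fixtures used across the suite.

# six-leaf tree whose matching is {{1,10},{2,3},{4,6},{5,7},{8,9}}
six_leaf_newick <- "(1,((4,6),(5,(2,3))));"
six_leaf_matching <- text_to_partition("1,10|2,3|4,6|5,7|8,9")

# rank-4 (caterpillar-like) fixed tree of the regular-subsemigroup example
rank4_ctx_matching <- text_to_partition("1,10|2,9|3,4|5,8|6,7")
rank4_ctx_diagram <- partition_diagram(6, 4, rank4_ctx_matching)

# a rank-0 (three-cherry) six-leaf tree
rank0_ctx_diagram <- partition_diagram(
  6, 4, list(c(1, 2), c(3, 4), c(5, 6), c(7, 8), c(9, 10)))

# nine-leaf non-binary tree from the partition of [12] into four blocks
nonbinary_partition <- text_to_partition("1,3,12|2,9|4,6,8,11|5,7,10")

# nine-leaf three-component forest partition of [13]
forest_partition <- text_to_partition("1,10|2,12|3,4,6|5|7,8|9,13|11")

random_brauer <- function(n) {
  elems <- seq_len(2L * n - 2L)
  blocks <- list()
  while (length(elems) > 0L) {
    j <- if (length(elems) == 2L) 2L else sample(2:length(elems), 1L)
    blocks[[length(blocks) + 1L]] <- c(elems[[1L]], elems[[j]])
    elems <- elems[-c(1L, j)]
  }
  partition_diagram(n, n - 2L, blocks)
}

# random balanced Brauer diagram of shape (n, m) drawn as a matching
random_diagram <- function(n, m) {
  stopifnot((n + m) %% 2L == 0L)
  elems <- seq_len(n + m)
  blocks <- list()
  while (length(elems) > 0L) {
    j <- if (length(elems) == 2L) 2L else sample(2:length(elems), 1L)
    blocks[[length(blocks) + 1L]] <- c(elems[[1L]], elems[[j]])
    elems <- elems[-c(1L, j)]
  }
  partition_diagram(n, m, blocks)
}
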