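#' Set partitions of \{1..t\}
#'
#' A `set_partition` is a collection of non-empty, pairwise disjoint integer
#' blocks whose union is `1:ground_size`.  It is the basic combinatorial
#' object of the package: matchings (all blocks of size 2) encode binary
#' trees, partitions with blocks of size >= 2 encode arbitrary rooted trees,
#' and partitions with singleton blocks encode forests.
#'
#' Blocks are stored canonically: each block sorted ascending and the blocks
#' ordered by their minimum element, so two equal partitions are `identical()`.
#'
#' @param blocks list of integer vectors (the blocks).
#' @param ground_size size of the ground set; defaults to the number of
#'   elements supplied, but can be given explicitly as a cross-check.
#' @return An object of class `set_partition`.
#' @examples
#' set_partition(list(c(1, 10), c(2, 3), c(4, 6), c(5, 7), c(8, 9)))
#' @export
set_partition <- function(blocks, ground_size = NULL) {
  if (!is.list(blocks) || length(blocks) == 0L)
    stop("`blocks` must be a non-empty list of integer vectors", call. = FALSE)
  blocks <- lapply(blocks, function(b) {
    b <- as.integer(b)
    if (length(b) == 0L) stop("empty block is not allowed", call. = FALSE)
    if (anyNA(b)) stop("block contains NA", call. = FALSE)
    sort(b)
  })
  all_elems <- unlist(blocks, use.names = FALSE)
  t <- if (is.null(ground_size)) length(all_elems) else as.integer(ground_size)
  if (any(all_elems < 1L))
    stop("partition elements must be positive integers", call. = FALSE)
  dup <- all_elems[duplicated(all_elems)]
  if (length(dup) > 0L)
    stop("element ", dup[[1L]], " appears in more than one block", call. = FALSE)
  missing <- setdiff(seq_len(t), all_elems)
  if (length(missing) > 0L)
    stop("element ", missing[[1L]], " of the ground set 1..", t,
         " is missing from the blocks", call. = FALSE)
  extra <- all_elems[all_elems > t]
  if (length(extra) > 0L)
    stop("element ", extra[[1L]], " exceeds the ground set 1..", t, call. = FALSE)
  blocks <- blocks[order(vapply(blocks, min, integer(1L)))]
  structure(list(ground_size = t, blocks = blocks), class = "set_partition")
}

#' @export
print.set_partition <- function(x, ...) {
  cat("<set_partition of [", x$ground_size, "]> ", partition_to_text(x), "\n",
      sep = "")
  invisible(x)
}

#' Accessors for set partitions
#'
#' `n_blocks()` is the number of blocks (the quantity usually written
#' \eqn{\ell(\pi)}), `ground_size()` the size of the ground set
#' (\eqn{|\pi|}), `n_nontrivial_blocks()` the number of blocks of size at
#' least 2 (\eqn{\ell_{\ge 2}(\pi)}) and `n_singletons()` the number of
#' singleton blocks.
#'
#' @param pi a `set_partition`.
#' @return An integer.
#' @export
n_blocks <- function(pi) length(pi$blocks)

#' @rdname n_blocks
#' @export
ground_size <- function(pi) pi$ground_size

#' @rdname n_blocks
#' @export
n_nontrivial_blocks <- function(pi) sum(block_sizes(pi) >= 2L)

#' @rdname n_blocks
#' @export
n_singletons <- function(pi) sum(block_sizes(pi) == 1L)

#' @rdname n_blocks
#' @export
block_sizes <- function(pi) vapply(pi$blocks, length, integer(1L))

#' Is every block a pair?
#'
#' A perfect matching is a set partition all of whose blocks have size
#' exactly 2; matchings on \[2n-2\] are exactly the binary-tree partitions.
#'
#' @param pi a `set_partition`.
#' @return `TRUE` or `FALSE`.
#' @export
is_perfect_matching <- function(pi) all(block_sizes(pi) == 2L)

#' @export
Ops.set_partition <- function(e1, e2) {
  if (!.Generic %in% c("==", "!="))
    stop("operation `", .Generic, "` not defined for set_partition objects",
         call. = FALSE)
  eq <- identical(unclass(e1), unclass(e2))
  if (.Generic == "==") eq else !eq
}

#' Block-list text dialect for partitions
#'
#' Partitions serialize as blocks joined by `|`, elements within a block
#' joined by `,`, in canonical order, e.g. `"1,10|2,3|4,6|5,7|8,9"`.
#' The round trip `text_to_partition(partition_to_text(pi))` is exact.
#'
#' @param pi a `set_partition`.
#' @param text a block-list string.
#' @return `partition_to_text()` a string; `text_to_partition()` a
#'   `set_partition`.
#' @export
partition_to_text <- function(pi) {
  paste(vapply(pi$blocks, function(b) paste(b, collapse = ","), character(1L)),
        collapse = "|")
}

#' @rdname partition_to_text
#' @export
text_to_partition <- function(text) {
  text <- trimws(text)
  if (text == "") stop("empty partition text", call. = FALSE)
  blocks <- lapply(strsplit(text, "|", fixed = TRUE)[[1L]], function(b) {
    v <- suppressWarnings(as.integer(strsplit(b, ",", fixed = TRUE)[[1L]]))
    if (anyNA(v)) stop("malformed block `", b, "` in partition text",
                       call. = FALSE)
    v
  })
  set_partition(blocks)
}

# membership vector: elem -> block index (internal)
block_membership <- function(pi) {
  mem <- integer(pi$ground_size)
  for (i in seq_along(pi$blocks)) mem[pi$blocks[[i]]] <- i
  mem
}

# rebuild a set_partition from a membership vector (internal)
membership_to_partition <- function(mem) {
  set_partition(unname(split(seq_along(mem), mem)), ground_size = length(mem))
}
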