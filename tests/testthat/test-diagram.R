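test_that("diagram construction and equality follow the clockwise layout", {
  d <- partition_diagram(6, 4, six_leaf_matching)
  expect_true(is_brauer(d))
  expect_true(d == partition_diagram(6, 4, list(c(10, 1), c(3, 2), c(6, 4),
                                                c(7, 5), c(9, 8))))
  expect_false(d == partition_diagram(5, 5, six_leaf_matching))
  # non-Brauer partition diagrams construct fine (classified elsewhere)
  nd <- partition_diagram(4, 2, list(c(1, 2, 6), c(3, 4, 5)))
  expect_false(is_brauer(nd))
  expect_error(partition_diagram(6, 3, six_leaf_matching), "n \\+ m")
})

test_that("analysis reproduces the printed dom/codom/ker/coker/rank", {
  st <- analyze(partition_diagram(6, 4, six_leaf_matching))
  expect_identical(st$dom, c(1L, 5L))
  expect_identical(st$codom, c(7L, 10L))
  expect_identical(st$rank, 2L)
  expect_setequal(split(st$ker, row(st$ker)) |> vapply(paste, character(1),
                                                       collapse = ","),
                  c("2,3", "3,2", "4,6", "6,4"))
  expect_setequal(split(st$coker, row(st$coker)) |> vapply(paste, character(1),
                                                           collapse = ","),
                  c("8,9", "9,8"))

  idn <- identity_diagram(4)
  st_id <- analyze(idn)
  expect_identical(st_id$rank, 4L)
  expect_identical(nrow(st_id$ker), 0L)

  # rank-0 diagram satisfies |U(ker)| = |U(coker)| + 2
  d0 <- partition_diagram(6, 4, list(c(1, 2), c(3, 4), c(5, 6), c(7, 8),
                                     c(9, 10)))
  st0 <- analyze(d0)
  expect_identical(st0$rank, 0L)
  expect_identical(length(st0$u_ker), 6L)
  expect_identical(length(st0$u_coker), 4L)
})

test_that("composition glues by position, removes and counts loops", {
  e1 <- brauer_generator("e", 1, 2)
  s1 <- brauer_generator("s", 1, 2)
  r <- compose(e1, e1)
  expect_true(r$diagram == e1)
  expect_identical(r$loops, 1L)
  r <- compose(s1, s1)
  expect_true(r$diagram == identity_diagram(2))
  expect_identical(r$loops, 0L)

  e1_3 <- brauer_generator("e", 1, 3)
  e2_3 <- brauer_generator("e", 2, 3)
  expect_true(compose(e1_3, compose(e2_3, e1_3)$diagram)$diagram == e1_3)

  expect_error(compose(partition_diagram(2, 0, list(c(1, 2))), e1),
               class = "brauerphylo_dimension_error")
})

test_that("flip is a positional reflection and an involution", {
  d <- partition_diagram(6, 4, six_leaf_matching)
  expect_true(flip(flip(d)) == d)
  # balanced transcription of the six-leaf tree is symmetric about the axis
  bal <- partition_diagram(5, 5, six_leaf_matching)
  expect_true(flip(bal) == bal)
  # flipped bottom row carries the former top kernel, positionally
  fb <- flip(d)
  expect_identical(partition_to_text(row_classes(fb, "bottom")),
                   "1|2,3|4,6|5")
})

test_that("join and separation behave as lattice operations", {
  r1 <- set_partition(list(c(1, 2), 3, 4))
  r2 <- set_partition(list(c(2, 3), 1, 4))
  expect_identical(partition_to_text(join_equivalences(r1, r2)), "1,2,3|4")
  expect_identical(partition_to_text(join_equivalences(r1, r1)),
                   partition_to_text(r1))
  expect_true(separates(r1, c(1, 3)))
  expect_false(separates(r1, c(1, 2)))
  expect_error(join_equivalences(r1, set_partition(list(1, 2, 3))),
               "different ground sets")
  # join with the empty (discrete) relation is the identity
  expect_identical(partition_to_text(
    join_equivalences(r1, set_partition(as.list(1:4)))),
    partition_to_text(r1))
})

test_that("composition is associative with additive loop counts", {
  set.seed(41)
  for (i in 1:100) {
    a <- random_diagram(4, 4)
    b <- random_diagram(4, 2)
    c_ <- random_diagram(2, 4)
    ab <- compose(a, b)
    bc <- compose(b, c_)
    left <- compose(ab$diagram, c_)
    right <- compose(a, bc$diagram)
    expect_true(left$diagram == right$diagram)
    expect_identical(ab$loops + left$loops, bc$loops + right$loops)
  }
})

test_that("flip is an anti-homomorphism and rank is monotone", {
  set.seed(42)
  for (i in 1:100) {
    a <- random_diagram(5, 3)
    b <- random_diagram(3, 5)
    ab <- compose(a, b)$diagram
    expect_true(flip(ab) == compose(flip(b), flip(a))$diagram)
    expect_lte(diagram_rank(ab), min(diagram_rank(a), diagram_rank(b)))
  }
})

test_that("generator relations hold diagrammatically at loop weight 1", {
  for (n in 3:6) {
    idn <- identity_diagram(n)
    s <- lapply(seq_len(n - 1L), brauer_generator, kind = "s", n = n)
    e <- lapply(seq_len(n - 1L), brauer_generator, kind = "e", n = n)
    mult <- function(...) Reduce(function(x, y) compose(x, y)$diagram,
                                 list(...))
    for (i in seq_len(n - 1L)) {
      expect_true(mult(s[[i]], s[[i]]) == idn)
      expect_true(mult(e[[i]], e[[i]]) == e[[i]])
      expect_true(mult(s[[i]], e[[i]]) == e[[i]])
      expect_true(mult(e[[i]], s[[i]]) == e[[i]])
      if (i < n - 1L) {
        expect_true(mult(s[[i]], s[[i + 1]], s[[i]]) ==
                      mult(s[[i + 1]], s[[i]], s[[i + 1]]))
        expect_true(mult(e[[i]], e[[i + 1]], e[[i]]) == e[[i]])
        expect_true(mult(e[[i + 1]], e[[i]], e[[i + 1]]) == e[[i + 1]])
      }
      for (j in seq_len(n - 1L)) if (abs(i - j) >= 2L) {
        expect_true(mult(s[[i]], s[[j]]) == mult(s[[j]], s[[i]]))
        expect_true(mult(e[[i]], e[[j]]) == mult(e[[j]], e[[i]]))
      }
    }
  }
})

test_that("text and JSON diagram dialects round-trip bit-exactly", {
  d <- partition_diagram(6, 4, six_leaf_matching)
  txt <- diagram_to_text(d)
  expect_identical(txt, "n=6;m=4;blocks=1,10|2,3|4,6|5,7|8,9")
  expect_true(text_to_diagram(txt) == d)
  expect_true(json_to_diagram(diagram_to_json(d)) == d)
  nd <- partition_diagram(5, 1, list(c(1, 2, 6), c(3, 4, 5)))
  expect_true(text_to_diagram(diagram_to_text(nd)) == nd)
  expect_true(json_to_diagram(diagram_to_json(nd)) == nd)
  expect_error(text_to_diagram("n=6;blocks=1,2"), "malformed")
})
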