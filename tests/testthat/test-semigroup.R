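test_that("symmetric-group actions fix diagrams in the expected cases", {
  fig <- partition_diagram(6, 4, six_leaf_matching)
  # a transposition acting on a cup between i and i+1 acts as the identity
  expect_true(act_top(brauer_generator("s", 2, 6), fig) == fig)
  expect_true(act_top(identity_diagram(6), fig) == fig)
  expect_true(act_bottom(fig, identity_diagram(4)) == fig)
  # s_1 below a diagram whose bottom positional pair is {1,2}
  d0 <- partition_diagram(4, 2, list(c(1, 2), c(3, 4), c(5, 6)))
  expect_true(act_bottom(d0, brauer_generator("s", 1, 2)) == d0)
})

test_that("a Temperley-Lieb action can push a tree diagram out of tree space", {
  # top block {1, 2, 6} with 6 on the bottom: e_1 splits off singleton {6}
  d <- partition_diagram(5, 1, list(c(1, 2, 6), c(3, 4, 5)))
  res <- act_top(brauer_generator("e", 1, 5), d)
  expect_identical(classify_diagram(res)$verdict, "forest")
})

test_that("top and bottom actions commute", {
  set.seed(51)
  for (i in 1:100) {
    d <- random_brauer(5)
    g1 <- permutation_diagram(sample(5))
    g2 <- permutation_diagram(sample(3))
    expect_true(act_bottom(act_top(g1, d), g2) ==
                  act_top(g1, act_bottom(d, g2)))
  }
})

test_that("Green keys agree with orbits under the restricted actions", {
  fig <- partition_diagram(6, 4, six_leaf_matching)
  gens <- lapply(1:5, function(i) brauer_generator("s", i, 6))
  seen <- new.env()
  frontier <- list(fig)
  assign(diagram_to_text(fig), TRUE, envir = seen)
  while (length(frontier) > 0L) {
    nxt <- list()
    for (d in frontier) for (g in gens) {
      r <- act_top(g, d)
      k <- diagram_to_text(r)
      if (!exists(k, envir = seen)) {
        assign(k, TRUE, envir = seen)
        nxt[[length(nxt) + 1L]] <- r
      }
    }
    frontier <- nxt
  }
  alld <- all_brauer_diagrams(6)
  lkey <- green_class_key(fig, "L")
  lclass <- alld[vapply(alld, green_class_key, character(1L), "L") == lkey]
  expect_setequal(ls(envir = seen),
                  vapply(lclass, diagram_to_text, character(1L)))
  # H-classmates share both halves; relabelling within a cup stays in class
  mate <- act_top(brauer_generator("s", 2, 6), fig)
  for (rel in c("L", "R", "H", "D"))
    expect_identical(green_class_key(mate, rel), green_class_key(fig, rel))
})

test_that("eggbox censuses match the rank decomposition of six-leaf trees", {
  e2 <- eggbox(6, 2)
  expect_identical(c(e2$n_L, e2$n_R, e2$h_size, e2$n_H, e2$total),
                   c(6L, 45L, 2, 270L, 540L))
  e0 <- eggbox(6, 0)
  expect_identical(c(e0$h_size, e0$total), c(1, 45L))
  e4 <- eggbox(6, 4)
  expect_identical(c(e4$n_L, e4$n_R, e4$h_size, e4$total),
                   c(1L, 15L, 24, 360L))
  expect_identical(e0$total + e2$total + e4$total, 945L)
  expect_error(eggbox(6, 3), "mod 2")
})

test_that("the sandwich product composes through the flipped fixed tree", {
  ctx <- sandwich_context(rank4_ctx_diagram)
  expect_identical(ctx$rank, 4L)
  expect_identical(ctx$classification$verdict, "binary_tree")
  set.seed(61)
  for (i in 1:100) {
    a <- random_brauer(6); b <- random_brauer(6)
    res <- sandwich_product(a, b, ctx)
    expect_lte(diagram_rank(res$diagram),
               min(diagram_rank(a), ctx$rank, diagram_rank(b)))
  }
  # T is regular with respect to itself: the sandwich square keeps its rank
  expect_true(is_regular(ctx$T, ctx))
  # product over a non-binary context can land on a forest
  nb_ctx <- sandwich_context(partition_diagram(5, 1, list(c(1, 2, 6),
                                                          c(3, 4, 5))))
  set.seed(62)
  verdicts <- replicate(200, {
    res <- sandwich_product(random_diagram(5, 1), random_diagram(5, 1), nb_ctx)
    res$classification$verdict
  })
  expect_true("forest" %in% verdicts)
})

test_that("the two regularity characterizations agree and match the example", {
  ctx <- sandwich_context(rank4_ctx_diagram)
  alld <- all_brauer_diagrams(6)
  reg_rank <- vapply(alld, is_regular, logical(1L), ctx = ctx, method = "rank")
  reg_sep <- vapply(alld, is_regular, logical(1L), ctx = ctx,
                    method = "separation")
  expect_identical(reg_rank, reg_sep)
  expect_identical(sum(reg_rank), 765L)
  # a diagram is non-regular here exactly when {3,4} lies inside its domain
  has34 <- vapply(alld, function(d) all(c(3L, 4L) %in% analyze(d)$dom),
                  logical(1L))
  expect_identical(!reg_rank, has34)
  # every rank-0 diagram is regular for this context
  rk <- vapply(alld, diagram_rank, integer(1L))
  expect_true(all(reg_rank[rk == 0L]))
})

test_that("the closed-form count matches brute force at every rank", {
  expect_identical(regular_count_formula(6, 4), 765)
  # printed summands of the rank-4 case
  expect_identical(regular_count_formula(6, 0), 45)
  ctx_by_rank <- list(
    `0` = sandwich_context(rank0_ctx_diagram),
    `2` = sandwich_context(partition_diagram(
      6, 4, list(c(1, 7), c(2, 3), c(4, 6), c(5, 10), c(8, 9)))),
    `4` = sandwich_context(rank4_ctx_diagram))
  for (k in c(0L, 2L, 4L)) {
    ctx <- ctx_by_rank[[as.character(k)]]
    expect_identical(ctx$rank, k)
    expect_identical(length(regular_elements(ctx)),
                     as.integer(regular_count_formula(6, k)))
  }
  expect_error(regular_count_formula(6, 3), "mod 2")
})

test_that("idempotent counts depend only on the context rank", {
  ctx0a <- sandwich_context(rank0_ctx_diagram)
  idm <- idempotents(ctx0a)
  expect_identical(length(idm), 45L)
  # idempotents are regular
  expect_true(all(vapply(idm, is_regular, logical(1L), ctx = ctx0a)))
  # a different rank-0 tree gives the same count
  ctx0b <- sandwich_context(partition_diagram(
    6, 4, list(c(1, 6), c(2, 3), c(4, 5), c(7, 8), c(9, 10))))
  expect_identical(ctx0b$rank, 0L)
  expect_identical(length(idempotents(ctx0b)), 45L)
})

test_that("balanced tree products and the involution behave algebraically", {
  t_self <- parse_newick(six_leaf_newick)
  expect_true(tree_involution(t_self) == t_self)
  set.seed(71)
  for (i in 1:50) {
    t <- random_phylo(sample(3:8, 1L))
    expect_true(tree_involution(tree_involution(t)) == t)
  }
  set.seed(72)
  for (i in 1:25) {
    t1 <- random_phylo(6); t2 <- random_phylo(6); t3 <- random_phylo(6)
    expect_true(tree_product_balanced(tree_product_balanced(t1, t2), t3) ==
                  tree_product_balanced(t1, tree_product_balanced(t2, t3)))
  }
  expect_error(tree_product_balanced("(1,2);", "(1,(2,3));"),
               class = "brauerphylo_dimension_error")
  expect_error(tree_involution("(1,2,3);"), class = "brauerphylo_not_a_tree")
})

test_that("double factorial uses the (-1)!! = 1 convention", {
  expect_identical(double_factorial(-1), 1)
  expect_identical(double_factorial(0), 1)
  expect_identical(double_factorial(9), 945)
  expect_error(double_factorial(-2), "undefined")
})
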