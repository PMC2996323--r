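test_that("pruning likelihood matches exhaustive enumeration", {
  m <- model_test()
  set.seed(7)
  for (tree in list(tree3(), tree4(), tree4_cat())) {
    for (i in 1:25) {
      col <- random_column(tree$tip.label)
      r <- runif(1, 0, 3)
      expect_equal(column_likelihood(col, tree, m, r),
                   brute_likelihood(col, tree, m, r),
                   tolerance = 1e-12)
    }
  }
})

test_that("likelihood at r = 0 is the stationary mass of invariant columns", {
  m <- model_test()
  tr <- tree3()
  col <- setNames(c("G", "G", "G"), c("A", "B", "C"))
  expect_equal(column_likelihood(col, tr, m, 0), unname(m$freq["G"]))
  col2 <- setNames(c("G", "G", "T"), c("A", "B", "C"))
  expect_equal(column_likelihood(col2, tr, m, 0), 0)
})

test_that("rescaling r multiplies branch lengths", {
  m <- model_test()
  tr <- tree4()
  col <- setNames(c("A", "C", "G", "T"), c("A", "B", "C", "D"))
  expect_equal(column_likelihood(col, tr, m, 2),
               column_likelihood(col, rescale_tree(tr, 2), m, 1),
               tolerance = 1e-14)
})

test_that("gapped species are projected out of the likelihood", {
  # marginalizing a missing leaf must equal the explicitly projected tree
  m <- model_test()
  tr <- tree4()
  col_gap <- setNames(c("A", "-", "G", "T"), c("A", "B", "C", "D"))
  col_sub <- col_gap[col_gap != "-"]
  for (r in c(0.3, 1, 2.5))
    expect_equal(column_likelihood(col_gap, tr, m, r),
                 brute_likelihood(col_sub, tr, m, r),
                 tolerance = 1e-12)
})

test_that("estimate_rate returns the unscored sentinel below 3 species", {
  m <- model_test()
  tr <- tree4()
  ps <- estimate_rate(setNames(c("A", "C", "-", "-"),
                               c("A", "B", "C", "D")), tr, m)
  expect_false(ps$scored)
  expect_equal(ps$neutral_rate, 0)
  expect_equal(ps$rs, 0)
})

test_that("boundary optima are returned exactly", {
  m <- model_test()
  tree <- default_tree(8, 4)
  # invariant column on a deep tree: no substitutions, r-hat = 0, RS = n
  inv <- setNames(rep("A", 8), tree$tip.label)
  ps <- estimate_rate(inv, tree, m)
  expect_equal(ps$rescaling, 0)
  expect_equal(ps$rs, ps$neutral_rate)
  expect_equal(ps$neutral_rate, 4)
  # maximally discordant column: optimizer hits the cap, RS = -2n
  dis <- setNames(rep(c("A", "C", "G", "T"), 2), tree$tip.label)
  ps2 <- estimate_rate(dis, tree, m)
  expect_equal(ps2$rescaling, 3)
  expect_equal(ps2$rs, -2 * ps2$neutral_rate)
})

test_that("scored positions respect the RS bounds and the r cap", {
  m <- default_model()
  tree <- default_tree()
  sim <- simulate_alignment(500, 1, tree = tree, model = m, gap_rate = 0.25,
                            seed = 3)
  trk <- score_alignment(sim$alignment, tree, m)
  s <- trk[trk$scored, ]
  expect_true(all(s$rescaling >= 0 & s$rescaling <= 3))
  expect_true(all(s$rs >= -2 * s$neutral_rate - 1e-9))
  expect_true(all(s$rs <= s$neutral_rate + 1e-9))
  # unscored sentinel rows are zeroed
  u <- trk[!trk$scored, ]
  expect_true(all(u$neutral_rate == 0 & u$rs == 0))
})

test_that("deepening agreement never increases the rate estimate", {
  m <- model_test()
  tree <- default_tree(8, 4)
  set.seed(11)
  for (i in 1:15) {
    col <- random_column(tree$tip.label, gap_rate = 0.4)
    if (sum(col != "-") < 3) next
    base <- names(which.max(table(col[col != "-"])))
    r0 <- estimate_rate(col, tree, m)$rescaling
    col2 <- col
    col2[col2 == "-"] <- base  # add agreeing species
    r1 <- estimate_rate(col2, tree, m)$rescaling
    expect_lte(r1, r0 + 1e-3)
  }
})

test_that("score_alignment is positionally independent and order-preserving", {
  m <- default_model()
  tree <- default_tree()
  sim <- simulate_alignment(200, 0.5, tree = tree, model = m,
                            gap_rate = 0.1, seed = 9)
  trk <- score_alignment(sim$alignment, tree, m)
  # permute input columns, score, un-permute: identical track
  set.seed(1)
  perm <- sample(200)
  aln2 <- sim$alignment
  aln2$states <- aln2$states[, perm]
  trk2 <- score_alignment(aln2, tree, m)
  expect_equal(trk2$rs[order(perm)], trk$rs)
  expect_equal(trk2$neutral_rate[order(perm)], trk$neutral_rate)
  # empty input
  empty <- ref_alignment(matrix(integer(), nrow = 1, ncol = 0,
                                dimnames = list("sp01", NULL)), "sp01")
  expect_equal(nrow(score_alignment(empty, tree, m)), 0L)
})

test_that("rate estimates recover the generating rescaling", {
  m <- default_model()
  tree <- default_tree()
  sim <- simulate_alignment(1000, 0.5, tree = tree, model = m, gap_rate = 0,
                            seed = 17)
  trk <- score_alignment(sim$alignment, tree, m)
  # per-column ML rate estimates are right-skewed, so the mean carries a
  # small positive bias; it must stay well under 0.1 at this depth
  expect_lt(abs(mean(trk$rescaling[trk$scored]) - 0.5), 0.1)
  expect_lt(abs(median(trk$rescaling[trk$scored]) - 0.5), 0.1)
})

test_that("species absent from the tree are rejected", {
  m <- model_test()
  expect_error(column_likelihood(setNames(c("A", "C", "G"),
                                          c("A", "B", "Z")),
                                 tree3(), m, 1), "absent from tree")
})

test_that("periodicity bias detects codon-patterned constraint", {
  expect_equal(periodicity_bias(rep(1.7, 30)), 0)
  expect_equal(periodicity_bias(rep(c(1, 1, 0), 10)), 1)
  # cyclic shift of whole periods does not change the metric
  expect_equal(periodicity_bias(rep(c(0, 1, 1), 10)), 1)
  expect_error(periodicity_bias(c(1, 2)), "at least 3")
  # unscored positions are excluded from the means
  x <- rep(c(1, 1, 0), 10)
  x[c(4, 8)] <- NA
  expect_equal(periodicity_bias(x), 1)
})
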