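test_that("histogram discretizes half-away-from-zero and applies the prior", {
  trk <- toy_track(c(0.37, 0.37, -0.14, 0.25), n = 2)
  h <- build_histogram(trk, gerp_params(prior_weight = 1))
  ks <- h$kmin:h$kmax
  expect_equal(range(ks), c(-1, 4))  # -0.14 -> -0.1, 0.37 -> 0.4
  expect_equal(sum(h$probs), 1, tolerance = 1e-9)
  expect_true(all(h$probs > 0))  # prior fills every bin in range
  # counts 2 at 0.4, 1 at -0.1, 1 at 0.2(0.25 -> 0.3? no: 0.25 -> 0.3)
  expect_equal(h$probs[ks == 4], (2 + 1) / (4 + 6), tolerance = 1e-12)
})

test_that("constant tracks yield a single certain bin", {
  h <- build_histogram(toy_track(rep(1.3, 50), n = 2), gerp_params())
  expect_equal(length(h$probs), 1L)
  expect_equal(h$probs, 1)
})

test_that("long shallow runs are excluded from the null histogram", {
  rs <- rep(1, 100)
  n <- rep(2, 100)
  n[40:51] <- 0.3   # 12 consecutive shallow positions
  rs[40:51] <- 5    # distinctive scores that must not appear
  trk <- gerpr:::scored_track(0:99, n, NA_real_, rs, TRUE)
  h <- build_histogram(trk, gerp_params())
  expect_lt(h$kmax * h$tol, 5)  # the shallow-run scores are absent
  # a shorter run stays (with penalty)
  n2 <- rep(2, 100)
  n2[40:44] <- 0.3
  trk2 <- gerpr:::scored_track(0:99, n2, NA_real_, rs, TRUE)
  h2 <- build_histogram(trk2, gerp_params())
  expect_gt(h2$kmax * h2$tol, 4)
  expect_error(build_histogram(trk, gerp_params(),
                               excluded = rep(TRUE, 100)), "unusable")
})

test_that("penalized shallow positions contribute rs minus the penalty", {
  n <- c(2, 2, 0.3, 2)
  rs <- c(1, 1, 1, 1)
  trk <- gerpr:::scored_track(0:3, n, NA_real_, rs, TRUE)
  h <- build_histogram(trk, gerp_params(prior_weight = 0))
  # penalty 0.5*(0.5-0.3) = 0.1 -> one score at 0.9
  ks <- h$kmin:h$kmax
  expect_equal(ks[h$probs > 0 & ks < 10], 9)
})

test_that("p-values match exhaustive enumeration and are monotone in S", {
  h <- score_histogram(c(0.5, 0, 0.5), kmin = -1, tol = 1)
  expect_equal(pvalue(2L, 2, h), 0.25)        # both draws must be +1
  expect_equal(pvalue(5L, 5 * (-1), h), 1.0)  # lower bound always met
  set.seed(3)
  for (rep in 1:3) {
    probs <- runif(5)
    kmin <- sample(-5:0, 1)
    hh <- score_histogram(probs, kmin, tol = 0.1)
    for (L in c(1L, 2L, 4L, 6L)) {
      qs <- seq((kmin - 1) * 0.1 * L, (kmin + 5) * 0.1 * L, length.out = 7)
      got <- pvalue(rep(L, 7), qs, hh)
      want <- vapply(qs, function(s) brute_pvalue(L, s, hh), 0)
      expect_equal(got, want, tolerance = 1e-12)
      expect_true(all(diff(got) <= 1e-12))  # non-increasing in S
      expect_true(all(got >= 0 & got <= 1))
    }
  }
})

test_that("candidate enumeration follows the maximal-run boundary rule", {
  trk <- toy_track(c(-1, 0.5, 0.8, -0.3, 0.7, -1), n = 2)
  p <- gerp_params(min_length = 1, max_length = 10, q = -Inf)
  cand <- enumerate_candidates(trk, p)
  got <- sprintf("[%d,%d)", cand$start, cand$end)
  expect_setequal(got, c("[1,3)", "[1,5)", "[4,5)"))
  expect_equal(cand$score[cand$start == 1 & cand$end == 5], 1.7)

  # all-negative track: no candidates
  expect_equal(nrow(enumerate_candidates(toy_track(rep(-1, 6), n = 2), p)),
               0L)
  # length filter
  p4 <- gerp_params(min_length = 4, max_length = 10, q = -Inf)
  cand4 <- enumerate_candidates(trk, p4)
  expect_equal(sprintf("[%d,%d)", cand4$start, cand4$end), "[1,5)")
})

test_that("unscored positions and long shallow runs break candidates", {
  rs <- rep(1, 30)
  scored <- rep(TRUE, 30)
  scored[15] <- FALSE
  trk <- toy_track(rs, n = 2, scored = scored)
  p <- gerp_params(min_length = 1, max_length = 30, q = -Inf)
  cand <- enumerate_candidates(trk, p)
  expect_true(all(cand$end <= 14 | cand$start >= 15))
  # shallow run of >= shallow_run positions acts the same way
  n <- rep(2, 30)
  n[10:20] <- 0.2
  trk2 <- gerpr:::scored_track(0:29, n, NA_real_, rs, TRUE)
  cand2 <- enumerate_candidates(trk2, p)
  expect_true(all(cand2$end <= 9 | cand2$start >= 20))
})

test_that("greedy selection respects significance order and overlap", {
  cand <- data.frame(start = c(0L, 5L, 20L), end = c(10L, 15L, 25L),
                     length = c(10L, 10L, 5L), score = c(5, 4, 3),
                     pvalue = c(1e-3, 1e-2, 5e-3))
  sel <- select_elements(cand, span = 30L)
  # overlapping 2nd candidate dropped; others ranked by p-value
  expect_equal(sel$start, c(0L, 20L))
  expect_equal(sel$rank, 1:2)

  # disjoint candidates are all accepted
  cand2 <- data.frame(start = c(0L, 12L), end = c(10L, 15L),
                      length = c(10L, 3L), score = c(5, 3),
                      pvalue = c(1e-3, 1e-2))
  expect_equal(nrow(select_elements(cand2, span = 20L)), 2L)

  # equal p-values: longer element first, nested shorter rejected
  cand3 <- data.frame(start = c(2L, 0L), end = c(8L, 10L),
                      length = c(6L, 10L), score = c(3, 5),
                      pvalue = c(1e-4, 1e-4))
  sel3 <- select_elements(cand3, span = 10L)
  expect_equal(sel3$length, 10L)
})

test_that("the fp stop rule caps the accepted prediction list", {
  cand <- data.frame(start = seq(0L, 90L, by = 10L))
  cand$end <- cand$start + 5L
  cand$length <- 5L
  cand$score <- 5
  cand$pvalue <- seq(1e-6, 1e-2, length.out = 10)
  # null track produced predictions at p >= 1e-3: expected false counts rise
  nullp <- list(c(1e-3, 2e-3, 5e-3), c(2e-3, 4e-3, 1e-2))
  sel <- select_elements(cand, null_pvalues = nullp, fp_cutoff = 0.05,
                         span = 100L)
  expect_lt(nrow(sel), 10L)
  k <- nrow(sel)
  expect_true(all(sel$expected_false <= 0.05 * seq_len(k)))
})

test_that("track permutation preserves the multiset and frozen stretches", {
  n <- rep(c(2, 0.3, 2), c(40, 15, 45))
  set.seed(8)
  rs <- rnorm(100)
  trk <- gerpr:::scored_track(0:99, n, NA_real_, rs, TRUE)
  p <- gerp_params()
  pt <- permute_track(trk, p, seed = 123)
  expect_equal(sort(pt$rs), sort(trk$rs))
  expect_equal(pt$rs[41:55], trk$rs[41:55])  # frozen shallow stretch
  expect_false(all(pt$rs == trk$rs))
  expect_equal(permute_track(trk, p, seed = 123), pt)  # determinism
  expect_false(all(permute_track(trk, p, seed = 124)$rs == pt$rs))
})

test_that("expected false counts average the shuffles", {
  ef <- gerpr:::expected_false_at(c(1e-4, 3e-3, 1e-2),
                                  list(c(1e-3, 5e-3), c(2e-3)))
  expect_equal(ef, c(0, mean(c(1, 1)), mean(c(2, 1))))
})

test_that("p-values are invariant to uniform additive score shifts", {
  sim <- simulate_alignment(3000, 1, gap_rate = 0.1, seed = 41)
  trk <- score_alignment(sim$alignment, default_tree(), default_model())
  p <- gerp_params()
  h1 <- build_histogram(trk, p)
  cand <- enumerate_candidates(trk, p, h1)
  expect_gt(nrow(cand), 10)
  shift <- 0.7  # a multiple of the discretization tolerance
  trk2 <- trk
  trk2$rs <- trk$rs + shift
  h2 <- build_histogram(trk2, p)
  pv2 <- pvalue(cand$length, cand$score + shift * cand$length, h2)
  expect_equal(pv2, cand$pvalue, tolerance = 1e-9)
})

test_that("a planted element is recovered while shuffles stay null", {
  prof <- constraint_profile(4000, 1,
                             data.frame(start = 1500, length = 120, r = 0.1))
  sim <- simulate_alignment(4000, prof$r, gap_rate = 0.1, seed = 19)
  trk <- score_alignment(sim$alignment, default_tree(), default_model())
  res <- find_elements(trk, gerp_params(), seed = 7)
  expect_gte(nrow(res$elements), 1L)
  top <- res$elements[1, ]
  ov <- min(top$end, 1620) - max(top$start, 1500)
  expect_gt(ov / (120 + top$length - ov), 0.7)  # Jaccard with the truth
  # selected elements are pairwise disjoint
  el <- res$elements[order(res$elements$start), ]
  if (nrow(el) > 1)
    expect_true(all(el$start[-1] >= el$end[-nrow(el)]))
  # determinism
  res2 <- find_elements(trk, gerp_params(), seed = 7)
  expect_identical(res$elements, res2$elements)
})

test_that("candidate pruning keeps everything that could be accepted", {
  prof <- constraint_profile(3000, 1,
                             data.frame(start = 1000, length = 100, r = 0.2))
  sim <- simulate_alignment(3000, prof$r, gap_rate = 0.1, seed = 23)
  trk <- score_alignment(sim$alignment, default_tree(), default_model())
  p <- gerp_params()
  h <- build_histogram(trk, p)
  cand_all <- enumerate_candidates(trk, gerp_params(q = -Inf), h)
  cand_def <- enumerate_candidates(trk, p, h)
  res <- find_elements(trk, p, seed = 3)
  if (nrow(res$elements)) {
    pmax_acc <- max(res$elements$pvalue)
    below_all <- cand_all[cand_all$pvalue <= pmax_acc, c("start", "end")]
    below_def <- cand_def[cand_def$pvalue <= pmax_acc, c("start", "end")]
    expect_equal(below_def, below_all, ignore_attr = TRUE)
  }
})

test_that("detection curves are monotone and flat on noise", {
  sim <- simulate_alignment(5000, 1, gap_rate = 0.1, seed = 29)
  trk <- score_alignment(sim$alignment, default_tree(), default_model())
  cv <- detection_curve(trk, cutoffs = c(0, 0.1, 0.25, 0.5),
                        params = gerp_params(n_shuffles = 3), seed = 2)
  expect_true(all(diff(cv$B) >= 0))
  expect_true(all(diff(cv$F) >= 0))
  # pure noise: adjusted detectable constraint is near zero
  expect_lt(max(abs(cv$Bstar)), 0.02 * nrow(trk))
})
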