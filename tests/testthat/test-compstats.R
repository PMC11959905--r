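test_that("Bayesian zero replacement preserves totals and stays below detection", {
  x <- matrix(c(0, 10, 5, 3), 2, 2, dimnames = list(c("a", "b"), c("f", "g")))
  r <- replace_zeros_bayesian(x)
  expect_equal(rowSums(r), rowSums(x))
  expect_true(all(r > 0))
  # identity when no zeros
  expect_equal(replace_zeros_bayesian(x[2, , drop = FALSE]),
               x[2, , drop = FALSE])
  expect_error(replace_zeros_bayesian(rbind(x, c(0, 0))), "all-zero")
  # property: replaced value < smallest observed nonzero in the same sample
  set.seed(21)
  for (i in 1:20) {
    m <- matrix(rpois(50, 3), 5, 10)
    m <- m[rowSums(m) > 0, , drop = FALSE]
    rr <- replace_zeros_bayesian(m)
    for (j in seq_len(nrow(m))) {
      z <- m[j, ] == 0
      if (any(z) && any(!z))
        expect_lt(max(rr[j, z]), min(rr[j, !z]))
    }
  }
})

test_that("pseudocount replacement only touches zeros", {
  expect_equal(replace_zeros_pseudocount(c(0, 0.3)), c(1e-6, 0.3))
  x <- c(0.2, 0.8)
  expect_identical(replace_zeros_pseudocount(x), x)
  expect_true(all(replace_zeros_pseudocount(c(0, 0, 1)) > 0))
  expect_error(replace_zeros_pseudocount(c(-1, 2)), "non-negative")
})

test_that("CLR transform matches closed forms and is scale invariant", {
  expect_equal(as.numeric(clr_transform(rbind(rep(1, 4)))), rep(0, 4))
  expect_equal(as.numeric(clr_transform(rbind(exp(0:3)))),
               c(-1.5, -0.5, 0.5, 1.5))
  set.seed(3)
  x <- matrix(rexp(20) + 0.1, 4, 5)
  expect_equal(clr_transform(x), clr_transform(7 * x))
  expect_equal(unname(rowSums(clr_transform(x))), rep(0, 4),
               tolerance = 1e-12)
  # error names the offending cell
  bad <- matrix(c(1, 0, 2, 3), 2, 2,
                dimnames = list(c("s1", "s2"), c("fa", "fb")))
  expect_error(clr_transform(bad), "s2.*fa")
})

test_that("Shannon and richness behave on closed-form cases", {
  expect_equal(unname(shannon(rep(0.25, 4))), log(4))
  expect_equal(unname(shannon(c(0, 5, 0))), 0)
  expect_equal(unname(shannon(c(0.5, 0.25, 0.25))),
               -sum(c(0.5, 0.25, 0.25) * log(c(0.5, 0.25, 0.25))))
  expect_equal(richness(c(1, 0, 2)), 2L)
  expect_equal(richness(c(0, 0, 0)), 0L)
  expect_equal(richness(runif(7) + 0.1), 7L)
  # Shannon <= ln(richness), equality iff uniform
  set.seed(8)
  p <- matrix(rexp(40), 4, 10)
  expect_true(all(shannon(p) <= log(richness(p)) + 1e-12))
})

test_that("pairwise Wilcoxon matches exact rank-sum enumeration", {
  vals <- setNames(c(1:5, 11:15), sprintf("s%02d", 1:10))
  res <- pairwise_wilcoxon_bh(vals, two_group_design())
  # fully separated n=5 vs 5: two-sided exact p = 2 / choose(10, 5)
  expect_equal(res$p, 2 / choose(10, 5), tolerance = 1e-12)
  expect_true(all(res$q >= res$p))
  # identical groups: p well above any rejection level
  same <- setNames(rep(c(3, 7, 1, 9, 5), 2), names(vals))
  expect_gt(pairwise_wilcoxon_bh(same, two_group_design())$p, 0.5)
})

test_that("pairwise KS statistic matches the ECDF construction", {
  vals <- setNames(c(1, 2, 3, 4.5, 2.5, 4, 5, 6, 7, 8.5),
                   sprintf("s%02d", 1:10))
  design <- two_group_design()
  res <- pairwise_ks_bh(vals, design)
  # disjoint supports -> D = 1
  disj <- setNames(c(1:5, 11:15), names(vals))
  expect_equal(pairwise_ks_bh(disj, design)$D, 1)
  # {1,2,3} vs {4,5,6}: ECDFs never overlap -> D = 1
  d6 <- population_design(paste0("t", 1:6), rep(c("x", "y"), each = 3))
  v6 <- setNames(c(1, 2, 3, 4, 5, 6), d6$sample)
  expect_equal(pairwise_ks_bh(v6, d6)$D, 1)
  # identical samples -> D = 0
  vid <- setNames(rep(c(1, 2, 3, 4, 5), 2), names(vals))
  expect_equal(pairwise_ks_bh(vid, design)$D, 0)
  expect_true(all(res$q >= res$p))
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(5)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q <= 1) && all(q >= p))
  # monotone in sorted order
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("core membership follows the prevalence rule", {
  m <- rbind(s1 = c(a = 1, b = 1, c = 0),
             s2 = c(a = 2, b = 0, c = 0),
             s3 = c(a = 3, b = 1, c = 1),
             s4 = c(a = 1, b = 1, c = 1))
  design <- population_design(paste0("s", 1:4), rep(c("P1", "P2"), each = 2))
  full <- core_membership(m, design, prevalence = 1)
  expect_equal(full$core, "a")                   # present in every sample
  expect_false("b" %in% full$per_population$P1)  # absent from s2
  half <- core_membership(m, design, prevalence = 0.5)
  expect_true("b" %in% half$per_population$P1)   # 1 of 2 samples = 0.5 >= 0.5
  expect_setequal(half$core, c("a", "b"))        # c absent from all of P1
  # prevalence 0.5 with a feature in 3 of 5 samples -> core (0.6 >= 0.5)
  m5 <- matrix(c(1, 1, 1, 0, 0), 5, 1,
               dimnames = list(paste0("t", 1:5), "f"))
  d5 <- population_design(paste0("t", 1:5), rep("P", 5))
  expect_equal(core_membership(m5, d5, prevalence = 0.5)$core, "f")
  # detection threshold excludes low abundances
  thr <- core_membership(m, design, prevalence = 1, min_abundance = 2.5)
  expect_equal(thr$core, character(0))
})
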