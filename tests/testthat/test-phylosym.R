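test_that("patristic distances are path sums of branch lengths", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  d <- patristic_distances(tree)
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  expect_equal(d["B", "C"], 4)
  expect_equal(diag(d), setNames(rep(0, 3), c("A", "B", "C")))
  expect_equal(d, t(d))
  # relabelling tips permutes the matrix consistently
  tree2 <- tree
  tree2$tip.label <- c("B", "A", "C")[match(tree$tip.label, c("A", "B", "C"))]
  d2 <- patristic_distances(tree2)
  expect_equal(d2[c("A", "B", "C"), c("A", "B", "C")][upper.tri(d)],
               d[c("B", "A", "C"), c("B", "A", "C")][upper.tri(d)])
})

test_that("PERMANOVA R2 equals the classical ANOVA ratio on Euclidean data", {
  # perfect separation: within 0, between 1
  d <- matrix(1, 4, 4) - diag(4)
  d[1, 2] <- d[2, 1] <- d[3, 4] <- d[4, 3] <- 0
  pm <- permanova(d, c("a", "a", "b", "b"))
  expect_equal(pm$R2, 1)
  # 1-D points {0,0,1,1}
  x <- c(0, 0, 1, 1)
  pm2 <- permanova(as.matrix(dist(x)), c("a", "a", "b", "b"))
  expect_equal(pm2$R2, anova_r2(cbind(x), c("a", "a", "b", "b")))
  # random multivariate point sets, 2 and 3 groups
  set.seed(41)
  for (k in 2:3) {
    pts <- matrix(rnorm(8 * 3), 8, 3)
    g <- rep(paste0("g", 1:k), length.out = 8)
    pm3 <- permanova(as.matrix(dist(pts)), g, n_permutations = 9)
    expect_equal(pm3$R2, anova_r2(pts, g), tolerance = 1e-10)
  }
})

test_that("PERMANOVA agrees with vegan::adonis2 as an independent cross-check", {
  set.seed(52)
  pts <- matrix(rnorm(12 * 2), 12, 2)
  g <- rep(c("a", "b", "c"), each = 4)
  pm <- permanova(as.matrix(dist(pts)), g, n_permutations = 99, seed = 1,
                  exact_limit = 1)
  ad <- vegan::adonis2(dist(pts) ~ g, permutations = 999)
  expect_equal(pm$R2, ad$R2[1], tolerance = 1e-10)
  expect_equal(pm$pseudo_F, ad$F[1], tolerance = 1e-10)
})

test_that("exact permutation p matches a brute-force enumeration", {
  set.seed(23)
  pts <- rnorm(6)
  g <- rep(c("a", "b"), each = 3)
  d <- as.matrix(dist(pts))
  pm <- permanova(d, g)               # 20 arrangements -> exact path
  expect_true(pm$exact)
  f_all <- brute_force_f(d, g)
  f_obs <- pm$pseudo_F
  expect_equal(pm$p_value, mean(f_all >= f_obs - 1e-12))
  # Monte-Carlo shuffles approach the exact value
  pm_mc <- permanova(d, g, n_permutations = 4999, seed = 3, exact_limit = 1)
  expect_false(pm_mc$exact)
  expect_lt(abs(pm_mc$p_value - pm$p_value), 0.05)
  expect_gte(pm_mc$p_value, 1 / 5000)
})

test_that("PERMANOVA is exchangeable over tip order and E[R2] = (k-1)/(n-1)", {
  set.seed(77)
  pts <- matrix(rnorm(8 * 2), 8, 2)
  g <- rep(c("a", "b"), each = 4)
  d <- as.matrix(dist(pts))
  pm <- permanova(d, g, seed = 1)
  ord <- sample(8)
  pm_perm <- permanova(d[ord, ord], g[ord], seed = 1)
  expect_equal(pm$R2, pm_perm$R2, tolerance = 1e-12)
  expect_equal(pm$pseudo_F, pm_perm$pseudo_F, tolerance = 1e-12)
  # expectation of R2 over all label arrangements, computed by enumeration
  sets <- utils::combn(8, 4, simplify = FALSE)
  r2_all <- vapply(sets, function(s) {
    gg <- rep("b", 8); gg[s] <- "a"
    permanova(d, gg, n_permutations = 1)$R2
  }, numeric(1))
  expect_equal(mean(r2_all), (2 - 1) / (8 - 1), tolerance = 1e-10)
})

test_that("gene screen accounts for every tree and collapses multi-copy tips", {
  cfg <- synth_config(n_populations = 2, samples_per_population = 4,
                      seed = 3)
  ts <- generate_population_trees(cfg, planted_signal(tree_signal_strength = 1),
                                  n_trees = 4)
  out <- gene_screen(ts, seed = 1)
  expect_equal(nrow(out) + length(attr(out, "skipped")), 4)
  expect_true(all(out$pass == (out$R2 > 0.5)))
  expect_true(all(out$q >= out$p))
  expect_equal(attr(out, "mean_R2"), mean(out$R2))
  # a tree with a single population is skipped with a reason
  one_pop <- ape::rcoal(4)
  one_pop$tip.label <- paste0("x", 1:4)
  ts2 <- labeled_tree_set(list(bad = one_pop, good = ts$trees[[1]]),
                          tip_map = c(setNames(paste0("x", 1:4),
                                               paste0("x", 1:4)),
                                      ts$tip_map),
                          design = rbind(ts$design,
                                         population_design(paste0("x", 1:4),
                                                           rep("only", 4))))
  out2 <- gene_screen(ts2, seed = 1)
  expect_equal(nrow(out2), 1)
  expect_match(attr(out2, "skipped")[["bad"]], "2 populations")
  # duplicated sample tips: collapsed by default, kept with keep_all
  dup <- ts$trees[[1]]
  dup$tip.label[2] <- dup$tip.label[1]
  ts3 <- labeled_tree_set(list(t = dup), tip_map = ts$tip_map,
                          design = ts$design)
  o_closest <- gene_screen(ts3, seed = 1)
  o_all <- gene_screen(ts3, seed = 1, multi_copy = "keep_all")
  expect_equal(o_closest$n_tips, 7)
  expect_equal(o_all$n_tips, 8)
})
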