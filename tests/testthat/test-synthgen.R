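test_that("generators are bit-identical under a fixed seed", {
  cfg <- synth_config(n_features = 50, samples_per_population = 5, seed = 8)
  a <- generate_count_table(cfg)
  b <- generate_count_table(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$counts$coverage_observed, b$counts$coverage_observed)
  expect_identical(a$truth, b$truth)
  expect_identical(generate_cazyme_table(cfg)$genes,
                   generate_cazyme_table(cfg)$genes)
  t1 <- generate_population_trees(cfg, n_trees = 2)
  t2 <- generate_population_trees(cfg, n_trees = 2)
  expect_identical(lapply(t1$trees, ape::write.tree),
                   lapply(t2$trees, ape::write.tree))
  # different seed changes the counts
  expect_false(identical(
    a$counts$counts,
    generate_count_table(synth_config(n_features = 50,
                                      samples_per_population = 5,
                                      seed = 9))$counts$counts))
})

test_that("config and signal validation rejects invalid inputs", {
  expect_error(synth_config(n_populations = 1))
  expect_error(synth_config(concentration = 0))
  expect_error(planted_signal(tree_signal_strength = 1.5))
  expect_error(planted_signal(substrate_shifts = data.frame(
    substrate = "x", host_group = "Homo", enrichment = 0)))
  cfg <- synth_config(n_features = 2)
  sig <- planted_signal(differential_features = data.frame(
    feature = 1:3, population = 1, lfc = 1))
  expect_error(generate_count_table(cfg, sig), "more planted")
})

test_that("null configuration gives equal per-feature means across populations", {
  cfg <- synth_config(n_features = 40, samples_per_population = 30, seed = 12)
  sim <- generate_count_table(cfg)
  props <- sweep(sim$counts$counts, 1, rowSums(sim$counts$counts), "/")
  m1 <- colMeans(props[sim$design$population == "Pop1", ])
  m2 <- colMeans(props[sim$design$population == "Pop2", ])
  # no feature differs beyond Monte-Carlo error (SE scale ~ sd/sqrt(30))
  pooled_se <- sqrt(apply(props, 2, var) * 2 / 30)
  expect_true(all(abs(m1 - m2) < 5 * pooled_se + 1e-6))
  # truth sidecar records identical proportions and zero LFC everywhere
  expect_true(all(sim$truth$lfc == 0))
})

test_that("a planted fold-change raises the target population's mean count", {
  hits <- vapply(1:100, function(s) {
    cfg <- synth_config(n_features = 50, seed = s)
    sig <- planted_signal(differential_features = data.frame(
      feature = 10, population = 1, lfc = 3))
    sim <- generate_count_table(cfg, sig)
    in_a <- sim$design$population == "Pop1"
    mean(sim$counts$counts[in_a, "F0010"]) >
      mean(sim$counts$counts[!in_a, "F0010"])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("cazyme generator conserves totals and encodes planted shifts", {
  cfg <- synth_config(samples_per_population = 6, seed = 5)
  caz <- generate_cazyme_table(cfg)
  expect_equal(sum(caz$genes$count), cfg$genes_per_sample * 12)
  expect_true(all(c("family", "ec", "substrate", "source", "population",
                    "count") %in% names(caz$genes)))
  # no shifts: per-substrate fractions close between host groups
  fr <- sample_substrate_fractions(assign_substrates(caz$genes))
  g <- caz$design$host_group[match(rownames(fr), caz$design$sample)]
  gap <- abs(colMeans(fr[g == "Homo", ]) - colMeans(fr[g == "Pan", ]))
  expect_lt(max(gap), 0.02)
  # planted shift recovered across seeds
  hits <- vapply(1:20, function(s) {
    sig <- planted_signal(substrate_shifts = data.frame(
      substrate = "pectin", host_group = "Pan", enrichment = 4))
    cz <- generate_cazyme_table(synth_config(seed = s), sig)
    f <- sample_substrate_fractions(assign_substrates(cz$genes))
    hg <- cz$design$host_group[match(rownames(f), cz$design$sample)]
    mean(f[hg == "Pan", "pectin"]) > mean(f[hg == "Homo", "pectin"])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("tree generator produces the right tips and round-trips newick", {
  cfg <- synth_config(n_populations = 3, samples_per_population = 4, seed = 2)
  ts <- generate_population_trees(cfg, n_trees = 3)
  for (tr in ts$trees) {
    expect_equal(length(tr$tip.label), 12)
    expect_setequal(tr$tip.label, ts$design$sample)
    reparsed <- ape::read.tree(text = ape::write.tree(tr))
    expect_setequal(reparsed$tip.label, tr$tip.label)
  }
  # strength 1: every population is monophyletic
  ts1 <- generate_population_trees(cfg,
                                   planted_signal(tree_signal_strength = 1),
                                   n_trees = 2)
  for (tr in ts1$trees) {
    for (p in unique(ts1$design$population)) {
      tips <- ts1$design$sample[ts1$design$population == p]
      expect_true(ape::is.monophyletic(tr, tips))
    }
  }
})
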