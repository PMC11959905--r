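test_that("substrate assignment joins exactly, falls back, and audits unmapped", {
  map <- data.frame(family = c("GH43", "GH13", "GH13"),
                    ec = c("3.2.1.55", "3.2.1.1", ""),
                    substrate = c("arabinan", "starch", "starch"),
                    source = c("Plant-glycans", "Plant-glycans",
                               "Plant-glycans"))
  genes <- data.frame(family = c("GH43", "GH13", "GH99"),
                      ec = c("3.2.1.55", "9.9.9.9", "1.1.1.1"),
                      sample = "s1", count = c(3L, 2L, 5L))
  ann <- assign_substrates(genes, map)
  expect_equal(ann$substrate, c("arabinan", "starch", NA))
  expect_equal(attr(ann, "unmapped"), 5)
  # unmapped genes still inflate the total-CAZyme denominator
  ann$population <- "P1"
  ra <- population_relative_abundance(ann)
  expect_equal(sum(ra$fraction), 5 / 10)  # mapped 5 of 10 genes
})

test_that("population relative abundances normalize and are scale invariant", {
  caz <- generate_cazyme_table(synth_config(seed = 4))
  ann <- assign_substrates(caz$genes)
  ra <- population_relative_abundance(ann)
  tot <- tapply(ra$fraction, ra$group, sum)
  expect_true(all(abs(tot - 1) < 1e-12))  # default map covers every gene
  ann2 <- ann; ann2$count <- ann2$count * 2L
  ra2 <- population_relative_abundance(ann2)
  expect_equal(ra$fraction, ra2$fraction)
  # single-substrate table -> fraction 1
  solo <- data.frame(family = "GH28", ec = "3.2.1.15", population = "P1",
                     sample = "s1", count = 9L)
  expect_equal(population_relative_abundance(assign_substrates(solo))$fraction,
               1)
  # per-sample fractions sum to 1 when all genes are mapped
  fr <- sample_substrate_fractions(ann)
  expect_equal(unname(rowSums(fr)), rep(1, nrow(fr)), tolerance = 1e-12)
})

test_that("bootstrap CI honours replicates, degenerates safely and mirrors", {
  design <- two_group_design(4)
  const <- matrix(rep(c(0.2, 0.3, 0.5), each = 8), 8, 3,
                  dimnames = list(design$sample, c("a", "b", "c")))
  b <- bootstrap_group_difference(const, design, n_boot = 100, seed = 1)
  expect_equal(b$estimate, rep(0, 3))
  expect_equal(b$ci_lower, rep(0, 3))
  expect_equal(b$ci_upper, rep(0, 3))
  expect_false(any(b$significant))
  expect_equal(b$n_replicates, rep(100L, 3))
  expect_true(all(b$ci_lower <= b$estimate & b$estimate <= b$ci_upper))
  # label swap negates the estimate and mirrors the CI
  set.seed(9)
  x <- matrix(runif(24, 0.01, 1), 8, 3,
              dimnames = dimnames(const))
  x <- x / rowSums(x)
  b1 <- bootstrap_group_difference(x, design, groups = c("Homo", "Pan"),
                                   n_boot = 500, seed = 3)
  b2 <- bootstrap_group_difference(x, design, groups = c("Pan", "Homo"),
                                   n_boot = 500, seed = 3)
  expect_equal(b1$estimate, -b2$estimate)
  expect_equal(b1$ci_lower, -b2$ci_upper, tolerance = 1e-12)
  expect_equal(b1$ci_upper, -b2$ci_lower, tolerance = 1e-12)
  # reproducible under a fixed seed
  b3 <- bootstrap_group_difference(x, design, groups = c("Homo", "Pan"),
                                   n_boot = 500, seed = 3)
  expect_identical(b1, b3)
  expect_error(bootstrap_group_difference(x[c(1, 5:8), ],
                                          design[c(1, 5:8), ],
                                          n_boot = 10), "at least 2")
})

test_that("bootstrap CI width shrinks like 1/sqrt(n)", {
  width_at <- function(n_per) {
    set.seed(123)                      # same generating distribution
    design <- two_group_design(n_per)
    x <- matrix(rgamma(2 * n_per * 5, 5), 2 * n_per, 5,
                dimnames = list(design$sample, paste0("sub", 1:5)))
    x <- x / rowSums(x)
    b <- bootstrap_group_difference(x, design, n_boot = 2000, seed = 7)
    mean(b$ci_upper - b$ci_lower)
  }
  w <- vapply(c(5, 20, 80), width_at, numeric(1))
  expect_equal(w[1] / w[2], 2, tolerance = 0.5)
  expect_equal(w[2] / w[3], 2, tolerance = 0.5)
  expect_true(all(diff(w) < 0))
})

test_that("planted substrate shifts are detected by the bootstrap CI", {
  sig <- planted_signal(substrate_shifts = data.frame(
    substrate = "pectin", host_group = "Pan", enrichment = 4))
  caz <- generate_cazyme_table(synth_config(seed = 15), sig)
  fr <- sample_substrate_fractions(assign_substrates(caz$genes))
  b <- bootstrap_group_difference(fr, caz$design, n_boot = 2000, seed = 2)
  row <- b[b$substrate == "pectin", ]
  expect_true(row$significant)
  expect_gt(row$estimate, 0)           # enriched in Pan = group 2
  # shifting a substrate absent from the map errors
  bad <- planted_signal(substrate_shifts = data.frame(
    substrate = "no-such-glycan", host_group = "Pan", enrichment = 2))
  expect_error(generate_cazyme_table(synth_config(seed = 1), bad),
               "absent from map")
})
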