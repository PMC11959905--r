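# Small fixtures shared across the suite; everything is built in code.

tiny_counts <- function() {
  m <- matrix(c(10L, 0L, 5L,
                2L,  8L, 0L,
                4L,  4L, 4L), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:3), paste0("f", 1:3)))
  count_matrix(m, lengths_kb = c(f1 = 1, f2 = 2, f3 = 4))
}

two_group_design <- function(n_per = 5, groups = c("Homo", "Pan")) {
  population_design(sprintf("s%02d", seq_len(2 * n_per)),
                    rep(groups, each = n_per))
}

# Classical ANOVA variance-explained for points in Euclidean space: the
# independent oracle for PERMANOVA R^2.
anova_r2 <- function(x, groups) {
  x <- as.matrix(x)
  grand <- colMeans(x)
  ss_tot <- sum(sweep(x, 2, grand)^2)
  ss_btw <- 0
  for (g in unique(groups)) {
    xg <- x[groups == g, , drop = FALSE]
    ss_btw <- ss_btw + nrow(xg) * sum((colMeans(xg) - grand)^2)
  }
  ss_btw / ss_tot
}

# Brute-force PERMANOVA permutation distribution for two equal groups:
# enumerate all assignments of group-1 membership.
brute_force_f <- function(d, groups) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  lev <- unique(groups)
  k <- length(lev)
  ss_tot <- sum(d2[upper.tri(d2)]) / n
  fstat <- function(g) {
    ss_w <- 0
    for (l in unique(g)) {
      idx <- which(g == l)
      ss_w <- ss_w + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
    }
    ((ss_tot - ss_w) / (k - 1)) / (ss_w / (n - k))
  }
  n1 <- sum(groups == lev[1])
  sets <- utils::combn(n, n1, simplify = FALSE)
  vapply(sets, function(s) {
    g <- rep(lev[2], n); g[s] <- lev[1]; fstat(g)
  }, numeric(1))
}
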