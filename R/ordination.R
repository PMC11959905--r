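#' Feature reduction ahead of CLR-PCA
#'
#' A PCA biplot of CLR-transformed counts only carries signal when the number
#' of features is at most the number of samples and low-variance,
#' low-abundance features (whose CLR coordinates are dominated by Poisson
#' noise) do not smear the projection. Features below the median on *both*
#' CLR variance and mean CLR abundance are dropped first; if the table is
#' still over budget, features are trimmed by decreasing variance down to
#' `min(max_features, n_samples)`.
#'
#' @param clr CLR matrix (samples x features).
#' @param max_features cap on retained features; default 100.
#' @return the CLR matrix restricted to the retained feature columns (input
#'   column order preserved).
#' @export
filter_features <- function(clr, max_features = 100L) {
  clr <- as.matrix(clr)
  budget <- min(max_features, nrow(clr))
  if (ncol(clr) <= budget) return(clr)
  v <- apply(clr, 2, stats::var)
  m <- colMeans(clr)
  weak <- v <= stats::median(v) & m <= stats::median(m)
  keep <- if (sum(!weak) >= 2) !weak else rep(TRUE, ncol(clr))
  if (sum(keep) > budget) {
    ord <- order(v, decreasing = TRUE)
    ord <- ord[keep[ord]]
    sel <- logical(ncol(clr))
    sel[ord[seq_len(budget)]] <- TRUE
    keep <- sel
  }
  clr[, keep, drop = FALSE]
}

#' Principal component analysis by singular value decomposition
#'
#' Column-centres (and by default unit-scales) the CLR matrix and decomposes
#' it by SVD. Scores are the projections of the samples, loadings the feature
#' eigenvectors, and component k explains sigma_k^2 / sum(sigma^2) of the
#' variance. Zero-variance features are dropped before scaling. The sign of
#' each component is fixed so its largest-magnitude loading is positive.
#'
#' @param clr CLR matrix (samples x features), >= 3 samples and >= 2 features.
#' @param scale_unit scale columns to unit variance; default TRUE.
#' @return object of class `clr_pca`: list with `scores` (samples x
#'   components), `loadings` (features x components), `explained_variance`,
#'   and `dropped_features`.
#' @export
pca_svd <- function(clr, scale_unit = TRUE) {
  clr <- as.matrix(clr)
  if (nrow(clr) < 3 || ncol(clr) < 2)
    stop("need at least 3 samples and 2 features")
  v <- apply(clr, 2, stats::var)
  dropped <- colnames(clr)[v == 0]
  if (scale_unit && length(dropped) > 0)
    clr <- clr[, v > 0, drop = FALSE]
  x <- scale(clr, center = TRUE, scale = scale_unit)
  sv <- svd(x)
  if (max(sv$d) == 0) stop("matrix has rank 0 after centering")
  keep <- seq_len(min(nrow(x) - 1, ncol(x)))
  d <- sv$d[keep]
  scores <- sv$u[, keep, drop = FALSE] %*% diag(d, length(keep))
  loadings <- sv$v[, keep, drop = FALSE]
  flip <- apply(loadings, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  scores <- sweep(scores, 2, flip, "*")
  loadings <- sweep(loadings, 2, flip, "*")
  pc <- paste0("PC", keep)
  dimnames(scores) <- list(rownames(clr), pc)
  dimnames(loadings) <- list(colnames(clr), pc)
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = stats::setNames(d^2 / sum(d^2), pc),
                 dropped_features = dropped),
            class = "clr_pca")
}

#' @export
print.clr_pca <- function(x, ...) {
  ev <- x$explained_variance
  cat("clr_pca:", nrow(x$scores), "samples,", nrow(x$loadings), "features,",
      length(ev), "components\n")
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%%\n", 100 * ev[1], 100 * ev[2]))
  invisible(x)
}

#' Per-population density contours on an ordination plane
#'
#' Estimates a Gaussian-kernel density for each population's samples on a
#' shared 2-D grid over the first two score columns, and masks grid cells
#' whose density falls below `truncation` times that population's peak.
#' Samples located in masked cells are returned as outliers (these are the
#' points drawn individually outside the contours in an ordination figure).
#'
#' @param scores matrix with at least 2 columns of per-sample coordinates.
#' @param design a [population_design()] covering the rows of `scores`.
#' @param truncation mask level as a fraction of the per-population peak
#'   density, in \[0, 1\]; default 0.10.
#' @param gridsize number of grid points per axis; default 64.
#' @param bandwidth optional length-2 kernel bandwidth passed to
#'   [MASS::kde2d()]; default: Scott-type rule per population.
#' @return list with `grid` (`x`, `y` axes), `populations` (per population:
#'   `density` matrix, logical `mask` of retained cells, `peak`), and
#'   `outliers` (data.frame of sample, population).
#' @export
density_contours <- function(scores, design, truncation = 0.10,
                             gridsize = 64L, bandwidth = NULL) {
  if (truncation < 0 || truncation > 1) stop("truncation must lie in [0, 1]")
  xy <- as.matrix(scores[, 1:2])
  groups <- design_groups(design, rownames(xy))
  pad <- 0.05 * c(diff(range(xy[, 1])), diff(range(xy[, 2])))
  lims <- c(range(xy[, 1]) + c(-1, 1) * pad[1],
            range(xy[, 2]) + c(-1, 1) * pad[2])
  gx <- seq(lims[1], lims[2], length.out = gridsize)
  gy <- seq(lims[3], lims[4], length.out = gridsize)
  pops <- sort(unique(groups))
  outliers <- list()
  dens <- lapply(pops, function(g) {
    pts <- xy[groups == g, , drop = FALSE]
    h <- bandwidth %||% pmax(c(MASS::bandwidth.nrd(pts[, 1]),
                               MASS::bandwidth.nrd(pts[, 2])), 1e-8)
    kd <- MASS::kde2d(pts[, 1], pts[, 2], h = h, n = gridsize, lims = lims)
    peak <- max(kd$z)
    keep <- kd$z >= truncation * peak
    ix <- findInterval(pts[, 1], gx, all.inside = TRUE)
    iy <- findInterval(pts[, 2], gy, all.inside = TRUE)
    out <- !keep[cbind(ix, iy)]
    outliers[[g]] <<- rownames(pts)[out]
    list(density = kd$z, mask = keep, peak = peak)
  })
  names(dens) <- pops
  out_df <- data.frame(
    sample = unlist(outliers, use.names = FALSE),
    population = rep(pops, lengths(outliers[pops])),
    stringsAsFactors = FALSE)
  list(grid = list(x = gx, y = gy), populations = dens, outliers = out_df)
}
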