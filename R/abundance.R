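#' Rarefy a count matrix to even depth
#'
#' Subsamples each sample's reads uniformly without replacement to a common
#' depth, so that richness and diversity comparisons are not confounded by
#' sequencing effort. The default depth is the minimum sample total, the usual
#' choice for even-depth rarefaction of a metagenome count table. Samples whose
#' total is below `depth` cannot be subsampled and are dropped with a warning.
#'
#' @param m a [count_matrix()].
#' @param depth target read count per sample; default `NULL` uses the minimum
#'   sample total.
#' @param seed integer RNG seed; the draw is deterministic given the seed.
#' @return a `count_matrix` whose retained samples each total exactly `depth`.
#'   Dropped sample ids are recorded in `attr(, "dropped_samples")`.
#' @export
rarefy <- function(m, depth = NULL, seed = 1L) {
  stopifnot(inherits(m, "count_matrix"))
  totals <- rowSums(m$counts)
  if (is.null(depth)) depth <- min(totals)
  depth <- as.numeric(depth)
  if (length(depth) != 1 || !is.finite(depth) || depth <= 0)
    stop("depth must be a single positive number")
  keep <- totals >= depth
  if (!all(keep))
    warning(sum(!keep), " sample(s) below rarefaction depth dropped: ",
            paste(rownames(m$counts)[!keep], collapse = ", "))
  if (!any(keep)) stop("no sample reaches the rarefaction depth")
  counts <- m$counts[keep, , drop = FALSE]
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  rare <- suppressWarnings(vegan::rrarefy(counts, depth))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  out <- count_matrix(
    rare, lengths_kb = m$lengths_kb,
    coverage_expected = if (!is.null(m$coverage_expected))
      m$coverage_expected[keep, , drop = FALSE],
    coverage_observed = if (!is.null(m$coverage_observed))
      m$coverage_observed[keep, , drop = FALSE]
  )
  attr(out, "dropped_samples") <- rownames(m$counts)[!keep]
  out
}

#' Zero out under-covered genome observations
#'
#' Removes spurious mappings: a genome counted in a sample but with observed
#' covered fraction well below what its read count should cover is most likely
#' cross-mapping noise. For each (sample, feature) cell the ratio
#' observed/expected covered fraction is compared against `ratio_threshold`;
#' cells with ratio below the threshold have their counts set to zero (the
#' `>=` comparison retains cells exactly at the threshold). Cells with
#' expected coverage 0 pass only when the observed coverage is also 0.
#'
#' @param m a [count_matrix()] with coverage metadata.
#' @param ratio_threshold minimum observed/expected covered-fraction ratio,
#'   in (0, 1]; default 0.5.
#' @return a filtered `count_matrix` (coverage metadata preserved).
#' @export
coverage_filter <- function(m, ratio_threshold = 0.5) {
  stopifnot(inherits(m, "count_matrix"))
  if (is.null(m$coverage_expected))
    stop("coverage metadata required for coverage_filter")
  if (length(ratio_threshold) != 1 || ratio_threshold <= 0 || ratio_threshold > 1)
    stop("ratio_threshold must lie in (0, 1]")
  exp <- m$coverage_expected
  obs <- m$coverage_observed
  fail <- ifelse(exp == 0, obs != 0, obs / exp < ratio_threshold)
  counts <- m$counts
  if (any(fail)) counts[fail] <- 0
  count_matrix(counts, lengths_kb = m$lengths_kb,
               coverage_expected = exp, coverage_observed = obs)
}

#' Transcripts-per-kilobase-million (TPM) normalization
#'
#' Length-normalized relative abundance: per sample, each feature's count is
#' divided by its length in kilobases to give a rate, and rates are rescaled
#' so every sample sums to one million. An all-zero sample stays all-zero
#' rather than producing NaN.
#'
#' @param m a [count_matrix()] with feature lengths.
#' @return numeric matrix (samples x features) of TPM values; every row with
#'   any reads sums to 1e6.
#' @export
tpm_transform <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  if (is.null(m$lengths_kb))
    stop("feature lengths required for TPM normalization")
  rate <- sweep(m$counts, 2, m$lengths_kb, "/")
  tot <- rowSums(rate)
  tpm <- 1e6 * rate / ifelse(tot > 0, tot, 1)
  tpm
}
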