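#' Filter miRNAs by minimum expression in the smallest group's quota
#'
#' A miRNA is considered expressed in a sample when its normalized count
#' (raw count / median library size x 1e6) is at least `min_norm_count`.
#' The sample quota is `ceiling(min_sample_frac x n_smallest)`, derived from
#' the smallest group. In the default `"all-groups"` mode (the filterByExpr
#' convention) a miRNA is retained when ANY group contains at least the quota
#' of expressed samples; `"smallest-only"` applies the literal rule to the
#' smallest group alone (ties broken by group order).
#'
#' @param x A [mir_counts()] object with group labels, or a matrix (then
#'   `groups` is required).
#' @param groups Group label per sample (defaults to `x$samples$group`).
#' @param min_norm_count Minimum normalized count (default 10).
#' @param min_sample_frac Minimum fraction of the smallest group (default
#'   0.7).
#' @param mode `"all-groups"` or `"smallest-only"` (see above).
#' @return Character vector of retained miRNA ids, input order preserved.
#' @export
filter_expressed <- function(x, groups = NULL, min_norm_count = 10,
                             min_sample_frac = 0.7,
                             mode = c("all-groups", "smallest-only")) {
  mode <- match.arg(mode)
  counts <- if (inherits(x, "mir_counts")) x$counts else as.matrix(x)
  if (is.null(groups) && inherits(x, "mir_counts")) groups <- x$samples$group
  stopifnot(!is.null(groups), length(groups) == ncol(counts),
            min_norm_count > 0, min_sample_frac > 0, min_sample_frac <= 1)
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("all samples must have positive library size")
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least two groups")
  n_small <- min(sizes)
  quota <- ceiling(min_sample_frac * n_small)
  # count >= min_norm_count * median(lib) / 1e6  <=>  normalized count >= min
  thresh <- min_norm_count * stats::median(lib) / 1e6
  expressed <- counts >= thresh
  if (mode == "smallest-only") {
    g <- names(sizes)[which.min(sizes)]
    pass <- rowSums(expressed[, groups == g, drop = FALSE]) >= quota
  } else {
    pass <- rep(FALSE, nrow(counts))
    for (g in names(sizes)) {
      pass <- pass |
        rowSums(expressed[, groups == g, drop = FALSE]) >= quota
    }
  }
  rownames(counts)[pass]
}

#' TMM normalization factors (trimmed mean of M-values)
#'
#' Computes per-sample scaling factors by the trimmed mean of M-values
#' method: the reference sample is the one whose upper-quartile of scaled
#' counts is closest to the mean upper-quartile; for every sample, gene-wise
#' log2 ratios of library-scaled proportions (M) and average log2 abundances
#' (A) are formed over genes positive in both sample and reference, the M
#' values are trimmed 30% on each tail and the A values 5% on each tail, and
#' the factor is 2 to the precision-weighted mean of the surviving M values.
#' Factors are rescaled to geometric mean 1.
#'
#' @param x A [mir_counts()] object or a counts matrix.
#' @param ref Reference sample id or index, or `NULL` for automatic
#'   upper-quartile selection.
#' @param logratio_trim,sum_trim Tail-trim fractions for M and A (defaults
#'   0.3 and 0.05).
#' @param do_weighting Use inverse asymptotic-variance weights (default TRUE).
#' @return Named numeric vector of factors, geometric mean 1; the chosen
#'   reference sample in `attr(,"ref")`.
#' @export
tmm_factors <- function(x, ref = NULL, logratio_trim = 0.3, sum_trim = 0.05,
                        do_weighting = TRUE) {
  counts <- if (inherits(x, "mir_counts")) x$counts else as.matrix(x)
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("all samples must have positive library size")
  counts <- counts[rowSums(counts > 0) > 0L, , drop = FALSE]  # all-zero rows
  if (is.null(ref)) {
    uq <- apply(counts, 2, function(v) stats::quantile(v, 0.75)) / lib
    if (stats::median(uq) < 1e-20) {
      ref_j <- which.max(colSums(sqrt(counts)))
    } else {
      ref_j <- which.min(abs(uq - mean(uq)))
    }
  } else {
    ref_j <- if (is.character(ref)) match(ref, colnames(counts)) else ref
    stopifnot(!is.na(ref_j), ref_j >= 1, ref_j <= ncol(counts))
  }
  refv <- counts[, ref_j]
  nR <- lib[ref_j]
  f <- vapply(seq_len(ncol(counts)), function(j) {
    .tmm_pair(counts[, j], refv, lib[j], nR, logratio_trim, sum_trim,
              do_weighting)
  }, numeric(1))
  if (anyNA(f)) stop("a sample shares no positive genes with the reference")
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  attr(f, "ref") <- colnames(counts)[ref_j]
  f
}

# one sample vs. reference; returns the unscaled TMM factor
.tmm_pair <- function(obs, ref, nO, nR, logratio_trim, sum_trim,
                      do_weighting) {
  logR <- log2((obs / nO) / (ref / nR))
  absE <- (log2(obs / nO) + log2(ref / nR)) / 2
  v <- (nO - obs) / nO / obs + (nR - ref) / nR / ref
  fin <- is.finite(logR) & is.finite(absE)
  if (!any(fin)) return(NA_real_)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * sum_trim) + 1
  hiS <- n + 1 - loS
  keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
    (rank(absE) >= loS & rank(absE) <= hiS)
  fbar <- if (do_weighting) {
    sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  } else {
    mean(logR[keep], na.rm = TRUE)
  }
  if (is.na(fbar)) fbar <- 0
  2^fbar
}

#' Log2 counts per million on TMM-effective library sizes
#'
#' `logCPM_ij = log2((count_ij + prior_j) / (efflib_j + 2 prior_j) x 1e6)`
#' with `efflib_j = lib_j x factor_j` and the prior count scaled in
#' proportion to the effective library size (`prior x efflib_j / mean
#' efflib`), so that zero counts map to a common floor.
#'
#' @param x A [mir_counts()] object or counts matrix.
#' @param factors TMM factors from [tmm_factors()] (default: all 1).
#' @param prior Prior count (default 2).
#' @return Numeric matrix of log2 CPM values, same dimnames as the counts.
#' @export
log_cpm <- function(x, factors = NULL, prior = 2) {
  counts <- if (inherits(x, "mir_counts")) x$counts else as.matrix(x)
  lib <- colSums(counts)
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  eff <- lib * as.numeric(factors)[seq_len(ncol(counts))]
  pj <- prior * eff / mean(eff)
  num <- sweep(counts, 2, pj, "+")
  den <- eff + 2 * pj
  log2(sweep(num, 2, den, "/") * 1e6)
}
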