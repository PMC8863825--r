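#' Quantile-to-quantile negative-binomial count adjustment
#'
#' Maps a count observed under `NB(input_mean, phi)` to the equivalent
#' quantile of `NB(output_mean, phi)`, using the average of a tail-matched
#' normal approximation and a tail-matched gamma approximation (both with
#' the NB mean-variance relation `Var = mu (1 + phi mu)`), computed on the
#' log scale for numerical stability. This is the standard pseudo-count
#' device that places all samples on a common library size before
#' conditional-likelihood computations.
#'
#' @param x Nonnegative counts (vector or matrix).
#' @param input_mean,output_mean Means under the observed and target
#'   libraries (recycled to `x`).
#' @param dispersion NB dispersion phi >= 0.
#' @return Adjusted (pseudo-)counts, same shape as `x`.
#' @export
q2q_nbinom <- function(x, input_mean, output_mean, dispersion = 0) {
  stopifnot(all(x >= 0), all(input_mean >= 0), all(output_mean >= 0),
            dispersion >= 0)
  if (is.matrix(x)) {
    dims <- dim(x)
  } else {
    dims <- NULL
  }
  x <- as.numeric(x)
  input_mean <- rep_len(as.numeric(input_mean), length(x))
  output_mean <- rep_len(as.numeric(output_mean), length(x))
  eps <- 1e-14
  zero <- input_mean < eps | output_mean < eps
  input_mean[zero] <- input_mean[zero] + 0.25
  output_mean[zero] <- output_mean[zero] + 0.25
  ri <- 1 + dispersion * input_mean
  vi <- input_mean * ri
  ro <- 1 + dispersion * output_mean
  vo <- output_mean * ro
  upper <- x >= input_mean
  q1 <- q2 <- x
  for (tail_upper in c(TRUE, FALSE)) {
    k <- if (tail_upper) upper else !upper
    if (!any(k)) next
    lt <- !tail_upper
    p1 <- stats::pnorm(x[k], mean = input_mean[k], sd = sqrt(vi[k]),
                       lower.tail = lt, log.p = TRUE)
    p2 <- stats::pgamma(x[k], shape = input_mean[k] / ri[k], scale = ri[k],
                        lower.tail = lt, log.p = TRUE)
    q1[k] <- stats::qnorm(p1, mean = output_mean[k], sd = sqrt(vo[k]),
                          lower.tail = lt, log.p = TRUE)
    q2[k] <- stats::qgamma(p2, shape = output_mean[k] / ro[k], scale = ro[k],
                           lower.tail = lt, log.p = TRUE)
  }
  out <- (q1 + q2) / 2
  out[out < 0] <- 0
  if (!is.null(dims)) dim(out) <- dims
  out
}

# one-group NB log-linear fit: per-gene abundance lambda with offsets
# log(lib); Fisher-scoring on beta = log(lambda)
.nb_one_group <- function(y, lib, dispersion) {
  tot <- rowSums(y)
  beta <- log(pmax(tot, 0.5) / sum(lib))
  for (it in 1:25) {
    mu <- exp(outer(beta, log(lib), "+"))
    w <- 1 + dispersion * mu
    score <- rowSums((y - mu) / w)
    info <- rowSums(mu / w)
    step <- score / pmax(info, 1e-10)
    step <- pmin(pmax(step, -5), 5)
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  exp(beta)
}

#' Equalize effective library sizes by NB pseudo-counts
#'
#' Estimates per-gene abundances within each group, then quantile-maps every
#' count from its sample's effective library size to the common library size
#' (geometric mean of the effective sizes, or a supplied value).
#'
#' @param counts Counts matrix.
#' @param groups Group label per sample.
#' @param dispersion NB dispersion used for the mapping.
#' @param factors Optional TMM factors (effective lib = lib x factor).
#' @param common_lib Target library size; default geometric mean.
#' @return List: `pseudo` (adjusted counts), `common_lib`.
#' @export
equalize_lib_sizes <- function(counts, groups, dispersion = 0.05,
                               factors = NULL, common_lib = NULL) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  if (!is.null(factors)) lib <- lib * as.numeric(factors)
  if (is.null(common_lib)) common_lib <- exp(mean(log(lib)))
  input_mean <- output_mean <- matrix(0, nrow(counts), ncol(counts))
  for (g in unique(groups)) {
    j <- groups == g
    lambda <- .nb_one_group(counts[, j, drop = FALSE], lib[j], dispersion)
    input_mean[, j] <- outer(lambda, lib[j])
    output_mean[, j] <- outer(lambda, rep(common_lib, sum(j)))
  }
  pseudo <- q2q_nbinom(counts, input_mean, output_mean, dispersion)
  dimnames(pseudo) <- dimnames(counts)
  list(pseudo = pseudo, common_lib = common_lib)
}

#' Common conditional log-likelihood of within-group counts given group sums
#'
#' For independent `NB(mu, phi)` observations the distribution of a group's
#' counts conditional on their sum does not depend on `mu`; summing the log
#' conditional probability over genes and groups gives the qCML objective
#' maximized by [estimate_common_dispersion()]. `phi = 0` uses the Poisson
#' (multinomial) limit.
#'
#' @param phi NB dispersion (scalar, >= 0).
#' @param y_split List of per-group count matrices (pseudo-counts).
#' @return Scalar log-likelihood.
#' @export
nb_cond_loglik <- function(phi, y_split) {
  ll <- 0
  for (y in y_split) {
    y <- as.matrix(y)
    n <- ncol(y)
    if (n < 1) next
    z <- rowSums(y)
    if (phi < 1e-10) {
      ll <- ll + sum(lgamma(z + 1) - rowSums(lgamma(y + 1)) - z * log(n))
    } else {
      r <- 1 / phi
      ll <- ll + sum(rowSums(lgamma(y + r)) - rowSums(lgamma(y + 1)) -
                       n * lgamma(r) + lgamma(z + 1) + lgamma(n * r) -
                       lgamma(z + n * r))
    }
  }
  ll
}

#' Estimate the common NB dispersion by conditional maximum likelihood
#'
#' Quantile-adjusted conditional maximum likelihood (qCML): counts are
#' mapped to a common library size by [equalize_lib_sizes()], then the
#' common conditional log-likelihood [nb_cond_loglik()] is maximized over
#' `delta = phi / (1 + phi)` on a coarse grid followed by golden-section
#' refinement; the pseudo-counts are refreshed at the estimate and the
#' maximization repeated. Genes with total count <= `rowsum_filter` carry
#' little dispersion information and are excluded from the likelihood.
#'
#' @param x A [mir_counts()] or counts matrix.
#' @param groups Group label per sample.
#' @param factors Optional TMM factors.
#' @param rowsum_filter Minimum gene total for inclusion (default 5).
#' @return List of class `disp_estimate`: `dispersion` (phi, clamped to
#'   `[0, 50]`), `method`, `common_lib`, `pseudo` (adjusted counts for all
#'   genes).
#' @export
estimate_common_dispersion <- function(x, groups = NULL, factors = NULL,
                                       rowsum_filter = 5) {
  counts <- if (inherits(x, "mir_counts")) x$counts else as.matrix(x)
  if (is.null(groups) && inherits(x, "mir_counts")) groups <- x$samples$group
  stopifnot(!is.null(groups), length(groups) == ncol(counts))
  if (max(table(groups)) < 2) {
    stop("no replication: every group is a singleton")
  }
  sel <- rowSums(counts) > rowsum_filter
  if (!any(sel)) stop("no genes pass the row-sum filter")
  phi <- 0.01
  eq <- NULL
  for (iter in 1:2) {
    eq <- equalize_lib_sizes(counts, groups, dispersion = phi,
                             factors = factors)
    y_split <- lapply(unique(groups), function(g) {
      eq$pseudo[sel, groups == g, drop = FALSE]
    })
    obj <- function(delta) nb_cond_loglik(delta / (1 - delta), y_split)
    grid <- c(1e-4, 10^seq(-3.5, log10(50 / 51), length.out = 18))
    vals <- vapply(grid, obj, numeric(1))
    best <- which.max(vals)
    lo <- grid[max(1, best - 1)]
    hi <- grid[min(length(grid), best + 1)]
    opt <- stats::optimize(obj, interval = c(lo, hi), maximum = TRUE,
                           tol = 1e-6)
    delta <- opt$maximum
    phi <- min(max(delta / (1 - delta), 0), 50)
  }
  structure(list(dispersion = phi, method = "qCML-common",
                 common_lib = eq$common_lib, pseudo = eq$pseudo),
            class = "disp_estimate")
}

#' @export
print.disp_estimate <- function(x, ...) {
  cat(sprintf("common NB dispersion (qCML): %.4f (BCV %.3f)\n",
              x$dispersion, sqrt(x$dispersion)))
  invisible(x)
}

#' Negative-binomial exact test between two groups
#'
#' Effective library sizes of the two groups' samples are equalized to their
#' arithmetic mean by NB pseudo-counts; per miRNA the (rounded) group-A
#' pseudo-sum is compared to its conditional distribution given the total,
#' under sums of i.i.d. `NB(mu, phi)` variables. The two-sided p-value
#' doubles the smaller tail (each tail includes the observed outcome) and is
#' capped at 1. `phi = 0` reduces to the conditional binomial (Poisson)
#' test. Zero totals give p = 1 and logFC = 0.
#'
#' @param x A [mir_counts()] or counts matrix.
#' @param groups Group label per sample.
#' @param pair Character vector `c(A, B)`; logFC is B relative to A.
#' @param dispersion NB dispersion phi (scalar), e.g. from
#'   [estimate_common_dispersion()].
#' @param factors Optional TMM factors (full-length, one per sample of `x`).
#' @param prior_count Prior count added to group mean CPMs for the logFC
#'   (default 0.125).
#' @return A `de_result` data frame: `mirna`, `logFC`, `logCPM`, `PValue`,
#'   with the comparison label in `attr(,"comparison")`.
#' @export
exact_test <- function(x, groups = NULL, pair, dispersion, factors = NULL,
                       prior_count = 0.125) {
  counts <- if (inherits(x, "mir_counts")) x$counts else as.matrix(x)
  if (is.null(groups) && inherits(x, "mir_counts")) groups <- x$samples$group
  if (inherits(dispersion, "disp_estimate")) dispersion <- dispersion$dispersion
  stopifnot(length(pair) == 2, all(pair %in% groups), dispersion >= 0)
  j <- groups %in% pair
  sub <- counts[, j, drop = FALSE]
  gsub <- groups[j]
  fsub <- if (!is.null(factors)) as.numeric(factors)[j] else NULL
  lib <- colSums(sub)
  eff <- if (is.null(fsub)) lib else lib * fsub
  eq <- equalize_lib_sizes(sub, gsub, dispersion = dispersion,
                           factors = fsub, common_lib = mean(eff))
  n1 <- sum(gsub == pair[1])
  n2 <- sum(gsub == pair[2])
  s1 <- round(rowSums(eq$pseudo[, gsub == pair[1], drop = FALSE]))
  s2 <- round(rowSums(eq$pseudo[, gsub == pair[2], drop = FALSE]))
  p <- nb_exact_pvalue(s1, s2, n1, n2, dispersion)
  m1 <- s1 / n1
  m2 <- s2 / n2
  logfc <- log2((m2 + prior_count) / (m1 + prior_count))
  avecpm <- ((s1 + s2) / (n1 + n2) + 2) / (eq$common_lib + 4) * 1e6
  out <- data.frame(
    mirna = rownames(counts), logFC = logfc, logCPM = log2(avecpm),
    PValue = p, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "comparison") <- paste0(pair[2], "_vs_", pair[1])
  class(out) <- c("de_result", "data.frame")
  out
}

#' Conditional double-tail p-values for NB group sums
#'
#' Workhorse of [exact_test()]: given rounded group sums `s1`, `s2` from
#' `n1` and `n2` equal-library samples and a common dispersion, computes
#' two-sided p-values by exhaustive enumeration of the conditional
#' distribution of the group-1 sum given the total (vectorized across
#' genes in chunks).
#'
#' For totals where both group sums exceed `big_count` the discrete
#' enumeration is replaced by the continuity-corrected beta approximation to
#' the conditional distribution of `s1 / s` (the standard large-count device
#' for this test; the discrete distribution is by then effectively
#' continuous).
#'
#' @param s1,s2 Integer group sums (vectors, same length).
#' @param n1,n2 Group sample counts.
#' @param dispersion Common NB dispersion.
#' @param big_count Both-sums threshold above which the beta approximation
#'   is used (default 900).
#' @param chunk_elems Maximum enumerated outcomes held in memory at once.
#' @return Vector of p-values in `[0, 1]`.
#' @export
nb_exact_pvalue <- function(s1, s2, n1, n2, dispersion, big_count = 900,
                            chunk_elems = 5e6) {
  stopifnot(length(s1) == length(s2), all(s1 >= 0), all(s2 >= 0))
  s <- s1 + s2
  p <- rep(1, length(s1))
  if (dispersion <= 0) {
    # Poisson limit: conditional distribution is Binomial(s, n1/(n1+n2))
    pr <- n1 / (n1 + n2)
    nz <- s > 0
    pl <- stats::pbinom(s1[nz], s[nz], pr)
    pu <- stats::pbinom(s1[nz] - 1, s[nz], pr, lower.tail = FALSE)
    p[nz] <- pmin(2 * pmin(pl, pu), 1)
    return(p)
  }
  mu <- s / (n1 + n2)
  size1 <- n1 / dispersion
  size2 <- n2 / dispersion
  big <- s1 > big_count & s2 > big_count
  if (any(big)) {
    a1 <- (n1 * mu / (1 + dispersion * mu))[big]
    a2 <- (n2 / n1) * a1
    x <- s1[big]
    y <- s[big]
    med <- stats::qbeta(0.5, a1, a2)
    pb <- rep(1, sum(big))
    lo <- (x + 0.5) / y < med
    hi <- (x - 0.5) / y > med
    pb[lo] <- 2 * stats::pbeta((x[lo] + 0.5) / y[lo], a1[lo], a2[lo])
    pb[hi] <- 2 * stats::pbeta((x[hi] - 0.5) / y[hi], a1[hi], a2[hi],
                               lower.tail = FALSE)
    p[big] <- pmin(pb, 1)
  }
  todo <- which(s > 0 & !big)
  # chunk genes so that sum(s + 1) stays bounded
  while (length(todo)) {
    take <- cumsum(s[todo] + 1) <= chunk_elems
    take[1] <- TRUE
    idx <- todo[take]
    todo <- todo[!take]
    lens <- s[idx] + 1
    gi <- rep(seq_along(idx), lens)
    k <- sequence(lens) - 1
    w <- stats::dnbinom(k, size = size1, mu = (n1 * mu)[idx][gi]) *
      stats::dnbinom(s[idx][gi] - k, size = size2, mu = (n2 * mu)[idx][gi])
    tot <- rowsum(w, gi)[, 1]
    wl <- rowsum(w * (k <= s1[idx][gi]), gi)[, 1]
    wu <- rowsum(w * (k >= s1[idx][gi]), gi)[, 1]
    p[idx] <- pmin(2 * pmin(wl, wu) / tot, 1)
  }
  p
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust()]).
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted values, input order preserved.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Run all pairwise exact tests and collect the significant union
#'
#' Estimates the common dispersion (unless supplied), runs the NB exact test
#' for every group pair in cohort order (later group relative to earlier),
#' BH-adjusts each comparison, and returns the union of miRNAs significant
#' at `fdr_threshold` in any comparison, together with volcano
#' (logFC vs. -log10 FDR) and MA (logCPM vs. logFC) tables.
#'
#' @param x A [mir_counts()] with group labels, or counts matrix.
#' @param groups Group labels (default from `x`).
#' @param factors Optional TMM factors.
#' @param dispersion Optional dispersion (estimated if NULL).
#' @param fdr_threshold FDR cutoff for the significant union (default 0.05).
#' @param group_order Order of group labels defining the comparisons;
#'   default: order of first appearance.
#' @return List of class `de_set`: `results` (named list of `de_result`
#'   data frames with an `FDR` column), `union` (character vector),
#'   `dispersion`, `volcano`, `ma` (long-format tables).
#' @export
run_all_comparisons <- function(x, groups = NULL, factors = NULL,
                                dispersion = NULL, fdr_threshold = 0.05,
                                group_order = NULL) {
  counts <- if (inherits(x, "mir_counts")) x$counts else as.matrix(x)
  if (is.null(groups) && inherits(x, "mir_counts")) groups <- x$samples$group
  stopifnot(!is.null(groups))
  if (is.null(group_order)) group_order <- unique(groups)
  if (is.null(dispersion)) {
    dispersion <- estimate_common_dispersion(counts, groups,
                                             factors = factors)
  }
  phi <- if (inherits(dispersion, "disp_estimate")) {
    dispersion$dispersion
  } else {
    dispersion
  }
  pairs <- utils::combn(group_order, 2, simplify = FALSE)
  results <- list()
  for (pr in pairs) {
    de <- exact_test(counts, groups, pair = pr, dispersion = phi,
                     factors = factors)
    de$FDR <- bh_adjust(de$PValue)
    results[[attr(de, "comparison")]] <- de
  }
  union_ids <- unique(unlist(lapply(results, function(d) {
    d$mirna[d$FDR <= fdr_threshold]
  })))
  long <- do.call(rbind, lapply(names(results), function(nm) {
    d <- results[[nm]]
    data.frame(comparison = nm, d, stringsAsFactors = FALSE)
  }))
  structure(list(
    results = results,
    union = union_ids,
    dispersion = phi,
    volcano = data.frame(comparison = long$comparison, mirna = long$mirna,
                         logFC = long$logFC,
                         neg_log10_fdr = -log10(pmax(long$FDR, 1e-300)),
                         stringsAsFactors = FALSE),
    ma = data.frame(comparison = long$comparison, mirna = long$mirna,
                    logCPM = long$logCPM, logFC = long$logFC,
                    stringsAsFactors = FALSE),
    fdr_threshold = fdr_threshold
  ), class = "de_set")
}

#' @export
print.de_set <- function(x, ...) {
  cat("pairwise NB exact tests (common dispersion",
      sprintf("%.4f):\n", x$dispersion))
  for (nm in names(x$results)) {
    d <- x$results[[nm]]
    cat(sprintf("  %-12s %d miRNAs, %d at FDR <= %.2f\n", nm, nrow(d),
                sum(d$FDR <= x$fdr_threshold), x$fdr_threshold))
  }
  cat("significant union:", length(x$union), "miRNAs\n")
  invisible(x)
}
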