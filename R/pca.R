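#' Build the combined miRNA-phenotype feature matrix for PCA
#'
#' Concatenates log-CPM values of the selected miRNAs with the phenotype
#' columns (log-transformed where all observed values are strictly
#' positive), per sample. Missing entries are mean-imputed per column, then
#' every column is centered and scaled to unit variance; zero-variance
#' columns are dropped with a warning.
#'
#' @param logcpm Matrix, miRNAs x samples (typically the significant DE
#'   union); may be `NULL` for a phenotype-only matrix.
#' @param pheno Data frame or matrix, samples x parameters (rownames or a
#'   `sample` column identify samples); may be `NULL` for a miRNA-only
#'   matrix.
#' @param log_pheno Log-transform strictly positive phenotype columns
#'   (default TRUE).
#' @return Numeric matrix, samples x features, each column mean 0 / SD 1;
#'   dropped column names in `attr(,"dropped")`.
#' @export
build_feature_matrix <- function(logcpm = NULL, pheno = NULL,
                                 log_pheno = TRUE) {
  parts <- list()
  if (!is.null(logcpm)) {
    parts$mir <- t(as.matrix(logcpm))
  }
  if (!is.null(pheno)) {
    if (is.data.frame(pheno) && "sample" %in% names(pheno)) {
      rownames(pheno) <- pheno$sample
      pheno$sample <- NULL
    }
    ph <- as.matrix(pheno)
    if (log_pheno) {
      for (k in seq_len(ncol(ph))) {
        v <- ph[, k]
        if (all(v[!is.na(v)] > 0)) ph[, k] <- log(v)
      }
    }
    parts$pheno <- ph
  }
  stopifnot(length(parts) > 0)
  if (length(parts) == 2) {
    common <- intersect(rownames(parts$mir), rownames(parts$pheno))
    if (length(common) < 3) stop("need >= 3 shared samples")
    x <- cbind(parts$mir[common, , drop = FALSE],
               parts$pheno[common, , drop = FALSE])
  } else {
    x <- parts[[1]]
  }
  # per-column mean imputation, then z-scoring
  for (k in seq_len(ncol(x))) {
    v <- x[, k]
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    x[, k] <- v
  }
  sds <- apply(x, 2, stats::sd)
  drop <- !is.finite(sds) | sds == 0
  if (any(drop)) {
    warning("dropping zero-variance feature(s): ",
            paste(colnames(x)[drop], collapse = ", "))
  }
  x <- x[, !drop, drop = FALSE]
  out <- scale(x)
  attr(out, "dropped") <- colnames(x)[drop]
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

#' Principal component analysis with deterministic sign convention
#'
#' Singular value decomposition of the (defensively re-centered) feature
#' matrix; eigenvalues are squared singular values over n - 1. Each
#' component's sign is fixed so that its largest-magnitude loading is
#' positive, making results reproducible across linear-algebra backends.
#' Contributions of feature i to component k are
#' `100 x loading_ik^2 / sum_i loading_ik^2`.
#'
#' @param x Samples x features matrix from [build_feature_matrix()].
#' @return A `pca_result`: `scores` (samples x components), `loadings`
#'   (features x components, orthonormal columns), `eigenvalues`,
#'   `var_frac` (fractions of total variance), `contrib` (percent,
#'   columns sum to 100).
#' @export
run_pca <- function(x) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 2, ncol(x) >= 2)
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc)
  ncomp <- sum(sv$d > max(sv$d) * 1e-12)
  d <- sv$d[seq_len(ncomp)]
  u <- sv$u[, seq_len(ncomp), drop = FALSE]
  v <- sv$v[, seq_len(ncomp), drop = FALSE]
  for (k in seq_len(ncomp)) {
    if (v[which.max(abs(v[, k])), k] < 0) {
      v[, k] <- -v[, k]
      u[, k] <- -u[, k]
    }
  }
  lambda <- d^2 / (nrow(x) - 1)
  comp <- paste0("PC", seq_len(ncomp))
  scores <- u %*% diag(d, ncomp)
  dimnames(scores) <- list(rownames(x), comp)
  dimnames(v) <- list(colnames(x), comp)
  contrib <- 100 * sweep(v^2, 2, colSums(v^2), "/")
  structure(list(scores = scores, loadings = v, eigenvalues = lambda,
                 var_frac = lambda / sum(lambda), contrib = contrib),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(5, length(x$var_frac))
  cat("PCA:", nrow(x$scores), "samples,", nrow(x$loadings), "features\n")
  cat("variance explained:",
      paste(sprintf("%s %.1f%%", paste0("PC", seq_len(k)),
                    100 * x$var_frac[seq_len(k)]), collapse = ", "), "\n")
  invisible(x)
}

#' Rank features by their contribution to selected components
#'
#' Combined score of feature i = eigenvalue-weighted mean of its percent
#' contributions over the selected components (the convention used for
#' variable-contribution plots). Ties are broken by feature name.
#'
#' @param res A `pca_result`.
#' @param k Number of features to return (default 30; all if fewer).
#' @param components Components combined (default 1:2).
#' @return Data frame `feature`, `contrib` (combined percent), plus the
#'   per-component contributions, ordered by decreasing combined score.
#' @export
top_contributors <- function(res, k = 30, components = 1:2) {
  stopifnot(inherits(res, "pca_result"),
            all(components <= ncol(res$contrib)))
  w <- res$eigenvalues[components]
  cc <- res$contrib[, components, drop = FALSE]
  combined <- as.numeric(cc %*% w) / sum(w)
  ord <- order(-combined, rownames(res$contrib))
  k <- min(k, length(combined))
  out <- data.frame(feature = rownames(res$contrib)[ord],
                    contrib = combined[ord],
                    stringsAsFactors = FALSE)
  out <- cbind(out, cc[ord, , drop = FALSE])
  rownames(out) <- NULL
  out[seq_len(k), , drop = FALSE]
}

#' Summarize group separation along the first principal component
#'
#' Reports per-group PC1 mean and SD, the best threshold-classifier accuracy
#' separating the two extreme groups (those with the lowest and highest PC1
#' means) and whether the remaining group's mean lies between them.
#'
#' @param res A `pca_result` (or a scores matrix).
#' @param groups Group label per sample.
#' @return List: `group_stats` (data frame), `extremes`, `accuracy`,
#'   `middle`, `intermediate` (logical, NA with only two groups).
#' @export
group_separation <- function(res, groups) {
  scores <- if (inherits(res, "pca_result")) res$scores else as.matrix(res)
  pc1 <- scores[, 1]
  stopifnot(length(groups) == length(pc1))
  gs <- data.frame(
    group = unique(groups),
    mean = tapply(pc1, groups, mean)[unique(groups)],
    sd = tapply(pc1, groups, stats::sd)[unique(groups)],
    n = as.integer(table(groups)[unique(groups)]),
    stringsAsFactors = FALSE
  )
  rownames(gs) <- NULL
  lo <- gs$group[which.min(gs$mean)]
  hi <- gs$group[which.max(gs$mean)]
  sel <- groups %in% c(lo, hi)
  v <- pc1[sel]
  lab <- groups[sel] == hi
  cand <- sort(unique(v))
  thr <- (cand[-1] + cand[-length(cand)]) / 2
  acc <- vapply(thr, function(t) {
    max(mean((v > t) == lab), mean((v <= t) == lab))
  }, numeric(1))
  accuracy <- if (length(acc)) max(acc) else NA_real_
  middle <- setdiff(gs$group, c(lo, hi))
  intermediate <- if (length(middle) == 1) {
    mm <- gs$mean[gs$group == middle]
    mm > min(gs$mean) & mm < max(gs$mean)
  } else {
    NA
  }
  list(group_stats = gs, extremes = c(low = lo, high = hi),
       accuracy = accuracy, middle = middle, intermediate = intermediate)
}

#' Biplot-style figure of samples and top feature loadings
#'
#' @param res A `pca_result`.
#' @param groups Group label per sample.
#' @param file Output PNG path.
#' @param n_arrows Number of top-contributing loadings drawn (default 15).
#' @return `file`, invisibly.
#' @export
plot_pca <- function(res, groups, file, n_arrows = 15) {
  grDevices::png(file, width = 1000, height = 800, res = 120)
  on.exit(grDevices::dev.off())
  sc <- res$scores
  cols <- as.integer(factor(groups)) + 1L
  graphics::plot(sc[, 1], sc[, 2], col = cols, pch = 19,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * res$var_frac[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * res$var_frac[2]))
  graphics::legend("topright", legend = levels(factor(groups)),
                   col = seq_along(unique(groups)) + 1L, pch = 19)
  top <- top_contributors(res, k = n_arrows)$feature
  ld <- res$loadings[top, 1:2, drop = FALSE] * max(abs(sc[, 1:2])) * 0.8
  graphics::arrows(0, 0, ld[, 1], ld[, 2], length = 0.08, col = "grey40")
  graphics::text(ld[, 1] * 1.05, ld[, 2] * 1.05, rownames(ld), cex = 0.6)
  invisible(file)
}
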