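#' Spearman correlation of miRNA expression with physiological parameters
#'
#' Rank correlation (average ranks, pairwise-complete samples) between each
#' miRNA's log-CPM profile and each numeric phenotype column. Pairs with
#' fewer than 3 complete observations, and pairs involving a constant
#' vector, are flagged `NA` (not 0).
#'
#' @param logcpm Matrix, miRNAs x samples (e.g. [log_cpm()] restricted to
#'   the significant miRNAs).
#' @param pheno Data frame or matrix, samples x parameters; rownames (or a
#'   `sample` column) must match the logcpm columns.
#' @return A `corr_matrix`: list with `rho` (miRNA x parameter Spearman
#'   matrix), `n` (pairwise complete counts), `row_order`, `col_order`
#'   (identity until [block_order()] is applied).
#' @export
spearman_matrix <- function(logcpm, pheno) {
  logcpm <- as.matrix(logcpm)
  if (is.data.frame(pheno) && "sample" %in% names(pheno)) {
    rownames(pheno) <- pheno$sample
    pheno$sample <- NULL
  }
  pheno <- as.matrix(pheno)
  stopifnot(ncol(logcpm) >= 3)
  common <- intersect(colnames(logcpm), rownames(pheno))
  if (length(common) < 3) stop("need >= 3 shared samples")
  x <- t(logcpm[, common, drop = FALSE])
  y <- pheno[common, , drop = FALSE]
  rho <- suppressWarnings(
    stats::cor(x, y, method = "spearman", use = "pairwise.complete.obs")
  )
  n <- crossprod(!is.na(x), !is.na(y))
  rho[n < 3] <- NA
  structure(list(rho = rho, n = n,
                 row_order = seq_len(nrow(rho)),
                 col_order = seq_len(ncol(rho))),
            class = "corr_matrix")
}

#' Order a correlation matrix to expose correlated blocks
#'
#' Average-linkage hierarchical clustering on Euclidean distances of the
#' correlation profiles, applied independently to rows and columns. Inputs
#' are first sorted by label so the result does not depend on the incoming
#' row/column order; missing correlations are treated as 0 for the distance
#' computation only.
#'
#' @param cm A `corr_matrix` from [spearman_matrix()].
#' @return The same object with `row_order` and `col_order` set; `rho` and
#'   `n` are unchanged (index with the orders for display).
#' @export
block_order <- function(cm) {
  stopifnot(inherits(cm, "corr_matrix"))
  ord1 <- function(m) {
    if (nrow(m) < 3) return(seq_len(nrow(m)))
    lab_ord <- order(rownames(m))
    m <- m[lab_ord, , drop = FALSE]
    m[is.na(m)] <- 0
    hc <- stats::hclust(stats::dist(m), method = "average")
    lab_ord[hc$order]
  }
  cm$row_order <- ord1(cm$rho)
  cm$col_order <- ord1(t(cm$rho))
  cm
}

#' @export
print.corr_matrix <- function(x, ...) {
  cat("corr_matrix:", nrow(x$rho), "miRNAs x", ncol(x$rho), "parameters;",
      sum(is.na(x$rho)), "flagged missing\n")
  invisible(x)
}

#' Write a correlation heatmap mirroring the miRNA-phenotype block figure
#'
#' Uses pheatmap when available, otherwise a base-graphics image. The
#' display order comes from [block_order()].
#'
#' @param cm A `corr_matrix`.
#' @param file Output PNG path.
#' @return `file`, invisibly.
#' @export
plot_corr_heatmap <- function(cm, file) {
  m <- cm$rho[cm$row_order, cm$col_order, drop = FALSE]
  grDevices::png(file, width = 1400, height = 900, res = 120)
  on.exit(grDevices::dev.off())
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                       na_col = "grey80",
                       main = "Spearman correlation: miRNA vs. phenotype")
  } else {
    graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m[rev(seq_len(nrow(m))), ]),
                    xlab = "", ylab = "", axes = FALSE,
                    col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                    zlim = c(-1, 1))
    graphics::axis(1, seq_len(ncol(m)), colnames(m), las = 2, cex.axis = 0.6)
    graphics::axis(2, seq_len(nrow(m)), rev(rownames(m)), las = 2,
                   cex.axis = 0.6)
  }
  invisible(file)
}
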