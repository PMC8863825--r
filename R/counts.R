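#' Fractional miRNA count matrix with sample metadata
#'
#' Lightweight container pairing a mature-miRNA x sample matrix of
#' nonnegative fractional counts with a sample table (group label, library
#' size = column sum, TMM normalization factor, initially 1).
#'
#' @param counts Numeric matrix, rows = mature miRNA ids, columns = samples.
#' @param groups Optional group label per sample.
#' @return An object of class `mir_counts`: list with `counts` and `samples`.
#' @export
mir_counts <- function(counts, groups = NULL) {
  counts <- as.matrix(counts)
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)),
            all(counts >= 0))
  samples <- data.frame(
    sample = colnames(counts),
    group = if (is.null(groups)) NA_character_ else as.character(groups),
    lib.size = colSums(counts),
    norm.factors = 1,
    stringsAsFactors = FALSE
  )
  structure(list(counts = counts, samples = samples), class = "mir_counts")
}

#' @export
print.mir_counts <- function(x, ...) {
  cat("mir_counts:", nrow(x$counts), "mature miRNAs x", ncol(x$counts),
      "samples\n")
  if (!all(is.na(x$samples$group))) {
    print(table(x$samples$group))
  }
  cat("library sizes:", paste(signif(range(x$samples$lib.size), 4),
                              collapse = " - "), "\n")
  invisible(x)
}

#' @export
`[.mir_counts` <- function(x, i, j, ...) {
  out <- x
  if (!missing(i)) out$counts <- out$counts[i, , drop = FALSE]
  if (!missing(j)) {
    out$counts <- out$counts[, j, drop = FALSE]
    out$samples <- out$samples[j, , drop = FALSE]
  }
  out$samples$lib.size <- colSums(out$counts)
  out
}

#' Write a count matrix to TSV
#'
#' @param x A `mir_counts` or matrix.
#' @param path Output path; first column `mirna`, then one column per sample.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(x, path) {
  m <- if (inherits(x, "mir_counts")) x$counts else as.matrix(x)
  df <- data.frame(mirna = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix from TSV
#'
#' @param path TSV written by [write_counts_tsv()].
#' @param sample_table Optional path to a sample table TSV with columns
#'   `sample` and `group`.
#' @return A `mir_counts` object.
#' @export
read_counts_tsv <- function(path, sample_table = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  groups <- NULL
  if (!is.null(sample_table)) {
    st <- utils::read.delim(sample_table, stringsAsFactors = FALSE)
    groups <- st$group[match(colnames(m), st$sample)]
  }
  mir_counts(m, groups = groups)
}
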