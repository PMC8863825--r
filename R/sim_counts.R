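#' Simulate negative-binomial miRNA counts, phenotypes and ground truth
#'
#' Counts follow `count_ij ~ NB(mean = s_j * mu_i * 2^eff_ij, dispersion phi)`
#' with `Var = mu + phi mu^2`; `eff_ij` is the signed log2 fold-change when
#' sample j's group is the miRNA's shifted group, 0 otherwise, and `s_j` is
#' the sample's expected library size. `phi = 0` degenerates to Poisson.
#'
#' Differential expression is injected as a risk block (shifted up in the
#' third group), a health block (shifted up in the first group) and, up to
#' `frac_de`, additional miRNAs with a random shifted group and sign. Block
#' members are drawn from the better-expressed half of the abundance range so
#' the blocks survive the expression filter, as well-characterised serum
#' miRNAs do.
#'
#' Each phenotype is a linear-Gaussian function of a group effect and the
#' standardized log2 latent abundances of its associated block miRNAs, with
#' association signs from [pheno_assoc_table()]; values are then mapped
#' affinely onto cohort-typical scales. Only the signs are ground truth.
#'
#' @param design A [sim_design()].
#' @param reference The [generate_reference()] output for the same design.
#' @return List with elements `truth` (a `mir_ground_truth`: `true_counts`,
#'   `expected_counts` — the truth redistributed across identical-sequence
#'   loci, what an exact 1/N quantifier recovers —, `de_flags`, `true_logfc`,
#'   `shift_group`, `shift_sign`, `pheno_signs`, `lib_sizes`), `pheno` (data
#'   frame, rows = samples), and `samples` (sample id + group).
#' @export
simulate_counts <- function(design, reference) {
  stopifnot(inherits(design, "sim_design"), inherits(reference, "precursor_set"))
  set.seed(design$seed + 1L)
  m <- reference$matures
  n_mir <- nrow(m)
  stopifnot(n_mir == design$n_mirna)
  groups <- rep(design$group_labels, design$group_sizes)
  n_samp <- length(groups)
  sample_ids <- sprintf("S%03d", seq_len(n_samp))
  samples <- data.frame(sample = sample_ids, group = groups,
                        stringsAsFactors = FALSE)

  # baseline relative abundances
  logw <- stats::runif(n_mir, design$baseline_logmean_range[1],
                       design$baseline_logmean_range[2])
  w <- 2^logw
  prop <- w / sum(w)

  # DE structure: blocks among the better-expressed half, extras anywhere
  n_de <- floor(design$frac_de * n_mir)
  n_block <- design$risk_block_size + design$health_block_size
  shift_group <- rep(NA_character_, n_mir)
  shift_sign <- rep(0L, n_mir)
  if (n_de > 0) {
    hi <- which(logw >= stats::median(logw))
    block_idx <- sample(hi, n_block)
    risk_idx <- block_idx[seq_len(design$risk_block_size)]
    health_idx <- block_idx[design$risk_block_size + seq_len(design$health_block_size)]
    pool <- setdiff(seq_len(n_mir), block_idx)
    extra_idx <- if (n_de > n_block) sample(pool, n_de - n_block) else integer(0)
    shift_group[risk_idx] <- design$group_labels[3]
    shift_sign[risk_idx] <- 1L
    shift_group[health_idx] <- design$group_labels[1]
    shift_sign[health_idx] <- 1L
    if (length(extra_idx)) {
      shift_group[extra_idx] <- sample(design$group_labels, length(extra_idx),
                                       replace = TRUE)
      shift_sign[extra_idx] <- sample(c(-1L, 1L), length(extra_idx),
                                      replace = TRUE)
    }
  } else {
    risk_idx <- health_idx <- integer(0)
  }

  # per-miRNA, per-group log2 effect
  eff <- matrix(0, n_mir, 3, dimnames = list(m$id, design$group_labels))
  de <- !is.na(shift_group)
  eff[cbind(which(de), match(shift_group[de], design$group_labels))] <-
    shift_sign[de] * design$logfc_magnitude

  comparisons <- comparison_labels(design$group_labels)
  true_logfc <- matrix(0, n_mir, 3, dimnames = list(m$id, comparisons$label))
  for (k in seq_len(3)) {
    true_logfc[, k] <- eff[, comparisons$b[k]] - eff[, comparisons$a[k]]
  }
  de_flags <- abs(true_logfc) > 0

  # expected library sizes and NB draws
  s_j <- round(stats::runif(n_samp, design$lib_size_range[1],
                            design$lib_size_range[2]))
  mu <- outer(prop, s_j) * 2^eff[, match(groups, design$group_labels)]
  counts <- matrix(0L, n_mir, n_samp, dimnames = list(m$id, sample_ids))
  if (design$dispersion > 0) {
    counts[] <- stats::rnbinom(length(mu), mu = mu,
                               size = 1 / design$dispersion)
  } else {
    counts[] <- stats::rpois(length(mu), lambda = mu)
  }

  # redistribution across identical mature sequences (multi-mapper truth)
  seq_grp <- match(m$sequence, m$sequence)
  expected <- counts
  for (g in unique(seq_grp[duplicated(seq_grp)])) {
    rows <- which(seq_grp == g)
    expected[rows, ] <- rep(colSums(counts[rows, , drop = FALSE]) /
                              length(rows), each = length(rows))
  }

  # phenotypes
  assoc <- pheno_assoc_table(design)
  block_all <- c(risk_idx, health_idx)
  assoc$mirna <- m$id[block_all][assoc$mirna_index]
  cat_used <- .pheno_catalog[seq_len(design$n_pheno), ]
  lat <- log2(mu + 0.5)
  zlat <- t(scale(t(lat)))  # per-miRNA standardized latent abundance
  zlat[!is.finite(zlat)] <- 0
  grp_idx <- match(groups, design$group_labels)
  pheno <- matrix(NA_real_, n_samp, design$n_pheno,
                  dimnames = list(sample_ids, cat_used$name))
  for (p in seq_len(design$n_pheno)) {
    cls <- cat_used$class[p]
    code <- switch(cls,
                   risk = c(-0.5, -0.5, 1)[grp_idx],
                   fitness = c(1, -0.5, -0.5)[grp_idx],
                   neutral = rep(0, n_samp))
    rows <- assoc[assoc$pheno == cat_used$name[p], , drop = FALSE]
    mir_term <- if (nrow(rows)) {
      colMeans(zlat[rows$mirna, , drop = FALSE] * rows$sign)
    } else {
      rep(0, n_samp)
    }
    z <- design$pheno_group_alpha * code + design$pheno_beta * mir_term +
      stats::rnorm(n_samp, 0, design$pheno_noise_sd)
    x <- cat_used$mean[p] + cat_used$sd[p] * z
    pheno[, p] <- pmax(x, 0.02 * cat_used$mean[p])
  }
  pheno <- as.data.frame(pheno)

  truth <- structure(list(
    true_counts = counts,
    expected_counts = expected,
    de_flags = de_flags,
    true_logfc = true_logfc,
    shift_group = shift_group,
    shift_sign = shift_sign,
    pheno_signs = assoc[, c("mirna", "pheno", "sign")],
    lib_sizes = colSums(counts),
    comparisons = comparisons
  ), class = "mir_ground_truth")
  list(truth = truth, pheno = pheno, samples = samples)
}

#' Pairwise comparison labels for an ordered set of group labels
#'
#' @param labels Three group labels in cohort order.
#' @return Data frame with columns `a`, `b`, `label` (`b_vs_a`), one row per
#'   unordered pair, later group always the numerator.
#' @export
comparison_labels <- function(labels) {
  stopifnot(length(labels) == 3)
  data.frame(
    a = labels[c(1, 1, 2)],
    b = labels[c(2, 3, 3)],
    label = paste0(labels[c(2, 3, 3)], "_vs_", labels[c(1, 1, 2)]),
    stringsAsFactors = FALSE
  )
}

#' Write simulated reads to per-sample gzipped FASTQ files
#'
#' Each counted molecule becomes one read: mature sequence + 3' adapter,
#' truncated to `design$read_length` bases, with independent per-base
#' substitution errors at `design$error_rate`. Quality lines are a constant
#' "I" (the described pipeline never uses base qualities). Read names encode
#' only the sample and a serial number, so no truth leaks to the pipeline.
#'
#' @param truth A `mir_ground_truth` from [simulate_counts()].
#' @param reference The matching `precursor_set`.
#' @param design The matching [sim_design()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of FASTQ paths (one per sample).
#' @export
write_fastq <- function(truth, reference, design, dir) {
  stopifnot(inherits(truth, "mir_ground_truth"))
  set.seed(design$seed + 2L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- reference$matures
  counts <- truth$true_counts
  stopifnot(identical(rownames(counts), m$id))
  full <- substr(paste0(m$sequence, design$adapter), 1L, design$read_length)
  bases <- c("A", "C", "G", "T")
  paths <- character(ncol(counts))
  names(paths) <- colnames(counts)
  for (j in seq_len(ncol(counts))) {
    sid <- colnames(counts)[j]
    idx <- rep(seq_len(nrow(counts)), counts[, j])
    reads <- full[idx]
    lens <- nchar(reads)
    if (design$error_rate > 0 && length(reads)) {
      nerr <- stats::rbinom(length(reads), lens, design$error_rate)
      for (r in which(nerr > 0L)) {
        pos <- sample.int(lens[r], nerr[r])
        ch <- strsplit(reads[r], "", fixed = TRUE)[[1]]
        for (p in pos) {
          ch[p] <- sample(setdiff(bases, ch[p]), 1L)
        }
        reads[r] <- paste(ch, collapse = "")
      }
    }
    path <- file.path(dir, paste0(sid, ".fastq.gz"))
    con <- gzfile(path, "wb")
    qual <- strrep("I", lens)
    block <- paste0("@", sid, "_", seq_along(reads), "\n", reads, "\n+\n",
                    qual)
    writeLines(block, con)
    close(con)
    paths[j] <- path
  }
  invisible(paths)
}
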