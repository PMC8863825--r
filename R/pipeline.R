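#' Pipeline configuration
#'
#' Collects every tunable of the full workflow under named keys. In
#' simulation mode (`simulate = sim_design(...)` or a list of its
#' arguments), the reference, counts and optionally reads are generated; in
#' file mode the `fastq_dir`, `fasta`, `gff` and `sample_table` paths are
#' used.
#'
#' @param out_dir Output directory.
#' @param fastq_dir,fasta,gff,sample_table Input paths (file mode).
#' @param adapter 3' adapter sequence.
#' @param max_mismatches Mapper mismatch tolerance.
#' @param min_len Minimum insert length after trimming.
#' @param min_norm_count,min_sample_frac,filter_mode Expression-filter rule
#'   (see [filter_expressed()]).
#' @param fdr_threshold FDR cutoff for the significant union.
#' @param run_correlation,run_pca_stage Stage toggles.
#' @param read_level In simulation mode, generate and quantify FASTQ reads
#'   (slow but exercises the full path); otherwise the simulated counts are
#'   used directly.
#' @param simulate `NULL`, a [sim_design()], or a list of arguments for it.
#' @param seed Seed recorded in the manifest (the simulation seed lives in
#'   the design).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            fastq_dir = NULL, fasta = NULL, gff = NULL,
                            sample_table = NULL,
                            adapter = "AACTGTAGGCACCATCAAT",
                            max_mismatches = 1L,
                            min_len = 15L,
                            min_norm_count = 10,
                            min_sample_frac = 0.7,
                            filter_mode = "all-groups",
                            fdr_threshold = 0.05,
                            run_correlation = TRUE,
                            run_pca_stage = TRUE,
                            read_level = FALSE,
                            simulate = NULL,
                            seed = 1L) {
  if (!is.null(simulate) && !inherits(simulate, "sim_design")) {
    simulate <- do.call(sim_design, simulate)
  }
  cfg <- list(out_dir = out_dir, fastq_dir = fastq_dir, fasta = fasta,
              gff = gff, sample_table = sample_table, adapter = adapter,
              max_mismatches = as.integer(max_mismatches),
              min_len = as.integer(min_len),
              min_norm_count = min_norm_count,
              min_sample_frac = min_sample_frac,
              filter_mode = filter_mode,
              fdr_threshold = fdr_threshold,
              run_correlation = isTRUE(run_correlation),
              run_pca_stage = isTRUE(run_pca_stage),
              read_level = isTRUE(read_level),
              simulate = simulate, seed = as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' @param cfg A config list.
#' @return `cfg` invisibly; stops with the offending field named otherwise.
#' @export
validate_config <- function(cfg) {
  if (!(cfg$fdr_threshold > 0 && cfg$fdr_threshold < 1)) {
    stop("config field 'fdr_threshold' must be in (0, 1)")
  }
  if (is.null(cfg$simulate)) {
    for (f in c("fastq_dir", "fasta", "gff", "sample_table")) {
      if (is.null(cfg[[f]]) || !file.exists(cfg[[f]])) {
        stop(sprintf("config field '%s' missing or does not exist", f))
      }
    }
  }
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file; keys mirror [pipeline_config()] arguments, with an
#'   optional `simulate:` block of [sim_design()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Per-miRNA detection and median-expression summaries
#'
#' For each annotated mature miRNA, the number of samples with a nonzero
#' count (histogram over 0..n samples), and the distribution of per-miRNA
#' median CPM (zero-median miRNAs excluded from the second summary).
#'
#' @param x A [mir_counts()] or counts matrix.
#' @return List: `detection_hist` (named integer vector over 0..n; sums to
#'   the number of annotated miRNAs), `median_cpm` (per-miRNA medians,
#'   zero-median rows removed).
#' @export
detection_summary <- function(x) {
  counts <- if (inherits(x, "mir_counts")) x$counts else as.matrix(x)
  n <- ncol(counts)
  det <- rowSums(counts > 0)
  hist <- table(factor(det, levels = 0:n))
  cpm <- sweep(counts, 2, colSums(counts), "/") * 1e6
  med <- apply(cpm, 1, stats::median)
  list(detection_hist = stats::setNames(as.integer(hist), names(hist)),
       median_cpm = med[med > 0])
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> quantify -> filter/normalize -> pairwise
#' DE -> correlation -> PCA, persisting every intermediate table under
#' `cfg$out_dir` together with a machine-readable manifest (per-stage
#' parameters and output MD5 hashes) and a human-readable summary. Identical
#' config and seed give identical manifest hashes.
#'
#' @param cfg A [pipeline_config()].
#' @return List of in-memory stage results, invisibly; the manifest is
#'   written to `manifest.json` and the summary to `summary.json`.
#' @export
run_pipeline <- function(cfg) {
  validate_config(cfg)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed, stages = list())
  add_stage <- function(name, params, files) {
    manifest$stages[[name]] <<- list(
      params = params,
      outputs = as.list(tools::md5sum(files[file.exists(files)]))
    )
  }
  truth <- NULL

  if (!is.null(cfg$simulate)) {
    design <- cfg$simulate
    ps <- generate_reference(design)
    fasta <- file.path(out, "reference.fa")
    gff <- file.path(out, "reference.gff3")
    write_precursor_fasta(ps, fasta)
    write_precursor_gff3(ps, gff)
    sim <- simulate_counts(design, ps)
    truth <- sim$truth
    samples <- sim$samples
    pheno <- data.frame(sample = samples$sample, sim$pheno,
                        stringsAsFactors = FALSE)
    utils::write.table(samples, file.path(out, "samples.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(pheno, file.path(out, "phenotypes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(lib_sizes = as.list(truth$lib_sizes),
           n_de = sum(rowSums(truth$de_flags) > 0)),
      file.path(out, "ground_truth.json"), auto_unbox = TRUE
    )
    add_stage("simulate", list(seed = design$seed, n_mirna = design$n_mirna),
              c(fasta, gff, file.path(out, c("samples.tsv",
                                             "phenotypes.tsv"))))
    if (cfg$read_level) {
      fq_dir <- file.path(out, "fastq")
      write_fastq(truth, ps, design, fq_dir)
      counts <- quantify_samples(fq_dir, ps, adapter = design$adapter,
                                 groups = samples$group,
                                 max_mismatches = cfg$max_mismatches)
    } else {
      counts <- mir_counts(truth$true_counts, groups = samples$group)
    }
  } else {
    ps <- read_precursor_set(cfg$fasta, cfg$gff)
    st <- utils::read.delim(cfg$sample_table, stringsAsFactors = FALSE)
    counts <- quantify_samples(cfg$fastq_dir, ps, adapter = cfg$adapter,
                               max_mismatches = cfg$max_mismatches)
    counts$samples$group <- st$group[match(counts$samples$sample, st$sample)]
    samples <- counts$samples[, c("sample", "group")]
    pheno_cols <- setdiff(names(st), c("sample", "group"))
    pheno <- st[, c("sample", pheno_cols), drop = FALSE]
  }
  counts_path <- file.path(out, "counts.tsv")
  write_counts_tsv(counts, counts_path)
  qc <- attr(counts, "qc")
  if (!is.null(qc)) {
    jsonlite::write_json(qc, file.path(out, "quantify_qc.json"),
                         auto_unbox = TRUE)
  }
  add_stage("quantify", list(adapter = cfg$adapter,
                             max_mismatches = cfg$max_mismatches,
                             min_len = cfg$min_len),
            c(counts_path, file.path(out, "quantify_qc.json")))

  det <- detection_summary(counts)
  jsonlite::write_json(
    list(detection_hist = as.list(det$detection_hist),
         n_with_nonzero_median = length(det$median_cpm)),
    file.path(out, "detection_summary.json"), auto_unbox = TRUE
  )
  keep <- filter_expressed(counts, min_norm_count = cfg$min_norm_count,
                           min_sample_frac = cfg$min_sample_frac,
                           mode = cfg$filter_mode)
  filtered <- counts[keep, ]
  factors <- tmm_factors(filtered)
  filtered$samples$norm.factors <- as.numeric(factors)
  logcpm <- log_cpm(filtered, factors)
  filt_path <- file.path(out, "filtered_counts.tsv")
  write_counts_tsv(filtered, filt_path)
  jsonlite::write_json(
    list(retained = length(keep), removed = nrow(counts$counts) - length(keep),
         factors = as.list(round(as.numeric(factors), 6))),
    file.path(out, "normalize_report.json"), auto_unbox = TRUE
  )
  add_stage("normalize", list(min_norm_count = cfg$min_norm_count,
                              min_sample_frac = cfg$min_sample_frac,
                              mode = cfg$filter_mode),
            c(filt_path, file.path(out, "normalize_report.json")))

  de <- run_all_comparisons(filtered, factors = factors,
                            fdr_threshold = cfg$fdr_threshold,
                            group_order = unique(samples$group))
  de_files <- character(0)
  for (nm in names(de$results)) {
    f <- file.path(out, paste0("de_", nm, ".tsv"))
    utils::write.table(de$results[[nm]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    de_files <- c(de_files, f)
  }
  union_path <- file.path(out, "de_union.tsv")
  utils::write.table(data.frame(mirna = de$union), union_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  add_stage("diffexp", list(fdr_threshold = cfg$fdr_threshold,
                            dispersion = de$dispersion),
            c(de_files, union_path))

  corr <- NULL
  if (cfg$run_correlation && length(de$union) >= 1 && !is.null(pheno)) {
    corr <- spearman_matrix(logcpm[de$union, , drop = FALSE], pheno)
    if (length(de$union) >= 2) corr <- block_order(corr)
    cp <- file.path(out, "spearman.tsv")
    m <- corr$rho[corr$row_order, corr$col_order, drop = FALSE]
    utils::write.table(data.frame(mirna = rownames(m), m,
                                  check.names = FALSE),
                       cp, sep = "\t", quote = FALSE, row.names = FALSE)
    add_stage("correlate", list(n_mirna = nrow(m)), cp)
  }

  pca <- sep <- NULL
  if (cfg$run_pca_stage && length(de$union) >= 2 && !is.null(pheno)) {
    fm <- build_feature_matrix(logcpm[de$union, , drop = FALSE], pheno)
    pca <- run_pca(fm)
    sep <- group_separation(pca, samples$group[match(rownames(fm),
                                                     samples$sample)])
    sp <- file.path(out, "pca_scores.tsv")
    utils::write.table(data.frame(sample = rownames(pca$scores),
                                  pca$scores[, 1:min(5, ncol(pca$scores))]),
                       sp, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(var_frac = round(pca$var_frac[1:min(10, length(pca$var_frac))], 6),
           pc1_accuracy = sep$accuracy, intermediate = sep$intermediate),
      file.path(out, "pca_summary.json"), auto_unbox = TRUE
    )
    add_stage("pca", list(features = nrow(pca$loadings)),
              c(sp, file.path(out, "pca_summary.json")))
  }

  summary <- list(
    n_samples = ncol(counts$counts),
    n_annotated = nrow(counts$counts),
    retained_after_filter = length(keep),
    de_per_comparison = lapply(de$results, function(d) {
      sum(d$FDR <= cfg$fdr_threshold)
    }),
    union_size = length(de$union),
    no_discoveries = length(de$union) == 0,
    pca_var_frac = if (!is.null(pca)) {
      round(pca$var_frac[1:min(5, length(pca$var_frac))], 4)
    } else NULL
  )
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(counts = counts, detection = det, filtered = filtered,
                 factors = factors, logcpm = logcpm, de = de, corr = corr,
                 pca = pca, separation = sep, truth = truth,
                 summary = summary, manifest = manifest))
}
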