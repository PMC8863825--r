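#' Simulation design for a three-group circulating-miRNA cohort
#'
#' Describes everything the synthetic-data generator needs: cohort layout
#' (three groups of unequal size, defaulting to the 38/36/84 healthy-active /
#' healthy-sedentary / sedentary-at-risk structure), the negative-binomial
#' count model (baseline abundances, dispersion, library sizes), the injected
#' differential-expression structure, the phenotype model, and the read-level
#' parameters (adapter, per-base error rate).
#'
#' Differential expression is injected as two biologically motivated blocks
#' plus unstructured DE: a "risk block" (default 13 mature miRNAs) shifted up
#' in the third (at-risk) group and a "health block" (default 6) shifted up in
#' the first (active) group, mirroring the correlated blocks seen in serum
#' miRNA profiles of sedentary at-risk versus active individuals. Remaining DE
#' miRNAs (up to `frac_de` of all miRNAs) are assigned a random shifted group
#' and sign.
#'
#' @param n_mirna Number of mature miRNAs (two per precursor; must be even).
#' @param group_sizes Integer vector of three group sizes, in order
#'   (active, sedentary, at-risk analogs).
#' @param group_labels Labels for the three groups.
#' @param frac_de Fraction of miRNAs differentially expressed (includes the
#'   two blocks).
#' @param logfc_magnitude Absolute log2 fold-change given to DE miRNAs.
#' @param dispersion Negative-binomial dispersion phi (Var = mu + phi mu^2);
#'   0 gives Poisson counts.
#' @param lib_size_range Min/max expected reads per sample.
#' @param baseline_logmean_range Range of log2-scale relative expression from
#'   which baseline abundances are drawn.
#' @param risk_block_size,health_block_size Sizes of the two planted blocks.
#' @param shared_mature_frac Fraction of mature sequences duplicated across
#'   two precursors, to create genuine multi-mappers.
#' @param n_pheno Number of phenotype variables (<= 28; named after standard
#'   cardiovascular-cohort parameters).
#' @param pheno_beta Weight of the miRNA latent-abundance term in the
#'   phenotype model.
#' @param pheno_group_alpha Weight of the group effect in the phenotype model.
#' @param pheno_noise_sd Standard deviation of phenotype noise.
#' @param error_rate Per-base substitution probability in simulated reads.
#' @param adapter 3' adapter sequence appended to each read.
#' @param read_length Sequencer read length; mature + adapter is truncated to
#'   this many bases.
#' @param seed Integer RNG seed; fixing it makes every generator output
#'   byte-identical across runs.
#'
#' @return An object of class `sim_design` (a validated list).
#' @export
#' @examples
#' d <- sim_design(n_mirna = 50, group_sizes = c(4, 4, 6), seed = 1)
#' d$group_sizes
sim_design <- function(n_mirna = 300L,
                       group_sizes = c(38L, 36L, 84L),
                       group_labels = c("HA", "HS", "SR"),
                       frac_de = 0.1,
                       logfc_magnitude = 2,
                       dispersion = 0.1,
                       lib_size_range = c(1.5e5, 2.5e5),
                       baseline_logmean_range = c(-4, 10),
                       risk_block_size = 13L,
                       health_block_size = 6L,
                       shared_mature_frac = 0.05,
                       n_pheno = 28L,
                       pheno_beta = 0.7,
                       pheno_group_alpha = 0.7,
                       pheno_noise_sd = 0.5,
                       error_rate = 0.001,
                       adapter = "AACTGTAGGCACCATCAAT",
                       read_length = 76L,
                       seed = 1L) {
  n_mirna <- as.integer(n_mirna)
  group_sizes <- as.integer(group_sizes)
  stopifnot(
    length(group_sizes) == 3L, all(group_sizes >= 2L),
    length(group_labels) == 3L, !anyDuplicated(group_labels),
    n_mirna >= 2L, n_mirna %% 2L == 0L,
    frac_de >= 0, frac_de <= 1,
    dispersion >= 0,
    length(lib_size_range) == 2L, lib_size_range[1] > 0,
    lib_size_range[1] <= lib_size_range[2],
    error_rate >= 0, error_rate < 0.25,
    nchar(adapter) >= 10L,
    shared_mature_frac >= 0, shared_mature_frac < 1,
    n_pheno >= 1L, n_pheno <= length(.pheno_catalog$name),
    read_length >= 20L
  )
  adapter <- toupper(adapter)
  if (grepl("[^ACGT]", adapter)) {
    stop("adapter must be an ACGT string")
  }
  n_de_cap <- floor(frac_de * n_mirna)
  if (risk_block_size + health_block_size > n_de_cap && frac_de > 0) {
    stop("risk_block_size + health_block_size exceeds frac_de * n_mirna")
  }
  if (frac_de == 0) {
    risk_block_size <- health_block_size <- 0L
  }
  design <- list(
    n_mirna = n_mirna,
    n_precursor = n_mirna %/% 2L,
    group_sizes = group_sizes,
    group_labels = group_labels,
    frac_de = frac_de,
    logfc_magnitude = logfc_magnitude,
    dispersion = dispersion,
    lib_size_range = lib_size_range,
    baseline_logmean_range = baseline_logmean_range,
    risk_block_size = as.integer(risk_block_size),
    health_block_size = as.integer(health_block_size),
    shared_mature_frac = shared_mature_frac,
    n_pheno = as.integer(n_pheno),
    pheno_beta = pheno_beta,
    pheno_group_alpha = pheno_group_alpha,
    pheno_noise_sd = pheno_noise_sd,
    error_rate = error_rate,
    adapter = adapter,
    read_length = as.integer(read_length),
    seed = as.integer(seed)
  )
  class(design) <- "sim_design"
  design
}

#' @export
print.sim_design <- function(x, ...) {
  cat("sim_design:", x$n_mirna, "mature miRNAs /", x$n_precursor,
      "precursors\n")
  cat("  groups:", paste(sprintf("%s(n=%d)", x$group_labels, x$group_sizes),
                         collapse = " "), "\n")
  cat(sprintf("  DE: frac %.2f at |log2FC| %.1f (risk block %d, health block %d)\n",
              x$frac_de, x$logfc_magnitude, x$risk_block_size,
              x$health_block_size))
  cat(sprintf("  NB dispersion %.3f, library sizes %g-%g, seed %d\n",
              x$dispersion, x$lib_size_range[1], x$lib_size_range[2], x$seed))
  invisible(x)
}

# Phenotype catalog: names, affine output scaling (cohort-typical mean/SD),
# and the association class. class "risk": higher in the at-risk group and
# positively coupled to risk-block miRNAs; class "fitness": higher in the
# active group and positively coupled to health-block miRNAs; class "neutral":
# no planted structure.
.pheno_catalog <- data.frame(
  name = c("fat", "bmi", "hipcirc", "hscrp", "waistcirc", "sys_24h",
           "dia_24h", "pwv", "ldl", "tnf_alpha", "crve", "pwv_24h", "crae",
           "acc_active", "acc_steps", "acc_walking", "acc_distance",
           "acc_sportive", "iop", "il6", "il10", "avr", "hdl", "vo2peak",
           "triglyceride", "glucose", "weight", "muscle_mass"),
  mean = c(26, 28, 100, 2.5, 98, 125, 78, 7.8, 3.1, 1.2, 212, 8.5, 173,
           10500, 10000, 118, 6600, 2, 16, 1.7, 0.11, 0.82, 1.6, 31,
           1.4, 5.2, 81, 29),
  sd = c(11, 5.5, 12, 3.2, 15, 10, 7, 1.5, 0.8, 1.6, 16, 1.1, 13,
         4100, 4300, 48, 3000, 6, 3, 2.2, 0.25, 0.06, 0.45, 8.5,
         0.9, 1.3, 16, 6),
  class = c("risk", "risk", "risk", "risk", "risk", "risk",
            "risk", "risk", "neutral", "neutral", "risk", "neutral", "fitness",
            "neutral", "fitness", "fitness", "fitness",
            "fitness", "neutral", "fitness", "neutral", "fitness", "fitness",
            "fitness", "risk", "risk", "risk", "neutral"),
  stringsAsFactors = FALSE
)

#' Planted miRNA-phenotype association signs for a design
#'
#' Enumerates every (mature miRNA, phenotype, sign) triple the generator
#' plants: risk-block miRNAs correlate positively with risk-class parameters
#' and negatively with fitness-class parameters; health-block miRNAs have the
#' opposite signs. Only the signs are ground truth (the downstream check is
#' rank-based).
#'
#' @param design A [sim_design()].
#' @return Data frame with columns `mirna` (index into mature miRNAs, filled
#'   in once the reference names are known), `pheno`, `sign`.
#' @export
pheno_assoc_table <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  cat_used <- .pheno_catalog[seq_len(design$n_pheno), ]
  risk_ph <- cat_used$name[cat_used$class == "risk"]
  fit_ph <- cat_used$name[cat_used$class == "fitness"]
  blocks <- list(
    list(idx = seq_len(design$risk_block_size), up = risk_ph, down = fit_ph),
    list(idx = design$risk_block_size + seq_len(design$health_block_size),
         up = fit_ph, down = risk_ph)
  )
  out <- do.call(rbind, lapply(blocks, function(b) {
    if (length(b$idx) == 0L) return(NULL)
    rbind(
      expand.grid(mirna_index = b$idx, pheno = b$up, sign = 1L,
                  stringsAsFactors = FALSE),
      expand.grid(mirna_index = b$idx, pheno = b$down, sign = -1L,
                  stringsAsFactors = FALSE)
    )
  }))
  if (is.null(out)) {
    out <- data.frame(mirna_index = integer(), pheno = character(),
                      sign = integer(), stringsAsFactors = FALSE)
  }
  out
}
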