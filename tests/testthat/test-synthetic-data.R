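test_that("design validation rejects impossible cohorts", {
  expect_error(sim_design(group_sizes = c(1, 4, 4)), "group_sizes")
  expect_error(sim_design(error_rate = 0.3), "error_rate")
  expect_error(sim_design(adapter = "ACGTACGT"), "adapter")
  expect_error(sim_design(n_mirna = 10, frac_de = 0.1,
                          risk_block_size = 13, health_block_size = 6),
               "exceeds")
})

test_that("reference has the declared record counts and shared matures", {
  d <- small_design(n_mirna = 20, shared_mature_frac = 0)
  ps <- generate_reference(d)
  expect_equal(nrow(ps$precursors), 10)
  expect_equal(nrow(ps$matures), 20)
  fa <- tempfile(fileext = ".fa")
  gff <- tempfile(fileext = ".gff3")
  write_precursor_fasta(ps, fa)
  write_precursor_gff3(ps, gff)
  expect_equal(sum(grepl("^>", readLines(fa))), 10)
  gl <- readLines(gff)
  expect_equal(sum(!grepl("^#", gl)), 30)  # 10 precursors + 20 matures
  expect_equal(sum(grepl("miRNA_primary_transcript", gl)), 10)

  d2 <- small_design(n_mirna = 20, shared_mature_frac = 0.2)
  ps2 <- generate_reference(d2)
  dup <- table(ps2$matures$sequence)
  expect_equal(sum(dup == 2), 2)  # 0.2 x 10 precursors
})

test_that("mature arms respect the half rule by construction", {
  ps <- generate_reference(small_design())
  plen <- ps$precursors$length[match(ps$matures$precursor_id,
                                     ps$precursors$id)]
  mid0 <- (ps$matures$start - 1 + ps$matures$end - 1) / 2
  expect_true(all(mid0[ps$matures$arm == "5p"] <= plen[ps$matures$arm == "5p"] / 2))
  expect_true(all(mid0[ps$matures$arm == "3p"] > plen[ps$matures$arm == "3p"] / 2))
})

test_that("reference writing is byte-deterministic and round-trips", {
  d <- small_design(seed = 3)
  f1 <- tempfile(); f2 <- tempfile(); g1 <- tempfile(); g2 <- tempfile()
  write_precursor_fasta(generate_reference(d), f1)
  write_precursor_gff3(generate_reference(d), g1)
  write_precursor_fasta(generate_reference(d), f2)
  write_precursor_gff3(generate_reference(d), g2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_identical(unname(tools::md5sum(g1)), unname(tools::md5sum(g2)))
  ps <- generate_reference(d)
  rt <- read_precursor_set(f1, g1)
  expect_equal(rt$precursors$sequence, ps$precursors$sequence)
  expect_equal(rt$matures[, c("id", "precursor_id", "start", "end", "arm")],
               ps$matures[, c("id", "precursor_id", "start", "end", "arm")])
})

test_that("duplicate identifiers are rejected", {
  p <- data.frame(id = c("a", "a"), sequence = c("ACGTACGTAA", "ACGTACGTAA"))
  m <- data.frame(id = c("a-5p", "a-3p"), precursor_id = "a",
                  start = c(1, 6), end = c(4, 10), arm = c("5p", "3p"))
  expect_error(precursor_set(p, m), "duplicate precursor")
})

test_that("zero-effect design yields no injected DE", {
  d <- small_design(frac_de = 0, risk_block_size = 0, health_block_size = 0)
  sim <- simulate_counts(d, generate_reference(d))
  expect_true(all(sim$truth$true_logfc == 0))
  expect_false(any(sim$truth$de_flags))
})

test_that("de_flags are true exactly where |true logFC| > 0", {
  d <- small_design(seed = 8)
  sim <- simulate_counts(d, generate_reference(d))
  expect_identical(sim$truth$de_flags, abs(sim$truth$true_logfc) > 0)
})

test_that("phi = 0 counts are Poisson (variance/mean ~ 1 vs oracle)", {
  d <- sim_design(n_mirna = 5000, group_sizes = c(12, 12, 12), frac_de = 0,
                  risk_block_size = 0, health_block_size = 0, dispersion = 0,
                  lib_size_range = c(1e5, 1e5), shared_mature_frac = 0,
                  seed = 4)
  sim <- simulate_counts(d, generate_reference(d))
  y <- sim$truth$true_counts
  g1 <- sim$samples$group == d$group_labels[1]
  m <- rowMeans(y[, g1]); v <- apply(y[, g1], 1, var)
  keep <- m > 1
  ratio <- mean(v[keep] / m[keep])
  # independent oracle: same-size Poisson simulation
  set.seed(99)
  yo <- matrix(rpois(sum(keep) * sum(g1), lambda = rep(m[keep], sum(g1))),
               ncol = sum(g1))
  mo <- rowMeans(yo); vo <- apply(yo, 1, var)
  oracle <- mean(vo / mo)
  expect_lt(abs(ratio - 1), 0.05)
  expect_lt(abs(ratio - oracle), 0.07)
})

test_that("strong planted association yields positive Spearman in >= 95% of replicates", {
  hits <- 0
  for (s in 1:100) {
    d <- small_design(seed = 100 + s, pheno_beta = 2, pheno_noise_sd = 0.1,
                      risk_block_size = 1, health_block_size = 0)
    sim <- simulate_counts(d, generate_reference(d))
    ps1 <- sim$truth$pheno_signs
    pair <- ps1[ps1$sign == 1, ][1, ]
    rho <- suppressWarnings(cor(
      log2(sim$truth$true_counts[pair$mirna, ] + 1),
      sim$pheno[[pair$pheno]], method = "spearman"))
    if (!is.na(rho) && rho > 0) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("FASTQ output conserves reads and is seed-deterministic", {
  d <- small_design(seed = 5)
  ps <- generate_reference(d)
  sim <- simulate_counts(d, ps)
  dir1 <- file.path(tempdir(), "fq_det1")
  dir2 <- file.path(tempdir(), "fq_det2")
  p1 <- write_fastq(sim$truth, ps, d, dir1)
  p2 <- write_fastq(sim$truth, ps, d, dir2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  n_reads <- vapply(p1, function(f) {
    length(readLines(f)) / 4L
  }, numeric(1))
  expect_equal(unname(n_reads), unname(as.numeric(sim$truth$lib_sizes)))
})

test_that("error-free reads are mature + adapter; error rate matches the binomial closed form", {
  d <- small_design(n_mirna = 8, group_sizes = c(2, 2, 2), frac_de = 0,
                    risk_block_size = 0, health_block_size = 0,
                    shared_mature_frac = 0, lib_size_range = c(5e4, 5e4),
                    error_rate = 0.01, seed = 21)
  ps <- generate_reference(d)
  sim <- simulate_counts(d, ps)
  fqd <- file.path(tempdir(), "fq_err")
  paths <- write_fastq(sim$truth, ps, d, fqd)
  reads <- Biostrings::readDNAStringSet(paths[1], format = "fastq")
  expected <- substr(paste0(ps$matures$sequence, d$adapter), 1,
                     d$read_length)
  truthv <- rep(expected, sim$truth$true_counts[, 1])
  expect_equal(length(reads), length(truthv))
  obs <- as.character(reads)
  nerr <- mapply(function(a, b) {
    sum(utf8ToInt(a) != utf8ToInt(b))
  }, obs, truthv)
  lens <- nchar(truthv)
  frac_hit <- mean(nerr >= 1)
  frac_expected <- mean(1 - (1 - d$error_rate)^lens)
  expect_lt(abs(frac_hit - frac_expected), 0.01)
})
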