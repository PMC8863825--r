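adapter <- "AACTGTAGGCACCATCAAT"

test_that("adapter trimming keeps inserts and applies the 15-nt floor", {
  insert22 <- "ACGTACGTACGTACGTACGTAC"
  insert14 <- "ACGTACGTACGTAC"
  tr <- trim_and_filter(c(paste0(insert22, adapter),
                          paste0(insert14, adapter),
                          insert22), adapter)
  expect_equal(tr$kept, c(insert22, insert22))  # no-adapter read kept whole
  expect_equal(tr$stats$discarded_short, 1)
  expect_equal(tr$stats$adapter_hit, 2)
})

test_that("partial terminal adapter and mismatched adapter are trimmed", {
  insert <- "TTGGCCAATTGGCCAATTGGCC"
  # only the first 12 adapter bases fit before the read ends
  r1 <- substr(paste0(insert, adapter), 1, nchar(insert) + 12)
  expect_equal(trim_and_filter(r1, adapter)$kept, insert)
  # one substitution inside a full adapter (tolerated at 10% of 19)
  ad_mut <- paste0(substr(adapter, 1, 5), "T", substr(adapter, 7, 19))
  expect_equal(trim_and_filter(paste0(insert, ad_mut), adapter)$kept, insert)
  # overlap below min_overlap is ignored
  r3 <- substr(paste0(insert, adapter), 1, nchar(insert) + 5)
  expect_equal(trim_and_filter(r3, adapter)$kept, r3)
})

test_that("collapsing counts distinct sequences and conserves reads", {
  s22a <- strrep("A", 22); s22c <- strrep("C", 22)
  out <- collapse_reads(c(s22a, s22a, s22c))
  expect_equal(nrow(out), 2)
  expect_equal(sum(out$multiplicity), 3)
  expect_equal(out$multiplicity[out$sequence == s22a], 2)
  expect_equal(nrow(collapse_reads(character(0))), 0)
  big <- collapse_reads(rep(s22a, 1e4))
  expect_equal(big$multiplicity, 1e4)
})

test_that("mapper agrees with a brute-force Hamming scan", {
  d <- sim_design(n_mirna = 100, group_sizes = c(2, 2, 2),
                  frac_de = 0.1, risk_block_size = 2, health_block_size = 1,
                  shared_mature_frac = 0.1, seed = 13)
  ps <- generate_reference(d)
  set.seed(17)
  reads <- c(
    sample(ps$matures$sequence, 20),
    vapply(sample(ps$matures$sequence, 20), function(s) {
      p <- sample.int(nchar(s), 1)
      paste0(substr(s, 1, p - 1),
             sample(setdiff(c("A", "C", "G", "T"), substr(s, p, p)), 1),
             substr(s, p + 1, nchar(s)))
    }, character(1)),
    vapply(1:10, function(i) {
      paste(sample(c("A", "C", "G", "T"), 22, TRUE), collapse = "")
    }, character(1))
  )
  coll <- collapse_reads(reads)
  aln <- map_reads(coll, ps, max_mismatches = 1)
  for (i in seq_len(nrow(coll))) {
    ora <- brute_force_map(coll$sequence[i], ps, 1)
    got <- aln[aln$read == i, c("precursor_id", "start", "mismatches")]
    got <- got[order(got$precursor_id, got$start), , drop = FALSE]
    rownames(got) <- rownames(ora) <- NULL
    expect_equal(got, ora)
    if (nrow(ora)) {
      expect_equal(unique(aln$n_loci[aln$read == i]), nrow(ora))
    }
  }
})

test_that("reads beyond the mismatch budget and N-heavy reads are unmapped", {
  ps <- generate_reference(small_design(shared_mature_frac = 0))
  s <- ps$matures$sequence[1]
  mut2 <- paste0("GG", substr(s, 3, nchar(s)))
  if (substr(s, 1, 2) == "GG") mut2 <- paste0("CC", substr(s, 3, nchar(s)))
  coll <- collapse_reads(c(mut2, gsub("[ACGT]", "N", s)))
  aln <- map_reads(coll, ps, max_mismatches = 1)
  expect_equal(nrow(aln), 0)
})

test_that("arm assignment follows the midpoint half rule with ties to 5p", {
  p <- data.frame(id = "p1", sequence = strrep("A", 60))
  m <- data.frame(id = c("p1-5p", "p1-3p"), precursor_id = "p1",
                  start = c(1, 40), end = c(22, 60), arm = c("5p", "3p"))
  ps <- precursor_set(p, m)
  # 0-based offsets 4-25, 36-57, 19-40 (1-based starts 5, 37, 20)
  aln <- data.frame(precursor_id = "p1", start = c(5, 37, 20),
                    end = c(26, 58, 41))
  expect_equal(assign_arm(aln, ps), c("5p", "3p", "5p"))
  # exact tie: offsets 19-41 -> midpoint 30 == L/2 -> 5p
  tie <- data.frame(precursor_id = "p1", start = 20, end = 42)
  expect_equal(assign_arm(tie, ps), "5p")
})

test_that("fractional counting splits multi-mappers and conserves multiplicity", {
  d <- small_design(n_mirna = 20, shared_mature_frac = 0.2)
  ps <- generate_reference(d)
  dup_seq <- names(which(table(ps$matures$sequence) == 2))[1]
  coll <- data.frame(sequence = dup_seq, multiplicity = 10L)
  aln <- map_reads(coll, ps)
  expect_equal(nrow(aln), 2)
  expect_equal(unique(aln$n_loci), 2)
  counts <- count_fractional(aln, ps)
  expect_equal(sum(counts), 10)
  expect_equal(unname(counts[counts > 0]), c(5, 5))
  # N = 1 identity
  uniq <- setdiff(ps$matures$sequence, dup_seq)[1]
  c1 <- count_fractional(map_reads(
    data.frame(sequence = uniq, multiplicity = 1L), ps), ps)
  expect_equal(sum(c1), 1)
})

test_that("counting aborts on an unknown precursor id", {
  ps <- generate_reference(small_design())
  aln <- data.frame(precursor_id = "nope", start = 1, end = 20,
                    multiplicity = 1, weight = 1, n_loci = 1)
  expect_error(count_fractional(aln, ps), "unknown precursor")
})

test_that("error-free round trip recovers the ground-truth counts exactly", {
  d <- small_design(seed = 31)
  ps <- generate_reference(d)
  sim <- simulate_counts(d, ps)
  fqd <- file.path(tempdir(), "fq_rt")
  write_fastq(sim$truth, ps, d, fqd)
  q <- quantify_samples(fqd, ps, adapter = d$adapter,
                        groups = sim$samples$group)
  expect_equal(q$counts[rownames(sim$truth$expected_counts), ],
               sim$truth$expected_counts, tolerance = 0)
  qc <- attr(q, "qc")[[1]]
  expect_equal(qc$mapped_reads, qc$reads_in)
})

test_that("count matrix is invariant to read order", {
  d <- small_design(n_mirna = 16, seed = 9)
  ps <- generate_reference(d)
  set.seed(3)
  reads <- sample(rep(ps$matures$sequence, sample(1:5, 16, TRUE)))
  c1 <- count_fractional(map_reads(collapse_reads(reads), ps), ps)
  c2 <- count_fractional(map_reads(collapse_reads(rev(reads)), ps), ps)
  expect_identical(c1, c2)
})
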