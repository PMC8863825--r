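# small simulation designs and independent oracles shared across tests

small_design <- function(seed = 1, ...) {
  args <- list(
    n_mirna = 40L, group_sizes = c(4L, 4L, 6L), frac_de = 0.2,
    risk_block_size = 2L, health_block_size = 1L,
    lib_size_range = c(2e4, 3e4), error_rate = 0, seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(sim_design, args)
}

# brute-force Hamming-distance scan over every offset of every precursor;
# independent of the package's seed-index mapper
brute_force_map <- function(read, ps, max_mismatches = 1L) {
  rint <- utf8ToInt(read)
  len <- length(rint)
  hits <- NULL
  for (p in seq_len(nrow(ps$precursors))) {
    pint <- utf8ToInt(ps$precursors$sequence[p])
    np <- length(pint) - len + 1L
    if (np < 1L) next
    for (st in seq_len(np)) {
      mm <- sum(rint != pint[st:(st + len - 1L)])
      if (mm <= max_mismatches) {
        hits <- rbind(hits, data.frame(precursor_id = ps$precursors$id[p],
                                       start = st, mismatches = mm))
      }
    }
  }
  if (is.null(hits)) {
    return(data.frame(precursor_id = character(0), start = integer(0),
                      mismatches = integer(0)))
  }
  best <- min(hits$mismatches)
  hits <- hits[hits$mismatches == best, , drop = FALSE]
  hits[order(hits$precursor_id, hits$start), , drop = FALSE]
}

# exhaustive conditional enumeration for the NB exact test, building the
# group-sum pmfs by brute-force convolution of per-sample NB pmfs (never via
# the closed-form NB sum the implementation uses)
conv_nb_sum_pmf <- function(n, mu, phi, smax) {
  single <- stats::dnbinom(0:smax, size = 1 / phi, mu = mu)
  pmf <- single
  for (i in seq_len(n - 1)) {
    pmf <- stats::convolve(pmf, rev(single), type = "open")[1:(smax + 1)]
  }
  pmf
}

oracle_exact_p <- function(s1, s2, n1, n2, phi) {
  s <- s1 + s2
  if (s == 0) return(1)
  mu <- s / (n1 + n2)
  p1 <- conv_nb_sum_pmf(n1, mu, phi, s)
  p2 <- conv_nb_sum_pmf(n2, mu, phi, s)
  k <- 0:s
  w <- p1[k + 1] * p2[s - k + 1]
  w <- w / sum(w)
  min(1, 2 * min(sum(w[k <= s1]), sum(w[k >= s1])))
}

# literal rank-transform Spearman, average ranks, pairwise complete
oracle_spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) return(NA_real_)
  stats::cor(rank(x[ok]), rank(y[ok]))
}
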