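#' Remove 3' adapter sequences and length-filter reads
#'
#' Finds, per read, the leftmost occurrence of the adapter — either the full
#' adapter anywhere in the read (tolerating `mismatch_frac` of its length as
#' substitutions) or an adapter prefix of at least `min_overlap` bases at the
#' read's 3' end (tolerating `mismatch_frac` of the overlap) — and keeps the
#' bases before it. Reads without any adapter hit are retained full-length
#' (the insert may fill the read). Trimmed reads shorter than `min_len`
#' bases are discarded.
#'
#' @param reads Character vector or [Biostrings::DNAStringSet] of raw reads.
#' @param adapter 3' adapter sequence (ACGT).
#' @param min_len Minimum insert length retained (default 15).
#' @param min_overlap Minimum adapter-prefix overlap recognised at the read
#'   end (default 10).
#' @param mismatch_frac Tolerated mismatch fraction of the matched adapter
#'   stretch (default 0.1).
#' @return List: `kept` (character vector of trimmed inserts, >= `min_len`),
#'   `stats` (reads in, with adapter hit, discarded short, kept).
#' @export
trim_and_filter <- function(reads, adapter, min_len = 15L, min_overlap = 10L,
                            mismatch_frac = 0.1) {
  stopifnot(nchar(adapter) >= 1)
  if (!methods::is(reads, "DNAStringSet")) {
    reads <- Biostrings::DNAStringSet(reads)
  }
  n <- length(reads)
  widths <- Biostrings::width(reads)
  cut <- widths + 1L  # first adapter base; default: no adapter found

  # full-adapter occurrences anywhere (leftmost)
  mm_full <- floor(mismatch_frac * nchar(adapter))
  hits <- Biostrings::vmatchPattern(adapter, reads, max.mismatch = mm_full,
                                    fixed = TRUE)
  st <- IRanges::start(hits)
  has <- lengths(st) > 0L
  cut[has] <- vapply(st[has], min, integer(1))

  # partial adapter prefix at the read end (overlap >= min_overlap)
  la <- nchar(adapter)
  max_r <- ifelse(seq_len(la) < min_overlap, -1,
                  floor(mismatch_frac * seq_len(la)))
  rng <- Biostrings::trimLRPatterns(Rpattern = adapter, subject = reads,
                                    max.Rmismatch = max_r, ranges = TRUE)
  cut <- pmin(cut, IRanges::end(rng) + 1L)

  trimmed <- substr(as.character(reads), 1L, cut - 1L)
  keep <- nchar(trimmed) >= min_len
  list(
    kept = trimmed[keep],
    stats = list(reads_in = n,
                 adapter_hit = sum(cut <= widths),
                 discarded_short = sum(!keep),
                 kept = sum(keep))
  )
}

#' Collapse identical read sequences
#'
#' @param seqs Character vector of (trimmed) read sequences.
#' @return Data frame with one row per distinct sequence: `sequence`,
#'   `multiplicity`; sorted by sequence so the output is order-invariant.
#'   Multiplicities sum to `length(seqs)`.
#' @export
collapse_reads <- function(seqs) {
  if (length(seqs) == 0L) {
    return(data.frame(sequence = character(0), multiplicity = integer(0),
                      stringsAsFactors = FALSE))
  }
  tab <- table(seqs)
  data.frame(sequence = names(tab), multiplicity = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Map collapsed reads end-to-end onto precursor sequences
#'
#' Every substitution-only, end-to-end alignment of each read against the
#' precursor set with at most `max_mismatches` mismatches is found (sense
#' strand only; small-RNA libraries are stranded). For each read, only
#' alignments in its minimal-mismatch stratum are retained; `n_loci` is the
#' number of retained (precursor, offset) sites and each carries weight
#' `1/n_loci` downstream. Reads with more than 10% ambiguous (N) bases are
#' unmapped; other N bases count as mismatches.
#'
#' @param collapsed Data frame from [collapse_reads()].
#' @param ps A `precursor_set`.
#' @param max_mismatches Maximum substitutions allowed (default 1).
#' @return Data frame of alignments: `read` (row index into `collapsed`),
#'   `sequence`, `multiplicity`, `precursor_id`, `start`, `end` (1-based
#'   inclusive on the precursor), `mismatches`, `n_loci`, `weight`.
#' @export
map_reads <- function(collapsed, ps, max_mismatches = 1L) {
  idx <- .seed_index(ps, k = 7L)
  pseq_int <- lapply(ps$precursors$sequence, utf8ToInt)
  plen <- ps$precursors$length
  out <- vector("list", nrow(collapsed))
  frac_n <- ifelse(nchar(collapsed$sequence) > 0,
                   nchar(gsub("[^N]", "", collapsed$sequence)) /
                     nchar(collapsed$sequence), 1)
  for (i in seq_len(nrow(collapsed))) {
    if (frac_n[i] > 0.1) next
    pat <- collapsed$sequence[i]
    len <- nchar(pat)
    cand <- .seed_candidates(pat, len, idx, plen, max_mismatches)
    if (nrow(cand) == 0L) next
    # verify candidates end-to-end (N counts as a mismatch)
    rint <- utf8ToInt(pat)
    mm <- vapply(seq_len(nrow(cand)), function(r) {
      p <- pseq_int[[cand$prec[r]]]
      sum(rint != p[cand$start[r]:(cand$start[r] + len - 1L)])
    }, integer(1))
    best <- min(mm)
    if (best > max_mismatches) next
    keep <- mm == best
    nh <- sum(keep)
    out[[i]] <- data.frame(
      read = i,
      sequence = pat,
      multiplicity = collapsed$multiplicity[i],
      precursor_id = ps$precursors$id[cand$prec[keep]],
      start = cand$start[keep],
      end = cand$start[keep] + len - 1L,
      mismatches = best,
      n_loci = nh,
      weight = 1 / nh,
      stringsAsFactors = FALSE
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(read = integer(0), sequence = character(0),
                      multiplicity = integer(0), precursor_id = character(0),
                      start = integer(0), end = integer(0),
                      mismatches = integer(0), n_loci = integer(0),
                      weight = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# hash of every k-mer in the precursor set -> (precursor index, 1-based pos)
.seed_index <- function(ps, k = 7L) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (p in seq_len(nrow(ps$precursors))) {
    s <- ps$precursors$sequence[p]
    np <- nchar(s) - k + 1L
    if (np < 1L) next
    kmers <- substring(s, seq_len(np), seq_len(np) + k - 1L)
    for (j in seq_len(np)) {
      key <- kmers[j]
      env[[key]] <- rbind(env[[key]], c(p, j))
    }
  }
  attr(env, "k") <- k
  env
}

# pigeonhole candidate (precursor, read start) pairs: split the read into
# max_mismatches + 1 segments; any alignment within the mismatch budget has
# one exact segment, whose leading k-mer is then an exact index hit. Reads
# too short for the segment scheme fall back to scanning every offset.
.seed_candidates <- function(pat, len, idx, plen, max_mismatches) {
  k <- attr(idx, "k")
  ns <- max_mismatches + 1L
  prec <- integer(0)
  start <- integer(0)
  if (len >= k * ns) {
    seg_starts <- 1L + floor((seq_len(ns) - 1L) * len / ns)
    for (ss in seg_starts) {
      hit <- idx[[substr(pat, ss, ss + k - 1L)]]
      if (!is.null(hit)) {
        prec <- c(prec, hit[, 1])
        start <- c(start, hit[, 2] - (ss - 1L))
      }
    }
    ok <- start >= 1L & start + len - 1L <= plen[prec]
    cand <- unique(data.frame(prec = prec[ok], start = start[ok]))
  } else {
    cand <- do.call(rbind, lapply(seq_along(plen), function(p) {
      np <- plen[p] - len + 1L
      if (np < 1L) return(NULL)
      data.frame(prec = p, start = seq_len(np))
    }))
    if (is.null(cand)) {
      cand <- data.frame(prec = integer(0), start = integer(0))
    }
  }
  cand
}

#' Assign alignments to the 5p or 3p arm by the precursor-half rule
#'
#' The read midpoint on the precursor (0-based) decides the arm: in the first
#' half (midpoint <= L/2, ties to 5p) the read counts towards the 5p mature
#' miRNA, otherwise towards the 3p.
#'
#' @param alignments Data frame from [map_reads()] (needs `precursor_id`,
#'   `start`, `end`).
#' @param ps A `precursor_set`.
#' @return Character vector, "5p" or "3p" per alignment.
#' @export
assign_arm <- function(alignments, ps) {
  plen <- ps$precursors$length[match(alignments$precursor_id,
                                     ps$precursors$id)]
  if (anyNA(plen)) stop("alignment to unknown precursor id")
  mid0 <- (alignments$start - 1 + alignments$end - 1) / 2
  ifelse(mid0 <= plen / 2, "5p", "3p")
}

#' Count fractional read contributions into mature miRNA rows
#'
#' Each alignment adds `multiplicity / n_loci` to the mature miRNA given by
#' its precursor and half-rule arm. Annotated matures with no reads are zero.
#' The sum of one read's contributions over its loci equals its multiplicity
#' exactly.
#'
#' @param alignments Data frame from [map_reads()].
#' @param ps A `precursor_set`.
#' @return Named numeric vector over all annotated mature ids (one sample's
#'   count column). Arms without an annotated mature are reported as
#'   `<precursor>-<arm>`, appended after the annotated rows.
#' @export
count_fractional <- function(alignments, ps) {
  counts <- stats::setNames(numeric(nrow(ps$matures)), ps$matures$id)
  if (nrow(alignments) == 0L) return(counts)
  if (!all(alignments$precursor_id %in% ps$precursors$id)) {
    stop("alignment to unknown precursor id (corrupt annotation?)")
  }
  arm <- assign_arm(alignments, ps)
  key <- paste(alignments$precursor_id, arm)
  mkey <- paste(ps$matures$precursor_id, ps$matures$arm)
  id <- ps$matures$id[match(key, mkey)]
  missing <- is.na(id)
  id[missing] <- paste0(alignments$precursor_id[missing], "-", arm[missing])
  contrib <- alignments$multiplicity * alignments$weight
  agg <- rowsum(contrib, id)
  extra <- setdiff(rownames(agg), names(counts))
  if (length(extra)) {
    counts <- c(counts, stats::setNames(numeric(length(extra)), extra))
  }
  counts[rownames(agg)] <- agg[, 1]
  counts
}

#' Quantify one sample's FASTQ into a mature-miRNA count column
#'
#' Runs adapter trimming, the 15-nt length filter, collapsing, precursor
#' mapping and fractional 1/N counting for a single FASTQ file.
#'
#' @param fastq Path to a (gzipped) FASTQ file.
#' @param ps A `precursor_set`.
#' @param adapter 3' adapter sequence.
#' @param max_mismatches Mapper mismatch tolerance (default 1).
#' @param min_len Minimum insert length (default 15).
#' @return List: `counts` (named numeric vector over mature ids), `qc`
#'   (reads in/trimmed/discarded, unique sequences, mapped reads,
#'   multi-mapped fraction).
#' @export
quantify_sample <- function(fastq, ps, adapter, max_mismatches = 1L,
                            min_len = 15L) {
  raw <- Biostrings::readDNAStringSet(fastq, format = "fastq")
  # collapse before trimming: identical raw reads trim identically, so
  # trimming the unique raw sequences and carrying multiplicities through is
  # equivalent to (and much faster than) trimming every read
  raw_tab <- collapse_reads(as.character(raw))
  trimmed_all <- .trim_all(raw_tab$sequence, adapter, min_len)
  ok <- !is.na(trimmed_all)
  collapsed <- stats::aggregate(
    list(multiplicity = raw_tab$multiplicity[ok]),
    by = list(sequence = trimmed_all[ok]), FUN = sum
  )
  collapsed <- collapsed[order(collapsed$sequence),
                         c("sequence", "multiplicity")]
  rownames(collapsed) <- NULL
  aln <- map_reads(collapsed, ps, max_mismatches = max_mismatches)
  counts <- count_fractional(aln, ps)
  mapped_mult <- sum(collapsed$multiplicity[unique(aln$read)])
  multi <- aln[aln$n_loci > 1, , drop = FALSE]
  qc <- list(
    reads_in = length(raw),
    kept_after_trim = sum(collapsed$multiplicity),
    discarded_short = length(raw) - sum(collapsed$multiplicity),
    unique_sequences = nrow(collapsed),
    mapped_reads = mapped_mult,
    multi_mapped_fraction = if (mapped_mult > 0) {
      sum(multi$multiplicity[!duplicated(multi$read)]) / mapped_mult
    } else 0
  )
  list(counts = counts, qc = qc)
}

# trim a vector of unique raw sequences; NA where discarded (< min_len)
.trim_all <- function(seqs, adapter, min_len) {
  tr <- trim_and_filter(seqs, adapter, min_len = 0L)
  out <- tr$kept
  out[nchar(out) < min_len] <- NA_character_
  out
}

#' Quantify a set of FASTQ files into a count matrix
#'
#' @param fastq_files Named character vector (names = sample ids) of FASTQ
#'   paths, or a directory containing `<sample>.fastq.gz` files.
#' @param ps A `precursor_set`.
#' @param adapter 3' adapter sequence.
#' @param groups Optional vector of group labels per sample (same order).
#' @param max_mismatches Mapper mismatch tolerance.
#' @return A [mir_counts()] object; per-sample QC in `attr(,"qc")`.
#' @export
quantify_samples <- function(fastq_files, ps, adapter, groups = NULL,
                             max_mismatches = 1L) {
  if (length(fastq_files) == 1L && dir.exists(fastq_files)) {
    paths <- list.files(fastq_files, pattern = "\\.f(ast)?q(\\.gz)?$",
                        full.names = TRUE)
    names(paths) <- sub("\\.f(ast)?q(\\.gz)?$", "", basename(paths))
    fastq_files <- paths[order(names(paths))]
  }
  stopifnot(length(fastq_files) > 0, !is.null(names(fastq_files)))
  res <- lapply(fastq_files, quantify_sample, ps = ps, adapter = adapter,
                max_mismatches = max_mismatches)
  ids <- unique(unlist(lapply(res, function(r) names(r$counts))))
  mat <- matrix(0, length(ids), length(res),
                dimnames = list(ids, names(fastq_files)))
  for (j in seq_along(res)) {
    mat[names(res[[j]]$counts), j] <- res[[j]]$counts
  }
  out <- mir_counts(mat, groups = groups)
  attr(out, "qc") <- lapply(res, `[[`, "qc")
  out
}
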