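#' Generate a synthetic miRNA precursor reference
#'
#' Builds a precursor set in which each hairpin precursor is a random 5p
#' mature arm (20-24 nt), a loop (10-20 nt) and a 3p mature arm (20-24 nt).
#' With these length ranges the 5p arm always lies entirely in the first half
#' of the precursor and the 3p arm entirely in the second half, so the
#' half-rule arm assignment used downstream recovers the generating arm
#' exactly. A configurable fraction of mature sequences is duplicated across
#' two precursors to create genuine multi-mapping reads.
#'
#' @param design A [sim_design()]. Uses `n_precursor`, `shared_mature_frac`
#'   and `seed` (the reference is drawn from `set.seed(design$seed)`).
#' @return A `precursor_set`: list with `precursors` (id, sequence, length)
#'   and `matures` (id, precursor_id, start, end, arm, sequence; coordinates
#'   1-based inclusive within the precursor).
#' @export
#' @examples
#' ps <- generate_reference(sim_design(n_mirna = 20, group_sizes = c(2, 2, 2)))
#' nrow(ps$matures)  # 20 mature arms over 10 precursors
generate_reference <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(design$seed)
  np <- design$n_precursor
  bases <- c("A", "C", "G", "T")
  rand_seq <- function(len) {
    paste(sample(bases, len, replace = TRUE), collapse = "")
  }
  l5 <- sample(20:24, np, replace = TRUE)
  ll <- sample(10:20, np, replace = TRUE)
  l3 <- sample(20:24, np, replace = TRUE)
  seq5 <- vapply(l5, rand_seq, character(1))
  seql <- vapply(ll, rand_seq, character(1))
  seq3 <- vapply(l3, rand_seq, character(1))

  # duplicate some mature sequences across precursor pairs (1,2), (3,4), ...
  n_shared <- floor(design$shared_mature_frac * np + 1e-9)
  if (2L * n_shared > np) {
    stop("shared_mature_frac too large for the number of precursors")
  }
  shared_pairs <- if (n_shared > 0) {
    cbind(donor = seq(1L, by = 2L, length.out = n_shared),
          recipient = seq(2L, by = 2L, length.out = n_shared))
  } else {
    matrix(integer(0), ncol = 2, dimnames = list(NULL, c("donor", "recipient")))
  }
  for (i in seq_len(n_shared)) {
    d <- shared_pairs[i, "donor"]
    r <- shared_pairs[i, "recipient"]
    seq5[r] <- seq5[d]
    l5[r] <- l5[d]
  }

  pid <- sprintf("sim-mir-%04d", seq_len(np))
  prec_seq <- paste0(seq5, seql, seq3)
  plen <- l5 + ll + l3
  precursors <- data.frame(
    id = pid, sequence = prec_seq, length = plen, stringsAsFactors = FALSE
  )
  matures <- data.frame(
    id = c(paste0(pid, "-5p"), paste0(pid, "-3p")),
    precursor_id = c(pid, pid),
    start = c(rep(1L, np), l5 + ll + 1L),
    end = c(l5, plen),
    arm = rep(c("5p", "3p"), each = np),
    sequence = c(seq5, seq3),
    stringsAsFactors = FALSE
  )
  matures <- matures[order(matures$precursor_id, matures$arm == "3p"), ]
  rownames(matures) <- NULL
  ps <- precursor_set(precursors, matures)
  ps$shared_pairs <- shared_pairs
  ps
}

#' Construct and validate a precursor set
#'
#' @param precursors Data frame with columns id, sequence, length.
#' @param matures Data frame with columns id, precursor_id, start, end, arm,
#'   sequence (sequence may be NA and is filled in from the precursor).
#' @return A validated `precursor_set` object.
#' @export
precursor_set <- function(precursors, matures) {
  stopifnot(
    all(c("id", "sequence") %in% names(precursors)),
    all(c("id", "precursor_id", "start", "end", "arm") %in% names(matures))
  )
  precursors$length <- nchar(precursors$sequence)
  if (anyDuplicated(precursors$id)) {
    stop("duplicate precursor identifiers")
  }
  if (anyDuplicated(matures$id)) {
    stop("duplicate mature identifiers")
  }
  if (!all(matures$precursor_id %in% precursors$id)) {
    stop("mature arm references unknown precursor")
  }
  plen <- precursors$length[match(matures$precursor_id, precursors$id)]
  if (!all(matures$start >= 1L & matures$start <= matures$end &
           matures$end <= plen)) {
    stop("mature arm coordinates out of precursor bounds")
  }
  if (anyDuplicated(paste(matures$precursor_id, matures$arm))) {
    stop("more than one mature arm with the same label on a precursor")
  }
  if (is.null(matures$sequence) || anyNA(matures$sequence)) {
    matures$sequence <- substr(
      precursors$sequence[match(matures$precursor_id, precursors$id)],
      matures$start, matures$end
    )
  }
  structure(list(precursors = precursors, matures = matures),
            class = "precursor_set")
}

#' @export
print.precursor_set <- function(x, ...) {
  cat("precursor_set:", nrow(x$precursors), "precursors,",
      nrow(x$matures), "mature arms\n")
  invisible(x)
}

#' Write precursor sequences to FASTA
#'
#' @param ps A `precursor_set`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_precursor_fasta <- function(ps, path) {
  seqs <- Biostrings::DNAStringSet(ps$precursors$sequence)
  names(seqs) <- ps$precursors$id
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' Write precursor and mature annotations to a miRBase-dialect GFF3
#'
#' Precursors are emitted as `miRNA_primary_transcript` features and mature
#' arms as `miRNA` features with `Derives_from` pointing at the precursor.
#' Coordinates are 1-based inclusive in precursor space (the seqid is the
#' precursor id).
#'
#' @param ps A `precursor_set`.
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_precursor_gff3 <- function(ps, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  lines <- character(0)
  p <- ps$precursors
  m <- ps$matures
  for (i in seq_len(nrow(p))) {
    lines <- c(lines, sprintf(
      "%s\tmirflow\tmiRNA_primary_transcript\t1\t%d\t.\t+\t.\tID=%s;Name=%s",
      p$id[i], p$length[i], p$id[i], p$id[i]
    ))
    mi <- m[m$precursor_id == p$id[i], , drop = FALSE]
    lines <- c(lines, sprintf(
      "%s\tmirflow\tmiRNA\t%d\t%d\t.\t+\t.\tID=%s;Name=%s;Derives_from=%s",
      mi$precursor_id, mi$start, mi$end, mi$id, mi$id, mi$precursor_id
    ))
  }
  writeLines(c("##gff-version 3", lines), con)
  invisible(path)
}

#' Read a precursor reference from FASTA + GFF3
#'
#' @param fasta Precursor FASTA path.
#' @param gff miRBase-dialect GFF3 path (`miRNA_primary_transcript` and
#'   `miRNA` features; `ID`/`Name` attributes; mature arms are labelled 5p/3p
#'   from their `Name` suffix when present, otherwise by the half rule on
#'   their annotated midpoint).
#' @return A `precursor_set`.
#' @export
read_precursor_set <- function(fasta, gff) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gr <- rtracklayer::import(gff, format = "gff3")
  typ <- as.character(gr$type)
  ids <- as.character(gr$ID)
  nm <- if (!is.null(gr$Name)) as.character(gr$Name) else ids
  is_mat <- typ == "miRNA"
  precursors <- data.frame(
    id = ids[!is_mat],
    sequence = as.character(seqs[ids[!is_mat]]),
    stringsAsFactors = FALSE
  )
  precursors$length <- nchar(precursors$sequence)
  parent <- if (!is.null(gr$Derives_from)) {
    as.character(gr$Derives_from)
  } else {
    as.character(GenomicRanges::seqnames(gr))
  }
  mstart <- GenomicRanges::start(gr)[is_mat]
  mend <- GenomicRanges::end(gr)[is_mat]
  mpar <- parent[is_mat]
  arm <- ifelse(grepl("-5p$", nm[is_mat]), "5p",
                ifelse(grepl("-3p$", nm[is_mat]), "3p", NA_character_))
  if (anyNA(arm)) {
    plen <- precursors$length[match(mpar, precursors$id)]
    mid0 <- (mstart - 1 + mend - 1) / 2
    arm[is.na(arm)] <- ifelse(mid0[is.na(arm)] <= plen[is.na(arm)] / 2,
                              "5p", "3p")
  }
  matures <- data.frame(
    id = nm[is_mat], precursor_id = mpar,
    start = mstart, end = mend, arm = arm,
    sequence = NA_character_, stringsAsFactors = FALSE
  )
  precursor_set(precursors, matures)
}
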