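#' Specify an IUPAC consensus motif
#'
#' @param pattern IUPAC nucleotide string; default is the hypoxia-response
#'   element core `RCGTG` (R = A/G).
#' @param both_strands Also count matches of the reverse complement.
#' @return List of class `motif_spec`.
#' @export
motif_spec <- function(pattern = "RCGTG", both_strands = TRUE) {
  if (!nzchar(pattern)) stop("empty motif pattern")
  pattern <- toupper(pattern)
  letters_ok <- names(Biostrings::IUPAC_CODE_MAP)
  bad <- setdiff(strsplit(pattern, "")[[1L]], letters_ok)
  if (length(bad))
    stop("invalid IUPAC character(s) in motif: ", paste(bad, collapse = ""))
  structure(list(pattern = pattern, both_strands = both_strands),
            class = "motif_spec")
}

.scan_one <- function(subject, pattern) {
  # pattern ambiguities are interpreted; subject is literal, so N in the
  # sequence never matches a non-N motif symbol
  m <- Biostrings::matchPattern(pattern, subject, fixed = "subject")
  BiocGenerics::start(m) - 1L  # 0-based
}

#' Scan a sequence for an IUPAC motif
#'
#' Overlapping matches are counted. With `both_strands`, occurrences of the
#' reverse complement of the pattern on the given strand are added (i.e.
#' matches of the motif on the opposite strand).
#'
#' @param seq A character string, `DNAString`, or `DNAStringSet` element.
#' @param motif A [motif_spec()] (or a bare IUPAC string).
#' @return List with `count`, `positions` (0-based forward-strand match
#'   starts) and `rc_positions` (0-based starts of reverse-complement
#'   matches; `NULL` when single-stranded).
#' @export
scan_sequence <- function(seq, motif = motif_spec()) {
  if (is.character(motif)) motif <- motif_spec(motif)
  if (is.character(seq)) seq <- Biostrings::DNAString(toupper(seq))
  fwd <- .scan_one(seq, motif$pattern)
  rc <- NULL
  if (motif$both_strands) {
    rc_pat <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(motif$pattern)))
    rc <- .scan_one(seq, rc_pat)
    if (rc_pat == motif$pattern) rc <- integer(0)  # palindromic: count once
  }
  list(count = length(fwd) + length(rc), positions = fwd,
       rc_positions = rc)
}

.region_matches_per_kb <- function(peaks, genome, motif) {
  total <- 0L
  kb <- sum(peaks$end - peaks$start) / 1000
  for (ch in unique(peaks$chrom)) {
    seq <- genome$sequence[[ch]]
    if (is.null(seq)) stop("genome sequence missing for chromosome ", ch)
    sel <- which(peaks$chrom == ch)
    for (i in sel) {
      sub <- Biostrings::subseq(seq, peaks$start[i] + 1, peaks$end[i])
      total <- total + scan_sequence(sub, motif)$count
    }
  }
  list(matches = total, kb = kb, per_kb = total / kb)
}

#' Consensus-motif enrichment in bound regions versus the shuffle null
#'
#' Computes the motif density (matches per kb, overlapping matches counted,
#' both strands by default) over the peak intervals and over each shuffled
#' replicate; the empirical p-value is the add-one-corrected fraction of
#' replicates at least as dense as the observed set.
#'
#' @param peaks A [peak_set].
#' @param genome A [hif_genome] with sequence for every peak chromosome.
#' @param motif A [motif_spec()].
#' @param n_shuffles Number of shuffle replicates.
#' @param seed Optional seed for the shuffle.
#' @return List with `observed_per_kb`, `expected_per_kb` (mean over
#'   replicates), `ratio`, `empirical_p`, `n_matches`, `kb_scanned` and the
#'   per-replicate densities.
#' @export
motif_enrichment <- function(peaks, genome, motif = motif_spec(),
                             n_shuffles = 100, seed = NULL) {
  if (is.null(genome$sequence)) stop("genome has no sequence")
  obs <- .region_matches_per_kb(peaks, genome, motif)
  reps <- shuffle_intervals(peaks, genome, n_replicates = n_shuffles,
                            seed = seed)
  null_per_kb <- vapply(reps, function(p)
    .region_matches_per_kb(p, genome, motif)$per_kb, numeric(1))
  expected <- mean(null_per_kb)
  list(observed_per_kb = obs$per_kb, expected_per_kb = expected,
       ratio = if (expected > 0) obs$per_kb / expected else Inf,
       empirical_p = (1 + sum(null_per_kb >= obs$per_kb)) /
         (n_shuffles + 1),
       n_matches = obs$matches, kb_scanned = obs$kb,
       null_per_kb = null_per_kb)
}
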