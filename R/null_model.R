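# Seeded RNG scoping: run code with a temporary seed, restoring the caller's
# RNG state afterwards so pipelines stay reproducible end to end.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Randomly re-place intervals across the genome (shuffle null)
#'
#' Generates replicate peak sets in which every interval keeps its length but
#' is re-placed at random: the chromosome is drawn with probability
#' proportional to its length (among chromosomes long enough to hold the
#' interval) and the start uniformly on `[0, chrom_len - len]`. Shuffled
#' intervals may overlap each other. In `same-chromosome` mode each interval
#' stays on its original chromosome. Summit offsets are preserved relative to
#' the interval start.
#'
#' @param peaks A [peak_set].
#' @param genome A [hif_genome].
#' @param n_replicates Number of replicate sets (>= 1).
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @param mode `"genome-wide"` (default) or `"same-chromosome"`.
#' @return List of `n_replicates` [peak_set] objects.
#' @export
shuffle_intervals <- function(peaks, genome, n_replicates = 100, seed = NULL,
                              mode = c("genome-wide", "same-chromosome")) {
  mode <- match.arg(mode)
  stopifnot(n_replicates >= 1)
  len <- peaks$end - peaks$start
  if (any(len > max(genome$chroms)))
    stop("interval longer than every chromosome (max length ",
         max(genome$chroms), " bp)")
  chrom_names <- names(genome$chroms)
  chrom_len <- as.numeric(genome$chroms)
  .with_seed(seed, {
    lapply(seq_len(n_replicates), function(r) {
      if (mode == "genome-wide") {
        # lengths differ per peak only in which chromosomes can host them
        ci <- integer(nrow(peaks))
        for (l in unique(len)) {
          sel <- which(len == l)
          fits <- which(chrom_len >= l)
          ci[sel] <- sample(fits, length(sel), replace = TRUE,
                            prob = chrom_len[fits])
        }
      } else {
        ci <- match(peaks$chrom, chrom_names)
        if (anyNA(ci)) stop("peak chromosome absent from genome")
        if (any(len > chrom_len[ci]))
          stop("interval longer than its chromosome in same-chromosome mode")
      }
      start <- floor(stats::runif(nrow(peaks)) * (chrom_len[ci] - len + 1))
      peak_set(chrom_names[ci], start, start + len, name = peaks$name,
               score = peaks$score, strand = peaks$strand,
               summit_offset = peaks$summit_offset)
    })
  })
}

#' Annotate shuffle replicates
#'
#' Applies the same annotation as the observed peaks to every replicate.
#'
#' @param replicates List of [peak_set] from [shuffle_intervals()].
#' @inheritParams annotate_peaks
#' @return List of `hif_annotation` data.frames.
#' @export
annotate_replicates <- function(replicates, genes, atac = NULL,
                                promoter_window = PROMOTER_WINDOW,
                                mode = c("any", "summit")) {
  lapply(replicates, function(p)
    suppressMessages(annotate_peaks(p, genes, atac,
                                    promoter_window, mode)))
}

.count_by <- function(ann, what) {
  switch(what,
    distance = {
      ok <- !is.na(ann$distance_bin)
      table(ann$distance_bin[ok])
    },
    feature = table(ann$feature),
    open_chromatin = table(
      factor(ifelse(ann$open_chromatin, "open", "closed"),
             levels = c("open", "closed"))),
    distance_by_chromatin = .bin_open_counts(ann),
    stop("unknown category set: ", what))
}

#' Expected category counts under the shuffle null
#'
#' Annotates every replicate and averages the per-category counts. Supported
#' category sets: `distance` (TSS-distance bins), `feature`
#' (promoter/genebody/intergenic), `open_chromatin` and
#' `distance_by_chromatin` (the joint 8-cell classification).
#'
#' @param replicates List of [peak_set] or pre-annotated `hif_annotation`
#'   objects.
#' @param genes A [gene_table] (ignored when replicates are pre-annotated).
#' @param atac Optional open-chromatin regions.
#' @param what Category set to tabulate.
#' @return List with `expected` (named mean counts) and `per_replicate`
#'   (replicates x categories count matrix).
#' @export
expected_distribution <- function(replicates, genes = NULL, atac = NULL,
                                  what = c("distance", "feature",
                                           "open_chromatin",
                                           "distance_by_chromatin")) {
  what <- match.arg(what)
  if (!methods::is(replicates[[1L]], "hif_annotation")) {
    if (is.null(genes)) stop("genes required to annotate replicates")
    replicates <- annotate_replicates(replicates, genes, atac)
  }
  mat <- do.call(rbind, lapply(replicates, function(a)
    as.numeric(.count_by(a, what))))
  colnames(mat) <- names(.count_by(replicates[[1L]], what))
  list(expected = colMeans(mat), per_replicate = mat)
}

#' Relative percentage difference of observed vs expected
#'
#' `rpd = 100 * (observed - expected) / expected`.
#'
#' @param observed Observed count(s).
#' @param expected Expected count(s) under the null; must be positive.
#' @return Numeric, in percent.
#' @export
relative_percentage_difference <- function(observed, expected) {
  if (any(expected <= 0))
    stop("expected count is zero; increase n_replicates so every tested ",
         "category has positive expectation")
  100 * (observed - expected) / expected
}

#' Chi-square goodness-of-fit of observed counts against a null distribution
#'
#' Expected counts are rescaled to the observed total, so the test compares
#' shapes (`df = k - 1`) even when replicates drop unannotatable peaks.
#'
#' @param observed Named integer counts (>= 2 categories).
#' @param expected Expected counts (any positive scale).
#' @return List with `statistic`, `df` and `pvalue`.
#' @export
gof_chi_square <- function(observed, expected) {
  if (length(observed) != length(expected))
    stop("observed and expected must have equal length")
  if (length(observed) < 2L) stop("need at least 2 categories")
  if (any(expected <= 0)) stop("all expected counts must be positive")
  if (sum(observed) <= 0) stop("observed total must be positive")
  p <- expected / sum(expected)
  e <- p * sum(observed)
  stat <- sum((observed - e)^2 / e)
  df <- length(observed) - 1L
  list(statistic = stat, df = df,
       pvalue = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Bonferroni adjustment
#'
#' @param pvalues Numeric p-values in `[0, 1]`.
#' @param m Number of tests (defaults to `length(pvalues)`; may be larger).
#' @return `min(1, m * p)` per p-value, order preserved.
#' @export
bonferroni_adjust <- function(pvalues, m = length(pvalues)) {
  if (any(pvalues < 0 | pvalues > 1)) stop("p-value outside [0, 1]")
  if (m < length(pvalues)) stop("m must be >= number of p-values")
  stats::p.adjust(pvalues, method = "bonferroni", n = m)
}

#' Per-category enrichment against the shuffle null
#'
#' For each category: the relative percentage difference of the observed
#' count from its null expectation, and a 1-df chi-square comparing the
#' observed in/out split for that category against the expected split
#' (expectations rescaled to the observed total). P-values are Bonferroni
#' corrected over the categories tested.
#'
#' @param observed Named observed counts.
#' @param expected Named expected counts (same categories).
#' @param m Number of tests for the Bonferroni correction.
#' @return `data.frame` with `category`, `observed`, `expected`, `rpd`,
#'   `chi2_stat`, `pvalue`, `pvalue_adj`.
#' @export
enrichment_test <- function(observed, expected, m = length(observed)) {
  stopifnot(length(observed) == length(expected))
  impossible <- expected <= 0 & observed <= 0
  if (any(impossible)) {   # category unreachable on this genome: drop
    observed <- observed[!impossible]
    expected <- expected[!impossible]
    m <- length(observed)
  }
  if (any(expected <= 0))
    stop("expected count is zero; increase n_replicates")
  n_obs <- sum(observed)
  n_exp <- sum(expected)
  res <- lapply(seq_along(observed), function(i) {
    o <- c(observed[i], n_obs - observed[i])
    e <- c(expected[i], n_exp - expected[i])
    gof <- gof_chi_square(o, e)
    c(gof$statistic, gof$pvalue)
  })
  stat <- vapply(res, `[`, numeric(1), 1L)
  p <- vapply(res, `[`, numeric(1), 2L)
  data.frame(category = names(observed),
             observed = as.numeric(observed),
             expected = as.numeric(expected),
             rpd = relative_percentage_difference(as.numeric(observed),
                                                  as.numeric(expected)),
             chi2_stat = stat, pvalue = p,
             pvalue_adj = bonferroni_adjust(p, m),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Joint distance-by-accessibility enrichment (8 cells)
#'
#' Cross-classifies annotated peaks by TSS-distance bin and open/closed
#' chromatin, computes each cell's expectation from annotated shuffle
#' replicates and tests each of the 8 cells with a 1-df chi-square,
#' Bonferroni corrected over 8 tests.
#'
#' @param ann Observed `hif_annotation` carrying `distance_bin` and
#'   `open_chromatin`.
#' @param replicate_anns List of identically annotated replicates (see
#'   [annotate_replicates()]).
#' @return An [enrichment_test()] table with one row per
#'   `distance_bin:chromatin` cell.
#' @export
joint_distance_accessibility_enrichment <- function(ann, replicate_anns) {
  if (is.null(ann$open_chromatin))
    stop("annotation lacks open_chromatin; supply ATAC regions")
  obs <- .bin_open_counts(ann)
  exp_d <- expected_distribution(replicate_anns,
                                 what = "distance_by_chromatin")
  enrichment_test(obs, exp_d$expected, m = length(obs))
}
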