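#' Configuration for the synthetic dataset generator
#'
#' Defaults emulate the qualitative structure of a genome-wide
#' transcription-factor binding study at desk scale: a few thousand peaks
#' preferentially placed near transcription start sites and inside open
#' chromatin, and an expression table in which proximally bound genes
#' (<= 3 kb) tend to be upregulated while genes bound at 3-10 kb tend to be
#' downregulated.
#'
#' @param seed Master seed; every emitted object is a deterministic function
#'   of it.
#' @param n_chroms,chrom_length Genome shape (chromosomes of equal length,
#'   bp).
#' @param n_genes Number of non-overlapping genes.
#' @param gene_length `c(min, max)` gene length in bp, drawn uniformly.
#' @param n_peaks,peak_length Number and fixed length of binding sites.
#' @param atac_fraction Fraction of the genome covered by open-chromatin
#'   regions (sum of region lengths).
#' @param atac_length Length of each open-chromatin region.
#' @param p_atac_promoter Probability an open-chromatin region is centered
#'   on a random TSS rather than placed uniformly.
#' @param p_peak_promoter Probability a peak is planted within 3 kb of a
#'   random TSS.
#' @param p_peak_open Probability a non-promoter peak is planted inside a
#'   random open-chromatin region.
#' @param p_up_given_proximal P(planted up | nearest-bound at <= 3 kb).
#' @param p_down_given_mid P(planted down | nearest-bound at 3-10 kb).
#' @param p_deg_baseline P(planted DE, random direction) for all other
#'   genes.
#' @param lfc_effect_mean,lfc_noise_sd Mean planted |log2FC| for DE genes
#'   and the Gaussian noise sd (also the sd of non-DE log2FC around 0).
#' @param pvalue_shape Shape `a` of the Beta(a, 1) draw for DE-gene
#'   p-values (skewed toward 0).
#' @param with_sequence Generate a nucleotide sequence (i.i.d. uniform
#'   ACGT).
#' @param motif_plant Plant one consensus motif at each peak reference point
#'   and disrupt occurrences elsewhere (implies `with_sequence`).
#' @param motif IUPAC motif used when planting.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chroms = 4L, chrom_length = 1e7,
                       n_genes = 2000L, gene_length = c(1000, 4000),
                       n_peaks = 1500L, peak_length = 400L,
                       atac_fraction = 0.10, atac_length = 1000L,
                       p_atac_promoter = 0.5, p_peak_promoter = 0.3,
                       p_peak_open = 0.3, p_up_given_proximal = 0.5,
                       p_down_given_mid = 0.4, p_deg_baseline = 0.03,
                       lfc_effect_mean = 1.5, lfc_noise_sd = 0.2,
                       pvalue_shape = 0.02, with_sequence = FALSE,
                       motif_plant = FALSE, motif = "RCGTG") {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = chrom_length, n_genes = as.integer(n_genes),
              gene_length = gene_length, n_peaks = as.integer(n_peaks),
              peak_length = as.integer(peak_length),
              atac_fraction = atac_fraction,
              atac_length = as.integer(atac_length),
              p_atac_promoter = p_atac_promoter,
              p_peak_promoter = p_peak_promoter, p_peak_open = p_peak_open,
              p_up_given_proximal = p_up_given_proximal,
              p_down_given_mid = p_down_given_mid,
              p_deg_baseline = p_deg_baseline,
              lfc_effect_mean = lfc_effect_mean,
              lfc_noise_sd = lfc_noise_sd, pvalue_shape = pvalue_shape,
              with_sequence = isTRUE(with_sequence) || isTRUE(motif_plant),
              motif_plant = isTRUE(motif_plant), motif = motif)
  probs <- unlist(cfg[c("atac_fraction", "p_atac_promoter",
                        "p_peak_promoter", "p_peak_open",
                        "p_up_given_proximal", "p_down_given_mid",
                        "p_deg_baseline")])
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$n_peaks < 1L) stop("n_peaks must be >= 1")
  if (cfg$peak_length >= cfg$chrom_length)
    stop("peak_length must be smaller than chrom_length")
  if (cfg$gene_length[1L] > cfg$gene_length[2L] ||
      cfg$gene_length[1L] < 1)
    stop("gene_length must be c(min, max) with 1 <= min <= max")
  structure(cfg, class = "sim_config")
}

#' Generate a random genome
#'
#' Chromosomes `chr1..chrN` of equal length; when `with_sequence`, i.i.d.
#' uniform ACGT sequence. Deterministic given the RNG state (seeded by
#' [simulate_dataset()]).
#'
#' @param cfg A [sim_config()].
#' @return A [hif_genome].
#' @export
generate_genome <- function(cfg) {
  nm <- paste0("chr", seq_len(cfg$n_chroms))
  lengths <- stats::setNames(rep(cfg$chrom_length, cfg$n_chroms), nm)
  seq <- NULL
  if (cfg$with_sequence) {
    seq <- Biostrings::DNAStringSet(vapply(nm, function(ch)
      paste(sample(c("A", "C", "G", "T"), cfg$chrom_length,
                   replace = TRUE), collapse = ""), character(1)))
    names(seq) <- nm
  }
  hif_genome(lengths, seq)
}

# Uniform non-overlapping placement of k interval lengths on [0, L):
# stick-breaking over the free space.
.place_nonoverlapping <- function(lens, L) {
  k <- length(lens)
  free <- L - sum(lens)
  if (free < 0) stop("infeasible packing: intervals exceed chromosome")
  gaps <- sort(floor(stats::runif(k) * (free + 1)))
  starts <- gaps + cumsum(c(0, lens[-k]))
  starts
}

#' Generate gene annotation and open-chromatin regions
#'
#' Genes are placed uniformly without overlap (strands 50/50); the requested
#' number may be reduced if a chromosome cannot hold its share, which raises
#' an error instead. Open-chromatin regions have a fixed length; a fraction
#' `p_atac_promoter` of them are centered on random TSSs, the rest placed
#' uniformly; regions may overlap each other.
#'
#' @param cfg A [sim_config()].
#' @param genome A [hif_genome] from [generate_genome()].
#' @return List with `genes` (a [gene_table]) and `atac` (data.frame
#'   `chrom`, `start`, `end`).
#' @export
generate_annotation <- function(cfg, genome) {
  nm <- names(genome$chroms)
  genes <- NULL
  if (cfg$n_genes > 0L) {
    per <- diff(round(seq(0, cfg$n_genes, length.out = length(nm) + 1)))
    recs <- list()
    off <- 0L
    for (i in seq_along(nm)) {
      k <- per[i]
      if (k == 0L) next
      lens <- floor(stats::runif(k, cfg$gene_length[1L],
                                 cfg$gene_length[2L] + 1))
      starts <- .place_nonoverlapping(lens, genome$chroms[[i]])
      recs[[i]] <- data.frame(
        gene_id = sprintf("g%04d", off + seq_len(k)), chrom = nm[i],
        strand = sample(c("+", "-"), k, replace = TRUE),
        start = starts, end = starts + lens, stringsAsFactors = FALSE)
      off <- off + k
    }
    g <- do.call(rbind, recs)
    genes <- gene_table(g$gene_id, g$chrom, g$strand, g$start, g$end)
  } else {
    genes <- gene_table(character(0), character(0), character(0),
                        numeric(0), numeric(0))
  }
  total <- sum(genome$chroms)
  n_atac <- max(1L, round(cfg$atac_fraction * total / cfg$atac_length))
  at_promoter <- stats::runif(n_atac) < cfg$p_atac_promoter &
    nrow(genes) > 0L
  chrom <- character(n_atac); center <- numeric(n_atac)
  n_prom <- sum(at_promoter)
  if (n_prom > 0L) {
    gi <- sample.int(nrow(genes), n_prom, replace = TRUE)
    chrom[at_promoter] <- genes$chrom[gi]
    center[at_promoter] <- genes$tss[gi]
  }
  n_unif <- n_atac - n_prom
  if (n_unif > 0L) {
    ci <- sample.int(length(nm), n_unif, replace = TRUE,
                     prob = genome$chroms)
    chrom[!at_promoter] <- nm[ci]
    center[!at_promoter] <- floor(stats::runif(n_unif) *
                                    genome$chroms[ci])
  }
  half <- floor(cfg$atac_length / 2)
  start <- pmax(0, center - half)
  end <- pmin(genome$chroms[chrom], start + cfg$atac_length)
  start <- pmax(0, end - cfg$atac_length)
  atac <- data.frame(chrom = chrom, start = start, end = end,
                     stringsAsFactors = FALSE)
  atac <- atac[order(atac$chrom, atac$start), , drop = FALSE]
  rownames(atac) <- NULL
  list(genes = genes, atac = atac)
}

# Place a fixed-length peak so that its reference point sits at ref.
.peak_at <- function(ref, len, chrom_len) {
  ref <- pmax(0, pmin(ref, chrom_len - 1))
  start <- pmax(0, pmin(ref - floor(len / 2), chrom_len - len))
  list(start = start, summit = pmin(len - 1, pmax(0, ref - start)))
}

#' Generate binding sites with planted placement classes
#'
#' Each peak is drawn as promoter-proximal (reference point uniform within
#' +/- 3 kb of a random TSS) with probability `p_peak_promoter`; otherwise
#' inside a random open-chromatin region with probability `p_peak_open`;
#' otherwise uniformly (chromosome weighted by length). The summit records
#' the drawn reference point.
#'
#' @param cfg A [sim_config()].
#' @param genome,genes,atac Outputs of the earlier generator stages.
#' @return List with `peaks` (a [peak_set] with narrowPeak-style summits)
#'   and `classes` (per-peak planting class: `promoter`, `open`,
#'   `uniform`).
#' @export
generate_peaks <- function(cfg, genome, genes, atac) {
  n <- cfg$n_peaks
  len <- cfg$peak_length
  u1 <- stats::runif(n); u2 <- stats::runif(n)
  class <- ifelse(u1 < cfg$p_peak_promoter & nrow(genes) > 0L, "promoter",
           ifelse(u2 < cfg$p_peak_open & nrow(atac) > 0L, "open",
                  "uniform"))
  chrom <- character(n); ref <- numeric(n)
  is_p <- class == "promoter"
  if (any(is_p)) {
    gi <- sample.int(nrow(genes), sum(is_p), replace = TRUE)
    chrom[is_p] <- genes$chrom[gi]
    ref[is_p] <- genes$tss[gi] +
      floor(stats::runif(sum(is_p), -3000, 3001))
  }
  is_o <- class == "open"
  if (any(is_o)) {
    ai <- sample.int(nrow(atac), sum(is_o), replace = TRUE)
    chrom[is_o] <- atac$chrom[ai]
    ref[is_o] <- atac$start[ai] +
      floor(stats::runif(sum(is_o)) * (atac$end[ai] - atac$start[ai]))
  }
  is_u <- class == "uniform"
  if (any(is_u)) {
    ci <- sample.int(cfg$n_chroms, sum(is_u), replace = TRUE,
                     prob = genome$chroms)
    chrom[is_u] <- names(genome$chroms)[ci]
    ref[is_u] <- floor(stats::runif(sum(is_u)) *
                         (genome$chroms[ci] - len)) + floor(len / 2) +
      round(stats::rnorm(sum(is_u), 0, 20))
  }
  placed <- .peak_at(ref, len, genome$chroms[chrom])
  peaks <- peak_set(chrom, placed$start, placed$start + len,
                    name = sprintf("peak_%05d", seq_len(n)),
                    score = round(stats::runif(n, 10, 1000), 1),
                    summit_offset = placed$summit, genome = genome)
  list(peaks = peaks, classes = class)
}

#' Generate a differential-expression table with planted binding effects
#'
#' Genes are stratified by their minimal nearest-neighbor binding distance
#' (computed with the package's own annotation): proximally bound genes
#' (<= 3 kb) are planted `up` with probability `p_up_given_proximal`;
#' mid-range bound genes (3-10 kb) are planted `down` with probability
#' `p_down_given_mid`; all remaining genes are planted DE with random
#' direction at `p_deg_baseline`. Planted DE genes draw
#' `|log2FC| ~ Normal(lfc_effect_mean, lfc_noise_sd)` and
#' `p ~ Beta(pvalue_shape, 1)`; others draw `log2FC ~ Normal(0,
#' lfc_noise_sd)` and `p ~ Uniform(0, 1)`.
#'
#' @param cfg A [sim_config()].
#' @param genes A [gene_table].
#' @param peaks A [peak_set] (the generated binding sites).
#' @return List with `expression` (`gene_id`, `log2fc`, `pvalue`) and
#'   `planted` (per-gene planted status `up`/`down`/`non` plus the binding
#'   stratum used).
#' @export
generate_expression <- function(cfg, genes, peaks) {
  if (nrow(genes) == 0L)
    return(list(expression = data.frame(gene_id = character(0),
                                        log2fc = numeric(0),
                                        pvalue = numeric(0)),
                planted = data.frame(gene_id = character(0),
                                     planted = character(0),
                                     stratum = character(0),
                                     min_abs_distance = numeric(0))))
  ann <- suppressMessages(assign_nearest_tss(peaks, genes))
  summ <- summarize_gene_binding(ann, genes)
  stratum <- .gene_stratum(summ$min_abs_distance)
  n <- nrow(genes)
  u <- stats::runif(n)
  planted <- rep("non", n)
  prox <- !is.na(stratum) & stratum == "0-3kb"
  mid <- !is.na(stratum) & stratum == "3-10kb"
  planted[prox & u < cfg$p_up_given_proximal] <- "up"
  planted[mid & u < cfg$p_down_given_mid] <- "down"
  rest <- !prox & !mid
  base_de <- rest & u < cfg$p_deg_baseline
  planted[base_de] <- sample(c("up", "down"), sum(base_de),
                             replace = TRUE)
  de <- planted != "non"
  lfc <- stats::rnorm(n, 0, cfg$lfc_noise_sd)
  mag <- abs(stats::rnorm(n, cfg$lfc_effect_mean, cfg$lfc_noise_sd))
  lfc[de] <- ifelse(planted[de] == "up", mag[de], -mag[de])
  p <- stats::runif(n)
  p[de] <- stats::rbeta(sum(de), cfg$pvalue_shape, 1)
  list(expression = data.frame(gene_id = genes$gene_id, log2fc = lfc,
                               pvalue = p, stringsAsFactors = FALSE),
       planted = data.frame(gene_id = genes$gene_id, planted = planted,
                            stratum = ifelse(is.na(stratum), "unbound",
                                             stratum),
                            min_abs_distance = summ$min_abs_distance,
                            stringsAsFactors = FALSE))
}

#' Plant the consensus motif in peaks and disrupt it elsewhere
#'
#' Writes one forward-strand occurrence of the motif (ambiguity codes
#' resolved to their first base, so `RCGTG` plants `ACGTG`) at each peak
#' reference point, and disrupts every other occurrence (both strands) by a
#' single-base substitution in the match core, repeating until no stray
#' occurrence remains.
#'
#' @param genome A [hif_genome] with sequence.
#' @param peaks A [peak_set].
#' @param motif A [motif_spec()] or IUPAC string.
#' @return The genome with modified sequence.
#' @export
plant_motif_sites <- function(genome, peaks, motif = motif_spec()) {
  if (is.character(motif)) motif <- motif_spec(motif)
  if (is.null(genome$sequence)) stop("genome has no sequence")
  k <- nchar(motif$pattern)
  concrete <- vapply(strsplit(motif$pattern, "")[[1L]], function(ch)
    substr(Biostrings::IUPAC_CODE_MAP[[ch]], 1, 1), character(1))
  concrete <- paste(concrete, collapse = "")
  seqs <- as.list(genome$sequence)
  for (ch in names(seqs)) {
    s <- seqs[[ch]]
    sel <- which(peaks$chrom == ch)
    in_peak <- rep(FALSE, length(s))
    for (i in sel)
      in_peak[(peaks$start[i] + 1):peaks$end[i]] <- TRUE
    for (iter in 1:10) {
      hits <- scan_sequence(s, motif)
      pos <- sort(unique(c(hits$positions, hits$rc_positions)))
      if (length(pos) == 0L) break
      # keep occurrences fully inside a peak footprint
      stray <- pos[!vapply(pos, function(p0)
        all(in_peak[(p0 + 1):(p0 + k)]), logical(1))]
      if (length(stray) == 0L) break
      at <- stray + 1 + floor(k / 2)  # 1-based core position
      cur <- strsplit(as.character(Biostrings::extractAt(
        s, IRanges::IRanges(at, at))), "")
      repl <- vapply(unlist(cur), function(b)
        switch(b, A = "T", C = "A", G = "T", T = "A", "A"), character(1))
      s <- Biostrings::replaceLetterAt(s, at, repl)
    }
    for (i in sel) {
      at <- peaks$ref_point[i] + 1
      if (at + k - 1 > length(s)) at <- length(s) - k + 1
      s <- Biostrings::replaceLetterAt(s, at:(at + k - 1),
                                       strsplit(concrete, "")[[1L]])
    }
    seqs[[ch]] <- s
  }
  hif_genome(genome$chroms, Biostrings::DNAStringSet(seqs))
}

#' Generate a complete synthetic dataset
#'
#' Runs every generator stage under the configuration's master seed and
#' optionally writes the standard files: `genome.chrom.sizes`, `genome.fa`
#' (when sequence is generated), `genes.tsv`, `atac.bed`,
#' `peaks.narrowPeak`, `expression.tsv`, `hypoxia_genes.txt` and
#' `ground_truth.json`. Output is byte-identical across reruns with the
#' same configuration.
#'
#' @param cfg A [sim_config()].
#' @param dir Optional output directory (created if needed).
#' @return List with `genome`, `genes`, `atac`, `peaks`, `expression`,
#'   `hypoxia_genes` and `ground_truth` (per-peak classes and per-gene
#'   planted labels).
#' @export
simulate_dataset <- function(cfg = sim_config(), dir = NULL) {
  .with_seed(cfg$seed, {
    genome <- generate_genome(cfg)
    annot <- generate_annotation(cfg, genome)
    pk <- generate_peaks(cfg, genome, annot$genes, annot$atac)
    if (cfg$motif_plant)
      genome <- plant_motif_sites(genome, pk$peaks, cfg$motif)
    expr <- generate_expression(cfg, annot$genes, pk$peaks)
    # known-hypoxia list: half of the planted DE genes plus decoys
    de_genes <- expr$planted$gene_id[expr$planted$planted != "non"]
    non_de <- setdiff(annot$genes$gene_id, de_genes)
    hypoxia <- sort(c(
      de_genes[stats::runif(length(de_genes)) < 0.5],
      non_de[stats::runif(length(non_de)) < 0.02]))
    result <- list(genome = genome, genes = annot$genes,
                   atac = annot$atac, peaks = pk$peaks,
                   expression = expr$expression, hypoxia_genes = hypoxia,
                   ground_truth = list(peak_classes = pk$classes,
                                       planted = expr$planted))
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      write_chrom_sizes(genome, file.path(dir, "genome.chrom.sizes"))
      if (!is.null(genome$sequence))
        write_genome_fasta(genome, file.path(dir, "genome.fa"))
      write_gene_table(annot$genes, file.path(dir, "genes.tsv"))
      writeLines(sprintf("%s\t%.0f\t%.0f", annot$atac$chrom,
                         annot$atac$start, annot$atac$end),
                 file.path(dir, "atac.bed"))
      write_peaks(pk$peaks, file.path(dir, "peaks.narrowPeak"),
                  format = "narrowPeak")
      e <- expr$expression
      writeLines(c("gene_id\tlog2FC\tpvalue",
                   sprintf("%s\t%.6g\t%.6g", e$gene_id, e$log2fc,
                           e$pvalue)),
                 file.path(dir, "expression.tsv"))
      writeLines(hypoxia, file.path(dir, "hypoxia_genes.txt"))
      jsonlite::write_json(
        list(seed = cfg$seed,
             peak_classes = pk$classes,
             planted = expr$planted),
        file.path(dir, "ground_truth.json"), auto_unbox = TRUE,
        digits = NA)
    }
    result
  })
}
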