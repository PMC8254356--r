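# Distance bins used throughout (upper edges closed: d <= 3000 is "0-3kb").
DISTANCE_BINS <- c("0-3kb", "3-10kb", "10-100kb", ">100kb")
FEATURE_CLASSES <- c("promoter", "genebody", "intergenic")
PROMOTER_WINDOW <- 3000

#' Bin an absolute TSS distance
#'
#' Bins are `0-3kb` (d <= 3000), `3-10kb` (3000 < d <= 10000), `10-100kb`
#' (10000 < d <= 100000) and `>100kb`; upper edges belong to the lower bin.
#'
#' @param abs_distance Non-negative distances in bp (`Inf` allowed; mapped to
#'   `NA`, meaning no gene on the chromosome).
#' @return Factor with levels `0-3kb`, `3-10kb`, `10-100kb`, `>100kb`.
#' @export
bin_distance <- function(abs_distance) {
  if (any(abs_distance < 0, na.rm = TRUE))
    stop("negative distance")
  bin <- rep(NA_character_, length(abs_distance))
  ok <- !is.na(abs_distance) & is.finite(abs_distance)
  d <- abs_distance[ok]
  bin[ok] <- ifelse(d <= 3000, "0-3kb",
             ifelse(d <= 10000, "3-10kb",
             ifelse(d <= 100000, "10-100kb", ">100kb")))
  factor(bin, levels = DISTANCE_BINS)
}

# Nearest-TSS search on one chromosome. Ties (left/right TSS equidistant, or
# several genes sharing a TSS coordinate) resolve to the lexicographically
# smallest gene_id.
.nearest_tss_chrom <- function(ref, tss, gene_id) {
  o <- order(tss, gene_id)
  tss <- tss[o]; gene_id <- gene_id[o]
  # one representative per distinct TSS position: the smallest gene_id
  keep <- !duplicated(tss)
  pos <- tss[keep]; rep_id <- gene_id[keep]
  i <- findInterval(ref, pos)
  n <- length(pos)
  dl <- ifelse(i >= 1, ref - pos[pmax(i, 1L)], Inf)
  dr <- ifelse(i < n, pos[pmin(i + 1L, n)] - ref, Inf)
  use_left <- (dl < dr) |
    (dl == dr & rep_id[pmax(i, 1L)] <= rep_id[pmin(i + 1L, n)])
  idx <- ifelse(use_left, pmax(i, 1L), pmin(i + 1L, n))
  list(gene = rep_id[idx], tss = pos[idx],
       abs_distance = pmin(dl, dr))
}

#' Assign each peak to its nearest-TSS gene
#'
#' The peak reference point (summit or midpoint) is compared with every TSS
#' on the same chromosome; the gene with minimal absolute distance wins, ties
#' broken by lexicographically smaller gene id. The signed distance is
#' orientation-corrected: positive means the peak lies downstream of the TSS
#' in the direction of transcription. Peaks on chromosomes without genes get
#' an infinite distance and an `NA` bin; they are excluded from bin counts.
#'
#' @param peaks A [peak_set].
#' @param genes A [gene_table]; must be non-empty.
#' @return A `data.frame` of class `hif_annotation`: one row per peak with
#'   `chrom`, `start`, `end`, `name`, `ref_point`, `nearest_gene`,
#'   `signed_distance`, `abs_distance`, `distance_bin`.
#' @export
assign_nearest_tss <- function(peaks, genes) {
  if (nrow(genes) == 0L) stop("empty gene list")
  ann <- data.frame(chrom = peaks$chrom, start = peaks$start,
                    end = peaks$end, name = peaks$name,
                    ref_point = peaks$ref_point,
                    nearest_gene = NA_character_,
                    signed_distance = NA_real_,
                    abs_distance = Inf,
                    stringsAsFactors = FALSE)
  strand_of <- stats::setNames(genes$strand, genes$gene_id)
  for (ch in unique(peaks$chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0L) next
    sel <- which(peaks$chrom == ch)
    hit <- .nearest_tss_chrom(peaks$ref_point[sel], g$tss, g$gene_id)
    ann$nearest_gene[sel] <- hit$gene
    ann$abs_distance[sel] <- hit$abs_distance
    raw <- peaks$ref_point[sel] - hit$tss
    ann$signed_distance[sel] <-
      ifelse(strand_of[hit$gene] == "+", raw, -raw)
  }
  n_orphan <- sum(!is.finite(ann$abs_distance))
  if (n_orphan > 0)
    message(n_orphan, " peak(s) on gene-free chromosomes left unannotated")
  ann$distance_bin <- bin_distance(ann$abs_distance)
  structure(ann, class = c("hif_annotation", "data.frame"))
}

#' Classify the genomic feature context of annotated peaks
#'
#' Mutually exclusive, exhaustive classes: `promoter` when the reference
#' point lies within 3 kb of any TSS (equivalently, the nearest-TSS distance
#' is at most 3000); otherwise `genebody` when the reference point falls
#' inside any gene span; otherwise `intergenic`. Unannotated peaks (gene-free
#' chromosome) are `intergenic` unless inside a gene span, which cannot occur.
#'
#' @param ann A `hif_annotation` from [assign_nearest_tss()].
#' @param genes The [gene_table] used for annotation.
#' @param promoter_window Half-width of the promoter window in bp.
#' @return Factor vector with levels `promoter`, `genebody`, `intergenic`.
#' @export
classify_feature <- function(ann, genes, promoter_window = PROMOTER_WINDOW) {
  promoter <- is.finite(ann$abs_distance) &
    ann$abs_distance <= promoter_window
  pts <- .as_granges(ann$chrom, ann$ref_point, ann$ref_point + 1)
  spans <- .as_granges(genes$chrom, genes$start, genes$end)
  inside <- IRanges::overlapsAny(pts, spans)
  factor(ifelse(promoter, "promoter",
         ifelse(inside, "genebody", "intergenic")),
         levels = FEATURE_CLASSES)
}

#' Flag peaks overlapping open chromatin
#'
#' @param peaks A [peak_set].
#' @param atac A `data.frame` with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. ATAC-seq regions read with [read_peaks()].
#' @param mode `"any"`: at least 1 bp of the peak interval overlaps a region;
#'   `"summit"`: the reference point itself falls inside a region.
#' @return Logical vector, one flag per peak.
#' @export
flag_open_chromatin <- function(peaks, atac, mode = c("any", "summit")) {
  mode <- match.arg(mode)
  if (nrow(atac) == 0L) return(rep(FALSE, nrow(peaks)))
  q <- if (mode == "any")
    .as_granges(peaks$chrom, peaks$start, peaks$end)
  else
    .as_granges(peaks$chrom, peaks$ref_point, peaks$ref_point + 1)
  IRanges::overlapsAny(q, .as_granges(atac$chrom, atac$start, atac$end))
}

#' Fully annotate a peak set
#'
#' Runs nearest-TSS assignment, feature classification and (when ATAC
#' regions are supplied) open-chromatin flagging in one call.
#'
#' @inheritParams assign_nearest_tss
#' @inheritParams flag_open_chromatin
#' @param atac Optional open-chromatin regions; when `NULL` the
#'   `open_chromatin` column is omitted.
#' @param promoter_window Promoter half-width in bp.
#' @return A `hif_annotation` data.frame with `feature` and (optionally)
#'   `open_chromatin` columns added.
#' @export
annotate_peaks <- function(peaks, genes, atac = NULL,
                           promoter_window = PROMOTER_WINDOW,
                           mode = c("any", "summit")) {
  ann <- assign_nearest_tss(peaks, genes)
  ann$feature <- classify_feature(ann, genes, promoter_window)
  if (!is.null(atac))
    ann$open_chromatin <- flag_open_chromatin(peaks, atac, mode)
  ann
}

#' Count/percentage table from a named count vector
#'
#' @param counts Named non-negative counts.
#' @return `data.frame` with `category`, `count` and `pct` (percent of the
#'   total, rounded to 1 decimal).
#' @export
percentage_table <- function(counts) {
  if (length(counts) == 0L || sum(counts) == 0)
    stop("empty count table")
  data.frame(category = names(counts), count = as.numeric(counts),
             pct = round(100 * as.numeric(counts) / sum(counts), 1),
             stringsAsFactors = FALSE)
}

.bin_open_counts <- function(ann) {
  ok <- !is.na(ann$distance_bin)
  chromatin <- factor(ifelse(ann$open_chromatin, "open", "closed"),
                      levels = c("open", "closed"))
  tab <- table(ann$distance_bin[ok], chromatin[ok])
  cells <- as.vector(tab)
  names(cells) <- paste(rep(rownames(tab), ncol(tab)),
                        rep(colnames(tab), each = nrow(tab)), sep = ":")
  cells
}

#' Summarize a peak annotation
#'
#' Tabulates annotated peaks by distance bin, feature class, open-chromatin
#' flag and the distance-bin-by-chromatin cross-classification, each with
#' percentages of the annotated total (1-decimal rounding). Peaks with no
#' gene on their chromosome are excluded from distance-bin tables.
#'
#' @param ann A `hif_annotation` from [annotate_peaks()].
#' @return Named list of [percentage_table()] data.frames: `distance`,
#'   `feature` (if classified), `open_chromatin` and `distance_by_chromatin`
#'   (if flagged).
#' @export
summarize_annotation <- function(ann) {
  if (nrow(ann) == 0L) stop("empty annotation")
  out <- list()
  ok <- !is.na(ann$distance_bin)
  out$distance <- percentage_table(table(ann$distance_bin[ok]))
  if (!is.null(ann$feature))
    out$feature <- percentage_table(table(ann$feature))
  if (!is.null(ann$open_chromatin)) {
    out$open_chromatin <- percentage_table(
      table(factor(ifelse(ann$open_chromatin, "open", "closed"),
                   levels = c("open", "closed"))))
    out$distance_by_chromatin <- percentage_table(.bin_open_counts(ann))
  }
  out
}

#' Write an annotated peak BED (BED6+ extra columns)
#'
#' Columns 7+ are nearest gene, signed distance, feature class and (when
#' present) the open-chromatin flag; a `#` header documents them.
#'
#' @param ann A `hif_annotation`.
#' @param path Output path.
#' @export
write_annotation_bed <- function(ann, path) {
  extra <- c("nearest_gene", "signed_distance", "feature")
  if (!is.null(ann$open_chromatin)) extra <- c(extra, "open_chromatin")
  header <- paste0("#chrom\tstart\tend\tname\tscore\tstrand\t",
                   paste(extra, collapse = "\t"))
  body <- sprintf("%s\t%.0f\t%.0f\t%s\t0\t.\t%s\t%s\t%s", ann$chrom,
                  ann$start, ann$end, ann$name,
                  ifelse(is.na(ann$nearest_gene), ".", ann$nearest_gene),
                  ifelse(is.finite(ann$signed_distance),
                         sprintf("%.0f", ann$signed_distance), "."),
                  as.character(ann$feature))
  if (!is.null(ann$open_chromatin))
    body <- paste0(body, "\t", ifelse(ann$open_chromatin, "1", "0"))
  writeLines(c(header, body), path)
  invisible(path)
}
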