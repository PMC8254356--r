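# Internal convention: all coordinates are 0-based half-open [start, end),
# BED-style. GTF input (1-based inclusive) is converted on read.

.parse_error <- function(path, line, msg) {
  stop(sprintf("%s: line %d: %s", path, line, msg), call. = FALSE)
}

#' Construct a genome object
#'
#' A genome is an ordered set of chromosome lengths with an optional
#' nucleotide sequence per chromosome. It defines the coordinate universe for
#' all interval operations and the support of the random-placement null.
#'
#' @param lengths Named numeric vector of chromosome lengths in bp; names are
#'   chromosome names, order is preserved.
#' @param sequence Optional [Biostrings::DNAStringSet] whose names and widths
#'   match `lengths`.
#' @return An object of class `hif_genome` with elements `chroms` (named
#'   numeric) and `sequence` (`DNAStringSet` or `NULL`).
#' @export
hif_genome <- function(lengths, sequence = NULL) {
  if (length(lengths) == 0L) stop("genome must have at least one chromosome")
  nm <- names(lengths)
  if (is.null(nm) || any(nm == "")) stop("chromosome lengths must be named")
  if (anyDuplicated(nm)) stop("duplicate chromosome name: ",
                              nm[duplicated(nm)][1L])
  if (any(!is.finite(lengths)) || any(lengths <= 0) ||
      any(lengths != floor(lengths)))
    stop("chromosome lengths must be positive integers")
  lengths <- stats::setNames(as.numeric(lengths), nm)
  if (!is.null(sequence)) {
    if (!methods::is(sequence, "DNAStringSet"))
      stop("sequence must be a DNAStringSet")
    if (!setequal(names(sequence), nm))
      stop("sequence names do not match chromosome names")
    sequence <- sequence[nm]
    w <- Biostrings::width(sequence)
    if (any(w != lengths))
      stop("sequence length disagrees with declared length for: ",
           paste(nm[w != lengths], collapse = ", "))
  }
  structure(list(chroms = lengths, sequence = sequence),
            class = "hif_genome")
}

#' @export
print.hif_genome <- function(x, ...) {
  cat(sprintf("hif_genome: %d chromosome(s), %.0f bp total%s\n",
              length(x$chroms), sum(x$chroms),
              if (is.null(x$sequence)) "" else " (with sequence)"))
  invisible(x)
}

#' Read a chrom.sizes file
#'
#' @param path Two whitespace-separated columns: chromosome name, length.
#' @return A [hif_genome] without sequence, in file order.
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(path, ": empty chrom.sizes file")
  nm <- character(length(lines))
  len <- numeric(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    if (length(f) < 2L) .parse_error(path, i, "expected two columns")
    v <- suppressWarnings(as.numeric(f[2L]))
    if (is.na(v) || v != floor(v))
      .parse_error(path, i, paste0("non-integer length '", f[2L], "'"))
    if (v <= 0) .parse_error(path, i, "non-positive chromosome length")
    nm[i] <- f[1L]
    len[i] <- v
  }
  if (anyDuplicated(nm))
    .parse_error(path, which(duplicated(nm))[1L],
                 paste0("duplicate chromosome '", nm[duplicated(nm)][1L], "'"))
  hif_genome(stats::setNames(len, nm))
}

#' Write a chrom.sizes file
#' @param genome A [hif_genome].
#' @param path Output path.
#' @export
write_chrom_sizes <- function(genome, path) {
  writeLines(sprintf("%s\t%.0f", names(genome$chroms), genome$chroms), path)
  invisible(path)
}

#' Read a genome FASTA
#'
#' Chromosome lengths are taken from the sequence widths.
#' @param path FASTA file.
#' @return A [hif_genome] with sequence.
#' @export
read_genome_fasta <- function(path) {
  seq <- Biostrings::readDNAStringSet(path)
  names(seq) <- sub("\\s.*$", "", names(seq))
  hif_genome(stats::setNames(Biostrings::width(seq), names(seq)), seq)
}

#' Write the genome sequence as FASTA
#' @param genome A [hif_genome] with sequence.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  if (is.null(genome$sequence)) stop("genome has no sequence")
  Biostrings::writeXStringSet(genome$sequence, path, width = 70L)
  invisible(path)
}

#' Construct a peak set
#'
#' Each peak carries a reference point used for all distance computations:
#' the summit when a summit offset is available (narrowPeak column 10),
#' otherwise the integer midpoint `floor((start + end) / 2)`.
#'
#' @param chrom,start,end Coordinates, 0-based half-open.
#' @param name Optional peak labels.
#' @param score Optional numeric score.
#' @param strand Strand characters (`+`, `-`, `.`).
#' @param summit_offset Optional offset of the summit from `start`; `NA` for
#'   the midpoint rule.
#' @param genome Optional [hif_genome] used to validate coordinates.
#' @return A `data.frame` of class `hif_peaks` with columns `chrom`, `start`,
#'   `end`, `name`, `score`, `strand`, `summit_offset`, `ref_point`.
#' @export
peak_set <- function(chrom, start, end, name = NULL, score = NA_real_,
                     strand = ".", summit_offset = NA_real_, genome = NULL) {
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(as.numeric(start), n)
  end <- rep_len(as.numeric(end), n)
  if (any(is.na(start)) || any(is.na(end)))
    stop("peak coordinates must be numeric")
  if (any(start < 0)) stop("negative start coordinate")
  if (any(start >= end)) stop("peak with start >= end at row ",
                              which(start >= end)[1L])
  if (is.null(name)) name <- sprintf("peak_%d", seq_len(n))
  summit_offset <- rep_len(as.numeric(summit_offset), n)
  bad <- !is.na(summit_offset) &
    (summit_offset < 0 | summit_offset >= end - start)
  if (any(bad)) stop("summit offset outside peak at row ", which(bad)[1L])
  ref <- ifelse(is.na(summit_offset), floor((start + end) / 2),
                start + summit_offset)
  if (!is.null(genome)) {
    unknown <- !(chrom %in% names(genome$chroms))
    if (any(unknown))
      stop("peak on unknown chromosome: ", chrom[unknown][1L])
    over <- end > genome$chroms[chrom]
    if (any(over))
      stop("peak extends beyond chromosome end at row ", which(over)[1L])
  }
  structure(data.frame(chrom = as.character(chrom), start = start, end = end,
                       name = rep_len(as.character(name), n),
                       score = rep_len(as.numeric(score), n),
                       strand = rep_len(as.character(strand), n),
                       summit_offset = summit_offset, ref_point = ref,
                       stringsAsFactors = FALSE),
            class = c("hif_peaks", "data.frame"))
}

#' Read peaks from BED or narrowPeak
#'
#' narrowPeak (10 columns) is detected automatically; its summit column sets
#' the peak reference point when non-negative, otherwise the midpoint rule
#' applies.
#'
#' @param path BED3/BED6 or ENCODE narrowPeak file.
#' @param genome Optional [hif_genome]; coordinates are validated against it.
#' @return A [peak_set].
#' @export
read_peaks <- function(path, genome = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#",
                           colClasses = "character", quote = "")
  nc <- ncol(tab)
  if (nc < 3L) stop(path, ": expected at least 3 tab-separated columns")
  start <- suppressWarnings(as.numeric(tab[[2L]]))
  end <- suppressWarnings(as.numeric(tab[[3L]]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) .parse_error(path, bad[1L], "non-numeric coordinate")
  bad <- which(start >= end)
  if (length(bad)) .parse_error(path, bad[1L], "start >= end")
  name <- if (nc >= 4L) tab[[4L]] else NULL
  score <- if (nc >= 5L) suppressWarnings(as.numeric(tab[[5L]])) else NA_real_
  strand <- if (nc >= 6L) tab[[6L]] else "."
  summit <- NA_real_
  if (nc >= 10L) {
    summit <- suppressWarnings(as.numeric(tab[[10L]]))
    summit[!is.na(summit) & summit < 0] <- NA_real_  # -1 = no summit called
  }
  peak_set(tab[[1L]], start, end, name = name, score = score,
           strand = strand, summit_offset = summit, genome = genome)
}

#' Write peaks to BED6 or narrowPeak
#'
#' @param peaks A [peak_set].
#' @param path Output path.
#' @param format `"auto"` writes narrowPeak when any summit offset is present,
#'   BED6 otherwise.
#' @export
write_peaks <- function(peaks, path, format = c("auto", "bed6", "narrowPeak")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (any(!is.na(peaks$summit_offset))) "narrowPeak" else "bed6"
  score <- ifelse(is.na(peaks$score), 0, peaks$score)
  if (format == "bed6") {
    lines <- sprintf("%s\t%.0f\t%.0f\t%s\t%g\t%s", peaks$chrom, peaks$start,
                     peaks$end, peaks$name, score, peaks$strand)
  } else {
    summit <- ifelse(is.na(peaks$summit_offset), -1, peaks$summit_offset)
    lines <- sprintf("%s\t%.0f\t%.0f\t%s\t%g\t%s\t0\t-1\t-1\t%.0f",
                     peaks$chrom, peaks$start, peaks$end, peaks$name, score,
                     peaks$strand, summit)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Construct a gene annotation table
#'
#' The TSS is derived from the strand: `gene_start` for `+` genes and
#' `gene_end - 1` (last base of the half-open span) for `-` genes.
#'
#' @param gene_id Unique gene identifiers.
#' @param chrom,start,end Gene spans, 0-based half-open.
#' @param strand `+` or `-`.
#' @param genome Optional [hif_genome]; genes on chromosomes absent from it
#'   are dropped with a warning.
#' @return A `data.frame` of class `hif_genes` with columns `gene_id`,
#'   `chrom`, `strand`, `start`, `end`, `tss`.
#' @export
gene_table <- function(gene_id, chrom, strand, start, end, genome = NULL) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(is.na(start) | is.na(end))) stop("non-numeric gene coordinates")
  if (any(start >= end)) stop("gene with start >= end: ",
                              gene_id[start >= end][1L])
  if (any(start < 0)) stop("negative gene start")
  bad <- !(strand %in% c("+", "-"))
  if (any(bad)) stop("unknown strand symbol '", strand[bad][1L], "' for gene ",
                     gene_id[bad][1L])
  if (anyDuplicated(gene_id))
    stop("duplicate gene_id: ", gene_id[duplicated(gene_id)][1L])
  tss <- ifelse(strand == "+", start, end - 1)
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   strand = as.character(strand),
                   start = start, end = end, tss = tss,
                   stringsAsFactors = FALSE)
  if (!is.null(genome)) {
    drop <- !(df$chrom %in% names(genome$chroms))
    if (any(drop)) {
      warning(sum(drop), " gene(s) on chromosomes absent from the genome ",
              "were dropped")
      df <- df[!drop, , drop = FALSE]
    }
  }
  structure(df, class = c("hif_genes", "data.frame"))
}

.looks_like_gtf <- function(path) {
  if (grepl("\\.(gtf|gff|gff3)(\\.gz)?$", path, ignore.case = TRUE))
    return(TRUE)
  first <- readLines(path, n = 50L)
  first <- first[!startsWith(first, "#") & nzchar(first)]
  if (length(first) == 0L) return(FALSE)
  length(strsplit(first[1L], "\t")[[1L]]) >= 9L
}

#' Read gene annotation from GTF or a simplified gene table
#'
#' GTF `gene` features are imported via \pkg{rtracklayer} and converted to
#' the internal 0-based half-open convention. The simplified table is
#' header-less TSV with columns gene_id, chrom, strand, start, end (already
#' 0-based half-open); a header line starting with `gene_id` is tolerated.
#'
#' @param path GTF/GFF or TSV file.
#' @param genome Optional [hif_genome] for chromosome filtering.
#' @return A [gene_table].
#' @export
read_gene_table <- function(path, genome = NULL) {
  if (.looks_like_gtf(path)) {
    gr <- rtracklayer::import(path)
    if ("type" %in% names(S4Vectors::mcols(gr)))
      gr <- gr[gr$type == "gene"]
    if (length(gr) == 0L) stop(path, ": no gene features found")
    ids <- S4Vectors::mcols(gr)$gene_id
    if (is.null(ids)) ids <- names(gr)
    if (is.null(ids)) stop(path, ": gene features lack gene_id attributes")
    return(gene_table(ids, as.character(GenomicRanges::seqnames(gr)),
                      as.character(GenomicRanges::strand(gr)),
                      GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
                      genome = genome))
  }
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "#")
  if (identical(tab[1L, 1L], "gene_id")) tab <- tab[-1L, , drop = FALSE]
  if (ncol(tab) < 5L) stop(path, ": expected 5 columns ",
                           "(gene_id, chrom, strand, start, end)")
  gene_table(tab[[1L]], tab[[2L]], tab[[3L]],
             suppressWarnings(as.numeric(tab[[4L]])),
             suppressWarnings(as.numeric(tab[[5L]])), genome = genome)
}

#' Write genes as GTF gene records
#' @param genes A [gene_table].
#' @param path Output path.
#' @export
write_gene_gtf <- function(genes, path) {
  lines <- sprintf(
    '%s\thifmap\tgene\t%.0f\t%.0f\t.\t%s\t.\tgene_id "%s";',
    genes$chrom, genes$start + 1, genes$end, genes$strand, genes$gene_id)
  writeLines(lines, path)
  invisible(path)
}

#' Write the simplified gene table (TSV, 0-based half-open)
#' @param genes A [gene_table].
#' @param path Output path.
#' @export
write_gene_table <- function(genes, path) {
  writeLines(sprintf("%s\t%s\t%s\t%.0f\t%.0f", genes$gene_id, genes$chrom,
                     genes$strand, genes$start, genes$end), path)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Expects a header; the three columns of interest can be renamed. Rows with
#' missing values are dropped with a message reporting how many.
#'
#' @param path TSV with at least gene id, log2 fold change and p-value
#'   columns.
#' @param gene_col,lfc_col,p_col Column names to use.
#' @return A `data.frame` with columns `gene_id`, `log2fc`, `pvalue`.
#' @export
read_expression_table <- function(path, gene_col = "gene_id",
                                  lfc_col = "log2FC", p_col = "pvalue") {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           check.names = FALSE)
  for (col in c(gene_col, lfc_col, p_col))
    if (!col %in% names(tab))
      stop(path, ": missing column '", col, "'")
  out <- data.frame(gene_id = as.character(tab[[gene_col]]),
                    log2fc = suppressWarnings(as.numeric(tab[[lfc_col]])),
                    pvalue = suppressWarnings(as.numeric(tab[[p_col]])),
                    stringsAsFactors = FALSE)
  drop <- is.na(out$gene_id) | out$gene_id == "" | is.na(out$log2fc) |
    is.na(out$pvalue)
  if (any(drop)) {
    message(sum(drop), " row(s) with missing values dropped from ", path)
    out <- out[!drop, , drop = FALSE]
  }
  if (any(out$pvalue < 0 | out$pvalue > 1))
    stop(path, ": p-value outside [0, 1] for gene ",
         out$gene_id[out$pvalue < 0 | out$pvalue > 1][1L])
  if (anyDuplicated(out$gene_id))
    stop(path, ": duplicate gene_id ",
         out$gene_id[duplicated(out$gene_id)][1L])
  rownames(out) <- NULL
  out
}

#' Read a plain gene list (one symbol per line)
#' @param path Text file.
#' @return Character vector, empty lines removed.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

# GRanges view of 0-based half-open intervals (1-based closed internally).
.as_granges <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
}
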