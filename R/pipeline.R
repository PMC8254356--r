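.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.enrich_as_list <- function(df) {
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

#' Run the full binding-integration pipeline
#'
#' Orchestrates annotation, shuffle-null enrichment, open-chromatin overlap,
#' expression integration and (when sequence is available) consensus-motif
#' enrichment, writing per-stage tables and a machine-readable summary JSON.
#' Omitting an optional input (`atac`, sequence, `hypoxia`) disables exactly
#' the panels that depend on it.
#'
#' Inputs may be given as file paths (standard formats, see
#' [read_peaks()], [read_gene_table()], [read_expression_table()]) or as the
#' corresponding in-memory objects.
#'
#' @param peaks Binding sites: path (BED/narrowPeak) or [peak_set].
#' @param genome Path to a chrom.sizes file or FASTA, or a [hif_genome].
#' @param genes Path (GTF/TSV) or [gene_table].
#' @param expression Path (TSV) or data.frame from
#'   [read_expression_table()].
#' @param atac Optional open-chromatin regions: path (BED) or data.frame.
#' @param hypoxia Optional known-hypoxia gene list: path or character
#'   vector.
#' @param out_dir Output directory; created if needed. `NULL` for no file
#'   output.
#' @param seed Seed governing the shuffle null (and motif null).
#' @param n_shuffles Shuffle replicates for expectation estimation.
#' @param lfc_threshold,alpha DEG thresholds.
#' @param promoter_window Promoter half-width (bp).
#' @param target_window Maximum TSS distance for target calling (bp).
#' @param overlap_mode Open-chromatin overlap rule, `"any"` or `"summit"`.
#' @param motif IUPAC consensus motif for the sequence panel.
#' @param correct Yates correction for 2x2 tests.
#' @return Invisibly, a list of class `hifmap_summary` keyed by figure-style
#'   panels: `fig2c` (distance distribution), `fig2d` (distance enrichment),
#'   `fig2e`/`fig2f` (feature distribution/enrichment), `fig3a` (joint
#'   distance x accessibility), `fig4a` (DEG counts), `fig4b`/`fig4e`
#'   (binding-DEG association), `fig4c`/`fig4f` (distance-stratified),
#'   `magnitude` (Mann-Whitney), `fig4j` (overlap counts), `targets`,
#'   `motif`, and `meta`.
#' @export
run_pipeline <- function(peaks, genome, genes, expression, atac = NULL,
                         hypoxia = NULL, out_dir = NULL, seed = 1L,
                         n_shuffles = 100L, lfc_threshold = 0.6,
                         alpha = 0.05, promoter_window = PROMOTER_WINDOW,
                         target_window = TARGET_WINDOW,
                         overlap_mode = c("any", "summit"),
                         motif = "RCGTG", correct = FALSE) {
  overlap_mode <- match.arg(overlap_mode)
  if (is.character(genome))
    genome <- if (grepl("\\.(fa|fasta|fna)(\\.gz)?$", genome,
                        ignore.case = TRUE))
      read_genome_fasta(genome) else read_chrom_sizes(genome)
  if (is.character(peaks)) peaks <- read_peaks(peaks, genome)
  if (is.character(genes)) genes <- read_gene_table(genes, genome)
  if (is.character(expression))
    expression <- read_expression_table(expression)
  if (is.character(atac)) atac <- read_peaks(atac, genome)
  if (is.character(hypoxia) && length(hypoxia) == 1L &&
      file.exists(hypoxia)) hypoxia <- read_gene_list(hypoxia)
  ann <- annotate_peaks(peaks, genes, atac, promoter_window, overlap_mode)
  obs <- summarize_annotation(ann)

  reps <- shuffle_intervals(peaks, genome, n_replicates = n_shuffles,
                            seed = seed)
  rep_anns <- annotate_replicates(reps, genes, atac, promoter_window,
                                  overlap_mode)
  exp_dist <- expected_distribution(rep_anns, what = "distance")
  exp_feat <- expected_distribution(rep_anns, what = "feature")
  obs_dist <- stats::setNames(obs$distance$count, obs$distance$category)
  obs_feat <- stats::setNames(obs$feature$count, obs$feature$category)
  fig2d <- enrichment_test(obs_dist, exp_dist$expected)
  fig2f <- enrichment_test(obs_feat, exp_feat$expected)
  keep_d <- obs_dist > 0 | exp_dist$expected > 0
  keep_f <- obs_feat > 0 | exp_feat$expected > 0
  gof_dist <- gof_chi_square(obs_dist[keep_d], exp_dist$expected[keep_d])
  gof_feat <- gof_chi_square(obs_feat[keep_f], exp_feat$expected[keep_f])

  fig3a <- NULL
  if (!is.null(atac))
    fig3a <- joint_distance_accessibility_enrichment(ann, rep_anns)

  degs <- classify_deg(expression, lfc_threshold, alpha)
  deg_counts <- attr(degs, "counts")
  summ <- summarize_gene_binding(ann, genes)
  m <- match(degs$gene_id, summ$gene_id)
  bound <- !is.na(m) & summ$is_bound[m]
  is_deg <- degs$status != "non"
  fig4b <- association_2x2(c(sum(is_deg & bound), sum(is_deg)),
                           c(sum(!is_deg & bound), sum(!is_deg)),
                           correct = correct)
  fig4e <- list(
    up = association_2x2(
      c(sum(degs$status == "up" & bound), sum(degs$status == "up")),
      c(sum(!is_deg & bound), sum(!is_deg)), correct = correct),
    down = association_2x2(
      c(sum(degs$status == "down" & bound), sum(degs$status == "down")),
      c(sum(!is_deg & bound), sum(!is_deg)), correct = correct))
  strat <- distance_stratified_association(degs, summ, correct = correct)
  mag <- magnitude_test(abs(degs$log2fc[bound]), abs(degs$log2fc[!bound]))
  fig4j <- overlap_counts(degs, summ, target_window)
  targets <- classify_targets(degs, summ, hypoxia, target_window)

  motif_res <- NULL
  if (!is.null(genome$sequence)) {
    motif_res <- motif_enrichment(peaks, genome, motif_spec(motif),
                                  n_shuffles = n_shuffles,
                                  seed = seed + 1L)
    motif_res$null_per_kb <- NULL
  }

  summary <- list(
    fig2c = obs$distance,
    fig2d = list(enrichment = .enrich_as_list(fig2d),
                 gof = gof_dist),
    fig2e = obs$feature,
    fig2f = list(enrichment = .enrich_as_list(fig2f),
                 gof = gof_feat),
    fig3a = if (!is.null(fig3a)) .enrich_as_list(fig3a) else "not run",
    fig4a = deg_counts,
    fig4b = fig4b[c("statistic", "pvalue", "prop_a", "prop_b")],
    fig4c = .enrich_as_list(strat[strat$comparison == "deg", ,
                                  drop = FALSE]),
    fig4e = list(up = fig4e$up[c("statistic", "pvalue", "prop_a",
                                 "prop_b")],
                 down = fig4e$down[c("statistic", "pvalue", "prop_a",
                                     "prop_b")]),
    fig4f = .enrich_as_list(strat[strat$comparison != "deg", ,
                                  drop = FALSE]),
    magnitude = mag,
    fig4j = fig4j,
    targets = targets$counts,
    motif = if (!is.null(motif_res)) motif_res else "not run",
    meta = list(seed = seed, n_shuffles = n_shuffles,
                lfc_threshold = lfc_threshold, alpha = alpha,
                promoter_window = promoter_window,
                target_window = target_window,
                overlap_mode = overlap_mode,
                rpd_definition = "100*(observed-expected)/expected",
                bin_edges = "upper edge closed (d<=3000 is 0-3kb)",
                ref_point = "summit if present else floor midpoint",
                n_peaks = nrow(peaks), n_genes = nrow(genes),
                n_expression = nrow(expression)))
  class(summary) <- "hifmap_summary"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_annotation_bed(ann, file.path(out_dir, "annotated_peaks.bed"))
    .write_tsv(obs$distance, file.path(out_dir, "distance_summary.tsv"))
    .write_tsv(obs$feature, file.path(out_dir, "feature_summary.tsv"))
    .write_tsv(fig2d, file.path(out_dir, "distance_enrichment.tsv"))
    .write_tsv(fig2f, file.path(out_dir, "feature_enrichment.tsv"))
    if (!is.null(fig3a))
      .write_tsv(fig3a, file.path(out_dir,
                                  "distance_chromatin_enrichment.tsv"))
    .write_tsv(strat, file.path(out_dir, "stratified_association.tsv"))
    master <- data.frame(degs,
                         min_abs_distance = summ$min_abs_distance[m],
                         is_bound = bound,
                         hif1a_dependent = targets$calls$hif1a_dependent,
                         direction = targets$calls$direction,
                         stringsAsFactors = FALSE)
    if (!is.null(hypoxia))
      master$known_hypoxia <- targets$calls$known_hypoxia
    .write_tsv(master, file.path(out_dir, "gene_master.tsv"))
    jsonlite::write_json(unclass(summary),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         pretty = TRUE)
  }
  invisible(summary)
}

#' Render a pipeline summary as a text report
#'
#' Tabulates each panel of a [run_pipeline()] summary without recomputing
#' anything; panels that were not run render as "not run".
#'
#' @param summary A `hifmap_summary` or the path to a `summary.json`.
#' @return Character vector of report lines (class `hifmap_report`), printed
#'   with [cat()].
#' @export
pipeline_report <- function(summary) {
  if (is.character(summary)) summary <- jsonlite::read_json(summary)
  need <- c("fig2c", "fig2e", "fig4a", "fig4b", "fig4j", "targets", "meta")
  missing <- setdiff(need, names(summary))
  if (length(missing))
    stop("summary does not match the expected schema; missing: ",
         paste(missing, collapse = ", "))
  fmt_pct_tab <- function(tab, title) {
    tab <- as.data.frame(do.call(rbind, lapply(tab, function(r)
      unlist(r))), stringsAsFactors = FALSE)
    c(sprintf("## %s", title),
      sprintf("  %-22s %8s %7s", "category", "count", "pct"),
      sprintf("  %-22s %8s %7s", tab$category, tab$count, tab$pct), "")
  }
  fmt_enrich <- function(rows, title) {
    if (identical(rows, "not run") || is.null(rows))
      return(c(sprintf("## %s", title), "  not run", ""))
    if (!is.null(rows$enrichment)) rows <- rows$enrichment
    c(sprintf("## %s", title),
      sprintf("  %-18s %9s %11s %9s %11s", "category", "observed",
              "expected", "rpd", "p_adj"),
      vapply(rows, function(r)
        sprintf("  %-18s %9s %11.2f %8.1f%% %11.3g", r$category,
                r$observed, as.numeric(r$expected), as.numeric(r$rpd),
                as.numeric(r$pvalue_adj)), character(1)), "")
  }
  as_tab <- function(x) lapply(seq_len(NROW(x)), function(i)
    if (is.data.frame(x)) as.list(x[i, ]) else x[[i]])
  s <- summary
  lines <- c(
    "# Binding-site integration report", "",
    sprintf("seed %s | %s peaks | %s genes | %s expression records",
            s$meta$seed, s$meta$n_peaks, s$meta$n_genes,
            s$meta$n_expression), "",
    fmt_pct_tab(as_tab(s$fig2c), "Distance to nearest TSS"),
    fmt_enrich(if (is.data.frame(s$fig2d$enrichment))
      list(enrichment = as_tab(s$fig2d$enrichment)) else s$fig2d,
      "Distance enrichment vs shuffle null"),
    fmt_pct_tab(as_tab(s$fig2e), "Feature classification"),
    fmt_enrich(if (is.data.frame(s$fig2f$enrichment))
      list(enrichment = as_tab(s$fig2f$enrichment)) else s$fig2f,
      "Feature enrichment vs shuffle null"),
    fmt_enrich(if (is.data.frame(s$fig3a)) as_tab(s$fig3a) else s$fig3a,
               "Distance x accessibility enrichment"),
    "## Differential expression",
    sprintf("  up %s | down %s | non %s", s$fig4a$up, s$fig4a$down,
            s$fig4a$non),
    sprintf("  DEG bound %.1f%% vs non-DEG %.1f%% (chi2 p = %.3g)",
            as.numeric(s$fig4b$prop_a), as.numeric(s$fig4b$prop_b),
            as.numeric(s$fig4b$pvalue)), "",
    "## Targets",
    sprintf("  activated %s + repressed %s = %s dependent targets",
            s$targets$activated, s$targets$repressed, s$targets$total),
    if (!is.null(s$targets$known))
      sprintf("  known hypoxia %s | novel %s", s$targets$known,
              s$targets$novel) else NULL,
    "")
  structure(lines, class = "hifmap_report")
}

#' @export
print.hifmap_report <- function(x, ...) {
  cat(paste(unclass(x), collapse = "\n"))
  invisible(x)
}

#' @export
print.hifmap_summary <- function(x, ...) {
  print(pipeline_report(x))
  invisible(x)
}
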