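TARGET_WINDOW <- 100000

#' Reduce peak annotation to gene-level binding summaries
#'
#' A gene is "bound" when it is the nearest-neighbor gene of at least one
#' peak. For each gene the minimal absolute TSS distance over its assigned
#' peaks is recorded (+Inf when unbound), together with per-stratum flags
#' set when *any* assigned peak falls in that stratum: within 3 kb, 3-10 kb,
#' 10-100 kb, and within 100 kb. A gene may carry several flags.
#'
#' @param ann A `hif_annotation` from [assign_nearest_tss()] or
#'   [annotate_peaks()].
#' @param genes The [gene_table]; genes with no assigned peak appear as
#'   unbound rows.
#' @return `data.frame` with one row per gene: `gene_id`, `is_bound`,
#'   `min_abs_distance`, `bound_within_3kb`, `bound_3_10kb`,
#'   `bound_10_100kb`, `bound_within_100kb`.
#' @export
summarize_gene_binding <- function(ann, genes) {
  out <- data.frame(gene_id = genes$gene_id, is_bound = FALSE,
                    min_abs_distance = Inf, bound_within_3kb = FALSE,
                    bound_3_10kb = FALSE, bound_10_100kb = FALSE,
                    bound_within_100kb = FALSE, stringsAsFactors = FALSE)
  ok <- !is.na(ann$nearest_gene) & is.finite(ann$abs_distance)
  if (any(ok)) {
    d <- ann$abs_distance[ok]
    g <- ann$nearest_gene[ok]
    agg <- function(f, subset = rep(TRUE, length(d)))
      tapply(d[subset], g[subset], f)
    mins <- tapply(d, g, min)
    i <- match(names(mins), out$gene_id)
    keep <- !is.na(i)
    i <- i[keep]; mins <- mins[keep]
    out$is_bound[i] <- TRUE
    out$min_abs_distance[i] <- as.numeric(mins)
    flag <- function(sel) {
      hit <- unique(g[sel])
      out$gene_id %in% hit
    }
    out$bound_within_3kb <- flag(d <= 3000)
    out$bound_3_10kb <- flag(d > 3000 & d <= 10000)
    out$bound_10_100kb <- flag(d > 10000 & d <= 100000)
    out$bound_within_100kb <- flag(d <= 100000)
  }
  out
}

#' Call differentially expressed genes
#'
#' `up` when `log2fc > lfc_threshold` and `pvalue < alpha`; `down` when
#' `log2fc < -lfc_threshold` and `pvalue < alpha`; `non` otherwise.
#'
#' @param records `data.frame` with `gene_id`, `log2fc`, `pvalue` (see
#'   [read_expression_table()]).
#' @param lfc_threshold Absolute log2 fold-change threshold (> 0).
#' @param alpha P-value threshold.
#' @return The input with a `status` factor column (`up`, `down`, `non`);
#'   the up/down/non totals are attached as attribute `counts`.
#' @export
classify_deg <- function(records, lfc_threshold = 0.6, alpha = 0.05) {
  stopifnot(lfc_threshold > 0, alpha > 0)
  status <- ifelse(records$pvalue < alpha & records$log2fc > lfc_threshold,
                   "up",
            ifelse(records$pvalue < alpha & records$log2fc < -lfc_threshold,
                   "down", "non"))
  records$status <- factor(status, levels = c("up", "down", "non"))
  attr(records, "counts") <- as.list(table(records$status))
  records
}

#' Pearson chi-square association between two bound/total groups
#'
#' Tests whether the proportion of bound genes differs between two groups
#' (e.g. DEGs vs non-DEGs) with a 2x2 Pearson chi-square, df = 1, no
#' continuity correction unless requested.
#'
#' @param group_a,group_b Length-2 vectors `c(bound, total)`.
#' @param correct Apply the Yates continuity correction.
#' @return List with `statistic`, `pvalue`, `prop_a`, `prop_b` (percent
#'   bound per group) and the 2x2 `table`.
#' @export
association_2x2 <- function(group_a, group_b, correct = FALSE) {
  stopifnot(length(group_a) == 2L, length(group_b) == 2L)
  if (group_a[2L] <= 0 || group_b[2L] <= 0) stop("group total must be > 0")
  if (group_a[1L] > group_a[2L] || group_b[1L] > group_b[2L])
    stop("bound count exceeds group total")
  tab <- matrix(c(group_a[1L], group_a[2L] - group_a[1L],
                  group_b[1L], group_b[2L] - group_b[1L]),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("a", "b"), c("bound", "unbound")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    zero <- if (any(colSums(tab) == 0))
      paste("column", colnames(tab)[colSums(tab) == 0][1L])
    else paste("row", rownames(tab)[rowSums(tab) == 0][1L])
    stop("degenerate 2x2 table: ", zero, " margin is zero")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), pvalue = ct$p.value,
       prop_a = 100 * group_a[1L] / group_a[2L],
       prop_b = 100 * group_b[1L] / group_b[2L],
       table = tab)
}

# Exclusive distance strata on the gene level, from the minimal assigned
# peak distance: <=3 kb, (3,10] kb, (10,100] kb.
.gene_stratum <- function(min_abs_distance) {
  ifelse(!is.finite(min_abs_distance) | min_abs_distance > 100000, NA,
  ifelse(min_abs_distance <= 3000, "0-3kb",
  ifelse(min_abs_distance <= 10000, "3-10kb", "10-100kb")))
}

#' Distance-stratified binding-DEG association
#'
#' For each comparison group (all DEGs, upregulated only, downregulated
#' only) versus non-DEGs, tests per distance stratum whether group genes are
#' more (or less) often bound in that stratum than non-DEG genes. Strata are
#' exclusive on the gene level, keyed by the minimal assigned peak distance:
#' `0-3kb`, `3-10kb`, `10-100kb`. P-values are Bonferroni corrected over the
#' strata within each comparison.
#'
#' @param degs Output of [classify_deg()].
#' @param summaries Output of [summarize_gene_binding()].
#' @param comparisons Subset of `c("deg", "up", "down")`.
#' @param correct Yates correction for the 2x2 tests.
#' @return `data.frame` with one row per comparison x stratum: counts,
#'   percent bound in each group, `chi2_stat`, `pvalue`, `pvalue_adj` and a
#'   `direction` label (`enriched`/`depleted`). Empty comparisons (no genes
#'   in a group) yield zero rows for that comparison.
#' @export
distance_stratified_association <- function(degs, summaries,
                                            comparisons = c("deg", "up",
                                                            "down"),
                                            correct = FALSE) {
  comparisons <- match.arg(comparisons, several.ok = TRUE)
  common <- intersect(degs$gene_id, summaries$gene_id)
  if (length(common) < 0.5 * nrow(degs))
    stop("more than half of the expression gene_ids are missing from the ",
         "binding annotation; check that the same gene annotation was used")
  m <- match(degs$gene_id, summaries$gene_id)
  stratum <- .gene_stratum(summaries$min_abs_distance[m])
  stratum[is.na(m)] <- NA  # genes absent from annotation count as unbound
  strata <- c("0-3kb", "3-10kb", "10-100kb")
  rows <- list()
  for (cmp in comparisons) {
    in_group <- switch(cmp, deg = degs$status != "non",
                       up = degs$status == "up",
                       down = degs$status == "down")
    ref <- degs$status == "non"
    if (!any(in_group) || !any(ref)) next
    p <- numeric(length(strata)); recs <- list()
    for (k in seq_along(strata)) {
      s <- strata[k]
      a <- c(sum(in_group & !is.na(stratum) & stratum == s), sum(in_group))
      b <- c(sum(ref & !is.na(stratum) & stratum == s), sum(ref))
      res <- association_2x2(a, b, correct = correct)
      p[k] <- res$pvalue
      recs[[k]] <- data.frame(
        comparison = cmp, stratum = s,
        group_bound = a[1L], group_total = a[2L],
        ref_bound = b[1L], ref_total = b[2L],
        group_pct = round(res$prop_a, 1), ref_pct = round(res$prop_b, 1),
        chi2_stat = res$statistic, pvalue = res$pvalue,
        direction = if (res$prop_a >= res$prop_b) "enriched" else "depleted",
        stringsAsFactors = FALSE)
    }
    block <- do.call(rbind, recs)
    block$pvalue_adj <- bonferroni_adjust(p)
    rows[[cmp]] <- block
  }
  if (length(rows) == 0L)
    return(data.frame(comparison = character(), stratum = character(),
                      group_bound = numeric(), group_total = numeric(),
                      ref_bound = numeric(), ref_total = numeric(),
                      group_pct = numeric(), ref_pct = numeric(),
                      chi2_stat = numeric(), pvalue = numeric(),
                      direction = character(), pvalue_adj = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Exact two-sided Mann-Whitney by complete enumeration of group labelings.
# Handles ties; the U null distribution is symmetric about n1*n2/2.
.mw_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  u_all <- apply(idx, 2L, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  center <- n1 * n2 / 2
  p <- mean(abs(u_all - center) >= abs(u_obs - center) - 1e-9)
  list(U = u_obs, pvalue = p)
}

#' Mann-Whitney comparison of fold-change magnitudes
#'
#' Two-sided test that bound and unbound genes have the same distribution of
#' absolute log2 fold changes. Uses exact enumeration of all group labelings
#' when both groups have at most `exact_max_n` observations (correct under
#' ties), and the normal approximation with tie correction otherwise.
#'
#' @param bound_lfcs,unbound_lfcs Numeric vectors of |log2FC| values.
#' @param exact_max_n Largest per-group size for the exact path.
#' @return List with `U` (statistic for the first group), `pvalue` and
#'   `method`.
#' @export
magnitude_test <- function(bound_lfcs, unbound_lfcs, exact_max_n = 8) {
  if (length(bound_lfcs) == 0L || length(unbound_lfcs) == 0L)
    stop("both groups must be non-empty")
  if (length(bound_lfcs) <= exact_max_n &&
      length(unbound_lfcs) <= exact_max_n) {
    res <- .mw_exact(bound_lfcs, unbound_lfcs)
    return(list(U = res$U, pvalue = res$pvalue, method = "exact"))
  }
  wt <- stats::wilcox.test(bound_lfcs, unbound_lfcs, exact = FALSE,
                           correct = TRUE)
  list(U = unname(wt$statistic), pvalue = wt$p.value,
       method = "normal-approximation")
}

#' Call distance-bounded, expression-responsive target genes
#'
#' A gene is a dependent target when it is differentially expressed (up or
#' down) and has at least one assigned binding site within `target_window`
#' bp of its TSS. Targets are `activated` (up) or `repressed` (down). When a
#' known-hypoxia gene list is supplied each target is flagged known vs novel
#' (case-insensitive symbol match).
#'
#' @param degs Output of [classify_deg()].
#' @param summaries Output of [summarize_gene_binding()].
#' @param known_hypoxia Optional character vector of known hypoxia-regulated
#'   gene symbols.
#' @param target_window Maximum TSS distance in bp (default 100 kb).
#' @return List with `calls` (per-gene `data.frame`: `gene_id`, `status`,
#'   `hif1a_dependent`, `direction`, `known_hypoxia`) and `counts`
#'   (`activated`, `repressed`, `total`, and `known`/`novel` when a list was
#'   given).
#' @export
classify_targets <- function(degs, summaries, known_hypoxia = NULL,
                             target_window = TARGET_WINDOW) {
  m <- match(degs$gene_id, summaries$gene_id)
  min_d <- summaries$min_abs_distance[m]
  min_d[is.na(m)] <- Inf
  bound <- is.finite(min_d) & min_d <= target_window
  dep <- degs$status != "non" & bound
  direction <- ifelse(dep & degs$status == "up", "activated",
               ifelse(dep & degs$status == "down", "repressed", "none"))
  calls <- data.frame(gene_id = degs$gene_id,
                      status = as.character(degs$status),
                      hif1a_dependent = dep, direction = direction,
                      stringsAsFactors = FALSE)
  counts <- list(activated = sum(direction == "activated"),
                 repressed = sum(direction == "repressed"))
  counts$total <- counts$activated + counts$repressed
  if (!is.null(known_hypoxia)) {
    calls$known_hypoxia <- toupper(calls$gene_id) %in%
      toupper(known_hypoxia)
    counts$known <- sum(dep & calls$known_hypoxia)
    counts$novel <- sum(dep & !calls$known_hypoxia)
  }
  list(calls = calls, counts = counts)
}

#' Overlap counts between DEG status and binding within the target window
#'
#' @inheritParams classify_targets
#' @return List with `up_bound`, `down_bound` (DEGs with a site within the
#'   window), `bound_nondeg` (non-DEGs with such a site), `deg_unbound`, and
#'   `total_targets = up_bound + down_bound`.
#' @export
overlap_counts <- function(degs, summaries, target_window = TARGET_WINDOW) {
  m <- match(degs$gene_id, summaries$gene_id)
  min_d <- summaries$min_abs_distance[m]
  min_d[is.na(m)] <- Inf
  bound <- is.finite(min_d) & min_d <= target_window
  list(up_bound = sum(degs$status == "up" & bound),
       down_bound = sum(degs$status == "down" & bound),
       bound_nondeg = sum(degs$status == "non" & bound),
       deg_unbound = sum(degs$status != "non" & !bound),
       total_targets = sum(degs$status != "non" & bound))
}
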