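make_degs <- function(status) {
  n <- length(status)
  lfc <- ifelse(status == "up", 1, ifelse(status == "down", -1, 0))
  p <- ifelse(status == "non", 0.5, 0.001)
  classify_deg(data.frame(gene_id = sprintf("g%04d", seq_len(n)),
                          log2fc = lfc, pvalue = p,
                          stringsAsFactors = FALSE))
}

make_summaries <- function(gene_id, min_dist) {
  data.frame(gene_id = gene_id, is_bound = is.finite(min_dist),
             min_abs_distance = min_dist,
             bound_within_3kb = min_dist <= 3000,
             bound_3_10kb = min_dist > 3000 & min_dist <= 10000,
             bound_10_100kb = min_dist > 10000 & min_dist <= 100000,
             bound_within_100kb = min_dist <= 100000,
             stringsAsFactors = FALSE)
}

test_that("gene binding summaries match a per-gene brute-force scan", {
  set.seed(19)
  for (i in 1:5) {
    genome <- random_genome()
    genes <- random_genes(genome, 100)
    peaks <- random_peaks(genome, 300)
    ann <- suppressMessages(assign_nearest_tss(peaks, genes))
    summ <- summarize_gene_binding(ann, genes)
    for (j in sample.int(100, 25)) {
      g <- genes$gene_id[j]
      d <- ann$abs_distance[!is.na(ann$nearest_gene) &
                              ann$nearest_gene == g]
      row <- summ[summ$gene_id == g, ]
      expect_equal(row$is_bound, length(d) > 0)
      expect_equal(row$min_abs_distance,
                   if (length(d)) min(d) else Inf)
      expect_equal(row$bound_within_3kb, any(d <= 3000))
      expect_equal(row$bound_3_10kb, any(d > 3000 & d <= 10000))
      expect_equal(row$bound_10_100kb, any(d > 10000 & d <= 100000))
      expect_equal(row$bound_within_100kb, any(d <= 100000))
    }
  }
  # a gene with peaks at 2 kb and 50 kb carries both stratum flags
  genes <- gene_table("gX", "chr1", "+", 100000, 101000)
  peaks <- peak_set("chr1", c(97900, 49900), c(98100, 50100))
  summ <- summarize_gene_binding(assign_nearest_tss(peaks, genes), genes)
  expect_true(summ$bound_within_3kb && summ$bound_10_100kb)
  expect_equal(summ$min_abs_distance, 2000)
})

test_that("DEG classification follows thresholds and is monotone", {
  rec <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                    log2fc = c(0.7, -0.61, 2.0, 0.6, 0.59),
                    pvalue = c(0.01, 0.049, 0.2, 0.01, 0.01))
  d <- classify_deg(rec)
  expect_identical(as.character(d$status),
                   c("up", "down", "non", "non", "non"))
  cnt <- attr(d, "counts")
  expect_equal(cnt$up + cnt$down + cnt$non, nrow(rec))

  set.seed(6)
  rec <- data.frame(gene_id = sprintf("g%d", 1:500),
                    log2fc = rnorm(500, 0, 1), pvalue = runif(500))
  n_deg <- vapply(c(0.2, 0.6, 1.0, 1.5), function(th) {
    d <- classify_deg(rec, lfc_threshold = th)
    sum(d$status != "non")
  }, numeric(1))
  expect_true(all(diff(n_deg) <= 0))
})

test_that("2x2 association matches hand summation and the exact test", {
  res <- association_2x2(c(212, 528), c(940, 16777))
  expect_equal(res$prop_a, 100 * 212 / 528)
  res0 <- association_2x2(c(10, 100), c(20, 200))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$pvalue, 1)
  expect_error(association_2x2(c(0, 10), c(0, 20)), "degenerate")
  expect_error(association_2x2(c(5, 0), c(1, 2)), "total")

  set.seed(14)
  for (i in 1:50) {
    tot <- sample(c(50, 80, 120), 1)
    a <- c(sample(1:(tot - 1), 1), tot)
    b <- c(sample(1:(tot - 1), 1), tot)
    res <- association_2x2(a, b)
    tab <- matrix(c(a[1], a[2] - a[1], b[1], b[2] - b[1]), 2,
                  byrow = TRUE)
    o <- as.vector(tab)
    e <- as.vector(outer(rowSums(tab), colSums(tab)) / sum(tab))
    expect_equal(res$statistic, sum((o - e)^2 / e), tolerance = 1e-9)
    # conditional hypergeometric enumeration (doubled one-sided mid-p)
    # agrees within the known chi-square/exact discrepancy envelope
    m1 <- sum(tab[1, ]); n1 <- sum(tab[2, ]); k1 <- sum(tab[, 1])
    up <- stats::phyper(tab[1, 1] - 1, m1, n1, k1, lower.tail = FALSE) -
      0.5 * stats::dhyper(tab[1, 1], m1, n1, k1)
    expect_lt(abs(res$pvalue - min(1, 2 * min(up, 1 - up))), 0.1)
  }
})

test_that("stratified association recovers planted direction effects", {
  set.seed(25)
  hits <- 0
  for (s in 1:20) {
    n <- 600
    min_d <- ifelse(runif(n) < 0.25,
                    sample(c(1000, 5000, 50000), n, replace = TRUE,
                           prob = c(.4, .4, .2)), Inf)
    stratum <- ifelse(min_d <= 3000, "prox",
               ifelse(min_d <= 10000 & is.finite(min_d), "mid", "other"))
    status <- rep("non", n)
    status[stratum == "prox" & runif(n) < 0.6] <- "up"
    status[stratum == "mid" & runif(n) < 0.55] <- "down"
    other <- stratum == "other" & runif(n) < 0.03
    status[other] <- sample(c("up", "down"), sum(other), replace = TRUE)
    degs <- make_degs(status)
    summ <- make_summaries(degs$gene_id, min_d)
    res <- distance_stratified_association(degs, summ)
    up3 <- res[res$comparison == "up" & res$stratum == "0-3kb", ]
    dn10 <- res[res$comparison == "down" & res$stratum == "3-10kb", ]
    if (nrow(up3) && nrow(dn10) &&
        up3$direction == "enriched" && up3$pvalue_adj < 0.05 &&
        dn10$direction == "enriched" && dn10$pvalue_adj < 0.05)
      hits <- hits + 1
  }
  expect_gte(hits, 18)

  # all genes non-DEG: explicit empty result, no test performed
  degs <- make_degs(rep("non", 50))
  summ <- make_summaries(degs$gene_id, rep(Inf, 50))
  expect_equal(nrow(distance_stratified_association(degs, summ)), 0)

  # mismatched gene universes are rejected
  degs2 <- make_degs(c("up", "non", "non", "down"))
  summ2 <- make_summaries(c("x1", "x2", "x3", "x4"), rep(Inf, 4))
  expect_error(distance_stratified_association(degs2, summ2), "gene_id")
})

test_that("Mann-Whitney magnitude test is exact for small samples", {
  res <- magnitude_test(c(3, 4, 5), c(0, 1, 2))
  expect_equal(res$U, 9)
  expect_equal(res$pvalue, 0.1)
  expect_identical(res$method, "exact")

  same <- magnitude_test(c(1, 2, 3), c(1, 2, 3))
  expect_gte(same$pvalue, 0.99)
  expect_error(magnitude_test(numeric(0), 1), "non-empty")

  set.seed(33)
  for (i in 1:30) {
    x <- sample(0:5, sample(3:6, 1), replace = TRUE)
    y <- sample(0:5, sample(3:6, 1), replace = TRUE)
    expect_equal(magnitude_test(x, y)$pvalue, oracle_mw_perm(x, y),
                 tolerance = 1e-12)
  }
  # large-sample path agrees with the base implementation
  set.seed(34)
  x <- abs(rnorm(60, 1)); y <- abs(rnorm(80))
  res <- magnitude_test(x, y)
  wt <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(res$pvalue, wt$p.value)
  expect_identical(res$method, "normal-approximation")
})

test_that("target calls honor the distance window and known-gene split", {
  degs <- make_degs(c("up", "down", "up", "non"))
  summ <- make_summaries(degs$gene_id, c(40000, 150000, 2000, 1000))
  res <- classify_targets(degs, summ,
                          known_hypoxia = c(degs$gene_id[1], "ZZZ"))
  expect_identical(res$calls$direction,
                   c("activated", "none", "activated", "none"))
  expect_equal(res$counts$total, 2)
  expect_equal(res$counts$known, 1)
  expect_equal(res$counts$novel, 1)

  oc <- overlap_counts(degs, summ)
  expect_equal(oc$up_bound, 2)
  expect_equal(oc$down_bound, 0)
  expect_equal(oc$deg_unbound, 1)
  expect_equal(oc$bound_nondeg, 1)
  expect_equal(oc$total_targets, res$counts$total)

  # no binding at all
  summ0 <- make_summaries(degs$gene_id, rep(Inf, 4))
  oc0 <- overlap_counts(degs, summ0)
  expect_equal(oc0$up_bound + oc0$down_bound, 0)

  # counts equal a brute-force set-intersection oracle
  set.seed(41)
  for (i in 1:10) {
    n <- 200
    status <- sample(c("up", "down", "non"), n, TRUE, c(.1, .1, .8))
    min_d <- ifelse(runif(n) < 0.4,
                    floor(runif(n, 0, 2e5)), Inf)
    degs <- make_degs(status)
    summ <- make_summaries(degs$gene_id, min_d)
    oc <- overlap_counts(degs, summ)
    bound_set <- degs$gene_id[min_d <= 1e5]
    up_set <- degs$gene_id[status == "up"]
    down_set <- degs$gene_id[status == "down"]
    expect_equal(oc$up_bound, length(intersect(up_set, bound_set)))
    expect_equal(oc$down_bound, length(intersect(down_set, bound_set)))
    expect_equal(oc$bound_nondeg,
                 length(setdiff(bound_set, union(up_set, down_set))))
    expect_equal(oc$total_targets, oc$up_bound + oc$down_bound)
  }
})
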