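test_that("shuffle preserves lengths, respects bounds, and is seeded", {
  genome <- hif_genome(c(chr1 = 1000))
  p <- peak_set("chr1", 0, 100)
  reps <- shuffle_intervals(p, genome, n_replicates = 50, seed = 1)
  for (r in reps) {
    expect_true(all(r$start >= 0 & r$start <= 900))
    expect_equal(r$end - r$start, 100)
  }
  r1 <- shuffle_intervals(p, genome, n_replicates = 5, seed = 99)
  r2 <- shuffle_intervals(p, genome, n_replicates = 5, seed = 99)
  expect_identical(r1, r2)

  # multiset of interval lengths preserved per replicate
  genome2 <- random_genome()
  set.seed(2)
  peaks <- random_peaks(genome2, 100)
  rep1 <- shuffle_intervals(peaks, genome2, n_replicates = 3, seed = 3)
  for (r in rep1)
    expect_equal(sort(r$end - r$start), sort(peaks$end - peaks$start))

  expect_error(shuffle_intervals(peak_set("chr1", 0, 2000), genome, 1),
               "longer than every chromosome")
})

test_that("shuffle placement is length-weighted and uniform within chroms", {
  genome <- hif_genome(c(big = 900, small = 100))
  p <- peak_set("big", 0, 1)
  reps <- shuffle_intervals(p, genome, n_replicates = 10000, seed = 7)
  chroms <- vapply(reps, function(r) r$chrom, character(1))
  phat <- mean(chroms == "big")
  se <- sqrt(0.9 * 0.1 / 10000)
  expect_lt(abs(phat - 0.9), 3 * se)
  # starts on the big chromosome pass a uniformity goodness-of-fit
  starts <- vapply(reps, function(r) r$start, numeric(1))
  starts <- starts[chroms == "big"]
  cnt <- table(cut(starts, seq(0, 900, by = 90), include.lowest = TRUE))
  expect_gt(stats::chisq.test(cnt)$p.value, 0.01)
})

test_that("expected distributions conserve totals and match coverage", {
  genome <- hif_genome(c(chr1 = 1e5))
  genes <- gene_table(sprintf("g%02d", 1:10), "chr1", "+",
                      seq(5000, 95000, by = 10000),
                      seq(5000, 95000, by = 10000) + 2000)
  peaks <- peak_set("chr1", seq(0, 990, by = 10), seq(0, 990, by = 10) + 5)
  reps <- shuffle_intervals(peaks, genome, n_replicates = 1, seed = 5)
  e1 <- expected_distribution(reps, genes, what = "feature")
  ann1 <- suppressMessages(annotate_peaks(reps[[1]], genes))
  expect_equal(e1$expected, colMeans(rbind(as.numeric(table(ann1$feature)))),
               ignore_attr = TRUE)
  expect_equal(sum(e1$expected), nrow(peaks))

  # promoter windows (+/-3kb around 10 TSS, clipped) tile ~60.5% of the
  # genome; the expected promoter fraction under the null must agree
  reps50 <- shuffle_intervals(peak_set("chr1", 1:200, 2:201), genome,
                              n_replicates = 50, seed = 6)
  e50 <- expected_distribution(reps50, genes, what = "feature")
  win <- IRanges::reduce(IRanges::IRanges(pmax(genes$tss - 3000, 0) + 1,
                                          genes$tss + 3000 + 1))
  frac <- sum(IRanges::width(win)) / 1e5
  expect_lt(abs(e50$expected[["promoter"]] / 200 - frac), 0.03)
})

test_that("relative percentage difference follows its definition", {
  expect_equal(relative_percentage_difference(100, 100), 0)
  expect_equal(relative_percentage_difference(150, 100), 50)
  expect_error(relative_percentage_difference(5, 0), "n_replicates")
  set.seed(4)
  o <- sample.int(200, 100, replace = TRUE)
  e <- runif(100, 1, 200)
  expect_identical(sign(relative_percentage_difference(o, e)),
                   sign(o - e))
})

test_that("chi-square GOF matches hand computation and the summation oracle", {
  res <- gof_chi_square(c(50, 50), c(25, 25))
  expect_equal(res$statistic, 0)
  expect_equal(res$pvalue, 1)
  res <- gof_chi_square(c(10, 0), c(0.5, 0.5))
  expect_equal(res$statistic, 10)
  expect_equal(res$df, 1)
  expect_error(gof_chi_square(c(1, 2), c(0, 3)), "positive")

  set.seed(12)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    o <- sample.int(100, k, replace = TRUE)
    e <- runif(k, 0.5, 20)
    expect_equal(gof_chi_square(o, e)$statistic, oracle_chisq(o, e),
                 tolerance = 1e-9)
  }
})

test_that("Bonferroni adjustment caps at 1 and preserves order", {
  expect_equal(bonferroni_adjust(0.01, m = 4), 0.04)
  expect_equal(bonferroni_adjust(0.5, m = 4), 1)
  expect_error(bonferroni_adjust(1.2), "outside")
  expect_error(bonferroni_adjust(c(0.1, 0.2), m = 1), "m must be")
  set.seed(23)
  for (i in 1:20) {
    p <- runif(sample(2:10, 1))
    adj <- bonferroni_adjust(p)
    expect_identical(order(adj), order(pmin(1, length(p) * p)))
    expect_equal(adj, pmin(1, length(p) * p))
  }
})

test_that("joint distance x accessibility enrichment is directional", {
  set.seed(77)
  genome <- hif_genome(c(chr1 = 5e5, chr2 = 5e5))
  genes <- random_genes(genome, 20)
  # plant every peak at a TSS inside an ATAC region
  gi <- sample.int(20, 120, replace = TRUE)
  ref <- genes$tss[gi]
  start <- pmax(0, ref - 100)
  peaks <- peak_set(genes$chrom[gi], start, start + 200)
  atac <- data.frame(chrom = genes$chrom, start = pmax(0, genes$tss - 500),
                     end = genes$tss + 500)
  ann <- annotate_peaks(peaks, genes, atac)
  reps <- shuffle_intervals(peaks, genome, n_replicates = 40, seed = 9)
  rep_anns <- annotate_replicates(reps, genes, atac)
  je <- joint_distance_accessibility_enrichment(ann, rep_anns)
  open <- grepl(":open$", je$category)
  expect_true(all(je$rpd[open & je$observed > 0] > 0))
  expect_true(all(je$rpd[!open] <= 0))
  expect_equal(sum(je$observed), nrow(peaks))
})
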