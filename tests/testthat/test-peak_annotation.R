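toy_genes <- function() {
  gene_table(c("gA", "gB"), c("chr1", "chr1"), c("+", "-"),
             c(6500, 20000), c(12000, 70000))
}

test_that("nearest-TSS distances follow the forced-arithmetic examples", {
  genes <- toy_genes()
  p <- peak_set("chr1", 4900, 5101)  # ref 5000, TSS gA at 6500
  ann <- assign_nearest_tss(p, genes)
  expect_identical(ann$nearest_gene, "gA")
  expect_equal(ann$abs_distance, 1500)
  expect_equal(as.character(ann$distance_bin), "0-3kb")
  # upstream of a plus-strand TSS: negative signed distance
  expect_equal(ann$signed_distance, -1500)

  # a peak whose reference point equals a TSS
  p0 <- peak_set("chr1", 6400, 6600)  # midpoint 6500
  ann0 <- assign_nearest_tss(p0, genes)
  expect_equal(ann0$abs_distance, 0)
  expect_identical(ann0$nearest_gene, "gA")

  expect_error(assign_nearest_tss(p, genes[0, ]), "empty")
})

test_that("distance binning respects closed upper edges", {
  expect_equal(as.character(bin_distance(c(0, 3000, 3001, 10000, 10001,
                                           100000, 100001))),
               c("0-3kb", "0-3kb", "3-10kb", "3-10kb", "10-100kb",
                 "10-100kb", ">100kb"))
  expect_error(bin_distance(-1), "negative")
  # membership oracle on random distances
  set.seed(3)
  d <- floor(runif(1000, 0, 2e5))
  edges <- list(`0-3kb` = c(0, 3000), `3-10kb` = c(3001, 10000),
                `10-100kb` = c(10001, 100000), `>100kb` = c(100001, Inf))
  want <- vapply(d, function(x)
    names(edges)[vapply(edges, function(e)
      x >= e[1] && x <= e[2], logical(1))], character(1))
  expect_identical(as.character(bin_distance(d)), want)
})

test_that("feature classes are exclusive, exhaustive and match the oracle", {
  genes <- toy_genes()
  # 2000 bp upstream of gA's TSS
  expect_identical(
    as.character(annotate_peaks(peak_set("chr1", 4400, 4601), genes)$feature),
    "promoter")
  # inside gB's 50-kb body, 20 kb from its TSS (at 69999), no TSS within 3 kb
  expect_identical(
    as.character(annotate_peaks(peak_set("chr1", 49900, 50101),
                                genes)$feature),
    "genebody")
  # far from everything
  expect_identical(
    as.character(annotate_peaks(peak_set("chr1", 90000, 90200),
                                genes)$feature),
    "intergenic")

  set.seed(21)
  for (i in 1:5) {
    genome <- random_genome()
    genes_r <- random_genes(genome, 30)
    peaks <- random_peaks(genome, 100)
    ann <- annotate_peaks(peaks, genes_r)
    expect_identical(as.character(ann$feature),
                     oracle_feature(peaks, genes_r))
    expect_equal(sum(table(ann$feature)), nrow(peaks))
  }
})

test_that("nearest assignment equals the all-pairs brute-force scan", {
  set.seed(17)
  for (i in 1:5) {
    genome <- random_genome()
    genes <- random_genes(genome, 50)
    peaks <- random_peaks(genome, 200)
    ann <- suppressMessages(assign_nearest_tss(peaks, genes))
    want <- oracle_nearest(peaks, genes)
    expect_identical(ann$nearest_gene, unname(want[, 1]))
    expect_equal(ann$abs_distance, as.numeric(want[, 2]))
    expect_equal(ann$abs_distance, abs(ann$signed_distance))
  }
})

test_that("nearest-TSS assignment is invariant under coordinate shifts", {
  set.seed(31)
  genome <- hif_genome(c(chr1 = 2e5))
  genes <- random_genes(genome, 20)
  peaks <- random_peaks(genome, 50, c(100, 200))
  shift <- 5000
  genes2 <- gene_table(genes$gene_id, genes$chrom, genes$strand,
                       genes$start + shift, genes$end + shift)
  peaks2 <- peak_set(peaks$chrom, peaks$start + shift, peaks$end + shift)
  a1 <- assign_nearest_tss(peaks, genes)
  a2 <- assign_nearest_tss(peaks2, genes2)
  expect_identical(a1$nearest_gene, a2$nearest_gene)
  expect_equal(a1$signed_distance, a2$signed_distance)
})

test_that("open-chromatin overlap uses half-open semantics and the oracle", {
  atac <- data.frame(chrom = "chr1", start = c(199, 200),
                     end = c(300, 300))
  p <- peak_set("chr1", 100, 200)
  expect_true(flag_open_chromatin(p, atac[1, ]))
  expect_false(flag_open_chromatin(p, atac[2, ]))

  set.seed(13)
  for (i in 1:5) {
    genome <- random_genome()
    peaks <- random_peaks(genome, 300)
    atac <- random_intervals(genome, 100)
    expect_identical(flag_open_chromatin(peaks, atac),
                     oracle_overlap(peaks, atac))
  }
  # summit mode: only the reference point counts
  p2 <- peak_set("chr1", 100, 300)  # ref 200
  expect_false(flag_open_chromatin(p2, data.frame(chrom = "chr1",
                                                  start = 100, end = 150),
                                   mode = "summit"))
  expect_true(flag_open_chromatin(p2, data.frame(chrom = "chr1",
                                                 start = 200, end = 250),
                                  mode = "summit"))
})

test_that("annotation summaries partition the peaks with 1-dp percentages", {
  pt <- percentage_table(c(promoter = 1359, genebody = 3708,
                           intergenic = 3308))
  expect_equal(pt$pct, c(16.2, 44.3, 39.5))
  expect_equal(sum(pt$count), 8375)

  set.seed(8)
  genome <- random_genome()
  genes <- random_genes(genome, 30)
  peaks <- random_peaks(genome, 500)
  atac <- random_intervals(genome, 50)
  ann <- annotate_peaks(peaks, genes, atac)
  s <- summarize_annotation(ann)
  for (tab in s) expect_equal(sum(tab$count), 500)
  # single annotated peak sits in its bin at 100%
  one <- summarize_annotation(annotate_peaks(peaks[1, ], genes))
  expect_equal(one$distance$pct[one$distance$count > 0], 100)
  expect_error(summarize_annotation(ann[0, ]), "empty")
})
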