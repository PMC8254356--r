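# Independent brute-force oracles and random fixture builders. These stay
# deliberately naive (all-pairs scans, position-by-position matching) so they
# cannot share a defect with the implementation they check.

random_genome <- function(n_chroms = 3, min_len = 1e4, max_len = 1e5) {
  len <- floor(runif(n_chroms, min_len, max_len))
  hif_genome(stats::setNames(len, paste0("chr", seq_len(n_chroms))))
}

random_genes <- function(genome, n = 50) {
  nm <- names(genome$chroms)
  chrom <- sample(nm, n, replace = TRUE)
  len <- floor(runif(n, 200, 2000))
  start <- floor(runif(n) * (genome$chroms[chrom] - len))
  gene_table(sprintf("g%03d", seq_len(n)), chrom,
             sample(c("+", "-"), n, replace = TRUE), start, start + len)
}

random_peaks <- function(genome, n = 200, len_range = c(50, 500)) {
  nm <- names(genome$chroms)
  chrom <- sample(nm, n, replace = TRUE)
  len <- floor(runif(n, len_range[1], len_range[2]))
  start <- floor(runif(n) * (genome$chroms[chrom] - len))
  peak_set(chrom, start, start + len)
}

random_intervals <- function(genome, n = 100) {
  p <- random_peaks(genome, n)
  data.frame(chrom = p$chrom, start = p$start, end = p$end,
             stringsAsFactors = FALSE)
}

# all-pairs nearest-TSS scan with lexicographic tie-break
oracle_nearest <- function(peaks, genes) {
  t(vapply(seq_len(nrow(peaks)), function(i) {
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) return(c(NA_character_, Inf))
    d <- abs(peaks$ref_point[i] - g$tss)
    cand <- g$gene_id[d == min(d)]
    c(sort(cand)[1], min(d))
  }, c(gene = "", dist = "")))
}

# O(n*m) interval overlap flags on 0-based half-open coordinates
oracle_overlap <- function(peaks, atac) {
  vapply(seq_len(nrow(peaks)), function(i) {
    any(atac$chrom == peaks$chrom[i] &
          atac$start < peaks$end[i] & atac$end > peaks$start[i])
  }, logical(1))
}

# per-peak region membership for feature classes
oracle_feature <- function(peaks, genes, window = 3000) {
  vapply(seq_len(nrow(peaks)), function(i) {
    r <- peaks$ref_point[i]
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(g) > 0 && any(abs(r - g$tss) <= window)) return("promoter")
    if (nrow(g) > 0 && any(r >= g$start & r < g$end)) return("genebody")
    "intergenic"
  }, character(1))
}

# position-by-position IUPAC matcher (both strands), counting overlaps
oracle_scan <- function(seq, pattern) {
  iupac <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
             S = "GC", W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT",
             H = "ACT", V = "ACG", N = "ACGT")
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  match_at <- function(s, pat, pos) {
    all(vapply(seq_len(nchar(pat)), function(j) {
      base <- substr(s, pos + j - 1, pos + j - 1)
      grepl(base, iupac[[substr(pat, j, j)]], fixed = TRUE)
    }, logical(1)))
  }
  rc <- paste(rev(vapply(strsplit(pattern, "")[[1]], function(ch)
    comp[[ch]], character(1))), collapse = "")
  k <- nchar(pattern)
  n <- nchar(seq)
  if (n < k) return(0L)
  hits <- 0L
  for (pos in seq_len(n - k + 1)) {
    if (match_at(seq, pattern, pos)) hits <- hits + 1L
    if (rc != pattern && match_at(seq, rc, pos)) hits <- hits + 1L
  }
  hits
}

# full permutation Mann-Whitney (labels over pooled values), two-sided
oracle_mw_perm <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  center <- n1 * n2 / 2
  us <- apply(utils::combn(n1 + n2, n1), 2, u_of)
  mean(abs(us - center) >= abs(u_obs - center) - 1e-9)
}

# term-by-term chi-square GOF (expected rescaled to observed total)
oracle_chisq <- function(obs, exp) {
  e <- exp / sum(exp) * sum(obs)
  sum((obs - e)^2 / e)
}
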