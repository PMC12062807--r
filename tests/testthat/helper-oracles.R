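# Independent brute-force oracles used to freeze expected values.

# Exact Hardy-Weinberg p by direct enumeration of the conditional
# distribution of the heterozygote count with multinomial coefficients.
oracle_hwe <- function(naa, nab, nbb) {
  n <- naa + nab + nbb
  n1 <- 2 * naa + nab
  hs <- seq(n1 %% 2, min(n1, 2 * n - n1), by = 2)
  pr <- vapply(hs, function(h) {
    exp(lfactorial(n) - lfactorial((n1 - h) / 2) - lfactorial(h) -
          lfactorial((2 * n - n1 - h) / 2) + h * log(2) -
          lchoose(2 * n, n1))
  }, numeric(1))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[hs == nab] * (1 + 1e-12)])
}

# Weir-Cockerham (1984) variance components, general-r transliteration
# with explicit sums, from per-population (n, p, h).
oracle_wc <- function(n, p, h) {
  r <- length(n)
  nbar <- sum(n) / r
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# Windowed nucleotide diversity by brute-force mean pairwise allele
# differences over every allele pair at every site in the window.
oracle_pi_window <- function(dosage, pos, start, end) {
  tot <- 0
  for (j in seq_along(pos)) {
    if (pos[j] - 1 < start || pos[j] - 1 >= end) next
    al <- unlist(lapply(dosage[, j], function(x) {
      if (is.na(x)) NULL else c(rep(1L, x), rep(0L, 2L - x))
    }))
    m <- length(al)
    if (m < 2) next
    nd <- 0; np <- 0
    for (u in seq_len(m - 1)) {
      for (v in seq(u + 1, m)) {
        nd <- nd + (al[u] != al[v])
        np <- np + 1
      }
    }
    tot <- tot + nd / np
  }
  unname(tot) / (end - start)
}

# Build a small geno object from a dosage matrix (samples x sites).
toy_geno <- function(dosage, pos = NULL, chrom = "chr1", chrom_len = NULL,
                     samples = NULL) {
  m <- ncol(dosage)
  pos <- pos %||% seq(100L, by = 100L, length.out = m)
  samples <- samples %||% sprintf("s%02d", seq_len(nrow(dosage)))
  geno(
    dosage,
    tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = "A", alt = "G"),
    samples,
    contigs = tibble::tibble(chrom = chrom,
                             length = chrom_len %||% (max(pos) + 100L))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Counts tibble for one group straight from per-population summaries.
counts_from <- function(n, alt, het, pos = seq_along(n) * 100L,
                        chrom = "chr1") {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), group = "g",
                 n_called = n, alt_count = alt, het_count = het,
                 miss_count = 0L)
}

# Dosage-level counts for a genotype vector of one population at one site.
pop_counts1 <- function(geno_vec, pos = 100L) {
  counts_from(n = sum(!is.na(geno_vec)), alt = sum(geno_vec, na.rm = TRUE),
              het = sum(geno_vec == 1, na.rm = TRUE), pos = pos)
}
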