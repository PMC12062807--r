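#' Exact Hardy-Weinberg test p-value
#'
#' Exact conditional test for Hardy-Weinberg proportions at a biallelic
#' site: conditional on the observed allele counts, the p-value is the sum
#' of the probabilities of every heterozygote count (of the same parity)
#' whose probability does not exceed that of the observed configuration.
#' This is the plain (non mid-p) exact test used by PLINK's `--hwe` filter.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (vectorised).
#' @return Numeric vector of p-values in `[0, 1]`. Sites with zero called
#'   genotypes return 1 (the test is undefined there).
#' @export
#' @examples
#' hwe_exact_p(25, 50, 25) # modal configuration: p = 1
hwe_exact_p <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- length(n_het)
  stopifnot(length(n_hom_ref) == n, length(n_hom_alt) == n)
  memo <- new.env(parent = emptyenv())
  vapply(seq_len(n), function(i) {
    hwe_exact_p_one(n_hom_ref[i], n_het[i], n_hom_alt[i], memo)
  }, numeric(1))
}

# Distribution of the heterozygote count conditional on allele counts:
# P(het = h) proportional to n! / (nAA! nAa! naa!) * 2^h, h of fixed parity.
hwe_het_logprobs <- function(n_total, n1) {
  n2 <- 2L * n_total - n1
  h <- seq.int(n1 %% 2L, min(n1, n2), by = 2L)
  lp <- lgamma(n_total + 1) - lgamma((n1 - h) / 2 + 1) - lgamma(h + 1) -
    lgamma((n2 - h) / 2 + 1) + h * log(2) +
    lgamma(n1 + 1) + lgamma(n2 + 1) - lgamma(2 * n_total + 1)
  list(h = h, lp = lp)
}

hwe_exact_p_one <- function(naa, nab, nbb, memo = NULL) {
  if (anyNA(c(naa, nab, nbb)) || naa < 0 || nab < 0 || nbb < 0) {
    abort("genotype counts must be non-negative")
  }
  n_total <- naa + nab + nbb
  if (n_total == 0L) return(1)
  n1 <- 2L * naa + nab # ref allele count; distribution is symmetric in n1
  key <- paste0(n_total, "_", min(n1, 2L * n_total - n1))
  dist <- if (!is.null(memo) && !is.null(memo[[key]])) {
    memo[[key]]
  } else {
    d <- hwe_het_logprobs(n_total, min(n1, 2L * n_total - n1))
    if (!is.null(memo)) memo[[key]] <- d
    d
  }
  p <- exp(dist$lp - max(dist$lp))
  p <- p / sum(p)
  obs <- p[match(nab, dist$h)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

site_qc_stats <- function(x) {
  d <- x$dosage
  n_called <- colSums(!is.na(d))
  alt <- colSums(d, na.rm = TRUE)
  het <- colSums(d == 1L, na.rm = TRUE)
  p <- ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
  tibble(
    chrom = x$sites$chrom, pos = x$sites$pos,
    n_called = n_called, alt_count = alt, het_count = het,
    miss_frac = 1 - n_called / length(x$samples),
    maf = pmin(p, 1 - p)
  )
}

#' Site QC: biallelic SNPs with a minimum minor-allele frequency
#'
#' Retains biallelic SNP records whose minor-allele frequency (computed on
#' called alleles) is at least `min_minor_af` and whose missing fraction is
#' at most `max_missing_frac`. Multi-allelic records and non-SNP alleles
#' are dropped, not split.
#'
#' @param x A `geno` object.
#' @param min_minor_af Minimum minor-allele frequency (default 0.01).
#' @param max_missing_frac Maximum fraction of missing genotypes
#'   (default 0.9).
#' @return A filtered `geno` object; the per-filter site tally is attached
#'   as the `"qc"` attribute (see [qc_report()]).
#' @export
filter_biallelic <- function(x, min_minor_af = 0.01, max_missing_frac = 0.9) {
  stop_if_not_geno(x)
  snp <- !grepl(",", x$sites$alt, fixed = TRUE) &
    nchar(x$sites$ref) == 1L & nchar(x$sites$alt) == 1L &
    x$sites$ref != x$sites$alt
  st <- site_qc_stats(x)
  maf_ok <- !is.na(st$maf) & st$maf >= min_minor_af
  miss_ok <- st$miss_frac <= max_missing_frac
  keep <- snp & maf_ok & miss_ok
  if (!any(keep)) warn("no sites pass the biallelic/MAF/missingness filter")
  out <- geno_subset(x, sites = keep)
  attr(out, "qc") <- dplyr::bind_rows(
    attr(x, "qc"),
    tibble(filter = c("non_snp_or_multiallelic", "low_maf", "high_missing"),
           removed = c(sum(!snp), sum(snp & !maf_ok),
                       sum(snp & maf_ok & !miss_ok)),
           retained = sum(keep))
  )
  out
}

#' Site QC: minor-allele-frequency and exact Hardy-Weinberg filters
#'
#' Removes sites with minor-allele frequency strictly below `maf_min` or an
#' exact Hardy-Weinberg test p-value (pooled across all samples) strictly
#' below `hwe_p_min`. Sites exactly at either threshold are retained.
#'
#' @param x A biallelic `geno` object.
#' @param maf_min Minimum minor-allele frequency (default 0.05).
#' @param hwe_p_min Minimum exact-test p-value (default 1e-6).
#' @return A filtered `geno` object with an updated `"qc"` attribute.
#' @export
filter_maf_hwe <- function(x, maf_min = 0.05, hwe_p_min = 1e-6) {
  stop_if_not_geno(x)
  st <- site_qc_stats(x)
  maf_ok <- !is.na(st$maf) & st$maf >= maf_min
  n_hom_alt <- (st$alt_count - st$het_count) / 2
  hwe_p <- rep(1, nrow(st))
  idx <- which(maf_ok) # HWE only decides among MAF survivors
  if (length(idx)) {
    hwe_p[idx] <- hwe_exact_p(
      st$n_called[idx] - st$het_count[idx] - n_hom_alt[idx],
      st$het_count[idx], n_hom_alt[idx]
    )
  }
  hwe_ok <- hwe_p >= hwe_p_min
  keep <- maf_ok & hwe_ok
  if (!any(keep)) warn("no sites pass the MAF/HWE filter")
  out <- geno_subset(x, sites = keep)
  attr(out, "qc") <- dplyr::bind_rows(
    attr(x, "qc"),
    tibble(filter = c("maf_lt_min", "hwe_p_lt_min"),
           removed = c(sum(!maf_ok), sum(maf_ok & !hwe_ok)),
           retained = sum(keep))
  )
  out
}

#' Tally of sites removed by each QC filter
#'
#' @param x A `geno` object that has passed through [filter_biallelic()]
#'   and/or [filter_maf_hwe()].
#' @return A tibble with columns `filter`, `removed`, `retained`, or an
#'   empty tibble when no filter has been applied.
#' @export
qc_report <- function(x) {
  attr(x, "qc") %||% tibble(filter = character(), removed = integer(),
                            retained = integer())
}
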