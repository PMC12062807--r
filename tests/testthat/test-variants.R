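write_test_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

vcf_header <- c(
  "##fileformat=VCFv4.2",
  "##contig=<ID=chr1,length=100000>",
  '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
  paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3"), collapse = "\t")
)

test_that("GT fields decode to alt-allele dosages, half and non-diploid calls to missing", {
  path <- write_test_vcf(c(
    vcf_header,
    "chr1\t100\t.\tA\tG\t.\t.\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\t.\tA\tC\t.\t.\t.\tGT\t./.\t0|1\t1/.",
    "chr1\t300\t.\tA\tT\t.\t.\t.\tGT\t0/0/1\t1|1\t0/0"
  ))
  g <- read_vcf(path)
  expect_equal(unname(g$dosage[, 1]), c(0L, 1L, 2L))
  expect_equal(unname(g$dosage[, 2]), c(NA_integer_, 1L, NA_integer_))
  expect_equal(unname(g$dosage[, 3]), c(NA_integer_, 2L, 0L))
  expect_equal(g$samples, c("s1", "s2", "s3"))
  expect_equal(g$contigs$length, 100000L)
})

test_that("simulate -> write -> read round-trips the genotype matrix", {
  sim <- simulate_three_pop(sim_config(
    n_chrom = 1, chrom_length_bp = 2e5, n_sites = 150, n_per_pop = 4,
    missing_rate = 0.05, seed = 7
  ))
  path <- tempfile(fileext = ".vcf")
  write_vcf(sim$geno, path)
  back <- read_vcf(path)
  expect_identical(unname(back$dosage), unname(sim$geno$dosage))
  expect_equal(back$sites, sim$geno$sites)
  expect_equal(back$contigs, sim$geno$contigs)
  expect_identical(back$samples, sim$geno$samples)
})

test_that("biallelic filter drops rare, missing-heavy, monomorphic and multi-allelic sites", {
  # 100 diploids: MAF 0.005 (1 alt allele), monomorphic, clean, multiallelic
  n <- 100
  d <- cbind(
    c(1L, rep(0L, n - 1)),          # MAF 0.005 -> removed
    rep(0L, n),                     # monomorphic -> removed
    rep(c(0L, 1L, 2L), length.out = n), # common -> kept
    rep(1L, n)                      # multiallelic record below -> removed
  )
  g <- toy_geno(d)
  g$sites$alt[4] <- "G,T"
  out <- filter_biallelic(g)
  expect_equal(out$sites$pos, 300L)
  rep <- qc_report(out)
  expect_equal(rep$removed[rep$filter == "non_snp_or_multiallelic"], 1L)

  # missingness boundary: 95% missing removed, exactly 90% kept
  d2 <- matrix(NA_integer_, 20, 2)
  d2[20, 1] <- 0L              # 19/20 = 95% missing
  d2[c(1, 20), 2] <- c(0L, 2L) # 18/20 = 90% missing exactly
  g2 <- toy_geno(d2)
  out2 <- filter_biallelic(g2, min_minor_af = 0)
  expect_equal(out2$sites$pos, 200L) # 95%-missing site dropped, 90% kept
})

test_that("MAF/HWE filter matches per-site hand evaluation on a crafted toy", {
  # 50 diploids x 6 sites: 2 low-MAF, 1 extreme HWE departure, 3 clean
  n <- 50
  clean <- rep(c(0L, 1L, 1L, 2L), length.out = n)
  d <- cbind(
    c(rep(1L, 2), rep(0L, n - 2)),  # MAF 0.02 < 0.05 -> removed
    c(rep(1L, 4), rep(0L, n - 4)),  # MAF 0.04 < 0.05 -> removed
    rep(c(0L, 2L), n / 2),          # no hets at p = 0.5: extreme departure
    clean, clean, clean
  )
  g <- toy_geno(d)
  expect_true(hwe_exact_p(25, 0, 25) < 1e-6) # confirms the crafted site
  out <- filter_maf_hwe(g)
  expect_equal(out$sites$pos, c(400L, 500L, 600L))
  # every survivor re-checks against both thresholds independently
  st <- group_site_counts(out, tibble::tibble(
    sample_id = out$samples, population = "p", breed = "b", type = "dual"
  ))
  p <- st$alt_count / (2 * st$n_called)
  expect_true(all(pmin(p, 1 - p) >= 0.05))
  expect_true(all(hwe_exact_p(st$n_called - st$het_count -
                                (st$alt_count - st$het_count) / 2,
                              st$het_count,
                              (st$alt_count - st$het_count) / 2) >= 1e-6))
})

test_that("exact HWE p-values match direct enumeration", {
  expect_equal(hwe_exact_p(25, 50, 25), 1.0, tolerance = 1e-12)
  expect_equal(hwe_exact_p(50, 0, 50), oracle_hwe(50, 0, 50),
               tolerance = 1e-12)
  expect_equal(hwe_exact_p(0, 2, 0), 1.0, tolerance = 1e-12)
  set.seed(42)
  for (i in 1:50) {
    n <- sample(2:100, 1)
    nab <- sample(0:n, 1)
    naa <- sample(0:(n - nab), 1)
    nbb <- n - nab - naa
    expect_equal(hwe_exact_p(naa, nab, nbb), oracle_hwe(naa, nab, nbb),
                 tolerance = 1e-12)
  }
  expect_equal(hwe_exact_p(0, 0, 0), 1) # all-missing site: undefined -> 1
})

test_that("QC result is independent of input site order", {
  set.seed(11)
  d <- matrix(sample(c(0L, 1L, 2L, NA), 30 * 40, replace = TRUE,
                     prob = c(.4, .3, .25, .05)), 30, 40)
  g <- toy_geno(d)
  perm <- sample(40)
  g_perm <- geno(d[, perm], g$sites[perm, ], g$samples, contigs = g$contigs)
  a <- filter_maf_hwe(filter_biallelic(g))
  b <- filter_maf_hwe(filter_biallelic(g_perm))
  expect_equal(a$sites, b$sites)
  expect_identical(unname(a$dosage), unname(b$dosage))
})

test_that("group counts are exact and partition to the pooled counts", {
  d <- rbind(c(0L, 2L), c(1L, NA), c(2L, 0L), c(0L, 1L), c(1L, 1L))
  g <- toy_geno(d)
  map <- tibble::tibble(sample_id = g$samples,
                        population = c("a", "a", "a", "b", "b"),
                        breed = "x", type = "dual")
  cts <- group_site_counts(g, map)
  a <- cts[cts$group == "a", ]
  expect_equal(a$n_called, c(3L, 2L))
  expect_equal(a$alt_count, c(3, 2))
  expect_equal(a$het_count, c(1L, 0L))
  pooled <- group_site_counts(g, dplyr::mutate(map, population = "all"))
  expect_equal(a$alt_count + cts$alt_count[cts$group == "b"],
               pooled$alt_count)
  expect_error(group_site_counts(g, map, groups = "zebra"), "unknown group")
})

test_that("GFF3 gene features convert to half-open intervals with strand", {
  path <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t100\t200\t.\t+\t.\tID=gene1;Name=G1",
    "chr1\tsrc\tmRNA\t100\t200\t.\t+\t.\tID=rna1;Parent=gene1",
    "chr1\tsrc\tgene\t300\t450\t.\t-\t.\tID=gene2"
  ), path)
  genes <- read_gff_genes(path)
  expect_equal(nrow(genes), 2)
  expect_equal(genes$start, c(99L, 299L))
  expect_equal(genes$end, c(200L, 450L))
  expect_equal(genes$strand, c("+", "-"))

  empty <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tmRNA\t1\t10\t.\t+\t.\tID=r"), empty)
  expect_warning(g0 <- read_gff_genes(empty), "no gene features")
  expect_equal(nrow(g0), 0)
})
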