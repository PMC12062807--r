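test_that("site Fst hits the fixation and all-heterozygote anchors exactly", {
  # pop1 fixed ref, pop2 fixed alt -> theta = 1
  c1 <- counts_from(n = 5L, alt = 0, het = 0L)
  c2 <- counts_from(n = 5L, alt = 10, het = 0L)
  expect_equal(wc_fst_site(c1, c2)$theta, 1)
  # both populations entirely heterozygous, equal n -> a = 0, theta = 0
  c3 <- counts_from(n = 6L, alt = 6, het = 6L)
  out <- wc_fst_site(c3, c3)
  expect_equal(out$a, 0, tolerance = 1e-15)
  expect_equal(out$theta, 0, tolerance = 1e-15)
})

test_that("site Fst components match the independent WC84 evaluation", {
  # pop1 = {AA, AA, Aa}, pop2 = {aa, aa, Aa} with alt = a
  c1 <- pop_counts1(c(0L, 0L, 1L))
  c2 <- pop_counts1(c(2L, 2L, 1L))
  got <- wc_fst_site(c1, c2)
  ref <- oracle_wc(n = c(3, 3), p = c(1 / 6, 5 / 6), h = c(1 / 3, 1 / 3))
  expect_equal(got$a, unname(ref["a"]), tolerance = 1e-12)
  expect_equal(got$b, unname(ref["b"]), tolerance = 1e-12)
  expect_equal(got$c, unname(ref["c"]), tolerance = 1e-12)
  expect_equal(got$theta, unname(ref["theta"]), tolerance = 1e-12)
})

test_that("sites unusable for the estimator are masked", {
  # both monomorphic for the same allele
  expect_true(is.na(wc_fst_site(counts_from(3L, 0, 0L),
                                counts_from(4L, 0, 0L))$theta))
  # a population with no called individuals
  expect_true(is.na(wc_fst_site(counts_from(0L, 0, 0L),
                                counts_from(4L, 4, 2L))$theta))
  # mean sample size of 1 leaves the components undefined
  expect_true(is.na(wc_fst_site(counts_from(1L, 2, 0L),
                                counts_from(1L, 0, 0L))$theta))
})

test_that("windowed Fst is the ratio of component sums", {
  c1 <- counts_from(n = c(5L, 5L), alt = c(0, 2), het = c(0L, 2L),
                    pos = c(1000L, 2000L))
  c2 <- counts_from(n = c(5L, 5L), alt = c(10, 7), het = c(0L, 3L),
                    pos = c(1000L, 2000L))
  comp <- wc_fst_site(c1, c2)
  contigs <- tibble::tibble(chrom = "chr1", length = 10000L)
  tr <- windowed_fst(comp, contigs, window = 10000, step = 10000)
  expect_equal(tr$value, sum(comp$a) / sum(comp$a + comp$b + comp$c),
               tolerance = 1e-12)
  expect_equal(tr$mean_theta, mean(comp$theta), tolerance = 1e-12)
  # a window whose every site is fully fixed has Fst exactly 1
  cf1 <- counts_from(n = c(4L, 4L), alt = c(0, 0), het = c(0L, 0L),
                     pos = c(1000L, 2000L))
  cf2 <- counts_from(n = c(4L, 4L), alt = c(8, 8), het = c(0L, 0L),
                     pos = c(1000L, 2000L))
  trf <- windowed_fst(wc_fst_site(cf1, cf2), contigs, window = 10000,
                      step = 10000)
  expect_equal(trf$value, 1)
})

test_that("LSBL follows the half-difference formula and the additive identity", {
  grid <- tibble::tibble(chrom = "chr1", start = 0L, end = 50000L,
                         n_snps = 20L)
  mk <- function(v) dplyr::mutate(grid, value = v)
  out <- lsbl(mk(0.3), mk(0.2), mk(0.1), focal = "X")
  expect_equal(out$value, 0.2)
  # symmetric star: all pairwise Fst equal v -> each branch v/2
  sym <- lsbl(mk(0.4), mk(0.4), mk(0.4))
  expect_equal(sym$value, 0.2)
  # grid mismatch rejected
  expect_error(lsbl(mk(0.3), mk(0.2), dplyr::mutate(mk(0.1), start = 1L)),
               "grid")
})

test_that("top-quantile region calling selects q of the windows and merges overlaps", {
  set.seed(2)
  vals <- sample(seq(0.001, 1, length.out = 1000))
  track <- tibble::tibble(
    chrom = "chr1", start = seq(0L, by = 25000L, length.out = 1000),
    end = seq(0L, by = 25000L, length.out = 1000) + 50000L,
    n_snps = 20L, value = vals
  )
  rg <- top_quantile_regions(track, q = 0.01)
  expect_equal(sum(rg$n_windows), 10) # 1% of 1000 distinct values
  expect_true(all(track$value[track$value >= attr(rg, "threshold")] %in%
                    sort(vals, decreasing = TRUE)[1:10]))
  # overlapping selected windows merge into one region
  two <- tibble::tibble(chrom = "chr1", start = c(0L, 25000L),
                        end = c(50000L, 75000L), n_snps = 20L,
                        value = c(10, 9))
  filler <- tibble::tibble(chrom = "chr1",
                           start = seq(100000L, by = 25000L, length.out = 98),
                           end = seq(100000L, by = 25000L, length.out = 98) +
                             50000L,
                           n_snps = 20L, value = seq(0.01, 0.98, length.out = 98))
  rg2 <- top_quantile_regions(dplyr::bind_rows(two, filler), q = 0.02)
  expect_equal(nrow(rg2), 1)
  expect_equal(rg2$start, 0L)
  expect_equal(rg2$end, 75000L)
  expect_equal(rg2$peak, 10)
  # result invariant to window order
  shuffled <- dplyr::bind_rows(two, filler)[sample(100), ]
  expect_equal(top_quantile_regions(shuffled, q = 0.02), rg2,
               ignore_attr = TRUE)
})

test_that("masked and sparse windows stay out of the quantile computation", {
  track <- tibble::tibble(
    chrom = "chr1", start = seq(0L, by = 50000L, length.out = 100),
    end = seq(0L, by = 50000L, length.out = 100) + 50000L,
    n_snps = c(rep(20L, 99), 2L),
    value = c(seq(0.01, 0.99, length.out = 99), 100)
  )
  rg <- top_quantile_regions(track, q = 0.01, min_snps = 10)
  expect_false(any(rg$peak == 100)) # the sparse window cannot be selected
  all_masked <- dplyr::mutate(track, value = NA_real_)
  expect_equal(nrow(top_quantile_regions(all_masked)), 0)
})

test_that("pi-ratio scan intersects ratio tails with the Fst tail", {
  expect_equal(log2(0.002 / 0.001), 1) # ratio orientation: dual over egg
  n <- 200
  start <- seq(0L, by = 50000L, length.out = n)
  base <- tibble::tibble(chrom = "chr1", start = start, end = start + 50000L,
                         n_snps = 20L)
  set.seed(10)
  pi_e <- dplyr::mutate(base, value = stats::runif(n, 0.8e-3, 1.2e-3))
  pi_d <- dplyr::mutate(base, value = pi_e$value)
  fst <- dplyr::mutate(base, value = stats::runif(n, 0, 0.05))
  # equal pi everywhere: every ratio is 0, no tail survives the intersection
  res0 <- pi_ratio_scan(pi_e, pi_d, fst, q = 0.05)
  expect_equal(nrow(res0$egg), 0)
  expect_equal(nrow(res0$dual), 0)
  # depress egg pi and raise Fst in one window: egg-selected region appears
  pi_e$value[7] <- 1e-5
  fst$value[7] <- 0.9
  res1 <- pi_ratio_scan(pi_e, pi_d, fst, q = 0.05)
  expect_true(any(res1$egg$start <= start[7] & res1$egg$end >= start[7]))
  expect_error(pi_ratio_scan(pi_e[-1, ], pi_d, fst), "grid")
})

test_that("gene annotation uses half-open interval overlap", {
  genes <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1",
                          start = c(99L, 500L), end = c(200L, 600L),
                          strand = "+")
  regions <- tibble::tibble(chrom = "chr1", start = c(150L, 200L, 0L),
                            end = c(300L, 300L, 1000L), peak = 1,
                            n_windows = 1L)
  ann <- annotate_regions(regions, genes)
  expect_equal(ann$genes, c("g1", "", "g1,g2"))
  expect_equal(ann$n_genes, c(1L, 0L, 2L))
  expect_warning(annotate_regions(regions, genes[0, ]), "empty gene set")
})

test_that("fine rescan aligns its grid to the region and localises the sweep", {
  sweep <- tibble::tibble(population = "commercial", chrom = "chr1",
                          start = 800000L, end = 1300000L,
                          target_freq = 0.98)
  sim <- simulate_three_pop(sim_config(
    n_chrom = 1, chrom_length_bp = 4e6, n_sites = 4000, n_per_pop = 15,
    sweep_windows = sweep, seed = 17
  ))
  region <- tibble::tibble(chrom = "chr1", start = 700000L, end = 1400000L)
  fs <- fine_scan(sim$geno, sim$sample_map, region, window = 10000,
                  step = 5000)
  expect_equal(fs$lsbl$start[1], 700000L)
  expect_true(all(diff(fs$lsbl$start) == 5000))
  expect_true(all(fs$lsbl$end <= 1400000L))
  expect_equal(sort(unique(fs$pi$population)),
               c("commercial", "local", "wild"))
  peak <- fs$lsbl[which.max(fs$lsbl$value), ]
  expect_true(peak$start < sweep$end && peak$end > sweep$start)
  # a region smaller than one fine window yields a single-window track
  small <- fine_scan(sim$geno, sim$sample_map,
                     tibble::tibble(chrom = "chr1", start = 100000L,
                                    end = 104000L),
                     window = 10000, step = 5000)
  expect_equal(nrow(small$lsbl), 1)
  expect_equal(small$lsbl$end, 104000L)
})
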