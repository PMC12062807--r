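test_that("identical configs give byte-identical VCF output", {
  cfg <- sim_config(n_chrom = 1, chrom_length_bp = 5e5, n_sites = 400,
                    n_per_pop = 5, missing_rate = 0.02, seed = 9)
  p1 <- tempfile(fileext = ".vcf"); p2 <- tempfile(fileext = ".vcf")
  write_vcf(simulate_three_pop(cfg)$geno, p1)
  write_vcf(simulate_three_pop(cfg)$geno, p2)
  expect_identical(readLines(p1), readLines(p2))
  # and a different seed changes the data
  cfg2 <- sim_config(n_chrom = 1, chrom_length_bp = 5e5, n_sites = 400,
                     n_per_pop = 5, missing_rate = 0.02, seed = 10)
  p3 <- tempfile(fileext = ".vcf")
  write_vcf(simulate_three_pop(cfg2)$geno, p3)
  expect_false(identical(readLines(p1), readLines(p3)))
})

test_that("with zero drift on every branch the genome-wide Fst is null", {
  sim <- simulate_three_pop(sim_config(
    n_chrom = 1, chrom_length_bp = 3e6, n_sites = 3000, n_per_pop = 12,
    f_wild = 0, f_local = 0, f_commercial = 0,
    n_founder_haplotypes = 800, egg_dual = NULL, seed = 61
  ))
  cw <- group_site_counts(sim$geno, sim$sample_map, groups = "wild")
  cc <- group_site_counts(sim$geno, sim$sample_map, groups = "commercial")
  comp <- wc_fst_site(cw, cc)
  ok <- !is.na(comp$a)
  theta_gw <- sum(comp$a[ok]) / sum((comp$a + comp$b + comp$c)[ok])
  expect_lt(abs(theta_gw), 0.01)
  # zero drift also copies ancestral frequencies unchanged
  expect_equal(sim$truth$freqs$p_wild, sim$truth$freqs$p_anc)
})

test_that("a sweep window depresses diversity far below the genome-wide mean", {
  ratios <- vapply(1:20, function(s) {
    sim <- simulate_three_pop(sim_config(
      n_chrom = 1, chrom_length_bp = 2e6, n_sites = 2000, n_per_pop = 8,
      sweep_windows = tibble::tibble(population = "commercial",
                                     chrom = "chr1", start = 500000L,
                                     end = 1000000L, target_freq = 0.98),
      seed = 100 + s
    ))
    gc <- geno_subset(sim$geno,
                      samples = grepl("commercial", sim$geno$samples))
    tr <- windowed_pi(gc, window = 50000, step = 50000)
    inside <- tr$start >= 500000 & tr$end <= 1000000
    mean(tr$value[inside]) / mean(tr$value)
  }, numeric(1))
  expect_lt(mean(ratios), 0.25)
})

test_that("Balding-Nichols drift is recovered from the He regression", {
  f_true <- 0.2
  sim <- simulate_three_pop(sim_config(
    n_chrom = 1, chrom_length_bp = 10e6, n_sites = 10000,
    n_per_pop = c(wild = 2, local = 2, commercial = 40),
    f_commercial = f_true, n_founder_haplotypes = 100, egg_dual = NULL,
    seed = 71
  ))
  gc <- geno_subset(sim$geno, samples = grepl("commercial", sim$geno$samples))
  cts <- group_site_counts(gc, sim$sample_map, groups = "commercial")
  he <- site_het(cts)$he
  x <- 2 * sim$truth$freqs$p_anc * (1 - sim$truth$freqs$p_anc)
  slope <- sum(he * x) / sum(x * x)
  expect_lt(abs(slope - (1 - f_true)), 0.05)
})

test_that("faster founder switching weakens short-range LD monotonically", {
  mean_r2_short <- function(rate) {
    tot <- 0; n <- 0
    for (s in 1:3) {
      sim <- simulate_three_pop(sim_config(
        n_chrom = 1, chrom_length_bp = 4e6, n_sites = 4000,
        n_per_pop = c(wild = 2, local = 2, commercial = 30),
        n_founder_haplotypes = c(wild = 10, local = 10, commercial = 10),
        switch_rate = rate, seed = s
      ))
      gc <- geno_subset(sim$geno,
                        samples = grepl("commercial", sim$geno$samples))
      b <- ld_decay(gc, max_dist = 10000, bin_width = 10000)
      tot <- tot + b$mean_r2[1] * b$n_pairs[1]
      n <- n + b$n_pairs[1]
    }
    tot / n
  }
  r2s <- vapply(c(1e-8, 1e-7, 1e-6), mean_r2_short, numeric(1))
  expect_true(all(diff(r2s) <= 0))
})

test_that("the egg/dual split nests inside the local population with its own sweeps", {
  sweep <- tibble::tibble(chrom = "chr1", start = 200000L, end = 600000L,
                          target_freq = 0.95)
  sim <- simulate_three_pop(sim_config(
    n_chrom = 1, chrom_length_bp = 2e6, n_sites = 1500, n_per_pop = 10,
    egg_dual = list(egg_fraction = 0.4, f_egg = 0.05, f_dual = 0.05,
                    sweep_windows = sweep),
    seed = 81
  ))
  expect_equal(sum(sim$sample_map$type == "egg"), 4)
  expect_equal(sum(sim$sample_map$type == "dual"), 6)
  expect_true(all(sim$sample_map$population[sim$sample_map$type %in%
                                              c("egg", "dual")] == "local"))
  tr <- sim$truth
  expect_equal(tr$sweeps$population, "egg")
  in_sweep <- tr$freqs$pos - 1 >= 200000 & tr$freqs$pos - 1 < 600000
  expect_equal(tr$freqs$p_egg[in_sweep],
               rep(0.95, sum(in_sweep)))
  expect_false(all(tr$freqs$p_dual[in_sweep] == 0.95))
})

test_that("invalid configurations are rejected", {
  sw <- function(...) tibble::tibble(...)
  expect_error(sim_config(f_wild = 1), "drift")
  expect_error(sim_config(n_per_pop = 1), "n_per_pop")
  expect_error(sim_config(sweep_windows = sw(
    population = "commercial", chrom = "chr1", start = 0L, end = 1e5L,
    target_freq = 0.4)), "target_freq")
  expect_error(sim_config(sweep_windows = sw(
    population = c("commercial", "commercial"), chrom = "chr1",
    start = c(0L, 50000L), end = c(100000L, 150000L),
    target_freq = 0.98)), "overlapping")
  expect_error(sim_config(n_chrom = 1, chrom_length_bp = 1e6,
                          roh_tracts = sw(sample_id = "wild_001",
                                          chrom = "chr1", start = 0L,
                                          end = 2e6L)),
               "outside")
  expect_error(sim_config(sweep_windows = sw(
    population = "commercial", chrom = "chr9", start = 0L, end = 1e5L,
    target_freq = 0.98)), "unknown chromosome")
  # non-overlapping sweeps on different branches are fine
  expect_s3_class(sim_config(sweep_windows = sw(
    population = c("commercial", "local"), chrom = "chr1",
    start = c(0L, 50000L), end = c(100000L, 150000L),
    target_freq = 0.98)), "sim_config")
})

test_that("truth files round-trip losslessly", {
  sim <- simulate_three_pop(sim_config(
    n_chrom = 2, chrom_length_bp = 3e5, n_sites = 120, n_per_pop = 4,
    sweep_windows = tibble::tibble(population = "commercial", chrom = "chr2",
                                   start = 0L, end = 100000L,
                                   target_freq = 0.9),
    roh_tracts = tibble::tibble(sample_id = "wild_002", chrom = "chr1",
                                start = 10000L, end = 250000L),
    seed = 91
  ))
  path <- tempfile(fileext = ".tsv")
  write_truth(sim$truth, path)
  back <- read_truth(path)
  expect_equal(back$freqs, sim$truth$freqs)
  expect_equal(back$sweeps, sim$truth$sweeps)
  expect_equal(back$tracts, sim$truth$tracts)
  expect_equal(back$seed, sim$truth$seed)

  # an empty truth writes a header-only file
  p0 <- tempfile(fileext = ".tsv")
  write_truth(sim_truth(), p0)
  expect_equal(length(readLines(p0)), 1)

  # two sweeps produce exactly two sweep rows
  t2 <- sim_truth(sweeps = tibble::tibble(
    population = c("commercial", "local"), chrom = "chr1",
    start = c(0L, 200000L), end = c(100000L, 300000L),
    target_freq = c(0.98, 0.9)
  ))
  p2 <- tempfile(fileext = ".tsv")
  write_truth(t2, p2)
  tab <- readr::read_tsv(p2, show_col_types = FALSE)
  expect_equal(sum(tab$record == "sweep"), 2)
})
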