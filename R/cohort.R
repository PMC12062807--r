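#' Reference duck resequencing cohort metadata
#'
#' Breed-level metadata for the 416-duck whole-genome resequencing cohort
#' (22 Chinese breeds across wild, local and commercial populations) whose
#' design the simulator's defaults emulate: breed, population, production
#' type (wild / egg / dual-purpose / meat), sampling location, sample
#' count and mean sequencing depth.
#'
#' @return A tibble with columns `population`, `breed`, `count`, `type`,
#'   `location`, `depth_x`.
#' @export
duck_cohort <- function() {
  readr::read_tsv(
    system.file("extdata", "duck_cohort.tsv", package = "lsblscan",
                mustWork = TRUE),
    col_types = readr::cols(count = "i", depth_x = "d", .default = "c"),
    progress = FALSE
  )
}

#' SNP sharing across the three reference populations
#'
#' Post-QC SNP totals for the reference cohort: counts per population,
#' the three-way shared count, per-population unique counts, and the
#' grand total.
#'
#' @return A tibble with columns `category`, `n_snps`.
#' @export
snp_sharing <- function() {
  readr::read_tsv(
    system.file("extdata", "snp_sharing.tsv", package = "lsblscan",
                mustWork = TRUE),
    col_types = readr::cols(category = "c", n_snps = "d"),
    progress = FALSE
  )
}

#' Percentage of SNPs shared by all three populations
#'
#' @param sharing SNP-sharing tibble (default [snp_sharing()]).
#' @return A single percentage: 100 x shared / total.
#' @export
shared_snp_percentage <- function(sharing = snp_sharing()) {
  shared <- sharing$n_snps[sharing$category == "shared_all_three"]
  total <- sharing$n_snps[sharing$category == "total"]
  100 * shared / total
}

#' Per-population sample totals of the reference cohort
#'
#' @param cohort Cohort tibble (default [duck_cohort()]).
#' @return A tibble with one row per population plus a `total` row.
#' @export
cohort_counts <- function(cohort = duck_cohort()) {
  per_pop <- cohort |>
    dplyr::group_by(population = .data$population) |>
    dplyr::summarise(n_samples = sum(.data$count), .groups = "drop")
  dplyr::bind_rows(per_pop,
                   tibble(population = "total",
                          n_samples = sum(cohort$count)))
}
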