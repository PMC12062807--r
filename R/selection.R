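#' Weir-Cockerham per-site Fst components
#'
#' Two-population Weir & Cockerham (1984) variance components computed per
#' site from group counts: `a` (among-population), `b` (between individuals
#' within populations) and `c` (within individuals), with the per-site
#' estimate `theta = a / (a + b + c)`. Sites where either population has no
#' called individuals, where the mean sample size is 1 (the components are
#' undefined), or where both populations are fixed for the same allele are
#' masked.
#'
#' @param counts1,counts2 Site-count tibbles for the two populations (rows
#'   aligned site-for-site; see [group_site_counts()]).
#' @return A tibble with columns `chrom`, `pos`, `a`, `b`, `c`, `theta`;
#'   masked sites carry `NA` components.
#' @export
wc_fst_site <- function(counts1, counts2) {
  stopifnot(nrow(counts1) == nrow(counts2),
            all(counts1$pos == counts2$pos))
  n1 <- counts1$n_called; n2 <- counts2$n_called
  p1 <- ifelse(n1 > 0, counts1$alt_count / (2 * n1), NA_real_)
  p2 <- ifelse(n2 > 0, counts2$alt_count / (2 * n2), NA_real_)
  h1 <- ifelse(n1 > 0, counts1$het_count / n1, NA_real_)
  h2 <- ifelse(n2 > 0, counts2$het_count / n2, NA_real_)
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)
  pbar <- ifelse(n1 + n2 > 0, (n1 * p1 + n2 * p2) / (n1 + n2), NA_real_)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- ifelse(n1 + n2 > 0, (n1 * h1 + n2 * h2) / (n1 + n2), NA_real_)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r -
       hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  usable <- n1 > 0 & n2 > 0 & nbar > 1 &
    !(pbar %in% c(0, 1) & s2 == 0 & hbar == 0)
  a[!usable] <- NA_real_; b[!usable] <- NA_real_; cc[!usable] <- NA_real_
  denom <- a + b + cc
  tibble(
    chrom = counts1$chrom, pos = counts1$pos, a = a, b = b, c = cc,
    theta = ifelse(usable & denom != 0, a / denom, NA_real_)
  )
}

#' Windowed Weir-Cockerham Fst
#'
#' Aggregates per-site variance components over sliding windows. The
#' default (`"weighted"`) window value is the ratio of sums
#' `sum(a) / sum(a + b + c)`; a mean-of-ratios column (`mean_theta`) is
#' also emitted. Windows with no usable site, or a non-positive component
#' sum, are masked. Negative window values are retained (not clamped) so
#' the LSBL additive identity holds exactly; `clamp = TRUE` floors them
#' at 0 for parity experiments with tools that do clamp.
#'
#' @param components Per-site component tibble from [wc_fst_site()].
#' @param contigs Contig tibble (`chrom`, `length`) defining the grid.
#' @param window,step Window and step size in bp (defaults 50000 / 25000).
#' @param grid Optional explicit grid (`chrom`, `start`, `end`).
#' @param clamp Floor negative window Fst values at 0 (default `FALSE`).
#' @return A window track tibble: `chrom`, `start`, `end`, `n_snps`,
#'   `value` (weighted Fst), `mean_theta`.
#' @export
windowed_fst <- function(components, contigs, window = 50000, step = 25000,
                         grid = NULL, clamp = FALSE) {
  usable <- !is.na(components$a)
  num <- window_apply(components, contigs,
                      values = ifelse(usable, components$a, 0),
                      usable = usable, window = window, step = step,
                      grid = grid)
  den <- window_apply(components, contigs,
                      values = ifelse(usable,
                                      components$a + components$b + components$c,
                                      0),
                      usable = usable, window = window, step = step,
                      grid = grid)
  theta_ok <- usable & !is.na(components$theta)
  th_sum <- window_apply(components, contigs,
                         values = ifelse(theta_ok, components$theta, 0),
                         usable = theta_ok, window = window, step = step,
                         grid = grid)
  value <- ifelse(num$n_snps > 0 & den$sum > 0, num$sum / den$sum, NA_real_)
  if (clamp) value <- pmax(value, 0)
  structure(
    tibble(
      chrom = num$chrom, start = num$start, end = num$end,
      n_snps = num$n_snps, value = value,
      mean_theta = ifelse(th_sum$n_snps > 0, th_sum$sum / th_sum$n_snps,
                          NA_real_)
    ),
    statistic = "fst", window = window, step = step
  )
}

#' Locus-specific branch length for a focal population
#'
#' For three populations X, Y, Z with pairwise window Fst tracks, the
#' locus-specific branch length of the focal population X is
#' `LSBL_X = (Fst_XY + Fst_XZ - Fst_YZ) / 2` per window: the length of X's
#' branch in the per-window three-population star. Windows masked in any
#' input are masked in the output.
#'
#' @param fst_xy,fst_xz,fst_yz Window tracks from [windowed_fst()] on an
#'   identical grid: the two pairs involving the focal population first,
#'   the outgroup pair last.
#' @param focal Name of the focal population (recorded on the track).
#' @return A window track tibble with columns `chrom`, `start`, `end`,
#'   `n_snps` (minimum across inputs), `value` (the LSBL), `fst_xy`,
#'   `fst_xz`, `fst_yz`.
#' @export
lsbl <- function(fst_xy, fst_xz, fst_yz, focal = "focal") {
  same_grid <- function(a, b) {
    nrow(a) == nrow(b) && all(a$chrom == b$chrom) &&
      all(a$start == b$start) && all(a$end == b$end)
  }
  if (!same_grid(fst_xy, fst_xz) || !same_grid(fst_xy, fst_yz)) {
    abort("Fst tracks are not on an identical window grid")
  }
  structure(
    tibble(
      chrom = fst_xy$chrom, start = fst_xy$start, end = fst_xy$end,
      n_snps = pmin(fst_xy$n_snps, fst_xz$n_snps, fst_yz$n_snps),
      value = (fst_xy$value + fst_xz$value - fst_yz$value) / 2,
      fst_xy = fst_xy$value, fst_xz = fst_xz$value, fst_yz = fst_yz$value
    ),
    statistic = "lsbl", focal = focal,
    window = attr(fst_xy, "window"), step = attr(fst_xy, "step")
  )
}

#' Call candidate regions from the top quantile of a window track
#'
#' The threshold is the empirical `(1 - q)` quantile of the track values
#' over unmasked windows with at least `min_snps` SNPs; windows at or above
#' it are selected and overlapping or abutting selected windows are merged
#' into regions.
#'
#' @param track A window track tibble (column `value`).
#' @param q Upper tail fraction (default 0.01).
#' @param min_snps Minimum SNPs for a window to enter the quantile
#'   computation (default 10).
#' @return A tibble of regions: `chrom`, `start`, `end`, `peak` (largest
#'   constituent value), `n_windows`; the threshold is attached as the
#'   `"threshold"` attribute. Empty when every window is masked.
#' @export
top_quantile_regions <- function(track, q = 0.01, min_snps = 10) {
  ok <- !is.na(track$value) & track$n_snps >= min_snps
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  peak = numeric(), n_windows = integer())
  if (!any(ok)) return(structure(empty, threshold = NA_real_))
  thr <- quantile(track$value[ok], 1 - q, type = 7, names = FALSE)
  sel <- track[ok & track$value >= thr, ]
  structure(merge_windows(sel), threshold = thr)
}

# Merge overlapping/abutting windows (per chromosome) into regions.
merge_windows <- function(sel) {
  sel |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      new_region = cumsum(dplyr::lag(cummax(.data$end), default = -1) < .data$start)
    ) |>
    dplyr::group_by(.data$chrom, .data$new_region) |>
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end),
      peak = max(.data$value), n_windows = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::select("chrom", "start", "end", "peak", "n_windows") |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Fine-scale rescan of a candidate region
#'
#' Recomputes the pairwise Fst tracks, the focal-population LSBL, and
#' per-population nucleotide diversity inside one region on a finer grid
#' (10-kb windows, 5-kb step by default) aligned to the region bounds.
#'
#' @param x A QC'd `geno` object.
#' @param sample_map Sample-map tibble.
#' @param region One-row region tibble (`chrom`, `start`, `end`).
#' @param pops Character vector of three population names; the first is
#'   the focal population.
#' @param window,step Fine window and step in bp (defaults 10000 / 5000).
#' @param pad Padding in bp added to both region bounds (default 0).
#' @return A list with `lsbl` (fine LSBL track) and `pi` (fine pi tracks,
#'   one row per window per population).
#' @export
fine_scan <- function(x, sample_map, region,
                      pops = c("commercial", "local", "wild"),
                      window = 10000, step = 5000, pad = 0) {
  stopifnot(nrow(region) == 1, length(pops) == 3)
  lo <- max(0, region$start - pad)
  hi <- region$end + pad
  in_region <- x$sites$chrom == region$chrom &
    (x$sites$pos - 1) >= lo & (x$sites$pos - 1) < hi
  sub <- geno_subset(x, sites = in_region)
  starts <- seq(lo, max(lo, hi - 1), by = step)
  grid <- tibble(chrom = region$chrom, start = starts,
                 end = pmin(starts + window, hi))
  if (!nrow(sub$sites)) {
    empty <- tibble(chrom = character(), start = integer(),
                    end = integer(), n_snps = integer(), value = numeric())
    return(list(lsbl = empty, pi = dplyr::mutate(empty, population = character())))
  }
  counts <- lapply(pops, function(p) {
    group_site_counts(sub, sample_map, groups = p)
  })
  comp_xy <- wc_fst_site(counts[[1]], counts[[2]])
  comp_xz <- wc_fst_site(counts[[1]], counts[[3]])
  comp_yz <- wc_fst_site(counts[[2]], counts[[3]])
  fst_xy <- windowed_fst(comp_xy, sub$contigs, grid = grid)
  fst_xz <- windowed_fst(comp_xz, sub$contigs, grid = grid)
  fst_yz <- windowed_fst(comp_yz, sub$contigs, grid = grid)
  fine_lsbl <- lsbl(fst_xy, fst_xz, fst_yz, focal = pops[1])
  pop_of <- setNames(sample_map$population, sample_map$sample_id)
  pi_tracks <- purrr::map_dfr(pops, function(p) {
    g <- geno_subset(sub, samples = pop_of[sub$samples] == p)
    dplyr::mutate(windowed_pi(g, grid = grid), population = p)
  })
  list(lsbl = fine_lsbl, pi = pi_tracks)
}

#' Two-group Fst and pi-ratio overlap scan
#'
#' Contrasts two groups (e.g. egg-laying vs dual-purpose breeds) by
#' intersecting the tails of the per-window log2 diversity ratio
#' `log2(pi_dual / pi_egg)` with the top tail of the between-group Fst:
#' windows in the top `q` of the ratio AND the top `q` of Fst are
#' candidates for selection in the first (egg) group (its diversity is
#' depressed), windows in the bottom `q` of the ratio AND the top `q` of
#' Fst for the second (dual) group. Windows where either pi is 0 or masked
#' are excluded.
#'
#' @param pi_egg,pi_dual Pi window tracks for the two groups (one grid).
#' @param fst_track Between-group Fst track on the same grid.
#' @param q Tail fraction (default 0.05).
#' @param min_snps Minimum SNPs per window (default 10).
#' @return A list with `egg` and `dual` region tibbles (merged as in
#'   [top_quantile_regions()]), and `thresholds`.
#' @export
pi_ratio_scan <- function(pi_egg, pi_dual, fst_track, q = 0.05,
                          min_snps = 10) {
  same <- nrow(pi_egg) == nrow(pi_dual) && nrow(pi_egg) == nrow(fst_track) &&
    all(pi_egg$start == pi_dual$start) && all(pi_egg$start == fst_track$start) &&
    all(pi_egg$chrom == fst_track$chrom)
  if (!same) abort("pi and Fst tracks are not on an identical window grid")
  ratio <- ifelse(pi_egg$value > 0 & pi_dual$value > 0,
                  log2(pi_dual$value / pi_egg$value), NA_real_)
  ok <- !is.na(ratio) & !is.na(fst_track$value) &
    fst_track$n_snps >= min_snps
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  peak = numeric(), n_windows = integer())
  if (!any(ok)) {
    return(list(egg = empty, dual = empty,
                thresholds = c(ratio_hi = NA, ratio_lo = NA, fst_hi = NA)))
  }
  ratio_hi <- quantile(ratio[ok], 1 - q, type = 7, names = FALSE)
  ratio_lo <- quantile(ratio[ok], q, type = 7, names = FALSE)
  fst_hi <- quantile(fst_track$value[ok], 1 - q, type = 7, names = FALSE)
  base <- tibble(chrom = fst_track$chrom, start = fst_track$start,
                 end = fst_track$end, value = fst_track$value)
  # ratio tails are strict: a flat ratio track (equal diversity in both
  # groups) has coincident tail thresholds and must select nothing
  egg_sel <- base[ok & ratio > ratio_hi & fst_track$value >= fst_hi, ]
  dual_sel <- base[ok & ratio < ratio_lo & fst_track$value >= fst_hi, ]
  list(
    egg = if (nrow(egg_sel)) merge_windows(egg_sel) else empty,
    dual = if (nrow(dual_sel)) merge_windows(dual_sel) else empty,
    thresholds = c(ratio_hi = ratio_hi, ratio_lo = ratio_lo, fst_hi = fst_hi)
  )
}

#' Attach overlapping genes to candidate regions
#'
#' A gene is attached to a region when their half-open intervals intersect.
#'
#' @param regions Region tibble (`chrom`, `start`, `end`).
#' @param genes Gene tibble from [read_gff_genes()].
#' @return `regions` with `genes` (comma-separated gene ids) and `n_genes`
#'   columns appended.
#' @export
annotate_regions <- function(regions, genes) {
  if (is.null(genes) || !nrow(genes)) {
    warn("empty gene set; regions returned unannotated")
    return(dplyr::mutate(regions, genes = "", n_genes = 0L))
  }
  hits <- purrr::map_chr(seq_len(nrow(regions)), function(i) {
    g <- genes[genes$chrom == regions$chrom[i] &
                 genes$start < regions$end[i] &
                 genes$end > regions$start[i], ]
    paste(g$gene_id, collapse = ",")
  })
  dplyr::mutate(regions, genes = hits,
                n_genes = ifelse(hits == "", 0L,
                                 lengths(strsplit(hits, ","))))
}
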