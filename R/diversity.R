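#' Per-site observed and expected heterozygosity
#'
#' For each site (and group, when `counts` carries several), observed
#' heterozygosity is the heterozygote fraction among called individuals and
#' expected heterozygosity is `2p(1-p)` with `p` the alternate-allele
#' frequency. Sites with no called individuals are masked (`NA`).
#'
#' @param counts Site-count tibble from [group_site_counts()] (columns
#'   `n_called`, `alt_count`, `het_count`).
#' @return `counts` with columns `ho`, `he` appended.
#' @export
site_het <- function(counts) {
  p <- ifelse(counts$n_called > 0, counts$alt_count / (2 * counts$n_called),
              NA_real_)
  dplyr::mutate(
    counts,
    ho = ifelse(.data$n_called > 0, .data$het_count / .data$n_called, NA_real_),
    he = 2 * p * (1 - p)
  )
}

#' Per-individual inbreeding coefficient F
#'
#' Method-of-moments excess homozygosity relative to the Hardy-Weinberg
#' expectation, computed against allele frequencies from the full sample:
#' `F = (O_hom - E_hom) / (L - E_hom)` over the individual's called sites,
#' where `E_hom` sums `1 - 2 p (1 - p) * 2n/(2n - 1)` (the unbiased
#' small-sample expected homozygosity) and `L` is the called-site count.
#'
#' @param x A QC'd `geno` object.
#' @return A tibble with columns `sample_id`, `n_sites` (called sites),
#'   `o_hom`, `e_hom`, `f`. Individuals with no informative sites are
#'   masked (`f = NA`).
#' @export
individual_f <- function(x) {
  stop_if_not_geno(x)
  d <- x$dosage
  n_j <- colSums(!is.na(d))
  p_j <- ifelse(n_j > 0, colSums(d, na.rm = TRUE) / (2 * n_j), NA_real_)
  e_hom_j <- ifelse(
    n_j > 0,
    1 - 2 * p_j * (1 - p_j) * (2 * n_j / pmax(2 * n_j - 1, 1)),
    0
  )
  called <- !is.na(d)
  hom <- called & d != 1L
  l <- rowSums(called)
  o_hom <- rowSums(hom)
  e_hom <- as.vector(called %*% e_hom_j)
  denom <- l - e_hom
  tibble(
    sample_id = x$samples, n_sites = unname(l), o_hom = unname(o_hom),
    e_hom = unname(e_hom),
    f = unname(ifelse(abs(denom) > 1e-12, (o_hom - e_hom) / denom, NA_real_))
  )
}

# Per-site unbiased heterozygosity estimator: 2 a (m - a) / (m (m - 1))
# with a = alt allele count and m = called allele count; NA when m < 2.
site_pi <- function(alt_count, n_called) {
  m <- 2 * n_called
  ifelse(m >= 2, 2 * alt_count * (m - alt_count) / (m * (m - 1)), NA_real_)
}

#' Windowed nucleotide diversity (pi)
#'
#' Sums the per-site unbiased heterozygosity estimator over sliding windows
#' and divides by the window span in bp, yielding per-bp nucleotide
#' diversity. Windows with no usable SNPs are emitted with value 0 and
#' `n_snps = 0` so tracks stay aligned across statistics; the final window
#' of each chromosome is truncated at the chromosome end and divided by its
#' actual span.
#'
#' @param x A QC'd `geno` object (subset to one population for
#'   population-level pi).
#' @param window Window size in bp (default 50000).
#' @param step Step size in bp (default 25000).
#' @param grid Optional explicit window grid: a tibble with columns
#'   `chrom`, `start`, `end` overriding the regular grid (used by the
#'   fine-scale rescan).
#' @param drop_empty Drop zero-SNP windows instead of emitting them
#'   (default `FALSE`).
#' @return A window track tibble: `chrom`, `start`, `end` (half-open bp),
#'   `n_snps`, `value`; window/step recorded as attributes.
#' @export
windowed_pi <- function(x, window = 50000, step = 25000, grid = NULL,
                        drop_empty = FALSE) {
  stop_if_not_geno(x)
  d <- x$dosage
  n_called <- colSums(!is.na(d))
  pi_j <- site_pi(colSums(d, na.rm = TRUE), n_called)
  usable <- !is.na(pi_j)
  track <- window_apply(
    x$sites, x$contigs, values = ifelse(usable, pi_j, 0),
    usable = usable, window = window, step = step, grid = grid
  )
  track$value <- track$sum / (track$end - track$start)
  track$sum <- NULL
  if (drop_empty) track <- track[track$n_snps > 0, ]
  structure(track, statistic = "pi", window = window, step = step)
}

# Apply window sums of `values` (restricted to `usable` sites) over a
# regular or explicit grid; returns chrom/start/end/n_snps/sum.
window_apply <- function(sites, contigs, values, usable, window, step,
                         grid = NULL) {
  chroms <- if (is.null(grid)) contigs$chrom else unique(grid$chrom)
  purrr::map_dfr(chroms, function(ch) {
    g <- if (is.null(grid)) {
      window_grid(contigs$length[contigs$chrom == ch], window, step)
    } else {
      grid[grid$chrom == ch, c("start", "end")]
    }
    on_ch <- sites$chrom == ch & usable
    pos0 <- sites$pos[on_ch] - 1
    ws <- window_sums(pos0, values[on_ch], g)
    tibble(chrom = ch, start = g$start, end = g$end,
           n_snps = ws$n, sum = ws$sum)
  })
}

#' Population-level diversity summary
#'
#' Tabulates mean and standard deviation per population for expected and
#' observed heterozygosity (across sites), windowed nucleotide diversity
#' (across windows), the inbreeding coefficient (across individuals), and
#' ROH segment length (across segments).
#'
#' @param het Per-site heterozygosity by population: [site_het()] applied
#'   to [group_site_counts()] output (column `group` = population).
#' @param pi_tracks Tibble of per-population pi tracks with a `population`
#'   column (rows = windows).
#' @param f Per-individual inbreeding tibble from [individual_f()].
#' @param roh Segment tibble from [detect_roh()] (may be empty).
#' @param sample_map Sample-map tibble.
#' @return A tibble with columns `population`, `metric`, `mean`, `sd`, `n`,
#'   `degenerate` (`TRUE` where fewer than two observations forced sd to 0).
#' @export
summarize_diversity <- function(het, pi_tracks, f, roh, sample_map) {
  pop_of <- setNames(sample_map$population, sample_map$sample_id)
  msd <- function(v) {
    v <- v[!is.na(v)]
    tibble(mean = if (length(v)) mean(v) else NA_real_,
           sd = if (length(v) > 1) sd(v) else 0,
           n = length(v), degenerate = length(v) < 2)
  }
  rows <- list()
  if (!is.null(het) && nrow(het)) {
    rows <- c(rows, list(
      het |>
        dplyr::group_by(population = .data$group) |>
        dplyr::reframe(metric = c("He", "Ho"),
                       dplyr::bind_rows(msd(.data$he), msd(.data$ho)))
    ))
  }
  if (!is.null(pi_tracks) && nrow(pi_tracks)) {
    rows <- c(rows, list(
      pi_tracks |>
        dplyr::group_by(.data$population) |>
        dplyr::reframe(metric = "Pi", msd(.data$value))
    ))
  }
  if (!is.null(f) && nrow(f)) {
    rows <- c(rows, list(
      f |>
        dplyr::mutate(population = pop_of[.data$sample_id]) |>
        dplyr::group_by(.data$population) |>
        dplyr::reframe(metric = "F", msd(.data$f))
    ))
  }
  if (!is.null(roh) && nrow(roh)) {
    rows <- c(rows, list(
      roh |>
        dplyr::mutate(population = pop_of[.data$sample_id]) |>
        dplyr::group_by(.data$population) |>
        dplyr::reframe(metric = "ROH_kb", msd(.data$length_bp / 1000))
    ))
  }
  dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$population, .data$metric)
}
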