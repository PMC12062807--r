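#' Parameters for scanning-window ROH detection
#'
#' Defaults mirror the PLINK `--homozyg` flag set used throughout:
#' 50-SNP scanning windows allowing 1 heterozygote and 5 missing calls, a
#' 5% window hit-rate threshold, segments of at least 50 SNPs and 1000 kb,
#' a density of at least one SNP per 500 kb, and a 1000-kb split gap.
#'
#' @param window_snp Scanning-window size in SNPs.
#' @param window_het Maximum heterozygous calls per homozygous window.
#' @param window_missing Maximum missing calls per homozygous window.
#' @param window_threshold Minimum fraction of homozygous windows covering
#'   a SNP for it to be eligible.
#' @param min_snp Minimum SNPs per segment.
#' @param min_kb Minimum segment length in kb.
#' @param density_kb_per_snp Maximum kb per SNP within a segment.
#' @param gap_kb Maximum inter-SNP gap in kb before a run is split.
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(window_snp = 50, window_het = 1, window_missing = 5,
                       window_threshold = 0.05, min_snp = 50, min_kb = 1000,
                       density_kb_per_snp = 500, gap_kb = 1000) {
  p <- list(window_snp = window_snp, window_het = window_het,
            window_missing = window_missing,
            window_threshold = window_threshold, min_snp = min_snp,
            min_kb = min_kb, density_kb_per_snp = density_kb_per_snp,
            gap_kb = gap_kb)
  stopifnot(all(vapply(p, function(v) is.numeric(v) && v > 0 || v == 0,
                       logical(1))),
            window_threshold > 0, window_threshold <= 1)
  structure(p, class = "roh_params")
}

#' Detect runs of homozygosity
#'
#' PLINK-style scanning-window ROH calling. Per individual and chromosome:
#' (1) a `window_snp`-SNP window slides one SNP at a time and is scored
#' homozygous when it holds at most `window_het` heterozygous and
#' `window_missing` missing calls; (2) each SNP's hit fraction is the
#' number of homozygous windows containing it divided by the number of
#' windows that contain it (edge-adjusted); SNPs with a fraction of at
#' least `window_threshold` are eligible; (3) maximal runs of consecutive
#' eligible SNPs, split wherever the gap between adjacent SNPs exceeds
#' `gap_kb`, become candidate segments; (4) candidates must meet the
#' `min_snp`, `min_kb` and density constraints.
#'
#' @param x A `geno` object (all individuals are scanned).
#' @param params A [roh_params()] list.
#' @return A tibble with columns `sample_id`, `chrom`, `start`, `end`
#'   (1-based positions of the first and last SNP in the segment),
#'   `n_snps`, `length_bp` (= end - start + 1).
#' @export
detect_roh <- function(x, params = roh_params()) {
  stop_if_not_geno(x)
  stopifnot(inherits(params, "roh_params"))
  chroms <- unique(x$sites$chrom)
  out <- purrr::map_dfr(chroms, function(ch) {
    on_ch <- which(x$sites$chrom == ch)
    pos <- x$sites$pos[on_ch]
    purrr::map_dfr(seq_along(x$samples), function(i) {
      segs <- roh_one(x$dosage[i, on_ch], pos, params)
      if (!nrow(segs)) return(segs)
      dplyr::mutate(segs, sample_id = x$samples[i], chrom = ch,
                    .before = 1)
    })
  })
  if (!nrow(out)) {
    out <- tibble(sample_id = character(), chrom = character(),
                  start = integer(), end = integer(), n_snps = integer(),
                  length_bp = integer())
  }
  out
}

# Core scanning algorithm for one individual on one chromosome.
roh_one <- function(d, pos, p) {
  empty <- tibble(start = integer(), end = integer(), n_snps = integer(),
                  length_bp = integer())
  s <- length(pos)
  w <- p$window_snp
  if (s < w) return(empty)
  het <- as.integer(!is.na(d) & d == 1L)
  mis <- as.integer(is.na(d))
  cs_het <- c(0L, cumsum(het))
  cs_mis <- c(0L, cumsum(mis))
  nw <- s - w + 1L
  win_idx <- seq_len(nw)
  hom_win <- (cs_het[win_idx + w] - cs_het[win_idx]) <= p$window_het &
    (cs_mis[win_idx + w] - cs_mis[win_idx]) <= p$window_missing
  cs_hom <- c(0L, cumsum(as.integer(hom_win)))
  # windows containing SNP i start in [i - w + 1, i] clipped to [1, nw]
  lo <- pmax(1L, seq_len(s) - w + 1L)
  hi <- pmin(seq_len(s), nw)
  hits <- cs_hom[hi + 1L] - cs_hom[lo]
  denom <- hi - lo + 1L
  eligible <- hits / denom >= p$window_threshold
  if (!any(eligible)) return(empty)
  idx <- which(eligible)
  brk <- c(TRUE, diff(idx) > 1L | diff(pos[idx]) > p$gap_kb * 1000)
  run <- cumsum(brk)
  segs <- purrr::map_dfr(split(idx, run), function(ii) {
    tibble(start = pos[ii[1]], end = pos[ii[length(ii)]],
           n_snps = length(ii),
           length_bp = pos[ii[length(ii)]] - pos[ii[1]] + 1L)
  })
  segs[
    segs$n_snps >= p$min_snp &
      segs$length_bp >= p$min_kb * 1000 &
      (segs$length_bp / 1000) / segs$n_snps <= p$density_kb_per_snp,
  ]
}

#' Summarise ROH segments per individual and population
#'
#' @param segments Segment tibble from [detect_roh()].
#' @param sample_map Sample-map tibble; individuals without segments are
#'   reported with zero totals.
#' @return A list with `by_individual` (sample_id, population, n_segments,
#'   total_kb, mean_kb) and `by_population` (population, mean and sd of
#'   segment length in kb, segment count).
#' @export
roh_summary <- function(segments, sample_map) {
  per_ind <- sample_map |>
    dplyr::select("sample_id", "population") |>
    dplyr::left_join(
      segments |>
        dplyr::group_by(.data$sample_id) |>
        dplyr::summarise(n_segments = dplyr::n(),
                         total_kb = sum(.data$length_bp) / 1000,
                         mean_kb = mean(.data$length_bp) / 1000,
                         .groups = "drop"),
      by = "sample_id"
    ) |>
    tidyr::replace_na(list(n_segments = 0L, total_kb = 0, mean_kb = 0))
  pop_of <- setNames(sample_map$population, sample_map$sample_id)
  per_pop <- if (nrow(segments)) {
    segments |>
      dplyr::mutate(population = pop_of[.data$sample_id]) |>
      dplyr::group_by(.data$population) |>
      dplyr::summarise(mean_kb = mean(.data$length_bp) / 1000,
                       sd_kb = if (dplyr::n() > 1) sd(.data$length_bp) / 1000 else 0,
                       n_segments = dplyr::n(), .groups = "drop")
  } else {
    tibble(population = character(), mean_kb = numeric(),
           sd_kb = numeric(), n_segments = integer())
  }
  list(by_individual = per_ind, by_population = per_pop)
}
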