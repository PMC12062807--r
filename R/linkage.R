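#' Genotype r-squared between two sites
#'
#' Squared Pearson correlation of dosage vectors over pairwise-complete
#' individuals. Undefined (NA) when fewer than two complete pairs remain or
#' either site is monomorphic among them.
#'
#' @param a,b Dosage vectors of equal length (0/1/2/NA).
#' @return A single r-squared value in `[0, 1]`, or `NA`.
#' @export
genotype_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  if (var(a) == 0 || var(b) == 0) return(NA_real_)
  cor(a, b)^2
}

# Vectorised r^2 for index pairs (ii, jj) into the dosage matrix, missing-
# aware: masks NA entries pairwise and accumulates moments by colSums.
pair_r2 <- function(d, ii, jj, chunk = 200000L) {
  out <- numeric(length(ii))
  for (lo in seq(1L, length(ii), by = chunk)) {
    hi <- min(lo + chunk - 1L, length(ii))
    x <- d[, ii[lo:hi], drop = FALSE]
    y <- d[, jj[lo:hi], drop = FALSE]
    ok <- !(is.na(x) | is.na(y))
    x[!ok] <- 0; y[!ok] <- 0
    n <- colSums(ok)
    sx <- colSums(x); sy <- colSums(y)
    sxx <- colSums(x * x); syy <- colSums(y * y); sxy <- colSums(x * y)
    vx <- sxx - sx^2 / n
    vy <- syy - sy^2 / n
    cv <- sxy - sx * sy / n
    r2 <- ifelse(n >= 2 & vx > 0 & vy > 0, cv^2 / (vx * vy), NA_real_)
    out[lo:hi] <- r2
  }
  out
}

#' Linkage-disequilibrium decay curve
#'
#' Bins all intra-chromosomal site pairs within `max_dist` by physical
#' distance and reports mean genotype r-squared per bin. Above
#' `max_pairs`, pairs are subsampled with the given seed.
#'
#' @param x A QC'd `geno` object (subset to one population for
#'   population-level curves).
#' @param max_dist Maximum pair distance in bp (default 500000).
#' @param bin_width Distance bin width in bp (default 10000).
#' @param max_pairs Cap on the number of pairs scored (default 2e6).
#' @param seed Seed for pair subsampling (default 1).
#' @return A tibble with columns `distance_low`, `distance_high`,
#'   `n_pairs` (pairs with a defined r-squared), `mean_r2` (`NA` for empty
#'   bins).
#' @export
ld_decay <- function(x, max_dist = 500000, bin_width = 10000,
                     max_pairs = 2e6, seed = 1) {
  stop_if_not_geno(x)
  pairs <- purrr::map(unique(x$sites$chrom), function(ch) {
    on_ch <- which(x$sites$chrom == ch)
    pos <- x$sites$pos[on_ch]
    hi <- findInterval(pos + max_dist, pos)
    cnt <- hi - seq_along(pos)
    i <- rep.int(seq_along(pos), cnt)
    j <- sequence(cnt, from = seq_along(pos) + 1L)
    list(i = on_ch[i], j = on_ch[j],
         dist = x$sites$pos[on_ch[j]] - x$sites$pos[on_ch[i]])
  })
  ii <- unlist(lapply(pairs, `[[`, "i"))
  jj <- unlist(lapply(pairs, `[[`, "j"))
  dist <- unlist(lapply(pairs, `[[`, "dist"))
  if (length(ii) > max_pairs) {
    sel <- with_local_seed(seed, sample.int(length(ii), max_pairs))
    ii <- ii[sel]; jj <- jj[sel]; dist <- dist[sel]
  }
  r2 <- if (length(ii)) pair_r2(x$dosage, ii, jj) else numeric(0)
  bin <- pmin(dist %/% bin_width, ceiling(max_dist / bin_width) - 1L)
  nb <- ceiling(max_dist / bin_width)
  ok <- !is.na(r2)
  n_pairs <- tabulate(bin[ok] + 1L, nbins = nb)
  sums <- rep(0, nb)
  if (any(ok)) {
    agg <- rowsum(r2[ok], bin[ok])
    sums[as.integer(rownames(agg)) + 1L] <- agg[, 1]
  }
  tibble(
    distance_low = (seq_len(nb) - 1L) * bin_width,
    distance_high = pmin(seq_len(nb) * bin_width, max_dist),
    n_pairs = n_pairs,
    mean_r2 = ifelse(n_pairs > 0, sums / n_pairs, NA_real_)
  )
}

#' Greedy pairwise LD pruning
#'
#' PLINK-style `--indep-pairwise` pass: within each `window_snp`-SNP
#' window, while any retained pair has r-squared above `r2_max`, the member
#' with the smaller minor-allele frequency is removed (ties remove the
#' later position); the window then slides by `step_snp` SNPs.
#'
#' @param x A QC'd `geno` object.
#' @param window_snp Window size in SNPs (default 50).
#' @param step_snp Step in SNPs (default 5).
#' @param r2_max Maximum retained pairwise r-squared (default 0.2).
#' @return Integer vector of retained site indices (columns of `x`).
#' @export
ld_prune <- function(x, window_snp = 50, step_snp = 5, r2_max = 0.2) {
  stop_if_not_geno(x)
  st <- site_qc_stats(x)
  maf <- st$maf
  keep <- rep(TRUE, nrow(x$sites))
  for (ch in unique(x$sites$chrom)) {
    on_ch <- which(x$sites$chrom == ch)
    s <- length(on_ch)
    starts <- seq(1L, max(1L, s), by = step_snp)
    for (w0 in starts) {
      idx <- on_ch[w0:min(w0 + window_snp - 1L, s)]
      repeat {
        act <- idx[keep[idx]]
        if (length(act) < 2) break
        removed <- FALSE
        done <- FALSE
        for (ai in seq_len(length(act) - 1L)) {
          for (bi in seq((ai + 1L), length(act))) {
            r2 <- genotype_r2(x$dosage[, act[ai]], x$dosage[, act[bi]])
            if (!is.na(r2) && r2 > r2_max) {
              drop <- if (isTRUE(maf[act[ai]] < maf[act[bi]])) act[ai]
                      else act[bi] # tie or smaller MAF at b: drop later site
              keep[drop] <- FALSE
              removed <- TRUE
              done <- TRUE
              break
            }
          }
          if (done) break
        }
        if (!removed) break
      }
    }
  }
  which(keep)
}

#' Effective population size from binned LD
#'
#' Inverts Sved's relation `E[r2] = 1 / (alpha + 4 N c)` per distance bin.
#' The recombination fraction is `c = map_rate * midpoint distance`, the
#' sample-size-adjusted LD is `r2_adj = mean_r2 - 1/(2 n_samples)`
#' (unphased-diploid approximation), and each bin dates the estimate at
#' `t = 1/(2c)` generations ago.
#'
#' @param bins LD-decay tibble from [ld_decay()].
#' @param n_samples Number of diploid samples behind the r-squared values.
#' @param alpha Sved constant: 1 (drift only, default) or 2.2
#'   (mutation-drift variant).
#' @param map_rate Recombination fraction per bp (default 1e-8, i.e.
#'   1 cM/Mb).
#' @return A tibble with columns `t` (generations ago), `ne`, `c`,
#'   `r2_adj`, plus the bin bounds; bins with no pairs, zero recombination
#'   fraction, or non-positive adjusted r-squared are masked (`ne = NA`).
#' @export
ne_from_ld <- function(bins, n_samples, alpha = 1, map_rate = 1e-8) {
  mid <- (bins$distance_low + bins$distance_high) / 2
  cc <- map_rate * mid
  r2_adj <- bins$mean_r2 - 1 / (2 * n_samples)
  ok <- bins$n_pairs > 0 & !is.na(bins$mean_r2) & cc > 0 & r2_adj > 0
  ne <- ifelse(ok, (1 / (4 * cc)) * (1 / r2_adj - alpha), NA_real_)
  ne[ok & ne <= 0] <- NA_real_
  tibble(
    distance_low = bins$distance_low, distance_high = bins$distance_high,
    c = cc, t = ifelse(cc > 0, 1 / (2 * cc), NA_real_),
    r2_adj = r2_adj, ne = ne
  )
}
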