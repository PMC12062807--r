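#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats cor sd quantile var setNames
#' @importFrom utils head tail
NULL

# Run code with a locally-seeded RNG, restoring the caller's RNG state.
# All stochastic entry points funnel through here so a single integer seed
# fixes the whole stream.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a stage-specific 31-bit seed from a master seed so adding stages
# never perturbs the streams of earlier ones.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  bytes <- utf8ToInt(as.character(stage))
  h <- as.numeric(seed %% .Machine$integer.max)
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Build a sliding-window grid over one chromosome
#'
#' Windows are BED-like half-open `[start, end)` intervals in bp, starting at
#' 0 and advancing by `step`; the final window is truncated at the chromosome
#' end so every emitted window lies inside the chromosome.
#'
#' @param chrom_len Chromosome length in bp.
#' @param window Window size in bp.
#' @param step Step size in bp.
#' @return A tibble with columns `start`, `end`.
#' @keywords internal
window_grid <- function(chrom_len, window, step) {
  stopifnot(window >= step, step > 0)
  starts <- seq(0L, max(0L, as.integer(chrom_len) - 1L), by = as.integer(step))
  starts <- starts[starts < chrom_len]
  tibble(start = starts, end = pmin(starts + as.integer(window), as.integer(chrom_len)))
}

# Sum a per-site numeric vector over a window grid using cumulative sums.
# `pos0` must be sorted 0-based site coordinates for one chromosome.
window_sums <- function(pos0, values, grid) {
  cs <- c(0, cumsum(values))
  lo <- findInterval(grid$start - 0.5, pos0) # sites strictly before start
  hi <- findInterval(grid$end - 0.5, pos0)   # sites with pos0 < end
  list(sum = cs[hi + 1] - cs[lo + 1], n = hi - lo)
}

stop_if_not_geno <- function(x, arg = "geno") {
  if (!inherits(x, "geno")) {
    abort(sprintf("`%s` must be a <geno> object, not %s", arg, class(x)[1]))
  }
}
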