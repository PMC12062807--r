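#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a PCA fit
#'
#' @param x A `geno_pca` object.
#' @param matrix `"scores"` (default: one row per sample per component) or
#'   `"eigenvalues"` (one row per component with explained percentages).
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.geno_pca <- function(x, matrix = c("scores", "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "scores") {
    x$scores |>
      tidyr::pivot_longer(-"sample_id", names_to = "component",
                          values_to = "score") |>
      dplyr::mutate(component = as.integer(sub("^PC", "", .data$component)))
  } else {
    tibble(component = seq_len(x$k),
           eigenvalue = x$values[seq_len(x$k)],
           explained_pct = x$explained,
           cumulative_pct = cumsum(x$explained))
  }
}

#' One-row summary of a PCA fit
#'
#' @param x A `geno_pca` object.
#' @param ... Unused.
#' @return A one-row tibble with the sample count, component count, and
#'   the percentages explained by the first two components.
#' @exportS3Method generics::glance
glance.geno_pca <- function(x, ...) {
  tibble(
    n_samples = nrow(x$scores), k = x$k,
    pc1_pct = x$explained[1],
    pc2_pct = if (x$k > 1) x$explained[2] else NA_real_
  )
}
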