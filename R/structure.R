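#' Principal component analysis of genotype dosages
#'
#' Missing dosages are imputed to the site mean, sites are centred by `2p`
#' and scaled by `sqrt(2p(1-p))` (Patterson variance standardisation;
#' monomorphic sites are dropped; `scale = "none"` gives plain centring),
#' and components come from the eigendecomposition of the sample
#' covariance matrix. Each component is oriented so that its
#' largest-magnitude sample coordinate is positive, making output signs
#' reproducible across runs.
#'
#' @param x A QC'd `geno` object.
#' @param k Number of components to return (default 10, capped at the
#'   sample count).
#' @param scale `"patterson"` (default) or `"none"`.
#' @return An object of class `geno_pca` with elements `scores` (tibble:
#'   `sample_id`, `PC1..PCk`), `explained` (percent of total positive
#'   eigenvariance per component), `values` (eigenvalues), `k`.
#' @export
geno_pca <- function(x, k = 10, scale = c("patterson", "none")) {
  stop_if_not_geno(x)
  scale <- match.arg(scale)
  n <- length(x$samples)
  if (k > n) abort("k exceeds the number of samples")
  d <- x$dosage
  n_j <- colSums(!is.na(d))
  mean_j <- ifelse(n_j > 0, colSums(d, na.rm = TRUE) / n_j, 0)
  p <- mean_j / 2
  poly <- p > 0 & p < 1 & n_j > 0
  d <- d[, poly, drop = FALSE]
  mean_j <- mean_j[poly]; p <- p[poly]
  xm <- sweep(d, 2, mean_j)
  xm[is.na(xm)] <- 0
  if (scale == "patterson") {
    xm <- sweep(xm, 2, sqrt(2 * p * (1 - p)), "/")
  }
  cv <- tcrossprod(xm) / ncol(xm)
  eig <- eigen(cv, symmetric = TRUE)
  vals <- eig$values
  pos <- pmax(vals, 0)
  vecs <- eig$vectors[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-|coordinate| entry positive
  for (j in seq_len(k)) {
    m <- which.max(abs(vecs[, j]))
    if (vecs[m, j] < 0) vecs[, j] <- -vecs[, j]
  }
  scores <- vecs %*% diag(sqrt(pos[seq_len(k)]), nrow = k)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(
    list(
      scores = dplyr::bind_cols(tibble(sample_id = x$samples),
                                as_tibble(scores)),
      explained = 100 * pos[seq_len(k)] / sum(pos),
      values = vals, k = k
    ),
    class = "geno_pca"
  )
}

#' @export
print.geno_pca <- function(x, ...) {
  cat(sprintf("<geno_pca> %d samples, %d components; PC1 %.2f%%, PC2 %.2f%%\n",
              nrow(x$scores), x$k, x$explained[1],
              if (x$k > 1) x$explained[2] else NA))
  invisible(x)
}

#' Identity-by-state distance matrix
#'
#' For each sample pair, the per-site allele-sharing similarity is
#' `(2 - |dosage_i - dosage_j|) / 2` averaged over sites called in both
#' individuals; the distance is one minus that mean. Pairs with no
#' co-called site are masked (`NA`).
#'
#' @param x A QC'd `geno` object.
#' @return A symmetric numeric matrix with zero diagonal, sample ids as
#'   dimnames.
#' @export
ibs_distance <- function(x) {
  stop_if_not_geno(x)
  d <- x$dosage
  called <- !is.na(d)
  ind <- lapply(0:2, function(v) {
    m <- called & d == v
    storage.mode(m) <- "double"
    m
  })
  cd <- called; storage.mode(cd) <- "double"
  n_co <- tcrossprod(cd)
  absdiff <- tcrossprod(ind[[1]], ind[[2]]) + tcrossprod(ind[[2]], ind[[1]]) +
    tcrossprod(ind[[2]], ind[[3]]) + tcrossprod(ind[[3]], ind[[2]]) +
    2 * (tcrossprod(ind[[1]], ind[[3]]) + tcrossprod(ind[[3]], ind[[1]]))
  dist <- ifelse(n_co > 0, (absdiff / 2) / n_co, NA_real_)
  diag(dist) <- 0
  dimnames(dist) <- list(x$samples, x$samples)
  dist
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via `ape::nj`) on a symmetric distance
#' matrix, returning an unrooted tree as a Newick string. Negative branch
#' lengths are floored at zero with the deficit shifted to the sister
#' branch sharing the same internal node, preserving path lengths between
#' the affected tips' neighborhoods as closely as possible.
#'
#' @param d Symmetric distance matrix (at least 3 taxa).
#' @param labels Optional tip labels (defaults to `rownames(d)`).
#' @return A Newick string; the `phylo` object is attached as the
#'   `"phylo"` attribute.
#' @export
nj_tree <- function(d, labels = NULL) {
  d <- as.matrix(d)
  if (nrow(d) < 3) abort("neighbor joining needs at least 3 taxa")
  if (!is.null(labels)) dimnames(d) <- list(labels, labels)
  if (is.null(rownames(d))) {
    dimnames(d) <- list(paste0("t", seq_len(nrow(d))),
                        paste0("t", seq_len(nrow(d))))
  }
  phy <- ape::nj(stats::as.dist(d))
  neg <- which(phy$edge.length < 0)
  for (e in neg) {
    parent <- phy$edge[e, 1]
    sisters <- setdiff(which(phy$edge[, 1] == parent), e)
    if (length(sisters)) {
      phy$edge.length[sisters[1]] <-
        phy$edge.length[sisters[1]] + phy$edge.length[e]
    }
    phy$edge.length[e] <- 0
  }
  structure(ape::write.tree(phy), phylo = phy)
}
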