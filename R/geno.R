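#' Genotype matrix container
#'
#' A `geno` object holds an individuals-by-sites dosage matrix (count of
#' alternate alleles: 0, 1, 2, or `NA` for missing) plus ordered site and
#' sample metadata. It is the substrate for every statistic in the package.
#'
#' @param dosage Integer matrix, samples in rows, sites in columns; entries
#'   in `{0, 1, 2, NA}`.
#' @param sites Tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   one row per matrix column, sorted by `(chrom, pos)`.
#' @param samples Character vector of sample ids, one per matrix row.
#' @param contigs Optional tibble with columns `chrom`, `length` (bp). When
#'   absent, chromosome lengths default to the largest observed position.
#' @return A `geno` object.
#' @export
geno <- function(dosage, sites, samples, contigs = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  sites <- as_tibble(sites)
  stopifnot(
    nrow(sites) == ncol(dosage),
    length(samples) == nrow(dosage),
    all(c("chrom", "pos", "ref", "alt") %in% names(sites))
  )
  ord <- order(sites$chrom, sites$pos)
  if (!identical(ord, seq_len(nrow(sites)))) {
    sites <- sites[ord, ]
    dosage <- dosage[, ord, drop = FALSE]
  }
  if (anyDuplicated(paste(sites$chrom, sites$pos))) {
    abort("duplicate (chrom, pos) entries in `sites`")
  }
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    abort("dosages must be 0, 1, 2 or NA")
  }
  rownames(dosage) <- samples
  if (is.null(contigs)) {
    contigs <- sites |>
      dplyr::group_by(.data$chrom) |>
      dplyr::summarise(length = max(.data$pos), .groups = "drop")
  }
  structure(
    list(dosage = dosage, sites = sites, samples = as.character(samples),
         contigs = as_tibble(contigs)),
    class = "geno"
  )
}

#' @export
print.geno <- function(x, ...) {
  cat(sprintf(
    "<geno> %d samples x %d sites on %d contig(s); %.2f%% missing\n",
    length(x$samples), nrow(x$sites), nrow(x$contigs),
    100 * mean(is.na(x$dosage))
  ))
  invisible(x)
}

#' @export
dim.geno <- function(x) dim(x$dosage)

#' Subset a genotype matrix
#'
#' @param x A `geno` object.
#' @param samples Sample ids or logical/integer index over samples; `NULL`
#'   keeps all.
#' @param sites Logical or integer index over sites; `NULL` keeps all.
#' @return A `geno` object.
#' @export
geno_subset <- function(x, samples = NULL, sites = NULL) {
  stop_if_not_geno(x)
  si <- if (is.null(samples)) seq_along(x$samples) else {
    if (is.character(samples)) match(samples, x$samples) else seq_along(x$samples)[samples]
  }
  if (anyNA(si)) abort("unknown sample id in `samples`")
  vi <- if (is.null(sites)) seq_len(nrow(x$sites)) else seq_len(nrow(x$sites))[sites]
  geno(x$dosage[si, vi, drop = FALSE], x$sites[vi, ], x$samples[si],
       contigs = x$contigs)
}

#' Read a VCF file into a genotype matrix
#'
#' Parses the GT field of a VCFv4.2 file. Dosage is the count of alternate
#' alleles; half-calls, non-diploid genotypes and genotypes carrying an
#' allele index above 1 (multi-allelic calls) are recorded as missing.
#' Multi-allelic records themselves are retained here and removed by
#' [filter_biallelic()].
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @return A `geno` object.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) abort("VCF has no GT field")
  gt <- sub(":.*$", "", gt)
  codes <- sort(unique(as.vector(gt)), na.last = TRUE)
  dose_of <- vapply(codes, function(g) {
    if (is.na(g)) return(NA_integer_)
    al <- strsplit(gsub("\\|", "/", g), "/", fixed = TRUE)[[1]]
    if (length(al) != 2L || any(al == ".")) return(NA_integer_)
    ai <- suppressWarnings(as.integer(al))
    if (anyNA(ai) || any(ai > 1L)) return(NA_integer_)
    sum(ai)
  }, integer(1))
  dosage <- matrix(dose_of[match(as.vector(gt), codes)],
                   nrow = nrow(gt), ncol = ncol(gt))
  sites <- tibble(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT
  )
  if (anyDuplicated(paste(sites$chrom, sites$pos))) {
    abort("duplicate positions in VCF")
  }
  contigs <- NULL
  meta <- v@meta
  ctg <- grep("^##contig=", meta, value = TRUE)
  if (length(ctg)) {
    id <- sub('.*ID=([^,>]+).*', "\\1", ctg)
    len <- suppressWarnings(as.integer(sub('.*length=([0-9]+).*', "\\1", ctg)))
    if (!anyNA(len)) contigs <- tibble(chrom = id, length = len)
  }
  geno(t(dosage), sites, colnames(gt), contigs = contigs)
}

#' Write a genotype matrix to a VCF file
#'
#' Emits GT-only VCFv4.2 with contig lines, suitable for round-tripping
#' through [read_vcf()]. Output is byte-stable for identical inputs.
#'
#' @param x A `geno` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  stop_if_not_geno(x)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  d <- x$dosage
  gt <- matrix("./.", nrow = nrow(d), ncol = ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gt_code[as.character(d[ok])]
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", x$contigs$chrom, x$contigs$length),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples), collapse = "\t")
  )
  body <- paste(
    x$sites$chrom, x$sites$pos, ".", x$sites$ref, x$sites$alt, ".", ".", ".",
    "GT", apply(gt, 2, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read or write a sample map
#'
#' The sample map assigns each sample to a population (e.g. wild / local /
#' commercial), a breed, and a type (`wild`, `egg`, `dual`, `meat`).
#'
#' @param path Path to a tab-separated file with columns `sample_id`,
#'   `population`, `breed`, `type`.
#' @return A tibble.
#' @export
read_sample_map <- function(path) {
  m <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  need <- c("sample_id", "population", "breed", "type")
  if (!all(need %in% names(m))) {
    abort(paste("sample map must have columns:", paste(need, collapse = ", ")))
  }
  m
}

#' @rdname read_sample_map
#' @param map A sample-map tibble.
#' @export
write_sample_map <- function(map, path) {
  readr::write_tsv(map, path, progress = FALSE)
  invisible(path)
}

#' Read gene intervals from a GFF3 file
#'
#' Extracts `gene` features. GFF3 coordinates are 1-based inclusive; they
#' are stored 0-based half-open to match the window tracks.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`
#'   (half-open bp), `strand`. Empty (with a warning) when the file holds no
#'   gene features.
#' @export
read_gff_genes <- function(path) {
  g <- ape::read.gff(path, na.strings = c(".", "?"), GFF3 = TRUE)
  g <- g[g$type == "gene", , drop = FALSE]
  if (!nrow(g)) {
    warn("no gene features found in GFF3")
    return(tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character()))
  }
  id <- sub(".*ID=([^;]+).*", "\\1", g$attributes)
  noid <- !grepl("ID=", g$attributes)
  id[noid] <- sprintf("gene_%d", which(noid))
  tibble(
    gene_id = id, chrom = as.character(g$seqid),
    start = as.integer(g$start) - 1L, end = as.integer(g$end),
    strand = as.character(g$strand)
  ) |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Per-site allele and genotype counts by group
#'
#' Shared precomputation for the Fst and diversity statistics: for every
#' site and every group, the number of called diploid individuals, the
#' alternate-allele count, the heterozygote count, and the missing count.
#'
#' @param x A `geno` object.
#' @param sample_map Sample-map tibble (see [read_sample_map()]).
#' @param grouping Column of `sample_map` to group by (default
#'   `"population"`).
#' @param groups Optional subset of group labels; all by default.
#' @return A tibble with columns `chrom`, `pos`, `group`, `n_called`,
#'   `alt_count`, `het_count`, `miss_count`.
#' @export
group_site_counts <- function(x, sample_map, grouping = "population",
                              groups = NULL) {
  stop_if_not_geno(x)
  if (!grouping %in% names(sample_map)) {
    abort(sprintf("grouping column `%s` not in sample map", grouping))
  }
  labels <- sample_map[[grouping]][match(x$samples, sample_map$sample_id)]
  if (anyNA(labels)) abort("samples missing from sample map")
  if (is.null(groups)) groups <- sort(unique(labels))
  if (!all(groups %in% labels)) abort("unknown group requested")
  purrr::map_dfr(groups, function(gr) {
    d <- x$dosage[labels == gr, , drop = FALSE]
    n_called <- colSums(!is.na(d))
    tibble(
      chrom = x$sites$chrom, pos = x$sites$pos, group = gr,
      n_called = n_called,
      alt_count = colSums(d, na.rm = TRUE),
      het_count = colSums(d == 1L, na.rm = TRUE),
      miss_count = nrow(d) - n_called
    )
  })
}
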