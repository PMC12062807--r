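#' Pipeline run configuration
#'
#' Collects every stage's settings: either a simulation block or input
#' paths, the QC thresholds, window geometry, the scan quantiles, ROH and
#' LD settings, and the master seed (per-stage seeds are derived from it
#' by stage-name hashing so adding stages never perturbs earlier streams).
#'
#' @param sim A [sim_config()] (synthetic input), or `NULL` to read files.
#' @param vcf,sample_map,gff Input paths (ignored when `sim` is given;
#'   `gff` optional).
#' @param maf_min,hwe_p_min QC thresholds.
#' @param window,step Coarse scan geometry in bp.
#' @param fine_window,fine_step Fine rescan geometry in bp.
#' @param lsbl_q Upper tail for LSBL region calling.
#' @param egg_q Tail for the Fst / pi-ratio overlap scan.
#' @param min_snps_per_window Window SNP floor for quantile computations.
#' @param roh [roh_params()] settings.
#' @param ld_max_dist,ld_bin LD decay geometry in bp.
#' @param equalize_n Per-population subsample size for LD/Ne (`NULL`
#'   disables equalisation).
#' @param pca_k Number of principal components.
#' @param focal Populations scanned by LSBL (each in turn focal).
#' @param seed Master seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), vcf = NULL, sample_map = NULL,
                       gff = NULL, maf_min = 0.05, hwe_p_min = 1e-6,
                       window = 50000, step = 25000,
                       fine_window = 10000, fine_step = 5000,
                       lsbl_q = 0.01, egg_q = 0.05,
                       min_snps_per_window = 10,
                       roh = roh_params(), ld_max_dist = 500000,
                       ld_bin = 10000, equalize_n = NULL, pca_k = 10,
                       focal = c("commercial", "local"), seed = 1) {
  stopifnot(window >= step, step > 0, lsbl_q > 0, lsbl_q < 0.5,
            egg_q > 0, egg_q < 0.5)
  structure(
    list(sim = sim, vcf = vcf, sample_map = sample_map, gff = gff,
         maf_min = maf_min, hwe_p_min = hwe_p_min, window = window,
         step = step, fine_window = fine_window, fine_step = fine_step,
         lsbl_q = lsbl_q, egg_q = egg_q,
         min_snps_per_window = min_snps_per_window, roh = roh,
         ld_max_dist = ld_max_dist, ld_bin = ld_bin,
         equalize_n = equalize_n, pca_k = pca_k, focal = focal,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [run_config()] arguments; a `sim` block (its
#' keys mirroring [sim_config()]) describes synthetic input, with
#' `sweep_windows` and `roh_tracts` given as lists of records. A `roh`
#' block mirrors [roh_params()]. The parsed configuration is echoed in
#' full into the run manifest, so a run is reproducible from its outputs.
#'
#' @param path Path to a YAML file.
#' @return A [run_config()] object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  rows <- function(x) if (is.null(x)) NULL else dplyr::bind_rows(x)
  if (!is.null(y$sim)) {
    s <- y$sim
    s$sweep_windows <- rows(s$sweep_windows)
    s$roh_tracts <- rows(s$roh_tracts)
    if (!is.null(s$egg_dual) && !is.null(s$egg_dual$sweep_windows)) {
      s$egg_dual$sweep_windows <- rows(s$egg_dual$sweep_windows)
    }
    if (!is.null(s$n_per_pop)) s$n_per_pop <- unlist(s$n_per_pop)
    if (!is.null(s$n_founder_haplotypes)) {
      s$n_founder_haplotypes <- unlist(s$n_founder_haplotypes)
    }
    y$sim <- do.call(sim_config, s)
  }
  if (!is.null(y$roh)) y$roh <- do.call(roh_params, y$roh)
  do.call(run_config, y)
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> site QC -> diversity (He/Ho, F, pi, ROH) ->
#' structure (PCA, IBS, NJ) -> LD decay and Ne -> pairwise Fst, LSBL
#' scans with top-quantile regions and fine rescans, and the egg/dual
#' Fst-and-pi-ratio scan when egg and dual types are present. All tabular
#' outputs are written as TSV under `out_dir` together with a manifest;
#' when ground truth is available the report includes a sweep-recovery
#' table.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param verbose Print one progress line per stage.
#' @return A list of stage results: `geno`, `sample_map`, `truth`,
#'   `diversity`, `structure`, `ld`, `selection`, `recovery`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  manifest <- list()
  outputs <- list()
  say <- function(stage, msg) {
    if (verbose) message(sprintf("[%s] %s", stage, msg))
    manifest[[length(manifest) + 1]] <<- tibble(
      stage = stage, detail = msg,
      seed = derive_seed(config$seed, stage) %||% NA_integer_
    )
  }

  # -- input ----------------------------------------------------------
  truth <- NULL
  if (!is.null(config$sim)) {
    sim_cfg <- config$sim
    sim_cfg$seed <- derive_seed(config$seed, "simulate")
    sim <- simulate_three_pop(sim_cfg)
    g <- sim$geno; smap <- sim$sample_map; truth <- sim$truth
    say("simulate", sprintf("%d samples x %d sites", length(g$samples),
                            nrow(g$sites)))
  } else {
    g <- read_vcf(config$vcf)
    smap <- read_sample_map(config$sample_map)
    say("load", sprintf("%d samples x %d sites", length(g$samples),
                        nrow(g$sites)))
  }
  genes <- if (!is.null(config$gff)) read_gff_genes(config$gff) else NULL

  # -- qc --------------------------------------------------------------
  qcd <- g |>
    filter_biallelic() |>
    filter_maf_hwe(maf_min = config$maf_min, hwe_p_min = config$hwe_p_min)
  say("qc", sprintf("%d of %d sites retained", nrow(qcd$sites),
                    nrow(g$sites)))
  outputs$qc_report <- qc_report(qcd)

  pops <- sort(unique(smap$population))
  pop_of <- setNames(smap$population, smap$sample_id)
  pop_geno <- lapply(setNames(pops, pops), function(p) {
    geno_subset(qcd, samples = pop_of[qcd$samples] == p)
  })

  # -- diversity -------------------------------------------------------
  het <- site_het(group_site_counts(qcd, smap))
  f_tbl <- individual_f(qcd)
  pi_tracks <- purrr::map_dfr(pops, function(p) {
    dplyr::mutate(windowed_pi(pop_geno[[p]], config$window, config$step),
                  population = p)
  })
  roh_segs <- detect_roh(qcd, config$roh)
  div <- summarize_diversity(het, pi_tracks, f_tbl, roh_segs, smap)
  say("diversity", sprintf("%d summary rows", nrow(div)))
  outputs$diversity_summary <- div
  outputs$pi_tracks <- pi_tracks
  outputs$inbreeding <- f_tbl
  outputs$roh_segments <- roh_segs

  # -- structure -------------------------------------------------------
  pca_fit <- geno_pca(qcd, k = min(config$pca_k, length(qcd$samples)))
  ibs <- ibs_distance(qcd)
  newick <- nj_tree(ibs)
  say("structure", sprintf("PC1 %.2f%%", pca_fit$explained[1]))
  outputs$pca_scores <- pca_fit$scores
  outputs$pca_explained <- tibble(component = seq_len(pca_fit$k),
                                  explained_pct = pca_fit$explained)

  # -- ld --------------------------------------------------------------
  ld_map <- smap
  if (!is.null(config$equalize_n)) {
    ld_map <- equalize_samples(smap, n = config$equalize_n,
                               seed = derive_seed(config$seed, "equalize"))
  }
  ld_bins <- purrr::map_dfr(pops, function(p) {
    ids <- ld_map$sample_id[ld_map$population == p]
    gg <- geno_subset(qcd, samples = intersect(qcd$samples, ids))
    dplyr::mutate(
      ld_decay(gg, max_dist = config$ld_max_dist, bin_width = config$ld_bin,
               seed = derive_seed(config$seed, paste0("ld_", p))),
      population = p, n_samples = length(gg$samples)
    )
  })
  ne_tbl <- ld_bins |>
    dplyr::group_by(.data$population) |>
    dplyr::group_modify(~ ne_from_ld(.x, n_samples = .x$n_samples[1])) |>
    dplyr::ungroup()
  say("ld", sprintf("%d bins", nrow(ld_bins)))
  outputs$ld_decay <- ld_bins
  outputs$ne <- ne_tbl

  # -- selection -------------------------------------------------------
  selection <- NULL
  recovery <- NULL
  if (all(c("wild", "local", "commercial") %in% pops)) {
    counts <- lapply(setNames(c("commercial", "local", "wild"),
                              c("commercial", "local", "wild")),
                     function(p) group_site_counts(qcd, smap, groups = p))
    comp <- list(
      cm_lc = wc_fst_site(counts$commercial, counts$local),
      cm_wt = wc_fst_site(counts$commercial, counts$wild),
      lc_wt = wc_fst_site(counts$local, counts$wild)
    )
    fst <- lapply(comp, windowed_fst, contigs = qcd$contigs,
                  window = config$window, step = config$step)
    lsbl_tracks <- list(
      commercial = lsbl(fst$cm_lc, fst$cm_wt, fst$lc_wt,
                        focal = "commercial"),
      local = lsbl(fst$cm_lc, fst$lc_wt, fst$cm_wt, focal = "local")
    )
    regions <- lapply(config$focal, function(p) {
      top_quantile_regions(lsbl_tracks[[p]], q = config$lsbl_q,
                           min_snps = config$min_snps_per_window)
    })
    names(regions) <- config$focal
    if (!is.null(genes)) {
      regions <- lapply(regions, annotate_regions, genes = genes)
    }
    fine <- lapply(config$focal, function(p) {
      rg <- regions[[p]]
      if (!nrow(rg)) return(NULL)
      top <- rg[which.max(rg$peak), ]
      pops3 <- c(p, setdiff(c("commercial", "local", "wild"), p))
      fine_scan(qcd, smap, top, pops = pops3,
                window = config$fine_window, step = config$fine_step)
    })
    names(fine) <- config$focal
    egg <- NULL
    if (all(c("egg", "dual") %in% smap$type)) {
      tmap <- dplyr::mutate(smap, population = .data$type)
      cts <- lapply(c(egg = "egg", dual = "dual"), function(p) {
        group_site_counts(qcd, tmap, groups = p)
      })
      fst_ed <- windowed_fst(wc_fst_site(cts$egg, cts$dual), qcd$contigs,
                             window = config$window, step = config$step)
      pi_egg <- windowed_pi(
        geno_subset(qcd, samples = pop_of[qcd$samples] == "local" &
                      smap$type[match(qcd$samples, smap$sample_id)] == "egg"),
        config$window, config$step)
      pi_dual <- windowed_pi(
        geno_subset(qcd, samples = smap$type[match(qcd$samples, smap$sample_id)] == "dual"),
        config$window, config$step)
      egg <- pi_ratio_scan(pi_egg, pi_dual, fst_ed, q = config$egg_q,
                           min_snps = config$min_snps_per_window)
    }
    selection <- list(fst = fst, lsbl = lsbl_tracks, regions = regions,
                      fine = fine, egg_dual = egg)
    say("selection", sprintf("%s region(s)",
                             paste(vapply(regions, nrow, 0L), collapse = "/")))
    outputs$lsbl_commercial <- lsbl_tracks$commercial
    outputs$lsbl_local <- lsbl_tracks$local
    for (p in config$focal) outputs[[paste0("regions_", p)]] <- regions[[p]]

    if (!is.null(truth) && nrow(truth$sweeps)) {
      recovery <- truth$sweeps |>
        dplyr::rowwise() |>
        dplyr::mutate(recovered = {
          scan_regions <- if (.data$population %in% names(regions)) {
            regions[[.data$population]]
          } else if (.data$population == "egg" && !is.null(egg)) {
            egg$egg
          } else {
            NULL
          }
          !is.null(scan_regions) && nrow(scan_regions) > 0 &&
            any(scan_regions$chrom == .data$chrom &
                  scan_regions$start < .data$end &
                  scan_regions$end > .data$start)
        }) |>
        dplyr::ungroup()
      outputs$sweep_recovery <- recovery
      say("recovery", sprintf("%d/%d sweeps recovered",
                              sum(recovery$recovered), nrow(recovery)))
    }
  }

  say("done", sprintf("%.1f s", as.numeric(Sys.time() - t0, units = "secs")))
  manifest <- dplyr::bind_rows(manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(outputs)) {
      readr::write_tsv(outputs[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                       progress = FALSE)
    }
    writeLines(unclass(newick), file.path(out_dir, "nj_tree.nwk"))
    write_vcf(qcd, file.path(out_dir, "qc.vcf"))
    write_sample_map(smap, file.path(out_dir, "sample_map.tsv"))
    if (!is.null(truth)) write_truth(truth, file.path(out_dir, "truth.tsv"))
    readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"),
                     progress = FALSE)
    # full config echo: a run is reproducible from its output directory
    yaml::write_yaml(rapply(unclass(config), unclass, how = "replace"),
                     file.path(out_dir, "config.yaml"))
  }

  list(geno = qcd, sample_map = smap, truth = truth,
       diversity = list(summary = div, het = het, f = f_tbl,
                        pi = pi_tracks, roh = roh_segs),
       structure = list(pca = pca_fit, ibs = ibs, newick = newick),
       ld = list(decay = ld_bins, ne = ne_tbl),
       selection = selection, recovery = recovery, manifest = manifest)
}

#' Equalise per-population sample sizes, proportional by breed
#'
#' Draws a seeded subsample of `n` individuals from each population,
#' allocating counts across breeds by largest-remainder rounding of the
#' breed proportions. Populations at or below `n` are kept whole (with a
#' warning when strictly below).
#'
#' @param sample_map Sample-map tibble.
#' @param n Target individuals per population (default 72).
#' @param seed Seed for the within-breed draws.
#' @return A subset of `sample_map`.
#' @export
equalize_samples <- function(sample_map, n = 72, seed = 1) {
  with_local_seed(seed, {
    purrr::map_dfr(split(sample_map, sample_map$population), function(pop) {
      if (nrow(pop) <= n) {
        if (nrow(pop) < n) {
          warn(sprintf("population %s has only %d samples (< %d); keeping all",
                       pop$population[1], nrow(pop), n))
        }
        return(pop)
      }
      breeds <- pop |>
        dplyr::count(.data$breed, name = "count") |>
        dplyr::mutate(quota = n * .data$count / nrow(pop),
                      base = floor(.data$quota),
                      frac = .data$quota - .data$base) |>
        dplyr::arrange(dplyr::desc(.data$frac), dplyr::desc(.data$count),
                       .data$breed)
      rem <- n - sum(breeds$base)
      breeds$take <- breeds$base + c(rep(1, rem), rep(0, nrow(breeds) - rem))
      purrr::map_dfr(seq_len(nrow(breeds)), function(i) {
        rows <- pop[pop$breed == breeds$breed[i], ]
        rows[sort(sample.int(nrow(rows), breeds$take[i])), ]
      })
    })
  })
}
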