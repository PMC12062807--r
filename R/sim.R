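#' Configuration for the three-population genotype simulator
#'
#' Defines a wild / local / commercial three-population design: ancestral
#' allele frequencies are drawn uniformly, each branch drifts according to
#' the Balding-Nichols model with its own drift coefficient, and diploid
#' individuals are built as haplotype mosaics over a founder pool so the
#' data carry realistic linkage disequilibrium. Selective sweeps (windows
#' forced to a high target frequency on one branch), long homozygous
#' tracts, and an egg/dual split nested inside the local population can be
#' injected; all are recorded in the returned ground truth.
#'
#' The defaults reproduce the simulation study conditions used throughout
#' the package's validation: 3 x 36 diploids on 2 chromosomes of 25 Mb
#' with 20,000 SNPs each, branch drift 0.05 (wild), 0.10 (local), 0.20
#' (commercial).
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length_bp Chromosome length in bp.
#' @param n_sites SNPs per chromosome.
#' @param n_per_pop Diploid individuals per population: scalar or named
#'   vector `c(wild=, local=, commercial=)`; each at least 2.
#' @param f_wild,f_local,f_commercial Branch drift coefficients in
#'   `[0, 1)`.
#' @param n_founder_haplotypes Founder haplotypes per population (the pool
#'   the mosaics copy from): scalar or named vector
#'   `c(wild=, local=, commercial=)`. Fewer founders mean stronger recent
#'   drift and more linkage disequilibrium; the defaults (40 / 60 / 20)
#'   mirror a large multi-breed local population, an intermediate wild
#'   one, and a bottlenecked commercial one. The egg/dual subgroups use
#'   the local pool size.
#' @param switch_rate Haplotype-mosaic founder-switch probability per bp.
#' @param sweep_windows Tibble (`population`, `chrom`, `start`, `end`,
#'   `target_freq`) of sweeps; half-open bp windows, `target_freq` in
#'   `(0.5, 1]`; sweeps on one branch must not overlap.
#' @param roh_tracts Tibble (`sample_id`, `chrom`, `start`, `end`) of
#'   tracts forced fully homozygous; sample ids follow the
#'   `<population>_<index>` naming (e.g. `"commercial_001"`).
#' @param egg_dual `NULL`, or a list with `egg_fraction` (fraction of the
#'   local population assigned to egg breeds), `f_egg`, `f_dual`
#'   (subgroup drift within the local branch), and `sweep_windows` (egg-
#'   branch sweeps, same columns as above minus `population`).
#' @param missing_rate Genotype missingness rate (default 0).
#' @param seed Integer seed; the whole simulation is deterministic in it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 2, chrom_length_bp = 25e6, n_sites = 20000,
                       n_per_pop = c(wild = 36, local = 36, commercial = 36),
                       f_wild = 0.05, f_local = 0.10, f_commercial = 0.20,
                       n_founder_haplotypes = c(wild = 40, local = 60,
                                                commercial = 20),
                       switch_rate = 1e-6,
                       sweep_windows = NULL, roh_tracts = NULL,
                       egg_dual = list(egg_fraction = 0.5, f_egg = 0.05,
                                       f_dual = 0.05, sweep_windows = NULL),
                       missing_rate = 0, seed = 1) {
  per_pop <- function(v) {
    if (length(v) == 1) v <- c(wild = v, local = v, commercial = v)
    stopifnot(all(c("wild", "local", "commercial") %in% names(v)))
    v
  }
  n_per_pop <- per_pop(n_per_pop)
  n_founder_haplotypes <- per_pop(n_founder_haplotypes)
  cfg <- list(
    n_chrom = as.integer(n_chrom),
    chrom_length_bp = as.integer(chrom_length_bp),
    n_sites = as.integer(n_sites),
    n_per_pop = n_per_pop,
    f = c(wild = f_wild, local = f_local, commercial = f_commercial),
    n_founder_haplotypes = setNames(as.integer(n_founder_haplotypes),
                                    names(n_founder_haplotypes)),
    switch_rate = switch_rate,
    sweep_windows = sweep_windows %||%
      tibble(population = character(), chrom = character(),
             start = integer(), end = integer(), target_freq = numeric()),
    roh_tracts = roh_tracts %||%
      tibble(sample_id = character(), chrom = character(),
             start = integer(), end = integer()),
    egg_dual = egg_dual, missing_rate = missing_rate,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (any(cfg$f < 0 | cfg$f >= 1)) abort("drift coefficients must be in [0, 1)")
  if (any(cfg$n_per_pop < 2)) abort("n_per_pop must be at least 2")
  chrom_names <- paste0("chr", seq_len(cfg$n_chrom))
  check_win <- function(w, what) {
    if (!nrow(w)) return(invisible())
    if (!all(w$chrom %in% chrom_names)) {
      abort(sprintf("%s on unknown chromosome", what))
    }
    if (any(w$start < 0 | w$end > cfg$chrom_length_bp | w$start >= w$end)) {
      abort(sprintf("%s outside simulated coordinates", what))
    }
  }
  sw <- cfg$sweep_windows
  check_win(sw, "sweep window")
  if (nrow(sw)) {
    if (any(sw$target_freq <= 0.5 | sw$target_freq > 1)) {
      abort("sweep target_freq must be in (0.5, 1]")
    }
    split_sw <- split(sw, paste(sw$population, sw$chrom))
    for (s in split_sw) {
      s <- s[order(s$start), ]
      if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)])) {
        abort("overlapping sweep windows on one branch")
      }
    }
  }
  check_win(cfg$roh_tracts, "homozygous tract")
  ed <- cfg$egg_dual
  if (!is.null(ed)) {
    stopifnot(ed$egg_fraction > 0, ed$egg_fraction < 1,
              ed$f_egg >= 0, ed$f_egg < 1, ed$f_dual >= 0, ed$f_dual < 1)
    if (!is.null(ed$sweep_windows) && nrow(ed$sweep_windows)) {
      check_win(ed$sweep_windows, "egg sweep window")
      if (any(ed$sweep_windows$target_freq <= 0.5 |
                ed$sweep_windows$target_freq > 1)) {
        abort("sweep target_freq must be in (0.5, 1]")
      }
    }
  }
  invisible(cfg)
}

# Balding-Nichols draw of a descendant frequency around ancestral p with
# drift coefficient f; f = 0 copies p unchanged (the Beta is undefined).
bn_drift <- function(p, f) {
  if (f == 0) return(p)
  stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

# One mosaic haplotype: a copy path over founder haplotypes that switches
# founder with probability psw between adjacent sites.
mosaic_hap <- function(founders, psw) {
  m <- ncol(founders)
  nf <- nrow(founders)
  seg <- cumsum(c(1L, as.integer(stats::runif(m - 1) < psw)))
  fid <- sample.int(nf, seg[m], replace = TRUE)[seg]
  founders[fid + (seq_len(m) - 1L) * nf]
}

#' Simulate three diverged populations of biallelic SNP genotypes
#'
#' See [sim_config()] for the generative model. The randomness stream is
#' fixed per chromosome in the order: site positions, ancestral
#' frequencies, branch frequencies (wild, local, commercial, egg, dual),
#' then per group (wild, local-egg, local-dual, commercial) founder
#' haplotypes followed by individual mosaics (two haplotypes per
#' individual, in sample order), then the missingness mask; identical
#' configurations therefore yield identical output.
#'
#' @param config A [sim_config()] object.
#' @return A list with `geno` (a [geno()] object), `sample_map` (tibble),
#'   and `truth` (class `sim_truth`: per-site ancestral and post-drift
#'   frequencies, the sweep and tract lists, and the seed).
#' @export
simulate_three_pop <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  cfg <- config
  ed <- cfg$egg_dual
  n_wild <- cfg$n_per_pop[["wild"]]
  n_local <- cfg$n_per_pop[["local"]]
  n_comm <- cfg$n_per_pop[["commercial"]]
  n_egg <- if (is.null(ed)) 0L else as.integer(round(ed$egg_fraction * n_local))
  n_dual <- n_local - n_egg
  ids <- c(sprintf("wild_%03d", seq_len(n_wild)),
           sprintf("local_%03d", seq_len(n_local)),
           sprintf("commercial_%03d", seq_len(n_comm)))
  local_type <- if (is.null(ed)) rep("dual", n_local) else
    rep(c("egg", "dual"), c(n_egg, n_dual))
  sample_map <- tibble(
    sample_id = ids,
    population = rep(c("wild", "local", "commercial"),
                     c(n_wild, n_local, n_comm)),
    breed = c(rep("mallard", n_wild), paste0(local_type, "_breed"),
              rep("commercial_breed", n_comm)),
    type = c(rep("wild", n_wild), local_type, rep("meat", n_comm))
  )
  bad_tract <- setdiff(cfg$roh_tracts$sample_id, ids)
  if (length(bad_tract)) {
    abort(paste("tract for unknown sample:", paste(bad_tract, collapse = ", ")))
  }

  with_local_seed(cfg$seed, {
    chrom_res <- purrr::map(seq_len(cfg$n_chrom), function(k) {
      ch <- paste0("chr", k)
      m <- cfg$n_sites
      pos <- sort(sample.int(cfg$chrom_length_bp, m))
      p_anc <- stats::runif(m, 0.05, 0.95)
      p <- list(
        wild = bn_drift(p_anc, cfg$f[["wild"]]),
        local = bn_drift(p_anc, cfg$f[["local"]]),
        commercial = bn_drift(p_anc, cfg$f[["commercial"]])
      )
      if (!is.null(ed)) {
        p$egg <- bn_drift(p$local, ed$f_egg)
        p$dual <- bn_drift(p$local, ed$f_dual)
      }
      apply_sweeps <- function(freq, sweeps) {
        for (i in seq_len(nrow(sweeps))) {
          if (sweeps$chrom[i] != ch) next
          hit <- (pos - 1) >= sweeps$start[i] & (pos - 1) < sweeps$end[i]
          freq[hit] <- sweeps$target_freq[i]
        }
        freq
      }
      for (pop in c("wild", "local", "commercial")) {
        sw <- cfg$sweep_windows[cfg$sweep_windows$population == pop, ]
        p[[pop]] <- apply_sweeps(p[[pop]], sw)
        # a sweep on the local branch propagates into its subgroups
        if (pop == "local" && !is.null(ed) && nrow(sw)) {
          p$egg <- apply_sweeps(p$egg, sw)
          p$dual <- apply_sweeps(p$dual, sw)
        }
      }
      if (!is.null(ed) && !is.null(ed$sweep_windows) &&
            nrow(ed$sweep_windows)) {
        p$egg <- apply_sweeps(p$egg, ed$sweep_windows)
      }
      nf <- cfg$n_founder_haplotypes
      groups <- if (is.null(ed)) {
        list(wild = list(freq = p$wild, n = n_wild, nf = nf[["wild"]]),
             local = list(freq = p$local, n = n_local, nf = nf[["local"]]),
             commercial = list(freq = p$commercial, n = n_comm,
                               nf = nf[["commercial"]]))
      } else {
        list(wild = list(freq = p$wild, n = n_wild, nf = nf[["wild"]]),
             egg = list(freq = p$egg, n = n_egg, nf = nf[["local"]]),
             dual = list(freq = p$dual, n = n_dual, nf = nf[["local"]]),
             commercial = list(freq = p$commercial, n = n_comm,
                               nf = nf[["commercial"]]))
      }
      psw <- 1 - exp(-cfg$switch_rate * diff(pos))
      dosage <- matrix(0L, nrow = length(ids), ncol = m)
      row0 <- 0L
      for (grp in groups) {
        if (grp$n == 0L) next
        founders <- matrix(
          stats::rbinom(grp$nf * m, 1L, rep(grp$freq, each = grp$nf)),
          nrow = grp$nf
        )
        for (i in seq_len(grp$n)) {
          h1 <- mosaic_hap(founders, psw)
          h2 <- mosaic_hap(founders, psw)
          id_i <- ids[row0 + i]
          tr <- cfg$roh_tracts[cfg$roh_tracts$sample_id == id_i &
                                 cfg$roh_tracts$chrom == ch, ]
          for (ti in seq_len(nrow(tr))) {
            hit <- (pos - 1) >= tr$start[ti] & (pos - 1) < tr$end[ti]
            h2[hit] <- h1[hit] # the tract's two haplotypes are identical
          }
          dosage[row0 + i, ] <- h1 + h2
        }
        row0 <- row0 + grp$n
      }
      if (cfg$missing_rate > 0) {
        mask <- stats::runif(length(dosage)) < cfg$missing_rate
        dosage[mask] <- NA_integer_
      }
      freq_tbl <- tibble(chrom = ch, pos = pos, p_anc = p_anc,
                         p_wild = p$wild, p_local = p$local,
                         p_commercial = p$commercial)
      if (!is.null(ed)) {
        freq_tbl$p_egg <- p$egg
        freq_tbl$p_dual <- p$dual
      }
      list(dosage = dosage, pos = pos, chrom = ch, freqs = freq_tbl)
    })

    dosage <- do.call(cbind, lapply(chrom_res, `[[`, "dosage"))
    sites <- tibble(
      chrom = unlist(lapply(chrom_res, function(r) rep(r$chrom, length(r$pos)))),
      pos = unlist(lapply(chrom_res, `[[`, "pos")),
      ref = "A", alt = "G"
    )
    contigs <- tibble(chrom = paste0("chr", seq_len(cfg$n_chrom)),
                      length = cfg$chrom_length_bp)
    g <- geno(dosage, sites, ids, contigs = contigs)
    sweeps <- cfg$sweep_windows
    if (!is.null(ed) && !is.null(ed$sweep_windows) &&
          nrow(ed$sweep_windows)) {
      sweeps <- dplyr::bind_rows(
        sweeps, dplyr::mutate(ed$sweep_windows, population = "egg")
      )
    }
    truth <- sim_truth(
      freqs = dplyr::bind_rows(lapply(chrom_res, `[[`, "freqs")),
      sweeps = sweeps, tracts = cfg$roh_tracts, seed = cfg$seed
    )
    list(geno = g, sample_map = sample_map, truth = truth)
  })
}

#' Ground-truth record of a simulation
#'
#' @param freqs Per-site frequency tibble (`chrom`, `pos`, `p_anc`, and
#'   one `p_<group>` column per simulated group).
#' @param sweeps Sweep-window tibble.
#' @param tracts Homozygous-tract tibble.
#' @param seed The simulation seed.
#' @return A list of class `sim_truth`.
#' @export
sim_truth <- function(freqs = NULL, sweeps = NULL, tracts = NULL,
                      seed = NA_integer_) {
  structure(
    list(
      freqs = freqs %||% tibble(chrom = character(), pos = integer()),
      sweeps = sweeps %||%
        tibble(population = character(), chrom = character(),
               start = integer(), end = integer(), target_freq = numeric()),
      tracts = tracts %||%
        tibble(sample_id = character(), chrom = character(),
               start = integer(), end = integer()),
      seed = as.integer(seed)
    ),
    class = "sim_truth"
  )
}

#' Write or read a simulation ground-truth file
#'
#' One long-format TSV holds the whole truth object: `freq` rows (one per
#' site per group), `sweep` rows, `tract` rows and a `seed` row; the file
#' round-trips losslessly through [read_truth()].
#'
#' @param truth A `sim_truth` object.
#' @param path Output path.
#' @return `path` invisibly; `read_truth()` returns the `sim_truth`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  cols <- c("record", "population", "chrom", "pos", "start", "end",
            "value", "sample_id")
  rows <- list()
  if (!is.na(truth$seed)) {
    rows$seed <- tibble(record = "seed", value = as.numeric(truth$seed))
  }
  if (nrow(truth$freqs)) {
    rows$freq <- truth$freqs |>
      tidyr::pivot_longer(dplyr::starts_with("p_"), names_to = "population",
                          names_prefix = "p_", values_to = "value") |>
      dplyr::mutate(record = "freq")
  }
  if (nrow(truth$sweeps)) {
    rows$sweep <- dplyr::mutate(
      dplyr::rename(truth$sweeps, value = "target_freq"), record = "sweep"
    )
  }
  if (nrow(truth$tracts)) {
    rows$tract <- dplyr::mutate(truth$tracts, record = "tract")
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble(record = character())
  }
  for (cn in setdiff(cols, names(out))) out[[cn]] <- NA
  readr::write_tsv(out[cols], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  t <- readr::read_tsv(
    path,
    col_types = readr::cols(
      record = "c", population = "c", chrom = "c", pos = "i",
      start = "i", end = "i", value = "d", sample_id = "c"
    ),
    progress = FALSE
  )
  seed <- t$value[t$record == "seed"]
  fr <- t[t$record == "freq", c("chrom", "pos", "population", "value")]
  freqs <- if (nrow(fr)) {
    fr |>
      tidyr::pivot_wider(names_from = "population", values_from = "value",
                         names_prefix = "p_") |>
      dplyr::arrange(.data$chrom, .data$pos)
  } else {
    NULL
  }
  sw <- t[t$record == "sweep", c("population", "chrom", "start", "end", "value")]
  tr <- t[t$record == "tract", c("sample_id", "chrom", "start", "end")]
  sim_truth(
    freqs = freqs,
    sweeps = if (nrow(sw)) dplyr::rename(sw, target_freq = "value") else NULL,
    tracts = if (nrow(tr)) tr else NULL,
    seed = if (length(seed)) seed else NA_integer_
  )
}
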