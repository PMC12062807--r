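---
title: "Methods: models, estimators and design choices in lsblscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in lsblscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

lsblscan implements a population-genetics analysis chain for biallelic SNP
genotypes from diverged populations — a wild / local / commercial design
with an egg-laying vs dual-purpose contrast nested inside the local group —
together with a simulator that makes every stage verifiable by parameter
recovery. This vignette is the package's account of the science: the
generative model, each estimator and its conventions, the numerical
choices, and the limits of what the validation shows.

## The synthetic-data generator

`simulate_three_pop()` draws, per site, an ancestral allele frequency
$p \sim \mathrm{Uniform}(0.05, 0.95)$ and then a frequency for each branch
from the Balding–Nichols distribution

$$p_i \sim \mathrm{Beta}\!\left(p\,\frac{1-F_i}{F_i},\;(1-p)\,\frac{1-F_i}{F_i}\right),$$

where $F_i \in [0,1)$ is the branch's drift coefficient ($F_i = 0$ copies
$p$ unchanged, since the Beta is then undefined). Under this model the
expected heterozygosity at a site is $2p(1-p)(1-F_i)$, which is the basis
of the drift-recovery regression test. The egg/dual split re-applies the
same draw *within* the local branch (a two-level hierarchy), mirroring the
nested contrast in the study design.

Linkage disequilibrium comes from a haplotype-mosaic process rather than a
coalescent: each population has a founder pool of `n_founder_haplotypes`
haplotypes sampled site-wise from the branch frequency, and each individual
haplotype is a copy path over that pool, switching founders between
adjacent sites with probability $1 - e^{-\text{switch\_rate} \cdot d}$ for
gap $d$ bp. Fewer founders mean more haplotype sharing and therefore more
LD — the knob that emulates recent effective population size. Selective
sweeps overwrite the focal branch's frequencies with `target_freq` inside
the sweep window before founder sampling; homozygous tracts copy one
haplotype over the other inside the tract; missing genotypes (default rate
0) are masked uniformly at random.

Site positions are drawn uniformly without replacement per chromosome and
sorted — simple and density-controllable. All randomness flows from a
single seed with a fixed stream order (positions, ancestral frequencies,
branch frequencies, then founders and mosaics per group in a documented
order), so identical configurations give byte-identical VCF output.

**Default study conditions.** The defaults are the simulation conditions
used throughout the package's validation: three populations of 36
diploids on 2 chromosomes of 25 Mb with 20,000 SNPs each; branch drift
0.05 (wild), 0.10 (local), 0.20 (commercial); founder pools 40 / 60 / 20
(local largest — it aggregates many breeds; commercial smallest — a
bottlenecked elite population); switch rate $10^{-6}$ per bp, which puts
the expected founder-segment length at ~1 Mb and gives visible r² decay
within 500 kb; an even egg/dual split with subgroup drift 0.05. These
sizes keep a full scan run in single-digit seconds on one CPU while
leaving thousands of windows for quantile-based region calling.

**What the generator does not emulate.** No mutation model, no coalescent
recombination structure (LD is stationary along the chromosome), a uniform
ancestral frequency spectrum rather than a neutral SFS, no genotyping
error beyond uniform missingness, no linked selection outside the declared
sweep windows. Recovery results on these data therefore demonstrate that
the estimators and scans are implemented correctly and behave as theory
predicts under drift and sweeps; they are not evidence about power on real
resequencing data.

## Site QC

The QC chain mirrors the standard two-stage practice: first biallelic-SNP
selection with minor-allele frequency ≥ 0.01 (computed on called alleles)
and missing fraction ≤ 0.9; then removal of sites with MAF < 0.05 or an
exact Hardy–Weinberg p-value < 10⁻⁶. Ties at either threshold are kept
(the filters are strict inequalities on the removal side). The HWE test is
the exact conditional test on the heterozygote count given the allele
counts, plain (non mid-p), evaluated by enumeration with a memo on the
(sample size, allele count) pair; it is tested against an independent
enumeration oracle to 10⁻¹². The test is pooled across all samples — the
common tool default — although pooling across structured populations makes
the filter conservative (Wahlund effect); per-group testing can be had by
subsetting first. Multi-allelic records are dropped, not split. All
contigs present are analysed; nothing is hard-coded about chromosome
naming or count.

Coordinates are 0-based half-open internally and in every window output
(BED convention); VCF and GFF3 are 1-based at the boundary.

## Diversity statistics

Per site, $H_o$ is the heterozygote fraction among called individuals and
$H_e = 2p(1-p)$. The per-individual inbreeding coefficient is the
method-of-moments estimator
$F = (O_{hom} - E_{hom}) / (L - E_{hom})$ with
$E_{hom} = \sum_j \left[1 - 2p_j(1-p_j)\tfrac{2n_j}{2n_j-1}\right]$ over
the individual's called sites. The asymmetry — $H_e$ plain, $F$ with the
unbiased small-sample correction — is deliberate: it matches how the
standard tooling reports the two quantities.

Windowed nucleotide diversity sums the per-site unbiased estimator
$\pi_j = 2a_j(m_j - a_j)/(m_j(m_j-1))$ ($a_j$ alt alleles among $m_j$
called alleles) over 50-kb windows stepped by 25 kb and divides by the
window span in bp; the final window of a chromosome is truncated and
divided by its actual span, so the normalisation is explicit and testable.
Zero-SNP windows are emitted with value 0 (flagged by `n_snps = 0`) so
tracks align across statistics; a `drop_empty` mode reproduces the
drop-empty behaviour of common tools. The implementation is verified to
10⁻¹² against a brute-force mean-pairwise-difference oracle.

In the per-population summary, He/Ho dispersion is reported across sites
(the ± in the summary), π across windows, F across individuals, ROH across
segments. Whether "±" should be across sites or individuals is genuinely
ambiguous in common reporting; across sites is implemented and stated.

## Runs of homozygosity

`detect_roh()` is the scanning-window algorithm behind PLINK's
`--homozyg`, with the parameter set window-snp 50, window-het 1,
window-missing 5, window-threshold 0.05, snp 50, density 500 kb/SNP, gap
1000 kb. A 50-SNP window slides one SNP at a time; a window is homozygous
if it has ≤ 1 heterozygous and ≤ 5 missing calls; a SNP's hit fraction
divides by the number of windows that actually contain it (so chromosome
edges are not penalised); eligible SNPs (fraction ≥ 0.05) form maximal
runs, split at inter-SNP gaps > 1 Mb, and candidates must hold ≥ 50 SNPs,
span ≥ 1 Mb and have ≥ 1 SNP per 500 kb on the final trimmed segment.
`min_kb` defaults to 1000 because the corresponding flag is typically left
unset; the segment-level heterozygote allowance is unlimited (the tool
default), so called segments may contain hets that survived the window
rule. Segment ends are not trimmed to the outermost homozygous call; that
choice is surfaced here because published pipelines rarely state it.

**Identifiability of injected tracts.** The tract-recovery validation
injects 2-Mb homozygous tracts and requires ≥ 90% reciprocal overlap
between tract and called segment. Under the default simulator conditions
individuals also carry *natural* autozygosity — both haplotypes copying
the same founder over ~1-Mb stretches — and when such a run abuts the
injected tract, the called segment correctly extends past the tract and
the tract boundary is not identifiable from the genotypes. The recovery
experiment therefore uses an outbred background (100 founders, switch
rate $5\times10^{-6}$), where tract boundaries are sharp; on the default
background the detector was verified to be calling genuinely homozygous
runs in those extended segments.

## Linkage disequilibrium and Ne

Pairwise LD is the squared Pearson correlation of dosage vectors over
pairwise-complete individuals. Decay curves bin all intra-chromosomal
pairs within 500 kb (default) by distance; above 2×10⁶ pairs a seeded
subsample keeps runtime flat. The missing-data path uses pairwise-complete
moments computed by masked column sums, so curves are exact, not imputed.

Ne inversion uses Sved's drift-only relation $E[r^2] = 1/(\alpha + 4Nc)$
per bin: $c$ maps from the bin's midpoint distance at 1 cM/Mb
(`map_rate = 1e-8`, configurable), the sample-size adjustment subtracts
$1/(2n)$ from the mean r² (the unphased-diploid approximation), each bin
is dated at $t = 1/(2c)$ generations, and $\alpha$ defaults to 1 with the
mutation–drift variant 2.2 available. Bins with no pairs, zero $c$, or a
non-positive adjusted r² are masked rather than extrapolated. Only this
inversion is promised — not numeric parity with any specific Ne tool,
whose binning and correction chains go beyond what is stated here.

LD pruning is the greedy windowed pass of `--indep-pairwise 50 5 0.2`:
within each 50-SNP window, while any retained pair exceeds r² = 0.2, the
member with the smaller MAF is removed (ties remove the later position),
iterating to a fixpoint before sliding by 5 SNPs. The postcondition — no
retained pair above the cap inside any scanned window — is verified
exhaustively on toys.

## Population structure

PCA imputes missing dosages to the site mean, centres by $2p$ and scales
by $\sqrt{2p(1-p)}$ (Patterson's variance standardisation; plain centring
is available), drops monomorphic sites, and eigendecomposes the sample
covariance; explained percentages are relative to the sum of positive
eigenvalues. Components are oriented so the largest-magnitude coordinate
is positive, making signs reproducible. The IBS distance is
$1 - \overline{(2 - |d_i - d_j|)/2}$ over co-called sites, a metric on
complete data; pairs with no co-called site are masked. Neighbor joining
is Saitou–Nei via `ape::nj`, exact on additive matrices (verified to
10⁻⁹); negative branch lengths are floored at zero with the deficit moved
to a sister edge at the same node, preserving local path lengths.

## Selection scans

Per site, the two-population Weir–Cockerham (1984) variance components
$a$ (among populations), $b$ (between individuals within populations) and
$c$ (within individuals) are computed from sample sizes, allele
frequencies and observed heterozygosity; the window statistic is the
ratio of sums $\sum a / \sum(a+b+c)$ ("weighted" estimator). The
mean-of-ratios column is also emitted because published pipelines rarely
say which fed their downstream statistic; weighted is the default here.
Sites where either population has no calls, where the mean sample size is
1 (the components are undefined), or where both populations are fixed for
the same allele, are masked. The implementation agrees with an
independent brute-force evaluation to 10⁻¹⁰ over random count tables, and
hits the fixation ($\theta = 1$) and all-heterozygote ($\theta = 0$)
anchors exactly.

The locus-specific branch length of focal population X against Y and Z is
$\mathrm{LSBL}_X = (F_{XY} + F_{XZ} - F_{YZ})/2$ per window — X's branch
in the per-window three-population star. Negative window Fst values are
**not** clamped before the combination: clamping breaks the additive
identities $\mathrm{LSBL}_X + \mathrm{LSBL}_Y = F_{XY}$ and
$\sum \mathrm{LSBL} = \tfrac12\sum F$, which the tests check to 10⁻¹²; a
clamp flag exists for parity experiments with tools that do clamp.

Region calling takes the empirical $(1-q)$ quantile (order statistic,
ties included at the threshold) of window values over unmasked windows
with ≥ 10 SNPs — sparse windows produce unstable ratios and are excluded
from both the quantile and selection — then merges overlapping or
abutting selected windows, recording the peak value. Candidate regions
are rescanned at 10-kb/5-kb resolution on a grid aligned to the region
bounds, recomputing pairwise Fst, LSBL and per-population π inside the
region. By default every merged top-quantile region is eligible for the
fine rescan; a top-n-by-peak selector reproduces the common practice of
hand-picking a few regions, which is otherwise criterion-free.

The two-group scan contrasts egg against dual-purpose breeds:
$\log_2(\pi_{dual}/\pi_{egg})$ per window (masked when either π is 0),
intersected with the top-$q$ tail of the between-group Fst. The ratio's
orientation is a stated convention — positive means diversity depressed
in the egg group. The ratio tails are strict inequalities: on a flat
ratio track (equal diversity everywhere) the two tail thresholds
coincide and nothing is selected, which is the correct degenerate
behaviour; the Fst tail keeps the tie-inclusive rule.

Gene annotation attaches a gene to a region when their half-open
intervals intersect; abutting intervals do not overlap.

## Pipeline conventions

`run_pipeline()` derives one seed per stage from the master seed by
stage-name hashing, so inserting a stage never perturbs the streams of
earlier ones; reruns with one seed are byte-identical. The per-population
sample equaliser (used before LD/Ne so sample size does not confound the
comparison; 72 per population in the motivating design) allocates breed
quotas by largest-remainder rounding and draws within breeds with the
stage seed. Every tabular output is TSV with headers, tracks are BED-like
half-open, trees Newick, genotypes VCFv4.2 (GT only, contigs declared).

## Validation scale and limitations

The test suite validates estimators on enumerable toys (exact oracles at
10⁻¹⁰–10⁻¹²) and behaviour on simulated genomes at the default study
conditions above: sweep recovery in ≥ 19/20 seeds for the top-1% LSBL
scan, ≥ 18/20 for the egg/dual overlap scan, ROH tract recovery at ≥ 90%
reciprocal overlap over 10 seeds, and the drift orderings of He and r²
across populations over 5 seeds. The zero-drift Fst null is validated
with a large founder pool (800), because with small pools the founder
resampling itself is real drift of order $1/n_f$ that the
individual-level estimator correctly reports. Known limitations: no
haplotype-based statistics (XP-EHH, iHS), no model-based ancestry
estimation, no enrichment analysis (all need external data or are
published-tool territory), and π/Fst windows use physical distance only —
no recombination-map input.
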