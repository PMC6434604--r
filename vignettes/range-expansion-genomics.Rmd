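---
title: "Methods: range-expansion genomics with edgefront"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: range-expansion genomics with edgefront}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgefront)
```

This vignette is the package's own account of its science: the models it
implements, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the choices made where the design was
genuinely open. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## The problem

A range expansion proceeds by serial founder events: each newly colonised
site is seeded by a few migrants from the previous one, grows, and seeds
the next. Repeated bottlenecks along the chain strip diversity and let
otherwise-rare alleles "surf" to high local frequency at the moving edge.
The expected observables in SNP data sampled along the pathway are (i)
diversity that declines with distance from the origin, (ii) growing
Hardy–Weinberg disequilibrium (positive F_IS) near the front, where
populations are young and internally structured, and (iii) asymmetries in
shared-allele frequencies between site pairs that point back toward the
origin — all potentially in the *absence* of conventional population
structure, because high dispersal keeps F_ST near zero. `edgefront`
implements an analysis pipeline for exactly this regime, plus a generator
that produces data with these properties so every stage can be tested.

## Statistics and conventions

**Per-locus, per-population statistics.** With `n` gene copies
(2 × genotyped diploids), reference-allele frequency `p` and `q = 1 − p`:
observed heterozygosity `H_I` is the fraction of heterozygous genotyped
individuals; `H_S = 2pq`; nucleotide diversity uses the unbiased
gene-diversity form `π = (n/(n−1)) · 2pq` (the Stacks convention — stated
here because sources often just say "Pi"); and
`F_IS = (H_S − H_I)/H_S`, **undefined** when `H_S = 0`. Monomorphic loci
are excluded from F_IS means and distributions rather than scored as
zero; coercing them to 0 would pile spurious mass at the centre of the
F_IS distribution.

**Table conventions.** The population summary's "major allele frequency"
averages, per population, the frequency of the *dataset-wide* major
allele (most frequent over all genotyped samples, ties at exactly 0.5
resolving to the reference allele, logged). A per-population
polarization is available via `major = "local"`; the global default is
documented because the two differ exactly at flip-flop loci, which are an
object of study here. Private alleles are alleles observed in one
population and no other. Rarefied allelic richness uses hypergeometric
rarefaction `Σ_a [1 − C(N−N_a, g)/C(N, g)]` with `g` the smallest
gene-copy count across populations with data at the locus.

**Binning.** All binned distributions (F_IS on [−1, 1], spectra on
[0.5, 1] or [0, 0.5]) use equal left-closed bins with the final bin
closed, pinned by tests; proportions are over records that survive the
undefined-value filter.

**F_ST.** Weir & Cockerham (1984) variance components a, b, c per locus;
multilocus `θ = Σa / Σ(a+b+c)`. The estimator is pinned to WC84 because
the upstream tooling this mirrors does not document its internal
estimator beyond defaults. Significance is by permutation of individuals
between the pair (add-one correction, `p = (1+#{θ* ≥ θ})/(B+1)`), with
Bonferroni division by the number of pairs. Small negative θ are
legitimate (finite-sample bias of order −1/(2n)) and are not truncated.

**PCA.** Dosages are imputed to column means, centred, scaled by
`sqrt(p̂(1−p̂))`, and the sample covariance eigen-decomposed; samples more
than 6 SD out on any top axis are removed and the PCA recomputed, four
iterations by default. This follows the EIGENSOFT description;
numerical equality with smartpca is not targeted.

## Geography

Ocean distances are shortest paths over the water cells of a raster mask
(8-neighbour adjacency, edge weights = great-circle distances between
cell centres; planar grids use Euclidean weights). Sites snap to the
nearest water cell, ties broken in row-major order. Waypoint constraints
concatenate shortest legs `src → w₁ → … → dst`; they encode
oceanographic knowledge such as "dispersal to sites west of an island
must first round its east side". The waypoint is configuration, not a
constant, because no authoritative coordinate exists for such rules. No
raster-file parser ships: any gridded mask can be supplied as a plain
matrix with a sea-level threshold (no raster package is assumed to be
installed).

Diversity–distance regressions are ordinary least squares with the
two-sided t test on the slope (n − 2 df). A constant response returns
slope 0, r² = 0, p = 1 rather than NaN.

## The directionality index ψ

For an ordered pair (i, j), both populations are downsampled **without
replacement** to `subsample_n` gene copies per locus (hypergeometric,
seeded); a locus is included iff the derived allele is present in both
subsamples and not fixed in their union; then
`ψ_ij = mean(f_i − f_j)` over included loci. Three things the source
literature leaves open had to be decided:

* **Subsample size** defaults to 10 gene copies — below the smallest
  per-population genotyped count a 7-individual population can supply
  after an 80% missingness filter, so no population is excluded.
* **Polarization**: the data carry no outgroup, so the dataset-wide
  *minor* allele stands in for the derived allele (`dataset_minor`,
  default; `pair_minor` also available). Ties at exactly 0.5 polarize to
  the alternate allele.
* **Orientation** was calibrated once against the serial-founder
  simulator and then frozen: under folded (minor-allele) polarization
  the *origin* shows the **highest** mean row ψ. The classical
  unfolded-derived expectation (edge populations carry more
  derived-frequency excess) reverses under folding because precisely the
  alleles that surf past 50% dataset-wide get re-polarized. The ranking
  therefore orders sites by descending mean row ψ, rank 1 = inferred
  origin. The calibration is a sign convention decided once — the
  recovery rate itself is measured by the acceptance suite, not assumed.

Each unordered pair is computed once and mirrored, so the matrix is
exactly antisymmetric by construction.

## Locus classifiers

"Flip-flop" loci have a dataset-wide major allele that is locally minor
in at least one population: minimum per-population frequency strictly
below 0.5 (a population at exactly 0.5 does not flag — "drops below" is
read strictly). Min–max difference scans flag `max − min ≥ t` for
t ∈ {0.5, …, 0.9}; the threshold is inclusive by default (the source
wording conflicts between "exceeded" and "at least"; both are
implemented, inclusive pinned as default). Classifiers are deterministic
— no RNG anywhere.

## Outlier scans

**F_ST outliers.** The original engine for this analysis simulates a
coalescent null; here the null is parametric Balding–Nichols (per
design): ancestral frequencies resampled from the data's pooled
spectrum, per-population frequencies `Beta(p(1−F)/F, q(1−F)/F)` at the
target F_ST, genotypes sampled at observed population sizes under HW,
then WC84 θ and pooled expected heterozygosity per simulated locus.
Simulated loci are binned by heterozygosity (sparse bins merged with a
warning); per-bin quantiles form the envelope and per-bin empirical
p-values feed a Benjamini–Hochberg correction. Finite simulation counts
floor the add-one empirical p-value at `1/(n_bin+1)` — a floor no FDR
correction can clear, and the reason the original analysis ran 10⁶
simulations — so above each bin's 95th percentile the null tail is
extended with a fitted exponential (peaks-over-threshold). The final
outlier flag requires both envelope exceedance and BH significance;
monomorphic loci are never flagged. Default simulation count is 10⁵
(configurable; calibration tests run 2×10⁴ per replicate to fit the CPU
budget — resolution affects only p-value granularity, not the thresholds
being tested).

**Environmental correlation.** Per-locus population frequencies are
standardized, whitened by an among-population covariance estimated
across loci (shrunk toward its diagonal, weight 0.1), and scored by
|Spearman correlation| with the gradient (distance from the origin). The
original Bayes-factor machinery is replaced by this fully specified
score; what is reproduced *exactly* is the selection procedure: loci
binned in decimal frequency intervals using p or q chosen by a seeded
coin flip (frequency 1.0 goes to the last bin, logged), ranked by
descending score within bin, rank/bin-size quantile ≤ top_frac selected.
Selection is invariant to monotone transforms of the score by
construction.

## The simulator's stated world

`simulate_expansion()` defaults state the world the analysis assumes:

| parameter | default | why |
|---|---|---|
| demes | 9 along a line, 500 km apart | sampling design of the motivating study |
| loci | 12,000 unlinked biallelic SNPs | RAD-scale dataset |
| ancestral spectrum | density ∝ 1/x on [1/2K, 1−1/2K] | neutral stationary spectrum |
| founder size | 10 diploids | strong serial bottlenecks |
| carrying capacity | 500 diploids | post-founding recovery |
| growth rate | 0.7 logistic | explosive invasion growth (~8 generations to K) |
| migration | 0.01 per generation, adjacent colonised demes | high-dispersal marine larvae, stepping-stone |
| event spacing | 5 generations (+5 after the last) | decadal invasion at roughly annual generations |
| samples | 11, 9, 11, 14, 16, 7, 20, 15, 16 diploids | the study's per-site sample sizes |
| missingness | 5% uniform per call | typical RAD genotyping rate |
| Wahlund structure | F₀ = 0.15 decaying with τ = 20 generations | young demes are internally patchy |

Founders are drawn **without replacement** from the source deme, so
founding with the whole source copies it exactly (the no-drift limit is
exact, and testable). The ancestral deme starts on the 2K allele-count
lattice for the same reason. The Wahlund term needs a word: genotypes
drawn straight from deme frequencies under HW would give F_IS ≈ 0
everywhere, so a generator without internal structure cannot produce the
front-loaded disequilibrium that motivates the analysis. Each deme's
sample is therefore drawn through two internal patches whose frequencies
diverge from the deme mean by a Balding–Nichols draw at
`F = F₀·exp(−(t−t_col)/τ)`: recently founded demes are patchy
(independent reef-scale founder cohorts), old demes have mixed. This is
the standard cryptic-structure explanation for elevated F_IS at invasion
fronts, with one scale (F₀) and one decay (τ) chosen once as plausible
and not revisited.

What the generator does **not** emulate: linkage, selection (surfing here
is pure drift), hybridization between source lineages, age-structured
overlapping generations, non-uniform missingness (real RAD missingness
is coverage- and allele-correlated), and sequencing error. A green test
on simulated data therefore establishes that the *statistics recover the
generator's world*, not that the pipeline is robust to every artefact of
real RAD data.

`simulate_null()` provides the matching island-model null (shared
ancestral frequencies, Balding–Nichols divergence at a target F_ST,
F = 0 collapsing to identical frequencies) used to calibrate false-positive
behaviour.

## Life history and genome arithmetic

Ages come from inverting the von Bertalanffy curve
`L(t) = L∞(1−e^{−K(t−t₀)})`; the inverse is exact (round-trip tested to
1e−9) and undefined at `SL ≥ L∞`. Growth and length-conversion
coefficients are configuration with documented defaults (L∞ = 425 mm,
K = 0.47 /yr, t₀ = −0.5 yr; SL = 0.78·TL), chosen as field-plausible
lionfish-scale values because the motivating sources cite but do not
print their fits. The default simulated age range stops at 5 years:
beyond that the curve is within a few mm of its asymptote and length
carries almost no age information, so age-recovery error explodes for
reasons that have nothing to do with the implementation.

Genome size is predicted from restriction cut-site counts by a log-log
linear model. The shipped SbfI coefficients are a **synthetic stand-in**:
back-derived from the two published anchor estimates (15,000 cut sites →
370,725,631 bp; 25,000 → 680,784,288 bp) because the original regression
coefficients are not printed in an offline-accessible form. The
genome-fraction report (`100·n_loci·len/G`, rounded to 2 decimals) uses a
90 bp locus length including the 6 bp restriction site, with the length a
flag.

## Numerical and degenerate-input choices

* Random SNP-per-tag choice iterates tags in sorted tag-ID order under
  one seeded stream — platform-stable.
* All seeded operations save and restore the caller's RNG state; derived
  sub-seeds stay below 2³¹.
* Zero shared polymorphic loci → θ reported 0 with a warning (not NaN);
  empty F_IS input → empty distribution flagged, with a warning; constant
  PCA input and all-land grids are explicit errors; unreachable water
  paths are errors naming the failing leg.
* Pipeline outputs are plain TSVs with `#`-comment headers carrying
  config and seeds; the manifest deliberately excludes timestamps so
  re-runs are byte-identical.

## Known limitations

* The WC84 permutation test permutes individuals, which under strong
  missingness imbalance can be slightly conservative.
* The environmental-association score is a rank correlation after
  whitening, not a posterior Bayes factor; its absolute scale is not
  comparable to MCMC-based tools, only its ranking is used.
* smartpca equivalence is approximate (no LD regression, no Tracy–Widom
  statistics).
* Real-data headline numbers from the motivating study (locus counts,
  specific r², outlier counts, the empirical ψ ordering) depend on raw
  reads and unpublished distances and are out of scope by design; the
  acceptance suite targets the in-text arithmetic and
  property-level recovery instead.
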