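# edgefront

Range-expansion population genomics for invasion SNP data.

When a species expands its range through serial founder events — an
invasion front hopping from site to site — repeated bottlenecks leave
characteristic genomic signatures: genetic diversity that declines with
distance from the point of introduction, alleles "surfing" to high
frequency at the moving edge, and growing Hardy–Weinberg disequilibrium in
recently founded populations even when classical population structure is
absent. `edgefront` is an R toolkit for detecting and characterising those
signatures in biallelic SNP datasets (e.g. RAD-seq genotypes) sampled
along an invasion pathway, written for marine-invasion settings where
dispersal follows the ocean rather than straight lines.

## What it computes

* **Locus retention filters** in the style of the Stacks `populations`
  program: a locus is kept when it is genotyped in ≥ *p* populations with
  ≥ *r* of individuals genotyped per population (both inclusive), with an
  optional seeded one-SNP-per-RAD-tag thinning.
* **Diversity statistics** per locus and population: allele frequencies,
  observed heterozygosity H_I, expected heterozygosity H_S = 2pq,
  nucleotide diversity π = (n/(n−1))·2pq with n gene copies, and the
  inbreeding coefficient F_IS = (H_S − H_I)/H_S, treated as *undefined*
  (not zero) when H_S = 0; private alleles and hypergeometric rarefied
  allelic richness; binned F_IS distributions and folded site-frequency
  spectra.
* **Structure**: pairwise Weir–Cockerham (1984) θ from variance components
  a, b, c (θ = Σa / Σ(a+b+c)), permutation p-values with Bonferroni
  correction; smartpca-style PCA (allele-frequency scaling, iterative
  6-SD outlier removal).
* **Geography**: least-cost ocean distances over a water/land raster
  (Dijkstra on the 8-neighbour graph, great-circle edge weights), with
  ordered waypoint constraints (e.g. "routes west must first round the
  east side of an island"); OLS regressions of diversity on distance.
* **Origin inference**: the directionality index ψ — pairwise asymmetries
  in shared-allele frequencies after downsampling both populations to a
  common number of gene copies — and a whole-matrix ranking whose first
  entry is the inferred expansion origin.
* **Locus classifiers**: "flip-flop" loci whose dataset-wide major allele
  is locally minor somewhere; min–max frequency-difference scans at
  0.5–0.9; centre-vs-edge excess counts; set-overlap tables.
* **Outlier scans**: an F_ST-vs-heterozygosity envelope built from a
  parametric Balding–Nichols null (per-population frequencies
  ~ Beta(p(1−F)/F, q(1−F)/F)) with BH-corrected empirical p-values, and an
  environmental-correlation scan (covariance-whitened rank correlation
  against a distance gradient) selected through empirical rank binning in
  decimal frequency intervals.
* **Simulator**: a forward-time Wright–Fisher serial founder-event
  generator (drift, logistic growth, stepping-stone migration, decaying
  within-deme Wahlund structure, missing genotypes) plus island-model
  nulls — so the whole pipeline is testable without external data.
* **Life history**: inverse von Bertalanffy ageing of fish from length,
  recruitment years, and genome-size / genome-fraction arithmetic from
  restriction cut-site counts.

## Worked example

Simulate a nine-deme serial founder expansion (~12,000 loci, sample sizes
7–20 diploids, 5% missing calls), filter as a real RAD dataset would be
filtered, and recover the expansion signal:

```r
library(edgefront)

sim <- simulate_expansion(expansion_config(seed = 1))
gm  <- apply_locus_filters(sim$gm, sim$pm,
                           filter_config(min_populations = 8,
                                         min_fraction_individuals = 0.8,
                                         seed = 1))
st <- summary_table(gm, sim$pm)
st[, c("pop", "n", "private", "obs_het_mean", "exp_het_mean", "fis_mean")]
#>   pop  n private obs_het_mean exp_het_mean fis_mean
#> 1  D1 11     979       0.1354       0.1306  -0.0392
#> 2  D2  9     251       0.1285       0.1217  -0.0574
#> 3  D3 11      85       0.1156       0.1112  -0.0416
#> 4  D4 14      17       0.1033       0.1007  -0.0269
#> 5  D5 16       2       0.0914       0.0903  -0.0163
#> 6  D6  7       0       0.0820       0.0778  -0.0587
#> 7  D7 20       0       0.0715       0.0720   0.0028
#> 8  D8 15       0       0.0625       0.0634   0.0073
#> 9  D9 16       0       0.0538       0.0557   0.0266
```

Observed heterozygosity and private-allele counts fall away from the
origin deme D1, and F_IS rises toward the range edge (recently founded
demes are internally structured, hence heterozygote-deficient) — the
geography of a serial founder expansion.

```r
d <- sim$truth$positions_km[st$pop]
diversity_distance_regression(setNames(st$obs_het_mean, st$pop), d)
#> obs het ~ distance: slope = -2.11e-05, r2 = 0.996, p = 9.1e-10

psi_matrix_and_ranking(gm, sim$pm, seed = 2)
#> psi_matrix: 9 populations, subsample 10 gene copies (dataset_minor polarization)
#> origin ranking: D1 < D2 < D9 < D3 < D4 < D8 < D5 < D6 < D7
```

The regression slope is negative (diversity decays with distance) and the
ψ ranking places the true origin D1 first — with no prior knowledge of
where the expansion started.

The full pipeline (filters → summary statistics → F_ST/PCA → distances →
regressions → ψ → locus classifiers → outlier scans → overlap table) runs
from one config via `run_pipeline(cfg, out_dir)`, or from the shell via
the `inst/cli/edgefront` script (`edgefront simulate|filter|sumstats|psi|
pipeline`). Every output TSV records its configuration and seeds in
`#`-comment headers, and a `manifest.json` fingerprints the run.

## Notes

* The methods vignette (`vignettes/range-expansion-genomics.Rmd`) documents
  the models, the simulator's stated world, numerical conventions, and
  known limitations.
* VCF parsing uses Bioconductor's VariantAnnotation; graphs use igraph;
  everything else is base R + stats.
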