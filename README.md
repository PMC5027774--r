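# barcodekit

Integrative species identification for closely related fishes, built
around the four northeast Atlantic sand lances (*Ammodytes marinus*,
*A. tobianus*, *Hyperoplus immaculatus*, *H. lanceolatus*).  Sand lances
are assessed and fished as a mixed stock largely because the species are
hard to tell apart; `barcodekit` implements both identification routes —
DNA barcodes and morphology — as one tested R toolkit, including the
statistics that reveal *when each route fails*.

## What it computes

**Molecular workflow** (aligned FASTA + specimen metadata):

* Kimura two-parameter and p-distances under pairwise deletion:
  `d = -½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q)` with `P`/`Q` the transition and
  transversion proportions among jointly resolved sites; saturated or
  empty comparisons are flagged undefined, never fabricated.
* Neighbour-joining trees with non-parametric (column-resampling)
  bootstrap support, written as Newick with a support-display threshold.
* Per-species barcode-gap summaries: the gap is the excess of the minimum
  interspecific (nearest-neighbour) distance over the maximum
  intraspecific distance; non-positive means "no gap" and distance-based
  identification fails for that species.
* Threshold single-linkage OTU clustering (default 2.2%) with a taxonomic
  concordance report (one species per cluster = concordant).
* Diagnostic-nucleotide detection: a site is diagnostic for a species iff
  that species is fixed for a base no other species' sequence (or
  compatible ambiguity) carries; species without pure diagnostics can
  still be identified by their combination of states across all variable
  sites.

**Morphological workflow** (CSV of counts, measurements in mm, standard
length, qualitative characters):

* Standardization of measurements to percent standard length
  (`raw × 100 / SL`) and per-species summaries (`min–max; mean ± SD (n)`).
* Multi-group discriminant function analysis: eigenstructure of `W⁻¹B`
  (pooled within-group vs between-group scatter), standardized
  coefficients, explained variance, Wilks' Λ with Bartlett's χ², Box's M,
  specimen scores, centroids and nearest-centroid classification.
* A rule-based identification key (genus by premaxilla protrusibility,
  prevomer "teeth", dermal plica count, pectoral-fin length; species by
  squamation, snout spot, and count ranges) returning per-character
  evidence and an explicit "indeterminate" on conflict.

**Synthetic data generators** reproduce the statistical structure of both
datasets (planted diagnostic sites, star-shaped haplotype divergence,
per-species character distributions), so the whole pipeline is testable
offline with known ground truth.

## Worked example

Simulate a barcode dataset with the structure of the sand-lance study
(group sizes 27/6/29/8) and summarize it:

```r
library(barcodekit)

sim <- simulate_alignment(sandlance_coi_config(), seed = 7)
dm  <- distance_matrix(sim$alignment, "K2P")
species_summaries(dm)
#>                  species n_specimens mean_intra sd_intra min_intra max_intra
#> 1      Ammodytes marinus          27     0.1024   0.1006         0     0.308
#> 2     Ammodytes tobianus           6     0.0512   0.0750         0     0.154
#> 3 Hyperoplus immaculatus           8     0.0384   0.0677         0     0.154
#> 4 Hyperoplus lanceolatus          29     0.0954   0.1138         0     0.462
#>         nearest_neighbor nn_distance barcode_gap
#> 1 Hyperoplus immaculatus       3.614       3.307
#> 2 Hyperoplus lanceolatus       0.307       0.154
#> 3      Ammodytes marinus       3.614       3.461
#> 4     Ammodytes tobianus       0.307          NA
```

*A. marinus* and *H. immaculatus* are mutual nearest neighbours about
3.6% apart with clear barcode gaps (3.3 and 3.5 points); *A. tobianus*
and *H. lanceolatus* sit only 0.31% apart, so their gaps collapse (an NA
gap prints as "no gap" in reports).  Clustering at the standard 2.2%
threshold shows the consequence — the two gapless species share one
discordant OTU:

```r
concordance_report(single_linkage_otus(dm, threshold = 2.2))
#>                         otu n_specimens n_species                                   species_tally concordant
#> 1      Ammodytes_marinus_01          27         1                            Ammodytes marinus:27       TRUE
#> 2     Ammodytes_tobianus_01          35         2 Hyperoplus lanceolatus:29; Ammodytes tobianus:6      FALSE
#> 3 Hyperoplus_immaculatus_01           8         1                        Hyperoplus immaculatus:8       TRUE
```

Morphology separates all four species where the barcodes cannot:

```r
morph <- simulate_morphology(sandlance_morph_config(n = 20), seed = 7)$table
fit   <- discriminant_analysis(morph, select_dfa_variables(morph, "meristic"))
fit
#> <dfa_result> 4 groups, 7 variables, 80 specimens (0 dropped)
#>                 DF1    DF2     DF3
#> Eigenvalue   60.026 12.079   5.029
#> Explained %  77.820 15.660   6.520
#> Cumulative % 77.820 93.480 100.000
#> Wilks' lambda = 0.0002078 (Bartlett chi2 = 623.201, df = 21, p = 2.1e-118)
#> Box's M undefined (singular group covariance)
#> Nearest-centroid reclassification: 100.0% correct

identification_key(list(PCP = "no", VTP = "yes", DSSS = "yes", LR = 21))
#> Hyperoplus lanceolatus (genus Hyperoplus), 100% of assessed characters in agreement
```

Four groups always give exactly three discriminant functions (explained
variance sums to 100%), and the tiny Wilks' Λ confirms strong meristic
separation.  `run_molecular_pipeline()` and `run_morphology_pipeline()`
run the full report bundles (distance matrix, tree, gap summary, OTUs,
diagnostics; summaries, DFA tables, key calls) to a directory with a run
log.

## Package layout

* `R/` — alignment I/O, distances, trees, barcode gap, OTUs, diagnostics,
  morphology, DFA, identification key, simulators, pipelines.
* `tests/testthat/` — unit, property and end-to-end suites with
  independent brute-force oracles.
* `vignettes/barcodekit-methods.Rmd` — models, conventions, design
  decisions and limitations.
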