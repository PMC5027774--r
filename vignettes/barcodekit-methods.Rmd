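---
title: "Integrative species identification with barcodekit: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative species identification with barcodekit: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodekit)
```

## The problem

Northeast Atlantic sand lances (Ammodytidae) comprise four abundant,
closely related species in two genera — *Ammodytes marinus*,
*A. tobianus*, *Hyperoplus immaculatus* and *H. lanceolatus* — that are
commercially exploited as a mixed stock precisely because routine
identification is unreliable.  `barcodekit` implements the two
complementary identification workflows used for this group and makes their
failure modes measurable:

* a **molecular workflow** on aligned marker sequences (the mitochondrial
  COI barcode and a short nuclear Rhodopsin fragment): substitution-model
  distances, neighbour-joining trees with bootstrap support, per-species
  barcode-gap summaries, single-linkage OTU clustering with taxonomic
  concordance, and diagnostic-nucleotide detection; and
* a **morphological workflow** on meristic counts, measurements and
  qualitative characters: standardization to percent standard length,
  per-species character summaries, multi-group discriminant function
  analysis, and a rule-based identification key.

A pair of synthetic-data generators reproduces the statistical structure
both workflows assume, so every stage is testable end-to-end without any
external sequence or specimen data.

## Distances

For two aligned sequences, a site enters the comparison only when both
carry an unambiguous base (`A/C/G/T`); gaps and IUPAC ambiguity codes
exclude the site *for that pair only* (pairwise deletion — the default
treatment in the software commonly used for barcode analyses, retained
here so results are comparable).  With `P` and `Q` the observed transition
(A↔G, C↔T) and transversion proportions among the jointly resolved sites,
the Kimura two-parameter distance is

$$ d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q), $$

and the p-distance is simply `P + Q`.  Two numerical choices matter:

* **Undefined distances are flagged, never fabricated.**  A pair with no
  jointly resolved site, or one saturated enough that a logarithm argument
  is non-positive, yields `NA`.  Downstream stages refuse to operate on
  `NA` pairs (trees, OTUs) or must skip them explicitly; the pipeline log
  counts every one.
* Percentages in reports are rounded half-up to two decimals, the
  convention of published distance tables; full precision is kept
  internally and available with `full_precision = TRUE`.

## Trees and bootstrap support

`nj_tree()` applies canonical Saitou–Nei neighbour joining (via `ape`).
Negative branch lengths, which NJ can produce on non-additive input, are
clamped to zero for display — they are reported, not used for inference —
and the clamped deficit is attached to the tree.  On additive matrices the
tree reproduces every pairwise distance exactly (tested to 1e-9).

`bootstrap_support()` is the standard non-parametric column bootstrap:
alignment columns are resampled with replacement, the tree rebuilt with
the same distance engine (pairwise deletion applies within each
replicate), and each internal edge of the original tree receives the
percentage of replicates containing the same leaf bipartition.  A
replicate with any undefined distance is skipped and counted; more than
50% skipped aborts.  The classical full-scale setting is 10,000
replicates; the packaged tests and the acceptance script use 100, at which
a clade with ten fixed differences already saturates at 100% support.

## Barcode gap

For each species, intraspecific distances are pooled over all unordered
within-species pairs (mean, sample SD, minimum, maximum), and the nearest
neighbour is the *species* containing the closest heterospecific specimen.
The barcode gap is the excess of that nearest-neighbour distance over the
maximum intraspecific distance; a non-positive excess is reported as
"no gap", the signature of a species pair that distance-based
identification cannot separate.  Two conventions are documented rather
than obvious: the SD is taken over pairs (not specimens) with the `n-1`
denominator, and tied nearest neighbours are all reported, joined
alphabetically — mutual ties at identical distances occur in real
datasets.  Specimens labelled `unknown` stay in trees and clustering but
are excluded from species-wise statistics, which supports the
identify-a-query use case.

## OTU clustering and concordance

`single_linkage_otus()` places two specimens in one OTU iff a chain of
pairwise distances at or below the threshold connects them — single
linkage, computed with `hclust`/`cutree` and verified against a
graph-components oracle.  The default threshold of 2.2% is the seed value
of the clustering behind public barcode-repository OTU assignment; the
subsequent Markov-refinement step of that system is repository-internal
and deliberately out of scope.  The concordance report flags an OTU as
concordant iff exactly one species name occurs in it (`unknown` ignored):
a discordant OTU containing two species is exactly how barcode-sharing
between *A. tobianus* and *H. lanceolatus* manifests.

## Diagnostic nucleotides

A site is diagnostic for species `s` iff (a) every sequence of `s` carries
the same unambiguous base `b` there and (b) no sequence of any other
species carries `b` *or an ambiguity code whose base set contains* `b`.
The ambiguity clause is deliberately conservative: a site is never claimed
diagnostic when an ambiguous read elsewhere could contradict it.  Only
this pure rule is implemented — partial or "private polymorphism"
diagnostics are out of scope.  Positions are 1-based on the trimmed
alignment.  A species with no pure diagnostic site can still be
identifiable through `combination_signature()`: its vector of consensus
states across all variable sites, flagged identifiable when distinct from
every other species' vector.  On the reconstructed 464-bp Rhodopsin
fragment this yields one diagnostic site each for *A. marinus* (site 460,
C), *H. lanceolatus* (82, T) and *H. immaculatus* (433, A), none for
*A. tobianus*, whose three-site combination (C, G, A) is unique.

## Morphology: summaries and discriminant analysis

Measurements are standardized to percent of standard length
(`raw × 100 / SL`); meristic counts enter as recorded.  Variable selection
for the discriminant analyses excludes qualitative characters, composite
counts that are sums of other variables (total gill rakers, total
vertebrae), and characters without variation (the principal caudal-fin ray
count is fixed at 15 in all four species).  Only specimens with a complete
suite of the selected characters are analysed; the dropped count is
reported.

The discriminant functions are eigenvectors of `W⁻¹B`, with `W` the pooled
within-group scatter and `B` the between-group scatter weighted by group
sizes; there are `min(groups − 1, variables)` functions, so four species
always give three.  Standardized coefficients scale the raw coefficients
by the pooled within-group standard deviation of each variable, making
their magnitudes comparable as variable weights; because eigenvector signs
are arbitrary, each function is oriented so its dominant variable loads
positively.  Wilks' Λ = Π 1/(1+λₖ) with Bartlett's χ² approximation
−(N−1−(p+g)/2)·ln Λ tests overall separation; Box's M tests equality of
group covariance matrices via the usual χ² approximation and is reported
as undefined (with a warning) when a group covariance is singular — which
legitimately happens when a count is invariant within a species.
Classification is by nearest group centroid in discriminant space with
equal priors: an identification key should not prejudge how common each
species is in a sample, even when the reference groups are unbalanced.
This choice, and the within-group (rather than total) standardization of
coefficients, are documented package decisions where common desktop
statistics tools differ silently.

The per-specimen scores exported for plotting come with group centroids;
95% group ellipses can be derived from per-group score covariances at the
χ²₂(0.95) radius.

## The identification key

The key proceeds in two stages.  Genus: protrusible premaxillae and
absence of the hooked prevomer ends ("vomerine teeth") indicate
*Ammodytes*; the reverse indicates *Hyperoplus*; the dermal plica count
and pectoral-fin length (%SL) add votes when the value falls in exactly
one genus's range (values in the overlap abstain).  Species within
*Hyperoplus*: the dark snout spot, and the gill-raker, vertebra and
fin-ray counts; within *Ammodytes*: the three squamation characters and
the plica/ray/vertebra counts.  The best-supported species is returned
with per-character evidence and a matched/assessed confidence; ties,
conflicts, or absence of usable characters give an explicit
"indeterminate" rather than a guess.  The default configuration encodes
the published per-species ranges; every range and expected state is
user-replaceable through the key-configuration object.

## Synthetic data: what it emulates and what it does not

`simulate_alignment()` draws a random root sequence, derives each species'
consensus by planting fixed substitutions, and adds independent per-site
intraspecific mutations with a 2:1 transition bias (enough to exercise the
P/Q asymmetry of the K2P model).  Planted columns can be protected so
ground-truth diagnostics stay clean.  It deliberately omits indels, rate
heterogeneity and coalescent structure: it generates the *distance and
diagnostic-site structure* the analyses consume, not realistic molecular
evolution.  Consequently, passing tests demonstrate correctness of the
statistics, not robustness to alignment error or heterotachy.

Two shipped configurations encode the study system.  The Rhodopsin
configuration reproduces the published 464-bp site pattern exactly (group
sizes 27/7/30/8, zero intraspecific rate, pinned root states at sites
82/433/460).  The COI-style configuration reproduces the structure of the
barcode dataset — *A. marinus* and *H. immaculatus* mutual nearest
neighbours with clear gaps and own OTUs; *A. tobianus* and
*H. lanceolatus* one fixed difference apart, co-clustered and gapless —
with group sizes 27/6/29/8 and an intraspecific rate of 5e-4.  The per-pair
substitution counts (30 fixed differences for *A. marinus*, 20 of them
shared with *H. immaculatus* plus 13 private, one each for the other two
species) are a modelling choice fixed once: real per-haplotype differences
are unpublished, and these counts place all pairwise distances inside the
published congeneric and intergeneric ranges.

`simulate_morphology()` draws standard length and %SL measurements from
Normal distributions (measurements back-converted to mm for storage),
meristic counts from rounded, range-clamped Normals (half away from zero),
derives the composite counts from their parts, and copies qualitative
states.  Characters are independent — published tables report only
marginal means, SDs and ranges, so no covariance structure is available to
emulate; real morphometric characters are correlated through body size,
which makes simulated discriminant analyses somewhat cleaner than real
ones.  Default parameters are the published per-species values, including
group sizes 27/21/8/29.

## Problem sizes and determinism

Every stochastic stage takes an explicit integer seed and is byte-identical
under it.  The packaged tests and the acceptance script use desk-scale
sizes chosen to exercise every code path with comfortable margins: 100
random alignments of 6×40 sites for the distance oracle, 4–6 taxon additive
matrices for tree recovery, 100 bootstrap replicates on 10 specimens,
70-specimen simulated barcode datasets, and 20 specimens per species for
the discriminant and key analyses.

## Known limitations

* Distances beyond K2P and p (e.g. TN93, GTR) and likelihood/Bayesian
  trees are out of scope; the package computes identification statistics,
  not phylogenies.
* The published discriminant coefficient tables cannot be reproduced
  numerically because the raw per-specimen data are unpublished; the
  package validates its discriminant machinery against brute-force scatter
  computation and an independent LDA implementation instead.
* The diagnostic-site detector ignores amino-acid-level diagnostics and
  probabilistic character-based assignment.
* Box's M is reported via its χ² approximation only, and is undefined for
  groups with singular covariance.
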