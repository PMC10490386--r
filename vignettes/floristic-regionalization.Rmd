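---
title: "Phylogeny-informed floristic regionalization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogeny-informed floristic regionalization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floregion)
```

## The problem

Given a binary site × taxon occurrence matrix (sites are geographic units,
taxa typically genera) and a rooted, dated phylogeny over the taxa,
`floregion` delineates floristic regions: groups of sites whose floras are
compositionally and phylogenetically coherent. The workflow is: pairwise
turnover matrices → tip-shuffle null model → dendrogram construction and
validation → silhouette-guided cut into regions nested in realms → NMDS
cross-check. This vignette explains each model choice, the tunable
parameters, and what the synthetic validation does and does not establish.

## Turnover indices

Taxonomic turnover between two sites uses the Simpson (turnover-only)
component of Sørensen dissimilarity, `β_sim = min(b,c)/(a + min(b,c))`,
where `a` counts shared taxa and `b`, `c` the taxa unique to each site. The
min() makes the index blind to nestedness: a species-poor site whose flora
is a subset of a rich one scores 0. This matters for real floras whose
richness spans an order of magnitude across sites. The Jaccard-family
turnover `β_jtu = 2min(b,c)/(a + 2min(b,c))` is provided for sensitivity
checks; it equals `2β_sim/(1 + β_sim)`, so the two can never disagree about
an ordering of site pairs — a property the test suite asserts exactly.

Phylogenetic turnover (`pβ_sim`, `pβ_jtu`) substitutes branch lengths for
counts. We define the phylogenetic diversity `P` of a site as the sum of
branch lengths on the union of root-to-tip paths of its taxa
(**root-anchored** Faith PD), and decompose a pair as
`a = P_i + P_j − P_u`, `b = P_u − P_j`, `c = P_u − P_i` with `P_u` the PD
of the pooled flora, so `a + b + c = P_u` holds identically (the suite
checks conservation to 1e-9 relative). Root-anchoring, rather than
anchoring at each pair's MRCA, is the convention of the reference
implementations for dated trees and is what makes the decomposition
conserve; the MRCA-anchored variant is nevertheless exposed through
`rooted_pd(..., anchor = "mrca")` for exploration. On a star phylogeny with
equal branch lengths the phylogenetic indices collapse to the taxonomic
ones exactly — a useful degenerate-case oracle.

Empty-versus-anything comparisons are errors, not conventions: empty sites
are removed at I/O and by `harmonize()`, so encountering one downstream
signals a bug.

`harmonize()` prunes the tree and restricts the matrix to their common
taxa. Pruning preserves every retained tip's root-to-tip path length — when
the retained tips' MRCA sits below the original root, the lost stem is kept
as an explicit root edge — so root-anchored PD, and hence `pβ`, is
invariant under harmonization. Without this, pruning would silently
re-anchor the analysis at the subtree crown.

## The tip-shuffle null model and SES

`pβ_sim` correlates strongly with `β_sim` wherever both are computed from
the same occupancies. To isolate the phylogenetic signal, the null model
permutes the tip labels of the phylogeny uniformly over **all** tips (the
regional species pool), recomputes the full `pβ_sim` matrix per
permutation, and standardizes each pair:
`SES = (obs − mean(null)) / sd(null)`, with the sample (n−1) standard
deviation of the 999-member ensemble. The shuffle preserves tree shape,
branch lengths, and every site's taxon list, so taxonomic turnover is
untouched by construction; the implementation exploits this by recomputing
only `pβ` (a permutation of occupancy columns against a fixed edge
incidence), which makes 999 permutations a few seconds' work at 40 sites ×
400 tips. An optional `check_taxonomic` flag verifies the invariance rather
than recomputing `β` matrices per permutation.

Degenerate pairs — where every permutation yields the same `pβ` value, as
on a star tree — have `sd(null) = 0`; their SES is recorded as missing,
excluded from site means, and counted. Degeneracy is detected from the
exact range of the null ensemble, not from the accumulator variance, which
carries ~1e-16 floating residue that a naive `sd > 0` test would mistake
for variation.

Per-site reporting averages each site's SES against all others; the
site-level significance rule applies |1.96| to that mean, matching the
per-unit tally style of county-scale studies. Under occupancy decoupled
from the tree, the SES distribution is calibrated (mean ≈ 0, sd ≈ 1,
two-sided 1.96-exceedance ≈ 5%), which the acceptance suite verifies with
999 permutations at 20 sites × 400 tips.

## Mantel tests

Matrix correlations use Pearson's r over strictly-lower triangles with a
one-sided (positive association) permutation p-value,
`p = (1 + #{null ≥ obs}) / (1 + 999)`, delegated to `vegan::mantel()`
behind a validating wrapper (seeding, NA handling for SES matrices with
degenerate pairs, zero-variance and alignment checks). The pipeline runs
the five standard comparisons: `β_jtu~β_sim`, `pβ_jtu~pβ_sim`,
`pβ_sim~β_sim`, `SES~pβ_sim`, `SES~β_sim`.

## Clustering, method selection, and region delineation

All eight Lance–Williams linkage variants are computed by `stats::hclust`
on the untransformed dissimilarities: single, complete, UPGMA (average),
WPGMA (mcquitty), UPGMC (centroid), WPGMC (median), and the two Ward
conventions (`ward.D` on raw, `ward.D2` on squared dissimilarities with
square-rooted heights). Centroid methods may produce inversions; these are
flagged (`has_inversions`), never repaired. Dendrogram faithfulness is
scored by the cophenetic correlation coefficient (CCC; Pearson r between
input and cophenetic distances, not clamped) and Gower's distance (GD; sum
of squared discrepancies). Selection maximizes CCC with ties broken by
minimal GD, then by a fixed method order for determinism. On distances that
are already ultrametric, UPGMA is a fixed point (CCC = 1, GD = 0 to 1e-10)
and is therefore always selected — the suite's strongest clustering oracle.

The number of regions k maximizes the mean silhouette width of the k-cut
(ties to the smaller k, the more parsimonious map), searched over 2..min(15,
n−1) by default; the cap reflects that county-scale studies recognize on
the order of ten regions, and is overridable. Realms are the 2-cut of the
same dendrogram, so every region nests in exactly one realm and every
region is a monophyletic clade of the dendrogram by construction.
Geographic contiguity, when an adjacency list is supplied, is **reported**
(connected components of each region's induced adjacency graph) rather than
enforced: contiguity and consistency with prior maps are expert judgments
in practice, and promoting them to hard constraints would invent an
optimization the method does not define. Regionalization clusters the
`pβ_sim` matrix by default (`metric = "beta_sim"` is available for
comparison tables).

## NMDS

Ordination minimizes Kruskal's stress-1 with primary treatment of ties
(`vegan::monoMDS`, global model) from `n_starts = 100` random Gaussian
initial configurations, keeping the lowest-stress solution; stress lives in
[0, 1] and lower is better. Coordinates are centered and rotated to
principal axes with a fixed sign convention — stress-invariant
post-processing that makes coordinates reproducible. Determinism holds per
seed; the retained stress is the minimum over starts by construction.

## The synthetic-flora generator

The generator emulates the shape of a county-scale genus-level dataset: a
dated ultrametric phylogeny and a presence–absence matrix whose sites
belong to regions nested in realms.

*Tree.* Pure birth (Yule): from two lineages, a uniformly chosen extant
lineage bifurcates after an Exp(k)-distributed wait at k lineages, plus a
final Exp(n) wait, giving expected depth `Σ_{k=2..n} 1/k` — a closed form
the suite checks by Monte Carlo. Only relative branch lengths matter to
`pβ`, so the simplest ultrametric generator suffices; a coalescent or
birth–death tree would change branch-length profiles but not the logic.

*Occupancy.* Affinity is planted at two depths. Each realm occupies one of
the two root-side subtrees (with probability `realm_depth_bias`, default 1,
realms alternating sides so they separate at the deepest split). Within a
realm, each region has a focal clade; focal clades are chosen disjoint with
sizes in `clade_band` (7.5–15% of the tips), maximizing the smallest clade,
because the min()-based turnover indices behave badly when regions differ
grossly in richness. A site then carries: its focal-clade tips with
`p_focal` (0.9), other tips of its realm's subtree with `p_realm` (default
twice `p_background`, i.e. 0.1), all remaining tips with `p_background`
(0.05), and a final per-cell flip with `noise_flip` (0.01). Empty sites are
resampled; trees on which the clade constraints cannot be met (e.g. a
near-pectinate root split) are redrawn from the same stream, keeping
fixed-seed fixtures deterministic and always pipeline-valid.

The intermediate realm-level probability deserves its rationale. With only
two occupancy levels, the realm labels would not actually be planted in the
data: every deep edge of the tree subtends enough tips that background
occupancy alone makes it present in essentially every site
(`1 − (1−p_b)^m ≈ 1` for m ≳ 75 tips), so shared deep branches cancel out
of every pairwise comparison and the within-realm versus between-realm
contrast in `pβ_sim` is measurably zero. Realms must therefore be expressed
as a mild compositional enrichment across the realm's subtree — which is
also the biological reading of a floristic realm: weak but pervasive
affinity across many lineages, much weaker than regional endemism. The
twofold default keeps the region level dominant (silhouette still selects
the planted number of regions) while making the realm split recoverable at
the dendrogram's deepest cut.

*What passing tests show, and what they do not.* The generator produces
independent Bernoulli occupancies structured only by clade membership. Real
floras add spatial autocorrelation, environmental gradients, richness
gradients, sampling effort artifacts, and non-random extinction — none of
which are emulated. Recovery of planted structure therefore validates the
pipeline's statistical machinery (that it finds hierarchical clade-driven
structure when present and stays calibrated when absent), not its behavior
under every failure mode of real survey data.

## Problem sizes and numerical choices

The default validation scenario is 2 realms × 2 regions × 10 sites = 40
sites over 400 tips with 999 permutations — small enough that the full
pipeline (four turnover matrices, SES ensemble, five Mantel tests, eight
linkages, silhouette scan, 100-start NMDS) completes in well under a minute
on one core, large enough that the planted structure is non-trivial.
Dissimilarities are computed in double precision and never rounded before
clustering; pairwise matrices are symmetrized exactly (averaging with the
transpose) and tiny negative `min(b,c)` values from floating cancellation
are clamped to zero. Pipeline stage seeds are derived from one master seed
as independent substreams, so changing the NMDS seed cannot perturb the SES
ensemble; reruns with an identical configuration are byte-identical,
including the JSON summary (which therefore carries no timestamps — timings
go to the log).

## Known limitations

- The null model permutes labels over the whole tip pool; richness- or
  abundance-constrained nulls (independent swap and relatives) are out of
  scope.
- Nestedness components and full Sørensen/Jaccard dissimilarities are not
  computed; the method is a turnover-component analysis by design.
- Contiguity reporting requires a user-supplied adjacency list; no
  geometry is read.
- Trees must arrive with branch lengths; unit lengths can be imposed
  explicitly for topology-only exploration, but `pβ` values then reflect
  node counts, not time.
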