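---
title: "Spatial immune-contexture feature discovery: models, conventions, and design choices"
author: "icFeatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial immune-contexture feature discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icFeatures)
```

# The problem

Immunohistochemistry pipelines reduce a whole-slide image to a point pattern:
every detected cell becomes a 2D coordinate (in micrometers) with a type
label, and human annotations delimit the tissue, the tumor region, and areas
to exclude (e.g. necrosis). The immune contexture — how many immune cells of
which kind sit where, relative to tumor cells and to each other — carries
prognostic and predictive signal, but which particular summary of the point
pattern is informative for a given binary endpoint (here: MSI vs MSS status
as the running example) is not known in advance.

`icFeatures` takes the data-driven route: it enumerates a large, systematic
catalog of candidate spatial features, computes all of them for every slide,
and ranks them by how well each one alone separates the two classes,
penalizing features that cannot be computed on part of the cohort. The
output is a ranked shortlist for expert review, not a classifier.

# Data model

A slide is a `SlideObjects` object: cell points with marker `Ki67`
(single-positive, by definition proliferating non-T cells, used as a tumor
cell surrogate), `CD4`, or `CD8` (T cells, each split into proliferating and
non-proliferating), plus region geometry. Three compartments are derived:

* **entire tissue** — the annotated tissue minus exclusion polygons;
* **tumor** — the intersection of the tissue with the tumor annotation;
* **non-tumor** — the tissue without the tumor annotation.

Boundary points count as inside (regions are closed) and tumor takes
precedence over non-tumor on the shared boundary, so every retained object
lies in exactly one compartment and `area(tumor) + area(non_tumor) =
area(entire)` holds exactly by construction. Objects outside the tissue or
inside an exclusion polygon are dropped at load time and counted in the
slide log. Areas are reported in mm²; a slide without tumor annotation has
an empty tumor compartment, and tumor-region features are reported
*unavailable* rather than erroring.

Object sets are named predicates over (marker, proliferating). The default
catalog has 10 entries: `Ki67`, the three CD4 and three CD8 variants
(any/proliferating/non-proliferating), and the three combined T-cell unions.
The set list is configurable; ratio enumeration additionally uses three
extended unions (all cells, all proliferating, all non-proliferating).

# The feature catalog

## Global features

For object sets $\Omega_a, \Omega_b$, a region $R$, and $\#(\Omega \cap R)$
the number of objects of a set inside a region:

* **counts** $\#(\Omega_a \cap R)$ (dimensionless),
* **densities** $\#(\Omega_a \cap R)\,/\,\mathrm{area}(R)$ (1/mm²),
* **ratios** $\#(\Omega_a \cap R)\,/\,\#(\Omega_b \cap R)$, including the
  *fraction* special case $\Omega_a \subseteq \Omega_b$ with values in
  $[0, 1]$.

**Distance criteria** restrict a count to objects whose distance to the
nearest member of a reference combination $M$ satisfies a threshold
comparison:
$$\#\{\omega \in \Omega_a \cap R : \mathop{\vee/\wedge}_{\Omega \in M}
\mathrm{dist}(\omega, \Omega) \le\!/\!> \theta\},$$
with $\theta \in \{15, 20, 25, 30, 35, 50, 100\}\,\mu m$ by default — a few
typical cell diameters up to cytokine-range interactions. Distance-based
ratios apply one criterion to the numerator and, optionally, the identical
criterion to the denominator (`den_crit`); independent numerator/denominator
criteria are deliberately out of scope. Distances are always computed
slide-wide: a criterion does not care whether the nearest neighbour falls in
another region or tile. A cell is never its own nearest neighbour (relevant
for overlapping sets such as CD8-any vs CD8-proliferating), and the distance
to an empty reference set is $+\infty$, so `LE` criteria count 0 and `GT`
criteria count everything — the natural limiting behaviour.

## Default enumeration sizes

The default configuration enumerates, per region, 10 counts, 10 densities,
and 156 ratio pairs (all ordered pairs over the 13-set extended catalog),
giving 528 density-based global features over the three regions; and 279
distance-based combinations × 7 thresholds = 1,953 distance-based features
per region (5,859 in total). The 279 combinations are the first entries of a
documented canonical enumeration ordered by structural complexity
(single-reference fractions first, then criterion counts, then two-set
references and general ratios), which guarantees that the verification
feature — the fraction of Ki67 objects within 15 µm of the closest
proliferating CD8 — is always present. Both lists are plain data.frames in
the configuration and can be replaced wholesale.

## Heterogeneity features

Global features are slide-level averages; heterogeneity features quantify
how a base feature varies across the tissue. The tissue is covered by
axis-aligned square tiles (edges 250, 500, 1,000 µm), the base feature is
evaluated per tile with the tile as the region, and the tile values are
summarized by eight dispersion measures: the coefficient of variation (COV,
sample standard deviation over mean), the quartile coefficient of dispersion
$\mathrm{QCD} = (p_{75} - p_{25}) / (p_{75} + p_{25})$, and the relative
percentiles $p_k / p_{50}$ for $k \in \{3, 5, 10, 90, 95, 97\}$ — peak
heights and trough depths relative to the typical tile. Each measure is
computed in two scopes: all tiles, and only tiles lying entirely inside the
tumor compartment. With the default catalog this yields
2,129 base features × 8 measures × 3 edges × 2 scopes = 102,192
heterogeneity features, and 108,579 features overall.

Per-tile evaluation intentionally produces non-finite values (a ratio with
an empty denominator in a sparse tile): these follow IEEE semantics
($x/0 = \infty$ for $x \neq 0$, $0/0 = \mathrm{NaN}$) and are filtered out
before any dispersion measure is computed. At the global level, by
contrast, a non-finite ratio makes the feature *unavailable* on that slide,
which feeds the availability penalty below.

# Ranking and screening

For each feature, the values of the two classes are compared with the
Mann–Whitney ROC-AUC (ties counted ½), computed on the slides where the
feature is available. Both separation directions are equally useful for a
decision rule, so the AUC is folded: $A \mapsto \max(A, 1 - A) \in
[0.5, 1]$. The overall performance measure then penalizes partial
availability per class:
$$\mathrm{OPM} = 2\,(A_{\mathrm{folded}} - 0.5)\cdot
\frac{C_{1,f}}{C_1}\cdot\frac{C_{2,f}}{C_2} \in [0, 1],$$
where $C_i$ are the class sizes and $C_{i,f}$ the numbers of slides per
class on which the feature is available. Features with no available value
in a class are flagged unrankable and receive OPM 0 rather than erroring.
Features are returned in descending OPM order with a deterministic
lexicographic tie-break on the canonical feature id; features at or above
the screening threshold (default 0.6, a configurable and admittedly
somewhat arbitrary choice) are flagged potentially predictive.

## Significance against random features

With $10^5$ candidate features, some will separate any two groups by
chance. `significanceNull()` regenerates the experiment under the null:
i.i.d. uniform(0, 1) features of the same cohort shape and class
assignment (AUC is invariant under monotone transforms, so uniform stands
in for any continuous marginal), with full availability — availability
patterns are *not* simulated, a documented simplification. Comparing the
real and null OPM histograms shows how many screened features random data
would produce. One caution is worth stating analytically: for class sizes
19/53 the exact Mann–Whitney tail gives
$P(A_{\mathrm{folded}} \ge 0.8) = 5.9\times10^{-5}$ per feature
(`stats::pwilcox`), so once a catalog reaches $\sim 10^4$ features an
isolated null exceedance of OPM 0.6 is *expected* occasionally; the null
comparison bounds the false-positive count, it does not make it exactly
zero.

# The synthetic-slide generator

The generator exists so that every stage can be verified end-to-end without
any external data.

**Verification slides** are 1 mm² square tissue sections without tumor
compartment holding 1,000 Ki67 and 50 proliferating CD8 objects placed
uniformly at random under hard constraints: at least 10 µm between any two
objects and, in group A, more than 15 µm between every Ki67–CD8 pair. Group
B relaxes the separation for exactly 5 CD8 objects, which are placed within
15 µm of 5 *distinct* Ki67 objects. The fraction of Ki67 objects within
15 µm of the closest proliferating CD8 is therefore exactly 0 on every
group-A slide and at least 5/1000 on every group-B slide — perfectly
discriminatory by construction (folded AUC 1, OPM 1 at full availability).
Placing the violators next to distinct Ki67 anchors is a deliberate
disambiguation: it fixes the guaranteed lower bound of the *Ki67-denominated*
fraction at 5/1000, independent of how many CD8 objects sit near the same
tumor cell. Placement is rejection sampling with a per-object retry budget
(default 10,000 attempts; the densities involved are far below jamming, so
budget exhaustion indicates an infeasible configuration and is reported as
an error naming the constraint). Every generated slide is re-checked by an
independent $O(n^2)$ certifier before it is returned, and generation is
bit-reproducible in (configuration, seed).

**Generic slides** place objects as homogeneous Poisson processes per
compartment (counts Poisson with mean intensity × area, positions uniform
by rejection), with optional circular hotspots that multiply the local
intensity — these exercise the heterogeneity measures. Hotspot discs are
polygonized (64-gon) for the exact overlap-area computation of the surplus
intensity.

What the generator does *not* emulate: real tissue morphology (annotations
here are simple polygons), cell-detection and classification errors,
annotation noise, and spatially correlated structures beyond isotropic
hotspots. Passing tests on synthetic cohorts therefore demonstrate the
correctness of the feature computation and ranking machinery and the
end-to-end discovery logic — not that any particular feature is informative
in real tissue.

# Numerical conventions and design choices

Several conventions are underdetermined by the mathematics and are fixed
(and tested) as follows; dispersion values at full scale are sensitive to
them, so they are stated explicitly:

* **Percentiles** use linear interpolation between order statistics
  (`quantile` type 7); **COV** uses the sample (n−1) standard deviation.
* **Tile grids** are anchored at the tissue bounding-box minimum; the
  anchor is configurable (`gridOffset`) for robustness experiments. Object
  membership in tiles is half-open ($x_{\min} \le x < x_{\max}$), so tiles
  partition the plane and per-tile counts add up exactly to region counts
  on exactly tiled tissue.
* **Tile retention** requires tile–tissue overlap of at least 10% of the
  tile area (configurable), which suppresses sliver artifacts at the tissue
  boundary; per-tile densities divide by the actual overlap area, not the
  nominal tile area. Tumor-scope grids require the tile to lie entirely
  inside the tumor compartment.
* **Dispersion measures** require at least 2 finite tile values; COV is
  unavailable at mean 0, QCD at $p_{25} + p_{75} = 0$, relative percentiles
  at median 0. Unavailability is always explicit (`NA` plus a reason code),
  never a numeric sentinel.
* **Geometry** is computed exactly: polygon areas by the shoelace formula,
  intersection areas by ear-clipping triangulation plus convex clipping
  (Sutherland–Hodgman). This is robust for annotation-style polygons
  (including holes and multi-polygon regions, assumed pairwise disjoint
  within a role); its cost grows with the product of triangle counts, so
  extremely vertex-rich annotations would benefit from simplification
  upstream. Point-in-polygon tests use `pracma::inpolygon` with closed
  boundaries.
* **Nearest neighbours** are computed exactly by chunked vectorized
  distance evaluation rather than a spatial index; at the object counts of
  typical slides (10³–10⁴ points, small reference sets) this is fast and
  has no tie-breaking or approximation subtleties. The engine path is
  verified against a naive $O(n^2)$ oracle in the tests.
* **Feature ids** are canonical strings; catalogs are deduplicated and
  lexicographically ordered, so ids and orders are stable across runs and
  machines.
* **The feature store** is a per-slide plain-text (TSV) table with
  provenance headers (slide content hash, configuration hash, timestamp),
  merged at the end — slides are independent, so cohort analysis
  parallelizes at the slide level and reruns with unchanged content and
  configuration are cache hits. Any configuration change invalidates the
  affected entries via the hash.

# Problem sizes used in the test suite

The tests run the full default catalog (108,579 features) on verification
cohorts of 10 slides per group, brute-force oracle comparisons on 50 random
slides of up to 200 objects with a reduced catalog (12 ratio pairs, 12
distance combinations, 2 thresholds), and null-model calibration at
5 × 10⁴–10⁵ random features. These sizes were chosen to exercise every code
path at the documented study conditions while keeping a full run in the
order of minutes on a single core.

# Known limitations

* Tumor-scope tiling under-represents tumor boundary zones (boundary tiles
  are discarded, and different tumor fractions are covered at different
  tile sizes); intersecting tiles with the tumor would trade this against
  variable effective tile areas and is not implemented.
* The null model does not simulate availability patterns.
* Catalog enumerations are canonical defaults, not a biologically curated
  list; strong redundancies between features are intentional (single
  features should pinpoint effects) but mean the ranked list must not be
  read as independent evidence.
* Hexagonal/ring tilings, overlap-weighted statistics, texture-style
  spatial statistics over tiles, and multi-feature classifiers with
  cross-validation are out of scope.
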