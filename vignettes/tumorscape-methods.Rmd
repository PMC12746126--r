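---
title: "tumorscape: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tumorscape: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the choices made
where the design was genuinely open. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## Gating and positivity

Multiplexed immunofluorescence intensities are compared against per-marker
gates chosen on the raw intensity axis. The package rescales each marker
piecewise-linearly through three anchors — `low_anchor → 0`,
`gate → 0.5`, `high_anchor → 1`, clamped outside — and calls a cell
positive iff the rescaled value is **strictly** greater than 0.5. Two
choices here were open:

* *Linearity.* Only the gate-to-0.5 contract is fixed by the gating
  convention; the saturating shape is not. The piecewise-linear map was
  chosen because it is monotone, invertible on the anchor interval, and
  idempotent on already-scaled data with anchors 0/0.5/1, all of which are
  tested properties.
* *The boundary.* A value of exactly 0.5 (a cell sitting on the gate) is
  negative, so "above 0.5" is literal. The same convention is used by the
  MPI and QCC rules so that the three calls can never disagree about a
  gate-valued marker.

When low/high anchors are not supplied they default to the 1st/99th
intensity percentiles per marker, which is robust to outliers; the gate
itself is never inferred.

## Hierarchical phenotyping

Phenotype rules form ordered levels of `(label, boolean expression,
parent)` triples; within a level the first matching rule wins, children
are evaluated only on cells carrying the parent label, and a cell keeps
the deepest label it reached (`Other` if none). Overlapping CD8 T states
are resolved most-specific-first: resident memory (CD45RO⁺CD103⁺) before
memory (CD45RO⁺), terminal exhaustion (PD1⁺LAG3⁺TIM3⁺) before partial
exhaustion (TIM3⁻), exhaustion before cytotoxicity, proliferative
cytotoxic (GZMB⁺KI67⁺) before cytotoxic (GZMB⁺). The rule grammar admits
only marker names, AND/OR/NOT and parentheses, and is validated against
the configured marker list at construction time, so a typo is a
configuration error rather than a silently false flag.

## Microanatomical regions

Tumor boundaries are reconstructed from tumor-cell centroids by DBSCAN
(defaults `eps = 40` µm, `min_samples = 10`) followed by an alpha-shape
concave hull per cluster at concavity scale `boundary_alpha = 2·eps`.
Parameters worth knowing:

* `peritumoral_band = 50` µm — the width of "immediately adjacent"
  tissue, matching the 50 µm neighborhood convention used everywhere else
  in the package.
* `necrosis_density_quantile = 0.2`, `density_k = 10` — "sparse cell
  counts" is operationalized as a local k-NN density (k = 10) below the
  20th percentile of the field's density distribution; necrosis further
  requires DNA-debris staining and residence in the peritumoral band.
* `vessel_radius = 50` µm — perivascular tissue is anything within this
  distance of a CD31⁺ centroid.
* `boundary_buffer = NA` (auto) — a concave hull of points sampled
  uniformly from a region lies systematically *inside* the region by about
  half the point spacing, which displaces the entire peritumoral band
  inward. The reconstruction therefore dilates each polygon outward by
  half the median nearest-neighbor spacing of its cluster. Set it to 0 to
  disable the correction.

Region labels follow the fixed precedence **tumor > necrotic >
perivascular > peritumoral > distal**, so the labels are exhaustive and
mutually exclusive; necrosis is by construction a sub-class of the
peritumoral band, and vascular niches are reported separately from
generic peritumoral tissue.

The DBSCAN variant is deterministic: core points are connected components
under eps-adjacency (a point is core when `min_samples` points including
itself lie within `eps`), and a border point joins the cluster of its
*nearest* core point rather than the first one encountered, removing the
input-order dependence of the textbook algorithm. This is what makes the
boundary polygons invariant to point order, a tested property.

## Proliferation and quiescence calls

MPI is a three-way rule on five gate-scaled markers: `−1` if p21 or p27
exceed 0.5 (arrest dominates, even when proliferation markers are
expressed), else `+1` if any of KI67/CCNA2/CCNB1 exceeds 0.5, else `0`.
The original multivariate proliferation index methodology derives
thresholds from marker distributions; this package deliberately simplifies
to the gate-based rule stated above — a fidelity trade-off that keeps the
call consistent with the gating convention and makes the rule exhaustively
testable against a 2⁵ truth table. A cell with no positive marker among
the five is `0` ("neither class"), the natural reading when all five are
measured. QCC (`KI67 ≤ 0.5` and `p21 > 0.5 ∨ p27 > 0.5`) is provably a
subset of MPI = −1 on the same inputs. Group summaries report binomial
standard deviations `sqrt(p(1−p)/n)`.

## Spatial statistics

* **KDE maps** use a product-Gaussian kernel with Scott's rule bandwidth
  per dimension (`sd · n^(−1/6)`), refuse fewer than 50 points, and take
  the 98th/10th percentiles *of the densities evaluated at the cell
  positions* as clip ceiling and mask floor before evaluating the surface
  on the regular grid; the grid values are computed exactly (the kernel
  sum is cheap at these sizes) rather than interpolated from the cell
  positions. The pre-clip surface integrates to ≈1, a tested invariant.
* **Filtered Delaunay graphs** retain an edge iff its length is at most
  `filter_factor` (default 3) times the **smaller** of its endpoints'
  nearest-neighbor distances. An edge must therefore be short on the local
  scale of *both* endpoints; an isolated far-away point keeps no long
  edges, which is the behavior that "retain short-range connections"
  requires.
* **Neighborhoods** use the inclusive 50 µm rule (distance to at least
  one target ≤ radius) with each neighbor counted once.
* **Proximity** is the per-cell nearest-neighbor distance to a target
  population (kd-tree backed), with the mean exposed for "average
  distance" summaries and `log(d + 1 µm)` as the log option.
* **Subtype ratios** return `NA` (flagged) on a zero denominator, never
  infinity.

## Microregional signatures

Counts are normalized with median-of-ratios size factors (genes with a
zero count in any microregion are excluded from the geometric-mean
reference), then `log10(x + 1)` transformed — the pseudocount is the
package's choice, as log-transforming raw zeros is otherwise undefined.
ssGSEA follows the Barbie formulation as implemented in GSVA: genes
ranked by expression, weight of a set member equal to its rank value
(highest expression = largest rank, average ranks for ties) raised to
`alpha = 0.25`, and the score is the summed difference between the
weighted in-set ECDF and the unweighted out-of-set ECDF. Written out in
ambiguous prose this convention is easy to invert (giving the highest
gene the *smallest* weight); the package pins it down with a literal
brute-force oracle test at 1e−9.

Stratified association uses two-sided Pearson correlation per compartment
(p from the t statistic on n−2 df; strata with n < 3 or zero variance are
flagged NA) and the Mann-Whitney U rank test (exact null distribution for
combined n ≤ 20 without ties; tie-corrected normal approximation with
continuity correction otherwise). No multiple-testing correction is
applied by default, matching per-test reporting conventions; a
Benjamini–Hochberg column is available via `adjust = "BH"`.

One subtlety of size factors: scaling the counts of a single microregion
by λ scales its size factor by `λ^(1−1/m)` and every other factor by
`λ^(−1/m)`, because the geometric-mean reference includes the scaled
column. Ratios of size factors — and normalized counts up to a common
reference shift — are exactly equivariant, and that is the property the
tests assert.

## The synthetic-tissue generator

The generator states a world and sticks to it:

* a 2000 × 2000 µm field split into two domains; circular tumor nests
  (radii 300–350 µm) with uniformly scattered tumor cells at per-domain
  tumor fractions 0.45/0.40; ambient immune/stromal cells from a fixed
  mixing table; one vessel corridor (CD31⁺ cells within ±10 µm of a
  polyline); one necrotic sector inside the peritumoral band where cells
  are thinned to 20% of ambient density and flagged debris-positive.
* per-marker two-component log-normal intensities: negative component at
  median 100, positive at 1000, both with log-SD 0.4 — a decade of
  separation at ~40% CV, typical of a well-behaved IF channel. The true
  gate is the geometric midpoint (~316); under these defaults true
  positivity is recovered for ≳99% of cells, comfortably above the 95%
  separability the tests require.
* tumor cell-cycle states with biologically ordered co-expression: all
  cycling states KI67⁺, G2/M adds CCNA2/CCNB1, M adds pH3, arrest states
  are KI67⁻ with p21 and/or p27. The default mixture plants 28% cycling
  (MPI +1) and 20% arrest-positive (MPI −1) tumor cells.
* microregion counts: negative-binomial (size 2) around log-normal gene
  baselines with per-MR library-size factors (log-SD 0.15); genes of an
  active signature get a ×4^activity mean shift; latent activities of two
  signatures can be drawn from a Gaussian copula correlated only within a
  designated compartment (default rho 0.7 peritumoral, 0 tumor) to
  emulate compartment-restricted association patterns.

What it does **not** emulate: segmentation errors, spatial intensity
gradients and autofluorescence structure, cell shapes, marker spillover,
3-D tissue, or inter-patient variability. A green test on synthetic
tissue therefore establishes that the pipeline recovers parameters from
data satisfying its own assumptions — not that those assumptions hold in
any particular specimen. Scales were chosen for desk-scale testing (10⁴
cells), not to match any whole-slide dataset; when a necrotic zone is
configured the returned table is slightly smaller than `n_cells` because
zone cells are thinned.

All generators take a mandatory seed, use one global RNG stream, restore
the caller's RNG state, and are byte-identical across repeated calls.

## Known limitations

* Polygon dilation uses per-vertex normal offsets, adequate for the small
  sampling-bias buffer but not a general polygon offsetting algorithm.
* Alpha-shape rings with pinch points fall back to the convex hull of the
  cluster; interior holes are not represented.
* The Mann-Whitney exact path requires tie-free data (midranks switch to
  the corrected normal approximation, as in common implementations).
* GeoJSON I/O handles single-ring polygons only, which is what the region
  model produces and consumes.
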