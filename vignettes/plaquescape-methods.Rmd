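---
title: "Methods: spatial neighbourhood and subregion analysis of plaque tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial neighbourhood and subregion analysis of plaque tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaquescape)
```

This vignette documents the statistical model behind each module, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic generator does and does not
emulate. Nothing stated here goes beyond what the package's tests and
`scripts/acceptance.R` themselves compute.

## The data model

A sample is a set of segmented cells (centroid in µm, area in µm²,
substate label, and the segmenter's QC fields: average transcript
assignment confidence, `max_cluster_frac` — a doublet indicator — and
`lifespan` — a stability indicator), a set of transcripts (coordinates,
Phred-like Q-score, either a cell assignment with a confidence or a noise
flag), a cell × gene count matrix, and a set of named subregion polygons.
All geometry is in real-valued micrometres; there is no pixel grid.

## Synthetic tissue generator

The generator exists so that every downstream statistic can be exercised
against planted ground truth. It emulates the *structure* of a
segmented imaging run, not its biology:

- **Geometry.** The tissue is a disc. The lumen is a 64-gon; every other
  region (fibrous cap, necrotic core, intima, media) is a concentric
  annulus emitted as one simple polygon — the ring is cut open by a slit
  of half-width 1 nm, so shoelace areas equal the emitted-vertex areas
  exactly and regions are genuinely disjoint. Control samples consist of
  lumen, intima and media only, with the intima extended to the lumen.
- **Cell placement.** Each substate occupies a radial band (fractions of
  the tissue radius), optionally restricted to an angular sector. Cells
  are placed with *uniform areal density* within their band (radius drawn
  as `sqrt(U(inner², outer²))`). Uniform-in-radius placement was rejected:
  it concentrates cells near the lumen (density ∝ 1/r), which injects an
  artificial radial gradient into neighbourhood-vector magnitudes and
  distorts any Euclidean analysis of those vectors. Gaussian radial
  jitter (default sd 10 µm) softens band edges; jitter 0 keeps bands
  exact, which the tests use for exact geometric checks.
- **Counts.** Gene counts are negative binomial with mean
  `program_mean × area / mean_area` and a dispersion (size) parameter
  shared across genes — overdispersed counts whose expectation scales
  with cell area, matching why area normalisation exists. Default
  programs give each substate 4 marker genes (mean 4) over a background
  of 0.45 per gene, so a typical cell clears the 10-nonzero-gene QC
  threshold the way most real cells do. No gene–gene correlation is
  simulated.
- **Transcripts.** One transcript per count unit, scattered around the
  cell centroid; Q-scores are normal (mean 32, sd 7) so a few percent
  fall below the Q < 20 filter; assignment confidences are Beta.
  Noise transcripts are uniform over the tissue disc, carry confidence 0
  and no cell id; their number is set so the expected noise *fraction*
  of all transcripts equals `noise_transcript_rate` (default 0.1).
- **QC fields.** Per-cell average confidence is Beta (default
  Beta(16, 2)); `max_cluster_frac` is Beta(40, 1) and `lifespan`
  Gamma(shape 10, scale 12), chosen once so that the default QC filters
  retain the large majority of cells, as they do on acceptable real
  segmentations.
- **Seeds.** One master seed; per-sample child seeds are derived by a
  counter, so sample *i* of a cohort can be regenerated alone,
  byte-identically.

What passing tests on this generator show is that the *statistics* are
implemented correctly and recover planted structure under realistic
geometry and noise; they do not show that any particular biological
claim transfers to real plaques, whose segmentation errors, panel
composition and spatial correlation structure are richer.

## Segmentation selection and QC

The confidence AUC fits a Gaussian KDE (Scott's bandwidth, 512-point
grid over the data range ± 3 bandwidths) to the per-cell average
confidences of a candidate segmentation and integrates the density over
[0.75, 1] by the trapezoid rule, normalised by the total density mass so
the value is a proportion and candidates of different dispersion are
comparable. The bandwidth is fitted per candidate. Zero-variance input
short-circuits: 1 if the constant is ≥ 0.75, else 0. The best candidate
is the argmax; ties break lexicographically on candidate id.

Filter boundaries follow strict-removal semantics: a transcript with
Q-score exactly 20 is kept, an assigned transcript with confidence
exactly 0.5 is removed (the assigned-transcript rule is a strict `>`),
and a cell sitting exactly on a cell-filter threshold is kept. Noise
transcripts pass only the Q-score filter and remain flagged. Filters are
idempotent and the attrition log counts per-criterion failures (their sum
can exceed the number removed, since one cell can fail several criteria).

## Subregions

Polygons are treated as closed sets — a cell on a boundary is inside —
which is the conservative choice for thin regions. Where digitised
polygons overlap, assignment follows anatomical containment
(lumen > thrombus > necrotic core > fibrous cap > intima > media).
Normalised areas divide by the sum of annotated region areas (the lumen
included by default; `include_lumen = FALSE` excludes it from both
numerator and denominator). Noise accounting bins *every* transcript by
its own coordinates, so counts conserve: regions plus "unassigned" sum
to the sample total.

## Composition and morphology

Fraction matrices are percentages per stratum (rows sum to 100);
thrombus-derived cells are excluded before tallying. Ward clustering uses
`hclust(method = "ward.D2")` on Euclidean distances of raw percentages —
column z-scoring is available but off by default, since the fractions
already share a scale. The number of clusters is an analyst's parameter
(default 4); the package does not automate its selection. Associations
use OLS with the slope's t-test for numeric pairs and two-sided rank-sum
tests for two-level factors, each BH-corrected across the declared
family. Patient-level random effects are out of scope; where samples
share patients, the OLS p-values should be read as descriptive.

## Neighbourhood enrichment

The spatial graph connects cells of the same sample at Euclidean distance
≤ radius (closed ball, default 100 µm). Neighbourhood vectors count
neighbours per substate with the focal cell excluded (`include_self`
exists for sensitivity analysis); isolated cells get zero rows.

Leiden clustering runs on an exact kNN graph (Euclidean, ties broken by
row index, default k = 15) of the pooled neighbourhood vectors, with the
modularity objective. Raw counts are the default feature space; `log1p`
is available. Two caveats are documented deliberately: modularity has a
resolution limit, so recovering a small number of large spatial domains
requires a resolution well below 1 (the package's domain-recovery checks
use 0.02 on ~4000 cells), and all-identical vectors short-circuit to a
single cluster, since a kNN graph over exact duplicates is degenerate.

The enrichment score of a substate pair {s, t} in a cluster is the
number of unique undirected edges joining s and t with both endpoints in
the cluster; same-substate pairs are included, and scores over all pairs
sum to the within-cluster edge count (a conservation law the tests check
on every instance). The null shuffles substate labels uniformly *within
each sample* — shuffling across samples would break exchangeability,
because samples differ in composition. With `l`/`r` the number of
permutations whose score falls strictly below/above the observed one,

```
p_left  = (l + 1) / (N + 1)
p_right = (r + 1) / (N + 1)
p_two   = min(2 p_left, 2 p_right), capped at 1
```

so p-values are never 0. Strict counting is the defining convention of
this test (a fully tied null gives `p_left = p_right = 1/(N+1)`, not 1);
its type-I calibration under exchangeable nulls is verified empirically
in the acceptance suite at N = 500 over 200 null cohorts. Agresti-Coull
intervals on the tail proportions (`ñ = N + z²`, `p̃ = (x + z²/2)/ñ`,
half-width `z √(p̃(1−p̃)/ñ)`) are combined endpoint-wise by the same
min-doubling rule, capped at 1. Only `l` and `r` are accumulated across
permutations, so memory does not grow with N. BH correction is joint
across all (cluster, pair) tests by default (`per_cluster_fdr` switches
to within-cluster families). One master seed drives per-permutation child
seeds through a counter.

## Local spatial statistics

Both statistics operate on binarised cell identities of one sample.
Standardisation uses the population SD (divide by n), so for
row-standardised weights the mean of the local Moran values equals the
global bivariate Moran's I exactly — an identity the tests verify.

- **Local bivariate Moran's I**: `I_i = z_x,i · Σ_j w_ij z_y,j` with
  row-standardised kNN weights (k = 30 default, distance ties broken by
  row order, small samples use all available neighbours). The statistic
  is asymmetric in (x, y) by construction.
- **Local Getis-Ord G** (plain G, self excluded):
  `G_i = Σ_{j∈N(i)} x_j / Σ_{j≠i} x_j` with binary distance-band weights
  (default 2500 µm). `G_i ∈ [0, 1]` for binary data. Cells with no
  neighbours, or with a zero denominator (a lone positive at an isolated
  cell), are emitted as `NA` with a warning rather than silently dropped.

Inference uses *conditional* permutation — the focal value stays in
place and the remaining values are redistributed over the other cells —
the classical scheme for local statistics. Each permutation draws one
random ordering of the n−1 "other" indices shared across cells and
remaps it per focal cell, which keeps the cost at O(n·k) per permutation.

Two inferential choices deserve emphasis. First, the Moran p-value is
one-sided on the *right* tail (positive local association): a folded
smaller-tail "one-sided" p is not uniform under the null and would make
calibration unverifiable. Negative association shows up in the quadrant
categories (HH/HL/LH/LL from the signs of `z_x` and the lag), not in the
p-value. Second, both statistics are heavily discrete for binarised data
(the lag takes k+1 values), so tie handling dominates calibration:
strict tie exclusion is anticonservative and full tie inclusion
conservative. The package uses the mid-p convention — ties contribute
half to each tail — which the acceptance suite shows restores KS
uniformity of the null p-values. The Getis-Ord p is two-sided
(`min(2 p_left, 2 p_right)`, capped), with hot/cold assigned by the sign
of the deviation from the permutation null mean among significant cells.
The Moran permutation count defaults to 999, as does Getis-Ord.

## Layering gradients

Expression is min-max normalised per gene *within* each sample — the
only reading that makes values comparable across cells of a sample while
compensating for depth differences across samples; constant genes map to
0 so profiles stay finite. Substate profiles are plain means; the top-20
genes by across-substate profile variance (ties by name) are Z-scored per
gene with the population SD.

Lumen distance is the Euclidean distance from the cell centroid to the
nearest point on any lumen polygon's boundary (0 inside the lumen;
fragmented lumens take the nearest fragment), normalised by the sample's
maximum raw distance — a per-sample scale that makes the 0.25 cap mean
"the innermost quarter of the tissue's depth range". The cap *filters*
cells (normalised ≤ 0.25) rather than truncating values, because its
purpose is to restrict attention to subluminal tissue. Layering ranks
substates by median normalised distance over included cells.

## Problem sizes and numerical choices

The test and acceptance suites run at sizes chosen to make the
statistical claims sharp while staying lightweight: oracle equivalences
on ≤ 300-cell instances; exact permutation enumeration on a 4-cell
square; type-I calibration over 200 label-shuffled cohorts of 150 cells
at N = 500; domain recovery on 2 × 2000 cells; archetype recovery over
20 cohort seeds; hotspot and layering recovery over 50 seeds each. The
sector-shaped spatial domains used for domain recovery are separated by
cell-free gaps wider than the graph radius: concentric three-band
domains at 2000 cells per sample cannot simultaneously give informative
neighbourhood vectors (mean degree ≈ n(r/R)²) and a small border zone
(≈ 4.7 r/R of the tissue area), so band-planted truth would be
ambiguous near borders — a generator design choice for identifiability,
not a limitation of the clustering.

## Known limitations

- The generator plants piecewise-constant architecture; it does not
  simulate images, thrombi, segmentation artefacts, or gene–gene
  correlation.
- Leiden modularity needs a resolution chosen for the expected domain
  scale; there is no automatic selection.
- Mixed-effects models for patient-nested designs are out of scope; the
  association helpers are plain OLS/rank-sum.
- Mid-p inference for the local statistics trades a small amount of
  conservatism for calibration; at very small permutation counts the
  p-value grid is coarse regardless.
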