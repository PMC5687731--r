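---
title: "Vertex-wise white matter connectivity: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vertex-wise white matter connectivity: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfconn)
```

## The model

`surfconn` treats white matter connectivity as a property of cortical
surface locations.  The inputs are a triangulated cortical mesh in
millimetre world space and a tractogram — an unordered set of undirected
3-D polylines whose extremities lie near the cortex.  Three rules define
everything downstream:

1. **Selection.**  A streamline *starts from* vertex *v* if either of its
   two extremities lies within the selection radius (default 5 mm,
   Euclidean, closed ball) of *v*.  Both extremities are eligible
   independently; a streamline may start from many vertices, and a
   streamline whose two extremities both fall near one vertex contributes
   twice there.  Streamlines shorter than the minimum length (default 3 mm)
   are discarded first — at 3 mm they are almost certainly tracking noise.
2. **Ending.**  For each selected (streamline, extremity) pair, the *ending
   vertex* is the mesh vertex globally nearest to the *other* extremity.
   Only the selecting side is radius-constrained; the ending side is a pure
   nearest-vertex projection.
3. **Weighting.**  Each streamline carries weight *w* = 1/*L*.  Streamline
   tractography reconstructs long pathways more often than short ones in
   proportion to their length, so length-inverse weighting removes that
   count bias.

From the selected sets, each vertex receives the **mean tracts' length**
and the **connectivity indices**

$$CI_{short}(T) = 100\cdot\frac{\sum_{L_i \le T} w_i}{\sum_i w_i},\qquad
  CI_{long}(T) = 100\cdot\frac{\sum_{L_i > T} w_i}{\sum_i w_i},$$

with sums over the streamlines starting from the vertex.  The default
cut-off is 30 mm — in the motivating application, the group-average mean
tract length — and because any single cut-off is arbitrary, the indices are
swept over 5–30 mm (short) and 30–60 mm (long) in 5 mm steps.

A vertex that selects no streamline is **invalid**: it carries `NA`, is
excluded from smoothing stencils and statistics, and is never zero-filled.
Zero-filling would read as "100% long-range" or "0% short-range" and bias
every comparison that touches sparsely tracked cortex.

### Boundary convention

The source definition of the indices assigns the boundary length to both
classes (short: *L* ≤ 30, long: *L* ≥ 30), so the two percentages would sum
to more than 100 whenever a streamline has exactly the cut-off length.
`surfconn` uses *short*: *L* ≤ *T* and *long*: *L* > *T*, which makes the
two indices an exact partition (`CI_short + CI_long = 100`, asserted in the
test suite).  The boundary set has measure zero for continuous lengths, so
the change is numerically immaterial while making the invariant testable.

### Choices the source leaves open

- *Is the mean tracts' length weighted?*  Not stated.  The default is the
  unweighted arithmetic mean (the literal reading of "mean length of all
  fibers"); `weighted = TRUE` gives the 1/L-weighted mean, which is the
  harmonic mean of the selected lengths.  Both are exposed.
- *Are termination proportions weighted?*  The sulcal/gyral analysis is
  explicitly length-normalized, so termination maps default to
  `weighted = TRUE` for consistency; the flag is exposed.
- *Deduplication of doubly selected streamlines at one vertex?*  Not
  stated; both extremities count once each (the symmetric choice for
  undirected fibers).
- *Nearest-vertex ties* are broken toward the lowest vertex index, for
  determinism.

## Endpoint search

The selection rule is implemented with a uniform spatial grid: vertices are
binned into cubic cells at least as large as the selection radius, each
extremity gathers candidates from its 27 surrounding cells, and candidates
are distance-tested exactly.  Because the grid only prunes candidates and
the final comparison is the same `d² ≤ r²` test an exhaustive search would
make, the result is identical to the brute-force all-pairs assignment — the
test suite asserts bit-identity against an independently written exhaustive
oracle on meshes up to 10,000 vertices.  The cell count is capped (cells
grow beyond the radius when the radius is tiny relative to the scene) so
the integer cell keys stay exactly representable in doubles.

## Smoothing

Maps are smoothed by iterated nearest-neighbor averaging: one step replaces
each valid vertex's value by the unweighted mean of itself and its valid
one-ring neighbors (the center vertex is included for stability; invalid
vertices neither change nor contribute).  The number of iterations realising
a target FWHM depends on the mesh's edge lengths, so it is *calibrated*
rather than derived: unit impulses at a few well-spread vertices are
smoothed step by step, each response is fitted to a Gaussian in
graph-geodesic distance (weighted least squares of log value on squared
distance, weights = vertex area × value), and the smallest iteration count
whose mean fitted FWHM reaches the target is returned, together with the
whole measured FWHM-per-iteration curve.  Graph shortest-path distance
along edges approximates the geodesic; at the 10 mm scales involved, and on
meshes with ~1 mm edges, the approximation error is far below the
calibration's granularity (one iteration step).  The default target is
10 mm FWHM, the standard choice for surface-based group studies.

After one step the impulse response is flat over its support, so its fitted
FWHM is infinite; calibration therefore requires a finite fit before
accepting an iteration count, and in practice targets are reached after
several steps where the response is already Gaussian-like.

## Group statistics

Per-subject maps in vertex correspondence are compared with an ordinary
least-squares GLM at each vertex (intercept, binary group, age, sex,
optionally white matter volume), t-testing the group contrast.  A vertex
must be valid in every subject.  Supra-threshold clusters — connected
components under mesh adjacency of vertices with |t| above the
cluster-forming threshold — are measured by area, the sum of member vertex
areas (one third of incident triangle areas, so vertex areas tile the
surface exactly).

Cluster-wise correction uses Freedman–Lane residual permutation: the
reduced model (covariates only) is fitted, its residuals are permuted
across subjects and added back to the reduced fit, the full model is
refitted, and the maximum cluster area over both signs is recorded per
permutation.  Each observed cluster's corrected p is
`(1 + #{null max ≥ observed}) / (1 + B)` — the unbiased estimator, whose
minimum attainable value is `1/(1+B)`.  This replaces the simulation-based
correction used by the original surface-analysis toolchain with a
self-contained procedure targeting the same family-wise error over cluster
area; the test suite verifies type-I error conservation on null cohorts.
The cluster-forming threshold is *not* reported in the source work; the
default here is the two-sided p < 0.001 equivalent t (a conservative modern
default — change `forming_p` to explore sensitivity).  Cluster-wise
significance defaults to p < 0.01.

Numerical edge cases: vertices where the model fits the data exactly
(residual variance below 10⁻²⁴ of the data scale) get t = ±∞ for a nonzero
contrast and t = 0 when the contrast effect is also zero, rather than 0/0.

**Effect size** is Cohen's d of the per-subject cluster-mean values,
(group level 1 − group level 2)/pooled SD — with levels
`c("control", "patient")`, positive d means control > patient.  The source
reports effect sizes without a formula; cluster-mean Cohen's d is the
interpretation used here, and it is documented as such.

**Reliability** across replicate acquisitions uses ICC(2,1) — two-way
random effects, single measure, absolute agreement — chosen because the
replicate ("session") is a random facet one wants to generalize over; the
variant was not specified in the source.  CV is 100 × within-subject SD /
within-subject mean, averaged over subjects.

## The synthetic world

The generator exists so that every claim above is testable without imaging
data.  Its defaults state one fixed world:

- **Mesh**: icospheres (closed, genus 0) at 80 mm radius — the scale of a
  hemisphere — or a sinusoidally folded sheet whose analytic curvature sign
  (positive in valleys = sulci) exercises the sulcal/gyral classifier.
- **Streamlines**: a two-component length mixture, 60% "short"
  (15 ± 5 mm) and 40% "long" (45 ± 10 mm), truncated at the 3 mm filter —
  numbers chosen to straddle the 30 mm cut-off the way real cortico-cortical
  length distributions straddle it, with plenty of mass on both sides.  A
  start vertex is drawn uniformly; the end vertex is the one whose
  graph-geodesic distance best matches the drawn target length (among
  vertices whose straight-line distance does not exceed it); the polyline
  is a two-segment chord with a perpendicular bump sized so its arc length
  *equals* the target.  A straight chord cannot realise a target length
  longer than the endpoint separation, so a pure straight-with-jitter
  construction would compress the upper tail of the stated mixture; the
  bump keeps the realised lengths faithful to it.  Extremities are jittered
  off the surface by a 0.5 mm (per axis SD) Gaussian, re-drawn if the
  jitter pushes a length under the minimum.
- **Cohorts**: per-subject maps at baseline 50 (a CI_short-like percent),
  subject random intercept SD 5, iid vertex noise SD 10, age drawn 6–28
  years with a −0.3/year trend (short-range connectivity declines with age),
  balanced groups.  A planted effect shifts the patient group by
  `100 × delta_p_short` percentage points inside a geodesic patch.  The
  "tractography" mode instead runs the full per-subject
  streamlines-to-CI pipeline with `p_short` shifted in the patch.

What the generator does **not** emulate: anatomically curved fiber
trajectories, spatially correlated vertex noise, hemispheric asymmetry,
registration error between subjects, or tractography failure modes
(crossing-fiber dropout, premature termination).  A green test therefore
establishes the correctness of the *computations* — selection, indices,
smoothing, inference — under the stated statistical structure, not the
anatomical validity of tractography itself, and inter-subject vertex
correspondence is assumed given throughout (spherical registration is out
of scope).

Reproducibility: every stochastic entry point takes a seed; cohort
generation derives per-subject sub-seeds so subjects can be regenerated
independently.  Fixed seeds give bit-identical outputs.

## File formats and conventions

All computation happens in the surface file's millimetre world space.  TCK
files store world coordinates natively; TRK files store corner-origin
voxel-mm coordinates and are converted at read time using the header's
voxel size and voxel-to-RAS matrix (`world = M (p/voxel_size − 0.5)`), so
downstream code never sees voxel units.  An optional 4×4 affine (plain
4-line text) brings tractograms into surface space.  Vertex maps round-trip
through FreeSurfer curv, GIFTI and CSV; the invalid-vertex sentinel is NaN
in binary formats and an empty field in CSV.  Inside R, indices are 1-based;
every on-disk format keeps its native 0-based convention, converted at I/O.

## Known limitations

- Graph-geodesic (edge-path) distances overestimate true geodesics by a few
  percent on coarse meshes; this affects FWHM calibration and synthetic
  length targeting, not the metrics themselves, which are Euclidean.
- The permutation engine assumes exchangeable subjects under the reduced
  model; heteroscedastic groups or family structure would need a restricted
  permutation scheme.
- Smoothing iteration counts are integers, so the realised FWHM overshoots
  the target by up to one step's worth of width (the calibration report
  exposes the whole curve).
- `assign_endpoints` keeps the full pair table in memory; tractograms far
  beyond ~10⁶ selected pairs would need chunked aggregation.
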