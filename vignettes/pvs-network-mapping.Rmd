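---
title: "Mapping perivascular spaces onto cognitive brain networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping perivascular spaces onto cognitive brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsmap)
library(dplyr)
```

## The problem

Perivascular spaces (PVS) are pial-lined fluid channels around cerebral
arterioles and venules. When enlarged, they become visible as thin,
hyperintense tubular structures on T2-weighted MRI, and their burden is read
as a marker of impaired perivascular (glymphatic) fluid exchange. pvsmap
implements a complete, testable pipeline for the question: *is regional PVS
burden, aggregated over large-scale cognitive networks, higher in patients
with more severe symptoms?* It targets the setting of a small pediatric
cohort (around 36 subjects) with clinical anisotropic scans, symptom
categories (language impairment, sensory disturbances, motor stereotypies,
support level), and no normative control group — so the analysis is a
within-cohort, rank-based, extreme-of-outcome comparison.

The pipeline has four stages, each exposed as ordinary functions over data
frames and arrays:

1. **Segmentation** — detect PVS voxels in a co-registered T2-like volume by
   local intensity contrast, cluster them under 26-connectivity, and measure
   per-cluster morphometrics.
2. **Quantification** — roll clusters up to per-region and per-network
   tables with region-size and white-matter normalizations, plus the Potter
   ordinal visual score for cross-checking.
3. **Group analysis** — extreme-of-outcome splits and Mann–Whitney U tests
   per (network, side, measure), rendered as a yellow/orange/red severity
   map.
4. **Synthetic data** — a phantom-MRI generator with voxel-level ground
   truth and a cohort generator with exact categorical marginals, which
   together let every stage be validated without patient data.

## The region registry and the networks

PVSs are quantified in the white matter underlying 32 cortical areas and in
4 basal-ganglia nuclei per hemisphere — 36 areas per side, 72 in all, each
carrying 4 variables (count, volume, diameter, underlying WM volume), hence
288 data points per subject. Three networks are analyzed per hemisphere:

* **DMN** (default mode): angular gyrus, medial orbitofrontal, middle
  temporal, posterior cingulate, precuneus (5 areas);
* **CEN/FPN** (central executive / frontoparietal, merged because their key
  regions overlap heavily): caudal anterior cingulate, inferior parietal,
  inferior temporal, lateral orbitofrontal, caudate, rostral middle frontal
  (6 areas);
* **SN** (salience): insula, rostral anterior cingulate (2 areas).

Two naming tensions had to be resolved. The insula is a salience-network key
region but is not one of the 72 quantified areas; and the DMN's "angular
gyrus" falls inside the inferior parietal label of DKT-style parcellations,
while inferior parietal is itself a CEN/FPN key region. The registry
therefore has two views: `build_registry("strict_72")` is exactly the
72-area listing, and `build_registry("analysis")` (the default) adds insula
and angular gyrus as two additional labeled regions per hemisphere (label
ids 37/137 and 38/138). The angular gyrus carries the DMN membership and
inferior parietal stays CEN/FPN-only, which keeps the two networks disjoint
and the per-hemisphere membership counts at 5/6/2. Basal-ganglia regions
other than the caudate (thalamus, putamen, pallidum) are quantified but
belong to no analyzed network; the caudate is treated as one label (no
separate "head").

## Segmentation model

The detector is deliberately simple and transparent. After optional
intensity uniformization, the **local contrast** at a voxel is its intensity
minus the mean of its surrounding voxels — by default the 26 voxels of the
3×3×3 neighborhood (`kernel = "3d26"`), with an in-plane 8-neighbor variant
(`"inplane8"`) available because the slices (4.4 mm) are far thicker than a
PVS. At volume borders the neighborhood truncates to in-volume voxels. A
voxel inside the WM ∪ BG masks is a PVS voxel when its contrast **strictly
exceeds** `diff_threshold` (default 60; a contrast of exactly 60 is not a
PVS). Supra-threshold voxels touching by face, edge or corner form one
cluster (26-connectivity), implemented as union-find over the sparse voxel
set and cross-checked in the tests against an independent graph-components
oracle.

Because a thin bright tube raises its own intensity but barely moves the
26-neighbor mean, contrast at a tube voxel is close to the full tube-to-
background contrast; conversely a voxel interior to a thick blob sees mostly
tube neighbors and low contrast. The detector is therefore tuned to exactly
the thin-tubular morphology of PVSs.

Choices worth stating explicitly:

* **Intensity scale.** An absolute threshold of 60 only means something on a
  particular intensity convention (uniformized T2 with parenchyma around
  100). `uniformize()` estimates the low-frequency field by normalized
  convolution (Gaussian smoothing of the masked image over the smoothed
  mask, FWHM 12 mm, two estimate-and-divide passes — the second pass mops up
  the residual the first leaves near mask boundaries) and rescales to
  preserve the masked median. The threshold is fully configurable.
* **Volume in voxels.** Slice thickness (4.4 mm) exceeds PVS thickness, so
  mm³ volumes would be dominated by the slice dimension; volumes are voxel
  counts throughout, and PVS volume is additionally normalized by the
  subject's WM voxel count (`wm_normalized_pvs_volume`) and by region voxel
  counts (`volume_fraction`, `count_fraction`).
* **Diameter.** There is no single field-standard definition, so the
  package states its own: per axial slice the cluster intersects, take the
  equivalent circular diameter `2·sqrt(area/π)` of the in-plane area; the
  cluster diameter is the maximum over slices. In-plane only, for the same
  anisotropy reason. A single 0.8×0.8 mm voxel gives 0.903 mm.
* **Region assignment.** A cluster spanning labels is counted once, in its
  majority label; ties break to the smallest label id; clusters entirely on
  background are excluded from region tables (with a message). The regional
  "diameter" variable is the mean over the region's clusters (0 when the
  region is empty, keeping tables rectangular).
* **Network diameter** is the cluster-count-weighted mean of member-region
  diameters; an unweighted mean would let near-empty regions dominate.

## Statistical model

For each symptom the cohort is split by the **extreme-of-outcome** rule:
only the lowest- and highest-severity categories are compared (language:
none/low vs absent; sensory and stereotypies: no vs yes; support: level 1 vs
level 3); intermediate and unknown values are excluded. At n ≈ 30 this
maximizes contrast at the cost of sample size.

Each of the 18 cells (3 networks × 2 sides × 3 measures) is tested with a
two-sided **Mann–Whitney U** test at α = 0.05. The implementation delegates
to `stats::wilcox.test`: exact U distribution when the combined n is ≤ 20
and tie-free, otherwise the normal approximation with continuity and tie
correction; the exact branch is pinned in the tests by full enumeration over
all group assignments. No multiplicity correction is applied by default —
each cell is judged marginally, as is common in small exploratory
neuroimaging cohorts — and a
Benjamini–Hochberg option (`fdr = TRUE`) is available for the 18 tests.

The **severity map** colors each (network, side) cell by how many of its
three measures are significant: 0 → none, 1 → yellow, 2 → orange, 3 → red.
The color is a deterministic function of the significance triple and is
invariant to the order the measures are listed in.

## What the synthetic data emulates — and what it does not

**Phantoms** (`generate_phantom()`) are built on the clinical geometry:
0.8 × 0.8 × 4.4 mm voxels, default 64 × 64 × 16 grid. The brain is an
ellipsoid, the basal ganglia two interior blobs, and each hemisphere's
masks are partitioned into the registry's regions by nearest-seed
assignment, so every region exists and every masked voxel is labeled. The
background is a per-region constant (base 100 ± 2) with an optional smooth
multiplicative bias field to exercise uniformization, plus Gaussian noise.
Tubes are rasterized in physical mm (a voxel belongs to a tube when its
center is within the tube radius of the axis segment); default radii
0.3–0.7 mm and lengths 2–7 mm keep them thin relative to both in-plane
spacing and slice thickness. By construction tubes are strictly interior to
the grid, 26-connected, pairwise non-adjacent, and no tube voxel has more
than 9 of its 26 neighbors in the same tube — the constructive form of
"thin": every PVS voxel keeps a majority of background neighbors, which is
what guarantees noiseless recovery at contrasts comfortably above the
threshold. The default contrast 120 is 2× the threshold.

Phantoms do **not** model MRI physics: no Rician noise, no partial-volume
averaging beyond center-in-radius rasterization, no T1 channel (its roles —
registration target and tissue segmentation — are upstream of this
pipeline). Passing recovery tests on phantoms shows the chain implements
its stated definitions exactly; it does not certify detection performance
on real scanner data.

**Cohorts** (`generate_cohort()`) reproduce the reference cohort
composition *exactly* (36 subjects; 22 M / 14 F; language 17/4/15; sensory
20/13/3 unknown; stereotypies 17/16/3 unknown; support 10/6/20); unknown
values sit deterministically on the last subjects so split sizes are
reproducible. The metric noise model is the package's own choice (none is
published): per (network, side), PVS count is Poisson with mean 4 per member
region (so ~20/24/8 for DMN/CEN-FPN/SN), volume is count × a lognormal mean
cluster size (median 9 voxels, σ_log 0.35), diameter is lognormal (median
1.3 mm, σ_log 0.2) — positive, right-skewed distributions standard for
morphometry. Males get volumes elevated by `1 + sex_effect` (default 0.35,
emulating the reported higher male WM-PVS burden; the magnitude is
unpublished and chosen for visible separation at n = 36, not to match
patient values). Injected effects shift one metric column of the
high-severity group by a stated number of baseline standard deviations;
with all effects at 0 the groups are exchangeable, and the pooled type-I
error of the 18-cell analysis sits at the nominal 0.05 (checked over 2000
simulated cohorts). Real per-region PVS distributions are unpublished, so
none of these defaults claims to match patient effect magnitudes — they are
calibrated for clear statistical power at the study's sample sizes (a
1.5-SD shift at n = 15/17 is detected in well over 80% of replicates).

## Numerical choices and degenerate inputs

* Thresholding is strictly `>`; equality is never segmented.
* Cluster connectivity is fixed at 26; the constructor rejects anything
  else.
* `uniformize()` errors on an all-zero mask; a flat image passes through
  unchanged to within 1e-6 relative.
* Empty PVS masks yield zero-row cluster tables, all-zero region/network
  tables, and fractions of 0 (not NaN) for empty regions.
* `potter_score` uses the printed bin edges inclusively (10 → 1, 11 → 2,
  20 → 2, 21 → 3, 40 → 3, 41 → 4) and rejects negative or fractional
  counts.
* Spearman correlation errors on constant inputs rather than returning NA.
* Tube placement retries up to `max_tries` per tube and then fails loudly;
  determinism is end-to-end under one integer seed.

## Problem sizes

The default desk-scale configuration (64 × 64 × 16 phantom, ≤ 50 tubes,
36-subject cohorts) runs each stage in under a second on one core; the full
simulate → segment → quantify → compare chain completes in a few seconds,
and the package's statistical validation suites (2000 null cohorts, 500
effect replicates) in a few minutes.

## A worked run

```{r pipeline, eval = FALSE}
out <- cmd_all(tempfile("pvsrun"), seed = 1, symptom = "language")
read_severity(out[["severity"]])$cells
```

Or stage by stage:

```{r stages, eval = FALSE}
reg <- build_registry()
ph <- generate_phantom(n_pvs = 40, seed = 1)
mask <- segment_pvs(ph$t2, ph$wm_mask, ph$bg_mask, ph$spacing)
clusters <- cluster_pvs(mask) |>
  annotate_clusters(ph$labels, ph$spacing, reg)
q <- quantify_subject(mask, clusters, ph$labels, ph$wm_mask, reg)
q$networks

cohort <- generate_cohort(cohort_spec(seed = 1))
res <- run_comparisons(cohort, "language")
severity_map(res) |> autoplot()
```

## Known limitations

* The intensity-difference kernel's true size/dimensionality in the source
  convention is unknown; both provided kernels are reasonable readings, and
  the choice can shift borderline voxels.
* The absolute threshold of 60 is scanner-convention-bound; on data with a
  different intensity normalization it must be re-derived.
* No vesselness or shape prior: any thin bright structure in the masks
  (e.g. an unmasked vessel) segments like a PVS.
* Per-cell p-values of the original patient analysis are not reproducible
  from synthetic data and are not targeted; only structural facts, worked
  examples and operating characteristics (type-I error, power) are.
* No covariate adjustment (age, sex) is performed in the group comparisons;
  the sex effect present in the generator is deliberately *not* removed by
  the analysis, mirroring the bivariate design.
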