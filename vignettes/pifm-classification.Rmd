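---
title: "Classifying plantar intrinsic foot muscles by PCSA and fiber length"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying plantar intrinsic foot muscles by PCSA and fiber length}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

The sole of the foot houses ten plantar intrinsic foot muscles (PIFMs).
Two architectural parameters summarize what each muscle can do: the
physiological cross-sectional area (PCSA, cm²) is proportional to the
muscle's maximal force, and the fiber length (FL, cm) to its maximal
shortening velocity. Neither is measurable directly from routine
anatomical MRI. `pifmclass` implements a fusion approach for the seven
large PIFMs (ABDH, ABDM, ADDH-OH, ADDH-TH, FDB, FHB, QP): in-vivo
morphometry (muscle volume and length from segmented image stacks) is
combined with cadaveric architecture constants, and the resulting
per-sample (PCSA, FL) feature space is partitioned into morphological
subtypes with k-means, followed by frequency statistics on the
muscle-by-cluster table.

## The estimation model

For a muscle with measured volume $V$ (cm³) and length $L$ (cm), with
cadaveric fiber-length-to-muscle-length ratio $r \in (0,1]$ and pennation
angle $\theta$:

$$\widehat{FL} = L \cdot r, \qquad
  \widehat{PCSA} = \frac{V \cos\theta}{\widehat{FL}}.$$

Assumptions worth keeping in mind:

* $r$ and $\theta$ are *population constants* taken from cadaveric
  studies and applied uniformly to every participant. Inter-individual
  variation in architecture is therefore absorbed into the volume and
  length terms only. `estimate_cohort()` accepts per-sample `ratio` /
  `pennation_deg` override columns for sensitivity analyses.
* For muscles with several muscular heads (FDB, FHB, QP) the ratio is the
  unweighted mean across heads, kept at full precision
  (`average_heads()`): FHB uses $(0.29 + 0.26)/2 = 0.275$, not the
  rounded 0.28 — the full-precision value reproduces the published
  cohort-mean FL (2.03 cm) where the rounded one does not. FDB is the
  exception: its 5th-toe head has no printed ratio, so the head mean is
  not computable and the printed muscle-level 0.25 is shipped instead.
* Angles are stored in degrees (the unit cadaveric tables print) and
  converted to radians only inside the cosine.
* Nothing is rounded until presentation.

The identity $\widehat{PCSA}\cdot\widehat{FL}/\cos\theta = V$ holds to
machine precision and is exercised as a property test.

## Morphometry from label stacks

`extract_acsa()` converts a segmented label stack (slices ordered
proximal to distal) into per-slice anatomical cross-sectional areas:
labelled pixel count × pixel area. Volume is the ACSA sum × slice
thickness (contiguous slices). Length is the *inclusive* visible-slice
count × thickness: a muscle visible in a single slice has length one
slice thickness, never zero. The half-open alternative
((count − 1) × thickness) is not recoverable from the measurement
description; the inclusive convention was chosen because it avoids the
zero-length degeneracy and keeps length monotone under extended
visibility. A muscle counts as visible in a slice iff its ACSA is
strictly positive — no minimum-area filter is applied.

The adductor hallucis transverse head runs orthogonally to the scan
axis, so its length uses the in-plane medial-to-lateral pixel span
(inclusive, × pixel size) across all slices where it appears; which
in-plane axis is medial–lateral is reader configuration (`ml_axis`,
default: image columns).

Labels are assumed to be clean muscle tissue; excluding bone, tendon and
fat is the segmenter's responsibility. NIfTI voxel sizes are converted
from mm to cm at the reader boundary (unknown spatial units are treated
as mm, the de-facto NIfTI standard).

On voxelized elliptic-cylinder phantoms with 0.05 cm pixels the volume
error stays below 2% and the length error below one slice thickness;
these bounds are enforced in the test suite.

## Clustering

Features are z-scored per column with the sample SD (n−1 denominator,
the convention of mainstream statistics environments; switchable to the
population SD). Clustering is Lloyd's algorithm with k-means++ seeding,
50 restarts by default; restart $r$ draws from an RNG stream seeded with
`seed + r`, so results are exactly reproducible and individual restarts
replayable. Convergence: assignments unchanged or WCSS improvement
< 1e-10, capped at 300 iterations. Empty clusters are repaired by
relocating the point farthest from its centroid. The returned solution
is the restart with minimal within-cluster sum of squares (WCSS).

The WCSS-vs-k curve (k = 1..10 by default) is made monotone by
warm-starting each k with the best (k−1) solution plus the worst-fitted
point as one extra deterministic initialization. The number of clusters
is selected by the knee rule: after min–max normalization of both axes,
the k with maximal perpendicular distance to the chord joining the
curve's endpoints; ties break toward smaller k (parsimony). The exact
initialization, restart count and elbow formalization used in the
original MATLAB analyses of this kind are generally unreported, so these
are documented package choices; consequently per-sample assignments are
not expected to reproduce any specific published run, only aggregate
structure is.

For reporting, clusters are re-indexed by descending centroid PCSA
(ties: ascending FL), so "cluster 1" is always the large-PCSA/short-FL
group regardless of initialization.

## Frequency statistics

`build_contingency()` counts samples per (muscle, cluster); row totals
equal the participant count. Independence is tested with the Pearson
chi-square statistic, no continuity correction (for a 7 × 4 table of 182
samples the expected counts are well away from the Yates regime). Empty
clusters are dropped with a warning rather than zero-padded.

Post-hoc, for each muscle, membership frequencies are compared between
every pair of clusters *that both contain samples of that muscle*, with
a two-sided exact binomial test of equal allocation on
$(n_a, n_a + n_b)$, Bonferroni-corrected within the muscle's family of
compared pairs. Restricting the family to occupied pairs is the design
choice that operationalizes "frequencies of muscle X higher in cluster a
than b": a muscle confined to one cluster offers nothing to compare, and
zero-count pairs would only inflate the correction factor. On the
published 7 × 4 count table this procedure reproduces every published
significance call (ADDH-OH 25 vs 1 and FDB 24 vs 2 significant, FHB 19
vs 6 and 19 vs 1 significant under its family of three, ABDH 14 vs 12
not significant). An adjusted-residual alternative can be built from the
chi-square output's expected counts.

Normality screening uses the Lilliefors-corrected one-sample
Kolmogorov–Smirnov test (parameters estimated from the sample make the
plain KS null distribution invalid); it requires n ≥ 5, the domain of
the Lilliefors p-value approximation.

Cluster profiles map centroid z-scores to ordinal labels — PCSA:
extremely small (≤ −1.5), small (−1.5, −0.5], moderate (−0.5, 0.5),
large (≥ 0.5); FL: short (≤ −0.5), moderate, long (≥ 0.5). The cuts were
fixed so that a centroid one SD out is "large/long", mirroring how such
cluster narratives are phrased; on default synthetic cohorts they
reproduce the four canonical labels (large PCSA/short FL; moderate/
moderate; small PCSA/long FL; extremely small PCSA/moderate FL).

## The synthetic cohort generator

`generate_cohort()` emulates a cohort of healthy young adult men (26
participants × 7 muscles by default). Each participant carries a latent
standard-normal body-size factor $u$; every measurement gets a score
$z = \rho u + \sqrt{1-\rho^2}\,\varepsilon$ and is mapped through the
Gaussian copula to its marginal: a normal truncated at zero with the
published per-muscle volume/length means and SDs. Because those SDs are
small relative to the means (truncation mass < 1e-4 everywhere), the
target mean/SD are used directly without truncation re-calibration — a
documented approximation. A moment-matched log-normal marginal is
available as an alternative.

$\rho = 0.5$ by default: participants with bigger feet have uniformly
bigger muscles, which produces realistic within-muscle spread without
destroying between-muscle separation. No cohort covariance data are
published, so $\rho$ is an assumption and is configuration-exposed;
volume and length of the same muscle share the latent factor but have
independent residuals.

What the generator does *not* emulate: measurement/segmentation error,
non-Gaussian shape, muscle-specific covariance structure, or any
volume–length coupling beyond the shared size factor. Pipeline tests
passing on synthetic cohorts therefore demonstrate that the method
recovers the cluster structure implied by the published summary moments
— not that it reproduces any individual-level dataset.

## Problem sizes and determinism

Default analyses run 26 × 7 = 182 samples, k up to 10, 50 restarts; the
stochastic recovery checks aggregate 20 cohorts, a scale at which the
elbow selects k = 4 in the clear majority of seeds and QP and ADDH-TH
each concentrate in ≥ 90% single-muscle clusters. Every random step
(generation, restarts) is governed by one integer seed; identical
configuration and seed give identical reports.

## Known limitations

* Cadaveric constants come from small, older donor samples; applying
  them to young athletes' feet imports that bias wholesale.
* The FDB muscle-level ratio 0.25 is not the mean of its three printed
  head ratios (0.2467) and its provenance is not stated in the cadaveric
  source; the printed value is shipped because it is the value the
  estimation chain was defined with.
* Whether multi-head pennation angles should be head-averaged is
  unknowable from the printed tables; the muscle-level values are used.
* The elbow rule is one formalization of a visual heuristic; silhouette
  or gap statistics are deliberately out of scope.
* Exact per-sample cluster assignments of any real cohort depend on
  unpublished individual data and are not a reproduction target.
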