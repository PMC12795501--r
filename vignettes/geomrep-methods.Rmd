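---
title: "Methods: geometric regularity, representational similarity, and oddball decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometric regularity, representational similarity, and oddball decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geomrep)
```

## The scientific question

Human perception of simple geometric shapes appears to rely on a discrete,
symbolic code - the presence or absence of right angles, equal sides, equal
angles, and parallel sides - rather than only on the graded similarity
computed by generic visual feature hierarchies. `geomrep` implements the
complete computational chain used to test this idea: a regularity-graded
quadrilateral stimulus set, the symbolic feature-coding model, behavioral
dissimilarity estimation from visual-search performance, cross-validated
multivariate pattern analyses of MEG-like and fMRI-like data, and
nonparametric cluster inference. A synthetic-data module plants known
representational structure in every data modality so that the whole chain
can be validated against ground truth.

## The quadrilateral set

Eleven quadrilateral families span the regularity scale, from the square
down to a fully irregular shape. All are matched on the mean pairwise
distance between their four vertices (mpd), the quantity used to
standardize deviant displacements; where the family geometry allows, the
bottom side is additionally pinned to a common length.

Both constraints cannot hold jointly for the parallelogram-like families.
Among parallelograms with bottom side $L$ the mpd is
$(2L + 2s + d_1 + d_2)/6$ with $d_1 + d_2 \le 2\sqrt{L^2+s^2}$ (equality at
right angles), and setting this bound equal to the square's mpd forces
$s = L$: the square is the unique maximizer. The rectangle, losange and
parallelogram therefore use fixed canonical proportions and a uniform
rescaling that matches the mpd exactly, with the residual bottom-side
deviation recorded on the returned object. Every other family solves one
free shape parameter by root finding (`stats::uniroot`, tolerance near
machine precision) with the bottom side pinned.

```{r shapes}
shapes <- make_reference_shapes()
round(vapply(shapes, mpd, numeric(1)), 6)
```

The irregular ("random") family is a frozen vertex set chosen, by a
documented randomized search, so that all 22 feature predicates are at
least 20% away from their decision thresholds at the default tolerance -
its feature count is robustly zero, not accidentally so. Corner-displacement
deviants move the bottom-right vertex by a fixed fraction (default 45%) of
the shape's mpd along one of four diagonal directions ($\pm 45^\circ$,
$\pm 135^\circ$); a direction that would self-intersect the polygon is
rejected with an explicit error so callers can try another.

## The geometric feature code

A quadrilateral is encoded by 22 binary features: 4 right angles, 6
pairwise angle equalities, 6 pairwise side-length equalities, and 6
pairwise side parallelisms. All predicates are evaluated up to a
dimensionless tolerance $\tau$ (default 0.125). The tolerance normalization
is a design choice the source text leaves open; we use relative bounds -
$|\theta - 90^\circ| \le \tau \cdot 90^\circ$ for right angles, pairwise
differences $\le \tau \times$ the pair mean for equalities, and undirected
direction differences $\le \tau \cdot 90^\circ$ for parallelism - because
they are dimensionless, scale invariant, and reduce to exact predicates as
$\tau \to 0$. Feature sets are nested in $\tau$ (raising the tolerance
never removes a feature).

Two dissimilarity readings exist for feature vectors: the count of features
not in common (Hamming distance, a true metric) and the difference between
total feature counts. They coincide when feature sets are nested; we adopt
Hamming as the default (`feature_dissimilarity(method = "hamming")`) because
the count reading degenerates for pairs of equally-complex but different
shapes, and expose the alternative behind `method = "count"`.

```{r features}
feature_table(shapes)[, c("shape", "score")]
```

## Behavioral dissimilarity

In the visual-search task, one intruder shape hides among exemplars of a
reference shape; easy search means the two shapes are far apart
perceptually. For each ordered pair, dissimilarity = mean accuracy / mean
response time (pooled over participants before the ratio), ordered
estimates are averaged (no prediction for search asymmetries), and the 55
unordered entries are z-scored. Error-trial RTs are included by default
(the estimator is defined on all trials; a switch excludes them).
Per-participant matrices - single trials giving 0 or 1/RT - are available
unpooled and are never z-scored per participant.

Model comparison uses ordinary least squares on the vectorized entries with
standardized model predictors, ordinal (non-metric) MDS
(`MASS::isoMDS`, 32 seeded restarts plus a classical-scaling start, best
stress kept, reported as a fraction), and projection of a per-shape
property (e.g. the feature count) onto the embedding axes. Because ordinal
MDS only constrains ranks, recovered configurations match metrically
realizable inputs only approximately (we test Procrustes residuals at 5%).
Significance of the projection uses a participant-level bootstrap: resample
participants, re-estimate the RDM, re-embed, Procrustes-align to the
point-estimate embedding, re-project; two-sided percentile p-values. The
statistical test behind the original projection analysis is not specified
in the source; the bootstrap is our choice and is not claimed to match it.

## Crossnobis distances and whitened model comparison

Condition patterns measured in independent folds (runs) are compared with
the cross-validated Mahalanobis distance,
$$d_{ij} = \mathrm{mean}_{m \ne n}\,
 (x_i^m - x_j^m)^\top \Sigma^{-1} (x_i^n - x_j^n) / P,$$
normalized by the channel count $P$ (a toolbox convention, switchable).
Because the two factors carry independent noise, the estimator is unbiased:
within-condition distances average zero and estimates may be negative; they
are never clipped. Two fold schemes are provided: all fold pairs, and
leave-one-out (each fold against the mean of the others), the scheme used
for the sensor-level time courses. The noise covariance $\Sigma$ is
estimated from residuals with shrinkage toward the diagonal (analytic
intensity in the Schafer-Strimmer style); with no residuals the identity is
used and the metric degrades to cross-validated Euclidean distance.

Empirical and model RDMs are compared by whitened Pearson correlation: both
entry vectors are multiplied by the matrix square root of an entry-precision
estimate before correlating. Model RDMs are compared one at a time (they
are constructed to be effectively orthogonal; no partialling). Two points
deserve emphasis:

* Under the balanced miniblock design with homoscedastic sensor noise, all
  RDM entries share one variance, so identity precision *is* the correct
  whitening and the comparison reduces to plain Pearson correlation. This
  is the default of `epoch_rdm_series()`.
* A data-driven diagonal precision (inverse variance of the per-fold
  distance contributions) is available for unbalanced designs
  (`crossnobis_rdm(return_precision = TRUE)`). Raw fold-variance weights
  are correlated with the values themselves - entries that are large by
  chance also look noisy - which biases whitened correlations negative
  (about $-0.12$ under pure noise in our simulations). The estimator is
  therefore shrunk toward uniform (`precision_shrink`, default 1), trading
  a little efficiency for approximate unbiasedness.

## Time-resolved oddball decoding

Epochs (epochs x channels x timepoints; default 250 Hz, -150 to +1150 ms)
come from miniblocks of 30 items with 4 oddballs that never occupy the
first six positions and never repeat back to back. The first six epochs of
every block are discarded (they can never be oddballs, and block
transitions make them oddballs of the previous shape). Each epoch is
normalized before fitting; the default z-scores the channel vector per
timepoint (whole-window scaling is the alternative; which normalization the
original used is not derivable, so both are provided). At each timepoint a
logistic regression classifies reference vs oddball, trained on all shapes
pooled and tested per shape on held-out runs, with the six run splits:
even vs odd runs, first vs second half, runs {1,2,5,6} vs {3,4,7,8}, each
in both directions. A small ridge penalty (default 0.01) keeps fits defined
on separable timepoints. Performance is the rank-based ROC AUC (robust to
the 4:26 class imbalance, invariant to monotone score transforms),
averaged over splits with missing cells propagated, then optionally
smoothed with a centered 100 ms uniform window (truncated at the edges).

Downstream statistics: per-participant Pearson correlation of the per-shape
AUC with a regularity predictor at each timepoint, submitted to a
one-tailed sign-flip cluster test ($2^{13}$ permutations, cluster-forming
p < 0.05); and the decoding latency, the first post-onset sample where the
smoothed AUC exceeds 0.57, regressed on regularity per participant with a
one-tailed t-test of the slopes against zero in the direction "more regular,
earlier".

## Cluster-based sign-flip inference

One-sample t statistics per timepoint (or voxel), clusters formed by
contiguity above the cluster-forming threshold (temporal: per-point
p < 0.05 one-tailed; spatial: voxelwise p < 0.001, 6-connectivity by
default), cluster mass = sum of t values, and a null distribution of
maximum masses from random sign flips of each participant's whole series or
map (exact under symmetric null distributions). The corrected p-value is
k/N - the count of permutation maxima at least as large as the observed
mass over the number of permutations, without re-adding the observed data -
so 3 exceedances in 10,000 swaps give p = 0.0003. Zero-variance points are
excluded rather than silently assigned. With few participants the test can
enumerate all $2^n$ sign patterns exactly (`exact = TRUE`).

## Searchlight analysis

Spheres are all integer voxel offsets with Euclidean norm *strictly* less
than the radius; at radius 3 (6 mm at 2 mm isotropic voxels) this gives
exactly 93 voxels, which pins down both the strictness and the voxel-unit
convention (the inclusive rule would give 123). Centers where more than 50%
of the sphere falls outside the brain mask are discarded (strict at the
boundary). Per center, a crossnobis RDM across runs over the sphere voxels
is correlated with each model RDM and assigned to the center; maps are
smoothed with a mask-aware 8 mm FWHM Gaussian (missing voxels excluded from
kernels, so constant maps stay constant) before group inference.
Subject-specific ROI responses use leave-one-run-out selection of the top
10% most responsive voxels and collect responses only from the remaining
runs, so selection and estimation never share data.

## The synthetic-data generator

The generator is the package's ground-truth instrument, not a fixture. To
plant a target RDM in channel space, conditions are embedded by classical
scaling of the square-rooted dissimilarities, padded and rotated by a
seeded random orthonormal map: squared Euclidean distances between the
returned patterns equal the RDM values up to one global scale (exact for
Euclidean-realizable RDMs such as Hamming feature distances; verified at
1e-6 relative error). Squared-distance matching is the right contract
because crossnobis is a squared metric - the planted crossnobis RDM is then
proportional to the model RDM. Patterns are normalized *after* rotation so
that the per-channel (per-voxel) RMS amplitude equals the nominal `snr`
times the noise sd irrespective of the embedding dimension; normalizing
before rotation would silently dilute the per-channel signal as the channel
or region size grows.

MEG-like epochs superimpose, on Gaussian channel noise (optionally with a
random SPD spatial covariance of condition number at most 10), boxcar
time courses of two model geometries: geometry A in an early window
(default 60-320 ms) and geometry B in a late window (default 128-400 ms),
the two windows identified by the sensor-level analyses this package
emulates. Oddball epochs add a deviance pattern whose amplitude is
`amp0 + amp_slope * regularity` and whose onset is
`lat0 - lat_slope * regularity`; deviance directions share a common
component across shapes (jitter 0.3), since a decoder trained on pooled
shapes can only transfer across shapes if the oddball signature is largely
shared. Defaults were fixed once to place single-subject effects in the
range reported for such data: pattern amplitude 5% of the noise sd
(within-window whitened correlations near 0.5) and oddball amplitudes
giving peak AUCs around 0.6-0.8 with a clear regularity gradient. The
in-trial 800 ms size ramp of the original presentation is a property of the
displays, not of these signals, and is deliberately not expressed (no
analysis consumes it).

fMRI-like beta volumes plant two disjoint regions (default 5x5x5 blocks on
a 20x20x20 grid) expressing two model geometries, with independent noise
per run; the default per-voxel amplitude (snr 0.3) puts single-subject
in-region searchlight similarities around 0.5-0.6, the scale of reported
searchlight effects. What the generator does *not* emulate: event overlap and
hemodynamics, sensor forward models, artifacts, autocorrelated noise,
inter-subject anatomical variability. Passing recovery tests therefore
validates the estimators and their wiring, not robustness to those
real-data complications.

## Validation scale

The test suite validates the chain at desk scale with fixed seeds: 20
cohorts of 10 simulated participants (14 channels, epochs -100 to 500 ms)
for the two-window recovery; 20 participants for the oddball decoding
recovery; 10 subjects on a 20x20x20 grid for the searchlight double
dissociation; 330 simulated participants for the behavioral estimator; 200
null datasets of 20 participants x 200 timepoints at 500 permutations for
cluster-test calibration (family-wise error required in [0.01, 0.10]).
`scripts/acceptance.R` re-runs the same computations from scratch at
comparable sizes and writes the resulting quantities as JSON.

## Known limitations

* The exact vertex coordinates of the original 11 shapes are not published
  in text form; the families here satisfy the stated matching constraints
  and produce a graded, square-maximal regularity profile, but individual
  coordinates (and hence model RDM entries) need not match the originals
  numerically.
* Whether the original tolerance was relative or absolute in degrees, which
  four deviant directions were used, and the exact whitening estimator of
  the original toolbox are not derivable from the source; our choices are
  documented above and equivalence is not claimed.
* Ordinal MDS embeddings are identified only up to monotone distortion,
  rotation and reflection; all downstream comparisons use Procrustes
  alignment.
* The sign-flip tests assume per-participant distributions symmetric about
  zero under the null; correlations of smoothed AUC series satisfy this
  only approximately.
* Searchlight clusters are intrinsically dilated: the similarity map's
  signal support is the true region expanded by the sphere radius, and the
  8 mm group smoothing expands it further while also shrinking map noise,
  so the cluster-forming threshold sits at a low similarity level. A
  significant cluster therefore contains its planted region plus a shell of
  roughly three voxels. Voxel-set overlap scores (Jaccard) between the
  cluster and the raw planted block consequently saturate around 0.3-0.5
  for compact regions at these scales - approximately
  $k^3 / (k+6)^3$ for a region of width $k$ voxels - and would reach 0.5
  only for regions too large to fit the simulated grid. Recovery of the
  double dissociation should be judged by significance and containment of
  the planted regions, not by a strict overlap ratio against the
  undilated block.
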