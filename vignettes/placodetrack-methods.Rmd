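---
title: "Methods: track kinematics, circular ANOVA and morphometry in placodetrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: track kinematics, circular ANOVA and morphometry in placodetrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placodetrack)
```

placodetrack quantifies cell and growth-cone behaviour in live imaging of
the zebrafish olfactory placode (OP) and adjacent forebrain, and the
tissue-scale morphometry that accompanies it. This vignette is the
package's account of the underlying models and the choices made where the
problem left the design open.

## Coordinate frame and data model

All positions are micrometres in the embryonic frame: `ml` mediolateral
(+ lateral), `dv` dorsoventral (+ dorsal), `ap` anteroposterior
(+ anterior); time is minutes. The atom is the `timed_track`: one tracked
object (a nucleus or a growth cone) with strictly increasing sampling
times on a nominal frame-interval grid (typically 10 min). Missing frames
are recorded as gaps, never interpolated: interpolation would
systematically deflate short-lag displacement statistics, so every
statistic either skips pairs with a missing endpoint (MSD) or excludes
gap-spanning steps from time-normalised quantities (speed).

Sign conventions are a package choice — imaging data only fix the display
("dorsal up, lateral left" in rose plots), not the algebra. The
convention is carried explicitly in every `track_set` so it can be
audited.

## Mean squared displacement

For lag $\tau = k\,\Delta t$ the per-track time-averaged MSD is

$$\mathrm{MSD}_i(\tau) = \left\langle \lVert \mathbf r_i(t+\tau) -
\mathbf r_i(t) \rVert^2 \right\rangle_t,$$

averaged over all admissible sample pairs of track $i$, then averaged
unweighted across tracks. Time-averaging over all overlapping pairs is
the standard estimator for short single-particle tracks; the per-lag pair
count is reported so weighted variants can be reconstructed. The default
maximum lag is 50 % of each track's duration, because long-lag estimates
rest on very few pairs and are dominated by noise. For 3D diffusion the
expectation is $6D\tau$; for uniform drift $\mathbf v$ it is
$\lVert\mathbf v\rVert^2\tau^2$ — both are exercised as closed-form
checks, and `msd_slope()` (ordinary least squares over the first 10 lags,
with intercept to absorb any localisation-error offset) recovers $D$
within 10 % on 200 simulated Brownian tracks.

## Tissue-drift subtraction

During the forebrain flexure the whole head rotates ventrally and
anteriorly, so raw growth-cone tracks mix intrinsic motility with bulk
tissue motion. The reference motion is estimated frame-wise: the mean
displacement over all reference-cohort cells (OP cell bodies) present at
both ends of each frame interval. It is deliberately not a fitted smooth
trajectory — frame-wise means make the estimate unbiased under the
additive model and the correction exactly invertible. Frames with no
eligible reference cell get a zero step plus a warning rather than an
interpolated one. Corrected positions subtract the cumulative reference
motion since the track's first frame, so corrected and raw tracks share
their starting point, and a cohort corrected by its own drift has exactly
zero ensemble mean net displacement (verified to 1e-9).

## Windowed speed, persistence, orientation

Movies are cut into consecutive closed windows (the growth-cone regime:
windows of 200 min starting at 200 min, four windows over a 1000-min
movie). Per track and window:

* **path length** — sum of all consecutive displacement magnitudes;
* **mean speed** — distance travelled divided by elapsed time *with
  data*: steps spanning a gap are excluded from both numerator and
  denominator, so a gap cannot dilute the speed;
* **persistence** — net displacement magnitude over path length,
  in $[0,1]$ by the triangle inequality (1 for straight motion, 0 for a
  closed loop); defined as 0 when the path length is 0;
* **orientation** — the angle of the net displacement against the DV
  axis: dorsal = 0°, +ML = +90°, in $(-180°, 180°]$.

Orientation uses the *net* (endpoint) displacement rather than a
step-wise mean direction: the measured quantity is "the angle between
the track and the DV axis", which is an endpoint property. Tracks with
zero net in-plane displacement have no defined angle; they are excluded
from circular samples and counted. A sample pair straddling a window
boundary contributes to the window containing its first sample, so no
step is double-counted.

## Circular statistics

Track orientations are circular data; genotype comparisons use a
likelihood-ratio ANOVA under a von Mises working model
$f(\theta) \propto \exp\{\kappa\cos(\theta-\mu)\}$. The concentration
link is $A(\kappa) = I_1(\kappa)/I_0(\kappa) = \bar R$; the package
inverts it by bracketed root-finding on $[0, 10^4]$ (tolerance 1e-12;
round-trip $A(\hat\kappa) = \bar R$ holds to 1e-8), never by a
closed-form approximation. Samples with $\bar R$ beyond $A(10^4)$ are
numerically degenerate and capped with a warning.

The test: under $H_0$ all groups share one mean direction ($\kappa$
estimated from the pooled resultant); under $H_1$ each group has its own
mean direction with a shared $\kappa$ estimated from the summed
within-group resultants. The statistic $2(\ell_1-\ell_0)$, floored at 0,
is referred to $\chi^2_{g-1}$. A common $\kappa$ re-estimated under each
hypothesis is the classical mean-direction likelihood-ratio ANOVA; the
choice is recorded in the result's `kappa_model` field so an
equal-$\kappa$-per-group variant could be compared. No small-sample
correction is applied, matching the practice of reporting raw p-values.

**Known limitation.** The uncorrected statistic is mildly
anti-conservative in small samples: the package's own calibration
simulation (two groups of 15, $\kappa = 2$, 2000 replicates, run in the
test suite and the acceptance script) places the empirical size at
$\alpha = 0.05$ near 0.06 rather than 0.05, while power against a 90°
mean-direction separation exceeds 0.99. Users comparing small groups
should read p-values near the threshold accordingly.

Rose histograms use equal-width, right-closed bins on $(-\pi, \pi]$; an
angle exactly on an edge belongs to the bin it right-closes. The von
Mises sampler (`r_von_mises`) is the Best–Fisher rejection algorithm.

## Morphometry

* **Extents** — per-axis max−min over main-flagged cells only. "Ectopic"
  (physically separated) cells are excluded; separation is
  operationalised as single-linkage connected components at a threshold
  (default 15 µm, about two cell diameters — the original judgement was
  by eye, so manually supplied flags always take precedence). The
  largest component is the main cluster; a size tie goes to the
  component containing the medoid of all points, which is deterministic
  under fixed input order.
* **Brain width** — ML distance between left and right brain boundaries
  at a 3 AP × 3 DV grid of query levels, by linear interpolation along
  each polyline; a negative width means the boundaries cross and is an
  error, not a value.
* **Distortion index** — boundary arc length divided by the Euclidean
  distance between its dorsal-most and ventral-most vertices (read
  literally as a point-to-point distance, not a DV-coordinate
  difference); 1 for a straight boundary, $\pi/2$ for a semicircle.
  The index is translation- and ML-reflection-invariant but *not*
  rotation-invariant, since the endpoint selection depends on the DV
  axis.
* **Interface thickness** — stations every 100 px of arc length along
  membrane A (10 stations on a 1000-px region); at each station the
  minimal distance to membrane B, converted to nm. Point-to-curve
  minimal distance is used instead of normal projection because it is
  robust to membrane roughness. Averaging is per region, then per
  embryo, unweighted.
* **Mask boundaries** — the traced frontier between two labels in an ROI
  is the chain of pixel edges separating 4-adjacent pixels of the two
  labels, with vertices at the pixel corners along the chain, so the arc
  length is exactly (number of interface pixel edges) × pixel size. The
  ROI must isolate a single open interface component; a split interface
  is reported with its component count so the caller can tighten the
  ROI. The confocal pixel size is a required parameter and is never
  defaulted.

## Synthetic data: what it emulates, what it does not

The generators reproduce the statistical structure the analyses assume,
at the study's acquisition scales chosen once as defaults in the tests
and acceptance script: 10-min frame intervals, movies of 600–1000 min
(21–101 frames), cohorts of order 10 cells per embryo for the imaging
regimes and 200 tracks where estimator calibration needs ensemble
precision, diffusion of order 0.02–0.05 µm²/min and drifts of order
0.1–0.5 µm/min, EM regions of 1000 px with gaps of 120 px (control-like)
and 40 px (mutant-like).

Walk steps are drift·dt plus AR(1) noise with stationary per-axis
variance $2D\,\Delta t$ and lag-1 correlation `persistence_p` — a
discrete Ornstein–Uhlenbeck-like persistence that is distinct from the
measured net/path persistence statistic. A shared drift applied to two
cohorts emulates the flexure; growth cones are built as intrinsic walk
plus the cumulative reference-cohort mean motion, so drift subtraction
recovers the intrinsic walk by construction. Boundaries are sinusoids of
controlled amplitude (their exact distortion index is an arc-length
integral, checked against quadrature); interfaces are parallel membranes
with a bounded sinusoidal perturbation; point clouds are uniform balls
plus displaced ectopic points with truth flags.

What synthetic data does **not** contain: tracking errors and
localisation noise, cell divisions and track splits, spatially varying
drift fields, curved (turning) flexure trajectories, non-von-Mises
orientation mixtures, segmentation artefacts in masks. Passing tests
therefore demonstrate correctness of the estimators under their stated
models, not robustness to every pathology of real microscopy data.

All generators take an explicit seed and are pure functions of
(configuration, seed); there is no hidden global RNG state between
calls.

## Numerical and degenerate-input choices

* Sampling grids are validated to 1e-6 of a frame interval; times off
  the grid are an error, not silently rounded.
* `total_displacement` and `orientation_angle` use the nearest-sample
  rule at window endpoints; no extrapolation beyond the track.
* Windows are closed intervals; a boundary sample serves as the earlier
  window's end and the later window's start.
* Zero-path-length windows give persistence 0; zero net in-plane
  displacement gives an undefined (NA) orientation, excluded and
  counted.
* $\bar R < 10^{-12}$ maps to $\kappa = 0$; fully concentrated samples
  cap $\kappa$ at $10^4$ with a warning; identical groups give
  statistic 0 and p 1.
* The group-comparison gate is Shapiro–Wilk at $\alpha = 0.05$ per group
  (both must pass for the t test, n ≥ 3 per group required for the
  check) — the most common practice; the choice and any forced override
  are recorded in the result. Mann–Whitney p-values fall back to exact
  enumeration of rank assignments when ties block the standard exact
  method and the pooled sample is small (n ≤ 18). No multiple-testing
  correction is applied; comparisons are reported per metric.
* Pipeline outputs contain no timestamps, so a config + seed pair
  reproduces byte-identical files.

## Problem sizes in the checks

The test suite and `scripts/acceptance.R` use: 100 random track sets of
up to 20 tracks × 50 frames for the MSD oracle equivalence; 200 tracks ×
60 frames for diffusion recovery; 40 growth cones over 21 frames for
drift-subtraction recovery; 2000 replicates for circular-ANOVA size and
power; 100 random clouds of up to 50 points for the ectopic-flagging
oracle; 4000-vertex polylines against arc-length quadrature. These sizes
give the estimators enough data to meet their stated tolerances while
keeping a full run in minutes on one core.
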