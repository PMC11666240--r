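# placodetrack

Quantitative analysis of cell and growth-cone behaviour in live imaging
of the zebrafish olfactory placode (OP) and adjacent forebrain, for
developmental biologists comparing genotypes (e.g. basement-membrane
mutants against control siblings). The package covers the three
quantitative layers of such a study:

* **3D track kinematics** — time-averaged mean squared displacement
  MSD(τ) = ⟨‖r(t+τ) − r(t)‖²⟩ (slope 6Dτ for diffusion, ‖v‖²τ² for
  drift), signed axis displacements, windowed mean speed and persistence
  (net displacement / path length), and subtraction of the shared tissue
  drift produced by the forebrain flexure, estimated as the frame-wise
  mean motion of a reference cohort of OP cell bodies.
* **Circular statistics** — track-orientation angles against the DV
  axis, rose histograms, and a likelihood-ratio circular ANOVA under a
  von Mises model (A(κ) = I₁(κ)/I₀(κ) = R̄ inverted by root-finding;
  statistic 2(ℓ₁−ℓ₀) against χ² with groups−1 df).
* **Morphometry** — placode extents with ectopic-cell exclusion
  (single-linkage separation), brain width at a 3 AP × 3 DV grid of
  levels, a boundary distortion index (arc length / distance between DV
  extremes), and intercellular-gap thickness from EM membrane traces
  sampled every 100 px (10 measurements per 1000-px region).

Inputs are CSV track tables (native dialect or Fiji "Manual Tracking"
exports), 2-column boundary polylines, TIFF label masks and labelled
point clouds. Seeded generators (`simulate_cohorts`,
`simulate_growth_cones`, `make_boundary`, `make_interface`,
`make_point_cloud`) produce synthetic data with the statistical
structure the analyses assume, so the whole pipeline is testable without
any imaging data. A configuration-driven runner (`run_pipeline`) writes
deterministic CSV/JSON outputs; `inst/cli/placodetrack.R` is a thin
shell wrapper.

## Worked example

Simulate coupled OP/brain cohorts riding a shared flexure-like drift,
then run the headline analyses:

```r
library(placodetrack)

op <- walk_config(n_tracks = 12, n_frames = 61, dt = 10,
                  drift = c(0.05, -0.15, 0.1), diffusion = 0.03, seed = 1)
br <- walk_config(n_tracks = 10, n_frames = 61, dt = 10,
                  diffusion = 0.05, seed = 2)
ts <- simulate_cohorts(op, br, shared_drift = c(0, -0.1, 0.1))
ts
#> <track_set> 22 tracks, dt = 10 min
#>   cohorts: op_cell=12, brain_cell=10

cur <- msd(ts, cohort = "op_cell")
head(as.data.frame(cur), 3)
#>  lag      msd n_pairs n_tracks
#>   10 12.32365     720       12
#>   20 45.31851     708       12
#>   30 98.83208     696       12
msd_slope(cur)
#> [1] 11.59519
```

The MSD at lag 10 min (~12.3 µm²) mixes diffusion (6Dτ = 1.8 µm²) with
the strong directed motion of this cohort; the growing slope reflects
the τ² drift term.

```r
s <- windowed_summaries(ts, t_start = 200, window_len = 200,
                        n_windows = 2, cohort = c("op_cell", "brain_cell"))
ok <- !is.na(s$orientation_deg)
circ_anova_lrt(circular_sample(s$orientation_deg[ok] * pi / 180,
                               s$cohort[ok]))
#>  Circular analysis of variance (von Mises likelihood-ratio test)
#>
#> LRT statistic = 14.3517, df = 1, p-value = 0.0001516
#> group mean directions (deg): brain_cell = 178.5 (n=20), op_cell = 169.1 (n=24)
#> shared kappa = 57.67   [common kappa, re-estimated under H0 and H1]
```

Both cohorts move ventrally (≈180°) under the shared drift, but the OP
cohort's extra lateral/anterior drift shifts its mean orientation by
~9°, which the circular ANOVA detects.

```r
th <- interface_thickness(make_interface(120, 1000, roughness_px = 5,
                                         seed = 3), step_px = 100)
c(th$n_samples, th$mean_nm)
#> [1]  10.0000 119.9704

distortion_index(make_boundary(boundary_config(100, 8, 3, 2000)))
#> <distortion_index> 1.4340 (arc 143.401 um / extremes distance 100.000 um)
```

A 1000-px interface sampled every 100 px yields exactly 10 thickness
measurements, averaging to the 120-px gap; a sinusoidal boundary of
amplitude 8 µm over 100 µm with 3 waves has distortion index 1.43
(1.0 would be a straight boundary).

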