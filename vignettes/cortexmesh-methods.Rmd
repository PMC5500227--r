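---
title: "Models and methods behind cortexmesh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cortexmesh}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cortexmesh)
```

`cortexmesh` analyses two coupled observations about membrane-protein
mobility: the *dynamics* side (single-particle trajectories whose
time-averaged MSD and turning-angle statistics identify the class of random
walk) and the *structure* side (superresolution images of the cortical actin
meshwork whose compartment morphometry explains the obstruction). This
vignette documents the models, the estimators, the parameter choices with
their units and defaults, and the numerical decisions that were genuinely
open — the things a referee or a maintainer would want stated explicitly.
Every number quoted here is computed by the package's test suite or the
acceptance script; the vignette adds no empirical claims of its own.

## Trajectory models

All simulators share a common observational frame: positions in micrometres
on a uniform time grid with frame interval `dt = 0.02` s (video-rate
tracking at 50 frames/s), one root seed per call, and one derived RNG
stream per trajectory index so that results are independent of batching.

**Fractional Brownian motion.** `simulate_fbm()` draws x and y as
independent fBM paths whose increments have the exact fractional
Gaussian-noise autocovariance
γ(k) = (σ²/2)(|k+1|^{2H} − 2|k|^{2H} + |k−1|^{2H}).
Synthesis is by Davies–Harte circulant embedding: the covariance circulant
of length 2N is diagonalized by FFT and a complex Gaussian vector with
variances λ/(2N) is transformed back, which is exact when all λ ≥ 0. For
fGn on the tested range H ∈ (0, 1) the embedding is nonnegative definite;
a Durbin–Levinson (Hosking) sampler is kept as an exact O(N²) fallback and
is itself covered by the tests. The ensemble MSD then grows as
2σ²k^{2H}, i.e. the anomalous exponent is α = 2H; the suite checks
|α̂ − 2H| ≤ 0.05 at 1000 trajectories × 1024 steps for
H ∈ {0.25, 0.3, 0.4, 0.5}. `step_scale` (default 0.1 μm per frame-step per
axis) only scales the curve and cancels from exponents and angles.

**Free Brownian motion.** i.i.d. Gaussian increments of per-axis variance
2 D dt; D defaults follow the freely diffusing control channel,
0.19 μm²/s, so MSD = 4 D Δ.

**Obstructed (percolation) diffusion.** A blind ant on a periodic square
lattice: at every microscopic step one of the four neighbours is drawn
uniformly and the move is accepted iff the target site is vacant — time
advances on blocked attempts (a myopic variant that only chooses among
vacant neighbours is available). Obstacles occupy exactly
`round(fraction · side²)` sites, placed uniformly; unwrapped coordinates
are reported so the periodic boundary leaves no reflection artifact in the
MSD. The interesting concentrations sit near the spanning transition of
the *vacant* phase; `estimate_percolation_threshold()` measures that
obstacle fraction by bisection on per-site uniform priorities (spanning is
then monotone in the fraction, so each realization yields one critical
value) with 4-connected top-to-bottom spanning checks; at side 256 with
200 realizations it gives ≈ 0.407–0.408, the complement of the classical
site-percolation threshold 0.5927. At 41% obstacles the fitted MSD
exponent over steps 10–10³ is ≈ 0.70 in our brute-force calibration runs;
the tests assert the frozen band 0.55–0.85 and monotonicity in crowding
against the 10% control.

*The lattice time base.* A camera frame is not a lattice step. The walk is
recorded once per frame with `steps_per_frame` microscopic steps in
between; with the default lattice constant of 10 nm — the diameter of an
individual actin filament, the molecular scale of the obstacles being
modelled — matching the vacant-lattice diffusion coefficient
a²/(4τ) to the measured free-diffusion value 0.19 μm²/s gives
τ ≈ 0.13 ms, i.e. ≈ 152 steps per 20-ms frame. This matters for the
turning-angle statistics: sampled at raw step resolution the lag-1 angles
are exactly {0°, 90°, 180°} and the distribution is grossly
lag-dependent purely through lattice discretization, an artifact of the
microscopic model rather than a property of obstructed diffusion. On the
frame time base the discretization is washed out and the distribution's
lag dependence reflects the physics. For the model-discrimination study
the walkers start on the largest vacant cluster: isolated vacancy islands
confine their walkers at a characteristic (island-size) time scale, which
is precisely the signature the statistic is designed to detect in the
*fenced* model, so including them blurs the contrast between the
scale-free and the characteristic-scale mechanisms. Unrestricted starts
remain the simulator default (molecules land anywhere).

**Hop diffusion (picket fences).** Gaussian steps on a square fence grid
of pitch L; every fence line a step crosses is tested independently in
crossing order and passed with probability `hop_probability`, otherwise
the offending coordinate is reflected about the fence — reflection rather
than rejection preserves step-length statistics. Starting points are
uniform in a compartment, so the impermeable walk is stationary from
frame one and its MSD plateaus at the two-uniform-points limit
E|r − r′|² = L²/3, which the tests verify within 5%. With
`hop_probability = 1` the fences vanish (α = 1.00 ± 0.03).

## Trajectory statistics

**TA-MSD.** The discrete estimator uses *all* overlapping windows: for lag
index k, the mean of |r(i+k) − r(i)|² over i. A 50-trajectory brute-force
double-loop oracle pins the vectorized implementation at relative 10⁻¹².
Ensemble averaging weights trajectories equally and reports the
between-trajectory standard deviation as the spread. Exponents are fitted
by unweighted least squares of log MSD on log lag; the default window
spans 2·dt to min(1 s, T/4) — short lags carry the signal, and beyond T/4
the time-average estimator is noise-dominated.

**Turning angles.** For lag Δ, θ(t) is the unsigned angle in [0°, 180°]
between r(t+Δ) − r(t) and r(t+2Δ) − r(t+Δ), computed as atan2(|cross|,
dot) over overlapping triplets; zero-length displacements carry no
direction and are skipped with a reported count (they are common on
lattices, where a blocked frame leaves the walker in place). Distributions
are histograms on [0°, 180°] normalized to unit integral, default bin
width 5° — fine enough to resolve the 180° edge, coarse enough not to
starve bins at realistic sample sizes. Brownian angles are uniform (the
suite checks a 36-bin chi-square at 10⁵ pooled angles and a 5% sup-norm
bound); anticorrelated walks peak at 180°.

One subtlety is deliberately documented rather than hidden: for fBM with
H = 0.3 the angle density rises to a *plateau* — by direct Monte Carlo of
the increment law, the terminal 5° bin exceeds its neighbour by only about
0.5%, so resolving the literal argmax at 5° bins needs ≥ 10⁷ angles. The
mode tests therefore use 15° bins, at which the edge bin dominates the
sampling noise decisively; the distribution itself is unchanged.

**Lag invariance.** `lag_invariance_statistic()` is the maximum over
distribution pairs of the sup-norm difference of binned CDFs (a binned
two-sample KS statistic). At the frozen discrimination conditions —
41% obstacles on a 512² lattice, 152 steps/frame, largest-cluster starts,
6000 trajectories × 150 frames, lags {1, 2, 5, 10, 25, 50} frames — the
obstructed walk gives ≈ 0.01–0.02 across seeds, while hop diffusion at
matched sampling gives ≈ 0.10, with its 180° peak growing to a maximum
near the compartment equilibration time (≈ 0.2 s at L = 0.4 μm,
p = 0.05) and decaying beyond: the package-level restatement of the
model-discrimination argument.

## Synthetic meshworks

**Fragmentation model.** Compartment areas of the cortical mesh follow a
log-normal law, the signature of repeated random breakage with
size-independent proportions (Kolmogorov). The generator implements that
model literally: starting from the region, every compartment at or above
`min_area` is split once per generation by an axis-aligned chord whose
relative position is drawn from a bounded law (default uniform on
[0.25, 0.75], bounded away from 0/1 to avoid slivers). Log-areas are then
sums of i.i.d. log-fractions and converge to a normal; at 11 generations
(≈ 2048 compartments on a 20 × 20 μm region, mean area ≈ 0.2 μm²) the KS
test against the fitted normal does not reject across seeds, and the
log-area skewness decays like 1/√generations. Two alternatives are kept
for comparison because the choice is consequential: sequential
single-split variants with area-weighted selection (≈ the same law) or
uniform selection, the latter producing strongly right-skewed log-areas
(leaf depths in a random recursive tree are wildly heterogeneous) and
*failing* the log-normal law — a fact worth knowing when choosing a
generative null. Chords default to cutting across the compartment's
longest side, which keeps cells compact; alternating or random
orientation are options, but alternating lets aspect ratios random-walk
to 5:1 and beyond, which no watershed can recover from a 20-nm-precision
image. The orientation rule does not affect the area sequence.

**Localizations and rendering.** Points are laid along every fence as a
Poisson process (default 500 per μm of fence), each displaced
isotropically by a Gaussian whose SD is drawn as |Normal(20, 8)| nm — the
localization precision — and assigned to uniform frames. Photophysics
(blinking, binding kinetics) is *not* modelled; frame-uniform sampling is
the stated emulation. Rendering is a plain 2D count histogram (default
10 nm/px for fixed-cell-style maps, the Nyquist choice for ≈ 20 nm
precision) with an optional normalized-Gaussian blur under a circular
boundary, so total intensity equals the localization count to machine
precision before and after blur. A zero-width filament rendered this way
fits a Gaussian cross-section of SD ≈ the localization precision, which
is both a test oracle and the correct physical reading of apparent
filament width near the resolution limit.

**Confined tracks.** `simulate_meshwork_confined_tracks()` reuses the
fence micro-rule on the meshwork's rectangle tiling (the outer boundary
always reflects), with area-weighted compartment starts; impermeable
walls keep each trajectory inside its starting rectangle exactly, which
the tests check geometrically.

## Image analysis

**Distance maps.** Exact Euclidean distance from each pixel centre to the
nearest feature-pixel centre (EBImage's exact transform), verified
against brute-force nearest-feature search; reported in nm.

**Distance-conditioned MSD.** Trajectories are cut into consecutive
200-ms segments; each segment is paired with the sliding-window
reconstruction covering its midpoint (nearest window centre on ties),
classified by the *maximum* over the segment of the distance to the
nearest actin pixel, and contributes its squared net displacement to the
distance bin. Two design constraints emerged from synthetic calibration
and are part of the method, not tuning: distances below ≈ 2.5× the
localization precision (default bins start at 50 nm) are not physically
resolvable, and the max-distance classifier has an intrinsic selection
effect there — segments that never leave the immediate vicinity of actin
are segments that barely moved, so even free walkers dip in the lowest
bin; and segments near the field-of-view edge are excluded (1 μm margin)
because the reflecting boundary compresses displacements. With both in
place, free tracks are flat (every bin within 3 SEM of the global mean)
while confined tracks (hop probability 0.05) rise monotonically with
distance — the dynamics-meets-structure contrast at simulation level.

**Watershed compartments.** Compartments are catchment basins between
actin ridges. The default landscape is the Euclidean distance map of the
thresholded (Otsu by default) smoothed image rather than the inverted
intensity itself: basin depth is then measured in pixels, making the
merging tolerance (default 1.5 px) scale-free, and flooding is several
times faster; intensity flooding is retained as an option. Ridge and
actin pixels are subsequently divided between their adjacent basins by
symmetric layer-wise growth, so labels partition the image and compartment
areas are unbiased (walls contribute half to each side); compartments
under `min_area` merge into the neighbour with the longest shared
boundary. Perimeters use a 4-direction Crofton estimate (π/2 × the
spacing-weighted mean of directional intercept counts), accurate to ≈ 2%
on digitized disks, rather than boundary-pixel counting, which biases the
perimeter–area exponent. Two coverage numbers are reported because the
underlying notion is ambiguous: `actin_coverage` (fraction of pixels at
or above the threshold) and `meshwork_actin_fraction` (fraction of
watershed boundary pixels that are actin).

On synthetic ground truth at the default study conditions (2048 true
compartments, 20 nm precision, 10 nm pixels) the segmentation recovers
the compartment count within ≈ 1%, the log-normal parameters within 3%,
and individual areas with ≈ 1% median error; 95–96% of compartments match
within 10%. The residual tail is physical, not algorithmic: compartments
below ≈ 0.01 μm² have no interior beyond the dilated walls, and
wall-position uncertainty of order the localization precision already
implies ≥ 10% area error for 150-nm cells. Tests assert the bulk
statement (≥ 90% within 10%, median ≤ 3%) rather than a per-compartment
guarantee no instrument could meet.

**Box counting.** N(ε) = number of ε×ε grid boxes (anchored at the image
origin) containing ≥ 1 occupied pixel; d_f is minus the log–log slope
over the fit range (default 2 px to a quarter of the short side — the
grid anchor and the upper cutoff are the dominant bias sources).
Optional averaging over four half-box grid offsets makes the estimate
stable under sub-box translations (±0.02 in the tests). Counts equal a
brute-force per-box scan exactly; the filled square, the line, and the
3⁷-pixel Sierpinski carpet reproduce 2, 1 and log 8/log 3 within 0.05.
`branching_ratio()` inverts R_b = R_r^{d_f} for hierarchically branched
structures.

## Pipeline and reproducibility

`run_dynamics_study()` and `run_meshwork_study()` chain the stages from a
validated configuration (plain list or YAML; unknown keys are errors).
Outputs are CSV tables and a JSON report carrying seed, a config
fingerprint and the package version; reruns with the same configuration
are metric-identical, which the tests assert. The package's interface is
its functions and these study drivers — the orchestration layer is not
shipped as a shell executable, since its users call it from R.

## Problem sizes

The default test and acceptance workloads were chosen as the smallest
sizes at which each statistical assertion has a comfortable margin: 10⁴
short trajectories for increment-autocovariance checks, 10³ × 2¹⁰ for
exponent recovery, ≥ 10⁵ pooled angles per lag for distribution tests,
512² lattices for near-threshold walks, and a 20 × 20 μm meshwork at
10 nm pixels (2000² image) for the end-to-end morphometry. The whole
suite runs in a few minutes on one CPU.

## Known limitations

* The meshwork generator produces axis-aligned rectangle tilings — the
  right geometry for testing area statistics and segmentation, but not a
  model of filament curvature, branching angles, or meshwork anisotropy;
  its box-count dimension over the accessible decade is not that of real
  cortical actin, which is why known-dimension reference fractals serve
  as the oracles for d_f.
* Localization photophysics is reduced to frame-uniform sampling; drift,
  repeated blinking of one fluorophore, and background localizations are
  not emulated, so passing tests say nothing about drift-induced
  artifacts in real reconstructions.
* The lattice walk models immobile obstacles only; slowly rearranging
  actin is outside scope.
* CTRW-class subdiffusion (power-law waiting times) is intentionally not
  simulated; the discrimination logic covers the anticorrelated classes.
* Angle statistics use overlapping triplets; for strongly correlated
  walks the effective sample size is far below the raw angle count, which
  is why distribution-level tolerances were calibrated by simulation
  rather than by multinomial error bars.
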