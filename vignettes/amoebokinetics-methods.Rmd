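---
title: "Models and methods behind amoebokinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind amoebokinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters, and the numerical
and design choices made where more than one defensible option existed.

# The generalized Langevin model of the centroid walk

Amoeboid centroid motion is modeled as a 2D velocity process with an
exponential memory kernel. Writing the memory as an auxiliary variable
$V$, the model is the linear system

$$ dv = (-\beta v + \alpha V)\,dt + \sigma\,dB, \qquad
   dV = (\alpha v - \gamma V)\,dt. $$

* $\beta$ (1/s) is the bare velocity decay rate, $\alpha$ (1/s) couples
  the velocity to its own exponentially weighted history, $\gamma$ (1/s)
  is the decay rate of that history, and $\sigma$ (μm s$^{-3/2}$) the
  white-noise strength. With $\alpha \to 0$ the model reduces to the
  memory-free Ornstein–Uhlenbeck process (single-exponential VAC).
* Stationarity requires both eigenvalues of the drift matrix
  $C = \begin{pmatrix}\beta & -\alpha\\ -\alpha & \gamma\end{pmatrix}$
  to be positive, i.e. $\beta\gamma > \alpha^2$; `gle_params()` enforces
  this. The eigenvalues
  $\lambda_\pm = \tfrac12\big(\beta + \gamma \pm
  \sqrt{(\beta-\gamma)^2 + 4\alpha^2}\big)$
  are the fast and slow decay rates of the stationary VAC
  $\phi_+ e^{-\lambda_+\Delta t} + \phi_- e^{-\lambda_-\Delta t}$, with
  closed-form weights $\phi_\pm$ computed from the eigenvector components
  (`gle_eigen()`).

## The sampled VAC and its lag-0 branch

Velocities are measured as finite differences of positions sampled every
$\delta t$ (1 s throughout). The autocorrelation of these sampled
velocities is the double integral of the continuous VAC over the two
sampling windows. For integer lags $m \ge 1$ this gives, per mode,
$e^{-(m-1)\lambda\delta t}(1-e^{-\lambda\delta t})^2/(\lambda\delta t)^2$;
at $m = 0$ the two windows coincide and the kink of
$e^{-\lambda|\Delta t|}$ sits inside the integration domain, so the
correct factor is $2(\lambda\delta t - 1 +
e^{-\lambda\delta t})/(\lambda\delta t)^2$. `analytic_vac()` implements
both branches; unit tests verify them against direct 2D quadrature.

Additive positional measurement noise of standard deviation $\sigma_X$
(μm) on each sampled position modifies the sampled VAC only at lags 0 and
1: $+2\sigma_X^2/\delta t^2$ and $-\sigma_X^2/\delta t^2$ respectively.
This is why the noise-free fitting variant uses lags $\tau \ge 2$ s and
the noisy variant includes lags 0 and 1.

## Simulation

`simulate_gle()` integrates the system with Euler–Maruyama at a 2 ms
internal step (configurable; the step enters the error as
$O(\sqrt{dt})$ in the strong sense, but for this linear system the mean
statistics converge as $O(dt)$ and 2 ms makes discretization error
negligible against Monte-Carlo error). The compiled core uses R's RNG, so
`set.seed()` gives bit-identical trajectories. $(v, V)$ start at rest and
a burn-in of $10/\lambda_-$ s is discarded before recording, which brings
the state within $e^{-10}$ of stationarity without needing to sample the
exact stationary law; the position is accumulated as the running integral
of $v$ and positional noise is added after sampling.

## Fitting

`fit_gle_to_vac()` minimizes the mean squared error between
`analytic_vac()` and an empirical curve. The objective is multimodal in
rate space, so the search is structured: for each pair of candidate rates
$(\lambda_+, \lambda_-)$ on a log-spaced grid, the weights
$(\phi_+, \phi_-)$ — and $\sigma_X^2$, when fitted — enter linearly and
are profiled out by nonnegative least squares (`pracma::lsqnonneg`). The
best grid candidates are mapped back to $(\alpha, \beta, \gamma, \sigma)$
through the closed-form inverse of the eigen-decomposition (a quadratic
in the squared eigenvector component) and refined by Nelder–Mead in
log-parameter space. Ties break by lowest MSE, then lowest fast rate.
Degenerate inputs (constant or nonpositive curves) return a flagged
failure object rather than a silent answer.

`fit_exponentials()` uses the same profile strategy over decay-time
grids. Its BIC is the standard Gaussian-error form
$N\ln(\mathrm{RSS}/N) + k\ln N$ with $k = 2 \times$ components. Residual
sums below numerical precision (relative $10^{-8}$) are clamped before
the logarithm so that model orders that all fit a noiseless curve exactly
are ranked by the penalty alone. On Monte-Carlo VACs the residuals are
correlated across lags, which makes 2-vs-3-component selection at small
ensemble size genuinely stochastic; the package's acceptance test
therefore judges the selection across replicate ensembles (one component
must never win; two must win the majority) over the 50-s analysis window.

## Descriptive statistics

MSD, speed histograms (left-closed bins, default width 0.1 μm/s),
speed-conditioned accelerations (unbiased SDs, bins with fewer than two
samples reported as missing), turning cosine, and the
magnitude/orientation split of the velocity autocorrelation follow the
standard estimator definitions; the magnitude autocorrelation is kept as
a raw centered product (not normalized at lag 0) because that is the
conventional form for this analysis, with a normalized variant behind a
flag. The MSD log–log exponent is fitted by OLS over lags 10–100 s — the
crossover-to-persistent regime between the two VAC timescales; the window
is a package default, exposed as an argument. Ensemble exponents are the
mean of per-(sub)trajectory slopes, with non-overlapping sub-windows
available.

# Boundary dynamics

Masks are traced with an in-package Moore-neighbour (8-connected) tracer,
clockwise from the upper-left-most boundary pixel, with cycle detection
on the (pixel, entry-direction) state. The chain is densely resampled,
lightly smoothed (circular Gaussian, σ = 2 final contour points) to
remove pixel staircase jaggedness, and resampled to 500 equal-arc points.
Consecutive frames are linked by the orientation-preserving cyclic shift
minimizing the mean squared inter-point distance, after which index $i$
follows the same material boundary point; the linked frame is re-indexed
so the point matched to the previous frame's index 1 becomes index 1.

**Curvature estimator.** Finite-difference estimates of the tangent angle
over short windows cannot resolve curvature on rasterized boundaries:
digital circles have staircase runs of length $\sim\sqrt{2R}$ px (≈ 9.5
px at R = 45) that alias into large curvature noise at small windows. The
package instead differentiates the contour with derivative-of-Gaussian
filters of scale σ = 16 contour points (≈ 10 px of arc at the default
geometry) and computes $c = (x'y'' - y'x'')/|r'|^3$, with the local arc
element $ds = |r'|$ taken from the same filtered curve so that the
closed-contour total $\oint c\,ds = 2\pi$ holds identically. On
calibration circles (R = 45 px in a 256 px frame) this gives a mean
curvature bias of ~3% and point-wise spread of ~4%, within the 5%
calibration requirement; the filter scale is the single resolution knob
and should be reduced for much finer protrusions, at the cost of noise.
The sign convention is protrusion-positive, and normal velocity is
outward-positive (displacement of same-index points projected on the
outward normal).

**Wave tracking.** The two thresholds of the three-class
(caved/flat/protrusive) split come from an exhaustive two-threshold Otsu
maximization over the whole kymograph — once per movie, not per frame, so
the classes are stable over time. Contiguous protrusive arcs (with
periodic wraparound) are fragments; fragments in consecutive frames are
linked whenever their index supports overlap, so splitting and merging
appear naturally as one-to-many links. Per-link angular velocities use
angle differences wrapped to $(-\pi, \pi]$. The representative
$\omega_c$ is the maximum-likelihood exponential scale of the absolute
angular velocities (their sample mean) — better-posed than a histogram
fit, which remains available behind a flag. The leading edge per frame is
the fragment whose centre normal is circularly closest to the centroid
velocity angle $\psi(t)$; frames with stationary centroid (undefined
$\psi$) or no fragments are excised and lifetimes never bridge those
gaps. Lifetimes are the spacings of consecutive link-break times minus
one frame interval, and $\tau_d$ is their mean (exponential MLE).

**Persistence estimator.** For the centroid angle performing a 1D
persistent random walk, the direction autocorrelation decays with time
constant $T_{est} = 4/(\omega_c^2 \tau_d)$. The closed form corresponds
to an angle-difference distribution with variance
$\omega_c^2\tau_d t/2$; the `make_prw1d()` generator is therefore
calibrated with binary steps of $\omega\tau/\sqrt{2}$ every $\tau$ (a
literal $\pm\omega\tau$ step doubles the angular diffusion and halves the
decay time; it is available via `step_scale = 1`). Monte-Carlo tests
confirm the generator and the closed form agree within a few percent.

**Front/rear fit.** The piecewise joint-cosine profile (amplitude
$A_1 \ge 0$ on a contiguous front arc, $-A_2 \le 0$ on the complementary
rear arc, with periodic midpoint rules for the centres) is fitted by
exhaustive search over the arc ends on a stride-5 grid plus local
refinement; given the arc, the two amplitudes live on disjoint supports
and are independent one-dimensional nonnegative least-squares solutions.

# Fourier morphometry

The elliptic Fourier descriptor samples the traced boundary chain at 160
equal-arc points, rescales by $3000A/(160L)$ ($A$ = mask pixel count,
$L$ = chain length in px), removes the mean (centroid at the origin), and
takes the DFT of $z = x + iy$; the power spectrum $S_k = |\tilde q_k|^2$
is invariant to translation, start-point choice and rotation. Because the
printed rescale grows with cell size (roughly as $R^2$ in the
coordinates), a size-invariant alternative (`rescale = "unit"`, divide by
$L$) is provided and used for shape-class analyses, where size variation
would otherwise dominate the spectrum variance.

Signed modes use $C_n = \tilde q_n$ for $n \ge 1$ and
$C_{-n} = \tilde q_{160-n}$. (An alternative convention shifted by one
index is sometimes seen; it is inconsistent with centering, which forces
$\tilde q_0 \approx 0$, and is not used here.)

Spectrum PCA uses the unbiased covariance and a deterministic
eigenvector sign convention (largest-magnitude loading positive). For
class ordering along "elongation", `elongation_pc()` selects the
component with the largest combined loading on the two fundamental
traversal modes ($S_1$ and $S_{159}$) and orients it positively on the
counter-rotating mode $S_{159}$, whose power grows monotonically with
the contour's aspect ratio — this mirrors the usual reading of the first
component as elongation. Reconstruction from scores rebuilds
$S = \bar S + \sum_m \mathrm{PC}_m e_m$ (negative entries clipped to
zero with a warning) and then a zero-phase contour; the printed
convention uses the spectrum entries directly as real DFT amplitudes,
and `amplitude = "sqrt"` uses $\sqrt{S_k}$, which makes the
reconstructed contour's own power spectrum reproduce $S$.

Mode autocorrelations are normalized complex autocorrelations after mean
removal; decay times are fitted log-linearly on $|AC|$ over the initial
decay (down to 0.1), and a non-decaying rotating phasor
($|AC| \approx 1$) is flagged with an infinite decay time. The
deformation–velocity coupling $C_{nm} = \dot C_{-n}C_m - C_{-n}\dot C_m$
uses forward differences at the frame interval, consistent with the
velocity definition; couplings with negligible magnitude are excluded
from angle statistics, association with the velocity angle is measured
by the Fisher–Lee circular correlation, and the component fits are
no-intercept least squares.

# The synthetic-data generator

The generator provides ground truth for every downstream analysis, at
the reference study conditions: the fitted reference GLE parameters
(α = 0.0741, β = 0.116, γ = 0.0641 s⁻¹, σ = 0.266 μm s^(−3/2),
σ_X = 0 or 0.155 μm), 35 trajectories × 3600 s at 2 ms integration and
1 s sampling, δv = 0.1 μm/s, 500 boundary points, 160 Fourier points.

Mask movies are star-shaped radius profiles — a constant-area polar
ellipse base (aspect 1 except the dumbbell's 2.2) plus radius harmonics
and traveling Gaussian bumps — rasterized at 256×256 px with base radius
45 px (so curvature calibration holds) and pixel-centre-inside tests.
Bumps are applied as radial perturbations at programmed arc angles, so
ground-truth wave positions and angular speeds are exact. The
fan / split / dumbbell / trident presets emulate the recurring
morphologies of crawling amoebae: one broad front; two clearly separated
fingers (±0.95 rad); an elongated bipolar form with two opposing end
bumps; three fingers. `make_shape_family()` jitters shape parameters (not
size) around a preset for population analyses.

What the generator does *not* emulate: segmentation errors and mask
noise, pixel-anisotropic imaging, cell–cell contacts, protrusion-scale
texture beyond smooth bumps, and any chemotactic bias. Passing tests on
synthetic movies therefore validate the estimators' geometry and
tracking logic, not robustness to segmentation artifacts.

# Problem sizes, tolerances and degenerate inputs

* Unit tests run reduced problem sizes (6–12 trajectories of 1200–1800 s,
  movies of up to 60 frames); the acceptance checks run the full
  35 × 3600 s ensemble. Euler–Maruyama steps of 5–10 ms are used where
  only statistical agreement is tested.
* The exponential-fit grids use 12–15 log-spaced nodes per rate; local
  refinement runs Nelder–Mead to `reltol 1e-15`, twice, from the best
  grid candidates.
* Degenerate inputs are first-class: empty or multi-component masks are
  rejected with diagnostics; constant kymographs yield a warned no-waves
  result; all-zero velocity profiles yield a flagged degenerate
  front/rear fit; zero-speed steps are excluded from angle statistics.

# Known limitations

* The boundary tracer assumes a single, simply connected cell per frame;
  holes that touch the traced boundary are not handled.
* Frame linking by cyclic shift assumes modest frame-to-frame
  deformation; very large inter-frame motion can alias the shift.
* The GLE is isotropic and Gaussian; it reproduces two-timescale VACs and
  speed distributions but, by construction, gives the same timescales to
  speed and orientation memory.
* Otsu thresholds are global per movie; movies with drifting curvature
  statistics would need per-window thresholds.
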