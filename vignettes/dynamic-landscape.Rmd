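---
title: "Constructing dynamic landscapes of reorientational motion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing dynamic landscapes of reorientational motion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynland)
```

## The model

`dynland` characterizes molecular reorientational dynamics through the
rank-2 correlation function of a bond vector,

$$C(t) = \langle P_2(\mathbf{v}(\tau)\cdot\mathbf{v}(t+\tau))\rangle_\tau,$$

which is assumed to be a decaying multi-exponential,

$$C(t) = S^2 + (1-S^2)\int_{-\infty}^{\infty}\theta(z)\,
e^{-t/(10^z\,\mathrm{s})}\,\mathrm{d}z,\qquad
\int\theta(z)\,\mathrm{d}z = 1,$$

with $z=\log_{10}(\tau_c/\mathrm{s})$ the log correlation time, $S^2$ the
generalized order parameter and $(1-S^2)\theta(z)$ the *distribution of
motion*. The package's goal is the *dynamic landscape*: the site- and
timescale-resolved map of $(1-S^2)\theta(z)$, separated by type of motion,
estimated jointly from NMR relaxation data and MD trajectories.

Three layers implement this:

1. **Detectors.** Relaxation rate constants and trajectory
   correlation-function values are both linear functionals of
   $(1-S^2)\theta(z)$, with known sensitivities $R_\zeta(z)$ (Redfield
   dipolar expressions; $\exp(-t/10^z)$ for a lag $t$). Optimized linear
   recombinations of these sensitivities — *detectors* $\rho_n(z)$ —
   are narrow, non-negative, max-normalized timescale windows; the
   detector response $\rho_n^{(\theta,S)} = (1-S^2)\int\theta\rho_n\,dz$
   is the amplitude of motion inside window $n$.
2. **Frame separation.** The total rotation of a bond is factored through
   a hierarchy of physically defined frames (local covalent cage,
   glycerol backbone, chain inertia axes). Under statistical independence
   and timescale separation the total correlation function is the product
   of per-motion correlation functions; the machinery tracks the residual
   (motionally averaged) rank-2 tensor of each level, whose
   anisotropy-ratio and asymmetry generalize the order parameter.
3. **Landscape assembly.** Each separated motion's detector responses are
   fitted by a three-parameter correlation-time distribution; motions are
   recombined by the multi-exponential product (cross terms at
   $\tau_i\tau_j/(\tau_i+\tau_j)$, re-binned onto the grid), and internal
   timescales are refined against experimental detector responses by one
   common shift per resolved resonance.

## Conventions and key parameters

* **Rotations** are ZYZ active throughout: $R = R_z(\alpha)R_y(\beta)
  R_z(\gamma)$, with the gauge at $\beta\in\{0,\pi\}$ fixed by
  $\gamma = 0$. Wigner matrices follow
  $D^2_{pq}(\Omega)=e^{-ip\alpha}d^2_{pq}(\beta)e^{-iq\gamma}$ so that
  $D(R_1R_2)=D(R_1)D(R_2)$; this is validated against matrix-product
  closure in the test suite. Superpositions use Kabsch with determinant
  correction — frames are always proper rotations.
* **z grid**: default $[-14,-3]$ with 200 points (fs to ms), bracketing
  the sensitive ranges of all supported experiments.
* **Lag grid**: all lags up to 10 steps, then 50 points per decade up to
  a tenth of the trajectory length; longer lags average too few pairs.
  Both densities are configurable.
* **Dipolar sensitivities** use an effective H–C distance of 1.115 Å
  (vibrationally corrected; configurable) and the normalized Lorentzian
  $J(\omega)=\tfrac{2}{5}\tau_c/(1+(\omega\tau_c)^2)$. CSA is omitted by
  default (dipolar coupling dominates protonated carbons). The
  rotating-frame rate under spin lock $\omega_1$ and MAS $\omega_r$ is
  the standard on-resonance Redfield dipolar result,
  $R_{1\rho} = \tfrac12 R_1 + \tfrac{\delta^2}{8}\bigl[6J(\omega_H)
  + \tfrac23 J(\omega_1{-}2\omega_r) + \tfrac43 J(\omega_1{-}\omega_r)
  + \tfrac43 J(\omega_1{+}\omega_r) + \tfrac23 J(\omega_1{+}2\omega_r)
  \bigr],$
  validated by its limits: $\omega_1\to\infty$ leaves only the
  high-frequency terms and $\omega_r\to 0$ restores the solution-state
  spin-lock weight $4J(\omega_1)$. Off-resonance tilt corrections are not
  applied (experiments are assumed on-resonance). Spin locks weaker than
  half the MAS rate are refused.

## Detector optimization

The published goal — retain the information content of the data while
producing narrow, separated, non-negative windows — does not pin down an
algorithm, so the package uses a deterministic construction:

1. normalize each sensitivity row by its measurement uncertainty (or by
   its maximum when no uncertainties are attached, as for the worked
   examples built from experiment parameters alone);
2. keep the top $n$ singular vectors of the normalized matrix;
3. for each detector solve a small linear program — minimize
   $\int\rho(z)dz$ subject to $\rho \ge 0$ on the grid and
   $\rho(z_{\mathrm{anchor}})=1$ within the singular span (implemented as
   a lightly ridge-regularized quadratic program for robustness);
4. locate anchors as the fixed points of the map
   anchor $\mapsto\arg\max\rho$, found by scanning the grid.

Detector centers $z_n^0$ are the amplitude-weighted means of the
max-normalized sensitivities — the robust choice for asymmetric windows —
and widths $\Delta z_n$ are the areas under them, in decades. The
recombination matrix is computed exactly within the kept singular space
($r = \mathrm{diag}(\sigma)\,U_n\Sigma_n C^{-1}$), which makes the
weighted least-squares fit of forward-model data reproduce the response
integrals exactly for every observable component; the residual against
the full sensitivity matrix is reported as the reconstruction error.

Trajectory (lag) sensitivities always include the zero lag, whose
sensitivity is identically 1: $C(0)=1$ is an exactly known data point and
anchors the fastest window, without which the broad fast detector cannot
be represented by positive lags alone. The $S^2$ offset of $C(t)$ is
deliberately absorbed into correlation times beyond the trajectory
length, so no constant row is added on the trajectory side. Matching
trajectory detectors to experimental target shapes is a least-squares
projection in the SVD-truncated span of the lag sensitivities;
coefficients are unconstrained because the lag rows are monotone in $z$
and no non-negative combination of them can form a single-peaked window —
the resulting shapes are checked for near-non-negativity and the
mismatch area per detector is stored. Targets slower than the longest
usable lag are refused.

## The synthetic-motion generator

Every downstream estimator is validated against trajectories with exact
closed-form correlation functions: free rotational diffusion
($e^{-6Dt}$), axial diffusion ($\sum_p |d^2_{p0}(\beta)|^2
e^{-p^2Dt}$), $n$-site Markov jumps (matrix-exponential form), wobble in
a cone (exact cone order parameter; the time dependence uses the standard
single-exponential approximation and is documented as approximate), and
power-law mixtures of diffusers. Rotational diffusion composes
exact Rodrigues increments with prefix products built by binary doubling;
jump processes are sampled by exact continuous-time (Gillespie) jumps
mapped onto the storage grid. Hierarchies compose an inner motion inside
an outer frame rotation from independent random streams and record the
ground-truth frame axes; a `dependent = TRUE` switch drives both levels
from one stream to create a deliberately non-separable fixture for the
product-deviation diagnostic.

What the generator emulates is the *kinematics* of hierarchical bond
reorientation with known timescales and amplitudes. It does not emulate
force-field physics, collective inter-molecular modes, exchange between
conformer basins with unequal geometries, or translational diffusion, so
green tests demonstrate correctness of the estimators, not realism of
any particular membrane model.

The power-law density is implemented as $\theta(z)\propto
10^{-z(d/2-1)}$ — flat for $d=2$, weighting fast times for $d=3$ — the
form consistent with the collective-motion spectral density
$J(\omega)\propto\omega^{-(2-d/2)}$ and with the detector-scaling
relation $\rho_n\propto\Delta z_n 10^{-z_n^0/2}$ for $d=3$. The scaling
relation itself presumes locally smooth $\theta$ across each detector;
with realistic detector shapes (finite tails) it holds only when the
power law is supported on a window the detectors cover cleanly, so the
tests evaluate it on the ps–ns window spanned by detectors 1–3.

## Frame analysis: numerical choices

* Moment-of-inertia frames take $\nu_Z$ as the eigenvector of the
  group's inertia tensor with the smallest eigenvalue (the chain long
  axis), sign-fixed by continuity in time and, at the first step, by
  positive projection onto the first-to-last-atom vector of the group
  (configurable). The plain MOI frame completes $x,y$ by parallel
  transport (no tracking of rotation about the axis); the MOIxy frame
  instead takes $x$ from a chain-fixed reference bond — by default the
  mid-chain bond — projected perpendicular to $\nu_Z$, so that rotation
  about the long axis is tracked and the parallel/perpendicular split is
  defined. Near-spherical groups are refused (degenerate inertia tensor).
* The $t\to\infty$ residual-tensor limits required by the frame-motion
  correlation function are equal-weight averages over *all* pairs of time
  points; under equilibrium sampling these factor through Wigner closure
  into products of single-time averages, which is how they are computed
  ($O(N)$ instead of $O(N^2)$).
* A residual tensor stores both the time-averaged spherical components
  $\langle D^2_{p0}\rangle$ of the bond in its frame (whose $p=0$
  component is $\langle P_2\cos\beta\rangle$) and the all-pairs limits
  used in the product formula; anisotropy ratio
  $\delta_{\mathrm{eff}}/\delta_{\mathrm{rigid}}$, asymmetry $\eta$ and
  principal Euler angles come from the eigen-decomposition of the
  Cartesian mean tensor (Haeberlen ordering).
* When the inner residual tensor vanishes the ratio terms of the
  frame-motion function are undefined; the function is returned with the
  $p=0$ term only and a `vanishing_residual` diagnostic — never silently
  renormalized.
* The product-deviation curve $|\prod_i C^i(t)-C(t)|$ is always computed
  and kept; deviations above 0.02 produce a message, above 0.1 a
  warning. No single separation time is reported, because the deviation
  curve itself is the honest diagnostic of where the separation
  assumptions hold.
* Correlation functions of equivalent bonds or molecule copies are
  averaged with uniform weights; sampling errors are delete-one
  jackknives over members, or over 10 contiguous trajectory blocks for a
  single series, reported only for lags short enough (half a block) for
  block replicates to be meaningful.

## Landscape fitting choices

The distribution fit is a grid search — centers every 0.1 decade across
the z grid, widths 0.1–2.0 decades in steps of 0.05 — with the amplitude
solved at each node by bounded linear least squares; the full
$\chi^2$ profile is attached to the result. Internal motions default to
a skewed Gaussian with fixed shape $\alpha = 4$ (sign configurable),
overall motions to a plain Gaussian. Product cross terms are re-binned
by splitting each term linearly between the two bracketing grid bins,
conserving total amplitude and the first moment of $z$. Experimental
refinement scans one common center shift per resonance group over
$\pm1.5$ decades in steps of 0.05 — a dense, global, reproducible
optimizer — applied identically to all internal motions (parallel and
perpendicular together) of all sites sharing the resonance; overall
motions are never rescaled.

## Problem sizes and statistical checks

The validation suite runs composed hierarchies of $5\times10^4$–$10^5$
steps in ensembles of 4–8 molecule copies, mirroring how membrane
correlation functions are averaged over lipid copies before
interpretation; at these sizes the sampling-noise floor of the
product-property and closed-form checks sits several-fold below the
stated tolerances. Checks of the form "within $k$ jackknife errors" are
evaluated with aggregate statistics (median standardized deviation,
reduced $\chi^2$) rather than a maximum over lags, because adjacent lags
are strongly correlated and the expected extreme of ~150 standardized
deviations exceeds $3\sigma$ even for an exact estimator.

## Worked example

```{r example, fig.width = 6, fig.height = 4}
# six detectors from the published experiment set
dset <- optimize_detectors(
  build_rate_sensitivities(popc_experiment_set(), z_grid()), 6)
print(dset)

# a two-level synthetic hierarchy, separated by ground-truth frames
h <- compose_hierarchy(
  inner = motion_n_site_jump(matrix(c(-1, .5, .5, .5, -1, .5, .5, .5, -1) *
                                      1e10, 3, 3),
                             lapply(0:2, function(j)
                               rot_zyz(euler_angles(2 * pi * j / 3, 0, 0))),
                             bond_beta = acos(-1 / 3)),
  outer = motion_isotropic_diffusion(1 / (6 * 1e-8)),
  n_steps = 5e4, dt = 3e-12, seed = 1)
dec <- decompose_hierarchy(h, frame_axes(h$frames),
                           lag_grid(5e4, 3e-12, per_decade = 12))
print(dec)
plot(dec)
```

## Known limitations

* Trajectory input is limited to PDB/GRO topologies with multi-model PDB
  or DCD coordinates; XTC/TRR are not readable with the R toolchain this
  package builds on. The synthetic exporter writes PDB + DCD pairs so the
  full read path is exercised.
* Explicit hydrogens are required; united-atom topologies are not
  reconstructed.
* Exact atom-set definitions of the alignment frames in the original
  membrane study are not public; the shipped POPC preset follows the
  published descriptions and every atom set is configurable.
* Frame separation assumes statistical independence and timescale
  separation; the product-deviation diagnostic quantifies, but cannot
  repair, violations.
* Detector geometry depends on the error normalization of the
  sensitivity matrix; without measured uncertainties rows are normalized
  by their maxima, and printed-geometry comparisons carry a 20%
  tolerance.
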