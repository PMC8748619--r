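# dynland

Dynamic landscapes of molecular reorientational motion from NMR
relaxation and MD trajectories.

`dynland` is for spectroscopists and simulators who want a site- and
timescale-resolved map of molecular motion — for example of the lipids in
a membrane — instead of a single order parameter per bond. It combines
three ingredients:

1. **Detector analysis.** Assuming a multi-exponential reorientational
   correlation function
   `C(t) = S² + (1−S²) ∫ θ(z) exp(−t/10^z) dz` with
   `z = log10(τc/s)`, both relaxation rate constants and trajectory
   correlation-function values are linear in the distribution of motion
   `(1−S²)θ(z)`. Optimized linear recombinations of their sensitivities
   — *detectors* `ρₙ(z)`, non-negative, single-peaked, max-normalized —
   turn measured data into timescale-specific amplitudes of motion
   `ρₙ^(θ,S) = (1−S²)∫θ(z)ρₙ(z)dz`, with 68% confidence intervals by
   linear error propagation.
2. **Frame separation.** The rank-2 correlation function of each bond is
   factored through a hierarchy of physical frames (local covalent cage,
   glycerol backbone, chain inertia axes), yielding per-motion
   correlation functions whose product reproduces the total, together
   with the residual dipolar tensor left by each motion (anisotropy
   ratio, asymmetry, orientation). The product deviation is always
   computed and reported.
3. **Landscape assembly.** Per-motion detector responses are fitted by
   three-parameter correlation-time distributions (amplitude `1−S²`,
   center, width), combined across motions by the multi-exponential
   product with re-binning, and refined against experimental detector
   responses by one common timescale shift per resolved resonance.

A kinematic simulator of bond-vector trajectories with exact closed-form
correlation functions (diffusion, jumps, cones, power-law mixtures,
composable hierarchies) ships as a first-class module and backs the
entire validation suite. A CHARMM36 POPC selection preset
(`popc_preset()`) and a command-line pipeline are included.

## Worked example

Six detectors from the published POPC experiment set (¹³C R1 at
100/150/175 MHz, NOE at 150 MHz, R1ρ at 7.0/12.0/22.1 kHz spin lock
under 5 kHz MAS, plus an order-parameter row):

```r
library(dynland)
dset <- optimize_detectors(
  build_rate_sensitivities(popc_experiment_set(), z_grid()), 6)
print(dset)
#> detector set (experimental): 6 detectors
#>  detector center_z center_tau width_decades
#>      rho0    -9.41   3.93e-10          6.90
#>      rho1    -9.93   1.18e-10          1.09
#>      rho2    -9.04   9.15e-10          0.80
#>      rho3    -8.40   3.99e-09          1.05
#>      rho4    -5.20   6.37e-06          1.31
#>      rho5    -4.17   6.78e-05          1.28
#>   sensitivity reconstruction error: 0.0286
```

Detectors 1–5 come out with widths 1.09, 0.80, 1.05, 1.31, 1.28 decades
and centers at ~118 ps, 915 ps, 4.0 ns, 6.4 µs and 68 µs: five windows
from fast picosecond librations to collective microsecond motion (ρ0
collects everything outside the other windows).

Separating a synthetic two-level hierarchy (tetrahedral 3-site jumps at
~0.1 ns inside isotropic tumbling at 10 ns) with its ground-truth frame:

```r
h <- compose_hierarchy(
  inner = motion_n_site_jump(
    matrix(c(-1, .5, .5, .5, -1, .5, .5, .5, -1) * 1e10, 3, 3),
    lapply(0:2, function(j) rot_zyz(euler_angles(2*pi*j/3, 0, 0))),
    bond_beta = acos(-1/3)),
  outer = motion_isotropic_diffusion(1 / (6 * 1e-8)),
  n_steps = 5e4, dt = 3e-12, seed = 1)
dec <- decompose_hierarchy(h, frame_axes(h$frames),
                           lag_grid(5e4, 3e-12, per_decade = 12))
print(dec)
#> frame decomposition: 2 motions, 43 lags
#>   internal       C(0)=1.000  C(t_max)=0.104  <D2_00>=-0.333
#>   overall        C(0)=1.000  C(t_max)=0.207  <D2_00>=-0.333
#>   max |product - total| = 0.0188
```

The internal motion plateaus at its analytic `S² = 1/9` with residual
`⟨D²₀₀⟩ = −1/3 = P₂(cos 109.47°)`, the overall motion follows
`exp(−6Dt)` (0.21 at the 15 ns maximum lag), and their product
reproduces the directly computed `C(t)` to ~0.02 for a single molecule
copy (averaging copies tightens this further).

## Command line

```sh
dynland_script=$(Rscript -e 'cat(system.file("scripts","dynland",package="dynland"))')
Rscript "$dynland_script" pipeline --config config.yaml --seed 1 --out results/
```

Subcommands `simulate`, `correlate`, `frames`, `detectors` and
`landscape` run individual stages; every stage re-reads the previous
stage's serialized outputs, logs the seed and all parameter values, and
is reproducible bit-for-bit under a fixed seed.

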