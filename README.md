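# memthermo

Quantitative analysis of how short cationic–hydrophobic peptides (such as
the arginine-rich R5F2 and lysine-rich K5F2) perturb phosphatidylcholine
bilayers, for experimentalists and simulators working on cell-penetrating
peptides and membrane thermotropics. The package covers the three
measurement channels such studies combine — temperature-dependent UV-Vis
turbidity, differential scanning calorimetry (DSC), and ATR-FTIR — plus the
standard structural observables of membrane MD trajectories, and ships
seeded synthetic-data generators for each channel so every analysis can be
validated by parameter recovery.

## What it computes

**Phase transitions from turbidity spectra.** A temperature-by-wavelength
absorbance matrix *D* is factorized into one bilinear component,

    D = c sᵀ + E,

by alternating least squares under nonnegativity of the concentration
profile *c*(T) and the spectral profile *s*(λ) (scale fixed by
‖s‖∞ = 1). The concentration profile is then fitted with a double-Boltzmann
sigmoid

    c(T) = a₀ + a₁ / (1 + e^{(T_p − T)/w_p}) + a₂ / (1 + e^{(T_m − T)/w_m}),

whose inflection points are exactly the pretransition temperature *T_p*
(gel → ripple) and the main transition *T_m* (ripple → fluid) of the
bilayer.

**DSC.** Reference subtraction, endpoint-anchored linear baseline inside the
30–52 °C window, and transition readout from the curve maxima
(*T*<sub>p,m</sub>, *T*<sub>m,m</sub>) with prominence-based rejection of
noise maxima.

**FTIR band tracking.** Buffer subtraction, region cropping over the six
diagnostic windows (C–H stretches, C=O, CH₂ scissoring/COO⁻, phosphate,
choline), Savitzky–Golay smoothing, two-point baseline, max-normalization,
prominence-based peak picking with parabolic refinement, and gel → fluid
band-shift bookkeeping (Δν > 0 = high-frequency shift).

**Membrane trajectories.** PBC-aware (orthorhombic, minimum-image)
observables: area per lipid *Lx·Ly/N*<sub>leaflet</sub>, bilayer thickness
from the phosphorus density-profile maxima, minimum peptide–P distance
traces and contact-episode detection, geometric hydrogen-bond counting
(donor–acceptor ≤ 0.35 nm, deviation from linearity ≤ 30°, split by
acceptor group), radial distribution functions, acyl-chain order parameters
S<sub>CD</sub> = ⟨3cos²θ − 1⟩/2, and number-density profiles.

## Worked example

```r
library(memthermo)

# synthetic DPPC' (DPPC + 5% DPPG) turbidity series: 30-52 degC, 250-300 nm
params <- thermo_params("dppc")     # T_p = 34.4, T_m = 42.2 degC injected
series <- gen_uvvis(params, seed = 1)
fit <- extract_transitions(series)  # smooth -> rank-1 MCR -> double-Boltzmann
fit
#> <double_boltzmann_fit> T_p = 34.40 +/- 0.02 degC, T_m = 42.20 +/- 0.00 degC, R^2 = 0.99999
glance(fit)$explained_variance      # fraction of ||D||^2 captured by c s'
#> [1] 0.9999896
```

The recovered inflection points sit on the injected transition temperatures
to within a few hundredths of a degree, and the single bilinear component
explains essentially all temperature variation — the regime in which the
turbidity readout of lipid melting is reliable.

```r
# a bound peptide trajectory: K5F2 on a fluid bilayer, desorbing at 113 ns
g <- gen_bilayer_traj(traj_script("dppc-k5f2", 50, seed = 1))
trace <- min_peptide_P_distance(g$trajectory, g$topology)
contact_episodes(trace, cutoff = 0.5)
#> # A tibble: 1 × 3
#>   start   end duration
#>   <dbl> <dbl>    <dbl>
#> 1     0   113      113
```

`autoplot()` methods exist for spectra series, fits, DSC curves and FTIR
spectra; `tidy()`/`glance()` expose fitted objects as tibbles. A thin CLI
(`exec/memthermo`) wraps the same functions for shell use, and
`run_full(run_config())` chains all stages into a consolidated
three-system JSON report.

## Acceptance script

`scripts/acceptance.R` regenerates every synthetic input from scratch with
the package's per-system defaults, runs the matching analysis pipelines
(turbidity ensembles for DPPC' and DPPC'+K5F2, the DSC readout, the
gel-phase FTIR region-(i) maximum, the 113-ns episode trace, and the
area-per-lipid / thickness / H-bond recoveries), and writes the recovered
quantities as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
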