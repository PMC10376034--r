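---
title: "Models and methods behind memthermo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind memthermo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memthermo)
```

memthermo studies the adsorption of short cationic–hydrophobic peptides
(R5F2, K5F2) on DPPC′ bilayers (DPPC with 5% DPPG) through three
measurement channels — temperature-dependent UV-Vis turbidity, DSC, and
ATR-FTIR — plus the structural observables of membrane MD trajectories.
This vignette documents the models, the conventions chosen where a method
is under-specified in practice, what the synthetic generators do and do not
emulate, and the known limitations.

## Turbidity spectra and the bilinear model

Vesicle suspensions scatter light; the apparent absorbance of the
suspension over 250–300 nm changes with the lipid phase state. Over the
30–52 °C window that brackets both DPPC transitions, the whole
temperature-by-wavelength matrix is well described by a single bilinear
component,

$$D = c\,s^\top + E,$$

where $c(T)$ carries all temperature dependence and $s(\lambda)$ is a fixed
spectral shape. `rank1_mcr()` fits this by alternating least squares with
nonnegativity on both profiles. Two conventions resolve ambiguities the
factorization itself leaves open:

* **Scale.** A bilinear product is only defined up to $c \to kc$,
  $s \to s/k$; the spectral profile is max-normalized, $\|s\|_\infty = 1$.
* **No centering.** The data are not mean-centered before factorization
  (a config choice, default off): the generator emits pure rank-1 + noise,
  and centering would break the nonnegativity interpretation.

Convergence is declared when the relative change of $\|E\|_F$ drops below
$10^{-10}$ (at most 500 iterations). On noiseless rank-1 input the result
matches the truncated singular value decomposition to $10^{-10}$, which the
test suite checks against `svd()` as an independent oracle.

## Double-Boltzmann readout of the transitions

The concentration profile of DPPC′ melting has a double-sigmoid shape, and
its inflection points are the two phase-transition temperatures. The fitted
form is

$$c(T) = a_0 + \frac{a_1}{1 + e^{(T_p - T)/w_p}} +
  \frac{a_2}{1 + e^{(T_m - T)/w_m}},$$

whose inflection points are exactly $T_p$ and $T_m$. Fitting is nonlinear
least squares (`nls`, port algorithm, widths bounded below at 0.05 °C).
Initialisation takes the two tallest peaks of the smoothed numerical
derivative $|dc/dT|$, at least 2 °C apart; peaks are selected by *height*
(≥ 10% of the maximum) rather than topographic prominence, because under
heavy noise the weak pretransition shoulder keeps its height while noise
valleys destroy its prominence. A profile whose derivative shows fewer than
two such peaks raises `"transitions not separable"` — by construction a
single-sigmoid input always does.

Standard errors come from the `nls` covariance and $R^2 = 1 -
SS_{res}/SS_{tot}$. One honest caveat: the fit covariance sees only the
scatter of $c$ around the fitted sigmoid. The factorization's spectral
profile is itself estimated from the same data, and its error moves the
whole concentration profile coherently between replicates, so empirical
between-seed dispersion of $T_p$ runs ~10% above the reported standard
error (±2 se coverage ≈ 88% for $T_p$, ≈ 94% for $T_m$; ≈ 91% pooled).
Users needing calibrated intervals should bootstrap over replicate series.

## Synthetic turbidity world

`gen_uvvis()` inverts the analysis model: $D_{ij} = c(T_i)s(\lambda_j) +
\varepsilon_{ij}$ with $s$ a smooth positive monotone decay
($e^{-(\lambda-250)/40}$, turbidity-like) and $c$ the double-Boltzmann of
the system's parameters. Transition temperatures are the UV-Vis replicate
means per system (DPPC′ 34.4/42.2 °C, +R5F2 33.6/42.0 °C, +K5F2
36.1/44.2 °C). Amplitudes, widths and noise are conventions of the stated
world, chosen once:

* $a_0 = 1.0$, $a_1 = -0.12$, $a_2 = -0.45$ — turbidity *decreases* through
  both transitions, the pretransition step being the smaller; the profile
  stays positive as the nonnegative factorization assumes.
* $w_p = 1.2$ °C, $w_m = 0.5$ °C — the pretransition is broader and weaker
  than the main transition, as in DPPC calorimetry.
* noise sd = 0.5% of the $c$-range, which makes the $R^2 \ge 0.998$ fit
  quality attainable, as observed on the real instrument data.
* grids: 30–52 °C in 0.5 °C steps, 250–300 nm in 1 nm steps.

What a green recovery test establishes: the pipeline is unbiased and
precise *under the bilinear + iid-noise model*. It does not establish
robustness to wavelength-dependent baseline drift, bubble artifacts, or a
genuine second component (though a planted 5% second component is verified
to surface in the residuals).

## DSC

The synthetic curve is two Gaussian peaks on a linear baseline plus noise
(20–60 °C, 0.1 °C steps); only the maxima positions are consumed
downstream, so the peak shape is immaterial. The main peak is 10× the
pretransition height. Analysis conventions:

* **Baseline**: the straight line through the mean signal of the first and
  last 1 °C of the 30–52 °C window — the simplest method consistent with
  "baseline corrected"; maxima positions are insensitive to gentle
  baseline choices (verified by a paired ramp/no-ramp test).
* **Transition readout**: $T_{m,m}$ is the global maximum; $T_{p,m}$ the
  most prominent local maximum ≥ 2 °C below it with prominence ≥ 5% of the
  global maximum (DPPC pre/main transitions are ≥ 7 °C apart). A curve
  whose maximum does not clear five robust standard deviations of the
  signal is reported as `"no transition detected"` — peptides in buffer
  show no thermotropic event, and the detector must say so rather than
  return a noise maximum.

## FTIR

Six diagnostic regions are analysed: (i) 3000–2820 cm⁻¹, (ii) 1780–1695,
(iii) 1515–1360, (iv) 1275–1190, (v) 1130–1020, (vi) 990–940.
Preprocessing is crop → Savitzky–Golay smooth (cubic, 21-point window;
region (i) is left unsmoothed) → subtract the straight line through the two
region endpoint samples ("two-point baseline") → divide by the region
maximum. "Normalized" is read as max-normalization; the two endpoint
samples are the only two canonical points of a cropped region. Peak
positions are parabolically refined and reported to 1 cm⁻¹, matching the
2 cm⁻¹ nominal instrument resolution.

The generators use pseudo-Voigt bands at the reported per-system,
per-temperature maxima. Band heights and widths are conventions; regions
(iii) and (vi) use narrow near-Gaussian bands (fwhm 5–7 cm⁻¹) because the
21-point smoothing otherwise merges the 11–13 cm⁻¹ K5F2 doublets that the
real spectra resolve. Region (iv) has no published positions and carries a
single synthetic stand-in band at 1230 cm⁻¹. Known limitation: at 50 °C
the K5F2 1456 cm⁻¹ shoulder (11 cm⁻¹ from the scissoring band) still
merges after smoothing; the gel-phase quadruplet 1468/1455/1417/1379
resolves and is what the recovery tests check. Atmospheric-line handling
and Amide-I deconvolution are out of scope.

## Trajectories

The generator builds the smallest geometry supporting every observable:
192 pseudo-lipids of 8 atoms (P, choline N, two carbonyl O, two chain C
each with one H) on leaflet lattices in an orthorhombic box (normal = z,
units nm/ns), and one peptide with 24 donor–H pairs, 4 acceptors and 6
other atoms. Per frame the lateral box is drawn so that
$L_xL_y/N_\text{leaflet} \sim \mathcal N(\text{APL}, \sigma)$; P atoms get
Gaussian z-jitter (0.05 nm); C–H vectors sit at the fixed polar angle that
makes $S_{CD}$ equal its target exactly (azimuth random); the peptide's
minimum distance to any P atom is < 0.5 nm exactly during scripted episodes
and ≥ 1 nm otherwise. During bound frames a Poisson number of
donor–H···acceptor triplets is planted at 0.285–0.315 nm and < 15°
deviation — safely inside the 0.35 nm / 30° detection criterion, so the
round-trip test cannot flake at the cutoff edge. Scenario defaults: APL and
leaflet separation per system/temperature from the simulated structural
parameters (e.g. fluid peptide-free APL 0.615 nm², gel R5F2 separation
5.150 nm); episodes R5F2-30 °C [33, 200] ns, R5F2-50 °C [0, 200] ns,
K5F2-50 °C [0, 113] ns, K5F2-30 °C three sub-2-ns contacts; planted H-bond
means 8/11 (R5F2 at 30/50 °C) and 5 (K5F2 at 50 °C), three quarters to the
phosphate group. Poisson draws truncate at the 24 donors (bias < 0.01 at
mean 11). In the pseudo-lipid the P atom stands in for the phosphate group
as H-bond acceptor and the carbonyl O atoms for C=O.

Analysis conventions: minimum-image wrapping into $[-L/2, L/2)$ per
component (orthorhombic boxes only; triclinic inputs are rejected);
adsorption cutoff 0.5 nm on the minimum peptide–P distance (just above
H-bonding range; configurable); H-bond criterion 0.35 nm / 30° (the
de-facto default of the major MD packages; configurable); thickness from a
0.02 nm phosphorus histogram with 3-point parabolic refinement (needed to
report thickness at 0.001 nm precision); H-bond averages over bound frames
only; equilibration handled by a `t_equil` argument on the aggregating
observables. Reported spreads are frame-wise standard deviations, not
block averages.

What the generator does not emulate: force-field energetics, thermostats
or barostats, water, realistic lipid chemistry, undulations, curved
membranes, or multiple peptides. A green round-trip establishes that the
observables are implemented correctly (they also match all-pairs brute
force oracles on small frames), not that any force field is right.

## Numerical choices

* Savitzky–Golay: least-squares convolution weights; "through 10/20
  points" is read as the closest valid odd window (11/21). Edges use
  symmetrically shrinking windows (down to identity at the outermost
  sample) — full-window polynomial extrapolation was tried first and
  produces spurious swing near region edges. Polynomials up to the fit
  degree pass through unchanged everywhere.
* Peak prominence: height above the higher of the two minima separating
  the peak from higher terrain.
* Parabolic refinement clamps the sub-grid offset to ±half a bin.
* All generators draw from a single seeded stream with a documented draw
  order, so identical seeds give bit-identical output across platforms.
* `rank1_mcr` errors on all-zero input ("degenerate input");
  `membrane_thickness` errors when the P profile is not bimodal ("leaflets
  not resolved"); `preprocess_region` errors on flat regions ("no signal
  in region").

## Open choices made

* Whether the original turbidity analysis centered or constrained the
  factorization is not knowable; nonnegativity + max-normalized $s$,
  centering off, is recorded as the package convention.
* The "adsorbed" state has no published numeric definition; 0.5 nm on the
  minimum peptide–P distance reproduces the reported onset/desorption
  times in the synthetic world and is configurable.
* Stock-concentration bookkeeping of the peptide solutions is internally
  inconsistent in the source material and is excluded; concentrations are
  metadata only.
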