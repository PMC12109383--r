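---
title: "Models and methods in quenchlab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in quenchlab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quenchlab)
```

quenchlab implements the standard spectroscopic analysis chain for
non-covalent protein–ligand binding. This vignette documents the models,
the tunable parameters and their defaults, the synthetic-data generators,
the numerical choices, and the limitations — the things a maintainer or a
careful user needs that the function reference does not say in one place.

## Fluorescence quenching model

A quencher Q added to a fluorescent protein reduces the emission intensity
F from its unquenched value F₀ according to the Stern–Volmer relation

$$F_0 / F = 1 + K_q \tau_0 [Q] = 1 + K_{sv} [Q],$$

where $K_{sv}$ (L/mol) is the quenching constant, $\tau_0$ the unquenched
fluorophore lifetime and $K_q = K_{sv}/\tau_0$ the bimolecular quenching
rate constant. `stern_volmer_fit()` estimates $K_{sv}$ by ordinary least
squares of $F_0/F$ on $[Q]$.

**Intercept handling.** The model pins the intercept at 1, but real
baselines drift; the default fit leaves the intercept free and flags it
when it strays more than 0.05 from 1. `fix_intercept = TRUE` gives the
textbook one-parameter fit. Free-intercept is the default because it is
robust to baseline error and its slope is an unbiased $K_{sv}$ estimate
under the model either way.

**Response definition.** Published quenching analyses rarely state whether
F is the per-spectrum maximum or the intensity at a fixed wavelength.
`build_quench_table()` defaults to the per-spectrum maximum
(`response_mode = "peak"`, the common literature practice) and offers
`"fixed_wavelength"` — intensity interpolated at the zero-ligand peak
position — as a sensitivity analysis. With no band shift the two are
identical; with a shifted band both still recover $K_{sv}$ within a couple
of percent under realistic noise.

**Mechanism classification.** Static quenching (ground-state complex
formation) and dynamic quenching (excited-state collisions) both produce
linear Stern–Volmer plots. The discriminating observation is the rate: a
collisional process cannot exceed the diffusion-controlled limit of about
$2.0 \times 10^{10}$ L·mol⁻¹·s⁻¹, so an apparent $K_q$ above that limit
implies a static mechanism. `classify_mechanism()` applies this as the
primary rule, with the temperature trend of $K_{sv}$ (decreasing → static,
increasing → dynamic) as corroborating evidence only: when trend and rate
disagree, the rate rule stands and a discordance note is recorded. A
minimum $K_q$ within ±5% of the threshold is reported as `"ambiguous"`;
the band is this package's convention, since no tie rule exists in the
literature the threshold comes from.

**Binding constant and stoichiometry.** For static quenching the
double-logarithmic plot

$$\lg[(F_0 - F)/F] = \lg K_a + n \lg [Q]$$

gives the apparent binding constant $K_a$ and binding-site number $n$.
Logarithms are decadic throughout ($n$ is base-invariant, the intercept is
not). Points with $[Q] = 0$ or $F \ge F_0$ carry no binding signal and are
dropped with a warning rather than an error, because isolated baseline
excursions are common in real titrations; fewer than three surviving
points is an error.

## Thermodynamics

`vant_hoff()` regresses $\ln K_a$ on $1/T$:
$\ln K_a = -\Delta H / (RT) + \Delta S / R$ with
$R = 8.314$ J·mol⁻¹·K⁻¹, so $\Delta H = -R \cdot \text{slope}$ and
$\Delta S = R \cdot \text{intercept}$. Internal units are J/mol and
J/(mol·K) everywhere; printing converts to kJ/mol. The fit never reorders
or re-weights points; with exactly two temperatures the line is determined
and standard errors are undefined (`NA`).

$\Delta G = \Delta H - T\Delta S$ (`gibbs()`) flags spontaneity, and
`classify_forces()` applies the classic sign-quadrant reading of
$(\Delta H, \Delta S)$: (+,+) hydrophobic, (−,+) electrostatic, (+,−)
electrostatic plus hydrophobic, (−,−) van der Waals and hydrogen bonding.
Zero bands (`epsilon_dh` = 100 J/mol, `epsilon_ds` = 1 J/(mol·K), both
package conventions) map near-zero values to `"indeterminate"` rather than
forcing a quadrant from noise.

Note an internal consistency check this design enables: binding constants
that *decrease* with temperature force a negative fitted $\Delta H$ under
the Van't Hoff relation. Published tables sometimes pair a decreasing
$K_a$ column with a positive printed $\Delta H$; `run_study()` accepts
externally reported values via `reference_thermo` and emits a machine-
readable discrepancy note when the fitted and reported signs disagree,
rather than guessing which number is right.

## Synchronous fluorescence

Series recorded at a fixed excitation–emission offset Δλ report residue-
class microenvironments: Δλ = 15 nm tyrosine, Δλ = 60 nm tryptophan (other
offsets are accepted and labelled `"custom"`). `analyze_sync()` reports
per-concentration peak positions and percent declines against the
zero-ligand spectrum, and the total band shift between the zero and top
concentrations. Peak calls use integer-grid argmax by default, matching
whole-nm instrument reporting; parabolic refinement is available. A blue
shift is read as increased hydrophobicity around the residue class, a red
shift as increased polarity. `compare_contributions()` reports which
residue class dominates the intrinsic fluorescence (larger zero-ligand
intensity) and which sits closer to the binding site (larger maximal
decline).

## CD secondary structure

`deconvolve_cd()` models a far-UV CD spectrum as a nonnegative linear
combination of four reference component spectra (α-helix, β-sheet, β-turn,
random coil), solved by non-negative least squares and renormalised to sum
to 1. Design choices:

- The basis is interpolated onto the *sample* grid, so the reported
  residual norm lives in measurement space.
- Sum-to-one is enforced by post-normalisation rather than a constrained
  solve; the residual is reported pre-normalisation, so any scale mismatch
  between sample and basis is visible rather than absorbed.
- Fractions are invariant to positive rescaling of the input signal (NNLS
  coefficients scale linearly and normalisation divides the scale out), so
  the estimator works identically on millidegrees and mean residue
  ellipticity up to the residual norm.

The shipped `default_cd_basis()` is **synthetic**: parametric Gaussian-band
curves with the canonical far-UV features (helix: positive band near
192 nm, double minima near 208/222 nm; sheet: positive near 196 nm, single
minimum near 218 nm; turn: weak positive near 202 nm; coil: strong
negative near 198 nm). It exists so that recovery of known mixtures is
exactly testable; it is *not* a measured reference set, and absolute
fractions from real spectra should be interpreted qualitatively unless a
measured basis is supplied (`read_basis_csv()`). Proprietary neural-network
deconvolution packages used in instrument software are intentionally not
reimplemented; NNLS against an explicit basis is transparent and testable.

`composition_delta()` accepts either fraction objects or bare percent
vectors, because published composition tables often carry rows that do not
sum exactly to 100 and should be comparable as printed.

## Antioxidant assays

The three assay formulas are implemented exactly as defined:
ABTS rate = (A₀ − A₁)/A₀ × 100; DPPH rate = (A_b − A_t − A_c)/A_b × 100;
FRAP power = A_t − A₁ − A₀. Rates outside [0, 100]% are reported with
warnings, never clipped — truncation would silently hide assay failure.
`calibrate_trolox()` fits a free-intercept standard curve (response vs
mg/L Trolox) and `to_teac()` inverts it; whether a zero or free intercept
was used in any given published TEAC is usually unstated, and a free
intercept subsumes both. A curve with r² < 0.99 is flagged.

## Synthetic-data generators

Every generator is a pure function of (parameters, seed): the caller's RNG
state is saved and restored, and repeated calls are bitwise identical.

What the generators emulate, and the defaults chosen once for the study
conditions:

- `simulate_titration()`: a single Gaussian emission band (center 345 nm,
  sd 25 nm — a typical tryptophan band width; zero-quencher amplitude
  3300 a.u.) quenched statically, with a saturating red shift of at most
  +2 nm and multiplicative Gaussian noise. Quenching acts on amplitude
  only; the band width is constant, reflecting that complex formation
  removes fluorophores rather than reshaping the emission of those
  remaining.
- `mechanism_scenario()`: static — quenching constants
  {5.0, 4.9, 4.0} × 10⁴ L/mol at 298/304/310 K over a 0–26.7 µM ladder;
  dynamic — {100, 120, 140} L/mol over a 0–13.3 mM ladder. The dynamic
  ladder is a factor 500 more concentrated because a collisional quencher
  with $K_{sv}$ of order 10² L/mol needs millimolar concentrations to
  produce comparable fractional quenching; this keeps the two scenarios at
  matched signal-to-noise rather than making the dynamic case
  unrecoverable by construction.
- `simulate_sync_pair()`: Gaussian bands (sd 12 nm) whose centers and
  amplitudes interpolate linearly in concentration between zero and top
  targets. Defaults: Trp 274 → 270 nm, 3311 → 1592 a.u.; Tyr fixed at
  303 nm, 746 → 400 a.u. The Tyr band position is an assumption (tyrosine
  emits near 303 nm), not a measured value.
- `simulate_cd()`: linear basis mixture plus additive noise scaled to the
  peak amplitude (CD noise is approximately signal-independent, unlike
  fluorescence shot noise, hence additive here and multiplicative there).
- `simulate_assay()`: true TEAC values mapped through a nominal standard
  curve (percent-rate curves: slope 2%/(mg/L), intercept 5%, keeping
  0–45 mg/L inside the usable assay window) and inverted into absorbance
  roles with fixed control absorbances (ABTS A₀ = 0.80; DPPH A_b = 0.90,
  A_c = 0.02; FRAP A₁ = 0.05, A₀ = 0.10).
- `simulate_study()`: one seeded call producing all of the above, with the
  static scenario, plus a five-step helix-to-sheet CD composition
  trajectory and per-assay TEAC triples.

What the generators do **not** emulate: inner-filter effects, photo-
bleaching, lifetimes/FRET, instrument response convolution, asymmetric
band shapes, pipetting error. Passing recovery tests therefore
demonstrates the estimators are correct under the stated forward models,
not that any particular real dataset satisfies those models.

## Numerical choices and degenerate inputs

- All linear fits go through ordinary least squares (`stats::lm`); NNLS
  uses the Lawson–Hanson solver (`pracma::lsqnonneg`). Test suites verify
  both against independent oracles (closed-form slope; exhaustive
  grid searches over the double-log parameters and the composition
  simplex).
- Peak ties are broken toward the smaller wavelength for determinism.
  Non-adjacent tied maxima — genuinely ambiguous band candidates — raise a
  warning; adjacent equal samples (a band peaking between grid points) do
  not. A flat spectrum is a degenerate peak: warned, smallest wavelength
  returned.
- Parabolic peak refinement is off by default so whole-nm grids report
  whole-nm maxima; when on, the vertex is clamped to the bracketing
  samples.
- Mixed wavelength grids are linearly interpolated onto the reference
  (zero-ligand) grid before comparison; extrapolation is an error.
- Dilution arithmetic defaults to the `"nominal"` volume convention
  (divide by the base volume only), which is how 80 µL of 10⁻³ M stock
  into 3.0 mL reads 26.7 µM; the `"additive"` convention is available, and
  the two converge as the added volume vanishes.
- Spectrum CSVs are written with 17 significant digits so read/write
  round-trips are bit-identical.

## Problem sizes used in the test suite

Property and recovery tests run at the study's native sizes: 8-point
titration ladders at 3 temperatures, 201-point emission grids, 151-point
synchronous grids, 71-point CD grids; 50–100 seeds for recovery medians,
500 random tables for the OLS oracle, and a two-stage exhaustive simplex
search (0.01 coarse, 0.0005 refined) for the NNLS oracle. The full suite
completes in under a minute on one CPU.

## Known limitations

- No inner-filter correction, modified (Lehrer) Stern–Volmer,
  sphere-of-action model, or lifetime analysis.
- No temperature-dependent ΔH (nonlinear Van't Hoff) or heat-capacity
  terms; error propagation is limited to OLS standard errors.
- CD fractions from the synthetic basis are for recovery testing and
  qualitative comparison; no path-length/concentration conversion to mean
  residue ellipticity is validated.
- Protein concentration is carried as metadata only; no molar protein
  concentration is computed.
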