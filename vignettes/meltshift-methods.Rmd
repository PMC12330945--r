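---
title: "Melting-curve models and shift statistics in meltshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Melting-curve models and shift statistics in meltshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meltshift)
```

## The unfolding model

Thermal profiling rests on a simple observation: heating denatures
proteins, denatured proteins aggregate and are removed by centrifugation,
and the soluble remainder can be quantified. Plotting soluble abundance
against temperature gives a melting curve, and ligand binding typically
shifts that curve to higher temperatures.

`meltshift` models the fraction folded at temperature $T$ as a logistic
with a lower plateau,

$$f(T) = \frac{1 - p}{1 + e^{-a (T - b)}} + p,$$

with three constants estimated by regression: the slope $a$ (°C$^{-1}$,
constrained negative so that the curve *decreases* with temperature — the
symmetric positive-$a$ parameterization describes the same family with the
roles of the asymptotes exchanged), the inflection temperature $b$ (°C),
and the plateau $p$, a heat-resistant residual fraction commonly seen in
immunoblot and MS quantification. The upper asymptote is fixed at 1 by
normalization; the model deliberately has exactly three free constants.

The melting point is defined as the absolute 50%-denaturation temperature,
the root of $f(T) = 1/2$:

$$T_m = b - \ln\!\left(\frac{0.5}{0.5 - p}\right)\big/\,a,$$

which exists only for $p < 0.5$; a curve whose plateau sits at or above
one-half never loses half its signal and has no melting point. Note $T_m
\ne b$ whenever $p > 0$: the plateau drags the 50% crossing above the
inflection. We use the absolute crossing rather than the plateau midpoint
because the Tm50 readout of densitometry experiments ("temperature at
which half the protein is denatured") refers to the normalized signal
itself, not to the transition's midpoint.

## Normalization and the shape of the fitted curve

Raw intensities are converted to relative abundances by dividing each
replicate series by its intensity at the lowest available temperature, so
the reference point is exactly 1. This has a consequence that is easy to
miss: the observable is not $f(T)$ but

$$r(T) = f(T) / f(T_{\mathrm{ref}}),$$

because the reference measurement itself sits slightly below the upper
asymptote ($f(T_{\mathrm{ref}}) < 1$ for any finite slope).
`fit_unfolding()` therefore fits $r(T)$ — the model family that actually
passes through the constrained reference point — and reads $T_m$ off the
absolute curve afterwards. Fitting $f$ directly to reference-normalized
data leaves a systematic residual of order $1 - f(T_{\mathrm{ref}})$
(typically $10^{-3}$) that biases all three parameters; with the $r(T)$
parameterization, noise-free data are recovered to machine precision,
which the test suite asserts on the six-point gradient.

Missing observations are dropped pointwise; a protein/condition needs at
least `min_points` (default 5) distinct temperatures after dropping. A
replicate whose reference intensity is zero or absent cannot be normalized
and is excluded with reason `no_reference`; if the lowest temperature is
missing but later ones are present, the lowest *available* temperature
serves as that replicate's reference.

## Fitting: bounds, starts, and failure handling

Estimation is bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) with an
analytic Jacobian, pooling all replicate points of one protein/condition
into a single fit (replicate-wise fits are used only for the optional
replicate-based significance mode). Box constraints are
$a \in [-10, -10^{-3}]$ °C$^{-1}$, $b \in [T_{\min} - 10, T_{\max} + 10]$
°C, $p \in [0, 1)$.

Starting values come from the data: $p_0$ is the smallest observed
relative abundance clipped to $[0, 0.3]$; $b_0$ is the temperature whose
mean abundance is closest to $(1 + p_0)/2$; and $a_0$ follows from the
finite-difference slope of the mean curve around $b_0$, using the fact
that a logistic has derivative $a(1-p)/4$ at its midpoint. If the first
run fails, a $3 \times 3$ grid of perturbed starts
($a_0 \times \{0.5, 1, 2\}$, $b_0 + \{-3, 0, 3\}$ °C) is tried and the
best successful refit kept; only if all fail is the protein reported
`converged = FALSE`. Convergence tolerances are `ftol = ptol = 1e-10`
with up to 500 iterations — tight enough that noise-free identifiability
holds far below the $10^{-6}$ level, loose enough that noisy curves
terminate reliably. A perfectly flat curve has zero abundance variance,
so its $r^2$ is undefined (`NA`) and it fails QC; this is the correct
outcome for a protein with no melting signal in the window.

## Quality control

A protein enters the shift analysis only if both condition fits pass:
converged, $r^2 \ge$ `r2_min` (default 0.8), plateau below `plateau_max`
(default 0.4 — above this the 50% crossing becomes poorly determined),
and a defined $T_m$ inside the measured window extended by
`tm_window_margin` (default 5 °C). Every violation contributes a named
reason code (`low_r2_treated`, `no_tm_control`, ...) accumulated into the
output's `qc_flags`. The thresholds follow common thermal-profiling
practice and are all exposed in `fit_settings()` and the run
configuration; none is applied silently.

## Shift significance and classification

$\Delta T_m = T_m^{\mathrm{treated}} - T_m^{\mathrm{vehicle}}$, positive
for stabilization. Two significance modes:

* **proteome_null** (default): the vast majority of the proteome does not
  bind the ligand, so the proteome itself estimates the null. Each shift
  is standardized as $z = (\Delta T_m - \mathrm{median}) / (1.4826 \cdot
  \mathrm{MAD})$ over QC-passing proteins, with a two-sided normal
  p-value. The robust location and scale tolerate a minority of true
  binders in either tail. A floor of $10^{-6}$ °C on the scale guards the
  degenerate all-identical case, where every $z$ is 0. This mode needs at
  least 3 QC-passing proteins and no replicate structure.
* **replicate**: each replicate pair (control vs treated, matched by
  replicate index) is fit separately, and per-protein replicate-wise
  shifts are tested against zero with a one-sample two-sided t-test
  (at least 2 values required).

Both modes are followed by Benjamini–Hochberg adjustment across proteins
(FDR was also the error-rate currency of the comparative-proteomics layer
this mirrors). Classification calls a protein stabilized when
$\Delta T_m \ge +2$ °C with $q \le 0.05$, destabilized at the mirrored
threshold, otherwise unchanged; both knobs are configuration-exposed and
echoed in output metadata, since published analyses rarely state the
calling rule explicitly. Ranking is by descending $|\Delta T_m|$ over
QC-passing proteins, with ties broken by ascending q-value and then
lexicographic protein id, making ranks fully deterministic. (Magnitude
rather than significance is the primary key because downstream validation
effort is usually allocated by effect size; the tie-break chain makes the
choice reproducible either way.)

Two documented conventions: stabilization is *positive* $\Delta T_m$
throughout (source reports occasionally flip signs between text and
figures), and the analysis fits *per-condition* curves rather than
treated/control ratio curves — ratio curves confound the two conditions'
plateaus and cannot yield per-condition melting points.

## Differential expression

The two-fold rule operates on the lowest-temperature (non-denaturing)
abundances, the closest available stand-in for an unheated comparative
proteomics experiment: per protein, the fold change of replicate means, a
Welch t-test on log intensities, BH adjustment, and the inclusive calls
fold change $\ge 2$ ("twice or more") with $q \le$ cutoff for `up`,
$\le 0.5$ for `down`. Zero control means leave the fold change undefined
and flag the protein.

## CETSA densitometry

Band-intensity series are normalized like abundance curves. The apparent
Tm50 comes either from the same unfolding fit (`method = "fit"`, the
default for grids of 5+ points) or from linear interpolation between the
first adjacent temperature pair bracketing 0.5 (`"interpolate"` — the
first-bracket rule is a deterministic tie-break for noisy series with
multiple crossings; coarse blot grids rarely support a stable nonlinear
fit). On dense noise-free sigmoid data the two methods agree within 1 °C,
asserted in the tests. The condition-level Tm50 pools replicate points;
with at least three replicate pairs a paired two-sided Student's t-test on
replicate-wise Tm50 differences is reported, matching the convention of
blot-based thermal shift figures.

## The synthetic thermal proteome

The simulator exists so that every downstream stage can be validated
against known truth without the original mass-spectrometry deposit. Its
defaults emulate the structure of a proteome-scale TPP experiment on a
drug-treated cell line:

| parameter | default | rationale |
|---|---|---|
| `n_proteins` | 3000 | proteome-scale run (~3000 proteins quantified) |
| `temperatures` | 43.0, 46.4, 49.8, 53.2, 56.6, 60.0 °C | six points evenly spaced over 43–60 °C: step (60 − 43)/5 = 3.4 |
| `n_replicates` | 3 | replicate count unreported upstream; 3 is the field's norm |
| `fraction_stabilized` / `fraction_destabilized` | 81/3000, 89/3000 | headline hit fractions of the motivating experiment |
| `slope_range` | [−1.5, −0.3] °C⁻¹ | 10–90% transition widths of ≈3–15 °C |
| `tm_range` | [46, 52] °C | a gradient is designed to bracket the proteome's melting points (median human Tm ≈ 49–50 °C) *including* ligand-shifted transitions of stabilized targets; inflections near the top of the window would place shifted curves outside the measured range, an undefined experiment rather than a hard one |
| `plateau_range` | [0, 0.2] | keeps the 50% crossing well-defined and realistic |
| `effect_distribution` | uniform 2–8 °C | spans the magnitude range of reported target shifts (≈1.3–8 °C) |
| `noise_cv` | 0.1 | typical label-free quantification precision |
| `missing_rate` | 0.05 | missing-completely-at-random dropout |
| `base_intensity_range` | 10⁶–10⁹ (log-uniform) | MS1 peak-volume dynamic range |

Treated and control curves share $(a, p)$; only the inflection moves by
the true $\Delta T_m$, isolating the melting-point shift as the single
causal difference — exactly the quantity the analysis claims to estimate.
Noise is multiplicative log-normal with $\sigma = \sqrt{\ln(1 + CV^2)}$ so
the linear-scale coefficient of variation equals `noise_cv`, the standard
error structure for label-free quantification; the log-noise is centered
at zero. Identical configurations (including seed) give bit-identical
output.

What the simulator does *not* emulate: peptide-level aggregation,
intensity-dependent noise and missingness (missingness here is MCAR,
whereas real MS dropout is abundance-dependent), co-melting complexes,
condition-dependent plateaus, and batch structure. Passing recovery tests
on this generator therefore demonstrates that the estimator chain is
correct and well-calibrated under its own assumptions, not that real data
meet those assumptions.

## Problem sizes and empirical checks

The test suite and acceptance script compute, at these sizes chosen to
keep a full run in the minutes range on one core:

* closed-form $T_m$ vs bisection root-finding of $f = 1/2$: 1000 random
  parameter sets, agreement to $10^{-9}$ °C;
* noise-free identifiability: 40 proteins × 2 conditions on the 6-point
  grid, parameters recovered to $10^{-6}$ and $T_m$ to $10^{-4}$ °C
  (observed: machine precision);
* recovery: 1000 proteins, 50 spiked at +6.4 °C, 3 replicates, 10% CV —
  ≥95% of spikes called stabilized, median $|\Delta T_m|$ error < 1 °C,
  ranking dominated by spike-ins;
* null calibration: ten zero-effect 1000-protein proteomes — fraction
  flagged at $q \le 0.05$ and $|\Delta T_m| \ge 2$ °C stays below 7.5%
  (observed ≈3%);
* CETSA worked examples: noise-free densitometry pairs with Tm50 50 → 55
  °C and 56 → 64 °C reproduce shifts of +5 and +8 °C exactly.

## Limitations

The model is a phenomenological two-state unfolding description; proteins
with multi-domain melting, ligand-dependent plateaus, or transitions
outside the measured gradient violate it and are meant to be caught by QC
rather than fit. The proteome-null significance mode assumes the null
majority; a ligand perturbing a large fraction of the proteome would
inflate the MAD and cost power. $\Delta T_m$ from 6-point curves carries
an irreducible uncertainty of a few tenths of a degree at 10% noise;
shifts near the 2 °C threshold should be treated as screening hits, not
conclusions. Isothermal dose-response profiling, Kelvin-scale
thermodynamic modeling ($\Delta G$ of unfolding) and pathway-level
interpretation are out of scope.
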