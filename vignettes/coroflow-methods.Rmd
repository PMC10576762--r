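---
title: "Methods: the coronary lumped-parameter model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the coronary lumped-parameter model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coroflow)
```

## The model and its assumptions

`coroflow` estimates absolute coronary blood flow (CBF) in patients with
an anomalous aortic origin of a coronary artery (AAOCA) by solving a
zero-dimensional electrical analog of the aortic root and the two
coronaries. The core physical assumptions are:

* **Newtonian blood**, density 1.06 g/cm³, dynamic viscosity 0.04 P.
* **Linear elastic walls**, Young's modulus 1.5 MPa, so each vessel
  tract reduces to one linear RLC compartment (a single-segment
  reduction of the transmission line): series resistance and inertance
  along the axis, shunt compliance to ground at the distal node (an
  inverted-L layout; a Pi or T layout would change results only at the
  compartment-count level, and the chain is short).
* **Fully developed laminar flow** in every tract: Poiseuille
  resistance `8μl/(πr⁴)` for circular tracts and the exact elliptical
  duct solution `4μl(a²+b²)/(πa³b³)` for coronary tracts, whose lumina
  are measured as ellipses on intravascular ultrasound. Inertance is
  `ρl/A`. Compliance uses the thin-wall formula `3πr³l/(2Eh)`; for an
  ellipse the area-equivalent radius `r_eq = √(ab)` is used, since the
  exact distensibility of an elliptical thick-walled tube is not
  available in closed form and the compliance of these short tracts is
  dynamically subdominant to the outlet circuits.
* **Open-loop venous return**: the venous side is a zero-pressure
  ground; there is no pulmonary or respiratory coupling.
* **Measured outlet resistances**: the total resistance of each
  coronary outlet is the in-vivo thermodilution measurement for the
  simulated condition, not an analytic estimate. This is what makes the
  model patient-specific at the hemodynamic (not just anatomic) level,
  and it is also why the predicted mean CBF is primarily a statement
  about the measured resistance and the reconstructed aortic pressure.

### Boundary conditions

The **inlet** is a pressure (voltage) source: a normalized template wave
rescaled so its extrema equal the measured systolic/diastolic pressures
and its period equals 60/HR. The **aortic outlet** is a three-element
Windkessel: total resistance MAP/CO split 9% proximal / 91% distal, with
C = 0.001 cm⁵/dyn. The **coronary outlets** are six-element circuits:
resistances 32% (`R_a`), 52% (`R_a-micro`) and 16% (series
`R_v + R_v-micro`) of the measured total; compliances `C_a` and `C_im`;
and an intramyocardial pressure source behind `C_im` that transmits
ventricular contraction to the microcirculation — the left-ventricular
wave on the left side, 20% of it on the right.

## Tunable parameters

| parameter | default | units | notes |
|---|---|---|---|
| blood density / viscosity | 1.06 / 0.04 | g/cm³ / P | `blood_properties()` |
| wall Young's modulus | 1.5e7 | dyn/cm² | `wall_properties()` |
| aortic wall thickness | 0.3 | cm | population average |
| coronary wall thickness | 0.03 | cm | population average |
| Windkessel compliance | 0.001 | cm⁵/dyn | literature-scale value |
| `c_a` | 1e-5 | cm⁵/dyn | order-of-magnitude; see below |
| `c_im` | 1e-4 | cm⁵/dyn | order-of-magnitude; see below |
| venous split of the 16% share | 0.5/0.5 | — | only the series sum is constrained by the circuit |
| Fourier harmonics | 16 | — | see "Waveforms" |
| LVP end-diastolic pressure | 10 | mmHg | typical ventricular diastole |
| MAP estimate | DBP + PP/3 | mmHg | `map_method = "waveform"` uses the template's time average instead |
| beats / samples per beat | 30 / 200 | — | reporting grid |

**`c_a` and `c_im` are the least constrained constants in the model.**
Published coronary outlet calibrations rarely print them and they cannot
be recovered from a total-resistance measurement. The defaults are
order-of-magnitude values typical of coronary outlet circuits; they are
deliberately exposed (and flagged here) rather than buried, and both can
be set per run via `lpm_control()` or a JSON configuration file. Because
capacitors pass no net flow over a converged periodic beat, the *mean*
CBF the package reports is insensitive to them; they shape the pulsatile
waveform (systolic impediment from `P_im`, diastolic refill) and any
within-beat quantity a user derives from the traces.

The one-third pulse-pressure MAP rule was chosen over the waveform
time-average because it is the standard clinical estimate and is
independent of the template shape; the difference between the two (the
template's mean is ≈ 0.39 of pulse pressure rather than 1/3) moves only
the aortic Windkessel calibration, not the coronary outlets.

## Waveforms

The template shape is a set of knots on the unit square (upstroke, peak
at 18% of the period, decline into a dicrotic notch of ≈ 0.1 pulse
pressure at 38%, secondary wave, decay back to the diastolic minimum)
interpolated with a monotone C1 cubic Hermite. Slopes are computed with
the Fritsch–Carlson/Brodlie rule — zero at local extrema, harmonic mean
of adjacent secants elsewhere — which guarantees no overshoot between
knots; the knot set is extended one period to each side so the slope is
periodic at the seam. (R's built-in `splinefun(method = "monoH.FC")`
averages secants across sign changes and visibly undershoots at the
seam, which is why the slopes are computed explicitly.) Any measured
wave can replace the template via `read_waveform_template()` (two-column
CSV, one period).

Time zero is the diastolic minimum, i.e. the foot of the systolic
upstroke; all sources share this convention and the common period 60/HR.

The circuit consumes the **Fourier series** of each source (coefficients
from FFT sampling of one period), because the intramyocardial capacitor
needs the analytic time derivative of its source. The default of 16
harmonics keeps the maximum reconstruction error of the default template
below 1% of pulse pressure (10 harmonics leave ≈ 2%, which violates that
bound — the bound won).

The left-ventricular pressure wave is synthesized, not measured: a
squared-sine systolic bump from a 10 mmHg end-diastolic pressure to the
aortic systolic peak over 45% of the period, constant in diastole. It
crosses the aortic wave shortly after the systolic foot and again near
end-systole, which is the qualitative behavior that matters for the
intramyocardial coupling; its exact shape is a modelling choice, made
explicit and replaceable.

## Numerics

`to_state_space()` reduces the network to `dx/dt = A x + B u + B_d u̇`
with one state per inductor flow and per free capacitor pressure.
Zero-compliance internal nodes are eliminated by nodal analysis (a
junction whose every branch is purely inductive cannot be eliminated and
is rejected at assembly, as is a zero-R/zero-L branch). Matrices are
materialized by evaluating the linear assembly on basis vectors, which
keeps the assembly code and the matrices trivially consistent.

**Integration.** The default method exploits linearity: the periodic
particular solution is assembled per harmonic from the frequency
response `(iωI − A)⁻¹(B + iωB_d)û`, the DC component from `−A⁻¹B a₀`,
and the transient from the initial condition is propagated with
`expm(A·Δt)` on the uniform reporting grid. This is exact up to the
matrix-exponential evaluation. It was made the default after profiling:
the segment compartments form weakly damped resonators (natural
frequencies ≈ 2000 rad/s at physiological geometry), and their ringing
forces a step-controlled stiff integrator to resolve ~10⁵ steps per
30-beat run. A conventional integrator (lsoda with the analytic
Jacobian, via deSolve) remains available through
`solver_settings(method = "lsoda")`; the test suite requires the two
routes to agree on final-beat mean flows.

**Initial conditions** are diastolic: all capacitor pressures at the
inlet diastolic pressure, all inductor flows zero. Thirty beats give
ample settling (the slowest mode decays with a ~1 s time constant), and
the run is flagged `converged` when the last two beats' mean coronary
flows agree within 1% (relative). The reported CBF is the mean flow into
each coronary outlet over the final complete beat — with periodic
convergence, any later beat would give the same value, and the choice of
the entering branch (rather than, say, the venous branch) is immaterial
in the mean because capacitors store no net volume over a period.

**Frequency scaling.** The joint transform (time compressed by a factor,
C and L divided by it) that block-diagram implementations use to cut
wall-clock time is implemented as `apply_frequency_scaling()` and is a
tested invariance of the solver: the factor-1000 run, un-scaled,
reproduces the direct run. It is off by default since the exact solver
gains nothing from it.

**Tolerances.** For the ODE route, rtol = 1e-6 with per-state absolute
tolerances scaled to typical magnitudes (~10⁵ dyn/cm² pressures, ~1 cm³/s
flows); halving tolerances must not move mean CBF by more than 0.1%
(tested). The exact route has no tolerance knobs.

## The synthetic cohort

`generate_cohort()` emulates the *inputs* of an AAOCA catheterization
cohort: aortic diameters 2–4 cm, coronary semi-axes 0.15–0.3 cm with a
flattened (axis ratio 0.4–0.7) intramural tract on the anomalous side,
segment lengths 0.5–3 cm, SV 50–110 ml, HR 55–95 bpm, SBP/DBP
100–160/60–95 mmHg, and a 15/19 anomalous-right fraction. Total coronary
resistances are generated *backwards* from right-skewed (log-normal)
resting flow targets spanning 0.4–10 ml/s (2–14 ml/s hyperemic, with
hyperemic targets a 2–4× multiple of rest so hyperemic resistance is
strictly lower), so that every generated record is guaranteed to be
simulable on the published flow scale. Each record stores its
"synthetic truth": the resistive-limit flow, mean inlet pressure over
total path resistance.

What the generator does **not** emulate: measurement noise structure,
correlations between geometry and resistance, demographic covariates,
tapered or branching coronary trees. Consequently, passing the
recovery and validation-pipeline tests on synthetic cohorts demonstrates
that the machinery is correct and self-consistent — not that the model
is clinically accurate on new patients; the packaged 19-patient cohort
is the empirical anchor for that question.

## Statistical conventions

* **Quantiles** use the inverse-CDF rule (`type = 1`): for n = 19 the
  25th/75th percentiles are the 5th/15th order statistics. This is the
  convention that reproduces the packaged cohort's printed percentile
  rows; R's default interpolation rule does not.
* **Wilcoxon signed-rank**: exact two-sided enumeration via the shift
  algorithm on a half-unit rank grid, so tied absolute differences
  (average ranks) are handled exactly; zero differences are dropped.
  n = 19 makes exact enumeration instant, and with ties present the
  usual exact routines refuse while the normal approximation (also
  provided, tie-corrected, optional continuity correction) is an
  approximation precisely where it matters at p ≈ 0.02–0.03. The
  significance threshold is reported against p < 0.025 (two comparisons
  per condition); no further multiplicity machinery is applied.
* **Bland–Altman** limits are bias ± 1.96·SD with the n−1 SD.
* **Relative differences** are always recomputed from the flow columns;
  the packaged table's printed rel-diff column is preserved as published
  (including one row whose printed value is inconsistent with its own
  flow columns) but is not used in computations.
* **UQ**: resistances drawn from Normal(measurement, level·measurement),
  truncated positive by redrawing, 100 draws per level at levels 5%,
  10%, 20% (the dispersion ladder is a package choice; the experiment's
  design — normal perturbation of both totals, rest condition —
  follows the validation study design). Reproducible given the seed.

## Problem sizes

The test-suite and acceptance-script simulations use the model's
standard conditions: 30 beats at 200 samples/beat (a 21-state system for
a two-coronary network), 19–20 patient cohorts for recovery and
resistive-limit checks, and 3 × 100 draws for the UQ experiment. A full
patient simulation takes on the order of 0.1 s with the default solver.

## Known limitations

* Mean CBF is governed by the measured total resistance and the
  reconstructed mean aortic pressure; the model cannot discover flow
  limitation that the resistance measurement itself missed.
* Rest and hyperemia reuse the same pressure targets unless the user
  provides per-condition pressures; the package accepts them but the
  synthetic generator keeps them equal.
* `c_a`/`c_im` defaults are order-of-magnitude (see above); pulsatile
  waveform detail should not be over-interpreted without calibrating
  them.
* No side branches, tapering, collapse, nonlinear compliance, or
  non-Newtonian rheology; no closed-loop or pulmonary circulation.
* The intramural tract is a fixed (if flattened) conduit: dynamic
  systolic compression of the intramural segment, a candidate ischemia
  mechanism in AAOCA, is not modelled — only the resistance it
  contributes at measurement time is.
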