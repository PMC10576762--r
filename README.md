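# coroflow

Patient-specific lumped-parameter (0D) modelling of coronary blood flow
for patients with an **anomalous aortic origin of a coronary artery
(AAOCA)** — a congenital variant in which a coronary arises from the
wrong sinus of Valsalva, sometimes with an intramural proximal tract, and
which carries a risk of exercise-related ischemia that routine stress
tests often miss.

The package is aimed at cardiovascular modellers and clinical researchers
who have per-patient data from CT/MRI imaging and an invasive coronary
functional assessment (continuous thermodilution), and who want a fast,
reproducible estimate of absolute coronary blood flow (CBF) at rest and
during maximal hyperemia — conditions that cannot be freely re-created in
the catheterization laboratory.

## The model

The aortic root and the two coronary arteries are represented as an
electrical-analog circuit (pressure ↔ voltage, flow ↔ current):

- **Vessel segments.** Each short vessel tract is one RLC compartment of
  a transmission line: Poiseuille resistance `R = 8 μ l / (π r⁴)`,
  inertance `L = ρ l / A`, thin-wall compliance `C = 3 π r³ l / (2 E h)`.
  The three aortic tracts (annulus, sinus of Valsalva at the sinotubular
  junction, proximal ascending aorta) are circular cylinders; coronary
  tracts are elliptical, with the exact elliptical-duct resistance
  `R = 4 μ l (a² + b²) / (π a³ b³)`. A normal coronary has two
  compartments, the anomalous one three (its ostial/intramural tract is
  the extra, flattened compartment).
- **Inlet.** A template aortic pressure wave is rescaled in amplitude and
  time to the patient's measured systolic/diastolic pressures and heart
  rate; its truncated Fourier series is the voltage source.
- **Aortic outlet.** Three-element Windkessel; the total systemic
  resistance MAP/CO (with CO = SV·HR) is split 91%/9% between the distal
  and proximal resistors, C = 0.001 cm⁵/dyn.
- **Coronary outlets.** Six-element circuit per coronary: the
  thermodilution-measured total resistance is split 32% / 52% / 16%
  among `R_a`, `R_a-micro` and the venous pair `R_v + R_v-micro`; two
  compliances `C_a` and `C_im`; the intramyocardial pressure source on
  `C_im` is the left-ventricular pressure wave (20% of it on the right
  side). The venous side is grounded at zero pressure.

The network is reduced to a linear state-space system (one state per
inductor flow and capacitor pressure), driven over thirty heartbeats, and
the reported CBF is the mean flow entering each coronary outlet over the
final beat. All computations are in cgs units (1 mmHg = 1333.22 dyn/cm²,
1 L/min = 16.667 cm³/s).

The validation statistics used for such models are included: exact
Wilcoxon signed-rank test (shift-algorithm enumeration with average ranks
for ties), Spearman correlation, Bland–Altman limits of agreement,
relative differences, median/IQR summaries, left/right flow splits, and a
Monte-Carlo uncertainty-quantification experiment over the coronary
resistances. A 19-patient AAOCA validation cohort (in-silico and in-vivo
CBF for both coronaries and both conditions) ships with the package, as
does a synthetic-cohort generator for end-to-end testing without clinical
data.

## Worked example

```r
library(coroflow)

## a synthetic patient with the cohort's statistical structure
spec    <- cohort_spec(n_patients = 19, seed = 42)
patient <- generate_patient(spec, 4)$patient
patient
#> Patient record: synth-004
#>   anomalous origin: right coronary
#>   stroke volume: 82.40575 ml
#>   rest      HR 76 bpm, 124.597/92.9521 mmHg, R(L/R) 854/954 mmHg/(L/min)
#>   hyperemia HR 83 bpm, 124.597/92.9521 mmHg, R(L/R) 222/270 mmHg/(L/min)

fit <- coronary_lpm(patient)   # calibrate both conditions
summary(fit)                   # runs the 30-beat simulations
#> Predicted coronary blood flow (final beat, ml/s):
#>  patient_id condition    ca cbf_insilico cbf_invivo converged  reldiff
#>   synth-004      rest  left        2.032      2.151      TRUE -0.05528
#>   synth-004      rest right        1.758      1.813      TRUE -0.03029
#>   synth-004 hyperemia  left        7.598      7.317      TRUE  0.03843
#>   synth-004 hyperemia right        5.597      5.532      TRUE  0.01183
```

`cbf_insilico` is the simulated mean flow into each coronary outlet
(ml/s) over the final beat; `reldiff` is (in-silico − in-vivo)/in-vivo.
As expected, hyperemic flows are several-fold the resting flows because
the measured microvascular resistances drop. `coef(fit)` exposes every
circuit parameter; `plot(fit)` draws the pressure and coronary flow
waveforms; `residuals(fit)` gives the in-silico minus in-vivo flows.

Validating against the packaged cohort:

```r
cv <- cohort_validation(cohort_cbf_long())
cv
#> Cohort validation: in-silico vs in-vivo CBF
#>   left  rest      n=19  p=0.020 *  rho=0.9482  bias=-0.10  LoA [-0.49, +0.30]
#>         median (IQR): in-silico 1.60 (1.01), in-vivo 1.72 (1.10) ml/s
#>   right rest      n=19  p=0.229  rho=0.9745  bias=-0.03  LoA [-0.20, +0.14]
#>         median (IQR): in-silico 1.06 (1.09), in-vivo 1.23 (1.13) ml/s
#>   left  hyperemia n=19  p=0.044  rho=0.9737  bias=+0.25  LoA [-0.71, +1.22]
#>         median (IQR): in-silico 5.90 (3.38), in-vivo 5.72 (3.61) ml/s
#>   right hyperemia n=19  p=0.026  rho=0.9377  bias=+0.31  LoA [-0.83, +1.45]
#>         median (IQR): in-silico 4.37 (2.28), in-vivo 3.53 (2.42) ml/s
#>   flow split rest.invivo        left 57(20)% / right 43(20)%
#>   ...
#>   (* significant at the adjusted threshold p < 0.025)
```

The model slightly underestimates resting CBF (negative bias, significant
only for the left coronary at rest) and slightly overestimates hyperemic
CBF; correlations are ≥ 0.94 throughout. The cohort's median flow split
at rest, 57%/43%, departs from the 70%/30% expected in normal coronary
anatomy.

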