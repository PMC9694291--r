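---
title: "Modelling roll compaction: maximum pressure, dwell time and ribbon solid fraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling roll compaction: maximum pressure, dwell time and ribbon solid fraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rollcompact)
```

## The problem

In roll compaction/dry granulation (RCDG) a powder is drawn between two
counter-rotating rolls and densified into a ribbon. The ribbon solid fraction
— apparent density over particle density — is the process's key quality
attribute: it controls granule size after milling and the tabletability of
the granules. Practitioners set the process through the specific compaction
force (SCF, roll force per cm of roll width), the gap width `S` and the roll
speed (RS). This package implements the closed-form model chain that predicts
the at-gap solid fraction from those settings, plus the measurement
reductions used to check the prediction, and a seeded synthetic-data
generator so the whole chain is testable without a compactor.

## Model

### From force to maximum pressure

Under the rolling-theory assumptions (the powder gripped at the nip angle
behaves as a solid body, deformation is uniaxial, mass flow is steady), the
maximum pressure at the gap follows from the specific compaction force, the
roll geometry and the material's compressibility index `K`:

$$P_{max} = \frac{2\,SCF}{D}\sqrt{\frac{2K}{\pi\,S/D}}$$

`K` is the exponent of the power-law densification $\rho \propto P^{1/K}$.
`pmax_from_scf()` evaluates this with SCF in kN/cm, lengths in mm and the
result in MPa; all unit conversions are centralized and exact. Pmax is linear
in SCF and increasing in `K`. For the study geometry (D = 250 mm, S = 2.0 mm)
and K = 3.84, SCFs of 2.9–7.6 kN/cm give 41–106 MPa:

```{r}
geom <- roll_geometry(D = 250, W = 25, S = 2.0)
round(pmax_from_scf(c(2.9, 4.0, 5.8, 7.6), geom, K = 3.84))
```

### Pressure-angle profile and dwell time

The pressure at a roll angle $\theta$ before the gap is

$$P(\theta) = P_{max}\left[\frac{S/D}{(1 + S/D - \cos\theta)\cos\theta}\right]^{K\cos\theta}$$

which equals $P_{max}$ at $\theta = 0$ and decreases monotonically over the
physical range. The *dwell time* is the pre-gap time during which the
pressure exceeds a fraction (by convention 90 %) of $P_{max}$: the threshold
angle $\theta^*$ solves $P(\theta^*)/P_{max} = 0.9$ (the ratio form cancels
$P_{max}$, so $\theta^*$ depends only on `K` and `S/D`), and
$DT = \theta^*/\omega$ with $\omega = 2\pi RS/60$. The post-gap relaxation
branch is ignored. Because $\theta^*$ is speed-independent, $DT \cdot RS$ is
constant, and a material with higher `K` (steeper pressure drop) dwells less
at every speed:

```{r}
rs <- c(1.0, 1.2, 1.5, 2.0, 3.0, 6.0, 10.0)
round(dwell_time(rs, geom, K = 3.84, round_theta = TRUE))  # plastic (MCC-like)
round(dwell_time(rs, geom, K = 6.90, round_theta = TRUE))  # brittle (lactose-like)
```

`round_theta = TRUE` rounds the threshold angle to 0.1 degree before the
division; this is the convention under which the reference dwell-time table
(200/150 ms at 1 rpm) is reproduced exactly. At full angular precision the
1 rpm values are 202.4 and 150.5 ms — about 1 % away; the default keeps full
precision and the flag is offered for table reproduction.

### Midoux number and at-gap solid fraction

The Midoux number $Mi = P_{max}/P_\alpha$ relates the gap pressure to the
pressure $P_\alpha$ at the nip angle. With the powder density $\rho_\alpha$
at the nip state, the power law predicts the maximum at-gap density
$\rho_{Mi} = \rho_\alpha Mi^{1/K}$ and the predicted solid fraction
$SF_{Mi} = \rho_{Mi}/\rho_0$. Constant `Mi` implies constant $SF_{Mi}$, which
is what makes the number usable for equipment transfer and up-scaling.
$P_\alpha$ and $\rho_\alpha$ must be supplied: they are instrument- and
material-specific and are not tabulated for the study materials, so the
package deliberately ships no defaults for them.

### Measurement reductions

The measured counterparts are plain ratios, implemented exactly:

* at-gap solid fraction from ribbon throughput: the ribbon volume collected
  in `t` seconds is `V = S · W · π · (D+S) · n_rev` (the gap cross-section
  advancing at the surface speed of the effective diameter `D + S`), and
  `SFgap = (m/V)/ρ0`;
* prediction accuracy `PA = SFgap / SFMi`;
* ribbon solid fraction from pycnometric density, `SFribbon = ρribbon/ρ0`;
* the dwell-time coefficient `SFcoefficient = SF(lowest DT)/SF(highest DT)`
  per maximum-pressure series — 1 means no dwell-time effect;
* ribbon tensile strength from a three-point beam test,
  `TS = 3 F span / (2 w h²)`, and tablet tensile strength from diametral
  compression, `TS = 2F/(π d h)`.

Replicates are reported as arithmetic mean ± sample SD (n − 1 denominator).
Solid fractions above 1 and prediction accuracies far from 1 are *flagged
with warnings, not errors*: measurement noise can legitimately produce them.

### Material descriptors from in-die tableting data

`fit_compressibility_index()` regresses ln(in-die density) on ln(pressure)
by ordinary least squares and returns `K` as the *reciprocal* of the slope
(a ln–ln slope near 0.26 corresponds to K = 3.84) — the convention required
for the Pmax closed form above to reproduce the study's printed pressures.
`fit_heckel()` regresses −ln(porosity) on pressure; the slope is the Heckel
constant and the yield pressure is its exact reciprocal. A low yield pressure
indicates plastic deformation, a high one brittleness. Records whose in-die
density reaches the particle density (porosity ≤ 0) cannot enter the log and
are excluded with a warning rather than failing the fit; the regressions are
unweighted over the full supplied pressure range, with an optional range
filter (`pressure_range`) since a linear subrange is sometimes preferred for
Heckel analysis.

## The synthetic-data generator

`generator_spec()` + `generate_ribbon_study()` emulate the full measurement
chain: nominal Pmax from SCF → optional dwell-time-dependent attenuation →
Midoux at-gap solid fraction → elastic recovery → inversion of the
throughput and pycnometry reductions into raw masses and densities, with
multiplicative log-normal noise per measured quantity. Defaults, chosen once:

* `noise_cv = 0.01` (1 % CV). The study reports only triplicate SDs, so the
  CV is a free knob; 1 % is typical for balance and pycnometer measurements.
* `elastic_recovery = 0.10`: the fractional solid-fraction loss from gap to
  relaxed ribbon. No functional form or value is published for the study
  materials; 0.1 is a placeholder within the commonly observed 5–15 % range.
* tablet mass 300 mg and radius 5.64 mm (an 11.28 mm flat-faced punch), five
  pressures spanning 25–250 MPa with 10 tablets each, for the in-die
  generator; one-minute ribbon collections; 42 mm bend-test span.
* nip-state truths used throughout the analysis scripts and tests:
  `P_alpha = 1` MPa with `rho_alpha = 0.42` g/cm³ (plastic material,
  ρ0 = 1.56) and `0.58` g/cm³ (brittle material, ρ0 = 1.54). These are
  realistic nip-state densifications of the bulk powders chosen so the
  predicted solid fractions stay inside (0, 1) over the whole process grid;
  they are *generating truths*, not estimates of the unpublished values.

The attenuation map is the generator's stand-in for the (unproven)
hypothesis that faster rolls reach a lower actual maximum pressure. It is a
user function of dwell time returning a multiplier in (0, 1]. By default it
is applied *only to conditions whose nominal Pmax is below the material's
yield pressure* (`attenuate_below_yield_only = TRUE`): below the yield
pressure densification is dwell-time-sensitive plastic flow, above it the
loss of pressure has little effect on the achieved solid fraction. This
gating is what lets a single dwell-time map reproduce the observed pattern —
dwell-time coefficients below 1 only in sub-yield pressure series — without
claiming a fitted mechanism.

Randomness uses one root seed with deterministic per-condition substreams, so
identical specifications produce bit-identical files and increasing the
replicate count only appends replicates.

In-die compression records are generated under either the power law or the
Heckel law — the two are mutually inconsistent except locally, so the mode is
an explicit argument rather than a default.

## What the generator does and does not emulate

Passing recovery and closure tests on synthetic data shows that the
estimators invert the generating laws and that the pipeline's algebra is
consistent; it does not validate the rolling-theory assumptions against real
powder, nor the attenuation hypothesis, nor elastic recovery's size. Granule
size distributions and tabletability are empirical outcomes with no published
generating model and are out of scope: the package neither simulates nor
predicts them. The measured study summaries (prediction accuracies of
1.02 ± 0.03 and 0.98 ± 0.04, dwell-time coefficients of 0.89–1.03, ribbon
tensile-strength drops) depend on unpublished raw measurements and on the
untabulated nip-state parameters, so they cannot be recomputed; the tests
cover them through property surrogates (closure at PA = 1 on clean data, the
sub-yield-only attenuation response).

## Numerical choices

* Threshold-angle root finding: `stats::uniroot` on (1e-8, 0.5] rad with a
  1e-13 x-tolerance, followed by a residual check at 1e-10 on the pressure
  ratio; the profile is strictly monotone there for all physical `K` and
  `S/D`, and a missing sign change raises a diagnostic error rather than
  returning a guess.
* Pmax is kept at full precision internally; the integer-MPa column in the
  study tables is presentation rounding only. One reference value sits on a
  rounding knife-edge: at SCF 5.2 kN/cm and K = 6.90 the closed form gives
  97.48 MPa, which rounds to 97 rather than the published 98 (any K above
  about 6.903 — within the two-decimal print precision of 6.90 — crosses the
  97.5 boundary). The package reports the computed value.
* Degenerate inputs (non-positive dimensions, forces, pressures; fractions
  outside (0,1); `Mi < 1`; nip pressure above gap pressure) raise domain
  errors naming the offending field. Supra-particle in-die densities are a
  data pathology, not a code path: they are excluded per record with a
  warning.
* Problem sizes in the tests and analysis scripts (3 replicates per process
  condition, 50-record fits, 100-record Monte-Carlo recoveries, 40-seed
  dispersion checks) are chosen so every property is decided by orders of
  magnitude rather than borderline statistics while the full suite stays
  fast.

## Limitations

The model chain inherits the rolling theory's idealizations: no slip after
the nip, uniaxial deformation, speed-independent Pmax. The study this package
models found the last assumption to be material-dependent — for a plastic
material the prediction degrades away from moderate roll speeds — which is
exactly what the attenuation knob lets you represent, but the package does
not estimate the attenuation from data. Nip angles, roll torque, screw
feeding and milling are out of scope.
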