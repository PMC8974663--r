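---
title: "Methods: fractional-order Windkessel calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fractional-order Windkessel calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracwk)
```

## The models and their assumptions

All four models in this package describe the aortic input impedance
$Z_{in}(\omega) = P(\mathrm{j}\omega)/Q(\mathrm{j}\omega)$ of a strictly
periodic pressure–flow pair at the ascending aorta. The two-element
Windkessel (WK2) is a peripheral resistance $R_p$ in parallel with an ideal
capacitance $C$; WK3 adds a characteristic impedance $Z_c$ in series; the
viscoelastic Windkessel (VWK) replaces the capacitor by a Voigt cell (a
dashpot resistance $R_d$ in series with a static compliance $C_{vw}$). The
fractional two-element model (FWK2) keeps the WK2 topology but uses a
fractional-order capacitor of impedance $1/(C_\alpha (\mathrm{j}\omega)^\alpha)$:

$$Z_{in}^{FWK2}(\omega) = \frac{R_p}{1 + R_p C_\alpha (\mathrm{j}\omega)^\alpha}.$$

Key assumptions, shared by every operation in the package:

- **Strict periodicity.** A record covers exactly one cardiac cycle on a
  uniform half-open grid $[0, T)$; the Fourier series is exact for such
  signals. Beat detection and multi-beat segmentation are out of scope.
- **Frequency-domain evaluation only.** Model responses are evaluated
  harmonic by harmonic at $n\omega_0$, $\omega_0 = 2\pi/T$. No fractional
  differential equation is integrated in time; for periodic steady state the
  two are equivalent, and the frequency-domain route is exact and fast.
- **Principal branch.** $(\mathrm{j}\omega)^\alpha = \omega^\alpha
  e^{\mathrm{j}\alpha\pi/2}$ for $\omega \ge 0$. Negative frequencies are
  never evaluated; real signals are handled through conjugate symmetry of
  the cosine-series representation. When $\alpha = 1$ the code substitutes
  $\mathrm{j}\omega$ exactly, so the integer-order models are special cases
  to machine precision, not merely to rounding in
  $\cos(\pi/2) \approx 6\cdot10^{-17}$.

## Identifiable form and calibration

Fitting works on the observational (black-box) form shared by all four
models,
$$H(\omega) = G\,\frac{1 + a_1 \mathrm{j}\omega}{1 + b_1 (\mathrm{j}\omega)^\alpha},$$
with $a_1 = 0$ for the one-pole models (FWK2, WK2) and $\alpha = 1$ for the
integer-order ones. WK3 and VWK map to the *same* zero-pole family
($G = Z_c + R_p,\; b_1 = R_p C,\; a_1 = Z_c b_1 / G$ versus $G = R_p,\;
a_1 = R_d C_{vw},\; b_1 = (R_p + R_d) C_{vw}$), so their fits must coincide
in objective value; the package asserts this equivalence in its tests
rather than assuming it, and reports the two models separately.

The gain is never optimized: $G = Z_{in}(0) = P_0/Q_0$, the ratio of mean
pressure to mean flow, which is also the total peripheral resistance (for
WK3, $G = Z_c + R_p$). The remaining coefficients are estimated by
minimizing

$$\mathrm{NRMSE} = \frac{\sqrt{\sum_{i=0}^{N}
  [\mathrm{Re}(Z_i) - \mathrm{Re}(\hat Z_i)]^2 +
  [\mathrm{Im}(Z_i) - \mathrm{Im}(\hat Z_i)]^2}}{(N+1)\,G}.$$

Two conventions deserve emphasis because reported magnitudes depend on
them:

- the divisor $(N+1)G$ sits **outside** the square root — this is a
  gain-normalized root-sum-square, smaller by $\sqrt{N+1}$ than an RMS
  would be;
- the per-harmonic modulus deviation $D_i = (|\hat Z_i| - |Z_i|)/|Z_i|
  \cdot 100$ is averaged over $i = 0..N$ with divisor $N+1$. Since $G$ is
  fixed to $Z(0)$, $D_0 = 0$ identically, so including harmonic 0 only
  rescales the mean.

### Optimizer

The residual vector $\big(\mathrm{Re}(Z)-\mathrm{Re}(\hat Z),\,
\mathrm{Im}(Z)-\mathrm{Im}(\hat Z)\big)/((N+1)G)$ is minimized by bounded
Levenberg–Marquardt (`minpack.lm::nls.lm`); its root-sum-square is exactly
the NRMSE above, so the fitted objective and the reported metric are the
same quantity by construction (the reported value is always recomputed
through the package's `nrmse()`). All coefficients have lower bound 0;
$\alpha$ has no upper bound by default (`fit_config(alpha_upper = )` can
impose one). Tolerances are `ftol = ptol = 1e-14`, tight enough that
noiseless synthetic spectra are recovered at machine precision; MINPACK
termination codes 1–4 are accepted as convergence (code 4 — gradient
orthogonality — is what an exactly-zero residual returns).

Initialization is deterministic: the time constant is seeded by a
first-harmonic moment match $\tau_0 = G\,\mathrm{Im}(1/Z_1)/\omega_1$
(fallback 1 s if non-positive), multiplied by scale factors
$\{1, 0.3, 3, \dots\}$; FWK2 additionally multistarts over
$\alpha_0 \in \{0.3, 0.5, 0.8\}$, and the zero-pole models over several
$a_1/\tau_0$ ratios. The best-objective start wins; ties are irrelevant
because only the objective value and its coefficients are reported. Three
starts (the default) sufficed for every truth configuration exercised in
the test suite; the count is configurable.

### Degenerate inputs

- A flow harmonic with amplitude below $10^{-12}\times$ the largest flow
  harmonic makes the impedance ratio meaningless; the spectrum constructor
  raises a typed error naming the harmonic rather than dividing.
- A non-positive DC gain (non-physiological record) is a data error.
- If a fitted zero-pole model violates the realizability inequality
  $a_1 < b_1$, the fit is retained (its objective is valid) but parameter
  extraction is flagged non-physical instead of returning negative
  resistances.
- An all-real spectrum has an undefined phase relative error; the metric is
  reported as `NA`, not an exception.
- Phases are principal values in $(-\pi, \pi]$ throughout; the phase
  relative error uses wrapped radians by default because no unwrapping rule
  is implied by the $L_2$ definition. `relative_errors(unwrap = TRUE)`
  switches to unwrapped sequences; for the smooth, low-phase-magnitude
  spectra produced by these models the two agree, but the choice matters
  for spectra whose phase crosses $\pm\pi$.

## Parameters that matter

| Parameter | Unit | Default | Why |
|---|---|---|---|
| `n_harmonics` | – | 20 | covers the band of physiological interest, up to 20× the heart rate |
| `alpha` bounds | – | $(0, \infty)$ | positivity is physical; the upper bound is deliberately open so the data, not the prior, drives $\hat\alpha \le 1$ |
| `multistart` | – | 3 | deterministic grid described above |
| `ftol`, `ptol` | – | $10^{-14}$ | machine-precision recovery on noiseless spectra |
| amplitude floor | relative | $10^{-12}$ | guards the harmonic ratio against numerically vanishing flow harmonics |

Internal units are mmHg, ml/s and seconds, making $C_\alpha$
ml/mmHg·s$^{1-\alpha}$ and impedances mmHg·s/ml; cardiac output is reported
in l/min. Compliance values in l/mmHg·s$^{1-\alpha}$ (as sometimes printed
in the literature) are a ×1000 conversion at the reporting boundary.

## The synthetic cohort: what it emulates, what it does not

`generate_cohort()` emulates the *structure* of an in-silico virtual adult
population: a 3 × 3 grid of heart rates (53, 63, 72 beats/min) and stroke
volumes (66, 83, 100 ml) whose cardiac outputs span 3.5–7.2 l/min, with
ground-truth model parameters drawn uniformly from physiological ranges
($R_p \in [0.7, 1.5]$ mmHg·s/ml, $\alpha \in [0.3, 0.6]$ — spanning
reported per-subject estimates of 0.33–0.52 — and time constants
$\tau \in [0.5, 2]$ s; $Z_c \in [0.03, 0.08]$ and $R_d \in [0.02, 0.06]$
mmHg·s/ml for the three-parameter models).

The flow waveform is a stylized half-sine ejection over a 0.33 cycle
fraction, scaled so the analytic cycle integral equals the stroke volume
exactly; pressure is the exact periodic steady-state response of the
ground-truth model, with optional i.i.d. complex Gaussian noise on the
pressure harmonics $1..N$ (standard deviation a configurable fraction of
the first harmonic's amplitude; the mean is left exact so the DC gain stays
identifiable). Everything is deterministic under the spec's seed, and the
generator restores the caller's RNG state.

What the generator does **not** emulate: real aortic flow morphology
(wave reflections, dicrotic notch), the distributed physics of a 1-D
arterial network, and measurement artifacts other than harmonic-domain
noise. Consequently, passing tests demonstrate the *correctness of the
pipeline* — decomposition, spectrum estimation, calibration, parameter
extraction, aggregation — and its statistical behavior under known truth;
they do not validate the physiological adequacy of any model for real
data, and cohort-level metric magnitudes are not comparable to values
obtained on richer waveforms, where none of the lumped models is the true
generator.

## Problem sizes

The shipped tests and the acceptance script use 256-sample single-cycle
records, 21-harmonic spectra, a 27-point truth grid for noiseless recovery,
100 replicates for noise robustness at a 2 % harmonic noise level, and
9-subject cohorts (one subject per grid cell) for the equivalence,
benchmark and compliance checks; the full suite completes in well under a
minute. Larger cohorts (`subjects_per_cell`) scale linearly.

## Known limitations

- One exact cycle per record; no beat segmentation or denoising.
- Local optimization with deterministic multistart: no global-optimality
  guarantee, though the identifiable forms are low-dimensional and
  well-behaved in practice.
- No uncertainty quantification on the estimates.
- The WK3/VWK equivalence means their fits are mutually redundant by
  design; they are kept as separate reporting columns deliberately, and
  their equality is a standing invariant of the test suite.
- Time-domain simulation (e.g. Grünwald–Letnikov integration of the
  fractional ODE) is out of scope; all statements are about periodic
  steady state.
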