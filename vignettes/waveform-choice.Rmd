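---
title: "Choosing between rectangular and sinusoidal drive in DEP: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing between rectangular and sinusoidal drive in DEP: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depwave)
```

## The model

Dielectrophoresis moves polarisable particles along gradients of the squared
electric field. For a homogeneous sphere of radius $R_p$ in a medium of
absolute permittivity $\varepsilon_m$, the time-averaged force is

$$\vec F = 2 \pi R_p^3\, \varepsilon_m\, \mathrm{Re}\{CM(f)\}\,
\nabla |\vec E_{rms}|^2 ,$$

with the Clausius–Mossotti factor built from the complex permittivities
$\varepsilon_i^* = \varepsilon_{r,i}\varepsilon_0 - j\sigma_i/\omega$ of
particle and medium. `depwave` evaluates its real part in the rationalised
single-relaxation form (see `re_cm()`), which runs monotonically between a
DC plateau set by the conductivity contrast and a high-frequency plateau set
by the permittivity contrast, is bounded in $[-0.5, 1]$, and changes sign at
most once — at the cross-over frequency $f_{co}$, available in closed form
(`crossover_frequency()`). Both permittivity symbols enter as absolute
values ($\varepsilon_r \varepsilon_0$); this is the only dimensionally
consistent reading of the rationalised formula and reproduces the standard
dispersion shape.

A square wave is an odd-harmonic series with line amplitudes
$A_n = (4/\pi) V_0 / n$. Two facts drive everything downstream:

* with the peak-amplitude-squared energy convention $P_n = A_n^2$ the full
  series carries exactly twice the energy of an equal-peak sinusoid
  ($\tfrac{16}{\pi^2}\sum 1/(2n-1)^2 = \tfrac{16}{\pi^2}\cdot\tfrac{\pi^2}{8}
  = 2$), and
* each line is weighted by $\mathrm{Re}\{CM\}$ *at its own frequency*, since
  the force is quadratic in the field and cross-frequency terms average to
  zero over a period. The per-line force weight $\propto A_n^2$ is the only
  choice consistent with the series energy accounting.

`decompose_force()` evaluates these weighted contributions, separates the
harmonic ones by sign into $A \ge 0$ (aiding) and $B \le 0$ (opposing), and
compares the total against a sinusoid of the same peak amplitude — the bench
convention, where both shapes are driven at the same peak-to-peak voltage.
An equal-RMS baseline is available via `comparison = "rms"`.

## The advisor and its two rules

`advise()` reports a tri-state verdict from the conservative *energy rule*:

* **beneficial** when $f_0 < f_{co}/5$. The divisor 5 is not an assumption
  but a consequence of the energy ledger: the harmonics carry
  $\pi^2/8 - 1 \approx 0.234$ of the normalised energy, and the third and
  fifth harmonic alone ($1/9 + 1/25 \approx 0.1511$) exceed half of that
  ($0.1168$), so keeping them on the fundamental's side of the cross-over
  guarantees $|A| > |B|$. `smallest_safe_divisor()` generalises the scan to
  any energy share.
* **always beneficial** when $f_0 > f_{co}$ or no cross-over exists: every
  harmonic then shares the fundamental's sign and can only deepen the force.
* **not guaranteed** in between. The rule is sufficient, not necessary, so
  this band is reported as its own state rather than forced into a binary,
  with the exact decomposition attached: `beneficial_exact` is true when the
  signed total exceeds the sine baseline (gain ratio > 1).

Both rules presuppose a single cross-over. The homogeneous-sphere dispersion
implemented here cannot have more than one, so the restriction is structural;
layered (multishell) particles with multiple cross-overs are out of scope.

## Numerical choices

* **Spectral tail.** A truncated series misses analytically known energy:
  at the default truncation (order 199, the first 100 odd lines) the missing
  share is about 0.4% of the total. Those lines all lie far above any
  plausible cross-over, on the high-frequency plateau of the dispersion, so
  `decompose_force()` adds their closed-form energy weighted by the plateau
  CM value (`tail = "plateau"`, the default). This makes the flat-dispersion
  gain ratio exactly 2 at any truncation and removes the truncation bias
  from all totals; `tail = "none"` gives the raw partial sum. The tail is
  omitted when a bandwidth limit is set, because the electronics then
  genuinely remove those lines.
* **Truncation default 199.** The tail bound
  $\pi^2/8 - \sum^N < 1/(4N)$ keeps the untailed residual below 0.25% of
  the harmonic ledger; with the plateau tail the choice only affects how
  finely the transition region of the dispersion is sampled.
* **Bandwidth limiting.** Default is an ideal brick-wall (reproducible and
  assumption-free); a single-pole low-pass magnitude
  $1/\sqrt{1+(f/f_c)^2}$ is available as the simplest physical alternative.
  Harmonic phases are the sine-series phases; duty cycle is fixed at 50%.
* **Cross-over solving.** The closed form is used directly; its validity is
  established in the test suite against a bracketing root finder on the
  dispersion itself (relative agreement better than $10^{-4}$ over 1000
  random systems — the suite's problem size, chosen to exercise both
  crossing and non-crossing draws at desk scale). Degenerate systems
  (particle $\equiv$ medium) return a zero dispersion and "no crossing"
  rather than an error.
* **Surface conductance.** The effective particle conductivity
  $\sigma_p = \sigma_{bulk} + 2 K_s / R_p$ is applied when the user supplies
  $K_s$; the default is 0. Published cross-overs for small latex spheres
  depend on $K_s$ values that are rarely printed, so the package never
  invents one — example parameter sets in the documentation are labelled as
  plausible, not asserted.
* **Frequencies** are ordinary frequencies in Hz at every interface;
  $\omega = 2\pi f$ is internal.
* **Signal energy.** The time-domain definition is implemented as twice the
  mean square over one period, the unique scaling under which the
  $P_n = A_n^2$ spectral convention, Parseval's theorem and the "twice the
  energy" ratio all agree (a naive $\int V\,dt$ is zero for any AC signal).

## Efficiency metrics and the synthetic trace generator

`failure_rate()` is the escaped/entered percentage from particle counting.
`separation_efficiency()` implements $\eta = 1 - \bar I_{trap}/\bar I_{c0}$
with arithmetic in-window means (no resampling or interpolation — the
simplest faithful reading of an averaged intensity). Replicate aggregation
reports the sample standard deviation ($n-1$) and, since the field's
"±" convention is often left unstated, the standard error as well. Negative
$\eta$ (outlet brighter than baseline) is physically meaningful — release or
accumulation — and is passed through with a warning, never clamped.

`synth_trace()` emulates a filter run as seen at the outlet detector: flat
baseline, exponential settle to `trap_fraction` × baseline while trapping,
and a pulse-shaped release back to baseline, plus optional additive Gaussian
noise, deterministic per seed. The schedule is the standard protocol — field
on at 60 s and off at 240 s — observed through a ~10 s transport lag from
filter to cuvette, so the outlet phases are 0–70 s baseline, 70–250 s
trapping, release from 250 s; the evaluation window 225–245 s and baseline
window 10–55 s (trimmed inside the baseline phase) are the defaults. Settle
and release time constants (8 s, 12 s) match the fast concentration drop
such filters show within seconds of energising; by 225 s the settle
transient is below $10^{-8}$, so noiseless recovery returns the generator's
ground truth $\eta = 1 - \text{trap fraction}$ essentially exactly.

What the generator does *not* emulate: detector drift and bleaching,
saturation of the filter at high retained mass (real filters plateau below
100% efficiency), flow-rate fluctuations, and particle-size polydispersity.
Passing recovery tests therefore demonstrates that the metric pipeline is
unbiased on well-behaved traces, not that real traces are this clean.

## Known limitations

* Homogeneous spheres only — no membrane-covered (multishell) cell models,
  no electrorotation (imaginary-part) spectra, no temperature dependence.
* The field-geometry factor $\nabla|E_{rms}|^2$ is a single user-supplied
  scalar, identical for all harmonics; dispersive electrode impedance is not
  modelled (verdicts are geometry-independent, gain magnitudes are not).
* Ideal 50%-duty square waves and pure sinusoids only; no measured-waveform
  ingestion, ramps, triangles, or Gibbs smoothing.
* The advisor compares force magnitudes at one operating point; it does not
  predict trajectories, throughput, or competing electrothermal flows.
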