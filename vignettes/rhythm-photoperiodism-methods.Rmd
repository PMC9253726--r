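---
title: "Methods: rhythm quantification, critical day length, and the period-CDL association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rhythm quantification, critical day length, and the period-CDL association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lemnaclock)
```

This vignette is the package's own account of its models and the choices
behind them. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The signal model and the experimental design it emulates

Circadian reporter assays in duckweed follow a fixed protocol: plants
carrying a luciferase reporter are entrained under light/dark cycles
(default 15 h light / 9 h dark for 2 days), then released into constant
light (LL), with luminescence integrated for 30 s every 20 min. The
synthetic generator `simulate_luminescence()` produces

$$y(t) = e^{g t}\left[M + A\,D(t)\cos\theta(t)\right] + \varepsilon_t,
\qquad \varepsilon_t \sim N(0, \sigma^2)\ \text{i.i.d.}$$

* **Phase continuity at release.** $\theta(t)$ advances at $2\pi/24$ per
  hour during entrainment — anchored so a cosine peak falls
  `entrained_peak_offset_h` (default 2 h, a morning phase) after each
  lights-on — and at $2\pi/\tau$ per hour afterwards, with no jump at the
  release. This is what makes the first LL peak a read-out of the entrained
  phase: under phase continuity the first-peak time increases strictly with
  $\tau$, which is the mechanism behind the positive period/peak-time
  association the pipeline tests for.
* **Release timing.** Release into LL is the dark period that never comes:
  `ll_start_h = 24·(entrain_days − 1) + photoperiod` (39 h under the
  default protocol). The grid runs to `24·entrain_days + ll_duration_h`
  (180 h by default), so the recording comfortably covers the 60–132 h
  analysis window. Peak-time phenotypes are referenced to the final
  lights-on before release (t = 24 h by default) — the "dawn of the last
  entrained day". The reference is a convention, not a measurement; it is
  configurable through the trace annotations.
* **Trend and damping.** A multiplicative envelope $e^{gt}$ (default
  $g = 0.005\,h^{-1}$) models reporter signal from an exponentially growing
  frond population acting on mesor and oscillation jointly; rhythm
  amplitude additionally damps at rate `damping_per_h` (default
  0.005 h⁻¹) after release, as reporter rhythms do in constant conditions.
* **Noise.** Additive, Gaussian, independent across time points (default
  SD 10 against amplitude 50, i.e. an amplitude-to-noise ratio of 5, a
  clean reporter signal). Real photomultiplier counts have Poisson-like,
  sometimes autocorrelated noise; neither is modelled in v1. Passing
  recovery tests therefore demonstrates correctness of the estimators under
  the stated signal model, not robustness to every pathology of real
  traces.

The flowering generator draws binomial counts per replicate well over the
standard day-length grid {9, 11, 11.5, …, 15} h with success probability
$(F_{max}/100)\cdot r(DL)$, where $r$ is a symmetric linear ramp of width
`transition_width_h` centred on the programmed CDL, so the
50%-of-maximum point equals the programmed CDL *by construction* and
recovery is exactly scorable. The true shape of the flowering response
near the CDL is unknown; the ramp (default width 1 h, default
$F_{max} = 80\%$, 2 replicate wells of 20 fronds) is a simulation device,
not a claim about the plant. The panel generator draws
$\tau_i \sim N(\mu_\tau, \sigma_\tau^2)$ (defaults 24 ± 1 h, bracketing the
20–28 h range over which plant clocks vary) and
$CDL_i = a + b\tau_i + N(0, \sigma_\epsilon^2)$ (defaults $a = 25$ h,
$b = -0.5$, $\sigma_\epsilon = 0.3$ h, putting CDLs in the observed
11–14 h band with a programmed negative dependence on period).

## Preprocessing

Detrending subtracts a centred moving average spanning
$[t - 12\,h, t + 12\,h]$ inclusive — 73 samples at 20-min sampling; for
other sampling intervals, the nearest odd count spanning at most the
window. Normalization divides by the centred moving **population** SD
(divide by N): it is a normalization constant, not an inferential
estimate, and the N-denominator makes results bit-reproducible without a
hidden d.o.f. convention. Both statistics are computed only where the full
window fits; each stage trims `window points − 1` samples, with no padding
— the period analysis uses an interior window (60–132 h), so edge behaviour
never matters and trimming is the least surprising choice. A constant
segment (zero window SD) is an error naming the offending time point, not
a silent NaN.

One consequence worth knowing: because the inclusive window duplicates an
endpoint, the 73-point mean of an exactly 24-h cosine is
$-\cos(\omega t)/73$ rather than 0, so detrending scales such a cosine by
exactly $1 + 1/73$. The tests assert this derived factor; it is irrelevant
downstream because the moving-SD normalization removes any common scale.

## Peak detection

Candidates are local maxima of a 2-h moving-average-smoothed copy; each is
refined by OLS of a quadratic on the *raw* samples within ±2 h, keeping the
vertex when the parabola opens downward and the vertex falls inside the
window. The 2-h choices are not from any measurement protocol: they make
the fit window about one sixth of a circadian cycle, where a cosine is
locally near-quadratic (vertex bias below 0.05 h, asserted by the test
oracle). Peaks closer than 12 h are merged, keeping the higher fitted
height (ties: earlier peak), which prevents double-counting shoulders.
Whether peak phenotypes should be read on raw or detrended traces is not
fixed by any convention; `analyze_rhythms()` defaults to detrended with a
switch.

## Period estimation and the relative amplitude error

`estimate_frp()` restricts the normalized trace to 60–132 h and fits
$y(t) = c_0 + \sum_m A_m \cos(2\pi(t-\phi_m)/\tau_m)$ by
Levenberg–Marquardt (via `minpack.lm::nls.lm`, analytic Jacobian,
convergence at relative RSS change `1e-10`, 200-iteration cap with a
`converged` flag on overrun). Numerical choices:

* **Seeding.** Each new component starts from the strongest local maximum
  of the residual periodogram, computed on an 8×-zero-padded FFT so the
  seed period is localized well below the Rayleigh resolution of the 72-h
  window (frequency bins of the raw DFT are ~1/72 h⁻¹ apart, which is a
  2–3 h period error near 24 h — enough to strand the optimizer in a local
  minimum).
* **Stopping.** Components are added one at a time (budget 4); a new
  component is kept only when its amplitude exceeds its linearized
  95% t-interval half-width, i.e. the CI excludes zero; otherwise it is
  discarded and fitting stops. This replaces the unpublished residual-
  whiteness tests of classic implementations with a reproducible rule.
* **Identifiability.** Negative amplitudes are flipped into the phase and
  phases wrapped to $[0, \tau)$, so the parameterization is canonical.
* **Degenerate inputs.** A constant series yields zero components with
  $c_0$ = the constant; an all-zero residual spectrum stops the stepping;
  a singular $J^\top J$ caps RAE at 1 with a warning.

The **circadian component** is the fitted component with $\tau \in$
[15, 35] h of largest amplitude — a range chosen to bracket the 20–28 h
spread of plant free-running periods with margin while excluding the 12-h
harmonic. Its **RAE** is $\min(\Delta A / A, 1)$ with $\Delta A$ the
95% t-interval half-width from $\hat\sigma^2 (J^\top J)^{-1}$,
$\hat\sigma^2 = RSS/(n-p)$. Classic FFT-NLLS software derives joint
confidence limits by a procedure that is cited but nowhere fully
specified; the linearized t-interval is adopted here because it is exactly
reproducible, and it differs from the joint interval only enough to matter
for strains sitting near the 0.1 threshold.

Replicates aggregate by mean and sample SD of $\tau$, mean RAE (figures in
this field plot replicate means, so the mean — not the max — is the
thresholded quantity), and the exclusion rule: mean RAE > 0.1 **or**
period SD > 1.5 h, or any replicate without a circadian component. The
literature is ambiguous about whether the RAE criterion operated alone or
jointly with the SD criterion; the OR-rule is the default and
`rhythm_config(exclusion_rule = "sd_only")` gives the alternative.

## Critical day length

`estimate_cdl()` reads the CDL off a piecewise-linear function —
straight-line interpolation of the pooled flowering rates over sorted day
lengths, with no fitted breakpoints or dose-response parameters. The CDL
is the first downward crossing of $F_{max}/2$ at or after the day length
attaining $F_{max}$: a short-day response declines with day length, so the
biologically meaningful boundary is the descending limb even when
non-monotone noise creates other crossings. If the curve never falls to
half-maximum the result is right-censored (`CDL > max DL`); zero flowering
everywhere leaves the CDL undefined, flagged. Pooling counts across
replicates (weighting wells by frond number) is the default; averaging the
replicate percentages is available because published protocols do not say
which was used. Censored CDLs are excluded from correlations and
regressions rather than imputed at a boundary.

## Association statistics

* **Pearson tests** delegate to `stats::cor.test` (the standard tool for
  this analysis); tests verify the closed form
  $p = 2\,P\!\left(T_{n-2} \le -|r|\sqrt{(n-2)/(1-r^2)}\right)$ to 1e-12.
* **Deming regression** uses the closed-form slope
  $\big(s_{yy}-\delta s_{xx} + \sqrt{(s_{yy}-\delta s_{xx})^2 +
  4\delta s_{xy}^2}\big)/(2 s_{xy})$ with $\delta = 1$ (orthogonal
  regression) by default: period and CDL are both measured in hours with
  comparable error, and no better variance ratio is available. $s_{xy}=0$
  is handled explicitly (horizontal fit, or a flagged vertical
  degeneracy).
* **Wilcoxon rank-sum**: exact p by full enumeration of rank splits when
  the combined sample is ≤ 12 with no ties, otherwise the normal
  approximation with tie-corrected variance and continuity correction.
  The switch point and the ties rule are fixed by the package so results
  do not depend on another implementation's heuristics; identical samples
  return p = 1.
* **Holm adjustment** wraps `stats::p.adjust`; **compact letters** use the
  insert-and-absorb algorithm, deterministic given group order, and
  satisfy the invariant *share a letter ⇔ adjusted p ≥ α* (checked on 500
  random matrices in the acceptance suite). Note the Holm step-down map is
  not idempotent — re-adjusting adjusted p values inflates them — so no
  such property is asserted.

Analyses involving the period or peak-time phenotypes drop excluded
strains; analyses involving CDL drop censored strains.

## The gate model

The external-coincidence reading of short-day flowering is reduced to two
parameters: a gate opening $d_0$ hours after lights-off in a 24-h strain,
shifting by $k$ hours per hour of $(\tau - 24)$. Induction requires the
gate to fall in darkness, so flowering occurs when night length
$24 - DL$ exceeds the delay, giving $CDL(\tau) = 24 - (d_0 + k(\tau-24))$,
strictly decreasing in $\tau$ for $k > 0$. The gate is anchored to dusk
because dark-induction experiments in this system track induction in hours
after light-off; dawn-anchored variants are out of scope. Fitting is the
exact reparameterization of the Deming line ($k = -b$,
$d_0 = 24 - a - 24b$), so `predicted_cdl()` reproduces the line, the round
trip is exact to machine precision, and a positive period–CDL slope
surfaces as a flagged $k < 0$ rather than being hidden. This is a toy
phenotype model — it says nothing about which genes implement the gate.

## Problem sizes and what the checks show

The acceptance-level checks run at the scale the design questions need
while staying desk-sized: period recovery over 100 traces with
$\tau \sim U(20, 28)$ h at amplitude-to-noise 5 and growth 0.005 h⁻¹; RAE
discrimination over 100 clean and 100 arrhythmic traces; CDL recovery over
200 assays with 40 fronds per day length and true CDL $\sim U(11, 14.5)$ h;
Deming-vs-OLS slope recovery over 200 panels of 72 strains. For the
association check, measurement error must hit *both* axes for the
errors-in-variables comparison to be meaningful, so equal-SD (0.3 h)
Gaussian error is added to the true periods and CDLs of a noiseless-line
panel — a cheap stand-in for "the period is itself estimated from traces
with error". All randomness derives from a single seed argument.

## Known limitations

* The fitted cosine model has constant amplitude; damping is handled only
  implicitly (the moving-SD normalization flattens the envelope), and no
  damping rate is estimated.
* No missing-data handling: traces must be complete uniform grids, and the
  readers reject rather than impute.
* The RAE uses a linearized interval, not the joint confidence region of
  classic FFT-NLLS; borderline strains can classify differently.
* No Lomb–Scargle, wavelet or MESA alternatives; no autocorrelated or
  signal-dependent noise in the generator; no logistic dose-response
  alternative to the piecewise-linear CDL rule.
* The gate model is linear in $(\tau - 24)$ by construction; it cannot
  express saturation of the gate shift.
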