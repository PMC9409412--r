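---
title: "Age-stage two-sex life tables: model, calibration and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-stage two-sex life tables: model, calibration and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agestagelt)
```

## The demographic model

The unit of observation is one insect followed from the day its egg was
laid (age 0) to its death, with a daily census. Age is discrete in whole
days, and an individual's stage on day $x$ is the stage occupied at the
end-of-day census: with stage durations (3, 5, 4) it is an egg on days
0–2, a larva on days 3–7, a pupa on days 8–11 and an adult from day 12.
It is counted alive at every age strictly before its death day. These two
conventions fix every downstream number, so they are stated here once and
asserted by the census tests.

From $n_0$ such records the age-stage survival matrix is
$S_{xj}$ = fraction of the $n_0$ newborns alive and in stage $j$ at age
$x$, and the fecundity matrix $f_{xj}$ = eggs laid at age $x$ per living
female adult (nonzero only in the female-adult column). Then

$$l_x = \sum_j S_{xj}, \qquad
  m_x = \frac{\sum_j S_{xj} f_{xj}}{\sum_j S_{xj}}, \qquad
  R_0 = \sum_{x \ge 0} l_x m_x,$$

and the intrinsic rate of increase $r$ solves the discrete Euler–Lotka
equation

$$\sum_{x \ge 0} e^{-r(x+1)}\, l_x m_x = 1,$$

with $\lambda = e^r$ and $T = \ln(R_0)/r$. The $(x+1)$ exponent is the
age-from-zero convention of the two-sex life-table literature; many
classical texts index ages from 1 and write $e^{-rx}$. Under the daily
census, $l_x m_x$ equals (eggs laid by the cohort at age $x$)/$n_0$, so
$R_0$ = total eggs/$n_0$ exactly — an algebraic identity the test suite
asserts on every cohort, and what makes the bootstrap fast (a resample's
population parameters depend only on its per-age egg schedule).

### Numerical choices

- **Root finding.** The Euler–Lotka left side is strictly decreasing in
  $r$, so the root is unique. It is found by Newton iteration started at
  the Lotka approximation $r_0 = \ln(R_0)/\bar T$ (with $\bar T$ the mean
  age of the $l_x m_x$ distribution), safeguarded by bisection inside the
  bracket $[-1, 2]\,\mathrm{d}^{-1}$ — generous for insect demography —
  which is extended downward automatically when $R_0$ is far below 1.
  Convergence is declared at residual $< 10^{-10}$; failure to converge is
  an error, never a silent result. A 1e-6-step grid search serves as the
  independent oracle in the tests, and a Leslie-matrix power iteration
  independently confirms $\lambda$ to $10^{-4}$.
- **Degenerate edges.** $m_x$ is defined as 0 at ages with no survivors
  (no survivors contribute nothing, avoiding 0/0). At $R_0 = 1$ the ratio
  $\ln(R_0)/r$ is 0/0 and $T$ is defined by continuity as
  $\sum (x+1) l_x m_x / R_0$. $R_0 = 0$ leaves $r$, $\lambda$, $T$
  undefined (an error for point estimates; recorded as missing inside the
  bootstrap).
- **Death-day edge.** The record model would admit an individual dying
  with zero days censused (death day 0), but then
  $\sum_j S_{0j} = 1$ — everyone censused alive at age 0 — could not
  hold, so validation requires death day $\ge 1$ and the generator draws
  the partial time in the death stage from $\{1, \dots, D\}$.
- **Rounding.** Full precision is kept internally; printed displays round
  to 2 decimals, matching how such tables are reported.

## Bootstrap inference

The resampling unit is the whole individual: $n_0$ records drawn with
replacement, every parameter recomputed per resample, SE = SD of the
resample estimates. Resampling individuals (not days or eggs) preserves
the within-individual correlation between development speed, longevity
and fecundity; the source study does not state its unit, and this is the
standard choice. Resamples with no reproducing female leave $r, \lambda,
T$ undefined; the default policy records them as missing and reports the
count (`n_degenerate`) rather than redrawing, because redrawing biases
small cohorts toward reproducing resamples. A `redraw` policy is
available. In exhaustive mode (all $n_0^{n_0}$ ordered resamples, used by
the $n=3$ enumeration oracle test) the SE is the population SD, since the
enumeration is complete.

The paired test compares two cohorts through the per-index differences
$d_b = \hat\theta_b(A) - \hat\theta_b(B)$ and reports the two-sided
tail fraction $p = 2\min(\#\{d_b<0\}, \#\{d_b>0\})/B$, floored at $1/B$;
if every $d_b$ is exactly zero the test reports $p = 1$. The source study
names a "paired bootstrap test" without defining it; this tail-fraction
form is the natural two-sided reading. Both cohorts' index matrices are
drawn from identically seeded streams, so comparing a cohort against
itself under one seed yields all-zero differences (and $p = 1$) by
construction; across distinct cohorts the estimates remain independent
because the cohorts are disjoint data with exchangeable record order. The
default $B = 2000$ keeps desk runtime in seconds while the Monte-Carlo
error of a 5%-level decision is $\approx \sqrt{0.05\cdot 0.95/2000} <
0.005$; the paper-scale $B = 100{,}000$ is available via `B`.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` draws, per newborn: integer stage durations
(shifted Poisson, $1 + \mathrm{Pois}(\mu - 1)$, the default — integer
days $\ge 1$ with small dispersion; a discretized gamma and a
deterministic family are selectable); per-stage survival; sex at a 0.5
ratio (individuals dying before pupation are recorded unsexed, as in the
underlying protocol where sexing happens at pupation); sex-specific adult
longevity; and for females a negative-binomial lifetime fecundity laid
over an early-peaked schedule.

The presets transcribe the published strain means (stage durations, adult
longevity by sex, APOP, oviposition days, fecundity). Survivorship was
not published, so overall preadult survival is implied by the identity
$R_0 = \text{fecundity} \times P(\text{newborn becomes a reproducing
female})$: $P = R_0/\text{fecundity}$ (0.358 for the wild type), divided
by the 0.5 sex ratio and split evenly across the three preadult stages.
This makes the generator's expected $R_0$ match the published $R_0$ by
construction — that is calibration, not evidence.

Two features of real data are *not* emulated, and green tests establish
nothing about them:

- **The daily fecundity shape.** The published daily curves are figures,
  not tables. Total eggs are allocated across a female's oviposition days
  (first day = emergence + APOP, count $1+\mathrm{Pois}$, truncated at
  death) with geometric-decay weights ($q = 0.65$), an early-peaked
  stand-in. Consequently the simulated reproductive schedule is somewhat
  earlier than the real one, and the simulated $r$ (≈0.30–0.33 for the
  wild-type preset) sits slightly above the published 0.29 with $T$
  (≈12–13 d) slightly below the published 13.68 d: $r$ weights early
  reproduction exponentially. The recovery tests therefore check the
  preset-*implied* quantities ($R_0$, durations, APOP, fecundity), not
  $r$ or $T$ against their printed values.
- **Dispersion choices.** The negative-binomial size 10 reproduces the
  published fecundity SEs at $n_0 = 120$ (CV ≈ 0.33); the shifted-Poisson
  duration SDs are larger than the (very small) printed duration SEs
  imply. Both are fixed, documented choices, not fits.

The study gave no rule for escaped/lost individuals; the record model has
no censored state, matching the published protocol where every individual
is followed to death.

## The smaller assays

- **Supercooling point.** The 1 Hz trace is median-smoothed (window 3);
  the exotherm is the first point of a declining run from which the
  smoothed trace starts rising and gains ≥ 0.5 °C within 3 s. The SCP is
  the raw minimum in the window up to that reversal; the freezing point
  is the raw plateau maximum before decline resumes. The 0.5 °C / 3 s
  default cannot miss real exotherms (several °C at the published SCP→FP
  gaps) and ignores 0.05 °C sensor noise; no detection parameters were
  published. A curve with no reversal returns `detected = FALSE`, not an
  error. The published cooling rate "0.5 °C/s" is implausibly fast for
  this assay (likely °C/min); it is kept as the printed default with
  `rate_unit = "per_min"` accepted.
- **Trehalose.** Glucose after minus before trehalase digestion; one
  trehalose (342.30 g/mol) yields two glucose (180.16 g/mol), so mass =
  0.95 × Δ. Negative Δ (assay noise) clamps to 0 with a warning.
- **qPCR.** Livak 2^−ΔCt / 2^−ΔΔCt with technical replicates averaged as
  arithmetic mean Ct and the ΔΔCt baseline = control-group mean ΔCt (the
  standard usage; the source is silent on both). The two-group comparison
  gates on Shapiro–Wilk at α = 0.05 per group: both normal → Welch
  *t*-test (no equal-variance assumption at n = 3–5), otherwise
  Mann–Whitney. Groups on which Shapiro–Wilk cannot run (zero variance)
  are treated as non-normal. Multi-group post-hoc comparisons are out of
  scope.
- **Proportions.** Wilson score intervals via `prop.test(correct =
  FALSE)`.

## Known limitations

- The calibration chain makes preset-recovery tests partly circular by
  design (the generator is built from the same table it is checked
  against); the non-circular content is that the *pipeline* recovers what
  the generator encodes.
- The paired test's behaviour under strong parameter skew (small $R_0$,
  few females) leans on the degenerate-resample policy; with very small
  cohorts prefer reporting `n_degenerate` alongside any p-value.
- Printed-table consistency checks (the acceptance targets) validate the
  arithmetic identities linking $r$, $R_0$, $T$, $\lambda$ — they cannot
  validate the original data reduction, whose raw records are
  unpublished.
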