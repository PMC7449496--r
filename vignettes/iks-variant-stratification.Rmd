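---
title: "Risk stratification of IKs channel variants in populations of model cardiomyocytes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk stratification of IKs channel variants in populations of model cardiomyocytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iksvar)
```

## The problem

Loss-of-function variants in KCNQ1, the pore-forming subunit of the slow
delayed-rectifier potassium channel (I~Ks~), reduce cardiac repolarization
reserve and cause type-1 long-QT syndrome; gain-of-function variants
associate with short-QT phenotypes. Automated patch clamp can characterize a
variant's channel-level effect as three summary numbers — the shift in
half-activation voltage (ΔV~1/2~), the change in activation slope (Δk), and
the current density relative to wild type — but the cellular consequence of
the same channel defect varies enormously between cells, because it depends
on the balance of all the other currents. `iksvar` turns the three summary
numbers into a cell-level risk estimate by (1) fitting a Hodgkin–Huxley I~Ks~
model to each variant, (2) propagating the fitted variant through a
phenotypically variable population of spontaneously beating iPSC-CM-like
model cells under a physiological noise current, and (3) classifying the
variant from the fraction of cells whose proarrhythmia markers degrade past
a threshold.

## The I~Ks~ model and the variant fit

The current is `IKs = G_Ks * x^2 * (Vm - E_K)` with one activation gate

* `x_inf(V) = 1 / (1 + x6 * exp(V * x7))`, with `x6 = x3/x1`,
  `x7 = 1/x4 - 1/x2 < 0`,
* `tau_x(V) = 1 / (x1 * exp(V/x2) + x3 * exp(V/x4)) + x5`,

so the steady-state activation is a Boltzmann curve with
`V_1/2 = -log(x6)/x7` and slope `k = -1/x7`. A variant's (ΔV~1/2~, Δk)
targets pin down only `(x6, x7)`; the remaining two degrees of freedom in
`(x1..x4)` are chosen to minimize the squared deviation of `tau_x` from the
wild-type time constant over a −80..+60 mV grid (`x5` stays at the WT value:
summary data carry no information about mutant time constants). The
conductance is then rescaled so the simulated voltage-clamp density ratio
equals the measured fraction — exactly, because the end-of-step current is
linear in `G_Ks` at fixed kinetics. Variants with unmeasurably small current
are complete blocks (`G_Ks = 0`, WT kinetics). When both activation deltas
are zero the optimum is the WT kinetics themselves, and the fit returns them
bitwise — this keeps the identity variant an exact no-op downstream.

```{r fit-example}
wt <- wt_iks_parameters()
fit <- fit_mutant(wt, mutant_spec("shift15", delta_v_half = 14.8,
                                  delta_slope = 0, rel_density = 0.5))
fit
```

The default voltage-clamp protocol (hold −80 mV, 2 s steps −80..+60 mV in
10 mV increments, measurement at step end, reference +40 mV, E~K~ −88 mV) is
a conventional activation protocol; "current density" here always means
end-of-step current at the reference step, a dialect switch recorded on the
protocol object. Two-second steps do not fully reach steady state for a
current this slow — exactly as in real recordings — so fitted activation
parameters are re-extracted from the model's closed-form summary (verified
against a bisection oracle to < 0.01 mV), while density is always measured
by simulation.

## The wild-type parameterization

The paper-level inputs are *relative* changes, so the package ships a
documented WT configuration rather than claiming measured values:
V~1/2~ = −12 mV, k = 14 mV, `tau_x`(0 mV) ≈ 600 ms with much faster
deactivation at diastolic voltages, G~Ks~ = 0.2 nS/pF. The positive-shifted
midpoint keeps diastolic I~Ks~ negligible in a spontaneously depolarizing
cell (a structural requirement: an I~Ks~ that is active at the maximum
diastolic potential stabilizes the quiescent fixed point and can silence the
pacemaker) while plateau activation remains strong.

## The cell model

The host cell is a compact 13-state iPSC-CM formulation written for this
package: I~Na~ (m³hj), I~CaL~ (d·f·fCa, ohmic driving force), I~Kr~, I~Ks~
(the model above), I~K1~, I~f~ (half Na⁺/half K⁺), Na/K pump, Na/Ca
exchanger, background Na/Ca and a sarcolemmal Ca pump, with Na~i~, Ca~i~
(buffered) and K~i~ tracked. It beats spontaneously (cycle length ≈ 1 s),
with AP amplitude > 70 mV and MDP ≈ −69 mV, and I~Ks~ carries a meaningful
share of repolarization: complete block prolongs APD~90~ by roughly 60% in
the baseline cell, and a 1.5× gain shortens it and slightly depolarizes the
MDP (the gain-of-function MDP rise emerges from the long-run K⁺ balance).
The right-hand side is compiled C integrated by `deSolve::lsoda`
(rtol 1e-6, atol 1e-8; the maximum step is capped at the noise update
interval during noise runs). What this model is *not*: it has no
sarcoplasmic-reticulum calcium cycling, no transient-outward current, no
KCNE1-stoichiometry or PKA dependence of I~Ks~, and no claim to reproduce
any published population's exact percentages. Passing tests therefore show
that the *framework* behaves correctly on a physiologically plausible host,
not that a specific published cell model was reproduced.

Steady state is declared when every tracked ion's per-beat minimum changes
by < 1% between the first and last beat of a 50 s window (total simulated
time capped at 600 s); quiescent cells converge trivially and are flagged.
Solver-tolerance halving moves the reference APD~90~ by < 0.005 ms and
output-grid halving by < 0.1 ms (the upstroke instant is refined by a
parabolic fit of dV/dt, which is what makes APD insensitive to the output
grid).

## Populations and the noise protocol

Phenotypic variability is modeled as independent log-normal (median 1,
sdlog σ) scale factors on the conductances of I~Na~, I~CaL~, I~Kr~, I~K1~
and I~f~ and on the gate time constants of the gated four (I~K1~ is
instantaneous here, so it contributes no kinetic factor); I~Ks~ itself is
never varied — variants enter deterministically through the fitted
parameters. σ defaults to 0.4, chosen once so the APD~90~ coefficient of
variation across included cells lands in the 20–40% range typical of
iPSC-CM recordings; this sampling law is the package's stand-in for the
original experimentally-calibrated population, which cannot be regenerated
from summary data. Inclusion requires spontaneous beating, amplitude
> 70 mV, MDP < −40 mV, no alternans (alternating-sign APD~90~ differences
with mean |Δ| > 5 ms over the last 6 beats) and no EADs (any > 1 mV
re-depolarization between the downward +10 mV crossing and the MDP); both
detector thresholds are configurable.

Each included cell is then simulated for 40 beats with additive Gaussian
white noise of amplitude 0.045 pA/pF, discretized as a piecewise-constant
current over 1 ms intervals (the amplitude is interpreted as the per-sample
standard deviation). The per-cell noise seed is `base_seed + cell_id` and is
reused for the WT run and every mutant run of that cell — a paired design
under which the identity variant yields *exactly* zero metric deltas, which
the tests assert bitwise. Mutant cells are re-run to steady state from the
same initial state the WT screen used (the other half of that exactness),
and cells whose mutant AP amplitude falls to ≤ 70 mV, that stop beating, or
that newly develop EADs/alternans/failed beats under noise are flagged as
repolarization failures, excluded from severity metrics, and reported as a
percentage of the WT included population.

## The severity statistic

Per cell, three paired percent changes are computed: mean AP triangulation
(APD~90~ − APD~30~, averaged over the noise run), beat-to-beat variability
of APD~90~ (mean of the 39 absolute successive differences), and APD~90~
from the noise-free 20 s run. A criterion flags when its change *strictly
exceeds* the threshold (default 4%); in GOF (short-QT) mode the APD
criterion flips to a shortening of at least the threshold while the other
two keep their direction. A variant's severity is the percentage of included
cells flagging all three criteria; it is classified pathogenic strictly
above 4.6%, benign strictly below 0.25%, and unclassified between — strict
inequalities at all three boundaries, matching the "surpassed / more than /
less than" wording the cut-offs were defined with, and configurable because
the original inclusivity is unstated. Cells with a zero WT quantity (a
degenerate triangulation, say) have that criterion undefined rather than
flagged, so division-by-zero can never inflate severity. Severity fractions
are monotone non-increasing in the threshold by construction; the threshold
sweep reports mutant rank stability across 4/8/10%.

## Adult translation

A fitted variant is translated to a paced adult ventricular regime by
multiplying G~Ks~ by 3.5 and keeping all kinetics verbatim. The adult host
is the same compact formulation re-parameterized (no funny current, strong
I~K1~, resting potential ≈ −85 mV), paced with a −40 pA/pF, 1 ms stimulus
delivered as a per-beat current injection so the adaptive solver never steps
over the pulse. APD is referenced to stimulus onset, measured on the last of
a configurable number of conditioning beats (default 500; the examples and
tests use 20–50, where pacing is already quasi-stationary for this model).
Because the adult base model is pluggable and its published coefficients are
not inputs here, everything asserted about it is property-based: block
prolongs APD~90~ at every cycle length, APD~90~ does not lengthen at faster
pacing, loss-of-function severity ordering is preserved, gain of function
shortens. A bisection calibrator (`calibrate_scale`) recovers the
conductance multiplier matching any reachable APD~90~ target within 1 ms.

## Problem sizes and reproducibility

The shipped tests run the full pipeline at sizes a laptop handles in
minutes: a 20-cell population (seed 42) for the population-level properties,
a 5-step conductance ladder (1.0/0.8/0.5/0.2/0), 100 random specs for
fit-recovery, 10⁶ draws for the noise amplitude, and 10–50 conditioning
beats for the paced adult checks. Every random draw is seeded; populations,
noise realizations and fixture tables are bit-reproducible from their seeds,
and the run manifest written by `run_pipeline()` records the configuration,
seeds and per-stage outputs needed to re-run any stage.

## Known limitations

* The host cell is a compact model: no SR calcium release, no I~to~, a
  simplified ohmic I~CaL~. Absolute severity fractions (e.g. the 21% the
  shipped 20-cell block experiment produces) are host- and σ-dependent and
  are not comparable to any published population's percentages; orderings
  and invariances are the tested claims.
* Repolarization failures are rare in the log-normal population because the
  compact pacemaker is robust; the gain-of-function failure/rescue mechanism
  is therefore demonstrated on a shipped fragile reference cell
  (`depolarized_cell_parameters()`) rather than as a population statistic.
* Heterozygous (WT/variant) data need no new code — they are just different
  table rows — but no heteromultimer model is implied: the fit treats
  whatever summary it is given as the cell's homogeneous I~Ks~.
* The fitting uses only the three summary statistics; it does not constrain
  deactivation kinetics or match raw current traces.
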