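---
title: "Quantifying inactivation-delay heterogeneity in Kv channel cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying inactivation-delay heterogeneity in Kv channel cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kvinact)
```

## The scientific problem

Fast N-type ("ball-and-chain") inactivation of Kv3.4 and related
voltage-gated K+ channels shows striking cell-to-cell variability when
the channel is expressed heterologously: under one and the same
depolarizing stimulus, some cells inactivate within a few milliseconds
while others stay conductive for hundreds. The working model is that
the channel population of each cell is a mixture of *glycoforms* —
aglycosylated, high-mannose and complex-glycosylated channels — and
that each glycoform carries its own inactivation delay. Blocking
N-glycosylation (e.g. with tunicamycin) leaves only the fast
aglycoform, and the heterogeneity collapses.

`kvinact` implements the quantification pipeline for this phenomenon:
two-stage patch-clamp quality control, extraction of a per-cell
*inactivation width*, and a boxplot *whisker-span* statistic that
summarises the heterogeneity of a cohort, together with a forward
simulator that generates voltage-clamp cohorts with known ground truth
so every stage can be validated by parameter recovery.

## The measurement

Each cell is stimulated with an 18-step protocol (−90 mV to +80 mV in
10 mV increments, 500 ms steps, 10 kHz sampling). Analysis uses the
+80 mV sweep only:

1. restrict the sweep to the analysis window (70–599 ms,
   sweep-relative);
2. normalize by the peak current `I_max` inside that window;
3. measure the **inactivation width**: the temporal width of the
   normalized trace at 70 % of its peak. `t_up` is the first upward
   crossing of the 0.7 level (linearly interpolated between samples),
   `t_down` the last downward crossing; the width is their difference.

A trace still above the level at the window end is *right-censored*:
the width is recorded as `window_end − t_up` and flagged, and censored
values are included by default (a sensitivity switch excludes them).
The first-up/last-down convention makes the width robust to brief
noise excursions through the level; an optional zero-phase Butterworth
low-pass (disabled by default) can be applied before crossing
detection for noisier data.

Cohort heterogeneity is summarised by Tukey boxplot statistics of the
widths: an outlier is a value more than 1.5 × IQR beyond the box, and
the whiskers run to the furthest observations *within* that fence. The
**whisker span** (upper minus lower whisker) is the scalar
heterogeneity metric; conditions are compared by span ratios against a
reference condition. No hypothesis tests are attached: the statistic
of interest is the spread itself, not a mean difference.

### Quartile convention

Published whisker ranges rarely state the quartile algorithm that
produced them, and the choice matters at small n. `boxplot_stats()`
therefore pins a convention — linear interpolation of the empirical
quantile function (the common "type 7" rule) — and exposes a
Tukey-hinge alternative (`quartile_method = "hinges"`) for sensitivity
checks. A consequence worth knowing: with interpolated quartiles and a
grossly skewed small sample, *every* point above the box can be an
outlier, in which case the upper whisker legitimately ends below Q3.

## Two-stage quality control

Stage 1 screens recording metadata with strict inequalities:
|V-offset| < 45 mV, seal resistance > 200 MΩ, series resistance
< 15 MΩ, slow capacitance < 35 pF. Values exactly at a threshold fail,
matching the printed operators; missing metadata fail the criterion
with a "missing" note rather than raising an error. V-offset is
compared as an absolute magnitude since offsets can be negative — the
conventional threshold is printed unsigned, so this is a documented
reading, not a given.

Stage 2, evaluated only for stage-1 passers, keeps cells whose peak
current at +80 mV lies between 0.5 and 45 nA. "Between" is read
inclusively at both bounds.

Manual review of unstable recordings is modelled as an explicit
exclusion list of cell ids: the package does not attempt to reproduce
human judgement with a heuristic (an optional sweep-drift screen was
considered and rejected as unspecifiable; the exclusion list keeps the
manual step explicit and auditable).

## The forward model

Simulated whole-cell current at step potential $V$ is

$$I(t) \;=\; \sum_i w_i \, g_{\max}\, m_i(t)^{p} h_i(t)\,(V - E_K)
\;+\; g_{\text{leak}}(V - E_{\text{leak}}) \;+\; \varepsilon(t),$$

summed over glycoform components $i$ with weights $w_i$.

**Activation** is Hodgkin–Huxley: $m$ relaxes exponentially with time
constant $\tau_m$ (default 2 ms) towards
$m_\infty(V) = 1/(1+e^{-(V-v_{1/2})/s})$, with $v_{1/2} = 0$ mV,
$s = 9$ mV and exponent $p = 4$ — placing the conductance midpoint in
the high-voltage range characteristic of Kv3 channels.

**Inactivation** is the package's mechanistic choice: the N-terminal
ball is modelled as docking through a chain of $k$ sequential steps,
each at rate $\lambda$ (ms⁻¹), so the docking latency is
Erlang($k,\lambda$)-distributed with mean $k/\lambda$ and CV
$1/\sqrt{k}$. The macroscopic survival gate is the Erlang upper tail
$$h(t) = f_{ss} + (1-f_{ss})\,e^{-\lambda t}
 \sum_{j=0}^{k-1}\frac{(\lambda t)^j}{j!},$$
which produces the sigmoidal, *delayed* inactivation onset that a
single-exponential gate cannot: a one-step gate ($k=1$) starts
decaying immediately, while larger $k$ at fixed mean delay gives a
flat shoulder followed by a sharp fall. This is the minimal mechanism
for the delayed-onset waveforms the analysis targets. The chain
engages at step onset (docking requires the depolarization-driven open
state), is treated as fully recovered between sweeps, and $\lambda$ is
voltage-independent by default. The non-inactivating fraction
$f_{ss}$ defaults to 0.

**Numerics.** At constant voltage both gates have exact solutions, and
the default path uses them: exponential update for $m$, gamma
survival function for $h$. A `deSolve::lsoda` route integrating the
$(m, s_0, \dots, s_{k-1})$ system exists as a cross-check and as the
extension point for time-varying rates; closed form and ODE agree to
better than $10^{-6}$ sup-norm (this is asserted in the test suite).
Output grids coarser than $\tau_m/2$ or $1/2\lambda$ trigger a
configurable warning.

**Reversal potential.** $E_K$ defaults to the Nernst potential of the
standard automated-patch solutions (4 mM external, 110 mM internal
K+): $\approx -85.15$ mV at 25 °C. Temperature is recorded as metadata
only; no Q10 scaling is applied.

## What the generator emulates — and what it does not

The built-in presets define the study conditions:

* **control** — every cell draws Dirichlet(1,1,1) weights over three
  glycoform components: aglyco ($k=1,\ \lambda=0.12$; mean delay
  ≈ 8 ms), high-mannose ($k=4,\ \lambda=0.05$; ≈ 80 ms) and complex
  ($k=12,\ \lambda=0.04$; ≈ 300 ms), spanning fast-to-slow delays of
  tens to hundreds of ms;
* **deglyco** — a single aglyco component (glycosylation blocked);
* **delay_sd** — one component per cell with mean delay drawn from a
  truncated normal (default mean 150 ms) of chosen SD: the controlled
  knob for heterogeneity-recovery experiments, deliberately without
  extra kinetic jitter so that SD = 0 is exactly homogeneous.

Per-cell total conductance is log-normal (median 40 nS, sdlog 0.35),
which at +80 mV and $E_K \approx -85$ mV keeps peak currents a few nA,
inside the 0.5–45 nA acceptance window. Control and deglyco rates get
a mild per-cell log-normal jitter (sdlog 0.1) so even a single-glycoform
cohort has biological, not merely instrumental, variability. Baseline
noise is Gaussian (5 pA SD), leak is ohmic (0.5 nS to 0 mV); both are
arbitrary but configurable defaults. QC metadata are drawn uniformly
from ranges safely inside the thresholds, and a configurable fraction
of cells is planted to violate one randomly chosen criterion —
ground truth for filter testing.

Determinism contract: cell $i$ (global index) draws parameters and QC
metadata under `param_seed + i` and noise under `seed + i`, so a fixed
`param_seed` holds the cohort's ground truth constant while noise
varies.

Known divergences from real recordings, hence limits of what passing
tests show:

* no capacitive transients, series-resistance voltage error, or
  leak-subtraction artefacts — real sweeps carry all three;
* deterministic macroscopic currents: no single-channel stochasticity;
* inactivation recovery between sweeps is assumed complete;
* because $h$ already decays during the brief activation rise, cells
  with faster inactivation have slightly attenuated peaks. This
  couples width and $I_{\max}$ positively in simulated control
  cohorts, so the width–amplitude correlation diagnostic is *not* a
  null in the simulator, whereas in real data it probes whether
  heterogeneity is an expression-level artefact;
* glycoform kinetic parameters are effective values chosen to
  reproduce the fast/intermediate/slow phenomenology, not measured
  constants.

## Sweep layout and windows

A sweep is pre-step holding (100 ms) + step (500 ms) + optional
post-step, sampled at 10 kHz from $t = 0$. The published analysis
window 70–599 ms is sweep-relative; the 100 ms pre-step default
reconciles the 500 ms pulse with a window ending at 599 ms (the window
then covers the last 30 ms of holding plus the full step). The
durations of the holding segments are a package choice — the
convention sources print the pulse length and the window, not the
segment layout.

## On-disk format

A cohort is `manifest.tsv` plus one long-format `traces/<cell_id>.tsv`
per cell (`step_potential_mV`, `time_ms`, `current_pA`) and a
`ground_truth.tsv` sidecar for simulated data. Currents are written at
6 significant digits and times at 10; the simulator canonicalises its
continuous outputs (currents, QC metadata) to 6 significant digits at
generation, so write→read round-trips are bit-exact and re-writing a
read cohort is byte-identical. Units are fixed package-wide (ms, mV,
nS, pA) with conversion (nA → pA) at the I/O boundary only. Adapters
for vendor amplifier formats are out of scope for the core.

## Problem sizes used in validation

The test suite and the acceptance script validate at desk scale,
chosen as the smallest sizes at which the cohort statistics are
stable: cohorts of 29/19 cells (the condition-comparison run), 30
cells per delay-SD level for heterogeneity recovery, 30 cells with 5
planted failures for QC, exhaustive ≤ 8-point subsets of a 12-value
pool for the boxplot oracle, and $k \le 20$ for the gating oracle.
All simulation-based checks fix their seeds; every number quoted in
the README is produced by the code shown there.
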