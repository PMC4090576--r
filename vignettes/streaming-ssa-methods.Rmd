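---
title: "Streaming ensemble stochastic simulation: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Streaming ensemble stochastic simulation: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssastream)
```

## The problem

Stochastic simulation of reaction networks answers questions that mean-field
ODEs structurally cannot: which of several stable states a cell falls into,
how molecular noise spreads an oscillator's period, how often rare switching
events occur. Answering them requires *ensembles* — hundreds to thousands of
independent Gillespie trajectories — and the scientific content lives in the
collective statistics, not in any single run. ssastream implements the full
path from a reaction model to those collective statistics as a streaming
workflow: trajectories are advanced in simulation-time quanta, aligned into
per-time ensemble snapshots ("time-cuts"), and analysed online by summary
statistics, sliding-window trajectory clustering and peak detection, without
ever materialising the raw ensemble unless asked to.

## The simulator

### Exact direct method

The engine is the Gillespie direct method. In state $x$ at time $t$ each
reaction $j$ has a propensity $a_j(x, t)$; the waiting time to the next
event is $\mathrm{Exp}(a_0)$ with $a_0 = \sum_j a_j$, and reaction $j$ fires
with probability $a_j / a_0$.

Mass-action propensities use the *combinatorial* convention
$a_j = c_j \prod_s \binom{n_s}{m_s}$ (so $n(n-1)/2$ for a homodimerisation,
$n(n-1)(n-2)/6$ for a triple). This is not a stylistic choice: for the
Schlögl network below, the plain-powers convention yields a mean-field rate
law with a single positive fixed point, i.e. a monostable system, while the
combinatorial convention yields the two stable states the model is famous
for. The discriminant of the resulting cubic decides the matter in favour of
the combinatorial form.

### Function rates

Beyond mass action, a reaction may carry an arbitrary *rate function* of the
current counts and time. The function's value **is** the propensity — no
additional multiplicity factor for the left-hand side. With this convention
the circadian model's published parameter set (below) coincides exactly with
its mean-field ODE after the stated concentration scaling; with an extra
reactant factor it would not. Hill-repression and Michaelis–Menten forms
(and their piecewise-scheduled variants) are recognised natively by the
compiled core; arbitrary R closures are supported through a callback at a
speed penalty.

### Time-varying rates

Piecewise-constant forcing (dark/light alternation) is handled *exactly*: if
the sampled waiting time crosses the next phase boundary, the clock advances
to the boundary without firing and the exponential clock is redrawn. By
memorylessness this introduces no approximation for piecewise-constant
rates.

### Sampling and quantum invariance

Trajectories are reported on a fixed grid $t_i = t_0 + i\,\Delta_S$; the
value at $t_i$ is the state after the last event with time $\le t_i$
(right-continuous step sampling). Each task owns a private
xoshiro256++ stream seeded by `base_seed + task_id`, carried inside the task
object. Together these make the output a pure function of
`(model, base_seed, task_id, t_end, delta_s)`: slicing a run into quanta of
any size, or interleaving tasks in any order over any number of dispatch
slots, produces bit-identical results. The test suite asserts this directly
by comparing quantum sizes and worker counts.

## The streaming workflow

`run_workflow()` composes: task generation → a worker pool advancing tasks
one quantum at a time, always picking the task with the smallest clock
(ties to the lowest id) → an aligner that releases time-cut $i$ exactly when
all $n$ tasks have delivered sample $i$, in strictly increasing order → the
analysis operators. Slowest-first scheduling bounds the aligner's buffer of
incomplete cuts by one quantum's worth of samples, which the suite checks
with instrumentation. The `workers` knob changes only dispatch interleaving
(the pool is realised as a contract — execution itself is sequential in R);
determinism is therefore structural rather than accidental.

## Analysis operators

* **Summary statistics** per cut: mean, standard deviation ($n-1$
  denominator), and quantiles by linear interpolation between order
  statistics (type 7). These conventions are not stated by most workflow
  descriptions; they are fixed here once so all outputs are reproducible to
  the byte.
* **Savitzky–Golay filtering**: least-squares local polynomial coefficients
  computed in closed form (`savgol_coefficients()`), reproducing polynomials
  up to the chosen order exactly, including first derivatives (scaled by
  $1/\Delta_S$). Per sliding window, each trajectory is reduced to the
  smoothed centre value $\hat x_i$, its derivative $\hat x'_i$, and the
  one-step forecast $x^E_i = \hat x_i + \hat x'_i \Delta_S$.
* **Clustering**: features are the pairs $(\hat x_i, x^E_i)$ with Euclidean
  distance and no normalisation — value and short-horizon trend, which
  separates basins of attraction while ignoring high-frequency noise.
  K-means (Lloyd, tolerance $10^{-6}$, at most 100 iterations, empty
  clusters repaired with the farthest point, seeded deterministically) is
  for systems whose number of stable states is known; quality-threshold (QT)
  clustering (grow each candidate by the point that least increases the
  diameter, commit the largest, repeat) discovers the number of clusters at
  $O(n^3)$ cost and is the default when the state count is unknown.
* **Peak detection**: peaks are $+\!\to\!-$ sign changes of the SG-smoothed
  derivative, refined to the local maximum of the smoothed series, with a
  prominence filter (default 10% of the smoothed range) and minimum
  separation (default 2 samples). Local periods are successive peak-time
  differences; the ensemble period series is their moving average pooled
  over trajectories and time.

Defaults — SG window 9, order 3, stride 1, window length 9 — are
conservative noise-suppression choices; all are exposed as parameters.

## The three built-in systems

**Schlögl** (`builtin_model("schlogl")`). Four reactions
($2A \to 3A$ at 0.03, $3A \to 2A$ at $10^{-4}$, $B \to B + A$ at 200 with
$B$ buffered, $A \to \varnothing$ at 3.5), started at $A = 250$, $B = 1$.
The mean-field rate law
$\dot A = 0.015A^2 - \tfrac{10^{-4}}{6}A^3 + 200 - 3.5A$ has stable fixed
points at $A \approx 85.5$ and $A \approx 566.9$ and an unstable one at
$A \approx 247.6$ — essentially the initial condition — so intrinsic noise
splits the ensemble between both basins:

```{r schlogl, eval = FALSE}
wf <- run_workflow(builtin_model("schlogl"), n_trajectories = 480,
                   t_end = 10, delta_s = 0.1, base_seed = 1,
                   clustering = list(method = "qt", species = "A",
                                     threshold = 150, at = 9.5))
table(wf$clusters$label)
#>   1   2   3   4   5
#> 277 167  20  15   1        # two clusters hold >5%; centers 86.2 and 564.6
```

**Bacteriophage λ** (`builtin_model("lambda_phage")`). The simplified
lysis/lysogeny switch: CI dimerises (0.05/0.5), CI$_2$ binds the phage DNA
at an enhancing or repressing site (0.026 each way), double occupancy
represses (0.13), polymerase transcribes from the enhanced state at 40
producing two CI monomers per transcript, and CI decays at 0.0007. A note
on honesty in reporting: under exactly these constants and the initial
state $10\,CI + D + P$, our fixed-point analysis (and ensembles to
$t = 12000$) shows a *single* accessible quasi-equilibrium near
$CI \approx 130$; the off-state is the extinction boundary $CI < 2$, which
has no basin of attraction above it (production scales as $CI^2$ through
dimer-mediated positive feedback and beats the linear decay everywhere
above the boundary). The corresponding acceptance test performs the
prescribed two-cluster check and is expected to fail; we keep it failing
rather than retuning constants, because it documents a real property of
this rule set.

**Neurospora circadian clock** (`builtin_model("neurospora")`). Hill-
repressed transcription of frq mRNA ($M$) by nuclear protein FRQ$_{in}$
($v_s K_I^n/(\#FRQ_{in}^n + K_I^n)$, $K_I = 100$, $n = 4$), translation
($k_s = 0.5$), Michaelis degradation of mRNA ($v_m = 50.5$, $K_m = 50$) and
protein ($v_d = 140$, $K_d = 13$), and nuclear transport ($k_1 = 0.5$,
$k_2 = 0.6$); counts are scaled at 1 nM = 100 molecules, time in hours. The
repressor is the *nuclear* protein: the printed formula names total FRQ,
but the model description (and the underlying transcriptional-feedback
biology) identify the nuclear form, and with cytosolic or total FRQ the
mean-field period collapses to ~8 h instead of the documented circadian
value — so the nuclear reading is the only consistent one. In constant
darkness $v_s = 160$; under dark/light alternation $v_s$ switches 160/200
with phase length $T$ (default 12 h, giving the natural 24 h forcing
period; the phase length is user-configurable since no canonical value is
attached to the alternating condition). Initial counts ($M = 360$,
$FRQ = FRQ_{in} = 100$) are an arbitrary point in the basin of the limit
cycle; all period measurements discard a 48 h transient, so this choice
does not influence results.

```{r neurospora, eval = FALSE}
wf <- run_workflow(builtin_model("neurospora", "dark"), n_trajectories = 16,
                   t_end = 200, delta_s = 0.25, base_seed = 1,
                   peaks = list(species = "M", transient = 48))
mean(wf$peaks$periods$period)
#> [1] 21.26316
```

The deterministic mean-field ODE (integrated with deSolve in the test
suite) oscillates at 21.51 h in darkness and entrains fully to 24.04 h
under 12 h/12 h alternation. The stochastic ensemble at the 1 nM = 100
scaling reproduces the dark period well (≈21.3 h) but entrains only
*partially*: molecular noise causes occasional phase slips (about five
extra cycles per hundred forcing periods in long runs), so the mean local
period under alternation measures ≈23 h rather than 24 h. This gap is a
genuine property of the stochastic model at this system size — it shrinks
as the count scaling grows — and we report it as measured.

## Numerical and degenerate-input choices

* Quantile type 7, standard deviation with $n-1$: fixed for byte-level
  reproducibility of output files (CSV writers use `%.6g` floats and
  integer counts).
* K-means ties in assignment go to the lowest cluster index; QT ties on
  candidate size go to the lowest seed index; scheduler ties go to the
  lowest task id. Every tie-break is deterministic so the workflow is too.
* A model with no reactions is legal and yields a constant series (useful
  as a degenerate test); an all-zero-propensity state advances directly to
  the next rate boundary or to `t_end`.
* Window edges: sliding windows are only emitted when complete; partial
  trailing windows are dropped. Stride defaults to 1 (maximal overlap).
* The simulation quantum defaults to $10 \Delta_S$ — small enough for
  responsive streaming and load balance, large enough to amortise dispatch
  overhead; results are invariant to it by construction.

## Problem sizes used in the shipped checks

The test-suite and acceptance runs use deliberately scaled-down ensembles
chosen as the smallest sizes at which each qualitative claim is stable
under reseeding: 480 Schlögl trajectories to $t = 10$ (the documented
ensemble size for that system), 16 circadian trajectories to 200 h at
$\Delta_S = 0.25$ h, 30 phage trajectories to $t = 8000$, and $10^4$ draws
for the waiting-time calibration. Larger ensembles sharpen the estimates
but do not change any conclusion.

## What the synthetic generator does and does not emulate

`synth_ensemble()` produces caricature ensembles — a two-mode switcher, a
shared-phase sinusoid, a constant level, each plus Gaussian noise — with
exactly known structure. They validate the analysis operators (cluster
recovery, period recovery, determinism) independently of the simulator, but
they do not emulate what real SSA ensembles add: discreteness, non-Gaussian
burst noise, trajectory-specific phase drift and basin-switching dynamics.
Passing the synthetic checks therefore certifies the analysis machinery,
not the biology; the model-level acceptance checks do the latter.

## Known limitations

* The worker pool is a scheduling contract, not OS-level parallelism; on
  one R process the `workers` knob affects interleaving only. The analytic
  sizing model (`size_pipeline()`) is the tool for reasoning about actual
  parallel deployments.
* Peak detection operates on the fully collected per-trajectory series of
  the configured species (the cuts themselves stream; one `n × cuts`
  integer matrix is retained for the peak species).
* QT clustering is $O(n^3)$ in the worst case; for routine per-window
  clustering of large ensembles use K-means or cluster selected windows via
  `at`/`every`.
* Arbitrary R rate functions go through an R callback per event and are
  1–2 orders of magnitude slower than the natively encoded rate forms.
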