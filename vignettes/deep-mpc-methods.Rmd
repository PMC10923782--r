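---
title: "Deep model predictive control of single-cell gene expression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep model predictive control of single-cell gene expression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`optoMPC` is an in-silico platform for receding-horizon control of
optogenetic gene expression in single bacterial cells. The experimental
setting it emulates is a mother machine: a mother cell trapped at the dead
end of a narrow microfluidic chamber, imaged every 5 minutes, and actuated
with a binary light input (red represses, green activates a light-switched
two-component system driving a fluorescent reporter). At every timepoint a
controller must pick the next red/green bit, per cell, so that each cell's
fluorescence tracks its own target trajectory.

The package implements the full loop in software:

* a stochastic **cell simulator** standing in for the microscope and the
  cells (the "plant"),
* a deep **forecaster** — a recurrent (LSTM) encoder and perceptron
  decoder — that predicts a cell's fluorescence response to any candidate
  light sequence from its own past,
* **baseline predictors** (linear regression; a 2-state ODE with a hybrid
  Kalman filter),
* a **binary particle swarm** strategy search with an exhaustive oracle,
* **objective builders** (constants, sinewaves with positional phase
  delays, movie-pixel trajectories), and
* the **evaluation toolkit** (across-time and across-cell RMSE, growth
  rates with artifact filters, growing-fraction partitioning, smoothing).

Everything is driven by seeds; every experiment is reproducible from its
configuration alone.

# The simulated plant

No plant equations are available for live cells, so the simulator is the
package's own minimal model, chosen to reproduce the qualitative
phenomenology that makes this control problem interesting: minutes-scale
activation kinetics, dilution-dominated decay, strong cell-to-cell
variability, aging, and rare catastrophic events.

Per cell, with light input $u \in \{0, 1\}$:

$$\dot a = k_{on} u (1 - a) - k_{off} (1 - u)\, a$$
$$\dot g = \beta_i \beta_0 \left[\ell + (1 - \ell) a\right]
  \max(0, 1 + \eta) - (\gamma_m + \mu_i(t))\, g$$
$$\dot \eta = -\eta / \tau_\eta + \sigma_\eta \sqrt{2/\tau_\eta}\, \xi(t)$$

where $a$ is promoter activation, $g$ the fluorophore concentration
(a.u.), $\eta$ a clipped Ornstein–Uhlenbeck production-noise multiplier,
and $\mu_i(t) = \mu_{cell,i}\, \mu_0 e^{-k_{age} t}$ the per-cell,
age-decaying specific growth rate. Cell area grows exponentially at
$\mu_i$; crossing the division area halves the area and leaves the
concentration $g$ untouched; dilution of $g$ enters only through the
$\mu_i g$ term, which is how stable fluorescent proteins actually decay.
Per-cell multipliers $\beta_{cell}$ and $\mu_{cell}$ are log-normal with
median 1 and CV `cv_cell`, giving rate heterogeneity between cells. Death
(probability `p_death` per 5-min step) freezes growth and lets $g$ decay
at $\gamma_m$; filamentation (`p_fil`) suppresses division for an
exponentially distributed duration (mean 2 h). Integration uses an
exponential (exact-linear-part) scheme on substeps of `dt_sim` = 0.5 min
inside each 5-min measurement interval: the light input and the noise
multiplier are frozen within a substep, under which $a$, $g$ and the
area are linear ODEs advanced by their closed-form solutions, and $\eta$
uses the exact Ornstein–Uhlenbeck Gaussian transition. A naive
Euler–Maruyama step at this substep size would carry a few-percent bias
on the minutes-scale activation transients; the exponential scheme makes
the deterministic part step-size independent (up to division-event
timing), which tests verify against a 10× finer substep to better than
$10^{-3}$ relative, alongside closed-form steady states and decays with
noise off.

Default rates were fixed once, before any downstream evaluation, to place
the plant in the regime the control experiments need: `k_on` = 0.2/min
and `k_off` = 0.1/min give an activation time scale of ~5–10 min;
`beta0` = 63 a.u./min, `leak` = 0.06, `gamma_m` = 0.002/min and
`mu0` = 1.4/h put the constant-green steady state near 2500 a.u. and the
constant-red state near 150 a.u., spanning the 800–1800 a.u. objective
band with a >15-fold dynamic range; `cv_cell` = 0.2 is a typical
cell-to-cell rate CV for bacterial gene expression; `p_death` = 5e-4 and
`p_fil` = 1e-3 per step produce a few hard-to-predict events per hundred
cells per day.

The emitted record per cell is the 8-feature timeseries used everywhere
downstream: applied stimulation bit, mother fluorescence, mother area (in
pixels of 0.0044 µm²), chamber mean and standard deviation of
fluorescence, cell count, neighbor-chamber stimulation, and image
sharpness. Chamber statistics are surrogates derived from the mother
(daughters are not tracked individually), with 5% relative noise;
sharpness is 1 plus small noise with rare spike artifacts emulating
glitches of the imaging pipeline.

What the simulator does *not* emulate — and hence what passing tests do
not show about real data: image segmentation artifacts beyond simple
glitches and floors, bursty transcription at the master-equation level
(the OU multiplier is a continuous surrogate), drug responses, chamber
crowding effects, or any coupling between neighboring cells. A forecaster
that excels here can still fail on a real microscope; the package's claims
are about the method, not about E. coli.

# The forecaster

The forecaster is split into an encoder and a decoder. The encoder — two
stacked LSTM layers of 64 and 16 units — consumes the normalized
8-feature past of a cell (any length; training uses 36–144 points, i.e.
3–12 h) and a linear projection produces a 32-dimensional latent vector, a
fixed-size summary of the cell's entire past. The decoder concatenates
this latent vector with the H future stimulation bits (H = 12, 24, 36 or
48 for 1–4 h horizons) and maps them through 5 rectified-linear layers of
32 units and a linear head of H units to the predicted normalized
fluorescence trajectory. The split matters operationally: the expensive
recurrent encoder runs once per cell per control step, while the cheap
decoder is evaluated 1000 times per cell against candidate strategies.

Training draws random (cell, timepoint) samples, minimizes mean squared
error with Adam at learning rate $10^{-3}$, and is fully determined by
one seed. The network is implemented from first principles in compiled
code (RcppArmadillo) with backpropagation through time; the analytic
gradients are verified against finite differences in the test suite.
Design choices the architecture leaves open were resolved as follows:
Glorot-uniform initialization with forget-gate biases at 1; each batch
shares one past length P (drawn uniformly in [36, 144]), which sidesteps
padding/masking ambiguity inside the recurrent layers; no early stopping
(fixed epoch budget); all training in normalized space, de-normalizing
only at reporting boundaries.

Normalization maps each channel to [0, 1] using per-channel 0.1/99.9
percentiles of the training corpus (robust to glitch spikes; binary
channels are pinned to (0, 1); a degenerate constant channel maps to 0).
The fitted bounds are persisted with the model so control-time
normalization uses the same parameters.

Training schedules are named presets. The full-scale reference is 500
epochs × 200 steps × batch 100; the package's scaled-down study profile —
used by the test suite and the acceptance script so a full study fits in
minutes of CPU — is 50 epochs × 50 steps × batch 64 on a corpus of 500
simulated cells of 192 timepoints (16 h), with 150 further cells held out.
The companion study models (horizon variants and feature-ablation
retrainings) use an equal-budget lighter schedule of 12 epochs × 40 steps
× batch 64, so that within-study comparisons are at matched training
effort.

## Baselines

The **linear forecaster** is a single linear map (equivalently a one-layer
perceptron) from the flattened most recent 3 h window of all 8 channels
plus the H future bits to the H outputs, fit by least squares. The 3 h
window is the minimum past every sample is guaranteed to have, so every
sample is usable without padding.

The **ODE baseline** is the minimal light-switched 2-state linear model,
$\dot a = k_a u - k_d a$, $\dot p = \beta a - \gamma p$, with
population-level parameters fit by least squares to open-loop
trajectories (multi-start Nelder–Mead in log-parameter space) and a
hybrid continuous-discrete Kalman filter carrying a per-cell belief over
$(a, p)$: exact linear-system propagation (matrix exponentials, Van Loan
noise discretization) between measurements and a discrete update
observing $p$. Process-noise intensities are chosen on a small grid by
multi-step prediction error on held-in samples; the measurement variance
comes from the half-variance of lag-1 residual differences.

A caveat the package reports honestly: in this simulator the linear model
sees the area channel, which cleanly encodes each cell's growth — and
hence dilution — rate, while the 2-state ODE belief cannot use it. Under
the default study conditions the measured ranking is deep < linear <
ODE+Kalman, with the deep model best but the ODE baseline behind the
linear one. This inversion of the two baselines relative to live-cell
experiments is a property of the clean in-silico plant, not of the
implementations, and the corresponding test documents it rather than
hiding it.

# Strategy search and the control loop

With a bit every 5 minutes, an L-hour horizon spans $2^{12L}$ strategies
(4096 at 1 h, ~$3\times10^{14}$ at 4 h) — exhaustive search is
intractable beyond short horizons. The controller instead runs a
canonical binary particle swarm: 40 particles iterated 25 times, so
exactly 1000 decoder evaluations per cell and step. Velocities follow
$v \leftarrow w v + c_1 r_1 (pbest - x) + c_2 r_2 (gbest - x)$ with
$w = 0.7$, $c_1 = c_2 = 1.5$, clamped to $\pm 4$, and squashed through a
logistic to give per-bit sampling probabilities; positions initialize
i.i.d. Bernoulli(0.5), velocities at 0. These are the standard
Kennedy–Eberhart binary-PSO constants; all are exposed in
`controlConfig()`. Ties in the exhaustive oracle break towards the lowest
integer encoding so results are deterministic. On 12-bit problems the
swarm matches the exhaustive optimum in ≥95/100 seeded runs and stays
within one bit otherwise; on trained-decoder cost surfaces its median gap
to the global optimum is below 1%.

One control step: encode the cell's past once (capped at the 144 most
recent points, the longest past seen in training), run the swarm with the
decoder as a batched cost oracle scoring candidates by across-time RMSE
against the objective segment, apply the first bit of the winning
strategy, and re-plan 5 minutes later. Strategy selection is
unconstrained. An objective segment shorter than the horizon (near the
end of an experiment) is padded by holding its last value. If the
predictor fails, the previous applied bit is repeated and flagged. Each
cell has its own swarm (no shared state), planned cold each step; decoder
calls are batched across cells and particles for speed. Campaigns start
with 3 h of all-red equilibration before control onset, and all
randomness derives from one root seed.

# Evaluation

Two error metrics, used everywhere: for cell $n$ across time,
$\mathrm{RMSE}_{time}(n) = \sqrt{\tfrac1T \sum_t (f_t^{(n)} -
g_t^{(n)})^2}$, and across cells at time $t$, $\mathrm{RMSE}_{cells}(t) =
\sqrt{\tfrac1N \sum_n (f_t^{(n)} - g_t^{(n)})^2}$. Missing values are
excluded pairwise, never imputed.

Growth rate is computed from area as $(\mathrm{area}(t+1) -
\mathrm{area}(t)) / \mathrm{area}(t)$ per 5-min interval. Positions where
area < 0.44 µm² or fluorescence < 100 a.u. (image-artifact signatures)
are set missing first, and growth below −2.4 h⁻¹ is set missing to remove
division timepoints — a division halves the area, i.e. −0.5 per interval
= −6 h⁻¹, safely below the threshold. The per-interval value is divided
by 1/12 h so the printed thresholds are dimensionally consistent. Filters
mark positions missing but never drop them, keeping series aligned. Cells
at or above 0.3 h⁻¹ (smoothed) count as "growing"; the growing fraction
is taken among cells with valid data. Two smoothing filters are provided:
a sliding 1 h (13-point) median, and a Savitzky–Golay filter of length 15
and order 2 implemented as a windowed least-squares quadratic so missing
values are simply excluded per window (edges shrink the window); it
reproduces quadratic series exactly in the interior, and matches the
reference implementation where no values are missing. Whether the
growing/dying thresholds should apply to raw or smoothed growth is
ambiguous in the source material; the package applies them to smoothed
growth, matching how the partition is displayed.

Error can be conditioned on covariates: objective value (linear bins),
objective time-derivative (signed log-scale bins, since derivatives span
positive and negative decades), or growth percentile (bins 1–100).

# Study conditions and problem sizes

The package's standard in-silico study, exercised end to end by
`scripts/acceptance.R` and the acceptance test suite, uses: 500 training
+ 150 validation cells × 192 timepoints of open-loop data under
binarized-random-walk stimulation; the scaled training profile above for
the reference 2 h model; 1500 held-out forecast samples for error
distributions; 50-cell, 19 h closed-loop campaigns (3 h equilibration,
then control to a sinewave objective of offset 1200 a.u., amplitude
400 a.u., period 6 h) compared against matched random-stimulation
campaigns; and horizon variants at 1–4 h. These sizes are the package's
choice of a desk-scale study; the architecture and all procedures are
unchanged at larger scale.

# Known limitations

* The plant is a surrogate; quantitative error levels are not comparable
  to live-cell numbers, only orderings and qualitative behaviors are.
* Horizon parity is a full-scale phenomenon. At full training scale the
  per-timepoint forecast error at matched lead times is the same whatever
  the output horizon, and control performance is nearly identical for 1–4 h
  controllers. At the package's desk-scale budgets the longer-horizon
  models remain underfit even at near lead times (measured: RMSE_cells at
  t = 1 of ~0.064 for the 4 h model vs ~0.03 for the 1 h model at equal
  budget, improving only to ~0.043 at double budget), so closed-loop
  medians still spread ~2× across horizons. The corresponding acceptance
  check is expected to fail at this scale and is retained unweakened; the
  swarm search itself is verified near-optimal at 48 bits, isolating
  training scale as the cause.
* The all-features-masked ablation model still receives future
  stimulation bits (the architecture requires them), so it converges to
  the stimulation-conditioned population predictor — substantially better
  than a literal unconditional mean. Ablation claims are therefore stated
  as orderings and information-content checks.
* Prediction uncertainty is not modeled; the controller optimizes point
  predictions.
* On-the-fly retraining during control is out of scope.
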