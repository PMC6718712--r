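---
title: "A firing-rate model of cerebellar OKR gain adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A firing-rate model of cerebellar OKR gain adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(okrsim)
```

## The circuit and its assumptions

`okrsim` models the cerebellar microcircuit that adapts the gain of the
horizontal optokinetic reflex (OKR). The model is a population firing-rate
description: each cell class is a single scalar rate, synaptic populations
are single scalar weights, and transmission delays are ignored. These are
deliberate simplifications — the aim is the steady-state evolution of
learning over hours and days, not spike timing.

Mossy fibers (rate `f_MF`, normalised to 1) excite the granular layer and
the deep nuclei (DN). Golgi-cell feedforward and feedback inhibition
attenuate granular transmission; solving the granular balance gives the
input-layer transmission coefficient

$$\alpha = \frac{1 - W_{PF\text{-}GO}}{1 + W_{MF\text{-}GO}} \in [0, 1],$$

so the parallel-fiber rate is $f_{PF} = \alpha f_{MF}$
(`transmission_coefficient()` derives $\alpha$ from the Golgi weights;
scenarios normally set it directly — 1 in the normal condition, 0.3 under
granular-layer attenuation). Purkinje cells (PC) integrate parallel-fiber
excitation and molecular-layer-interneuron (MLI) inhibition,
$f_{PC} = (W_{PF\text{-}PC} - W_{PF\text{-}MLI}) f_{PF}$, and inhibit the
nuclei: $f_{DN} = W_{MF\text{-}DN} f_{MF} - f_{PC}$. Climbing fibers carry
the error between desired and actual output, $e = d\,f_{MF} - f_{DN}$.

Three weights are plastic. The reduced rate equations (after substituting
the spontaneous LTD/LTP balance, which removes the background-activity
symbols from the evaluated model) are

$$\dot W_{PF\text{-}PC} = -\lambda_1 \beta_1 r\, \alpha f_{MF}\, e
  - \lambda_3 (W_{PF\text{-}PC} - W^0_{PF\text{-}PC}),$$
$$\dot W_{PF\text{-}MLI} = +\lambda_1 \beta_3\, \alpha f_{MF}\, e
  - \lambda_3 (W_{PF\text{-}MLI} - W^0_{PF\text{-}MLI}),$$
$$\dot W_{MF\text{-}DN} = \lambda_4 \gamma\,
  (W_{PF\text{-}MLI} - W_{PF\text{-}PC} + W^0_{PF\text{-}PC} -
   W^0_{PF\text{-}MLI})\, \alpha f_{MF}^2
  + \lambda_6 (W^0_{MF\text{-}DN} - W_{MF\text{-}DN}),$$

with $\lambda_i = 1/\tau_i$. By construction the configured baseline is an
exact fixed point; `check_baseline_balance()` verifies this and catches
corrupted configurations. The behavioural read-out is

$$G_{OKR} = g_{OKR0}\,(W_{MF\text{-}DN} - \alpha W_{PF\text{-}PC}
  + \alpha W_{PF\text{-}MLI}), \qquad g_{OKR0} = 0.3,$$

which equals 0.3 at the normal baseline and approaches
$g_{OKR0}\, d$ under sustained training.

## Protocol, phase gating and the early-session ramp

The standard paradigm is five daily sessions of 1 h training (desired gain
`d_train`) followed by 23 h off task. The error-driven cortical terms act
only during training: in darkness there is no structured retinal-slip
signal, so the cortical weights relax toward baseline with $\tau_3$ while
the nuclear equation — which depends on the cortical state, not on the
error — continues to transfer the decaying cortical trace into
$W_{MF\text{-}DN}$. Most of the transfer therefore happens during the late,
slowly-recovering phase of cortical depression, which is exactly what makes
the model consolidate.

Long-term OKR gain is known to rise along an S-shaped curve over the first
days. We reproduce this with a per-session ramp factor
$r(s) = \min(1, s/3)$ multiplying the error-driven term of the PF-PC rule
for sessions 1–3. Two choices here were genuinely open:

* **Functional form.** Only the qualitative S-shape is constrained; we use
  the piecewise-linear $\min(1, s/3)$, constant within a session, and expose
  the whole schedule (`ramp` argument of `okr_protocol()`) for
  sensitivity analysis.
* **Scope.** The ramp could also multiply the PF-MLI error term. We apply
  it to the PF-PC rule only (configurable via `ramp_on_mli`): the
  interneuron pathway learns through climbing-fiber spillover rather than
  the direct teaching signal, and leaving it unramped reproduces the
  lesion-scenario weight excursions noticeably better than the symmetric
  choice.

## Parameters: values, units and why

| parameter | default | meaning |
|---|---|---|
| `f_mf` | 1 | normalised MF population rate |
| `alpha` | 1 | granular transmission (0.3 in the attenuation lesion) |
| `beta1`, `beta3` | 1, 0.5 | strength of train-induced PF-PC LTD / PF-MLI LTP |
| `gamma` | 1 | corticonuclear transfer strength |
| `w0_*` | 1, 1, 1 | baseline weights (lesions shift them) |
| `tau1` | 0.33 h | error-driven induction time constant (~20 min) |
| `tau3` | 60 h (2.5 d) | cortical recovery in darkness |
| `tau4 = tau6` | 132 h (5.5 d) | nuclear transfer and decay |
| `d0`, `g_okr0` | 1, 0.3 | baseline desired gain; read-out scale |

The time-constant scales deserve a note, because they are the single most
consequential numerical choice in the package. Electrophysiology constrains
cortical LTD induction to minutes (hence $\tau_1 = 0.33$ h) but recovery
from training to *more than a day*; and the defining behavioural phenomena
— the day-by-day staircase of pre-training gains, and the saving of
accumulated gain when the corticonuclear tract is cut after four sessions —
require the cortical trace to survive a 23 h rest substantially and the
nuclear trace to decay over many days. Hour-scale recovery constants
(e.g. $\tau_3 = 2.5$ h, $\tau_4 = 5.5$ h) would erase both traces every
night: the model then shows no consolidation at all, and lesion-induced
weight excursions overshoot several-fold. We therefore place induction on
the sub-hour scale and recovery/consolidation on the day scale
($\tau_3 = 2.5$ d, $\tau_4 = \tau_6 = 5.5$ d; the rate-alteration scenario
analogously uses $\tau_1 = 2$ h, $\tau_3 = 1.5$ d). All values are stored
in hours.

`d_train` is the one free behavioural parameter. It is calibrated once, by
a single scalar root search (`calibrate_d_train()`), so that the normal
five-session run ends session-5 training at gain 0.56 (the canonical
wild-type outcome, starting from 0.30); the result, ≈ 1.87, is then frozen
for every scenario:

```{r calibrate}
d <- calibrate_d_train()
d
pr <- okr_protocol(d_train = d)
sim <- simulate_okr("normal", pr)
session_metrics(sim)[, 1:6]
```

## Numerical choices

* **Integrator.** Adaptive explicit Runge-Kutta (Dormand-Prince 4(5), via
  `deSolve`), `rtol = 1e-6`, `atol = 1e-8`. The system is non-stiff at
  these time constants (fastest rate ≈ 4.5/h, phases of 1–23 h).
  Trajectories are recorded every 0.01 h during training and 0.1 h during
  rest, plus exact phase boundaries; the test suite cross-checks the
  adaptive solution against an independently written fixed-step Euler
  integrator to better than $10^{-4}$ on all weights over a full run.
* **Weight floor.** Weights are clamped at zero (a weight is a synaptic
  efficacy): the derivative field is projected at the floor, so a clamped
  weight also stops expressing error-driven induction, and recorded samples
  are non-negative. The spontaneous-LTP-blockade scenario starts with the
  PF-PC weight at the floor and stays there, as intended.
* **Events.** Parameter overrides (the corticonuclear cut
  $\gamma \to 0$ after session-4 training) are applied at phase boundaries
  only; each fires once. State is continuous everywhere else.
* **Tie-breaks / degenerate inputs.** `tau3 = Inf` encodes a vanishing
  recovery rate exactly (no division by a large number); percentage weight
  changes are undefined (error, or `NA` in tables) when a scenario's
  baseline weight is zero.

## Lesion scenarios and measurement conventions

`list_scenarios()` registers twelve configurations. Two conventions matter
when comparing lesions:

* **Weight changes** (`weight_change_pct()`): the *net* change is the
  weight at the end of a session relative to the scenario's own baseline
  $W^0$ — the state a slice experiment would measure after that day. The
  *training* component is the within-session (post-train minus pre-train)
  change over $W^0$ — the day's error-driven induction. Both are referenced
  to the scenario's own baseline, because lesions shift baselines.
* **Gain increments**: short-term is post-train minus pre-train of the same
  session; long-term is post-train minus the very first pre-train.

```{r lesions}
weight_change_pct(simulate_okr("pf_pc_train_ltd_complete", pr), 5, "PF-MLI")
weight_change_pct(simulate_okr("pf_pc_spont_ltd_block", pr), 5, "PF-PC")
```

The first number is the compensatory interneuron-pathway potentiation when
train-induced PF-PC LTD is completely blocked; the second the deepened
train-induced depression when the spontaneous LTD that normally balances
the baseline is removed. With PF-MLI plasticity frozen, the training
component of PF-PC depression exceeds normal by ≈ 5 percentage points —
the cortex over-induces LTD to compensate the silent interneuron pathway:

```{r overinduction}
frozen <- simulate_okr("pf_mli_no_plasticity", pr)
abs(weight_change_pct(frozen, 5, "PF-PC", "training")) -
  abs(weight_change_pct(sim, 5, "PF-PC", "training"))
```

One structural caveat the package states plainly: in this reduced model any
compensatory PF-MLI potentiation feeds the gain read-out directly
($G_{OKR}$ is linear in $W_{PF\text{-}MLI}$), so complete train-LTD
blockade still yields a substantial long-term gain increment here, and the
complete climbing-fiber blockade — whose baseline is an exact fixed point —
yields exactly zero increment, never a negative one. Claims that these
lesions leave the gain at, or below, its initial level are not reproducible
from the balanced equations; the acceptance suite records these checks as
failing rather than papering over them.

## The fixture generator

`make_fixtures()` writes pinned reference gain curves (normal,
complete climbing-fiber blockade, corticonuclear cut) as CSV, optionally
with seeded Gaussian observation noise on the gain samples
(`noise_sd`, default 0). These emulate the *shape* of behavioural
recordings — deterministic model output plus measurement noise — and serve
as regression baselines and as synthetic stand-ins for experimental
overlays. They do not emulate inter-animal variability, session-order
effects, or any feature of real eye-movement data beyond the mean curve;
tests passing against them show numerical stability of the simulator, not
agreement with any animal.

## Problem sizes

All computations are small by construction: a five-session run integrates
three ODEs over 120 h (≈ 1700 recorded samples, well under 0.1 s); the
full twelve-scenario comparison completes in about a second; the
Euler-oracle cross-check (step 10⁻⁴ h during training) is the most
expensive test at a few seconds. The acceptance script, including the
calibration search, runs in seconds.

## Known limitations

* Population-scalar description: no spiking, no spike-timing-dependent
  plasticity, no transmission delays, no intrinsic plasticity beyond
  baseline shifts.
* The desired gain `d` is an abstract cerebellar-space quantity; the
  mapping from physical stimulus parameters to `d` is not modelled, and
  `d_train` is calibrated, not measured.
* The first-days ramp is phenomenological; its form is a package choice.
* Deterministic by design: run-to-run variability must be added externally
  (the fixture generator's observation noise is the only stochastic
  element, and it never feeds back into the dynamics).
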