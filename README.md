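# okrsim

Firing-rate simulation of cerebellar motor learning, using adaptation of the
horizontal optokinetic reflex (OKR) as the behavioural read-out.

## The problem and who this is for

Motor learning in the cerebellum is distributed over several plasticity
sites: long-term depression/potentiation at parallel fiber–Purkinje cell
(PF–PC) synapses, plasticity of opposite sign at parallel fiber–molecular
layer interneuron (PF–MLI) synapses, and a slow Hebbian-like consolidation
at mossy fiber–deep nuclei (MF–DN) synapses. Experimental lesion studies of
these sites disagree about which one is necessary for learning. `okrsim`
implements a population firing-rate model of this circuit in which the
efficacy of signal transfer between layers is captured by transmission
coefficients, and lets you run systematic in-silico lesion experiments:
block one pathway, re-run the training protocol, and quantify what happens
to short-term adaptation, long-term memory, and its consolidation. It is
aimed at computational and systems neuroscientists who want a small,
fully-tested, deterministic model of OKR gain adaptation.

## The model

Population rates: mossy-fiber input `f_MF` reaches the granular layer,
whose output is `f_PF = α f_MF` with transmission coefficient
`α = (1 − W_PF-GO)/(1 + W_MF-GO)` set by Golgi-cell inhibition. The
Purkinje output is `f_PC = (W_PF-PC − W_PF-MLI) f_PF` and the deep-nuclei
output `f_DN = W_MF-DN f_MF − f_PC`. Climbing fibers carry the learning
error `e = d f_MF − f_DN` for desired gain `d`.

Three coupled plasticity equations (λᵢ = 1/τᵢ):

```
Ẇ_PF-PC  = −λ₁ β₁ r α f_MF e − λ₃ (W_PF-PC − W⁰_PF-PC)
Ẇ_PF-MLI = +λ₁ β₃   α f_MF e − λ₃ (W_PF-MLI − W⁰_PF-MLI)
Ẇ_MF-DN  =  λ₄ γ (W_PF-MLI − W_PF-PC + W⁰_PF-PC − W⁰_PF-MLI) α f_MF²
            + λ₆ (W⁰_MF-DN − W_MF-DN)
```

The error-driven cortical terms act during the daily 1 h training phase
(`r` is an S-shaped ramp over the first three sessions); during the 23 h
off-task phase the cortical weights relax toward baseline while the slow
nuclear equation keeps transferring the cortical memory trace — this is the
consolidation channel. The behavioural read-out is
`G_OKR = g_OKR0 (W_MF-DN − α W_PF-PC + α W_PF-MLI)`, 0.3 before training.

Twelve named lesion scenarios (granular-layer attenuation, partial/complete
blockade of train-induced PF–PC LTD, blockade of spontaneous LTD or LTP,
learning/recovery-rate alteration, partial/complete climbing-fiber blockade,
two PF–MLI lesions, and a corticonuclear cut mid-protocol) are registered
with their parameter and baseline overrides.

## Worked example

```r
library(okrsim)

d <- calibrate_d_train()        # one scalar search on the normal anchor
#> d = 1.869949
pr  <- okr_protocol(n_sessions = 5, d_train = d)
sim <- simulate_okr("normal", pr)
summary(sim)
```

```
Scenario: normal
Per-session adaptation metrics:
 session gain_pre gain_post gain_end_rest stm_increment ltm_increment pct_pf_pc
       1   0.3000    0.5394        0.4948       0.23942        0.2394    -21.65
       2   0.4948    0.5584        0.5112       0.06359        0.2584    -22.94
       3   0.5112    0.5600        0.5131       0.04879        0.2600    -23.00
       4   0.5131    0.5600        0.5136       0.04690        0.2600    -22.75
       5   0.5136    0.5600        0.5139       0.04642        0.2600    -22.51
 pct_pf_mli pct_mf_dn
      32.47     10.84
      28.09     19.37
      22.64     25.39
      18.84     29.60
      16.26     32.53
Final synaptic weights:
 w_pf_pc w_pf_mli  w_mf_dn
  0.7749   1.1626   1.3253
```

The gain climbs from 0.30 to 0.56 over five daily sessions
(`ltm_increment` 0.26); within each day it rises during the training hour
(`stm_increment`), decays during rest, but never falls back to the previous
morning's level. The PF–PC weight is depressed by training and recovers
slowly, while the MF–DN weight accumulates steadily (`pct_mf_dn` rising
10.8 → 32.5 %): the memory formed in the cortex is transferred to the
nuclei. A lesion run differs only in the scenario name:

```r
weight_change_pct(simulate_okr("pf_pc_train_ltd_complete", pr), 5, "PF-MLI")
#> 37.29  (% compensatory PF-MLI potentiation when train-induced LTD is blocked)
compare_scenarios(c("normal", "cf_block_complete", "mf_gc_attenuation"), pr)
```

A command-line interface wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "okrsim.R", package = "okrsim"))')" \
  simulate --scenario normal --out run.csv
```

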