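---
title: "An agent-based model of narcissistic self-esteem regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of narcissistic self-esteem regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sernarc)
```

## The model

`sernarc` simulates agents whose central state variable is *self-esteem*
(`se`, unitless in [0, 1]). Each timestep, an agent's self-esteem updates as

$$SE_{t+1} = SE_t + RSP_t(A_t, S_t) - L_t(SE_t)$$

where $L_t = \lambda \, SE_t$ is a relative leakage (a fixed proportion
$\lambda$ drains away each step, which is what makes regulation necessary at
all) and $RSP_t$ is the social response to the agent's regulation behaviour
$A_t$, modulated by the agent's status $S_t$ (operationalised as the
self-esteem gap to the interaction partner).

The reference signal of the control loop is the *need for admiration*
(`nfa`), the agent's expectancy value for its own self-esteem. The signed
shortfall

$$\mathit{Diff}_t = \mathit{NfA}_t - SE_t$$

is the need for regulation: when it exceeds a behaviour-initiation threshold,
behaviour fires. Behaviours are hierarchical:

* **intra-individual regulation** (threshold `ts_intra`, always the lowest):
  a deterministic, relatively small boost the agent can grant itself;
* **admiration** (`ts_admi`): agentic self-presentation, which mostly earns
  positive responses;
* **rivalry** (`ts_riva`): antagonistic derogation of others, which mostly
  earns negative responses.

Inter-individual behaviours require a partner in the Moore neighbourhood of
the agent's grid cell (same cell or the 8 surrounding cells; one of several
candidates is chosen uniformly). Among the inter-individual thresholds the
need exceeds, the *highest* threshold wins (the more drastic strategy is
reserved for the greater need); with no partner, the agent falls back to
intra-individual regulation. The partner's probability of responding
positively is the behaviour's base probability plus `status_coupling` times
the self-esteem gap, clamped to [0, 1]; the response magnitude is fixed per
behaviour and only the *actor's* self-esteem changes.

### Tolerance development

The need for admiration habituates toward current self-esteem. We implement
this as an exponential moving average with *asymmetric* rates:

$$\mathit{NfA}_{t+1} = \mathit{NfA}_t + \alpha_{\uparrow/\downarrow}
  \,(SE_t - \mathit{NfA}_t),$$

with a fast upward rate ($\alpha_\uparrow = 0.4$ when $SE > \mathit{NfA}$)
and a slow downward rate ($\alpha_\downarrow = 0.1$). The asymmetry is the
tolerance mechanism of addiction theory applied to esteem: every regulation
gain is immediately banked as a raised expectation, so the demand for
validation keeps renewing itself at the top, while after a crash the inflated
expectation lets go only slowly and keeps the regulation need — and hence the
pressure to act — high for many timesteps. The asymmetry is also what lets
agents recover at the pace seen in the reference patterns: with a single slow
symmetric rate, each gain leaks away before the need rebuilds and every
post-crash recovery crawls at the habituation drift; with a fast symmetric
rate, the post-crash need collapses instantly and rivalry episodes lose their
characteristic persistence.

### Learning (LSER)

With the learning component enabled, the inter-individual thresholds adapt:

$$TS_{A|t+1} = TS_{A|t} - NCL_t - CL_t$$

* **Contingent learning** (reinforcement): after an inter-individual act, if
  the received response exceeded the pre-response need ($RSP > \mathit{Diff}$)
  the behaviour is positively reinforced and its threshold drops by
  `cl_step`; otherwise a need remains and the threshold rises. A
  zero-magnitude response (indifferent feedback) carries no reinforcement
  signal and leaves thresholds unchanged — indifference teaches nothing.
* **Non-contingent learning** (parenting style): an *overvaluation* event
  lowers the admiration threshold by `ncl_step`; a *devaluation* event lowers
  the rivalry threshold. Events are drawn independently per agent and
  timestep from the environment profile.

Thresholds are clamped to `[ts_floor, ts_ceiling]` = [0.0055, 0.15]; the
floor is the lowest calibrated threshold value and acts as the lower limit of
learning.

### Environments

* **overvaluing**: `p_overvaluation = 0.5` plus excessive, need-surpassing
  contingent praise (all responses positive with magnitude 0.15). The
  magnitude must exceed any need that admiration can be chosen for —
  otherwise a positive-but-insufficient response counts as failure and the
  learned admiration threshold would not be absorbed at the floor with zero
  between-run dispersion.
* **devaluing**: `p_devaluation = 0.5` plus indifferent contingent feedback
  (response magnitudes 0).
* **control**: `p_overvaluation = p_devaluation = 0.01` and ordinary
  behaviour-dependent feedback.

## Parameters and calibration

| parameter | default | meaning |
|---|---|---|
| `leak_rate` | 0.04 /step | relative self-esteem leakage $\lambda$ |
| `intra_boost` | 0.032 | deterministic intra-individual gain |
| `nfa_adapt_up` / `nfa_adapt_down` | 0.4 / 0.1 /step | tolerance development rates |
| `ts_intra` | 0.005 | intra threshold (below the floor 0.0055) |
| `ts_admi` / `ts_riva` | 0.08 / 0.09 | default inter-individual thresholds |
| `p_pos_admi` / `p_pos_riva` | 0.98 / 0.3 | base positive-response probabilities |
| `status_coupling` | 0.25 | slope on the self-esteem gap |
| `mag_admi` / `mag_riva` | 0.048 / 0.12 | response magnitudes |
| `cl_step` / `ncl_step` | 0.0005 | learning step sizes |
| grid, agents | 10 × 10, 20 | world geometry |
| initial `se` = `nfa` | 0.8 | standard initial state |

The defaults were calibrated, pattern-oriented, against the target behaviours
the model is meant to exhibit, in this order of priority:

1. **Baseline inertness.** At default thresholds the focal agent must show
   only minor oscillations and *no* inter-individual behaviour. With
   `intra_boost = leak_rate × 0.8` the undisturbed agent sits exactly at the
   initial state `se = 0.8` and regenerates a per-step need of
   `0.032` — far below 0.08/0.09, so the baseline is deterministic and inert.
2. **A sensitive threshold band.** The model must respond to thresholds
   between the floor 0.0055 and the defaults, and be insensitive at the
   defaults and above. The per-step need (≈ 0.032–0.04) lies inside
   (0.0055, 0.05), so the calibrated sweep levels 0.0055 and 0.025 engage
   behaviour while 0.05 and the defaults do not. The band also brackets the
   thresholds that the four trait groups map onto (0.024–0.069), which is
   what separates the groups behaviourally.
3. **Survivable failures.** A single failed admiration must not
   automatically escalate past the rivalry threshold, and no self-esteem
   level may be absorbing: `mag_admi` is small enough to keep a lone failure
   below `ts_riva` in most states, and `status_coupling` is small enough
   that the positive-response probability for admiration stays well above
   one half even at the bottom of the hierarchy, so recovery is always
   expected-positive. With the spec'd-out larger coupling, an agent at
   `se = 0` could never again earn a positive response — an absorbing state
   that inverts every high-level pattern.

## The studies as experiment recipes

* `run_study1()`: SER threshold sweep, 50 paired-seed runs × 200 timesteps,
  burn-in 50, focal-agent statistics averaged across runs.
* `run_study2()`: LSER, one learning agent among 19 plain agents, 50 runs ×
  1000 timesteps per environment; reports the mean and sample SD of the
  *final* learned thresholds plus full time courses.
* `run_study3()`: SER with focal thresholds drawn per run from the learned
  distributions of a rearing environment — admiration N(0.0055, 0),
  rivalry N(0.0576, 0.0037) for the overvaluing origin; N(0.0833, 0.0029)
  and N(0.0072, 0.0007) for the devaluing origin; N(0.0562, 0.0037) and
  N(0.1125, 0.0074) for the control origin — truncated to the calibrated
  threshold range (the devaluing rivalry distribution can otherwise dip
  below the floor); 50 runs × 1000 timesteps in the control environment.
* `run_study4()`: four trait groups × 50 focal agents × 1000 timesteps.
  Group-level agency and antagonism scores map *inversely* and linearly onto
  the admiration and rivalry thresholds (the highest score maps to the
  floor). Per-agent self-esteem medians and variances plus negated final
  thresholds are z-standardised over the pooled 200 agents (sample SD) and
  averaged per group. The built-in four-group fixture is synthetic: "low"
  and "high" are the 25th and 75th percentile of an arbitrary 1–5 instrument
  scale; user-supplied group scores replace it for faithful comparisons.

Every recipe is a pure function of its parameters and a master seed: per-run
seeds are derived from the master seed once, so adding runs or recording
never perturbs earlier draws, and identical calls reproduce bit-identical
results.

## Numerical and design choices

* `se` and `nfa` are clamped to [0, 1]; thresholds to
  `[ts_floor, ts_ceiling]`. Ties between equally exceeded inter-individual
  thresholds go to admiration (the socially cheaper strategy).
* Within a timestep: all agents move (uniform redraw over all *other* cells,
  non-wrapping), then act one by one in a freshly shuffled order (leakage →
  need → partner check → selection → execution → learning), then every
  agent's need for admiration habituates to its post-action self-esteem.
  Partners are passive: responding costs nothing and does not consume the
  partner's own turn.
* Burn-in records are kept and flagged (`is_burnin`), never dropped, so
  summaries are auditable.
* The miniature fixture world (1 × 2 grid, 2 agents) guarantees partner
  availability at every timestep and exercises all operations in
  milliseconds.

## What the simulations do and do not show

The generator emulates the *qualitative* regularities of momentary
self-esteem dynamics: high stable courses under default predispositions,
high oscillating courses with spikes under low admiration thresholds, low
oscillating courses with recurrent drops under low rivalry thresholds,
floor-absorbed threshold learning under non-contingent over-/devaluation, and
group-ordered medians and variances under trait-mapped thresholds. It does
not emulate measurement noise, missingness, diurnal structure, or
within-group heterogeneity of real experience-sampling data — real data show
vulnerable and grandiose states in *all* trait groups, while the model's
groups are ideal-typical. Passing tests therefore certify the mechanism, not
distributional realism.

Known limitations: no persistent dyadic relationships, reputation, or memory
of past partners; a scalar stand-in for the cognitive content of
intra-individual strategies; one action per agent per timestep; and an
unknown wall-clock meaning of a timestep, so no temporal calibration is
attempted.

## A minimal session

```{r, eval = FALSE}
cfg <- sim_config(n_timesteps = 200, seed = 1,
                  focal_overrides = list(ts_admi = 0.0055), record = "focal")
traj <- run_simulation(cfg)
autoplot(traj)

s2 <- run_study2("overvaluing", master_seed = 1)
tidy(s2)
autoplot(s2)

s4 <- run_study4(master_seed = 1)
tidy(s4)
```
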