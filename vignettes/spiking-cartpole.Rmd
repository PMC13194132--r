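---
title: "Methods: spiking networks with sparse-reward three-factor plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spiking networks with sparse-reward three-factor plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(snnkit)
```

This vignette is the package's methods account: the models it implements,
the conventions and constants it fixes where the underlying approach leaves
them open, the numerical choices, and what the synthetic benchmarks do and
do not establish.

## Blueprints and execution semantics

A model is described by a **blueprint**: typed nodes (soma pools, synapse
groups, a spiker encoder, a trace integrator, raw inputs) and directed
port-to-port edges, serialized as canonical JSON (schema version string,
sorted keys, nodes sorted by id) so that serialization round-trips
byte-for-byte. `build_model()` turns a blueprint into a stateful model;
every component draws its initial state from a private stream derived by a
fixed hash of `(global seed, node id)`, so builds are bit-reproducible and
independent of construction order.

Execution is synchronous with a fixed step `dt` (1 ms for the cartpole
model). The execution order is decided once at build time: topological
order over the component graph; inside a strongly connected component,
synapse groups run first (they already buffer their presynaptic input by at
least one step), remaining ties break lexicographically on node id. A
component reads an input port from the value produced *this* step when its
upstream neighbor has already run, and from the *previous* step otherwise —
the standard one-step-latency convention for back edges, which makes
recurrent and mutually inhibitory loops well defined. Time is derived from
an integer step counter (`t = step_index * dt`), never accumulated in
floating point.

Precision: all computation is in 64-bit floats; `build_model(precision =)`
accepts only `"float64"`. Reduced-precision execution is an
accelerator-specific concern outside this package's scope.

## Soma models

**LIF with refractory period and threshold adaptation** (the cartpole
soma). Within a step: the refractory clock advances; the threshold decays
toward `theta_base` (exponential Euler); the potential integrates its leak
(exponential Euler) plus, for non-refractory units, the forward-Euler input
term `(dt/tau_m) R I`; the spike test `v > theta` is evaluated *after* the
update; spiking units reset to `v_reset`, increment their threshold by `a`,
and are input-gated for `r_spike` ms (the leak always acts — the refractory
state gates the input only). The spike test could equally be placed before
the within-step threshold decay; it is fixed after the update, once, for
determinism. Defaults (`tau_m` 20 ms, `v_rest` −65 mV, `theta_base` −50 mV,
`R` 1, `a` 2 mV, `tau_th` 50 ms, `r_spike` 5 ms, `v_reset = v_rest`) are
standard textbook values; all are configurable per pool. `v_reset` defaults
to the rest potential — the simplest consistent choice.

**AdEx** uses the classic regular-spiking parameter set (capacitance 281 pF,
leak 30 nS, slope 2 mV, `tau_w` 144 ms, `a` 4 nS, `b` 80.5 pA), forward
Euler with the exponential argument clamped at 20. **Hodgkin–Huxley** uses
the classic squid-axon set with the standard alpha/beta rate functions
(singularities filled by their analytic limits); gating variables use
exponential Euler and are therefore confined to [0, 1] by construction; a
spike is an upward crossing of 0 mV. Compiled loops (`simulate_soma()`)
reproduce the R steppers' arithmetic operation for operation, and the test
suite asserts their agreement to 10^-9.

## Synapses, plasticity, and their numerical form

Synaptic currents are traced: each connection decays by `exp(-dt/tau_s)`
and jumps by `w_ji` when the presynaptic spike emitted `d_ji` steps earlier
arrives. Delays are integer multiples of `dt`, drawn uniform on
`[dt, d_max]` (default `d_max` 10 ms) per connection. The drive onto a
postsynaptic unit is the sum of its incoming traced currents; inhibition is
carried by negative weights (population sign), and weights never change
sign: clipping is to `[w_min, w_max]` for excitatory groups and
`[-w_max, -w_min]` for inhibitory ones.

The plasticity rule is the three-factor quadruplet STDP update shown in the
README, applied as per-step forward-Euler increments (`* dt`) and then
clipped. Eligibility traces decay exponentially and jump by 1 on their
triggering spike — the pre trace on the *delayed* presynaptic arrival, the
post trace on the postsynaptic spike. With connection-uniform time
constants the post trace is identical across a unit's incoming connections,
which the compiled engine exploits (per-unit storage); the R-level API keeps
the per-connection matrices. `M3rd = 0` leaves weights exactly unchanged —
this identity is what implements frozen evaluation, and is asserted
bit-for-bit in the tests.

Structural plasticity deletes connections with `|w| < prune_eps` and adds
absent connections with a per-step probability, at magnitude `growth_w`
with the population's sign. The training loop applies it once per episode
with the per-step probability compounded over the episode's network steps
(per-ms application would force a connectivity-index rebuild every
millisecond for no behavioral difference at the default rates). It is off
by default: measured on this task, structural turnover did not rescue
non-stabilizing initializations.

## Interfaces

The **topological spiker** covers each observation dimension with `n_units`
Gaussian tuning curves (width `sigma_frac` of the range) on an even grid;
unit `i` fires a Bernoulli spike per ms with probability
`rate_max * exp(-d^2 / 2 sigma^2)`, where the distance respects the
dimension's topology — clipped for line segments, wrap-around for circles
(the borders are glued, so the two ends are one point). Encoding noise is
refreshed every ms while an observation is held; Bernoulli-per-ms (rather
than Poisson counts) keeps spikes binary, matching the soma input
convention. All four cartpole observations are line segments: position
±2.4 m, angle ±12°, both velocities clipped to ±3 (units/s) — spanning the
termination bounds.

The **integrator** holds one saturable trace per action in [0, 1]: decay
`exp(-dt/tau_out)` then `y += (1 - y)(1 - exp(-gain * count))` — bounded,
monotone in the count, exactly testable. The greedy policy takes the argmax
at the interaction step, ties to the lowest index.

## The cartpole task and training protocol

The environment is the community-standard cartpole (gravity 9.8, cart 1 kg,
pole 0.1 kg, half-length 0.5 m, force 10 N, step 0.02 s, limits 12° and
±2.4 m, caps 200/500 for v0/v1), integrated by semi-implicit Euler and
verified against an independent scalar transcription of the equations of
motion plus an energy-drift order check.

Training is online: the observation is encoded and held for a 50 ms
interaction, the network runs with plasticity at the background factor
`lambda`, the integrator is read, the greedy action is applied. On failure
(pole fell or out of bounds — truncation at the cap is not a failure), one
extra interaction runs on the final observation while the decaying
modulation is delivered; the suppressed action is the one chosen most
recently before termination (it drove the failure), and the episode-length
EMA updates once per episode, after the extra step, initialized by the
first observed episode length. The per-episode integrator state is reset at
episode start; neural state (potentials, currents, traces) is continuous
across episodes.

### The recorded working set

The approach leaves every learning constant free; these are the package's
defaults, chosen once during method development and recorded here:

| constant | default | role |
|---|---|---|
| `eta` | 0.05 | learning rate |
| `lambda` | 1e-4 | background third factor |
| `xi` | 0.5 | opposite-motor gain on failure |
| `tau_R` | 0.02 /ms | decay of the terminal modulation |
| EMA coeff | 0.1 | episode-length average |
| `alpha, beta, gamma, delta` | −0.1, 1, 1, −0.1 | quadruplet scalings |
| `tau_pre = tau_post` | 200 ms | eligibility traces |
| `w_in / w_rec / w_ei / w_ie` | 2.2 / 0.4 / 1.2 / 4 | weight scales |
| densities (in/rec/ei/ie) | 0.3 / 0.1 / 0.3 / 0.3 | connectivity |
| integrator `gain`, `tau_out` | 0.02, 25 ms | decoder |
| encoder | 32 units/dim, `sigma_frac` 0.1, `rate_max` 0.5/ms | input |

Two of these deserve comment. The eligibility traces are **200 ms**, i.e.
about four interaction steps: with the sparse terminal reward, the traces
are the only channel assigning credit to the actions *leading up to* the
failure, and 20 ms traces (a common pairwise-STDP default) span only the
final observation — under them the agent never repairs the decisions that
caused the failure and does not learn at all. Second, only the
**input → motor** synapses are plastic by default (`rec_plastic = FALSE`):
the recurrent groups' third-factor update is not state-specific (it
depresses a whole pool rather than a stimulus-action association) and
empirically drives winner-take-all collapse; the machinery for plastic
recurrence is fully implemented and tested, the default blueprint simply
does not enable it.

### Candidate restarts

Weight initialization is the only difference between two agents, and a
substantial fraction of initializations (roughly two thirds under these
defaults) never stabilizes within a 300-episode budget — the same
qualitative split reported for this class of agent. `solve_cartpole()`
therefore trains candidate initializations sequentially (seeds derived from
the protocol seed), stops a candidate at its first cap-length episode,
validates it with a short frozen evaluation (mean ≥ 300 over 5 episodes;
failures resume training), and returns the first accepted candidate.
Stopping at success also matters for a second reason: the punishment
magnitude scales with the episode-length EMA, so a competent agent that
keeps training through occasional failures receives its largest weight
updates exactly when it has most to lose; extended post-success training
often destabilizes a solved agent.

## Fidelity benchmark

For each soma, 100 one-second trials are driven by a seeded
Ornstein–Uhlenbeck current (Euler–Maruyama; drive constants per soma chosen
so the cell fires in the 10–50 Hz range: LIF 17 ± 8, AdEx 550 ± 250 pA, HH
2 ± 3 µA/cm², `tau_ou` 5 ms) at the step of record — 0.1 ms for LIF/AdEx,
0.05 ms for HH — and again at a 10×-finer step under the identical drive
(zero-order hold). The ISI- and SPIKE-distances between the two runs are
compared with the same distances against an ISI-shuffled surrogate of the
reference train (interval permutation preserves count, duration and rate
structure — the features the null should keep). Both metrics follow the
standard parameter-free definitions, with auxiliary spikes at 0 and T for
the edge intervals; the ISI profile is piecewise constant and the SPIKE
profile piecewise linear between events, so segment-wise integration is
exact, and the suite cross-checks it against an independent pointwise
evaluator to 10^-6.

## What the synthetic benchmarks show — and what they do not

Everything here is synthetic by construction: the OU drive stands in for
"irregular naturalistic input" and the cartpole environment for "an
agent-environment loop". Passing the fidelity property shows the package's
integrators lose little spike-timing information at their steps of record
*under noise drive in the fired regime*; it says nothing about regimes the
drive never visits (bursting, strong adaptation, near-rheobase
bistability). Passing the learning criteria shows the three-factor rule
with this architecture solves a standard control task from sparse reward;
it does not show robustness to observation noise, other tasks, or
larger action spaces.

## Problem sizes used by the tests

The automated suite uses: full-size agents (256E + 64I per side) for the
learning criteria (one solve-protocol run with 50 frozen test episodes;
3 + 3 speed-run seeds at ≤ 120 episodes; 5 × 100-episode learning-signal
runs); 8E + 4I miniatures for engine/executor parity, replay-oracle, and
freeze-contract tests; 10-unit random networks over 1 000 steps for the
STDP scalar-replay oracle; 100 × 1 s trials per soma for fidelity; and 50
random train pairs for the metric oracle. These sizes were chosen so each
check exercises the full code path at meaningful scale.

## Known limitations

* Per-initialization success is ~1/3; the package treats restarts as part
  of the protocol rather than hiding the failure mode.
* A solved agent can destabilize if trained far past success (EMA-scaled
  punishments); see the early-stopping rationale above.
* The compiled engine implements LIF pools only (the architecture the
  agent uses); AdEx/HH models run through the generic executor and
  `simulate_soma()`.
* Only 64-bit floats; reduced precision is out of scope.
* The encoder emits Bernoulli spikes per ms; Poisson or temporal-code
  variants are not implemented.
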