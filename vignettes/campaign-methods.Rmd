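---
title: "Methods: coupled opinion-epidemic simulation and campaign targeting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled opinion-epidemic simulation and campaign targeting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaxcampsim)
```

## The model in brief

`vaxcampsim` couples two stochastic processes on one contact network: a
complex-contagion *opinion stage* that determines who refuses vaccination,
and a discrete-time *SIR stage* among the unvaccinated that measures the
final epidemic size. The staging assumes opinion formation and vaccination
complete before disease introduction, as is natural for childhood
vaccine-preventable diseases, and implies no feedback from disease to
opinion.

The contact structure is a Watts–Strogatz graph: a ring lattice of `n`
nodes with `k` neighbours each, every edge rewired with probability `p`.
Small `p` keeps the high clustering that makes opinion clusters — and the
herd-protection effects of breaking them up — meaningful, while giving
short path lengths. Rewiring can in principle disconnect the graph; the
simulator keeps such realisations (components simply evolve independently),
with a `require_connected` flag for users who prefer to regenerate.

### Opinion stage

Agents are neutral (`o0`), anti-vaccine (`o-`) or pro-vaccine (`o+`), with
exposure counters `phi-` and `phi+` that only accumulate while the agent is
neutral. Each step applies, in a fixed order:

1. **campaign retargeting**, when due (every `t_r` steps for dynamic
   strategies, once at step 0 for static ones);
2. **general exposures**: one Bernoulli trial per channel per neutral agent
   — probability `mu_minus` for the negative channel, the per-agent
   allocation `mu_i_plus` for the positive one;
3. **social exposures**: one Bernoulli trial per committed-neighbour link,
   with probability `omega_minus` (`omega_plus`) per anti- (pro-) vaccine
   neighbour, sources being the adopters *as of the start of the step*;
4. **synchronous threshold update**: a neutral agent commits to `o-` when
   `phi- - phi+ >= theta`, to `o+` when `phi- - phi+ <= -theta`.

Commitment is absorbing, so the negative and positive counts are
non-decreasing and the stage terminates either at `tau` steps or — in the
long-run regime `tau = Inf` — when no neutral agent remains (with a hard
`max_steps` cap of 10^6 that raises an error rather than silently
truncating). An agent committing at step `t` exerts social influence from
step `t + 1`. Each neutral agent with `m` negative neighbours therefore
receives a `Binomial(m, omega_minus)` counter increment per step, which is
how the engine draws it (one binomial per agent rather than `m` Bernoullis
— identical in distribution, far cheaper).

### The opinion threshold

`theta` is the committed-opinion threshold: the net exposure surplus one
side must accumulate. The package default is `theta = 2`, the smallest
threshold that is still a complex contagion (no single exposure can
convert). This choice is forced by the rate regime the model is built
around: general exposure rates of order 10^-3 per step mean an isolated
agent accumulates about 0.4 exposures over a 400-step campaign, so for any
threshold much above 2 the negative channel can never self-seed —
P(Binomial(400, 0.001) >= theta) is about 6% at theta = 2, 0.8% at
theta = 3, and astronomically small at theta = 10 — and the two-stage model
would produce empty epidemics at every finite horizon. At `theta = 2` the
seeded fraction is small but sufficient for social amplification, which is
the dynamically interesting regime: thresholds in this model should be read
jointly with the exposure rates, and `theta` is an explicit configuration
value so users can explore other pairings.

### Campaigns

A campaign is a budget `mu_plus` (a population-averaged positive exposure
rate) plus a targeting rule. Targeting concentrates the budget:
`mu_i_plus = T_i * mu_plus * n / sum(T_i)`, conserving the total
`mu_plus * n` exactly. Seven rules are implemented; the dynamic ones
reselect among *currently neutral* agents every `t_r` steps, so an agent
targeted earlier but still neutral remains eligible (selection criteria are
state-based, not history-based). `DynAntiT` tops up with uniformly random
neutral agents when fewer than `T` neutral agents have an anti-vaccine
neighbour — the same shortfall rule the score-based strategies use — which
keeps the per-target allocation constant at `mu_plus * n / T`.

Two boundary conditions deserve note:

* **Configured overdraw.** If `mu_plus * n / T > 1` for the configured `T`,
  the per-target value is not a probability and the run aborts with an
  error naming the offending combination. Silent clamping would
  misrepresent the requested budget.
* **Endgame shortfall.** In `tau = Inf` runs the neutral population
  eventually drops below `T`, and conservation would then demand
  probabilities above 1. In exactly this emergent case the per-target
  probability caps at 1 (exposure with certainty); the remaining budget is
  simply unspendable, since fewer people than planned remain persuadable.

Ties in any selection — equal betweenness at the static-centrality cut,
equal scores in `DynLocT`/`DynAdvLocT` — break uniformly at random.
Betweenness is unnormalised shortest-path centrality with fractional
credit for multiple shortest paths (Brandes' algorithm via igraph; the test
suite checks it against a brute-force path-enumeration oracle).

### SIR stage

Vaccination removes all non-negative agents from the disease dynamics
while leaving them in place structurally, so transmission paths through
vaccinated nodes are blocked. The SIR stage is synchronous: every agent
infected at the start of a step transmits independently along each edge to
a currently susceptible neighbour with probability `beta`, then recovers
with probability `gamma`; a newly infected agent neither transmits nor
recovers in its infection step. A susceptible with `m` infectious
neighbours is infected with probability `1 - (1 - beta)^m`. This
convention makes the two-node system exactly solvable —
`E[S_r] = 1 + beta / (1 - (1 - beta)(1 - gamma))` — which the test suite
verifies to three digits over 10^5 replicates.

## Replication design

A scenario runs `n_networks` independent network + opinion realisations;
each fixes one vaccination outcome, shared by `n_sir_runs` independent SIR
runs (matching the design in which many infection simulations reuse each
generated network). The 95% confidence interval is
`1.96 * sd / sqrt(n)` over the pooled SIR-level replicates; per-network
summaries are exposed through `tidy(x, per_network = TRUE)` because the
between-network component dominates the variance in most scenarios — final
sizes are driven by the largest anti-vaccine cluster, whose size varies
strongly across opinion realisations (per-network standard deviations of
several hundred agents at N = 5000 are typical for the mid-range
scenarios). Sweeps (`run_sweep()`) reuse the same master seed at every
point of the axis, so network seeds are shared and comparisons along the
axis are paired.

Seeding: the master seed is consumed once to derive one sub-seed per
network and one per (network, SIR run); every stochastic draw then comes
from the replicate's stream in the documented in-step order, making any
`(seed, config)` pair bit-reproducible, independent of evaluation order.

## What the simulated conditions do and do not capture

The Watts–Strogatz substrate reproduces two features that drive the
phenomena of interest — local clustering (so opinion clusters form and
vaccinated agents can encircle them) and short global paths (so both
sentiment and disease can percolate). It does not reproduce degree
heterogeneity, community structure, household/workplace layering, or
distinct channels for information versus physical contact, all present in
real populations; nor do agents ever revise a committed opinion. Passing
tests therefore demonstrate correctness of the mechanisms and faithfulness
to the modelled dynamics, not calibration to any real outbreak.

## Numerical and scale choices

* Exposure counters are exact integers; the threshold comparison is
  integer arithmetic, so no tolerance is involved in the dynamics.
* Budget conservation is checked to 1e-12 (floating summation only).
* The SIR engine uses a dense adjacency submatrix when at most 512 agents
  are susceptible and a sparse one above, purely for speed; results are
  identical.
* Degenerate inputs: an empty susceptible set records `S_r = 0` without
  resampling; `tau = Inf` with no positive-probability exposure channel is
  rejected up front; seeding more infections than there are susceptibles is
  an error.
* Test and acceptance problem sizes: the unit and property tests run at
  N of a few hundred; the scenario-reproduction checks run the full
  N = 5000 networks at a desk-scale replication (5 networks x 4 SIR runs
  in the test suite, 24 x 8 in `scripts/acceptance.R`), a deliberate
  trade-off between Monte-Carlo error — a few pooled standard errors on
  scenario means — and a suite that completes in minutes on one CPU. The
  reference replication for the headline figures is 500 x 500.

## Known limitations

* Reported epidemic-size means for the weakly-suppressed dynamic scenarios
  (large per-network variance, bimodal outbreak sizes) remain noisy at
  desk-scale replication; scale `n_networks` up (e.g. `reps_scale`) for
  publication-grade intervals.
* The exact shortfall behaviour of `DynAntiT` before any anti-vaccine
  agent exists (top-up versus a smaller target set) is a genuine modelling
  fork; the package tops up, keeping the allocation constant, and the
  choice is visible in early-phase dynamics of weak-budget runs.
* Betweenness is recomputed per generated network (Brandes,
  O(VE)); at N = 5000, k = 10 this costs a couple of seconds per network
  and dominates the runtime of static-centrality scenarios.
* Only betweenness centrality is built in as a topological targeting
  criterion; other centralities can be emulated by passing a custom
  `centrality` table to `run_opinion_stage()`.
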