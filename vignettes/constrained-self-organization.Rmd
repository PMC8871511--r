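---
title: "Models and methods: constrained self-organization of heterarchical networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: constrained self-organization of heterarchical networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csorg)
```

`csorg` is a simulation-and-analysis workbench for a single question asked
three ways: when a population of initially equivalent dynamical elements is
evolved under a *global* constraint — maximize transmitted information,
minimize classification error — what structure emerges? The package
implements the three model systems in which we study this (networks of
elementary map units, evolutionary reservoir computers, and polynomial
epigenetic landscapes), the genetic-algorithm engine that applies the
constraint, and the analysis tools (time-dependent mutual information,
layer/feedback classification, ablation, attractor counting, and a
constructive Kolmogorov–Arnold–Sprecher superposition) used to
characterize the outcome.

This vignette documents the models, the tunable parameters with their
defaults and rationale, the numerical choices, and what the synthetic
experiments do and do not show.

## 1. The elementary dynamical unit

Each network element is the scalar discrete-time map

$$x_k(t+1) = a_1\tanh\!\big(a_2 (x_k(t) - a_3)\big) - a_4\tanh\!\big(a_5 (x_k(t) - a_6)\big) + b_k,$$

a difference of two saturating branches plus a per-unit bias. The map's
graph can be monotone, unimodal or bimodal (`map_shape()`), and its
iterated dynamics realize three biologically suggestive regimes, which
`classify_unit_state()` separates with an explicit probe protocol:

* **passive** — a stable rest state whose pulse response stays below the
  pulse amplitude and decays monotonically (a glia-like susceptible
  element);
* **excitable** — a rest state whose pulse response transiently exceeds
  `overshoot_ratio` (default 2.0) times the pulse before returning to
  rest (a spiking element);
* **oscillatory** — a sustained autonomous orbit with a detected period
  of at least 2;
* **other** — everything else, deliberately including aperiodic
  large-amplitude orbits and responses with gain between 1 and the
  overshoot threshold. The taxonomy has a genuine gap: a unit that
  amplifies a pulse 1.5-fold is neither passive nor excitable under
  these rules, and we report it as `other` rather than stretch a
  category.

Probe defaults (all configurable through `classify_protocol()`):
transient 500 steps, observation 500 steps, pulse amplitude 0.5,
fixed-point tolerance `1e-4`, oscillation amplitude threshold `1e-3`,
orbit-recurrence tolerance `1e-6`. The autonomous probe starts at
`x0 = 1e-3` rather than exactly 0 so that an unstable symmetric
equilibrium does not mask an oscillation.

**Coupling.** For a network, coupling and external input enter the map
*argument*: unit `k` sees `u_k = x_k + \sum_l w_{kl} x_l +
g\,[k = \mathrm{receiver}]\,I(t)` and maps it through the two-branch
nonlinearity. This choice preserves the exact state bound
`|x_k(t)| <= |a_1| + |a_4| + |b_k|` for all `t >= 1` (the test suite
asserts it on random networks) and keeps the receiver — unit 0 by
convention — the single injection site, consistent with how layers are
defined below. Initial conditions default to independent uniform draws
on [-0.1, 0.1].

## 2. The constraint engine

`evolve()` is a plain generational genetic algorithm: tournament
selection (size 3), uniform crossover (probability 0.7), per-locus
Gaussian mutation (rate 0.1, scale 0.1 of the bound range), elitism
(2). Fitness is maximized; all our fitness adapters evaluate a gene on
a *fixed-seed* simulation protocol, so fitness is a pure function of
the gene and elitist best-fitness monotonicity holds exactly. Defaults
(population 30; here typically 16–20) are deliberately parameter-light:
nothing in our questions depends on a sophisticated optimizer, only on
the constraint it enforces.

Two gene layouts are used for map networks, matching the two
experiments: the connection strengths over a fixed topology
(`evolve_eds_weights()`), and the shared parameters `a1..a6` plus the
per-unit biases `b_1..b_N` (`evolve_eds_params()`).

## 3. Information at fixed state resolution

`histogram_mi()` is a plug-in estimator on a 2-D equal-width histogram
(default 8 bins, bits); integer or categorical references get one bin
per category, and a zero-range variable occupies a single bin (zero
entropy) rather than erroring. `time_mi()` applies it across an
ensemble of trials separately at each time step — the time-dependent
mutual information between a unit's state and the input pattern
identity.

One estimator decision matters a great deal for noise-free dynamics and
deserves its own paragraph. Binning over the *observed* range is
scale-invariant: if all trial states converge toward a common fixed
point, their differences shrink but the histogram rescales with them,
and the measured information never decays (until floating-point
resolution — we observed exactly this, including a pathological variant
where a symmetric fixed point sits on a bin edge and the *sign* of a
`1e-15` residual still encodes one bit). The ensemble protocols
therefore bin unit states over the network's fixed dynamical range
`±(|a1| + |a4| + max|b|)` (`eds_state_bound()`): information is
measured at a fixed state resolution, and trajectories that converge
below one bin width genuinely lose it. `histogram_mi()` itself keeps
the observed-range default; the fixed range is a protocol choice,
passed explicitly.

`decay_rate()` is the negated least-squares slope of
`log(bits + 1e-6)` over a window; the additive floor caps the dynamic
range of the fit (about 3 decades for typical MI levels), which is why
tests compare slopes at `1e-3`-level tolerances rather than machine
precision.

## 4. Heterarchy: layers, feedback, ablation

Layers are shortest directed path lengths from the receiver
(`assign_layers()`, via igraph); an edge from a higher to a lower layer
is *feedback*, lower to higher *feedforward*, equal layers *lateral*.
Directed forward reachability is the right notion here because the
layer index is a signal-propagation order; an undirected notion would
make "feedback" ill-defined. A useful consequence: every edge on a
shortest path is feedforward, so removing all feedback edges never
disconnects a reachable unit.

`ablation_experiment()` presents one of `P = 4` pattern identities
(constant input levels spread over [-1, 1]) for `T_in = 20` of
`T = 100` steps over `E = 200` trials, and compares named ablation
variants under *identical* seeds, so any difference is structural.

`heterarchy_experiment()` packages the full study. Its conditions were
fixed on mechanistic grounds:

* units are passively susceptible (`a1 = 0.9`, `a2 = 1`; per-step gain
  0.9 < 1) and evolved weights are bounded to [-1, 1], so every cycle
  has loop gain at most 0.81. Attractor pinning is then *impossible*:
  retention of pattern information beyond the presentation window can
  only come from network recurrence. In exploratory regimes outside
  these bounds the experiment degenerates — strong weights pin
  multistable attractors (nothing decays), chaotic units destroy the
  signal during presentation, and strong leak attenuates it below bin
  resolution;
* per-unit biases are heterogeneous (uniform on [-0.2, 0.2]), which
  moves the network fixed point off histogram bin edges (see §3);
* the random 10-unit topology (edge probability 0.25) is redrawn, with
  seeded rejection, until at least `N - 1` units are reachable from the
  receiver, the deepest layer is at least 2, and at least two feedback
  edges exist — otherwise the ablation question is not well posed;
* the probe is the deepest reachable unit, and the single-edge variant
  removes a feedback edge into the probe when one exists.

After weights are evolved for maximal time-averaged mutual information,
removing *all* feedback makes the probe's information decay an order of
magnitude faster than removing a *single* feedback edge, across seeds;
the intact and single-ablation variants hold more information
throughout. That is the heterarchy claim in testable form.

## 5. The evolutionary reservoir computer

`erc_network()` implements the leaky-tanh reservoir
$$x_k(t+1) = (1-\alpha_k)x_k(t) + \alpha_k\tanh\!\Big(\sum_l w_{kl}x_l(t) + w_{k0} + \sum_l w^{(in)}_{kl} I_l(t)\Big) + \sigma_k(t)$$
with a fixed two-layer internal partition: the first `N/2` units form
the internal input layer (the only ones wired to the input channels),
the rest the internal output layer (the only ones feeding the linear
readout `y = W^* x`). Output-to-input-layer connections are the
feedback class.

Tasks (`make_patterns()`): 4 spatial classes — fixed random ±1 vectors
on 8 channels held constant for 60 steps — and 4 temporal classes —
sinusoids of periods 4, 8, 16, 32 on all channels with a random phase
per trial; 20 trials per class, stratified 70/30 train/validation
split. The random phase makes the temporal task a genuine
period-discrimination problem rather than a waveform lookup. Readouts
are trained per modality by closed-form ridge regression
(`train_readout()`, default λ = 1e-4; λ = 0 falls back to the
minimum-norm SVD solution) on the response-window states (last 30
steps, washout 10) of output-layer units, and a trial is scored by the
argmax of its window-averaged outputs within its modality (ties to the
lowest class index).

`evolve_erc()` treats the flattened off-diagonal internal weights as
the gene (bound 1; magnitudes below `1e-3` count as absent edges in
`structure_stats()`); fitness is mean validation accuracy across
modalities under a fixed noise seed. `feedback_scale_sweep()` then
multiplies all feedback weights by a factor `s`, *retrains the
readouts*, and reports accuracy relative to `s = 1` (100% by
construction). In evolved networks the temporal modality collapses
toward chance at `s = 0` and degrades at `s = 2`, while the spatial
modality (solvable feedforward) stays flat — the reservoir-side
signature of functional differentiation relying on feedback.

Scaled problem sizes used throughout (our choice of study size):
`N = 60` units, population 16, 30 generations, 5 seeds in the
acceptance suite and 3 in the reporting script.

## 6. Constructive superposition

The representation
$$f(x_1,\dots,x_n) = \sum_{j=0}^{m}\phi_j\Big(\sum_{i=1}^{n}\lambda_i\,\psi(x_i + jc)\Big)$$
holds for any continuous `f` on the unit cube, for admissible integers
`n >= 2`, `m >= 2n`, `γ >= m + 2`, with constants
`c = 1/(γ(γ-1))`, `λ_1 = 1`,
`λ_i = Σ_l γ^{-(i-1)β_n(l)}` (series truncated below `1e-16`; the
terms decay super-geometrically since `β_n(l) = 1 + n + … + n^{l-1}`),
`α = log_γ 2`. Two numerical readings required a decision:

* **The Hölder constant ν.** The source typography admits both
  `2 - α(γ+3)` and `2^{-α}(γ+3)`; the former is negative for γ = 10,
  contradicting `ν > 0` in the Hölder definition itself, so we adopt
  `ν = 2^{-α}(γ+3)` and *verify it empirically*: `check_holder()`
  exhaustively maximizes `|Δψ|/|Δx|^α` over grid pairs and the
  constructed tables pass with a wide margin.
* **The inner function ψ.** The literature defines it constructively
  but with several correction variants; we implement the digit-sum
  construction: for a depth-`k` base-γ rational `d = Σ_r i_r γ^{-r}` in
  [0, 1), `ψ(d) = Σ_r i_r γ^{-β_n(r)}`, extended to [1, 2] by
  `ψ(1+u) = 1 + ψ(u)`. This table is strictly increasing (the tail of
  the digit weights is dominated by any leading-digit increment), maps
  [0, 2] onto itself, and is refinement-consistent — depth-`k` values
  reappear unchanged at depth `k + 1` — all asserted by tests, which is
  what the representation requires of *any* admissible variant.

What makes the superposition work is injectivity of the inner map
`x ↦ (z_0,…,z_m)`: the test suite checks all 10⁴ depth-2 grid points
for γ = 10 exhaustively. Outer functions are fitted *empirically*
(`fit_outer()`): `f` is sampled on the depth-`k` grid and each branch
receives `f(x)/(m+1)` at argument `z_j(x)`, interpolated piecewise
linearly with exact duplicates averaged. By injectivity the
reconstruction is exact at training points; off-grid quality is
*reported*, not guaranteed — `kas_reconstruct()` evaluates on a test
grid offset by half a grid step and returns the sup-error, which
decreases with depth for smooth targets (e.g. `x₁x₂`). We deliberately
do not implement the exact iterative outer-function algorithm; the
empirical branch-split keeps the module auditable and the structural
claims (monotone ψ, Hölder bound, injectivity) carry the theory.

## 7. Epigenetic landscapes

`landscape_S(y, b, n)` is the single-attractor stem landscape
`y^n + by + 1`; `h(b) ≡ S(·; b)` (`stem_index()`) reads it as a
function of its one parameter — the activation state of an
undifferentiated cell. `landscape_D(y, c_1..c_n)` adds a confining even
leading monomial `y^{confine}` (degree > n, an explicit design choice:
bounded-below wells are what the multistable-attractor picture needs on
the real line) to the coefficient polynomial, so the coefficient vector
acts as an n-dimensional phenotype index. Attractors are *interior*
local minima (`count_attractors()`: grid scan of first-difference sign
changes, skipping flat steps, refined by root-finding on the analytic
derivative); boundary minima are flagged, not counted, because edge
artifacts are not metastable states. `differentiation_path()`
interpolates linearly in coefficient space and reports where the
attractor count changes — the bifurcations of a differentiation event —
and `gradient_flow()` provides the Lyapunov-descending dynamics (step
default `1e-3` of the interval width; descent monotonicity is tested).
`index_transform()` closes the loop with §6: applying ψ to each
landscape index gives the stem-cell-side representation, injective on
the grid, of any continuous function of the differentiated indices.

## 8. What the synthetic experiments do and do not show

The generators emulate the *structure* of the study conditions: pattern
identities as constant input levels (ablation study) or short random
binary sequences (differentiation study), sinusoidal/static task
classes, sparse random directed topologies. They do not emulate
measurement noise, heterogeneous unit time constants, continuous-time
dynamics, or any biological parameter values; passing tests show that
the *mechanisms* (feedback-dependent retention, constraint-driven
differentiation, accuracy loss under feedback rescaling) operate in the
models, not that any biological system is quantitatively reproduced.

Two honest caveats from our own measurements. First, the
differentiation study is genuinely stochastic at its scaled size: over
repeated seeds roughly half the runs end with units in at least two
clean categories, the rest landing in one category plus `other`
(intermediate response gains). Second, the ablation study's side
observation in the source material — that full feedback removal leaves
a *larger* information magnitude than single-edge removal while
decaying faster — is not reproduced here (our full-removal magnitude is
smaller); we treat it as an observation about their particular network,
not an invariant.

## 9. Problem sizes and reproducibility

Every stochastic run derives its streams from one master seed via
`child_seed(master, tag)` (a stable string hash into `[1, 2^31 - 2]`),
so any experiment is reproducible bit-for-bit from its configuration.
The suite and the reporting script use deliberately scaled study sizes
— 10-unit map networks (pop 20 × 50 generations), 8-unit
differentiation runs (pop 20 × 40), 60-unit reservoirs (pop 16 × 30),
ensembles of 100–200 trials — chosen as the smallest sizes at which the
qualitative phenomena are stable across seeds.
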