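# csorg — constrained self-organization of heterarchical networks

`csorg` is an R workbench for studying how specialized structure emerges
when a population of initially equivalent dynamical elements evolves
under a single global constraint. It is aimed at computational/systems
biologists and complex-systems researchers who want small, fully
reproducible models of *functional differentiation* — the emergence of
distinct unit roles — and *heterarchy* — feedforward hierarchy combined
with feedback connections that carry real function.

The package implements, end to end:

* **Elementary dynamical units** — the two-tanh map
  `x(t+1) = a1 tanh(a2(x − a3)) − a4 tanh(a5(x − a6)) + b`, coupled into
  directed weighted networks, with a probe protocol that classifies each
  unit as passive / excitable / oscillatory from its isolated dynamics.
* **A genetic-algorithm engine** (tournament selection, uniform
  crossover, Gaussian mutation, elitism) driving "self-organization with
  constraints": maximize transmitted information (map networks) or
  classification accuracy (reservoirs).
* **Information metrics** — plug-in histogram mutual information and the
  *time-dependent* mutual information between a unit and the input
  pattern identity across an ensemble of trials, with log-linear decay
  rates.
* **Heterarchy analysis** — layers as shortest directed path lengths
  from the receiving unit, feedforward/feedback/lateral edge
  classification, and seeded ablation experiments that measure what
  feedback edges do for information retention.
* **An evolutionary reservoir computer (ERC)** — the leaky-tanh
  reservoir `x(t+1) = (1−α)x + α tanh(Wx + w0 + W_in I) + σ`, ridge
  readouts (`y = W* x`), spatial/temporal discrimination tasks, GA over
  the internal wiring, and a feedback scale-factor sweep.
* **A constructive Kolmogorov–Arnold–Sprecher superposition** —
  `f(x1..xn) = Σ_j φ_j(Σ_i λ_i ψ(x_i + jc))`: constants, the monotone
  self-similar inner function ψ tabulated at precision γ⁻ᵏ, Hölder
  verification, inner-map injectivity, empirical outer functions, and
  reconstruction error reporting.
* **Polynomial epigenetic landscapes** — stem landscape
  `S(y;b) = yⁿ + by + 1`, multi-well differentiated landscapes,
  attractor counting against an analytic root oracle, gradient flow,
  and bifurcation profiles along coefficient paths.

## Worked example

The headline experiment: evolve the connection strengths of a random
10-unit map network to maximize the time-averaged mutual information
between the input pattern and the units, then ablate feedback edges and
watch what happens to information retention.

```r
library(csorg)

hx <- heterarchy_experiment(seed = 2)
hx$probe                    # deepest reachable unit: 6
hx$n_feedback               # feedback edges in the evolved net: 10
hx$best_fitness             # evolved mean MI: 1.50 bits
hx$decay_all                # MI decay, all feedback removed: 0.147 / step
hx$decay_one                # MI decay, one feedback edge removed: -0.0002 / step
```

On this seed the evolved network transmits 1.50 bits on average; after
the input is switched off, the probe's mutual information with the
pattern stays flat when only one feedback edge is removed (decay rate
≈ 0, mean post-offset MI 1.51 bits) but collapses at 0.147 per step
(mean 0.20 bits) when *all* feedback is removed — the feedback
connections are what preserves the input information, while the intact
network holds 1.65 bits. The same asymmetry holds across seeds.

The superposition module in three lines:

```r
kp  <- kas_constants(n = 2, m = 4, gamma = 10)
#> c = 0.0111111, lambda = 1, 0.1010001, alpha = 0.30103, nu = 10.5517
tab <- inner_psi(10, 2, 3)        # 2001 grid points on [0, 2]
check_holder(tab, kp$nu, kp$alpha)$pass
#> TRUE   (max |dpsi|/|dx|^alpha = 1.641, far below nu = 10.55)
kas_reconstruct(function(X) X[,1] * X[,2], kp, tab)$sup_error
#> 0.179  (down from 0.796 at depth k = 1)
```

The reconstruction error for `f = x1·x2`, measured half a training-grid
step away from every knot, falls from 0.796 at depth 1 to 0.179 at
depth 3.

## Layout

```
R/                 implementation (one file per module)
tests/testthat/    unit + property tests, oracles in helper-oracles.R,
                   end-to-end scientific checks in test-acceptance.R
scripts/           acceptance.R (reproduction script)
vignettes/         methods vignette: models, parameters, design choices
inst/cli/csorg.R   thin command-line wrapper over run_experiment()
```
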