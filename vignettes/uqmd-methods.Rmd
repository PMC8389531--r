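---
title: "Adaptive sparse-grid uncertainty quantification for ensemble simulators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive sparse-grid uncertainty quantification for ensemble simulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uqmd)
```

## The problem

Classical molecular-dynamics estimates of a ligand-protein binding free
energy depend on two very different sources of uncertainty. *Parametric*
(epistemic) uncertainty enters through the simulation inputs — thermostat
targets, pressure couplings, cutoffs, box padding and so on — whose "right"
values are never known exactly. *Aleatoric* uncertainty enters through the
random seed that draws the initial velocities: because the dynamics are
chaotic, replicas that differ only in their seed diverge into genuinely
different trajectories. `uqmd` implements a forward
uncertainty-quantification pipeline for this setting: it treats the
simulator as a black-box map `(configuration, seed) -> energy`, propagates
independent uniform input distributions through it with a dimension-adaptive
stochastic-collocation surrogate, decomposes the resulting output variance
into per-input Sobol indices, and analyses replica ensembles with
probability boxes, shape statistics and coefficient-of-variation ratios.

Because one real binding-affinity campaign costs millions of CPU hours, the
package ships a seeded synthetic simulator with planted structure, so every
statistical claim the package makes can be tested end-to-end at desk scale.

## Stochastic collocation and the combination technique

Each of the $d$ inputs $\xi_i$ is uniform on $[lo_i, hi_i]$; an affine map
sends the input box to the unit hypercube, where all quadrature lives. The
surrogate is a sum of tensor-product Lagrange interpolants over nested
Clenshaw–Curtis rules. A one-dimensional rule of level $l$ has
$m(0)=1$, $m(l)=2^l+1$ points: the level-0 rule is the single midpoint, and
every level's point set is contained in the next one. Nesting is what makes
anisotropic combinations affordable — coinciding points are evaluated once.

A *multi-index* $l = (l_1,\dots,l_d)$ selects one tensor grid. An index set
$\Lambda$ is *admissible* (downward closed) when every backward neighbor of
every member is itself a member. The surrogate over $\Lambda$ is the
combination-technique sum
$\tilde e(\xi) = \sum_{l \in \Lambda} c_l\, p_l(\xi)$ with integer
coefficients
$c_l = \sum_{z\in\{0,1\}^d,\ l+z\in\Lambda} (-1)^{|z|}$,
which always sum to one, so constants are reproduced exactly.

Numerical choices worth knowing about:

* **Points.** Abscissae are generated from exact dyadic fractions through
  `cospi()` and mirrored about $1/2$, so nesting and symmetry hold
  *bitwise* and point deduplication across member grids needs no tolerance.
* **Weights.** Quadrature weights are integrals of the Lagrange cardinal
  basis (Gauss–Legendre of sufficient order), normalized to a probability
  measure: a level-$l$ rule therefore integrates every polynomial of degree
  $\le m-1$ exactly, which the test suite checks to $10^{-10}$.
* **Moments.** The surrogate mean applies the signed combination of product
  rules to the stored values. The variance applies the same quadrature to
  the *squared* surrogate (whose nodal values are the squared model values)
  and subtracts the squared mean, clipping round-off at zero. This is
  self-consistent with the interpolant rather than exact for its square;
  the suite verifies it against analytic moments for low-degree models and
  against a $10^6$-sample Monte-Carlo oracle within three standard errors.

## Dimension-adaptive refinement

The campaign starts from $\Lambda = \{(0,\dots,0)\}$ — one midpoint
configuration — and alternates a *look-ahead* step with an acceptance step.
Look-ahead evaluates the model ensemble at the new unique points of every
admissible forward neighbor; each candidate is scored by the absolute
change in surrogate variance it would cause,
$\epsilon_l = |\mathrm{Var}(\Lambda\cup\{l\}) - \mathrm{Var}(\Lambda)|$.
The candidate with the largest $\epsilon_l$ is accepted, ties going to the
lexicographically smallest index so runs are deterministic. Zero-error
candidates stay in the pool — later acceptances can revive them.

The refined quantity of interest is the ensemble average over a fixed seed
list (the same seeds for every configuration), or a single fixed seed when
the no-ensemble variant is wanted. Look-ahead evaluations count against the
budget when they are computed, and all evaluations are cached, so the total
number of simulator calls is exactly (unique configurations) × (seeds).

The loop stops when the next look-ahead would exceed the budget, when no
candidates remain, when an optional absolute tolerance on
$\max_l \epsilon_l$ is undershot (disabled by default), or when every
candidate's indicator is zero up to a $10^{-10}$ relative round-off guard.
The last rule is a deliberate design choice: once the surrogate reproduces
the model exactly, all indicators are round-off, and the lexicographic
tie-break would otherwise start refining directions the model does not
depend on. With it, additive models of $k < d$ inputs never trigger
refinement of an inactive dimension, a property the suite asserts.

Two known limitations of the variance-change indicator are worth stating,
because they are properties of the method, not of the implementation. A
model that vanishes identically on the midpoint hyperplane of some input
(the Ishigami function does, for all three inputs, since level-1
Clenshaw–Curtis points hit the zeros of the sine on $[-\pi,\pi]$; so does a
`g_function` coordinate with $a_i=0$) gives $\epsilon_l = 0$ for every
candidate in the other directions, and the campaign cannot discover them.
For such models a converged full tensor box is the appropriate plan, and
that is how the package's tests check Ishigami index recovery. Sensitivity
benchmarks driven through the adaptive loop use strictly positive
g-function coefficients.

## Sobol indices via an orthonormal Legendre expansion

Each accepted tensor interpolant is a polynomial of per-dimension degree
$m_i - 1$, so its projection onto the tensor basis of shifted Legendre
polynomials (orthonormal under the uniform measure) is exact; projections
are combined with the $c_l$ coefficients. By Parseval, the total variance
$D$ is the sum of squared coefficients over nonzero degrees, the partial
variance $D_u$ of an input subset $u$ collects coefficients whose support
is exactly $u$, and $S_u = D_u / D$. All subsets that actually carry
coefficients are reported (the count is bounded by the grid size, not by
the power set), with the first-order vector extracted separately. A
surrogate whose variance sits at the round-off floor of its mean term is
flagged undefined rather than propagating `NaN`. Recovery of the
closed-form g-function and Ishigami decompositions within 0.05 is part of
the acceptance suite.

## Aleatoric analysis of replica ensembles

With energies $e(\xi, \eta)$ on a complete configurations × seeds table,
three views separate the uncertainty sources: the raw pool, the per-seed
means over configurations (aleatoric view) and the per-configuration means
over seeds (epistemic view).

The *probability box* fixes each seed $\eta_i$ and forms the empirical cdf
of the energies over configurations, then takes the pointwise envelopes
$\underline P(e) = \min_i F_{\eta_i}(e)$ and
$\bar P(e) = \max_i F_{\eta_i}(e)$. A conservative central interval at
level $1-\alpha$ is
$[\bar P^{-}(\alpha/2), \underline P^{-}(1-\alpha/2)]$ with the
left-continuous infimum convention $F^-(q) = \min\{x : F(x) \ge q\}$; it
contains every individual seed's quantile interval by construction. The
alternative summary that takes extreme per-seed quantiles is exposed as
`convention = "per_seed_extremes"`.

Shape statistics use the biased moment-based estimators
$g_1 = m_3/m_2^{3/2}$ and $g_2 = m_4/m_2^2 - 3$ (the usual Gaussian
references 0 and 3 apply at large $n$; the bias-corrected variants differ
only by $O(1/n)$ factors and the choice is documented here rather than
configurable per call — `e1071` provides both if a user needs the other
convention). Confidence intervals are percentile bootstrap over replicas
within a configuration, default 2000 resamples at level 90%, under an
explicit integer seed with the caller's RNG state restored. The point
skewness is classified as region A ($|g_1| < 0.5$, approximately
symmetric), B ($0.5 \le |g_1| \le 1$, moderately skewed) or C
($|g_1| > 1$, highly skewed).

## Coefficient-of-variation ratios

The CVR compares relative variability at the output to the average
relative variability assumed at the input,
$\mathrm{CVR} = |\mathrm{CV}(e)| / \overline{\mathrm{CV}}(\xi)$, with
amplification declared above 1. Input CVs are analytic,
$((hi-lo)/\sqrt{12})/((lo+hi)/2)$ per uniform input — $0.15/\sqrt 3 \approx
0.0866$ for any $\pm15\%$ interval. The ensemble-averaged mode takes the
CV of per-configuration ensemble means; the per-replica mode averages the
absolute per-seed CVs over configurations, and by Jensen's inequality it
always dominates the ensemble-averaged mode. Sample standard deviations
use the $n-1$ denominator. Because a reduced temperature range lowers the
input-side average, `mean_input_cv()` offers both the actual-bounds value
and the all-$\pm15\%$ convention (`all_pm15 = TRUE`, giving 0.087 for 14
inputs); both are reported so either bookkeeping can be reproduced.

## The synthetic simulator

`mock_esmacs()` stands in for an ensemble-MD workflow execution. It is a
deterministic function of `(configuration, seed)`: a smooth trend over the
input space plus a seed-indexed draw from a centred, unit-variance
skew-normal family (delta parameterization), scaled by
`seed_noise_scale`. Defaults plant:

* base level $-34.5$ kcal/mol, so pooled campaign means land near the
  scale a binding-affinity study reports;
* a low effective dimension: linear coefficients 2.0 (temperature), 0.6
  (box padding) and 0.4 (cutoff) kcal/mol per unit coordinate plus a 0.5
  temperature quadratic, making temperature carry ~88% of the parametric
  variance;
* seed noise with standard deviation 1.4 kcal/mol and skew-normal shape 4
  (population skewness ≈ 0.78), giving replica ensembles a spread of order
  1–2 kcal/mol, mild positive skewness, and a pooled standard deviation
  near 1.5 kcal/mol.

By default the noise depends on the seed *only*, so per-seed ecdfs across
configurations are coherent translations of one another — the structure a
p-box makes visible. The `seed_mix` knob multiplies the noise amplitude by
a linear function of the leading input to plant a seed-configuration
interaction; that is what strictly separates the per-replica CVR from the
ensemble-averaged one, and it is off by default. The 13 non-temperature
nominal values are synthetic placeholders in plausible simulation units;
only relative bounds enter the unit-cube mathematics. What the mock does
*not* emulate: force-field physics, correlations between inputs, drifts in
the skewness with the configuration mean beyond what `seed_mix` induces,
or heavy-tailed replica outliers — so passing tests validate the
statistical machinery, not any claim about real MD output.

## Problem sizes used in the tests

The suite exercises campaigns at deliberately small scale: fixed-plan
tables of 63 × 25 (matching a realistic ensemble-campaign layout) down to
6 × 8, adaptive budgets of 150–800 evaluations, full tensor boxes up to
level 4 in two dimensions and level 3 in three, $10^6$ samples for the
Monte-Carlo variance oracle and the Gaussian kurtosis reference, and
bootstrap sizes of 100–300 where only reproducibility (not CI accuracy) is
at stake. These sizes keep the full suite around half a minute while still
leaving every statistical tolerance comfortably met.

## Interfaces

The package is a library, not a shell tool: `run_pipeline()` orchestrates
synthesize → sample → Sobol → p-box/shapes → CVR over one output directory
(plan, history, table, reports, manifest), accepts a YAML or list
configuration, and `rerun_pipeline()` replays a manifest into
byte-identical tables. All tabular artifacts are headered CSV and all
reports JSON, so campaigns produced elsewhere can be analysed by reading
an evaluation table with `read_evaluation_table()`.
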