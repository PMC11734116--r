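---
title: "Methods: a Bayesian-network risk model for seabed mining impacts on benthic fauna"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Bayesian-network risk model for seabed mining impacts on benthic fauna}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chathamrisk)
```

## The model and its assumptions

`chathamrisk` represents the risk pathway from seabed-mining operations to
benthic fauna as a discrete Bayesian network: a directed acyclic graph whose
nodes are discrete variables and whose edges carry conditional probability
tables (CPTs), so that the product of the CPTs is the joint distribution over
all variables. Querying the network under *scenario evidence* — fixing the
operational decision variables and the spatial domain — yields exact posterior
distributions for every pressure and every biotic response node.

The shipped model covers three spatial domains (inside the mined block, the
near-field roughly 0.5 km out, the far-field to roughly 5 km) and two time
steps (immediately after disturbance, one year later). Impacts are expressed
as the *relative decrease in abundance* of fifteen trait-based benthic
functional groups, discretised into five 20-%-wide bins. Structural
assumptions worth making explicit:

* Impacts are homogeneous within a domain (the model is not spatially
  explicit) and only decreases in abundance are modelled; transient
  post-disturbance increases are outside scope.
* The immediate decrease separates a *direct* component (removal by the
  extraction tool, only inside the block) from an *indirect* component
  (suspended sediment, redeposition, contaminant release acting on the
  survivors); habitat alteration (sediment changes, nodule removal, food
  availability) affects only the one-year outcome.
* Decision variables (extraction depth, processing-return technique, mining
  intensity, distance, nodule removal) are controlled by the operator: they
  carry no CPT and are fixed as evidence in every scenario query. If one is
  queried without evidence it must be given an explicit prior in the
  configuration; the shipped configuration deliberately supplies none.
* State order is meaningful. Every ordinal scale runs from the least to the
  most adverse state for the affected child. For food availability this puts
  *increased* (post-disturbance organic enrichment, beneficial to grazing and
  scavenging epifauna) before *unchanged*; particle size is flagged nominal
  and takes no part in ordinal machinery.

## Exact inference

Posterior queries use sum-product variable elimination over the ancestral
subgraph of the query and evidence (barren descendants integrate to one and
are pruned). The elimination order is the min-fill heuristic with a
lexicographic tie-break, which is deterministic and adequate at this model's
treewidth. Normalisation happens once, at the end; evidence with probability
zero under the model raises an error rather than propagating `NaN`s. Two
independent oracles guard the implementation: `enumerate_joint()` multiplies
every CPT into the full joint table (guarded to state spaces of at most 10^6
entries) and `forward_sample()` draws ancestral samples; the test suite
requires elimination, enumeration and sampling to agree.

## CPT elicitation by best/worst-case interpolation

Full CPTs over many parents are too large to elicit directly. For an ordinal
child the package asks for the minimal input:

* a **best-case** beta distribution (every parent at its least adverse
  state) and a **worst-case** beta distribution (every parent at its most
  adverse state), with `mean(worst) >= mean(best)`;
* one weight `w_i >= 0` per parent and a score `s_i(state)` per parent state,
  nondecreasing over the ordinal order and spanning exactly [0, 1].

A parent configuration is positioned by the relevance index
`lambda = sum_i w_i s_i / sum_i w_i`, the beta parameters are interpolated
linearly, `alpha(lambda) = (1 - lambda) alpha_best + lambda alpha_worst` (and
likewise `beta`), and the interpolated distribution is discretised into the
decrease bins with the regularised incomplete beta function. The endpoints
reproduce the elicited distributions exactly, and because the interpolated
mean is a ratio of two linear functions of `lambda` it moves monotonically
from `mean(best)` to `mean(worst)`.

Interpolating in `(alpha, beta)` space is a design choice: interpolating
moments (mean and precision) instead would also be coherent, but the linear
parameter rule is the simplest scheme with exact endpoints and a provably
monotone mean, and the package's property tests (monotone mean on a 101-point
grid; ordinal coherence of the midpoint-weighted expected decrease under
single-parent state increases) document the behaviour users rely on. Nominal
parents bypass the method entirely — their CPTs are specified directly in the
configuration.

Empirical *best-case* distributions can be derived from before/after core
surveys: bootstrap resampling of cores (default 1000 replicates) turns count
tables into relative-decrease fractions, clipped to [0, 1], and
`fit_beta_moments()` converts them to beta parameters by the method of
moments (values are clipped to [0.001, 0.999] before fitting; degenerate
moments are an error that suggests a point-mass column instead).

## Deterministic impact constructors

**Direct removal.** Outside the block the direct decrease is zero. Inside,
the removed fraction is `p(intensity) in {0.5, 0.75, 1.0}` times
`1 - escape_fraction` times, for infaunal groups, a depth multiplier. The
resulting CPT is a point mass on the bin containing the fraction; fractions
landing exactly on a bin edge go to the lower-impact bin. Defaults: escape
fractions 0 (sessile epifauna, infauna), 0.2 (mobile epifauna), 0.3
(hyperbenthos); depth multipliers 0.8 / 0.95 / 1.0 at <10 / 10–30 / >30 cm,
encoding that shallow extraction spares deeper-dwelling infauna. Both are
reconstruction choices and both are configurable.

**Immediate combination.** With `D1` uniform on the direct bin and `D2`
uniform on the indirect bin, the survivors-multiply rule gives the total
decrease `T = 1 - (1 - D1)(1 - D2)`. Each CPT column is `P(T in bin k)`,
computed by midpoint quadrature on a 200 x 200 grid (configurable, minimum
50); the (0–20, 0–20) column has the closed form
`P(T <= 0.2) = 25 (0.2 + 0.8 ln 0.8)`, used as a test oracle together with a
Monte Carlo cross-check. `T >= max(D1, D2)` pointwise, so the combined
decrease stochastically dominates both inputs, and the construction is
symmetric in its arguments.

## The default configuration as a calibrated reconstruction

The original model's CPTs were elicited in expert workshops; the
configuration shipped here is a *reconstruction*: the variable roster, edge
rules, scenario definitions, elicitation structure (which parent matters most
for which group, with contaminant release always weighted lowest) and
confidence tags follow the original assessment, while the numeric pressure
tables and beta pairs were calibrated so that the assembled model reproduces
the qualitative posterior outcomes the original assessment reported — moderate suspended sediment
inside and near-field with low far-field; high deposition inside and low in
the far-field; unlikely contaminant release everywhere; significant sediment
change everywhere under high disturbance but confined to the block under
intermediate disturbance; 81–100 % immediate decrease inside for all sessile
and infaunal groups under both scenarios; 41–60 % (high) versus 21–40 %
(intermediate) near-field immediate decrease for macroinfauna; near-complete
one-year recovery of the soft-bodied group outside the block; and expected
decrease monotone over domains and scenarios for every group and time step.
These statements are exactly the calibration regressions in the test suite
and the acceptance script; nothing beyond them should be read into the
shipped numbers.

Two reconstruction decisions deserve a note. First, the original scenario
table fixes intensity, extraction depth and return technique; nodule removal
is set to *yes* under high disturbance and *no* under intermediate
disturbance, matching the narrative that a surface-collector operation leaves
most nodules in place. Second, the worst-case betas of the infaunal groups
are stronger than the qualitative "relatively tolerant to indirect impacts"
wording alone would suggest: with 50 % mining intensity the direct removal of
infauna caps at 0.4, so reproducing the reported 81–100 % most-likely
immediate decrease inside the block under the intermediate scenario requires
the indirect component to carry the remainder. The calibration follows the
reported posterior outcomes where the two conflict.

## Numerical choices and degenerate inputs

* Probability vectors must sum to one within `1e-9`; CPT columns off by at
  most `1e-6` are accepted (constructors renormalise), larger errors are
  validation failures. `validate_network()` returns a list of named
  violations rather than raising, so broken networks can be inspected.
* Ties in `most_likely_outcome()` break toward the lower-impact state, and
  bin assignment is right-closed (a fraction exactly on an edge goes to the
  lower bin).
* All randomness flows through explicit integer seed arguments; generators
  save and restore the ambient RNG state, so no global state leaks.
* The scenario-difference metric is the total-variation distance
  `TV = 0.5 sum_k |pA_k - pB_k|` alongside the signed difference in
  midpoint-weighted expected decrease (midpoints 0.1 ... 0.9).

## What the synthetic generators emulate — and what they do not

`random_dag()` / `random_cpts()` produce small random networks (parents drawn
only from earlier nodes in a shuffled order, Dirichlet CPT columns) purely to
exercise the inference machinery against the enumeration oracle; they have no
ecological content. `simulate_survey()` emulates the *statistical shape* of a
before/after multicorer survey: negative-binomial counts (overdispersed, as
patchy benthic cores are; dispersion is a parameter, default 5 in the tests)
with a group-specific relative decrease in the impacted arm. It does not
emulate spatial autocorrelation between cores, taxon-level heterogeneity
within a group, detection error, or temporal drift between surveys — so
passing the recovery tests shows the estimator chain is unbiased under the
assumed count model, not that real surveys are this well behaved.

The test and acceptance problem sizes are deliberate package choices: 50
random oracle networks of up to 10 nodes; 10^6 Monte Carlo draws per
combination check; surveys of 200 cores per arm with 1000 bootstrap
replicates over 10 seeds (at these sizes the per-seed sampling noise of the
recovered mean decrease is about 0.03, which is why recovery is asserted on
the seed average); 10^5 forward samples against exact marginals.

## Known limitations

Inference is exact only because the model is discrete and of modest
treewidth; approximate inference, continuous or hybrid nodes, structure
learning and time-sliced (dynamic) networks are out of scope, as are noise
and vibration pressures, non-benthic ecosystem components, spatially explicit
plume dispersion and socioeconomic decision layers. The acyclic structure
cannot express feedback between ecosystem components. Confidence tags are
carried as metadata on every output record but never alter probabilities.
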