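---
title: "Robustified tracer design for 13C metabolic flux analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robustified tracer design for 13C metabolic flux analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxred)
```

## The design problem

13C metabolic flux analysis (13C-MFA) infers intracellular reaction rates
(fluxes) from the isotope labeling patterns that a 13C-labeled substrate
mixture imprints on metabolic intermediates, typically measured as GC-MS
mass isotopomer distributions (MIDs) of proteinogenic amino acids.  How much
a labeling experiment can reveal depends critically on *which* tracer
mixture is fed: a poor choice produces measurements that are insensitive to
the fluxes of interest, at four-digit tracer prices.

Classical optimal experimental design scores a candidate mixture by the
Fisher information of the measurements at one assumed flux vector
$\mathbf{v}^\star$:
$$
\mathrm{FIM}(\mathbf{v}^\star, \mathbf{x}^{inp}, \Sigma)
  = \left.\frac{\partial \mathbf{y}}{\partial \mathbf{v}}\right|_{\mathbf{v}^\star}^{T}
    \Sigma^{-1}
    \left.\frac{\partial \mathbf{y}}{\partial \mathbf{v}}\right|_{\mathbf{v}^\star},
\qquad
\mathrm{Cov} = \mathrm{FIM}^{-1},
$$
where $\mathbf{y} = f(\mathbf{v}, \mathbf{x}^{inp})$ is the steady-state
labeling model, $\mathbf{x}^{inp}$ the tracer composition, and $\Sigma$ the
measurement covariance.  When no trustworthy flux estimate exists — new
organisms, unusual substrates — conditioning the design on a single
$\mathbf{v}^\star$ is circular: the design depends on the very fluxes the
experiment is meant to determine.

`fluxred` implements the *robustified* alternative: score every candidate
mixture over a uniform sample $V_{n_S} = \{\mathbf{v}_i\}$ of the **entire
feasible flux polytope**
$$
V = \{\mathbf{v} : S\mathbf{v} = 0,\; C\mathbf{v} \le c\},
$$
and aggregate three criteria per mixture:

* $\hat\Phi_{D,n_{act}}$ — the **median** over flux samples of the
  reference-normalized D-criterion
  $\Phi_{D,n_{act}} = \bigl(\det \mathrm{Cov}_{ref} / \det \mathrm{Cov}\bigr)^{1/(2 n_{act})}$,
  computed on the set of $n_{act}$ statistically identifiable ("active")
  fluxes.  Values above 1 mean "more precise than the reference mixture".
* $\Phi_{cover,n_{act}}$ — the **coverage**: the percentage of flux samples
  for which the mixture renders $n_{act}$ fluxes identifiable at all.  A
  mixture with high median precision but low coverage is a gamble; coverage
  is the robustness axis of the trade-off.
* $\Phi_\$$ — the tracer cost, summing fraction × required grams × price
  over all species.

The result is an exploratory data pool, not a single "optimal" answer: the
decision (which $n_{act}$ to target, how much coverage to require, how much
to spend) is deliberately left to the experimenter, made after inspecting
the aggregated metrics.

## The computational pipeline

```{r workflow, eval = FALSE}
model   <- parse_model("model.fml")                    # network + atom maps
catalog <- parse_tracer_spec("tracers.yml", model)     # priced species
samples <- sample_flux_space(model, n_samples = 1000, seed = 1)   # Phase I
grid    <- enumerate_mixtures(catalog, step = 0.1)
pool    <- run_red(model, catalog, grid, samples,      # Phase II
                   reference = mixture(...))
agg     <- aggregate_pool(pool)                        # Phase III
autoplot(agg)
```

**Free fluxes.**  The flux vector is parameterized by free coordinates: the
stoichiometric null space (one free net flux per degree of freedom,
$n - \mathrm{rank}$ after folding fixed rates such as the normalized uptake)
plus one exchange coordinate per bidirectional reaction, with
$fwd = \max(net, 0) + xch$, $bwd = \max(-net, 0) + xch$.  The free set is
chosen deterministically by column-pivoted QR; ties follow reaction
declaration order.  Exchange fluxes are sampled and differentiated on their
natural bounded scale, so the D-criterion is defined on that
parametrization.

**Sampling (Phase I).**  Uniform draws from the polytope come from
hit-and-run MCMC started at the Chebyshev center (found by linear
programming).  Directions are isotropic Gaussian after per-coordinate
pre-scaling by the chord widths through the center, which helps mixing on
elongated flux polytopes.  Defaults: burn-in 1000 steps, thinning
$\lceil d^2 \rceil$ where $d$ is the polytope dimension, $n_S = 1000$
samples.  These are conservative conventions, not inferences; the seed and
settings are recorded in the sample set and the pool.  Degenerate
(lower-dimensional) polytopes are rejected with guidance to convert
near-equality constraints into equalities.  A truncated-Gaussian target for
prior-informed sampling would reuse the same chain and is a natural
extension hook, but only the uniform target is implemented.

**Labeling simulation.**  The steady-state measurement model is evaluated by
elementary metabolite unit (EMU) decomposition: each measured fragment is
traced back through the atom transitions to the minimal set of
carbon-position subsets whose flux-weighted balances close; condensation
reactions enter as convolutions of strictly smaller EMUs, which keeps each
size level linear.  Level systems are solved densely (they stay small for
networks in the tested range); a pool with no production throughput makes
the level matrix singular and is reported by name rather than silently
zeroed.  An independent cumomer-cascade implementation — brute-force over
all $2^n$ carbon subsets per metabolite — serves as the oracle: the test
suite pins EMU against cumomer results to $10^{-8}$ on every fixture.
Substrate pools are boundary conditions: species patterns with purity
$p$ atom% become independent per-position Bernoulli isotopomer
distributions ($^{13}$C with probability $p/100$ at nominally labeled
positions, optionally a natural-abundance background at unlabeled ones,
default 0), mixed by the tracer fractions.

**Sensitivities.**  Jacobians $\partial \mathbf{y}/\partial \mathbf{z}$ with
respect to the free coordinates are computed by implicit differentiation of
the EMU cascade (per level, solve $A\,dX = dB - dA\,X$ and propagate
derivative MIDs through the convolutions), with rate-measurement rows given
by the constant affine map.  At $net = 0$ the forward/backward split is
non-smooth; the right derivative is used and affected samples are flagged.
A central finite-difference oracle (step $10^{-6}$, shrunk near the
boundary) validates the analytic Jacobian to $10^{-5}$ relative error in
the tests.

**Identifiability and active fluxes.**  The FIM of a mixture at a flux
sample is often singular — some fluxes are simply not determined by the
measurements there.  Fluxes are removed (conceptually fixed to their sample
value) until the restricted FIM passes two thresholds: minimal singular
value $\ge$ `sv_rel` $\times \lVert \mathrm{FIM} \rVert_2$ (default
$10^{-9}$, relative to the spectral norm of the **full** FIM) and condition
number $\le$ `cond_max` (default $10^{10}$).  Anchoring the floor to the
full FIM's norm makes admissibility monotone under taking principal
submatrices (eigenvalue interlacing), which guarantees the observed
behavior that coverage never increases with $n_{act}$, and gives the
one-flux partial designs a meaningful absolute scale.  Removal is greedy —
drop the flux with the largest component in the singular vector of the
smallest singular value, ties by declaration order — which matches the
iterative practice in the field; for problems up to
`exhaustive_limit = 12` fluxes an exact subset enumeration (minimal
$\det \mathrm{Cov}$ among admissible equal-size sets) is available and is
used as the oracle against the greedy chain.  All three knobs live in
`identifiability_control()` and are recorded in the pool's provenance.

**The D-criterion exponent.**  The determinant ratio is raised to
$1/(2 n_{act})$, so the criterion reads as a geometric-mean
standard-deviation ratio; `exponent = 1/n_act` switches to the
variance-ratio convention.  The reference covariance is recomputed per
candidate *on the candidate's active set* at the same flux sample; if the
reference mixture cannot identify that set, the record carries a
reference-degenerate flag and the median simply ignores it.

**Aggregation conventions.**  The median $\hat\Phi_{D,n_{act}}$ is taken
over the samples that achieve $n_{act}$ — the achieving fraction *is* the
coverage, so no information is lost by the restriction.  Samples whose
labeling system fails to simulate (zero-throughput pools at extreme flux
constellations) count as non-covering and are flagged separately.  Costs
use grams = concentration (g/L) × dilution rate (1/h) × working volume (L)
× duration (h), duration = residence times / dilution rate — the standard
chemostat bookkeeping in which the dilution rate cancels.

## File formats

Models are read from a documented subset of the FluxML XML dialect —
`<reactionnetwork>` with letter-coded atom transitions, `<constraints>`
(net/exchange bounds, fixed fluxes, linear inequalities), `<measurement>`
with MS groups, the affine error model
$\sigma(y) = 4.120\cdot 10^{-2}\, y + 6.655\cdot 10^{-3}$ (the default
GC-MS literature-survey coefficients, overridable per model), rate
measurements and an optional normalization flux.  NMR and isotopologue
measurement types of the full standard are rejected with a clear message;
carbon positions are 1-based in files.  Annotated examples ship in
`inst/extdata/`.  Tracer catalogues are YAML (or an equivalent XML
rendering).  Pools, sample sets and polytopes export to plain CSV with a
JSON provenance sidecar; `read_pool()` restores an aggregated pool
identically.  Everything is text, so pools diff and version cleanly.

## What the bundled fixtures emulate — and what they do not

`make_chain()` (linear pathway) has analytically known behavior: the
terminal MID equals the substrate MID and the labeling Jacobian is zero —
the degenerate baseline every simulator must reproduce.
`make_branch_cycle()` is the smallest network exhibiting the phenomenon the
coverage criterion exists for: two cleavage routes deliver different carbon
pairs to a common pool, one route passes a carbon-permuting isomerase and a
bidirectional cleavage.  Its manifest names one mixture that identifies all
3 free fluxes and one (fully unlabeled) that is design-singular.  Both
routes are constrained to carry at least 5% of the uptake and the exchange
is capped at 50% — with a vanishing route flux its exchange would be
inherently non-identifiable and no mixture could guarantee full coverage.
`make_clavam_analog()` is a reduced two-substrate central-metabolism
analog (glycerol-like 3-carbon plus amino-acid-like 5-carbon feed,
glycolysis, a pentose-phosphate-like recycle, a TCA-like cycle with
CO2-balanced anaplerosis, and a condensation product pathway; 10 free
fluxes).  Its two price anchors (0.36 \$/g unlabeled glycerol, 3,449 \$/g
uniformly labeled amino acid) are market values; the remaining prices are
synthetic placeholders flagged in the manifest, and the stoichiometry is
structure-matched, **not** a reconstruction of any published genome-scale
or core model.  Passing tests on these fixtures therefore demonstrates the
correctness of the machinery (simulation, sensitivities, selection,
aggregation), not the biological conclusions one would draw for a real
organism — those require the organism's own validated model and price
list.

Test problem sizes are deliberately modest so the whole suite runs in about
a minute: sampler moment checks use 5,000–20,000 draws on boxes, the
EMU–cumomer battery 10 flux samples × 5 mixtures per fixture, pipeline
checks 1–50 flux samples with handfuls of mixtures.  A production scan
(1,000 samples × 18,876 mixtures) is embarrassingly parallel over flux
samples; the per-record contract is order-independence, verified in the
tests.

## Known limitations

* Isotopically nonstationary (INST) labeling dynamics are out of scope; the
  simulator assumes isotopic steady state.
* Natural-abundance correction matrices for derivatization atoms are not
  modeled; the affine error model is taken to absorb that contribution.
* Only the D-criterion is implemented; the covariance machinery is generic,
  so A- or E-type criteria would be a small addition, but none is exposed.
* The cumomer oracle enumerates $2^n$ subsets per metabolite and is capped
  at 14 carbons per pool — it is a verification device, not a production
  path.
* Multi-objective (Pareto) optimization over the three criteria is
  intentionally absent: the package's contract is the exploratory pool.
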