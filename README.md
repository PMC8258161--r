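# fluxred

Robustified experimental design of isotope tracer experiments for
¹³C metabolic flux analysis (¹³C-MFA).

## The problem

¹³C-MFA measures intracellular reaction rates (fluxes) by feeding a mixture
of ¹³C-labeled substrates and fitting an atom-transition model to the
resulting GC-MS mass isotopomer distributions.  The choice of the tracer
mixture decides whether the experiment is informative or a four-digit-cost
blank — and classical design tools score mixtures at a *single assumed flux
vector* **v**\*, which is circular when no reliable flux estimate exists
(new strains, unusual substrates).

`fluxred` is for experimenters and modelers planning the *first* labeling
experiment for such a system.  Instead of one flux guess it scores every
candidate mixture over a uniform sample {**v**ᵢ} of the entire feasible flux
polytope *V* = {**v** : S**v** = 0, C**v** ≤ c} and aggregates, per mixture
**x**ⁱⁿᵖ and design size *n*<sub>act</sub>:

- **Φ̂<sub>D,n_act</sub>** — median over flux samples of the
  reference-normalized D-criterion
  (det Cov<sub>ref</sub> / det Cov)<sup>1/(2·n_act)</sup>, with
  FIM = Jᵀ Σ⁻¹ J and Cov = FIM⁻¹ restricted to the *n*<sub>act</sub>
  statistically identifiable ("active") fluxes; > 1 beats the reference
  mixture;
- **Φ<sub>cover,n_act</sub>** — *coverage*: the percentage of flux samples
  for which the mixture identifies *n*<sub>act</sub> fluxes at all — the
  robustness criterion;
- **Φ<sub>$</sub>** — tracer cost (fraction × required grams × $/g price).

The machinery underneath: a FluxML-subset XML reader for networks with
carbon atom transitions, hit-and-run sampling of the flux polytope, EMU
(elementary metabolite unit) labeling simulation with an independent
cumomer-cascade oracle, analytic Jacobians by implicit differentiation, and
singular-value-based active-flux selection.

## Worked example

The bundled generator `make_clavam_analog()` builds a reduced two-substrate
central-metabolism network (3-carbon glycerol-like and 5-carbon
amino-acid-like feed, 10 free fluxes, 7 MS fragment groups, 3 rate
measurements) with a priced 4 + 3-species tracer catalogue.

```r
library(fluxred)

fx      <- make_clavam_analog()
samples <- sample_flux_space(fx$model, n_samples = 25, seed = 42)
#> <flux_sample_set> 25 samples x 10 coordinates (seed 42, thinning 100)

ref  <- mixture(fx$facts$reference_mixture)   # 100% 2-13C1 + 100% 5-13C1
pool <- run_red(fx$model, fx$catalog, list(
  mix1 = mixture(GLYCx = c("2-13C1" = 1), ARGx = c("U-13C5" = 1)),
  mix2 = mixture(GLYCx = c("12C" = 0.5, "2-13C1" = 0.4, "1,3-13C2" = 0.1),
                 ARGx  = c("12C" = 0.5, "5-13C1" = 0.4, "U-13C5" = 0.1)),
  mix3 = mixture(GLYCx = c("U-13C3" = 0.1, "12C" = 0.9),
                 ARGx  = c("U-13C5" = 0.4, "12C" = 0.6))),
  samples, reference = ref)

dplyr::filter(aggregate_pool(pool)$metrics, n_act == 8)
#> # A tibble: 3 × 5
#>   mixture n_act phi_d_med coverage   cost
#>     <int> <int>     <dbl>    <dbl>  <dbl>
#> 1       1     8     1.25        96 17083.
#> 2       2     8     0.358       92  9171.
#> 3       3     8     0.438       88  1902.
```

Read: targeting 8 identifiable fluxes, the all-labeled `mix1` identifies
them for 96% of the sampled flux space and is ~25% more precise than the
reference (Φ̂ = 1.25) at ~17.1 k$; the diluted `mix2` keeps 92% coverage at
about half the price but lower precision; the cheap `mix3` (10% uniformly
labeled glycerol) still covers 88% at 1.9 k$.  `autoplot(aggregate_pool(pool))`
draws the Φ̂–coverage scatter colored by cost; `ternary_slice()` +
`plot_ternary()` give mixture-triangle views.

Per-flux (dimension-reduced) designs ask whether one flux of interest is
identifiable on its own:

```r
partial_design(pool, "net.arg_in")
#> # A tibble: 3 × 5
#>   mixture ident_freq  sd_q1 sd_med  sd_q3
#>     <int>      <dbl>  <dbl>  <dbl>  <dbl>
#> 1       1          1 0.0749 0.0790 0.0815
#> 2       2          1 0.0903 0.0905 0.0906
#> 3       3          1 0.0880 0.0889 0.0892
```

(the amino-acid uptake is rate-measured, so every mixture pins it — with a
standard deviation set by the rate error, not the labeling).

Models come from FluxML-subset XML files and tracer catalogues from YAML;
annotated examples live in `inst/extdata/`, and
`vignettes/robust-tracer-design.Rmd` documents the model, the
identifiability thresholds, and the numerical choices.  A thin CLI over the
same functions is in `inst/cli/red.R`
(`Rscript red.R sample|scan|aggregate|partial ...`).

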