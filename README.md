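# pulseCR

Microbial community assembly under continuous versus pulsed resource supply.

Theory in microbial ecology usually assumes resources flow in continuously
(a chemostat at steady state), while experiments overwhelmingly use
serial-batch culture, where resources arrive as large discrete pulses and
cells are diluted at each transfer. `pulseCR` asks the question that matters
for anyone designing or optimising a microbial community against either kind
of system: **do the same species win under both supply regimes?**

It answers it by simulation of the classical consumer-resource competition
model. For consumer *i* (density *N_i*) and resource *j* (concentration
*R_j*):

    dN_i/dt = N_i ( Σ_j μ_ij(R_j) − m )
    dR_j/dt = Ψ_j(R_j) − Σ_i Q_ij μ_ij(R_j) N_i

with the Monod functional response μ_ij(R) = μ_max,ij · R / (K_s,ij + R),
per-capita dilution mortality *m*, resource quotas *Q_ij*, and chemostat
supply Ψ_j(R_j) = D (S_j − R_j). Under **pulsed supply** the Ψ and m terms
are switched off and replaced by discrete events every *T* hours: cells are
transferred with survival e^(−mT) and resources replenished by D·S_j·T, so
total resource flux and total mortality are identical for every pulsing
interval — less frequent replenishment simply means bigger pulses.

The package provides:

- **model_core / regimes** — the dynamical system (substitutable or
  essential/Liebig resource use) with a compiled right-hand side, integrated
  by `deSolve::lsoda` with exact-time pulse events, plus pure-R reference
  implementations (`rhs_continuous()`, `rhs_batch()`, `apply_pulse()`);
- **sampling** — a randomised trait generator for 5-consumer × 5-resource
  communities whose minimum doubling times span 21–52 min, with an optional
  gleaner–opportunist trade-off `affinity = c · μ_max^(−θ)` between maximum
  growth rate and substrate affinity (μ_max/K_s);
- **metrics** — persistence sets, Jaccard compositional overlap between each
  pulsed community and its continuous-supply baseline, richness, and
  abundance-weighted mean traits;
- **stability** — the continuous-supply equilibrium (root-refined) and the
  leading eigenvalue of its Jacobian, paired with the variance of overlap
  across pulsing intervals;
- **experiment** — a declarative, seed-provenanced orchestrator
  (`run_experiment()`, `reduced_run()`), YAML configs, JSON manifests that
  reproduce every table byte for byte, and a thin CLI
  (`inst/scripts/pulsecr.R`).

## Worked example

Ten random competitor combinations under the growth–affinity trade-off,
simulated under continuous supply and pulsing every 0.5–24 h:

```r
library(pulseCR)

cfg <- experiment_config(
  sampler = sampler_config(tradeoff = "strict", n_combos = 100, seed = 1),
  compute_stability = FALSE
)
exp10 <- reduced_run(cfg, 10)
exp10
#> <crm_experiment> 10 combos; tradeoff = strict; rule = substitutable
#> # A tibble: 7 × 9
#>   regime interval_h mean_jaccard se_jaccard mean_richness mean_weighted_affinity
#>   <chr>       <dbl>        <dbl>      <dbl>         <dbl>                  <dbl>
#> 1 conti…       NA         1          0               1.2                    5.08
#> 2 0.5           0.5       0.75       0.0945          1.62                   4.89
#> 3 1             1         0.367      0.0988          1.6                    3.97
#> 4 2             2         0.117      0.0611          1.6                    2.82
#> 5 4             4         0.0333     0.0333          1.4                    2.36
#> 6 12           12         0          0               1.12                   2.17
#> 7 24           24         0          0               1.1                    2.31
```

Reading the table: `mean_jaccard` is the average similarity between the
species that persist under pulsing and those that persist under continuous
supply for the *same* competitors — here it collapses from 0.75 at half-hour
pulses to zero overlap at 12–24 h, i.e. serial-batch conditions assemble an
entirely different community than a chemostat. `mean_weighted_affinity`
falls as the interval grows (high-affinity gleaners lose their advantage)
while richness peaks at intermediate intervals, where gleaners and
fast-growing opportunists coexist. `n_excluded` counts runs that had not
settled by the horizon; they are left out of the means.

Single draws are available too:

```r
tr <- sample_traits(sampler_config(tradeoff = "strict", seed = 1))
round(min_doubling_time(tr), 1)
#>  sp1  sp2  sp3  sp4  sp5
#> 29.2 32.5 38.8 49.2 27.3
sim <- simulate_community(model_spec(tr), supply_regime("pulsed", interval_h = 24))
```

## Further reading

The methods vignette (`vignettes/pulsed-vs-continuous.Rmd`) documents the
model assumptions, the trait generator and its calibration, the numerical
choices (pulse event handling, steady-state detection, extinction
thresholds), and known limitations.
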