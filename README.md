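# smrmap

Bayesian spatio-temporal disease mapping of standardized mortality
ratios (SMRs) for small administrative areas, with a fully synthetic,
ground-truth-known data generator so that every stage of the analysis is
testable without access to confidential registry microdata.

## Who this is for

Epidemiologists and biostatisticians analysing cause-specific death
counts aggregated by small area (e.g. ~2,500 municipalities), calendar
period and age, who want smoothed small-area mortality maps and
covariate effects with honest uncertainty, in the presence of areas far
too small for stable crude rates.

## The model

Deaths are first indirectly standardized: with nationwide age-specific
reference rates \(r_b\) (5-year bands \(b\), pooled over all periods),
the expected count in area \(i\), period \(t\), coarse age group \(a\)
is

\[ E_{ita} = \sum_{b \in a} \mathrm{PY}_{itb} \, r_b . \]

Counts are then modelled per coarse age group (<55, 55–74, 75+) as

\[ y_{it} \sim \mathrm{Poisson}(E_{it}\, \rho_{it})
   \quad\text{or}\quad
   y_{it} \sim \mathrm{NB}(\mu = E_{it}\,\rho_{it}, \kappa), \]

\[ \log \rho_{it} = \alpha + \beta^{\mathrm{per}}_{t}
   + \beta^{\mathrm{lang}}_{\ell(i)} + \beta^{\mathrm{urb}}_{u(i)}
   + \phi_i \;(+\, \theta_i), \]

where \(\phi\) is an intrinsic conditional autoregressive (ICAR) spatial
field over the area adjacency graph (sum-to-zero per connected
component), \(\theta\) an optional exchangeable area effect
(BYM-type convolution), and the negative binomial variance is
\(\mu(1 + \mu/\kappa)\). The four canonical models — (Poisson | NB)
crossed with (spatial RE | spatial + unstructured RE) — are fitted by
adaptive Metropolis-within-Gibbs MCMC (C++ core) and compared by the
Deviance Information Criterion. Exponentiated coefficients are *SMR
ratios* relative to a reference level fixed at 1; an effect is
"significant" when its 95% credible interval excludes 1.

## Worked example

Simulate the documented synthetic study — a 20×20 lattice of units with
log-uniform population sizes, five periods with true period SMR ratios
(1.0, 0.8, 0.6, 0.45, 0.3), urban SMR ratio 0.85 and spatial standard
deviation 0.3 — then standardize and fit model 1 (Poisson + spatial RE)
for one age group:

```r
library(smrmap)
st  <- simulate_study(rows = 20, cols = 20, seed = 1)
rts <- compute_reference_rates(st$deaths, st$population)
ex  <- compute_expected(st$population, rts)
dg  <- aggregate_to_age_groups(st$deaths)
fit <- sample_posterior(dg, ex, st$covariates, st$graph,
                        model_spec("poisson", "spatial"),
                        config = mcmc_config(chains = 4, iterations = 5000,
                                             burn_in = 2500, thin = 10,
                                             seed = 1),
                        age_group = "55-74")
summarize_effects(fit)
```

```
SMR ratio summary (age group 55-74)
       effect          level smr_ratio          ci significant
       period             P1      1.00 (1.00;1.00)       FALSE
       period             P2      0.82 (0.74;0.92)        TRUE
       period             P3      0.59 (0.52;0.66)        TRUE
       period             P4      0.44 (0.38;0.50)        TRUE
       period             P5      0.27 (0.23;0.32)        TRUE
     language         German      1.00 (1.00;1.00)       FALSE
     language         French      0.88 (0.73;1.11)       FALSE
     language ItalianRomansh      0.93 (0.73;1.14)       FALSE
 urbanisation          rural      1.00 (1.00;1.00)       FALSE
 urbanisation          urban      0.84 (0.77;0.93)        TRUE
Spatial variation 0.27 (0.18;0.38)
```

The posterior medians recover the generating period ratios (0.8, 0.6,
0.45, 0.3) and the urban ratio (0.85) to within a few hundredths; the
spatial-variation estimate 0.27 (0.18; 0.38) brackets the generating
value 0.3. Reference levels are exactly 1 by construction. Language
effects, simulated as null, are correctly non-significant.
`smoothed_unit_smr(fit)` returns the per-(unit, period) smoothed SMRs
that feed a choropleth via `export_maps()`, and `compare_models_dic()`
reproduces the four-model DIC table. `run_pipeline(run_config())` runs
everything end to end and writes all artifacts to disk.

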