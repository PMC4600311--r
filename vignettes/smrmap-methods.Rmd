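---
title: "Methods: spatio-temporal SMR mapping with smrmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatio-temporal SMR mapping with smrmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

smrmap estimates small-area mortality risk from counts that are far too
sparse for stable crude rates, by combining indirect age
standardization with hierarchical count regression and an intrinsic
conditional autoregressive (ICAR) spatial prior. This vignette is the
package's own account of the statistical choices, their defaults, and
their limits.

## The estimation problem

The data are death counts and person-years indexed by spatial unit,
calendar period and 5-year age band. A typical unit contributes a
handful of deaths per period; many contribute none. The crude
observed/expected ratio (SMR) of such a unit is dominated by Poisson
noise, so maps of raw SMRs mostly display population size. The model
borrows strength in two directions: across age (through indirect
standardization against a national reference schedule) and across space
(through the ICAR field, which shrinks each unit toward its
neighbours).

## Standardization

Reference rates are computed per 5-year band by pooling deaths and
person-years over **all** units and **all** periods. Pooling over
periods is deliberate: with a single all-period reference, the fitted
period coefficients are interpretable as temporal trends in mortality
relative to the study-wide level. Bands with zero person-years receive
rate 0, so expected counts remain defined everywhere. When the
reference rates come from the same data being standardized, total
expected equals total observed exactly; the test suite asserts this
closure identity at 1e-9 relative error.

Cause-of-death coding changes (e.g. a revision of certificate priority
rules) can be corrected by user-supplied multiplicative factors per
band and period, with `"*"` wildcards. The corrected counts are rounded
half-to-even so the count likelihood sees integers; rounding happens at
the (unit, period, band) level before any aggregation. The unrounded
pipeline remains available (`round_counts = FALSE`) for sensitivity
analysis. How such corrections should enter a Poisson likelihood is
genuinely underdetermined — rounding before aggregation is our
documented choice, not the only defensible one. No specific published
correction-factor values ship with the package; factors are
configuration.

Age is collapsed to three coarse groups (<55, 55–74, 75+) for
modelling, and models are fitted **separately per coarse group**: age
patterns of covariate effects are of direct interest, and separate fits
avoid imposing proportionality across groups. The upper band is taken
as 85+.

## The count model

For one coarse age group, with expected counts $E_{it}$,

$$y_{it} \sim \text{Poisson}(E_{it}\rho_{it}) \text{ or }
  \text{NB}(\mu = E_{it}\rho_{it}, \kappa),\qquad
 \log \rho_{it} = \alpha + \beta^{per}_t + \beta^{lang}_{\ell(i)}
 + \beta^{urb}_{u(i)} + \phi_i (+\,\theta_i).$$

The first level of each factor (first period, German, rural) is the
reference with coefficient pinned at 0; exponentiated coefficients are
SMR ratios. The NB variance is $\mu(1+\mu/\kappa)$, chosen for its
clean Poisson limit $\kappa \to \infty$ (which the tests exercise at
$\kappa = 10^8$, agreeing with Poisson to $10^{-6}$ per cell).
Covariates are fixed in time. The four canonical models cross family
(Poisson/NB) with random effects (spatial only / spatial +
unstructured); a non-spatial variant (`random_effects = "none"`) is
provided for preliminary, unsmoothed analyses and for calibration
checks where the classical effective-parameter count is known.

The spatial prior is the *intrinsic* CAR: conditionally,
$\phi_i \mid \phi_{-i} \sim N(\bar\phi_{\partial i}, \sigma_\phi^2/n_i)$
with $n_i$ the neighbour count. The ICAR is improper; identifiability
is restored by a sum-to-zero constraint per connected component of the
adjacency graph, with the intercept absorbing the field's level.
Degree-0 units ("islands") carry no spatial information and their
$\phi$ is pinned at 0; they still receive the exchangeable $\theta$ in
BYM-type models. Cells with $E = 0$ force $y = 0$ and contribute
nothing to the likelihood; $E = 0$ with $y > 0$ is rejected as
impossible under the model.

## Priors

All configurable; defaults are weakly informative on the scale of log
SMR ratios: $N(0, 10^2)$ on $\alpha$ and every $\beta$; half-normal(1)
on $\sigma_\phi$ and $\sigma_\theta$ (a prior median of 0.67, far above
any plausible spatial variation, so the data dominate); $N(0, 2^2)$ on
$\log\kappa$, spanning near-Poisson ($\kappa > 50$) to severe
overdispersion ($\kappa < 0.1$).

## MCMC

Metropolis-within-Gibbs with random-walk proposals on every scalar:
$\alpha$, each $\beta$, each $\phi_i$ (using the ICAR full conditional
as the prior term), each $\theta_i$, and the logs of $\sigma_\phi$,
$\sigma_\theta$, $\kappa$. Proposal scales adapt toward 0.44 acceptance
every `adapt_interval` (default 50) sweeps **during burn-in only**, so
the retained kernel is a fixed Markov kernel and detailed balance is
preserved. Two structural moves matter:

* **Re-centering.** After each sweep $\phi$ is centred to sum to zero
  within each component, and the size-weighted overall mean is
  transferred to $\alpha$. On a connected graph (every bundled
  geography) this transfer is exact — the likelihood is untouched. With
  several components the per-component shifts cannot all be absorbed by
  a single intercept; the centering then matches the long-standing
  WinBUGS `car.normal` practice.
* **Joint field–scale rescaling.** A proposal
  $(\phi, \sigma_\phi) \to (c\phi, c\sigma_\phi)$, $\log c \sim N(0, s^2)$.
  The ICAR prior ratio cancels against the $\phi$ part of the Jacobian,
  leaving the likelihood ratio, the half-normal prior and a single
  factor of $c$. Without it, single-site updates leave $\sigma_\phi$
  with high autocorrelation (potential scale reduction around 1.1 on
  the documented fixture); with it, all monitored parameters sit below
  1.05.

Defaults: 4 chains of 5,000 sweeps, 2,500 burn-in, thinning to at
least 100 retained draws per chain (enforced), intercept/coefficient
starts jittered $N(0, 0.2^2)$ per chain, variance parameters started at
their prior medians. Chains are bit-reproducible from the seed (chain
$c$ uses `seed + c` for initialization and `seed + 1000 + c` for its
sweep stream; the C++ core draws from R's RNG). The per-cell mean
matrix is maintained incrementally and refreshed exactly every 200
sweeps to stop multiplicative drift.

Convergence is monitored by the (non-split) Gelman–Rubin statistic with
the finite-sample correction; parameters above 1.1 are flagged.

## DIC and model choice

Per-draw deviances are stored during sampling; `dbar` is their mean and
`dhat` the deviance at the plug-in posterior mean of **all** quantities
entering the likelihood, including $\phi$ and $\theta$ — the "focused"
DIC of the original formulation. Alternative focuses (integrating out
the fields) are out of scope. Negative $p_D$ is reported with a flag,
never hidden. Ties in model selection break toward simplicity: fewer
random-effect sets, then Poisson over NB. On Poisson-generated data the
DIC margin between the generating model and its BYM extension is small
(a few units) — an honest reflection of DIC's weak penalization of
nearly-null random effects — so selection consistency is asserted as a
replicate-majority property (at least 7 of 10), not per dataset.

Posterior point estimates are **medians** (robust under the
exponential transform to the ratio scale; for any monotone transform
the median commutes, so ratio medians equal exponentiated coefficient
medians). Central 95% intervals; significance = interval excludes 1;
reference levels are emitted as exactly 1.

## The synthetic-data generator

The generator emulates the *statistical structure* the analysis
assumes, with known ground truth:

* geography: a rook-adjacency lattice (default 20×20) standing in for a
  municipality mosaic; polygon (queen/rook) and edge-list constructors
  cover irregular real geographies;
* population: unit-period person-years log-uniform in [500, 50,000] —
  heterogeneity spanning two orders of magnitude, as in real
  municipality systems — split deterministically over 18 five-year
  bands by a stylized female age profile;
* covariates: language regions grown as contiguous blocks by seeded
  multi-source BFS (so language is spatially autocorrelated, and
  partially confounded with the spatial field, as in reality); urban
  status assigned to the largest units by population, ties broken by
  unit id;
* risk: period SMR ratios defaulting to (1.0, 0.8, 0.6, 0.45, 0.3) — a
  strong, plausible four-decade decline — urban ratio 0.85, null
  language effects, and an ICAR field with $\sigma_\phi = 0.3$, drawn
  exactly from $N(0, \sigma_\phi^2 Q^+)$ via the eigendecomposition of
  the ICAR precision per component (the pseudoinverse construction,
  stated explicitly because the ICAR is improper);
* counts: Poisson, or negative binomial in which the stated dispersion
  $\kappa$ applies to the (unit, period, coarse group) cells the models
  are fitted to. Band-level draws receive dispersion shares
  proportional to their means, so bands share a common success
  probability and their within-group sums are *exactly*
  NB$(\mu, \kappa)$. Simulating a fixed $\kappa$ at band level instead
  would attenuate under aggregation (roughly by the number of active
  bands), silently weakening any overdispersion scenario.

Reference rates default to a stylized schedule rising from $10^{-6}$
(childhood) to $2\times10^{-3}$ (85+) deaths per person-year, giving
registry-like magnitudes: many unit-period cells with expected counts
below 1 (the shrinkage regime) alongside well-populated urban cells.

What the generator does **not** emulate: the real Swiss population
pyramid or true municipality sizes, municipality fusions over time,
cross-border edge effects, non-proportional (age-varying) covariate
effects, space-time interaction, or period-specific spatial fields.
Passing tests therefore demonstrate correctness of the machinery and
calibration under the stated generating model — not robustness to the
many ways real registry data violate it.

## Problem sizes used by the checks

The recovery scenario fits 4×5,000 sweeps on the 20×20 lattice
(posterior medians within ±0.10 of the generating period and urban
ratios and of $\sigma_\phi$; 95% interval coverage of all coefficients
over 20 replicate studies). DIC selection consistency uses 12×12
lattices with 2×3,000 sweeps per model — sizes chosen so a full
replicate set runs on a single CPU in minutes while leaving the DIC
margins clearly resolvable. The shrinkage property is measured on the
<55 age group, whose expected counts are smallest.

## Known limitations

* Queen contiguity from polygons is vertex-based (shared vertices, two
  for rook), which assumes topologically consistent mosaics; no
  geometric snapping or repair is attempted. The contiguity rule for
  real municipality data is a modelling choice — corner-touching units
  do occur — and is switchable.
* DIC is the only model-choice criterion (no WAIC/LOO), matching the
  analysis this package operationalizes.
* The temporal structure is a fixed period factor plus one
  time-constant spatial field; temporal random walks and space-time
  interactions are deliberate non-goals.
* Single-site Metropolis on $\phi$ is adequate at these problem sizes;
  much larger graphs would warrant block updates.
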