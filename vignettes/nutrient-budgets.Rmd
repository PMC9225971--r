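---
title: "Nutrient import/export budgets from deer grazing surveys: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nutrient import/export budgets from deer grazing surveys: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deerflux)
```

## The accounting problem

Semi-natural open habitats of low nutrient status — dry heaths, lowland hay
meadows — are threatened by atmospheric nitrogen and phosphorus deposition.
Wild red deer (*Cervus elaphus*) move nutrients in both directions: grazing
removes N and P bound in forage, while dung and urine return them.
`deerflux` turns one year of raw field survey records into habitat-level
annual budgets of these two fluxes, with propagated uncertainty, and weighs
the net balance against deposition rates.

The survey design the package ships as its default is a 2 × 4 × 2 layout:
two habitat types, four sites per habitat, and two management treatments
(burnt B, untreated U) per site, observed on six sampling dates that bound
five consecutive periods tiling exactly one year. Dung is recorded on
dedicated dung plots — two flanking each U plot (averaged pairwise), one
adjoining each B plot — giving 16 plot series and 80 plot × period
observations per response variable. The design object is configurable, so
other layouts work unchanged.

## From pellet counts to dung mass

Dung input is estimated by the faecal accumulation rate method: plots are
cleared, and pellet groups accumulated since the previous visit are counted
(groups on the plot edge count as inside). Counts are corrected for decay
with site- and period-specific decay fractions $r$ estimated from marked
fresh pellet groups (a group counts as decayed when fewer than six pellets
remain):

$$ pg_{cor} = \frac{pg_{obs}}{1 - r/2}. $$

The factor $r/2$ rather than $r$ reflects deposition times being uniform
over a period: a group deposited mid-period is exposed to decay for half
the period on average, so the detection probability of a random group is
$1 - r/2$. The corrected count is kept as a real number and converted to
kg DM ha⁻¹ with the site × date mean dry mass of collected pellet groups
(five per site and date) and the plot area (default 225 m²). Fallbacks are
deliberately conservative: a missing site × period decay trial falls back
to the habitat × period mean, then to $r = 0$ (no correction) with a
warning; a missing site × date pellet mass falls back to the habitat × date
mean. With $r \le 0.3$, observed counts are 85–100% of the corrected ones.

## Concentrations, forage removal, and imputation

Fluxes are products of a mass term and a concentration (% of dry mass).
Because concentrations drift within a period, every period value is the
mean of the values at the period's bounding dates. The imputation ladder,
applied per endpoint and recorded in a provenance column, is:

1. a measured value is never altered;
2. a missing endpoint is replaced by the habitat × date mean;
3. plant concentrations missing at the first date by design are substituted
   with the final date's values (the same calendar month one year on);
4. if an endpoint has neither a measurement nor a fallback, the other
   endpoint stands alone — only when both ends fail is the period value
   missing (with a warning), and missingness then propagates; a missing
   value never becomes a zero anywhere in the pipeline.

Forage removal per plot and period is the difference in biomass increment
between a movable exclusion cage and the surrounding grazed sward, with
standing biomass derived from rising-plate compressed sward height through
a linear calibration against cut quadrats (`fit_calibration()`). Negative
removal values, which arise from measurement noise, are retained and
flagged rather than truncated — truncation would bias annual export upward;
users who prefer the truncating convention can apply it downstream. Burnt
heathland plots without a usable productivity calibration have structurally
missing export data and simply drop out of the habitat summaries for the
export variables.

## Fluxes

Per plot and period, faecal import is dung mass × faecal concentration,
with faecal concentrations measured at site level and shared by the site's
plots; export is removal × plant concentration at plot level. Urinary N is
not measured but estimated through an empirical allometric ratio of urinary
to faecal N excretion,

$$ U_{ratio} = \frac{11.56\,pN + 0.004/(pN\,w^{0.75}) + 0.078}
                    {0.05 + 0.00421/pN}, $$

with $pN$ the dietary N concentration as a mass *fraction* of dry matter
and $w = 100$ kg the default red deer body mass. Public interfaces take
concentrations in percent (as reported in the field); the conversion to
fraction happens inside — at deer scale the ratio is 0.6–0.9, and passing
percent by mistake inflates it by orders of magnitude, so values above 0.1
trigger a warning. The ratio is evaluated per observation at the plot's
period-mean plant N (the hand-pluck diet proxy) and rises with diet
quality; total N import is $faecal\,N \times (1 + U_{ratio})$. Averaging
per-observation ratios differs slightly from evaluating the ratio at the
mean diet (0.64 vs 0.65 at heathland-scale diets) — the per-observation
convention is the default. Urinary P is zero (P is excreted almost entirely
in dung), and urine is assumed to follow the spatial pattern of dung.

## Annual budgets and error propagation

For each habitat × period × variable the plot values are averaged (missing
plots reduce $n$; SE = SD/$\sqrt n$). Annual rates sum the five period
means; their SE is the square root of the summed squared period SEs
(independence across periods), and confidence intervals use $z = 1.96$.
The normal quantile rather than a $t$ quantile, and the no-covariance
assumption, are retained deliberately: they are the conventions under
which the published budget table's confidence intervals reproduce exactly
from its printed import/export columns (`net_balance()` propagates the
difference in quadrature). Treatments are pooled within habitats —
the treatments exist in the design for other purposes, and pooling yields
the canonical 80-observation layout.

Net balance Δ = import − export is negative when grazing removes more than
excreta return. Derived quantities: the net N:P export ratio
$|\Delta N| / |\Delta P|$ (reported to one decimal), deposition scenarios
$net = deposition + \Delta$ with a conservative variant using the upper CI
limit of Δ (the smallest net removal the data support — the number to hold
against a habitat's critical load), and net removal as a fraction of the
nutrient pool in annual aboveground production.

## The synthetic survey generator

`generate_survey()` exists so that every stage is testable without field
data. It draws, in one documented stream order (counts, decay trials,
masses, faecal then plant concentrations, forage, missingness) from a
single seed:

* pellet-group deposition per dung plot and period from a negative
  binomial with habitat-specific dispersion — heathland counts are
  strongly overdispersed (size ≈ 1.5) while grassland counts are close to
  Poisson, as the contrast between the two habitats' reported count SEs
  implies — with winter-heavy deposition in heathland and summer-heavy in
  grassland;
* observed counts by binomial thinning at detection probability
  $1 - r_{true}/2$, which makes the decay correction the exactly matched
  estimator;
* decay trials as Binomial($n_{placed}$, $r_{true}$); pellet masses
  lognormal; concentrations normal truncated to (0, 100), with
  habitat × date means built from annual grand means at the studied
  habitats' reported values times seasonal profiles (spring-peaking plant
  tissue, early-summer-peaking faeces); forage removal normal at plot
  level;
* the default study-like structural gaps: no plant samples at the first
  date, no forage for two burnt heathland plots, and ~15% of faecal
  concentration cells missing.

Residual (non-seasonal) noise magnitudes are back-of-envelope
reconstructions from reported standard errors — the source material prints
SEs of means, not plot-level SDs, so these defaults are documented
approximations. They are nonetheless observably study-like: the pipeline's
propagated relative annual SEs on default synthetic data fall in the same
band as the published CI widths imply (a property the test suite checks
against the shipped reference table).

`true_budget()` returns the closed-form expected annual fluxes implied by
a configuration (counts × masses × concentrations at their means, urinary
ratio at the mean diet), independent of any draw. A configuration with all
SDs, decay and missingness at zero and `count_model = "fixed"` makes the
full pipeline reproduce this truth to numerical precision — the package's
strongest end-to-end identity test.

### What the generator does not emulate

Real surveys have spatially autocorrelated deposition, observer effects,
non-normal concentration errors, and seasonal decay dynamics within
periods; none of these are modelled. Passing recovery tests on synthetic
data therefore demonstrates internal consistency of the estimator chain,
not field accuracy.

## Known limitations: CI coverage of the import components

Simulation at the default study-like configuration shows the annual
estimators are unbiased, but the propagated 95% CIs of the *import*
components are mildly anticonservative (empirical coverage of the truth
roughly 85–90% over replicates), while export components and net balances
are at or above nominal. The cause is structural: faecal concentrations
and pellet-mass means are measured at site level and shared by both plots
of a site, and adjacent periods share their boundary-date concentration,
so the between-plot, between-period independence that the Gaussian
propagation assumes does not fully hold. This is a property of the
published method itself, which the package reproduces deliberately; the
conservative scenario arithmetic (using CI limits) should be read with
that asymmetry in mind.

Budgets are excreta-versus-grazing only: volatilisation, leaching,
N₂ fixation, carcasses and antlers are outside the balance.

## Problem sizes and numerical choices

The shipped tests run the full pipeline on the 80-observation default
layout; recovery properties use 200 replicate surveys, and the
error-propagation Monte-Carlo oracle uses 10⁵ replicates of the period
summaries — sizes chosen to keep Monte-Carlo error well below the asserted
tolerances. Ties and degenerate inputs are handled explicitly: a period
summary from a single plot gets SE 0 with a warning, an all-missing
summary is missing (never zero), `r` outside [0, 1] and concentrations
outside (0, 100) are rejected at validation, and a missing U-subplot makes
the plot-period missing rather than averaging one side against unknown
exposure.

## A worked run

```{r example}
ds <- generate_survey(synthetic_config(), seed = 42)
fit <- nutrient_budget(ds)
fit
round(fit$np_ratio, 1)
fit$scenarios
```

The negative balances mean the simulated deer remove more N and P than
their excreta return, and the conservative heathland N scenario shows how
close deposition comes to cancelling that removal.
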