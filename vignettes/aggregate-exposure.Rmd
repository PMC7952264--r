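---
title: "Lifestage-resolved aggregate oral exposure: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lifestage-resolved aggregate oral exposure: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggexpo)
```

## The model

`aggexpo` estimates deterministic, central-tendency oral doses of a single
chemical from ten ingestion media — soil, dust, drinking water, breastmilk
and six food groups (dairy, meat, fish, vegetables, fruit, grains) — and
aggregates them across a 70-year lifespan split into seven lifestages.

For one medium and one age group the average daily dose is

$$\mathrm{ADD} = \frac{C \times \mathrm{IR} \times \mathrm{EF} \times \mathrm{ED}}{\mathrm{AT} \times \mathrm{BW}}$$

- $C$: mean concentration in the medium, mg/g for solids and foods,
  mg/mL for liquids;
- $\mathrm{IR}$: intake rate — mg/day for soil and dust, mL/kg-day for
  water and breastmilk, g/kg-day for foods;
- $\mathrm{EF}$ (days/year), $\mathrm{ED}$ (years), $\mathrm{AT}$ (days):
  frequency, duration and averaging time of exposure;
- $\mathrm{BW}$: body weight, kg.

The single displayed equation hides a unit subtlety that the implementation
makes explicit per intake-rate class. Soil and dust intake rates are mass
rates *not* normalised to body weight, so the mg/day rate is converted to
g/day ($10^{-3}$) to cancel the mg/g concentration, and the result is
divided by body weight. Water, breastmilk and food intake rates are already
per-kg rates, so the $\mathrm{BW}$ divisor is suppressed (set to 1):
dividing again would double-count body weight and the result would not be
in mg/kg-day. This interpretation-by-unit-class is a deliberate design
decision; it is the only reading under which all ten media yield mg/kg-day.

Under the chronic central-tendency scenario used throughout —
$\mathrm{EF} = 365$, $\mathrm{ED}$ equal to the age-group span, and
$\mathrm{AT} = \mathrm{ED} \times 365$ — the time terms cancel and each
dose reduces to $C \times \mathrm{IR}$ (over $\mathrm{BW}$ for soil and
dust). The package still carries all five variables so that sub-chronic
scenarios (EF < 365, AT decoupled from ED) can be expressed through a
user-supplied factor table.

## Age groups and lifestages

Doses are first computed on the eleven-age-group grid used by exposure
factor handbooks: four sub-year groups (birth–<1, 1–<3, 3–<6, 6–<12
months), six further childhood groups, and one adult group (21–<70 y).
Intervals are half-open, so the adult group spans 49 years. The seven
lifestages regroup these by time-weighted averaging:

$$\mathrm{ADD}_j = \frac{\sum_i \mathrm{ADD}_i \, Y_i}{\sum_i Y_i},$$

where $Y_i$ is each member's length in years. Sub-year members carry exact
month fractions (1/12, 2/12, 3/12, 6/12) rather than rounded day counts,
because the groups are defined in months; only the young-infant (four
members, 1 year) and infant (two members, 2 years) lifestages actually
combine groups. The lifestage durations are 1, 2, 3, 5, 5, 5 and 49 years
and sum to 70.

Lifetime average daily doses rescale each lifestage by the time spent in
it, $\mathrm{LADD}_j = \mathrm{ADD}_j \, Y_j / L$ with lifespan $L = 70$
years by default ($L$ is a parameter of `regroup_lifestages()` because
other horizons are legitimate uses). Percent contributions divide each
medium's lifestage ADD by the lifestage total.

Three aggregate rows — childhood (birth–<21 y), adult, lifetime
(birth–<70 y) — are stored alongside the lifestages. Whether such
aggregate bars should be time-weighted means or simple means of lifestage
values is genuinely open; we use time-weighted means, consistent with the
definition of $\mathrm{ADD}_j$ itself. This choice makes the lifetime row
per medium algebraically equal to $\sum_j \mathrm{LADD}_j$, an identity
the tests assert. Aggregate LADD rows use their own durations (21, 49, 70
years), so the lifetime LADD equals the lifetime ADD.

## Non-detect policies

Concentration summaries from raw samples support four substitutions for
observations below the limit of detection (LOD):

- **exclude** (default): detects only; if *all* samples are censored the
  mean is flagged undefined rather than silently set to 0;
- **lod_over_sqrt2**: each censored sample becomes $\mathrm{LOD}/\sqrt 2$,
  a standard substitution when the censored fraction is modest;
- **half_lod_split**: half the censored samples take the full LOD, half
  take LOD/2 — the convention some water-quality monitoring programs use.
  The split is deterministic by input order and an odd count gives the
  extra sample the full LOD; determinism was preferred over random
  assignment so that runs reproduce exactly;
- **zero**: censored samples contribute 0 (a lower bound).

When the LOD is reported as a range, substitutions use the midpoint — the
least-assuming point estimate in the absence of a stated rule. For
chemicals whose parent compound is measured through components (e.g.
metabolites in breastmilk), `metabolite_sum_proxy()` sums component means
and records their provenance.

## Bundled data

Three case-example concentration tables are packaged
(`load_fixture()`): DEHP in all ten media, manganese in all ten, and
endosulfan sulfate in the six food media before the 2010 US phase-out and
in only vegetables and fruit after it. These are published study-level
summary statistics (mean, median, SD, n, detection frequency, LOD range),
not raw samples, so the censoring policies are exercised on synthetic data
instead. Media missing from a table are represented downstream as explicit
zero columns flagged `absent` — never dropped — so stacked bars remain
comparable across chemicals and time periods.

The bundled exposure-factor table (`default_exposure_factors()`) holds
**representative placeholders**: per-capita central-tendency intake rates
and mean body weights of handbook style and magnitude, chosen once to be
realistic for a US general population, not a transcription of any handbook
edition. Two structural rules are encoded: soil and dust intake is zero
for the birth–<1-month group (no hand-to-mouth ingestion data exist for
newborns), and the sub-year water/breastmilk rates describe an exclusively
breastfed scenario (large breastmilk volumes, small water volumes).
Conclusions that depend on the *relative* size of intake rates — e.g.
which medium dominates a lifestage — are conditional on these values;
assessments should substitute the current handbook values via a factor
CSV.

## Synthetic data

`simulate_concentration_samples()` draws lognormal concentrations —
the canonical shape for environmental concentration data — and censors a
fixed fraction at an empirical detection limit (the lowest
$\lfloor fn \rceil$ samples, LOD at the censoring threshold). It attaches
the closed-form mean $e^{\mu + \sigma^2/2}$ so recovery by the summary
policies can be tested. It emulates a single homogeneous study; it does
not emulate between-study heterogeneity, varying LODs within a study,
measurement error, or correlations between media, so passing recovery
tests says nothing about combining real heterogeneous sources.
`simulate_exposure_factors()` jitters the bundled table with lognormal
noise (CV 0.2, mean-preserving) while keeping the chronic time terms and
structural zeros intact.

## Numerical choices

- Doses are carried at full double precision end to end; CSV outputs are
  written with 17 significant digits so that files round-trip bit-exactly
  (display rounding is left to the reader).
- Zero-total percent rows return zeros plus a machine-readable `empty`
  flag instead of NaN, so an all-censored or all-absent chemical still
  renders.
- Degenerate inputs fail loudly: $\mathrm{AT} = 0$ or $\mathrm{BW} = 0$,
  negative inputs, unit mismatches, unknown media or age-group labels, and
  duplicate factor rows are rejected with the offending coordinates.
- Figures are never the testing surface: every figure is accompanied by a
  sidecar CSV of exactly the plotted values, and all assertions run
  against sidecars.
- Media stack in a fixed order (soil, dust, water, breastmilk, dairy,
  meat, fish, vegetables, fruit, grains) with a fixed colour map across
  all figures of a run.

## Verification

The test suite checks the engine against independent oracles: the dose
equation against a direct scalar transcription on 1,000 random factor
records (relative tolerance $10^{-12}$), and the lifestage regrouping
against a brute-force month-expansion (each age group replicated by its
length in months, then plainly averaged; tolerance $10^{-9}$). Algebraic
identities — lifestage LADDs summing to the lifetime aggregate, percent
rows totalling 100, linearity in concentration, ED-independence of the
chronic scenario — are asserted on randomly generated grids. Parameter
recovery uses 10,000 lognormal samples and a 3-standard-error band.
These problem sizes keep the full suite under a minute while leaving the
Monte-Carlo checks well-powered.

## Limitations

Oral route only; deterministic point estimates, no probabilistic
distributions or uncertainty whiskers; no prenatal lifestage, dermal or
inhalation routes, PBPK modelling, or formula-feeding scenarios; no
sex-stratified factors; concentrations are assumed constant over the
lifespan, and each lifestage's LADD averages only that lifestage's intake
over the lifetime, so summing LADDs understates total lifetime exposure
when media coverage differs by age.
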