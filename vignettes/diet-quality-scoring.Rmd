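---
title: "Energy-adjusted diet quality scoring: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-adjusted diet quality scoring: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(dietscore)
library(dplyr)
```

## The model

`dietscore` scores the healthiness of a 24-hour dietary intake with a single
number on \[0, 1\], built from three components:

1. **Nutrient subscores.** Sixteen index nutrients — thirteen *adequacy*
   nutrients (carbohydrate, protein, total fat, fiber, potassium, calcium,
   magnesium, iron, food folate, vitamins A, D, E, C) and three *moderation*
   nutrients (sodium, saturated fat, added sugars) — are each scored with a
   piecewise-linear function of the day's intake. Adequacy nutrients use a
   trapezoid with abscissae $A < B \le C < D$: zero at or below $A$, a
   linear rise to a full-score plateau on $[B, C]$, a linear fall to zero at
   or above $D$. Moderation nutrients keep the full score from zero intake
   up to their limit $B$ and decline linearly to zero at $C$.
2. **Nutrient mean.** The unweighted arithmetic mean of the sixteen
   subscores. No nutrient is privileged; a weighting hook exists in
   `score_intakes()` but defaults to uniform.
3. **Energy adjustment.** The day's energy is scored with the same
   trapezoid shape around the person's estimated energy requirement (EER):
   plateau at $\pm 15\%$, zero at or below $0.5 \times$ and at or above
   $1.5 \times$ the EER. The **total** is the nutrient mean multiplied by
   the energy score, so a nutritionally balanced day eaten at an
   implausibly low or excessive energy level still scores low. This is the
   point of difference from density-based indices, which score quality
   independently of quantity.

The breakpoints are personalised. For an adequacy nutrient with reference
intake $R$ (RDA where available, else AI, by age band and gender):
$B = R$, $C = u R$ with the upper healthy-range multiple $u = 2$ by default
(vitamin C uses $u = 3$, reflecting its wide safety margin and its
abundance in diets rich in fruit and vegetables), $A = 0.5\,B$, and
$D = 1.5\,C$ **capped at the tolerable upper intake level** (TUL) where one
applies to dietary intake. Macronutrients are scored on the percent-of-energy
scale against their AMDR ($B$ and $C$ are the AMDR bounds; $A$ and $D$
mirror the $0.5\times$/$1.5\times$ rules). Moderation nutrients use the WHO
recommendations (sodium 2000 mg/day; saturated fat and added sugars 10% of
energy) as $B$.

```{r}
profile <- person_profile(40, "female", fixed_eer_kcal = 2000)
derive_breakpoints(lookup_reference(default_references(), profile))
```

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `upper_multiple` | 2 (vitamin C: 3) | ratio $C/B$ | healthy range 100–200% of reference (100–300% for vitamin C) |
| `zero_floor` | 0.5 | ratio $A/B$ | intakes at or below half the reference earn nothing |
| `zero_ceiling` | 1.5 | ratio $D/C$ | zero credit at 1.5× the upper healthy range, TUL-capped |
| `moderation_ceiling` | 1.5 | ratio $C/B$ | zero credit at 1.5× the WHO limit |
| energy plateau | ±15% of EER | kcal | a 2000 kcal requirement keeps full credit on 1700–2300 kcal |
| `scale` | 1 | — | set 100 for a 0–100 display scale; the arithmetic is unchanged |

Three of these deserve comment because the verbal scoring rules do not pin
them down completely, and we had to make a call:

* **Boundary semantics.** Zero is awarded exactly *at* $A$ and $D$
  (adequacy) and *at* $C$ (moderation); the full score is awarded exactly
  at $B$ and $C$. The functions are continuous everywhere, so only exact
  breakpoint hits are affected.
* **The moderation ceiling.** The $1.5\times$ zero rule is stated for
  intakes above the healthy range of micronutrients; we extend the same
  multiplier to the moderation nutrients as the most parsimonious reading
  of the declining-chart shape, and expose it as `moderation_ceiling` so a
  user who prefers a different ceiling can change it without touching code.
* **AMDR floors/ceilings.** $A = 0.5 B$ and $D = 1.5 C$ mirror the
  micronutrient rules; also configurable.

Reference values themselves ship as an editable YAML table
(`dq_example("references.yaml")`), one entry per (gender, age band,
nutrient), each with a provenance note, because the defaults are a
reconstruction from the cited public sources (IOM DRI and AMDR tables, WHO
limits), not a verbatim copy of any published breakpoint table. Users with
different national references can swap the file. Two entries are worth
flagging: fiber is scored against its AI in grams (not the 14 g/1000 kcal
density rule — representable via the AMDR mode if preferred), and food
folate is scored against the folate DRI although that DRI is expressed in
dietary folate equivalents; both notes are carried in the config. The
calcium TUL is held at 2500 mg in all adult bands because the 2000 mg TUL
published for ages 51+ lies below 200% of that band's 1200 mg RDA and would
make the upper healthy range degenerate (`derive_breakpoints()` treats
TUL $\le C$ as an error rather than silently collapsing the trapezoid).

Pregnancy and lactation change reference needs qualitatively, so the
default table refuses to score pregnant or lactating profiles; scoring them
requires an explicit band. The bundled EER equations are the IOM adult
equations only; any other age class can be scored by supplying
`fixed_eer_kcal`.

## Degenerate inputs and numerical choices

* Zero-energy days: percent-of-energy subscores are reported as 0 and the
  energy score is 0 (hence total 0); the day is logged as degenerate.
* Missing nutrients: a strict error by default, naming the nutrients;
  `allow_missing = TRUE` drops them from the mean and says so. Silent
  zero-filling is never done, since zero intake and unknown intake score
  very differently.
* The piecewise scorers are evaluated in closed form; the test suite pins
  them to an independent pointwise translation of the verbal rules on
  10,001-point grids (agreement to $10^{-12}$) and checks continuity at
  every breakpoint.
* Quantile stratification resolves ties by average rank, then stable input
  order, so repeated runs on the same data give identical strata. With all
  compared values tied, the omnibus p-value is reported as 1.
* Cronbach's alpha uses the variance-ratio formula with Feldt's F-based
  confidence interval; PCA decomposes the covariance (not correlation)
  matrix because all subscores share the \[0, 1\] scale.
* Bland–Altman limits are $\mathrm{bias} \pm 1.96\,\mathrm{SD}$ of the
  paired differences; the difference direction is always `a - b` and the
  caller is expected to rescale a 0–1 score to 0–100 before comparing it
  with a 0–100 index (the `run_compare()` pipeline does this and reports
  the direction).

## What the synthetic generator emulates — and what it does not

`sample_days()` and `sample_population()` draw intakes *relative to the
personalised breakpoints*: each archetype gives every nutrient a sampling
band in anchor coordinates (e.g. `["B", "C"]` = inside the healthy range;
`["0", "A"]` = deficient), draws uniformly inside the band — with a
Gaussian copula inducing between-nutrient correlation where configured —
and multiplies by a mean-one lognormal day-to-day jitter (`noise_cv`).
Truncated-to-positive, right-skewed amounts are what real intake data look
like, which is why the jitter is lognormal rather than Gaussian.

The bundled archetypes are all synthetic and labelled as such:

* `plateau`, `deficient`, `excess` — calibration extremes with known exact
  scores (1, 3/16, 0 for the default profile).
* `nhanes_like` — a typical-US pattern: shortfalls in fiber, potassium,
  folate and vitamins A/D/E, excess sodium and added sugars, macronutrients
  mostly in range, and correlated vegetable-borne
  (potassium–magnesium–folate–fiber) and dairy-borne
  (vitamin A–vitamin D–calcium) clusters. Its bands were set once so the
  cohort mean total for the default female 31–50, 2000 kcal profile lands
  in 0.40–0.55; the constants are versioned in
  `inst/extdata/archetypes.yaml`, not hard-coded.
* `myplate_like`, `dash_like` — exemplary-menu-style weeks (vitamins and
  minerals at 100–175% of reference, vitamin C in excess, vitamin D low,
  vitamin E slightly short in `myplate_like` only, moderation nutrients at
  or under their limits, energy within a few percent of requirement).
  These are reconstructions of what a well-designed 7-day menu looks like
  in percent-of-reference terms — **not** transcriptions of any published
  menu's nutrient composition.

Passing tests on these cohorts therefore show that the scoring machinery
behaves correctly and that the score separates diets *designed* to be good
from diets *designed* to be mediocre. They do not show how the score
distributes over real dietary recalls: real data add measurement error,
under-reporting, survey weighting and food-composition uncertainty that no
archetype here models. Replicating published survey results additionally
requires the survey's recall files and an external implementation of the
comparison index, both out of scope for this package.

## Problem sizes

The shipped tests and the acceptance script use: 10,001-point grids per
nutrient for the piecewise oracle; 1,000 plateau days; cohorts of 200
subjects for separation and consistency summaries; n = 10,000 draws for the
Bland–Altman and PCA sampling checks; 7-day weeks for the menu-style
archetypes. These sizes keep Monte-Carlo error well inside the asserted
margins (e.g. the standard error of the Bland–Altman bias at n = 10,000
with SD 1 is 0.01) while the whole suite runs in well under a minute.

## A worked example

```{r}
week <- sample_days(diet_archetype("dash_like"), profile, n_days = 7,
                    seed = 42)
res <- score_period(week, profile)
res$summary
res$days |> select(day, fiber, sodium, vit_d, energy_score, total)
```

The weekly summary is the mean and sample SD of the seven daily totals (the
aggregate is deliberately the mean of daily scores, not the score of mean
intakes, so one extreme day cannot be averaged away before scoring).

```{r, fig.width = 6, fig.height = 4}
percent_dri_profile(week, profile) |> plot_percent_dri()
```

## Known limitations

* The default reference table covers non-pregnant, non-lactating adults;
  children, pregnancy and lactation need user-supplied bands (and, for
  children, an external energy requirement).
* Added sugars are scarce in public food databases; the scorer treats them
  like any other column and leaves the estimation problem upstream.
* The score is only as good as the intake totals fed to it;
  under-reporting biases it upward through the energy score's lower ramp.
* A single day is a noisy measure of habitual diet; multi-day means (the
  `score_period()` summary) are the intended unit for between-group
  comparisons.
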