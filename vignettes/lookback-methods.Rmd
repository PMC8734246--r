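---
title: "Lookback windows and misclassification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lookback windows and misclassification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lookback)
```

## The problem

Administrative health claims cannot report whether a person *has* a chronic
disease; they only record dated, coded encounters (hospital discharges,
physician billings, drug dispensations).  To decide whether someone is a
case in an estimation year $Y$, a case-finding algorithm is evaluated over
the claims falling in a retrospective *lookback window* (LW) of $k$ years
plus the estimation year itself.  The choice of $k$ is consequential:

* short windows miss long-standing ("prevalent") cases whose last
  disease-coded encounter predates the window, deflating period prevalence;
* the same missed cases can resurface with a new encounter in year $Y$ and
  be mistaken for *incident* cases, inflating cumulative incidence.

`lookback` quantifies both distortions.  Classification with the longest
feasible window (16 years when data start in 1996 and $Y = 2012$) serves as
the reference standard, and for every shorter $k$ the package reports, on
person *sets* rather than count differences:

* **misclassified prevalent proportion**
  $|\mathrm{Prev}_{ref} \setminus \mathrm{Prev}_k| / |\mathrm{Prev}_{ref}|$ —
  the share of reference prevalent cases a $k$-year window fails to capture;
* **misclassified incident proportion**
  $|\{p \in \mathrm{Inc}_k : p \text{ prior-prevalent under } ref\}| /
  |\mathrm{Inc}_k|$ — the share of apparent incident cases that are in fact
  long-standing ones.

Because the real linked cohort data behind analyses of this kind are
access-restricted, the package pairs the analysis machinery with a seeded
synthetic claims generator so that every stage is testable end to end.

## Classification model

For estimation year $Y$ and lookback $k$, ascertainment for prevalence runs
over the single contiguous half-open interval
$[\mathrm{Jan\,1}(Y-k), \mathrm{Jan\,1}(Y+1))$ — the lookback interval and
the estimation year together.  A person is

* **prevalent** if some clause of the case definition is satisfied by
  claims inside that union window;
* **at risk** if no clause is satisfied by claims inside the lookback
  interval $[\mathrm{Jan\,1}(Y-k), \mathrm{Jan\,1}(Y))$ alone (no *prior*
  prevalent case);
* **incident** if at risk *and* the identification date falls inside year
  $Y$.

Two semantic decisions here were genuinely open and deserve emphasis.

**Identification date = rule completion date.**  A clause requiring, say,
two physician claims within 730 days identifies a person on the date of the
claim that *completes* the rule, not the first qualifying claim.  This
makes incident classification well-defined when the evidence straddles the
LW / estimation-year boundary.

**Union-window evaluation.**  Multi-claim rules may combine lookback and
estimation-year claims: one physician claim in November $Y-1$ and a second
in March $Y$ completes a two-claim rule with an in-year identification date,
so the person is incident (provided the lookback claims alone never
complete a rule).  A defensible alternative — requiring the rule to
complete using estimation-year claims only — would make incident counts
exactly monotone in $k$ but would miss every boundary-straddling case; we
chose the union window because it mirrors how a surveillance algorithm
would actually be run against a fixed extraction window.

A documented consequence of these two choices: **incident sets (and
therefore counts) are not guaranteed to be monotone at the shortest
windows**.  At $k = 0$ a two-claim rule can rarely complete inside a single
year, so moving to $k = 1$ or $2$ *adds* boundary-straddling incident cases
before the usual attrition (newly detected prior-prevalent cases leaving
the at-risk pool) takes over.  Empirically, on the package's default
30,000-person synthetic run, incident counts for multi-claim-dominated
diseases rise between $k = 0$ and $k \approx 2$ and decrease monotonically
thereafter; prevalence and at-risk counts are monotone everywhere, as is
prevalent-set nesting $\mathrm{Prev}_k \subseteq \mathrm{Prev}_{k+1}$.
This is why misclassification is computed set-wise, never as count
differences, and why analyses of the shortest windows (0–1 years) should be
interpreted with care.

Other conventions: window intervals are half-open, $k = 0$ means no
historical data; within-span constraints are evaluated only among in-window
claims; age restrictions (strictly older than 20 / 35 / 40 years for
hypertension, COPD and dementia analyses) are applied *before* denominators
are formed, so each disease has its own analysis population; undefined
proportions (zero denominators) are emitted as `NA` with a reason flag,
never as silent zeros, because a silent zero would fake perfect agreement.

## Closed-form anchor

The misclassification machinery is anchored to an exact result.  Under a
single-claim rule, disease onset before the data start, full registration
over 1996–2012 and disease-coded claims arriving as a homogeneous Poisson
process at rate $\lambda$ per year, the expected misclassified-prevalent
proportion at lookback $k$ (reference $K = 16$) is

$$
m(k; \lambda) \;=\;
\frac{e^{-\lambda(k+1)} - e^{-\lambda(K+1)}}{1 - e^{-\lambda(K+1)}},
$$

i.e. the probability of no claim in the $(k{+}1)$-year ascertainment window
given at least one claim in all $K{+}1 = 17$ years.  The acceptance suite
simulates 20,000 persons at $\lambda \in \{0.1, 0.5, 1.0\}$ and requires
agreement within three Monte-Carlo standard errors at every $k$.  Because
$m(k;\lambda)$ is decreasing in $\lambda$, the same machinery reproduces the
central qualitative contrast: diseases with frequent encounters (e.g. one
managed with regular drug dispensations) reach a given misclassification
tolerance at a much shorter lookback than sparsely-encountered ones.

## The synthetic generator

The generator emulates the structure the analysis assumes, not any real
population's magnitudes:

* **Two populations**, an index group and a control pool, all registered
  with a single-payer system from January 1 of the first data year.  The
  default shape — 82% male, birth years uniform on 1932–1992 (median age
  about 50 in 2012), complete follow-up 1996–2012 (`dropout_rate = 0`) —
  mirrors a closed cohort with complete follow-up; a positive per-year
  dropout hazard is available for robustness exercises.
* **Absorbing disease onset** with a constant per-year hazard, multiplied
  by a disease-specific factor for the index population.  Onset exposure
  starts at a configurable `burn_in_year`; the pipeline default (1986, ten
  years before the data start) creates *left-truncated* histories — persons
  whose onset predates the data window — which are exactly the cases only
  long lookbacks can capture.  Onset dates are uniform within the onset
  year.
* **Claims as Poisson processes.**  While diseased and registered, a person
  emits disease-coded claims per source (hospital / physician / pharmacy)
  at the disease model's `encounter_rates` (claims per person-year), with
  codes drawn from that disease's pool.  Background (non-disease) claims
  arrive over the whole registration spell and carry codes from a reserved
  pool disjoint from every disease pool, so case-finding specificity is
  perfect by construction.  Each disease model carries its own
  `background_claim_rate`; the total background intensity is their sum
  (defaults: 0.15/year across eight models, about 1.2 claims per
  person-year).
* **Coding dialect.**  Hospital claims use ICD-10-style codes with dots,
  physician claims ICD-9-style codes without dots, pharmacy claims DIN
  digit strings; code matching is prefix-based.

Default onset hazards (0.002–0.020 per year) and encounter rates
(0.25–3 claims/year across diseases) were chosen once as order-of-magnitude
plausible values spanning the frequent-vs-sparse encounter spectrum, since
no public source reports the real populations' encounter-rate magnitudes;
they are deliberately not calibrated to any published estimate.  The
shipped case definitions are likewise *stand-ins* patterned on Canadian
Chronic Disease Surveillance System style rules (one hospitalization OR two
physician claims within two years; diabetes additionally via a synthetic
DIN list) — the genuine published algorithms are not reproduced here, and
the defaults must not be read as them.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: coding errors and false-positive codes,
remitting/relapsing disease, migration into the data region, care-seeking
heterogeneity beyond a single rate multiplier, seasonality, and any
dependence between diseases within a person.

## Matching and eligibility

Eligibility for estimation year $Y$ requires age $\ge$ 19 (computed as
$Y - \text{birth year}$, matching the granularity of the matching key),
registration since January 1 of the first data year, and at least one day
of registration overlap with $Y$ (so death or dropout during $Y$ keeps a
person eligible).  Exclusion counts are logged stepwise.  Matching is exact
1:5 on birth year and sex at birth, sampling controls without replacement
in a deterministic shuffled order keyed by the seed; a stratum with too few
controls is a hard error naming the stratum, because silently degrading the
ratio would bias population comparisons.  Exact matching needs headroom:
with birth years spread over 61 strata per sex, small cohorts should use a
control pool of 20–25 times the index size for a 1:5 ratio (the pipeline
demo uses 25).

## Reproducibility and numerical choices

Every stochastic operation draws from its own RNG stream derived from the
master seed and a fixed operation label (`derive_seed()`), so adding a
disease model does not perturb the population draw, and identical
config + seed reproduce byte-identical outputs.  Dates are held at day
resolution (year-level logic derives from it losslessly).  Percentages are
rounded to one decimal place only in written output tables; in-memory
results keep full precision.  Ascertainment is evaluated through
precomputed clause-completion candidates — valid because a query window is
a date interval, so in-window claims always form a contiguous slice of a
person's sorted claim list; the vectorised path is tested for exact
equality against a brute-force subset-enumeration oracle on hundreds of
random instances.

Problem sizes used by the test suite were chosen to make Monte-Carlo checks
sharp while keeping a full run comfortably interactive: 30,000 persons for
the monotonicity suite, 20,000 for the closed-form and encounter-contrast
checks (three standard errors at these sizes resolve proportions to within
roughly one percentage point), and 56,661 for the matching worked example.

## Limitations

The reference standard is itself a finite window: a 16-year lookback is a
proxy for truth, not truth, so misclassification proportions quantify
disagreement with the longest available window rather than true bias.  The
incidence denominator excludes prior-prevalent persons, so lookback length
affects numerator and denominator simultaneously; incidence is an incidence
*proportion* (cumulative incidence), not a person-time rate, and no
confidence intervals are attached.  The boundary non-monotonicity of
incident counts at $k \le 2$ under multi-claim rules is inherent to
union-window completion semantics, as discussed above.  Synthetic defaults
are for testability and method exposition; substantive conclusions about
any real population require that population's own claims and validated
case-finding algorithms.
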