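---
title: "A static budget impact model for RRMS disease-modifying therapies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A static budget impact model for RRMS disease-modifying therapies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`rrmsbia` implements a static, annual-cycle budget impact analysis (BIA) of
disease-modifying therapies (DMTs) for relapsing-remitting multiple
sclerosis (RRMS), from a national payer perspective, over a 5-year horizon
with undiscounted costs — the conventional ISPOR good-practice shape for a
payer BIA. The primary outcome is the **net budget impact**: the expenditure
of a world in which a new intervention takes market share, minus the
expenditure of a reference world in which the eligible population stays on
the standard-of-care (SOC) basket. Negative cells are savings.

The computation is a chain of four components.

**1. Eligibility cascade.** A national adult population is reduced
multiplicatively to the treated population:

\[
N_s(1) = P_{\text{adult}} \cdot \frac{\text{prev}}{10^5} \cdot
  f_{\text{RRMS}} \cdot f_{\text{elig}} \cdot \pi_s ,
\qquad
N_s(t) = (1-e)\,N_s(t-1) + P_{\text{adult}} \cdot \frac{\text{inc}}{10^5}
  \cdot f_{\text{RRMS}} \cdot f_{\text{elig}} \cdot \pi_s ,
\]

where \(\pi_s\) combines the disease-activity split (active / highly
active / aggressive) with the treatment-history split (naive / non-naive)
into the five modelled subgroups, and \(e\) is an optional annual exit rate
(default 0: a static model with no mortality or discontinuation). The
prevalent pool opens the model in year 1; incident patients flow in each
later year, distributed across subgroups by the same cascade fractions, and
never migrate between subgroups afterwards (treatment switching is not
modelled). Counts stay real-valued internally; rounding to whole persons is
a reporting step only, which avoids order-dependent rounding drift.

**2. Per-patient cost decomposition.** Each drug carries schedules of unit
costs per *treatment year* (year on therapy, distinct from model year):
acquisition, administration, monitoring and premedication, plus a flat
adverse-event (AE) management cost and an annualised relapse rate (ARR).
The five reported components of a patient-year are

* acquisition: \((1-d)\,A(\tau)\) with \(d\) the effective MEA discount,
* administration: \( \text{admin}(\tau) + \text{premedication}(\tau) \)
  (premedication is never a separate column in reporting),
* monitoring: \(M(\tau)\) (disease-management costs fold in here unless
  configured separately — the canonical decomposition has five components),
* adverse events: a flat per-year cost,
* relapse: \( \text{ARR} \times c_{\text{relapse}} \), so relapse savings
  against SOC scale with the comparative ARR. Whether relapse
  hospitalisation belongs in \(c_{\text{relapse}}\) is a configuration
  choice; the unit cost is taken to include it.

Treatment years are mapped per cohort: an incident cohort entering at model
year \(t_0\) is in treatment year \(t - t_0 + 1\); a prevalent cohort sits
at maintenance dosing, defined as the first year of the longest constant
tail of the acquisition schedule (so a loading-dose drug maps to year 2).
Fixed-course therapies (cladribine-style: two dosing years, zero
acquisition afterwards) are the exception: their prevalent cohort is taken
to start its course at model year 1 and tracks the model year. Reading a
schedule beyond its last year is an error — there is no silent
extrapolation.

**3. Managed entry agreements.** Every contract reduces to an effective
percentage discount on acquisition. Fixed-discount contracts are taken as
given. Free-goods patient splits are reduced deterministically rather than
simulated: for existing patients, "2 + 2" (2 paid + 2 free cycles) is the
free-unit fraction \(2/(2+2) = 0.50\) and "3 + 1" is \(0.25\); several
existing-patient groups blend by configurable weights defaulting to
headcounts (the blending rule across mixed cycle schemes is not otherwise
determined, so it is left to configuration). For new patients, a
payer-vs-sponsor intake of 100 : 120 is the sponsor share \(120/220\). The
engine applies the existing-cohort discount to prevalent patients and the
new-cohort discount to incident patients. Performance-based features
(relapse/MRI response triggers, rebates for non-responders) are
representable only through their financial-equivalent fixed discount;
response adjudication is out of scope.

**4. Market-share worlds.** Expert-elicited uptake is given as a
(year-1, year-H) range per drug and interpolated linearly; the residual
share in each year falls to the SOC basket in its configured internal mix
(the SOC mix is a configuration input — it is not publicly documented).
Interpolated new-drug shares exceeding 1 fail loudly before any
renormalisation could hide it. Full uptake places the entire subgroup on a
single drug. Expenditure is then

\[
E(y, c, d) = \sum_{s}\sum_{\text{cohorts}} N_{s,\text{coh}}(y)\,
  \sigma_{s,d}(y)\, C_c\big(d, \tau(\text{coh}, y), d_{\text{coh}}\big),
\]

and the net budget impact table is the cell-wise difference of two worlds,
with row totals and the grand total always recomputed from components.

## Currency arithmetic

Published budget tables are printed to the cent, and their row totals must
equal the sum of the five components to the cent. Binary floating point
cannot hold most multiples of 0.01, so all reported sums run on integer
cents (`round(x * 100)`, summed as doubles — exact below \(2^{53}\)). Each
(subgroup, cohort, drug, year, component) contribution is rounded to the
cent before accumulation, which makes "to the cent" agreement with the
brute-force enumeration oracle well defined. Population counts and
sensitivity sweeps use ordinary doubles; cent-exactness is only asserted
where money is reported.

The packaged fixture of published decomposition rows shows the consequence
of *not* doing this: a minority of printed totals sit one cent away from
their exact component sum (rounding of unrounded internals before
printing). The engine reports exact sums and documents the discrepancy
(`analysis/05_fixture_checks.R`) rather than emulating it. Two fixture
cells are stored in reconciled form because the printed cell is
inconsistent with its own printed row total (one acquisition cell with a
spurious digit, one relapse cell with a flipped sign); both are flagged in
the fixture's `note` column.

## Tunable parameters

| parameter | units | default | why |
|---|---|---|---|
| horizon | years | 5 | the analysis horizon of the study design |
| `ms_prevalence` | per 100,000 adults | sampled 35–50 | brackets the national figure of 41/100,000 |
| `ms_incidence` | per 100,000/yr | sampled 3–8 | plausible national inflow given the prevalence |
| `frac_rrms` | fraction | 0.8 | ~80% of MS is RRMS |
| `frac_eligible` | fraction | sampled 0.70–0.95 | treatment-eligible share of RRMS |
| severity split | fractions | ~0.45–0.60 / 0.20–0.28 / 0.05–0.10 | active-majority casemix; may sum below 1 (remainder unmodelled) |
| naive split | fraction | active 1; others 0.4–0.7 | the active subgroup is modelled naive-only |
| `exit_rate` | fraction/yr | 0 | static model: no exits |
| `adult_population` | persons | 1.5e7 | national adult population scale |
| acquisition scale | SAR/patient-yr | 60,000 | high-cost DMT magnitude; SOC basket at 0.4× |
| `discount_range` | fraction | 0.1–0.5 | realistic MEA discount band |
| OSA bounds | relative | ±20% | conventional deterministic one-way default; configurable per parameter |

## The synthetic generator

Real drug acquisition prices and healthcare unit costs for this model are
confidential (national procurement and service-code lists), and the
population cascade values live in unpublished supplementary material. The
generator therefore emulates the *structure* of those inputs so every
module is exercisable end to end with no download: five subgroups wired to
the published drug–subgroup intervention matrix, one fixed-course drug, one
drug with three MEA variants shaped like the published contract table
(free-goods cycles for existing patients, payer:sponsor intake splits for
new ones), an SOC basket with higher ARRs than the new interventions (so
relapse savings carry the expected sign), and component costs sampled
log-uniformly around per-component scales, rounded to the cent. All
randomness flows from one seed; generation restores the caller's RNG state.

What passing tests on synthetic bundles do **not** show: agreement with the
study's absolute SAR totals (those depend on the confidential inputs and
are deliberately not targets), realism of price *levels* or correlations
between cost components, and any behaviour driven by real-world access,
adherence or switching. What they do show: the arithmetic identities every
published table exhibits — decomposition additivity, MEA rows differing
from their no-MEA pair only in acquisition, zero-discount equivalence,
linearity in population and shares — hold by construction in the engine.

## Sensitivity analysis

The one-way analysis perturbs each of the seven cascade parameters
(prevalence, RRMS fraction, eligibility fraction, three severity
proportions, naive proportion) to its low/high bound with the others at
base, and ranks by the swing of the outcome. The outcome is the 5-year
**total cost** of the with-intervention world (not the net impact): that is
what the tornado measures here, and it is also what makes the observed rank
ordering structural — a cascade-level parameter scales the whole total, so
its swing is \(0.4\,T\) under ±20% bounds, while a severity proportion only
scales its own subgroup's share of \(T\), and the naive proportion merely
moves patients between two subgroups with near-identical costing. Severity
bounds are truncated so the perturbed split never exceeds 1 (the perturbed
cascade must remain valid). Whether bounds are relative or absolute is a
configuration decision (`sensitivity_specs()` builds relative defaults);
nothing is inferred from unreadable figure axes.

## Numerical and design choices

* Sign convention: savings are negative throughout.
* Annual cycle, no half-cycle correction; no discounting of future costs.
* Tornado ties: stable descending sort, so a zero-swing (degenerate)
  parameter ranks last.
* Scenario-matrix cells fail independently; one broken cell is reported in
  its `error` column and the rest of the matrix completes.
* Config files serialize currency as fixed two-decimal strings and
  generated fractions at fixed decimal precision, so write → read → write
  round trips are byte-identical; machine output uses dot decimals and no
  thousands grouping regardless of locale.
* Problem sizes used in the shipped checks: bundles with 7 interventions +
  an SOC basket of 4 over 5 years; oracle and equivalence sweeps over 100
  seeded bundles; a 20-cell scenario matrix. These sizes exercise every
  code path while keeping the whole suite fast to re-run.

## Limitations

No cost-effectiveness or QALY analysis; no indirect or caregiver costs; no
treatment switching, titration, weight-based dosing or vial sharing; no
probabilistic sensitivity analysis; no age/sex or regional structure. The
reference-world SOC mix and all absolute price levels are configuration
inputs, so absolute totals produced from synthetic bundles characterize the
model's behaviour, not any real payer's budget.

## A worked run

```{r}
library(rrmsbia)
bundle <- generate_bundle(synth_config(seed = 1))
pop <- project_population(bundle$cascade, bundle$horizon)
tab <- run_bia(bundle, "ha_naive", "cladribine", uptake = "expert",
               mea = "default", pop = pop)
print(tab)
bia_summary_row(tab)
```

The numbered drivers under `analysis/` run the full sequence — input
generation, single-drug scenario rows, the MEA-variant comparison, the two
tornado analyses and the published-row decomposition check — writing tidy
CSVs under `results/`.
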