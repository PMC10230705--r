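---
title: "A Markov cohort cost-utility model for sequential rheumatoid arthritis treatment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort cost-utility model for sequential rheumatoid arthritis treatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramcea)
```

## The decision problem

Rheumatoid arthritis (RA) patients whose disease remains highly active
(DAS28-ESR > 5.1) after three conventional synthetic DMARDs can be offered a
biologic, targeted synthetic or biosimilar DMARD combined with methotrexate
(MTX), or remain on the standard of care (SoC: cyclosporine/azathioprine with
MTX). The new regimens improve remission rates but cost far more. `ramcea`
implements a cohort state-transition model that weighs lifetime costs against
quality-adjusted life years (QALYs) for twelve strategies from a societal
perspective in the Thai setting, producing incremental cost-effectiveness
ratios (ICERs) against SoC, a tornado (one-way) analysis and a probabilistic
sensitivity analysis (PSA) with cost-effectiveness acceptability curves.

## Model structure

Four health states are defined by DAS28-ESR: high disease activity (> 5.1),
moderate/low (2.6–5.1), remission (< 2.6), and death. The cycle length is 6
months (the clinical response-assessment interval); the cohort enters at age
56 in the high-activity state and is followed over a lifetime horizon of 200
cycles (100 years), with all occupants absorbed into death by the life
table's terminal row well before the horizon.

The engine expands the health states with two bookkeeping dimensions that
encode the treatment-sequencing rules (`ra_states()` lists all 16 states):

* **Line** — `int` (the novel regimen) or `soc`. High-activity occupants who
  fail a cycle on the novel regimen switch to SoC for the next cycle
  (`switch_after = 1`, the earliest reading of switching "at 6-month
  intervals after treatment failure"; a documented option defers the switch
  by one more cycle). Patients on SoC stay on SoC.
* **Phase** — `act` (full regimen), `taper` (remission maintained on MTX
  only) and `sae` (serious-adverse-event interruption). Remission entrants
  receive the full regimen for one more 6-month cycle, then discontinue
  everything except MTX (`taper`). A serious adverse event interrupts the
  regimen for exactly one cycle, during which transitions revert to their
  baseline (unadjusted) probabilities and the admission cost is charged
  once on entry; treatment resumes afterwards.

Where the sequencing rules are silent the model makes explicit, configurable
choices: relapse out of the MTX-only taper resumes the current line's full
regimen (patients who achieved remission on the novel drug restart it, those
who tapered on SoC restart SoC); adverse-event risk applies in every
active-treatment phase, including the single full-regimen remission cycle,
but not during the MTX-only taper; and an interrupted patient returns to the
`act` phase of the health state reached during the interruption.

## Transition probabilities

Each disease-activity transition follows a Weibull proportional-hazards
model on the 6-month time axis, with cumulative hazard
$H(t) = \lambda t^{\gamma}$, survival $S(t) = \exp\{-H(t)\}$ and per-cycle
transition probability

$$tp(u) = 1 - \exp\{\lambda (t-u)^{\gamma} - \lambda t^{\gamma}\},$$

where $u$ is the cycle length and $t$ the time at the end of the cycle. The
scale is $\lambda = \exp(\text{constant} + \sum \beta x)$; only the
high-to-moderate/low transition carries a covariate (disease duration,
$\beta = -0.08$ per year, evaluated at the cohort mean of 14 years). The five
transitions use the published constants, shapes and lambdas:

| transition | constant | shape $\gamma$ | $\lambda$ |
|---|---|---|---|
| high → moderate/low | 1.55 (−0.08 × duration) | 1.08 | 1.61 |
| high → remission | −2.92 | 1.00 | 0.05 |
| moderate/low → high | −1.39 | 0.50 | 0.25 |
| moderate/low → remission | −1.86 | 0.63 | 0.16 |
| remission → moderate/low | −0.22 | 0.96 | 0.80 |

Two numerical points deserve note. First, the printed $\lambda$ for
high-to-moderate/low (1.61) differs slightly from
$\exp(1.55 - 0.08 \cdot 14) = 1.537$, presumably because unrounded
coefficients produced it; `table2_fixture()` stores both, and the engine's
base case uses the printed $\lambda$. Second, $t$ is measured from model
start (cycle index × cycle length) — a cohort-level spreadsheet convention.
True time-in-state semantics would require tunnel-expanding every state by
its occupancy clock; with shapes near 1 the difference is small, and only
the model-time convention is implemented.

`fit_weibull_ph()` estimates these parameters from right-censored event
histories by maximum likelihood (via `flexsurv` in the same
proportional-hazards parameterisation, standard errors from the observed
information); with the shape fixed at 1 the exponential special case
reduces to the analytic rate estimate, events/exposure.

The novel regimens act through relative risks (RR vs MTX monotherapy, from a
network meta-analysis) applied multiplicatively to the baseline per-cycle
probabilities of the response transitions (high→moderate/low,
high→remission) and to the adverse-event probability; the
moderate/low→remission RR reuses the high→remission RR (the published
assumption that these efficacies are comparable), and efficacy is assumed
constant over time. Worsening (moderate/low→high) and relapse
(remission→moderate/low) are never RR-adjusted. Applying RRs to the SoC
baseline, although the RRs were estimated against MTX monotherapy, follows
the source analysis and is a known limitation.

## Mortality

Background mortality comes from an annual life table (the shipped table is
synthetic — see below). The annual probability $q$ at the occupant's current
integer age is converted on the hazard scale to a per-cycle probability,
with the mortality hazard ratio for high disease activity (2.43, 95% CI
1.64–3.61) applied while — and only while — the occupant is in the
high-activity state:

$$p_{\text{die}} = 1 - (1-q)^{0.5 \cdot \text{HR}_{\text{eff}}}.$$

Ages beyond the table are treated as certain death only if the terminal row
carries $q = 1$; otherwise they are an error.

### Composing a row of the transition matrix

Within each row, unconditional probabilities are composed in a fixed order —
death, adverse event, then the health-state exits in the order the
transitions are tabulated (high→moderate/low before high→remission;
moderate/low→high before moderate/low→remission) — and each is capped at the
mass not yet committed, $\min(\text{RR} \cdot tp,\ 1 - \text{competing})$;
the residual stays in place. The cap order is a documented tie-break; it
only binds when probabilities are extreme (with $\lambda = 1.61$ the
high→moderate/low probability is ≈ 0.80 per cycle, so large RRs on that
transition can starve the remission exit). Residual "stay" masses that round
to −1 ulp when a cap binds exactly are clamped to zero; every matrix is
verified row-stochastic to 1e−9 at construction, and any genuinely negative
entry raises an error rather than being silently repaired.

## Economics

Costs (year-2022 THB) accrue per cycle of state occupancy: the regimen's
drug cost (full price in `act`, the MTX-only price in `taper`, nothing
during an interruption), outpatient visits by health state (6, 2 and 1 per
6 months for high, moderate/low and remission) at the service fee (78) plus
direct non-medical cost per visit (451.52: transport 329.97 + food
121.55), infusion administration fees (31 per infusion; infliximab-type
regimens 5 infusions in the loading cycle then 3 per cycle, rituximab-type
2 per cycle), the nine-item pre-treatment screening panel (2,309.02) at
every regimen start — model entry and again on the switch to SoC — and the
adverse-event admission cost (36,070) once per interruption entry. The
MTX-only maintenance price is not published; the bundle sets it to 10% of
the SoC+MTX combination price (1,870 per 6 months) as a flagged assumption.
Caregiver opportunity costs are mentioned in the source but not itemised,
and are excluded, as are indirect (productivity) costs.

QALYs weight occupancy by state utilities (high 0.79, moderate/low 0.86,
remission 0.93; death 0) times the half-year cycle. Accrual uses the state
occupied at the start of each cycle (trace rows 0 … N−1), each discounted by
$(1.03)^{-0.5k}$; an optional half-cycle correction averages adjacent trace
rows instead (off by default, matching the source model). Totals are kept in
full floating precision and rounded to the satang only at serialization.
ICERs are $\Delta C / \Delta Q$ against SoC, with dominance flagged instead
of a ratio when $\Delta Q \le 0$, and converted to USD at 34.53 THB per USD
against the 160,000 THB/QALY willingness-to-pay threshold.

## Synthetic inputs: what they emulate and what they do not

Three inputs of the original analysis are not publicly available: the
84-patient medical-record review, the national life table, and the
network-meta-analysis RR table. `synthetic_config()` and the `gen_*()`
generators produce seeded stand-ins with the statistical structure the
pipeline assumes:

* `gen_patient_histories()` draws per-patient, per-transition event times
  from the Weibull models above (disease duration gamma-distributed with
  mean 14, SD 7 years), right-censored by a 5-year administrative window
  and an independent exponential censoring time calibrated to a target
  censoring fraction (20% by default). It does not reproduce the review's
  exact event counts (44/12/23/18/12), its within-patient correlation
  between transitions, or informative censoring.
* `gen_life_table()` builds a Gompertz–Makeham table
  ($h(x) = 5\times10^{-4} + 3\times10^{-5} e^{0.085x}$, male hazard ×1.6,
  92% female weight as in the study cohort, terminal certainty at 110).
  It is deliberately labelled synthetic: it is a plausible middle-income
  country schedule, not Thai vital statistics, and `read_life_table()`
  accepts a real table in the same format.
* `gen_efficacy_table()` draws remission RRs in 1.5–3.0,
  high-to-moderate/low RRs in 1.05–1.40 and serious-infection RRs in
  0.90–1.80 with log-symmetric 95% CIs — ranges typical of published
  network meta-analyses in this population — but carries no real evidence
  about any named drug.

Consequently the package's *relative* machinery (conservation, oracles,
incremental logic, reproducibility) is fully testable, while its *absolute*
outputs (lifetime costs, ICERs) characterise the synthetic inputs, not the
original study's. With the synthetic life table the cohort lives much longer
than the source model's reported 6.5 undiscounted life years (a figure hard
to reconcile with any standard life table given its own survival-validation
claim of "3% below the general population"), so costs and ICERs here are
correspondingly larger.

## Uncertainty analysis

`make_distribution()` builds method-of-moments distributions: beta for
probabilities and utilities, gamma for costs, lognormal for survival
parameters and hazard ratios (matched to a printed 95% CI when one exists).
The PSA draws every parameter independently — the published inputs come with
no correlation structure — including the per-transition $\lambda$ and
$\gamma$ on the log scale. No standard errors are published for the survival
parameters, so the bundle assumes a 10% coefficient of variation for them;
drug prices carry no uncertainty and stay fixed. Each iteration re-seeds
deterministically from the master seed (results are independent of execution
order and bit-reproducible), and infeasible draws are rejected, redrawn and
counted. The acceptability curve assigns each iteration to the strategy
maximising net monetary benefit (threshold × QALYs − cost), splitting exact
ties equally, so the curves sum to one at every threshold.

Two empirical properties of this model are worth knowing before reading PSA
output. First, the PSA mean cost of the intervention strategies sits several
percent *below* the deterministic base case (up to ≈ 8% at 500 iterations in
the test suite): lifetime cost is convex in the remission-related
parameters, because remission tapering drops the drug cost from the full
regimen to MTX-only, so parameter uncertainty lowers expected cost (Jensen's
inequality) — with degenerate distributions the PSA reproduces the
deterministic run exactly, confirming this is nonlinearity rather than a
defect. Second, in the one-way analysis under the default ranges the
mortality hazard ratio is *not* the dominant bar: it acts only during
high-activity occupancy, which the very fast high→moderate/low transition
($\lambda = 1.61$) empties within about one cycle, leaving the analysed
treatment's remission RR, its drug price and the utilities as the most
influential parameters (see `results/tornado.tsv` from
`analysis/04_owsa.R`). The source analysis reported its mortality hazard
ratio as the most influential input, which appears tied to its much shorter
survival; under the transition rules implemented here that ranking does not
emerge.

One-way bounds default to the printed 95% CI where one exists (the hazard
ratio, the RRs), mean ± 1.96 SE truncated to the feasible domain where only
an SE is printed, and ±20% where no SE exists (the lambdas, drug prices);
bounds outside the feasible domain are clipped with a warning.

## Numerical and testing choices

Degenerate inputs are rejected rather than repaired: a zero time-at-risk
with an observed event is invalid; fits with no events raise an
estimation-impossible error; `tp(u)` with `t < u` is a domain error. The
cohort trace conserves mass to 1e−12 over 200 cycles and death occupancy is
monotone. The test suite checks the engine against an independent
individual-level microsimulation (100,000 paths over 40 cycles, and a
smaller 20,000-path variant in the unit tests) within three binomial
Monte-Carlo SEs per cell, the economics against an independently coded
cycle-by-cycle accumulation to 1e−9, the transition formula against the
survival-ratio identity on a 1,000-point grid to 1e−12, and parameter
recovery on synthetic histories of 2,000 patients (3-SE criteria; at this
size one sampling SE of the near-zero remission-relapse constant is ≈ 12% of
its own magnitude, so relative-bias summaries of that parameter are noisy by
construction). PSA determinism is asserted bit-for-bit. These sizes keep the
default suite under a minute apart from the microsimulation and a 500-
iteration PSA consistency check.

## Limitations

Beyond the synthetic-input caveats above: no competing-risks joint
likelihood across transitions (each is fitted separately, as published); no
individual-level heterogeneity in the production engine (cohort-level only);
no dose-tapering alternatives to remission discontinuation; no budget
impact or fully incremental frontier across all twelve strategies (each
strategy is compared with SoC, as published); and no expected-value-of-
perfect-information analysis.
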