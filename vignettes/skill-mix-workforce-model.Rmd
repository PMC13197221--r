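---
title: "Needs-led skill-mix workforce modelling for child dental care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Needs-led skill-mix workforce modelling for child dental care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dentalmix)
```

## The problem and the model

Most childhood dental disease is preventable, and national guidance
(the Delivering Better Oral Health toolkit) prescribes what preventive
care every child should receive, with additional interventions for
children at high caries risk. `dentalmix` answers the workforce-planning
question this raises: **how many whole-time-equivalent (WTE) clinicians,
of which kinds, are needed to deliver that care to a national child
population**, and how does the answer change when tasks are delegated
from dentists to dental hygienists/therapists (DH/DThs) and extended
duties dental nurses (EDDNs)?

The model is needs-led: demand comes from population × risk × care
timings, not from historical utilisation. For age bands
$a \in \{0\text{–}4, 5\text{–}9, 10\text{–}17\}$, risk strata
$s \in \{\text{high}, \text{low}\}$, care components $c$ and cadres $g$,
annual demand minutes assigned to cadre $g$ in year $y$ are

$$D_g(y) = \sum_{c,a,s} P(a,y)\,\rho(s \mid a,y)\,\alpha\,
  w(c,a,s,g)\, t(c,a,s,g),$$

where $P$ is the band population, $\rho$ the risk-stratum fraction,
$\alpha$ the attendance rate, $w$ the scenario's delegation share and
$t$ the per-child annual minutes. Capacity per WTE is
$H_g = \text{hours/week} \times 60 \times (52 - \text{leave weeks})$,
and the workforce is the linear programme

$$\min \sum_g x_g \quad \text{s.t.} \quad H_g x_g \ge D_g, \; x_g \ge 0 .$$

Key behavioural assumptions inherited from the framing: every child
attends once a year ($\alpha = 1$ by default, adjustable — at
$\alpha = 0.5$ every workforce number halves exactly, by linearity);
each cadre dedicates 100% of its NHS clinical time to children; EDDN
task timings equal DH/DTh timings except that the EDDN examination is a
two-minute confirmatory check performed under prescription.

## Care-plan timing rules

The timing table `build_timing_table()` encodes the structural rules:

* **Fissure sealants** are applied once per tooth, so their chair time is
  amortised across the band's years: 4 sealants × 9.3 min over the five
  years of 5–9 gives 7.44 min/yr; 12 sealants × 9.3 min over the eight
  years of 10–17 gives 13.95 min/yr. High risk only.
* **Fluoride varnish**: 3 applications/yr at high risk, 2/yr at low
  risk. 0-year-olds have no dentition, so within 0–4 the high-risk
  schedule covers ages 1–4 (eligible fraction 4/5 under a uniform
  single-year age assumption) and the low-risk schedule ages 3–4 (2/5).
* **Restorative care**: 30 min/yr for every high-risk child, all ages.
* **Very brief advice** on tobacco/vaping: 0.3 min once a year for
  10–17-year-olds (most are never-smokers, so the exploration is brief).
* **Radiographs**: none under 5. The guidance is silent on whether
  low-risk 5–17-year-olds receive radiograph time; we include the cell
  and leave its value to the timing input, so setting it to zero
  recovers the stricter reading.
* **Examination**: dentists and DH/DThs perform the full
  examination/treatment plan; the EDDN equivalent is the two-minute
  confirmatory examination, modelled as a separate component so scope
  validation stays clean.

Durations for examination, radiographs, varnish application and the two
advice components are practice-timing estimates published only in a
per-team timing source that cannot be redistributed with the package;
`england_inputs()` flags them as missing (`NA`) and any computation that
needs them fails with a coverage error naming the components. Supplying
a complete timing CSV (`read_timing_csv()`) unlocks national runs.

## Scenarios and scope of practice

`builtin_scenarios()` provides six delegation patterns, `a`–`f`, from
dentists-only to maximum delegation. Scope of practice is enforced
everywhere: EDDNs may deliver varnish, advice, VBA and the confirmatory
examination only. Two design points were genuinely open:

* In the delegation scenarios whose rule is "everything else to EDDNs"
  (`c`, the remainder of `e`, and `f`), radiographs fall outside EDDN
  scope; we route them to DH/DThs so every built-in scenario passes
  validation. Routing them to dentists instead would be a one-line
  scenario edit.
* When an EDDN delivers care in a pathway where a dentist or DH/DTh
  already performs the examination of record, no confirmatory
  examination is charged. The `charge_confirmatory` toggle adds it for
  pathways without a same-visit examiner; it is off by default.

Scenario `e` carves 10% of high-risk children out to receive their whole
care plan from dentists; the remainder follows scenario `c`'s split. The
carve-out is applied to the stratum population before shares, so setting
the fraction to zero reproduces scenario `c` exactly (a property the
test suite checks).

## Population, risk and projection

The bundled England table carries the 2022 census bands 0–4, 5–9 and
10–14 with a 0–17 total; the 15–17 band is derived by subtraction so
that counts conserve the printed total. Projection anchors (2023, 2030,
2040, 2050) give totals only: totals are interpolated linearly between
anchors and category shares are frozen at the most recent detailed
anchor. No extrapolation outside the anchor span is permitted.

The overall high-risk rate follows a linear trajectory in calendar year
— 31.02% in 2023 falling to 16.56% (one standard deviation lower) by
2050 — and per-band fractions are scaled proportionally
(`new_rate / baseline_rate`, clipped to $[0,1]$), since nothing in the
source says how band-level risk evolves. Both headline populations are
runnable: `population_at(tab, 2023)` uses the 2023 projection
(12,059,255); passing `year = 2022` uses the census total (12,097,402).

## The optimiser

With fixed shares the programme separates by cadre and the optimum is
$x_g = D_g / H_g$. We nevertheless solve it as a genuine LP (a dense
two-phase primal simplex with Bland's rule, written for this package
because no LP solver library is available in the supported dependency
set) so that the optional extensions — per-cadre supply ceilings and
cost-weighted objectives — work unchanged, and we verify every returned
solution against the constraints post-solve (feasibility tolerance
$10^{-6}$ minutes). The closed-form solution is kept as an independent
oracle: the test suite compares the two on over a hundred random
instances at $10^{-9}$ relative tolerance. Published workforce numbers
are integers, but the printed rounding rule is unstated; decision
variables stay continuous and `round_for_report()` offers
round-to-nearest (default, halves up) and ceiling.

## The synthetic-data generator

`generate_population()`, `generate_risk_profile()` and
`generate_timing_table()` produce inputs with the statistical structure
the analysis assumes, so every stage is testable without any download.
Defaults, chosen once: total population 12,097,402 split over the four
census bands in their published proportions (log-normal share jitter,
SD 0.02, then largest-remainder rounding so counts sum exactly); risk
fractions drawn from a normal with mean 0.3102 and SD 0.1446 (the
one-standard-deviation spread consistent with the 31.02% → 16.56%
trajectory), clipped to $[0,1]$; unamortised unit timings uniform on
[1, 15] minutes per application, a realistic chairside range; projected
totals declining at 0.3%/yr, roughly the published trajectory. All
generators are deterministic given the seed.

What the generator emulates: band structure, risk stratification, the
timing table's structural rules (amortisation, varnish schedule, EDDN
mirroring, high ⊇ low plans). What it does not emulate: survey sampling
error in the epidemiology sources, deprivation/ethnicity gradients in
risk, regional heterogeneity, or correlated year-on-year demographic
shocks. Passing tests therefore certify the pipeline's arithmetic and
invariants on realistic structure, not the accuracy of any particular
national estimate, which depends on the real timing table being
supplied.

`parameter_recovery_check()` closes the loop end to end: it plants a
known WTE vector $x^\*$, sets capacities $H_g = D_g / x^\*_g$, runs the
full pipeline and verifies recovery to $10^{-6}$ relative — exact by
construction, so any failure indicates a defect in demand assembly or
the solver.

## Numerical choices

Share sums are validated to $\pm 10^{-9}$; population totals against
printed totals to ±1 person; a year's listed categories may undershoot
the total (the residual band is derived) but never exceed it. Largest-
remainder rounding breaks ties by order of decreasing fractional part.
Reports are bit-stable: rows sorted by year, scenario and cadre;
continuous WTE and risk rates written to two decimals; combined totals
always the sum of the rounded cadre values.

## Problem sizes used in testing

The test suite runs entirely on generated inputs at national scale
(single-year national runs and four-anchor projections), 20–100 random
LP instances, 1,000-seed Monte-Carlo calibration of the risk generator
and a 50-seed parameter-recovery sweep; the whole suite completes in
well under a minute on a single CPU.

## Known limitations

Adult care, regional disaggregation, commissioning costs, transfer time
between team members and appointment-level scheduling are out of scope.
DH and DTh registrants are modelled as one combined cadre although
restorative work is beyond a dental hygienist's scope. Headcount-to-WTE
conversion, vacancies and attrition are not modelled. The urgent-care
uplift (a fraction of the total population times a per-visit duration,
assigned to one cadre) is a deliberately coarse extension and is off by
default.
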