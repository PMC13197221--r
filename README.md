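# dentalmix

Needs-led, risk-based skill-mix workforce modelling for child dental care.

`dentalmix` sizes the dental workforce — whole-time-equivalent (WTE)
dentists, dental hygienists/therapists (DH/DThs) and extended duties
dental nurses (EDDNs) — required to deliver evidence-based preventive
care to the child population of England under alternative task-delegation
("skill mix") scenarios, projected from 2023 to 2050. It is aimed at
health-services operational researchers and workforce planners.

## The model

Children are partitioned into age bands *a* ∈ {0–4, 5–9, 10–17} and
caries-risk strata *s* ∈ {high, low}. Inputs are:

- **Population** *P(a, y)*: children per band per calendar year,
  interpolated linearly between projection anchors.
- **Risk** *r(a, y)*: the high-risk fraction per band, following a linear
  trajectory of the overall rate (31.02% in 2023 declining to 16.56% by
  2050 under improving prevention).
- **Timings** *t(c, a, s, g)*: minutes per child per year for care
  component *c* delivered by cadre *g* — annual examination, radiographs
  (5–17 only), fluoride varnish (3×/year high risk, 2×/year low risk,
  age-restricted under 5), fissure sealants amortised over the band's
  years (4 × 9.3 min / 5 yr = 7.44 min/yr for 5–9; 12 × 9.3 / 8 =
  13.95 min/yr for 10–17, high risk only), oral-health and diet advice,
  very brief advice on tobacco/vaping (0.3 min, 10–17), and 30 min/yr of
  restorative care for high-risk children.
- **Delegation shares** *w(c, a, s, g)* per scenario, validated against
  each cadre's scope of practice.
- **Capacity** *H(g)*: annual NHS clinical minutes per WTE,
  `hours/week × 60 × (52 − leave weeks)` — 76,255.2 for dentists and
  EDDNs (26.7 h, 4.4 wk leave), 33,700.8 for DH/DThs (11.8 NHS h/week).

Demand assigned to cadre *g* in year *y* is

```
D(g, y) = Σ_{c,a,s} P(a, y) · ρ(s | a, y) · attendance · w(c, a, s, g) · t(c, a, s, g)
```

and the workforce is the linear programme

```
min Σ_g x_g   subject to   H(g) · x_g ≥ D(g, y),  x_g ≥ 0
```

solved by a two-phase simplex and cross-checked against the closed-form
separable optimum *x*<sub>*g*</sub> = *D*<sub>*g*</sub>/*H*<sub>*g*</sub>.
Six built-in scenarios (`a`–`f`) range from dentists-only through to
maximum delegation, including a combination scenario in which dentists
deliver the whole care plan for 10% of high-risk children.

## Worked example

With synthetic inputs (the generator reproduces the structure of the
published tables; seed fixed for reproducibility):

```r
library(dentalmix)
cfg <- synth_config(seed = 42)
inputs <- run_config(scenario = "f", year = 2023,
                     population = generate_population(cfg),
                     risk = generate_risk_profile(cfg),
                     timings = generate_timing_table(cfg))
run_single(inputs)
#> year 2023, scenario f, risk rate 22.85%, population 12,063,555
#> <workforce_result> status: optimal
#>    cadre wte_continuous wte_reported
#>  dentist        1472.49         1472
#>   dh_dth        3999.45         3999
#>     eddn        6277.86         6278
#> combined total (reported): 11749
```

Under maximum skill mix the model needs 1,472 WTE dentists (examinations
only), 3,999 DH/DThs (sealants, restorations, radiographs) and 6,278
EDDNs (varnish and advice) for this synthetic population: 11,749 WTE in
all. Projecting to 2050 with the declining population and risk rate,
`run_projection(inputs, years = c(2023, 2030, 2040, 2050))` shows the
DH/DTh requirement falling from 3,999 to 1,726 WTE.

Reference England inputs (2022 census population with projections, the
31.02% → 16.56% risk trajectory, the evidence-based fixed durations and
NHS working patterns) are bundled as `england_inputs()`; component
durations published only in the full per-team timing source are flagged
missing there, and a run that needs them fails with a coverage error
rather than guessing — supply a complete timing CSV (see
`read_timing_csv()`) to compute national workforce numbers.

A command-line front end for shell use is installed at
`inst/cli/dentalmix.R` (subcommands `run`, `project`, `synth`,
`validate`, `scenarios`).

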