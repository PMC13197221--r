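# small in-code fixtures shared across test files

# one-component toy timing table: a single band, both risks, chosen cadres
toy_timing <- function(high = 50, low = 20, band = "0-4",
                       cadre = "dentist") {
  rows <- expand.grid(cadre = cadre, risk = c("high", "low"),
                      stringsAsFactors = FALSE)
  as_timing_table(data.frame(component = "exam", age_category = band,
                             risk = rows$risk, cadre = rows$cadre,
                             minutes_per_year =
                               ifelse(rows$risk == "high", high, low)))
}

# scenario assigning every cell of a timing table to one cadre
toy_scenario <- function(timings, cadre = "dentist", name = "toy") {
  cells <- care_plan_cells(timings)
  scenario_spec(name, data.frame(cells, cadre = cadre, share = 1,
                                 stringsAsFactors = FALSE))
}

# complete synthetic inputs for end-to-end runs
synth_inputs <- function(seed = 1) {
  cfg <- synth_config(seed = seed)
  list(cfg = cfg,
       population = generate_population(cfg),
       risk = generate_risk_profile(cfg),
       timings = generate_timing_table(cfg),
       capacities = default_capacities())
}

# the England 2022 census rows (Table-style source: three bands + a total)
england_records <- function() {
  data.frame(year = 2022,
             age_category = c("0-4", "5-9", "10-14", "0-17"),
             count = c(3237500, 3542074, 3436207, 12097402))
}
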