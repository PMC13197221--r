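test_that("scope of practice restricts EDDNs and frees dentists", {
  expect_false(scope_of_practice("eddn", "restorative"))
  expect_false(scope_of_practice("eddn", "fissure_sealants"))
  expect_false(scope_of_practice("eddn", "radiographs"))
  expect_false(scope_of_practice("eddn", "exam"))
  expect_true(scope_of_practice("eddn", "fluoride_varnish"))
  expect_true(scope_of_practice("eddn", "confirmatory_exam"))
  for (comp in setdiff(c("exam", "radiographs", "fluoride_varnish",
                         "fissure_sealants", "oh_advice", "diet_advice",
                         "vba", "restorative"), "confirmatory_exam")) {
    expect_true(scope_of_practice("dentist", comp))
    expect_true(scope_of_practice("dh_dth", comp))
  }
  expect_error(scope_of_practice("dentist", "orthodontics"), "unknown")
  expect_error(scope_of_practice("gp", "exam"), "unknown")
})

test_that("six built-in scenarios exist, validate, and share-conserve", {
  sc <- builtin_scenarios()
  expect_length(sc, 6)
  expect_named(sc, c("a", "b", "c", "d", "e", "f"))
  for (nm in names(sc)) {
    expect_length(validate_scenario(sc[[nm]]), 0)
    sums <- tapply(sc[[nm]]$shares$share,
                   paste(sc[[nm]]$shares$component,
                         sc[[nm]]$shares$age_category,
                         sc[[nm]]$shares$risk),
                   sum)
    expect_true(all(abs(sums - 1) < 1e-9))
  }
  expect_true(all(sc$a$shares$cadre == "dentist"))
  expect_true(all(sc$b$shares$cadre == "dh_dth"))
  expect_equal(sc$e$population_split,
               list(stratum = "high", fraction = 0.10, cadre = "dentist"))
  # (c) and (f) differ only in who performs the examination
  expect_equal(unique(sc$c$shares$cadre[sc$c$shares$component == "exam"]),
               "dh_dth")
  expect_equal(unique(sc$f$shares$cadre[sc$f$shares$component == "exam"]),
               "dentist")
})

test_that("scenario validation reports violations instead of raising", {
  cells <- care_plan_cells()
  bad_scope <- scenario_spec("x", data.frame(
    cells, cadre = ifelse(cells$component == "restorative", "eddn",
                          "dentist"),
    share = 1, stringsAsFactors = FALSE))
  v <- validate_scenario(bad_scope)
  expect_true(any(grepl("scope violation: restorative -> eddn", v)))

  bad_sum <- scenario_spec("y", data.frame(cells, cadre = "dentist",
                                           share = 0.9,
                                           stringsAsFactors = FALSE))
  v2 <- validate_scenario(bad_sum)
  expect_true(any(grepl("do not sum to 1", v2)))
  expect_length(v2, nrow(cells))
})

test_that("demand matches hand arithmetic on a toy population", {
  tt <- toy_timing(high = 50, low = 20)
  spec <- toy_scenario(tt)
  d <- demand_by_cadre(spec, c("0-4" = 1000), c("0-4" = 0.4), tt)
  # oracle: 1000 x (0.4 x 50 + 0.6 x 20) = 32,000 minutes
  expect_equal(unname(d$minutes["dentist"]), 32000)
  expect_equal(unname(d$minutes["dh_dth"]), 0)
  expect_equal(sum(d$breakdown$minutes), sum(d$minutes))

  # attendance scales demand linearly; 0.5 halves every entry
  d_half <- demand_by_cadre(spec, c("0-4" = 1000), c("0-4" = 0.4), tt,
                            attendance_rate = 0.5)
  expect_equal(d_half$minutes, d$minutes / 2)
  expect_equal(d_half$breakdown$minutes, d$breakdown$minutes / 2)
})

test_that("scenario (a) leaves DCP cadres idle; demand is degree-1", {
  inp <- synth_inputs(seed = 5)
  pop <- merge_to_care_bands(population_at(inp$population, 2023))
  rf <- band_risk_fractions(inp$risk$fractions,
                            population_at(inp$population, 2023))
  sc <- builtin_scenarios(care_plan_cells(inp$timings))
  da <- demand_by_cadre(sc$a, pop, rf, inp$timings)
  expect_equal(unname(da$minutes["dh_dth"]), 0)
  expect_equal(unname(da$minutes["eddn"]), 0)
  expect_gt(da$minutes["dentist"], 0)

  # homogeneity of degree 1 in the population
  d2 <- demand_by_cadre(sc$a, pop * 3, rf, inp$timings)
  expect_equal(d2$minutes, da$minutes * 3)
})

test_that("raising timings or risk never decreases any cadre's demand", {
  inp <- synth_inputs(seed = 9)
  pop <- merge_to_care_bands(population_at(inp$population, 2023))
  rf <- band_risk_fractions(inp$risk$fractions,
                            population_at(inp$population, 2023))
  sc <- builtin_scenarios(care_plan_cells(inp$timings))
  for (nm in c("c", "d", "f")) {
    base <- demand_by_cadre(sc[[nm]], pop, rf, inp$timings)
    up <- inp$timings
    i <- which(up$component == "oh_advice")[1]
    up$minutes_per_year[i] <- up$minutes_per_year[i] + 5
    d_up <- demand_by_cadre(sc[[nm]], pop, rf, up)
    expect_true(all(d_up$minutes >= base$minutes - 1e-9))
    # raising the high-risk fraction cannot reduce demand (high plan is
    # a superset of the low plan)
    d_risk <- demand_by_cadre(sc[[nm]], pop, pmin(rf + 0.05, 1),
                              inp$timings)
    expect_true(all(d_risk$minutes >= base$minutes - 1e-6))
  }
})

test_that("total delivered minutes are scenario-invariant at equal speeds", {
  # with every cadre equally fast on every component, reallocating tasks
  # moves minutes between cadres but conserves the total
  inp <- synth_inputs(seed = 13)
  pop <- merge_to_care_bands(population_at(inp$population, 2023))
  rf <- band_risk_fractions(inp$risk$fractions,
                            population_at(inp$population, 2023))
  sc <- builtin_scenarios(care_plan_cells(inp$timings))
  totals <- vapply(c("a", "b", "c", "d", "f"), function(nm) {
    sum(demand_by_cadre(sc[[nm]], pop, rf, inp$timings)$minutes)
  }, numeric(1))
  expect_equal(max(totals) - min(totals), 0, tolerance = 1e-6 * totals[1])
})

test_that("the population split carves a full-plan fraction to one cadre", {
  inp <- synth_inputs(seed = 17)
  pop <- merge_to_care_bands(population_at(inp$population, 2023))
  rf <- band_risk_fractions(inp$risk$fractions,
                            population_at(inp$population, 2023))
  cells <- care_plan_cells(inp$timings)
  sc <- builtin_scenarios(cells)

  # fraction 0 reduces scenario (e) to scenario (c)
  e0 <- sc$e
  e0$population_split$fraction <- 0
  expect_equal(demand_by_cadre(e0, pop, rf, inp$timings)$minutes,
               demand_by_cadre(sc$c, pop, rf, inp$timings)$minutes)

  # with everyone high risk, 10% of each band goes wholly to the dentist
  # and the delegated cadres keep exactly 90% of their scenario-(c) load
  rf1 <- setNames(rep(1, length(pop)), names(pop))
  de <- demand_by_cadre(sc$e, pop, rf1, inp$timings)
  dc <- demand_by_cadre(sc$c, pop, rf1, inp$timings)
  expect_equal(unname(de$minutes[c("dh_dth", "eddn")]),
               unname(0.9 * dc$minutes[c("dh_dth", "eddn")]))
  dentist_carve <- sum(vapply(names(pop), function(band) {
    0.1 * pop[[band]] *
      annual_care_minutes(inp$timings[inp$timings$cadre == "dentist", ],
                          band, "high", "dentist")
  }, numeric(1)))
  expect_equal(unname(de$minutes["dentist"]), dentist_carve)
})

test_that("urgent-care uplift and confirmatory charging add demand", {
  tt <- toy_timing(high = 50, low = 20)
  spec <- toy_scenario(tt)
  base <- demand_by_cadre(spec, c("0-4" = 1000), c("0-4" = 0.4), tt)
  up <- demand_by_cadre(spec, c("0-4" = 1000), c("0-4" = 0.4), tt,
                        urgent_uplift = 0.03, urgent_minutes = 15)
  expect_equal(unname(up$minutes["dentist"] - base$minutes["dentist"]),
               0.03 * 1000 * 15)
  expect_error(demand_by_cadre(spec, c("0-4" = 1000), c("0-4" = 0.4), tt,
                               urgent_uplift = 0.03), "urgent_minutes")

  inp <- synth_inputs(seed = 21)
  pop <- merge_to_care_bands(population_at(inp$population, 2023))
  rf <- band_risk_fractions(inp$risk$fractions,
                            population_at(inp$population, 2023))
  sc <- builtin_scenarios(care_plan_cells(inp$timings))
  noconf <- demand_by_cadre(sc$c, pop, rf, inp$timings)
  conf_spec <- sc$c
  conf_spec$charge_confirmatory <- TRUE
  conf <- demand_by_cadre(conf_spec, pop, rf, inp$timings)
  # every attending child gains the 2-minute EDDN confirmatory exam
  expect_equal(unname(conf$minutes["eddn"] - noconf$minutes["eddn"]),
               2 * sum(pop))
  expect_equal(conf$minutes["dentist"], noconf$minutes["dentist"])
})

test_that("bundled scenario YAML files mirror the built-ins", {
  dir <- system.file("extdata", "scenarios", package = "dentalmix")
  sc <- builtin_scenarios()
  for (nm in names(sc)) {
    spec <- read_scenario_yaml(file.path(dir, paste0(nm, ".yaml")))
    expect_length(validate_scenario(spec), 0)
    key <- function(d) paste(d$component, d$age_category, d$risk, d$cadre)
    a <- spec$shares[order(key(spec$shares)), ]
    b <- sc[[nm]]$shares[order(key(sc[[nm]]$shares)), ]
    expect_equal(a$cadre, b$cadre)
    expect_equal(a$share, b$share)
    if (nm == "e") {
      expect_equal(spec$population_split$fraction, 0.10)
      expect_equal(spec$population_split$cadre, "dentist")
    }
  }
})
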