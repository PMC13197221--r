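test_that("sealant amortisation follows the per-band rule", {
  expect_equal(amortised_minutes_per_year(4, 9.3, 5), 7.44)
  expect_equal(amortised_minutes_per_year(12, 9.3, 8), 13.95)
  expect_equal(amortised_minutes_per_year(0, 9.3, 5), 0)
  expect_error(amortised_minutes_per_year(4, 9.3, 0), "span_years")

  # linear in both the unit count and the unit time
  set.seed(7)
  for (i in 1:10) {
    u <- sample(0:20, 1); m <- runif(1, 0, 15); s <- sample(1:10, 1)
    expect_equal(amortised_minutes_per_year(2 * u, m, s),
                 2 * amortised_minutes_per_year(u, m, s))
    expect_equal(amortised_minutes_per_year(u, 3 * m, s),
                 3 * amortised_minutes_per_year(u, m, s))
  }
})

test_that("fluoride varnish frequency and eligibility depend on age and risk", {
  expect_equal(varnish_schedule("5-9", "high"),
               list(applications = 3, eligible_fraction = 1))
  expect_equal(varnish_schedule("5-9", "low"),
               list(applications = 2, eligible_fraction = 1))
  expect_equal(varnish_schedule("10-17", "high")$applications, 3)
  # 0-year-olds have no dentition; low-risk varnish is for 3-4-year-olds
  expect_equal(varnish_schedule("0-4", "high"),
               list(applications = 3, eligible_fraction = 4 / 5))
  expect_equal(varnish_schedule("0-4", "low"),
               list(applications = 2, eligible_fraction = 2 / 5))
})

test_that("the built timing table encodes the evidence-based durations", {
  tt <- build_timing_table(dboh_components())
  pick <- function(comp, band, risk, cad) {
    tt$minutes_per_year[tt$component == comp & tt$age_category == band &
                          tt$risk == risk & tt$cadre == cad]
  }
  expect_equal(pick("restorative", "0-4", "high", "dentist"), 30)
  expect_equal(pick("restorative", "10-17", "high", "dh_dth"), 30)
  expect_equal(pick("confirmatory_exam", "5-9", "high", "eddn"), 2)
  expect_equal(pick("vba", "10-17", "low", "eddn"), 0.3)
  expect_equal(pick("fissure_sealants", "5-9", "high", "dentist"), 7.44)
  expect_equal(pick("fissure_sealants", "10-17", "high", "dh_dth"), 13.95)
  # no radiographs under 5; sealants and restorative are high-risk only
  expect_length(pick("radiographs", "0-4", "high", "dentist"), 0)
  expect_length(pick("fissure_sealants", "5-9", "low", "dentist"), 0)
  expect_length(pick("restorative", "5-9", "low", "dh_dth"), 0)

  expect_error(
    build_timing_table(dboh_components(
      unit_minutes = list(exam = c(dentist = -1)))), "nonnegative")
  expect_error(
    build_timing_table(dboh_components(
      unit_minutes = list(restorative = c(eddn = 30)))), "scope")
})

test_that("EDDN timings mirror DH/DTh except the examination", {
  inp <- synth_inputs(seed = 11)
  tt <- inp$timings
  ed <- tt[tt$cadre == "eddn" & tt$component != "confirmatory_exam", ]
  for (i in seq_len(nrow(ed))) {
    dh <- tt$minutes_per_year[tt$component == ed$component[i] &
                                tt$age_category == ed$age_category[i] &
                                tt$risk == ed$risk[i] & tt$cadre == "dh_dth"]
    expect_equal(ed$minutes_per_year[i], dh)
  }
  # EDDNs have no 'exam' entry: theirs is the 2-minute confirmatory exam
  expect_equal(nrow(tt[tt$cadre == "eddn" & tt$component == "exam", ]), 0)
  expect_true(all(tt$minutes_per_year[tt$cadre == "eddn" &
                                        tt$component == "confirmatory_exam"]
                  == 2))
})

test_that("annual care minutes sum the cell and report missing coverage", {
  toy <- as_timing_table(data.frame(
    component = c("oh_advice", "vba"), age_category = "10-17",
    risk = "high", cadre = "dentist", minutes_per_year = c(10, 2.5)))
  expect_equal(annual_care_minutes(toy, "10-17", "high", "dentist"), 12.5)
  expect_equal(annual_care_minutes(toy[0, ], "10-17", "high", "dentist"), 0)

  eng <- england_inputs()
  expect_error(annual_care_minutes(eng$timings, "10-17", "high", "dentist"),
               "exam")

  # additivity: splitting a component's minutes leaves the cell sum fixed
  split <- as_timing_table(data.frame(
    component = c("oh_advice", "diet_advice", "vba"),
    age_category = "10-17", risk = "high", cadre = "dentist",
    minutes_per_year = c(6, 4, 2.5)))
  expect_equal(annual_care_minutes(split, "10-17", "high", "dentist"),
               annual_care_minutes(toy, "10-17", "high", "dentist"))
})

test_that("high-risk plans dominate low-risk plans for every cell", {
  for (seed in c(2, 23, 101)) {
    tt <- generate_timing_table(synth_config(seed = seed))
    for (band in care_bands()) {
      for (cad in c("dentist", "dh_dth", "eddn")) {
        hi <- sum(tt$minutes_per_year[tt$age_category == band &
                                        tt$risk == "high" & tt$cadre == cad])
        lo <- sum(tt$minutes_per_year[tt$age_category == band &
                                        tt$risk == "low" & tt$cadre == cad])
        expect_gte(hi, lo)
      }
    }
  }
})
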