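test_that("population loading validates, totals and trivial cases", {
  tab <- load_population_table(england_records())
  expect_s3_class(tab, "population_table")
  expect_equal(tab$totals$total[tab$totals$year == 2022], 12097402)

  empty <- load_population_table(
    data.frame(year = 2022, age_category = "0-17", count = 0))
  expect_equal(empty$totals$total, 0)

  three <- load_population_table(
    data.frame(year = 2022, age_category = c("0-4", "5-9", "10-17"),
               count = c(100, 200, 300)))
  expect_equal(three$totals$total, 600)

  expect_error(load_population_table(
    data.frame(year = 2022, age_category = c("0-4", "3-9"),
               count = c(1, 1))), "overlap")
  expect_error(load_population_table(
    data.frame(year = 2022, age_category = "0-4", count = -5)),
    "nonnegative")
  expect_error(load_population_table(
    data.frame(year = 2022, age_category = c("0-4", "5-17", "0-17"),
               count = c(100, 200, 350))), "total")
})

test_that("the residual 15-17 band is recovered from the 0-17 total", {
  tab <- derive_residual_category(load_population_table(england_records()))
  res <- tab$counts[tab$counts$age_category == "15-17", ]
  # oracle: independent subtraction from the printed rows
  expect_equal(res$count, 12097402 - 3237500 - 3542074 - 3436207)
  expect_equal(res$count, 1881621)

  same <- load_population_table(
    data.frame(year = 2022, age_category = c("0-9", "10-17", "0-17"),
               count = c(400, 600, 1000)))
  expect_equal(nrow(derive_residual_category(same)$counts), 2)

  over <- load_population_table(
    data.frame(year = 2022, age_category = c("0-4", "0-17"),
               count = c(900, 1000)))
  over$counts$count <- 1100  # push the listed band past the total
  expect_error(derive_residual_category(over), "residual")
})

test_that("population interpolation is exact at anchors, linear between", {
  tab <- derive_residual_category(load_population_table(rbind(
    england_records(),
    data.frame(year = c(2023, 2030, 2040, 2050), age_category = "0-17",
               count = c(12059255, 11643646, 10807953, 11121906)))))
  expect_equal(attr(population_at(tab, 2023), "total"), 12059255)
  expect_equal(attr(population_at(tab, 2050), "total"), 11121906)
  # oracle: linear midpoint of the 2030 and 2040 anchors
  expect_equal(attr(population_at(tab, 2035), "total"),
               (11643646 + 10807953) / 2)
  expect_equal(attr(population_at(tab, 2035), "total"), 11225799.5)

  # second differences vanish inside an anchor interval
  yrs <- 2031:2039
  tots <- vapply(yrs, function(y) attr(population_at(tab, y), "total"),
                 numeric(1))
  expect_equal(max(abs(diff(tots, differences = 2))), 0, tolerance = 1e-7)

  # category shares are frozen at the most recent detailed anchor
  p30 <- population_at(tab, 2030)
  p22 <- population_at(tab, 2022)
  expect_equal(as.vector(p30 / sum(p30)), as.vector(p22 / sum(p22)),
               tolerance = 1e-12)

  expect_error(population_at(tab, 2051), "extrapolation")
  expect_error(population_at(tab, 2021), "extrapolation")
})

test_that("merging categories onto care bands conserves children", {
  pop <- c("0-4" = 100, "5-9" = 200, "10-14" = 300, "15-17" = 50)
  merged <- merge_to_care_bands(pop)
  expect_equal(unname(merged), c(100, 200, 350))
  expect_equal(sum(merged), sum(pop))
  expect_error(merge_to_care_bands(c("3-6" = 10)), "single care band")
})

test_that("average risk rate behaves as a weighted mean", {
  expect_equal(average_risk_rate(c(a = 0.2, b = 0.2, c = 0.2),
                                 c(a = 5, b = 1, c = 94)), 20)
  expect_equal(average_risk_rate(c(0.1, 0.2, 0.3), c(1, 1, 1)), 20)
  expect_error(average_risk_rate(c(0.1, 0.2), c(0, 0)), "zero")
  expect_error(average_risk_rate(c(1.2, 0.2), c(1, 1)), "\\[0, 1\\]")

  set.seed(42)
  for (i in 1:20) {
    f <- runif(4)
    w <- runif(4, 0, 100)
    r <- average_risk_rate(f, w)
    # invariant to rescaling the weights
    expect_equal(average_risk_rate(f, w * 17.3), r)
    # bounded by the extreme category fractions
    expect_gte(r, 100 * min(f) - 1e-12)
    expect_lte(r, 100 * max(f) + 1e-12)
  }
})

test_that("risk trajectory interpolates linearly and scales fractions", {
  prof <- risk_profile(c("0-4" = 0.31, "5-9" = 0.31), overall_rate = 31.02,
                       trajectory = list(start_year = 2023,
                                         start_rate = 31.02,
                                         end_year = 2050,
                                         end_rate = 16.56))
  expect_equal(risk_rate_at(prof, 2023), 31.02)
  expect_equal(risk_rate_at(prof, 2050), 16.56)
  # oracle: arithmetic mean of the endpoints at the midpoint year
  expect_equal(risk_rate_at(prof, 2036.5), (31.02 + 16.56) / 2)
  expect_equal(risk_rate_at(prof, 2036.5), 23.79)
  expect_error(risk_rate_at(prof, 2060), "trajectory")

  # monotone decline between the endpoints
  rates <- vapply(2023:2050, function(y) risk_rate_at(prof, y), numeric(1))
  expect_true(all(diff(rates) < 0))

  # proportional category scaling preserves ratios and respects [0, 1]
  f50 <- risk_fractions_at(prof, 2050)
  expect_equal(unname(f50 / prof$fractions),
               rep(16.56 / 31.02, 2), tolerance = 1e-12)
  expect_true(all(f50 >= 0 & f50 <= 1))
})
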