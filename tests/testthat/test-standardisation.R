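make_strata <- function(pop, deaths = NULL) {
  g <- expand.grid(area_id = seq_along(pop),
                   age_group = c(paste(seq(0, 80, 5), seq(4, 84, 5),
                                       sep = "-"), "85+"),
                   sex = c("men", "women"),
                   period = c("1999-2003", "2004-2008"),
                   stringsAsFactors = FALSE)
  g$population <- pop[g$area_id] / (18 * 2 * 2)
  g$deaths <- if (is.null(deaths)) rep(0L, nrow(g)) else deaths
  g
}

test_that("person-years are mid-period population times five, additive over strata", {
  s <- make_strata(c(1000 * 18 * 2 * 2))
  py <- person_years(s)
  expect_equal(py$person_years, py$population * 5)
  one <- py[py$age_group == "0-4" & py$sex == "men", ]
  expect_equal(sum(one$person_years), sum(one$population) * 5)
  # two quinquennia, populations 100 and 200 -> 1,500 total person-years
  s2 <- s[s$age_group == "0-4" & s$sex == "men", ]
  s2$population <- c(100, 200)
  expect_equal(sum(person_years(s2)$person_years), 1500)
  # zero population -> zero person-years
  s$population <- 0
  expect_true(all(person_years(s)$person_years == 0))
  s$population <- -1
  expect_error(person_years(s), "non-negative")
})

test_that("pooled rates are death sums over person-year sums", {
  s <- make_strata(c(4e5, 4e5))
  s$deaths <- 0L
  pick <- s$age_group == "40-44" & s$sex == "women" & s$period == "1999-2003"
  # 10 deaths over 2 areas x (pop per stratum) x 5 person-years
  s$deaths[pick] <- 5L
  rt <- national_rates(s)
  r <- rt$rate[rt$age_group == "40-44" & rt$sex == "women" &
                 rt$period == "1999-2003"]
  py <- sum(s$population[pick]) * 5
  expect_equal(r, 10 / py)
  # a stratum with deaths 10 and person-years 100,000 has rate 1e-4
  expect_equal(10 / 1e5, 1e-4)
  expect_true(all(rt$rate[!(rt$age_group == "40-44" & rt$sex == "women" &
                              rt$period == "1999-2003")] == 0))
})

test_that("empty strata get rate zero with a warning; all-empty fails", {
  s <- make_strata(c(1000 * 72))
  s$population[s$age_group == "85+"] <- 0
  s$deaths[s$age_group == "0-4"] <- 1L
  expect_warning(rt <- national_rates(s), "zero person-years")
  expect_true(all(rt$rate[rt$age_group == "85+"] == 0))
  s$population <- 0
  expect_error(suppressWarnings(national_rates(s)), "zero person-years")
})

test_that("expected cases are additive and fail loudly on uncovered strata", {
  s <- make_strata(c(72000, 144000))
  rt <- national_rates(transform(s, deaths = 2L))
  ec <- expected_cases(s, rt)
  expect_equal(nrow(ec), 4)   # 2 areas x 2 sexes
  # doubling populations doubles expected cases (scale equivariance)
  s2 <- s
  s2$population <- 2 * s2$population
  ec2 <- expected_cases(s2, rt)
  expect_equal(ec2$expected, 2 * ec$expected)
  # all-zero rates give zero expected
  rt0 <- rt
  rt0$rate <- 0
  expect_true(all(expected_cases(s, rt0)$expected == 0))
  # a missing stratum is named in the failure
  expect_error(expected_cases(s, rt[rt$age_group != "85+", ]), "85\\+")
})

test_that("stratum structure is hard-checked at 18 x 2 x 2", {
  s <- make_strata(c(72000))
  expect_error(national_rates(s[s$age_group != "85+", ]), "18 age groups")
  expect_error(national_rates(s[s$period == "1999-2003", ]), "2 sexes and 2")
})

test_that("internally derived rates conserve total deaths exactly per sex", {
  # oracle: direct summation identity of indirect standardisation
  u <- default_universe()
  for (sx in c("men", "women")) {
    expect_equal(sum(u$areas[[paste0("expected_", sx)]]),
                 sum(u$areas[[paste0("observed_", sx)]]),
                 tolerance = 1e-9)
  }
})
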