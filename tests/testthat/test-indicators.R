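test_that("percent increase reproduces the printed worked examples", {
  expect_equal(percent_increase(580, 780), 34.5)
  expect_equal(percent_increase(580, 908), 56.6)
  expect_equal(percent_increase(57, 121), 112.3)
  expect_equal(percent_increase(100, 100), 0.0)
  expect_error(percent_increase(0, 10), "baseline")
  # monotone in the enhanced count
  expect_lte(percent_increase(100, 120), percent_increase(100, 150))
})

test_that("rounding is half away from zero", {
  expect_equal(round_half_out(0.05, 1), 0.1)
  expect_equal(round_half_out(-0.05, 1), -0.1)
  expect_equal(round_half_out(2.25, 1), 2.3)
  expect_equal(round_half_out(1.96999, 2), 1.97)
})

test_that("median age matches a sort-based oracle", {
  expect_equal(median_age(63), 63.0)
  expect_equal(median_age(c(60, 62, 64, 70)), 63.0)
  expect_true(is.na(median_age(numeric())))
  set.seed(41)
  ages <- sample(0:100, 101, replace = TRUE)
  s <- sort(ages)
  expect_equal(median_age(ages), s[51])
})

test_that("expected deaths sums rate x population over matching strata", {
  r1 <- data.frame(sex = "male", age_band = "0-4", rate = 0.01)
  p1 <- data.frame(sex = "male", age_band = "0-4", count = 1000)
  expect_equal(expected_deaths(r1, p1), 10)

  r2 <- rbind(r1, data.frame(sex = "female", age_band = "0-4",
                             rate = 0.002))
  p2 <- rbind(p1, data.frame(sex = "female", age_band = "0-4",
                             count = 5000))
  expect_equal(expected_deaths(r2, p2), 20)
  expect_error(expected_deaths(r2, p1), "mismatch")

  # random 36-stratum tables against a brute-force loop
  set.seed(42)
  grid <- expand.grid(sex = c("male", "female"),
                      age_band = age_band_levels("five_year"),
                      stringsAsFactors = FALSE)
  rates <- cbind(grid, rate = runif(nrow(grid), 0, 0.1))
  pop <- cbind(grid[sample(nrow(grid)), ], count = 0)
  pop$count <- rpois(nrow(pop), 500)
  acc <- 0
  for (i in seq_len(nrow(rates))) {
    j <- which(pop$sex == rates$sex[i] & pop$age_band == rates$age_band[i])
    acc <- acc + rates$rate[i] * pop$count[j]
  }
  expect_equal(expected_deaths(rates, pop), acc)
})

test_that("SMR exact limits match closed forms and the chi-square identity", {
  r <- smr_with_ci(50, 50)
  expect_equal(r$smr, 100)
  expect_lte(r$ci_low, r$smr); expect_gte(r$ci_high, r$smr)

  # zero observed: lower limit 0, upper -log(alpha/2) for shape-1 gamma
  r0 <- smr_with_ci(0, 2)
  expect_equal(r0$ci_low, 0)
  expect_equal(r0$ci_high, 100 * (-log(0.025)) / 2, tolerance = 1e-12)

  for (d in c(1, 10, 100, 200)) {
    r <- smr_with_ci(d, 5)
    expect_equal(r$ci_low, 100 * 0.5 * qchisq(0.025, 2 * d) / 5,
                 tolerance = 1e-9)
    expect_equal(r$ci_high, 100 * 0.5 * qchisq(0.975, 2 * (d + 1)) / 5,
                 tolerance = 1e-9)
  }
  expect_error(smr_with_ci(3, 0), "positive")
  expect_error(smr_with_ci(-1, 2), "non-negative")
})

test_that("age bands follow the two schemes", {
  expect_equal(as.character(age_band(c(0, 1, 4, 5, 84, 85, 99), "counts")),
               c("0", "1-4", "1-4", "5-9", "80-84", "85+", "85+"))
  expect_equal(as.character(age_band(c(0, 4, 5), "five_year")),
               c("0-4", "0-4", "5-9"))
  expect_equal(length(age_band_levels("counts")), 19L)
  expect_equal(length(age_band_levels("five_year")), 18L)
})

make_tables_fixture <- function(n = 400, seed = 51) {
  set.seed(seed)
  deaths <- death_records(
    death_id = sprintf("D%04d", 1:n),
    age_years = sample(0:100, n, replace = TRUE),
    sex = sample(c("male", "female"), n, replace = TRUE),
    remoteness = sample(c("MajorCities", "InnerRegional", "OuterRegional",
                          "Remote", "VeryRemote", "Unknown"), n,
                        replace = TRUE,
                        prob = c(.4, .25, .2, .07, .05, .03)),
    cause_icd10 = sample(c("C34", "C50.9", "I21", "I64", "X42", "V43",
                           "J18", "E11"), n, replace = TRUE),
    reported_indigenous = sample(c("yes", "no", "missing"), n,
                                 replace = TRUE, prob = c(.3, .6, .1)))
  results <- data.frame(
    death_id = deaths$death_id,
    as_reported = deaths$reported_indigenous == "yes",
    n_units = 0L, n_units_yes = 0L)
  extra <- runif(n)
  results$algorithm <- results$as_reported | extra < 0.15
  results$at_least_one <- results$algorithm | extra < 0.3
  class(results) <- c("enhancement_results", "data.frame")
  list(deaths = deaths, results = results)
}

test_that("count table cells equal independent group-by recomputation", {
  fx <- make_tables_fixture()
  tabs <- build_tables(fx$deaths, fx$results)
  counts <- tabs$counts

  # per-cell oracle over raw rows
  band <- as.character(age_band(fx$deaths$age_years, "counts"))
  for (i in sample(seq_len(nrow(counts)), 12)) {
    sel <- switch(counts$axis[i],
      age = band == counts$stratum[i],
      sex = fx$deaths$sex == counts$stratum[i],
      remoteness = fx$deaths$remoteness == counts$stratum[i],
      cause = icd10_group_of(fx$deaths$cause_icd10) == counts$stratum[i],
      total = rep(TRUE, nrow(fx$deaths)))
    expect_equal(counts$as_reported[i], sum(fx$results$as_reported[sel]))
    expect_equal(counts$algorithm[i], sum(fx$results$algorithm[sel]))
    expect_equal(counts$at_least_one[i],
                 sum(fx$results$at_least_one[sel]))
    if (counts$as_reported[i] > 0)
      expect_equal(counts$algorithm_increase[i],
                   percent_increase(counts$as_reported[i],
                                    counts$algorithm[i]))
  }

  # conservation: age bands sum to the Total row; remoteness strata plus
  # Unknown sum to the Total row
  tot <- counts[counts$axis == "total", ]
  expect_equal(sum(counts$as_reported[counts$axis == "age"]),
               tot$as_reported)
  unk <- sum(fx$results$as_reported[fx$deaths$remoteness == "Unknown"])
  expect_equal(sum(counts$as_reported[counts$axis == "remoteness"]) + unk,
               tot$as_reported)

  # row-order invariance
  perm <- sample(nrow(fx$deaths))
  d2 <- fx$deaths[perm, ]; r2 <- fx$results[perm, ]
  class(d2) <- class(fx$deaths); class(r2) <- class(fx$results)
  tabs2 <- build_tables(d2, r2)
  expect_equal(tabs2$counts, tabs$counts)
})

test_that("median-age table matches direct stratum medians", {
  fx <- make_tables_fixture(seed = 52)
  med <- build_tables(fx$deaths, fx$results)$median_age
  row <- med[med$axis == "total" & med$method == "algorithm", ]
  expect_equal(row$total,
               median_age(fx$deaths$age_years[fx$results$algorithm]))
  expect_equal(row$male,
               median_age(fx$deaths$age_years[fx$results$algorithm &
                                                fx$deaths$sex == "male"]))
})

test_that("SMR table uses the supplied standardisation tables", {
  fx <- make_tables_fixture(seed = 53)
  grid <- expand.grid(sex = c("male", "female"),
                      age_band = age_band_levels("five_year"),
                      stringsAsFactors = FALSE)
  set.seed(54)
  rates <- cbind(grid, rate = runif(nrow(grid), 0.001, 0.05))
  pop <- cbind(grid, count = rpois(nrow(grid), 800))
  tabs <- build_tables(fx$deaths, fx$results, rates = rates,
                       population = pop)
  smr <- tabs$smr
  # all-cause rates -> Total cause only, 3 methods x 3 sex groups
  expect_equal(nrow(smr), 9L)
  row <- smr[smr$method == "at_least_one" & smr$sex == "total", ]
  e_tot <- expected_deaths(rates, pop)
  expect_equal(row$observed, sum(fx$results$at_least_one))
  expect_equal(row$smr, 100 * row$observed / e_tot)
  # identical count columns -> identical SMRs
  fx$results$algorithm <- fx$results$at_least_one
  fx$results$as_reported <- fx$results$at_least_one
  t2 <- build_tables(fx$deaths, fx$results, rates = rates,
                     population = pop)
  expect_equal(length(unique(t2$smr$smr[t2$smr$sex == "total"])), 1L)
})
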