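# A small headcount table: 2 years x 2 sexes x bands either side of 40.
toy_headcounts <- function() {
  tidyr::expand_grid(
    year = 2012:2013, sex = c("M", "F"),
    age_band = c("20-24", "35-39", "40-44", "55-59")
  ) |>
    dplyr::mutate(count = 100 * seq_along(year))
}

test_that("annual headcounts convert to person-years linearly and additively", {
  one <- tibble::tibble(year = 2012, sex = "M", age_band = "40-44", count = 5000)
  expect_equal(person_year_denominator(one), 5000)

  h <- toy_headcounts()
  total <- person_year_denominator(h)
  expect_equal(total, sum(h$count))
  # doubling every count doubles the denominator
  h2 <- dplyr::mutate(h, count = 2 * count)
  expect_equal(person_year_denominator(h2), 2 * total)
  # sex and age strata partition the total
  parts <- c(
    person_year_denominator(h, "M", c(20, 40)),
    person_year_denominator(h, "M", c(40, 60)),
    person_year_denominator(h, "F", c(20, 40)),
    person_year_denominator(h, "F", c(40, 60))
  )
  expect_equal(sum(parts), total)

  expect_error(person_year_denominator(h, "M", c(20, 43)), "straddle")
  expect_error(
    person_year_denominator(h[h$sex == "M", ], "F"),
    "no headcount rows"
  )
  expect_error(
    person_year_denominator(dplyr::mutate(h, count = -count)),
    "non-negative"
  )
})

test_that("per-myriad is the stated fraction of 10,000", {
  expect_equal(per_myriad(100, 10000), 100)
  expect_equal(per_myriad(0, 123456), 0)
  # inverting the all-cause row of a 506,883 person-year denominator
  expect_equal(round(per_myriad(4354.1, 506883), 1), 85.9)
  expect_error(per_myriad(1, 0), "denominator")
  expect_error(per_myriad(-1, 10), "non-negative")
})

test_that("the Poisson interval matches its closed form and scales as 1/sqrt(n)", {
  ci <- rate_ci(250, 1e5)
  z <- qnorm(0.975)
  expect_equal(ci$lower, (250 - z * sqrt(250)) / 1e5 * 1e4)
  expect_equal(ci$upper, (250 + z * sqrt(250)) / 1e5 * 1e4)

  expect_equal(rate_ci(0, 1000), tibble::tibble(lower = 0, upper = 0))

  # fixed rate, growing denominator: width * sqrt(denom) is constant
  rate <- 50e-4
  denoms <- c(1e4, 4e4, 1e6)
  widths <- vapply(denoms, function(d) {
    ci <- rate_ci(rate * d, d)
    ci$upper - ci$lower
  }, numeric(1))
  expect_equal(
    widths * sqrt(denoms) / (widths[1] * sqrt(denoms[1])),
    rep(1, 3)
  )
  # the lower bound never dips below zero
  expect_gte(rate_ci(0.5, 100)$lower, 0)
  expect_error(rate_ci(10, 100, level = 1.2), "level")
})

test_that("shares reproduce the printed percentages", {
  expect_equal(round(burden_share(47.0, 85.9), 1), 54.7)
  expect_equal(burden_share(12.3, 12.3), 100)
  expect_equal(round(burden_share(6.5, 17.0), 1), 38.2)
  expect_error(burden_share(1, 0), "positive")
})

test_that("the stratum chi-squared test matches the direct 2x2 formula", {
  # equal proportions: no signal
  same <- compare_strata(100, 10000, 50, 5000)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  got <- compare_strata(100, 10000, 50, 10000)
  O <- rbind(c(100, 9900), c(50, 9950))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(got$statistic, sum((O - E)^2 / E))
  expect_equal(got$p_value, pchisq(got$statistic, df = 1, lower.tail = FALSE))

  # symmetry under swapping the strata
  swapped <- compare_strata(50, 10000, 100, 10000)
  expect_equal(swapped$statistic, got$statistic)

  expect_error(compare_strata(0, 10, 0, 10), "zero margin")
  expect_error(compare_strata(1, 0, 2, 10), "positive")
})

test_that("a single fully-observed spell tabulates to its exact per-myriad", {
  emp <- tibble::tibble(id = "e1", sex = "M", birth_date = as.Date("1980-01-01"))
  ep <- tibble::tibble(
    employee_id = "e1", start_date = as.Date("2013-01-01"),
    end_date = as.Date("2013-01-01") + 365, icd10_code = "F32", outcome = "return"
  )
  contrib <- compute_burden(emp, ep)
  tbl <- build_burden_table(contrib, emp, 10000)
  f <- tbl[tbl$disease_group == "Mental and behavioural disorders", ]
  expect_equal(
    f$per_myriad[f$consequence == "sa"],
    365 / 365.25 / 10000 * 10000
  )
  expect_equal(
    f$per_myriad[f$consequence == "total"],
    f$per_myriad[f$consequence == "sa"]
  )
  # every other group is present and zero
  other <- tbl[!tbl$disease_group %in% c("Mental and behavioural disorders", "All causes"), ]
  expect_equal(length(unique(tbl$disease_group)), 21L) # 20 groups + all-cause
  expect_true(all(other$years_lost == 0))
})

test_that("an empty burden list yields an all-zero table", {
  emp <- tibble::tibble(id = "e1", sex = "F", birth_date = as.Date("1980-01-01"))
  tbl <- build_burden_table(NULL, emp, toy_headcounts())
  expect_true(all(tbl$years_lost == 0))
  expect_true(all(tbl$per_myriad == 0))
  expect_equal(nrow(tbl), 5L * 21L * 4L) # strata x groups x consequences
})

test_that("marginal identities hold exactly before rounding", {
  p <- cohort_params(n_employees = 3000, seed = 7)
  sim <- simulate_cohort(p)
  contrib <- compute_burden(sim$employees, sim$sa_episodes, sim$deaths)
  tbl <- build_burden_table(contrib, sim$employees, sim$headcounts)

  wide <- tidyr::pivot_wider(
    tbl[c("sex", "age_group", "disease_group", "consequence", "years_lost")],
    names_from = "consequence", values_from = "years_lost"
  )
  expect_equal(wide$total, wide$sa + wide$mortality + wide$retirement)

  # group rows sum to the all-cause row
  groups <- tbl[tbl$disease_group != "All causes", ]
  allc <- tbl[tbl$disease_group == "All causes", ]
  got <- dplyr::summarise(
    dplyr::group_by(groups, sex, age_group, consequence),
    years_lost = sum(years_lost), .groups = "drop"
  )
  j <- dplyr::left_join(got, allc, by = c("sex", "age_group", "consequence"))
  expect_equal(j$years_lost.x, j$years_lost.y)

  # the four sex x age strata partition the overall years lost
  strata <- tbl[tbl$sex != "all", ]
  overall <- tbl[tbl$sex == "all", ]
  got <- dplyr::summarise(
    dplyr::group_by(strata, disease_group, consequence),
    years_lost = sum(years_lost), .groups = "drop"
  )
  j <- dplyr::left_join(got, overall, by = c("disease_group", "consequence"))
  expect_equal(j$years_lost.x, j$years_lost.y)

  # and the stratum denominators partition the overall denominator
  dns <- unique(tbl[c("sex", "age_group", "denominator")])
  expect_equal(
    sum(dns$denominator[dns$sex != "all"]),
    dns$denominator[dns$sex == "all"]
  )
})

test_that("a contribution spanning an age-group boundary splits exactly", {
  # born 1974-01-01: turns 40 on 2014-01-01, mid-spell
  emp <- tibble::tibble(id = "e1", sex = "F", birth_date = as.Date("1974-01-01"))
  ep <- tibble::tibble(
    employee_id = "e1", start_date = as.Date("2013-11-01"),
    end_date = as.Date("2014-03-01"), icd10_code = "M54", outcome = "return"
  )
  h <- toy_headcounts()
  tbl <- build_burden_table(compute_burden(emp, ep), emp, h)
  msk <- tbl[tbl$disease_group == "Diseases of the musculoskeletal system and connective tissue" &
    tbl$consequence == "sa", ]
  young <- msk$years_lost[msk$sex == "F" & msk$age_group == "20-39"]
  old <- msk$years_lost[msk$sex == "F" & msk$age_group == "40-59"]
  expect_equal(young * 365.25, 61) # 2013-11-01 .. 2014-01-01
  expect_equal(old * 365.25, 59) # 2014-01-01 .. 2014-03-01
  expect_equal(young + old, msk$years_lost[msk$sex == "all"])
})
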