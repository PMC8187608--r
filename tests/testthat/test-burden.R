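emp1 <- function(birth = "1980-01-01") {
  tibble::tibble(id = "e1", sex = "M", birth_date = as.Date(birth))
}

test_that("a returned spell contributes exactly its in-window days", {
  ep <- tibble::tibble(
    employee_id = "e1", start_date = as.Date("2013-01-01"),
    end_date = as.Date("2013-03-02"), icd10_code = "F32", outcome = "return"
  )
  b <- person_burden(emp1(), ep)
  expect_equal(nrow(b), 1L)
  expect_equal(b$consequence, "sa")
  expect_equal(b$days, 60)
  expect_equal(b$years, 60 / 365.25, tolerance = 1e-12)
})

test_that("a death without recorded absence loses the rest of the window", {
  d <- tibble::tibble(
    employee_id = "e1", date = as.Date("2015-04-01"), icd10_code = "C34"
  )
  b <- person_burden(emp1(), deaths = d)
  expect_equal(b$consequence, "mortality")
  expect_equal(b$disease_group, "Neoplasms")
  expect_equal(b$days, 1095)
  expect_equal(b$years, 1095 / 365.25, tolerance = 1e-12)
})

test_that("retirement hands off from the spell and stops at the 60th birthday", {
  # born 1957-10-01: turns 60 on 2017-10-01
  emp <- emp1("1957-10-01")
  ep <- tibble::tibble(
    employee_id = "e1", start_date = as.Date("2017-01-01"),
    end_date = as.Date("2017-07-01"), icd10_code = "F32",
    outcome = "retirement", outcome_date = as.Date("2017-07-01")
  )
  b <- person_burden(emp, ep)
  b <- b[order(b$consequence), ]
  expect_equal(b$consequence, c("retirement", "sa"))
  expect_equal(b$days[b$consequence == "sa"], 181)
  expect_equal(b$days[b$consequence == "retirement"], 92)
  expect_true(all(b$end <= as.Date("2017-10-01")))
  # zero-gap handoff: retirement starts the day the spell ends
  expect_equal(
    b$start[b$consequence == "retirement"],
    b$end[b$consequence == "sa"]
  )
})

test_that("employees with no events contribute nothing", {
  expect_equal(nrow(person_burden(emp1())), 0L)
})

test_that("boundary cases contribute exactly zero", {
  # dying on the 60th birthday: the personal window is already closed
  emp <- emp1("1955-01-15")
  d <- tibble::tibble(
    employee_id = "e1", date = as.Date("2015-01-15"), icd10_code = "I21"
  )
  expect_equal(nrow(person_burden(emp, deaths = d)), 0L)

  # spell ending exactly on the window start has no in-window day
  ep <- tibble::tibble(
    employee_id = "e1", start_date = as.Date("2012-02-01"),
    end_date = as.Date("2012-04-01"), icd10_code = "F32", outcome = "return"
  )
  expect_equal(nrow(person_burden(emp1(), ep)), 0L)
})

test_that("data-integrity violations raise distinct named errors", {
  ep <- function(outcome, start = "2014-01-01", id = "e1") {
    tibble::tibble(
      employee_id = id, start_date = as.Date(start),
      end_date = as.Date(start) + 60, icd10_code = "F32", outcome = outcome
    )
  }
  d <- tibble::tibble(
    employee_id = "e1", date = as.Date("2015-01-01"), icd10_code = "C34"
  )
  # events for someone not on the roster
  expect_error(
    compute_burden(emp1(), ep("return", id = "ghost")),
    "absent from the roster.*ghost"
  )
  # two terminal spells
  expect_error(
    compute_burden(emp1(), rbind(ep("retirement"), ep("death", start = "2015-06-01"))),
    "more than one terminal"
  )
  # retirement spell plus a death record
  expect_error(
    compute_burden(emp1(), ep("retirement"), d),
    "both a terminal spell outcome.*death record"
  )
  # a recorded death before the spell even starts
  early <- tibble::tibble(
    employee_id = "e1", date = as.Date("2013-01-01"), icd10_code = "C34"
  )
  expect_error(
    compute_burden(emp1(), ep("return"), early),
    "death precedes"
  )
  # duplicate death records
  expect_error(compute_burden(emp1(), deaths = rbind(d, d)), "more than one death")
})

test_that("interval engine agrees with the day-by-day oracle on random cases", {
  cases <- random_burden_cases(200, seed = 20260925)
  contrib <- compute_burden(cases$employees, cases$sa_episodes, cases$deaths)
  eng <- engine_totals(contrib)
  for (i in seq_len(nrow(cases$employees))) {
    emp <- cases$employees[i, ]
    want <- oracle_person_burden(emp, cases$sa_episodes, cases$deaths)
    got <- eng[eng$employee_id == emp$id, ]
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      key <- function(d) paste(d$consequence, d$disease_group)
      got <- got[order(key(got)), ]
      want <- want[order(key(want)), ]
      expect_equal(key(got), key(want))
      expect_true(all(abs(got$years - want$years) <= 1 / 365.25))
    }
  }
})

test_that("consequences never double-count a day and burden is conserved", {
  cases <- random_burden_cases(150, seed = 99)
  contrib <- compute_burden(cases$employees, cases$sa_episodes, cases$deaths)
  w <- obs_window()
  # conservation: per-employee total <= personal window length
  tot <- tapply(contrib$years, contrib$employee_id, sum)
  pw <- interval_years(personal_window(
    cases$employees$birth_date[match(names(tot), cases$employees$id)], w
  ))
  expect_true(all(tot <= pw + 1e-9))
  # disjointness: within an employee, contribution intervals never overlap
  by_emp <- split(contrib, contrib$employee_id)
  for (ec in by_emp) {
    ec <- ec[order(ec$start), ]
    if (nrow(ec) > 1L) {
      expect_true(all(utils::head(ec$end, -1) <= utils::tail(ec$start, -1)))
    }
  }
})

test_that("enlarging the observation window never shrinks a contribution", {
  cases <- random_burden_cases(150, seed = 4242)
  small <- obs_window("2013-04-01", "2017-03-31")
  big <- obs_window("2012-04-01", "2018-03-31")
  cs <- engine_totals(compute_burden(cases$employees, cases$sa_episodes, cases$deaths, small))
  cb <- engine_totals(compute_burden(cases$employees, cases$sa_episodes, cases$deaths, big))
  j <- merge(cs, cb,
    by = c("employee_id", "consequence", "disease_group"),
    all.x = TRUE, suffixes = c("_small", "_big")
  )
  expect_false(anyNA(j$years_big))
  expect_true(all(j$years_big >= j$years_small - 1e-12))
})
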