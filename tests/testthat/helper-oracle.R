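# Brute-force day-by-day oracle: enumerates every calendar day of an
# employee's personal window and labels it none / sa / mortality /
# retirement, independently of the package's interval arithmetic. Slow on
# purpose; used to pin down the clipping calculus.

oracle_birthday <- function(birth, n) {
  y <- as.integer(format(birth, "%Y")) + n
  d <- as.Date(paste0(y, format(birth, "-%m-%d")), optional = TRUE)
  if (is.na(d)) d <- as.Date(paste0(y, "-02-28")) # Feb 29 birth, non-leap year
  d
}

# Returns data.frame(consequence, disease_group, years) for one employee.
oracle_person_burden <- function(emp, episodes = NULL, deaths = NULL,
                                 window = obs_window(), min_days = 30) {
  empty <- data.frame(
    consequence = character(), disease_group = character(), years = numeric()
  )
  p_lo <- max(window$window$start, oracle_birthday(emp$birth_date, window$min_age))
  p_hi <- min(window$window$end, oracle_birthday(emp$birth_date, window$max_age))
  if (p_hi <= p_lo) {
    return(empty)
  }
  days <- seq(p_lo, p_hi - 1, by = "day")
  lab_cons <- rep(NA_character_, length(days))
  lab_grp <- rep(NA_character_, length(days))

  ep <- episodes
  if (!is.null(ep) && nrow(ep)) {
    ep <- ep[ep$employee_id == emp$id &
      as.numeric(ep$end_date - ep$start_date) >= min_days, , drop = FALSE]
  }
  dth <- deaths
  if (!is.null(dth) && nrow(dth)) {
    dth <- dth[dth$employee_id == emp$id, , drop = FALSE]
  }

  tdate <- as.Date("9999-12-31")
  tkind <- NULL
  tgrp <- NULL
  if (!is.null(ep) && nrow(ep)) {
    ti <- which(ep$outcome != "return")
    stopifnot(length(ti) <= 1L)
    if (length(ti) == 1L) {
      od <- ep$outcome_date[ti]
      if (is.na(od)) od <- ep$end_date[ti]
      tdate <- od
      tkind <- if (ep$outcome[ti] == "death") "mortality" else "retirement"
      tgrp <- icd10_group(ep$icd10_code[ti])
    }
  }
  if (!is.null(dth) && nrow(dth) == 1L) {
    tdate <- dth$date
    tkind <- "mortality"
    tgrp <- icd10_group(dth$icd10_code)
  }

  if (!is.null(ep)) {
    for (i in seq_len(nrow(ep))) {
      hit <- days >= ep$start_date[i] & days < ep$end_date[i] & days < tdate
      lab_cons[hit] <- "sa"
      lab_grp[hit] <- icd10_group(ep$icd10_code[i])
    }
  }
  if (!is.null(tkind)) {
    hit <- days >= tdate
    lab_cons[hit] <- tkind
    lab_grp[hit] <- tgrp
  }
  keep <- !is.na(lab_cons)
  if (!any(keep)) {
    return(empty)
  }
  agg <- stats::aggregate(
    list(days = rep(1, sum(keep))),
    by = list(consequence = lab_cons[keep], disease_group = lab_grp[keep]),
    FUN = sum
  )
  agg$years <- agg$days / 365.25
  agg[c("consequence", "disease_group", "years")]
}

# Random employees with random spells, outcomes and birth dates, built
# directly (not via simulate_cohort) so the oracle comparison does not
# depend on the generator. Spells may straddle the window and the
# 20th/60th birthdays; some are below the 30-day threshold; spells of one
# employee never overlap (abutting is allowed).
random_burden_cases <- function(n, seed) {
  set.seed(seed)
  codes <- c("F32", "C50", "M54", "I63", "J45", "K50")
  employees <- tibble::tibble(
    id = sprintf("R%05d", seq_len(n)),
    sex = sample(c("M", "F"), n, replace = TRUE),
    birth_date = as.Date("2012-04-01") -
      round(stats::runif(n, 15 * 365.25, 65 * 365.25))
  )
  eps <- list()
  dths <- list()
  for (i in seq_len(n)) {
    k <- sample(0:3, 1)
    rows <- NULL
    last_end <- as.Date("1900-01-01")
    if (k > 0) {
      starts <- sort(as.Date("2009-06-01") + sample.int(3400, k))
      for (si in seq_along(starts)) {
        s <- starts[si]
        if (s < last_end) next
        dur <- sample(10:600, 1)
        rows <- rbind(rows, data.frame(start = s, end = s + dur))
        last_end <- s + dur
      }
    }
    has_terminal <- FALSE
    if (!is.null(rows)) {
      m <- nrow(rows)
      outcome <- rep("return", m)
      outcome[m] <- sample(c("return", "retirement", "death"), 1,
        prob = c(0.7, 0.15, 0.15)
      )
      has_terminal <- outcome[m] != "return"
      odate <- as.Date(rep(NA, m))
      if (has_terminal) {
        odate[m] <- if (stats::runif(1) < 0.7) {
          rows$end[m]
        } else {
          rows$start[m] + sample.int(as.numeric(rows$end[m] - rows$start[m]), 1)
        }
      }
      eps[[i]] <- tibble::tibble(
        employee_id = employees$id[i],
        start_date = rows$start, end_date = rows$end,
        icd10_code = sample(codes, m, replace = TRUE),
        outcome = outcome, outcome_date = odate
      )
    }
    if (!has_terminal && stats::runif(1) < 0.12) {
      floor_date <- if (is.null(rows)) as.Date("2011-01-01") else max(rows$start)
      dths[[i]] <- tibble::tibble(
        employee_id = employees$id[i],
        date = floor_date + sample.int(1500, 1),
        icd10_code = sample(c("C34", "I21", "X70"), 1)
      )
    }
  }
  list(
    employees = employees,
    sa_episodes = dplyr::bind_rows(eps),
    deaths = dplyr::bind_rows(dths)
  )
}

# Aggregate engine contributions to (employee, consequence, group) years.
engine_totals <- function(contrib) {
  out <- stats::aggregate(
    contrib["years"],
    by = contrib[c("employee_id", "consequence", "disease_group")],
    FUN = sum
  )
  out[order(out$employee_id, out$consequence, out$disease_group), ]
}
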