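# Seeded synthetic occupational cohort: roster, long-term sickness-absence
# spells, deaths without recorded absence, and annual headcounts, with known
# generating rates so the whole accounting pipeline can be tested end to end.
#
# The generator reproduces the record *structure* of a multi-company
# occupational cohort, not any disease-specific epidemiology: spell onsets
# follow a homogeneous Poisson process over each employee's personal window,
# durations are log-normal, and each spell ends in return to work,
# ill-health retirement, or death with fixed probabilities. Spells may by
# construction straddle the window edges and the 20th/60th birthdays, so all
# clipping paths of the accounting engine occur with realistic frequency.

with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Parameters of a synthetic occupational cohort
#'
#' Defaults describe a large, mostly male workforce with burden in the
#' tens-per-myriad range: male share 0.81 (the person-year split of a large
#' Japanese multi-company cohort), ages uniform over 18-59 at the window
#' start (so some employees cross the age-20 and age-60 boundaries
#' mid-window), log-normal spell durations with median 60 days, and spell
#' outcomes of return / ill-health retirement / death with probabilities
#' 0.86 / 0.10 / 0.04.
#'
#' @param n_employees Number of employees on the roster.
#' @param sex_ratio Male share of the roster, in (0, 1).
#' @param age_range Ages (years) at the window start; uniform in between.
#' @param sa_rates Named numeric: sickness-absence onset rate per
#'   person-year by representative ICD-10 code (the code fixes the disease
#'   group of every spell it generates).
#' @param duration_meanlog,duration_sdlog Log-normal spell-duration
#'   parameters, in days.
#' @param outcome_probs Probabilities of `return`, `retirement`, `death`
#'   ending a spell (must sum to 1); either one vector for all codes or a
#'   named list keyed by ICD-10 code.
#' @param death_rates Named numeric: rate per person-year of death with no
#'   recorded preceding absence, by ICD-10 cause code.
#' @param seed Integer seed; identical parameters and seed give identical
#'   cohorts.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_employees = 10000L,
                          sex_ratio = 0.81,
                          age_range = c(18, 60),
                          sa_rates = c(
                            F32 = 0.008, M54 = 0.002, C50 = 0.0015,
                            I63 = 0.001, S82 = 0.001, K50 = 0.0005
                          ),
                          duration_meanlog = log(60),
                          duration_sdlog = 1,
                          outcome_probs = c(return = 0.86, retirement = 0.10, death = 0.04),
                          death_rates = c(C34 = 2e-4, I21 = 1e-4, X70 = 1e-4),
                          seed = 1L) {
  n_employees <- as.integer(n_employees)
  if (is.na(n_employees) || n_employees < 1L) {
    stop("cohort_params: n_employees must be a positive integer", call. = FALSE)
  }
  if (sex_ratio <= 0 || sex_ratio >= 1) {
    stop("cohort_params: sex_ratio must be in (0, 1)", call. = FALSE)
  }
  stopifnot(length(age_range) == 2L, age_range[1] < age_range[2], age_range[1] >= 0)
  if (length(sa_rates) && (is.null(names(sa_rates)) || any(!nzchar(names(sa_rates))))) {
    stop("cohort_params: sa_rates must be named by ICD-10 code", call. = FALSE)
  }
  if (any(sa_rates < 0) || any(death_rates < 0)) {
    stop("cohort_params: rates must be non-negative", call. = FALSE)
  }
  if (length(death_rates) && is.null(names(death_rates))) {
    stop("cohort_params: death_rates must be named by ICD-10 code", call. = FALSE)
  }
  if (duration_sdlog <= 0) {
    stop("cohort_params: duration_sdlog must be positive", call. = FALSE)
  }
  check_simplex <- function(p) {
    p <- p[c("return", "retirement", "death")]
    if (anyNA(p) || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("cohort_params: outcome_probs must be a (return, retirement, death) simplex",
        call. = FALSE
      )
    }
    p
  }
  if (is.list(outcome_probs)) {
    missing <- setdiff(names(sa_rates), names(outcome_probs))
    if (length(missing)) {
      stop(sprintf(
        "cohort_params: outcome_probs missing for code(s) %s",
        paste(missing, collapse = ", ")
      ), call. = FALSE)
    }
    outcome_probs <- lapply(outcome_probs, check_simplex)
  } else {
    outcome_probs <- check_simplex(outcome_probs)
  }
  structure(
    list(
      n_employees = n_employees, sex_ratio = sex_ratio, age_range = age_range,
      sa_rates = sa_rates, duration_meanlog = duration_meanlog,
      duration_sdlog = duration_sdlog, outcome_probs = outcome_probs,
      death_rates = death_rates, seed = as.integer(seed)
    ),
    class = "cohort_params"
  )
}

outcome_probs_for <- function(params, code) {
  if (is.list(params$outcome_probs)) params$outcome_probs[[code]] else params$outcome_probs
}

#' Simulate a synthetic occupational cohort
#'
#' Draws a roster, sickness-absence spells, deaths with no recorded
#' preceding absence, and annual headcounts under the given parameters. Per
#' employee, spell onsets are a homogeneous Poisson process over the
#' personal window for each diagnosis code; overlapping draws are resolved
#' by keeping the earliest-starting spell; the first terminal outcome
#' (retirement or death) censors all later events. Direct deaths are drawn
#' (exponential competing time) only for employees without a terminal
#' spell, and spells starting after a death are discarded. Headcounts count
#' the employees active (inside their personal window, not yet dead or
#' retired) on each April 1 inside the window, by sex and 5-year age band.
#'
#' The output tables satisfy every precondition of [compute_burden()];
#' durations are raw (many below the long-term threshold) so the 30-day
#' filter has work to do.
#'
#' @param params A [cohort_params()] object.
#' @param window An [obs_window()].
#' @return List with tibbles `employees`, `sa_episodes`, `deaths`,
#'   `headcounts` (the CSV schemas of [read_cohort()]).
#' @export
simulate_cohort <- function(params, window = obs_window()) {
  stopifnot(inherits(params, "cohort_params"), inherits(window, "obs_window"))
  with_local_seed(params$seed, {
    n <- params$n_employees
    employees <- tibble::tibble(
      id = sprintf("S%06d", seq_len(n)),
      sex = ifelse(stats::runif(n) < params$sex_ratio, "M", "F"),
      birth_date = window$window$start -
        round(stats::runif(n, params$age_range[1] * 365.25, params$age_range[2] * 365.25))
    )
    P <- personal_window(employees$birth_date, window)
    py <- interval_years(P)
    pdays <- interval_days(P)

    # --- raw spell draws, all codes pooled ------------------------------
    draws <- list()
    for (code in names(params$sa_rates)) {
      rate <- params$sa_rates[[code]]
      if (rate <= 0) next
      k <- stats::rpois(n, rate * py)
      idx <- rep.int(seq_len(n), k)
      if (!length(idx)) next
      onset <- P$start[idx] + floor(stats::runif(length(idx)) * pdays[idx])
      dur <- pmax(1, round(stats::rlnorm(
        length(idx), params$duration_meanlog, params$duration_sdlog
      )))
      pr <- outcome_probs_for(params, code)
      draws[[code]] <- tibble::tibble(
        emp = idx,
        start_date = onset,
        end_date = onset + dur,
        icd10_code = code,
        outcome = sample(names(pr), length(idx), replace = TRUE, prob = pr)
      )
    }
    ep <- if (length(draws)) dplyr::bind_rows(draws) else NULL

    # --- per-employee resolution: no overlaps, first terminal wins ------
    if (!is.null(ep) && nrow(ep)) {
      ep <- ep[order(ep$emp, ep$start_date), ]
      keep_idx <- unlist(lapply(split(seq_len(nrow(ep)), ep$emp), function(rows) {
        keep <- integer()
        reach <- -Inf
        for (r in rows) {
          if (as.numeric(ep$start_date[r]) < reach) next
          keep <- c(keep, r)
          reach <- as.numeric(ep$end_date[r])
          if (ep$outcome[r] != "return") break
        }
        keep
      }), use.names = FALSE)
      ep <- ep[sort(keep_idx), ]
    }

    # --- direct deaths for employees with no terminal spell -------------
    terminal_emp <- if (!is.null(ep)) unique(ep$emp[ep$outcome != "return"]) else integer()
    deaths <- death_template()
    total_death_rate <- sum(params$death_rates)
    if (total_death_rate > 0) {
      eligible <- setdiff(which(py > 0), terminal_emp)
      t_days <- stats::rexp(length(eligible), total_death_rate) * 365.25
      hit <- t_days < pdays[eligible]
      who <- eligible[hit]
      if (length(who)) {
        deaths <- tibble::tibble(
          employee_id = employees$id[who],
          date = P$start[who] + floor(t_days[hit]),
          icd10_code = sample(names(params$death_rates), length(who),
            replace = TRUE, prob = params$death_rates
          )
        )
        # nothing can start after death
        if (!is.null(ep) && nrow(ep)) {
          dd <- deaths$date[match(employees$id[ep$emp], deaths$employee_id)]
          ep <- ep[is.na(dd) | ep$start_date <= dd, ]
        }
      }
    }

    sa_episodes <- if (is.null(ep) || nrow(ep) == 0L) {
      episode_template()
    } else {
      tibble::tibble(
        employee_id = employees$id[ep$emp],
        start_date = ep$start_date,
        end_date = ep$end_date,
        icd10_code = ep$icd10_code,
        outcome = ep$outcome,
        outcome_date = as.Date(ifelse(ep$outcome == "return", NA, ep$end_date))
      )
    }

    # --- annual headcounts on April 1 -----------------------------------
    yrs <- seq(
      as.integer(format(window$window$start, "%Y")),
      as.integer(format(window$window$end, "%Y"))
    )
    aprils <- as.Date(sprintf("%d-04-01", yrs))
    aprils <- aprils[aprils >= window$window$start & aprils < window$window$end]
    term_date <- rep(SENTINEL_FUTURE, n)
    if (!is.null(ep) && nrow(ep)) {
      te <- ep[ep$outcome != "return", ]
      term_date[te$emp] <- te$end_date
    }
    if (nrow(deaths)) {
      j <- match(deaths$employee_id, employees$id)
      term_date[j] <- pmin(term_date[j], deaths$date)
    }
    hc <- list()
    for (a in seq_along(aprils)) {
      apr <- aprils[a]
      active <- P$start <= apr & apr < P$end & term_date > apr
      if (!any(active)) next
      yr <- as.integer(format(apr, "%Y"))
      age <- as.integer(format(apr, "%Y")) - as.integer(format(employees$birth_date, "%Y")) -
        (format(apr, "%m-%d") < format(employees$birth_date, "%m-%d"))
      lo <- (age %/% 5) * 5
      hc[[a]] <- dplyr::count(
        tibble::tibble(
          year = yr, sex = employees$sex[active],
          age_band = sprintf("%d-%d", lo[active], lo[active] + 4)
        ),
        .data$year, .data$sex, .data$age_band,
        name = "count"
      )
    }
    headcounts <- if (length(hc)) {
      dplyr::bind_rows(hc)
    } else {
      tibble::tibble(
        year = integer(), sex = character(),
        age_band = character(), count = integer()
      )
    }

    list(
      employees = employees, sa_episodes = sa_episodes,
      deaths = deaths, headcounts = headcounts
    )
  })
}

#' Monte-Carlo expected per-myriad burden under cohort parameters
#'
#' Averages the full pipeline (simulate, account, tabulate) over independent
#' replicates, giving the reference ("true") per-myriad burden per disease
#' group and consequence for parameter-recovery and coverage tests.
#' Replicate *r* uses seed `seed + r`.
#'
#' @param params A [cohort_params()].
#' @param window An [obs_window()].
#' @param n_reps Number of replicates; default 20.
#' @param seed Base seed for the replicate schedule; defaults to
#'   `params$seed * 1000`.
#' @return Tibble: `disease_group`, `consequence`, `mean_per_myriad`,
#'   `sd_per_myriad`, `se_per_myriad`, `n_reps`.
#' @export
expected_burden <- function(params, window = obs_window(), n_reps = 20L,
                            seed = params$seed * 1000L) {
  stopifnot(inherits(params, "cohort_params"), n_reps >= 2L)
  reps <- lapply(seq_len(n_reps), function(r) {
    p <- params
    p$seed <- as.integer(seed + r)
    sim <- simulate_cohort(p, window)
    contrib <- compute_burden(sim$employees, sim$sa_episodes, sim$deaths, window)
    tbl <- build_burden_table(contrib, sim$employees, sim$headcounts,
      window = window, age_breaks = NULL, by_sex = FALSE
    )
    tbl$replicate <- r
    tbl
  })
  all <- dplyr::bind_rows(reps)
  dplyr::summarise(
    dplyr::group_by(all, .data$disease_group, .data$consequence),
    mean_per_myriad = mean(.data$per_myriad),
    sd_per_myriad = stats::sd(.data$per_myriad),
    se_per_myriad = stats::sd(.data$per_myriad) / sqrt(n_reps),
    n_reps = n_reps,
    .groups = "drop"
  )
}
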