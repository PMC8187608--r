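# The clipping calculus: turn an employee's sickness-absence spells, death
# and ill-health retirement into working-years-lost contributions.
#
# Every contribution is a half-open calendar interval clipped to the
# employee's personal window (study window intersected with their
# 20th-to-60th-birthday span). Consequences partition calendar time:
#   sa          spell days up to (excluding) any terminal event date
#   mortality   death date to the end of the personal window
#   retirement  retirement date to the end of the personal window
# so no day is ever counted under two consequences.

normalize_employees <- function(employees) {
  required <- c("id", "sex", "birth_date")
  missing <- setdiff(required, names(employees))
  if (length(missing)) {
    stop(sprintf("employees: missing column(s) %s", paste(missing, collapse = ", ")),
      call. = FALSE
    )
  }
  emp <- tibble::as_tibble(employees)
  emp$id <- as.character(emp$id)
  emp$sex <- as.character(emp$sex)
  emp$birth_date <- as.Date(emp$birth_date)
  if (!all(emp$sex %in% c("M", "F"))) {
    stop("employees: sex must be 'M' or 'F'", call. = FALSE)
  }
  if (anyNA(emp$birth_date)) stop("employees: missing birth date(s)", call. = FALSE)
  dup <- unique(emp$id[duplicated(emp$id)])
  if (length(dup)) {
    stop(sprintf(
      "employees: duplicated id(s) %s",
      paste(dup, collapse = ", ")
    ), call. = FALSE)
  }
  emp[required]
}

contribution_template <- function() {
  tibble::tibble(
    employee_id = character(),
    consequence = character(),
    disease_group = character(),
    start = as.Date(character()),
    end = as.Date(character()),
    days = numeric(),
    years = numeric()
  )
}

clip_rows <- function(employee_id, consequence, disease_group, start, end) {
  start <- unname(start)
  end <- unname(end)
  keep <- end > start
  days <- as.numeric(end - start)[keep]
  tibble::tibble(
    employee_id = employee_id[keep],
    consequence = consequence[keep],
    disease_group = disease_group[keep],
    start = start[keep],
    end = end[keep],
    days = days,
    years = days / 365.25
  )
}

#' Working-years-lost contributions for a whole cohort
#'
#' The main accounting engine. Applies the long-term filter
#' ([filter_ltsa()]) and spell merging ([merge_episodes()]), resolves each
#' employee's terminal event (death or ill-health retirement, from a spell
#' outcome or from the deaths table), then clips every resulting loss
#' interval to the employee's personal window.
#'
#' Loss attribution:
#' * each spell contributes `sa` days over its span, truncated at any
#'   terminal event date;
#' * a death at date *d* contributes `mortality` from *d* to the end of the
#'   personal window, attributed to the death cause (the spell diagnosis
#'   when death ended a spell, the death-certificate cause otherwise);
#' * an ill-health retirement at date *r* contributes `retirement` from *r*
#'   to the end of the personal window, attributed to the spell diagnosis.
#'
#' Data-integrity violations raise distinct errors: events for employees not
#' on the roster, more than one terminal event (e.g. both retirement and
#' death), a duplicate death record for a spell that already ended in death,
#' and a recorded death preceding a spell's start.
#'
#' @param employees Roster tibble: `id`, `sex` (`"M"`/`"F"`), `birth_date`.
#' @param episodes Sickness-absence tibble (see [merge_episodes()]); may be
#'   `NULL`.
#' @param deaths Deaths with no preceding recorded absence: `employee_id`,
#'   `date`, `icd10_code`; may be `NULL`.
#' @param window An [obs_window()].
#' @param ltsa_min_days Minimum raw spell length in days; default 30.
#' @param unmapped Passed to [icd10_group()].
#' @return A tibble of contributions: `employee_id`, `consequence`
#'   (`"sa"`/`"mortality"`/`"retirement"`), `disease_group`, clipped `start`
#'   and `end` dates, `days`, and `years` (`days / 365.25`). Employees with
#'   no in-window loss contribute no rows.
#' @examples
#' emp <- tibble::tibble(id = "e1", sex = "M", birth_date = as.Date("1980-01-01"))
#' ep <- tibble::tibble(
#'   employee_id = "e1", start_date = as.Date("2013-01-01"),
#'   end_date = as.Date("2013-03-02"), icd10_code = "F32", outcome = "return"
#' )
#' compute_burden(emp, ep, window = obs_window())
#' @export
compute_burden <- function(employees, episodes = NULL, deaths = NULL,
                           window = obs_window(), ltsa_min_days = 30L,
                           unmapped = c("error", "unclassified")) {
  unmapped <- match.arg(unmapped)
  stopifnot(inherits(window, "obs_window"))
  emp <- normalize_employees(employees)
  ep <- filter_ltsa(normalize_episodes(episodes), ltsa_min_days)
  ep <- merge_episodes(ep, unmapped)
  dth <- normalize_deaths(deaths)

  unknown <- setdiff(unique(c(ep$employee_id, dth$employee_id)), emp$id)
  if (length(unknown)) {
    stop(sprintf(
      "compute_burden: events for employee(s) absent from the roster: %s",
      paste(unknown, collapse = ", ")
    ), call. = FALSE)
  }

  # --- terminal events: at most one per employee -------------------------
  term_ep <- ep[ep$outcome != "return", ]
  dup <- unique(term_ep$employee_id[duplicated(term_ep$employee_id)])
  if (length(dup)) {
    stop(sprintf(
      "compute_burden: more than one terminal spell outcome for employee(s) %s",
      paste(dup, collapse = ", ")
    ), call. = FALSE)
  }
  both <- intersect(term_ep$employee_id, dth$employee_id)
  if (length(both)) {
    kinds <- term_ep$outcome[match(both, term_ep$employee_id)]
    stop(sprintf(
      "compute_burden: employee(s) %s have both a terminal spell outcome (%s) and a death record",
      paste(both, collapse = ", "), paste(kinds, collapse = ", ")
    ), call. = FALSE)
  }
  terminal <- rbind(
    data.frame(
      employee_id = term_ep$employee_id,
      terminal_date = term_ep$outcome_date,
      terminal_kind = term_ep$outcome,
      terminal_group = term_ep$disease_group,
      stringsAsFactors = FALSE
    ),
    data.frame(
      employee_id = dth$employee_id,
      terminal_date = dth$date,
      terminal_kind = rep("death", nrow(dth)),
      terminal_group = if (nrow(dth)) icd10_group(dth$icd10_code, unmapped) else character(),
      stringsAsFactors = FALSE
    )
  )

  # a death can truncate a spell, but cannot precede one
  if (nrow(ep) && nrow(terminal)) {
    j <- match(ep$employee_id, terminal$employee_id)
    dies <- !is.na(j) & terminal$terminal_kind[j] == "death"
    bad <- dies & terminal$terminal_date[j] < ep$start_date
    if (any(bad)) {
      stop(sprintf(
        "compute_burden: death precedes a sickness-absence spell for employee(s) %s",
        paste(unique(ep$employee_id[bad]), collapse = ", ")
      ), call. = FALSE)
    }
  }

  # --- personal windows --------------------------------------------------
  P <- personal_window(emp$birth_date, window)
  p_start <- stats::setNames(P$start, emp$id)
  p_end <- stats::setNames(P$end, emp$id)

  # --- sa contributions --------------------------------------------------
  tcut <- rep(SENTINEL_FUTURE, nrow(ep))
  if (nrow(terminal)) {
    j <- match(ep$employee_id, terminal$employee_id)
    tcut[!is.na(j)] <- terminal$terminal_date[j[!is.na(j)]]
  }
  sa <- clip_rows(
    ep$employee_id, rep("sa", nrow(ep)), ep$disease_group,
    pmax(ep$start_date, p_start[ep$employee_id]),
    pmin(ep$end_date, tcut, p_end[ep$employee_id])
  )

  # --- terminal contributions -------------------------------------------
  consequence <- ifelse(terminal$terminal_kind == "death", "mortality", "retirement")
  term <- clip_rows(
    terminal$employee_id, consequence, terminal$terminal_group,
    pmax(terminal$terminal_date, p_start[terminal$employee_id]),
    p_end[terminal$employee_id]
  )

  out <- rbind(contribution_template(), sa, term)
  out[order(out$employee_id, out$start), ]
}

#' Working-years-lost contributions for a single employee
#'
#' Convenience wrapper around [compute_burden()] for one person; the result
#' decomposes that employee's lost working years by consequence and disease
#' group. An employee with no events (or none inside their personal window)
#' yields a zero-row tibble.
#'
#' @param employee A one-row tibble or list with `id`, `sex`, `birth_date`.
#' @param episodes,deaths Event tables for (at least) this employee; rows
#'   for other employees are ignored.
#' @param window An [obs_window()].
#' @inheritParams compute_burden
#' @return Contribution tibble as in [compute_burden()].
#' @export
person_burden <- function(employee, episodes = NULL, deaths = NULL,
                          window = obs_window(), ltsa_min_days = 30L,
                          unmapped = c("error", "unclassified")) {
  emp <- normalize_employees(tibble::as_tibble(employee[c("id", "sex", "birth_date")]))
  if (nrow(emp) != 1L) stop("person_burden: exactly one employee expected", call. = FALSE)
  ep <- normalize_episodes(episodes)
  dth <- normalize_deaths(deaths)
  compute_burden(
    emp,
    ep[ep$employee_id == emp$id, ],
    dth[dth$employee_id == emp$id, ],
    window = window, ltsa_min_days = ltsa_min_days, unmapped = unmapped
  )
}
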