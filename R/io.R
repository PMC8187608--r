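# CSV readers/writers for the four input tables and the burden table, plus
# the aligned-text report renderer. All dates are ISO 8601 (YYYY-MM-DD);
# anything else is rejected with the offending line number. Unknown columns
# are ignored with a warning so upstream HR extracts can carry extra fields.

read_raw_csv <- function(path, expected, optional = character()) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  raw <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing <- setdiff(expected, names(raw))
  if (length(missing)) {
    stop(sprintf(
      "%s: missing required column(s) %s",
      basename(path), paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  extra <- setdiff(names(raw), c(expected, optional))
  if (length(extra)) {
    warning(sprintf(
      "%s: ignoring unknown column(s) %s",
      basename(path), paste(extra, collapse = ", ")
    ), call. = FALSE)
  }
  raw[intersect(c(expected, optional), names(raw))]
}

# Validate a character column of ISO dates; returns Dates and appends
# per-row messages (with file line numbers, header = line 1) to the
# collector environment.
check_iso_dates <- function(x, column, file, errors, allow_na = FALSE) {
  ok_form <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  parsed <- as.Date(rep(NA_character_, length(x)))
  parsed[ok_form] <- as.Date(x[ok_form], format = "%Y-%m-%d", optional = TRUE)
  bad <- if (allow_na) {
    !is.na(x) & nzchar(x) & (!ok_form | is.na(parsed))
  } else {
    !ok_form | is.na(parsed)
  }
  if (any(bad)) {
    errors$msgs <- c(errors$msgs, sprintf(
      "%s line %d: invalid date '%s' in column %s",
      file, which(bad) + 1L, x[bad], column
    ))
  }
  parsed
}

collect_errors <- function() new.env(parent = emptyenv())

raise_collected <- function(errors) {
  if (length(errors$msgs)) {
    stop(paste(
      c(
        sprintf("%d row-level validation error(s):", length(errors$msgs)),
        errors$msgs
      ),
      collapse = "\n"
    ), call. = FALSE)
  }
}

#' Read and validate the four cohort input tables
#'
#' Reads `employees.csv` (`id`, `sex`, `birth_date`), `sa_episodes.csv`
#' (`employee_id`, `start_date`, `end_date`, `icd10_code`, `outcome`,
#' optional `outcome_date`), `deaths.csv` (`employee_id`, `date`,
#' `icd10_code`) and `headcounts.csv` (`year`, `sex`, `age_band`, `count`)
#' from a directory. Episode and death files may be absent (treated as
#' empty). Row-level problems (unparseable dates, bad enumerations) are
#' collected and reported together with line numbers before aborting, and
#' every episode or death must reference a rostered employee.
#'
#' @param dir Directory holding the CSV files.
#' @return List with tibbles `employees`, `sa_episodes`, `deaths`,
#'   `headcounts`.
#' @export
read_cohort <- function(dir) {
  errors <- collect_errors()

  path <- file.path(dir, "employees.csv")
  raw <- read_raw_csv(path, c("id", "sex", "birth_date"))
  employees <- tibble::tibble(
    id = raw$id,
    sex = raw$sex,
    birth_date = check_iso_dates(raw$birth_date, "birth_date", "employees.csv", errors)
  )
  bad_sex <- !(raw$sex %in% c("M", "F"))
  if (any(bad_sex)) {
    errors$msgs <- c(errors$msgs, sprintf(
      "employees.csv line %d: sex must be M or F, got '%s'",
      which(bad_sex) + 1L, raw$sex[bad_sex]
    ))
  }

  ep_path <- file.path(dir, "sa_episodes.csv")
  if (file.exists(ep_path)) {
    raw <- read_raw_csv(
      ep_path,
      c("employee_id", "start_date", "end_date", "icd10_code", "outcome"),
      optional = "outcome_date"
    )
    out_raw <- if ("outcome_date" %in% names(raw)) raw$outcome_date else rep(NA_character_, nrow(raw))
    sa_episodes <- tibble::tibble(
      employee_id = raw$employee_id,
      start_date = check_iso_dates(raw$start_date, "start_date", "sa_episodes.csv", errors),
      end_date = check_iso_dates(raw$end_date, "end_date", "sa_episodes.csv", errors),
      icd10_code = raw$icd10_code,
      outcome = raw$outcome,
      outcome_date = check_iso_dates(out_raw, "outcome_date", "sa_episodes.csv", errors,
        allow_na = TRUE
      )
    )
    bad_out <- !(raw$outcome %in% c("return", "retirement", "death"))
    if (any(bad_out)) {
      errors$msgs <- c(errors$msgs, sprintf(
        "sa_episodes.csv line %d: outcome must be return/retirement/death, got '%s'",
        which(bad_out) + 1L, raw$outcome[bad_out]
      ))
    }
  } else {
    sa_episodes <- episode_template()
  }

  d_path <- file.path(dir, "deaths.csv")
  if (file.exists(d_path)) {
    raw <- read_raw_csv(d_path, c("employee_id", "date", "icd10_code"))
    deaths <- tibble::tibble(
      employee_id = raw$employee_id,
      date = check_iso_dates(raw$date, "date", "deaths.csv", errors),
      icd10_code = raw$icd10_code
    )
  } else {
    deaths <- death_template()
  }

  path <- file.path(dir, "headcounts.csv")
  raw <- read_raw_csv(path, c("year", "sex", "age_band", "count"))
  yr <- suppressWarnings(as.integer(raw$year))
  cnt <- suppressWarnings(as.numeric(raw$count))
  bad <- is.na(yr)
  if (any(bad)) {
    errors$msgs <- c(errors$msgs, sprintf(
      "headcounts.csv line %d: invalid year '%s'", which(bad) + 1L, raw$year[bad]
    ))
  }
  bad <- is.na(cnt) | cnt < 0
  if (any(bad)) {
    errors$msgs <- c(errors$msgs, sprintf(
      "headcounts.csv line %d: invalid count '%s'", which(bad) + 1L, raw$count[bad]
    ))
  }
  headcounts <- tibble::tibble(
    year = yr, sex = raw$sex, age_band = raw$age_band, count = cnt
  )

  raise_collected(errors)

  orphans <- setdiff(
    unique(c(sa_episodes$employee_id, deaths$employee_id)),
    employees$id
  )
  if (length(orphans)) {
    stop(sprintf(
      "events reference employee id(s) absent from the roster: %s",
      paste(orphans, collapse = ", ")
    ), call. = FALSE)
  }

  list(
    employees = normalize_employees(employees),
    sa_episodes = normalize_episodes(sa_episodes),
    deaths = normalize_deaths(deaths),
    headcounts = normalize_headcounts(headcounts)[
      , c("year", "sex", "age_band", "count")
    ]
  )
}

#' Write a cohort's four tables as CSV
#'
#' Inverse of [read_cohort()]; `dir` is created if needed.
#'
#' @param cohort List with `employees`, `sa_episodes`, `deaths`,
#'   `headcounts` (as from [simulate_cohort()] or [read_cohort()]).
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(cohort$employees, file.path(dir, "employees.csv"))
  readr::write_csv(cohort$sa_episodes, file.path(dir, "sa_episodes.csv"))
  readr::write_csv(cohort$deaths, file.path(dir, "deaths.csv"))
  readr::write_csv(cohort$headcounts, file.path(dir, "headcounts.csv"))
  invisible(dir)
}

#' Write / read a burden table as CSV
#'
#' Values are written unrounded; write-then-read is the identity on the
#' numeric columns (rounding is purely a presentation concern, see
#' [format_burden_report()]).
#'
#' @param table Burden table from [build_burden_table()].
#' @param path CSV path.
#' @return `path` invisibly (write); the table (read).
#' @export
write_burden_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname write_burden_table
#' @export
read_burden_table <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    sex = readr::col_character(),
    age_group = readr::col_character(),
    disease_group = readr::col_character(),
    consequence = readr::col_character(),
    years_lost = readr::col_double(),
    denominator = readr::col_double(),
    per_myriad = readr::col_double(),
    ci_low = readr::col_double(),
    ci_high = readr::col_double()
  ), progress = FALSE)
}

#' Render a burden table as an aligned markdown report
#'
#' One section per stratum; columns ordered Total, Sickness absence,
#' Mortality, Ill health retirement; cells formatted `est (lo, hi)` with
#' one decimal (presentation only - numbers are never altered, only
#' rounded for display). Disease groups are sorted by descending total
#' burden; the all-cause row closes each section.
#'
#' @param table Burden table from [build_burden_table()].
#' @return Character vector of report lines.
#' @export
format_burden_report <- function(table) {
  cell <- function(est, lo, hi) sprintf("%.1f (%.1f, %.1f)", est, lo, hi)
  cons_cols <- c(
    total = "Total", sa = "Sickness absence",
    mortality = "Mortality", retirement = "Ill health retirement"
  )
  lines <- character()
  strata <- unique(table[c("sex", "age_group")])
  for (s in seq_len(nrow(strata))) {
    sx <- strata$sex[s]
    ag <- strata$age_group[s]
    sub <- table[table$sex == sx & table$age_group == ag, ]
    wide <- tidyr::pivot_wider(
      sub[c("disease_group", "consequence", "per_myriad", "ci_low", "ci_high")],
      names_from = "consequence",
      values_from = c("per_myriad", "ci_low", "ci_high")
    )
    allc <- wide$disease_group == "All causes"
    wide <- rbind(
      wide[!allc, ][order(-wide$per_myriad_total[!allc], wide$disease_group[!allc]), ],
      wide[allc, ]
    )
    wide$disease_group[wide$disease_group == "All causes"] <- "Total"
    body <- data.frame(`Disease category` = wide$disease_group, check.names = FALSE)
    for (cc in names(cons_cols)) {
      body[[cons_cols[[cc]]]] <- cell(
        wide[[paste0("per_myriad_", cc)]],
        wide[[paste0("ci_low_", cc)]],
        wide[[paste0("ci_high_", cc)]]
      )
    }
    widths <- vapply(
      names(body),
      function(nm) max(nchar(c(nm, body[[nm]]))), numeric(1)
    )
    pad <- function(x, w) formatC(x, width = -w)
    header <- sprintf(
      "Working life years lost per 10,000 person-years - stratum: sex %s, age %s",
      sx, ag
    )
    lines <- c(
      lines, header, "",
      paste0("| ", paste(Map(pad, names(body), widths), collapse = " | "), " |"),
      paste0("|-", paste(vapply(widths, function(w) {
        paste(rep("-", w), collapse = "")
      }, character(1)), collapse = "-|-"), "-|")
    )
    for (r in seq_len(nrow(body))) {
      lines <- c(lines, paste0(
        "| ",
        paste(Map(pad, as.character(body[r, ]), widths), collapse = " | "),
        " |"
      ))
    }
    lines <- c(lines, "")
  }
  lines
}
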