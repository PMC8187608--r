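# Normalisation, long-term filtering and merging of sickness-absence spells.
#
# Episode tables are plain tibbles with columns:
#   employee_id, start_date, end_date, icd10_code, outcome, outcome_date
# where [start_date, end_date) is the half-open absence span, outcome is one
# of "return" / "retirement" / "death", and outcome_date (required
# conceptually for terminal outcomes) defaults to end_date when missing.

SENTINEL_FUTURE <- as.Date("9999-12-31")

episode_template <- function() {
  tibble::tibble(
    employee_id = character(),
    start_date = as.Date(character()),
    end_date = as.Date(character()),
    icd10_code = character(),
    outcome = character(),
    outcome_date = as.Date(character())
  )
}

death_template <- function() {
  tibble::tibble(
    employee_id = character(),
    date = as.Date(character()),
    icd10_code = character()
  )
}

normalize_episodes <- function(episodes) {
  if (is.null(episodes) || nrow(episodes) == 0L) {
    return(episode_template())
  }
  required <- c("employee_id", "start_date", "end_date", "icd10_code", "outcome")
  missing <- setdiff(required, names(episodes))
  if (length(missing)) {
    stop(sprintf("episodes: missing column(s) %s", paste(missing, collapse = ", ")),
      call. = FALSE
    )
  }
  ep <- tibble::as_tibble(episodes)
  ep$employee_id <- as.character(ep$employee_id)
  ep$start_date <- as.Date(ep$start_date)
  ep$end_date <- as.Date(ep$end_date)
  ep$icd10_code <- parse_icd10(ep$icd10_code)
  if (!all(ep$outcome %in% c("return", "retirement", "death"))) {
    stop("episodes: outcome must be one of return/retirement/death", call. = FALSE)
  }
  if (!"outcome_date" %in% names(ep)) ep$outcome_date <- as.Date(NA)
  ep$outcome_date <- as.Date(ep$outcome_date)
  if (any(ep$end_date <= ep$start_date)) {
    stop("episodes: empty or inverted absence span(s)", call. = FALSE)
  }
  # terminal outcomes: default the event date to the spell end, then require
  # it to sit inside (or at the boundary of) the spell
  terminal <- ep$outcome != "return"
  ep$outcome_date[terminal & is.na(ep$outcome_date)] <-
    ep$end_date[terminal & is.na(ep$outcome_date)]
  ep$outcome_date[!terminal] <- as.Date(NA)
  bad <- terminal &
    (ep$outcome_date < ep$start_date | ep$outcome_date > ep$end_date)
  if (any(bad)) {
    stop(sprintf(
      "episodes: outcome_date outside the absence span for employee(s) %s",
      paste(unique(ep$employee_id[bad]), collapse = ", ")
    ), call. = FALSE)
  }
  ep[c("employee_id", "start_date", "end_date", "icd10_code", "outcome", "outcome_date")]
}

normalize_deaths <- function(deaths) {
  if (is.null(deaths) || nrow(deaths) == 0L) {
    return(death_template())
  }
  required <- c("employee_id", "date", "icd10_code")
  missing <- setdiff(required, names(deaths))
  if (length(missing)) {
    stop(sprintf("deaths: missing column(s) %s", paste(missing, collapse = ", ")),
      call. = FALSE
    )
  }
  d <- tibble::as_tibble(deaths)
  d$employee_id <- as.character(d$employee_id)
  d$date <- as.Date(d$date)
  d$icd10_code <- parse_icd10(d$icd10_code)
  if (anyNA(d$date)) stop("deaths: missing date(s)", call. = FALSE)
  dup <- unique(d$employee_id[duplicated(d$employee_id)])
  if (length(dup)) {
    stop(sprintf(
      "deaths: more than one death record for employee(s) %s",
      paste(dup, collapse = ", ")
    ), call. = FALSE)
  }
  d[c("employee_id", "date", "icd10_code")]
}

#' Keep only long-term sickness-absence spells
#'
#' Retains episodes whose raw span is at least `min_days` long. The filter
#' applies to the spell as recorded, before any clipping to the observation
#' window: a long spell truncated by the window edge is still long-term
#' illness and stays in (its burden is clipped later).
#'
#' @param episodes Episode tibble (see [merge_episodes()] for the schema).
#' @param min_days Minimum consecutive days, inclusive; default 30.
#' @return The filtered episode tibble.
#' @export
filter_ltsa <- function(episodes, min_days = 30L) {
  if (min_days < 1L) stop("filter_ltsa: min_days must be >= 1", call. = FALSE)
  ep <- normalize_episodes(episodes)
  ep[as.numeric(ep$end_date - ep$start_date) >= min_days, ]
}

#' Merge overlapping or abutting same-group spells
#'
#' Multiple certificates for the same underlying illness often arrive as
#' consecutive or overlapping spells. Spells of one employee that overlap or
#' abut and fall in the same disease group are merged into a single spell;
#' overlapping spells in *different* disease groups are a data-integrity
#' error (named by employee and dates) rather than silently resolved.
#' Disjoint spells are preserved. A merged spell inherits the diagnosis of
#' its earliest constituent and the outcome of its latest-ending one; a
#' terminal outcome on any other constituent is an error (nothing can follow
#' a death or retirement).
#'
#' @param episodes Episode tibble: `employee_id`, `start_date`, `end_date`,
#'   `icd10_code`, `outcome`, `outcome_date`. May hold many employees.
#' @param unmapped Passed to [icd10_group()].
#' @return The merged tibble, sorted by employee and start date, with a
#'   `disease_group` column added.
#' @export
merge_episodes <- function(episodes, unmapped = c("error", "unclassified")) {
  unmapped <- match.arg(unmapped)
  ep <- normalize_episodes(episodes)
  if (nrow(ep) == 0L) {
    ep$disease_group <- character()
    return(ep)
  }
  ep$disease_group <- icd10_group(ep$icd10_code, unmapped)

  ep <- dplyr::arrange(ep, .data$employee_id, .data$disease_group, .data$start_date)
  ep <- dplyr::group_by(ep, .data$employee_id, .data$disease_group)
  ep <- dplyr::mutate(ep,
    .reach = dplyr::lag(cummax(as.numeric(.data$end_date)), default = -Inf),
    .cluster = cumsum(as.numeric(.data$start_date) > .data$.reach)
  )
  merged <- dplyr::summarise(
    dplyr::group_by(ep, .data$employee_id, .data$disease_group, .data$.cluster),
    .last = which.max(.data$end_date),
    .n_terminal = sum(.data$outcome != "return"),
    .terminal_is_last = all(which(.data$outcome != "return") == .last),
    icd10_code = .data$icd10_code[which.min(.data$start_date)],
    outcome = .data$outcome[.last],
    outcome_date = .data$outcome_date[.last],
    start_date = min(.data$start_date),
    end_date = max(.data$end_date),
    .groups = "drop"
  )
  bad <- merged$.n_terminal > 1L |
    (merged$.n_terminal == 1L & !merged$.terminal_is_last)
  if (any(bad)) {
    stop(sprintf(
      "merge_episodes: terminal outcome inside a merged spell for employee(s) %s",
      paste(unique(merged$employee_id[bad]), collapse = ", ")
    ), call. = FALSE)
  }
  merged <- merged[order(merged$employee_id, merged$start_date), ]

  # any overlap still present must involve two different disease groups
  reach <- stats::ave(
    as.numeric(merged$end_date), merged$employee_id,
    FUN = function(e) dplyr::lag(cummax(e), default = -Inf)
  )
  clash <- as.numeric(merged$start_date) < reach
  if (any(clash)) {
    i <- which(clash)[1L]
    stop(sprintf(
      "merge_episodes: overlapping spells with conflicting diagnoses for employee %s around %s",
      merged$employee_id[i], format(merged$start_date[i])
    ), call. = FALSE)
  }
  merged[c(
    "employee_id", "start_date", "end_date", "icd10_code",
    "outcome", "outcome_date", "disease_group"
  )]
}
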