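# Aggregation of person-level losses into per-myriad burden tables.
#
# The denominator is workforce person-time built from annual headcounts
# (one headcount row of n employees contributes n person-years), and burden
# is expressed per myriad: person-years lost per 10,000 person-years of
# working time. Confidence intervals treat the person-years lost as a
# Poisson count (normal approximation on the count scale).

normalize_headcounts <- function(headcounts) {
  required <- c("year", "sex", "age_band", "count")
  missing <- setdiff(required, names(headcounts))
  if (length(missing)) {
    stop(sprintf("headcounts: missing column(s) %s", paste(missing, collapse = ", ")),
      call. = FALSE
    )
  }
  h <- tibble::as_tibble(headcounts)
  h$year <- as.integer(h$year)
  h$sex <- as.character(h$sex)
  h$age_band <- as.character(h$age_band)
  h$count <- as.numeric(h$count)
  if (!all(h$sex %in% c("M", "F"))) {
    stop("headcounts: sex must be 'M' or 'F'", call. = FALSE)
  }
  if (anyNA(h$count) || any(h$count < 0)) {
    stop("headcounts: counts must be non-negative", call. = FALSE)
  }
  band <- regmatches(h$age_band, regexec("^([0-9]+)-([0-9]+)$", h$age_band))
  ok <- lengths(band) == 3L
  if (!all(ok)) {
    stop(sprintf(
      "headcounts: unparseable age band(s) %s",
      paste(sQuote(unique(h$age_band[!ok])), collapse = ", ")
    ), call. = FALSE)
  }
  h$band_lo <- vapply(band, function(b) as.numeric(b[2]), numeric(1))
  h$band_hi <- vapply(band, function(b) as.numeric(b[3]), numeric(1)) + 1
  if (any(h$band_hi <= h$band_lo)) {
    stop("headcounts: inverted age band(s)", call. = FALSE)
  }
  key <- paste(h$year, h$sex, h$age_band)
  if (anyDuplicated(key)) {
    stop("headcounts: duplicated (year, sex, age_band) row(s)", call. = FALSE)
  }
  h
}

#' Person-year denominator from annual headcounts
#'
#' Each annual headcount row of `count` employees contributes `count` x 1
#' person-years: annual counts are the finest information available, so a
#' counted head stands for one year of working time. Stratum denominators
#' therefore sum exactly to the all-stratum denominator.
#'
#' @param headcounts Tibble with `year`, `sex` (`"M"`/`"F"`), `age_band`
#'   (e.g. `"40-44"`, both endpoints inclusive), `count`.
#' @param sex `"all"`, `"M"` or `"F"`.
#' @param age_range Length-2 numeric `[lo, hi)` in years, or `NULL` for all
#'   bands. Bands must nest inside the range; a straddling band is an error.
#' @return Person-years (numeric scalar).
#' @examples
#' h <- tibble::tibble(year = 2012, sex = "M", age_band = "40-44", count = 5000)
#' person_year_denominator(h) # 5000
#' @export
person_year_denominator <- function(headcounts, sex = "all", age_range = NULL) {
  h <- normalize_headcounts(headcounts)
  if (!identical(sex, "all")) h <- h[h$sex == sex, ]
  if (!is.null(age_range)) {
    stopifnot(length(age_range) == 2L, age_range[1] < age_range[2])
    touching <- h$band_hi > age_range[1] & h$band_lo < age_range[2]
    inside <- h$band_lo >= age_range[1] & h$band_hi <= age_range[2]
    if (any(touching & !inside)) {
      stop(sprintf(
        "person_year_denominator: age band(s) %s straddle the stratum boundary [%g, %g)",
        paste(sQuote(unique(h$age_band[touching & !inside])), collapse = ", "),
        age_range[1], age_range[2]
      ), call. = FALSE)
    }
    h <- h[inside, ]
  }
  if (nrow(h) == 0L) {
    stop("person_year_denominator: no headcount rows for the requested stratum",
      call. = FALSE
    )
  }
  sum(h$count)
}

#' Per-myriad proportion
#'
#' Working years lost per 10,000 person-years of working time. A loss of
#' 100 per myriad is equivalent to 100 employees of a 10,000-employee
#' company supplying no labour for a one-year observation period.
#'
#' @param years_lost Person-years lost (>= 0).
#' @param denominator Person-years of working time (> 0).
#' @return `years_lost / denominator * 10000`, vectorised.
#' @examples
#' per_myriad(100, 10000) # 100
#' @export
per_myriad <- function(years_lost, denominator) {
  if (any(denominator <= 0)) {
    stop("per_myriad: denominator must be positive", call. = FALSE)
  }
  if (any(years_lost < 0)) {
    stop("per_myriad: years_lost must be non-negative", call. = FALSE)
  }
  years_lost / denominator * 10000
}

#' Poisson normal-approximation confidence interval, per myriad
#'
#' Treats the person-years lost as a Poisson count `c` and returns
#' `(c - z * sqrt(c), c + z * sqrt(c)) / denominator * 10000`, the lower
#' bound floored at zero. With losses dominated by spells much shorter than
#' a year this interval is conservative (the compound-Poisson variance of
#' total years lost is below the Poisson-count variance assumed here).
#'
#' @param years_lost Person-years lost (vectorised).
#' @param denominator Person-years of working time.
#' @param level Confidence level in (0, 1); default 0.95.
#' @return Tibble with per-myriad columns `lower` and `upper`.
#' @examples
#' rate_ci(85.9e-4 * 506883, 506883) # about (83.3, 88.5)
#' @export
rate_ci <- function(years_lost, denominator, level = 0.95) {
  if (level <= 0 || level >= 1) stop("rate_ci: level must be in (0, 1)", call. = FALSE)
  if (any(denominator <= 0)) stop("rate_ci: denominator must be positive", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(years_lost)
  tibble::tibble(
    lower = pmax(0, years_lost - half) / denominator * 10000,
    upper = (years_lost + half) / denominator * 10000
  )
}

#' Share of one burden estimate in a total
#'
#' @param group,total Per-myriad estimates (or person-years over a common
#'   denominator); `total` must be positive.
#' @return `group / total * 100`, in percent.
#' @examples
#' burden_share(47.0, 85.9) # 54.7%
#' @export
burden_share <- function(group, total) {
  if (any(total <= 0)) stop("burden_share: total must be positive", call. = FALSE)
  group / total * 100
}

#' Chi-squared comparison of lost-time proportions between two strata
#'
#' One-degree-of-freedom chi-squared test (no continuity correction) on the
#' 2x2 table of person-years lost vs person-years not lost in each stratum,
#' with person-years rounded to whole counts (the test assumes counts).
#'
#' @param lost1,denom1 Person-years lost and total person-years, stratum 1.
#' @param lost2,denom2 Same for stratum 2.
#' @return List with `statistic`, `p_value`, and the rounded 2x2 `table`.
#' @export
compare_strata <- function(lost1, denom1, lost2, denom2) {
  if (denom1 <= 0 || denom2 <= 0) {
    stop("compare_strata: denominators must be positive", call. = FALSE)
  }
  tab <- rbind(
    round(c(lost1, denom1 - lost1)),
    round(c(lost2, denom2 - lost2))
  )
  dimnames(tab) <- list(c("stratum1", "stratum2"), c("lost", "not_lost"))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("compare_strata: degenerate 2x2 table (zero margin)", call. = FALSE)
  }
  ht <- stats::chisq.test(tab, correct = FALSE)
  list(
    statistic = unname(ht$statistic),
    p_value = unname(ht$p.value),
    table = tab
  )
}

split_at_age <- function(contrib, birth_date, break_age) {
  # split contribution intervals at the break_age-th birthday so each row
  # sits wholly inside one age stratum
  d <- add_years(birth_date, break_age)
  needs <- contrib$start < d & d < contrib$end
  if (!any(needs)) {
    return(contrib)
  }
  left <- contrib[needs, ]
  right <- contrib[needs, ]
  left$end <- d[needs]
  right$start <- d[needs]
  out <- rbind(contrib[!needs, ], left, right)
  out$days <- as.numeric(out$end - out$start)
  out$years <- out$days / 365.25
  out
}

#' Stratified per-myriad burden table
#'
#' Aggregates the contributions of [compute_burden()] into the canonical
#' burden table: one row per stratum x disease group x consequence, with
#' person-years lost, the person-year denominator, the per-myriad estimate
#' and its confidence interval. Strata are the whole workforce
#' (`sex = "all"`, `age_group = "all"`) plus, by default, sex crossed with
#' the 20-39 / 40-59 age groups. A burden day is assigned to the age group
#' the employee occupies on that day (contributions are split at the
#' 40th-birthday boundary), so stratum rows add up exactly to the overall
#' row. Disease-group rows are completed with zeros and summed into an
#' `"All causes"` row; consequences `sa`, `mortality` and `retirement` are
#' summed into `total`.
#'
#' @param contributions Contribution tibble from [compute_burden()].
#' @param employees Roster tibble (`id`, `sex`, `birth_date`).
#' @param headcounts Headcount tibble (see [person_year_denominator()]), or
#'   a single number taken as the overall person-year denominator (in which
#'   case only the overall stratum is produced).
#' @param window The [obs_window()] the contributions were computed under.
#' @param age_breaks Increasing ages delimiting age groups, spanning
#'   the window's working-age range; default `c(20, 40, 60)` (i.e. 20-39
#'   and 40-59). Use `NULL` for no age stratification.
#' @param by_sex Stratify by sex in addition to the overall row?
#' @param level Confidence level for [rate_ci()].
#' @return A tibble with columns `sex`, `age_group`, `disease_group`,
#'   `consequence`, `years_lost`, `denominator`, `per_myriad`, `ci_low`,
#'   `ci_high`.
#' @export
build_burden_table <- function(contributions, employees, headcounts,
                               window = obs_window(),
                               age_breaks = c(20, 40, 60), by_sex = TRUE,
                               level = 0.95) {
  emp <- normalize_employees(employees)
  contrib <- if (is.null(contributions) || nrow(contributions) == 0L) {
    contribution_template()
  } else {
    tibble::as_tibble(contributions)
  }
  unknown <- setdiff(unique(contrib$employee_id), emp$id)
  if (length(unknown)) {
    stop(sprintf(
      "build_burden_table: contributions for employee(s) absent from the roster: %s",
      paste(unknown, collapse = ", ")
    ), call. = FALSE)
  }

  flat_denominator <- is.numeric(headcounts) && length(headcounts) == 1L
  if (flat_denominator) {
    age_breaks <- NULL
    by_sex <- FALSE
  }
  if (is.null(age_breaks)) {
    age_breaks <- c(window$min_age, window$max_age)
  }
  age_breaks <- sort(unique(as.numeric(age_breaks)))
  if (age_breaks[1] != window$min_age ||
    age_breaks[length(age_breaks)] != window$max_age) {
    stop("build_burden_table: age_breaks must span the window's working-age range",
      call. = FALSE
    )
  }
  n_bands <- length(age_breaks) - 1L
  band_labels <- sprintf("%g-%g", age_breaks[-length(age_breaks)], age_breaks[-1] - 1)

  # --- assign each contribution day to its sex x age-group stratum -------
  for (b in age_breaks[c(-1, -length(age_breaks))]) {
    contrib <- split_at_age(contrib, emp$birth_date[match(contrib$employee_id, emp$id)], b)
  }
  birth <- emp$birth_date[match(contrib$employee_id, emp$id)]
  band_idx <- rep(1L, nrow(contrib))
  for (b in age_breaks[c(-1, -length(age_breaks))]) {
    band_idx <- band_idx + (contrib$start >= add_years(birth, b))
  }
  contrib$age_group <- band_labels[band_idx]
  contrib$sex <- emp$sex[match(contrib$employee_id, emp$id)]

  # --- strata grid -------------------------------------------------------
  strata <- tibble::tibble(sex = "all", age_group = "all")
  stratified <- by_sex || n_bands > 1L
  if (stratified) {
    strata <- rbind(strata, tidyr::expand_grid(
      sex = if (by_sex) c("M", "F") else "all",
      age_group = band_labels
    ))
  }
  groups <- disease_group_labels()
  if (any(contrib$disease_group == "Unclassified")) {
    groups <- c(groups, "Unclassified")
  }

  cell_rows <- function(sx, ag) {
    rows <- contrib
    if (sx != "all") rows <- rows[rows$sex == sx, ]
    if (ag != "all") rows <- rows[rows$age_group == ag, ]
    agg <- dplyr::summarise(
      dplyr::group_by(rows, .data$disease_group, .data$consequence),
      years_lost = sum(.data$years), .groups = "drop"
    )
    grid <- tidyr::expand_grid(
      disease_group = groups,
      consequence = c("sa", "mortality", "retirement")
    )
    grid <- dplyr::left_join(grid, agg, by = c("disease_group", "consequence"))
    grid$years_lost[is.na(grid$years_lost)] <- 0
    # consequence totals, then the all-cause row over groups
    tot <- dplyr::summarise(dplyr::group_by(grid, .data$disease_group),
      consequence = "total", years_lost = sum(.data$years_lost), .groups = "drop"
    )
    grid <- rbind(grid, tot[names(grid)])
    allc <- dplyr::summarise(dplyr::group_by(grid, .data$consequence),
      disease_group = "All causes", years_lost = sum(.data$years_lost),
      .groups = "drop"
    )
    grid <- rbind(grid, allc[names(grid)])
    grid$sex <- sx
    grid$age_group <- ag
    grid
  }

  cells <- do.call(rbind, Map(cell_rows, strata$sex, strata$age_group))

  denom_for <- function(sx, ag) {
    if (flat_denominator) {
      return(as.numeric(headcounts))
    }
    rng <- if (ag == "all") {
      c(window$min_age, window$max_age)
    } else {
      lo <- as.numeric(sub("-.*", "", ag))
      hi <- as.numeric(sub(".*-", "", ag)) + 1
      c(lo, hi)
    }
    tryCatch(
      person_year_denominator(headcounts, sex = sx, age_range = rng),
      error = function(e) {
        if (grepl("no headcount rows", conditionMessage(e))) NA_real_ else stop(e)
      }
    )
  }
  strata$denominator <- unname(vapply(
    Map(denom_for, strata$sex, strata$age_group), identity, numeric(1)
  ))

  out <- dplyr::left_join(cells, strata, by = c("sex", "age_group"))
  # a stratum without headcounts is tolerable only while it has no burden;
  # burden without a denominator is a data error, an idle stratum is dropped
  uncovered <- is.na(out$denominator)
  if (any(uncovered & out$years_lost > 0)) {
    bad <- unique(paste(out$sex[uncovered & out$years_lost > 0],
      out$age_group[uncovered & out$years_lost > 0],
      sep = "/"
    ))
    stop(sprintf(
      "build_burden_table: missing headcounts for populated stratum(s) %s",
      paste(bad, collapse = ", ")
    ), call. = FALSE)
  }
  out <- out[!uncovered, ]
  out$per_myriad <- per_myriad(out$years_lost, out$denominator)
  ci <- rate_ci(out$years_lost, out$denominator, level = level)
  out$ci_low <- ci$lower
  out$ci_high <- ci$upper
  tibble::as_tibble(out[c(
    "sex", "age_group", "disease_group", "consequence",
    "years_lost", "denominator", "per_myriad", "ci_low", "ci_high"
  )])
}
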