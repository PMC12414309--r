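#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

#' Psychopathology facet abbreviations
#'
#' The eight facets used as measurement-model indicators: anxious/depressed
#' (ad), withdrawn/depressed (wd), somatic complaints (som), oppositional
#' defiance (odd), conduct problems (cd), hyperactivity (hyp), inattention
#' (at), and emotion dysregulation (eri).
#'
#' @export
facet_names <- c("ad", "wd", "som", "odd", "cd", "hyp", "at", "eri")

#' @rdname facet_names
#' @export
rater_names <- c("cg", "yr")

metric_names <- c("duration_min", "bedtime_min", "waketime_min")

facet_cols <- function() {
  as.vector(outer(facet_names, rater_names, paste, sep = "_"))
}

person_col_types <- function() {
  readr::cols(
    person_id = readr::col_character(),
    .default = readr::col_double()
  )
}

#' Build a cohort object from person-level and nightly tables
#'
#' A cohort couples a person-level table (demographics + two-rater facet
#' scores) with a long-format table of nightly sleep records. Persons with no
#' nightly rows are legal (their sleep is simply missing); nightly rows for a
#' person absent from the person table are not.
#'
#' @param persons tibble with columns `person_id`, `age`, `sex`,
#'   `maternal_education`, `income_to_needs` and the 16 facet columns
#'   `<facet>_<rater>` (facet in [facet_names], rater `cg`/`yr`).
#' @param nights tibble with columns `person_id`, `night_index`, `weekend`,
#'   `duration_min`, `bedtime_min`, `waketime_min`. Missing metrics are `NA`;
#'   a night on which nothing was measured is simply absent.
#' @return an object of class `nightvar_cohort`: a list with elements
#'   `persons` and `nights`.
#' @export
cohort <- function(persons, nights) {
  persons <- as_tibble(persons)
  nights <- as_tibble(nights)
  need_p <- c("person_id", "age", "sex", "maternal_education", "income_to_needs")
  miss <- setdiff(need_p, names(persons))
  if (length(miss)) stop("persons table lacks columns: ", paste(miss, collapse = ", "))
  need_n <- c("person_id", "night_index", "weekend", metric_names)
  miss <- setdiff(need_n, names(nights))
  if (length(miss)) stop("nights table lacks columns: ", paste(miss, collapse = ", "))

  unknown <- setdiff(unique(nights$person_id), persons$person_id)
  if (length(unknown)) {
    stop("nights table contains person_id absent from person table: ",
         paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(persons$person_id)) stop("duplicated person_id in person table")
  if (any(!is.na(nights$weekend) & !nights$weekend %in% c(0, 1))) {
    stop("weekend must be 0 (weekday) or 1 (weekend)")
  }
  if (any(!is.na(nights$night_index) & nights$night_index < 0)) {
    stop("night_index must be >= 0")
  }
  bad_dur <- !is.na(nights$duration_min) &
    (nights$duration_min < 0 | nights$duration_min > 1440)
  if (any(bad_dur)) stop("duration_min outside [0, 1440]")
  dup <- nights |>
    dplyr::count(.data$person_id, .data$night_index) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    stop("duplicate night_index for person ", dup$person_id[1])
  }
  nights <- dplyr::arrange(nights, .data$person_id, .data$night_index)
  structure(list(persons = persons, nights = nights), class = "nightvar_cohort")
}

#' @export
print.nightvar_cohort <- function(x, ...) {
  obs <- observed_nights(x)
  cat("<nightvar_cohort> ", nrow(x$persons), " persons, ",
      nrow(x$nights), " person-nights (",
      sum(obs$n_observed == 0), " persons with no nightly data)\n", sep = "")
  invisible(x)
}

#' Read a cohort from delimited files
#'
#' @param person_path path to a persons CSV (see [cohort] for the layout).
#' @param nights_path path to a nights CSV.
#' @return a `nightvar_cohort`.
#' @export
read_cohort <- function(person_path, nights_path) {
  # parse problems are escalated to errors below, so readr's own warning is
  # redundant noise
  persons <- suppressWarnings(
    readr::read_csv(person_path, col_types = person_col_types(),
                    progress = FALSE))
  stop_on_parse_problems(persons, person_path)
  nights <- suppressWarnings(
    readr::read_csv(nights_path, col_types = person_col_types(),
                    progress = FALSE))
  stop_on_parse_problems(nights, nights_path)
  cohort(persons, nights)
}

stop_on_parse_problems <- function(df, path) {
  pr <- readr::problems(df)
  if (nrow(pr)) {
    stop("malformed field in ", path, " at row ", pr$row[1],
         " (", pr$expected[1], ", got ", pr$actual[1], ")")
  }
  invisible(df)
}

#' Write a cohort to delimited files
#'
#' Inverse of [read_cohort] up to floating-point formatting.
#'
#' @param x a `nightvar_cohort`.
#' @inheritParams read_cohort
#' @export
write_cohort <- function(x, person_path, nights_path) {
  stopifnot(inherits(x, "nightvar_cohort"))
  readr::write_csv(x$persons, person_path, progress = FALSE)
  readr::write_csv(x$nights, nights_path, progress = FALSE)
  invisible(x)
}

#' Convert a clock reading to minutes relative to midnight
#'
#' Bedtimes and waketimes are coded as signed minutes around 12 am of the
#' sleep episode: a 23:30 bedtime is -30, midnight is 0, a 07:43 waketime is
#' 463. The caller flags whether the reading falls before or after midnight.
#'
#' @param time clock reading(s) as `"HH:MM"` strings.
#' @param after_midnight logical, `TRUE` when the reading falls on or after
#'   midnight of the episode. Recycled against `time`.
#' @return signed minutes relative to midnight (numeric vector).
#' @export
center_clock_time <- function(time, after_midnight) {
  parts <- strsplit(as.character(time), ":", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) stop("clock time must be 'HH:MM': ", time[which(bad)[1]])
  h <- as.numeric(vapply(parts, `[`, "", 1L))
  m <- as.numeric(vapply(parts, `[`, "", 2L))
  if (any(is.na(h) | is.na(m) | h < 0 | h >= 24 | m < 0 | m >= 60)) {
    stop("clock time out of range")
  }
  tod <- h * 60 + m
  after_midnight <- rep_len(as.logical(after_midnight), length(tod))
  out <- ifelse(after_midnight, tod, tod - 1440)
  # midnight itself is 0 whichever side it was tagged on
  out[tod == 0] <- 0
  out
}

#' Count observed nights per person
#'
#' A night counts as observed when at least one of the three metrics is
#' non-missing. Persons with no nightly rows get a zero count.
#'
#' @param x a `nightvar_cohort`.
#' @return tibble `person_id`, `n_observed`.
#' @export
observed_nights <- function(x) {
  stopifnot(inherits(x, "nightvar_cohort"))
  any_obs <- rowSums(!is.na(x$nights[metric_names])) > 0
  counts <- x$nights |>
    dplyr::mutate(obs = any_obs) |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(n_observed = sum(.data$obs), .groups = "drop")
  tibble(person_id = x$persons$person_id) |>
    dplyr::left_join(counts, by = "person_id") |>
    dplyr::mutate(n_observed = dplyr::coalesce(.data$n_observed, 0L))
}

#' Apply the minimum-nights validity rule
#'
#' Persons with fewer than `min_nights` observed nights have every sleep
#' metric set to missing; nobody is dropped. The person table gains a logical
#' `valid_sleep` column. The operation is idempotent.
#'
#' @param x a `nightvar_cohort`.
#' @param min_nights minimum observed nights required to keep a person's
#'   sleep data (default 3).
#' @return the filtered `nightvar_cohort`.
#' @export
apply_validity_filter <- function(x, min_nights = 3L) {
  stopifnot(inherits(x, "nightvar_cohort"), min_nights >= 1L)
  obs <- observed_nights(x)
  valid <- obs$n_observed >= min_nights
  names(valid) <- obs$person_id
  mask <- x$nights$person_id %in% obs$person_id[!valid]
  nights <- x$nights
  nights[mask, metric_names] <- NA_real_
  persons <- x$persons
  persons$valid_sleep <- unname(valid[persons$person_id])
  out <- cohort(persons, nights)
  out
}

#' Per-person and cohort descriptives of the nightly metrics
#'
#' Means and sample SDs (n - 1 denominator) across each person's available
#' nights, metric by metric (pairwise deletion), followed by cohort-level
#' summaries of those person scores. Persons with fewer than two observed
#' nights for a metric get a missing SD; all-missing persons keep their row.
#'
#' @param x a `nightvar_cohort`.
#' @return list with `person` (one row per person: mean/sd per metric and
#'   `n_observed`) and `cohort` (one row per metric summary).
#' @export
person_descriptives <- function(x) {
  stopifnot(inherits(x, "nightvar_cohort"))
  per <- x$nights |>
    tidyr::pivot_longer(dplyr::all_of(metric_names),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$person_id, .data$metric) |>
    dplyr::summarise(
      mean = if (any(!is.na(.data$value))) mean(.data$value, na.rm = TRUE) else NA_real_,
      sd = if (sum(!is.na(.data$value)) >= 2) stats::sd(.data$value, na.rm = TRUE) else NA_real_,
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(names_from = "metric", values_from = c("mean", "sd"),
                       names_glue = "{metric}_{.value}")
  person <- tibble(person_id = x$persons$person_id) |>
    dplyr::left_join(per, by = "person_id") |>
    dplyr::left_join(observed_nights(x), by = "person_id")
  stat_cols <- setdiff(names(person), c("person_id", "n_observed"))
  cohort <- tibble(
    statistic = stat_cols,
    mean = vapply(person[stat_cols], function(v) mean(v, na.rm = TRUE), 0),
    sd = vapply(person[stat_cols], function(v) stats::sd(v, na.rm = TRUE), 0),
    n = vapply(person[stat_cols], function(v) sum(!is.na(v)), 0L)
  )
  list(person = person, cohort = cohort)
}
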