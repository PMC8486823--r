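#' Split harmonized minute series into calendar days
#'
#' Pivots the per-stream minute series to one row per user-minute (columns
#' `hr`, `steps`, `sleep`) and assigns each minute to the calendar day of
#' its local midnight (timezone `tz`, default UTC). Every non-missing
#' minute belongs to exactly one day; days are capped at 1440 slots by
#' construction.
#'
#' @param minutes Minute-grid tibble from [preprocess_events()].
#' @param tz Nominal timezone governing day boundaries.
#' @return A tibble with columns `user_id`, `date`, `minute_of_day`
#'   (0–1439), `hr`, `steps`, `sleep`.
#' @export
split_days <- function(minutes, tz = "UTC") {
  if (nrow(minutes) == 0) {
    return(tibble::tibble(user_id = character(), date = as.Date(character()),
                          minute_of_day = integer(), hr = double(),
                          steps = double(), sleep = double()))
  }
  wide <- tidyr::pivot_wider(minutes, id_cols = c("user_id", "minute"),
                             names_from = "stream", values_from = "value")
  for (nm in c("heart_rate", "steps", "sleep")) {
    if (is.null(wide[[nm]])) wide[[nm]] <- NA_real_
  }
  local_min <- as.numeric(wide$minute) / 60 # minutes since epoch, UTC
  if (tz != "UTC") {
    lt <- as.POSIXlt(wide$minute, tz = tz)
    off <- lt$gmtoff
    off[is.na(off)] <- 0
    local_min <- local_min + off / 60
  }
  day <- floor(local_min / 1440)
  tibble::tibble(
    user_id = wide$user_id,
    date = as.Date(day, origin = "1970-01-01"),
    minute_of_day = as.integer(local_min - day * 1440),
    hr = wide$heart_rate,
    steps = wide$steps,
    sleep = wide$sleep
  ) |>
    dplyr::arrange(.data$user_id, .data$date, .data$minute_of_day)
}

#' Stratify one day's heart-rate minutes by sleep and movement
#'
#' Sleeping heart rate: minutes with binary sleep indicator 1. Resting
#' heart rate: minutes with a step count of 0 (the literal definition —
#' sleep minutes with zero steps are included; set `awake_only = TRUE` for
#' the awake-only variant). Active heart rate: minutes with positive step
#' count. Minutes with missing heart rate are excluded everywhere; minutes
#' with missing steps are excluded from resting and active.
#'
#' @param day One day's slots: a data frame with columns `hr`, `steps`,
#'   `sleep`.
#' @param awake_only If `TRUE`, resting excludes sleep-indicator-1 minutes.
#' @return A list with numeric vectors `sleeping`, `resting`, `active`.
#' @export
#' @examples
#' d <- data.frame(hr = c(50, 60, 90), steps = c(0, 0, 120),
#'                 sleep = c(1, 0, 0))
#' stratify_hr(d)
stratify_hr <- function(day, awake_only = FALSE) {
  hr_ok <- !is.na(day$hr)
  st_ok <- !is.na(day$steps)
  resting_sel <- hr_ok & st_ok & day$steps == 0
  if (awake_only) resting_sel <- resting_sel & !(!is.na(day$sleep) & day$sleep == 1)
  list(
    sleeping = day$hr[hr_ok & !is.na(day$sleep) & day$sleep == 1],
    resting = day$hr[resting_sel],
    active = day$hr[hr_ok & st_ok & day$steps > 0]
  )
}

#' Percentage of outliers beyond k standard deviations
#'
#' `100 * |{v : |v - mean| > k * sd}| / n` over the non-missing values,
#' with the sample (n-1) standard deviation. A zero or undefined standard
#' deviation yields 0%; an empty input yields missing.
#'
#' @param values Numeric vector.
#' @param k Threshold in standard deviations (default 2).
#' @return Percentage in `[0, 100]`, or `NA` for empty input.
#' @export
#' @examples
#' outlier_fraction(c(rep(1, 10), 100))  # 1/11 -> 9.09
outlier_fraction <- function(values, k = 2) {
  v <- values[!is.na(values)]
  if (length(v) == 0) return(NA_real_)
  s <- sd(v)
  if (is.na(s) || s == 0) return(0)
  100 * sum(abs(v - mean(v)) > k * s) / length(v)
}

mean_or_na <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) == 0) NA_real_ else mean(v)
}

# linear-interpolation (type 7) quantile, NA for empty input
quantile_or_na <- function(v, p) {
  v <- v[!is.na(v)]
  if (length(v) == 0) NA_real_ else
    quantile(v, p, names = FALSE, type = 7)
}

# The 12 domain-knowledge features for one day's slots (hr/steps/sleep).
day_feature_row <- function(hr, steps, sleep, k, awake_only = FALSE) {
  strata <- stratify_hr(list(hr = hr, steps = steps, sleep = sleep),
                        awake_only = awake_only)
  sleeping_hr <- mean_or_na(strata$sleeping)
  active_hr <- mean_or_na(strata$active)
  tibble::tibble(
    avg_hr = mean_or_na(hr),
    sleeping_hr = sleeping_hr,
    resting_hr = mean_or_na(strata$resting),
    active_hr = active_hr,
    active_minus_sleeping_hr = active_hr - sleeping_hr,
    total_steps = if (all(is.na(steps))) NA_real_ else
      sum(steps, na.rm = TRUE),
    sleep_hours = if (all(is.na(sleep))) NA_real_ else
      sum(sleep == 1, na.rm = TRUE) / 60,
    outlier_pct_hr = outlier_fraction(hr, k),
    outlier_pct_sleeping_hr = outlier_fraction(strata$sleeping, k),
    outlier_pct_resting_hr = outlier_fraction(strata$resting, k),
    outlier_pct_active_hr = outlier_fraction(strata$active, k),
    outlier_pct_steps = outlier_fraction(steps, k)
  )
}

#' Compute the 12 daily domain-knowledge features
#'
#' For every user-day of the harmonized minute series: mean heart rate,
#' total steps, sleep hours, mean sleeping / resting / active heart rate
#' (see [stratify_hr()]), the active-minus-sleeping difference, and five
#' outlier percentages ([outlier_fraction()] at `outlier_k` standard
#' deviations of that day's own distribution) for overall heart rate, the
#' three strata, and steps. Strata with no measurements yield missing
#' features; days with no data in any stream are skipped.
#'
#' @param minutes Minute-grid tibble from [preprocess_events()], or a
#'   day-slot tibble from [split_days()].
#' @param params A [pipeline_params()].
#' @param tz Timezone for day boundaries.
#' @param awake_only Resting-stratum variant, see [stratify_hr()].
#' @return A tibble with `user_id`, `date` and the 12 feature columns.
#' @export
daily_features <- function(minutes, params = pipeline_params(), tz = "UTC",
                           awake_only = FALSE) {
  days <- if (all(c("minute_of_day", "hr") %in% names(minutes))) minutes
          else split_days(minutes, tz)
  if (nrow(days) == 0) {
    out <- tibble::tibble(user_id = character(), date = as.Date(character()))
    for (f in DAILY_FEATURES) out[[f]] <- double()
    return(out)
  }
  out <- days |>
    dplyr::group_by(.data$user_id, .data$date) |>
    dplyr::filter(!all(is.na(.data$hr) & is.na(.data$steps) &
                         is.na(.data$sleep))) |>
    dplyr::reframe(day_feature_row(.data$hr, .data$steps, .data$sleep,
                                   .env$params$outlier_k,
                                   awake_only = .env$awake_only))
  tibble::as_tibble(out)
}

#' Apply the cohort inclusion filters
#'
#' Drops users without the target label, drops users with fewer than
#' `min_days` usable days after preprocessing, and truncates the remaining
#' users to their first `horizon_days` calendar days. A per-user inclusion
#' report is attached as attribute `"report"`.
#'
#' @param daily Daily-features tibble from [daily_features()].
#' @param labels Labels tibble (`user_id`, `phenotype`, `sex`).
#' @param params A [pipeline_params()].
#' @param target Which label column defines "labeled".
#' @return Filtered daily-features tibble with attribute `"report"`.
#' @export
filter_cohort <- function(daily, labels, params = pipeline_params(),
                          target = c("phenotype", "sex")) {
  target <- match.arg(target)
  if (nrow(daily) == 0) {
    stop("no users remain after cohort filtering", call. = FALSE)
  }
  lab <- labels[, c("user_id", target)]
  names(lab)[2] <- ".label"
  per_user <- daily |>
    dplyr::group_by(.data$user_id) |>
    dplyr::summarise(n_days = dplyr::n(), first_date = min(.data$date),
                     .groups = "drop") |>
    dplyr::left_join(lab, by = "user_id") |>
    dplyr::mutate(
      labeled = !is.na(.data$.label),
      enough_days = .data$n_days >= .env$params$min_days,
      included = .data$labeled & .data$enough_days,
      reason = dplyr::case_when(
        !labeled ~ "unlabeled",
        !enough_days ~ "too_few_days",
        TRUE ~ "included"
      )
    )
  keep <- per_user[per_user$included, c("user_id", "first_date")]
  out <- daily |>
    dplyr::inner_join(keep, by = "user_id") |>
    dplyr::filter(.data$date < .data$first_date + .env$params$horizon_days) |>
    dplyr::select(-"first_date")
  if (nrow(out) == 0) {
    stop("no users remain after cohort filtering", call. = FALSE)
  }
  attr(out, "report") <-
    per_user[, c("user_id", "n_days", "labeled", "included", "reason")]
  out
}

#' Aggregate daily features into 84 user-level summary features
#'
#' Seven summary statistics (mean, sample sd, min, max and the 25%, 50%,
#' 75% quartiles by linear interpolation) of each of the 12 daily features
#' over a user's available (non-missing) days, named `stat__feature`.
#'
#' @param daily Daily-features tibble, typically after [filter_cohort()].
#' @param labels Labels tibble, joined onto the output.
#' @param params A [pipeline_params()].
#' @return A tibble with one row per user: `user_id`, 84 feature columns,
#'   `n_days_used`, and the label columns.
#' @export
user_features <- function(daily, labels = NULL,
                          params = pipeline_params()) {
  counts <- table(daily$user_id)
  if (any(counts < 2)) {
    stop("users with fewer than 2 days: ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  }
  long <- tidyr::pivot_longer(daily, cols = dplyr::all_of(DAILY_FEATURES),
                              names_to = "feature", values_to = "value")
  stats <- long |>
    dplyr::group_by(.data$user_id, .data$feature) |>
    dplyr::summarise(
      mean = mean_or_na(.data$value),
      sd = if (sum(!is.na(.data$value)) >= 2)
        sd(.data$value, na.rm = TRUE) else NA_real_,
      min = if (any(!is.na(.data$value)))
        min(.data$value, na.rm = TRUE) else NA_real_,
      max = if (any(!is.na(.data$value)))
        max(.data$value, na.rm = TRUE) else NA_real_,
      q25 = quantile_or_na(.data$value, 0.25),
      q50 = quantile_or_na(.data$value, 0.50),
      q75 = quantile_or_na(.data$value, 0.75),
      .groups = "drop"
    )
  wide <- stats |>
    tidyr::pivot_longer(dplyr::all_of(SUMMARY_STATS), names_to = "stat",
                        values_to = "value") |>
    dplyr::mutate(
      feature = factor(.data$feature, levels = DAILY_FEATURES),
      stat = factor(.data$stat, levels = SUMMARY_STATS)
    ) |>
    dplyr::arrange(.data$feature, .data$stat) |>
    dplyr::mutate(column = paste0(.data$stat, "__", .data$feature)) |>
    tidyr::pivot_wider(id_cols = "user_id", names_from = "column",
                       values_from = "value")
  n_days <- daily |>
    dplyr::count(.data$user_id, name = "n_days_used")
  out <- dplyr::left_join(wide, n_days, by = "user_id")
  if (!is.null(labels)) {
    out <- dplyr::left_join(out, labels, by = "user_id")
  }
  tibble::as_tibble(out)
}

#' Names of the 84 user-level feature columns
#' @return Character vector of length 84 (`stat__feature`).
#' @export
user_feature_names <- function() {
  as.vector(t(outer(DAILY_FEATURES, SUMMARY_STATS,
                    function(f, s) paste0(s, "__", f))))
}
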