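#' Binarize sleep-stage tokens
#'
#' Collapses the 8 device sleep categories to a binary asleep indicator
#' (see [sleep_mapping()]): asleep-like stages map to 1, awake stages to 0,
#' `unknown` to missing. Unrecognized tokens map to missing with a warning
#' and are counted in the `"rejected"` attribute.
#'
#' @param category Character vector of sleep tokens.
#' @param mapping Named integer vector, as from [sleep_mapping()].
#' @return Integer vector of 1 / 0 / `NA` with attribute `"rejected"`
#'   (count of unrecognized tokens).
#' @export
#' @examples
#' binarize_sleep(c("deep", "awake", "unknown"))
binarize_sleep <- function(category, mapping = sleep_mapping()) {
  out <- unname(mapping[match(tolower(category), names(mapping))])
  unrec <- !is.na(category) & !(tolower(category) %in% names(mapping))
  if (any(unrec)) {
    warning(sum(unrec), " unrecognized sleep token(s) set to missing",
            call. = FALSE)
  }
  attr(out, "rejected") <- sum(unrec)
  out
}

# Trailing rolling mean over the last `window` positions; missing values
# excluded from the statistic; all-missing window -> NA. Partial windows at
# the series start use the available prefix.
roll_mean_trailing <- function(x, window) {
  n <- length(x)
  obs <- !is.na(x)
  cv <- cumsum(ifelse(obs, x, 0))
  co <- cumsum(obs)
  i <- seq_len(n)
  j <- i - window
  cv0 <- c(0, cv)[pmax(j, 0) + 1L]
  co0 <- c(0, co)[pmax(j, 0) + 1L]
  cnt <- co - co0
  out <- (cv - cv0) / cnt
  out[cnt == 0] <- NA_real_
  out
}

# Trailing rolling max for a binary 0/1 indicator series.
roll_max_binary <- function(x, window) {
  if (!all(is.na(x) | x %in% c(0, 1))) {
    stop("rolling max is defined for binary 0/1 series", call. = FALSE)
  }
  n <- length(x)
  obs <- !is.na(x)
  c1 <- cumsum(ifelse(obs & x == 1, 1, 0))
  co <- cumsum(obs)
  i <- seq_len(n)
  j <- pmax(i - window, 0)
  ones <- c1 - c(0, c1)[j + 1L]
  cnt <- co - c(0, co)[j + 1L]
  out <- ifelse(ones > 0, 1, 0)
  out[cnt == 0] <- NA_real_
  out
}

#' Trailing rolling smoothing of a single series
#'
#' `mode = "mean"` is the rolling average used for heart rate and steps;
#' `mode = "max"` is the rolling max used for the binarized sleep
#' indicator. Windows are trailing (causal): position i summarizes
#' positions `i - window + 1 ... i`, with a partial window at the start.
#' Missing values are excluded from the window statistic; the output is
#' missing only where the whole window is missing, so smoothing never
#' imputes into all-missing stretches. `window = 1` is the identity.
#'
#' @param x Numeric vector (binary 0/1 for `mode = "max"`).
#' @param window Window length in positions (>= 1).
#' @param mode `"mean"` or `"max"`.
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' smooth_series(c(0, 0, 0, 0, 5), 5, "mean")  # last value 1
#' smooth_series(c(0, 1, 0, 0, 0, 0), 5, "max")
smooth_series <- function(x, window, mode = c("mean", "max")) {
  mode <- match.arg(mode)
  if (!is.numeric(window) || window < 1) {
    stop("window must be >= 1", call. = FALSE)
  }
  window <- as.integer(window)
  if (mode == "mean") roll_mean_trailing(x, window) else
    roll_max_binary(x, window)
}

#' Aggregate raw events onto a regular 1-minute grid
#'
#' Per user and stream: heart rate is the mean of within-minute samples,
#' steps the sum of within-minute counts, and sleep the binarized
#' any-asleep rule (1 if any within-minute sample is asleep, else 0 if any
#' is awake, else missing). The grid runs contiguously from the first to
#' the last observed minute of each user-stream; minutes with no samples
#' are explicitly missing — never imputed.
#'
#' @param events Events tibble (see [read_events()]).
#' @param mapping Sleep binarization mapping (see [sleep_mapping()]).
#' @return A tibble with columns `user_id`, `stream`, `minute` (POSIXct,
#'   UTC, truncated to the minute) and `value` (double, `NA` = missing).
#' @export
to_minute_grid <- function(events, mapping = sleep_mapping()) {
  stopifnot(all(c("user_id", "stream", "timestamp") %in% names(events)))
  parts <- list()
  minute_of <- function(ts) floor(as.numeric(ts) / 60)

  agg_stream <- function(ev, fun) {
    m <- minute_of(ev$timestamp)
    g <- paste(ev$user_id, m, sep = "\r")
    o <- order(ev$user_id, m)
    fun(ev[o, ], m[o], g[o])
  }
  ev_hr <- events[events$stream == "heart_rate", ]
  if (nrow(ev_hr)) {
    parts$heart_rate <- agg_stream(ev_hr, function(ev, m, g) {
      s <- rowsum(ev$value, g, reorder = FALSE)
      n <- rowsum(rep(1, nrow(ev)), g, reorder = FALSE)
      first <- !duplicated(g)
      tibble::tibble(user_id = ev$user_id[first], stream = "heart_rate",
                     minute_num = m[first], value = unname(drop(s / n)))
    })
  }
  ev_st <- events[events$stream == "steps", ]
  if (nrow(ev_st)) {
    parts$steps <- agg_stream(ev_st, function(ev, m, g) {
      s <- rowsum(ev$value, g, reorder = FALSE)
      first <- !duplicated(g)
      tibble::tibble(user_id = ev$user_id[first], stream = "steps",
                     minute_num = m[first], value = unname(drop(s)))
    })
  }
  ev_sl <- events[events$stream == "sleep", ]
  if (nrow(ev_sl)) {
    bin <- suppressWarnings(binarize_sleep(ev_sl$category, mapping))
    parts$sleep <- agg_stream(ev_sl, function(ev, m, g) {
      b <- bin[order(ev_sl$user_id, minute_of(ev_sl$timestamp))]
      s1 <- rowsum(as.numeric(!is.na(b) & b == 1L), g, reorder = FALSE)
      s0 <- rowsum(as.numeric(!is.na(b) & b == 0L), g, reorder = FALSE)
      first <- !duplicated(g)
      v <- unname(ifelse(drop(s1) > 0, 1, ifelse(drop(s0) > 0, 0, NA_real_)))
      tibble::tibble(user_id = ev$user_id[first], stream = "sleep",
                     minute_num = m[first], value = v)
    })
  }
  agg <- dplyr::bind_rows(parts)
  if (nrow(agg) == 0) {
    return(tibble::tibble(user_id = character(), stream = character(),
                          minute = as.POSIXct(character(), tz = "UTC"),
                          value = double()))
  }
  # expand each user-stream to its full contiguous minute range
  grid <- agg |>
    dplyr::group_by(.data$user_id, .data$stream) |>
    dplyr::reframe({
      full <- seq(min(minute_num), max(minute_num))
      vals <- value[match(full, minute_num)]
      tibble::tibble(minute_num = full, value = vals)
    })
  grid$minute <- as.POSIXct(grid$minute_num * 60,
                            origin = "1970-01-01", tz = "UTC")
  grid <- dplyr::arrange(grid, .data$user_id, .data$stream, .data$minute)
  tibble::as_tibble(grid[, c("user_id", "stream", "minute", "value")])
}

#' Remove implausibly low heart-rate minutes
#'
#' Minute heart-rate values strictly below `hr_floor` (default 20 bpm)
#' become missing; values at or above the floor are unchanged. Other
#' streams pass through. The number of removed values is attached as
#' attribute `"hr_removed"`.
#'
#' @param minutes Minute-grid tibble from [to_minute_grid()].
#' @param hr_floor Cleaning floor in bpm.
#' @return The cleaned minute tibble.
#' @export
clean_heart_rate <- function(minutes, hr_floor = 20) {
  bad <- minutes$stream == "heart_rate" & !is.na(minutes$value) &
    minutes$value < hr_floor
  minutes$value[bad] <- NA_real_
  n_hr <- sum(minutes$stream == "heart_rate" & !is.na(minutes$value))
  if (n_hr == 0 && any(minutes$stream == "heart_rate")) {
    warning("all heart-rate minutes fell below the cleaning floor",
            call. = FALSE)
  }
  attr(minutes, "hr_removed") <- sum(bad)
  minutes
}

#' Smooth all minute series of a cohort
#'
#' Applies [smooth_series()] per user-stream: rolling mean for heart rate
#' and steps, rolling max for the binarized sleep indicator.
#'
#' @param minutes Minute-grid tibble.
#' @param window Trailing window length in minutes.
#' @return Smoothed minute tibble.
#' @export
smooth_minutes <- function(minutes, window = 5L) {
  if (window < 1) stop("window must be >= 1", call. = FALSE)
  minutes <- dplyr::arrange(minutes, .data$user_id, .data$stream,
                            .data$minute)
  grp <- paste(minutes$user_id, minutes$stream, sep = "\r")
  idx <- split(seq_len(nrow(minutes)), factor(grp, levels = unique(grp)))
  val <- minutes$value
  for (ii in idx) {
    mode <- if (minutes$stream[ii[1]] == "sleep") "max" else "mean"
    val[ii] <- smooth_series(minutes$value[ii], window, mode)
  }
  minutes$value <- val
  minutes
}

#' Harmonize raw events into cleaned, smoothed minute series
#'
#' Per-user composition of sleep binarization, 1-minute aggregation,
#' heart-rate cleaning and trailing rolling smoothing, with explicit
#' missingness throughout (no imputation anywhere). A per-user-stream
#' preprocessing report (minutes present / missing, absent streams) is
#' attached as attribute `"report"`.
#'
#' @param events Events tibble.
#' @param params A [pipeline_params()].
#' @param mapping Sleep binarization mapping.
#' @return Smoothed minute-grid tibble with attributes `"report"` and
#'   `"hr_removed"`.
#' @export
preprocess_events <- function(events, params = pipeline_params(),
                              mapping = sleep_mapping()) {
  grid <- to_minute_grid(events, mapping)
  grid <- clean_heart_rate(grid, params$hr_floor)
  hr_removed <- attr(grid, "hr_removed")
  out <- smooth_minutes(grid, params$smooth_window)

  users <- unique(events$user_id)
  report <- tidyr::expand_grid(user_id = users,
                               stream = c("heart_rate", "steps", "sleep"))
  present <- out |>
    dplyr::group_by(.data$user_id, .data$stream) |>
    dplyr::summarise(minutes_total = dplyr::n(),
                     minutes_present = sum(!is.na(.data$value)),
                     .groups = "drop")
  report <- dplyr::left_join(report, present,
                             by = c("user_id", "stream")) |>
    dplyr::mutate(minutes_total = dplyr::coalesce(.data$minutes_total, 0L),
                  minutes_present = dplyr::coalesce(.data$minutes_present,
                                                    0L),
                  minutes_missing = .data$minutes_total -
                    .data$minutes_present,
                  absent = .data$minutes_total == 0L)
  attr(out, "report") <- report
  attr(out, "hr_removed") <- hr_removed
  out
}
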