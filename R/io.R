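#' Read event-timestamped sensor records from a CSV file
#'
#' Events are one row per observation: an opaque user token, a stream name
#' (`heart_rate`, `steps`, `sleep`, `label`, `survey`), an ISO-8601
#' timestamp, and a value (numeric for heart rate / steps, a sleep-stage
#' token for sleep). Malformed rows are never silently dropped: they are
#' collected into a rejects report attached as attribute `"rejects"`.
#'
#' @param path Path to a CSV file with a header.
#' @param schema Named character vector mapping the canonical column names
#'   (`user_id`, `stream`, `timestamp`, `value`) to the file's column names.
#' @return A tibble of events with columns `user_id`, `stream`, `timestamp`
#'   (POSIXct, UTC), `value` (double; `NA` for sleep rows) and `category`
#'   (character; `NA` for numeric streams), sorted by user, stream and
#'   timestamp. Attribute `"rejects"` is a tibble with columns `row`,
#'   `reason`.
#' @export
read_events <- function(path,
                        schema = c(user_id = "user_id", stream = "stream",
                                   timestamp = "timestamp", value = "value")) {
  if (!file.exists(path)) stop("cannot read events file: ", path, call. = FALSE)
  need <- c("user_id", "stream", "timestamp", "value")
  stopifnot(all(need %in% names(schema)))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing_cols <- setdiff(unname(schema[need]), names(raw))
  if (length(missing_cols)) {
    stop("events file lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  raw <- tibble::tibble(
    user_id = raw[[schema[["user_id"]]]],
    stream = raw[[schema[["stream"]]]],
    ts_raw = raw[[schema[["timestamp"]]]],
    val_raw = raw[[schema[["value"]]]],
    row = seq_len(nrow(raw))
  )
  as_events(raw)
}

# Validate a raw character event table; returns events + rejects attribute.
as_events <- function(raw) {
  ts <- suppressWarnings(
    readr::parse_datetime(raw$ts_raw, locale = readr::locale(tz = "UTC"))
  )
  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(ts)] <- "bad_timestamp"
  bad_stream <- !(raw$stream %in% STREAMS)
  reason[is.na(reason) & bad_stream] <- "bad_stream"

  numeric_stream <- raw$stream %in% c("heart_rate", "steps")
  num <- suppressWarnings(as.numeric(raw$val_raw))
  bad_num <- numeric_stream & (is.na(num) | !is.finite(num))
  bad_num <- bad_num | (raw$stream == "heart_rate" & !is.na(num) & num <= 0)
  reason[is.na(reason) & bad_num] <- "bad_value"

  sleep_stream <- raw$stream == "sleep"
  bad_sleep <- sleep_stream & !(tolower(raw$val_raw) %in% SLEEP_TOKENS)
  reason[is.na(reason) & bad_sleep] <- "bad_sleep_category"

  keep <- is.na(reason)
  rejects <- tibble::tibble(row = raw$row[!keep], reason = reason[!keep])
  out <- tibble::tibble(
    user_id = raw$user_id[keep],
    stream = raw$stream[keep],
    timestamp = ts[keep],
    value = ifelse(numeric_stream[keep], num[keep], NA_real_),
    category = ifelse(sleep_stream[keep], tolower(raw$val_raw[keep]),
                      NA_character_)
  )
  out <- dplyr::arrange(out, .data$user_id, .data$stream, .data$timestamp)
  attr(out, "rejects") <- rejects
  out
}

#' Write events to CSV
#'
#' Inverse of [read_events()]: the `value` and `category` columns are folded
#' back into a single `value` column.
#'
#' @param events Events tibble as produced by [read_events()] or
#'   [generate_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  out <- tibble::tibble(
    user_id = events$user_id,
    stream = events$stream,
    timestamp = format(events$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    value = ifelse(events$stream == "sleep", events$category,
                   ifelse(is.na(events$value), "",
                          format(events$value, scientific = FALSE,
                                 trim = TRUE, digits = 15)))
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write / read a tabular artifact as CSV
#'
#' RFC-4180 comma-separated files with empty fields as the missing-value
#' sentinel. `read_table_csv(write_table(x, p))` round-trips values and
#' missingness for the pipeline's feature and label tables.
#'
#' @param rows A data frame / tibble.
#' @param path File path.
#' @return `write_table()` returns `path` invisibly; `read_table_csv()`
#'   returns a tibble.
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  readr::write_csv(rows, path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table_csv <- function(path) {
  if (!file.exists(path)) stop("cannot read table: ", path, call. = FALSE)
  readr::read_csv(path, na = "", col_types = readr::cols(), progress = FALSE,
                  show_col_types = FALSE)
}

#' Read per-user labels
#'
#' @param path CSV with columns `user_id`, `phenotype`, `sex`; unknown
#'   labels are empty fields.
#' @return A tibble with one row per user; labels are integer 0/1 or `NA`.
#' @export
read_labels <- function(path) {
  x <- read_table_csv(path)
  stopifnot(all(c("user_id", "phenotype", "sex") %in% names(x)))
  out <- tibble::tibble(
    user_id = as.character(x$user_id),
    phenotype = as.integer(x$phenotype),
    sex = as.integer(x$sex)
  )
  if (anyDuplicated(out$user_id)) {
    stop("labels must have one row per user", call. = FALSE)
  }
  bad <- function(v) any(!is.na(v) & !v %in% c(0L, 1L))
  if (bad(out$phenotype) || bad(out$sex)) {
    stop("labels must be 0, 1 or unknown (empty)", call. = FALSE)
  }
  out
}
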