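#' Assign future time-shift anchors to users
#'
#' Each user receives one strictly positive offset, drawn uniformly (at
#' whole-day granularity by default, so within-day clock structure — sleep
#' at night — survives the shift). Offsets are pairwise distinct whenever
#' the day range admits as many distinct values as users; a degenerate
#' range (`min == max`) gives every user that exact offset. The anchor map
#' is the re-identification key and must be stored separately from the
#' de-identified data.
#'
#' @param user_ids Character vector of users.
#' @param min_offset_days,max_offset_days Offset range in whole days;
#'   `0 < min <= max`.
#' @param seed Integer seed.
#' @return A tibble of class `wear_anchors` with columns `user_id`,
#'   `offset_days`.
#' @export
#' @examples
#' assign_anchors(c("a", "b"), 100, 1000, seed = 1)
assign_anchors <- function(user_ids, min_offset_days = 100,
                           max_offset_days = 1000, seed = 1L) {
  if (min_offset_days <= 0) {
    stop("min_offset_days must be strictly positive", call. = FALSE)
  }
  if (max_offset_days < min_offset_days) {
    stop("max_offset_days must be >= min_offset_days", call. = FALSE)
  }
  user_ids <- as.character(user_ids)
  n <- length(user_ids)
  range <- seq(as.integer(min_offset_days), as.integer(max_offset_days))
  offsets <- withr::with_seed(seed, {
    if (length(range) == 1L) rep(range, n)          # degenerate min == max
    else if (length(range) >= n) sample(range, n)   # distinct by construction
    else sample(range, n, replace = TRUE)
  })
  structure(tibble::tibble(user_id = user_ids, offset_days = offsets),
            class = c("wear_anchors", class(tibble::tibble())))
}

#' Shift all of a user's timestamps by their anchor offset
#'
#' Every record of a user is advanced by the same offset, so all
#' within-user pairwise time differences are preserved exactly while
#' absolute dates (and cross-user relative times) are not.
#'
#' @param events Events tibble.
#' @param anchors Anchor map from [assign_anchors()].
#' @return Events tibble with shifted timestamps.
#' @export
shift_timestamps <- function(events, anchors) {
  if (nrow(events) == 0) return(events)
  miss <- setdiff(unique(events$user_id), anchors$user_id)
  if (length(miss)) {
    stop("no anchor offset for user(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  off <- anchors$offset_days[match(events$user_id, anchors$user_id)]
  events$timestamp <- events$timestamp + off * 86400
  events
}

#' Add slight value noise to numeric streams
#'
#' Independent zero-mean Gaussian noise per stream (default sd 0.5 bpm for
#' heart rate, 0 for steps); categorical sleep records are never touched.
#' Perturbed step counts are re-clamped to non-negative integers.
#'
#' @param events Events tibble.
#' @param noise_sd Named numeric vector of per-stream noise sd
#'   (`heart_rate`, `steps`).
#' @param seed Integer seed.
#' @return Events tibble with perturbed values.
#' @export
perturb_values <- function(events, noise_sd = c(heart_rate = 0.5, steps = 0),
                           seed = 1L) {
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0", call. = FALSE)
  withr::with_seed(seed, {
    for (st in intersect(names(noise_sd), c("heart_rate", "steps"))) {
      sel <- which(events$stream == st & !is.na(events$value))
      if (length(sel) == 0 || noise_sd[[st]] == 0) next
      v <- events$value[sel] + rnorm(length(sel), 0, noise_sd[[st]])
      if (st == "steps") v <- pmax(0, round(v))
      events$value[sel] <- v
    }
  })
  events
}

#' De-identify an event table
#'
#' Convenience composition of [assign_anchors()], [shift_timestamps()] and
#' [perturb_values()]. The returned anchor map must be persisted separately
#' from the de-identified events.
#'
#' @inheritParams assign_anchors
#' @inheritParams perturb_values
#' @param events Events tibble.
#' @return A list with elements `events` (de-identified) and `anchors`.
#' @export
deidentify_events <- function(events, min_offset_days = 100,
                              max_offset_days = 1000,
                              noise_sd = c(heart_rate = 0.5, steps = 0),
                              seed = 1L) {
  anchors <- assign_anchors(unique(events$user_id), min_offset_days,
                            max_offset_days, seed = derive_seed(seed,
                                                                "anchors"))
  out <- shift_timestamps(events, anchors)
  out <- perturb_values(out, noise_sd, seed = derive_seed(seed, "noise"))
  list(events = out, anchors = anchors)
}

#' Write / read an anchor map as JSON
#' @param anchors Anchor map tibble.
#' @param path JSON file path.
#' @return `write_anchors()` returns `path` invisibly; `read_anchors()`
#'   returns the anchor tibble.
#' @export
write_anchors <- function(anchors, path) {
  jsonlite::write_json(as.data.frame(anchors), path, dataframe = "rows",
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_anchors
#' @export
read_anchors <- function(path) {
  x <- jsonlite::fromJSON(path)
  structure(tibble::tibble(user_id = as.character(x$user_id),
                           offset_days = as.integer(x$offset_days)),
            class = c("wear_anchors", class(tibble::tibble())))
}
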