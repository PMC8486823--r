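#' Label-linked effect specification for the synthetic cohort
#'
#' Controls how the binary phenotype shifts the generated physiology:
#' cases (phenotype = 1) get their awake resting heart-rate level shifted
#' by `rest_hr_delta` bpm, their mean daily steps by `step_delta`, and
#' their nightly sleep duration by `sleep_delta` hours. `missing_rate`
#' drops each generated minute independently with that probability.
#'
#' @param rest_hr_delta bpm added to the awake resting heart-rate level of
#'   cases. Default 0.
#' @param step_delta counts/day added to cases' mean daily steps. Default 0.
#' @param sleep_delta hours added to cases' sleep duration. Default 0.
#' @param missing_rate Fraction of minutes dropped, in `[0, 1)`. Default 0.
#' @return A list of class `wear_effect`.
#' @export
effect_spec <- function(rest_hr_delta = 0, step_delta = 0,
                        sleep_delta = 0, missing_rate = 0) {
  stopifnot(
    "missing_rate must be in [0,1)" =
      is.numeric(missing_rate) && missing_rate >= 0 && missing_rate < 1
  )
  structure(list(rest_hr_delta = rest_hr_delta, step_delta = step_delta,
                 sleep_delta = sleep_delta, missing_rate = missing_rate),
            class = "wear_effect")
}

#' Draw per-user physiological profiles
#'
#' One row per user: heart-rate levels for the three states
#' (sleeping < resting < active, enforced by construction), the nightly
#' sleep window, mean daily steps, and heart-rate noise. Each user's draws
#' come from an RNG stream derived from `(seed, user_id)`, so adding users
#' never reshuffles existing ones.
#'
#' @param n_users Number of users (>= 2).
#' @param n_days Days of data per user.
#' @param effect An [effect_spec()].
#' @param seed Integer seed.
#' @return A tibble with one row per user.
#' @export
user_profiles <- function(n_users, n_days = 30L, effect = effect_spec(),
                          seed = 1L) {
  stopifnot("n_users must be >= 2" = n_users >= 2, n_days >= 1)
  ids <- sprintf("u%03d", seq_len(n_users))
  phenotype <- rep_len(c(0L, 1L), n_users)
  rows <- purrr::map2(ids, phenotype, function(id, ph) {
    withr::with_seed(derive_seed(seed, "profile", id), {
      sleep_hr <- rnorm(1, 54, 4)
      rest_hr <- sleep_hr + runif(1, 8, 14) + ph * effect$rest_hr_delta
      active_hr <- sleep_hr + runif(1, 8, 14) + runif(1, 20, 35)
      onset <- 22.5 + rnorm(1, 0, 0.6)
      duration <- max(4, 8 + rnorm(1, 0, 0.5) + ph * effect$sleep_delta)
      tibble::tibble(
        user_id = id,
        baseline_sleep_hr = sleep_hr,
        baseline_rest_hr = rest_hr,
        baseline_active_hr = active_hr,
        sleep_onset = onset %% 24,
        sleep_offset = (onset + duration) %% 24,
        mean_daily_steps = max(1500, rnorm(1, 8000, 2000) +
                                 ph * effect$step_delta),
        hr_noise_sd = runif(1, 2.5, 4),
        phenotype = ph,
        sex = as.integer(runif(1) < 0.5),
        n_days = as.integer(n_days)
      )
    })
  })
  dplyr::bind_rows(rows)
}

# Awake heart rate is "resting" unless the minute falls in an activity bout;
# all draws for one user come from one seeded stream.
simulate_user_events <- function(profile, effect, seed, origin_time,
                                 hr_interval_s, sleep_interval_s,
                                 awake_mark_every_min, unknown_rate) {
  p <- profile
  n_min <- p$n_days * 1440L
  tod_min <- (seq_len(n_min) - 1L) %% 1440L
  tod_h <- tod_min / 60
  asleep <- if (p$sleep_onset <= p$sleep_offset) {
    tod_h >= p$sleep_onset & tod_h < p$sleep_offset
  } else {
    tod_h >= p$sleep_onset | tod_h < p$sleep_offset
  }

  withr::with_seed(derive_seed(seed, "events", p$user_id), {
    ## --- activity bouts on awake minutes --------------------------------
    spm_mean <- 85
    target_active <- p$mean_daily_steps / spm_mean
    bout_len_mean <- 18
    n_bouts <- pmax(1L, rpois(p$n_days, target_active / bout_len_mean))
    awake_tod <- which(!asleep[seq_len(1440L)]) - 1L
    steps <- numeric(n_min)
    for (d in seq_len(p$n_days)) {
      starts <- sample(awake_tod, n_bouts[d], replace = TRUE)
      lens <- 5L + rpois(n_bouts[d], bout_len_mean - 5)
      idx <- unique(rep(starts, lens) + sequence(lens) - 1L)
      idx <- idx[idx < 1440L]
      idx <- intersect(idx, awake_tod)
      if (length(idx)) {
        gi <- (d - 1L) * 1440L + idx + 1L
        steps[gi] <- pmin(200, pmax(1, round(rnorm(length(idx), spm_mean, 20))))
      }
    }

    ## --- heart rate events at second resolution -------------------------
    phase <- sample.int(hr_interval_s, 1L) - 1L
    hr_t <- seq(phase, n_min * 60 - 1, by = hr_interval_s)
    hr_minute <- hr_t %/% 60 + 1L
    level <- ifelse(asleep[hr_minute], p$baseline_sleep_hr,
                    ifelse(steps[hr_minute] > 0, p$baseline_active_hr,
                           p$baseline_rest_hr))
    hr_val <- round(level + rnorm(length(hr_t), 0, p$hr_noise_sd))

    ## --- step events: one per awake minute (zeros included) -------------
    awake_idx <- which(!asleep)
    step_t <- (awake_idx - 1L) * 60
    step_val <- steps[awake_idx]

    ## --- sleep-stage events ---------------------------------------------
    per_min <- max(1L, 60L %/% sleep_interval_s)
    asleep_idx <- which(asleep)
    sl_t <- rep((asleep_idx - 1L) * 60, each = per_min) +
      rep(seq(0L, by = sleep_interval_s, length.out = per_min),
          times = length(asleep_idx))
    sl_cat <- sample(c("asleep", "light", "deep", "restless", "rem"),
                     length(sl_t), replace = TRUE,
                     prob = c(0.2, 0.3, 0.2, 0.1, 0.2))
    mark_idx <- awake_idx[(tod_min[awake_idx] %% awake_mark_every_min) == 0L]
    mk_t <- (mark_idx - 1L) * 60
    mk_cat <- sample(c("awake", "wake"), length(mk_t), replace = TRUE,
                     prob = c(0.85, 0.15))
    all_sl_t <- c(sl_t, mk_t)
    all_sl_cat <- c(sl_cat, mk_cat)
    unk <- runif(length(all_sl_cat)) < unknown_rate
    all_sl_cat[unk] <- "unknown"
  })

  events <- dplyr::bind_rows(
    tibble::tibble(user_id = p$user_id, stream = "heart_rate",
                   timestamp = origin_time + hr_t, value = hr_val,
                   category = NA_character_),
    tibble::tibble(user_id = p$user_id, stream = "steps",
                   timestamp = origin_time + step_t, value = step_val,
                   category = NA_character_),
    tibble::tibble(user_id = p$user_id, stream = "sleep",
                   timestamp = origin_time + all_sl_t, value = NA_real_,
                   category = all_sl_cat)
  )
  dplyr::arrange(events, .data$stream, .data$timestamp)
}

#' Generate a synthetic wearables cohort
#'
#' Emulates multi-day, multi-user raw streams with the structure the
#' analysis assumes: heart-rate events with second-level timestamps
#' following a sleep/rest/active level profile plus Gaussian noise,
#' per-minute step counts concentrated in daytime activity bouts, one
#' nightly sleep bout emitting the 8-token sleep categories, optional
#' missingness, and label-linked effects (e.g., elevated resting heart
#' rate in cases). Identical seeds give byte-identical output.
#'
#' @inheritParams user_profiles
#' @param params A [pipeline_params()] (carried along for downstream stages).
#' @param hr_interval_s Seconds between heart-rate events. Default 30.
#' @param sleep_interval_s Seconds between in-bout sleep-stage events.
#'   Default 60.
#' @param awake_mark_every_min Minutes between awake/wake markers outside
#'   sleep bouts. Default 5.
#' @param unknown_rate Probability a sleep-stage event reads `unknown`.
#'   Default 0.01.
#' @param origin Calendar date (UTC) of the cohort's first midnight.
#' @param profiles Optional pre-drawn [user_profiles()] table.
#' @return A list of class `wear_cohort` with elements `events` (tibble),
#'   `labels` (tibble: `user_id`, `phenotype`, `sex`) and `profiles`.
#' @export
#' @examples
#' coh <- generate_cohort(4, n_days = 2, seed = 1)
#' dplyr::count(coh$events, stream)
generate_cohort <- function(n_users, n_days = 30L, effect = effect_spec(),
                            seed = 1L, params = pipeline_params(),
                            hr_interval_s = 30L, sleep_interval_s = 60L,
                            awake_mark_every_min = 5L, unknown_rate = 0.01,
                            origin = "2023-01-01", profiles = NULL) {
  if (n_users < 2) stop("n_users must be >= 2", call. = FALSE)
  if (is.null(profiles)) {
    profiles <- user_profiles(n_users, n_days, effect, seed)
  }
  if (length(unique(profiles$phenotype)) < 2) {
    stop("cohort must contain both phenotype classes", call. = FALSE)
  }
  origin_time <- as.POSIXct(paste0(origin, " 00:00:00"), tz = "UTC")
  events <- dplyr::bind_rows(lapply(seq_len(nrow(profiles)), function(i) {
    simulate_user_events(profiles[i, ], effect, seed, origin_time,
                         hr_interval_s, sleep_interval_s,
                         awake_mark_every_min, unknown_rate)
  }))
  events <- dplyr::arrange(events, .data$user_id, .data$stream,
                           .data$timestamp)
  if (effect$missing_rate > 0) {
    events <- inject_missingness(events, effect$missing_rate,
                                 derive_seed(seed, "missingness"))
  }
  labels <- tibble::tibble(user_id = profiles$user_id,
                           phenotype = profiles$phenotype,
                           sex = profiles$sex)
  structure(list(events = events, labels = labels, profiles = profiles),
            class = "wear_cohort")
}

#' @export
print.wear_cohort <- function(x, ...) {
  cat("<wear_cohort> ", nrow(x$labels), " users, ",
      nrow(x$events), " events\n", sep = "")
  invisible(x)
}

#' Drop whole minutes of events at random
#'
#' Each (user, stream, minute) cell is dropped independently with
#' probability `missing_rate`; all events inside a dropped minute vanish.
#' The dropped set depends only on the seed and the cell keys, not on
#' input row order.
#'
#' @param events Events tibble.
#' @param missing_rate Drop probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return Events tibble with dropped minutes removed.
#' @export
inject_missingness <- function(events, missing_rate, seed) {
  if (missing_rate >= 1 || missing_rate < 0) {
    stop("missing_rate must be in [0,1)", call. = FALSE)
  }
  if (missing_rate == 0) return(events)
  minute <- floor(as.numeric(events$timestamp) / 60)
  key <- paste(events$user_id, events$stream, minute, sep = "\r")
  ukey <- sort(unique(key))
  keep_key <- withr::with_seed(seed, runif(length(ukey)) >= missing_rate)
  events[keep_key[match(key, ukey)], ]
}
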