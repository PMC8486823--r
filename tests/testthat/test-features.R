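# build a wide day-slot tibble directly
make_day <- function(hr, steps, sleep, user = "u", date = "2023-01-01") {
  n <- max(length(hr), length(steps), length(sleep))
  tibble::tibble(user_id = user, date = as.Date(date),
                 minute_of_day = seq_len(n) - 1L,
                 hr = rep_len(hr, n), steps = rep_len(steps, n),
                 sleep = rep_len(sleep, n))
}

test_that("day splitting partitions minutes at midnight", {
  ev <- make_events("u", "heart_rate", seq(0, 48 * 3600 - 60, by = 60),
                    value = 60)
  d <- split_days(to_minute_grid(ev))
  expect_equal(length(unique(d$date)), 2)
  expect_equal(unname(table(d$date)), c(1440L, 1440L), ignore_attr = TRUE)

  ev2 <- make_events("u", "heart_rate",
                     c(86340, 86400 + 60), value = 60) # 23:59 and 00:01
  d2 <- split_days(to_minute_grid(ev2))
  present <- d2[!is.na(d2$hr), ]
  expect_equal(length(unique(present$date)), 2)
  expect_equal(nrow(split_days(to_minute_grid(ev[0, ]))), 0)
})

test_that("heart-rate stratification follows the literal definitions", {
  d <- make_day(hr = c(50, 60, 90), steps = c(0, 0, 120),
                sleep = c(1, 0, 0))
  s <- stratify_hr(d)
  expect_equal(s$sleeping, 50)
  expect_equal(sort(s$resting), c(50, 60)) # sleep minutes with 0 steps count
  expect_equal(s$active, 90)
  # awake-only variant excludes the sleeping minute from resting
  expect_equal(stratify_hr(d, awake_only = TRUE)$resting, 60)

  allmove <- make_day(hr = c(70, 80), steps = c(5, 10), sleep = c(0, 0))
  expect_length(stratify_hr(allmove)$resting, 0)
  nohr <- make_day(hr = c(NA, NA), steps = c(0, 5), sleep = c(1, 0))
  expect_true(all(lengths(stratify_hr(nohr)) == 0))
})

test_that("stratification equals an independent brute-force filter", {
  withr::with_seed(13, {
    for (i in 1:30) {
      n <- 50
      d <- make_day(
        hr = ifelse(runif(n) < 0.2, NA, rnorm(n, 70, 10)),
        steps = ifelse(runif(n) < 0.2, NA, rpois(n, 1)),
        sleep = ifelse(runif(n) < 0.2, NA, rbinom(n, 1, 0.4))
      )
      s <- stratify_hr(d)
      sleeping <- resting <- active <- numeric(0)
      for (j in seq_len(n)) {
        if (is.na(d$hr[j])) next
        if (!is.na(d$sleep[j]) && d$sleep[j] == 1) {
          sleeping <- c(sleeping, d$hr[j])
        }
        if (!is.na(d$steps[j])) {
          if (d$steps[j] == 0) resting <- c(resting, d$hr[j])
          if (d$steps[j] > 0) active <- c(active, d$hr[j])
        }
      }
      expect_equal(s$sleeping, sleeping)
      expect_equal(s$resting, resting)
      expect_equal(s$active, active)
    }
  })
})

test_that("outlier fraction matches hand calculations and closed forms", {
  expect_equal(outlier_fraction(c(rep(1, 10), 100)), 100 / 11,
               tolerance = 1e-12)
  expect_equal(outlier_fraction(rep(7, 5)), 0)
  # any 2-point set: each point sits sd/sqrt(2) < k*sd from the mean
  expect_equal(outlier_fraction(c(3, 11)), 0)
  expect_true(is.na(outlier_fraction(numeric(0))))
  expect_true(is.na(outlier_fraction(c(NA, NA))))
})

test_that("outlier fraction equals a brute-force loop on randomized inputs", {
  withr::with_seed(17, {
    for (i in 1:50) {
      v <- rnorm(sample(3:80, 1)) * sample(1:20, 1)
      k <- sample(c(1, 2, 3), 1)
      m <- mean(v); s <- sd(v)
      cnt <- 0
      for (x in v) if (abs(x - m) > k * s) cnt <- cnt + 1
      expect_equal(outlier_fraction(v, k), 100 * cnt / length(v))
    }
  })
})

test_that("the constructed constant day reproduces its hand-computed features", {
  hr <- rep(60, 1440)
  sleep <- c(rep(1, 480), rep(0, 960))                   # 00:00-08:00 asleep
  steps <- rep(0, 1440); steps[721:780] <- 100           # 12:00-13:00 active
  d <- make_day(hr, steps, sleep)
  f <- daily_features(d)
  expect_equal(nrow(f), 1)
  expect_equal(ncol(f) - 2L, 12L) # user_id + date + exactly 12 features
  expect_equal(f$avg_hr, 60)
  expect_equal(f$total_steps, 6000)
  expect_equal(f$sleep_hours, 8)
  expect_equal(f$sleeping_hr, 60)
  expect_equal(f$resting_hr, 60)
  expect_equal(f$active_hr, 60)
  expect_equal(f$active_minus_sleeping_hr, 0)
  expect_equal(f$outlier_pct_hr, 0)
  expect_equal(f$outlier_pct_sleeping_hr, 0)
  expect_equal(f$outlier_pct_resting_hr, 0)
  expect_equal(f$outlier_pct_active_hr, 0)
  # steps that day are 1380 zeros and 60 hundreds: mean 25/6, sd ~19.99,
  # so exactly the 60 active minutes exceed 2 sd -> 60/1440
  expect_equal(f$outlier_pct_steps, 100 * 60 / 1440, tolerance = 1e-12)
})

test_that("empty strata yield missing features", {
  d <- make_day(hr = rep(70, 100), steps = rep(0, 100), sleep = rep(0, 100))
  f <- daily_features(d)
  expect_true(is.na(f$active_hr))
  expect_true(is.na(f$active_minus_sleeping_hr))
  expect_true(is.na(f$sleeping_hr))
  expect_equal(f$resting_hr, 70)
})

test_that("feature extraction is invariant to event input order", {
  coh <- generate_cohort(3, n_days = 2, seed = 18)
  ev <- coh$events
  shuffled <- ev[withr::with_seed(2, sample(nrow(ev))), ]
  f1 <- daily_features(preprocess_events(ev))
  f2 <- daily_features(preprocess_events(shuffled))
  expect_identical(f1, f2)
})

test_that("user-level aggregation yields the 7 x 12 summary set", {
  uf <- small_user_features()
  expect_true(all(user_feature_names() %in% names(uf)))
  expect_length(user_feature_names(), 84)
  # identical daily vectors collapse every statistic onto the value
  daily <- dplyr::bind_rows(
    make_day(rep(60, 10), rep(0, 10), rep(1, 10), date = "2023-01-01"),
    make_day(rep(60, 10), rep(0, 10), rep(1, 10), date = "2023-01-02")
  ) |> daily_features()
  u <- user_features(daily)
  expect_equal(u$mean__resting_hr, 60)
  expect_equal(u$min__resting_hr, 60)
  expect_equal(u$max__resting_hr, 60)
  expect_equal(u$q50__resting_hr, 60)
  expect_equal(u$sd__resting_hr, 0)
})

test_that("quartiles use linear interpolation and respect ordering", {
  daily <- purrr::map(1:4, function(i) {
    make_day(rep(60 + i, 10), rep(0, 10), rep(0, 10),
             date = sprintf("2023-01-%02d", i))
  }) |> dplyr::bind_rows() |> daily_features()
  u <- user_features(daily)
  # resting_hr over days is {61,62,63,64}
  expect_equal(u$q25__resting_hr, 61.75)
  expect_equal(u$q50__resting_hr, 62.5)
  expect_equal(u$q75__resting_hr, 63.25)
  uf <- small_user_features()
  for (f in c("avg_hr", "resting_hr", "total_steps")) {
    expect_true(all(uf[[paste0("min__", f)]] <= uf[[paste0("q25__", f)]]))
    expect_true(all(uf[[paste0("q25__", f)]] <= uf[[paste0("q50__", f)]]))
    expect_true(all(uf[[paste0("q50__", f)]] <= uf[[paste0("q75__", f)]]))
    expect_true(all(uf[[paste0("q75__", f)]] <= uf[[paste0("max__", f)]]))
  }
})

test_that("cohort filters drop unlabeled and short users and truncate to the horizon", {
  mk_user <- function(u, n) {
    purrr::map(seq_len(n), function(i) {
      make_day(rep(60, 10), rep(i, 10), rep(0, 10), user = u,
               date = as.character(as.Date("2023-01-01") + i - 1))
    }) |> dplyr::bind_rows()
  }
  daily <- daily_features(dplyr::bind_rows(
    mk_user("a", 20), mk_user("b", 10), mk_user("c", 100), mk_user("d", 14),
    mk_user("e", 30)
  ))
  labels <- tibble::tibble(user_id = c("a", "b", "c", "d", "e"),
                           phenotype = c(1L, 0L, 1L, 0L, NA),
                           sex = c(0L, 1L, 0L, 1L, 1L))
  out <- filter_cohort(daily, labels)
  rep_ <- attr(out, "report")
  counts <- table(out$user_id)
  expect_setequal(names(counts), c("a", "c", "d"))
  expect_equal(unname(counts[["a"]]), 20)
  expect_equal(unname(counts[["c"]]), 90) # truncated to first 90 days
  expect_equal(unname(counts[["d"]]), 14) # exactly 14 days is kept
  expect_equal(rep_$reason[rep_$user_id == "b"], "too_few_days")
  expect_equal(rep_$reason[rep_$user_id == "e"], "unlabeled")
  # filtering on sex keeps e but still drops b
  out_sex <- filter_cohort(daily, labels, target = "sex")
  expect_true("e" %in% out_sex$user_id)
  expect_error(filter_cohort(daily[0, ], labels), "no users")
})
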