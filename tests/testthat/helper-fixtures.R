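# Shared fixtures (built once per test run) and independent brute-force
# oracles used across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# 10 users x 16 days with an 8 bpm resting-HR case shift
small_cohort <- function() {
  fixture("small_cohort", function() {
    generate_cohort(10, n_days = 16,
                    effect = effect_spec(rest_hr_delta = 8), seed = 101)
  })
}

small_minutes <- function() {
  fixture("small_minutes", function() {
    preprocess_events(small_cohort()$events)
  })
}

small_daily <- function() {
  fixture("small_daily", function() daily_features(small_minutes()))
}

small_user_features <- function() {
  fixture("small_user_features", function() {
    coh <- small_cohort()
    filtered <- filter_cohort(small_daily(), coh$labels)
    user_features(filtered, coh$labels)
  })
}

# convenience constructor for hand-built event tables
make_events <- function(user_id, stream, t_sec, value = NA_real_,
                        category = NA_character_) {
  origin <- as.POSIXct("2023-01-01 00:00:00", tz = "UTC")
  tibble::tibble(user_id = user_id, stream = stream,
                 timestamp = origin + t_sec,
                 value = as.numeric(value),
                 category = as.character(category))
}

# ---- independent oracles ---------------------------------------------------

# AUROC as an explicit double loop over positive-negative pairs
brute_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}

# average precision as an explicit sweep over descending unique thresholds
brute_ap <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  prev_r <- 0
  ap <- 0
  for (t in th) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    p <- tp / sum(sel)
    r <- tp / n_pos
    ap <- ap + (r - prev_r) * p
    prev_r <- r
  }
  ap
}

# trailing rolling statistic as an explicit per-position loop
brute_roll <- function(x, window, fun) {
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    w <- x[max(1, i - window + 1):i]
    w <- w[!is.na(w)]
    if (length(w)) out[i] <- fun(w)
  }
  out
}

random_score_set <- function(n = 30) {
  repeat {
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) == 2) break
  }
  # coarse grid forces ties so tie handling is exercised
  list(scores = sample(0:10, n, replace = TRUE) / 10, labels = labels)
}
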