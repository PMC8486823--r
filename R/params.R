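#' Pipeline parameter registry
#'
#' Collects every numeric constant of the analysis in one validated object:
#' the heart-rate cleaning floor, the rolling smoothing window, the outlier
#' threshold in standard deviations, the cohort filters (minimum days,
#' analysis horizon), and the cross-validation / elastic-net settings.
#'
#' @param hr_floor Heart-rate cleaning floor in bpm; minute values strictly
#'   below it become missing. Default 20.
#' @param smooth_window Trailing rolling-window length in minutes for
#'   smoothing (mean for heart rate and steps, max for binarized sleep).
#'   Default 5.
#' @param outlier_k Outlier threshold in sample standard deviations.
#'   Default 2.
#' @param min_days Minimum number of usable days a user must have after
#'   preprocessing to enter the cohort. Default 14.
#' @param horizon_days Analysis horizon: users are truncated to their first
#'   `horizon_days` calendar days. Default 90.
#' @param cv_folds Number of cross-validation folds. Default 5.
#' @param cv_repeats Number of repeated random splits. Default 10.
#' @param l1_ratio Elastic-net mixing parameter in \[0, 1\] (1 = lasso,
#'   0 = ridge). Default 0.5.
#' @param regularization_strength Inverse regularization strength (larger =
#'   weaker penalty); the penalty weight used is
#'   `1 / (regularization_strength * n_train)`. Default 1.
#' @param rng_seed Master integer seed driving all randomized stages.
#' @return A list of class `wear_params`.
#' @export
#' @examples
#' pipeline_params(rng_seed = 7)
pipeline_params <- function(hr_floor = 20,
                            smooth_window = 5L,
                            outlier_k = 2,
                            min_days = 14L,
                            horizon_days = 90L,
                            cv_folds = 5L,
                            cv_repeats = 10L,
                            l1_ratio = 0.5,
                            regularization_strength = 1.0,
                            rng_seed = 1L) {
  stopifnot(
    "hr_floor must be > 0" = is.numeric(hr_floor) && hr_floor > 0,
    "outlier_k must be > 0" = is.numeric(outlier_k) && outlier_k > 0,
    "l1_ratio must be in [0,1]" =
      is.numeric(l1_ratio) && l1_ratio >= 0 && l1_ratio <= 1,
    "regularization_strength must be > 0" =
      is.numeric(regularization_strength) && regularization_strength > 0
  )
  counts <- list(smooth_window = smooth_window, min_days = min_days,
                 horizon_days = horizon_days, cv_folds = cv_folds,
                 cv_repeats = cv_repeats)
  for (nm in names(counts)) {
    v <- counts[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != as.integer(v)) {
      stop(nm, " must be a positive integer", call. = FALSE)
    }
  }
  structure(list(
    hr_floor = hr_floor,
    smooth_window = as.integer(smooth_window),
    outlier_k = outlier_k,
    min_days = as.integer(min_days),
    horizon_days = as.integer(horizon_days),
    cv_folds = as.integer(cv_folds),
    cv_repeats = as.integer(cv_repeats),
    l1_ratio = l1_ratio,
    regularization_strength = regularization_strength,
    rng_seed = as.integer(rng_seed)
  ), class = "wear_params")
}

#' @export
print.wear_params <- function(x, ...) {
  cat("<wear_params>\n")
  for (nm in names(x)) cat(" ", nm, "=", format(x[[nm]]), "\n")
  invisible(x)
}

#' Default sleep-stage binarization mapping
#'
#' Maps the eight device sleep-stage tokens to a binary asleep indicator:
#' asleep-like stages (`asleep`, `light`, `deep`, `restless`, `rem`) to 1,
#' awake stages (`awake`, `wake`) to 0, and `unknown` to missing.
#'
#' @return Named integer vector over the 8 tokens (`NA` for `unknown`).
#' @export
sleep_mapping <- function() {
  c(asleep = 1L, light = 1L, deep = 1L, restless = 1L, rem = 1L,
    awake = 0L, wake = 0L, unknown = NA_integer_)
}

#' Derive a child seed from a master seed and a string key
#'
#' Deterministic polynomial string hash of the key folded with the master
#' seed, reduced below 2^31 so it is a valid R integer seed. Used to give
#' each user, repeat, or stage an independent reproducible RNG stream.
#'
#' @param seed Master integer seed.
#' @param ... Character/numeric components identifying the child stream.
#' @return A positive integer seed.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed, scientific = FALSE), as.character(list(...))),
               collapse = "/")
  m <- 2^31 - 1
  h <- 2166136261 %% m
  for (b in utf8ToInt(key)) {
    # doubles are exact below 2^53, so (h * 131 + b) never loses precision
    h <- (h * 131 + b) %% m
  }
  as.integer(h) + 1L
}
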