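#' Drop days with a total step count of 0
#'
#' @param daily Daily-features tibble.
#' @return Filtered tibble; the number of removed rows is attached as
#'   attribute `"n_removed"`. All rows removed is an error.
#' @export
filter_zero_step_days <- function(daily) {
  drop <- !is.na(daily$total_steps) & daily$total_steps == 0
  out <- daily[!drop, ]
  if (nrow(out) == 0) {
    stop("all days have a zero total step count", call. = FALSE)
  }
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Signed log transform and standardization of the day-level feature matrix
#'
#' Applies `sign(x) * log(1 + |x|)` per cell (defined on all reals, so the
#' signed active-minus-sleeping difference and zero counts are handled),
#' then centers and scales each column to mean 0 and sd 1. Constant
#' columns become all-zero and are flagged in attribute
#' `"zero_variance"`.
#'
#' @param daily Daily-features tibble (or a numeric matrix of the 12
#'   feature columns).
#' @param signed Use the signed log1p (default). `FALSE` applies plain
#'   `log1p` and errors on negative values.
#' @return A numeric matrix with one row per day.
#' @export
log_standardize <- function(daily, signed = TRUE) {
  M <- if (is.matrix(daily)) daily else
    as.matrix(daily[, intersect(DAILY_FEATURES, names(daily))])
  if (signed) {
    L <- sign(M) * log1p(abs(M))
  } else {
    if (any(M < 0, na.rm = TRUE)) {
      stop("plain log1p requires non-negative features", call. = FALSE)
    }
    L <- log1p(M)
  }
  ctr <- colMeans(L)
  scl <- apply(L, 2, sd)
  zero <- !is.finite(scl) | scl == 0
  scl[zero] <- 1
  out <- sweep(sweep(L, 2, ctr), 2, scl, "/")
  attr(out, "zero_variance") <- colnames(M)[zero]
  out
}

#' Embed the day-level feature space in 2-D
#'
#' Filters zero-step days, keeps complete cases of the 12 features,
#' applies [log_standardize()], and hands the matrix to a pluggable
#' seeded embedding engine: non-metric multidimensional scaling
#' (`vegan::monoMDS`, default) or classical PCoA (`stats::cmdscale`).
#' Returns per-day coordinates plus each user's coordinate-wise median
#' point.
#'
#' @param daily Daily-features tibble.
#' @param seed Integer seed for the engine.
#' @param engine `"nmds"` or `"pcoa"`.
#' @return An object of class `wear_embedding`: list with `days`
#'   (`user_id`, `date`, `dim1`, `dim2`), `user_medians`, `engine`,
#'   `seed`, `n_dropped` (zero-step or incomplete rows removed).
#' @export
embed_days <- function(daily, seed = 1L, engine = c("nmds", "pcoa")) {
  engine <- match.arg(engine)
  kept <- filter_zero_step_days(daily)
  cc <- complete.cases(kept[, DAILY_FEATURES])
  kept <- kept[cc, ]
  if (nrow(kept) < 2) stop("need >= 2 complete days to embed", call. = FALSE)
  Z <- log_standardize(kept)
  d <- dist(Z)
  coords <- withr::with_seed(seed, {
    if (engine == "nmds") {
      init <- cmdscale(d, k = 2)
      fit <- vegan::monoMDS(d, y = init, k = 2, model = "global")
      fit$points
    } else {
      cmdscale(d, k = 2)
    }
  })
  days <- tibble::tibble(user_id = kept$user_id, date = kept$date,
                         dim1 = coords[, 1], dim2 = coords[, 2])
  med <- days |>
    dplyr::group_by(.data$user_id) |>
    dplyr::summarise(dim1 = median(.data$dim1),
                     dim2 = median(.data$dim2), .groups = "drop")
  structure(list(days = days, user_medians = med, engine = engine,
                 seed = seed,
                 n_dropped = nrow(daily) - nrow(kept)),
            class = "wear_embedding")
}

#' @export
print.wear_embedding <- function(x, ...) {
  cat("<wear_embedding> ", nrow(x$days), " days, ",
      nrow(x$user_medians), " users (", x$engine, ")\n", sep = "")
  invisible(x)
}

#' Scatter plot of the 2-D day embedding
#'
#' Days as points, per-user medians as diamonds; colored by user or, when
#' a labels table is supplied, by phenotype.
#'
#' @param object A `wear_embedding`.
#' @param labels Optional labels tibble to color by phenotype.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wear_embedding <- function(object, labels = NULL, ...) {
  days <- object$days
  med <- object$user_medians
  if (!is.null(labels)) {
    days <- dplyr::left_join(days, labels, by = "user_id")
    med <- dplyr::left_join(med, labels, by = "user_id")
    col <- ggplot2::aes(colour = factor(.data$phenotype))
    lab <- "phenotype"
  } else {
    col <- ggplot2::aes(colour = .data$user_id)
    lab <- "user"
  }
  ggplot2::ggplot(days, ggplot2::aes(x = .data$dim1, y = .data$dim2)) +
    ggplot2::geom_point(col, alpha = 0.5, size = 1) +
    ggplot2::geom_point(data = med, mapping = col, shape = 18, size = 4) +
    ggplot2::labs(colour = lab, x = "dim 1", y = "dim 2",
                  title = "Day-level feature-space embedding") +
    ggplot2::theme_minimal()
}
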