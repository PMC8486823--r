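#' Randomly partition users into k non-overlapping folds
#'
#' Plain (unstratified) random split; fold sizes differ by at most one.
#'
#' @param user_ids Character vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @param stratify Optional vector of class labels aligned with
#'   `user_ids`; when supplied, folds are filled class by class so each
#'   fold's class mix is as even as possible.
#' @return A tibble with columns `user_id`, `fold`.
#' @export
make_partitions <- function(user_ids, k, seed = 1L, stratify = NULL) {
  n <- length(user_ids)
  if (n < k) stop("need at least k users for k folds", call. = FALSE)
  withr::with_seed(seed, {
    if (is.null(stratify)) {
      fold <- sample(rep_len(seq_len(k), n))
    } else {
      fold <- integer(n)
      pos <- 0L
      for (cl in unique(stratify)) {
        idx <- sample(which(stratify == cl))
        fold[idx] <- ((pos + seq_along(idx) - 1L) %% k) + 1L
        pos <- pos + length(idx)
      }
    }
  })
  tibble::tibble(user_id = as.character(user_ids), fold = fold)
}

# ---- Yeo-Johnson power transform -------------------------------------------

yeo_johnson <- function(x, lambda) {
  out <- numeric(length(x))
  pos <- !is.na(x) & x >= 0
  neg <- !is.na(x) & x < 0
  if (abs(lambda) > 1e-8) {
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  } else {
    out[pos] <- log1p(x[pos])
  }
  if (abs(lambda - 2) > 1e-8) {
    out[neg] <- -((-x[neg] + 1)^(2 - lambda) - 1) / (2 - lambda)
  } else {
    out[neg] <- -log1p(-x[neg])
  }
  out[is.na(x)] <- NA_real_
  out
}

yj_loglik <- function(lambda, x) {
  psi <- yeo_johnson(x, lambda)
  n <- length(x)
  v <- var(psi) * (n - 1) / n
  # large finite penalty (not -Inf) keeps optimize() quiet on degenerate lambda
  if (!is.finite(v) || v <= 0) return(-1e300)
  -n / 2 * log(v) + (lambda - 1) * sum(sign(x) * log1p(abs(x)))
}

#' Fit a train-only power-transform normalization
#'
#' Per feature: a Yeo-Johnson power transform with the profile-maximum-
#' likelihood exponent, followed by centering and scaling so transformed
#' training columns have mean 0 and sd 1. All parameters depend only on
#' the rows given here; apply them to held-out data with
#' [power_transform_apply()]. Constant columns pass through unchanged and
#' are flagged.
#'
#' @param X Numeric matrix or data frame of the training rows (no missing
#'   cells; impute beforehand).
#' @return An object of class `wear_power_transform`: a tibble with
#'   columns `column`, `lambda`, `center`, `scale`, `zero_variance`.
#' @export
power_transform_fit <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need >= 2 training rows", call. = FALSE)
  if (anyNA(X)) stop("training matrix has missing cells", call. = FALSE)
  cols <- colnames(X)
  if (is.null(cols)) cols <- paste0("V", seq_len(ncol(X)))
  fit_one <- function(x) {
    if (sd(x) == 0) {
      return(c(lambda = 1, center = 0, scale = 1, zero_variance = 1))
    }
    lam <- optimize(function(l) yj_loglik(l, x), interval = c(-5, 5),
                    maximum = TRUE)$maximum
    t <- yeo_johnson(x, lam)
    c(lambda = lam, center = mean(t), scale = sd(t), zero_variance = 0)
  }
  par <- t(apply(X, 2, fit_one))
  structure(tibble::tibble(
    column = cols,
    lambda = par[, "lambda"],
    center = par[, "center"],
    scale = par[, "scale"],
    zero_variance = par[, "zero_variance"] == 1
  ), class = c("wear_power_transform", class(tibble::tibble())))
}

#' Apply fitted power-transform parameters
#'
#' Deterministic: no refitting, identical rows map to identical outputs.
#' Columns flagged zero-variance at fit time pass through unchanged.
#'
#' @param pt A `wear_power_transform` from [power_transform_fit()].
#' @param X Matrix / data frame with the same columns as at fit time.
#' @return A numeric matrix.
#' @export
power_transform_apply <- function(pt, X) {
  X <- as.matrix(X)
  cols <- colnames(X)
  if (is.null(cols)) cols <- paste0("V", seq_len(ncol(X)))
  if (!identical(cols, pt$column)) {
    stop("column mismatch between transform parameters and matrix",
         call. = FALSE)
  }
  if (nrow(X) == 0) return(X)
  out <- X
  for (j in seq_len(ncol(X))) {
    if (pt$zero_variance[j]) next
    out[, j] <- (yeo_johnson(X[, j], pt$lambda[j]) - pt$center[j]) /
      pt$scale[j]
  }
  out
}

#' Fit an L1-L2 regularized logistic regression
#'
#' Minimizes average logistic loss plus
#' `lambda * (alpha * ||b||_1 + (1 - alpha)/2 * ||b||_2^2)` (the standard
#' elastic-net convention; fitted with glmnet at a single penalty value).
#' By default `lambda = 1 / (strength * n)`, so `strength` acts as an
#' inverse regularization strength; pass `lambda` explicitly to pin the
#' penalty independently of n.
#'
#' @param X Numeric matrix (rows = users, columns = features).
#' @param y Binary 0/1 vector; both classes must be present.
#' @param l1_ratio Elastic-net mixing `alpha` in `[0, 1]`.
#' @param strength Inverse regularization strength (> 0).
#' @param lambda Optional explicit penalty weight overriding `strength`.
#' @return An object of class `wear_enet` with elements `coefficients`
#'   (named vector), `intercept`, `lambda`, `l1_ratio`.
#' @export
fit_elastic_logistic <- function(X, y, l1_ratio = 0.5, strength = 1,
                                 lambda = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2) {
    stop("both classes must be present in y", call. = FALSE)
  }
  if (is.null(lambda)) lambda <- 1 / (strength * nrow(X))
  if (min(table(y)) < 2) {
    stop("each class needs at least 2 observations to fit", call. = FALSE)
  }
  # small cohorts are the norm here; glmnet's sample-size caution is noise
  fit <- withCallingHandlers(
    glmnet::glmnet(X, y, family = "binomial", alpha = l1_ratio,
                   lambda = lambda, standardize = FALSE,
                   thresh = 1e-10, maxit = 1e6),
    warning = function(w) {
      if (grepl("dangerous ground", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- as.numeric(fit$beta)
  names(beta) <- rownames(fit$beta)
  structure(list(coefficients = beta, intercept = as.numeric(fit$a0),
                 lambda = lambda, l1_ratio = l1_ratio),
            class = "wear_enet")
}

#' @export
predict.wear_enet <- function(object, newdata, ...) {
  eta <- as.matrix(newdata) %*% object$coefficients + object$intercept
  plogis(drop(eta))
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive
#' outranks a random negative, with half credit for ties.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary 0/1 labels; both classes required.
#' @return AUROC in `[0, 1]`.
#' @export
#' @examples
#' auroc(c(0.1, 0.2, 0.3, 0.4), c(0, 1, 0, 1))  # 0.75
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUROC undefined: both classes required", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision
#'
#' Step-sum of the precision-recall curve over descending unique score
#' thresholds: `sum_n (R_n - R_{n-1}) * P_n`.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary 0/1 labels; at least one positive required.
#' @return Average precision in `(0, 1]`.
#' @export
#' @examples
#' average_precision(c(0.9, 0.8, 0.7), c(1, 0, 1))  # 0.8333
average_precision <- function(scores, labels) {
  labels <- as.integer(labels)
  p <- sum(labels == 1)
  if (p == 0) {
    stop("average precision undefined: no positives", call. = FALSE)
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  # cumulative TP / predicted-positive counts at each unique threshold
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(l)[last_of_tie]
  np <- seq_along(l)[last_of_tie]
  recall <- tp / p
  precision <- tp / np
  sum(diff(c(0, recall)) * precision)
}

#' Repeated k-fold cross-validated elastic-net classification
#'
#' For each of `cv_repeats` repeats: a fresh seeded `cv_folds`-way random
#' split of the users; per fold, missing cells are imputed with the
#' train-fold median, the power transform is fitted on the training rows
#' only and applied to both sides, an elastic-net logistic model is
#' trained, and the held-out users are scored. All out-of-fold scores of a
#' repeat are pooled into one AUROC and one average precision, giving
#' `cv_repeats` values of each. Fully deterministic given the master seed.
#'
#' @param features User-feature tibble from [user_features()] (must carry
#'   the label columns).
#' @param target `"phenotype"` or `"sex"`.
#' @param params A [pipeline_params()] (folds, repeats, l1_ratio,
#'   strength, master seed).
#' @param seed Master seed; defaults to `params$rng_seed`.
#' @param stratified Use class-stratified folds (default `FALSE`, plain
#'   random splits).
#' @return An object of class `wear_cv`: list with `metrics` (tibble:
#'   `repeat_id`, `auroc`, `average_precision`), `scores` (per-user
#'   out-of-fold scores per repeat), `folds`, `coefficients`, `target`,
#'   `params`.
#' @export
cross_validate <- function(features, target = c("phenotype", "sex"),
                           params = pipeline_params(),
                           seed = params$rng_seed, stratified = FALSE) {
  target <- match.arg(target)
  if (!target %in% names(features)) {
    stop("features lack label column ", target, call. = FALSE)
  }
  feat_cols <- intersect(user_feature_names(), names(features))
  if (length(feat_cols) == 0) stop("no feature columns found", call. = FALSE)
  y <- as.integer(features[[target]])
  if (anyNA(y)) stop("unlabeled users present; filter the cohort first",
                     call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("both classes required for classification", call. = FALSE)
  }
  X <- as.matrix(features[, feat_cols])
  rownames(X) <- features$user_id
  k <- params$cv_folds

  metrics <- vector("list", params$cv_repeats)
  scores_l <- vector("list", params$cv_repeats)
  folds_l <- vector("list", params$cv_repeats)
  coefs_l <- vector("list", params$cv_repeats)

  for (r in seq_len(params$cv_repeats)) {
    folds <- make_partitions(features$user_id, k,
                             seed = derive_seed(seed, "repeat", r),
                             stratify = if (stratified) y else NULL)
    fold_of <- folds$fold[match(features$user_id, folds$user_id)]
    sc <- numeric(length(y))
    cf <- vector("list", k)
    for (f in seq_len(k)) {
      tr <- fold_of != f
      te <- !tr
      if (length(unique(y[tr])) < 2 || min(table(y[tr])) < 2) {
        stop("training set of repeat ", r, ", fold ", f,
             " has fewer than 2 users of one class; cohort too small or ",
             "imbalanced for ", k, "-fold cross-validation", call. = FALSE)
      }
      Xtr <- X[tr, , drop = FALSE]
      Xte <- X[te, , drop = FALSE]
      # train-only median imputation of missing user-level cells
      med <- apply(Xtr, 2, median, na.rm = TRUE)
      med[is.na(med)] <- 0
      for (j in which(colSums(is.na(Xtr)) > 0 | colSums(is.na(Xte)) > 0)) {
        Xtr[is.na(Xtr[, j]), j] <- med[j]
        Xte[is.na(Xte[, j]), j] <- med[j]
      }
      pt <- power_transform_fit(Xtr)
      Ztr <- power_transform_apply(pt, Xtr)
      Zte <- power_transform_apply(pt, Xte)
      fit <- fit_elastic_logistic(Ztr, y[tr], l1_ratio = params$l1_ratio,
                                  strength = params$regularization_strength)
      sc[te] <- predict(fit, Zte)
      cf[[f]] <- tibble::tibble(repeat_id = r, fold = f,
                                term = c("(Intercept)",
                                         names(fit$coefficients)),
                                estimate = c(fit$intercept,
                                             unname(fit$coefficients)))
    }
    metrics[[r]] <- tibble::tibble(repeat_id = r,
                                   auroc = auroc(sc, y),
                                   average_precision =
                                     average_precision(sc, y))
    scores_l[[r]] <- tibble::tibble(repeat_id = r,
                                    user_id = features$user_id,
                                    fold = fold_of, score = sc, label = y)
    folds_l[[r]] <- dplyr::mutate(folds, repeat_id = r)
    coefs_l[[r]] <- dplyr::bind_rows(cf)
  }
  structure(list(
    metrics = dplyr::bind_rows(metrics),
    scores = dplyr::bind_rows(scores_l),
    folds = dplyr::bind_rows(folds_l),
    coefficients = dplyr::bind_rows(coefs_l),
    target = target,
    params = params,
    seed = seed
  ), class = "wear_cv")
}

#' @export
print.wear_cv <- function(x, ...) {
  cat("<wear_cv> target =", x$target, "|", nrow(x$metrics), "repeats x",
      x$params$cv_folds, "folds\n")
  cat(sprintf("  mean AUROC %.3f  mean AP %.3f\n",
              mean(x$metrics$auroc), mean(x$metrics$average_precision)))
  invisible(x)
}

#' @rdname cross_validate
#' @param x A `wear_cv` object.
#' @param ... Unused.
#' @export
tidy.wear_cv <- function(x, ...) x$metrics

#' @rdname cross_validate
#' @export
glance.wear_cv <- function(x, ...) {
  tibble::tibble(
    target = x$target,
    n_users = length(unique(x$scores$user_id)),
    n_repeats = nrow(x$metrics),
    n_folds = x$params$cv_folds,
    mean_auroc = mean(x$metrics$auroc),
    sd_auroc = sd(x$metrics$auroc),
    mean_average_precision = mean(x$metrics$average_precision),
    sd_average_precision = sd(x$metrics$average_precision)
  )
}

#' Boxplots of the per-repeat pooled AUROC and average precision
#' @param object A `wear_cv` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wear_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(object$metrics,
                              c("auroc", "average_precision"),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(width = 0.4, outlier.shape = 21) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "score",
                  title = paste0("Repeated CV (", object$target, ")"),
                  subtitle = paste(nrow(object$metrics), "repeats,",
                                   object$params$cv_folds, "folds")) +
    ggplot2::theme_minimal()
}
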