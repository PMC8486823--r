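test_that("partitions are balanced, disjoint, exhaustive and seeded", {
  ids10 <- sprintf("u%02d", 1:10)
  f <- make_partitions(ids10, 5, seed = 1)
  expect_equal(unname(table(f$fold)), rep(2L, 5), ignore_attr = TRUE)
  expect_setequal(f$user_id, ids10)
  expect_identical(make_partitions(ids10, 5, seed = 1), f)
  ids11 <- sprintf("u%02d", 1:11)
  f11 <- make_partitions(ids11, 5, seed = 2)
  expect_equal(sort(unname(table(f11$fold))), c(2L, 2L, 2L, 2L, 3L),
               ignore_attr = TRUE)
  expect_error(make_partitions(ids10[1:3], 5), "at least k")
})

test_that("power transform standardizes training columns to mean 0, sd 1", {
  withr::with_seed(31, {
    X <- cbind(normal = rnorm(200), lognorm = exp(rnorm(200)),
               shifted = rnorm(200, 50, 5))
    pt <- power_transform_fit(X)
    Z <- power_transform_apply(pt, X)
    expect_lt(max(abs(colMeans(Z))), 1e-9)
    expect_lt(max(abs(apply(Z, 2, sd) - 1)), 1e-9)
    # an already standard-normal column needs little warping
    expect_lt(abs(pt$lambda[1] - 1), 0.4)
  })
})

test_that("the transform reduces skewness of log-normal columns", {
  skew <- function(x) mean((x - mean(x))^3) / sd(x)^3
  withr::with_seed(32, {
    for (i in 1:5) {
      x <- exp(rnorm(300))
      pt <- power_transform_fit(matrix(x, dimnames = list(NULL, "v")))
      z <- power_transform_apply(pt, matrix(x, dimnames = list(NULL, "v")))
      expect_lt(abs(skew(z)), abs(skew(x)))
    }
  })
})

test_that("the Yeo-Johnson formula agrees with the reference implementation", {
  skip_if_not_installed("car")
  withr::with_seed(33, {
    x <- c(rnorm(50), -3, 0, 7)
    for (lam in c(-1, -0.5, 0, 0.5, 1, 1.3, 2)) {
      expect_equal(wearpipe:::yeo_johnson(x, lam),
                   unname(car::yjPower(x, lam)), tolerance = 1e-8)
    }
  })
})

test_that("constant columns pass through flagged; mismatches are fatal", {
  X <- cbind(a = c(1, 1, 1, 1), b = c(1, 2, 3, 4))
  pt <- power_transform_fit(X)
  expect_true(pt$zero_variance[pt$column == "a"])
  Z <- power_transform_apply(pt, X)
  expect_equal(Z[, "a"], X[, "a"], ignore_attr = TRUE)
  expect_error(power_transform_apply(pt, X[, c("b", "a")]),
               "column mismatch")
  expect_equal(nrow(power_transform_apply(pt, X[0, , drop = FALSE])), 0)
  expect_error(power_transform_fit(X[1, , drop = FALSE]), ">= 2")
})

test_that("transform application is deterministic and train-only", {
  withr::with_seed(34, {
    Xtr <- matrix(rnorm(100), 25, dimnames = list(NULL, letters[1:4]))
    Xte <- matrix(rnorm(40), 10, dimnames = list(NULL, letters[1:4]))
    pt <- power_transform_fit(Xtr)
    expect_identical(power_transform_apply(pt, Xte),
                     power_transform_apply(pt, Xte))
    # parameters ignore anything outside the training rows
    expect_identical(pt, power_transform_fit(Xtr))
  })
})

test_that("elastic-net fit has finite separating coefficients on a toy problem", {
  X <- cbind(x1 = c(-2, -1.5, -1, 1, 1.5, 2), x2 = c(0.1, -0.2, 0, 0.1, -0.1, 0.2))
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- fit_elastic_logistic(X, y, strength = 1)
  expect_true(all(is.finite(fit$coefficients)))
  expect_gt(fit$coefficients["x1"], 0)
  sc <- predict(fit, X)
  expect_gt(auroc(sc, y), 0.99)
  expect_error(fit_elastic_logistic(X, rep(1, 6)), "both classes")
})

test_that("out-of-sample AUROC is null when labels are independent of features", {
  withr::with_seed(35, {
    n <- 200
    X <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("f", 1:5)))
    y <- rbinom(n, 1, 0.5)
    tr <- seq_len(n) <= n / 2
    fit <- fit_elastic_logistic(X[tr, ], y[tr], strength = 1)
    a <- auroc(predict(fit, X[!tr, ]), y[!tr])
    expect_gt(a, 0.4)
    expect_lt(a, 0.6)
  })
})

test_that("duplicating every row leaves the fit unchanged under a pinned penalty", {
  withr::with_seed(36, {
    X <- matrix(rnorm(60), 20, dimnames = list(NULL, paste0("f", 1:3)))
    y <- rbinom(20, 1, 0.5); y[1:3] <- 0; y[4:6] <- 1
    lam <- 0.05 # average-loss convention: penalty independent of n
    f1 <- fit_elastic_logistic(X, y, lambda = lam)
    f2 <- fit_elastic_logistic(rbind(X, X), c(y, y), lambda = lam)
    expect_equal(f2$coefficients, f1$coefficients, tolerance = 1e-6)
    expect_equal(f2$intercept, f1$intercept, tolerance = 1e-6)
  })
})

test_that("AUROC matches its stated examples and the pairwise oracle", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(c(0.1, 0.2, 0.3, 0.4), c(0, 1, 0, 1)), 0.75)
  expect_equal(auroc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
  withr::with_seed(37, {
    for (i in 1:50) {
      s <- random_score_set()
      expect_equal(auroc(s$scores, s$labels),
                   brute_auroc(s$scores, s$labels))
    }
  })
})

test_that("average precision matches its stated examples and the sweep oracle", {
  expect_equal(average_precision(c(0.9, 0.1), c(1, 0)), 1)
  expect_equal(average_precision(c(0.9, 0.8, 0.7), c(1, 0, 1)),
               0.5 * 1 + 0.5 * (2 / 3))
  expect_equal(average_precision(c(0.3, 0.6), c(1, 1)), 1)
  expect_error(average_precision(1:3, c(0, 0, 0)), "no positives")
  withr::with_seed(38, {
    for (i in 1:50) {
      s <- random_score_set()
      expect_equal(average_precision(s$scores, s$labels),
                   brute_ap(s$scores, s$labels))
    }
  })
})

test_that("repeated CV pools one score per user per repeat and is deterministic", {
  uf <- small_user_features()
  params <- pipeline_params(cv_repeats = 3, rng_seed = 5)
  cv <- cross_validate(uf, params = params)
  expect_equal(nrow(cv$metrics), 3)
  expect_true(all(cv$metrics$auroc >= 0 & cv$metrics$auroc <= 1))
  expect_true(all(cv$metrics$average_precision >= 0 &
                    cv$metrics$average_precision <= 1))
  per_rep <- table(cv$scores$repeat_id)
  expect_true(all(per_rep == nrow(uf)))
  # each user in exactly one test fold per repeat
  dup <- cv$scores |> dplyr::count(.data$repeat_id, .data$user_id)
  expect_true(all(dup$n == 1))
  cv2 <- cross_validate(uf, params = params)
  expect_identical(cv$metrics, cv2$metrics)
  expect_identical(cv$coefficients, cv2$coefficients)
  # different master seed gives different splits
  cv3 <- cross_validate(uf, params = params, seed = 99)
  expect_false(identical(cv$folds, cv3$folds))
})

test_that("tidy, glance and autoplot expose the CV results", {
  uf <- small_user_features()
  cv <- cross_validate(uf, params = pipeline_params(cv_repeats = 2))
  expect_named(tidy(cv), c("repeat_id", "auroc", "average_precision"))
  g <- glance(cv)
  expect_equal(g$n_repeats, 2)
  expect_equal(g$n_users, nrow(uf))
  expect_s3_class(autoplot(cv), "ggplot")
})

test_that("an informative error reports folds that cannot be trained", {
  uf <- small_user_features()[1:5, ] # 5 users in 5 folds: singleton training classes
  expect_error(cross_validate(uf, params = pipeline_params(cv_repeats = 1)),
               "fewer than 2 users")
})
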