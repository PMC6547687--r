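test_that("preprocessing drops constants, flags skew, and z-scores", {
  set.seed(12)
  X <- cbind(normal = rnorm(200),
             skewed = rexp(200),
             constant = rep(2, 200))
  Z <- preprocess_features(X)
  expect_equal(attr(Z, "dropped"), "constant")
  expect_equal(colnames(Z), c("normal", "skewed"))
  expect_equal(unname(colMeans(Z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(Z, 2, sd)), c(1, 1), tolerance = 1e-12)
  # auto-detection: exponential flagged, normal not
  expect_equal(unname(attr(Z, "skewed")), c(FALSE, TRUE))
  # log transform reduces sample skewness of the skewed feature
  expect_lt(abs(e1071::skewness(Z[, "skewed"])),
            abs(e1071::skewness(X[, "skewed"])))
  # an already-normal unflagged feature is only centered/scaled
  expect_equal(unname(Z[, "normal"]),
               unname(as.numeric(scale(X[, "normal"]))))
})

test_that("explicit skew flags override auto-detection and bad input errors", {
  set.seed(13)
  X <- cbind(a = rexp(100), b = rnorm(100))
  Z <- preprocess_features(X, skewed = c(a = FALSE, b = FALSE))
  expect_false(any(attr(Z, "skewed")))
  X[5, 1] <- NA
  expect_error(preprocess_features(X), class = "starr_bad_input")
})

test_that("noiseless single-feature response is recovered exactly", {
  set.seed(19)
  X <- matrix(rnorm(100 * 10), 100, 10,
              dimnames = list(NULL, sprintf("f%02d", 1:10)))
  y <- 2 * X[, 1]
  fit <- fit_lasso_cv(X, y, seed = 1L, nested = FALSE)
  expect_equal(unname(fit$coefficients["f01"]), 2, tolerance = 0.005)
  expect_true(all(abs(fit$coefficients[-1]) < 0.01))
  top <- top_coefficients(fit, k = 1)
  expect_equal(top$feature, "f01")
})

test_that("pure-noise response selects an (almost) empty model", {
  set.seed(20)
  X <- matrix(rnorm(300 * 20), 300, 20,
              dimnames = list(NULL, sprintf("f%02d", 1:20)))
  y <- rnorm(300)
  fit <- fit_lasso_cv(X, y, seed = 2L, nested = FALSE)
  expect_lte(fit$n_nonzero, 3L)
  expect_lt(abs(fit$rho), 0.3)
})

test_that("causal features are recovered with correct signs", {
  fs <- simulate_features(n_regions = 500, n_features = 100, n_causal = 5,
                          noise_sd = 1, seed = 7L)
  Z <- preprocess_features(fs$X, skewed = fs$skewed)
  fit <- fit_lasso_cv(Z, fs$y, seed = 7L, nested = FALSE)
  causal <- names(fs$beta)[fs$beta != 0]
  expect_true(all(fit$coefficients[causal] != 0))
  expect_equal(sign(fit$coefficients[causal]), sign(fs$beta[fs$beta != 0]))
  expect_gt(fit$rho, 0.4)
})

test_that("fold bookkeeping prevents leakage into out-of-fold predictions", {
  fs <- simulate_features(n_regions = 120, n_features = 10, n_causal = 2,
                          noise_sd = 0.5, seed = 9L)
  Z <- preprocess_features(fs$X, skewed = fs$skewed)
  fit <- fit_lasso_cv(Z, fs$y, n_folds = 5L, seed = 3L, nested = TRUE)
  expect_false(anyNA(fit$oof_pred))
  expect_equal(sort(unique(fit$foldid)), 1:5)
  # perturbing a fold's responses must not move that fold's predictions
  y2 <- fs$y
  f1 <- fit$foldid == 1L
  y2[f1] <- y2[f1] + 100
  fit2 <- fit_lasso_cv(Z, y2, n_folds = 5L, seed = 3L, nested = TRUE)
  expect_equal(fit$oof_pred[f1], fit2$oof_pred[f1])
})

test_that("fits are invariant to feature column order", {
  fs <- simulate_features(n_regions = 150, n_features = 12, n_causal = 3,
                          noise_sd = 0.5, seed = 11L)
  Z <- preprocess_features(fs$X, skewed = fs$skewed)
  perm <- sample(ncol(Z))
  fit1 <- fit_lasso_cv(Z, fs$y, seed = 4L, nested = FALSE)
  fit2 <- fit_lasso_cv(Z[, perm], fs$y, seed = 4L, nested = FALSE)
  expect_equal(fit1$coefficients[sort(names(fit1$coefficients))],
               fit2$coefficients[sort(names(fit2$coefficients))],
               tolerance = 1e-3)
})

test_that("heavier penalties never add coefficients along the path", {
  fs <- simulate_features(n_regions = 200, n_features = 15, n_causal = 4,
                          noise_sd = 0.5, skew_frac = 0, seed = 13L)
  fit <- glmnet::glmnet(fs$X, fs$y, alpha = 1)
  nnz <- fit$df                      # nonzero count along decreasing lambda
  expect_true(all(diff(nnz) >= 0))
})

test_that("Spearman evaluation handles perfect, reversed, and null cases", {
  y <- c(3, 1, 4, 1.5, 5, 9, 2.6)
  expect_equal(evaluate_predictions(y, y), 1)
  expect_equal(evaluate_predictions(-y, y), -1)
  expect_error(evaluate_predictions(y, y[-1]), class = "starr_bad_input")
  set.seed(25)
  expect_lt(abs(evaluate_predictions(rnorm(100), rnorm(100))), 0.25)
})

test_that("top_coefficients ranks by magnitude with name tie-break", {
  fit <- structure(list(coefficients = c(b = -0.5, a = 0.5, c = 2, d = 0,
                                         e = -3)),
                   class = "lasso_fit")
  top <- top_coefficients(fit, k = 30)
  expect_equal(top$feature, c("e", "c", "a", "b"))   # d excluded (zero)
  expect_equal(top$coefficient[1], -3)               # sign retained
  expect_equal(nrow(top_coefficients(fit, k = 2)), 2L)
  expect_equal(nrow(top_coefficients(fit, k = 0)), 0L)
})
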