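#' Preprocess a feature matrix for penalized regression
#'
#' Right-skewed features (ChIP-seq-like signal) are log-transformed with
#' \code{log1p}, then every feature is z-score normalized so coefficient
#' magnitudes are directly comparable. Skewed features are either flagged
#' explicitly or auto-detected by sample skewness above
#' \code{skew_threshold}. Zero-variance features are dropped and recorded.
#'
#' @param X Numeric matrix (regions x features) with column names.
#' @param skewed Logical vector (by position or name) flagging skewed
#'   features; \code{NULL} enables skewness-based auto-detection.
#' @param skew_threshold Sample-skewness cutoff for auto-detection.
#' @return Normalized matrix with attributes \code{skewed} (flags used)
#'   and \code{dropped} (names of removed constant features).
#' @export
preprocess_features <- function(X, skewed = NULL, skew_threshold = 1) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) {
    bad <- colnames(X)[apply(!is.finite(X), 2, any)]
    stop_starr("starr_bad_input",
               paste("non-finite values in feature(s):",
                     paste(bad, collapse = ", ")))
  }
  if (is.null(skewed)) {
    skewed <- apply(X, 2, e1071::skewness) > skew_threshold
    skewed[is.na(skewed)] <- FALSE
  } else if (!is.null(names(skewed))) {
    skewed <- skewed[colnames(X)]
    skewed[is.na(skewed)] <- FALSE
  }
  X[, skewed] <- log1p(X[, skewed, drop = FALSE])
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0]
  keep <- sds > 0
  out <- scale(X[, keep, drop = FALSE])
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "skewed") <- skewed[keep]
  attr(out, "dropped") <- dropped
  out
}

#' Cross-validated lasso model of enhancer activity
#'
#' Fits an L1-penalized linear model of activity on the normalized feature
#' matrix. The penalty strength lambda is chosen by 10-fold
#' cross-validation minimizing mean squared error (the 1-SE rule is
#' available via \code{rule = "1se"}). Out-of-fold predictions are produced
#' for every region: with \code{nested = TRUE} (default) lambda is re-tuned
#' inside each training fold so held-out predictions never see their own
#' fold, with \code{nested = FALSE} the single-level pre-validated
#' predictions at the selected lambda are used. The reported model is
#' refit on the full data at the selected lambda.
#'
#' @param X Normalized matrix from \code{\link{preprocess_features}}.
#' @param y Numeric activity vector aligned with rows of X.
#' @param n_folds Number of CV folds (default 10).
#' @param seed Integer seed controlling fold assignment.
#' @param nested Logical; tune lambda inside each training fold.
#' @param rule Lambda selection rule, \code{"min"} or \code{"1se"}.
#' @return Object of class \code{lasso_fit}: list with lambda,
#'   lambda_grid, intercept, coefficients (named, full-data refit),
#'   oof_pred, foldid, rho (out-of-fold Spearman), n_nonzero.
#' @export
fit_lasso_cv <- function(X, y, n_folds = 10L, seed = 1L, nested = TRUE,
                         rule = c("min", "1se")) {
  rule <- match.arg(rule)
  if (nrow(X) != length(y))
    stop_starr("starr_bad_input", "rows of X must align with y")
  if (stats::sd(y) == 0)
    stop_starr("starr_bad_input", "y has zero variance")
  if (nrow(X) < n_folds)
    stop_starr("starr_bad_input", "need at least n_folds rows")
  set.seed(seed)
  foldid <- sample(rep(seq_len(n_folds), length.out = nrow(X)))
  pick <- function(cvfit) if (rule == "min") cvfit$lambda.min else cvfit$lambda.1se

  # explicit log-spaced grid down to a near-zero penalty; glmnet's default
  # path stops early once the deviance plateaus, which would keep a
  # noiseless fit away from the ordinary-least-squares limit
  l_max <- glmnet::glmnet(X, y, alpha = 1, nlambda = 5)$lambda[1]
  grid <- exp(seq(log(l_max), log(l_max * 1e-6), length.out = 100))
  cv_full <- glmnet::cv.glmnet(X, y, alpha = 1, foldid = foldid,
                               lambda = grid, keep = !nested)
  lambda <- pick(cv_full)
  oof <- rep(NA_real_, length(y))
  if (nested) {
    for (f in seq_len(n_folds)) {
      tr <- foldid != f
      # the inner grid must derive from the training fold only, or the
      # held-out responses would leak into lambda selection
      inner <- glmnet::cv.glmnet(X[tr, , drop = FALSE], y[tr],
                                 alpha = 1, nfolds = n_folds,
                                 lambda.min.ratio = 1e-6)
      oof[!tr] <- as.numeric(stats::predict(
        inner, newx = X[!tr, , drop = FALSE], s = pick(inner)))
    }
  } else {
    oof <- cv_full$fit.preval[, match(lambda, cv_full$lambda)]
  }
  cf <- as.matrix(stats::coef(cv_full, s = lambda))
  fit <- list(lambda = lambda,
              lambda_grid = cv_full$lambda,
              intercept = cf[1, 1],
              coefficients = stats::setNames(cf[-1, 1], rownames(cf)[-1]),
              oof_pred = oof,
              foldid = foldid,
              rho = evaluate_predictions(oof, y),
              n_nonzero = sum(cf[-1, 1] != 0),
              cv = cv_full)
  class(fit) <- "lasso_fit"
  fit
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("lasso enhancer-activity model: lambda = %.4g, %d nonzero coefficients, out-of-fold Spearman rho = %.3f\n",
              x$lambda, x$n_nonzero, x$rho))
  invisible(x)
}

#' Spearman evaluation of out-of-fold predictions
#'
#' @param pred,obs Aligned numeric vectors.
#' @return Spearman rank correlation (mid-rank ties).
#' @export
evaluate_predictions <- function(pred, obs) {
  if (length(pred) != length(obs))
    stop_starr("starr_bad_input", "prediction/observation length mismatch")
  stats::cor(pred, obs, method = "spearman")
}

#' Top model coefficients by magnitude
#'
#' @param fit A \code{lasso_fit}.
#' @param k Number of features to report (default 30). When fewer than k
#'   coefficients are nonzero, all nonzero ones are returned.
#' @return data.frame feature, coefficient, ordered by decreasing
#'   magnitude (ties broken by feature name); signs retained.
#' @export
top_coefficients <- function(fit, k = 30L) {
  cf <- fit$coefficients[fit$coefficients != 0]
  if (k <= 0 || length(cf) == 0)
    return(data.frame(feature = character(0), coefficient = numeric(0)))
  ord <- order(-abs(cf), names(cf))
  cf <- cf[ord][seq_len(min(k, length(cf)))]
  data.frame(feature = names(cf), coefficient = unname(cf),
             stringsAsFactors = FALSE)
}
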