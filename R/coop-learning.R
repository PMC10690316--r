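#' Augmented design matrix realizing the agreement penalty
#'
#' Cooperative learning fits all views jointly while penalizing
#' disagreement between their per-view predictions. For views
#' \eqn{X_1, \dots, X_M} and centered response \eqn{y - \bar y}, minimizing
#' \deqn{\tfrac12\|y - \textstyle\sum_m X_m\beta_m\|^2 +
#'       \tfrac{\rho}{2}\sum_{m<m'}\|X_m\beta_m - X_{m'}\beta_{m'}\|^2 +
#'       \lambda P(\beta)}
#' is exactly an (elastic-net) least-squares problem on an augmented
#' system: the stacked views on top, plus one \eqn{\pm\sqrt{\rho}} contrast
#' block per unordered view pair with response 0. \eqn{\rho = 0} recovers
#' early fusion (simple feature concatenation); large \eqn{\rho} forces the
#' per-view predictions to agree, approaching late-fusion behavior.
#'
#' @param views List of row-aligned numeric matrices (one per view).
#' @param y Numeric response (centered internally for the top block).
#' @param rho Non-negative agreement weight.
#' @return List with `x` (augmented matrix), `y` (augmented response),
#'   `blocks` (column index ranges per view) and `n` (original sample
#'   count).
#' @export
build_augmented_design <- function(views, y, rho = 0) {
  views <- view_matrices(views)
  if (rho < 0) stop("rho must be non-negative", call. = FALSE)
  n <- unique(vapply(views, nrow, integer(1L)))
  if (length(n) != 1L) stop("views have mismatched row counts", call. = FALSE)
  if (length(y) != n) stop("response length does not match views", call. = FALSE)
  M <- length(views)
  ps <- vapply(views, ncol, integer(1L))
  ends <- cumsum(ps)
  blocks <- Map(function(s, e) s:e, c(1L, utils::head(ends, -1L) + 1L), ends)
  Xtop <- do.call(cbind, views)
  pairs <- if (M >= 2L) utils::combn(M, 2L) else matrix(integer(0), 2L, 0L)
  aug <- matrix(0, n * ncol(pairs), sum(ps))
  sr <- sqrt(rho)
  if (ncol(pairs) > 0L) {
    for (cidx in seq_len(ncol(pairs))) {
      rows <- ((cidx - 1L) * n + 1L):(cidx * n)
      aug[rows, blocks[[pairs[1L, cidx]]]] <- -sr * views[[pairs[1L, cidx]]]
      aug[rows, blocks[[pairs[2L, cidx]]]] <- sr * views[[pairs[2L, cidx]]]
    }
  }
  list(x = rbind(Xtop, aug), y = c(y - mean(y), rep(0, nrow(aug))),
       blocks = blocks, n = n)
}

coop_lambda_max <- function(X, y, family, n, alpha) {
  a <- max(alpha, 0.05)
  if (family == "binomial") {
    p0 <- mean(y)
    max(abs(crossprod(X, y - p0))) / (n * a)
  } else {
    max(abs(crossprod(X, y - mean(y)))) / (n * a)
  }
}

default_lambda_path <- function(lambda_max, nlambda = 50L, min_ratio = 1e-3) {
  # tiny headroom so the first path point zeroes every coefficient strictly
  lambda_max <- lambda_max * (1 + 1e-6)
  exp(seq(log(lambda_max), log(lambda_max * min_ratio), length.out = nlambda))
}

#' Fit a cooperative-learning model
#'
#' Multi-view elastic-net regression with an agreement penalty of weight
#' `rho` (see [build_augmented_design()] for the objective). Gaussian
#' responses are fit by coordinate descent on the augmented least-squares
#' system over a decreasing \eqn{\lambda} path with warm starts and
#' active-set cycling. Binomial responses are fit by penalized iteratively
#' reweighted least squares in which every weighted working-response
#' problem carries the same augmentation, so the agreement penalty acts on
#' the per-view linear predictors. The penalty is
#' \eqn{\lambda\sum_j(\alpha|\beta_j| + \tfrac{1-\alpha}{2}\beta_j^2)}
#' with loss scaled by \eqn{1/n} (glmnet convention); the intercept is
#' unpenalized.
#'
#' Views are expected to be standardized (see [standardize()]); no
#' internal standardization is performed.
#'
#' @param views List of standardized row-aligned matrices, or a
#'   `multiview_dataset`.
#' @param y Response: numeric (gaussian) or 0/1 (binomial).
#' @param rho Agreement-penalty weight \eqn{\ge 0}.
#' @param alpha Elastic-net mix in \eqn{[0,1]} (1 = lasso, 0 = ridge).
#' @param lambda Optional decreasing \eqn{\lambda} path; computed from the
#'   data when `NULL` (50 values, log-spaced down to `1e-3` of
#'   \eqn{\lambda_{max}}).
#' @param family `"gaussian"` or `"binomial"`.
#' @param nlambda,lambda_min_ratio Path construction controls.
#' @param tol Coordinate-descent convergence tolerance.
#' @param max_sweeps Maximum coordinate-descent sweeps per \eqn{\lambda}.
#' @return Object of class `coop_model`: coefficient matrix `beta`
#'   (features x lambdas), `intercept` per lambda, per-view `blocks`,
#'   the `lambda` path, `rho`, `alpha` and `family`.
#' @export
fit_coop <- function(views, y, rho = 0, alpha = 1, lambda = NULL,
                     family = c("gaussian", "binomial"),
                     nlambda = 50L, lambda_min_ratio = 1e-3,
                     tol = 1e-7, max_sweeps = 2000L) {
  family <- match.arg(family)
  views <- view_matrices(views)
  y <- as.numeric(y)
  if (family == "binomial" && !all(y %in% c(0, 1)))
    stop("binomial family requires a 0/1 response", call. = FALSE)
  ad <- build_augmented_design(views, y, rho)
  n <- ad$n
  if (rho == 0 && nrow(ad$x) > n) {      # all-zero contrast rows: drop them
    ad$x <- ad$x[seq_len(n), , drop = FALSE]
    ad$y <- ad$y[seq_len(n)]
  }
  p <- ncol(ad$x)
  if (is.null(lambda)) {
    lmax <- coop_lambda_max(do.call(cbind, views), y, family, n, alpha)
    lambda <- default_lambda_path(lmax, nlambda, lambda_min_ratio)
  }
  lambda <- sort(as.numeric(lambda), decreasing = TRUE)
  if (length(lambda) == 0L) stop("empty lambda path", call. = FALSE)
  pf <- rep(1, p)

  if (family == "gaussian") {
    w <- rep(1, nrow(ad$x))
    B <- .cd_enet_path(ad$x, ad$y, w, lambda, alpha, pf, n, rep(0, p),
                       tol, as.integer(max_sweeps))
    intercept <- rep(mean(y), length(lambda))
  } else {
    # explicit unpenalized intercept column: 1 on loss rows, 0 on
    # augmentation rows (the agreement penalty ignores the intercept)
    Xa <- cbind(c(rep(1, n), rep(0, nrow(ad$x) - n)), ad$x)
    pfa <- c(0, pf)
    coefs <- .coop_binom_path(Xa, y, lambda, alpha, pfa, n,
                              tol, as.integer(max_sweeps),
                              irls_tol = max(tol, 1e-8), irls_max = 25L)
    intercept <- coefs[1L, ]
    B <- coefs[-1L, , drop = FALSE]
  }
  feature_names <- unlist(lapply(seq_along(views), function(m) {
    cn <- colnames(views[[m]])
    if (is.null(cn)) cn <- paste0("f", seq_len(ncol(views[[m]])))
    nm <- names(views)[m]
    if (is.null(nm) || nm == "") nm <- paste0("view", m)
    paste(nm, cn, sep = ":")
  }))
  rownames(B) <- feature_names
  structure(list(beta = B, intercept = intercept, blocks = ad$blocks,
                 lambda = lambda, rho = rho, alpha = alpha, family = family,
                 view_dims = vapply(views, ncol, integer(1L)),
                 view_names = names(views)),
            class = "coop_model")
}

#' @export
print.coop_model <- function(x, ...) {
  cat(sprintf("<coop_model: %s, %d views, rho=%.3g, alpha=%.2f, %d lambdas>\n",
              x$family, length(x$blocks), x$rho, x$alpha, length(x$lambda)))
  invisible(x)
}

lambda_index <- function(model, lambda) {
  if (is.null(lambda)) return(length(model$lambda))
  which.min(abs(model$lambda - lambda))
}

#' Predict from a cooperative-learning model
#'
#' @param object A `coop_model`.
#' @param views List of matrices (or `multiview_dataset`) with feature
#'   counts matching the training views.
#' @param lambda Value on the fitted path (nearest used); default the
#'   smallest (densest) path point.
#' @param type `"response"` (probability scale for binomial) or `"link"`.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.coop_model <- function(object, views, lambda = NULL,
                               type = c("response", "link"), ...) {
  type <- match.arg(type)
  views <- view_matrices(views)
  if (!identical(unname(vapply(views, ncol, integer(1L))), unname(object$view_dims)))
    stop("view feature counts do not match the fitted model", call. = FALSE)
  l <- lambda_index(object, lambda)
  eta <- object$intercept[l] + drop(do.call(cbind, views) %*% object$beta[, l])
  if (object$family == "binomial" && type == "response") logistic(eta) else eta
}

#' Extract per-view coefficient blocks
#'
#' @param object A `coop_model`.
#' @param lambda Path value (nearest used).
#' @param ... Unused.
#' @return Named list of per-view coefficient vectors.
#' @export
coef.coop_model <- function(object, lambda = NULL, ...) {
  l <- lambda_index(object, lambda)
  out <- lapply(object$blocks, function(b) object$beta[b, l])
  names(out) <- object$view_names
  out
}

#' Evaluate the cooperative-learning objective
#'
#' Computes loss + agreement penalty + elastic-net penalty at given
#' coefficients: for gaussian,
#' \eqn{\frac{1}{2n}\|y-\bar y-\sum X_m\beta_m\|^2}; for binomial, the mean
#' negative log-likelihood \eqn{-\frac{1}{n}\ell(\beta)}; plus
#' \eqn{\frac{\rho}{2n}\sum_{m<m'}\|X_m\beta_m - X_{m'}\beta_{m'}\|^2 +
#' \lambda\sum_j(\alpha|\beta_j| + \frac{1-\alpha}{2}\beta_j^2)}.
#'
#' Exposed mainly so solutions can be compared against independent convex
#' solvers.
#'
#' @param views List of matrices.
#' @param y Response.
#' @param beta Concatenated coefficient vector (all views stacked).
#' @param intercept Intercept value.
#' @param rho,alpha,lambda Objective parameters.
#' @param family `"gaussian"` or `"binomial"`.
#' @return The objective value (a scalar).
#' @export
coop_objective <- function(views, y, beta, intercept = NULL, rho = 0,
                           alpha = 1, lambda = 0,
                           family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  views <- view_matrices(views)
  n <- nrow(views[[1L]])
  ps <- vapply(views, ncol, integer(1L))
  ends <- cumsum(ps)
  blocks <- Map(function(s, e) s:e, c(1L, utils::head(ends, -1L) + 1L), ends)
  etas <- Map(function(X, b) drop(X %*% beta[b]), views, blocks)
  eta <- Reduce(`+`, etas)
  if (family == "gaussian") {
    if (is.null(intercept)) intercept <- mean(y)
    loss <- sum((y - intercept - eta)^2) / (2 * n)
  } else {
    if (is.null(intercept)) stop("intercept required for binomial objective", call. = FALSE)
    mu <- logistic(intercept + eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    loss <- -mean(y * log(mu) + (1 - y) * log(1 - mu))
  }
  agree <- 0
  M <- length(views)
  if (M >= 2L) {
    pairs <- utils::combn(M, 2L)
    for (cidx in seq_len(ncol(pairs)))
      agree <- agree + sum((etas[[pairs[1L, cidx]]] - etas[[pairs[2L, cidx]]])^2)
  }
  pen <- lambda * sum(alpha * abs(beta) + (1 - alpha) / 2 * beta^2)
  loss + rho / (2 * n) * agree + pen
}

#' Mean binomial deviance
#'
#' \eqn{-\frac{2}{n}\sum_i [y_i\log\hat p_i + (1-y_i)\log(1-\hat p_i)]},
#' the tuning loss used throughout the cross-validation machinery.
#'
#' @param y 0/1 outcomes.
#' @param prob Predicted probabilities.
#' @return Scalar mean deviance.
#' @export
binomial_deviance <- function(y, prob) {
  prob <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  -2 * mean(y * log(prob) + (1 - y) * log(1 - prob))
}

#' Late-fusion ensemble of single-view elastic nets
#'
#' Fits one elastic-net model per view (with \eqn{\lambda} tuned by k-fold
#' cross-validation at minimum deviance/MSE) and predicts with the average
#' of the per-view predictions: the late-fusion endpoint of the
#' cooperative-learning continuum, and the source of unimodal baselines.
#'
#' @param views List of standardized matrices or `multiview_dataset`.
#' @param y Response.
#' @param alpha Elastic-net mix for every view model.
#' @param family `"gaussian"` or `"binomial"`.
#' @param nfolds CV folds for the per-view \eqn{\lambda}.
#' @param seed Seed for the CV splits.
#' @return Object of class `coop_ensemble`; `predict()` returns the
#'   averaged per-view predictions (response scale).
#' @export
fit_late_fusion <- function(views, y, alpha = 1,
                            family = c("gaussian", "binomial"),
                            nfolds = 5L, seed = 1L) {
  family <- match.arg(family)
  views <- view_matrices(views)
  models <- vector("list", length(views))
  chosen <- numeric(length(views))
  for (m in seq_along(views)) {
    fit <- fit_coop(views[m], y, rho = 0, alpha = alpha, family = family)
    # one shared fold split for every view: identical views then get
    # identical tuning, and the late-fusion comparison is apples-to-apples
    folds <- if (family == "binomial")
      stratified_folds(y, nfolds, seed = derive_seed(seed, "latefuse"))
    else with_seed(derive_seed(seed, "latefuse"),
                   sample(rep_len(seq_len(nfolds), length(y))))
    dev <- matrix(NA_real_, nfolds, length(fit$lambda))
    for (f in seq_len(nfolds)) {
      tr <- folds != f
      cvfit <- fit_coop(list(views[[m]][tr, , drop = FALSE]), y[tr], rho = 0,
                        alpha = alpha, lambda = fit$lambda, family = family)
      for (l in seq_along(fit$lambda)) {
        pr <- predict(cvfit, list(views[[m]][!tr, , drop = FALSE]),
                      lambda = fit$lambda[l])
        dev[f, l] <- if (family == "binomial") binomial_deviance(y[!tr], pr)
                     else mean((y[!tr] - pr)^2)
      }
    }
    chosen[m] <- fit$lambda[which.min(colMeans(dev))]
    models[[m]] <- fit
  }
  structure(list(models = models, lambda = chosen, family = family,
                 view_names = names(views)),
            class = "coop_ensemble")
}

#' @export
predict.coop_ensemble <- function(object, views, ...) {
  views <- view_matrices(views)
  preds <- vapply(seq_along(object$models), function(m)
    predict(object$models[[m]], views[m], lambda = object$lambda[m]),
    numeric(nrow(views[[1L]])))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1L)
  rowMeans(preds)
}
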