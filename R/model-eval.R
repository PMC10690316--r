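#' Stratified fold assignment for a binary outcome
#'
#' Shuffles each class independently and deals samples round-robin over
#' `k` folds, so every fold's positive count differs from the ideal
#' proportional count by at most one. Deterministic given `seed`.
#'
#' @param y 0/1 outcome vector.
#' @param k Number of folds (at most the minority-class count).
#' @param seed Integer seed.
#' @return Integer vector of fold labels in `1:k`, aligned with `y`.
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L)) || length(unique(y)) < 2L)
    stop("y must contain both 0 and 1", call. = FALSE)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (k > min(table(y))) stop("k exceeds the minority-class count", call. = FALSE)
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(sample.int(k), length(idx))
    }
  })
  folds
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, with half credit for ties; identical to the
#' trapezoidal area under the ROC curve.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param y 0/1 labels.
#' @return AUC in \eqn{[0, 1]}.
#' @export
auc <- function(scores, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)                      # average ranks give the tie half-credit
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (as.numeric(n1) * n0)
}

#' Nested cross-validation configuration
#'
#' @param outer_folds,inner_folds,repeats Protocol sizes: the outer loop
#'   estimates generalization performance, the inner loop tunes
#'   `(alpha, rho)` by minimum mean deviance, and the whole nested
#'   procedure is repeated with fresh splits.
#' @param alpha_grid,rho_grid Hyperparameter candidates.
#' @param seed Master seed from which all split seeds are derived.
#' @return A `cv_config` list.
#' @export
cv_config <- function(outer_folds = 5L, inner_folds = 10L, repeats = 30L,
                      alpha_grid = c(0, 0.2, 0.4, 0.6, 0.8, 1.0),
                      rho_grid = c(0, 0.1, 0.25, 0.5, 1.0),
                      seed = 1L) {
  stopifnot(outer_folds >= 2L, inner_folds >= 2L, repeats >= 1L,
            length(alpha_grid) >= 1L, length(rho_grid) >= 1L)
  structure(list(outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 repeats = as.integer(repeats),
                 alpha_grid = alpha_grid, rho_grid = rho_grid,
                 loss = "deviance", seed = as.integer(seed)),
            class = "cv_config")
}

# inner-CV score for one (alpha, rho): minimum over the lambda path of the
# mean validation deviance; returns the best lambda too. Solver tolerance
# is relaxed relative to final fits: deviance ranking does not need
# 1e-7 coefficients.
inner_cv_score <- function(views, y, alpha, rho, inner_folds, seed,
                           cd_tol = 1e-5) {
  ref <- fit_coop(views, y, rho = rho, alpha = alpha, family = "binomial",
                  tol = cd_tol)
  folds <- stratified_folds(y, inner_folds, seed = seed)
  dev <- matrix(NA_real_, inner_folds, length(ref$lambda))
  for (f in seq_len(inner_folds)) {
    tr <- folds != f
    tr_views <- lapply(views, function(X) X[tr, , drop = FALSE])
    va_views <- lapply(views, function(X) X[!tr, , drop = FALSE])
    fit <- fit_coop(tr_views, y[tr], rho = rho, alpha = alpha,
                    lambda = ref$lambda, family = "binomial", tol = cd_tol)
    Xva <- do.call(cbind, va_views)
    etas <- sweep(Xva %*% fit$beta, 2L, fit$intercept, "+")
    probs <- logistic(etas)
    dev[f, ] <- apply(probs, 2L, function(p) binomial_deviance(y[!tr], p))
  }
  mdev <- colMeans(dev)
  list(deviance = min(mdev), lambda = ref$lambda[which.min(mdev)])
}

#' Repeated stratified nested cross-validation for cooperative learning
#'
#' For each repeat: a fresh stratified outer split; within each outer
#' training fold, an inner stratified k-fold grid search over
#' `(alpha, rho)` minimizing mean binomial deviance (with \eqn{\lambda}
#' chosen at the minimum-deviance point of its path); the winning model is
#' refit on the full outer training fold and scored (AUC, accuracy at 0.5)
#' on the outer test fold. Standardization is re-estimated inside each
#' outer training fold and applied to the held-out fold, so no information
#' leaks from test samples into tuning.
#'
#' @param views List of *unstandardized* row-aligned matrices or a
#'   `multiview_dataset`.
#' @param y 0/1 outcome.
#' @param config A [cv_config()].
#' @return Object of class `cv_result` with per-repeat AUC/accuracy
#'   (means over outer folds), overall `mean_auc`, `sd_auc`, `mean_acc`,
#'   `sd_acc`, and the most frequently selected `(alpha, rho)`.
#' @export
nested_cv <- function(views, y, config = cv_config()) {
  views <- view_matrices(views)
  y <- as.integer(y)
  grid <- expand.grid(alpha = config$alpha_grid, rho = config$rho_grid,
                      KEEP.OUT.ATTRS = FALSE)
  per_repeat_auc <- per_repeat_acc <- numeric(config$repeats)
  picks <- list()
  for (r in seq_len(config$repeats)) {
    outer <- stratified_folds(y, config$outer_folds,
                              seed = derive_seed(config$seed, paste0("outer", r)))
    fold_auc <- fold_acc <- numeric(config$outer_folds)
    for (f in seq_len(config$outer_folds)) {
      tr <- outer != f
      raw_tr <- lapply(views, function(X) X[tr, , drop = FALSE])
      raw_te <- lapply(views, function(X) X[!tr, , drop = FALSE])
      # fold-internal standardization
      ctr <- lapply(raw_tr, colMeans)
      scl <- lapply(raw_tr, function(X) apply(X, 2L, stats::sd))
      std <- function(Xs) Map(function(X, m, s) {
        keep <- s > 0
        sweep(sweep(X[, keep, drop = FALSE], 2L, m[keep], "-"), 2L, s[keep], "/")
      }, Xs, ctr, scl)
      tr_views <- std(raw_tr); te_views <- std(raw_te)
      scores <- lapply(seq_len(nrow(grid)), function(gi)
        inner_cv_score(tr_views, y[tr], grid$alpha[gi], grid$rho[gi],
                       config$inner_folds,
                       seed = derive_seed(config$seed, paste0("inner", r, "_", f))))
      best <- which.min(vapply(scores, `[[`, numeric(1L), "deviance"))
      fit <- fit_coop(tr_views, y[tr], rho = grid$rho[best],
                      alpha = grid$alpha[best], family = "binomial")
      pr <- predict(fit, te_views, lambda = scores[[best]]$lambda)
      fold_auc[f] <- auc(pr, y[!tr])
      fold_acc[f] <- mean((pr >= 0.5) == (y[!tr] == 1L))
      picks[[length(picks) + 1L]] <- c(alpha = grid$alpha[best], rho = grid$rho[best])
    }
    per_repeat_auc[r] <- mean(fold_auc)
    per_repeat_acc[r] <- mean(fold_acc)
  }
  pick_tab <- table(vapply(picks, function(p) paste(p, collapse = "/"), character(1L)))
  chosen <- strsplit(names(pick_tab)[which.max(pick_tab)], "/")[[1L]]
  structure(list(per_repeat_auc = per_repeat_auc, per_repeat_acc = per_repeat_acc,
                 mean_auc = mean(per_repeat_auc), sd_auc = stats::sd(per_repeat_auc),
                 mean_acc = mean(per_repeat_acc), sd_acc = stats::sd(per_repeat_acc),
                 chosen_hyperparams = c(alpha = as.numeric(chosen[1L]),
                                        rho = as.numeric(chosen[2L])),
                 config = config),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<nested CV: %d repeats x %d outer folds>\n",
              x$config$repeats, x$config$outer_folds))
  cat(sprintf("  AUC %.3f +/- %.3f; accuracy %.3f +/- %.3f\n",
              x$mean_auc, if (is.na(x$sd_auc)) 0 else x$sd_auc,
              x$mean_acc, if (is.na(x$sd_acc)) 0 else x$sd_acc))
  cat(sprintf("  modal hyperparameters: alpha=%s, rho=%s\n",
              x$chosen_hyperparams["alpha"], x$chosen_hyperparams["rho"]))
  invisible(x)
}

#' Games-Howell pairwise post-hoc comparisons
#'
#' Pairwise comparisons of group means that do not assume equal variances:
#' Welch t-statistics with Welch-Satterthwaite degrees of freedom,
#' referred to the studentized-range distribution (so the p-values are
#' adjusted for all \eqn{k(k-1)/2} comparisons).
#'
#' @param groups List of numeric vectors.
#' @return Data frame with one row per pair: group indices, mean
#'   difference, t statistic, df, adjusted p-value.
#' @export
games_howell <- function(groups) {
  k <- length(groups)
  m <- vapply(groups, mean, numeric(1L))
  v <- vapply(groups, stats::var, numeric(1L))
  n <- vapply(groups, length, numeric(1L))
  pairs <- utils::combn(k, 2L)
  res <- apply(pairs, 2L, function(ij) {
    i <- ij[1L]; j <- ij[2L]
    se2 <- v[i] / n[i] + v[j] / n[j]
    t <- (m[i] - m[j]) / sqrt(se2)
    df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) + (v[j] / n[j])^2 / (n[j] - 1))
    p <- stats::ptukey(abs(t) * sqrt(2), nmeans = k, df = df, lower.tail = FALSE)
    c(i, j, m[i] - m[j], t, df, p)
  })
  out <- as.data.frame(t(res))
  names(out) <- c("group1", "group2", "diff", "t", "df", "p_adj")
  out
}

#' Compare per-repeat performance of several models
#'
#' Variance homogeneity is assessed with Bartlett's test; group means are
#' compared with Welch's ANOVA (which does not assume equal variances),
#' followed by Games-Howell pairwise post-hoc comparisons.
#'
#' @param groups Named list of numeric vectors (e.g. per-repeat AUCs of
#'   competing models), each of length \eqn{\ge 3}.
#' @return List with `bartlett` (statistic, p), `welch` (F, df, p) and
#'   `pairwise` (the [games_howell()] table).
#' @export
compare_models <- function(groups) {
  if (length(groups) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1L)) < 3L))
    stop("each group needs at least 3 values", call. = FALSE)
  if (any(vapply(groups, stats::var, numeric(1L)) == 0))
    warning("a group has zero variance; Bartlett's test is undefined", call. = FALSE)
  vals <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  bt <- tryCatch(stats::bartlett.test(vals, g),
                 error = function(e) list(statistic = NA_real_, p.value = NA_real_))
  wt <- stats::oneway.test(vals ~ g, var.equal = FALSE)
  list(bartlett = c(statistic = unname(bt$statistic), p = unname(bt$p.value)),
       welch = c(F = unname(wt$statistic), df1 = unname(wt$parameter[1L]),
                 df2 = unname(wt$parameter[2L]), p = unname(wt$p.value)),
       pairwise = games_howell(groups))
}
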