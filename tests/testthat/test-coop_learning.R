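test_that("augmented design has the right shape and encodes the objective", {
  set.seed(21)
  views <- list(matrix(rnorm(30), 10, 3), matrix(rnorm(40), 10, 4))
  y <- rnorm(10)
  ad <- build_augmented_design(views, y, rho = 0.5)
  expect_equal(dim(ad$x), c(20L, 7L))
  expect_equal(ad$y[11:20], rep(0, 10))
  expect_equal(ad$y[1:10], y - mean(y))

  # rho = 0: contrast rows vanish
  ad0 <- build_augmented_design(views, y, rho = 0)
  expect_true(all(ad0$x[11:20, ] == 0))

  # algebraic identity: 1/2||y_aug - X_aug b||^2 equals loss + agreement at any b
  b <- rnorm(7)
  lhs <- sum((ad$y - ad$x %*% b)^2) / 2
  eta1 <- views[[1L]] %*% b[1:3]; eta2 <- views[[2L]] %*% b[4:7]
  rhs <- sum((y - mean(y) - eta1 - eta2)^2) / 2 + 0.5 / 2 * sum((eta1 - eta2)^2)
  expect_equal(lhs, rhs, tolerance = 1e-10)

  expect_error(build_augmented_design(list(matrix(0, 5, 2), matrix(0, 6, 2)),
                                      rnorm(5), 1), "mismatched")
})

test_that("rho = 0 equals a concatenated-view elastic net (glmnet oracle)", {
  skip_if_not_installed("glmnet")
  set.seed(2)
  n <- 50
  X1 <- scale(matrix(rnorm(n * 5), n, 5)); X2 <- scale(matrix(rnorm(n * 4), n, 4))
  sdn <- function(x) sqrt(sum((x - mean(x))^2) / length(x))
  y <- rnorm(n); y <- (y - mean(y)) / sdn(y)   # unit-variance response: both
  # solvers then share the same lambda scale exactly
  fit <- fit_coop(list(X1, X2), y, rho = 0, alpha = 0.5, family = "gaussian",
                  tol = 1e-12)
  g <- glmnet::glmnet(cbind(X1, X2), y, alpha = 0.5, lambda = fit$lambda,
                      standardize = FALSE, thresh = 1e-16)
  expect_lt(max(abs(as.matrix(g$beta) - fit$beta)), 1e-6)

  yb <- rbinom(n, 1, plogis(X1[, 1] - X2[, 2]))
  fitb <- fit_coop(list(X1, X2), yb, rho = 0, alpha = 0.5, family = "binomial",
                   tol = 1e-10)
  gb <- glmnet::glmnet(cbind(X1, X2), yb, family = "binomial", alpha = 0.5,
                       lambda = fitb$lambda, standardize = FALSE, thresh = 1e-14)
  expect_lt(max(abs(as.matrix(gb$beta) - fitb$beta)), 1e-4)
  expect_lt(max(abs(gb$a0 - fitb$intercept)), 1e-4)
})

test_that("the solver attains the convex minimum (proximal-gradient oracle)", {
  set.seed(33)
  n <- 20
  views <- list(scale(matrix(rnorm(n * 3), n, 3)), scale(matrix(rnorm(n * 3), n, 3)))
  y <- rnorm(n)
  lam <- 0.05
  fit <- fit_coop(views, y, rho = 0.7, alpha = 1, lambda = lam,
                  family = "gaussian", tol = 1e-12)
  b_fista <- fista_coop(views, y, rho = 0.7, alpha = 1, lambda = lam)
  o_cd <- coop_objective(views, y, fit$beta[, 1L], rho = 0.7, alpha = 1, lambda = lam)
  o_fista <- coop_objective(views, y, b_fista, rho = 0.7, alpha = 1, lambda = lam)
  expect_lt(abs(o_cd - o_fista), 1e-6)
  expect_lte(o_cd, o_fista + 1e-8)
})

test_that("a large agreement penalty aligns duplicated views", {
  set.seed(12)
  n <- 40
  X <- scale(matrix(rnorm(n * 3), n, 3))
  y <- rnorm(n)
  fit <- fit_coop(list(X, X), y, rho = 50, alpha = 0, family = "gaussian",
                  tol = 1e-12)
  cf <- coef(fit)
  expect_lt(max(abs(cf[[1L]] - cf[[2L]])), 1e-3)
})

test_that("agreement disagreement is non-increasing in rho", {
  set.seed(14)
  n <- 60
  views <- list(scale(matrix(rnorm(n * 5), n, 5)), scale(matrix(rnorm(n * 5), n, 5)))
  y <- rnorm(n)
  lam <- 0.02
  dis <- vapply(c(0, 0.1, 0.5, 1, 5), function(r) {
    fit <- fit_coop(views, y, rho = r, alpha = 0.5, lambda = lam,
                    family = "gaussian", tol = 1e-10)
    cf <- coef(fit)
    sum((views[[1L]] %*% cf[[1L]] - views[[2L]] %*% cf[[2L]])^2)
  }, numeric(1L))
  expect_true(all(diff(dis) <= 1e-6))
})

test_that("sparsity is non-increasing in lambda at fixed rho and alpha", {
  set.seed(15)
  n <- 50
  views <- list(scale(matrix(rnorm(n * 8), n, 8)), scale(matrix(rnorm(n * 8), n, 8)))
  y <- rnorm(n)
  fit <- fit_coop(views, y, rho = 0.3, alpha = 1, family = "gaussian")
  nnz <- colSums(fit$beta != 0)       # lambda path is decreasing
  expect_true(all(diff(nnz) >= 0))
})

test_that("predictions are consistent with the fitted model", {
  set.seed(16)
  n <- 30
  views <- list(scale(matrix(rnorm(n * 4), n, 4)), scale(matrix(rnorm(n * 3), n, 3)))
  yb <- rbinom(n, 1, 0.5)
  fit <- fit_coop(views, yb, rho = 0.2, alpha = 0.5, family = "binomial")
  pr <- predict(fit, views)
  expect_true(all(pr > 0 & pr < 1))
  # at lambda_max all coefficients are zero: constant intercept prediction
  pr_max <- predict(fit, views, lambda = fit$lambda[1L], type = "link")
  expect_equal(unname(pr_max), rep(fit$intercept[1L], n))
  expect_equal(sum(fit$beta[, 1L] != 0), 0L)
  # internal consistency at the dense path end
  eta <- fit$intercept[length(fit$lambda)] +
    drop(do.call(cbind, views) %*% fit$beta[, length(fit$lambda)])
  expect_equal(predict(fit, views, type = "link"), eta, tolerance = 1e-8)
  expect_error(predict(fit, list(views[[1L]], views[[2L]][, 1:2])), "feature counts")
})

test_that("late fusion averages per-view models and ranks signal views higher", {
  set.seed(17)
  n <- 120
  S <- rnorm(n)
  X1 <- scale(S + matrix(rnorm(n * 6, sd = 1), n, 6))   # signal view
  X2 <- scale(matrix(rnorm(n * 6), n, 6))               # pure noise view
  yb <- rbinom(n, 1, plogis(2 * S))
  ens1 <- fit_late_fusion(list(X1), yb, family = "binomial", seed = 3L)
  ens_dup <- fit_late_fusion(list(X1, X1), yb, family = "binomial", seed = 3L)
  expect_equal(predict(ens_dup, list(X1, X1)), predict(ens1, list(X1)),
               tolerance = 1e-10)
  ens2 <- fit_late_fusion(list(X2), yb, family = "binomial", seed = 3L)
  expect_gt(auc(predict(ens1, list(X1)), yb), auc(predict(ens2, list(X2)), yb))
})
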