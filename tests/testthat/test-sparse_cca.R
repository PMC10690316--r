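test_that("soft thresholding shrinks, preserves zeros and saturates", {
  expect_equal(soft_threshold(c(2.5, -0.3, 0), 0.5), c(2.0, 0, 0))
  a <- c(-1.2, 0.4, 3, 0)
  expect_equal(soft_threshold(a, 0), a)
  expect_equal(soft_threshold(a, 3), rep(0, 4))
  expect_error(soft_threshold(a, -1), "non-negative")
})

test_that("L1-constrained unit maximizer handles binding and non-binding bounds", {
  expect_equal(l1_constrained_unit_vector(c(3, 0, 0), 1), c(1, 0, 0))
  expect_equal(l1_constrained_unit_vector(c(1, 1), sqrt(2)),
               c(1, 1) / sqrt(2), tolerance = 1e-9)
  expect_error(l1_constrained_unit_vector(c(0, 0), 1), "zero")

  # brute-force grid-search oracle on a binding bound
  a <- c(3, 1, 0.5); c_bound <- 1.2
  w <- l1_constrained_unit_vector(a, c_bound)
  w_star <- l1_unit_gridsearch(a, c_bound)
  expect_lt(max(abs(w - w_star)), 1e-4)
  expect_lte(sum(abs(w)), c_bound + 1e-8)
  expect_equal(sum(w^2), 1, tolerance = 1e-10)
})

test_that("self-correlation of identical views is exactly 1", {
  set.seed(3)
  X <- scale(matrix(rnorm(60), 20, 3))
  fit <- sparse_cca(X, X, 1, 1, K = 1L)
  expect_equal(fit$correlations[1L], 1, tolerance = 1e-8)
})

test_that("non-binding bounds reproduce classical CCA on orthonormal views", {
  set.seed(42)
  devs <- replicate(20, {
    X <- gen_orthonormal_view(30, 4)
    Z <- gen_orthonormal_view(30, 3)
    fit <- sparse_cca(X, Z, 1, 1, K = 1L, tol = 1e-10, max_iter = 200L)
    abs(abs(fit$correlations[1L]) - classical_cca_cor(X, Z))
  })
  expect_lt(max(devs), 1e-6)
})

test_that("planted sparse loadings are recovered", {
  gen <- gen_multiview(multiview_scenario(seed = 1L))
  std <- standardize(gen$dataset)
  fit <- sparse_cca(std$views[[1L]], std$views[[2L]], 0.3, 0.3, K = 1L)
  cos1 <- abs(sum(fit$u[, 1L] * gen$truth$W[[1L]][, 1L]))
  cos2 <- abs(sum(fit$v[, 1L] * gen$truth$W[[2L]][, 1L]))
  expect_gte(cos1, 0.9)
  expect_gte(cos2, 0.9)
})

test_that("canonical columns satisfy norm and L1 feasibility; sparsity is monotone", {
  set.seed(8)
  X <- scale(matrix(rnorm(50 * 12), 50, 12))
  Z <- scale(matrix(rnorm(50 * 9), 50, 9))
  nz_prev <- Inf
  for (f in c(0.9, 0.6, 0.4, 0.2)) {
    fit <- sparse_cca(X, Z, f, f, K = 2L)
    for (k in 1:2) {
      expect_lte(sum(fit$u[, k]^2), 1 + 1e-8)
      expect_lte(sum(abs(fit$u[, k])), max(1, f * sqrt(12)) + 1e-8)
      expect_lte(sum(abs(fit$v[, k])), max(1, f * sqrt(9)) + 1e-8)
    }
    nz <- fit$nonzero[1L, 1L]
    expect_lte(nz, nz_prev)
    nz_prev <- nz
  }
})

test_that("deflated components are nearly uncorrelated on well-conditioned data", {
  gen <- gen_multiview(multiview_scenario(n = 300L, K = 2L, seed = 4L))
  std <- standardize(gen$dataset)
  X <- std$views[[1L]]$values
  fit <- sparse_cca(X, std$views[[2L]]$values, 0.5, 0.5, K = 2L)
  r <- abs(stats::cor(X %*% fit$u[, 1L], X %*% fit$u[, 2L]))
  expect_lte(r, 0.15)
})

test_that("permutation tuning finds planted signal and reports valid p-values", {
  gen <- gen_multiview(multiview_scenario(seed = 2L))
  std <- standardize(gen$dataset)
  tune <- cca_permute(std$views[[1L]], std$views[[2L]],
                      grid = c(0.2, 0.4), n_permutations = 99L, seed = 5L)
  expect_lte(tune$pvalue, 0.02)
  expect_gte(tune$pvalue, 1 / 100)
  expect_equal(tune$best, which.max(tune$zstats))
  # p-value definition: (1 + #{r_perm >= r_obs}) / (1 + B)
  expect_true(tune$pvalue %in% ((1 + 0:99) / 100))
})

test_that("multi-view CCA: identical views correlate perfectly, ascent is monotone", {
  set.seed(6)
  X <- scale(matrix(rnorm(40 * 5), 40, 5))
  fit <- multi_cca(list(X, X, X), penalties = sqrt(5), K = 1L)
  cors <- fit$correlations[[1L]][upper.tri(fit$correlations[[1L]])]
  expect_equal(unname(cors), rep(1, 3), tolerance = 1e-6)

  for (s in 1:50) {
    Xs <- make_std_views(25, c(4, 3, 5), seed = s)
    f <- multi_cca(Xs, penalties = c(1.5, 1.4, 1.8), K = 1L)
    tr <- f$objective[[1L]]
    expect_true(all(diff(tr) >= -1e-9))
  }
})

test_that("multi-view CCA recovers a shared latent factor", {
  gen <- gen_multiview(multiview_scenario(n = 200L, p = c(30L, 30L, 30L),
                                          seed = 9L))
  std <- standardize(gen$dataset)
  fit <- multi_cca(std, penalties = 3, K = 1L)
  for (m in 1:3) {
    cosm <- abs(sum(fit$weights[[m]][, 1L] * gen$truth$W[[m]][, 1L]))
    expect_gte(cosm, 0.85)
  }
})

test_that("multi-view permutation tuning: degenerate grid and planted signal", {
  gen <- gen_multiview(multiview_scenario(n = 120L, p = c(20L, 20L, 20L),
                                          seed = 10L))
  std <- standardize(gen$dataset)
  one <- multi_cca_permute(std, grid = list(c(2, 2, 2)), n_permutations = 20L,
                           seed = 2L)
  expect_equal(one$best, 1L)

  tune <- multi_cca_permute(std, grid = list(c(1.5, 1.5, 1.5), c(3, 3, 3)),
                            n_permutations = 99L, seed = 3L)
  expect_equal(tune$best, which.max(tune$zstats))
  expect_lte(tune$pvalue, 0.02)
})
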