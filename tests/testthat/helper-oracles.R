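# Independent oracles used across the suite. These deliberately avoid the
# package's own numerical routines.

# centered views whose columns are exactly orthonormal (up to scaling to
# unit sd): the regime in which the diagonal-covariance treatment of
# penalized CCA coincides with classical CCA
gen_orthonormal_view <- function(n, p) {
  X <- matrix(stats::rnorm(n * p), n, p)
  X <- scale(X, scale = FALSE)
  Q <- qr.Q(qr(X))[, seq_len(p), drop = FALSE]
  sweep(Q, 2L, apply(Q, 2L, stats::sd), "/")
}

# brute-force grid-search solution of max a'w s.t. ||w||2<=1, ||w||1<=c
l1_unit_gridsearch <- function(a, c, step = 1e-6) {
  deltas <- seq(0, max(abs(a)), by = step)
  best <- NULL; best_val <- -Inf
  for (d in deltas) {
    s <- sign(a) * pmax(abs(a) - d, 0)
    nrm <- sqrt(sum(s^2))
    if (nrm == 0) next
    w <- s / nrm
    if (sum(abs(w)) <= c + 1e-9) {
      val <- sum(a * w)
      if (val > best_val) { best_val <- val; best <- w }
    }
  }
  best
}

# proximal-gradient (FISTA) minimizer of the cooperative objective for
# gaussian loss: an independent generic convex solver
fista_coop <- function(views, y, rho, alpha, lambda, iters = 20000L) {
  X <- do.call(cbind, views)
  n <- nrow(X)
  ps <- vapply(views, ncol, integer(1L))
  ends <- cumsum(ps)
  blocks <- Map(function(s, e) s:e, c(1L, head(ends, -1L) + 1L), ends)
  yc <- y - mean(y)
  # smooth part: 1/(2n)||yc - Xb||^2 + rho/(2n) sum_pairs ||X_m b_m - X_m' b_m'||^2
  grad <- function(b) {
    etas <- Map(function(Xm, bl) drop(Xm %*% b[bl]), views, blocks)
    eta <- Reduce(`+`, etas)
    g <- -as.vector(crossprod(X, yc - eta)) / n
    M <- length(views)
    if (M >= 2L && rho > 0) {
      for (m in seq_len(M)) {
        diffsum <- Reduce(`+`, lapply(setdiff(seq_len(M), m),
                                      function(mm) etas[[m]] - etas[[mm]]))
        g[blocks[[m]]] <- g[blocks[[m]]] +
          rho / n * as.vector(crossprod(views[[m]], diffsum))
      }
    }
    g + lambda * (1 - alpha) * b
  }
  prox <- function(b, t) sign(b) * pmax(abs(b) - t * lambda * alpha, 0)
  L <- (1 + 2 * rho * length(views)) * max(svd(X)$d)^2 / n + lambda * (1 - alpha)
  b <- rep(0, ncol(X)); z <- b; tk <- 1
  for (i in seq_len(iters)) {
    b_new <- prox(z - grad(z) / L, 1 / L)
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- b_new + (tk - 1) / t_new * (b_new - b)
    if (max(abs(b_new - b)) < 1e-12) { b <- b_new; break }
    b <- b_new; tk <- t_new
  }
  b
}

# leave-one-out k-nearest-neighbour accuracy on a dissimilarity matrix
knn_accuracy <- function(D, labels, k = 5L) {
  n <- nrow(D)
  hits <- vapply(seq_len(n), function(i) {
    nn <- order(D[i, -i])[seq_len(k)]
    idx <- seq_len(n)[-i][nn]
    tab <- table(labels[idx])
    names(tab)[which.max(tab)] == labels[i]
  }, logical(1L))
  mean(hits)
}

# classical CCA first correlation via the generalized-eigenvalue route
classical_cca_cor <- function(X, Z) {
  stats::cancor(X, Z)$cor[1L]
}

view_matrices_for_test <- function(ds) lapply(ds$views, function(v) v$values)

make_std_views <- function(n, ps, seed) {
  with_seed <- function(s, code) { set.seed(s); code }
  with_seed(seed, lapply(ps, function(p) scale(matrix(rnorm(n * p), n, p))))
}
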