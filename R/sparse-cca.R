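#' Soft-thresholding operator
#'
#' Elementwise \eqn{S(a, \delta)_i = \mathrm{sign}(a_i)\,\max(|a_i| - \delta, 0)},
#' the proximal operator of the L1 norm and the basic ingredient of the
#' penalized matrix decomposition.
#'
#' @param a Numeric vector.
#' @param delta Non-negative threshold.
#' @return Numeric vector of the same length.
#' @export
soft_threshold <- function(a, delta) {
  if (delta < 0) stop("delta must be non-negative", call. = FALSE)
  sign(a) * pmax(abs(a) - delta, 0)
}

#' Maximize a linear form over the L1/L2-constrained unit ball
#'
#' Solves \eqn{\max_w a^T w} subject to \eqn{\|w\|_2 \le 1} and
#' \eqn{\|w\|_1 \le c}: the inner step of the penalized matrix
#' decomposition. The solution is \eqn{w = S(a, \Delta)/\|S(a, \Delta)\|_2}
#' with \eqn{\Delta \ge 0} the smallest threshold (found by bisection) for
#' which the L1 bound holds; \eqn{\Delta = 0} when the bound is not binding.
#'
#' @param a Numeric vector, not all zero.
#' @param c L1 bound, in \eqn{[1, \sqrt{\mathrm{length}(a)}]}.
#' @param tol Bisection tolerance on \eqn{\Delta}.
#' @return Unit vector satisfying both constraints.
#' @export
l1_constrained_unit_vector <- function(a, c, tol = 1e-10) {
  .l1_unit_vector(as.numeric(a), c, tol)
}

# deterministic leading singular pair, sign fixed so that the
# largest-|coordinate| entry of v is positive
leading_sv <- function(M) {
  s <- svd(M, nu = 1L, nv = 1L)
  u <- s$u[, 1L]; v <- s$v[, 1L]
  j <- which.max(abs(v))
  if (v[j] < 0) { v <- -v; u <- -u }
  list(u = u, v = v, d = s$d[1L])
}

fix_sign <- function(w) {
  j <- which.max(abs(w))
  if (w[j] < 0) -w else w
}

#' Sparse canonical correlation analysis of two views
#'
#' Penalized-matrix-decomposition (PMD) sparse CCA: finds sparse canonical
#' vectors \eqn{u, v} maximizing \eqn{u^T X^T Z v} subject to
#' \eqn{\|u\|_2 \le 1, \|u\|_1 \le c_x} (and likewise for \eqn{v}), by
#' alternating L1-constrained linear maximizations on the cross-product
#' matrix \eqn{M = X^T Z}. Within-view covariance is treated as the
#' identity, the standard PMD approximation for high-dimensional views.
#' Subsequent components are obtained by rank-one deflation of \eqn{M}.
#'
#' The L1 bounds are given as fractions \eqn{f \in (0, 1]} of
#' \eqn{\sqrt{p}}: the constraint used is \eqn{c = \max(1, f\sqrt{p})}, so
#' `l1 = 1` is (essentially) unpenalized and small fractions give very
#' sparse vectors.
#'
#' @param X,Z Standardized, row-aligned views ([feature_matrix()] or plain
#'   numeric matrices with identical row counts).
#' @param l1_x,l1_z Sparsity fractions in `(0, 1]`.
#' @param K Number of canonical components.
#' @param max_iter,tol Convergence controls on the maximal coordinate
#'   change per alternation.
#' @return Object of class `sparse_cca_result` with matrices `u`
#'   (\eqn{p \times K}), `v` (\eqn{q \times K}), the canonical
#'   `correlations` \eqn{\mathrm{cor}(Xu_k, Zv_k)}, `d` (the objective
#'   values \eqn{u_k^T M v_k} at extraction), `nonzero` (2 x K matrix of
#'   non-zero counts), the bounds used, and iteration counts.
#' @export
sparse_cca <- function(X, Z, l1_x = 0.7, l1_z = 0.7, K = 1L,
                       max_iter = 50L, tol = 1e-6) {
  X <- as_feature_values(X); Z <- as_feature_values(Z)
  if (nrow(X) != nrow(Z)) stop("X and Z must have the same samples", call. = FALSE)
  if (l1_x <= 0 || l1_x > 1 || l1_z <= 0 || l1_z > 1)
    stop("l1 fractions must lie in (0, 1]", call. = FALSE)
  p <- ncol(X); q <- ncol(Z)
  if (K > min(p, q)) stop("K exceeds min(p, q)", call. = FALSE)
  cx <- max(1, l1_x * sqrt(p)); cz <- max(1, l1_z * sqrt(q))
  M <- crossprod(X, Z)
  U <- matrix(0, p, K); V <- matrix(0, q, K)
  d <- cors <- numeric(K); iters <- integer(K)
  for (k in seq_len(K)) {
    sv <- leading_sv(M)
    v <- sv$v
    u <- l1_constrained_unit_vector(as.vector(M %*% v), cx)
    it <- 0L
    repeat {
      it <- it + 1L
      u_new <- l1_constrained_unit_vector(as.vector(M %*% v), cx)
      v_new <- l1_constrained_unit_vector(as.vector(crossprod(M, u_new)), cz)
      delta <- max(max(abs(u_new - u)), max(abs(v_new - v)))
      u <- u_new; v <- v_new
      if (delta < tol || it >= max_iter) break
    }
    dk <- as.numeric(crossprod(u, M %*% v))
    # sign convention: largest-|coordinate| entry of u positive; v flipped
    # with it so that u'Mv (and the canonical correlation) is unchanged
    if (u[which.max(abs(u))] < 0) { u <- -u; v <- -v }
    xs <- X %*% u; zs <- Z %*% v
    cors[k] <- if (stats::sd(xs) == 0 || stats::sd(zs) == 0) 0 else stats::cor(xs, zs)
    U[, k] <- u; V[, k] <- v; d[k] <- dk; iters[k] <- it
    M <- M - dk * tcrossprod(u, v)
  }
  rownames(U) <- colnames(X); rownames(V) <- colnames(Z)
  structure(list(u = U, v = V, correlations = cors, d = d,
                 l1_bounds = c(x = l1_x, z = l1_z),
                 constraints = c(x = cx, z = cz),
                 nonzero = rbind(x = colSums(U != 0), z = colSums(V != 0)),
                 K = K, iterations = iters),
            class = "sparse_cca_result")
}

#' @export
print.sparse_cca_result <- function(x, ...) {
  cat(sprintf("<sparse CCA: K=%d, l1 bounds (%.2f, %.2f)>\n",
              x$K, x$l1_bounds[1L], x$l1_bounds[2L]))
  for (k in seq_len(x$K))
    cat(sprintf("  component %d: cor=%.3f, nonzero=(%d, %d)\n",
                k, x$correlations[k], x$nonzero[1L, k], x$nonzero[2L, k]))
  invisible(x)
}

permutation_sets <- function(n, n_permutations, seed) {
  with_seed(seed, replicate(n_permutations, sample.int(n), simplify = FALSE))
}

perm_zstat <- function(r_obs, r_perm) {
  z <- atanh(pmin(pmax(r_obs, -1 + 1e-12), 1 - 1e-12))
  zp <- atanh(pmin(pmax(r_perm, -1 + 1e-12), 1 - 1e-12))
  s <- stats::sd(zp)
  if (!is.finite(s) || s == 0) {
    warning("degenerate permutation distribution; z-statistic set to 0", call. = FALSE)
    return(0)
  }
  (z - mean(zp)) / s
}

#' Permutation-based selection of sparse-CCA sparsity parameters
#'
#' For each candidate pair of L1 fractions, computes the observed first
#' canonical correlation and its null distribution over row permutations of
#' `Z` (the same permutation set reused across the grid). Candidates are
#' scored by the Fisher-transformed z-statistic
#' \eqn{z = (\mathrm{atanh}(r_{obs}) - \overline{\mathrm{atanh}(r_{perm})}) /
#' \mathrm{sd}(\mathrm{atanh}(r_{perm}))}; the selected candidate is the one
#' with the largest z (ties broken toward the smaller, i.e. sparser, bound)
#' and its permutation p-value is
#' \eqn{(1 + \#\{r_{perm} \ge r_{obs}\}) / (1 + B)}.
#'
#' @param X,Z Standardized aligned views.
#' @param grid List of length-2 numeric vectors `(l1_x, l1_z)`, or a numeric
#'   vector of fractions used for both views.
#' @param n_permutations Number of permutations (at least 10).
#' @param seed Integer seed for the permutation set.
#' @return Object of class `permutation_tuning` with the grid, per-candidate
#'   `zstats`, correlations, non-zero counts, the selected candidate `best`,
#'   and its `pvalue`.
#' @export
cca_permute <- function(X, Z, grid = seq(0.1, 0.7, by = 0.1),
                        n_permutations = 100L, seed = 1L) {
  X <- as_feature_values(X); Z <- as_feature_values(Z)
  if (is.numeric(grid)) grid <- lapply(grid, function(f) c(f, f))
  if (length(grid) == 0L) stop("empty grid", call. = FALSE)
  if (n_permutations < 10L) stop("need at least 10 permutations", call. = FALSE)
  perms <- permutation_sets(nrow(Z), n_permutations, seed)
  G <- length(grid)
  r_obs <- zstats <- numeric(G)
  cors_perm <- matrix(0, n_permutations, G)
  nonzero <- matrix(0L, 2L, G)
  for (g in seq_len(G)) {
    fit <- sparse_cca(X, Z, grid[[g]][1L], grid[[g]][2L], K = 1L)
    r_obs[g] <- fit$correlations[1L]
    nonzero[, g] <- fit$nonzero[, 1L]
    for (b in seq_len(n_permutations)) {
      pf <- sparse_cca(X, Z[perms[[b]], , drop = FALSE],
                       grid[[g]][1L], grid[[g]][2L], K = 1L)
      cors_perm[b, g] <- pf$correlations[1L]
    }
    zstats[g] <- perm_zstat(r_obs[g], cors_perm[, g])
  }
  best <- tune_pick(grid, zstats)
  pvalue <- (1 + sum(cors_perm[, best] >= r_obs[best])) / (1 + n_permutations)
  structure(list(grid = grid, zstats = zstats, correlations = r_obs,
                 nonzero = nonzero, best = best, best_l1 = grid[[best]],
                 pvalue = pvalue, n_permutations = n_permutations, seed = seed),
            class = "permutation_tuning")
}

# argmax of zstat; ties go to the smallest total bound (sparsest model)
tune_pick <- function(grid, zstats) {
  mx <- max(zstats)
  cand <- which(zstats >= mx - 1e-12)
  if (length(cand) == 1L) return(cand)
  sizes <- vapply(grid[cand], sum, numeric(1L))
  cand[order(sizes, cand)[1L]]
}

#' @export
print.permutation_tuning <- function(x, ...) {
  cat(sprintf("<permutation tuning: %d candidates, %d permutations>\n",
              length(x$grid), x$n_permutations))
  cat(sprintf("  best: (%s), z=%.3f, p=%.4g, cor=%.3f\n",
              paste(signif(x$best_l1, 3), collapse = ", "),
              x$zstats[x$best], x$pvalue, x$correlations[x$best]))
  invisible(x)
}

#' Sparse multi-view CCA
#'
#' Extension of [sparse_cca()] to three or more views: block-coordinate
#' ascent on \eqn{\sum_{i<j} w_i^T X_i^T X_j w_j} with each
#' \eqn{w_i} constrained to \eqn{\|w_i\|_2 \le 1, \|w_i\|_1 \le c_i}. The
#' penalties \eqn{c_i} are given on the absolute scale (not as fractions),
#' matching how multi-view penalties are conventionally reported. Each
#' block update is an exact constrained maximization, so the objective is
#' non-decreasing over iterations. Further components deflate every
#' pairwise cross-product matrix by its fitted rank-one term.
#'
#' @param views A `multiview_dataset` or list of standardized, aligned
#'   matrices (at least 3; for two views use [sparse_cca()]).
#' @param penalties Numeric vector of absolute L1 bounds \eqn{c_i}, one per
#'   view (each in \eqn{[1, \sqrt{p_i}]}); a single value is recycled.
#' @param K Number of components.
#' @param max_iter,tol Convergence controls on the objective change.
#' @return Object of class `multi_cca_result` with `weights` (list of
#'   \eqn{p_i \times K} matrices), pairwise `correlations` (per component a
#'   matrix of \eqn{\mathrm{cor}(X_i w_i, X_j w_j)}), the ascent `objective`
#'   trace per component, `penalties` and non-zero counts.
#' @export
multi_cca <- function(views, penalties = NULL, K = 1L, max_iter = 100L, tol = 1e-8) {
  Xs <- view_matrices(views)
  M_views <- length(Xs)
  if (M_views < 3L) stop("multi_cca needs at least 3 views; use sparse_cca for two", call. = FALSE)
  ps <- vapply(Xs, ncol, integer(1L))
  if (is.null(penalties)) penalties <- pmax(1, 0.5 * sqrt(ps))
  if (length(penalties) == 1L) penalties <- rep(penalties, M_views)
  penalties <- pmax(1, pmin(penalties, sqrt(ps)))
  pairs <- utils::combn(M_views, 2L)
  # pairwise cross-products, deflated across components
  Ms <- apply(pairs, 2L, function(ij) crossprod(Xs[[ij[1L]]], Xs[[ij[2L]]]),
              simplify = FALSE)
  W <- lapply(ps, function(p) matrix(0, p, K))
  cors <- vector("list", K)
  obj_traces <- vector("list", K)
  getM <- function(i, j) {
    col <- which(pairs[1L, ] == min(i, j) & pairs[2L, ] == max(i, j))
    if (i < j) Ms[[col]] else t(Ms[[col]])
  }
  for (k in seq_len(K)) {
    ws <- lapply(Xs, function(X) fix_sign(leading_sv(X)$v))
    objective <- function() {
      sum(apply(pairs, 2L, function(ij)
        as.numeric(crossprod(ws[[ij[1L]]], getM(ij[1L], ij[2L]) %*% ws[[ij[2L]]]))))
    }
    obj <- objective(); trace <- obj
    for (it in seq_len(max_iter)) {
      for (i in seq_len(M_views)) {
        a <- Reduce(`+`, lapply(setdiff(seq_len(M_views), i), function(j)
          as.vector(getM(i, j) %*% ws[[j]])))
        if (any(a != 0)) ws[[i]] <- l1_constrained_unit_vector(a, penalties[i])
      }
      new_obj <- objective()
      trace <- c(trace, new_obj)
      if (abs(new_obj - obj) < tol * (abs(obj) + 1)) { obj <- new_obj; break }
      obj <- new_obj
    }
    cmat <- matrix(1, M_views, M_views)
    for (cidx in seq_len(ncol(pairs))) {
      i <- pairs[1L, cidx]; j <- pairs[2L, cidx]
      si <- Xs[[i]] %*% ws[[i]]; sj <- Xs[[j]] %*% ws[[j]]
      cmat[i, j] <- cmat[j, i] <-
        if (stats::sd(si) == 0 || stats::sd(sj) == 0) 0 else stats::cor(si, sj)
      d <- as.numeric(crossprod(ws[[i]], Ms[[cidx]] %*% ws[[j]]))
      Ms[[cidx]] <- Ms[[cidx]] - d * tcrossprod(ws[[i]], ws[[j]])
    }
    for (i in seq_len(M_views)) W[[i]][, k] <- ws[[i]]
    cors[[k]] <- cmat
    obj_traces[[k]] <- trace
  }
  for (i in seq_len(M_views)) rownames(W[[i]]) <- colnames(Xs[[i]])
  names(W) <- names(Xs)
  structure(list(weights = W, correlations = cors, objective = obj_traces,
                 penalties = penalties,
                 nonzero = vapply(W, function(w) colSums(w != 0)[1L], numeric(1L)),
                 K = K),
            class = "multi_cca_result")
}

multi_cca_stat <- function(Xs, fit, k = 1L) {
  M_views <- length(Xs)
  pairs <- utils::combn(M_views, 2L)
  sum(apply(pairs, 2L, function(ij) {
    si <- Xs[[ij[1L]]] %*% fit$weights[[ij[1L]]][, k]
    sj <- Xs[[ij[2L]]] %*% fit$weights[[ij[2L]]][, k]
    r <- if (stats::sd(si) == 0 || stats::sd(sj) == 0) 0 else stats::cor(si, sj)
    atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
  }))
}

#' Permutation tuning for sparse multi-view CCA
#'
#' As [cca_permute()], with test statistic
#' \eqn{\sum_{i<j} \mathrm{atanh}\,\mathrm{cor}(X_i w_i, X_j w_j)} and null
#' draws obtained by permuting the rows of each view independently (the
#' first view held fixed).
#'
#' @param views `multiview_dataset` or list of aligned standardized matrices.
#' @param grid List of penalty vectors (one \eqn{c_i} per view), or a
#'   numeric vector of single penalties recycled across views.
#' @param n_permutations,seed As in [cca_permute()].
#' @return A `permutation_tuning` object (fields as in [cca_permute()], with
#'   `correlations` holding the observed sum-statistic per candidate).
#' @export
multi_cca_permute <- function(views, grid, n_permutations = 100L, seed = 1L) {
  Xs <- view_matrices(views)
  M_views <- length(Xs)
  if (is.numeric(grid)) grid <- lapply(grid, function(cc) rep(cc, M_views))
  if (length(grid) == 0L) stop("empty grid", call. = FALSE)
  if (n_permutations < 10L) stop("need at least 10 permutations", call. = FALSE)
  n <- nrow(Xs[[1L]])
  perm_sets <- with_seed(seed, replicate(n_permutations, {
    c(list(seq_len(n)), replicate(M_views - 1L, sample.int(n), simplify = FALSE))
  }, simplify = FALSE))
  G <- length(grid)
  stat_obs <- zstats <- numeric(G)
  stat_perm <- matrix(0, n_permutations, G)
  for (g in seq_len(G)) {
    fit <- multi_cca(Xs, penalties = grid[[g]], K = 1L)
    stat_obs[g] <- multi_cca_stat(Xs, fit)
    for (b in seq_len(n_permutations)) {
      Xp <- lapply(seq_len(M_views), function(i) Xs[[i]][perm_sets[[b]][[i]], , drop = FALSE])
      pf <- multi_cca(Xp, penalties = grid[[g]], K = 1L)
      stat_perm[b, g] <- multi_cca_stat(Xp, pf)
    }
    s <- stats::sd(stat_perm[, g])
    zstats[g] <- if (!is.finite(s) || s == 0) {
      warning("degenerate permutation distribution; z-statistic set to 0", call. = FALSE)
      0
    } else (stat_obs[g] - mean(stat_perm[, g])) / s
  }
  best <- tune_pick(grid, zstats)
  pvalue <- (1 + sum(stat_perm[, best] >= stat_obs[best])) / (1 + n_permutations)
  structure(list(grid = grid, zstats = zstats, correlations = stat_obs,
                 best = best, best_l1 = grid[[best]], pvalue = pvalue,
                 n_permutations = n_permutations, seed = seed),
            class = "permutation_tuning")
}
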