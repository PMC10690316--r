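#' Multi-view latent-factor scenario
#'
#' Describes a synthetic cohort in which several views share sparse latent
#' canonical structure and a binary outcome is driven by the first latent
#' factor: latent scores \eqn{S} (\eqn{n \times K}, standard normal),
#' per-view sparse sign loadings, \eqn{X_m = \mathrm{snr}\, S W_m^T +
#' \varepsilon} with unit Gaussian noise, and outcome
#' \eqn{y \sim \mathrm{Bern}(\mathrm{logistic}(\gamma S_1))}. Loaded
#' features therefore have marginal variance \eqn{snr^2 + 1}; the stored
#' truth holds the unit-normalized loading vectors for recovery scoring.
#'
#' @param n Samples.
#' @param p Per-view feature counts (vector, one entry per view).
#' @param K Number of latent factors.
#' @param sparsity Non-zero loadings per factor per view.
#' @param snr Signal-to-noise ratio (per-feature signal standard
#'   deviation against unit noise).
#' @param outcome_strength Logit slope \eqn{\gamma} on the first factor
#'   (0 = outcome independent of the views).
#' @param binary_views Indices of views to binarize (thresholded at 0),
#'   emulating clinical-style indicator features.
#' @param seed Integer seed.
#' @return A `multiview_scenario` list.
#' @export
multiview_scenario <- function(n = 200L, p = c(50L, 50L), K = 1L,
                               sparsity = 5L, snr = 1, outcome_strength = 2,
                               binary_views = integer(0), seed = 1L) {
  stopifnot(n >= 4L, all(p >= 1L), K >= 1L, sparsity >= 1L, snr > 0)
  if (K > min(p)) stop("K exceeds the smallest view dimension", call. = FALSE)
  if (sparsity > min(p)) stop("sparsity exceeds the smallest view dimension", call. = FALSE)
  structure(list(n = as.integer(n), p = as.integer(p), K = as.integer(K),
                 sparsity = as.integer(sparsity), snr = snr,
                 outcome_strength = outcome_strength,
                 binary_views = as.integer(binary_views),
                 seed = as.integer(seed)),
            class = "multiview_scenario")
}

#' Generate a multi-view dataset with planted latent structure
#'
#' @param scenario A [multiview_scenario()].
#' @return List with `dataset` (a `multiview_dataset` carrying the
#'   outcome) and `truth` (latent scores `S`, unit-norm loading matrices
#'   `W` per view, and the sign-loading support).
#' @export
gen_multiview <- function(scenario = multiview_scenario()) {
  stopifnot(inherits(scenario, "multiview_scenario"))
  sc <- scenario
  with_seed(sc$seed, {
    S <- matrix(stats::rnorm(sc$n * sc$K), sc$n, sc$K)
    ids <- sprintf("s%04d", seq_len(sc$n))
    W <- vector("list", length(sc$p))
    views <- vector("list", length(sc$p))
    for (m in seq_along(sc$p)) {
      Wm <- matrix(0, sc$p[m], sc$K)
      for (k in seq_len(sc$K)) {
        supp <- sample.int(sc$p[m], sc$sparsity)
        Wm[supp, k] <- sample(c(-1, 1), sc$sparsity, replace = TRUE)
      }
      X <- sc$snr * tcrossprod(S, Wm) +
        matrix(stats::rnorm(sc$n * sc$p[m]), sc$n, sc$p[m])
      if (m %in% sc$binary_views) X <- (X > 0) * 1
      colnames(X) <- sprintf("v%d_f%03d", m, seq_len(sc$p[m]))
      views[[m]] <- feature_matrix(X, sample_ids = ids,
                                   view_name = paste0("view", m))
      W[[m]] <- sweep(Wm, 2L, sqrt(colSums(Wm^2)), "/")
    }
    outcome <- stats::rbinom(sc$n, 1L,
                             logistic(sc$outcome_strength * S[, 1L]))
    names(outcome) <- ids
    dataset <- align_views(views, outcome = outcome)
    list(dataset = dataset, truth = list(S = S, W = W, scenario = sc))
  })
}

#' Clade-structured phylogeny scenario
#'
#' Describes a synthetic strain population: a random clade tree in which
#' every edge contributes novel mutation tokens, strains inherit their
#' clade's root-to-leaf tokens (each lost with probability `dropout`) plus
#' Poisson-distributed private mutations, a fraction of strains are
#' outliers carrying many extra tokens, and (optionally) recombinants
#' merge two clades' token sets.
#'
#' @param n_clades Number of leaf clades.
#' @param tree_depth Edges from root to every leaf.
#' @param mutations_per_branch Novel tokens added per edge.
#' @param dropout Per-token probability that a strain loses an inherited
#'   mutation.
#' @param private_rate Poisson mean of private mutations per strain.
#' @param n_strains_per_clade Strains sampled per clade.
#' @param outlier_rate Probability a strain is a planted outlier.
#' @param outlier_size Extra private tokens given to an outlier.
#' @param recombinant_rate Probability a strain merges a second clade's
#'   inherited tokens (labelled `"recombinant"`).
#' @param seed Integer seed.
#' @return A `phylogeny_scenario` list.
#' @export
phylogeny_scenario <- function(n_clades = 4L, tree_depth = 4L,
                               mutations_per_branch = 6L, dropout = 0.05,
                               private_rate = 3, n_strains_per_clade = 50L,
                               outlier_rate = 0.05, outlier_size = 30L,
                               recombinant_rate = 0, seed = 1L) {
  stopifnot(n_clades >= 1L, tree_depth >= 1L, mutations_per_branch >= 1L,
            dropout >= 0, dropout <= 1, private_rate >= 0,
            n_strains_per_clade >= 1L, outlier_rate >= 0, outlier_rate <= 1,
            recombinant_rate >= 0, recombinant_rate <= 1)
  structure(list(n_clades = as.integer(n_clades),
                 tree_depth = as.integer(tree_depth),
                 mutations_per_branch = as.integer(mutations_per_branch),
                 dropout = dropout, private_rate = private_rate,
                 n_strains_per_clade = as.integer(n_strains_per_clade),
                 outlier_rate = outlier_rate,
                 outlier_size = as.integer(outlier_size),
                 recombinant_rate = recombinant_rate,
                 seed = as.integer(seed)),
            class = "phylogeny_scenario")
}

# token factory: unique genomic positions guarantee unique tokens
make_tokens <- function(counter, k) {
  genes <- c("ORF1a", "ORF1b", "S", "ORF3a", "M", "N")
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
  pos <- counter + seq_len(k)
  toks <- sprintf("%s:%s%d%s", genes[(pos %% length(genes)) + 1L],
                  sample(aa, k, replace = TRUE), pos,
                  sample(aa, k, replace = TRUE))
  list(tokens = toks, counter = counter + k)
}

#' Generate a clade-structured mutation catalog
#'
#' Builds the clade tree by recursive random bipartition (every leaf at
#' depth `tree_depth`, every edge carrying `mutations_per_branch` novel
#' tokens), then samples strains per clade as described in
#' [phylogeny_scenario()]. Sibling clades share exactly the tokens of
#' their common ancestors.
#'
#' @param scenario A [phylogeny_scenario()].
#' @return A [mutation_catalog()] with clade labels; attributes
#'   `"outliers"` and `"recombinants"` list the planted strain ids, and
#'   `"clade_tokens"` the per-clade inherited token sets.
#' @export
gen_phylogeny <- function(scenario = phylogeny_scenario()) {
  stopifnot(inherits(scenario, "phylogeny_scenario"))
  sc <- scenario
  with_seed(sc$seed, {
    counter <- 0L
    clade_tokens <- rep(list(character(0)), sc$n_clades)
    # recursive bipartition: every clade inherits tree_depth edges of tokens
    grow <- function(clades, depth, inherited) {
      if (depth == 0L) {
        for (cl in clades) clade_tokens[[cl]] <<- inherited
        return(invisible(NULL))
      }
      split_into <- if (length(clades) >= 2L) {
        cut <- sample.int(length(clades) - 1L, 1L)
        sh <- sample(clades)
        list(sh[seq_len(cut)], sh[-seq_len(cut)])
      } else list(clades)
      for (child in split_into) {
        tk <- make_tokens(counter, sc$mutations_per_branch)
        counter <<- tk$counter
        grow(child, depth - 1L, c(inherited, tk$tokens))
      }
    }
    grow(seq_len(sc$n_clades), sc$tree_depth, character(0))

    strains <- character(0); toks <- list(); clades <- character(0)
    outliers <- character(0); recombinants <- character(0)
    for (cl in seq_len(sc$n_clades)) {
      for (s in seq_len(sc$n_strains_per_clade)) {
        id <- sprintf("clade%02d_strain%03d", cl, s)
        inherited <- clade_tokens[[cl]]
        clade_lab <- paste0("clade", sprintf("%02d", cl))
        if (sc$recombinant_rate > 0 && stats::runif(1) < sc$recombinant_rate &&
            sc$n_clades >= 2L) {
          other <- sample(setdiff(seq_len(sc$n_clades), cl), 1L)
          inherited <- union(inherited, clade_tokens[[other]])
          clade_lab <- "recombinant"
          recombinants <- c(recombinants, id)
        }
        keep <- stats::runif(length(inherited)) >= sc$dropout
        tk_strain <- inherited[keep]
        n_priv <- stats::rpois(1L, sc$private_rate)
        if (stats::runif(1) < sc$outlier_rate) {
          n_priv <- n_priv + sc$outlier_size
          outliers <- c(outliers, id)
        }
        if (n_priv > 0L) {
          priv <- make_tokens(counter, n_priv)
          counter <- priv$counter
          tk_strain <- c(tk_strain, priv$tokens)
        }
        strains <- c(strains, id)
        toks[[length(toks) + 1L]] <- tk_strain
        clades <- c(clades, clade_lab)
      }
    }
    cat_out <- mutation_catalog(strains, toks, clades = clades)
    attr(cat_out, "outliers") <- outliers
    attr(cat_out, "recombinants") <- recombinants
    attr(cat_out, "clade_tokens") <- clade_tokens
    cat_out
  })
}

#' Generate a mutation catalog with a fixed planted vocabulary
#'
#' Draws random token subsets for each strain from a vocabulary of exactly
#' `vocab_size` tokens and guarantees every token appears in at least one
#' strain, so the binary encoding has exactly `vocab_size` columns.
#'
#' @param n_strains Number of strains.
#' @param vocab_size Number of distinct mutation tokens.
#' @param mean_tokens Average tokens per strain.
#' @param seed Integer seed.
#' @return A [mutation_catalog()].
#' @export
gen_catalog_fixed_vocab <- function(n_strains = 105L, vocab_size = 439L,
                                    mean_tokens = 22L, seed = 1L) {
  with_seed(seed, {
    vocab <- make_tokens(0L, vocab_size)$tokens
    toks <- lapply(seq_len(n_strains), function(i) {
      k <- min(vocab_size, max(1L, stats::rpois(1L, mean_tokens)))
      sample(vocab, k)
    })
    # coverage pass: park unused tokens on random strains
    unused <- setdiff(vocab, unlist(toks))
    for (tk in unused) {
      i <- sample.int(n_strains, 1L)
      toks[[i]] <- union(toks[[i]], tk)
    }
    mutation_catalog(sprintf("strain%03d", seq_len(n_strains)), toks)
  })
}

#' Generate a two-group cohort of comorbidities and covariates
#'
#' Binary comorbidities are Bernoulli draws with group-specific
#' prevalences; continuous covariates are normal or log-normal with
#' group-specific means and SDs. Deterministic given `seed`.
#'
#' @param n Total patients.
#' @param group_sizes Length-2 vector of group sizes (summing to `n`);
#'   group label 1 first.
#' @param prevalences Named list of length-2 rate vectors
#'   `c(group1, group2)` for binary variables.
#' @param continuous_specs Named list of lists with `mean` and `sd`
#'   (length-2 each) and optional `log = TRUE` for log-normal variables.
#' @param seed Integer seed.
#' @return Data frame with a 0/1 `group` column (1 = group 1) plus one
#'   column per variable.
#' @export
gen_cohort <- function(n = 149L, group_sizes = c(63L, 86L),
                       prevalences = list(), continuous_specs = list(),
                       seed = 1L) {
  stopifnot(sum(group_sizes) == n, length(group_sizes) == 2L)
  rates_ok <- all(vapply(prevalences, function(r)
    length(r) == 2L && all(r >= 0) && all(r <= 1), logical(1L)))
  if (!rates_ok) stop("prevalences must be length-2 vectors in [0, 1]", call. = FALSE)
  with_seed(seed, {
    group <- rep(c(1L, 0L), group_sizes)
    df <- data.frame(group = group)
    for (v in names(prevalences)) {
      r <- prevalences[[v]]
      df[[v]] <- stats::rbinom(n, 1L, ifelse(group == 1L, r[1L], r[2L]))
    }
    for (v in names(continuous_specs)) {
      spec <- continuous_specs[[v]]
      mu <- ifelse(group == 1L, spec$mean[1L], spec$mean[2L])
      sdv <- ifelse(group == 1L, spec$sd[1L], spec$sd[2L])
      x <- stats::rnorm(n, mu, sdv)
      if (isTRUE(spec$log)) x <- exp(x)
      df[[v]] <- x
    }
    df
  })
}
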