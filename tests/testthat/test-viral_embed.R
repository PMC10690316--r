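test_that("binary encoding builds the presence matrix directly", {
  cat2 <- mutation_catalog(c("A", "B"),
                           list(c("S:N501Y", "S:E484K"), c("S:E484K", "N:R203K")))
  fm <- binary_encode(cat2)
  expect_equal(dim(fm), c(2L, 3L))
  expect_equal(unname(rowSums(fm$values)), c(2, 2))
  expect_equal(unname(fm$values["A", c("S:E484K", "S:N501Y", "N:R203K")]),
               c(1, 1, 0))

  # strain without mutations: all-zero row
  cat3 <- mutation_catalog(c("A", "B", "empty"),
                           list(c("S:N501Y"), c("S:N501Y", "N:R203K"),
                                character(0)))
  fm3 <- binary_encode(cat3)
  expect_equal(unname(rowSums(fm3$values)), c(1, 2, 0))

  # column count equals unique tokens; row sums equal token counts
  cat_big <- gen_catalog_fixed_vocab(n_strains = 105L, vocab_size = 439L, seed = 3L)
  fm_big <- binary_encode(cat_big)
  expect_equal(ncol(fm_big$values), 439L)
  expect_equal(unname(rowSums(fm_big$values)),
               as.numeric(lengths(cat_big$tokens)))
})

test_that("token syntax and duplicates are validated", {
  expect_error(mutation_catalog("A", list(c("S:N501Y", "S:N501Y"))), "invalid")
  expect_error(mutation_catalog("A", list("not a token")), "invalid")
  expect_error(mutation_catalog(c("A", "A"), list("S:N501Y", "S:E484K")),
               "duplicate")
})

test_that("IQR filter removes extreme strains and keeps the median", {
  mk <- function(counts) mutation_catalog(
    sprintf("s%02d", seq_along(counts)),
    lapply(counts, function(k) if (k == 0) character(0)
           else sprintf("S:A%dT", seq_len(k))))
  res <- iqr_filter(mk(c(20:28, 200)))
  expect_equal(res$removed, "s10")
  res2 <- iqr_filter(mk(rep(7, 6)))
  expect_length(res2$removed, 0L)
  res3 <- iqr_filter(mk(c(1, 1, 1, 1, 50)))
  expect_equal(res3$removed, "s05")
  # a strain at the median count can never be removed
  set.seed(4)
  counts <- rpois(40, 20)
  res4 <- iqr_filter(mk(counts))
  med_ids <- sprintf("s%02d", which(counts == median(counts)))
  expect_length(intersect(res4$removed, med_ids), 0L)
})

test_that("catalog TSV and JSON-lines round trips preserve content", {
  cat_in <- gen_phylogeny(phylogeny_scenario(n_clades = 2L,
                                             n_strains_per_clade = 5L, seed = 2L))
  for (ext in c(".tsv", ".jsonl")) {
    path <- tempfile(fileext = ext)
    write_mutation_catalog(cat_in, path)
    back <- read_mutation_catalog(path)
    expect_equal(back$strains, cat_in$strains)
    expect_equal(back$tokens, cat_in$tokens)
    expect_equal(back$clades, cat_in$clades)
  }
})

test_that("skip-gram training is deterministic and respects token identity", {
  cat_in <- gen_phylogeny(phylogeny_scenario(n_clades = 2L,
                                             n_strains_per_clade = 20L, seed = 5L))
  emb1 <- train_skipgram(cat_in, d = 8L, window = 20L, epochs = 3L, seed = 11L)
  emb2 <- train_skipgram(cat_in, d = 8L, window = 20L, epochs = 3L, seed = 11L)
  expect_identical(emb1$token_vectors, emb2$token_vectors)

  # strains with identical token lists embed identically
  tw <- mutation_catalog(c("x", "y", "z"),
                         list(cat_in$tokens[[1L]], cat_in$tokens[[1L]],
                              cat_in$tokens[[2L]]))
  sv <- embed_new_strains(emb1, tw)
  expect_equal(sv$vectors["x", ], sv$vectors["y", ])
  cossim <- sum(sv$vectors["x", ] * sv$vectors["y", ]) /
    sqrt(sum(sv$vectors["x", ]^2) * sum(sv$vectors["y", ]^2))
  expect_equal(cossim, 1)
})

test_that("strain vectors are token means; OOV strains are excluded", {
  emb <- structure(list(
    token_vectors = rbind("S:A1T" = c(1, 0), "S:A2T" = c(0, 1)),
    vocab = c("S:A1T", "S:A2T"), d = 2L, window = 5L),
    class = "strain_embedding")
  cat_in <- mutation_catalog(c("m", "oov"),
                             list(c("S:A1T", "S:A2T"), "N:Q9L"))
  res <- suppressMessages(embed_new_strains(emb, cat_in))
  expect_equal(unname(res$vectors["m", ]), c(0.5, 0.5))
  expect_equal(res$excluded, "oov")
  expect_equal(res$oov_tokens, 1L)

  # permutation of tokens within a strain leaves the embedding unchanged
  cat_perm <- mutation_catalog("m", list(c("S:A2T", "S:A1T")))
  res_p <- embed_new_strains(emb, cat_perm)
  expect_equal(res_p$vectors["m", ], res$vectors["m", ])
})

test_that("within-clade similarity exceeds between-clade similarity", {
  cat_in <- gen_phylogeny(phylogeny_scenario(n_clades = 2L, tree_depth = 3L,
                                             n_strains_per_clade = 40L,
                                             outlier_rate = 0, seed = 6L))
  emb <- train_skipgram(cat_in, d = 16L, window = 20L, epochs = 5L, seed = 2L)
  sv <- emb$strain_vectors
  cl <- cat_in$clades[match(rownames(sv), cat_in$strains)]
  S <- 1 - cosine_dissimilarity(sv)
  same <- outer(cl, cl, "==") & upper.tri(S)
  diff_cl <- outer(cl, cl, "!=") & upper.tri(S)
  expect_gt(mean(S[same]), mean(S[diff_cl]))
})

test_that("cosine dissimilarity spans [0, 2] on canonical cases", {
  v <- rbind(c(1, 0), c(2, 0), c(0, 3), c(-1, 0))
  D <- cosine_dissimilarity(v)
  expect_equal(D[1L, 2L], 0)
  expect_equal(D[1L, 3L], 1)
  expect_equal(D[1L, 4L], 2)
  expect_equal(diag(D), rep(0, 4))
  expect_true(isSymmetric(D))
  expect_error(cosine_dissimilarity(rbind(c(0, 0), c(1, 1))), "zero-norm")
})

test_that("MDS reproduces simple geometries and rejects bad input", {
  # three mutually equidistant points form an equilateral triangle
  D3 <- matrix(1, 3, 3); diag(D3) <- 0
  pr <- mds_project(D3, seed = 1L)
  d <- as.matrix(dist(pr$coordinates))
  off <- d[upper.tri(d)]
  expect_lt(max(off) - min(off), 1e-6)
  expect_lt(pr$stress, 1e-4)

  # two points: distance preserved exactly
  D2 <- matrix(c(0, 1.7, 1.7, 0), 2, 2)
  pr2 <- mds_project(D2, seed = 1L)
  expect_equal(as.numeric(dist(pr2$coordinates)), 1.7, tolerance = 1e-8)
  expect_equal(pr2$stress, 0, tolerance = 1e-8)

  expect_error(mds_project(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  expect_error(mds_project(matrix(c(0, -1, -1, 0), 2, 2)), "negative")
})
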