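#' Mutation catalog for a set of viral strains
#'
#' Holds, per strain, the list of amino-acid mutation tokens it carries
#' (e.g. `"S:N501Y"`, `"ORF1a:T3255I"`, deletions like `"S:H69-"`), plus an
#' optional clade label. Tokens follow the `<gene>:<ref><pos><alt>` syntax
#' and must be unique within a strain.
#'
#' @param strains Character vector of unique strain identifiers.
#' @param tokens List of character vectors, one per strain.
#' @param clades Optional character vector of clade labels per strain.
#' @return Object of class `mutation_catalog`.
#' @export
mutation_catalog <- function(strains, tokens, clades = NULL) {
  strains <- as.character(strains)
  if (anyDuplicated(strains)) stop("duplicate strain identifiers", call. = FALSE)
  if (length(tokens) != length(strains))
    stop("one token list per strain required", call. = FALSE)
  tokens <- lapply(tokens, as.character)
  ok <- vapply(tokens, function(tk) {
    length(tk) == 0L ||
      (all(grepl("^[A-Za-z0-9_]+:[A-Z*][0-9]+[A-Z*-]+$", tk)) && !anyDuplicated(tk))
  }, logical(1L))
  if (!all(ok))
    stop("invalid or duplicated mutation tokens in strain(s): ",
         paste(utils::head(strains[!ok]), collapse = ", "), call. = FALSE)
  if (!is.null(clades)) {
    clades <- as.character(clades)
    if (length(clades) != length(strains))
      stop("one clade label per strain required", call. = FALSE)
  }
  structure(list(strains = strains, tokens = tokens, clades = clades),
            class = "mutation_catalog")
}

#' @export
print.mutation_catalog <- function(x, ...) {
  cat(sprintf("<mutation_catalog: %d strains, %d unique tokens%s>\n",
              length(x$strains), length(unique(unlist(x$tokens))),
              if (is.null(x$clades)) "" else sprintf(", %d clades",
                                                     length(unique(x$clades)))))
  invisible(x)
}

#' @export
length.mutation_catalog <- function(x) length(x$strains)

#' Read/write mutation catalogs
#'
#' Two plain-text formats are supported: TSV with columns
#' `strain_id<TAB>tokens` (comma-separated) and optional `clade`, and
#' JSON-lines with objects `{"strain": ..., "mutations": [...], "clade": ...}`.
#' The format is chosen by file extension (`.jsonl`/`.json` vs anything
#' else).
#'
#' @param path File path.
#' @return A [mutation_catalog()] (for the reader); `path` invisibly (writer).
#' @export
read_mutation_catalog <- function(path) {
  if (grepl("\\.jsonl?$", path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, jsonlite::fromJSON)
    mutation_catalog(
      strains = vapply(recs, `[[`, character(1L), "strain"),
      tokens = lapply(recs, function(r) as.character(r$mutations)),
      clades = if (all(vapply(recs, function(r) !is.null(r$clade), logical(1L))))
        vapply(recs, `[[`, character(1L), "clade") else NULL)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, quote = "",
                            comment.char = "")
    toks <- lapply(strsplit(df$tokens, ",", fixed = TRUE),
                   function(tk) tk[nzchar(tk)])
    mutation_catalog(df$strain_id, toks,
                     clades = if ("clade" %in% names(df)) df$clade else NULL)
  }
}

#' @rdname read_mutation_catalog
#' @param catalog A [mutation_catalog()].
#' @export
write_mutation_catalog <- function(catalog, path) {
  if (grepl("\\.jsonl?$", path)) {
    lines <- vapply(seq_along(catalog$strains), function(i) {
      rec <- list(strain = catalog$strains[i],
                  mutations = catalog$tokens[[i]])
      if (!is.null(catalog$clades)) rec$clade <- catalog$clades[i]
      jsonlite::toJSON(rec, auto_unbox = TRUE)
    }, character(1L))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    df <- data.frame(
      strain_id = catalog$strains,
      tokens = vapply(catalog$tokens, paste, character(1L), collapse = ","),
      stringsAsFactors = FALSE)
    if (!is.null(catalog$clades)) df$clade <- catalog$clades
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Binary mutation-presence encoding
#'
#' Encodes each strain as a 0/1 vector over the catalog's unique mutation
#' tokens: one column per mutation, 1 if the strain carries it. Columns
#' are ordered by first appearance (scanning strains in order, tokens
#' within a strain lexicographically).
#'
#' @param catalog A [mutation_catalog()].
#' @return A [feature_matrix()] (view `"viral_binary"`) of size
#'   strains x unique tokens.
#' @export
binary_encode <- function(catalog) {
  stopifnot(inherits(catalog, "mutation_catalog"))
  if (length(catalog$strains) == 0L) stop("empty strain list", call. = FALSE)
  vocab <- unique(unlist(lapply(catalog$tokens, sort)))
  mat <- matrix(0, length(catalog$strains), length(vocab),
                dimnames = list(catalog$strains, vocab))
  for (i in seq_along(catalog$tokens))
    mat[i, catalog$tokens[[i]]] <- 1
  feature_matrix(mat, view_name = "viral_binary")
}

#' Remove strains with outlying mutation counts
#'
#' Flags strains whose token count falls below \eqn{Q_1 - 1.5\,IQR} or
#' above \eqn{Q_3 + 1.5\,IQR}, with quartiles computed by linear
#' interpolation (type 7).
#'
#' @param catalog A [mutation_catalog()] with at least 4 strains.
#' @return List with `catalog` (filtered) and `removed` (strain ids).
#' @export
iqr_filter <- function(catalog) {
  stopifnot(inherits(catalog, "mutation_catalog"))
  if (length(catalog$strains) < 4L) stop("need at least 4 strains", call. = FALSE)
  counts <- lengths(catalog$tokens)
  q <- stats::quantile(counts, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2L] - q[1L]
  keep <- counts >= q[1L] - 1.5 * iqr & counts <= q[2L] + 1.5 * iqr
  list(catalog = mutation_catalog(catalog$strains[keep], catalog$tokens[keep],
                                  clades = catalog$clades[keep]),
       removed = catalog$strains[!keep])
}

# order tokens within a strain by genomic coordinate (gene, then position)
order_tokens <- function(tokens) {
  if (length(tokens) == 0L) return(tokens)
  gene <- sub(":.*$", "", tokens)
  pos <- as.integer(sub("^[^:]+:[A-Z*]([0-9]+).*$", "\\1", tokens))
  tokens[order(gene, pos, tokens)]
}

#' Train skip-gram embeddings of mutation tokens
#'
#' Treats amino-acid mutations as words and strains as sentences (tokens
#' ordered by genomic coordinate), and trains skip-gram word vectors with
#' negative sampling. Strain vectors are the mean of their tokens'
#' vectors. Training is single-threaded with a self-contained generator,
#' so results are bit-identical for a given seed.
#'
#' With `window` at least the longest sentence, every token in a strain is
#' context for every other, which is the intended regime for unordered
#' mutation sets.
#'
#' @param catalog A [mutation_catalog()] (outlier-filter beforehand with
#'   [iqr_filter()] when emulating the full preprocessing).
#' @param d Embedding dimension.
#' @param window Context window (tokens to each side).
#' @param epochs Training epochs.
#' @param seed Integer seed.
#' @param negative Negative samples per positive pair.
#' @param min_count Minimum token frequency kept in the vocabulary.
#' @param lr,lr_min Initial and final learning rate (linear decay).
#' @return Object of class `strain_embedding`: `token_vectors`
#'   (vocabulary x d), `strain_vectors` (strains x d), `vocab`, `excluded`
#'   (strains with no in-vocabulary tokens), and the training parameters.
#' @export
train_skipgram <- function(catalog, d = 300L, window = 115L, epochs = 10L,
                           seed = 1L, negative = 5L, min_count = 1L,
                           lr = 0.025, lr_min = 1e-4) {
  stopifnot(inherits(catalog, "mutation_catalog"))
  sentences <- lapply(catalog$tokens, order_tokens)
  counts <- table(unlist(sentences))
  vocab <- names(counts)[counts >= min_count]
  if (length(vocab) == 0L) stop("empty vocabulary after min_count filter", call. = FALSE)
  vocab <- vocab[order(match(vocab, names(counts)))]
  idx <- stats::setNames(seq_along(vocab) - 1L, vocab)
  sent_ids <- lapply(sentences, function(tk) unname(idx[tk[tk %in% vocab]]))
  tv <- .sgns_train(sent_ids, as.integer(counts[vocab]), as.integer(d),
                    as.integer(window), as.integer(epochs), as.integer(negative),
                    lr, lr_min, as.integer(seed))
  rownames(tv) <- vocab
  emb <- structure(list(token_vectors = tv, d = as.integer(d),
                        window = as.integer(window), vocab = vocab,
                        epochs = as.integer(epochs), seed = as.integer(seed)),
                   class = "strain_embedding")
  sv <- embed_new_strains(emb, catalog)
  emb$strain_vectors <- sv$vectors
  emb$excluded <- sv$excluded
  emb
}

#' @export
print.strain_embedding <- function(x, ...) {
  cat(sprintf("<strain_embedding: |vocab|=%d, d=%d, window=%d, %d strains>\n",
              length(x$vocab), x$d, x$window,
              if (is.null(x$strain_vectors)) 0L else nrow(x$strain_vectors)))
  invisible(x)
}

#' Embed strains as mean mutation vectors
#'
#' Each strain's vector is the arithmetic mean of its in-vocabulary
#' tokens' vectors. Out-of-vocabulary tokens are skipped (and counted);
#' strains with no in-vocabulary token are excluded and reported.
#'
#' @param embedding A trained `strain_embedding`.
#' @param catalog A [mutation_catalog()] of strains to embed.
#' @return List with `vectors` (strains x d matrix), `excluded` (strain
#'   ids with no in-vocabulary tokens), and `oov_tokens` (count skipped).
#' @export
embed_new_strains <- function(embedding, catalog) {
  stopifnot(inherits(embedding, "strain_embedding"),
            inherits(catalog, "mutation_catalog"))
  tv <- embedding$token_vectors
  oov <- 0L
  rows <- lapply(catalog$tokens, function(tk) {
    known <- tk[tk %in% embedding$vocab]
    oov <<- oov + (length(tk) - length(known))
    if (length(known) == 0L) return(NULL)
    colMeans(tv[known, , drop = FALSE])
  })
  keep <- !vapply(rows, is.null, logical(1L))
  if (oov > 0L) message(sprintf("skipped %d out-of-vocabulary token(s)", oov))
  vectors <- do.call(rbind, rows[keep])
  rownames(vectors) <- catalog$strains[keep]
  list(vectors = vectors, excluded = catalog$strains[!keep], oov_tokens = oov)
}

#' Pairwise cosine dissimilarity
#'
#' \eqn{D_{ij} = 1 - \cos(v_i, v_j)}: 0 for identical directions, 1 for
#' orthogonal, 2 for opposite vectors.
#'
#' @param vectors n x d matrix with no zero-norm rows.
#' @return Symmetric n x n dissimilarity matrix with zero diagonal.
#' @export
cosine_dissimilarity <- function(vectors) {
  vectors <- as.matrix(vectors)
  nrm <- sqrt(rowSums(vectors^2))
  if (any(nrm == 0)) stop("zero-norm row(s) in input", call. = FALSE)
  S <- tcrossprod(vectors / nrm)
  D <- 1 - pmin(pmax(S, -1), 1)
  diag(D) <- 0
  D
}

#' Metric MDS projection by stress majorization
#'
#' Projects a precomputed dissimilarity matrix to `ndim` dimensions by
#' SMACOF-style stress majorization, initialized from classical scaling
#' (seeded random jitter only when that initialization is degenerate).
#' Reports Kruskal's normalized stress-1,
#' \eqn{\sqrt{\sum_{i<j}(d_{ij}-\delta_{ij})^2 / \sum_{i<j}\delta_{ij}^2}}.
#'
#' @param D Symmetric non-negative dissimilarity matrix, zero diagonal.
#' @param seed Integer seed (used only for degenerate initialization).
#' @param ndim Output dimension (default 2).
#' @param maxit,tol Majorization iteration controls.
#' @param method `"smacof"` (default) or `"classical"`
#'   ([stats::cmdscale()] only).
#' @return Object of class `projection2d`: `coordinates` (n x ndim),
#'   `stress`, and the `dissimilarity` used.
#' @export
mds_project <- function(D, seed = 1L, ndim = 2L, maxit = 300L, tol = 1e-9,
                        method = c("smacof", "classical")) {
  method <- match.arg(method)
  D <- as.matrix(D)
  n <- nrow(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("dissimilarity must be symmetric", call. = FALSE)
  if (any(D < -1e-12)) stop("negative dissimilarities", call. = FALSE)
  D <- (D + t(D)) / 2
  X <- suppressWarnings(stats::cmdscale(D, k = min(ndim, n - 1L)))
  if (ncol(X) < ndim) X <- cbind(X, matrix(0, n, ndim - ncol(X)))
  if (any(!is.finite(X)) || all(X == 0)) {
    X <- with_seed(seed, matrix(stats::rnorm(n * ndim, sd = 1e-3), n, ndim))
  }
  stress_num <- function(X) {
    d <- as.matrix(stats::dist(X))
    sum((d[upper.tri(d)] - D[upper.tri(D)])^2)
  }
  denom <- sum(D[upper.tri(D)]^2)
  if (method == "smacof" && n > 2L) {
    s_old <- stress_num(X)
    for (it in seq_len(maxit)) {
      d <- as.matrix(stats::dist(X))
      ratio <- ifelse(d > 1e-12, D / d, 0)
      B <- -ratio
      diag(B) <- 0
      diag(B) <- -rowSums(B)
      X <- B %*% X / n                       # Guttman transform (V = n*J)
      X <- sweep(X, 2L, colMeans(X), "-")
      s_new <- stress_num(X)
      if (s_old - s_new < tol * (s_old + 1e-12)) break
      s_old <- s_new
    }
  }
  stress <- if (denom > 0) sqrt(stress_num(X) / denom) else 0
  rownames(X) <- rownames(D)
  structure(list(coordinates = X, stress = stress, dissimilarity = D,
                 method = method),
            class = "projection2d")
}

#' @export
print.projection2d <- function(x, ...) {
  cat(sprintf("<projection2d: %d points, stress %.4f (%s)>\n",
              nrow(x$coordinates), x$stress, x$method))
  invisible(x)
}
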