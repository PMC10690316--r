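#' Construct a feature matrix for one data view
#'
#' A feature matrix is the basic container for one data modality ("view"):
#' an \eqn{n \times p} numeric matrix of \eqn{n} samples by \eqn{p} features,
#' with unique sample and feature identifiers and a view label.
#'
#' @param values Numeric matrix (samples in rows, features in columns).
#' @param sample_ids Character vector of unique sample identifiers (length
#'   `nrow(values)`).
#' @param feature_names Character vector of unique feature names (length
#'   `ncol(values)`).
#' @param view_name Single string labelling the view (e.g. `"labs"`,
#'   `"radiomics"`).
#' @param allow_missing Logical; permit `NA` entries (only sensible before a
#'   completeness filter). Non-finite values other than `NA` always error.
#'
#' @return An object of class `feature_matrix`: a list with elements
#'   `view_name` and `values` (a numeric matrix carrying the identifiers as
#'   dimnames).
#' @export
feature_matrix <- function(values, sample_ids = rownames(values),
                           feature_names = colnames(values),
                           view_name = "view", allow_missing = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2L || ncol(values) < 1L)
    stop("feature matrix needs at least 2 samples and 1 feature", call. = FALSE)
  if (is.null(sample_ids) || is.null(feature_names))
    stop("sample_ids and feature_names are required", call. = FALSE)
  sample_ids <- as.character(sample_ids)
  feature_names <- as.character(feature_names)
  if (length(sample_ids) != nrow(values) || length(feature_names) != ncol(values))
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(feature_names))
    stop("duplicate feature names: ",
         paste(unique(feature_names[duplicated(feature_names)]), collapse = ", "),
         call. = FALSE)
  bad <- !is.finite(values)
  if (allow_missing) bad <- bad & !is.na(values)
  if (any(bad))
    stop("non-finite values in view '", view_name, "'", call. = FALSE)
  dimnames(values) <- list(sample_ids, feature_names)
  structure(list(view_name = as.character(view_name)[1L], values = values),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix '%s': %d samples x %d features>\n",
              x$view_name, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @rdname feature_matrix
#' @param x A `feature_matrix`.
#' @export
sample_ids <- function(x) UseMethod("sample_ids")

#' @export
sample_ids.feature_matrix <- function(x) rownames(x$values)

#' @export
sample_ids.multiview_dataset <- function(x) x$sample_ids

#' @export
dim.feature_matrix <- function(x) dim(x$values)

as_feature_values <- function(x) {
  if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
}

sniff_delimiter <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L) stop("empty file: ", path, call. = FALSE)
  # whichever of tab / comma splits the header into more fields wins
  n_tab <- length(strsplit(header, "\t", fixed = TRUE)[[1L]])
  n_com <- length(strsplit(header, ",", fixed = TRUE)[[1L]])
  if (n_tab >= n_com) "\t" else ","
}

#' Read a feature matrix from a delimited text file
#'
#' The file must have a header row; the first column holds the sample
#' identifier and every remaining column must be numeric. The delimiter
#' (comma or tab) is sniffed from the header line, so `.csv` and `.tsv`
#' twins of the same table parse identically.
#'
#' @param path Path to a CSV/TSV file.
#' @param view_name View label for the resulting matrix.
#' @param allow_missing Passed to [feature_matrix()].
#' @return A [feature_matrix()].
#' @export
read_feature_matrix <- function(path, view_name = tools::file_path_sans_ext(basename(path)),
                                allow_missing = FALSE) {
  sep <- sniff_delimiter(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", comment.char = "",
                          quote = "\"", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected a sample-id column plus at least one feature", call. = FALSE)
  ids <- df[[1L]]
  payload <- df[, -1L, drop = FALSE]
  num <- vapply(payload, function(col) {
    suppressWarnings(as.numeric(col))
  }, numeric(nrow(df)))
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(df), dimnames = list(NULL, names(payload)))
  non_numeric <- is.na(num) & !(trimws(as.matrix(payload)) %in% c("NA", ""))
  if (any(non_numeric)) {
    bad <- which(non_numeric, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at row %d, column '%s'",
                 bad[1L], names(payload)[bad[2L]]), call. = FALSE)
  }
  feature_matrix(num, sample_ids = ids, feature_names = names(payload),
                 view_name = view_name, allow_missing = allow_missing)
}

#' Write a feature matrix to a delimited text file
#'
#' Values are written with 17 significant digits so that a
#' read/write round trip reproduces finite doubles bit-identically.
#'
#' @param fm A [feature_matrix()].
#' @param path Output path.
#' @param sep Field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path, sep = ",") {
  stopifnot(inherits(fm, "feature_matrix"))
  vals <- fm$values
  header <- paste(c("sample_id", colnames(vals)), collapse = sep)
  body <- vapply(seq_len(nrow(vals)), function(i) {
    paste(c(rownames(vals)[i], sprintf("%.17g", vals[i, ])), collapse = sep)
  }, character(1L))
  writeLines(c(header, body), con = path, useBytes = TRUE)
  invisible(path)
}

#' Read a binary outcome file
#'
#' Expects columns `sample_id` and `outcome` with values in \{0, 1\}.
#'
#' @param path CSV/TSV path.
#' @return Named integer vector of 0/1 outcomes.
#' @export
read_outcome <- function(path) {
  sep <- sniff_delimiter(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "outcome") %in% names(df)))
    stop("outcome file needs columns 'sample_id' and 'outcome'", call. = FALSE)
  y <- df$outcome
  if (!all(y %in% c(0, 1))) stop("outcome values must be 0/1", call. = FALSE)
  stats::setNames(as.integer(y), as.character(df$sample_id))
}

#' Align several views (and an optional outcome) on common samples
#'
#' Restricts all views to the intersection of their sample identifiers, in
#' lexicographically sorted order, mirroring the usual cohort bookkeeping in
#' which each analysis uses the patients for whom every required modality is
#' available. Rows containing missing values are dropped (per view, before
#' intersecting) and counted.
#'
#' @param views List of [feature_matrix()] objects (at least 2).
#' @param outcome Optional named 0/1 vector; subset to the common samples.
#' @return An object of class `multiview_dataset`: list with `views` (named
#'   list of aligned feature matrices), `outcome` (or `NULL`), `sample_ids`,
#'   and `counts` (per-view and intersection sample counts).
#' @export
align_views <- function(views, outcome = NULL) {
  if (!is.list(views) || length(views) < 2L)
    stop("need at least two views", call. = FALSE)
  views <- lapply(views, function(v) {
    if (!inherits(v, "feature_matrix")) stop("views must be feature_matrix objects", call. = FALSE)
    miss <- rowSums(is.na(v$values)) > 0L
    if (any(miss)) {
      message(sprintf("view '%s': dropping %d sample(s) with missing values",
                      v$view_name, sum(miss)))
      v$values <- v$values[!miss, , drop = FALSE]
    }
    v
  })
  nm <- vapply(views, `[[`, character(1L), "view_name")
  if (anyDuplicated(nm)) nm <- make.unique(nm)
  names(views) <- nm
  ids <- Reduce(intersect, lapply(views, function(v) rownames(v$values)))
  if (length(ids) == 0L) stop("no samples shared by all views", call. = FALSE)
  ids <- sort(ids)
  counts <- c(vapply(views, function(v) nrow(v$values), integer(1L)),
              intersection = length(ids))
  views <- lapply(views, function(v) {
    v$values <- v$values[ids, , drop = FALSE]
    v
  })
  if (!is.null(outcome)) {
    if (is.null(names(outcome))) stop("outcome must be named by sample id", call. = FALSE)
    if (!all(ids %in% names(outcome)))
      stop("outcome missing for samples: ",
           paste(utils::head(setdiff(ids, names(outcome))), collapse = ", "), call. = FALSE)
    outcome <- outcome[ids]
    if (!all(outcome %in% c(0L, 1L))) stop("outcome must be binary 0/1", call. = FALSE)
  }
  structure(list(views = views, outcome = outcome, sample_ids = ids,
                 counts = counts),
            class = "multiview_dataset")
}

#' @export
print.multiview_dataset <- function(x, ...) {
  cat(sprintf("<multiview_dataset: %d samples, %d views%s>\n",
              length(x$sample_ids), length(x$views),
              if (is.null(x$outcome)) "" else ", with outcome"))
  for (v in x$views)
    cat(sprintf("  %-12s %d features\n", v$view_name, ncol(v$values)))
  invisible(x)
}

#' Standardize every view of a multi-view dataset
#'
#' Centers each feature to mean zero and scales to unit standard deviation
#' (denominator \eqn{n-1}). Zero-variance features are dropped with a
#' warning. The estimated transform is attached so it can be re-applied to
#' held-out samples without leaking their statistics (see
#' [apply_standardization()]).
#'
#' @param dataset A `multiview_dataset`.
#' @return The standardized dataset, with attribute `"scaling"`: a per-view
#'   list of `center`, `scale`, and `dropped` feature names.
#' @export
standardize <- function(dataset) {
  stopifnot(inherits(dataset, "multiview_dataset"))
  scaling <- vector("list", length(dataset$views))
  names(scaling) <- names(dataset$views)
  for (k in seq_along(dataset$views)) {
    v <- dataset$views[[k]]
    ctr <- colMeans(v$values)
    scl <- apply(v$values, 2L, stats::sd)
    keep <- scl > 0
    if (!any(keep))
      stop(sprintf("view '%s': all features have zero variance", v$view_name), call. = FALSE)
    if (any(!keep))
      warning(sprintf("view '%s': dropping %d zero-variance feature(s)",
                      v$view_name, sum(!keep)), call. = FALSE)
    scaling[[k]] <- list(center = ctr[keep], scale = scl[keep],
                         dropped = colnames(v$values)[!keep])
    v$values <- sweep(sweep(v$values[, keep, drop = FALSE], 2L, ctr[keep], "-"),
                      2L, scl[keep], "/")
    dataset$views[[k]] <- v
  }
  attr(dataset, "scaling") <- scaling
  dataset
}

#' Apply a stored standardization transform to new samples
#'
#' @param scaling The `"scaling"` attribute produced by [standardize()] on
#'   training data.
#' @param dataset A `multiview_dataset` of new (e.g. held-out) samples with
#'   the same views and features.
#' @return The dataset transformed with the training means and scales.
#' @export
apply_standardization <- function(scaling, dataset) {
  stopifnot(inherits(dataset, "multiview_dataset"))
  for (k in seq_along(dataset$views)) {
    v <- dataset$views[[k]]
    sc <- scaling[[v$view_name]]
    if (is.null(sc)) sc <- scaling[[k]]
    keep <- names(sc$center)
    v$values <- sweep(sweep(v$values[, keep, drop = FALSE], 2L, sc$center, "-"),
                      2L, sc$scale, "/")
    dataset$views[[k]] <- v
  }
  attr(dataset, "scaling") <- scaling
  dataset
}

subset_dataset <- function(dataset, idx) {
  dataset$views <- lapply(dataset$views, function(v) {
    v$values <- v$values[idx, , drop = FALSE]
    v
  })
  dataset$sample_ids <- dataset$sample_ids[idx]
  if (!is.null(dataset$outcome)) dataset$outcome <- dataset$outcome[idx]
  dataset
}

view_matrices <- function(x) {
  if (inherits(x, "multiview_dataset")) lapply(x$views, `[[`, "values")
  else lapply(x, as_feature_values)
}
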