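test_that("feature matrices parse from CSV and TSV identically", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,f1,f2", "a,1,4.5", "b,2,-1", "c,3,0"), csv)
  fm <- read_feature_matrix(csv, view_name = "demo")
  expect_s3_class(fm, "feature_matrix")
  expect_equal(dim(fm), c(3L, 2L))
  expect_equal(rownames(fm$values), c("a", "b", "c"))
  expect_equal(unname(fm$values[, 1L]), c(1, 2, 3))

  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tf1\tf2", "a\t1\t4.5", "b\t2\t-1", "c\t3\t0"), tsv)
  expect_equal(read_feature_matrix(tsv, view_name = "demo"), fm)
})

test_that("malformed feature files are rejected with clear errors", {
  dup <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,f1", "a,1", "a,2", "b,1"), dup)
  expect_error(read_feature_matrix(dup), "duplicate sample identifiers")

  txt <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,f1", "a,1", "b,oops", "c,2"), txt)
  expect_error(read_feature_matrix(txt), "non-numeric cell")

  empty <- tempfile(fileext = ".csv")
  file.create(empty)
  expect_error(read_feature_matrix(empty), "empty file")
})

test_that("write/read round trip reproduces finite doubles bit-identically", {
  set.seed(5)
  vals <- matrix(rnorm(40) * 10^sample(-8:8, 40, TRUE), 8, 5)
  fm <- feature_matrix(vals, sample_ids = paste0("s", 1:8),
                       feature_names = paste0("f", 1:5), view_name = "rt")
  path <- tempfile(fileext = ".csv")
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path, view_name = "rt")
  expect_identical(back$values, fm$values)
})

test_that("align_views intersects samples in sorted order and is idempotent", {
  mk <- function(ids, nm) feature_matrix(matrix(seq_along(ids), ncol = 1),
                                         sample_ids = ids, feature_names = "f",
                                         view_name = nm)
  ds <- align_views(list(mk(c("c", "a", "b"), "v1"), mk(c("b", "c", "d"), "v2")))
  expect_equal(ds$sample_ids, c("b", "c"))
  expect_equal(rownames(ds$views$v1$values), c("b", "c"))

  same <- align_views(list(mk(c("a", "b", "c"), "v1"), mk(c("c", "b", "a"), "v2")))
  expect_equal(length(same$sample_ids), 3L)

  # idempotence
  twice <- align_views(ds$views, outcome = ds$outcome)
  expect_identical(twice$sample_ids, ds$sample_ids)
  expect_identical(view_matrices_for_test(twice), view_matrices_for_test(ds))
})

test_that("intersection size matches a brute-force set oracle on a roster", {
  set.seed(77)
  roster <- sprintf("pt%03d", 1:160)
  ids <- list(sample(roster, 127), sample(roster, 105), sample(roster, 149))
  views <- lapply(seq_along(ids), function(i)
    feature_matrix(matrix(rnorm(length(ids[[i]]) * 2), ncol = 2),
                   sample_ids = ids[[i]], feature_names = c("f1", "f2"),
                   view_name = paste0("v", i)))
  ds <- align_views(views)
  oracle <- Reduce(intersect, ids)
  expect_equal(length(ds$sample_ids), length(oracle))
  expect_equal(ds$sample_ids, sort(oracle))
  expect_equal(unname(ds$counts), c(127L, 105L, 149L, length(oracle)))
})

test_that("empty intersection is an error", {
  mk <- function(ids, nm) feature_matrix(matrix(seq_along(ids), ncol = 1),
                                         sample_ids = ids, feature_names = "f",
                                         view_name = nm)
  expect_error(align_views(list(mk(c("a", "b"), "v1"), mk(c("c", "d"), "v2"))),
               "no samples shared")
})

test_that("standardize centers and scales with the n-1 denominator", {
  fm <- feature_matrix(cbind(x = c(1, 2, 3), const = c(7, 7, 7)),
                       sample_ids = c("a", "b", "c"),
                       feature_names = c("x", "const"), view_name = "v1")
  fm2 <- feature_matrix(matrix(c(0, 5, 9), ncol = 1), sample_ids = c("a", "b", "c"),
                        feature_names = "z", view_name = "v2")
  ds <- align_views(list(fm, fm2))
  expect_warning(std <- standardize(ds), "zero-variance")
  expect_equal(unname(std$views$v1$values[, "x"]), c(-1, 0, 1))
  expect_false("const" %in% colnames(std$views$v1$values))

  # standardizing a standardized dataset is the identity
  again <- standardize(std)
  expect_equal(again$views$v1$values, std$views$v1$values, tolerance = 1e-12)

  # all-constant view is fatal
  flat <- feature_matrix(matrix(1, 3, 2), sample_ids = c("a", "b", "c"),
                         feature_names = c("p", "q"), view_name = "flat")
  expect_error(standardize(align_views(list(flat, fm2))), "zero variance")
})

test_that("stored fold-train parameters transform held-out rows exactly", {
  set.seed(11)
  X <- matrix(rnorm(60), 20, 3)
  ids <- sprintf("s%02d", 1:20)
  mk <- function(rows) align_views(list(
    feature_matrix(X[rows, , drop = FALSE], sample_ids = ids[rows],
                   feature_names = paste0("f", 1:3), view_name = "v1"),
    feature_matrix(X[rows, 1:2] + 1, sample_ids = ids[rows],
                   feature_names = c("g1", "g2"), view_name = "v2")))
  train <- mk(1:15); test <- mk(16:20)
  std_train <- standardize(train)
  params <- attr(std_train, "scaling")
  std_test <- apply_standardization(params, test)
  hand <- sweep(sweep(test$views$v1$values, 2L, params$v1$center, "-"),
                2L, params$v1$scale, "/")
  expect_equal(std_test$views$v1$values, hand, tolerance = 1e-15)
})
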