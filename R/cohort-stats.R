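#' Percentage rounded half-away-from-zero to one decimal
#'
#' The convention used in clinical characteristics tables ("63 (42.3)"):
#' `100 * count / denom`, with ties rounded away from zero rather than to
#' even.
#'
#' @param count,denom Non-negative integers, `count <= denom`, `denom > 0`.
#' @return The percentage with one decimal place.
#' @export
percent <- function(count, denom) {
  if (denom <= 0) stop("denominator must be positive", call. = FALSE)
  if (count < 0 || count > denom) stop("count must lie in [0, denom]", call. = FALSE)
  x <- 100 * count / denom
  sign(x) * floor(abs(x) * 10 + 0.5) / 10
}

as_table2x2 <- function(t) {
  if (is.matrix(t)) t <- c(t[1, 1], t[1, 2], t[2, 1], t[2, 2])
  if (length(t) != 4L || any(t < 0) || sum(t) == 0 || any(t != floor(t)))
    stop("need four non-negative integer cell counts (a, b, c, d)", call. = FALSE)
  matrix(as.numeric(t), 2L, 2L, byrow = TRUE)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Cell order is `(a, b, c, d)` read row-wise: rows are the two exposure
#' levels, columns the two groups. Yates continuity correction is applied
#' by default.
#'
#' @param t Length-4 count vector or 2x2 matrix.
#' @param continuity Apply the Yates correction (default `TRUE`).
#' @return List with `statistic`, `p`, `df` and the expected counts.
#' @export
chi_square_2x2 <- function(t, continuity = TRUE) {
  m <- as_table2x2(t)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero margin in table", call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(m, correct = continuity))
  if (any(res$expected <= 0)) stop("zero expected count", call. = FALSE)
  list(statistic = unname(res$statistic), p = res$p.value, df = 1L,
       expected = res$expected)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the probability-mass rule: the sum of
#' hypergeometric probabilities of all tables no more probable than the
#' observed one.
#'
#' @param t Length-4 count vector or 2x2 matrix (order as in
#'   [chi_square_2x2()]).
#' @return The two-sided p-value.
#' @export
fisher_exact <- function(t) {
  m <- as_table2x2(t)
  stats::fisher.test(m)$p.value
}

#' Two-group test for a continuous variable
#'
#' `normal = TRUE` gives the independent two-sided t-test (pooled variance
#' by default, Welch via `var_equal = FALSE`); otherwise the Mann-Whitney
#' U test with normal approximation and tie correction.
#'
#' @param x,y Numeric vectors (each of length \eqn{\ge 2}).
#' @param normal Is a normal model appropriate for this variable?
#' @param var_equal Pool variances in the t-test (default `TRUE`).
#' @return List with `test`, `statistic` and `p`.
#' @export
two_group_continuous <- function(x, y, normal = TRUE, var_equal = TRUE) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  if (normal) {
    if (stats::var(c(x, y)) == 0) stop("zero combined variance", call. = FALSE)
    res <- stats::t.test(x, y, var.equal = var_equal)
    list(test = if (var_equal) "t" else "welch_t",
         statistic = unname(res$statistic), p = res$p.value)
  } else {
    res <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    list(test = "mann_whitney", statistic = unname(res$statistic), p = res$p.value)
  }
}

#' Build a clinical characteristics table
#'
#' Summarizes each variable by group and attaches the appropriate
#' two-group test: categorical variables get count (percent) per group and
#' a chi-square test with Yates correction, replaced by Fisher's exact
#' test when any expected cell count is below 5; normal continuous
#' variables get mean (SD) and a t-test; non-normal continuous variables
#' get median (IQR) and a Mann-Whitney U test.
#'
#' @param data Data frame of per-patient records.
#' @param group Name of the binary (0/1 or two-level) grouping column.
#' @param schema Named character vector mapping each variable to one of
#'   `"categorical"`, `"normal"`, `"nonnormal"`.
#' @return Object of class `cohort_table`: a data frame with one row per
#'   variable (summary per group, test used, p-value).
#' @export
build_cohort_table <- function(data, group, schema) {
  stopifnot(is.data.frame(data), group %in% names(data))
  g <- data[[group]]
  lev <- sort(unique(g), decreasing = TRUE)
  if (length(lev) != 2L) stop("grouping column must have exactly two levels", call. = FALSE)
  g1 <- g == lev[1L]; g2 <- g == lev[2L]
  rows <- lapply(names(schema), function(v) {
    if (!v %in% names(data)) stop("variable not in data: ", v, call. = FALSE)
    type <- schema[[v]]
    x <- data[[v]]
    if (type == "categorical") {
      x <- as.integer(x != 0)
      tab <- c(sum(x[g1] == 1), sum(x[g1] == 0), sum(x[g2] == 1), sum(x[g2] == 0))
      expected <- suppressWarnings(stats::chisq.test(as_table2x2(tab), correct = TRUE)$expected)
      use_fisher <- any(expected < 5)
      p <- if (use_fisher) fisher_exact(tab) else chi_square_2x2(tab)$p
      data.frame(
        variable = v, type = type,
        group1 = sprintf("%d (%.1f)", tab[1L], percent(tab[1L], sum(g1))),
        group2 = sprintf("%d (%.1f)", tab[3L], percent(tab[3L], sum(g2))),
        test = if (use_fisher) "fisher" else "chi_square", p = p,
        stringsAsFactors = FALSE)
    } else if (type == "normal") {
      res <- two_group_continuous(x[g1], x[g2], normal = TRUE)
      data.frame(
        variable = v, type = type,
        group1 = sprintf("%.1f (%.1f)", mean(x[g1]), stats::sd(x[g1])),
        group2 = sprintf("%.1f (%.1f)", mean(x[g2]), stats::sd(x[g2])),
        test = res$test, p = res$p, stringsAsFactors = FALSE)
    } else if (type == "nonnormal") {
      res <- two_group_continuous(x[g1], x[g2], normal = FALSE)
      qs1 <- stats::quantile(x[g1], c(0.25, 0.5, 0.75), names = FALSE)
      qs2 <- stats::quantile(x[g2], c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(
        variable = v, type = type,
        group1 = sprintf("%.1f (%.1f-%.1f)", qs1[2L], qs1[1L], qs1[3L]),
        group2 = sprintf("%.1f (%.1f-%.1f)", qs2[2L], qs2[1L], qs2[3L]),
        test = res$test, p = res$p, stringsAsFactors = FALSE)
    } else stop("unknown variable type: ", type, call. = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "group_levels") <- lev
  attr(out, "group_n") <- c(sum(g1), sum(g2))
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Write a cohort table as CSV or Markdown
#'
#' @param x A `cohort_table`.
#' @param path Output path; format chosen by extension (`.md` for
#'   Markdown, otherwise CSV).
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(x, path) {
  df <- as.data.frame(x)
  if (grepl("\\.md$", path)) {
    n <- attr(x, "group_n")
    hdr <- sprintf("| Variable | Group 1 (n=%d) | Group 2 (n=%d) | Test | p |",
                   n[1L], n[2L])
    lines <- c(hdr, "|---|---|---|---|---|",
               sprintf("| %s | %s | %s | %s | %.3g |",
                       df$variable, df$group1, df$group2, df$test, df$p))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
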