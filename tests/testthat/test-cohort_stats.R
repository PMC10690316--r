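test_that("percentages follow the half-away-from-zero convention", {
  expect_equal(percent(63, 149), 42.3)
  expect_equal(percent(72, 149), 48.3)
  expect_equal(percent(0, 10), 0)
  expect_equal(percent(1, 8), 12.5)
  expect_equal(percent(1, 16), 6.3)     # 6.25 rounds away from zero
  expect_error(percent(5, 0), "positive")
  expect_error(percent(11, 10), "count")
  # complements sum to 100 within rounding slack
  for (cnt in c(0, 7, 38, 63, 100)) {
    s <- percent(cnt, 149) + percent(149 - cnt, 149)
    expect_lte(abs(s - 100), 0.1)
  }
})

test_that("2x2 chi-square with Yates reproduces printed cohort p-values", {
  hyp <- chi_square_2x2(c(38, 25, 34, 52))
  expect_equal(round(hyp$p, 2), 0.02)
  cad <- chi_square_2x2(c(22, 41, 11, 75))
  expect_equal(round(cad$p, 3), 0.003)
  prop <- chi_square_2x2(c(10, 10, 10, 10))
  expect_equal(prop$statistic, 0)
  expect_equal(prop$p, 1)
  # continuity correction only ever shrinks the statistic
  for (t in list(c(5, 9, 12, 3), c(30, 12, 18, 40), c(2, 8, 7, 3))) {
    expect_gte(chi_square_2x2(t, continuity = FALSE)$statistic,
               chi_square_2x2(t, continuity = TRUE)$statistic)
    expect_lte(chi_square_2x2(t, continuity = FALSE)$p,
               chi_square_2x2(t, continuity = TRUE)$p)
  }
  expect_error(chi_square_2x2(c(0, 0, 5, 5)), "margin")
})

test_that("Fisher's exact test uses the probability-mass two-sided rule", {
  expect_equal(round(fisher_exact(c(2, 61, 0, 86)), 2), 0.18)
  expect_equal(fisher_exact(c(5, 5, 5, 5)), 1)
  # fully crossed extreme table: only the two extreme arrangements count
  expect_equal(fisher_exact(c(0, 10, 10, 0)), 2 / choose(20, 10), tolerance = 1e-12)
})

test_that("chi-square and Fisher converge on well-populated tables", {
  set.seed(55)
  diffs <- vapply(1:100, function(i) {
    t <- rpois(4, 40) + 25                 # expected counts all >> 20
    abs(chi_square_2x2(t)$p - fisher_exact(t))
  }, numeric(1L))
  expect_lt(max(diffs), 0.15)
  # the two tests agree on 0.05-level significance almost always
  set.seed(55)
  agree <- vapply(1:100, function(i) {
    t <- rpois(4, 40) + 25
    (chi_square_2x2(t)$p < 0.05) == (fisher_exact(t) < 0.05)
  }, logical(1L))
  expect_gte(mean(agree), 0.95)
  # and the discrepancy shrinks as tables grow
  set.seed(66)
  big <- vapply(1:100, function(i) {
    t <- rpois(4, 400) + 100
    abs(chi_square_2x2(t)$p - fisher_exact(t))
  }, numeric(1L))
  expect_lt(mean(big), mean(diffs))
})

test_that("two-group continuous tests behave on identical and separated samples", {
  x <- c(1.2, 3.4, 2.2, 4.8, 0.6)
  expect_gte(two_group_continuous(x, x, normal = TRUE)$p, 0.99)
  expect_gte(two_group_continuous(x, x, normal = FALSE)$p, 0.99)

  # complete separation: U statistic 0, direction consistent with enumeration
  mw <- two_group_continuous(c(10, 11, 12), c(1, 2, 3), normal = FALSE)
  expect_equal(mw$statistic, 9)         # all 9 pairs favour x
  mw_rev <- two_group_continuous(c(1, 2, 3), c(10, 11, 12), normal = FALSE)
  expect_equal(mw_rev$statistic, 0)
  # exact one-sided tail by full enumeration: 1 of choose(6,3) arrangements
  combos <- combn(6, 3)
  vals <- c(1, 2, 3, 10, 11, 12)
  u_all <- apply(combos, 2L, function(idx) {
    xg <- vals[idx]; yg <- vals[-idx]
    sum(outer(xg, yg, ">")) + 0.5 * sum(outer(xg, yg, "=="))
  })
  expect_equal(mean(u_all <= 0), 1 / choose(6, 3))
  expect_error(two_group_continuous(rep(1, 3), rep(1, 4), normal = TRUE),
               "zero combined variance")
})

test_that("t-test keeps nominal size under the null", {
  set.seed(99)
  rej <- vapply(1:500, function(i) {
    two_group_continuous(rnorm(50), rnorm(50), normal = TRUE)$p < 0.05
  }, logical(1L))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
})

test_that("cohort tables count correctly and pick the right tests", {
  df <- gen_cohort(n = 149L, group_sizes = c(63L, 86L),
                   prevalences = list(hyper = c(0.60, 0.40),
                                      rare = c(0.03, 0.01)),
                   continuous_specs = list(age = list(mean = c(64, 53),
                                                      sd = c(15, 16)),
                                           los = list(mean = c(2.5, 2.2),
                                                      sd = c(0.5, 0.5),
                                                      log = TRUE)),
                   seed = 21L)
  tab <- build_cohort_table(df, "group",
                            c(hyper = "categorical", rare = "categorical",
                              age = "normal", los = "nonnormal"))
  expect_s3_class(tab, "cohort_table")
  # percentages match direct counting
  n1 <- sum(df$group == 1L)
  cnt <- sum(df$hyper[df$group == 1L])
  expect_equal(tab$group1[tab$variable == "hyper"],
               sprintf("%d (%.1f)", cnt, percent(cnt, n1)))
  # sparse variable falls back to Fisher (expected count < 5)
  expect_equal(tab$test[tab$variable == "rare"], "fisher")
  expect_equal(tab$test[tab$variable == "hyper"], "chi_square")
  expect_equal(tab$test[tab$variable == "age"], "t")
  expect_equal(tab$test[tab$variable == "los"], "mann_whitney")
  expect_true(all(tab$p >= 0 & tab$p <= 1))

  df$flat <- 1L
  expect_error(build_cohort_table(df[df$group == 1L, ], "group",
                                  c(hyper = "categorical")), "two levels")
  expect_error(build_cohort_table(df, "group", c(hyper = "weird")),
               "unknown variable type")
})
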