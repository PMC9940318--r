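test_that("Yates chi-squared matches base R and its closed form", {
  t <- contingency_2x2(57, 23, 41, 39)
  y <- yates_chi2(t)
  ref <- chisq.test(matrix(c(57, 23, 41, 39), 2, byrow = TRUE),
                    correct = TRUE)
  expect_equal(y$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(y$p, ref$p.value, tolerance = 1e-12)
  ## identical rows: statistic clamps at zero, p = 1
  y0 <- yates_chi2(contingency_2x2(10, 10, 10, 10))
  expect_equal(y0$statistic, 0)
  expect_equal(y0$p, 1)
  expect_error(yates_chi2(contingency_2x2(0, 0, 5, 5)), "margin")
})

test_that("selection-count p-values reproduce the published table", {
  sel <- reference_selection_counts()
  row_p <- function(section, row) {
    r <- sel[sel$section == section & sel$row == row, ]
    compare_proportions(r$standard_x, r$standard_n,
                        r$computer_x, r$computer_n)
  }
  e <- row_p("anaortic_preference", "E")
  expect_equal(e$test, "chi-squared")
  expect_equal(round(e$p, 3), 0.015)
  expect_equal(round(row_p("aortic_preference", "C")$p, 3), 0.746)
  expect_equal(round(row_p("ideal_selected", "aortic")$p, 3), 0.743)
  i <- row_p("anaortic_preference", "I")
  expect_equal(i$test, "fisher")
  expect_equal(round(i$p, 3), 0.497)
  expect_equal(row_p("anaortic_preference", "G")$p, 1)
  ## rows testing zero-vs-zero selections are degenerate and exactly 1
  expect_equal(row_p("anaortic_preference", "L")$p, 1)
  ## remaining printed rows agree to within rounding of the 3rd decimal
  for (rr in c("A", "B", "D")) {
    r <- sel[sel$section == "aortic_preference" & sel$row == rr, ]
    expect_lt(abs(compare_proportions(r$standard_x, r$standard_n,
                                      r$computer_x, r$computer_n)$p -
                    r$printed_p), 1.5e-3)
  }
})

test_that("Fisher exact equals full margin enumeration for small tables", {
  enum_fisher <- function(a, b, c, d) {
    r1 <- a + b; c1 <- a + c; n <- a + b + c + d
    as <- max(0, c1 - (n - r1)):min(r1, c1)
    probs <- dhyper(as, r1, n - r1, c1)
    p_obs <- dhyper(a, r1, n - r1, c1)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  set.seed(11)
  for (i in 1:60) {
    x <- as.integer(rmultinom(1, sample(4:30, 1), rep(0.25, 4)))
    p1 <- fisher_exact(contingency_2x2(x[1], x[2], x[3], x[4]))
    p2 <- enum_fisher(x[1], x[2], x[3], x[4])
    expect_equal(p1, p2, tolerance = 1e-10)
  }
  expect_equal(fisher_exact(contingency_2x2(0, 10, 0, 10)), 1)
})

test_that("the proportion-comparison policy switches on expected counts", {
  expect_equal(compare_proportions(57, 80, 41, 80)$test, "chi-squared")
  expect_equal(compare_proportions(0, 80, 2, 80)$test, "fisher")
  expect_equal(compare_proportions(0, 1, 0, 1)$p, 1)
})

test_that("exact McNemar follows the binomial closed form", {
  expect_equal(mcnemar_exact(13, 0), 2 * 0.5^13)
  expect_lt(mcnemar_exact(13, 0), 0.001)
  expect_equal(mcnemar_exact(2, 0), 0.5)
  expect_equal(mcnemar_exact(0, 0), 1)
  expect_equal(mcnemar_exact(4, 4), 1)
  ## symmetric in its arguments
  expect_equal(mcnemar_exact(3, 9), mcnemar_exact(9, 3))
})

test_that("paired t matches the closed form and is antisymmetric", {
  set.seed(3)
  x <- rnorm(12)
  y <- x - 0.7 + rnorm(12, sd = 0.3)
  r <- paired_t(x, y)
  d <- x - y
  t_manual <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(r$t, t_manual, tolerance = 1e-12)
  expect_equal(r$p, 2 * pt(abs(t_manual), length(d) - 1, lower.tail = FALSE),
               tolerance = 1e-12)
  r2 <- paired_t(y, x)
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)
  expect_error(paired_t(x, x), "zero variance")
})

test_that("nonparametric fallbacks return valid p-values", {
  set.seed(5)
  x <- rnorm(15)
  y <- rnorm(15, 1)
  expect_lt(mann_whitney_u(x, y), 0.05)
  expect_gt(wilcoxon_signed_rank(x, x + rnorm(15, 0, 1e-1)), 0.01)
})
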