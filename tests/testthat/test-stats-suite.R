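test_that("signed-rank statistic and exact p match hand enumeration", {
  res <- wilcoxon_signed_rank(c(1, 2, 3), alternative = "greater")
  expect_equal(unname(res$statistic["V"]), 6)
  expect_equal(res$p_value, 1 / 8)   # 1 of 2^3 sign patterns reaches V = 6
  expect_true(res$exact)

  res10 <- wilcoxon_signed_rank(seq(0.5, 5, by = 0.5), alternative = "greater")
  expect_equal(res10$p_value, 1 / 1024)

  # symmetric two-point sample, checked against the literal oracle
  orc <- wilcoxon_enumeration_oracle(c(-1, 1), alternative = "two.sided")
  res2 <- wilcoxon_signed_rank(c(-1, 1), alternative = "two.sided")
  expect_equal(unname(res2$statistic["V"]), orc$V)
  expect_equal(res2$p_value, orc$p_value)

  expect_error(wilcoxon_signed_rank(c(0, 0), alternative = "greater"),
               class = "rfidforage_undefined_test_error")
  expect_error(wilcoxon_signed_rank(c(1, 2)), "alternative",
               class = "rfidforage_config_error")
})

test_that("exact signed-rank p agrees with enumeration and wilcox.test for n <= 10", {
  set.seed(101)
  for (i in 1:15) {
    n <- sample(3:10, 1)
    x <- round(rnorm(n, 0.3, 1), 2)
    x <- x[x != 0]
    if (length(x) < 2) next
    alt <- sample(c("greater", "less", "two.sided"), 1)
    mine <- wilcoxon_signed_rank(x, alternative = alt)
    orc <- wilcoxon_enumeration_oracle(x, alternative = alt)
    expect_equal(mine$p_value, orc$p_value)
    if (!any(duplicated(abs(x)))) {  # wilcox.test is exact only without ties
      ref <- stats::wilcox.test(x, alternative = alt, exact = TRUE)
      expect_equal(mine$p_value, ref$p.value)
      expect_equal(unname(mine$statistic["V"]), unname(ref$statistic))
    }
  }
})

test_that("large-sample signed-rank approximation matches wilcox.test", {
  set.seed(5)
  x <- rnorm(40, 0.2)
  for (alt in c("greater", "less", "two.sided")) {
    mine <- wilcoxon_signed_rank(x, alternative = alt)
    ref <- stats::wilcox.test(x, alternative = alt, exact = FALSE,
                              correct = TRUE)
    expect_false(mine$exact)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("chi-square goodness of fit matches the formula and chisq.test", {
  expect_equal(unname(chi_square_proportions(c(50, 50), c(0.5, 0.5))$statistic),
               0)
  expect_equal(chi_square_proportions(c(50, 50), c(0.5, 0.5))$p_value, 1)
  expect_equal(unname(chi_square_proportions(c(60, 40), c(0.5, 0.5))$statistic),
               4)

  set.seed(2)
  for (i in 1:10) {
    k <- sample(2:5, 1)
    obs <- rpois(k, 30)
    prop <- rexp(k); prop <- prop / sum(prop)
    mine <- chi_square_proportions(obs, prop)
    ref <- suppressWarnings(stats::chisq.test(obs, p = prop))
    expect_equal(unname(mine$statistic), unname(ref$statistic),
                 tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
  expect_error(chi_square_proportions(c(10, 10), c(1, 0)),
               class = "rfidforage_config_error")
})

test_that("paired t matches hand arithmetic and t.test", {
  res <- paired_t_test(c(2, 4), c(1, 1))      # d = (1, 3)
  expect_equal(unname(res$statistic), 2)
  expect_equal(res$df, 1L)

  expect_error(paired_t_test(1:5, 1:5),
               class = "rfidforage_undefined_test_error")

  zero_mean <- paired_t_test(c(1, -1, 2, -2), c(0, 0, 0, 0))
  expect_equal(unname(zero_mean$statistic), 0)
  expect_equal(zero_mean$p_value, 1)

  set.seed(3)
  x <- rnorm(15); y <- rnorm(15)
  for (alt in c("two.sided", "greater", "less")) {
    mine <- paired_t_test(x, y, alternative = alt)
    ref <- stats::t.test(x, y, paired = TRUE, alternative = alt)
    expect_equal(unname(mine$statistic), unname(ref$statistic),
                 tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("least squares matches closed form, lm, and the offset slope test", {
  perfect <- ols_regression(1:3, 1:3, null_slope = 1)
  expect_equal(unname(perfect$coefficients),
               c(0, 1))
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$f_statistic, 0)

  prop <- ols_regression(c(1, 2, 3), c(2, 4, 6))
  expect_equal(unname(prop$coefficients["slope"]), 2)
  expect_equal(unname(prop$coefficients["intercept"]), 0)

  flat <- ols_regression(1:5, rep(3, 5))
  expect_equal(unname(flat$coefficients["slope"]), 0)
  expect_equal(flat$r_squared, 0)

  expect_error(ols_regression(rep(1, 5), rnorm(5)),
               class = "rfidforage_rank_error")
  expect_error(ols_regression(c(0, 1, 2), 1:3, log_x = TRUE),
               class = "rfidforage_data_error")

  set.seed(11)
  x <- runif(30, 1, 10); y <- 2 + 0.8 * x + rnorm(30, 0, 0.5)
  mine <- ols_regression(x, y, null_slope = 1)
  ref <- stats::lm(y ~ x)
  expect_equal(unname(mine$coefficients), unname(coef(ref)),
               tolerance = 1e-12)
  expect_equal(mine$r_squared, summary(ref)$r.squared, tolerance = 1e-12)
  # offset construction: F test of slope against 1
  ref_f <- stats::anova(stats::lm(y ~ 1 + offset(x)), ref)
  expect_equal(mine$f_statistic, ref_f$F[2], tolerance = 1e-12)
  expect_equal(mine$f_p_value, ref_f$`Pr(>F)`[2], tolerance = 1e-12)
})

test_that("nested F test matches anova and handles degenerate fits", {
  x <- c(1, 2, 3, 4, 5)
  linear_y <- 2 * x + 1
  f_lin <- nested_f_test(ols_regression(x, linear_y),
                         ols_regression(x, linear_y, degree = 2))
  expect_equal(unname(f_lin$statistic), 0, tolerance = 1e-8)

  quad_y <- x^2
  f_quad <- nested_f_test(ols_regression(x, quad_y),
                          ols_regression(x, quad_y, degree = 2))
  expect_true(is.infinite(unname(f_quad$statistic)))
  expect_equal(f_quad$p_value, 0)
  expect_true(f_quad$degenerate)

  set.seed(9)
  xx <- runif(25, 0, 4); yy <- 1 + xx + 0.3 * xx^2 + rnorm(25, 0, 0.4)
  mine <- nested_f_test(ols_regression(xx, yy),
                        ols_regression(xx, yy, degree = 2))
  ref <- stats::anova(stats::lm(yy ~ xx), stats::lm(yy ~ xx + I(xx^2)))
  expect_equal(unname(mine$statistic), ref$F[2], tolerance = 1e-12)
  expect_equal(mine$p_value, ref$`Pr(>F)`[2], tolerance = 1e-12)

  expect_error(nested_f_test(ols_regression(x, linear_y),
                             ols_regression(x, rev(linear_y), degree = 2)),
               class = "rfidforage_config_error")
})

test_that("correlation matrix is pairwise-complete Pearson with flagged gaps", {
  set.seed(4)
  tbl <- tibble::tibble(a = rnorm(20), b = rnorm(20))
  tbl$dup <- tbl$a
  tbl$neg <- -tbl$a
  m <- correlation_matrix(tbl)
  expect_equal(m["a", "dup"], 1)
  expect_equal(m["a", "neg"], -1)
  expect_equal(m, t(m))
  expect_equal(diag(m), setNames(rep(1, 4), colnames(m)))
  ref <- stats::cor(as.data.frame(tbl), use = "pairwise.complete.obs")
  expect_equal(m, ref, tolerance = 1e-12)

  tbl$flat <- 1
  expect_warning(m2 <- correlation_matrix(tbl), "flat")
  expect_true(all(is.na(m2["flat", ])))
})

test_that("zero-value filtering reports counts and Bonferroni helper divides alpha", {
  tbl <- tibble::tibble(tag = c("a", "b", "c"),
                        nectar = c(3, 0, 5), pollen = c(1, 2, 4))
  expect_message(out <- filter_zero_rows(tbl, c("nectar", "pollen")),
                 "dropped 1")
  expect_equal(nrow(out), 2L)
  expect_equal(attr(out, "n_dropped"), 1L)

  expect_equal(bonferroni_alpha(8), 0.05 / 8)
  expect_equal(bonferroni_alpha(3), 0.05 / 3)
})
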