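# Hypothesis-testing battery applied to pipeline outputs.  Statistics are
# computed from first principles (exact signed-rank distribution by
# enumeration of sign patterns, closed-form least squares) so that every
# number is auditable; standard library routines serve as independent
# cross-checks in the test suite.

new_test_result <- function(method, statistic, p_value, n = NULL, df = NULL,
                            alternative = NA_character_,
                            alpha_adjusted = NULL, ...) {
  structure(
    list(method = method, statistic = statistic, p_value = p_value,
         n = n, df = df, alternative = alternative,
         alpha_adjusted = alpha_adjusted, ...),
    class = "forage_test"
  )
}

#' @export
print.forage_test <- function(x, ...) {
  cat(sprintf("<forage_test> %s\n", x$method))
  cat(sprintf("  %s = %g, p = %.4g%s\n", names(x$statistic)[1], x$statistic[1],
              x$p_value,
              if (!is.na(x$alternative)) paste0(" (", x$alternative, ")") else ""))
  if (!is.null(x$df)) cat(sprintf("  df = %s\n", paste(x$df, collapse = ", ")))
  if (!is.null(x$n)) cat(sprintf("  n = %d\n", x$n))
  if (!is.null(x$alpha_adjusted)) {
    cat(sprintf("  Bonferroni-adjusted alpha = %g -> %s\n", x$alpha_adjusted,
                if (x$p_value < x$alpha_adjusted) "significant" else
                  "not significant"))
  }
  invisible(x)
}

#' Bonferroni-corrected significance level
#'
#' @param n_tests Number of tests in the family.
#' @param alpha Family-wise error rate (default 0.05).
#' @return `alpha / n_tests`.  The analysis families used with colony data
#'   in this package use corrected alphas of 0.006 (eight morphology models)
#'   and 0.017 (three colony-age models).
#' @export
bonferroni_alpha <- function(n_tests, alpha = 0.05) {
  assert_count(n_tests, "n_tests", min = 1L)
  alpha / n_tests
}

# Exact null distribution of the signed-rank statistic for the given ranks:
# probability vector over 2*V = 0 .. sum(2r), obtained by convolving one
# two-point distribution per rank (equivalent to enumerating all 2^n sign
# patterns).  Average ranks under ties are handled by doubling to integers.
signed_rank_distribution <- function(ranks) {
  w <- as.integer(round(2 * ranks))
  f <- numeric(sum(w) + 1)
  f[1] <- 1
  for (wi in w) {
    g <- f
    g[(wi + 1):length(f)] <- g[(wi + 1):length(f)] + f[1:(length(f) - wi)]
    f <- g
  }
  f / 2^length(w)
}

#' Wilcoxon signed-rank test (one-sample, exact for small n)
#'
#' Tests the symmetry point of `values` against `mu0`.  Zero differences
#' are dropped and tied absolute differences get average ranks (signed-rank
#' convention).  For `n <= exact_limit` the p-value is exact, from the full
#' null distribution of the statistic over all `2^n` sign patterns;
#' otherwise a normal approximation with tie and continuity corrections is
#' used.
#'
#' The direction must be given explicitly: testing whether foragers forage
#' in runs (constancy index above zero) is `alternative = "greater"`.
#'
#' @param values Numeric sample.
#' @param mu0 Null symmetry point (default 0).
#' @param alternative `"greater"`, `"less"` or `"two.sided"`; required, no
#'   default.
#' @param exact_limit Largest n for which the exact distribution is used.
#' @param alpha_adjusted Optional Bonferroni-corrected alpha recorded in the
#'   result.
#' @return A `forage_test` with statistic `V` (sum of positive-difference
#'   ranks), the p-value, `n` (nonzero differences) and an `exact` flag.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3), alternative = "greater")$p_value  # 1/8
wilcoxon_signed_rank <- function(values, mu0 = 0, alternative,
                                 exact_limit = 12, alpha_adjusted = NULL) {
  if (missing(alternative)) {
    stop_config("`alternative` must be given explicitly ('greater', 'less' or 'two.sided')")
  }
  alternative <- match.arg(alternative, c("greater", "less", "two.sided"))
  d <- values - mu0
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    rlang::abort("all differences are zero: signed-rank test undefined",
                 class = "rfidforage_undefined_test_error")
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  exact <- n <= exact_limit
  if (exact) {
    f <- signed_rank_distribution(r)
    idx <- as.integer(round(2 * v)) + 1L
    p_ge <- sum(f[idx:length(f)])
    p_le <- sum(f[1:idx])
    p <- switch(alternative,
                greater = p_ge,
                less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    sigma <- sqrt(sigma2)
    p <- switch(alternative,
                greater = pnorm((v - mu - 0.5) / sigma, lower.tail = FALSE),
                less = pnorm((v - mu + 0.5) / sigma),
                two.sided = {
                  z <- (v - mu - sign(v - mu) * 0.5) / sigma
                  min(1, 2 * pnorm(-abs(z)))
                })
  }
  new_test_result("Wilcoxon signed-rank test", c(V = v), p, n = n,
                  alternative = alternative, alpha_adjusted = alpha_adjusted,
                  exact = exact)
}

#' Pearson chi-square goodness-of-fit test
#'
#' Compares observed category counts to expected proportions, e.g. the null
#' expectation that the percentage of bouts made by reward specialists
#' equals the percentage of foragers that are reward specialists.
#'
#' @param observed Non-negative counts.
#' @param expected Expected proportions (same length, summing to 1, all
#'   positive).
#' @param alpha_adjusted Optional corrected alpha recorded in the result.
#' @return A `forage_test` with the `X_squared` statistic, `df = k - 1` and
#'   the upper-tail p-value.
#' @export
#' @examples
#' chi_square_proportions(c(60, 40), c(0.5, 0.5))$statistic  # 4
chi_square_proportions <- function(observed, expected, alpha_adjusted = NULL) {
  if (length(observed) != length(expected) || length(observed) < 2) {
    stop_config("`observed` and `expected` must have equal length >= 2")
  }
  if (any(observed < 0) || any(!is.finite(observed))) {
    stop_data("`observed` must be finite non-negative counts")
  }
  if (any(expected <= 0)) {
    stop_config("expected proportions must all be positive (zero expected cell)")
  }
  if (abs(sum(expected) - 1) > 1e-9) {
    stop_config("expected proportions must sum to 1")
  }
  n <- sum(observed)
  exp_counts <- n * expected
  x2 <- sum((observed - exp_counts)^2 / exp_counts)
  df <- length(observed) - 1L
  new_test_result("Chi-square goodness-of-fit test", c(X_squared = x2),
                  pchisq(x2, df, lower.tail = FALSE), df = df,
                  n = as.integer(n), alpha_adjusted = alpha_adjusted)
}

#' Paired t test
#'
#' @param x,y Equal-length paired samples (length >= 2).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`,
#'   applied to `mean(x - y)`.
#' @param alpha_adjusted Optional corrected alpha recorded in the result.
#' @return A `forage_test` with statistic `t`, `df = n - 1` and the
#'   p-value.  Zero variance of the differences is an undefined-test error.
#' @export
paired_t_test <- function(x, y, alternative = c("two.sided", "greater", "less"),
                          alpha_adjusted = NULL) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y) || length(x) < 2) {
    stop_config("`x` and `y` must be paired samples of equal length >= 2")
  }
  d <- x - y
  s <- sd(d)
  if (s == 0) {
    rlang::abort("differences have zero variance: paired t test undefined",
                 class = "rfidforage_undefined_test_error")
  }
  n <- length(d)
  t_stat <- mean(d) / (s / sqrt(n))
  df <- n - 1L
  p <- switch(alternative,
              two.sided = 2 * pt(-abs(t_stat), df),
              greater = pt(t_stat, df, lower.tail = FALSE),
              less = pt(t_stat, df))
  new_test_result("Paired t test", c(t = t_stat), p, df = df, n = n,
                  alternative = alternative, alpha_adjusted = alpha_adjusted)
}

#' Least-squares regression with a configurable null slope
#'
#' Ordinary least squares of `y` on `x` (optionally on `x` and `x^2`),
#' computed in closed form, with an F test of the slope against a
#' configurable null value.  Setting `null_slope = 1` reproduces the
#' "offset" construction used to ask whether one log-scaled effort measure
#' grows proportionally with another; the default `null_slope = 0` is the
#' usual test of no association.
#'
#' @param x,y Numeric vectors, length >= 3 (>= 4 for `degree = 2`).
#' @param log_x,log_y Apply natural-log transforms first; non-positive
#'   values are an error (filter them beforehand, see
#'   [filter_zero_rows()]).
#' @param null_slope Null value for the slope F test (linear fits only).
#' @param degree 1 (linear) or 2 (adds a quadratic term; used with
#'   [nested_f_test()]).
#' @return An object of class `forage_ols`: coefficients, `fitted`,
#'   `residuals`, `rss`, `tss`, `r_squared`, `df_residual`, `n`, `degree`,
#'   and for linear fits `f_statistic`, `f_p_value` against `null_slope`.
#' @export
#' @examples
#' fit <- ols_regression(1:3, c(2, 4, 6))
#' fit$coefficients  # intercept 0, slope 2
ols_regression <- function(x, y, log_x = FALSE, log_y = FALSE,
                           null_slope = 0, degree = 1) {
  if (length(x) != length(y)) stop_config("`x` and `y` must have equal length")
  if (!degree %in% c(1, 2)) stop_config("`degree` must be 1 or 2")
  if (log_x) {
    if (any(x <= 0)) stop_data("log_x requires strictly positive x (filter zeros first)")
    x <- log(x)
  }
  if (log_y) {
    if (any(y <= 0)) stop_data("log_y requires strictly positive y (filter zeros first)")
    y <- log(y)
  }
  n <- length(x)
  if (n < degree + 2) stop_config("need at least %d observations", degree + 2)
  if (sd(x) == 0) {
    rlang::abort("`x` is constant: design is rank deficient",
                 class = "rfidforage_rank_error")
  }
  if (degree == 1) {
    sxx <- sum((x - mean(x))^2)
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    slope <- sxy / sxx
    intercept <- mean(y) - slope * mean(x)
    coefs <- c(intercept = intercept, slope = slope)
    fitted <- intercept + slope * x
  } else {
    X <- cbind(1, x, x^2)
    qr_x <- qr(X)
    if (qr_x$rank < 3) {
      rlang::abort("quadratic design is rank deficient",
                   class = "rfidforage_rank_error")
    }
    coefs <- qr.coef(qr_x, y)
    names(coefs) <- c("intercept", "slope", "quadratic")
    fitted <- as.vector(X %*% coefs)
  }
  res <- y - fitted
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) 0 else 1 - rss / tss
  df_resid <- n - (degree + 1L)
  out <- list(coefficients = coefs, fitted = fitted, residuals = res,
              rss = rss, tss = tss, r_squared = r2,
              df_residual = df_resid, n = n, degree = degree, y = y)
  if (degree == 1) {
    # Restricted fit with slope fixed at the null: intercept-only fit of
    # y - b0 * x.
    rss0 <- sum((y - null_slope * x - mean(y - null_slope * x))^2)
    num <- rss0 - rss
    out$null_slope <- null_slope
    if (num <= 0) {
      out$f_statistic <- 0
      out$f_p_value <- 1
    } else if (rss == 0) {
      out$f_statistic <- Inf
      out$f_p_value <- 0
    } else {
      out$f_statistic <- num / (rss / df_resid)
      out$f_p_value <- pf(out$f_statistic, 1, df_resid, lower.tail = FALSE)
    }
  }
  structure(out, class = "forage_ols")
}

#' @export
print.forage_ols <- function(x, ...) {
  cat(sprintf("<forage_ols> degree %d, n = %d\n", x$degree, x$n))
  print(round(x$coefficients, 6))
  cat(sprintf("  R^2 = %.4f, RSS = %.6g (df = %d)\n", x$r_squared, x$rss,
              x$df_residual))
  if (!is.null(x$f_statistic)) {
    cat(sprintf("  F(slope = %g) = %.4g, p = %.4g\n", x$null_slope,
                x$f_statistic, x$f_p_value))
  }
  invisible(x)
}

#' Nested F test between a linear and a quadratic fit
#'
#' Tests whether adding a quadratic term improves the fit, as when asking
#' whether the foraging force grows nonlinearly with colony age.
#'
#' @param fit_linear,fit_quadratic `forage_ols` fits of the same response
#'   (degrees 1 and 2 on the same data).
#' @param alpha_adjusted Optional corrected alpha recorded in the result.
#' @return A `forage_test` with the F statistic, `df = (q, df2)` and the
#'   upper-tail p-value.  A perfect quadratic fit (zero residual sum of
#'   squares) reports `p = 0` with `degenerate = TRUE`.
#' @export
nested_f_test <- function(fit_linear, fit_quadratic, alpha_adjusted = NULL) {
  stopifnot(inherits(fit_linear, "forage_ols"),
            inherits(fit_quadratic, "forage_ols"))
  if (fit_linear$n != fit_quadratic$n ||
      !isTRUE(all.equal(fit_linear$y, fit_quadratic$y))) {
    stop_config("fits must share the same response vector")
  }
  q <- fit_linear$df_residual - fit_quadratic$df_residual
  df2 <- fit_quadratic$df_residual
  if (df2 <= 0) {
    rlang::abort("no residual degrees of freedom in the larger model",
                 class = "rfidforage_insufficient_data_error")
  }
  num <- (fit_linear$rss - fit_quadratic$rss) / q
  if (fit_quadratic$rss == 0) {
    return(new_test_result("Nested F test (linear vs quadratic)",
                           c(F = Inf), 0, df = c(q, df2),
                           n = fit_linear$n, alpha_adjusted = alpha_adjusted,
                           degenerate = TRUE))
  }
  f <- max(0, num) / (fit_quadratic$rss / df2)  # guard roundoff when RSS1 ~ RSS2
  new_test_result("Nested F test (linear vs quadratic)", c(F = f),
                  pf(f, q, df2, lower.tail = FALSE), df = c(q, df2),
                  n = fit_linear$n, alpha_adjusted = alpha_adjusted,
                  degenerate = FALSE)
}

#' Pairwise-complete Pearson correlation matrix
#'
#' Correlates every pair of numeric columns (morphological measures,
#' lifetime behavioural measures, ...) using pairwise-complete observations.
#' Pairs with fewer than 3 complete rows, or involving a constant column,
#' get `NA` and a warning naming them.
#'
#' @param table Data frame of numeric columns.
#' @return Symmetric matrix of Pearson r with unit diagonal (where defined).
#' @export
correlation_matrix <- function(table) {
  tbl <- as.data.frame(table)
  num <- vapply(tbl, is.numeric, logical(1))
  tbl <- tbl[num]
  k <- ncol(tbl)
  if (k < 2) stop_config("need at least two numeric columns")
  out <- matrix(NA_real_, k, k, dimnames = list(names(tbl), names(tbl)))
  flagged <- character()
  for (i in seq_len(k)) {
    for (j in i:k) {
      xi <- tbl[[i]]; xj <- tbl[[j]]
      ok <- is.finite(xi) & is.finite(xj)
      ni <- sum(ok)
      if (ni < 3 || sd(xi[ok]) == 0 || sd(xj[ok]) == 0) {
        flagged <- c(flagged, paste(names(tbl)[i], names(tbl)[j], sep = "~"))
        next
      }
      xm <- xi[ok] - mean(xi[ok]); ym <- xj[ok] - mean(xj[ok])
      out[i, j] <- out[j, i] <- sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
    }
  }
  if (length(flagged) > 0) {
    warn(sprintf("correlation undefined for: %s",
                 paste(unique(flagged), collapse = ", ")))
  }
  out
}

#' Drop rows containing zero values before log-scaled analyses
#'
#' Log-scaled effort models cannot use foragers with zero bouts in a
#' category; this filter removes such rows and reports how many were
#' dropped (never silently).
#'
#' @param table Data frame.
#' @param cols Character vector of columns to screen (default: all numeric
#'   columns).
#' @return The filtered table; the number of dropped rows is reported via a
#'   message and stored in the `n_dropped` attribute.
#' @export
filter_zero_rows <- function(table, cols = NULL) {
  tbl <- as_tibble(table)
  if (is.null(cols)) {
    cols <- names(tbl)[vapply(tbl, is.numeric, logical(1))]
  }
  missing_cols <- setdiff(cols, names(tbl))
  if (length(missing_cols) > 0) {
    stop_config("unknown columns: %s", paste(missing_cols, collapse = ", "))
  }
  has_zero <- Reduce(`|`, lapply(tbl[cols], function(x) x == 0))
  has_zero[is.na(has_zero)] <- FALSE
  out <- tbl[!has_zero, ]
  inform(sprintf("filter_zero_rows: dropped %d of %d rows with zero values",
                 sum(has_zero), nrow(tbl)))
  attr(out, "n_dropped") <- sum(has_zero)
  out
}
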