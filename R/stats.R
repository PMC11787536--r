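# Self-contained statistical test contracts used across the package. The
# rank-sum test is implemented directly so that exact enumeration works with
# average ranks under ties; the remaining tests delegate to base R's vetted
# routines behind a uniform TestResult surface.

test_result <- function(statistic, p, n, method, extra = list()) {
  structure(c(list(statistic = statistic, p.value = p, n = n,
                   method = method), extra),
            class = "tcs_test")
}

#' @export
print.tcs_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g (n = %s)\n", x$method,
              x$statistic, x$p.value, paste(x$n, collapse = ", ")))
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' For small pooled samples (`n1 + n2 <= exact_threshold`) the null
#' distribution of the rank sum is enumerated exactly over all
#' `choose(n1 + n2, n1)` group assignments using average ranks, so ties are
#' handled exactly; larger samples use the tie-corrected normal
#' approximation with continuity correction.
#'
#' @param x,y Numeric samples, each with at least one value.
#' @param exact_threshold Pooled-size cutoff for exact enumeration
#'   (default 20).
#' @return A `tcs_test` with the rank-sum statistic of `x`, the two-sided
#'   p-value, the sample sizes and the method used.
#' @export
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p.value  # exact: 0.1
rank_sum_test <- function(x, y, exact_threshold = 20L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L) {
    stop("both samples must contain at least one value", call. = FALSE)
  }
  if (!all(is.finite(c(x, y)))) stop("samples must be finite", call. = FALSE)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  if (n <= exact_threshold) {
    combs <- utils::combn(n, n1)
    Ws <- colSums(matrix(r[combs], nrow = n1))
    eps <- 1e-9
    p <- min(1, 2 * min(mean(Ws <= W + eps), mean(Ws >= W - eps)))
    return(test_result(W, p, c(n1, n2), "rank-sum (exact)"))
  }
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(test_result(W, 1, c(n1, n2), "rank-sum (normal)"))
  z <- (W - mu - 0.5 * sign(W - mu)) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  test_result(W, p, c(n1, n2), "rank-sum (normal)")
}

#' Two-sided one-sample t-test of a null distribution against a real value
#'
#' Tests whether a shuffle-null sample is centered on the observed (real)
#' value: a small p means the real value lies outside the null distribution.
#' The direction (`sign(value - mean(null_sample))`) is reported.
#'
#' @param value Observed scalar.
#' @param null_sample Numeric vector of null values (>= 2).
#' @return A `tcs_test`; `degenerate = TRUE` with `p.value = NA` when the
#'   null sample has zero variance.
#' @export
one_sample_t_vs_null <- function(value, null_sample) {
  null_sample <- as.numeric(null_sample)
  if (length(null_sample) < 2L) stop("null sample needs >= 2 values",
                                     call. = FALSE)
  dir_ <- sign(value - mean(null_sample))
  if (stats::sd(null_sample) == 0) {
    return(test_result(NA_real_, NA_real_, length(null_sample),
                       "one-sample t vs null",
                       list(direction = dir_, degenerate = TRUE)))
  }
  tt <- stats::t.test(null_sample, mu = value)
  test_result(unname(tt$statistic), tt$p.value, length(null_sample),
              "one-sample t vs null",
              list(direction = dir_, degenerate = FALSE))
}

#' Two-sided two-sample Kolmogorov-Smirnov test
#'
#' @param x,y Numeric samples with at least 2 values each.
#' @return A `tcs_test` with the D statistic.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("both samples must contain at least 2 values", call. = FALSE)
  }
  kt <- suppressWarnings(stats::ks.test(x, y))
  test_result(unname(kt$statistic), kt$p.value,
              c(length(x), length(y)), "two-sample KS")
}

#' Two-way ANOVA with Tukey HSD follow-up
#'
#' Fits `values ~ factor_a * factor_b` and reports the F table plus
#' Tukey-adjusted pairwise comparisons on `factor_a` (the layer factor in
#' the population-average analysis). If either factor has a single level the
#' model reduces to a one-way ANOVA with a warning.
#'
#' @param values Numeric response.
#' @param factor_a,factor_b Grouping factors (coerced with `factor()`).
#' @return List with `anova` (data.frame: term, df, F, p) and `tukey`
#'   (data.frame of pairwise comparisons on `factor_a`).
#' @export
anova_tukey <- function(values, factor_a, factor_b) {
  factor_a <- factor(factor_a); factor_b <- factor(factor_b)
  if (nlevels(factor_a) < 2L && nlevels(factor_b) < 2L) {
    stop("need at least one factor with >= 2 levels", call. = FALSE)
  }
  dat <- data.frame(values = values, A = factor_a, B = factor_b)
  if (nlevels(factor_a) < 2L || nlevels(factor_b) < 2L) {
    warning("a factor has a single level; reducing to one-way ANOVA")
    keyvar <- if (nlevels(factor_a) >= 2L) "A" else "B"
    fit <- stats::aov(stats::reformulate(keyvar, "values"), data = dat)
    tuk <- stats::TukeyHSD(fit, which = keyvar)[[keyvar]]
  } else {
    fit <- stats::aov(values ~ A * B, data = dat)
    tuk <- stats::TukeyHSD(fit, which = "A")$A
  }
  sm <- summary(fit)[[1L]]
  terms <- trimws(rownames(sm))
  keep <- terms != "Residuals"
  anova_df <- data.frame(
    term = terms[keep],
    df = sm$Df[keep],
    F = sm$`F value`[keep],
    p = sm$`Pr(>F)`[keep]
  )
  tukey_df <- data.frame(
    comparison = rownames(tuk),
    diff = tuk[, "diff"],
    p_adj = tuk[, "p adj"],
    row.names = NULL
  )
  list(anova = anova_df, tukey = tukey_df)
}
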