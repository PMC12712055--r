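#' Summarize an interblade-distance sample
#'
#' @param distances Numeric vector of interblade distances (nm).
#' @return List of class `condition_summary`: `n`, `mean`, `sd`, `sem`
#'   (unbiased SD; SEM = sd/sqrt(n)). With a single observation `sd` and
#'   `sem` are `NA` and the result carries `flag = "n<2"`.
#' @export
summarize_distances <- function(distances) {
  distances <- as.numeric(distances)
  if (length(distances) == 0) stop("empty input", call. = FALSE)
  n <- length(distances)
  s <- if (n >= 2) stats::sd(distances) else NA_real_
  structure(
    list(n = n, mean = mean(distances), sd = s,
         sem = if (n >= 2) s / sqrt(n) else NA_real_,
         flag = if (n < 2) "n<2" else NA_character_),
    class = "condition_summary"
  )
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("n = %d, mean = %.3f +/- %.3f (SEM) nm, SD = %.3f nm\n",
              x$n, x$mean, x$sem, x$sd))
  invisible(x)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino (1970) skewness z-statistic with the Anscombe &
#' Glynn (1983) kurtosis z-statistic into the K-squared omnibus statistic,
#' referred to a chi-squared distribution with 2 degrees of freedom.
#' Requires n >= 8.
#'
#' @param x Numeric vector.
#' @return An object of class `htest` with `statistic` (K-squared),
#'   `p.value` and the two component z-scores in `estimate`.
#' @export
dagostino_pearson_test <- function(x) {
  x <- as.numeric(x[is.finite(x)])
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson test requires n >= 8", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  if (m2 <= 0) stop("zero variance sample", call. = FALSE)

  # skewness component (D'Agostino 1970)
  g1 <- m3 / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis component (Anscombe & Glynn 1983)
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xs <- (b2 - eb2) / sqrt(vb2)
  sqrtb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrtb1 * (2 / sqrtb1 + sqrt(1 + 4 / sqrtb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xs * sqrt(2 / (a - 4))))^(1 / 3)) *
    sqrt(9 * a / 2)

  k2 <- z1^2 + z2^2
  structure(
    list(statistic = c(K.squared = k2),
         parameter = c(df = 2),
         p.value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
         estimate = c(z.skewness = z1, z.kurtosis = z2),
         method = "D'Agostino-Pearson omnibus normality test",
         data.name = deparse(substitute(x))),
    class = "htest"
  )
}

#' Normality-gated two-group comparison
#'
#' Gates the test choice on per-group D'Agostino-Pearson normality: if both
#' groups pass at `alpha_normality`, a two-sided unpaired Student's t-test
#' (equal variances by default, mirroring the classic test; Welch via
#' `var_equal = FALSE`); otherwise a two-sided Mann-Whitney U test. Groups
#' too small for the normality test (n < 8) fall back to Mann-Whitney with
#' a warning. No multiple-testing adjustment is applied.
#'
#' @param group_a,group_b Numeric vectors, each with n >= 3.
#' @param alpha_normality Gate level for the normality tests.
#' @param var_equal Use the equal-variance t statistic when the gate selects
#'   the t-test.
#' @return List of class `condition_comparison`: `test` ("Student t" or
#'   "Mann-Whitney"), `statistic`, `p.value`, `normality_p` (per-group gate
#'   p-values, `NA` when not computable), `effect_nm` (mean(A) - mean(B))
#'   and the two [summarize_distances()] summaries.
#' @export
compare_conditions <- function(group_a, group_b, alpha_normality = 0.05,
                               var_equal = TRUE) {
  group_a <- as.numeric(group_a)
  group_b <- as.numeric(group_b)
  if (length(group_a) < 3 || length(group_b) < 3) {
    stop("each group needs n >= 3", call. = FALSE)
  }
  norm_p <- c(a = NA_real_, b = NA_real_)
  if (length(group_a) >= 8 && length(group_b) >= 8) {
    norm_p["a"] <- dagostino_pearson_test(group_a)$p.value
    norm_p["b"] <- dagostino_pearson_test(group_b)$p.value
    parametric <- all(norm_p > alpha_normality)
  } else {
    warning("group too small for the normality gate; using Mann-Whitney",
            call. = FALSE)
    parametric <- FALSE
  }
  if (parametric) {
    ht <- stats::t.test(group_a, group_b, var.equal = var_equal)
    test <- "Student t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(group_a, group_b, exact = FALSE))
    test <- "Mann-Whitney"
  }
  structure(
    list(test = test, statistic = unname(ht$statistic), p.value = ht$p.value,
         normality_p = norm_p,
         effect_nm = mean(group_a) - mean(group_b),
         summary_a = summarize_distances(group_a),
         summary_b = summarize_distances(group_b)),
    class = "condition_comparison"
  )
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4g, p = %.4g\n",
              x$test, x$statistic, x$p.value))
  cat(sprintf("effect (mean A - mean B): %.3f nm\n", x$effect_nm))
  cat(sprintf("normality gate p-values: A = %.3g, B = %.3g\n",
              x$normality_p["a"], x$normality_p["b"]))
  invisible(x)
}

#' Simulation-based detection-rate check for the gated comparison
#'
#' Draws `n_sims` pairs of normal samples separated by `mean_shift` and
#' reports the fraction in which [compare_conditions()] rejects at the 0.05
#' level. With `mean_shift = 0` this estimates the type-I error of the
#' gated procedure.
#'
#' @param mean_shift True difference of means (nm).
#' @param sd Common SD (nm).
#' @param n_per_group Sample size per group.
#' @param n_sims Number of simulations (>= 100).
#' @param seed Integer seed.
#' @param alpha Rejection level.
#' @return Detection rate in `[0, 1]`.
#' @export
power_check <- function(mean_shift, sd, n_per_group, n_sims = 200,
                        seed = 1L, alpha = 0.05) {
  stopifnot(n_sims >= 100)
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_sims)) {
    a <- stats::rnorm(n_per_group, 0, sd)
    b <- stats::rnorm(n_per_group, mean_shift, sd)
    if (compare_conditions(a, b)$p.value < alpha) hits <- hits + 1L
  }
  hits / n_sims
}
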