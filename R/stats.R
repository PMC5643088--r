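# The study's statistical layer: box-plot style summaries, non-parametric
# two-sample / paired tests with exact small-sample branches,
# Holm-Bonferroni correction, and quadratic fits with pointwise confidence
# bands.

#' Summary statistics in the study's box-plot convention
#'
#' Mean and SD (n-1 denominator), median, first/third quartiles and
#' 10th/90th percentiles (the box-plot whiskers), using R's default
#' linear-interpolation quantile rule (type 7).
#'
#' @param values numeric vector, n >= 1.
#' @return one-row data.frame `n, mean, sd, median, q1, q3, p10, p90`.
#' @export
summarize_values <- function(values) {
  pb_assert(is.numeric(values) && length(values) >= 1L,
            "empty value list", "pb_input_error")
  q <- quantile(values, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE, type = 7)
  data.frame(n = length(values), mean = mean(values),
             sd = if (length(values) > 1) sd(values) else 0,
             median = q[3], q1 = q[2], q3 = q[4], p10 = q[1], p90 = q[5])
}

test_result <- function(name, statistic, p, label, degenerate = FALSE) {
  structure(list(test_name = name, statistic = unname(statistic),
                 p_raw = p, p_adjusted = NA_real_,
                 comparison_label = label, degenerate = degenerate),
            class = "pb_test_result")
}

#' Mann-Whitney U test (between-subject comparisons)
#'
#' Exact-distribution p-value when both groups have n <= `exact_max` and no
#' ties straddle the groups (matching the study's sample sizes, all
#' n <= 19); otherwise the normal approximation with tie correction. When
#' every value is tied across both groups the comparison is degenerate and
#' p = 1.
#'
#' @param a,b numeric samples.
#' @param two_tailed two-sided test (default TRUE).
#' @param exact_max largest per-group n for the exact branch (default 20).
#' @param label comparison label carried into the result.
#' @return a `pb_test_result` with the U statistic (for sample `a`).
#' @export
mann_whitney <- function(a, b, two_tailed = TRUE, exact_max = 20,
                         label = "a vs b") {
  pb_assert(length(a) >= 1L && length(b) >= 1L, "both samples must be non-empty",
            "pb_input_error")
  alt <- if (two_tailed) "two.sided" else "greater"
  if (length(unique(c(a, b))) == 1L) {
    warning("all values tied across both groups; degenerate comparison")
    return(test_result("mann_whitney", NA_real_, 1, label, degenerate = TRUE))
  }
  exact <- length(a) <= exact_max && length(b) <= exact_max &&
    !any(duplicated(c(a, b)))
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = alt,
                                            exact = exact, correct = TRUE))
  test_result("mann_whitney", wt$statistic, min(wt$p.value, 1), label)
}

#' Wilcoxon signed-rank test (within-subject comparisons)
#'
#' Zero differences are dropped (classic procedure; set `zero_method =
#' "pratt"` to keep them in the ranking). Exact p-value for n <= `exact_max`
#' non-zero differences without tied magnitudes, else the normal
#' approximation.
#'
#' @param diffs paired differences.
#' @param two_tailed two-sided test (default TRUE).
#' @param exact_max largest n for the exact branch (default 25).
#' @param zero_method `"drop"` (default) or `"pratt"`.
#' @param label comparison label.
#' @return a `pb_test_result` with the signed-rank statistic V.
#' @export
wilcoxon_signed_rank <- function(diffs, two_tailed = TRUE, exact_max = 25,
                                 zero_method = c("drop", "pratt"),
                                 label = "paired") {
  zero_method <- match.arg(zero_method)
  pb_assert(length(diffs) >= 1L, "empty differences", "pb_input_error")
  d <- diffs
  if (zero_method == "drop") d <- d[d != 0]
  if (length(d) == 0L || all(d == 0)) {
    warning("all paired differences are zero; degenerate comparison")
    return(test_result("wilcoxon_signed_rank", NA_real_, 1, label,
                       degenerate = TRUE))
  }
  alt <- if (two_tailed) "two.sided" else "greater"
  if (zero_method == "pratt") {
    # rank zeros with everything, then discard their contribution
    r <- rank(abs(d))
    v <- sum(r[d > 0])
    nz <- sum(d != 0)
    mu <- sum(r[d != 0]) / 2
    sig <- sqrt(sum(r[d != 0]^2) / 4)
    z <- (v - mu) / sig
    p <- if (two_tailed) 2 * stats::pnorm(-abs(z)) else stats::pnorm(-z)
    return(test_result("wilcoxon_signed_rank", v, min(p, 1), label))
  }
  exact <- length(d) <= exact_max && !any(duplicated(abs(d)))
  wt <- suppressWarnings(stats::wilcox.test(d, alternative = alt,
                                            exact = exact, correct = TRUE))
  test_result("wilcoxon_signed_rank", wt$statistic, min(wt$p.value, 1), label)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Adjusted p-values in the input order, with the step-down monotonicity
#' enforcement and capping at 1.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
holm_bonferroni <- function(p_values) {
  pb_assert(is.numeric(p_values) && all(p_values >= 0 & p_values <= 1),
            "p-values must lie in [0, 1]", "pb_input_error")
  stats::p.adjust(p_values, method = "holm")
}

#' Second-order polynomial fit with a pointwise confidence band
#'
#' Least-squares quadratic `y ~ x + x^2` with coefficient confidence
#' intervals and a pointwise confidence band from the coefficient
#' covariance under homoscedastic Gaussian errors (the fit-line + shaded
#' band convention used for phase-resolved spike summaries).
#'
#' @param x,y numeric vectors; at least 4 distinct x values.
#' @param confidence band level (default 0.95).
#' @param xout evaluation points for the band (default sorted unique x).
#' @return list with `coefficients` (intercept, x, x^2), `coef_ci` (matrix),
#'   `band` (data.frame x, fit, lwr, upr), `r_squared`, `sigma`.
#' @export
polyfit2_ci <- function(x, y, confidence = 0.95, xout = NULL) {
  pb_assert(length(x) == length(y), "x and y must match", "pb_input_error")
  if (length(unique(x)) < 4L)
    pb_stop("quadratic fit with a confidence band needs >= 4 distinct x",
            "pb_fit_error")
  df <- data.frame(x = x, y = y)
  fit <- stats::lm(y ~ x + I(x^2), data = df)
  if (any(!is.finite(stats::coef(fit))))
    pb_stop("rank-deficient design", "pb_fit_error")
  xo <- xout %||% sort(unique(x))
  # exact fits trip "essentially perfect fit" warnings; they are valid input
  pr <- suppressWarnings(
    stats::predict(fit, newdata = data.frame(x = xo),
                   interval = "confidence", level = confidence))
  sm <- suppressWarnings(summary(fit))
  list(coefficients = stats::coef(fit),
       coef_ci = suppressWarnings(stats::confint(fit, level = confidence)),
       band = data.frame(x = xo, fit = pr[, "fit"],
                         lwr = pr[, "lwr"], upr = pr[, "upr"]),
       r_squared = sm$r.squared,
       sigma = sm$sigma)
}
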