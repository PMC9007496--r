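#' Modified Thompson-Tau outlier screen
#'
#' Iteratively removes at most one point per pass: with sample mean
#' \eqn{\bar x}, sample SD \eqn{s} and
#' \eqn{\tau = t_{\alpha/2,\,n-2}\,(n-1) / (\sqrt n \sqrt{n-2+t^2_{\alpha/2,\,n-2}})},
#' the point with the largest absolute deviation is removed when that
#' deviation exceeds \eqn{\tau s}; the statistics are then recomputed on the
#' reduced sample.  Screening stops when no point exceeds the cutoff, when
#' only two points remain, or when the sample SD is zero.  When two points
#' tie in absolute deviation, the larger value is removed first.
#'
#' @param values numeric vector, `n >= 3`.
#' @param alpha two-sided significance level of the cutoff, in `(0, 0.5)`.
#' @return A list of class `outlier_screen`: `retained`, `removed` (in
#'   removal order), `tau_thresholds` (the `tau * s` cutoff evaluated at
#'   each iteration, including the final one that removed nothing), and
#'   `alpha`.
#' @examples
#' thompson_tau_screen(c(1, 2, 3, 4, 100))  # removes 100
#' @export
thompson_tau_screen <- function(values, alpha = 0.05) {
  if (!is.numeric(values)) stop_config("values must be numeric")
  if (length(values) < 3)
    stop_config("Thompson-Tau screening needs at least 3 values")
  if (alpha <= 0 || alpha >= 0.5) stop_config("alpha must lie in (0, 0.5)")
  retained <- as.numeric(values)
  removed <- numeric(0)
  cutoffs <- numeric(0)
  repeat {
    n <- length(retained)
    if (n < 3) break
    s <- sd(retained)
    if (s == 0) break
    tq <- qt(1 - alpha / 2, df = n - 2)
    tau <- tq * (n - 1) / (sqrt(n) * sqrt(n - 2 + tq^2))
    cutoffs <- c(cutoffs, tau * s)
    dev <- abs(retained - mean(retained))
    if (max(dev) <= tau * s) break
    cand <- which(dev == max(dev))
    if (length(cand) > 1) cand <- cand[which.max(retained[cand])]
    removed <- c(removed, retained[cand])
    retained <- retained[-cand]
  }
  structure(list(retained = retained, removed = removed,
                 tau_thresholds = cutoffs, alpha = alpha),
            class = "outlier_screen")
}

#' @export
print.outlier_screen <- function(x, ...) {
  cat(sprintf("<outlier_screen> %d retained, %d removed (alpha = %g)\n",
              length(x$retained), length(x$removed), x$alpha))
  if (length(x$removed))
    cat("  removed:", paste(signif(x$removed, 5), collapse = ", "), "\n")
  invisible(x)
}

ttest_result <- function(t, df, p, variant, g1, g2) {
  structure(list(t_statistic = t, degrees_of_freedom = df,
                 p_value = p, variant = variant,
                 group_summaries = rbind(g1, g2)),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("<ttest_result> t = %.4g, df = %.4g, two-tailed p = %.4g (%s)\n",
              x$t_statistic, x$degrees_of_freedom, x$p_value, x$variant))
  invisible(x)
}

group_summary <- function(x) {
  data.frame(n = length(x), mean = mean(x), sem = sd(x) / sqrt(length(x)))
}

#' Two-tailed two-sample t-test
#'
#' Classical two-sided comparison of two groups of raw values, either with
#' pooled variance (Student's, the default) or without (Welch).  When both
#' groups have zero variance, equal means give `p = 1` by convention and
#' unequal means `p = 0`.
#'
#' @param group_a,group_b numeric vectors, each of length `>= 2`.
#' @param variant `"pooled"` or `"welch"`.
#' @return A `ttest_result`: `t_statistic`, `degrees_of_freedom`, `p_value`,
#'   `variant`, and per-group `(n, mean, sem)` summaries.
#' @export
t_test_two_tailed <- function(group_a, group_b,
                              variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(group_a) < 2 || length(group_b) < 2)
    stop_config("each group needs at least 2 values")
  g1 <- group_summary(group_a); g2 <- group_summary(group_b)
  if (var(group_a) == 0 && var(group_b) == 0) {
    if (mean(group_a) == mean(group_b))
      return(ttest_result(0, length(group_a) + length(group_b) - 2, 1,
                          variant, g1, g2))
    return(ttest_result(sign(mean(group_a) - mean(group_b)) * Inf,
                        length(group_a) + length(group_b) - 2, 0,
                        variant, g1, g2))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = variant == "pooled")
  ttest_result(unname(tt$statistic), unname(tt$parameter),
               tt$p.value, variant, g1, g2)
}

#' Two-tailed t-test from printed summary statistics
#'
#' Reconstructs the two-sample test from `(n, mean, SEM)` per group, as
#' needed to check values reported as mean +/- SEM in a publication.  The
#' Welch variant (default) uses
#' \eqn{t = (m_1 - m_2)/\sqrt{SEM_1^2 + SEM_2^2}} with
#' Welch-Satterthwaite degrees of freedom; the pooled variant reconstructs
#' the group SDs from the SEMs first.
#'
#' @param n1,n2 group sizes (`>= 2`).
#' @param mean1,mean2 group means.
#' @param sem1,sem2 group standard errors of the mean (`>= 0`).
#' @param variant `"welch"` or `"pooled"`.
#' @return A `ttest_result`.
#' @examples
#' # two strains with near-identical neurite fluorescence, mean +/- SEM:
#' t_test_from_summary(15, 470.4, 66.1, 11, 465.6, 68.2)
#' @export
t_test_from_summary <- function(n1, mean1, sem1, n2, mean2, sem2,
                                variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (n1 < 2 || n2 < 2) stop_config("each group needs n >= 2")
  if (sem1 < 0 || sem2 < 0) stop_config("SEMs must be >= 0")
  g1 <- data.frame(n = n1, mean = mean1, sem = sem1)
  g2 <- data.frame(n = n2, mean = mean2, sem = sem2)
  if (sem1 == 0 && sem2 == 0) {
    if (mean1 == mean2)
      return(ttest_result(0, n1 + n2 - 2, 1, variant, g1, g2))
    return(ttest_result(sign(mean1 - mean2) * Inf, n1 + n2 - 2, 0,
                        variant, g1, g2))
  }
  if (variant == "welch") {
    se2 <- sem1^2 + sem2^2
    t <- (mean1 - mean2) / sqrt(se2)
    df <- se2^2 / (sem1^4 / (n1 - 1) + sem2^4 / (n2 - 1))
  } else {
    sd1 <- sem1 * sqrt(n1); sd2 <- sem2 * sqrt(n2)
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  ttest_result(t, df, 2 * pt(-abs(t), df), variant, g1, g2)
}
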