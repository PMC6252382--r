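#' Above-chance z-statistic under the maximum-chance criterion
#'
#' For a two-class test set the maximum-chance criterion takes the larger of
#' the two class sizes, `hc`, as the number of test items a trivial
#' majority-class classifier gets right. A classifier producing `h0` correct
#' out of `n` is compared against that baseline with
#' \deqn{z = (H_0 - H_C) / \sqrt{H_C (N - H_C) / N}.}
#'
#' @param h0 integer, number of correctly classified test segments.
#' @param hc integer, maximum-chance count (the larger class size).
#' @param n integer, total number of test segments.
#' @return the z value (length-1 numeric).
#' @examples
#' z_statistic(167, 150, 300)
#' @export
z_statistic <- function(h0, hc, n) {
  stopifnot(h0 >= 0, h0 <= n, n > 0)
  if (hc <= 0 || hc >= n) {
    stop("'hc' must lie strictly between 0 and 'n' (zero-variance baseline)")
  }
  (h0 - hc) / sqrt(hc * (n - hc) / n)
}

#' Smallest correct count declared significantly above chance
#'
#' Scans upward from the maximum-chance count for the first `h0` whose
#' z-statistic exceeds the standard-normal critical value at level `alpha`.
#' With `n = 300` balanced test segments (`hc = 150`) and `alpha = 0.05`
#' (two-sided) this is 167 correct, i.e. 55.66\% accuracy.
#'
#' @param hc maximum-chance count.
#' @param n total test segments.
#' @param alpha significance level in (0, 1).
#' @param two_sided use the two-sided critical value `qnorm(1 - alpha/2)`
#'   (default); otherwise the one-sided `qnorm(1 - alpha)`.
#' @return smallest integer `h0` with `z_statistic(h0, hc, n)` strictly above
#'   the critical value, or `NA` if even `h0 = n` is not significant.
#' @export
critical_count <- function(hc, n, alpha = 0.05, two_sided = TRUE) {
  stopifnot(alpha > 0, alpha < 1)
  z_crit <- if (two_sided) stats::qnorm(1 - alpha / 2) else stats::qnorm(1 - alpha)
  # analytic threshold, then nudge for strict inequality / float edge cases
  h0 <- min(ceiling(hc + z_crit * sqrt(hc * (n - hc) / n)), n + 1)
  while (h0 <= n && z_statistic(h0, hc, n) <= z_crit) h0 <- h0 + 1L
  while (h0 - 1 >= 0 && h0 - 1 <= n && z_statistic(h0 - 1, hc, n) > z_crit) {
    h0 <- h0 - 1L
  }
  if (h0 > n) return(NA_integer_)
  as.integer(h0)
}

#' Bonferroni-corrected significance level
#'
#' @param alpha family-wise level.
#' @param n_tests number of tests in the family.
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_alpha(0.05, 14) # 7 condition pairs x 2 feature kinds
#' @export
bonferroni_alpha <- function(alpha, n_tests) {
  stopifnot(n_tests >= 1)
  alpha / n_tests
}

#' Chance criterion summary for a test-set composition
#'
#' Bundles the maximum-chance baseline with the critical z, critical correct
#' count and critical accuracy at a given level.
#'
#' @inheritParams critical_count
#' @return a list of class `chance_criterion` with fields `n`, `hc`, `alpha`,
#'   `two_sided`, `z_critical`, `critical_count`, `critical_accuracy`.
#' @export
chance_criterion <- function(hc, n, alpha = 0.05, two_sided = TRUE) {
  stopifnot(hc <= n)
  cc <- critical_count(hc, n, alpha = alpha, two_sided = two_sided)
  structure(
    list(
      n = as.integer(n), hc = as.integer(hc), alpha = alpha,
      two_sided = two_sided,
      z_critical = if (two_sided) stats::qnorm(1 - alpha / 2) else stats::qnorm(1 - alpha),
      critical_count = cc,
      critical_accuracy = if (is.na(cc)) NA_real_ else cc / n
    ),
    class = "chance_criterion"
  )
}

#' @export
print.chance_criterion <- function(x, ...) {
  cat(sprintf(
    "Chance criterion: N = %d, HC = %d, alpha = %.4g (%s)\n", x$n, x$hc,
    x$alpha, if (x$two_sided) "two-sided" else "one-sided"
  ))
  cat(sprintf(
    "  z critical = %.4f -> critical count = %s (%.2f%% accuracy)\n",
    x$z_critical, x$critical_count, 100 * x$critical_accuracy
  ))
  invisible(x)
}
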