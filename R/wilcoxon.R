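#' Exact Wilcoxon signed-rank test for paired samples
#'
#' Tests whether paired differences are symmetric about zero.  Zero
#' differences are dropped before ranking (the reduced-sample convention)
#' and tied absolute differences receive average ranks.  The reported
#' statistic is `W = min(W+, W-)`, the smaller of the positive- and
#' negative-rank sums.
#'
#' For `n <= 25` retained pairs the two-sided p-value is exact: the null
#' distribution of the positive-rank sum over all `2^n` equiprobable sign
#' assignments is computed by dynamic programming over the doubled
#' (integer) ranks, which handles tied average ranks exactly.  For larger
#' `n` a normal approximation with continuity and tie correction is used.
#'
#' @param x first sample, or the vector of differences if `y` is `NULL`.
#' @param y optional second sample (paired with `x`).
#' @param exact_max largest `n` for which the exact null is computed.
#' @return A list of class `wilcoxon_result`: `statistic` (W), `w_plus`,
#'   `p.value` (two-sided), `n` (retained pairs), `exact` (logical).
#' @examples
#' wilcoxon_signed_rank(c(1.2, 0.8, 2.1, 0.4, 1.0))  # all positive, n = 5
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 25L) {
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  pw_check(all(is.finite(d)), "differences must be finite")
  d <- d[d != 0]
  if (length(d) == 0) {
    pw_abort("all paired differences are zero; the test is undefined",
             "protonWET_degenerate_test_error")
  }
  n <- length(d)
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  w <- min(w_plus, w_minus)
  if (n <= exact_max) {
    # distribution of 2*W+ over doubled ranks (integers even with ties)
    dr <- as.integer(round(2 * r))
    total <- sum(dr)
    counts <- numeric(total + 1L)  # index i holds count of 2*W+ == i - 1
    counts[1L] <- 1
    for (ri in dr) {
      shifted <- c(numeric(ri), counts[seq_len(total + 1L - ri)])
      counts <- counts + shifted
    }
    probs <- counts / 2^n
    wp2 <- as.integer(round(2 * w_plus))
    p_le <- sum(probs[seq_len(wp2 + 1L)])
    p_ge <- sum(probs[(wp2 + 1L):(total + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w_plus - mu - sign(w_plus - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  structure(list(statistic = w, w_plus = w_plus, w_minus = w_minus,
                 p.value = p, n = n, exact = exact),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: W = %g (n = %d), two-sided p = %.4g%s\n",
              x$statistic, x$n, x$p.value,
              if (x$exact) " [exact]" else " [normal approximation]"))
  invisible(x)
}
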