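# Welch's unpaired two-sample t-test on per-run reactive counts.

#' Welch's unpaired t-test
#'
#' Compares per-run reactive counts of two systems without assuming equal
#' variances: t = (mean1 - mean2) / sqrt(var1/n1 + var2/n2), with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value. The unit
#' of replication is the independent production run (30 per system), the
#' only replication the simulation design provides.
#'
#' Degenerate inputs: if both samples have zero variance and equal means the
#' difference is exactly zero and `p = 1` is returned by convention; zero
#' variance with unequal means has no finite t and is an error.
#'
#' @param x,y Numeric vectors of per-run counts (each length >= 2).
#' @return A list of class `WelchResult` with `t`, `df`, `p`, `n1`, `n2`,
#'   `mean1`, `mean2`, `var1`, `var2`.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("each sample needs at least 2 runs (variance undefined)", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite values in input", call. = FALSE)
  }
  n1 <- length(x); n2 <- length(y)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    if (m1 == m2) {
      res <- list(t = 0, df = n1 + n2 - 2, p = 1, n1 = n1, n2 = n2,
                  mean1 = m1, mean2 = m2, var1 = v1, var2 = v2)
      class(res) <- "WelchResult"
      return(res)
    }
    stop("zero variance in both samples with unequal means: t undefined",
         call. = FALSE)
  }
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  res <- list(t = t, df = df, p = p, n1 = n1, n2 = n2,
              mean1 = m1, mean2 = m2, var1 = v1, var2 = v2)
  class(res) <- "WelchResult"
  res
}

#' @export
print.WelchResult <- function(x, ...) {
  cat(sprintf("Welch's unpaired t-test: t = %.4g, df = %.4g, p = %.4g\n",
              x$t, x$df, x$p))
  cat(sprintf("  n = %d vs %d; mean = %.4g vs %.4g; var = %.4g vs %.4g\n",
              x$n1, x$n2, x$mean1, x$mean2, x$var1, x$var2))
  invisible(x)
}
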