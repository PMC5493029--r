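#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditional on the table margins, the two-sided p-value is the sum of
#' hypergeometric probabilities of all tables no more probable than the
#' observed one (the convention of [stats::fisher.test()], which performs
#' the enumeration).  A table with a zero margin carries no information
#' about association; its p is 1 by convention.
#'
#' @param table 2x2 matrix of non-negative integer counts, e.g. rows =
#'   group, columns = pass/fail.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(3, 43, 1, 55), 2, byrow = TRUE))  # 0.324
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    stop("need a 2x2 table")
  if (anyNA(table) || any(table < 0) || any(table != floor(table)))
    stop("table entries must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    message("fisher_exact_2x2: zero margin, p = 1 by convention")
    return(1)
  }
  stats::fisher.test(table, alternative = "two.sided")$p.value
}

#' Compare group mean biodiversity numbers with a t-test
#'
#' Two-sided t-test on per-sample Ewens theta estimates between two
#' groups.  `variant = "student"` (default) pools the variance as in the
#' classical Student test; `"welch"` drops the equal-variance assumption.
#'
#' @param fits_a,fits_b lists of [ewens_fit][ewens_theta_mle] objects (or
#'   plain numeric vectors of theta estimates).
#' @param variant `"student"` or `"welch"`.
#' @return Object of class `theta_comparison`: `p_value`, `mean_a`,
#'   `mean_b`, `n_a`, `n_b`, `variant`.
#' @export
compare_theta_groups <- function(fits_a, fits_b,
                                 variant = c("student", "welch")) {
  variant <- match.arg(variant)
  thetas <- function(fits) {
    if (is.numeric(fits)) return(as.numeric(fits))
    vapply(fits, function(f) f$theta_hat, numeric(1))
  }
  a <- thetas(fits_a)
  b <- thetas(fits_b)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 theta estimates")
  if (any(!is.finite(c(a, b))))
    stop("non-finite theta estimates (boundary fits); remove them first")
  tt <- stats::t.test(a, b, var.equal = (variant == "student"))
  structure(list(p_value = tt$p.value, mean_a = mean(a), mean_b = mean(b),
                 n_a = length(a), n_b = length(b), variant = variant),
            class = "theta_comparison")
}

#' @export
print.theta_comparison <- function(x, ...) {
  cat("Group theta comparison (", x$variant, " t-test)\n", sep = "")
  cat("  mean_a =", format(x$mean_a, digits = 5), "(n =", x$n_a, ")",
      " mean_b =", format(x$mean_b, digits = 5), "(n =", x$n_b, ")\n")
  cat("  p =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}
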