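# Unsigned Stirling numbers of the first kind, kept entirely in log space.
# s(n,1) = (n-1)!, s(n,n) = 1, and the triangle grows by
#   s(n,a) = s(n-1,a-1) + (n-1) * s(n-1,a),
# which in log space is one vectorised logaddexp per row.  Magnitudes reach
# (n-1)! so nothing here is representable outside log space for n beyond
# ~170.

logaddexp <- function(x, y) {
  m <- pmax(x, y)
  d <- -abs(x - y)
  out <- m + log1p(exp(d))
  # when one side is -Inf the other dominates exactly
  ifelse(is.infinite(m) & m < 0, -Inf, out)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Table of log unsigned Stirling numbers of the first kind
#'
#' Builds the triangle `log s(n, a)` for `1 <= a <= n <= max_n` by the
#' standard recurrence, evaluated stably in log space.  These coefficients
#' are the backbone of the ancestor-count weights K(D, A) in Etienne's
#' sampling formula.
#'
#' @param max_n largest `n` needed (at least the largest abundance in the
#'   sample under analysis).
#' @return An object of class `stirling_table`: list with `max_n` and
#'   `log_s`, an `max_n x max_n` matrix whose `[n, a]` entry is
#'   `log s(n, a)` (`-Inf` above the diagonal).
#' @examples
#' st <- stirling_table(4)
#' exp(st$log_s[4, 2])  # 11
#' @export
stirling_table <- function(max_n) {
  if (!is.numeric(max_n) || max_n < 1) stop("max_n must be >= 1")
  max_n <- as.integer(max_n)
  log_s <- matrix(-Inf, max_n, max_n)
  log_s[1, 1] <- 0
  if (max_n >= 2) {
    for (n in 2:max_n) {
      prev <- log_s[n - 1, 1:(n - 1)]
      row <- numeric(n)
      row[1] <- log(n - 1) + prev[1]          # (n-1)!
      row[n] <- 0
      if (n > 2) {
        a <- 2:(n - 1)
        row[a] <- logaddexp(prev[a - 1], log(n - 1) + prev[a])
      }
      log_s[n, 1:n] <- row
    }
  }
  structure(list(max_n = max_n, log_s = log_s), class = "stirling_table")
}

#' @export
print.stirling_table <- function(x, ...) {
  cat("log-space Stirling (first kind) triangle up to n =", x$max_n, "\n")
  invisible(x)
}

# grow-on-demand cache shared across fits within a session
stirling_cached <- function(max_n) {
  tab <- .neutralsad_env$stirling
  if (is.null(tab) || tab$max_n < max_n) {
    tab <- stirling_table(max(max_n, 64L))
    .neutralsad_env$stirling <- tab
  }
  tab
}
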