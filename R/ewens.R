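#' Ewens sampling formula log-likelihood
#'
#' Log-probability of a sample's abundance configuration under the Ewens
#' sampling formula, the neutral model without dispersal limitation
#' (immigration probability m = 1):
#' \deqn{\Pr(n_1,\dots,n_S \mid \theta, J) =
#'   \frac{J!\,\theta^S}{\prod_a a^{\phi_a} \phi_a!\;
#'   \prod_{k=1}^{J}(\theta+k-1)}}
#' where `phi_a` is the number of species with abundance `a` and `theta`
#' is the fundamental biodiversity number.  All terms are computed in log
#' space via `lgamma`, so samples with J in the thousands are safe.
#'
#' @param sample a [community_sample][make_sample] (or a counts vector).
#' @param theta positive fundamental biodiversity number.
#' @return The log-probability (a non-positive number).
#' @examples
#' ewens_log_likelihood(make_sample(c(2, 1)), theta = 1)  # log(1/2)
#' @export
ewens_log_likelihood <- function(sample, theta) {
  sample <- as_sample(sample)
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) || theta <= 0)
    stop("theta must be a positive number")
  J <- sample$J
  phi <- phi_spectrum(sample)
  lgamma(J + 1) + sample$S * log(theta) -
    sum(log(sample$abundances)) - sum(lgamma(as.numeric(phi) + 1)) -
    sum(log(theta + 0:(J - 1)))
}

# expected species richness under Ewens: E[S] = sum_{k=0}^{J-1} theta/(theta+k)
#   = theta * (digamma(theta+J) - digamma(theta))
ewens_expected_richness <- function(theta, J) {
  theta * (digamma(theta + J) - digamma(theta))
}

#' Maximum-likelihood Ewens fit (fundamental biodiversity number)
#'
#' Under the Ewens sampling formula the species count `S` is sufficient for
#' `theta`; the MLE solves the richness equation
#' \deqn{S = \sum_{k=0}^{J-1} \frac{\theta}{\theta+k}
#'         = \theta\,(\psi(\theta+J)-\psi(\theta)).}
#' The root is bracketed on `theta` in \[1e-8, 1e8\] (the right-hand side is
#' smooth and strictly increasing in `theta`), solved by bisection via
#' [stats::uniroot()] on the log scale and polished with Newton steps to
#' machine precision.
#'
#' @param J total number of reads (individuals) in the sample, or a
#'   [community_sample][make_sample] (in which case `S` is ignored).
#' @param S number of species in the sample, `1 <= S <= J`.
#' @param sample optional [community_sample][make_sample] used to evaluate
#'   the log-likelihood at the optimum; when `J` is itself a sample it is
#'   used automatically.
#' @return An object of class `ewens_fit`: list with `theta_hat`, `logL`
#'   (log-likelihood at the optimum; `NA` when no abundance vector is
#'   available), and `boundary_flag` (`"interior"`, `"at_zero"` for S = 1,
#'   `"at_infinity"` for S = J, where the MLE lies on the boundary).
#' @examples
#' ewens_theta_mle(479, 57)$theta_hat   # 16.654
#' @export
ewens_theta_mle <- function(J, S = NULL, sample = NULL) {
  if (is_community_sample(J)) {
    sample <- J
    J <- sample$J
    S <- sample$S
  }
  if (!is.numeric(J) || !is.numeric(S) || J < 1 || S < 1 || S > J)
    stop("need 1 <= S <= J")
  J <- as.numeric(J)
  S <- as.numeric(S)
  logL_at <- function(th) {
    if (is.null(sample)) NA_real_ else ewens_log_likelihood(sample, th)
  }
  if (S == J) {
    # all singletons: likelihood increases to its supremum as theta -> Inf
    fit <- list(theta_hat = Inf, logL = 0, boundary_flag = "at_infinity")
    return(structure(fit, class = "ewens_fit"))
  }
  if (S == 1) {
    # monodominant: supremum at theta -> 0, P -> 1
    fit <- list(theta_hat = 0, logL = 0, boundary_flag = "at_zero")
    return(structure(fit, class = "ewens_fit"))
  }
  f <- function(lt) ewens_expected_richness(exp(lt), J) - S
  root <- stats::uniroot(f, lower = log(1e-8), upper = log(1e8),
                         tol = 1e-12)$root
  theta <- exp(root)
  # Newton polish on theta; derivative of E[S] wrt theta
  for (i in 1:3) {
    g <- ewens_expected_richness(theta, J) - S
    dg <- (digamma(theta + J) - digamma(theta)) +
      theta * (trigamma(theta + J) - trigamma(theta))
    step <- g / dg
    if (!is.finite(step) || abs(step) >= theta) break
    theta <- theta - step
  }
  structure(list(theta_hat = theta, logL = logL_at(theta),
                 boundary_flag = "interior"),
            class = "ewens_fit")
}

#' @export
print.ewens_fit <- function(x, ...) {
  cat("Ewens fit: theta_hat =", format(x$theta_hat, digits = 6),
      " logL =", format(x$logL, digits = 6),
      " [", x$boundary_flag, "]\n")
  invisible(x)
}
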