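# Etienne's dispersal-limited sampling formula.
#
# P(D | theta, m, J) = J! / (prod_i n_i * prod_j phi_j!) *
#   theta^S / (I)_J * sum_{A=S}^{J} K(D,A) I^A / (theta)_A
# with I = m (J-1) / (1-m) and (x)_A the rising factorial.  K(D,A) sums,
# over assignments of ancestor counts a_i (1 <= a_i <= n_i, sum a_i = A),
# the products s(n_i,a_i) (a_i-1)! / (n_i-1)!.  That sum is the coefficient
# of a product of per-species polynomials, so it is computed by log-space
# polynomial convolution, never by enumerating assignments.

# convolution of two polynomials given by log-coefficients (ascending degree)
log_poly_mult <- function(la, lb) {
  na <- length(la)
  nb <- length(lb)
  out <- numeric(na + nb - 1L)
  for (k in seq_along(out)) {
    i <- max(1L, k - nb + 1L):min(na, k)
    v <- la[i] + lb[k - i + 1L]
    m <- max(v)
    out[k] <- if (is.finite(m)) m + log(sum(exp(v - m))) else -Inf
  }
  out
}

#' Ancestor-count coefficients K(D, A) for Etienne's formula
#'
#' For a sample D with abundances `n_1..n_S`, `K(D, A)` weights the
#' configurations in which the J sampled individuals descend from exactly
#' `A` immigrant ancestors (`S <= A <= J`).  Species `i` contributes a
#' polynomial in its ancestor count `a_i` with coefficients
#' `s(n_i, a_i) (a_i - 1)! / (n_i - 1)!`; `K(D, A)` is the degree-`A`
#' coefficient of the product of all `S` polynomials.  The product is
#' evaluated by log-space convolution, which is stable and polynomial-time
#' where direct enumeration of the assignments is combinatorial.
#'
#' @param sample a [community_sample][make_sample].
#' @param table optional [stirling_table()] covering the largest abundance;
#'   built (and cached) automatically when omitted.
#' @return Object of class `k_coefficients`: list with `A` (the vector
#'   `S:J`) and `logK` (log K(D, A), same length).  `K(D,S) = K(D,J) = 1`.
#' @examples
#' k <- k_coefficients(make_sample(c(3, 1)))
#' exp(k$logK)  # 1, 1.5, 1 for A = 2, 3, 4
#' @export
k_coefficients <- function(sample, table = NULL) {
  sample <- as_sample(sample)
  nmax <- max(sample$abundances)
  if (is.null(table)) table <- stirling_cached(nmax)
  if (table$max_n < nmax)
    stop("stirling_table too small: need max_n >= ", nmax)
  log_s <- table$log_s
  # per-species log-coefficients for a = 1..n_i (ascending)
  acc <- NULL
  for (n_i in sample$abundances) {
    a <- seq_len(n_i)
    co <- log_s[n_i, a] + lgamma(a) - lgamma(n_i)
    acc <- if (is.null(acc)) co else log_poly_mult(acc, co)
  }
  # acc[k] is the coefficient for A = S + (k - 1) ... no: product of S
  # polynomials each starting at degree 1, stored from their lowest degree;
  # entry k corresponds to A = S + k - 1.
  structure(list(A = sample$S:sample$J, logK = acc,
                 J = sample$J, S = sample$S),
            class = "k_coefficients")
}

#' @export
print.k_coefficients <- function(x, ...) {
  cat("K(D,A) coefficients, A =", x$S, "..", x$J, "\n")
  invisible(x)
}

# log rising factorial (x)_n as an exact sum of logs; immune to the
# cancellation lgamma(x+n)-lgamma(x) suffers when x ~ 1e11 (m near 1)
log_rising <- function(x, n) {
  if (n == 0) return(0)
  sum(log(x + 0:(n - 1)))
}

#' Etienne sampling formula log-likelihood
#'
#' Log-probability of a sample under the dispersal-limited neutral model
#' with biodiversity number `theta` and immigration probability `m`.  The
#' immigration pressure is `I = m (J - 1) / (1 - m)`; `m = 1` is the
#' no-dispersal-limitation limit and is routed to
#' [ewens_log_likelihood()] exactly (I diverges there).
#'
#' @param sample a [community_sample][make_sample].
#' @param theta positive biodiversity number.
#' @param m immigration probability in (0, 1].
#' @param kcoef optional precomputed [k_coefficients()] for `sample`
#'   (compute once per sample when optimising).
#' @return The log-probability.
#' @export
etienne_log_likelihood <- function(sample, theta, m, kcoef = NULL) {
  sample <- as_sample(sample)
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) || theta <= 0)
    stop("theta must be a positive number")
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m <= 0 || m > 1)
    stop("m must be in (0, 1]")
  if (m == 1) return(ewens_log_likelihood(sample, theta))
  J <- sample$J
  S <- sample$S
  if (J == 1) return(0)  # a single individual is one species surely; I = 0
  if (is.null(kcoef)) kcoef <- k_coefficients(sample)
  I <- m * (J - 1) / (1 - m)
  phi <- phi_spectrum(sample)
  const <- lgamma(J + 1) - sum(log(sample$abundances)) -
    sum(lgamma(as.numeric(phi) + 1))
  log_poch_theta <- cumsum(log(theta + 0:(J - 1)))  # (theta)_A for A = 1..J
  A <- kcoef$A
  terms <- kcoef$logK + A * log(I) - log_poch_theta[A]
  const + S * log(theta) - log_rising(I, J) + log_sum_exp(terms)
}

#' Joint maximum-likelihood Etienne fit
#'
#' Maximises the Etienne log-likelihood over `(log theta, logit m)` with
#' derivative-free Nelder-Mead from several starts: the Ewens MLE of
#' `theta` paired with `m` in {1 - 1e-6, 0.999, 0.9, 0.5, 0.1}.  The
#' K(D, A) coefficients are computed once per sample, so each likelihood
#' evaluation is O(J).  `m` is clamped to \[1e-6, 1 - 1e-9\]; the fitted
#' `m` for dispersal-unlimited data sits against the upper clamp, where the
#' formula agrees with Ewens.
#'
#' @param sample a [community_sample][make_sample] with `S >= 2` (a single
#'   species cannot constrain the model; matches the one real sample the
#'   formula could not be fitted to).
#' @param starts_m immigration-probability starting values.
#' @param control passed to [stats::optim()] (Nelder-Mead).
#' @return Object of class `etienne_fit`: `theta_hat`, `m_hat`, `I_hat`
#'   (`= m(J-1)/(1-m)`), `logL`, `converged`, `failure_reason`.
#' @export
etienne_mle <- function(sample,
                        starts_m = c(1 - 1e-6, 0.999, 0.9, 0.5, 0.1),
                        control = list(maxit = 500, reltol = 1e-10)) {
  sample <- as_sample(sample)
  if (sample$S < 2)
    stop("etienne_mle infeasible: need at least 2 species (S = ",
         sample$S, ")")
  J <- sample$J
  kcoef <- k_coefficients(sample)
  m_lo <- 1e-6
  m_hi <- 1 - 1e-9
  clamp_m <- function(m) min(max(m, m_lo), m_hi)
  negll <- function(par) {
    theta <- exp(par[1])
    m <- clamp_m(stats::plogis(par[2]))
    v <- etienne_log_likelihood(sample, theta, m, kcoef)
    if (!is.finite(v)) 1e10 else -v
  }
  ew <- ewens_theta_mle(sample)
  th0 <- if (is.finite(ew$theta_hat) && ew$theta_hat > 0) ew$theta_hat
         else max(sample$S / 2, 1)
  best <- NULL
  any_ok <- FALSE
  for (m0 in starts_m) {
    fit <- tryCatch(
      stats::optim(c(log(th0), stats::qlogis(clamp_m(m0))), negll,
                   method = "Nelder-Mead", control = control),
      error = function(e) NULL)
    if (is.null(fit)) next
    any_ok <- any_ok || fit$convergence == 0
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # the Ewens boundary (m -> 1) is always a candidate: Etienne nests Ewens
  boundary_par <- c(log(th0), stats::qlogis(m_hi))
  boundary_val <- negll(boundary_par)
  if (is.null(best) || boundary_val < best$value)
    best <- list(par = boundary_par, value = boundary_val,
                 convergence = 0L)
  theta_hat <- exp(best$par[1])
  m_hat <- clamp_m(stats::plogis(best$par[2]))
  structure(list(theta_hat = theta_hat, m_hat = m_hat,
                 I_hat = m_hat * (J - 1) / (1 - m_hat),
                 logL = -best$value,
                 converged = any_ok || best$convergence == 0L,
                 failure_reason = if (any_ok) NULL else
                   "no optimiser start converged; boundary candidate used"),
            class = "etienne_fit")
}

#' @export
print.etienne_fit <- function(x, ...) {
  cat("Etienne fit: theta_hat =", format(x$theta_hat, digits = 6),
      " m_hat =", format(x$m_hat, digits = 6),
      " logL =", format(x$logL, digits = 6),
      if (x$converged) "" else " (not converged)", "\n")
  invisible(x)
}
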