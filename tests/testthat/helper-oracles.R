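# Independent oracles used across the suite.  Everything here is
# deliberately brute-force: enumeration and direct products, no shared
# code paths with the package internals they check.

# all integer partitions of n (decreasing parts)
all_partitions <- function(n) {
  rec <- function(n, max) {
    if (n == 0) return(list(integer(0)))
    out <- list()
    for (k in min(n, max):1)
      for (p in rec(n - k, k)) out <- c(out, list(c(k, p)))
    out
  }
  rec(n, n)
}

# Ewens probability of one partition, by the raw formula (small J only)
ewens_prob_direct <- function(part, theta) {
  J <- sum(part)
  phi <- tabulate(part)
  num <- factorial(J) * theta^length(part)
  den <- prod((seq_along(phi)^phi) * factorial(phi)) *
    prod(theta + 0:(J - 1))
  num / den
}

# unsigned Stirling numbers of the first kind by integer recurrence
stirling_direct <- function(max_n) {
  s <- matrix(0, max_n, max_n)
  s[1, 1] <- 1
  if (max_n >= 2) for (n in 2:max_n) {
    s[n, 1] <- (n - 1) * s[n - 1, 1]
    s[n, n] <- 1
    if (n > 2) for (a in 2:(n - 1))
      s[n, a] <- s[n - 1, a - 1] + (n - 1) * s[n - 1, a]
  }
  s
}

# K(D,A) by full enumeration of ancestor-count assignments (J <= 12)
k_brute_force <- function(ab) {
  S <- length(ab)
  s <- stirling_direct(max(ab))
  g <- do.call(expand.grid, lapply(ab, seq_len))
  A <- rowSums(g)
  w <- apply(g, 1, function(a)
    prod(vapply(seq_len(S), function(i)
      s[ab[i], a[i]] * factorial(a[i] - 1) / factorial(ab[i] - 1),
      numeric(1))))
  as.vector(tapply(w, A, sum))
}

# Fisher two-sided p by direct hypergeometric summation (independent of
# fisher.test): sum P(tables with same margins) over tables no more
# probable than the observed one
fisher_enum <- function(tab) {
  a <- tab[1, 1]
  m1 <- sum(tab[1, ])
  m2 <- sum(tab[2, ])
  cs <- sum(tab[, 1])
  lo <- max(0, cs - m2)
  hi <- min(cs, m1)
  p_all <- dhyper(lo:hi, m1, m2, cs)
  p_obs <- dhyper(a, m1, m2, cs)
  sum(p_all[p_all <= p_obs * (1 + 1e-7)])
}

# the package's documented substream policy, restated independently
substream_seed_test <- function(master, i)
  as.integer((as.numeric(master) + as.numeric(i) * 7919) %% 2147483647)

# independent log(exp(x) + exp(y))
logaddexp_test <- function(x, y) pmax(x, y) + log1p(exp(-abs(x - y)))

# deterministic per-test RNG scope
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
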