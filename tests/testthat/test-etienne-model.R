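test_that("Stirling log-table matches the exact integer triangle", {
  st <- stirling_table(12)
  expect_equal(exp(st$log_s[4, 1]), 6)   # (n-1)!
  expect_equal(exp(st$log_s[4, 4]), 1)
  expect_equal(exp(st$log_s[4, 2]), 11)
  s_exact <- stirling_direct(12)
  for (n in 1:12) for (a in 1:n)
    expect_equal(exp(st$log_s[n, a]), s_exact[n, a],
                 tolerance = 1e-9 * s_exact[n, a])
  # recurrence holds in log space well beyond exact-integer range
  st2 <- stirling_table(120)
  for (n in c(50, 120)) for (a in c(2, 10, n - 1)) {
    lhs <- st2$log_s[n, a]
    rhs <- logaddexp_test(st2$log_s[n - 1, a - 1],
                          log(n - 1) + st2$log_s[n - 1, a])
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("K(D,A) endpoints are forced and the convolution matches brute force", {
  for (ab in list(c(3, 1), c(5, 4, 2, 1), c(6, 3, 2, 1), c(4, 4, 4),
                  c(2, 2, 2, 2, 2, 1, 1), c(9, 2, 1), c(12))) {
    k <- k_coefficients(make_sample(ab))
    expect_equal(k$A, sum(ab > 0):sum(ab))
    expect_equal(exp(k$logK[1]), 1, tolerance = 1e-10)        # A = S
    expect_equal(exp(k$logK[length(k$logK)]), 1, tolerance = 1e-10)  # A = J
    expect_true(all(is.finite(k$logK)))                       # K > 0
    bk <- k_brute_force(ab)
    expect_equal(exp(k$logK), unname(bk), tolerance = 1e-10)
  }
  expect_equal(exp(k_coefficients(make_sample(c(3, 1)))$logK[2]), 1.5,
               tolerance = 1e-12)
  expect_error(k_coefficients(make_sample(c(9, 1)), stirling_table(5)),
               "too small")
})

test_that("Etienne likelihood normalises and degenerates correctly", {
  expect_equal(etienne_log_likelihood(make_sample(1), 3, 0.4), 0)
  # normalisation over all abundance configurations, J <= 5, (theta,m) grid
  for (J in 3:5) for (theta in c(0.5, 1, 3)) for (m in c(0.2, 0.5, 0.9)) {
    total <- sum(vapply(all_partitions(J), function(p)
      exp(etienne_log_likelihood(make_sample(p), theta, m)), numeric(1)))
    expect_equal(total, 1, tolerance = 1e-8)
  }
  # m -> 1 boundary agrees with Ewens
  expect_equal(etienne_log_likelihood(make_sample(c(2, 1)), 1, 0.999999),
               log(0.5), tolerance = 1e-4)
  with_seed(23, for (r in 1:20) {
    s <- simulate_community(neutral_params(runif(1, 2, 25), 1,
                                           sample(20:200, 1),
                                           seed = sample.int(1e6, 1)))
    theta <- runif(1, 0.5, 30)
    expect_equal(etienne_log_likelihood(s, theta, 1 - 1e-8),
                 ewens_log_likelihood(s, theta), tolerance = 1e-4)
  })
  # m = 1 exactly routes to Ewens
  s <- make_sample(c(4, 2, 1))
  expect_identical(etienne_log_likelihood(s, 2, 1),
                   ewens_log_likelihood(s, 2))
  expect_error(etienne_log_likelihood(s, -1, 0.5), "positive")
  expect_error(etienne_log_likelihood(s, 2, 0), "in \\(0, 1\\]")
  expect_error(etienne_log_likelihood(s, 2, 1.2), "in \\(0, 1\\]")
})

test_that("Etienne MLE nests Ewens and is infeasible for S < 2", {
  expect_error(etienne_mle(make_sample(9)), "at least 2 species")
  with_seed(31, for (r in 1:8) {
    s <- simulate_community(neutral_params(runif(1, 3, 20), 1,
                                           sample(80:300, 1),
                                           seed = sample.int(1e6, 1)))
    ew <- ewens_theta_mle(s)
    et <- etienne_mle(s)
    expect_true(et$converged)
    expect_gte(et$logL, ew$logL - 1e-6)     # Ewens is the m -> 1 boundary
    expect_gt(et$m_hat, 0)
    expect_lte(et$m_hat, 1)
    expect_equal(et$I_hat, et$m_hat * (s$J - 1) / (1 - et$m_hat),
                 tolerance = 1e-9)
  })
})

test_that("Etienne MLE recovers theta from dispersal-limited data", {
  # median theta_hat within 30% of truth; the median is the right summary
  # because (theta, m) sit on a weakly identified ridge near m = 1 and a
  # minority of fits wander far along it
  with_seed(47, {
    th <- replicate(50, {
      s <- simulate_community(neutral_params(17, 0.9999, 800,
                                             seed = sample.int(1e6, 1)))
      etienne_mle(s)$theta_hat
    })
    expect_lt(abs(median(th) - 17) / 17, 0.30)
  })
})
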