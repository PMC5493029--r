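test_that("likelihood-ratio test handles ties, clamping and propagation", {
  f0 <- structure(list(theta_hat = 5, logL = -12), class = "ewens_fit")
  f1 <- structure(list(theta_hat = 5, m_hat = 1, logL = -12),
                  class = "etienne_fit")
  r <- likelihood_ratio_test(f0, f1)
  expect_identical(r$deviance, 0)
  expect_identical(r$p_value, 1)
  # tiny negative deviance from optimiser tolerance clamps silently
  f1$logL <- -12 - 1e-8
  expect_identical(likelihood_ratio_test(f0, f1)$deviance, 0)
  f1$logL <- NA_real_
  expect_error(likelihood_ratio_test(f0, f1), "log-likelihood")
})

test_that("fisher_exact_2x2 matches independent hypergeometric enumeration", {
  expect_lt(abs(fisher_exact_2x2(matrix(c(3, 43, 1, 55), 2,
                                        byrow = TRUE)) - 0.324), 1e-3)
  expect_message(
    p0 <- fisher_exact_2x2(matrix(c(0, 46, 0, 56), 2, byrow = TRUE)),
    "zero margin")
  expect_identical(p0, 1)
  expect_equal(fisher_exact_2x2(matrix(c(2, 2, 2, 2), 2)), 1)
  expect_error(fisher_exact_2x2(matrix(1:6, 2)), "2x2")
  expect_error(fisher_exact_2x2(matrix(c(1.5, 2, 3, 4), 2)), "integer")
  with_seed(13, for (r in 1:50) {
    tab <- matrix(rpois(4, 8), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab), fisher_enum(tab),
                 tolerance = 1e-9)
  })
})

test_that("group theta comparison behaves at the edges", {
  same <- c(3, 5, 7, 9)
  expect_equal(compare_theta_groups(same, same)$p_value, 1)
  expect_error(compare_theta_groups(c(1, 2), 5), "at least 2")
  fits <- lapply(c(4, 6, 8), function(t)
    structure(list(theta_hat = t), class = "ewens_fit"))
  cmp <- compare_theta_groups(fits, c(10, 12, 14), variant = "welch")
  expect_equal(cmp$mean_a, 6)
  expect_equal(cmp$mean_b, 12)
  # student variant agrees with the pooled-variance t-test
  a <- c(2, 4, 9, 3)
  b <- c(7, 8, 12)
  expect_equal(compare_theta_groups(a, b, "student")$p_value,
               t.test(a, b, var.equal = TRUE)$p.value)
})

test_that("exact neutrality test is deterministic and reports both p-values", {
  s <- simulate_community(neutral_params(10, 1, 300, seed = 5))
  r1 <- exact_neutrality_test(s, n_sim = 40, seed = 17)
  r2 <- exact_neutrality_test(s, n_sim = 40, seed = 17)
  expect_identical(r1$sim_logLs, r2$sim_logLs)
  expect_identical(r1$p_quantile, r2$p_quantile)
  expect_length(r1$sim_logLs, 40)
  expect_gte(r1$p_quantile, 0)
  expect_lte(r1$p_quantile, 1)
  expect_gte(r1$p_chisq, 0)
  expect_lte(r1$p_chisq, 1)
  expect_identical(r1$is_neutral, r1$p_used >= r1$alpha)
  # boundary samples are untestable
  expect_error(exact_neutrality_test(make_sample(rep(1, 8)), n_sim = 5),
               "untestable")
})

test_that("exact test keeps size under the null and rejects niche SADs", {
  # type-I error at alpha = 0.05 (reduced replication; the acceptance
  # suite runs the full calibration)
  with_seed(61, {
    rej <- mean(replicate(60, {
      s <- simulate_community(neutral_params(15, 1, 500,
                                             seed = sample.int(1e6, 1)))
      exact_neutrality_test(s, n_sim = 100,
                            seed = sample.int(1e6, 1))$p_quantile < 0.05
    }))
    expect_lt(abs(rej - 0.05), 0.07)
  })
  # power against niche SADs whose shape departs from the logseries: a
  # near-even geometric series and a moderate lognormal.  (A ratio-0.5
  # geometric series is shape-indistinguishable from the neutral
  # logseries at its fitted theta, so no SAD-based test can reject it.)
  with_seed(67, {
    rej <- mean(replicate(25, {
      s <- generate_non_neutral("geometric", S_target = 30, J = 1000,
                                shape = 0.9, seed = sample.int(1e6, 1))
      exact_neutrality_test(s, n_sim = 100,
                            seed = sample.int(1e6, 1))$p_quantile < 0.05
    }))
    expect_gt(rej, 0.8)
  })
  with_seed(68, {
    rej <- mean(replicate(25, {
      s <- generate_non_neutral("lognormal", S_target = 30, J = 1000,
                                shape = 1, seed = sample.int(1e6, 1))
      exact_neutrality_test(s, n_sim = 100,
                            seed = sample.int(1e6, 1))$p_quantile < 0.05
    }))
    expect_gt(rej, 0.8)
  })
})

test_that("p_quantile is approximately uniform under the null", {
  with_seed(71, {
    p <- replicate(120, {
      s <- simulate_community(neutral_params(12, 1, 300,
                                             seed = sample.int(1e6, 1)))
      exact_neutrality_test(s, n_sim = 50,
                            seed = sample.int(1e6, 1))$p_quantile
    })
    expect_gt(suppressWarnings(
      ks.test(p, "punif")$p.value), 0.01)
  })
})

test_that("run_cohort composes per-sample results and group statistics", {
  coh <- generate_cohort(cohort_spec(n_control = 6, n_disease = 5,
                                     J_range = c(100, 300), seed = 3))
  cfg <- run_config(n_sim = 30, seed = 9)
  rep <- run_cohort(coh$samples, cfg)
  ps <- rep$per_sample
  expect_identical(nrow(ps), 11L)
  # rows reproduce the individual operations
  i <- 4
  s <- coh$samples[[i]]
  expect_equal(ps$theta_ewens[i], ewens_theta_mle(s)$theta_hat)
  nt <- exact_neutrality_test(s, n_sim = 30, seed = substream_seed_test(9, i))
  expect_equal(ps$p_quantile[i], nt$p_quantile)
  # pass counts equal the per-sample verdicts
  expect_identical(
    as.integer(rep$pass_counts["control", "pass"]),
    sum(ps$is_neutral[ps$group == "control"], na.rm = TRUE))
  expect_identical(
    as.integer(rep$pass_counts["disease", "pass"]),
    sum(ps$is_neutral[ps$group == "disease"], na.rm = TRUE))
  expect_equal(unname(rep$percentages),
               unname(rep$pass_counts[, "pass"] / rowSums(rep$pass_counts)))
  expect_true(is.finite(rep$fisher_p))
  expect_true(is.finite(rep$ttest_p))
  # margins equal group sizes
  expect_identical(unname(rowSums(rep$pass_counts)), c(6, 5))
})

test_that("run_cohort tolerates a missing group and per-sample failures", {
  samples <- simulate_ensemble(neutral_params(8, 1, 120, seed = 2), 4)
  rep <- run_cohort(samples, run_config(n_sim = 10, seed = 1,
                                        fit_etienne = FALSE))
  expect_identical(nrow(rep$per_sample), 4L)
  expect_null(rep$pass_counts)
  expect_true(is.na(rep$ttest_p))
  # a monodominant sample fails Etienne + exact test but is still reported
  samples2 <- c(samples, list(make_sample(c(50), "mono", "control")))
  rep2 <- run_cohort(samples2, run_config(n_sim = 10, seed = 1))
  row <- rep2$per_sample[rep2$per_sample$sample_id == "mono", ]
  expect_false(row$testable)
  expect_true(is.na(row$theta_etienne))
  expect_match(row$etienne_error, "at least 2 species")
})
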