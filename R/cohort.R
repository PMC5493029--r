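#' Configuration for a cohort analysis run
#'
#' Defaults follow the study design the pipeline emulates: the exact test
#' uses the Ewens formula with 100 simulated communities per sample at
#' alpha = 0.05, and group mean theta is compared with a Student (pooled
#' variance) t-test.
#'
#' @param model sampling formula driving the exact test: `"ewens"` or
#'   `"etienne"`.
#' @param n_sim simulated communities per sample.
#' @param alpha significance level of the neutrality verdict.
#' @param p_variant p-value driving the verdict, `"quantile"` or
#'   `"chisq"` (see [exact_neutrality_test()]).
#' @param ttest `"student"` or `"welch"`.
#' @param seed master seed; each sample gets its own substream.
#' @param refit refit the model to each simulated community.
#' @param fit_etienne also fit the Etienne formula per sample (needed for
#'   the likelihood-ratio columns; failures are tolerated and recorded).
#' @return Object of class `run_config`.
#' @export
run_config <- function(model = c("ewens", "etienne"), n_sim = 100,
                       alpha = 0.05, p_variant = c("quantile", "chisq"),
                       ttest = c("student", "welch"), seed = 1L,
                       refit = TRUE, fit_etienne = TRUE) {
  stopifnot(n_sim >= 1, alpha > 0, alpha < 1)
  structure(list(model = match.arg(model), n_sim = n_sim, alpha = alpha,
                 p_variant = match.arg(p_variant),
                 ttest = match.arg(ttest), seed = as.integer(seed),
                 refit = isTRUE(refit), fit_etienne = isTRUE(fit_etienne)),
            class = "run_config")
}

#' Run the full neutrality pipeline on a cohort of samples
#'
#' Per sample: Ewens maximum-likelihood fit, Etienne fit (failure, e.g.
#' S < 2, is tolerated and recorded), the exact neutrality test, and the
#' Ewens-vs-Etienne likelihood-ratio test.  Across samples: a
#' group-by-verdict contingency table with Fisher's exact p, per-group
#' mean theta with a t-test p, and per-group pass percentages.  Group
#' statistics require both a `"control"` and a `"disease"` group; with
#' anything else they are marked unavailable while per-sample results are
#' still produced.
#'
#' @param samples list of [community_sample][make_sample] objects.
#' @param config a [run_config()].
#' @return Object of class `cohort_report`: `per_sample` (data frame, one
#'   row per sample), `pass_counts` (2x2 group x verdict table or NULL),
#'   `fisher_p`, `theta_means`, `ttest_p`, `percentages`, `config`.
#' @export
run_cohort <- function(samples, config = run_config()) {
  stopifnot(length(samples) >= 1, inherits(config, "run_config"))
  samples <- lapply(samples, as_sample)

  rows <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    ew <- ewens_theta_mle(s)
    et <- NULL
    et_err <- NA_character_
    if (config$fit_etienne) {
      et <- tryCatch(etienne_mle(s), error = function(e) {
        et_err <<- conditionMessage(e)
        NULL
      })
    }
    lrt <- if (!is.null(et) && is.finite(ew$theta_hat) && ew$theta_hat > 0)
      likelihood_ratio_test(ew, et) else NULL
    nt <- tryCatch(
      exact_neutrality_test(s, n_sim = config$n_sim, alpha = config$alpha,
                            model = config$model,
                            seed = substream_seed(config$seed, i),
                            p_variant = config$p_variant,
                            refit = config$refit),
      error = function(e) NULL)
    rows[[i]] <- data.frame(
      sample_id = s$sample_id, group = s$group, J = s$J, S = s$S,
      theta_ewens = ew$theta_hat, logL_ewens = ew$logL,
      theta_etienne = if (!is.null(et)) et$theta_hat else NA_real_,
      m_etienne = if (!is.null(et)) et$m_hat else NA_real_,
      logL_etienne = if (!is.null(et)) et$logL else NA_real_,
      etienne_error = et_err,
      lrt_deviance = if (!is.null(lrt)) lrt$deviance else NA_real_,
      lrt_p = if (!is.null(lrt)) lrt$p_value else NA_real_,
      p_quantile = if (!is.null(nt)) nt$p_quantile else NA_real_,
      p_chisq = if (!is.null(nt)) nt$p_chisq else NA_real_,
      is_neutral = if (!is.null(nt)) nt$is_neutral else NA,
      testable = !is.null(nt),
      stringsAsFactors = FALSE)
  }
  per_sample <- do.call(rbind, rows)

  groups <- c("control", "disease")
  have_groups <- all(vapply(groups,
                            function(g) any(per_sample$group == g),
                            logical(1)))
  pass_counts <- NULL
  fisher_p <- NA_real_
  theta_means <- NULL
  ttest_p <- NA_real_
  percentages <- NULL
  if (have_groups) {
    tested <- per_sample[!is.na(per_sample$is_neutral) &
                           per_sample$group %in% groups, ]
    pass_counts <- matrix(0L, 2, 2,
                          dimnames = list(group = groups,
                                          verdict = c("pass", "fail")))
    for (g in groups) {
      pass_counts[g, "pass"] <- sum(tested$group == g & tested$is_neutral)
      pass_counts[g, "fail"] <- sum(tested$group == g & !tested$is_neutral)
    }
    fisher_p <- fisher_exact_2x2(pass_counts)
    th <- per_sample[is.finite(per_sample$theta_ewens) &
                       per_sample$group %in% groups, ]
    theta_means <- vapply(groups, function(g)
      mean(th$theta_ewens[th$group == g]), numeric(1))
    if (all(table(factor(th$group, groups)) >= 2)) {
      cmp <- compare_theta_groups(th$theta_ewens[th$group == "control"],
                                  th$theta_ewens[th$group == "disease"],
                                  variant = config$ttest)
      ttest_p <- cmp$p_value
    }
    percentages <- pass_counts[, "pass"] / rowSums(pass_counts)
  }
  structure(list(per_sample = per_sample, pass_counts = pass_counts,
                 fisher_p = fisher_p, theta_means = theta_means,
                 ttest_p = ttest_p, percentages = percentages,
                 config = config),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  n <- nrow(x$per_sample)
  cat("Cohort neutrality report:", n, "samples (model:",
      x$config$model, ", n_sim:", x$config$n_sim, ")\n")
  if (!is.null(x$pass_counts)) {
    cat("  pass counts:\n")
    print(x$pass_counts)
    cat("  pass rates:",
        paste(sprintf("%s %.1f%%", names(x$percentages),
                      100 * x$percentages), collapse = ", "), "\n")
    cat("  Fisher exact p =", format(x$fisher_p, digits = 4), "\n")
    cat("  mean theta:",
        paste(sprintf("%s %.2f", names(x$theta_means), x$theta_means),
              collapse = ", "),
        " t-test p =", format(x$ttest_p, digits = 4), "\n")
  } else {
    cat("  group statistics unavailable (need control and disease groups)\n")
  }
  invisible(x)
}

#' Write a cohort report to disk
#'
#' Writes one TSV with the per-sample results in the supplementary-table
#' column layout -- sample, group, J, S, theta, m, Log(L0), Log(L1),
#' q-value (the likelihood-ratio deviance statistic) and p-value -- plus
#' the neutrality-test p-values and verdict, and one JSON file with the
#' group summary (pass counts, Fisher p, theta means, t-test p) and the
#' full run configuration including the seed, so every stochastic output
#' can be reproduced.
#'
#' @param report a [run_cohort()] result.
#' @param tsv_path path of the per-sample TSV.
#' @param json_path path of the JSON summary (default: TSV path with
#'   `.json` extension).
#' @return Invisibly, the two paths.
#' @export
write_cohort_report <- function(report, tsv_path,
                                json_path = sub("\\.tsv$", ".json",
                                                tsv_path)) {
  stopifnot(inherits(report, "cohort_report"))
  ps <- report$per_sample
  out <- data.frame(sample = ps$sample_id, group = ps$group,
                    J = ps$J, S = ps$S,
                    theta = ps$theta_ewens, m = ps$m_etienne,
                    ps$logL_ewens, ps$logL_etienne,
                    ps$lrt_deviance, ps$lrt_p,
                    neutrality.p = if (report$config$p_variant ==
                                         "quantile")
                      ps$p_quantile else ps$p_chisq,
                    neutral = ps$is_neutral,
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out)[7:10] <- c("Log(L0)", "Log(L1)", "q-value", "p-value")
  utils::write.table(out, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summary <- list(
    n_samples = nrow(ps),
    pass_counts = if (!is.null(report$pass_counts))
      as.data.frame(as.table(report$pass_counts)) else NULL,
    fisher_p = report$fisher_p,
    theta_means = as.list(report$theta_means),
    ttest_p = report$ttest_p,
    percentages = as.list(report$percentages),
    config = unclass(report$config))
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(tsv = tsv_path, json = json_path))
}
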