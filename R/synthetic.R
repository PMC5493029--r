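#' Specification of a synthetic two-group cohort
#'
#' Defaults emulate the cohort structure the pipeline is designed for: 56
#' control and 46 disease (CRC) gut-microbiome samples, per-sample read
#' totals J drawn uniformly from a few hundred to near a thousand, and
#' per-sample biodiversity numbers drawn from group-specific truncated
#' normal distributions centred on 57.13 (control) and 42.89 (disease).
#' A designated fraction of samples can instead be generated from a
#' classical niche-type SAD (lognormal or geometric series) so the exact
#' test has structured non-neutral communities to reject.
#'
#' @param n_control,n_disease group sizes.
#' @param theta_control,theta_disease length-2 vectors `c(mean, sd)` of
#'   the per-sample theta distribution (normal truncated to > 0).
#' @param m immigration probability used by the neutral generator.
#' @param J_range integer interval for per-sample community size
#'   (within \[50, 10000\]).
#' @param non_neutral_fraction fraction of each group generated from the
#'   non-neutral model.
#' @param non_neutral_model `"lognormal"` or `"geometric"`.
#' @param non_neutral_shape shape of the non-neutral SAD: the lognormal
#'   sigma (default 2) or the geometric ratio (default 0.5).
#' @param seed master seed; every sample derives its own substream.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 56, n_disease = 46,
                        theta_control = c(mean = 57.13, sd = 8),
                        theta_disease = c(mean = 42.89, sd = 8),
                        m = 1, J_range = c(300, 900),
                        non_neutral_fraction = 0,
                        non_neutral_model = c("lognormal", "geometric"),
                        non_neutral_shape = NULL,
                        seed = 1L) {
  non_neutral_model <- match.arg(non_neutral_model)
  if (is.null(non_neutral_shape))
    non_neutral_shape <- if (non_neutral_model == "lognormal") 2 else 0.5
  stopifnot(n_control >= 0, n_disease >= 0, n_control + n_disease >= 1,
            length(J_range) == 2, J_range[1] <= J_range[2],
            J_range[1] >= 50, J_range[2] <= 10000,
            non_neutral_fraction >= 0, non_neutral_fraction <= 1,
            m > 0, m <= 1,
            theta_control[1] > 0, theta_disease[1] > 0,
            theta_control[2] >= 0, theta_disease[2] >= 0)
  structure(list(n_control = as.integer(n_control),
                 n_disease = as.integer(n_disease),
                 theta_control = theta_control,
                 theta_disease = theta_disease,
                 m = m, J_range = as.integer(J_range),
                 non_neutral_fraction = non_neutral_fraction,
                 non_neutral_model = non_neutral_model,
                 non_neutral_shape = non_neutral_shape,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# normal truncated to positives, by rejection
rtrunc_pos <- function(mean, sd) {
  for (i in 1:1000) {
    x <- stats::rnorm(1, mean, sd)
    if (x > 0) return(x)
  }
  stop("could not draw a positive theta from N(", mean, ", ", sd, ")")
}

# apportion J individuals to weights w by largest-remainder rounding;
# returns integers summing to J exactly (zero cells possible)
largest_remainder <- function(w, J) {
  x <- J * w / sum(w)
  n <- floor(x)
  r <- J - sum(n)
  if (r > 0) {
    top <- order(x - n, decreasing = TRUE)[seq_len(r)]
    n[top] <- n[top] + 1
  }
  as.integer(n)
}

#' Generate one non-neutral (niche-type) community
#'
#' Classical niche SAD alternatives: `"lognormal"` draws species weights
#' `exp(N(0, shape))`; `"geometric"` uses the geometric series
#' `shape^(rank - 1)`.  Weights are apportioned to exactly `J` individuals
#' by largest-remainder rounding; species rounded to zero are dropped.  If
#' rounding degenerates to fewer than 2 species the draw is retried on a
#' fresh substream (at most 100 times).
#'
#' @param model `"lognormal"` or `"geometric"`.
#' @param S_target number of species to draw weights for (`<= J`).
#' @param J community size; abundances sum to `J` exactly.
#' @param shape lognormal sigma or geometric ratio.
#' @param seed integer seed.
#' @param sample_id,group passed to the returned sample.
#' @return A [community_sample][make_sample].
#' @export
generate_non_neutral <- function(model = c("lognormal", "geometric"),
                                 S_target, J, shape, seed = 1L,
                                 sample_id = "nonneutral",
                                 group = "unlabeled") {
  model <- match.arg(model)
  stopifnot(S_target >= 1, S_target <= J, shape > 0)
  for (attempt in 0:99) {
    w <- with_seed_restore(substream_seed(seed, attempt),
      switch(model,
             lognormal = exp(stats::rnorm(S_target, 0, shape)),
             geometric = shape^(seq_len(S_target) - 1)))
    counts <- largest_remainder(w, J)
    if (sum(counts > 0) >= 2)
      return(make_sample(counts, sample_id = sample_id, group = group))
  }
  stop("generate_non_neutral: rounding degenerated to S < 2 in 100 attempts")
}

#' Generate a synthetic two-group cohort with known ground truth
#'
#' Per sample: draw theta from its group's truncated-normal distribution
#' and J uniformly from `J_range`, then simulate a neutral community at
#' `(theta, m, J)` -- or, for the designated non-neutral fraction of each
#' group, generate a niche-type SAD with the expected neutral richness as
#' its species count.  Every generator call is recorded in a truth table
#' so parameter-recovery and power properties can be checked.
#'
#' @param spec a [cohort_spec()].
#' @return Object of class `synthetic_cohort`: `samples` (list of
#'   [community_sample][make_sample]), `truth` (data frame: sample_id,
#'   group, model, theta, m, J, S_target, shape, seed), `spec`.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_control = 3, n_disease = 2,
#'                                    J_range = c(100, 200), seed = 7))
#' coh$truth
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- c(rep("control", spec$n_control),
              rep("disease", spec$n_disease))
  ids <- c(sprintf("H%02d", seq_len(spec$n_control)),
           sprintf("C%02d", seq_len(spec$n_disease)))
  n <- length(groups)
  # choose which samples are non-neutral, per group, reproducibly
  non_neutral <- with_seed_restore(spec$seed, {
    flags <- logical(n)
    for (g in c("control", "disease")) {
      idx <- which(groups == g)
      k <- round(spec$non_neutral_fraction * length(idx))
      if (k > 0) flags[sample(idx, k)] <- TRUE
    }
    flags
  })
  samples <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    seed_i <- substream_seed(spec$seed, 100000 + i)
    par <- if (groups[i] == "control") spec$theta_control else
      spec$theta_disease
    draw <- with_seed_restore(seed_i, list(
      theta = rtrunc_pos(par[[1]], par[[2]]),
      J = sample(spec$J_range[1]:spec$J_range[2], 1)))
    theta <- draw$theta
    J <- draw$J
    if (!non_neutral[i]) {
      samples[[i]] <- simulate_community(
        neutral_params(theta, spec$m, J, seed = substream_seed(seed_i, 1)),
        sample_id = ids[i], group = groups[i])
      truth[[i]] <- data.frame(
        sample_id = ids[i], group = groups[i], model = "neutral",
        theta = theta, m = spec$m, J = J, S_target = NA_integer_,
        shape = NA_real_, seed = seed_i, stringsAsFactors = FALSE)
    } else {
      S_target <- max(2L, round(ewens_expected_richness(theta, J)))
      samples[[i]] <- generate_non_neutral(
        spec$non_neutral_model, S_target, J, spec$non_neutral_shape,
        seed = substream_seed(seed_i, 1), sample_id = ids[i],
        group = groups[i])
      truth[[i]] <- data.frame(
        sample_id = ids[i], group = groups[i],
        model = spec$non_neutral_model, theta = NA_real_, m = NA_real_,
        J = J, S_target = S_target, shape = spec$non_neutral_shape,
        seed = seed_i, stringsAsFactors = FALSE)
    }
  }
  structure(list(samples = samples, truth = do.call(rbind, truth),
                 spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", length(x$samples), "samples (",
      x$spec$n_control, "control /", x$spec$n_disease, "disease )\n")
  cat("  non-neutral fraction:", x$spec$non_neutral_fraction,
      "(", x$spec$non_neutral_model, ")\n")
  invisible(x)
}
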