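# Sequential (urn) construction of neutral local communities.
#
# The sample of J individuals is built one individual at a time, which
# draws exactly from the stationary sampling formulas rather than
# approximating them with forward dynamics:
#
#   m = 1 (no dispersal limitation; Ewens / Chinese-restaurant urn):
#     individual k founds a new species with probability theta/(theta+k-1),
#     otherwise it copies a uniformly chosen earlier individual.
#
#   m < 1 (Etienne): individual k is an immigrant with probability
#     I/(I+k-1), I = m(J-1)/(1-m); otherwise it copies a uniformly chosen
#     earlier local individual.  The a-th immigrant founds a new species
#     with probability theta/(theta+a-1), otherwise it copies the species
#     of a uniformly chosen earlier immigrant.

#' Parameters of a neutral local community
#'
#' @param theta positive fundamental biodiversity number.
#' @param m immigration probability in (0, 1]; `m = 1` removes dispersal
#'   limitation.
#' @param J community size (number of individuals / reads).
#' @param seed integer seed; [simulate_ensemble()] derives one reproducible
#'   substream per community from it.
#' @return Object of class `neutral_params`.
#' @export
neutral_params <- function(theta, m = 1, J, seed = 1L) {
  if (!is.numeric(theta) || theta <= 0) stop("theta must be > 0")
  if (!is.numeric(m) || m <= 0 || m > 1) stop("m must be in (0, 1]")
  if (!is.numeric(J) || J < 1) stop("J must be a positive integer")
  structure(list(theta = theta, m = m, J = as.integer(J),
                 seed = as.integer(seed)),
            class = "neutral_params")
}

# deterministic substream derivation, kept inside 32-bit integer range
substream_seed <- function(master, i) {
  as.integer((as.numeric(master) + as.numeric(i) * 7919) %% 2147483647)
}

# evaluate code under a fixed seed, then restore the caller's RNG state:
# seeded generators must not perturb an enclosing simulation loop
with_seed_restore <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

#' Simulate one neutral local community
#'
#' Sequential urn sampling from the neutral model (see the package
#' vignette): exact draws from the Ewens formula when `m = 1` and from the
#' dispersal-limited (Etienne) formula when `m < 1`, in O(J) time.
#'
#' @param params a [neutral_params()] object.
#' @param sample_id,group passed to the returned sample.
#' @return A [community_sample][make_sample] with total abundance exactly
#'   `params$J`.
#' @examples
#' simulate_community(neutral_params(theta = 5, m = 1, J = 100, seed = 42))
#' @export
simulate_community <- function(params, sample_id = "sim",
                               group = "unlabeled") {
  stopifnot(inherits(params, "neutral_params"))
  J <- params$J
  theta <- params$theta
  m <- params$m
  species <- with_seed_restore(params$seed, {
  species <- integer(J)
  if (m == 1) {
    k <- seq_len(J)
    is_new <- stats::runif(J) < theta / (theta + k - 1)
    is_new[1] <- TRUE
    # pre-draw the copied ancestor index for every individual
    copy_from <- c(1L, 1L + floor(stats::runif(J - 1) * (k[-1] - 1)))
    n_sp <- 0L
    for (kk in k) {
      if (is_new[kk]) {
        n_sp <- n_sp + 1L
        species[kk] <- n_sp
      } else {
        species[kk] <- species[copy_from[kk]]
      }
    }
  } else {
    I <- m * (J - 1) / (1 - m)
    k <- seq_len(J)
    is_imm <- stats::runif(J) < I / (I + k - 1)
    is_imm[1] <- TRUE
    copy_local <- c(1L, 1L + floor(stats::runif(J - 1) * (k[-1] - 1)))
    u_new <- stats::runif(J)      # consumed per immigrant, in order
    u_anc <- stats::runif(J)
    imm_species <- integer(J)     # species of the a-th immigrant
    n_imm <- 0L
    n_sp <- 0L
    for (kk in k) {
      if (is_imm[kk]) {
        n_imm <- n_imm + 1L
        if (u_new[n_imm] < theta / (theta + n_imm - 1)) {
          n_sp <- n_sp + 1L
          imm_species[n_imm] <- n_sp
        } else {
          imm_species[n_imm] <-
            imm_species[1L + floor(u_anc[n_imm] * (n_imm - 1))]
        }
        species[kk] <- imm_species[n_imm]
      } else {
        species[kk] <- species[copy_local[kk]]
      }
    }
  }
  species
  })
  make_sample(tabulate(species), sample_id = sample_id, group = group)
}

#' Simulate an ensemble of independent neutral communities
#'
#' Each community uses its own substream seed derived deterministically
#' from `params$seed`, so ensembles are bitwise reproducible and
#' individually re-creatable.
#'
#' @param params a [neutral_params()] object.
#' @param n_sim number of communities.
#' @param id_prefix prefix for the generated sample ids.
#' @return List of [community_sample][make_sample] objects, length `n_sim`.
#' @export
simulate_ensemble <- function(params, n_sim, id_prefix = "sim") {
  stopifnot(inherits(params, "neutral_params"), n_sim >= 1)
  lapply(seq_len(n_sim), function(i) {
    p_i <- params
    p_i$seed <- substream_seed(params$seed, i)
    simulate_community(p_i, sample_id = paste0(id_prefix, i))
  })
}
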