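#' Construct a community sample from raw OTU counts
#'
#' A `community_sample` is one sample's species abundance distribution
#' (SAD): the vector of per-OTU read counts with zeros removed, stored in
#' decreasing order (the sampling formulas are label-invariant, so the
#' sorted vector is a canonical form).  `J` is the total number of reads in
#' the sample and `S` the number of species (OTUs) present.
#'
#' @param counts non-negative integer vector of per-OTU read counts.
#' @param sample_id character scalar identifying the sample.
#' @param group group label, one of `"control"`, `"disease"`,
#'   `"unlabeled"`.
#'
#' @return An object of class `community_sample`: a list with elements
#'   `sample_id`, `group`, `abundances` (positive integers, decreasing),
#'   `J`, `S`, and `n_dropped` (number of zero-count OTUs removed).
#'
#' @examples
#' make_sample(c(0, 5, 2, 0, 1), "toy")
#' @export
make_sample <- function(counts, sample_id = "sample",
                        group = c("unlabeled", "control", "disease")) {
  group <- match.arg(group)
  if (length(counts) == 0L)
    stop("empty sample: no counts supplied for '", sample_id, "'")
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers (sample '", sample_id, "')")
  counts <- as.integer(counts)
  n_dropped <- sum(counts == 0L)
  ab <- sort(counts[counts > 0L], decreasing = TRUE)
  if (length(ab) == 0L)
    stop("empty sample: all counts are zero in '", sample_id, "'")
  structure(
    list(sample_id = as.character(sample_id), group = group,
         abundances = ab, J = sum(ab), S = length(ab),
         n_dropped = n_dropped),
    class = "community_sample")
}

#' @export
print.community_sample <- function(x, ...) {
  cat("Community sample '", x$sample_id, "' (", x$group, ")\n", sep = "")
  cat("  J =", x$J, " S =", x$S, "\n")
  ab <- x$abundances
  if (length(ab) > 12L) ab <- c(ab[1:12], "...")
  cat("  abundances:", paste(ab, collapse = " "), "\n")
  invisible(x)
}

is_community_sample <- function(x) inherits(x, "community_sample")

as_sample <- function(x, sample_id = "sample", group = "unlabeled") {
  if (is_community_sample(x)) x else make_sample(x, sample_id, group)
}

#' Abundance spectrum of a sample
#'
#' The spectrum phi maps each abundance value `a` to `phi_a`, the number of
#' species observed exactly `a` times; it is the sufficient summary the
#' sampling formulas are written in.  `sum(phi) == S` and
#' `sum(a * phi_a) == J`.
#'
#' @param sample a [community_sample][make_sample].
#' @return A named integer vector of class `phi_spectrum`; names are the
#'   abundance values with `phi_a > 0`.
#' @examples
#' phi_spectrum(make_sample(c(5, 5, 1)))
#' @export
phi_spectrum <- function(sample) {
  sample <- as_sample(sample)
  tab <- tabulate(sample$abundances)
  keep <- which(tab > 0L)
  structure(stats::setNames(tab[keep], keep), class = "phi_spectrum")
}

#' @export
print.phi_spectrum <- function(x, ...) {
  cat("phi spectrum (abundance : n species)\n")
  print(stats::setNames(as.integer(x), names(x)))
  invisible(x)
}
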