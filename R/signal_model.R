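# Shared LRR/BAF cluster model: one place defines what each copy-number
# state looks like, used both to render simulated signal and to score it.

#' Default LRR state means per copy number
#'
#' The widely used Illumina-style cluster values: CN0 = -3.5, CN1 = -0.66,
#' CN2 = 0, CN3 = +0.40, CN4 = +0.68. Chip vendors do not publish emission
#' parameters; these are configurable defaults.
#'
#' @return Named numeric vector, names "0".."4".
#' @export
lrr_state_means <- function() {
  c(`0` = -3.5, `1` = -0.66, `2` = 0.0, `3` = 0.40, `4` = 0.68)
}

#' BAF genotype clusters for a copy-number state
#'
#' For total copy number n > 0 the BAF clusters lie at k/n for k = 0..n B
#' alleles, with Hardy-Weinberg weights Binomial(n, p_b). CN0 has no
#' genotype: BAF is modelled uniform on [0, 1].
#'
#' @param cn Integer copy number in 0..4.
#' @param p_b Population B-allele frequency (default 0.5).
#' @return List with `means` and `weights` (NULL for cn = 0).
#' @export
baf_clusters <- function(cn, p_b = 0.5) {
  cn <- as.integer(cn)
  stopifnot(cn >= 0L, cn <= 4L)
  if (cn == 0L) return(list(means = NULL, weights = NULL))
  k <- 0:cn
  list(means = k / cn, weights = stats::dbinom(k, cn, p_b))
}

# Log-density of one BAF value under a state's cluster mixture.
# A 1% uniform floor keeps clipped or outlying values from zeroing the
# likelihood; CN0 is exactly uniform.
baf_logdens <- function(baf, cn, baf_sd, p_b = 0.5) {
  out <- numeric(length(baf))
  ok <- !is.na(baf)
  if (cn == 0L) {
    out[ok] <- 0  # log(1): uniform on [0,1]
  } else {
    cl <- baf_clusters(cn, p_b)
    dens <- rep(0, sum(ok))
    for (j in seq_along(cl$means)) {
      dens <- dens + cl$weights[j] * stats::dnorm(baf[ok], cl$means[j], baf_sd)
    }
    out[ok] <- log(0.99 * dens + 0.01)
  }
  out[!ok] <- 0  # missing values drop out of the likelihood
  out
}

# Log-density of LRR values under a state (missing -> 0 contribution).
lrr_logdens <- function(lrr, mean, sd) {
  out <- numeric(length(lrr))
  ok <- !is.na(lrr)
  out[ok] <- stats::dnorm(lrr[ok], mean, sd, log = TRUE)
  out
}

# n x 5 matrix of per-probe log emission densities for CN states 0..4.
emission_loglik <- function(lrr, baf, state_means, state_sds, baf_sd,
                            p_b = 0.5) {
  n <- length(lrr)
  E <- matrix(0, n, 5L)
  for (s in 0:4) {
    E[, s + 1L] <- lrr_logdens(lrr, state_means[[as.character(s)]],
                               state_sds[[as.character(s)]]) +
      baf_logdens(baf, s, baf_sd, p_b)
  }
  E
}

# Robust per-track noise scale from successive LRR differences; immune to
# the (sparse) CNV level shifts. Floored so noiseless input stays finite.
estimate_lrr_sd <- function(lrr, floor = 1e-4) {
  d <- diff(lrr[!is.na(lrr)])
  max(stats::mad(d) / sqrt(2), floor)
}
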