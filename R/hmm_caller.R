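#' Parameters for the hidden Markov model caller
#'
#' Five copy-number states (0..4). Emissions are the product of an LRR
#' Gaussian and the BAF genotype-cluster mixture for the state.
#' Transitions are distance-dependent: the off-diagonal mass is scaled by
#' 1 - exp(-d/D) for inter-probe distance d, so distant probes are nearly
#' independent while dense probes resist state flips.
#'
#' @param state_means Named LRR means per state (monotone in CN).
#' @param state_sds Named LRR sds per state (the CN0 emission is wide:
#'   homozygous deletions have unstable intensity).
#' @param baf_cluster_sd BAF sd around cluster means.
#' @param p_b Population B-allele frequency for cluster weights.
#' @param D Transition decay length in bp (default 1e5).
#' @param max_switch Total off-diagonal transition mass at large distance.
#' @param state_prior Prior weights over states (favours CN2).
#' @param min_snps Minimum probes per emitted call (default 3).
#' @return List of class `hmm_params`.
#' @export
hmm_params <- function(state_means = lrr_state_means(),
                       state_sds = c(`0` = 1.0, `1` = 0.25, `2` = 0.2,
                                     `3` = 0.25, `4` = 0.3),
                       baf_cluster_sd = 0.04, p_b = 0.5, D = 1e5,
                       max_switch = 0.05,
                       state_prior = c(`0` = 0.005, `1` = 0.045, `2` = 0.9,
                                       `3` = 0.045, `4` = 0.005),
                       min_snps = 3L) {
  stopifnot(all(diff(unlist(state_means)) > 0), all(unlist(state_sds) > 0),
            D > 0, max_switch > 0, max_switch < 1, min_snps >= 1)
  structure(list(state_means = state_means, state_sds = state_sds,
                 baf_cluster_sd = baf_cluster_sd, p_b = p_b, D = D,
                 max_switch = max_switch,
                 state_prior = state_prior / sum(state_prior),
                 min_snps = as.integer(min_snps)),
            class = "hmm_params")
}

# Log transition matrix for one inter-probe distance:
# A(d) = I + (1 - exp(-d/D)) * (T0 - I), T0 having off-diagonal mass
# max_switch split in proportion to the state prior.
hmm_log_trans <- function(d, params) {
  f <- 1 - exp(-d / params$D)
  pri <- params$state_prior
  A <- matrix(0, 5, 5)
  for (i in 1:5) {
    off <- pri[-i] / sum(pri[-i]) * params$max_switch
    A[i, -i] <- f * off
    A[i, i] <- 1 - sum(A[i, -i])
  }
  log(A)
}

# Viterbi decoding over CN states 0..4 for one chromosome.
# Ties are broken toward the smaller copy-number change (state 2 first),
# implemented by scanning states in preference order with strict >.
viterbi_cn <- function(E, pos, params) {
  n <- nrow(E)
  pref <- c(3L, 2L, 4L, 1L, 5L)  # states 2,1,3,0,4
  logpri <- log(params$state_prior)
  delta <- matrix(-Inf, n, 5)
  psi <- matrix(0L, n, 5)
  delta[1, ] <- logpri + E[1, ]
  if (n > 1) for (t in 2:n) {
    logA <- hmm_log_trans(pos[t] - pos[t - 1], params)
    for (j in 1:5) {
      best <- -Inf; arg <- pref[1]
      for (i in pref) {
        v <- delta[t - 1, i] + logA[i, j]
        if (v > best) { best <- v; arg <- i }
      }
      delta[t, j] <- best + E[t, j]
      psi[t, j] <- arg
    }
  }
  path <- integer(n)
  best <- -Inf; arg <- pref[1]
  for (i in pref) if (delta[n, i] > best) { best <- delta[n, i]; arg <- i }
  path[n] <- arg
  if (n > 1) for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  list(path = path - 1L, logprob = best)  # states back to CN 0..4
}

# Maximal runs of a constant non-2 state with >= min_snps probes become
# calls; score is the summed log-likelihood ratio against CN2.
path_to_calls <- function(path, E, map_chr, sample_id, caller, min_snps) {
  out <- list()
  r <- rle(path)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    s <- r$values[k]
    if (s == 2L || r$lengths[k] < min_snps) next
    idx <- starts[k]:ends[k]
    out[[length(out) + 1L]] <- data.frame(
      sample_id = sample_id, chrom = map_chr$chrom[1],
      start = map_chr$pos[starts[k]], end = map_chr$pos[ends[k]],
      n_snps = length(idx), state = s,
      direction = if (s < 2L) "loss" else "gain", caller = caller,
      score = sum(E[idx, s + 1L] - E[idx, 3L]), stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else as_cnv_calls()
}

#' Call CNVs with a five-state hidden Markov model
#'
#' Viterbi decoding over copy-number states \{0,1,2,3,4\} per chromosome;
#' maximal runs of a non-diploid state spanning at least `min_snps`
#' probes are emitted as calls. When parental tracks are supplied, a trio
#' consistency pass drops offspring calls contradicted by both parents'
#' signal likelihood ratio and rescues sub-threshold offspring calls
#' that overlap a confident parental call.
#'
#' @param track A [signal_track()] aligned to the map.
#' @param map A [snp_map()].
#' @param params [hmm_params()].
#' @param trio Optional list with elements `sire` and `dam`, each a
#'   [signal_track()].
#' @return A call data.frame (possibly empty): sample_id, chrom, start,
#'   end, n_snps, state, direction, caller, score.
#' @export
hmm_call <- function(track, map, params = hmm_params(), trio = NULL) {
  stopifnot(inherits(track, "signal_track"))
  if (length(track$lrr) != nrow(map)) {
    stop("signal track length does not match the SNP map")
  }
  calls <- list()
  for (ch in map_chrom_order(map)) {
    idx <- which(map$chrom == ch)
    lrr <- track$lrr[idx]; baf <- track$baf[idx]
    if (all(is.na(lrr))) {
      warning("chromosome ", ch, " has no signal for ", track$sample_id,
              "; skipped")
      next
    }
    E <- emission_loglik(lrr, baf, params$state_means, params$state_sds,
                         params$baf_cluster_sd, params$p_b)
    vit <- viterbi_cn(E, map$pos[idx], params)
    cc <- path_to_calls(vit$path, E, map[idx, , drop = FALSE],
                        track$sample_id, "hmm", params$min_snps)
    if (nrow(cc)) calls[[length(calls) + 1L]] <- cc
  }
  calls <- if (length(calls)) do.call(rbind, calls) else as_cnv_calls()
  if (!is.null(trio)) {
    calls <- trio_adjust(calls, track, map, params, trio)
  }
  as_cnv_calls(calls)
}

# Summed log-likelihood ratio of the best non-diploid state vs CN2 over an
# interval of one parent's signal; negative = the data favour diploid.
interval_support <- function(track, map, chrom, start, end, params,
                             state = NULL) {
  idx <- probes_in_interval(map, chrom, start, end)
  E <- emission_loglik(track$lrr[idx], track$baf[idx], params$state_means,
                       params$state_sds, params$baf_cluster_sd, params$p_b)
  lr <- colSums(E) - sum(E[, 3L])
  if (is.null(state)) max(lr[-3L]) else lr[state + 1L]
}

# Trio consistency pass: drop offspring calls that both parents' signal
# contradicts; rescue confident parental calls whose interval shows
# positive (but sub-threshold) support in the offspring.
trio_adjust <- function(calls, track, map, params, trio,
                        rescue_parent_min = 10, rescue_min = 2) {
  keep <- rep(TRUE, nrow(calls))
  for (k in seq_len(nrow(calls))) {
    s_sire <- interval_support(trio$sire, map, calls$chrom[k],
                               calls$start[k], calls$end[k], params)
    s_dam <- interval_support(trio$dam, map, calls$chrom[k],
                              calls$start[k], calls$end[k], params)
    if (s_sire < 0 && s_dam < 0) keep[k] <- FALSE
  }
  calls <- calls[keep, , drop = FALSE]
  for (pt in trio) {
    pcalls <- hmm_call(pt, map, params, trio = NULL)
    for (k in seq_len(nrow(pcalls))) {
      if (pcalls$score[k] < rescue_parent_min) next
      hit <- calls$chrom == pcalls$chrom[k] &
        calls$start < pcalls$end[k] & pcalls$start[k] < calls$end
      if (any(hit)) next
      supp <- interval_support(track, map, pcalls$chrom[k], pcalls$start[k],
                               pcalls$end[k], params, state = pcalls$state[k])
      if (supp > rescue_min) {
        rescued <- pcalls[k, , drop = FALSE]
        rescued$sample_id <- track$sample_id
        rescued$score <- supp
        rescued$caller <- "hmm"
        calls <- rbind(calls, rescued)
      }
    }
  }
  calls
}
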