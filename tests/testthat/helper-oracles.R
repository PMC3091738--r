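# Independent oracles used to check the algorithmic paths: exhaustive
# path enumeration for the HMM, naive re-scoring backward elimination,
# and transitive-closure interval clustering. Deliberately slow and
# simple; they share the model definition (emissions, transitions) with
# the package but none of its algorithm code.

# Exhaustive Viterbi: best path over all 5^n state sequences, scanning
# candidates in the same small-CN-change preference order as the decoder
# so tie-breaking agrees.
enumerate_viterbi <- function(E, pos, params) {
  n <- nrow(E)
  pref <- c(2L, 1L, 3L, 0L, 4L)  # CN order of preference
  grid <- as.matrix(expand.grid(rep(list(pref), n))[, n:1, drop = FALSE])
  logpri <- log(params$state_prior)
  lp <- logpri[grid[, 1] + 1L] + E[1, grid[, 1] + 1L]
  if (n > 1) for (t in 2:n) {
    logA <- snpcnvr:::hmm_log_trans(pos[t] - pos[t - 1], params)
    lp <- lp + logA[cbind(grid[, t - 1] + 1L, grid[, t] + 1L)] +
      E[t, grid[, t] + 1L]
  }
  best <- which.max(lp)  # first index = most-preferred tie survivor
  list(path = unname(grid[best, ]), logprob = unname(lp[best]))
}

# Naive backward elimination: recompute every segment mean and score
# from scratch after each removal, with plain loops.
be_oracle <- function(y, breakpoints, sigma, critical_T, min_seg_len) {
  bp <- sort(unique(as.integer(breakpoints)))
  removed <- integer(0)
  repeat {
    if (length(bp) == 0) break
    bounds <- c(0L, bp, length(y))
    nseg <- length(bounds) - 1L
    means <- numeric(nseg); sizes <- integer(nseg)
    for (k in 1:nseg) {
      seg <- y[(bounds[k] + 1L):bounds[k + 1L]]
      means[k] <- mean(seg); sizes[k] <- length(seg)
    }
    scores <- numeric(length(bp))
    for (k in seq_along(bp)) {
      scores[k] <- abs(means[k + 1L] - means[k]) /
        (sigma * sqrt(1 / sizes[k] + 1 / sizes[k + 1L]))
    }
    short <- which(sizes < min_seg_len)
    if (length(short) > 0) {
      cand <- integer(0)
      for (s in short) {
        if (s > 1L) cand <- c(cand, s - 1L)
        if (s <= length(bp)) cand <- c(cand, s)
      }
      cand <- unique(cand)
      k <- cand[which.min(scores[cand])]
    } else if (min(scores) < critical_T) {
      k <- which.min(scores)
    } else break
    removed <- c(removed, bp[k])
    bp <- bp[-k]
  }
  list(breakpoints = bp, removed = removed)
}

# Brute-force CNVR construction: pairwise-overlap graph, transitive
# closure by repeated expansion, then the same >= min_carriers filter.
# Returns spans sorted by chromosome (map order) then start.
cnvr_oracle <- function(consensus, map, min_carriers = 2L) {
  n <- nrow(consensus)
  if (n == 0) return(data.frame(chrom = character(0), start = integer(0),
                                end = integer(0), n_carriers = integer(0)))
  adj <- matrix(FALSE, n, n)
  for (i in 1:n) for (j in 1:n) {
    adj[i, j] <- consensus$chrom[i] == consensus$chrom[j] &&
      max(consensus$start[i], consensus$start[j]) <
        min(consensus$end[i], consensus$end[j])
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in 1:n) for (j in 1:n) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  rows <- list()
  for (cl in unique(comp)) {
    m <- consensus[comp == cl, , drop = FALSE]
    if (length(unique(m$sample_id)) < min_carriers) next
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = m$chrom[1], start = min(m$start), end = max(m$end),
      n_carriers = length(unique(m$sample_id)), stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(data.frame(chrom = character(0),
                                       start = integer(0), end = integer(0),
                                       n_carriers = integer(0)))
  out <- do.call(rbind, rows)
  out <- out[order(match(out$chrom, unique(map$chrom)), out$start), ]
  rownames(out) <- NULL
  out
}
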