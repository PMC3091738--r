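#' Parameters for the sparse-Bayesian-learning segmenter
#'
#' The LRR vector is modelled as piecewise constant: y = F w + e, where F
#' is the step basis (column j steps from 0 to 1 after probe j) and each
#' step weight carries a hierarchical Gaussian-Gamma prior,
#' w_j ~ N(0, 1/alpha_j), alpha_j ~ Gamma(a_alpha, b_alpha). EM updates
#' shrink spurious steps; backward elimination (BE) then removes
#' breakpoints whose t-like score (segment mean difference over its
#' standard error) falls below the critical value, and enforces the
#' minimum segment length.
#'
#' @param a_alpha Sparseness shape hyperparameter (default 0.8).
#' @param be_critical_T Critical value of the BE score (default 8).
#' @param min_seg_len Minimum probes per segment (default 3).
#' @param b_alpha Rate hyperparameter (default 0.2; smaller values give
#'   stronger sparsity and EM-level pruning).
#' @param max_em_iterations,convergence_tol EM controls.
#' @param lrr_loss_threshold,lrr_gain_threshold Segment-mean thresholds
#'   classifying loss/gain segments.
#' @return List of class `sbl_params`.
#' @export
sbl_params <- function(a_alpha = 0.8, be_critical_T = 8, min_seg_len = 3L,
                       b_alpha = 0.2, max_em_iterations = 500L,
                       convergence_tol = 1e-6,
                       lrr_loss_threshold = -0.25,
                       lrr_gain_threshold = 0.20) {
  stopifnot(a_alpha > 0, be_critical_T > 0, min_seg_len >= 1, b_alpha >= 0)
  structure(list(a_alpha = a_alpha, be_critical_T = be_critical_T,
                 min_seg_len = as.integer(min_seg_len), b_alpha = b_alpha,
                 max_em_iterations = as.integer(max_em_iterations),
                 convergence_tol = convergence_tol,
                 lrr_loss_threshold = lrr_loss_threshold,
                 lrr_gain_threshold = lrr_gain_threshold),
            class = "sbl_params")
}

# EM for the sparse step-basis model on a centred LRR vector. Returns the
# indices (1..n-1) of breakpoints surviving shrinkage/pruning, plus a
# convergence flag. Sufficient statistics of the step basis are closed
# form: (F'F)[j,k] = n - max(j,k), (F'y)[j] = sum_{i>j} y_i.
sbl_em <- function(y, params, sigma2, alpha_max = 1e8) {
  n <- length(y)
  if (n < 2) return(list(breakpoints = integer(0), converged = TRUE))
  y <- y - mean(y)
  active <- seq_len(n - 1L)
  Fty_all <- rev(cumsum(rev(y)))[-1L]  # sum of y after each candidate
  alpha <- rep(1, n - 1L)
  mu_old <- rep(0, n - 1L)
  converged <- FALSE
  for (it in seq_len(params$max_em_iterations)) {
    m <- length(active)
    if (m == 0) { converged <- TRUE; break }
    FtF <- n - outer(active, active, pmax)
    A <- FtF / sigma2 + diag(alpha[active], m)
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) break
    Sigma <- chol2inv(ch)
    mu <- drop(Sigma %*% Fty_all[active]) / sigma2
    alpha[active] <- (1 + 2 * params$a_alpha) /
      (mu^2 + diag(Sigma) + 2 * params$b_alpha)
    drop_j <- alpha[active] > alpha_max
    mu_full <- rep(0, n - 1L); mu_full[active] <- mu
    if (any(drop_j)) active <- active[!drop_j]
    if (max(abs(mu_full - mu_old)) < params$convergence_tol) {
      converged <- TRUE
      mu_old <- mu_full
      break
    }
    mu_old <- mu_full
  }
  list(breakpoints = active, converged = converged)
}

# Backward elimination over a breakpoint set. Score of breakpoint b
# separating segments L|R: |mean_L - mean_R| / (sigma * sqrt(1/nL+1/nR)).
# Short segments are repaired first (their weakest flanking breakpoint is
# removed); then the globally weakest breakpoint below T is removed;
# scores are recomputed after every removal. Returns surviving
# breakpoints and the removal order.
backward_eliminate <- function(y, breakpoints, sigma, critical_T,
                               min_seg_len) {
  n <- length(y)
  bp <- sort(unique(as.integer(breakpoints)))
  removed <- integer(0)
  repeat {
    if (length(bp) == 0) break
    bounds <- c(0L, bp, n)
    seg_n <- diff(bounds)
    seg_mean <- vapply(seq_along(seg_n), function(k) {
      mean(y[(bounds[k] + 1L):bounds[k + 1L]])
    }, 0)
    score <- abs(diff(seg_mean)) /
      (sigma * sqrt(1 / seg_n[-length(seg_n)] + 1 / seg_n[-1L]))
    short <- which(seg_n < min_seg_len)
    if (length(short)) {
      # candidate breakpoints flanking any short segment
      cand <- unique(pmin(pmax(c(short - 1L, short), 1L), length(bp)))
      k <- cand[which.min(score[cand])]
    } else if (min(score) < critical_T) {
      k <- which.min(score)
    } else break
    removed <- c(removed, bp[k])
    bp <- bp[-k]
  }
  list(breakpoints = bp, removed = removed)
}

# Segment means for a breakpoint set (bounds are probe indices).
segment_table <- function(y, bp) {
  n <- length(y)
  bounds <- c(0L, sort(bp), n)
  data.frame(first = bounds[-length(bounds)] + 1L, last = bounds[-1L],
             mean = vapply(seq_len(length(bounds) - 1L), function(k) {
               mean(y[(bounds[k] + 1L):bounds[k + 1L]])
             }, 0))
}

#' Call CNVs by sparse Bayesian learning plus backward elimination
#'
#' Fits a piecewise-constant mean to each chromosome's LRR vector with
#' the step-basis SBL model, prunes breakpoints by backward elimination
#' at the critical score, and classifies surviving segments as loss/gain
#' by their mean LRR; the copy-number state is the nearest LRR state
#' mean on the relevant side of diploid. If EM fails to converge the BE
#' stage runs over all inter-probe candidate breakpoints (with a
#' message).
#'
#' @param track A [signal_track()].
#' @param map A [snp_map()].
#' @param params [sbl_params()].
#' @return A call data.frame.
#' @export
sbl_call <- function(track, map, params = sbl_params()) {
  stopifnot(inherits(track, "signal_track"))
  if (length(track$lrr) != nrow(map)) {
    stop("signal track length does not match the SNP map")
  }
  means <- unlist(lrr_state_means())
  calls <- list()
  for (ch in map_chrom_order(map)) {
    idx <- which(map$chrom == ch)
    y <- track$lrr[idx]
    ok <- !is.na(y)
    if (!any(ok)) {
      warning("chromosome ", ch, " has no signal for ", track$sample_id,
              "; skipped")
      next
    }
    y_use <- y[ok]; pos <- map$pos[idx][ok]
    n <- length(y_use)
    if (n < 2 * params$min_seg_len) next
    sigma <- estimate_lrr_sd(y_use)
    fit <- sbl_em(y_use, params, sigma^2)
    cand <- fit$breakpoints
    if (!fit$converged) {
      message("SBL EM did not converge on chromosome ", ch,
              "; backward elimination over all candidate breakpoints")
      cand <- seq_len(n - 1L)
    }
    be <- backward_eliminate(y_use, cand, sigma, params$be_critical_T,
                             params$min_seg_len)
    segs <- segment_table(y_use, be$breakpoints)
    for (k in seq_len(nrow(segs))) {
      m <- segs$mean[k]
      if (m > params$lrr_loss_threshold && m < params$lrr_gain_threshold) next
      side <- if (m <= params$lrr_loss_threshold) c(0L, 1L) else c(3L, 4L)
      state <- side[which.min(abs(means[as.character(side)] - m))]
      nk <- segs$last[k] - segs$first[k] + 1L
      calls[[length(calls) + 1L]] <- data.frame(
        sample_id = track$sample_id, chrom = ch,
        start = pos[segs$first[k]], end = pos[segs$last[k]],
        n_snps = nk, state = state,
        direction = if (state < 2L) "loss" else "gain", caller = "sbl",
        score = abs(m) / (sigma / sqrt(nk)), stringsAsFactors = FALSE)
    }
  }
  as_cnv_calls(if (length(calls)) do.call(rbind, calls) else NULL)
}
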