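#' Parameters for the recursive likelihood partitioner
#'
#' A desk-scale stand-in for proprietary partition-style CNV detection:
#' recursive binary segmentation of the LRR vector accepting each split
#' while its Gaussian log-likelihood gain exceeds `bic_penalty * log(n)`,
#' followed by thresholding of segment means and a BAF corroboration
#' check.
#'
#' @param min_probe_count Minimum probes per emitted call (default 3).
#' @param bic_penalty Penalty multiplier on log(n) per accepted split.
#' @param lrr_loss_threshold,lrr_gain_threshold Segment-mean call
#'   thresholds (defaults -0.25 / +0.20).
#' @param het_band Half-width definition of the heterozygous BAF band
#'   (values in 0.5 +/- band count as heterozygous; default 0.06).
#' @param het_max Maximum heterozygous fraction tolerated for CN1/CN3
#'   calls, whose cluster model has no 0.5 cluster (default 0.2).
#' @return List of class `partition_params`.
#' @export
partition_params <- function(min_probe_count = 3L, bic_penalty = 2.0,
                             lrr_loss_threshold = -0.25,
                             lrr_gain_threshold = 0.20,
                             het_band = 0.06, het_max = 0.2) {
  stopifnot(min_probe_count >= 1, bic_penalty > 0)
  structure(list(min_probe_count = as.integer(min_probe_count),
                 bic_penalty = bic_penalty,
                 lrr_loss_threshold = lrr_loss_threshold,
                 lrr_gain_threshold = lrr_gain_threshold,
                 het_band = het_band, het_max = het_max),
            class = "partition_params")
}

# Recursive binary segmentation: returns sorted breakpoint indices
# (split after probe k). The likelihood gain of a split with known noise
# scale sigma is (RSS - RSS_L - RSS_R) / (2 sigma^2).
recursive_partition <- function(y, sigma, penalty) {
  n <- length(y)
  threshold <- penalty * log(n)
  split_rec <- function(l, r) {
    m <- r - l + 1L
    if (m < 2L) return(integer(0))
    yy <- y[l:r]
    cs <- cumsum(yy); css <- cumsum(yy^2)
    tot_rss <- css[m] - cs[m]^2 / m
    k <- seq_len(m - 1L)
    rss_l <- css[k] - cs[k]^2 / k
    sr <- cs[m] - cs[k]
    rss_r <- (css[m] - css[k]) - sr^2 / (m - k)
    gain <- (tot_rss - rss_l - rss_r) / (2 * sigma^2)
    kbest <- which.max(gain)
    if (gain[kbest] <= threshold) return(integer(0))
    cut <- l + kbest - 1L
    c(split_rec(l, cut), cut, split_rec(cut + 1L, r))
  }
  split_rec(1L, n)
}

#' Call CNVs by recursive likelihood partitioning
#'
#' Segments each chromosome's LRR vector by recursive binary splitting
#' under a BIC-style acceptance rule, then emits segments whose mean LRR
#' is beyond the loss/gain thresholds, that span at least
#' `min_probe_count` probes, and whose BAF pattern corroborates the
#' state (CN1 and CN3 have no heterozygous cluster, so a high
#' heterozygous fraction vetoes those calls).
#'
#' @param track A [signal_track()].
#' @param map A [snp_map()].
#' @param params [partition_params()].
#' @return A call data.frame.
#' @export
partition_call <- function(track, map, params = partition_params()) {
  stopifnot(inherits(track, "signal_track"))
  if (length(track$lrr) != nrow(map)) {
    stop("signal track length does not match the SNP map")
  }
  means <- unlist(lrr_state_means())
  calls <- list()
  for (ch in map_chrom_order(map)) {
    idx <- which(map$chrom == ch)
    y <- track$lrr[idx]; baf <- track$baf[idx]
    ok <- !is.na(y)
    if (!any(ok)) {
      warning("chromosome ", ch, " has no signal for ", track$sample_id,
              "; skipped")
      next
    }
    y_use <- y[ok]; baf_use <- baf[ok]; pos <- map$pos[idx][ok]
    sigma <- estimate_lrr_sd(y_use)
    bp <- recursive_partition(y_use, sigma, params$bic_penalty)
    segs <- segment_table(y_use, bp)
    for (k in seq_len(nrow(segs))) {
      m <- segs$mean[k]
      nk <- segs$last[k] - segs$first[k] + 1L
      if (nk < params$min_probe_count) next
      if (m > params$lrr_loss_threshold && m < params$lrr_gain_threshold) next
      side <- if (m <= params$lrr_loss_threshold) c(0L, 1L) else c(3L, 4L)
      state <- side[which.min(abs(means[as.character(side)] - m))]
      if (state %in% c(1L, 3L)) {
        b <- baf_use[segs$first[k]:segs$last[k]]
        b <- b[!is.na(b)]
        if (length(b)) {
          het <- mean(abs(b - 0.5) <= params$het_band)
          if (het > params$het_max) next  # BAF contradicts the state
        }
      }
      calls[[length(calls) + 1L]] <- data.frame(
        sample_id = track$sample_id, chrom = ch,
        start = pos[segs$first[k]], end = pos[segs$last[k]],
        n_snps = nk, state = state,
        direction = if (state < 2L) "loss" else "gain",
        caller = "partition",
        score = abs(m) / (sigma / sqrt(nk)), stringsAsFactors = FALSE)
    }
  }
  as_cnv_calls(if (length(calls)) do.call(rbind, calls) else NULL)
}

#' Run one caller over every sample of a cohort
#'
#' Convenience wrapper binding the per-sample call tables of
#' [hmm_call()], [sbl_call()] or [partition_call()] into one table. For
#' the HMM, trios from the cohort pedigree are used automatically when
#' both parents have signal.
#'
#' @param cohort A rendered `cnv_cohort`, or a list with `map` and
#'   `signals`.
#' @param method One of "hmm", "sbl", "partition".
#' @param params Optional parameter object for the method.
#' @param use_trios Use pedigree trio information for the HMM (default
#'   TRUE when a pedigree is present).
#' @return A combined call data.frame.
#' @export
call_cohort <- function(cohort, method = c("hmm", "sbl", "partition"),
                        params = NULL, use_trios = !is.null(cohort$pedigree)) {
  method <- match.arg(method)
  if (is.null(params)) {
    params <- switch(method, hmm = hmm_params(), sbl = sbl_params(),
                     partition = partition_params())
  }
  out <- list()
  for (id in names(cohort$signals)) {
    track <- cohort$signals[[id]]
    if (method == "hmm") {
      trio <- NULL
      if (use_trios) {
        p <- cohort$pedigree[cohort$pedigree$id == id, ]
        if (nrow(p) == 1 && p$sire != "0" &&
            !is.null(cohort$signals[[p$sire]]) &&
            !is.null(cohort$signals[[p$dam]])) {
          trio <- list(sire = cohort$signals[[p$sire]],
                       dam = cohort$signals[[p$dam]])
        }
      }
      cc <- hmm_call(track, cohort$map, params, trio = trio)
    } else if (method == "sbl") {
      cc <- sbl_call(track, cohort$map, params)
    } else {
      cc <- partition_call(track, cohort$map, params)
    }
    if (nrow(cc)) out[[length(out) + 1L]] <- cc
  }
  as_cnv_calls(if (length(out)) do.call(rbind, out) else NULL)
}
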