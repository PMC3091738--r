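# qPCR validation by the 2^-ddCt comparative method: a target assay on
# the region of interest, a single-copy reference assay (e.g. glucagon)
# on each sample, and a calibrator sample assumed to carry two copies.
# RQ = 2^-(dCt_sample - dCt_calibrator) estimates relative copy number;
# PCR efficiency is assumed exactly 2 (verified experimentally upstream).

#' Relative quantification by the 2^-ddCt method
#'
#' For every sample of every assay: delta Ct = mean(target Ct) -
#' mean(reference Ct); delta-delta Ct subtracts the calibrator's delta
#' Ct; RQ = 2^-ddCt. The standard error of RQ is the delta-method
#' propagation se(RQ) = RQ * ln2 * se(ddCt), with se(ddCt) from the
#' replicate variances of both samples' target and reference means added
#' in quadrature. The calibrator's own RQ is exactly 1. Samples whose
#' replicate spread (range) exceeds `outlier_range` cycles are flagged,
#' not dropped.
#'
#' @param ct data.frame with columns sample_id, assay_id, target_ct,
#'   reference_ct (one row per replicate) and a logical/0-1 `calibrator`
#'   column marking exactly one sample per assay. Extra columns (group,
#'   population) are carried through.
#' @param outlier_range Replicate-range flag threshold in cycles
#'   (default 0.5).
#' @return data.frame: sample_id, assay_id, n_reps, delta_ct,
#'   delta_delta_ct, rq, rq_se, flagged (+ carried columns).
#' @export
relative_quantify <- function(ct, outlier_range = 0.5) {
  out <- list()
  for (assay in unique(ct$assay_id)) {
    tab <- ct[ct$assay_id == assay, , drop = FALSE]
    cal_ids <- unique(tab$sample_id[as.logical(tab$calibrator)])
    if (length(cal_ids) != 1) {
      stop("assay ", assay, " must have exactly one calibrator sample (found ",
           length(cal_ids), ")")
    }
    if (any(!is.finite(tab$target_ct) | tab$target_ct <= 0) ||
        any(!is.finite(tab$reference_ct) | tab$reference_ct <= 0)) {
      stop("Ct values must be positive and finite (assay ", assay, ")")
    }
    per_sample <- function(sid) {
      s <- tab[tab$sample_id == sid, , drop = FALSE]
      n <- nrow(s)
      list(n = n, dct = mean(s$target_ct) - mean(s$reference_ct),
           var_dct = stats::var(s$target_ct) / n +
             stats::var(s$reference_ct) / n,
           spread = max(diff(range(s$target_ct)),
                        diff(range(s$reference_ct))))
    }
    cal <- per_sample(cal_ids)
    if (is.na(cal$var_dct)) cal$var_dct <- 0  # single replicate
    for (sid in unique(tab$sample_id)) {
      x <- per_sample(sid)
      if (is.na(x$var_dct)) x$var_dct <- 0
      ddct <- if (sid == cal_ids) 0 else x$dct - cal$dct
      rq <- 2^(-ddct)
      se_ddct <- sqrt(x$var_dct + if (sid == cal_ids) 0 else cal$var_dct)
      row <- data.frame(sample_id = sid, assay_id = assay, n_reps = x$n,
                        delta_ct = x$dct, delta_delta_ct = ddct, rq = rq,
                        rq_se = rq * log(2) * se_ddct,
                        flagged = x$spread > outlier_range,
                        stringsAsFactors = FALSE)
      for (col in intersect(c("group", "population"), names(tab))) {
        row[[col]] <- tab[[col]][tab$sample_id == sid][1]
      }
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify copy number from an RQ value
#'
#' CN is the nearest integer to calibrator_cn * RQ, capped at 4. Values
#' whose implied copy number lies within `guard` of a half-integer
#' decision boundary are flagged ambiguous (still classified to the
#' nearest integer).
#'
#' @param rq Numeric RQ values (or the data.frame from
#'   [relative_quantify()], whose rq column is used and to which the
#'   classification is appended).
#' @param calibrator_cn Copy number of the calibrator (default 2).
#' @param guard Half-width of the ambiguity band around k + 0.5
#'   boundaries (default 0.25).
#' @return Integer CN vector with an `ambiguous` logical attribute, or
#'   the input data.frame with `cn` and `ambiguous` columns.
#' @export
classify_copy_number <- function(rq, calibrator_cn = 2, guard = 0.25) {
  df <- NULL
  if (is.data.frame(rq)) { df <- rq; rq <- df$rq }
  est <- calibrator_cn * rq
  cn <- as.integer(pmin(round(est), 4))
  ambiguous <- abs(est - (floor(est) + 0.5)) < guard & est < 4.5
  if (!is.null(df)) {
    df$cn <- cn; df$ambiguous <- ambiguous
    return(df)
  }
  attr(cn, "ambiguous") <- ambiguous
  cn
}

#' Per-animal validation rates (FDR and FNR)
#'
#' A false positive is a predicted carrier whose qPCR copy number equals
#' the calibrator's; FDR = false positives / predicted carriers tested.
#' A false negative is a control (predicted non-carrier) whose qPCR copy
#' number differs from the calibrator's; FNR = changed controls /
#' controls tested. Rates are reported both as exact fractions and
#' rounded to the nearest whole percent; an optional population column
#' yields a per-population breakdown of the carrier FDR.
#'
#' @param classified Output of [classify_copy_number()] on a
#'   [relative_quantify()] data.frame; must carry a `group` column with
#'   values "carrier" (predicted) or "control", and optionally
#'   `population`.
#' @param calibrator_cn Calibrator copy number (default 2).
#' @return List of class `validation_report`: per assay a list with
#'   n_carriers, n_confirmed, n_false_positive, fdr, fdr_pct,
#'   n_controls, n_changed_controls, fnr, fnr_pct, and `by_population`
#'   when available.
#' @export
validation_rates <- function(classified, calibrator_cn = 2) {
  if (is.null(classified$group) || anyNA(classified$group)) {
    bad <- classified$sample_id[is.na(classified$group)]
    stop("samples missing a carrier/control label: ",
         paste(bad, collapse = ", "))
  }
  if (is.null(classified$cn)) stop("run classify_copy_number() first")
  reports <- list()
  for (assay in unique(classified$assay_id)) {
    tab <- classified[classified$assay_id == assay, , drop = FALSE]
    carr <- tab[tab$group == "carrier", , drop = FALSE]
    ctrl <- tab[tab$group == "control", , drop = FALSE]
    fp <- sum(carr$cn == calibrator_cn)
    chg <- sum(ctrl$cn != calibrator_cn)
    rep_a <- list(
      assay_id = assay,
      n_carriers = nrow(carr), n_confirmed = nrow(carr) - fp,
      n_false_positive = fp,
      fdr = if (nrow(carr)) fp / nrow(carr) else NA_real_,
      fdr_pct = if (nrow(carr)) round(100 * fp / nrow(carr)) else NA_real_,
      n_controls = nrow(ctrl), n_changed_controls = chg,
      fnr = if (nrow(ctrl)) chg / nrow(ctrl) else NA_real_,
      fnr_pct = if (nrow(ctrl)) round(100 * chg / nrow(ctrl)) else NA_real_)
    if (!is.null(tab$population)) {
      rep_a$by_population <- do.call(rbind, lapply(
        unique(carr$population), function(p) {
          cp <- carr[carr$population == p, ]
          fpp <- sum(cp$cn == calibrator_cn)
          data.frame(population = p, n_carriers = nrow(cp),
                     n_confirmed = nrow(cp) - fpp, n_false_positive = fpp,
                     fdr = fpp / nrow(cp),
                     fdr_pct = round(100 * fpp / nrow(cp)))
        }))
    }
    reports[[assay]] <- rep_a
  }
  structure(reports, class = "validation_report")
}

#' Region-level false discovery rate
#'
#' The fraction of tested regions not confirmed, and its complement,
#' both as exact fractions and whole percents.
#'
#' @param confirmed Logical vector, one element per tested region.
#' @return List: n_tested, n_confirmed, fdr, fdr_pct, validated,
#'   validated_pct.
#' @export
region_level_fdr <- function(confirmed) {
  if (length(confirmed) == 0) stop("no tested regions")
  confirmed <- as.logical(confirmed)
  list(n_tested = length(confirmed), n_confirmed = sum(confirmed),
       fdr = mean(!confirmed), fdr_pct = round(100 * mean(!confirmed)),
       validated = mean(confirmed),
       validated_pct = round(100 * mean(confirmed)))
}

#' Simulate a triplicate Ct table from true copy numbers
#'
#' Target Ct is generated as reference Ct - log2(CN / calibrator_cn)
#' plus replicate noise; a homozygous deletion (CN 0) yields the
#' censoring value `max_ct` (no amplification). The calibrator must have
#' the calibrator copy number.
#'
#' @param true_cn Named integer vector of true copy numbers per sample.
#' @param calibrator Name of the calibrator sample (true CN must equal
#'   `calibrator_cn`).
#' @param assay_id Assay label.
#' @param noise_sd Per-replicate Ct noise sd in cycles.
#' @param n_reps Replicates per sample (default 3).
#' @param ref_ct Mean reference Ct (default 20).
#' @param max_ct Censoring cycle count for no amplification (default 40).
#' @param calibrator_cn Calibrator copy number (default 2).
#' @param group Optional named vector of carrier/control labels.
#' @param seed Integer seed.
#' @return A Ct data.frame suitable for [relative_quantify()].
#' @export
simulate_ct_table <- function(true_cn, calibrator, assay_id = "assay1",
                              noise_sd = 0.1, n_reps = 3L, ref_ct = 20,
                              max_ct = 40, calibrator_cn = 2,
                              group = NULL, seed = 1L) {
  stopifnot(!is.null(names(true_cn)), calibrator %in% names(true_cn))
  if (true_cn[[calibrator]] != calibrator_cn) {
    stop("calibrator must carry ", calibrator_cn, " copies")
  }
  set.seed(as.integer(seed))
  rows <- list()
  for (sid in names(true_cn)) {
    cn <- true_cn[[sid]]
    tgt_mean <- if (cn == 0) max_ct else ref_ct - log2(cn / calibrator_cn)
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sid, assay_id = assay_id, replicate = seq_len(n_reps),
      target_ct = pmin(tgt_mean + stats::rnorm(n_reps, 0, noise_sd), max_ct),
      reference_ct = ref_ct + stats::rnorm(n_reps, 0, noise_sd),
      calibrator = sid == calibrator,
      stringsAsFactors = FALSE)
    if (!is.null(group)) rows[[length(rows)]]$group <- group[[sid]]
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
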