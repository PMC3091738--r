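# Consensus CNVR construction: the pipeline's defining filters are
# (i) each event recalled by >= 2 of the 3 callers within a sample,
# (ii) the consensus interval spans >= 3 consecutive map SNPs,
# (iii) each region carried by >= 2 animals.
# Interval overlap means >= 1 shared bp under the length = end - start
# convention (i.e. half-open: a < d and c < b for [a,b), [c,d)).

overlaps <- function(s1, e1, s2, e2) pmax(s1, s2) < pmin(e1, e2)

#' Within-sample consensus across callers
#'
#' For each maximal set of same-direction calls from at least
#' `min_callers` distinct callers whose intervals pairwise overlap, one
#' consensus event is emitted whose interval is the intersection of the
#' supporting calls; intersections spanning fewer than `min_snps` map
#' probes are discarded. Maximal sets are enumerated by the interval
#' Helly property: every pairwise-overlapping set of intervals shares a
#' common point, so candidate sets are the covering sets at interval
#' start points, deduplicated and filtered to maximal ones.
#'
#' @param calls Call data.frame (one sample, or any mix: samples are
#'   processed independently).
#' @param map A [snp_map()].
#' @param min_callers Minimum distinct supporting callers (default 2).
#' @param min_snps Minimum consecutive map SNPs in the consensus
#'   interval (default 3).
#' @return data.frame: sample_id, chrom, start, end, n_snps, direction,
#'   supporters (comma-joined caller ids), n_callers.
#' @export
per_sample_consensus <- function(calls, map, min_callers = 2L,
                                 min_snps = 3L) {
  unknown <- setdiff(unique(calls$chrom), unique(map$chrom))
  if (length(unknown)) {
    stop("calls reference chromosomes absent from the map: ",
         paste(unknown, collapse = ", "))
  }
  out <- list()
  for (sid in unique(calls$sample_id)) {
    for (ch in unique(calls$chrom[calls$sample_id == sid])) {
      for (dir in c("loss", "gain")) {
        cs <- calls[calls$sample_id == sid & calls$chrom == ch &
                      calls$direction == dir, , drop = FALSE]
        if (nrow(cs) < min_callers) next
        sets <- list()
        for (p in sort(unique(cs$start))) {
          member <- which(cs$start <= p & p < cs$end)
          if (length(member) >= 2) sets[[length(sets) + 1L]] <- sort(member)
        }
        sets <- unique(sets)
        maximal <- sets[!vapply(seq_along(sets), function(i) {
          any(vapply(seq_along(sets), function(j) {
            i != j && all(sets[[i]] %in% sets[[j]])
          }, TRUE))
        }, TRUE)]
        for (s in maximal) {
          callers <- sort(unique(cs$caller[s]))
          if (length(callers) < min_callers) next
          lo <- max(cs$start[s]); hi <- min(cs$end[s])
          if (lo >= hi) next
          nsnp <- length(probes_in_interval(map, ch, lo, hi))
          if (nsnp < min_snps) next
          out[[length(out) + 1L]] <- data.frame(
            sample_id = sid, chrom = ch, start = lo, end = hi,
            n_snps = nsnp, direction = dir,
            supporters = paste(callers, collapse = ","),
            n_callers = length(callers), stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out)) {
    res <- do.call(rbind, out)
    res <- res[order(match(res$chrom, map_chrom_order(map)), res$start), ]
    rownames(res) <- NULL
    res
  } else {
    data.frame(sample_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0), n_snps = integer(0),
               direction = character(0), supporters = character(0),
               n_callers = integer(0), stringsAsFactors = FALSE)
  }
}

#' Build CNVRs from per-sample consensus events
#'
#' Single-linkage clustering of overlapping consensus intervals per
#' chromosome; clusters carried by at least `min_carriers` distinct
#' samples become CNVRs. The CNVR span is the union of member intervals,
#' status comes from member directions (all loss -> "Loss", all gain ->
#' "Gain", mixed -> "Loss-Gain"), and ids are assigned in genome order
#' (chromosome order of the map, then start position).
#'
#' @param consensus Output of [per_sample_consensus()] over all samples.
#' @param map A [snp_map()].
#' @param min_carriers Minimum distinct carrier samples (default 2).
#' @return data.frame of class `cnvr_set`: cnvr_id, chrom, start, end,
#'   length_kb, status, n_snps, n_carriers, carriers (list column),
#'   supporters (list column of contributing callers).
#' @export
build_cnvrs <- function(consensus, map, min_carriers = 2L) {
  rows <- list()
  for (ch in intersect(map_chrom_order(map), unique(consensus$chrom))) {
    cc <- consensus[consensus$chrom == ch, , drop = FALSE]
    cc <- cc[order(cc$start, cc$end), , drop = FALSE]
    k <- 0L; cluster <- integer(nrow(cc)); max_end <- -Inf
    for (i in seq_len(nrow(cc))) {
      if (cc$start[i] < max_end) {
        cluster[i] <- k
        max_end <- max(max_end, cc$end[i])
      } else {
        k <- k + 1L
        cluster[i] <- k
        max_end <- cc$end[i]
      }
    }
    for (cl in seq_len(k)) {
      m <- cc[cluster == cl, , drop = FALSE]
      carriers <- sort(unique(m$sample_id))
      if (length(carriers) < min_carriers) next
      dirs <- unique(m$direction)
      status <- if (setequal(dirs, "loss")) "Loss"
        else if (setequal(dirs, "gain")) "Gain" else "Loss-Gain"
      lo <- min(m$start); hi <- max(m$end)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = lo, end = hi,
        length_kb = (hi - lo) / 1000, status = status,
        n_snps = length(probes_in_interval(map, ch, lo, hi)),
        n_carriers = length(carriers), stringsAsFactors = FALSE)
      rows[[length(rows)]]$carriers <- I(list(carriers))
      rows[[length(rows)]]$supporters <-
        I(list(sort(unique(unlist(strsplit(m$supporters, ","))))))
    }
  }
  if (length(rows)) {
    res <- do.call(rbind, rows)
    res <- res[order(match(res$chrom, map_chrom_order(map)), res$start), ]
    res <- cbind(cnvr_id = seq_len(nrow(res)), res)
    rownames(res) <- NULL
  } else {
    res <- data.frame(cnvr_id = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      length_kb = numeric(0), status = character(0),
                      n_snps = integer(0), n_carriers = integer(0))
    res$carriers <- I(list()); res$supporters <- I(list())
  }
  class(res) <- c("cnvr_set", "data.frame")
  res
}

#' Summarize a CNVR set
#'
#' Region count, chromosomes hit, length statistics in kb, status counts
#' and percentages (one decimal), and the carrier-count range. Works on
#' [build_cnvrs()] output or any CNVR table with length_kb, status,
#' chrom and a carrier count column.
#'
#' @param cnvrs A `cnvr_set` data.frame (possibly empty).
#' @return List of class `cnvr_summary`.
#' @export
summarize_cnvrs <- function(cnvrs) {
  statuses <- c("Gain", "Loss", "Loss-Gain")
  if (nrow(cnvrs) == 0) {
    return(structure(list(
      n_cnvrs = 0L, n_chromosomes = 0L,
      length_min_kb = 0, length_max_kb = 0, length_mean_kb = 0,
      length_median_kb = 0,
      status_counts = stats::setNames(rep(0L, 3), statuses),
      status_pct = stats::setNames(rep(0, 3), statuses),
      carrier_min = 0L, carrier_max = 0L, n_supported_by_all = 0L),
      class = "cnvr_summary"))
  }
  ncv <- nrow(cnvrs)
  counts <- stats::setNames(
    vapply(statuses, function(s) sum(cnvrs$status == s), 0L), statuses)
  carriers <- if (!is.null(cnvrs$n_carriers)) cnvrs$n_carriers else NA_integer_
  all3 <- if (!is.null(cnvrs$supporters)) {
    sum(vapply(cnvrs$supporters, length, 0L) >= 3L)
  } else NA_integer_
  structure(list(
    n_cnvrs = ncv, n_chromosomes = length(unique(cnvrs$chrom)),
    length_min_kb = min(cnvrs$length_kb),
    length_max_kb = max(cnvrs$length_kb),
    length_mean_kb = mean(cnvrs$length_kb),
    length_median_kb = stats::median(cnvrs$length_kb),
    status_counts = counts,
    status_pct = round(100 * counts / ncv, 1),
    carrier_min = min(carriers), carrier_max = max(carriers),
    n_supported_by_all = all3), class = "cnvr_summary")
}

#' @export
print.cnvr_summary <- function(x, ...) {
  cat(sprintf("%d CNVRs on %d chromosomes\n", x$n_cnvrs, x$n_chromosomes))
  cat(sprintf("length (kb): min %.2f, max %.2f, mean %.2f, median %.2f\n",
              x$length_min_kb, x$length_max_kb, x$length_mean_kb,
              x$length_median_kb))
  for (s in names(x$status_counts)) {
    cat(sprintf("  %-9s %3d (%.1f%%)\n", s, x$status_counts[[s]],
                x$status_pct[[s]]))
  }
  cat(sprintf("carriers per region: %d-%d\n", x$carrier_min, x$carrier_max))
  invisible(x)
}

#' Per-caller confirmation rates and three-way support
#'
#' For each caller, the fraction of its raw calls that overlap a final
#' CNVR; plus the count and percentage of CNVRs supported by all three
#' callers. A caller with zero raw calls gets an NA rate.
#'
#' @param calls Combined raw call table (all callers).
#' @param cnvrs [build_cnvrs()] output.
#' @return List with `per_caller` (data.frame: caller, n_calls,
#'   n_confirmed, rate_pct) and `three_way` (list: n, total, pct).
#' @export
caller_agreement <- function(calls, cnvrs) {
  callers <- c("hmm", "sbl", "partition")
  per <- lapply(callers, function(cl) {
    cs <- calls[calls$caller == cl, , drop = FALSE]
    if (nrow(cs) == 0) {
      return(data.frame(caller = cl, n_calls = 0L, n_confirmed = 0L,
                        rate_pct = NA_real_))
    }
    conf <- vapply(seq_len(nrow(cs)), function(i) {
      any(cnvrs$chrom == cs$chrom[i] &
            overlaps(cnvrs$start, cnvrs$end, cs$start[i], cs$end[i]))
    }, TRUE)
    data.frame(caller = cl, n_calls = nrow(cs), n_confirmed = sum(conf),
               rate_pct = round(100 * mean(conf), 2))
  })
  n3 <- if (nrow(cnvrs)) sum(vapply(cnvrs$supporters, length, 0L) >= 3L) else 0L
  list(per_caller = do.call(rbind, per),
       three_way = list(n = n3, total = nrow(cnvrs),
                        pct = if (nrow(cnvrs)) round(100 * n3 / nrow(cnvrs), 2)
                              else NA_real_))
}

#' Annotate CNVRs with overlapping genes
#'
#' A gene is assigned to a CNVR when their intervals share at least one
#' bp under the length = end - start convention (a gene abutting the
#' boundary is not assigned). Overlap is computed with GenomicRanges.
#'
#' @param cnvrs A `cnvr_set` data.frame.
#' @param genes data.frame with chrom, start, end (1-based inclusive),
#'   id, biotype (see [read_gene_annotation()]).
#' @return List with `assignments` (data.frame: cnvr_id, gene_id,
#'   biotype), `biotype_counts` (named integer vector of distinct genes
#'   per biotype), and `empty_cnvrs` (ids with no gene).
#' @export
annotate_genes <- function(cnvrs, genes) {
  if (length(intersect(unique(cnvrs$chrom), unique(genes$chrom))) == 0 &&
      nrow(cnvrs) && nrow(genes)) {
    stop("no shared chromosome names between CNVRs and annotation; ",
         "CNVR names: ", paste(unique(cnvrs$chrom), collapse = ","),
         " vs annotation names: ", paste(unique(genes$chrom), collapse = ","))
  }
  # internal half-open [start, end) -> inclusive last covered base end - 1
  gr_c <- GenomicRanges::GRanges(cnvrs$chrom,
                                 IRanges::IRanges(cnvrs$start,
                                                  pmax(cnvrs$end - 1L,
                                                       cnvrs$start)))
  gr_g <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start,
                                                  pmax(genes$end - 1L,
                                                       genes$start)))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_g, gr_c))
  assignments <- data.frame(
    cnvr_id = cnvrs$cnvr_id[S4Vectors::subjectHits(hits)],
    gene_id = genes$id[S4Vectors::queryHits(hits)],
    biotype = genes$biotype[S4Vectors::queryHits(hits)],
    stringsAsFactors = FALSE)
  hit_genes <- unique(assignments[, c("gene_id", "biotype")])
  counts <- table(hit_genes$biotype)
  list(assignments = assignments,
       biotype_counts = stats::setNames(as.integer(counts), names(counts)),
       empty_cnvrs = setdiff(cnvrs$cnvr_id, assignments$cnvr_id))
}
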