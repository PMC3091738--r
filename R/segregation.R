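# Mendelian segregation of CNVR copy-number genotypes. Intensity data is
# unphased, so a total copy number is compatible with several ordered
# haplotype pairs; consistency is decided existentially over the
# restricted allele space implied by the CNVR status (an unrestricted
# space would make nearly everything consistent).

kind_alleles <- function(kind) {
  switch(match.arg(kind, c("loss", "gain", "mixed")),
         loss = 0:1, gain = 1:3, mixed = 0:3)
}

#' Haplotype genotype space for a total copy number
#'
#' All ordered pairs (a, b) of per-haplotype copy counts with
#' a + b = total_cn, components drawn from the allele space of the locus
#' kind: \{0,1\} for loss-only loci, \{1,2,3\} for gain-only, \{0,1,2,3\}
#' for mixed.
#'
#' @param total_cn Integer total copy number in 0..4.
#' @param kind "loss", "gain" or "mixed".
#' @return Integer matrix with columns a, b (possibly 0 rows).
#' @export
genotype_space <- function(total_cn, kind) {
  total_cn <- as.integer(total_cn)
  if (is.na(total_cn) || total_cn < 0L || total_cn > 4L) {
    stop("total_cn must be in 0..4")
  }
  alleles <- kind_alleles(kind)
  g <- expand.grid(a = alleles, b = alleles)
  as.matrix(g[g$a + g$b == total_cn, , drop = FALSE])
}

#' Mendelian consistency of one trio at one CNVR
#'
#' TRUE iff there exist genotypes g_o, g_s, g_d in the respective
#' genotype spaces such that one component of the offspring genotype is
#' transmissible by the sire and the other by the dam. Decided by
#' exhaustive enumeration (the spaces are tiny); symmetric in sire/dam.
#'
#' @param offspring_cn,sire_cn,dam_cn Observed total copy numbers (0..4).
#' @param kind Locus kind ("loss", "gain", "mixed").
#' @return List with `consistent` (logical) and, when consistent,
#'   `witness`: the offspring genotype and the parental genotypes that
#'   transmit it.
#' @export
trio_consistent <- function(offspring_cn, sire_cn, dam_cn, kind) {
  if (any(is.na(c(offspring_cn, sire_cn, dam_cn)))) {
    stop("trio_consistent requires all three copy numbers observed")
  }
  go <- genotype_space(offspring_cn, kind)
  gs <- genotype_space(sire_cn, kind)
  gd <- genotype_space(dam_cn, kind)
  for (i in seq_len(nrow(go))) {
    from_sire <- go[i, 1]; from_dam <- go[i, 2]
    si <- which(gs[, 1] == from_sire | gs[, 2] == from_sire)
    di <- which(gd[, 1] == from_dam | gd[, 2] == from_dam)
    if (length(si) && length(di)) {
      return(list(consistent = TRUE,
                  witness = list(offspring = go[i, ],
                                 sire = gs[si[1], ], dam = gd[di[1], ])))
    }
  }
  list(consistent = FALSE, witness = NULL)
}

#' Check Mendelian segregation through a pedigree
#'
#' Applies [trio_consistent()] to every complete trio (offspring with
#' both parents known and all three copy numbers observed) for every
#' CNVR. Trios with a missing member or missing copy number are
#' excluded, not counted.
#'
#' @param carriers data.frame: cnvr_id, sample_id, cn, and either a
#'   `kind` column or `status` (Loss/Gain/Loss-Gain, mapped to
#'   loss/gain/mixed).
#' @param pedigree Pedigree data.frame (id, sire, dam, ...); must be
#'   acyclic.
#' @return List of class `mendelian_report`: `trios` (per trio and CNVR:
#'   consistent flag), `per_cnvr` (consistency rate and trio count),
#'   `overall_rate` (NA when no trios), `violations`.
#' @export
check_pedigree <- function(carriers, pedigree) {
  validate_pedigree(pedigree)  # errors on cycles
  if (is.null(carriers$kind)) {
    if (is.null(carriers$status)) stop("carriers need a kind or status column")
    carriers$kind <- c(Loss = "loss", Gain = "gain",
                       `Loss-Gain` = "mixed")[carriers$status]
  }
  trios <- list()
  for (cnvr in unique(carriers$cnvr_id)) {
    tab <- carriers[carriers$cnvr_id == cnvr, , drop = FALSE]
    cn_of <- stats::setNames(tab$cn, tab$sample_id)
    for (i in seq_len(nrow(pedigree))) {
      o <- pedigree$id[i]; s <- pedigree$sire[i]; d <- pedigree$dam[i]
      if (s == "0" || d == "0") next
      if (any(is.na(cn_of[c(o, s, d)])) ||
          !all(c(o, s, d) %in% names(cn_of))) next
      res <- trio_consistent(cn_of[[o]], cn_of[[s]], cn_of[[d]],
                             tab$kind[1])
      trios[[length(trios) + 1L]] <- data.frame(
        cnvr_id = cnvr, offspring = o, sire = s, dam = d,
        offspring_cn = cn_of[[o]], sire_cn = cn_of[[s]], dam_cn = cn_of[[d]],
        consistent = res$consistent, stringsAsFactors = FALSE)
    }
  }
  trios <- if (length(trios)) do.call(rbind, trios) else
    data.frame(cnvr_id = character(0), offspring = character(0),
               sire = character(0), dam = character(0),
               offspring_cn = integer(0), sire_cn = integer(0),
               dam_cn = integer(0), consistent = logical(0))
  per <- do.call(rbind, lapply(unique(trios$cnvr_id), function(cv) {
    t <- trios[trios$cnvr_id == cv, ]
    data.frame(cnvr_id = cv, n_trios = nrow(t), rate = mean(t$consistent))
  }))
  structure(list(
    trios = trios,
    per_cnvr = if (is.null(per)) data.frame(cnvr_id = character(0),
                                            n_trios = integer(0),
                                            rate = numeric(0)) else per,
    overall_rate = if (nrow(trios)) mean(trios$consistent) else NA_real_,
    violations = trios[!trios$consistent, , drop = FALSE]),
    class = "mendelian_report")
}

#' Per-population carrier counts per CNVR
#'
#' An individual is a carrier when its copy number differs from two.
#' Populations where a CNVR has no carriers are flagged absent.
#'
#' @param carriers data.frame: cnvr_id, sample_id, cn, population.
#' @return List with `counts` (data.frame: cnvr_id, population,
#'   n_carriers), `total` (per CNVR) and `absent` (data.frame: cnvr_id,
#'   population with zero carriers).
#' @export
segregation_summary <- function(carriers) {
  pops <- sort(unique(carriers$population))
  rows <- list(); absent <- list()
  for (cv in unique(carriers$cnvr_id)) {
    tab <- carriers[carriers$cnvr_id == cv, ]
    for (p in pops) {
      n <- sum(tab$population == p & tab$cn != 2L)
      rows[[length(rows) + 1L]] <- data.frame(
        cnvr_id = cv, population = p, n_carriers = n,
        stringsAsFactors = FALSE)
      if (n == 0L) absent[[length(absent) + 1L]] <- data.frame(
        cnvr_id = cv, population = p, stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(rbind, rows)
  total <- do.call(rbind, lapply(unique(carriers$cnvr_id), function(cv) {
    data.frame(cnvr_id = cv,
               n_carriers = sum(carriers$cn[carriers$cnvr_id == cv] != 2L))
  }))
  list(counts = counts, total = total,
       absent = if (length(absent)) do.call(rbind, absent) else
         data.frame(cnvr_id = character(0), population = character(0)))
}
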