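#' SNP probe map
#'
#' An ordered table of autosomal SNP probes, the backbone that signal
#' tracks and calls index into. Positions are 1-based; interval lengths
#' throughout the package follow the end - start convention.
#'
#' @param probe_id Character vector of unique probe names.
#' @param chrom Chromosome label per probe (autosomes only; "X"/"Y"
#'   labels are rejected, mirroring the usual exclusion of sex
#'   chromosomes from array CNV calling).
#' @param pos Integer base-pair position, strictly increasing within each
#'   chromosome.
#' @return A data.frame of class `snp_map` with columns probe_id, chrom,
#'   pos. Chromosome order is order of first appearance.
#' @export
snp_map <- function(probe_id, chrom, pos) {
  stopifnot(length(probe_id) == length(chrom),
            length(chrom) == length(pos))
  probe_id <- as.character(probe_id)
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  if (anyDuplicated(probe_id)) {
    stop("probe_id values must be unique")
  }
  sex <- toupper(sub("^CHR", "", toupper(chrom))) %in% c("X", "Y")
  if (any(sex)) {
    stop("sex chromosomes are not supported: ",
         paste(unique(chrom[sex]), collapse = ", "))
  }
  m <- data.frame(probe_id = probe_id, chrom = chrom, pos = pos,
                  stringsAsFactors = FALSE)
  for (ch in unique(m$chrom)) {
    p <- m$pos[m$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("positions must be strictly increasing within chromosome ", ch)
    }
  }
  class(m) <- c("snp_map", "data.frame")
  m
}

#' Simulate a SNP map with exponential inter-probe spacing
#'
#' Probe spacing is drawn i.i.d. exponential with the stated mean, the
#' default being the 39.61 kb average autosomal inter-SNP distance of the
#' Porcine SNP60 BeadChip.
#'
#' @param n_probes Probes per chromosome (recycled over `chromosomes`).
#' @param chromosomes Chromosome labels (default "1", "2", ...).
#' @param spacing_mean Mean inter-probe distance in bp (default 39610).
#' @param seed Integer seed.
#' @return A `snp_map`.
#' @export
simulate_snp_map <- function(n_probes, chromosomes = as.character(seq_along(n_probes)),
                             spacing_mean = 39610, seed = 1L) {
  n_probes <- rep_len(as.integer(n_probes), length(chromosomes))
  set.seed(as.integer(seed))
  ids <- character(0); chs <- character(0); pos <- integer(0)
  for (i in seq_along(chromosomes)) {
    gaps <- pmax(1L, as.integer(round(stats::rexp(n_probes[i], 1 / spacing_mean))))
    p <- cumsum(gaps)
    ids <- c(ids, sprintf("chr%s_p%04d", chromosomes[i], seq_len(n_probes[i])))
    chs <- c(chs, rep(chromosomes[i], n_probes[i]))
    pos <- c(pos, p)
  }
  snp_map(ids, chs, pos)
}

# Indices of map probes lying in [start, end] (probe positions inclusive:
# call boundaries are themselves probe coordinates).
probes_in_interval <- function(map, chrom, start, end) {
  which(map$chrom == chrom & map$pos >= start & map$pos <= end)
}

# Chromosome order as given by the map (genome order for cnvr ids).
map_chrom_order <- function(map) unique(map$chrom)
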