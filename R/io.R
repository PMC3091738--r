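# Readers/writers for the tabular interchange formats: GenomeStudio-style
# final report signal tables, PED-like pedigrees, call tables, CNVR tables
# and gene annotation (BED/GFF3 via rtracklayer).

#' Write a cohort's signal table in Final-Report-like layout
#'
#' Tab-separated, one row per probe: "SNP Name", "Chr", "Position", then
#' per sample `<id>.Log R Ratio` and `<id>.B Allele Freq`. Signal values
#' are written with 4 decimals.
#'
#' @param cohort A rendered `cnv_cohort` (or a list with map and signals).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_final_report <- function(cohort, path) {
  stopifnot(!is.null(cohort$signals))
  df <- data.frame(`SNP Name` = cohort$map$probe_id,
                   Chr = cohort$map$chrom, Position = cohort$map$pos,
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (id in names(cohort$signals)) {
    tr <- cohort$signals[[id]]
    df[[paste0(id, ".Log R Ratio")]] <- sprintf("%.4f", tr$lrr)
    df[[paste0(id, ".B Allele Freq")]] <- sprintf("%.4f", tr$baf)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a Final-Report-like signal table
#'
#' @param path Tab-separated file as written by [write_final_report()].
#' @return List with `map` (a [snp_map()]) and `signals` (named list of
#'   [signal_track()]s). A sample with only one of its two signal columns
#'   present is an error naming the sample.
#' @export
read_final_report <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("SNP Name", "Chr", "Position")
  if (!all(need %in% names(df))) {
    stop("signal table must have columns: ", paste(need, collapse = ", "))
  }
  map <- snp_map(df[["SNP Name"]], df[["Chr"]], df[["Position"]])
  other <- setdiff(names(df), need)
  lrr_ids <- sub("\\.Log R Ratio$", "", grep("\\.Log R Ratio$", other, value = TRUE))
  baf_ids <- sub("\\.B Allele Freq$", "", grep("\\.B Allele Freq$", other, value = TRUE))
  half <- c(setdiff(lrr_ids, baf_ids), setdiff(baf_ids, lrr_ids))
  if (length(half)) {
    stop("sample(s) missing one signal column: ", paste(half, collapse = ", "))
  }
  signals <- list()
  for (id in lrr_ids) {
    signals[[id]] <- signal_track(
      id, as.numeric(df[[paste0(id, ".Log R Ratio")]]),
      as.numeric(df[[paste0(id, ".B Allele Freq")]]))
  }
  list(map = map, signals = signals)
}

#' Write / read a PED-like pedigree file
#'
#' White-space separated: family, individual, sire, dam, sex,
#' population/generation label; "0" marks an unknown parent.
#'
#' @param pedigree Pedigree data.frame (or a `cnv_cohort`).
#' @param path File path.
#' @return `path` invisibly; the pedigree data.frame for the reader.
#' @export
write_pedigree <- function(pedigree, path) {
  if (inherits(pedigree, "cnv_cohort")) pedigree <- pedigree$pedigree
  utils::write.table(pedigree[, c("family", "id", "sire", "dam", "sex",
                                  "population")],
                     path, sep = " ", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("family", "id", "sire", "dam",
                                        "sex", "population"))
  df$id <- as.character(df$id); df$sire <- as.character(df$sire)
  df$dam <- as.character(df$dam)
  df$generation <- df$population
  validate_pedigree(df)
  df
}

#' Write / read a CNV call table
#'
#' Tab-separated with header: sample_id, chrom, start, end, n_snps,
#' state, direction, caller, score. Round trip is lossless; rows with
#' state 2 (copy-neutral) are rejected on read with their line number.
#'
#' @param calls A call data.frame (see [hmm_call()]).
#' @param path File path.
#' @return `path` invisibly; the call data.frame for the reader.
#' @export
write_calls <- function(calls, path) {
  cols <- c("sample_id", "chrom", "start", "end", "n_snps", "state",
            "direction", "caller", "score")
  df <- if (nrow(calls)) calls[, cols] else
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character",
                                         sample_id = "character"))
  bad <- which(!df$state %in% c(0L, 1L, 3L, 4L))
  if (length(bad)) {
    stop("invalid copy-number state at line(s) ",
         paste(bad + 1L, collapse = ", "), " (state 2 is not a CNV)")
  }
  bad_dir <- which(!df$direction %in% c("loss", "gain"))
  if (length(bad_dir)) {
    stop("invalid direction at line(s) ", paste(bad_dir + 1L, collapse = ", "))
  }
  as_cnv_calls(df)
}

# Canonical empty/validated call table.
as_cnv_calls <- function(df = NULL) {
  if (is.null(df)) {
    df <- data.frame(sample_id = character(0), chrom = character(0),
                     start = integer(0), end = integer(0),
                     n_snps = integer(0), state = integer(0),
                     direction = character(0), caller = character(0),
                     score = numeric(0), stringsAsFactors = FALSE)
  }
  stopifnot(all(df$state != 2L), all(df$end > df$start | df$n_snps == 1L))
  rownames(df) <- NULL
  df
}

#' Write a CNVR table and its BED companion
#'
#' The table mirrors the usual CNVR report: id, chrom, start, end,
#' length_kb, status, n_carriers, carriers, supporters, n_snps. The BED
#' file is 0-based half-open (internal coordinates are 1-based with
#' length = end - start, so BED start = start - 1, BED end = end - 1).
#'
#' @param cnvrs CNVR data.frame from [build_cnvrs()].
#' @param path Output TSV path.
#' @param bed_path Optional BED output path.
#' @return `path` invisibly.
#' @export
write_cnvr_table <- function(cnvrs, path, bed_path = NULL) {
  df <- cnvrs
  df$carriers <- vapply(cnvrs$carriers, paste, "", collapse = ",")
  df$supporters <- vapply(cnvrs$supporters, paste, "", collapse = ",")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = cnvrs$chrom, start = cnvrs$start - 1L,
                      end = cnvrs$end - 1L,
                      name = paste0("CNVR", cnvrs$cnvr_id),
                      score = cnvrs$n_carriers,
                      strand = ".")
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a CNVR table
#'
#' Accepts the package's own output or any table with at least cnvr_id,
#' chrom, start, end, status columns; length_kb is recomputed when absent.
#'
#' @param path TSV path.
#' @return A CNVR data.frame of class `cnvr_set`.
#' @export
read_cnvr_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  if (is.null(df$length_kb)) df$length_kb <- (df$end - df$start) / 1000
  if (!is.null(df$carriers) && is.character(df$carriers)) {
    df$carriers <- I(strsplit(df$carriers, ","))
  }
  if (!is.null(df$supporters) && is.character(df$supporters)) {
    df$supporters <- I(strsplit(df$supporters, ","))
  }
  class(df) <- c("cnvr_set", "data.frame")
  df
}

#' The 49-region porcine CNVR catalogue
#'
#' The published table of 49 autosomal CNVRs detected in a 55-animal
#' Iberian x Landrace cross genotyped on the Porcine SNP60 BeadChip:
#' coordinates (Sscrofa9), printed length in kb, Loss/Gain/Loss-Gain
#' status and carrier counts from the follow-up segregation cohort.
#' Shipped as a plain-text fixture for worked examples and summary
#' reproduction.
#'
#' @return A `cnvr_set` data.frame with 49 rows: cnvr_id, chrom, start,
#'   end, length_kb, status, n_animals.
#' @export
pig_cnvr_catalog <- function() {
  path <- system.file("extdata", "pig_cnvr_catalog.tsv", package = "snpcnvr",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  df$n_carriers <- df$n_animals
  class(df) <- c("cnvr_set", "data.frame")
  df
}

#' Read gene annotation intervals from BED or GFF3
#'
#' BED input may carry a 7th column named `biotype` (via rtracklayer's
#' extraCols); GFF3 input uses the `biotype` attribute (falling back to
#' the feature type) and `ID`/`gene_id` for the gene id. BED's 0-based
#' half-open coordinates are converted to the package's 1-based
#' convention.
#'
#' @param path Path ending in .bed, .gff, .gff3 (case-insensitive).
#' @return data.frame with columns chrom, start, end, id, biotype
#'   (1-based inclusive start/end, as imported).
#' @export
read_gene_annotation <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.bed$", lower)) {
    ncol_file <- length(strsplit(readLines(path, n = 1), "\t")[[1]])
    extra <- if (ncol_file >= 7) c(biotype = "character") else character(0)
    gr <- rtracklayer::import(path, format = "BED", extraCols = extra)
    biotype <- if (ncol_file >= 7) gr$biotype else rep("gene", length(gr))
    id <- if (!is.null(gr$name)) gr$name else sprintf("gene%03d", seq_along(gr))
  } else if (grepl("\\.gff3?$", lower)) {
    gr <- rtracklayer::import(path, format = "GFF3")
    meta <- S4Vectors::mcols(gr)
    biotype <- if ("biotype" %in% names(meta)) as.character(meta$biotype)
      else as.character(meta$type)
    id <- if ("ID" %in% names(meta) && !all(is.na(meta$ID)))
      as.character(meta$ID)
      else if ("gene_id" %in% names(meta)) as.character(meta$gene_id)
      else sprintf("gene%03d", seq_along(gr))
  } else {
    stop("unsupported annotation format (expect .bed or .gff3): ", path)
  }
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             id = id, biotype = biotype, stringsAsFactors = FALSE)
}
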