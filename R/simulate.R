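#' Define a CNV locus for simulation
#'
#' A locus is a genomic interval plus the per-haplotype copy counts that
#' segregate there. The normal haplotype carries one copy; a deletion
#' allele carries 0, duplication alleles 2 or 3. Total copy number of an
#' individual at the locus is the sum of its two haplotype counts.
#'
#' @param chrom Chromosome label.
#' @param start,end 1-based interval, end > start (length = end - start bp).
#' @param alleles Integer vector of permitted per-haplotype copy counts;
#'   must contain 1 (the normal allele); values in 0..3.
#' @param freq Allele frequencies: either a named numeric vector over
#'   `alleles` (applied to every founder population) or a named list of
#'   such vectors keyed by population label. Each must sum to 1.
#' @param id Optional locus id.
#' @return A list of class `cnv_locus`.
#' @export
cnv_locus <- function(chrom, start, end, alleles, freq, id = NULL) {
  alleles <- sort(unique(as.integer(alleles)))
  stopifnot(end > start, all(alleles >= 0L), all(alleles <= 3L))
  if (!1L %in% alleles) stop("the normal allele (1 copy) must be in the allele space")
  if (!is.list(freq)) freq <- list(.default = freq)
  for (nm in names(freq)) {
    f <- freq[[nm]]
    if (is.null(names(f)) || !setequal(names(f), as.character(alleles))) {
      stop("freq must be named by the allele copy counts: ",
           paste(alleles, collapse = ","))
    }
    if (any(f < 0) || any(f > 1) || abs(sum(f) - 1) > 1e-8) {
      stop("allele frequencies must lie in [0,1] and sum to 1")
    }
  }
  structure(list(id = id, chrom = as.character(chrom),
                 start = as.integer(start), end = as.integer(end),
                 alleles = alleles, freq = freq),
            class = "cnv_locus")
}

# Frequency vector of a locus for one population (falls back to .default).
locus_freq <- function(locus, population) {
  f <- locus$freq[[population]]
  if (is.null(f)) f <- locus$freq[[".default"]]
  if (is.null(f)) stop("no allele frequencies for population ", population)
  f
}

# Kind of a locus from its allele space: used to pick the Mendelian
# genotype space ("loss", "gain" or "mixed").
locus_kind <- function(locus) {
  a <- locus$alleles
  if (all(a <= 1L)) "loss" else if (all(a >= 1L)) "gain" else "mixed"
}

#' Noise model for signal rendering
#'
#' @param lrr_sd Gaussian LRR noise sd (dimensionless, log2 scale).
#' @param baf_sd Gaussian BAF noise sd around genotype cluster means.
#' @param outlier_rate Fraction of probes whose LRR noise is drawn from a
#'   5x heavier Gaussian (heavy-tailed contamination), in [0, 1).
#' @param seed Integer seed; all stochastic draws of a simulation flow
#'   from it.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(lrr_sd = 0.2, baf_sd = 0.03, outlier_rate = 0,
                        seed = 1L) {
  stopifnot(lrr_sd >= 0, baf_sd >= 0, outlier_rate >= 0, outlier_rate < 1)
  structure(list(lrr_sd = lrr_sd, baf_sd = baf_sd,
                 outlier_rate = outlier_rate, seed = as.integer(seed)),
            class = "noise_model")
}

#' Build a pedigree from founders and a mating plan
#'
#' @param founders data.frame with columns id, sex (1 = male, 2 = female),
#'   population.
#' @param matings data.frame with columns sire, dam, n_offspring,
#'   generation. Offspring of earlier matings may appear as parents in
#'   later ones. Offspring ids are `<generation>_<k>`.
#' @return data.frame with columns family, id, sire, dam, sex, population,
#'   generation; "0" marks an unknown (founder) parent.
#' @export
pedigree_spec <- function(founders, matings) {
  ped <- data.frame(family = "FAM1", id = as.character(founders$id),
                    sire = "0", dam = "0",
                    sex = as.integer(founders$sex),
                    population = as.character(founders$population),
                    generation = "founder", stringsAsFactors = FALSE)
  k <- 0L
  for (i in seq_len(nrow(matings))) {
    m <- matings[i, ]
    for (s in c(as.character(m$sire), as.character(m$dam))) {
      if (!s %in% ped$id) stop("parent not in pedigree: ", s)
    }
    for (j in seq_len(m$n_offspring)) {
      k <- k + 1L
      ped <- rbind(ped, data.frame(
        family = "FAM1", id = sprintf("%s_%03d", m$generation, k),
        sire = as.character(m$sire), dam = as.character(m$dam),
        sex = if (j %% 2 == 1) 1L else 2L,
        population = as.character(m$generation),
        generation = as.character(m$generation), stringsAsFactors = FALSE))
    }
  }
  validate_pedigree(ped)
  ped
}

#' Iberian x Landrace style intercross pedigree template
#'
#' Mirrors the structure of a three-boar x many-sow intercross: founder
#' boars of one population crossed to founder sows of another, then F1
#' intercross (F2) and backcross to the sow line.
#'
#' @param n_boars,n_sows Founder counts (defaults 3 Iberian boars and 24
#'   Landrace sows).
#' @param n_f1,n_f2,n_bc Offspring counts per generation (defaults 17, 3,
#'   8, giving the 55-animal discovery cohort layout).
#' @return A pedigree data.frame (see [pedigree_spec()]).
#' @export
ibmap_pedigree <- function(n_boars = 3, n_sows = 24, n_f1 = 17, n_f2 = 3,
                           n_bc = 8) {
  founders <- data.frame(
    id = c(sprintf("IB_%02d", seq_len(n_boars)),
           sprintf("LD_%02d", seq_len(n_sows))),
    sex = c(rep(1L, n_boars), rep(2L, n_sows)),
    population = c(rep("Iberian", n_boars), rep("Landrace", n_sows)))
  # spread F1 matings over boar x sow pairs
  matings <- data.frame(
    sire = sprintf("IB_%02d", (seq_len(n_f1) - 1L) %% n_boars + 1L),
    dam = sprintf("LD_%02d", (seq_len(n_f1) - 1L) %% n_sows + 1L),
    n_offspring = rep(1L, n_f1), generation = rep("F1", n_f1))
  ped <- pedigree_spec(founders, matings)
  f1_ids <- ped$id[ped$generation == "F1"]
  f1_m <- ped$id[ped$generation == "F1" & ped$sex == 1L]
  f1_f <- ped$id[ped$generation == "F1" & ped$sex == 2L]
  m2 <- data.frame(sire = character(0), dam = character(0),
                   n_offspring = integer(0), generation = character(0))
  if (n_f2 > 0 && length(f1_m) && length(f1_f)) {
    m2 <- rbind(m2, data.frame(
      sire = f1_m[(seq_len(n_f2) - 1L) %% length(f1_m) + 1L],
      dam = f1_f[(seq_len(n_f2) - 1L) %% length(f1_f) + 1L],
      n_offspring = 1L, generation = "F2"))
  }
  if (n_bc > 0 && length(f1_m)) {
    m2 <- rbind(m2, data.frame(
      sire = f1_m[(seq_len(n_bc) - 1L) %% length(f1_m) + 1L],
      dam = sprintf("LD_%02d", (seq_len(n_bc) - 1L) %% n_sows + 1L),
      n_offspring = 1L, generation = "BC"))
  }
  matings <- rbind(matings, m2)
  pedigree_spec(founders, matings)
}

# Checks acyclicity and two-parents-or-none; returns ids in an order where
# parents precede offspring.
validate_pedigree <- function(ped) {
  ids <- ped$id
  if (anyDuplicated(ids)) stop("duplicate individual ids in pedigree")
  one_parent <- xor(ped$sire == "0", ped$dam == "0")
  if (any(one_parent)) {
    stop("individuals with exactly one known parent: ",
         paste(ids[one_parent], collapse = ", "))
  }
  missing <- setdiff(c(ped$sire, ped$dam), c("0", ids))
  if (length(missing)) stop("parents absent from pedigree: ",
                            paste(missing, collapse = ", "))
  # Kahn topological sort; failure to exhaust => cycle
  placed <- character(0)
  remaining <- ped
  while (nrow(remaining) > 0) {
    ready <- (remaining$sire %in% c("0", placed)) &
      (remaining$dam %in% c("0", placed))
    if (!any(ready)) stop("pedigree contains a cycle")
    placed <- c(placed, remaining$id[ready])
    remaining <- remaining[!ready, , drop = FALSE]
  }
  placed
}

#' Simulate a pedigree cohort with planted CNV alleles
#'
#' Founder haplotypes are drawn from the locus allele frequencies of the
#' founder's population; every offspring inherits one haplotype chosen at
#' random from each parent, so Mendelian transmission holds by
#' construction. Total copy number at a probe inside a locus is the sum
#' of the two haplotype copy counts; elsewhere it is 2.
#'
#' @param map A [snp_map()].
#' @param loci List of [cnv_locus()] objects; must not overlap one
#'   another and must lie within the map span of their chromosome.
#' @param pedigree Pedigree data.frame (see [pedigree_spec()]).
#' @param noise A [noise_model()]; its seed drives all draws.
#' @param render If TRUE (default) also render LRR/BAF signals.
#' @return A list of class `cnv_cohort` with elements map, pedigree,
#'   loci, truth (data.frame: locus_id, sample_id, hap1, hap2, total_cn),
#'   signals (named list of signal tracks, if rendered), noise.
#' @export
simulate_cohort <- function(map, loci, pedigree, noise = noise_model(),
                            render = TRUE) {
  stopifnot(inherits(map, "snp_map"))
  loci <- check_loci(map, loci)
  order_ids <- validate_pedigree(pedigree)
  ped <- pedigree[match(order_ids, pedigree$id), , drop = FALSE]
  set.seed(noise$seed)
  truth <- list()
  for (li in seq_along(loci)) {
    loc <- loci[[li]]
    h <- matrix(1L, nrow(ped), 2, dimnames = list(ped$id, NULL))
    for (i in seq_len(nrow(ped))) {
      if (ped$sire[i] == "0") {
        f <- locus_freq(loc, ped$population[i])
        a <- as.integer(names(f))
        h[i, ] <- sample(a, 2, replace = TRUE, prob = f)
      } else {
        h[i, 1] <- h[ped$sire[i], sample.int(2, 1)]
        h[i, 2] <- h[ped$dam[i], sample.int(2, 1)]
      }
    }
    truth[[li]] <- data.frame(locus_id = loc$id, sample_id = ped$id,
                              hap1 = h[, 1], hap2 = h[, 2],
                              total_cn = h[, 1] + h[, 2],
                              stringsAsFactors = FALSE)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(locus_id = character(0), sample_id = character(0),
               hap1 = integer(0), hap2 = integer(0), total_cn = integer(0))
  rownames(truth) <- NULL
  cohort <- structure(list(map = map, pedigree = ped, loci = loci,
                           truth = truth, signals = NULL, noise = noise),
                      class = "cnv_cohort")
  if (render) cohort <- render_signals(cohort, noise)
  cohort
}

check_loci <- function(map, loci) {
  if (length(loci) == 0) return(loci)
  for (i in seq_along(loci)) {
    loc <- loci[[i]]
    stopifnot(inherits(loc, "cnv_locus"))
    if (is.null(loc$id)) loci[[i]]$id <- loc$id <- sprintf("locus%02d", i)
    p <- map$pos[map$chrom == loc$chrom]
    if (length(p) == 0 || loc$start < min(p) || loc$end > max(p)) {
      stop("locus ", loc$id, " lies outside the SNP map span of chromosome ",
           loc$chrom)
    }
  }
  for (i in seq_along(loci)) for (j in seq_len(i - 1L)) {
    a <- loci[[i]]; b <- loci[[j]]
    if (a$chrom == b$chrom && max(a$start, b$start) < min(a$end, b$end)) {
      stop("loci overlap: ", a$id, " and ", b$id)
    }
  }
  loci
}

# Per-probe total copy number of one individual given the locus truth.
sample_cn_vector <- function(cohort, sample_id) {
  map <- cohort$map
  cn <- rep(2L, nrow(map))
  tr <- cohort$truth[cohort$truth$sample_id == sample_id, , drop = FALSE]
  for (k in seq_len(nrow(tr))) {
    loc <- cohort$loci[[match(tr$locus_id[k],
                              vapply(cohort$loci, `[[`, "", "id"))]]
    idx <- probes_in_interval(map, loc$chrom, loc$start, loc$end)
    cn[idx] <- tr$total_cn[k]
  }
  cn
}

#' Render LRR/BAF signal tracks for a simulated cohort
#'
#' At each probe the expected LRR is the state mean for the individual's
#' total copy number (capped at 4); BAF is drawn from the
#' genotype-cluster mixture for that copy number (uniform for CN0).
#' Gaussian noise is added per the noise model, with an optional
#' heavy-tailed contamination fraction; BAF is clipped to [0, 1].
#'
#' @param cohort A `cnv_cohort` with truth populated.
#' @param noise A [noise_model()]; defaults to the cohort's own. Signal
#'   rendering uses seed + 1 so that simulation and rendering draws are
#'   decoupled but jointly deterministic.
#' @return The cohort with `$signals` filled (one track per individual).
#' @export
render_signals <- function(cohort, noise = cohort$noise) {
  stopifnot(inherits(cohort, "cnv_cohort"))
  means <- lrr_state_means()
  set.seed((noise$seed + 1L) %% .Machine$integer.max)
  n <- nrow(cohort$map)
  signals <- list()
  for (id in cohort$pedigree$id) {
    cn <- pmin(sample_cn_vector(cohort, id), 4L)
    lrr <- means[as.character(cn)]
    if (noise$lrr_sd > 0) {
      sd_vec <- rep(noise$lrr_sd, n)
      if (noise$outlier_rate > 0) {
        out <- stats::runif(n) < noise$outlier_rate
        sd_vec[out] <- 5 * noise$lrr_sd
      }
      lrr <- lrr + stats::rnorm(n, 0, sd_vec)
    }
    b <- numeric(n)
    pos_cn <- cn > 0L
    b[!pos_cn] <- stats::runif(sum(!pos_cn))
    if (any(pos_cn)) {
      k <- stats::rbinom(sum(pos_cn), cn[pos_cn], 0.5)
      b[pos_cn] <- k / cn[pos_cn]
    }
    if (noise$baf_sd > 0) b <- b + stats::rnorm(n, 0, noise$baf_sd)
    b <- pmin(pmax(b, 0), 1)
    signals[[id]] <- signal_track(id, unname(lrr), b)
  }
  cohort$signals <- signals
  cohort
}

#' Construct a signal track
#'
#' @param sample_id Sample name.
#' @param lrr,baf Numeric vectors, one value per map probe; NA marks a
#'   missing measurement. BAF must lie in [0, 1].
#' @return A list of class `signal_track`.
#' @export
signal_track <- function(sample_id, lrr, baf) {
  stopifnot(length(lrr) == length(baf))
  if (any(baf < 0 | baf > 1, na.rm = TRUE)) stop("BAF outside [0,1]")
  structure(list(sample_id = as.character(sample_id),
                 lrr = as.numeric(lrr), baf = as.numeric(baf)),
            class = "signal_track")
}

#' Total copy number per (locus, sample) from simulation truth
#'
#' The truth-derived analogue of a CNVR carrier table, for segregation
#' checking: one row per locus and individual with the true total copy
#' number, the population label, and the locus kind.
#'
#' @param cohort A `cnv_cohort`.
#' @return data.frame with columns cnvr_id, sample_id, cn, population,
#'   kind.
#' @export
truth_carrier_table <- function(cohort) {
  tr <- cohort$truth
  kinds <- vapply(cohort$loci, locus_kind, "")
  names(kinds) <- vapply(cohort$loci, `[[`, "", "id")
  data.frame(cnvr_id = tr$locus_id, sample_id = tr$sample_id,
             cn = pmin(tr$total_cn, 4L),  # totals above 4 reported as "4"
             population = cohort$pedigree$population[
               match(tr$sample_id, cohort$pedigree$id)],
             kind = unname(kinds[tr$locus_id]), stringsAsFactors = FALSE)
}
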