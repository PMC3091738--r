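# Fixture builders shared across test files. All fixtures are generated
# in code under fixed seeds.

# Evenly spaced single-chromosome map (deterministic positions).
toy_map <- function(n = 100, chrom = "1", spacing = 40000L) {
  snp_map(sprintf("p%04d", seq_len(n)), rep(chrom, n),
          spacing * seq_len(n))
}

# Track rendered from a copy-number vector under the package's cluster
# model (the same construction as the simulator, but standalone so
# caller tests do not depend on the cohort machinery).
render_track <- function(cn, lrr_sd = 0, baf_sd = 0, sample_id = "s1",
                         seed = 1L) {
  set.seed(seed)
  means <- lrr_state_means()
  n <- length(cn)
  lrr <- unname(means[as.character(pmin(cn, 4L))]) + rnorm(n, 0, lrr_sd)
  baf <- numeric(n)
  pos <- cn > 0L
  baf[!pos] <- runif(sum(!pos))
  if (any(pos)) baf[pos] <- rbinom(sum(pos), cn[pos], 0.5) / cn[pos]
  if (baf_sd > 0) baf <- pmin(pmax(baf + rnorm(n, 0, baf_sd), 0), 1)
  signal_track(sample_id, lrr, baf)
}

# A small three-locus cohort used by several suites; locus footprints
# scale with the map so reduced probe counts stay valid.
toy_cohort <- function(seed = 7L, lrr_sd = 0.2, n_probes = c(200L, 200L)) {
  map <- simulate_snp_map(n_probes, c("1", "2"), seed = 3)
  n1 <- n_probes[1]; n2 <- n_probes[2]
  at <- function(chr_off, frac) chr_off + as.integer(round(frac * n1))
  loci <- list(
    cnv_locus("1", map$pos[at(0L, 0.15)], map$pos[at(0L, 0.22)],
              alleles = 0:1, freq = c(`0` = 0.35, `1` = 0.65), id = "del1"),
    cnv_locus("1", map$pos[at(0L, 0.50)], map$pos[at(0L, 0.65)],
              alleles = 1:2, freq = c(`1` = 0.6, `2` = 0.4), id = "dup1"),
    cnv_locus("2", map$pos[n1 + as.integer(round(0.25 * n2))],
              map$pos[n1 + as.integer(round(0.31 * n2)) + 1L],
              alleles = 0:1, freq = c(`0` = 0.3, `1` = 0.7), id = "del2"))
  simulate_cohort(map, loci, ibmap_pedigree(3, 12, 10, 2, 5),
                  noise_model(lrr_sd = lrr_sd, baf_sd = 0.03, seed = seed))
}

# One row of a raw call table.
call_row <- function(sample_id, chrom, start, end, n_snps, state, caller,
                     score = 10) {
  data.frame(sample_id = sample_id, chrom = chrom, start = as.integer(start),
             end = as.integer(end), n_snps = as.integer(n_snps),
             state = as.integer(state),
             direction = if (state < 2) "loss" else "gain",
             caller = caller, score = score, stringsAsFactors = FALSE)
}
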