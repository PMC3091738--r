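test_that("snp_map enforces ordering, uniqueness and autosomes", {
  expect_s3_class(toy_map(10), "snp_map")
  expect_error(snp_map(c("a", "a"), c("1", "1"), c(1, 2)), "unique")
  expect_error(snp_map(c("a", "b"), c("1", "1"), c(5, 5)), "increasing")
  expect_error(snp_map(c("a", "b"), c("1", "X"), c(1, 2)), "sex chromosome")
  # per-chromosome ordering: positions may restart between chromosomes
  m <- snp_map(c("a", "b", "c"), c("1", "1", "2"), c(10, 20, 5))
  expect_equal(nrow(m), 3)
})

test_that("simulated maps have the requested density", {
  m <- simulate_snp_map(c(2000), "1", spacing_mean = 39610, seed = 4)
  gaps <- diff(m$pos)
  # exponential spacing: mean recovers the chip's average inter-SNP gap
  expect_lt(abs(mean(gaps) - 39610) / 39610, 0.1)
})

test_that("a cohort without variant loci is diploid everywhere", {
  map <- toy_map(50)
  ped <- ibmap_pedigree(2, 3, 2, 0, 0)
  coh <- simulate_cohort(map, list(), ped,
                         noise_model(lrr_sd = 0, baf_sd = 0, seed = 1))
  expect_equal(nrow(coh$truth), 0)
  for (tr in coh$signals) {
    expect_true(all(tr$lrr == 0))
    expect_true(all(tr$baf %in% c(0, 0.5, 1)))
  }
})

test_that("a fixed deletion allele makes its founder population CN 0", {
  map <- toy_map(60)
  loc <- cnv_locus("1", map$pos[20], map$pos[30], alleles = 0:1,
                   freq = list(Iberian = c(`0` = 1, `1` = 0),
                               Landrace = c(`0` = 0, `1` = 1)))
  ped <- ibmap_pedigree(2, 3, 0, 0, 0)
  coh <- simulate_cohort(map, list(loc), ped,
                         noise_model(lrr_sd = 0, baf_sd = 0, seed = 2))
  tr <- coh$truth
  ib <- coh$pedigree$id[coh$pedigree$population == "Iberian"]
  ld <- coh$pedigree$id[coh$pedigree$population == "Landrace"]
  expect_true(all(tr$total_cn[tr$sample_id %in% ib] == 0))
  expect_true(all(tr$hap1[tr$sample_id %in% ib] == 0))
  expect_true(all(tr$total_cn[tr$sample_id %in% ld] == 2))
})

test_that("founder allele frequencies are recovered within binomial error", {
  map <- toy_map(30)
  loc <- cnv_locus("1", map$pos[10], map$pos[20], alleles = 0:1,
                   freq = c(`0` = 0.5, `1` = 0.5))
  founders <- data.frame(id = sprintf("f%04d", 1:1000),
                         sex = rep(1:2, 500), population = "P")
  ped <- pedigree_spec(founders, data.frame(sire = character(0),
                                            dam = character(0),
                                            n_offspring = integer(0),
                                            generation = character(0)))
  coh <- simulate_cohort(map, list(loc), ped,
                         noise_model(seed = 11), render = FALSE)
  # 2000 founder haplotypes at frequency 0.5
  hap_frac <- mean(c(coh$truth$hap1, coh$truth$hap2) == 0)
  se <- sqrt(0.5 * 0.5 / 2000)
  expect_lt(abs(hap_frac - 0.5), 3 * se)
})

test_that("Mendelian transmission holds for every trio and locus", {
  coh <- toy_cohort(seed = 13)
  tr <- coh$truth
  ped <- coh$pedigree
  for (i in which(ped$sire != "0")) {
    for (loc in unique(tr$locus_id)) {
      o <- tr[tr$sample_id == ped$id[i] & tr$locus_id == loc, ]
      s <- tr[tr$sample_id == ped$sire[i] & tr$locus_id == loc, ]
      d <- tr[tr$sample_id == ped$dam[i] & tr$locus_id == loc, ]
      expect_true(o$hap1 %in% c(s$hap1, s$hap2))
      expect_true(o$hap2 %in% c(d$hap1, d$hap2))
    }
  }
})

test_that("simulation is deterministic given the seed", {
  c1 <- toy_cohort(seed = 21)
  c2 <- toy_cohort(seed = 21)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$signals, c2$signals)
  c3 <- toy_cohort(seed = 22)
  expect_false(identical(c1$signals, c3$signals))
})

test_that("rendered signal statistics follow the noise model", {
  map <- toy_map(10000)
  ped <- data.frame(family = "F", id = "solo", sire = "0", dam = "0",
                    sex = 1, population = "P", generation = "founder")
  coh <- simulate_cohort(map, list(), ped,
                         noise_model(lrr_sd = 0.2, baf_sd = 0, seed = 5))
  # moment recovery on 10,000 diploid probes
  expect_lt(abs(sd(coh$signals$solo$lrr) - 0.2) / 0.2, 0.05)
})

test_that("hemizygous segments have no heterozygous BAF cluster", {
  map <- toy_map(100)
  ped <- data.frame(family = "F", id = sprintf("s%02d", 1:8), sire = "0",
                    dam = "0", sex = rep(1:2, 4), population = "P",
                    generation = "founder")
  loc1 <- cnv_locus("1", map$pos[40], map$pos[60], alleles = 0:1,
                    freq = c(`0` = 0.5, `1` = 0.5))
  coh <- simulate_cohort(map, list(loc1), ped,
                         noise_model(lrr_sd = 0, baf_sd = 0, seed = 8))
  cn1 <- coh$truth$sample_id[coh$truth$total_cn == 1]
  expect_gt(length(cn1), 0)  # 8 founders at het frequency 1/2
  idx <- 40:60
  tr <- coh$signals[[cn1[1]]]
  expect_true(all(tr$baf[idx] %in% c(0, 1)))
  expect_true(all(tr$lrr[idx] == lrr_state_means()[["1"]]))
})

test_that("overlapping or out-of-span loci are rejected", {
  map <- toy_map(50)
  a <- cnv_locus("1", map$pos[10], map$pos[20], 0:1, c(`0` = .5, `1` = .5))
  b <- cnv_locus("1", map$pos[15], map$pos[25], 0:1, c(`0` = .5, `1` = .5))
  ped <- ibmap_pedigree(1, 1, 0, 0, 0)
  expect_error(simulate_cohort(map, list(a, b), ped), "overlap")
  far <- cnv_locus("1", map$pos[50] + 1000, map$pos[50] + 2000, 0:1,
                   c(`0` = .5, `1` = .5))
  expect_error(simulate_cohort(map, list(far), ped), "outside")
  expect_error(cnv_locus("1", 100, 200, c(0L, 2L), c(`0` = .5, `2` = .5)),
               "normal allele")
})

test_that("pedigree validation rejects cycles and half-known parents", {
  ped <- data.frame(family = "F", id = c("a", "b"), sire = c("b", "a"),
                    dam = c("b", "a"), sex = 1, population = "P",
                    generation = "g")
  expect_error(snpcnvr:::validate_pedigree(ped), "cycle")
  ped2 <- data.frame(family = "F", id = c("a", "b"), sire = c("0", "a"),
                     dam = c("0", "0"), sex = 1, population = "P",
                     generation = "g")
  expect_error(snpcnvr:::validate_pedigree(ped2), "one known parent")
})

test_that("final report and pedigree round-trip through files", {
  coh <- toy_cohort(seed = 31, n_probes = c(40L, 40L))
  coh$signals <- coh$signals[1:3]
  f <- withr::local_tempfile(fileext = ".txt")
  p <- withr::local_tempfile(fileext = ".ped")
  write_final_report(coh, f)
  write_pedigree(coh, p)
  back <- read_final_report(f)
  expect_equal(as.data.frame(back$map), as.data.frame(coh$map))
  for (id in names(coh$signals)) {
    # values are printed with 4 decimals: absolute error <= 5e-5
    expect_lt(max(abs(back$signals[[id]]$lrr - coh$signals[[id]]$lrr)),
              5.01e-5)
    expect_lt(max(abs(back$signals[[id]]$baf - coh$signals[[id]]$baf)),
              5.01e-5)
  }
  ped <- read_pedigree(p)
  expect_equal(ped[, c("id", "sire", "dam")],
               coh$pedigree[, c("id", "sire", "dam")],
               ignore_attr = TRUE)
})

test_that("a sample missing one signal column is reported by name", {
  coh <- toy_cohort(seed = 32, n_probes = c(30L, 30L))
  coh$signals <- coh$signals[1:2]
  f <- withr::local_tempfile(fileext = ".txt")
  write_final_report(coh, f)
  df <- read.delim(f, check.names = FALSE)
  broken <- names(coh$signals)[2]
  df[[paste0(broken, ".B Allele Freq")]] <- NULL
  f2 <- withr::local_tempfile(fileext = ".txt")
  write.table(df, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_final_report(f2), broken)
})

test_that("the signal table has one row per probe", {
  map <- simulate_snp_map(5000L, "1", seed = 9)
  founders <- data.frame(id = sprintf("s%02d", 1:55), sex = rep(1:2, len = 55),
                         population = "P")
  ped <- pedigree_spec(founders, data.frame(sire = character(0),
                                            dam = character(0),
                                            n_offspring = integer(0),
                                            generation = character(0)))
  coh <- simulate_cohort(map, list(), ped,
                         noise_model(lrr_sd = 0.1, baf_sd = 0.03, seed = 3))
  f <- withr::local_tempfile(fileext = ".txt")
  write_final_report(coh, f)
  n_lines <- length(readLines(f))
  expect_equal(n_lines - 1L, 5000L)  # header + one row per probe
})
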