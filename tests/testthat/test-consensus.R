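# dense little map: probes every 10 bp from 10 to 1000
dense_map <- function() snp_map(sprintf("p%03d", 1:100), rep("1", 100),
                                10L * (1:100))

test_that("calls from a single caller never reach consensus", {
  map <- dense_map()
  calls <- call_row("a", "1", 100L, 200L, 11, 1, "hmm")
  expect_equal(nrow(per_sample_consensus(calls, map)), 0)
})

test_that("the consensus interval is the intersection of supporters", {
  map <- dense_map()
  calls <- rbind(call_row("a", "1", 100L, 200L, 11, 1, "hmm"),
                 call_row("a", "1", 150L, 300L, 16, 1, "sbl"))
  cons <- per_sample_consensus(calls, map)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$start, 150L)
  expect_equal(cons$end, 200L)
  expect_equal(cons$supporters, "hmm,sbl")
  expect_equal(cons$direction, "loss")
})

test_that("opposite directions do not corroborate each other", {
  map <- dense_map()
  for (st in list(c(1L, 3L), c(0L, 4L), c(3L, 1L))) {
    calls <- rbind(call_row("a", "1", 100L, 200L, 11, st[1], "hmm"),
                   call_row("a", "1", 150L, 300L, 16, st[2], "sbl"))
    expect_equal(nrow(per_sample_consensus(calls, map)), 0)
  }
  # same direction, different states still corroborate
  calls <- rbind(call_row("a", "1", 100L, 200L, 11, 0L, "hmm"),
                 call_row("a", "1", 150L, 300L, 16, 1L, "sbl"))
  expect_equal(nrow(per_sample_consensus(calls, map)), 1)
})

test_that("intersections below three map SNPs are discarded", {
  map <- snp_map(c("a", "b", "c", "d"), rep("1", 4),
                 c(100L, 180L, 400L, 500L))
  # intersection [150, 200] holds only one probe of this sparse map
  calls <- rbind(call_row("s", "1", 100L, 200L, 2, 1, "hmm"),
                 call_row("s", "1", 150L, 300L, 2, 1, "sbl"))
  expect_equal(nrow(per_sample_consensus(calls, map)), 0)
})

test_that("a triple overlap yields one maximal consensus, not three pairs", {
  map <- dense_map()
  calls <- rbind(call_row("a", "1", 100L, 300L, 21, 1, "hmm"),
                 call_row("a", "1", 150L, 350L, 21, 1, "sbl"),
                 call_row("a", "1", 120L, 320L, 21, 1, "partition"))
  cons <- per_sample_consensus(calls, map)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$start, 150L)
  expect_equal(cons$end, 300L)
  expect_equal(cons$n_callers, 3L)
})

test_that("CNVR spans are unions over carriers and require two animals", {
  map <- dense_map()
  calls_one <- rbind(call_row("a", "1", 100L, 200L, 11, 1, "hmm"),
                     call_row("a", "1", 100L, 200L, 11, 1, "sbl"))
  cons_one <- per_sample_consensus(calls_one, map)
  expect_equal(nrow(build_cnvrs(cons_one, map)), 0)  # one carrier only

  calls_two <- rbind(calls_one,
                     call_row("b", "1", 150L, 250L, 11, 1, "hmm"),
                     call_row("b", "1", 150L, 250L, 11, 1, "partition"))
  cnvrs <- build_cnvrs(per_sample_consensus(calls_two, map), map)
  expect_equal(nrow(cnvrs), 1)
  expect_equal(cnvrs$start, 100L)
  expect_equal(cnvrs$end, 250L)
  expect_equal(cnvrs$status, "Loss")
  expect_equal(cnvrs$n_carriers, 2L)
  expect_equal(cnvrs$carriers[[1]], c("a", "b"))
})

test_that("mixed carrier directions give Loss-Gain status", {
  map <- dense_map()
  calls <- rbind(call_row("a", "1", 100L, 200L, 11, 1, "hmm"),
                 call_row("a", "1", 100L, 200L, 11, 1, "sbl"),
                 call_row("b", "1", 150L, 250L, 11, 3, "hmm"),
                 call_row("b", "1", 150L, 250L, 11, 3, "partition"))
  cnvrs <- build_cnvrs(per_sample_consensus(calls, map), map)
  expect_equal(cnvrs$status, "Loss-Gain")
})

test_that("every emitted CNVR satisfies the three filters", {
  coh <- toy_cohort(seed = 51)
  calls <- rbind(call_cohort(coh, "hmm"), call_cohort(coh, "sbl"),
                 call_cohort(coh, "partition"))
  cons <- per_sample_consensus(calls, coh$map)
  expect_true(all(cons$n_callers >= 2))
  expect_true(all(cons$n_snps >= 3))
  cnvrs <- build_cnvrs(cons, coh$map)
  expect_true(all(cnvrs$n_carriers >= 2))
  expect_true(all(cnvrs$n_snps >= 3))
  expect_true(all(vapply(cnvrs$supporters, length, 0L) >= 2))
  expect_true(all(cnvrs$length_kb > 0))
})

test_that("consensus construction is invariant to input order", {
  coh <- toy_cohort(seed = 52)
  calls <- rbind(call_cohort(coh, "hmm"), call_cohort(coh, "sbl"),
                 call_cohort(coh, "partition"))
  cnvrs1 <- build_cnvrs(per_sample_consensus(calls, coh$map), coh$map)
  set.seed(99)
  shuffled <- calls[sample(nrow(calls)), ]
  cnvrs2 <- build_cnvrs(per_sample_consensus(shuffled, coh$map), coh$map)
  expect_equal(as.data.frame(cnvrs1), as.data.frame(cnvrs2))
})

test_that("clustering matches the transitive-closure oracle", {
  map <- toy_map(300)
  for (s in 1:5) {
    set.seed(s)
    n <- sample(20:50, 1)
    start <- sample(map$pos, n, replace = TRUE)
    width <- sample(3:30, n, replace = TRUE) * 40000L
    cons <- data.frame(sample_id = sample(letters[1:8], n, replace = TRUE),
                       chrom = "1", start = start, end = start + width,
                       n_snps = 5L, direction = "loss", supporters = "hmm,sbl",
                       n_callers = 2L, stringsAsFactors = FALSE)
    got <- build_cnvrs(cons, map)
    oracle <- cnvr_oracle(cons, map)
    expect_equal(got$start, oracle$start)
    expect_equal(got$end, oracle$end)
    expect_equal(got$n_carriers, oracle$n_carriers)
  }
})

test_that("summaries report lengths, chromosomes and status shares", {
  one <- data.frame(cnvr_id = 1L, chrom = "1", start = 100L, end = 100100L,
                    length_kb = 100, status = "Gain", n_snps = 5L,
                    n_carriers = 3L)
  s <- summarize_cnvrs(one)
  expect_equal(s$length_min_kb, 100)
  expect_equal(s$length_max_kb, 100)
  expect_equal(s$length_mean_kb, 100)
  expect_equal(s$length_median_kb, 100)
  expect_equal(unname(s$status_pct[["Gain"]]), 100)
  empty <- summarize_cnvrs(one[0, ])
  expect_equal(empty$n_cnvrs, 0L)
  expect_equal(sum(empty$status_counts), 0L)
})

test_that("caller agreement handles identical and absent call sets", {
  map <- dense_map()
  base <- rbind(call_row("a", "1", 100L, 200L, 11, 1, "hmm"),
                call_row("b", "1", 120L, 220L, 11, 1, "hmm"))
  calls <- rbind(base,
                 transform(base, caller = "sbl"),
                 transform(base, caller = "partition"))
  cnvrs <- build_cnvrs(per_sample_consensus(calls, map), map)
  ag <- caller_agreement(calls, cnvrs)
  expect_true(all(ag$per_caller$rate_pct == 100))
  expect_equal(ag$three_way$pct, 100)
  ag2 <- caller_agreement(calls[calls$caller != "sbl", ], cnvrs)
  expect_true(is.na(ag2$per_caller$rate_pct[ag2$per_caller$caller == "sbl"]))
})

test_that("gene overlap follows the shared-basepair rule", {
  cnvrs <- data.frame(cnvr_id = 1:3, chrom = c("1", "1", "2"),
                      start = c(100L, 500L, 100L),
                      end = c(200L, 700L, 300L),
                      length_kb = c(0.1, 0.2, 0.2),
                      status = "Loss", n_snps = 5L, n_carriers = 2L)
  genes <- data.frame(chrom = c("1", "1", "1", "2", "2"),
                      start = c(150L, 200L, 690L, 90L, 299L),
                      end = c(180L, 250L, 800L, 120L, 350L),
                      id = paste0("g", 1:5),
                      biotype = c("protein_coding", "protein_coding",
                                  "miRNA", "protein_coding", "rRNA"))
  ann <- annotate_genes(cnvrs, genes)
  # hand enumeration: g1 inside cnvr1; g2 abuts cnvr1 (no shared bp);
  # g3 overlaps cnvr2; g4 overlaps cnvr3; g5 touches the last covered
  # base of cnvr3 (299 < 300), so it is assigned
  expect_setequal(
    paste(ann$assignments$cnvr_id, ann$assignments$gene_id),
    c("1 g1", "2 g3", "3 g4", "3 g5"))
  expect_equal(ann$biotype_counts[["protein_coding"]], 2L)
  expect_equal(length(ann$empty_cnvrs), 0L)

  bad <- genes; bad$chrom <- paste0("chr", bad$chrom)
  expect_error(annotate_genes(cnvrs, bad), "no shared chromosome")
})
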