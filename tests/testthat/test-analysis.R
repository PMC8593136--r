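test_that("adapter trimming removes the ligated adapter and filters lengths", {
  adapter_rna <- "CUGUAGGCACCAUCAAU"
  insert28 <- paste(rep("ACGU", 7), collapse = "")
  expect_equal(trim_and_filter(paste0(insert28, adapter_rna)), insert28)
  # 14-nt insert: trimmed then discarded by the 15-nt floor
  insert14 <- substr(insert28, 1, 14)
  expect_length(trim_and_filter(paste0(insert14, adapter_rna)), 0)
  # 36-nt insert: discarded by the 35-nt ceiling
  insert36 <- paste(rep("ACGU", 9), collapse = "")
  expect_length(trim_and_filter(paste0(insert36, adapter_rna)), 0)
  # partial adapter at the read end is recognized
  partial <- paste0(insert28, substr("CTGTAGGCACCATCAAT", 1, 7))
  expect_equal(trim_and_filter(partial), insert28)
  # untrimmable reads pass through to the length filter
  expect_equal(trim_and_filter(insert28), insert28)
  expect_error(trim_and_filter("ACGU", adapter = ""), "non-empty")
})

test_that("trimming is idempotent for arbitrary reads", {
  set.seed(71)
  ad <- "CTGTAGGCACCATCAAT"
  reads <- vapply(1:300, function(i) {
    insert <- paste(sample(c("A", "C", "G", "T"), sample(15:35, 1),
                           replace = TRUE), collapse = "")
    paste0(insert, substr(ad, 1, sample(0:17, 1)))
  }, character(1))
  once <- trim_and_filter(reads, min_len = 1, max_len = 100)
  twice <- trim_and_filter(once, min_len = 1, max_len = 100)
  expect_identical(twice, once)
})

test_that("read regions partition with the documented precedence", {
  tx <- ref_transcript()
  reads <- data.frame(
    transcript_id = "ref600",
    start = c(0L, 188L, 50L, 1L, 300L, 550L, 195L),
    end = c(40L, 217L, 79L, 30L, 330L, 580L, 203L))
  reg <- classify_read_region(reads, tx)
  expect_equal(as.character(reg),
               c("TSS", "start_codon", "UTR5", "TSS", "CDS", "UTR3",
                 "start_codon"))
  # conservation over a random library
  ann <- small_annotation(n = 20)
  lib <- snapshot_library(ann, scan_config(), 5000, "eif3", seed = 3)
  ld <- length_distribution_by_region(lib, ann)
  expect_equal(sum(vapply(ld, `[[`, integer(1), "n")), nrow(lib))
  expect_error(classify_read_region(
    data.frame(transcript_id = "ref600", start = 590L, end = 610L), tx),
    "outside")
})

test_that("length distributions report per-region counts with low tie-breaking", {
  tx <- ref_transcript()
  one <- data.frame(transcript_id = "ref600", start = 300L, end = 329L)
  ld <- length_distribution_by_region(one, tx)
  expect_equal(ld$CDS$n, 1L)
  expect_equal(ld$CDS$mode, 29L)
  expect_equal(ld$TSS$n, 0L)
  # ties break toward the smaller length
  ties <- data.frame(transcript_id = "ref600",
                     start = c(300L, 310L, 320L, 330L),
                     end = c(329L, 339L, 350L, 360L))
  ld2 <- length_distribution_by_region(ties, tx)  # lengths 29,29,30,30
  expect_equal(ld2$CDS$mode, 29L)
  expect_equal(ld2$CDS$median, 29L)
  empty <- length_distribution_by_region(one[0, ], tx)
  expect_true(all(vapply(empty, `[[`, integer(1), "n") == 0L))
})

test_that("TSS footprints run longer than 5'UTR footprints in a wt library", {
  ann <- small_annotation()
  lib <- snapshot_library(ann, scan_config(), 5e4, "eif3", seed = 4)
  ld <- length_distribution_by_region(lib, ann)
  expect_gt(ld$TSS$median, ld$UTR5$median)
  reg <- classify_read_region(lib, ann)
  len <- lib$end - lib$start
  cmp <- compare_distributions(len[reg == "TSS"], len[reg == "UTR5"])
  expect_equal(cmp$direction, "a>b")
  expect_lt(cmp$p_value, 0.01)
})

test_that("aggregation profiles implement the per-transcript normalization", {
  tx <- ref_transcript()
  one <- data.frame(transcript_id = "ref600", start = 0L, end = 40L)
  prof <- end_aggregation_profile(one, tx, "TSS", "five_prime", c(0L, 100L))
  expect_equal(unname(prof$values[["0"]]), 600)
  expect_true(all(prof$values[-1] == 0))
  # with one read per transcript at a fixed relative position, the profile
  # value equals the mean transcript length there and zero elsewhere
  ann <- small_annotation(n = 15)
  reads <- do.call(rbind, lapply(ann$transcripts, function(t)
    data.frame(transcript_id = t$id, start = 5L, end = 35L)))
  p <- end_aggregation_profile(reads, ann, "TSS", "five_prime", c(0L, 50L))
  lens <- vapply(ann$transcripts, `[[`, integer(1), "length")
  expect_equal(unname(p$values[["5"]]), mean(lens))
  expect_true(all(p$values[setdiff(names(p$values), "5")] == 0))
  expect_equal(p$n_transcripts, 15L)
  expect_error(end_aggregation_profile(one, tx, window = c(10L, 5L)), "lo < hi")
  expect_error(end_aggregation_profile(one[0, ], tx), "no transcript")
})

test_that("three-prime ends anchor at the last protected nucleotide", {
  tx <- ref_transcript()
  one <- data.frame(transcript_id = "ref600", start = 150L, end = 200L)
  p3 <- end_aggregation_profile(one, tx, "start_codon", "three_prime",
                                c(-10L, 10L))
  expect_equal(unname(p3$values[["-1"]]), 600)
})

test_that("RPKM follows its definition and the < 1 exclusion rule", {
  # 1000 CDS reads on a 1-kb CDS among 10^6 mapped reads -> RPKM 1000
  tx <- transcript("t", 1400L, 200L, 1200L)
  mito <- transcript("mt_t", 500L, 100L, 400L, is_mito = TRUE)
  ann <- transcriptome(list(tx, mito))
  reads <- rbind(
    data.frame(transcript_id = "t", start = 500L, end = 530L)[rep(1, 1000), ],
    data.frame(transcript_id = "t", start = 10L, end = 40L)[rep(1, 999000), ],
    data.frame(transcript_id = "mt_t", start = 10L, end = 40L)[rep(1, 50), ])
  occ <- mito_normalized_density(reads, ann)
  expect_equal(occ$rpkm[occ$transcript_id == "t"], 1000)
  expect_true(occ$included[occ$transcript_id == "t"])
  # scale invariance: doubling every count leaves RPKM unchanged
  occ2 <- mito_normalized_density(reads[rep(seq_len(nrow(reads)), 2), ], ann,
                                  reference_mito_count = 50)
  expect_equal(occ2$rpkm, occ$rpkm)
  # boundary behavior: one CDS read in 10^6 mapped is RPKM 1 on a 1-kb CDS
  # (kept by the "< 1 excluded" rule) and RPKM 0.5 on a 2-kb CDS (excluded)
  tx2 <- transcript("t2", 2600L, 200L, 2200L)
  ann2 <- transcriptome(list(tx, tx2, mito))
  few <- rbind(
    data.frame(transcript_id = "t", start = 500L, end = 530L),
    data.frame(transcript_id = "t2", start = 500L, end = 530L),
    data.frame(transcript_id = "t", start = 10L, end = 40L)[rep(1, 999998), ],
    data.frame(transcript_id = "mt_t", start = 10L, end = 40L))
  occ3 <- mito_normalized_density(few, ann2)
  expect_equal(occ3$rpkm[occ3$transcript_id == "t"], 1)
  expect_true(occ3$included[occ3$transcript_id == "t"])
  expect_equal(occ3$rpkm[occ3$transcript_id == "t2"], 0.5)
  expect_false(occ3$included[occ3$transcript_id == "t2"])
  expect_error(mito_normalized_density(reads[reads$transcript_id == "t", ],
                                       ann, reference_mito_count = 50),
               "mito")
})

test_that("5'UTR/CDS occupancy ratios follow densities and flag zero controls", {
  tx <- transcript("t", 1400L, 200L, 1200L)
  ann <- transcriptome(list(tx))
  reads <- rbind(
    data.frame(transcript_id = "t", start = 50L, end = 80L)[rep(1, 10), ],
    data.frame(transcript_id = "t", start = 600L, end = 630L)[rep(1, 100), ])
  occ <- utr5_cds_occupancy(reads, ann)
  expect_equal(occ$utr5_cds_ratio, (10 / 200) / (100 / 1000))
  only_utr <- data.frame(transcript_id = "t", start = 50L, end = 80L)
  occ2 <- utr5_cds_occupancy(only_utr, ann)
  expect_true(is.na(occ2$utr5_cds_ratio))
  expect_false(occ2$defined)
})

test_that("pateamine raises the median 5'UTR/CDS occupancy ratio", {
  ann <- generate_transcriptome(150, seed = 21, decoy_aug_rate = 0.02)
  wt <- scan_config(); pa <- apply_preset(wt, "pata")
  rw <- snapshot_library(ann, wt, 3e4, "ribo80s", seed = 9)
  rp <- snapshot_library(ann, pa, 3e4, "ribo80s", seed = 9)
  mw <- stats::median(utr5_cds_occupancy(rw, ann)$utr5_cds_ratio, na.rm = TRUE)
  mp <- stats::median(utr5_cds_occupancy(rp, ann)$utr5_cds_ratio, na.rm = TRUE)
  expect_gt(mp, mw)
})

test_that("80S subtraction removes matched counts and honors its edge cases", {
  ann <- small_annotation(n = 15)
  cfg <- scan_config()
  eif3 <- snapshot_library(ann, cfg, 2e4, "eif3", seed = 31)
  r80 <- snapshot_library(ann, cfg, 5e4, "ribo80s", seed = 32)
  # self-subtraction at scale 1 leaves nothing
  self <- subtract_80s(eif3, eif3, ann, scale = 1)
  expect_equal(nrow(self), 0L)
  # scale 0 is the identity (as a multiset)
  id <- subtract_80s(eif3, r80, ann, scale = 0)
  key <- function(r) sort(paste(r$transcript_id, r$start, r$end))
  expect_identical(key(id), key(eif3))
  # default scale strongly depletes true 80S reads
  enr <- subtract_80s(eif3, r80, ann)
  frac_in <- mean(eif3$true_complex == "ribo80s")
  frac_out <- mean(enr$true_complex == "ribo80s")
  expect_lt(frac_out, 0.05 * frac_in + 1e-9)
  expect_warning(out <- subtract_80s(eif3, r80[0, ], ann), "empty 80S")
  expect_identical(out, eif3)
  # the length-gate strategy drops the 80S modal band
  gated <- subtract_80s(eif3, r80, ann, strategy = "length_gate")
  modal <- as.integer(names(which.max(table(r80$end - r80$start))))
  expect_false(any(abs((gated$end - gated$start) - modal) <= 2))
})

test_that("rank-sum comparison reports direction and degeneracy", {
  same <- rep(1:30, 3)
  cmp <- compare_distributions(same, same)
  expect_equal(cmp$direction, "none")
  expect_gt(cmp$p_value, 0.9)
  set.seed(5)
  a <- rnorm(1e4, 30, 3); b <- a + 5
  cmp2 <- compare_distributions(a, b)
  expect_equal(cmp2$direction, "b>a")
  expect_lt(cmp2$p_value, 1e-10)
  deg <- compare_distributions(rep(2, 5), rep(2, 8))
  expect_true(deg$degenerate)
  expect_error(compare_distributions(numeric(0), 1), "non-empty")
})
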