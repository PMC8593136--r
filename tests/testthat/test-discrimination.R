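make_profile <- function(values, lo = 0L, end_type = "three_prime",
                         anchor = "TSS") {
  structure(list(anchor = anchor, end_type = end_type,
                 window = c(lo, lo + length(values) - 1L),
                 values = stats::setNames(values,
                                          seq(lo, lo + length(values) - 1L)),
                 n_transcripts = 10L),
            class = "aggregation_profile")
}

test_that("bump statistic scores flat and degenerate profiles as documented", {
  flat <- make_profile(rep(2, 101))
  expect_equal(as.numeric(bump_statistic(flat, 24)), 1)
  delta <- make_profile(c(rep(0, 40), 50, rep(0, 60)))
  b <- bump_statistic(delta, 24)
  expect_equal(as.numeric(b), 100)
  expect_true(attr(b, "capped"))
  zero <- make_profile(rep(0, 101))
  expect_equal(as.numeric(bump_statistic(zero, 24)), 0)
  expect_error(bump_statistic(make_profile(rep(1, 50)), 24), "window too small")
})

test_that("bidirectional scanning inflates the TSS bump over pure slot-in", {
  ann <- small_annotation()
  gm <- scanpic:::generating_models(scan_config())
  b <- vapply(c("slot_in", "slot_in_bidirectional"), function(nm) {
    reads <- snapshot_library(ann, gm[[nm]], 1e5, "eif3", seed = 17)
    signature_statistics(reads, ann)$tss_3p_bump
  }, numeric(1))
  expect_gt(b[["slot_in_bidirectional"]], b[["slot_in"]])
})

test_that("the TSS bump is nondecreasing in the backslide probability", {
  # metagene averaging needs on the order of a thousand transcripts for a
  # stable bump estimate
  ann <- generate_transcriptome(1000, seed = 11)
  bump_at <- function(pb) {
    cfg <- scan_config(backslide_enabled = pb > 0, p_fwd = 0.42, p_back = pb,
                       p_stay = 1 - 0.42 - pb)
    mean(vapply(1:3, function(sd) {
      reads <- snapshot_library(ann, cfg, 2e5, "eif3", seed = sd)
      signature_statistics(reads, ann)$tss_3p_bump
    }, numeric(1)))
  }
  bumps <- vapply(c(0, 0.1, 0.2, 0.3), bump_at, numeric(1))
  expect_true(all(diff(bumps) >= -0.02))
  expect_gt(bumps[4], bumps[1])
})

test_that("length gradients separate growing from full-width footprints", {
  ann <- small_annotation()
  # identical lengths: slope exactly zero
  reads <- data.frame(transcript_id = names(ann$transcripts)[1],
                      start = 0:39, end = 0:39 + 29L)
  expect_equal(length_gradient(reads, ann, min_reads = 10)$slope_5p, 0)
  thr <- snapshot_library(ann, scan_config(loading_mode = "threading"), 5e4,
                          "eif3", seed = 8)
  slt <- snapshot_library(ann, scanpic:::generating_models(scan_config())$slot_in,
                          5e4, "eif3", seed = 8)
  g_thr <- length_gradient(thr, ann)$slope_3p
  g_slt <- length_gradient(slt, ann)$slope_3p
  expect_gt(g_thr, 0)
  expect_error(length_gradient(thr[1:10, ], ann), "insufficient")
})

test_that("flanking peaks recover the configured oscillation reach", {
  ann <- small_annotation()
  wt <- scan_config()
  reads <- snapshot_library(ann, wt, 2e5, "eif3", seed = 19)
  p5 <- end_aggregation_profile(reads, ann, "start_codon", "five_prime",
                                c(-60L, 60L))
  p3 <- end_aggregation_profile(reads, ann, "start_codon", "three_prime",
                                c(-60L, 60L))
  fl <- flanking_peak_offsets(p5, p3)
  expect_lt(abs(fl$mean_offset - wt$osc_reach), 2)
  expect_error(flanking_peak_offsets(
    make_profile(rep(1, 50), -20L, "five_prime", "start_codon"),
    make_profile(rep(1, 50), -20L, "three_prime", "start_codon")),
    "window too small")
})

test_that("an 80S-only library shows no PIC flanking peaks", {
  ann <- small_annotation()
  r80 <- snapshot_library(ann, scan_config(), 5e4, "ribo80s", seed = 23)
  p5 <- end_aggregation_profile(r80, ann, "start_codon", "five_prime",
                                c(-60L, 60L))
  p3 <- end_aggregation_profile(r80, ann, "start_codon", "three_prime",
                                c(-60L, 60L))
  fl <- flanking_peak_offsets(p5, p3)
  # 80S 5' ends sit upstream and 3' ends downstream of the codon, so both
  # flanking searches find nothing prominent
  expect_true(is.na(fl$downstream_offset))
  expect_true(is.na(fl$upstream_offset))
})

test_that("eIF4A1 knockdown suppresses flanking-peak prominence", {
  ann <- small_annotation()
  wt <- scan_config(); kd <- apply_preset(wt, "eif4a1_kd")
  prominence <- function(cfg) {
    reads <- snapshot_library(ann, cfg, 1e5, "eif3", seed = 25)
    p3 <- end_aggregation_profile(reads, ann, "start_codon", "three_prime",
                                  c(-60L, 60L))
    pos <- as.integer(names(p3$values))
    sel <- pos >= -60L & pos <= -1L
    k <- which.max(p3$values[sel]); pk <- pos[sel][k]
    loc <- p3$values[pos >= pk - 10L & pos <= pk + 10L]
    p3$values[sel][k] / stats::median(loc)
  }
  expect_gt(prominence(wt), prominence(kd))
})

test_that("the calibrated classifier recovers its generating model", {
  ann <- small_annotation()
  base <- scan_config()
  cal <- calibrate_classifier(ann, base, n_reads = 5e4, seeds = 1:2)
  gm <- scanpic:::generating_models(base)
  for (nm in names(gm)) for (sd in 31:32) {
    reads <- snapshot_library(ann, gm[[nm]], 5e4, "eif3", seed = sd)
    v <- classify_loading_model(signature_statistics(reads, ann), cal)
    expect_equal(v$model, nm)
    expect_named(v$scores, c("threading", "bidirectional_bump"))
  }
  bad <- list(tss_3p_low_mass = NA_real_, tss_3p_bump = 1)
  expect_equal(classify_loading_model(bad, cal)$model, "undetermined")
})
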