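test_that("loading geometry follows the mechanism", {
  tx <- ref_transcript()
  slot <- scan_config()
  expect_equal(load_pic(tx, slot)$p_site, 12L)
  expect_true(load_pic(tx, slot)$eif4e_bound)
  thr <- scan_config(loading_mode = "threading")
  expect_equal(load_pic(tx, thr)$p_site, 0L)
  expect_false(load_pic(tx, thr)$eif4e_bound)
  ir <- transcript("ir", 600L, 200L, 500L, entry_site = 50L)
  st <- load_pic(ir, apply_preset(slot, "ires_only"))
  expect_equal(st$p_site, 50L)
  expect_false(st$eif4e_bound)
  # transcript too short for slot-in: a counted failure, not an error
  shorty <- transcript("s", 8L, 0L, 6L)
  st <- load_pic(shorty, slot)
  expect_false(st$alive)
  expect_true(st$failed)
})

test_that("condition presets override the documented fields", {
  wt <- scan_config()
  expect_false(apply_preset(wt, "wt")$eif4e_tethered)
  teth <- apply_preset(wt, "tethered_eif4e")
  expect_true(teth$eif4e_tethered)
  expect_equal(teth$eif4e_release_rate, 0)
  expect_lt(apply_preset(wt, "eif4a1_kd")$p_open, wt$p_open)
  expect_lt(apply_preset(wt, "eif4a1_kd")$p_back, wt$p_back)
  expect_gt(apply_preset(wt, "pata")$p_back, wt$p_back)
  expect_true(apply_preset(wt, "ires_only")$internal_entry)
  expect_error(apply_preset(wt, "mystery_drug"))
})

test_that("the tethered reflecting floor bounds every visited position", {
  tx <- ref_transcript()
  cfg <- apply_preset(scan_config(dropoff_rate = 0, recognition_base = 0),
                      "tethered_eif4e")
  wa <- scanpic:::walk_args(tx, cfg)
  wa$max_steps <- 1e5L
  set.seed(4)
  res <- do.call(scanpic:::cpp_trajectories,
                 c(wa, list(n_traj = 20L, want_dwell = TRUE, want_trace = FALSE)))
  visited <- which(res$dwell > 0) - 1L
  expect_equal(min(visited), cfg$cap_offset)
})

test_that("a deterministic forward walk commits at the first AUG in aug_pos steps", {
  tx <- build_reporter("ultra_short_utr", utr5_len = 20L, context = 1)
  cfg <- linear_config(recognition_base = 1)
  set.seed(1)
  out <- run_trajectory(tx, cfg)
  expect_equal(out$state$outcome, "committed")
  expect_equal(out$state$committed_at, 20L)
  # one commitment check per position from entry 0 through the AUG
  expect_equal(out$state$step_count, 21L)
})

test_that("step_pic refuses dead or committed states and respects the floor", {
  tx <- ref_transcript()
  cfg <- scan_config()
  st <- load_pic(tx, cfg)
  st$committed <- TRUE
  expect_error(step_pic(st, tx, cfg), "dead or committed")
  st <- load_pic(tx, cfg)
  st$alive <- FALSE
  expect_error(step_pic(st, tx, cfg), "dead or committed")
  # forced backslide attempts at the floor stay in place while bound
  teth <- apply_preset(scan_config(p_fwd = 0, p_back = 1, p_stay = 0,
                                   recognition_base = 0, dropoff_rate = 0),
                       "tethered_eif4e")
  st <- load_pic(tx, teth)
  set.seed(2)
  for (i in 1:50) st <- step_pic(st, tx, teth)
  expect_equal(st$p_site, teth$cap_offset)
})

test_that("trajectory outcomes conserve probability", {
  tx <- build_reporter("two_aug_spacer", spacer = 6L, context = 0.8)
  cfg <- scan_config()
  mc <- selection_mc(tx, cfg, 5e3, seed = 8)
  # committed + dropoff + runoff exhaust the non-censored trajectories
  expect_equal(sum(mc$per_aug) + mc$p_runoff + mc$p_dropoff, 1,
               tolerance = 1e-9)
  expect_true(all(c(mc$per_aug, mc$p_runoff, mc$p_dropoff) >= 0))
})

test_that("committed_at is always an annotated AUG position", {
  tx <- build_reporter("two_aug_spacer", spacer = 6L, context = 0.8)
  wa <- scanpic:::walk_args(tx, scan_config())
  set.seed(3)
  res <- do.call(scanpic:::cpp_trajectories,
                 c(wa, list(n_traj = 2000L, want_dwell = FALSE,
                            want_trace = FALSE)))
  hits <- res$committed_at[res$outcome == 1L]
  expect_true(all(hits %in% tx$aug_sites$pos))
})

test_that("runoff is certain without recognition, dropoff or backsliding", {
  tx <- ref_transcript()
  cfg <- scan_config(backslide_enabled = FALSE, p_fwd = 0.6, p_stay = 0.4,
                     p_back = 0, recognition_base = 0, dropoff_rate = 0)
  mc <- selection_mc(tx, cfg, 500, seed = 5)
  expect_equal(mc$p_runoff, 1)
})

test_that("released backsliding PICs reach the blind spot", {
  # utr5 = 2 reporter: position 2 is visited only via 3'->5' excursions
  tx <- build_reporter("ultra_short_utr", utr5_len = 2L)
  wa <- scanpic:::walk_args(tx, scan_config())
  set.seed(6)
  res <- do.call(scanpic:::cpp_trajectories,
                 c(wa, list(n_traj = 1e4L, want_dwell = TRUE,
                            want_trace = FALSE)))
  expect_gt(res$dwell[2 + 1], 0)
  # and the exact chain agrees that the AUG there is reachable
  o <- absorption_oracle(tx, scan_config())
  expect_gt(o$per_aug[["2"]], 0)
})

test_that("pateamine increases 5'UTR dwell relative to wild type", {
  tx <- ref_transcript()
  wt <- scan_config(); pa <- apply_preset(wt, "pata")
  dwell_utr <- function(cfg) {
    wa <- scanpic:::walk_args(tx, cfg)
    set.seed(12)
    res <- do.call(scanpic:::cpp_trajectories,
                   c(wa, list(n_traj = 5e3L, want_dwell = TRUE,
                              want_trace = FALSE)))
    sum(res$dwell[seq_len(tx$cds_start)])
  }
  expect_gt(dwell_utr(pa), dwell_utr(wt))
})

test_that("80S snapshot geometry places the P-site 12 nt into the read", {
  tx <- ref_transcript()
  cfg <- scan_config(boundary_noise_sd = 0, ribo80s_len = c(29, 0),
                     p_fwd = 1, p_back = 0, p_stay = 0,
                     backslide_enabled = FALSE, eif4e_release_rate = 1,
                     recognition_base = 1, dropoff_rate = 0)
  reads <- snapshot_library(tx, cfg, 50, "ribo80s", seed = 1)
  expect_true(all(reads$start == 188L))
  expect_true(all(reads$end == 217L))
})

test_that("cap-complex reads all start at the cap without boundary noise", {
  tx <- ref_transcript()
  cfg <- scan_config(backslide_enabled = FALSE, eif4e_release_rate = 0,
                     p_fwd = 0.42, p_back = 0, p_stay = 0.58,
                     boundary_noise_sd = 0)
  reads <- snapshot_library(tx, cfg, 2000, "pic", seed = 2)
  cap <- reads[reads$true_complex == "cap_complex", ]
  expect_gt(nrow(cap), 0)
  expect_true(all(cap$start == 0L))
})

test_that("eIF4A1 knockdown lengthens scanning footprints", {
  ann <- small_annotation()
  wt <- scan_config(); kd <- apply_preset(wt, "eif4a1_kd")
  rw <- snapshot_library(ann, wt, 2e4, "pic", seed = 9)
  rk <- snapshot_library(ann, kd, 2e4, "pic", seed = 9)
  expect_gt(mean(rk$end - rk$start), mean(rw$end - rw$start))
})

test_that("snapshot libraries are deterministic and order-independent", {
  ann <- small_annotation(n = 10)
  cfg <- scan_config()
  a <- snapshot_library(ann, cfg, 3000, "eif3", seed = 21)
  b <- snapshot_library(ann, cfg, 3000, "eif3", seed = 21)
  expect_identical(a, b)
  # reversing transcript order leaves each transcript's reads unchanged
  rev_ann <- transcriptome(rev(ann$transcripts), name = ann$name,
                           seed = ann$seed)
  c <- snapshot_library(rev_ann, cfg, 3000, "eif3", seed = 21)
  key <- function(r) sort(paste(r$transcript_id, r$start, r$end, r$true_complex))
  expect_identical(key(a), key(c))
})

test_that("net displacement per step matches p_fwd - p_back", {
  # long AUG-free stretch, entry mid-transcript, no absorbing events nearby
  tx <- transcript("freeway", 4000L, 3500L, 3980L)
  cfg <- scan_config(p_fwd = 0.45, p_back = 0.3, p_stay = 0.25,
                     eif4e_release_rate = 1, recognition_base = 0,
                     dropoff_rate = 0, max_steps = 400L)
  wa <- scanpic:::walk_args(tx, cfg)
  wa$entry <- 1500L
  set.seed(31)
  n <- 400L
  disp <- vapply(seq_len(n), function(i) {
    res <- do.call(scanpic:::cpp_trajectories,
                   c(wa, list(n_traj = 1L, want_dwell = FALSE,
                              want_trace = TRUE)))
    tr <- res$trace
    (tr[length(tr)] - tr[1]) / (length(tr) - 1)
  }, numeric(1))
  drift <- 0.45 - 0.3
  se <- sd(disp) / sqrt(n)
  expect_lt(abs(mean(disp) - drift), 3 * se + 1e-12)
})

test_that("library classes filter the complex types", {
  ann <- small_annotation(n = 10)
  cfg <- scan_config()
  expect_true(all(snapshot_library(ann, cfg, 500, "ribo80s",
                                   seed = 1)$true_complex == "ribo80s"))
  pic <- snapshot_library(ann, cfg, 500, "pic", seed = 1)
  expect_false(any(pic$true_complex == "ribo80s"))
  eif3 <- snapshot_library(ann, cfg, 5000, "eif3", seed = 1)
  expect_setequal(unique(eif3$true_complex),
                  c("cap_complex", "scanning_pic", "ribo80s"))
})

test_that("reads always lie within their transcript after clipping", {
  ann <- small_annotation(n = 20)
  reads <- snapshot_library(ann, scan_config(boundary_noise_sd = 3), 5000,
                            "eif3", seed = 13)
  lens <- vapply(ann$transcripts, `[[`, integer(1), "length")
  expect_true(all(reads$start >= 0))
  expect_true(all(reads$end <= lens[reads$transcript_id]))
  expect_true(all(reads$end > reads$start))
})
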