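#' Emit the canonical small fixtures
#'
#' Writes the constructs and small libraries used throughout the tests and
#' examples: a 600-nt reference transcript (200-nt 5'UTR, 300-nt CDS),
#' two-AUG spacer constructs (spacer 4, 10, 16, 22 nt), the triple-AUG
#' blind-spot construct, the internal-entry constructs (6 and 18 nt), and a
#' 10^4-read eIF3-class library per condition preset. Regeneration with the
#' same seed is byte-identical.
#'
#' @param output_dir Output directory (created if needed).
#' @param seed Root seed.
#' @param presets Condition presets to simulate.
#' @param n_reads Reads per preset library.
#' @return Invisibly, the paths written.
#' @export
fixture_suite <- function(output_dir, seed = 7L,
                          presets = c("wt", "eif4a1_kd", "pata"),
                          n_reads = 1e4) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  ref <- transcript("ref600", 600L, 200L, 500L)
  constructs <- c(
    list(ref600 = ref,
         three_aug = build_reporter("three_aug"),
         ires_6nt = build_reporter("ires_entry", entry_distance = 6L),
         ires_18nt = build_reporter("ires_entry", entry_distance = 18L)),
    stats::setNames(
      lapply(c(4L, 10L, 16L, 22L), function(d)
        build_reporter("two_aug_spacer", spacer = d)),
      paste0("spacer_", c(4, 10, 16, 22), "nt")))
  cons <- transcriptome(constructs, name = "canonical_constructs", seed = seed)
  p <- file.path(output_dir, "constructs")
  write_annotation(cons, p)
  paths <- c(paths, paste0(p, c(".bed", ".sites.tsv")))
  ann <- generate_transcriptome(50L, mito_fraction = 0.1, seed = seed)
  p <- file.path(output_dir, "transcriptome")
  write_annotation(ann, p)
  paths <- c(paths, paste0(p, c(".bed", ".sites.tsv")))
  base <- scan_config(seed = seed)
  for (ps in presets) {
    cfg <- apply_preset(base, ps)
    reads <- snapshot_library(ann, cfg, n_reads, "eif3", seed = seed)
    rp <- file.path(output_dir, sprintf("reads_%s.bed", ps))
    export_reads(reads, rp, "bed")
    paths <- c(paths, rp)
  }
  sp_log("fixtures", "fixture_suite", list(dir = output_dir, seed = seed))
  invisible(paths)
}

#' Run the full chain at demonstration scale
#'
#' Generates a small annotated transcriptome, simulates wild-type,
#' eIF4A1-knockdown and pateamine-A libraries, runs the length/occupancy/
#' aggregation analyses and the loading-model classifier, and writes the
#' result tables. Deterministic for a fixed seed.
#'
#' @param output_dir Output directory.
#' @param seed Root seed.
#' @param n_transcripts,n_reads Problem size.
#' @return A list with the classifier verdict and the paths written.
#' @export
run_demo <- function(output_dir, seed = 7L, n_transcripts = 100L,
                     n_reads = 5e4) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  ann <- generate_transcriptome(n_transcripts, mito_fraction = 0.05,
                                seed = seed, decoy_aug_rate = 0.01)
  write_annotation(ann, file.path(output_dir, "annotation"))
  base <- scan_config(seed = seed)
  verdicts <- list()
  occ <- list()
  for (ps in c("wt", "eif4a1_kd", "pata")) {
    cfg <- apply_preset(base, ps)
    eif3 <- snapshot_library(ann, cfg, n_reads, "eif3", seed = seed)
    r80 <- snapshot_library(ann, cfg, n_reads %/% 2, "ribo80s", seed = seed + 1L)
    export_reads(eif3, file.path(output_dir, sprintf("eif3_%s.bed", ps)))
    ld <- length_distribution_by_region(eif3, ann)
    occ[[ps]] <- stats::median(
      utr5_cds_occupancy(r80, ann)$utr5_cds_ratio, na.rm = TRUE)
    utils::write.table(
      data.frame(region = names(ld),
                 n = vapply(ld, `[[`, integer(1), "n"),
                 median_len = vapply(ld, `[[`, integer(1), "median"),
                 mode_len = vapply(ld, `[[`, integer(1), "mode")),
      file.path(output_dir, sprintf("lengths_%s.tsv", ps)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cal <- calibrate_classifier(ann, base, n_reads = n_reads, seeds = seed + 1:2)
  wt_reads <- snapshot_library(ann, base, n_reads, "eif3", seed = seed + 10L)
  verdict <- classify_loading_model(signature_statistics(wt_reads, ann), cal)
  utils::write.table(
    data.frame(model = verdict$model, t(verdict$scores)),
    file.path(output_dir, "verdict.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  list(verdict = verdict, occupancy_ratio_median = unlist(occ),
       output_dir = output_dir)
}
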