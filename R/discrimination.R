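## Signature statistics that separate the three loading models from the
## shapes of end-resolved metagene profiles: threading gives a strong 5'-end
## TSS peak with footprints growing from the cap; slot-in gives parallel
## cap-anchored 5'/3' end peaks; bidirectional scanning adds a downstream
## 3'-end bump at the TSS (backslid PICs) and flanking peaks at start codons.

#' Bump statistic of a TSS-anchored 3'-end profile
#'
#' Ratio of the maximum profile value downstream of the cap-complex peak
#' (positions in `(modal_cap_len + 5, 100]`) to the median over the tail
#' quartile of that range. A flat profile scores about 1; a secondary bump
#' from backslid scanning PICs scores higher. A zero tail median caps the
#' statistic (attribute `capped`).
#'
#' @param profile A TSS-anchored `three_prime` [end_aggregation_profile()]
#'   whose window covers `[0, 100]`.
#' @param modal_cap_len Modal cap-complex footprint length (nt).
#' @param cap Value returned when the tail median is zero.
#' @return Non-negative number with attribute `capped`.
#' @export
bump_statistic <- function(profile, modal_cap_len, cap = 100) {
  stopifnot(inherits(profile, "aggregation_profile"),
            profile$end_type == "three_prime")
  pos <- as.integer(names(profile$values))
  if (min(pos) > 0L || max(pos) < 100L)
    stop("window too small: bump statistic needs relative positions [0, 100]")
  lo <- modal_cap_len + 5
  sel <- pos > lo & pos <= 100L
  if (!any(sel)) stop("window too small beyond the cap-complex peak")
  v <- profile$values[sel]
  p <- pos[sel]
  tail_start <- lo + 0.75 * (100 - lo)
  tail_med <- stats::median(v[p > tail_start])
  if (!is.finite(tail_med) || tail_med <= 0) {
    out <- if (max(v) > 0) cap else 0
    attr(out, "capped") <- max(v) > 0
    return(out)
  }
  out <- max(v) / tail_med
  attr(out, "capped") <- FALSE
  out
}

#' Footprint-length gradient away from the TSS
#'
#' Least-squares slopes of read length on end position over the first
#' `span` nt. Under threading, footprints grow as the mRNA is fed in
#' base-by-base, so length rises with the 3'-end position; under slot-in the
#' near-cap footprints are full-width from the start. Both the 5'-end and
#' 3'-end regressions are reported.
#'
#' @param reads A `footprint_reads` data frame.
#' @param annotation The [transcriptome()].
#' @param span Regression span (nt) from the TSS.
#' @param min_reads Minimum reads with an end in `[0, span]`.
#' @return List with `slope_5p` and `slope_3p` (nt per nt).
#' @export
length_gradient <- function(reads, annotation, span = 40L, min_reads = 100L) {
  len <- reads$end - reads$start
  p5 <- reads$start
  p3 <- reads$end - 1L
  sel5 <- p5 >= 0L & p5 <= span
  sel3 <- p3 >= 0L & p3 <= span
  if (sum(sel5) < min_reads && sum(sel3) < min_reads)
    stop("insufficient reads within the TSS span for a length gradient")
  slope <- function(sel, x) {
    if (sum(sel) < min_reads || stats::var(x[sel]) == 0) return(NA_real_)
    unname(stats::coef(stats::lm(len[sel] ~ x[sel]))[2])
  }
  list(slope_5p = slope(sel5, p5), slope_3p = slope(sel3, p3))
}

#' Flanking footprint-end peaks around the start codon
#'
#' Locates the upstream 3'-end peak and downstream 5'-end peak that
#' oscillating PICs leave on either side of the start codon. A peak must
#' exceed `prominence` times the local median (21-nt window) to count;
#' otherwise it is flagged absent (`NA`), never fabricated.
#'
#' @param profile_5p,profile_3p Start-codon-anchored
#'   [end_aggregation_profile()]s of each end type; windows must cover
#'   `[-60, 60]`.
#' @param prominence Peak prominence multiplier over the local median.
#' @return List with `upstream_offset` (distance of the 3'-end peak,
#'   searched over `[-60, -1]`), `downstream_offset` (5'-end peak over
#'   `[1, 60]`) and `mean_offset`; each `NA` when absent.
#' @export
flanking_peak_offsets <- function(profile_5p, profile_3p, prominence = 1.5) {
  stopifnot(profile_5p$end_type == "five_prime",
            profile_3p$end_type == "three_prime")
  find_peak <- function(profile, from, to) {
    pos <- as.integer(names(profile$values))
    if (min(pos) > -60L || max(pos) < 60L)
      stop("window too small: flanking peaks need relative positions [-60, 60]")
    sel <- pos >= from & pos <= to
    v <- profile$values[sel]; p <- pos[sel]
    if (!length(v) || max(v) <= 0) return(NA_integer_)
    k <- which.max(v)
    loc <- profile$values[pos >= p[k] - 10L & pos <= p[k] + 10L]
    med <- stats::median(loc)
    if (med > 0 && v[k] < prominence * med) return(NA_integer_)
    if (med == 0 && v[k] == 0) return(NA_integer_)
    p[k]
  }
  up_pos <- find_peak(profile_3p, -60L, -1L)
  down_pos <- find_peak(profile_5p, 1L, 60L)
  upstream <- if (is.na(up_pos)) NA_real_ else -up_pos
  downstream <- if (is.na(down_pos)) NA_real_ else as.numeric(down_pos)
  offs <- c(upstream, downstream)
  list(upstream_offset = upstream, downstream_offset = downstream,
       mean_offset = if (all(is.na(offs))) NA_real_ else mean(offs, na.rm = TRUE))
}

#' Compute the full signature-statistics set for a footprint library
#'
#' Builds the TSS- and start-codon-anchored end profiles and derives the
#' statistics used to classify the loading model: the 5'-end TSS peak height
#' (relative to the downstream background), the 3'-end TSS bump, the
#' 5'/3'-end parallelism (correlation after shifting by the modal
#' cap-anchored length), the length gradient, and the start-codon flanking
#' peak offsets.
#'
#' @param reads A `footprint_reads` data frame.
#' @param annotation The [transcriptome()].
#' @param prominence Peak prominence rule, see [flanking_peak_offsets()].
#' @return A `signature_statistics` list.
#' @export
signature_statistics <- function(reads, annotation, prominence = 1.5) {
  p5_tss <- end_aggregation_profile(reads, annotation, "TSS", "five_prime",
                                    c(0L, 100L))
  p3_tss <- end_aggregation_profile(reads, annotation, "TSS", "three_prime",
                                    c(0L, 100L))
  p5_sc <- end_aggregation_profile(reads, annotation, "start_codon",
                                   "five_prime", c(-60L, 60L))
  p3_sc <- end_aggregation_profile(reads, annotation, "start_codon",
                                   "three_prime", c(-60L, 60L))
  # modal cap-anchored fragment length: modal 3' end among cap-anchored reads
  capish <- reads$start <= 1L
  modal_cap <- if (any(capish)) mode_smallest(reads$end[capish] - 1L) else 24L
  v5 <- p5_tss$values
  bg <- stats::median(v5[as.integer(names(v5)) >= 20L])
  peak0 <- if (bg > 0) unname(v5["0"]) / bg else unname(v5["0"])
  pos <- as.integer(names(v5))
  shift_sel <- pos <= 60L
  v3shift <- p3_tss$values[as.character(pos[shift_sel] + modal_cap)]
  parallelism <- suppressWarnings(
    stats::cor(v5[shift_sel], v3shift, use = "complete.obs"))
  # diffuse low-side 3'-end structure at the TSS: base-by-base entry yields
  # short growing footprints whose 3' ends fall below any cap-anchored span,
  # a region laterally loaded complexes cannot populate
  v3 <- p3_tss$values
  p3pos <- as.integer(names(v3))
  low_mass <- sum(v3[p3pos >= 5L & p3pos <= 25L]) /
    max(sum(v3[p3pos >= 5L]), .Machine$double.eps)
  grad <- length_gradient(reads, annotation)
  fl <- flanking_peak_offsets(p5_sc, p3_sc, prominence)
  structure(list(tss_5p_peak_height = peak0,
                 tss_3p_bump = as.numeric(bump_statistic(p3_tss, modal_cap)),
                 tss_3p_low_mass = low_mass,
                 parallelism = parallelism,
                 length_gradient = grad,
                 flanking_peak_offsets = fl,
                 modal_cap_len = modal_cap),
            class = "signature_statistics")
}

#' Calibrate classifier thresholds on simulation
#'
#' Simulates libraries under the three generating models (threading; slot-in
#' without backsliding; slot-in with bidirectional scanning) and places each
#' decision threshold at the midpoint (on the log scale) between the
#' adjacent models' observed statistic ranges. Thresholds are never
#' hard-coded: classification always takes a calibration produced here.
#'
#' @param annotation A [transcriptome()] to simulate on.
#' @param config Base [scan_config()] (the bidirectional model; the other
#'   two are derived from it).
#' @param n_reads Reads per calibration library.
#' @param seeds Seeds (one library per seed and model).
#' @param library Library class to simulate.
#' @return A `model_calibration` list with `thresholds` and the raw
#'   per-model statistics.
#' @export
calibrate_classifier <- function(annotation, config, n_reads = 2e5,
                                 seeds = 1:3, library = "eif3") {
  models <- generating_models(config)
  stats_by <- lapply(models, function(cfg) {
    lapply(seeds, function(sd) {
      reads <- snapshot_library(annotation, cfg, n_reads, library, seed = sd)
      signature_statistics(reads, annotation)
    })
  })
  pull <- function(model, field)
    vapply(stats_by[[model]], function(s) as.numeric(s[[field]]), numeric(1))
  geo_mid <- function(a, b) exp((log(max(a, 1e-6)) + log(max(b, 1e-6))) / 2)
  thr <- list(
    low_mass = geo_mid(min(pull("threading", "tss_3p_low_mass")),
                       max(c(pull("slot_in", "tss_3p_low_mass"),
                             pull("slot_in_bidirectional", "tss_3p_low_mass")))),
    bump = geo_mid(min(pull("slot_in_bidirectional", "tss_3p_bump")),
                   max(pull("slot_in", "tss_3p_bump"))))
  structure(list(thresholds = thr, statistics = stats_by,
                 n_reads = n_reads, seeds = seeds),
            class = "model_calibration")
}

## the three generating configurations contrasted by the classifier
generating_models <- function(config) {
  base <- unclass(config)
  thr <- base; thr$loading_mode <- "threading"
  si <- base; si$backslide_enabled <- FALSE; si$p_back <- 0
  si$p_stay <- base$p_stay + base$p_back
  list(threading = do.call(scan_config, thr),
       slot_in = do.call(scan_config, si),
       slot_in_bidirectional = config)
}

#' Classify a footprint library by loading model
#'
#' Decision rule (auditable via the returned score vector): a library whose
#' TSS-anchored 3'-end profile carries threading-grade diffuse low-side mass
#' (short footprints growing from the cap) is `threading`; otherwise the TSS
#' 3'-end bump decides between `slot_in` (low) and `slot_in_bidirectional`
#' (high). Degenerate statistics give `undetermined`.
#'
#' @param stats A [signature_statistics()] result.
#' @param calibration A [calibrate_classifier()] result.
#' @return List with `model`, and `scores` (each statistic divided by its
#'   threshold).
#' @export
classify_loading_model <- function(stats, calibration) {
  thr <- calibration$thresholds
  scores <- c(threading = stats$tss_3p_low_mass / thr$low_mass,
              bidirectional_bump = stats$tss_3p_bump / thr$bump)
  if (!all(is.finite(scores))) return(list(model = "undetermined",
                                           scores = scores))
  model <- if (scores[["threading"]] > 1) "threading"
           else if (scores[["bidirectional_bump"]] > 1) "slot_in_bidirectional"
           else "slot_in"
  list(model = model, scores = scores)
}
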