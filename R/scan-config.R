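#' Mechanistic configuration of the scanning simulator
#'
#' All parameters of the discrete-time PIC model live here. One step of the
#' model is one attempted single-nucleotide displacement of the P-site. Per
#' step the PIC (i) may commit if an AUG occupies the P-site, with probability
#' `recognition_base * context`; (ii) may drop off; (iii) may release eIF4E
#' from the cap (geometric kinetics) when cap-bound and not tethered; and
#' (iv) moves -1/0/+1 with probabilities `(p_back, p_stay, p_fwd)`, with a
#' reflecting floor at `cap_offset` while eIF4E-bound (the cap blocks
#' backsliding into the cap-proximal region under slot-in loading), a
#' reflecting floor at 0 otherwise, and a runoff absorber `runoff_margin` nt
#' past the CDS end.
#'
#' Footprint geometry: a snapshot of a scanning PIC protects a fragment of
#' length drawn from the open- or closed-conformation distribution (the open
#' conformation is eIF4A-dependent and is caught with probability `p_open`);
#' `channel_up_frac` of the fragment lies 5' of the P-site. While eIF4E-bound
#' the complex protects two fragments -- a cap-anchored one starting at
#' position 0 (length `cap_complex_len`, extended under the closed
#' conformation) and the channel fragment -- and a snapshot captures one of
#' the two with equal probability. A
#' committed complex lingers at the start codon: during `engage_dwell` steps
#' it oscillates around the codon with excursion amplitude about `osc_reach`
#' nt (footprints flank the codon), then sits as an 80S for `ribo80s_dwell`
#' steps protecting the canonical ~29-nt fragment.
#'
#' @param loading_mode `"slot_in"` (lateral attachment, P-site lands
#'   `cap_offset` nt from the cap) or `"threading"` (cap fed base-by-base
#'   into the channel; entry at position 0, eIF4E detached).
#' @param backslide_enabled Allow 3'->5' excursions (`p_back > 0`).
#' @param p_fwd,p_back,p_stay Per-step displacement probabilities (sum to 1;
#'   `p_back` is forced to 0 when backsliding is disabled).
#' @param eif4e_release_rate Per-step probability of eIF4E-cap dissociation.
#' @param bound_mobility Factor in `(0, 1]` scaling both `p_fwd` and
#'   `p_back` while eIF4E is cap-bound (the tether restrains displacement;
#'   dissociation frees bidirectional scanning). 1 disables the restraint.
#' @param eif4e_tethered Non-dissociable eIF4E (release rate forced to 0).
#' @param internal_entry Cap-independent loading at the transcript's
#'   `entry_site` (IRES-like); eIF4E never engaged.
#' @param cap_offset Distance (nt) from the cap to the P-site at slot-in
#'   loading; this is the geometric origin of the ~12-nt blind spot.
#' @param pic_len_open,pic_len_closed `(mean, sd)` of scanning-PIC footprint
#'   length in the open / closed conformation.
#' @param p_open Probability that a snapshot catches the PIC open
#'   (eIF4A-dependent).
#' @param cap_complex_len `(mean, sd)` of the cap-anchored footprint length.
#' @param ribo80s_len `(mean, sd)` of 80S footprint length (default mean 29).
#' @param ribo80s_p_offset nt from the 80S footprint 5' end to the P-site.
#' @param recognition_base Per-step commitment probability at an AUG of
#'   context strength 1.
#' @param dropoff_rate Per-step PIC dissociation probability.
#' @param max_steps Trajectory cap; `NA` means 10 x transcript length.
#' @param boundary_noise_sd Gaussian jitter (nt) applied to both footprint
#'   ends (RNase boundary raggedness).
#' @param osc_reach,osc_reach_sd Mean and sd (nt) of the start-codon
#'   oscillation excursion amplitude.
#' @param engage_dwell,ribo80s_dwell Steps spent engaged at the start codon
#'   before/after subunit joining (sets the start-codon occupancy peak).
#' @param channel_up_frac Fraction of a scanning footprint 5' of the P-site.
#' @param runoff_margin nt past `cds_end` at which scanning is absorbed as
#'   runoff.
#' @param snapshots_per_trajectory Reads sampled per simulated complex by
#'   [snapshot_library()].
#' @param seed Root seed recorded with the configuration.
#' @return An object of class `scan_config` (a validated named list).
#' @export
scan_config <- function(loading_mode = c("slot_in", "threading"),
                        backslide_enabled = TRUE,
                        p_fwd = 0.42, p_back = 0.35, p_stay = 0.23,
                        eif4e_release_rate = 0.002,
                        bound_mobility = 0.2,
                        eif4e_tethered = FALSE,
                        internal_entry = FALSE,
                        cap_offset = 12L,
                        pic_len_open = c(30, 5),
                        pic_len_closed = c(60, 10),
                        p_open = 0.7,
                        cap_complex_len = c(35, 2),
                        ribo80s_len = c(29, 2),
                        ribo80s_p_offset = 12L,
                        recognition_base = 0.5,
                        dropoff_rate = 2e-4,
                        max_steps = NA_integer_,
                        boundary_noise_sd = 1,
                        osc_reach = 12,
                        osc_reach_sd = 2,
                        engage_dwell = 300L,
                        ribo80s_dwell = 300L,
                        channel_up_frac = 0.5,
                        runoff_margin = 30L,
                        snapshots_per_trajectory = 10L,
                        seed = 1L) {
  loading_mode <- match.arg(loading_mode)
  if (!backslide_enabled) {
    p_stay <- p_stay + p_back
    p_back <- 0
  }
  if (eif4e_tethered) eif4e_release_rate <- 0
  cfg <- structure(list(
    loading_mode = loading_mode, backslide_enabled = backslide_enabled,
    p_fwd = p_fwd, p_back = p_back, p_stay = p_stay,
    eif4e_release_rate = eif4e_release_rate,
    bound_mobility = bound_mobility, eif4e_tethered = eif4e_tethered,
    internal_entry = internal_entry,
    cap_offset = as.integer(cap_offset),
    pic_len_open = as.numeric(pic_len_open),
    pic_len_closed = as.numeric(pic_len_closed),
    p_open = p_open,
    cap_complex_len = as.numeric(cap_complex_len),
    ribo80s_len = as.numeric(ribo80s_len),
    ribo80s_p_offset = as.integer(ribo80s_p_offset),
    recognition_base = recognition_base, dropoff_rate = dropoff_rate,
    max_steps = as.integer(max_steps),
    boundary_noise_sd = boundary_noise_sd,
    osc_reach = osc_reach, osc_reach_sd = osc_reach_sd,
    engage_dwell = as.integer(engage_dwell),
    ribo80s_dwell = as.integer(ribo80s_dwell),
    channel_up_frac = channel_up_frac,
    runoff_margin = as.integer(runoff_margin),
    snapshots_per_trajectory = as.integer(snapshots_per_trajectory),
    seed = as.integer(seed)), class = "scan_config")
  validate_scan_config(cfg)
  cfg
}

validate_scan_config <- function(cfg) {
  with(cfg, {
    if (any(c(p_fwd, p_back, p_stay) < 0))
      stop("step probabilities must be non-negative")
    if (abs(p_fwd + p_back + p_stay - 1) > 1e-9)
      stop("p_fwd + p_back + p_stay must equal 1")
    if (!backslide_enabled && p_back != 0)
      stop("p_back must be 0 when backsliding is disabled")
    if (p_open < 0 || p_open > 1) stop("p_open must lie in [0, 1]")
    if (bound_mobility <= 0 || bound_mobility > 1)
      stop("bound_mobility must lie in (0, 1]")
    if (cap_offset < 0) stop("cap_offset must be >= 0")
    if (eif4e_tethered && eif4e_release_rate != 0)
      stop("tethered eIF4E requires a zero release rate")
    if (any(c(pic_len_open[1], pic_len_closed[1], cap_complex_len[1],
              ribo80s_len[1]) <= 0))
      stop("footprint length means must be positive")
    if (recognition_base < 0 || recognition_base > 1)
      stop("recognition_base must lie in [0, 1]")
    if (dropoff_rate < 0 || dropoff_rate >= 1) stop("dropoff_rate in [0, 1)")
    if (channel_up_frac < 0 || channel_up_frac > 1)
      stop("channel_up_frac must lie in [0, 1]")
  })
  invisible(cfg)
}

#' @export
print.scan_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<scan_config> %s%s, p_fwd/back/stay = %.3g/%.3g/%.3g\n",
    "  eIF4E release %.3g%s, cap_offset %d, recognition_base %.3g, dropoff %.3g\n",
    "  p_open %.2g, PIC len open N(%g,%g) closed N(%g,%g), cap N(%g,%g), 80S N(%g,%g)\n",
    "  oscillation reach %g +/- %g nt, seed %d\n"),
    x$loading_mode,
    if (x$internal_entry) " (internal entry)" else "",
    x$p_fwd, x$p_back, x$p_stay,
    x$eif4e_release_rate, if (x$eif4e_tethered) " (tethered)" else "",
    x$cap_offset, x$recognition_base, x$dropoff_rate,
    x$p_open, x$pic_len_open[1], x$pic_len_open[2],
    x$pic_len_closed[1], x$pic_len_closed[2],
    x$cap_complex_len[1], x$cap_complex_len[2],
    x$ribo80s_len[1], x$ribo80s_len[2],
    x$osc_reach, x$osc_reach_sd, x$seed))
  invisible(x)
}

#' Named experimental condition presets
#'
#' Pure functions of the preset name; each returns the default (`wt`)
#' configuration with a documented set of overrides:
#'
#' * `wt`: slot-in loading with bidirectional scanning (package defaults).
#' * `eif4a1_kd`: eIF4A1 knockdown; the closed conformation dominates
#'   (`p_open` lowered) and oscillation is damped (`p_back` lowered,
#'   `p_stay` raised): longer footprints, stalled scanning.
#' * `hippu`: hippuristanol, an eIF4A ATPase inhibitor; modelled like the
#'   knockdown (recognition parameters untouched). The compound label is a
#'   preset name only; no chemistry is simulated.
#' * `pata`: pateamine A, an eIF4A ATPase enhancer; more oscillation and
#'   dwell (`p_back`, `p_stay`, `p_open` raised, net advance slowed),
#'   which raises upstream-start commitment.
#' * `tethered_eif4e`: non-dissociable cap-bound eIF4E (release rate 0).
#' * `ires_only`: cap-independent internal entry at the transcript's
#'   `entry_site`; eIF4E never engaged.
#'
#' @param config A [scan_config()] to start from (`wt` values).
#' @param preset_name Preset name.
#' @return A new `scan_config`.
#' @export
apply_preset <- function(config, preset_name) {
  stopifnot(inherits(config, "scan_config"))
  preset_name <- match.arg(preset_name,
    c("wt", "eif4a1_kd", "hippu", "pata", "tethered_eif4e", "ires_only"))
  ov <- switch(preset_name,
    wt = list(),
    eif4a1_kd = list(p_open = 0.2, p_fwd = 0.42, p_back = 0.05, p_stay = 0.53),
    hippu     = list(p_open = 0.2, p_fwd = 0.42, p_back = 0.05, p_stay = 0.53),
    pata      = list(p_open = 0.9, p_fwd = 0.40, p_back = 0.36, p_stay = 0.24),
    tethered_eif4e = list(eif4e_tethered = TRUE, eif4e_release_rate = 0),
    ires_only = list(internal_entry = TRUE))
  cfg <- unclass(config)
  cfg[names(ov)] <- ov
  cfg <- do.call(scan_config, cfg)
  sp_log("scan_config", "apply_preset",
         c(list(preset = preset_name), ov))
  cfg
}

## ---- config file IO -----------------------------------------------------

#' Write / read a scan configuration as flat YAML
#'
#' The file mirrors the `scan_config` field names one-to-one. Unknown keys
#' are an error on read (a typo guard).
#'
#' @param config A `scan_config`.
#' @param path File path.
#' @return `read_scan_config` returns a `scan_config`.
#' @export
write_scan_config <- function(config, path) {
  stopifnot(inherits(config, "scan_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_scan_config
#' @export
read_scan_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(scan_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown scan_config key(s): ", paste(unknown, collapse = ", "))
  vals$loading_mode <- match.arg(vals$loading_mode, c("slot_in", "threading"))
  do.call(scan_config, vals)
}

## structured log line; silent unless options(scanpic.verbose = TRUE)
sp_log <- function(module, event, params = list()) {
  if (!isTRUE(getOption("scanpic.verbose", FALSE))) return(invisible(NULL))
  kv <- paste(names(params), vapply(params, function(p)
    paste(format(p), collapse = ","), character(1)), sep = "=", collapse = " ")
  message(sprintf("%s | %s | %s | %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), module, event, kv))
  invisible(NULL)
}
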