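## ---- PIC state and single-step dynamics ---------------------------------

#' Load a 43S PIC onto a transcript
#'
#' Under `threading` the cap is fed into the mRNA channel: the P-site starts
#' at position 0 and eIF4E has dissociated. Under `slot_in` the mRNA attaches
#' laterally with eIF4E still cap-bound and the P-site lands `cap_offset` nt
#' from the cap, leaving the cap-proximal blind spot. With `internal_entry`
#' (IRES-like) the P-site starts at the transcript's `entry_site` and eIF4E
#' is never engaged.
#'
#' @param transcript A [transcript()].
#' @param config A [scan_config()].
#' @return An object of class `pic_state`. Geometrically impossible loading
#'   (transcript too short for slot-in) returns a dead state with
#'   `failed = TRUE` rather than raising.
#' @export
load_pic <- function(transcript, config) {
  stopifnot(inherits(transcript, "transcript"), inherits(config, "scan_config"))
  if (config$internal_entry) {
    if (is.na(transcript$entry_site))
      stop("internal_entry requires a transcript with an entry_site")
    p <- transcript$entry_site; bound <- FALSE
  } else if (config$loading_mode == "threading") {
    p <- 0L; bound <- FALSE
  } else {
    if (transcript$length < config$cap_offset + 3L)
      return(structure(list(transcript_id = transcript$id, p_site = NA_integer_,
                            eif4e_bound = FALSE, committed = FALSE,
                            committed_at = NA_integer_, alive = FALSE,
                            failed = TRUE, step_count = 0L),
                       class = "pic_state"))
    p <- config$cap_offset; bound <- TRUE
  }
  structure(list(transcript_id = transcript$id, p_site = as.integer(p),
                 eif4e_bound = bound, committed = FALSE,
                 committed_at = NA_integer_, alive = TRUE, failed = FALSE,
                 step_count = 0L),
            class = "pic_state")
}

runoff_boundary <- function(transcript, config) {
  min(transcript$length - 3L, transcript$cds_end + config$runoff_margin)
}

trajectory_cap <- function(transcript, config) {
  if (!is.na(config$max_steps)) return(config$max_steps)
  # cover both the traversal time-scale of a near-balanced walk and the
  # dropoff time-scale, so censoring is a negligible tail event
  cap <- 50L * transcript$length
  if (config$dropoff_rate > 0)
    cap <- max(cap, as.integer(ceiling(30 / config$dropoff_rate)))
  cap
}

#' Advance a PIC by one step
#'
#' One discrete step: commitment check at the current P-site (probability
#' `recognition_base * context` when an AUG occupies it), dropoff, eIF4E
#' release (unless tethered), then a -1/0/+1 move with the reflecting floor
#' at `cap_offset` while eIF4E-bound (slot-in) and runoff absorption past the
#' CDS end. Calling it on a dead or committed state is a contract violation.
#'
#' @param state A `pic_state`.
#' @inheritParams load_pic
#' @return The updated `pic_state`; dropoff and runoff set `alive = FALSE`
#'   with `outcome` `"dropoff"` / `"runoff"`.
#' @export
step_pic <- function(state, transcript, config) {
  if (!isTRUE(state$alive) || isTRUE(state$committed))
    stop("step_pic() called on a dead or committed PIC state")
  p <- state$p_site
  a <- transcript$aug_sites
  hit <- match(p, a$pos)
  if (!is.na(hit) &&
      stats::runif(1) < config$recognition_base * a$context[hit]) {
    state$committed <- TRUE
    state$committed_at <- p
    state$step_count <- state$step_count + 1L
    return(state)
  }
  if (stats::runif(1) < config$dropoff_rate) {
    state$alive <- FALSE; state$outcome <- "dropoff"
    state$step_count <- state$step_count + 1L
    return(state)
  }
  if (state$eif4e_bound && !config$eif4e_tethered &&
      stats::runif(1) < config$eif4e_release_rate)
    state$eif4e_bound <- FALSE
  u <- stats::runif(1)
  floorpos <- if (state$eif4e_bound && config$loading_mode == "slot_in")
    config$cap_offset else 0L
  mob <- if (state$eif4e_bound) config$bound_mobility else 1
  np <- p
  if (u < config$p_back * mob) {
    np <- if (p - 1L >= floorpos) p - 1L else p
  } else if (u < (config$p_back + config$p_fwd) * mob) {
    np <- p + 1L
    if (np >= runoff_boundary(transcript, config)) {
      state$alive <- FALSE; state$outcome <- "runoff"
      state$step_count <- state$step_count + 1L
      return(state)
    }
  }
  state$p_site <- np
  state$step_count <- state$step_count + 1L
  state
}

walk_args <- function(transcript, config) {
  st <- load_pic(transcript, config)
  if (isTRUE(st$failed)) return(NULL)
  list(len = transcript$length,
       aug_pos = as.integer(transcript$aug_sites$pos),
       aug_r = config$recognition_base * transcript$aug_sites$context,
       entry = st$p_site, bound0 = st$eif4e_bound,
       tethered = config$eif4e_tethered,
       slot_floor = config$loading_mode == "slot_in",
       p_fwd = config$p_fwd, p_back = config$p_back,
       bound_mobility = config$bound_mobility,
       release_rate = config$eif4e_release_rate,
       dropoff_rate = config$dropoff_rate,
       cap_offset = config$cap_offset,
       pmax = as.integer(runoff_boundary(transcript, config)),
       max_steps = as.integer(trajectory_cap(transcript, config)))
}

#' Run one scanning trajectory
#'
#' Iterates the stepper until commitment, dropoff, runoff past the CDS end,
#' or the trajectory cap (censoring). The trace records per-position dwell
#' counts, the raw material of occupancy statistics: back-and-forth
#' excursions increase dwell in the 5'UTR.
#'
#' @inheritParams load_pic
#' @return A list with `state` (final `pic_state` carrying `outcome` among
#'   `committed`/`dropoff`/`runoff`/`censored`), `dwell` (per-position step
#'   counts, positions 0-based) and `positions` (the visited position per
#'   step).
#' @export
run_trajectory <- function(transcript, config) {
  wa <- walk_args(transcript, config)
  if (is.null(wa)) stop("loading failure: transcript too short for slot-in")
  res <- do.call(cpp_trajectories, c(wa, list(n_traj = 1L, want_dwell = TRUE,
                                              want_trace = TRUE)))
  outc <- res$outcome[1]
  st <- structure(list(
    transcript_id = transcript$id,
    p_site = res$trace[length(res$trace)],
    eif4e_bound = NA,
    committed = outc == 1L,
    committed_at = res$committed_at[1],
    alive = FALSE, failed = FALSE,
    step_count = res$steps[1],
    outcome = c(`1` = "committed", `-1` = "dropoff", `-2` = "runoff",
                `-3` = "censored")[as.character(outc)][[1]]),
    class = "pic_state")
  dwell <- res$dwell
  names(dwell) <- as.character(seq_along(dwell) - 1L)
  list(state = st, dwell = dwell, positions = res$trace)
}

## ---- snapshot libraries -------------------------------------------------

#' Simulate a footprint snapshot library
#'
#' Emulates formaldehyde-crosslinking footprinting: each simulated complex is
#' caught at uniformly random moments of its life and emits one protected
#' fragment per snapshot. Cap-bound complexes protect a cap-anchored fragment
#' (5' end at the cap); scanning PICs protect a fragment straddling the
#' P-site with `channel_up_frac` of its length 5' of it (open or closed
#' conformation length); complexes engaged at a start codon emit either
#' codon-centred fragments or oscillation-excursion fragments flanking the
#' codon at about `osc_reach` nt; committed 80S ribosomes protect the
#' canonical fragment with the P-site `ribo80s_p_offset` nt from the 5' end.
#' Both fragment ends get Gaussian RNase jitter and are clipped to the
#' transcript.
#'
#' Library classes filter the complexes: `ribo80s` keeps 80S only (Ribo-seq
#' like), `pic` keeps scanning/cap complexes only (PIC-seq like), `eif3`
#' keeps everything (eIF3-seq like).
#'
#' Reads are allocated evenly across transcripts; each transcript uses an
#' RNG stream derived from the root seed and a stable hash of its id, so the
#' result is independent of transcript order.
#'
#' @param annotation A [transcriptome()] (or a single [transcript()]).
#' @param config A [scan_config()].
#' @param n_reads_target Total number of reads to emit (>= 1).
#' @param library `"ribo80s"`, `"pic"` or `"eif3"`.
#' @param seed Root seed; defaults to the config's seed.
#' @return A `footprint_reads` data frame with columns `transcript_id`,
#'   `start`, `end` (0-based half-open), `library` and `true_complex`
#'   (simulation ground truth: `cap_complex`, `scanning_pic` or `ribo80s`).
#' @export
snapshot_library <- function(annotation, config, n_reads_target,
                             library = c("eif3", "pic", "ribo80s"),
                             seed = NULL) {
  library <- match.arg(library)
  if (inherits(annotation, "transcript"))
    annotation <- transcriptome(list(annotation), name = annotation$id)
  stopifnot(inherits(annotation, "transcriptome"),
            inherits(config, "scan_config"), n_reads_target >= 1)
  seed <- seed %||% config$seed
  phase <- c(eif3 = 0L, pic = 1L, ribo80s = 2L)[[library]]
  txs <- annotation$transcripts
  nt <- length(txs)
  alloc <- rep(n_reads_target %/% nt, nt) +
    c(rep(1L, n_reads_target %% nt), rep(0L, nt - n_reads_target %% nt))
  out <- vector("list", nt)
  for (i in seq_len(nt)) {
    if (alloc[i] == 0L) next
    tx <- txs[[i]]
    wa <- walk_args(tx, config)
    if (is.null(wa)) next  # loading failure: counted by absence
    snaps <- config$snapshots_per_trajectory
    res <- withr_seed(per_transcript_seed(seed, tx$id),
      do.call(cpp_snapshot, c(wa, list(
        phase_filter = phase, snaps = snaps, n_reads_target = alloc[i],
        max_traj = 200L * (alloc[i] %/% snaps + 1L) + 100L,
        cap_mean = config$cap_complex_len[1], cap_sd = config$cap_complex_len[2],
        open_mean = config$pic_len_open[1], open_sd = config$pic_len_open[2],
        closed_mean = config$pic_len_closed[1],
        closed_sd = config$pic_len_closed[2], p_open = config$p_open,
        up_frac = config$channel_up_frac,
        r80_mean = config$ribo80s_len[1], r80_sd = config$ribo80s_len[2],
        r80_offset = config$ribo80s_p_offset,
        engage_dwell = config$engage_dwell, r80_dwell = config$ribo80s_dwell,
        osc_reach = config$osc_reach, osc_sd = config$osc_reach_sd,
        noise_sd = config$boundary_noise_sd))))
    if (length(res$start) == 0L) next
    out[[i]] <- data.frame(
      transcript_id = tx$id, start = res$start, end = res$end,
      library = library,
      true_complex = c("cap_complex", "scanning_pic", "ribo80s")[res$cls])
  }
  reads <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(reads))
    reads <- data.frame(transcript_id = character(), start = integer(),
                        end = integer(), library = character(),
                        true_complex = character())
  rownames(reads) <- NULL
  class(reads) <- c("footprint_reads", "data.frame")
  sp_log("simulator", "snapshot_library",
         list(library = library, n = nrow(reads), seed = seed))
  reads
}

## ---- read import/export -------------------------------------------------

#' Export footprint reads to BED6 or TSV
#'
#' BED6 uses the transcript id as the chromosome, the library class as the
#' name, score 0 and strand `+`; the simulation ground-truth column is
#' dropped. TSV keeps all columns when `keep_truth = TRUE`.
#'
#' @param reads A `footprint_reads` data frame.
#' @param path Output file.
#' @param format `"bed"` or `"tsv"`.
#' @param keep_truth Keep the `true_complex` column (TSV only).
#' @return The path, invisibly.
#' @export
export_reads <- function(reads, path, format = c("bed", "tsv"),
                         keep_truth = FALSE) {
  format <- match.arg(format)
  if (format == "bed") {
    df <- data.frame(chrom = reads$transcript_id, start = reads$start,
                     end = reads$end, name = reads$library, score = 0L,
                     strand = "+")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    cols <- c("transcript_id", "start", "end", "library",
              if (keep_truth) "true_complex")
    utils::write.table(as.data.frame(reads)[, cols, drop = FALSE], path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read footprint reads from BED6 or TSV
#'
#' @param path Input file (format auto-detected from the extension unless
#'   given).
#' @param format `"bed"` or `"tsv"`.
#' @return A `footprint_reads` data frame.
#' @export
read_reads <- function(path, format = c("auto", "bed", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path)) "bed" else "tsv"
  if (format == "bed") {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("chrom", "start", "end", "name",
                                          "score", "strand"),
                            colClasses = c("character", "integer", "integer",
                                           "character", "integer", "character"))
    reads <- data.frame(transcript_id = df$chrom, start = df$start,
                        end = df$end, library = df$name,
                        true_complex = NA_character_)
  } else {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = "character")
    if (!all(c("transcript_id", "start", "end", "library") %in% names(df)))
      stop("malformed reads TSV: missing required columns in header")
    reads <- data.frame(transcript_id = df$transcript_id,
                        start = as.integer(df$start),
                        end = as.integer(df$end), library = df$library,
                        true_complex = if ("true_complex" %in% names(df))
                          df$true_complex else NA_character_)
  }
  if (any(is.na(reads$start)) || any(reads$end <= reads$start))
    stop("malformed reads file: non-numeric or empty intervals")
  class(reads) <- c("footprint_reads", "data.frame")
  reads
}

#' Turn simulated reads into sequencing-style read sequences
#'
#' Extracts each fragment's sequence from its transcript (which must carry
#' sequences) and appends the 3' sequencing adapter, as an RNase-protected
#' fragment would appear after adapter ligation. Used to exercise the
#' trimming/length-filter stage on simulated libraries.
#'
#' @param reads A `footprint_reads` data frame.
#' @param annotation The [transcriptome()] the reads live on.
#' @param adapter Adapter appended 3' of each fragment (DNA or RNA alphabet).
#' @return Character vector of read sequences (RNA alphabet).
#' @export
reads_to_sequences <- function(reads, annotation,
                               adapter = "CTGTAGGCACCATCAAT") {
  adapter <- chartr("Tt", "Uu", toupper(adapter))
  seqs <- vapply(annotation$transcripts, function(t) {
    if (is.null(t$sequence)) stop("transcript '", t$id, "' has no sequence")
    t$sequence
  }, character(1))
  frag <- substring(seqs[reads$transcript_id], reads$start + 1L, reads$end)
  paste0(frag, adapter)
}
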