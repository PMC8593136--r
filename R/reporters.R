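#' Build a reporter construct
#'
#' Reproduces, in transcript coordinates, the reporter mRNAs used to probe
#' start-codon selection near the cap:
#'
#' * `ultra_short_utr`: a single AUG at position `utr5_len` (ultra-short
#'   5'UTRs of 2-20 nt probe the cap-proximal blind spot). The default
#'   context strength is suboptimal (no -3 purine in the real constructs).
#' * `two_aug_spacer`: two AUGs of identical context separated by a spacer of
#'   `spacer` nt between the end of AUG1 and the start of AUG2.
#' * `three_aug`: three AUGs at positions `first_aug`, `first_aug + 4`,
#'   `first_aug + 8` (a single G between codons), mutually out of frame, all
#'   within the first 12 nt of the transcript.
#' * `ires_entry`: an upstream ORF followed by an internal entry site placed
#'   `entry_distance` nt downstream of the uORF stop codon; the construct is
#'   translated cap-independently (`entry_site` set, no cap loading).
#'
#' @param kind One of `"ultra_short_utr"`, `"two_aug_spacer"`, `"three_aug"`,
#'   `"ires_entry"`.
#' @param ... Construct parameters, see Details.
#' @param utr5_len 5'UTR length (ultra_short_utr; also the position of AUG1
#'   for two_aug_spacer).
#' @param context Context strength of the (shared) AUGs.
#' @param cds_len CDS length in nt (multiple of 3).
#' @param utr3_len 3'UTR length in nt.
#' @param sequence Logical; generate a random sequence with planted AUGs.
#' @param id Transcript id.
#' @return A [transcript()] object.
#' @export
build_reporter <- function(kind, ..., utr5_len = NULL, context = NULL,
                           cds_len = 300L, utr3_len = 50L, sequence = FALSE,
                           id = NULL) {
  dots <- list(...)
  kind <- match.arg(kind, c("ultra_short_utr", "two_aug_spacer", "three_aug",
                            "ires_entry"))
  cds_len <- as.integer(cds_len)
  if (cds_len %% 3L != 0L) stop("cds_len must be a multiple of 3")
  tx <- switch(kind,
    ultra_short_utr = {
      u5 <- as.integer(utr5_len %||% 2L)
      if (u5 < 0L) stop("utr5_len must be >= 0")
      ctx <- context %||% 0.6  # suboptimal context, as in the real reporters
      transcript(id %||% sprintf("ultra_short_%dnt", u5),
                 length = u5 + cds_len + utr3_len,
                 cds_start = u5, cds_end = u5 + cds_len,
                 aug_sites = data.frame(pos = u5, context = ctx),
                 sequence = NULL)
    },
    two_aug_spacer = {
      d <- as.integer(dots$spacer %||% 4L)
      if (d < 0L) stop("spacer must be >= 0")
      u5 <- as.integer(utr5_len %||% 50L)
      ctx <- context %||% 1
      aug1 <- u5
      aug2 <- aug1 + 3L + d
      transcript(id %||% sprintf("two_aug_spacer_%dnt", d),
                 length = u5 + 3L + d + cds_len + utr3_len,
                 cds_start = aug1, cds_end = aug2 + cds_len,
                 aug_sites = data.frame(pos = c(aug1, aug2),
                                        context = c(ctx, ctx)))
    },
    three_aug = {
      p <- as.integer(dots$first_aug %||% 2L)
      if (p < 0L) stop("first_aug must be >= 0")
      pos <- p + c(0L, 4L, 8L)
      if (max(pos) > 11L)
        stop("geometrically impossible placement: AUGs must lie within the first 12 nt")
      ctx <- context %||% 1
      transcript(id %||% sprintf("three_aug_p%d", p),
                 length = p + 11L + cds_len + utr3_len,
                 cds_start = pos[1], cds_end = pos[1] + cds_len,
                 aug_sites = data.frame(pos = pos, context = rep(ctx, 3)))
    },
    ires_entry = {
      dist <- as.integer(dots$entry_distance %||% 6L)
      if (dist < 0L) stop("entry_distance must be >= 0")
      u5 <- as.integer(utr5_len %||% 30L)
      uorf_len <- as.integer(dots$uorf_len %||% 27L)  # SIINFEKL + stop
      if (uorf_len %% 3L != 0L) stop("uorf_len must be a multiple of 3")
      main_gap <- as.integer(dots$main_gap %||% 50L)
      ctx <- context %||% 1
      uorf_aug <- u5
      uorf_stop_end <- uorf_aug + uorf_len      # exclusive end of uORF stop
      entry <- uorf_stop_end + dist
      main_aug <- entry + main_gap
      transcript(id %||% sprintf("ires_entry_%dnt", dist),
                 length = main_aug + cds_len + utr3_len,
                 cds_start = main_aug, cds_end = main_aug + cds_len,
                 aug_sites = data.frame(pos = c(uorf_aug, main_aug),
                                        context = c(ctx, ctx)),
                 entry_site = entry)
    })
  if (sequence) {
    tx$sequence <- withr_seed(stable_hash(tx$id),
                              random_sequence(tx$length, tx$aug_sites$pos))
    validate_transcript(tx)
  }
  tx
}

`%||%` <- function(a, b) if (is.null(a)) b else a
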