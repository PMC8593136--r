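## The sequencing-side pipeline: adapter trimming and length filtering,
## region classification, length distributions, end-resolved metagene
## aggregation, mitochondria-normalized occupancy, 80S subtraction, and the
## rank-sum comparison used throughout the figures.

#' Trim the 3' adapter and filter reads by length
#'
#' Removes, from the 3' end of each read, the longest suffix that is a
#' prefix of the adapter (full internal occurrences are removed from the
#' leftmost match; partial adapter prefixes at the read end need at least
#' `min_overlap` matching bases). Trimming is iterated to a fixed point, so
#' applying the function twice equals applying it once. Reads whose trimmed
#' length falls outside `[min_len, max_len]` are discarded; untrimmable
#' reads pass through to the length filter. Matching is U/T-insensitive.
#'
#' @param raw_reads Character vector of read sequences.
#' @param adapter 3' adapter sequence (default the canonical ligation
#'   adapter used in ribosome-profiling libraries).
#' @param min_len,max_len Retained length window (nt); the alignment-stage
#'   defaults discard reads shorter than 15 or longer than 35 nt.
#' @param min_overlap Minimum adapter prefix length recognized at the read
#'   end.
#' @return Character vector of trimmed, length-filtered reads.
#' @export
trim_and_filter <- function(raw_reads, adapter = "CTGTAGGCACCATCAAT",
                            min_len = 15L, max_len = 35L, min_overlap = 5L) {
  if (!nzchar(adapter)) stop("adapter must be non-empty")
  ad <- chartr("Uu", "Tt", toupper(adapter))
  trimmed <- vapply(raw_reads, function(s) {
    x <- chartr("Uu", "Tt", toupper(s))
    repeat {
      n <- nchar(x)
      hit <- regexpr(ad, x, fixed = TRUE)[1]
      if (hit > 0L) { x <- substr(x, 1L, hit - 1L); next }
      cut <- 0L
      for (k in min(n, nchar(ad) - 1L):min_overlap) {
        if (k < min_overlap) break
        if (substr(x, n - k + 1L, n) == substr(ad, 1L, k)) { cut <- k; break }
      }
      if (cut == 0L) break
      x <- substr(x, 1L, n - cut)
    }
    x
  }, character(1), USE.NAMES = FALSE)
  keep <- nchar(trimmed) >= min_len & nchar(trimmed) <= max_len
  # restore the original alphabet of the untrimmed prefix
  out <- substr(raw_reads[keep], 1L, nchar(trimmed[keep]))
  out
}

#' Classify a read into a transcript region
#'
#' Regions form a partition with the fixed precedence
#' TSS > start_codon > UTR5 > CDS > UTR3: a read starting within
#' `tss_margin` nt of the cap is TSS; a read overlapping the start AUG
#' triplet is start_codon; a read wholly inside the 5'UTR is UTR5; the rest
#' are CDS or UTR3 by the read midpoint.
#'
#' @param reads A `footprint_reads` data frame (single transcript or many).
#' @param annotation A [transcriptome()] or single [transcript()].
#' @param tss_margin TSS class margin (nt) on the read start.
#' @return Factor of regions, one per read, levels
#'   `TSS, start_codon, UTR5, CDS, UTR3`.
#' @export
classify_read_region <- function(reads, annotation, tss_margin = 1L) {
  if (inherits(annotation, "transcript"))
    annotation <- transcriptome(list(annotation), name = annotation$id)
  txs <- annotation$transcripts
  lens <- vapply(txs, `[[`, integer(1), "length")[reads$transcript_id]
  cs <- vapply(txs, `[[`, integer(1), "cds_start")[reads$transcript_id]
  ce <- vapply(txs, `[[`, integer(1), "cds_end")[reads$transcript_id]
  if (any(is.na(lens)))
    stop("read on unknown transcript: ",
         reads$transcript_id[which(is.na(lens))[1]])
  if (any(reads$start < 0L | reads$end > lens | reads$end <= reads$start))
    stop("read interval outside its transcript")
  mid <- (reads$start + reads$end - 1L) / 2
  region <- ifelse(reads$start <= tss_margin, "TSS",
            ifelse(reads$start < cs + 3L & reads$end > cs, "start_codon",
            ifelse(reads$end <= cs, "UTR5",
            ifelse(mid < ce, "CDS", "UTR3"))))
  factor(region, levels = c("TSS", "start_codon", "UTR5", "CDS", "UTR3"))
}

#' Read-length distributions stratified by region
#'
#' One length histogram per region (TSS, 5'UTR, start codon, CDS, 3'UTR);
#' region counts sum to the total classified reads. Medians and modes break
#' ties toward the smaller length.
#'
#' @inheritParams classify_read_region
#' @return A list of `length_distribution` objects (fields `region`,
#'   `counts` named by length, `n`, `median`, `mode`), one per region.
#' @export
length_distribution_by_region <- function(reads, annotation, tss_margin = 1L) {
  regions <- levels(classify_read_region(reads[0, ], annotation, tss_margin))
  if (nrow(reads) == 0L) {
    return(lapply(stats::setNames(nm = regions), function(rg)
      structure(list(region = rg, counts = integer(0), n = 0L,
                     median = NA_integer_, mode = NA_integer_),
                class = "length_distribution")))
  }
  reg <- classify_read_region(reads, annotation, tss_margin)
  len <- reads$end - reads$start
  lapply(stats::setNames(nm = regions), function(rg) {
    l <- len[reg == rg]
    counts <- table(l)
    structure(list(region = rg,
                   counts = stats::setNames(as.integer(counts), names(counts)),
                   n = length(l),
                   median = if (length(l)) low_median(l) else NA_integer_,
                   mode = if (length(l)) mode_smallest(l) else NA_integer_),
              class = "length_distribution")
  })
}

## median with ties broken to the smaller length (lower median)
low_median <- function(x) sort(x)[ceiling(length(x) / 2)]

## modal value; ties broken to the smaller length
mode_smallest <- function(x) {
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])  # which.max takes the first = smallest
}

#' End-resolved metagene aggregation profile
#'
#' For each transcript, counts of selected read ends (5' or 3') at each
#' position relative to the anchor (TSS or start codon) are normalized by
#' the transcript's average reads -- total selected ends divided by
#' transcript length -- and the normalized counts at the same relative
#' position are averaged over transcripts. Transcripts without any selected
#' end are excluded. The 3' end of a read `[start, end)` is `end - 1`, the
#' last protected nucleotide.
#'
#' @inheritParams classify_read_region
#' @param anchor `"TSS"` (position 0) or `"start_codon"` (`cds_start`).
#' @param end_type `"five_prime"` or `"three_prime"`.
#' @param window Integer `c(lo, hi)` of relative positions (inclusive).
#' @return An `aggregation_profile`: `anchor`, `end_type`, `window`,
#'   `values` (named by relative position, length `hi - lo + 1`),
#'   `n_transcripts`.
#' @export
end_aggregation_profile <- function(reads, annotation,
                                    anchor = c("TSS", "start_codon"),
                                    end_type = c("five_prime", "three_prime"),
                                    window = c(-60L, 60L)) {
  anchor <- match.arg(anchor)
  end_type <- match.arg(end_type)
  if (inherits(annotation, "transcript"))
    annotation <- transcriptome(list(annotation), name = annotation$id)
  lo <- as.integer(window[1]); hi <- as.integer(window[2])
  if (lo >= hi) stop("window must satisfy lo < hi")
  txs <- annotation$transcripts
  ids <- names(txs)
  anchors <- if (anchor == "TSS") stats::setNames(rep(0L, length(ids)), ids)
             else vapply(txs, `[[`, integer(1), "cds_start")
  lens <- vapply(txs, `[[`, integer(1), "length")
  endpos <- if (end_type == "five_prime") reads$start else reads$end - 1L
  tid <- factor(reads$transcript_id, levels = ids)
  ends_per_tx <- tabulate(tid, nbins = length(ids))
  m <- ends_per_tx / lens                       # average reads per nt
  rel <- endpos - anchors[as.character(tid)]
  inw <- !is.na(rel) & rel >= lo & rel <= hi
  width <- hi - lo + 1L
  cmat <- matrix(0, nrow = length(ids), ncol = width)
  if (any(inw)) {
    ij <- cbind(as.integer(tid)[inw], rel[inw] - lo + 1L)
    agg <- table(factor(ij[, 1], levels = seq_along(ids)),
                 factor(ij[, 2], levels = seq_len(width)))
    cmat <- matrix(as.numeric(agg), nrow = length(ids))
  }
  inc <- m > 0
  if (!any(inc)) stop("no transcript with coverage; cannot aggregate")
  values <- colMeans(cmat[inc, , drop = FALSE] / m[inc])
  names(values) <- as.character(lo:hi)
  structure(list(anchor = anchor, end_type = end_type, window = c(lo, hi),
                 values = values, n_transcripts = sum(inc)),
            class = "aggregation_profile")
}

#' @export
print.aggregation_profile <- function(x, ...) {
  pk <- which.max(x$values)
  cat(sprintf(
    "<aggregation_profile> %s-anchored %s ends, window [%d, %d], %d transcripts, peak %.3g at %s\n",
    x$anchor, sub("_", " ", x$end_type), x$window[1], x$window[2],
    x$n_transcripts, x$values[pk], names(x$values)[pk]))
  invisible(x)
}

#' Mitochondria-normalized ribosome density (RPKM) per transcript
#'
#' Scales a sample's counts by `reference_mito_count / sample_mito_count`
#' (mitochondrial reads as the between-sample yardstick, insensitive to
#' global translational shifts), then computes RPKM over the CDS (reads per
#' kilobase of CDS per million mapped reads). Transcripts with RPKM < 1 are
#' flagged excluded; RPKM exactly 1 is kept.
#'
#' @inheritParams classify_read_region
#' @param reference_mito_count Mitochondrial read count of the reference
#'   sample; defaults to this sample's own count (scale 1).
#' @return An `occupancy_table` data frame: `transcript_id`, `cds_reads`,
#'   `scaled_cds_reads`, `rpkm`, `included`.
#' @export
mito_normalized_density <- function(reads, annotation,
                                    reference_mito_count = NULL) {
  txs <- annotation$transcripts
  is_mito <- vapply(txs, `[[`, logical(1), "is_mito")
  mito_ids <- names(txs)[is_mito]
  cyto_ids <- names(txs)[!is_mito]
  mito_count <- sum(reads$transcript_id %in% mito_ids)
  if (!is.null(reference_mito_count) && mito_count == 0L)
    stop("no reads on mitochondrial transcripts; mitochondrial normalization ",
         "needs at least one mito transcript with reads in each sample")
  s <- if (is.null(reference_mito_count)) 1 else reference_mito_count / mito_count
  cyto <- reads[reads$transcript_id %in% cyto_ids, , drop = FALSE]
  mid <- (cyto$start + cyto$end - 1L) / 2
  cs <- vapply(txs, `[[`, integer(1), "cds_start")[cyto$transcript_id]
  ce <- vapply(txs, `[[`, integer(1), "cds_end")[cyto$transcript_id]
  in_cds <- mid >= cs & mid < ce
  cds_counts <- table(factor(cyto$transcript_id[in_cds], levels = cyto_ids))
  total_mapped <- nrow(cyto)
  cds_kb <- vapply(txs[cyto_ids], function(t) (t$cds_end - t$cds_start) / 1000,
                   numeric(1))
  rpkm <- (s * as.numeric(cds_counts)) /
    (cds_kb * (s * total_mapped / 1e6))
  out <- data.frame(transcript_id = cyto_ids,
                    cds_reads = as.integer(cds_counts),
                    scaled_cds_reads = s * as.numeric(cds_counts),
                    rpkm = rpkm,
                    included = rpkm >= 1)
  rownames(out) <- NULL
  class(out) <- c("occupancy_table", "data.frame")
  out
}

#' 5'UTR / CDS occupancy ratio per transcript
#'
#' Uses CDS read density as the internal control for 5'UTR ribosome
#' occupancy: `ratio = (UTR5 reads / UTR5 length) / (CDS reads / CDS
#' length)`, with the analogous 3'UTR-controlled ratio as an alternative.
#' Reads are assigned by midpoint. Ratios are `NA` (flagged undefined) when
#' the control density is zero.
#'
#' @inheritParams classify_read_region
#' @return An `occupancy_table` data frame: per transcript the region read
#'   counts, `utr5_cds_ratio`, `utr5_utr3_ratio` and a `defined` flag.
#' @export
utr5_cds_occupancy <- function(reads, annotation) {
  txs <- annotation$transcripts
  ids <- names(txs)
  cs <- vapply(txs, `[[`, integer(1), "cds_start")
  ce <- vapply(txs, `[[`, integer(1), "cds_end")
  len <- vapply(txs, `[[`, integer(1), "length")
  mid <- (reads$start + reads$end - 1L) / 2
  tid <- factor(reads$transcript_id, levels = ids)
  zone <- ifelse(mid < cs[as.character(tid)], "u5",
          ifelse(mid < ce[as.character(tid)], "cds", "u3"))
  cnt <- function(z) as.numeric(table(tid[zone == z]))
  u5 <- cnt("u5"); cds <- cnt("cds"); u3 <- cnt("u3")
  u5_len <- pmax(cs, 1L); cds_len <- ce - cs; u3_len <- pmax(len - ce, 1L)
  dens_u5 <- u5 / u5_len; dens_cds <- cds / cds_len; dens_u3 <- u3 / u3_len
  ratio <- ifelse(dens_cds > 0, dens_u5 / dens_cds, NA_real_)
  ratio_alt <- ifelse(dens_u3 > 0, dens_u5 / dens_u3, NA_real_)
  out <- data.frame(transcript_id = ids, utr5_reads = u5, cds_reads = cds,
                    utr3_reads = u3, utr5_cds_ratio = ratio,
                    utr5_utr3_ratio = ratio_alt, defined = !is.na(ratio))
  rownames(out) <- NULL
  class(out) <- c("occupancy_table", "data.frame")
  out
}

#' Computationally subtract 80S footprints from a mixed library
#'
#' Enriches scanning-PIC footprints by removing the 80S component of a mixed
#' (eIF3-like) library. With `strategy = "matched_counts"`, per-transcript
#' counts at each (position, length) are reduced by `scale` times the
#' matched 80S-library counts, floored at zero, and re-expanded to reads.
#' With `strategy = "length_gate"`, reads within `gate_halfwidth` nt of the
#' 80S modal length are dropped. `scale` defaults to the ratio of
#' start-codon-region totals between the two libraries.
#'
#' @param eif3_reads,ribo80s_reads `footprint_reads` on the same annotation.
#' @param annotation The shared [transcriptome()].
#' @param scale Subtraction factor; `NULL` for the start-codon-total default.
#' @param strategy `"matched_counts"` or `"length_gate"`.
#' @param gate_halfwidth Half-width (nt) of the modal-length gate.
#' @return A `footprint_reads` data frame of PIC-enriched reads.
#' @export
subtract_80s <- function(eif3_reads, ribo80s_reads, annotation, scale = NULL,
                         strategy = c("matched_counts", "length_gate"),
                         gate_halfwidth = 2L) {
  strategy <- match.arg(strategy)
  if (nrow(ribo80s_reads) == 0L) {
    warning("empty 80S read set; returning the input unchanged")
    return(eif3_reads)
  }
  if (strategy == "length_gate") {
    modal <- mode_smallest(ribo80s_reads$end - ribo80s_reads$start)
    len <- eif3_reads$end - eif3_reads$start
    return(eif3_reads[abs(len - modal) > gate_halfwidth, , drop = FALSE])
  }
  if (is.null(scale)) {
    # per-transcript default: transcripts differ widely in their 80S share,
    # so one global factor under-subtracts high-occupancy transcripts
    reg_a <- classify_read_region(eif3_reads, annotation)
    reg_b <- classify_read_region(ribo80s_reads, annotation)
    n_a <- table(factor(eif3_reads$transcript_id[reg_a == "start_codon"],
                        levels = names(annotation$transcripts)))
    n_b <- table(factor(ribo80s_reads$transcript_id[reg_b == "start_codon"],
                        levels = names(annotation$transcripts)))
    scale <- ifelse(as.numeric(n_b) > 0, as.numeric(n_a) / as.numeric(n_b), 1)
    names(scale) <- names(n_a)
  }
  key <- function(r) paste(r$transcript_id, r$start, r$end, sep = "\r")
  ka <- key(eif3_reads); kb <- key(ribo80s_reads)
  ta <- table(ka); tb <- table(kb)
  tx_of <- sub("\r.*", "", names(ta))
  s_vec <- if (length(scale) == 1L) rep(scale, length(ta))
           else scale[tx_of] %+na% 1
  # fractional subtraction rounds down: enrichment errs on the side of
  # removing contamination wherever the 80S library covers the combination
  sub <- s_vec * as.numeric(tb[names(ta)] %+na% 0)
  keep <- pmax(0, floor(as.numeric(ta) - sub + 1e-9))
  idx <- rep(seq_along(ta), keep)
  uniq <- eif3_reads[match(names(ta), ka), , drop = FALSE]
  out <- uniq[idx, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("footprint_reads", "data.frame")
  out
}

## table lookup with NA -> default
`%+na%` <- function(x, default) {
  x <- as.numeric(x)
  x[is.na(x)] <- default
  x
}

#' Two-sided rank-sum comparison of two samples
#'
#' Wilcoxon rank-sum test (standard implementation) with the direction of
#' the median difference reported.
#'
#' @param sample_a,sample_b Numeric samples (non-empty).
#' @return List with `statistic`, `p_value`, `direction` (`"a>b"`, `"b>a"`
#'   or `"none"`) and `degenerate` (all values tied).
#' @export
compare_distributions <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b)) stop("both samples must be non-empty")
  degenerate <- length(unique(c(sample_a, sample_b))) == 1L
  if (degenerate)
    return(list(statistic = NA_real_, p_value = 1, direction = "none",
                degenerate = TRUE))
  wt <- stats::wilcox.test(sample_a, sample_b, exact = FALSE)
  ma <- stats::median(sample_a); mb <- stats::median(sample_b)
  direction <- if (ma > mb) "a>b" else if (mb > ma) "b>a" else "none"
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       direction = direction, degenerate = FALSE)
}
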