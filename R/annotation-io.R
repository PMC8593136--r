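## Annotation files: BED12 in transcript space (the transcript id doubles as
## the chromosome; thickStart/thickEnd carry the CDS), a TSV sidecar with the
## AUG sites, context strengths and flags, and an optional FASTA with the
## sequences. write -> read is the identity.

#' Write / read a transcriptome annotation
#'
#' `write_annotation()` emits `<prefix>.bed` (BED12, one line per
#' transcript), `<prefix>.sites.tsv` (header `transcript_id, aug_pos,
#' context, is_mito, entry_site`, one row per AUG site, with the annotation
#' name and seed in `#`-comment header lines) and, when sequences are
#' present, `<prefix>.fa`. `read_annotation()` reverses it exactly.
#'
#' @param annotation A [transcriptome()].
#' @param prefix Path prefix for the three files.
#' @return `write_annotation` returns the prefix invisibly;
#'   `read_annotation` returns a [transcriptome()].
#' @export
write_annotation <- function(annotation, prefix) {
  stopifnot(inherits(annotation, "transcriptome"))
  txs <- annotation$transcripts
  bed <- vapply(txs, function(t) paste(
    t$id, 0L, t$length, t$id, 0L, "+", t$cds_start, t$cds_end, 0L,
    1L, paste0(t$length, ","), "0,", sep = "\t"), character(1))
  writeLines(bed, paste0(prefix, ".bed"))
  con <- file(paste0(prefix, ".sites.tsv"), "w")
  on.exit(close(con))
  writeLines(c(sprintf("# name=%s", annotation$name),
               sprintf("# seed=%s", annotation$seed),
               paste("transcript_id", "aug_pos", "context", "is_mito",
                     "entry_site", sep = "\t")), con)
  for (t in txs) {
    writeLines(paste(t$id, t$aug_sites$pos,
                     formatC(t$aug_sites$context, digits = 17, format = "g"),
                     as.integer(t$is_mito),
                     ifelse(is.na(t$entry_site), "NA", t$entry_site),
                     sep = "\t"), con)
  }
  has_seq <- vapply(txs, function(t) !is.null(t$sequence), logical(1))
  if (any(has_seq)) {
    seqs <- Biostrings::RNAStringSet(
      vapply(txs[has_seq], `[[`, character(1), "sequence"))
    names(seqs) <- names(txs)[has_seq]
    Biostrings::writeXStringSet(seqs, paste0(prefix, ".fa"))
  }
  invisible(prefix)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(prefix) {
  bed_path <- paste0(prefix, ".bed")
  tsv_path <- paste0(prefix, ".sites.tsv")
  if (!file.exists(bed_path)) stop("missing annotation file: ", bed_path)
  if (!file.exists(tsv_path)) stop("missing annotation file: ", tsv_path)
  bed_lines <- readLines(bed_path)
  bed <- lapply(seq_along(bed_lines), function(i) {
    f <- strsplit(bed_lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 12L)
      stop(sprintf("malformed BED12 at %s line %d: %d fields", bed_path, i,
                   length(f)))
    f
  })
  tsv_lines <- readLines(tsv_path)
  hdr <- grep("^#", tsv_lines)
  meta <- sub("^# ", "", tsv_lines[hdr])
  name <- sub("^name=", "", meta[startsWith(meta, "name=")])
  seed <- suppressWarnings(as.integer(
    sub("^seed=", "", meta[startsWith(meta, "seed=")])))
  body <- tsv_lines[-hdr]
  if (!length(body) || body[1] != paste("transcript_id", "aug_pos", "context",
                                        "is_mito", "entry_site", sep = "\t"))
    stop("malformed sites TSV at ", tsv_path, " line ", length(hdr) + 1L,
         ": bad header row")
  rows <- lapply(seq_along(body[-1]), function(i) {
    f <- strsplit(body[-1][i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 5L)
      stop(sprintf("malformed sites TSV at %s line %d: %d fields", tsv_path,
                   i + length(hdr) + 1L, length(f)))
    f
  })
  sites <- data.frame(
    transcript_id = vapply(rows, `[`, character(1), 1),
    aug_pos = as.integer(vapply(rows, `[`, character(1), 2)),
    context = as.numeric(vapply(rows, `[`, character(1), 3)),
    is_mito = vapply(rows, `[`, character(1), 4) == "1",
    entry_site = suppressWarnings(
      as.integer(vapply(rows, `[`, character(1), 5))))
  seqs <- NULL
  fa_path <- paste0(prefix, ".fa")
  if (file.exists(fa_path)) {
    ss <- Biostrings::readBStringSet(fa_path)
    seqs <- stats::setNames(as.character(ss), names(ss))
    bad <- grepl("[^ACGU]", seqs)
    if (any(bad))
      stop("FASTA parse error in ", fa_path, ": non-ACGU character in record '",
           names(seqs)[bad][1], "'")
  }
  txs <- lapply(bed, function(f) {
    id <- f[1]
    sx <- sites[sites$transcript_id == id, , drop = FALSE]
    if (nrow(sx) == 0L)
      stop("sites TSV ", tsv_path, " has no rows for transcript '", id, "'")
    transcript(id, length = as.integer(f[3]),
               cds_start = as.integer(f[7]), cds_end = as.integer(f[8]),
               aug_sites = data.frame(pos = sx$aug_pos, context = sx$context),
               is_mito = sx$is_mito[1], entry_site = sx$entry_site[1],
               sequence = if (!is.null(seqs) && id %in% names(seqs))
                 seqs[[id]] else NULL)
  })
  transcriptome(txs, name = name, seed = seed)
}
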