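#' Construct a transcript in transcript-space coordinates
#'
#' A transcript is the coordinate unit of the whole package: positions are
#' 0-based, half-open, with position 0 being the transcription start site
#' (TSS), treated as synonymous with the 5' cap. The 5'UTR is `[0, cds_start)`,
#' the CDS `[cds_start, cds_end)` and the 3'UTR `[cds_end, length)`.
#'
#' @param id Transcript identifier (unique within an annotation).
#' @param length Transcript length in nucleotides.
#' @param cds_start 0-based position of the A of the annotated start AUG.
#' @param cds_end 0-based exclusive end of the CDS.
#' @param aug_sites Data frame with columns `pos` (0-based AUG positions,
#'   ascending) and `context` (recognition context strength in `[0, 1]`,
#'   an abstraction of Kozak context). Must contain `cds_start`.
#' @param is_mito Logical, mitochondrial transcript flag (used for
#'   between-sample normalization of read counts).
#' @param entry_site Optional 0-based position of internal (IRES-like) PIC
#'   entry, or `NA` for cap-dependent transcripts.
#' @param sequence Optional nucleotide string (RNA alphabet `ACGU`); when
#'   present it must carry `AUG` at every listed AUG site.
#'
#' @return An object of class `transcript`.
#' @export
transcript <- function(id, length, cds_start, cds_end, aug_sites = NULL,
                       is_mito = FALSE, entry_site = NA_integer_,
                       sequence = NULL) {
  length <- as.integer(length)
  cds_start <- as.integer(cds_start)
  cds_end <- as.integer(cds_end)
  if (is.null(aug_sites)) {
    aug_sites <- data.frame(pos = cds_start, context = 1)
  }
  aug_sites <- data.frame(pos = as.integer(aug_sites$pos),
                          context = as.numeric(aug_sites$context))
  aug_sites <- aug_sites[order(aug_sites$pos), , drop = FALSE]
  rownames(aug_sites) <- NULL
  tx <- structure(
    list(id = as.character(id), length = length, cds_start = cds_start,
         cds_end = cds_end, aug_sites = aug_sites, is_mito = isTRUE(is_mito),
         entry_site = as.integer(entry_site), sequence = sequence),
    class = "transcript")
  validate_transcript(tx)
  tx
}

validate_transcript <- function(tx) {
  stopifnot(inherits(tx, "transcript"))
  if (!(0 <= tx$cds_start && tx$cds_start < tx$cds_end && tx$cds_end <= tx$length))
    stop("transcript '", tx$id, "': need 0 <= cds_start < cds_end <= length")
  a <- tx$aug_sites
  if (nrow(a) == 0L) stop("transcript '", tx$id, "': no AUG sites")
  if (is.unsorted(a$pos)) stop("transcript '", tx$id, "': aug_sites not sorted")
  if (anyDuplicated(a$pos)) stop("transcript '", tx$id, "': duplicated AUG positions")
  if (any(a$pos < 0L | a$pos > tx$length - 3L))
    stop("transcript '", tx$id, "': AUG position outside [0, length-3]")
  if (any(a$context < 0 | a$context > 1))
    stop("transcript '", tx$id, "': context strength outside [0, 1]")
  if (!tx$cds_start %in% a$pos)
    stop("transcript '", tx$id, "': cds_start missing from aug_sites")
  if (!is.na(tx$entry_site) && (tx$entry_site < 0L || tx$entry_site > tx$length - 3L))
    stop("transcript '", tx$id, "': entry_site outside transcript")
  if (!is.null(tx$sequence)) {
    if (nchar(tx$sequence) != tx$length)
      stop("transcript '", tx$id, "': sequence length != length")
    if (grepl("[^ACGU]", tx$sequence))
      stop("transcript '", tx$id, "': sequence has non-ACGU characters")
    cods <- substring(tx$sequence, a$pos + 1L, a$pos + 3L)
    if (any(cods != "AUG"))
      stop("transcript '", tx$id, "': sequence lacks AUG at a listed site")
  }
  invisible(tx)
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript %s> length %d nt, CDS [%d, %d), %d AUG site(s)%s%s\n",
              x$id, x$length, x$cds_start, x$cds_end, nrow(x$aug_sites),
              if (x$is_mito) ", mitochondrial" else "",
              if (!is.na(x$entry_site)) sprintf(", internal entry at %d", x$entry_site) else ""))
  invisible(x)
}

utr5_length <- function(tx) tx$cds_start
utr3_length <- function(tx) tx$length - tx$cds_end

#' Bundle transcripts into an annotation
#'
#' @param transcripts List of [transcript()] objects with unique ids.
#' @param name Annotation name.
#' @param seed Integer seed recorded with the annotation (the seed used to
#'   generate it, or `NA` for hand-built sets).
#' @return An object of class `transcriptome`.
#' @export
transcriptome <- function(transcripts, name = "annotation", seed = NA_integer_) {
  ids <- vapply(transcripts, function(t) t$id, character(1))
  if (anyDuplicated(ids)) stop("transcript ids are not unique")
  names(transcripts) <- ids
  structure(list(transcripts = transcripts, name = name,
                 seed = as.integer(seed)),
            class = "transcriptome")
}

#' @export
print.transcriptome <- function(x, ...) {
  n_mito <- sum(vapply(x$transcripts, function(t) t$is_mito, logical(1)))
  cat(sprintf("<transcriptome '%s'> %d transcripts (%d mitochondrial), seed %s\n",
              x$name, length(x$transcripts), n_mito,
              ifelse(is.na(x$seed), "NA", x$seed)))
  invisible(x)
}

#' @export
length.transcriptome <- function(x) length(x$transcripts)

## ---- distribution specs -------------------------------------------------

#' Length sampler specification
#'
#' Samplers for UTR/CDS lengths are given as flat lists:
#' `list(dist = "fixed", value = )`, `list(dist = "lognormal", meanlog = ,
#' sdlog = )` or `list(dist = "uniform", min = , max = )`. Draws are rounded
#' to non-negative integers.
#'
#' @param spec Sampler specification list.
#' @return A function of `n` returning `n` integer lengths.
#' @keywords internal
make_sampler <- function(spec) {
  if (!is.list(spec) || is.null(spec$dist))
    stop("invalid sampler spec: expected list(dist = ...)")
  switch(spec$dist,
    fixed = {
      if (is.null(spec$value)) stop("invalid sampler spec: fixed needs 'value'")
      v <- as.integer(round(spec$value))
      function(n) rep.int(v, n)
    },
    lognormal = {
      if (is.null(spec$meanlog) || is.null(spec$sdlog))
        stop("invalid sampler spec: lognormal needs 'meanlog' and 'sdlog'")
      function(n) as.integer(round(stats::rlnorm(n, spec$meanlog, spec$sdlog)))
    },
    uniform = {
      if (is.null(spec$min) || is.null(spec$max))
        stop("invalid sampler spec: uniform needs 'min' and 'max'")
      function(n) as.integer(round(stats::runif(n, spec$min, spec$max)))
    },
    stop("invalid sampler spec: unknown dist '", spec$dist, "'")
  )
}

#' Lognormal spec with a given mean (nt) and log-scale sd
#' @param mean Target mean length in nt.
#' @param sdlog Log-scale standard deviation.
#' @return A sampler spec list.
#' @export
lognormal_around <- function(mean, sdlog = 0.6) {
  list(dist = "lognormal", meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

## ---- generator ----------------------------------------------------------

#' Generate a synthetic single-isoform transcriptome
#'
#' Emulates a one-mRNA-per-gene transcript set in transcript coordinates.
#' Each transcript gets a 5'UTR, CDS and 3'UTR length from the supplied
#' samplers, an annotated start AUG at `cds_start` with a context strength
#' drawn from `context_range`, and optionally decoy (upstream, mostly weak)
#' AUGs planted in the 5'UTR at rate `decoy_aug_rate` per nucleotide. A fixed
#' fraction of transcripts is flagged mitochondrial (deterministic count,
#' `max(1, round(mito_fraction * n))` when the fraction is positive).
#'
#' The default 5'UTR sampler is lognormal with mean 200 nt, the typical
#' mammalian 5'UTR length.
#'
#' @param n_transcripts Number of transcripts (>= 1).
#' @param utr5_len_sampler,cds_len_sampler,utr3_len_sampler Sampler specs,
#'   see [make_sampler()].
#' @param mito_fraction Proportion of mitochondrial transcripts in `[0, 1)`.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param context_range Range for the annotated start's context strength.
#' @param decoy_aug_rate Per-nucleotide rate of decoy AUGs in the 5'UTR
#'   (default 0 = off); decoy context strengths are drawn from
#'   `decoy_context_range`.
#' @param decoy_context_range Range of decoy AUG context strengths.
#' @param sequences Logical; also generate random ACGU sequences with AUG
#'   planted at every annotated site.
#' @return A [transcriptome()] object.
#' @export
generate_transcriptome <- function(n_transcripts,
                                   utr5_len_sampler = lognormal_around(200),
                                   cds_len_sampler = lognormal_around(1200, 0.5),
                                   utr3_len_sampler = lognormal_around(500, 0.6),
                                   mito_fraction = 0,
                                   seed = 1L,
                                   context_range = c(0.6, 1),
                                   decoy_aug_rate = 0,
                                   decoy_context_range = c(0.02, 0.1),
                                   sequences = FALSE) {
  stopifnot(n_transcripts >= 1, mito_fraction >= 0, mito_fraction < 1)
  s5 <- make_sampler(utr5_len_sampler)
  sc <- make_sampler(cds_len_sampler)
  s3 <- make_sampler(utr3_len_sampler)
  n_mito <- if (mito_fraction > 0) max(1L, as.integer(round(mito_fraction * n_transcripts))) else 0L
  withr_seed(seed, {
    u5 <- pmax(0L, s5(n_transcripts))
    cds <- pmax(6L, sc(n_transcripts))
    cds <- cds - cds %% 3L  # whole codons
    u3 <- pmax(0L, s3(n_transcripts))
    ctx <- stats::runif(n_transcripts, context_range[1], context_range[2])
    txs <- vector("list", n_transcripts)
    for (i in seq_len(n_transcripts)) {
      mito <- i > n_transcripts - n_mito
      id <- if (mito) sprintf("mt_tx%04d", i) else sprintf("tx%04d", i)
      len <- u5[i] + cds[i] + u3[i]
      sites <- data.frame(pos = u5[i], context = ctx[i])
      if (decoy_aug_rate > 0 && u5[i] > 3L) {
        nd <- stats::rpois(1, decoy_aug_rate * u5[i])
        if (nd > 0) {
          dp <- sort(unique(sample.int(u5[i] - 3L, min(nd, u5[i] - 3L)) - 1L))
          # keep decoys at least one codon apart so planted AUGs never overlap
          keep <- logical(length(dp))
          last <- -3L
          for (j in seq_along(dp)) {
            if (dp[j] - last >= 3L) { keep[j] <- TRUE; last <- dp[j] }
          }
          dp <- dp[keep]
          if (length(dp))
            sites <- rbind(data.frame(
              pos = dp,
              context = stats::runif(length(dp), decoy_context_range[1],
                                     decoy_context_range[2])), sites)
        }
      }
      sq <- if (sequences) random_sequence(len, sites$pos) else NULL
      txs[[i]] <- transcript(id, len, u5[i], u5[i] + cds[i], sites,
                             is_mito = mito, sequence = sq)
    }
    transcriptome(txs, name = sprintf("synthetic_n%d_seed%d", n_transcripts, seed),
                  seed = seed)
  })
}

## random RNA sequence with AUG planted at the given 0-based sites
random_sequence <- function(len, aug_pos) {
  s <- sample(c("A", "C", "G", "U"), len, replace = TRUE)
  for (p in aug_pos) s[(p + 1L):(p + 3L)] <- c("A", "U", "G")
  paste(s, collapse = "")
}

## evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## stable non-negative integer hash of a string (for per-transcript RNG streams)
stable_hash <- function(x) {
  h <- 0
  for (code in utf8ToInt(x)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

per_transcript_seed <- function(root_seed, id) {
  as.integer((as.numeric(root_seed) + stable_hash(id)) %% 2147483647)
}
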