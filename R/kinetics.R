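## Exact and Monte-Carlo start-codon selection.
##
## The scanning walk is a finite Markov chain on states (position, eIF4E
## flag) with absorbing states for commitment at each AUG, dropoff, and
## runoff. Commitment is an exit probability at AUG-occupying states
## (geometric per visit), so the competition between neighbouring AUGs --
## a downstream codon draining an upstream one through back-and-forth
## excursions -- is computed exactly by a sparse direct solve.

#' Exact absorption probabilities for start-codon selection
#'
#' Builds the transition matrix of the scanning walk defined by the
#' configuration (identical event order to the simulator: commitment check,
#' dropoff, eIF4E release, move with reflecting floor and runoff absorber)
#' and solves the linear absorption system directly. No sampling is
#' involved; the per-outcome probabilities sum to one within 1e-9.
#'
#' @param transcript A [transcript()].
#' @param config A [scan_config()].
#' @return A `selection_result`: `per_aug` (named by AUG position),
#'   `p_runoff`, `p_dropoff`, `method = "oracle"`.
#' @export
absorption_oracle <- function(transcript, config) {
  wa <- walk_args(transcript, config)
  if (is.null(wa)) stop("loading failure: transcript too short for slot-in")
  pmax <- wa$pmax
  if (wa$entry >= pmax) stop("entry position at or past the runoff boundary")
  n_aug <- length(wa$aug_pos)
  r <- numeric(pmax)
  live <- wa$aug_pos < pmax
  r[wa$aug_pos[live] + 1L] <- wa$aug_r[live]
  aug_col <- integer(pmax)
  aug_col[wa$aug_pos[live] + 1L] <- which(live)
  d <- wa$dropoff_rate
  rho <- wa$release_rate
  n_states <- 2L * pmax                      # (p, bound) pairs
  idx <- function(p, b) p + 1L + b * pmax
  n_abs <- n_aug + 2L                        # + dropoff + runoff
  ti <- tj <- integer(0); tx <- numeric(0)   # transient -> transient
  ri <- rj <- integer(0); rx <- numeric(0)   # transient -> absorbing
  add_t <- function(i, j, v) { ti[[length(ti) + 1L]] <<- i
    tj[[length(tj) + 1L]] <<- j; tx[[length(tx) + 1L]] <<- v }
  add_r <- function(i, k, v) { ri[[length(ri) + 1L]] <<- i
    rj[[length(rj) + 1L]] <<- k; rx[[length(rx) + 1L]] <<- v }
  for (b in 0:1) {
    if (b == 1L && !wa$bound0) next
    for (p in 0:(pmax - 1L)) {
      i <- idx(p, b)
      rp <- r[p + 1L]
      if (rp > 0) add_r(i, aug_col[p + 1L], rp)
      m <- 1 - rp
      if (d > 0) add_r(i, n_aug + 1L, m * d)
      m <- m * (1 - d)
      branches <- if (b == 1L && !wa$tethered && rho > 0)
        list(c(0L, m * rho), c(1L, m * (1 - rho)))
      else list(c(b, m))
      for (br in branches) {
        b2 <- br[1]; w <- br[2]
        if (w == 0) next
        mob <- if (b2 == 1L) wa$bound_mobility else 1
        pb <- wa$p_back * mob; pf <- wa$p_fwd * mob
        floorpos <- if (b2 == 1L && wa$slot_floor) wa$cap_offset else 0L
        back_to <- if (p - 1L >= floorpos) p - 1L else p
        if (pb > 0) add_t(i, idx(back_to, b2), w * pb)
        stay <- 1 - pb - pf
        if (stay > 0) add_t(i, idx(p, b2), w * stay)
        if (p + 1L >= pmax) add_r(i, n_aug + 2L, w * pf)
        else add_t(i, idx(p + 1L, b2), w * pf)
      }
    }
  }
  Q <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(n_states, n_states))
  R <- Matrix::sparseMatrix(i = unlist(ri), j = unlist(rj), x = unlist(rx),
                            dims = c(n_states, n_abs))
  A <- Matrix::Diagonal(n_states) - Q
  e <- numeric(n_states)
  e[idx(wa$entry, as.integer(wa$bound0))] <- 1
  y <- tryCatch(Matrix::solve(Matrix::t(A), e),
                error = function(err) stop(
                  "singular absorption system (no absorbing path reachable): ",
                  conditionMessage(err)))
  probs <- as.numeric(Matrix::crossprod(R, y))
  per_aug <- numeric(n_aug)
  per_aug[seq_len(n_aug)] <- probs[seq_len(n_aug)]
  names(per_aug) <- as.character(wa$aug_pos)
  res <- structure(list(per_aug = per_aug,
                        p_dropoff = probs[n_aug + 1L],
                        p_runoff = probs[n_aug + 2L],
                        method = "oracle", n_trajectories = NA_integer_,
                        standard_errors = NULL),
                   class = "selection_result")
  tot <- sum(per_aug) + res$p_dropoff + res$p_runoff
  if (abs(tot - 1) > 1e-9)
    stop(sprintf("absorption probabilities sum to %.12f, not 1", tot))
  res
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> method %s%s\n", x$method,
              if (!is.na(x$n_trajectories))
                sprintf(" (n = %d)", x$n_trajectories) else ""))
  for (nm in names(x$per_aug))
    cat(sprintf("  AUG @ %s: %.6g%s\n", nm, x$per_aug[[nm]],
                if (!is.null(x$standard_errors))
                  sprintf(" (se %.3g)", x$standard_errors[[nm]]) else ""))
  cat(sprintf("  runoff %.6g, dropoff %.6g%s\n", x$p_runoff, x$p_dropoff,
              if (!is.null(x$p_censored) && x$p_censored > 0)
                sprintf(", censored %.3g (excluded)", x$p_censored) else ""))
  invisible(x)
}

#' Monte-Carlo twin of the absorption oracle
#'
#' Runs `n_trajectories` scanning trajectories and estimates the per-AUG
#' commitment probabilities with binomial standard errors. Censored
#' trajectories (trajectory cap reached) are excluded from the denominator
#' and reported separately as `p_censored`.
#'
#' @inheritParams absorption_oracle
#' @param n_trajectories Number of trajectories (>= 1).
#' @param seed RNG seed.
#' @return A `selection_result` with `method = "monte_carlo"`.
#' @export
selection_mc <- function(transcript, config, n_trajectories = 1e4,
                         seed = NULL) {
  stopifnot(n_trajectories >= 1)
  wa <- walk_args(transcript, config)
  if (is.null(wa)) stop("loading failure: transcript too short for slot-in")
  seed <- seed %||% config$seed
  res <- withr_seed(seed,
    do.call(cpp_trajectories, c(wa, list(n_traj = as.integer(n_trajectories),
                                         want_dwell = FALSE,
                                         want_trace = FALSE))))
  n_cens <- sum(res$outcome == -3L)
  n_eff <- n_trajectories - n_cens
  if (n_eff == 0L)
    stop("all trajectories censored; raise max_steps or check the configuration")
  per_aug <- vapply(wa$aug_pos, function(p)
    sum(res$outcome == 1L & res$committed_at == p), numeric(1)) / n_eff
  names(per_aug) <- as.character(wa$aug_pos)
  se <- sqrt(per_aug * (1 - per_aug) / n_eff)  # 0 when the estimate is degenerate
  structure(list(per_aug = per_aug,
                 p_dropoff = sum(res$outcome == -1L) / n_eff,
                 p_runoff = sum(res$outcome == -2L) / n_eff,
                 p_censored = n_cens / n_trajectories,
                 method = "monte_carlo",
                 n_trajectories = as.integer(n_trajectories),
                 standard_errors = se),
            class = "selection_result")
}

## ---- reporter sweeps ----------------------------------------------------

#' Spacer sweep over two competing AUGs
#'
#' Oracle-computed selection of two equal-context AUGs separated by `spacer`
#' nt (end of AUG1 to start of AUG2). With backsliding enabled the second
#' codon drains the first through 3'->5' excursions, so recognition of AUG1
#' ascends and of AUG2 descends with increasing spacer; with backsliding
#' disabled AUG1 recognition is spacer-independent (first-AUG rule).
#'
#' @param spacers Non-negative spacer lengths (nt).
#' @param config A [scan_config()].
#' @param utr5_len,context Construct parameters, see [build_reporter()].
#' @return Data frame with columns `spacer`, `P_AUG1`, `P_AUG2`.
#' @export
spacer_sweep <- function(spacers, config, utr5_len = 50L, context = 1) {
  stopifnot(all(spacers >= 0))
  rows <- lapply(spacers, function(d) {
    tx <- build_reporter("two_aug_spacer", spacer = d, utr5_len = utr5_len,
                         context = context)
    r <- absorption_oracle(tx, config)
    data.frame(spacer = d, P_AUG1 = unname(r$per_aug[1]),
               P_AUG2 = unname(r$per_aug[2]))
  })
  do.call(rbind, rows)
}

#' Initiation probability across ultra-short 5'UTR lengths
#'
#' The cap-proximal blind-spot profile: per-length initiation probability of
#' a single AUG at position `utr5_len`, from the oracle. Under slot-in with
#' tethered eIF4E the probability is exactly zero for lengths below
#' `cap_offset`; with backsliding and eIF4E release even a 2-nt 5'UTR is
#' translatable.
#'
#' @param config A [scan_config()].
#' @param utr_lengths 5'UTR lengths (nt) to profile.
#' @param context Context strength of the reporter AUG.
#' @return Data frame with columns `utr5_len`, `P_initiation`.
#' @export
blind_spot_profile <- function(config, utr_lengths = seq(0L, 30L),
                               context = 0.6) {
  rows <- lapply(utr_lengths, function(L) {
    tx <- build_reporter("ultra_short_utr", utr5_len = L, context = context)
    r <- absorption_oracle(tx, config)
    data.frame(utr5_len = L,
               P_initiation = unname(r$per_aug[as.character(L)]))
  })
  do.call(rbind, rows)
}

#' Retrograde selection of a uORF upstream of an internal entry site
#'
#' Loads the PIC at an IRES-like internal entry site placed downstream of a
#' uORF stop codon and asks how often the upstream uORF start is selected.
#' Only backward excursions can reach it, so the probability is zero under
#' forward-only scanning and decays with the entry-to-uORF distance.
#'
#' @param upstream_distances Distances (nt) from the uORF stop to the entry
#'   site.
#' @param config A [scan_config()]; internal entry is enforced.
#' @param ... Further construct parameters for [build_reporter()].
#' @return Data frame with columns `distance`, `P_uORF`, `P_downstream`.
#' @export
ires_entry_selection <- function(upstream_distances, config, ...) {
  cfg <- apply_preset(config, "ires_only")
  rows <- lapply(upstream_distances, function(d) {
    tx <- build_reporter("ires_entry", entry_distance = d, ...)
    r <- absorption_oracle(tx, cfg)
    data.frame(distance = d,
               P_uORF = unname(r$per_aug[1]),
               P_downstream = unname(r$per_aug[2]))
  })
  do.call(rbind, rows)
}
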