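# Shared fixtures, built in code. Small sizes keep the unit tests fast;
# acceptance-grade sizes live in test-acceptance.R.

ref_transcript <- function() transcript("ref600", 600L, 200L, 500L)

small_annotation <- function(n = 60, seed = 11, ...)
  generate_transcriptome(n, mito_fraction = 0.1, seed = seed, ...)

# a deterministic forward-only configuration for closed-form checks
linear_config <- function(recognition_base = 0.5)
  scan_config(loading_mode = "threading", backslide_enabled = FALSE,
              p_fwd = 1, p_back = 0, p_stay = 0, eif4e_release_rate = 0,
              recognition_base = recognition_base, dropoff_rate = 0,
              boundary_noise_sd = 0)

# random selection problems on short reporters, for oracle/MC equivalence
random_problem <- function(seed) {
  set.seed(seed)
  p_fwd <- runif(1, 0.3, 0.6)
  p_back <- runif(1, 0, min(0.9 * p_fwd, 1 - p_fwd - 0.05))
  ctx <- runif(2, 0.2, 1)
  tx <- build_reporter("two_aug_spacer", spacer = sample(0:12, 1),
                       utr5_len = sample(15:40, 1), context = 1,
                       cds_len = 60L, utr3_len = 10L)
  tx$aug_sites$context <- ctx
  cfg <- scan_config(backslide_enabled = p_back > 0, p_fwd = p_fwd,
                     p_back = p_back, p_stay = 1 - p_fwd - p_back,
                     eif4e_release_rate = runif(1, 0.005, 0.05),
                     recognition_base = runif(1, 0.2, 0.8),
                     dropoff_rate = runif(1, 1e-3, 1e-2),
                     bound_mobility = runif(1, 0.2, 1))
  list(tx = tx, cfg = cfg)
}

# leaky-scanning closed form: the independent oracle for the linear limit
leaky_closed_form <- function(r) {
  p <- numeric(length(r))
  surv <- 1
  for (i in seq_along(r)) {
    p[i] <- surv * r[i]
    surv <- surv * (1 - r[i])
  }
  list(per_aug = p, p_runoff = surv)
}
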