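# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the suite stays fast.

# A clean, fully deterministic recording: no noise, no jitter, no modulation.
clean_config <- function(duration_min = 1, ...) {
  synth_config(
    duration_min = duration_min, noise_sd = 0, rr_jitter_sd = 0,
    amp_jitter_sd = 0, apnea_rr_modulation_depth = 0, normal_hf_depth = 0,
    amp_modulation_depth = 0, artifact_prob = 0, artifact_depth = 0,
    label_pattern = rep("N", duration_min), ...
  )
}

# Noise level giving a 10 dB power signal-to-noise ratio for a config:
# sd(clean signal) / 10^(SNR/20).
noise_sd_for_snr <- function(snr_db, config = clean_config(2)) {
  rec <- simulate_recording(config)
  stats::sd(rec$signal) / 10^(snr_db / 20)
}

# Match detected peaks to ground truth within a sample tolerance; returns
# recall, precision, f1.
match_peaks <- function(detected, truth, tol) {
  tp <- sum(vapply(truth, function(p) any(abs(detected - p) <= tol), logical(1)))
  recall <- tp / length(truth)
  precision <- if (length(detected) > 0) {
    sum(vapply(detected, function(p) any(abs(truth - p) <= tol), logical(1))) /
      length(detected)
  } else 0
  c(recall = recall, precision = precision,
    f1 = 2 * recall * precision / max(recall + precision, 1e-12))
}

# A small labelled feature table built directly (no signal processing), for
# window/model tests: `n` minutes, features drawn from two shifted Gaussians.
toy_features <- function(n = 40, record_id = "toy", seed = 1,
                         labels = NULL, shift = 2) {
  withr::with_seed(seed, {
    labels <- labels %||% rep(c("N", "A"), length.out = n)
    mu <- ifelse(labels == "A", shift, 0)
    f <- purrr::map(apnea_feature_names(), ~ rnorm(n, mean = mu))
    names(f) <- apnea_feature_names()
    dplyr::bind_cols(
      tibble::tibble(record_id = record_id, minute = seq_len(n) - 1L,
                     label = labels, n_beats = 60L),
      tibble::as_tibble(f),
      tibble::tibble(valid = TRUE)
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force recomputation of the time-domain HRV definitions,
# written as plain loops so it shares nothing with the implementation.
brute_time_domain <- function(rr) {
  n <- length(rr)
  mrr <- sum(rr) / n
  mhr <- 0
  for (v in rr) mhr <- mhr + 60 / v
  mhr <- mhr / n
  ssd <- 0
  nn50 <- 0
  for (i in 2:n) {
    ssd <- ssd + (rr[i] - rr[i - 1])^2
    if (abs(rr[i] - rr[i - 1]) > 0.05) nn50 <- nn50 + 1
  }
  sdd <- 0
  for (v in rr) sdd <- sdd + (v - mrr)^2
  list(mrr = mrr, mhr = mhr, rmssd = sqrt(ssd / (n - 1)),
       sdnn = sqrt(sdd / (n - 1)), nn50 = nn50, pnn50 = nn50 / (n - 1))
}
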