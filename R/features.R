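#' Time-domain HRV features of one segment
#'
#' The six classical short-term heart-rate-variability statistics of an RR
#' series RR(1..N): MRR, the mean RR interval; MHR, the mean of the
#' instantaneous heart rates 60/RR(n) in beats/min; RMSSD,
#' sqrt(sum_{n=2..N} (RR(n) - RR(n-1))^2 / (N - 1)); SDNN, the sample
#' standard deviation of the RR series (denominator N - 1); NN50, the number
#' of adjacent-interval differences exceeding 50 ms; and pNN50, NN50 divided
#' by the number of adjacent pairs (N - 1 by default; set
#' `pnn50_denom = "n"` to divide by N instead).
#'
#' @param rr_s Numeric vector of RR intervals in seconds (N >= 2).
#' @param pnn50_denom `"pairs"` (N - 1, default) or `"n"`.
#' @return One-row tibble with columns `mrr`, `mhr`, `rmssd`, `sdnn`,
#'   `nn50`, `pnn50`, or all-`NA` with zero rows of validity when N < 2
#'   (caller marks the segment invalid).
#' @export
#' @examples
#' time_domain_features(c(0.8, 1.0))
time_domain_features <- function(rr_s, pnn50_denom = c("pairs", "n")) {
  pnn50_denom <- match.arg(pnn50_denom)
  n <- length(rr_s)
  if (n < 2) {
    return(tibble(mrr = NA_real_, mhr = NA_real_, rmssd = NA_real_,
                  sdnn = NA_real_, nn50 = NA_real_, pnn50 = NA_real_))
  }
  d <- diff(rr_s)
  nn50 <- sum(abs(d) > 0.05)
  tibble(
    mrr = mean(rr_s),
    mhr = mean(60 / rr_s),
    rmssd = sqrt(sum(d^2) / (n - 1)),
    sdnn = sd(rr_s),
    nn50 = as.numeric(nn50),
    pnn50 = nn50 / if (pnn50_denom == "pairs") n - 1 else n
  )
}

#' Welch power spectral density
#'
#' Welch's averaged-periodogram estimate: the (mean-removed) series is cut
#' into Hann-windowed segments of length `min(nfft, length(x))` with 50%
#' overlap, each zero-padded to an `nfft`-point FFT (default 256), and the
#' one-sided density periodograms are averaged.
#'
#' @param x Uniformly sampled numeric series.
#' @param fs Sampling rate in Hz.
#' @param nfft FFT length (default 256).
#' @return A tibble with columns `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, nfft = 256L) {
  x <- x - mean(x)
  n <- length(x)
  nper <- min(nfft, n)
  step <- max(1L, nper %/% 2L)
  starts <- seq(1L, max(1L, n - nper + 1L), by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nper) / (nper + 1)))  # Hann
  scale <- 1 / (fs * sum(w^2))
  nf <- nfft %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)] * w
    sp <- fft(c(seg, numeric(nfft - nper)))[seq_len(nf)]
    acc <- acc + scale * Mod(sp)^2
  }
  psd <- acc / length(starts)
  psd[2:(nf - 1L)] <- 2 * psd[2:(nf - 1L)]  # one-sided
  tibble(freq = (seq_len(nf) - 1) * fs / nfft, psd = psd)
}

# trapezoidal integral of psd over [lo, hi)
band_power <- function(freq, psd, lo, hi) {
  i <- which(freq >= lo & freq < hi)
  if (length(i) < 2) return(0)
  sum(diff(freq[i]) * (psd[i][-1] + psd[i][-length(i)]) / 2)
}

#' Band-power features of an unevenly sampled series
#'
#' Resamples an event series (an RR tachogram or R-amplitude/EDR series,
#' valued at beat times) onto a uniform 4 Hz grid by cubic-spline
#' interpolation, removes the mean, estimates the PSD with [welch_psd()],
#' and integrates it over the standard HRV bands: VLF 0-0.04 Hz,
#' LF 0.04-0.15 Hz, HF 0.15-0.4 Hz. Ratios use the convention 0/0 = 0 and
#' x/0 capped at `ratio_cap`.
#'
#' @param values Series values at `times`.
#' @param times Sample times in seconds (strictly increasing).
#' @param interp_hz Uniform resampling rate (default 4 Hz).
#' @param nfft FFT length for [welch_psd()].
#' @param ratio_cap Value substituted for a finite power divided by zero.
#' @return One-row tibble `vlf`, `lf`, `hf`, `lf_hf`, `lf_norm`, `hf_norm`,
#'   or all-`NA` when fewer than 4 points or less than 10 s of span.
#' @export
#' @examples
#' t <- seq(0, 60, by = 0.25)
#' spectral_features(sin(2 * pi * 0.1 * t), t)
spectral_features <- function(values, times, interp_hz = 4, nfft = 256L,
                              ratio_cap = 100) {
  na <- tibble(vlf = NA_real_, lf = NA_real_, hf = NA_real_,
               lf_hf = NA_real_, lf_norm = NA_real_, hf_norm = NA_real_)
  if (length(values) < 4 || diff(range(times)) <= 10) return(na)
  grid <- seq(min(times), max(times), by = 1 / interp_hz)
  if (length(grid) < 8) return(na)
  y <- spline(times, values, xout = grid, method = "fmm")$y
  ps <- welch_psd(y, fs = interp_hz, nfft = nfft)
  p <- purrr::map_dbl(HRV_BANDS, ~ band_power(ps$freq, ps$psd, .x[1], .x[2]))
  ratio <- function(a, b) {
    if (b > 0) a / b else if (a == 0) 0 else ratio_cap
  }
  tibble(
    vlf = p[["vlf"]], lf = p[["lf"]], hf = p[["hf"]],
    lf_hf = ratio(p[["lf"]], p[["hf"]]),
    lf_norm = ratio(p[["lf"]], p[["lf"]] + p[["hf"]]),
    hf_norm = ratio(p[["hf"]], p[["lf"]] + p[["hf"]])
  )
}

#' Extract the 18-feature vector of one segment
#'
#' Combines [time_domain_features()] on the RR series with
#' [spectral_features()] on the RR tachogram and on the R-peak-amplitude
#' (ECG-derived respiration) series. The segment is invalid when any
#' sub-extractor fails; invalid segments carry `NA` features.
#'
#' @param rr_s RR intervals in seconds.
#' @param rr_time_s Time of each interval's second peak, seconds.
#' @param amp R-peak amplitudes.
#' @param amp_time_s R-peak times, seconds.
#' @inheritParams spectral_features
#' @inheritParams time_domain_features
#' @return One-row tibble with the 18 columns of [apnea_feature_names()]
#'   plus `valid`.
#' @export
extract_segment <- function(rr_s, rr_time_s, amp, amp_time_s,
                            pnn50_denom = "pairs", interp_hz = 4,
                            nfft = 256L, ratio_cap = 100) {
  td <- time_domain_features(rr_s, pnn50_denom = pnn50_denom)
  rrf <- spectral_features(rr_s, rr_time_s, interp_hz, nfft, ratio_cap)
  amf <- spectral_features(amp, amp_time_s, interp_hz, nfft, ratio_cap)
  out <- dplyr::bind_cols(
    td,
    stats::setNames(rrf, paste0("rr_", names(rrf))),
    stats::setNames(amf, paste0("amp_", names(amf)))
  )
  out <- out[, APNEA_FEATURES]
  out$valid <- !anyNA(out)
  out
}

#' Run the full per-minute feature pipeline on a recording
#'
#' Bandpass-filters the signal, detects R peaks, corrects RR intervals
#' across the recording, assigns beats to one-minute segments, and computes
#' the 18 features for every minute. This is the front half of the detector;
#' feed its output to [fit_tw_mlp()] or [build_windows()].
#'
#' @param rec An `ecg_recording` or `synth_recording`.
#' @param min_beats Minimum beats per minute for validity.
#' @param filter_low_hz,filter_high_hz Bandpass edges.
#' @param rr_window,rr_max_dev Median-correction parameters.
#' @inheritParams extract_segment
#' @return A tibble with one row per minute: `record_id`, `minute`
#'   (0-based), `label` ("A"/"N" or `NA`), `n_beats`, `valid`, and the 18
#'   feature columns.
#' @export
#' @examples
#' rec <- simulate_recording(synth_config(duration_min = 3, seed = 2))
#' extract_features(rec)
extract_features <- function(rec, min_beats = 20L,
                             filter_low_hz = 3, filter_high_hz = 45,
                             rr_window = 5L, rr_max_dev = 0.2,
                             pnn50_denom = "pairs", interp_hz = 4,
                             nfft = 256L, ratio_cap = 100) {
  n_min <- length(rec$signal) %/% as.integer(round(60 * rec$fs))
  filt <- bandpass_filter(rec$signal, rec$fs, filter_low_hz, filter_high_hz)
  beats <- detect_r_peaks(filt, rec$fs)
  seg <- segment_beats(beats, n_minutes = n_min, fs = rec$fs,
                       min_beats = min_beats, correct = TRUE,
                       window = rr_window, max_dev = rr_max_dev)
  labels <- rec$minute_labels %||% rep(NA_character_, n_min)
  feats <- purrr::pmap_dfr(
    list(seg$rr_s, seg$rr_time_s, seg$amp, seg$amp_time_s, seg$valid),
    function(rr, rrt, am, amt, ok) {
      if (!ok) {
        out <- tibble::as_tibble_row(
          stats::setNames(as.list(rep(NA_real_, 18)), APNEA_FEATURES))
        out$valid <- FALSE
        out
      } else {
        extract_segment(rr, rrt, am, amt, pnn50_denom = pnn50_denom,
                        interp_hz = interp_hz, nfft = nfft,
                        ratio_cap = ratio_cap)
      }
    }
  )
  dplyr::bind_cols(
    tibble(record_id = rec$record_id %||% "rec",
           minute = seg$minute,
           label = labels[seg$minute + 1L],
           n_beats = seg$n_beats),
    feats
  )
}

#' Fit and apply per-feature z-score normalisation
#'
#' `fit_normalizer()` computes the per-feature mean and standard deviation on
#' a training feature table (valid segments only); `apply_normalizer()`
#' standardises any feature table with those statistics, so held-out data
#' never leaks into them. Features with zero training variance map to 0.
#'
#' @param features Feature tibble from [extract_features()].
#' @param stats A `norm_stats` tibble from `fit_normalizer()`.
#' @return `fit_normalizer()`: a tibble of class `norm_stats` with columns
#'   `feature`, `mean`, `sd`. `apply_normalizer()`: `features` with the 18
#'   feature columns standardised.
#' @export
fit_normalizer <- function(features) {
  ok <- features[features$valid %||% TRUE, , drop = FALSE]
  if (nrow(ok) < 2) {
    abort("fit_normalizer: need at least 2 valid training segments",
          class = "apneatw_config_error")
  }
  st <- tibble(
    feature = APNEA_FEATURES,
    mean = purrr::map_dbl(APNEA_FEATURES, ~ mean(ok[[.x]])),
    sd = purrr::map_dbl(APNEA_FEATURES, ~ sd(ok[[.x]]))
  )
  class(st) <- c("norm_stats", class(st))
  st
}

#' @rdname fit_normalizer
#' @export
apply_normalizer <- function(features, stats) {
  for (i in seq_len(nrow(stats))) {
    f <- stats$feature[i]
    s <- stats$sd[i]
    features[[f]] <- if (is.na(s) || s == 0) {
      ifelse(is.na(features[[f]]), NA_real_, 0)
    } else {
      (features[[f]] - stats$mean[i]) / s
    }
  }
  features
}
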