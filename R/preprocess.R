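#' Zero-lag FIR bandpass filter for ECG denoising
#'
#' Removes baseline wander and high-frequency/powerline noise with a
#' linear-phase windowed-sinc (Hamming) FIR bandpass, passband 3-45 Hz by
#' default. The filter is applied once via FFT convolution and the constant
#' group delay of the symmetric FIR is compensated exactly, so R-peak
#' positions and amplitudes are not shifted or biased.
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate in Hz; must exceed twice the upper band edge.
#' @param low_hz,high_hz Passband edges in Hz.
#' @param order Filter order (even); the default gives transition bands of
#'   about 1 Hz at 100 Hz sampling.
#' @return Filtered signal, same length as `x`.
#' @export
#' @examples
#' s <- sin(2 * pi * 10 * seq(0, 2, by = 0.01))
#' f <- bandpass_filter(s, fs = 100)
bandpass_filter <- function(x, fs, low_hz = 3, high_hz = 45, order = 330L) {
  if (fs <= 2 * high_hz) {
    abort(sprintf(
      "bandpass_filter: fs = %g Hz is too low for a %g Hz upper band edge (need fs > %g)",
      fs, high_hz, 2 * high_hz), class = "apneatw_config_error")
  }
  order <- as.integer(order)
  if (order %% 2 == 1) order <- order + 1L
  b <- signal::fir1(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  n <- length(x)
  gd <- order %/% 2L
  y <- signal::fftfilt(b, c(x, numeric(order)))
  y[(gd + 1):(gd + n)]
}

#' Locate R peaks with a Hamilton-style adaptive-threshold detector
#'
#' Classic open-source QRS detection chain: first difference, rectification,
#' an 80 ms moving-window integration, then an adaptive detection threshold
#' held between the running means of the last 8 accepted QRS peak heights and
#' the last 8 noise peak heights (coefficient 0.3125), a 200 ms refractory
#' period, and a search-back that rescues a missed beat whenever the gap
#' since the last detection exceeds 1.5 times the running mean RR. Each
#' detection is refined to the local maximum of the filtered signal within
#' +/-20 ms (after exact group-delay compensation of the integration stage)
#' and the amplitude is read from the filtered signal there.
#'
#' @param x Filtered ECG signal (see [bandpass_filter()]).
#' @param fs Sampling rate in Hz.
#' @return A tibble of class `beat_series` with columns `sample` (1-based,
#'   strictly increasing), `time_s`, and `amplitude`; the sampling rate is
#'   stored in `attr(, "fs")`. When no peak is found an empty (zero-row)
#'   tibble is returned with a warning, not an error.
#' @export
detect_r_peaks <- function(x, fs) {
  if (length(x) < 2 * fs) {
    abort("detect_r_peaks: need at least 2 s of signal",
          class = "apneatw_config_error")
  }
  n <- length(x)
  refract <- as.integer(round(0.2 * fs))
  win <- max(2L, as.integer(round(0.08 * fs)))
  smo <- max(1L, as.integer(round(0.03 * fs)))

  causal_ma <- function(v, k) {
    cs <- cumsum(v)
    (cs - c(rep(0, k), head(cs, length(v) - k))) / k
  }
  # short pre-smoothing keeps the QRS slope but suppresses broadband noise
  # in the derivative
  d <- c(0, diff(causal_ma(x, smo)))
  integ <- causal_ma(abs(d), win)

  # candidate local maxima of the integrated signal
  cand <- which(diff(sign(diff(integ))) < 0) + 1L
  empty <- tibble(sample = integer(), time_s = numeric(), amplitude = numeric())
  attr(empty, "fs") <- fs
  class(empty) <- c("beat_series", class(empty))
  if (length(cand) == 0) {
    warn("detect_r_peaks: no candidate peaks found; returning an empty beat series")
    return(empty)
  }
  vals <- integ[cand]

  init_spk <- max(integ[seq_len(min(n, as.integer(2 * fs)))])
  spk_hist <- rep(init_spk, 8)
  npk_hist <- rep(init_spk / 10, 8)
  rr_hist <- rep(fs, 8)

  accepted <- integer(0)
  last_qrs <- -Inf
  last_scan <- 0L  # candidates already consumed by search-back

  for (i in seq_along(cand)) {
    # medians keep the running levels robust to occasional misclassified peaks
    spk <- median(spk_hist)
    npk <- median(npk_hist)
    thr <- npk + 0.3125 * (spk - npk)
    ci <- cand[i]
    vi <- vals[i]
    if (ci - last_qrs <= refract) next
    if (vi > thr && vi > 0.4 * spk) {
      if (length(accepted) > 0) {
        rr_hist <- c(rr_hist[-1], ci - last_qrs)
      }
      accepted <- c(accepted, ci)
      last_qrs <- ci
      spk_hist <- c(spk_hist[-1], vi)
      last_scan <- i
    } else {
      npk_hist <- c(npk_hist[-1], vi)
      # search-back: a long gap suggests a missed beat below threshold
      if (is.finite(last_qrs) && (ci - last_qrs) > 1.5 * mean(rr_hist)) {
        seg <- which(cand > last_qrs + refract & cand <= ci)
        seg <- seg[seg > last_scan]
        if (length(seg) > 0) {
          j <- seg[which.max(vals[seg])]
          if (vals[j] > 0.5 * thr && vals[j] > 0.25 * spk) {
            cj <- cand[j]
            rr_hist <- c(rr_hist[-1], cj - last_qrs)
            accepted <- c(accepted, cj)
            last_qrs <- cj
            spk_hist <- c(spk_hist[-1], vals[j])
            last_scan <- i
          }
        }
      }
    }
  }

  if (length(accepted) == 0) {
    warn("detect_r_peaks: no QRS accepted above threshold; returning an empty beat series")
    return(empty)
  }

  # map back: smoothing + differentiation + centre of the integration window
  shift <- 1L + (smo %/% 2L) + (win %/% 2L)
  tol <- as.integer(round(0.02 * fs))
  refined <- vapply(accepted, function(ci) {
    c0 <- min(max(ci - shift, 1L), n)
    lo <- max(1L, c0 - tol)
    hi <- min(n, c0 + tol)
    p <- lo + which.max(x[lo:hi]) - 1L
    # bounded hill-climb mops up residual delay-compensation error without
    # letting noise bumps drag the peak away
    steps <- tol
    while (p > 1L && steps > 0L && x[p - 1L] > x[p]) { p <- p - 1L; steps <- steps - 1L }
    while (p < n && steps > 0L && x[p + 1L] > x[p]) { p <- p + 1L; steps <- steps - 1L }
    p
  }, integer(1))

  ord <- order(refined)
  refined <- refined[ord]
  keep <- c(TRUE, diff(refined) >= refract)
  refined <- refined[keep]

  out <- tibble(sample = refined, time_s = (refined - 1) / fs,
                amplitude = x[refined])
  attr(out, "fs") <- fs
  class(out) <- c("beat_series", class(out))
  out
}

#' Median-filter correction of RR intervals
#'
#' Flags an RR interval as physiologically implausible when it deviates from
#' its 5-point local median by more than 20%, and replaces flagged values by
#' that local median. Order and length are preserved; the operation is
#' idempotent on series with isolated outliers.
#'
#' @param rr Tibble with at least an `rr_s` column (as from
#'   [segment_beats()]), or a bare numeric vector of RR intervals in seconds.
#' @param window Odd local-median window length (default 5).
#' @param max_dev Maximum tolerated relative deviation from the local median
#'   (default 0.2).
#' @return Input with `rr_s` corrected and a logical `corrected` column.
#' @export
#' @examples
#' correct_rr(c(1, 1, 3, 1, 1))
correct_rr <- function(rr, window = 5L, max_dev = 0.2) {
  vec_in <- is.numeric(rr)
  rr_s <- if (vec_in) rr else rr$rr_s
  n <- length(rr_s)
  if (n == 0) {
    out <- if (vec_in) tibble(rr_s = numeric()) else rr
    out$corrected <- logical(0)
    return(out)
  }
  half <- (as.integer(window) - 1L) %/% 2L
  med <- vapply(seq_len(n), function(i) {
    median(rr_s[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
  bad <- abs(rr_s - med) > max_dev * med
  fixed <- ifelse(bad, med, rr_s)
  if (vec_in) {
    tibble(rr_s = fixed, corrected = bad)
  } else {
    rr$rr_s <- fixed
    rr$corrected <- bad
    rr
  }
}

#' Assign beats, RR intervals and amplitudes to one-minute segments
#'
#' RR intervals are computed between consecutive detected peaks, corrected
#' with [correct_rr()] across the whole recording, and assigned to the minute
#' containing their *second* peak; amplitudes are assigned by their own
#' sample index. Minutes are half-open: a beat at exactly the boundary sample
#' belongs to the later minute. Minutes with fewer than `min_beats` beats are
#' marked invalid (detection failure or severe artifact) and excluded from
#' modelling downstream.
#'
#' @param beats A `beat_series` from [detect_r_peaks()].
#' @param n_minutes Number of full minutes in the recording.
#' @param fs Sampling rate in Hz (defaults to the beat series attribute).
#' @param min_beats Minimum beats for a minute to be usable (default 20).
#' @param correct Apply median RR correction (default TRUE).
#' @param window,max_dev Passed to [correct_rr()].
#' @return A tibble with one row per minute: `minute` (0-based), `n_beats`,
#'   `valid`, and list columns `rr_s`, `rr_time_s` (time of each interval's
#'   second peak), `amp`, `amp_time_s`.
#' @export
segment_beats <- function(beats, n_minutes, fs = attr(beats, "fs"),
                          min_beats = 20L, correct = TRUE,
                          window = 5L, max_dev = 0.2) {
  stopifnot(is.numeric(fs), fs > 0, n_minutes >= 1)
  n_beats_tot <- nrow(beats)
  if (n_beats_tot >= 2) {
    rr_s <- diff(beats$sample) / fs
    if (correct) rr_s <- correct_rr(rr_s, window = window, max_dev = max_dev)$rr_s
    rr_time <- beats$time_s[-1]
  } else {
    rr_s <- numeric(0)
    rr_time <- numeric(0)
  }
  # half-open minutes on 0-based sample index: minute k holds samples
  # [k*60*fs, (k+1)*60*fs)
  spm <- 60 * fs
  beat_min <- (beats$sample - 1) %/% spm
  rr_min <- if (length(rr_time) > 0) (beats$sample[-1] - 1) %/% spm else integer(0)

  purrr::map_dfr(seq_len(n_minutes) - 1L, function(k) {
    bi <- which(beat_min == k)
    ri <- which(rr_min == k)
    tibble(
      minute = k,
      n_beats = length(bi),
      valid = length(bi) >= min_beats,
      rr_s = list(rr_s[ri]),
      rr_time_s = list(rr_time[ri]),
      amp = list(beats$amplitude[bi]),
      amp_time_s = list(beats$time_s[bi])
    )
  })
}
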