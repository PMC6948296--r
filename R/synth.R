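#' Configuration for the synthetic apnea-ECG generator
#'
#' Builds and validates the parameter set that [simulate_recording()] uses to
#' synthesise a single-lead ECG with known ground truth. The generator encodes
#' the physiological signature the downstream features look for: during apnea,
#' heart rate and R-peak amplitude oscillate slowly (very-low-frequency band,
#' default 0.02 Hz, the cyclic-variation-of-heart-rate pattern), while normal
#' breathing imprints a faster, weaker modulation (respiratory sinus
#' arrhythmia, high-frequency band, default 0.25 Hz).
#'
#' Heterogeneity knobs make the detection problem realistically imperfect:
#' each apnea episode draws a severity multiplier (weak events look nearly
#' normal), a fraction of normal minutes carry a low-amplitude VLF artifact
#' (body movement), and every RR interval receives broadband Gaussian jitter.
#'
#' @param duration_min Recording length in whole minutes (>= 1).
#' @param fs Sampling rate in Hz (default 100).
#' @param baseline_rr_s Mean RR interval in seconds, in (0.3, 2.0).
#' @param apnea_rr_modulation_depth Fractional RR modulation depth in apnea
#'   minutes, in `[0, 1)`.
#' @param apnea_cycle_hz Apnea oscillation frequency in Hz (inside the VLF
#'   band, default 0.02).
#' @param normal_hf_depth Fractional RR modulation depth in normal minutes.
#' @param normal_hf_hz Respiratory modulation frequency in Hz (inside the HF
#'   band, default 0.25).
#' @param amp_modulation_depth Fractional R-peak amplitude modulation depth
#'   (the ECG-derived respiration surrogate).
#' @param noise_sd Standard deviation of additive Gaussian noise, in units of
#'   the unit-amplitude R peak.
#' @param qrs_width_ms Width of the raised-cosine QRS template, milliseconds.
#' @param rr_jitter_sd Per-beat broadband RR jitter, seconds.
#' @param amp_jitter_sd Per-beat broadband R-amplitude jitter (electrode and
#'   contact noise on the ECG-derived respiration surrogate), signal units.
#' @param apnea_severity_range Range of the per-episode severity multiplier
#'   applied to the apnea modulation depths.
#' @param apnea_coverage_range Range of the fraction of each apnea minute
#'   actually covered by the oscillation: scored apnea events rarely span
#'   the whole labelled minute, so the modulation is active only on a random
#'   contiguous sub-interval.
#' @param artifact_prob Probability that a normal minute carries a VLF
#'   movement artifact.
#' @param artifact_depth Range (or single value) of the RR modulation depth
#'   of such artifacts, drawn per artifact minute: artifact strength varies
#'   as much as event strength does, so artifacts overlap the weak end of
#'   the apnea distribution instead of sitting at one separable magnitude.
#' @param label_pattern Per-minute labels: a character vector of "A"/"N" of
#'   length `duration_min`, one of the recording classes `"A"`, `"B"`, `"C"`
#'   (severe / borderline / normal, expanded by [simulate_labels()]), or a
#'   single number taken as a target AHI in events/hour.
#' @param seed Integer seed; identical seed and config give bit-identical
#'   output.
#'
#' @return A validated list of class `synth_config`.
#' @export
#' @examples
#' synth_config(duration_min = 10, label_pattern = "A", seed = 1)
synth_config <- function(duration_min = 60,
                         fs = 100,
                         baseline_rr_s = 1.0,
                         apnea_rr_modulation_depth = 0.25,
                         apnea_cycle_hz = 0.02,
                         normal_hf_depth = 0.05,
                         normal_hf_hz = 0.25,
                         amp_modulation_depth = 0.10,
                         noise_sd = 0.05,
                         qrs_width_ms = 80,
                         rr_jitter_sd = 0.03,
                         amp_jitter_sd = 0.05,
                         apnea_severity_range = c(0.2, 1),
                         apnea_coverage_range = c(0.02, 1),
                         artifact_prob = 0.3,
                         artifact_depth = c(0.05, 0.3),
                         label_pattern = "B",
                         seed = 1L) {
  cfg <- list(
    duration_min = duration_min, fs = fs, baseline_rr_s = baseline_rr_s,
    apnea_rr_modulation_depth = apnea_rr_modulation_depth,
    apnea_cycle_hz = apnea_cycle_hz,
    normal_hf_depth = normal_hf_depth, normal_hf_hz = normal_hf_hz,
    amp_modulation_depth = amp_modulation_depth, noise_sd = noise_sd,
    qrs_width_ms = qrs_width_ms, rr_jitter_sd = rr_jitter_sd,
    amp_jitter_sd = amp_jitter_sd,
    apnea_severity_range = apnea_severity_range,
    apnea_coverage_range = apnea_coverage_range,
    artifact_prob = artifact_prob, artifact_depth = artifact_depth,
    label_pattern = label_pattern, seed = as.integer(seed)
  )
  check_num <- function(field, lo, hi, lo_open = FALSE, hi_open = FALSE) {
    x <- cfg[[field]]
    bad <- !is.numeric(x) || length(x) != 1 || !is.finite(x) ||
      (if (lo_open) x <= lo else x < lo) || (if (hi_open) x >= hi else x > hi)
    if (bad) {
      abort(sprintf("synth_config: field `%s` = %s is outside [%s, %s]",
                    field, format(cfg[[field]]), lo, hi),
            class = "apneatw_config_error")
    }
  }
  if (!is.numeric(duration_min) || length(duration_min) != 1 ||
      duration_min < 1 || duration_min != floor(duration_min)) {
    abort("synth_config: field `duration_min` must be a whole number >= 1",
          class = "apneatw_config_error")
  }
  cfg$duration_min <- as.integer(duration_min)
  check_num("fs", 0, Inf, lo_open = TRUE)
  check_num("baseline_rr_s", 0.3, 2.0, lo_open = TRUE, hi_open = TRUE)
  for (f in c("apnea_rr_modulation_depth", "normal_hf_depth",
              "amp_modulation_depth")) {
    check_num(f, 0, 1, hi_open = TRUE)
  }
  ad <- cfg$artifact_depth
  if (length(ad) == 1) ad <- c(ad, ad)
  if (length(ad) != 2 || ad[1] > ad[2] || any(ad < 0) || any(ad >= 1) ||
      !is.numeric(ad)) {
    abort("synth_config: field `artifact_depth` must be a value or increasing pair in [0, 1)",
          class = "apneatw_config_error")
  }
  cfg$artifact_depth <- ad
  check_num("apnea_cycle_hz", 0, 0.5, lo_open = TRUE)
  check_num("normal_hf_hz", 0, 0.5, lo_open = TRUE)
  check_num("noise_sd", 0, Inf)
  check_num("qrs_width_ms", 0, 1000, lo_open = TRUE)
  check_num("rr_jitter_sd", 0, Inf)
  check_num("amp_jitter_sd", 0, Inf)
  check_num("artifact_prob", 0, 1)
  for (f in c("apnea_severity_range", "apnea_coverage_range")) {
    rng <- cfg[[f]]
    if (length(rng) != 2 || rng[1] > rng[2] || any(rng < 0) || any(rng > 1)) {
      abort(sprintf("synth_config: field `%s` must be an increasing pair in [0, 1]", f),
            class = "apneatw_config_error")
    }
  }
  if (is.character(label_pattern) && length(label_pattern) > 1 &&
      length(label_pattern) != cfg$duration_min) {
    abort("synth_config: field `label_pattern` has length != duration_min",
          class = "apneatw_config_error")
  }
  structure(cfg, class = "synth_config")
}

# Two-state Markov chain parameters for a target apnea fraction and mean
# episode (bout) length in minutes.
markov_params <- function(frac, bout_min) {
  p_stay <- 1 - 1 / bout_min
  p_enter <- (1 - p_stay) * frac / (1 - frac)
  c(p_enter = min(p_enter, 1), p_stay = p_stay)
}

#' Simulate per-minute apnea labels with temporal dependence
#'
#' Labels follow a two-state Markov chain, so apnea occurs in multi-minute
#' bouts: the same persistence that clinical scorers see and that the
#' time-window classifier exploits. Recording classes map to stationary apnea
#' fractions and mean bout lengths: class A (severe, AHI about 30) 50% apnea
#' in 12-minute bouts, class B (borderline, AHI about 7.5) 12.5% in 6-minute
#' bouts, class C (normal, AHI about 1.8) 3% in 2-minute bouts. A numeric
#' `pattern` is interpreted as a target AHI with a 3-minute mean bout.
#'
#' @param duration_min Number of minutes.
#' @param pattern `"A"`, `"B"`, `"C"`, a target AHI (events/hour), or an
#'   explicit character vector of `"A"`/`"N"` labels.
#' @param seed Integer seed.
#' @return Character vector of length `duration_min` with entries "A"/"N".
#' @export
simulate_labels <- function(duration_min, pattern = "B", seed = 1L) {
  explicit <- is.character(pattern) &&
    (length(pattern) > 1 ||
       (duration_min == 1 && all(pattern %in% c("A", "N"))) ||
       identical(pattern, "N"))
  if (explicit) {
    if (length(pattern) != duration_min || !all(pattern %in% c("A", "N"))) {
      abort("label_pattern: explicit labels must be 'A'/'N' of length duration_min",
            class = "apneatw_config_error")
    }
    return(pattern)
  }
  if (is.numeric(pattern)) {
    frac <- min(max(pattern / 60, 0), 0.95)
    par <- markov_params(max(frac, 1e-6), 3)
  } else {
    par <- switch(pattern,
      A = markov_params(0.5, 12),
      B = markov_params(0.125, 6),
      C = markov_params(0.03, 2),
      abort(sprintf("label_pattern: unknown class '%s' (use A, B, C, an AHI, or explicit labels)",
                    pattern), class = "apneatw_config_error")
    )
  }
  withr::with_seed(seed, {
    lab <- character(duration_min)
    state <- runif(1) < par[["p_enter"]] / (par[["p_enter"]] + 1 - par[["p_stay"]])
    for (m in seq_len(duration_min)) {
      p <- if (state) par[["p_stay"]] else par[["p_enter"]]
      state <- runif(1) < p
      lab[m] <- if (state) "A" else "N"
    }
    lab
  })
}

#' Simulate a single-lead apnea-ECG recording with known ground truth
#'
#' Integrates an instantaneous RR series (slow deep oscillation in apnea
#' minutes, fast shallow oscillation in normal minutes, broadband jitter
#' throughout), renders each beat as a raised-cosine QRS spike whose
#' amplitude is co-modulated in the same bands, and adds Gaussian noise.
#' Ground-truth R-peak positions and amplitudes, per-minute labels and the
#' AHI are recorded exactly from the construction.
#'
#' @param config A [synth_config()].
#' @param record_id Identifier stored with the recording.
#' @return A list of class `synth_recording` with elements `signal`, `fs`,
#'   `true_r_peaks` (1-based sample indices), `true_r_amplitudes`,
#'   `minute_labels`, `true_ahi`, `duration_min`, `record_id`, `config`.
#' @export
#' @examples
#' rec <- simulate_recording(synth_config(duration_min = 3, seed = 42))
#' length(rec$signal)  # 3 * 60 * 100
#' rec$true_ahi
simulate_recording <- function(config = synth_config(), record_id = "synth") {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  fs <- config$fs
  dur_s <- config$duration_min * 60
  n <- as.integer(round(dur_s * fs))
  labels <- simulate_labels(config$duration_min, config$label_pattern,
                            seed = config$seed)

  withr::with_seed(config$seed + 1L, {
    # per-minute modulation frequency and depth (episode severity, artifacts)
    dep <- numeric(config$duration_min)
    frq <- numeric(config$duration_min)
    cov_lo <- numeric(config$duration_min)  # active sub-interval, s in minute
    cov_hi <- rep(60, config$duration_min)
    runs <- rle(labels)
    pos <- 1L
    for (j in seq_along(runs$lengths)) {
      idx <- pos:(pos + runs$lengths[j] - 1L)
      if (runs$values[j] == "A") {
        sev <- runif(1, config$apnea_severity_range[1], config$apnea_severity_range[2])
        dep[idx] <- config$apnea_rr_modulation_depth * sev
        frq[idx] <- config$apnea_cycle_hz
        # scored events rarely fill the labelled minute: the oscillation is
        # active only on a random contiguous fraction of each apnea minute
        cov <- runif(length(idx), config$apnea_coverage_range[1],
                     config$apnea_coverage_range[2])
        off <- runif(length(idx)) * (1 - cov) * 60
        cov_lo[idx] <- off
        cov_hi[idx] <- off + cov * 60
      } else {
        art <- runif(length(idx)) < config$artifact_prob
        art_dep <- runif(length(idx), config$artifact_depth[1],
                         config$artifact_depth[2])
        dep[idx] <- ifelse(art, art_dep, config$normal_hf_depth)
        frq[idx] <- ifelse(art, config$apnea_cycle_hz, config$normal_hf_hz)
      }
      pos <- pos + runs$lengths[j]
    }

    # integrate beat times: t_{i+1} = t_i + RR(t_i)
    max_beats <- ceiling(dur_s / 0.3) + 2L
    beat_t <- numeric(max_beats)
    beat_amp <- numeric(max_beats)
    t <- config$baseline_rr_s / 2
    k <- 0L
    while (t < dur_s) {
      m <- min(floor(t / 60) + 1, config$duration_min)
      tin <- t - (m - 1) * 60
      active <- tin >= cov_lo[m] && tin < cov_hi[m]
      d_t <- if (active) dep[m] else if (labels[m] == "A") config$normal_hf_depth else dep[m]
      f_t <- if (active) frq[m] else if (labels[m] == "A") config$normal_hf_hz else frq[m]
      phase <- 2 * pi * f_t * t
      k <- k + 1L
      beat_t[k] <- t
      beat_amp[k] <- 1 + config$amp_modulation_depth *
        (d_t / max(config$apnea_rr_modulation_depth, 1e-12)) * sin(phase) +
        rnorm(1, 0, config$amp_jitter_sd)
      rr <- config$baseline_rr_s * (1 + d_t * sin(phase)) +
        rnorm(1, 0, config$rr_jitter_sd)
      t <- t + max(rr, 0.3)
    }
    beat_t <- beat_t[seq_len(k)]
    beat_amp <- beat_amp[seq_len(k)]

    # render raised-cosine QRS spikes
    wsamp <- max(3L, as.integer(round(config$qrs_width_ms / 1000 * fs)))
    if (wsamp %% 2 == 0) wsamp <- wsamp + 1L
    half <- (wsamp - 1L) %/% 2L
    tpl <- 0.5 * (1 + cos(pi * seq(-1, 1, length.out = wsamp)))
    centers <- as.integer(round(beat_t * fs)) + 1L
    keep <- centers >= 1L & centers <= n
    centers <- centers[keep]
    beat_amp <- beat_amp[keep]
    sig <- numeric(n)
    for (i in seq_along(centers)) {
      lo <- centers[i] - half
      hi <- centers[i] + half
      tlo <- 1L + max(0L, 1L - lo)
      thi <- wsamp - max(0L, hi - n)
      lo <- max(lo, 1L)
      hi <- min(hi, n)
      sig[lo:hi] <- sig[lo:hi] + beat_amp[i] * tpl[tlo:thi]
    }
    if (config$noise_sd > 0) sig <- sig + rnorm(n, 0, config$noise_sd)

    structure(list(
      signal = sig, fs = fs,
      true_r_peaks = centers, true_r_amplitudes = beat_amp,
      minute_labels = labels,
      true_ahi = 60 / config$duration_min * sum(labels == "A"),
      duration_min = config$duration_min,
      record_id = record_id, config = config
    ), class = "synth_recording")
  })
}

#' Simulate a cohort of synthetic recordings
#'
#' @param classes Character vector of recording classes ("A"/"B"/"C"), one per
#'   recording; determines labels via [simulate_labels()].
#' @param duration_min Minutes per recording.
#' @param seed Integer seed; recording `i` uses `seed + i`.
#' @param ... Further arguments passed to [synth_config()].
#' @return A list of `synth_recording` objects named by record id.
#' @export
simulate_dataset <- function(classes = c("A", "A", "B", "C"),
                             duration_min = 60, seed = 1L, ...) {
  recs <- purrr::imap(classes, function(cl, i) {
    simulate_recording(
      synth_config(duration_min = duration_min, label_pattern = cl,
                   seed = seed + i, ...),
      record_id = sprintf("s%02d%s", i, tolower(cl))
    )
  })
  names(recs) <- purrr::map_chr(recs, "record_id")
  recs
}

#' @export
print.synth_recording <- function(x, ...) {
  cat(sprintf(
    "<synth_recording '%s'> %d min @ %g Hz, %d beats, AHI %.1f (%d apnea min)\n",
    x$record_id, x$duration_min, x$fs, length(x$true_r_peaks), x$true_ahi,
    sum(x$minute_labels == "A")
  ))
  invisible(x)
}

#' Write a recording to disk as a WFDB-style or CSV fixture
#'
#' The WFDB-style format mirrors the field's single-lead archive layout: a
#' plain-text `.hea` header (record name, one channel, sampling rate, sample
#' count; channel line with 16-bit format and gain), a binary `.dat` of
#' 16-bit little-endian samples (signal quantised by the header gain), and a
#' `.apn` annotation file with one label character ("A"/"N") per minute. The
#' CSV format writes one sample value per line (full precision) with a
#' `.labels` sidecar.
#'
#' @param rec A `synth_recording` (or any list with `signal`, `fs`,
#'   `minute_labels`).
#' @param path Base path without extension; files `<path>.hea/.dat/.apn` or
#'   `<path>.csv/.labels` are created.
#' @param format `"wfdb"` or `"csv"`.
#' @param gain Integer quantisation gain for the 16-bit format (units per
#'   physical unit).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("wfdb", "csv"), gain = 1000) {
  format <- match.arg(format)
  if (is.null(rec$signal) || length(rec$signal) == 0) {
    abort("write_recording: recording has an empty signal",
          class = "apneatw_format_error")
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  name <- basename(path)
  if (format == "wfdb") {
    q <- as.integer(pmax(pmin(round(rec$signal * gain), 32767), -32768))
    writeLines(c(
      sprintf("%s 1 %g %d", name, rec$fs, length(q)),
      sprintf("%s.dat 16 %d/unit 16 0 0 0 0 ECG", name, as.integer(gain))
    ), paste0(path, ".hea"))
    con <- file(paste0(path, ".dat"), "wb")
    on.exit(close(con), add = TRUE)
    writeBin(q, con, size = 2L, endian = "little")
    if (!is.null(rec$minute_labels)) {
      writeLines(rec$minute_labels, paste0(path, ".apn"))
    }
  } else {
    writeLines(format(rec$signal, digits = 17, scientific = FALSE, trim = TRUE),
               paste0(path, ".csv"))
    if (!is.null(rec$minute_labels)) {
      writeLines(rec$minute_labels, paste0(path, ".labels"))
    }
  }
  invisible(path)
}
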