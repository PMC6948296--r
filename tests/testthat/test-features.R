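test_that("time-domain features match hand-computed values on tiny series", {
  f <- time_domain_features(c(1, 1, 1))
  expect_equal(f$mrr, 1.0)
  expect_equal(f$sdnn, 0)
  expect_equal(f$rmssd, 0)
  expect_equal(f$nn50, 0)
  expect_equal(f$mhr, 60)

  f2 <- time_domain_features(c(0.8, 1.0))
  expect_equal(f2$rmssd, 0.2)
  expect_equal(f2$nn50, 1)
  expect_equal(f2$pnn50, 1.0)

  # 40 ms differences do not trip the strict 50 ms rule
  expect_equal(time_domain_features(c(1.0, 1.04, 1.0))$nn50, 0)

  # N < 2 marks the segment invalid upstream
  expect_true(is.na(time_domain_features(1.0)$mrr))
})

test_that("time-domain features agree with brute-force loops to 1e-12", {
  withr::with_seed(42, {
    for (rep in 1:200) {
      rr <- runif(sample(2:80, 1), 0.4, 1.6)
      got <- time_domain_features(rr)
      want <- brute_time_domain(rr)
      for (nm in names(want)) {
        expect_equal(got[[nm]], want[[nm]], tolerance = 1e-12)
      }
    }
  })
})

test_that("pNN50 denominator is switchable between pairs and intervals", {
  rr <- c(1.0, 1.1, 1.0, 1.2)
  expect_equal(time_domain_features(rr)$pnn50, 3 / 3)
  expect_equal(time_domain_features(rr, pnn50_denom = "n")$pnn50, 3 / 4)
})

test_that("single tones concentrate band power in their own band", {
  t <- seq(0, 60, by = 0.25)
  tones <- c(vlf = 0.02, lf = 0.1, hf = 0.25)
  for (band in names(tones)) {
    sp <- spectral_features(sin(2 * pi * tones[[band]] * t), t)
    p <- c(vlf = sp$vlf, lf = sp$lf, hf = sp$hf)
    expect_gt(p[[band]] / sum(p), 0.9)
  }
  # constant series: all band power zero after mean removal
  spc <- spectral_features(rep(3.7, length(t)), t)
  expect_equal(spc$vlf + spc$lf + spc$hf, 0)
})

test_that("an LF tone dominates VLF and HF by an order of magnitude", {
  t <- seq(0, 60, by = 0.25)
  sp <- spectral_features(sin(2 * pi * 0.1 * t), t)
  expect_gt(sp$lf, 10 * (sp$vlf + sp$hf))
})

test_that("total band power is bounded by the series variance", {
  withr::with_seed(7, {
    for (rep in 1:10) {
      # beat-like spacing keeps the spline well behaved, as in real tachograms
      tt <- cumsum(runif(70, 0.7, 1.3))
      v <- rnorm(70)
      sp <- spectral_features(v, tt)
      grid <- seq(min(tt), max(tt), by = 0.25)
      vi <- stats::spline(tt, v, xout = grid)$y
      expect_lte(sp$vlf + sp$lf + sp$hf, stats::var(vi) * 1.2 + 1e-9)
    }
  })
})

test_that("spectral features are invariant to a constant offset", {
  t <- seq(0, 60, by = 0.25)
  v <- sin(2 * pi * 0.1 * t) + 0.2 * sin(2 * pi * 0.3 * t)
  a <- spectral_features(v, t)
  b <- spectral_features(v + 100, t)
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("welch estimate matches an independent single-periodogram oracle", {
  # one full segment, no overlap: Welch reduces to a windowed periodogram,
  # recomputed here directly from the definition
  fs <- 4
  x <- sin(2 * pi * 0.5 * seq(0, 63.75, by = 1 / fs))
  got <- welch_psd(x, fs, nfft = 256)
  n <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
  seg <- (x - mean(x)) * w
  sp <- Mod(fft(seg))[1:129]^2 / (fs * sum(w^2))
  sp[2:128] <- 2 * sp[2:128]
  expect_equal(got$psd, sp, tolerance = 1e-10)
  # Parseval on the periodogram: integrated PSD ~ windowed power
  expect_equal(sum(got$psd) * fs / 256, sum(seg^2) / (fs * sum(w^2)) * fs,
               tolerance = 1e-8)
})

test_that("segment assembly yields 18 named features in canonical order", {
  rec <- simulate_recording(synth_config(duration_min = 2, seed = 13))
  f <- extract_features(rec)
  expect_equal(nrow(f), 2)
  expect_true(all(apnea_feature_names() %in% names(f)))
  expect_length(apnea_feature_names(), 18)
  # ratio normalisations sum to one where LF+HF > 0
  ok <- f$valid & (f$rr_lf + f$rr_hf) > 0
  expect_equal(f$rr_lf_norm[ok] + f$rr_hf_norm[ok], rep(1, sum(ok)))
})

test_that("invalid minutes carry NA features and valid = FALSE", {
  rec <- simulate_recording(synth_config(duration_min = 2, seed = 13))
  rec$signal[6001:12000] <- 0  # second minute has no beats
  f <- extract_features(rec)
  expect_false(f$valid[2])
  expect_true(anyNA(f[2, apnea_feature_names()]))
  expect_true(f$valid[1])
})

test_that("apnea minutes show more VLF power than normal minutes", {
  recs <- simulate_dataset(c("A", "A"), duration_min = 30, seed = 21,
                           apnea_severity_range = c(1, 1),
                           apnea_coverage_range = c(1, 1))
  f <- dplyr::bind_rows(lapply(recs, extract_features))
  f <- f[f$valid, ]
  expect_gt(mean(f$rr_vlf[f$label == "A"]), mean(f$rr_vlf[f$label == "N"]))
})

test_that("normalisation is fitted on train only and applied to held-out data", {
  tr <- toy_features(20, seed = 1)
  te <- toy_features(20, record_id = "toy2", seed = 2, shift = 5)
  ns <- fit_normalizer(tr)
  # train set self-normalises to mean 0 sd 1
  trn <- apply_normalizer(tr, ns)
  for (nm in apnea_feature_names()[1:4]) {
    expect_equal(mean(trn[[nm]]), 0, tolerance = 1e-12)
    expect_equal(sd(trn[[nm]]), 1, tolerance = 1e-12)
  }
  # held-out normalisation uses train statistics, recomputed by hand
  ten <- apply_normalizer(te, ns)
  nm <- apnea_feature_names()[1]
  expect_equal(ten[[nm]], (te[[nm]] - mean(tr[[nm]])) / sd(tr[[nm]]),
               tolerance = 1e-12)
  # a constant feature column maps to zero
  tr2 <- tr
  tr2$mrr <- 1
  ns2 <- fit_normalizer(tr2)
  expect_true(all(apply_normalizer(tr2, ns2)$mrr == 0))
  expect_error(fit_normalizer(tr[0, ]), "at least 2",
               class = "apneatw_config_error")
})
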