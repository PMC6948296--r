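test_that("confusion metrics match hand-computed values", {
  truth <- rep(c("A", "A", "N", "N"), c(8, 2, 9, 1))
  pred <- rep(c("A", "N", "N", "A"), c(8, 2, 9, 1))
  m <- segment_metrics(truth, pred)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$sensitivity, 0.80)
  expect_equal(m$specificity, 0.90)
  expect_equal(m[, c("tp", "fn", "tn", "fp")],
               tibble::tibble(tp = 8L, fn = 2L, tn = 9L, fp = 1L))
  expect_equal(m$n, 20L)
})

test_that("metrics agree with brute-force counting on random vectors", {
  withr::with_seed(9, {
    for (rep in 1:50) {
      n <- sample(10:200, 1)
      truth <- sample(c(0L, 1L), n, replace = TRUE)
      pred <- sample(c(0L, 1L), n, replace = TRUE)
      if (length(unique(truth)) < 2) next
      m <- segment_metrics(truth, pred)
      tp <- 0; tn <- 0; fp <- 0; fn <- 0
      for (i in seq_len(n)) {
        if (truth[i] == 1 && pred[i] == 1) tp <- tp + 1
        if (truth[i] == 0 && pred[i] == 0) tn <- tn + 1
        if (truth[i] == 0 && pred[i] == 1) fp <- fp + 1
        if (truth[i] == 1 && pred[i] == 0) fn <- fn + 1
      }
      expect_equal(m$accuracy, (tp + tn) / n)
      expect_equal(m$sensitivity, tp / (tp + fn))
      expect_equal(m$specificity, tn / (tn + fp))
    }
  })
})

test_that("AUC: perfect separation gives 1, random scores give ~0.5", {
  truth <- rep(c("N", "A"), each = 50)
  expect_equal(auc_score(c(rnorm(50, -5), rnorm(50, 5)), truth), 1.0)
  withr::with_seed(2, {
    big_truth <- sample(c(0L, 1L), 10000, replace = TRUE)
    auc <- auc_score(rnorm(10000), big_truth)
  })
  expect_gt(auc, 0.48)
  expect_lt(auc, 0.52)
  expect_warning(auc_score(rnorm(5), rep("A", 5)), "single-class")
})

test_that("AHI follows 60/T * apnea count with a strict >5 rule", {
  p <- tibble::tibble(record_id = "r", pred = rep(c("A", "N"), c(10, 50)),
                      label = rep(c("A", "N"), c(12, 48)))
  s <- compute_ahi(p)
  expect_equal(s$ahi_pred, 10)
  expect_equal(s$class_pred, "A")
  expect_equal(s$ahi_true, 12)

  # boundary: AHI exactly 5 is classified normal
  pb <- tibble::tibble(record_id = "b", pred = rep(c("A", "N"), c(40, 440)))
  expect_equal(compute_ahi(pb)$ahi_pred, 5)
  expect_equal(compute_ahi(pb)$class_pred, "N")

  p0 <- tibble::tibble(record_id = "z", pred = rep("N", 30))
  expect_equal(compute_ahi(p0)$ahi_pred, 0)

  # rational-arithmetic exactness: 60 * n == ahi * T
  withr::with_seed(3, {
    for (rep in 1:20) {
      t_min <- sample(10:600, 1)
      n_sa <- sample(0:t_min, 1)
      pr <- tibble::tibble(record_id = "q",
                           pred = rep(c("A", "N"), c(n_sa, t_min - n_sa)))
      ahi <- compute_ahi(pr)$ahi_pred
      expect_equal(60 * n_sa, ahi * t_min)
    }
  })
})

test_that("recording metrics: identity gives accuracy 1 and correlation 1", {
  s <- tibble::tibble(record_id = letters[1:5],
                      ahi_pred = c(0, 3, 8, 20, 40),
                      ahi_true = c(0, 3, 8, 20, 40))
  s$class_pred <- ifelse(s$ahi_pred > 5, "A", "N")
  s$class_true <- ifelse(s$ahi_true > 5, "A", "N")
  m <- recording_metrics(s)
  expect_equal(m$accuracy, 1)
  expect_equal(m$pearson_corr, 1)
  expect_equal(m$auc, 1)
})

test_that("pearson correlation matches the brute-force formula", {
  withr::with_seed(5, {
    ap <- runif(5, 0, 40)
    at <- ap + rnorm(5, 0, 4)
  })
  s <- tibble::tibble(record_id = letters[1:5], ahi_pred = ap, ahi_true = at,
                      class_pred = ifelse(ap > 5, "A", "N"),
                      class_true = ifelse(at > 5, "A", "N"))
  m <- suppressWarnings(recording_metrics(s))
  num <- sum((ap - mean(ap)) * (at - mean(at)))
  den <- sqrt(sum((ap - mean(ap))^2) * sum((at - mean(at))^2))
  expect_equal(m$pearson_corr, num / den, tolerance = 1e-12)
  # inverted 2-point toy gives correlation -1
  s2 <- tibble::tibble(record_id = c("a", "b"), ahi_pred = c(1, 10),
                       ahi_true = c(10, 1),
                       class_pred = c("N", "A"), class_true = c("A", "N"))
  expect_equal(suppressWarnings(recording_metrics(s2))$pearson_corr, -1)
})

test_that("bland-altman matches hand computation and degenerate cases", {
  ba0 <- bland_altman(c(5, 10, 20), c(5, 10, 20))
  expect_equal(ba0$bias, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))

  ba3 <- bland_altman(c(8, 13, 23), c(5, 10, 20))
  expect_equal(ba3$bias, 3)
  expect_equal(ba3$sd_diff, 0)

  # hand-computed toy
  pred <- c(12, 30, 4, 18)
  ref <- c(10, 33, 5, 15)
  ba <- bland_altman(pred, ref)
  d <- pred - ref
  expect_equal(ba$bias, mean(d))
  expect_equal(ba$loa_low, mean(d) - 1.96 * sd(d))
  expect_equal(ba$loa_high, mean(d) + 1.96 * sd(d))
  expect_equal(tidy(ba)$mean, (pred + ref) / 2)
  expect_error(bland_altman(1, numeric(0)), class = "apneatw_config_error")
  expect_s3_class(autoplot(ba), "ggplot")
})

test_that("limits of agreement contain about 95% of large-n differences", {
  withr::with_seed(8, {
    pred <- rnorm(5000, 10, 3)
    ref <- rnorm(5000, 10, 3)
  })
  ba <- bland_altman(pred, ref)
  inside <- mean(tidy(ba)$diff > ba$loa_low & tidy(ba)$diff < ba$loa_high)
  expect_gt(inside, 0.94)
  expect_lt(inside, 0.96)
})

test_that("window sweep recomputes 2(18w)+1 hidden nodes per row", {
  f <- dplyr::bind_rows(lapply(1:4, function(i)
    toy_features(25, sprintf("r%d", i), seed = i)))
  sw <- window_sweep(f, w_values = c(1, 2, 3),
                     config = mlp_config(epochs = 10, seed = 1), seed = 1)
  expect_equal(sw$w, c(1L, 2L, 3L))
  expect_equal(sw$h_nodes, 2L * 18L * c(1L, 2L, 3L) + 1L)
  expect_true(all(diff(sw$w) > 0))
  expect_s3_class(autoplot(sw), "ggplot")
})

test_that("k-fold CV partitions recordings disjointly and covers all", {
  f <- dplyr::bind_rows(lapply(1:14, function(i)
    toy_features(25, sprintf("r%02d", i), seed = i)))
  # toy recordings share one AHI class, so recording-level sensitivity /
  # correlation warnings are expected here
  cv <- suppressWarnings(
    kfold_cv(f, k = 7, w = 2, config = mlp_config(epochs = 5, seed = 1),
             seed = 2))
  expect_equal(sort(unique(cv$folds$fold)), 1:7)
  expect_equal(nrow(cv$folds), 14)
  expect_equal(anyDuplicated(cv$folds$record_id), 0)
  expect_true(all(table(cv$folds$fold) == 2))
  expect_equal(nrow(cv$per_fold), 7)
  expect_true(all(c("metric", "mean", "ci_low", "ci_high") %in% names(cv$summary)))
  expect_error(kfold_cv(f, k = 20), class = "apneatw_config_error")
})
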