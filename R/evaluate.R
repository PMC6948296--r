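#' Confusion counts for per-segment predictions
#'
#' @param truth Character "A"/"N" (or integer 0/1) true labels; apnea is the
#'   positive class.
#' @param pred Predicted labels, same encoding.
#' @return One-row tibble `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, pred) {
  t1 <- as_binary_label(truth)
  p1 <- as_binary_label(pred)
  tibble(
    tp = sum(t1 == 1 & p1 == 1), tn = sum(t1 == 0 & p1 == 0),
    fp = sum(t1 == 0 & p1 == 1), fn = sum(t1 == 1 & p1 == 0)
  )
}

as_binary_label <- function(x) {
  if (is.character(x)) as.integer(x == "A") else as.integer(x)
}

#' Rank-based AUC
#'
#' Probability that a randomly chosen positive outscores a randomly chosen
#' negative, ties counting one half (the Mann-Whitney statistic), equal to
#' the trapezoidal area under the ROC curve.
#'
#' @param score Numeric scores, larger = more apnea-like.
#' @param truth True labels ("A"/"N" or 0/1).
#' @return AUC in `[0, 1]`, or `NA` with a warning for single-class truth.
#' @export
auc_score <- function(score, truth) {
  y <- as_binary_label(truth)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    warn("auc_score: single-class truth; AUC undefined")
    return(NA_real_)
  }
  r <- rank(score)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-segment classification metrics
#'
#' Accuracy (TP+TN)/(TP+TN+FP+FN), sensitivity TP/(TP+FN), specificity
#' TN/(TN+FP), and rank [auc_score()] when scores are supplied. With
#' single-class truth the undefined rate is returned as `NaN` with a
#' warning.
#'
#' @param truth,pred Labels ("A"/"N" or 0/1); apnea positive.
#' @param score Optional numeric scores for the AUC.
#' @return One-row tibble `accuracy`, `sensitivity`, `specificity`, `auc`,
#'   `tp`, `tn`, `fp`, `fn`, `n`.
#' @export
#' @examples
#' segment_metrics(c("A", "A", "N"), c("A", "N", "N"))
segment_metrics <- function(truth, pred, score = NULL) {
  cc <- confusion_counts(truth, pred)
  n <- cc$tp + cc$tn + cc$fp + cc$fn
  if (cc$tp + cc$fn == 0 || cc$tn + cc$fp == 0) {
    warn("segment_metrics: single-class truth; sensitivity or specificity undefined")
  }
  tibble(
    accuracy = (cc$tp + cc$tn) / n,
    sensitivity = cc$tp / (cc$tp + cc$fn),
    specificity = cc$tn / (cc$tn + cc$fp),
    auc = if (is.null(score)) NA_real_ else auc_score(score, truth),
    tp = cc$tp, tn = cc$tn, fp = cc$fp, fn = cc$fn, n = n
  )
}

#' Apnea-hypopnea index and per-recording diagnosis
#'
#' AHI = 60 / T * (number of apnea segments), with T the number of evaluated
#' minutes; a recording is classified apnea when AHI exceeds 5 strictly.
#' Applied to predicted and (when present) true labels of each recording.
#'
#' @param predictions Tibble from [predict.tw_mlp()] (columns `record_id`,
#'   `pred`, optionally `label`).
#' @param t_minutes Optional named vector of full recording durations in
#'   minutes; by default T is the number of evaluated minutes per recording
#'   (window-trimmed).
#' @return A tibble, one row per recording: `record_id`, `t_min`,
#'   `n_sa_segments`, `ahi_pred`, `class_pred`, and `ahi_true`/`class_true`
#'   when labels are present.
#' @export
#' @examples
#' compute_ahi(tibble::tibble(record_id = "r", pred = rep(c("A", "N"), c(10, 50)),
#'                            label = rep(c("A", "N"), c(12, 48))))
compute_ahi <- function(predictions, t_minutes = NULL) {
  has_truth <- "label" %in% names(predictions) && !all(is.na(predictions$label))
  out <- predictions |>
    dplyr::group_by(.data$record_id) |>
    dplyr::summarise(
      t_min = dplyr::n(),
      n_sa_segments = sum(.data$pred == "A"),
      n_sa_true = if (has_truth) sum(.data$label == "A") else NA_integer_,
      .groups = "drop"
    )
  if (!is.null(t_minutes)) {
    if (any(out$t_min > t_minutes[out$record_id])) {
      abort("compute_ahi: t_minutes smaller than the number of evaluated minutes",
            class = "apneatw_config_error")
    }
    out$t_min <- as.integer(t_minutes[out$record_id])
  }
  if (any(out$t_min <= 0)) {
    abort("compute_ahi: T must be positive", class = "apneatw_config_error")
  }
  out$ahi_pred <- 60 / out$t_min * out$n_sa_segments
  out$class_pred <- ifelse(out$ahi_pred > 5, "A", "N")
  if (has_truth) {
    out$ahi_true <- 60 / out$t_min * out$n_sa_true
    out$class_true <- ifelse(out$ahi_true > 5, "A", "N")
  }
  out$n_sa_true <- NULL
  out
}

#' Per-recording diagnosis metrics
#'
#' Confusion metrics on the predicted versus true recording class, AUC using
#' the predicted AHI as the ranking score, and the Pearson correlation
#' between predicted and true AHI.
#'
#' @param summaries Output of [compute_ahi()] with truth columns.
#' @return One-row tibble `accuracy`, `sensitivity`, `specificity`, `auc`,
#'   `pearson_corr`, `n_recordings`.
#' @export
recording_metrics <- function(summaries) {
  if (nrow(summaries) < 2) {
    abort("recording_metrics: need at least 2 recordings",
          class = "apneatw_config_error")
  }
  if (sd(summaries$ahi_pred) == 0 || sd(summaries$ahi_true) == 0) {
    warn("recording_metrics: constant AHI vector; correlation undefined")
    pc <- NA_real_
  } else {
    pc <- cor(summaries$ahi_pred, summaries$ahi_true)
  }
  sm <- segment_metrics(summaries$class_true, summaries$class_pred,
                        score = summaries$ahi_pred)
  tibble(accuracy = sm$accuracy, sensitivity = sm$sensitivity,
         specificity = sm$specificity, auc = sm$auc,
         pearson_corr = pc, n_recordings = nrow(summaries))
}

#' Bland-Altman agreement between predicted and reference AHI
#'
#' Bias is the mean of the differences (predicted minus reference); the
#' limits of agreement are bias +/- 1.96 times their standard deviation.
#'
#' @param ahi_pred,ahi_true Numeric vectors of equal length >= 2.
#' @return A list of class `bland_altman`: `bias`, `loa_low`, `loa_high`,
#'   `sd_diff`, and `points` (tibble `mean`, `diff`).
#' @export
#' @examples
#' bland_altman(c(10, 20, 31), c(11, 19, 30))
bland_altman <- function(ahi_pred, ahi_true) {
  if (length(ahi_pred) != length(ahi_true) || length(ahi_pred) < 2) {
    abort("bland_altman: need two equal-length vectors of at least 2 pairs",
          class = "apneatw_config_error")
  }
  d <- ahi_pred - ahi_true
  bias <- mean(d)
  s <- sd(d)
  structure(list(
    bias = bias, sd_diff = s,
    loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
    points = tibble(mean = (ahi_pred + ahi_true) / 2, diff = d)
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %.3f, limits of agreement [%.3f, %.3f] (n = %d)\n",
              x$bias, x$loa_low, x$loa_high, nrow(x$points)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bland_altman <- function(x, ...) x$points

#' @exportS3Method generics::glance
glance.bland_altman <- function(x, ...) {
  tibble(bias = x$bias, sd_diff = x$sd_diff,
         loa_low = x$loa_low, loa_high = x$loa_high, n = nrow(x$points))
}

#' @exportS3Method ggplot2::autoplot
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$bias, linetype = 1) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = 2) +
    ggplot2::labs(x = "mean of predicted and reference AHI (events/h)",
                  y = "difference (predicted - reference)",
                  title = "Bland-Altman agreement") +
    ggplot2::theme_minimal()
}

# Recording-level train/test split, optionally stratified (e.g. by AHI
# class) so small cohorts keep both diagnoses in the test set.
split_recordings <- function(ids, test_fraction, seed, strata = NULL) {
  withr::with_seed(seed, {
    if (is.null(strata)) strata <- rep("all", length(ids))
    test <- unlist(lapply(split(ids, strata), function(g) {
      sample(g, max(1L, round(test_fraction * length(g))))
    }), use.names = FALSE)
    list(train = setdiff(ids, test), test = test)
  })
}

#' Window-size sweep
#'
#' Trains and evaluates the detector once per window size on a fixed
#' recording-level train/test split, recomputing the hidden width 2M+1 as
#' the window grows. This reproduces the characteristic accuracy-versus-
#' window curve: rising at first (more context), then flattening or
#' declining (overfitting, coverage loss).
#'
#' @param features Labelled feature tibble (several recordings).
#' @param w_values Integer window sizes to try.
#' @param config An [mlp_config()].
#' @param test_fraction Fraction of recordings held out.
#' @param seed Seed for the split.
#' @return A tibble of class `window_sweep`: one row per `w` with `m`,
#'   `h_nodes`, `n_test`, `accuracy`, `sensitivity`, `specificity`, `auc`.
#' @export
window_sweep <- function(features, w_values = 1:7, config = mlp_config(),
                         test_fraction = 0.3, seed = 1L) {
  sp <- split_recordings(unique(features$record_id), test_fraction, seed)
  ftr <- features[features$record_id %in% sp$train, , drop = FALSE]
  fte <- features[features$record_id %in% sp$test, , drop = FALSE]
  out <- purrr::map_dfr(sort(unique(as.integer(w_values))), function(w) {
    fit <- fit_tw_mlp(ftr, w = w, config = config)
    pr <- predict(fit, fte)
    sm <- segment_metrics(pr$label, pr$pred, pr$score)
    tibble(w = w, m = fit$model$m, h_nodes = fit$model$h,
           n_test = nrow(pr), accuracy = sm$accuracy,
           sensitivity = sm$sensitivity, specificity = sm$specificity,
           auc = sm$auc)
  })
  class(out) <- c("window_sweep", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.window_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$w, y = .data$accuracy)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "time window size (segments)",
                  y = "per-segment accuracy",
                  title = "Effect of the time window") +
    ggplot2::theme_minimal()
}

#' Recording-level k-fold cross-validation
#'
#' Recordings (never individual minutes) are partitioned into `k` seeded
#' folds, so no subject contributes segments to both train and test of any
#' fold; normalisation and training are refit per fold. Fold means come
#' with t-distribution 95% confidence intervals (k - 1 degrees of freedom).
#'
#' @param features Labelled feature tibble covering at least `k` recordings.
#' @param k Number of folds (default 7).
#' @param w Window size.
#' @param config An [mlp_config()].
#' @param seed Seed for the fold assignment.
#' @return A list of class `cv_result`: `folds` (tibble of fold/record
#'   assignment), `per_fold` (segment + recording metrics per fold), and
#'   `summary` (metric, mean, ci_low, ci_high).
#' @export
kfold_cv <- function(features, k = 7L, w = 5L, config = mlp_config(),
                     seed = 1L) {
  ids <- unique(features$record_id)
  if (length(ids) < k) {
    abort(sprintf("kfold_cv: %d recordings cannot fill %d folds",
                  length(ids), k), class = "apneatw_config_error")
  }
  folds <- withr::with_seed(seed, {
    tibble(record_id = sample(ids),
           fold = rep_len(seq_len(k), length(ids)))
  })
  per_fold <- purrr::map_dfr(seq_len(k), function(f) {
    te_ids <- folds$record_id[folds$fold == f]
    fit <- fit_tw_mlp(features[!features$record_id %in% te_ids, , drop = FALSE],
                      w = w, config = config)
    pr <- predict(fit, features[features$record_id %in% te_ids, , drop = FALSE])
    sm <- segment_metrics(pr$label, pr$pred, pr$score)
    rec <- if (length(te_ids) >= 2) {
      recording_metrics(compute_ahi(pr))
    } else {
      tibble(accuracy = NA_real_)
    }
    tibble(fold = f, n_test_segments = nrow(pr),
           seg_accuracy = sm$accuracy, seg_sensitivity = sm$sensitivity,
           seg_specificity = sm$specificity, seg_auc = sm$auc,
           rec_accuracy = rec$accuracy)
  })
  metrics <- c("seg_accuracy", "seg_sensitivity", "seg_specificity",
               "seg_auc", "rec_accuracy")
  summary <- purrr::map_dfr(metrics, function(m) {
    v <- per_fold[[m]]
    v <- v[!is.na(v)]
    se <- sd(v) / sqrt(length(v))
    half <- qt(0.975, df = length(v) - 1) * se
    tibble(metric = m, mean = mean(v),
           ci_low = mean(v) - half, ci_high = mean(v) + half)
  })
  structure(list(folds = folds, per_fold = per_fold, summary = summary,
                 k = k, w = w), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold recording-level CV, w = %d\n", x$k, x$w))
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}
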