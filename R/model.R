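#' Build the moving-time-window design matrix
#'
#' For every minute `k >= w - 1` of each recording, concatenates the
#' normalised features of the `w` consecutive segments `k - w + 1 .. k`
#' (oldest first, current segment last) into one input row labelled with the
#' *current* segment's label. Successive windows differ by one segment (a
#' moving window). Windows that would span two recordings, contain an
#' invalid segment, or skip a missing minute are dropped; `w = 1` reduces
#' exactly to the plain per-segment (non-window) design.
#'
#' @param features Feature tibble from [extract_features()] (already
#'   normalised), possibly several recordings stacked.
#' @param w Window size: total number of segments per input, including the
#'   current one (>= 1).
#' @return A list of class `windowed_dataset`: `X` (n x (w*18) matrix,
#'   columns named `<feature>_lag<j>` with lag w-1..0), `y` (integer 0/1,
#'   apnea = 1; `NA` when unlabelled), `index` (tibble `record_id`,
#'   `minute`), and `w`.
#' @export
#' @examples
#' f <- extract_features(simulate_recording(synth_config(duration_min = 8, seed = 3)))
#' bw <- build_windows(apply_normalizer(f, fit_normalizer(f)), w = 2)
#' dim(bw$X)
build_windows <- function(features, w = 5L) {
  w <- as.integer(w)
  if (is.na(w) || w < 1L) {
    abort("build_windows: window size w must be an integer >= 1",
          class = "apneatw_config_error")
  }
  nfeat <- length(APNEA_FEATURES)
  cn <- as.vector(vapply((w - 1L):0L, function(l) paste0(APNEA_FEATURES, "_lag", l),
                         character(nfeat)))
  rows <- list()
  ys <- integer(0)
  ids <- character(0)
  mins <- integer(0)
  for (rid in unique(features$record_id)) {
    fr <- features[features$record_id == rid, , drop = FALSE]
    fr <- fr[order(fr$minute), , drop = FALSE]
    if (nrow(fr) < w) next
    fmat <- as.matrix(fr[, APNEA_FEATURES])
    for (i in w:nrow(fr)) {
      sel <- (i - w + 1L):i
      if (!all(fr$valid[sel])) next
      if (fr$minute[i] - fr$minute[i - w + 1L] != w - 1L) next  # gap
      rows[[length(rows) + 1L]] <- as.vector(t(fmat[sel, , drop = FALSE]))
      ys <- c(ys, if (is.na(fr$label[i])) NA_integer_ else as.integer(fr$label[i] == "A"))
      ids <- c(ids, rid)
      mins <- c(mins, fr$minute[i])
    }
  }
  X <- if (length(rows) > 0) do.call(rbind, rows) else
    matrix(numeric(0), 0, w * nfeat)
  colnames(X) <- cn
  structure(list(X = X, y = ys,
                 index = tibble(record_id = ids, minute = mins), w = w),
            class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf("<windowed_dataset> %d samples x %d inputs (w = %d), %d apnea / %d normal\n",
              nrow(x$X), ncol(x$X), x$w,
              sum(x$y == 1, na.rm = TRUE), sum(x$y == 0, na.rm = TRUE)))
  invisible(x)
}

#' Training configuration for the perceptron
#'
#' @param lr Learning rate for mini-batch stochastic gradient descent.
#' @param momentum Classical momentum coefficient.
#' @param batch_size Mini-batch size.
#' @param epochs Maximum number of epochs.
#' @param l2 L2 weight-decay coefficient applied to the connection weights
#'   (not biases); 0 disables it. A small penalty keeps the wide 2M+1 hidden
#'   layer from memorising small training sets.
#' @param val_fraction Fraction of training samples held out for early
#'   stopping.
#' @param patience Epochs without validation improvement before stopping.
#' @param seed Integer seed for weight initialisation, shuffling and the
#'   validation split.
#' @return A list of class `mlp_config`.
#' @export
mlp_config <- function(lr = 0.01, momentum = 0.9, batch_size = 128L,
                       epochs = 200L, l2 = 3e-2, val_fraction = 0.1,
                       patience = 20L, seed = 1L) {
  structure(list(lr = lr, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), l2 = l2,
                 val_fraction = val_fraction,
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "mlp_config")
}

#' Hidden-layer width by the Kolmogorov superposition rule
#'
#' One hidden layer of `2 * M + 1` relu units for `M` inputs; with 18
#' features per segment and a 5-segment window, `M = 90` and `H = 181`.
#'
#' @param m Number of network inputs.
#' @return Integer hidden-layer width.
#' @export
#' @examples
#' hidden_size(90)
hidden_size <- function(m) 2L * as.integer(m) + 1L

#' Initialise a one-hidden-layer perceptron
#'
#' Hidden width follows [hidden_size()] (2M+1). Weights are drawn uniformly
#' from +/- sqrt(6 / (fan_in + fan_out)); biases start at zero.
#'
#' @param m Input dimension (>= 1).
#' @param c_out Output dimension (2: normal, apnea).
#' @param seed Integer seed.
#' @return A list of class `mlp_model` with `W1` (m x H), `b1`, `W2`
#'   (H x C), `b2`, `m`, `h`, `c_out`.
#' @export
mlp_init <- function(m, c_out = 2L, seed = 1L) {
  stopifnot(m >= 1)
  h <- hidden_size(m)
  withr::with_seed(seed, {
    l1 <- sqrt(6 / (m + h))
    l2 <- sqrt(6 / (h + c_out))
    structure(list(
      W1 = matrix(runif(m * h, -l1, l1), m, h),
      b1 = numeric(h),
      W2 = matrix(runif(h * c_out, -l2, l2), h, c_out),
      b2 = numeric(c_out),
      m = as.integer(m), h = h, c_out = as.integer(c_out)
    ), class = "mlp_model")
  })
}

#' Forward pass of the perceptron
#'
#' Hidden activations v = relu(W1' x + b1); linear outputs y = W2' v + b2.
#' The apnea score is `y_apnea - y_normal`; the predicted label is the
#' arg-max output, with ties resolved to normal.
#'
#' @param model An `mlp_model`.
#' @param X Input matrix (n x m).
#' @return A list: `outputs` (n x 2 matrix, columns normal/apnea), `score`
#'   (numeric), `pred` (integer 0/1).
#' @export
mlp_forward <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$m) {
    abort(sprintf("mlp_forward: input has %d columns but the model expects %d",
                  ncol(X), model$m), class = "apneatw_dim_error")
  }
  V <- pmax(sweep(X %*% model$W1, 2, model$b1, "+"), 0)
  Y <- sweep(V %*% model$W2, 2, model$b2, "+")
  colnames(Y) <- c("normal", "apnea")
  score <- Y[, 2] - Y[, 1]
  list(outputs = Y, score = score, pred = as.integer(score > 0))
}

#' Train the perceptron by backpropagation on the summed squared error
#'
#' Minimises E = sum over samples and outputs of (t_c - y_c)^2 with one-hot
#' targets, by mini-batch stochastic gradient descent with momentum
#' (gradients averaged within the batch). A seeded fraction of the training
#' samples is held out for early stopping: training stops once the
#' validation loss has not improved for `patience` epochs and the best
#' weights are restored. Fully deterministic given the config seed.
#'
#' @param model An `mlp_model` from [mlp_init()].
#' @param X Training inputs (n x m).
#' @param y Integer labels, 0 = normal, 1 = apnea; both classes required.
#' @param config An [mlp_config()].
#' @return The fitted `mlp_model`, with a `history` tibble (epoch, train and
#'   validation mean loss) attached.
#' @export
mlp_train <- function(model, X, y, config = mlp_config()) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2) {
    abort("mlp_train: training labels contain a single class",
          class = "apneatw_config_error")
  }
  if (nrow(X) != length(y)) {
    abort("mlp_train: X rows and labels differ in length",
          class = "apneatw_dim_error")
  }
  n <- nrow(X)
  Tmat <- cbind(normal = 1 - y, apnea = y)

  withr::with_seed(config$seed, {
    n_val <- max(0L, as.integer(floor(config$val_fraction * n)))
    val_idx <- if (n_val >= 2) sample.int(n, n_val) else integer(0)
    tr_idx <- setdiff(seq_len(n), val_idx)
    if (length(unique(y[tr_idx])) < 2) {  # degenerate split; train on all
      tr_idx <- seq_len(n)
      val_idx <- integer(0)
    }
    Xtr <- X[tr_idx, , drop = FALSE]
    Ttr <- Tmat[tr_idx, , drop = FALSE]
    Xval <- X[val_idx, , drop = FALSE]
    Tval <- Tmat[val_idx, , drop = FALSE]

    vW1 <- model$W1 * 0; vb1 <- model$b1 * 0
    vW2 <- model$W2 * 0; vb2 <- model$b2 * 0
    best <- list(loss = Inf, model = model)
    wait <- 0L
    hist_tr <- numeric(0); hist_val <- numeric(0)
    loss_of <- function(mod, Xs, Ts) {
      if (nrow(Xs) == 0) return(NA_real_)
      Y <- mlp_forward(mod, Xs)$outputs
      mean(rowSums((Ts - Y)^2))
    }

    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(nrow(Xtr))
      for (bs in seq(1L, nrow(Xtr), by = config$batch_size)) {
        bi <- ord[bs:min(bs + config$batch_size - 1L, nrow(Xtr))]
        Xb <- Xtr[bi, , drop = FALSE]
        Tb <- Ttr[bi, , drop = FALSE]
        Z1 <- sweep(Xb %*% model$W1, 2, model$b1, "+")
        V <- pmax(Z1, 0)
        Y <- sweep(V %*% model$W2, 2, model$b2, "+")
        dY <- 2 * (Y - Tb) / nrow(Xb)
        gW2 <- crossprod(V, dY) + config$l2 * model$W2
        gb2 <- colSums(dY)
        dV <- dY %*% t(model$W2) * (Z1 > 0)
        gW1 <- crossprod(Xb, dV) + config$l2 * model$W1
        gb1 <- colSums(dV)
        vW2 <- config$momentum * vW2 - config$lr * gW2
        vb2 <- config$momentum * vb2 - config$lr * gb2
        vW1 <- config$momentum * vW1 - config$lr * gW1
        vb1 <- config$momentum * vb1 - config$lr * gb1
        model$W2 <- model$W2 + vW2
        model$b2 <- model$b2 + vb2
        model$W1 <- model$W1 + vW1
        model$b1 <- model$b1 + vb1
      }
      ltr <- loss_of(model, Xtr, Ttr)
      lval <- loss_of(model, Xval, Tval)
      hist_tr <- c(hist_tr, ltr)
      hist_val <- c(hist_val, lval)
      monitor <- if (is.na(lval)) ltr else lval
      if (monitor < best$loss - 1e-9) {
        best <- list(loss = monitor, model = model)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    out <- best$model
    out$history <- tibble(epoch = seq_along(hist_tr),
                          train_loss = hist_tr, val_loss = hist_val)
    out$config <- config
    out
  })
}

#' Fit the time-window apnea detector end to end
#'
#' The user-facing fit: takes a raw (unnormalised) feature table, fits the
#' z-score normaliser on it, builds `w`-segment moving windows, sizes the
#' hidden layer as 2M+1, and trains the perceptron. `w = 1` is the plain
#' non-window MLP baseline.
#'
#' @param features Feature tibble from [extract_features()] (one or more
#'   recordings), with labels.
#' @param w Window size in segments (including the current one).
#' @param config An [mlp_config()].
#' @param pnn50_denom Recorded for provenance.
#' @return An object of class `tw_mlp`: `model`, `norm_stats`, `w`,
#'   `feature_names`, `config`, `train_index`.
#' @export
#' @examples
#' recs <- simulate_dataset(c("A", "C"), duration_min = 12, seed = 5)
#' feats <- dplyr::bind_rows(lapply(recs, extract_features))
#' fit <- fit_tw_mlp(feats, w = 2, config = mlp_config(epochs = 20))
fit_tw_mlp <- function(features, w = 5L, config = mlp_config(),
                       pnn50_denom = "pairs") {
  ns <- fit_normalizer(features)
  bw <- build_windows(apply_normalizer(features, ns), w = w)
  keep <- !is.na(bw$y)
  if (sum(keep) == 0) {
    abort("fit_tw_mlp: no labelled windowed samples to train on",
          class = "apneatw_config_error")
  }
  model <- mlp_init(ncol(bw$X), c_out = 2L, seed = config$seed)
  model <- mlp_train(model, bw$X[keep, , drop = FALSE], bw$y[keep], config)
  structure(list(model = model, norm_stats = ns, w = bw$w,
                 feature_names = APNEA_FEATURES, config = config,
                 pnn50_denom = pnn50_denom,
                 train_index = bw$index[keep, , drop = FALSE]),
            class = "tw_mlp")
}

#' @export
print.tw_mlp <- function(x, ...) {
  cat(sprintf("<tw_mlp> w = %d, M = %d inputs, H = %d hidden (2M+1), trained %d epochs\n",
              x$w, x$model$m, x$model$h, nrow(x$model$history)))
  invisible(x)
}

#' Per-segment predictions of a fitted detector
#'
#' Normalises `features` with the training statistics, windows them with the
#' training window size, and scores every predictable minute.
#'
#' @param object A `tw_mlp` fit.
#' @param features A feature tibble from [extract_features()].
#' @param ... Unused.
#' @return A tibble `record_id`, `minute`, `label`, `score`
#'   (y_apnea - y_normal) and `pred` ("A"/"N").
#' @export
predict.tw_mlp <- function(object, features, ...) {
  bw <- build_windows(apply_normalizer(features, object$norm_stats),
                      w = object$w)
  fw <- mlp_forward(object$model, bw$X)
  dplyr::bind_cols(
    bw$index,
    tibble(label = ifelse(is.na(bw$y), NA_character_,
                          ifelse(bw$y == 1, "A", "N")),
           score = fw$score,
           pred = ifelse(fw$pred == 1, "A", "N"))
  )
}

#' @exportS3Method generics::tidy
tidy.tw_mlp <- function(x, ...) {
  x$model$history
}

#' @exportS3Method generics::glance
glance.tw_mlp <- function(x, ...) {
  h <- x$model$history
  tibble(
    w = x$w, m = x$model$m, h_nodes = x$model$h,
    epochs = nrow(h),
    train_loss = h$train_loss[nrow(h)],
    val_loss = h$val_loss[nrow(h)],
    n_train = nrow(x$train_index)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.tw_mlp <- function(object, ...) {
  d <- tidyr::pivot_longer(object$model$history, -"epoch",
                           names_to = "set", values_to = "loss")
  ggplot2::ggplot(d[!is.na(d$loss), ],
                  ggplot2::aes(x = .data$epoch, y = .data$loss,
                               colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean squared error",
                  colour = NULL, title = "Training history") +
    ggplot2::theme_minimal()
}

#' Serialise a fitted detector to JSON
#'
#' Everything needed to reproduce predictions bit for bit: weights at full
#' precision, normalisation statistics, feature order, window size and
#' training configuration.
#'
#' @param fit A `tw_mlp`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tw_mlp <- function(fit, path) {
  obj <- list(
    format = "apneatw-mlp-1",
    w = fit$w, feature_names = fit$feature_names,
    pnn50_denom = fit$pnn50_denom,
    norm_stats = as.data.frame(fit$norm_stats),
    config = unclass(fit$config),
    model = list(m = fit$model$m, h = fit$model$h, c_out = fit$model$c_out,
                 W1 = fit$model$W1, b1 = fit$model$b1,
                 W2 = fit$model$W2, b2 = fit$model$b2)
  )
  # digits = I(17) round-trips IEEE doubles exactly, so reloaded models
  # reproduce predictions bit for bit
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_tw_mlp
#' @export
read_tw_mlp <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "apneatw-mlp-1")) {
    abort(sprintf("read_tw_mlp: '%s' is not an apneatw model file", path),
          class = "apneatw_format_error")
  }
  ns <- as_tibble(obj$norm_stats)
  class(ns) <- c("norm_stats", class(ns))
  model <- structure(list(
    W1 = matrix(obj$model$W1, obj$model$m, obj$model$h),
    b1 = as.numeric(obj$model$b1),
    W2 = matrix(obj$model$W2, obj$model$h, obj$model$c_out),
    b2 = as.numeric(obj$model$b2),
    m = as.integer(obj$model$m), h = as.integer(obj$model$h),
    c_out = as.integer(obj$model$c_out),
    history = tibble(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  ), class = "mlp_model")
  structure(list(model = model, norm_stats = ns, w = as.integer(obj$w),
                 feature_names = obj$feature_names,
                 config = do.call(mlp_config, as.list(obj$config)),
                 pnn50_denom = obj$pnn50_denom,
                 train_index = tibble(record_id = character(),
                                      minute = integer())),
            class = "tw_mlp")
}
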