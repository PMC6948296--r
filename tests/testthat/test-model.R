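test_that("window counting: 10 valid segments with w=5 give 6 samples", {
  f <- toy_features(10)
  bw <- build_windows(f, w = 5)
  expect_equal(nrow(bw$X), 6)
  expect_equal(bw$index$minute, 4:9)
  expect_equal(ncol(bw$X), 90)
  # brute enumeration over several sizes
  for (n in c(5, 7, 12)) {
    for (w in 1:4) {
      bwk <- build_windows(toy_features(n), w = w)
      expect_equal(nrow(bwk$X), max(0, n - w + 1))
    }
  }
})

test_that("w=1 reduces to the plain per-segment design", {
  f <- toy_features(8)
  bw <- build_windows(f, w = 1)
  expect_equal(dim(bw$X), c(8L, 18L))
  expect_equal(unname(bw$X[3, ]),
               unname(as.numeric(f[3, apnea_feature_names()])))
})

test_that("each row concatenates w consecutive segments oldest first", {
  f <- toy_features(6)
  bw <- build_windows(f, w = 3)
  fm <- as.matrix(f[, apnea_feature_names()])
  # last 18 columns of row k are segment k's features
  expect_equal(unname(bw$X[1, 37:54]), unname(fm[3, ]))
  expect_equal(unname(bw$X[1, 1:18]), unname(fm[1, ]))
  expect_equal(unname(bw$X[4, 37:54]), unname(fm[6, ]))
})

test_that("windows with invalid segments or gaps are dropped and never span recordings", {
  f <- toy_features(10)
  f$valid[5] <- FALSE
  bw <- build_windows(f, w = 3)
  # windows ending at minutes 4,5,6 include minute index 4 (0-based) -> dropped
  expect_false(any(bw$index$minute %in% 4:6))
  f2 <- dplyr::bind_rows(toy_features(5, record_id = "a"),
                         toy_features(5, record_id = "b"))
  bw2 <- build_windows(f2, w = 4)
  expect_true(all(table(bw2$index$record_id) == 2))
  expect_error(build_windows(f, w = 0), "w", class = "apneatw_config_error")
})

test_that("hidden width follows the 2M+1 rule", {
  expect_equal(hidden_size(90), 181L)
  expect_equal(hidden_size(18), 37L)
  m1 <- mlp_init(90, seed = 1)
  expect_equal(m1$h, 181L)
  expect_equal(dim(m1$W1), c(90L, 181L))
  m2 <- mlp_init(18, seed = 1)
  expect_equal(m2$h, 37L)
  # determinism
  expect_identical(mlp_init(18, seed = 3)$W1, mlp_init(18, seed = 3)$W1)
  expect_false(identical(mlp_init(18, seed = 3)$W1, mlp_init(18, seed = 4)$W1))
})

test_that("forward pass matches a hand-computed one-hidden-unit network", {
  model <- structure(list(
    W1 = matrix(c(0.5, -1), 2, 1), b1 = 0.1,
    W2 = matrix(c(2, -3), 1, 2), b2 = c(0.2, -0.2),
    m = 2L, h = 1L, c_out = 2L
  ), class = "mlp_model")
  X <- rbind(c(1, 0.2), c(-1, 0.5))
  fw <- mlp_forward(model, X)
  # row 1: z = 0.5*1 - 1*0.2 + 0.1 = 0.4 -> v = 0.4; y = (1.0, -1.4)
  expect_equal(unname(fw$outputs[1, ]), c(0.4 * 2 + 0.2, 0.4 * -3 - 0.2))
  # row 2: z = -0.5 - 0.5 + 0.1 = -0.9 -> relu -> 0; y = (0.2, -0.2)
  expect_equal(unname(fw$outputs[2, ]), c(0.2, -0.2))
  expect_equal(fw$pred, c(0L, 0L))
})

test_that("all-zero weights predict normal everywhere (tie rule)", {
  model <- structure(list(
    W1 = matrix(0, 3, 7), b1 = numeric(7),
    W2 = matrix(0, 7, 2), b2 = numeric(2),
    m = 3L, h = 7L, c_out = 2L
  ), class = "mlp_model")
  fw <- mlp_forward(model, matrix(rnorm(30), 10, 3))
  expect_true(all(fw$outputs == 0))
  expect_true(all(fw$pred == 0L))
  expect_error(mlp_forward(model, matrix(0, 2, 5)), "expects",
               class = "apneatw_dim_error")
})

test_that("training separates two Gaussians and is seed-deterministic", {
  withr::with_seed(11, {
    X <- rbind(matrix(rnorm(200 * 4, -2), 200, 4),
               matrix(rnorm(200 * 4, 2), 200, 4))
    y <- rep(c(0L, 1L), each = 200)
  })
  cfg <- mlp_config(epochs = 100, seed = 5)
  fit <- mlp_train(mlp_init(4, seed = 5), X, y, cfg)
  acc <- mean(mlp_forward(fit, X)$pred == y)
  expect_gte(acc, 0.99)
  # loss broadly decreases from start to finish
  h <- fit$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  # determinism
  fit2 <- mlp_train(mlp_init(4, seed = 5), X, y, cfg)
  expect_identical(fit$W1, fit2$W1)
  expect_identical(fit$W2, fit2$W2)
  expect_error(mlp_train(mlp_init(4), X, rep(0L, 400), cfg),
               "single class", class = "apneatw_config_error")
})

test_that("fit_tw_mlp sizes the network from the window and predicts aligned tibbles", {
  f <- dplyr::bind_rows(toy_features(30, "r1", seed = 1),
                        toy_features(30, "r2", seed = 2))
  fit <- fit_tw_mlp(f, w = 5, config = mlp_config(epochs = 30, seed = 2))
  expect_equal(fit$model$m, 90L)
  expect_equal(fit$model$h, 181L)
  pr <- predict(fit, toy_features(12, "r3", seed = 3))
  expect_equal(nrow(pr), 8)
  expect_named(pr, c("record_id", "minute", "label", "score", "pred"))
  expect_true(all(pr$pred %in% c("A", "N")))
  # scores are monotone in the output difference by construction
  expect_identical(pr$pred, ifelse(pr$score > 0, "A", "N"))
})

test_that("w=1 pipeline equals an independently coded plain-MLP path", {
  f <- dplyr::bind_rows(toy_features(40, "r1", seed = 1),
                        toy_features(40, "r2", seed = 2))
  te <- toy_features(20, "r9", seed = 9)
  cfg <- mlp_config(epochs = 40, seed = 3)
  fit <- fit_tw_mlp(f, w = 1, config = cfg)
  pr <- predict(fit, te)

  # independent path: explicit z-scoring and direct matrix training
  mu <- colMeans(as.matrix(f[, apnea_feature_names()]))
  sg <- apply(as.matrix(f[, apnea_feature_names()]), 2, sd)
  Xtr <- scale(as.matrix(f[, apnea_feature_names()]), mu, sg)
  Xte <- scale(as.matrix(te[, apnea_feature_names()]), mu, sg)
  m0 <- mlp_init(18, seed = cfg$seed)
  m1 <- mlp_train(m0, Xtr, as.integer(f$label == "A"), cfg)
  fw <- mlp_forward(m1, Xte)
  expect_equal(unname(pr$score), unname(fw$score), tolerance = 1e-10)
})

test_that("model serialisation reproduces predictions bit for bit", {
  f <- toy_features(40, seed = 6)
  fit <- fit_tw_mlp(f, w = 2, config = mlp_config(epochs = 15, seed = 7))
  path <- file.path(withr::local_tempdir(), "model.json")
  write_tw_mlp(fit, path)
  back <- read_tw_mlp(path)
  te <- toy_features(15, "z", seed = 8)
  expect_identical(predict(fit, te)$score, predict(back, te)$score)
  expect_error(read_tw_mlp(tempfile()))
})

test_that("tidy and glance summarise a fit", {
  f <- toy_features(30, seed = 4)
  fit <- fit_tw_mlp(f, w = 2, config = mlp_config(epochs = 10, seed = 1))
  expect_named(tidy(fit), c("epoch", "train_loss", "val_loss"))
  g <- glance(fit)
  expect_equal(g$w, 2L)
  expect_equal(g$h_nodes, 2L * 36L + 1L)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
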