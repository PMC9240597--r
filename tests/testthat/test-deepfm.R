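test_that("the FM value matches the brute-force double sum", {
  # printed toy instance
  expect_equal(fm_interaction(c(1, 2), c(0.5, -1), rbind(c(1, 0), c(0.5, 0.5))),
               -0.5)
  # no interactions when V = 0
  x <- c(1, -2, 3)
  w <- c(0.2, 0.4, -0.1)
  expect_equal(fm_interaction(x, w, matrix(0, 3, 2)), sum(w * x))
  # random instances against explicit pair enumeration
  set.seed(5)
  for (i in 1:50) {
    n <- 10
    x <- rnorm(n)
    w <- rnorm(n)
    V <- matrix(rnorm(n * 4), n, 4)
    expect_equal(fm_interaction(x, w, V), oracle_fm(x, w, V),
                 tolerance = 1e-6)
  }
  expect_error(fm_interaction(1:3, 1:2, matrix(0, 3, 2)), "mismatch")
})

test_that("the FM forward pass respects its head contract", {
  set.seed(8)
  p <- 6
  k <- 3
  K <- 4
  fm <- list(w = rnorm(p), V = matrix(rnorm(p * k), p, k),
             H = matrix(rnorm((p + k) * K), p + k, K), bh = rnorm(K))
  x <- rnorm(p)
  # zero head gives zero scores
  fm0 <- fm
  fm0$H[] <- 0
  fm0$bh[] <- 0
  expect_equal(fm_forward(x, fm0), rep(0, K))
  # sum-of-inputs head reproduces the FM value for every label
  fm1 <- fm
  fm1$H[] <- 1
  fm1$bh[] <- 0
  expect_equal(fm_forward(x, fm1), rep(fm_interaction(x, fm$w, fm$V), K),
               tolerance = 1e-10)
  # shape contract
  expect_length(fm_forward(x, fm), K)
  expect_equal(dim(fm_forward(matrix(rnorm(5 * p), 5), fm)), c(5L, K))
  expect_error(fm_forward(x, list(w = 1)), "initialized")
})

test_that("the deep forward pass is a ReLU chain with a linear head", {
  zero <- list(list(W = matrix(0, 2, 3), b = rep(0, 3)),
               list(W = matrix(0, 3, 2), b = rep(0, 2)))
  expect_equal(deep_forward(c(1, 2), zero), c(0, 0))
  # hand-computed single hidden layer
  layers <- list(list(W = diag(2), b = c(0, 0)),
                 list(W = matrix(c(1, 0, 0, -1), 2, 2), b = c(0.5, 0)))
  # x = (2, -3): hidden relu -> (2, 0); out = (2 + 0.5, 0)
  expect_equal(deep_forward(c(2, -3), layers), c(2.5, 0))
  # the linear head can emit negative scores
  layers2 <- list(list(W = diag(2), b = c(0, 0)),
                  list(W = -diag(2), b = c(0, 0)))
  expect_true(any(deep_forward(c(5, 1), layers2) < 0))
  expect_error(deep_forward(c(1, 2, 3), layers), "dimension")
})

test_that("the ranking loss matches direct evaluation and is stable", {
  # all scores at the threshold: log(1 + ab + a + b)
  expect_equal(multilabel_loss(c(0, 0, 0), c(1, 0, 0)), log(6))
  expect_equal(multilabel_loss(c(0, 0, 0), c(1, 0, 0), plus_one = FALSE),
               log(5))
  # term-by-term worked case
  expect_equal(multilabel_loss(c(2, 0, 0), c(1, 0, 0)),
               log(1 + 2 * exp(-2) + 2 + exp(-2)))
  # perfect separation drives the loss to zero
  expect_lt(multilabel_loss(c(50, -50, -50), c(1, 0, 0)), 1e-10)
  # huge scores do not overflow
  expect_true(is.finite(multilabel_loss(c(800, -800, 0), c(0, 1, 1))))
  # random instances against plain exp arithmetic
  set.seed(13)
  for (i in 1:60) {
    k <- sample(2:8, 1)
    s <- rnorm(k, sd = 2)
    y <- rbinom(k, 1, 0.5)
    if (sum(y) == 0) y[1] <- 1
    y0 <- rnorm(1)
    po <- i %% 2 == 0
    expect_equal(multilabel_loss(s, y, y0 = y0, plus_one = po),
                 oracle_ml_loss(s, y, y0, po), tolerance = 1e-9)
  }
  # batch reduction is the sum of per-sample values
  S <- rbind(c(1, -1, 0), c(0, 2, -2))
  Y <- rbind(c(1, 0, 1), c(0, 1, 0))
  expect_equal(multilabel_loss(S, Y),
               multilabel_loss(S[1, ], Y[1, ]) + multilabel_loss(S[2, ], Y[2, ]))
  expect_equal(multilabel_loss(S, Y, reduction = "mean"),
               multilabel_loss(S, Y) / 2)
  expect_error(multilabel_loss(c(1, 2), c(0, 0)), "relevant")
})

test_that("analytic loss gradients match central finite differences", {
  set.seed(21)
  for (i in 1:25) {
    k <- sample(3:8, 1)
    s <- rnorm(k, sd = 2)
    y <- rbinom(k, 1, 0.5)
    if (sum(y) == 0) y[1] <- 1
    g <- multilabel_loss_grad(s, y)
    fd <- vapply(seq_len(k), function(j) {
      e <- rep(0, k)
      e[j] <- 1e-5
      (multilabel_loss(s + e, y) - multilabel_loss(s - e, y)) / 2e-5
    }, numeric(1))
    expect_equal(g, fd, tolerance = 1e-4)
    # monotone: relevant scores have negative slope, irrelevant positive
    expect_true(all(g[y == 1] < 0))
    expect_true(all(g[y == 0] > 0))
  }
})

test_that("score prediction is the additive sum of the two components", {
  ds <- toy_two_class(10, seed = 2)
  X <- ds$features
  cfg_fm <- deepfm_config(2, 2, latent_dim = 2, hidden = c(4),
                          epochs = 2, learning_rate = 0.01,
                          components = "fm", seed = 1)
  cfg_deep <- cfg_fm
  cfg_deep$components <- "deep"
  m_fm <- train_deepfm(ds, config = cfg_fm)
  m_deep <- train_deepfm(ds, config = cfg_deep)
  expect_equal(predict_scores(m_fm, X), fm_forward(X, m_fm$fm),
               ignore_attr = TRUE)
  expect_equal(predict_scores(m_deep, X), deep_forward(X, m_deep$deep),
               ignore_attr = TRUE)
})

test_that("label decisions threshold at y0 with a top-1 fallback", {
  expect_equal(decide_labels(c(0.5, -0.2, 0.1)), c(1L, 0L, 1L))
  expect_equal(decide_labels(c(-3, -1, -2)), c(0L, 1L, 0L))  # top-1 fallback
  expect_equal(decide_labels(c(-1, -1, -1)), c(1L, 0L, 0L))  # index tie-break
  M <- decide_labels(rbind(c(1, -1), c(-2, -3)), 0)
  expect_equal(M, rbind(c(1L, 0L), c(1L, 0L)))
})

test_that("training reduces the loss, is seed-deterministic, and can overfit one sample", {
  ds <- toy_two_class(30, seed = 4)
  sc <- fit_feature_scaler(ds)
  X <- scale_features(sc, ds$features)
  cfg <- deepfm_config(2, 2, latent_dim = 4, hidden = c(16, 8),
                       epochs = 120, learning_rate = 0.01, dropout = 0.3,
                       batch_size = 64, seed = 9)
  fit <- train_deepfm(X, ds$labels, cfg)
  expect_lt(fit$trace[length(fit$trace)], fit$trace[1])
  fit2 <- train_deepfm(X, ds$labels, cfg)
  expect_identical(fit$trace, fit2$trace)
  expect_identical(fit$fm, fit2$fm)

  # one sample repeated: the trained model reproduces its label set
  x1 <- matrix(rep(c(1, -1), 20), ncol = 2, byrow = TRUE)
  y1 <- matrix(rep(c(1, 0), 20), ncol = 2, byrow = TRUE)
  cfg1 <- deepfm_config(2, 2, latent_dim = 2, hidden = c(8), epochs = 250,
                        learning_rate = 0.02, dropout = 0, seed = 3)
  fit1 <- train_deepfm(x1, y1, cfg1)
  expect_equal(unname(predict(fit1, x1[1, , drop = FALSE], type = "labels")),
               y1[1, , drop = FALSE] * 1L)
  expect_error(train_deepfm(matrix(numeric(0), 0, 2),
                            matrix(numeric(0), 0, 2), cfg1), "empty")
})
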