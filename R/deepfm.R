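#' Configuration for the multi-label DeepFM classifier
#'
#' The classifier sums two parallel components over the same dense feature
#' vector: a factorization machine (linear weights plus low-rank pairwise
#' interactions) and a deep fully connected network, giving a K-vector of
#' label scores `y_hat = y_FM + y_Deep`. Training minimizes a thresholded
#' exponential ranking loss (see [multilabel_loss()]) that pushes every
#' relevant label's score above the threshold `y0` and every irrelevant
#' label's score below it.
#'
#' @param n_features Input dimension p (400 for flattened 20x20 features).
#' @param n_labels Number of labels K.
#' @param latent_dim FM latent factor dimension (default 8).
#' @param hidden Deep-component hidden widths (default 256, 128, 64, 32,
#'   followed by the K-unit linear output layer).
#' @param dropout Dropout rate on deep hidden activations (default 0.5).
#' @param epochs,batch_size,learning_rate Adam schedule; defaults follow the
#'   published setup (1,000 epochs, batch 512 clipped to the dataset,
#'   learning rate 1e-4).
#' @param y0 Ranking threshold (fixed, default 0; also used by
#'   [decide_labels()]).
#' @param plus_one Add 1 inside the log of the ranking loss so it is bounded
#'   below by 0 (default TRUE); FALSE gives the literal unbounded form.
#' @param reduction `"sum"` (as printed) or `"mean"` over the batch.
#' @param components Which components to train: subset of
#'   `c("fm", "deep")`; both by default, one alone gives the ML-FM or
#'   ML-Deep ablation arm.
#' @param seed Training seed.
#' @return A list of class `"deepfm_config"`.
#' @export
deepfm_config <- function(n_features, n_labels, latent_dim = 8,
                          hidden = c(256, 128, 64, 32), dropout = 0.5,
                          epochs = 1000, batch_size = 512,
                          learning_rate = 1e-4, y0 = 0, plus_one = TRUE,
                          reduction = c("sum", "mean"),
                          components = c("fm", "deep"), seed = NULL) {
  reduction <- match.arg(reduction)
  components <- match.arg(components, several.ok = TRUE)
  stopifnot(n_features >= 1, n_labels >= 2, latent_dim >= 1,
            dropout >= 0, dropout < 1, epochs >= 1, batch_size >= 1,
            learning_rate > 0)
  structure(list(n_features = as.integer(n_features),
                 n_labels = as.integer(n_labels),
                 latent_dim = as.integer(latent_dim),
                 hidden = as.integer(hidden), dropout = dropout,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, y0 = y0,
                 plus_one = isTRUE(plus_one), reduction = reduction,
                 components = components, seed = seed),
            class = "deepfm_config")
}

#' Factorization-machine value for a single feature vector
#'
#' The FM scalar `sum_i w_i x_i + sum_{i<j} <v_i, v_j> x_i x_j`, computed
#' with the O(n*k) identity
#' `0.5 * sum_f [ (sum_i V_if x_i)^2 - sum_i V_if^2 x_i^2 ]` for the pairwise
#' term, which equals the brute-force double sum exactly.
#'
#' @param x Length-n feature vector.
#' @param w Length-n first-order weights.
#' @param V n x k latent matrix (row i is feature i's latent vector).
#' @return A scalar.
#' @export
fm_interaction <- function(x, w, V) {
  V <- as.matrix(V)
  if (length(x) != length(w) || length(x) != nrow(V)) {
    stop("x, w and V have mismatched dimensions")
  }
  xv <- drop(crossprod(V, x))             # length k
  pairwise <- 0.5 * sum(xv^2 - colSums(V^2 * x^2))
  sum(w * x) + pairwise
}

# FM layer output for a batch: n x (p + k) matrix [per-feature first-order
# terms w_i * x_i ("addition units") | per-factor pooled pairwise terms];
# summing its columns reproduces fm_interaction exactly.
fm_layer <- function(X, w, V) {
  XV <- X %*% V
  Q <- 0.5 * (XV^2 - (X^2) %*% (V^2))
  list(F = cbind(sweep(X, 2L, w, "*"), Q), XV = XV)
}

#' Forward pass of the FM component
#'
#' The FM layer emits the concatenation of the per-feature first-order terms
#' `w_i * x_i` (the addition units of the original DeepFM) and the k
#' per-factor pooled pairwise-interaction terms; a dense head maps that
#' (p+k)-vector to K label scores. A head that simply sums its inputs
#' reproduces [fm_interaction()] for every label.
#'
#' @param x Feature vector or n x p matrix.
#' @param fm FM parameter list with `w` (p), `V` (p x k), `H` ((p+k) x K),
#'   `bh` (K).
#' @return Score matrix (n x K), or a length-K vector for a single sample.
#' @export
fm_forward <- function(x, fm) {
  if (!all(c("w", "V", "H", "bh") %in% names(fm))) {
    stop("fm must be an initialized FM parameter list (w, V, H, bh)")
  }
  X <- as_matrix_rows(x)
  if (ncol(X) != length(fm$w)) stop("feature dimension does not match FM parameters")
  Fm <- fm_layer(X, fm$w, fm$V)$F
  out <- sweep(Fm %*% fm$H, 2L, fm$bh, "+")
  if (is.null(dim(x))) drop(out) else out
}

#' Forward pass of the deep component
#'
#' A fully connected chain with ReLU hidden activations and a linear output
#' layer (no activation on the final layer, so scores may be negative).
#'
#' @param x Feature vector or n x p matrix.
#' @param layers Layer list as produced by the trainer.
#' @return Score matrix (n x K), or a length-K vector for a single sample.
#' @export
deep_forward <- function(x, layers) {
  X <- as_matrix_rows(x)
  if (ncol(X) != nrow(layers[[1L]]$W)) {
    stop("feature dimension does not match the deep component")
  }
  out <- nn_forward(layers, X)$out
  if (is.null(dim(x))) drop(out) else out
}

#' Thresholded exponential multi-label ranking loss
#'
#' Per sample, with relevant label set R and irrelevant set I and threshold
#' `y0`, the loss is
#' `log( c + sum_{k in I, r in R} e^{s_k - s_r} + sum_{k in I} e^{s_k - y0}
#'  + sum_{r in R} e^{y0 - s_r} )` with `c = 1` when `plus_one = TRUE`
#' (bounding the loss below by 0) and `c = 0` for the literal form. The batch
#' value is the sum (or mean) over samples. Computed with log-sum-exp
#' reductions so large scores do not overflow.
#'
#' @param scores Length-K score vector or N x K matrix.
#' @param y Matching binary label vector/matrix; every row needs >= 1
#'   relevant label.
#' @param y0 Threshold (default 0).
#' @param plus_one Add 1 inside the log (default TRUE).
#' @param reduction `"sum"` or `"mean"` over samples.
#' @return A scalar.
#' @export
multilabel_loss <- function(scores, y, y0 = 0, plus_one = TRUE,
                            reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  S <- as_matrix_rows(scores)
  Y <- as_matrix_rows(y)
  stopifnot(all(dim(S) == dim(Y)), all(Y %in% c(0, 1)))
  if (any(rowSums(Y) < 1)) stop("every sample must have at least one relevant label")
  vals <- ml_loss_core(S, Y, y0, plus_one)$logS
  if (reduction == "sum") sum(vals) else mean(vals)
}

# Row-wise log-sum-exp over a matrix with -Inf-masked entries.
row_lse <- function(M) {
  m <- as.vector(do.call(pmax, c(lapply(asplit(M, 2L), as.vector),
                                 list(-Inf))))
  out <- rep(-Inf, nrow(M))
  ok <- is.finite(m)
  if (any(ok)) {
    out[ok] <- m[ok] +
      log(rowSums(exp(M[ok, , drop = FALSE] - m[ok]), na.rm = TRUE))
  }
  out
}

# Shared stable computation: per-sample logA = log sum_{k in I} e^{s_k},
# logB = log sum_{r in R} e^{-s_r}, and the per-sample log of the Eq. 12
# bracket logS.  Fully vectorized over the batch.
ml_loss_core <- function(S, Y, y0, plus_one) {
  SA <- S
  SA[Y == 1] <- -Inf
  logA <- row_lse(SA)
  SB <- -S
  SB[Y == 0] <- -Inf
  logB <- row_lse(SB)
  terms <- cbind(if (plus_one) 0 else -Inf,
                 logA + logB,   # pairwise block
                 logA - y0,     # irrelevant vs threshold
                 y0 + logB)     # threshold vs relevant
  terms[is.nan(terms)] <- -Inf  # (-Inf) + Inf never occurs; guard anyway
  list(logA = logA, logB = logB, logS = row_lse(terms))
}

#' Analytic gradient of [multilabel_loss()] with respect to the scores
#'
#' @inheritParams multilabel_loss
#' @return Gradient with the same shape as `scores`.
#' @export
multilabel_loss_grad <- function(scores, y, y0 = 0, plus_one = TRUE,
                                 reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  S <- as_matrix_rows(scores)
  Y <- as_matrix_rows(y)
  core <- ml_loss_core(S, Y, y0, plus_one)
  # d logS / d s_k (k irrelevant) = e^{s_k} (B + e^{-y0}) / S
  # d logS / d s_r (r relevant)  = -e^{-s_r} (A + e^{y0}) / S
  lse_b <- row_lse(cbind(core$logB, -y0))
  lse_a <- row_lse(cbind(core$logA, y0))
  G <- matrix(0, nrow(S), ncol(S))
  irre <- Y == 0
  re <- Y == 1
  Gi <- exp(S + (lse_b - core$logS))
  Gr <- -exp(-S + (lse_a - core$logS))
  G[irre] <- Gi[irre]
  G[re] <- Gr[re]
  if (reduction == "mean") G <- G / nrow(S)
  if (is.null(dim(scores))) drop(G) else G
}

#' Predict label scores
#'
#' Elementwise sum of the FM and deep component outputs (a disabled
#' component contributes zero, giving the ML-FM / ML-Deep ablation arms).
#'
#' @param model A trained `"ml_deepfm"` model.
#' @param x Feature vector or matrix in the model's (scaled) feature space.
#' @return Score matrix n x K (or vector for one sample).
#' @export
predict_scores <- function(model, x) {
  stopifnot(inherits(model, "ml_deepfm"))
  X <- as_matrix_rows(x)
  out <- matrix(0, nrow(X), model$config$n_labels)
  if ("fm" %in% model$config$components) out <- out + fm_forward(X, model$fm)
  if ("deep" %in% model$config$components) out <- out + deep_forward(X, model$deep)
  colnames(out) <- model$label_names
  if (is.null(dim(x))) drop(out) else out
}

#' Threshold scores into a predicted label set
#'
#' Predicts every label whose score exceeds `y0`. If no score does, the
#' top-scoring label is emitted alone (every protein resides in at least one
#' compartment); ties go to the lowest label index.
#'
#' @param scores Length-K vector or N x K matrix of scores.
#' @param y0 Threshold (default 0).
#' @return Binary vector/matrix of predictions.
#' @export
decide_labels <- function(scores, y0 = 0) {
  S <- as_matrix_rows(scores)
  out <- matrix(0L, nrow(S), ncol(S), dimnames = dimnames(S))
  for (i in seq_len(nrow(S))) {
    hit <- which(S[i, ] > y0)
    if (length(hit) == 0L) hit <- which.max(S[i, ])
    out[i, hit] <- 1L
  }
  if (is.null(dim(scores))) drop(out) else out
}

init_deepfm_params <- function(cfg) {
  p <- cfg$n_features
  k <- cfg$latent_dim
  K <- cfg$n_labels
  fm <- list(w = rnorm(p, sd = 0.5),
             V = matrix(rnorm(p * k, sd = 0.05), p, k),
             H = matrix(rnorm((p + k) * K, sd = sqrt(2 / (p + k))), p + k, K),
             bh = numeric(K))
  deep <- nn_init(c(p, cfg$hidden, K))
  list(fm = fm, deep = deep)
}

# Batch gradients of the FM component given d(loss)/d(y_FM).
fm_backward <- function(X, fm, layer, Gy) {
  p <- ncol(X)
  GF <- Gy %*% t(fm$H)                          # n x (p+k)
  dQ <- GF[, -seq_len(p), drop = FALSE]         # n x k
  list(w = colSums(GF[, seq_len(p), drop = FALSE] * X),
       V = crossprod(X, dQ * layer$XV) - crossprod(X^2, dQ) * fm$V,
       H = crossprod(layer$F, Gy),
       bh = colSums(Gy))
}

#' Train the multi-label DeepFM
#'
#' Joint Adam training of the FM and deep components (or either alone,
#' per `config$components`) under the thresholded exponential ranking loss.
#' Dropout is applied to deep hidden activations during training only.
#' Deterministic given `config$seed`. The returned model records the loss
#' over the full training set at each epoch (evaluated without dropout).
#'
#' @param x An [ml_dataset()] or an n x p matrix of scaled features.
#' @param y N x K binary labels (ignored when `x` is an `ml_dataset`).
#' @param config A [deepfm_config()].
#' @return An object of class `"ml_deepfm"` with elements `fm`, `deep`,
#'   `config`, `trace` (per-epoch loss) and `label_names`.
#' @export
train_deepfm <- function(x, y = NULL, config) {
  if (inherits(x, "ml_dataset")) {
    y <- x$labels
    x <- x$features
  }
  X <- as_matrix_rows(x)
  Y <- as_matrix_rows(y)
  stopifnot(inherits(config, "deepfm_config"))
  if (nrow(X) == 0L) stop("cannot train on an empty dataset")
  if (nrow(X) != nrow(Y)) stop("features and labels must align")
  if (ncol(X) != config$n_features || ncol(Y) != config$n_labels) {
    stop("dataset shape does not match the configuration")
  }
  n <- nrow(X)
  bs <- min(config$batch_size, n)
  use_fm <- "fm" %in% config$components
  use_deep <- "deep" %in% config$components

  with_seed(config$seed, {
    par <- init_deepfm_params(config)
    st <- adam_init(par)
    trace <- numeric(config$epochs)

    eval_scores <- function(par, Xb) {
      out <- matrix(0, nrow(Xb), config$n_labels)
      if (use_fm) out <- out + fm_forward(Xb, par$fm)
      if (use_deep) out <- out + deep_forward(Xb, par$deep)
      out
    }

    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(n)
      for (s in seq(1L, n, by = bs)) {
        idx <- perm[s:min(s + bs - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        Yb <- Y[idx, , drop = FALSE]
        scores <- matrix(0, length(idx), config$n_labels)
        if (use_fm) {
          layer <- fm_layer(Xb, par$fm$w, par$fm$V)
          scores <- scores + sweep(layer$F %*% par$fm$H, 2L, par$fm$bh, "+")
        }
        if (use_deep) {
          fwd <- nn_forward(par$deep, Xb, dropout = config$dropout,
                            training = TRUE)
          scores <- scores + fwd$out
        }
        G <- multilabel_loss_grad(scores, Yb, y0 = config$y0,
                                  plus_one = config$plus_one,
                                  reduction = config$reduction)
        grads <- list(fm = tree_zero(par$fm), deep = tree_zero(par$deep))
        if (use_fm) grads$fm <- fm_backward(Xb, par$fm, layer, G)
        if (use_deep) grads$deep <- nn_backward(par$deep, fwd, G)$grads
        upd <- adam_step(par, grads, st, config$learning_rate)
        par <- upd$params
        st <- upd$state
      }
      trace[ep] <- multilabel_loss(eval_scores(par, X), Y, y0 = config$y0,
                                   plus_one = config$plus_one,
                                   reduction = config$reduction)
    }

    structure(list(fm = par$fm, deep = par$deep, config = config,
                   trace = trace,
                   label_names = colnames(Y) %||%
                     paste0("L", seq_len(config$n_labels))),
              class = "ml_deepfm")
  })
}

#' @export
print.ml_deepfm <- function(x, ...) {
  cat(sprintf("ml_deepfm: %d features -> %d labels (components: %s; final loss %.4f)\n",
              x$config$n_features, x$config$n_labels,
              paste(x$config$components, collapse = "+"),
              x$trace[length(x$trace)]))
  invisible(x)
}

#' @export
predict.ml_deepfm <- function(object, newdata, type = c("scores", "labels"),
                              ...) {
  type <- match.arg(type)
  if (inherits(newdata, "ml_dataset")) newdata <- newdata$features
  sc <- predict_scores(object, newdata)
  if (type == "scores") sc else decide_labels(sc, object$config$y0)
}
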