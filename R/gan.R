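#' Configuration for the distance-regularized GAN
#'
#' The GAN used to oversample minority localization classes. Its objectives
#' extend the standard non-saturating GAN game with a log-distance term
#' between generated samples and the real-sample mean: the discriminator
#' maximizes `E[log D(x)] + E[log(1 - D(G(z)))] + E[log d(G(z), x_bar)]` and
#' the generator minimizes `E[-log D(G(z))] + lambda * E[log d(G(z), x_bar)]`,
#' which pulls synthetic samples toward the minority-class mean while the
#' adversarial term preserves their spread.
#'
#' @param latent_dim Dimension of the latent noise vector z ~ N(0, I).
#' @param g_hidden Hidden widths of the generator (dense layers; the default
#'   mirrors a dense stem followed by three upsampling stages to the 400-d
#'   output).
#' @param d_hidden Hidden widths of the discriminator (two hidden layers plus
#'   the sigmoid head).
#' @param lambda Weight of the log-distance regularizer in the generator
#'   objective (nonnegative).
#' @param epochs,batch_size,learning_rate Adam training schedule; batch size
#'   is clipped to the pool size. Defaults follow the published setup
#'   (1,000 epochs, batch 512, learning rate 1e-4).
#' @param epsilon_dist Floor applied to distances before the log, preventing
#'   log(0) if a sample collapses onto the mean.
#' @param instance_noise Standard deviation of Gaussian noise added to the
#'   discriminator's inputs (real and generated alike) during training.
#'   Smooths the discriminator so it cannot memorize the handful of samples
#'   a minority-class pool may contain; 0 disables it.
#' @param seed Training seed (NULL = ambient RNG).
#' @return A list of class `"gan_config"`.
#' @export
gan_config <- function(latent_dim = 64, g_hidden = c(64, 128, 256),
                       d_hidden = c(128, 64), lambda = 0.1,
                       epochs = 1000, batch_size = 512,
                       learning_rate = 1e-4, epsilon_dist = 1e-6,
                       instance_noise = 0.25, seed = NULL) {
  stopifnot(latent_dim >= 1, lambda >= 0, epochs >= 1, batch_size >= 1,
            learning_rate > 0, epsilon_dist > 0, instance_noise >= 0)
  structure(list(latent_dim = as.integer(latent_dim),
                 g_hidden = as.integer(g_hidden),
                 d_hidden = as.integer(d_hidden),
                 lambda = lambda, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 epsilon_dist = epsilon_dist,
                 instance_noise = instance_noise, seed = seed),
            class = "gan_config")
}

#' Distance of generated samples to the real-sample mean
#'
#' Per-sample Euclidean distance between each generated feature vector and
#' the mean of the real training pool, floored at `epsilon` so its logarithm
#' stays finite.
#'
#' @param fake n x p matrix (or length-p vector) of generated samples.
#' @param real_mean Length-p mean of the real samples.
#' @param epsilon Positive floor.
#' @return Positive numeric vector of length n.
#' @export
gan_distance <- function(fake, real_mean, epsilon = 1e-6) {
  fake <- as_matrix_rows(fake)
  if (ncol(fake) != length(real_mean)) {
    stop("fake samples and real_mean have mismatched feature dimension")
  }
  stopifnot(epsilon > 0)
  diff <- sweep(fake, 2L, real_mean, "-")
  pmax(sqrt(rowSums(diff^2)), epsilon)
}

#' GAN objective values
#'
#' `discriminator_objective()` is the quantity the discriminator maximizes:
#' `mean(log d_real) + mean(log(1 - d_fake)) + mean(log dist)`.
#' `generator_objective()` is the quantity the generator minimizes:
#' `mean(-log d_fake) + lambda * mean(log dist)`. With `lambda = 0` and unit
#' distances both reduce exactly to the standard non-saturating GAN
#' objectives. Probabilities are clamped away from 0 and 1 so the values are
#' always finite.
#'
#' @param d_real,d_fake Discriminator probabilities in (0, 1) for real and
#'   generated samples.
#' @param dist Positive per-sample distances (see [gan_distance()]).
#' @param lambda Nonnegative regularizer weight.
#' @return A finite scalar.
#' @export
discriminator_objective <- function(d_real, d_fake, dist) {
  stopifnot(all(dist > 0))
  mean(log(clamp01(d_real))) + mean(log(1 - clamp01(d_fake))) +
    mean(log(dist))
}

#' @rdname discriminator_objective
#' @export
generator_objective <- function(d_fake, dist, lambda) {
  stopifnot(all(dist > 0), lambda >= 0)
  mean(-log(clamp01(d_fake))) + lambda * mean(log(dist))
}

#' Train the distance-regularized GAN on a minority-class pool
#'
#' Alternating single-step updates: one Adam step on the discriminator
#' (binary real/fake discrimination) then one on the generator (non-saturating
#' adversarial term plus the lambda-weighted log-distance pull toward the
#' pool mean). Training is deterministic given `config$seed`.
#'
#' @param x n x p matrix of (scaled) feature vectors, n >= 2.
#' @param config A [gan_config()].
#' @param scaler Optional [fit_feature_scaler()] result; if supplied it is
#'   stored with the model so [gan_synthesize()] can map samples back to
#'   feature units.
#' @return An object of class `"gan_model"`: generator and discriminator
#'   layers, the real-pool mean, the config and a per-epoch objective trace.
#' @export
train_gan <- function(x, config = gan_config(), scaler = NULL) {
  x <- as_matrix_rows(x)
  n <- nrow(x)
  p <- ncol(x)
  if (n < 2L) stop("GAN training needs at least 2 real samples")
  stopifnot(inherits(config, "gan_config"))
  if (!is.null(scaler)) check_scaler(scaler)
  bs <- min(config$batch_size, n)
  dz <- config$latent_dim
  lam <- config$lambda
  eps <- config$epsilon_dist
  lr <- config$learning_rate

  with_seed(config$seed, {
    G <- nn_init(c(dz, config$g_hidden, p))
    D <- nn_init(c(p, config$d_hidden, 1L))
    real_mean <- colMeans(x)
    # Start the generator centered on the real pool: with the output bias at
    # the pool mean, the adversarial game only has to shape the spread rather
    # than first travel to the data region, which stabilizes training on the
    # small pools typical of minority classes.
    G[[length(G)]]$b <- real_mean
    stG <- adam_init(G)
    stD <- adam_init(D)
    trace <- data.frame(epoch = seq_len(config$epochs),
                        d_objective = NA_real_, g_objective = NA_real_)

    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = bs)
      for (s in starts) {
        idx <- perm[s:min(s + bs - 1L, n)]
        nb <- length(idx)
        xb <- x[idx, , drop = FALSE]

        # --- discriminator step (the log-distance term has no D parameters,
        #     so its gradient w.r.t. D is zero) ---
        z <- matrix(rnorm(nb * dz), nrow = nb)
        fake <- nn_forward(G, z)$out
        xb_d <- xb
        fake_d <- fake
        if (config$instance_noise > 0) {
          xb_d <- xb + matrix(rnorm(length(xb), sd = config$instance_noise),
                              nrow = nb)
          fake_d <- fake + matrix(rnorm(length(fake),
                                        sd = config$instance_noise), nrow = nb)
        }
        fr <- nn_forward(D, xb_d)
        ff <- nn_forward(D, fake_d)
        pr <- sigmoid(fr$out)
        pf <- sigmoid(ff$out)
        gr <- nn_backward(D, fr, (pr - 1) / nb)$grads
        gf <- nn_backward(D, ff, pf / nb)$grads
        gD <- tree_map2(`+`, gr, gf)
        updD <- adam_step(D, gD, stD, lr)
        D <- updD$params
        stD <- updD$state

        # --- generator step ---
        z <- matrix(rnorm(nb * dz), nrow = nb)
        fwdG <- nn_forward(G, z)
        fake <- fwdG$out
        fake_d <- fake
        if (config$instance_noise > 0) {
          fake_d <- fake + matrix(rnorm(length(fake),
                                        sd = config$instance_noise), nrow = nb)
        }
        fwdD <- nn_forward(D, fake_d)
        pf <- sigmoid(fwdD$out)
        g_adv <- nn_backward(D, fwdD, (pf - 1) / nb)$gin
        diff <- sweep(fake, 2L, real_mean, "-")
        nrm <- sqrt(rowSums(diff^2))
        g_dist <- matrix(0, nb, p)
        on_floor <- nrm <= eps
        if (any(!on_floor)) {
          g_dist[!on_floor, ] <- lam * diff[!on_floor, , drop = FALSE] /
            nrm[!on_floor]^2 / nb
        }
        bwG <- nn_backward(G, fwdG, g_adv + g_dist)$grads
        updG <- adam_step(G, bwG, stG, lr)
        G <- updG$params
        stG <- updG$state

        if (s == starts[length(starts)]) {
          dist <- gan_distance(fake, real_mean, eps)
          trace$d_objective[ep] <- discriminator_objective(pr, pf, dist)
          trace$g_objective[ep] <- generator_objective(pf, dist, lam)
        }
      }
    }

    structure(list(generator = G, discriminator = D, real_mean = real_mean,
                   feature_dim = p, config = config, scaler = scaler,
                   trace = trace, n_real = n),
              class = "gan_model")
  })
}

#' @export
print.gan_model <- function(x, ...) {
  cat(sprintf("gan_model: %d-d latent -> %d-d features, trained on %d samples (%d epochs, lambda=%g)\n",
              x$config$latent_dim, x$feature_dim, x$n_real,
              x$config$epochs, x$config$lambda))
  invisible(x)
}

#' Synthesize samples from a trained GAN generator
#'
#' @param model A `"gan_model"` from [train_gan()].
#' @param n Number of samples to draw (n >= 0).
#' @param seed Sampling seed; same seed gives identical output.
#' @param inverse_scale If TRUE and a scaler is attached to the model, map
#'   the samples back to original feature units.
#' @return An n x p matrix of synthetic feature vectors.
#' @export
gan_synthesize <- function(model, n, seed = NULL, inverse_scale = TRUE) {
  stopifnot(inherits(model, "gan_model"))
  if (n < 0) stop("cannot synthesize a negative number of samples")
  n <- as.integer(n)
  if (n == 0L) return(matrix(numeric(0), nrow = 0L, ncol = model$feature_dim))
  out <- with_seed(seed, {
    z <- matrix(rnorm(n * model$config$latent_dim), nrow = n)
    nn_forward(model$generator, z)$out
  })
  if (inverse_scale && !is.null(model$scaler)) {
    out <- unscale_features(model$scaler, out)
  }
  out
}

#' Plan how many synthetic samples each class needs
#'
#' Class counts are the number of samples bearing each label (a multi-label
#' sample counts toward every label it carries). Under `"match_majority"`
#' every class is topped up to the majority count; under `"ratio"` to
#' `ceiling(r * majority)`.
#'
#' @param labels N x K binary label matrix (every row >= 1 label).
#' @param policy `"match_majority"` or `"ratio"`.
#' @param ratio Target fraction of the majority count (used by `"ratio"`).
#' @return A data.frame of class `"rebalance_plan"` with columns `label`,
#'   `n_real`, `n_synth`.
#' @export
plan_rebalance <- function(labels, policy = c("match_majority", "ratio"),
                           ratio = 1) {
  labels <- as_matrix_rows(labels)
  if (nrow(labels) == 0L) stop("cannot plan rebalancing for an empty dataset")
  if (any(rowSums(labels) < 1)) stop("every sample must carry at least one label")
  policy <- match.arg(policy)
  counts <- colSums(labels)
  target <- if (policy == "match_majority") max(counts) else ceiling(ratio * max(counts))
  synth <- pmax(0, target - counts)
  plan <- data.frame(
    label = colnames(labels) %||% paste0("L", seq_along(counts)),
    n_real = as.integer(counts),
    n_synth = as.integer(synth),
    stringsAsFactors = FALSE
  )
  class(plan) <- c("rebalance_plan", "data.frame")
  attr(plan, "policy") <- policy
  plan
}

#' Rebalance a training dataset by GAN oversampling
#'
#' For every class with a nonzero synthesis count, trains one GAN on the
#' (scaled) features of the samples bearing that label and appends the
#' requested number of synthetic samples, each labeled with that single class
#' and flagged `synthetic = TRUE`. Real samples are untouched. A class with
#' fewer than 2 real samples cannot support GAN training; it falls back to
#' duplicate-with-jitter with a warning, and a class with no real samples in
#' the pool is skipped with a warning.
#'
#' The plan must be computed from the same (training-fold) dataset, never
#' from data containing the evaluation fold.
#'
#' @param dataset An [ml_dataset()] (features already scaled for training).
#' @param plan A [plan_rebalance()] result (computed from `dataset$labels`);
#'   NULL recomputes it with `policy`.
#' @param config A [gan_config()]; per-class seeds are derived from
#'   `config$seed`.
#' @param policy Passed to [plan_rebalance()] when `plan` is NULL.
#' @param ratio Passed to [plan_rebalance()] when `plan` is NULL.
#' @return The augmented `ml_dataset`.
#' @export
rebalance_dataset <- function(dataset, plan = NULL, config = gan_config(),
                              policy = "match_majority", ratio = 1) {
  stopifnot(inherits(dataset, "ml_dataset"))
  if (is.null(plan)) plan <- plan_rebalance(dataset$labels, policy, ratio)
  K <- ncol(dataset$labels)
  stopifnot(nrow(plan) == K)
  out <- dataset
  jitter_sd <- 0.05 * stats::median(apply(dataset$features, 2L, sd), na.rm = TRUE)
  if (!is.finite(jitter_sd) || jitter_sd <= 0) jitter_sd <- 0.05
  for (k in seq_len(K)) {
    n_syn <- plan$n_synth[k]
    if (n_syn == 0L) next
    pool <- which(dataset$labels[, k] == 1)
    if (length(pool) == 0L) {
      warning(sprintf("class '%s' has no samples in this training set; skipped by the rebalancer",
                      plan$label[k]))
      next
    }
    Xk <- dataset$features[pool, , drop = FALSE]
    if (length(pool) < 2L) {
      warning(sprintf("class '%s' has < 2 real samples; falling back to duplicate-with-jitter",
                      plan$label[k]))
      syn <- with_seed(derive_seed(config$seed, 7000L + k), {
        base <- Xk[sample.int(nrow(Xk), n_syn, replace = TRUE), , drop = FALSE]
        base + matrix(rnorm(length(base), sd = jitter_sd), nrow = n_syn)
      })
    } else {
      cfg_k <- config
      cfg_k$seed <- derive_seed(config$seed, k)
      model <- train_gan(Xk, cfg_k)
      syn <- gan_synthesize(model, n_syn,
                            seed = derive_seed(config$seed, 5000L + k),
                            inverse_scale = FALSE)
    }
    Yk <- matrix(0L, nrow = n_syn, ncol = K,
                 dimnames = list(NULL, colnames(dataset$labels)))
    Yk[, k] <- 1L
    out <- dataset_append(out, syn, Yk,
                          ids = sprintf("syn_%s_%d", plan$label[k], seq_len(n_syn)),
                          synthetic = rep(TRUE, n_syn))
  }
  out$manifest$rebalance_plan <- as.data.frame(plan)
  out
}
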