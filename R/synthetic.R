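#' Configuration for the synthetic imbalanced multi-label generator
#'
#' Emulates the structure of a protein-localization benchmark: class-
#' conditional Gaussian feature matrices with a controllable per-class
#' imbalance vector and multi-label co-occurrence. Each sample is drawn from
#' an isotropic Gaussian at its base class's mean; extra labels are attached
#' independently with the probabilities in the `cooccurrence` matrix. The
#' default imbalance vector (500/50/20 over three classes) reproduces the
#' severe skew the rebalancer is designed for; the default 20x20 feature
#' shape matches the PSSM-composition pipeline, while tests may use small toy
#' shapes so GAN and classifier runs finish in seconds.
#'
#' @param n_per_class Per-class sample counts (the imbalance vector).
#' @param feature_shape Dimensions of each feature matrix (e.g. `c(20, 20)`
#'   or `2` for a toy problem).
#' @param class_means Optional K x p matrix of class means (p =
#'   `prod(feature_shape)`); by default drawn once from N(0, mean_scale^2)
#'   under `seed`.
#' @param mean_scale Spread of the default class means (default 2, giving
#'   overlapping but separable classes at `noise_sd = 1`).
#' @param noise_sd Isotropic within-class standard deviation (default 1).
#' @param cooccurrence K x K matrix; entry (k, j) is the probability that a
#'   sample of base class k also carries label j (diagonal 1). Default:
#'   0.05 off-diagonal, echoing benchmarks where most proteins are
#'   single-location.
#' @param seed RNG seed for reproducible datasets.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_per_class = c(500, 50, 20),
                             feature_shape = c(20, 20),
                             class_means = NULL, mean_scale = 2,
                             noise_sd = 1, cooccurrence = NULL, seed = 1) {
  K <- length(n_per_class)
  p <- prod(feature_shape)
  stopifnot(K >= 1, all(n_per_class >= 0), noise_sd > 0, p >= 1)
  if (sum(n_per_class) == 0) stop("at least one class must have samples")
  if (is.null(cooccurrence)) {
    cooccurrence <- matrix(0.05, K, K)
    diag(cooccurrence) <- 1
  }
  cooccurrence <- as.matrix(cooccurrence)
  stopifnot(all(dim(cooccurrence) == c(K, K)),
            all(cooccurrence >= 0), all(cooccurrence <= 1),
            all(diag(cooccurrence) == 1))
  if (is.null(class_means)) {
    class_means <- with_seed(derive_seed(seed, 77L),
                             matrix(rnorm(K * p, sd = mean_scale), K, p))
  }
  class_means <- as.matrix(class_means)
  stopifnot(all(dim(class_means) == c(K, p)))
  structure(list(n_per_class = as.integer(n_per_class),
                 feature_shape = as.integer(feature_shape),
                 class_means = class_means, noise_sd = noise_sd,
                 cooccurrence = cooccurrence, seed = seed),
            class = "synthetic_config")
}

#' Generate a synthetic imbalanced multi-label dataset
#'
#' @param cfg A [synthetic_config()].
#' @return An [ml_dataset()] with `sum(n_per_class)` samples; the manifest
#'   records the configuration and seed so identical configs give
#'   byte-identical datasets.
#' @export
generate_multilabel_dataset <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  K <- length(cfg$n_per_class)
  p <- prod(cfg$feature_shape)
  with_seed(cfg$seed, {
    feats <- list()
    labs <- list()
    base <- integer(0)
    for (k in seq_len(K)) {
      nk <- cfg$n_per_class[k]
      if (nk == 0L) next
      Xk <- matrix(rnorm(nk * p, sd = cfg$noise_sd), nk, p, byrow = TRUE) +
        matrix(cfg$class_means[k, ], nk, p, byrow = TRUE)
      Yk <- matrix(0L, nk, K)
      Yk[, k] <- 1L
      for (j in seq_len(K)) {
        if (j == k) next
        pj <- cfg$cooccurrence[k, j]
        if (pj > 0) Yk[, j] <- rbinom(nk, 1L, pj)
      }
      feats[[length(feats) + 1L]] <- Xk
      labs[[length(labs) + 1L]] <- Yk
      base <- c(base, rep(k, nk))
    }
    X <- do.call(rbind, feats)
    Y <- do.call(rbind, labs)
    colnames(Y) <- paste0("C", seq_len(K))
    ids <- sprintf("sim_%04d", seq_len(nrow(X)))
    ds <- ml_dataset(X, Y, ids = ids,
                     manifest = list(source = "synthetic",
                                     n_per_class = cfg$n_per_class,
                                     feature_shape = cfg$feature_shape,
                                     noise_sd = cfg$noise_sd,
                                     seed = cfg$seed,
                                     base_class = base))
    ds
  })
}

#' Per-class label proportions of a dataset
#'
#' Proportion of samples bearing each label. For multi-label data the
#' proportions can sum to more than 1 (a sample counts toward every label it
#' carries).
#'
#' @param x An [ml_dataset()] or an N x K binary label matrix.
#' @return Named numeric vector of length K.
#' @export
imbalance_profile <- function(x) {
  Y <- if (inherits(x, "ml_dataset")) x$labels else as_matrix_rows(x)
  if (nrow(Y) == 0L) stop("empty dataset")
  colSums(Y) / nrow(Y)
}

#' Write a PSI-BLAST-style ASCII PSSM fixture file
#'
#' Emits a file in the ASCII dialect accepted by [parse_pssm_ascii()]
#' (header, column-label line, one data row per residue, footer), so
#' synthetic proteins can exercise the parser without running PSI-BLAST.
#' Round-trips exactly: parsing the written file recovers `sequence` and
#' `scores`.
#'
#' @param sequence Character scalar amino-acid sequence (length L >= 1).
#' @param scores L x 20 integer matrix of log-odds scores, columns in
#'   ARNDCQEGHILKMFPSTWYV order.
#' @param path Output file path.
#' @param include_percentages Also emit the 20 weighted-percentage columns
#'   and two trailing statistics columns after the log-odds block (ignored by
#'   the parser), mimicking full PSI-BLAST output.
#' @return `path`, invisibly.
#' @export
write_pssm_fixture <- function(sequence, scores, path,
                               include_percentages = FALSE) {
  res <- strsplit(toupper(sequence), "")[[1L]]
  if (length(res) == 0L) stop("sequence must contain at least one residue")
  scores <- as.matrix(scores)
  if (nrow(scores) != length(res) || ncol(scores) != 20L) {
    stop("scores must be an L x 20 matrix matching the sequence length")
  }
  hdr_cols <- paste(sprintf("%4s", AA20), collapse = "")
  if (include_percentages) hdr_cols <- paste0(hdr_cols, hdr_cols)
  lines <- c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("         ", hdr_cols)
  )
  for (i in seq_along(res)) {
    row <- paste(sprintf("%4d", as.integer(scores[i, ])), collapse = "")
    if (include_percentages) {
      pct <- paste(sprintf("%4d", rep(5L, 20L)), collapse = "")
      row <- paste0(row, pct, sprintf("  %4.2f %8.2f", 0.35, 1.10))
    }
    lines <- c(lines, sprintf("%5d %s %s", i, res[i], row))
  }
  lines <- c(lines, "",
             "                      K         Lambda",
             "Standard Ungapped    0.1347     0.3179")
  writeLines(lines, path)
  invisible(path)
}
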