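#' Random k-fold split
#'
#' Partitions 1..n into k disjoint index sets whose sizes differ by at most
#' one, by random assignment (the default) or by greedy iterative multi-label
#' stratification when a label matrix is supplied.
#'
#' @param n Number of samples (n >= k).
#' @param k Number of folds.
#' @param seed RNG seed; the assignment is deterministic given the seed.
#' @param labels Optional N x K binary label matrix; when given, folds are
#'   stratified so each label's positives spread evenly across folds.
#' @return List of k integer index vectors (the test sets); their union is
#'   1..n.
#' @export
kfold_split <- function(n, k, seed = NULL, labels = NULL) {
  n <- as.integer(n)
  k <- as.integer(k)
  if (n < k) stop("cannot split ", n, " samples into ", k, " folds")
  if (!is.null(labels)) return(stratified_kfold(labels, k, seed))
  sizes <- rep(n %/% k, k)
  if (n %% k > 0L) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  with_seed(seed, {
    idx <- sample.int(n)
    split(idx, rep(seq_len(k), times = sizes))
  })
}

# Greedy iterative stratification (Sechidis-style): repeatedly take the label
# with fewest remaining unassigned positives and deal its samples to the fold
# with the greatest remaining demand for that label.
stratified_kfold <- function(labels, k, seed = NULL) {
  Y <- as_matrix_rows(labels)
  n <- nrow(Y)
  if (n < k) stop("cannot split ", n, " samples into ", k, " folds")
  with_seed(seed, {
    assigned <- integer(n)
    cap <- rep(n %/% k, k)
    if (n %% k > 0L) cap[seq_len(n %% k)] <- cap[seq_len(n %% k)] + 1L
    desire <- outer(rep(1 / k, k), colSums(Y))   # k x K desired positives
    remaining <- rep(TRUE, n)
    while (any(remaining)) {
      cnt <- colSums(Y[remaining, , drop = FALSE])
      active <- which(cnt > 0)
      if (length(active) == 0L) {
        # label-free leftovers: deal by remaining capacity
        for (i in which(remaining)) {
          f <- which.max(cap)
          assigned[i] <- f
          cap[f] <- cap[f] - 1L
          remaining[i] <- FALSE
        }
        break
      }
      lab <- active[which.min(cnt[active])]
      rows <- which(remaining & Y[, lab] == 1)
      rows <- rows[sample.int(length(rows))]
      for (i in rows) {
        ok <- which(cap > 0)
        f <- ok[order(-desire[ok, lab], -cap[ok], ok)][1L]
        assigned[i] <- f
        cap[f] <- cap[f] - 1L
        desire[f, Y[i, ] == 1] <- desire[f, Y[i, ] == 1] - 1
        remaining[i] <- FALSE
      }
    }
    split(seq_len(n), assigned)
  })
}

default_arms <- function() {
  data.frame(model = rep(c("deepfm", "fm", "deep"), each = 2L),
             rebalance = rep(c(TRUE, FALSE), times = 3L),
             stringsAsFactors = FALSE)
}

arm_name <- function(model, rebalance) {
  paste0(model, if (rebalance) "+gan" else "")
}

model_components <- function(model) {
  switch(model,
         deepfm = c("fm", "deep"),
         fm = "fm",
         deep = "deep",
         stop("unknown model arm: ", model))
}

#' Cross-validated evaluation with fold-restricted rebalancing
#'
#' Runs k-fold cross-validation over an experiment matrix of classifier arms
#' (full DeepFM, FM component alone, deep component alone) with and without
#' GAN rebalancing. Inside each fold, the feature scaler is fitted on the
#' training split only, GAN training and synthesis see only the training
#' split (synthetic samples never leak into a test fold), and each arm's
#' classifier is trained on the (possibly augmented) training split and
#' evaluated on the untouched test split with the five multi-label metrics.
#'
#' @param dataset An [ml_dataset()] (unscaled features).
#' @param arms Data frame with columns `model`
#'   (`"deepfm"`, `"fm"`, `"deep"`) and `rebalance` (logical); default all
#'   six combinations.
#' @param folds Number of CV folds (default 10).
#' @param seed Global seed; fold assignment and all per-fold training seeds
#'   derive from it.
#' @param classifier List of [deepfm_config()] overrides (e.g.
#'   `list(epochs = 150, hidden = c(32, 16))`) applied to every arm.
#' @param gan A [gan_config()] used by the rebalancer (its seed is re-derived
#'   per fold).
#' @param rebalance_policy Passed to [plan_rebalance()].
#' @param stratified Use iterative multi-label stratification for the folds.
#' @param y0 Decision threshold for label prediction.
#' @return An object of class `"cv_result"`: `per_fold` (one row per fold x
#'   arm with the five metrics), `summary` (per-arm means and standard
#'   deviations), and the fold assignment manifest.
#' @export
run_cross_validation <- function(dataset, arms = default_arms(), folds = 10,
                                 seed = 1, classifier = list(),
                                 gan = gan_config(),
                                 rebalance_policy = "match_majority",
                                 stratified = FALSE, y0 = 0) {
  stopifnot(inherits(dataset, "ml_dataset"), folds >= 2)
  arms <- as.data.frame(arms)
  stopifnot(nrow(arms) >= 1, all(c("model", "rebalance") %in% names(arms)))
  N <- nrow(dataset$features)
  p <- ncol(dataset$features)
  K <- ncol(dataset$labels)
  fold_idx <- kfold_split(N, folds, seed = derive_seed(seed, 1L),
                          labels = if (stratified) dataset$labels else NULL)

  rows <- list()
  for (f in seq_along(fold_idx)) {
    test <- fold_idx[[f]]
    train <- setdiff(seq_len(N), test)
    sc <- fit_feature_scaler(dataset$features[train, , drop = FALSE])
    Xtr <- scale_features(sc, dataset$features[train, , drop = FALSE])
    Xte <- scale_features(sc, dataset$features[test, , drop = FALSE])
    Ytr <- dataset$labels[train, , drop = FALSE]
    Yte <- dataset$labels[test, , drop = FALSE]
    train_ds <- ml_dataset(Xtr, Ytr, ids = dataset$ids[train])

    aug_ds <- NULL
    if (any(arms$rebalance)) {
      gan_f <- gan
      gan_f$seed <- derive_seed(seed, 100L + f)
      plan <- plan_rebalance(Ytr, policy = rebalance_policy)
      aug_ds <- rebalance_dataset(train_ds, plan, config = gan_f)
    }

    for (a in seq_len(nrow(arms))) {
      ds_a <- if (arms$rebalance[a]) aug_ds else train_ds
      cfg <- do.call(deepfm_config, modifyList(
        list(n_features = p, n_labels = K,
             components = model_components(arms$model[a]),
             y0 = y0, seed = derive_seed(seed, 200L + 10L * f + a)),
        classifier))
      fit <- train_deepfm(ds_a, config = cfg)
      sc_te <- predict_scores(fit, Xte)
      rep <- suppressWarnings(evaluate_multilabel(sc_te, Yte, y0 = y0))
      rows[[length(rows) + 1L]] <- data.frame(
        fold = f, arm = arm_name(arms$model[a], arms$rebalance[a]),
        model = arms$model[a], rebalance = arms$rebalance[a],
        as.data.frame(rep), stringsAsFactors = FALSE)
    }
  }
  per_fold <- do.call(rbind, rows)
  metric_cols <- c("hl", "oe", "co", "rl", "ap")
  mean_df <- aggregate(per_fold[metric_cols], by = list(arm = per_fold$arm),
                       FUN = mean)
  sd_df <- aggregate(per_fold[metric_cols], by = list(arm = per_fold$arm),
                     FUN = sd)
  names(sd_df)[-1L] <- paste0(metric_cols, "_sd")
  summary <- merge(mean_df, sd_df, by = "arm")
  structure(list(per_fold = per_fold, summary = summary,
                 fold_index = fold_idx, seed = seed, arms = arms),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cross-validation over %d folds (seed %s):\n",
              length(x$fold_index), format(x$seed)))
  print(x$summary, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Imbalance report for a labeled dataset
#'
#' Summarizes the class-imbalance structure of a multi-label dataset:
#' per-class sample counts and proportions, the label-cardinality histogram
#' (how many samples carry 1, 2, 3, or 4+ labels) and the majority/minority
#' count ratio.
#'
#' @param x An [ml_dataset()], an N x K binary label matrix, or a label
#'   table data.frame with columns `protein_id` and `locations`.
#' @return A list of class `"dataset_report"` with `n`, `counts`,
#'   `proportions`, `cardinality` (named counts for "1", "2", "3", "4+") and
#'   `imbalance_ratio`.
#' @export
dataset_report <- function(x) {
  Y <- if (inherits(x, "ml_dataset")) {
    x$labels
  } else if (is.data.frame(x)) {
    make_label_matrix(x)
  } else {
    as_matrix_rows(x)
  }
  if (nrow(Y) == 0L) stop("empty dataset")
  counts <- colSums(Y)
  card <- rowSums(Y)
  hist <- c(`1` = sum(card == 1), `2` = sum(card == 2),
            `3` = sum(card == 3), `4+` = sum(card >= 4))
  structure(list(n = nrow(Y), counts = counts,
                 proportions = counts / nrow(Y),
                 cardinality = hist,
                 imbalance_ratio = max(counts) / max(min(counts), 1)),
            class = "dataset_report")
}

#' @export
print.dataset_report <- function(x, ...) {
  cat(sprintf("dataset report: %d samples, %d classes (majority/minority ratio %.1f)\n",
              x$n, length(x$counts), x$imbalance_ratio))
  cat("label cardinality:",
      paste(sprintf("%s:%d", names(x$cardinality), x$cardinality),
            collapse = "  "), "\n")
  df <- data.frame(class = names(x$counts) %||% seq_along(x$counts),
                   count = as.integer(x$counts),
                   proportion = round(x$proportions, 4))
  print(df, row.names = FALSE)
  invisible(x)
}
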