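# Independent brute-force oracles used to cross-check the package
# implementations.  These deliberately use naive loops / pair enumeration and
# never call the package's own code paths.

oracle_rank <- function(s) {
  ord <- order(-s, seq_along(s))
  r <- integer(length(s))
  r[ord] <- seq_along(s)
  r
}

oracle_hamming <- function(pred, y) sum(pred != y) / length(y)

oracle_one_error <- function(S, Y) {
  bad <- 0
  for (i in seq_len(nrow(S))) {
    top <- which(S[i, ] == max(S[i, ]))[1L]
    if (Y[i, top] == 0) bad <- bad + 1
  }
  bad / nrow(S)
}

oracle_coverage <- function(S, Y) {
  tot <- 0
  for (i in seq_len(nrow(S))) {
    r <- oracle_rank(S[i, ])
    tot <- tot + max(r[Y[i, ] == 1])
  }
  tot / nrow(S)
}

oracle_ranking_loss <- function(S, Y) {
  vals <- c()
  for (i in seq_len(nrow(S))) {
    re <- which(Y[i, ] == 1)
    ir <- which(Y[i, ] == 0)
    if (length(ir) == 0L) next
    bad <- 0
    for (a in re) for (b in ir) if (S[i, b] >= S[i, a]) bad <- bad + 1
    vals <- c(vals, bad / (length(re) * length(ir)))
  }
  mean(vals)
}

oracle_average_precision <- function(S, Y) {
  vals <- numeric(nrow(S))
  for (i in seq_len(nrow(S))) {
    re <- which(Y[i, ] == 1)
    r <- oracle_rank(S[i, ])
    acc <- 0
    for (j in re) {
      L <- sum(S[i, re] >= S[i, j])
      acc <- acc + L / r[j]
    }
    vals[i] <- acc / length(re)
  }
  mean(vals)
}

# Eq.-style FM value via explicit double sum over i < j pairs.
oracle_fm <- function(x, w, V) {
  n <- length(x)
  tot <- sum(w * x)
  for (i in seq_len(n)) {
    j <- i + 1L
    while (j <= n) {
      tot <- tot + sum(V[i, ] * V[j, ]) * x[i] * x[j]
      j <- j + 1L
    }
  }
  tot
}

# Ranking loss of the classifier, term-by-term in plain exp arithmetic.
oracle_ml_loss <- function(s, y, y0 = 0, plus_one = TRUE) {
  re <- which(y == 1)
  ir <- which(y == 0)
  tot <- if (plus_one) 1 else 0
  for (k in ir) for (r in re) tot <- tot + exp(s[k] - s[r])
  for (k in ir) tot <- tot + exp(s[k] - y0)
  for (r in re) tot <- tot + exp(y0 - s[r])
  log(tot)
}

# Random multi-label instance with every row carrying at least one relevant
# and one irrelevant label (the all-relevant exclusion path has its own test).
random_prediction_set <- function(n, k) {
  S <- matrix(rnorm(n * k), n, k)
  Y <- matrix(rbinom(n * k, 1L, 0.4), n, k)
  empty <- rowSums(Y) == 0
  Y[cbind(which(empty), sample.int(k, sum(empty), replace = TRUE))] <- 1L
  full <- rowSums(Y) == k
  Y[cbind(which(full), sample.int(k, sum(full), replace = TRUE))] <- 0L
  list(S = S, Y = Y)
}

# Small toy dataset with two well-separated classes for trainer tests.
toy_two_class <- function(n_per = 30, seed = 1) {
  cfg <- synthetic_config(n_per_class = c(n_per, n_per), feature_shape = 2,
                          class_means = rbind(c(-2, 0), c(2, 0)),
                          noise_sd = 0.5,
                          cooccurrence = diag(2), seed = seed)
  generate_multilabel_dataset(cfg)
}
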