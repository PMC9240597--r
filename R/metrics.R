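#' Rank labels by score
#'
#' Rank 1 is the highest score; ties are broken deterministically in favor of
#' the lower label index.
#'
#' @param scores Length-K finite score vector.
#' @return Integer vector of ranks (a permutation of 1..K).
#' @export
rank_labels <- function(scores) {
  stopifnot(all(is.finite(scores)))
  r <- integer(length(scores))
  r[order(-scores, seq_along(scores))] <- seq_along(scores)
  r
}

check_pred <- function(scores, y) {
  S <- as_matrix_rows(scores)
  Y <- as_matrix_rows(y)
  stopifnot(all(dim(S) == dim(Y)), all(Y %in% c(0, 1)))
  if (any(rowSums(Y) < 1)) stop("every sample must have at least one relevant label")
  list(S = S, Y = Y)
}

#' Hamming loss
#'
#' Fraction of label assignments that disagree with the ground truth,
#' covering both missed relevant labels and spuriously predicted irrelevant
#' ones. With `normalize = TRUE` (the standard definition) the count is
#' divided by N*K so the value lies in \[0, 1\]; `normalize = FALSE` divides
#' by N only.
#'
#' @param pred N x K binary predictions.
#' @param y N x K binary ground truth.
#' @param normalize Divide by the number of labels K as well as N.
#' @return A scalar.
#' @export
hamming_loss <- function(pred, y, normalize = TRUE) {
  P <- as_matrix_rows(pred)
  Y <- as_matrix_rows(y)
  stopifnot(all(dim(P) == dim(Y)))
  miss <- sum(P != Y)
  if (normalize) miss / length(Y) else miss / nrow(Y)
}

#' One-error
#'
#' Fraction of samples whose single top-ranked label is not among the
#' relevant labels (ties at the top go to the lowest index).
#'
#' @param scores N x K score matrix.
#' @param y N x K binary ground truth.
#' @return A scalar in \[0, 1\].
#' @export
one_error <- function(scores, y) {
  pr <- check_pred(scores, y)
  top <- apply(pr$S, 1L, which.max)
  mean(pr$Y[cbind(seq_len(nrow(pr$Y)), top)] == 0)
}

#' Coverage
#'
#' Average depth one must descend the score-ranked label list to cover every
#' relevant label of a sample. As defined here the best attainable value for
#' a sample is its number of relevant labels (no minus-one correction); set
#' `minus_one = TRUE` for the convention used elsewhere in the multi-label
#' literature.
#'
#' @inheritParams one_error
#' @param minus_one Subtract 1 from the per-sample depth.
#' @return A scalar in \[1, K\] (or \[0, K-1\] with `minus_one`).
#' @export
coverage <- function(scores, y, minus_one = FALSE) {
  pr <- check_pred(scores, y)
  depth <- vapply(seq_len(nrow(pr$S)), function(i) {
    r <- rank_labels(pr$S[i, ])
    max(r[pr$Y[i, ] == 1])
  }, numeric(1L))
  mean(depth) - as.numeric(minus_one)
}

#' Ranking loss
#'
#' Mean fraction of (relevant, irrelevant) label pairs that are mis-ordered,
#' i.e. the irrelevant label scores at least as high as the relevant one.
#' Samples with no irrelevant label have no pairs to order; they are excluded
#' from the mean with a warning.
#'
#' @inheritParams one_error
#' @return A scalar in \[0, 1\].
#' @export
ranking_loss <- function(scores, y) {
  pr <- check_pred(scores, y)
  full <- rowSums(pr$Y) == ncol(pr$Y)
  if (any(full)) {
    warning(sprintf("%d sample(s) with all labels relevant excluded from ranking loss",
                    sum(full)))
  }
  rows <- which(!full)
  if (length(rows) == 0L) stop("no sample has both a relevant and an irrelevant label")
  vals <- vapply(rows, function(i) {
    s <- pr$S[i, ]
    re <- which(pr$Y[i, ] == 1)
    irre <- which(pr$Y[i, ] == 0)
    bad <- sum(outer(s[re], s[irre], function(a, b) b >= a))
    bad / (length(re) * length(irre))
  }, numeric(1L))
  mean(vals)
}

#' Average precision
#'
#' For each relevant label j of a sample, the precision of the ranked list
#' truncated at j: the number of relevant labels scoring at least as high as
#' j, divided by j's rank. Averaged over relevant labels, then samples.
#' Perfect ranking gives 1.
#'
#' @inheritParams one_error
#' @return A scalar in (0, 1\].
#' @export
average_precision <- function(scores, y) {
  pr <- check_pred(scores, y)
  vals <- vapply(seq_len(nrow(pr$S)), function(i) {
    s <- pr$S[i, ]
    r <- rank_labels(s)
    re <- which(pr$Y[i, ] == 1)
    prec <- vapply(re, function(j) sum(s[re] >= s[j]) / r[j], numeric(1L))
    mean(prec)
  }, numeric(1L))
  mean(vals)
}

#' Evaluate all five multi-label metrics
#'
#' One pass computing Hamming loss, one-error, coverage, ranking loss and
#' average precision. Binary predictions default to thresholding the scores
#' at `y0` via [decide_labels()].
#'
#' @param scores N x K real score matrix.
#' @param y N x K binary ground truth (each row >= 1 relevant label).
#' @param pred Optional N x K binary predictions; default
#'   `decide_labels(scores, y0)`.
#' @param y0 Threshold used for the default predictions.
#' @param minus_one Passed to [coverage()].
#' @return A list of class `"metrics_report"` with elements `hl`, `oe`, `co`,
#'   `rl`, `ap`, plus `n` and `k`.
#' @export
evaluate_multilabel <- function(scores, y, pred = NULL, y0 = 0,
                                minus_one = FALSE) {
  pr <- check_pred(scores, y)
  if (is.null(pred)) pred <- decide_labels(pr$S, y0)
  structure(list(
    hl = hamming_loss(pred, pr$Y),
    oe = one_error(pr$S, pr$Y),
    co = coverage(pr$S, pr$Y, minus_one = minus_one),
    rl = ranking_loss(pr$S, pr$Y),
    ap = average_precision(pr$S, pr$Y),
    n = nrow(pr$Y), k = ncol(pr$Y)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("multi-label metrics (n=%d, K=%d):\n", x$n, x$k))
  cat(sprintf("  Hamming loss      %.4f\n", x$hl))
  cat(sprintf("  one-error         %.4f\n", x$oe))
  cat(sprintf("  coverage          %.4f\n", x$co))
  cat(sprintf("  ranking loss      %.4f\n", x$rl))
  cat(sprintf("  average precision %.4f\n", x$ap))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(hl = x$hl, oe = x$oe, co = x$co, rl = x$rl, ap = x$ap,
             n = x$n, k = x$k)
}
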