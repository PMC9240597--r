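#' Per-feature standardization fitted on training data
#'
#' Centers and scales each feature to zero mean and unit standard deviation.
#' Both GAN and classifier training are scale-sensitive, so the scaler is
#' fitted on each training fold only and then applied to the held-out fold,
#' avoiding information leakage. Zero-variance features keep scale 1 so the
#' transform stays finite.
#'
#' @param x Numeric matrix (samples x features) or an [ml_dataset()].
#' @return An object of class `"feature_scaler"` holding per-feature `center`
#'   and `scale` (all `scale` entries > 0).
#' @export
fit_feature_scaler <- function(x) {
  if (inherits(x, "ml_dataset")) x <- x$features
  x <- as_matrix_rows(x)
  if (nrow(x) < 1L) stop("cannot fit a scaler on an empty training set")
  center <- colMeans(x)
  scale <- apply(x, 2L, sd)
  scale[!is.finite(scale) | scale <= 0] <- 1
  structure(list(center = center, scale = scale, p = ncol(x)),
            class = "feature_scaler")
}

check_scaler <- function(scaler) {
  if (!inherits(scaler, "feature_scaler")) {
    stop("scaler must be a fitted 'feature_scaler' (see fit_feature_scaler)")
  }
}

#' @rdname fit_feature_scaler
#' @param scaler A fitted `"feature_scaler"`.
#' @export
scale_features <- function(scaler, x) {
  check_scaler(scaler)
  x <- as_matrix_rows(x)
  if (ncol(x) != scaler$p) stop("feature dimension does not match the scaler")
  sweep(sweep(x, 2L, scaler$center, "-"), 2L, scaler$scale, "/")
}

#' @rdname fit_feature_scaler
#' @export
unscale_features <- function(scaler, x) {
  check_scaler(scaler)
  x <- as_matrix_rows(x)
  if (ncol(x) != scaler$p) stop("feature dimension does not match the scaler")
  sweep(sweep(x, 2L, scaler$scale, "*"), 2L, scaler$center, "+")
}

#' @export
print.feature_scaler <- function(x, ...) {
  cat(sprintf("feature_scaler over %d features\n", x$p))
  invisible(x)
}
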