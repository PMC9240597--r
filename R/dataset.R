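#' Multi-label feature dataset
#'
#' The container shared by all pipeline stages: an aligned collection of
#' per-protein feature vectors, binary label vectors, identifiers and a
#' synthetic-sample flag (TRUE for GAN-generated samples).
#'
#' @param features N x p numeric matrix (flattened feature matrices; the
#'   pipeline default is p = 400 from a 20x20 PSSM composition).
#' @param labels N x K binary matrix; every row must carry at least one label.
#' @param ids Character identifiers (default `s1..sN`).
#' @param synthetic Logical vector flagging generated samples (default all
#'   FALSE).
#' @param manifest Free-form provenance list (generator config, seed, ...).
#' @return An object of class `"ml_dataset"`.
#' @export
ml_dataset <- function(features, labels, ids = NULL, synthetic = NULL,
                       manifest = list()) {
  features <- as_matrix_rows(features)
  labels <- as_matrix_rows(labels)
  n <- nrow(features)
  if (nrow(labels) != n) stop("features and labels must have the same number of rows")
  if (!all(labels %in% c(0, 1))) stop("labels must be a binary matrix")
  if (any(rowSums(labels) < 1)) stop("every sample must carry at least one label")
  if (any(!is.finite(features))) stop("features must be finite")
  ids <- ids %||% paste0("s", seq_len(n))
  synthetic <- synthetic %||% rep(FALSE, n)
  stopifnot(length(ids) == n, length(synthetic) == n)
  structure(
    list(features = features, labels = labels, ids = as.character(ids),
         synthetic = as.logical(synthetic), manifest = manifest),
    class = "ml_dataset"
  )
}

#' @export
print.ml_dataset <- function(x, ...) {
  cat(sprintf("ml_dataset: %d samples x %d features, %d labels (%d synthetic)\n",
              nrow(x$features), ncol(x$features), ncol(x$labels),
              sum(x$synthetic)))
  invisible(x)
}

#' @export
dim.ml_dataset <- function(x) dim(x$features)

#' Subset a multi-label dataset by sample index
#'
#' @param dataset An [ml_dataset()].
#' @param idx Integer or logical row index.
#' @return The subsetted `ml_dataset` (manifest carried along).
#' @export
dataset_subset <- function(dataset, idx) {
  stopifnot(inherits(dataset, "ml_dataset"))
  ml_dataset(dataset$features[idx, , drop = FALSE],
             dataset$labels[idx, , drop = FALSE],
             ids = dataset$ids[idx],
             synthetic = dataset$synthetic[idx],
             manifest = dataset$manifest)
}

# Append rows (used by the rebalancer).
dataset_append <- function(dataset, features, labels, ids, synthetic) {
  ml_dataset(rbind(dataset$features, features),
             rbind(dataset$labels, labels),
             ids = c(dataset$ids, ids),
             synthetic = c(dataset$synthetic, synthetic),
             manifest = dataset$manifest)
}

#' Write a dataset as plain-text feature/label tables with a JSON manifest
#'
#' Writes `features.tsv` (protein id + one column per feature), `labels.tsv`
#' (protein id + semicolon-separated labels) and `manifest.json` into `dir`.
#'
#' @param dataset An [ml_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "ml_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  feat <- data.frame(protein_id = dataset$ids, dataset$features,
                     check.names = FALSE)
  write.table(feat, file.path(dir, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  vocab <- colnames(dataset$labels) %||% paste0("L", seq_len(ncol(dataset$labels)))
  locs <- apply(dataset$labels, 1L, function(y) paste(vocab[y == 1], collapse = ";"))
  lab <- data.frame(protein_id = dataset$ids, locations = locs)
  write.table(lab, file.path(dir, "labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest <- c(dataset$manifest,
                list(n_samples = nrow(dataset$features),
                     n_features = ncol(dataset$features),
                     label_vocabulary = vocab,
                     n_synthetic = sum(dataset$synthetic)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing `features.tsv` and `labels.tsv`.
#' @return An [ml_dataset()].
#' @export
read_dataset <- function(dir) {
  feat <- read.delim(file.path(dir, "features.tsv"), check.names = FALSE)
  lab <- read_label_table(file.path(dir, "labels.tsv"))
  manifest <- list()
  mf <- file.path(dir, "manifest.json")
  vocab <- NULL
  if (file.exists(mf)) {
    manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
    vocab <- manifest$label_vocabulary
  }
  ids <- as.character(feat$protein_id)
  X <- as.matrix(feat[, setdiff(names(feat), "protein_id"), drop = FALSE])
  Y <- make_label_matrix(lab[match(ids, lab$protein_id), , drop = FALSE],
                         vocabulary = vocab)
  ml_dataset(X, Y, ids = ids, manifest = as.list(manifest))
}
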