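#' Parse a PSI-BLAST ASCII PSSM
#'
#' Reads the per-query ASCII position-specific scoring matrix emitted by
#' PSI-BLAST (`-out_ascii_pssm`): two header lines, a column-label line
#' naming the 20 amino-acid columns, then one data row per residue starting
#' with the position index and residue letter followed by 20 integer log-odds
#' scores. Trailing columns (weighted observed percentages, information
#' content) and footer statistics lines are ignored; only the log-odds block
#' is retained.
#'
#' @param text Character scalar (whole file) or character vector of lines.
#' @param protein_id Identifier stored with the parsed matrix.
#' @return An object of class `"pssm"`: a list with `protein_id`, `residues`
#'   (length-L character vector), `scores` (L x 20 numeric matrix of log-odds
#'   scores, columns named by `column_order`), and `column_order` (the file's
#'   amino-acid column ordering).
#' @seealso [pssm_features()], [write_pssm_fixture()]
#' @export
parse_pssm_ascii <- function(text, protein_id = NA_character_) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  }
  lines <- as.character(text)

  tok <- function(line) strsplit(trimws(line), "[[:space:]]+")[[1L]]

  # Locate the column-label line: >= 20 single-letter amino-acid tokens.
  header_at <- NA_integer_
  for (i in seq_along(lines)) {
    tk <- tok(lines[i])
    if (length(tk) >= 20L && all(nchar(tk) == 1L) && all(tk %in% AA20)) {
      header_at <- i
      break
    }
  }
  if (is.na(header_at)) {
    stop("not a PSI-BLAST ASCII PSSM: no amino-acid column-label line found")
  }
  column_order <- tok(lines[header_at])[1:20]
  if (anyDuplicated(column_order) || !setequal(column_order, AA20)) {
    stop("column-label line is not a permutation of the 20 standard amino acids")
  }

  residues <- character(0)
  scores <- list()
  pos_expected <- 1L
  in_block <- FALSE
  body_idx <- if (header_at < length(lines)) {
    (header_at + 1L):length(lines)
  } else {
    integer(0)
  }
  for (i in body_idx) {
    line <- lines[i]
    tk <- tok(line)
    starts_numeric <- length(tk) > 0L && grepl("^[0-9]+$", tk[1L])
    if (!starts_numeric) {
      if (in_block) break  # footer reached
      next                 # blank line between header and data
    }
    in_block <- TRUE
    if (length(tk) < 22L) {
      stop(sprintf("malformed PSSM row at line %d: expected residue letter and 20 scores, found %d tokens",
                   i, length(tk)))
    }
    pos <- as.integer(tk[1L])
    if (pos != pos_expected) {
      stop(sprintf("inconsistent position index at line %d: expected %d, found %d",
                   i, pos_expected, pos))
    }
    res <- tk[2L]
    if (!grepl("^[A-Za-z]$", res)) {
      stop(sprintf("malformed PSSM row at line %d: '%s' is not a residue letter",
                   i, res))
    }
    row <- suppressWarnings(as.numeric(tk[3:22]))
    if (anyNA(row)) {
      stop(sprintf("non-numeric score in PSSM row at line %d", i))
    }
    residues <- c(residues, toupper(res))
    scores[[pos_expected]] <- row
    pos_expected <- pos_expected + 1L
  }
  if (length(scores) == 0L) {
    stop("empty PSSM: no data rows found")
  }
  sc <- do.call(rbind, scores)
  colnames(sc) <- column_order
  structure(
    list(protein_id = protein_id, residues = residues, scores = sc,
         column_order = column_order),
    class = "pssm"
  )
}

#' @rdname parse_pssm_ascii
#' @param path Path to a PSSM file; the protein id defaults to the file name
#'   without extension.
#' @export
parse_pssm_file <- function(path, protein_id = NULL) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  id <- protein_id %||% sub("\\.[^.]*$", "", basename(path))
  parse_pssm_ascii(readLines(path, warn = FALSE), protein_id = id)
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("PSI-BLAST PSSM '%s': %d residues x 20 amino-acid columns\n",
              x$protein_id, length(x$residues)))
  invisible(x)
}

#' Discretize a variable-length PSSM into a fixed 20x20 feature matrix
#'
#' A PSSM has one row per sequence position, so its shape varies with protein
#' length. Classifiers need a fixed-size input, so the matrix is reduced to
#' 20 x 20: in `"grouped"` mode (the default, the standard PSSM-composition
#' encoding), entry (a, j) is the mean log-odds score toward amino acid j over
#' all positions occupied by residue type a; rows for residue types absent
#' from the sequence are set to `fill`. In `"column_mean"` mode the per-column
#' mean over all positions (a 20-vector) is placed in the first row, the
#' remaining rows at `fill`.
#'
#' Non-standard residues (X/B/Z/U and other ambiguity codes) have no row of
#' their own: they are dropped in `"grouped"` mode (counted in the
#' `"n_nonstandard"` attribute) but still contribute to `"column_mean"`.
#'
#' @param pssm A `"pssm"` object from [parse_pssm_ascii()].
#' @param mode `"grouped"` or `"column_mean"`.
#' @param fill Value used for rows with no occupying residue (default 0, the
#'   neutral log-odds score).
#' @return A 20 x 20 numeric matrix (rows and columns in the canonical
#'   ARNDCQEGHILKMFPSTWYV order) with attributes `protein_id`, `mode` and
#'   `n_nonstandard`.
#' @export
pssm_features <- function(pssm, mode = c("grouped", "column_mean"), fill = 0) {
  stopifnot(inherits(pssm, "pssm"))
  mode <- match.arg(mode)
  L <- length(pssm$residues)
  if (L == 0L) stop("empty PSSM: no residues")
  # reorder score columns into the canonical ordering
  sc <- pssm$scores[, match(AA20, pssm$column_order), drop = FALSE]
  out <- matrix(fill, nrow = 20L, ncol = 20L, dimnames = list(AA20, AA20))
  nonstandard <- sum(!(pssm$residues %in% AA20))
  if (mode == "column_mean") {
    out[1L, ] <- colMeans(sc)
  } else {
    for (a in AA20) {
      rows <- which(pssm$residues == a)
      if (length(rows) > 0L) {
        out[a, ] <- colMeans(sc[rows, , drop = FALSE])
      }
    }
  }
  attr(out, "protein_id") <- pssm$protein_id
  attr(out, "mode") <- mode
  attr(out, "n_nonstandard") <- nonstandard
  out
}

#' Flatten a feature matrix to a vector in row-major order
#'
#' @param x A feature matrix (e.g. 20 x 20 from [pssm_features()]).
#' @return A numeric vector of length `nrow(x) * ncol(x)`, rows concatenated.
#' @export
flatten_features <- function(x) {
  stopifnot(is.matrix(x))
  as.vector(t(x))
}

#' Read a protein-to-locations label table
#'
#' Expects a TSV with columns `protein_id` and `locations`, the latter a
#' semicolon-separated list of subcellular location names (a protein may
#' reside in several compartments).
#'
#' @param path Path to the TSV file.
#' @return A data.frame with character columns `protein_id` and `locations`.
#' @export
read_label_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("protein_id", "locations") %in% names(df))) {
    stop("label table must have columns 'protein_id' and 'locations'")
  }
  df$protein_id <- as.character(df$protein_id)
  df$locations <- as.character(df$locations)
  df
}

#' Convert a label table to a binary label matrix
#'
#' @param labels A data.frame from [read_label_table()] (or equivalent).
#' @param vocabulary Optional fixed label vocabulary (column order); defaults
#'   to the sorted set of observed location names.
#' @return An N x K binary matrix, rows named by protein id.
#' @export
make_label_matrix <- function(labels, vocabulary = NULL) {
  sets <- strsplit(labels$locations, ";", fixed = TRUE)
  sets <- lapply(sets, function(s) unique(trimws(s[nzchar(trimws(s))])))
  if (any(lengths(sets) == 0L)) {
    stop("every protein must carry at least one location label")
  }
  vocab <- vocabulary %||% sort(unique(unlist(sets)))
  unknown <- setdiff(unlist(sets), vocab)
  if (length(unknown) > 0L) {
    stop("location(s) not in vocabulary: ", paste(unknown, collapse = ", "))
  }
  Y <- matrix(0L, nrow = length(sets), ncol = length(vocab),
              dimnames = list(labels$protein_id, vocab))
  for (i in seq_along(sets)) Y[i, sets[[i]]] <- 1L
  Y
}

#' Build a multi-label dataset from a directory of PSSM files
#'
#' Parses every PSSM file in `pssm_dir` whose base name (without extension)
#' appears in the label table, discretizes each to a 20x20 feature matrix and
#' assembles the aligned feature/label dataset.
#'
#' @param pssm_dir Directory of PSI-BLAST ASCII PSSM files (one per protein,
#'   extension-agnostic; file name without extension = protein id).
#' @param labels Label table data.frame (see [read_label_table()]) or a path
#'   to one.
#' @param mode Discretization mode passed to [pssm_features()].
#' @param vocabulary Optional fixed label vocabulary.
#' @return An [ml_dataset()] with 400-dimensional flattened features.
#' @export
featurize_pssm_dir <- function(pssm_dir, labels, mode = "grouped",
                               vocabulary = NULL) {
  if (is.character(labels)) labels <- read_label_table(labels)
  files <- list.files(pssm_dir, full.names = TRUE)
  if (length(files) == 0L) stop("no PSSM files found in ", pssm_dir)
  ids <- sub("\\.[^.]*$", "", basename(files))
  keep <- ids %in% labels$protein_id
  if (!any(keep)) stop("no PSSM file matches a protein id in the label table")
  files <- files[keep]
  ids <- ids[keep]
  feats <- t(vapply(files, function(f) {
    flatten_features(pssm_features(parse_pssm_file(f), mode = mode))
  }, numeric(400L)))
  rownames(feats) <- ids
  lab <- labels[match(ids, labels$protein_id), , drop = FALSE]
  Y <- make_label_matrix(lab, vocabulary = vocabulary)
  ml_dataset(feats, Y, ids = ids,
             manifest = list(source = "pssm", mode = mode,
                             feature_shape = c(20L, 20L)))
}
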