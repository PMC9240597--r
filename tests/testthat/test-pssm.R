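random_scores <- function(L) matrix(sample(-12:12, L * 20, replace = TRUE), L, 20)

test_that("writing and parsing a PSSM fixture round-trips residues and scores", {
  set.seed(1)
  tf <- withr::local_tempfile()
  sc <- random_scores(3)
  write_pssm_fixture("MAC", sc, tf)
  ps <- parse_pssm_file(tf)
  expect_s3_class(ps, "pssm")
  expect_equal(ps$residues, c("M", "A", "C"))
  expect_equal(unname(ps$scores), sc + 0)
  expect_equal(ps$column_order, c("A", "R", "N", "D", "C", "Q", "E", "G",
                                  "H", "I", "L", "K", "M", "F", "P", "S",
                                  "T", "W", "Y", "V"))
  # implausible score magnitudes serialize without clamping
  big <- matrix(99L, 2, 20)
  write_pssm_fixture("KY", big, tf)
  expect_equal(unname(parse_pssm_file(tf)$scores), big + 0)
  expect_error(write_pssm_fixture("", random_scores(1), tf), "residue")
  expect_error(write_pssm_fixture("MA", random_scores(3), tf), "L x 20")
})

test_that("trailing percentage columns and footers are ignored by the parser", {
  set.seed(2)
  tf1 <- withr::local_tempfile()
  tf2 <- withr::local_tempfile()
  sc <- random_scores(5)
  write_pssm_fixture("MACKY", sc, tf1, include_percentages = FALSE)
  write_pssm_fixture("MACKY", sc, tf2, include_percentages = TRUE)
  expect_equal(parse_pssm_file(tf1)$scores, parse_pssm_file(tf2)$scores)
})

test_that("malformed PSSM input produces diagnostic errors naming the line", {
  set.seed(3)
  tf <- withr::local_tempfile()
  write_pssm_fixture("MAC", random_scores(3), tf)
  lines <- readLines(tf)
  # row with only 19 scores
  bad <- lines
  bad[5] <- substr(bad[5], 1, nchar(bad[5]) - 4)
  expect_error(parse_pssm_ascii(bad), "line 5")
  # non-numeric score
  bad2 <- lines
  bad2[5] <- sub("-?\\d+ *$", "xx", bad2[5])
  expect_error(parse_pssm_ascii(bad2), "line 5")
  # duplicated position index (second data row claims position 1 again)
  bad3 <- lines
  bad3[5] <- sub("^ *2 ", "    1 ", bad3[5])
  expect_error(parse_pssm_ascii(bad3), "position index")
  # no data rows at all
  expect_error(parse_pssm_ascii(lines[1:3]), "empty")
  # no header line
  expect_error(parse_pssm_ascii("not a pssm at all"), "column-label")
})

test_that("discretization implements both the grouped and column-mean conventions", {
  set.seed(4)
  tf <- withr::local_tempfile()
  sc <- matrix(0L, 3, 20)
  sc[, 1] <- c(2L, -1L, 4L)   # column A
  write_pssm_fixture("ACA", sc, tf)
  ps <- parse_pssm_file(tf)
  g <- pssm_features(ps, mode = "grouped")
  expect_equal(dim(g), c(20L, 20L))
  expect_equal(g["A", "A"], 3)
  expect_equal(g["C", "A"], -1)
  expect_equal(g["M", "A"], 0)   # fill value for absent residue types
  cm <- pssm_features(ps, mode = "column_mean")
  expect_equal(cm[1, "A"], 5 / 3)
  expect_true(all(cm[2:20, ] == 0))
  # constant PSSM: every populated cell equals the constant in both modes
  sc7 <- matrix(7L, 4, 20)
  write_pssm_fixture("ACDE", sc7, tf)
  ps7 <- parse_pssm_file(tf)
  g7 <- pssm_features(ps7)
  expect_true(all(g7[c("A", "C", "D", "E"), ] == 7))
  expect_true(all(pssm_features(ps7, mode = "column_mean")[1, ] == 7))
})

test_that("discretization is invariant to the documented row permutations", {
  set.seed(5)
  tf <- withr::local_tempfile()
  seqs <- "MACKAMC"
  sc <- random_scores(7)
  write_pssm_fixture(seqs, sc, tf)
  ps <- parse_pssm_file(tf)
  # permute full rows (residue + scores together)
  perm <- sample(7)
  ps2 <- ps
  ps2$residues <- ps$residues[perm]
  ps2$scores <- ps$scores[perm, ]
  expect_equal(pssm_features(ps2), pssm_features(ps))
  expect_equal(pssm_features(ps2, mode = "column_mean"),
               pssm_features(ps, mode = "column_mean"))
})

test_that("grouped rows weighted by residue frequency reproduce the column means", {
  set.seed(6)
  tf <- withr::local_tempfile()
  seqs <- "MACKAMCA"
  write_pssm_fixture(seqs, random_scores(8), tf)
  ps <- parse_pssm_file(tf)
  g <- pssm_features(ps)
  freq <- table(factor(ps$residues, levels = rownames(g))) / length(ps$residues)
  recovered <- drop(as.numeric(freq) %*% g)
  cm <- pssm_features(ps, mode = "column_mean")[1, ]
  expect_equal(recovered, cm, ignore_attr = TRUE)
})

test_that("nonstandard residues are dropped from grouping but counted", {
  set.seed(7)
  tf <- withr::local_tempfile()
  sc <- random_scores(4)
  write_pssm_fixture("MAXC", sc, tf)
  ps <- parse_pssm_file(tf)
  g <- pssm_features(ps)
  expect_equal(attr(g, "n_nonstandard"), 1L)
  # the X row contributed nowhere in grouped mode
  expect_equal(g["M", ], sc[1, ], ignore_attr = TRUE)
  # but contributes to the column mean
  cm <- pssm_features(ps, mode = "column_mean")
  expect_equal(cm[1, ], colMeans(sc), ignore_attr = TRUE)
})

test_that("feature flattening is row-major", {
  m <- matrix(1:6, 2, 3, byrow = TRUE)
  expect_equal(flatten_features(m), 1:6)
})

test_that("label tables build binary matrices with a fixed vocabulary", {
  tf <- withr::local_tempfile()
  writeLines(c("protein_id\tlocations",
               "P1\tnucleus",
               "P2\tnucleus;cytoplasm",
               "P3\tmembrane"), tf)
  df <- read_label_table(tf)
  Y <- make_label_matrix(df)
  expect_equal(colnames(Y), c("cytoplasm", "membrane", "nucleus"))
  expect_equal(unname(Y["P2", ]), c(1L, 0L, 1L))
  expect_equal(rowSums(Y), c(P1 = 1, P2 = 2, P3 = 1))
  Y2 <- make_label_matrix(df, vocabulary = c("nucleus", "cytoplasm",
                                             "membrane", "golgi"))
  expect_equal(ncol(Y2), 4L)
  expect_error(make_label_matrix(df, vocabulary = "nucleus"), "vocabulary")
})

test_that("a PSSM directory plus labels becomes an aligned 400-feature dataset", {
  set.seed(8)
  dir <- withr::local_tempdir()
  for (id in c("P1", "P2")) {
    write_pssm_fixture("MACKY", random_scores(5),
                       file.path(dir, paste0(id, ".pssm")))
  }
  lab <- withr::local_tempfile()
  writeLines(c("protein_id\tlocations", "P1\tnucleus", "P2\tnucleus;er"), lab)
  ds <- featurize_pssm_dir(dir, lab)
  expect_s3_class(ds, "ml_dataset")
  expect_equal(dim(ds$features), c(2L, 400L))
  expect_equal(ds$ids, c("P1", "P2"))
  expect_equal(unname(rowSums(ds$labels)), c(1, 2))
  # features equal the flattened grouped discretization of each file
  f1 <- flatten_features(pssm_features(parse_pssm_file(
    file.path(dir, "P1.pssm"))))
  expect_equal(unname(ds$features["P1", ]), f1)
})

test_that("feature scaling centers, guards zero variance, and inverts", {
  set.seed(9)
  X <- matrix(rnorm(50 * 8, mean = 3, sd = 2), 50, 8)
  X[, 3] <- 1  # constant feature
  sc <- fit_feature_scaler(X)
  Z <- scale_features(sc, X)
  expect_equal(unname(colMeans(Z)), rep(0, 8), tolerance = 1e-12)
  expect_equal(unname(apply(Z[, -3], 2, sd)), rep(1, 7), tolerance = 1e-12)
  # zero-variance feature: scale 1, centered only
  expect_true(all(Z[, 3] == 0))
  expect_equal(unscale_features(sc, Z), X, tolerance = 1e-12)
  # a single training sample maps to the zero vector
  sc1 <- fit_feature_scaler(X[1, , drop = FALSE])
  expect_true(all(scale_features(sc1, X[1, , drop = FALSE]) == 0))
  expect_error(scale_features(list(), X), "feature_scaler")
  expect_error(scale_features(sc, X[, 1:3]), "dimension")
})
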