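# Feature tables and preprocessing ------------------------------------------

#' Construct a feature table
#'
#' The pipeline's container for a binary-labelled numeric dataset: a sample
#' by feature matrix plus M/B diagnosis labels (M = malignant = +1,
#' B = benign = -1) and a record of the scaling transforms applied.
#'
#' @param features Numeric matrix or data frame (samples x features).
#' @param labels Character vector of `"M"`/`"B"` labels, or `NULL` for an
#'   unlabelled table.
#' @param ids Optional sample identifiers (default `S1..Sn`).
#' @return An object of class `feature_table` with fields `ids`, `features`,
#'   `labels` (original strings), `y` (+1/-1) and `scaling` (list of applied
#'   transforms with their parameters).
#' @export
feature_table <- function(features, labels = NULL, ids = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (is.null(colnames(features)))
    colnames(features) <- paste0("feature_", seq_len(ncol(features)))
  n <- nrow(features)
  if (is.null(ids)) ids <- paste0("S", seq_len(n))
  y <- NULL
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n)
      gf_stop("gf_input_error", "%d labels for %d samples", length(labels), n)
    bad <- which(!labels %in% c("M", "B"))
    if (length(bad))
      gf_stop("gf_parse_error",
              "unknown label '%s' in row %d (labels must be M or B)",
              labels[bad[1]], bad[1])
    y <- ifelse(labels == "M", 1, -1)
  }
  structure(list(ids = as.character(ids), features = features,
                 labels = labels, y = y, scaling = list()),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d samples x %d features",
              nrow(x$features), ncol(x$features)))
  if (!is.null(x$labels))
    cat(sprintf(" (M: %d, B: %d)", sum(x$labels == "M"), sum(x$labels == "B")))
  cat("\n")
  if (length(x$scaling))
    cat(" transforms:", paste(names(x$scaling), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$features)

# subset rows, keeping labels and scaling state
ft_subset <- function(t, idx) {
  out <- t
  out$ids <- t$ids[idx]
  out$features <- t$features[idx, , drop = FALSE]
  if (!is.null(t$labels)) out$labels <- t$labels[idx]
  if (!is.null(t$y)) out$y <- t$y[idx]
  out
}

#' Read a feature table from CSV
#'
#' Expects a header row; every non-label, non-id column must be numeric, and
#' the label column (when named) must contain only `M`/`B`.
#'
#' @param path CSV file path.
#' @param label_column Name of the diagnosis column; `NULL` loads an
#'   unlabelled table.
#' @param id_column Optional name of a sample-id column (dropped from the
#'   features; a column literally named `id` is dropped by default).
#' @param na_action `"error"` (default) rejects missing values;
#'   `"impute_mean"` replaces them with the column mean.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, label_column = "Diagnosis",
                               id_column = NULL, na_action = c("error", "impute_mean")) {
  na_action <- match.arg(na_action)
  if (!file.exists(path))
    gf_stop("gf_input_error", "data file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  labels <- NULL
  if (!is.null(label_column)) {
    if (!label_column %in% names(df))
      gf_stop("gf_parse_error", "label column '%s' not found in %s",
              label_column, path)
    labels <- as.character(df[[label_column]])
    df[[label_column]] <- NULL
  }
  ids <- NULL
  if (is.null(id_column) && "id" %in% names(df)) id_column <- "id"
  if (!is.null(id_column) && id_column %in% names(df)) {
    ids <- as.character(df[[id_column]])
    df[[id_column]] <- NULL
  }
  for (nm in names(df)) {
    col <- df[[nm]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & nzchar(trimws(col)))
      if (length(bad))
        gf_stop("gf_parse_error",
                "non-numeric value '%s' in column '%s', row %d",
                col[bad[1]], nm, bad[1])
      df[[nm]] <- num
    }
  }
  X <- as.matrix(df)
  if (anyNA(X)) {
    if (na_action == "error")
      gf_stop("gf_parse_error", "missing values in %s (use na_action = 'impute_mean')",
              path)
    for (j in seq_len(ncol(X))) {
      nas <- is.na(X[, j])
      if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
    }
  }
  feature_table(X, labels, ids)
}

#' Write a feature table to CSV
#'
#' Values round-trip at full precision; the original `M`/`B` labels are
#' written back in the label column.
#'
#' @param t A `feature_table`.
#' @param path Output path.
#' @param label_column Name of the label column to write.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(t, path, label_column = "Diagnosis") {
  df <- as.data.frame(format(t$features, digits = 17, trim = TRUE,
                             scientific = TRUE), stringsAsFactors = FALSE)
  names(df) <- colnames(t$features)
  if (!is.null(t$labels)) df[[label_column]] <- t$labels
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Numeric class labels of a table
#'
#' `M` (malignant, the positive class) maps to +1 and `B` (benign) to -1.
#' The original strings are retained on the table for reporting.  When given
#' a character vector, returns the coded vector directly.
#'
#' @param x A `feature_table` or a character vector of `M`/`B` labels.
#' @return For a table, the table (coding is stored in `$y`, with a
#'   `single_class` attribute flagged when only one class is present); for a
#'   vector, a numeric +1/-1 vector.
#' @export
#' @examples
#' encode_labels(c("M", "B", "M"))  # +1 -1 +1
encode_labels <- function(x) {
  if (is.character(x)) {
    bad <- which(!x %in% c("M", "B"))
    if (length(bad))
      gf_stop("gf_parse_error", "unknown label '%s' in position %d",
              x[bad[1]], bad[1])
    return(ifelse(x == "M", 1, -1))
  }
  if (!inherits(x, "feature_table"))
    gf_stop("gf_input_error", "encode_labels expects labels or a feature_table")
  if (is.null(x$labels))
    gf_stop("gf_input_error", "table has no labels to encode")
  x$y <- encode_labels(x$labels)
  attr(x, "single_class") <- length(unique(x$y)) < 2L
  x
}

#' Recover the original label strings
#'
#' @param y Numeric +1/-1 vector.
#' @return Character `M`/`B` vector.
#' @export
decode_labels <- function(y) ifelse(y > 0, "M", "B")

# Scaling --------------------------------------------------------------------

#' Min-max standardization
#'
#' Maps each feature to `[0, 1]` via `(v - min) / (max - min)`, storing the
#' per-feature minima and maxima so that held-out samples can be scaled with
#' the same parameters ([apply_minmax()]).  Constant features map to 0.
#'
#' @param t A `feature_table`.
#' @return The scaled table; parameters live in `t$scaling$minmax`.
#' @export
minmax_scale <- function(t) {
  mins <- apply(t$features, 2, min)
  maxs <- apply(t$features, 2, max)
  t$features <- apply_minmax(t$features, list(min = mins, max = maxs))
  t$scaling$minmax <- list(min = mins, max = maxs)
  t
}

#' @rdname minmax_scale
#' @param X Numeric matrix (or vector) to scale with stored parameters.
#' @param params The `list(min, max)` stored by a previous `minmax_scale()`.
#' @export
apply_minmax <- function(X, params) {
  X <- as.matrix(X)
  rng <- params$max - params$min
  rng[rng == 0] <- 1  # constant feature: (v - min) / 1 = 0
  sweep(sweep(X, 2, params$min, "-"), 2, rng, "/")
}

#' Log transformation
#'
#' Applies `v -> log(v + 1)` per feature (shift-by-one keeps the transform
#' total on non-negative data).  With `shift = FALSE`, applies a plain
#' `log(v)` and rejects non-positive values.
#'
#' @param t A `feature_table`.
#' @param shift Use the `log1p` form (default).
#' @return The transformed table; recorded in `t$scaling$log`.
#' @export
log_transform <- function(t, shift = TRUE) {
  mn <- min(t$features)
  if (shift) {
    if (mn < 0)
      gf_stop("gf_transform_error",
              "negative feature value %g; log transform expects non-negative data", mn)
    t$features <- log1p(t$features)
  } else {
    if (mn <= 0)
      gf_stop("gf_transform_error",
              "non-positive feature value %g with shift disabled", mn)
    t$features <- log(t$features)
  }
  t$scaling$log <- list(shift = shift)
  t
}

#' Z-score outlier removal
#'
#' Single-pass filter: z-scores are computed once on the incoming table
#' (column mean and standard deviation); any sample with `|z| > threshold`
#' in any feature is removed.  Constant columns contribute z = 0.
#'
#' @param t A `feature_table` with at least 2 samples.
#' @param threshold Positive cutoff (default 3).
#' @return List with `table` (filtered) and `removed` (sample ids).
#' @export
zscore_filter <- function(t, threshold = 3) {
  if (nrow(t$features) < 2L)
    gf_stop("gf_input_error", "z-score filter needs at least 2 samples")
  mu <- colMeans(t$features)
  sdv <- apply(t$features, 2, stats::sd)
  sdv[sdv == 0] <- Inf  # constant column: z = 0
  z <- abs(sweep(sweep(t$features, 2, mu, "-"), 2, sdv, "/"))
  drop <- apply(z > threshold, 1, any)
  list(table = ft_subset(t, !drop), removed = t$ids[drop])
}

# Fold assignment ------------------------------------------------------------

#' Stratified k-fold assignment
#'
#' Shuffles samples within each class under the given seed and deals them
#' out round-robin, so per-fold class proportions stay within one sample of
#' the global proportions.  Deterministic per seed; the caller's RNG stream
#' is untouched.
#'
#' @param labels Numeric +1/-1 (or character M/B) labels, one per sample.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer vector of fold indices in `1..k`.
#' @export
kfold_split <- function(labels, k = 5, seed = 1) {
  if (is.character(labels)) labels <- encode_labels(labels)
  n <- length(labels)
  if (k < 2L) gf_stop("gf_input_error", "k must be >= 2")
  if (k > n) gf_stop("gf_input_error", "k = %d exceeds n = %d", k, n)
  folds <- integer(n)
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Synthetic fixture ----------------------------------------------------------

#' Generate a synthetic two-class feature table
#'
#' Emulates the shape of the malignant/benign tumour tables the pipeline
#' targets: two Gaussian classes in `d` dimensions with unit within-class
#' standard deviation, class-mean distance `separation` (in pooled-sd
#' units), and strictly positive feature values (the whole table is shifted
#' so its minimum is 1).  `separation = 0` gives label-independent features
#' (a null dataset); `separation = 6` is comfortably linearly separable.
#'
#' @param n Number of samples (>= 4).
#' @param d Number of features (>= 1).
#' @param separation Distance between class means in pooled-sd units.
#' @param class_balance Fraction of malignant (`M`) samples.
#' @param seed Integer seed; the table is a deterministic function of it.
#' @return A [feature_table()] with labels `M`/`B`.
#' @export
#' @examples
#' t <- synth_dataset(100, 8, separation = 6, seed = 1)
#' table(t$labels)
synth_dataset <- function(n = 200, d = 8, separation = 6,
                          class_balance = 0.5, seed = 1) {
  if (n < 4L || d < 1L)
    gf_stop("gf_input_error", "need n >= 4 and d >= 1")
  n_pos <- round(n * class_balance)
  n_pos <- max(2L, min(n - 2L, n_pos))
  labels <- c(rep("M", n_pos), rep("B", n - n_pos))
  delta <- separation / sqrt(d)   # per-dimension offset: ||mu_M - mu_B|| = separation
  with_seed(seed, {
    X <- matrix(stats::rnorm(n * d), n, d)
    X[labels == "M", ] <- X[labels == "M", ] + delta / 2
    X[labels == "B", ] <- X[labels == "B", ] - delta / 2
    perm <- sample.int(n)
  })
  X <- X - min(X) + 1  # strictly positive features
  colnames(X) <- paste0("feature_", seq_len(d))
  ft <- feature_table(X[perm, , drop = FALSE], labels[perm],
                      ids = paste0("S", seq_len(n)))
  ft
}
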