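# Precomputed-kernel SVM bridge ----------------------------------------------
#
# The quadratic program is delegated to kernlab's SMO solver; this module
# owns the contract: a model is the stored dual form
#     f(z) = sum_i coef_i * K(x_i, z) + bias,   coef_i = alpha_i * y_i,
# kept only for the support vectors, with sign(f) the predicted label and
# sign(0) -> +1 by convention.

#' Train an SVM on a precomputed Gram matrix
#'
#' Solves the soft-margin dual for a binary +1/-1 problem on the given
#' training Gram.  Deterministic for a fixed Gram and cost.
#'
#' @param gram Square symmetric training Gram (`gf_gram` or matrix).
#' @param y Numeric +1/-1 labels (both classes required).
#' @param C Soft-margin cost (> 0).
#' @return An object of class `gf_svm`: `coefs` (alpha_i * y_i per support
#'   vector), `bias`, `sv_index` (rows of the training set), `C`, `n_train`.
#' @export
gf_svm_train <- function(gram, y, C = 1) {
  K <- as_gram_matrix(gram)
  if (nrow(K) != ncol(K))
    gf_stop("gf_input_error", "training Gram must be square (%d x %d)",
            nrow(K), ncol(K))
  if (!isSymmetric(unname(K), tol = 1e-8))
    gf_stop("gf_input_error", "training Gram must be symmetric")
  y <- as.numeric(y)
  if (length(y) != nrow(K))
    gf_stop("gf_input_error", "%d labels for a %d-row Gram", length(y), nrow(K))
  if (length(unique(sign(y))) < 2L)
    gf_stop("gf_input_error", "labels contain a single class")
  if (C <= 0) gf_stop("gf_input_error", "C must be positive")
  yf <- factor(ifelse(y > 0, "1", "-1"), levels = c("-1", "1"))
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(K), yf, type = "C-svc",
                       C = C, kernel = "matrix")
  structure(list(
    coefs = unlist(kernlab::coef(fit)),
    bias = -kernlab::b(fit),     # f = K[, sv] %*% coefs + bias
    sv_index = kernlab::SVindex(fit),
    C = C,
    n_train = nrow(K)
  ), class = "gf_svm")
}

#' @export
print.gf_svm <- function(x, ...) {
  cat(sprintf("Precomputed-kernel SVM: %d support vectors of %d, C = %g\n",
              length(x$sv_index), x$n_train, x$C))
  invisible(x)
}

#' Predict from a precomputed cross-Gram
#'
#' @param model A `gf_svm`.
#' @param cross_gram Test-by-train kernel matrix (`gf_gram` or matrix);
#'   columns must match the training samples.
#' @return List with `scores` (decision values `f(z)`) and `labels`
#'   (+1/-1; `sign(0)` maps to +1).
#' @export
gf_svm_predict <- function(model, cross_gram) {
  K <- as_gram_matrix(cross_gram)
  if (ncol(K) != model$n_train)
    gf_stop("gf_input_error",
            "cross-Gram has %d columns but the model was trained on %d samples",
            ncol(K), model$n_train)
  f <- as.vector(K[, model$sv_index, drop = FALSE] %*% model$coefs + model$bias)
  list(scores = f, labels = ifelse(f >= 0, 1, -1))
}

#' Serialize / restore an SVM model as JSON
#'
#' @param model A `gf_svm`.
#' @param path File path.
#' @param kernel_ref Optional description of the kernel the Gram came from.
#' @return `gf_read_svm()` returns a `gf_svm`.
#' @export
gf_write_svm <- function(model, path, kernel_ref = NULL) {
  jsonlite::write_json(list(
    coefs = model$coefs, bias = model$bias, sv_index = model$sv_index,
    C = model$C, n_train = model$n_train, kernel = kernel_ref
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname gf_write_svm
#' @export
gf_read_svm <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(coefs = rec$coefs, bias = rec$bias,
                 sv_index = as.integer(rec$sv_index), C = rec$C,
                 n_train = as.integer(rec$n_train)), class = "gf_svm")
}

# Kernel dispatch used by the pipeline: an evolved expression/chromosome or
# a preset kernel spec.

#' Preset kernel specification
#'
#' @param name `"linear"`, `"polynomial"` or `"rbf"`.
#' @param gamma,degree Kernel parameters.
#' @return A `gf_preset` kernel handle accepted wherever an evolved
#'   chromosome is.
#' @export
gf_preset <- function(name, gamma = 1, degree = 3) {
  structure(list(name = check_baseline(name, gamma, degree),
                 gamma = gamma, degree = degree),
            class = "gf_preset")
}

kernel_gram <- function(kernel, X, Z = NULL, reduce = "sum") {
  if (inherits(kernel, "gf_preset"))
    gf_baseline_gram(kernel$name, X, Z, gamma = kernel$gamma,
                     degree = kernel$degree)
  else
    gf_gram(kernel, X, Z, reduce = reduce)
}

kernel_ref_string <- function(kernel) {
  if (inherits(kernel, "gf_preset"))
    sprintf("%s(gamma=%g, degree=%d)", kernel$name, kernel$gamma,
            as.integer(kernel$degree))
  else if (inherits(kernel, "gf_chromosome"))
    gf_format_bracketed(kernel$symbols)
  else gf_format_expr(kernel)
}

# Bagging ensemble ------------------------------------------------------------

#' Bootstrap-aggregated SVM ensemble
#'
#' Trains `members` SVMs, each on an n-sample bootstrap of the training
#' table, all sharing one kernel (evolved chromosome/expression or
#' [gf_preset()]); prediction is a majority vote of member labels.  The
#' member count must be odd so votes cannot tie.
#'
#' @param data A labelled `feature_table`.
#' @param kernel Kernel handle.
#' @param members Odd number of ensemble members (default 11).
#' @param C Soft-margin cost.
#' @param seed Seed driving the bootstrap draws.
#' @param bootstrap Set `FALSE` to train every member on the full table
#'   (degenerate ensemble, used for testing the vote).
#' @param reduce Scalar reduction rule for evolved kernels.
#' @return An object of class `gf_bagging`.
#' @export
gf_bagging_fit <- function(data, kernel, members = 11, C = 1, seed = 1,
                           bootstrap = TRUE, reduce = "sum") {
  if (members < 1 || members %% 2 == 0)
    gf_stop("gf_config_error", "members must be odd and >= 1 (got %d)", members)
  if (is.null(data$y))
    gf_stop("gf_input_error", "bagging needs a labelled table")
  n <- nrow(data$features)
  if (inherits(kernel, "gf_chromosome")) kernel <- gf_decode(kernel)
  idx_list <- with_seed(seed, lapply(seq_len(members), function(i)
    if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)))
  models <- vector("list", members)
  for (i in seq_len(members)) {
    idx <- idx_list[[i]]
    K <- kernel_gram(kernel, data$features[idx, , drop = FALSE],
                     reduce = reduce)
    models[[i]] <- gf_svm_train(K, data$y[idx], C = C)
  }
  structure(list(models = models, indices = idx_list, kernel = kernel,
                 train_features = data$features, C = C, seed = seed,
                 reduce = reduce),
            class = "gf_bagging")
}

#' @export
print.gf_bagging <- function(x, ...) {
  cat(sprintf("Bagged SVM ensemble: %d members, kernel %s\n",
              length(x$models), kernel_ref_string(x$kernel)))
  invisible(x)
}

#' Majority-vote prediction from a bagged ensemble
#'
#' @param ensemble A `gf_bagging`.
#' @param newdata Feature matrix or `feature_table` of test samples.
#' @return List with `labels` (majority vote) and `scores` (mean member
#'   decision value).
#' @export
gf_bagging_predict <- function(ensemble, newdata) {
  X <- if (inherits(newdata, "feature_table")) newdata$features
       else as.matrix(newdata)
  votes <- matrix(0, nrow(X), length(ensemble$models))
  scores <- matrix(0, nrow(X), length(ensemble$models))
  for (i in seq_along(ensemble$models)) {
    idx <- ensemble$indices[[i]]
    Kc <- kernel_gram(ensemble$kernel, X,
                      ensemble$train_features[idx, , drop = FALSE],
                      reduce = ensemble$reduce)
    p <- gf_svm_predict(ensemble$models[[i]], Kc)
    votes[, i] <- p$labels
    scores[, i] <- p$scores
  }
  list(labels = ifelse(rowSums(votes) >= 0, 1, -1),
       scores = rowMeans(scores))
}
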