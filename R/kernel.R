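# Kernel semantics -----------------------------------------------------------
#
# An expression node is either vector-valued (a d-vector per input pair) or
# scalar-valued.  The algebra:
#   leaves:      x -> x,  y -> y,  Plus_v -> x + y,  Minus_v -> x - y
#   vector ops:  elementwise on their children's values (scalars broadcast)
#   scalar ops:  act on scalar reductions of their children
#   reduction:   a vector v reduces to sum(v) ("sum", default) or to the
#                squared norm v.v ("sqnorm"); a vector-valued root is reduced
#                the same way.
# The raw function need not be symmetric in (x, y) (e.g. a Minus_v leaf), so
# Gram matrices symmetrize by averaging K(x, z) and K(z, x).
#
# The Gram evaluator is vectorized: a vector-valued node over an n x m pair
# grid is held as an n x m x d array, a scalar-valued node as an n x m
# matrix, so one pass over the tree computes the whole raw Gram block.

reduce_fun <- function(reduce = c("sum", "sqnorm")) {
  reduce <- match.arg(reduce)
  if (reduce == "sum") function(v) sum(v) else function(v) sum(v * v)
}

#' Evaluate a kernel expression on one pair of feature vectors
#'
#' @param expr A `gf_expr` (or a `gf_chromosome`, decoded on the fly).
#' @param x,y Numeric feature vectors of equal length.
#' @param reduce Scalar reduction applied to vector values where a scalar is
#'   needed: `"sum"` (component sum, default) or `"sqnorm"` (squared norm).
#' @return The raw (unsymmetrized) scalar kernel value.
#' @export
#' @examples
#' e <- gf_decode(c("Multi_s", "x", "y"), c("1.2", "0.1", "0.2"))
#' gf_evaluate(e, c(1, 2), c(3, 4))  # sum(x) * sum(y) = 21
gf_evaluate <- function(expr, x, y, reduce = "sum") {
  if (inherits(expr, "gf_chromosome")) expr <- gf_decode(expr)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    gf_stop("gf_input_error", "x (%d) and y (%d) differ in dimension",
            length(x), length(y))
  red <- reduce_fun(reduce)
  val <- eval_node(expr, x, y, red)
  if (is_vec_val(val)) red(val$v) else val$s
}

is_vec_val <- function(v) !is.null(v$v)

eval_node <- function(node, x, y, red = reduce_fun("sum")) {
  sym <- node$symbol
  if (is_leaf(node)) {
    v <- switch(sym,
                x = x, y = y,
                Plus_v = x + y, Minus_v = x - y,
                gf_stop("gf_invalid_terminal_error",
                        "'%s' cannot act as a terminal", sym))
    return(list(v = v, s = NULL))
  }
  a <- eval_node(node$children[[1]], x, y, red)
  b <- eval_node(node$children[[2]], x, y, red)
  if (is_vector_op(sym)) {
    if (!is_vec_val(a) && !is_vec_val(b)) {
      # two scalar children: the result stays scalar
      s <- if (sym == "Plus_v") a$s + b$s else a$s - b$s
      return(list(v = NULL, s = s))
    }
    av <- if (is_vec_val(a)) a$v else a$s   # scalar broadcasts
    bv <- if (is_vec_val(b)) b$v else b$s
    list(v = if (sym == "Plus_v") av + bv else av - bv, s = NULL)
  } else {
    as_ <- if (is_vec_val(a)) red(a$v) else a$s
    bs <- if (is_vec_val(b)) red(b$v) else b$s
    list(v = NULL,
         s = switch(sym, Plus_s = as_ + bs, Minus_s = as_ - bs,
                    Multi_s = as_ * bs))
  }
}

# Vectorized evaluation over the full pair grid X x Z.  Returns the raw
# (unsymmetrized) n x m matrix.  A vector node is an n x m x d array, a
# scalar node an n x m matrix.
eval_grid <- function(expr, X, Z, reduce = "sum") {
  n <- nrow(X); m <- nrow(Z); d <- ncol(X)
  sq <- reduce == "sqnorm"
  leaf_cache <- new.env(parent = emptyenv())  # only 4 possible leaf values
  leaf_val <- function(sym) {
    if (!is.null(leaf_cache[[sym]])) return(leaf_cache[[sym]])
    # column k of X/Z spread over the n x m pair grid
    arr <- array(0, dim = c(n, m, d))
    for (k in seq_len(d)) {
      arr[, , k] <- switch(sym,
        x = matrix(X[, k], n, m),
        y = matrix(Z[, k], n, m, byrow = TRUE),
        Plus_v = outer(X[, k], Z[, k], "+"),
        Minus_v = outer(X[, k], Z[, k], "-"))
    }
    leaf_cache[[sym]] <- arr
    arr
  }
  red_mat <- function(val) {
    if (!is.null(val$s)) return(val$s)
    arr <- if (sq) val$v * val$v else val$v
    rowSums(arr, dims = 2L)  # sum over the feature dimension
  }
  rec <- function(node) {
    sym <- node$symbol
    if (is_leaf(node)) return(list(v = leaf_val(sym), s = NULL))
    a <- rec(node$children[[1]])
    b <- rec(node$children[[2]])
    if (is_vector_op(sym)) {
      if (is.null(a$v) && is.null(b$v)) {
        # two scalar children: the op acts on length-1 values and the
        # result stays scalar (matches the pairwise evaluator)
        return(list(v = NULL,
                    s = if (sym == "Plus_v") a$s + b$s else a$s - b$s))
      }
      av <- a$v; bv <- b$v
      if (is.null(av)) av <- array(a$s, dim = c(n, m, d))  # broadcast scalar
      if (is.null(bv)) bv <- array(b$s, dim = c(n, m, d))
      list(v = if (sym == "Plus_v") av + bv else av - bv, s = NULL)
    } else {
      list(v = NULL,
           s = switch(sym, Plus_s = red_mat(a) + red_mat(b),
                      Minus_s = red_mat(a) - red_mat(b),
                      Multi_s = red_mat(a) * red_mat(b)))
    }
  }
  red_mat(rec(expr))
}

# Gram matrices --------------------------------------------------------------

#' Build a (symmetrized, sanitized) Gram matrix from a kernel expression
#'
#' Entry (i, j) is `(K(X[i], Z[j]) + K(Z[j], X[i])) / 2`, which makes the
#' square self-Gram exactly symmetric even for expressions whose raw algebra
#' is not.  Any non-finite entry is replaced by 0 and the `sanitized` flag is
#' set; evolution treats a sanitized Gram as a failed kernel.
#'
#' @param expr A `gf_expr` or `gf_chromosome`.
#' @param X An `n x d` numeric matrix (rows are samples).
#' @param Z An `m x d` matrix; defaults to `X` (training self-Gram).
#' @param reduce Scalar reduction rule, see [gf_evaluate()].
#' @return An object of class `gf_gram`: list with `values` (n x m matrix),
#'   `symmetrized = TRUE`, `sanitized` flag and dimensions.
#' @export
gf_gram <- function(expr, X, Z = NULL, reduce = "sum") {
  if (inherits(expr, "gf_chromosome")) expr <- gf_decode(expr)
  X <- as.matrix(X)
  self <- is.null(Z)
  Z <- if (self) X else as.matrix(Z)
  if (ncol(X) != ncol(Z))
    gf_stop("gf_input_error", "X has %d columns but Z has %d",
            ncol(X), ncol(Z))
  raw_xz <- eval_grid(expr, X, Z, reduce)
  raw_zx <- if (self) t(raw_xz) else t(eval_grid(expr, Z, X, reduce))
  K <- (raw_xz + raw_zx) / 2
  sanitized <- FALSE
  if (!all(is.finite(K))) {
    K[!is.finite(K)] <- 0
    sanitized <- TRUE
  }
  if (self) K <- (K + t(K)) / 2  # guard exact symmetry against rounding
  structure(list(values = K, n = nrow(X), m = nrow(Z),
                 symmetrized = TRUE, sanitized = sanitized),
            class = "gf_gram")
}

#' @export
print.gf_gram <- function(x, ...) {
  cat(sprintf("Gram matrix %d x %d (symmetrized%s)\n", x$n, x$m,
              if (x$sanitized) ", sanitized" else ""))
  invisible(x)
}

as_gram_matrix <- function(K) {
  if (inherits(K, "gf_gram")) K$values else as.matrix(K)
}

# Rescale a Gram to unit maximum absolute entry.  Used by the fitness and
# cross-validation paths: an evolved kernel's overall scale carries no
# information (it is equivalent to rescaling the SVM cost), and bounded
# entries keep the QP solver well conditioned.
scale_gram_unit <- function(K) {
  s <- max(abs(K))
  if (is.finite(s) && s > 0) K / s else K
}

# Preset kernels -------------------------------------------------------------

#' Preset kernel functions
#'
#' The three conventional kernels used as baselines: linear
#' `k(x, y) = x . y`, polynomial `k(x, y) = (x . y + 1)^p` and RBF
#' `k(x, y) = exp(-gamma * |x - y|^2)`.
#'
#' @param name One of `"linear"`, `"polynomial"`, `"rbf"`.
#' @param x,y Numeric feature vectors.
#' @param gamma RBF width parameter (> 0).
#' @param degree Polynomial degree `p` (>= 1).
#' @return Scalar kernel value; `gf_baseline_gram()` returns a `gf_gram`.
#' @export
#' @examples
#' gf_baseline_kernel("linear", c(1, 2), c(3, 4))        # 11
#' gf_baseline_kernel("polynomial", c(1, 2), c(3, 4), degree = 2)  # 144
gf_baseline_kernel <- function(name, x, y, gamma = 1, degree = 3) {
  name <- check_baseline(name, gamma, degree)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    gf_stop("gf_input_error", "x and y differ in dimension")
  switch(name,
         linear = sum(x * y),
         polynomial = (sum(x * y) + 1)^degree,
         rbf = exp(-gamma * sum((x - y)^2)))
}

check_baseline <- function(name, gamma, degree) {
  if (!name %in% c("linear", "polynomial", "rbf"))
    gf_stop("gf_input_error", "unknown baseline kernel '%s'", name)
  if (gamma <= 0) gf_stop("gf_input_error", "gamma must be > 0")
  if (degree < 1) gf_stop("gf_input_error", "degree must be >= 1")
  name
}

#' @rdname gf_baseline_kernel
#' @param X,Z Sample matrices as in [gf_gram()].
#' @export
gf_baseline_gram <- function(name, X, Z = NULL, gamma = 1, degree = 3) {
  name <- check_baseline(name, gamma, degree)
  X <- as.matrix(X)
  self <- is.null(Z)
  Z <- if (self) X else as.matrix(Z)
  if (ncol(X) != ncol(Z))
    gf_stop("gf_input_error", "X has %d columns but Z has %d",
            ncol(X), ncol(Z))
  dots <- tcrossprod(X, Z)
  K <- switch(name,
              linear = dots,
              polynomial = (dots + 1)^degree,
              rbf = {
                d2 <- outer(rowSums(X^2), rowSums(Z^2), "+") - 2 * dots
                exp(-gamma * pmax(d2, 0))
              })
  if (self) K <- (K + t(K)) / 2
  structure(list(values = K, n = nrow(X), m = nrow(Z),
                 symmetrized = TRUE, sanitized = FALSE),
            class = "gf_gram")
}

# Mercer diagnostics ---------------------------------------------------------

#' Check positive semidefiniteness of a training Gram
#'
#' An SVM kernel is a Mercer kernel when every Gram matrix it produces is
#' positive semidefinite, which guarantees a convex dual problem.  Evolved
#' kernels carry no such guarantee, so this diagnostic reports the smallest
#' eigenvalue of the (symmetrized) square Gram.
#'
#' @param g A square `gf_gram` or numeric matrix.
#' @param tol Eigenvalues above `-tol` count as non-negative.
#' @return List with `psd` (logical) and `min_eigenvalue`.
#' @export
gf_mercer_check <- function(g, tol = 1e-8) {
  K <- as_gram_matrix(g)
  if (nrow(K) != ncol(K))
    gf_stop("gf_input_error", "Mercer check needs a square Gram (%d x %d)",
            nrow(K), ncol(K))
  K <- (K + t(K)) / 2
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  list(psd = min(ev) >= -tol, min_eigenvalue = min(ev))
}

#' Optional spectral clipping of a training Gram
#'
#' Projects a square Gram onto the PSD cone by zeroing negative eigenvalues.
#' Off by default in the pipeline; evolved kernels are used as-is unless the
#' caller opts in.
#'
#' @param g A square `gf_gram` or matrix.
#' @return A `gf_gram` with non-negative spectrum.
#' @export
gf_psd_clip <- function(g) {
  K <- as_gram_matrix(g)
  if (nrow(K) != ncol(K))
    gf_stop("gf_input_error", "spectral clipping needs a square Gram")
  K <- (K + t(K)) / 2
  e <- eigen(K, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  K2 <- e$vectors %*% (lam * t(e$vectors))
  K2 <- (K2 + t(K2)) / 2
  structure(list(values = K2, n = nrow(K2), m = ncol(K2),
                 symmetrized = TRUE,
                 sanitized = inherits(g, "gf_gram") && g$sanitized),
            class = "gf_gram")
}

# Text export ----------------------------------------------------------------

#' Write or read a Gram matrix as plain text
#'
#' The format is one header line `n m symmetrized sanitized` followed by the
#' dense numeric matrix, full precision.
#'
#' @param g A `gf_gram`.
#' @param path File path.
#' @return `gf_read_gram()` returns a `gf_gram`; the writer returns `path`
#'   invisibly.
#' @export
gf_write_gram <- function(g, path) {
  K <- as_gram_matrix(g)
  header <- sprintf("%d %d %d %d", nrow(K), ncol(K),
                    as.integer(isTRUE(g$symmetrized)),
                    as.integer(isTRUE(g$sanitized)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(format(K, digits = 17, trim = TRUE, scientific = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname gf_write_gram
#' @export
gf_read_gram <- function(path) {
  header <- as.integer(strsplit(readLines(path, n = 1L), " ")[[1]])
  vals <- as.matrix(utils::read.table(path, skip = 1L))
  dimnames(vals) <- NULL
  structure(list(values = vals, n = header[1], m = header[2],
                 symmetrized = header[3] == 1L, sanitized = header[4] == 1L),
            class = "gf_gram")
}
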