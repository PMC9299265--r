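#' @keywords internal
"_PACKAGE"

# Symbol vocabulary ----------------------------------------------------------
#
# The kernel language has exactly seven symbols: three scalar operators
# (Plus_s, Minus_s, Multi_s), two vector operators (Plus_v, Minus_v) and two
# operands (x, y).  The arity column is carried as metadata; tree decoding
# itself always reads two children per internal node from the folding index.

GF_SYMBOLS <- data.frame(
  name       = c("Plus_s", "Minus_s", "Multi_s", "Plus_v", "Minus_v", "x", "y"),
  category   = c("operator", "operator", "operator", "operator", "operator",
                 "operand", "operand"),
  value_kind = c("scalar-op", "scalar-op", "scalar-op", "vector-op",
                 "vector-op", "operand", "operand"),
  arity      = c(1L, 1L, 1L, 2L, 2L, 1L, 1L),
  stringsAsFactors = FALSE
)

GF_OPERATORS <- GF_SYMBOLS$name[GF_SYMBOLS$category == "operator"]
GF_SCALAR_OPS <- GF_SYMBOLS$name[GF_SYMBOLS$value_kind == "scalar-op"]
GF_VECTOR_OPS <- GF_SYMBOLS$name[GF_SYMBOLS$value_kind == "vector-op"]
GF_OPERANDS <- GF_SYMBOLS$name[GF_SYMBOLS$category == "operand"]
# symbols that may close a dangling child slot
GF_TERMINAL_POOL <- c(GF_OPERANDS, GF_VECTOR_OPS)

#' Symbol table of the kernel language
#'
#' Returns the seven-symbol vocabulary used to build kernel expressions:
#' name, category (operator/operand), value kind (scalar-op, vector-op,
#' operand) and the published arity metadata.
#'
#' @return A data frame with one row per symbol.
#' @export
#' @examples
#' gf_symbols()
gf_symbols <- function() GF_SYMBOLS

is_gf_symbol <- function(s) s %in% GF_SYMBOLS$name
is_operator <- function(s) s %in% GF_OPERATORS
is_scalar_op <- function(s) s %in% GF_SCALAR_OPS
is_vector_op <- function(s) s %in% GF_VECTOR_OPS
is_operand <- function(s) s %in% GF_OPERANDS

# Condition helpers ----------------------------------------------------------

gf_stop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "gf_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
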