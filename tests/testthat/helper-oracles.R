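# Independent oracles used across the suite.  These deliberately do not
# share code with the package: the decoder oracle is a plain recursive
# builder over the fold table, and the evaluator oracle is a direct
# interpreter over numeric vectors.

# --- brute-force recursive decoder -----------------------------------------
# Returns a nested list (sym, kids) independent of the package's gf_expr.
oracle_decode <- function(symbols, folds) {
  lr <- do.call(rbind, lapply(strsplit(folds, ".", fixed = TRUE), as.integer))
  build <- function(i) {  # 0-based
    l <- lr[i + 1, 1]; r <- lr[i + 1, 2]
    if (l == 0 && r == i) return(list(sym = symbols[i + 1], kids = NULL))
    list(sym = symbols[i + 1], kids = list(build(l), build(r)))
  }
  build(0L)
}

# canonical string form of an oracle tree, comparable with gf_format_expr()
oracle_format <- function(tree) {
  if (is.null(tree$kids)) return(tree$sym)
  sprintf("%s(%s, %s)", tree$sym,
          oracle_format(tree$kids[[1]]), oracle_format(tree$kids[[2]]))
}

# --- brute-force expression interpreter ------------------------------------
# Walks a gf_expr directly on a pair of numeric vectors; scalar reduction is
# the component sum.  Values are kept as plain numeric vectors (a scalar is
# a length-1 vector flagged by attribute).
oracle_eval <- function(expr, x, y) {
  walk <- function(node) {
    sym <- node$symbol
    if (length(node$children) == 0) {
      v <- switch(sym, x = x, y = y, Plus_v = x + y, Minus_v = x - y)
      return(list(val = v, scalar = FALSE))
    }
    a <- walk(node$children[[1]])
    b <- walk(node$children[[2]])
    if (sym %in% c("Plus_v", "Minus_v")) {
      # elementwise; a scalar operand broadcasts over the vector
      op <- if (sym == "Plus_v") `+` else `-`
      list(val = op(a$val, b$val), scalar = a$scalar && b$scalar)
    } else {
      sa <- if (a$scalar) a$val else sum(a$val)
      sb <- if (b$scalar) b$val else sum(b$val)
      s <- switch(sym, Plus_s = sa + sb, Minus_s = sa - sb, Multi_s = sa * sb)
      list(val = s, scalar = TRUE)
    }
  }
  out <- walk(expr)
  if (out$scalar) out$val else sum(out$val)
}

# --- exhaustive tree enumeration -------------------------------------------
# All expression trees with exactly `n` nodes (internal nodes have two
# children) over the given symbol pools, as oracle-style nested lists.
enumerate_trees <- function(n, operators, terminals) {
  if (n == 1)
    return(lapply(terminals, function(s) list(sym = s, kids = NULL)))
  out <- list()
  for (nl in seq(1, n - 2, by = 2)) {
    lefts <- enumerate_trees(nl, operators, terminals)
    rights <- enumerate_trees(n - 1 - nl, operators, terminals)
    for (op in operators)
      for (lt in lefts)
        for (rt in rights)
          out[[length(out) + 1]] <- list(sym = op, kids = list(lt, rt))
  }
  out
}

# oracle tree -> gf_expr (for feeding enumerated trees to gf_encode)
oracle_to_expr <- function(tree) {
  if (is.null(tree$kids)) return(genefold:::gf_expr(tree$sym))
  genefold:::gf_expr(tree$sym,
                     oracle_to_expr(tree$kids[[1]]),
                     oracle_to_expr(tree$kids[[2]]))
}

# random expression generator, independent of gf_random_chromosome
random_expr <- function(depth = 3, p_leaf = 0.4) {
  ops <- c("Plus_s", "Minus_s", "Multi_s", "Plus_v", "Minus_v")
  leaves <- c("x", "y", "Plus_v", "Minus_v")
  if (depth == 0 || runif(1) < p_leaf)
    return(genefold:::gf_expr(sample(leaves, 1)))
  genefold:::gf_expr(sample(ops, 1),
                     random_expr(depth - 1, p_leaf),
                     random_expr(depth - 1, p_leaf))
}

# small labelled table helpers
toy_table <- function(n = 60, d = 4, separation = 6, seed = 42)
  synth_dataset(n, d, separation = separation, seed = seed)

prostate_fixture <- function()
  system.file("extdata", "prostate_sample.csv", package = "genefold")
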