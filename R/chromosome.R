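# Chromosome genotype --------------------------------------------------------
#
# A chromosome is a linear string of genes.  Gene i (positions are 0-based)
# carries a symbol and a folding index "l.r".  A gene with fold "0.i" acts as
# a terminal; any other fold names the positions of its two children, which
# must both lie strictly beyond i (forward references only, so the genotype
# is acyclic by construction).  Decoding grows the kernel expression tree
# from gene 0.

#' Construct a chromosome
#'
#' Bundles a symbol list and a folding-index list into a chromosome object.
#' The constructor performs only structural parsing (equal lengths, each fold
#' a parsable `"l.r"` pair); use [gf_validate()] for full diagnostics or
#' [gf_decode()] to obtain the expression tree.
#'
#' @param symbols Character vector of symbol names (see [gf_symbols()]).
#' @param folds Character vector of `"l.r"` folding indices, same length.
#' @param head_length Optional operator-only prefix length used when the
#'   chromosome was generated; kept as metadata.
#' @return An object of class `gf_chromosome`.
#' @seealso [gf_decode()], [gf_validate()], [gf_random_chromosome()]
#' @export
#' @examples
#' gf_chromosome(c("Minus_s", "Plus_s", "y", "y", "x"),
#'               c("1.2", "3.4", "0.2", "0.3", "0.4"))
gf_chromosome <- function(symbols, folds, head_length = NA_integer_) {
  symbols <- as.character(symbols)
  folds <- as.character(folds)
  if (length(symbols) != length(folds) || length(symbols) < 1L)
    gf_stop("gf_input_error",
            "symbols (%d) and folds (%d) must have equal length >= 1",
            length(symbols), length(folds))
  lr <- parse_folds(folds)
  structure(
    list(symbols = symbols, left = lr$left, right = lr$right,
         head_length = as.integer(head_length)),
    class = "gf_chromosome"
  )
}

parse_folds <- function(folds) {
  m <- regmatches(folds, regexec("^([0-9]+)\\.([0-9]+)$", folds))
  bad <- which(vapply(m, length, 1L) != 3L)
  if (length(bad))
    gf_stop("gf_malformed_error",
            "fold '%s' at position %d does not parse as 'l.r'",
            folds[bad[1]], bad[1] - 1L)
  list(left = vapply(m, function(g) as.integer(g[2]), 1L),
       right = vapply(m, function(g) as.integer(g[3]), 1L))
}

fold_strings <- function(chrom) paste0(chrom$left, ".", chrom$right)

is_terminal_gene <- function(chrom, i) {
  # i is 0-based
  chrom$left[i + 1L] == 0L && chrom$right[i + 1L] == i
}

#' @export
print.gf_chromosome <- function(x, ...) {
  cat(sprintf("Genetic Folding chromosome: %d genes\n", length(x$symbols)))
  cat(" symbols:", gf_format_bracketed(x$symbols), "\n")
  cat(" folds:  ", gf_format_bracketed(fold_strings(x)), "\n")
  invisible(x)
}

#' @export
length.gf_chromosome <- function(x) length(x$symbols)

# Decoding -------------------------------------------------------------------

#' Decode a chromosome into a kernel expression tree
#'
#' Applies the child-indexing rule: gene `i` with fold `"a.b"` becomes an
#' internal node whose left subtree is decoded at position `a` and right
#' subtree at position `b`; a self-referencing fold `"0.i"` marks a terminal.
#' The tree is rooted at gene 0 and must span every gene exactly once.
#'
#' @param symbols A chromosome (`gf_chromosome`) or a character vector of
#'   symbol names.
#' @param folds Character vector of `"l.r"` folding indices (ignored when
#'   `symbols` is already a chromosome).
#' @return The root node, an object of class `gf_expr`.
#' @export
#' @examples
#' e <- gf_decode(c("Minus_s", "Plus_s", "y", "y", "x"),
#'                c("1.2", "3.4", "0.2", "0.3", "0.4"))
#' gf_format_expr(e)  # "Minus_s(Plus_s(y, x), y)"
gf_decode <- function(symbols, folds = NULL) {
  chrom <- if (inherits(symbols, "gf_chromosome")) symbols
           else gf_chromosome(symbols, folds)
  n <- length(chrom$symbols)
  refs <- integer(n)      # how many times each gene is used as a child
  visited <- logical(n)

  build <- function(i) {  # 0-based position
    if (i < 0L || i >= n)
      gf_stop("gf_malformed_error",
              "child index %d out of range [0, %d]", i, n - 1L)
    if (visited[i + 1L])
      gf_stop("gf_spanning_error",
              "gene %d is referenced more than once (not a tree)", i)
    visited[i + 1L] <<- TRUE
    sym <- chrom$symbols[i + 1L]
    if (!is_gf_symbol(sym))
      gf_stop("gf_malformed_error", "unknown symbol '%s' at position %d",
              sym, i)
    if (is_terminal_gene(chrom, i)) {
      if (is_scalar_op(sym))
        gf_stop("gf_invalid_terminal_error",
                "scalar operator '%s' cannot act as a terminal (position %d)",
                sym, i)
      return(gf_expr(sym))
    }
    l <- chrom$left[i + 1L]; r <- chrom$right[i + 1L]
    if (l >= n || r >= n)
      gf_stop("gf_malformed_error",
              "fold '%d.%d' at position %d references beyond the last gene %d",
              l, r, i, n - 1L)
    if (l <= i || r <= i)
      gf_stop("gf_malformed_error",
              "backward reference in fold '%d.%d' at position %d", l, r, i)
    if (is_operand(sym))
      gf_stop("gf_malformed_error",
              "operand '%s' at position %d cannot have children", sym, i)
    refs[l + 1L] <<- refs[l + 1L] + 1L
    refs[r + 1L] <<- refs[r + 1L] + 1L
    gf_expr(sym, build(l), build(r))
  }

  root <- build(0L)
  if (any(!visited))
    gf_stop("gf_spanning_error",
            "gene(s) %s unreachable from the root",
            paste(which(!visited) - 1L, collapse = ", "))
  if (any(refs[-1L] != 1L))
    gf_stop("gf_spanning_error",
            "gene(s) %s not referenced by exactly one parent",
            paste(which(refs[-1L] != 1L), collapse = ", "))
  root
}

# Expression node constructor (phenotype); children are 0 or 2 nodes.
gf_expr <- function(symbol, left = NULL, right = NULL) {
  children <- if (is.null(left)) list() else list(left, right)
  kind <- if (is_scalar_op(symbol) && length(children)) "scalar"
          else if (is_scalar_op(symbol)) "scalar"  # never reached for leaves
          else "vector"
  structure(list(symbol = symbol, children = children, value_kind = kind),
            class = "gf_expr")
}

is_leaf <- function(e) length(e$children) == 0L

#' Render a kernel expression as a prefix string
#'
#' @param expr A `gf_expr` node.
#' @return A string such as `"Plus_s(Multi_s(x, y), Minus_v)"`; terminals
#'   print bare.
#' @export
gf_format_expr <- function(expr) {
  if (is_leaf(expr)) return(expr$symbol)
  sprintf("%s(%s, %s)", expr$symbol,
          gf_format_expr(expr$children[[1]]),
          gf_format_expr(expr$children[[2]]))
}

#' @export
print.gf_expr <- function(x, ...) {
  cat("Kernel expression:", gf_format_expr(x), "\n")
  invisible(x)
}

# Encoding -------------------------------------------------------------------

#' Encode an expression tree back into a chromosome
#'
#' Emits genes in breadth-first (level) order from the root, the same layout
#' the decoder-printed chromosomes use, so that `gf_decode(gf_encode(e))`
#' reproduces `e` exactly.  Terminals receive self-referencing folds `"0.i"`.
#'
#' @param expr A well-formed `gf_expr`.
#' @return A `gf_chromosome`.
#' @export
gf_encode <- function(expr) {
  nodes <- list(expr)       # queue of nodes, position = index - 1
  child_l <- integer(1)
  child_r <- integer(1)
  i <- 1L
  while (i <= length(nodes)) {
    node <- nodes[[i]]
    if (is_leaf(node)) {
      child_l[i] <- 0L
      child_r[i] <- i - 1L  # self reference, 0-based
    } else {
      child_l[i] <- length(nodes)       # 0-based position of next slot
      child_r[i] <- length(nodes) + 1L
      nodes[[length(nodes) + 1L]] <- node$children[[1]]
      nodes[[length(nodes) + 1L]] <- node$children[[2]]
    }
    i <- i + 1L
  }
  symbols <- vapply(nodes, function(nd) nd$symbol, "")
  gf_chromosome(symbols, paste0(child_l, ".", child_r))
}

# Validation -----------------------------------------------------------------

#' Diagnostic validity check of a chromosome
#'
#' Unlike [gf_decode()], this never raises on a bad genotype: it returns a
#' pass/fail flag and the list of violated invariants (fold range, forward
#' references, spanning tree, terminal legality, head composition).
#'
#' @param chrom A `gf_chromosome`, or a symbol vector (with `folds`).
#' @param folds Optional fold strings when `chrom` is a symbol vector.
#' @return A list with elements `ok` (logical) and `violations` (character).
#' @export
gf_validate <- function(chrom, folds = NULL) {
  chrom <- tryCatch(
    if (inherits(chrom, "gf_chromosome")) chrom else gf_chromosome(chrom, folds),
    gf_error = function(e) e
  )
  if (inherits(chrom, "condition"))
    return(list(ok = FALSE, violations = conditionMessage(chrom)))

  v <- character()
  n <- length(chrom$symbols)
  unknown <- !is_gf_symbol(chrom$symbols)
  if (any(unknown))
    v <- c(v, sprintf("unknown symbol(s) at position(s) %s",
                      paste(which(unknown) - 1L, collapse = ", ")))

  term <- vapply(seq_len(n) - 1L, function(i) is_terminal_gene(chrom, i), TRUE)
  for (i in which(!term) - 1L) {   # internal genes, 0-based
    l <- chrom$left[i + 1L]; r <- chrom$right[i + 1L]
    if (l >= n || r >= n)
      v <- c(v, sprintf("out-of-range fold '%d.%d' at position %d", l, r, i))
    else if (l <= i || r <= i)
      v <- c(v, sprintf("backward reference '%d.%d' at position %d", l, r, i))
  }
  bad_term <- which(term & is_scalar_op(chrom$symbols)) - 1L
  if (length(bad_term))
    v <- c(v, sprintf("scalar operator in terminal position %s",
                      paste(bad_term, collapse = ", ")))
  bad_int <- which(!term & is_operand(chrom$symbols)) - 1L
  if (length(bad_int))
    v <- c(v, sprintf("operand with children at position %s",
                      paste(bad_int, collapse = ", ")))

  if (!length(v)) {
    # spanning-tree check: every non-root gene referenced exactly once and
    # reachable from gene 0 (forward references make traversal finite)
    refs <- integer(n)
    reach <- logical(n)
    stack <- 0L
    while (length(stack)) {
      i <- stack[1]; stack <- stack[-1]
      if (reach[i + 1L]) next
      reach[i + 1L] <- TRUE
      if (!term[i + 1L]) {
        ch <- c(chrom$left[i + 1L], chrom$right[i + 1L])
        refs[ch + 1L] <- refs[ch + 1L] + 1L
        stack <- c(stack, ch)
      }
    }
    if (any(!reach))
      v <- c(v, sprintf("unreachable gene(s) %s",
                        paste(which(!reach) - 1L, collapse = ", ")))
    multi <- which(refs[-1L] != 1L)
    if (length(multi))
      v <- c(v, sprintf("gene(s) %s referenced by %s parent(s)",
                        paste(multi, collapse = ", "),
                        paste(refs[multi + 1L], collapse = ", ")))
  }

  h <- chrom$head_length
  if (!is.na(h) && h > 0L) {
    head_idx <- seq_len(min(h, n))
    if (any(!is_operator(chrom$symbols[head_idx])))
      v <- c(v, sprintf("head segment (first %d genes) contains non-operator symbols", h))
  }
  list(ok = length(v) == 0L, violations = v)
}

#' Number of genes in a chromosome
#'
#' The gene count is the complexity measure tracked against accuracy during
#' evolution.
#'
#' @param chrom A `gf_chromosome` or `gf_expr`.
#' @return Integer gene count (for an expression, the number of tree nodes).
#' @export
gf_complexity <- function(chrom) {
  if (inherits(chrom, "gf_expr")) {
    if (is_leaf(chrom)) return(1L)
    return(1L + gf_complexity(chrom$children[[1]]) +
             gf_complexity(chrom$children[[2]]))
  }
  length(chrom$symbols)
}

# Random generation ----------------------------------------------------------

#' Draw a random valid chromosome
#'
#' Fills the head with internal operator genes, then grows the tail by
#' serving dangling child slots in first-in-first-out order (which yields the
#' level-by-level gene layout of the printed chromosomes).  Each tail slot
#' becomes a new internal operator with probability `p_grow`, subject to the
#' gene cap; otherwise it is closed with an operand or a terminal-acting
#' vector operator.  The tail size is therefore not fixed in advance.
#'
#' @param head_length Number of leading operator genes (>= 1).
#' @param gene_cap Maximum total number of genes (default 50).
#' @param operators,terminals Symbol pools for internal and terminal genes.
#' @param p_grow Probability that a tail slot becomes an internal operator.
#' @param seed Optional seed; when given, the draw is reproducible and the
#'   caller's RNG stream is left untouched.
#' @return A valid `gf_chromosome` (its [gf_validate()] report passes).
#' @export
#' @examples
#' c1 <- gf_random_chromosome(head_length = 3, seed = 7)
#' gf_validate(c1)$ok
gf_random_chromosome <- function(head_length = 7L, gene_cap = 50L,
                                 operators = GF_OPERATORS,
                                 terminals = GF_TERMINAL_POOL,
                                 p_grow = 0.3, seed = NULL) {
  if (head_length < 1L)
    gf_stop("gf_config_error", "head_length must be >= 1")
  if (!length(operators) || !length(terminals))
    gf_stop("gf_config_error", "operator and terminal pools must be non-empty")
  if (2L * head_length + 1L > gene_cap)
    gf_stop("gf_generation_error",
            "gene cap %d too small to close a head of %d operators (needs >= %d)",
            gene_cap, head_length, 2L * head_length + 1L)
  if (!is.null(seed))
    return(with_seed(seed,
      gf_random_chromosome(head_length, gene_cap, operators, terminals, p_grow)))

  symbols <- character()
  parent <- integer()   # 0-based parent position per gene (NA for root)
  internal <- logical()
  slots <- list()       # FIFO of open child slots: parent position (0-based)
  lefts <- integer(); rights <- integer()

  place <- function(pos, sym, is_internal) {
    symbols[pos + 1L] <<- sym
    internal[pos + 1L] <<- is_internal
    lefts[pos + 1L] <<- 0L; rights[pos + 1L] <<- pos  # provisional terminal
    if (is_internal) slots[[length(slots) + 1L]] <<- pos
  }

  place(0L, sample(operators, 1L), TRUE)
  pos <- 0L
  # each open parent consumes two child genes; serve parents FIFO, left first
  pending <- c()  # vector of parent positions, one entry per unfilled child
  pending <- c(pending, 0L, 0L)
  while (length(pending)) {
    pos <- pos + 1L
    par <- pending[1]; pending <- pending[-1]
    open_before <- length(pending) + 1L
    must_head <- pos < head_length
    can_grow <- (pos + 1L) + open_before + 1L <= gene_cap
    if (must_head && !can_grow)
      gf_stop("gf_generation_error",
              "gene cap %d exhausted while filling the operator head", gene_cap)
    grow <- must_head || (can_grow && stats::runif(1) < p_grow)
    if (grow) {
      place(pos, sample(operators, 1L), TRUE)
      pending <- c(pending, pos, pos)
    } else {
      place(pos, sample(terminals, 1L), FALSE)
    }
    # record child position in the parent's fold
    if (lefts[par + 1L] == 0L && rights[par + 1L] == par) {
      lefts[par + 1L] <- pos     # first child of this parent
      rights[par + 1L] <- -1L    # sentinel until second child arrives
    } else {
      rights[par + 1L] <- pos
    }
  }
  gf_chromosome(symbols, paste0(lefts, ".", rights),
                head_length = head_length)
}

# Serialization --------------------------------------------------------------

gf_format_bracketed <- function(x) {
  paste0("[", paste(sprintf("'%s'", x), collapse = ", "), "]")
}

parse_bracketed <- function(line) {
  line <- trimws(line)
  if (!grepl("^\\[.*\\]$", line))
    gf_stop("gf_parse_error", "expected a bracketed list, got: %s",
            substr(line, 1, 40))
  inner <- sub("^\\[", "", sub("\\]$", "", line))
  items <- strsplit(inner, ",")[[1]]
  items <- gsub("^[\\s'‘’\"]+|[\\s'‘’\"]+$", "",
                trimws(items), perl = TRUE)
  items[nzchar(items)]
}

#' Read and write chromosomes in the bracketed text dialect
#'
#' The plain-text form is two bracketed, quoted lists — the symbol list and
#' the fold-index list — exactly as the best evolved kernels are printed,
#' e.g. `['Minus_s', 'Plus_s', 'y', 'y', 'x']` over
#' `['1.2', '3.4', '0.2', '0.3', '0.4']`.  `gf_write_chromosome()` emits the
#' two lines (plus optional metadata as JSON when `json = TRUE`);
#' `gf_read_chromosome()` accepts either the two-line text form or the JSON
#' record `{symbols, folds, ...}`.
#'
#' @param chrom A `gf_chromosome`.
#' @param path File path.
#' @param json Write a JSON record instead of the two-line text dialect.
#' @param fitness,dataset,seed Optional metadata stored in the JSON record.
#' @return `gf_read_chromosome()` returns a `gf_chromosome`;
#'   `gf_write_chromosome()` returns `path` invisibly.
#' @export
gf_write_chromosome <- function(chrom, path, json = FALSE,
                                fitness = NULL, dataset = NULL, seed = NULL) {
  if (json) {
    rec <- list(symbols = chrom$symbols, folds = fold_strings(chrom))
    if (!is.null(fitness)) rec$fitness <- fitness
    if (!is.null(dataset)) rec$dataset <- dataset
    if (!is.null(seed)) rec$seed <- seed
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  } else {
    writeLines(c(gf_format_bracketed(chrom$symbols),
                 gf_format_bracketed(fold_strings(chrom))), path)
  }
  invisible(path)
}

#' @rdname gf_write_chromosome
#' @export
gf_read_chromosome <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^\\s*\\{", first)) {
    rec <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(gf_chromosome(rec$symbols, rec$folds))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    gf_stop("gf_parse_error",
            "chromosome file must contain a symbol list and a fold list")
  gf_chromosome(parse_bracketed(lines[1]), parse_bracketed(lines[2]))
}

#' Parse a chromosome from two bracketed strings
#'
#' @param symbols_line,folds_line The two bracketed lists as strings.
#' @return A `gf_chromosome`.
#' @export
gf_parse_chromosome <- function(symbols_line, folds_line) {
  gf_chromosome(parse_bracketed(symbols_line), parse_bracketed(folds_line))
}
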