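# Genetic Folding evolution ---------------------------------------------------
#
# The search loop: a population of random valid chromosomes is scored by
# stratified cross-validated SVM accuracy on each chromosome's own Gram
# matrix, then improved by tournament selection, one-point crossover with
# repair, category-preserving point mutation, and elitism.  Ties in fitness
# break toward lower complexity (fewer genes), then earlier creation.

#' Configuration of a Genetic Folding run
#'
#' @param population_size Number of chromosomes per generation (>= 2).
#' @param generations Number of generations (0 = score the initial
#'   population only).
#' @param head_length Operator-only prefix length of generated chromosomes.
#' @param gene_cap Maximum genes per chromosome (default 50, the published
#'   chromosome budget).
#' @param crossover_rate Probability a selected pair is recombined.
#' @param mutation_rate Per-gene mutation probability.
#' @param tournament_size Competitors per selection tournament.
#' @param elite_count Individuals copied unchanged each generation.
#' @param cv_folds Stratified folds for the fitness estimate (default 5).
#' @param cost Soft-margin cost C of the SVM.
#' @param seed Root seed; every random choice in the run flows from it.
#' @param operator_pool,operand_pool Symbol pools for generation/mutation
#'   (operand pool may include the vector operators, which are legal
#'   terminals).
#' @param p_grow Tail growth probability of [gf_random_chromosome()].
#' @param reduce Scalar reduction rule of the kernel algebra.
#' @return A list of class `gf_config`.
#' @export
gf_config <- function(population_size = 50, generations = 20,
                      head_length = 7, gene_cap = 50,
                      crossover_rate = 0.9, mutation_rate = 0.1,
                      tournament_size = 2, elite_count = 1,
                      cv_folds = 5, cost = 1, seed = 1,
                      operator_pool = GF_OPERATORS,
                      operand_pool = GF_TERMINAL_POOL,
                      p_grow = 0.3, reduce = "sum") {
  cfg <- list(population_size = as.integer(population_size),
              generations = as.integer(generations),
              head_length = as.integer(head_length),
              gene_cap = as.integer(gene_cap),
              crossover_rate = crossover_rate,
              mutation_rate = mutation_rate,
              tournament_size = as.integer(tournament_size),
              elite_count = as.integer(elite_count),
              cv_folds = as.integer(cv_folds),
              cost = cost, seed = as.integer(seed),
              operator_pool = operator_pool, operand_pool = operand_pool,
              p_grow = p_grow, reduce = reduce)
  if (cfg$population_size < 2L)
    gf_stop("gf_config_error", "population_size must be >= 2")
  if (cfg$generations < 0L)
    gf_stop("gf_config_error", "generations must be >= 0")
  if (cfg$crossover_rate < 0 || cfg$crossover_rate > 1 ||
      cfg$mutation_rate < 0 || cfg$mutation_rate > 1)
    gf_stop("gf_config_error", "rates must lie in [0, 1]")
  if (cfg$elite_count >= cfg$population_size)
    gf_stop("gf_config_error", "elite_count must be < population_size")
  if (cfg$cv_folds < 2L) gf_stop("gf_config_error", "cv_folds must be >= 2")
  if (cfg$gene_cap < 3L) gf_stop("gf_config_error", "gene_cap must be >= 3")
  if (cfg$cost <= 0) gf_stop("gf_config_error", "cost must be positive")
  structure(cfg, class = "gf_config")
}

chrom_key <- function(chrom)
  paste(paste(chrom$symbols, collapse = ","),
        paste(fold_strings(chrom), collapse = ","), sep = "|")

#' Cross-validated fitness of a chromosome
#'
#' Decodes the chromosome, builds its Gram matrix over the full table once,
#' and averages the held-out accuracy (as a fraction in `[0, 1]`) of an SVM
#' trained on each training-fold sub-Gram.  Chromosomes whose Gram needed
#' sanitization (non-finite entries) or is degenerate (constant), and
#' chromosomes on which the solver fails, score 0.
#'
#' @param chrom A `gf_chromosome` (or `gf_expr`).
#' @param data A labelled `feature_table` containing both classes.
#' @param config A [gf_config()]; supplies folds seed, C, reduction rule.
#' @param folds Optional precomputed fold assignment (from [kfold_split()]).
#' @return Mean held-out accuracy in `[0, 1]`.
#' @export
gf_fitness <- function(chrom, data, config = gf_config(), folds = NULL) {
  if (is.null(data$y) || length(unique(data$y)) < 2L)
    gf_stop("gf_input_error", "fitness needs a labelled two-class table")
  expr <- tryCatch(
    if (inherits(chrom, "gf_expr")) chrom else gf_decode(chrom),
    gf_error = function(e) NULL)
  if (is.null(expr)) return(0)
  K <- gf_gram(expr, data$features, reduce = config$reduce)
  if (K$sanitized) return(0)
  rng <- max(K$values) - min(K$values)
  if (!is.finite(rng) || rng < 1e-12) return(0)  # degenerate kernel
  # kernel scale is arbitrary for evolved expressions; training on the
  # unit-max-abs rescaled Gram makes fitness scale-invariant and keeps the
  # QP solver well conditioned
  K$values <- scale_gram_unit(K$values)
  if (is.null(folds))
    folds <- kfold_split(data$y, k = config$cv_folds, seed = config$seed)
  acc <- vapply(seq_len(max(folds)), function(f) {
    tr <- which(folds != f); te <- which(folds == f)
    fit <- tryCatch(
      gf_svm_train(K$values[tr, tr, drop = FALSE], data$y[tr],
                   C = config$cost),
      error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    p <- gf_svm_predict(fit, K$values[te, tr, drop = FALSE])
    mean(p$labels == data$y[te])
  }, 1.0)
  if (anyNA(acc)) return(0)
  mean(acc)
}

# Variation operators ---------------------------------------------------------

# Rebuild a valid chromosome from a proposed symbol string: serve child
# slots FIFO; an operator symbol opens a new internal node while the gene
# cap allows, otherwise the slot is closed with a terminal (a scalar
# operator that cannot stay internal is replaced by a random terminal; a
# vector operator simply becomes terminal-acting).  Missing genes are
# appended as random terminals, surplus genes are dropped.
rebuild_chromosome <- function(proposed, gene_cap = 50L,
                               terminals = GF_TERMINAL_POOL) {
  symbols <- character(); lefts <- integer(); rights <- integer()
  place_terminal <- function(pos, sym) {
    if (is_scalar_op(sym) || !is_gf_symbol(sym))
      sym <- sample(terminals, 1L)
    symbols[pos + 1L] <<- sym
    lefts[pos + 1L] <<- 0L; rights[pos + 1L] <<- pos
  }
  pos <- 0L
  pending <- integer()   # parent position per unfilled child slot, FIFO
  root_sym <- if (length(proposed)) proposed[1] else sample(terminals, 1L)
  if (is_operator(root_sym) && gene_cap >= 3L) {
    symbols[1] <- root_sym; lefts[1] <- 0L; rights[1] <- 0L
    pending <- c(0L, 0L)
  } else {
    place_terminal(0L, root_sym)
  }
  while (length(pending)) {
    pos <- pos + 1L
    par <- pending[1]; pending <- pending[-1]
    open_before <- length(pending) + 1L
    sym <- if (pos + 1L <= length(proposed)) proposed[pos + 1L]
           else sample(terminals, 1L)
    can_grow <- (pos + 1L) + open_before + 1L <= gene_cap
    if (is_operator(sym) && can_grow) {
      symbols[pos + 1L] <- sym; lefts[pos + 1L] <- 0L; rights[pos + 1L] <- pos
      pending <- c(pending, pos, pos)
    } else {
      place_terminal(pos, sym)
    }
    if (lefts[par + 1L] == 0L && rights[par + 1L] == par) {
      lefts[par + 1L] <- pos; rights[par + 1L] <- -1L
    } else {
      rights[par + 1L] <- pos
    }
  }
  h <- 0L
  while (h < length(symbols) &&
         !(lefts[h + 1L] == 0L && rights[h + 1L] == h)) h <- h + 1L
  gf_chromosome(symbols, paste0(lefts, ".", rights),
                head_length = if (h > 0L) h else NA_integer_)
}

#' One-point crossover with repair
#'
#' Cuts both parents' gene strings at one point, swaps the suffixes, and
#' repairs each child so every dangling child slot is closed and the gene
#' cap is honoured — both children always pass [gf_validate()].  With
#' probability `1 - rate` the parents are returned unchanged.
#'
#' @param a,b Parent chromosomes.
#' @param rate Crossover probability.
#' @param gene_cap Gene budget for the repaired children.
#' @param terminals Terminal pool used by the repair.
#' @param seed Optional seed for a reproducible standalone call.
#' @return List of two valid chromosomes.
#' @export
gf_crossover <- function(a, b, rate = 1, gene_cap = 50L,
                         terminals = GF_TERMINAL_POOL, seed = NULL) {
  if (!is.null(seed))
    return(with_seed(seed, gf_crossover(a, b, rate, gene_cap, terminals)))
  if (stats::runif(1) >= rate) return(list(a, b))
  na <- length(a$symbols); nb <- length(b$symbols)
  cut_max <- min(na, nb) - 1L
  if (cut_max < 1L) return(list(a, b))
  cut <- sample.int(cut_max, 1L)
  s1 <- c(a$symbols[seq_len(cut)], b$symbols[(cut + 1L):nb])
  s2 <- c(b$symbols[seq_len(cut)], a$symbols[(cut + 1L):na])
  list(rebuild_chromosome(s1, gene_cap, terminals),
       rebuild_chromosome(s2, gene_cap, terminals))
}

#' Category-preserving point mutation
#'
#' Each gene independently, with probability `rate`, has its symbol redrawn
#' from the pool compatible with its role: internal genes from the operator
#' pool, terminal genes from the terminal pool (operands and terminal-acting
#' vector operators).  Tree shape — the folding indices — is untouched, so
#' the result always passes [gf_validate()].
#'
#' @param chrom A valid chromosome.
#' @param rate Per-gene mutation probability.
#' @param operators,terminals Symbol pools.
#' @param seed Optional seed for a reproducible standalone call.
#' @return A valid chromosome of identical shape.
#' @export
gf_mutate <- function(chrom, rate = 0.1, operators = GF_OPERATORS,
                      terminals = GF_TERMINAL_POOL, seed = NULL) {
  if (!is.null(seed))
    return(with_seed(seed, gf_mutate(chrom, rate, operators, terminals)))
  n <- length(chrom$symbols)
  hit <- stats::runif(n) < rate
  if (!any(hit)) return(chrom)
  for (i in which(hit)) {
    if (is_terminal_gene(chrom, i - 1L))
      chrom$symbols[i] <- sample(terminals, 1L)
    else
      chrom$symbols[i] <- sample(operators, 1L)
  }
  chrom
}

#' Population diversity
#'
#' Mean pairwise normalized Hamming distance between symbol strings; the
#' shorter chromosome is padded with a sentinel and the distance divided by
#' the longer length, so the score lies in `[0, 1]`.
#'
#' @param pop List of at least two chromosomes.
#' @return Diversity in `[0, 1]` (0 = all identical).
#' @export
gf_diversity <- function(pop) {
  if (length(pop) < 2L)
    gf_stop("gf_input_error", "diversity needs a population of >= 2")
  syms <- lapply(pop, function(c) c$symbols)
  total <- 0; npairs <- 0L
  for (i in seq_len(length(syms) - 1L)) {
    for (j in (i + 1L):length(syms)) {
      a <- syms[[i]]; b <- syms[[j]]
      n <- max(length(a), length(b))
      a <- c(a, rep("<pad>", n - length(a)))
      b <- c(b, rep("<pad>", n - length(b)))
      total <- total + sum(a != b) / n
      npairs <- npairs + 1L
    }
  }
  total / npairs
}

# Main loop -------------------------------------------------------------------

#' Run the Genetic Folding search
#'
#' Initializes a population of random valid chromosomes, scores each by
#' [gf_fitness()], then iterates selection, crossover with repair, mutation
#' and elitism for `config$generations` generations.  Elitism makes the
#' per-generation best fitness non-decreasing.  The whole run is a
#' deterministic function of `config` and `data`.
#'
#' @param data A labelled `feature_table`.
#' @param config A [gf_config()].
#' @param keep_populations Store every generation's serialized population
#'   (used by closure tests; off by default).
#' @return An object of class `gf_evolution`: `best_chromosome`,
#'   `best_expression`, `best_fitness`, `history` (one row per generation:
#'   best/median/mean/std fitness, diversity, best complexity, best-of-
#'   generation chromosome serialization), `population_fitness` (list of
#'   per-individual fitness vectors), `config` and `seed`.
#' @export
gf_evolve <- function(data, config = gf_config(), keep_populations = FALSE) {
  if (!inherits(config, "gf_config")) config <- do.call(gf_config, config)
  if (is.null(data$y) || length(unique(data$y)) < 2L)
    gf_stop("gf_input_error", "evolution needs a labelled two-class table")

  folds <- kfold_split(data$y, k = config$cv_folds, seed = config$seed)
  cache <- new.env(parent = emptyenv())
  eval_pop <- function(pop) vapply(pop, function(ch) {
    key <- chrom_key(ch)
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- gf_fitness(ch, data, config, folds = folds)
    cache[[key]] <- f
    f
  }, 1.0)

  run <- function() {
    pop <- lapply(seq_len(config$population_size), function(i)
      gf_random_chromosome(config$head_length, config$gene_cap,
                           config$operator_pool, config$operand_pool,
                           config$p_grow))
    fit <- eval_pop(pop)
    # global best (ties -> lower complexity, then earlier)
    pick_best <- function(pop, fit) {
      cx <- vapply(pop, gf_complexity, 1L)
      ord <- order(-fit, cx, seq_along(pop))
      ord[1]
    }
    b <- pick_best(pop, fit)
    best <- list(chrom = pop[[b]], fitness = fit[b])

    hist <- vector("list", config$generations)
    pops_fit <- vector("list", config$generations)
    pops_kept <- if (keep_populations) vector("list", config$generations + 1L)
    if (keep_populations) pops_kept[[1]] <- pop

    for (g in seq_len(config$generations)) {
      cx <- vapply(pop, gf_complexity, 1L)
      elite_ord <- order(-fit, cx, seq_along(pop))
      elites <- pop[elite_ord[seq_len(config$elite_count)]]
      tournament <- function() {
        cand <- sample.int(config$population_size,
                           min(config$tournament_size, config$population_size))
        cand[order(-fit[cand], cx[cand], cand)][1]
      }
      offspring <- list()
      while (length(offspring) < config$population_size - config$elite_count) {
        p1 <- pop[[tournament()]]; p2 <- pop[[tournament()]]
        kids <- gf_crossover(p1, p2, rate = config$crossover_rate,
                             gene_cap = config$gene_cap,
                             terminals = config$operand_pool)
        kids <- lapply(kids, gf_mutate, rate = config$mutation_rate,
                       operators = config$operator_pool,
                       terminals = config$operand_pool)
        offspring <- c(offspring, kids)
      }
      offspring <- offspring[seq_len(config$population_size - config$elite_count)]
      pop <- c(elites, offspring)
      fit <- eval_pop(pop)
      if (keep_populations) pops_kept[[g + 1L]] <- pop

      b <- pick_best(pop, fit)
      if (fit[b] > best$fitness ||
          (fit[b] == best$fitness &&
           gf_complexity(pop[[b]]) < gf_complexity(best$chrom))) {
        best <- list(chrom = pop[[b]], fitness = fit[b])
      }
      hist[[g]] <- data.frame(
        generation = g,
        best = max(fit),
        median = stats::median(fit),
        mean = mean(fit),
        std = stats::sd(fit),
        diversity = gf_diversity(pop),
        best_complexity = gf_complexity(pop[[b]]),
        best_symbols = gf_format_bracketed(pop[[b]]$symbols),
        best_folds = gf_format_bracketed(fold_strings(pop[[b]])),
        stringsAsFactors = FALSE
      )
      pops_fit[[g]] <- fit
    }
    history <- if (config$generations > 0L) do.call(rbind, hist)
               else data.frame()
    structure(list(
      best_chromosome = best$chrom,
      best_expression = gf_decode(best$chrom),
      best_fitness = best$fitness,
      history = history,
      population_fitness = pops_fit,
      populations = if (keep_populations) pops_kept,
      config = config,
      seed = config$seed
    ), class = "gf_evolution")
  }
  with_seed(config$seed, run())
}

#' @export
print.gf_evolution <- function(x, ...) {
  cat(sprintf(
    "Genetic Folding run: %d generations, population %d, seed %d\n",
    x$config$generations, x$config$population_size, x$seed))
  cat(sprintf(" best CV accuracy: %.4f (%d genes)\n", x$best_fitness,
              gf_complexity(x$best_chromosome)))
  cat(" best kernel:", gf_format_expr(x$best_expression), "\n")
  invisible(x)
}

#' Serialize an evolution result
#'
#' Writes the run as JSON (config, per-generation history, best chromosome
#' in the bracketed text dialect) and, optionally, the per-generation
#' statistics as a plot-ready CSV (generation, best, median, mean, std,
#' diversity, complexity).
#'
#' @param result A `gf_evolution`.
#' @param path JSON output path.
#' @param csv_path Optional CSV path for the history table.
#' @return `path`, invisibly.
#' @export
gf_write_evolution <- function(result, path, csv_path = NULL) {
  cfg <- unclass(result$config)
  jsonlite::write_json(list(
    config = cfg,
    seed = result$seed,
    best = list(
      symbols = result$best_chromosome$symbols,
      folds = fold_strings(result$best_chromosome),
      expression = gf_format_expr(result$best_expression),
      fitness = result$best_fitness,
      complexity = gf_complexity(result$best_chromosome)
    ),
    history = result$history
  ), path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path)) {
    utils::write.csv(
      result$history[, c("generation", "best", "median", "mean", "std",
                         "diversity", "best_complexity")],
      csv_path, row.names = FALSE)
  }
  invisible(path)
}
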