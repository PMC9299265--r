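---
title: "Evolving SVM kernels by Genetic Folding: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving SVM kernels by Genetic Folding: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genefold)
```

## The problem

A support vector machine separates two classes through a kernel function
$K(x_i, x_j)$, an implicit inner product in a lifted feature space.  The
choice of kernel is usually made from a small preset menu (linear,
polynomial, RBF).  `genefold` instead *searches* for a kernel: it evolves a
population of candidate kernel expressions and keeps whichever classifies a
given binary-labelled feature table best under cross-validation.  The
motivating application is malignant-versus-benign tumour classification
from numeric cell-nucleus features, with `M` (malignant) coded +1 and `B`
(benign) coded −1.

## Genotype: chromosomes of folding indices

A candidate kernel is stored as a linear chromosome.  Gene $i$ (positions
are 0-based) carries one of seven symbols — the scalar operators `Plus_s`,
`Minus_s`, `Multi_s`, the vector operators `Plus_v`, `Minus_v`, and the
operands `x`, `y` — plus a *folding index* `"l.r"`.  A gene whose fold is
its own position (`"0.i"`) acts as a terminal; any other fold names the
positions of the gene's two children.  Decoding grows the expression tree
from gene 0.  Validity demands forward references only (`l, r > i`, which
makes the genotype acyclic), a spanning tree (every other gene referenced
exactly once, all reachable), and legal terminals.

```{r decode}
e <- gf_decode(c("Minus_s", "Plus_s", "y", "y", "x"),
               c("1.2", "3.4", "0.2", "0.3", "0.4"))
gf_format_expr(e)
```

Two conventions deserve a note, because the symbol table's published arity
metadata (1 for scalar operators, 2 for vector operators) does not describe
how trees are decoded:

* **Two-children rule.**  Every internal node reads exactly two children
  from its fold, whatever its arity metadata says.  The published best
  chromosomes (27 genes for the prostate table, 15 for the breast table,
  available via `gf_published_kernel()`) are only consistent with this
  reading, so the arity column is retained as metadata only.
* **Terminal-acting vector operators.**  A vector operator with a
  self-fold is a legal leaf meaning direct application to the input pair
  (`Minus_v` ↦ $x - y$); both published chromosomes use `Minus_v` leaves.
  Scalar operators are never legal leaves — they have no sensible direct
  form — and the validator rejects them.

Chromosomes are generated with an operator-only *head* of configurable
length followed by a *tail* grown automatically: dangling child slots are
served first-in-first-out (which reproduces the level-by-level layout of
the published chromosomes) and each slot becomes a new operator with
probability `p_grow = 0.3`, subject to the 50-gene cap, or is closed with a
terminal.  The tail size is therefore not fixed in advance.  The default
head length of 7 produces kernels in the 15–50 gene range in which the
published best kernels sit.

## Phenotype: the kernel algebra

The seven symbols do not come with published arithmetic semantics, so the
package defines one total algebra and isolates it behind a single
interface:

* leaves: `x` ↦ $x$, `y` ↦ $y$, `Plus_v` ↦ $x + y$, `Minus_v` ↦ $x − y$;
* internal vector operators act elementwise (a scalar value broadcasts
  over a vector sibling; two scalar children yield a scalar);
* internal scalar operators act on scalar *reductions* of their children,
  where a vector $v$ reduces to its component sum $\sum_k v_k$ (default;
  the squared norm $v \cdot v$ is available via `reduce = "sqnorm"` for
  sensitivity checks);
* a vector-valued root is reduced the same way.

The component sum is the simplest total rule consistent with the
scalar/vector operator naming; swapping it requires touching nothing
outside the evaluator.  Because the raw algebra need not be symmetric in
$(x, y)$ (a `Minus_v` leaf is antisymmetric), Gram matrices symmetrize by
averaging $K(x, z)$ and $K(z, x)$ — an SVM kernel must be symmetric.  Any
non-finite Gram entry is replaced by zero and flagged; evolution scores a
flagged kernel 0 rather than crashing the search.

Positive semidefiniteness is **not** enforced: evolved kernels carry no
Mercer guarantee.  `gf_mercer_check()` reports the smallest eigenvalue of a
training Gram, and `gf_psd_clip()` offers optional spectral clipping, but
the default pipeline trains on the Gram as evolved; kernlab's SMO solver
handles indefinite matrices.

## Fitness and the search loop

Fitness is the mean held-out accuracy (a fraction in $[0,1]$) over
stratified $k$-fold cross-validation (default $k = 5$) of a C-SVM trained
on the chromosome's own precomputed Gram.  Two numerical choices matter:

* **Gram scale normalization.**  Before the SVM sees it, every Gram in the
  fitness and cross-validation path is divided by its maximum absolute
  entry.  An evolved expression's overall scale is arbitrary (rescaling
  the Gram is equivalent to rescaling the cost $C$), and unbounded entries
  — easily $10^8$ after a few `Multi_s` nodes — make the QP solver's
  running time explode on non-separable data.  Normalization makes fitness
  scale-invariant and keeps every fit well conditioned.
* **Failure scoring.**  Sanitized Grams, degenerate (constant) Grams and
  solver failures all score exactly 0, keeping the search total.

The loop itself is a conventional generational GA: tournament selection
(size 2), one-point crossover at a gene boundary followed by *repair*
(the child's symbol string is re-closed slot-by-slot under the gene cap, so
offspring are valid by construction), category-preserving point mutation
(internal genes stay operators, terminals stay terminals, so tree shape is
preserved), and elitism (top 1 by default), which makes the per-generation
best fitness non-decreasing.  Fitness ties break toward fewer genes —
mild parsimony pressure of the kind visible in the compact 15-gene
published breast kernel — then toward earlier creation.  Per-generation
bookkeeping records best/median/mean/std fitness, mean pairwise normalized
Hamming diversity, and the best individual's complexity (gene count).
Fitness values are cached on the chromosome's serialization, which matters
because elites and duplicated offspring recur.

Defaults the search does not take from any published setting: population
50, 20 generations, $C = 1$, tournament size 2, crossover rate 0.9,
per-gene mutation rate 0.1.  The 50-gene cap and the 5 folds are the
published budget.  All randomness flows from one root seed; a run is a
deterministic function of (data, config).

## Honest evaluation of the winner

The search *maximizes* the cross-validated fitness estimate, so that
estimate is optimistically biased for the winning kernel (a selection
effect, most visible on label-permuted data where the best of a few
hundred noisy 50%-estimates can sit several points above chance).
`gf_run_evolve()` and `gf_run_compare()` therefore report the final model
on a fold split derived from `seed + 1`, independent of the fitness folds.
On permuted labels this reported accuracy stays at chance level.

## Preprocessing

The pipeline mirrors the study design it reimplements: min-max
standardization of each feature to $[0,1]$ (fit on the full table by
default, matching the original preprocessing; fitting per training fold is
available by scaling externally with `apply_minmax()` and is the
leakage-safe alternative), optional `log1p` transformation, optional
single-pass Z-score outlier removal (any feature beyond 3 sd removes the
sample; constant columns contribute $z = 0$), and stratified seeded
$k$-fold splitting.  Min-max scaling also bounds the inputs, which keeps
evolved-kernel Grams finite at the 50-gene cap.

## The synthetic fixture

The patient tables the original experiments used are external and not
redistributable, so the package ships a generator of schema-compatible
stand-ins: two Gaussian classes in $d$ dimensions, unit within-class
standard deviation, class-mean distance `separation` in pooled-sd units,
strictly positive features, `M`/`B` labels.  The test suite and the
acceptance script use $n = 200$, $d = 8$, separation 6 (comfortably
linearly separable, so the preset linear kernel is a strong yardstick) and
separation 0 or permuted labels as the null.  What passing on this fixture
shows: the decoder, algebra, solver bridge and search behave correctly and
the search recovers separating structure when it exists, without
overfitting noise.  What it does not show: performance on real tumour
tables, whose features are correlated, non-Gaussian and unbalanced in
scale — those require the user's own data via `read_feature_table()`.

Problem sizes throughout (population 20, 10 generations, $n \le 200$ in
tests; exhaustive decoder checks up to 7 genes) were chosen so the full
suite and the acceptance script each run in minutes on one CPU.

## Known limitations

* The kernel algebra is a documented choice, not a published semantics;
  results depend on it, which is why it is isolated and configurable.
* Evolved kernels may be indefinite; the SVM dual is then non-convex and
  the solver returns a stationary point rather than a guaranteed global
  optimum.
* `BAGGINGSVM` is implemented as standard bootstrap-aggregated
  precomputed-kernel SVMs with majority vote (11 members by default); the
  original description names the approach without a recipe, so this is an
  interpretation.
* Only binary M/B classification; no probability calibration; vocabularies
  beyond the seven canonical symbols are not supported in this version.
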