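# Published best kernels ------------------------------------------------------
#
# The two best evolved kernel chromosomes reported for the prostate (27
# genes) and breast (15 genes) tumour feature tables, in the bracketed
# symbol/fold dialect.  They serve as decoder fixtures and as ready-made
# kernels for gf_run_evaluate().

PUBLISHED_KERNELS <- list(
  prostate = list(
    symbols = c("Plus_s", "Multi_s", "Multi_s", "Plus_s", "Minus_s",
                "Minus_v", "Minus_v", "Plus_s", "Plus_s", "x", "Minus_s",
                "Plus_v", "Plus_v", "Plus_v", "x", "Plus_s", "Minus_s",
                "Minus_v", "Minus_v", "Minus_v", "x", "x", "x", "x", "x",
                "x", "x"),
    folds = c("1.2", "3.4", "5.6", "7.8", "9.10", "0.5", "0.6", "11.12",
              "13.14", "0.9", "15.16", "17.18", "19.20", "21.22", "0.14",
              "23.24", "25.26", "0.17", "0.18", "0.19", "0.20", "0.21",
              "0.22", "0.23", "0.24", "0.25", "0.26")
  ),
  breast = list(
    symbols = c("Plus_s", "Plus_s", "x", "Plus_s", "Multi_s", "Multi_s",
                "Minus_v", "Plus_s", "Plus_s", "x", "Minus_v", "x", "x",
                "x", "Minus_v"),
    folds = c("1.2", "3.4", "0.2", "5.6", "7.8", "9.10", "0.6", "11.12",
              "13.14", "0.9", "0.10", "0.11", "0.12", "0.13", "0.14")
  )
)

#' Published best evolved kernels
#'
#' Returns, as a `gf_chromosome`, one of the two best kernel chromosomes
#' reported for the cancer feature tables: `"prostate"` (27 genes) or
#' `"breast"` (15 genes).
#'
#' @param dataset `"prostate"` or `"breast"`.
#' @return A `gf_chromosome`.
#' @export
#' @examples
#' gf_format_expr(gf_decode(gf_published_kernel("breast")))
gf_published_kernel <- function(dataset = c("prostate", "breast")) {
  dataset <- match.arg(dataset)
  rec <- PUBLISHED_KERNELS[[dataset]]
  gf_chromosome(rec$symbols, rec$folds)
}
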