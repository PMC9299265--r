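test_that("the worked encoding row decodes by the child-indexing rule", {
  e <- gf_decode(c("Minus_s", "Plus_s", "y", "y", "x"),
                 c("1.2", "3.4", "0.2", "0.3", "0.4"))
  expect_equal(gf_format_expr(e), "Minus_s(Plus_s(y, x), y)")
  expect_equal(gf_format_expr(e),
               oracle_format(oracle_decode(
                 c("Minus_s", "Plus_s", "y", "y", "x"),
                 c("1.2", "3.4", "0.2", "0.3", "0.4"))))
})

test_that("published best chromosomes decode into valid spanning trees", {
  pro <- gf_published_kernel("prostate")
  bre <- gf_published_kernel("breast")
  expect_equal(gf_complexity(pro), 27L)
  expect_equal(gf_complexity(bre), 15L)
  expect_true(gf_validate(pro)$ok)
  expect_true(gf_validate(bre)$ok)

  eb <- gf_decode(bre)
  expect_equal(eb$symbol, "Plus_s")
  # left child decoded at position 1, right at position 2 (a leaf 'x')
  expect_equal(eb$children[[1]]$symbol, "Plus_s")
  expect_equal(eb$children[[2]]$symbol, "x")
  expect_length(eb$children[[2]]$children, 0)

  # leaf gene positions of the 15-gene chromosome, by the self-fold rule
  leaves <- which(bre$left == 0L & bre$right == seq_along(bre$symbols) - 1L) - 1L
  expect_equal(leaves, c(2, 6, 9, 10, 11, 12, 13, 14))
  expect_equal(bre$symbols[c(6, 10, 14) + 1], rep("Minus_v", 3))

  ep <- gf_decode(pro)
  expect_equal(ep$symbol, "Plus_s")
  # decode() itself enforces every gene referenced exactly once; agreement
  # with the independent recursive builder:
  expect_equal(gf_format_expr(ep),
               oracle_format(oracle_decode(pro$symbols,
                                           paste0(pro$left, ".", pro$right))))
})

test_that("decode rejects malformed genotypes with named positions", {
  expect_error(gf_decode(c("Plus_s", "x", "x"), c("5.6", "0.1", "0.2")),
               class = "gf_malformed_error")
  expect_error(gf_decode(c("Plus_s", "x", "x"), c("5.6", "0.1", "0.2")),
               "position 0")
  # backward reference
  expect_error(gf_decode(c("Plus_s", "Plus_s", "x", "x", "x"),
                         c("1.2", "0.3", "0.2", "0.3", "0.4")),
               class = "gf_malformed_error")
  # scalar operator as terminal
  expect_error(gf_decode(c("Plus_s", "Minus_s", "x"),
                         c("1.2", "0.1", "0.2")),
               class = "gf_invalid_terminal_error")
  # gene referenced twice while another is orphaned
  expect_error(gf_decode(c("Plus_s", "x", "x"), c("1.1", "0.1", "0.2")),
               class = "gf_spanning_error")
  # operand with children
  expect_error(gf_decode(c("x", "x", "x"), c("1.2", "0.1", "0.2")),
               class = "gf_malformed_error")
})

test_that("decode handles non-level-order layouts", {
  e <- gf_decode(c("Plus_s", "Minus_s", "x", "x", "x"),
                 c("1.4", "2.3", "0.2", "0.3", "0.4"))
  expect_equal(gf_format_expr(e), "Plus_s(Minus_s(x, x), x)")
})

test_that("validate diagnoses violations without raising", {
  # "0.1" at position 2 is neither a self-reference nor a forward fold
  bad <- gf_chromosome(c("Plus_s", "x", "x"), c("1.2", "0.1", "0.1"))
  rep1 <- gf_validate(bad)
  expect_false(rep1$ok)
  expect_true(any(grepl("backward", rep1$violations)))

  # gene 1 referenced twice, gene 2 orphaned: spanning-tree violation
  dbl <- gf_validate(gf_chromosome(c("Plus_s", "x", "x"),
                                   c("1.1", "0.1", "0.2")))
  expect_false(dbl$ok)
  expect_true(any(grepl("referenced", dbl$violations)))
  expect_true(any(grepl("unreachable", dbl$violations)))

  rep2 <- gf_validate(gf_chromosome(c("Plus_s", "x", "x"),
                                    c("5.6", "0.1", "0.2")))
  expect_false(rep2$ok)
  expect_true(any(grepl("out-of-range", rep2$violations)))

  expect_true(gf_validate(gf_published_kernel("prostate"))$ok)
  expect_true(gf_validate(gf_published_kernel("breast"))$ok)
})

test_that("encode emits level order and round-trips through decode", {
  # the worked example re-encodes to the same symbol string and an
  # equivalent fold list (identical tree on re-decoding)
  syms <- c("Minus_s", "Plus_s", "y", "y", "x")
  folds <- c("1.2", "3.4", "0.2", "0.3", "0.4")
  enc <- gf_encode(gf_decode(syms, folds))
  expect_equal(enc$symbols, syms)
  expect_equal(gf_format_expr(gf_decode(enc)),
               gf_format_expr(gf_decode(syms, folds)))

  leaf <- gf_encode(gf_decode("x", "0.0"))
  expect_equal(leaf$symbols, "x")
  expect_equal(paste0(leaf$left, ".", leaf$right), "0.0")
})

test_that("encode/decode are mutual identities on random chromosomes", {
  for (s in 1:200) {
    ch <- gf_random_chromosome(head_length = 1 + s %% 6, gene_cap = 40,
                               seed = 1000 + s)
    e1 <- gf_decode(ch)
    ch2 <- gf_encode(e1)
    expect_true(gf_validate(ch2)$ok)
    expect_identical(gf_format_expr(gf_decode(ch2)), gf_format_expr(e1))
  }
})

test_that("random chromosomes are valid, capped and head-respecting", {
  for (s in 1:1000) {
    ch <- gf_random_chromosome(head_length = 1 + s %% 8, seed = s)
    expect_true(gf_validate(ch)$ok)
    expect_lte(length(ch$symbols), 50)
  }
  # head composition: first head_length genes are operators
  ch <- gf_random_chromosome(head_length = 5, seed = 11)
  expect_true(all(ch$symbols[1:5] %in%
                    c("Plus_s", "Minus_s", "Multi_s", "Plus_v", "Minus_v")))
  # minimal head: one operator closes with two terminals unless it grows
  ch1 <- gf_random_chromosome(head_length = 1, gene_cap = 3, seed = 2)
  expect_equal(length(ch1$symbols), 3L)
  # determinism
  expect_identical(gf_random_chromosome(seed = 99),
                   gf_random_chromosome(seed = 99))
  # impossible configuration
  expect_error(gf_random_chromosome(head_length = 10, gene_cap = 12),
               class = "gf_generation_error")
})

test_that("chromosomes serialize through the bracketed dialect and JSON", {
  pro <- gf_published_kernel("prostate")
  txt <- tempfile(fileext = ".txt")
  gf_write_chromosome(pro, txt)
  back <- gf_read_chromosome(txt)
  expect_identical(back$symbols, pro$symbols)
  expect_identical(paste0(back$left, ".", back$right),
                   paste0(pro$left, ".", pro$right))
  # the serialized lines use the printed dialect byte-for-byte
  lines <- readLines(txt)
  expect_match(lines[1], "^\\['Plus_s', 'Multi_s'")
  expect_match(lines[2], "^\\['1\\.2', '3\\.4', '5\\.6'")

  js <- tempfile(fileext = ".json")
  gf_write_chromosome(pro, js, json = TRUE, fitness = 0.96,
                      dataset = "prostate", seed = 1)
  back2 <- gf_read_chromosome(js)
  expect_identical(back2$symbols, pro$symbols)
})
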