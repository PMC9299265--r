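test_that("a minimal two-point problem is separated with both points as SVs", {
  X <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)
  K <- tcrossprod(X)
  fit <- gf_svm_train(K, c(1, -1), C = 100)
  expect_setequal(fit$sv_index, c(1, 2))
  p <- gf_svm_predict(fit, K)
  expect_equal(p$labels, c(1, -1))
  expect_true(p$scores[1] > 0 && p$scores[2] < 0)
})

test_that("separable data is fit perfectly and matches a feature-space oracle", {
  set.seed(1)
  X <- rbind(matrix(rnorm(40, mean = 2), 20, 2),
             matrix(rnorm(40, mean = -2), 20, 2))
  y <- rep(c(1, -1), each = 20)
  fit <- gf_svm_train(tcrossprod(X), y, C = 1)
  p <- gf_svm_predict(fit, tcrossprod(X))
  expect_equal(mean(p$labels == y), 1)

  # independent oracle: e1071's linear SVM on the raw features
  or <- e1071::svm(X, factor(y), kernel = "linear", cost = 1, scale = FALSE)
  expect_equal(as.numeric(as.character(predict(or, X))), p$labels)
})

test_that("stored duals reconstruct the delegated solver's decision values", {
  set.seed(2)
  for (rep in 1:5) {
    X <- rbind(matrix(rnorm(30, mean = 1.5), 15, 2),
               matrix(rnorm(30, mean = -1.5), 15, 2))
    y <- rep(c(1, -1), each = 15)
    K <- tcrossprod(X)
    fit <- gf_svm_train(K, y, C = 1)
    yf <- factor(ifelse(y > 0, "1", "-1"), levels = c("-1", "1"))
    ref <- kernlab::ksvm(kernlab::as.kernelMatrix(K), yf, type = "C-svc",
                         C = 1, kernel = "matrix")
    dec <- kernlab::predict(
      ref, kernlab::as.kernelMatrix(K[, kernlab::SVindex(ref), drop = FALSE]),
      type = "decision")
    mine <- gf_svm_predict(fit, K)$scores
    expect_lt(max(abs(mine - as.vector(dec))), 1e-8)
  }
})

test_that("doubling the Gram with halved cost leaves decision signs unchanged", {
  set.seed(3)
  X <- rbind(matrix(rnorm(40, 1.5), 20, 2), matrix(rnorm(40, -1.5), 20, 2))
  y <- rep(c(1, -1), each = 20)
  K <- tcrossprod(X)
  p1 <- gf_svm_predict(gf_svm_train(K, y, C = 1), K)
  p2 <- gf_svm_predict(gf_svm_train(2 * K, y, C = 0.5), 2 * K)
  expect_equal(p1$labels, p2$labels)
})

test_that("predictions are invariant to permuting the training rows", {
  set.seed(4)
  X <- rbind(matrix(rnorm(30, 2), 15, 2), matrix(rnorm(30, -2), 15, 2))
  y <- rep(c(1, -1), each = 15)
  Xte <- matrix(rnorm(20), 10, 2)
  fit <- gf_svm_train(tcrossprod(X), y, C = 1)
  p <- gf_svm_predict(fit, tcrossprod(Xte, X))
  perm <- sample(30)
  fitp <- gf_svm_train(tcrossprod(X[perm, ]), y[perm], C = 1)
  pp <- gf_svm_predict(fitp, tcrossprod(Xte, X[perm, ]))
  expect_equal(p$labels, pp$labels)
  # scores agree up to the SMO solver's convergence tolerance
  expect_equal(p$scores, pp$scores, tolerance = 1e-2)
})

test_that("degenerate inputs follow the stated conventions", {
  set.seed(5)
  X <- rbind(matrix(rnorm(20, 2), 10, 2), matrix(rnorm(20, -2), 10, 2))
  y <- rep(c(1, -1), each = 10)
  fit <- gf_svm_train(tcrossprod(X), y, C = 1)
  p0 <- gf_svm_predict(fit, matrix(0, 7, 20))
  expect_true(all(p0$scores == fit$bias))
  expect_true(all(p0$labels == ifelse(fit$bias >= 0, 1, -1)))
  # label always equals the sign of the emitted score (sign(0) -> +1)
  expect_equal(p0$labels, ifelse(p0$scores >= 0, 1, -1))

  expect_error(gf_svm_train(tcrossprod(X), rep(1, 20)),
               class = "gf_input_error")
  Kas <- tcrossprod(X); Kas[1, 2] <- Kas[1, 2] + 1
  expect_error(gf_svm_train(Kas, y), class = "gf_input_error")
  expect_error(gf_svm_predict(fit, matrix(0, 3, 19)),
               class = "gf_input_error")
})

test_that("more cost never increases the total training margin slack", {
  # the optimal total hinge slack sum(max(0, 1 - y f(x))) is non-increasing
  # in C; asserted over a moderate grid where the SMO solution is reliable
  set.seed(6)
  n <- 30
  X <- rbind(matrix(rnorm(n / 2, 0.7), n / 2, 1),
             matrix(rnorm(n / 2, -0.7), n / 2, 1))
  y <- rep(c(1, -1), each = n / 2)
  K <- tcrossprod(X)
  slack <- sapply(c(0.01, 0.05, 0.2, 1), function(C) {
    p <- gf_svm_predict(gf_svm_train(K, y, C = C), K)
    sum(pmax(0, 1 - y * p$scores))
  })
  expect_true(all(diff(slack) <= 1e-6))
})

test_that("models round-trip through JSON", {
  set.seed(7)
  X <- rbind(matrix(rnorm(20, 2), 10, 2), matrix(rnorm(20, -2), 10, 2))
  y <- rep(c(1, -1), each = 10)
  K <- tcrossprod(X)
  fit <- gf_svm_train(K, y, C = 1)
  path <- tempfile(fileext = ".json")
  gf_write_svm(fit, path, kernel_ref = "linear")
  back <- gf_read_svm(path)
  expect_equal(gf_svm_predict(back, K)$scores, gf_svm_predict(fit, K)$scores)
})

test_that("bagging reduces to a single model and votes sensibly", {
  t <- toy_table(n = 80, d = 4, separation = 6, seed = 9)
  lin <- gf_preset("linear")

  one <- gf_bagging_fit(t, lin, members = 1, seed = 1, bootstrap = FALSE)
  single <- gf_svm_train(gf_baseline_gram("linear", t$features), t$y)
  p_one <- gf_bagging_predict(one, t)
  p_single <- gf_svm_predict(single,
                             gf_baseline_gram("linear", t$features))
  expect_equal(p_one$labels, p_single$labels)

  # identical members (bootstrap disabled): vote equals member prediction
  same <- gf_bagging_fit(t, lin, members = 5, seed = 1, bootstrap = FALSE)
  p_same <- gf_bagging_predict(same, t)
  expect_equal(p_same$labels, p_single$labels)

  expect_error(gf_bagging_fit(t, lin, members = 4),
               class = "gf_config_error")
})

test_that("the bagged ensemble tracks its members' accuracy", {
  for (s in 1:5) {
    tr <- synth_dataset(80, 4, separation = 6, seed = 100 + s)
    te <- synth_dataset(60, 4, separation = 6, seed = 200 + s)
    ens <- gf_bagging_fit(tr, gf_preset("linear"), members = 5, seed = s)
    ens_acc <- mean(gf_bagging_predict(ens, te)$labels == te$y)
    member_acc <- sapply(seq_along(ens$models), function(i) {
      idx <- ens$indices[[i]]
      Kc <- gf_baseline_gram("linear", te$features,
                             tr$features[idx, , drop = FALSE])
      mean(gf_svm_predict(ens$models[[i]], Kc)$labels == te$y)
    })
    expect_gte(ens_acc, mean(member_acc) - 0.05)
  }
})

test_that("an evolved chromosome works as the bagging kernel", {
  t <- toy_table(n = 60, d = 4, separation = 6, seed = 12)
  mult <- gf_chromosome(c("Multi_s", "x", "y"), c("1.2", "0.1", "0.2"))
  ens <- gf_bagging_fit(t, mult, members = 3, seed = 2)
  p <- gf_bagging_predict(ens, t)
  expect_gte(mean(p$labels == t$y), 0.9)
})
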