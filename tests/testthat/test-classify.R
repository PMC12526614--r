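# LSTM cell mechanics, training, gradient correctness; SVM contract.

zero_params <- function(m, h) {
  p <- lstm_params(m, h)
  for (nm in names(p)[1:14]) p[[nm]] <- p[[nm]] * 0
  p
}

test_that("the zero-weight cell reproduces the hand-evaluated gate algebra", {
  p <- zero_params(2, 3)
  cvals <- c(0.4, -1.2, 2)
  st <- lstm_cell_step(c(0.5, -0.5),
                       list(H = matrix(0, 1, 3), C = matrix(cvals, 1, 3)),
                       p, cache = TRUE)
  # all gates sigma(0) = 0.5, input node tanh(0) = 0
  expect_equal(as.numeric(st$X), rep(0.5, 3))
  expect_equal(as.numeric(st$F_), rep(0.5, 3))
  expect_equal(as.numeric(st$Y), rep(0.5, 3))
  expect_equal(as.numeric(st$G), rep(0, 3))
  expect_equal(as.numeric(st$C), 0.5 * cvals)
  expect_equal(as.numeric(st$H), 0.5 * tanh(0.5 * cvals))
})

test_that("forced gates give exact memory retention and output suppression", {
  withr::with_seed(2, p <- lstm_params(2, 4))
  cprev <- matrix(rnorm(4), 1, 4)
  # forget gate -> 1, input gate -> 0: cell state is carried unchanged
  p$bf <- rep(1e3, 4); p$Wuf <- p$Wuf * 0; p$Whf <- p$Whf * 0
  p$bi <- rep(-1e3, 4); p$Wui <- p$Wui * 0; p$Whi <- p$Whi * 0
  st <- lstm_cell_step(c(1, -1), list(H = matrix(0, 1, 4), C = cprev), p)
  expect_equal(st$C, cprev)
  # output gate -> 0: the memory does not reach the rest of the layers
  p$bo <- rep(-1e3, 4); p$Wuo <- p$Wuo * 0; p$Who <- p$Who * 0
  st0 <- lstm_cell_step(c(1, -1), list(H = matrix(0, 1, 4), C = cprev), p)
  expect_equal(st0$H, matrix(0, 1, 4))
})

test_that("gate ranges hold across random parameters and inputs", {
  withr::with_seed(77, {
    for (rep_i in 1:200) {
      p <- lstm_params(3, 2)
      st <- lstm_cell_step(matrix(rnorm(6, sd = 3), 2, 3),
                           list(H = matrix(runif(4, -1, 1), 2, 2),
                                C = matrix(rnorm(4, sd = 2), 2, 2)),
                           p, cache = TRUE)
      expect_true(all(st$X > 0 & st$X < 1))
      expect_true(all(st$F_ > 0 & st$F_ < 1))
      expect_true(all(st$Y > 0 & st$Y < 1))
      expect_true(all(abs(st$G) < 1))
      expect_true(all(abs(st$H) < 1))
    }
  })
})

test_that("softmax outputs sum to one and the zero network scores 0.5", {
  withr::with_seed(4, {
    p <- lstm_params(5, 8)
    seqs <- matrix(rnorm(100), 20, 5)
  })
  fw <- lstm_forward(seqs, p)
  expect_equal(sum(fw$probs), 1)
  p0 <- zero_params(5, 8)
  expect_equal(lstm_forward(seqs, p0)$score, 0.5)
  expect_error(lstm_forward(matrix(0, 20, 3), p), "channels")
})

test_that("the unrolled forward pass equals step-by-step cell application", {
  withr::with_seed(9, {
    p <- lstm_params(4, 6)
    x <- matrix(rnorm(80), 20, 4)
  })
  state <- list(H = matrix(0, 1, 6), C = matrix(0, 1, 6))
  for (t in 1:20) state <- lstm_cell_step(x[t, ], state, p)
  logits <- as.numeric(state$H %*% p$Wfc + p$bfc)
  probs <- exp(logits - max(logits)); probs <- probs / sum(probs)
  fw <- lstm_forward(x, p)
  expect_equal(fw$logits, logits, tolerance = 1e-12)
  expect_equal(fw$score, probs[2], tolerance = 1e-12)
})

test_that("analytic BPTT gradients agree with numerical differentiation", {
  withr::with_seed(12, {
    p <- lstm_params(2, 2)
    x <- array(rnorm(3 * 6 * 2), c(3, 6, 2))
    y <- c(0L, 1L, 1L)
  })
  lg <- squatstab:::lstm_loss_grad(x, y, p)
  eps <- 1e-6
  for (nm in c("Wui", "Whf", "bo", "Wuc", "Wfc", "bfc")) {
    target <- p[[nm]]
    for (idx in seq_len(min(4, length(target)))) {
      pp <- p; pm <- p
      pp[[nm]][idx] <- pp[[nm]][idx] + eps
      pm[[nm]][idx] <- pm[[nm]][idx] - eps
      num <- (squatstab:::lstm_loss_grad(x, y, pp)$loss -
                squatstab:::lstm_loss_grad(x, y, pm)$loss) / (2 * eps)
      expect_equal(lg$grad[[nm]][idx], num, tolerance = 1e-5)
    }
  }
})

# Separable toy: class 1 iff channel 1's mean exceeds channel 2's.
toy_dataset <- function(n, seed) {
  withr::with_seed(seed, {
    x <- array(rnorm(n * 20 * 2, sd = 0.3), c(n, 20, 2))
    y <- rep(0:1, length.out = n)
    x[y == 1, , 1] <- x[y == 1, , 1] + 1
    x[y == 0, , 2] <- x[y == 0, , 2] + 1
  })
  list(x = x, y = y)
}

test_that("the LSTM learns a separable toy problem deterministically", {
  toy <- toy_dataset(200, 55)
  cfg <- train_config(hidden = 8L, epochs = 40L, batch = 32L, lr = 1e-2, seed = 5L)
  fit <- train_lstm(toy$x, cfg, labels = toy$y)
  pr <- predict(fit, toy$x)
  expect_gte(mean(pr$label == toy$y), 0.95)
  # smoothed loss trace decreases
  expect_lt(mean(utils::tail(fit$loss_trace, 10)),
            mean(utils::head(fit$loss_trace, 10)))
  fit2 <- train_lstm(toy$x, cfg, labels = toy$y)
  expect_identical(fit$loss_trace, fit2$loss_trace)
  expect_identical(fit$params, fit2$params)
  expect_error(train_lstm(toy$x, cfg, labels = rep(0L, 200)), "single-class")
})

test_that("prediction is a pointwise map and validates the feature set", {
  toy <- toy_dataset(60, 14)
  cfg <- train_config(hidden = 6L, epochs = 15L, batch = 32L, lr = 1e-2, seed = 3L)
  fit <- train_lstm(toy$x, cfg, labels = toy$y)
  pr <- predict(fit, toy$x)
  perm <- sample(60)
  pr_perm <- predict(fit, toy$x[perm, , , drop = FALSE])
  expect_equal(pr_perm$score, pr$score[perm])
  expect_error(predict(fit, toy$x[, , 1, drop = FALSE]), "feature-set mismatch")
})

blob_dataset <- function(n, seed) {
  withr::with_seed(seed, {
    x <- array(rnorm(n * 20 * 2, sd = 0.2), c(n, 20, 2))
    y <- rep(0:1, length.out = n)
    x[y == 1, , ] <- x[y == 1, , ] + 2
  })
  list(x = x, y = y)
}

test_that("the SVM separates Gaussian blobs within the KKT contract", {
  blobs <- blob_dataset(80, 91)
  cfg <- train_config(seed = 7L, svm_cost = 10)
  fit <- train_svm(blobs$x, cfg, labels = blobs$y)
  pr <- predict(fit, blobs$x)
  expect_equal(mean(pr$label == blobs$y), 1)
  expect_lte(fit$kkt_residual, 1e-3)
  expect_gte(fit$fit$tot.nSV, 1)
  expect_error(train_svm(blobs$x, cfg, labels = rep(1L, 80)), "single-class")
})

test_that("duplicating every training point leaves the decision function unchanged", {
  # separable data with no alpha at the box bound: duplication preserves the
  # primal optimum; fixed gamma and tight tolerance isolate the duality check
  blobs <- blob_dataset(40, 33)
  cfg <- train_config(seed = 7L, svm_cost = 10, svm_gamma = 0.02,
                      svm_tolerance = 1e-9)
  fit1 <- train_svm(blobs$x, cfg, labels = blobs$y)
  dup_idx <- rep(seq_len(40), 2)
  fit2 <- train_svm(blobs$x[dup_idx, , , drop = FALSE], cfg,
                    labels = blobs$y[dup_idx])
  probe <- blob_dataset(30, 99)
  f1 <- squatstab:::svm_decision(fit1, squatstab:::flatten_tensor(probe$x))
  f2 <- squatstab:::svm_decision(fit2, squatstab:::flatten_tensor(probe$x))
  expect_equal(f1, f2, tolerance = 1e-6)
})

test_that("svm training order does not change the decision function", {
  blobs <- blob_dataset(50, 17)
  cfg <- train_config(seed = 7L, svm_cost = 10, svm_gamma = 0.02,
                      svm_tolerance = 1e-9)
  perm <- withr::with_seed(1, sample(50))
  fit1 <- train_svm(blobs$x, cfg, labels = blobs$y)
  fit2 <- train_svm(blobs$x[perm, , , drop = FALSE], cfg, labels = blobs$y[perm])
  probe <- squatstab:::flatten_tensor(blob_dataset(20, 5)$x)
  expect_equal(squatstab:::svm_decision(fit1, probe),
               squatstab:::svm_decision(fit2, probe), tolerance = 1e-6)
})

test_that("the gamma -> 0 limit flattens the decision scores", {
  blobs <- blob_dataset(40, 3)
  cfg <- train_config(seed = 7L, svm_gamma = 1e-9)
  fit <- train_svm(blobs$x, cfg, labels = blobs$y)
  probe <- squatstab:::flatten_tensor(blob_dataset(30, 8)$x)
  f <- squatstab:::svm_decision(fit, probe)
  expect_lt(stats::sd(f), 1e-3)
})
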