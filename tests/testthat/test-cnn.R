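ns <- asNamespace("apneaband")

test_that("architecture bookkeeping fixes the flatten width", {
  # floor-halving 6000 ten times: 6000 -> ... -> 5, flatten 5 * 45 = 225
  full <- cnn_architecture()
  expect_equal(full$block_lengths,
               c(6000L, 3000L, 1500L, 750L, 375L, 187L, 93L, 46L, 23L,
                 11L, 5L))
  expect_equal(full$flatten_width, 225L)

  expect_error(cnn_architecture(input_len = 512, n_feature_blocks = 10),
               "at least 1024")
})

test_that("seeded builds are identical and softmax outputs are proper", {
  spec <- tiny_arch()
  m1 <- build_cnn(spec, seed = 7)
  m2 <- build_cnn(spec, seed = 7)
  expect_identical(m1$layers, m2$layers)
  m3 <- build_cnn(spec, seed = 8)
  expect_false(identical(m1$layers[[1]]$W, m3$layers[[1]]$W))

  set.seed(1)
  x <- matrix(rnorm(3 * spec$input_len), 3)
  p <- predict(m1, x)
  expect_equal(rowSums(p), rep(1, 3))
  expect_true(all(p >= 0))

  # shifting all logits by a constant leaves the probabilities unchanged
  fwd <- ns$cnn_forward(m1, x)
  p1 <- ns$softmax_probs(fwd$logits)
  p2 <- ns$softmax_probs(fwd$logits + 37.5)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  spec <- cnn_architecture(input_len = 32, n_feature_blocks = 2,
                           conv_channels = 3, kernel_len = 5,
                           n_fc_blocks = 1, fc_width = 4, dropout = 0)
  model <- build_cnn(spec, seed = 42)
  set.seed(2)
  X <- matrix(rnorm(4 * 32), 4, 32)
  y <- c(0L, 1L, 1L, 0L)
  fwd <- ns$cnn_forward(model, X, training = TRUE, keep_cache = TRUE)
  lg <- ns$cnn_loss_grad(fwd, y, 2)
  grads <- ns$cnn_backward(model, fwd, lg$dlogits)
  loss_at <- function(m) {
    f <- ns$cnn_forward(m, X, training = TRUE)
    ns$cnn_loss_grad(f, y, 2)$loss
  }
  eps <- 1e-5
  set.seed(3)
  for (i in seq_along(model$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      p <- model$layers[[i]][[nm]]
      for (j in sample(seq_along(p), min(6, length(p)))) {
        m_plus <- model
        m_plus$layers[[i]][[nm]][j] <- p[j] + eps
        m_minus <- model
        m_minus$layers[[i]][[nm]][j] <- p[j] - eps
        num <- (loss_at(m_plus) - loss_at(m_minus)) / (2 * eps)
        # absolute comparison: bias-into-batch-norm gradients are exactly 0
        expect_lt(abs(g[[nm]][j] - num), 1e-6)
      }
    }
  }
})

test_that("evaluation mode is deterministic, training mode stochastic", {
  spec <- tiny_arch()
  model <- build_cnn(spec, seed = 9)
  set.seed(4)
  x <- matrix(rnorm(5 * spec$input_len), 5)
  expect_identical(predict(model, x), predict(model, x))
  # dropout makes two training-mode passes differ
  set.seed(10)
  a <- ns$cnn_forward(model, x, training = TRUE)$logits
  b <- ns$cnn_forward(model, x, training = TRUE)$logits
  expect_false(identical(a, b))
})

test_that("training separates a frequency-coded class structure", {
  set.seed(17)
  len <- 512
  make <- function(n, seed) {
    set.seed(seed)
    y <- rep(c("N", "A"), length.out = n)
    x <- matrix(rnorm(n * len, sd = 0.5), n, len)
    tt <- (seq_len(len) - 1) / 100
    for (i in which(y == "A")) x[i, ] <- x[i, ] + 2 * sin(2 * pi * 30 * tt)
    list(x = x, y = y)
  }
  tr <- make(200, 18)
  te <- make(200, 19)
  spec <- cnn_architecture(input_len = len, n_feature_blocks = 3,
                           conv_channels = 8, kernel_len = 9,
                           n_fc_blocks = 1, fc_width = 16)
  cfg <- train_config(epochs = 5, repeats = 1, batch_size = 32, seed = 5)
  fit <- train_cnn(build_cnn(spec, seed = 5), tr$x, tr$y, te$x, te$y, cfg)
  expect_gte(fit$best$test_acc, 95)
  expect_equal(nrow(fit$history), 5L)
  expect_true(all(fit$history$test_acc >= 0 & fit$history$test_acc <= 100))
  expect_equal(fit$best$test_acc, max(fit$history$test_acc))

  # the kept weights reproduce the recorded best accuracy
  pred <- predict(fit$model, te$x, type = "label")
  expect_equal(100 * mean(pred == te$y), fit$best$test_acc)

  # permuted labels leave nothing to learn: accuracy within binomial noise
  set.seed(20)
  y_shuf <- sample(tr$y)
  fit0 <- train_cnn(build_cnn(spec, seed = 6), tr$x, y_shuf, te$x,
                    sample(te$y), cfg)
  # max over 5 epochs of a chance-level classifier on n = 200:
  # generous band around 50%
  expect_lt(fit0$best$test_acc, 65)
  expect_gt(fit0$best$test_acc, 35)

  expect_error(
    train_cnn(build_cnn(spec, seed = 7), tr$x, rep("N", 200), te$x, te$y,
              cfg),
    "single class"
  )
})

test_that("repeat-and-select returns the max over repeats reproducibly", {
  set.seed(23)
  len <- 128
  x_tr <- matrix(rnorm(60 * len), 60)
  y_tr <- rep(c("N", "A"), 30)
  x_te <- matrix(rnorm(40 * len), 40)
  y_te <- rep(c("N", "A"), 20)
  spec <- cnn_architecture(input_len = len, n_feature_blocks = 2,
                           conv_channels = 4, kernel_len = 5,
                           n_fc_blocks = 1, fc_width = 8)
  cfg <- train_config(epochs = 2, repeats = 3, batch_size = 16, seed = 11)
  fit_fn <- function(seed) {
    train_cnn(build_cnn(spec, seed = seed), x_tr, y_tr, x_te, y_te, cfg,
              seed = seed)
  }
  sel <- repeat_and_select(fit_fn, cfg)
  expect_equal(sel$best_acc, max(sel$runs$best_test_acc))
  expect_true(all(sel$best_acc >=
                    vapply(sel$fits, function(f)
                      f$history$test_acc[nrow(f$history)], numeric(1))))
  expect_equal(sel$runs$seed, 11:13)

  # a single repeat equals that run's max over epochs
  cfg1 <- train_config(epochs = 2, repeats = 1, batch_size = 16, seed = 11)
  sel1 <- repeat_and_select(fit_fn, cfg1)
  expect_equal(sel1$best_acc, max(sel1$fits[[1]]$history$test_acc))

  # rerun under the same master seed reproduces the selection exactly
  sel2 <- repeat_and_select(fit_fn, cfg)
  expect_identical(sel$runs, sel2$runs)
  expect_equal(sel$best_repeat, sel2$best_repeat)
  expect_equal(sel$best_epoch, sel2$best_epoch)
})

test_that("training on zero signal with balanced labels stays at chance", {
  len <- 128
  x <- matrix(0, 80, len)
  y <- rep(c("N", "A"), 40)
  spec <- cnn_architecture(input_len = len, n_feature_blocks = 2,
                           conv_channels = 4, kernel_len = 5,
                           n_fc_blocks = 1, fc_width = 8)
  cfg <- train_config(epochs = 3, repeats = 1, batch_size = 16, seed = 31)
  fit <- train_cnn(build_cnn(spec, seed = 31), x, y, x, y, cfg)
  expect_equal(fit$best$test_acc, 50)
})
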