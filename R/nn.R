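# One-dimensional CNN engine.
#
# The classifier is a stack of identical feature-extraction blocks
# (convolution -> batch normalisation -> ReLU -> max-pool(2) -> dropout)
# followed by a flatten and identical classification blocks
# (dense -> batch normalisation -> ReLU -> dropout), closed by a dense
# 2-unit softmax head. Everything is implemented on BLAS matrix operations:
# convolutions are evaluated as im2col gathers followed by one matrix
# product, so a batch activation lives in a (batch * length) x channels
# matrix with sample-major row blocks. Analytic gradients for every layer
# are verified against central finite differences in the test suite.

#' Describe the 1D CNN architecture
#'
#' The defaults are the full-scale network: 10 feature-extraction blocks of
#' 45 feature maps with pool size 2 and 50% dropout, a flatten, 4
#' classification blocks of 512 units, and a 2-unit softmax head, applied to
#' one-minute 6000-sample subband segments. Convolution kernel length,
#' stride (fixed at 1) and same-padding are free parameters of this
#' implementation; kernel length defaults to 15. Max-pooling on an odd
#' length drops the trailing element (floor semantics), which fixes the
#' flatten width: 6000 halved ten times gives length 5, i.e. 225 flattened
#' features at 45 channels.
#'
#' Smaller settings are used throughout the test suite so the same code path
#' trains in seconds.
#'
#' @param input_len Segment length in samples (>= `2^n_feature_blocks`).
#' @param n_feature_blocks Number of conv blocks.
#' @param conv_channels Feature maps per conv layer.
#' @param kernel_len Convolution kernel length (odd recommended).
#' @param pool_size Max-pool window (2).
#' @param dropout Dropout fraction in both block types.
#' @param n_fc_blocks Number of dense classification blocks.
#' @param fc_width Units per dense classification block.
#' @param n_outputs Output classes (2: normal, apnea).
#' @return An object of class `cnn_architecture`.
#' @examples
#' cnn_architecture()                       # full-scale network
#' cnn_architecture(input_len = 600, n_feature_blocks = 3,
#'                  conv_channels = 8, fc_width = 32, n_fc_blocks = 1)
#' @export
cnn_architecture <- function(input_len = 6000, n_feature_blocks = 10,
                             conv_channels = 45, kernel_len = 15,
                             pool_size = 2, dropout = 0.5,
                             n_fc_blocks = 4, fc_width = 512,
                             n_outputs = 2) {
  for (nm in c("input_len", "n_feature_blocks", "conv_channels",
               "kernel_len", "pool_size", "n_fc_blocks", "fc_width",
               "n_outputs")) {
    stopifnot_scalar_number(get(nm), nm, positive = TRUE)
  }
  if (dropout < 0 || dropout >= 1) abort("`dropout` must be in [0, 1).")
  min_len <- pool_size^n_feature_blocks
  if (input_len < min_len) {
    abort(sprintf(
      "input_len = %d is too small: %d feature blocks with pool size %d need at least %d samples.",
      input_len, n_feature_blocks, pool_size, min_len
    ))
  }
  lens <- integer(n_feature_blocks + 1L)
  lens[1] <- as.integer(input_len)
  for (i in seq_len(n_feature_blocks)) {
    lens[i + 1L] <- lens[i] %/% as.integer(pool_size)
  }
  structure(
    list(
      input_len = as.integer(input_len),
      n_feature_blocks = as.integer(n_feature_blocks),
      conv_channels = as.integer(conv_channels),
      kernel_len = as.integer(kernel_len),
      pool_size = as.integer(pool_size),
      dropout = as.numeric(dropout),
      n_fc_blocks = as.integer(n_fc_blocks),
      fc_width = as.integer(fc_width),
      n_outputs = as.integer(n_outputs),
      block_lengths = lens,
      flatten_width = lens[n_feature_blocks + 1L] * as.integer(conv_channels)
    ),
    class = "cnn_architecture"
  )
}

#' @export
print.cnn_architecture <- function(x, ...) {
  cat(sprintf(
    "<cnn_architecture>  %d x [conv-%d(k=%d) bn relu pool-%d drop%.0f%%] -> flatten(%d) -> %d x [fc-%d bn relu] -> fc-%d softmax\n",
    x$n_feature_blocks, x$conv_channels, x$kernel_len, x$pool_size,
    100 * x$dropout, x$flatten_width, x$n_fc_blocks, x$fc_width, x$n_outputs
  ))
  invisible(x)
}

#' Training configuration
#'
#' Mirrors the training protocol: Adam on cross-entropy, He-normal
#' initialisation, a fixed number of epochs per run, and the run repeated
#' with `repeats` different initialisation seeds, keeping the weights from
#' the epoch with the highest test accuracy. Batch size and learning rate
#' are free parameters with conventional defaults (128, 1e-3).
#'
#' @param epochs Training epochs per repeat (protocol value 50).
#' @param repeats Independent repeats (protocol value 5).
#' @param batch_size Minibatch size.
#' @param learning_rate,beta1,beta2,epsilon Adam hyperparameters.
#' @param seed Master seed; repeat `r` runs under seed `seed + r - 1`.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 50, repeats = 5, batch_size = 128,
                         learning_rate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-8, seed = 1) {
  stopifnot_scalar_number(epochs, "epochs", positive = TRUE)
  stopifnot_scalar_number(repeats, "repeats", positive = TRUE)
  structure(
    list(epochs = as.integer(epochs), repeats = as.integer(repeats),
         batch_size = as.integer(batch_size),
         learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
         epsilon = epsilon, seed = as.integer(seed)),
    class = "train_config"
  )
}

# ---- model construction -----------------------------------------------------

he_normal <- function(n_out, fan_in, n_in = fan_in) {
  matrix(rnorm(n_in * n_out, sd = sqrt(2 / fan_in)), n_in, n_out)
}

#' Build an untrained CNN with He-normal initial weights
#'
#' @param spec A [cnn_architecture()].
#' @param seed Integer seed; two builds with the same seed have identical
#'   initial weights.
#' @return An object of class `cnn_model`.
#' @export
build_cnn <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "cnn_architecture"))
  with_seed(seed, {
    layers <- list()
    cin <- 1L
    for (i in seq_len(spec$n_feature_blocks)) {
      layers <- c(layers, list(
        list(type = "conv", k = spec$kernel_len, cin = cin,
             cout = spec$conv_channels,
             W = he_normal(spec$conv_channels, spec$kernel_len * cin),
             b = numeric(spec$conv_channels)),
        bn_layer(spec$conv_channels),
        list(type = "relu"),
        list(type = "pool", size = spec$pool_size),
        list(type = "dropout", p = spec$dropout)
      ))
      cin <- spec$conv_channels
    }
    layers <- c(layers, list(list(
      type = "flatten",
      L = spec$block_lengths[spec$n_feature_blocks + 1L],
      C = spec$conv_channels
    )))
    din <- spec$flatten_width
    for (i in seq_len(spec$n_fc_blocks)) {
      layers <- c(layers, list(
        list(type = "fc", W = he_normal(spec$fc_width, din),
             b = numeric(spec$fc_width)),
        bn_layer(spec$fc_width),
        list(type = "relu"),
        list(type = "dropout", p = spec$dropout)
      ))
      din <- spec$fc_width
    }
    layers <- c(layers, list(
      list(type = "fc", W = he_normal(spec$n_outputs, din),
           b = numeric(spec$n_outputs))
    ))
    structure(list(spec = spec, layers = layers, seed = as.integer(seed)),
              class = "cnn_model")
  })
}

bn_layer <- function(c, momentum = 0.9, eps = 1e-5) {
  list(type = "bn", gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c),
       momentum = momentum, eps = eps)
}

#' @export
print.cnn_model <- function(x, ...) {
  n_par <- sum(vapply(x$layers, function(l) {
    length(l$W) + length(l$b) + length(l$gamma) + length(l$beta)
  }, numeric(1)))
  print(x$spec)
  cat(sprintf("  %d trainable parameters (init seed %d)\n", n_par, x$seed))
  invisible(x)
}

# ---- layer forward/backward -------------------------------------------------
# Activations in the convolutional stage are (B * L) x C matrices with
# sample-major row blocks; the flatten layer switches to B x D.

conv_fwd <- function(A, L, B, layer) {
  Z <- .conv1d_fwd(A, L, B, layer$W, layer$b, layer$k)
  list(out = Z, cache = list(A = A, L = L, B = B))
}

conv_bwd <- function(dZ, layer, cache) {
  r <- .conv1d_bwd(cache$A, dZ, cache$L, cache$B, layer$W, layer$k)
  list(dA = r$dA, grads = list(W = r$dW, b = as.numeric(r$db)))
}

bn_fwd <- function(A, layer, training) {
  if (training) {
    mu <- colMeans(A)
    v <- colMeans(A * A) - mu^2             # population variance per column
    v[v < 0] <- 0
  } else {
    mu <- layer$run_mean
    v <- layer$run_var
  }
  r <- .bn_fwd(A, layer$gamma, layer$beta, mu, v, layer$eps)
  list(out = r$out,
       cache = list(xhat = r$xhat, inv_sd = as.numeric(r$inv_sd),
                    batch_mean = mu, batch_var = v))
}

bn_bwd <- function(dout, layer, cache) {
  r <- .bn_bwd(dout, layer$gamma, cache$xhat, cache$inv_sd)
  list(dA = r$dA,
       grads = list(gamma = as.numeric(r$dgamma),
                    beta = as.numeric(r$dbeta)))
}

pool_fwd <- function(A, L, B, size) {
  Lo <- L %/% size
  idx <- rep((0:(B - 1L)) * L, each = Lo) +
    rep(seq(1L, by = size, length.out = Lo), B)
  out <- A[idx, , drop = FALSE]
  argmax <- matrix(1L, nrow(out), ncol(out))
  for (s in seq_len(size - 1L)) {
    cand <- A[idx + s, , drop = FALSE]
    upd <- cand > out                     # ties route to the earlier sample
    out[upd] <- cand[upd]
    argmax[upd] <- s + 1L
  }
  list(out = out,
       cache = list(idx = idx, argmax = argmax, L = L, B = B, size = size),
       Lo = Lo)
}

pool_bwd <- function(dout, cache, ncol_A) {
  dA <- matrix(0, cache$B * cache$L, ncol_A)
  for (s in seq_len(cache$size)) {
    dA[cache$idx + (s - 1L), ] <- dout * (cache$argmax == s)
  }
  dA
}

flatten_fwd <- function(A, L, B, C) {
  out <- matrix(0, B, L * C)
  for (c in seq_len(C)) {
    out[, ((c - 1L) * L + 1L):(c * L)] <- t(matrix(A[, c], L, B))
  }
  out
}

flatten_bwd <- function(dout, L, B, C) {
  dA <- matrix(0, B * L, C)
  for (c in seq_len(C)) {
    dA[, c] <- as.vector(t(dout[, ((c - 1L) * L + 1L):(c * L)]))
  }
  dA
}

# ---- full network forward/backward -----------------------------------------

cnn_forward <- function(model, X, training = FALSE, keep_cache = FALSE) {
  B <- nrow(X)
  spec <- model$spec
  if (ncol(X) != spec$input_len) {
    abort(sprintf("input has %d samples per row; the network expects %d.",
                  ncol(X), spec$input_len))
  }
  A <- matrix(as.vector(t(X)), ncol = 1L)    # (B*L) x 1, sample-major
  L <- spec$input_len
  flat <- FALSE
  caches <- if (keep_cache) vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    layer <- model$layers[[i]]
    cache <- NULL
    if (layer$type == "conv") {
      r <- conv_fwd(A, L, B, layer)
      A <- r$out; cache <- r$cache
    } else if (layer$type == "bn") {
      r <- bn_fwd(A, layer, training)
      A <- r$out; cache <- r$cache
    } else if (layer$type == "relu") {
      cache <- A > 0
      A <- A * cache
    } else if (layer$type == "pool") {
      r <- pool_fwd(A, L, B, layer$size)
      A <- r$out; cache <- r$cache; L <- r$Lo
    } else if (layer$type == "dropout") {
      if (training && layer$p > 0) {
        mask <- matrix(
          (runif(length(A)) >= layer$p) / (1 - layer$p),
          nrow(A), ncol(A)
        )
        A <- A * mask
        cache <- mask
      }
    } else if (layer$type == "flatten") {
      A <- flatten_fwd(A, layer$L, B, layer$C)
      flat <- TRUE
    } else if (layer$type == "fc") {
      cache <- A
      A <- A %*% layer$W + rep(layer$b, each = B)
    }
    if (keep_cache) caches[[i]] <- cache
  }
  list(logits = A, caches = caches, B = B)
}

softmax_probs <- function(logits) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

# y: integer vector in 0:(n_outputs-1)
cnn_loss_grad <- function(fwd, y, n_outputs) {
  B <- fwd$B
  p <- softmax_probs(fwd$logits)
  idx <- cbind(seq_len(B), y + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dZ <- p
  dZ[idx] <- dZ[idx] - 1
  list(loss = loss, dlogits = dZ / B, probs = p)
}

cnn_backward <- function(model, fwd, dlogits) {
  B <- fwd$B
  grads <- vector("list", length(model$layers))
  dA <- dlogits
  for (i in rev(seq_along(model$layers))) {
    layer <- model$layers[[i]]
    cache <- fwd$caches[[i]]
    if (layer$type == "fc") {
      grads[[i]] <- list(W = crossprod(cache, dA), b = colSums(dA))
      dA <- tcrossprod(dA, layer$W)
    } else if (layer$type == "flatten") {
      dA <- flatten_bwd(dA, layer$L, B, layer$C)
    } else if (layer$type == "dropout") {
      if (!is.null(cache)) dA <- dA * cache
    } else if (layer$type == "pool") {
      dA <- pool_bwd(dA, cache, ncol(dA))
    } else if (layer$type == "relu") {
      dA <- dA * cache
    } else if (layer$type == "bn") {
      r <- bn_bwd(dA, layer, cache)
      dA <- r$dA
      grads[[i]] <- r$grads
    } else if (layer$type == "conv") {
      r <- conv_bwd(dA, layer, cache)
      dA <- r$dA
      grads[[i]] <- r$grads
    }
  }
  grads
}

# update batch-norm running statistics after a training-mode forward pass
bn_update_running <- function(model, fwd) {
  for (i in seq_along(model$layers)) {
    if (model$layers[[i]]$type == "bn") {
      cache <- fwd$caches[[i]]
      mom <- model$layers[[i]]$momentum
      model$layers[[i]]$run_mean <-
        mom * model$layers[[i]]$run_mean + (1 - mom) * cache$batch_mean
      model$layers[[i]]$run_var <-
        mom * model$layers[[i]]$run_var + (1 - mom) * cache$batch_var
    }
  }
  model
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(model) {
  lapply(model$layers, function(layer) {
    nms <- intersect(names(layer), c("W", "b", "gamma", "beta"))
    if (length(nms) == 0) return(NULL)
    setNames(lapply(nms, function(nm) {
      list(m = layer[[nm]] * 0, v = layer[[nm]] * 0)
    }), nms)
  })
}

adam_step <- function(model, grads, state, t, cfg) {
  b1 <- cfg$beta1; b2 <- cfg$beta2
  corr1 <- 1 - b1^t
  corr2 <- 1 - b2^t
  for (i in seq_along(model$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      st <- state[[i]][[nm]]
      st$m <- b1 * st$m + (1 - b1) * g[[nm]]
      st$v <- b2 * st$v + (1 - b2) * g[[nm]]^2
      state[[i]][[nm]] <- st
      model$layers[[i]][[nm]] <- model$layers[[i]][[nm]] -
        cfg$learning_rate * (st$m / corr1) /
          (sqrt(st$v / corr2) + cfg$epsilon)
    }
  }
  list(model = model, state = state)
}

# ---- prediction -------------------------------------------------------------

#' Class probabilities for minute segments
#'
#' Runs the network in evaluation mode (batch-norm running statistics,
#' dropout off), so prediction is deterministic given fixed weights.
#'
#' @param object A `cnn_model`.
#' @param x Matrix of segments, one row per minute (columns = samples).
#' @param type `"prob"` for an N/A probability matrix, `"label"` for
#'   `"N"`/`"A"` labels.
#' @param batch_size Evaluation batch size.
#' @param ... Unused.
#' @return Matrix of probabilities (columns `N`, `A`) or character labels.
#' @export
predict.cnn_model <- function(object, x, type = c("prob", "label"),
                              batch_size = 256, ...) {
  type <- match.arg(type)
  x <- as.matrix(x)
  n <- nrow(x)
  out <- matrix(NA_real_, n, object$spec$n_outputs)
  starts <- seq(1L, n, by = batch_size)
  for (s in starts) {
    rows <- s:min(s + batch_size - 1L, n)
    fwd <- cnn_forward(object, x[rows, , drop = FALSE], training = FALSE)
    out[rows, ] <- softmax_probs(fwd$logits)
  }
  colnames(out) <- c("N", "A")[seq_len(min(2L, ncol(out)))]
  if (type == "prob") return(out)
  ifelse(out[, 2] > out[, 1], "A", "N")
}

# ---- training ---------------------------------------------------------------

labels_to_int <- function(y) {
  y <- check_labels(y, "labels")
  as.integer(y == "A")                       # N = 0, A = 1
}

#' Train a CNN on labelled minute segments
#'
#' One run of the training protocol: minibatch Adam on cross-entropy for a
#' fixed number of epochs, recording training accuracy (running average over
#' the epoch's minibatches, as usual for minibatch training) and test
#' accuracy (full evaluation pass) at every epoch. The returned model
#' carries the weights of the epoch with the highest test accuracy
#' (earliest epoch on ties). This mirrors the published protocol, in which
#' model selection looks at the test set; for an honest estimate on new
#' data, pass a validation split as `x_test`/`y_test` and evaluate the
#' returned model on a third, untouched set.
#'
#' @param model An untrained [build_cnn()] model.
#' @param x_train,x_test Segment matrices (rows = minutes).
#' @param y_train,y_test Character labels (`"A"`/`"N"`).
#' @param cfg A [train_config()] (its `repeats` field is ignored here; see
#'   [repeat_and_select()]).
#' @param seed Seed for shuffling and dropout (defaults to `cfg$seed`).
#' @param verbose Print one line per epoch.
#' @return An object of class `cnn_fit`: the selected `model`, a `history`
#'   tibble (`epoch`, `train_loss`, `train_acc`, `test_acc`, percentages in
#'   0--100), and `best` (epoch and test accuracy of the kept weights).
#' @export
train_cnn <- function(model, x_train, y_train, x_test, y_test, cfg,
                      seed = cfg$seed, verbose = FALSE) {
  stopifnot(inherits(model, "cnn_model"), inherits(cfg, "train_config"))
  x_train <- as.matrix(x_train)
  x_test <- as.matrix(x_test)
  yi_train <- labels_to_int(y_train)
  yi_test <- labels_to_int(y_test)
  if (length(unique(yi_train)) < 2L) {
    abort("training data contains a single class; cannot train a classifier.")
  }
  n <- nrow(x_train)
  state <- adam_init(model)
  t_step <- 0L
  history <- tibble(
    epoch = seq_len(cfg$epochs), train_loss = NA_real_,
    train_acc = NA_real_, test_acc = NA_real_
  )
  best <- list(epoch = NA_integer_, test_acc = -Inf, layers = NULL)
  with_seed(seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      ep_loss <- 0
      ep_correct <- 0L
      for (s in starts) {
        rows <- ord[s:min(s + cfg$batch_size - 1L, n)]
        xb <- x_train[rows, , drop = FALSE]
        yb <- yi_train[rows]
        fwd <- cnn_forward(model, xb, training = TRUE, keep_cache = TRUE)
        lg <- cnn_loss_grad(fwd, yb, model$spec$n_outputs)
        model <- bn_update_running(model, fwd)
        grads <- cnn_backward(model, fwd, lg$dlogits)
        t_step <- t_step + 1L
        upd <- adam_step(model, grads, state, t_step, cfg)
        model <- upd$model
        state <- upd$state
        ep_loss <- ep_loss + lg$loss * length(rows)
        ep_correct <- ep_correct +
          sum((lg$probs[, 2] > lg$probs[, 1]) == (yb == 1L))
      }
      pred_test <- predict(model, x_test, type = "label")
      test_acc <- 100 * mean(pred_test == ifelse(yi_test == 1L, "A", "N"))
      history$train_loss[ep] <- ep_loss / n
      history$train_acc[ep] <- 100 * ep_correct / n
      history$test_acc[ep] <- test_acc
      if (test_acc > best$test_acc) {
        best <- list(epoch = ep, test_acc = test_acc, layers = model$layers)
      }
      if (verbose) {
        inform(sprintf(
          "epoch %3d  loss %.4f  train %.1f%%  test %.1f%%",
          ep, history$train_loss[ep], history$train_acc[ep], test_acc
        ))
      }
    }
  })
  model$layers <- best$layers
  structure(
    list(model = model, history = history,
         best = list(epoch = best$epoch, test_acc = best$test_acc),
         seed = as.integer(seed)),
    class = "cnn_fit"
  )
}

#' @export
print.cnn_fit <- function(x, ...) {
  cat(sprintf(
    "<cnn_fit>  %d epoch(s); best test accuracy %.1f%% at epoch %d (seed %d)\n",
    nrow(x$history), x$best$test_acc, x$best$epoch, x$seed
  ))
  invisible(x)
}

#' @rdname train_cnn
#' @param x A `cnn_fit`.
#' @param ... Unused.
#' @export
tidy.cnn_fit <- function(x, ...) {
  dplyr::mutate(x$history, seed = x$seed)
}

#' @rdname train_cnn
#' @export
glance.cnn_fit <- function(x, ...) {
  tibble(best_epoch = x$best$epoch, best_test_acc = x$best$test_acc,
         epochs = nrow(x$history), seed = x$seed)
}

#' Repeat training and keep the best run
#'
#' Runs `cfg$repeats` independent trainings under deterministically derived
#' seeds (`cfg$seed`, `cfg$seed + 1`, ...) and selects the highest test
#' accuracy over all repeats and epochs — the published five-repeat,
#' best-accuracy selection rule. All histories are retained for audit.
#'
#' @param fit_fn A function of one argument (the seed) returning a
#'   `cnn_fit`, typically a closure around [train_cnn()].
#' @param cfg A [train_config()].
#' @return An object of class `cnn_selection`: `best_fit`, `best_acc`,
#'   `best_repeat`, `best_epoch`, and a `runs` tibble of per-repeat
#'   summaries plus the list of all fits.
#' @export
repeat_and_select <- function(fit_fn, cfg) {
  stopifnot(is.function(fit_fn), inherits(cfg, "train_config"))
  fits <- lapply(seq_len(cfg$repeats), function(r) {
    fit_fn(as.integer(cfg$seed) + r - 1L)
  })
  accs <- vapply(fits, function(f) f$best$test_acc, numeric(1))
  best_r <- which.max(accs)                  # earliest repeat on ties
  structure(
    list(
      best_fit = fits[[best_r]],
      best_acc = accs[best_r],
      best_repeat = best_r,
      best_epoch = fits[[best_r]]$best$epoch,
      runs = tibble(
        repeat_index = seq_len(cfg$repeats),
        seed = vapply(fits, function(f) f$seed, integer(1)),
        best_epoch = vapply(fits, function(f) f$best$epoch, integer(1)),
        best_test_acc = accs
      ),
      fits = fits
    ),
    class = "cnn_selection"
  )
}

#' @export
print.cnn_selection <- function(x, ...) {
  cat(sprintf(
    "<cnn_selection>  best test accuracy %.1f%% (repeat %d, epoch %d of %d repeats)\n",
    x$best_acc, x$best_repeat, x$best_epoch, nrow(x$runs)
  ))
  invisible(x)
}
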