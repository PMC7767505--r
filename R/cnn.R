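# Binary promoter CNN: conv1d(ReLU) -> batchnorm -> avgpool -> dropout ->
# conv1d(ReLU) -> avgpool -> dropout -> flatten -> dense(ReLU) ->
# dense(1, sigmoid), trained with binary cross-entropy and SGD + momentum.
#
# Implemented directly on matrices: convolutions are im2col matrix products,
# so a batch of N one-hot sequences of length L is an (N*L) x (k*C) design
# matrix times a (k*C) x F filter matrix. Convolution padding is "same"
# (output length preserved); average pooling is unpadded with the trailing
# element dropped at odd lengths, so 81 -> 40 -> 20 positions.

#' CNN architecture configuration
#'
#' Defaults are the production architecture: 32 filters of kernel size 7,
#' then 32 filters of kernel size 5, average pooling of size 2 with stride 2
#' after each convolution, dropout of 0.35 and 0.30, a 16-neuron ReLU dense
#' layer and a single sigmoid output neuron, with L2 regularization on the
#' convolutional and dense weights and batch normalization after the first
#' convolution only.
#'
#' @param conv1_filters,conv2_filters filter counts of the two convolutions.
#' @param conv1_kernel,conv2_kernel odd kernel sizes.
#' @param pool_size,pool_stride average-pooling window and stride.
#' @param dropout1,dropout2 dropout rates in \[0,1) after each pooling.
#' @param dense1_units neurons of the penultimate dense layer.
#' @param l2_lambda L2 penalty weight on conv/dense weight matrices.
#' @param use_batchnorm_after_conv1 apply batch normalization after conv1.
#' @param batchnorm_before_relu if TRUE use conv -> BN -> ReLU instead of
#'   the default conv -> ReLU -> BN ordering.
#' @return object of class `arch_config`.
#' @export
arch_config <- function(conv1_filters = 32L, conv1_kernel = 7L,
                        conv2_filters = 32L, conv2_kernel = 5L,
                        pool_size = 2L, pool_stride = 2L,
                        dropout1 = 0.35, dropout2 = 0.30,
                        dense1_units = 16L, l2_lambda = 1e-3,
                        use_batchnorm_after_conv1 = TRUE,
                        batchnorm_before_relu = FALSE) {
  stopifnot(
    conv1_kernel >= 1, conv1_kernel %% 2 == 1,
    conv2_kernel >= 1, conv2_kernel %% 2 == 1,
    conv1_filters >= 1, conv2_filters >= 1,
    pool_size >= 1, pool_stride >= 1,
    dropout1 >= 0, dropout1 < 1, dropout2 >= 0, dropout2 < 1,
    dense1_units >= 1, l2_lambda >= 0
  )
  structure(list(
    conv1_filters = as.integer(conv1_filters),
    conv1_kernel = as.integer(conv1_kernel),
    conv2_filters = as.integer(conv2_filters),
    conv2_kernel = as.integer(conv2_kernel),
    pool_size = as.integer(pool_size),
    pool_stride = as.integer(pool_stride),
    dropout1 = dropout1, dropout2 = dropout2,
    dense1_units = as.integer(dense1_units),
    l2_lambda = l2_lambda,
    use_batchnorm_after_conv1 = isTRUE(use_batchnorm_after_conv1),
    batchnorm_before_relu = isTRUE(batchnorm_before_relu)
  ), class = "arch_config")
}

#' Training configuration
#'
#' Defaults: stochastic gradient descent with learning rate 0.007 and
#' momentum 0.95, 50 epochs of mini-batches of 32, decision threshold 0.5.
#'
#' @param learning_rate positive SGD step size.
#' @param momentum classical momentum coefficient in \[0,1).
#' @param epochs,batch_size training schedule.
#' @param seed integer seed controlling weight initialization, shuffling
#'   and dropout.
#' @param decision_threshold probability cutoff in (0,1) for the positive
#'   call.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.007, momentum = 0.95,
                         epochs = 50L, batch_size = 32L, seed = 1L,
                         decision_threshold = 0.5) {
  stopifnot(learning_rate > 0, momentum >= 0, momentum < 1,
            epochs >= 1, batch_size >= 1,
            decision_threshold > 0, decision_threshold < 1)
  structure(list(
    learning_rate = learning_rate, momentum = momentum,
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    seed = as.integer(seed), decision_threshold = decision_threshold
  ), class = "train_config")
}

#' Rectified linear activation
#'
#' @param x numeric vector/matrix.
#' @return `max(0, x)` elementwise.
#' @export
relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Logistic sigmoid
#' @param x numeric vector/matrix.
#' @return `1 / (1 + exp(-x))` elementwise.
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Binary cross-entropy loss
#'
#' Mean negative log-likelihood over all examples (positives and negatives
#' together); probabilities are clipped away from 0 and 1 by `eps` before
#' the logarithms.
#'
#' @param probs predicted probabilities in (0,1).
#' @param labels 0/1 vector of the same length.
#' @param eps clipping epsilon.
#' @return non-negative scalar loss.
#' @export
binary_cross_entropy <- function(probs, labels, eps = 1e-7) {
  if (length(probs) != length(labels)) {
    stop("probs and labels must have equal length", call. = FALSE)
  }
  stopifnot(all(labels %in% c(0, 1)))
  p <- pmin(pmax(probs, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

# ---- layer shapes -----------------------------------------------------------

.pooled_length <- function(L, size, stride) {
  if (L < size) 0L else as.integer((L - size) %/% stride + 1L)
}

.cnn_shapes <- function(arch, input_length) {
  L1 <- as.integer(input_length)
  Lp1 <- .pooled_length(L1, arch$pool_size, arch$pool_stride)
  Lp2 <- .pooled_length(Lp1, arch$pool_size, arch$pool_stride)
  if (Lp2 < 1) stop("input too short for the pooling pipeline", call. = FALSE)
  list(L1 = L1, Lp1 = Lp1, Lp2 = Lp2, flat = Lp2 * arch$conv2_filters)
}

.layer_order <- function(arch) {
  act_bn <- if (arch$batchnorm_before_relu) c("batchnorm", "relu") else
    c("relu", "batchnorm")
  c("conv1",
    if (arch$use_batchnorm_after_conv1) act_bn else "relu",
    "avgpool", "dropout",
    "conv2", "relu", "avgpool", "dropout",
    "flatten", "dense1_relu", "dense2_sigmoid")
}

.init_params <- function(arch, input_length) {
  sh <- .cnn_shapes(arch, input_length)
  he <- function(nr, nc, fan_in) {
    matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
  }
  list(
    conv1_W = he(arch$conv1_kernel * 4L, arch$conv1_filters,
                 arch$conv1_kernel * 4L),
    conv1_b = numeric(arch$conv1_filters),
    bn_gamma = rep(1, arch$conv1_filters),
    bn_beta = numeric(arch$conv1_filters),
    bn_mean = numeric(arch$conv1_filters),
    bn_var = rep(1, arch$conv1_filters),
    conv2_W = he(arch$conv2_kernel * arch$conv1_filters, arch$conv2_filters,
                 arch$conv2_kernel * arch$conv1_filters),
    conv2_b = numeric(arch$conv2_filters),
    dense1_W = he(sh$flat, arch$dense1_units, sh$flat),
    dense1_b = numeric(arch$dense1_units),
    dense2_W = matrix(stats::rnorm(arch$dense1_units,
                                   sd = sqrt(1 / arch$dense1_units)),
                      arch$dense1_units, 1L),
    dense2_b = numeric(1L)
  )
}

#' Build an (untrained) binary promoter CNN
#'
#' Assembles the layer pipeline for one-hot inputs of a fixed length and
#' initializes weights from a seeded fan-in-scaled normal stream. The model
#' predicts immediately (sigmoid output in (0,1)) but is marked untrained
#' until [fit()] is called.
#'
#' @param arch an [arch_config()].
#' @param input_length sequence length the model accepts (81 for the
#'   benchmark window); must be at least the larger kernel size.
#' @param seed seed for weight initialization.
#' @param name stage name carried in reports.
#' @return object of class `promoter_cnn`.
#' @export
build_model <- function(arch = arch_config(), input_length = 81L,
                        seed = 1L, name = "binary") {
  stopifnot(inherits(arch, "arch_config"))
  if (input_length < max(arch$conv1_kernel, arch$conv2_kernel)) {
    stop("input_length must be at least the kernel size", call. = FALSE)
  }
  params <- .with_local_seed(seed, .init_params(arch, input_length))
  structure(list(
    arch = arch, input_length = as.integer(input_length),
    params = params, name = name, trained = FALSE,
    train = NULL, loss_trace = NULL,
    layers = .layer_order(arch)
  ), class = "promoter_cnn")
}

# Evaluate `expr` under set.seed(seed) and restore the caller's RNG state.
.with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Trainable parameter counts per layer
#'
#' @param model a `promoter_cnn`.
#' @return named integer vector of weight+bias counts (batch-norm counts its
#'   gamma/beta pair; running moments are not trainable).
#' @export
count_parameters <- function(model) {
  p <- model$params
  c(conv1 = length(p$conv1_W) + length(p$conv1_b),
    batchnorm = if (model$arch$use_batchnorm_after_conv1) {
      length(p$bn_gamma) + length(p$bn_beta)
    } else 0L,
    conv2 = length(p$conv2_W) + length(p$conv2_b),
    dense1 = length(p$dense1_W) + length(p$dense1_b),
    dense2 = length(p$dense2_W) + length(p$dense2_b))
}

# ---- primitive layers (batched; x is an array [N, L, C]) -------------------

.im2col <- function(x, k) {
  d <- dim(x); N <- d[1]; L <- d[2]; C <- d[3]
  p <- (k - 1L) %/% 2L
  xp <- array(0, c(N, L + 2L * p, C))
  xp[, p + seq_len(L), ] <- x
  xcol <- matrix(0, N * L, k * C)
  for (j in seq_len(k)) {
    xcol[, (j - 1L) * C + seq_len(C)] <-
      matrix(xp[, j:(j + L - 1L), , drop = FALSE], N * L, C)
  }
  xcol
}

.col2im <- function(dxcol, N, L, C, k) {
  p <- (k - 1L) %/% 2L
  dxp <- array(0, c(N, L + 2L * p, C))
  for (j in seq_len(k)) {
    dxp[, j:(j + L - 1L), ] <- dxp[, j:(j + L - 1L), , drop = FALSE] +
      array(dxcol[, (j - 1L) * C + seq_len(C)], c(N, L, C))
  }
  dxp[, p + seq_len(L), , drop = FALSE]
}

.avgpool_fwd <- function(x, size, stride) {
  d <- dim(x); N <- d[1]; L <- d[2]; C <- d[3]
  Lo <- .pooled_length(L, size, stride)
  y <- array(0, c(N, Lo, C))
  for (j in seq_len(size)) {
    idx <- (seq_len(Lo) - 1L) * stride + j
    y <- y + x[, idx, , drop = FALSE]
  }
  y / size
}

.avgpool_bwd <- function(dy, L, size, stride) {
  d <- dim(dy); N <- d[1]; Lo <- d[2]; C <- d[3]
  dx <- array(0, c(N, L, C))
  for (j in seq_len(size)) {
    idx <- (seq_len(Lo) - 1L) * stride + j
    dx[, idx, ] <- dx[, idx, , drop = FALSE] + dy / size
  }
  dx
}

.bn_fwd <- function(xmat, p, training, eps = 1e-5, rho = 0.9) {
  if (training) {
    mu <- colMeans(xmat)
    v <- colMeans(xmat^2) - mu^2
    upd <- list(mean = rho * p$bn_mean + (1 - rho) * mu,
                var = rho * p$bn_var + (1 - rho) * v)
  } else {
    mu <- p$bn_mean; v <- p$bn_var; upd <- NULL
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(xmat, 2L, mu, "-")
  xhat <- sweep(xhat, 2L, inv, "*")
  y <- sweep(sweep(xhat, 2L, p$bn_gamma, "*"), 2L, p$bn_beta, "+")
  list(y = y, xhat = xhat, inv = inv, upd = upd)
}

.bn_bwd <- function(dy, cache, gamma) {
  m <- nrow(dy)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2L, gamma, "*")
  # dx = inv/m * (m*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
  t1 <- sweep(m * dxhat, 2L, colSums(dxhat), "-")
  t2 <- sweep(cache$xhat, 2L, colSums(dxhat * cache$xhat), "*")
  dx <- sweep(t1 - t2, 2L, cache$inv / m, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Full forward pass. x: [N, L, 4]. Returns probs and, when training, the
# caches needed for backprop (dropout masks drawn from the current RNG).
.cnn_forward <- function(model, x, training = FALSE) {
  a <- model$arch; p <- model$params
  d <- dim(x); N <- d[1]; L <- d[2]
  cache <- list(N = N)

  xcol1 <- .im2col(x, a$conv1_kernel)
  z1 <- sweep(xcol1 %*% p$conv1_W, 2L, p$conv1_b, "+")  # (N*L) x F1
  if (a$use_batchnorm_after_conv1 && a$batchnorm_before_relu) {
    bn <- .bn_fwd(z1, p, training)
    h1 <- relu(bn$y)
    cache$relu1_in <- bn$y
  } else if (a$use_batchnorm_after_conv1) {
    r1 <- relu(z1)
    bn <- .bn_fwd(r1, p, training)
    h1 <- bn$y
    cache$relu1_in <- z1
  } else {
    bn <- NULL
    h1 <- relu(z1)
    cache$relu1_in <- z1
  }
  h1a <- array(h1, c(N, L, a$conv1_filters))
  pool1 <- .avgpool_fwd(h1a, a$pool_size, a$pool_stride)
  Lp1 <- dim(pool1)[2]

  if (training && a$dropout1 > 0) {
    mask1 <- array(stats::runif(length(pool1)) >= a$dropout1, dim(pool1))
    drop1 <- pool1 * mask1 / (1 - a$dropout1)
  } else {
    mask1 <- NULL; drop1 <- pool1
  }

  xcol2 <- .im2col(drop1, a$conv2_kernel)
  z2 <- sweep(xcol2 %*% p$conv2_W, 2L, p$conv2_b, "+")  # (N*Lp1) x F2
  h2 <- relu(z2)
  h2a <- array(h2, c(N, Lp1, a$conv2_filters))
  pool2 <- .avgpool_fwd(h2a, a$pool_size, a$pool_stride)

  if (training && a$dropout2 > 0) {
    mask2 <- array(stats::runif(length(pool2)) >= a$dropout2, dim(pool2))
    drop2 <- pool2 * mask2 / (1 - a$dropout2)
  } else {
    mask2 <- NULL; drop2 <- pool2
  }

  flat <- matrix(drop2, N, length(drop2) / N)  # [N, Lp2*F2], column-major
  z3 <- sweep(flat %*% p$dense1_W, 2L, p$dense1_b, "+")
  h3 <- relu(z3)
  z4 <- as.vector(h3 %*% p$dense2_W) + p$dense2_b
  probs <- sigmoid(z4)

  if (!training) return(list(probs = probs))
  cache <- c(cache, list(
    x = x, xcol1 = xcol1, bn = bn, h1 = h1, L = L, Lp1 = Lp1,
    pool1 = pool1, mask1 = mask1, drop1 = drop1,
    xcol2 = xcol2, z2 = z2, pool2 = pool2, mask2 = mask2,
    flat = flat, z3 = z3, h3 = h3
  ))
  list(probs = probs, cache = cache)
}

# Backward pass from dL/dz4 (pre-sigmoid gradient). Returns gradient list
# matching the trainable parameter names, L2 included.
.cnn_backward <- function(model, cache, dz4) {
  a <- model$arch; p <- model$params; lam <- a$l2_lambda
  N <- cache$N
  g <- list()

  dz4 <- matrix(dz4, ncol = 1L)
  g$dense2_W <- crossprod(cache$h3, dz4) + 2 * lam * p$dense2_W
  g$dense2_b <- sum(dz4)
  dh3 <- dz4 %*% t(p$dense2_W)
  dz3 <- dh3 * (cache$z3 > 0)
  g$dense1_W <- crossprod(cache$flat, dz3) + 2 * lam * p$dense1_W
  g$dense1_b <- colSums(dz3)
  dflat <- dz3 %*% t(p$dense1_W)

  ddrop2 <- array(dflat, dim(cache$pool2))
  if (!is.null(cache$mask2)) {
    ddrop2 <- ddrop2 * cache$mask2 / (1 - a$dropout2)
  }
  dh2a <- .avgpool_bwd(ddrop2, cache$Lp1, a$pool_size, a$pool_stride)
  dz2 <- matrix(dh2a, N * cache$Lp1, a$conv2_filters) * (cache$z2 > 0)
  g$conv2_W <- crossprod(cache$xcol2, dz2) + 2 * lam * p$conv2_W
  g$conv2_b <- colSums(dz2)
  dxcol2 <- dz2 %*% t(p$conv2_W)
  ddrop1 <- .col2im(dxcol2, N, cache$Lp1, a$conv1_filters, a$conv2_kernel)
  if (!is.null(cache$mask1)) {
    ddrop1 <- ddrop1 * cache$mask1 / (1 - a$dropout1)
  }
  dh1a <- .avgpool_bwd(ddrop1, cache$L, a$pool_size, a$pool_stride)
  dh1 <- matrix(dh1a, N * cache$L, a$conv1_filters)

  if (a$use_batchnorm_after_conv1 && a$batchnorm_before_relu) {
    dbn_y <- dh1 * (cache$relu1_in > 0)
    bnb <- .bn_bwd(dbn_y, cache$bn, p$bn_gamma)
    dz1 <- bnb$dx
    g$bn_gamma <- bnb$dgamma; g$bn_beta <- bnb$dbeta
  } else if (a$use_batchnorm_after_conv1) {
    bnb <- .bn_bwd(dh1, cache$bn, p$bn_gamma)
    dz1 <- bnb$dx * (cache$relu1_in > 0)
    g$bn_gamma <- bnb$dgamma; g$bn_beta <- bnb$dbeta
  } else {
    dz1 <- dh1 * (cache$relu1_in > 0)
  }
  g$conv1_W <- crossprod(cache$xcol1, dz1) + 2 * lam * p$conv1_W
  g$conv1_b <- colSums(dz1)
  g
}

#' Train a binary promoter CNN
#'
#' Stochastic gradient descent with classical momentum on the binary
#' cross-entropy loss (plus the architecture's L2 penalty). Weights are
#' (re-)initialized from `train$seed` before the first epoch, and shuffling
#' and dropout draw from the same seeded stream, so a given (data, seed)
#' pair always yields identical final weights.
#'
#' @param model a `promoter_cnn` from [build_model()].
#' @param x encoded inputs: an array `[n, L, 4]` from [encode_batch()], or a
#'   character vector of sequences.
#' @param y binary labels (0 = negative, 1 = positive); both classes must
#'   be present.
#' @param train a [train_config()]; defaults to the model's stored config
#'   or [train_config()].
#' @param verbose print per-epoch loss.
#' @return the trained model, with `$loss_trace` holding mean training loss
#'   per epoch.
#' @export
fit <- function(model, x, y, train = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "promoter_cnn"), inherits(train, "train_config"))
  if (is.character(x)) x <- encode_batch(x)
  stopifnot(length(dim(x)) == 3, dim(x)[2] == model$input_length)
  y <- as.numeric(y)
  if (length(y) != dim(x)[1]) stop("x and y sizes differ", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("training data must contain both classes", call. = FALSE)
  }
  n <- dim(x)[1]
  .with_local_seed(train$seed, {
    model$params <- .init_params(model$arch, model$input_length)
    vel <- lapply(model$params, function(w) w * 0)
    trainable <- setdiff(names(model$params), c("bn_mean", "bn_var"))
    if (!model$arch$use_batchnorm_after_conv1) {
      trainable <- setdiff(trainable, c("bn_gamma", "bn_beta"))
    }
    loss_trace <- numeric(train$epochs)
    for (epoch in seq_len(train$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = train$batch_size)
      epoch_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + train$batch_size - 1L, n)]
        xb <- x[idx, , , drop = FALSE]
        yb <- y[idx]
        fw <- .cnn_forward(model, xb, training = TRUE)
        loss <- binary_cross_entropy(fw$probs, yb)
        if (!is.finite(loss)) {
          stop(sprintf("training diverged (non-finite loss) at epoch %d",
                       epoch), call. = FALSE)
        }
        epoch_loss <- epoch_loss + loss * length(idx)
        dz4 <- (fw$probs - yb) / length(yb)
        grads <- .cnn_backward(model, fw$cache, dz4)
        if (!is.null(fw$cache$bn$upd)) {
          model$params$bn_mean <- fw$cache$bn$upd$mean
          model$params$bn_var <- fw$cache$bn$upd$var
        }
        for (nm in trainable) {
          vel[[nm]] <- train$momentum * vel[[nm]] -
            train$learning_rate * grads[[nm]]
          model$params[[nm]] <- model$params[[nm]] + vel[[nm]]
        }
      }
      loss_trace[epoch] <- epoch_loss / n
      if (verbose) {
        message(sprintf("epoch %d/%d  loss %.4f", epoch, train$epochs,
                        loss_trace[epoch]))
      }
    }
    model$loss_trace <- loss_trace
  })
  model$train <- train
  model$trained <- TRUE
  model
}

#' Predict promoter probabilities
#'
#' Inference-mode forward pass: dropout disabled, batch normalization using
#' running moments, so predictions are deterministic and independent of how
#' inputs are batched.
#'
#' @param object a trained model (or any classifier implementing this
#'   generic, e.g. stubs used in cascade testing).
#' @param x encoded array `[n, L, 4]` or character vector of sequences.
#' @param ... unused.
#' @return numeric vector of probabilities in (0, 1), one per input.
#' @export
predict_proba <- function(object, x, ...) UseMethod("predict_proba")

#' @rdname predict_proba
#' @export
predict_proba.promoter_cnn <- function(object, x, ...) {
  if (is.character(x)) x <- encode_batch(x)
  stopifnot(length(dim(x)) == 3)
  if (dim(x)[2] != object$input_length) {
    stop(sprintf("input length %d does not match model length %d",
                 dim(x)[2], object$input_length), call. = FALSE)
  }
  .cnn_forward(object, x, training = FALSE)$probs
}

# ---- persistence ------------------------------------------------------------

#' Save / load a model bundle
#'
#' A bundle is a directory holding `manifest.json` (version, architecture
#' and training configs, stage name, input length) and `weights.rds` (the
#' numeric parameter state). `load_model()` verifies that the stored weight
#' shapes match the manifest's architecture and errors on mismatch or
#' corruption; a loaded model predicts identically to the saved one.
#'
#' @param model a `promoter_cnn`.
#' @param path bundle directory (created for save).
#' @return `save_model()`: `path` invisibly; `load_model()`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "promoter_cnn"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    format = "promcascade-model", version = 1L,
    name = model$name, input_length = model$input_length,
    trained = model$trained,
    arch = unclass(model$arch),
    train = if (!is.null(model$train)) unclass(model$train)
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  saveRDS(list(params = model$params, loss_trace = model$loss_trace),
          file.path(path, "weights.rds"))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  mf <- file.path(path, "manifest.json")
  wf <- file.path(path, "weights.rds")
  if (!file.exists(mf) || !file.exists(wf)) {
    stop("not a model bundle (missing manifest.json or weights.rds): ", path,
         call. = FALSE)
  }
  manifest <- tryCatch(jsonlite::read_json(mf, simplifyVector = TRUE),
                       error = function(e) stop("corrupt model manifest: ",
                                                conditionMessage(e),
                                                call. = FALSE))
  if (!identical(manifest$format, "promcascade-model")) {
    stop("not a promcascade model bundle: ", path, call. = FALSE)
  }
  blob <- tryCatch(readRDS(wf),
                   error = function(e) stop("corrupt weight blob: ",
                                            conditionMessage(e),
                                            call. = FALSE))
  arch <- do.call(arch_config, manifest$arch)
  model <- structure(list(
    arch = arch, input_length = as.integer(manifest$input_length),
    params = blob$params, name = manifest$name,
    trained = isTRUE(manifest$trained),
    train = if (!is.null(manifest$train)) do.call(train_config,
                                                  manifest$train),
    loss_trace = blob$loss_trace,
    layers = .layer_order(arch)
  ), class = "promoter_cnn")
  ref <- .with_local_seed(0L, .init_params(arch, model$input_length))
  for (nm in names(ref)) {
    got <- model$params[[nm]]
    if (is.null(got) || !identical(dim(ref[[nm]]), dim(got)) ||
        length(ref[[nm]]) != length(got)) {
      stop("weight blob does not match the manifest architecture (", nm, ")",
           call. = FALSE)
    }
  }
  model
}

#' @export
print.promoter_cnn <- function(x, ...) {
  cat(sprintf("<promoter_cnn '%s'> input %d nt, %s\n", x$name,
              x$input_length, if (x$trained) "trained" else "untrained"))
  cat("layers:", paste(x$layers, collapse = " -> "), "\n")
  cat("trainable parameters:", sum(count_parameters(x)), "\n")
  invisible(x)
}
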