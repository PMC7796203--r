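#' Restricted Boltzmann machine parameters
#'
#' Parameter set `theta = (W, a, b)` of a binary RBM: weights `W`
#' (`n_visible x n_hidden`), visible offsets `a`, hidden offsets `b`.
#' Weights are initialized from `Normal(0, 0.01)` and offsets at zero, the
#' usual small-weight starting point.
#'
#' @param n_visible,n_hidden Layer sizes (>= 1).
#' @param seed Optional seed for the weight initialization.
#' @param init_sd Standard deviation of the initial weights.
#' @return Object of class `rbm_params`.
#' @export
rbm_params <- function(n_visible, n_hidden, seed = NULL, init_sd = 0.01) {
  if (n_visible < 1L || n_hidden < 1L) stopf("layer sizes must be >= 1")
  draw <- function() matrix(stats::rnorm(n_visible * n_hidden, 0, init_sd),
                            n_visible, n_hidden)
  W <- if (is.null(seed)) draw() else with_seed(seed, draw())
  structure(list(W = W, a = numeric(n_visible), b = numeric(n_hidden)),
            class = "rbm_params")
}

check_rbm <- function(theta) {
  if (!is.list(theta) || !all(c("W", "a", "b") %in% names(theta)))
    stopf("theta must have fields W, a, b")
  if (length(theta$a) != nrow(theta$W) || length(theta$b) != ncol(theta$W))
    stopf("RBM shapes inconsistent: W is %dx%d, a has %d, b has %d",
          nrow(theta$W), ncol(theta$W), length(theta$a), length(theta$b))
  invisible(theta)
}

#' RBM energy
#'
#' The bilinear energy
#' `E(v, h) = -sum_i a_i v_i - sum_j b_j h_j - sum_ij w_ij v_i h_j`.
#'
#' @param v Visible vector (length `n_visible`).
#' @param h Hidden vector (length `n_hidden`).
#' @param theta An [rbm_params()].
#' @return Scalar energy.
#' @export
rbm_energy <- function(v, h, theta) {
  check_rbm(theta)
  if (length(v) != length(theta$a) || length(h) != length(theta$b))
    stopf("v/h lengths do not match theta")
  -sum(theta$a * v) - sum(theta$b * h) - as.numeric(v %*% theta$W %*% h)
}

# All binary state vectors of `n` units, as a 2^n x n matrix.
binary_states <- function(n) {
  g <- as.matrix(expand.grid(rep(list(0:1), n)))
  dimnames(g) <- NULL
  g[, rev(seq_len(n)), drop = FALSE]
}

#' Exact joint distribution of a small RBM
#'
#' Enumerates all `2^(n_visible + n_hidden)` states and returns the
#' Boltzmann joint `P(v, h) = exp(-E(v, h)) / Z` with the partition
#' function `Z` computed by full summation. Guarded to at most 16 total
#' units.
#'
#' @param theta An [rbm_params()].
#' @return List with `prob` (matrix `2^n_v x 2^n_h`), `v_states`,
#'   `h_states` (state matrices, row order matching `prob`), and `logZ`.
#' @export
rbm_joint_table <- function(theta) {
  check_rbm(theta)
  nv <- length(theta$a); nh <- length(theta$b)
  if (nv + nh > 16L)
    stopf("joint enumeration guarded to <= 16 total units (got %d)", nv + nh)
  V <- binary_states(nv)
  H <- binary_states(nh)
  negE <- outer(as.numeric(V %*% theta$a), as.numeric(H %*% theta$b), "+") +
    V %*% theta$W %*% t(H)
  mx <- max(negE)
  un <- exp(negE - mx)
  Z <- sum(un)
  list(prob = un / Z, v_states = V, h_states = H, logZ = log(Z) + mx)
}

#' Hidden activation probabilities
#'
#' `P(h_j = 1 | v) = sigmoid(b_j + sum_i w_ij v_i)`; the hidden units are
#' conditionally independent given the visible layer.
#'
#' @param v Visible vector.
#' @param theta An [rbm_params()].
#' @return Vector of probabilities in (0, 1), length `n_hidden`.
#' @export
p_h_given_v <- function(v, theta) {
  check_rbm(theta)
  if (length(v) != length(theta$a)) stopf("v has length %d, expected %d",
                                          length(v), length(theta$a))
  stats::plogis(theta$b + as.numeric(v %*% theta$W))
}

#' Visible activation probabilities
#'
#' `P(v_i = 1 | h) = sigmoid(a_i + sum_j w_ij h_j)`, the mirror of
#' [p_h_given_v()].
#'
#' @param h Hidden vector.
#' @param theta An [rbm_params()].
#' @return Vector of probabilities in (0, 1), length `n_visible`.
#' @export
p_v_given_h <- function(h, theta) {
  check_rbm(theta)
  if (length(h) != length(theta$b)) stopf("h has length %d, expected %d",
                                          length(h), length(theta$b))
  stats::plogis(theta$a + as.numeric(theta$W %*% h))
}

sigmoid_mat <- function(x) stats::plogis(x)

#' One contrastive-divergence parameter update
#'
#' CD-k on one mini-batch: hidden states are sampled binary from the data
#' activations, the reconstruction chain runs `cd_k` alternating Gibbs
#' steps with visible units kept as probabilities (reduces sampling
#' noise), and the parameters move along the difference between data and
#' reconstruction statistics scaled by `lr / batch_size`. Uses the current
#' RNG stream; seed the session (or wrap the call) for reproducibility.
#'
#' @param batch Matrix of visible rows, entries in `[0, 1]`.
#' @param theta An [rbm_params()].
#' @param lr Learning rate.
#' @param cd_k Number of Gibbs steps (>= 1).
#' @return Updated `rbm_params`.
#' @export
cd_update <- function(batch, theta, lr, cd_k = 1L) {
  check_rbm(theta)
  if (!is.matrix(batch)) batch <- matrix(batch, nrow = 1L)
  if (nrow(batch) == 0L) stopf("batch is empty")
  if (ncol(batch) != length(theta$a))
    stopf("batch has %d columns, expected %d", ncol(batch), length(theta$a))
  if (any(batch < 0 | batch > 1)) stopf("batch entries must lie in [0, 1]")
  if (cd_k < 1L) stopf("cd_k must be >= 1")
  n <- nrow(batch)
  ph0 <- sigmoid_mat(sweep(batch %*% theta$W, 2L, theta$b, "+"))
  h <- matrix(stats::runif(length(ph0)) < ph0, n, ncol(ph0)) * 1
  vk <- batch
  phk <- ph0
  for (step in seq_len(cd_k)) {
    vk <- sigmoid_mat(sweep(tcrossprod(h, theta$W), 2L, theta$a, "+"))
    phk <- sigmoid_mat(sweep(vk %*% theta$W, 2L, theta$b, "+"))
    if (step < cd_k)
      h <- matrix(stats::runif(length(phk)) < phk, n, ncol(phk)) * 1
  }
  theta$W <- theta$W + lr * (crossprod(batch, ph0) - crossprod(vk, phk)) / n
  theta$a <- theta$a + lr * colMeans(batch - vk)
  theta$b <- theta$b + lr * colMeans(ph0 - phk)
  theta
}

#' Train one RBM by contrastive divergence
#'
#' Mini-batch CD over several epochs with per-epoch shuffling. Returns the
#' trained parameters and the mean reconstruction cross-entropy per epoch
#' (a monitoring quantity, not the CD objective).
#'
#' @param data Matrix of visible rows in `[0, 1]`.
#' @param n_hidden Hidden layer size.
#' @param lr Learning rate.
#' @param epochs Number of passes over the data (0 returns the initialized,
#'   untrained parameters).
#' @param batch_size Mini-batch size.
#' @param cd_k Gibbs steps per update.
#' @param seed Seed for initialization, shuffling and sampling.
#' @return List with `theta` ([rbm_params()]) and `recon_ce` (numeric, one
#'   entry per epoch).
#' @export
rbm_train <- function(data, n_hidden, lr = 0.05, epochs = 30L,
                      batch_size = 20L, cd_k = 1L, seed = 1L) {
  if (!is.matrix(data) || nrow(data) == 0L) stopf("data must be a non-empty matrix")
  with_seed(seed, {
    theta <- rbm_params(ncol(data), n_hidden)
    recon <- numeric(epochs)
    n <- nrow(data)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = batch_size)
      for (s in starts) {
        rows <- ord[s:min(s + batch_size - 1L, n)]
        theta <- cd_update(data[rows, , drop = FALSE], theta, lr, cd_k)
      }
      recon[ep] <- rbm_reconstruction_ce(data, theta)
    }
    list(theta = theta, recon_ce = recon)
  })
}

#' Mean reconstruction cross-entropy of an RBM
#'
#' Deterministic one-step reconstruction (probabilities both ways) scored
#' by elementwise binary cross-entropy, averaged over rows; a standard
#' monitor of CD training progress.
#'
#' @param data Matrix of visible rows in `[0, 1]`.
#' @param theta An [rbm_params()].
#' @return Scalar mean cross-entropy (nats per visible unit).
#' @export
rbm_reconstruction_ce <- function(data, theta) {
  ph <- sigmoid_mat(sweep(data %*% theta$W, 2L, theta$b, "+"))
  pv <- sigmoid_mat(sweep(tcrossprod(ph, theta$W), 2L, theta$a, "+"))
  eps <- 1e-12
  -mean(data * log(pv + eps) + (1 - data) * log(1 - pv + eps))
}

#' Exact log-likelihood of visible data under a small RBM
#'
#' Computes `sum_v log P(v)` by enumerating the hidden layer analytically
#' (`log P(v) = a'v + sum_j log(1 + exp(b_j + (v'W)_j)) - log Z`) with
#' `log Z` from full enumeration. Guarded to 16 total units; used to
#' verify that contrastive divergence increases the data likelihood on toy
#' problems.
#'
#' @param data Matrix of binary visible rows.
#' @param theta An [rbm_params()].
#' @return Mean log-likelihood per row (nats).
#' @export
rbm_exact_loglik <- function(data, theta) {
  check_rbm(theta)
  logZ <- rbm_joint_table(theta)$logZ
  act <- sweep(data %*% theta$W, 2L, theta$b, "+")
  free <- as.numeric(data %*% theta$a) + rowSums(log1p(exp(act)))
  mean(free - logZ)
}

#' Training configuration for the deep belief network
#'
#' @param layer_sizes Hidden layer sizes, bottom to top. Default
#'   `c(300, 300, 300)`: three hidden layers of 300 units, the
#'   architecture at which the reference experiments peaked.
#' @param lr_pretrain,epochs_pretrain Contrastive-divergence learning rate
#'   and epochs per layer.
#' @param lr_finetune,epochs_finetune Gradient fine-tuning rate and epochs.
#'   The defaults (rate 2, 2000 epochs) suit the small entropy-feature
#'   tables this package produces: plain SGD through three sigmoid layers
#'   needs a large rate and many passes before the loss breaks away from
#'   the initial plateau.
#' @param batch_size Mini-batch size for both phases.
#' @param cd_k Gibbs steps for pretraining.
#' @param momentum,weight_decay Optional classical-momentum coefficient and
#'   L2 penalty for fine-tuning; both 0 (off) by default.
#' @param seed Master seed for all randomness (initialization, sampling,
#'   shuffling).
#' @return Object of class `train_config`.
#' @export
train_config <- function(layer_sizes = c(300L, 300L, 300L),
                         lr_pretrain = 0.1, epochs_pretrain = 40L,
                         lr_finetune = 2, epochs_finetune = 2000L,
                         batch_size = 20L, cd_k = 1L,
                         momentum = 0, weight_decay = 0, seed = 1L) {
  if (any(layer_sizes < 1L)) stopf("layer sizes must be >= 1")
  if (lr_pretrain <= 0 || lr_finetune <= 0) stopf("learning rates must be > 0")
  if (epochs_pretrain < 0L || epochs_finetune < 0L) stopf("epochs must be >= 0")
  if (cd_k < 1L) stopf("cd_k must be >= 1")
  if (momentum < 0 || momentum >= 1) stopf("momentum must lie in [0, 1)")
  if (weight_decay < 0) stopf("weight_decay must be >= 0")
  structure(list(layer_sizes = as.integer(layer_sizes),
                 lr_pretrain = lr_pretrain,
                 epochs_pretrain = as.integer(epochs_pretrain),
                 lr_finetune = lr_finetune,
                 epochs_finetune = as.integer(epochs_finetune),
                 batch_size = as.integer(batch_size), cd_k = as.integer(cd_k),
                 momentum = momentum, weight_decay = weight_decay,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Greedy layerwise pretraining
#'
#' Trains a stack of RBMs bottom-up: each layer is trained by contrastive
#' divergence on the activation probabilities propagated through the
#' layers below it.
#'
#' @param features Matrix of rows scaled to `[0, 1]`.
#' @param layer_sizes Hidden sizes, bottom to top.
#' @param cfg A [train_config()].
#' @return List of [rbm_params()], bottom to top.
#' @export
pretrain <- function(features, layer_sizes, cfg = train_config()) {
  if (!is.matrix(features)) features <- as.matrix(features)
  if (any(features < 0 | features > 1))
    stopf("pretraining features must be scaled to [0, 1]")
  if (any(layer_sizes < 1L)) stopf("layer sizes must be >= 1")
  input <- features
  stack <- vector("list", length(layer_sizes))
  for (k in seq_along(layer_sizes)) {
    fit <- rbm_train(input, layer_sizes[k], lr = cfg$lr_pretrain,
                     epochs = cfg$epochs_pretrain,
                     batch_size = cfg$batch_size, cd_k = cfg$cd_k,
                     seed = derive_seed(cfg$seed, 101L + k))
    stack[[k]] <- fit$theta
    input <- sigmoid_mat(sweep(input %*% fit$theta$W, 2L, fit$theta$b, "+"))
  }
  stack
}

# Min-max scaler fitted on training features; constant columns are
# flagged and mapped to 0.
fit_scaler <- function(features) {
  mn <- apply(features, 2L, min)
  mx <- apply(features, 2L, max)
  list(min = mn, max = mx, constant = mx - mn <= 0)
}

apply_scaler <- function(features, scaler) {
  rng <- scaler$max - scaler$min
  rng[scaler$constant] <- 1
  out <- sweep(sweep(features, 2L, scaler$min, "-"), 2L, rng, "/")
  out[, scaler$constant] <- 0
  pmin(pmax(out, 0), 1)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

dbn_forward <- function(model, x) {
  acts <- list(x)
  for (theta in model$rbm_stack)
    acts[[length(acts) + 1L]] <-
      sigmoid_mat(sweep(acts[[length(acts)]] %*% theta$W, 2L, theta$b, "+"))
  top <- acts[[length(acts)]]
  probs <- softmax_rows(sweep(top %*% model$softmax$W, 2L, model$softmax$b, "+"))
  list(acts = acts, probs = probs)
}

#' Supervised fine-tuning of a pretrained stack
#'
#' Adds a softmax output layer on top of the pretrained sigmoid layers and
#' trains the whole network by mini-batch gradient descent on the
#' cross-entropy loss, starting from the pretrained weights.
#'
#' @param stack List of [rbm_params()] from [pretrain()].
#' @param features Matrix of rows scaled to `[0, 1]` (same scaling as
#'   pretraining).
#' @param labels Integer class ids in `1..n_classes`.
#' @param cfg A [train_config()].
#' @param n_classes Number of classes (default `max(labels)`).
#' @param scaler Optional scaler to store in the model (see
#'   [dbn_train()] for the usual entry point that fits it).
#' @return Object of class `dbn_model`: `rbm_stack`, `softmax` (`W`, `b`),
#'   `input_scaler`, `n_classes`, `config`, `history` (per-epoch loss and
#'   training accuracy).
#' @export
finetune <- function(stack, features, labels, cfg = train_config(),
                     n_classes = NULL, scaler = NULL) {
  if (!is.matrix(features)) features <- as.matrix(features)
  labels <- as.integer(labels)
  if (anyNA(labels) || any(labels < 1L)) stopf("labels must be positive integers")
  n_classes <- n_classes %||% max(labels)
  if (any(labels > n_classes)) stopf("label outside 1..%d", n_classes)
  n_top <- ncol(stack[[length(stack)]]$W)
  model <- structure(
    list(rbm_stack = stack,
         softmax = with_seed(derive_seed(cfg$seed, 7L), list(
           W = matrix(stats::rnorm(n_top * n_classes, 0, 0.01), n_top, n_classes),
           b = numeric(n_classes))),
         input_scaler = scaler %||% list(min = rep(0, ncol(features)),
                                         max = rep(1, ncol(features)),
                                         constant = rep(FALSE, ncol(features))),
         n_classes = n_classes, config = cfg,
         history = NULL),
    class = "dbn_model")
  n <- nrow(features)
  Y <- matrix(0, n, n_classes)
  Y[cbind(seq_len(n), labels)] <- 1
  loss <- acc <- numeric(cfg$epochs_finetune)
  mom <- cfg$momentum %||% 0
  wd <- cfg$weight_decay %||% 0
  vel <- list(sW = 0, sb = 0,
              W = rep(list(0), length(stack)), b = rep(list(0), length(stack)))
  with_seed(derive_seed(cfg$seed, 11L), {
    for (ep in seq_len(cfg$epochs_finetune)) {
      ord <- sample.int(n)
      for (s in seq(1L, n, by = cfg$batch_size)) {
        rows <- ord[s:min(s + cfg$batch_size - 1L, n)]
        xb <- features[rows, , drop = FALSE]
        yb <- Y[rows, , drop = FALSE]
        fw <- dbn_forward(model, xb)
        nb <- length(rows)
        delta <- (fw$probs - yb) / nb # gradient at the softmax pre-activation
        gW_s <- crossprod(fw$acts[[length(fw$acts)]], delta)
        gb_s <- colSums(delta)
        back <- delta %*% t(model$softmax$W)
        L <- length(model$rbm_stack)
        gW <- vector("list", L); gb <- vector("list", L)
        for (k in L:1) {
          a_out <- fw$acts[[k + 1L]]
          back <- back * a_out * (1 - a_out)
          gW[[k]] <- crossprod(fw$acts[[k]], back)
          gb[[k]] <- colSums(back)
          if (k > 1L) back <- back %*% t(model$rbm_stack[[k]]$W)
        }
        vel$sW <- mom * vel$sW -
          cfg$lr_finetune * (gW_s + wd * model$softmax$W)
        vel$sb <- mom * vel$sb - cfg$lr_finetune * gb_s
        model$softmax$W <- model$softmax$W + vel$sW
        model$softmax$b <- model$softmax$b + vel$sb
        for (k in seq_len(L)) {
          vel$W[[k]] <- mom * vel$W[[k]] -
            cfg$lr_finetune * (gW[[k]] + wd * model$rbm_stack[[k]]$W)
          vel$b[[k]] <- mom * vel$b[[k]] - cfg$lr_finetune * gb[[k]]
          model$rbm_stack[[k]]$W <- model$rbm_stack[[k]]$W + vel$W[[k]]
          model$rbm_stack[[k]]$b <- model$rbm_stack[[k]]$b + vel$b[[k]]
        }
      }
      fw <- dbn_forward(model, features)
      loss[ep] <- -mean(log(pmax(fw$probs[cbind(seq_len(n), labels)], 1e-12)))
      acc[ep] <- mean(max.col(fw$probs, ties.method = "first") == labels)
    }
  })
  model$history <- data.frame(epoch = seq_len(cfg$epochs_finetune),
                              loss = loss, train_accuracy = acc)
  model
}

#' Train a DBN classifier on a feature table
#'
#' The usual entry point: fits the min-max scaler on the training
#' features, pretrains the RBM stack greedily, then fine-tunes the full
#' network with a softmax head.
#'
#' @param features Numeric matrix or data frame of raw (unscaled) feature
#'   rows.
#' @param labels Integer class ids in `1..n_classes`.
#' @param cfg A [train_config()].
#' @param n_classes Number of classes (default `max(labels)`).
#' @return A `dbn_model` (see [finetune()]).
#' @export
dbn_train <- function(features, labels, cfg = train_config(), n_classes = NULL) {
  features <- as.matrix(features)
  assert_finite(features, "features")
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stopf("training data contains a single class; need at least 2")
  scaler <- fit_scaler(features)
  scaled <- apply_scaler(features, scaler)
  stack <- pretrain(scaled, cfg$layer_sizes, cfg)
  finetune(stack, scaled, labels, cfg, n_classes = n_classes, scaler = scaler)
}

#' @export
print.dbn_model <- function(x, ...) {
  sizes <- c(nrow(x$rbm_stack[[1L]]$W),
             vapply(x$rbm_stack, function(t) ncol(t$W), integer(1)),
             x$n_classes)
  cat("<dbn_model>", paste(sizes, collapse = " -> "), "\n")
  if (!is.null(x$history) && nrow(x$history))
    cat(sprintf("  final training accuracy: %.4f\n",
                x$history$train_accuracy[nrow(x$history)]))
  invisible(x)
}

#' Predict gesture classes
#'
#' Applies the stored input scaler, propagates through the sigmoid layers
#' and softmax head, and returns class probabilities and hard labels
#' (argmax, lowest class index on ties).
#'
#' @param object A `dbn_model`.
#' @param newdata Matrix or data frame of raw feature rows with the
#'   model's input dimension.
#' @param ... Unused.
#' @return List with `prob` (rows summing to 1) and `class` (integer
#'   labels).
#' @export
predict.dbn_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nrow(object$rbm_stack[[1L]]$W))
    stopf("newdata has %d features, model expects %d",
          ncol(newdata), nrow(object$rbm_stack[[1L]]$W))
  x <- apply_scaler(newdata, object$input_scaler)
  probs <- dbn_forward(object, x)$probs
  list(prob = probs, class = max.col(probs, ties.method = "first"))
}

#' Save / load a DBN model
#'
#' Serializes all parameter arrays, the scaler, the class count and the
#' training configuration to JSON at full precision; `load_dbn()`
#' restores a bit-exact copy.
#'
#' @param model A `dbn_model`.
#' @param path Destination / source path.
#' @return `path` invisibly (save); the model (load).
#' @export
save_dbn <- function(model, path) {
  ser <- list(
    layer_sizes = vapply(model$rbm_stack, function(t) ncol(t$W), integer(1)),
    n_classes = model$n_classes,
    rbm_stack = lapply(model$rbm_stack, function(t)
      list(W = t$W, a = t$a, b = t$b)),
    softmax = list(W = model$softmax$W, b = model$softmax$b),
    input_scaler = model$input_scaler,
    config = unclass(model$config),
    history = if (is.null(model$history)) NULL else as.list(model$history))
  json <- jsonlite::toJSON(ser, digits = I(17), auto_unbox = TRUE,
                           matrix = "rowmajor")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname save_dbn
#' @export
load_dbn <- function(path) {
  if (!file.exists(path)) stopf("model file not found: %s", path)
  ser <- jsonlite::fromJSON(paste(readLines(path, warn = FALSE), collapse = "\n"),
                            simplifyVector = TRUE, simplifyDataFrame = FALSE)
  stack <- lapply(ser$rbm_stack, function(t) {
    structure(list(W = t$W, a = as.numeric(t$a), b = as.numeric(t$b)),
              class = "rbm_params")
  })
  cfg <- ser$config
  cfg$layer_sizes <- as.integer(cfg$layer_sizes)
  model <- structure(
    list(rbm_stack = stack,
         softmax = list(W = ser$softmax$W, b = as.numeric(ser$softmax$b)),
         input_scaler = list(min = as.numeric(ser$input_scaler$min),
                             max = as.numeric(ser$input_scaler$max),
                             constant = as.logical(ser$input_scaler$constant)),
         n_classes = as.integer(ser$n_classes),
         config = structure(cfg, class = "train_config"),
         history = if (is.null(ser$history)) NULL else
           as.data.frame(lapply(ser$history, unlist))),
    class = "dbn_model")
  model
}
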