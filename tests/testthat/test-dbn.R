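test_that("the energy function is the stated bilinear form", {
  nil <- rbm_params(2, 3)
  nil$W[] <- 0
  expect_equal(rbm_energy(c(1, 0), c(1, 1, 0), nil), 0)

  theta <- structure(list(W = matrix(c(1, 0), 2, 1), a = c(0.5, 0),
                          b = -0.2), class = "rbm_params")
  expect_equal(rbm_energy(c(1, 0), 1, theta), -1.3)

  set.seed(5)
  for (i in 1:20) {
    th <- random_small_rbm(3, 2)
    v <- sample(0:1, 3, replace = TRUE)
    h <- sample(0:1, 2, replace = TRUE)
    expect_equal(rbm_energy(v, h, th), rbm_energy_oracle(v, h, th),
                 tolerance = 1e-12)
  }
  expect_error(rbm_energy(c(1, 0, 1), 1, theta), "lengths")
})

test_that("the enumerated joint is normalized and uniform at theta = 0", {
  th <- rbm_params(3, 2)
  th$W[] <- 0
  tab <- rbm_joint_table(th)
  expect_equal(sum(tab$prob), 1, tolerance = 1e-12)
  expect_true(all(abs(tab$prob - 1 / 32) < 1e-12))
  expect_error(rbm_joint_table(rbm_params(10, 10)), "16 total units")
})

test_that("conditionals match the sigmoid formulas and the joint table", {
  th0 <- rbm_params(4, 3); th0$W[] <- 0
  expect_equal(p_h_given_v(rep(1, 4), th0), rep(0.5, 3))
  sat <- th0; sat$b <- rep(20, 3)
  expect_equal(p_h_given_v(rep(0, 4), sat), rep(1, 3), tolerance = 1e-8)
  expect_equal(p_v_given_h(rep(1, 3), th0), rep(0.5, 4))

  set.seed(6)
  for (i in 1:20) {
    th <- random_small_rbm(2, 2)
    v <- sample(0:1, 2, replace = TRUE)
    expect_equal(p_h_given_v(v, th), p_h_from_table(v, th), tolerance = 1e-10)
    # visible conditional via the transposed machine
    swap <- structure(list(W = t(th$W), a = th$b, b = th$a),
                      class = "rbm_params")
    h <- sample(0:1, 2, replace = TRUE)
    expect_equal(p_v_given_h(h, th), p_h_from_table(h, swap), tolerance = 1e-10)
  }
  expect_error(p_h_given_v(1:3, rbm_params(2, 2)), "length")
})

test_that("cd_update contracts: zero rate, determinism, input guards", {
  th <- rbm_params(4, 3, seed = 1)
  batch <- matrix(runif(20), 5, 4)
  set.seed(9); same1 <- cd_update(batch, th, lr = 0.1)
  set.seed(9); same2 <- cd_update(batch, th, lr = 0.1)
  expect_identical(same1, same2)
  set.seed(9); frozen <- cd_update(batch, th, lr = 0)
  expect_equal(frozen$W, th$W)
  expect_equal(frozen$a, th$a)
  expect_equal(frozen$b, th$b)
  expect_error(cd_update(batch[0, , drop = FALSE], th, 0.1), "empty")
  expect_error(cd_update(batch * 2, th, 0.1), "\\[0, 1\\]")
})

test_that("CD training reduces reconstruction cross-entropy on a toy set", {
  toy <- rbind(c(1, 1, 1, 0, 0, 0), c(0, 0, 0, 1, 1, 1),
               c(1, 0, 1, 0, 1, 0), c(0, 1, 0, 1, 0, 1))
  drops <- vapply(1:5, function(s) {
    fit <- rbm_train(toy, n_hidden = 6, lr = 0.2, epochs = 200,
                     batch_size = 4, seed = s)
    fit$recon_ce[1] - fit$recon_ce[200]
  }, numeric(1))
  expect_gte(sum(drops > 0), 4)
})

test_that("pretraining stacks layers with the architecture shapes", {
  x <- matrix(runif(240), 20, 12)
  cfg <- train_config(epochs_pretrain = 0L, seed = 2)
  stack <- pretrain(x, c(300, 300, 300), cfg)
  dims <- lapply(stack, function(t) dim(t$W))
  expect_equal(dims, list(c(12L, 300L), c(300L, 300L), c(300L, 300L)))
  # epochs = 0 returns initialized-but-untrained parameters
  expect_true(all(stack[[1]]$a == 0) && all(stack[[1]]$b == 0))
  expect_gt(stats::sd(stack[[1]]$W), 0)
  stack2 <- pretrain(x, c(300, 300, 300), cfg)
  expect_identical(stack, stack2)
  expect_error(pretrain(x * 3, c(10), cfg), "\\[0, 1\\]")
})

test_that("fine-tuning learns a separable toy problem and is reproducible", {
  set.seed(3)
  x <- rbind(matrix(runif(60, 0, 0.4), 15), matrix(runif(60, 0.6, 1), 15))
  y <- rep(1:2, each = 15)
  cfg <- train_config(layer_sizes = c(10, 10), epochs_pretrain = 5L,
                      epochs_finetune = 500L, lr_finetune = 1,
                      batch_size = 10L, seed = 4)
  stack <- pretrain(x, cfg$layer_sizes, cfg)
  m <- finetune(stack, x, y, cfg)
  expect_equal(m$history$train_accuracy[500], 1)
  m2 <- finetune(stack, x, y, cfg)
  expect_identical(m$softmax, m2$softmax)

  # momentum/weight decay engage without breaking learning
  cfgm <- train_config(layer_sizes = c(10, 10), epochs_pretrain = 5L,
                       epochs_finetune = 500L, lr_finetune = 0.5,
                       batch_size = 10L, momentum = 0.5,
                       weight_decay = 1e-4, seed = 4)
  mm <- finetune(pretrain(x, cfgm$layer_sizes, cfgm), x, y, cfgm)
  expect_equal(mm$history$train_accuracy[500], 1)
  expect_false(identical(mm$softmax$W, m$softmax$W))

  # epochs = 0: stack plus untrained softmax still predicts
  cfg0 <- train_config(layer_sizes = c(10, 10), epochs_pretrain = 0L,
                       epochs_finetune = 0L, seed = 4)
  m0 <- finetune(pretrain(x, cfg0$layer_sizes, cfg0), x, y, cfg0)
  p0 <- predict(m0, x)
  expect_equal(rowSums(p0$prob), rep(1, 30), tolerance = 1e-12)
  expect_error(finetune(stack, x, c(y[-1], 7), cfg, n_classes = 2), "label")
})

test_that("fine-tuning does not fall below a softmax-only baseline", {
  skip_if_not_installed("nnet")
  set.seed(11)
  centers <- matrix(runif(36), 3, 12)
  x <- do.call(rbind, lapply(1:3, function(k)
    matrix(rep(centers[k, ], 12), 12, byrow = TRUE) + rnorm(144, 0, 0.08)))
  x <- pmin(pmax(x, 0), 1)
  y <- rep(1:3, each = 12)
  cfg <- train_config(layer_sizes = c(30, 30), epochs_pretrain = 10L,
                      epochs_finetune = 800L, lr_finetune = 1,
                      batch_size = 12L, seed = 5)
  stack <- pretrain(x, cfg$layer_sizes, cfg)
  dbn <- finetune(stack, x, y, cfg)
  # baseline: multinomial logistic regression on the frozen top activations
  top <- x
  for (th in stack)
    top <- 1 / (1 + exp(-sweep(top %*% th$W, 2, th$b, "+")))
  base <- nnet::multinom(y ~ ., data = data.frame(top, y = factor(y)),
                         trace = FALSE, maxit = 500)
  base_acc <- mean(predict(base) == factor(y))
  expect_gte(dbn$history$train_accuracy[800], base_acc)
})

test_that("prediction is normalized with deterministic tie-breaking", {
  x <- matrix(runif(36), 3, 12)
  cfg <- train_config(layer_sizes = c(8), epochs_pretrain = 0L,
                      epochs_finetune = 0L, seed = 1)
  m <- finetune(pretrain(x, 8, cfg), x, c(1, 2, 3), cfg, n_classes = 9)
  p <- predict(m, x)
  expect_equal(dim(p$prob), c(3L, 9L))
  expect_equal(rowSums(p$prob), rep(1, 3), tolerance = 1e-12)
  # duplicated row predicts identically
  p2 <- predict(m, x[c(1, 1), ])
  expect_identical(p2$prob[1, ], p2$prob[2, ])
  # exact ties resolve to the lowest class index
  m$softmax$W[] <- 0; m$softmax$b[] <- 0
  expect_equal(predict(m, x)$class, rep(1L, 3))
  expect_error(predict(m, x[, 1:5]), "expects 12")
})

test_that("models serialize and reload bit-exactly", {
  set.seed(8)
  x <- matrix(runif(120), 10, 12)
  y <- rep(1:2, 5)
  cfg <- train_config(layer_sizes = c(7, 5), epochs_pretrain = 3L,
                      epochs_finetune = 20L, batch_size = 5L, seed = 6)
  m <- dbn_train(x, y, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  save_dbn(m, path)
  back <- load_dbn(path)
  expect_identical(lapply(back$rbm_stack, function(t) t$W),
                   lapply(m$rbm_stack, function(t) t$W))
  expect_identical(back$softmax$W, m$softmax$W)
  expect_identical(back$input_scaler$min, unname(m$input_scaler$min))
  expect_equal(predict(back, x)$prob, predict(m, x)$prob)
})

test_that("exact likelihood and training guards behave", {
  th <- random_small_rbm(4, 3)
  toy <- rbind(c(1, 0, 1, 0), c(0, 1, 0, 1))
  ll <- rbm_exact_loglik(toy, th)
  expect_true(is.finite(ll) && ll < 0)
  expect_error(dbn_train(matrix(runif(24), 2, 12), c(1, 1)), "single class")
})
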