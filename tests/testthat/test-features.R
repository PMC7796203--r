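test_that("singular values match hand and spectral oracles", {
  expect_equal(singular_values(diag(3)), c(1, 1, 1))
  expect_equal(singular_values(diag(c(3, 2, 1))), c(3, 2, 1))
  set.seed(4)
  for (i in 1:5) {
    a <- matrix(rnorm(20), 5, 4)
    d <- singular_values(a)
    expect_equal(sum(d^2), sum(a^2), tolerance = 1e-10)
    # eigenvalues of t(A) A as an independent route
    ev <- sqrt(pmax(eigen(crossprod(a), symmetric = TRUE)$values, 0))
    expect_equal(d, ev, tolerance = 1e-10)
  }
  expect_error(singular_values(matrix(c(1, NA), 1)), "non-finite")
})

test_that("partitioning is contiguous, exhaustive, remainder-leading", {
  m <- matrix(seq_len(40), 4, 10)
  b2 <- partition_blocks(m, 2, "time")
  expect_equal(vapply(b2, ncol, integer(1)), c(5L, 5L))
  b3 <- partition_blocks(m, 3, "time")
  expect_equal(vapply(b3, ncol, integer(1)), c(4L, 3L, 3L))
  expect_identical(do.call(cbind, b3), m)
  r3 <- partition_blocks(m, 3, "frequency")
  expect_equal(vapply(r3, nrow, integer(1)), c(2L, 1L, 1L))
  expect_identical(do.call(rbind, r3), m)
  expect_error(partition_blocks(m, 11, "time"), "exceeds")
})

test_that("multiscale spectrum has the documented shape and block values", {
  cfg <- partition_config()
  z <- multiscale_spectrum(matrix(0, 32, 64), cfg)
  expect_true(all(z$lambda_A == 0) && all(z$lambda_t == 0) &&
                all(z$lambda_f == 0))
  expect_length(z$lambda_t, 16L)
  expect_length(z$lambda_f, 16L)

  # study-scale TFM: 16 blocks per axis, 20 global singular values
  set.seed(8)
  big <- matrix(abs(rnorm(256 * 2000)), 256, 2000)
  sp <- multiscale_spectrum(big, partition_config(q = 16, p = 16, k_keep = 20))
  expect_length(sp$lambda_A, 20L)
  expect_length(sp$lambda_t, 16L)
  expect_length(sp$lambda_f, 16L)
  expect_true(!is.unsorted(rev(sp$lambda_A)))
  expect_lte(max(sp$lambda_t), sp$lambda_A[1] * (1 + 1e-12))
  expect_lte(max(sp$lambda_f), sp$lambda_A[1] * (1 + 1e-12))

  # block-diagonal oracle: time-block maxima equal per-block SVD maxima
  blocks <- lapply(1:4, function(i) matrix(rnorm(16), 4, 4) * i)
  bd <- do.call(cbind, blocks)
  sp2 <- multiscale_spectrum(bd, partition_config(q = 4, p = 1, k_keep = 4))
  expect_equal(sp2$lambda_t,
               vapply(blocks, function(b) max(svd(b)$d), numeric(1)),
               tolerance = 1e-10)

  expect_warning(multiscale_spectrum(matrix(rnorm(16 * 20), 16, 20),
                                     partition_config(k_keep = 50)),
                 "truncated")
})

test_that("permutation entropy follows its definition", {
  cfg <- pe_config(m = 3, tau = 1)
  expect_equal(permutation_entropy(1:10, cfg), 0)
  expect_equal(permutation_entropy(seq(10, 1), cfg), 0)
  expect_equal(permutation_entropy(rep(2, 8), cfg), 0) # stable ties

  # worked example: 5 windows, two patterns twice, one once
  h <- permutation_entropy(c(4, 7, 9, 10, 6, 11, 3), cfg)
  expect_equal(h, -(2 * 0.4 * log(0.4) + 0.2 * log(0.2)), tolerance = 1e-12)
  expect_equal(h, pe_oracle(c(4, 7, 9, 10, 6, 11, 3)), tolerance = 1e-12)

  expect_error(permutation_entropy(c(1, 2), cfg), "at least 3")
  expect_equal(permutation_entropy(c(1, 2, 1, 2, 1),
                                   pe_config(m = 2, tau = 1, normalize = TRUE)),
               1) # rank patterns equiprobable -> maximal normalized entropy
})

test_that("permutation entropy agrees with the enumeration oracle", {
  set.seed(12)
  for (i in 1:200) {
    n <- sample(8:40, 1)
    x <- if (i %% 3 == 0) sample(0:4, n, replace = TRUE) else rnorm(n)
    m <- sample(2:4, 1); tau <- sample(1:2, 1)
    if (n - (m - 1) * tau < 2) next
    expect_equal(permutation_entropy(x, pe_config(m = m, tau = tau)),
                 pe_oracle(x, m, tau), tolerance = 1e-12)
  }
})

test_that("permutation entropy is bounded and ordinally invariant", {
  set.seed(13)
  for (i in 1:100) {
    x <- rnorm(25)
    cfg <- pe_config(m = 3, tau = 1)
    h <- permutation_entropy(x, cfg)
    expect_gte(h, 0)
    expect_lte(h, log(6))
    # strictly increasing transforms leave ordinal patterns untouched
    expect_equal(permutation_entropy(exp(x), cfg), h)
    expect_equal(permutation_entropy(5 * x - 2, cfg), h)
    expect_equal(permutation_entropy(x^3, cfg), h)
  }
})

test_that("channel features are the entropy triple with its range contract", {
  f0 <- channel_features(matrix(0, 32, 64))
  expect_equal(unname(f0), c(0, 0, 0))
  set.seed(2)
  f <- channel_features(matrix(abs(rnorm(40 * 120)), 40, 120))
  expect_named(f, c("Et", "Ef", "EA"))
  expect_true(all(f >= 0 & f <= log(6)))
})

test_that("features are invariant to uniform signal scaling", {
  sig <- class_signature(center = 100, bandwidth = 60, n_channels = 1)
  rec <- synth_trial(sig, fs = 2000, duration = 0.25, seed = 4)
  cfg <- st_config(fs = 2000, fmax = 500)
  a1 <- tfm_modulus(stransform(rec$samples[, 1], cfg))
  a2 <- tfm_modulus(stransform(7.5 * rec$samples[, 1], cfg))
  expect_equal(channel_features(a1), channel_features(a2))
})

test_that("dataset_features builds the ordered 12-column table", {
  ds <- synth_dataset(trials_per_class = 2, duration = 0.1, seed = 3)
  fe <- dataset_features(ds)
  expect_equal(dim(fe), c(18L, 14L))
  expect_identical(names(fe)[1:5], c("trial_id", "label", "ECR_Et", "ECR_Ef",
                                     "ECR_EA"))
  expect_identical(fe$label, rep(1:9, each = 2L))
  # permuted input order gives identically permuted rows
  perm <- c(5, 1, 18, 9)
  fe2 <- dataset_features(ds[perm])
  expect_equal(as.matrix(fe2[, -1]), as.matrix(fe[perm, -1]),
               ignore_attr = TRUE)

  empty <- dataset_features(list())
  expect_equal(nrow(empty), 0L)
  expect_length(names(empty), 14L)

  bad <- ds
  bad[[2]] <- recording(matrix(rnorm(100), 50, 2), fs = 2000)
  expect_error(dataset_features(bad), "heterogeneous")
})

test_that("feature CSVs round-trip through the writers", {
  ds <- synth_dataset(default_signatures()[1:2], trials_per_class = 1,
                      duration = 0.1, seed = 6)
  fe <- dataset_features(ds)
  path <- withr::local_tempfile(fileext = ".csv")
  write_features_csv(fe, path)
  back <- read_features_csv(path)
  expect_equal(back, fe, tolerance = 1e-15)
})
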