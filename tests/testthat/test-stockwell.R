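test_that("st_config enforces the band invariants", {
  expect_error(st_config(fs = 1000, fmin = -1), "fmin")
  expect_error(st_config(fs = 1000, fmin = 300, fmax = 200), "fmin")
  expect_error(st_config(fs = 1000, fmax = 600), "Nyquist")
  cfg <- st_config(fs = 1000, fmax = 400)
  expect_s3_class(cfg, "st_config")
})

test_that("degenerate signals transform as expected", {
  cfg <- st_config(fs = 1000, fmax = 200)
  z <- stransform(numeric(64), cfg)
  expect_true(all(Mod(z$values) == 0))
  expect_equal(ncol(z$values), 64L)
  expect_equal(diff(z$freqs)[1], 1000 / 64)

  const <- stransform(rep(2.5, 64), cfg)
  expect_equal(Mod(const$values[1, ]), rep(2.5, 64)) # DC row = mean
  # voices vanish up to the circular Gaussian's DC leakage exp(-2*pi^2)
  expect_lt(max(Mod(const$values[-1, ])), 1e-8 * 2.5)

  expect_error(stransform(rnorm(4), cfg), "at least 8")
  expect_error(stransform(c(rnorm(63), NA), cfg), "non-finite")
})

test_that("time marginal of the complex TFM equals the signal DFT", {
  set.seed(42)
  for (i in 1:5) {
    x <- rnorm(128)
    tf <- stransform(x, st_config(fs = 500, fmin = 0, fmax = 250))
    marg <- rowSums(tf$values)
    dft <- fft(x)[round(tf$freqs * 128 / 500) + 1]
    expect_equal(Mod(marg[1] - sum(x)), 0, tolerance = 1e-10) # DC row sums to sum(x)
    rel <- Mod(marg[-1] - dft[-1]) / Mod(dft[-1])
    expect_lt(max(rel), 1e-8)
  }
})

test_that("the transform is linear", {
  set.seed(7)
  x <- rnorm(128); y <- rnorm(128)
  cfg <- st_config(fs = 1000, fmax = 300)
  lhs <- stransform(2 * x - 3 * y, cfg)$values
  rhs <- 2 * stransform(x, cfg)$values - 3 * stransform(y, cfg)$values
  expect_lt(max(Mod(lhs - rhs)), 1e-10 * max(Mod(rhs)))
})

test_that("a sinusoid is localized at its frequency row", {
  fs <- 1000; N <- 512
  x <- sin(2 * pi * 50 * (0:(N - 1)) / fs)
  tf <- stransform(x, st_config(fs = fs, fmax = 400))
  A <- tfm_modulus(tf)
  best <- which.max(rowMeans(A))
  expect_equal(best, which.min(abs(tf$freqs - 50)))
  # away from edges the sinusoid row dominates every time column
  mid <- 100:400
  expect_true(all(A[best, mid] == apply(A[, mid], 2L, max)))
})

test_that("the transform matches direct quadrature of the definition", {
  fs <- 1000; N <- 1024
  set.seed(3)
  x <- rnorm(N)
  tf <- stransform(x, st_config(fs = fs, fmin = 40, fmax = 400))
  for (f in c(60, 150, 350)) {
    r <- which.min(abs(tf$freqs - f))
    fg <- tf$freqs[r]
    for (j in c(400, 600)) {
      q <- st_quadrature(x, fs, fg, j)
      expect_lt(Mod(tf$values[r, j + 1] - q) / Mod(q), 1e-6)
    }
  }
})

test_that("voices are Gaussian with width inversely proportional to frequency", {
  x <- numeric(1024); x[513] <- 1 # unit impulse at t = 0.512 s
  tf <- stransform(x, st_config(fs = 1000, fmin = 50, fmax = 400))
  for (f in c(100, 200, 400)) {
    r <- which.min(abs(tf$freqs - f))
    a <- Mod(tf$values[r, ]); a <- a / sum(a)
    mu <- sum(tf$times * a)
    sdv <- sqrt(sum((tf$times - mu)^2 * a))
    expect_equal(mu, 0.512, tolerance = 1e-6)
    expect_equal(sdv, 1 / tf$freqs[r], tolerance = 1e-3)
  }
})

test_that("tfm_modulus is the elementwise complex modulus", {
  cfg <- st_config(fs = 1000, fmax = 100)
  z <- stransform(numeric(32), cfg)
  expect_true(all(tfm_modulus(z) == 0))
  z$values[2, 5] <- 3 + 4i
  expect_equal(tfm_modulus(z)[2, 5], 5)
  expect_equal(attr(tfm_modulus(z), "freqs"), z$freqs)
  expect_error(tfm_modulus(1:5), "semg_tfm")
})

test_that("detrend and zero padding flags work", {
  set.seed(1)
  x <- rnorm(100) + 5
  cfg <- st_config(fs = 1000, fmax = 300)
  tf <- stransform(x, cfg, detrend = "mean")
  expect_lt(Mod(tf$values[1, 1]), 1e-12)
  tfp <- stransform(x, cfg, pad_to = 128)
  expect_equal(ncol(tfp$values), 128L)
  expect_equal(diff(tfp$freqs)[1], 1000 / 128)
  expect_error(stransform(x, cfg, pad_to = 50), "pad_to")
})
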