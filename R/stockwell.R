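#' Stockwell transform configuration
#'
#' Frequency band and sampling rate for [stransform()]. The analysis band
#' defaults to 0-500 Hz, the range in which the main sEMG frequency
#' content lies.
#'
#' @param fs Sampling rate, Hz.
#' @param fmin,fmax Band edges, Hz; must satisfy `0 <= fmin < fmax <= fs/2`.
#' @return Object of class `st_config`.
#' @export
st_config <- function(fs, fmin = 0, fmax = 500) {
  assert_scalar_number(fs, "fs", positive = TRUE)
  assert_scalar_number(fmin, "fmin")
  assert_scalar_number(fmax, "fmax")
  if (fmin < 0 || fmin >= fmax) stopf("need 0 <= fmin < fmax")
  if (fmax > fs / 2 + 1e-9) stopf("fmax = %g exceeds the Nyquist frequency %g",
                                  fmax, fs / 2)
  structure(list(fs = fs, fmin = fmin, fmax = fmax), class = "st_config")
}

#' Discrete Stockwell transform
#'
#' Computes the S-transform of a real signal on the DFT frequency grid
#' `n/(N*T)` restricted to the configured band. The transform uses the
#' frequency-domain ("voice") formulation: with `H` the DFT of the signal,
#' row `n` is the inverse DFT over `m` of
#' `H[(m + n) mod N] * exp(-2 * pi^2 * m^2 / n^2)`,
#' i.e. the signal's spectrum shifted to the voice frequency and weighted
#' by a Gaussian whose width scales with `1/n`, giving the
#' frequency-dependent time resolution that distinguishes the S-transform
#' from a fixed-window STFT. The Gaussian is evaluated on circularly
#' wrapped offsets (`m` and `m - N`), the standard convention, which keeps
#' the window symmetric and preserves the time-marginal identity
#' `sum_j S[j, n] = H[n] * N` (the DFT of the signal at each retained
#' frequency). When `fmin = 0` the zero-frequency row is the signal mean,
#' the transform's special case at DC where no Gaussian voice exists.
#'
#' @param x Real signal vector, length `N >= 8`, all finite.
#' @param config An [st_config()].
#' @param detrend One of `"none"` (default), `"mean"`, `"linear"`: optional
#'   removal of the mean or a least-squares line before transforming.
#' @param pad_to Optional length (`>= N`) to zero-pad the signal to before
#'   transforming; refines the frequency grid to `1/(pad_to * T)`.
#' @return Object of class `semg_tfm`: list with `values` (complex matrix,
#'   `n_freqs x n_times`), `freqs` (Hz, ascending), `times` (s), `N`
#'   (analysis length), `T` (sampling period, s), `fs`.
#' @export
#' @examples
#' x <- sin(2 * pi * 50 * seq(0, 0.255, by = 1/1000))
#' tf <- stransform(x, st_config(fs = 1000, fmax = 200))
#' dim(tf$values)
stransform <- function(x, config, detrend = c("none", "mean", "linear"),
                       pad_to = NULL) {
  detrend <- match.arg(detrend)
  if (!inherits(config, "st_config")) stopf("config must be an st_config()")
  if (!is.numeric(x) || length(x) < 8L)
    stopf("signal must be numeric with at least 8 samples")
  assert_finite(x, "signal")
  if (detrend == "mean") x <- x - mean(x)
  if (detrend == "linear") {
    t0 <- seq_along(x)
    x <- stats::residuals(stats::lm.fit(cbind(1, t0), x))
  }
  if (!is.null(pad_to)) {
    if (pad_to < length(x)) stopf("pad_to must be >= signal length")
    x <- c(x, numeric(pad_to - length(x)))
  }
  N <- length(x)
  Ts <- 1 / config$fs
  df <- 1 / (N * Ts)
  H <- stats::fft(x) / N
  n_min <- ceiling(config$fmin / df - 1e-9)
  n_max <- floor(config$fmax / df + 1e-9)
  n_max <- min(n_max, floor(N / 2))
  if (n_min > n_max) stopf("band [%g, %g] Hz contains no DFT frequency",
                           config$fmin, config$fmax)
  ns <- n_min:n_max
  voiced <- ns[ns != 0L]
  m <- 0:(N - 1)
  mw <- ifelse(m <= N / 2, m, m - N) # wrapped frequency offsets
  vals <- matrix(0 + 0i, length(ns), N)
  if (length(voiced)) {
    idx <- outer(m, voiced, function(mm, nn) ((mm + nn) %% N) + 1L)
    G <- exp(-2 * pi^2 * outer(mw^2, voiced^2, "/"))
    V <- matrix(H[idx], N, length(voiced)) * G
    S <- t(stats::mvfft(V, inverse = TRUE)) # rows = voices, no 1/N factor
    vals[match(voiced, ns), ] <- S
  }
  if (n_min == 0L) vals[1L, ] <- mean(x) # DC row: running mean of the signal
  structure(
    list(values = vals, freqs = ns * df, times = (m) * Ts,
         N = N, T = Ts, fs = config$fs),
    class = "semg_tfm")
}

#' @export
print.semg_tfm <- function(x, ...) {
  cat(sprintf("<semg_tfm> %d frequencies x %d times, band [%g, %g] Hz, fs %g Hz\n",
              nrow(x$values), ncol(x$values), min(x$freqs), max(x$freqs), x$fs))
  invisible(x)
}

#' Modulus of a time-frequency matrix
#'
#' The elementwise complex modulus of the S-transform output; this
#' nonnegative matrix is the time-frequency matrix (TFM) that feature
#' extraction operates on.
#'
#' @param tfm A `semg_tfm` from [stransform()].
#' @return Real nonnegative matrix (`n_freqs x n_times`) with the `freqs`
#'   and `times` axes attached as attributes.
#' @export
tfm_modulus <- function(tfm) {
  if (!inherits(tfm, "semg_tfm")) stopf("tfm must be a semg_tfm")
  a <- Mod(tfm$values)
  attr(a, "freqs") <- tfm$freqs
  attr(a, "times") <- tfm$times
  a
}

#' Export a TFM to plain text
#'
#' Writes the modulus as CSV: first column the frequency (Hz), remaining
#' columns the time samples, with a header row of times in seconds.
#'
#' @param tfm A `semg_tfm`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tfm_csv <- function(tfm, path) {
  a <- tfm_modulus(tfm)
  header <- paste(c("freq_hz", format_full(tfm$times)), collapse = ",")
  fmt <- matrix(format_full(a), nrow(a), ncol(a))
  rows <- paste(format_full(tfm$freqs),
                apply(fmt, 1L, paste, collapse = ","), sep = ",")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
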