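#' Partition configuration for multiscale SVD
#'
#' How the TFM is split for blockwise decomposition: `q` blocks along the
#' time axis (columns), `p` along the frequency axis (rows), and the number
#' of leading global singular values retained. Defaults follow the
#' reference setting of 16 blocks per axis and 20 global singular values.
#'
#' @param q Number of time-axis blocks (>= 1).
#' @param p Number of frequency-axis blocks (>= 1).
#' @param k_keep Number of retained global singular values (>= 1); silently
#'   truncated (with a warning) when it exceeds `min(dim)`.
#' @param global_sequence `"descending"` (default; the classical
#'   descending-order singular-value sequence) or `"as_computed"` (the
#'   order emitted by the decomposition routine, exposed for
#'   experimentation; LAPACK already returns descending order, so the two
#'   coincide in practice).
#' @return Object of class `partition_config`.
#' @export
partition_config <- function(q = 16L, p = 16L, k_keep = 20L,
                             global_sequence = c("descending", "as_computed")) {
  global_sequence <- match.arg(global_sequence)
  for (v in list(q = q, p = p, k_keep = k_keep)) {
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != as.integer(v))
      stopf("q, p and k_keep must be positive integers")
  }
  structure(list(q = as.integer(q), p = as.integer(p),
                 k_keep = as.integer(k_keep),
                 global_sequence = global_sequence),
            class = "partition_config")
}

#' Permutation-entropy configuration
#'
#' @param m Embedding dimension (>= 2). Default 3: the singular-value
#'   sequences fed to the entropy are short (16-20 values), and `m = 3`
#'   keeps the number of ordinal patterns (`3! = 6`) small relative to the
#'   number of embedded windows.
#' @param tau Embedding delay in samples (>= 1).
#' @param normalize If `TRUE`, divide by `ln(m!)` so the entropy lies in
#'   `[0, 1]`; default `FALSE` (nats).
#' @return Object of class `pe_config`.
#' @export
pe_config <- function(m = 3L, tau = 1L, normalize = FALSE) {
  if (!is.numeric(m) || length(m) != 1L || m < 2 || m != as.integer(m))
    stopf("m must be an integer >= 2")
  if (!is.numeric(tau) || length(tau) != 1L || tau < 1 || tau != as.integer(tau))
    stopf("tau must be an integer >= 1")
  structure(list(m = as.integer(m), tau = as.integer(tau),
                 normalize = isTRUE(normalize)),
            class = "pe_config")
}

#' Singular values of a matrix
#'
#' @param x Real matrix with finite entries.
#' @return Numeric vector of singular values in descending order, length
#'   `min(nrow, ncol)`.
#' @export
#' @examples
#' singular_values(diag(c(3, 2, 1)))
singular_values <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (!is.numeric(x) || nrow(x) < 1L || ncol(x) < 1L)
    stopf("x must be a non-empty numeric matrix")
  assert_finite(x, "matrix")
  svd(x, nu = 0L, nv = 0L)$d
}

#' Split a matrix into contiguous blocks along one axis
#'
#' Blocks are contiguous, non-overlapping and exhaustive, in axis order;
#' sizes differ by at most one, with the remainder absorbed by the leading
#' blocks. The time axis is the column axis of a TFM, the frequency axis
#' the row axis.
#'
#' @param x Matrix to split.
#' @param n_blocks Number of blocks; must not exceed the axis length.
#' @param axis `"time"` (columns) or `"frequency"` (rows).
#' @return List of submatrices in axis order.
#' @export
#' @examples
#' lengths(lapply(partition_blocks(matrix(0, 2, 10), 3, "time"), ncol))
partition_blocks <- function(x, n_blocks, axis = c("time", "frequency")) {
  axis <- match.arg(axis)
  if (!is.matrix(x)) stopf("x must be a matrix")
  len <- if (axis == "time") ncol(x) else nrow(x)
  if (!is.numeric(n_blocks) || length(n_blocks) != 1L || n_blocks < 1 ||
      n_blocks != as.integer(n_blocks))
    stopf("n_blocks must be a positive integer")
  if (n_blocks > len)
    stopf("n_blocks = %d exceeds the %s-axis length %d", n_blocks, axis, len)
  base <- len %/% n_blocks
  rem <- len %% n_blocks
  sizes <- rep(base, n_blocks) + c(rep(1L, rem), rep(0L, n_blocks - rem))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  lapply(seq_len(n_blocks), function(i) {
    if (axis == "time") x[, starts[i]:ends[i], drop = FALSE]
    else x[starts[i]:ends[i], , drop = FALSE]
  })
}

# Largest singular value only, via the Gram matrix of the thin side;
# much cheaper than a full SVD for the wide/tall blocks of a TFM.
max_singular_value <- function(x) {
  g <- if (nrow(x) <= ncol(x)) tcrossprod(x) else crossprod(x)
  sqrt(max(0, eigen(g, symmetric = TRUE, only.values = TRUE)$values[1L]))
}

#' Multiscale singular-value spectrum of a TFM
#'
#' Computes the three singular-value sequences that summarize a TFM
#' modulus at global and local scale: `lambda_A`, the first `k_keep`
#' singular values of the whole matrix (descending); `lambda_t`, the
#' largest singular value of each of `q` time-axis blocks; and `lambda_f`,
#' the largest singular value of each of `p` frequency-axis blocks. The
#' block maxima are used because a block's singular-value sequence decays
#' rapidly, so its leading value carries most of the block's energy.
#'
#' @param a TFM modulus: real nonnegative matrix, frequencies in rows and
#'   times in columns (see [tfm_modulus()]).
#' @param cfg A [partition_config()].
#' @return Object of class `msv_spectrum`: list with `lambda_A`,
#'   `lambda_t` (length `q`), `lambda_f` (length `p`).
#' @export
multiscale_spectrum <- function(a, cfg = partition_config()) {
  if (!is.matrix(a)) stopf("a must be a matrix (TFM modulus)")
  assert_finite(a, "TFM modulus")
  if (!inherits(cfg, "partition_config")) stopf("cfg must be a partition_config()")
  d <- singular_values(a)
  if (cfg$global_sequence == "descending") d <- sort(d, decreasing = TRUE)
  k <- cfg$k_keep
  if (k > length(d)) {
    warning(sprintf("k_keep = %d exceeds the %d available singular values; truncated",
                    k, length(d)), call. = FALSE)
    k <- length(d)
  }
  lambda_t <- vapply(partition_blocks(a, cfg$q, "time"),
                     max_singular_value, numeric(1))
  lambda_f <- vapply(partition_blocks(a, cfg$p, "frequency"),
                     max_singular_value, numeric(1))
  structure(list(lambda_A = d[seq_len(k)], lambda_t = unname(lambda_t),
                 lambda_f = unname(lambda_f)),
            class = "msv_spectrum")
}

# Stable ordinal pattern of one window: permutation sorting the window
# ascending, equal values ranked by position (earlier index first).
ordinal_pattern <- function(w) order(w)

#' Permutation entropy
#'
#' Shannon entropy (nats) of the distribution of ordinal patterns of the
#' length-`m` delay-embedded windows of a sequence. Each window
#' `(x[t], x[t + tau], ..., x[t + (m-1) tau])` is mapped to the
#' permutation that sorts it ascending; equal values are ranked by
#' position (stable ties), so a constant sequence has a single pattern and
#' zero entropy. The entropy is bounded by `ln(m!)` and is invariant under
#' strictly increasing transforms of the sequence values.
#'
#' @param x Numeric sequence of length `l` with `l - (m-1) * tau >= 1`.
#' @param cfg A [pe_config()].
#' @return Entropy in nats, or in `[0, 1]` if `cfg$normalize`.
#' @export
#' @examples
#' permutation_entropy(c(4, 7, 9, 10, 6, 11, 3), pe_config(m = 3, tau = 1))
permutation_entropy <- function(x, cfg = pe_config()) {
  if (!is.numeric(x)) stopf("x must be numeric")
  assert_finite(x, "sequence")
  m <- cfg$m; tau <- cfg$tau
  l <- length(x)
  n_win <- l - (m - 1L) * tau
  if (n_win < 1L)
    stopf("sequence length %d too short for (m = %d, tau = %d); need at least %d",
          l, m, tau, (m - 1L) * tau + 1L)
  offs <- seq.int(0L, by = tau, length.out = m)
  win <- outer(seq_len(n_win) - 1L, offs, "+") + 1L # n_win x m index matrix
  vals <- matrix(x[win], n_win, m)
  patterns <- apply(vals, 1L, function(w) paste(order(w), collapse = "."))
  p <- tabulate(factor(patterns)) / n_win
  h <- -sum(p * log(p))
  if (cfg$normalize) h <- h / log(factorial(m))
  h
}

#' Per-channel entropy features of a TFM
#'
#' The feature triple `F = (Et, Ef, EA)`: permutation entropy of the
#' time-block maxima `lambda_t`, of the frequency-block maxima `lambda_f`,
#' and of the global singular-value sequence `lambda_A`.
#'
#' @param a TFM modulus matrix.
#' @param partition_cfg A [partition_config()].
#' @param pe_cfg A [pe_config()]; the lengths `q`, `p`, `k_keep` must each
#'   satisfy the embedding length constraint.
#' @return Named numeric vector `c(Et, Ef, EA)`.
#' @export
channel_features <- function(a, partition_cfg = partition_config(),
                             pe_cfg = pe_config()) {
  sp <- multiscale_spectrum(a, partition_cfg)
  c(Et = permutation_entropy(sp$lambda_t, pe_cfg),
    Ef = permutation_entropy(sp$lambda_f, pe_cfg),
    EA = permutation_entropy(sp$lambda_A, pe_cfg))
}

#' Feature table for a list of recordings
#'
#' Runs the S-transform and entropy feature extraction on every channel of
#' every recording. Rows preserve the input order; columns are the
#' `(Et, Ef, EA)` triple per channel, channels in recording order, so four
#' channels yield twelve feature columns.
#'
#' @param recordings List of [recording()] objects with identical channel
#'   layout and sampling rate.
#' @param st_cfg An [st_config()] or `NULL` to use the default 0-500 Hz
#'   band at the recordings' sampling rate.
#' @param partition_cfg A [partition_config()].
#' @param pe_cfg A [pe_config()].
#' @param verbose Print per-trial progress.
#' @return Data frame with columns `trial_id`, `label`, then
#'   `<channel>_Et`, `<channel>_Ef`, `<channel>_EA` per channel. An empty
#'   input yields an empty data frame with the header of a 4-channel
#'   montage.
#' @export
dataset_features <- function(recordings, st_cfg = NULL,
                             partition_cfg = partition_config(),
                             pe_cfg = pe_config(), verbose = FALSE) {
  feature_cols <- function(chs) {
    as.vector(t(outer(chs, c("Et", "Ef", "EA"), paste, sep = "_")))
  }
  if (length(recordings) == 0L) {
    cols <- c("trial_id", "label", feature_cols(default_channels()))
    df <- as.data.frame(matrix(numeric(0), 0L, length(cols)))
    names(df) <- cols
    return(df)
  }
  ok <- vapply(recordings, inherits, logical(1), "semg_recording")
  if (!all(ok)) stopf("recordings must all be semg_recording objects")
  fs <- vapply(recordings, function(r) r$fs, numeric(1))
  nch <- vapply(recordings, function(r) ncol(r$samples), integer(1))
  if (length(unique(fs)) != 1L || length(unique(nch)) != 1L)
    stopf("recordings are heterogeneous: all must share fs and channel count")
  chs <- recordings[[1L]]$channel_names
  if (is.null(st_cfg)) st_cfg <- st_config(fs = fs[1L], fmax = min(500, fs[1L] / 2))
  if (abs(st_cfg$fs - fs[1L]) > 1e-9)
    stopf("st_cfg$fs = %g does not match the recordings' fs = %g", st_cfg$fs, fs[1L])
  n <- length(recordings)
  feats <- matrix(NA_real_, n, 3L * length(chs))
  for (i in seq_len(n)) {
    t0 <- proc.time()[["elapsed"]]
    row <- unlist(lapply(seq_along(chs), function(ch) {
      tf <- stransform(recordings[[i]]$samples[, ch], st_cfg)
      channel_features(tfm_modulus(tf), partition_cfg, pe_cfg)
    }))
    feats[i, ] <- row
    if (verbose)
      message(sprintf("trial %d/%d (%.2f s)", i, n,
                      proc.time()[["elapsed"]] - t0))
  }
  labels <- vapply(recordings, function(r)
    if (is.null(r$label)) NA_integer_ else r$label, integer(1))
  df <- data.frame(trial_id = seq_len(n), label = labels, feats)
  names(df) <- c("trial_id", "label", feature_cols(chs))
  df
}

#' Write a feature table as CSV
#'
#' Full-precision (`%.17g`) CSV with the `trial_id,label,<ch>_Et,...`
#' header; byte-reproducible for identical inputs.
#'
#' @param features Data frame from [dataset_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(features), collapse = ","), con, sep = "\n",
             useBytes = TRUE)
  if (nrow(features)) {
    cols <- lapply(seq_along(features), function(j) {
      v <- features[[j]]
      if (names(features)[j] %in% c("trial_id", "label")) as.character(v)
      else format_full(v)
    })
    writeLines(do.call(paste, c(cols, sep = ",")), con, sep = "\n",
               useBytes = TRUE)
  }
  invisible(path)
}

#' Read a feature table CSV
#'
#' @param path CSV written by [write_features_csv()].
#' @return Data frame.
#' @export
read_features_csv <- function(path) {
  if (!file.exists(path)) stopf("feature file not found: %s", path)
  utils::read.csv(path)
}
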