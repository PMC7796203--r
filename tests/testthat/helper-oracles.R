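# Independent reference implementations used to cross-check the package.

# Permutation entropy by explicit window enumeration: ranks each embedded
# window with rank(..., ties.method = "first") and counts patterns in a
# plain loop. Deliberately structured differently from the package path.
pe_oracle <- function(x, m = 3L, tau = 1L) {
  n_win <- length(x) - (m - 1L) * tau
  counts <- new.env(parent = emptyenv())
  for (t in seq_len(n_win)) {
    w <- x[t + seq.int(0L, by = tau, length.out = m)]
    key <- paste(rank(w, ties.method = "first"), collapse = "-")
    counts[[key]] <- (counts[[key]] %||% 0L) + 1L
  }
  cnt <- unlist(as.list(counts))
  p <- cnt / n_win
  -sum(p * log(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Direct quadrature of the continuous S-transform definition at one
# (time index j0, grid frequency f): Riemann sum of the windowed,
# demodulated signal.
st_quadrature <- function(x, fs, f, j0) {
  Ts <- 1 / fs
  tt <- (seq_along(x) - 1) * Ts
  w <- (f / sqrt(2 * pi)) * exp(-(tt[j0 + 1] - tt)^2 * f^2 / 2)
  sum(x * w * exp(-2i * pi * f * tt)) * Ts
}

# RBM energy by naive triple loop.
rbm_energy_oracle <- function(v, h, theta) {
  e <- 0
  for (i in seq_along(v)) e <- e - theta$a[i] * v[i]
  for (j in seq_along(h)) e <- e - theta$b[j] * h[j]
  for (i in seq_along(v)) for (j in seq_along(h))
    e <- e - theta$W[i, j] * v[i] * h[j]
  e
}

# Conditional P(h_j = 1 | v) extracted from the enumerated joint table.
p_h_from_table <- function(v, theta) {
  tab <- rbm_joint_table(theta)
  row <- which(apply(tab$v_states, 1L, function(s) all(s == v)))
  pv <- tab$prob[row, ]
  vapply(seq_len(ncol(tab$h_states)), function(j)
    sum(pv[tab$h_states[, j] == 1]) / sum(pv), numeric(1))
}

# Random RBM with small weights, sized for enumeration.
random_small_rbm <- function(nv, nh, scale = 1) {
  theta <- rbm_params(nv, nh)
  theta$W <- matrix(stats::rnorm(nv * nh, 0, scale), nv, nh)
  theta$a <- stats::rnorm(nv, 0, scale)
  theta$b <- stats::rnorm(nh, 0, scale)
  theta
}
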