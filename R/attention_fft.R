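# FFT path for the local-attention causal convolution.
#
# The attention module convolves the single-channel input with
# `attention_channels` kernels of length 7 * epoch_len (7168 samples at full
# width). Direct evaluation is O(K * L * C) and becomes prohibitive on a
# whole-night signal (~10^12 multiply-adds at full width), so when the work
# exceeds a threshold the convolution is evaluated in the frequency domain.
# Both paths produce the same operator (verified against each other in the
# test suite); the choice is purely computational.

ATT_FFT_WORK_THRESHOLD <- 1e8

att_use_fft <- function(K, L, ca) as.numeric(K) * L * ca > ATT_FFT_WORK_THRESHOLD

# Causal convolution: A[c, t] = b[c] + sum_k w[c, 1, k] * x[t + k - K]
# (x indexed 1-based, out-of-range samples are zero), i.e. tap k = K touches
# the current sample and tap k = 1 the sample K - 1 steps in the past.
# Equivalently A[c, ] is the first L samples of linconv(x, rev(w[c, 1, ])).
att_fft_forward <- function(x, w, b, v1, b1, keep_A = FALSE, chunk = 16L) {
  K <- dim(w)[3]
  ca <- dim(w)[1]
  L <- length(x)
  n <- next_pow2(L + K - 1)
  fx <- stats::fft(c(x, numeric(n - L)))
  s_pre <- rep(b1, L)
  A <- if (keep_A) matrix(0, ca, L) else NULL
  for (start in seq(1L, ca, by = chunk)) {
    ci <- start:min(start + chunk - 1L, ca)
    km <- matrix(0, n, length(ci))
    for (j in seq_along(ci)) km[1:K, j] <- rev(w[ci[j], 1, ])
    y <- Re(stats::mvfft(stats::mvfft(km) * fx, inverse = TRUE)) / n
    y <- y[1:L, , drop = FALSE]
    y <- sweep(y, 2, b[ci], "+")
    s_pre <- s_pre + as.vector(y %*% v1[ci])
    if (keep_A) A[ci, ] <- t(y)
  }
  list(s_pre = s_pre, A = A, L = L, K = K, n = n)
}

# Gradient of the attention parameters given d(loss)/d(s_pre).
# Because the per-sample score is s_pre = v1 . A + b1, the upstream gradient
# of every causal-conv channel is proportional to grad_s: the weight
# gradient collapses to a single cross-correlation of grad_s with the
# (causally padded) input, shared by all channels.
att_fft_backward <- function(x, w, v1, A, grad_s) {
  K <- dim(w)[3]
  ca <- dim(w)[1]
  L <- length(x)
  g_v1 <- as.vector(A %*% grad_s)
  g_b1 <- sum(grad_s)
  xp <- c(numeric(K - 1), x)
  n2 <- next_pow2(length(xp) + L)
  fxp <- stats::fft(c(xp, numeric(n2 - length(xp))))
  fg <- stats::fft(c(grad_s, numeric(n2 - L)))
  cc <- Re(stats::fft(fxp * Conj(fg), inverse = TRUE)) / n2
  corr_k <- cc[1:K]  # lag k-1: sum_t grad_s[t] * xp[t + k - 1]
  g_w <- array(0, dim = dim(w))
  for (c in seq_len(ca)) g_w[c, 1, ] <- v1[c] * corr_k
  g_b <- v1 * sum(grad_s)
  list(att_conv = list(w = g_w, b = g_b),
       att_proj = list(w = array(g_v1, dim = c(1, ca, 1)), b = g_b1))
}
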