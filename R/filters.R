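# Zero-phase second-order Butterworth low-pass.  No DSP package is
# available in the target environment, so the biquad and forward-backward
# pass are implemented here; odd reflection padding (as in the usual
# filtfilt convention) keeps constants exactly invariant and suppresses
# edge transients.

butter2_coefs <- function(cutoff_hz, fs_hz) {
  if (cutoff_hz <= 0) stop("`cutoff_hz` must be positive")
  if (cutoff_hz >= fs_hz / 2) {
    return(NULL) # cutoff at/above Nyquist: identity filter
  }
  w <- tan(pi * cutoff_hz / fs_hz)
  k1 <- sqrt(2) * w
  k2 <- w^2
  a0 <- 1 + k1 + k2
  list(b = c(k2, 2 * k2, k2) / a0,
       a = c(1, 2 * (k2 - 1) / a0, (1 - k1 + k2) / a0))
}

iir_filter <- function(b, a, x) {
  n <- length(x)
  y <- numeric(n)
  x1 <- 0; x2 <- 0; y1 <- 0; y2 <- 0
  for (i in seq_len(n)) {
    yi <- b[1] * x[i] + b[2] * x1 + b[3] * x2 - a[2] * y1 - a[3] * y2
    x2 <- x1; x1 <- x[i]
    y2 <- y1; y1 <- yi
    y[i] <- yi
  }
  y
}

lowpass_zerophase <- function(x, cutoff_hz, fs_hz) {
  n <- length(x)
  co <- butter2_coefs(cutoff_hz, fs_hz)
  if (is.null(co) || n < 4L) return(x)
  pad <- min(n - 1L, max(12L, 3L * ceiling(fs_hz / cutoff_hz)))
  # odd reflection about the end points
  left <- 2 * x[1] - x[seq(pad + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - pad)]
  xe <- c(left, x, right)
  y <- iir_filter(co$b, co$a, xe)
  y <- rev(iir_filter(co$b, co$a, rev(y)))
  y[seq(pad + 1, pad + n)]
}

# Strict local maxima with topographic prominence; runs of equal values
# (plateaus) count once, located at the start of the run.
find_peaks <- function(x, min_prominence = 0) {
  n <- length(x)
  if (n < 3L) return(integer())
  r <- rle(x)
  m <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  peaks <- integer()
  for (j in seq_len(m)) {
    if (j == 1L || j == m) next
    if (r$values[j] > r$values[j - 1L] && r$values[j] > r$values[j + 1L]) {
      peaks <- c(peaks, starts[j])
    }
  }
  if (!length(peaks)) return(integer())
  prom <- vapply(peaks, function(i) peak_prominence(x, i), numeric(1))
  peaks[prom >= min_prominence]
}

peak_prominence <- function(x, i) {
  h <- x[i]
  left <- x[seq_len(i - 1L)]
  higher_l <- which(left > h)
  lo_l <- if (length(higher_l)) {
    min(x[seq(max(higher_l) + 1L, i - 1L)])
  } else min(left)
  right <- x[seq(i + 1L, length(x))]
  higher_r <- which(right > h)
  lo_r <- if (length(higher_r)) {
    min(right[seq_len(min(higher_r) - 1L)])
  } else min(right)
  h - max(lo_l, lo_r)
}
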