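#' @keywords internal
"_PACKAGE"

## Signal-processing primitives. No DSP package ships with the analysis
## stack we target, so the few primitives needed (zero-phase FFT band-pass,
## analytic signal, Gaussian kernel smoothing) are implemented here on top
## of base-R FFTs.

#' Gaussian kernel smoothing of a regularly sampled vector
#'
#' Smooths by direct convolution with a discrete Gaussian kernel truncated
#' at 4 standard deviations. Edges are renormalized by the local kernel
#' mass so that a constant input maps to itself (no wrap-around).
#'
#' @param x numeric vector sampled on a regular grid.
#' @param sd kernel standard deviation in samples; `sd <= 0` returns `x`.
#' @param normalize_edges renormalize by local kernel mass at the edges.
#'   Set `FALSE` when smoothing quantities whose total mass must be
#'   conserved (e.g. spike counts before dividing by occupancy).
#' @return smoothed numeric vector, same length as `x`.
#' @export
gauss_smooth <- function(x, sd, normalize_edges = TRUE) {
  if (sd <= 0) return(x)
  half <- max(1L, ceiling(4 * sd))
  k <- stats::dnorm(seq(-half, half), sd = sd)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(0, half), x, rep(0, half))
  sm <- stats::filter(xp, k, sides = 2)[(half + 1):(half + n)]
  if (normalize_edges) {
    wp <- c(rep(0, half), rep(1, n), rep(0, half))
    w <- stats::filter(wp, k, sides = 2)[(half + 1):(half + n)]
    sm <- sm / w
  }
  as.numeric(sm)
}

#' Zero-phase band-pass filter via FFT masking
#'
#' Multiplies the spectrum by a band mask with raised-cosine transition
#' edges and inverts the transform; being applied in the frequency domain
#' the filter has exactly zero phase delay.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param lo,hi pass-band edges, Hz.
#' @param trans transition width, Hz (raised-cosine roll-off on either side).
#' @return filtered numeric vector.
#' @export
bandpass_fft <- function(x, fs, lo, hi, trans = 1) {
  n <- length(x)
  if (n < 8) stop("signal too short to filter")
  if (stats::sd(x) == 0) stop("constant signal: band-pass undefined")
  nfft <- stats::nextn(n, c(2, 3, 5))
  xp <- c(x - mean(x), rep(0, nfft - n))
  f <- (seq_len(nfft) - 1) * fs / nfft
  f <- pmin(f, fs - f)  # two-sided frequency magnitude
  mask <- rep(0, nfft)
  mask[f >= lo & f <= hi] <- 1
  rise <- f >= (lo - trans) & f < lo
  mask[rise] <- 0.5 * (1 + cos(pi * (lo - f[rise]) / trans))
  fall <- f > hi & f <= (hi + trans)
  mask[fall] <- 0.5 * (1 + cos(pi * (f[fall] - hi) / trans))
  y <- Re(stats::fft(stats::fft(xp) * mask, inverse = TRUE)) / nfft
  y[seq_len(n)]
}

#' Analytic signal via the Hilbert transform
#'
#' @param x real numeric signal (typically already band-passed).
#' @return complex vector `x + i*H(x)`; `Arg()` gives instantaneous phase,
#'   `Mod()` the envelope.
#' @export
analytic_signal <- function(x) {
  n0 <- length(x)
  # pad to a 2-3-5-smooth length: R's FFT is O(n*p) in the largest prime
  # factor p, which is catastrophic for arbitrary lengths
  n <- stats::nextn(n0, c(2, 3, 5))
  xp <- c(x, rep(0, n - n0))
  X <- stats::fft(xp)
  h <- rep(0, n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  (stats::fft(X * h, inverse = TRUE) / n)[seq_len(n0)]
}

#' Welch power- and cross-spectral estimate
#'
#' Hann-tapered segments with 50% overlap; returns one-sided spectra.
#'
#' @param x,y numeric signals of equal length (`y` may be `NULL` for
#'   auto-spectrum only).
#' @param fs sampling rate, Hz.
#' @param seg_s segment length, seconds.
#' @return list with `freq`, `pxx`, and when `y` is given `pyy` and complex
#'   cross-spectrum `pxy`.
#' @keywords internal
welch_spectra <- function(x, y = NULL, fs, seg_s = 1) {
  nseg <- max(16L, round(seg_s * fs))
  nseg <- min(nseg, length(x))
  step <- max(1L, nseg %/% 2L)
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  nf <- nseg %/% 2L + 1L
  pxx <- pyy <- numeric(nf)
  pxy <- complex(nf)
  for (s in starts) {
    xi <- x[s:(s + nseg - 1L)]
    X <- stats::fft((xi - mean(xi)) * w)[seq_len(nf)]
    pxx <- pxx + Mod(X)^2
    if (!is.null(y)) {
      yi <- y[s:(s + nseg - 1L)]
      Y <- stats::fft((yi - mean(yi)) * w)[seq_len(nf)]
      pyy <- pyy + Mod(Y)^2
      pxy <- pxy + X * Conj(Y)
    }
  }
  out <- list(freq = (seq_len(nf) - 1) * fs / nseg,
              pxx = pxx / length(starts))
  if (!is.null(y)) {
    out$pyy <- pyy / length(starts)
    out$pxy <- pxy / length(starts)
  }
  out
}

#' Log-sum-exp
#' @param x numeric vector of log-values.
#' @return `log(sum(exp(x)))` computed stably.
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Convert a logical sample mask into an interval table
#'
#' Contiguous `TRUE` runs on a regular time grid become rows of
#' `(start_s, end_s)`, closed on the left and half-open on the right
#' (the end is one sample step past the last `TRUE` sample).
#'
#' @param time_s sample times (regular grid).
#' @param mask logical vector, same length; `NA` counts as `FALSE`.
#' @return data.frame with `start_s`, `end_s`.
#' @export
mask_to_intervals <- function(time_s, mask) {
  mask[is.na(mask)] <- FALSE
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  dt <- stats::median(diff(time_s))
  data.frame(start_s = time_s[starts[keep]],
             end_s = time_s[ends[keep]] + dt)
}

## TRUE for times falling in any [start, end) interval.
in_intervals <- function(t, intervals) {
  if (nrow(intervals) == 0) return(rep(FALSE, length(t)))
  idx <- findInterval(t, intervals$start_s)
  idx > 0 & t < intervals$end_s[pmax(idx, 1L)]
}
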