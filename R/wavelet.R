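# Maximal-overlap discrete wavelet transform (MODWT), Daubechies-4 family,
# periodic boundary. The MODWT is shift-invariant and defined for any series
# length; its multiresolution details D_j partition the series additively,
# with detail level j nominally covering the dyadic band
# [fs/2^(j+1), fs/2^j] at sampling frequency fs.

# Daubechies-4 (two vanishing moments, 4 taps) scaling filter
.d4_scaling <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) /
  (4 * sqrt(2))
# quadrature mirror wavelet filter h_l = (-1)^l g_{L-1-l}
.d4_wavelet <- rev(.d4_scaling) * c(1, -1, 1, -1)

# y[t] = sum_l f[l] x[(t - step*l) mod N]  (analysis direction)
.circ_down <- function(x, f, step) {
  n <- length(x)
  y <- numeric(n)
  for (l in seq_along(f)) {
    shift <- (l - 1L) * step
    idx <- ((seq_len(n) - 1L - shift) %% n) + 1L
    y <- y + f[l] * x[idx]
  }
  y
}

# y[t] = sum_l f[l] x[(t + step*l) mod N]  (synthesis direction)
.circ_up <- function(x, f, step) {
  n <- length(x)
  y <- numeric(n)
  for (l in seq_along(f)) {
    shift <- (l - 1L) * step
    idx <- ((seq_len(n) - 1L + shift) %% n) + 1L
    y <- y + f[l] * x[idx]
  }
  y
}

#' MODWT of a single series
#'
#' @param x numeric vector.
#' @param n_levels decomposition depth J (requires length(x) >= 2^J is not
#'   needed for the MODWT, but J is capped at floor(log2(N))).
#' @return list with `W` (N x J matrix of wavelet coefficients) and `V`
#'   (final-level scaling coefficients).
#' @export
modwt <- function(x, n_levels) {
  n <- length(x)
  if (n < length(.d4_scaling)) {
    stop("series shorter than the wavelet filter support")
  }
  n_levels <- min(as.integer(n_levels), floor(log2(n)))
  ht <- .d4_wavelet / sqrt(2)
  gt <- .d4_scaling / sqrt(2)
  W <- matrix(0, n, n_levels)
  v <- x
  for (j in seq_len(n_levels)) {
    step <- 2L^(j - 1L)
    W[, j] <- .circ_down(v, ht, step)
    v <- .circ_down(v, gt, step)
  }
  list(W = W, V = v, n_levels = n_levels)
}

#' Multiresolution detail series from a MODWT
#'
#' Reconstructs the detail D_j: the component of the series carried by
#' wavelet level j. Details are additive: sum of all details plus the final
#' smooth recovers the input exactly.
#'
#' @param wt result of [modwt()].
#' @param level detail level j.
#' @return numeric vector of the same length as the input series.
#' @export
modwt_detail <- function(wt, level) {
  ht <- .d4_wavelet / sqrt(2)
  gt <- .d4_scaling / sqrt(2)
  d <- .circ_up(wt$W[, level], ht, 2L^(level - 1L))
  # propagate back through the scaling (smooth) branches below this level
  j <- level - 1L
  while (j >= 1L) {
    d <- .circ_up(d, gt, 2L^(j - 1L))
    j <- j - 1L
  }
  d
}

# dyadic frequency band of detail level j at sampling frequency fs
.detail_band <- function(j, fs) c(fs / 2^(j + 1), fs / 2^j)

#' Wavelet sub-band filter for regional time series
#'
#' Reconstructs each regional series from the MODWT detail level(s) whose
#' dyadic frequency support overlaps the requested band — the standard way
#' of isolating the low-frequency resting-state fluctuations (default
#' 0.06–0.1 Hz) before computing inter-regional correlations. The
#' transform is shift invariant with periodic boundary handling, output
#' length equals input length, and the operation is linear. A direct
#' zero-phase FFT band-pass is available behind the same interface.
#'
#' @param ts a `regional_ts`.
#' @param band numeric length-2 vector, band in Hz within (0, Nyquist\].
#' @param method `"modwt"` (dyadic detail selection, default) or `"fft"`
#'   (hard zero-phase band-pass).
#' @return a `regional_ts` of filtered series; the selected detail levels
#'   (modwt method) are recorded in attribute `"levels"`.
#' @export
wavelet_subband_filter <- function(ts, band = c(0.06, 0.1),
                                   method = c("modwt", "fft")) {
  method <- match.arg(method)
  fs <- 1 / ts$sampling_interval
  nyq <- fs / 2
  if (length(band) != 2L || band[1L] <= 0 || band[2L] <= band[1L]) {
    stop("band must be an increasing positive frequency interval")
  }
  if (band[2L] > nyq + 1e-12) {
    stop(sprintf("band upper edge %.4g Hz exceeds the Nyquist %.4g Hz",
                 band[2L], nyq))
  }
  n <- ncol(ts$values)

  if (method == "fft") {
    filt <- t(apply(ts$values, 1L, .fft_bandpass, fs = fs, band = band))
  } else {
    j_max <- floor(log2(n))
    bands <- vapply(seq_len(j_max), .detail_band, numeric(2), fs = fs)
    overlap <- which(bands[1L, ] < band[2L] & bands[2L, ] > band[1L])
    if (length(overlap) == 0L) {
      stop("no wavelet detail level overlaps the requested band")
    }
    J <- max(overlap)
    filt <- t(apply(ts$values, 1L, function(x) {
      wt <- modwt(x, J)
      Reduce(`+`, lapply(overlap, function(j) modwt_detail(wt, j)))
    }))
  }
  out <- regional_ts(filt, ts$region_labels, ts$sampling_interval)
  if (method == "modwt") attr(out, "levels") <- overlap
  out
}

# hard zero-phase band-pass by zeroing FFT bins outside [band[1], band[2]]
.fft_bandpass <- function(x, fs, band) {
  n <- length(x)
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)               # two-sided -> folded frequency
  keep <- f >= band[1L] & f <= band[2L]
  Re(stats::fft(stats::fft(x) * keep, inverse = TRUE)) / n
}
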