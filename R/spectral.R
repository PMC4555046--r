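#' Hanning-windowed power spectral density per segment and channel
#'
#' For each 1-s segment and channel, the samples are multiplied by the
#' Hanning window \eqn{H(t) = (1 + \cos(2\pi t / T)) / 2}, Fourier
#' transformed, and the squared coefficient magnitude divided by \eqn{T}
#' is kept at the 70 analysis frequencies 1..70 Hz (1 Hz resolution for
#' 1-s segments). No window-power compensation is applied: every
#' downstream quantity (log differences, PCA, r-squared, scaled features)
#' is invariant to that constant.
#'
#' @param segments A `segment_set` whose segments are exactly 1 s long.
#' @return A `psd_set`: list with `values` (segments x channels x 70
#'   array), `freq` (1..70), `labels`, `channel_labels`, `montage`.
#' @export
compute_psd <- function(segments) {
  d <- segments$data
  T <- dim(d)[3]
  if (T != segments$sampling_rate_hz)
    stop("segments must be exactly 1 s long (samples == sampling rate)", call. = FALSE)
  f <- 1:70
  H <- (1 + cos(2 * pi * seq_len(T) / T)) / 2
  m <- dim(d)[1]; n <- dim(d)[2]
  vals <- array(NA_real_, dim = c(m, n, 70))
  for (i in seq_len(m)) {
    # channels in columns -> one mvfft per segment
    xw <- t(matrix(d[i, , ], n, T)) * H         # T x N
    X <- stats::mvfft(xw)
    vals[i, , ] <- t(abs(X[f + 1L, , drop = FALSE])^2 / T)
  }
  structure(list(values = vals, freq = f, labels = segments$labels,
                 channel_labels = segments$channel_labels,
                 montage = segments$montage),
            class = "psd_set")
}

#' Log-normalize spectra against the mean over all segments
#'
#' Implements \eqn{\tilde P_n^m(f) = \ln P_n^m(f) - \ln\left(\frac{1}{M}
#' \sum_m P_n^m(f)\right)}, the reference mean being taken over *all*
#' segments (movement and rest pooled), so that power increases and
#' decreases relative to the session mean are scaled symmetrically.
#'
#' @param psd A `psd_set`.
#' @param floor_eps Strictly positive floor applied to the PSD before the
#'   logarithm; set to `NULL` to disable (a zero PSD value then errors).
#' @return A `logpsd_set` with `values` (same shape) and `reference`
#'   (channels x frequencies matrix of across-segment mean PSD).
#' @export
log_normalize <- function(psd, floor_eps = 1e-20) {
  v <- psd$values
  if (!is.null(floor_eps)) {
    v <- pmax(v, floor_eps)
  } else if (any(v <= 0)) {
    stop("zero PSD value encountered; set floor_eps to a small positive floor",
         call. = FALSE)
  }
  ref <- apply(v, c(2, 3), mean)           # channels x freq
  lv <- log(v)
  for (i in seq_len(dim(v)[1])) lv[i, , ] <- lv[i, , ] - log(ref)
  out <- psd
  out$values <- lv
  out$reference <- ref
  class(out) <- "logpsd_set"
  out
}

#' Mean band power per segment and channel
#'
#' Arithmetic mean of the PSD over the band's integer frequency bins:
#' alpha (mu) is 8..12 Hz inclusive (5 bins), beta 13..30 Hz inclusive
#' (18 bins).
#'
#' @param psd A `psd_set`.
#' @param band `"alpha"` or `"beta"`.
#' @return A `band_power_table`: list with `values` (segments x channels
#'   matrix), `band`, `labels`, `channel_labels`, `montage`.
#' @export
band_power <- function(psd, band = c("alpha", "beta")) {
  band <- match.arg(band)
  bins <- band_bins(band)
  vals <- apply(psd$values[, , bins, drop = FALSE], c(1, 2), mean)
  structure(list(values = vals, band = band, labels = psd$labels,
                 channel_labels = psd$channel_labels, montage = psd$montage),
            class = "band_power_table")
}

band_bins <- function(band) {
  switch(band,
         alpha = 8:12,
         beta = 13:30,
         stop(sprintf("unknown band '%s'", band), call. = FALSE))
}
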