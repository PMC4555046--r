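# Independent oracles and small fixture builders shared across tests.

# O(T^2) direct-summation DFT oracle for the Hanning-windowed PSD at the
# 1..70 Hz analysis bins (independent of the fft-based pipeline path).
psd_direct_oracle <- function(x) {
  T <- length(x)
  H <- (1 + cos(2 * pi * seq_len(T) / T)) / 2
  vapply(1:70, function(f) {
    s <- sum(x * H * exp(1i * 2 * pi * f * seq_len(T) / T))
    Mod(s)^2 / T
  }, numeric(1))
}

# Rectangular-window periodogram band power over integer-Hz bins of a 1-s
# window (independent Welch-style oracle for band-power checks).
rect_band_power <- function(x, bins) {
  X <- stats::fft(x)
  mean(Mod(X[bins + 1L])^2 / length(x))
}

# |H(f)| of a designed digital filter by direct polynomial evaluation.
filter_gain <- function(flt, f, fs) {
  w <- 2 * pi * f / fs
  vapply(w, function(wi) {
    zb <- exp(-1i * wi * (seq_along(flt$b) - 1))
    za <- exp(-1i * wi * (seq_along(flt$a) - 1))
    Mod(sum(flt$b * zb) / sum(flt$a * za))
  }, numeric(1))
}

# Minimal psd_set-like object from an explicit values array.
make_psd_set <- function(values, labels = NULL, channel_labels = NULL) {
  structure(list(values = values, freq = seq_len(dim(values)[3]),
                 labels = labels %||% rep("rest", dim(values)[1]),
                 channel_labels = channel_labels %||%
                   paste0("ch", seq_len(dim(values)[2])),
                 montage = NULL),
            class = "psd_set")
}

make_logpsd_set <- function(values, labels = NULL) {
  out <- make_psd_set(values, labels)
  class(out) <- "logpsd_set"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Neutral (zero-effect) synthetic configuration: no ERD, no broadband
# shift, no finger signatures.
neutral_config <- function(n_channels = 32, trials_per_finger = 4, seed = 1,
                           ...) {
  mon <- default_montage(n_channels)
  labs <- mon$label
  fingers <- c("thumb", "index", "middle", "ring", "little")
  synth_config(
    n_channels = n_channels, trials_per_finger = trials_per_finger,
    erd_map = stats::setNames(rep(1, n_channels), labs),
    broadband_shift = stats::setNames(rep(0, n_channels), labs),
    finger_effect = list(
      broadband = matrix(0, 5, n_channels, dimnames = list(fingers, labs)),
      erd = matrix(0, 5, n_channels, dimnames = list(fingers, labs))),
    seed = seed, ...)
}

# Tiny session whose samples encode their own 0-based index (identical on
# every channel); for segment-extraction bookkeeping checks.
index_session <- function(n_trials = 3, fs = 250, n_channels = 2) {
  total <- n_trials * 6L * fs
  data <- matrix(rep(seq_len(total) - 1, each = n_channels), n_channels, total,
                 byrow = FALSE)
  mon <- default_montage(32)[seq_len(n_channels), ]
  new_session(data = data, sampling_rate_hz = fs,
              channel_labels = mon$label, montage = mon,
              trials = data.frame(onset_sample = (seq_len(n_trials) - 1L) * 6L * fs,
                                  finger = rep(c("thumb", "index", "middle"),
                                               length.out = n_trials)))
}

# Session wrapper around an arbitrary channels x samples matrix.
matrix_session <- function(data, fs = 250) {
  mon <- default_montage(32)[seq_len(nrow(data)), ]
  new_session(data = data, sampling_rate_hz = fs,
              channel_labels = mon$label, montage = mon,
              trials = data.frame(onset_sample = integer(0),
                                  finger = character(0)))
}
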