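#' Configuration for the synthetic EEG session generator
#'
#' The generator emulates a cued finger-movement session: 6-s trials (2 s
#' blank screen, 2 s fixation/rest, 2 s movement cue), five fingers of the
#' right hand presented in seeded-random order, a 1/f background spectrum
#' with alpha and beta rhythmic peaks, movement-related event-related
#' desynchronization (ERD) of the rhythms over the contralateral motor
#' cortex, a movement-related broadband log-power offset, 60 Hz line noise
#' and additive white sensor noise.
#'
#' The spectral model per channel and condition is, in power units,
#' \deqn{P(f) = e^{s} \, B(f) \, (1 + \gamma^2 q(f)),}
#' where \eqn{B(f) = \exp(b_0 - \chi \ln f)} is the 1/f background,
#' \eqn{q(f) = \exp(a_\alpha G_\alpha(f) + a_\beta G_\beta(f)) - 1} is the
#' rhythmic excess shaped by Gaussian bumps \eqn{G} at the alpha and beta
#' centers, \eqn{\gamma \le 1} is the per-channel ERD amplitude attenuation
#' (active during movement; \eqn{\gamma = 1} at rest) and \eqn{s} is the
#' per-channel broadband log-power shift (movement only). Attenuating the
#' rhythm *amplitude* by \eqn{\gamma} scales its band power by
#' \eqn{\gamma^2}. Finger-specific signatures perturb \eqn{(s, \gamma)}
#' per finger and channel.
#'
#' @param n_channels Number of montage channels (16..64).
#' @param sampling_rate_hz Sampling rate; must be even and > 140 so that
#'   the 1-70 Hz analysis grid is below Nyquist.
#' @param trials_per_finger Trials per finger condition.
#' @param fingers Ordered condition labels.
#' @param background_exponent 1/f slope \eqn{\chi} of the log-PSD.
#' @param background_log_offset Log-power of the background at 1 Hz.
#' @param alpha_peak,beta_peak Numeric triplets
#'   `(center_hz, bandwidth_hz, log_amplitude)`; bandwidth is the Gaussian
#'   standard deviation of the bump in Hz.
#' @param rhythm_fluctuation_sd Standard deviation of the spontaneous
#'   log-power fluctuation of the rhythmic component, drawn independently
#'   per 2-s block and channel. Mu/beta rhythms wax and wane from moment
#'   to moment in real EEG; this condition-independent variability is what
#'   makes the coupled alpha+beta spectral structure a prominent variance
#'   direction. Rhythm waxing is accompanied by a small compensatory
#'   broadband decrease (the classic anticorrelation between rhythmic
#'   idling and broadband activation), scaled so that the fluctuation
#'   leaves the band-average log power unchanged to first order.
#' @param erd_map Named per-channel multiplicative amplitude attenuation in
#'   (0, 1] applied to the rhythms during movement; `NULL` uses the default
#'   motor-strip map (strongest over C3 and neighbours).
#' @param broadband_shift Named per-channel additive log-power offset
#'   during movement; `NULL` uses the default motor/premotor/parietal map.
#' @param finger_effect List with matrices `broadband` and `erd`
#'   (fingers x channels) of per-finger perturbations added to
#'   `broadband_shift` and `erd_map` during that finger's movement blocks;
#'   `NULL` uses the default somatotopic parietal-gradient signatures.
#' @param line_noise_amp Amplitude (uV) of the 60 Hz line component.
#' @param noise_sd Standard deviation (uV) of additive white noise.
#' @param seed Integer RNG seed; the whole session is deterministic in it.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_channels = 64,
                         sampling_rate_hz = 250,
                         trials_per_finger = 80,
                         fingers = c("thumb", "index", "middle", "ring", "little"),
                         background_exponent = 1.0,
                         background_log_offset = 3.0,
                         alpha_peak = c(center_hz = 10, bandwidth_hz = 1.2, log_amplitude = 2.5),
                         beta_peak = c(center_hz = 20, bandwidth_hz = 2.0, log_amplitude = 1.5),
                         rhythm_fluctuation_sd = 1.0,
                         erd_map = NULL,
                         broadband_shift = NULL,
                         finger_effect = NULL,
                         line_noise_amp = 2.0,
                         noise_sd = 0.3,
                         seed = 1L) {
  montage <- default_montage(n_channels)
  if (is.null(erd_map)) erd_map <- default_erd_map(montage)
  if (is.null(broadband_shift)) broadband_shift <- default_broadband_shift(montage)
  if (is.null(finger_effect)) finger_effect <- default_finger_effect(montage, fingers)
  cfg <- structure(list(
    n_channels = as.integer(n_channels),
    sampling_rate_hz = as.integer(sampling_rate_hz),
    trials_per_finger = as.integer(trials_per_finger),
    fingers = fingers,
    background_exponent = background_exponent,
    background_log_offset = background_log_offset,
    alpha_peak = unname(alpha_peak),
    beta_peak = unname(beta_peak),
    rhythm_fluctuation_sd = rhythm_fluctuation_sd,
    erd_map = erd_map,
    broadband_shift = broadband_shift,
    finger_effect = finger_effect,
    line_noise_amp = line_noise_amp,
    noise_sd = noise_sd,
    seed = as.integer(seed),
    montage = montage
  ), class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  fail <- function(field, why) {
    stop(sprintf("invalid synth_config field '%s': %s", field, why), call. = FALSE)
  }
  if (cfg$trials_per_finger < 1L) fail("trials_per_finger", "must be >= 1")
  if (cfg$sampling_rate_hz %% 2L != 0L || cfg$sampling_rate_hz <= 140L)
    fail("sampling_rate_hz", "must be even and > 140 (Nyquist above 70 Hz)")
  if (length(cfg$fingers) < 2L || anyDuplicated(cfg$fingers))
    fail("fingers", "need >= 2 distinct labels")
  for (pk in c("alpha_peak", "beta_peak")) {
    p <- cfg[[pk]]
    if (length(p) != 3L || !is.numeric(p)) fail(pk, "must be numeric (center, bandwidth, log_amplitude)")
    if (p[2] <= 0) fail(pk, "bandwidth must be > 0")
  }
  n <- cfg$n_channels
  labs <- cfg$montage$label
  for (mp in c("erd_map", "broadband_shift")) {
    v <- cfg[[mp]]
    if (length(v) != n || !identical(names(v), labs))
      fail(mp, "must be named per montage channel")
  }
  if (any(cfg$erd_map <= 0) || any(cfg$erd_map > 1))
    fail("erd_map", "attenuation factors must lie in (0, 1]")
  fe <- cfg$finger_effect
  nf <- length(cfg$fingers)
  for (part in c("broadband", "erd")) {
    m <- fe[[part]]
    if (!is.matrix(m) || !identical(dim(m), c(nf, n)))
      fail("finger_effect", sprintf("'%s' must be a fingers x channels matrix", part))
  }
  if (cfg$noise_sd < 0) fail("noise_sd", "must be >= 0")
  if (cfg$rhythm_fluctuation_sd < 0) fail("rhythm_fluctuation_sd", "must be >= 0")
  if (cfg$line_noise_amp < 0) fail("line_noise_amp", "must be >= 0")
  invisible(cfg)
}

default_erd_map <- function(montage) {
  nb <- attr(montage, "neighbors")
  v <- rep(1.0, nrow(montage))
  names(v) <- montage$label
  left <- intersect(c("C3", nb$C3), montage$label)
  right <- intersect(c("C4", nb$C4), montage$label)
  v[left] <- 0.30
  v[right] <- 0.40
  v[intersect(c("FCz", "Cz", "CPz"), montage$label)] <- 0.50
  v[intersect(c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8"),
              montage$label)] <- 0.55
  v
}

default_broadband_shift <- function(montage) {
  nb <- attr(montage, "neighbors")
  v <- rep(0.0, nrow(montage))
  names(v) <- montage$label
  v[intersect(c("C3", nb$C3), montage$label)] <- 0.50
  v[intersect(c("C4", nb$C4), montage$label)] <- 0.25
  v[intersect(c("FCz", "F3", "F1", "Fz"), montage$label)] <- 0.25
  v[intersect(c("P5", "P3", "P1", "Pz", "P2"), montage$label)] <- 0.35
  v
}

# Somatotopic-style finger signatures: each finger adds a broadband bump on
# one channel of the left/central parietal row (plus a smaller spill-over on
# the row neighbours), deliberately outside the C3 neighbourhood so the
# finger information is carried by spectral-PC features rather than by the
# fixed mu/beta channel set.
default_finger_effect <- function(montage, fingers,
                                  magnitude = 0.5, spill = 0.25) {
  labs <- montage$label
  nf <- length(fingers)
  centers <- c("P7", "P3", "Pz", "P4", "P8")
  centers <- rep_len(centers, nf)
  bb <- matrix(0, nf, length(labs), dimnames = list(fingers, labs))
  erd <- matrix(0, nf, length(labs), dimnames = list(fingers, labs))
  row_order <- c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8")
  for (i in seq_len(nf)) {
    ci <- match(centers[i], row_order)
    for (j in seq_along(row_order)) {
      ch <- row_order[j]
      if (!(ch %in% labs)) next
      d <- abs(j - ci)
      if (d == 0) bb[i, ch] <- bb[i, ch] + magnitude
      else if (d == 1) bb[i, ch] <- bb[i, ch] + spill
    }
  }
  list(broadband = bb, erd = erd)
}

# Expected one-sided PSD (power units) of the generative model at
# frequencies f (Hz) for one channel: broadband shift `shift` (log units)
# and rhythm amplitude attenuation `atten`. The spontaneous rhythm
# fluctuation e^z (z ~ N(0, sd^2)) enters through its mean e^{sd^2/2}.
model_psd <- function(cfg, f, shift = 0, atten = 1) {
  fc <- pmax(f, 0.25)
  bg <- exp(cfg$background_log_offset - cfg$background_exponent * log(fc))
  q <- rhythm_excess(cfg, f) * exp(cfg$rhythm_fluctuation_sd^2 / 2)
  exp(shift) * bg * (1 + atten^2 * q)
}

# Saturating rhythm fraction on the 1-70 Hz grid (expected, i.e. with the
# lognormal mean factor of the fluctuation applied), and the broadband
# compensation coefficient kappa that makes the fluctuation direction
# (fraction - kappa) sum to zero across the band.
rhythm_fraction <- function(cfg) {
  q <- rhythm_excess(cfg, 1:70) * exp(cfg$rhythm_fluctuation_sd^2 / 2)
  sat <- q / (1 + q)
  list(sat = sat, kappa = mean(sat))
}

# Rhythmic excess q(f) = exp(alpha bump + beta bump) - 1 (>= 0).
rhythm_excess <- function(cfg, f) {
  a <- cfg$alpha_peak; b <- cfg$beta_peak
  bump <- a[3] * exp(-(f - a[1])^2 / (2 * a[2]^2)) +
          b[3] * exp(-(f - b[1])^2 / (2 * b[2]^2))
  exp(bump) - 1
}

# Per-condition effective (shift, attenuation) for every channel.
condition_effects <- function(cfg, condition) {
  n <- cfg$n_channels
  if (condition == "rest") {
    return(list(shift = rep(0, n), atten = rep(1, n)))
  }
  i <- match(condition, cfg$fingers)
  if (is.na(i)) stop(sprintf("unknown condition '%s'", condition), call. = FALSE)
  shift <- cfg$broadband_shift + cfg$finger_effect$broadband[i, ]
  atten <- pmin(pmax(cfg$erd_map + cfg$finger_effect$erd[i, ], 0.01), 1)
  list(shift = unname(shift), atten = unname(atten))
}

#' Planted spectral ground truth of a synthetic configuration
#'
#' Returns the unit-norm spectral profiles planted by the generator on the
#' 1-70 Hz analysis grid -- the flat broadband profile and the coupled
#' alpha+beta rhythm-modulation profile -- together with the expected
#' per-condition, per-channel log-power curves. These are the oracles for
#' structure-recovery tests: the spectral PCA of a generated session should
#' span both profiles.
#'
#' The coupled profile is the normalized band-balanced rhythm direction
#' \eqn{q(f)/(1+q(f)) - \kappa} (the saturating rhythm fraction minus its
#' band mean \eqn{\kappa}), the frequency shape along which the spontaneous
#' rhythm fluctuation -- and, up to a broadband admixture, the movement
#' ERD -- moves the log spectrum.
#'
#' @param config A `synth_config`.
#' @return A `ground_truth` list with elements `freq` (1..70),
#'   `broadband_profile`, `coupled_profile` (both unit norm, length 70) and
#'   `expected_log_psd` (condition x channel x frequency array).
#' @export
ground_truth_profiles <- function(config) {
  validate_synth_config(config)
  f <- 1:70
  broadband <- rep(1, 70) / sqrt(70)
  rf <- rhythm_fraction(config)
  cp <- rf$sat - rf$kappa
  coupled <- cp / sqrt(sum(cp^2))
  conds <- c("rest", config$fingers)
  exp_lp <- array(NA_real_, dim = c(length(conds), config$n_channels, 70),
                  dimnames = list(conds, config$montage$label, NULL))
  for (cd in conds) {
    ef <- condition_effects(config, cd)
    for (n in seq_len(config$n_channels)) {
      exp_lp[cd, n, ] <- log(model_psd(config, f, ef$shift[n], ef$atten[n]))
    }
  }
  structure(list(freq = f, broadband_profile = broadband,
                 coupled_profile = coupled, expected_log_psd = exp_lp),
            class = "ground_truth")
}

# Synthesize one 2-s block for all channels: inverse-FFT colored noise with
# seeded random phases, shaped so that the rectangular-window periodogram
# (1/L)|DFT|^2 of the block equals the target PSD at every interior bin.
# `amp` is an (L/2 - 1) x N matrix of target DFT amplitudes.
synth_block <- function(amp, L, n_channels) {
  half <- L / 2
  ph <- matrix(stats::runif((half - 1) * n_channels, 0, 2 * pi),
               half - 1, n_channels)
  X <- matrix(0i, L, n_channels)
  X[2:half, ] <- amp * exp(1i * ph)
  X[(half + 2):L, ] <- Conj(X[half:2, , drop = FALSE])
  Re(stats::mvfft(X, inverse = TRUE)) / L
}

#' Generate a synthetic EEG session with ground truth
#'
#' Produces a continuous multichannel recording of
#' `5 * trials_per_finger` 6-s trials in seeded-random finger order. Each
#' trial is three 2-s blocks: blank (rest spectrum), fixation (rest
#' spectrum), movement cue (the finger's movement spectrum with ERD
#' attenuation and broadband shift applied). Each block is colored noise
#' realized by inverse FFT of the target amplitude spectrum with random
#' phases, with a short raised-cosine taper (about 10 ms) at block edges to
#' avoid boundary discontinuities; a continuous 60 Hz sinusoid and white
#' noise are added on top. The output is bit-reproducible given the
#' config's seed.
#'
#' @param config A `synth_config`.
#' @return A list with elements `session` (an `eeg_session`) and
#'   `ground_truth` (see [ground_truth_profiles()]).
#' @export
generate_session <- function(config) {
  validate_synth_config(config)
  cfg <- config
  fs <- cfg$sampling_rate_hz
  L <- 2L * fs                       # one 2-s block
  trial_len <- 3L * L
  n <- cfg$n_channels
  n_trials <- cfg$trials_per_finger * length(cfg$fingers)
  total <- n_trials * trial_len

  conds <- c("rest", cfg$fingers)
  half <- L / 2
  f_bins <- (1:(half - 1)) * fs / L
  # per-condition target power split into background and rhythm parts,
  # (half-1) x N each; the rhythm part is scaled by e^z per block/channel
  fc <- pmax(f_bins, 0.25)
  bg_curve <- exp(cfg$background_log_offset - cfg$background_exponent * log(fc))
  q_curve <- rhythm_excess(cfg, f_bins)
  parts <- lapply(conds, function(cd) {
    ef <- condition_effects(cfg, cd)
    bgp <- outer(bg_curve, exp(ef$shift))
    rhy <- bgp * outer(q_curve, ef$atten^2)
    list(bg = bgp, rhythm = rhy)
  })
  names(parts) <- conds

  kappa_z <- rhythm_fraction(cfg)$kappa

  nc <- max(1L, round(0.01 * fs))    # ~10 ms raised-cosine edge taper
  ramp <- 0.5 * (1 - cos(pi * (seq_len(nc) - 0.5) / nc))
  taper <- rep(1, L)
  taper[seq_len(nc)] <- ramp
  taper[L - seq_len(nc) + 1L] <- ramp

  withr::with_seed(cfg$seed, {
    finger_seq <- sample(rep(cfg$fingers, each = cfg$trials_per_finger))
    data <- matrix(0, n, total)
    for (tr in seq_len(n_trials)) {
      o <- (tr - 1L) * trial_len
      block_conds <- c("rest", "rest", finger_seq[tr])
      for (b in 1:3) {
        p <- parts[[block_conds[b]]]
        z <- if (cfg$rhythm_fluctuation_sd > 0)
          stats::rnorm(n, sd = cfg$rhythm_fluctuation_sd) else numeric(n)
        pow <- sweep(p$bg, 2, exp(-kappa_z * z), "*") +
          sweep(p$rhythm, 2, exp(z), "*")
        x <- synth_block(sqrt(pow * L), L, n)   # L x N
        x <- x * taper
        data[, (o + (b - 1L) * L + 1L):(o + b * L)] <- t(x)
      }
    }
    if (cfg$line_noise_amp > 0) {
      tt <- seq_len(total) / fs
      phase <- stats::runif(n, 0, 2 * pi)
      for (ch in seq_len(n)) {
        data[ch, ] <- data[ch, ] +
          cfg$line_noise_amp * sin(2 * pi * 60 * tt + phase[ch])
      }
    }
    if (cfg$noise_sd > 0) {
      data <- data + matrix(stats::rnorm(n * total, sd = cfg$noise_sd), n, total)
    }
  })

  session <- new_session(
    data = data,
    sampling_rate_hz = fs,
    channel_labels = cfg$montage$label,
    montage = cfg$montage,
    trials = data.frame(onset_sample = (seq_len(n_trials) - 1L) * trial_len,
                        finger = finger_seq, stringsAsFactors = FALSE)
  )
  list(session = session, ground_truth = ground_truth_profiles(cfg))
}

#' Construct an EEG session container
#'
#' @param data channels x samples numeric matrix (uV).
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param channel_labels Character vector, one label per row of `data`.
#' @param montage Data frame with columns `label`, `x`, `y` (2-D layout).
#' @param trials Data frame with columns `onset_sample` (0-based) and
#'   `finger`; each trial spans 6 s from its onset.
#' @return An `eeg_session`.
#' @export
new_session <- function(data, sampling_rate_hz, channel_labels, montage, trials) {
  stopifnot(is.matrix(data), nrow(data) == length(channel_labels))
  trial_len <- 6L * sampling_rate_hz
  if (nrow(trials) > 0 && any(trials$onset_sample + trial_len > ncol(data)))
    stop("trial extends past end of recording", call. = FALSE)
  structure(list(data = data,
                 sampling_rate_hz = as.integer(sampling_rate_hz),
                 channel_labels = channel_labels,
                 montage = montage,
                 trials = trials),
            class = "eeg_session")
}

#' @export
print.eeg_session <- function(x, ...) {
  cat(sprintf("<eeg_session> %d channels x %d samples @ %d Hz, %d trials\n",
              nrow(x$data), ncol(x$data), x$sampling_rate_hz, nrow(x$trials)))
  invisible(x)
}
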