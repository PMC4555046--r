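---
title: "Cross-frequency spectral structures as EEG decoding features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-frequency spectral structures as EEG decoding features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spectralbci)
```

## The model

EEG power spectra during a motor task are not independent frequency bins:
rhythmic activity in the mu (8–12 Hz) and beta (13–30 Hz) bands waxes and
wanes together, and movement adds a broadband, non-rhythmic power shift.
This package treats the *log-normalized power spectrum of a 1-s segment*
as the observation and asks which cross-frequency directions carry its
variance. Concretely:

1. **Periodogram** (`compute_psd`). Each segment and channel is windowed
   with $H(t) = (1+\cos(2\pi t/T))/2$ and Fourier transformed;
   $P^m_n(f) = \frac{1}{T}\lvert\sum_t X^m_n(t)H(t)e^{i2\pi f t/T}\rvert^2$
   is kept at $f = 1\ldots70$ Hz. For 1-s segments at 250 Hz the grid
   resolution is exactly 1 Hz, so bin $k$ *is* $k$ Hz. No window-power
   compensation is applied; every downstream quantity (log differences,
   PCA directions, $r^2$, scaled features) is invariant to that constant.
2. **Log normalization** (`log_normalize`).
   $\tilde P^m_n(f) = \ln P^m_n(f) - \ln\bigl(\tfrac1M\sum_m P^m_n(f)\bigr)$,
   the reference mean pooling movement and rest segments, so increases and
   decreases relative to the session mean scale symmetrically.
3. **Spectral PCA** (`spectral_covariance`, `eigendecompose`). The
   covariance $C(f,f') = \sum_{m,n}\tilde P^m_n(f)\tilde P^m_n(f')$ pools
   every (segment, channel) pair as one observation — the only reading
   under which a single basis $e_k$ can be applied at every channel, which
   is how the projection step uses it. The sum is a literal second moment
   (no further centering): the log normalization already references the
   mean spectrum. A consequence worth knowing is that the mean
   log-deviation (a flat, negative, Jensen-type offset: the mean of logs
   sits below the log of the mean) dominates the first eigenvector, which
   is why PC1 is reliably the flat *broadband* direction.
4. **Projection features** (`project`).
   $W^m_{n,k} = \sum_f e_k(f)\tilde P^m_n(f)$, the same basis at all
   channels; $K = 3$ components by default.
5. **Discriminability and selection** (`r_squared`, `rsq_topography`,
   `select_channels`). The group statistic uses the *population* SD of the
   pooled sample, which makes it exactly the point-biserial Pearson
   correlation with a binary condition indicator; channels are ranked by
   $r^2$ per condition pair, the top 10 kept, unions taken across pairs.
   Mu/beta band-power features instead use the fixed anatomical set
   C3 + 8 neighbours (contralateral to right-hand movement;
   `mu_beta_channels`).
6. **Decoding** (`cross_validate`). RBF-kernel soft-margin SVM (LIBSVM via
   e1071), cost and gamma from base-2 exponent grids $-10..20$ and
   $-15..10$ (806 pairs), features scaled to $[-1,1]$ on the training
   portion only, one-vs-one majority voting for the 5-class task with ties
   broken by summed signed decision values then smallest class index, and
   30 repeats of seeded stratified 5-fold cross-validation.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| analysis grid | 1–70 Hz, 1 Hz | spectral support of all features |
| bands | alpha 8–12, beta 13–30 Hz (bin means) | classic rhythm features |
| `K` | 3 | retained spectral PCs |
| `top_n` | 10 | channels kept per $r^2$ map |
| folds × repeats | 5 × 30 | outer CV shape |
| grid exponents | cost $2^{-10..20}$, gamma $2^{-15..10}$ | SVM search space |
| `floor_eps` | 1e-20 | PSD floor before logs (notch nulls, silence) |

Design choices that were genuinely open, and how they were settled:

* **Grid exponent base**: 2, the convention of the grid-search methodology
  the ranges come from (the printed ranges match that convention).
* **Kernel**: Gaussian RBF; a kernel-width grid only exists for RBF.
* **Model selection**: inner 5-fold CV on each outer training fold; the
  optimistic variant (select on the outer test fold) is not implemented.
* **Channel selection and leakage**: by default $r^2$ ranking is computed
  *inside each training fold* (`top_n` argument of `cross_validate`), so
  selection cannot leak test information; `selection_mode = "all"` in
  `run_config` reproduces the optimistic all-data variant for comparison.
* **Eigenvector sign**: flipped so the mean over the 8–12 Hz bins is
  $\ge 0$ (ties: largest-magnitude component positive) — purely a
  reporting convention, features are sign-covariant.
* **$r^2$ ties in ranking**: stable order by channel index, for
  determinism.
* **Paired accuracy comparisons** (`compare_accuracies`) use per-repeat
  mean accuracies (n = 30) as the matched unit; at desk scale there are no
  independent subjects, so these p-values characterize the synthetic
  session at hand, not a population.

## The synthetic-data generator

Human recordings behind this method are not deposited, so the generator
(`synth_config`, `generate_session`) emulates the study conditions: 6-s
trials (2 s blank, 2 s fixation, 2 s cue), five right-hand fingers × 80
trials in seeded random order, 250 Hz, 64 channels on a 10-10-style
montage with an annotated C3/C4 neighbourhood.

Per channel and condition the target spectrum is, in power units,

$$P(f) = e^{s}\,B(f)\,\bigl(1 + \gamma^2\,q(f)\,e^{z}\bigr),$$

with $B(f) = \exp(b_0 - \chi\ln f)$ the 1/f background ($\chi = 1$,
$b_0 = 3$), $q(f) = \exp(a_\alpha G_\alpha + a_\beta G_\beta) - 1$ the
rhythmic excess (Gaussian bumps at 10 and 20 Hz, SDs 1.2 and 2.0 Hz,
log-amplitudes 2.5 and 1.5), $\gamma$ the per-channel ERD amplitude
attenuation (movement only; band power scales as $\gamma^2$), $s$ the
per-channel movement broadband log-shift, and $z \sim N(0, 1)$ a
per-block, per-channel *spontaneous rhythm fluctuation*. Rhythm waxing is
accompanied by a small compensatory broadband decrease ($e^{-\kappa z}$ on
$B$, $\kappa$ = band mean of the saturating rhythm fraction), emulating
the classic anticorrelation between rhythmic idling and broadband
activation; it makes the fluctuation direction band-balanced in log power.
Signals are realized per 2-s block by inverse FFT of the target amplitude
spectrum with seeded random phases (10 ms raised-cosine edge tapers), plus
a continuous 60 Hz line sinusoid and white noise.

Default effect maps: deep bilateral ERD ($\gamma$ = 0.30 over C3 and
neighbours, 0.40 over C4's, 0.50 midline, 0.55 parietal row — strong but
within the range reported for executed movement), broadband shifts of
0.25–0.50 log units over motor/premotor/parietal channels, and
finger-specific broadband bumps (0.5, spill-over 0.25) at P7/P3/Pz/P4/P8
— a somatotopic parietal gradient placed deliberately *outside* the C3
neighbourhood, so finger identity is visible to spectral-PC features but
not to the fixed mu/beta channel set. Effect magnitudes are free
parameters of the emulation, not estimates from any dataset.

`ground_truth_profiles` returns the two planted unit-norm spectral
directions on the 1–70 Hz grid — the flat broadband profile and the
band-balanced coupled rhythm direction $q̃/(1+q̃) - \kappa$ (with the
lognormal mean factor $e^{\sigma_z^2/2}$ applied to $q$) — plus expected
per-condition log-power curves. Recovery tests demand
$\lvert\cos\rvert \ge 0.9$ between each planted profile and some top-3
eigenvector. Two geometric facts shaped the generator design and are
worth recording: (i) since PC1 is pinned to the flat direction by the
uncentered second moment, an eigenvector can only align with a second
planted profile to $\sqrt{1-\cos^2(\text{flat},\text{profile})}$, so a
one-signed bump profile (flat-cosine ≈ 0.4) is unrecoverable at 0.9 by
*any* orthogonal decomposition — hence the band-balanced fluctuation
direction; (ii) the Hann kernel correlates adjacent periodogram bins,
inflating the covariance noise floor ~70% above the iid prediction, which
sets how much planted variance the coupled structure needs to emerge.

## What the generator does not emulate

No ocular/muscle artifacts, electrode drift, volume conduction / forward
modeling, inter-subject variability, non-stationary baselines, or
behavioral finger co-movement. Tests passing on synthetic sessions
demonstrate that the pipeline's inference machinery is correct and
calibrated (null sessions decode at chance; planted structure is
recovered); they do not certify the accuracies achievable on real EEG,
which depend on artifact handling and physiology outside this model.

## Numerical choices

* PSD floor `1e-20` before logs (notch nulls and silent channels).
* Eigenvalues in $[-10^{-10}, 0)$ clipped to 0; larger negatives error.
* Zero-phase filtering pads with odd reflection (10 s) and steady-state
  initial conditions before the forward and reverse passes; the 0.3 Hz
  high-pass and the 0.3 Hz-transition notch have multi-second transients,
  which this keeps out of the data (settling is exact for constant
  inputs). Filters are 4th-order elliptic with 0.02 dB passband ripple and
  40 dB stopband: the small ripple keeps the double-pass passband within
  1% amplitude, which a conventional 0.5 dB design would violate.
* Constant features scale to 0; test values may extrapolate beyond
  $[-1, 1]$.
* Grid-search ties resolve to the earliest grid row (cost-major order);
  all partitions are seeded; the full pipeline is bit-reproducible.

## Problem sizes used in the shipped checks

Module tests run on miniature sessions (16–48 channels, 2–10 trials per
finger). The end-to-end property checks use: profile recovery at 64
channels × 20 trials/finger; null calibration at 64 × 20 with 150 CV
folds (5 × 30) and a reduced 2 × 2 hyperparameter grid; the
feature-family ordering comparison at 64 × 30 with 5 × 6 folds and a
3 × 3 grid, milder ERD ($\gamma$ 0.6–0.8) and a softened broadband map so
that no feature family saturates at ceiling. These sizes were chosen so
each property is measured with comfortable statistical margin on a single
CPU; the counting contracts use the full 80-trials-per-finger manifest.

## Known limitations

* One covariance per session: per-channel bases (an alternative reading
  of the channel index in the covariance) are deliberately not offered.
* The paired t-test helper treats CV repeats as matched units; repeats
  share one dataset, so its p-values are optimistic relative to
  subject-level replication.
* EDF import is not implemented; any recording mapped into the
  float32 + JSON session container (`write_session`/`read_session`) can
  enter the pipeline.
* The notch/high-pass transients require ~15 s of recording on each end;
  sessions shorter than ~1 min should be filtered with caution.
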