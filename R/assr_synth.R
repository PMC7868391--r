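#' ASSR experiment protocol
#'
#' Study conditions of the simulated auditory steady-state response (ASSR)
#' experiment: 120 one-second 43-Hz click trains per subject with randomized
#' 2-4 s inter-stimulus intervals, sampled at 1 kHz. Each train evokes three
#' components: an early high-frequency thalamic burst at 5-9 ms, a late slow
#' wave peaking near 350 ms, and 43-Hz entrainment from 400 ms to the end of
#' the train at bilateral auditory sources.
#'
#' Component amplitudes are sensor-level peak amplitudes in the recording's
#' (microvolt-like) units; each component's lead-field pattern is scaled to
#' unit channel RMS and its time course to unit peak, so amplitudes are
#' directly comparable to the background noise RMS.
#'
#' @param n_subjects number of subjects
#' @param n_trials click trains per subject (default 120)
#' @param train_duration train length, s
#' @param isi_range inter-stimulus interval range, s
#' @param stim_freq stimulation frequency, Hz (default 43)
#' @param fs sampling rate, Hz
#' @param amplitudes named vector: sensor peak amplitudes of the `thalamic`,
#'   `late` and `entrainment` components
#' @param amplitude_cv between-subject lognormal coefficient of variation
#' @param noise_rms total background noise RMS per channel (1/f + white,
#'   equal power)
#' @param entrain_onset entrainment onset after train start, s (with a 50-ms
#'   raised-cosine ramp)
#' @param artifact_spec artifact injection spec (see [inject_artifacts()]);
#'   `NULL` disables injection
#' @param seed master seed
#' @export
assr_protocol <- function(n_subjects = 20, n_trials = 120, train_duration = 1,
                          isi_range = c(2, 4), stim_freq = 43, fs = 1000,
                          amplitudes = c(thalamic = 4, late = 15,
                                         entrainment = 6),
                          amplitude_cv = 0.3, noise_rms = 10,
                          entrain_onset = 0.4, artifact_spec = NULL,
                          seed = 1) {
  assert_that(stim_freq < fs / 2, "component frequency must be below Nyquist")
  structure(list(n_subjects = n_subjects, n_trials = n_trials,
                 train_duration = train_duration, isi_range = isi_range,
                 stim_freq = stim_freq, fs = fs, amplitudes = amplitudes,
                 amplitude_cv = amplitude_cv, noise_rms = noise_rms,
                 entrain_onset = entrain_onset, artifact_spec = artifact_spec,
                 seed = seed),
            class = "assr_protocol")
}

#' Default component source dipoles for the ASSR generator
#'
#' Thalamic component: the dipole nearest the deep (diencephalic) region
#' centroid. Late slow wave: two shallow frontal/central dipoles. 43-Hz
#' entrainment: two shallow bilateral dipoles over the temporal ("auditory")
#' positions.
#'
#' @param grid a `source_grid`
#' @return named list of grid index vectors
#' @export
assr_sources <- function(grid) {
  pos <- grid$pos
  ztop <- stats::quantile(pos[, 3], 0.98)
  nearest <- function(target, pool = seq_len(grid$P)) {
    pool[which.min(rowSums(sweep(pos[pool, , drop = FALSE], 2, target)^2))]
  }
  deep_pool <- if (any(grid$label == 2L)) which(grid$label == 2L) else
    seq_len(grid$P)
  thal <- deep_pool[which.min(rowSums(
    sweep(pos[deep_pool, , drop = FALSE], 2,
          colMeans(pos[deep_pool, , drop = FALSE]))^2))]
  shallow <- which(pos[, 3] >= ztop - 2)
  list(
    thalamic = thal,
    late = c(nearest(c(-2.5, 3, ztop - 1), shallow),
             nearest(c(2.5, 3, ztop - 1), shallow)),
    entrainment = c(nearest(c(-5.5, -3.6, ztop - 2), shallow),
                    nearest(c(5.5, -3.6, ztop - 2), shallow)))
}

# Component moment time courses over one train; unit-RMS normalized later.
# The thalamic burst carrier sits at 300 Hz (mid high-frequency band, clear
# of the 110-130 Hz artifact-detection band); `phase` decorrelates the
# entrainment oscillation between hemispheres / trials.
assr_component_tc <- function(name, n, fs, stim_freq, entrain_onset,
                              phase = 0) {
  tt <- (seq_len(n) - 1) / fs
  switch(name,
    thalamic = {
      env <- exp(-(tt - 0.007)^2 / (2 * 0.0012^2))
      env * sin(2 * pi * 300 * tt)
    },
    late = {
      env <- exp(-(tt - 0.35)^2 / (2 * 0.06^2))
      env * (tt >= 0.10 & tt <= 0.60)
    },
    entrainment = {
      ramp <- pmin(1, pmax(0, (tt - entrain_onset) / 0.05))
      ramp <- (1 - cos(pi * ramp)) / 2
      ramp * sin(2 * pi * stim_freq * (tt - entrain_onset) + phase)
    },
    stopf("unknown component '%s'", name))
}

# 1/f (power slope -1) noise via spectral shaping, unit variance.
pink_noise <- function(n, n_ch) {
  m0 <- stats::nextn(n)
  m <- matrix(rnorm(m0 * n_ch), m0, n_ch)
  ft <- stats::mvfft(m)
  f <- c(1, seq_len(m0 - 1))
  f <- pmin(f, m0 - f + 1)              # symmetric frequency index
  ft <- ft / sqrt(f)
  out <- Re(stats::mvfft(ft, inverse = TRUE))[seq_len(n), , drop = FALSE] / m0
  scale(out, center = FALSE, scale = apply(out, 2, stats::sd))
}

#' Generate a synthetic multi-subject ASSR dataset
#'
#' Per subject: a continuous multichannel recording with event-locked
#' thalamic, late and entrainment components projected through the lead
#' field at fixed source dipoles, on top of per-channel 1/f-plus-white
#' background noise; between-subject amplitude variability is lognormal.
#' Optionally injects ground-truth artifacts. Bit-identical under the
#' protocol seed.
#'
#' @param lf a `lead_field`
#' @param protocol an [assr_protocol()]
#' @param sources component dipoles (default [assr_sources()] on the grid)
#' @return list of subjects, each `list(rec, truth)` where `truth` holds the
#'   component dipole indices, event onsets and the artifact mask (if any)
#' @export
generate_assr_dataset <- function(lf, protocol = assr_protocol(),
                                  sources = assr_sources(lf$grid)) {
  K <- lf$K
  fs <- protocol$fs
  n_train <- round(protocol$train_duration * fs)
  lapply(seq_len(protocol$n_subjects), function(subj) {
    with_seed(substream_seed(protocol$seed, 50, subj), {
      isi <- runif(protocol$n_trials, protocol$isi_range[1],
                   protocol$isi_range[2])
      onsets <- round(cumsum(c(2, head(isi, -1) + protocol$train_duration)) * fs)
      n_total <- max(onsets) + n_train + 2 * fs
      N <- nrow(K)

      noise <- t(pink_noise(n_total, N)) * (protocol$noise_rms / sqrt(2)) +
        matrix(rnorm(N * n_total, sd = protocol$noise_rms / sqrt(2)),
               N, n_total)
      X <- noise

      subj_amp <- exp(rnorm(length(protocol$amplitudes),
                            sd = sqrt(log(1 + protocol$amplitude_cv^2))))
      names(subj_amp) <- names(protocol$amplitudes)

      # Per-source unit-channel-RMS patterns (dorsoventral moment axis).
      comp_pat <- lapply(sources, function(dipoles) {
        vapply(dipoles, function(p) {
          u <- K[, 3 * (p - 1) + 3]
          u / sqrt(mean(u^2))
        }, numeric(N))
      })
      amp_of <- function(nm) protocol$amplitudes[[nm]] * subj_amp[[nm]]
      unit_peak <- function(tc) tc / max(abs(tc), .Machine$double.eps)

      # Deterministic single-source components share one time course per
      # subject; the bilateral entrainment pair is dominantly unilateral
      # (right 1 : left 0.6) with independent per-trial phase jitter per
      # hemisphere, so the two sources are only partially coherent, as in
      # real steady-state responses.
      fixed_tc <- lapply(c("thalamic", "late"), function(nm) {
        unit_peak(assr_component_tc(nm, n_train, fs, protocol$stim_freq,
                                    protocol$entrain_onset)) * amp_of(nm)
      })
      names(fixed_tc) <- c("thalamic", "late")
      hemi_gain <- c(0.6, 1)[seq_along(sources$entrainment)]

      for (e in onsets) {
        idx <- e:(e + n_train - 1)
        for (nm in c("thalamic", "late")) {
          pat <- rowMeans(comp_pat[[nm]])
          X[, idx] <- X[, idx] + pat %o% fixed_tc[[nm]]
        }
        for (h in seq_along(sources$entrainment)) {
          tc <- unit_peak(assr_component_tc(
            "entrainment", n_train, fs, protocol$stim_freq,
            protocol$entrain_onset, phase = rnorm(1, sd = 0.6))) *
            amp_of("entrainment") * hemi_gain[h]
          X[, idx] <- X[, idx] + comp_pat$entrainment[, h] %o% tc
        }
      }

      rec <- sensor_recording(X, fs, channels = lf$channels,
                              events = tibble::tibble(sample = onsets,
                                                      code = "train43"),
                              units = "uV")
      truth <- list(sources = sources, onsets = onsets,
                    subject_amplitude = subj_amp, artifact_mask = NULL)
      if (!is.null(protocol$artifact_spec)) {
        inj <- inject_artifacts(rec, protocol$artifact_spec)
        rec <- inj$rec
        truth$artifact_mask <- inj$mask
      }
      list(rec = rec, truth = truth)
    })
  })
}

#' Inject ground-truth artifacts into a recording
#'
#' Adds high-amplitude broadband noise bursts (which cover the 110-130 Hz
#' detection band and produce extreme peak-to-peak excursions) at random
#' times, and returns the recording together with the exact injected
#' intervals as the ground-truth mask. Uses the current RNG state.
#'
#' @param rec a `sensor_recording`
#' @param spec list: `rate_per_min` (bursts per minute), `duration` (s),
#'   `amplitude` (burst RMS as a multiple of the recording's channel RMS)
#' @return list with the modified `rec` and `mask` tibble (`start`, `end`
#'   samples, inclusive)
#' @export
inject_artifacts <- function(rec, spec = list(rate_per_min = 2,
                                              duration = 0.25,
                                              amplitude = 15)) {
  n <- ncol(rec$data)
  n_art <- round(spec$rate_per_min * n / rec$fs / 60)
  if (n_art < 1) {
    return(list(rec = rec, mask = tibble::tibble(start = integer(0),
                                                 end = integer(0))))
  }
  dur <- round(spec$duration * rec$fs)
  base_rms <- sqrt(mean(rec$data^2))
  starts <- sort(sample.int(n - dur, n_art))
  X <- rec$data
  for (s in starts) {
    idx <- s:(s + dur - 1)
    burst <- matrix(rnorm(nrow(X) * dur), nrow(X)) *
      (spec$amplitude * base_rms)
    win <- sin(pi * seq_along(idx) / length(idx))^2
    X[, idx] <- X[, idx] + burst * rep(win, each = nrow(X))
  }
  rec$data <- X
  list(rec = rec,
       mask = tibble::tibble(start = starts, end = starts + dur - 1L))
}
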