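#' Detect artifact-contaminated trials
#'
#' Three criteria, applied to the paired (prestimulus + stimulus) window of
#' each trial: (i) the recording is bandpass filtered at 110-130 Hz, the
#' channel-averaged analytic (Hilbert) envelope is z-scored over time, and
#' trials containing samples above `z_thresh` are flagged; (ii) trials whose
#' peak-to-peak amplitude on any channel exceeds `ptp_limit` are flagged;
#' (iii) trials overlapping manually marked intervals are flagged.
#'
#' @param rec a `sensor_recording`
#' @param events trial onset samples (default: the recording's events)
#' @param z_thresh envelope z-score threshold (> 0)
#' @param ptp_limit peak-to-peak amplitude limit (same units as the data)
#' @param manual optional tibble of manually marked intervals
#'   (`start`, `end` samples)
#' @return tibble: `trial`, `onset`, `bad`, `reason`
#' @export
detect_artifact_segments <- function(rec, events = NULL, z_thresh = 4,
                                     ptp_limit = Inf, manual = NULL) {
  assert_that(z_thresh > 0, "z_thresh must be positive")
  onsets <- events %||% rec$events$sample
  fs <- rec$fs
  n <- ncol(rec$data)
  assert_that(n > 6 * fs / 110, "recording shorter than the filter warm-up")

  bf <- signal::butter(4, c(110, 130) / (fs / 2), type = "pass")
  filt <- fd_filtfilt(rec$data, bf)
  env <- rowMeans(vapply(seq_len(nrow(filt)), function(ch) {
    Mod(analytic_signal(filt[ch, ]))
  }, numeric(n)))
  z <- (env - mean(env)) / sd(env)

  purrr::map_dfr(seq_along(onsets), function(tr) {
    e <- onsets[tr]
    idx <- max(1, e - fs):min(n, e + fs - 1)
    reasons <- character(0)
    if (any(z[idx] > z_thresh)) reasons <- c(reasons, "envelope")
    ptp <- max(apply(rec$data[, idx, drop = FALSE], 1,
                     function(x) diff(range(x))))
    if (ptp > ptp_limit) reasons <- c(reasons, "peak-to-peak")
    if (!is.null(manual) && nrow(manual) > 0 &&
        any(manual$start <= max(idx) & manual$end >= min(idx))) {
      reasons <- c(reasons, "manual")
    }
    tibble::tibble(trial = tr, onset = e, bad = length(reasons) > 0,
                   reason = paste(reasons, collapse = "+"))
  })
}

# Analytic signal via frequency-domain Hilbert transform. The signal is
# reflect-padded to an FFT-friendly length (R's FFT is slow for lengths with
# large prime factors) and cropped back.
analytic_signal <- function(x) {
  n <- length(x)
  m <- stats::nextn(n + min(n, 2048))
  xp <- c(x, rev(x)[seq_len(m - n)])
  ft <- fft(xp)
  h <- numeric(m)
  if (m %% 2 == 0) {
    h[c(1, m / 2 + 1)] <- 1
    h[2:(m / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((m + 1) / 2)] <- 2
  }
  (fft(ft * h, inverse = TRUE) / m)[seq_len(n)]
}

# Frequency response of a digital IIR filter at m equispaced frequencies.
iir_freq_response <- function(bf, m) {
  w <- 2 * pi * (seq_len(m) - 1) / m
  z <- exp(-1i * outer(w, seq_along(bf$b) - 1))
  num <- z %*% bf$b
  zd <- exp(-1i * outer(w, seq_along(bf$a) - 1))
  den <- zd %*% bf$a
  as.vector(num / den)
}

# Zero-phase IIR filtering of a channels x time matrix, applied in the
# frequency domain as |H|^2 (the transfer function of forward-backward
# filtering) with reflective padding. Rows are filtered simultaneously.
fd_filtfilt <- function(X, bf) {
  n <- ncol(X)
  pad <- min(n, 4096)
  m <- stats::nextn(n + 2 * pad)
  extra <- m - n - 2 * pad
  left <- X[, pad:1, drop = FALSE]
  right <- X[, n:(n - pad - extra + 1), drop = FALSE]
  Xp <- cbind(left, X, right)
  H2 <- Mod(iir_freq_response(bf, m))^2
  ft <- stats::mvfft(t(Xp))
  out <- Re(stats::mvfft(ft * H2, inverse = TRUE)) / m
  t(out)[, (pad + 1):(pad + n), drop = FALSE]
}

#' Standard preprocessing chain
#'
#' DFT notch at the line frequency (least-squares fit and subtraction of the
#' sine/cosine pair), 6th-order Butterworth low-pass (zero-phase by default),
#' and average re-referencing.
#'
#' @param rec a `sensor_recording`
#' @param notch line frequency to remove, Hz (`NULL` skips)
#' @param lowpass low-pass cutoff, Hz (`NULL` skips)
#' @param reref re-reference to the channel average
#' @param zero_phase forward-backward filtering (no phase distortion);
#'   `FALSE` gives single-pass causal filtering
#' @return the preprocessed `sensor_recording`
#' @export
preprocess_recording <- function(rec, notch = 50, lowpass = 100,
                                 reref = TRUE, zero_phase = TRUE) {
  X <- rec$data
  fs <- rec$fs
  if (!is.null(lowpass)) {
    assert_that(fs > 2 * lowpass, "fs must exceed twice the low-pass cutoff")
  }
  if (!is.null(notch)) {
    tt <- seq_len(ncol(X)) / fs
    B <- cbind(sin(2 * pi * notch * tt), cos(2 * pi * notch * tt))
    coef <- solve(crossprod(B), crossprod(B, t(X)))
    X <- X - t(B %*% coef)
  }
  if (!is.null(lowpass)) {
    bf <- signal::butter(6, lowpass / (fs / 2), type = "low")
    X <- if (zero_phase) fd_filtfilt(X, bf) else {
      t(apply(X, 1, function(x) as.numeric(signal::filter(bf, x))))
    }
  }
  if (reref) X <- sweep(X, 2, colMeans(X))
  rec$data <- X
  rec
}

# Canonical analysis windows in seconds relative to train onset.
assr_windows <- function() {
  list(prestim = c(-1, 0), early = c(0, 0.15), late = c(0.15, 0.4),
       entrainment = c(0.4, 0.95), thalamic = c(0.005, 0.009))
}

#' Segment a recording into paired prestimulus/stimulus epochs
#'
#' Cuts one-second stimulus epochs and their matched preceding one-second
#' prestimulus epochs at each event; trials flagged by the artifact mask or
#' falling too close to the recording edges are dropped (both members of the
#' pair) with a log entry.
#'
#' @param rec a `sensor_recording`
#' @param events onset samples (default: the recording's events)
#' @param bad_trials logical vector or trial indices to drop (e.g. from
#'   [detect_artifact_segments()])
#' @param windows named list of windows in seconds relative to onset
#' @return an `epoch_set`: per-trial prestim/stim matrices, window table,
#'   rejection log
#' @export
segment_epochs <- function(rec, events = NULL, bad_trials = NULL,
                           windows = assr_windows()) {
  onsets <- events %||% rec$events$sample
  fs <- rec$fs
  n <- ncol(rec$data)
  if (length(onsets) == 0) {
    warnf("no events: empty epoch set")
    return(structure(list(trials = list(), onsets = integer(0), fs = fs,
                          windows = windows,
                          log = tibble::tibble(trial = integer(0),
                                               reason = character(0))),
                     class = "epoch_set"))
  }
  if (is.logical(bad_trials)) bad_trials <- which(bad_trials)
  log <- tibble::tibble(trial = integer(0), reason = character(0))
  trials <- list()
  keep_onsets <- integer(0)
  for (tr in seq_along(onsets)) {
    e <- onsets[tr]
    if (tr %in% bad_trials) {
      log <- dplyr::bind_rows(log, tibble::tibble(trial = tr,
                                                  reason = "artifact"))
      next
    }
    if (e - fs < 1 || e + fs - 1 > n) {
      log <- dplyr::bind_rows(log, tibble::tibble(trial = tr,
                                                  reason = "edge"))
      next
    }
    trials[[length(trials) + 1]] <- list(
      pre = rec$data[, (e - fs):(e - 1), drop = FALSE],
      stim = rec$data[, e:(e + fs - 1), drop = FALSE])
    keep_onsets <- c(keep_onsets, e)
  }
  structure(list(trials = trials, onsets = keep_onsets, fs = fs,
                 windows = windows, log = log),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d paired trials @ %g Hz (%d rejected)\n",
              length(x$trials), x$fs, nrow(x$log)))
  invisible(x)
}

# Matched stimulus/prestimulus segment lists for one window tag. The
# prestimulus counterpart occupies the same relative samples within the
# prestimulus second.
epoch_window_pair <- function(ep, tag) {
  w <- ep$windows[[tag]]
  assert_that(!is.null(w), "unknown window tag '%s'", tag)
  fs <- ep$fs
  if (tag == "prestim") w <- c(0, 1) else assert_that(w[2] > w[1], "bad window")
  i0 <- round(w[1] * fs) + 1
  i1 <- round(w[2] * fs)
  stim <- lapply(ep$trials, function(tr) tr$stim[, i0:i1, drop = FALSE])
  pre <- lapply(ep$trials, function(tr) tr$pre[, i0:i1, drop = FALSE])
  list(stim = stim, pre = pre)
}

contrast_values <- function(stim, pre, mode) {
  switch(mode,
         power = stim,
         relative = {
           floor_ <- 1e-12 * mean(abs(pre))
           if (floor_ == 0) return(numeric(length(pre)))
           (stim - pre) / pmax(pre, floor_)
         },
         difference = stim - pre,
         stopf("unknown contrast mode '%s'", mode))
}

#' Frequency-domain source contrast (entrainment window)
#'
#' Common spatial filters are computed from the cross-spectral density of the
#' pooled (concatenated prestimulus + stimulus) segments at the analysis
#' frequency, then applied to each condition separately; the contrast is the
#' per-dipole relative change of source activity (stim vs prestim).
#'
#' @param ep an `epoch_set`
#' @param lf a `lead_field`
#' @param solver `"dics"` or `"eloreta_freq"`
#' @param f analysis frequency, Hz (default 43, the stimulation frequency)
#' @param window window tag (default `"entrainment"`)
#' @param mode `"relative"` (default) or `"difference"`
#' @param gamma_frac eLORETA regularization as a fraction of the mean
#'   lead-field Gram diagonal (`mean(rowSums(K^2))`)
#' @return list of `source_map`s: `stim`, `prestim`, `contrast`
#' @export
source_contrast_freq <- function(ep, lf, solver = c("dics", "eloreta_freq"),
                                 f = 43, window = "entrainment",
                                 mode = "relative", gamma_frac = 1e-3) {
  solver <- match.arg(solver)
  assert_that(length(ep$trials) >= 2, "need at least 2 retained trials")
  pair <- epoch_window_pair(ep, window)
  S_pool <- estimate_csd(c(pair$pre, pair$stim), f = f, fs = ep$fs)
  S_pre <- estimate_csd(pair$pre, f = f, fs = ep$fs)
  S_stim <- estimate_csd(pair$stim, f = f, fs = ep$fs)
  K <- lf$K

  if (solver == "dics") {
    gamma <- reg_from_eigenvalue(S_pool)
    sol <- dics(K, S_pool, gamma = gamma, grid = lf$grid,
                return_filters = TRUE)
    denom <- nai_denominator(K)
    act <- function(S) {
      vapply(seq_along(sol$filters), function(p) {
        w <- sol$filters[[p]]
        Re(sum(diag(w %*% S %*% Conj(t(w)))))
      }, numeric(1)) / denom
    }
  } else {
    gamma <- gamma_frac * mean(rowSums(K^2))
    w <- eloreta_weights(K, gamma = gamma)
    L <- eloreta_operator(K, w)
    act <- function(S) {
      LS <- L %*% S
      v3 <- rowSums(Re(LS * Conj(L)))
      colSums(matrix(v3, nrow = 3))
    }
  }
  a_stim <- act(S_stim)
  a_pre <- act(S_pre)
  list(stim = source_map(a_stim, lf$grid, solver, gamma = gamma),
       prestim = source_map(a_pre, lf$grid, solver, gamma = gamma),
       contrast = source_map(contrast_values(a_stim, a_pre, mode),
                             lf$grid, paste0(solver, "_contrast"),
                             gamma = gamma))
}

#' Time-domain source contrast (late-latency window)
#'
#' As [source_contrast_freq()] but with time-domain covariances: common
#' filters from the pooled prestimulus + stimulus covariance, per-condition
#' activity through those filters.
#'
#' @inheritParams source_contrast_freq
#' @param solver `"lcmv"` or `"eloreta"`
#' @export
source_contrast_time <- function(ep, lf, solver = c("lcmv", "eloreta"),
                                 window = "late", mode = "relative",
                                 gamma_frac = 1e-3) {
  solver <- match.arg(solver)
  assert_that(length(ep$trials) >= 2, "need at least 2 retained trials")
  pair <- epoch_window_pair(ep, window)
  C_pool <- estimate_covariance(c(pair$pre, pair$stim))
  C_pre <- estimate_covariance(pair$pre)
  C_stim <- estimate_covariance(pair$stim)
  K <- lf$K

  if (solver == "lcmv") {
    gamma <- reg_from_eigenvalue(C_pool)
    sol <- lcmv(K, C_pool, gamma = gamma, grid = lf$grid,
                return_filters = TRUE)
    denom <- nai_denominator(K)
    act <- function(C) {
      vapply(seq_along(sol$filters), function(p) {
        w <- sol$filters[[p]]
        sum(diag(w %*% C %*% t(w)))
      }, numeric(1)) / denom
    }
  } else {
    gamma <- gamma_frac * mean(rowSums(K^2))
    w <- eloreta_weights(K, gamma = gamma)
    L <- eloreta_operator(K, w)
    act <- function(C) {
      LC <- L %*% C
      colSums(matrix(rowSums(LC * L), nrow = 3))
    }
  }
  a_stim <- act(C_stim)
  a_pre <- act(C_pre)
  list(stim = source_map(a_stim, lf$grid, solver, gamma = gamma),
       prestim = source_map(a_pre, lf$grid, solver, gamma = gamma),
       contrast = source_map(contrast_values(a_stim, a_pre, mode),
                             lf$grid, paste0(solver, "_contrast"),
                             gamma = gamma))
}

#' Thalamic-component source pathway
#'
#' Dedicated high-frequency route for the early thalamic component: the raw
#' recording is bandpass filtered at 100-400 Hz (6th-order Butterworth,
#' zero-phase) and average referenced instead of the standard low-pass chain,
#' epochs are cut at 5-9 ms post-onset with a matched 4-ms window ending at
#' onset as the prestimulus condition. The per-subject quantity taken to the
#' statistical evaluation is the raw power of the estimated moments in the
#' stimulus window (`mode = "power"`, the default for this component);
#' `"relative"` and `"difference"` contrasts against the matched prestimulus
#' window are also available.
#'
#' @param rec the raw (unfiltered) `sensor_recording`
#' @param lf a `lead_field`
#' @param events onset samples (default: the recording's events)
#' @param bad_trials trials to drop
#' @param mode contrast mode
#' @param gamma_frac eLORETA regularization fraction
#' @return list of `source_map`s as in [source_contrast_freq()]
#' @export
thalamic_pathway <- function(rec, lf, events = NULL, bad_trials = NULL,
                             mode = "power", gamma_frac = 1e-3) {
  fs <- rec$fs
  if (fs < 800) stopf("100-400 Hz band unrepresentable at fs = %g Hz", fs)
  if (fs < 5000) warnf(paste("fs = %g Hz: the 5-9 ms window holds only",
                             "%d samples"), fs, round(0.004 * fs))
  bf <- signal::butter(3, c(100, 400) / (fs / 2), type = "pass")
  rec$data <- fd_filtfilt(rec$data, bf)
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))

  onsets <- events %||% rec$events$sample
  if (is.logical(bad_trials)) bad_trials <- which(bad_trials)
  i0 <- round(0.005 * fs); i1 <- round(0.009 * fs) - 1
  wlen <- i1 - i0 + 1
  stim <- list(); pre <- list()
  n <- ncol(rec$data)
  for (tr in seq_along(onsets)) {
    if (tr %in% bad_trials) next
    e <- onsets[tr]
    if (e - wlen < 1 || e + i1 > n) next
    stim[[length(stim) + 1]] <- rec$data[, (e + i0):(e + i1), drop = FALSE]
    pre[[length(pre) + 1]] <- rec$data[, (e - wlen):(e - 1), drop = FALSE]
  }
  assert_that(length(stim) >= 2, "need at least 2 retained trials")
  C_pool <- estimate_covariance(c(pre, stim))
  gamma <- gamma_frac * mean(rowSums(lf$K^2))
  w <- eloreta_weights(lf$K, gamma = gamma)
  L <- eloreta_operator(lf$K, w)
  act <- function(C) {
    LC <- L %*% C
    colSums(matrix(rowSums(LC * L), nrow = 3))
  }
  a_stim <- act(estimate_covariance(stim))
  a_pre <- act(estimate_covariance(pre))
  list(stim = source_map(a_stim, lf$grid, "eloreta", gamma = gamma),
       prestim = source_map(a_pre, lf$grid, "eloreta", gamma = gamma),
       contrast = source_map(contrast_values(a_stim, a_pre, mode),
                             lf$grid, "eloreta_contrast", gamma = gamma))
}

#' Per-subject ASSR source analysis
#'
#' Convenience wrapper running artifact rejection, preprocessing, epoching
#' and one source contrast for a single subject.
#'
#' @param rec raw `sensor_recording` with events
#' @param lf `lead_field`
#' @param window `"entrainment"` (frequency domain), `"late"` (time domain)
#'   or `"thalamic"`
#' @param solver solver appropriate for the window
#' @param f analysis frequency for the entrainment window
#' @param z_thresh,ptp_limit artifact thresholds
#' @return list: `maps` (stim/prestim/contrast), `rejected` trial log
#' @export
assr_subject_analysis <- function(rec, lf, window = "entrainment",
                                  solver = NULL, f = 43,
                                  z_thresh = 4, ptp_limit = Inf) {
  art <- detect_artifact_segments(rec, z_thresh = z_thresh,
                                  ptp_limit = ptp_limit)
  if (window == "thalamic") {
    maps <- thalamic_pathway(rec, lf, bad_trials = art$bad)
    return(list(maps = maps, rejected = art))
  }
  pp <- preprocess_recording(rec)
  ep <- segment_epochs(pp, bad_trials = art$bad)
  maps <- if (window == "entrainment") {
    source_contrast_freq(ep, lf, solver = solver %||% "dics", f = f)
  } else {
    source_contrast_time(ep, lf, solver = solver %||% "eloreta",
                         window = window)
  }
  list(maps = maps, rejected = art)
}

#' Spatial-correlation curve versus number of subjects
#'
#' For each subset size `n`, draws random subject subsets, averages their
#' source maps, and correlates the subsample grand average with the full
#' grand average across dipoles (Pearson); reports mean and SD per `n`.
#'
#' @param subject_maps subjects x dipoles matrix (or list of `source_map`s)
#' @param ns subset sizes (default `1:(N-1)`)
#' @param n_draws random draws per subset size
#' @param seed RNG seed
#' @return tibble: `n`, `mean_cor`, `sd_cor`
#' @export
subject_correlation_curve <- function(subject_maps, ns = NULL, n_draws = 100,
                                      seed = 1) {
  if (is.list(subject_maps)) {
    subject_maps <- do.call(rbind, lapply(subject_maps, map_values))
  }
  N <- nrow(subject_maps)
  assert_that(N >= 3, "need at least 3 subjects")
  ns <- ns %||% seq_len(N - 1)
  assert_that(all(ns < N) && all(ns >= 1), "subset sizes must be in [1, N-1]")
  full <- colMeans(subject_maps)
  with_seed(seed, {
    purrr::map_dfr(ns, function(n) {
      cors <- vapply(seq_len(n_draws), function(d) {
        idx <- sample.int(N, n)
        cor(colMeans(subject_maps[idx, , drop = FALSE]), full)
      }, numeric(1))
      tibble::tibble(n = n, mean_cor = mean(cors), sd_cor = sd(cors))
    })
  })
}

#' Sensitivity of artifact detection against a ground-truth mask
#'
#' Sample-level sensitivity: the fraction of ground-truth artifact samples
#' falling inside any trial analysis window (prestimulus + stimulus second)
#' that lie within a flagged trial's window.
#'
#' @param art detection table from [detect_artifact_segments()]
#' @param mask ground-truth artifact intervals (`start`, `end` samples)
#' @param fs sampling rate, Hz
#' @return list: `sensitivity`, `n_catchable` (artifact samples in windows)
#' @export
artifact_detection_sensitivity <- function(art, mask, fs) {
  if (nrow(mask) == 0) return(list(sensitivity = NA_real_, n_catchable = 0L))
  art_samples <- unlist(lapply(seq_len(nrow(mask)), function(i) {
    mask$start[i]:mask$end[i]
  }))
  in_window <- function(onsets) {
    if (length(onsets) == 0) return(rep(FALSE, length(art_samples)))
    hit <- rep(FALSE, length(art_samples))
    for (e in onsets) {
      hit <- hit | (art_samples >= e - fs & art_samples <= e + fs - 1)
    }
    hit
  }
  catchable <- in_window(art$onset)
  caught <- in_window(art$onset[art$bad])
  list(sensitivity = sum(caught & catchable) / max(1L, sum(catchable)),
       n_catchable = sum(catchable))
}
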