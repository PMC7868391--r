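test_that("the preprocessing chain notches, low-passes and re-references", {
  fs <- 1000
  tt <- seq_len(20000) / fs
  line <- sin(2 * pi * 50 * tt)
  rec <- sensor_recording(rbind(line, 0.5 * line, -line), fs)
  out <- preprocess_recording(rec, notch = 50, lowpass = NULL, reref = FALSE)
  expect_lt(sqrt(mean(out$data^2)) / sqrt(mean(rec$data^2)), 1e-6)

  # Butterworth magnitude at the cutoff: -3 dB single pass, -6 dB zero phase
  probe <- sin(2 * pi * 100 * tt)
  rec2 <- sensor_recording(rbind(probe, probe), fs)
  mid <- 5000:15000
  sp <- preprocess_recording(rec2, notch = NULL, reref = FALSE,
                             zero_phase = FALSE)
  g1 <- sqrt(mean(sp$data[1, mid]^2) / mean(probe[mid]^2))
  expect_equal(g1, 1 / sqrt(2), tolerance = 0.02)
  zp <- preprocess_recording(rec2, notch = NULL, reref = FALSE,
                             zero_phase = TRUE)
  g2 <- sqrt(mean(zp$data[1, mid]^2) / mean(probe[mid]^2))
  expect_equal(g2, 0.5, tolerance = 0.02)

  set.seed(1)
  rec3 <- sensor_recording(matrix(rnorm(4 * 5000), 4), fs)
  out3 <- preprocess_recording(rec3)
  expect_lt(max(abs(colSums(out3$data))), 1e-9)

  expect_error(preprocess_recording(sensor_recording(matrix(0, 2, 100), 150)),
               "twice")
})

test_that("epoch segmentation cuts the canonical windows at the right samples", {
  fs <- 1000
  X <- matrix(rep(seq_len(12000), each = 2), 2, byrow = FALSE)  # sample index
  rec <- sensor_recording(X, fs, events = tibble::tibble(sample = 5001,
                                                         code = "a"))
  ep <- segment_epochs(rec)
  expect_equal(length(ep$trials), 1)
  pair <- ratesi:::epoch_window_pair(ep, "entrainment")
  # onset at sample 5001 (0-based 5000): entrainment covers 5400-5949 0-based
  expect_equal(pair$stim[[1]][1, 1], 5401)
  expect_equal(pair$stim[[1]][1, 550], 5950)
  expect_equal(ncol(pair$pre[[1]]), 550)

  ep0 <- expect_warning(segment_epochs(sensor_recording(X, fs)), "no events")
  expect_equal(length(ep0$trials), 0)

  # edge trials are dropped with a log entry; bad trials likewise
  rec2 <- sensor_recording(X, fs,
                           events = tibble::tibble(sample = c(500, 5001, 6002),
                                                   code = "a"))
  ep2 <- segment_epochs(rec2, bad_trials = c(3))
  expect_equal(length(ep2$trials), 1)
  expect_setequal(ep2$log$reason, c("edge", "artifact"))
})

test_that("a full set of clean events yields a full pair count", {
  fx <- assr_fixture()
  pp <- preprocess_recording(fx$ds[[1]]$rec)
  ep <- segment_epochs(pp)
  expect_equal(length(ep$trials), 120)
})

test_that("identical conditions give identically zero contrasts", {
  mdl <- small_model()
  set.seed(2)
  tr <- lapply(1:8, function(i) matrix(rnorm(12 * 1000), 12))
  ep <- structure(list(
    trials = lapply(tr, function(m) list(pre = m, stim = m)),
    onsets = seq_len(8) * 3000, fs = 1000, windows = ratesi:::assr_windows(),
    log = tibble::tibble(trial = integer(0), reason = character(0))),
    class = "epoch_set")
  for (sv in c("dics", "eloreta_freq")) {
    sc <- source_contrast_freq(ep, mdl$lf, solver = sv, f = 43)
    expect_equal(max(abs(sc$contrast$values)), 0, tolerance = 1e-9)
  }
  for (sv in c("lcmv", "eloreta")) {
    sc <- source_contrast_time(ep, mdl$lf, solver = sv)
    expect_equal(max(abs(sc$contrast$values)), 0, tolerance = 1e-9)
  }
})

test_that("planted sources are recovered by their dedicated routes", {
  mdl <- small_model()
  # single-source high-SNR configuration for the recovery examples (the
  # default bilateral late pair blends toward the midline under minimum norm)
  src <- assr_sources(mdl$grid)
  src$late <- src$late[2]
  proto <- assr_protocol(n_subjects = 1, n_trials = 80, seed = 21,
                         amplitudes = c(thalamic = 20, late = 30,
                                        entrainment = 12))
  ds <- generate_assr_dataset(mdl$lf, proto, sources = src)
  rec <- ds[[1]]$rec
  truth <- ds[[1]]$truth$sources
  step <- mdl$grid$spacing

  pp <- preprocess_recording(rec)
  ep <- segment_epochs(pp)
  fr <- source_contrast_freq(ep, mdl$lf, solver = "dics", f = 43)
  expect_lte(argmax_dist(fr$contrast$values, mdl$grid, truth$entrainment),
             step)

  tm <- source_contrast_time(ep, mdl$lf, solver = "eloreta")
  expect_lte(argmax_dist(tm$contrast$values, mdl$grid, truth$late), 2 * step)

  expect_warning(th <- thalamic_pathway(rec, mdl$lf), "samples")
  expect_lte(argmax_dist(th$contrast$values, mdl$grid, truth$thalamic),
             3 * step)

  low <- rec; low$fs <- 500
  expect_error(thalamic_pathway(low, mdl$lf), "unrepresentable")
})

test_that("the artifact detector is specific on clean data and catches extremes", {
  set.seed(3)
  fs <- 1000
  X <- matrix(rnorm(8 * 200000), 8)
  events <- seq(2000, 198000, by = 2000)
  rec <- sensor_recording(X, fs, events = tibble::tibble(sample = events,
                                                         code = "a"))
  art <- detect_artifact_segments(rec, z_thresh = 4)
  expect_lt(mean(art$bad), 0.04)

  # a peak-to-peak violation is always flagged
  X2 <- X
  X2[3, 50500] <- 400
  rec2 <- sensor_recording(X2, fs, events = rec$events)
  art2 <- detect_artifact_segments(rec2, z_thresh = 4, ptp_limit = 50)
  hit <- art2$trial[art2$onset - fs <= 50500 & art2$onset + fs > 50500]
  expect_true(all(art2$bad[hit]))
  expect_match(art2$reason[hit[1]], "peak-to-peak")

  # manual intervals are honoured
  art3 <- detect_artifact_segments(rec, z_thresh = 50,
                                   manual = tibble::tibble(start = 10100,
                                                           end = 10200))
  expect_true(any(art3$bad & grepl("manual", art3$reason)))
  expect_error(detect_artifact_segments(rec, z_thresh = 0), "positive")
})

test_that("the subject-count correlation curve rises toward the full set", {
  set.seed(4)
  P <- 40; N <- 12
  signal <- runif(P)
  maps <- t(replicate(N, signal + rnorm(P, sd = 0.5)))
  cur <- subject_correlation_curve(maps, ns = c(2, 5, 8, 11), n_draws = 200,
                                   seed = 5)
  expect_true(all(diff(cur$mean_cor) > 0))
  expect_gt(cur$mean_cor[4], 0.9)
  expect_error(subject_correlation_curve(maps[1:2, ]), "3 subjects")
  expect_error(subject_correlation_curve(maps, ns = N), "N-1")
})
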