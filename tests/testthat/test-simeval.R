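test_that("clean single-dipole trials are rank-1 projections of the lead field", {
  mdl <- small_model()
  X <- ratesi:::with_seed(1, simulate_dipole_trial(mdl$lf, 12, 2, 50))
  expect_equal(qr(X)$rank, 1)
  k <- mdl$lf$K[, 3 * 11 + 2]
  # channel ratios equal lead-field-column ratios
  expect_equal(X[2, ] / X[1, ], rep(k[2] / k[1], 50), tolerance = 1e-9)

  # channel variance matches the squared lead-field entry
  Xl <- ratesi:::with_seed(2, simulate_dipole_trial(mdl$lf, 12, 2, 1e5))
  expect_lt(abs(var(Xl[3, ]) / k[3]^2 - 1), 3 / sqrt(1e5) * 2)
  expect_error(simulate_dipole_trial(mdl$lf, 12, "w", 50), "orientation")
})

test_that("sensor noise hits the prescribed SNR", {
  X <- matrix(rnorm(5 * 100), 5)
  p_sig <- mean(X^2)
  n0 <- ratesi:::with_seed(3, add_channel_noise(X, 0))
  expect_equal(attr(n0, "noise_var"), p_sig, tolerance = 1e-12)
  n25 <- ratesi:::with_seed(4, add_channel_noise(X, 25))
  expect_equal(attr(n25, "noise_var"), p_sig / 10^2.5, tolerance = 1e-12)

  # empirical post-hoc SNR within 0.5 dB at T = 1e4
  Xl <- matrix(rnorm(5 * 1e4), 5)
  nl <- ratesi:::with_seed(5, add_channel_noise(Xl, 10))
  snr_emp <- 10 * log10(mean(Xl^2) / mean((nl - Xl)^2))
  expect_lt(abs(snr_emp - 10), 0.5)
  expect_error(add_channel_noise(matrix(0, 3, 4), 10), "zero signal")
})

test_that("ED1 is the distance of the global maximum", {
  mdl <- small_model()
  grid <- mdl$grid
  v <- numeric(grid$P); v[10] <- 1
  expect_equal(ed1(source_map(v, grid, "t"), 10), 0)
  nb <- grid$neighbors[[10]]
  face <- nb[which(abs(rowSums(abs(sweep(grid$pos[nb, , drop = FALSE], 2,
                                         grid$pos[10, ]))) -
                         grid$spacing) < 1e-9)][1]
  v2 <- numeric(grid$P); v2[face] <- 1
  expect_equal(ed1(source_map(v2, grid, "t"), 10), grid$spacing)
  expect_error(ed1(source_map(numeric(grid$P), grid, "t"), 1), "all-zero")
})

test_that("local maxima match a brute-force neighbour scan", {
  mdl <- small_model()
  grid <- mdl$grid
  # smooth unimodal map: distance-based bump
  d <- sqrt(rowSums(sweep(grid$pos, 2, grid$pos[30, ])^2))
  v <- exp(-d^2 / 8)
  expect_equal(find_local_maxima(source_map(v, grid, "t"))$dipole, 30)

  # two separated bumps against an explicit brute-force oracle
  d2 <- sqrt(rowSums(sweep(grid$pos, 2, grid$pos[60, ])^2))
  v2 <- exp(-d^2 / 4) + 0.6 * exp(-d2^2 / 4)
  got <- find_local_maxima(source_map(v2, grid, "t"))$dipole
  brute <- which(vapply(seq_len(grid$P), function(p) {
    all(v2[p] > v2[grid$neighbors[[p]]])
  }, logical(1)))
  expect_setequal(got, brute)

  # constant map collapses to a single plateau representative
  flat <- find_local_maxima(source_map(rep(1, grid$P), grid, "t"))
  expect_equal(nrow(flat), 1)
  expect_equal(flat$dipole, 1)
})

test_that("ED2 reproduces the worked weighted-distance examples", {
  # 1-D line grid built directly: 7 dipoles, 1 mm apart
  pos <- cbind(0:6, 0, 0)
  grid <- ratesi:::rebuild_grid(pos, rep(1L, 7), 1)

  # single local max at the true position
  expect_equal(ed2(source_map(c(0.1, 1, 0.1, 0, 0, 0, 0), grid, "t"), 2), 0)

  # global max at the truth plus a secondary max 2 mm away at half activation
  v <- c(0.2, 1, 0.2, 0.5, 0.1, 0, 0)
  expect_equal(ed2(source_map(v, grid, "t"), 2), 2 * 0.5)

  # global max 3 mm off, no other maxima
  v2 <- c(0, 0, 0, 0, 1, 0.4, 0.1)
  expect_equal(ed2(source_map(v2, grid, "t"), 2), 3)
})

test_that("ED2 dominates the global-maximum distance and equals ED1 when unimodal", {
  mdl <- small_model()
  grid <- mdl$grid
  set.seed(6)
  for (i in 1:5) {
    v <- runif(grid$P)
    p0 <- sample(grid$P, 1)
    m <- source_map(v, grid, "t")
    expect_gte(ed2(m, p0) + 1e-12, ed1(m, p0))
  }
  d <- sqrt(rowSums(sweep(grid$pos, 2, grid$pos[45, ])^2))
  uni <- source_map(exp(-d^2 / 8), grid, "t")
  expect_equal(ed2(uni, 12), ed1(uni, 12))
})

test_that("reliability maps are bounded discrepancy measures", {
  set.seed(7)
  fam <- matrix(abs(rnorm(12 * 30)), 12)
  expect_equal(reliability_map(fam, fam), rep(0, 30))

  # one simulation, all estimated mass on the wrong dipole
  sim <- matrix(0, 1, 5); sim[1, 2] <- 3
  est <- matrix(0, 1, 5); est[1, 4] <- 7
  r <- reliability_map(sim, est)
  expect_equal(r[2], 1)
  expect_equal(r[4], 1)

  r2 <- reliability_map(fam, matrix(abs(rnorm(12 * 30)), 12))
  expect_true(all(r2 >= 0 & r2 <= 1))

  sim0 <- rbind(sim, 0)
  est0 <- rbind(est, est)
  expect_warning(reliability_map(sim0, est0), "zero-norm")
})

test_that("the surrogate sweep is bit-reproducible and correctly structured", {
  mdl <- small_model()
  cfg <- surrogate_config(snr_db = c(10, 25), seed = 9)
  dip <- c(5, 25, 50)
  ev1 <- surrogate_sweep(mdl$lf, solvers = c("sloreta", "lcmv"), cfg = cfg,
                         dipoles = dip)
  ev2 <- surrogate_sweep(mdl$lf, solvers = c("sloreta", "lcmv"), cfg = cfg,
                         dipoles = dip)
  expect_identical(ev1$summary, ev2$summary)
  expect_identical(ev1$maps, ev2$maps)

  expect_setequal(names(ev1$maps), c("sloreta", "lcmv"))
  expect_equal(dim(ev1$maps$lcmv$ed1), c(3, 2))        # dipoles x SNR
  expect_true(all(ev1$maps$lcmv$reliability >= 0 &
                    ev1$maps$lcmv$reliability <= 1))
  expect_setequal(unique(ev1$summary$metric), c("ed1", "ed2"))
  expect_true(all(ev1$summary$mean >= 0))
})
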