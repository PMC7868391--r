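test_that("sample covariance behaves like a covariance", {
  X <- matrix(rep(c(1, 2, 3), 5), 3)      # identical repeated columns
  expect_equal(unname(estimate_covariance(X)), matrix(0, 3, 3),
               ignore_attr = TRUE)

  set.seed(1)
  Xw <- matrix(rnorm(4 * 1e5), 4)
  C <- estimate_covariance(Xw)
  expect_lt(max(abs(diag(C) - 1)), 3 / sqrt(1e5))

  Xr <- matrix(rnorm(6 * 4), 6)           # T = 4 < N
  expect_lte(qr(estimate_covariance(Xr))$rank, 3)
  expect_error(estimate_covariance(matrix(1:3, 3, 1)), "2 samples")
})

test_that("the cross-spectral density picks out the analysis frequency", {
  fs <- 1000; T_ <- 1000
  tt <- seq_len(T_) / fs
  s <- sin(2 * pi * 43 * tt)
  X <- rbind(s, s)                        # identical 43-Hz channels
  S <- estimate_csd(X, f = 43, fs = fs)
  coh <- Mod(S[1, 2]) / sqrt(Re(S[1, 1]) * Re(S[2, 2]))
  expect_equal(coh, 1, tolerance = 1e-9)

  set.seed(2)
  trials <- lapply(1:200, function(i) matrix(rnorm(2 * 250), 2))
  Sn <- estimate_csd(trials, f = 43, fs = fs)
  expect_lt(Mod(Sn[1, 2]) / sqrt(Re(Sn[1, 1]) * Re(Sn[2, 2])),
            3 / sqrt(200))

  expect_error(estimate_csd(X, f = 600, fs = fs), "Nyquist")
})

test_that("the eigenvalue regularization rule is 0.003 lambda_max", {
  expect_equal(reg_from_eigenvalue(diag(c(10, 1))), 0.03)
  expect_equal(reg_from_eigenvalue(diag(2)), 0.003)
  expect_equal(reg_from_eigenvalue(matrix(0, 3, 3)), 0)
})

test_that("LCMV satisfies the unit-gain constraint and NAI normalization", {
  mdl <- small_model()
  set.seed(3)
  C <- estimate_covariance(matrix(rnorm(12 * 400), 12))
  sol <- lcmv(mdl$lf, C, gamma = 0)
  dev <- max(vapply(seq_len(mdl$grid$P), function(p) {
    j <- (3 * (p - 1) + 1):(3 * p)
    max(abs(sol$filters[[p]] %*% mdl$lf$K[, j] - diag(3)))
  }, numeric(1)))
  expect_lt(dev, 1e-10)

  # C = Q = I gives NAI = 1 everywhere
  sol_id <- lcmv(mdl$lf, diag(12), gamma = 0, return_filters = FALSE)
  expect_equal(sol_id$map$values, rep(1, mdl$grid$P), tolerance = 1e-9)
})

test_that("LCMV matches a dense brute-force evaluation on a toy problem", {
  set.seed(4)
  N <- 6; P <- 6
  K <- matrix(rnorm(N * 3 * P), N)
  # two active dipoles
  act <- c(2, 5)
  Y <- matrix(0, 3 * P, 200)
  for (p in act) Y[3 * (p - 1) + 1, ] <- rnorm(200)
  X <- K %*% Y + 0.05 * matrix(rnorm(N * 200), N)
  C <- estimate_covariance(X)
  sol <- lcmv(K, C, gamma = 0.001 * max(eigen(C)$values))

  # independent matrix-by-matrix oracle straight from the defining equations
  Creg <- C + sol$gamma * diag(N)
  oracle <- vapply(seq_len(P), function(p) {
    Kp <- K[, (3 * (p - 1) + 1):(3 * p)]
    v <- sum(diag(solve(t(Kp) %*% solve(Creg) %*% Kp)))
    v / sum(diag(solve(t(Kp) %*% Kp)))
  }, numeric(1))
  expect_equal(sol$map$values, oracle, tolerance = 1e-10)
  # the two active dipoles are the two NAI maxima
  expect_setequal(order(oracle, decreasing = TRUE)[1:2], act)
  expect_gt(min(oracle[act]), 2 * median(oracle[-act]))
})

test_that("DICS reduces to LCMV behaviour on narrowband data", {
  mdl <- small_model()
  expect_equal(dics(mdl$lf, diag(12) + 0i, gamma = 0,
                    return_filters = FALSE)$map$values,
               rep(1, mdl$grid$P), tolerance = 1e-9)

  tt <- seq_len(2500) / 1000
  p0 <- 42
  clean <- mdl$lf$K[, 3 * (p0 - 1) + 3] %o% sin(2 * pi * 43 * tt)
  X <- ratesi:::with_seed(6, add_channel_noise(clean, 25))
  segs <- lapply(0:4, function(k) X[, (k * 500 + 1):((k + 1) * 500)])
  S <- estimate_csd(segs, f = 43, fs = 1000)
  md <- dics(mdl$lf, S, return_filters = FALSE)$map
  expect_lte(ed1(md, p0), mdl$grid$spacing)
  ml <- lcmv(mdl$lf, estimate_covariance(X), return_filters = FALSE)$map
  expect_gt(cor(rank(md$values), rank(ml$values)), 0.95)
})

test_that("sLORETA localizes noiseless single dipoles exactly as gamma -> 0", {
  mdl <- small_model()
  for (p in c(5, 33, 67)) {
    X <- ratesi:::with_seed(p, simulate_dipole_trial(mdl$lf, p, 2, 60))
    sol <- sloreta(mdl$lf, X, gamma = 0)
    expect_equal(ed1(sol$map, p), 0)
  }
  z <- sloreta(mdl$lf, matrix(0, 12, 10), gamma = 1)
  expect_equal(z$map$values, rep(0, mdl$grid$P))
  expect_error(sloreta(mdl$lf, matrix(1, 12, 10), gamma = -1), "gamma")
})

test_that("eLORETA weights solve the fixed-point equation", {
  set.seed(7)
  K <- matrix(rnorm(6 * 3 * 8), 6)
  w <- eloreta_weights(K, gamma = 0.01, tol = 1e-6)
  # residual of the defining equation at the reported solution
  M <- w$M
  res <- max(vapply(1:8, function(p) {
    j <- (3 * (p - 1) + 1):(3 * p)
    S <- t(K[, j]) %*% M %*% K[, j]
    e <- eigen((S + t(S)) / 2, symmetric = TRUE)
    Wnew <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
    norm(Wnew - w$W[, , p], "F") / norm(w$W[, , p], "F")
  }, numeric(1)))
  expect_lt(res, 1e-5)

  # agrees with an independent plain-R fixed-point run at 10x tighter tol
  W <- array(rep(diag(3), 8), c(3, 3, 8))
  for (it in 1:2000) {
    KW <- K
    for (p in 1:8) {
      j <- (3 * (p - 1) + 1):(3 * p)
      KW[, j] <- K[, j] %*% solve(W[, , p])
    }
    M2 <- solve(KW %*% t(K) + 0.01 * diag(6))
    delta <- 0
    for (p in 1:8) {
      j <- (3 * (p - 1) + 1):(3 * p)
      S <- t(K[, j]) %*% M2 %*% K[, j]
      e <- eigen((S + t(S)) / 2, symmetric = TRUE)
      Wn <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
      delta <- max(delta, norm(Wn - W[, , p], "F") / norm(W[, , p], "F"))
      W[, , p] <- Wn
    }
    if (delta < 1e-7) break
  }
  expect_lt(max(abs(W - w$W)) / max(abs(W)), 1e-4)

  expect_warning(expect_warning(
    eloreta_weights(matrix(rnorm(3), 1), gamma = 0.01, max_iter = 2000),
    "rank"), "rank")
})

test_that("eLORETA localizes noiseless dipoles and is quadratic in the data", {
  mdl <- small_model()
  w0 <- cached("elor_w0", eloreta_weights(mdl$lf$K, gamma = 0))
  for (p in c(9, 41, 60)) {
    X <- ratesi:::with_seed(p, simulate_dipole_trial(mdl$lf, p, 3, 60))
    sol <- eloreta(mdl$lf, X, gamma = 0, weights = w0)
    expect_equal(ed1(sol$map, p), 0)
  }
  X <- ratesi:::with_seed(1, simulate_dipole_trial(mdl$lf, 20, 1, 40))
  m1 <- eloreta(mdl$lf, X, gamma = 0, weights = w0)$map$values
  m2 <- eloreta(mdl$lf, 2 * X, gamma = 0, weights = w0)$map$values
  expect_equal(m2, 4 * m1, tolerance = 1e-9)
  z <- eloreta(mdl$lf, matrix(0, 12, 10), gamma = 0, weights = w0)
  expect_equal(max(z$map$values), 0)
})

test_that("leave-one-out cross-validation picks small gamma for clean data", {
  set.seed(8)
  K <- matrix(rnorm(8 * 3 * 10), 8)
  X <- K[, 4] %o% rnorm(80)               # noiseless single dipole
  scale <- mean(diag(estimate_covariance(X)))
  g <- reg_loocv(K, X, solver = "sloreta",
                 gamma_grid = c(1e-8, 1) * scale)
  expect_equal(as.numeric(g), 1e-8 * scale)
  expect_equal(reg_loocv(K, X, solver = "sloreta", gamma_grid = 0.5), 0.5)
  expect_error(reg_loocv(K, X, solver = "sloreta", gamma_grid = numeric(0)),
               "non-empty")
})

test_that("solver maps are finite, non-negative and seed-reproducible", {
  mdl <- small_model()
  w0 <- cached("elor_w0", eloreta_weights(mdl$lf$K, gamma = 0))
  for (seed in 1:3) {
    X <- ratesi:::with_seed(seed, add_channel_noise(
      simulate_dipole_trial(mdl$lf, 15, 1, 100), 10))
    C <- estimate_covariance(X)
    for (vals in list(lcmv(mdl$lf, C, return_filters = FALSE)$map$values,
                      sloreta(mdl$lf, X)$map$values,
                      eloreta(mdl$lf, X, weights = w0)$map$values)) {
      expect_true(all(is.finite(vals)))
      expect_true(all(vals >= 0))
    }
    X2 <- ratesi:::with_seed(seed, add_channel_noise(
      simulate_dipole_trial(mdl$lf, 15, 1, 100), 10))
    expect_identical(X, X2)
  }
})
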