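#' Construct a sensor recording
#'
#' Container for multichannel electrode potentials: a channels x time matrix
#' with sampling rate, channel labels, and event markers.
#'
#' @param data N x T numeric matrix (channels x samples)
#' @param fs sampling frequency, Hz
#' @param channels channel labels (default `ch1..chN`)
#' @param events tibble with columns `sample`, `code` (may be empty)
#' @param units physical unit string (default "V")
#' @return a `sensor_recording`
#' @export
sensor_recording <- function(data, fs, channels = NULL, events = NULL,
                             units = "V") {
  data <- as.matrix(data)
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(data)))
  assert_that(length(channels) == nrow(data),
              "channel labels must match the number of rows")
  if (is.null(events)) events <- tibble::tibble(sample = integer(0),
                                                code = character(0))
  structure(list(data = data, fs = fs, channels = channels,
                 events = tibble::as_tibble(events), units = units),
            class = "sensor_recording")
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf("<sensor_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              nrow(x$events)))
  invisible(x)
}

rec_data <- function(x) {
  if (inherits(x, "sensor_recording")) x$data else as.matrix(x)
}

#' Sample covariance of a recording
#'
#' Unbiased sample covariance over the concatenated segments with the channel
#' means removed.
#'
#' @param x a `sensor_recording`, an N x T matrix, or a list of such segments
#' @return N x N covariance matrix (class `covariance_model` attributes:
#'   `type = "covariance"`)
#' @export
estimate_covariance <- function(x) {
  segs <- if (is.list(x) && !inherits(x, "sensor_recording")) {
    lapply(x, rec_data)
  } else list(rec_data(x))
  X <- do.call(cbind, segs)
  T_ <- ncol(X)
  assert_that(T_ >= 2, "need at least 2 samples for a covariance")
  Xc <- X - rowMeans(X)
  C <- Xc %*% t(Xc) / (T_ - 1)
  dimnames(C) <- NULL
  attr(C, "type") <- "covariance"
  attr(C, "n") <- T_
  C
}

#' Cross-spectral density at one frequency
#'
#' Per-trial tapered FFT cross products at the frequency bin nearest `f`,
#' averaged over trials. The output is Hermitian.
#'
#' @param trials list of N x T segments (or a single matrix / recording)
#' @param f analysis frequency, Hz
#' @param fs sampling frequency, Hz
#' @param taper `"hann"` or `"none"`
#' @return complex Hermitian N x N matrix, attribute `freq` = actual bin Hz
#' @export
estimate_csd <- function(trials, f, fs, taper = "hann") {
  assert_that(f < fs / 2, "analysis frequency must be below Nyquist (fs/2)")
  if (!is.list(trials) || inherits(trials, "sensor_recording")) {
    trials <- list(trials)
  }
  trials <- lapply(trials, rec_data)
  T_ <- ncol(trials[[1]])
  assert_that(T_ >= fs / f, "segment shorter than one cycle of f")
  w <- switch(taper,
              hann = 0.5 - 0.5 * cos(2 * pi * seq_len(T_) / (T_ + 1)),
              none = rep(1, T_),
              stopf("unknown taper '%s'", taper))
  freqs <- (seq_len(T_) - 1) * fs / T_
  bin <- which.min(abs(freqs[seq_len(floor(T_ / 2) + 1)] - f))
  N <- nrow(trials[[1]])
  S <- matrix(0 + 0i, N, N)
  for (tr in trials) {
    tc <- tr - rowMeans(tr)
    ft <- t(stats::mvfft(t(tc * rep(w, each = N))))
    v <- ft[, bin]
    S <- S + v %*% Conj(t(v))
  }
  S <- S / length(trials)
  S <- (S + Conj(t(S))) / 2
  dimnames(S) <- NULL
  attr(S, "type") <- "csd"
  attr(S, "freq") <- freqs[bin]
  S
}

#' Regularization parameter from the largest covariance eigenvalue
#'
#' `gamma = 0.003 * lambda_max(C)`, the rule used for the LCMV and DICS
#' beamformers.
#'
#' @param C covariance or cross-spectral matrix
#' @return gamma
#' @export
reg_from_eigenvalue <- function(C) {
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  0.003 * max(Re(ev), 0)
}

#' Source map container
#' @param values non-negative per-dipole scalar activity, length P
#' @param grid the `source_grid`
#' @param solver solver tag
#' @param moments optional 3P x T moment time courses
#' @param gamma regularization used
#' @return a `source_map`
#' @export
source_map <- function(values, grid, solver, moments = NULL, gamma = NA) {
  structure(list(values = as.numeric(values), grid = grid, solver = solver,
                 moments = moments, gamma = gamma),
            class = "source_map")
}

#' @export
print.source_map <- function(x, ...) {
  cat(sprintf("<source_map> %s: P = %d, max %.3g at dipole %d, gamma = %.3g\n",
              x$solver, length(x$values), max(x$values),
              which.max(x$values), x$gamma))
  invisible(x)
}

# Shared LCMV/DICS algebra on a (possibly complex Hermitian) matrix C.
beamform_core <- function(K, C, gamma, Q_inv_denoms, return_filters) {
  N <- nrow(K)
  P <- ncol(K) / 3
  Creg <- C + gamma * diag(N)
  Ci <- tryCatch(solve(Creg), error = function(e)
    stopf("regularized covariance is singular (gamma = %.3g)", gamma))
  CiK <- Ci %*% K
  vals <- numeric(P)
  filters <- if (return_filters) vector("list", P) else NULL
  for (p in seq_len(P)) {
    j <- (3 * (p - 1) + 1):(3 * p)
    G <- Conj(t(K[, j, drop = FALSE])) %*% CiK[, j, drop = FALSE]
    Gi <- solve(G)
    vals[p] <- Re(sum(diag(Gi)))
    if (return_filters) {
      filters[[p]] <- Gi %*% Conj(t(CiK[, j, drop = FALSE]))
    }
  }
  list(vals = vals, filters = filters, gamma = gamma)
}

# Denominator of the neural activity index: tr[(K_p' Q^-1 K_p)^-1] per dipole.
nai_denominator <- function(K, Q_inv = NULL) {
  QiK <- if (is.null(Q_inv)) K else Q_inv %*% K
  sym3_inv_trace(sym3_blocks(Re(K), Re(QiK)))
}

#' LCMV beamformer
#'
#' Linearly constrained minimum-variance spatial filters
#' `w_p = (K_p' C^-1 K_p)^-1 K_p' C^-1` with the unit-gain constraint
#' `w_p' K_p = I`, source variance `Var_p = tr[(K_p' C^-1 K_p)^-1]`, and the
#' neural activity index `NAI_p = Var_p / tr[(K_p' Q^-1 K_p)^-1]` with the
#' noise covariance `Q` taken as the identity. Regularization replaces `C` by
#' `C + gamma I`, with `gamma = 0.003 * lambda_max(C)` by default.
#'
#' @param lf a `lead_field` (or plain N x 3P matrix with `grid` supplied)
#' @param C data covariance (from [estimate_covariance()])
#' @param gamma regularization; `NULL` uses the eigenvalue rule
#' @param grid `source_grid` when `lf` is a bare matrix
#' @param return_filters keep the per-dipole 3 x N filters
#' @return an `esi_solution` containing `filters`, `map` (NAI), `var`
#' @export
lcmv <- function(lf, C, gamma = NULL, grid = NULL, return_filters = TRUE) {
  K <- if (inherits(lf, "lead_field")) lf$K else lf
  grid <- grid %||% (if (inherits(lf, "lead_field")) lf$grid else NULL)
  if (is.null(gamma)) gamma <- reg_from_eigenvalue(C)
  core <- beamform_core(K, C, gamma, NULL, return_filters)
  denom <- nai_denominator(K)
  nai <- core$vals / denom
  structure(list(
    filters = core$filters, gamma = gamma, solver = "lcmv",
    var = core$vals,
    map = source_map(nai, grid, "lcmv", gamma = gamma)),
    class = c("lcmv_solution", "esi_solution"))
}

#' DICS beamformer
#'
#' Dynamic imaging of coherent sources: identical algebra to [lcmv()] with the
#' complex cross-spectral density at one frequency in place of the covariance;
#' activity is the real part of the trace quantity.
#'
#' @inheritParams lcmv
#' @param CSD Hermitian cross-spectral matrix (from [estimate_csd()])
#' @return an `esi_solution`
#' @export
dics <- function(lf, CSD, gamma = NULL, grid = NULL, return_filters = TRUE) {
  K <- if (inherits(lf, "lead_field")) lf$K else lf
  grid <- grid %||% (if (inherits(lf, "lead_field")) lf$grid else NULL)
  if (is.null(gamma)) gamma <- reg_from_eigenvalue(CSD)
  core <- beamform_core(K, CSD, gamma, NULL, return_filters)
  denom <- nai_denominator(K)
  nai <- core$vals / denom
  structure(list(
    filters = core$filters, gamma = gamma, solver = "dics",
    var = core$vals,
    map = source_map(nai, grid, "dics", gamma = gamma)),
    class = c("dics_solution", "esi_solution"))
}

#' sLORETA source estimate
#'
#' Minimum-norm estimate `Y = K'(KK' + gamma I)^-1 X` standardized per dipole
#' by the corresponding 3 x 3 diagonal block of the resolution matrix. The
#' scalar map is the time-summed standardized power. The default
#' regularization is 5% of the mean diagonal of the data covariance.
#'
#' @inheritParams lcmv
#' @param X data matrix or `sensor_recording`
#' @return an `esi_solution` with the standardized power map
#' @export
sloreta <- function(lf, X, gamma = NULL, grid = NULL) {
  K <- if (inherits(lf, "lead_field")) lf$K else lf
  grid <- grid %||% (if (inherits(lf, "lead_field")) lf$grid else NULL)
  X <- rec_data(X)
  if (is.null(gamma)) {
    C <- estimate_covariance(X)
    gamma <- 0.05 * mean(diag(C))
  }
  assert_that(gamma >= 0, "gamma must be non-negative")
  N <- nrow(K)
  G <- K %*% t(K) + gamma * diag(N)
  Gi <- if (gamma > 0) solve(G) else pinv(G)
  Tm <- t(K) %*% Gi                       # 3P x N minimum-norm operator
  Y <- Tm %*% X
  P <- ncol(K) / 3
  vals <- numeric(P)
  for (p in seq_len(P)) {
    j <- (3 * (p - 1) + 1):(3 * p)
    Rpp <- Tm[j, , drop = FALSE] %*% K[, j, drop = FALSE]
    S <- Y[j, , drop = FALSE] %*% t(Y[j, , drop = FALSE])
    vals[p] <- sum(diag(spd_solve(Rpp, S)))
  }
  structure(list(
    operator = Tm, gamma = gamma, solver = "sloreta", moments = Y,
    map = source_map(vals, grid, "sloreta", gamma = gamma)),
    class = c("sloreta_solution", "esi_solution"))
}

#' eLORETA weight blocks
#'
#' Fixed-point iteration for the 3 x 3 symmetric positive-definite weight
#' blocks `W_p = [K_p' (K W^-1 K' + gamma I)^-1 K_p]^(1/2)` that give the
#' weighted minimum-norm estimator exact localization under zero noise.
#' Iteration starts from identity blocks (or `W_init`) and stops when the
#' maximum relative Frobenius change falls below `tol`.
#'
#' @param K N x 3P lead-field matrix
#' @param gamma regularization (>= 0; 0 uses a pseudo-inverse)
#' @param tol relative convergence tolerance
#' @param max_iter iteration limit; non-convergence is an error carrying the
#'   last residual
#' @param W_init optional 3 x 3 x P warm-start array
#' @return list with `W`, `W_inv` (3 x 3 x P arrays), `M` (the N x N inverse
#'   at convergence), `iterations`, `residual`
#' @export
eloreta_weights <- function(K, gamma = 0, tol = 1e-6, max_iter = 500,
                            W_init = NULL) {
  assert_that(gamma >= 0, "gamma must be non-negative")
  N <- nrow(K); P <- ncol(K) / 3
  if (N < 2) warnf("rank-deficient lead field: only %d channel(s)", N)
  W <- W_init %||% array(rep(diag(3), P), c(3, 3, P))
  Winv <- array(0, c(3, 3, P))
  rank_warned <- FALSE
  # Ridge-regularized block inverse: keeps the iteration bounded when a
  # weight block is (numerically) rank deficient.
  ridge_inv <- function(m) {
    e <- eigen(m, symmetric = TRUE)
    lam <- pmax(e$values, 0) + 1e-10 * max(e$values, .Machine$double.xmin)
    e$vectors %*% ((1 / lam) * t(e$vectors))
  }
  for (it in seq_len(max_iter)) {
    for (p in seq_len(P)) Winv[, , p] <- ridge_inv(W[, , p])
    # K W^-1 K' accumulated blockwise.
    KW <- K
    for (p in seq_len(P)) {
      j <- (3 * (p - 1) + 1):(3 * p)
      KW[, j] <- K[, j, drop = FALSE] %*% Winv[, , p]
    }
    Mmat <- KW %*% t(K) + gamma * diag(N)
    M <- if (gamma > 0) {
      tryCatch(solve(Mmat), error = function(e) pinv(Mmat))
    } else pinv(Mmat)
    MK <- M %*% K
    Sb <- sym3_blocks(K, MK)
    delta <- 0
    for (p in seq_len(P)) {
      S <- matrix(c(Sb$g11[p], Sb$g12[p], Sb$g13[p],
                    Sb$g12[p], Sb$g22[p], Sb$g23[p],
                    Sb$g13[p], Sb$g23[p], Sb$g33[p]), 3, 3)
      e <- eigen(S, symmetric = TRUE)
      lam <- pmax(e$values, 0)
      Wnew <- e$vectors %*% (sqrt(lam) * t(e$vectors))
      if (!rank_warned && e$values[3] < 1e-12 * max(e$values[1],
                                                    .Machine$double.xmin)) {
        warnf("eLORETA weight block %d is rank deficient", p)
        rank_warned <- TRUE
      }
      delta <- max(delta, norm(Wnew - W[, , p], "F") /
                     max(norm(W[, , p], "F"), .Machine$double.eps))
      W[, , p] <- Wnew
    }
    if (delta < tol) {
      for (p in seq_len(P)) Winv[, , p] <- ridge_inv(W[, , p])
      return(list(W = W, W_inv = Winv, M = M, iterations = it,
                  residual = delta))
    }
  }
  stopf("eLORETA weights did not converge in %d iterations (residual %.3g)",
        max_iter, delta)
}

# 3P x N eLORETA inverse operator from converged weights.
eloreta_operator <- function(K, weights) {
  P <- ncol(K) / 3
  MK <- weights$M %*% K
  L <- matrix(0, 3 * P, nrow(K))
  for (p in seq_len(P)) {
    j <- (3 * (p - 1) + 1):(3 * p)
    L[j, ] <- weights$W_inv[, , p] %*% t(MK[, j, drop = FALSE])
  }
  L
}

#' eLORETA source estimate
#'
#' Weighted minimum-norm solution
#' `Y_p = W_p^-1 K_p' (K W^-1 K' + gamma I)^-1 X` with the weight blocks of
#' [eloreta_weights()]; the scalar map is the time-summed squared moment norm
#' per dipole.
#'
#' @inheritParams sloreta
#' @param weights optional precomputed [eloreta_weights()] result (reused
#'   across datasets: the weights depend only on `K` and `gamma`)
#' @param gamma regularization (default 0: exact-localization regime)
#' @return an `esi_solution` with moments and power map
#' @export
eloreta <- function(lf, X, gamma = 0, grid = NULL, weights = NULL, ...) {
  K <- if (inherits(lf, "lead_field")) lf$K else lf
  grid <- grid %||% (if (inherits(lf, "lead_field")) lf$grid else NULL)
  X <- rec_data(X)
  if (is.null(weights)) weights <- eloreta_weights(K, gamma = gamma, ...)
  L <- eloreta_operator(K, weights)
  Y <- L %*% X
  vals <- colSums(matrix(rowSums(Y^2), nrow = 3))
  structure(list(
    operator = L, gamma = gamma, solver = "eloreta", moments = Y,
    weights = weights,
    map = source_map(vals, grid, "eloreta", gamma = gamma)),
    class = c("eloreta_solution", "esi_solution"))
}

#' Leave-one-out cross-validation of the regularization parameter
#'
#' For each candidate `gamma` and each electrode, sources are estimated from
#' the remaining channels and the held-out channel is predicted through its
#' lead-field row; the `gamma` minimizing the mean squared prediction error is
#' returned.
#'
#' @param lf a `lead_field` or N x 3P matrix
#' @param X data (matrix or `sensor_recording`)
#' @param solver `"eloreta"`, `"sloreta"` (minimum-norm moments) or `"lcmv"`
#' @param gamma_grid candidate values; default 10 log-spaced values spanning
#'   `1e-6` to `1e-1` times the mean diagonal of the data covariance
#' @param warm_start reuse full-montage eLORETA weights as initialization for
#'   the reduced-montage refits (much faster, identical optimum in practice)
#' @return the selected gamma (attribute `errors`: per-gamma mean errors)
#' @export
reg_loocv <- function(lf, X, solver = c("eloreta", "sloreta", "lcmv"),
                      gamma_grid = NULL, warm_start = TRUE) {
  solver <- match.arg(solver)
  K <- if (inherits(lf, "lead_field")) lf$K else lf
  X <- rec_data(X)
  N <- nrow(K)
  assert_that(N >= 3, "need at least 3 channels for leave-one-out")
  if (is.null(gamma_grid)) {
    C <- estimate_covariance(X)
    gamma_grid <- 10^seq(-6, -1, length.out = 10) * mean(diag(C))
  }
  assert_that(length(gamma_grid) >= 1, "gamma_grid must be non-empty")
  if (length(gamma_grid) == 1) return(gamma_grid)

  errs <- numeric(length(gamma_grid))
  for (g in seq_along(gamma_grid)) {
    gamma <- gamma_grid[g]
    full_w <- if (solver == "eloreta") {
      tryCatch(eloreta_weights(K, gamma = gamma), error = function(e) NULL)
    } else NULL
    if (solver == "eloreta" && is.null(full_w)) {
      errs[g] <- Inf
      next
    }
    se <- 0
    for (i in seq_len(N)) {
      Kr <- K[-i, , drop = FALSE]
      Xr <- X[-i, , drop = FALSE]
      Yhat <- switch(solver,
        eloreta = {
          # A gamma whose weight iteration stalls is simply not a candidate.
          w <- tryCatch(
            eloreta_weights(Kr, gamma = gamma,
                            W_init = if (warm_start) full_w$W else NULL),
            error = function(e) NULL)
          if (is.null(w)) NULL else eloreta_operator(Kr, w) %*% Xr
        },
        sloreta = {
          G <- Kr %*% t(Kr) + gamma * diag(N - 1)
          t(Kr) %*% ((if (gamma > 0) solve(G) else pinv(G)) %*% Xr)
        },
        lcmv = {
          C <- estimate_covariance(Xr)
          sol <- lcmv(Kr, C, gamma = gamma, return_filters = TRUE)
          do.call(rbind, lapply(sol$filters, function(w) w %*% Xr))
        })
      if (is.null(Yhat)) {
        se <- Inf
        break
      }
      xhat <- K[i, , drop = FALSE] %*% Yhat
      se <- se + sum((X[i, ] - xhat)^2)
    }
    errs[g] <- se / (N * ncol(X))
  }
  out <- gamma_grid[which.min(errs)]
  attr(out, "errors") <- errs
  out
}
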