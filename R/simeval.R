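#' Surrogate simulation configuration
#'
#' Study conditions for the single-dipole surrogate evaluation: 0.1 s of
#' white-Gaussian dipole activity at 1 kHz (100 samples), sensor noise at
#' 5/10/15/25 dB SNR, three fixed perpendicular orientations, full crossing
#' over the source grid.
#'
#' @param n_samples samples per trial (default 100)
#' @param fs sampling rate, Hz (default 1000)
#' @param snr_db SNR levels in dB (default 5, 10, 15, 25)
#' @param seed master seed; per-(dipole, axis, SNR) streams are derived from
#'   it by counter-based splitting
#' @param loocv_dipoles number of evenly spaced dipole positions over which
#'   the eLORETA leave-one-out gamma is averaged per SNR
#' @param gamma_grid relative LOOCV grid (multiplied by the mean diagonal of
#'   each dataset's covariance)
#' @return a `surrogate_config` list
#' @export
surrogate_config <- function(n_samples = 100, fs = 1000,
                             snr_db = c(5, 10, 15, 25), seed = 1,
                             loocv_dipoles = 8,
                             gamma_grid = 10^seq(-4, -1, length.out = 4)) {
  assert_that(n_samples >= 2, "need at least 2 samples")
  assert_that(all(is.finite(snr_db)), "SNR levels must be finite")
  structure(list(n_samples = n_samples, fs = fs, snr_db = snr_db, seed = seed,
                 loocv_dipoles = loocv_dipoles, gamma_grid = gamma_grid),
            class = "surrogate_config")
}

#' Simulate a clean single-dipole trial
#'
#' White-Gaussian dipole moment time course projected through the lead-field
#' column of one dipole and one fixed orientation; no sensor noise. Uses the
#' current RNG state.
#'
#' @param lf a `lead_field`
#' @param p dipole index in the grid
#' @param orientation 1, 2, 3 or "x", "y", "z"
#' @param n_samples trial length in samples
#' @return N x T clean potential matrix (attribute `source_tc`: the moment
#'   time course)
#' @export
simulate_dipole_trial <- function(lf, p, orientation, n_samples = 100) {
  K <- if (inherits(lf, "lead_field")) lf$K else lf
  ax <- if (is.character(orientation)) {
    match(tolower(orientation), c("x", "y", "z"))
  } else as.integer(orientation)
  if (is.na(ax) || ax < 1 || ax > 3) stopf("orientation must be x, y or z")
  s <- rnorm(n_samples)
  X <- K[, 3 * (p - 1) + ax] %o% s
  attr(X, "source_tc") <- s
  X
}

#' Add white sensor noise at a prescribed SNR
#'
#' Measures the mean signal power pooled across all channels and samples and
#' adds i.i.d. Gaussian noise with power `P_sig / 10^(snr_db/10)`, the same
#' variance on every channel.
#'
#' @param X_clean clean N x T potentials
#' @param snr_db target signal-to-noise ratio in dB
#' @param per_channel scale noise to each channel's own power instead of the
#'   pooled power
#' @return noisy matrix (attribute `noise_var`)
#' @export
add_channel_noise <- function(X_clean, snr_db, per_channel = FALSE) {
  X_clean <- rec_data(X_clean)
  p_sig <- if (per_channel) rowMeans(X_clean^2) else mean(X_clean^2)
  if (all(p_sig == 0)) stopf("zero signal: SNR undefined")
  nv <- p_sig / 10^(snr_db / 10)
  noise <- matrix(rnorm(length(X_clean)), nrow(X_clean)) *
    sqrt(if (per_channel) rep(nv, ncol(X_clean)) else nv)
  out <- X_clean + noise
  attr(out, "noise_var") <- nv
  out
}

map_values <- function(map) {
  if (inherits(map, "source_map")) map$values else as.numeric(map)
}

# A length-1 true_p is a grid index; a length-3 true_p is a position in mm.
true_position <- function(grid, true_p) {
  if (length(true_p) == 1) grid$pos[true_p, ] else as.numeric(true_p)
}

#' ED1 localization error
#'
#' Euclidean distance (mm) between the simulated dipole position and the
#' position of the map's global maximum; ties resolved to the lowest dipole
#' index.
#'
#' @param map a `source_map` (or numeric vector with `grid`)
#' @param true_p true dipole index, or a position in mm
#' @param grid `source_grid` when `map` is a bare vector
#' @return distance in mm
#' @export
ed1 <- function(map, true_p, grid = NULL) {
  grid <- grid %||% map$grid
  y <- map_values(map)
  if (all(y == 0)) stopf("all-zero source map: ED1 undefined")
  imax <- which.max(y)   # which.max takes the first (lowest index) on ties
  sqrt(sum((grid$pos[imax, ] - true_position(grid, true_p))^2))
}

#' Local maxima of a source map
#'
#' A dipole is a local maximum iff its value exceeds all its 26-neighbourhood
#' grid neighbours; connected plateaus of equal value collapse to their
#' lowest-index representative. The global maximum is always included.
#'
#' @inheritParams ed1
#' @return tibble with columns `dipole`, `x`, `y`, `z`, `value`
#' @export
find_local_maxima <- function(map, grid = NULL) {
  grid <- grid %||% map$grid
  y <- map_values(map)
  nbm <- grid$nb_mat
  nbv <- matrix(y[nbm], nrow = grid$P)
  nbv[is.na(nbv)] <- -Inf
  nmax <- do.call(pmax, as.data.frame(nbv))
  cand <- which(y >= nmax)

  # Plateau collapse is only needed when equal-valued neighbours both qualify.
  has_plateau <- length(cand) > 1 &&
    any(nbv[cand, , drop = FALSE] == y[cand], na.rm = TRUE)
  if (!has_plateau) {
    reps <- cand
  } else if (length(cand) > 1) {
    # Collapse equal-valued plateaus among candidates (union-find).
    parent <- seq_len(grid$P)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    in_cand <- logical(grid$P); in_cand[cand] <- TRUE
    for (p in cand) {
      nb <- grid$neighbors[[p]]
      eq <- nb[in_cand[nb] & y[nb] == y[p]]
      for (q in eq) {
        rp <- find(p); rq <- find(q)
        if (rp != rq) parent[max(rp, rq)] <- min(rp, rq)
      }
    }
    reps <- sort(unique(vapply(cand, find, integer(1))))
  } else reps <- cand

  vals <- y[reps]
  tibble::tibble(dipole = reps,
                 x = grid$pos[reps, 1], y = grid$pos[reps, 2],
                 z = grid$pos[reps, 3], value = vals)
}

#' ED2 activation-weighted localization error
#'
#' Sum over all local maxima of the distance to the true dipole position,
#' each weighted by the local maximum's activation relative to the global
#' maximum (the global maximum enters with weight 1).
#'
#' @inheritParams ed1
#' @return dimensionless weighted distance
#' @export
ed2 <- function(map, true_p, grid = NULL) {
  grid <- grid %||% map$grid
  y <- map_values(map)
  if (all(y == 0)) stopf("all-zero source map: ED2 undefined")
  lm <- find_local_maxima(map, grid)
  rt <- true_position(grid, true_p)
  d <- sqrt((lm$x - rt[1])^2 + (lm$y - rt[2])^2 + (lm$z - rt[3])^2)
  sum(d * abs(lm$value / max(lm$value)))
}

#' Reliability map from paired simulated/estimated activation families
#'
#' For a family of `I` test simulations, the reliability value at position `p`
#' is the mean absolute difference between the estimated and simulated
#' activations after normalizing each family member to unit Euclidean norm
#' over positions. Values lie in `[0, 1]`; 0 means the normalized estimate
#' reproduces the normalized simulation exactly.
#'
#' @param sim_family I x P matrix of simulated (non-negative) activations
#' @param est_family I x P matrix of estimated activations
#' @return numeric vector of length P
#' @export
reliability_map <- function(sim_family, est_family) {
  sim_family <- as.matrix(sim_family); est_family <- as.matrix(est_family)
  assert_that(all(dim(sim_family) == dim(est_family)),
              "families must have identical dimensions")
  acc <- numeric(ncol(sim_family))
  used <- 0L
  for (i in seq_len(nrow(sim_family))) {
    en <- sqrt(sum(est_family[i, ]^2))
    sn <- sqrt(sum(sim_family[i, ]^2))
    if (en == 0 || sn == 0) {
      warnf("zero-norm activation in family member %d; skipped", i)
      next
    }
    acc <- acc + abs(est_family[i, ] / en - sim_family[i, ] / sn)
    used <- used + 1L
  }
  if (used == 0L) stopf("no usable family members")
  acc / used
}

# Fast per-dataset map evaluators used by the sweep ---------------------------

# Vectorized symmetric 3x3 block algebra over all dipoles at once. Blocks are
# given by six P-vectors of entries (11, 22, 33, 12, 13, 23).
sym3_blocks <- function(A, B) {
  # G_p = A_p' B_p for N x 3P matrices A, B (blocks of 3 columns).
  i1 <- seq(1, ncol(A), by = 3); i2 <- i1 + 1; i3 <- i1 + 2
  list(g11 = colSums(A[, i1, drop = FALSE] * B[, i1, drop = FALSE]),
       g22 = colSums(A[, i2, drop = FALSE] * B[, i2, drop = FALSE]),
       g33 = colSums(A[, i3, drop = FALSE] * B[, i3, drop = FALSE]),
       g12 = colSums(A[, i1, drop = FALSE] * B[, i2, drop = FALSE]),
       g13 = colSums(A[, i1, drop = FALSE] * B[, i3, drop = FALSE]),
       g23 = colSums(A[, i2, drop = FALSE] * B[, i3, drop = FALSE]))
}

sym3_det <- function(g) {
  g$g11 * (g$g22 * g$g33 - g$g23^2) -
    g$g12 * (g$g12 * g$g33 - g$g23 * g$g13) +
    g$g13 * (g$g12 * g$g23 - g$g22 * g$g13)
}

# tr(G^-1) per block.
sym3_inv_trace <- function(g) {
  c11 <- g$g22 * g$g33 - g$g23^2
  c22 <- g$g11 * g$g33 - g$g13^2
  c33 <- g$g11 * g$g22 - g$g12^2
  (c11 + c22 + c33) / sym3_det(g)
}

# tr(G^-1 S) per block for symmetric blocks G, S.
sym3_inv_quad <- function(g, s) {
  a11 <- g$g22 * g$g33 - g$g23^2
  a22 <- g$g11 * g$g33 - g$g13^2
  a33 <- g$g11 * g$g22 - g$g12^2
  a12 <- g$g13 * g$g23 - g$g12 * g$g33
  a13 <- g$g12 * g$g23 - g$g13 * g$g22
  a23 <- g$g12 * g$g13 - g$g11 * g$g23
  (a11 * s$g11 + a22 * s$g22 + a33 * s$g33 +
     2 * (a12 * s$g12 + a13 * s$g13 + a23 * s$g23)) / sym3_det(g)
}

# LCMV NAI map from data covariance (gamma by the eigenvalue rule).
lcmv_map_fast <- function(K, C, denom, gamma = NULL) {
  if (is.null(gamma)) gamma <- reg_from_eigenvalue(C)
  N <- nrow(K)
  Ci <- solve(C + gamma * diag(N))
  sym3_inv_trace(sym3_blocks(K, Ci %*% K)) / denom
}

# Precomputed pieces for fast repeated sLORETA maps: KK' = U diag(lam) U'.
sloreta_precompute <- function(K) {
  e <- eigen(K %*% t(K), symmetric = TRUE)
  list(U = e$vectors, lam = pmax(e$values, 0), Z = t(e$vectors) %*% K)
}

sloreta_map_fast <- function(pre, X, gamma) {
  d <- 1 / (pre$lam + gamma)
  if (gamma == 0) d[pre$lam < max(pre$lam) * 1e-12] <- 0
  Y <- t(pre$Z) %*% (d * (t(pre$U) %*% X))      # 3P x T minimum-norm moments
  R <- sym3_blocks(pre$Z, d * pre$Z)            # resolution diagonal blocks
  i1 <- seq(1, nrow(Y), by = 3); i2 <- i1 + 1; i3 <- i1 + 2
  S <- list(g11 = rowSums(Y[i1, , drop = FALSE]^2),
            g22 = rowSums(Y[i2, , drop = FALSE]^2),
            g33 = rowSums(Y[i3, , drop = FALSE]^2),
            g12 = rowSums(Y[i1, , drop = FALSE] * Y[i2, , drop = FALSE]),
            g13 = rowSums(Y[i1, , drop = FALSE] * Y[i3, , drop = FALSE]),
            g23 = rowSums(Y[i2, , drop = FALSE] * Y[i3, , drop = FALSE]))
  sym3_inv_quad(R, S)
}

eloreta_map_fast <- function(L, X) {
  Y <- L %*% X
  colSums(matrix(rowSums(Y^2), nrow = 3))
}

#' Surrogate single-dipole evaluation sweep
#'
#' Full crossing of grid dipoles x 3 orientations x SNR levels x solvers:
#' each cell simulates a white-noise dipole trial, adds sensor noise, runs
#' the inverse solution and scores ED1/ED2 against the true position;
#' per-solver reliability maps and a summary table (mean and population SD of
#' ED1 and ED2 over all dipole/orientation cells per solver and SNR) are
#' accumulated. Deterministic under the configuration seed.
#'
#' The eLORETA regularization per SNR is the mean of leave-one-out
#' cross-validated values over a spread of dipole positions, then frozen for
#' the sweep; sLORETA uses 5% of the mean covariance diagonal per dataset;
#' LCMV uses the largest-eigenvalue rule per dataset.
#'
#' @param lf a `lead_field`
#' @param solvers subset of `"sloreta"`, `"eloreta"`, `"lcmv"`
#' @param cfg a [surrogate_config()]
#' @param dipoles optional subset of dipole indices to sweep (default: all)
#' @return an `eval_maps` object: `summary` tibble, per-solver/SNR ED1, ED2
#'   and reliability maps, and the configuration
#' @export
surrogate_sweep <- function(lf, solvers = c("sloreta", "eloreta", "lcmv"),
                            cfg = surrogate_config(), dipoles = NULL) {
  solvers <- match.arg(solvers, several.ok = TRUE)
  K <- lf$K
  grid <- lf$grid
  P <- grid$P
  dipoles <- dipoles %||% seq_len(P)
  nS <- length(cfg$snr_db)
  denom <- if ("lcmv" %in% solvers) nai_denominator(K) else NULL
  pre <- if ("sloreta" %in% solvers) sloreta_precompute(K) else NULL

  # Per-SNR eLORETA gamma: mean LOOCV over spread dipole positions, frozen.
  elor_ops <- list()
  if ("eloreta" %in% solvers) {
    probe <- dipoles[unique(round(seq(1, length(dipoles),
                                      length.out = min(cfg$loocv_dipoles,
                                                       length(dipoles)))))]
    for (s in seq_len(nS)) {
      gammas <- vapply(seq_along(probe), function(k) {
        p <- probe[k]
        X <- with_seed(substream_seed(cfg$seed, 900, s, k), {
          add_channel_noise(simulate_dipole_trial(lf, p, 1, cfg$n_samples),
                            cfg$snr_db[s])
        })
        grid_abs <- cfg$gamma_grid * mean(diag(estimate_covariance(X)))
        as.numeric(reg_loocv(K, X, solver = "eloreta",
                             gamma_grid = grid_abs))
      }, numeric(1))
      g <- mean(gammas)
      w <- eloreta_weights(K, gamma = g)
      elor_ops[[s]] <- list(gamma = g, L = eloreta_operator(K, w))
    }
  }

  dims <- c(length(dipoles), 3, nS)
  res <- list()
  for (sv in solvers) {
    res[[sv]] <- list(ed1 = array(NA_real_, dims), ed2 = array(NA_real_, dims),
                      rel = matrix(0, nS, P), rel_n = integer(nS))
  }

  for (di in seq_along(dipoles)) {
    p <- dipoles[di]
    for (ax in 1:3) {
      clean <- with_seed(substream_seed(cfg$seed, 1, p, ax),
                         simulate_dipole_trial(lf, p, ax, cfg$n_samples))
      sim_act <- numeric(P)
      sim_act[p] <- sum(attr(clean, "source_tc")^2)
      sim_norm <- sim_act / sqrt(sum(sim_act^2))
      for (s in seq_len(nS)) {
        X <- with_seed(substream_seed(cfg$seed, 2, p, ax, s),
                       add_channel_noise(clean, cfg$snr_db[s]))
        for (sv in solvers) {
          vals <- switch(sv,
            lcmv = lcmv_map_fast(K, estimate_covariance(X), denom),
            sloreta = {
              g <- 0.05 * mean(diag(estimate_covariance(X)))
              sloreta_map_fast(pre, X, g)
            },
            eloreta = eloreta_map_fast(elor_ops[[s]]$L, X))
          m <- source_map(vals, grid, sv)
          res[[sv]]$ed1[di, ax, s] <- ed1(m, p)
          res[[sv]]$ed2[di, ax, s] <- ed2(m, p)
          en <- sqrt(sum(vals^2))
          if (en > 0) {
            res[[sv]]$rel[s, ] <- res[[sv]]$rel[s, ] + abs(vals / en - sim_norm)
            res[[sv]]$rel_n[s] <- res[[sv]]$rel_n[s] + 1L
          }
        }
      }
    }
  }

  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  summary_tbl <- purrr::map_dfr(solvers, function(sv) {
    purrr::map_dfr(seq_len(nS), function(s) {
      tibble::tibble(
        solver = sv, snr_db = cfg$snr_db[s],
        metric = c("ed1", "ed2"),
        mean = c(mean(res[[sv]]$ed1[, , s]), mean(res[[sv]]$ed2[, , s])),
        sd = c(pop_sd(res[[sv]]$ed1[, , s]), pop_sd(res[[sv]]$ed2[, , s])))
    })
  })

  maps <- purrr::map(res, function(r) {
    list(ed1 = apply(r$ed1, c(1, 3), mean),
         ed2 = apply(r$ed2, c(1, 3), mean),
         reliability = sweep(r$rel, 1, pmax(r$rel_n, 1L), "/"))
  })

  structure(list(summary = summary_tbl, maps = maps, cells = res,
                 dipoles = dipoles, config = cfg,
                 gammas = if (length(elor_ops)) {
                   vapply(elor_ops, `[[`, numeric(1), "gamma")
                 } else NULL,
                 grid = grid),
            class = "eval_maps")
}

#' @export
print.eval_maps <- function(x, ...) {
  cat(sprintf("<eval_maps> %d dipoles x 3 orientations x %d SNR levels\n",
              length(x$dipoles), length(x$config$snr_db)))
  print(tidyr::pivot_wider(x$summary,
                           names_from = "snr_db",
                           values_from = c("mean", "sd")), n = Inf)
  invisible(x)
}
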