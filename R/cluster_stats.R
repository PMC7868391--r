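#' Paired one-sided t map over dipoles
#'
#' One-sided paired t statistic (`A > B`) in each source position, df = n-1.
#' The canonical contrast condition `B` is each subject's whole-brain mean
#' activity broadcast to all dipoles, see [whole_brain_contrast()].
#'
#' @param A,B subjects x dipoles matrices (aligned)
#' @return numeric t values, length P; zero-variance differences give a
#'   signed infinite sentinel with a warning
#' @export
paired_t_map <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  assert_that(all(dim(A) == dim(B)), "A and B must be aligned")
  n <- nrow(A)
  assert_that(n >= 2, "need at least 2 subjects")
  D <- A - B
  m <- colMeans(D)
  s <- sqrt(colSums(sweep(D, 2, m)^2) / (n - 1))
  t_ <- m / (s / sqrt(n))
  degen <- s == 0
  if (any(degen)) {
    warnf("%d dipole(s) with zero-variance differences: infinite t sentinel",
          sum(degen))
    t_[degen] <- sign(m[degen]) * Inf
    t_[degen & m == 0] <- 0
  }
  t_
}

#' Whole-brain mean contrast condition
#'
#' The per-subject average activity over all dipoles, broadcast to every
#' dipole, used as the contrast condition when the whole brain shows a
#' global activity increase.
#'
#' @param A subjects x dipoles matrix
#' @return matrix of the same shape
#' @export
whole_brain_contrast <- function(A) {
  A <- as.matrix(A)
  matrix(rowMeans(A), nrow(A), ncol(A))
}

# Connected components of a dipole subset under grid adjacency (BFS).
connected_components <- function(members, neighbors) {
  in_set <- logical(length(neighbors))
  in_set[members] <- TRUE
  seen <- logical(length(neighbors))
  comps <- list()
  for (m in members) {
    if (seen[m]) next
    comp <- integer(0)
    queue <- m
    seen[m] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, v)
      nb <- neighbors[[v]]
      nb <- nb[in_set[nb] & !seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

#' Form supra-threshold clusters from a t map
#'
#' Thresholds the t map at the one-sided t quantile of `threshold_p` and
#' groups supra-threshold dipoles into connected components under the grid
#' adjacency (26-neighbourhood by default); cluster mass is the sum of member
#' t values.
#'
#' @param t_map t values per dipole
#' @param threshold_p cluster-forming p threshold (e.g. `1e-3` for the late
#'   and entrainment windows, `1e-9` for the thalamic component)
#' @param grid a `source_grid` providing the adjacency
#' @param df degrees of freedom of the t map
#' @return list of clusters (`members`, `mass`), ordered by decreasing mass;
#'   empty list when nothing is supra-threshold
#' @export
form_clusters <- function(t_map, threshold_p, grid, df) {
  assert_that(df >= 1, "df must be at least 1")
  t_star <- qt(1 - threshold_p, df)
  supra <- which(t_map > t_star)
  if (length(supra) == 0) return(list())
  comps <- connected_components(supra, grid$neighbors)
  comps <- lapply(comps, function(cm) {
    list(members = cm, mass = sum(t_map[cm]))
  })
  comps[order(-vapply(comps, `[[`, numeric(1), "mass"))]
}

#' Cluster-based permutation test on source maps
#'
#' Non-parametric family-wise-error-controlled test: the observed paired
#' one-sided t map is clustered at the `threshold_p` quantile; the null
#' distribution of the maximum cluster mass is built by exchanging the
#' condition labels within subjects (equivalently, random sign flips of the
#' paired differences), and each observed cluster receives the Monte Carlo p
#' value `(1 + #(null >= mass)) / (1 + n_perm)`. Clusters with p below
#' `alpha` are marked significant.
#'
#' @param A,B subjects x dipoles condition matrices
#' @param grid a `source_grid`
#' @param n_perm number of permutations (default 1000)
#' @param threshold_p cluster-forming threshold
#' @param alpha cluster significance level
#' @param seed RNG seed for the permutations
#' @return a `cluster_result`: t map, cluster table, per-dipole significance
#'   mask, null distribution
#' @export
cluster_permutation_test <- function(A, B, grid, n_perm = 1000,
                                     threshold_p = 1e-3, alpha = 0.05,
                                     seed = 1) {
  assert_that(n_perm >= 1, "n_perm must be at least 1")
  A <- as.matrix(A); B <- as.matrix(B)
  n <- nrow(A)
  df <- n - 1
  t_obs <- paired_t_map(A, B)
  obs_clusters <- form_clusters(t_obs, threshold_p, grid, df)

  D <- A - B
  colssq <- colSums(D^2)
  t_star <- qt(1 - threshold_p, df)
  null_mass <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      sgn <- sample(c(-1, 1), n, replace = TRUE)
      m <- as.vector(sgn %*% D) / n
      s2 <- (colssq - n * m^2) / (n - 1)
      tt <- m / sqrt(s2 / n)
      tt[s2 <= 0] <- 0
      supra <- which(tt > t_star)
      if (length(supra) == 0) return(0)
      max(vapply(connected_components(supra, grid$neighbors),
                 function(cm) sum(tt[cm]), numeric(1)))
    }, numeric(1))
  })

  cluster_tbl <- if (length(obs_clusters) == 0) {
    tibble::tibble(id = integer(0), size = integer(0), mass = numeric(0),
                   p = numeric(0), significant = logical(0))
  } else {
    purrr::map_dfr(seq_along(obs_clusters), function(i) {
      cl <- obs_clusters[[i]]
      p <- (1 + sum(null_mass >= cl$mass)) / (1 + n_perm)
      tibble::tibble(id = i, size = length(cl$members), mass = cl$mass,
                     p = p, significant = p < alpha)
    })
  }
  mask <- logical(grid$P)
  for (i in seq_along(obs_clusters)) {
    if (nrow(cluster_tbl) >= i && cluster_tbl$significant[i]) {
      mask[obs_clusters[[i]]$members] <- TRUE
    }
  }
  structure(list(t = t_obs, clusters = obs_clusters, table = cluster_tbl,
                 mask = mask, null_mass = null_mass, n_perm = n_perm,
                 threshold_p = threshold_p, t_star = t_star, alpha = alpha,
                 df = df, grid = grid),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s) at p < %g forming threshold (t* = %.2f, df = %d), %d permutations\n",
              length(x$clusters), x$threshold_p, x$t_star, x$df, x$n_perm))
  if (nrow(x$table)) print(x$table)
  invisible(x)
}
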