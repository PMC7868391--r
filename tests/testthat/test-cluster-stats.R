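test_that("the paired one-sided t map matches hand calculation", {
  A <- matrix(rnorm(5 * 7), 5)
  expect_warning(t0 <- paired_t_map(A, A), "zero-variance")
  expect_equal(t0, rep(0, 7))

  # differences 1, 2, 3 -> t = mean/(sd/sqrt(n)) = 2 sqrt(3)
  A2 <- matrix(c(1, 2, 3), 3, 1)
  B2 <- matrix(0, 3, 1)
  expect_equal(paired_t_map(A2, B2), 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(paired_t_map(A2, B2), 3.4641, tolerance = 1e-4)

  # zero-variance differences get a signed infinite sentinel
  A3 <- cbind(c(1, 1, 1), c(-2, -2, -2), c(0, 0, 0))
  expect_warning(t3 <- paired_t_map(A3, 0 * A3), "zero-variance")
  expect_equal(t3, c(Inf, -Inf, 0))

  # the canonical contrast condition broadcasts subject means
  wb <- whole_brain_contrast(A)
  expect_equal(wb[, 1], rowMeans(A))
  expect_equal(wb[, 3], rowMeans(A))
})

test_that("cluster forming matches brute-force connected components", {
  mdl <- small_model()
  grid <- mdl$grid
  t_map <- rep(0, grid$P)
  expect_equal(length(form_clusters(t_map, 1e-3, grid, df = 19)), 0)

  t_star <- qt(1 - 1e-3, 19)
  # two adjacent supra-threshold dipoles: one cluster of size 2
  p <- 20; q <- grid$neighbors[[20]][1]
  t_map[c(p, q)] <- t_star + 1
  cl <- form_clusters(t_map, 1e-3, grid, df = 19)
  expect_equal(length(cl), 1)
  expect_setequal(cl[[1]]$members, c(p, q))
  expect_equal(cl[[1]]$mass, 2 * (t_star + 1))

  # a far non-adjacent dipole: two clusters
  far <- which.max(rowSums(sweep(grid$pos, 2, grid$pos[p, ])^2))
  t_map[far] <- t_star + 2
  cl2 <- form_clusters(t_map, 1e-3, grid, df = 19)
  expect_equal(length(cl2), 2)
  # ordered by decreasing mass: the two-dipole cluster outweighs the singleton
  expect_setequal(cl2[[1]]$members, c(p, q))
  expect_equal(cl2[[2]]$members, far)
})

test_that("the permutation test is reproducible, monotone and detects planted effects", {
  mdl <- small_model()
  grid <- mdl$grid
  set.seed(5)
  n <- 20
  A <- matrix(rnorm(n * grid$P), n)
  B <- matrix(rnorm(n * grid$P), n)
  r1 <- cluster_permutation_test(A, B, grid, n_perm = 300, seed = 9)
  r2 <- cluster_permutation_test(A, B, grid, n_perm = 300, seed = 9)
  expect_identical(r1$null_mass, r2$null_mass)
  expect_identical(r1$table, r2$table)

  # relabeling the conditions flips the t map sign
  r3 <- cluster_permutation_test(B, A, grid, n_perm = 10, seed = 9)
  expect_equal(r3$t, -r1$t)

  # p decreases monotonically with observed mass against a fixed null
  null <- r1$null_mass
  p_of <- function(mass) (1 + sum(null >= mass)) / (1 + length(null))
  masses <- quantile(null, c(0.2, 0.5, 0.9, 0.999))
  expect_true(all(diff(vapply(masses, p_of, numeric(1))) <= 0))

  # a strong planted cluster (2 SD effect, 20 subjects) is detected
  eff <- numeric(grid$P)
  eff[c(30, grid$neighbors[[30]])] <- 2
  A2 <- A + matrix(eff, n, grid$P, byrow = TRUE)
  r4 <- cluster_permutation_test(A2, B, grid, n_perm = 1000, seed = 10)
  expect_gt(nrow(r4$table), 0)
  expect_lte(min(r4$table$p), 0.01)
  expect_true(30 %in% r4$clusters[[which.min(r4$table$p)]]$members)
  # the mask is confined to significant clusters
  expect_true(all(which(r4$mask) %in%
                    unlist(lapply(r4$clusters[r4$table$significant],
                                  `[[`, "members"))))
})

test_that("tidiers summarize cluster results", {
  mdl <- small_model()
  set.seed(6)
  A <- matrix(rnorm(10 * mdl$grid$P), 10)
  eff <- numeric(mdl$grid$P)
  eff[c(25, mdl$grid$neighbors[[25]])] <- 3
  A <- A + matrix(eff, 10, mdl$grid$P, byrow = TRUE)
  r <- cluster_permutation_test(A, whole_brain_contrast(A),
                                mdl$grid, n_perm = 200, seed = 3)
  td <- tidy(r)
  expect_true(all(c("id", "size", "mass", "p", "significant") %in% names(td)))
  gl <- glance(r)
  expect_equal(gl$n_perm, 200)
  expect_equal(gl$df, 9)
})
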