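test_that("the FEM operator has the Neumann structure", {
  mdl <- small_model()
  A <- assemble_fem_system(mdl$mesh)
  # partition of unity: row sums vanish
  expect_lt(max(abs(Matrix::rowSums(A))), 1e-10 * max(abs(A)))
  # constant potentials span the null space
  v <- rep(1, nrow(A))
  expect_lt(max(abs(as.vector(A %*% v))), 1e-10 * max(abs(A)))
})

test_that("element stiffness matches a hand-assembled local matrix", {
  # single reference tetrahedron (mm coordinates)
  nodes <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
  mesh <- structure(list(nodes = nodes, elems = matrix(1:4, 1),
                         sigma = 0.5, label = 1L, volume_info = NULL),
                    class = "tet_mesh")
  A <- as.matrix(assemble_fem_system(mesh))
  # hand assembly in SI units: edge length 2 mm = 2e-3 m
  h <- 2e-3
  V <- h^3 / 6
  g <- rbind(c(-1, -1, -1), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)) / h
  S_hand <- 0.5 * V * g %*% t(g)
  expect_equal(A, S_hand, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("St. Venant loads conserve charge and reproduce the moment", {
  mdl <- small_model()
  moment <- c(2e-9, -1e-9, 3e-9)
  ld <- st_venant_load(mdl$mesh, c(0.4, -0.7, 0.6), moment)
  expect_lt(abs(sum(ld$loads)), 1e-12 * max(abs(ld$loads)))
  X <- (mdl$mesh$nodes[ld$nodes, ] -
          matrix(c(0.4, -0.7, 0.6), length(ld$nodes), 3, byrow = TRUE)) * 1e-3
  m_real <- colSums(ld$loads * X)
  expect_lt(max(abs(m_real - moment)) / sqrt(sum(moment^2)), 1e-6)

  # linearity in the moment
  ld2 <- st_venant_load(mdl$mesh, c(0.4, -0.7, 0.6), 2 * moment)
  expect_equal(ld2$loads, 2 * ld$loads, tolerance = 1e-9)

  expect_error(st_venant_load(mdl$mesh, c(100, 100, 100), moment), "outside")
})

test_that("transfer-matrix lead field agrees with direct per-dipole solves", {
  mdl <- cached("small_model_raw", {
    m <- small_model()
    list(lf = compute_lead_field(m$mesh, m$montage, m$grid,
                                 average_reference = FALSE),
         mesh = m$mesh, montage = m$montage, grid = m$grid)
  })
  for (p in c(2, 30, 60)) {
    for (ax in 1:3) {
      mom <- c(0, 0, 0); mom[ax] <- 1
      u <- solve_forward_direct(mdl$mesh, mdl$montage, mdl$grid$pos[p, ], mom)
      k <- mdl$lf$K[, 3 * (p - 1) + ax]
      expect_lt(max(abs(u - k)) / max(abs(k)), 1e-8)
    }
  }
})

test_that("average-referenced lead-field columns sum to zero", {
  mdl <- small_model()
  expect_lt(max(abs(colSums(mdl$lf$K))), 1e-9 * max(abs(mdl$lf$K)))
})

test_that("doubling the conductivity halves the lead field", {
  m <- small_model()
  mesh2 <- m$mesh
  mesh2$sigma <- 2 * mesh2$sigma
  lf2 <- compute_lead_field(mesh2, m$montage, m$grid)
  expect_equal(lf2$K, m$lf$K / 2, tolerance = 1e-9)
})

test_that("the analytic sphere potential has the required structure", {
  # central radial dipole: closed form 3 m cos(theta) / (4 pi sigma R^2)
  R <- 10; sigma <- 0.33
  th <- seq(0.1, pi, length.out = 7)
  pts <- cbind(R * sin(th), 0, R * cos(th))
  v <- analytic_sphere_potential(R, sigma, c(0, 0, 0), c(0, 0, 1e-9), pts)
  v_hand <- 3 * 1e-9 * cos(th) / (4 * pi * sigma * (R * 1e-3)^2)
  expect_equal(v, v_hand, tolerance = 1e-9)

  # axial symmetry about the moment axis on a constant-latitude orbit
  phi <- seq(0, 2 * pi, length.out = 13)
  orbit <- cbind(R * sin(1) * cos(phi), R * sin(1) * sin(phi),
                 R * cos(1))
  vo <- analytic_sphere_potential(R, sigma, c(0, 0, 3), c(0, 0, 1), orbit)
  expect_lt(diff(range(vo)), 1e-9 * max(abs(vo)))

  # zero average over a uniform surface sampling, any dipole
  set.seed(1)
  ps <- matrix(rnorm(3 * 4000), ncol = 3)
  ps <- ps / sqrt(rowSums(ps^2)) * R
  vs <- analytic_sphere_potential(R, sigma, c(1, 2, 3), c(1, 1, 0), ps)
  expect_lt(abs(mean(vs)), 0.02 * stats::sd(vs))

  expect_error(analytic_sphere_potential(R, sigma, c(0, 0, 11), c(0, 0, 1),
                                         pts), "inside")
})

test_that("FEM potentials track the analytic sphere solution", {
  mesh <- coarse_sphere()
  A <- assemble_fem_system(mesh)
  bn <- boundary_nodes(mesh)
  ref <- bn[which.min(mesh$nodes[bn, 3])]
  keep <- setdiff(seq_len(nrow(A)), ref)
  fac <- Matrix::Cholesky(A[keep, keep], LDL = FALSE)
  pos <- c(0, 0, 3); mom <- c(1, 0, 1) / sqrt(2)
  ld <- st_venant_load(mesh, pos, mom)
  b <- numeric(nrow(A)); b[ld$nodes] <- ld$loads
  u <- numeric(nrow(A)); u[keep] <- as.vector(Matrix::solve(fac, b[keep]))
  ufem <- u[bn] - mean(u[bn])
  uana <- analytic_sphere_potential(10, 0.33, pos, mom, mesh$nodes[bn, ])
  uana <- uana - mean(uana)
  expect_lt(sqrt(sum((ufem - uana)^2) / sum(uana^2)), 0.05)
})

test_that("lead-field magnitude attenuates with depth under an electrode", {
  mesh <- coarse_sphere()
  A <- assemble_fem_system(mesh)
  bn <- boundary_nodes(mesh)
  top <- bn[which.max(mesh$nodes[bn, 3])]   # electrode at the north pole
  ref <- bn[which.min(mesh$nodes[bn, 3])]
  keep <- setdiff(seq_len(nrow(A)), ref)
  fac <- Matrix::Cholesky(A[keep, keep], LDL = FALSE)
  norms <- vapply(c(8, 6, 4, 2, 0), function(z) {
    blk <- vapply(1:3, function(ax) {
      mom <- c(0, 0, 0); mom[ax] <- 1
      ld <- st_venant_load(mesh, c(0, 0, z), mom)
      b <- numeric(nrow(A)); b[ld$nodes] <- ld$loads
      u <- numeric(nrow(A)); u[keep] <- as.vector(Matrix::solve(fac, b[keep]))
      u[top]
    }, numeric(1))
    sqrt(sum(blk^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})
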