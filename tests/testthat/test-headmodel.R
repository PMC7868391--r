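test_that("synthetic ellipsoid volume matches the closed form within a voxel shell", {
  sa <- c(10, 7, 5)
  vol <- generate_synthetic_brain(semi_axes = sa, voxel = 0.5,
                                  regions = list())
  v_closed <- 4 / 3 * pi * prod(sa)
  # Thomsen surface-area approximation bounds the one-voxel-shell error.
  p <- 1.6075
  area <- 4 * pi * ((sa[1]^p * sa[2]^p + sa[1]^p * sa[3]^p +
                       sa[2]^p * sa[3]^p) / 3)^(1 / p)
  expect_lt(abs(volume_mm3(vol) - v_closed), area * 0.5)
})

test_that("degenerate voxel size is rejected", {
  expect_error(generate_synthetic_brain(semi_axes = c(1, 1, 1), voxel = 2),
               "degenerate")
})

test_that("the default rat-like brain is about 2 cm^3", {
  vol <- generate_synthetic_brain()
  expect_gt(volume_mm3(vol), 1500)
  expect_lt(volume_mm3(vol), 2500)
  # nested regions present: deep blob, caudal lobe, exclusions
  expect_setequal(unique(as.vector(vol$labels)), c(0L, 1L, 2L, 3L, 4L, 5L))
  expect_setequal(vol$include, c(1L, 2L, 3L))
})

test_that("tetrahedralization conserves volume and orientation", {
  cube <- cube_volume(1, 0.5)
  mesh <- tetrahedralize(cube, target_edge = 0.5)
  expect_lt(abs(mesh_volume(mesh) - 1), 0.05)
  expect_gt(min(ratesi:::element_volumes(mesh)), 0)

  vol <- generate_synthetic_brain(semi_axes = c(5, 6, 4), voxel = 0.5,
                                  regions = list())
  mesh2 <- tetrahedralize(vol)
  expect_lt(abs(mesh_volume(mesh2) - volume_mm3(vol)) / volume_mm3(vol), 0.05)
  # remeshing at a different edge stays within 5% of the voxel-count volume
  mesh3 <- tetrahedralize(vol, target_edge = 0.8)
  expect_lt(abs(mesh_volume(mesh3) - volume_mm3(vol)) / volume_mm3(vol), 0.05)

  empty <- cube_volume(1, 0.5)
  empty$labels[] <- 0L
  expect_error(tetrahedralize(empty), "empty mask")
})

test_that("electrode registration snaps to nearest boundary nodes", {
  mesh <- tetrahedralize(cube_volume(10, 1))
  bn <- boundary_nodes(mesh)
  target <- mesh$nodes[bn[10], ]

  # a coordinate exactly at a surface node snaps with zero distance
  coords <- tibble::tibble(
    channel = c("a", "ref"),
    x = c(target[1], 5), y = c(target[2], 5), z = c(target[3], 10),
    reference = c(FALSE, TRUE))
  mon <- register_electrodes(mesh, coords)
  expect_equal(mon$node[1], bn[10])
  expect_equal(mon$snap_dist[1], 0)

  # an interior coordinate moves outward to the brute-force nearest boundary node
  inner <- c(5.2, 5.1, 4.9)
  coords2 <- tibble::tibble(channel = c("in", "ref"),
                            x = c(inner[1], 5), y = c(inner[2], 5),
                            z = c(inner[3], 10),
                            reference = c(FALSE, TRUE))
  mon2 <- register_electrodes(mesh, coords2)
  d_all <- sqrt(rowSums(sweep(mesh$nodes[bn, , drop = FALSE], 2, inner)^2))
  expect_equal(mon2$node[1], bn[which.min(d_all)])
  expect_gt(mon2$snap_dist[1], 0)

  # idempotence: re-registering the snapped coordinates changes nothing
  coords3 <- tibble::tibble(channel = mon2$channel, x = mon2$snap_x,
                            y = mon2$snap_y, z = mon2$snap_z,
                            reference = mon2$reference)
  mon3 <- register_electrodes(mesh, coords3)
  expect_equal(mon3$node, mon2$node)
  expect_equal(max(mon3$snap_dist), 0)

  expect_error(register_electrodes(
    mesh, tibble::tibble(channel = c("a", "a"), x = 0, y = 0, z = 0,
                         reference = c(FALSE, TRUE))), "duplicate")
})

test_that("the source grid enumerates included lattice points exactly", {
  cube <- cube_volume(10, 0.5)
  grid <- build_source_grid(cube, spacing = 1, include = 1L)

  # brute-force lattice scan oracle
  pts <- as.matrix(expand.grid(x = -2:12, y = -2:12, z = -2:12))
  inside <- pts[, 1] >= 0 & pts[, 1] < 10 &
    pts[, 2] >= 0 & pts[, 2] < 10 & pts[, 3] >= 0 & pts[, 3] < 10
  expect_equal(grid$P, sum(inside))

  expect_error(build_source_grid(cube, spacing = 1, include = integer(0)),
               "empty")
  expect_error(build_source_grid(cube, spacing = 1, include = 99L),
               "absent")
})

test_that("grid adjacency is a symmetric 26-neighbourhood one lattice step wide", {
  mdl <- small_model()
  grid <- mdl$grid
  for (p in c(1, 10, grid$P)) {
    nb <- grid$neighbors[[p]]
    expect_lte(length(nb), 26)
    d <- abs(sweep(grid$pos[nb, , drop = FALSE], 2, grid$pos[p, ]))
    expect_true(all(d <= grid$spacing + 1e-9))
    expect_true(all(vapply(nb, function(q) p %in% grid$neighbors[[q]],
                           logical(1))))
  }
})

test_that("every grid dipole lies strictly inside the mesh", {
  cube <- cube_volume(6, 0.6)
  mesh <- tetrahedralize(cube)
  grid <- build_source_grid(cube, spacing = 1.2, include = 1L)
  expect_true(all(points_in_mesh(mesh, grid$pos, method = "barycentric")))

  mdl <- small_model()
  expect_true(all(points_in_mesh(mdl$mesh, mdl$grid$pos, method = "voxel")))
})
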