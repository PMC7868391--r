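#' Generate a synthetic labeled rat-like brain volume
#'
#' Builds an ellipsoidal brain mask on a regular voxel grid, with nested
#' sub-ellipsoids standing in for anatomical regions of interest (a deep
#' diencephalic blob, a caudal cerebellar lobe, and a ventricle that is
#' excluded from the source model). Coordinates are stereotactic millimetres
#' with the bregma at the origin: +x lateral-right, +y anterior, +z dorsal.
#'
#' The default geometry is "rat-like": total brain volume close to 2 cm^3,
#' which matches the approximate volume of the adult rat brain.
#'
#' @param semi_axes numeric length-3, ellipsoid semi-axes in mm (x, y, z).
#' @param voxel voxel edge length in mm.
#' @param center ellipsoid centre in stereotactic mm.
#' @param regions list of region specs, each a list with elements `label`
#'   (integer > 1), `name`, `semi_axes`, `center`, and `include` (logical).
#'   Regions are painted in order on top of the brain mask (label 1).
#'   `NULL` uses the built-in rat-like defaults.
#' @return a `labeled_volume`: integer label array (0 = outside), voxel size,
#'   grid origin (mm coordinate of the centre of voxel `[1,1,1]`), region
#'   table, and the set of labels included in the source model by default.
#' @export
generate_synthetic_brain <- function(semi_axes = c(7.5, 10.5, 6.0),
                                     voxel = 0.5,
                                     center = c(0, -1, 0),
                                     regions = NULL) {
  assert_that(length(semi_axes) == 3 && all(semi_axes > 0),
              "semi_axes must be three positive lengths (mm)")
  assert_that(voxel > 0, "voxel must be positive")
  if (voxel > min(semi_axes)) {
    stopf("degenerate volume: voxel (%g mm) exceeds smallest semi-axis (%g mm)",
          voxel, min(semi_axes))
  }
  if (is.null(regions)) {
    # Default nested regions scale with the brain ellipsoid so scaled-down
    # bench models keep the same relative anatomy. The ventral cap (painted
    # first, so deeper included structures overwrite it) emulates the
    # electrically silent basal structures excluded from the source model;
    # the included diencephalic blob sits on top of it.
    sa <- semi_axes
    regions <- list(
      list(label = 5L, name = "ventral_excluded",
           semi_axes = sa * c(3, 3, 0.67),
           center = center + sa * c(0, 0, -1), include = FALSE),
      list(label = 2L, name = "diencephalon",
           semi_axes = sa * c(0.40, 0.33, 0.42),
           center = center + sa * c(0, -0.095, -0.25), include = TRUE),
      list(label = 3L, name = "cerebellum",
           semi_axes = sa * c(0.47, 0.24, 0.42),
           center = center + sa * c(0, -0.76, 0), include = TRUE),
      list(label = 4L, name = "ventricle",
           semi_axes = sa * c(0.20, 0.24, 0.17),
           center = center + sa * c(0, 0.19, 0.083), include = FALSE)
    )
  }

  lo <- center - semi_axes - voxel
  hi <- center + semi_axes + voxel
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / voxel)))
  origin <- lo + voxel / 2
  xs <- origin[1] + (seq_len(dims[1]) - 1) * voxel
  ys <- origin[2] + (seq_len(dims[2]) - 1) * voxel
  zs <- origin[3] + (seq_len(dims[3]) - 1) * voxel

  in_ellipsoid <- function(sa, ct) {
    dx2 <- ((xs - ct[1]) / sa[1])^2
    dy2 <- ((ys - ct[2]) / sa[2])^2
    dz2 <- ((zs - ct[3]) / sa[3])^2
    outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
  }

  lab <- array(0L, dims)
  lab[in_ellipsoid(semi_axes, center)] <- 1L

  region_tbl <- tibble::tibble(label = 1L, name = "cerebrum", include = TRUE)
  for (rg in regions) {
    inside <- in_ellipsoid(rg$semi_axes, rg$center) & lab > 0L
    lab[inside] <- as.integer(rg$label)
    region_tbl <- dplyr::bind_rows(
      region_tbl,
      tibble::tibble(label = as.integer(rg$label), name = rg$name,
                     include = isTRUE(rg$include)))
  }

  present <- sort(unique(as.vector(lab[lab > 0L])))
  structure(
    list(labels = lab, voxel = voxel, origin = origin,
         regions = region_tbl,
         include = intersect(region_tbl$label[region_tbl$include], present)),
    class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  nvox <- sum(x$labels > 0)
  cat(sprintf("<labeled_volume> %s voxels @ %.3g mm, %d labeled (%.2f cm^3)\n",
              paste(dim(x$labels), collapse = "x"), x$voxel,
              nvox, nvox * x$voxel^3 / 1000))
  print(x$regions)
  invisible(x)
}

#' Volume of the labeled mask in mm^3
#' @param vol a `labeled_volume`
#' @param labels which labels to count (default: all non-zero)
#' @export
volume_mm3 <- function(vol, labels = NULL) {
  if (is.null(labels)) n <- sum(vol$labels > 0L)
  else n <- sum(vol$labels %in% labels)
  n * vol$voxel^3
}

# Voxel index (i,j,k) containing each point under half-open voxel ownership;
# returns NA rows for points outside the array.
voxel_index_of <- function(vol, pts) {
  pts <- matrix(pts, ncol = 3)
  dims <- dim(vol$labels)
  idx <- matrix(NA_integer_, nrow(pts), 3)
  for (a in 1:3) {
    idx[, a] <- as.integer(floor((pts[, a] - (vol$origin[a] - vol$voxel / 2)) /
                                   vol$voxel)) + 1L
  }
  bad <- idx[, 1] < 1L | idx[, 1] > dims[1] |
    idx[, 2] < 1L | idx[, 2] > dims[2] |
    idx[, 3] < 1L | idx[, 3] > dims[3]
  idx[bad, ] <- NA_integer_
  idx
}

# Label of the voxel owning each point (0 outside array).
voxel_label_of <- function(vol, pts) {
  idx <- voxel_index_of(vol, pts)
  out <- integer(nrow(idx))
  ok <- !is.na(idx[, 1])
  if (any(ok)) {
    out[ok] <- vol$labels[cbind(idx[ok, 1], idx[ok, 2], idx[ok, 3])]
  }
  out
}

# Nearest-neighbour resample of a labeled volume to a new voxel edge length.
resample_volume <- function(vol, voxel) {
  if (isTRUE(all.equal(voxel, vol$voxel))) return(vol)
  dims <- dim(vol$labels)
  lo <- vol$origin - vol$voxel / 2
  hi <- vol$origin + (dims - 0.5) * vol$voxel
  ndim <- pmax(1L, as.integer(ceiling((hi - lo) / voxel)))
  norig <- lo + voxel / 2
  xs <- norig[1] + (seq_len(ndim[1]) - 1) * voxel
  ys <- norig[2] + (seq_len(ndim[2]) - 1) * voxel
  zs <- norig[3] + (seq_len(ndim[3]) - 1) * voxel
  pts <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  lab <- array(voxel_label_of(vol, pts), ndim)
  structure(list(labels = lab, voxel = voxel, origin = norig,
                 regions = vol$regions, include = vol$include),
            class = "labeled_volume")
}

#' Tetrahedralize a labeled volume into a single-compartment conductor
#'
#' Converts the labeled voxel mask into a conforming tetrahedral mesh by Kuhn
#' subdivision: every labeled voxel cube is split into six positively oriented
#' tetrahedra sharing the cube's main diagonal, which conforms across
#' neighbouring voxels and conserves the mask volume exactly at the meshing
#' resolution. If `target_edge` differs from the voxel size the mask is first
#' resampled (nearest neighbour).
#'
#' @param vol a `labeled_volume` with a non-empty mask.
#' @param target_edge edge length of the mesh voxels in mm (default: the
#'   volume's own voxel size).
#' @param sigma homogeneous isotropic conductivity in S/m assigned to every
#'   element (default 0.33 S/m, the standard brain-tissue value).
#' @return a `tet_mesh`: node coordinates (mm), element node indices,
#'   per-element conductivity and region label.
#' @export
tetrahedralize <- function(vol, target_edge = vol$voxel, sigma = 0.33) {
  assert_that(inherits(vol, "labeled_volume"), "vol must be a labeled_volume")
  assert_that(target_edge > 0, "target_edge must be positive")
  assert_that(all(sigma > 0), "conductivity must be positive")
  vol <- resample_volume(vol, target_edge)
  if (!any(vol$labels > 0L)) stopf("empty mask: nothing to mesh")

  dims <- dim(vol$labels)
  vox <- which(vol$labels > 0L, arr.ind = TRUE)
  h <- vol$voxel
  corner0 <- vol$origin - h / 2

  # Corner grid ids: (nx+1) x (ny+1) x (nz+1).
  cn <- dims + 1L
  corner_id <- function(i, j, k) {
    (i - 1) + cn[1] * ((j - 1) + cn[2] * (k - 1)) + 1
  }
  # 8 corners per voxel, code order: 1:(0,0,0) 2:(1,0,0) 3:(0,1,0) 4:(1,1,0)
  #                                  5:(0,0,1) 6:(1,0,1) 7:(0,1,1) 8:(1,1,1)
  offs <- cbind(c(0, 1, 0, 1, 0, 1, 0, 1),
                c(0, 0, 1, 1, 0, 0, 1, 1),
                c(0, 0, 0, 0, 1, 1, 1, 1))
  corners <- matrix(0, nrow(vox), 8)
  for (c8 in 1:8) {
    corners[, c8] <- corner_id(vox[, 1] + offs[c8, 1],
                               vox[, 2] + offs[c8, 2],
                               vox[, 3] + offs[c8, 3])
  }
  used <- sort(unique(as.vector(corners)))
  remap <- integer(0)
  remap[used] <- seq_along(used)

  # Node coordinates from corner grid ids.
  u0 <- used - 1
  ci <- u0 %% cn[1]
  cj <- (u0 %/% cn[1]) %% cn[2]
  ck <- u0 %/% (cn[1] * cn[2])
  nodes <- cbind(x = corner0[1] + ci * h,
                 y = corner0[2] + cj * h,
                 z = corner0[3] + ck * h)

  # Kuhn subdivision: six tets per cube through the main diagonal (1 -> 8).
  kuhn <- rbind(c(1, 2, 4, 8), c(1, 2, 6, 8), c(1, 3, 4, 8),
                c(1, 3, 7, 8), c(1, 5, 6, 8), c(1, 5, 7, 8))
  nt <- nrow(vox) * 6L
  elems <- matrix(0L, nt, 4)
  for (t6 in 1:6) {
    rows <- seq(t6, nt, by = 6L)
    elems[rows, ] <- matrix(remap[corners[, kuhn[t6, ]]], ncol = 4)
  }

  labels <- rep(vol$labels[vox], each = 6L)
  mesh <- structure(
    list(nodes = nodes, elems = elems,
         sigma = rep_len(sigma, nt), label = labels,
         volume_info = list(voxel = h, origin = vol$origin, dims = dims,
                            mask = vol$labels > 0L)),
    class = "tet_mesh")
  mesh <- orient_elements(mesh)
  bad <- element_volumes(mesh) <= 0
  if (any(bad)) stopf("degenerate element(s): %s",
                      paste(head(which(bad), 5), collapse = ", "))
  mesh
}

# Signed volumes of all elements (mm^3).
element_volumes <- function(mesh) {
  p1 <- mesh$nodes[mesh$elems[, 1], , drop = FALSE]
  a <- mesh$nodes[mesh$elems[, 2], , drop = FALSE] - p1
  b <- mesh$nodes[mesh$elems[, 3], , drop = FALSE] - p1
  c3 <- mesh$nodes[mesh$elems[, 4], , drop = FALSE] - p1
  (a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
      a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
      a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
}

# Swap two nodes of negatively oriented elements so all volumes are positive.
orient_elements <- function(mesh) {
  v <- element_volumes(mesh)
  neg <- v < 0
  if (any(neg)) {
    tmp <- mesh$elems[neg, 3]
    mesh$elems[neg, 3] <- mesh$elems[neg, 4]
    mesh$elems[neg, 4] <- tmp
  }
  mesh
}

#' Total mesh volume in mm^3
#' @param mesh a `tet_mesh`
#' @export
mesh_volume <- function(mesh) sum(element_volumes(mesh))

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("<tet_mesh> %d nodes, %d tetrahedra, volume %.1f mm^3, sigma [%g, %g] S/m\n",
              nrow(x$nodes), nrow(x$elems), mesh_volume(x),
              min(x$sigma), max(x$sigma)))
  invisible(x)
}

# Boundary faces: triangles referenced by exactly one element. Encoded with
# sorted node triples folded into a single double key (< 2^53 for meshes up to
# ~2e5 nodes, checked).
boundary_faces <- function(mesh) {
  nn <- nrow(mesh$nodes)
  assert_that(nn^3 < 2^53, "mesh too large for face hashing")
  faces_idx <- rbind(mesh$elems[, c(1, 2, 3)], mesh$elems[, c(1, 2, 4)],
                     mesh$elems[, c(1, 3, 4)], mesh$elems[, c(2, 3, 4)])
  srt <- t(apply(faces_idx, 1, sort))
  key <- (srt[, 1] - 1) + nn * ((srt[, 2] - 1) + nn * (srt[, 3] - 1))
  tab <- table(key)
  single <- as.numeric(names(tab)[tab == 1])
  faces_idx[match(single, key), , drop = FALSE]
}

#' Boundary (surface) node indices of a mesh
#' @param mesh a `tet_mesh`
#' @export
boundary_nodes <- function(mesh) {
  sort(unique(as.vector(boundary_faces(mesh))))
}

# Node-to-node adjacency over element edges, as a list of integer vectors.
node_adjacency <- function(mesh) {
  e <- mesh$elems
  pairs <- rbind(e[, c(1, 2)], e[, c(1, 3)], e[, c(1, 4)],
                 e[, c(2, 3)], e[, c(2, 4)], e[, c(3, 4)])
  pairs <- rbind(pairs, pairs[, 2:1])
  pairs <- unique(pairs)
  split(pairs[, 2], factor(pairs[, 1], levels = seq_len(nrow(mesh$nodes))))
}

#' Test whether points lie inside a mesh
#'
#' Uses the voxel ownership map when the mesh was built from a labeled volume,
#' otherwise a brute-force barycentric point-in-tetrahedron test.
#'
#' @param mesh a `tet_mesh`
#' @param pts n x 3 matrix of mm coordinates
#' @param method `"auto"`, `"voxel"`, or `"barycentric"`
#' @param tol barycentric tolerance
#' @return logical vector of length n
#' @export
points_in_mesh <- function(mesh, pts, method = "auto", tol = 1e-9) {
  pts <- matrix(pts, ncol = 3)
  if (method == "auto") {
    method <- if (!is.null(mesh$volume_info)) "voxel" else "barycentric"
  }
  if (method == "voxel") {
    vi <- mesh$volume_info
    vol <- structure(list(labels = vi$mask * 1L, voxel = vi$voxel,
                          origin = vi$origin), class = "labeled_volume")
    return(voxel_label_of(vol, pts) > 0L)
  }
  p1 <- mesh$nodes[mesh$elems[, 1], , drop = FALSE]
  a <- mesh$nodes[mesh$elems[, 2], , drop = FALSE] - p1
  b <- mesh$nodes[mesh$elems[, 3], , drop = FALSE] - p1
  c3 <- mesh$nodes[mesh$elems[, 4], , drop = FALSE] - p1
  vapply(seq_len(nrow(pts)), function(i) {
    d <- matrix(pts[i, ], nrow(p1), 3, byrow = TRUE) - p1
    # Solve [a b c] l = d per element via Cramer's rule (vectorized).
    det3 <- function(u, v, w) {
      u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
        u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
        u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])
    }
    dt <- det3(a, b, c3)
    l1 <- det3(d, b, c3) / dt
    l2 <- det3(a, d, c3) / dt
    l3 <- det3(a, b, d) / dt
    any(l1 >= -tol & l2 >= -tol & l3 >= -tol & (l1 + l2 + l3) <= 1 + tol,
        na.rm = TRUE)
  }, logical(1))
}

#' The default 12-electrode rat cortical montage
#'
#' Channel positions of the 12-electrode cortical EEG system in stereotactic
#' mm relative to bregma (x = lateral, y = anterior/posterior), plus the
#' reference electrode above the olfactory bulb. Dorsoventral placement is by
#' surface projection, so `z` is `NA` until registered to a head model.
#'
#' @return a tibble with columns `channel`, `x`, `y`, `z`, `reference`.
#' @export
rat_montage_12 <- function() {
  tibble::tibble(
    channel = c("F3", "F4", "C3", "C4", "P3", "P4",
                "P5", "P6", "T3", "T4", "T5", "T6", "Ref"),
    x = c(-2.0, 2.0, -3.2, 3.2, -2.5, 2.5,
          -4.5, 4.5, -7.2, 7.2, -5.8, 5.8, 0.0),
    y = c(5.0, 5.0, 2.2, 2.2, -3.8, -3.8,
          -4.5, -4.5, -3.6, -3.6, -8.3, -8.3, 9.0),
    z = NA_real_,
    reference = c(rep(FALSE, 12), TRUE)
  )
}

#' Register an electrode montage to a mesh surface
#'
#' Each channel is snapped to the boundary mesh node of minimal Euclidean
#' distance. Channels with missing `z` are surface-projected: among boundary
#' nodes closest in (x, y), the most dorsal node is taken.
#'
#' @param mesh a `tet_mesh`
#' @param coords a data frame with columns `channel`, `x`, `y`, `z` and
#'   optionally `reference` (exactly one `TRUE`; default: last row).
#' @param max_snap warn-flag threshold on the snap distance in mm.
#' @return an `electrode_montage` tibble with registered node indices, snapped
#'   coordinates, snap distances and a `flagged` column.
#' @export
register_electrodes <- function(mesh, coords, max_snap = Inf) {
  assert_that(nrow(coords) > 0, "coords must be non-empty")
  if (anyDuplicated(coords$channel)) {
    stopf("duplicate channel labels: %s",
          paste(unique(coords$channel[duplicated(coords$channel)]),
                collapse = ", "))
  }
  if (!"reference" %in% names(coords)) {
    coords$reference <- c(rep(FALSE, nrow(coords) - 1), TRUE)
  }
  assert_that(sum(coords$reference) == 1, "exactly one reference channel required")

  bn <- boundary_nodes(mesh)
  bxyz <- mesh$nodes[bn, , drop = FALSE]
  snap_tol <- if (!is.null(mesh$volume_info)) mesh$volume_info$voxel else
    mean(row_norms(diff(bxyz[1:min(10, nrow(bxyz)), , drop = FALSE])))

  node <- integer(nrow(coords))
  for (i in seq_len(nrow(coords))) {
    if (is.na(coords$z[i])) {
      dxy <- sqrt((bxyz[, 1] - coords$x[i])^2 + (bxyz[, 2] - coords$y[i])^2)
      cand <- which(dxy <= min(dxy) + snap_tol)
      node[i] <- bn[cand[which.max(bxyz[cand, 3])]]
    } else {
      d <- sqrt((bxyz[, 1] - coords$x[i])^2 + (bxyz[, 2] - coords$y[i])^2 +
                  (bxyz[, 3] - coords$z[i])^2)
      node[i] <- bn[which.min(d)]
    }
  }
  sx <- mesh$nodes[node, , drop = FALSE]
  snap <- as.numeric(sqrt((sx[, 1] - coords$x)^2 + (sx[, 2] - coords$y)^2 +
                            ifelse(is.na(coords$z), 0,
                                   (sx[, 3] - coords$z)^2)))
  out <- tibble::tibble(
    channel = coords$channel,
    x = coords$x, y = coords$y, z = coords$z,
    node = node,
    snap_x = as.numeric(sx[, 1]), snap_y = as.numeric(sx[, 2]),
    snap_z = as.numeric(sx[, 3]),
    snap_dist = snap,
    reference = coords$reference,
    flagged = snap > max_snap)
  if (any(out$flagged)) {
    warnf("%d channel(s) snapped farther than %g mm: %s",
          sum(out$flagged), max_snap,
          paste(out$channel[out$flagged], collapse = ", "))
  }
  class(out) <- c("electrode_montage", class(out))
  out
}

#' Build the restricted dipole source grid
#'
#' Dipoles are placed on a regular lattice (integer multiples of `spacing` in
#' stereotactic mm) and kept when the voxel owning the lattice point carries a
#' label in the inclusion list (half-open voxel ownership). Adjacency is the
#' 26-neighbourhood on the lattice.
#'
#' @param vol a `labeled_volume`
#' @param spacing grid edge length in mm (default 1 mm)
#' @param include integer labels forming the electrically active source space
#'   (default: the volume's own inclusion list)
#' @return a `source_grid`: positions (P x 3 mm), labels, spacing, adjacency.
#' @export
build_source_grid <- function(vol, spacing = 1, include = vol$include) {
  assert_that(spacing > 0, "spacing must be positive")
  present <- sort(unique(as.vector(vol$labels[vol$labels > 0L])))
  if (length(include) == 0) stopf("inclusion list is empty")
  assert_that(all(include %in% present),
              "inclusion labels absent from volume: %s",
              paste(setdiff(include, present), collapse = ", "))
  dims <- dim(vol$labels)
  lo <- vol$origin - vol$voxel / 2
  hi <- vol$origin + (dims - 0.5) * vol$voxel
  qr_ <- lapply(1:3, function(a) {
    seq(ceiling(lo[a] / spacing), floor(hi[a] / spacing)) * spacing
  })
  pts <- as.matrix(expand.grid(x = qr_[[1]], y = qr_[[2]], z = qr_[[3]]))
  lab <- voxel_label_of(vol, pts)
  keep <- lab %in% include
  if (!any(keep)) stopf("empty source grid: no lattice point in included labels")
  pos <- pts[keep, , drop = FALSE]
  lab <- lab[keep]
  P <- nrow(pos)

  # Lattice 26-neighbourhood via integer lattice keys.
  qi <- round(sweep(pos, 2, spacing, "/"))
  off <- sapply(1:3, function(a) qi[, a] - min(qi[, a]))
  nd <- apply(off, 2, max) + 1
  key <- off[, 1] + nd[1] * (off[, 2] + nd[2] * off[, 3])
  lookup <- integer(0)
  lookup[key + 1] <- seq_len(P)
  shifts <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  shifts <- shifts[rowSums(abs(shifts)) > 0, , drop = FALSE]
  neigh <- vector("list", P)
  nb_mat <- matrix(NA_integer_, P, nrow(shifts))
  for (s in seq_len(nrow(shifts))) {
    o1 <- off[, 1] + shifts[s, 1]
    o2 <- off[, 2] + shifts[s, 2]
    o3 <- off[, 3] + shifts[s, 3]
    ok <- o1 >= 0 & o1 < nd[1] & o2 >= 0 & o2 < nd[2] & o3 >= 0 & o3 < nd[3]
    k2 <- o1 + nd[1] * (o2 + nd[2] * o3)
    hit <- rep(NA_integer_, P)
    hit[ok] <- lookup[k2[ok] + 1]
    nb_mat[, s] <- hit
  }
  neigh <- lapply(seq_len(P), function(p) {
    v <- nb_mat[p, ]
    as.integer(v[!is.na(v)])
  })

  structure(
    list(pos = pos, spacing = spacing, label = lab,
         neighbors = neigh, nb_mat = nb_mat, P = P),
    class = "source_grid")
}

#' @export
print.source_grid <- function(x, ...) {
  cat(sprintf("<source_grid> P = %d dipoles @ %g mm spacing, labels: %s\n",
              x$P, x$spacing,
              paste(sort(unique(x$label)), collapse = ", ")))
  invisible(x)
}
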