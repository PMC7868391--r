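#' Assemble the FEM stiffness operator of the volume conductor
#'
#' Linear (P1) Lagrange elements on the tetrahedral mesh, homogeneous Neumann
#' (insulating) boundary. The operator is symmetric positive semi-definite
#' with a one-dimensional null space spanned by the constant vector. Node
#' coordinates are mm; lengths are converted to metres internally so that,
#' with conductivity in S/m, solving `A u = b` with loads in amperes yields
#' potentials in volts.
#'
#' @param mesh a `tet_mesh`
#' @return sparse symmetric `dgCMatrix` (n_nodes x n_nodes)
#' @export
assemble_fem_system <- function(mesh) {
  nn <- nrow(mesh$nodes)
  nodes_m <- mesh$nodes * 1e-3   # mm -> m
  e <- mesh$elems
  p1 <- nodes_m[e[, 1], , drop = FALSE]
  a <- nodes_m[e[, 2], , drop = FALSE] - p1
  b <- nodes_m[e[, 3], , drop = FALSE] - p1
  c3 <- nodes_m[e[, 4], , drop = FALSE] - p1
  cross3 <- function(u, v) {
    cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
          u[, 3] * v[, 1] - u[, 1] * v[, 3],
          u[, 1] * v[, 2] - u[, 2] * v[, 1])
  }
  bc <- cross3(b, c3)
  det6 <- rowSums(a * bc)           # 6 * volume (m^3)
  if (any(det6 <= 0)) {
    stopf("degenerate element(s): %s",
          paste(head(which(det6 <= 0), 5), collapse = ", "))
  }
  # Gradients of barycentric coordinates lambda_2..4 are rows of inv([a b c]);
  # columns of [a b c] are the edge vectors, inverse via adjugate.
  g2 <- bc / det6
  g3 <- cross3(c3, a) / det6
  g4 <- cross3(a, b) / det6
  g1 <- -(g2 + g3 + g4)
  vols <- det6 / 6
  w <- mesh$sigma * vols            # S/m * m^3
  G <- list(g1, g2, g3, g4)

  nE <- nrow(e)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  ii <- vector("list", 16); jj <- vector("list", 16); xx <- vector("list", 16)
  k <- 1
  for (r in 1:4) for (s in 1:4) {
    ii[[k]] <- e[, r]
    jj[[k]] <- e[, s]
    xx[[k]] <- w * rowSums(G[[r]] * G[[s]])
    k <- k + 1
  }
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(nn, nn))
  Matrix::forceSymmetric((A + Matrix::t(A)) / 2)
}

#' St. Venant dipole load vector
#'
#' Distributes monopolar current loads over the mesh node nearest the dipole
#' position and its edge-connected neighbours, such that the total load is
#' exactly zero (charge conservation) and the first moment of the loads about
#' the dipole position reproduces the dipole moment. The minimum-norm load
#' satisfying both constraints is used.
#'
#' @param mesh a `tet_mesh`
#' @param position dipole position, mm
#' @param moment dipole moment vector, A*m
#' @param adjacency optional precomputed [node_adjacency()] list
#' @return list with `nodes` (indices) and `loads` (amperes)
#' @export
st_venant_load <- function(mesh, position, moment, adjacency = NULL) {
  assert_that(sum(moment^2) > 0, "dipole moment must be non-zero")
  if (!any(points_in_mesh(mesh, matrix(position, 1)))) {
    stopf("dipole position (%.2f, %.2f, %.2f) lies outside the mesh",
          position[1], position[2], position[3])
  }
  d2 <- (mesh$nodes[, 1] - position[1])^2 + (mesh$nodes[, 2] - position[2])^2 +
    (mesh$nodes[, 3] - position[3])^2
  center <- which.min(d2)
  nb <- if (is.null(adjacency)) {
    touching <- mesh$elems[rowSums(matrix(mesh$elems %in% center,
                                          nrow(mesh$elems))) > 0, , drop = FALSE]
    setdiff(unique(as.vector(touching)), center)
  } else adjacency[[center]]
  nodes <- c(center, nb)
  # Offsets in metres; moments in A*m.
  X <- (mesh$nodes[nodes, , drop = FALSE] -
          matrix(position, length(nodes), 3, byrow = TRUE)) * 1e-3
  q <- as.vector(venant_solve(X, moment))
  list(nodes = nodes, loads = q)
}

# Core St. Venant moment matching: monopole and dipole moments are hard
# (KKT) constraints; second (quadrupole) moments are suppressed by a strong
# quadratic penalty so the load cluster's far field is a clean dipole.
venant_solve <- function(X, moments) {
  moments <- as.matrix(moments)             # 3 x k target dipole moments
  scale <- max(sqrt(rowSums(X^2)))
  Xs <- X / scale
  m <- nrow(Xs)
  M <- rbind(rep(1, m), t(Xs))              # 4 x m hard constraints
  Q <- rbind(Xs[, 1]^2, Xs[, 2]^2, Xs[, 3]^2,
             Xs[, 1] * Xs[, 2], Xs[, 1] * Xs[, 3], Xs[, 2] * Xs[, 3])
  B <- diag(m) + 1e3 * crossprod(Q)
  Bi_Mt <- solve(B, t(M))
  G <- M %*% Bi_Mt
  t_mat <- rbind(0, moments / scale)        # 4 x k
  ridge <- 1e-12 * mean(diag(G))
  Bi_Mt %*% solve(G + ridge * diag(4), t_mat)
}

# Sparse load matrix for all grid dipoles x 3 axes (n_nodes x 3P). The
# St. Venant neighbourhood and KKT solve are shared across the three unit
# moments of each dipole.
venant_load_matrix <- function(mesh, grid) {
  adjacency <- node_adjacency(mesh)
  P <- grid$P
  ii <- vector("list", P); jj <- ii; xx <- ii
  nx <- mesh$nodes[, 1]; ny <- mesh$nodes[, 2]; nz <- mesh$nodes[, 3]
  for (p in seq_len(P)) {
    pos <- grid$pos[p, ]
    d2 <- (nx - pos[1])^2 + (ny - pos[2])^2 + (nz - pos[3])^2
    center <- which.min(d2)
    nodes <- c(center, adjacency[[center]])
    X <- (mesh$nodes[nodes, , drop = FALSE] -
            matrix(pos, length(nodes), 3, byrow = TRUE)) * 1e-3
    Q <- venant_solve(X, diag(3))                    # n_neigh x 3
    ii[[p]] <- rep(nodes, 3)
    jj[[p]] <- rep(3L * (p - 1L) + 1:3, each = length(nodes))
    xx[[p]] <- as.vector(Q)
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(nrow(mesh$nodes), 3L * P))
}

#' Compute the lead field by the transfer-matrix scheme
#'
#' One FEM solve per non-reference electrode: the singular Neumann system is
#' deflated by grounding the reference electrode's node, the sparse Cholesky
#' factor is reused across right-hand sides, and lead-field entries are inner
#' products of transfer vectors with St. Venant load vectors. Entries are
#' volts per unit dipole moment (A*m).
#'
#' @param mesh a `tet_mesh`
#' @param montage a registered `electrode_montage`
#' @param grid a `source_grid`
#' @param average_reference re-reference rows to the channel mean (default
#'   TRUE; the raw rows are potentials relative to the reference electrode)
#' @return a `lead_field` with matrix `K` (N x 3P)
#' @export
compute_lead_field <- function(mesh, montage, grid, average_reference = TRUE) {
  act <- which(!montage$reference)
  ref_node <- montage$node[montage$reference]
  elec_nodes <- montage$node[act]
  N <- length(act)
  A <- assemble_fem_system(mesh)
  nn <- nrow(A)
  keep <- setdiff(seq_len(nn), ref_node)
  Ar <- A[keep, keep]
  fac <- tryCatch(Matrix::Cholesky(Ar, LDL = FALSE),
                  error = function(e) stopf(
                    "FEM system solve failed (disconnected mesh?): %s",
                    conditionMessage(e)))
  # Transfer vectors: A_r t_i = e_i (electrode node unit load, reduced system).
  rhs <- Matrix::sparseMatrix(i = match(elec_nodes, keep), j = seq_len(N),
                              x = 1, dims = c(length(keep), N))
  Tr_red <- as.matrix(Matrix::solve(fac, rhs, system = "A"))
  Tmat <- matrix(0, nn, N)
  Tmat[keep, ] <- Tr_red

  B <- venant_load_matrix(mesh, grid)
  K <- as.matrix(Matrix::t(Matrix::t(B) %*% Tmat))  # N x 3P
  if (average_reference) K <- sweep(K, 2, colMeans(K))
  structure(
    list(K = K, N = N, channels = montage$channel[act],
         montage = montage, grid = grid,
         referencing = if (average_reference) "average" else "raw"),
    class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf("<lead_field> %d channels x %d dipoles (3 orientations), %s reference\n",
              x$N, ncol(x$K) / 3, x$referencing))
  invisible(x)
}

# N x 3 lead-field block of dipole p.
lf_block <- function(K, p) K[, (3 * (p - 1) + 1):(3 * p), drop = FALSE]

#' Direct (per-dipole) FEM solve of electrode potentials
#'
#' Reference implementation used to validate the transfer-matrix scheme:
#' solves the deflated FEM system once per dipole load and reads potentials
#' at the electrode nodes.
#'
#' @inheritParams compute_lead_field
#' @param position,moment dipole position (mm) and moment (A*m)
#' @return channel potentials (volts), raw reference
#' @export
solve_forward_direct <- function(mesh, montage, position, moment) {
  A <- assemble_fem_system(mesh)
  nn <- nrow(A)
  ref_node <- montage$node[montage$reference]
  keep <- setdiff(seq_len(nn), ref_node)
  ld <- st_venant_load(mesh, position, moment)
  b <- numeric(nn)
  b[ld$nodes] <- ld$loads
  u <- numeric(nn)
  u[keep] <- as.vector(Matrix::solve(A[keep, keep], b[keep]))
  u[montage$node[!montage$reference]]
}

#' Layered icosphere tetrahedral mesh of a homogeneous sphere
#'
#' Concentric subdivided-icosahedron shells joined by prisms, each prism split
#' into three conforming tetrahedra; the innermost shell closes onto the
#' centre vertex. Used as the validation fixture against the analytic dipole
#' potential in a conducting sphere.
#'
#' @param radius sphere radius in mm
#' @param subdiv icosahedron subdivision level (surface edge approx.
#'   `1.05 * radius / 2^subdiv`)
#' @param layers number of radial layers
#' @param sigma conductivity S/m
#' @return a `tet_mesh`
#' @export
sphere_mesh <- function(radius = 10, subdiv = 3, layers = 8, sigma = 0.33) {
  surf <- icosphere(subdiv)
  V <- surf$vertices; F3 <- surf$faces
  nv <- nrow(V)
  # Nodes: centre + shells k = 1..layers at radii k/layers * R.
  radii <- radius * seq_len(layers) / layers
  nodes <- rbind(c(0, 0, 0),
                 do.call(rbind, lapply(radii, function(r) V * r)))
  shell_id <- function(k, v) 1L + (k - 1L) * nv + v   # node index of vertex v on shell k

  # Sort triangle vertices ascending so prism diagonals conform globally.
  Fs <- t(apply(F3, 1, sort))
  u <- Fs[, 1]; v <- Fs[, 2]; w <- Fs[, 3]

  elems <- vector("list", layers)
  # Innermost: centre -> shell 1.
  elems[[1]] <- cbind(1L, shell_id(1, u), shell_id(1, v), shell_id(1, w))
  if (layers > 1) {
    for (k in 1:(layers - 1)) {
      bu <- shell_id(k, u); bv <- shell_id(k, v); bw <- shell_id(k, w)
      tu <- shell_id(k + 1, u); tv <- shell_id(k + 1, v); tw <- shell_id(k + 1, w)
      elems[[k + 1]] <- rbind(cbind(bu, bv, bw, tw),
                              cbind(bu, bv, tv, tw),
                              cbind(bu, tu, tv, tw))
    }
  }
  elems <- do.call(rbind, elems)
  mesh <- structure(
    list(nodes = nodes, elems = elems,
         sigma = rep_len(sigma, nrow(elems)),
         label = rep_len(1L, nrow(elems)), volume_info = NULL),
    class = "tet_mesh")
  orient_elements(mesh)
}

# Subdivided icosahedron on the unit sphere.
icosphere <- function(subdiv = 3) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  F3 <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    nv <- nrow(V)
    edge_key <- function(a, b) pmin(a, b) * (nv + 1) + pmax(a, b)
    e1 <- edge_key(F3[, 1], F3[, 2])
    e2 <- edge_key(F3[, 2], F3[, 3])
    e3 <- edge_key(F3[, 3], F3[, 1])
    keys <- unique(c(e1, e2, e3))
    ka <- keys %/% (nv + 1); kb <- keys %% (nv + 1)
    mid <- (V[ka, , drop = FALSE] + V[kb, , drop = FALSE])
    mid <- mid / sqrt(rowSums(mid^2))
    V <- rbind(V, mid)
    midx <- nv + match(c(e1, e2, e3), keys)
    m1 <- midx[seq_len(nrow(F3))]
    m2 <- midx[nrow(F3) + seq_len(nrow(F3))]
    m3 <- midx[2 * nrow(F3) + seq_len(nrow(F3))]
    F3 <- rbind(cbind(F3[, 1], m1, m3),
                cbind(F3[, 2], m2, m1),
                cbind(F3[, 3], m3, m2),
                cbind(m1, m2, m3))
  }
  list(vertices = V, faces = F3)
}

#' Analytic potential of a dipole in a homogeneous conducting sphere
#'
#' Truncated Legendre series for the electric potential generated by a current
#' dipole inside a homogeneous sphere with insulating boundary. The series is
#' summed until a term falls below `tol` of the running sum. Serves as the
#' independent oracle for the FEM forward solution.
#'
#' @param radius sphere radius, mm
#' @param sigma conductivity, S/m
#' @param position dipole position, mm (strictly inside)
#' @param moment dipole moment, A*m
#' @param surface_points n x 3 matrix of evaluation points on the surface (mm)
#' @param tol relative series truncation tolerance
#' @param max_n maximum series degree
#' @return potentials in volts at the surface points
#' @export
analytic_sphere_potential <- function(radius, sigma, position, moment,
                                      surface_points, tol = 1e-10,
                                      max_n = 600) {
  b <- sqrt(sum(position^2))
  if (b >= radius) stopf("dipole must lie strictly inside the sphere")
  pts <- matrix(surface_points, ncol = 3)
  R_m <- radius * 1e-3
  b_m <- b * 1e-3

  # Geometry: radial unit vector of the dipole, tangential moment direction.
  if (b > 1e-12) {
    er <- position / b
  } else {
    er <- c(0, 0, 1)
  }
  m_r <- sum(moment * er)
  mt_vec <- moment - m_r * er
  m_t <- sqrt(sum(mt_vec^2))
  et <- if (m_t > 1e-15 * sqrt(sum(moment^2))) mt_vec / m_t else c(0, 0, 0)

  rp <- pts / sqrt(rowSums(pts^2))
  cosg <- pmin(1, pmax(-1, rp %*% er))           # cos of angle dipole-point
  # Azimuth of the point around the dipole axis, measured from et.
  perp <- rp - as.vector(cosg) * matrix(er, nrow(rp), 3, byrow = TRUE)
  pn <- sqrt(rowSums(perp^2))
  cosb <- ifelse(pn > 1e-14, (perp %*% et) / pn, 0)

  np <- nrow(pts)
  out <- numeric(np)
  # Legendre recurrences: P_n(cosg) and P_n^1(cosg).
  Pnm1 <- rep(1, np); Pn <- as.vector(cosg)
  x <- as.vector(cosg)
  sx <- sqrt(pmax(0, 1 - x^2))
  P1nm1 <- rep(0, np); P1n <- sx                   # P_0^1 = 0, P_1^1 = sin
  ratio <- b_m / R_m
  pw <- 1                                           # (b/R)^(n-1) at n = 1
  run <- 0
  for (n in 1:max_n) {
    coef <- (2 * n + 1) / n * pw / (4 * pi * sigma * R_m^2)
    term <- coef * (n * m_r * Pn + m_t * P1n * cosb)
    out <- out + term
    run <- run + mean(abs(term))
    if (n >= 3 && mean(abs(term)) < tol * max(run, .Machine$double.xmin)) break
    # advance recurrences to degree n + 1
    Pnp1 <- ((2 * n + 1) * x * Pn - n * Pnm1) / (n + 1)
    P1np1 <- ((2 * n + 1) * x * P1n - (n + 1) * P1nm1) / n
    Pnm1 <- Pn; Pn <- Pnp1
    P1nm1 <- P1n; P1n <- P1np1
    pw <- pw * ratio
  }
  as.vector(out)
}
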