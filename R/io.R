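#' Read a multichannel recording
#'
#' Supports EDF (16-bit European Data Format, one data record) and delimited
#' text with a `time` column (`time,F3,F4,...`); the sampling rate is
#' inferred from the time column and must be uniform to within 1e-6 relative.
#' Event markers are read from an optional two-column TSV (`sample`, `code`).
#'
#' @param path recording file
#' @param format `"auto"` (by extension), `"edf"` or `"csv"`
#' @param events_path optional events TSV
#' @return a `sensor_recording`
#' @export
read_recording <- function(path, format = c("auto", "edf", "csv"),
                           events_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (file.size(path) == 0) stopf("empty file: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  rec <- if (format == "edf") read_edf(path) else read_recording_csv(path)
  if (!is.null(events_path)) {
    ev <- utils::read.delim(events_path, header = TRUE)
    rec$events <- tibble::tibble(sample = as.integer(ev[[1]]),
                                 code = as.character(ev[[2]]))
  }
  rec
}

read_recording_csv <- function(path) {
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) stopf("parse error in %s: %s", path,
                                           conditionMessage(e)))
  assert_that(nrow(df) >= 2 && "time" %in% names(df),
              "CSV recording needs a 'time' column and at least 2 rows")
  dt <- diff(df$time)
  if (max(abs(dt - dt[1])) > 1e-6 * abs(dt[1])) {
    stopf("non-uniform time column in %s (max deviation %.3g)",
          path, max(abs(dt - dt[1])))
  }
  fs <- 1 / dt[1]
  chans <- setdiff(names(df), "time")
  sensor_recording(t(as.matrix(df[chans])), fs = fs, channels = chans)
}

#' Write a recording as delimited text
#' @param rec a `sensor_recording`
#' @param path output CSV path
#' @export
write_recording_csv <- function(rec, path) {
  df <- data.frame(time = (seq_len(ncol(rec$data)) - 1) / rec$fs,
                   t(rec$data), check.names = FALSE)
  names(df) <- c("time", rec$channels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write events as a two-column TSV
#' @param events tibble with `sample`, `code`
#' @param path output path
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# --- EDF ---------------------------------------------------------------------

pad_field <- function(x, width) {
  s <- substr(format(x, scientific = FALSE, trim = TRUE), 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write an EDF file
#'
#' Minimal European Data Format writer: one data record holding the whole
#' recording, 16-bit samples scaled per channel to the physical range.
#'
#' @param rec a `sensor_recording`
#' @param path output `.edf` path
#' @export
write_edf <- function(rec, path) {
  N <- nrow(rec$data); n <- ncol(rec$data)
  pmin_ <- apply(rec$data, 1, min)
  pmax_ <- apply(rec$data, 1, max)
  pmax_ <- ifelse(pmax_ > pmin_, pmax_, pmin_ + 1)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field("ratesi", 80), pad_field("synthetic", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (N + 1), 8), pad_field("", 44),
    pad_field("1", 8), pad_field(n / rec$fs, 8), pad_field(N, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, pad_field, character(1), width = width),
                     collapse = ""), con, eos = NULL)
  }
  field(rec$channels, 16)
  field(rep("synthetic", N), 80)
  field(rep(rec$units, N), 8)
  field(sprintf("%.6g", pmin_), 8)
  field(sprintf("%.6g", pmax_), 8)
  field(rep("-32768", N), 8)
  field(rep("32767", N), 8)
  field(rep("", N), 80)
  field(rep(n, N), 8)
  field(rep("", N), 32)
  for (ch in seq_len(N)) {
    dig <- round((rec$data[ch, ] - pmin_[ch]) / (pmax_[ch] - pmin_[ch]) *
                   65535 - 32768)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#' @param path `.edf` file
#' @return a `sensor_recording`
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    out <- readChar(con, w, useBytes = TRUE)
    if (length(out) == 0) stopf("parse error in %s: truncated header", path)
    trimws(out)
  }
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                       # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  N <- as.integer(rd(4))
  if (is.na(N) || N < 1) stopf("parse error in %s: bad channel count", path)
  rdv <- function(w) vapply(seq_len(N), function(i) rd(w), character(1))
  labels <- rdv(16); rdv(80)
  units <- rdv(8)
  pmin_ <- as.numeric(rdv(8)); pmax_ <- as.numeric(rdv(8))
  dmin_ <- as.numeric(rdv(8)); dmax_ <- as.numeric(rdv(8))
  rdv(80)
  nsamp <- as.integer(rdv(8))
  rdv(32)
  data <- matrix(0, N, nsamp[1] * n_rec)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(N)) {
      dig <- readBin(con, integer(), n = nsamp[ch], size = 2,
                     endian = "little")
      phys <- pmin_[ch] + (dig - dmin_[ch]) / (dmax_[ch] - dmin_[ch]) *
        (pmax_[ch] - pmin_[ch])
      data[ch, ((r - 1) * nsamp[ch] + 1):(r * nsamp[ch])] <- phys
    }
  }
  sensor_recording(data, fs = nsamp[1] / dur, channels = labels,
                   units = units[1])
}

# --- Montage -----------------------------------------------------------------

#' Read an electrode montage TSV (label, x_mm, y_mm, z_mm[, reference])
#' @param path TSV file
#' @export
read_montage_tsv <- function(path) {
  df <- utils::read.delim(path)
  names(df)[1:4] <- c("channel", "x", "y", "z")
  if (!"reference" %in% names(df)) {
    df$reference <- c(rep(FALSE, nrow(df) - 1), TRUE)
  } else df$reference <- as.logical(df$reference)
  tibble::as_tibble(df)
}

#' Write an electrode montage TSV
#' @param montage montage tibble
#' @param path output path
#' @export
write_montage_tsv <- function(montage, path) {
  df <- montage[, intersect(c("channel", "x", "y", "z", "reference"),
                            names(montage))]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- Volumes (NIfTI) ---------------------------------------------------------

#' Read a labeled brain volume from NIfTI
#'
#' Optional ingestion path for external (atlas-derived) volumes. Continuous
#' images can be thresholded into a binary mask; integer images are taken as
#' label fields directly. Optional integer down-sampling.
#'
#' @param path `.nii` / `.nii.gz` file
#' @param threshold if non-`NULL`, voxels above it become label 1
#' @param downsample integer factor (voxel decimation)
#' @return a `labeled_volume`
#' @export
read_labeled_volume <- function(path, threshold = NULL, downsample = 1) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  pd <- attr(img, "pixdim") %||% RNifti::pixdim(img)
  voxel <- pd[1]
  assert_that(max(abs(pd[1:3] - voxel)) < 1e-6 * voxel,
              "anisotropic voxels are not supported")
  if (downsample > 1) {
    idx <- lapply(dim(arr), function(d) seq(1, d, by = downsample))
    arr <- arr[idx[[1]], idx[[2]], idx[[3]]]
    voxel <- voxel * downsample
  }
  lab <- if (!is.null(threshold)) (arr > threshold) * 1L else {
    array(as.integer(round(arr)), dim(arr))
  }
  orig <- RNifti::worldToVoxel(c(0, 0, 0), img)   # bregma voxel (1-based)
  origin <- -(orig - 1) * voxel
  labels_present <- sort(unique(as.vector(lab[lab > 0L])))
  structure(list(labels = lab, voxel = voxel, origin = origin,
                 regions = tibble::tibble(label = labels_present,
                                          name = paste0("region", labels_present),
                                          include = TRUE),
                 include = labels_present),
            class = "labeled_volume")
}

#' Write a labeled volume (or values on its grid) to NIfTI
#' @param vol a `labeled_volume`
#' @param path output path
#' @param values optional array matching the volume dims (default: labels)
#' @export
write_labeled_volume <- function(vol, path, values = NULL) {
  arr <- values %||% vol$labels
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(vol$voxel, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Rasterize a source map to NIfTI on the volume grid
#'
#' Nearest-neighbour: each dipole value is painted into the voxel owning its
#' position.
#'
#' @param map a `source_map`
#' @param vol the `labeled_volume` the grid was built from
#' @param path output path
#' @export
write_source_map_nifti <- function(map, vol, path) {
  arr <- array(0, dim(vol$labels))
  idx <- voxel_index_of(vol, map$grid$pos)
  ok <- !is.na(idx[, 1])
  arr[idx[ok, , drop = FALSE]] <- map$values[ok]
  write_labeled_volume(vol, path, values = arr)
}

#' Export a source map as CSV (x, y, z, value)
#' @param map a `source_map`
#' @param path output path
#' @export
write_source_map_csv <- function(map, path) {
  df <- data.frame(x = map$grid$pos[, 1], y = map$grid$pos[, 2],
                   z = map$grid$pos[, 3], value = map$values)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# --- Meshes ------------------------------------------------------------------

#' Write a mesh as Gmsh MSH v2.2 ASCII
#' @param mesh a `tet_mesh`
#' @param path output `.msh` path
#' @export
write_mesh_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(nrow(mesh$nodes))), con)
  writeLines(sprintf("%d %.9g %.9g %.9g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines(c("$EndNodes", "$Elements", as.character(nrow(mesh$elems))), con)
  writeLines(sprintf("%d 4 2 %d %d %d %d %d %d", seq_len(nrow(mesh$elems)),
                     mesh$label, mesh$label,
                     mesh$elems[, 1], mesh$elems[, 2], mesh$elems[, 3],
                     mesh$elems[, 4]), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Read a Gmsh MSH v2.2 ASCII mesh (tetrahedral elements only)
#' @param path `.msh` file
#' @param sigma conductivity assigned to all elements
#' @export
read_mesh_msh <- function(path, sigma = 0.33) {
  lines <- readLines(path)
  ni <- which(lines == "$Nodes")
  ei <- which(lines == "$Elements")
  if (!length(ni) || !length(ei)) stopf("parse error in %s: not MSH v2.2", path)
  nn <- as.integer(lines[ni + 1])
  node_rows <- do.call(rbind, strsplit(lines[(ni + 2):(ni + 1 + nn)], " "))
  nodes <- matrix(as.numeric(node_rows[, 2:4]), ncol = 3)
  ne <- as.integer(lines[ei + 1])
  elem_rows <- strsplit(lines[(ei + 2):(ei + 1 + ne)], " ")
  tets <- Filter(function(r) r[2] == "4", elem_rows)
  assert_that(length(tets) > 0, "no tetrahedra in %s", path)
  em <- do.call(rbind, lapply(tets, function(r) {
    ntags <- as.integer(r[3])
    c(as.integer(r[3 + ntags + 1:4]), as.integer(r[4]))
  }))
  mesh <- structure(list(nodes = nodes, elems = em[, 1:4, drop = FALSE],
                         sigma = rep_len(sigma, nrow(em)),
                         label = em[, 5], volume_info = NULL),
                    class = "tet_mesh")
  orient_elements(mesh)
}

# --- Lead fields (delimited text) --------------------------------------------

#' Write a lead field as delimited text plus a YAML header
#'
#' `<prefix>_K.csv` holds the N x 3P gain matrix, `<prefix>_positions.csv`
#' the dipole grid, `<prefix>_meta.yaml` channels, referencing and units.
#'
#' @param lf a `lead_field`
#' @param prefix output path prefix
#' @export
write_lead_field <- function(lf, prefix) {
  utils::write.table(lf$K, paste0(prefix, "_K.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.csv(data.frame(x = lf$grid$pos[, 1], y = lf$grid$pos[, 2],
                              z = lf$grid$pos[, 3], label = lf$grid$label),
                   paste0(prefix, "_positions.csv"), row.names = FALSE)
  yaml::write_yaml(list(channels = lf$channels,
                        referencing = lf$referencing,
                        units = "V per A*m",
                        spacing = lf$grid$spacing),
                   paste0(prefix, "_meta.yaml"))
  invisible(prefix)
}

#' Read a lead field written by [write_lead_field()]
#' @param prefix path prefix
#' @export
read_lead_field <- function(prefix) {
  K <- as.matrix(utils::read.table(paste0(prefix, "_K.csv"), sep = ","))
  dimnames(K) <- NULL
  posdf <- utils::read.csv(paste0(prefix, "_positions.csv"))
  meta <- yaml::read_yaml(paste0(prefix, "_meta.yaml"))
  grid <- rebuild_grid(as.matrix(posdf[, c("x", "y", "z")]), posdf$label,
                       meta$spacing)
  structure(list(K = K, N = nrow(K), channels = meta$channels,
                 montage = NULL, grid = grid,
                 referencing = meta$referencing),
            class = "lead_field")
}

# Rebuild a source_grid (positions + lattice adjacency) from raw positions.
rebuild_grid <- function(pos, label, spacing) {
  P <- nrow(pos)
  qi <- round(sweep(pos, 2, spacing, "/"))
  off <- sapply(1:3, function(a) qi[, a] - min(qi[, a]))
  nd <- apply(off, 2, max) + 1
  key <- off[, 1] + nd[1] * (off[, 2] + nd[2] * off[, 3])
  lookup <- integer(0)
  lookup[key + 1] <- seq_len(P)
  shifts <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  shifts <- shifts[rowSums(abs(shifts)) > 0, , drop = FALSE]
  nb_mat <- matrix(NA_integer_, P, nrow(shifts))
  for (s in seq_len(nrow(shifts))) {
    o1 <- off[, 1] + shifts[s, 1]; o2 <- off[, 2] + shifts[s, 2]
    o3 <- off[, 3] + shifts[s, 3]
    ok <- o1 >= 0 & o1 < nd[1] & o2 >= 0 & o2 < nd[2] & o3 >= 0 & o3 < nd[3]
    k2 <- o1 + nd[1] * (o2 + nd[2] * o3)
    hit <- rep(NA_integer_, P)
    hit[ok] <- lookup[k2[ok] + 1]
    nb_mat[, s] <- hit
  }
  neigh <- lapply(seq_len(P), function(p) {
    v <- nb_mat[p, ]; as.integer(v[!is.na(v)])
  })
  structure(list(pos = pos, spacing = spacing, label = label,
                 neighbors = neigh, nb_mat = nb_mat, P = P),
            class = "source_grid")
}

# --- Run manifests -----------------------------------------------------------

# FNV-1a hash of a file, hex string (pure R, used for stage checksums).
file_checksum <- function(path) {
  bytes <- as.integer(readBin(path, "raw", file.size(path)))
  h <- 2166136261
  for (chunk in split(bytes, ceiling(seq_along(bytes) / 65536))) {
    for (b in chunk) {
      h <- bitwXor(as.integer(h %% 2^31), b)
      h <- (h * 16777619) %% 2^31
    }
  }
  sprintf("%08x", as.integer(h))
}

#' Write a run manifest
#'
#' Records the configuration snapshot, master seed, package version, stage
#' output checksums and a timestamp, sufficient to re-run a deterministic
#' stage bit-identically.
#'
#' @param path output YAML path
#' @param stage stage name
#' @param config configuration list
#' @param seed master seed
#' @param outputs character vector of produced files (checksummed)
#' @export
write_run_manifest <- function(path, stage, config, seed, outputs = character(0)) {
  outputs <- outputs[file.exists(outputs)]
  yaml::write_yaml(list(
    stage = stage,
    seed = seed,
    package_version = as.character(utils::packageVersion("ratesi")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    checksums = as.list(setNames(vapply(outputs, file_checksum, character(1)),
                                 basename(outputs)))), path)
  invisible(path)
}
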