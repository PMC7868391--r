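#' Build a complete synthetic bench head model
#'
#' One-call construction of labeled volume, tetrahedral mesh, registered
#' 12-electrode montage, source grid and lead field on synthetic ellipsoidal
#' geometry. Two sizes are provided: `"rat"` is the full rat-like geometry
#' (about 2 cm^3, 1-mm source grid); `"small"` is a geometrically similar
#' scaled-down bench model (about 0.4 cm^3, 1.5-mm grid, roughly 120 dipoles)
#' used for fast benchmarking, with the montage coordinates scaled by the
#' same factor.
#'
#' @param size `"small"`, `"medium"` or `"rat"`
#' @param average_reference lead-field referencing
#' @return list: `vol`, `mesh`, `montage`, `grid`, `lf`
#' @export
demo_head_model <- function(size = c("small", "medium", "rat"),
                            average_reference = TRUE) {
  size <- match.arg(size)
  if (size == "rat") {
    vol <- generate_synthetic_brain()
    mesh <- tetrahedralize(vol)
    coords <- rat_montage_12()
    grid <- build_source_grid(vol, spacing = 1)
  } else {
    s <- if (size == "small") 0.55 else 0.75
    vol <- generate_synthetic_brain(semi_axes = c(7.5, 10.5, 6.0) * s,
                                    voxel = 0.6, center = c(0, -1, 0) * s)
    mesh <- tetrahedralize(vol)
    coords <- rat_montage_12()
    coords$x <- coords$x * s
    coords$y <- coords$y * s
    grid <- build_source_grid(vol, spacing = if (size == "small") 1.5 else 1.25)
  }
  montage <- register_electrodes(mesh, coords)
  lf <- compute_lead_field(mesh, montage, grid,
                           average_reference = average_reference)
  list(vol = vol, mesh = mesh, montage = montage, grid = grid, lf = lf)
}
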