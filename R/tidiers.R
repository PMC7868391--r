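#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_line geom_point
#'   geom_errorbar facet_wrap scale_fill_viridis_c labs theme_minimal
#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a source map into a tibble
#' @param x a `source_map`
#' @param ... unused
#' @return tibble: dipole, x, y, z, label, value
#' @method tidy source_map
#' @export
tidy.source_map <- function(x, ...) {
  tibble::tibble(dipole = seq_len(x$grid$P),
                 x = x$grid$pos[, 1], y = x$grid$pos[, 2],
                 z = x$grid$pos[, 3], label = x$grid$label,
                 value = x$values)
}

#' Tidy a surrogate evaluation into the summary table
#' @param x an `eval_maps`
#' @param ... unused
#' @method tidy eval_maps
#' @export
tidy.eval_maps <- function(x, ...) x$summary

#' One-row summary of a surrogate evaluation
#' @param x an `eval_maps`
#' @param ... unused
#' @method glance eval_maps
#' @export
glance.eval_maps <- function(x, ...) {
  best <- dplyr::slice_min(
    dplyr::filter(x$summary, .data$metric == "ed1",
                  .data$snr_db == max(.data$snr_db)),
    .data$mean, n = 1, with_ties = FALSE)
  tibble::tibble(n_dipoles = length(x$dipoles),
                 n_snr = length(x$config$snr_db),
                 n_samples = x$config$n_samples,
                 best_solver = best$solver,
                 best_ed1 = best$mean)
}

#' Tidy a cluster permutation result into the cluster table
#' @param x a `cluster_result`
#' @param ... unused
#' @method tidy cluster_result
#' @export
tidy.cluster_result <- function(x, ...) x$table

#' One-row summary of a cluster permutation test
#' @param x a `cluster_result`
#' @param ... unused
#' @method glance cluster_result
#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(n_clusters = length(x$clusters),
                 n_significant = sum(x$table$significant %||% logical(0)),
                 n_perm = x$n_perm, threshold_p = x$threshold_p,
                 t_star = x$t_star, df = x$df, alpha = x$alpha)
}

#' Axial-slice heat map of a source map
#' @param object a `source_map`
#' @param ... unused
#' @method autoplot source_map
#' @export
autoplot.source_map <- function(object, ...) {
  df <- tidy.source_map(object)
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$value)) +
    geom_tile(width = object$grid$spacing, height = object$grid$spacing) +
    facet_wrap(~z, labeller = "label_both") +
    scale_fill_viridis_c() +
    labs(title = sprintf("%s source map", object$solver),
         x = "lateral (mm)", y = "anterior (mm)") +
    theme_minimal()
}

#' Error-distance versus SNR curves of a surrogate evaluation
#' @param object an `eval_maps`
#' @param metric `"ed1"` or `"ed2"`
#' @param ... unused
#' @method autoplot eval_maps
#' @export
autoplot.eval_maps <- function(object, metric = "ed1", ...) {
  df <- dplyr::filter(object$summary, .data$metric == !!metric)
  ggplot(df, aes(x = .data$snr_db, y = .data$mean, colour = .data$solver)) +
    geom_line() + geom_point() +
    geom_errorbar(aes(ymin = pmax(0, .data$mean - .data$sd),
                      ymax = .data$mean + .data$sd), width = 0.6) +
    labs(x = "SNR (dB)", y = toupper(metric),
         title = sprintf("%s across SNR levels", toupper(metric))) +
    theme_minimal()
}

#' Axial-slice t map with significant-cluster mask
#' @param object a `cluster_result`
#' @param ... unused
#' @method autoplot cluster_result
#' @export
autoplot.cluster_result <- function(object, ...) {
  df <- tibble::tibble(x = object$grid$pos[, 1], y = object$grid$pos[, 2],
                       z = object$grid$pos[, 3], t = object$t,
                       significant = object$mask)
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$t)) +
    geom_tile(width = object$grid$spacing, height = object$grid$spacing) +
    geom_point(data = dplyr::filter(df, .data$significant),
               aes(x = .data$x, y = .data$y), inherit.aes = FALSE,
               shape = 4, size = 0.8) +
    facet_wrap(~z, labeller = "label_both") +
    scale_fill_viridis_c() +
    labs(x = "lateral (mm)", y = "anterior (mm)",
         title = "Cluster permutation t map (x = significant)") +
    theme_minimal()
}

#' Subject-count spatial-correlation curve plot
#' @param curve tibble from [subject_correlation_curve()]
#' @export
plot_correlation_curve <- function(curve) {
  ggplot(curve, aes(x = .data$n, y = .data$mean_cor)) +
    geom_line() + geom_point() +
    geom_errorbar(aes(ymin = .data$mean_cor - .data$sd_cor,
                      ymax = pmin(1, .data$mean_cor + .data$sd_cor)),
                  width = 0.3) +
    labs(x = "subjects in subsample", y = "spatial correlation",
         title = "Grand-average stability vs number of subjects") +
    theme_minimal()
}
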