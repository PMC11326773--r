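#' Tidy per-component summary of a fitted model
#'
#' @param x An `oca_model` (from [oca_fit()]).
#' @param ... Unused.
#' @return A tibble with one row per oscillation component: center
#'   frequency, damping, process-noise variance, band label and the maximum
#'   sensor-map magnitude.
#' @export
tidy.oca_model <- function(x, ...) {
  maps <- mixing_maps(x)
  max_mag <- vapply(seq_len(x$fit$M), function(m)
    max(maps$magnitude[maps$component == m]), numeric(1))
  tibble::tibble(component = seq_len(x$fit$M),
                 frequency = x$bank$f, damping = x$bank$a,
                 sigma2 = x$bank$sigma2,
                 band = band_group(x),
                 max_map_magnitude = max_mag)
}

#' One-row model summary
#'
#' @param x An `oca_model` (from [oca_fit()]).
#' @param ... Unused.
#' @return A tibble with the selected component count, final ELBO,
#'   convergence flag, mixing-prior precision and data dimensions.
#' @export
glance.oca_model <- function(x, ...) {
  tibble::tibble(n_components = x$fit$M,
                 free_energy = x$fit$free_energy,
                 converged = x$fit$converged,
                 alpha = x$fit$alpha,
                 n_channels = length(x$channel_names),
                 retained_pcs = length(x$pca$retained),
                 fs = x$fs)
}

#' @export
tidy.model_grid <- function(x, ...) {
  tibble::tibble(M = x$candidate_Ms, free_energy = x$free_energies, q = x$q,
                 selected = x$candidate_Ms == x$selected_M)
}

need_ggplot2 <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
}

#' Plot the model-selection free-energy profile
#'
#' @param grid A `"model_grid"` (or an `oca_model` (from [oca_fit()]), whose grid is used).
#' @return A ggplot object: negative variational free energy and posterior
#'   model probability against the candidate component count.
#' @export
plot_model_selection <- function(grid) {
  need_ggplot2()
  if (inherits(grid, "oca_model")) grid <- grid$grid
  df <- tidy.model_grid(grid)
  ggplot2::ggplot(df, ggplot2::aes(x = M, y = q)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = selected), size = 2) +
    ggplot2::labs(x = "number of oscillations",
                  y = "model-structure posterior q(M)",
                  shape = "selected") +
    ggplot2::theme_minimal()
}

#' Plot the free-energy trace of the fitting run
#'
#' @param fit An `"oca_single_fit"` or `oca_model` (from [oca_fit()]).
#' @return A ggplot object of the ELBO over updates.
#' @export
plot_free_energy <- function(fit) {
  need_ggplot2()
  if (inherits(fit, "oca_model")) fit <- fit$fit
  df <- fit$trace
  df$step <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = step, y = free_energy,
                                   colour = phase)) +
    ggplot2::geom_line(ggplot2::aes(group = 1)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "update", y = "negative variational free energy") +
    ggplot2::theme_minimal()
}

#' Plot extracted component time courses
#'
#' @param tc A `"component_timecourses"` from [get_sources()].
#' @param components Which components to show (default all).
#' @param epoch Epoch index (default 1).
#' @return A ggplot object: real and imaginary traces per component.
#' @export
plot_sources <- function(tc, components = seq_len(tc$M), epoch = 1L) {
  need_ggplot2()
  X <- tc$states[[epoch]]
  tt <- seq_len(nrow(X)) / tc$fs
  df <- do.call(rbind, lapply(components, function(m)
    tibble::tibble(time = rep(tt, 2L),
                   value = c(X[, 2L * m - 1L], X[, 2L * m]),
                   part = rep(c("real", "imaginary"), each = length(tt)),
                   component = factor(m))))
  ggplot2::ggplot(df, ggplot2::aes(x = time, y = value,
                                   colour = part)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~component, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "amplitude") +
    ggplot2::theme_minimal()
}
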