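#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

as_raster_df <- function(mat, value = "intensity") {
  tibble::tibble(
    row = rep(seq_len(nrow(mat)), times = ncol(mat)),
    col = rep(seq_len(ncol(mat)), each = nrow(mat)),
    !!value := as.vector(mat)
  )
}

#' @export
autoplot.gray_image <- function(object, ...) {
  df <- as_raster_df(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "I") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.edge_map <- function(object, ...) {
  df <- as_raster_df(object$edges, "edge")
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = factor(.data$edge))) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(`0` = "white", `1` = "black"),
                               guide = "none") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste0(object$operator,
                                 if (!is.na(object$scale_index)) {
                                   paste0(" (j=", object$scale_index, ")")
                                 }),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.claw_fit <- function(object, n_grid = 200, ...) {
  grid <- tibble::tibble(
    x_um = seq(min(object$data$x_um), max(object$data$x_um),
               length.out = n_grid)
  )
  grid$y_um <- eval_family(object$family, object$coefficients, grid$x_um)$y
  ggplot2::ggplot(object$data, ggplot2::aes(.data$x_um, .data$y_um)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(
      x = "x (µm)", y = "y (µm)",
      title = sprintf("%s fit, R² = %.4f", object$family,
                      object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.curvature_profile <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("x", "d2y", "curvature")],
    c("d2y", "curvature"),
    names_to = "quantity", values_to = "value"
  )
  labels <- c(d2y = "y'' (µm⁻¹)",
              curvature = "K (µm⁻¹)")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1,
                        labeller = ggplot2::as_labeller(labels)) +
    ggplot2::labs(x = "x (µm)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.adhesion_sweep <- function(object, ...) {
  rel <- attr(object, "relationship")
  df <- dplyr::filter(tibble::as_tibble(object), !.data$singular)
  switch(rel,
    theta_vs_alpha_mu =
      ggplot2::ggplot(df, ggplot2::aes(.data$alpha_deg, .data$theta_deg,
                                       colour = factor(.data$mu))) +
        ggplot2::geom_line() +
        ggplot2::geom_hline(yintercept = 0, linetype = 3) +
        ggplot2::labs(x = "pressure angle α (°)",
                      y = "load angle θ (°)", colour = "μ") +
        ggplot2::theme_minimal(),
    alpha_vs_R_over_r =
      ggplot2::ggplot(df, ggplot2::aes(.data$R_over_r, .data$alpha_deg,
                                       colour = factor(.data$h_over_R))) +
        ggplot2::geom_line() +
        ggplot2::labs(x = "R / r", y = "α (°)",
                      colour = "h / R") +
        ggplot2::theme_minimal(),
    alpha_vs_d_R_r =
      ggplot2::ggplot(df, ggplot2::aes(.data$d_over_R, .data$alpha_deg,
                                       colour = factor(.data$R_over_r))) +
        ggplot2::geom_line() +
        ggplot2::labs(x = "d / R", y = "α (°)",
                      colour = "R / r") +
        ggplot2::theme_minimal(),
    forces_vs_theta = {
      long <- tidyr::pivot_longer(df, c("N1", "N2", "Fp", "Fv"),
                                  names_to = "force", values_to = "value")
      ggplot2::ggplot(long, ggplot2::aes(.data$theta_deg, .data$value,
                                         colour = .data$force)) +
        ggplot2::geom_line() +
        ggplot2::geom_hline(yintercept = 0, linetype = 3) +
        ggplot2::labs(x = "load angle θ (°)", y = "force (N)",
                      colour = NULL) +
        ggplot2::theme_minimal()
    }
  )
}

#' Plot an indentation load-displacement record
#'
#' @param curve tibble with `displacement_nm`, `load_mN` and optionally
#'   `segment`.
#' @return a ggplot object.
#' @export
plot_indentation_curve <- function(curve) {
  aes <- if ("segment" %in% names(curve)) {
    ggplot2::aes(.data$displacement_nm, .data$load_mN,
                 colour = .data$segment)
  } else {
    ggplot2::aes(.data$displacement_nm, .data$load_mN)
  }
  ggplot2::ggplot(curve, aes) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "displacement (nm)", y = "load (mN)") +
    ggplot2::theme_minimal()
}
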