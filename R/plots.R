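#' Scatter plot of voxel-wise BMD against PI
#'
#' The per-specimen diagnostic plot: sampled voxel pairs with the fitted
#' regression line.
#'
#' @param scatter Tibble with columns `bmd` and `pi` (e.g. from
#'   [run_specimen()]).
#' @param regression Optional [regress_specimen()] result drawn as a line.
#' @param alpha Point transparency.
#' @return A ggplot object.
#' @export
plot_bmd_pi <- function(scatter, regression = NULL, alpha = 0.15) {
  p <- ggplot2::ggplot(scatter, ggplot2::aes(x = .data$bmd, y = .data$pi)) +
    ggplot2::geom_point(alpha = alpha, size = 0.4) +
    ggplot2::labs(x = "BMD (mg HA/cm³)", y = "Porosity index (%)") +
    ggplot2::theme_minimal()
  if (!is.null(regression)) {
    p <- p + ggplot2::geom_abline(slope = regression$slope,
                                  intercept = regression$intercept,
                                  colour = "red") +
      ggplot2::ggtitle(sprintf("slope = %.4g, r = %.2f", regression$slope,
                               regression$r))
  }
  p
}

#' @export
autoplot.pi_regression <- function(object, ...) {
  stop("plot the scatter sample with plot_bmd_pi(); a pi_regression stores ",
       "only the fitted summaries", call. = FALSE)
}

#' Per-limb correlation overview of a study
#'
#' Dot plot of per-specimen r by limb class with group means.
#'
#' @param object A `pi_study`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pi_study <- function(object, ...) {
  tbl <- object$table[!object$table$excluded & is.finite(object$table$r), ]
  tbl$limb <- factor(tbl$limb, levels = c("LF", "RF", "LH", "RH"))
  means <- dplyr::summarise(dplyr::group_by(tbl, .data$limb),
                            r = mean(.data$r), .groups = "drop")
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$limb, y = .data$r)) +
    ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.08, seed = 1),
                        alpha = 0.7) +
    ggplot2::geom_point(data = means, shape = 95, size = 10, colour = "red") +
    ggplot2::labs(x = NULL, y = "Pearson r (BMD vs PI)") +
    ggplot2::theme_minimal()
}

#' Plot one slice of a volume
#'
#' Axial (k) slice as a raster, in world mm coordinates.
#'
#' @param grid A [voxel_grid()].
#' @param k 1-based slice index (default: middle slice).
#' @return A ggplot object.
#' @export
plot_slice <- function(grid, k = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  d <- dim(grid)
  if (is.null(k)) k <- ceiling(d[3] / 2)
  sl <- grid$values[, , k]
  df <- tidyr::expand_grid(
    j = seq_len(d[2]), i = seq_len(d[1])
  )
  df$x <- grid$origin[1] + (df$i - 1) * grid$spacing[1]
  df$y <- grid$origin[2] + (df$j - 1) * grid$spacing[2]
  df$value <- as.numeric(sl[cbind(df$i, df$j)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = NULL) +
    ggplot2::theme_minimal()
}
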