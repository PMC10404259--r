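# Thin optional plotting layer. All analysis results are available as
# plain tables; these helpers only draw them.

#' Plot AMMI1 biplot coordinates
#'
#' Marginal means against IPCA1 scores with the grand-mean and zero-score
#' reference lines.
#'
#' @param fit An [fit_ammi()] result.
#' @param data The matching [met_dataset].
#' @return A ggplot object.
#' @export
plot_ammi1 <- function(fit, data) {
  coords <- ammi1_coords(fit, data)
  ggplot2::ggplot(coords, ggplot2::aes(x = .data$mean, y = .data$ipca1,
                                       colour = .data$type)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_vline(xintercept = attr(coords, "grand_mean"),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_text(ggplot2::aes(label = .data$name), size = 3) +
    ggplot2::labs(x = paste("Mean", fit$trait), y = "IPCA1 score",
                  title = "AMMI1 biplot") +
    ggplot2::theme_minimal()
}

#' Plot a GGE biplot
#'
#' Genotype and environment coordinates; optionally the genotype convex
#' hull and sector boundary rays (`type = "www"`) or the AEC axis
#' (`type = "aec"`).
#'
#' @param fit A [gge_fit()].
#' @param type `"points"`, `"www"` or `"aec"`.
#' @return A ggplot object.
#' @export
plot_gge <- function(fit, type = c("points", "www", "aec")) {
  type <- match.arg(type)
  gc <- fit$genotype_coords
  ec <- fit$environment_coords
  pts <- rbind(
    tibble::tibble(kind = "genotype", name = rownames(gc),
                   x = gc[, 1], y = gc[, 2]),
    tibble::tibble(kind = "environment", name = rownames(ec),
                   x = ec[, 1], y = ec[, 2])
  )
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y,
                                         colour = .data$kind)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = .data$name), size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Axis 1", y = "Axis 2",
                  title = sprintf("GGE biplot (%.2f%% of G+GE)", fit$pct_explained)) +
    ggplot2::theme_minimal()
  if (type == "www") {
    www <- which_won_where(fit)
    hull <- gc[www$hull_vertices, , drop = FALSE]
    hull_df <- tibble::tibble(x = hull[, 1], y = hull[, 2])
    hull_df <- rbind(hull_df, hull_df[1, ])
    rng <- max(abs(c(gc, ec)))
    rays <- www$sector_boundaries
    ray_df <- tibble::tibble(x = 0, y = 0,
                             xend = 1.2 * rng * cos(rays$angle),
                             yend = 1.2 * rng * sin(rays$angle))
    p <- p +
      ggplot2::geom_path(data = hull_df,
                         ggplot2::aes(x = .data$x, y = .data$y),
                         inherit.aes = FALSE, colour = "grey40") +
      ggplot2::geom_segment(data = ray_df,
                            ggplot2::aes(x = .data$x, y = .data$y,
                                         xend = .data$xend, yend = .data$yend),
                            inherit.aes = FALSE, linetype = "dotted",
                            colour = "grey40")
  }
  if (type == "aec") {
    u <- aec_axis(fit)
    rng <- max(abs(c(gc, ec)))
    p <- p + ggplot2::geom_segment(
      data = tibble::tibble(x = -1.2 * rng * u[1], y = -1.2 * rng * u[2],
                            xend = 1.2 * rng * u[1], yend = 1.2 * rng * u[2]),
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      inherit.aes = FALSE, colour = "grey40",
      arrow = ggplot2::arrow(length = ggplot2::unit(0.2, "cm")))
  }
  p
}
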