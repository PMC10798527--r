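#' Plot pre-balance diagnostics
#'
#' Biomass density (log10) against trophic level with the fitted decline,
#' the standard visual check that a parameterization spans a plausible
#' biomass range and thins out up the food web. Detritus groups are drawn
#' but excluded from the fit.
#'
#' @param object A `prebal_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot prebal_report
#' @export
autoplot.prebal_report <- function(object, ...) {
  df <- object$table
  df$in_fit <- df$id %in% object$slope_subset
  ggplot2::ggplot(df[df$biomass > 0, ],
                  ggplot2::aes(x = .data$tl, y = log10(.data$biomass))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$category,
                                     shape = .data$in_fit)) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         linetype = 2) +
    ggplot2::labs(x = "Trophic level", y = "log10 biomass density (mt km⁻²)",
                  colour = NULL, shape = "in regression",
                  title = sprintf("Biomass span %d orders; slope %.3f per TL",
                                  object$span_orders, object$slope)) +
    ggplot2::theme_minimal()
}

#' Plot simulated group trajectories
#'
#' Annual mean mass of every living group relative to its starting value,
#' the standard equilibrium/stability visual.
#'
#' @param object A `shelfweb_sim`.
#' @param relative Plot mass relative to year 1 (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot shelfweb_sim
#' @export
autoplot.shelfweb_sim <- function(object, relative = TRUE, ...) {
  df <- tidy(object)
  df <- df[df$group %in% object$living, ]
  if (relative) {
    df <- df |>
      dplyr::group_by(.data$group) |>
      dplyr::mutate(mass_mmol = .data$mass_mmol / .data$mass_mmol[1]) |>
      dplyr::ungroup()
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$mass_mmol,
                                   group = .data$group)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "Year",
                  y = if (relative) "Mass relative to start" else "Mass (mmol N)") +
    ggplot2::theme_minimal()
}

#' Plot a trophic network as a flow heatmap
#'
#' Production-fate fractions from each living group (columns) to consumers
#' and pools (rows).
#'
#' @param object A `trophic_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot trophic_network
#' @export
autoplot.trophic_network <- function(object, ...) {
  df <- tidy(object)
  df$from_id <- factor(df$from_id, levels = unique(colnames(object$A)))
  df$to_id <- factor(df$to_id, levels = rev(rownames(object$A)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$from_id, y = .data$to_id,
                                   fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Producing group", y = "Receiving group / pool",
                  fill = "fraction of\nproduction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Plot tuning surfaces
#'
#' f-ratio or extinction-count surfaces over two of the three recycling
#' parameters, faceted by the third.
#'
#' @param object A `tuning_result`.
#' @param metric Column to plot (default `"total_pp"`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tuning_result
#' @export
autoplot.tuning_result <- function(object, metric = "total_pp", ...) {
  df <- object$grid[!is.na(object$grid[[metric]]), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pelagic_remin,
                                   y = .data$benthic_remin,
                                   fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~sequestration, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::theme_minimal()
}
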