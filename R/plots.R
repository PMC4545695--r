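## ggplot2 visualisations of flux ranges and reduction trajectories.

#' Plot per-scenario flux ranges
#'
#' Horizontal range bars of the feasible flux interval of each reaction,
#' one facet per scenario; capped (unbounded, clipped) ends are marked.
#'
#' @param table tibble from [fva()] or [flux_range_table()].
#' @return a ggplot object.
#' @export
plot_flux_ranges <- function(table) {
  if (!"scenario" %in% names(table)) table$scenario <- "base"
  tab <- dplyr::filter(table, !is.na(.data$lo))
  tab$capped <- tab$capped_lo | tab$capped_hi
  ggplot2::ggplot(tab, ggplot2::aes(y = .data$reaction)) +
    ggplot2::geom_linerange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi,
                                         colour = .data$capped),
                            linewidth = 2) +
    ggplot2::geom_point(ggplot2::aes(x = .data$lo), shape = "|", size = 3) +
    ggplot2::geom_point(ggplot2::aes(x = .data$hi), shape = "|", size = 3) +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "feasible flux range", y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn prune autoplot method: reduction trajectory (network size
#'   against removal-log events, coloured by action).
#' @param object a `prune_result`.
#' @param ... unused.
#' @export
autoplot.prune_result <- function(object, ...) {
  log <- object$log
  n0 <- object$stats$n_reactions[object$stats$stage == "full"]
  log$event <- seq_len(nrow(log))
  log$n_remaining <- n0 - cumsum(log$action %in% c("removed", "blocked"))
  ggplot2::ggplot(log, ggplot2::aes(x = .data$event, y = .data$n_remaining)) +
    ggplot2::geom_step(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$action), size = 2) +
    ggplot2::labs(x = "removal-log event", y = "reactions remaining",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn compress autoplot method: enzyme-subset sizes in the
#'   compressed model.
#' @param object a `compressed_model`.
#' @param ... unused.
#' @export
autoplot.compressed_model <- function(object, ...) {
  sizes <- object$subsets |>
    dplyr::count(.data$lumped_id, name = "members") |>
    dplyr::arrange(dplyr::desc(.data$members))
  sizes$lumped_id <- factor(sizes$lumped_id, levels = sizes$lumped_id)
  ggplot2::ggplot(sizes, ggplot2::aes(x = .data$members, y = .data$lumped_id)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "member reactions", y = NULL) +
    ggplot2::theme_minimal()
}
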