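#' Tidy a persistence diagram
#'
#' @param x A `persistence_diagram`.
#' @param ... Unused.
#' @return A plain tibble with the scalar columns plus birth simplex node
#'   labels collapsed to a string.
#' @method tidy persistence_diagram
#' @export
tidy.persistence_diagram <- function(x, ...) {
  ids <- attr(x, "node_ids")
  out <- as_tibble(x)
  out$birth_simplex <- vapply(
    out$birth_simplex, function(s) paste(ids[s], collapse = "-"), character(1)
  )
  out$death_simplex <- NULL
  out
}

#' @rdname tidy.persistence_diagram
#' @method glance persistence_diagram
#' @export
glance.persistence_diagram <- function(x, ...) {
  as_tibble(x) |>
    group_by(.data$dimension) |>
    summarise(
      n_classes = dplyr::n(),
      n_infinite = sum(is.infinite(.data$rho_death)),
      max_lifetime = suppressWarnings(
        max(.data$lifetime[is.finite(.data$lifetime)], -Inf)
      ),
      max_pi = suppressWarnings(max(.data$pi[is.finite(.data$pi)], -Inf)),
      .groups = "drop"
    )
}

#' Persistence diagram plot
#'
#' Birth density against death density, one panel-free scatter with the
#' diagonal; infinite deaths are drawn at the top margin with open symbols.
#'
#' @param object A `persistence_diagram`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot persistence_diagram
#' @export
autoplot.persistence_diagram <- function(object, ...) {
  df <- as_tibble(object)
  finite_max <- max(c(df$rho_death[is.finite(df$rho_death)], df$rho_birth, 1))
  df$death_plot <- ifelse(is.finite(df$rho_death), df$rho_death,
                          finite_max * 1.05)
  df$infinite <- !is.finite(df$rho_death)
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$rho_birth, y = .data$death_plot,
      colour = factor(.data$dimension), shape = .data$infinite
    )
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                guide = "none") +
    ggplot2::labs(
      x = expression(rho["birth"]), y = expression(rho["death"]),
      colour = "dimension"
    ) +
    ggplot2::theme_minimal()
}

#' Betti curve plot
#'
#' @param curves Tibble from [betti_curves()].
#' @return A ggplot of each Betti number against edge density.
#' @export
plot_betti_curves <- function(curves) {
  long <- tidyr::pivot_longer(
    curves, dplyr::starts_with("beta_"),
    names_to = "dimension", values_to = "betti",
    names_prefix = "beta_"
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$rho, y = .data$betti, colour = .data$dimension)
  ) +
    ggplot2::geom_step() +
    ggplot2::labs(x = expression(rho), y = expression(beta[k])) +
    ggplot2::theme_minimal()
}

#' Participation heat table plot
#'
#' Node participation in maximal k-cliques as a tile map, optionally sorted
#' by a system label.
#'
#' @param table Participation table from [node_participation()].
#' @param labels Optional node system labels (vector over node index).
#' @return A ggplot.
#' @export
plot_participation <- function(table, labels = NULL) {
  df <- table
  if (!is.null(labels)) {
    df <- mutate(df, system = labels[.data$node]) |>
      arrange(.data$system, .data$node)
  }
  df$node_id <- factor(df$node_id, levels = unique(df$node_id))
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = factor(.data$k), y = .data$node_id, fill = .data$count)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "maximal clique degree k", y = NULL,
                  fill = expression(P[k](v))) +
    ggplot2::theme_minimal()
}

#' @rdname tidy.persistence_diagram
#' @method glance rich_club
#' @export
glance.rich_club <- function(x, ...) {
  tibble(
    n_levels = nrow(x),
    n_defined = sum(!is.na(x$phi)),
    n_significant = sum(x$significant, na.rm = TRUE),
    n_null = attr(x, "n_null")
  )
}

#' Rich-club curve plot
#'
#' @param object A `rich_club` result.
#' @param ... Unused.
#' @return A ggplot of the observed and null rich-club coefficients.
#' @method autoplot rich_club
#' @export
autoplot.rich_club <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$null_mean - .data$null_sd,
        ymax = .data$null_mean + .data$null_sd
      ),
      fill = "grey80"
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$null_mean), colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$phi), colour = "steelblue") +
    ggplot2::geom_point(
      data = df[which(df$significant), ],
      ggplot2::aes(y = .data$phi), colour = "orange", size = 2
    ) +
    ggplot2::labs(x = "k", y = expression(phi^w * (k))) +
    ggplot2::theme_minimal()
}
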