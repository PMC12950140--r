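#' Tidy a backbone into a tibble
#'
#' @param x A `backbone`.
#' @param ... Unused.
#' @return Tibble: x_um, y_um, z_um, radius_um, arc_um.
#' @export
tidy.backbone <- function(x, ...) {
  tibble::tibble(
    x_um = x$points_um[, 1], y_um = x$points_um[, 2], z_um = x$points_um[, 3],
    radius_um = x$radius_um, arc_um = x$cum_arclength_um
  )
}

#' Tidy spine tracks
#' @param x A `spine_tracks` object.
#' @param ... Unused.
#' @return The underlying tibble (track_id, session, present, mark_row, arc_um).
#' @export
tidy.spine_tracks <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("track_id", "session", "present", "mark_row", "arc_um")])
}

#' One-row summary of spine tracks
#' @param x A `spine_tracks` object.
#' @param ... Unused.
#' @return Tibble: n_tracks, n_sessions, n_always_present.
#' @export
glance.spine_tracks <- function(x, ...) {
  p <- track_presence(x)
  tibble::tibble(
    n_tracks = nrow(p),
    n_sessions = ncol(p),
    n_always_present = sum(rowSums(p) == ncol(p))
  )
}

#' Tidy a dynamics summary
#' @param x A `spine_dynamics` object.
#' @param ... Unused.
#' @return Long tibble: session, metric, value.
#' @export
tidy.spine_dynamics <- function(x, ...) {
  dens <- tidyr::pivot_longer(x$density, -"session",
                              names_to = "metric", values_to = "value")
  rat <- tidyr::pivot_longer(
    x$ratios[, c("session", "addition_ratio", "elimination_ratio", "turnover_ratio")],
    -"session", names_to = "metric", values_to = "value"
  )
  dplyr::bind_rows(dens, rat)
}

#' One-row summary of a dynamics summary
#' @param x A `spine_dynamics` object.
#' @param ... Unused.
#' @return Tibble with backbone length, mode, mean ratios.
#' @export
glance.spine_dynamics <- function(x, ...) {
  tibble::tibble(
    backbone_length_um = x$backbone_length_um,
    mode = x$mode,
    mean_addition_ratio = mean(x$ratios$addition_ratio, na.rm = TRUE),
    mean_elimination_ratio = mean(x$ratios$elimination_ratio, na.rm = TRUE),
    mean_turnover_ratio = mean(x$ratios$turnover_ratio, na.rm = TRUE)
  )
}

#' Plot per-session density and per-interval dynamics ratios
#'
#' @param object A `spine_dynamics` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spine_dynamics <- function(object, ...) {
  rat <- tidyr::pivot_longer(
    object$ratios[, c("session", "addition_ratio", "elimination_ratio", "turnover_ratio")],
    -"session", names_to = "metric", values_to = "value"
  )
  rat$metric <- sub("_ratio$", "", rat$metric)
  dens <- object$density
  dens$metric <- "density (/um)"
  dens$value <- dens$density_per_um
  df <- dplyr::bind_rows(
    rat[, c("session", "metric", "value")],
    dens[, c("session", "metric", "value")]
  )
  df$session <- factor(df$session, levels = unique(object$density$session))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$session, y = .data$value,
                                   group = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Spine density and turnover dynamics") +
    ggplot2::theme_minimal()
}

#' Plot a normalized intensity series (group mean +/- SEM)
#' @param object An `intensity_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.intensity_series <- function(object, ...) {
  s <- object$summary
  s$session <- factor(s$session, levels = colnames(object$matrix))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$session, y = .data$mean, group = 1)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem
    )) +
    ggplot2::labs(x = NULL, y = "spine intensity (relative to baseline)",
                  title = "Normalized spine structure intensity") +
    ggplot2::theme_minimal()
}

#' Heat map of per-track relative intensity across sessions
#' @param series An `intensity_series`.
#' @return A ggplot (tracks x sessions tile map).
#' @export
plot_intensity_heatmap <- function(series) {
  m <- series$matrix
  df <- tibble::as_tibble(m, rownames = "track_id") |>
    tidyr::pivot_longer(-"track_id", names_to = "session", values_to = "value")
  df$session <- factor(df$session, levels = colnames(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$session, y = .data$track_id,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = NULL, y = "track", fill = "rel. intensity") +
    ggplot2::theme_minimal()
}

#' Plot a Sholl profile
#' @param object Tibble from [sholl_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_sholl <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$radius_um,
                                       y = .data$intersections)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "radius (um)", y = "intersections",
                  title = "Sholl profile") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
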