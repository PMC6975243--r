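# broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' Tidy a sphere fit
#'
#' @param x A `sphere_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`center_x`, `center_y`,
#'   `center_z`, `radius`) and its estimate.
#' @export
tidy.sphere_fit <- function(x, ...) {
  tibble(
    term = c("center_x", "center_y", "center_z", "radius"),
    estimate = c(x$center, x$radius)
  )
}

#' One-row summary of a sphere fit
#'
#' @param x A `sphere_fit`.
#' @param ... Unused.
#' @return One-row tibble: radius, error metrics, point count, curvature
#'   sense and convergence.
#' @export
glance.sphere_fit <- function(x, ...) {
  tibble(
    radius = x$radius,
    mean_abs_error = x$mean_abs_error,
    mean_error_pct = x$mean_error_pct,
    rms_error = x$rms_error,
    n_points = x$n_points,
    curvature_sense = x$curvature_sense,
    converged = x$converged,
    n_iter = x$n_iter
  )
}

#' Tidy a bicondylar decomposition
#'
#' @param x A `bicondylar_fit`.
#' @param ... Unused.
#' @return Tibble with one row per condyle: label, radius, error, area
#'   fraction, curvature sense.
#' @export
tidy.bicondylar_fit <- function(x, ...) {
  tibble(
    condyle = c("radial", "ulnar"),
    radius = c(x$radial_fit$radius, x$ulnar_fit$radius),
    mean_abs_error = c(x$radial_fit$mean_abs_error, x$ulnar_fit$mean_abs_error),
    area_fraction = c(x$radial_area_fraction, x$ulnar_area_fraction),
    curvature_sense = c(x$radial_fit$curvature_sense, x$ulnar_fit$curvature_sense)
  )
}

#' One-row summary of a bicondylar decomposition
#'
#' @param x A `bicondylar_fit`.
#' @param ... Unused.
#' @return One-row tibble: both radii, divergence angle, ulnar area
#'   fraction, iteration count, convergence and the bicondylar flag.
#' @export
glance.bicondylar_fit <- function(x, ...) {
  tibble(
    radial_roc = x$radial_fit$radius,
    ulnar_roc = x$ulnar_fit$radius,
    divergence_angle = x$divergence_angle,
    ulnar_area_fraction = x$ulnar_area_fraction,
    n_iterations = x$n_iterations,
    converged = x$converged,
    bicondylar = x$bicondylar
  )
}

#' Plot a cross-section polyline in its cutting plane
#'
#' Projects the section onto an orthonormal basis of the cutting plane
#' and draws the polyline.
#'
#' @param object A `cross_section`.
#' @param ... Unused.
#' @return A ggplot object (axes in mm).
#' @export
autoplot.cross_section <- function(object, ...) {
  n <- object$plane_normal
  seed_vec <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- normalize(seed_vec - sum(seed_vec * n) * n)
  v <- cross3(n, u)
  p <- sweep(object$points, 2, object$plane_point)
  df <- tibble(u = as.vector(p %*% u), v = as.vector(p %*% v))
  ggplot2::ggplot(df, ggplot2::aes(x = u, y = v)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "in-plane u (mm)", y = "in-plane v (mm)",
      title = sprintf("Cross-section, arc length %.2f mm", object$arc_length)
    )
}

#' Plot a bicondylar decomposition in the coronal-normal plane
#'
#' Vertices are projected onto the coronal-normal plane of the fit's
#' frame and coloured by condyle assignment; the two sphere centres are
#' marked.
#'
#' @param object A `bicondylar_fit`.
#' @param ... Unused.
#' @return A ggplot object (axes in mm).
#' @export
autoplot.bicondylar_fit <- function(object, ...) {
  fr <- object$frame
  pc <- frame_coords(object$mesh$vertices, fr)
  df <- tibble(
    coronal = pc[, "c"], normal = pc[, "n"],
    condyle = object$assignment
  )
  centers <- rbind(object$radial_fit$center, object$ulnar_fit$center)
  cc <- frame_coords(centers, fr)
  cdf <- tibble(coronal = cc[, "c"], normal = cc[, "n"], condyle = c("radial", "ulnar"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$coronal, y = .data$normal, colour = .data$condyle)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.6) +
    ggplot2::geom_point(data = cdf, shape = 4, size = 3, stroke = 1.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "coronal (mm)", y = "normal (mm)",
      title = sprintf("Bicondylar decomposition: divergence %.1f°", object$divergence_angle)
    )
}

#' Plot cohort measurements by role
#'
#' One panel per metric, points per facet grouped by role.
#'
#' @param measurements Output of [measure_cohort()].
#' @param metrics Character vector of metric columns to show.
#' @return A ggplot object.
#' @export
plot_cohort <- function(measurements,
                        metrics = c("roc", "surface_area", "mid_sagittal_length",
                                    "mid_coronal_width")) {
  ok <- dplyr::filter(measurements, .data$status == "ok")
  keep <- intersect(metrics, names(ok))
  long <- tidyr::pivot_longer(
    dplyr::select(ok, dplyr::all_of(c("role", keep))),
    dplyr::all_of(keep), names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(dplyr::filter(long, !is.na(.data$value)),
                  ggplot2::aes(x = .data$role, y = .data$value)) +
    ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.1, seed = 1), alpha = 0.7) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "value (mm, mm², %, or degrees)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
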