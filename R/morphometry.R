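# Per-facet measurements mirroring the study's tables: area, mid-plane
# length/width, sphere-fit radius of curvature and error, dorsal
# flattening, bicondylar decomposition, divergence and inter-facet angles.

#' Measure a single articular facet
#'
#' Computes the row the study tabulates per facet: surface area,
#' mid-sagittal length and mid-coronal width (arc lengths of the mid-plane
#' cross-sections through the area-weighted centroid), best sphere-fit
#' radius of curvature with mean absolute error (mm and as a fraction of
#' the radius), and the concave/convex sense. A coplanar (flat) patch
#' cannot support a sphere; it is reported with `roc = NA` and a warning,
#' alongside its plane-fit rms.
#'
#' @param mesh A [facet_mesh()].
#' @param frame An `anatomical_frame` from [build_frame()].
#' @param flattening If `TRUE`, dorsal flattening is evaluated via
#'   [detect_dorsal_flattening()] and reported in `flattened_dorsal`.
#' @param flat_threshold,dorsal_fraction Passed to
#'   [detect_dorsal_flattening()].
#' @return A one-row tibble: `name`, `surface_area`,
#'   `mid_sagittal_length`, `mid_coronal_width`, `roc`, `mean_abs_error`,
#'   `mean_error_pct`, `curvature_sense`, `flattened_dorsal`.
#' @export
measure_facet <- function(mesh, frame, flattening = FALSE,
                          flat_threshold = 0.25, dorsal_fraction = 0.5) {
  validate_mesh(mesh)
  area <- surface_area(mesh)
  len <- cross_section(mesh, frame$origin, frame$coronal_axis)$arc_length
  wid <- cross_section(mesh, frame$origin, frame$sagittal_axis)$arc_length
  fit <- tryCatch(fit_sphere(mesh), facetmorph_error = function(e) e)
  if (inherits(fit, "fm_coplanar_error")) {
    pl <- fit_plane(mesh)
    rlang::warn(sprintf("facet '%s' is planar (plane rms %.4g mm); ROC unavailable", mesh$name, pl$rms))
    roc <- NA_real_; mae <- pl$rms; pct <- NA_real_; sense <- NA_character_
  } else if (inherits(fit, "error")) {
    stop(fit)
  } else {
    roc <- fit$radius; mae <- fit$mean_abs_error; pct <- fit$mean_error_pct
    sense <- fit$curvature_sense
  }
  flat <- NA
  if (isTRUE(flattening) && !is.na(roc)) {
    flat <- detect_dorsal_flattening(
      mesh, frame, sphere = fit,
      dorsal_fraction = dorsal_fraction, threshold = flat_threshold
    )$flagged
  }
  tibble(
    name = mesh$name, surface_area = area,
    mid_sagittal_length = len, mid_coronal_width = wid,
    roc = roc, mean_abs_error = mae, mean_error_pct = pct,
    curvature_sense = sense, flattened_dorsal = flat
  )
}

#' Detect dorsal flattening of a facet
#'
#' The study flagged dorsally flattened fourth-CMC articulations when the
#' sphere-fit mean error exceeded 0.25 mm. Because mean error also rises
#' with scan noise, the flag here combines that criterion with a
#' geometric check: a plane fitted to the dorsal portion of the vertices
#' (split by sagittal coordinate; dorsal = +sagittal) must describe that
#' region better (smaller rms) than the sphere does. Both sub-criteria
#' are reported so the bare mean-error rule remains recoverable.
#'
#' @param mesh A [facet_mesh()].
#' @param frame An `anatomical_frame` whose +sagittal axis is dorsal.
#' @param sphere Optional precomputed `sphere_fit` of the whole facet.
#' @param dorsal_fraction Fraction of vertices, by sagittal coordinate,
#'   treated as the dorsal region (default 0.5).
#' @param threshold Mean-error threshold in mm (default 0.25).
#' @return One-row tibble: `flagged`, `sphere_mean_abs_error`,
#'   `dorsal_plane_rms`, `dorsal_sphere_error`, `dorsal_fraction_used`,
#'   `threshold`.
#' @export
detect_dorsal_flattening <- function(mesh, frame, sphere = NULL,
                                     dorsal_fraction = 0.5, threshold = 0.25) {
  validate_mesh(mesh)
  if (dorsal_fraction <= 0 || dorsal_fraction >= 1) {
    fm_abort("dorsal_fraction must lie in (0, 1)", "fm_validation_error")
  }
  if (is.null(sphere)) sphere <- fit_sphere(mesh)
  s <- frame_coords(mesh$vertices, frame)[, "s"]
  # the flattened extent is unknown a priori, so the plane-vs-sphere
  # contrast is evaluated over a ladder of dorsal fractions up to
  # dorsal_fraction; the best contrast is reported
  fracs <- unique(c(seq(0.2, dorsal_fraction, by = 0.1), dorsal_fraction))
  fracs <- fracs[fracs > 0 & fracs <= dorsal_fraction]
  best <- NULL
  for (fr in fracs) {
    cut <- quantile(s, 1 - fr)
    dorsal <- which(s >= cut)
    if (length(dorsal) < 10) next
    dv <- mesh$vertices[dorsal, , drop = FALSE]
    plane_rms <- fit_plane(dv)$rms
    sph_rms <- sqrt(mean(point_sphere_residuals(dv, sphere)^2))
    ratio <- plane_rms / max(sph_rms, 1e-12)
    if (is.null(best) || ratio < best$ratio) {
      best <- list(ratio = ratio, plane_rms = plane_rms, sph_rms = sph_rms, frac = fr)
    }
  }
  if (is.null(best)) {
    fm_abort("dorsal region has fewer than 10 vertices", "fm_insufficient_region")
  }
  flagged <- (sphere$mean_abs_error > threshold) && (best$plane_rms < best$sph_rms)
  tibble(
    flagged = flagged,
    sphere_mean_abs_error = sphere$mean_abs_error,
    dorsal_plane_rms = best$plane_rms,
    dorsal_sphere_error = best$sph_rms,
    dorsal_fraction_used = best$frac,
    threshold = threshold
  )
}

#' Bicondylar decomposition: alternating two-sphere fit
#'
#' Splits the facet into two condylar regions each modelled by its own
#' sphere. Vertices are initialised by the median coronal coordinate and
#' the algorithm alternates between fitting a sphere to each group and
#' reassigning every vertex to the sphere with the smaller absolute
#' residual, until the assignment is a fixed point (or `max_iter`
#' sweeps). Each sweep cannot increase the total squared residual.
#' Groups are labelled radial/ulnar by mean coronal coordinate
#' (+coronal = ulnar); faces take the majority vertex label (ties to
#' radial) and area fractions are summed face areas over the total.
#'
#' @param mesh A [facet_mesh()].
#' @param frame An `anatomical_frame`.
#' @param labels Optional initial per-vertex labels (`"radial"`/`"ulnar"`
#'   character vector, e.g. from a manual outline CSV); replaces the
#'   coronal-median initialisation. With `iterate = FALSE` they are used
#'   as the final assignment.
#' @param iterate If `FALSE`, fit one sphere per supplied label group
#'   without reassignment (mimics a manual outline).
#' @param max_iter Maximum alternating sweeps (default 50).
#' @return A `bicondylar_fit`: `radial_fit`, `ulnar_fit` (sphere fits),
#'   `assignment` (per-vertex labels), `radial_area_fraction`,
#'   `ulnar_area_fraction` (percent), `divergence_angle` (degrees),
#'   `n_iterations`, `converged`, `bicondylar` (FALSE when the two radii
#'   agree within 1 percent, signalling a unicondylar surface), plus the
#'   mesh/frame for downstream use.
#' @export
partition_bicondylar <- function(mesh, frame, labels = NULL, iterate = TRUE,
                                 max_iter = 50L) {
  validate_mesh(mesh)
  co <- frame_coords(mesh$vertices, frame)[, "c"]
  nv <- nrow(mesh$vertices)
  if (is.null(labels)) {
    grp <- co > stats::median(co)
  } else {
    if (length(labels) != nv) fm_abort("labels must have one entry per vertex", "fm_validation_error")
    grp <- labels == "ulnar"
  }
  nrms <- vertex_normals(mesh)

  fit_group <- function(idx) {
    if (sum(idx) < 4) {
      fm_abort("a condylar group shrank below 4 vertices; surface appears unicondylar", "fm_degenerate_partition")
    }
    tryCatch(
      fit_sphere(mesh$vertices[idx, , drop = FALSE], normals = nrms[idx, , drop = FALSE]),
      fm_coplanar_error = function(e) {
        fm_abort("a condylar group is coplanar; surface appears unicondylar", "fm_degenerate_partition")
      }
    )
  }

  # reassignment: the condyles are separated by a ridge running in the
  # sagittal direction, so the boundary is constrained to a coronal
  # threshold; each sweep picks the threshold (and sphere-to-side
  # pairing) minimising the total squared residual. Unconstrained
  # per-vertex competition is degenerate under scan noise: a sphere can
  # lower the objective by capturing the rim of the other condyle.
  ord <- order(co)
  co_sorted <- co[ord]
  run_end <- which(diff(co_sorted) > 1e-12)   # valid cut positions (lower-side size)
  run_end <- run_end[run_end >= 4 & run_end <= nv - 4]
  if (length(run_end) == 0) {
    fm_abort("no valid coronal split supports two condylar groups", "fm_degenerate_partition")
  }

  iters <- 0L
  converged <- !iterate
  if (iterate) {
    repeat {
      iters <- iters + 1L
      f1 <- fit_group(grp)
      f0 <- fit_group(!grp)
      r1 <- point_sphere_residuals(mesh$vertices, f1)^2
      r0 <- point_sphere_residuals(mesh$vertices, f0)^2
      best <- NULL
      for (upper_fit in list(c(1, 0), c(0, 1))) {
        ru2 <- if (upper_fit[1] == 1) r1 else r0   # sphere on the high-coronal side
        rl2 <- if (upper_fit[1] == 1) r0 else r1
        lower_cum <- cumsum(rl2[ord])
        upper_cum <- rev(cumsum(rev(ru2[ord])))    # upper_cum[i] = sum from i to n
        tot <- lower_cum[run_end] + upper_cum[run_end + 1L]
        k <- which.min(tot)
        if (is.null(best) || tot[k] < best$sse) {
          best <- list(sse = tot[k], cut = run_end[k], upper_is_f1 = upper_fit[1] == 1)
        }
      }
      new_grp <- logical(nv)
      new_grp[ord[(best$cut + 1L):nv]] <- TRUE     # TRUE = high-coronal group
      if (all(new_grp == grp)) {
        converged <- TRUE
        break
      }
      grp <- new_grp
      if (iters >= max_iter) break
    }
  }
  fit_in <- fit_group(grp)
  fit_out <- fit_group(!grp)

  # label groups anatomically: +coronal = ulnar
  mean_in <- mean(co[grp])
  mean_out <- mean(co[!grp])
  if (mean_in >= mean_out) {
    ulnar_fit <- fit_in; radial_fit <- fit_out; ulnar_idx <- grp
  } else {
    ulnar_fit <- fit_out; radial_fit <- fit_in; ulnar_idx <- !grp
  }
  assignment <- ifelse(ulnar_idx, "ulnar", "radial")

  n_ulnar_verts <- matrix(ulnar_idx[mesh$faces], ncol = 3)
  face_label <- ifelse(rowSums(n_ulnar_verts) >= 2, "ulnar", "radial")
  areas <- face_areas(mesh)
  total <- sum(areas)
  ulnar_frac <- 100 * sum(areas[face_label == "ulnar"]) / total

  out <- structure(
    list(
      radial_fit = radial_fit, ulnar_fit = ulnar_fit,
      assignment = assignment, face_label = face_label,
      radial_area_fraction = 100 - ulnar_frac,
      ulnar_area_fraction = ulnar_frac,
      n_iterations = iters, converged = converged,
      bicondylar = abs(radial_fit$radius - ulnar_fit$radius) /
        mean(c(radial_fit$radius, ulnar_fit$radius)) > 0.01,
      mesh = mesh, frame = frame
    ),
    class = "bicondylar_fit"
  )
  out$divergence_angle <- divergence_angle(out, frame)
  out
}

#' Angle of divergence between the two condylar spheres
#'
#' For each condyle a ray is cast from its sphere centre through the
#' area-weighted centroid of its region; both rays are projected onto the
#' mid-coronal plane (spanned by the coronal and normal axes) and the
#' angle between the projections is returned. `method = "mean_normal"`
#' instead uses each region's area-weighted mean face normal.
#'
#' @param result A `bicondylar_fit`.
#' @param frame An `anatomical_frame`.
#' @param method `"centroid_ray"` (default) or `"mean_normal"`.
#' @return Angle in degrees, in \[0, 180\].
#' @export
divergence_angle <- function(result, frame, method = c("centroid_ray", "mean_normal")) {
  method <- match.arg(method)
  mesh <- result$mesh
  areas <- face_areas(mesh)
  fc <- face_centroids(mesh)
  fn <- face_normals(mesh)
  region_vec <- function(label, fit) {
    sel <- result$face_label == label
    if (!any(sel)) fm_abort("empty condylar region", "fm_undefined_angle")
    if (method == "centroid_ray") {
      centroid <- colSums(fc[sel, , drop = FALSE] * areas[sel]) / sum(areas[sel])
      centroid - fit$center
    } else {
      colSums(fn[sel, , drop = FALSE] * areas[sel])
    }
  }
  u <- region_vec("radial", result$radial_fit)
  v <- region_vec("ulnar", result$ulnar_fit)
  angle_between(u, v, plane_normal = frame$sagittal_axis)
}

#' Area fraction of a face subset
#'
#' @param sub Integer indices of faces within `whole`.
#' @param whole A [facet_mesh()].
#' @return Percentage of the total surface area, in \[0, 100\].
#' @export
area_fraction <- function(sub, whole) {
  validate_mesh(whole)
  areas <- face_areas(whole)
  total <- sum(areas)
  if (total <= 0) fm_abort("mesh has zero total area", "fm_validation_error")
  if (length(sub) == 0) return(0)
  sub <- as.integer(sub)
  if (min(sub) < 1 || max(sub) > nrow(whole$faces)) {
    fm_abort("face subset indices out of range", "fm_validation_error")
  }
  100 * sum(areas[sub]) / total
}

#' Inter-facet angle at the shared mid-coronal plane
#'
#' Both facets (expressed in one coordinate system) are cut by the shared
#' mid-coronal plane; a total-least-squares line is fitted to each
#' cross-section and the angle between the two line directions returned.
#' Line directions are sign-fixed toward +coronal (falling back to
#' +normal when a section runs perpendicular to the coronal axis) so the
#' acute/obtuse character is deterministic.
#'
#' @param facet4,facet5 Two [facet_mesh()] objects in one frame.
#' @param shared_frame The shared `anatomical_frame`.
#' @return Angle in degrees, in \[0, 180\].
#' @export
interfacet_angle <- function(facet4, facet5, shared_frame) {
  dir_of <- function(mesh) {
    cs <- cross_section(mesh, shared_frame$origin, shared_frame$sagittal_axis)
    d <- section_direction(cs)
    comp_c <- sum(d * shared_frame$coronal_axis)
    comp_n <- sum(d * shared_frame$normal_axis)
    if (abs(comp_c) > 1e-8) {
      if (comp_c < 0) d <- -d
    } else if (comp_n < 0) {
      d <- -d
    }
    d
  }
  angle_between(dir_of(facet4), dir_of(facet5))
}

#' Three-point radius of curvature of a facet at its mid-axial section
#'
#' Cuts the facet by the mid-axial plane (through the centroid, spanned
#' by the coronal and normal axes), then takes the two endpoints and the
#' mid-arc-length point of the section as the three points of a
#' circumradius.
#'
#' @param mesh A [facet_mesh()].
#' @param frame An `anatomical_frame`.
#' @return Radius in mm.
#' @export
facet_three_point_roc <- function(mesh, frame) {
  cs <- cross_section(mesh, frame$origin, frame$sagittal_axis)
  p1 <- cs$points[1, ]
  p3 <- cs$points[nrow(cs$points), ]
  p2 <- section_point_at(cs, 0.5)
  three_point_roc(p1, p2, p3)
}

#' @export
print.bicondylar_fit <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<bicondylar_fit: radial ROC %.2f mm (%.1f%% of area), ulnar ROC %.2f mm (%.1f%%),\n",
      "  divergence %.2f deg, %d iterations%s%s>\n"
    ),
    x$radial_fit$radius, x$radial_area_fraction,
    x$ulnar_fit$radius, x$ulnar_area_fraction,
    x$divergence_angle, x$n_iterations,
    if (x$converged) "" else " (not converged)",
    if (x$bicondylar) "" else " [non-bicondylar]"
  ))
  invisible(x)
}
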