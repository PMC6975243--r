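# Geometric primitives: anatomical frames, least-squares sphere and plane
# fits, three-point radius of curvature, angles.

#' Build the anatomical frame of a facet patch
#'
#' The frame fixes the plane conventions used throughout: the
#' *mid-sagittal* plane (length direction) is spanned by the sagittal and
#' normal axes, the *mid-coronal* plane (width direction) by the coronal
#' and normal axes; both pass through the area-weighted centroid.
#'
#' With a landmark-sourced orientation the sagittal axis is the
#' dorsal-volar landmark axis projected into the surface tangent plane
#' and the coronal axis the radial-ulnar axis likewise. Without
#' landmarks, vertex PCA supplies the axes: sagittal = largest-variance
#' direction, coronal = second, normal = smallest, the normal flipped to
#' agree with the mean face normal.
#'
#' @param mesh A [facet_mesh()].
#' @param orientation An [orientation_spec()], or `NULL` for PCA axes.
#' @return An `anatomical_frame` with `origin`, `sagittal_axis`,
#'   `coronal_axis`, `normal_axis`, `handedness` and `source`.
#' @export
build_frame <- function(mesh, orientation = NULL) {
  validate_mesh(mesh)
  if (is.null(orientation)) orientation <- orientation_spec(source = "pca-default")
  origin <- area_centroid(mesh)
  mn <- mean_vertex_normal(mesh)

  if (identical(orientation$source, "landmarks")) {
    n <- mn
    dv <- orientation$dorsal_volar_axis
    s <- dv - sum(dv * n) * n
    if (vnorm(s) < 1e-9) fm_abort("dorsal-volar axis is parallel to the surface normal", "fm_validation_error")
    s <- normalize(s)
    ru <- orientation$radial_ulnar_axis
    co <- ru - sum(ru * n) * n - sum(ru * s) * s
    if (vnorm(co) < 1e-9) fm_abort("radial-ulnar axis degenerate after projection", "fm_validation_error")
    co <- normalize(co)
    hand <- if (sum(cross3(s, co) * n) >= 0) 1 else -1
  } else {
    v <- sweep(mesh$vertices, 2, colMeans(mesh$vertices))
    ev <- eigen(crossprod(v) / nrow(v), symmetric = TRUE)
    lambda <- ev$values
    if ((lambda[2] - lambda[3]) / lambda[1] < 1e-9) {
      fm_abort(
        "PCA axes are ambiguous (two equal smallest eigenvalues); supply a landmark orientation file",
        "fm_ambiguous_frame"
      )
    }
    s <- ev$vectors[, 1]
    n <- ev$vectors[, 3]
    if (sum(n * mn) < 0) n <- -n
    co <- cross3(n, s)  # right-handed completion
    hand <- 1
  }
  structure(
    list(
      origin = origin, sagittal_axis = s, coronal_axis = co,
      normal_axis = n, handedness = hand, source = orientation$source
    ),
    class = "anatomical_frame"
  )
}

#' Construct an anatomical frame from explicit axes
#'
#' Useful when the axes are known a priori (e.g. simulated scenes or
#' shared frames for inter-facet measurements). Axes are re-orthonormalised
#' by Gram-Schmidt in the order sagittal, coronal, normal.
#'
#' @param origin 3D point (mm).
#' @param sagittal,coronal Direction vectors; `normal` defaults to their
#'   cross product.
#' @param normal Optional normal direction.
#' @return An `anatomical_frame`.
#' @export
anatomical_frame <- function(origin = c(0, 0, 0), sagittal = c(1, 0, 0),
                             coronal = c(0, 1, 0), normal = NULL) {
  s <- normalize(as_point3(sagittal, "sagittal"))
  co <- as_point3(coronal, "coronal")
  co <- normalize(co - sum(co * s) * s)
  n <- if (is.null(normal)) cross3(s, co) else {
    nn <- as_point3(normal, "normal")
    normalize(nn - sum(nn * s) * s - sum(nn * co) * co)
  }
  hand <- if (sum(cross3(s, co) * n) >= 0) 1 else -1
  structure(
    list(origin = as_point3(origin, "origin"), sagittal_axis = s,
         coronal_axis = co, normal_axis = n, handedness = hand, source = "manual"),
    class = "anatomical_frame"
  )
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat(sprintf(
    "<anatomical_frame (%s): origin (%.2f, %.2f, %.2f) mm>\n",
    x$source, x$origin[1], x$origin[2], x$origin[3]
  ))
  invisible(x)
}

# Coordinates of points in a frame: columns sagittal, coronal, normal.
frame_coords <- function(points, frame) {
  p <- sweep(as_points_matrix(points), 2, frame$origin)
  cbind(
    s = as.vector(p %*% frame$sagittal_axis),
    c = as.vector(p %*% frame$coronal_axis),
    n = as.vector(p %*% frame$normal_axis)
  )
}

#' Least-squares sphere fit (radius of curvature)
#'
#' Fits the sphere minimising the sum of squared orthogonal distances
#' \eqn{\sum_i (\lVert p_i - c\rVert - r)^2}: an algebraic linear
#' least-squares sphere provides the starting point, refined by
#' Gauss-Newton with step halving until the relative parameter change
#' falls below `tol` (or `max_iter` iterations, in which case the best
#' iterate is returned with `converged = FALSE` and a warning). The mean
#' absolute residual and its fraction of the radius are the study's
#' "mean error" metrics.
#'
#' @param x A [facet_mesh()] or an n x 3 matrix of points (n >= 4,
#'   non-coplanar). A mesh also supplies vertex normals for the
#'   concave/convex call.
#' @param normals Optional n x 3 matrix of outward surface normals used to
#'   classify curvature sense when `x` is a bare point matrix.
#' @param tol Relative parameter-change convergence tolerance.
#' @param max_iter Maximum Gauss-Newton iterations.
#' @return A `sphere_fit` with `center` (mm), `radius` (mm),
#'   `mean_abs_error` (mm), `mean_error_pct` (fraction of radius),
#'   `rms_error` (mm), `n_points`, `curvature_sense` (`"concave"`,
#'   `"convex"` or `NA`), `converged`, `n_iter`.
#' @export
fit_sphere <- function(x, normals = NULL, tol = 1e-10, max_iter = 100L) {
  if (is_facet_mesh(x) && is.null(normals)) normals <- vertex_normals(x)
  p <- as_points_matrix(x)
  n <- nrow(p)
  if (n < 4) fm_abort("sphere fit needs at least 4 points", "fm_degenerate_input")
  ctr <- colMeans(p)
  q <- sweep(p, 2, ctr)
  lambda <- eigen(crossprod(q) / n, symmetric = TRUE, only.values = TRUE)$values
  if (lambda[3] / lambda[1] < 1e-10) {
    fm_abort("points are coplanar; a sphere is unidentifiable", "fm_coplanar_error")
  }

  # algebraic initialisation: ||p||^2 = 2 c.p + (r^2 - ||c||^2), linear in (c, k)
  A <- cbind(2 * q, 1)
  b <- rowSums(q^2)
  sol <- qr.solve(A, b)
  c0 <- sol[1:3]
  r0 <- sqrt(max(sol[4] + sum(c0^2), .Machine$double.eps))

  sse <- function(par) {
    d <- sqrt(rowSums(sweep(q, 2, par[1:3])^2))
    sum((d - par[4])^2)
  }
  par <- c(c0, r0)
  best_sse <- sse(par)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    diff <- sweep(q, 2, par[1:3])
    d <- sqrt(rowSums(diff^2))
    d <- pmax(d, 1e-12)
    res <- d - par[4]
    J <- cbind(-diff / d, -1)
    step <- tryCatch(qr.solve(J, -res), error = function(e) rep(0, 4))
    # damped acceptance: never leave with a worse objective than the start
    alpha <- 1
    new_par <- par + alpha * step
    new_sse <- sse(new_par)
    halvings <- 0L
    while (new_sse > best_sse && halvings < 30L) {
      alpha <- alpha / 2
      new_par <- par + alpha * step
      new_sse <- sse(new_par)
      halvings <- halvings + 1L
    }
    if (new_sse > best_sse) break
    rel_change <- vnorm(alpha * step) / max(vnorm(par), 1e-12)
    par <- new_par
    best_sse <- new_sse
    if (rel_change < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged && iter >= max_iter) {
    rlang::warn("sphere fit did not converge; returning best iterate")
  } else {
    converged <- TRUE
  }

  center <- par[1:3] + ctr
  radius <- abs(par[4])
  d <- sqrt(rowSums(sweep(p, 2, center)^2))
  res <- d - radius
  sense <- NA_character_
  if (!is.null(normals)) {
    # concave: the sphere center lies on the outward-normal side of the surface
    mn <- colSums(as_points_matrix(normals, "normals"))
    mn <- mn / max(vnorm(mn), 1e-300)
    sense <- if (sum(mn * (center - colMeans(p))) > 0) "concave" else "convex"
  }
  structure(
    list(
      center = center, radius = radius,
      mean_abs_error = mean(abs(res)),
      mean_error_pct = mean(abs(res)) / radius,
      rms_error = sqrt(mean(res^2)),
      n_points = n, curvature_sense = sense,
      converged = converged, n_iter = iter
    ),
    class = "sphere_fit"
  )
}

#' Signed point-to-sphere residuals
#'
#' @param points n x 3 matrix (or [facet_mesh()]).
#' @param sphere A `sphere_fit`.
#' @return Signed distances \eqn{\lVert p_i - c\rVert - r} in mm
#'   (outside positive).
#' @export
point_sphere_residuals <- function(points, sphere) {
  p <- as_points_matrix(points)
  sqrt(rowSums(sweep(p, 2, sphere$center)^2)) - sphere$radius
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf(
    "<sphere_fit: ROC %.3f mm (%s), mean error %.4f mm (%.2f%% of radius), n = %d>\n",
    x$radius, ifelse(is.na(x$curvature_sense), "sense unknown", x$curvature_sense),
    x$mean_abs_error, 100 * x$mean_error_pct, x$n_points
  ))
  invisible(x)
}

#' Total-least-squares plane fit
#'
#' @param points n x 3 matrix (or [facet_mesh()]), n >= 3, non-collinear.
#' @return List with `point` (centroid), `normal` (unit) and `rms`
#'   (root-mean-square orthogonal distance, mm).
#' @export
fit_plane <- function(points) {
  p <- as_points_matrix(points)
  if (nrow(p) < 3) fm_abort("plane fit needs at least 3 points", "fm_degenerate_input")
  ctr <- colMeans(p)
  q <- sweep(p, 2, ctr)
  ev <- eigen(crossprod(q) / nrow(p), symmetric = TRUE)
  if (ev$values[2] / max(ev$values[1], 1e-300) < 1e-12) {
    fm_abort("points are collinear; a plane is unidentifiable", "fm_degenerate_input")
  }
  normal <- ev$vectors[, 3]
  d <- q %*% normal
  list(point = ctr, normal = normal, rms = sqrt(mean(d^2)))
}

#' Radius of the circle through three points
#'
#' Circumradius R = abc / 4K with a, b, c the side lengths and K the
#' triangle area.
#'
#' @param p1,p2,p3 3D points (mm), pairwise distinct and non-collinear.
#' @return Radius in mm.
#' @export
three_point_roc <- function(p1, p2, p3) {
  p1 <- as_point3(p1, "p1"); p2 <- as_point3(p2, "p2"); p3 <- as_point3(p3, "p3")
  K <- 0.5 * vnorm(cross3(p2 - p1, p3 - p1))
  if (K <= 1e-12) fm_abort("points are collinear; no circle is defined", "fm_collinear_error")
  a <- vnorm(p2 - p3)
  b <- vnorm(p1 - p3)
  cc <- vnorm(p1 - p2)
  a * b * cc / (4 * K)
}

#' Angle between two vectors, optionally within a plane
#'
#' @param u,v Nonzero 3-vectors.
#' @param plane_normal Optional unit normal; `u` and `v` are projected
#'   onto that plane first (and must remain nonzero).
#' @return Angle in degrees, in \[0, 180\].
#' @export
angle_between <- function(u, v, plane_normal = NULL) {
  u <- as_point3(u, "u")
  v <- as_point3(v, "v")
  if (!is.null(plane_normal)) {
    n <- normalize(as_point3(plane_normal, "plane_normal"))
    u <- u - sum(u * n) * n
    v <- v - sum(v * n) * n
  }
  if (vnorm(u) < 1e-12 || vnorm(v) < 1e-12) {
    fm_abort("angle undefined: zero vector (possibly after projection)", "fm_undefined_angle")
  }
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}
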