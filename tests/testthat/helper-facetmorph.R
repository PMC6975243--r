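# Shared fixtures and independent oracles used across the suite.

unit_square_mesh <- function() {
  facet_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
    rbind(c(1, 2, 3), c(1, 3, 4)),
    name = "square"
  )
}

# canonical generator axes as a landmark orientation
xy_orientation <- function() {
  orientation_spec(c(1, 0, 0), c(0, 1, 0), source = "landmarks")
}

# deterministic random rotation matrix (QR of a Gaussian matrix)
random_rotation <- function(seed) {
  set.seed(seed)
  qr_dec <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_dec)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Independent circumradius oracle: solve the circumcentre linear system
# in the plane of the triangle and verify equidistance.
oracle_circumradius <- function(p1, p2, p3) {
  u <- p2 - p1
  v <- p3 - p1
  # plane basis
  e1 <- u / sqrt(sum(u^2))
  w <- v - sum(v * e1) * e1
  e2 <- w / sqrt(sum(w^2))
  a <- c(0, 0)
  b <- c(sum(u * e1), sum(u * e2))
  cc <- c(sum(v * e1), sum(v * e2))
  # perpendicular bisector intersection: 2(b-a).x = |b|^2-|a|^2 etc.
  A <- rbind(2 * (b - a), 2 * (cc - a))
  rhs <- c(sum(b^2) - sum(a^2), sum(cc^2) - sum(a^2))
  ctr <- solve(A, rhs)
  r <- sqrt(sum((ctr - a)^2))
  stopifnot(abs(sqrt(sum((ctr - b)^2)) - r) < 1e-9 * max(1, r))
  r
}

# sum of squared orthogonal residuals of points to a sphere (c, r)
sphere_sse <- function(points, center, radius) {
  sum((sqrt(rowSums(sweep(points, 2, center)^2)) - radius)^2)
}

# independent algebraic sphere (linear least squares on the Kasa form)
oracle_algebraic_sphere <- function(p) {
  A <- cbind(2 * p, 1)
  b <- rowSums(p^2)
  sol <- qr.solve(A, b)
  list(center = sol[1:3], radius = sqrt(sol[4] + sum(sol[1:3]^2)))
}

# points drawn on a full sphere surface
sphere_points <- function(n, radius, seed) {
  set.seed(seed)
  v <- matrix(rnorm(3 * n), ncol = 3)
  radius * v / sqrt(rowSums(v^2))
}

# area-weighted centroid computed directly from triangle areas
area_centroid_of <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  a <- 0.5 * sqrt(rowSums(cr^2))
  fc <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] + v[f[, 3], , drop = FALSE]) / 3
  colSums(fc * a) / sum(a)
}

# coordinates of points in a frame (columns s, c, n)
facetmorph_frame_coords <- function(points, frame) {
  p <- sweep(points, 2, frame$origin)
  cbind(
    s = as.vector(p %*% frame$sagittal_axis),
    c = as.vector(p %*% frame$coronal_axis),
    n = as.vector(p %*% frame$normal_axis)
  )
}

# planar rectangular facet tilted about the sagittal (x) axis
tilted_plane_facet <- function(angle_deg, y_range = c(0.5, 6), name = "plane") {
  ang <- angle_deg * pi / 180
  ys <- seq(y_range[1], y_range[2], length.out = 14)
  xs <- seq(-5, 5, length.out = 14)
  g <- expand.grid(x = xs, t = ys)
  v <- cbind(g$x, g$t * cos(ang), g$t * sin(ang))
  nx <- length(xs)
  f <- list()
  for (j in seq_len(length(ys) - 1)) {
    for (i in seq_len(nx - 1)) {
      a <- (j - 1) * nx + i
      f[[length(f) + 1]] <- rbind(c(a, a + 1, a + nx), c(a + 1, a + nx + 1, a + nx))
    }
  }
  facet_mesh(v, do.call(rbind, f), name = name)
}
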