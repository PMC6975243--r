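# Planar cross-sections of a mesh. The mid-sagittal and mid-coronal
# length/width measurements are arc lengths of these sections.

#' Cross-section of a mesh by a plane
#'
#' Intersects every triangle with the plane, chains the resulting
#' segments into polylines (segment endpoints are keyed by the mesh edge
#' they lie on, so chaining is exact), and returns the longest connected
#' polyline by arc length. Ties are broken by the lowest starting vertex
#' index. Vertices exactly on the plane are nudged by 1e-12 mm so every
#' crossing triangle contributes exactly one segment.
#'
#' @param mesh A [facet_mesh()].
#' @param plane_point A point on the plane.
#' @param plane_normal Plane normal (need not be unit).
#' @return A `cross_section` with ordered `points` (k x 3), `plane_point`,
#'   `plane_normal` (unit), `arc_length` (mm) and `closed` flag.
#' @export
cross_section <- function(mesh, plane_point, plane_normal) {
  validate_mesh(mesh)
  p0 <- as_point3(plane_point, "plane_point")
  nrm <- normalize(as_point3(plane_normal, "plane_normal"))
  v <- mesh$vertices
  f <- mesh$faces
  d <- as.vector(sweep(v, 2, p0) %*% nrm)
  d[abs(d) < 1e-12] <- 1e-12  # push on-plane vertices to one side

  dmat <- matrix(d[f], ncol = 3)
  pos <- dmat > 0
  npos <- rowSums(pos)
  crossing <- which(npos == 1L | npos == 2L)
  if (length(crossing) == 0) {
    fm_abort("the plane does not intersect the mesh", "fm_no_intersection")
  }

  nv <- nrow(v)
  edge_key <- function(i, j) {
    lo <- pmin(i, j); hi <- pmax(i, j)
    (lo - 1) * nv + hi
  }
  # intersection point on every crossing edge, computed vectorised
  fa <- f[crossing, , drop = FALSE]
  da <- dmat[crossing, , drop = FALSE]
  edge_pairs <- list(c(1L, 2L), c(2L, 3L), c(1L, 3L))
  # collect all crossing edges across faces
  all_i <- integer(0); all_j <- integer(0); owner <- integer(0)
  for (ep in edge_pairs) {
    cr <- da[, ep[1]] * da[, ep[2]] < 0
    if (any(cr)) {
      all_i <- c(all_i, fa[cr, ep[1]])
      all_j <- c(all_j, fa[cr, ep[2]])
      owner <- c(owner, which(cr))
    }
  }
  # each crossing face has exactly two crossing edges
  t_i <- d[all_i]; t_j <- d[all_j]
  t <- t_i / (t_i - t_j)
  pts <- v[all_i, , drop = FALSE] + (v[all_j, , drop = FALSE] - v[all_i, , drop = FALSE]) * t
  keys <- edge_key(all_i, all_j)

  # unique nodes
  uk <- unique(keys)
  node_of <- match(keys, uk)
  node_pts <- pts[match(uk, keys), , drop = FALSE]
  # smallest incident vertex index per node, for deterministic tie-breaks
  node_minvert <- pmin((uk - 1) %/% nv + 1, (uk - 1) %% nv + 1)

  # per-face segment: group the crossing-edge records by owner face
  ord <- order(owner)
  owner_s <- owner[ord]
  node_s <- node_of[ord]
  if (length(node_s) %% 2 != 0 || any(owner_s[seq(1, length(owner_s), 2)] != owner_s[seq(2, length(owner_s), 2)])) {
    fm_abort("degenerate cross-section (isolated intersection points)", "fm_degenerate_section")
  }
  seg_a <- node_s[seq(1, length(node_s), 2)]
  seg_b <- node_s[seq(2, length(node_s), 2)]

  # adjacency: chain polylines through nodes of degree <= 2
  nseg <- length(seg_a)
  nn <- nrow(node_pts)
  adj <- vector("list", nn)
  for (s in seq_len(nseg)) {
    adj[[seg_a[s]]] <- c(adj[[seg_a[s]]], s)
    adj[[seg_b[s]]] <- c(adj[[seg_b[s]]], s)
  }
  deg <- lengths(adj)
  used <- logical(nseg)
  polylines <- list()
  walk <- function(start_node) {
    path <- start_node
    node <- start_node
    repeat {
      nxt_seg <- adj[[node]][!used[adj[[node]]]]
      if (length(nxt_seg) == 0) break
      s <- nxt_seg[1]
      used[s] <<- TRUE
      node <- if (seg_a[s] == node) seg_b[s] else seg_a[s]
      path <- c(path, node)
      if (node == start_node) break
    }
    path
  }
  # open chains first, from endpoints (degree 1), lowest vertex index first
  endpoints <- which(deg == 1)
  for (en in endpoints[order(node_minvert[endpoints])]) {
    if (all(used[adj[[en]]])) next
    polylines[[length(polylines) + 1]] <- walk(en)
  }
  # remaining cycles
  for (nd in order(node_minvert)) {
    if (length(adj[[nd]]) > 0 && any(!used[adj[[nd]]])) {
      polylines[[length(polylines) + 1]] <- walk(nd)
    }
  }
  if (length(polylines) == 0) fm_abort("degenerate cross-section", "fm_degenerate_section")

  arc_of <- function(path) {
    pp <- node_pts[path, , drop = FALSE]
    sum(sqrt(rowSums((pp[-1, , drop = FALSE] - pp[-nrow(pp), , drop = FALSE])^2)))
  }
  arcs <- vapply(polylines, arc_of, numeric(1))
  starts <- vapply(polylines, function(p) node_minvert[p[1]], numeric(1))
  best <- order(-arcs, starts)[1]
  path <- polylines[[best]]
  pts_out <- node_pts[path, , drop = FALSE]
  structure(
    list(
      points = pts_out, plane_point = p0, plane_normal = nrm,
      arc_length = arcs[best],
      closed = path[1] == path[length(path)] && length(path) > 2
    ),
    class = "cross_section"
  )
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf(
    "<cross_section: %d points, arc length %.3f mm%s>\n",
    nrow(x$points), x$arc_length, if (isTRUE(x$closed)) ", closed" else ""
  ))
  invisible(x)
}

# Point at a given fraction of the arc length along a section polyline.
section_point_at <- function(section, frac) {
  pts <- section$points
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  target <- frac * sum(seg)
  cum <- cumsum(seg)
  k <- which(cum >= target - 1e-12)[1]
  prev <- if (k == 1) 0 else cum[k - 1]
  t <- if (seg[k] < 1e-300) 0 else (target - prev) / seg[k]
  pts[k, ] + t * (pts[k + 1, ] - pts[k, ])
}

# Principal direction of a section polyline (total least squares line).
section_direction <- function(section) {
  p <- section$points
  q <- sweep(p, 2, colMeans(p))
  ev <- eigen(crossprod(q), symmetric = TRUE)
  ev$vectors[, 1]
}
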