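# Virtual cell layer: polygonal cells tiling the outer canvas surface, bound
# to the mesh by barycentric coordinates so that they ride with the growing
# tissue; threshold-area division under CDIV competence; clone marking.

#' Cell division rule
#'
#' @param threshold_area execution threshold T_A in square micrometres
#'   (default 70): a competent cell divides when its area reaches this value.
#' @param competence_end_dai time at which division competence (CDIV) is
#'   switched off everywhere, in days after initiation (default 6.5).
#' @param stk_cutoff cells whose stalk-factor level exceeds this value never
#'   carry CDIV (default 0.5).
#' @param jitter_deg standard deviation of the seeded angular jitter applied
#'   to the division wall, degrees (default 10).
#' @param seed RNG seed for the wall jitter.
#' @return an object of class \code{division_rule}.
#' @export
division_rule <- function(threshold_area = 70, competence_end_dai = 6.5,
                          stk_cutoff = 0.5, jitter_deg = 10, seed = 1L) {
  if (threshold_area <= 0) stop("threshold_area must be positive")
  structure(list(threshold_area = threshold_area,
                 competence_end_dai = competence_end_dai,
                 stk_cutoff = stk_cutoff, jitter_deg = jitter_deg,
                 seed = seed), class = "division_rule")
}

# --- spherical centroidal Voronoi tessellation ------------------------------

# Voronoi diagram of unit points on the sphere from the convex hull
# (Delaunay); returns per-seed ordered polygons of circumcentre directions.
sphere_voronoi <- function(seeds) {
  n <- nrow(seeds)
  # deterministic tiny jitter guards against exactly degenerate hull facets
  pts <- seeds + 1e-9 * cbind(sin(seq_len(n) * 12.9898),
                              sin(seq_len(n) * 78.233),
                              sin(seq_len(n) * 37.719))
  pts <- normalize_rows(pts)
  hull <- convhull3d(pts)
  cc <- normalize_rows(cross3(pts[hull[, 2], ] - pts[hull[, 1], ],
                              pts[hull[, 3], ] - pts[hull[, 1], ]))
  tri_of_seed <- split(rep(seq_len(nrow(hull)), 3), c(hull))
  polys <- vector("list", n)
  for (i in seq_len(n)) {
    tris <- tri_of_seed[[as.character(i)]]
    ctrs <- cc[tris, , drop = FALSE]
    # order circumcentres around the seed direction
    s <- pts[i, ]
    e1 <- ctrs[1, ] - s * sum(ctrs[1, ] * s)
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(s[2] * e1[3] - s[3] * e1[2],
            s[3] * e1[1] - s[1] * e1[3],
            s[1] * e1[2] - s[2] * e1[1])
    ang <- atan2(ctrs %*% e2, ctrs %*% e1)
    polys[[i]] <- ctrs[order(ang), , drop = FALSE]
  }
  list(polys = polys, hull = hull, seeds = pts)
}

# Lloyd relaxation of seeds on the unit sphere
sphere_cvt <- function(seeds, iterations = 40) {
  for (it in seq_len(iterations)) {
    vor <- sphere_voronoi(seeds)
    seeds <- normalize_rows(t(vapply(vor$polys, function(p) {
      # area-weighted centroid of the (nearly planar) polygon fan
      ctr <- colMeans(p)
      tot <- c(0, 0, 0); aw <- 0
      for (k in seq_len(nrow(p))) {
        k2 <- if (k == nrow(p)) 1L else k + 1L
        a <- sqrt(sum(crossprod_vec(p[k, ] - ctr, p[k2, ] - ctr)^2)) / 2
        tot <- tot + a * (ctr + p[k, ] + p[k2, ]) / 3
        aw <- aw + a
      }
      if (aw == 0) ctr else tot / aw
    }, numeric(3))))
  }
  seeds
}

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Tile the canvas surface with virtual cells
#'
#' Generates a centroidal (Lloyd-relaxed) random Voronoi tessellation of the
#' outer canvas surface with the requested mean cell area. Cell polygon
#' vertices are bound to the outer mesh sheet by barycentric coordinates and
#' are displaced with the canvas as it grows.
#'
#' @param canvas a \code{canvas}.
#' @param target_mean_area target mean cell area, square micrometres.
#' @param seed RNG seed (the tessellation is deterministic given the seed).
#' @param lloyd_iterations Lloyd relaxation sweeps (default 40).
#' @return an object of class \code{cell_layer}.
#' @export
tile_cells <- function(canvas, target_mean_area = 50, seed = 1L,
                       lloyd_iterations = 40) {
  if (target_mean_area <= 0) stop("target_mean_area must be positive")
  vtop <- canvas$nodes_top
  f <- canvas$triangles
  area <- sum(tri_areas(vtop, f))
  n <- round(area / target_mean_area)
  if (n < 4)
    stop("cannot tessellate the closed surface into fewer than 4 cells ",
         "(target mean area too large)")
  rs <- local_seed(seed)
  on.exit(restore_seed(rs), add = TRUE)
  seeds <- normalize_rows(matrix(stats::rnorm(3 * n), ncol = 3))
  seeds <- sphere_cvt(seeds, lloyd_iterations)
  vor <- sphere_voronoi(seeds)

  r_out <- mean(row_norms(vtop))
  vt <- vertex_tri_map(f, nrow(vtop))
  vadj <- vertex_adjacency(f, nrow(vtop))
  polys <- vector("list", n)
  for (i in seq_len(n)) {
    p3 <- vor$polys[[i]] * r_out
    b <- bind_points_to_mesh(p3, vtop, f, vt, vadj)
    polys[[i]] <- cbind(tri = b$tri, b$bary)
  }
  # neighbour pairs from the Delaunay edges
  h <- vor$hull
  ed <- unique(rbind(cbind(pmin(h[, 1], h[, 2]), pmax(h[, 1], h[, 2])),
                     cbind(pmin(h[, 2], h[, 3]), pmax(h[, 2], h[, 3])),
                     cbind(pmin(h[, 3], h[, 1]), pmax(h[, 3], h[, 1]))))
  neighbours <- vector("list", n)
  for (k in seq_len(nrow(ed))) {
    neighbours[[ed[k, 1]]] <- c(neighbours[[ed[k, 1]]], ed[k, 2])
    neighbours[[ed[k, 2]]] <- c(neighbours[[ed[k, 2]]], ed[k, 1])
  }

  layer <- structure(list(
    polys = polys,
    cells = data.frame(id = seq_len(n), lineage = seq_len(n),
                       clone = NA_integer_, cdiv = TRUE,
                       parent = NA_integer_),
    neighbours = neighbours,
    bound = TRUE,
    next_id = n + 1L
  ), class = "cell_layer")
  # CDIV is absent from the stalk region
  ctr <- cell_centroids(layer, canvas)
  layer$cells$cdiv <- factor_at_points(canvas, "stk", ctr) <=
    division_rule()$stk_cutoff
  layer
}

#' @export
print.cell_layer <- function(x, ...) {
  cat("cell_layer:", nrow(x$cells), "cells")
  if (any(!is.na(x$cells$clone)))
    cat(";", sum(!is.na(x$cells$clone)), "clone-marked")
  cat(if (x$bound) "; bound to canvas" else "; free (static coordinates)", "\n")
  invisible(x)
}

# 3D coordinates of a cell polygon
poly_coords <- function(layer, canvas, i) {
  p <- layer$polys[[i]]
  if (!layer$bound) return(p)
  v <- canvas$nodes_top
  f <- canvas$triangles
  tri <- p[, 1]
  p[, 2] * v[f[tri, 1], , drop = FALSE] +
    p[, 3] * v[f[tri, 2], , drop = FALSE] +
    p[, 4] * v[f[tri, 3], , drop = FALSE]
}

# polygon area by fan triangulation from the first vertex (equals the exact
# area for planar polygons; daughters of a planar split sum exactly)
poly_area3d <- function(pts) {
  if (nrow(pts) < 3) return(0)
  v1 <- sweep(pts[-1, , drop = FALSE], 2, pts[1, ])
  k <- nrow(v1)
  sum(0.5 * row_norms(cross3(v1[-k, , drop = FALSE], v1[-1, , drop = FALSE])))
}

poly_centroid3d <- function(pts) {
  k <- nrow(pts)
  if (k < 3) return(colMeans(pts))
  # fan triangles (1, j, j+1), j = 2..k-1
  a <- 0.5 * row_norms(cross3(
    pts[2:(k - 1), , drop = FALSE] - matrix(pts[1, ], k - 2, 3, byrow = TRUE),
    pts[3:k, , drop = FALSE] - matrix(pts[1, ], k - 2, 3, byrow = TRUE)))
  if (sum(a) == 0) return(colMeans(pts))
  mids <- (matrix(pts[1, ], k - 2, 3, byrow = TRUE) +
             pts[2:(k - 1), , drop = FALSE] + pts[3:k, , drop = FALSE]) / 3
  colSums(mids * a) / sum(a)
}

#' Cell areas
#' @param layer a \code{cell_layer}.
#' @param canvas the canvas the layer is bound to (ignored for static layers).
#' @return numeric vector of areas, square micrometres.
#' @export
cell_areas <- function(layer, canvas = NULL) {
  vapply(seq_len(nrow(layer$cells)), function(i)
    poly_area3d(poly_coords(layer, canvas, i)), numeric(1))
}

cell_centroids <- function(layer, canvas = NULL) {
  t(vapply(seq_len(nrow(layer$cells)), function(i)
    poly_centroid3d(poly_coords(layer, canvas, i)), numeric(3)))
}

# --- second-moment shape metrics -------------------------------------------

# local tangent frame of a polygon: unit vector area normal + two tangents
poly_frame <- function(pts) {
  k <- nrow(pts)
  va <- colSums(cross3(pts, pts[c(2:k, 1), , drop = FALSE])) / 2
  n <- va / sqrt(sum(va^2))
  e1 <- pts[2, ] - pts[1, ]
  e1 <- e1 - n * sum(e1 * n)
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- crossprod_vec(n, e1)
  list(n = n, e1 = e1, e2 = e2, origin = colMeans(pts))
}

# closed-form polygon second moments of area about the centroid (2D)
polygon_second_moments <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  cx <- sum((x + x2) * cr) / (6 * a)
  cy <- sum((y + y2) * cr) / (6 * a)
  sxx <- sum((x^2 + x * x2 + x2^2) * cr) / 12
  syy <- sum((y^2 + y * y2 + y2^2) * cr) / 12
  sxy <- sum((x * y2 + 2 * x * y + 2 * x2 * y2 + x2 * y) * cr) / 24
  list(area = a,
       centroid = c(cx, cy),
       m = matrix(c(sxx - a * cx^2, sxy - a * cx * cy,
                    sxy - a * cx * cy, syy - a * cy^2), 2, 2))
}

# anisotropy from a 2x2 second-moment matrix: r = sqrt(l1/l2), a = (r-1)/(r+1)
moment_anisotropy <- function(m) {
  ev <- eigen(m, symmetric = TRUE)
  l <- pmax(ev$values, 0)
  r <- sqrt(l[1] / max(l[2], .Machine$double.eps))
  list(a = (r - 1) / (r + 1), r = r, axis2d = ev$vectors[, 1])
}

#' Cell shape metrics: area and second-moment anisotropy
#'
#' Computes, per cell, the surface area and the shape anisotropy
#' \code{a = (r - 1) / (r + 1)} with \code{r = sqrt(lambda1 / lambda2)} from
#' the eigenvalues of the second moment of area
#' \code{M_ij = int (x_i - x_i^c)(x_j - x_j^c) dA} evaluated in the cell's
#' tangent plane, together with the long-axis direction (leading
#' eigenvector). \code{a} is 0 for an isometric cell and 1/3 when the long
#' axis is twice the short axis. Degenerate (zero-area) cells are flagged
#' and their metrics set to NA.
#'
#' @param layer a \code{cell_layer}.
#' @param canvas the bound canvas (ignored for static layers).
#' @return data.frame with id, area, anisotropy, aspect ratio, long-axis
#'   vector (3 columns), centroid (3 columns), degenerate flag.
#' @export
cell_shape_metrics <- function(layer, canvas = NULL) {
  n <- nrow(layer$cells)
  out <- data.frame(id = layer$cells$id, area = NA_real_,
                    anisotropy = NA_real_, aspect = NA_real_,
                    axis_x = NA_real_, axis_y = NA_real_, axis_z = NA_real_,
                    cx = NA_real_, cy = NA_real_, cz = NA_real_,
                    degenerate = FALSE)
  for (i in seq_len(n)) {
    pts <- poly_coords(layer, canvas, i)
    if (nrow(pts) < 3) { out$degenerate[i] <- TRUE; next }
    fr <- poly_frame(pts)
    xy <- cbind((pts - matrix(fr$origin, nrow(pts), 3, byrow = TRUE)) %*% fr$e1,
                (pts - matrix(fr$origin, nrow(pts), 3, byrow = TRUE)) %*% fr$e2)
    sm <- polygon_second_moments(xy)
    if (!is.finite(sm$area) || abs(sm$area) < 1e-12) {
      out$degenerate[i] <- TRUE
      next
    }
    an <- moment_anisotropy(sm$m)
    ax <- an$axis2d[1] * fr$e1 + an$axis2d[2] * fr$e2
    ctr3 <- fr$origin + sm$centroid[1] * fr$e1 + sm$centroid[2] * fr$e2
    out$area[i] <- abs(sm$area)
    out$anisotropy[i] <- an$a
    out$aspect[i] <- an$r
    out[i, c("axis_x", "axis_y", "axis_z")] <- ax
    out[i, c("cx", "cy", "cz")] <- ctr3
  }
  out
}

# --- division ---------------------------------------------------------------

# split a polygon (3D points) by the plane through `centre` with in-plane
# direction `wall_dir`; returns the two parts' row indices with the two
# intersection points, or NULL on failure
split_polygon <- function(pts, centre, wall_dir, frame) {
  k <- nrow(pts)
  rel <- sweep(pts, 2, centre)
  xy <- cbind(rel %*% frame$e1, rel %*% frame$e2)
  w2 <- c(sum(wall_dir * frame$e1), sum(wall_dir * frame$e2))
  w2 <- w2 / sqrt(sum(w2^2))
  side <- xy[, 1] * w2[2] - xy[, 2] * w2[1]   # signed distance to wall line
  s <- side >= 0
  flips <- which(s != s[c(2:k, 1)])
  if (length(flips) < 2) return(NULL)
  cutpt <- function(i) {
    j <- if (i == k) 1L else i + 1L
    t <- side[i] / (side[i] - side[j])
    list(p = pts[i, ] + t * (pts[j, ] - pts[i, ]), i = i, t = t)
  }
  idx <- seq_len(k)
  # a non-convex polygon can be crossed more than twice; choose the crossing
  # pair whose chord midpoint lies inside the polygon, nearest the centroid
  pairs <- utils::combn(flips, 2)
  best <- NULL; best_d <- Inf
  for (p in seq_len(ncol(pairs))) {
    f1 <- pairs[1, p]; f2 <- pairs[2, p]
    c1 <- cutpt(f1); c2 <- cutpt(f2)
    mid <- (c1$p + c2$p) / 2
    mid2 <- c(sum((mid - centre) * frame$e1), sum((mid - centre) * frame$e2))
    if (ncol(pairs) > 1 && !point_in_poly(mid2, xy)) next
    d <- sum(mid2^2)
    if (d < best_d) { best_d <- d; best <- list(f1 = f1, f2 = f2, c1 = c1, c2 = c2) }
  }
  if (is.null(best)) return(NULL)
  f1 <- best$f1; f2 <- best$f2; c1 <- best$c1; c2 <- best$c2
  seg1 <- idx[(idx > f1 & idx <= f2)]
  seg2 <- c(idx[idx > f2], idx[idx <= f1])
  if (length(seg1) < 1 || length(seg2) < 1) return(NULL)
  poly1 <- rbind(c1$p, pts[seg1, , drop = FALSE], c2$p)
  poly2 <- rbind(c2$p, pts[seg2, , drop = FALSE], c1$p)
  if (nrow(poly1) < 3 || nrow(poly2) < 3) return(NULL)
  list(poly1 = poly1, poly2 = poly2,
       rows1 = seg1, rows2 = seg2, cuts = list(c1, c2))
}

#' Advect the cell layer and execute divisions
#'
#' Cell polygon vertices ride with the canvas deformation (their mesh binding
#' is material, so advection is implicit). Each competent cell whose area has
#' reached the division threshold is split by a new wall through its centroid
#' perpendicular to its long axis (with a small seeded angular jitter);
#' daughters inherit the clone mark and competence. Divisions stop after the
#' competence end time and never occur where the stalk factor exceeds the
#' rule cutoff.
#'
#' @param layer a bound \code{cell_layer}.
#' @param canvas_before,canvas_after canvas states before and after the
#'   growth step (shared connectivity).
#' @param rule a \code{\link{division_rule}}.
#' @param t current time, hours after initiation.
#' @return the updated \code{cell_layer}.
#' @export
step_cells <- function(layer, canvas_before, canvas_after, rule, t) {
  stopifnot(layer$bound)
  if (t > rule$competence_end_dai * 24) return(layer)
  areas <- cell_areas(layer, canvas_after)
  to_divide <- which(areas >= rule$threshold_area & layer$cells$cdiv)
  if (!length(to_divide)) return(layer)
  rs <- local_seed(rule$seed * 1000L + (round(t * 8) %% 100000L))
  on.exit(restore_seed(rs), add = TRUE)
  vt <- vertex_tri_map(canvas_after$triangles, nrow(canvas_after$nodes_top))
  vadj <- vertex_adjacency(canvas_after$triangles, nrow(canvas_after$nodes_top))
  for (i in to_divide) {
    layer <- divide_cell(layer, canvas_after, i, rule, vt, vadj)
  }
  layer
}

# mask keeping non-duplicate consecutive vertices (cuts landing on a vertex)
dedup_mask <- function(pts, tol = 1e-9) {
  k <- nrow(pts)
  if (k < 2) return(rep(TRUE, k))
  keep <- c(TRUE, rowSums((pts[-1, , drop = FALSE] -
                             pts[-k, , drop = FALSE])^2) > tol^2)
  if (keep[k] && sum((pts[1, ] - pts[k, ])^2) <= tol^2) keep[k] <- FALSE
  keep
}

divide_cell <- function(layer, canvas, i, rule, vt = NULL, vadj = NULL) {
  pts <- poly_coords(layer, canvas, i)
  keep <- dedup_mask(pts)
  if (!all(keep)) {
    layer$polys[[i]] <- layer$polys[[i]][keep, , drop = FALSE]
    pts <- pts[keep, , drop = FALSE]
  }
  if (nrow(pts) < 4) return(layer)  # cannot split a triangle-degenerate cell
  fr <- poly_frame(pts)
  rel <- sweep(pts, 2, fr$origin)
  xy <- cbind(rel %*% fr$e1, rel %*% fr$e2)
  sm <- polygon_second_moments(xy)
  if (!all(is.finite(unlist(sm))) || abs(sm$area) < 1e-9) return(layer)
  an <- moment_anisotropy(sm$m)
  centre3 <- fr$origin + sm$centroid[1] * fr$e1 + sm$centroid[2] * fr$e2
  # wall perpendicular to the long axis, with seeded jitter
  th <- atan2(an$axis2d[2], an$axis2d[1]) + pi / 2 +
    stats::rnorm(1, 0, rule$jitter_deg * pi / 180)
  wall3 <- cos(th) * fr$e1 + sin(th) * fr$e2
  sp <- split_polygon(pts, centre3, wall3, fr)
  if (is.null(sp)) {
    # retry without jitter, then sweep wall angles, before giving up
    th0 <- atan2(an$axis2d[2], an$axis2d[1]) + pi / 2
    for (dth in c(0, pi / 8, -pi / 8, pi / 4, -pi / 4, 3 * pi / 8, -3 * pi / 8,
                  pi / 2)) {
      wall3 <- cos(th0 + dth) * fr$e1 + sin(th0 + dth) * fr$e2
      sp <- split_polygon(pts, centre3, wall3, fr)
      if (!is.null(sp)) break
    }
    if (is.null(sp)) stop("failed to split cell ", layer$cells$id[i])
  }
  old <- layer$polys[[i]]
  bind_cut <- function(cut) {
    if (!layer$bound) return(NULL)
    # interpolate the mesh binding along the parent edge when both ends lie
    # in the same triangle, otherwise re-locate on the mesh
    i1 <- cut$i; i2 <- if (cut$i == nrow(old)) 1L else cut$i + 1L
    if (old[i1, 1] == old[i2, 1]) {
      cbind(old[i1, 1, drop = FALSE],
            matrix((1 - cut$t) * old[i1, 2:4] + cut$t * old[i2, 2:4], 1))
    } else {
      b <- bind_points_to_mesh(matrix(cut$p, 1), canvas$nodes_top,
                               canvas$triangles, vt, vadj)
      cbind(b$tri, b$bary)
    }
  }
  if (layer$bound) {
    cb1 <- bind_cut(sp$cuts[[1]])
    cb2 <- bind_cut(sp$cuts[[2]])
    p1 <- rbind(cb1, old[sp$rows1, , drop = FALSE], cb2)
    p2 <- rbind(cb2, old[sp$rows2, , drop = FALSE], cb1)
  } else {
    p1 <- sp$poly1
    p2 <- sp$poly2
  }
  id1 <- layer$next_id
  id2 <- layer$next_id + 1L
  layer$next_id <- layer$next_id + 2L
  row <- layer$cells[i, ]
  n0 <- nrow(layer$cells)
  layer$polys[[i]] <- p1
  layer$polys[[n0 + 1L]] <- p2
  layer$cells[i, ] <- data.frame(id = id1, lineage = row$lineage,
                                 clone = row$clone, cdiv = row$cdiv,
                                 parent = row$id)
  layer$cells[n0 + 1L, ] <- data.frame(id = id2, lineage = row$lineage,
                                       clone = row$clone, cdiv = row$cdiv,
                                       parent = row$id)
  nb <- layer$neighbours[[i]]
  layer$neighbours[[i]] <- unique(c(nb, n0 + 1L))
  layer$neighbours[[n0 + 1L]] <- unique(c(nb, i))
  for (j in nb) layer$neighbours[[j]] <- unique(c(layer$neighbours[[j]], n0 + 1L))
  layer
}

#' Mark clone founder cells
#'
#' Marks each cell independently with the given probability; marks are
#' heritable through division, so every marked founder seeds one clone
#' identified by its lineage at induction.
#'
#' @param layer a \code{cell_layer}.
#' @param fraction marking probability in (0, 1).
#' @param seed RNG seed.
#' @return the layer with clone ids set on marked cells.
#' @export
induce_clones <- function(layer, fraction = 0.4, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  rs <- local_seed(seed)
  on.exit(restore_seed(rs), add = TRUE)
  marked <- stats::runif(nrow(layer$cells)) < fraction
  layer$cells$clone <- ifelse(marked, layer$cells$id, NA_integer_)
  layer
}

# construct a static (unbound) cell layer from a list of polygon coordinate
# matrices; used by the synthetic generator and in tests
static_cell_layer <- function(polys, clone = NULL, cdiv = TRUE) {
  n <- length(polys)
  structure(list(
    polys = polys,
    cells = data.frame(id = seq_len(n), lineage = seq_len(n),
                       clone = if (is.null(clone)) NA_integer_ else clone,
                       cdiv = cdiv, parent = NA_integer_),
    neighbours = vector("list", n),
    bound = FALSE,
    next_id = n + 1L
  ), class = "cell_layer")
}
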