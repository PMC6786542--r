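# Triangle-mesh geometry utilities shared by the canvas, solver and
# morphometrics code. All functions are internal; positions are micrometres.

row_norms <- function(m) sqrt(rowSums(m * m))

normalize_rows <- function(m) {
  n <- row_norms(m)
  n[n == 0] <- 1
  m / n
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' @keywords internal
icosahedron <- function() {
  # poles at +/- z, two rings of five; mirror-symmetric about the x-z plane
  zr <- 1 / sqrt(5)
  rr <- 2 / sqrt(5)
  # sinpi/cospi give exact zeros on the 0/180 meridians, keeping the mesh
  # exactly mirror-symmetric about the sagittal (x-z) plane
  upper <- 2 * (0:4) / 5
  lower <- 2 * (0:4) / 5 + 1 / 5
  v <- rbind(c(0, 0, 1),
             cbind(rr * cospi(upper), rr * sinpi(upper), zr),
             cbind(rr * cospi(lower), rr * sinpi(lower), -zr),
             c(0, 0, -1))
  up <- 2:6
  lo <- 7:11
  f <- NULL
  for (i in 0:4) {
    j <- (i + 1) %% 5
    f <- rbind(f,
               c(1, up[i + 1], up[j + 1]),
               c(up[i + 1], lo[i + 1], up[j + 1]),
               c(up[j + 1], lo[i + 1], lo[j + 1]),
               c(lo[i + 1], 12, lo[j + 1]))
  }
  # enforce outward orientation (unit sphere centred at origin)
  ctr <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
  nrm <- cross3(v[f[, 2], ] - v[f[, 1], ], v[f[, 3], ] - v[f[, 1], ])
  flip <- rowSums(nrm * ctr) < 0
  f[flip, c(2, 3)] <- f[flip, c(3, 2)]
  list(vertices = v, triangles = f)
}

#' @keywords internal
subdivide_mesh <- function(v, f, project_sphere = TRUE) {
  nv <- nrow(v)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  ue <- !duplicated(ekey)
  mid_idx <- stats::setNames(nv + seq_len(sum(ue)), ekey[ue])
  mids <- (v[e[ue, 1], ] + v[e[ue, 2], ]) / 2
  if (project_sphere) mids <- normalize_rows(mids)
  v2 <- rbind(v, mids)
  m12 <- mid_idx[paste(pmin(f[, 1], f[, 2]), pmax(f[, 1], f[, 2]))]
  m23 <- mid_idx[paste(pmin(f[, 2], f[, 3]), pmax(f[, 2], f[, 3]))]
  m31 <- mid_idx[paste(pmin(f[, 3], f[, 1]), pmax(f[, 3], f[, 1]))]
  f2 <- rbind(cbind(f[, 1], m12, m31),
              cbind(f[, 2], m23, m12),
              cbind(f[, 3], m31, m23),
              cbind(m12, m23, m31))
  dimnames(f2) <- NULL
  list(vertices = v2, triangles = f2)
}

#' @keywords internal
icosphere <- function(level) {
  m <- icosahedron()
  if (level > 0) {
    for (i in seq_len(level)) m <- subdivide_mesh(m$vertices, m$triangles)
  }
  m
}

tri_areas <- function(v, f) {
  0.5 * row_norms(cross3(v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE],
                         v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]))
}

tri_normals <- function(v, f) {
  normalize_rows(cross3(v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE],
                        v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]))
}

tri_centroids <- function(v, f) {
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
     v[f[, 3], , drop = FALSE]) / 3
}

vertex_normals <- function(v, f) {
  fn <- cross3(v[f[, 2], ] - v[f[, 1], ], v[f[, 3], ] - v[f[, 1], ])  # area-weighted
  acc <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    s <- rowsum(fn, group = f[, k], reorder = FALSE)
    acc[as.integer(rownames(s)), ] <- acc[as.integer(rownames(s)), ] + s
  }
  normalize_rows(acc)
}

mesh_edges <- function(f) {
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

# cotangent stiffness matrix K (psd): u' K u = int |grad u|^2
cotan_stiffness <- function(v, f) {
  i1 <- f[, 1]; i2 <- f[, 2]; i3 <- f[, 3]
  cot_at <- function(a, b, c) {
    u <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
    w <- v[c, , drop = FALSE] - v[a, , drop = FALSE]
    rowSums(u * w) / row_norms(cross3(u, w))
  }
  c1 <- cot_at(i1, i2, i3)  # opposite edge (2,3)
  c2 <- cot_at(i2, i3, i1)  # opposite edge (3,1)
  c3 <- cot_at(i3, i1, i2)  # opposite edge (1,2)
  ii <- c(i2, i3, i3, i1, i1, i2)
  jj <- c(i3, i2, i1, i3, i2, i1)
  xx <- -0.5 * c(c1, c1, c2, c2, c3, c3)
  k <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nrow(v), nrow(v)))
  d <- -Matrix::rowSums(k)
  k + Matrix::Diagonal(nrow(v), d)
}

lumped_mass <- function(v, f) {
  a <- tri_areas(v, f) / 3
  m <- numeric(nrow(v))
  for (k in 1:3) {
    s <- rowsum(a, group = f[, k], reorder = FALSE)
    m[as.integer(rownames(s))] <- m[as.integer(rownames(s))] + s[, 1]
  }
  m
}

# per-triangle surface gradient of a per-vertex scalar field
face_gradients <- function(v, f, u) {
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  n <- cross3(p2 - p1, p3 - p1)
  a2 <- row_norms(n)           # 2 * area
  nh <- n / a2
  g1 <- cross3(nh, p3 - p2) / a2
  g2 <- cross3(nh, p1 - p3) / a2
  g3 <- cross3(nh, p2 - p1) / a2
  g1 * u[f[, 1]] + g2 * u[f[, 2]] + g3 * u[f[, 3]]
}

# Steady reaction-diffusion: (D K + M diag(decay)) p = M * production
solve_reaction_diffusion <- function(k, m, production, decay) {
  a <- k + Matrix::Diagonal(length(m), m * decay)
  as.numeric(Matrix::solve(a, m * production))
}

# --- point location -------------------------------------------------------

nearest_vertices <- function(p, v) {
  p <- matrix(p, ncol = 3)
  out <- integer(nrow(p))
  v2 <- rowSums(v * v)
  chunk <- max(1L, floor(2e6 / nrow(v)))
  for (s in seq(1, nrow(p), by = chunk)) {
    idx <- s:min(s + chunk - 1, nrow(p))
    d2 <- matrix(v2, length(idx), nrow(v), byrow = TRUE) -
      2 * p[idx, , drop = FALSE] %*% t(v)
    out[idx] <- max.col(-d2, ties.method = "first")
  }
  out
}

vertex_tri_map <- function(f, nv) {
  lst <- split(rep(seq_len(nrow(f)), 3), c(f[, 1], f[, 2], f[, 3]))
  out <- vector("list", nv)
  out[as.integer(names(lst))] <- lst
  out
}

vertex_adjacency <- function(f, nv) {
  e <- mesh_edges(f)
  lst <- split(c(e[, 2], e[, 1]), c(e[, 1], e[, 2]))
  out <- vector("list", nv)
  out[as.integer(names(lst))] <- lapply(lst, unique)
  out
}

# closest point on triangle abc to p; returns list(point, bary, dist2)
closest_point_on_tri <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(list(bary = c(1, 0, 0)))
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(list(bary = c(0, 1, 0)))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    t <- d1 / (d1 - d3)
    return(list(bary = c(1 - t, t, 0)))
  }
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(list(bary = c(0, 0, 1)))
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    t <- d2 / (d2 - d6)
    return(list(bary = c(1 - t, 0, t)))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    t <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(list(bary = c(0, 1 - t, t)))
  }
  denom <- 1 / (va + vb + vc)
  u <- vb * denom; w <- vc * denom
  list(bary = c(1 - u - w, u, w))
}

# Bind free points to a mesh: per point, the containing/closest triangle and
# barycentric coordinates, searched over triangles near the nearest vertex.
bind_points_to_mesh <- function(p, v, f, vt = NULL, vadj = NULL) {
  p <- matrix(p, ncol = 3)
  if (is.null(vt)) vt <- vertex_tri_map(f, nrow(v))
  if (is.null(vadj)) vadj <- vertex_adjacency(f, nrow(v))
  nv_idx <- nearest_vertices(p, v)
  tri <- integer(nrow(p))
  bary <- matrix(0, nrow(p), 3)
  for (i in seq_len(nrow(p))) {
    ring <- unique(c(nv_idx[i], vadj[[nv_idx[i]]]))
    cand <- unique(unlist(vt[ring]))
    best <- Inf; bt <- cand[1]; bb <- c(1, 0, 0)
    pi_ <- p[i, ]
    for (t in cand) {
      cp <- closest_point_on_tri(pi_, v[f[t, 1], ], v[f[t, 2], ], v[f[t, 3], ])
      pt <- cp$bary[1] * v[f[t, 1], ] + cp$bary[2] * v[f[t, 2], ] +
        cp$bary[3] * v[f[t, 3], ]
      d2 <- sum((pi_ - pt)^2)
      if (d2 < best) { best <- d2; bt <- t; bb <- cp$bary }
    }
    tri[i] <- bt
    bary[i, ] <- bb
  }
  list(tri = tri, bary = bary)
}

bary_positions <- function(binding, v, f) {
  tri <- binding$tri
  binding$bary[, 1] * v[f[tri, 1], , drop = FALSE] +
    binding$bary[, 2] * v[f[tri, 2], , drop = FALSE] +
    binding$bary[, 3] * v[f[tri, 3], , drop = FALSE]
}

# --- plane section --------------------------------------------------------

# Intersect a triangle mesh with a plane; returns closed polyline loops.
# Each loop carries the points, and per point the mesh edge (vertex index
# pair) and interpolation parameter, so the section is a material object that
# can be re-evaluated on any later deformation of the same mesh.
mesh_plane_cut <- function(v, f, point, normal) {
  normal <- normal / sqrt(sum(normal^2))
  d <- as.numeric(v %*% normal) - sum(point * normal)
  segs <- list(); ekeys <- list(); einfo <- list()
  for (t in seq_len(nrow(f))) {
    vs <- f[t, ]
    dv <- d[vs]
    if (all(dv > 0) || all(dv < 0)) next
    pts <- NULL; keys <- NULL; inf <- NULL
    for (k in 1:3) {
      i <- vs[k]; j <- vs[k %% 3 + 1]
      if ((d[i] > 0) != (d[j] > 0)) {
        tt <- d[i] / (d[i] - d[j])
        pts <- rbind(pts, v[i, ] + tt * (v[j, ] - v[i, ]))
        keys <- c(keys, paste(min(i, j), max(i, j)))
        inf <- rbind(inf, if (i < j) c(i, j, tt) else c(j, i, 1 - tt))
      }
    }
    if (is.null(pts) || nrow(pts) != 2) next
    segs[[length(segs) + 1]] <- pts
    ekeys[[length(ekeys) + 1]] <- keys
    einfo[[length(einfo) + 1]] <- inf
  }
  if (!length(segs)) stop("plane does not intersect the mesh")
  # chain segments into loops via shared edge keys
  nseg <- length(segs)
  ends <- do.call(rbind, lapply(ekeys, function(k) k))
  used <- rep(FALSE, nseg)
  by_key <- split(rep(seq_len(nseg), 2), c(ends[, 1], ends[, 2]))
  loops <- list()
  for (s0 in seq_len(nseg)) {
    if (used[s0]) next
    pts <- segs[[s0]]
    keys <- ekeys[[s0]]
    einf <- einfo[[s0]]
    cur_key <- keys[2]
    used[s0] <- TRUE
    repeat {
      nxt <- setdiff(by_key[[cur_key]], which(used))
      if (!length(nxt)) break
      cur <- nxt[1]
      used[cur] <- TRUE
      k2 <- ekeys[[cur]]
      pick <- if (k2[1] == cur_key) 2L else 1L
      pts <- rbind(pts, segs[[cur]][pick, ])
      keys <- c(keys, k2[pick])
      einf <- rbind(einf, einfo[[cur]][pick, ])
      cur_key <- k2[pick]
    }
    loops[[length(loops) + 1]] <- list(points = pts, edges = keys,
                                       edge_info = einf)
  }
  loops
}

# re-evaluate a material section (edge_info from mesh_plane_cut) on a
# deformed canvas sharing the mesh connectivity
material_section_points <- function(edge_info, v) {
  (1 - edge_info[, 3]) * v[edge_info[, 1], , drop = FALSE] +
    edge_info[, 3] * v[edge_info[, 2], , drop = FALSE]
}

polyline_length <- function(pts, closed = TRUE) {
  if (closed) pts <- rbind(pts, pts[1, ])
  sum(row_norms(pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE]))
}

# breadth-first distance over an adjacency list from a set of sources
bfs_distance <- function(adj, sources, max_dist = Inf) {
  n <- length(adj)
  d <- rep(Inf, n)
  d[sources] <- 0
  frontier <- sources
  depth <- 0
  while (length(frontier) && depth < max_dist) {
    depth <- depth + 1
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[is.finite(nxt) & d[nxt] == Inf]
    if (!length(nxt)) break
    d[nxt] <- depth
    frontier <- nxt
  }
  d
}
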