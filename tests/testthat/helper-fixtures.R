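# Shared fixtures, built in code and cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# small dressed canvas (level 2 by default, ~320 triangles)
small_canvas <- function(level = 2, polarity = FALSE) {
  cached(paste0("canvas", level, polarity), {
    setup_trap_factors(build_sphere_canvas(100, 30, level),
                       with_polarity = polarity)
  })
}

# mirror map: index of the y -> -y partner of every vertex
mirror_map <- function(canvas) {
  v <- canvas$vertices
  key <- paste(round(v[, 1], 6), round(v[, 2], 6), round(v[, 3], 6))
  match(paste(round(v[, 1], 6), round(-v[, 2], 6), round(v[, 3], 6)), key)
}

# flat rectangular patch discretised as a wedge shell, for conflict-free
# growth oracles: nx x ny quads split into triangles, plane z = 0
make_patch_canvas <- function(nx = 6, ny = 6, size = 10, thickness = 1) {
  xs <- seq(0, size, length.out = nx + 1)
  ys <- seq(0, size, length.out = ny + 1)
  v <- as.matrix(expand.grid(x = xs, y = ys))
  v <- cbind(v, 0)
  idx <- function(i, j) (j - 1) * (nx + 1) + i
  f <- NULL
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      f <- rbind(f,
                 c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
                 c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
    }
  }
  structure(list(
    vertices = v, triangles = f,
    nodes_top = v + matrix(c(0, 0, thickness / 2), nrow(v), 3, byrow = TRUE),
    nodes_bot = v - matrix(c(0, 0, thickness / 2), nrow(v), 3, byrow = TRUE),
    thickness = rep(thickness, nrow(v)),
    factors = list(), pol = NULL, polarity = NULL, polarity_ok = NULL,
    landmarks = c(stalk_pole = 1L), time = 0,
    config = list(diameter = size, wall_thickness = thickness)
  ), class = "canvas")
}

# uniform specified growth field on any canvas
uniform_growth <- function(canvas, k_par, k_per = k_par, k_nor = k_par,
                           direction = NULL) {
  nt <- nrow(canvas$triangles)
  d <- if (is.null(direction)) {
    trapmorph:::default_tangent(canvas)
  } else matrix(direction, nt, 3, byrow = TRUE)
  structure(list(k_par = rep(k_par, nt), k_per = rep(k_per, nt),
                 k_nor = rep(k_nor, nt),
                 anisotropy = rep((k_par - k_per) / (k_par + k_per), nt),
                 direction = d),
            class = "specified_growth")
}

# edge lengths of a canvas mid-surface
edge_lengths <- function(canvas) {
  e <- trapmorph:::mesh_edges(canvas$triangles)
  trapmorph:::row_norms(canvas$vertices[e[, 1], ] - canvas$vertices[e[, 2], ])
}

# run a preset-like model on a small canvas (cached)
small_run <- function(preset, level = 2, dt = 2, t_end = 252, cells = FALSE,
                      seed = 11) {
  cached(paste("run", preset, level, dt, t_end, cells, seed), {
    p <- krn_preset(preset)
    cv <- setup_trap_factors(build_sphere_canvas(100, 30, level),
                             with_polarity = p$model_kind != "areal")
    lay <- NULL
    if (cells) {
      lay <- tile_cells(cv, 50, seed = seed)
      lay <- induce_clones(lay, 0.4, seed = seed)
    }
    run_simulation(cv, p, cells = lay, t_start = 96, t_end = t_end,
                   config = solver_config(dt = dt),
                   rule = division_rule(seed = seed))
  })
}

# dense rasterisation oracle for polygon second moments (independent of the
# closed-form implementation)
raster_moments <- function(xy, n = 400) {
  gx <- seq(min(xy[, 1]), max(xy[, 1]), length.out = n)
  gy <- seq(min(xy[, 2]), max(xy[, 2]), length.out = n)
  cellw <- diff(gx[1:2]) * diff(gy[1:2])
  pts <- as.matrix(expand.grid(gx, gy))
  inside <- apply(pts, 1, function(p) trapmorph:::point_in_poly(p, xy))
  pin <- pts[inside, , drop = FALSE]
  ctr <- colMeans(pin)
  rel <- sweep(pin, 2, ctr)
  m <- crossprod(rel) * cellw
  list(m = m, area = nrow(pin) * cellw, centroid = ctr)
}

# numeric ellipse perimeter (independent oracle)
ellipse_perimeter <- function(a, b, n = 20000) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-1]
  dth <- 2 * pi / n
  sum(sqrt((a * sin(th))^2 + (b * cos(th))^2)) * dth
}
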