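# Morphometrics: exponential-growth strain-rate fitting, developmental
# staging from trap length, circumference extraction from canvas sections,
# and clone anisotropy decomposition. The same operations serve simulated
# trajectories and (synthetic or measured) data.

#' Construct a growth series
#'
#' Length-versus-time observations for one or more traps.
#' @param time_d observation times in days.
#' @param length_um trap lengths in micrometres (> 0).
#' @param subject subject identifier (recycled).
#' @param fixed logical: fixed (dehydrated/cleared) specimens, which shrink
#'   and receive the staging shrinkage correction (recycled).
#' @return data.frame of class \code{growth_series}.
#' @export
growth_series <- function(time_d, length_um, subject = 1L, fixed = FALSE) {
  if (any(length_um <= 0)) stop("lengths must be positive")
  out <- data.frame(subject = subject, time_d = time_d, length_um = length_um,
                    fixed = fixed)
  for (s in split(out, out$subject))
    if (is.unsorted(s$time_d)) stop("times must be non-decreasing per subject")
  class(out) <- c("growth_series", "data.frame")
  out
}

#' Fit an exponential strain rate
#'
#' Ordinary least squares of log length on time in hours, pooled over
#' subjects: the slope is the relative growth rate (strain rate) in h^-1,
#' reported with twice its standard error and the fit R-squared.
#'
#' @param series a \code{\link{growth_series}} (>= 3 observations).
#' @return list with \code{rate} (h^-1), \code{two_se}, \code{r_squared} and
#'   the underlying \code{lm} fit.
#' @export
fit_strain_rate <- function(series) {
  if (nrow(series) < 3) stop("need at least 3 observations")
  hours <- series$time_d * 24
  fit <- stats::lm(log(series$length_um) ~ hours)
  sm <- summary(fit)
  list(rate = unname(stats::coef(fit)[2]),
       two_se = unname(2 * sm$coefficients[2, 2]),
       r_squared = sm$r.squared,
       fit = fit)
}

#' Staging parameters
#'
#' Constants of the exponential staging law: traps are placed on the mean
#' growth trend line extrapolated back to the initiation length.
#' @param initiation_length length at initiation, micrometres (default 10).
#' @param reference_rate mean relative growth rate, h^-1 (default 0.018).
#' @param shrinkage shrinkage of fixed specimens as a proportion
#'   (default 0.0578); fixed trap lengths are increased by this fraction
#'   before staging.
#' @return object of class \code{staging_params}.
#' @export
staging_params <- function(initiation_length = 10, reference_rate = 0.018,
                           shrinkage = 0.0578) {
  if (initiation_length <= 0 || reference_rate <= 0 || shrinkage < 0)
    stop("staging parameters must be positive")
  structure(list(initiation_length = initiation_length,
                 reference_rate = reference_rate, shrinkage = shrinkage),
            class = "staging_params")
}

#' Developmental stage from trap length
#'
#' Inverts the exponential growth law: \code{DAI = ln(L' / L0) / (rate * 24)}
#' with \code{L' = L * (1 + shrinkage)} for fixed specimens and \code{L}
#' unchanged for live ones. A 139 um live trap stages to 6.1 DAI; a 55 um
#' trap to 3.9 DAI (4 DAI to the nearest day).
#'
#' @param length trap length, micrometres.
#' @param fixed logical; apply the shrinkage correction.
#' @param params a \code{\link{staging_params}}.
#' @return stage in days after initiation (unrounded).
#' @export
stage_from_length <- function(length, fixed = FALSE, params = staging_params()) {
  lc <- length * ifelse(fixed, 1 + params$shrinkage, 1)
  if (any(lc < params$initiation_length))
    stop("length below the initiation length")
  log(lc / params$initiation_length) / (params$reference_rate * 24)
}

#' Extract a section circumference from a canvas
#'
#' Intersects the canvas mid-surface with one of the three anatomical
#' section planes and measures the circumference polyline. Planes are
#' anchored to landmark material points: the sagittal plane is the mirror
#' plane through the stalk pole and mouth centre; the frontal plane passes
#' through the stalk pole normal to the sagittal-transverse line; the
#' transverse plane passes through the section centre. For the sagittal
#' section the circumference is partitioned at the tracked landmarks into
#' ventral midline, dorsal midline and mouth arcs, and the stalk arc is
#' reported where the stalk factor exceeds 0.5.
#'
#' @param canvas a \code{canvas}.
#' @param plane "sagittal", "frontal" or "transverse".
#' @return list with \code{length} (um), the \code{polyline}, and for the
#'   sagittal plane a named \code{subdomains} vector (ventral_midline,
#'   dorsal_midline, mouth, stalk_arc).
#' @export
extract_circumference <- function(canvas,
                                  plane = c("sagittal", "frontal", "transverse")) {
  plane <- match.arg(plane)
  v <- canvas$vertices
  lm <- canvas$landmarks
  anchor <- switch(plane,
                   sagittal = v[lm[["stalk_pole"]], ],
                   frontal = v[lm[["stalk_pole"]], ],
                   transverse = colMeans(v))
  normal <- switch(plane,
                   sagittal = c(0, 1, 0),
                   frontal = c(1, 0, 0),
                   transverse = c(0, 0, 1))
  if (plane == "frontal") {
    # through the tallest central region: anchor at the mesh centre instead
    anchor <- colMeans(v)
  }
  loops <- mesh_plane_cut(v, canvas$triangles, anchor, normal)
  # keep the longest loop (the outer circumference)
  lens <- vapply(loops, function(l) polyline_length(l$points), numeric(1))
  loop <- loops[[which.max(lens)]]
  out <- list(length = max(lens), polyline = loop$points, plane = plane)
  if (plane == "sagittal") {
    pts <- loop$points
    seg_len <- row_norms(rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE]) - pts)
    near_idx <- function(name)
      which.min(rowSums(sweep(pts, 2, v[lm[[name]], ])^2))
    iv <- near_idx("ventral_lip")
    id <- near_idx("dorsal_lip")
    is_ <- near_idx("stalk_indentation")
    np <- nrow(pts)
    arc <- function(from, to) {
      # walk forward from `from` to `to`; also compute the complement
      if (from <= to) idx <- from:(to - 1) else idx <- c(from:np, seq_len(to - 1))
      sum(seg_len[idx])
    }
    # orientation: choose the walking direction so the ventral arc
    # (ventral lip -> stalk indentation) does not contain the dorsal lip
    fwd_contains <- function(from, to, probe) {
      idx <- if (from <= to) from:to else c(from:np, 1:to)
      probe %in% idx
    }
    ven <- if (!fwd_contains(iv, is_, id)) arc(iv, is_) else arc(is_, iv)
    dor <- if (!fwd_contains(id, is_, iv)) arc(id, is_) else arc(is_, id)
    mouth <- max(out$length - ven - dor, 0)
    # stalk arc: portion of the loop inside the stalk factor region
    stk_arc <- if (!is.null(canvas$factors$stk)) {
      lvl <- pmin(canvas$factors$stk, 1)[nearest_vertices(pts, v)]
      sum(seg_len[lvl >= 0.5])
    } else NA_real_
    out$subdomains <- c(ventral_midline = ven, dorsal_midline = dor,
                        mouth = mouth, stalk_arc = stk_arc)
  }
  out
}

#' Ingest measured circumference lengths
#'
#' Deep traps cannot always be imaged through their full depth, in which case
#' half the circumference is measured and doubled. This helper applies that
#' convention when ingesting measured data; simulated circumferences never
#' need it.
#' @param length measured length(s), micrometres.
#' @param halved logical (recycled): TRUE where half the circumference was
#'   measured.
#' @return full circumference lengths.
#' @export
measured_circumference <- function(length, halved = FALSE) {
  ifelse(halved, 2 * length, length)
}

#' Material midline measurements across a trajectory
#'
#' Computes the sagittal circumference and its ventral/dorsal midline arcs as
#' material curves: the section polyline is cut on the first snapshot and its
#' edge-bound points are re-evaluated on the last (or a chosen) snapshot, so
#' the measures follow the tissue even if the deformed shape drifts slightly
#' off the initial mirror plane. Returns the circumference and arc strain
#' rates over the trajectory and the straightness of the final ventral
#' midline (maximum deviation of the arc from its chord, normalised by the
#' chord length; lower is straighter).
#'
#' @param traj a \code{trajectory}.
#' @param snapshot index of the evaluation snapshot (default: last).
#' @return list with \code{sagittal_rate}, \code{ventral_rate},
#'   \code{dorsal_rate} (h^-1), \code{ventral_straightness},
#'   \code{ventral_curve} (final arc points) and initial/final lengths.
#' @export
trap_midline_metrics <- function(traj, snapshot = length(traj$snapshots)) {
  cv0 <- traj$snapshots[[1]]
  cvf <- traj$snapshots[[snapshot]]
  dt <- cvf$time - cv0$time
  v0 <- cv0$vertices
  loops <- mesh_plane_cut(v0, cv0$triangles, v0[cv0$landmarks[["stalk_pole"]], ],
                          c(0, 1, 0))
  lens <- vapply(loops, function(l) polyline_length(l$points), numeric(1))
  loop <- loops[[which.max(lens)]]
  np <- nrow(loop$points)
  near <- function(name) which.min(rowSums(
    sweep(loop$points, 2, v0[cv0$landmarks[[name]], ])^2))
  iv <- near("ventral_lip"); id <- near("dorsal_lip")
  is_ <- near("stalk_indentation")
  fwd <- function(from, to) if (from <= to) from:to else c(from:np, 1:to)
  ven_idx <- if (!(id %in% fwd(iv, is_))) fwd(iv, is_) else fwd(is_, iv)
  dor_idx <- if (!(iv %in% fwd(id, is_))) fwd(id, is_) else fwd(is_, id)
  p0 <- loop$points
  pf <- material_section_points(loop$edge_info, cvf$vertices)
  open_len <- function(p) sum(row_norms(p[-1, , drop = FALSE] -
                                          p[-nrow(p), , drop = FALSE]))
  arc0v <- open_len(p0[ven_idx, , drop = FALSE])
  arcfv <- open_len(pf[ven_idx, , drop = FALSE])
  arc0d <- open_len(p0[dor_idx, , drop = FALSE])
  arcfd <- open_len(pf[dor_idx, , drop = FALSE])
  c0 <- polyline_length(p0); cf <- polyline_length(pf)
  arc <- pf[ven_idx, , drop = FALSE]
  chord <- arc[nrow(arc), ] - arc[1, ]
  cl <- sqrt(sum(chord^2))
  u <- chord / cl
  rel <- sweep(arc, 2, arc[1, ])
  perp <- rel - outer(as.numeric(rel %*% u), u)
  list(sagittal_rate = log(cf / c0) / dt,
       ventral_rate = log(arcfv / arc0v) / dt,
       dorsal_rate = log(arcfd / arc0d) / dt,
       ventral_straightness = max(row_norms(perp)) / cl,
       ventral_curve = arc,
       lengths = c(sagittal0 = c0, sagittal1 = cf, ventral0 = arc0v,
                   ventral1 = arcfv, dorsal0 = arc0d, dorsal1 = arcfd))
}

#' Clone anisotropy metrics
#'
#' For every clone (connected set of cells sharing a clone mark) computes the
#' paper's three anisotropy measures: clone anisotropy (major / minor axis
#' length of the clone patch, axes from the second-moment eigenvectors of the
#' patch), cell-number anisotropy (number of distinct cells intersected by
#' the major axis divided by the number intersected by the minor axis) and
#' cell-shape anisotropy (their quotient, an exact identity). Clones are
#' assigned to the ventral midline, dorsal midline or lamina region by
#' cell-graph distance from the sagittal midline (within
#' \code{midline_band_cells} cells).
#'
#' @param layer a \code{cell_layer} with clones induced.
#' @param canvas the bound canvas (NULL for static layers; regions are then
#'   not assigned).
#' @param midline_band_cells maximum distance in cells from the midline for
#'   a clone centre to count as a midline clone (default 5).
#' @param min_cells,max_cells clone size selection (defaults 3 and 30, the
#'   selection used for measured clones).
#' @return data.frame with one row per connected clone: sizes, axis lengths,
#'   the three anisotropies, the major-axis direction and region label.
#' @export
clone_metrics <- function(layer, canvas = NULL, midline_band_cells = 5,
                          min_cells = 3, max_cells = 30) {
  cl <- layer$cells$clone
  if (all(is.na(cl))) stop("no clones present")
  adj <- geometric_adjacency(layer, canvas)
  groups <- split(seq_len(nrow(layer$cells)), cl)
  # connected components within each clone id
  comps <- list()
  for (g in groups) {
    remaining <- g
    while (length(remaining)) {
      comp <- remaining[1]
      frontier <- comp
      while (length(frontier)) {
        nxt <- intersect(unique(unlist(adj[frontier])), remaining)
        nxt <- setdiff(nxt, comp)
        comp <- c(comp, nxt)
        frontier <- nxt
      }
      comps[[length(comps) + 1]] <- comp
      if (length(comp) < length(remaining) && length(remaining) > length(comp))
        message("clone ", cl[g[1]], " has disconnected pieces; treated separately")
      remaining <- setdiff(remaining, comp)
    }
  }
  comps <- Filter(function(x) length(x) >= min_cells && length(x) <= max_cells,
                  comps)
  if (!length(comps)) return(data.frame())

  region_info <- if (!is.null(canvas) && layer$bound)
    midline_cell_classes(layer, canvas, adj) else NULL

  rows <- lapply(comps, function(comp) {
    polys <- lapply(comp, function(i) {
      p <- poly_coords(layer, canvas, i)
      p[dedup_mask(p), , drop = FALSE]
    })
    ok <- vapply(polys, function(p) nrow(p) >= 3 && all(is.finite(p)),
                 logical(1))
    polys <- polys[ok]
    comp <- comp[ok]
    if (length(comp) < 1) return(NULL)
    allpts <- do.call(rbind, polys)
    fr <- poly_frame_patch(allpts)
    ctr <- colMeans(allpts)
    proj <- function(pts) cbind((sweep(pts, 2, ctr)) %*% fr$e1,
                                (sweep(pts, 2, ctr)) %*% fr$e2)
    # combined second moment about the patch centroid
    m <- matrix(0, 2, 2); atot <- 0
    for (p in polys) {
      xy <- proj(p)
      sm <- polygon_second_moments(xy)
      a <- abs(sm$area)
      s <- sign(sm$area)  # orientation-corrected central moment
      shift <- sm$centroid
      m <- m + s * sm$m + a * (shift %o% shift)  # parallel-axis to patch centroid
      atot <- atot + a
    }
    if (!all(is.finite(m)) || atot <= 0) return(NULL)
    an <- moment_anisotropy(m)
    e1 <- an$axis2d
    e2 <- c(-e1[2], e1[1])
    xyall <- proj(allpts)
    p1 <- xyall %*% e1
    p2 <- xyall %*% e2
    major_len <- diff(range(p1))
    minor_len <- diff(range(p2))
    cellxy <- lapply(polys, proj)
    # nudge each axis line off exact shared walls so the count is stable
    cn_major <- count_cells_on_axis(cellxy, comp, e1, range(p1),
                                    offset = e2 * 1e-6 * minor_len)
    cn_minor <- count_cells_on_axis(cellxy, comp, e2, range(p2),
                                    offset = e1 * 1e-6 * major_len)
    clone_a <- major_len / minor_len
    cn_a <- cn_major / cn_minor
    region <- if (is.null(region_info)) NA_character_ else {
      ctr_cell <- comp[which.min(vapply(comp, function(i)
        sum((poly_centroid3d(poly_coords(layer, canvas, i)) - ctr)^2),
        numeric(1)))]
      dmid <- region_info$dist[ctr_cell]
      if (is.finite(dmid) && dmid <= midline_band_cells)
        region_info$type[region_info$nearest[ctr_cell]]
      else "lamina"
    }
    axis3d <- e1[1] * fr$e1 + e1[2] * fr$e2
    data.frame(clone = cl[comp[1]], n_cells = length(comp), area = atot,
               major_len = major_len, minor_len = minor_len,
               clone_anisotropy = clone_a,
               cells_major = cn_major, cells_minor = cn_minor,
               cell_number_anisotropy = cn_a,
               cell_shape_anisotropy = clone_a / cn_a,
               axis_x = axis3d[1], axis_y = axis3d[2], axis_z = axis3d[3],
               region = region)
  })
  do.call(rbind, rows)
}

# tangent frame for a multi-polygon patch (mean vector-area normal)
poly_frame_patch <- function(pts) {
  ctr <- colMeans(pts)
  rel <- sweep(pts, 2, ctr)
  sv <- svd(rel)
  n <- sv$v[, 3]
  e1 <- sv$v[, 1]
  e2 <- crossprod_vec(n, e1)
  list(n = n, e1 = e1, e2 = e2)
}

# number of distinct cells whose polygon intersects the axis segment; sampled
# along the segment, points on shared walls resolved to the lowest cell index
count_cells_on_axis <- function(cellxy, ids, dir, extent, n_samples = 201,
                                offset = c(0, 0)) {
  ts <- seq(extent[1] + 1e-9, extent[2] - 1e-9, length.out = n_samples)
  hit <- integer(0)
  for (t in ts) {
    p <- t * dir + offset
    found <- 0L
    found_near <- 1L
    best_d <- Inf
    for (k in seq_along(cellxy)) {
      xy <- cellxy[[k]]
      if (point_in_poly(p, xy)) { found <- k; break }
      d <- min((xy[, 1] - p[1])^2 + (xy[, 2] - p[2])^2)
      if (d < best_d) { best_d <- d; found_near <- k }
    }
    if (found == 0L) found <- found_near
    hit <- c(hit, found)
  }
  length(unique(hit))
}

point_in_poly <- function(p, xy) {
  n <- nrow(xy)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((xy[i, 2] > p[2]) != (xy[j, 2] > p[2]) &&
        p[1] < (xy[j, 1] - xy[i, 1]) * (p[2] - xy[i, 2]) /
          (xy[j, 2] - xy[i, 2]) + xy[i, 1])
      inside <- !inside
    j <- i
  }
  inside
}

# adjacency from shared polygon vertex positions (robust to divisions, which
# make the stored neighbour lists over-connected)
geometric_adjacency <- function(layer, canvas) {
  n <- nrow(layer$cells)
  keys <- vector("list", n)
  for (i in seq_len(n)) {
    p <- poly_coords(layer, canvas, i)
    keys[[i]] <- paste(round(p[, 1], 5), round(p[, 2], 5), round(p[, 3], 5))
  }
  df <- data.frame(key = unlist(keys),
                   cell = rep(seq_len(n), vapply(keys, length, integer(1))))
  adj <- vector("list", n)
  for (grp in split(df$cell, df$key)) {
    u <- unique(grp)
    if (length(u) > 1)
      for (c1 in u) adj[[c1]] <- c(adj[[c1]], setdiff(u, c1))
  }
  lapply(adj, unique)
}

# classify midline cells (on the material MID domain) as ventral or dorsal
# and return per-cell graph distances to the midline; the MID factor is used
# rather than the current sagittal plane because the factor is material and
# stays on the midline even if the deformed shape drifts slightly off-plane
midline_cell_classes <- function(layer, canvas, adj = NULL) {
  if (is.null(adj)) adj <- geometric_adjacency(layer, canvas)
  n <- nrow(layer$cells)
  ctrs <- cell_centroids(layer, canvas)
  on_mid <- factor_at_points(canvas, "mid", ctrs) >= 0.5
  ven <- factor_at_points(canvas, "ven", ctrs) >= 0.5
  stk <- factor_at_points(canvas, "stk", ctrs) >= 0.5
  mid <- which(on_mid & !stk)
  type <- ifelse(ven, "ventral_midline", "dorsal_midline")
  d <- bfs_distance(adj, mid)
  # nearest midline cell per cell (approximate: BFS parent chain not stored;
  # use the closest midline cell centroid)
  ctrs <- cell_centroids(layer, canvas)
  nearest <- integer(n)
  if (length(mid)) {
    for (i in seq_len(n)) {
      dm <- colSums((t(ctrs[mid, , drop = FALSE]) - ctrs[i, ])^2)
      nearest[i] <- mid[which.min(dm)]
    }
  }
  list(dist = d, type = type, nearest = nearest)
}

#' Per-region clone summaries
#'
#' Arithmetic mean and standard error of the three clone anisotropy measures
#' per region (no hypothesis testing).
#' @param metrics output of \code{\link{clone_metrics}}.
#' @return data.frame with one row per region and measure.
#' @export
group_summary <- function(metrics) {
  if (!nrow(metrics)) stop("no clones to summarise")
  regions <- split(metrics, metrics$region)
  empty <- setdiff(c("ventral_midline", "dorsal_midline", "lamina"),
                   names(regions))
  if (length(empty))
    warning("regions without clones omitted: ", paste(empty, collapse = ", "))
  out <- lapply(names(regions), function(r) {
    m <- regions[[r]]
    vals <- c(clone = "clone_anisotropy", cell_number = "cell_number_anisotropy",
              cell_shape = "cell_shape_anisotropy")
    data.frame(region = r, measure = names(vals),
               mean = vapply(vals, function(v) mean(m[[v]]), numeric(1)),
               se = vapply(vals, function(v)
                 stats::sd(m[[v]]) / sqrt(nrow(m)), numeric(1)),
               n = nrow(m), row.names = NULL)
  })
  do.call(rbind, out)
}
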