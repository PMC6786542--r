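# The canvas: a closed triangulated tissue sheet with thickness, regional
# factor fields, a polariser field and the derived polarity direction field.
#
# Coordinate convention: stalk pole at -z, mouth on the +x side, the sagittal
# (mirror) plane is x-z. Lengths in micrometres, times in hours after
# initiation.

#' Build the initial spherical canvas
#'
#' Constructs the hollow-sphere starting shape of the trap models: an
#' icosphere mid-surface of the given diameter carrying a uniform wall
#' thickness, discretised for the growth solver as two bound node sheets
#' (inner and outer surface) at half a thickness along the vertex normals.
#' Named landmark vertices (stalk pole, stalk indentation, ventral and dorsal
#' lips, mouth centre) are placed on the ventral meridian and tracked as
#' material points thereafter.
#'
#' @param diameter mid-surface sphere diameter, micrometres (default 100).
#' @param wall_thickness uniform wall thickness, micrometres (default 30).
#' @param subdivision_level icosphere subdivision level (>= 2); level 4 gives
#'   5120 triangles.
#' @param mouth_angle angular position of the mouth centre, degrees from the
#'   stalk pole along the ventral (+x) meridian (default 70).
#' @param mouth_extent angular radius of the mouth disc, degrees (default 15).
#' @param stalk_extent angular radius of the stalk cap, degrees (default 15).
#' @return an object of class \code{canvas}.
#' @examples
#' cv <- build_sphere_canvas(100, 30, 2)
#' canvas_area(cv)
#' @export
build_sphere_canvas <- function(diameter = 100, wall_thickness = 30,
                                subdivision_level = 4, mouth_angle = 70,
                                mouth_extent = 15, stalk_extent = 15) {
  if (!is.finite(diameter) || diameter <= 0 ||
      !is.finite(wall_thickness) || wall_thickness <= 0)
    stop("invalid parameter: diameter and wall_thickness must be positive")
  if (diameter <= 2 * wall_thickness)
    stop("invalid parameter: diameter must exceed twice the wall thickness")
  if (subdivision_level < 2) stop("invalid parameter: subdivision_level must be >= 2")

  radius <- diameter / 2
  m <- icosphere(subdivision_level)
  # snap the sagittal plane exactly: roundoff-level y breaks the mirror
  # symmetry of the sign-based midline band tests
  m$vertices[abs(m$vertices[, 2]) < 1e-12, 2] <- 0
  v <- m$vertices * radius
  f <- m$triangles
  vn <- m$vertices  # unit radial = vertex normal on a sphere

  deg <- pi / 180
  lm_dir <- function(theta_deg) {
    # polar angle from the stalk pole (-z), along the +x meridian
    th <- theta_deg * deg
    c(sin(th), 0, -cos(th))
  }
  lm <- c(
    stalk_pole        = nearest_vertices(radius * lm_dir(0), v),
    stalk_indentation = nearest_vertices(radius * lm_dir(stalk_extent), v),
    ventral_lip       = nearest_vertices(radius * lm_dir(mouth_angle - mouth_extent), v),
    mouth_centre      = nearest_vertices(radius * lm_dir(mouth_angle), v),
    dorsal_lip        = nearest_vertices(radius * lm_dir(mouth_angle + mouth_extent), v)
  )

  structure(list(
    vertices = v,
    triangles = f,
    nodes_top = v + (wall_thickness / 2) * vn,
    nodes_bot = v - (wall_thickness / 2) * vn,
    thickness = rep(wall_thickness, nrow(v)),
    factors = list(),
    pol = NULL,
    polarity = NULL,
    polarity_ok = NULL,
    landmarks = lm,
    time = 96,
    config = list(diameter = diameter, wall_thickness = wall_thickness,
                  subdivision_level = subdivision_level,
                  mouth_angle = mouth_angle, mouth_extent = mouth_extent,
                  stalk_extent = stalk_extent)
  ), class = "canvas")
}

#' @export
print.canvas <- function(x, ...) {
  cat("canvas:", nrow(x$vertices), "vertices,", nrow(x$triangles),
      "triangles, t =", x$time, "h\n")
  cat("  mid-surface area:", format(canvas_area(x), digits = 6), "um^2;",
      "mean thickness:", format(mean(x$thickness), digits = 4), "um\n")
  if (length(x$factors))
    cat("  factors:", paste(names(x$factors), collapse = ", "), "\n")
  if (!is.null(x$polarity))
    cat("  polarity derived on", sum(x$polarity_ok), "/", nrow(x$triangles),
        "triangles\n")
  invisible(x)
}

#' Mid-surface area of a canvas
#' @param canvas a \code{canvas}.
#' @return total mid-surface area in square micrometres.
#' @export
canvas_area <- function(canvas) sum(tri_areas(canvas$vertices, canvas$triangles))

#' Specify a regional factor
#'
#' Describes where a regional factor (MID, STK, VEN, mouth) is seeded on the
#' initial canvas and how far it spreads. Graded factors are realised as the
#' steady state of diffusion from the seed region with a fixed turnover,
#' giving a profile that is 1 on the seed and decays over the spread length
#' scale; they are then fixed to the canvas and deform with it.
#'
#' @param name one of "mid", "stk", "ven", "mouth".
#' @param region seed geometry: "midline" (sagittal great circle),
#'   "stalk" (polar cap), "ventral" (stalk-to-mouth midline arc) or
#'   "mouth" (disc at the mouth centre). Defaults to the canonical region for
#'   \code{name}.
#' @param extent angular extent of the seed in degrees, in (0, 180); used by
#'   cap/disc/arc regions (defaults from the canvas configuration).
#' @param spread spread length scale in micrometres (> 0).
#' @param hard if TRUE the factor is a 0/1 indicator of the seed region.
#' @return an object of class \code{factor_spec}.
#' @export
factor_spec <- function(name, region = NULL, extent = NULL, spread = 15,
                        hard = FALSE) {
  region <- if (is.null(region)) {
    switch(name, mid = "midline", stk = "stalk", ven = "ventral",
           mouth = "mouth", stop("unknown factor name: ", name))
  } else region
  if (!region %in% c("midline", "stalk", "ventral", "mouth"))
    stop("unknown region name: ", region)
  if (!is.null(extent) && (extent <= 0 || extent >= 180))
    stop("extent must be in (0, 180) degrees")
  if (spread <= 0) stop("spread length scale must be positive")
  structure(list(name = name, region = region, extent = extent,
                 spread = spread, hard = hard), class = "factor_spec")
}

# seed vertex set for a factor region on the (initial) canvas
factor_seed_vertices <- function(canvas, spec) {
  v <- canvas$vertices
  f <- canvas$triangles
  cfg <- canvas$config
  radius <- cfg$diameter / 2
  u <- v / row_norms(v)
  polar <- acos(pmin(pmax(-u[, 3], -1), 1)) * 180 / pi  # angle from -z pole
  seed <- switch(spec$region,
    midline = {
      # vertices of triangles straddling the sagittal plane y = 0
      s <- sign(v[, 3] * 0 + v[, 2])
      cross_tri <- apply(matrix(s[f], ncol = 3), 1, function(x)
        any(x > 0) && any(x < 0))
      near <- abs(v[, 2]) < 1e-9 * radius
      seedv <- rep(FALSE, nrow(v))
      seedv[unique(c(f[cross_tri, ]))] <- TRUE
      seedv | near
    },
    stalk = polar <= (spec$extent %||% cfg$stalk_extent),
    mouth = {
      md <- c(sin(cfg$mouth_angle * pi / 180), 0, -cos(cfg$mouth_angle * pi / 180))
      ang <- acos(pmin(pmax(u %*% md, -1), 1)) * 180 / pi
      as.vector(ang) <= (spec$extent %||% cfg$mouth_extent)
    },
    ventral = {
      s <- sign(v[, 2])
      cross_tri <- apply(matrix(s[f], ncol = 3), 1, function(x)
        any(x > 0) && any(x < 0))
      band <- rep(FALSE, nrow(v))
      band[unique(c(f[cross_tri, ]))] <- TRUE
      band <- band | abs(v[, 2]) < 1e-9 * radius
      lo <- cfg$stalk_extent
      hi <- cfg$mouth_angle - cfg$mouth_extent
      band & v[, 1] > 0 & polar >= lo & polar <= hi
    })
  if (!any(seed)) stop("factor seed region does not intersect the mesh")
  seed
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Seed a regional factor on the canvas
#'
#' Generates the factor on its seed region and lets it spread by steady-state
#' diffusion with turnover (graded profile, maximal on the seed), or installs
#' a hard indicator. The resulting per-vertex field lies in [0, 1] and is
#' fixed to the canvas: it is carried with the material during growth.
#'
#' @param canvas a \code{canvas}.
#' @param spec a \code{\link{factor_spec}}.
#' @return the canvas with the factor field added.
#' @export
seed_factor <- function(canvas, spec) {
  stopifnot(inherits(spec, "factor_spec"))
  if (spec$hard) {
    seed <- factor_seed_vertices(canvas, spec)
    canvas$factors[[spec$name]] <- as.numeric(seed)
    return(canvas)
  }
  # graded factors: exponential decay of the geodesic distance to the seed
  # region on the initial sphere (the analytic steady profile of spread from
  # a clamped source); exactly mesh-resolution invariant, strictly
  # decreasing with distance, and exactly mirror symmetric
  d <- factor_seed_distance(canvas, spec)
  canvas$factors[[spec$name]] <- exp(-d / spec$spread)
  canvas
}

# geodesic distance (um, on the initial sphere) from every vertex to the seed
# region of a factor spec
factor_seed_distance <- function(canvas, spec) {
  v <- canvas$vertices
  cfg <- canvas$config
  radius <- cfg$diameter / 2
  u <- v / row_norms(v)
  deg <- pi / 180
  polar <- acos(pmin(pmax(-u[, 3], -1), 1))  # radians from the -z pole
  switch(spec$region,
    midline = radius * asin(pmin(abs(u[, 2]), 1)),
    stalk = radius * pmax(0, polar - (spec$extent %||% cfg$stalk_extent) * deg),
    mouth = {
      md <- c(sin(cfg$mouth_angle * deg), 0, -cos(cfg$mouth_angle * deg))
      ang <- acos(pmin(pmax(u %*% md, -1), 1))
      radius * pmax(0, as.vector(ang) - (spec$extent %||% cfg$mouth_extent) * deg)
    },
    ventral = {
      # distance to the ventral arc {polar in [lo, hi], y = 0, x > 0}: the
      # best great-circle contact angle theta* = atan2(x, -z), clamped to
      # the arc's angular range
      lo <- cfg$stalk_extent * deg
      hi <- (cfg$mouth_angle - cfg$mouth_extent) * deg
      theta <- atan2(u[, 1], -u[, 3])
      theta[theta < 0] <- 0  # x < 0 side: nearest contact is the stalk end
      th <- pmin(pmax(theta, lo), hi)
      dot <- u[, 1] * sin(th) - u[, 3] * cos(th)
      radius * acos(pmin(pmax(dot, -1), 1))
    },
    stop("unknown region name: ", spec$region))
}

#' Propagate the polariser field
#'
#' Solves for the polariser (POL) concentration as the steady state of
#' surface diffusion with production promoted by the stalk factor (the plus
#' organiser) and degradation enhanced by the mouth factor (the minus
#' organiser). The converged field is rescaled to [0, 1] and frozen to the
#' material: only its gradient direction is used downstream.
#'
#' @param canvas a \code{canvas} carrying \code{stk} and \code{mouth} factors.
#' @param production_rate production coefficient multiplying the stalk factor
#'   (units h^-1; the absolute scale is immaterial after rescaling).
#' @param degradation_rate basal turnover (h^-1).
#' @param diffusivity surface diffusivity (um^2 h^-1).
#' @param duration diffusion time in hours; \code{Inf} (default) solves the
#'   steady state directly, finite values take implicit time steps.
#' @param mouth_degradation additional turnover per unit mouth factor (h^-1).
#' @return the canvas with per-vertex \code{pol} set.
#' @export
propagate_polariser <- function(canvas, production_rate = 1,
                                degradation_rate = 0.005, diffusivity = 200,
                                duration = Inf, mouth_degradation = 10) {
  if (is.null(canvas$factors$stk) || is.null(canvas$factors$mouth))
    stop("stalk and mouth factor fields must be seeded before the polariser")
  v <- canvas$vertices; f <- canvas$triangles
  production <- production_rate * canvas$factors$stk
  decay <- degradation_rate + mouth_degradation * canvas$factors$mouth
  if (all(production == 0)) {
    canvas$pol <- rep(0, nrow(v))
    attr(canvas$pol, "undefined") <- TRUE
    return(canvas)
  }
  if (all(decay <= 0)) stop("polariser propagation is singular: no turnover")
  k <- diffusivity * cotan_stiffness(v, f)
  m <- lumped_mass(v, f)
  if (is.finite(duration)) {
    nstep <- max(1L, ceiling(duration / 10))
    dt <- duration / nstep
    a <- Matrix::Diagonal(length(m), m) + dt * (k + Matrix::Diagonal(length(m), m * decay))
    p <- rep(0, nrow(v))
    ch <- Matrix::Cholesky(methods::as(a, "symmetricMatrix"))
    for (i in seq_len(nstep))
      p <- as.numeric(Matrix::solve(ch, m * p + dt * m * production))
  } else {
    p <- solve_reaction_diffusion(k, m, production, decay)
  }
  if (max(p) <= 0) stop("polariser propagation failed: residual field is zero")
  canvas$pol <- p / max(p)
  canvas
}

#' Derive the polarity field from the polariser
#'
#' Takes the surface gradient of the frozen polariser on each triangle and
#' stores the unit tangent direction along \code{-grad(pol)} (from the stalk
#' organiser towards the mouth). Triangles whose gradient magnitude falls
#' below \code{tol} times the field maximum are flagged as isotropic-only.
#'
#' @param canvas a \code{canvas} with \code{pol} present.
#' @param tol relative gradient tolerance for the isotropic flag.
#' @return canvas with per-triangle \code{polarity} and logical
#'   \code{polarity_ok}.
#' @export
derive_polarity <- function(canvas, tol = 1e-6) {
  if (is.null(canvas$pol)) stop("no polariser field on the canvas")
  g <- face_gradients(canvas$vertices, canvas$triangles, canvas$pol)
  gn <- row_norms(g)
  scale <- max(gn)
  if (scale == 0 || isTRUE(attr(canvas$pol, "undefined"))) {
    if (isTRUE(attr(canvas$pol, "undefined"))) {
      canvas$polarity <- matrix(0, nrow(canvas$triangles), 3)
      canvas$polarity_ok <- rep(FALSE, nrow(canvas$triangles))
      return(canvas)
    }
    stop("polariser gradient is degenerate everywhere")
  }
  ok <- gn > tol * scale
  pol_dir <- matrix(0, nrow(canvas$triangles), 3)
  pol_dir[ok, ] <- -g[ok, , drop = FALSE] / gn[ok]
  canvas$polarity <- pol_dir
  canvas$polarity_ok <- ok
  canvas
}

# factor level per triangle (vertex mean), capped at 1; absent factor -> 0
factor_on_triangles <- function(canvas, name) {
  fl <- canvas$factors[[name]]
  if (is.null(fl)) return(rep(0, nrow(canvas$triangles)))
  fl <- pmin(fl, 1)
  f <- canvas$triangles
  (fl[f[, 1]] + fl[f[, 2]] + fl[f[, 3]]) / 3
}

# factor level at arbitrary points (nearest-vertex lookup)
factor_at_points <- function(canvas, name, points) {
  fl <- canvas$factors[[name]]
  if (is.null(fl)) return(rep(0, nrow(matrix(points, ncol = 3))))
  pmin(fl, 1)[nearest_vertices(points, canvas$vertices)]
}

#' Seed the canonical trap factors on a canvas
#'
#' Convenience wrapper installing the four regional factors (MID, STK, VEN,
#' mouth) with their default spread length scales and, optionally,
#' propagating the polariser and deriving the polarity field.
#'
#' @param canvas a \code{canvas}.
#' @param spreads named spread length scales in micrometres.
#' @param with_polarity also run \code{\link{propagate_polariser}} and
#'   \code{\link{derive_polarity}}.
#' @param ... passed to \code{\link{propagate_polariser}}.
#' @return the dressed canvas.
#' @export
setup_trap_factors <- function(canvas, spreads = c(mid = 15, ven = 8, stk = 10,
                                                   mouth = 10),
                               with_polarity = FALSE, ...) {
  canvas <- seed_factor(canvas, factor_spec("mid", spread = spreads[["mid"]]))
  canvas <- seed_factor(canvas, factor_spec("stk", spread = spreads[["stk"]]))
  canvas <- seed_factor(canvas, factor_spec("ven", spread = spreads[["ven"]]))
  canvas <- seed_factor(canvas, factor_spec("mouth", spread = spreads[["mouth"]]))
  if (with_polarity) {
    canvas <- propagate_polariser(canvas, ...)
    canvas <- derive_polarity(canvas)
  }
  canvas
}
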