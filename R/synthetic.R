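# Synthetic data generators with known ground truth: exponential trap-length
# series, quadrifid landmark fields with a controlled stalk-to-mouth polarity,
# and labelled cell mosaics with controlled area and aspect-ratio
# distributions. All generators are pure functions of their arguments and the
# seed.

#' Generate synthetic trap growth series
#'
#' Lengths follow \code{L(t) = L0 exp(rate * 24 * t) * exp(eps)} with
#' independent multiplicative lognormal noise per observation
#' (\code{eps ~ N(0, noise_sigma^2)}), sampled daily, emulating live imaging
#' of traps at daily intervals growing at ~1.8 percent per hour.
#'
#' @param rate relative growth rate in h^-1 (default 0.018).
#' @param l0 initial length at the first observation, micrometres
#'   (default 150, a trap just emerged from the circinate apex).
#' @param days number of daily observations per subject (default 8).
#' @param noise_sigma lognormal noise standard deviation (default 0.05).
#' @param n_subjects number of traps (default 10).
#' @param seed RNG seed.
#' @return a \code{\link{growth_series}}.
#' @export
gen_growth_series <- function(rate = 0.018, l0 = 150, days = 8,
                              noise_sigma = 0.05, n_subjects = 10, seed = 1L) {
  if (rate <= 0) stop("rate must be positive")
  rs <- local_seed(seed)
  on.exit(restore_seed(rs), add = TRUE)
  t_d <- rep(0:(days - 1), n_subjects)
  subj <- rep(seq_len(n_subjects), each = days)
  eps <- stats::rnorm(length(t_d), 0, noise_sigma)
  growth_series(time_d = t_d,
                length_um = l0 * exp(rate * 24 * t_d) * exp(eps),
                subject = subj, fixed = FALSE)
}

#' Generate a synthetic quadrifid gland field
#'
#' Places glands at random positions on a sphere (or on the outer surface of
#' a canvas) and constructs each from a near arm pair and a far (more
#' splayed) arm pair whose tip distances differ by \code{splay_diff}, with
#' the far-side arms shortened by \code{arm_bias}. The gland axis follows the
#' local stalk-to-mouth reference direction rotated in the tangent plane by
#' Gaussian angular noise; the ground-truth polarity (towards the far pair)
#' is recorded.
#'
#' @param n number of glands.
#' @param splay_diff difference between far and near tip-pair distances,
#'   micrometres (default 6).
#' @param arm_bias proportional shortening of the far-side arms (default 0.2).
#' @param angular_noise standard deviation of the axis rotation, degrees.
#' @param seed RNG seed.
#' @param radius sphere radius, micrometres (default 300, a mid-stage trap).
#' @param arm_length basal arm length, micrometres (default 10).
#' @param mouth_angle angular position of the mouth reference point, degrees
#'   from the stalk pole (default 70).
#' @param canvas optional canvas; glands are then placed on its outer surface.
#' @return list with \code{glands} (list of \code{\link{quadrifid}}),
#'   \code{truth} (per-gland reference and polarity directions),
#'   \code{stalk_point} and \code{mouth_point}.
#' @export
gen_quadrifid_field <- function(n = 40, splay_diff = 6, arm_bias = 0.2,
                                angular_noise = 0, seed = 1L, radius = 300,
                                arm_length = 10, mouth_angle = 70,
                                canvas = NULL) {
  if (n < 1) stop("need at least one gland")
  rs <- local_seed(seed)
  on.exit(restore_seed(rs), add = TRUE)
  if (is.null(canvas)) {
    stalk_point <- radius * c(0, 0, -1)
    ma <- mouth_angle * pi / 180
    mouth_point <- radius * c(sin(ma), 0, -cos(ma))
    # uniform random directions, kept away from the reference poles
    pts <- matrix(0, 0, 3)
    while (nrow(pts) < n) {
      cand <- normalize_rows(matrix(stats::rnorm(3 * 2 * n), ncol = 3))
      ang_s <- acos(pmin(pmax(cand %*% (stalk_point / radius), -1), 1))
      ang_m <- acos(pmin(pmax(cand %*% (mouth_point / radius), -1), 1))
      cand <- cand[ang_s > 0.35 & ang_m > 0.35, , drop = FALSE]
      pts <- rbind(pts, cand)
    }
    pts <- pts[seq_len(n), , drop = FALSE]
    centres <- pts * radius
    normals <- pts
  } else {
    v <- canvas$nodes_top
    f <- canvas$triangles
    a <- tri_areas(v, f)
    tri <- sample.int(nrow(f), n, replace = TRUE, prob = a)
    b <- matrix(stats::rexp(3 * n), ncol = 3)
    b <- b / rowSums(b)
    centres <- b[, 1] * v[f[tri, 1], ] + b[, 2] * v[f[tri, 2], ] +
      b[, 3] * v[f[tri, 3], ]
    normals <- tri_normals(v, f)[tri, , drop = FALSE]
    stalk_point <- v[canvas$landmarks[["stalk_pole"]], ]
    mouth_point <- v[canvas$landmarks[["mouth_centre"]], ]
  }

  ref_glob <- mouth_point - stalk_point
  near_dist <- 4  # near-pair tip separation, micrometres
  r_n <- arm_length
  r_f <- arm_length * (1 - arm_bias)
  alpha_n <- asin(near_dist / (2 * r_n))
  sin_af <- (near_dist + splay_diff) / (2 * r_f)
  if (sin_af >= 0.95)
    stop("splay_diff too large for the given arm length and bias")
  alpha_f <- asin(sin_af)

  glands <- vector("list", n)
  truth <- data.frame(id = seq_len(n), ref_x = NA_real_, ref_y = NA_real_,
                      ref_z = NA_real_, pol_x = NA_real_, pol_y = NA_real_,
                      pol_z = NA_real_)
  for (i in seq_len(n)) {
    nrm <- normals[i, ]
    ref <- ref_glob - nrm * sum(ref_glob * nrm)
    ref <- ref / sqrt(sum(ref^2))
    t2 <- crossprod_vec(nrm, ref)
    th <- stats::rnorm(1, 0, angular_noise * pi / 180)
    t1 <- cos(th) * ref + sin(th) * t2
    t2r <- crossprod_vec(nrm, t1)
    ctr <- centres[i, ]
    tips <- rbind(
      ctr + r_n * (-cos(alpha_n) * t1 + sin(alpha_n) * t2r),
      ctr + r_n * (-cos(alpha_n) * t1 - sin(alpha_n) * t2r),
      ctr + r_f * (cos(alpha_f) * t1 + sin(alpha_f) * t2r),
      ctr + r_f * (cos(alpha_f) * t1 - sin(alpha_f) * t2r))
    glands[[i]] <- quadrifid(i, ctr, tips, normal = nrm)
    truth[i, 2:4] <- ref
    truth[i, 5:7] <- t1
  }
  list(glands = glands, truth = truth, stalk_point = stalk_point,
       mouth_point = mouth_point)
}

#' Generate a labelled cell mosaic with controlled shape statistics
#'
#' Builds a brick mosaic of rectangular cells emulating a segmented cell
#' surface: cell extents along and across the orientation are lognormal with
#' geometric means \code{sqrt(mean_area * aspect_ratio)} and
#' \code{sqrt(mean_area / aspect_ratio)}, so the realised per-cell area
#' coefficient of variation matches \code{area_cv} and the mean second-moment
#' anisotropy corresponds to the requested aspect ratio. The patch is either
#' planar (rotated by \code{orientation}) or wrapped onto a spherical cap by
#' the azimuthal equidistant projection.
#'
#' @param n_cells number of cells (>= 2).
#' @param aspect_ratio target cell long/short axis ratio (>= 1).
#' @param orientation in-plane orientation of the long axis, degrees.
#' @param area_cv coefficient of variation of cell areas (default 0.05).
#' @param mean_area mean cell area, square micrometres (default 50).
#' @param patch "plane" or "cap".
#' @param cap_radius sphere radius for the cap patch, micrometres.
#' @param seed RNG seed.
#' @return a static \code{cell_layer}; attribute \code{truth} records the
#'   generator parameters per cell.
#' @export
gen_labelled_surface <- function(n_cells = 200, aspect_ratio = 1,
                                 orientation = 0, area_cv = 0.05,
                                 mean_area = 50, patch = c("plane", "cap"),
                                 cap_radius = 300, seed = 1L) {
  patch <- match.arg(patch)
  if (n_cells < 2) stop("need at least 2 cells")
  if (aspect_ratio < 1) stop("aspect_ratio must be >= 1")
  rs <- local_seed(seed)
  on.exit(restore_seed(rs), add = TRUE)

  # lognormal extents: var of log area = 2 sigma^2 -> cv mapping
  sigma <- sqrt(log(1 + area_cv^2) / 2)
  w0 <- sqrt(mean_area * aspect_ratio)
  h0 <- sqrt(mean_area / aspect_ratio)
  nc <- ceiling(sqrt(n_cells / aspect_ratio))
  nr <- ceiling(n_cells / nc)

  th <- orientation * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  polys <- list()
  truth_w <- truth_h <- numeric(0)
  y <- 0
  for (j in seq_len(nr)) {
    h <- h0 * exp(stats::rnorm(1, -sigma^2 / 2, sigma))
    x <- if (j %% 2 == 0) -w0 / 2 else 0  # brick offset
    for (k in seq_len(nc)) {
      if (length(polys) >= n_cells) break
      w <- w0 * exp(stats::rnorm(1, -sigma^2 / 2, sigma))
      rect <- rbind(c(x, y), c(x + w, y), c(x + w, y + h), c(x, y + h))
      polys[[length(polys) + 1]] <- rect %*% t(rot)
      truth_w <- c(truth_w, w); truth_h <- c(truth_h, h)
      x <- x + w
    }
    y <- y + h
  }
  # centre the patch
  allp <- do.call(rbind, polys)
  ctr <- colMeans(allp)
  polys <- lapply(polys, function(p) sweep(p, 2, ctr))

  to3d <- if (patch == "plane") {
    function(p) cbind(p, 0)
  } else {
    function(p) {
      r <- sqrt(rowSums(p^2))
      dir <- p / pmax(r, 1e-12)
      phi <- r / cap_radius
      cbind(cap_radius * sin(phi) * dir[, 1],
            cap_radius * sin(phi) * dir[, 2],
            cap_radius * cos(phi))
    }
  }
  layer <- static_cell_layer(lapply(polys, to3d))
  attr(layer, "truth") <- data.frame(
    id = seq_along(polys), width = truth_w, height = truth_h,
    area = truth_w * truth_h, aspect_ratio = aspect_ratio,
    orientation = orientation)
  layer
}
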