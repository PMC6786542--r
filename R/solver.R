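# Growth solver: converts specified growth into resultant deformation by
# minimising the residual elastic strain energy over a single layer of wedge
# elements spanning the wall thickness, with full dissipation of residual
# strain after every step (plastic reset: the deformed state becomes the new
# reference).

#' Solver configuration
#'
#' @param dt time step in hours (> 0; per-step specified strains should stay
#'   below ~5 percent).
#' @param elastic_modulus elastic modulus (arbitrary units; the resultant
#'   shape depends on growth-rate ratios, not the absolute stiffness).
#' @param poisson_ratio Poisson ratio in [0, 0.5).
#' @param tol linear-solve tolerance (used for diagnostics).
#' @param perturbation optional seeded vertex perturbation amplitude in
#'   micrometres applied once at the start of a run (symmetry breaking;
#'   default 0).
#' @param seed seed for the perturbation.
#' @return an object of class \code{solver_config}.
#' @export
solver_config <- function(dt = 1, elastic_modulus = 1, poisson_ratio = 0.3,
                          tol = 1e-9, perturbation = 0, seed = 1L,
                          integration = c("selective", "reduced")) {
  if (dt <= 0) stop("time step must be positive")
  if (poisson_ratio < 0 || poisson_ratio >= 0.5)
    stop("poisson_ratio must lie in [0, 0.5)")
  if (tol <= 0) stop("tolerance must be positive")
  structure(list(dt = dt, elastic_modulus = elastic_modulus,
                 poisson_ratio = poisson_ratio, tol = tol,
                 perturbation = perturbation, seed = seed,
                 integration = match.arg(integration)),
            class = "solver_config")
}

# wedge connectivity: bottom sheet nodes 1..V, top sheet V+1..2V
wedge_elements <- function(canvas) {
  f <- canvas$triangles
  nv <- nrow(canvas$vertices)
  cbind(f, f + nv)
}

# specified strain per element in global Voigt coordinates
specified_strain_voigt <- function(canvas, growth, dt) {
  n <- tri_normals(canvas$vertices, canvas$triangles)
  d <- growth$direction
  # project direction into the triangle plane
  d <- d - n * rowSums(d * n)
  dn <- row_norms(d)
  bad <- dn < 1e-12
  if (any(bad)) {
    # direction degenerate (e.g. polarity parallel to normal): any tangent
    alt <- default_tangent(canvas)
    alt <- alt - n * rowSums(alt * n)
    d[bad, ] <- alt[bad, , drop = FALSE]
    dn[bad] <- row_norms(d[bad, , drop = FALSE])
  }
  e1 <- d / dn
  e2 <- cross3(n, e1)
  a <- expm1(growth$k_par * dt)
  b <- expm1(growth$k_per * dt)
  c_ <- expm1(growth$k_nor * dt)
  # S = a e1 e1' + b e2 e2' + c n n'
  sxx <- a * e1[, 1]^2 + b * e2[, 1]^2 + c_ * n[, 1]^2
  syy <- a * e1[, 2]^2 + b * e2[, 2]^2 + c_ * n[, 2]^2
  szz <- a * e1[, 3]^2 + b * e2[, 3]^2 + c_ * n[, 3]^2
  sxy <- a * e1[, 1] * e1[, 2] + b * e2[, 1] * e2[, 2] + c_ * n[, 1] * n[, 2]
  syz <- a * e1[, 2] * e1[, 3] + b * e2[, 2] * e2[, 3] + c_ * n[, 2] * n[, 3]
  sxz <- a * e1[, 1] * e1[, 3] + b * e2[, 1] * e2[, 3] + c_ * n[, 1] * n[, 3]
  cbind(sxx, syy, szz, 2 * sxy, 2 * syz, 2 * sxz)
}

# choose 6 pin dofs that fix the rigid-body modes exactly (gauge fixing: the
# constrained minimiser coincides with a global minimiser because the
# constraint surface intersects every rigid-motion coset)
rigid_modes <- function(nodes) {
  n <- nrow(nodes)
  ctr <- colMeans(nodes)
  x <- sweep(nodes, 2, ctr)
  t1 <- rep(c(1, 0, 0), n); t2 <- rep(c(0, 1, 0), n); t3 <- rep(c(0, 0, 1), n)
  rx <- as.vector(t(cbind(0, -x[, 3], x[, 2])))
  ry <- as.vector(t(cbind(x[, 3], 0, -x[, 1])))
  rz <- as.vector(t(cbind(-x[, 2], x[, 1], 0)))
  cbind(matrix(c(t1, t2, t3), ncol = 3), rx, ry, rz)
}

choose_pin_dofs <- function(nodes) {
  # four well-spread nodes, then QR-pivot their 12 dofs against the modes
  n <- nrow(nodes)
  i1 <- 1L
  d <- rowSums(sweep(nodes, 2, nodes[i1, ])^2)
  i2 <- which.max(d)
  e <- nodes[i2, ] - nodes[i1, ]
  cr <- cross3(sweep(nodes, 2, nodes[i1, ]), matrix(e, n, 3, byrow = TRUE))
  i3 <- which.max(rowSums(cr * cr))
  nrm <- cross3(matrix(e, 1, 3),
                matrix(nodes[i3, ] - nodes[i1, ], 1, 3))
  i4 <- which.max(abs(as.numeric(sweep(nodes, 2, nodes[i1, ]) %*% t(nrm))))
  cand <- as.vector(outer(c(-2L, -1L, 0L), 3L * c(i1, i2, i3, i4), `+`))
  tmat <- rigid_modes(nodes)
  qrres <- qr(t(tmat[cand, , drop = FALSE]), LAPACK = TRUE)
  sort(cand[qrres$pivot[1:6]])
}

#' Advance the canvas by one growth step
#'
#' Applies the specified growth field over one time step: the displacement
#' field minimising the residual elastic energy between the actual
#' deformation and the specified per-element stretch
#' (\code{exp(K dt)} along polarity, perpendicular, and normal) is solved on
#' the wedge-element shell, rigid-body motion is removed, and the deformed
#' state becomes the new reference (full dissipation of residual strain).
#' Factor fields ride with the material; the polarity field is re-derived on
#' the deformed surface from the frozen polariser.
#'
#' @param canvas a \code{canvas}.
#' @param growth a \code{specified_growth} from \code{\link{evaluate_krn}}.
#' @param config a \code{\link{solver_config}}.
#' @param cache optional environment reusing the factorisation pattern across
#'   steps.
#' @return the deformed canvas; attributes \code{residual_energy} (at the
#'   minimiser) and \code{specified_energy} (of the unrelaxed
#'   growth-prescribed configuration) report the energy decrease.
#' @export
growth_step <- function(canvas, growth, config = solver_config(),
                        cache = NULL) {
  dt <- config$dt
  max_strain <- max(abs(c(growth$k_par, growth$k_per, growth$k_nor))) * dt
  if (max_strain > 0.08)
    warning("per-step specified strain exceeds 8%; reduce dt")
  nodes <- rbind(canvas$nodes_bot, canvas$nodes_top)
  elems <- wedge_elements(canvas)
  eps0 <- specified_strain_voigt(canvas, growth, dt)

  asm <- assemble_wedge(nodes, elems, eps0, config$elastic_modulus,
                        config$poisson_ratio,
                        if (identical(config$integration, "reduced")) 1L else 3L)
  if (asm$mindet <= 0) stop("inverted wedge element in reference configuration")
  ndof <- 3L * nrow(nodes)

  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  if (is.null(cache$ready)) {
    dofs <- t(apply(elems, 1, function(nd) {
      as.vector(rbind(3L * (nd - 1L) + 1L, 3L * (nd - 1L) + 2L, 3L * (nd - 1L) + 3L))
    }))
    ii <- as.vector(t(dofs[, rep(seq_len(18), times = 18)]))
    jj <- as.vector(t(dofs[, rep(seq_len(18), each = 18)]))
    pins <- choose_pin_dofs(nodes)
    free <- setdiff(seq_len(ndof), pins)
    remap <- integer(ndof)
    remap[free] <- seq_along(free)
    fi <- remap[ii]; fj <- remap[jj]
    keep <- fi > 0L & fj > 0L & fi <= fj   # free x free, upper triangle
    nf <- length(free)
    key <- (as.double(fj[keep]) - 1) * nf + as.double(fi[keep])
    ord <- order(key)
    ks <- key[ord]
    ends <- c(which(diff(ks) > 0), length(ks))
    iu <- fi[keep][ord][ends]
    ju <- fj[keep][ord][ends]
    cache$free <- free
    cache$keep <- keep
    cache$ord <- ord
    cache$ends <- ends
    cache$kff <- Matrix::sparseMatrix(i = iu, j = ju, x = rep(0, length(ends)),
                                      dims = c(nf, nf), symmetric = TRUE)
    cache$full_ii <- ii; cache$full_jj <- jj
    cache$ready <- TRUE
  }
  free <- cache$free
  xs <- cumsum(asm$vals[cache$keep][cache$ord])
  cache$kff@x <- diff(c(0, xs[cache$ends]))
  rhs <- asm$rhs[free]
  sol <- tryCatch({
    if (is.null(cache$chol)) {
      cache$chol <- Matrix::Cholesky(cache$kff, LDL = FALSE, super = TRUE)
    } else {
      cache$chol <- Matrix::update(cache$chol, cache$kff)
    }
    as.numeric(Matrix::solve(cache$chol, rhs))
  }, error = function(e) {
    res <- tryCatch(as.numeric(Matrix::solve(cache$kff, rhs)),
                    error = function(e2) NULL)
    if (is.null(res))
      stop("growth solver failed to converge: ", conditionMessage(e))
    res
  })
  u <- numeric(ndof)
  u[free] <- sol

  # re-gauge: remove the best-fit linearised rigid motion
  tmat <- rigid_modes(nodes)
  beta <- solve(crossprod(tmat), crossprod(tmat, u))
  u <- u - as.numeric(tmat %*% beta)

  umat <- matrix(u, ncol = 3, byrow = TRUE)
  new_nodes <- nodes + umat
  mj <- wedge_min_jacobian(new_nodes, elems)
  if (mj <= 0) stop("element inversion after growth step (min |J| = ",
                    format(mj), ")")

  nv <- nrow(canvas$vertices)
  canvas$nodes_bot <- new_nodes[seq_len(nv), , drop = FALSE]
  canvas$nodes_top <- new_nodes[nv + seq_len(nv), , drop = FALSE]
  canvas$vertices <- (canvas$nodes_bot + canvas$nodes_top) / 2
  canvas$thickness <- row_norms(canvas$nodes_top - canvas$nodes_bot)
  canvas$time <- canvas$time + dt
  if (!is.null(canvas$pol) && !isTRUE(attr(canvas$pol, "undefined")))
    canvas <- derive_polarity(canvas)

  # energy is gauge-invariant (rigid modes are in the stiffness null space)
  resid <- 0.5 * sum(sol * as.numeric(cache$kff %*% sol)) - sum(rhs * sol) +
    asm$e0const
  attr(canvas, "residual_energy") <- resid
  attr(canvas, "specified_energy") <- asm$e0const
  canvas
}

#' Run a growth simulation
#'
#' Repeatedly re-evaluates the KRN (factors ride with the material,
#' thresholds are reapplied, the polarity direction follows the deforming
#' surface), takes a growth step, and optionally updates a virtual cell
#' layer, from \code{t_start} to \code{t_end} hours.
#'
#' @param canvas initial \code{canvas} (its clock is set to \code{t_start}).
#' @param params a \code{krn_params}.
#' @param cells optional \code{cell_layer} advected and divided during the
#'   run.
#' @param t_start,t_end simulation window in hours after initiation.
#' @param config a \code{\link{solver_config}}.
#' @param rule a \code{\link{division_rule}} used when \code{cells} is given.
#' @param snapshot_every record a canvas (and cell layer) snapshot every this
#'   many steps (the first and last states are always kept).
#' @return an object of class \code{trajectory}: snapshot canvases, per-step
#'   material triangle areas, per-step lengths of polarity-aligned material
#'   segments, energies, times.
#' @export
run_simulation <- function(canvas, params, cells = NULL, t_start = 96,
                           t_end = 252, config = solver_config(),
                           rule = division_rule(),
                           snapshot_every = NULL) {
  if (t_start >= t_end) stop("t_start must be before t_end")
  canvas$time <- t_start
  nstep <- max(1L, round((t_end - t_start) / config$dt))
  if (is.null(snapshot_every)) snapshot_every <- nstep
  if (config$perturbation > 0) {
    rs <- local_seed(config$seed)
    on.exit(restore_seed(rs), add = TRUE)
    vn <- vertex_normals(canvas$vertices, canvas$triangles)
    disp <- config$perturbation * stats::runif(nrow(canvas$vertices), -1, 1)
    canvas$nodes_top <- canvas$nodes_top + disp * vn
    canvas$nodes_bot <- canvas$nodes_bot + disp * vn
    canvas$vertices <- (canvas$nodes_top + canvas$nodes_bot) / 2
  }

  nt <- nrow(canvas$triangles)
  tri_area_log <- matrix(NA_real_, nstep + 1, nt)
  par_rate_log <- matrix(NA_real_, nstep, nt)
  energies <- data.frame(time = numeric(0), residual = numeric(0),
                         specified = numeric(0))
  tri_area_log[1, ] <- tri_areas(canvas$vertices, canvas$triangles)

  snapshots <- list(canvas)
  cell_snapshots <- if (!is.null(cells)) list(cells) else NULL
  snap_times <- canvas$time
  cache <- new.env(parent = emptyenv())
  times <- canvas$time

  for (s in seq_len(nstep)) {
    growth <- evaluate_krn(params, canvas)
    segs <- polarity_segments(canvas, params)
    len_before <- segment_lengths(segs, canvas)
    prev <- canvas
    canvas <- growth_step(canvas, growth, config, cache = cache)
    times <- c(times, canvas$time)
    tri_area_log[s + 1, ] <- tri_areas(canvas$vertices, canvas$triangles)
    par_rate_log[s, ] <- log(segment_lengths(segs, canvas) / len_before) /
      config$dt
    energies <- rbind(energies, data.frame(
      time = canvas$time,
      residual = attr(canvas, "residual_energy"),
      specified = attr(canvas, "specified_energy")))
    if (!is.null(cells))
      cells <- step_cells(cells, prev, canvas, rule, canvas$time)
    if (s %% snapshot_every == 0 || s == nstep) {
      snapshots[[length(snapshots) + 1]] <- canvas
      snap_times <- c(snap_times, canvas$time)
      if (!is.null(cells)) cell_snapshots[[length(cell_snapshots) + 1]] <- cells
    }
  }

  structure(list(times = times, snapshot_times = snap_times,
                 snapshots = snapshots, cells = cell_snapshots,
                 tri_areas = tri_area_log, parallel_rates = par_rate_log,
                 energies = energies, params = params, config = config),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", length(x$times), "states,",
      format(x$times[1]), "->", format(x$times[length(x$times)]), "h;",
      length(x$snapshots), "snapshots\n")
  invisible(x)
}

# per-triangle material segments along the current polarity (or an arbitrary
# tangent for isotropic models), stored as barycentric endpoints about the
# centroid; re-derived every step so that the measured parallel rate is the
# instantaneous rate along the (advected) polarity direction
polarity_segments <- function(canvas, params) {
  v <- canvas$vertices; f <- canvas$triangles
  needs_dir <- params$model_kind %in% c("directional", "integrated")
  d <- if (needs_dir && !is.null(canvas$polarity)) canvas$polarity
       else default_tangent(canvas)
  n <- tri_normals(v, f)
  d <- d - n * rowSums(d * n)
  d <- normalize_rows(d)
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  scale <- 0.15 * row_norms(e1)
  g11 <- rowSums(e1 * e1); g12 <- rowSums(e1 * e2); g22 <- rowSums(e2 * e2)
  b1 <- rowSums(e1 * d) * scale; b2 <- rowSums(e2 * d) * scale
  det <- g11 * g22 - g12^2
  a <- (g22 * b1 - g12 * b2) / det
  b <- (g11 * b2 - g12 * b1) / det
  db <- cbind(-a - b, a, b)
  ctr <- matrix(1 / 3, nrow(f), 3)
  list(plus = ctr + db, minus = ctr - db)
}

segment_lengths <- function(segs, canvas) {
  v <- canvas$vertices; f <- canvas$triangles
  pp <- segs$plus[, 1] * v[f[, 1], ] + segs$plus[, 2] * v[f[, 2], ] +
    segs$plus[, 3] * v[f[, 3], ]
  pm <- segs$minus[, 1] * v[f[, 1], ] + segs$minus[, 2] * v[f[, 2], ] +
    segs$minus[, 3] * v[f[, 3], ]
  row_norms(pp - pm)
}

#' Region mask from a factor field
#'
#' Logical per-triangle mask of the region where a factor exceeds a level
#' (evaluated on the run's initial canvas; the mask is material).
#' @param canvas a canvas carrying the factor.
#' @param name factor name.
#' @param level threshold level (default 0.5).
#' @return logical vector over triangles.
#' @export
region_mask <- function(canvas, name, level = 0.5) {
  factor_on_triangles(canvas, name) >= level
}

#' Resultant strain rates from a trajectory
#'
#' Measures resultant growth over a time interval from material quantities:
#' the areal rate \code{ln(A2 / A1) / (t2 - t1)} of the summed
#' material-triangle areas of a region, or the mean linear rate
#' \code{ln(L2 / L1) / (t2 - t1)} of the region's polarity-aligned material
#' segments.
#'
#' @param traj a \code{trajectory}.
#' @param region logical per-triangle mask (see \code{\link{region_mask}}).
#' @param interval time interval \code{c(t1, t2)} in hours; defaults to the
#'   whole run.
#' @param direction \code{"areal"} or \code{"parallel"} (time-mean of the
#'   instantaneous linear rate along the current local polarity direction).
#' @return strain rate in h^-1.
#' @export
resultant_strain <- function(traj, region, interval = NULL,
                             direction = c("areal", "parallel")) {
  direction <- match.arg(direction)
  if (!any(region)) stop("empty region")
  if (is.null(interval)) interval <- range(traj$times)
  i1 <- which.min(abs(traj$times - interval[1]))
  i2 <- which.min(abs(traj$times - interval[2]))
  if (i1 == i2) stop("interval endpoints coincide")
  dt <- traj$times[i2] - traj$times[i1]
  if (direction == "areal") {
    a1 <- sum(traj$tri_areas[i1, region])
    a2 <- sum(traj$tri_areas[i2, region])
    log(a2 / a1) / dt
  } else {
    steps <- max(i1, 1):(i2 - 1)
    mean(rowMeans(traj$parallel_rates[steps, region, drop = FALSE]))
  }
}

# seeded RNG scoping helpers
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
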