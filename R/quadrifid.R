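# Quadrifid gland polarity: each gland is recorded as five 3D landmarks (a
# centre and four arm tips). The two arm pairs are identified from the
# centre-subtended angles, an axis is drawn between the pair midpoints, and a
# polarity is assigned towards the more widely splayed pair when the tip
# distances differ by at least a threshold (DistArms), optionally requiring
# agreement with the arm-length criterion (SumArms).

#' Quadrifid polarity parameters
#'
#' @param threshold distance-difference threshold in micrometres (default 2):
#'   glands whose two tip-pair distances differ by less receive an axiality
#'   but no polarity.
#' @param criterion "distarms" (distance between tips), "sumarms" (summed arm
#'   lengths, arrow towards the shorter arms) or "distarms_and_sumarms"
#'   (polarity retained only when both criteria agree).
#' @return object of class \code{quadrifid_params}.
#' @export
quadrifid_params <- function(threshold = 2,
                             criterion = c("distarms", "sumarms",
                                           "distarms_and_sumarms")) {
  if (threshold < 0) stop("threshold must be >= 0")
  structure(list(threshold = threshold, criterion = match.arg(criterion)),
            class = "quadrifid_params")
}

#' Construct a quadrifid gland record
#'
#' @param id gland identifier.
#' @param centre numeric length-3 centre position, micrometres.
#' @param tips 4 x 3 matrix of arm tip positions.
#' @param normal optional unit surface normal at the gland (used to project
#'   the alignment reference into the tangent plane).
#' @return object of class \code{quadrifid}.
#' @export
quadrifid <- function(id, centre, tips, normal = NULL) {
  tips <- matrix(tips, ncol = 3)
  if (nrow(tips) != 4) stop("a quadrifid has exactly 4 arm tips")
  if (any(row_norms(sweep(tips, 2, centre)) == 0))
    stop("arm tips must be distinct from the centre")
  structure(list(id = id, centre = as.numeric(centre), tips = tips,
                 normal = normal), class = "quadrifid")
}

#' Pair the arms of a quadrifid
#'
#' Computes the six centre-subtended angles between arm tips; the two
#' smallest angles identify the two pairs of arms closest together. If the
#' two smallest angles do not partition the four tips, or are tied with a
#' conflicting pair within tolerance (e.g. a perfectly cross-shaped gland),
#' the gland is flagged unpairable.
#'
#' @param q a \code{\link{quadrifid}}.
#' @param tie_tol angle tie tolerance in radians.
#' @return list with \code{pairs} (two index pairs into the tips), logical
#'   \code{ok}, and the six pair angles.
#' @export
pair_arms <- function(q, tie_tol = 1e-6) {
  arms <- sweep(q$tips, 2, q$centre)
  an <- row_norms(arms)
  if (any(!is.finite(an)) || any(an == 0))
    return(list(pairs = NULL, ok = FALSE, angles = NULL))
  u <- arms / an
  combos <- utils::combn(4, 2)
  angles <- apply(combos, 2, function(ij)
    acos(pmin(pmax(sum(u[ij[1], ] * u[ij[2], ]), -1), 1)))
  ord <- order(angles)
  p1 <- combos[, ord[1]]
  p2 <- combos[, ord[2]]
  ok <- length(intersect(p1, p2)) == 0
  if (ok) {
    # ambiguous if a conflicting pair ties with the selected second pair
    conflicting <- ord[-(1:2)]
    tied <- angles[conflicting] <= angles[ord[2]] + tie_tol
    if (any(tied)) {
      overlaps <- vapply(conflicting[tied], function(k)
        length(intersect(combos[, k], c(p1, p2))) > 0 &&
          !setequal(combos[, k], p1) && !setequal(combos[, k], p2),
        logical(1))
      if (any(overlaps)) ok <- FALSE
    }
  }
  list(pairs = if (ok) list(p1, p2) else NULL, ok = ok, angles = angles)
}

#' Assign axis and polarity to a quadrifid
#'
#' The gland axis is the unit vector joining the two pair midpoints through
#' the centre. Under the DistArms criterion the gland is polarised towards
#' the pair with the greater tip-to-tip distance provided the two distances
#' differ by at least the threshold; under SumArms, towards the pair with the
#' smaller summed arm length; under the combined criterion the polarity is
#' retained only when both agree. Otherwise the gland keeps an axiality only.
#'
#' @param q a \code{\link{quadrifid}}.
#' @param params a \code{\link{quadrifid_params}}.
#' @return the gland with fields \code{axis}, \code{polarity} (signed unit
#'   vector or NULL), \code{assigned}, \code{dist_diff}, \code{pair_dists},
#'   \code{arm_sums}, \code{pairable}.
#' @export
assign_polarity <- function(q, params = quadrifid_params()) {
  pr <- pair_arms(q)
  q$pairable <- pr$ok
  q$assigned <- FALSE
  q$polarity <- NULL
  q$axis <- NULL
  if (!pr$ok) return(q)
  p1 <- pr$pairs[[1]]; p2 <- pr$pairs[[2]]
  mid1 <- colMeans(q$tips[p1, , drop = FALSE])
  mid2 <- colMeans(q$tips[p2, , drop = FALSE])
  ax <- mid2 - mid1
  ax <- ax / sqrt(sum(ax^2))
  d1 <- sqrt(sum((q$tips[p1[1], ] - q$tips[p1[2], ])^2))
  d2 <- sqrt(sum((q$tips[p2[1], ] - q$tips[p2[2], ])^2))
  s1 <- sum(row_norms(sweep(q$tips[p1, , drop = FALSE], 2, q$centre)))
  s2 <- sum(row_norms(sweep(q$tips[p2, , drop = FALSE], 2, q$centre)))
  q$axis <- ax
  q$pair_dists <- c(d1, d2)
  q$arm_sums <- c(s1, s2)
  q$dist_diff <- abs(d1 - d2)
  dist_dir <- if (d2 > d1) ax else -ax           # towards wider-splayed pair
  sum_dir <- if (s2 < s1) ax else -ax            # towards shorter arms
  pol <- switch(params$criterion,
    distarms = if (q$dist_diff >= params$threshold) dist_dir else NULL,
    sumarms = if (abs(s1 - s2) > 0) sum_dir else NULL,
    distarms_and_sumarms = {
      if (q$dist_diff >= params$threshold &&
          sum(dist_dir * sum_dir) > 0) dist_dir else NULL
    })
  if (!is.null(pol)) {
    q$polarity <- pol
    q$assigned <- TRUE
  }
  q
}

#' Summarise a quadrifid polarity field
#'
#' Counts polarised glands as aligned or anti-aligned with the local
#' stalk-to-mouth reference direction (the ambient direction from the stalk
#' point to the mouth point, projected into the gland's tangent plane when a
#' surface normal is available), plus unassigned glands, and bins the
#' distance differences into a histogram.
#'
#' @param glands list of \code{\link{quadrifid}}s processed by
#'   \code{\link{assign_polarity}}.
#' @param stalk_point,mouth_point 3D reference points, micrometres.
#' @param bin_width histogram bin width for the distance difference
#'   (micrometres, default 1).
#' @return list with \code{counts} (aligned, anti_aligned, unassigned,
#'   total), per-gland \code{alignment} data.frame and \code{histogram}.
#' @export
summarize_field <- function(glands, stalk_point, mouth_point, bin_width = 1) {
  if (!length(glands)) stop("no glands supplied")
  assigned <- vapply(glands, function(q) isTRUE(q$assigned), logical(1))
  if (!any(assigned))
    warning("no glands with assigned polarity")
  ref0 <- mouth_point - stalk_point
  rows <- lapply(glands, function(q) {
    ref <- ref0
    if (!is.null(q$normal)) {
      ref <- ref - q$normal * sum(ref * q$normal)
    }
    ref <- ref / max(sqrt(sum(ref^2)), .Machine$double.eps)
    proj <- if (isTRUE(q$assigned)) sum(q$polarity * ref) else NA_real_
    data.frame(id = q$id, assigned = isTRUE(q$assigned),
               projection = proj,
               aligned = if (isTRUE(q$assigned)) proj > 0 else NA,
               dist_diff = if (!is.null(q$dist_diff)) q$dist_diff else NA_real_)
  })
  tab <- do.call(rbind, rows)
  counts <- c(aligned = sum(tab$aligned %in% TRUE),
              anti_aligned = sum(tab$aligned %in% FALSE),
              unassigned = sum(!tab$assigned),
              total = nrow(tab))
  dd <- tab$dist_diff[is.finite(tab$dist_diff)]
  brk <- seq(0, max(dd, bin_width) + bin_width, by = bin_width)
  hist <- data.frame(lower = brk[-length(brk)], upper = brk[-1],
                     count = as.vector(table(cut(dd, brk, right = FALSE,
                                                 include.lowest = TRUE))))
  list(counts = counts, alignment = tab, histogram = hist)
}

#' Read quadrifid landmarks from a table or CSV
#'
#' Canonical format: columns \code{gland_id}, \code{landmark} (one of
#' "centre", "arm1".."arm4"), \code{x}, \code{y}, \code{z}.
#' @param x a data.frame or path to a CSV file.
#' @return list of \code{\link{quadrifid}} objects.
#' @export
read_quadrifids <- function(x) {
  df <- if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE) else x
  need <- c("gland_id", "landmark", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("landmark table needs columns: ", paste(need, collapse = ", "))
  lapply(split(df, df$gland_id), function(g) {
    ctr <- g[g$landmark == "centre", c("x", "y", "z")]
    arms <- g[grepl("^arm[1-4]$", g$landmark), ]
    arms <- arms[order(arms$landmark), c("x", "y", "z")]
    if (nrow(ctr) != 1 || nrow(arms) != 4)
      stop("gland ", g$gland_id[1], " must have one centre and four arms")
    quadrifid(g$gland_id[1], as.numeric(ctr), as.matrix(arms))
  })
}

#' Write quadrifid results to a data.frame
#' @param glands list of assigned \code{\link{quadrifid}}s.
#' @return data.frame with axis, polarity, distance difference and flags.
#' @export
quadrifid_table <- function(glands) {
  do.call(rbind, lapply(glands, function(q) {
    data.frame(id = q$id,
               pairable = isTRUE(q$pairable), assigned = isTRUE(q$assigned),
               axis_x = if (!is.null(q$axis)) q$axis[1] else NA_real_,
               axis_y = if (!is.null(q$axis)) q$axis[2] else NA_real_,
               axis_z = if (!is.null(q$axis)) q$axis[3] else NA_real_,
               pol_x = if (isTRUE(q$assigned)) q$polarity[1] else NA_real_,
               pol_y = if (isTRUE(q$assigned)) q$polarity[2] else NA_real_,
               pol_z = if (isTRUE(q$assigned)) q$polarity[3] else NA_real_,
               dist_diff = if (!is.null(q$dist_diff)) q$dist_diff else NA_real_)
  }))
}

#' Import landmarks from a minimal MSR-like text dialect
#'
#' Reads named 3D point objects from a plain-text file with lines of the form
#' \code{<gland>_<landmark>: x y z} (landmark one of centre, arm1..arm4);
#' lines starting with \code{#} are ignored. This covers legacy landmark
#' exports from 3D viewers.
#' @param path file path.
#' @return list of \code{\link{quadrifid}} objects.
#' @export
read_msr_landmarks <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- regmatches(lines,
                      regexec("^(\\S+)_(centre|arm[1-4]):\\s+(\\S+)\\s+(\\S+)\\s+(\\S+)$",
                              lines))
  bad <- vapply(parts, length, integer(1)) != 6
  if (any(bad)) stop("unparseable landmark line: ", lines[which(bad)[1]])
  df <- do.call(rbind, lapply(parts, function(p)
    data.frame(gland_id = p[2], landmark = p[3],
               x = as.numeric(p[4]), y = as.numeric(p[5]),
               z = as.numeric(p[6]))))
  read_quadrifids(df)
}
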