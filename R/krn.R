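# Growth regulatory networks (KRNs): the factor-dependent rules that set the
# specified growth rates K_par (parallel to polarity), K_per (perpendicular,
# in plane) and K_nor (thickness) for each model variant.

#' Promotion operator
#'
#' \code{pro(z, i)} multiplies a rate by \code{1 + z * i}, the standard
#' promotion of a growth rate by factor level \code{i} with coefficient
#' \code{z}.
#' @param z promotion coefficient (>= 0).
#' @param i factor level(s).
#' @return multiplier \code{1 + z * i}.
#' @examples pro(0.165, 1)
#' @export
pro <- function(z, i) 1 + z * i

#' Inhibition operator
#'
#' \code{inh(z, i)} multiplies a rate by \code{1 / (1 + z * i)}.
#' @param z inhibition coefficient (>= 0).
#' @param i factor level(s); requires \code{z * i > -1}.
#' @return multiplier \code{1 / (1 + z * i)}.
#' @examples inh(1.4, 1)
#' @export
inh <- function(z, i) {
  if (any(z * i <= -1)) stop("inh(z, i) requires z * i > -1")
  1 / (1 + z * i)
}

#' Threshold a factor field
#'
#' Sets the field to 1 where it exceeds the threshold and to 0 elsewhere,
#' widening the domain of action of a graded factor (used for the VEN factor
#' in the integrated model).
#' @param i factor field.
#' @param t threshold in [0, 1].
#' @return 0/1 field.
#' @export
threshold_factor <- function(i, t) {
  if (t < 0 || t > 1) stop("threshold must lie in [0, 1]")
  as.numeric(i > t)
}

#' Growth regulatory network parameters
#'
#' Bundles the rate constants of the trap growth models. \code{model_kind}
#' selects how the factor terms combine: \code{"areal"} (isotropic specified
#' growth, areal conflict only), \code{"directional"} (uniform specified
#' areal rate \code{2 b_planar} with anisotropy redistributed between K_par
#' and K_per) or \code{"integrated"} (separable regulation of K_par and
#' K_per). The \code{use_*} flags reproduce the progressive model series in
#' which the factors are introduced one at a time.
#'
#' @param model_kind "areal", "directional" or "integrated".
#' @param b_planar basic specified planar growth rate (h^-1, > 0).
#' @param p_mid promotion of K_par (and K_per for areal models) by MID.
#' @param h_stk inhibition coefficient of STK.
#' @param p_ven promotion coefficient of VEN.
#' @param h_ven inhibition of K_per by thresholded VEN (integrated model).
#' @param t_ven threshold widening the VEN domain, in [0, 1].
#' @param b_thickness specified growth rate in thickness (h^-1, >= 0).
#' @param p_th promotion of thickness growth by STK and thresholded VEN
#'   (thickness-variant model); 0 disables the variant.
#' @param use_mid,use_stk,use_ven enable the MID / STK / VEN terms.
#' @return an object of class \code{krn_params}.
#' @export
krn_params <- function(model_kind = c("areal", "directional", "integrated"),
                       b_planar = 0.0145, p_mid = 0.165, h_stk = 0,
                       p_ven = 0, h_ven = 0, t_ven = 0.01,
                       b_thickness = 0.005, p_th = 0,
                       use_mid = TRUE, use_stk = h_stk > 0,
                       use_ven = p_ven > 0) {
  model_kind <- match.arg(model_kind)
  if (b_planar <= 0) stop("b_planar must be positive")
  if (b_thickness < 0) stop("b_thickness must be >= 0")
  if (any(c(p_mid, h_stk, p_ven, h_ven, p_th) < 0))
    stop("promotion/inhibition coefficients must be >= 0")
  if (t_ven < 0 || t_ven > 1) stop("t_ven must lie in [0, 1]")
  structure(list(model_kind = model_kind, b_planar = b_planar, p_mid = p_mid,
                 h_stk = h_stk, p_ven = p_ven, h_ven = h_ven, t_ven = t_ven,
                 b_thickness = b_thickness, p_th = p_th,
                 use_mid = use_mid, use_stk = use_stk, use_ven = use_ven),
            class = "krn_params")
}

#' @export
print.krn_params <- function(x, ...) {
  cat("KRN (", x$model_kind, "): b_planar=", x$b_planar,
      " p_mid=", if (x$use_mid) x$p_mid else "off",
      " h_stk=", if (x$use_stk) x$h_stk else "off",
      " p_ven=", if (x$use_ven) x$p_ven else "off", sep = "")
  if (x$model_kind == "integrated")
    cat(" h_ven=", x$h_ven, " t_ven=", x$t_ven, sep = "")
  cat(" b_thickness=", x$b_thickness, "\n", sep = "")
  invisible(x)
}

#' Published KRN presets
#'
#' Returns the parameter set of one of the published model variants. Areal
#' models: \code{fig4AF} (MID only), \code{fig4GJ} (+STK), \code{fig4KN}
#' (+VEN); directional models: \code{fig6AD}, \code{fig6EH}, \code{fig6IL};
#' \code{fig6MP} the integrated model; \code{fig7_terminal} /
#' \code{fig7_basal} the species variants; \code{s3_thickness} the
#' thickness-promotion variant.
#'
#' @param name preset name.
#' @return a \code{krn_params}.
#' @export
krn_preset <- function(name) {
  switch(name,
    fig4AF = krn_params("areal", b_planar = 0.0145, p_mid = 0.165,
                        b_thickness = 0.005),
    fig4GJ = krn_params("areal", b_planar = 0.0145, p_mid = 0.165,
                        h_stk = 1.4, b_thickness = 0.005),
    fig4KN = krn_params("areal", b_planar = 0.0145, p_mid = 0.165,
                        h_stk = 1.4, p_ven = 0.2, b_thickness = 0.005),
    fig6AD = krn_params("directional", b_planar = 0.015, p_mid = 0.35,
                        b_thickness = 0.005),
    fig6EH = krn_params("directional", b_planar = 0.015, p_mid = 0.35,
                        h_stk = 1.5, b_thickness = 0.005),
    fig6IL = krn_params("directional", b_planar = 0.015, p_mid = 0.35,
                        h_stk = 1.5, p_ven = 0.5, b_thickness = 0.005),
    fig6MP = krn_params("integrated", b_planar = 0.015, p_mid = 0.35,
                        h_stk = 1.5, p_ven = 0.5, h_ven = 0.8, t_ven = 0.01,
                        b_thickness = 0.005),
    fig7_terminal = species_preset("terminal"),
    fig7_basal = species_preset("basal"),
    s3_thickness = {
      p <- krn_preset("fig6MP"); p$p_th <- 0.5; p
    },
    stop("unknown KRN preset: ", name)
  )
}

#' Species-variant parameter sets
#'
#' The integrated model with the promotion coefficients of MID and VEN on
#' K_par varied to reproduce the trap types of different species: terminal
#' (p_mid = 0.05, p_ven = 1.25), basal (p_mid = 0.45, p_ven = 0.1) and
#' lateral (the unmodified integrated model).
#'
#' @param type "terminal", "basal" or "lateral".
#' @return a \code{krn_params}.
#' @export
species_preset <- function(type = c("terminal", "basal", "lateral")) {
  type <- match.arg(type)
  p <- krn_params("integrated", b_planar = 0.015, p_mid = 0.35, h_stk = 1.5,
                  p_ven = 0.5, h_ven = 0.8, t_ven = 0.01, b_thickness = 0.005)
  if (type == "terminal") { p$p_mid <- 0.05; p$p_ven <- 1.25 }
  if (type == "basal")    { p$p_mid <- 0.45; p$p_ven <- 0.1 }
  p
}

#' Evaluate a KRN on a canvas
#'
#' Computes the per-triangle specified growth rates for the selected model
#' variant from the canvas factor fields (capped at 1 before evaluation).
#' For areal models K_per = K_par (isotropic specified growth). For
#' directional models K_par is clamped at \code{2 b_planar} and K_per is set
#' to \code{2 b_planar - K_par} so the specified areal rate is uniform. For
#' the integrated model K_par and K_per are regulated separately, with VEN
#' acting on K_per through its thresholded (widened) domain.
#'
#' @param params a \code{krn_params}.
#' @param canvas a \code{canvas}; directional/integrated models require a
#'   derived polarity field.
#' @return an object of class \code{specified_growth}: per-triangle
#'   \code{k_par}, \code{k_per}, \code{k_nor}, \code{anisotropy} and unit
#'   \code{direction} (rows).
#' @export
evaluate_krn <- function(params, canvas) {
  stopifnot(inherits(params, "krn_params"), inherits(canvas, "canvas") ||
              is.list(canvas))
  nt <- nrow(canvas$triangles)
  i_mid <- if (params$use_mid) factor_on_triangles(canvas, "mid") else rep(0, nt)
  i_stk <- if (params$use_stk) factor_on_triangles(canvas, "stk") else rep(0, nt)
  i_ven <- if (params$use_ven) factor_on_triangles(canvas, "ven") else rep(0, nt)

  needs_dir <- params$model_kind %in% c("directional", "integrated")
  if (needs_dir && (is.null(canvas$polarity) || !any(canvas$polarity_ok)))
    stop(params$model_kind, " model requires a derived polarity field")

  b <- params$b_planar
  if (params$model_kind == "areal") {
    k_par <- b * pro(params$p_mid, i_mid) * inh(params$h_stk, i_stk) *
      pro(params$p_ven, i_ven)
    k_per <- k_par
    k_nor <- rep(params$b_thickness, nt)
  } else if (params$model_kind == "directional") {
    k_par <- b * pro(params$p_mid, i_mid) * inh(params$h_stk, i_stk) *
      pro(params$p_ven, i_ven)
    k_par <- pmin(2 * b, k_par)
    k_per <- 2 * b - k_par
    k_nor <- rep(params$b_thickness, nt)
  } else {
    i_ven_thr <- threshold_factor(i_ven, params$t_ven)
    k_par <- b * pro(params$p_mid, i_mid) * inh(params$h_stk, i_stk) *
      pro(params$p_ven, i_ven)
    k_per <- b * inh(params$h_stk, i_stk) * inh(params$h_ven, i_ven_thr)
    k_nor <- rep(params$b_thickness, nt)
  }
  if (params$p_th > 0) {
    i_ven_thr <- threshold_factor(i_ven, params$t_ven)
    k_nor <- params$b_thickness * pro(params$p_th, i_stk) *
      pro(params$p_th, i_ven_thr)
  }

  if (needs_dir) {
    direction <- canvas$polarity
    iso <- !canvas$polarity_ok
    if (any(iso)) {
      # isotropic-only triangles: no anisotropy can be expressed there
      mean_rate <- (k_par[iso] + k_per[iso]) / 2
      k_par[iso] <- mean_rate
      k_per[iso] <- mean_rate
      direction[iso, ] <- default_tangent(canvas)[iso, , drop = FALSE]
    }
  } else {
    direction <- default_tangent(canvas)
  }

  structure(list(
    k_par = k_par, k_per = k_per, k_nor = k_nor,
    anisotropy = (k_par - k_per) / (k_par + k_per),
    direction = direction
  ), class = "specified_growth")
}

# arbitrary unit tangent per triangle (first edge), for isotropic models
default_tangent <- function(canvas) {
  v <- canvas$vertices; f <- canvas$triangles
  normalize_rows(v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE])
}
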