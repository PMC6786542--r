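test_that("strain-rate fitting is exact on noiseless exponential data", {
  gs <- growth_series(time_d = 0:7, length_um = 10 * exp(0.018 * 24 * (0:7)))
  f <- suppressWarnings(fit_strain_rate(gs))  # lm flags the perfect fit
  expect_equal(f$rate, 0.018, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)
  const <- growth_series(time_d = 0:5, length_um = rep(100, 6))
  expect_equal(suppressWarnings(fit_strain_rate(const))$rate, 0)
  expect_error(fit_strain_rate(growth_series(0:1, c(10, 12))), "at least 3")
  expect_error(growth_series(0:2, c(1, -1, 2)), "positive")
})

test_that("staging inverts the exponential growth law", {
  expect_equal(round(stage_from_length(139), 1), 6.1)
  expect_equal(round(stage_from_length(55)), 4)
  expect_equal(stage_from_length(10), 0)
  # exact inverse at machine precision, for a range of stages
  d <- c(0, 0.5, 2, 4, 6.1, 10.4)
  expect_equal(stage_from_length(10 * exp(0.018 * 24 * d)), d, tolerance = 1e-12)
  expect_error(stage_from_length(5), "initiation")
  # fixed specimens are corrected upward before staging
  expect_gt(stage_from_length(139, fixed = TRUE), stage_from_length(139))
  expect_equal(stage_from_length(139, fixed = TRUE),
               log(139 * 1.0578 / 10) / (0.018 * 24))
})

test_that("circumference extraction matches analytic perimeters", {
  cv <- small_canvas(3)
  for (plane in c("sagittal", "frontal", "transverse")) {
    res <- extract_circumference(cv, plane)
    expect_equal(res$length, pi * 100, tolerance = 0.01)
  }
  sub <- extract_circumference(cv, "sagittal")$subdomains
  expect_equal(unname(sub["ventral_midline"] + sub["dorsal_midline"] +
                        sub["mouth"]),
               extract_circumference(cv, "sagittal")$length, tolerance = 1e-9)
  # oblate spheroid: scale a sphere canvas into semi-axes a = b = 60, c = 40;
  # oracle: numeric ellipse perimeter
  ell <- cv
  scale <- diag(c(60 / 50, 60 / 50, 40 / 50))
  ell$vertices <- cv$vertices %*% scale
  ell$nodes_top <- cv$nodes_top %*% scale
  ell$nodes_bot <- cv$nodes_bot %*% scale
  expect_equal(extract_circumference(ell, "transverse")$length, 2 * pi * 60,
               tolerance = 0.01)
  expect_equal(extract_circumference(ell, "sagittal")$length,
               ellipse_perimeter(60, 40), tolerance = 0.01)
  expect_equal(extract_circumference(ell, "frontal")$length,
               ellipse_perimeter(60, 40), tolerance = 0.01)
})

test_that("clone metrics reproduce constructed patches", {
  # 3 x 2 brick of unit squares: clone 1.5, cell-number 1.5, cell-shape 1.0
  sq <- function(i, j) cbind(c(i, i + 1, i + 1, i), c(j, j, j + 1, j + 1), 0)
  brick <- lapply(seq_len(6), function(k)
    sq((k - 1) %% 3, (k - 1) %/% 3))
  lay <- trapmorph:::static_cell_layer(brick, clone = 1L)
  cm <- clone_metrics(lay, min_cells = 3, max_cells = 30)
  expect_equal(cm$clone_anisotropy, 1.5, tolerance = 1e-9)
  expect_equal(cm$cell_number_anisotropy, 1.5, tolerance = 1e-9)
  expect_equal(cm$cell_shape_anisotropy, 1.0, tolerance = 1e-9)
  # single row of four 2:1 cells aligned with the row: clone 8/1,
  # cells along axes 4 and 1, so cell-shape anisotropy 2.0
  row4 <- lapply(0:3, function(k)
    cbind(c(2 * k, 2 * k + 2, 2 * k + 2, 2 * k), c(0, 0, 1, 1), 0))
  lay2 <- trapmorph:::static_cell_layer(row4, clone = 1L)
  cm2 <- clone_metrics(lay2, min_cells = 3, max_cells = 30)
  expect_equal(cm2$clone_anisotropy, 8, tolerance = 1e-9)
  expect_equal(cm2$cells_major, 4)
  expect_equal(cm2$cells_minor, 1)
  expect_equal(cm2$cell_shape_anisotropy, 2.0, tolerance = 1e-9)
  # identity: clone anisotropy = cell-number x cell-shape, exactly
  for (cmx in list(cm, cm2))
    expect_identical(cmx$clone_anisotropy,
                     cmx$cell_number_anisotropy * cmx$cell_shape_anisotropy)
})

test_that("clone size selection and error handling behave", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0)
  lay <- trapmorph:::static_cell_layer(list(sq), clone = 1L)
  expect_equal(nrow(clone_metrics(lay, min_cells = 3)), 0)  # too small
  lay2 <- trapmorph:::static_cell_layer(list(sq))
  expect_error(clone_metrics(lay2), "no clones")
})

test_that("group summaries report means and standard errors per region", {
  m <- data.frame(region = rep(c("lamina", "ventral_midline"), c(3, 2)),
                  clone_anisotropy = c(2, 2, 2, 4, 6),
                  cell_number_anisotropy = c(1, 1, 1, 2, 2),
                  cell_shape_anisotropy = c(2, 2, 2, 2, 3))
  expect_warning(gs <- group_summary(m), "dorsal_midline")
  lam <- gs[gs$region == "lamina" & gs$measure == "clone", ]
  expect_equal(lam$mean, 2)
  expect_equal(lam$se, 0)   # identical clones
  vm <- gs[gs$region == "ventral_midline" & gs$measure == "clone", ]
  expect_equal(vm$mean, 5)
  expect_equal(vm$se, sd(c(4, 6)) / sqrt(2))
  # recovery: lognormal anisotropies, mean recovered within 2 SE
  set.seed(21)
  vals <- exp(rnorm(60, log(2), 0.3))
  m2 <- data.frame(region = "lamina", clone_anisotropy = vals,
                   cell_number_anisotropy = 1, cell_shape_anisotropy = vals)
  g2 <- suppressWarnings(group_summary(m2))
  cl <- g2[g2$measure == "clone", ]
  expect_lt(abs(cl$mean - mean(vals)), 1e-12)
  expect_lt(abs(cl$mean - exp(log(2) + 0.3^2 / 2)), 2 * cl$se)
})

test_that("material midline metrics agree with uniform growth", {
  cv <- small_canvas(2)
  p <- krn_params("areal", b_planar = 0.01, p_mid = 0, b_thickness = 0.01,
                  use_mid = FALSE)
  tr <- run_simulation(cv, p, t_start = 0, t_end = 10,
                       config = solver_config(dt = 2))
  m <- trap_midline_metrics(tr)
  expect_equal(m$sagittal_rate, 0.01, tolerance = 0.001)
  expect_equal(m$ventral_rate, 0.01, tolerance = 0.001)
  expect_equal(m$dorsal_rate, 0.01, tolerance = 0.001)
})
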