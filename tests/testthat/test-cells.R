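test_that("tiling reaches the target mean area deterministically", {
  cv <- small_canvas(3)
  lay <- cached("tiled50", tile_cells(cv, 50, seed = 7))
  a <- cell_areas(lay, cv)
  expect_equal(mean(a), 50, tolerance = 0.1)   # within 10 percent
  expect_gt(mean(a), 45); expect_lt(mean(a), 55)
  lay2 <- tile_cells(cv, 50, seed = 7)
  expect_identical(lay$polys, lay2$polys)
  lay3 <- tile_cells(cv, 50, seed = 8)
  expect_false(identical(lay$polys, lay3$polys))
  # degenerate target: a closed surface cannot be one simple polygon
  expect_error(tile_cells(cv, canvas_area(cv) * 2), "cannot tessellate")
})

test_that("a competent threshold-size cell divides into equal daughters", {
  # planar 70 um^2 rectangle: symmetric division through the centroid
  rect70 <- cbind(c(0, 14, 14, 0), c(0, 0, 5, 5), 0)
  lay <- trapmorph:::static_cell_layer(list(rect70))
  lay <- trapmorph:::divide_cell(lay, NULL, 1, division_rule(jitter_deg = 0))
  a <- cell_areas(lay)
  expect_equal(sort(a), c(35, 35))
  expect_identical(sum(a), 70)  # exact area conservation
  # daughters inherit lineage and clone marks
  lay2 <- trapmorph:::static_cell_layer(list(rect70), clone = 42L)
  lay2 <- trapmorph:::divide_cell(lay2, NULL, 1, division_rule(jitter_deg = 0))
  expect_equal(lay2$cells$clone, c(42L, 42L))
  expect_equal(lay2$cells$lineage, c(1L, 1L))
})

test_that("division respects competence in space and time", {
  cv <- small_canvas(2)
  lay <- cached("tiled_small", tile_cells(cv, 400, seed = 3))
  rule <- division_rule(threshold_area = 100, jitter_deg = 0)
  # everything is far above threshold, so competent cells divide...
  n0 <- nrow(lay$cells)
  lay1 <- step_cells(lay, cv, cv, rule, t = 100)
  expect_gt(nrow(lay1$cells), n0)
  # ...but not after the competence end time (6.5 DAI = 156 h)
  lay2 <- step_cells(lay, cv, cv, rule, t = 157)
  expect_equal(nrow(lay2$cells), n0)
  # ...and never in the stalk region
  cvs <- cv
  cvs$factors$stk <- rep(1, nrow(cv$vertices))
  lays <- tile_cells(cvs, 400, seed = 3)
  expect_true(all(!lays$cells$cdiv))
  lay3 <- step_cells(lays, cvs, cvs, rule, t = 100)
  expect_equal(nrow(lay3$cells), nrow(lays$cells))
  # divisions are deterministic given the rule seed
  lay4 <- step_cells(lay, cv, cv, rule, t = 100)
  expect_identical(lay1$polys, lay4$polys)
})

test_that("clone induction marks the expected fraction heritably", {
  cv <- small_canvas(2)
  lay <- cached("tiled_small", tile_cells(cv, 400, seed = 3))
  n <- nrow(lay$cells)
  lay1 <- induce_clones(lay, 0.4, seed = 2)
  k <- sum(!is.na(lay1$cells$clone))
  ci <- qbinom(c(0.005, 0.995), n, 0.4)
  expect_gte(k, ci[1]); expect_lte(k, ci[2])
  expect_identical(induce_clones(lay, 0.4, seed = 2)$cells$clone,
                   lay1$cells$clone)
  expect_error(induce_clones(lay, 0), "fraction")
})

test_that("second-moment anisotropy matches exact and oracle values", {
  # 2:1 rectangle: a = 1/3 exactly, at any triangulated resolution
  rect <- cbind(c(0, 2, 2, 0), c(0, 0, 1, 1), 0)
  m <- cell_shape_metrics(trapmorph:::static_cell_layer(list(rect)))
  expect_equal(m$anisotropy, 1 / 3, tolerance = 1e-12)
  expect_equal(m$aspect, 2, tolerance = 1e-12)
  # regular hexagon: isometric, a = 0
  th <- 2 * pi * (0:5) / 6
  hexpoly <- cbind(cos(th), sin(th), 0)
  mh <- cell_shape_metrics(trapmorph:::static_cell_layer(list(hexpoly)))
  expect_lt(mh$anisotropy, 1e-6)
  # arbitrary polygon vs dense rasterisation oracle
  set.seed(4)
  ang <- sort(runif(7, 0, 2 * pi))
  rad <- runif(7, 0.5, 1.5)
  poly <- cbind(rad * cos(ang), rad * sin(ang))
  mp <- cell_shape_metrics(trapmorph:::static_cell_layer(list(cbind(poly, 0))))
  orc <- raster_moments(poly, n = 600)
  ev <- eigen(orc$m, symmetric = TRUE)$values
  r <- sqrt(ev[1] / ev[2])
  expect_equal(mp$anisotropy, (r - 1) / (r + 1), tolerance = 1e-3)
  expect_equal(mp$area, orc$area, tolerance = 0.01)
})

test_that("anisotropy is invariant to rigid motion and uniform scaling", {
  set.seed(9)
  ang <- sort(runif(6, 0, 2 * pi))
  poly <- cbind(1.5 * cos(ang), 0.7 * sin(ang), 0)
  a0 <- cell_shape_metrics(trapmorph:::static_cell_layer(list(poly)))$anisotropy
  th <- 0.9
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- sweep(3.7 * poly %*% rot, 2, c(5, -2, 8), `+`)
  a1 <- cell_shape_metrics(trapmorph:::static_cell_layer(list(moved)))$anisotropy
  expect_equal(a1, a0, tolerance = 1e-10)
})

test_that("curved-surface divisions conserve area to discretisation accuracy", {
  cv <- small_canvas(2)
  lay <- cached("tiled_small", tile_cells(cv, 400, seed = 3))
  i <- which.max(cell_areas(lay, cv))
  a0 <- cell_areas(lay, cv)[i]
  lay1 <- trapmorph:::divide_cell(lay, cv, i, division_rule(jitter_deg = 0))
  a1 <- cell_areas(lay1, cv)
  daughters <- which(lay1$cells$parent %in% lay$cells$id[i])
  # exact for planar polygons; curvature of the large test cell allows ~0.5%
  expect_equal(sum(a1[daughters]), a0, tolerance = 5e-3)
})
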