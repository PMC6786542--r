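test_that("conflict-free uniform growth of a sphere achieves its specification", {
  cv <- small_canvas(2)
  g <- 0.01
  gr <- uniform_growth(cv, g)
  cv1 <- growth_step(cv, gr, solver_config(dt = 1))
  ratio <- edge_lengths(cv1) / edge_lengths(cv)
  expect_true(all(abs(ratio - exp(g)) < 0.001 * exp(g)))
  # shape remains spherical; thickness follows K_nor
  r <- trapmorph:::row_norms(cv1$vertices)
  expect_lt(diff(range(r)) / mean(r), 1e-8)
  expect_equal(mean(cv1$thickness), 30 * exp(g), tolerance = 1e-6)
  # residual energy vanishes for compatible growth
  expect_lt(abs(attr(cv1, "residual_energy")),
            1e-8 * attr(cv1, "specified_energy"))
})

test_that("a flat free patch under uniform anisotropic growth stretches affinely", {
  cv <- make_patch_canvas(6, 6, 10, 1)
  k_par <- 0.03
  k_per <- 0.01
  gr <- uniform_growth(cv, k_par, k_per, 0.005, direction = c(1, 0, 0))
  cv1 <- growth_step(cv, gr, solver_config(dt = 1))
  # closed-form oracle: the affine map diag(exp(k_par), exp(k_per))
  x_ext <- diff(range(cv1$vertices[, 1])) / diff(range(cv$vertices[, 1]))
  y_ext <- diff(range(cv1$vertices[, 2])) / diff(range(cv$vertices[, 2]))
  expect_equal(x_ext, exp(k_par), tolerance = 0.005)
  expect_equal(y_ext, exp(k_per), tolerance = 0.005)
  # every edge follows the same affine map
  aff <- cv$vertices %*% diag(c(exp(k_par), exp(k_per), 1))
  aff <- sweep(aff, 2, colMeans(aff))
  got <- sweep(cv1$vertices, 2, colMeans(cv1$vertices))
  expect_lt(max(trapmorph:::row_norms(got - aff)), 0.005 * 10)
})

test_that("zero growth leaves the canvas unchanged", {
  cv <- small_canvas(2)
  gr <- uniform_growth(cv, 0, 0, 0)
  cv1 <- growth_step(cv, gr, solver_config(dt = 1))
  expect_equal(cv1$vertices, cv$vertices, tolerance = 1e-10)
  tr <- run_simulation(cv, krn_params("areal", b_planar = 1e-12, p_mid = 0,
                                      b_thickness = 0, use_mid = FALSE),
                       t_start = 96, t_end = 100, config = solver_config(dt = 1))
  last <- tr$snapshots[[length(tr$snapshots)]]
  expect_equal(last$vertices, cv$vertices, tolerance = 1e-6)
})

test_that("the solved deformation never exceeds the unrelaxed residual energy", {
  tr <- small_run("fig6EH", level = 2, dt = 2, t_end = 130)
  expect_true(all(tr$energies$residual <= tr$energies$specified))
  expect_true(all(tr$energies$residual >= -1e-8 * tr$energies$specified))
})

test_that("conflict-free results are insensitive to the Poisson ratio", {
  cv <- small_canvas(2)
  gr <- uniform_growth(cv, 0.01)
  a <- growth_step(cv, gr, solver_config(dt = 1, poisson_ratio = 0.3))
  b <- growth_step(cv, gr, solver_config(dt = 1, poisson_ratio = 0))
  expect_equal(a$vertices, b$vertices, tolerance = 1e-6)
})

test_that("symmetric inputs give mirror-symmetric outputs", {
  cv <- small_canvas(2, polarity = TRUE)
  tr <- run_simulation(cv, krn_preset("fig6MP"), t_start = 96, t_end = 116,
                       config = solver_config(dt = 2))
  vf <- tr$snapshots[[length(tr$snapshots)]]$vertices
  mm <- mirror_map(cv)
  asym <- sqrt(rowSums((vf - cbind(vf[mm, 1], -vf[mm, 2], vf[mm, 3]))^2))
  expect_lt(max(asym) / max(trapmorph:::row_norms(vf)), 0.005)
})

test_that("strain measurement recovers uniform growth rates", {
  cv <- small_canvas(2)
  p <- krn_params("areal", b_planar = 0.01, p_mid = 0, b_thickness = 0.01,
                  use_mid = FALSE)
  tr <- run_simulation(cv, p, t_start = 0, t_end = 10,
                       config = solver_config(dt = 1))
  all_tris <- rep(TRUE, nrow(cv$triangles))
  expect_equal(resultant_strain(tr, all_tris, direction = "areal"), 0.02,
               tolerance = 0.001)
  expect_equal(resultant_strain(tr, all_tris, direction = "parallel"), 0.01,
               tolerance = 0.001)
  expect_error(resultant_strain(tr, rep(FALSE, nrow(cv$triangles))), "empty")
})

test_that("per-step strain warning triggers for oversized time steps", {
  cv <- small_canvas(2)
  gr <- uniform_growth(cv, 0.05)
  expect_warning(growth_step(cv, gr, solver_config(dt = 2)), "reduce dt")
})

test_that("seeded perturbation is reproducible and off by default", {
  cv <- small_canvas(2)
  p <- krn_params("areal", b_planar = 0.01, p_mid = 0, b_thickness = 0.01,
                  use_mid = FALSE)
  t1 <- run_simulation(cv, p, t_start = 0, t_end = 4,
                       config = solver_config(dt = 2, perturbation = 0.5, seed = 3))
  t2 <- run_simulation(cv, p, t_start = 0, t_end = 4,
                       config = solver_config(dt = 2, perturbation = 0.5, seed = 3))
  expect_equal(t1$snapshots[[2]]$vertices, t2$snapshots[[2]]$vertices)
  t3 <- run_simulation(cv, p, t_start = 0, t_end = 4,
                       config = solver_config(dt = 2))
  expect_false(isTRUE(all.equal(t1$snapshots[[2]]$vertices,
                                t3$snapshots[[2]]$vertices)))
})
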