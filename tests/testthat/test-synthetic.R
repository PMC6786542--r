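test_that("growth series generator has the stated exponential structure", {
  gs <- gen_growth_series(rate = 0.018, l0 = 150, days = 8, noise_sigma = 0,
                          n_subjects = 1, seed = 1)
  expect_equal(nrow(gs), 8)
  f <- suppressWarnings(fit_strain_rate(gs))  # lm flags the perfect fit
  expect_equal(f$rate, 0.018, tolerance = 1e-12)
  expect_identical(gen_growth_series(seed = 3), gen_growth_series(seed = 3))
  expect_false(identical(gen_growth_series(seed = 3), gen_growth_series(seed = 4)))
  # noisy recovery: pooled slope within 2 SE of the generating rate
  gs2 <- gen_growth_series(0.018, 150, 8, 0.05, n_subjects = 20, seed = 6)
  f2 <- fit_strain_rate(gs2)
  expect_lt(abs(f2$rate - 0.018), f2$two_se)
})

test_that("quadrifid generator ground truth is recovered by the scorer", {
  qf <- gen_quadrifid_field(n = 40, splay_diff = 6, arm_bias = 0.2,
                            angular_noise = 0, seed = 2)
  gl <- lapply(qf$glands, assign_polarity)
  hit <- mapply(function(q, i) {
    isTRUE(q$assigned) &&
      sum(q$polarity * as.numeric(qf$truth[i, c("pol_x", "pol_y", "pol_z")])) > 0.99
  }, gl, seq_along(gl))
  expect_true(all(hit))
  # splay below the 2 um threshold: every gland axiality-only
  qf2 <- gen_quadrifid_field(n = 30, splay_diff = 1, seed = 2)
  gl2 <- lapply(qf2$glands, assign_polarity)
  expect_true(all(!vapply(gl2, `[[`, logical(1), "assigned")))
  expect_true(all(vapply(gl2, `[[`, logical(1), "pairable")))
  # noise below half the splay difference still recovers every polarity
  qf3 <- gen_quadrifid_field(n = 40, splay_diff = 6, angular_noise = 5, seed = 9)
  gl3 <- lapply(qf3$glands, assign_polarity)
  al <- summarize_field(gl3, qf3$stalk_point, qf3$mouth_point)
  expect_equal(unname(al$counts["aligned"]), 40)
})

test_that("angular noise produces the aligned fraction the model implies", {
  # axis noise ~ N(0, 30 deg): P(aligned) = P(|theta| < 90) ~ 0.9973
  qf <- gen_quadrifid_field(n = 200, splay_diff = 6, angular_noise = 30,
                            seed = 7)
  gl <- lapply(qf$glands, assign_polarity)
  sm <- summarize_field(gl, qf$stalk_point, qf$mouth_point)
  p <- 2 * pnorm(90 / 30) - 1
  ci <- qbinom(c(0.005, 0.995), 200, p)
  expect_gte(sm$counts[["aligned"]], ci[1])
  expect_lte(sm$counts[["aligned"]], ci[2])
})

test_that("labelled surfaces realise the requested shape statistics", {
  # 2:1 cells: mean measured anisotropy near 1/3
  l2 <- gen_labelled_surface(n_cells = 200, aspect_ratio = 2, area_cv = 0.05,
                             seed = 4)
  m2 <- cell_shape_metrics(l2)
  expect_lt(abs(mean(m2$anisotropy) - 1 / 3), 0.05)
  # isotropic tessellation: mean anisotropy below 0.05
  l1 <- gen_labelled_surface(n_cells = 200, aspect_ratio = 1, area_cv = 0.05,
                             seed = 4)
  expect_lt(mean(cell_shape_metrics(l1)$anisotropy), 0.05)
  # area coefficient of variation within 20 percent of the request
  l3 <- gen_labelled_surface(n_cells = 400, aspect_ratio = 1, area_cv = 0.3,
                             seed = 5)
  a <- cell_areas(l3)
  expect_lt(abs(sd(a) / mean(a) - 0.3), 0.2 * 0.3)
  # generators are pure functions of (config, seed)
  expect_identical(gen_labelled_surface(seed = 8), gen_labelled_surface(seed = 8))
  # orientation field: long axes follow the requested direction
  l4 <- gen_labelled_surface(n_cells = 150, aspect_ratio = 2, orientation = 40,
                             area_cv = 0.05, seed = 6)
  m4 <- cell_shape_metrics(l4)
  angs <- atan2(m4$axis_y, m4$axis_x) * 180 / pi
  angs <- ((angs - 40) + 90) %% 180 - 90
  expect_lt(mean(abs(angs)), 5)
  # spherical cap wrapping keeps areas approximately
  l5 <- gen_labelled_surface(n_cells = 100, patch = "cap", cap_radius = 300,
                             seed = 3)
  expect_equal(mean(cell_areas(l5)), 50, tolerance = 0.05)
})
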