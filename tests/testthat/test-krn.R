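test_that("pro, inh and threshold operators follow their definitions", {
  expect_equal(pro(0.165, 1), 1.165)
  expect_equal(pro(5, 0), 1)
  expect_equal(pro(0.35, 0.5), 1.175)
  expect_equal(inh(1.4, 1), 1 / 2.4)
  expect_equal(inh(7, 0), 1)
  expect_equal(inh(1.5, 1), 0.4)
  fld <- c(0, 0.005, 0.02, 0.9)
  expect_equal(threshold_factor(fld, 0.01), c(0, 0, 1, 1))
  expect_equal(threshold_factor(fld, 1), rep(0, 4))
  bin <- c(0, 1, 1, 0)
  expect_equal(threshold_factor(bin, 0.5), bin)  # idempotent on 0/1 fields
  expect_error(threshold_factor(fld, 2), "threshold")
})

test_that("KRN evaluation reproduces the printed rate equations", {
  cv <- small_canvas(2, polarity = TRUE)
  nv <- nrow(cv$vertices)
  # force factor levels so the printed point evaluations apply everywhere
  at_levels <- function(mid, stk, ven) {
    cc <- cv
    cc$factors$mid <- rep(mid, nv)
    cc$factors$stk <- rep(stk, nv)
    cc$factors$ven <- rep(ven, nv)
    cc
  }
  # areal MID-only at i_mid = 1: K = 0.0145 * 1.165, areal rate 0.033785
  g <- evaluate_krn(krn_preset("fig4AF"), at_levels(1, 0, 0))
  expect_equal(unique(g$k_par), 0.0145 * 1.165)
  expect_equal(unique(g$k_par + g$k_per), 0.033785)
  expect_equal(unique(g$k_nor), 0.005)
  # directional at i_mid = 1, i_stk = i_ven = 0
  g <- evaluate_krn(krn_preset("fig6IL"), at_levels(1, 0, 0))
  expect_equal(unique(g$k_par), 0.02025)
  expect_equal(unique(g$k_per), 0.00975)
  expect_equal(unique(g$anisotropy), 0.35, tolerance = 1e-12)
  # directional at i_stk = 1, i_mid = 1 (hand-evaluated oracle)
  g <- evaluate_krn(krn_preset("fig6EH"), at_levels(1, 1, 0))
  expect_equal(unique(g$k_par), 0.015 * 1.35 * 0.4)
  expect_equal(unique(g$k_per), 0.03 - 0.0081)
  expect_equal(unique(g$anisotropy), (0.0081 - 0.0219) / 0.03)
  # integrated: separable regulation with thresholded VEN on K_per
  g <- evaluate_krn(krn_preset("fig6MP"), at_levels(1, 0, 0.5))
  expect_equal(unique(g$k_par), 0.015 * 1.35 * 1.25)
  expect_equal(unique(g$k_per), 0.015 / 1.8)  # i_ven 0.5 > t_ven -> 1
  # thickness variant
  g <- evaluate_krn(krn_preset("s3_thickness"), at_levels(0, 1, 1))
  expect_equal(unique(g$k_nor), 0.005 * 1.5 * 1.5)
})

test_that("directional conservation and clamp hold on real canvases", {
  cv <- small_canvas(3, polarity = TRUE)
  for (preset in c("fig6AD", "fig6EH", "fig6IL")) {
    p <- krn_preset(preset)
    g <- evaluate_krn(p, cv)
    expect_lt(max(abs(g$k_par + g$k_per - 2 * p$b_planar)), 1e-12)
    expect_true(all(g$k_par <= 2 * p$b_planar + 1e-15))
    expect_true(all(g$k_par >= 0 & g$k_per >= 0))
    expect_true(all(abs(g$anisotropy) <= 1))
  }
})

test_that("promotion and inhibition coefficients act monotonically", {
  cv <- small_canvas(3, polarity = TRUE)
  base <- krn_preset("fig6MP")
  g0 <- evaluate_krn(base, cv)
  up <- base; up$p_mid <- base$p_mid * 2
  expect_true(all(evaluate_krn(up, cv)$k_par >= g0$k_par - 1e-15))
  hi <- base; hi$h_stk <- base$h_stk * 2; hi$use_stk <- TRUE
  expect_true(all(evaluate_krn(hi, cv)$k_par <= g0$k_par + 1e-15))
  expect_true(all(evaluate_krn(hi, cv)$k_per <= g0$k_per + 1e-15))
})

test_that("presets carry the printed parameters and round-trip through JSON", {
  p <- krn_preset("fig4AF")
  expect_equal(c(p$b_planar, p$p_mid, p$b_thickness), c(0.0145, 0.165, 0.005))
  expect_equal(krn_preset("fig4GJ")$h_stk, 1.4)
  expect_equal(krn_preset("fig4KN")$p_ven, 0.2)
  p6 <- krn_preset("fig6MP")
  expect_equal(c(p6$b_planar, p6$p_mid, p6$h_stk, p6$p_ven, p6$h_ven, p6$t_ven),
               c(0.015, 0.35, 1.5, 0.5, 0.8, 0.01))
  expect_equal(krn_preset("s3_thickness")$p_th, 0.5)
  st <- species_preset("terminal")
  expect_equal(c(st$p_mid, st$p_ven), c(0.05, 1.25))
  sb <- species_preset("basal")
  expect_equal(c(sb$p_mid, sb$p_ven), c(0.45, 0.1))
  expect_equal(species_preset("lateral")[], krn_preset("fig6MP")[])
  expect_error(krn_preset("fig99"), "unknown")
  # configuration round-trip
  tf <- tempfile(fileext = ".json")
  write_config(p6, tf, solver = solver_config(dt = 0.5))
  back <- read_config(tf)
  expect_equal(back$krn[], p6[])
  expect_equal(back$solver$dt, 0.5)
})

test_that("isotropic growth is independent of the bookkeeping direction", {
  cv <- small_canvas(2)
  g <- evaluate_krn(krn_preset("fig4AF"), cv)
  set.seed(5)
  g2 <- g
  g2$direction <- trapmorph:::normalize_rows(matrix(rnorm(3 * nrow(cv$triangles)), ncol = 3))
  a <- growth_step(cv, g, solver_config(dt = 1))
  b <- growth_step(cv, g2, solver_config(dt = 1))
  expect_equal(a$vertices, b$vertices, tolerance = 1e-9)
})
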