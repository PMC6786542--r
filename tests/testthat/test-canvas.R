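test_that("sphere canvas geometry matches the analytic sphere", {
  cv <- cached("canvas4bare", build_sphere_canvas(100, 30, 4))
  expect_equal(canvas_area(cv), 4 * pi * 50^2, tolerance = 0.01)
  expect_true(all(cv$thickness == 30))
  r <- trapmorph:::row_norms(cv$vertices)
  expect_true(all(abs(r - 50) < 0.005 * 50))
  # closed, orientable mesh: every edge shared by exactly two triangles
  f <- cv$triangles
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  expect_true(all(table(ekey) == 2))
  # outward orientation
  n <- trapmorph:::tri_normals(cv$vertices, f)
  ctr <- trapmorph:::tri_centroids(cv$vertices, f)
  expect_true(all(rowSums(n * ctr) > 0))
})

test_that("landmarks are resolution invariant and parameters validated", {
  cv2 <- build_sphere_canvas(100, 30, 2)
  cv4 <- cached("canvas4bare", build_sphere_canvas(100, 30, 4))
  # landmark positions agree up to the coarse mesh's vertex spacing
  h2 <- max(edge_lengths(cv2))
  for (nm in names(cv2$landmarks)) {
    d <- sqrt(sum((cv2$vertices[cv2$landmarks[[nm]], ] -
                     cv4$vertices[cv4$landmarks[[nm]], ])^2))
    expect_lt(d, h2)
  }
  expect_equal(nrow(cv2$triangles), 320)
  expect_equal(nrow(cv4$triangles), 5120)
  expect_error(build_sphere_canvas(-1, 30), "invalid parameter")
  expect_error(build_sphere_canvas(100, 0), "invalid parameter")
  expect_error(build_sphere_canvas(100, 60), "invalid parameter")
  expect_error(build_sphere_canvas(100, 30, 1), "subdivision_level")
})

test_that("factor seeding gives graded fields with the right supports", {
  cv <- small_canvas(3)
  v <- cv$vertices
  u <- v / trapmorph:::row_norms(v)
  polar <- acos(pmin(pmax(-u[, 3], -1), 1)) * 180 / pi
  # midline: max 1 on the sagittal band, decreasing with distance from it
  expect_equal(max(cv$factors$mid), 1)
  band <- abs(v[, 2])
  bins <- cut(band, seq(0, max(band) + 1, by = 6))
  mid_by_bin <- tapply(cv$factors$mid, bins, mean)
  mid_by_bin <- mid_by_bin[!is.na(mid_by_bin)]
  expect_true(all(diff(mid_by_bin) < 0))
  # stalk support: only within the cap plus its spread margin
  margin <- 5 * 10  # five length scales
  cap_dist <- (polar - cv$config$stalk_extent) * pi / 180 * 50
  expect_true(all(cv$factors$stk[cap_dist > margin] < 0.01))
  expect_true(all(cv$factors$stk[polar <= cv$config$stalk_extent] > 0.9))
  # ventral support: only near the stalk-to-mouth portion of the midline band
  strong <- cv$factors$ven > 0.5
  expect_true(all(v[strong, 1] > 0))
  expect_true(all(polar[strong] > 5 & polar[strong] < 65))
  expect_error(seed_factor(cv, factor_spec("mid", region = "nowhere")),
               "unknown region")
})

test_that("factor fields are mirror symmetric and refinement stable", {
  cv2 <- small_canvas(2)
  cv3 <- small_canvas(3)
  mm <- mirror_map(cv3)
  for (nm in names(cv3$factors))
    expect_lt(max(abs(cv3$factors[[nm]] - cv3$factors[[nm]][mm])), 1e-10)
  # refinement invariance at matched positions (level-2 vertices exist in the
  # level-3 mesh at the same indices by construction of the subdivision)
  n2 <- nrow(cv2$vertices)
  expect_equal(cv2$vertices, cv3$vertices[seq_len(n2), ])
  for (nm in c("mid", "stk", "ven"))
    expect_lt(max(abs(cv2$factors[[nm]] - cv3$factors[[nm]][seq_len(n2)])),
              0.03)
})

test_that("polariser propagates from stalk to mouth and freezes", {
  cv <- small_canvas(3, polarity = TRUE)
  lm <- cv$landmarks
  expect_gt(cv$pol[lm[["stalk_pole"]]], 0.9)
  expect_lt(cv$pol[lm[["mouth_centre"]]], 0.05)
  # strictly decreasing along the ventral meridian path from stalk to mouth
  v <- cv$vertices
  u <- v / trapmorph:::row_norms(v)
  polar <- acos(pmin(pmax(-u[, 3], -1), 1)) * 180 / pi
  on_meridian <- which(v[, 2] == 0 & v[, 1] >= 0)
  ord <- on_meridian[order(polar[on_meridian])]
  path <- ord[polar[ord] < 68]  # up to the mouth rim
  expect_true(all(diff(cv$pol[path]) < 0))
  # polarity points from stalk towards mouth along meridians
  ctr <- trapmorph:::tri_centroids(v, cv$triangles)
  uc <- ctr / trapmorph:::row_norms(ctr)
  south <- matrix(c(0, 0, -1), nrow(uc), 3, byrow = TRUE)
  away <- -(south - uc * rowSums(uc * south))
  away <- away / trapmorph:::row_norms(away)
  polar_t <- acos(pmin(pmax(-uc[, 3], -1), 1)) * 180 / pi
  mid_band <- polar_t > 10 & polar_t < 50
  expect_true(mean(rowSums(cv$polarity[mid_band, ] * away[mid_band, ]) > 0) > 0.99)
  # unit tangent wherever defined
  n <- trapmorph:::tri_normals(v, cv$triangles)
  ok <- cv$polarity_ok
  expect_equal(trapmorph:::row_norms(cv$polarity[ok, ]), rep(1, sum(ok)))
  expect_true(max(abs(rowSums(cv$polarity[ok, ] * n[ok, ]))) < 1e-6)
})

test_that("zero polariser production flags polarity as undefined", {
  cv <- small_canvas(2)
  cv$factors$stk <- rep(0, nrow(cv$vertices))
  cv <- propagate_polariser(cv)
  expect_true(all(cv$pol == 0))
  expect_true(isTRUE(attr(cv$pol, "undefined")))
  cv <- derive_polarity(cv)
  expect_false(any(cv$polarity_ok))
  expect_error(evaluate_krn(krn_preset("fig6AD"), cv), "polarity")
})

test_that("steady diffusion-decay on a ring matches the closed form", {
  # 1D ring FEM: source clamped at node 1, uniform decay elsewhere;
  # closed form on (0, L): p(s) = cosh((L/2 - s)/l) / cosh(L/(2 l))
  n <- 400
  len <- 100
  h <- len / n
  dvals <- 20   # diffusivity
  kdec <- 0.05  # decay
  ell <- sqrt(dvals / kdec)
  i <- seq_len(n)
  nxt <- c(2:n, 1L)
  k <- Matrix::sparseMatrix(i = c(i, nxt), j = c(nxt, i), x = rep(-1 / h, 2 * n),
                            dims = c(n, n))
  k <- k + Matrix::Diagonal(n, 2 / h)
  m <- rep(h, n)
  a <- dvals * k + Matrix::Diagonal(n, m * kdec)
  free <- 2:n
  p <- numeric(n)
  p[1] <- 1
  p[free] <- as.numeric(Matrix::solve(a[free, free], -a[free, 1, drop = FALSE] * 1))
  s <- (i - 1) * h
  exact <- cosh((len / 2 - pmin(s, len - s)) / ell) / cosh(len / (2 * ell))
  expect_lt(max(abs(p - exact) / exact), 0.02)
})

test_that("polarity is equivariant under rigid rotations", {
  cv <- small_canvas(2, polarity = TRUE)
  th <- 0.7
  rot <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  cv2 <- cv
  cv2$vertices <- cv$vertices %*% t(rot)
  cv2$nodes_top <- cv$nodes_top %*% t(rot)
  cv2$nodes_bot <- cv$nodes_bot %*% t(rot)
  cv2 <- derive_polarity(cv2)
  expect_equal(cv2$polarity[cv2$polarity_ok, ],
               (cv$polarity %*% t(rot))[cv2$polarity_ok, ],
               tolerance = 1e-8)
})
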