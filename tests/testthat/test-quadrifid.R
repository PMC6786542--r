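planar_gland <- function(angles_deg, radii = rep(10, 4), centre = c(0, 0, 0)) {
  a <- angles_deg * pi / 180
  tips <- cbind(radii * cos(a), radii * sin(a), 0)
  quadrifid("g", centre, sweep(tips, 2, centre, `+`))
}

test_that("arm pairing follows the two smallest centre angles", {
  q <- planar_gland(c(0, 30, 180, 210))
  pr <- pair_arms(q)
  expect_true(pr$ok)
  got <- vapply(pr$pairs, function(p) paste(sort(p), collapse = "-"), "")
  expect_setequal(got, c("1-2", "3-4"))
  # perfectly cross-shaped gland: ambiguous ties, flagged unpairable
  qx <- planar_gland(c(0, 90, 180, 270))
  expect_false(pair_arms(qx)$ok)
  aq <- assign_polarity(qx)
  expect_false(aq$pairable)
  expect_false(aq$assigned)
  # degenerate landmarks
  expect_error(quadrifid("g", c(0, 0, 0), rbind(c(0, 0, 0), diag(3))),
               "distinct")
})

test_that("polarity points to the more splayed pair above the threshold", {
  # far pair tip distance 8, near pair 4: polarity towards the far pair
  q <- quadrifid("g", c(0, 0, 0),
                 rbind(c(-10, 2, 0), c(-10, -2, 0),   # near pair at -x
                       c(10, 4, 0), c(10, -4, 0)))    # far pair at +x
  aq <- assign_polarity(q)
  expect_true(aq$assigned)
  expect_equal(aq$dist_diff, 4)
  expect_gt(sum(aq$polarity * c(1, 0, 0)), 0.99)
  expect_equal(aq$axis, aq$polarity)  # polarity is the signed axis
  # distances 5 and 4: difference below the 2 um threshold, axiality only
  q2 <- quadrifid("g", c(0, 0, 0),
                  rbind(c(-10, 2, 0), c(-10, -2, 0),
                        c(10, 2.5, 0), c(10, -2.5, 0)))
  aq2 <- assign_polarity(q2)
  expect_false(aq2$assigned)
  expect_false(is.null(aq2$axis))
  # lowering the threshold never decreases the number of assigned glands
  aq3 <- assign_polarity(q2, quadrifid_params(threshold = 0.5))
  expect_true(aq3$assigned)
})

test_that("the combined criterion requires DistArms and SumArms to agree", {
  # far pair more splayed but with LONGER arms: the two criteria disagree
  q <- quadrifid("g", c(0, 0, 0),
                 rbind(c(-8, 1.5, 0), c(-8, -1.5, 0),    # near, short arms
                       c(14, 4, 0), c(14, -4, 0)))       # far, long arms
  d <- assign_polarity(q, quadrifid_params(criterion = "distarms"))
  s <- assign_polarity(q, quadrifid_params(criterion = "sumarms"))
  expect_true(d$assigned && s$assigned)
  expect_lt(sum(d$polarity * s$polarity), 0)  # opposite calls
  b <- assign_polarity(q, quadrifid_params(criterion = "distarms_and_sumarms"))
  expect_false(b$assigned)   # disagreement leaves axiality only
  # agreement case: far pair splayed AND shorter arms
  q2 <- quadrifid("g", c(0, 0, 0),
                  rbind(c(-12, 1.5, 0), c(-12, -1.5, 0),
                        c(8, 4, 0), c(8, -4, 0)))
  b2 <- assign_polarity(q2, quadrifid_params(criterion = "distarms_and_sumarms"))
  expect_true(b2$assigned)
})

test_that("polarity assignment is invariant to rigid motion and scaling", {
  q <- quadrifid("g", c(0, 0, 0),
                 rbind(c(-10, 2, 0), c(-10, -2, 0), c(10, 4, 0), c(10, -4, 0)))
  a0 <- assign_polarity(q)
  th <- 1.1
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  shift <- c(100, -30, 12)
  q1 <- quadrifid("g", shift, sweep(q$tips %*% rot, 2, shift, `+`))
  a1 <- assign_polarity(q1)
  expect_equal(a1$polarity, as.numeric(a0$polarity %*% rot), tolerance = 1e-9)
  # uniform scaling with the threshold co-scaled (the 2 um default is an
  # absolute length, so it must scale with the coordinates)
  s <- 0.25
  q2 <- quadrifid("g", c(0, 0, 0), q$tips * s)
  a2 <- assign_polarity(q2, quadrifid_params(threshold = 2 * s))
  expect_equal(a2$polarity, a0$polarity, tolerance = 1e-9)
  expect_equal(a2$dist_diff, a0$dist_diff * s)
})

test_that("field summaries partition the glands and bin the differences", {
  qf <- gen_quadrifid_field(n = 40, splay_diff = 6, angular_noise = 0, seed = 2)
  gl <- lapply(qf$glands, assign_polarity)
  sm <- summarize_field(gl, qf$stalk_point, qf$mouth_point)
  expect_equal(unname(sm$counts["aligned"]), 40)
  expect_equal(unname(sm$counts["anti_aligned"] + sm$counts["unassigned"]), 0)
  expect_equal(unname(sm$counts["aligned"] + sm$counts["anti_aligned"] +
                        sm$counts["unassigned"]),
               unname(sm$counts["total"]))
  expect_equal(sum(sm$histogram$count), 40)
  # mixed case: noise flips some glands, partition identity still holds
  qf2 <- gen_quadrifid_field(n = 60, splay_diff = 6, angular_noise = 80,
                             seed = 5)
  gl2 <- lapply(qf2$glands, assign_polarity)
  sm2 <- summarize_field(gl2, qf2$stalk_point, qf2$mouth_point)
  expect_equal(unname(sum(sm2$counts[1:3])), unname(sm2$counts["total"]))
  expect_gt(sm2$counts[["anti_aligned"]], 0)
})

test_that("landmark tables and the MSR dialect round-trip", {
  qf <- gen_quadrifid_field(n = 3, seed = 4)
  df <- do.call(rbind, lapply(qf$glands, function(q)
    data.frame(gland_id = q$id,
               landmark = c("centre", paste0("arm", 1:4)),
               x = c(q$centre[1], q$tips[, 1]),
               y = c(q$centre[2], q$tips[, 2]),
               z = c(q$centre[3], q$tips[, 3]))))
  tf <- tempfile(fileext = ".csv")
  utils::write.csv(df, tf, row.names = FALSE)
  back <- read_quadrifids(tf)
  expect_equal(length(back), 3)
  expect_equal(back[[1]]$tips, qf$glands[[1]]$tips, tolerance = 1e-9)
  tab <- quadrifid_table(lapply(back, assign_polarity))
  expect_true(all(tab$assigned))
  # MSR-like text dialect
  tm <- tempfile(fileext = ".msr")
  lines <- c("# gland landmarks",
             apply(df, 1, function(r)
               sprintf("%s_%s: %s %s %s", r["gland_id"], r["landmark"],
                       r["x"], r["y"], r["z"])))
  writeLines(lines, tm)
  back2 <- read_msr_landmarks(tm)
  expect_equal(length(back2), 3)
  expect_equal(back2[[1]]$centre, qf$glands[[1]]$centre, tolerance = 1e-6)
})
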