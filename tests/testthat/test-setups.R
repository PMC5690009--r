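test_that("standard setups have the prescribed geometry", {
  one <- make_setup("one_dwell")
  expect_equal(nrow(one$positions), 1L)
  expect_equal(one$positions[1, ], c(0, 0))

  short <- make_setup("short_applicator")
  expect_equal(nrow(short$positions), 6L)
  expect_equal(diff(range(short$positions[, 2])), 3.5)
  expect_equal(unique(round(diff(short$positions[, 2]), 12)), 0.7)

  long <- make_setup("long_applicator")
  expect_equal(nrow(long$positions), 19L)
  expect_equal(diff(range(long$positions[, 2])), 9)

  fl <- make_setup("fletcher")
  tandem <- fl$positions[fl$positions[, 1] == 0, ]
  expect_equal(diff(range(tandem[, 2])), 6)
  expect_equal(sum(fl$positions[, 1] != 0), 2L)   # two ovoid dwells

  multi <- make_setup("multi_applicator")
  expect_equal(length(unique(multi$positions[, 1])), 5L)
  expect_error(make_setup("short_applicator", span = -1), "positive")
})

test_that("a single-dwell plane reproduces the engine pointwise", {
  eng <- fix_engines()$reference
  grid <- plane_grid(1.5, 0.25)
  pl <- compute_dose_plane(make_setup("one_dwell"), eng, grid)
  iz <- 3; iy <- 11
  p <- cartesian_to_polar(grid$y[iy], grid$z[iz], zero_toward = "-z")
  expect_equal(pl$values[iz, iy], dose_rate(p$r, p$theta, eng),
               tolerance = 1e-13)
})

test_that("superposition is additive and weight-linear", {
  eng <- fix_engines()$reference
  grid <- plane_grid(2, 0.2)
  pos <- cbind(c(0, 0.4, -0.6, 0, 0.8, -0.2), c(-1, 0, 0.5, 1.2, -0.7, 0.9))
  all6 <- compute_dose_plane(dwell_set("six", pos), eng, grid)
  acc <- 0
  for (k in 1:6)
    acc <- acc + compute_dose_plane(
      dwell_set("one", pos[k, , drop = FALSE]), eng, grid)$values
  expect_equal(all6$values, acc, tolerance = 1e-12)

  # two co-located dwells of weight 1 double the single-dwell plane
  two <- compute_dose_plane(dwell_set("two", rbind(c(0, 0), c(0, 0))), eng, grid)
  one <- compute_dose_plane(dwell_set("one", matrix(0, 1, 2)), eng, grid)
  expect_equal(two$values, 2 * one$values, tolerance = 1e-13)
  # equivalent to doubling the weight
  w2 <- compute_dose_plane(dwell_set("w2", matrix(0, 1, 2), weights = 2),
                           eng, grid)
  expect_equal(w2$values, two$values, tolerance = 1e-13)
})

test_that("plane symmetry in z follows the anisotropy table's symmetry", {
  src <- fix_source(); g <- fix_g()
  spec_sym <- fix_spec(A_cable = 0.5, A_tip = 0.5, w_cable = 7, w_tip = 7,
                       slope_cable = 0, slope_tip = 0)
  sym_eng <- tg43_engine(src, g, make_reference_anisotropy(spec_sym))
  asym_eng <- tg43_engine(src, g, fix_dense())
  grid <- plane_grid(2, 0.2)
  one <- make_setup("one_dwell")
  flip <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]
  p_sym <- compute_dose_plane(one, sym_eng, grid)$values
  expect_equal(p_sym, flip(p_sym), tolerance = 1e-10)
  p_asym <- compute_dose_plane(one, asym_eng, grid)$values
  expect_gt(max(abs(p_asym - flip(p_asym)) / p_asym, na.rm = TRUE), 0.01)
})

test_that("percent difference planes behave as signed local differences", {
  eng <- fix_engines()$reference
  grid <- plane_grid(1, 0.25)
  pl <- compute_dose_plane(make_setup("one_dwell"), eng, grid)
  d0 <- percent_diff_plane(pl, pl)
  expect_true(all(d0$values[is.finite(d0$values)] == 0))
  p9 <- dose_plane(pl$y, pl$z, 0.9 * pl$values, pl$spacing, "0.9x")
  d9 <- percent_diff_plane(p9, pl)
  expect_equal(range(d9$values, na.rm = TRUE), c(-10, -10), tolerance = 1e-12)
})

test_that("the worst one-dwell discrepancy sits within 15 deg of a pole", {
  eng <- fix_engines()
  grid <- plane_grid(3, 0.1)
  one <- make_setup("one_dwell")
  dm <- percent_diff_plane(compute_dose_plane(one, eng$vendor, grid),
                           compute_dose_plane(one, eng$reference, grid))
  worst <- which(dm$values == min(dm$values, na.rm = TRUE), arr.ind = TRUE)
  th <- atan2(abs(dm$axis2[worst[1, 2]]), -dm$axis1[worst[1, 1]]) * 180 / pi
  expect_true(th < 15 || th > 165)
})

test_that("setup summaries match an independent two-pass computation", {
  cm <- diff_map(matrix(1.5, 3, 4), "polar", c(1, 2, 3), c(10, 20, 30, 40))
  s <- setup_summary(cm)
  expect_equal(s$mean, 1.5); expect_equal(s$median, 1.5)
  expect_equal(s$sd, 0); expect_equal(c(s$min, s$max), c(1.5, 1.5))

  s4 <- setup_summary(diff_map(matrix(1:4, 1), "polar", 1, c(1, 2, 3, 4)))
  expect_equal(s4$median, 2.5); expect_equal(s4$mean, 2.5)

  set.seed(21)
  v <- rnorm(1e4)
  sm <- setup_summary(diff_map(matrix(v, 100, 100), "polar",
                               seq_len(100), seq(1, 100)))
  mean_oracle <- sum(v) / length(v)
  sd_oracle <- sqrt(sum((v - mean_oracle)^2) / (length(v) - 1))
  expect_equal(sm$mean, mean_oracle, tolerance = 1e-10)
  expect_equal(sm$sd, sd_oracle, tolerance = 1e-10)
})

test_that("ABS reporting points evaluate by bilinear interpolation", {
  eng <- fix_engines()
  grid <- plane_grid(6, 0.1)
  fl <- make_setup("fletcher")
  pr <- compute_dose_plane(fl, eng$reference, grid)
  pv <- compute_dose_plane(fl, eng$vendor, grid)
  pts <- attr(fl, "abs_points")

  d0 <- percent_diff_plane(pr, pr)
  ev0 <- evaluate_abs_points(pts, d0)
  expect_true(all(abs(ev0$pct_diff) < 1e-12))

  dm <- percent_diff_plane(pv, pr)
  # a point coinciding with a grid node returns the node value exactly
  node <- data.frame(name = "node", y = grid$y[31], z = grid$z[41])
  evn <- evaluate_abs_points(node, dm)
  expect_equal(evn$pct_diff, dm$values[41, 31], tolerance = 1e-14)

  # named reporting points all sit below the plane's worst pole-band cell
  ev <- evaluate_abs_points(pts, dm)
  expect_true(all(is.finite(ev$pct_diff)))
  expect_true(max(abs(ev$pct_diff)) < max(abs(dm$values), na.rm = TRUE))
  expect_error(evaluate_abs_points(data.frame(name = "far", y = 99, z = 0), dm),
               "bounds")
})
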