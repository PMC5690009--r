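test_that("resampling onto a table's own axes is the identity", {
  tb <- fix_dense()
  rs <- resample_table(tb, tb$radii, tb$angles, dst_label = "self")
  expect_equal(rs$values, tb$values, tolerance = 1e-14)
  expect_match(rs$provenance, "^int-reference2self$")
})

test_that("dense -> sparse preserves shared nodes", {
  dense <- fix_dense()
  vendor <- subsample_vendor(dense)
  shared_a <- intersect(vendor$angles, dense$angles)
  shared_r <- intersect(vendor$radii, dense$radii)
  for (a in shared_a) {
    ja <- which(vendor$angles == a)
    for (r in shared_r) {
      expect_equal(vendor$values[which(vendor$radii == r), ja],
                   dense$values[which(dense$radii == r),
                                which(dense$angles == a)],
                   tolerance = 1e-14)
    }
  }
})

test_that("round-trip resampling errs worst inside the widest angular gap", {
  dense <- fix_dense()
  vendor <- subsample_vendor(dense)
  back <- resample_table(vendor, dense$radii, dense$angles, "reference")
  rel <- abs(back$values / dense$values - 1)
  gaps <- vendor_gap_bands(vendor)
  widths <- vapply(gaps, diff, numeric(1))
  widest <- gaps[[which.max(widths)]]
  worst_angle <- dense$angles[which(rel == max(rel), arr.ind = TRUE)[1, 2]]
  expect_gt(worst_angle, widest[1])
  expect_lt(worst_angle, widest[2])
})

test_that("compare_tables handles identity and uniform scaling", {
  a <- fix_dense()
  d0 <- compare_tables(a, a)
  expect_true(all(d0$values == 0))
  s0 <- summary(d0)
  expect_equal(s0$mean, 0)
  expect_equal(s0$sd, 0)

  # uniform scaling (on a table without a tabulated 90-degree column, where
  # the normalisation invariant does not pin F to 1)
  keep <- a$angles != 90
  a90 <- anisotropy_table(a$radii, a$angles[keep], a$values[, keep])
  b <- anisotropy_table(a90$radii, a90$angles, 1.02 * a90$values, "scaled")
  d2 <- compare_tables(a90, b, denominator = "a")
  expect_equal(max(d2$values), 2, tolerance = 1e-12)
  expect_equal(min(d2$values), 2, tolerance = 1e-12)
})

test_that("denominator choice relates the two comparison directions", {
  a <- fix_dense()
  b_vals <- a$values * (1 + 0.03 * sin(outer(a$radii, a$angles - 90) / 40))
  b <- anisotropy_table(a$radii, a$angles, b_vals, "perturbed")
  dab <- compare_tables(a, b, denominator = "a")
  dba <- compare_tables(b, a, denominator = "a")
  # the two comparison directions are antisymmetric up to the ratio of the
  # normalising tables
  expect_equal(dab$values, -dba$values * (b$values / a$values),
               tolerance = 1e-10)
  expect_error(compare_tables(a, fix_vendor()), "identical")
})

test_that("anisotropy extraction inverts the along-away generator", {
  eng <- fix_engines()
  aa <- make_alongaway(eng$reference)
  expect_equal(aa$n_points, 362L)
  ex <- extract_anisotropy(aa, eng$reference$source, eng$reference$g)
  truth <- anisotropy_lookup(ex$r, ex$theta, eng$dense)
  expect_true(all(abs(ex$F / truth - 1) < 1e-6))
})

test_that("extraction returns F = 1 on the transverse axis", {
  eng <- fix_engines()$reference
  aa <- make_alongaway(eng, y_values = c(1, 2, 3), z_values = c(-1, 0, 1))
  ex <- extract_anisotropy(aa, eng$source, eng$g)
  on_axis <- ex[ex$z == 0, ]
  expect_gt(nrow(on_axis), 0)
  expect_true(all(abs(on_axis$F - 1) < 1e-10))
})

test_that("extraction is homogeneous in the table values", {
  eng <- fix_engines()$reference
  aa <- make_alongaway(eng, y_values = c(0.5, 1, 2), z_values = c(-2, -1, 1, 2))
  ex1 <- extract_anisotropy(aa, eng$source, eng$g)
  aa2 <- alongaway_table(aa$y_values, aa$z_values, 2 * aa$values)
  ex2 <- extract_anisotropy(aa2, eng$source, eng$g)
  expect_equal(ex2$F, 2 * ex1$F, tolerance = 1e-13)
})

test_that("points inside the singular zone are skipped with a message", {
  eng <- fix_engines()$reference
  aa <- make_alongaway(eng, y_values = c(0.5, 1), z_values = c(-1, 1))
  # extract with a wider exclusion than the generator used
  aa_close <- make_alongaway(eng, y_values = c(0.4, 1), z_values = c(-0.1, 0.1))
  expect_message(
    ex <- extract_anisotropy(aa_close, eng$source, eng$g,
                             exclusion_radius = 0.5),
    "skipped")
  expect_true(all(ex$r > 0.5))
  expect_silent(extract_anisotropy(aa, eng$source, eng$g))
})

test_that("ODIN detection classifies, bands and covers correctly", {
  angles <- seq(0, 180, by = 3)
  radii <- c(1, 2, 3)
  z <- matrix(0, 3, length(angles))
  d0 <- diff_map(z, "polar", radii, angles)
  rep0 <- odin_detect(d0)
  expect_equal(rep0$n_flagged, 0L)
  expect_equal(rep0$coverage_fraction, 0)

  # one intervention-level band near the cable pole
  v <- z; v[, angles >= 6 & angles <= 12] <- -6
  rep1 <- odin_detect(diff_map(v, "polar", radii, angles))
  expect_equal(length(rep1$bands), 1L)
  expect_equal(rep1$n_intervention, rep1$n_flagged)

  # bands exactly [0,15] U [165,180] -> 30/180 of the angular domain
  v2 <- z; v2[, angles <= 15 | angles >= 165] <- 3
  rep2 <- odin_detect(diff_map(v2, "polar", radii, angles))
  expect_equal(length(rep2$bands), 2L)
  expect_equal(rep2$bands[[1]], c(0, 15))
  expect_equal(rep2$bands[[2]], c(165, 180))
  expect_equal(rep2$coverage_fraction, 30 / 180, tolerance = 1e-12)
})

test_that("raising the investigation level never adds flagged cells", {
  eng <- fix_engines()
  back <- resample_table(eng$vendor_table, eng$dense$radii, eng$dense$angles,
                         "reference")
  d <- compare_tables(eng$dense, back, denominator = "a")
  n_prev <- Inf
  for (lev in c(1, 2, 3, 5, 8)) {
    n <- odin_detect(d, investigation = lev, intervention = 10)$n_flagged
    expect_lte(n, n_prev)
    n_prev <- n
  }
})
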