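test_that("zero pole amplitudes give an isotropic table", {
  spec <- fix_spec(A_cable = 0, A_tip = 0)
  tb <- make_reference_anisotropy(spec)
  expect_true(all(abs(tb$values - 1) < 1e-14))
})

test_that("the synthetic F is exactly 1 on the transverse axis", {
  tb <- fix_dense()
  i90 <- which(tb$angles == 90)
  expect_length(i90, 1L)
  expect_true(all(tb$values[, i90] == 1))
  expect_true(all(tb$values > 0 & tb$values <= 1.05))
})

test_that("linear interpolation across the cable gap underestimates F", {
  # the ODIN mechanism, by direct evaluation of the generating function
  spec <- fix_spec(A_cable = 0.55, w_cable = 6)
  f <- function(th) synthetic_anisotropy_value(spec, 3, th)
  interp7 <- f(1.5) + (f(15) - f(1.5)) * (7 - 1.5) / (15 - 1.5)
  expect_lt((interp7 - f(7)) / f(7), -0.05)
})

test_that("the vendor subsample has the mandated sparse structure", {
  dense <- fix_dense()
  vendor <- subsample_vendor(dense)
  expect_length(vendor$angles, 17L)
  expect_length(vendor$radii, 10L)
  expect_true(all(c(0, 180) %in% vendor$angles))
  # no samples strictly inside the pole-side gaps
  expect_false(any(vendor$angles > 1.5 & vendor$angles < 25.5))
  expect_false(any(vendor$angles > 155.5 & vendor$angles < 178.5))
  # the pole rows equal the linear extrapolation of the dense table
  expect_equal(vendor$values[, 1], pole_extrapolate(dense, vendor$radii, 0),
               tolerance = 1e-13)
  expect_equal(vendor$values[, 17], pole_extrapolate(dense, vendor$radii, 180),
               tolerance = 1e-13)
})

test_that("subsampling onto the dense table's own axes is the identity", {
  dense <- fix_dense()
  same <- subsample_vendor(dense, angles = dense$angles, radii = dense$radii)
  expect_equal(same$values, dense$values, tolerance = 1e-14)
})

test_that("vendor-vs-reference discrepancies localise to the gap bands", {
  dense <- fix_dense()
  vendor <- subsample_vendor(dense)
  back <- resample_table(vendor, dense$radii, dense$angles, "reference")
  d <- compare_tables(dense, back, denominator = "a")
  gaps <- vendor_gap_bands(vendor)
  expect_length(gaps, 2L)
  flagged <- odin_detect(d)$flagged
  expect_gt(nrow(flagged), 0)
  in_gap <- vapply(flagged$theta, function(th)
    any(vapply(gaps, function(b) th >= b[1] && th <= b[2], logical(1))),
    logical(1))
  expect_true(all(in_gap))
  # the worst underestimate in the widest gap exceeds 10%
  expect_lt(min(d$values), -10)
})

test_that("the generator is deterministic under a fixed seed", {
  s1 <- fix_spec(noise_sd = 0.002, seed = 42L)
  s2 <- fix_spec(noise_sd = 0.002, seed = 42L)
  s3 <- fix_spec(noise_sd = 0.002, seed = 43L)
  expect_identical(make_reference_anisotropy(s1)$values,
                   make_reference_anisotropy(s2)$values)
  expect_false(identical(make_reference_anisotropy(s1)$values,
                         make_reference_anisotropy(s3)$values))
  # and does not disturb the caller's RNG stream
  set.seed(5); before <- runif(1)
  set.seed(5); invisible(make_reference_anisotropy(s1)); after <- runif(1)
  expect_identical(before, after)
})

test_that("the default along-away grid has 362 valid points and Lambda at r0", {
  eng <- fix_engines()$reference
  aa <- make_alongaway(eng)
  expect_equal(aa$n_points, 362L)
  aa0 <- make_alongaway(eng, y_values = c(1, 2), z_values = c(-1, 0, 1))
  expect_equal(aa0$values[2, 1],
               eng$source$dose_rate_constant_Lambda, tolerance = 1e-12)
})

test_that("radial models are normalised by construction", {
  expect_equal(radial_dose(c(0.5, 1, 7), make_radial_model("flat")),
               c(1, 1, 1))
  expect_equal(radial_dose(1, make_radial_model("polynomial")), 1,
               tolerance = 1e-12)
  expect_equal(radial_dose(1, make_radial_model("table")), 1,
               tolerance = 1e-12)
})

test_that("a degree-4 fit to a sampled table recovers the coefficients", {
  g <- make_radial_model("polynomial")
  radii <- c(0.5, 1, 1.5, 2, 3, 4, 5, 7, 10, 12, 15)
  gv <- radial_dose(radii, g)
  fit <- stats::lm.fit(outer(radii, 0:4, "^"), gv)
  expect_equal(unname(fit$coefficients), g$coefficients, tolerance = 1e-8)
})
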