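test_that("lookup at tabulated nodes is the identity", {
  tb <- fix_dense()
  qs <- expand.grid(i = seq_along(tb$radii), j = seq_along(tb$angles))
  got <- anisotropy_lookup(tb$radii[qs$i], tb$angles[qs$j], tb)
  expect_equal(got, tb$values[cbind(qs$i, qs$j)], tolerance = 1e-14)
})

test_that("bilinear midpoint of a cell averages the four corners", {
  tb <- anisotropy_table(c(1, 2), c(80, 100),
                         matrix(c(0.4, 0.4, 0.6, 0.6), 2, 2))
  expect_equal(anisotropy_lookup(1.5, 90, tb), 0.5, tolerance = 1e-14)
})

test_that("interpolated values stay inside the enclosing-cell bounds", {
  set.seed(11)
  radii <- sort(runif(8, 0.5, 10))
  angles <- sort(runif(12, 5, 175))
  vals <- matrix(runif(8 * 12, 0.4, 1.0), 8, 12)
  tb <- anisotropy_table(radii, angles, vals)
  rq <- seq(min(radii), max(radii), length.out = 50)
  aq <- seq(min(angles), max(angles), length.out = 50)
  for (a in aq) {
    v <- anisotropy_lookup(rq, a, tb)
    i <- pmin(pmax(findInterval(rq, radii, rightmost.closed = TRUE), 1L), 7L)
    j <- pmin(pmax(findInterval(a, angles, rightmost.closed = TRUE), 1L), 11L)
    lo <- pmin(vals[cbind(i, j)], vals[cbind(i, j + 1L)],
               vals[cbind(i + 1L, j)], vals[cbind(i + 1L, j + 1L)])
    hi <- pmax(vals[cbind(i, j)], vals[cbind(i, j + 1L)],
               vals[cbind(i + 1L, j)], vals[cbind(i + 1L, j + 1L)])
    expect_true(all(v >= lo - 1e-12 & v <= hi + 1e-12))
  }
})

test_that("pole extrapolation is the line through the two nearest angles", {
  tb <- anisotropy_table(c(1, 2), c(3, 6, 174, 177),
                         matrix(c(0.52, 0.52, 0.56, 0.56,
                                  0.60, 0.60, 0.58, 0.58), 2, 4))
  expect_equal(pole_extrapolate(tb, 1, 0), 0.48, tolerance = 1e-12)
  expect_equal(pole_extrapolate(tb, 1, 180), 0.56, tolerance = 1e-12)
  # lookup beyond the angular range uses the same linear extrapolation
  expect_equal(anisotropy_lookup(1, 0, tb), 0.48, tolerance = 1e-12)
  expect_equal(anisotropy_lookup(1, 180, tb), 0.56, tolerance = 1e-12)
})

test_that("pole extrapolation is floored to stay positive", {
  tb <- anisotropy_table(c(1, 2), c(30, 60),
                         matrix(c(0.05, 0.05, 0.9, 0.9), 2, 2))
  expect_equal(pole_extrapolate(tb, 1, 0), 1e-3)     # raw line goes negative
  expect_error(pole_extrapolate(tb, 1, 90), "0 or 180")
})

test_that("radii outside the tabulated range are clamped", {
  tb <- fix_dense()
  expect_equal(anisotropy_lookup(0.1, 90, tb),
               anisotropy_lookup(min(tb$radii), 90, tb))
  expect_equal(anisotropy_lookup(50, 45, tb),
               anisotropy_lookup(max(tb$radii), 45, tb))
})

test_that("table invariants are enforced", {
  expect_error(anisotropy_table(c(2, 1), c(10, 20), matrix(1, 2, 2)),
               "increasing")
  expect_error(anisotropy_table(1, c(10, 20), matrix(c(1, -1), 1, 2)),
               "positive")
  expect_error(anisotropy_table(c(1, 2), c(10, 20), matrix(1, 3, 2)),
               "matrix")
  expect_error(anisotropy_table(1, c(45, 90), matrix(c(0.9, 0.95), 1, 2)),
               "90 deg")
  expect_error(anisotropy_table(numeric(0), c(1), matrix(0, 0, 1)), "empty")
})
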