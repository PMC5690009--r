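test_that("the half-star pattern probes both pole-gradient zones", {
  p <- half_star_pattern()
  expect_length(p$ray_angles, 6L)
  expect_true(any(p$ray_angles > 0 & p$ray_angles < 15))
  expect_true(any(p$ray_angles > 165 & p$ray_angles < 180))
  expect_equal(nrow(p$points), 18L)   # 6 rays x 3 radii
  expect_identical(p$symmetry, "none")
  expect_error(half_star_pattern(low_ray = 15), "\\(0, 15\\)")
  expect_error(half_star_pattern(high_ray = 180), "\\(165, 180\\)")

  # every pattern point survives a polar -> cartesian -> polar round trip
  off_pole <- p$points[p$points$theta > 0 & p$points$theta < 180, ]
  xy <- polar_to_cartesian(off_pole$r, off_pole$theta)
  back <- cartesian_to_polar(xy$y, xy$z)
  expect_equal(back$r, off_pole$r, tolerance = 1e-12)
  expect_equal(back$theta, off_pole$theta, tolerance = 1e-12)
})

test_that("legacy patterns have the pole blind spot", {
  for (kind in c("ncs", "estro")) {
    p <- legacy_pattern(kind)
    expect_false(any(p$ray_angles > 0 & p$ray_angles < 15))
    expect_identical(p$symmetry, "transverse-mirror")
    expect_equal(nrow(p$points),
                 length(p$ray_angles) * length(p$radii))
  }
})

test_that("identical engines produce a clean report", {
  eng <- fix_engines()$reference
  rep <- evaluate_pattern(half_star_pattern(), eng, eng)
  expect_true(all(rep$diff_pct == 0))
  expect_true(all(rep$level == "ok"))
  expect_identical(attr(rep, "exit_status"), 0L)
  expect_equal(nrow(rep), 18L)
})

test_that("a constructed cable-side defect is flagged by the half-star only", {
  src <- fix_source(); g <- fix_g()
  dense <- fix_dense()
  # engine B: a deep underdose confined to the 9 and 12 degree samples, so
  # the 7 degree half-star ray sees about -6.7% while the poles (whose
  # values extrapolate from the untouched 3 and 6 degree samples) stay clean
  depress <- ifelse(dense$angles %in% c(9, 12), 0.80, 1)
  b_tab <- anisotropy_table(dense$radii, dense$angles,
                            sweep(dense$values, 2, depress, "*"), "defect")
  ea <- tg43_engine(src, g, dense, label = "a")
  eb <- tg43_engine(src, g, b_tab, label = "b")
  star <- evaluate_pattern(half_star_pattern(), ea, eb)
  expect_identical(attr(star, "exit_status"), 4L)
  flagged <- star[star$level == "intervention", ]
  expect_true(all(flagged$theta < 15))
  for (kind in c("ncs", "estro")) {
    leg <- evaluate_pattern(legacy_pattern(kind), ea, eb)
    expect_identical(attr(leg, "exit_status"), 0L)
  }
})

test_that("domain errors at single points do not abort the report", {
  eng <- fix_engines()$reference
  p <- qa_pattern("tight", c(0, 90), c(0.2, 1))   # r = 0.2 is inside L/2
  rep <- evaluate_pattern(p, eng, eng)
  expect_equal(nrow(rep), 4L)
  expect_true(any(is.na(rep$diff_pct)))
  expect_true(any(rep$diff_pct == 0, na.rm = TRUE))
})

test_that("legacy patterns under-report the synthetic vendor defect", {
  eng <- fix_engines()
  star <- evaluate_pattern(half_star_pattern(), eng$reference, eng$vendor)
  ncs <- evaluate_pattern(legacy_pattern("ncs"), eng$reference, eng$vendor)
  estro <- evaluate_pattern(legacy_pattern("estro"), eng$reference, eng$vendor)
  expect_gt(max(abs(star$diff_pct)),
            max(abs(ncs$diff_pct), abs(estro$diff_pct)))
  expect_identical(attr(star, "exit_status"), 4L)
  expect_identical(attr(ncs, "exit_status"), 0L)
  expect_identical(attr(estro, "exit_status"), 0L)
})
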