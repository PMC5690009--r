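# shared fixtures: default source, radial model, synthetic table pair

fix_source <- function() source_model()

fix_g <- function() make_radial_model("polynomial")

fix_spec <- function(...) synthetic_anisotropy_spec(...)

fix_dense <- function(spec = fix_spec()) make_reference_anisotropy(spec)

fix_vendor <- function(dense = fix_dense()) subsample_vendor(dense)

fix_engines <- function(spec = fix_spec()) {
  dense <- make_reference_anisotropy(spec)
  vendor <- subsample_vendor(dense)
  list(
    reference = tg43_engine(fix_source(), fix_g(), dense, label = "reference"),
    vendor = tg43_engine(fix_source(), fix_g(), vendor, label = "vendor"),
    dense = dense, vendor_table = vendor
  )
}

# independent bilinear interpolation oracle: two successive 1-D linear
# interpolations (rows first, then across the two bracketing columns) —
# a different construction than the package's four-corner-weight formula
oracle_bilinear <- function(ax_r, ax_c, V, qr, qc) {
  n <- max(length(qr), length(qc))
  qr <- rep_len(qr, n); qc <- rep_len(qc, n)
  out <- rep(NA_real_, n)
  nr <- length(ax_r); nc <- length(ax_c)
  ok <- qr >= ax_r[1] & qr <= ax_r[nr] & qc >= ax_c[1] & qc <= ax_c[nc]
  if (!any(ok)) return(out)
  qr <- qr[ok]; qc <- qc[ok]
  i <- pmin(pmax(findInterval(qr, ax_r), 1L), nr - 1L)
  j <- pmin(pmax(findInterval(qc, ax_c), 1L), nc - 1L)
  tz <- (qr - ax_r[i]) / (ax_r[i + 1L] - ax_r[i])
  lin_z <- function(jj) {
    lo <- V[cbind(i, jj)]
    lo + tz * (V[cbind(i + 1L, jj)] - lo)
  }
  vleft <- lin_z(j)
  vright <- lin_z(j + 1L)
  out[ok] <- vleft + (qc - ax_c[j]) / (ax_c[j + 1L] - ax_c[j]) * (vright - vleft)
  out
}

# brute-force gamma oracle: exhaustive minimisation on a dense candidate
# lattice (step_frac x DTA step within radius_factor x DTA), interpolating
# the evaluated plane with the independent oracle_bilinear
oracle_gamma <- function(reference, evaluated, dta_mm, dd_pct,
                         step_frac = 0.02, radius_factor = 3) {
  dta <- dta_mm / 10
  step <- step_frac * dta
  nst <- round(radius_factor * dta / step)
  offs <- seq(-nst, nst) * step
  cand <- expand.grid(dz = offs, dy = offs)
  cand <- cand[cand$dz^2 + cand$dy^2 <= (radius_factor * dta)^2 + 1e-12, ]
  out <- matrix(NA_real_, length(reference$z), length(reference$y))
  for (iz in seq_along(reference$z)) {
    for (iy in seq_along(reference$y)) {
      dref <- reference$values[iz, iy]
      if (!is.finite(dref)) next
      dq <- oracle_bilinear(evaluated$z, evaluated$y, evaluated$values,
                            reference$z[iz] + cand$dz,
                            reference$y[iy] + cand$dy)
      g2 <- (cand$dz^2 + cand$dy^2) / dta^2 +
            ((dq - dref) / (dd_pct / 100 * dref))^2
      out[iz, iy] <- sqrt(min(g2, na.rm = TRUE))
    }
  }
  out
}

# smooth 21x21 plane pair for gamma oracle comparisons; gradients are kept
# gentle relative to the dose criterion so the gamma surface is well
# resolved by both search lattices
fix_gamma_planes <- function(n_half = 10, spacing = 0.1) {
  ax <- seq(-n_half, n_half) * spacing
  yy <- matrix(ax, length(ax), length(ax), byrow = TRUE)
  zz <- matrix(ax, length(ax), length(ax))
  D <- 100 * exp(-(yy^2 + zz^2) / 1000)
  ratio <- 1 + 0.005 * sin(2 * pi * yy / 6) * cos(2 * pi * zz / 7) +
           0.002 * (yy - zz) / 2
  list(
    reference = dose_plane(ax, ax, D, spacing, label = "ref"),
    evaluated = dose_plane(ax, ax, D * ratio, spacing, label = "eval")
  )
}
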