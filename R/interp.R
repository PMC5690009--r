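# Bilinear interpolation on a regular (not necessarily uniform) grid.
# V is indexed V[row, col] with row coordinate ax_r and column coordinate
# ax_c, both strictly increasing. Queries outside the grid return NA; NA
# cells in V propagate to any query touching them.
bilinear_at <- function(ax_r, ax_c, V, qr, qc) {
  n <- max(length(qr), length(qc))
  qr <- rep_len(as.numeric(qr), n)
  qc <- rep_len(as.numeric(qc), n)
  out <- rep(NA_real_, n)
  nr <- length(ax_r); nc <- length(ax_c)
  ok <- is.finite(qr) & is.finite(qc) &
    qr >= ax_r[1] & qr <= ax_r[nr] & qc >= ax_c[1] & qc <= ax_c[nc]
  if (!any(ok)) return(out)
  i <- pmin(pmax(findInterval(qr[ok], ax_r, rightmost.closed = TRUE), 1L), nr - 1L)
  j <- pmin(pmax(findInterval(qc[ok], ax_c, rightmost.closed = TRUE), 1L), nc - 1L)
  wr <- (qr[ok] - ax_r[i]) / (ax_r[i + 1L] - ax_r[i])
  wc <- (qc[ok] - ax_c[j]) / (ax_c[j + 1L] - ax_c[j])
  out[ok] <- (1 - wr) * (1 - wc) * V[cbind(i, j)] +
             (1 - wr) * wc       * V[cbind(i, j + 1L)] +
             wr       * (1 - wc) * V[cbind(i + 1L, j)] +
             wr       * wc       * V[cbind(i + 1L, j + 1L)]
  out
}

# Tensor-product bilinear interpolation: interpolate V (rows ~ ax_r, cols ~
# ax_c) at the full outer grid qr x qc. Returns a length(qr) x length(qc)
# matrix with NA outside the domain. Much faster than bilinear_at for the
# shifted-grid lookups of the gamma search.
bilinear_grid <- function(ax_r, ax_c, V, qr, qc) {
  nr <- length(ax_r); nc <- length(ax_c)
  axw <- function(ax, q, nmax) {
    ok <- q >= ax[1] & q <= ax[nmax]
    i <- pmin(pmax(findInterval(q, ax, rightmost.closed = TRUE), 1L), nmax - 1L)
    w <- (q - ax[i]) / (ax[i + 1L] - ax[i])
    w[!ok] <- NA_real_
    list(i = i, w = w)
  }
  a <- axw(ax_r, qr, nr)
  b <- axw(ax_c, qc, nc)
  W00 <- outer(1 - a$w, 1 - b$w)
  W01 <- outer(1 - a$w, b$w)
  W10 <- outer(a$w, 1 - b$w)
  W11 <- outer(a$w, b$w)
  W00 * V[a$i, b$i, drop = FALSE] + W01 * V[a$i, b$i + 1L, drop = FALSE] +
  W10 * V[a$i + 1L, b$i, drop = FALSE] + W11 * V[a$i + 1L, b$i + 1L, drop = FALSE]
}
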