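#' 2D anisotropy function table F(r, theta)
#'
#' The 2D anisotropy function gives the angular variation of dose about the
#' source relative to the transverse axis, normalised to F(r, 90 deg) = 1.
#' Real tables for cable-driven HDR sources show steep gradients within about
#' 15 degrees of both poles, steeper on the cable side where the drive cable
#' perturbs the medium.
#'
#' @param radii strictly increasing radii, cm.
#' @param angles strictly increasing polar angles, degrees in \[0, 180\].
#' @param values matrix of F values, dimension `length(radii)` x
#'   `length(angles)`, all positive.
#' @param provenance free-text label recording where the table came from
#'   (e.g. `"vendor"`, `"reference"`, `"int-vendor2reference"`).
#' @return An object of class `anisotropy_table`.
#' @export
anisotropy_table <- function(radii, angles, values, provenance = "") {
  radii <- as.numeric(radii)
  angles <- as.numeric(angles)
  values <- as.matrix(values)
  if (length(radii) < 1L || length(angles) < 1L)
    stop("empty anisotropy table")
  if (any(diff(radii) <= 0)) stop("radii must be strictly increasing")
  if (any(diff(angles) <= 0)) stop("angles must be strictly increasing")
  if (any(angles < 0 | angles > 180)) stop("angles must lie in [0, 180] degrees")
  if (!all(dim(values) == c(length(radii), length(angles))))
    stop(sprintf("values must be a %d x %d matrix (radii x angles)",
                 length(radii), length(angles)))
  if (any(!is.finite(values)) || any(values <= 0))
    stop("all F values must be finite and positive")
  i90 <- which(abs(angles - 90) < 1e-9)
  if (length(i90) == 1L && any(abs(values[, i90] - 1) > 1e-3))
    stop("F(r, 90 deg) must equal 1 within 1e-3 for all radii")
  structure(
    list(radii = radii, angles = angles, values = values,
         provenance = provenance),
    class = "anisotropy_table"
  )
}

#' Bilinear anisotropy lookup with pole extrapolation
#'
#' Bilinear interpolation of F(r, theta) on the table grid. Queries at
#' tabulated nodes return the stored values exactly. Radii outside the
#' tabulated range are clamped to the nearest tabulated radius (the common
#' TPS behaviour). Angles beyond the tabulated angular range are linearly
#' extrapolated from the two tabulated angles nearest that pole and floored
#' at `pole_floor` to preserve positivity — at theta = 0 or 180 this is
#' exactly [pole_extrapolate()].
#'
#' @param r query radii, cm (vectorised).
#' @param theta query angles, degrees in \[0, 180\] (recycled against `r`).
#' @param table an [anisotropy_table()].
#' @param pole_floor minimum value returned by angular extrapolation.
#' @return interpolated F values, dimensionless.
#' @export
anisotropy_lookup <- function(r, theta, table, pole_floor = 1e-3) {
  stopifnot(inherits(table, "anisotropy_table"))
  n <- max(length(r), length(theta))
  r <- rep_len(as.numeric(r), n)
  theta <- rep_len(as.numeric(theta), n)
  if (any(theta < 0 | theta > 180))
    stop("theta outside [0, 180] degrees")
  rr <- table$radii
  aa <- table$angles
  V <- table$values
  nr <- length(rr)
  na <- length(aa)

  rq <- pmin(rr[nr], pmax(rr[1], r))     # radial clamp
  if (nr > 1L) {
    i <- pmin(pmax(findInterval(rq, rr, rightmost.closed = TRUE), 1L), nr - 1L)
    wr <- (rq - rr[i]) / (rr[i + 1L] - rr[i])
    i2 <- i + 1L
  } else {
    i <- rep(1L, n); i2 <- i; wr <- rep(0, n)
  }
  if (na > 1L) {
    j <- pmin(pmax(findInterval(theta, aa, rightmost.closed = TRUE), 1L), na - 1L)
    # weights outside [0,1] give the linear pole extrapolation through the
    # two tabulated angles nearest the relevant end
    wa <- (theta - aa[j]) / (aa[j + 1L] - aa[j])
    j2 <- j + 1L
  } else {
    j <- rep(1L, n); j2 <- j; wa <- rep(0, n)
  }
  v <- (1 - wr) * (1 - wa) * V[cbind(i, j)] +
       (1 - wr) * wa       * V[cbind(i, j2)] +
       wr       * (1 - wa) * V[cbind(i2, j)] +
       wr       * wa       * V[cbind(i2, j2)]
  outside <- theta < aa[1] | theta > aa[na]
  v[outside] <- pmax(v[outside], pole_floor)
  v
}

#' Linear pole extrapolation of an anisotropy table
#'
#' Vendor software typically requires F entries at 0 and 180 degrees even
#' when the reference publication tabulates neither. This fills a pole value
#' by a first-order (linear) fit through the two tabulated angles nearest
#' that pole, evaluated at the pole, floored at `floor` to preserve
#' positivity.
#'
#' @param table an [anisotropy_table()].
#' @param r radius at which to extrapolate, cm (vectorised; clamped to the
#'   tabulated radial range).
#' @param target_theta 0 or 180 (degrees).
#' @param floor positivity floor (default 1e-3).
#' @return extrapolated F value(s) at the pole.
#' @export
pole_extrapolate <- function(table, r, target_theta, floor = 1e-3) {
  stopifnot(inherits(table, "anisotropy_table"))
  if (!target_theta %in% c(0, 180))
    stop("target_theta must be 0 or 180 degrees")
  aa <- table$angles
  na <- length(aa)
  if (na < 2L)
    stop("need at least two tabulated angles on that side of the table")
  if (target_theta == 0) {
    a1 <- aa[1]; a2 <- aa[2]
  } else {
    a1 <- aa[na - 1L]; a2 <- aa[na]
  }
  f1 <- anisotropy_lookup(r, a1, table)
  f2 <- anisotropy_lookup(r, a2, table)
  v <- f1 + (f2 - f1) * (target_theta - a1) / (a2 - a1)
  pmax(v, floor)
}

#' @export
print.anisotropy_table <- function(x, ...) {
  cat(sprintf("2D anisotropy table F(r,theta)%s\n",
              if (nzchar(x$provenance)) paste0(" [", x$provenance, "]") else ""))
  cat(sprintf("  %d radii: %g .. %g cm\n", length(x$radii),
              min(x$radii), max(x$radii)))
  cat(sprintf("  %d angles: %g .. %g deg\n", length(x$angles),
              min(x$angles), max(x$angles)))
  cat(sprintf("  F range: %.4f .. %.4f\n", min(x$values), max(x$values)))
  invisible(x)
}
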